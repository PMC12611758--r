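# Synthetic reference genomes with clean gene models.

codons_no_stop <- function() {
  gc <- genetic_code()
  names(gc)[gc != "*"]
}

#' Simulate a reference genome with gene models
#'
#' Builds one contig per gene: `pad` bases of intergenic flank, then CDS
#' exons (random non-stop codons, ATG start, stop codon last) separated by
#' random introns. Strands alternate +/- so strand handling is exercised.
#'
#' @param n_genes number of genes.
#' @param n_exons CDS exons per gene.
#' @param exon_len bases per exon (total CDS is rounded to a codon multiple).
#' @param intron_len intron length.
#' @param pad intergenic flank per contig end.
#' @param seed integer seed.
#' @return list with `genome` (a `genome_ref`), `genes` (a `gene_models`
#'   tibble) and `panel` (gene footprints plus 10 bp flanks).
#' @export
sim_genome <- function(n_genes = 10, n_exons = 2, exon_len = 150,
                       intron_len = 60, pad = 60, seed = 1) {
  with_seed(substream_seed(seed, "genome"), {
    cds_len <- (n_exons * exon_len) %/% 3 * 3
    n_codons <- cds_len %/% 3
    pool <- codons_no_stop()
    stops <- c("TAA", "TAG", "TGA")
    contigs <- character(n_genes)
    names(contigs) <- paste0("g", seq_len(n_genes))
    starts_l <- vector("list", n_genes)
    ends_l <- vector("list", n_genes)
    strands <- rep(c("+", "-"), length.out = n_genes)
    rand_seq <- function(n) {
      paste(sample(the_bases, n, replace = TRUE), collapse = "")
    }
    for (i in seq_len(n_genes)) {
      cds <- paste(c("ATG", sample(pool, n_codons - 2, replace = TRUE),
                     sample(stops, 1)), collapse = "")
      # split into exons (coding order)
      per <- cds_len %/% n_exons
      cuts <- c(seq(0, by = per, length.out = n_exons), cds_len)
      pieces <- vapply(seq_len(n_exons), function(j) {
        substr(cds, cuts[j] + 1, cuts[j + 1])
      }, character(1))
      if (strands[i] == "-") pieces <- rev(revcomp(pieces))
      seq_parts <- character(0)
      es <- integer(0)
      ee <- integer(0)
      at <- pad
      seq_parts <- rand_seq(pad)
      for (j in seq_len(n_exons)) {
        es <- c(es, at)
        ee <- c(ee, at + nchar(pieces[j]))
        seq_parts <- paste0(seq_parts, pieces[j])
        at <- at + nchar(pieces[j])
        if (j < n_exons) {
          seq_parts <- paste0(seq_parts, rand_seq(intron_len))
          at <- at + intron_len
        }
      }
      seq_parts <- paste0(seq_parts, rand_seq(pad))
      contigs[i] <- seq_parts
      starts_l[[i]] <- es
      ends_l[[i]] <- ee
    }
    genome <- genome_ref(contigs)
    gm <- gene_models(names(contigs), names(contigs), strands, starts_l,
                      ends_l)
    list(genome = genome, genes = gm,
         panel = genes_panel(gm, flank = 10))
  })
}
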