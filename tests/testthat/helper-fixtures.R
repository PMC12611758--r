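# Shared fixtures, built in code.

# A hand-crafted two-exon gene on the + strand with known codons:
#   pad(12) | exon1 ATG GCT CAA GGA TTC | intron(24, GT...AG) |
#   exon2 ACT TGC CGA CTA TGA | pad(12)
toy_gene_fixture <- function() {
  exon1 <- "ATGGCTCAAGGATTC"
  intron <- "GTAAGTCCCCCCCCCCCCCCCCAG"
  exon2 <- "ACTTGCCGACTATGA"
  pad_l <- "TTCATCGAGCAT"
  pad_r <- "CGATGCAATGCA"
  seqs <- paste0(pad_l, exon1, intron, exon2, pad_r)
  genome <- genome_ref(c(chr1 = seqs))
  gm <- gene_models("TOY", "chr1", "+",
                    list(c(12L, 51L)), list(c(27L, 66L)))
  list(genome = genome, gm = gm,
       exon1 = c(12L, 27L), intron = c(27L, 51L), exon2 = c(51L, 66L))
}

# Mirror a single-contig fixture onto the minus strand.
mirror_fixture <- function(fx) {
  L <- nchar(unclass(fx$genome)[["chr1"]])
  genome <- genome_ref(c(chr1 = revcomp(unclass(fx$genome)[["chr1"]])))
  starts <- rev(L - fx$gm$exon_ends[[1]])
  ends <- rev(L - fx$gm$exon_starts[[1]])
  gm <- gene_models(fx$gm$gene_id, "chr1", "-", list(starts), list(ends))
  list(genome = genome, gm = gm, L = L)
}

# Build a read-bundle tibble by hand: one molecule sequence per strand,
# replicated into k reads, with optional per-read overrides.
make_bundle <- function(bundle_id, contig, frag_start, seq_a, seq_b,
                        n_a = 2, n_b = 2, qual = 90, asxs = 50) {
  L <- nchar(seq_a)
  stopifnot(nchar(seq_b) == L)
  qual_chr <- function(q) {
    if (length(q) == 1) strrep(intToUtf8(q + 33L), L) else
      intToUtf8(q + 33L, multiple = FALSE)
  }
  rows <- list()
  for (i in seq_len(n_a)) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      bundle_id = bundle_id, contig = contig, frag_start = frag_start,
      frag_end = frag_start + L, strand = "A",
      read_id = paste0("b", bundle_id, "A", i), seq = seq_a,
      qual = qual_chr(qual), asxs = asxs)
  }
  for (i in seq_len(n_b)) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      bundle_id = bundle_id, contig = contig, frag_start = frag_start,
      frag_end = frag_start + L, strand = "B",
      read_id = paste0("b", bundle_id, "B", i), seq = seq_b,
      qual = qual_chr(qual), asxs = asxs)
  }
  dplyr::bind_rows(rows)
}

mutate_at_offset <- function(seq, offset1, base) {
  substr(seq, offset1, offset1) <- base
  seq
}

# Uniform coverage over all distinct sites of a site table.
uniform_coverage <- function(sites, depth) {
  out <- dplyr::distinct(tibble::as_tibble(sites)[, c("contig", "pos")])
  out$depth <- depth
  out
}

# Small neutral simulation shared by selection tests: returns cfg and grid.
neutral_sim_fixture <- function(n_genes = 40, exon_len = 300, seed = 17,
                                mut_rate = 3e-5, drivers = NULL) {
  sg <- sim_genome(n_genes = n_genes, n_exons = 1, exon_len = exon_len,
                   pad = 30, seed = seed)
  cfg <- sim_config(sg$genome, sg$genes, mut_rate = mut_rate,
                    germline_density = 0, drivers = drivers, seed = seed)
  list(sg = sg, cfg = cfg, grid = site_rate_grid(cfg))
}

# Every site of a genome as a (contig, pos) tibble.
panel_sites_all <- function(genome) {
  dplyr::bind_rows(lapply(names(genome), function(ctg) {
    tibble::tibble(contig = ctg,
                   pos = seq_len(nchar(unclass(genome)[[ctg]])) - 1L)
  }))
}
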