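# Mutation consequence annotation.

#' Mutation consequence classes
#'
#' Every variant maps to exactly one class per overlapping gene.
#'
#' @return character vector of the 13 impact class names.
#' @export
impact_classes <- function() {
  c("synonymous", "missense", "nonsense", "stop_loss", "essential_splice",
    "intronic_near_splice", "intronic_other", "utr5", "utr3", "promoter",
    "noncoding_other", "indel_coding", "indel_noncoding")
}

alt_bases_for <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                      G = c("A", "C", "T"), T = c("A", "C", "G"))

genetic_code <- function() Biostrings::GENETIC_CODE

codon_impact <- function(aa_ref, aa_alt) {
  dplyr::case_when(
    aa_ref == aa_alt ~ "synonymous",
    aa_alt == "*" ~ "nonsense",
    aa_ref == "*" ~ "stop_loss",
    TRUE ~ "missense"
  )
}

# Distance-based intronic class: d is 1 for the intronic base adjacent to an
# exon. The two bases flanking each CDS exon boundary are essential splice
# sites; bases 3..splice_window are "intronic near splice".
intron_class <- function(d, splice_window) {
  dplyr::case_when(
    d <= 2 ~ "essential_splice",
    d <= splice_window ~ "intronic_near_splice",
    TRUE ~ "intronic_other"
  )
}

in_intervals <- function(pos, mat) {
  if (is.null(mat) || length(mat) == 0) return(rep(FALSE, length(pos)))
  out <- rep(FALSE, length(pos))
  for (r in seq_len(nrow(mat))) {
    out <- out | (pos >= mat[r, 1] & pos < mat[r, 2])
  }
  out
}

#' Annotate the consequence of variants in one gene
#'
#' Assigns each variant exactly one impact class with respect to a gene
#' model: coding consequences through the genetic code, the two intronic
#' bases flanking each CDS exon boundary as essential splice sites, a
#' configurable window beyond them as "intronic near splice", annotated
#' UTR/promoter intervals when present, and `noncoding_other` outside the
#' gene span. Indels map to `indel_coding`/`indel_noncoding`.
#'
#' @param variants tibble with columns `contig`, `pos` (0-based), `ref`,
#'   `alt`.
#' @param gene one row of a [gene_models()] tibble (or the tibble plus
#'   `gene_id=`).
#' @param genome a `genome_ref`; SNV `ref` alleles are checked against it.
#' @param gene_id gene to annotate against when `gene` has several rows.
#' @param splice_window outer bound (in bp from the exon edge) of the
#'   intronic-near-splice class; default 10.
#' @return character vector of impact classes, one per variant.
#' @export
annotate_impact <- function(variants, gene, genome, gene_id = NULL,
                            splice_window = 10) {
  if (!is.null(gene_id)) gene <- gene_row(gene, gene_id)
  assert_that(nrow(gene) == 1, "gene must be a single gene-model row")
  v <- as_tibble(variants)
  assert_that(all(c("contig", "pos", "ref", "alt") %in% names(v)),
              "variants need columns contig, pos, ref, alt")
  n <- nrow(v)
  out <- rep(NA_character_, n)

  is_indel <- nchar(v$ref) != nchar(v$alt)
  span <- gene_span(gene)
  cds_pos <- cds_positions(gene)
  in_cds <- function(p) p %in% cds_pos

  # indels
  if (any(is_indel)) {
    idx <- which(is_indel)
    touches_cds <- map_lgl(idx, function(i) {
      lo <- v$pos[i]
      hi <- v$pos[i] + max(nchar(v$ref[i]), 1L)
      any(cds_pos >= lo & cds_pos < hi)
    })
    out[idx] <- ifelse(touches_cds & v$contig[idx] == gene$contig,
                       "indel_coding", "indel_noncoding")
  }

  snv <- which(!is_indel)
  if (length(snv) == 0) return(out)
  # reference check
  same_ctg <- v$contig[snv] == gene$contig
  gref <- rep(NA_character_, length(snv))
  gref[same_ctg] <- get_base(genome, gene$contig, v$pos[snv][same_ctg])
  bad <- same_ctg & gref != v$ref[snv]
  if (any(bad)) {
    abort(sprintf("ref allele mismatch with genome at %s:%d (genome %s, given %s)",
                  v$contig[snv][bad][1], v$pos[snv][bad][1],
                  gref[bad][1], v$ref[snv][bad][1]),
          class = "duplexome_ref_mismatch")
  }

  cds <- coding_sequence(gene, genome)
  gc <- genetic_code()
  k <- match(v$pos[snv], cds_pos)  # coding index or NA
  for (j in seq_along(snv)) {
    i <- snv[j]
    if (v$contig[i] != gene$contig) {
      out[i] <- "noncoding_other"
      next
    }
    if (!is.na(k[j])) {
      kk <- k[j]
      ci <- (kk - 1) %/% 3
      w <- (kk - 1) %% 3
      codon <- substr(cds, ci * 3 + 1, ci * 3 + 3)
      alt_coding <- if (gene$strand == "+") v$alt[i] else complement(v$alt[i])
      alt_codon <- codon
      substr(alt_codon, w + 1, w + 1) <- alt_coding
      out[i] <- codon_impact(unname(gc[codon]), unname(gc[alt_codon]))
      next
    }
    p <- v$pos[i]
    if (p >= span[1] && p < span[2]) {
      starts <- gene$exon_starts[[1]]
      ends <- gene$exon_ends[[1]]
      # distance to nearest exon edge within the containing intron
      d_right <- suppressWarnings(min((starts - p)[starts > p]))
      d_left <- suppressWarnings(min((p - ends + 1)[ends <= p]))
      d <- min(d_left, d_right)
      out[i] <- intron_class(d, splice_window)
      next
    }
    if ("utr5" %in% names(gene) && in_intervals(p, gene$utr5[[1]])) {
      out[i] <- "utr5"
    } else if ("utr3" %in% names(gene) && in_intervals(p, gene$utr3[[1]])) {
      out[i] <- "utr3"
    } else if ("promoter" %in% names(gene) &&
               in_intervals(p, gene$promoter[[1]])) {
      out[i] <- "promoter"
    } else {
      out[i] <- "noncoding_other"
    }
  }
  out
}

#' Enumerate every possible substitution in and around a gene
#'
#' The workhorse behind expected mutation counts, neutral-rate fitting and
#' site-level tests: one row per (site, alternate allele) with its impact
#' class and context channels. Coding sites cover the CDS; intronic sites
#' within `splice_window` of each exon boundary are included when
#' `include_flanks` is `TRUE`.
#'
#' @param gm a `gene_models` tibble (all rows are enumerated).
#' @param genome a `genome_ref`.
#' @param splice_window intronic window, as in [annotate_impact()].
#' @param include_flanks include splice-flank intronic sites.
#' @return tibble with columns `gene_id`, `contig`, `pos`, `ref`, `alt`,
#'   `impact`, `aa_change`, `channel96`, `channel192`.
#' @export
enumerate_gene_sites <- function(gm, genome, splice_window = 10,
                                 include_flanks = TRUE) {
  res <- lapply(seq_len(nrow(gm)), function(gi) {
    g <- gm[gi, ]
    cds_pos <- cds_positions(g)
    cds <- coding_sequence(g, genome)
    L <- length(cds_pos)
    gc <- genetic_code()
    k <- seq_len(L)
    ci <- (k - 1) %/% 3
    w <- (k - 1) %% 3
    codon <- substring(cds, ci * 3 + 1, ci * 3 + 3)
    ref_g <- get_base(genome, g$contig, cds_pos)
    aa_ref <- unname(gc[codon])

    pos3 <- rep(cds_pos, each = 3)
    ref3 <- rep(ref_g, each = 3)
    alt3 <- unlist(alt_bases_for[ref_g], use.names = FALSE)
    codon3 <- rep(codon, each = 3)
    w3 <- rep(w, each = 3)
    ci3 <- rep(ci, each = 3)
    aa_ref3 <- rep(aa_ref, each = 3)
    alt_coding3 <- if (g$strand == "+") alt3 else complement(alt3)
    alt_codon3 <- codon3
    substr(alt_codon3, w3 + 1, w3 + 1) <- alt_coding3
    aa_alt3 <- unname(gc[alt_codon3])
    impact3 <- codon_impact(aa_ref3, aa_alt3)
    coding <- tibble(
      gene_id = g$gene_id, contig = g$contig, pos = pos3, ref = ref3,
      alt = alt3, impact = impact3,
      aa_change = paste0(aa_ref3, ci3 + 1, aa_alt3)
    )

    flank <- NULL
    if (include_flanks && length(g$exon_starts[[1]]) > 1) {
      starts <- g$exon_starts[[1]]
      ends <- g$exon_ends[[1]]
      ipos <- integer(0)
      idist <- integer(0)
      for (j in seq_len(length(starts) - 1)) {
        i_lo <- ends[j]
        i_hi <- starts[j + 1]  # intron = [i_lo, i_hi)
        p <- seq(i_lo, i_hi - 1L)
        d <- pmin(p - i_lo + 1L, i_hi - p)
        keep <- d <= splice_window
        ipos <- c(ipos, p[keep])
        idist <- c(idist, d[keep])
      }
      if (length(ipos)) {
        dup <- duplicated(ipos)
        ipos <- ipos[!dup]
        idist <- idist[!dup]
        refs <- get_base(genome, g$contig, ipos)
        flank <- tibble(
          gene_id = g$gene_id, contig = g$contig,
          pos = rep(ipos, each = 3), ref = rep(refs, each = 3),
          alt = unlist(alt_bases_for[refs], use.names = FALSE),
          impact = rep(intron_class(idist, splice_window), each = 3),
          aa_change = NA_character_
        )
      }
    }
    bind_rows(coding, flank)
  })
  out <- bind_rows(res)
  ctx <- character(nrow(out))
  for (ctg in unique(out$contig)) {
    sel <- out$contig == ctg
    ctx[sel] <- get_context(genome, ctg, out$pos[sel], k = 1)
  }
  out$channel96 <- sbs96_channel(out$ref, out$alt, ctx)
  strand_of <- gm$strand[match(out$gene_id, gm$gene_id)]
  out$channel192 <- ifelse(is.na(out$channel96), NA_character_,
                           paste0(tsw_strand_code(out$ref, strand_of), ":",
                                  out$channel96))
  out
}

#' Context channel of variants
#'
#' Maps variants to a channel of the requested system. SBS96 collapses
#' purine-centred variants by reverse complement; TSW192 additionally records
#' whether the pyrimidine of the mutated pair lies on the transcribed or
#' untranscribed strand of the containing gene; PENTA_TC_256 uses a +/-2 bp
#' context restricted to T>C changes. Variants whose context contains N (or
#' that do not fit the system) return `NA` and are counted as exclusions by
#' [build_catalogue()].
#'
#' @param variants tibble with `contig`, `pos` (0-based), `ref`, `alt`.
#' @param genome a `genome_ref`.
#' @param system channel system (see [channel_labels()]).
#' @param gene_strand per-variant gene strand ("+"/"-"), required for TSW192.
#' @return character vector of channel labels (NA where excluded).
#' @export
context_channel <- function(variants, genome, system = "SBS96",
                            gene_strand = NULL) {
  system <- match.arg(system, channel_systems)
  v <- as_tibble(variants)
  get_ctx <- function(k) {
    ctx <- character(nrow(v))
    for (ctg in unique(v$contig)) {
      sel <- v$contig == ctg
      ctx[sel] <- get_context(genome, ctg, v$pos[sel], k = k)
    }
    ctx
  }
  switch(system,
    SBS96 = sbs96_channel(v$ref, v$alt, get_ctx(1)),
    TSW192 = {
      assert_that(!is.null(gene_strand),
                  "TSW192 channels need per-variant gene_strand")
      tsw192_channel(v$ref, v$alt, get_ctx(1), gene_strand)
    },
    PENTA_TC_256 = penta256_channel(v$ref, v$alt, get_ctx(2)),
    DBS78 = dbs78_channel(v$ref, v$alt),
    ID83 = id83_channel(genome, v$contig, v$pos, v$ref, v$alt)
  )
}
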