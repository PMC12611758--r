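# Sample-level quality control and contamination metrics.

#' Genotype common SNP sites from a pileup
#'
#' Genotypes are assigned by fixed VAF bins: hom-alt (1/1) above 0.8, het
#' (0/1) in [0.3, 0.7], hom-ref (0/0) below 0.1; sites with coverage below
#' `min_depth` or with VAFs between the bins are `missing`.
#'
#' @param pileup tibble with `contig`, `pos`, `depth`, `vaf` (alt VAF) per
#'   SNP site.
#' @param snp_sites optional tibble (`contig`, `pos`) restricting to a SNP
#'   list.
#' @param min_depth minimum depth to genotype (default 20).
#' @return the pileup with a `genotype` column in
#'   `c("hom_ref", "het", "hom_alt", "missing")`.
#' @export
genotype_sites <- function(pileup, snp_sites = NULL, min_depth = 20) {
  p <- as_tibble(pileup)
  if (!is.null(snp_sites)) {
    p <- inner_join(p, as_tibble(snp_sites)[, c("contig", "pos")],
                    by = c("contig", "pos"))
  }
  p$genotype <- dplyr::case_when(
    p$depth < min_depth ~ "missing",
    p$vaf > 0.8 ~ "hom_alt",
    p$vaf >= 0.3 & p$vaf <= 0.7 ~ "het",
    p$vaf < 0.1 ~ "hom_ref",
    TRUE ~ "missing"
  )
  p
}

#' Contamination metric from hom-alt SNP sites
#'
#' At non-reference homozygous SNP sites, any reference reads indicate DNA
#' from another individual. The metric is the median reference-base fraction
#' across hom-alt sites; samples with a median above `threshold` (strictly)
#' are flagged as contaminated.
#'
#' @param genotypes output of [genotype_sites()], with `ref_count` and
#'   `depth` columns (or `vaf`, from which the reference fraction is
#'   `1 - vaf`).
#' @param threshold flagging threshold on the median reference fraction.
#' @return tibble `median_ref_fraction`, `n_hom_alt_sites`, `flagged`,
#'   `needs_review` (no eligible sites).
#' @export
contamination_ref_fraction <- function(genotypes, threshold = 0.01) {
  g <- as_tibble(genotypes)
  g <- g[g$genotype == "hom_alt", ]
  if (nrow(g) == 0) {
    return(tibble(median_ref_fraction = NA_real_, n_hom_alt_sites = 0L,
                  flagged = FALSE, needs_review = TRUE))
  }
  rf <- if ("ref_count" %in% names(g)) g$ref_count / g$depth else 1 - g$vaf
  med <- median(rf)
  tibble(median_ref_fraction = med, n_hom_alt_sites = nrow(g),
         flagged = med > threshold, needs_review = FALSE)
}

#' Sample quality-control report
#'
#' Conjunctive pass/fail over the cohort rules: mean duplex coverage at least
#' `min_dx` (50 dx), contamination median reference fraction at most 0.01,
#' externally supplied non-human read fraction at most 0.25%, burden CI ratio
#' (upper/lower) at most 5, and genotype concordance with the expected donor
#' when supplied. Every failure cites its rule and threshold.
#'
#' @param metrics one-row tibble (or named list) with any of `mean_dx`,
#'   `contamination_ref_fraction`, `non_human_fraction`, `burden_ci_ratio`,
#'   `genotype_concordant`.
#' @param min_dx,max_contamination,max_non_human,max_burden_ci_ratio rule
#'   thresholds.
#' @return a `sample_qc` tibble row with `pass` and a `reasons` list-column.
#' @export
sample_qc <- function(metrics, min_dx = 50, max_contamination = 0.01,
                      max_non_human = 0.0025, max_burden_ci_ratio = 5) {
  m <- as.list(metrics)
  reasons <- character(0)
  chk <- function(value, ok, msg) {
    if (!is.null(value) && !is.na(value) && !ok) reasons <<- c(reasons, msg)
  }
  chk(m$mean_dx, isTRUE(m$mean_dx >= min_dx),
      sprintf("mean duplex coverage %.1f dx below %g dx", m$mean_dx, min_dx))
  chk(m$contamination_ref_fraction,
      isTRUE(m$contamination_ref_fraction <= max_contamination),
      sprintf("contamination median ref fraction %.4f above %g",
              m$contamination_ref_fraction, max_contamination))
  chk(m$non_human_fraction, isTRUE(m$non_human_fraction <= max_non_human),
      sprintf("non-human read fraction %.4f%% above %g%%",
              100 * m$non_human_fraction, 100 * max_non_human))
  chk(m$burden_ci_ratio, isTRUE(m$burden_ci_ratio <= max_burden_ci_ratio),
      sprintf("burden CI ratio %.2f above %g", m$burden_ci_ratio,
              max_burden_ci_ratio))
  chk(m$genotype_concordant, isTRUE(m$genotype_concordant),
      "genotypes discordant with expected donor")
  out <- tibble(
    mean_dx = m$mean_dx %||% NA_real_,
    contamination_ref_fraction = m$contamination_ref_fraction %||% NA_real_,
    non_human_fraction = m$non_human_fraction %||% NA_real_,
    burden_ci_ratio = m$burden_ci_ratio %||% NA_real_,
    genotype_concordant = m$genotype_concordant %||% NA,
    pass = length(reasons) == 0,
    reasons = list(reasons)
  )
  class(out) <- c("sample_qc", class(out))
  out
}

#' Per-sample passenger-gene global dN/dS
#'
#' A contamination diagnostic: cross-species contamination depletes
#' non-synonymous mutations (conserved sites), pulling the passenger dN/dS
#' below one, so per-sample omega can be compared against the non-human read
#' fraction.
#'
#' @param calls one sample's passing calls.
#' @param gm gene models.
#' @param rates a `rate_model`.
#' @param coverage coverage profile.
#' @param passenger_genes gene ids treated as passengers.
#' @param sites optional precomputed enumeration.
#' @param genome `genome_ref` if `sites` not given.
#' @return one-row tibble with pooled `omega`, CI and mutation count; warns
#'   when based on fewer than 10 mutations.
#' @export
passenger_global_dnds_per_sample <- function(calls, gm, rates, coverage,
                                             passenger_genes, sites = NULL,
                                             genome = NULL) {
  assert_that(nrow(as_tibble(calls)) > 0, "no calls for sample",
              class = "duplexome_empty_sample")
  cnt <- gene_counts(calls, gm, rates, coverage, genome = genome,
                     sites = sites)
  res <- global_dnds(cnt, gene_set = passenger_genes)
  res <- res[res$impact == "all_nonsynonymous", ]
  if (res$observed < 10) {
    warn("fewer than 10 mutations: per-sample dN/dS CI will be wide")
  }
  res
}
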