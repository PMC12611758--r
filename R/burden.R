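# Mutation burden estimation.
#
# Burden is the number of mutant duplex bases divided by the total number of
# duplex bases sequenced: every mutant molecule counts (mutations are not
# collapsed per site), which implicitly weights each mutation by its VAF and
# makes the estimate robust to clonal composition. A per-site-collapsed
# variant is available as an explicit lower-bound mode.

#' Estimate a mutation burden
#'
#' @param calls tibble of passing calls with `contig`, `pos`,
#'   `n_mutant_bundles` (e.g. [passing_calls()] output restricted to SNVs).
#' @param coverage coverage profile tibble (`contig`, `pos`, `depth`).
#' @param genome optional `genome_ref`; when given, a trinucleotide
#'   genome-corrected burden is reported (see [correct_burden_to_genome()]).
#' @param genome_freqs optional precomputed whole-genome
#'   [context_frequencies()]; computed from `genome` when missing.
#' @param method `"poisson"` for exact Poisson CIs, `"site_bootstrap"` for
#'   Poisson bootstrapping of mutant sites (wider CIs when single sites
#'   dominate).
#' @param passenger_genes optional character vector of gene ids; with
#'   `gene_models`, restricts calls and coverage to those gene footprints so
#'   burdens are estimated from passenger genes only.
#' @param gene_models `gene_models` tibble (needed with `passenger_genes`).
#' @param collapse_sites count each mutant site once (lower-bound mode).
#' @param n_boot bootstrap replicates.
#' @param conf_level CI level.
#' @param seed bootstrap seed.
#' @return a `burden_estimate`: tibble row with counts, raw and
#'   genome-corrected burdens and CI.
#' @export
estimate_burden <- function(calls, coverage, genome = NULL,
                            genome_freqs = NULL,
                            method = c("poisson", "site_bootstrap"),
                            passenger_genes = NULL, gene_models = NULL,
                            collapse_sites = FALSE, n_boot = 10000,
                            conf_level = 0.95, seed = 1) {
  method <- match.arg(method)
  calls <- as_tibble(calls)
  coverage <- as_tibble(coverage)
  if (!is.null(passenger_genes)) {
    assert_that(!is.null(gene_models),
                "passenger_genes requires gene_models")
    keep <- gene_models$gene_id %in% passenger_genes
    panel <- genes_panel(gene_models[keep, , drop = FALSE])
    calls <- calls[mask_covers(site_mask(as_tibble(panel)), calls$contig,
                               calls$pos), ]
    coverage <- coverage[mask_covers(site_mask(as_tibble(panel)),
                                     coverage$contig, coverage$pos), ]
  }
  n_duplex <- sum(coverage$depth)
  assert_that(n_duplex > 0, "zero duplex bases",
              class = "duplexome_empty_coverage")
  if (!"n_mutant_bundles" %in% names(calls)) calls$n_mutant_bundles <- 1L
  site_counts <- if (collapse_sites) {
    rep(1L, nrow(calls))
  } else {
    calls$n_mutant_bundles
  }
  n_mut <- sum(site_counts)
  raw <- n_mut / n_duplex
  alpha <- 1 - conf_level
  if (method == "poisson") {
    ci <- stats::poisson.test(n_mut, conf.level = conf_level)$conf.int / n_duplex
    lower <- ci[1]
    upper <- ci[2]
  } else {
    bs <- with_seed(substream_seed(seed, "burden_bootstrap"), {
      k <- length(site_counts)
      if (k == 0) {
        rep(0, n_boot)
      } else {
        w <- matrix(rpois(n_boot * k, 1), nrow = n_boot)
        as.vector(w %*% site_counts) / n_duplex
      }
    })
    lower <- unname(quantile(bs, alpha / 2))
    upper <- unname(quantile(bs, 1 - alpha / 2))
  }
  corrected <- NA_real_
  corr_factor <- 1
  if (!is.null(genome)) {
    if (is.null(genome_freqs)) genome_freqs <- context_frequencies(genome)
    corr <- correct_burden_to_genome(
      channel_counts = mutation_context_counts(calls, genome,
                                               weights = site_counts),
      channel_coverage = context_frequencies_trinuc(
        context_frequencies(genome, coverage)),
      genome_freqs = context_frequencies_trinuc(genome_freqs)
    )
    corrected <- corr
    corr_factor <- if (raw > 0) corrected / raw else 1
  }
  out <- tibble(n_mutant_bases = n_mut, n_duplex_bases = n_duplex,
                burden = raw, lower = lower, upper = upper,
                burden_corrected = corrected,
                lower_corrected = lower * corr_factor,
                upper_corrected = upper * corr_factor,
                method = method)
  class(out) <- c("burden_estimate", class(out))
  out
}

# Mutant-base counts per pyrimidine-centred trinucleotide context.
mutation_context_counts <- function(calls, genome, weights = NULL) {
  if (nrow(calls) == 0) {
    return(tibble(context = character(0), count = numeric(0)))
  }
  ctx <- character(nrow(calls))
  for (ctg in unique(calls$contig)) {
    sel <- calls$contig == ctg
    ctx[sel] <- get_context(genome, ctg, calls$pos[sel], 1)
  }
  pur <- substr(ctx, 2, 2) %in% c("A", "G")
  ctx[pur] <- revcomp(ctx[pur])
  w <- weights %||% rep(1, nrow(calls))
  keep <- !is.na(ctx) & !grepl("N", ctx, fixed = TRUE)
  summarise(group_by(tibble(context = ctx[keep], w = w[keep]),
                     .data$context),
            count = sum(.data$w), .groups = "drop")
}

#' Trinucleotide genome correction of a burden
#'
#' Computes `sum_t (m_t/n_t) F_t / sum_t F_t` over trinucleotide contexts
#' `t`, where `m_t` are mutant-base counts, `n_t` duplex-base coverage and
#' `F_t` whole-genome context frequencies: the burden the sample would show
#' if its sequence composition matched the genome. Contexts with zero
#' coverage and zero counts contribute nothing; counts without coverage are
#' an error.
#'
#' @param channel_counts tibble `context`, `count` (see
#'   [mutation_context_counts()]).
#' @param channel_coverage tibble `context`, `opportunity` — duplex coverage
#'   per context ([context_frequencies_trinuc()] of the coverage profile).
#' @param genome_freqs tibble `context`, `opportunity` — whole-genome
#'   context frequencies.
#' @return the genome-corrected burden (mutations per duplex base).
#' @export
correct_burden_to_genome <- function(channel_counts, channel_coverage,
                                     genome_freqs) {
  df <- left_join(rename(genome_freqs, F = "opportunity"),
                  rename(channel_coverage, n = "opportunity"),
                  by = "context")
  df <- left_join(df, rename(channel_counts, m = "count"), by = "context")
  df$n[is.na(df$n)] <- 0
  df$m[is.na(df$m)] <- 0
  assert_that(all(df$n > 0 | df$m == 0),
              "mutation counts in a zero-coverage context",
              class = "duplexome_zero_coverage_channel")
  rate <- ifelse(df$n > 0, df$m / df$n, 0)
  sum(rate * df$F) / sum(df$F)
}

#' Regress burdens on age
#'
#' Ordinary least squares of per-sample burden against donor age, with the
#' sample-QC rule that samples whose burden CI ratio (upper/lower) exceeds
#' `max_ci_ratio` are excluded before fitting.
#'
#' @param burdens tibble with columns `sample`, `age`, `burden` and
#'   optionally `lower`, `upper`.
#' @param max_ci_ratio exclusion threshold on upper/lower.
#' @param conf_level CI level for slope/intercept.
#' @return a `burden_regression` object (list with `fit`, `excluded`,
#'   `slope`, `intercept`, CIs and `r_squared`).
#' @export
regress_burden_on_age <- function(burdens, max_ci_ratio = 5,
                                  conf_level = 0.95) {
  df <- as_tibble(burdens)
  assert_that(all(c("age", "burden") %in% names(df)),
              "burdens needs age and burden columns")
  excluded <- character(0)
  if (all(c("lower", "upper") %in% names(df))) {
    ratio <- df$upper / df$lower
    bad <- is.finite(ratio) & ratio > max_ci_ratio
    bad[!is.finite(ratio)] <- df$lower[!is.finite(ratio)] <= 0
    excluded <- if ("sample" %in% names(df)) df$sample[bad] else
      as.character(which(bad))
    df <- df[!bad, ]
  }
  assert_that(nrow(df) >= 3, "need at least 3 samples after exclusions")
  assert_that(length(unique(df$age)) > 1, "ages are constant")
  fit <- lm(burden ~ age, data = df)
  ci <- confint(fit, level = conf_level)
  out <- list(fit = fit, excluded = excluded,
              slope = unname(coef(fit)["age"]),
              intercept = unname(coef(fit)["(Intercept)"]),
              slope_ci = unname(ci["age", ]),
              intercept_ci = unname(ci["(Intercept)", ]),
              r_squared = summary(fit)$r.squared,
              n = nrow(df))
  class(out) <- "burden_regression"
  out
}

#' @export
print.burden_regression <- function(x, ...) {
  cat("<burden_regression> slope ", signif(x$slope, 4), " [",
      signif(x$slope_ci[1], 4), ", ", signif(x$slope_ci[2], 4),
      "] per year; R^2 ", round(x$r_squared, 3), "; n = ", x$n,
      if (length(x$excluded)) paste0(" (", length(x$excluded),
                                     " excluded by CI-ratio rule)") else "",
      "\n", sep = "")
  invisible(x)
}
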