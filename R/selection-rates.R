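# Background mutation-rate model.
#
# The neutral model is Poisson with 192 strand-resolved trinucleotide
# substitution channel rates (per duplex base) and per-site duplex coverage
# weights. Rates are estimated from synonymous sites and/or passenger genes;
# empty channels are shrunk toward the global mean rate by a pseudocount.

#' Fit the 192-channel background rate model
#'
#' For channel `t`, `r_t = (m_t + a) / (n_t + a / rbar)` where `m_t` is the
#' observed neutral mutation count, `n_t` the depth-weighted opportunity and
#' `rbar` the global mean rate; the pseudocount `a` shrinks sparse channels
#' toward `rbar` (a channel with no opportunity returns exactly `rbar` and is
#' flagged).
#'
#' @param calls tibble of passing somatic calls (`contig`, `pos`, `alt`,
#'   optionally `n_mutant_bundles`).
#' @param coverage coverage profile (`contig`, `pos`, `depth`).
#' @param sites site enumeration from [enumerate_gene_sites()].
#' @param neutral `"synonymous"` (synonymous site-alternates only) or
#'   `"passenger"` (every site of `neutral_genes`).
#' @param neutral_genes gene ids used when `neutral = "passenger"`.
#' @param pseudocount shrinkage pseudocount `a`.
#' @param count `"molecules"` to weight observations by `n_mutant_bundles`,
#'   `"collapsed"` to count each called site/alt once.
#' @return a `rate_model` tibble (`channel`, `m`, `n`, `rate`, `flagged`)
#'   with attributes `rbar`, `pseudocount` and `indel_rate` slot filled by
#'   [set_indel_rate()] when needed.
#' @export
fit_rate_model <- function(calls, coverage, sites,
                           neutral = c("synonymous", "passenger"),
                           neutral_genes = NULL, pseudocount = 0.5,
                           count = c("molecules", "collapsed")) {
  neutral <- match.arg(neutral)
  count <- match.arg(count)
  sites <- as_tibble(sites)
  nsites <- switch(neutral,
    synonymous = sites[sites$impact == "synonymous", ],
    passenger = {
      assert_that(!is.null(neutral_genes),
                  "neutral = 'passenger' needs neutral_genes")
      sites[sites$gene_id %in% neutral_genes, ]
    })
  assert_that(nrow(nsites) > 0, "no neutral sites")
  cov <- as_tibble(coverage)[, c("contig", "pos", "depth")]
  ns <- left_join(nsites, cov, by = c("contig", "pos"))
  ns$depth[is.na(ns$depth)] <- 0
  assert_that(sum(ns$depth) > 0, "zero total coverage on neutral sites",
              class = "duplexome_empty_coverage")
  opp <- summarise(group_by(ns, .data$channel192),
                   n = sum(.data$depth), .groups = "drop")
  calls <- as_tibble(calls)
  w <- if (count == "molecules" && "n_mutant_bundles" %in% names(calls)) {
    calls$n_mutant_bundles
  } else {
    rep(1, nrow(calls))
  }
  hit <- inner_join(mutate(calls[, c("contig", "pos", "alt")], w = w),
                    ns[, c("contig", "pos", "alt", "channel192")],
                    by = c("contig", "pos", "alt"))
  obs <- summarise(group_by(hit, .data$channel192),
                   m = sum(.data$w), .groups = "drop")
  labs <- channel_labels("TSW192")
  df <- tibble(channel = labs)
  df <- left_join(df, rename(opp, channel = "channel192"), by = "channel")
  df <- left_join(df, rename(obs, channel = "channel192"), by = "channel")
  df$n[is.na(df$n)] <- 0
  df$m[is.na(df$m)] <- 0
  a <- pseudocount
  # hierarchical shrinkage, coarse to fine: global mean -> substitution type
  # (6) -> strand-pooled trinucleotide channel (96) -> strand-wise channel
  # (192). Each level is shrunk toward its parent; channels without
  # opportunity inherit their parent's rate.
  ch96 <- sub("^[TU]:", "", df$channel)
  subtype <- sub("^.\\[(.>.)\\].$", "\\1", ch96)
  rates_from <- function(m) {
    rbar <- sum(m) / sum(df$n)
    if (rbar <= 0) return(rep(0, nrow(df)))
    mty <- tapply(m, subtype, sum)[subtype]
    nty <- tapply(df$n, subtype, sum)[subtype]
    rty <- (mty + a) / (nty + a / rbar)
    m96 <- tapply(m, ch96, sum)[ch96]
    n96 <- tapply(df$n, ch96, sum)[ch96]
    r96 <- (m96 + a) / (n96 + a / rty)
    as.numeric((m + a) / (df$n + a / r96))
  }
  rbar <- sum(df$m) / sum(df$n)
  df$rate <- rates_from(df$m)
  # exact linearization of the fit: Jacobian of the 192 rates with respect
  # to the neutral channel counts. Together with Var(m_t) = r_t n_t this
  # carries the full covariance of the shrinkage hierarchy into downstream
  # expected-count variances.
  if (rbar > 0) {
    base <- df$rate
    J <- matrix(0, nrow(df), nrow(df))
    for (t in seq_len(nrow(df))) {
      m2 <- df$m
      m2[t] <- m2[t] + 1
      J[, t] <- rates_from(m2) - base
    }
    m_var <- pmax(df$rate * df$n, 1e-12)
    df$rate_var <- as.numeric((J^2) %*% m_var)
  } else {
    J <- matrix(0, nrow(df), nrow(df))
    m_var <- rep(0, nrow(df))
    df$rate_var <- rep(0, nrow(df))
  }
  df$flagged <- df$n == 0
  attr(df, "m_jacobian") <- J
  attr(df, "m_var") <- m_var
  attr(df, "rbar") <- rbar
  attr(df, "pseudocount") <- a
  attr(df, "neutral") <- neutral
  attr(df, "indel_rate") <- NA_real_
  class(df) <- c("rate_model", class(df))
  df
}

#' Attach a global indel rate to a rate model
#'
#' Indel selection uses a single global indel rate per duplex base, scaled by
#' gene footprint.
#'
#' @param rates a `rate_model`.
#' @param n_indels observed neutral indel count.
#' @param n_duplex_bases duplex bases over the neutral footprint.
#' @return the `rate_model` with its `indel_rate` attribute set.
#' @export
set_indel_rate <- function(rates, n_indels, n_duplex_bases) {
  assert_that(n_duplex_bases > 0, "zero duplex bases")
  attr(rates, "indel_rate") <- n_indels / n_duplex_bases
  rates
}

rate_lookup <- function(rates, channel192) {
  rates$rate[match(channel192, rates$channel)]
}

#' @export
print.rate_model <- function(x, ...) {
  cat("<rate_model> 192 channels; global mean rate ",
      signif(attr(x, "rbar"), 4), " per duplex base; ",
      sum(x$flagged), " channel(s) without opportunity\n", sep = "")
  invisible(x)
}

#' Expected mutation counts per gene and impact class
#'
#' Enumerates every possible substitution at every covered site of each gene,
#' classifies its impact, and accumulates `rate x coverage` — the duplex
#' coverage-corrected neutral expectation against which observed counts are
#' compared.
#'
#' @param gm a `gene_models` tibble.
#' @param rates a `rate_model`.
#' @param coverage coverage profile (`contig`, `pos`, `depth`).
#' @param genome a `genome_ref` (used to enumerate sites unless `sites` is
#'   given).
#' @param sites optional precomputed [enumerate_gene_sites()] output.
#' @param splice_window intronic window for enumeration.
#' @return tibble `gene_id`, `impact`, `expected`.
#' @export
expected_counts <- function(gm, rates, coverage, genome = NULL, sites = NULL,
                            splice_window = 10) {
  if (is.null(sites)) {
    assert_that(!is.null(genome), "need genome or a precomputed sites table")
    sites <- enumerate_gene_sites(gm, genome, splice_window = splice_window)
  }
  cov <- as_tibble(coverage)[, c("contig", "pos", "depth")]
  s <- left_join(as_tibble(sites), cov, by = c("contig", "pos"))
  s$depth[is.na(s$depth)] <- 0
  detail <- summarise(group_by(s, .data$gene_id, .data$impact,
                               .data$channel192),
                      d = sum(.data$depth), .groups = "drop")
  detail$rate <- rate_lookup(rates, detail$channel192)
  out <- summarise(group_by(detail, .data$gene_id, .data$impact),
                   expected = sum(.data$rate * .data$d),
                   .groups = "drop")
  key <- paste(out$gene_id, out$impact)
  out$expected_var <- vapply(seq_len(nrow(out)), function(i) {
    sel <- paste(detail$gene_id, detail$impact) == key[i]
    pooled_expected_var_detail(detail[sel, ], rates)
  }, numeric(1))
  attr(out, "channel_detail") <- detail
  attr(out, "rate_model") <- rates
  out
}

# Variance of a pooled expectation E = sum_t d_t r_t through the full
# linearization of the rate fit: the same fitted channel rates enter every
# gene, so depth weights are aggregated per channel and pushed through the
# Jacobian of the fit, carrying all shrinkage-induced covariance.
pooled_expected_var_detail <- function(detail, rates) {
  J <- attr(rates, "m_jacobian")
  m_var <- attr(rates, "m_var")
  if (is.null(J)) return(0)
  d_vec <- rep(0, nrow(rates))
  agg <- tapply(detail$d, detail$channel192, sum)
  idx <- match(names(agg), rates$channel)
  ok <- !is.na(idx)
  d_vec[idx[ok]] <- agg[ok]
  g <- as.vector(crossprod(J, d_vec))
  sum(g^2 * m_var)
}

pooled_expected_var <- function(detail, rates, gene_set = NULL,
                                impacts = NULL) {
  d <- detail
  if (!is.null(gene_set)) d <- d[d$gene_id %in% gene_set, ]
  if (!is.null(impacts)) d <- d[d$impact %in% impacts, ]
  pooled_expected_var_detail(d, rates)
}

#' Observed and expected counts per gene and impact class
#'
#' @inheritParams expected_counts
#' @param calls tibble of passing calls (`contig`, `pos`, `alt`, optionally
#'   `n_mutant_bundles`).
#' @param count `"molecules"` or `"collapsed"` observation counting.
#' @return tibble `gene_id`, `impact`, `observed`, `expected`.
#' @export
gene_counts <- function(calls, gm, rates, coverage, genome = NULL,
                        sites = NULL, splice_window = 10,
                        count = c("molecules", "collapsed")) {
  count <- match.arg(count)
  if (is.null(sites)) {
    assert_that(!is.null(genome), "need genome or a precomputed sites table")
    sites <- enumerate_gene_sites(gm, genome, splice_window = splice_window)
  }
  exp_df <- expected_counts(gm, rates, coverage, sites = sites)
  calls <- as_tibble(calls)
  w <- if (count == "molecules" && "n_mutant_bundles" %in% names(calls)) {
    calls$n_mutant_bundles
  } else {
    rep(1, nrow(calls))
  }
  hit <- inner_join(mutate(calls[, c("contig", "pos", "alt")], w = w),
                    as_tibble(sites)[, c("contig", "pos", "alt", "gene_id",
                                         "impact")],
                    by = c("contig", "pos", "alt"))
  obs <- summarise(group_by(hit, .data$gene_id, .data$impact),
                   observed = sum(.data$w), .groups = "drop")
  out <- left_join(exp_df, obs, by = c("gene_id", "impact"))
  out$observed[is.na(out$observed)] <- 0
  out <- out[, c("gene_id", "impact", "observed", "expected",
                 "expected_var")]
  attr(out, "channel_detail") <- attr(exp_df, "channel_detail")
  attr(out, "rate_model") <- attr(exp_df, "rate_model")
  out
}
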