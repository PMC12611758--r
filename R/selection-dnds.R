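# dN/dS selection statistics.
#
# omega per impact class is the ratio of observed to expected counts under
# the Poisson background model; two-sided p-values come from the Poisson
# likelihood-ratio test (chi^2, 1 df), one-sided p-values by directional
# halving of the two-sided p (p/2 on the favoured side, 1 - p/2 otherwise).
# Benjamini-Hochberg q-values are computed within explicitly declared test
# families.

# Log-likelihood of n under a gamma-mixed Poisson with mean mu and shape k:
# k = Inf is the plain Poisson; finite k absorbs the sampling uncertainty of
# the fitted background rates (k = E^2 / Var(E)), the optional
# overdispersion of the background model.
mix_loglik <- function(n, mu, k) {
  if (is.infinite(k)) {
    if (n == 0) -mu else n * log(mu) - mu
  } else {
    if (n == 0) -k * log1p(mu / k) else n * log(mu) - (n + k) * log1p(mu / k)
  }
}

pois_deviance <- function(n, E, omega = 1, k = Inf) {
  if (length(n) > 1 || length(omega) > 1) {
    k <- rep(k, length.out = max(length(n), length(omega)))
    n2 <- rep(n, length.out = length(k))
    E2 <- rep(E, length.out = length(k))
    o2 <- rep(omega, length.out = length(k))
    return(vapply(seq_along(k), function(i) {
      pois_deviance(n2[i], E2[i], o2[i], k[i])
    }, numeric(1)))
  }
  lhat <- mix_loglik(n, max(n, .Machine$double.xmin), k)
  2 * (lhat - mix_loglik(n, omega * E, k))
}

# Profile-likelihood CI for omega in n ~ mixPoisson(omega * E, shape k).
pois_omega_ci <- function(n, E, conf_level = 0.95, k = Inf) {
  crit <- qchisq(conf_level, 1)
  if (E <= 0) return(c(NA_real_, NA_real_))
  hat <- n / E
  f <- function(w) pois_deviance(n, E, w, k) - crit
  lower <- if (n == 0) 0 else {
    uniroot(f, lower = hat * 1e-8, upper = hat, tol = 1e-10)$root
  }
  hi <- max(hat, 1e-8)
  up <- hi * 2 + 2 / E
  while (f(up) < 0) up <- up * 4
  upper <- uniroot(f, lower = hi, upper = up, tol = 1e-10)$root
  c(lower, upper)
}

dnds_test <- function(n, E, conf_level = 0.95, k = Inf) {
  if (length(n) == 0) {
    return(tibble(omega = numeric(0), lower = numeric(0),
                  upper = numeric(0), p_two_sided = numeric(0),
                  p_negative = numeric(0), p_positive = numeric(0)))
  }
  k <- rep(k, length.out = length(n))
  k[is.na(k) | k <= 0] <- Inf
  omega <- ifelse(E > 0, n / E, NA_real_)
  dev <- pois_deviance(n, E, 1, k)
  p_two <- pchisq(dev, 1, lower.tail = FALSE)
  p_neg <- ifelse(omega < 1, p_two / 2, 1 - p_two / 2)
  p_pos <- ifelse(omega > 1, p_two / 2, 1 - p_two / 2)
  p_two[E <= 0] <- NA_real_
  p_neg[E <= 0] <- NA_real_
  p_pos[E <= 0] <- NA_real_
  ci <- t(vapply(seq_along(n), function(i) {
    if (is.na(omega[i])) c(NA_real_, NA_real_) else
      pois_omega_ci(n[i], E[i], conf_level, k[i])
  }, numeric(2)))
  tibble(omega = omega, lower = ci[, 1], upper = ci[, 2],
         p_two_sided = p_two, p_negative = p_neg, p_positive = p_pos)
}

shape_from_var <- function(E, V) {
  ifelse(is.na(V) | V <= 0 | E <= 0, Inf, E^2 / V)
}

nonsyn_classes <- function() {
  c("missense", "nonsense", "stop_loss", "essential_splice")
}

#' Gene-level dN/dS
#'
#' Per gene and impact class: omega (observed/expected), profile-likelihood
#' CI, two-sided LRT p, one-sided negative- and positive-selection p, and a
#' pooled `all_nonsynonymous` row per gene. Zero-expectation classes are
#' dropped. q-values are Benjamini-Hochberg within each (impact class, test
#' side) family across genes.
#'
#' @param counts output of [gene_counts()] (`gene_id`, `impact`, `observed`,
#'   `expected`).
#' @param classes impact classes to test (default the non-synonymous SNV
#'   classes).
#' @param conf_level CI level.
#' @return a `gene_selection` tibble.
#' @export
gene_dnds <- function(counts, classes = nonsyn_classes(), conf_level = 0.95) {
  df <- as_tibble(counts)
  detail <- attr(counts, "channel_detail")
  rmod <- attr(counts, "rate_model")
  if (!"expected_var" %in% names(df)) df$expected_var <- 0
  df <- df[df$impact %in% classes & df$expected > 0, ]
  joint <- summarise(group_by(df, .data$gene_id),
                     observed = sum(.data$observed),
                     expected = sum(.data$expected),
                     expected_var = sum(.data$expected_var),
                     .groups = "drop")
  if (!is.null(detail) && !is.null(rmod)) {
    joint$expected_var <- vapply(joint$gene_id, function(g) {
      pooled_expected_var(detail, rmod, gene_set = g, impacts = classes)
    }, numeric(1))
  }
  joint$impact <- "all_nonsynonymous"
  df <- bind_rows(df, joint[, c("gene_id", "impact", "observed", "expected",
                                "expected_var")])
  res <- bind_cols(df, dnds_test(df$observed, df$expected, conf_level,
                                 k = shape_from_var(df$expected,
                                                    df$expected_var)))
  res <- group_by(res, .data$impact)
  res <- ungroup(mutate(res,
                        q_two_sided = p.adjust(.data$p_two_sided, "BH"),
                        q_negative = p.adjust(.data$p_negative, "BH"),
                        q_positive = p.adjust(.data$p_positive, "BH")))
  class(res) <- c("gene_selection", class(res))
  res
}

#' Global (pooled) dN/dS over a gene set
#'
#' Pools observed and expected counts per impact class across a gene set and
#' tests the pooled omega. With one gene this equals the per-gene result.
#'
#' @param counts output of [gene_counts()].
#' @param gene_set optional character vector of gene ids to pool (default:
#'   all genes in `counts`).
#' @param classes impact classes to report (plus a pooled
#'   `all_nonsynonymous` row).
#' @param conf_level CI level.
#' @return tibble with one row per class: pooled `observed`, `expected`,
#'   `omega`, CI and p-values.
#' @export
global_dnds <- function(counts, gene_set = NULL, classes = nonsyn_classes(),
                        conf_level = 0.95) {
  df <- as_tibble(counts)
  detail <- attr(counts, "channel_detail")
  rmod <- attr(counts, "rate_model")
  if (!"expected_var" %in% names(df)) df$expected_var <- 0
  if (!is.null(gene_set)) df <- df[df$gene_id %in% gene_set, ]
  df <- df[df$impact %in% classes, ]
  pooled <- summarise(group_by(df, .data$impact),
                      observed = sum(.data$observed),
                      expected = sum(.data$expected),
                      expected_var = sum(.data$expected_var),
                      .groups = "drop")
  all_row <- tibble(impact = "all_nonsynonymous",
                    observed = sum(pooled$observed),
                    expected = sum(pooled$expected),
                    expected_var = sum(pooled$expected_var))
  if (!is.null(detail) && !is.null(rmod)) {
    pooled$expected_var <- vapply(pooled$impact, function(cl) {
      pooled_expected_var(detail, rmod, gene_set = gene_set, impacts = cl)
    }, numeric(1))
    all_row$expected_var <- pooled_expected_var(detail, rmod,
                                                gene_set = gene_set,
                                                impacts = classes)
  }
  pooled <- bind_rows(pooled, all_row)
  pooled <- pooled[pooled$expected > 0, ]
  assert_that(nrow(pooled) > 0, "no classes with positive expectation")
  bind_cols(pooled, dnds_test(pooled$observed, pooled$expected, conf_level,
                              k = shape_from_var(pooled$expected,
                                                 pooled$expected_var)))
}

#' Site-level dN/dS (hotspot recurrence test)
#'
#' For each candidate (site, alternate) the expected count is
#' `lambda_s = r_t(s) x coverage(s) x rho`, with `rho` an optional per-gene
#' non-synonymous inflation factor (the gene's fitted omega) guarding against
#' anti-conservative tests inside strong driver genes; `rho = 1` is the
#' pure-rate mode. The p-value is the Poisson upper tail
#' `P(Poisson(lambda) >= k)`. In `restricted` mode only the supplied hotspot
#' list is tested and q-values are computed within that family alone.
#'
#' @param calls passing calls (`contig`, `pos`, `alt`, optionally
#'   `n_mutant_bundles`).
#' @param sites site enumeration ([enumerate_gene_sites()]).
#' @param rates a `rate_model`.
#' @param coverage coverage profile.
#' @param mode `"site_wide"` or `"restricted"`.
#' @param hotspots tibble (`contig`, `pos`, `alt`) of the restricted family.
#' @param rho optional tibble (`gene_id`, `rho`).
#' @param impacts impact classes eligible for testing.
#' @param count `"molecules"` or `"collapsed"` recurrence counting.
#' @param aggregate_aa also aggregate sites/alternates producing the same
#'   amino-acid change.
#' @return list with `sites` (per site/alt results) and `aa` (per amino-acid
#'   change aggregation, when requested).
#' @export
site_dnds <- function(calls, sites, rates, coverage,
                      mode = c("site_wide", "restricted"), hotspots = NULL,
                      rho = NULL, impacts = nonsyn_classes(),
                      count = c("molecules", "collapsed"),
                      aggregate_aa = TRUE) {
  mode <- match.arg(mode)
  count <- match.arg(count)
  s <- as_tibble(sites)
  s <- s[s$impact %in% impacts, ]
  if (mode == "restricted") {
    assert_that(!is.null(hotspots), "restricted mode needs a hotspot list")
    s <- inner_join(s, as_tibble(hotspots)[, c("contig", "pos", "alt")],
                    by = c("contig", "pos", "alt"))
  }
  cov <- as_tibble(coverage)[, c("contig", "pos", "depth")]
  s <- left_join(s, cov, by = c("contig", "pos"))
  s$depth[is.na(s$depth)] <- 0
  rho_of <- if (is.null(rho)) {
    rep(1, nrow(s))
  } else {
    r <- as_tibble(rho)
    v <- r$rho[match(s$gene_id, r$gene_id)]
    ifelse(is.na(v), 1, pmax(v, 1))
  }
  s$lambda <- rate_lookup(rates, s$channel192) * s$depth * rho_of
  calls <- as_tibble(calls)
  w <- if (count == "molecules" && "n_mutant_bundles" %in% names(calls)) {
    calls$n_mutant_bundles
  } else {
    rep(1, nrow(calls))
  }
  obs <- summarise(group_by(mutate(calls[, c("contig", "pos", "alt")], w = w),
                            .data$contig, .data$pos, .data$alt),
                   k = sum(.data$w), .groups = "drop")
  s <- left_join(s, obs, by = c("contig", "pos", "alt"))
  s$k[is.na(s$k)] <- 0
  bad <- s$k > 0 & s$depth <= 0
  assert_that(!any(bad),
              "observed recurrence at a site with zero coverage",
              class = "duplexome_inconsistent_inputs")
  s$p <- ppois(s$k - 1, s$lambda, lower.tail = FALSE)
  s$p[s$k == 0] <- 1
  # a degenerate rate model (no neutral mutations) supports no inference
  s$p[s$k > 0 & s$lambda <= 0] <- NA_real_
  s$q <- p.adjust(s$p, "BH")
  out_sites <- s[, c("gene_id", "contig", "pos", "ref", "alt", "impact",
                     "aa_change", "lambda", "k", "p", "q")]
  aa <- NULL
  if (aggregate_aa) {
    cod <- s[!is.na(s$aa_change), ]
    aa <- summarise(group_by(cod, .data$gene_id, .data$aa_change,
                             .data$impact),
                    lambda = sum(.data$lambda), k = sum(.data$k),
                    .groups = "drop")
    aa$p <- ppois(aa$k - 1, aa$lambda, lower.tail = FALSE)
    aa$p[aa$k == 0] <- 1
    aa$q <- p.adjust(aa$p, "BH")
  }
  list(sites = out_sites, aa = aa)
}

#' Within-gene site-set dN/dS
#'
#' Tests selection on declared subsets of a gene's sites (e.g. last-exon
#' nonsense, intronic splice-flank, stop-loss, listed synonymous sites)
#' against the gene's coverage-corrected neutral expectation, with an
#' optional likelihood-ratio contrast between two sets.
#'
#' @param site_sets named list of tibbles (`contig`, `pos`, `alt`) selecting
#'   site-alternates from `sites`.
#' @param calls,sites,rates,coverage as in [site_dnds()].
#' @param allow_overlap declare that sets may overlap (otherwise overlapping
#'   sets are an error).
#' @param count observation counting mode.
#' @param conf_level CI level.
#' @return tibble with one row per set: `observed`, `expected`, `omega`, CI
#'   and p-values; pairwise set contrasts via [contrast_site_sets()].
#' @export
withingene_dnds <- function(site_sets, calls, sites, rates, coverage,
                            allow_overlap = FALSE,
                            count = c("molecules", "collapsed"),
                            conf_level = 0.95) {
  count <- match.arg(count)
  assert_that(length(site_sets) >= 1 && !is.null(names(site_sets)),
              "site_sets must be a named list")
  keys <- lapply(site_sets, function(ss) {
    ss <- as_tibble(ss)
    assert_that(nrow(ss) > 0, "empty site set",
                class = "duplexome_empty_site_set")
    paste(ss$contig, ss$pos, ss$alt)
  })
  if (!allow_overlap && length(keys) > 1) {
    all_keys <- unlist(keys)
    assert_that(!any(duplicated(all_keys)),
                "site sets overlap; declare allow_overlap = TRUE",
                class = "duplexome_overlapping_sets")
  }
  s <- as_tibble(sites)
  cov <- as_tibble(coverage)[, c("contig", "pos", "depth")]
  s <- left_join(s, cov, by = c("contig", "pos"))
  s$depth[is.na(s$depth)] <- 0
  s$lambda <- rate_lookup(rates, s$channel192) * s$depth
  calls <- as_tibble(calls)
  w <- if (count == "molecules" && "n_mutant_bundles" %in% names(calls)) {
    calls$n_mutant_bundles
  } else {
    rep(1, nrow(calls))
  }
  obs <- summarise(group_by(mutate(calls[, c("contig", "pos", "alt")], w = w),
                            .data$contig, .data$pos, .data$alt),
                   k = sum(.data$w), .groups = "drop")
  s <- left_join(s, obs, by = c("contig", "pos", "alt"))
  s$k[is.na(s$k)] <- 0
  skey <- paste(s$contig, s$pos, s$alt)
  rows <- lapply(names(site_sets), function(nm) {
    sel <- skey %in% keys[[nm]]
    E <- sum(s$lambda[sel])
    assert_that(E > 0, paste0("site set '", nm, "' has zero expectation"),
                class = "duplexome_empty_site_set")
    detail <- summarise(group_by(s[sel, ], .data$channel192),
                        d = sum(.data$depth), .groups = "drop")
    V <- pooled_expected_var_detail(detail, rates)
    tibble(set = nm, observed = sum(s$k[sel]), expected = E,
           expected_var = V)
  })
  df <- bind_rows(rows)
  bind_cols(df, dnds_test(df$observed, df$expected, conf_level,
                          k = shape_from_var(df$expected, df$expected_var)))
}

#' Likelihood-ratio contrast between two site sets
#'
#' Tests whether two site sets share one omega against separate omegas.
#'
#' @param wg output of [withingene_dnds()].
#' @param set_a,set_b set names to contrast.
#' @return tibble with the two omegas, the LRT statistic and p-value.
#' @export
contrast_site_sets <- function(wg, set_a, set_b) {
  a <- wg[wg$set == set_a, ]
  b <- wg[wg$set == set_b, ]
  assert_that(nrow(a) == 1 && nrow(b) == 1, "unknown set names")
  n <- c(a$observed, b$observed)
  E <- c(a$expected, b$expected)
  w_pool <- sum(n) / sum(E)
  dev <- sum(pois_deviance(n, E, w_pool)) - sum(pois_deviance(n, E, n / E))
  tibble(set_a = set_a, set_b = set_b, omega_a = a$omega, omega_b = b$omega,
         lrt = dev, p = pchisq(dev, 1, lower.tail = FALSE))
}

#' Driver fraction from a dN/dS ratio
#'
#' The excess fraction of observed mutations attributable to selection:
#' `(omega - 1) / omega` for classes with `omega >= 1`, zero otherwise.
#'
#' @param omega non-negative dN/dS ratio(s).
#' @return driver fraction(s) in `[0, 1)`.
#' @examples
#' driver_fraction(5) # 0.8
#' @export
driver_fraction <- function(omega) {
  assert_that(all(omega >= 0), "omega must be non-negative",
              class = "duplexome_negative_omega")
  ifelse(omega >= 1, (omega - 1) / omega, 0)
}

#' Estimated number of driver mutations in a result set
#'
#' Sums `n x (omega - 1) / omega` over rows with omega above one; the CI
#' propagates the per-row omega CIs through the same transform.
#'
#' @param results tibble with columns `observed`, `omega`, `lower`, `upper`
#'   (e.g. a [gene_dnds()] subset).
#' @return tibble `drivers`, `lower`, `upper`.
#' @export
driver_count_excess <- function(results) {
  df <- as_tibble(results)
  sel <- !is.na(df$omega) & df$omega > 1
  df <- df[sel, ]
  if (nrow(df) == 0) return(tibble(drivers = 0, lower = 0, upper = 0))
  est <- sum(df$observed * driver_fraction(df$omega))
  lo <- sum(df$observed * driver_fraction(pmax(df$lower, 0)))
  hi <- sum(df$observed * driver_fraction(df$upper))
  tibble(drivers = est, lower = lo, upper = hi)
}

#' Mutant-cell-fraction estimate for one gene
#'
#' Sums duplex VAFs across the gene's mutations: under a diploid population
#' with at most one heterozygous mutation per cell the mutant cell fraction
#' is `2 * sum(v_d)`; under haploidy (or two mutant copies per cell) it is
#' `sum(v_d)`; in general it falls within `[sum, 2 sum]`. An optional
#' per-class omega table converts the non-synonymous cell fraction into a
#' driver-cell fraction via the per-class driver fractions.
#'
#' @param calls calls of one gene in one sample, with `duplex_vaf` and
#'   (for the driver adjustment) `impact`.
#' @param ploidy `"diploid_het"` or `"haploid"` headline estimate.
#' @param omega optional tibble (`impact`, `omega`) of per-class dN/dS
#'   estimated without collapsing recurrent mutations.
#' @return a `clone_fraction` tibble row: `sum_vaf`, `f`, `range_low`,
#'   `range_high`, `driver_fraction_of_cells`.
#' @export
mutant_cell_fraction <- function(calls, ploidy = c("diploid_het", "haploid"),
                                 omega = NULL) {
  ploidy <- match.arg(ploidy)
  v <- as_tibble(calls)
  assert_that(all(v$duplex_vaf >= 0 & v$duplex_vaf <= 1),
              "duplex VAFs outside [0, 1]",
              class = "duplexome_bad_vaf")
  sv <- sum(v$duplex_vaf)
  f <- if (ploidy == "diploid_het") 2 * sv else sv
  if (f > 1) {
    warn("mutant cell fraction capped at 1")
    f <- 1
  }
  drv <- NA_real_
  if (!is.null(omega) && "impact" %in% names(v)) {
    om <- as_tibble(omega)
    per_class <- summarise(group_by(v, .data$impact),
                           sv = sum(.data$duplex_vaf), .groups = "drop")
    per_class <- left_join(per_class, om, by = "impact")
    per_class$omega[is.na(per_class$omega)] <- 0
    mult <- if (ploidy == "diploid_het") 2 else 1
    drv <- min(1, sum(mult * per_class$sv *
                        driver_fraction(pmax(per_class$omega, 0))))
  }
  tibble(sum_vaf = sv, f = f, range_low = min(sv, 1),
         range_high = min(2 * sv, 1), ploidy = ploidy,
         driver_fraction_of_cells = drv)
}
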