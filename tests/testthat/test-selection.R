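# Selection statistics: rate model, expected counts, dN/dS at gene, site and
# site-set level, driver estimators.

test_that("rate model reproduces a single-channel rate and flags empty channels", {
  fx <- toy_gene_fixture()
  sites <- enumerate_gene_sites(fx$gm, fx$genome)
  syn <- sites[sites$impact == "synonymous", ]
  cov <- uniform_coverage(sites, 1e6 / nrow(syn) * 3)
  # put 3 mutations in one synonymous channel
  ch <- syn$channel192[1]
  calls <- syn[syn$channel192 == ch, ][1, c("contig", "pos", "alt")]
  calls$n_mutant_bundles <- 3L
  rm0 <- fit_rate_model(calls, cov, sites, pseudocount = 0)
  n_ch <- sum(cov$depth[1]) * sum(syn$channel192 == ch)
  expect_equal(rm0$rate[rm0$channel == ch], 3 / n_ch)
  # channels without synonymous opportunity inherit their shrinkage target
  # and are flagged
  expect_true(any(rm0$flagged))
  expect_true(all(rm0$rate[rm0$flagged & !is.na(rm0$rate)] >= 0))
  rm1 <- fit_rate_model(calls, cov, sites, pseudocount = 0.5)
  # a channel with no opportunity anywhere in its substitution type inherits
  # the global mean rate
  ty_of <- sub("^.\\[(.>.)\\].$", "\\1", sub("^[TU]:", "", rm1$channel))
  empty_ty <- tapply(rm1$n, ty_of, sum)[ty_of] == 0
  if (any(empty_ty)) {
    expect_true(all(abs(rm1$rate[empty_ty] - attr(rm1, "rbar")) <
                      attr(rm1, "rbar") * 1e-6))
  }
  expect_true(all(rm1$rate > 0))
})

test_that("uniform-rate simulation recovers channel rates within 3 SE", {
  fx <- neutral_sim_fixture(n_genes = 30, exon_len = 300, seed = 71,
                            mut_rate = 2e-5)
  fx$cfg$rate_profile <- setNames(rep(1, 96), channel_labels("SBS96"))
  grid <- site_rate_grid(fx$cfg)
  depth <- 3000
  sim <- simulate_site_counts(fx$cfg, depth = depth, seed = 72, grid = grid)
  rm <- fit_rate_model(sim$calls, sim$coverage, grid)
  r_true <- fx$cfg$mut_rate / 3
  present <- rm$n > 0
  se <- sqrt(r_true / rm$n[present])
  expect_gt(mean(abs(rm$rate[present] - r_true) <= 3 * se + 1e-12), 0.98)
})

test_that("expected counts match a brute-force enumeration oracle exactly", {
  fx <- toy_gene_fixture()
  sites <- enumerate_gene_sites(fx$gm, fx$genome, include_flanks = FALSE)
  cov <- uniform_coverage(sites, 50)
  # flat-rate model: every channel at the same rate
  rm <- fit_rate_model(sites[1, c("contig", "pos", "alt")] |>
                         dplyr::mutate(n_mutant_bundles = 0L),
                       cov, sites, pseudocount = 1)
  rm$rate <- rep(2e-6, nrow(rm))
  ec <- expected_counts(fx$gm, rm, cov, sites = sites)
  # oracle: walk the 30 CDS bases, mutate each to every alternative,
  # translate both codons with Biostrings and tally by class
  gc <- Biostrings::GENETIC_CODE
  cds <- paste0(get_seq(fx$genome, "chr1", 12, 27),
                get_seq(fx$genome, "chr1", 51, 66))
  tally <- c(synonymous = 0, missense = 0, nonsense = 0, stop_loss = 0)
  for (k in seq_len(nchar(cds))) {
    ref <- substr(cds, k, k)
    ci <- (k - 1) %/% 3
    codon <- substr(cds, ci * 3 + 1, ci * 3 + 3)
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      alt_codon <- codon
      substr(alt_codon, (k - 1) %% 3 + 1, (k - 1) %% 3 + 1) <- alt
      aa_r <- unname(gc[codon])
      aa_a <- unname(gc[alt_codon])
      cls <- if (aa_r == aa_a) "synonymous" else if (aa_a == "*") "nonsense"
        else if (aa_r == "*") "stop_loss" else "missense"
      tally[cls] <- tally[cls] + 2e-6 * 50
    }
  }
  for (cls in names(tally)) {
    got <- ec$expected[ec$impact == cls]
    if (length(got) == 0) got <- 0
    expect_equal(got, unname(tally[cls]), tolerance = 1e-12)
  }
  # doubling coverage doubles every expectation
  ec2 <- expected_counts(fx$gm, rm, dplyr::mutate(cov, depth = depth * 2),
                         sites = sites)
  expect_equal(ec2$expected, ec$expected * 2)
  # a zero-coverage gene has zero expectation everywhere
  ec0 <- expected_counts(fx$gm, rm, dplyr::mutate(cov, depth = 0),
                         sites = sites)
  expect_true(all(ec0$expected == 0))
})

test_that("gene dN/dS arithmetic matches the closed-form Poisson LRT", {
  counts <- tibble::tibble(gene_id = c("g", "g"),
                           impact = c("missense", "nonsense"),
                           observed = c(20, 5),
                           expected = c(5, 5))
  res <- gene_dnds(counts)
  mis <- res[res$impact == "missense", ]
  expect_equal(mis$omega, 4)
  lrt <- 2 * (20 * log(20 / 5) - 15)
  expect_equal(mis$p_two_sided, pchisq(lrt, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(lrt, 25.45, tolerance = 1e-2)
  # n = E: omega 1, two-sided p 1
  non <- res[res$impact == "nonsense", ]
  expect_equal(non$omega, 1)
  expect_equal(non$p_two_sided, 1)
  # one-sided construction: omega > 1 makes the negative-selection p >= 0.5
  expect_gte(mis$p_negative, 0.5)
  expect_lt(mis$p_positive, 0.001)
  # profile CI covers the MLE and excludes 1 for the missense class
  expect_true(mis$lower > 1 && mis$lower < 4 && mis$upper > 4)
  # q >= p within each family
  expect_true(all(res$q_two_sided >= res$p_two_sided - 1e-12))
})

test_that("global dN/dS on a single gene equals the per-gene result", {
  counts <- tibble::tibble(gene_id = "g1",
                           impact = c("missense", "nonsense", "synonymous"),
                           observed = c(12, 3, 10),
                           expected = c(10, 4, 10))
  g1 <- gene_dnds(counts)
  gl <- global_dnds(counts)
  for (cls in c("missense", "nonsense", "all_nonsynonymous")) {
    expect_equal(gl$omega[gl$impact == cls], g1$omega[g1$impact == cls])
    expect_equal(gl$p_two_sided[gl$impact == cls],
                 g1$p_two_sided[g1$impact == cls])
  }
})

test_that("monotonicity: more observations never lower omega or raise positive p", {
  E <- 7
  res <- dplyr::bind_rows(lapply(0:30, function(n) {
    gene_dnds(tibble::tibble(gene_id = "g", impact = "missense",
                             observed = n, expected = E))[1, ]
  }))
  expect_true(all(diff(res$omega) >= 0))
  expect_true(all(diff(res$p_positive) <= 1e-12))
})

test_that("site-level Poisson tails match a series-summation oracle", {
  # independent oracle: sum the Poisson pmf series directly
  series_tail <- function(lambda, k) {
    j <- k
    term <- exp(-lambda + k * log(lambda) - lgamma(k + 1))
    total <- 0
    while (term > total * 1e-18 || j < k + 60) {
      total <- total + term
      j <- j + 1
      term <- term * lambda / j
      if (j > k + 2000) break
    }
    total
  }
  for (lambda in c(1e-3, 0.05, 2)) {
    for (k in c(1, 3, 7)) {
      p <- ppois(k - 1, lambda, lower.tail = FALSE)
      expect_equal(p, series_tail(lambda, k), tolerance = 1e-12)
    }
  }
  expect_equal(ppois(2, 0.001, lower.tail = FALSE), 1.66e-10,
               tolerance = 5e-3)
})

test_that("site dN/dS tests recurrence against coverage-weighted rates", {
  fx <- toy_gene_fixture()
  sites <- enumerate_gene_sites(fx$gm, fx$genome)
  cov <- uniform_coverage(sites, 1000)
  syn <- sites[sites$impact == "synonymous", ]
  calls <- syn[1:2, c("contig", "pos", "alt")]
  calls$n_mutant_bundles <- 1L
  rm <- fit_rate_model(calls, cov, sites)
  # k = 0 sites have p = 1
  sd0 <- site_dnds(calls[0, ], sites, rm, cov)
  expect_true(all(sd0$sites$p == 1))
  # a recurrent missense site gets a small Poisson tail p
  mis <- sites[sites$impact == "missense", ][1, ]
  hot <- mis[, c("contig", "pos", "alt")]
  hot$n_mutant_bundles <- 5L
  sdh <- site_dnds(hot, sites, rm, cov)
  row <- sdh$sites[sdh$sites$k == 5, ]
  expect_equal(nrow(row), 1)
  expect_equal(row$p, ppois(4, row$lambda, lower.tail = FALSE),
               tolerance = 1e-12)
  # restricted mode computes q over exactly the hotspot family
  hotlist <- sites[sites$impact == "missense", ][1:10, c("contig", "pos",
                                                         "alt")]
  sdr <- site_dnds(hot, sites, rm, cov, mode = "restricted",
                   hotspots = hotlist)
  expect_equal(nrow(sdr$sites), 10)
  # inconsistent input: recurrence at a zero-coverage site
  cov0 <- dplyr::mutate(cov, depth = 0)
  expect_error(site_dnds(hot, sites, rm, cov0),
               class = "duplexome_inconsistent_inputs")
})

test_that("within-gene site sets reproduce the gene-level joint test", {
  fx <- neutral_sim_fixture(n_genes = 4, exon_len = 300, seed = 81,
                            mut_rate = 5e-4)
  sim <- simulate_site_counts(fx$cfg, depth = 500, seed = 82, grid = fx$grid)
  rm <- fit_rate_model(sim$calls, sim$coverage, fx$grid)
  cnt <- gene_counts(sim$calls, fx$cfg$genes, rm, sim$coverage,
                     sites = fx$grid)
  gsel <- gene_dnds(cnt)
  g <- "g1"
  nonsyn <- fx$grid[fx$grid$gene_id == g &
                      fx$grid$impact %in% c("missense", "nonsense",
                                            "stop_loss", "essential_splice"), ]
  wg <- withingene_dnds(list(all_nonsyn = nonsyn[, c("contig", "pos",
                                                     "alt")]),
                        sim$calls, fx$grid, rm, sim$coverage)
  joint <- gsel[gsel$gene_id == g & gsel$impact == "all_nonsynonymous", ]
  expect_equal(wg$omega, joint$omega, tolerance = 1e-12)
  expect_equal(wg$p_two_sided, joint$p_two_sided, tolerance = 1e-12)
  # empty set errors
  expect_error(withingene_dnds(list(none = nonsyn[0, ]), sim$calls, fx$grid,
                               rm, sim$coverage),
               class = "duplexome_empty_site_set")
  # undeclared overlap errors; declared overlap is allowed
  expect_error(withingene_dnds(list(a = nonsyn, b = nonsyn), sim$calls,
                               fx$grid, rm, sim$coverage),
               class = "duplexome_overlapping_sets")
  wg2 <- withingene_dnds(list(a = nonsyn, b = nonsyn), sim$calls, fx$grid,
                         rm, sim$coverage, allow_overlap = TRUE)
  expect_equal(wg2$omega[1], wg2$omega[2])
  ct <- contrast_site_sets(wg2, "a", "b")
  expect_gt(ct$p, 0.99)
})

test_that("driver fraction and excess-driver counts follow (omega-1)/omega", {
  expect_equal(driver_fraction(5), 0.8)
  expect_equal(driver_fraction(1), 0)
  expect_equal(driver_fraction(0.5), 0)
  expect_equal(driver_fraction(68.4), (68.4 - 1) / 68.4)
  expect_equal(driver_fraction(68.4), 0.98538, tolerance = 1e-5)
  expect_error(driver_fraction(-1), class = "duplexome_negative_omega")
  one <- tibble::tibble(observed = 100, omega = 5, lower = 3, upper = 8)
  dc <- driver_count_excess(one)
  expect_equal(dc$drivers, 80)
  expect_equal(dc$lower, 100 * (3 - 1) / 3)
  expect_equal(dc$upper, 100 * (8 - 1) / 8)
  none <- tibble::tibble(observed = c(10, 20), omega = c(0.5, 1),
                         lower = c(0.1, 0.6), upper = c(0.9, 1.4))
  expect_equal(driver_count_excess(none)$drivers, 0)
})

test_that("mutant cell fractions double summed duplex VAFs under diploidy", {
  calls <- tibble::tibble(duplex_vaf = c(0.02, 0.03),
                          impact = c("missense", "missense"))
  f <- mutant_cell_fraction(calls)
  expect_equal(f$sum_vaf, 0.05)
  expect_equal(f$f, 0.10)
  expect_equal(mutant_cell_fraction(calls, ploidy = "haploid")$f, 0.05)
  expect_equal(f$range_low, 0.05)
  expect_equal(f$range_high, 0.10)
  # driver adjustment multiplies by the per-class driver fraction
  fd <- mutant_cell_fraction(calls, omega = tibble::tibble(
    impact = "missense", omega = 5))
  expect_equal(fd$driver_fraction_of_cells, 0.10 * 0.8)
  expect_error(mutant_cell_fraction(tibble::tibble(duplex_vaf = 1.2)),
               class = "duplexome_bad_vaf")
  expect_warning(mutant_cell_fraction(tibble::tibble(duplex_vaf = 0.6)),
                 "capped")
})

test_that("BH q-values match a reference step-up implementation", {
  set.seed(91)
  for (i in 1:5) {
    p <- runif(50)^2
    ref_bh <- function(p) {
      n <- length(p)
      o <- order(p)
      q <- p[o] * n / seq_len(n)
      q <- rev(cummin(rev(q)))
      out <- numeric(n)
      out[o] <- pmin(q, 1)
      out
    }
    counts <- tibble::tibble(gene_id = paste0("g", 1:50),
                             impact = "missense",
                             observed = rpois(50, 5), expected = 5)
    res <- gene_dnds(counts)
    mis <- res[res$impact == "missense", ]
    expect_equal(mis$q_two_sided, ref_bh(mis$p_two_sided), tolerance = 1e-12)
    expect_equal(p.adjust(p, "BH"), ref_bh(p), tolerance = 1e-12)
  }
})
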