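# Duplex consensus calling and the filter battery.

test_that("strand consensus needs two unanimous reads and takes min quality", {
  p <- filter_params(end_trim_bp = 0)
  # a single read gives an all-null consensus
  one <- strand_consensus("ACGT", intToUtf8(rep(40 + 33, 4)), p)
  expect_true(all(is.na(one$base)))
  # three agreeing reads: consensus quality is the minimum (35)
  quals <- vapply(c(35, 40, 38), function(q) intToUtf8(rep(q + 33, 4)),
                  character(1))
  three <- strand_consensus(rep("TTTT", 3), quals, p)
  expect_equal(three$base, rep("T", 4))
  expect_equal(three$qual, rep(35L, 4))
  # two reads disagreeing at one position: null there only
  two <- strand_consensus(c("TATT", "TCTT"),
                          rep(intToUtf8(rep(70 + 33, 4)), 2), p)
  expect_equal(two$base, c("T", NA, "T", "T"))
})

test_that("end trimming nulls the first and last 8 bp", {
  p <- filter_params()
  s <- strrep("A", 30)
  q <- intToUtf8(rep(90 + 33, 30))
  cons <- strand_consensus(c(s, s), c(q, q), p)
  expect_true(all(is.na(cons$base[c(1:8, 23:30)])))
  expect_true(all(cons$base[9:22] == "A"))
})

test_that("duplex calling requires strand agreement, quality and AS-XS", {
  fx <- toy_gene_fixture()
  ref <- get_seq(fx$genome, "chr1", 0, 40)
  p <- filter_params()
  # both strands agree on T over reference C at offset 19 (pos 18)
  mut <- mutate_at_offset(ref, 19, "T")
  b <- make_bundle(1, "chr1", 0, mut, mut, qual = 80)
  res <- duplex_call(b, fx$genome, p)
  expect_true(res$callable)
  cand <- res$called[res$called$base != res$called$ref, ]
  expect_equal(nrow(cand), 1)
  expect_equal(cand$pos, 18L)
  expect_equal(cand$ref, "C")
  expect_equal(cand$base, "T")
  # combined consensus quality 59 -> no call anywhere
  b59 <- make_bundle(2, "chr1", 0, mut, mut, qual = 59)
  expect_equal(nrow(duplex_call(b59, fx$genome, p)$called), 0)
  # AS-XS below 10 -> whole bundle uncallable
  b5 <- make_bundle(3, "chr1", 0, mut, mut, qual = 80, asxs = 5)
  res5 <- duplex_call(b5, fx$genome, p)
  expect_false(res5$callable)
  expect_equal(res5$reason, "asxs")
  # strand disagreement at the variant position -> no call there
  bd <- make_bundle(4, "chr1", 0, mut, ref, qual = 80)
  expect_false(18L %in% duplex_call(bd, fx$genome, p)$called$pos)
  # off-reference bundle is rejected with a diagnostic
  bo <- make_bundle(5, "chr1", 60, strrep("A", 40), strrep("A", 40))
  expect_error(duplex_call(bo, fx$genome, p),
               class = "duplexome_bundle_off_reference")
})

test_that("mean-mismatch limits allow one extra mismatch for variant bundles", {
  g <- genome_ref(c(c1 = strrep("A", 60)))
  p <- filter_params()
  base <- strrep("A", 60)
  with4 <- base
  for (o in c(20, 25, 30, 35)) with4 <- mutate_at_offset(with4, o, "G")
  b4 <- make_bundle(1, "c1", 0, with4, with4, qual = 80)
  res4 <- duplex_call(b4, g, p)
  expect_true(res4$callable)  # 4 mismatches, all called variants
  expect_equal(nrow(res4$called[res4$called$base != res4$called$ref, ]), 4)
  with5 <- mutate_at_offset(with4, 40, "G")
  b5 <- make_bundle(2, "c1", 0, with5, with5, qual = 80)
  res5 <- duplex_call(b5, g, p)
  expect_false(res5$callable)
  expect_equal(res5$reason, "mismatches")
  # 4 mean mismatches but strand-discordant (nothing called) -> limit 3
  with4b <- base
  for (o in c(20, 25, 30, 35)) with4b <- mutate_at_offset(with4b, o, "T")
  bnv <- make_bundle(3, "c1", 0, with4, with4b, qual = 80)
  resnv <- duplex_call(bnv, g, p)
  expect_false(resnv$callable)
  expect_equal(resnv$reason, "mismatches")
})

test_that("no called variant lies within the trimmed fragment ends", {
  sg <- sim_genome(n_genes = 2, seed = 21)
  cfg <- sim_config(sg$genome, sg$genes, n_clones = 10,
                    clone_model = "neutral", total_fraction = 1,
                    mut_rate = 2e-3, germline_density = 0, seed = 21)
  pop <- simulate_population(cfg)
  bs <- simulate_bundles(pop, 30, err = error_model(strand_error_rate = 0),
                         seed = 22)
  calls <- call_mutations(bs, sg$genome, germline_mode = "self")
  expect_gt(nrow(calls$calls), 0)
  # within-read offsets of every mutant base respect the 8 bp trim
  offs <- unlist(calls$mutant_offsets)
  expect_true(all(offs > 8))
  frag_len <- bs$reads$frag_end[1] - bs$reads$frag_start[1]
  expect_true(all(offs <= frag_len - 8))
})

test_that("the three VAFs use the documented denominators", {
  g <- genome_ref(c(c1 = strrep("C", 40)))
  alt_mol <- mutate_at_offset(strrep("C", 40), 20, "T")
  ref_mol <- strrep("C", 40)
  bundles <- list()
  # 2 mutant callable bundles
  for (i in 1:2) bundles[[i]] <- make_bundle(i, "c1", 0, alt_mol, alt_mol)
  # 18 reference callable bundles
  for (i in 3:20) bundles[[i]] <- make_bundle(i, "c1", 0, ref_mol, ref_mol)
  # 5 non-calling bundles (one read per strand), 2 of them mutant
  for (i in 21:25) {
    m <- if (i <= 22) alt_mol else ref_mol
    bundles[[i]] <- make_bundle(i, "c1", 0, m, m, n_a = 1, n_b = 1)
  }
  reads <- dplyr::bind_rows(bundles)
  v <- compute_vafs(reads, tibble::tibble(contig = "c1", pos = 19L,
                                          alt = "T"), g)
  expect_equal(v$callable_depth, 20L)
  expect_equal(v$n_mutant_bundles, 2L)
  expect_equal(v$duplex_vaf, 0.1)
  expect_equal(v$bam_vaf, 4 / 25)
  expect_equal(v$unbiased_vaf, 2 / 5)
  # all bundles callable -> unbiased VAF is missing
  v2 <- compute_vafs(dplyr::bind_rows(bundles[1:20]),
                     tibble::tibble(contig = "c1", pos = 19L, alt = "T"), g)
  expect_true(is.na(v2$unbiased_vaf))
})

test_that("germline and mask site filters behave as specified", {
  g <- genome_ref(c(c1 = strrep("C", 60)))
  alt_mol <- mutate_at_offset(strrep("C", 60), 20, "T")
  ref_mol <- strrep("C", 60)
  bundles <- list()
  for (i in 1:3) bundles[[i]] <- make_bundle(i, "c1", 0, alt_mol, alt_mol)
  for (i in 4:20) bundles[[i]] <- make_bundle(i, "c1", 0, ref_mol, ref_mol)
  reads <- dplyr::bind_rows(bundles)
  # self mode: BAM VAF 3/20 = 0.15 >= 0.10 -> germline
  calls_self <- call_mutations(reads, g, germline_mode = "self")
  expect_equal(calls_self$calls$filter, "germline_vaf")
  # matched mode, clean normal at 30x -> retained
  normal <- tibble::tibble(contig = "c1", pos = 19L, depth = 30, vaf = 0)
  calls_m <- call_mutations(reads, g, germline_mode = "matched",
                            normal = normal)
  expect_equal(calls_m$calls$filter, "PASS")
  # matched mode, normal VAF 0.5 -> germline; coverage 20x -> normal_coverage
  calls_g <- call_mutations(reads, g, germline_mode = "matched",
                            normal = dplyr::mutate(normal, vaf = 0.5))
  expect_equal(calls_g$calls$filter, "germline_vaf")
  calls_c <- call_mutations(reads, g, germline_mode = "matched",
                            normal = dplyr::mutate(normal, depth = 20))
  expect_equal(calls_c$calls$filter, "normal_coverage")
  # masked site
  m <- site_mask("c1", pos = 19L)
  calls_mask <- call_mutations(reads, g, mask = m, germline_mode = "matched",
                               normal = normal)
  expect_equal(calls_mask$calls$filter, "snp_noise_mask")
  # masked sites leave the coverage profile
  expect_false(19L %in% calls_mask$coverage$pos)
  # matched mode requires a normal
  expect_error(call_mutations(reads, g, germline_mode = "matched"),
               class = "duplexome_no_germline_source")
})

test_that("adjacent same-bundle substitutions merge into a DBS", {
  g <- genome_ref(c(c1 = strrep("C", 60)))
  mol <- mutate_at_offset(mutate_at_offset(strrep("C", 60), 25, "T"), 26, "G")
  reads <- dplyr::bind_rows(
    make_bundle(1, "c1", 0, mol, mol),
    lapply(2:30, function(i) make_bundle(i, "c1", 0, strrep("C", 60),
                                         strrep("C", 60))))
  calls <- call_mutations(reads, g, germline_mode = "self")
  expect_equal(calls$calls$type, "DBS")
  expect_equal(calls$calls$ref, "CC")
  expect_equal(calls$calls$alt, "TG")
  expect_equal(calls$calls$pos, 24L)
})

test_that("KS positional test flags read-position-biased artefacts", {
  set.seed(31)
  bg <- rep(9:130, 4)
  # strongly biased mutant positions
  biased <- ks_positional_test(rep(15, 20), bg, alpha = 1e-3)
  expect_true(biased$flagged)
  # mutant positions drawn from the background: flag rate ~ alpha
  n_flag <- 0
  for (i in 1:100) {
    mp <- sample(bg, 8)
    r <- ks_positional_test(mp, bg, alpha = 0.05)
    n_flag <- n_flag + r$flagged
  }
  expect_lt(n_flag, 20)
  # a single supporting molecule is never tested
  single <- ks_positional_test(15, bg, alpha = 0.5, min_support = 4)
  expect_false(single$flagged)
  expect_true(is.na(single$p_value))
  expect_error(ks_positional_test(rep(15, 5), numeric(0)),
               class = "duplexome_empty_background")
})

test_that("indel filters apply the four rules conjunctively and log removals", {
  mask <- site_mask("c1", start = 100L, end = 120L)
  indels <- tibble::tibble(
    contig = "c1",
    pos = c(110L, 200L, 300L, 400L, 500L),
    ref = c("CAA", "CA", "CA", "CA", "CAAA"),
    alt = "C",
    vaf = c(0.05, 0.05, 0.05, 0.2, 0.05),
    n_samples = c(1L, 51L, 1L, 1L, 1L),
    site_called = c(TRUE, TRUE, FALSE, TRUE, TRUE))
  res <- filter_indels(indels, mask = mask)
  expect_equal(nrow(res$kept), 1)
  expect_equal(res$kept$pos, 500L)
  reasons <- setNames(res$removed$filter, res$removed$pos)
  expect_equal(unname(reasons[c("110", "200", "300", "400")]),
               c("mask_overlap", "cohort_recurrence", "uncalled_site", "vaf"))
  expect_equal(sum(res$log$n[res$log$rule == "kept"]) +
                 sum(res$log$n[res$log$rule %in% unique(res$removed$filter)]),
               nrow(indels))
  # exactly 50% mask overlap is removed (">= 50%")
  half <- tibble::tibble(contig = "c1", pos = 118L, ref = "CAAA", alt = "C",
                         vaf = 0.05, n_samples = 1L, site_called = TRUE)
  expect_equal(filter_indels(half, mask = mask)$removed$filter, "mask_overlap")
})

test_that("per-rule removals plus kept calls account for every candidate", {
  sg <- sim_genome(n_genes = 3, seed = 41)
  cfg <- sim_config(sg$genome, sg$genes, n_clones = 30, mut_rate = 5e-4,
                    germline_density = 2e-3, seed = 41)
  pop <- simulate_population(cfg)
  bs <- simulate_bundles(pop, 25, err = error_model(strand_error_rate = 1e-4),
                         seed = 42)
  calls <- call_mutations(bs, sg$genome, germline_mode = "self")
  log <- calls$log
  n_cand <- log$n[log$rule == "candidates"]
  rule_sum <- sum(log$n[!log$rule %in% c("candidates", "kept",
                                         "mnv_excluded")])
  expect_equal(rule_sum + log$n[log$rule == "kept"], n_cand)
  expect_gt(n_cand, 0)
})
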