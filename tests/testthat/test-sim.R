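# Synthetic-data generator.

test_that("zero mutation rate yields zero somatic mutations", {
  sg <- sim_genome(n_genes = 2, seed = 3)
  cfg <- sim_config(sg$genome, sg$genes, mut_rate = 0,
                    germline_density = 0, seed = 3)
  pop <- simulate_population(cfg)
  expect_equal(nrow(pop$somatic), 0)
})

test_that("a heterozygous clone at cell fraction 0.10 has true VAF 0.05", {
  sg <- sim_genome(n_genes = 2, seed = 4)
  cfg <- sim_config(sg$genome, sg$genes, n_clones = 1,
                    total_fraction = 0.10, hom_prob = 0, mut_rate = 1e-3,
                    germline_density = 0, seed = 4)
  pop <- simulate_population(cfg)
  expect_gt(nrow(pop$somatic), 0)
  expect_true(all(pop$somatic$true_vaf == 0.05))
})

test_that("neutral mean mutation count matches the analytic expectation", {
  sg <- sim_genome(n_genes = 3, n_exons = 1, exon_len = 150, pad = 20,
                   seed = 5)
  r <- 2e-4
  profile <- setNames(rep(1, 96), channel_labels("SBS96"))
  n_clones <- 80
  total <- 0
  n_seeds <- 8
  S <- 0
  for (s in seq_len(n_seeds)) {
    cfg <- sim_config(sg$genome, sg$genes, n_clones = n_clones,
                      mut_rate = r, rate_profile = profile,
                      germline_density = 0, hom_prob = 0, seed = 100 + s)
    pop <- simulate_population(cfg)
    S <- length(unique(paste(pop$grid$contig, pop$grid$pos)))
    total <- total + nrow(pop$somatic)
  }
  expected <- r * S * n_clones * n_seeds
  expect_lt(abs(total - expected), 3 * sqrt(expected) + 3)
})

test_that("clone fractions never exceed one", {
  sg <- sim_genome(n_genes = 2, seed = 6)
  expect_error(sim_config(sg$genome, sg$genes, total_fraction = 1.2,
                          seed = 6))
})

test_that("depth zero yields an empty bundle set", {
  sg <- sim_genome(n_genes = 2, seed = 7)
  cfg <- sim_config(sg$genome, sg$genes, mut_rate = 1e-4, seed = 7)
  pop <- simulate_population(cfg)
  bs <- simulate_bundles(pop, target_duplex_depth = 0)
  expect_equal(nrow(bs$reads), 0)
})

test_that("mutant-bundle fraction at a VAF-0.5 site is binomial", {
  sg <- sim_genome(n_genes = 1, n_exons = 1, exon_len = 90, pad = 40,
                   seed = 8)
  cfg <- sim_config(sg$genome, sg$genes, n_clones = 1, total_fraction = 1,
                    hom_prob = 0, mut_rate = 0, germline_density = 0,
                    seed = 8)
  pop <- simulate_population(cfg)
  # plant one heterozygous mutation carried by the whole tissue (VAF 0.5)
  site <- 100L
  ref <- duplexome:::get_base(sg$genome, "g1", site)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  pop$somatic <- tibble::tibble(
    gene_id = "g1", contig = "g1", pos = site, ref = ref, alt = alt,
    impact = "missense", aa_change = NA_character_,
    channel96 = NA_character_, channel192 = NA_character_,
    clone_id = 1L, zygosity = "het", hap = 1L, true_vaf = 0.5)
  bs <- simulate_bundles(pop, target_duplex_depth = 250,
                         err = error_model(strand_error_rate = 0),
                         seed = 88)
  reads <- bs$reads
  cover <- reads[reads$frag_start <= site & reads$frag_end > site, ]
  one_per_bundle <- cover[!duplicated(cover$bundle_id), ]
  off <- site - one_per_bundle$frag_start + 1L
  is_mut <- substr(one_per_bundle$seq, off, off) == alt
  n <- nrow(one_per_bundle)
  expect_gt(n, 200)
  ci <- stats::binom.test(sum(is_mut), n, conf.level = 0.99)$conf.int
  expect_true(ci[1] <= 0.5 && 0.5 <= ci[2])
})

test_that("damage-only errors never reach both strands and are logged", {
  sg <- sim_genome(n_genes = 1, n_exons = 1, exon_len = 120, pad = 30,
                   seed = 9)
  cfg <- sim_config(sg$genome, sg$genes, mut_rate = 0,
                    germline_density = 0, seed = 9)
  pop <- simulate_population(cfg)
  bs <- simulate_bundles(pop, target_duplex_depth = 20,
                         err = error_model(strand_error_rate = 0,
                                           damage_rate = 0.01), seed = 99)
  expect_true(all(bs$truth$events$origin %in% c("damage", "error")))
  expect_gt(sum(bs$truth$events$origin == "damage"), 0)
  expect_equal(nrow(bs$truth$variants), 0)
  # no bundle shows the same non-reference base on both strand consensuses
  calls <- call_mutations(bs, sg$genome, germline_mode = "self")
  expect_equal(nrow(calls$calls), 0)
})

test_that("empirical mutant-bundle fractions converge to true VAFs", {
  sg <- sim_genome(n_genes = 1, n_exons = 1, exon_len = 60, pad = 45,
                   seed = 10)
  cfg <- sim_config(sg$genome, sg$genes, n_clones = 5, clone_model = "neutral",
                    total_fraction = 0.8, mut_rate = 5e-3, hom_prob = 0.3,
                    germline_density = 0, seed = 10)
  pop <- simulate_population(cfg)
  tv <- true_variants(pop)
  expect_gt(nrow(tv), 0)
  bs <- simulate_bundles(pop, target_duplex_depth = 300,
                         err = error_model(strand_error_rate = 0), seed = 111)
  reads <- bs$reads
  for (i in seq_len(min(nrow(tv), 5))) {
    cover <- reads[reads$contig == tv$contig[i] &
                     reads$frag_start <= tv$pos[i] &
                     reads$frag_end > tv$pos[i], ]
    one <- cover[!duplicated(cover$bundle_id), ]
    off <- tv$pos[i] - one$frag_start + 1L
    phat <- mean(substr(one$seq, off, off) == tv$alt[i])
    se <- sqrt(tv$true_vaf[i] * (1 - tv$true_vaf[i]) / nrow(one))
    expect_lt(abs(phat - tv$true_vaf[i]), 3 * se + 1e-9)
  }
})

test_that("simulation is reproducible from its seed", {
  sg <- sim_genome(n_genes = 2, seed = 12)
  cfg <- sim_config(sg$genome, sg$genes, mut_rate = 1e-4, seed = 12)
  p1 <- simulate_population(cfg)
  p2 <- simulate_population(cfg)
  expect_equal(p1$somatic, p2$somatic)
  b1 <- simulate_bundles(p1, 10, seed = 5)
  b2 <- simulate_bundles(p2, 10, seed = 5)
  expect_equal(b1$reads, b2$reads)
})
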