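# Synthetic polyclonal tissue simulator: cell populations.
#
# The generator emulates a polyclonal epithelium: the tissue is partitioned
# into many clones whose sizes follow a configurable growth law, each clone
# carries Poisson numbers of somatic mutations placed on a per-(site, alt)
# rate grid (trinucleotide-channel weighted, with planted selection in driver
# genes), on top of shared germline SNPs. Every simulated variant is recorded
# in a truth table with its true VAF.

#' Simulation configuration
#'
#' @param genome a `genome_ref`.
#' @param genes a `gene_models` tibble.
#' @param panel optional `target_panel`; defaults to the gene footprints plus
#'   `splice_window` flanks.
#' @param n_clones number of clones the tissue is partitioned into.
#' @param clone_model clone-size law: `"plateauing"` (exponential sizes capped
#'   at `clone_cap`), `"exponential"`, `"quadratic"` or `"neutral"` (equal
#'   fractions).
#' @param clone_cap cap on single-clone cell fraction (plateauing model).
#' @param clone_size_mean mean of the raw exponential clone-size draw.
#' @param total_fraction total cell fraction covered by clones (<= 1); the
#'   remainder of the tissue is mutation-free.
#' @param mut_rate somatic mutations per base per cell lineage.
#' @param rate_profile optional non-negative weight per SBS96 channel shaping
#'   relative channel mutabilities (recycled/normalised internally); default
#'   mildly elevated C>T.
#' @param drivers tibble with columns `gene_id`, `impact`, `omega`: planted
#'   selection multipliers on the mutation rate of matching (gene, impact)
#'   site-alternates.
#' @param hom_prob probability a somatic mutation is homozygous in its clone.
#' @param germline_density per-bp probability of a germline SNP.
#' @param germline_hom_prob probability a germline SNP is homozygous.
#' @param splice_window intronic enumeration window (see
#'   [enumerate_gene_sites()]).
#' @param seed mandatory integer seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(genome, genes, panel = NULL,
                       n_clones = 150, clone_model = "plateauing",
                       clone_cap = 0.03, clone_size_mean = 0.005,
                       total_fraction = 1,
                       mut_rate = 2e-6, rate_profile = NULL,
                       drivers = NULL, hom_prob = 0.1,
                       germline_density = 1e-3, germline_hom_prob = 0.3,
                       splice_window = 10, seed) {
  assert_that(!missing(seed) && length(seed) == 1 && is.finite(seed),
              "a seed is mandatory for reproducibility")
  clone_model <- match.arg(clone_model,
                           c("plateauing", "exponential", "quadratic",
                             "neutral"))
  assert_that(mut_rate >= 0 && germline_density >= 0 && hom_prob >= 0 &&
                hom_prob <= 1, "rates must be non-negative probabilities")
  assert_that(total_fraction > 0 && total_fraction <= 1,
              "total_fraction must be in (0, 1]")
  if (is.null(panel)) panel <- genes_panel(genes, flank = splice_window)
  if (is.null(rate_profile)) {
    w <- rep(1, 96)
    names(w) <- channel_labels("SBS96")
    w[grepl("C>T", names(w), fixed = TRUE)] <- 2.5
    rate_profile <- w
  }
  assert_that(all(rate_profile >= 0), "rate_profile weights must be >= 0")
  if (!is.null(drivers)) {
    drivers <- as_tibble(drivers)
    assert_that(all(c("gene_id", "impact", "omega") %in% names(drivers)) &&
                  all(drivers$omega >= 0),
                "drivers needs gene_id, impact, omega >= 0")
  }
  structure(list(genome = genome, genes = genes, panel = panel,
                 n_clones = n_clones, clone_model = clone_model,
                 clone_cap = clone_cap, clone_size_mean = clone_size_mean,
                 total_fraction = total_fraction, mut_rate = mut_rate,
                 rate_profile = rate_profile, drivers = drivers,
                 hom_prob = hom_prob, germline_density = germline_density,
                 germline_hom_prob = germline_hom_prob,
                 splice_window = splice_window, seed = as.integer(seed)),
            class = "sim_config")
}

#' Per-(site, alternate) mutation rate grid of a simulation config
#'
#' Genic sites come from the gene enumeration; remaining panel sites are
#' noncoding. Rates are per cell lineage, channel-weighted, with driver
#' multipliers applied.
#'
#' @param cfg a [sim_config()].
#' @return the site enumeration with a `rate` column.
#' @export
site_rate_grid <- function(cfg) {
  enum <- enumerate_gene_sites(cfg$genes, cfg$genome,
                               splice_window = cfg$splice_window)
  psites <- panel_sites(cfg$panel)
  extra <- anti_join(psites, distinct(enum[, c("contig", "pos")]),
                     by = c("contig", "pos"))
  if (nrow(extra) > 0) {
    refs <- character(nrow(extra))
    for (ctg in unique(extra$contig)) {
      sel <- extra$contig == ctg
      refs[sel] <- get_base(cfg$genome, ctg, extra$pos[sel])
    }
    keep <- refs %in% the_bases
    extra <- extra[keep, ]
    refs <- refs[keep]
    ctx <- character(nrow(extra))
    for (ctg in unique(extra$contig)) {
      sel <- extra$contig == ctg
      ctx[sel] <- get_context(cfg$genome, ctg, extra$pos[sel], 1)
    }
    extra <- tibble(gene_id = NA_character_, contig = rep(extra$contig, each = 1),
                    pos = extra$pos, ref = refs) |>
      (\(d) tibble(gene_id = rep(d$gene_id, each = 3),
                   contig = rep(d$contig, each = 3),
                   pos = rep(d$pos, each = 3),
                   ref = rep(d$ref, each = 3),
                   alt = unlist(alt_bases_for[d$ref], use.names = FALSE),
                   impact = "noncoding_other",
                   aa_change = NA_character_,
                   channel96 = sbs96_channel(rep(d$ref, each = 3),
                                             unlist(alt_bases_for[d$ref],
                                                    use.names = FALSE),
                                             rep(ctx, each = 3)),
                   channel192 = NA_character_))()
    enum <- bind_rows(enum, extra)
  }
  w <- cfg$rate_profile[enum$channel96]
  w[is.na(w)] <- mean(cfg$rate_profile)
  wbar <- mean(cfg$rate_profile)
  rate <- cfg$mut_rate * (w / wbar) / 3
  if (!is.null(cfg$drivers)) {
    key <- paste(enum$gene_id, enum$impact)
    dkey <- paste(cfg$drivers$gene_id, cfg$drivers$impact)
    m <- match(key, dkey)
    mult <- ifelse(is.na(m), 1, cfg$drivers$omega[m])
    rate <- rate * mult
  }
  enum$rate <- unname(rate)
  enum
}

clone_fractions <- function(cfg) {
  n <- cfg$n_clones
  raw <- switch(cfg$clone_model,
    plateauing = pmin(rexp(n, 1 / cfg$clone_size_mean), cfg$clone_cap),
    exponential = exp(3 * runif(n)) * cfg$clone_size_mean,
    quadratic = (runif(n))^2 * cfg$clone_size_mean * 10,
    neutral = rep(1, n)
  )
  f <- raw / sum(raw) * cfg$total_fraction
  assert_that(sum(f) <= 1 + 1e-9, "clone fractions exceed 1",
              class = "duplexome_fraction_error")
  f
}

#' Simulate a polyclonal cell population
#'
#' Reproducible given the config seed. Driver (gene, impact) combinations
#' receive mutations at `omega` times the neutral channel expectation.
#'
#' @param cfg a [sim_config()].
#' @return a `clone_population`: list with `clones` (clone_id, fraction),
#'   `somatic` (per-mutation rows with clone, zygosity, haplotype and true
#'   VAF), `germline`, the site-rate grid, and the config.
#' @export
simulate_population <- function(cfg) {
  assert_that(inherits(cfg, "sim_config"), "cfg must be a sim_config")
  with_seed(substream_seed(cfg$seed, "population"), {
    grid <- site_rate_grid(cfg)
    fracs <- clone_fractions(cfg)
    clones <- tibble(clone_id = seq_along(fracs), fraction = fracs)
    lambda_total <- sum(grid$rate)
    som <- NULL
    if (lambda_total > 0) {
      n_mut <- rpois(nrow(clones), lambda_total)
      idx <- unlist(lapply(seq_len(nrow(clones)), function(i) {
        if (n_mut[i] == 0) return(integer(0))
        sample.int(nrow(grid), n_mut[i], replace = TRUE,
                   prob = grid$rate)
      }))
      clone_of <- rep(clones$clone_id, n_mut)
      if (length(idx) > 0) {
        som <- grid[idx, c("gene_id", "contig", "pos", "ref", "alt",
                           "impact", "aa_change", "channel96", "channel192")]
        som$clone_id <- clone_of
        som$zygosity <- ifelse(runif(nrow(som)) < cfg$hom_prob,
                               "hom", "het")
        som$hap <- sample(1:2, nrow(som), replace = TRUE)
        som$true_vaf <- clones$fraction[som$clone_id] *
          ifelse(som$zygosity == "hom", 1, 0.5)
        # the same (clone, site) should not mutate twice
        som <- som[!duplicated(som[, c("clone_id", "contig", "pos")]), ]
      }
    }
    if (is.null(som)) {
      som <- tibble(gene_id = character(0), contig = character(0),
                    pos = integer(0), ref = character(0), alt = character(0),
                    impact = character(0), aa_change = character(0),
                    channel96 = character(0), channel192 = character(0),
                    clone_id = integer(0), zygosity = character(0),
                    hap = integer(0), true_vaf = numeric(0))
    }
    germ <- NULL
    if (cfg$germline_density > 0) {
      psites <- distinct(grid[, c("contig", "pos", "ref")])
      take <- runif(nrow(psites)) < cfg$germline_density
      gs <- psites[take, ]
      if (nrow(gs) > 0) {
        gs$alt <- vapply(gs$ref, function(r) sample(alt_bases_for[[r]], 1),
                         character(1))
        gs$genotype <- ifelse(runif(nrow(gs)) < cfg$germline_hom_prob,
                              "hom", "het")
        gs$hap <- sample(1:2, nrow(gs), replace = TRUE)
        gs$true_vaf <- ifelse(gs$genotype == "hom", 1, 0.5)
        germ <- gs
      }
    }
    if (is.null(germ)) {
      germ <- tibble(contig = character(0), pos = integer(0),
                     ref = character(0), alt = character(0),
                     genotype = character(0), hap = integer(0),
                     true_vaf = numeric(0))
    }
    structure(list(clones = clones, somatic = som, germline = germ,
                   grid = grid, config = cfg),
              class = "clone_population")
  })
}

#' @export
print.clone_population <- function(x, ...) {
  cat("<clone_population> ", nrow(x$clones), " clones, ",
      nrow(x$somatic), " somatic mutations, ", nrow(x$germline),
      " germline SNPs\n", sep = "")
  invisible(x)
}

#' Aggregate true somatic variants of a population
#'
#' Sums true VAFs across clones carrying the same (site, alt).
#'
#' @param pop a `clone_population`.
#' @return tibble with one row per distinct somatic variant and its true VAF.
#' @export
true_variants <- function(pop) {
  summarise(group_by(pop$somatic, .data$contig, .data$pos, .data$ref,
                     .data$alt, .data$gene_id, .data$impact,
                     .data$channel96),
            true_vaf = sum(.data$true_vaf), n_clones = n(),
            .groups = "drop")
}

#' Simulate mutant-molecule counts directly on the site grid
#'
#' Sequencing-free companion to [simulate_bundles()]: observed mutant
#' molecule counts per (site, alternate) are drawn as
#' `Poisson(rate x depth)` under the config's channel rates and planted
#' drivers — the observation model the selection stack assumes. Used for
#' calibration studies at mutation counts that would be wasteful to push
#' through read-level simulation.
#'
#' @param cfg a [sim_config()]; `mut_rate` is interpreted per molecule here.
#' @param depth uniform duplex depth applied to every panel site (or a
#'   coverage tibble `contig`, `pos`, `depth`).
#' @param seed integer seed (defaults to a substream of the config seed).
#' @param grid optional precomputed [site_rate_grid()] to reuse across
#'   replicates.
#' @return list with `calls` (`contig`, `pos`, `ref`, `alt`, gene/impact
#'   annotation, `n_mutant_bundles`), `coverage`, and the `grid`.
#' @export
simulate_site_counts <- function(cfg, depth, seed = NULL, grid = NULL) {
  assert_that(inherits(cfg, "sim_config"), "cfg must be a sim_config")
  if (is.null(grid)) grid <- site_rate_grid(cfg)
  seed <- seed %||% substream_seed(cfg$seed, "site_counts")
  if (is.data.frame(depth)) {
    cov <- as_tibble(depth)[, c("contig", "pos", "depth")]
  } else {
    cov <- distinct(grid[, c("contig", "pos")])
    cov$depth <- depth
  }
  g <- left_join(grid, cov, by = c("contig", "pos"))
  g$depth[is.na(g$depth)] <- 0
  with_seed(seed, {
    k <- rpois(nrow(g), g$rate * g$depth)
    hit <- k > 0
    calls <- g[hit, c("gene_id", "contig", "pos", "ref", "alt", "impact",
                      "aa_change", "channel96", "channel192")]
    calls$n_mutant_bundles <- k[hit]
    list(calls = calls, coverage = cov, grid = grid)
  })
}
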