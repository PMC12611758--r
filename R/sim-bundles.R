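# Synthetic duplex read bundles.
#
# Each bundle is the set of reads derived from both strands of one original
# DNA fragment sampled from one cell. Damage lesions are applied to a single
# strand of the molecule (so they can never produce duplex consensus);
# sequencing/PCR errors are applied independently per read; mapping-artifact
# sites inject mutant bases at molecule level with a read-positional bias.

#' Error model for bundle simulation
#'
#' @param strand_error_rate independent per-read, per-base error probability.
#' @param damage_rate per-base probability of a single-strand lesion on the
#'   molecule (copied to all reads of one strand only).
#' @param artifact_sites tibble with columns `contig`, `pos`, `alt`, `rate`,
#'   `offset_min`, `offset_max`: molecule-level injection of `alt` with
#'   probability `rate` when the site falls at a within-read offset (1-based)
#'   inside the window — producing read-positionally biased artefacts.
#' @param contamination_fraction fraction of bundles drawn from a second
#'   (contaminant) individual.
#' @param reads_per_strand_mean mean of the zero-truncated Poisson read count
#'   per strand.
#' @param base_qual constant per-base quality of simulated reads.
#' @param asxs alignment-score margin (AS-XS) assigned to every bundle.
#' @param frag_len fragment length.
#' @return an `error_model` list.
#' @export
error_model <- function(strand_error_rate = 1e-4, damage_rate = 0,
                        artifact_sites = NULL, contamination_fraction = 0,
                        reads_per_strand_mean = 3, base_qual = 90,
                        asxs = 50, frag_len = 150) {
  rates <- c(strand_error_rate, damage_rate, contamination_fraction)
  assert_that(all(rates >= 0 & rates <= 1), "rates must be in [0, 1]")
  if (!is.null(artifact_sites)) {
    artifact_sites <- as_tibble(artifact_sites)
    assert_that(all(c("contig", "pos", "alt", "rate", "offset_min",
                      "offset_max") %in% names(artifact_sites)),
                "artifact_sites missing required columns")
  }
  structure(list(strand_error_rate = strand_error_rate,
                 damage_rate = damage_rate,
                 artifact_sites = artifact_sites,
                 contamination_fraction = contamination_fraction,
                 reads_per_strand_mean = reads_per_strand_mean,
                 base_qual = base_qual, asxs = asxs, frag_len = frag_len),
            class = "error_model")
}

rztpois <- function(n, mean) {
  if (n == 0) return(integer(0))
  qpois(runif(n, ppois(0, mean), 1), mean)
}

# Probability a bundle reaches the 2+2 duplex requirement under the
# zero-truncated Poisson reads-per-strand model.
callable_bundle_prob <- function(mean) {
  p2 <- (1 - ppois(1, mean)) / (1 - ppois(0, mean))
  p2^2
}

mutate_string_at <- function(s, offsets, bases) {
  for (i in seq_along(offsets)) {
    substr(s, offsets[i], offsets[i]) <- bases[i]
  }
  s
}

random_other_base <- function(cur) {
  vapply(cur, function(b) sample(setdiff(the_bases, b), 1), character(1),
         USE.NAMES = FALSE)
}

#' Simulate duplex read bundles from a cell population
#'
#' Samples fragments uniformly over the panel, each from one cell (clone)
#' picked by cell fraction; germline and clonal somatic variants are applied
#' haplotype-consistently; lesions, errors and artefacts are injected per the
#' error model; reads per strand follow a zero-truncated Poisson.
#'
#' @param pop a `clone_population`.
#' @param target_duplex_depth target mean callable duplex depth per site.
#' @param err an [error_model()].
#' @param panel optional panel override (defaults to the population's).
#' @param seed integer seed (defaults to a substream of the config seed).
#' @return list with `reads` (the bundle table: one row per read), `truth`
#'   (variant origins and event log) and `bundles` (per-bundle source
#'   metadata). Class `bundle_set`.
#' @export
simulate_bundles <- function(pop, target_duplex_depth, err = error_model(),
                             panel = NULL, seed = NULL) {
  assert_that(inherits(pop, "clone_population"),
              "pop must be a clone_population")
  assert_that(target_duplex_depth >= 0, "depth must be >= 0")
  cfg <- pop$config
  panel <- panel %||% cfg$panel
  seed <- seed %||% substream_seed(cfg$seed, "bundles")
  with_seed(seed, {
    frag_len <- err$frag_len
    ivs <- as_tibble(panel)
    ivs$len <- ivs$end - ivs$start
    panel_bp <- sum(ivs$len)
    n_bundles <- round(target_duplex_depth * panel_bp /
                         (frag_len * callable_bundle_prob(err$reads_per_strand_mean)))
    reads_out <- vector("list", n_bundles)
    meta_out <- vector("list", n_bundles)
    events <- list()
    germ <- pop$germline
    # contaminant: an unrelated diploid individual; independent genotypes at
    # the same germline SNP sites
    contam_germ <- NULL
    if (err$contamination_fraction > 0 && nrow(germ) > 0) {
      contam_germ <- germ
      contam_germ$genotype <- sample(c("hom", "het", "absent"), nrow(germ),
                                     replace = TRUE, prob = c(.25, .5, .25))
      contam_germ <- contam_germ[contam_germ$genotype != "absent", ]
      contam_germ$hap <- sample(1:2, nrow(contam_germ), replace = TRUE)
    }
    som <- pop$somatic
    qual_chr <- strrep(intToUtf8(min(err$base_qual, 93) + 33L), frag_len)
    if (n_bundles == 0) {
      return(empty_bundle_set(pop, events))
    }
    # sample fragment locations
    iv_idx <- sample.int(nrow(ivs), n_bundles, replace = TRUE,
                         prob = ivs$len)
    starts <- ivs$start[iv_idx] +
      floor(runif(n_bundles) * pmax(1, ivs$len[iv_idx] - frag_len + 1))
    contigs <- ivs$contig[iv_idx]
    is_contam <- runif(n_bundles) < err$contamination_fraction
    u <- runif(n_bundles)
    cum <- cumsum(pop$clones$fraction)
    clone_pick <- findInterval(u, cum) + 1L  # > n_clones => unmutated background
    clone_pick[clone_pick > nrow(pop$clones)] <- NA_integer_
    haps <- sample(1:2, n_bundles, replace = TRUE)
    kA <- rztpois(n_bundles, err$reads_per_strand_mean)
    kB <- rztpois(n_bundles, err$reads_per_strand_mean)

    for (b in seq_len(n_bundles)) {
      ctg <- contigs[b]
      fs <- starts[b]
      fe <- min(fs + frag_len, contig_length(cfg$genome, ctg))
      L <- fe - fs
      mol <- get_seq(cfg$genome, ctg, fs, fe)
      gsrc <- if (is_contam[b]) contam_germ else germ
      if (!is.null(gsrc) && nrow(gsrc) > 0) {
        gg <- gsrc[gsrc$contig == ctg & gsrc$pos >= fs & gsrc$pos < fe, ]
        gg <- gg[gg$genotype == "hom" | gg$hap == haps[b], ]
        if (nrow(gg) > 0) {
          mol <- mutate_string_at(mol, gg$pos - fs + 1L, gg$alt)
        }
      }
      if (!is_contam[b] && !is.na(clone_pick[b]) && nrow(som) > 0) {
        ss <- som[som$clone_id == clone_pick[b] & som$contig == ctg &
                    som$pos >= fs & som$pos < fe, ]
        ss <- ss[ss$zygosity == "hom" | ss$hap == haps[b], ]
        if (nrow(ss) > 0) {
          mol <- mutate_string_at(mol, ss$pos - fs + 1L, ss$alt)
        }
      }
      # artefact injection (molecule level, positionally biased)
      if (!is.null(err$artifact_sites)) {
        aa <- err$artifact_sites
        aa <- aa[aa$contig == ctg & aa$pos >= fs & aa$pos < fe, ]
        if (nrow(aa) > 0) {
          off <- aa$pos - fs + 1L
          hit <- off >= aa$offset_min & off <= aa$offset_max &
            runif(nrow(aa)) < aa$rate
          if (any(hit)) {
            mol <- mutate_string_at(mol, off[hit], aa$alt[hit])
            events[[length(events) + 1]] <- tibble(
              contig = ctg, pos = aa$pos[hit],
              ref = get_base(cfg$genome, ctg, aa$pos[hit]),
              alt = aa$alt[hit], origin = "artifact")
          }
        }
      }
      molA <- mol
      molB <- mol
      if (err$damage_rate > 0) {
        nles <- rbinom(1, L, err$damage_rate)
        if (nles > 0) {
          at <- sample.int(L, nles)
          cur <- substring(mol, at, at)
          dalt <- random_other_base(cur)
          which_strand <- sample(c("A", "B"), 1)
          if (which_strand == "A") {
            molA <- mutate_string_at(molA, at, dalt)
          } else {
            molB <- mutate_string_at(molB, at, dalt)
          }
          events[[length(events) + 1]] <- tibble(
            contig = ctg, pos = fs + at - 1L, ref = cur, alt = dalt,
            origin = "damage")
        }
      }
      make_reads <- function(strand_mol, k, strand) {
        seqs <- character(k)
        for (r in seq_len(k)) {
          s <- strand_mol
          if (err$strand_error_rate > 0) {
            nerr <- rbinom(1, L, err$strand_error_rate)
            if (nerr > 0) {
              at <- sample.int(L, nerr)
              cur <- substring(s, at, at)
              ealt <- random_other_base(cur)
              s <- mutate_string_at(s, at, ealt)
              events[[length(events) + 1]] <<- tibble(
                contig = ctg, pos = fs + at - 1L, ref = cur, alt = ealt,
                origin = "error")
            }
          }
          seqs[r] <- s
        }
        tibble(bundle_id = b, contig = ctg, frag_start = fs, frag_end = fe,
               strand = strand, read_id = paste0("b", b, strand,
                                                 seq_len(k)),
               seq = seqs, qual = substr(qual_chr, 1, L), asxs = err$asxs)
      }
      reads_out[[b]] <- bind_rows(make_reads(molA, kA[b], "A"),
                                  make_reads(molB, kB[b], "B"))
      meta_out[[b]] <- tibble(bundle_id = b, contig = ctg, frag_start = fs,
                              frag_end = fe,
                              source = if (is_contam[b]) "contaminant"
                                       else if (is.na(clone_pick[b])) "background"
                                       else paste0("clone", clone_pick[b]))
    }
    truth_variants <- bind_rows(
      if (nrow(pop$somatic) > 0) mutate(true_variants(pop), origin = "somatic"),
      if (nrow(germ) > 0) tibble(contig = germ$contig, pos = germ$pos,
                                 ref = germ$ref, alt = germ$alt,
                                 true_vaf = germ$true_vaf * (1 - err$contamination_fraction),
                                 origin = "germline"),
      if (!is.null(contam_germ) && nrow(contam_germ) > 0) {
        tibble(contig = contam_germ$contig, pos = contam_germ$pos,
               ref = contam_germ$ref, alt = contam_germ$alt,
               true_vaf = contam_germ$true_vaf * err$contamination_fraction,
               origin = "contaminant")
      }
    )
    event_log <- if (length(events)) bind_rows(events) else
      tibble(contig = character(0), pos = integer(0), ref = character(0),
             alt = character(0), origin = character(0))
    structure(list(reads = bind_rows(reads_out),
                   bundles = bind_rows(meta_out),
                   truth = list(variants = truth_variants,
                                events = event_log)),
              class = "bundle_set")
  })
}

empty_bundle_set <- function(pop, events) {
  structure(list(
    reads = tibble(bundle_id = integer(0), contig = character(0),
                   frag_start = integer(0), frag_end = integer(0),
                   strand = character(0), read_id = character(0),
                   seq = character(0), qual = character(0),
                   asxs = numeric(0)),
    bundles = tibble(bundle_id = integer(0), contig = character(0),
                     frag_start = integer(0), frag_end = integer(0),
                     source = character(0)),
    truth = list(variants = tibble(contig = character(0), pos = integer(0),
                                   ref = character(0), alt = character(0),
                                   true_vaf = numeric(0),
                                   origin = character(0)),
                 events = tibble(contig = character(0), pos = integer(0),
                                 ref = character(0), alt = character(0),
                                 origin = character(0)))),
    class = "bundle_set")
}

#' @export
print.bundle_set <- function(x, ...) {
  cat("<bundle_set> ", length(unique(x$reads$bundle_id)), " bundles, ",
      nrow(x$reads), " reads\n", sep = "")
  invisible(x)
}
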