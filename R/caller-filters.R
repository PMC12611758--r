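# Variant filter battery, VAFs and the calling pipeline.

#' SNP+noise site mask
#'
#' A blacklist of sites (common germline SNPs and recurrent mapping
#' artefacts). Stored as merged intervals; membership queries are
#' binary-search based.
#'
#' @param contig,start,end 0-based half-open intervals, or a data frame with
#'   those columns; single sites can be given via `pos` (start = pos,
#'   end = pos + 1).
#' @param pos optional site positions (alternative to start/end).
#' @return a `site_mask` object.
#' @export
site_mask <- function(contig, start = NULL, end = NULL, pos = NULL) {
  if (is.data.frame(contig)) {
    df <- contig
    if ("pos" %in% names(df) && !"start" %in% names(df)) {
      df$start <- df$pos
      df$end <- df$pos + 1L
    }
  } else if (!is.null(pos)) {
    df <- tibble(contig = contig, start = as.integer(pos),
                 end = as.integer(pos) + 1L)
  } else {
    df <- tibble(contig = contig, start = as.integer(start),
                 end = as.integer(end))
  }
  df <- suppressWarnings(target_panel(df[, c("contig", "start", "end")]))
  structure(list(intervals = as_tibble(df)[, c("contig", "start", "end")]),
            class = "site_mask")
}

#' Read a site mask from BED
#' @param path BED path.
#' @return a `site_mask`.
#' @export
read_site_mask <- function(path) {
  site_mask(as_tibble(read_bed_panel(path)))
}

mask_covers <- function(mask, contig, pos) {
  if (is.null(mask)) return(rep(FALSE, length(pos)))
  out <- rep(FALSE, length(pos))
  iv <- mask$intervals
  for (ctg in unique(contig)) {
    sub <- iv[iv$contig == ctg, ]
    sel <- contig == ctg
    if (nrow(sub) == 0) next
    i <- findInterval(pos[sel], sub$start)
    hit <- i >= 1 & pos[sel] < sub$end[pmax(i, 1)]
    out[sel] <- hit
  }
  out
}

mask_overlap_fraction <- function(mask, contig, start, end) {
  if (is.null(mask)) return(rep(0, length(start)))
  iv <- mask$intervals
  vapply(seq_along(start), function(i) {
    sub <- iv[iv$contig == contig[i], ]
    if (nrow(sub) == 0) return(0)
    ov <- pmax(0, pmin(sub$end, end[i]) - pmax(sub$start, start[i]))
    sum(ov) / (end[i] - start[i])
  }, numeric(1))
}

#' Read-positional Kolmogorov-Smirnov artefact test
#'
#' Recurrent mapping artefacts tend to place the mutant base at specific
#' positions within reads. The test compares the within-read positions of
#' mutant bases against the background positions of called bases at the same
#' locus with a two-sample two-sided KS test (exact for small samples).
#' Variants with mutant support below `min_support` are not tested and never
#' flagged.
#'
#' @param mutant_positions within-read positions of the mutant bases (pooled
#'   across samples for the variant site).
#' @param background_positions within-read positions of all called bases at
#'   the locus.
#' @param alpha flagging level.
#' @param min_support minimum mutant support to run the test.
#' @return tibble with `statistic`, `p_value`, `flagged`, `n_mutant`.
#' @export
ks_positional_test <- function(mutant_positions, background_positions,
                               alpha = 1e-3, min_support = 4) {
  assert_that(length(background_positions) > 0, "empty background",
              class = "duplexome_empty_background")
  n <- length(mutant_positions)
  if (n < min_support) {
    return(tibble(statistic = NA_real_, p_value = NA_real_, flagged = FALSE,
                  n_mutant = n))
  }
  kt <- suppressWarnings(ks.test(mutant_positions, background_positions))
  tibble(statistic = unname(kt$statistic), p_value = kt$p.value,
         flagged = kt$p.value < alpha, n_mutant = n)
}

#' Duplex, BAM and unbiased VAFs at a locus
#'
#' * duplex VAF: fraction of callable (2+2) bundles at the locus supporting
#'   the mutation;
#' * BAM VAF: fraction over one representative read per bundle, calling and
#'   non-calling bundles alike;
#' * unbiased VAF: representatives of non-calling bundles only (`NA` when no
#'   non-calling bundle spans the locus).
#'
#' Representatives are chosen by a seeded shuffle so results are
#' deterministic given the seed.
#'
#' @param bundles a `bundle_set` or its `reads` tibble.
#' @param variants tibble with `contig`, `pos`, `alt` loci to evaluate.
#' @param genome a `genome_ref`.
#' @param params a [filter_params()].
#' @param seed seed for representative selection.
#' @return `variants` with columns `n_mutant_bundles`, `callable_depth`,
#'   `duplex_vaf`, `bam_vaf`, `unbiased_vaf` appended.
#' @export
compute_vafs <- function(bundles, variants, genome, params = filter_params(),
                         seed = 1) {
  cd <- call_bundles(bundles, genome, params, seed = seed)
  vaf_table(cd, as_tibble(variants))
}

# Run duplex consensus over every bundle. Internal workhorse shared by
# compute_vafs() and call_mutations().
call_bundles <- function(bundles, genome, params = filter_params(),
                         seed = 1) {
  reads <- if (inherits(bundles, "bundle_set")) bundles$reads else
    as_tibble(bundles)
  meta <- distinct(reads[, c("bundle_id", "contig", "frag_start",
                             "frag_end", "asxs")])
  by_bundle <- split(reads, reads$bundle_id)
  res <- lapply(by_bundle, function(b) duplex_call(b, genome, params))
  called <- bind_rows(lapply(seq_along(res), function(i) {
    cc <- res[[i]]$called
    if (nrow(cc)) cc$bundle_id <- by_bundle[[i]]$bundle_id[1]
    cc
  }))
  callable <- tibble(
    bundle_id = vapply(by_bundle, function(b) b$bundle_id[1], numeric(1)),
    callable = vapply(res, function(r) r$callable, logical(1)),
    reason = vapply(res, function(r) r$reason, character(1))
  )
  # seeded representative read per bundle (deduplicated-BAM stand-in)
  rep_reads <- with_seed(substream_seed(seed, "dedup"), {
    u <- runif(nrow(reads))
    idx <- tapply(seq_len(nrow(reads)), reads$bundle_id,
                  function(ii) ii[which.min(u[ii])])
    reads[unlist(idx), ]
  })
  list(called = called, callable = callable, meta = meta,
       rep_reads = rep_reads, reads = reads)
}

vaf_table <- function(cd, variants) {
  v <- variants
  n <- nrow(v)
  v$n_mutant_bundles <- integer(n)
  v$callable_depth <- integer(n)
  v$bam_vaf <- numeric(n)
  v$unbiased_vaf <- numeric(n)
  called <- cd$called
  for (i in seq_len(n)) {
    at <- called[called$contig == v$contig[i] & called$pos == v$pos[i], ]
    v$callable_depth[i] <- nrow(at)
    v$n_mutant_bundles[i] <- sum(at$base == v$alt[i])
    covering <- cd$rep_reads[cd$rep_reads$contig == v$contig[i] &
                               cd$rep_reads$frag_start <= v$pos[i] &
                               cd$rep_reads$frag_end > v$pos[i], ]
    if (nrow(covering) == 0) {
      v$bam_vaf[i] <- NA_real_
      v$unbiased_vaf[i] <- NA_real_
      next
    }
    off <- v$pos[i] - covering$frag_start + 1L
    rep_base <- substr(covering$seq, off, off)
    v$bam_vaf[i] <- mean(rep_base == v$alt[i])
    calling_ids <- at$bundle_id
    nonc <- !(covering$bundle_id %in% calling_ids)
    v$unbiased_vaf[i] <- if (any(nonc)) {
      mean(rep_base[nonc] == v$alt[i])
    } else {
      NA_real_
    }
  }
  v$duplex_vaf <- ifelse(v$callable_depth > 0,
                         v$n_mutant_bundles / v$callable_depth, NA_real_)
  v
}

#' Call somatic mutations from duplex read bundles
#'
#' Runs duplex consensus over every bundle, forms SNV and DBS candidates,
#' computes the three VAFs, applies the site filter battery (SNP+noise mask,
#' matched-normal or self-sample germline filter, read-positional KS artefact
#' test) and returns the calls together with the callable duplex coverage
#' profile and an itemised filter log. Every filter is recorded as its own
#' flag column so rules can be ablated individually; removals attributed to
#' the first failing rule plus kept calls always sum to the candidate count.
#'
#' @param bundles a `bundle_set` or reads tibble.
#' @param genome a `genome_ref`.
#' @param params a [filter_params()].
#' @param mask optional [site_mask()].
#' @param normal optional matched-normal pileup tibble (`contig`, `pos`,
#'   `depth`, `vaf`; an `alt` column makes the VAF allele-specific).
#' @param germline_mode `"self"` (sample BAM VAF >= `germline_self_vaf`
#'   filtered as germline) or `"matched"` (requires `normal`).
#' @param sample_id sample label attached to calls.
#' @param seed seed for the representative-read shuffle.
#' @return a `duplex_calls` object: list with `calls`, `coverage`, `log`,
#'   `params`, `sample_id`.
#' @export
call_mutations <- function(bundles, genome, params = filter_params(),
                           mask = NULL, normal = NULL,
                           germline_mode = c("self", "matched"),
                           sample_id = "S1", seed = 1) {
  germline_mode <- match.arg(germline_mode)
  if (germline_mode == "matched") {
    assert_that(!is.null(normal), "matched mode requires a normal pileup",
                class = "duplexome_no_germline_source")
  }
  cd <- call_bundles(bundles, genome, params, seed = seed)
  called <- cd$called

  coverage <- count(called, .data$contig, .data$pos, name = "depth")

  # SNV/DBS candidates: per bundle, runs of adjacent non-reference calls
  cands <- called[called$base != called$ref, ]
  snv <- NULL
  dbs <- NULL
  n_mnv <- 0L
  if (nrow(cands) > 0) {
    cands <- arrange(cands, .data$bundle_id, .data$contig, .data$pos)
    run_id <- cumsum(c(TRUE, !(diff(cands$pos) == 1 &
                                 cands$bundle_id[-1] == cands$bundle_id[-nrow(cands)] &
                                 cands$contig[-1] == cands$contig[-nrow(cands)])))
    runs <- split(cands, run_id)
    lens <- vapply(runs, nrow, integer(1))
    snv <- bind_rows(runs[lens == 1])
    dbs_runs <- runs[lens == 2]
    n_mnv <- sum(lens > 2)
    if (length(dbs_runs)) {
      dbs <- bind_rows(lapply(dbs_runs, function(r) {
        tibble(bundle_id = r$bundle_id[1], contig = r$contig[1],
               pos = r$pos[1], offset = r$offset[1],
               ref = paste(r$ref, collapse = ""),
               base = paste(r$base, collapse = ""),
               qual = min(r$qual))
      }))
    }
  }
  mk_variant_table <- function(per_bundle, type) {
    if (is.null(per_bundle) || nrow(per_bundle) == 0) return(NULL)
    agg <- summarise(group_by(per_bundle, .data$contig, .data$pos,
                              .data$ref, .data$base),
                     n_mutant_bundles = n(),
                     mutant_offsets = list(.data$offset),
                     min_qual = min(.data$qual), .groups = "drop")
    agg$type <- type
    rename(agg, alt = "base")
  }
  vt <- bind_rows(mk_variant_table(snv, "SNV"), mk_variant_table(dbs, "DBS"))
  if (is.null(vt) || nrow(vt) == 0) {
    vt <- tibble(contig = character(0), pos = integer(0), ref = character(0),
                 alt = character(0), n_mutant_bundles = integer(0),
                 mutant_offsets = list(), min_qual = integer(0),
                 type = character(0))
  }

  # VAFs (duplex vaf denominators only count called bases at the locus)
  vt <- vaf_table(cd, vt)

  # site filters
  vt$flag_mask <- mask_covers(mask, vt$contig, vt$pos)
  if (germline_mode == "matched") {
    nm <- as_tibble(normal)
    key <- if ("alt" %in% names(nm)) c("contig", "pos", "alt") else
      c("contig", "pos")
    nm <- nm[, unique(c(key, "depth", "vaf"))]
    names(nm)[names(nm) == "depth"] <- "normal_depth"
    names(nm)[names(nm) == "vaf"] <- "normal_vaf"
    vt <- left_join(vt, nm, by = key)
    vt$flag_normal_cov <- is.na(vt$normal_depth) |
      vt$normal_depth < params$min_normal_cov
    vt$flag_germline <- !is.na(vt$normal_vaf) &
      vt$normal_vaf >= params$max_normal_vaf
  } else {
    vt$flag_normal_cov <- FALSE
    vt$flag_germline <- !is.na(vt$bam_vaf) &
      vt$bam_vaf >= params$germline_self_vaf
  }
  # KS read-positional artefact test, per variant site
  vt$ks_p <- NA_real_
  vt$flag_ks <- FALSE
  for (i in seq_len(nrow(vt))) {
    if (vt$n_mutant_bundles[i] < params$ks_min_support) next
    bg <- called[called$contig == vt$contig[i] & called$pos == vt$pos[i], ]
    kt <- ks_positional_test(vt$mutant_offsets[[i]], bg$offset,
                             alpha = params$ks_alpha,
                             min_support = params$ks_min_support)
    vt$ks_p[i] <- kt$p_value
    vt$flag_ks[i] <- kt$flagged
  }

  rules <- c("flag_mask", "flag_normal_cov", "flag_germline", "flag_ks")
  rule_names <- c("snp_noise_mask", "normal_coverage", "germline_vaf",
                  "ks_positional")
  first_rule <- rep(NA_character_, nrow(vt))
  for (j in rev(seq_along(rules))) {
    first_rule[vt[[rules[j]]]] <- rule_names[j]
  }
  vt$filter <- ifelse(is.na(first_rule), "PASS", first_rule)
  vt$sample <- sample_id

  # coverage profile: only bases surviving the site-level filters
  cov_keep <- !mask_covers(mask, coverage$contig, coverage$pos)
  if (germline_mode == "matched") {
    nm <- as_tibble(normal)
    nm_site <- distinct(nm[, c("contig", "pos", "depth")])
    names(nm_site)[3] <- "normal_depth"
    cov2 <- left_join(coverage, nm_site, by = c("contig", "pos"))
    cov_keep <- cov_keep & !is.na(cov2$normal_depth) &
      cov2$normal_depth >= params$min_normal_cov
  }
  coverage <- coverage[cov_keep, ]

  log <- bind_rows(
    tibble(rule = "candidates", n = nrow(vt)),
    tibble(rule = rule_names,
           n = vapply(rules, function(r) sum(vt$filter ==
                                               rule_names[match(r, rules)]),
                      numeric(1))),
    tibble(rule = "mnv_excluded", n = n_mnv),
    tibble(rule = "kept", n = sum(vt$filter == "PASS"))
  )
  structure(list(calls = select(vt, -"mutant_offsets"),
                 mutant_offsets = setNames(vt$mutant_offsets,
                                           paste(vt$contig, vt$pos, vt$alt)),
                 coverage = coverage, log = log, params = params,
                 sample_id = sample_id),
            class = "duplex_calls")
}

#' @export
print.duplex_calls <- function(x, ...) {
  cat("<duplex_calls> sample ", x$sample_id, ": ",
      sum(x$calls$filter == "PASS"), " PASS / ", nrow(x$calls),
      " candidate variants; ", nrow(x$coverage), " covered sites (mean dx ",
      round(mean(x$coverage$depth), 1), ")\n", sep = "")
  invisible(x)
}

#' Passing calls of a duplex_calls object
#' @param x a `duplex_calls` object.
#' @return tibble of PASS calls.
#' @export
passing_calls <- function(x) {
  x$calls[x$calls$filter == "PASS", ]
}

#' Filter indel candidates
#'
#' Applies the four indel rules conjunctively: removed if mask overlap is
#' `indel_mask_overlap` (50%) or greater, if the site has no called base, if
#' the VAF exceeds `indel_max_vaf`, or if seen in more than
#' `indel_max_samples` samples. Removals are itemised per rule in the log.
#'
#' @param indels tibble with columns `contig`, `pos`, `ref`, `alt`, `vaf`,
#'   `n_samples`, and either `site_called` (logical) or nothing (assumed
#'   called); `mask_overlap` may be precomputed, otherwise it is derived from
#'   `mask`.
#' @param mask optional [site_mask()].
#' @param params a [filter_params()].
#' @return list with `kept`, `removed` (with `reason`), `log`.
#' @export
filter_indels <- function(indels, mask = NULL, params = filter_params()) {
  v <- as_tibble(indels)
  if (!"mask_overlap" %in% names(v)) {
    span_end <- v$pos + pmax(nchar(v$ref), 1L)
    v$mask_overlap <- mask_overlap_fraction(mask, v$contig, v$pos, span_end)
  }
  if (!"site_called" %in% names(v)) v$site_called <- TRUE
  v$flag_mask <- v$mask_overlap >= params$indel_mask_overlap
  v$flag_uncalled <- !v$site_called
  v$flag_vaf <- v$vaf > params$indel_max_vaf
  v$flag_recurrent <- v$n_samples > params$indel_max_samples
  rules <- c("flag_mask", "flag_uncalled", "flag_vaf", "flag_recurrent")
  rule_names <- c("mask_overlap", "uncalled_site", "vaf", "cohort_recurrence")
  reason <- rep(NA_character_, nrow(v))
  for (j in rev(seq_along(rules))) reason[v[[rules[j]]]] <- rule_names[j]
  v$filter <- ifelse(is.na(reason), "PASS", reason)
  log <- bind_rows(
    tibble(rule = "candidates", n = nrow(v)),
    tibble(rule = rule_names,
           n = vapply(rule_names, function(r) sum(v$filter == r),
                      numeric(1))),
    tibble(rule = "kept", n = sum(v$filter == "PASS"))
  )
  list(kept = v[v$filter == "PASS", ], removed = v[v$filter != "PASS", ],
       log = log)
}
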