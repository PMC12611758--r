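# Pipeline orchestration: simulate -> call -> burden/spectra -> select -> qc.

#' Run configuration
#'
#' A fully serialisable description of a pipeline run. All randomness flows
#' from the single `seed` through named substreams.
#'
#' @param outdir output directory.
#' @param seed integer base seed.
#' @param sim a [sim_config()] (built-in simulation mode), or `NULL` to read
#'   `bundles_tsv` instead.
#' @param bundles_tsv,reference_fasta,gene_models_tsv,mask_bed input paths
#'   (file mode).
#' @param target_duplex_depth simulated target duplex depth.
#' @param params a [filter_params()].
#' @param germline_mode `"self"` or `"matched"`.
#' @param error_model an [error_model()] for simulation mode.
#' @param signatures optional reference-signature tibble for exposure
#'   fitting.
#' @return a `run_config` list.
#' @export
run_config <- function(outdir, seed, sim = NULL, bundles_tsv = NULL,
                       reference_fasta = NULL, gene_models_tsv = NULL,
                       mask_bed = NULL, target_duplex_depth = 40,
                       params = filter_params(),
                       germline_mode = "self", error_model = NULL,
                       signatures = NULL) {
  assert_that(!missing(seed), "run_config requires a seed")
  if (is.null(sim)) {
    for (p in c(bundles_tsv, reference_fasta, gene_models_tsv)) {
      assert_that(file.exists(p), paste0("missing input: ", p),
                  class = "duplexome_validation_error")
    }
  }
  structure(list(outdir = outdir, seed = as.integer(seed), sim = sim,
                 bundles_tsv = bundles_tsv,
                 reference_fasta = reference_fasta,
                 gene_models_tsv = gene_models_tsv, mask_bed = mask_bed,
                 target_duplex_depth = target_duplex_depth, params = params,
                 germline_mode = germline_mode,
                 error_model = error_model %||% error_model(),
                 signatures = signatures),
            class = "run_config")
}

#' Run the full pipeline
#'
#' Simulation mode: simulates a population and read bundles, calls mutations,
#' estimates burdens and catalogues, fits the background rate model on
#' synonymous sites, runs gene/global/site selection, and writes every stage
#' output (VCF, TSVs, JSON reports, log) under `config$outdir`. Deterministic
#' stages are bit-identical across reruns with the same config; stochastic
#' stages are seed-identical.
#'
#' @param config a [run_config()].
#' @return (invisibly) a list of in-memory stage results.
#' @export
run_pipeline <- function(config) {
  assert_that(inherits(config, "run_config"), "config must be a run_config",
              class = "duplexome_validation_error")
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
  }
  if (!is.null(config$sim)) {
    cfg <- config$sim
    genome <- cfg$genome
    gm <- cfg$genes
    pop <- simulate_population(cfg)
    bundles <- simulate_bundles(pop, config$target_duplex_depth,
                                err = config$error_model,
                                seed = substream_seed(config$seed, "bundles"))
    write_bundles_tsv(bundles, file.path(config$outdir, "bundles.tsv"))
    say("simulate: %d clones, %d somatic mutations, %d bundles",
        nrow(pop$clones), nrow(pop$somatic), nrow(bundles$bundles))
    mask <- NULL
  } else {
    genome <- read_genome_fasta(config$reference_fasta)
    gm <- read_gene_models(config$gene_models_tsv)
    bundles <- read_bundles_tsv(config$bundles_tsv)
    mask <- if (!is.null(config$mask_bed)) read_site_mask(config$mask_bed)
    pop <- NULL
  }
  calls <- call_mutations(bundles, genome, params = config$params,
                          mask = mask, germline_mode = config$germline_mode,
                          seed = substream_seed(config$seed, "dedup"))
  for (i in seq_len(nrow(calls$log))) {
    say("call/%s: %d", calls$log$rule[i], calls$log$n[i])
  }
  write_variants_vcf(calls, genome, file.path(config$outdir, "calls.vcf"))
  write_coverage_tsv(calls$coverage, file.path(config$outdir, "coverage.tsv"))
  pass <- passing_calls(calls)
  pass_snv <- pass[pass$type == "SNV", ]
  burden <- estimate_burden(pass_snv, calls$coverage, genome = genome,
                            seed = substream_seed(config$seed, "burden"))
  jsonlite::write_json(as.list(burden),
                       file.path(config$outdir, "burden.json"),
                       auto_unbox = TRUE, digits = NA)
  say("burden: %.3g per bp [%.3g, %.3g]", burden$burden, burden$lower,
      burden$upper)
  cat96 <- build_catalogue(pass_snv, "SBS96", genome)
  write_catalogue_tsv(cat96, file.path(config$outdir, "catalogue_sbs96.tsv"))
  cat192 <- build_catalogue(pass_snv, "TSW192", genome, genes = gm)
  write_catalogue_tsv(cat192, file.path(config$outdir, "catalogue_tsw192.tsv"))
  exposures <- NULL
  if (!is.null(config$signatures)) {
    exposures <- fit_exposures(cat96, config$signatures)
    jsonlite::write_json(as.list(exposures$exposures),
                         file.path(config$outdir, "exposures.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  sites <- enumerate_gene_sites(gm, genome)
  rates <- fit_rate_model(pass_snv, calls$coverage, sites)
  counts <- gene_counts(pass_snv, gm, rates, calls$coverage, sites = sites)
  sel <- tryCatch(gene_dnds(counts), error = function(e) {
    say("select/gene_dnds skipped: %s", conditionMessage(e))
    NULL
  })
  readr::write_tsv(sel %||% tibble(), file.path(config$outdir,
                                                "gene_selection.tsv"))
  glob <- tryCatch(global_dnds(counts), error = function(e) {
    say("select/global_dnds skipped: %s", conditionMessage(e))
    NULL
  })
  readr::write_tsv(glob %||% tibble(), file.path(config$outdir,
                                                 "global_dnds.tsv"))
  sd <- site_dnds(pass_snv, sites, rates, calls$coverage)
  readr::write_tsv(sd$sites, file.path(config$outdir, "site_selection.tsv"))
  say("select: %d genes, %d tested sites", length(unique(counts$gene_id)),
      nrow(sd$sites))
  qc <- sample_qc(list(mean_dx = mean(calls$coverage$depth),
                       burden_ci_ratio = burden$upper / max(burden$lower,
                                                            .Machine$double.xmin)))
  qc_out <- as.list(qc)
  qc_out$reasons <- unlist(qc$reasons[[1]])
  jsonlite::write_json(qc_out, file.path(config$outdir, "qc.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(log_lines, file.path(config$outdir, "run.log"))
  invisible(list(population = pop, bundles = bundles, calls = calls,
                 burden = burden, catalogue_sbs96 = cat96,
                 catalogue_tsw192 = cat192, exposures = exposures,
                 rates = rates, gene_counts = counts, gene_selection = sel,
                 global_dnds = glob, site_selection = sd, qc = qc))
}
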