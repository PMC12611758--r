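# Mutational catalogues and spectra.

#' Build a mutational catalogue
#'
#' Tallies mutations into the channels of one system. Mutations whose context
#' cannot be determined (N bases, outside a gene for strand-wise systems, or
#' not fitting the system) are excluded and counted in `n_excluded`, so that
#' channel counts plus exclusions always equal the number of input mutations.
#'
#' @param mutations tibble with `contig`, `pos` (0-based), `ref`, `alt`; an
#'   optional `weight` column counts each row with multiplicity (e.g.
#'   `n_mutant_bundles` for molecule-level catalogues).
#' @param system channel system (see [channel_labels()]).
#' @param genome a `genome_ref`.
#' @param genes `gene_models`, required for TSW systems: each mutation takes
#'   the strand of the first gene whose CDS span contains it.
#' @return a `mut_catalogue` tibble (`channel`, `count`) with attributes
#'   `system` and `n_excluded`.
#' @export
build_catalogue <- function(mutations, system = "SBS96", genome = NULL,
                            genes = NULL) {
  system <- match.arg(system, channel_systems)
  m <- as_tibble(mutations)
  w <- if ("weight" %in% names(m)) m$weight else rep(1, nrow(m))
  gene_strand <- NULL
  if (system %in% c("TSW192")) {
    assert_that(!is.null(genes), "TSW catalogues need gene models")
    gene_strand <- strand_at(genes, m$contig, m$pos)
  }
  ch <- if (nrow(m) == 0) {
    character(0)
  } else {
    context_channel(m, genome, system = system, gene_strand = gene_strand)
  }
  labs <- channel_labels(system)
  keep <- !is.na(ch)
  counts <- tapply(w[keep], factor(ch[keep], levels = labs), sum)
  counts[is.na(counts)] <- 0
  out <- tibble(channel = labs, count = as.numeric(counts))
  attr(out, "system") <- system
  attr(out, "n_excluded") <- sum(w[!keep])
  class(out) <- c("mut_catalogue", class(out))
  out
}

# Gene strand at positions (first gene whose CDS span covers the site, NA
# outside all genes).
strand_at <- function(genes, contig, pos) {
  out <- rep(NA_character_, length(pos))
  for (i in seq_len(nrow(genes))) {
    sp <- gene_span(genes[i, ])
    hit <- is.na(out) & contig == genes$contig[i] & pos >= sp[1] - 10 &
      pos < sp[2] + 10
    out[hit] <- genes$strand[i]
  }
  out
}

#' @export
print.mut_catalogue <- function(x, ...) {
  cat("<mut_catalogue> ", attr(x, "system"), ": ", sum(x$count),
      " mutations in ", nrow(x), " channels (", attr(x, "n_excluded"),
      " excluded)\n", sep = "")
  invisible(x)
}

#' Opportunity-correct a catalogue into a normalized spectrum
#'
#' Channel probability is proportional to the observed count times the ratio
#' of genome to observed opportunities, renormalised to sum to one — the
#' spectrum the sample would show under genome-average sequence composition.
#'
#' @param catalogue a `mut_catalogue` (or tibble `channel`, `count`).
#' @param genome_opportunities,observed_opportunities tibbles with `channel`
#'   and `opportunity` columns (any channel missing from
#'   `observed_opportunities` while carrying counts is an error).
#' @return tibble `channel`, `prob`.
#' @export
correct_spectrum <- function(catalogue, genome_opportunities,
                             observed_opportunities) {
  df <- left_join(as_tibble(catalogue)[, c("channel", "count")],
                  rename(as_tibble(genome_opportunities),
                         g = "opportunity"), by = "channel")
  df <- left_join(df, rename(as_tibble(observed_opportunities),
                             o = "opportunity"), by = "channel")
  df$o[is.na(df$o)] <- 0
  assert_that(all(df$o > 0 | df$count == 0),
              "counts in channels with zero observed opportunity",
              class = "duplexome_zero_coverage_channel")
  wt <- ifelse(df$o > 0, df$count * df$g / df$o, 0)
  assert_that(sum(wt) > 0, "empty spectrum")
  tibble(channel = df$channel, prob = wt / sum(wt))
}

#' Cosine similarity between two spectra
#'
#' With count catalogues, a resampling CI is computed by drawing `n_boot`
#' multinomial samples from each observed profile and recomputing the
#' similarity.
#'
#' @param a,b `mut_catalogue`s, count vectors or probability vectors over the
#'   same channel system.
#' @param n_boot resampling draws for the CI (0 to skip).
#' @param conf_level CI level.
#' @param seed resampling seed.
#' @return tibble with `cosine`, `lower`, `upper`.
#' @export
cosine_similarity <- function(a, b, n_boot = 1000, conf_level = 0.95,
                              seed = 1) {
  get_counts <- function(x) {
    if (is.data.frame(x)) x$count else as.numeric(x)
  }
  ca <- get_counts(a)
  cb <- get_counts(b)
  assert_that(length(ca) == length(cb), "spectra have different lengths")
  assert_that(sum(ca) > 0 && sum(cb) > 0, "zero spectrum",
              class = "duplexome_zero_vector")
  cosv <- function(x, y) sum(x * y) / sqrt(sum(x^2) * sum(y^2))
  point <- cosv(ca, cb)
  lower <- upper <- NA_real_
  whole_a <- isTRUE(all.equal(ca, round(ca)))
  whole_b <- isTRUE(all.equal(cb, round(cb)))
  if (n_boot > 0 && whole_a && whole_b) {
    sims <- with_seed(substream_seed(seed, "cosine_boot"), {
      ra <- rmultinom(n_boot, sum(ca), ca / sum(ca))
      rb <- rmultinom(n_boot, sum(cb), cb / sum(cb))
      vapply(seq_len(n_boot), function(i) cosv(ra[, i], rb[, i]), numeric(1))
    })
    alpha <- 1 - conf_level
    lower <- unname(quantile(sims, alpha / 2))
    upper <- unname(quantile(sims, 1 - alpha / 2))
  }
  tibble(cosine = point, lower = lower, upper = upper)
}

#' Write / read a catalogue TSV
#'
#' @param catalogue a `mut_catalogue`.
#' @param path TSV path.
#' @return `path` (write) or a `mut_catalogue` (read).
#' @export
write_catalogue_tsv <- function(catalogue, path) {
  df <- as_tibble(catalogue)
  df$system <- attr(catalogue, "system")
  df$n_excluded <- attr(catalogue, "n_excluded")
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_catalogue_tsv
#' @export
read_catalogue_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  out <- tibble(channel = df$channel, count = df$count)
  attr(out, "system") <- df$system[1]
  attr(out, "n_excluded") <- df$n_excluded[1]
  class(out) <- c("mut_catalogue", class(out))
  out
}
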