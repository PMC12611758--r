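# Duplex consensus calling.

#' Filter parameters for duplex calling
#'
#' Defaults follow the targeted single-molecule calling battery: a 2+2 read
#' bundle requirement, minimum duplex consensus quality 60, matched-normal
#' VAF < 0.1 at >= 25x (or sample VAF < 10% in self-germline mode), minimum
#' AS-XS 10, a per-bundle mean mismatch limit of 3 (4 when a variant is
#' called), 8 bp end trimming, and the four indel rules (>= 50% mask overlap,
#' uncalled site, VAF > 0.1, seen in > 50 samples).
#'
#' @param min_reads_per_strand minimum reads per strand for consensus.
#' @param min_consensus_qual minimum combined duplex consensus quality.
#' @param max_normal_vaf germline threshold in the matched normal.
#' @param min_asxs minimum alignment-score margin (AS-XS) per bundle.
#' @param max_mismatches,max_mismatches_variant mean per-read mismatch limits
#'   without/with a called variant (the variant base counts as a mismatch).
#' @param min_normal_cov minimum matched-normal coverage.
#' @param end_trim_bp bases trimmed from each fragment end.
#' @param germline_self_vaf sample-VAF germline threshold in self mode.
#' @param indel_mask_overlap,indel_max_vaf,indel_max_samples indel filter
#'   thresholds.
#' @param ks_alpha,ks_min_support read-positional KS artefact test: flagging
#'   level and minimum mutant support to test.
#' @return a `filter_params` list.
#' @export
filter_params <- function(min_reads_per_strand = 2, min_consensus_qual = 60,
                          max_normal_vaf = 0.1, min_asxs = 10,
                          max_mismatches = 3, max_mismatches_variant = 4,
                          min_normal_cov = 25, end_trim_bp = 8,
                          germline_self_vaf = 0.10,
                          indel_mask_overlap = 0.5, indel_max_vaf = 0.1,
                          indel_max_samples = 50, ks_alpha = 1e-3,
                          ks_min_support = 4) {
  structure(as.list(environment()), class = "filter_params")
}

qual_ints <- function(qual) utf8ToInt(qual) - 33L

#' Within-strand read consensus
#'
#' Positions with fewer than `min_reads_per_strand` reads, any within-strand
#' disagreement, or inside the trimmed fragment ends return `NA`. The
#' consensus quality is the minimum base quality among the (unanimous) reads.
#'
#' @param seqs character vector: the reads of one strand (equal length,
#'   spanning the fragment).
#' @param quals character vector of Phred+33 quality strings.
#' @param params a [filter_params()].
#' @return list with `base` (character, NA where no consensus) and `qual`
#'   (integer) vectors over fragment positions.
#' @export
strand_consensus <- function(seqs, quals, params = filter_params()) {
  assert_that(length(seqs) == length(quals), "seqs/quals length mismatch")
  L <- if (length(seqs)) nchar(seqs[1]) else 0L
  out_na <- list(base = rep(NA_character_, L), qual = rep(NA_integer_, L))
  k <- length(seqs)
  if (k < params$min_reads_per_strand || L == 0) return(out_na)
  assert_that(all(nchar(seqs) == L) && all(nchar(quals) == L),
              "all reads must span the fragment interval")
  m <- matrix(unlist(strsplit(seqs, "", fixed = TRUE)), nrow = k,
              byrow = TRUE)
  agree <- colSums(m != m[rep(1L, k), , drop = FALSE]) == 0
  qm <- matrix(unlist(lapply(quals, qual_ints)), nrow = k, byrow = TRUE)
  qmin <- do.call(pmin, lapply(seq_len(k), function(i) qm[i, ]))
  base <- m[1, ]
  base[!agree] <- NA_character_
  qmin[!agree] <- NA_integer_
  trim <- params$end_trim_bp
  if (trim > 0 && L > 0) {
    cut <- c(seq_len(min(trim, L)), seq.int(max(L - trim + 1L, 1L), L))
    base[cut] <- NA_character_
    qmin[cut] <- NA_integer_
  }
  list(base = base, qual = qmin)
}

count_mismatches <- function(seqs, ref) {
  refv <- strsplit(ref, "", fixed = TRUE)[[1]]
  vapply(strsplit(seqs, "", fixed = TRUE),
         function(s) sum(s != refv & refv != "N" & s != "N"), numeric(1))
}

#' Duplex consensus of one read bundle
#'
#' A base is called only where both strand consensuses agree and the combined
#' consensus quality (the minimum of the two strand consensus qualities)
#' meets `min_consensus_qual`. Bundles failing the AS-XS or mean-mismatch
#' limits contribute no called bases; adjacent called substitutions merge
#' into doublet (DBS) candidates downstream.
#'
#' @param bundle tibble of the reads of one bundle (columns `contig`,
#'   `frag_start`, `frag_end`, `strand`, `seq`, `qual`, `asxs`).
#' @param genome a `genome_ref`.
#' @param params a [filter_params()].
#' @return list with `called` (tibble: contig, pos, offset, ref, base, qual),
#'   `callable` (did the bundle pass bundle-level gates) and `reason`.
#' @export
duplex_call <- function(bundle, genome, params = filter_params()) {
  b <- as_tibble(bundle)
  ctg <- b$contig[1]
  fs <- b$frag_start[1]
  fe <- b$frag_end[1]
  assert_that(ctg %in% names(genome) && fs >= 0 &&
                fe <= contig_length(genome, ctg),
              sprintf("bundle interval %s:[%d,%d) off reference", ctg, fs, fe),
              class = "duplexome_bundle_off_reference")
  L <- fe - fs
  ref <- get_seq(genome, ctg, fs, fe)
  empty <- tibble(contig = character(0), pos = integer(0),
                  offset = integer(0), ref = character(0),
                  base = character(0), qual = integer(0))
  if (b$asxs[1] < params$min_asxs) {
    return(list(called = empty, callable = FALSE, reason = "asxs"))
  }
  a_rows <- b$strand == "A"
  consA <- strand_consensus(b$seq[a_rows], b$qual[a_rows], params)
  consB <- strand_consensus(b$seq[!a_rows], b$qual[!a_rows], params)
  ok <- !is.na(consA$base) & !is.na(consB$base) & consA$base == consB$base
  qual <- pmin(consA$qual, consB$qual)
  ok <- ok & !is.na(qual) & qual >= params$min_consensus_qual
  refv <- strsplit(ref, "", fixed = TRUE)[[1]]
  ok <- ok & refv != "N"
  mean_mm <- mean(count_mismatches(b$seq, ref))
  has_variant <- any(ok & consA$base != refv)
  mm_limit <- if (has_variant) params$max_mismatches_variant else
    params$max_mismatches
  if (mean_mm > mm_limit) {
    return(list(called = empty, callable = FALSE, reason = "mismatches"))
  }
  off <- which(ok)
  list(called = tibble(contig = ctg, pos = fs + off - 1L, offset = off,
                       ref = refv[off], base = consA$base[off],
                       qual = qual[off]),
       callable = TRUE, reason = NA_character_)
}
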