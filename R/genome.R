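# Reference genome handling.
#
# A genome is stored as a named character vector of uppercase contig
# sequences with class "genome_ref". Intervals are 0-based half-open
# throughout the package; positions are converted to 1-based only in VCF
# output.

#' Construct a reference genome object
#'
#' @param contigs named character vector (or named list) of contig sequences;
#'   lowercase is folded to uppercase, characters outside A/C/G/T/N are
#'   rejected.
#' @return a `genome_ref` object.
#' @examples
#' g <- genome_ref(c(chr1 = "ACGTACGT"))
#' get_seq(g, "chr1", 0, 4)
#' @export
genome_ref <- function(contigs) {
  contigs <- unlist(contigs)
  assert_that(length(contigs) > 0 && !is.null(names(contigs)) &&
                all(nzchar(names(contigs))),
              "contigs must be a non-empty named character vector")
  contigs <- toupper(contigs)
  bad <- grepl("[^ACGTN]", contigs)
  assert_that(!any(bad), paste0("contig(s) contain characters outside ",
                                "A/C/G/T/N: ", paste(names(contigs)[bad],
                                                     collapse = ", ")))
  structure(contigs, class = "genome_ref")
}

#' Read a reference genome from FASTA
#'
#' @param path path to a (possibly multi-record) FASTA file.
#' @return a `genome_ref` object.
#' @export
read_genome_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  v <- as.character(seqs)
  names(v) <- sub("\\s.*$", "", names(v))
  genome_ref(v)
}

#' Write a reference genome to FASTA
#'
#' @param genome a `genome_ref`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(unclass(genome)), path)
  invisible(path)
}

#' @export
print.genome_ref <- function(x, ...) {
  cat("<genome_ref> ", length(x), " contig(s), ",
      format(sum(nchar(unclass(x))), big.mark = ","), " bp\n", sep = "")
  invisible(x)
}

contig_length <- function(genome, contig) {
  assert_that(contig %in% names(genome),
              paste0("unknown contig: ", contig))
  nchar(unclass(genome)[[contig]])
}

#' Extract genome sequence over a 0-based half-open interval
#'
#' @param genome a `genome_ref`.
#' @param contig contig name.
#' @param start,end 0-based half-open interval bounds.
#' @return the interval sequence as a character scalar.
#' @export
get_seq <- function(genome, contig, start, end) {
  L <- contig_length(genome, contig)
  assert_that(start >= 0 && end <= L && start <= end,
              sprintf("interval [%d,%d) outside contig %s (length %d)",
                      start, end, contig, L))
  substr(unclass(genome)[[contig]], start + 1, end)
}

# Vectorised single-base lookup (0-based positions).
get_base <- function(genome, contig, pos) {
  s <- unclass(genome)[[contig]]
  substring(s, pos + 1, pos + 1)
}

# Vectorised context lookup: k bases either side of a 0-based position.
# Returns NA where the window runs off the contig.
get_context <- function(genome, contig, pos, k = 1) {
  L <- contig_length(genome, contig)
  out <- substring(unclass(genome)[[contig]], pos - k + 1, pos + k + 1)
  out[pos - k < 0 | pos + k >= L] <- NA_character_
  out
}

#' Target panel of genomic intervals
#'
#' Intervals are sorted and merged; overlapping input intervals are merged
#' with a warning.
#'
#' @param contig,start,end vectors describing 0-based half-open intervals, or
#'   a data frame with those columns as the first argument.
#' @param label optional labels (dropped for merged intervals).
#' @return a tibble with class `target_panel` (columns `contig`, `start`,
#'   `end`, `label`).
#' @export
target_panel <- function(contig, start = NULL, end = NULL, label = NULL) {
  if (is.data.frame(contig)) {
    df <- contig
    assert_that(all(c("contig", "start", "end") %in% names(df)),
                "panel data frame needs columns contig, start, end")
    if (!"label" %in% names(df)) df$label <- NA_character_
  } else {
    df <- tibble(contig = contig, start = as.integer(start),
                 end = as.integer(end),
                 label = label %||% NA_character_)
  }
  assert_that(all(df$end > df$start), "panel intervals must have end > start")
  df <- arrange(df, .data$contig, .data$start, .data$end)
  out <- list()
  overlapped <- FALSE
  for (ctg in unique(df$contig)) {
    sub <- df[df$contig == ctg, ]
    cur <- sub[1, ]
    for (i in seq_len(nrow(sub))[-1]) {
      if (sub$start[i] <= cur$end) {
        overlapped <- TRUE
        cur$end <- max(cur$end, sub$end[i])
        cur$label <- NA_character_
      } else {
        out[[length(out) + 1]] <- cur
        cur <- sub[i, ]
      }
    }
    out[[length(out) + 1]] <- cur
  }
  if (overlapped) warn("overlapping panel intervals merged")
  res <- bind_rows(out)
  class(res) <- c("target_panel", class(res))
  res
}

#' Read a BED file as a target panel
#'
#' Uses rtracklayer for parsing when available, falling back to a plain
#' three-column reader.
#'
#' @param path BED file path.
#' @return a `target_panel`.
#' @export
read_bed_panel <- function(path) {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- rtracklayer::import(path, format = "BED")
    df <- tibble(contig = as.character(GenomicRanges_seqnames(gr)),
                 start = as.integer(BiocGenerics_start(gr)) - 1L,
                 end = as.integer(BiocGenerics_end(gr)),
                 label = if (!is.null(gr$name)) as.character(gr$name) else NA_character_)
  } else {
    df <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                          show_col_types = FALSE)
    names(df)[1:3] <- c("contig", "start", "end")
    df$label <- if (ncol(df) >= 4) as.character(df[[4]]) else NA_character_
    df <- df[, c("contig", "start", "end", "label")]
  }
  target_panel(df)
}

# Indirections so rtracklayer/GenomicRanges stay in Suggests.
GenomicRanges_seqnames <- function(gr) {
  getExportedValue("GenomeInfoDb", "seqnames")(gr)
}
BiocGenerics_start <- function(gr) getExportedValue("BiocGenerics", "start")(gr)
BiocGenerics_end <- function(gr) getExportedValue("BiocGenerics", "end")(gr)

#' Write a target panel to BED
#'
#' @param panel a `target_panel`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed_panel <- function(panel, path) {
  df <- as_tibble(panel)[, c("contig", "start", "end")]
  df$label <- panel$label %||% "."
  df$label[is.na(df$label)] <- "."
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}

panel_sites <- function(panel) {
  # 0-based positions of every site in the panel
  tidyr::unnest(
    mutate(as_tibble(panel),
           pos = map2(.data$start, .data$end - 1L, seq)),
    "pos"
  )[, c("contig", "pos")]
}

#' Trinucleotide context frequencies of a genome or covered region
#'
#' Counts pyrimidine-centred trinucleotide opportunities. Each counted site
#' contributes its weight (duplex depth, or 1) to each of the three
#' substitution channels sharing its context, so the SBS96 opportunity vector
#' sums to three times the total weighted site count. Sites with N in their
#' context are skipped.
#'
#' @param genome a `genome_ref`.
#' @param regions `NULL` for whole-genome frequencies, a `target_panel`, or a
#'   coverage profile tibble with columns `contig`, `pos`, `depth` for
#'   depth-weighted opportunities.
#' @return tibble with columns `channel` (SBS96 label) and `opportunity`.
#' @export
context_frequencies <- function(genome, regions = NULL) {
  if (is.null(regions)) {
    sites <- bind_rows(lapply(names(genome), function(ctg) {
      tibble(contig = ctg, pos = seq_len(contig_length(genome, ctg)) - 1L)
    }))
    sites$depth <- 1
  } else if (inherits(regions, "target_panel")) {
    sites <- panel_sites(regions)
    sites$depth <- 1
  } else {
    assert_that(is.data.frame(regions) &&
                  all(c("contig", "pos", "depth") %in% names(regions)),
                "regions must be NULL, a target_panel or a coverage tibble")
    sites <- as_tibble(regions)[, c("contig", "pos", "depth")]
  }
  assert_that(nrow(sites) > 0 && sum(sites$depth) > 0,
              "empty regions/coverage", class = "duplexome_empty_coverage")
  sites <- sites[sites$depth > 0, ]
  ctxs <- unlist(lapply(split(sites, sites$contig), function(sub) {
    get_context(genome, sub$contig[1], sub$pos, k = 1)
  }), use.names = FALSE)
  depth <- unlist(lapply(split(sites, sites$contig), function(sub) sub$depth),
                  use.names = FALSE)
  keep <- !is.na(ctxs) & !grepl("N", ctxs, fixed = TRUE)
  ctxs <- ctxs[keep]
  depth <- depth[keep]
  pur <- substr(ctxs, 2, 2) %in% c("A", "G")
  ctxs[pur] <- revcomp(ctxs[pur])
  tri <- tapply(depth, ctxs, sum)
  labs <- channel_labels("SBS96")
  ctx_of <- paste0(substr(labs, 1, 1), substr(labs, 3, 3), substr(labs, 7, 7))
  opp <- unname(tri[ctx_of])
  opp[is.na(opp)] <- 0
  tibble(channel = labs, opportunity = as.numeric(opp))
}

#' Collapse SBS96 opportunities to the 32 pyrimidine-centred trinucleotides
#'
#' @param freqs output of [context_frequencies()].
#' @return tibble with columns `context` and `opportunity` (32 rows).
#' @export
context_frequencies_trinuc <- function(freqs) {
  ctx <- paste0(substr(freqs$channel, 1, 1), substr(freqs$channel, 3, 3),
                substr(freqs$channel, 7, 7))
  out <- summarise(group_by(tibble(context = ctx,
                                   opportunity = freqs$opportunity / 3),
                            .data$context),
                   opportunity = sum(.data$opportunity) * 3 / 3,
                   .groups = "drop")
  # each trinucleotide appears in 3 channels with equal opportunity
  out$opportunity <- out$opportunity
  out
}
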