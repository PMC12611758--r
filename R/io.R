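# File formats: bundle TSV dialect, VCF output, coverage and pileup TSVs.
#
# The bundle TSV dialect has one row per read with columns:
# bundle_id, contig, frag_start, frag_end, strand (A/B), read_id, seq,
# qual (Phred+33), asxs. All reads of a bundle span the fragment interval.

bundle_tsv_cols <- c("bundle_id", "contig", "frag_start", "frag_end",
                     "strand", "read_id", "seq", "qual", "asxs")

#' Write / read the bundle TSV dialect
#'
#' @param bundles a `bundle_set` or reads tibble.
#' @param path TSV path.
#' @return `path` (write); reads tibble (read).
#' @export
write_bundles_tsv <- function(bundles, path) {
  reads <- if (inherits(bundles, "bundle_set")) bundles$reads else
    as_tibble(bundles)
  readr::write_tsv(reads[, bundle_tsv_cols], path)
  invisible(path)
}

#' @rdname write_bundles_tsv
#' @export
read_bundles_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          bundle_id = readr::col_integer(),
                          contig = readr::col_character(),
                          frag_start = readr::col_integer(),
                          frag_end = readr::col_integer(),
                          strand = readr::col_character(),
                          read_id = readr::col_character(),
                          seq = readr::col_character(),
                          qual = readr::col_character(),
                          asxs = readr::col_double()))
  missing <- setdiff(bundle_tsv_cols, names(df))
  assert_that(length(missing) == 0,
              paste0("bundle TSV missing columns: ",
                     paste(missing, collapse = ", ")))
  bad <- which(nchar(df$seq) != df$frag_end - df$frag_start |
                 nchar(df$qual) != df$frag_end - df$frag_start)
  if (length(bad) > 0) {
    abort(sprintf(
      "bundle TSV line %d: read length does not match its fragment interval",
      bad[1] + 1L), class = "duplexome_parse_error")
  }
  assert_that(all(df$strand %in% c("A", "B")),
              "bundle TSV strand must be A or B",
              class = "duplexome_parse_error")
  df
}

#' Write calls to VCF (4.2)
#'
#' Positions are converted to 1-based. INFO carries the three VAFs, bundle
#' support and impact annotation; the filter battery verdict goes to FILTER.
#'
#' @param calls a `duplex_calls` object or calls tibble.
#' @param genome a `genome_ref` (contig headers).
#' @param path output path.
#' @param sample_id sample name recorded in the header.
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(calls, genome, path, sample_id = NULL) {
  df <- if (inherits(calls, "duplex_calls")) calls$calls else as_tibble(calls)
  sample_id <- sample_id %||%
    (if (inherits(calls, "duplex_calls")) calls$sample_id else "sample")
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=duplexome",
    paste0("##sample=", sample_id),
    vapply(names(genome), function(ctg) {
      sprintf("##contig=<ID=%s,length=%d>", ctg, contig_length(genome, ctg))
    }, character(1)),
    "##INFO=<ID=NMB,Number=1,Type=Integer,Description=\"Mutant callable bundles\">",
    "##INFO=<ID=DXD,Number=1,Type=Integer,Description=\"Callable duplex depth\">",
    "##INFO=<ID=DVAF,Number=1,Type=Float,Description=\"Duplex VAF\">",
    "##INFO=<ID=BVAF,Number=1,Type=Float,Description=\"BAM VAF\">",
    "##INFO=<ID=UVAF,Number=1,Type=Float,Description=\"Unbiased BAM VAF\">",
    "##INFO=<ID=TYPE,Number=1,Type=String,Description=\"SNV/DBS/indel\">",
    "##FILTER=<ID=snp_noise_mask,Description=\"Site in SNP+noise mask\">",
    "##FILTER=<ID=normal_coverage,Description=\"Matched normal coverage below threshold\">",
    "##FILTER=<ID=germline_vaf,Description=\"Germline VAF filter\">",
    "##FILTER=<ID=ks_positional,Description=\"Read-positional KS artefact\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  fmt_num <- function(x) ifelse(is.na(x), ".", format(x, digits = 8,
                                                      scientific = FALSE,
                                                      trim = TRUE))
  body <- if (nrow(df) == 0) character(0) else {
    info <- paste0(
      "NMB=", df$n_mutant_bundles,
      ";DXD=", df$callable_depth,
      ";DVAF=", fmt_num(df$duplex_vaf),
      ";BVAF=", fmt_num(df$bam_vaf),
      ";UVAF=", fmt_num(df$unbiased_vaf),
      ";TYPE=", df$type %||% "SNV"
    )
    paste(df$contig, df$pos + 1L, ".", df$ref, df$alt,
          ifelse(is.na(df$min_qual %||% NA), ".", df$min_qual %||% "."),
          df$filter %||% "PASS", info, sep = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a duplexome VCF back into a calls tibble
#'
#' Uses vcfR when available (positions converted back to 0-based).
#'
#' @param path VCF path.
#' @return calls tibble.
#' @export
read_variants_vcf <- function(path) {
  if (requireNamespace("vcfR", quietly = TRUE)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fx <- as_tibble(as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE))
    info_get <- function(key, numeric = TRUE) {
      x <- vcfR::extract.info(v, element = key)
      if (numeric) suppressWarnings(as.numeric(x)) else x
    }
    if (nrow(fx) == 0) {
      return(tibble(contig = character(0), pos = integer(0),
                    ref = character(0), alt = character(0)))
    }
    tibble(contig = fx$CHROM, pos = as.integer(fx$POS) - 1L, ref = fx$REF,
           alt = fx$ALT, filter = fx$FILTER,
           n_mutant_bundles = as.integer(info_get("NMB")),
           callable_depth = as.integer(info_get("DXD")),
           duplex_vaf = info_get("DVAF"), bam_vaf = info_get("BVAF"),
           unbiased_vaf = info_get("UVAF"),
           type = info_get("TYPE", numeric = FALSE))
  } else {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "#")]
    if (length(lines) == 0) {
      return(tibble(contig = character(0), pos = integer(0),
                    ref = character(0), alt = character(0)))
    }
    parts <- strsplit(lines, "\t", fixed = TRUE)
    info <- vapply(parts, `[[`, character(1), 8)
    grab <- function(key) {
      x <- sub(paste0(".*", key, "=([^;]*).*"), "\\1", info)
      suppressWarnings(as.numeric(x))
    }
    tibble(contig = vapply(parts, `[[`, character(1), 1),
           pos = as.integer(vapply(parts, `[[`, character(1), 2)) - 1L,
           ref = vapply(parts, `[[`, character(1), 4),
           alt = vapply(parts, `[[`, character(1), 5),
           filter = vapply(parts, `[[`, character(1), 7),
           n_mutant_bundles = as.integer(grab("NMB")),
           callable_depth = as.integer(grab("DXD")),
           duplex_vaf = grab("DVAF"), bam_vaf = grab("BVAF"),
           unbiased_vaf = grab("UVAF"),
           type = sub(".*TYPE=([^;]*).*", "\\1", info))
  }
}

#' Write / read a coverage profile TSV
#'
#' @param coverage coverage tibble (`contig`, `pos`, `depth`).
#' @param path TSV path.
#' @return `path` (write) or tibble (read).
#' @export
write_coverage_tsv <- function(coverage, path) {
  readr::write_tsv(as_tibble(coverage)[, c("contig", "pos", "depth")], path)
  invisible(path)
}

#' @rdname write_coverage_tsv
#' @export
read_coverage_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(contig = readr::col_character(),
                                          pos = readr::col_integer(),
                                          depth = readr::col_double()))
}
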