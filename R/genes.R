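# Gene models.
#
# A gene model table is a tibble with one row per gene:
#   gene_id   character
#   contig    character
#   strand    "+" or "-"
#   exon_starts, exon_ends   list-columns of ordered 0-based half-open CDS
#                            exon intervals (genomic order)
#   frame     coding frame of the first exon (0/1/2; genomic-order first exon
#             for "+" genes, last genomic exon read first for "-" genes)
# Optional annotated non-coding intervals may be supplied as list-columns of
# two-column matrices (start, end): utr5, utr3, promoter.

#' Construct a gene model table
#'
#' @param gene_id,contig,strand per-gene vectors.
#' @param exon_starts,exon_ends lists of integer vectors of 0-based half-open
#'   CDS exon intervals, ordered and non-overlapping.
#' @param frame coding frame offset of the first coding exon (default 0).
#' @param utr5,utr3,promoter optional lists of two-column (start, end)
#'   matrices of annotated non-coding intervals.
#' @return a tibble with class `gene_models`.
#' @export
gene_models <- function(gene_id, contig, strand, exon_starts, exon_ends,
                        frame = 0L, utr5 = NULL, utr3 = NULL, promoter = NULL) {
  assert_that(all(strand %in% c("+", "-")), "strand must be '+' or '-'")
  gm <- tibble(gene_id = gene_id, contig = contig, strand = strand,
               exon_starts = exon_starts, exon_ends = exon_ends,
               frame = as.integer(frame))
  if (!is.null(utr5)) gm$utr5 <- utr5
  if (!is.null(utr3)) gm$utr3 <- utr3
  if (!is.null(promoter)) gm$promoter <- promoter
  for (i in seq_len(nrow(gm))) {
    s <- gm$exon_starts[[i]]
    e <- gm$exon_ends[[i]]
    assert_that(length(s) == length(e) && all(e > s),
                paste0(gm$gene_id[i], ": malformed exon intervals"))
    if (length(s) > 1) {
      assert_that(all(diff(s) > 0) && all(utils::head(e, -1) <= s[-1]),
                  paste0(gm$gene_id[i],
                         ": exons must be ordered and non-overlapping"))
    }
    cds_len <- sum(e - s) - gm$frame[i]
    assert_that(cds_len %% 3 == 0,
                paste0(gm$gene_id[i], ": CDS length (minus frame) not a ",
                       "multiple of 3"))
  }
  class(gm) <- c("gene_models", class(gm))
  gm
}

#' Read a gene model TSV
#'
#' Expected columns: `gene_id`, `contig`, `strand`, `exon_starts`,
#' `exon_ends` (comma-separated 0-based half-open interval bounds), and
#' optionally `frame`.
#'
#' @param path TSV path.
#' @return a `gene_models` tibble.
#' @export
read_gene_models <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          exon_starts = readr::col_character(),
                          exon_ends = readr::col_character(),
                          .default = readr::col_guess()))
  assert_that(all(c("gene_id", "contig", "strand", "exon_starts",
                    "exon_ends") %in% names(df)),
              "gene model TSV missing required columns")
  parse_ints <- function(x) {
    lapply(strsplit(as.character(x), ","), function(v) as.integer(v))
  }
  gene_models(df$gene_id, df$contig, df$strand,
              parse_ints(df$exon_starts), parse_ints(df$exon_ends),
              frame = if ("frame" %in% names(df)) df$frame else 0L)
}

#' Write a gene model TSV
#'
#' @param gm a `gene_models` tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(gm, path) {
  df <- tibble(gene_id = gm$gene_id, contig = gm$contig, strand = gm$strand,
               exon_starts = map_chr(gm$exon_starts, paste, collapse = ","),
               exon_ends = map_chr(gm$exon_ends, paste, collapse = ","),
               frame = gm$frame)
  readr::write_tsv(df, path)
  invisible(path)
}

#' Import gene models from GFF3 (CDS features only)
#'
#' A minimal import shim: only `CDS` features are read and grouped by their
#' `Parent` (or `ID`) attribute; one model per parent.
#'
#' @param path GFF3 path.
#' @return a `gene_models` tibble.
#' @export
read_gene_models_gff3 <- function(path) {
  assert_that(requireNamespace("rtracklayer", quietly = TRUE),
              "rtracklayer is required for GFF3 import")
  gr <- rtracklayer::import(path, format = "GFF3")
  gr <- gr[gr$type == "CDS"]
  assert_that(length(gr) > 0, "no CDS features in GFF3")
  parent <- as.character(unlist(lapply(gr$Parent, function(p) {
    if (length(p) == 0) NA_character_ else p[[1]]
  })))
  if (all(is.na(parent)) && !is.null(gr$ID)) parent <- as.character(gr$ID)
  df <- tibble(gene_id = parent,
               contig = as.character(GenomicRanges_seqnames(gr)),
               strand = as.character(getExportedValue("BiocGenerics",
                                                      "strand")(gr)),
               start = as.integer(BiocGenerics_start(gr)) - 1L,
               end = as.integer(BiocGenerics_end(gr)))
  df <- arrange(df, .data$gene_id, .data$start)
  by_gene <- split(df, df$gene_id)
  gene_models(
    gene_id = names(by_gene),
    contig = map_chr(by_gene, ~ .x$contig[1]),
    strand = map_chr(by_gene, ~ .x$strand[1]),
    exon_starts = map(by_gene, ~ .x$start),
    exon_ends = map(by_gene, ~ .x$end)
  )
}

gene_row <- function(gm, gene_id) {
  i <- match(gene_id, gm$gene_id)
  assert_that(!is.na(i), paste0("unknown gene: ", gene_id))
  gm[i, ]
}

# Genomic span (0-based half-open) of the CDS of one gene-model row.
gene_span <- function(g) {
  c(min(g$exon_starts[[1]]), max(g$exon_ends[[1]]))
}

# Genomic 0-based positions of the CDS in coding (5'->3' of the mRNA) order.
cds_positions <- function(g) {
  pos <- unlist(map2(g$exon_starts[[1]], g$exon_ends[[1]] - 1L, seq))
  if (g$strand == "-") pos <- rev(pos)
  if (g$frame > 0) pos <- pos[-seq_len(g$frame)]
  pos
}

# Coding sequence (gene strand) of one gene-model row.
coding_sequence <- function(g, genome) {
  pieces <- map2_chr_local(g$exon_starts[[1]], g$exon_ends[[1]],
                           function(s, e) get_seq(genome, g$contig, s, e))
  cds <- paste(pieces, collapse = "")
  if (g$strand == "-") cds <- revcomp(cds)
  if (g$frame > 0) cds <- substr(cds, g$frame + 1, nchar(cds))
  cds
}

map2_chr_local <- function(x, y, f) {
  vapply(seq_along(x), function(i) f(x[[i]], y[[i]]), character(1))
}

#' Convert a target panel covering whole genes
#'
#' Convenience: the merged genomic footprint of a set of gene models, with an
#' optional flank.
#'
#' @param gm a `gene_models` tibble.
#' @param flank bases of flank to add on each side of each gene span.
#' @return a `target_panel`.
#' @export
genes_panel <- function(gm, flank = 0L) {
  spans <- lapply(seq_len(nrow(gm)), function(i) {
    sp <- gene_span(gm[i, ])
    tibble(contig = gm$contig[i], start = max(0L, sp[1] - as.integer(flank)),
           end = sp[2] + as.integer(flank), label = gm$gene_id[i])
  })
  suppressWarnings(target_panel(bind_rows(spans)))
}
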