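# Mutation channel systems.
#
# Five fixed channel systems are supported:
#   SBS96      - pyrimidine-centred trinucleotide single-base substitutions
#   TSW192     - SBS96 split by the strand carrying the pyrimidine of the
#                mutated pair relative to the containing gene (transcribed /
#                untranscribed)
#   PENTA_TC_256 - +/-2 bp context of T>C substitutions (pyrimidine-centred)
#   DBS78      - canonical doublet-base substitutions
#   ID83       - small insertions/deletions by type, length, repeat context
#                and microhomology
#
# Channel label orderings follow the COSMIC conventions so that catalogues
# line up with reference signature files.

channel_systems <- c("SBS96", "TSW192", "PENTA_TC_256", "DBS78", "ID83")

sbs_subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' Channel labels of a mutation channel system
#'
#' @param system one of `"SBS96"`, `"TSW192"`, `"PENTA_TC_256"`, `"DBS78"`,
#'   `"ID83"`.
#' @return character vector of channel labels in canonical order (length
#'   96, 192, 256, 78 or 83).
#' @examples
#' length(channel_labels("DBS78"))
#' @export
channel_labels <- function(system) {
  system <- match.arg(system, channel_systems)
  switch(system,
    SBS96 = sbs96_labels(),
    TSW192 = tsw192_labels(),
    PENTA_TC_256 = penta256_labels(),
    DBS78 = dbs78_labels(),
    ID83 = id83_labels()
  )
}

sbs96_labels <- function() {
  out <- character(0)
  for (s in sbs_subs) {
    for (f5 in the_bases) {
      for (f3 in the_bases) {
        out <- c(out, paste0(f5, "[", s, "]", f3))
      }
    }
  }
  out
}

# Strand labels: "U" = pyrimidine of the mutated pair on the untranscribed
# (coding/sense) strand of the gene; "T" = on the transcribed (template)
# strand.
tsw192_labels <- function() {
  as.vector(rbind(paste0("T:", sbs96_labels()), paste0("U:", sbs96_labels())))
}

penta256_labels <- function() {
  out <- character(0)
  for (m2 in the_bases) {
    for (m1 in the_bases) {
      for (p1 in the_bases) {
        for (p2 in the_bases) {
          out <- c(out, paste0(m2, m1, "[T>C]", p1, p2))
        }
      }
    }
  }
  out
}

dbs_canonical_refs <- c("AC", "AT", "CC", "CG", "CT", "GC", "TA", "TC", "TG", "TT")

dbs78_labels <- function() {
  out <- character(0)
  for (ref in dbs_canonical_refs) {
    r1 <- substr(ref, 1, 1)
    r2 <- substr(ref, 2, 2)
    alts <- as.vector(outer(setdiff(the_bases, r1), setdiff(the_bases, r2),
                            paste0))
    if (revcomp(ref) == ref) {
      alts <- unique(pmin(alts, revcomp(alts)))
    }
    out <- c(out, paste0(ref, ">", sort(alts)))
  }
  out
}

id83_labels <- function() {
  lab <- character(0)
  for (b in c("C", "T")) lab <- c(lab, paste0("1:Del:", b, ":", c(1:5, "6+")))
  for (b in c("C", "T")) lab <- c(lab, paste0("1:Ins:", b, ":", c(0:4, "5+")))
  for (l in c("2", "3", "4", "5+")) lab <- c(lab, paste0(l, ":Del:R:", c(1:5, "6+")))
  for (l in c("2", "3", "4", "5+")) lab <- c(lab, paste0(l, ":Ins:R:", c(0:4, "5+")))
  lab <- c(lab, "2:Del:M:1")
  lab <- c(lab, paste0("3:Del:M:", 1:2))
  lab <- c(lab, paste0("4:Del:M:", 1:3))
  lab <- c(lab, paste0("5+:Del:M:", c(1:4, "5+")))
  lab
}

#' SBS96 channel of single-base substitutions
#'
#' Collapses purine-centred variants onto the pyrimidine strand by reverse
#' complement, so the channel is invariant under reverse complementation of
#' the variant description.
#'
#' @param ref,alt single reference/alternate bases (vectorised).
#' @param ctx 3-base genomic context centred on the variant (plus strand).
#' @return character vector of SBS96 channel labels; `NA` where the context
#'   contains N.
#' @export
sbs96_channel <- function(ref, alt, ctx) {
  stopifnot(length(ref) == length(alt), length(ref) == length(ctx))
  bad <- grepl("N", ctx, fixed = TRUE) | !ref %in% the_bases | !alt %in% the_bases
  pur <- ref %in% c("A", "G")
  ctx2 <- ifelse(pur, revcomp(ctx), ctx)
  alt2 <- ifelse(pur, complement(alt), alt)
  ref2 <- ifelse(pur, complement(ref), ref)
  out <- paste0(substr(ctx2, 1, 1), "[", ref2, ">", alt2, "]", substr(ctx2, 3, 3))
  out[bad] <- NA_character_
  out
}

# TSW strand code for a variant inside a gene: which strand carries the
# pyrimidine of the mutated base pair, relative to the gene's coding strand.
tsw_strand_code <- function(ref, gene_strand) {
  pyr_strand <- ifelse(ref %in% c("C", "T"), "+", "-")
  ifelse(pyr_strand == gene_strand, "U", "T")
}

tsw192_channel <- function(ref, alt, ctx, gene_strand) {
  ch <- sbs96_channel(ref, alt, ctx)
  code <- tsw_strand_code(ref, gene_strand)
  ifelse(is.na(ch), NA_character_, paste0(code, ":", ch))
}

penta256_channel <- function(ref, alt, ctx5) {
  # ctx5: 5-base genomic context centred on the variant.
  bad <- grepl("N", ctx5, fixed = TRUE)
  pur <- ref %in% c("A", "G")
  ctx2 <- ifelse(pur, revcomp(ctx5), ctx5)
  ref2 <- ifelse(pur, complement(ref), ref)
  alt2 <- ifelse(pur, complement(alt), alt)
  ok <- ref2 == "T" & alt2 == "C"
  out <- paste0(substr(ctx2, 1, 2), "[T>C]", substr(ctx2, 4, 5))
  out[bad | !ok] <- NA_character_
  out
}

dbs78_channel <- function(ref, alt) {
  stopifnot(all(nchar(ref) == 2), all(nchar(alt) == 2))
  out <- character(length(ref))
  for (i in seq_along(ref)) {
    r <- ref[i]
    a <- alt[i]
    if (!r %in% dbs_canonical_refs) {
      r <- revcomp(r)
      a <- revcomp(a)
    }
    if (revcomp(r) == r) a <- min(a, revcomp(a))
    out[i] <- paste0(r, ">", a)
  }
  bad <- !out %in% dbs78_labels()
  out[bad] <- NA_character_
  out
}

cap_count <- function(n, top, plus) {
  ifelse(n >= top, plus, as.character(n))
}

# ID83 classification of one indel given in VCF-style (anchored) notation.
# `pos` is 0-based; ref and alt share their first (anchor) base.
id83_channel_one <- function(genome, contig, pos, ref, alt) {
  if (nchar(ref) == nchar(alt)) return(NA_character_)
  seq_len_contig <- contig_length(genome, contig)
  window <- function(start, end) {
    start <- max(start, 0)
    end <- min(end, seq_len_contig)
    if (start >= end) "" else get_seq(genome, contig, start, end)
  }
  if (nchar(ref) > nchar(alt)) {
    d <- substr(ref, nchar(alt) + 1, nchar(ref))   # deleted sequence
    del_start <- pos + nchar(alt)                   # 0-based start of deletion
    del_end <- del_start + nchar(d)
    m <- nchar(d)
    if (m == 1) {
      b <- d
      run <- 1
      left <- del_start - 1
      while (left >= 0 && window(left, left + 1) == b) {
        run <- run + 1
        left <- left - 1
      }
      right <- del_end
      while (right < seq_len_contig && window(right, right + 1) == b) {
        run <- run + 1
        right <- right + 1
      }
      b2 <- if (b %in% c("A", "G")) complement(b) else b
      return(paste0("1:Del:", b2, ":", cap_count(run, 6, "6+")))
    }
    len_cat <- cap_count(m, 5, "5+")
    # repeat copies of the deleted unit, including the deleted copy
    copies <- 1
    right <- del_end
    while (window(right, right + m) == d) {
      copies <- copies + 1
      right <- right + m
    }
    left <- del_start - m
    while (left >= 0 && window(left, left + m) == d) {
      copies <- copies + 1
      left <- left - m
    }
    if (copies > 1) {
      return(paste0(len_cat, ":Del:R:", cap_count(copies, 6, "6+")))
    }
    # microhomology at the breakpoint
    mh <- 0
    for (j in seq_len(m - 1)) {
      if (window(del_end, del_end + j) == substr(d, 1, j)) mh <- max(mh, j)
      if (window(del_start - j, del_start) ==
          substr(d, m - j + 1, m)) mh <- max(mh, j)
    }
    if (mh >= 1) {
      mh_cat <- if (m >= 5) cap_count(min(mh, 5), 5, "5+") else as.character(min(mh, m - 1))
      return(paste0(len_cat, ":Del:M:", mh_cat))
    }
    return(paste0(len_cat, ":Del:R:1"))
  }
  # insertion
  ins <- substr(alt, nchar(ref) + 1, nchar(alt))
  ins_point <- pos + nchar(ref)  # inserted before this 0-based position
  m <- nchar(ins)
  if (m == 1) {
    b <- ins
    run <- 0
    right <- ins_point
    while (right < seq_len_contig && window(right, right + 1) == b) {
      run <- run + 1
      right <- right + 1
    }
    left <- ins_point - 1
    while (left >= 0 && window(left, left + 1) == b) {
      run <- run + 1
      left <- left - 1
    }
    b2 <- if (b %in% c("A", "G")) complement(b) else b
    return(paste0("1:Ins:", b2, ":", cap_count(run, 5, "5+")))
  }
  len_cat <- cap_count(m, 5, "5+")
  copies <- 0
  right <- ins_point
  while (window(right, right + m) == ins) {
    copies <- copies + 1
    right <- right + m
  }
  left <- ins_point - m
  while (left >= 0 && window(left, left + m) == ins) {
    copies <- copies + 1
    left <- left - m
  }
  paste0(len_cat, ":Ins:R:", cap_count(copies, 5, "5+"))
}

id83_channel <- function(genome, contig, pos, ref, alt) {
  mapply(id83_channel_one, contig, pos, ref, alt,
         MoreArgs = list(genome = genome), USE.NAMES = FALSE)
}
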