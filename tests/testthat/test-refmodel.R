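# Reference model: impact annotation, context channels, opportunities.

test_that("coding impacts follow the genetic code", {
  fx <- toy_gene_fixture()
  imp <- function(pos, ref, alt) {
    annotate_impact(tibble::tibble(contig = "chr1", pos = pos, ref = ref,
                                   alt = alt), fx$gm, fx$genome)
  }
  # ATG -> ATA (3rd base G>A): missense M->I
  expect_equal(imp(14L, "G", "A"), "missense")
  # CAA -> TAA (1st base C>T): nonsense
  expect_equal(imp(18L, "C", "T"), "nonsense")
  # GCT -> GCC (3rd base T>C): synonymous
  expect_equal(imp(17L, "T", "C"), "synonymous")
  # TGA stop codon -> CGA: stop loss
  expect_equal(imp(63L, "T", "C"), "stop_loss")
  # SNV at the G of the canonical GT donor dinucleotide
  expect_equal(imp(27L, "G", "A"), "essential_splice")
  expect_equal(imp(28L, "T", "C"), "essential_splice")
  # acceptor AG
  expect_equal(imp(49L, "A", "G"), "essential_splice")
  expect_equal(imp(50L, "G", "T"), "essential_splice")
  # beyond the 2 bp: intronic near splice (default window 10)
  expect_equal(imp(29L, "A", "T"), "intronic_near_splice")
  expect_equal(imp(36L, "C", "T"), "intronic_near_splice")
  expect_equal(imp(38L, "C", "T"), "intronic_other")
  # outside the gene span
  expect_equal(imp(2L, "C", "T"), "noncoding_other")
  # indels
  expect_equal(imp(15L, "GC", "G"), "indel_coding")
  expect_equal(imp(2L, "CA", "C"), "indel_noncoding")
  # reference mismatch is rejected with a diagnostic
  expect_error(imp(14L, "C", "A"), class = "duplexome_ref_mismatch")
})

test_that("impact annotation is strand-consistent under reflection", {
  fx <- toy_gene_fixture()
  mir <- mirror_fixture(fx)
  a <- enumerate_gene_sites(fx$gm, fx$genome)
  b <- enumerate_gene_sites(mir$gm, mir$genome)
  expect_equal(table(a$impact), table(b$impact))
  # site-by-site: position p maps to L-1-p with complemented alleles
  b_key <- paste(mir$L - 1L - b$pos, complement(b$ref), complement(b$alt))
  a_key <- paste(a$pos, a$ref, a$alt)
  m <- match(a_key, b_key)
  expect_false(anyNA(m))
  expect_equal(a$impact, b$impact[m])
})

test_that("SBS96 channels collapse to the pyrimidine strand", {
  expect_equal(duplexome:::sbs96_channel("G", "A", "CGA"), "T[C>T]G")
  expect_equal(duplexome:::sbs96_channel("T", "C", "ATT"), "A[T>C]T")
  # invariance under reverse complement of the variant description
  set.seed(42)
  for (i in 1:50) {
    ctx <- paste(sample(c("A", "C", "G", "T"), 3, replace = TRUE),
                 collapse = "")
    ref <- substr(ctx, 2, 2)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    expect_equal(
      duplexome:::sbs96_channel(ref, alt, ctx),
      duplexome:::sbs96_channel(complement(ref), complement(alt),
                                revcomp(ctx)))
  }
})

test_that("TSW192 distinguishes gene strand while SBS96 does not", {
  fx <- toy_gene_fixture()
  v <- tibble::tibble(contig = "chr1", pos = 17L, ref = "T", alt = "C")
  ch_plus <- context_channel(v, fx$genome, "TSW192", gene_strand = "+")
  ch_minus <- context_channel(v, fx$genome, "TSW192", gene_strand = "-")
  expect_false(ch_plus == ch_minus)
  expect_equal(sub("^[TU]:", "", ch_plus), sub("^[TU]:", "", ch_minus))
  expect_equal(sub("^[TU]:", "", ch_plus),
               context_channel(v, fx$genome, "SBS96"))
})

test_that("channel systems have the canonical sizes and unique labels", {
  sizes <- c(SBS96 = 96, TSW192 = 192, PENTA_TC_256 = 256, DBS78 = 78,
             ID83 = 83)
  for (sys in names(sizes)) {
    labs <- channel_labels(sys)
    expect_length(labs, sizes[[sys]])
    expect_false(anyDuplicated(labs) > 0)
  }
})

test_that("context frequencies count depth-weighted opportunities", {
  g <- genome_ref(c(c1 = "AACAA"))
  cov <- tibble::tibble(contig = "c1", pos = 2L, depth = 7)
  cf <- context_frequencies(g, cov)
  hit <- cf[cf$opportunity > 0, ]
  expect_equal(nrow(hit), 3)
  expect_true(all(grepl("^A\\[C>[AGT]\\]A$", hit$channel)))
  expect_true(all(hit$opportunity == 7))
  expect_equal(sum(cf$opportunity), 3 * 7)
  expect_error(context_frequencies(g, cov[0, ]),
               class = "duplexome_empty_coverage")
})

test_that("uniform depth-1 opportunities equal plain trinucleotide counts", {
  seqs <- "ACGTTGCAGGCCATTACGATCGGATCCTAG"  # 30 bp toy sequence
  g <- genome_ref(c(c1 = seqs))
  cf <- context_frequencies(g)
  # independent brute-force oracle: walk every interior position
  oracle <- setNames(rep(0, 96), channel_labels("SBS96"))
  for (p in 2:(nchar(seqs) - 1)) {
    ctx <- substr(seqs, p - 1, p + 1)
    ref <- substr(ctx, 2, 2)
    if (ref %in% c("A", "G")) ctx <- revcomp(ctx)
    ref2 <- substr(ctx, 2, 2)
    for (alt in setdiff(c("A", "C", "G", "T"), ref2)) {
      lab <- paste0(substr(ctx, 1, 1), "[", ref2, ">", alt, "]",
                    substr(ctx, 3, 3))
      oracle[lab] <- oracle[lab] + 1
    }
  }
  expect_equal(setNames(cf$opportunity, cf$channel), oracle)
  expect_equal(sum(cf$opportunity), 3 * (nchar(seqs) - 2))
})

test_that("DBS78 channels are reverse-complement canonical", {
  labs <- channel_labels("DBS78")
  ch <- duplexome:::dbs78_channel("GT", "CA")  # revcomp of AC>TG
  expect_equal(ch, duplexome:::dbs78_channel("AC", "TG"))
  expect_true(ch %in% labs)
  # palindromic reference: alt collapses with its reverse complement
  expect_equal(duplexome:::dbs78_channel("AT", "CG"),
               duplexome:::dbs78_channel("AT", "CG"))
  expect_equal(duplexome:::dbs78_channel("AT", "GC"),
               duplexome:::dbs78_channel("AT", revcomp("GC")))
})

test_that("ID83 classifies indels by type, length, repeat and microhomology", {
  # 1 bp T insertion into a run of 6 Ts -> homopolymer category 5+
  g1 <- genome_ref(c(c1 = "ACGTTTTTTACG"))
  expect_equal(duplexome:::id83_channel(g1, "c1", 2L, "G", "GT"),
               "1:Ins:T:5+")
  # 1 bp deletion of a T in a run of 3
  g2 <- genome_ref(c(c1 = "ACGTTTACG"))
  expect_equal(duplexome:::id83_channel(g2, "c1", 2L, "GT", "G"),
               "1:Del:T:3")
  # 1 bp G deletion reports the pyrimidine-strand base C
  g3 <- genome_ref(c(c1 = "ATAGATA"))
  expect_equal(duplexome:::id83_channel(g3, "c1", 2L, "AG", "A"),
               "1:Del:C:1")
  # 3 bp deletion of a unit present twice -> repeat category 2
  g4 <- genome_ref(c(c1 = "TTACGACGTT"))
  expect_equal(duplexome:::id83_channel(g4, "c1", 1L, "TACG", "T"),
               "3:Del:R:2")
  # 4 bp deletion with 2 bp of breakpoint microhomology
  # delete GATC from ...A[GATC]GAttt: following seq starts GA (prefix match 2)
  g5 <- genome_ref(c(c1 = "CCAGATCGACTTCC"))
  expect_equal(duplexome:::id83_channel(g5, "c1", 2L, "AGATC", "A"),
               "4:Del:M:2")
  # 2 bp insertion, no adjacent copy -> 2:Ins:R:0
  g6 <- genome_ref(c(c1 = "AACCGGTT"))
  expect_equal(duplexome:::id83_channel(g6, "c1", 3L, "C", "CAG"),
               "2:Ins:R:0")
})
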