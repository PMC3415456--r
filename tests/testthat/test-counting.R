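ann2 <- two_gene_annotation()

test_that("empty input gives zero counts and zero library size", {
  ga <- make_alignments(tibble::tibble(
    read_id = character(), chrom = character(), strand = character(),
    start = integer(), cigar = character()
  ))
  cnt <- count_reads(ga, ann2, mode = "stranded_sense")
  expect_true(all(cnt$count == 0))
  expect_equal(attr(cnt, "library_size"), 0L)
})

test_that("a sense read inside an exon is counted for exactly its gene", {
  ga <- make_alignments(tibble::tibble(
    read_id = "r1", chrom = "chr1", strand = "+", start = 120L, cigar = "50M"
  ))
  cnt <- count_reads(ga, ann2, mode = "stranded_sense", protocol = "forward")
  expect_equal(cnt$count[cnt$gene_id == "geneA"], 1L)
  expect_equal(cnt$count[cnt$gene_id == "geneB"], 0L)
  expect_equal(attr(cnt, "library_size"), 1L)
})

test_that("strand handling: antisense reads are invisible in sense mode, seen unstranded", {
  ga <- make_alignments(tibble::tibble(
    read_id = "r1", chrom = "chr1", strand = "-", start = 120L, cigar = "50M"
  ))
  sn <- count_reads(ga, ann2, mode = "stranded_sense", protocol = "forward")
  un <- count_reads(ga, ann2, mode = "unstranded")
  expect_equal(sn$count[sn$gene_id == "geneA"], 0L)
  expect_equal(un$count[un$gene_id == "geneA"], 1L)
  # reverse protocol flips the sense convention
  rv <- count_reads(ga, ann2, mode = "stranded_sense", protocol = "reverse")
  expect_equal(rv$count[rv$gene_id == "geneA"], 1L)
})

test_that("a read overlapping two genes is ambiguous: counted nowhere, still in N", {
  ann <- toy_annotation(tibble::tribble(
    ~gene_id, ~chrom, ~strand, ~start, ~end,
    "g1", "chr1", "+", 100L, 200L,
    "g2", "chr1", "+", 180L, 300L
  ))
  ga <- make_alignments(tibble::tibble(
    read_id = "r1", chrom = "chr1", strand = "+", start = 170L, cigar = "50M"
  ))
  cnt <- count_reads(ga, ann, mode = "stranded_sense")
  expect_true(all(cnt$count == 0))
  expect_equal(attr(cnt, "library_size"), 1L)
  expect_equal(attr(cnt, "n_ambiguous"), 1L)
})

test_that("reads on unannotated chromosomes are no-feature and reported", {
  ga <- make_alignments(tibble::tibble(
    read_id = "r1", chrom = "chr2", strand = "+", start = 10L, cigar = "50M"
  ))
  expect_message(
    cnt <- count_reads(ga, ann2, mode = "stranded_sense"),
    "absent from the annotation"
  )
  expect_equal(attr(cnt, "n_no_feature"), 1L)
})

test_that("read counting conserves reads: assigned + ambiguous + no-feature = N", {
  set.seed(7)
  reads <- tibble::tibble(
    read_id = sprintf("r%02d", 1:60),
    chrom = "chr1",
    strand = sample(c("+", "-"), 60, replace = TRUE),
    start = sample(0:1600, 60, replace = TRUE),
    cigar = "50M"
  )
  ga <- make_alignments(reads)
  for (mode in c("stranded_sense", "unstranded")) {
    cnt <- count_reads(ga, ann2, mode = mode)
    expect_equal(
      sum(cnt$count) + attr(cnt, "n_ambiguous") + attr(cnt, "n_no_feature"),
      attr(cnt, "library_size")
    )
  }
})

test_that("union counting matches the per-base brute-force oracle on mixed fixtures", {
  ann <- toy_annotation(tibble::tribble(
    ~gene_id, ~chrom, ~strand, ~start, ~end,
    "gA", "chr1", "+", 100L, 200L,
    "gA", "chr1", "+", 300L, 400L,
    "gB", "chr1", "-", 150L, 450L, # overlaps gA on the opposite strand
    "gC", "chr1", "+", 1000L, 1400L,
    "gD", "chr2", "-", 50L, 500L
  ))
  set.seed(11)
  reads <- tibble::tibble(
    read_id = sprintf("r%02d", 1:80),
    chrom = sample(c("chr1", "chr2"), 80, replace = TRUE, prob = c(0.8, 0.2)),
    strand = sample(c("+", "-"), 80, replace = TRUE),
    start = sample(0:1500, 80, replace = TRUE),
    cigar = sample(c("50M", "20M100N30M", "25M"), 80, replace = TRUE, prob = c(0.7, 0.2, 0.1))
  )
  ga <- make_alignments(reads)
  for (mode in c("stranded_sense", "unstranded")) {
    cnt <- suppressMessages(count_reads(ga, ann, mode = mode))
    orc <- oracle_count(reads, ann, mode = mode)
    expect_equal(
      stats::setNames(cnt$count, cnt$gene_id)[names(orc$counts)],
      orc$counts,
      info = mode
    )
    expect_equal(attr(cnt, "n_ambiguous"), orc$n_ambiguous, info = mode)
    expect_equal(attr(cnt, "n_no_feature"), orc$n_no_feature, info = mode)
  }
})

test_that("union counting agrees with summarizeOverlaps union mode", {
  set.seed(3)
  reads <- tibble::tibble(
    read_id = sprintf("r%02d", 1:50),
    chrom = "chr1",
    strand = sample(c("+", "-"), 50, replace = TRUE),
    start = sample(0:1600, 50, replace = TRUE),
    cigar = "50M"
  )
  ga <- make_alignments(reads)
  cnt <- count_reads(ga, ann2, mode = "stranded_sense")
  so <- GenomicAlignments::summarizeOverlaps(
    strawdeg:::annotation_features(ann2), ga,
    mode = "Union", ignore.strand = FALSE
  )
  so_counts <- SummarizedExperiment::assay(so)[, 1]
  expect_equal(stats::setNames(cnt$count, cnt$gene_id)[names(so_counts)], so_counts)
})

test_that("antisense counts are the clamped mode difference", {
  s <- tibble::tibble(gene_id = c("a", "b"), count = c(10L, 5L))
  u <- tibble::tibble(gene_id = c("a", "b"), count = c(30L, 5L))
  as_ <- antisense_counts(s, u)
  expect_equal(as_$count[as_$gene_id == "a"], 20L)
  expect_equal(as_$count[as_$gene_id == "b"], 0L)

  # discrepancy (unstranded < sense) is clamped and reported
  u2 <- tibble::tibble(gene_id = c("a", "b"), count = c(8L, 5L))
  expect_message(as2 <- antisense_counts(s, u2), "clamped")
  expect_equal(as2$count[as2$gene_id == "a"], 0L)

  expect_error(
    antisense_counts(s, tibble::tibble(gene_id = "a", count = 1L)),
    "universes differ"
  )
})

test_that("an overlap-ambiguity fixture triggers the antisense clamp", {
  # read sense to geneB, antisense to overlapping geneA: stranded counting
  # assigns it to geneB, unstranded counting calls it ambiguous
  ann <- toy_annotation(tibble::tribble(
    ~gene_id, ~chrom, ~strand, ~start, ~end,
    "geneA", "chr1", "+", 100L, 400L,
    "geneB", "chr1", "-", 200L, 300L
  ))
  ga <- make_alignments(tibble::tibble(
    read_id = "r1", chrom = "chr1", strand = "-", start = 220L, cigar = "50M"
  ))
  sn <- count_reads(ga, ann, mode = "stranded_sense")
  un <- count_reads(ga, ann, mode = "unstranded")
  expect_equal(sn$count[sn$gene_id == "geneB"], 1L)
  expect_equal(un$count[un$gene_id == "geneB"], 0L)
  expect_message(as_ <- antisense_counts(sn, un), "clamped")
  expect_true(all(as_$count == 0))
})

test_that("rRNA filtering removes reads by reference and preserves others", {
  reads <- tibble::tibble(
    read_id = sprintf("r%03d", 1:100),
    chrom = c(rep("rRNA_1", 10), rep("chr1", 90)),
    strand = "+",
    start = 10L,
    cigar = "50M"
  )
  ga <- make_alignments(reads, chrom_lengths = c(chr1 = 1e5L, rRNA_1 = 5000L))
  expect_equal(length(filter_rrna(ga, character())), 100)
  suppressMessages({
    expect_equal(length(filter_rrna(ga, "rRNA_1")), 90)
    expect_equal(length(filter_rrna(ga[1:10], "rRNA_1")), 0)
  })
})

test_that("SAM reading keeps primary mapped alignments and junction structure", {
  path <- tempfile(fileext = ".sam")
  reads <- tibble::tibble(
    read_id = c("r1", "r2", "r3"),
    chrom = "chr1", strand = c("+", "-", "+"),
    start = c(100L, 200L, 300L),
    cigar = c("50M", "20M100N30M", "50M")
  )
  write_sam_fixture(reads, path, flags = c(0L, 16L, 256L)) # r3 is secondary
  ga <- read_alignments(path)
  expect_equal(sort(S4Vectors::mcols(ga)$qname), c("r1", "r2"))
  blocks <- tidy(ga)
  r2 <- blocks[blocks$read_id == "r2", ]
  expect_equal(nrow(r2), 2)
  expect_equal(r2$start, c(200L, 320L))
  expect_equal(r2$end, c(220L, 350L))
  expect_equal(unique(r2$strand), "-")
})
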