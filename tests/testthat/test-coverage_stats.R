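test_that("GTF exon records become transcript models with correct lengths", {
  f <- writeGtf(c(gtfExon("chr1", 11, 20),
                  gtfExon("chr2", 101, 130, tx = "t2"),
                  gtfExon("chr2", 201, 270, tx = "t2")))
  tx <- readTranscriptModels(f)
  expect_setequal(names(tx), c("t1", "t2"))
  expect_equal(GenomicRanges::start(tx[["t1"]]), 11)
  expect_equal(GenomicRanges::end(tx[["t1"]]), 20)
  expect_equal(sum(GenomicRanges::width(tx[["t1"]])), 10)
  expect_equal(sum(GenomicRanges::width(tx[["t2"]])), 100)
})

test_that("malformed or conflicting transcript models are rejected", {
  expect_error(readTranscriptModels(writeGtf(gtfExon("chr1", 20, 11))),
               "parse error")
  # same transcript_id with overlapping exon coordinates
  f <- writeGtf(c(gtfExon("chr1", 11, 50), gtfExon("chr1", 30, 80)))
  expect_error(readTranscriptModels(f), "overlapping exons")
  expect_error(readTranscriptModels(tempfile()), "not found")
})

test_that("BedGraph intervals are read as 0-based half-open depths", {
  cov <- readCoverage(writeBedGraph("chr1\t0\t5\t3"))
  d <- as.numeric(cov[["chr1"]])
  expect_equal(d, rep(3, 5))  # positions 0..4; position 5 beyond the vector
  expect_equal(length(cov[["chr1"]]), 5)
})

test_that("coverage edge cases: empty file, absent chrom, bad depths", {
  empty <- tempfile(); file.create(empty)
  cov <- readCoverage(empty)
  expect_equal(length(cov), 0)
  expect_error(readCoverage(writeBedGraph("chr1\t0\t5\t-1")), "negative")
  expect_error(
    readCoverage(writeBedGraph(c("chr1\t0\t10\t2", "chr1\t5\t15\t7"))),
    "conflicting")
  # equal-depth overlap is merged, not summed
  cov2 <- readCoverage(writeBedGraph(c("chr1\t0\t10\t2", "chr1\t5\t15\t2")))
  expect_equal(as.numeric(cov2[["chr1"]]), rep(2, 15))
})

test_that("per-base coverage dialects are auto-detected", {
  cov3 <- readCoverage(writeBedGraph(c("chr1\t3\t7", "chr1\t4\t7")))
  expect_equal(as.numeric(cov3[["chr1"]]), c(0, 0, 7, 7))
  cov2 <- readCoverage(writeBedGraph(c("2\t5", "3\t5")))
  expect_equal(as.numeric(cov2[["."]]), c(0, 5, 5))
})

test_that("positional mean matches hand-enumerated depth profiles", {
  # uniform coverage over L = 100 is exactly 0.5
  f <- writeGtf(gtfExon("chr1", 1, 100))
  covU <- readCoverage(writeBedGraph("chr1\t0\t100\t1"))
  pmU <- positionalMean(readTranscriptModels(f)[["t1"]], covU)
  expect_equal(pmU$mu, 0.5)
  expect_equal(pmU$expression, 100)
  # depth only at the last base of L = 10
  f10 <- writeGtf(gtfExon("chr1", 1, 10))
  covL <- readCoverage(writeBedGraph("chr1\t9\t10\t4"))
  expect_equal(positionalMean(readTranscriptModels(f10)[["t1"]], covL)$mu,
               0.95)
  # depth vector [1,0,0,3]: mu = (1*0.125 + 3*0.875)/4
  f4 <- writeGtf(gtfExon("chr1", 1, 4))
  cov4 <- readCoverage(writeBedGraph(c("chr1\t0\t1\t1", "chr1\t3\t4\t3")))
  expect_equal(positionalMean(readTranscriptModels(f4)[["t1"]], cov4)$mu,
               0.6875)
})

test_that("zero coverage yields an undetected transcript", {
  f <- writeGtf(gtfExon("chr1", 1, 50))
  cov <- readCoverage(writeBedGraph("chr2\t0\t10\t5"))
  pm <- positionalMean(readTranscriptModels(f)[["t1"]], cov)
  expect_false(pm$detected)
  expect_true(is.na(pm$mu))
  expect_equal(pm$expression, 0)
})

test_that("strand reversal mirrors mu and an unstranded flag disables it", {
  f <- writeGtf(c(gtfExon("chr1", 1, 10, "+", tx = "tp"),
                  gtfExon("chr1", 1, 10, "-", tx = "tm")))
  cov <- readCoverage(writeBedGraph("chr1\t0\t2\t5"))  # 5' end on + strand
  tx <- readTranscriptModels(f)
  muP <- positionalMean(tx[["tp"]], cov)$mu
  muM <- positionalMean(tx[["tm"]], cov)$mu
  expect_equal(muM, 1 - muP)
  expect_equal(positionalMean(tx[["tm"]], cov, unstranded = TRUE)$mu, muP)
})

test_that("expression and mu agree with a brute-force per-position oracle", {
  set.seed(7)
  for (rep in 1:5) {
    L1 <- sample(5:30, 1); L2 <- sample(5:30, 1)
    gap <- sample(2:10, 1)
    s2 <- 1 + L1 + gap
    f <- writeGtf(c(gtfExon("chrX", 1, L1),
                    gtfExon("chrX", s2, s2 + L2 - 1)))
    depth <- sample(0:4, L1 + gap + L2, replace = TRUE)
    lines <- sprintf("chrX\t%d\t%d\t%d", seq_along(depth) - 1,
                     seq_along(depth), depth)
    cov <- readCoverage(writeBedGraph(lines[depth > 0]))
    pm <- positionalMean(readTranscriptModels(f)[["t1"]], cov)
    # oracle: explicit per-position enumeration of the exonic profile
    d <- depth[c(seq_len(L1), seq(s2, s2 + L2 - 1))]
    expect_equal(pm$expression, sum(d))
    if (sum(d) > 0) {
      L <- L1 + L2
      expect_equal(pm$mu,
                   sum(d * ((seq_len(L) - 0.5) / L)) / sum(d))
    }
  }
})

test_that("coverage table sorts by descending expression with id tie-break", {
  f <- writeGtf(c(gtfExon("chr1", 1, 10, tx = "t1"),
                  gtfExon("chr1", 21, 30, tx = "t2"),
                  gtfExon("chr1", 41, 50, tx = "t3")))
  cov <- readCoverage(writeBedGraph(c(
    "chr1\t0\t5\t1",     # t1: 5
    "chr1\t20\t29\t1",   # t2: 9
    "chr1\t40\t45\t1"))) # t3: 5
  tab <- coverageTable(readTranscriptModels(f), cov)
  expect_equal(tab$transcript_id, c("t2", "t1", "t3"))
  expect_equal(tab$expression, c(9, 5, 5))
  expect_error(coverageTable(GenomicRanges::GRangesList(), cov), "empty")
})

test_that("undetected transcripts are flagged and warned about", {
  f <- writeGtf(c(gtfExon("chr1", 1, 10, tx = "t1"),
                  gtfExon("chr1", 21, 30, tx = "t2")))
  covNone <- readCoverage(writeBedGraph("chr9\t0\t5\t1"))
  expect_warning(tab <- coverageTable(readTranscriptModels(f), covNone),
                 "no detected")
  expect_equal(sum(tab$detected), 0)
  covOne <- readCoverage(writeBedGraph("chr1\t0\t5\t1"))
  tab1 <- coverageTable(readTranscriptModels(f), covOne)
  expect_equal(sum(tab1$detected), 1)
})

test_that("an external expression vector overrides coverage sums", {
  f <- writeGtf(c(gtfExon("chr1", 1, 10, tx = "t1"),
                  gtfExon("chr1", 21, 30, tx = "t2")))
  cov <- readCoverage(writeBedGraph(c("chr1\t0\t10\t2", "chr1\t20\t30\t9")))
  tab <- coverageTable(readTranscriptModels(f), cov,
                       expression = c(t1 = 100, t2 = 1))
  expect_equal(tab$transcript_id, c("t1", "t2"))
  expect_equal(tab$expression, c(100, 1))
  expect_error(coverageTable(readTranscriptModels(f), cov,
                             expression = c(t1 = 1)),
               "missing")
})
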