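test_that("TSV count tables round-trip through readCounts", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2", "g1\t1\t4", "g2\t0\t2", "g3\t7\t0"), f)
  m <- readCounts(f, format = "tsv", design = c("A", "B"))
  expect_s4_class(m, "CountMatrix")
  expect_equal(dim(m), c(3L, 2L))
  expect_equal(countsMatrix(m)["g3", "s1"], 7)
  expect_equal(designGroups(m), c("A", "B"))
})

test_that("MatrixMarket triplets with sidecars are read and validated", {
  dir <- tempfile(); dir.create(dir)
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "3 2 5",
               "1 1 2", "2 1 1", "3 1 4", "1 2 3", "3 2 1"),
             file.path(dir, "m.mtx"))
  writeLines(c("g1", "g2", "g3"), file.path(dir, "features.tsv"))
  writeLines(c("c1", "c2"), file.path(dir, "barcodes.tsv"))
  m <- readCounts(file.path(dir, "m.mtx"), format = "mtx_triplet",
                  modality = "single_cell")
  expect_equal(sum(countsMatrix(m) > 0), 5)
  expect_equal(countsMatrix(m)["g1", "c2"], 3)
  # truncated barcode sidecar
  writeLines("c1", file.path(dir, "barcodes.tsv"))
  expect_error(readCounts(file.path(dir, "m.mtx"), format = "mtx_triplet"),
               "barcodes")
})

test_that("invalid count values are rejected", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2", "g1\t1\t-3"), f)
  expect_error(readCounts(f, format = "tsv"), "negative")
  writeLines(c("gene\ts1\ts2", "g1\t1\t2.5"), f)
  expect_error(readCounts(f, format = "tsv"), "integer")
})

test_that("CountMatrix validity enforces the design and integer counts", {
  m <- matrix(1:4, 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_error(CountMatrix(m, design = "A", modality = "bulk"),
               "one group label per column")
  expect_error(CountMatrix(m / 2, design = c("A", "B")), "integer")
})

test_that("feature-count cell filter keeps the stated inclusive bounds", {
  # cells with unique feature counts 500, 1000, 1500, 2500, 3000
  nGenes <- 3000
  cnt <- sapply(c(500, 1000, 1500, 2500, 3000), function(k)
    c(rep(1L, k), rep(0L, nGenes - k)))
  rownames(cnt) <- paste0("g", seq_len(nGenes))
  colnames(cnt) <- paste0("c", 1:5)
  m <- toyCounts(cnt, design = rep("A", 5), modality = "single_cell")
  kept <- filterCells(m)
  expect_equal(colnames(kept), c("c2", "c3", "c4"))
  # idempotent, and all kept cells satisfy the bounds
  expect_equal(colnames(filterCells(kept)), colnames(kept))
  nf <- colSums(countsMatrix(kept) > 0)
  expect_true(all(nf >= 1000 & nf <= 2500))
})

test_that("cell filter degenerate cases", {
  cnt <- matrix(1L, 1200, 3,
                dimnames = list(paste0("g", 1:1200), paste0("c", 1:3)))
  m <- toyCounts(cnt, design = rep("A", 3), modality = "single_cell")
  expect_equal(ncol(filterCells(m)), 3)  # all at 1200 features: identity
  lo <- toyCounts(cnt[1:100, ], design = rep("A", 3),
                  modality = "single_cell")
  expect_error(filterCells(lo), "all cells removed")
  expect_error(filterCells(toyCounts(cnt, design = rep("A", 3),
                                     modality = "bulk")),
               "single_cell")
})

test_that("log normalization matches the stated formula", {
  cnt <- matrix(c(10, 0, 5, 5), 2,
                dimnames = list(c("g1", "g2"), c("s1", "s2")))
  m <- toyCounts(cnt, design = c("A", "B"))
  v <- normalizedMatrix(logNormalize(m))
  expect_equal(v["g1", "s1"], log(10001))  # c=10, total=10, scale=10000
  expect_equal(v["g2", "s1"], 0)           # zero stays zero
  # scale equal to the column total reduces to ln(1 + c)
  v2 <- normalizedMatrix(logNormalize(m, scale = 10))
  expect_equal(v2["g1", "s1"], log(1 + 10))
  # strictly monotone in counts within a column
  cnt3 <- matrix(c(1, 5, 9, 2, 2, 2), 3)
  rownames(cnt3) <- paste0("g", 1:3)
  v3 <- normalizedMatrix(logNormalize(toyCounts(cnt3, design = c("A", "B"))))
  expect_true(all(diff(v3[, 1]) > 0))
  # zero-total column errors and names the column
  bad <- toyCounts(matrix(c(1L, 0L), 1, 2,
                          dimnames = list("g1", c("ok", "empty"))),
                   design = c("A", "B"))
  expect_error(logNormalize(bad), "empty")
})

test_that("median-of-ratios size factors satisfy the scaling identities", {
  cnt <- matrix(c(4, 10, 20, 4, 10, 20), 3,
                dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  m <- toyCounts(cnt, design = c("A", "B"))
  expect_equal(unname(medianOfRatios(m)), c(1, 1))
  # sample2 = 2 x sample1 -> factors (1/sqrt(2), sqrt(2))
  cnt2 <- cbind(s1 = c(4, 10, 20), s2 = c(8, 20, 40))
  rownames(cnt2) <- paste0("g", 1:3)
  sf2 <- medianOfRatios(toyCounts(cnt2, design = c("A", "B")))
  expect_equal(unname(sf2), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-10)
  # a gene with a zero anywhere is excluded from the reference set:
  # adding it must not change the factors
  cnt3 <- rbind(cnt2, g4 = c(0, 1000))
  sf3 <- medianOfRatios(toyCounts(cnt3, design = c("A", "B")))
  expect_equal(unname(sf3), unname(sf2))
  # no all-positive gene
  cnt4 <- cbind(s1 = c(1, 0), s2 = c(0, 1))
  rownames(cnt4) <- c("g1", "g2")
  expect_error(medianOfRatios(toyCounts(cnt4, design = c("A", "B"))),
               "pseudoReference")
})

test_that("gene filtering preserves columns and warns on unknown ids", {
  cnt <- matrix(1:6, 3, dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  m <- toyCounts(cnt, design = c("A", "B"))
  expect_equal(rownames(applyGeneFilter(m, c("g1", "g2", "g3"))),
               rownames(m))
  one <- applyGeneFilter(m, "g2")
  expect_equal(rownames(one), "g2")
  expect_equal(colnames(one), c("s1", "s2"))
  expect_warning(applyGeneFilter(m, c("g2", "nope")), "ignored")
  expect_error(suppressWarnings(applyGeneFilter(m, "nope")),
               "every gene")
})

test_that("capture rate truncates to one decimal", {
  expect_equal(qcSummary(41805, 26916)$capture_rate_pct, 64.3)
  expect_equal(qcSummary(100, 0)$capture_rate_pct, 0)
  expect_equal(qcSummary(100, 100)$capture_rate_pct, 100)
  expect_equal(qcSummary(3, 2)$capture_rate_pct, 66.6)  # 66.66 -> 66.6
  expect_error(qcSummary(10, 11), "between 0 and loaded")
  expect_error(qcSummary(0, 0), "> 0")
})
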