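rankSum <- function(x, y, exactMax = 10) lclear:::.rankSumTest(x, y, exactMax)

test_that("exact rank-sum p matches hand enumeration with ties", {
  # A = (0,0,0) vs B = (5,6,7): only 2 of the C(6,3)=20 labelings are as
  # extreme as the observed split
  expect_equal(rankSum(c(0, 0, 0), c(5, 6, 7))$p, 0.1)
  expect_equal(rankSum(c(1, 1), c(1, 1))$p, 1)
})

test_that("exact rank-sum p equals the reference exact test when tie-free", {
  set.seed(21)
  for (rep in 1:20) {
    nx <- sample(2:10, 1); ny <- sample(2:10, 1)
    x <- rnorm(nx); y <- rnorm(ny)
    ours <- rankSum(x, y)$p
    ref <- wilcox.test(x, y, exact = TRUE)$p.value
    expect_equal(ours, ref, tolerance = 1e-12,
                 info = sprintf("nx=%d ny=%d rep=%d", nx, ny, rep))
  }
})

test_that("large-sample path matches the tie-corrected normal reference", {
  set.seed(22)
  for (rep in 1:10) {
    x <- rpois(15, 3); y <- rpois(20, 3.5)
    ours <- rankSum(x, y, exactMax = 10)$p
    ref <- suppressWarnings(
      wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
    expect_equal(ours, ref, tolerance = 1e-10)
  }
})

test_that("wilcoxon engine: prefilter, Bonferroni and DEG call semantics", {
  set.seed(23)
  nc <- 16
  cnt <- matrix(rpois(50 * nc, 20), 50, nc,
                dimnames = list(paste0("g", 1:50), paste0("c", 1:nc)))
  cnt["g1", ] <- c(rep(100L, 8), rep(5L, 8))  # strong DEG, higher in A
  cnt["g2", ] <- rep(30L, nc)                 # constant gene
  # equalize library sizes so constant counts stay constant after
  # normalization
  cnt["g3", ] <- max(colSums(cnt)) - colSums(cnt) + cnt["g3", ]
  m <- toyCounts(cnt, design = rep(c("A", "B"), each = 8),
                 modality = "single_cell")
  tab <- wilcoxonDEG(logNormalize(m), lfcMin = 0.36, minPct = 0.1)
  expect_equal(nrow(tab), 50)
  g1 <- tab[tab$gene == "g1", ]
  expect_true(g1$is_deg)
  expect_equal(g1$direction, "up")
  expect_equal(g1$p_raw, 2 / choose(16, 8))  # most extreme exact split
  # Bonferroni over all features in the dataset
  expect_equal(g1$p_adj, min(1, g1$p_raw * 50))
  g2 <- tab[tab$gene == "g2", ]
  expect_true(is.na(g2$p_raw))     # |log2fc| = 0 < lfcMin: not tested
  expect_false(g2$is_deg)
  # with the fold-change prefilter off, an identical gene gives p = 1
  tab0 <- wilcoxonDEG(logNormalize(m), lfcMin = 0, minPct = 0)
  expect_equal(tab0$p_raw[tab0$gene == "g2"], 1)
  expect_true(all(tab0$p_adj >= tab0$p_raw, na.rm = TRUE))
  expect_error(wilcoxonDEG(logNormalize(m), groups = rep("A", nc)),
               "two groups")
})

test_that("dispersion estimation is calibrated on Poisson and NB data", {
  set.seed(24)
  muP <- rlnorm(1000, 5, 1)
  cntP <- matrix(rpois(1000 * 10, muP), 1000, 10,
                 dimnames = list(paste0("g", 1:1000), paste0("s", 1:10)))
  mP <- toyCounts(cntP, design = rep(c("A", "B"), each = 5))
  dispP <- estimateDispersionsNB(mP, medianOfRatios(mP))
  expect_lte(median(dispP$final), 0.01)
  set.seed(25)
  muN <- rlnorm(2000, 5, 1)
  cntN <- matrix(rnbinom(2000 * 10, mu = muN, size = 1 / 0.2), 2000, 10,
                 dimnames = list(paste0("g", 1:2000), paste0("s", 1:10)))
  mN <- toyCounts(cntN, design = rep(c("A", "B"), each = 5))
  dispN <- estimateDispersionsNB(mN, medianOfRatios(mN))
  expect_gte(median(dispN$final), 0.1)
  expect_lte(median(dispN$final), 0.3)
  # zero-variance gene floored
  cntZ <- rbind(cntN, gz = rep(50L, 10))
  mZ <- toyCounts(cntZ, design = rep(c("A", "B"), each = 5))
  dispZ <- estimateDispersionsNB(mZ, medianOfRatios(mZ))
  expect_equal(unname(dispZ$genewise["gz"]), 1e-8)
})

test_that("NB Wald: null genes give z = 0 and relabeling flips the sign", {
  cnt <- matrix(c(10, 20, 10, 20, 10, 20, 10, 20), 2, 4,
                dimnames = list(c("g1", "g2"), paste0("s", 1:4)))
  m <- toyCounts(cnt, design = c("A", "A", "B", "B"))
  sf <- setNames(rep(1, 4), colnames(cnt))
  disp <- estimateDispersionsNB(m, sf)
  tab <- nbWaldDEG(m, sf, disp)
  expect_equal(tab$log2fc, c(0, 0))
  expect_equal(tab$statistic, c(0, 0))
  expect_equal(tab$p_raw, c(1, 1))
  # relabeling invariance
  set.seed(26)
  cnt2 <- matrix(rnbinom(200 * 6, mu = 50, size = 10), 200, 6,
                 dimnames = list(paste0("g", 1:200), paste0("s", 1:6)))
  m2 <- toyCounts(cnt2, design = rep(c("A", "B"), each = 3))
  sf2 <- medianOfRatios(m2)
  disp2 <- estimateDispersionsNB(m2, sf2)
  tabAB <- nbWaldDEG(m2, sf2, disp2)
  tabBA <- nbWaldDEG(m2, sf2, disp2,
                     groups = rep(c("B", "A"), each = 3))
  # sorted labels swap the roles of the two groups
  expect_equal(tabBA$log2fc, -tabAB$log2fc)
  expect_equal(tabBA$p_raw, tabAB$p_raw, tolerance = 1e-12)
})

test_that("NB Wald detects a strongly spiked gene", {
  set.seed(27)
  nG <- 500
  mu <- rlnorm(nG, 4, 1)
  mu[1] <- 200
  fc <- rep(1, nG); fc[1] <- 4
  cnt <- cbind(
    matrix(rnbinom(nG * 3, mu = mu, size = 1 / 0.05), nG, 3),
    matrix(rnbinom(nG * 3, mu = mu * fc, size = 1 / 0.05), nG, 3))
  dimnames(cnt) <- list(paste0("g", seq_len(nG)), paste0("s", 1:6))
  m <- toyCounts(cnt, design = rep(c("A", "B"), each = 3))
  sf <- medianOfRatios(m)
  disp <- estimateDispersionsNB(m, sf)
  tab <- nbWaldDEG(m, sf, disp)
  expect_true(tab$is_deg[1])
  expect_gte(tab$log2fc[1], 1)
  # BH q sequence: step-up adjusted values are monotone in raw p
  ord <- order(tab$p_raw)
  expect_true(all(diff(tab$p_adj[ord]) >= -1e-12, na.rm = TRUE))
})

test_that("genes with no counts anywhere are untestable, not significant", {
  cnt <- rbind(matrix(rpois(40, 30), 10, 4), gz = rep(0L, 4))
  rownames(cnt)[1:10] <- paste0("g", 1:10)
  m <- toyCounts(cnt, design = rep(c("A", "B"), each = 2))
  sf <- setNames(rep(1, 4), colnames(countsMatrix(m)))
  disp <- estimateDispersionsNB(m, sf)
  tab <- nbWaldDEG(m, sf, disp)
  expect_true(is.na(tab$p_raw[tab$gene == "gz"]))
  expect_false(tab$is_deg[tab$gene == "gz"])
})

test_that("permutation null is deterministic and clean on duplicated cells", {
  cnt <- matrix(rep(c(5L, 9L, 2L, 14L), each = 8), 4, 8, byrow = TRUE,
                dimnames = list(paste0("g", 1:4), paste0("c", 1:8)))
  m <- toyCounts(cnt, design = rep(c("A", "B"), each = 4),
                 modality = "single_cell")
  norm <- logNormalize(m)
  rep1 <- permutationNull(norm, nPerm = 10, seed = 7)
  expect_true(all(rep1$deg_counts == 0))
  rep2 <- permutationNull(norm, nPerm = 10, seed = 7)
  expect_identical(rep1, rep2)
  expect_error(permutationNull(norm, nPerm = 0, seed = 1), ">= 1")
  expect_error(permutationNull(norm[, 1:3], nPerm = 1, seed = 1),
               "4 columns")
})
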