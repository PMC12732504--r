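# Build a counts container where each cell has an exact number of
# detected genes and an exact total count.
cellsWithProfile <- function(profiles, nGenes) {
  m <- matrix(0, nGenes, nrow(profiles))
  for (i in seq_len(nrow(profiles))) {
    k <- profiles[i, 1]; tot <- profiles[i, 2]
    stopifnot(tot >= k, k <= nGenes)
    m[seq_len(k), i] <- 1
    m[1, i] <- m[1, i] + (tot - k)
  }
  rownames(m) <- sprintf("g%04d", seq_len(nGenes))
  colnames(m) <- sprintf("c%02d", seq_len(nrow(profiles)))
  SingleCellExperiment::SingleCellExperiment(assays = list(counts = m))
}

test_that("cell filter boundaries follow at-least/fewer-than semantics", {
  profiles <- rbind(c(200, 500),    # keep: both minima met exactly
                    c(199, 500),    # drop: 199 < 200 detected genes
                    c(200, 499),    # drop: 499 < 500 counts
                    c(5000, 9000),  # drop: 5000 is not 'fewer than 5000'
                    c(4999, 9000),  # keep
                    c(300, 600))    # keep
  sce <- cellsWithProfile(profiles, 6000)
  kept <- filterCells(sce)
  expect_identical(colnames(kept), c("c01", "c05", "c06"))
  expect_identical(nrow(kept), 6000L)  # gene axis untouched
})

test_that("gene filter boundary keeps >= 5 cells, drops < 5 and all-zero", {
  m <- matrix(0, 3, 8)
  m[1, 1:5] <- 1   # detected in exactly 5 cells -> kept
  m[2, 1:4] <- 2   # detected in 4 cells -> dropped
  rownames(m) <- c("five", "four", "zero")
  colnames(m) <- sprintf("c%d", 1:8)
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = m))
  kept <- filterGenes(sce)
  expect_identical(rownames(kept), "five")
  expect_identical(ncol(kept), 8L)
  expect_error(filterGenes(sce, minCells = 9), "empty result")
})

test_that("filtering is idempotent and matches brute-force predicates", {
  set.seed(42)
  for (rep in 1:5) {
    m <- matrix(rbinom(20 * 15, 8, 0.25), 15, 20)  # genes x cells
    rownames(m) <- sprintf("g%02d", 1:15)
    colnames(m) <- sprintf("c%02d", 1:20)
    sce <- SingleCellExperiment::SingleCellExperiment(
      assays = list(counts = m))
    out <- tryCatch(
      filterGenes(filterCells(sce, 3, 10, 14), 4),
      error = function(e) NULL)
    # brute force: cells first, then genes on the surviving cells
    keepC <- colSums(m > 0) >= 3 & colSums(m) >= 10 & colSums(m > 0) < 14
    m2 <- m[, keepC, drop = FALSE]
    keepG <- rowSums(m2 > 0) >= 4
    if (is.null(out)) {
      expect_true(sum(keepC) == 0 || sum(keepG) == 0)
    } else {
      expect_identical(
        SummarizedExperiment::assay(out, "counts"),
        m2[keepG, , drop = FALSE])
      twice <- filterGenes(filterCells(out, 3, 10, 14), 4)
      expect_identical(SummarizedExperiment::assay(twice, "counts"),
                       SummarizedExperiment::assay(out, "counts"))
    }
  }
})

test_that("normalization divides by the cell mean and round-trips", {
  m <- matrix(c(2, 0, 4, 1, 1, 1), 3, 2)
  rownames(m) <- c("gA", "gB", "gC"); colnames(m) <- c("c1", "c2")
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = m))
  nm <- normalizeLog1p(sce)
  # cell 1 mean count = 2: values log1p(1), 0, log1p(2)
  expect_equal(unname(SummarizedExperiment::assay(nm, "lognorm")[, "c1"]),
               c(log1p(1), 0, log1p(2)))
  expect_equal(unname(SummarizedExperiment::colData(nm)$scaleFactor),
               c(2, 1))
  expect_identical(inverseNormalize(nm), m)
})

test_that("round trip is exact on random matrices", {
  set.seed(9)
  for (rep in 1:5) {
    m <- matrix(rnbinom(12 * 30, size = 1, mu = 4), 12, 30)
    m[1, ] <- m[1, ] + 1  # no all-zero cells
    rownames(m) <- sprintf("g%02d", 1:12)
    colnames(m) <- sprintf("c%02d", 1:30)
    sce <- normalizeLog1p(SingleCellExperiment::SingleCellExperiment(
      assays = list(counts = m)))
    expect_identical(inverseNormalize(sce), m)
  }
})

test_that("HVG selection ranks by dispersion and honors forcing", {
  set.seed(11)
  n <- 40
  m <- rbind(constant = rep(5, n),
             noisy = rnbinom(n, size = 0.3, mu = 5))
  colnames(m) <- sprintf("c%02d", seq_len(n))
  sce <- normalizeLog1p(SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = m)))
  expect_identical(selectHVGs(sce, 1), "noisy")
  expect_setequal(selectHVGs(sce, 2), c("constant", "noisy"))
  # forcing a below-cutoff gene keeps the size at nTop exactly
  expect_identical(selectHVGs(sce, 1, forceInclude = "constant"),
                   "constant")
  expect_error(selectHVGs(sce, 1, forceInclude = "nope"), "unknown forced")
  expect_error(selectHVGs(sce, 3), "exceeds")
})

test_that("forced genes displace the lowest-ranked selection", {
  sim <- tinyFixture()$sim
  sce <- normalizeLog1p(sim$counts)
  free <- selectHVGs(sce, 20)
  outsider <- setdiff(rownames(sce), free)[1]
  forced <- selectHVGs(sce, 20, forceInclude = outsider)
  expect_length(forced, 20)
  expect_true(outsider %in% forced)
  # only the lowest-ranked free pick was displaced
  expect_setequal(setdiff(free, forced), free[20])
})

test_that("82/9/9 split has floored val/test sizes and is seeded", {
  sim <- tinyFixture()$sim
  sce100 <- sim$counts[, 1:100]
  sp <- SummarizedExperiment::colData(splitCells(sce100, seed = 3))$partition
  expect_equal(as.integer(table(sp)[c("train", "val", "test")]),
               c(82L, 9L, 9L))
  sp2 <- SummarizedExperiment::colData(splitCells(sce100, seed = 3))$partition
  expect_identical(sp, sp2)
  sp3 <- SummarizedExperiment::colData(splitCells(sce100, seed = 4))$partition
  expect_false(identical(sp, sp3))
  expect_error(splitCells(sce100[, 1:2]), "at least 3")
})

test_that("split partitions are disjoint and exhaustive at n = 1000", {
  cfg <- syntheticConfig(nCells = 1000, nGenes = 30, latentDim = 3,
                         nEffectGenes = 3, seed = 2)
  sim <- suppressWarnings(generateSyntheticData(cfg))
  part <- SummarizedExperiment::colData(
    splitCells(sim$counts, seed = 8))$partition
  expect_equal(as.integer(table(part)[c("train", "val", "test")]),
               c(820L, 90L, 90L))
  expect_false(anyNA(part))
})
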