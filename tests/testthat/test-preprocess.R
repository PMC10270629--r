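.mkCohort <- function(counts, lengths = NULL, groups = NULL) {
  if (is.null(lengths))
    lengths <- stats::setNames(rep(1000, nrow(counts)), rownames(counts))
  if (is.null(groups))
    groups <- stats::setNames(rep(c("healthy", "disease"),
                                  length.out = ncol(counts)),
                              colnames(counts))
  expressionCohort(counts, lengths, groups)
}

test_that("the low-count filter keeps genes reaching the threshold in enough samples", {
  counts <- rbind(gA = c(6, 6, 0, 0),    # 50% of samples >= 5 -> kept
                  gB = c(4, 4, 4, 4),    # never reaches 5 -> removed
                  gC = c(5, 0, 0, 0),    # exactly 25% -> kept
                  gD = c(100, 100, 100, 100))
  colnames(counts) <- paste0("s", 1:4)
  out <- filterLowExpressed(.mkCohort(counts))
  expect_setequal(rownames(out), c("gA", "gC", "gD"))
  expect_identical(colnames(out), colnames(counts))
})

test_that("planted low-expression genes are filtered exactly", {
  set.seed(5)
  counts <- rbind(
    matrix(rnbinom(90 * 12, mu = 100, size = 10), 90, 12,
           dimnames = list(sprintf("g%02d", 1:90), sprintf("s%02d", 1:12))),
    matrix(0L, 10, 12,
           dimnames = list(sprintf("low%02d", 1:10), sprintf("s%02d", 1:12))))
  out <- filterLowExpressed(.mkCohort(counts))
  expect_equal(nrow(out), 90)
  expect_false(any(grepl("^low", rownames(out))))
})

test_that("filtering everything is an error, not an empty matrix", {
  counts <- matrix(1, 3, 4, dimnames = list(paste0("g", 1:3),
                                            paste0("s", 1:4)))
  expect_error(filterLowExpressed(.mkCohort(counts)), "filtered out")
})

test_that("identical samples get unit size factors and the plain transform", {
  counts <- matrix(c(10, 20, 30, 40, 50), 5, 2,
                   dimnames = list(paste0("g", 1:5), c("s1", "s2")))
  lengths <- stats::setNames(c(500, 1000, 2000, 1000, 4000), rownames(counts))
  out <- normalizeCohort(.mkCohort(counts, lengths))
  a <- SummarizedExperiment::assay(out, "normalized")
  expected <- log2(counts[, 1] / (lengths / 1000) + 1)
  expect_equal(a[, 1], expected)
  expect_equal(a[, 1], a[, 2])
  expect_equal(unname(S4Vectors::metadata(out)$sizeFactors), c(1, 1))
})

test_that("a doubled sample gets size factor ratio 2 (median-of-ratios by hand)", {
  base <- c(10, 20, 30, 40, 50)
  counts <- cbind(s1 = base, s2 = 2 * base)
  rownames(counts) <- paste0("g", 1:5)
  out <- normalizeCohort(.mkCohort(counts))
  sf <- S4Vectors::metadata(out)$sizeFactors
  ## hand computation: geometric means base*sqrt(2); ratios 1/sqrt(2), sqrt(2)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
  a <- SummarizedExperiment::assay(out, "normalized")
  expect_equal(a[, "s1"], a[, "s2"], tolerance = 1e-12)
})

test_that("an all-zero gene stays zero after normalization", {
  counts <- rbind(g1 = c(10, 20), g2 = c(30, 15), g3 = c(0, 0))
  colnames(counts) <- c("s1", "s2")
  out <- normalizeCohort(.mkCohort(counts))
  expect_equal(unname(SummarizedExperiment::assay(out)["g3", ]), c(0, 0))
})

test_that("rescaling a sample's counts leaves its relative profile invariant", {
  ## median-of-ratios absorbs a per-sample scale c into the size factors
  ## up to the common factor c^(1/m) that the geometric-mean reference
  ## inherits; the within-sample relative profile is exactly invariant
  set.seed(9)
  counts <- matrix(rnbinom(50 * 6, mu = 200, size = 10) + 1, 50, 6,
                   dimnames = list(sprintf("g%02d", 1:50), paste0("s", 1:6)))
  c2 <- counts
  c2[, 3] <- counts[, 3] * 7
  a1 <- SummarizedExperiment::assay(normalizeCohort(.mkCohort(counts)))
  a2 <- SummarizedExperiment::assay(normalizeCohort(.mkCohort(c2)))
  lin1 <- 2^a1[, 3] - 1
  lin2 <- 2^a2[, 3] - 1
  expect_equal(lin2 / lin1, rep(7^(1 / 6), 50), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("undefined size factors (no all-positive gene) are an error", {
  counts <- rbind(g1 = c(0, 5), g2 = c(5, 0))
  colnames(counts) <- c("s1", "s2")
  expect_error(normalizeCohort(.mkCohort(counts)), "size factors")
})

test_that("stage flags gate the pipeline order", {
  counts <- matrix(10, 4, 4, dimnames = list(paste0("g", 1:4),
                                             paste0("s", 1:4)))
  norm <- normalizeCohort(.mkCohort(counts))
  expect_identical(cohortStage(norm), "normalized")
  expect_error(normalizeCohort(norm), "already normalized")
  expect_error(filterLowExpressed(norm), "raw")
})

test_that("cohorts round-trip through the TSV interfaces", {
  set.seed(3)
  counts <- matrix(rnbinom(12, mu = 50, size = 10), 3, 4,
                   dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  d <- withr::local_tempdir()
  utils::write.table(data.frame(gene = rownames(counts), counts),
                     file.path(d, "counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(gene = rownames(counts), length = 1000),
                     file.path(d, "lengths.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample = colnames(counts),
                                group = rep(c("healthy", "disease"), 2)),
                     file.path(d, "groups.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  coh <- readCohort(file.path(d, "counts.tsv"), file.path(d, "lengths.tsv"),
                    file.path(d, "groups.tsv"))
  expect_equal(unname(SummarizedExperiment::assay(coh)), unname(counts))
  expect_identical(unname(cohortGroups(coh)),
                   rep(c("healthy", "disease"), 2))
})
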