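.fvaTable <- function(ids, mins, maxs) {
  data.frame(reaction = ids, min = mins, max = maxs, status = "optimal")
}

test_that("interval-Jaccard shift detection flags moved exchange ranges", {
  m <- chainModel(10)   # EX_a and EX_b are exchanges, CONV is internal
  ids <- c("EX_a", "CONV", "EX_b")
  h <- .fvaTable(ids, c(-10, 0, 0), c(0, 10, 10))
  ## identical ranges: no candidates
  expect_length(detectShiftedExchanges(h, h, m), 0)
  ## EX_a shrinks to [-5, 0]: J = 0.5 < 0.9 -> shifted
  d <- .fvaTable(ids, c(-5, 0, 0), c(0, 10, 10))
  expect_equal(detectShiftedExchanges(h, d, m), "EX_a")
  ## an internal reaction shift is never a candidate
  d2 <- .fvaTable(ids, c(-10, 5, 0), c(0, 10, 10))
  expect_length(detectShiftedExchanges(h, d2, m), 0)
  ## point intervals compared by endpoint distance
  hp <- .fvaTable(ids, c(-3, 0, 0), c(-3, 10, 10))
  dp <- .fvaTable(ids, c(-3.2, 0, 0), c(-3.2, 10, 10))
  expect_equal(detectShiftedExchanges(hp, dp, m), "EX_a")
  expect_length(detectShiftedExchanges(hp, hp, m), 0)
  expect_error(detectShiftedExchanges(h, d[1:2, ], m), "different")
})

test_that("classifier metrics follow the standard formulas", {
  m <- classMetrics(c(TP = 3, TN = 4, FP = 1, FN = 2))
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$sensitivity, 0.6)
  expect_equal(m$specificity, 0.8)
  perfect <- classMetrics(c(TP = 5, TN = 5, FP = 0, FN = 0))
  expect_equal(unlist(perfect), c(accuracy = 1, sensitivity = 1,
                                  specificity = 1))
  ## empty positive class: sensitivity undefined, never 0
  und <- classMetrics(c(TP = 0, TN = 5, FP = 1, FN = 0))
  expect_true(is.na(und$sensitivity))
  expect_false(is.na(und$specificity))
  expect_error(classMetrics(c(TP = -1, TN = 1, FP = 1, FN = 1)),
               "negative")
})

test_that("metrics match direct arithmetic on random confusion matrices", {
  set.seed(41)
  for (i in 1:1000) {
    cm <- stats::setNames(sample(0:30, 4, replace = TRUE),
                          c("TP", "TN", "FP", "FN"))
    if (sum(cm) == 0) cm["TN"] <- 1
    m <- classMetrics(cm)
    expect_equal(m$accuracy, (cm[["TP"]] + cm[["TN"]]) / sum(cm))
    sens <- if (cm[["TP"]] + cm[["FN"]] > 0)
      cm[["TP"]] / (cm[["TP"]] + cm[["FN"]]) else NA_real_
    expect_identical(is.na(m$sensitivity), is.na(sens))
    if (!is.na(sens)) expect_equal(m$sensitivity, sens)
  }
})

.syntheticTable <- function(nPerGroup = 20, nNoise = 19, sep = 6,
                            seed = 1) {
  set.seed(seed)
  n <- 2 * nPerGroup
  noiseNames <- paste0("EX_n", rep(seq_len(nNoise), each = 2), "|",
                       c("min", "max"))[seq_len(nNoise)]
  x <- matrix(stats::rnorm(n * (nNoise + 1)), nrow = n,
              dimnames = list(
                c(sprintf("H%02d", 1:nPerGroup),
                  sprintf("D%02d", 1:nPerGroup)),
                c("EX_m1|max", noiseNames)))
  x[(nPerGroup + 1):n, "EX_m1|max"] <- x[(nPerGroup + 1):n, "EX_m1|max"] + sep
  labels <- stats::setNames(rep(c("healthy", "disease"), each = nPerGroup),
                            rownames(x))
  structure(list(x = x, labels = labels, positive = "disease"),
            class = "FeatureTable")
}

test_that("a perfectly separating feature yields perfect CV accuracy", {
  tab <- .syntheticTable()
  ev <- evaluateSvm(tab, features = "EX_m1|max", folds = 10, repeats = 3,
                    seed = 2)
  expect_equal(ev$mean$accuracy, 1)
  expect_equal(ev$mean$sensitivity, 1)
})

test_that("label permutation drives accuracy to chance", {
  tab <- .syntheticTable(nPerGroup = 25)
  set.seed(99)
  tab$labels[] <- sample(tab$labels)
  ev <- evaluateSvm(tab, folds = 5, repeats = 20, seed = 3)
  expect_lt(abs(ev$mean$accuracy - 0.5), 0.12)
})

test_that("evaluation is reproducible under a fixed seed", {
  tab <- .syntheticTable()
  a <- evaluateSvm(tab, folds = 10, repeats = 5, seed = 7)
  b <- evaluateSvm(tab, folds = 10, repeats = 5, seed = 7)
  expect_identical(a$perRepeat, b$perRepeat)
  expect_error(evaluateSvm(tab, features = character()), "empty")
  expect_error(evaluateSvm(tab, features = "nope"), "absent")
  one <- tab; one$labels[] <- "disease"
  expect_error(evaluateSvm(one), "single class")
})

test_that("the GA recovers a planted separating feature", {
  recovered <- logical(10)
  for (s in 1:10) {
    tab <- .syntheticTable(nPerGroup = 15, seed = 100 + s)
    cfg <- gaConfig(populationSize = 40, generations = 15,
                    fitnessFolds = 5, seed = s)
    run <- gaSelect(tab, cfg)
    recovered[s] <- "EX_m1|max" %in% run$features
    expect_lte(run$generations, 15)
  }
  expect_gte(mean(recovered), 0.9)
})

test_that("all-noise features never reach the stopping fitness", {
  set.seed(55)
  tab <- .syntheticTable(nPerGroup = 10, sep = 0, seed = 5)
  cfg <- gaConfig(populationSize = 12, generations = 5, fitnessFolds = 5,
                  seed = 1)
  run <- gaSelect(tab, cfg)
  expect_equal(run$generations, 5)   # generation cap reached
  expect_lt(max(run$trace), 0.9)
})

test_that("a degenerate GA without variation keeps a flat fitness trace", {
  tab <- .syntheticTable(nPerGroup = 10, seed = 9)
  cfg <- gaConfig(populationSize = 1, generations = 4, crossoverRate = 0,
                  mutationRate = 0, elitism = 1, fitnessFolds = 5,
                  fitnessStop = 1.01, seed = 4)
  ## fitnessStop above 1 forces the run to the generation cap
  run <- gaSelect(tab, cfg)
  expect_equal(length(unique(round(run$trace, 12))), 1)
})

test_that("feature frequencies and the 80% threshold rank reactions", {
  features <- c("EX_a|min", "EX_a|max", "EX_b|min", "EX_b|max")
  subsets <- c(replicate(85, c("EX_a|max"), simplify = FALSE),
               replicate(15, c("EX_b|min"), simplify = FALSE))
  ## put EX_b in 79 more subsets: boundary case below threshold
  subsets <- c(subsets, replicate(64, c("EX_b|min"), simplify = FALSE),
               replicate(36, c("EX_a|max"), simplify = FALSE))
  panel <- rankFeatures(subsets, features, threshold = 80)
  expect_equal(panel@nRepeats, 200)
  expect_equal(unname(reactionFrequency(panel)[["EX_a"]]),
               100 * 121 / 200)
  ## frequencies lie in [0, 100] and adding a subset never lowers a count
  expect_true(all(panel@featureFrequency >= 0 &
                  panel@featureFrequency <= 100))
  p2 <- rankFeatures(c(subsets, list("EX_b|min")), features, 80)
  expect_true(all(p2@featureFrequency[c("EX_b|min")] >=
                  panel@featureFrequency[c("EX_b|min")]))
})

test_that("the 80% boundary is inclusive for 80 and exclusive below", {
  features <- c("EX_a|min", "EX_a|max", "EX_b|min", "EX_b|max")
  ## EX_a|max in 80 of 100 subsets, EX_b|max in 79 of 100
  subsets <- lapply(1:100, function(i)
    c(if (i <= 80) "EX_a|max", if (i <= 79) "EX_b|max"))
  panel <- rankFeatures(subsets, features, threshold = 80)
  expect_equal(unname(reactionFrequency(panel)[c("EX_a", "EX_b")]),
               c(80, 79))
  expect_identical(topRanked(panel), "EX_a")
})

test_that("panel validation restricts to panel features and filters samples", {
  tab <- .syntheticTable(nPerGroup = 15, seed = 77)
  ## a panel reaction contributes both its min and max features
  tab$x <- cbind(tab$x, "EX_m1|min" = stats::rnorm(nrow(tab$x)))
  panel <- rankFeatures(replicate(10, "EX_m1|max", simplify = FALSE),
                        colnames(tab$x))
  expect_identical(topRanked(panel), "EX_m1")
  v <- validatePanel(panel, tab, folds = 5, seed = 11)
  expect_gt(v$mean$accuracy, 0.9)
  ## excluding samples shrinks the evaluated table
  v2 <- validatePanel(panel, tab, exclude = c("H01", "H02"), folds = 5,
                      seed = 11)
  expect_equal(sum(v2$confusion), 28)
  ## missing panel features are an error listing them
  bad <- rankFeatures(replicate(10, "EX_zz|max", simplify = FALSE),
                      c("EX_zz|min", "EX_zz|max"))
  expect_error(validatePanel(bad, tab), "EX_zz")
})
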