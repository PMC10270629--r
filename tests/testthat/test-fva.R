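test_that("FBA finds the bottleneck optimum on a chain", {
  m <- chainModel(10)
  sol <- fba(m, "EX_b")
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective, 10)
  expect_equal(unname(sol$fluxes), c(-10, 10, 10))
})

test_that("FBA with all exchanges closed yields zero", {
  m <- chainModel(0)
  sol <- fba(m, "EX_b")
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective, 0)
})

test_that("FBA picks the higher-yield branch", {
  sol <- fba(branchModel(), "EX_atp")
  expect_equal(sol$objective, 30)
  expect_equal(sol$fluxes[["HIGHY"]], 10)
  expect_equal(sol$fluxes[["LOWY"]], 0)
})

test_that("an infeasible model returns a typed status, not an error", {
  rxn <- data.frame(id = "R1", lower_bound = 5, upper_bound = 10)
  m <- metabolicModel(data.frame(id = c("a_c", "x_c")), rxn,
                      list(R1 = c(a_c = -1, x_c = 1)),
                      c(c = "cytosol", s = "extracellular"),
                      biomassId = "R1", objectiveId = "R1")
  expect_equal(fba(m, "R1")$status, "infeasible")
})

test_that("gamma = 1 pinches the whole chain to the optimum", {
  f <- fva(chainModel(10), fvaConfig(gamma = 1, beta = 1e-9))
  expect_true(attr(f, "feasible"))
  expect_equal(f$min[f$reaction == "CONV"], 10, tolerance = 1e-7)
  expect_equal(f$max[f$reaction == "CONV"], 10, tolerance = 1e-7)
  expect_equal(f$min[f$reaction == "EX_a"], -10, tolerance = 1e-7)
  expect_equal(f$max[f$reaction == "EX_a"], -10, tolerance = 1e-7)
})

test_that("gamma = 0.5 opens every range to half the optimum", {
  f <- fva(chainModel(10), fvaConfig(gamma = 0.5, beta = 1e-9))
  for (r in c("CONV", "EX_b")) {
    expect_equal(f$min[f$reaction == r], 5, tolerance = 1e-7)
    expect_equal(f$max[f$reaction == r], 10, tolerance = 1e-7)
  }
})

test_that("FVA agrees with the vertex-enumeration oracle on small fixtures", {
  fixtures <- list(chainModel(10), branchModel(), revModel(),
                   diamondModel())
  for (m in fixtures) {
    for (gamma in c(1, 0.7)) {
      f <- fva(m, fvaConfig(gamma = gamma, beta = 1e-9))
      o <- oracleFvaFloored(m, gamma = gamma, beta = 1e-9)
      ord <- match(f$reaction, reactions(m)$id)
      expect_equal(f$min, o$min[ord], tolerance = 1e-6)
      expect_equal(f$max, o$max[ord], tolerance = 1e-6)
    }
  }
})

test_that("every FVA interval lies within the reaction bounds", {
  core <- applyMedia(makeToyModel("core"), toyMedia("core"))
  f <- fva(core, fvaConfig())
  rxn <- reactions(core)
  lb <- pmax(rxn$lower_bound[match(f$reaction, rxn$id)], -1000)
  ub <- pmin(rxn$upper_bound[match(f$reaction, rxn$id)], 1000)
  expect_true(all(f$min >= lb - 1e-6))
  expect_true(all(f$max <= ub + 1e-6))
  expect_true(all(f$min <= f$max + 1e-6))
  ## gamma = 1 pinches the objective to a point
  expect_equal(f$min[f$reaction == "DM_ATPM"],
               f$max[f$reaction == "DM_ATPM"], tolerance = 1e-6)
})

test_that("tightening a bound never widens any interval", {
  ## with negligible floors the feasible polytope can only shrink,
  ## so every minimum rises and every maximum falls
  m <- diamondModel()
  cfg <- fvaConfig(gamma = 1e-9, beta = 1e-9)
  f0 <- fva(m, cfg)
  m2 <- m
  m2@reactions$upper_bound[m2@reactions$id == "AC"] <- 5
  f1 <- fva(m2, cfg)
  expect_true(all(f1$min >= f0$min - 1e-9))
  expect_true(all(f1$max <= f0$max + 1e-9))
  ## with relative floors (gamma, beta) the interval *width* still
  ## never grows even though the floors track the new optimum
  cfg2 <- fvaConfig(gamma = 0.5, beta = 1e-9)
  w0 <- with(fva(m, cfg2), max - min)
  w1 <- with(fva(m2, cfg2), max - min)
  expect_true(all(w1 <= w0 + 1e-9))
})

test_that("cohort FVA is deterministic and keeps only feasible samples", {
  m <- chainModel(10)
  cfg <- fvaConfig(gamma = 1, beta = 0.8, biomassRef = 10)
  ranges <- cohortFva(list(s1 = m, s2 = m),
                      c(s1 = "healthy", s2 = "disease"), cfg)
  r1 <- ranges[ranges$sample == "s1", c("reaction", "min", "max")]
  r2 <- ranges[ranges$sample == "s2", c("reaction", "min", "max")]
  rownames(r1) <- rownames(r2) <- NULL
  expect_identical(r1, r2)
  ## one infeasible individual is excluded with a warning
  bad <- chainModel(0)   # biomass floor 8 unreachable
  expect_warning(
    mix <- cohortFva(list(s1 = m, s2 = bad, s3 = m),
                     c(s1 = "healthy", s2 = "healthy", s3 = "disease"),
                     cfg),
    "infeasible")
  expect_setequal(unique(mix$sample), c("s1", "s3"))
  expect_identical(attr(mix, "infeasible"), "s2")
  ## a group losing every sample aborts
  expect_error(
    suppressWarnings(cohortFva(list(s1 = bad, s2 = m),
                               c(s1 = "healthy", s2 = "disease"), cfg)),
    "healthy")
})

test_that("flux-range tables round-trip through TSV", {
  m <- chainModel(10)
  ranges <- cohortFva(list(s1 = m, s2 = m),
                      c(s1 = "healthy", s2 = "disease"),
                      fvaConfig(beta = 1e-9))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeFluxRanges(ranges, path)
  back <- readFluxRanges(path)
  expect_equal(back$min, ranges$min)
  expect_identical(back$reaction, ranges$reaction)
})
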