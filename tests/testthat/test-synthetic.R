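test_that("the mini template is the documented 12-reaction fixture", {
  m <- makeToyModel("mini")
  expect_equal(nrow(reactions(m)), 12)
  media <- toyMedia("mini")
  sol <- fba(applyMedia(m, media))
  expect_equal(sol$status, "optimal")
  expect_gt(sol$objective, 0)
  expect_identical(reactions(removeDeadEnds(m))$id, reactions(m)$id)
})

test_that("the core template satisfies every declared structural requirement", {
  m <- makeToyModel("core")
  rxn <- reactions(m)
  expect_gte(length(setdiff(unique(rxn$subsystem),
                            c("Exchange", "Transport", ""))), 2)
  expect_gte(sum(rxn$kind == "exchange"), 5)
  expect_gte(sum(rxn$kind == "transport"), 1)
  ## biomass consumes at least 3 precursors
  S <- stoichiometry(m)
  expect_gte(sum(S[, biomassId(m)] < 0), 3)
  ## mitochondrial ATP demand as objective
  obj <- objectiveId(m)
  expect_equal(rxn$kind[rxn$id == obj], "objective-demand")
  expect_true("atp_m" %in%
              rownames(S)[S[, obj] != 0])
  ## AND and OR rules both present
  expect_true(any(grepl(" and ", rxn$gpr)))
  expect_true(any(grepl(" or ", rxn$gpr)))
  ## dead-end free and feasible under its media
  expect_identical(reactions(removeDeadEnds(m))$id, rxn$id)
  sol <- fba(applyMedia(m, toyMedia("core")))
  expect_equal(sol$status, "optimal")
  expect_gt(sol$objective, 0)
  expect_error(makeToyModel("giant"), "arg")
})

test_that("model generation is deterministic", {
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  writeModel(makeToyModel("core", seed = 1), p1)
  writeModel(makeToyModel("core", seed = 1), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("cohort generation is seeded and reproducible", {
  m <- makeToyModel("mini")
  a <- makeCohort(m, 4, 4, seed = 3)
  b <- makeCohort(m, 4, 4, seed = 3)
  expect_identical(SummarizedExperiment::assay(a$cohort),
                   SummarizedExperiment::assay(b$cohort))
  c2 <- makeCohort(m, 4, 4, seed = 4)
  expect_false(identical(SummarizedExperiment::assay(a$cohort),
                         SummarizedExperiment::assay(c2$cohort)))
  expect_error(makeCohort(m, 4, 4), "seed")
})

test_that("the planted knockdown halves disease-group count means", {
  m <- makeToyModel("core")
  sim <- makeCohort(m, 60, 60, perturbedPathways = "Folate metabolism",
                    effectSize = 0.5, seed = 8)
  a <- SummarizedExperiment::assay(sim$cohort)
  grp <- cohortGroups(sim$cohort)
  planted <- sim$truth$plantedGenes
  expect_gt(length(planted), 5)
  ratio <- rowMeans(a[planted, grp == "disease"]) /
    rowMeans(a[planted, grp == "healthy"])
  expect_equal(mean(ratio), 0.5, tolerance = 0.12)
  nullGenes <- setdiff(rownames(a), planted)
  ratioNull <- rowMeans(a[nullGenes, grp == "disease"]) /
    rowMeans(a[nullGenes, grp == "healthy"])
  expect_equal(mean(ratioNull), 1, tolerance = 0.12)
  ## ground truth names exactly the GPR-bearing reactions of the pathway
  rxn <- reactions(m)
  expect_setequal(sim$truth$plantedReactions,
                  rxn$id[rxn$subsystem == "Folate metabolism" &
                         nzchar(rxn$gpr)])
  expect_error(makeCohort(m, 4, 4, perturbedPathways = "No such pathway",
                          seed = 1), "not in model")
})

test_that("planted low-expression genes fail the count filter", {
  m <- makeToyModel("mini")
  sim <- makeCohort(m, 10, 10, nLowGenes = 10, seed = 12)
  expect_equal(nrow(sim$cohort), length(geneIds(m)) + 10)
  kept <- filterLowExpressed(sim$cohort)
  expect_false(any(sim$truth$lowGenes %in% rownames(kept)))
  expect_equal(nrow(kept), length(geneIds(m)))
})

test_that("external cohorts support a mislabelled confounder subgroup", {
  m <- makeToyModel("mini")
  plain <- makeExternalCohort(m, 6, 6, shiftFraction = 0, seed = 5)
  expect_length(plain$truth$confounders, 0)
  base <- makeCohort(m, 6, 6, seed = 5)
  expect_identical(SummarizedExperiment::assay(plain$cohort),
                   SummarizedExperiment::assay(base$cohort))
  half <- makeExternalCohort(m, 6, 6, shiftFraction = 0.5,
                             separatingExchange = "EX_lac", seed = 5)
  expect_identical(half$truth$confounders, c("H01", "H02", "H03"))
  ## confounders keep the healthy label
  expect_true(all(cohortGroups(half$cohort)[half$truth$confounders] ==
                  "healthy"))
  expect_error(makeExternalCohort(m, 6, 6, shiftFraction = 2, seed = 1),
               "\\[0, 1\\]")
})

test_that("the marker knockdown separates the marker exchange flux", {
  core <- makeToyModel("core")
  media <- toyMedia("core")
  sim <- makeCohort(core, 8, 8, separatingExchange = "EX_mkc", seed = 21)
  expect_setequal(sim$truth$markerPathways, "Marker metabolism")
  coh <- normalizeCohort(filterLowExpressed(sim$cohort))
  cfg <- fvaConfig(biomassRef = fba(
    personalizeModel(core, coh, media, group = "healthy"), "BIOMASS")$objective)
  rng <- cohortFva(personalizeCohort(core, coh, media),
                   cohortGroups(coh), cfg, reactions = "EX_mkc")
  h <- rng$max[rng$group == "healthy"]
  d <- rng$max[rng$group == "disease"]
  expect_gt(min(h), max(d))   # clean separation
})
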