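.efluxFixture <- function() {
  rxn <- data.frame(
    id = c("EX_a", "R1", "R2", "R3", "EX_b"),
    lower_bound = c(-1000, -1000, 0, 0, 0),
    upper_bound = c(1000, 1000, 1000, 1000, 1000),
    gpr = c("", "gA", "gB", "", ""))
  stoich <- list(EX_a = c(a_s = -1),
                 R1 = c(a_s = -1, b_s = 1),
                 R2 = c(a_s = -1, b_s = 1),
                 R3 = c(b_s = -1, c_s = 1),
                 EX_b = c(c_s = -1))
  metabolicModel(data.frame(id = c("a_s", "b_s", "c_s")), rxn, stoich,
                 c(c = "cytosol", s = "extracellular"),
                 biomassId = "R3", objectiveId = "R3")
}

test_that("bounds scale proportionally to activity over the per-sample maximum", {
  m <- .efluxFixture()
  out <- applyEflux(m, c(EX_a = NA, R1 = 7, R2 = 10, R3 = NA, EX_b = NA))
  rxn <- reactions(out)
  ## reversible reaction scaled symmetrically: 7/10 of [-1000, 1000]
  expect_equal(rxn$lower_bound[rxn$id == "R1"], -700)
  expect_equal(rxn$upper_bound[rxn$id == "R1"], 700)
  ## activity equal to the maximum leaves bounds unchanged
  expect_equal(rxn$upper_bound[rxn$id == "R2"], 1000)
  ## unconstrained and exchange reactions keep original bounds
  expect_equal(rxn$lower_bound[rxn$id == "EX_a"], -1000)
  expect_equal(rxn$upper_bound[rxn$id == "R3"], 1000)
})

test_that("zero activity blocks a reaction and zero maximum is an error", {
  m <- .efluxFixture()
  out <- applyEflux(m, c(EX_a = NA, R1 = 0, R2 = 10, R3 = NA, EX_b = NA))
  rxn <- reactions(out)
  expect_equal(rxn$lower_bound[rxn$id == "R1"], 0)
  expect_equal(rxn$upper_bound[rxn$id == "R1"], 0)
  expect_error(
    applyEflux(m, c(EX_a = NA, R1 = 0, R2 = 0, R3 = NA, EX_b = NA)),
    "degenerate")
})

test_that("scaling is invariant to rescaling all activities", {
  m <- .efluxFixture()
  a <- c(EX_a = NA, R1 = 3, R2 = 8, R3 = NA, EX_b = NA)
  expect_equal(reactions(applyEflux(m, a)),
               reactions(applyEflux(m, a * 13)))
})

test_that("media set uptake bounds and are idempotent", {
  mini <- makeToyModel("mini")
  media <- mediaSpec(c("glc"), uptake = 10)
  out <- applyMedia(mini, media)
  rxn <- reactions(out)
  expect_equal(rxn$lower_bound[rxn$id == "EX_glc"], -10)
  expect_equal(rxn$lower_bound[rxn$id == "EX_ala"], 0)   # closed
  expect_equal(rxn$lower_bound[rxn$id == "EX_lac"], 0)
  ## secretion bounds untouched
  expect_equal(rxn$upper_bound[rxn$id == "EX_lac"], 1000)
  expect_identical(reactions(applyMedia(out, media)), rxn)
})

test_that("media metabolites without exchange reactions are an error", {
  mini <- makeToyModel("mini")
  expect_error(applyMedia(mini, mediaSpec(c("unobtainium"))),
               "unobtainium")
})

test_that("media specifications round-trip through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("metabolites:", "  - glc", "  - ala", "uptake: 12"), path)
  media <- readMedia(path)
  expect_setequal(media$metabolites, c("glc", "ala"))
  expect_equal(media$uptake, 12)
})

test_that("personalization is deterministic and group means degenerate correctly", {
  mini <- makeToyModel("mini")
  media <- toyMedia("mini")
  counts <- matrix(rep(c(100, 200, 300, 150, 250, 120, 90, 80), 3), 8, 3,
                   dimnames = list(paste0("g", 1:8), c("s1", "s2", "s3")))
  coh <- normalizeCohort(expressionCohort(
    counts, stats::setNames(rep(1000, 8), rownames(counts)),
    c(s1 = "healthy", s2 = "healthy", s3 = "disease")))
  m1 <- personalizeModel(mini, coh, media, sample = "s1")
  m2 <- personalizeModel(mini, coh, media, sample = "s2")
  expect_identical(reactions(m1), reactions(m2))
  ## a one-sample group equals that sample's model
  mg <- personalizeModel(mini, coh, media, group = "disease")
  m3 <- personalizeModel(mini, coh, media, sample = "s3")
  expect_identical(reactions(mg), reactions(m3))
  ## only bounds differ from the template, never stoichiometry
  expect_identical(as.matrix(stoichiometry(m1)),
                   as.matrix(stoichiometry(mini)))
  expect_error(personalizeModel(mini, coh, media, sample = "nope"),
               "unknown sample")
  expect_error(personalizeModel(mini, coh, media), "exactly one")
})

test_that("a planted expression knockdown lowers the group-average bounds", {
  core <- makeToyModel("core")
  media <- toyMedia("core")
  sim <- makeCohort(core, 10, 10,
                    perturbedPathways = "Glycerolipid metabolism",
                    effectSize = 0.5, seed = 31)
  coh <- normalizeCohort(filterLowExpressed(sim$cohort))
  h <- reactions(personalizeModel(core, coh, media, group = "healthy"))
  d <- reactions(personalizeModel(core, coh, media, group = "disease"))
  planted <- setdiff(sim$truth$plantedReactions, h$id[h$kind == "exchange"])
  expect_true(all(d$upper_bound[match(planted, d$id)] <
                  h$upper_bound[match(planted, h$id)]))
  ## null pathway bounds move far less than planted ones on average
  null <- h$id[h$subsystem == "Keratan biosynthesis"]
  dropPlanted <- mean(1 - d$upper_bound[match(planted, d$id)] /
                        h$upper_bound[match(planted, h$id)])
  dropNull <- mean(abs(1 - d$upper_bound[match(null, d$id)] /
                         h$upper_bound[match(null, h$id)]))
  expect_gt(dropPlanted, 2 * dropNull)
})
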