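## Synthetic toy models and cohorts with known ground truth.
##
## The generator emulates the statistical structure the pipeline assumes:
## a compartmentalized metabolic network whose peripheral pathways carry
## expression-limited flux, and a two-group RNA-Seq cohort with
## negative-binomial counts in which a disease effect is planted at the
## gene level only -- the E-Flux -> FVA chain must transduce it to fluxes.

.pathwayMotif <- function(prefix, label, comp, geneStart) {
  ## dense 5-metabolite motif: every internal metabolite takes part in
  ## >= 3 reactions, so metabolite-level enrichment has power
  a <- paste0(prefix, "a"); b <- paste0(prefix, "b")
  cm <- paste0(prefix, "c"); d <- paste0(prefix, "d")
  e <- paste0(prefix, "e")
  cc <- function(m) paste0(m, "_", comp)
  g <- function(i) paste0("g", prefix, geneStart + i)
  gprs <- c(g(1),
            paste(g(2), "and", g(3)),
            paste(g(4), "or", g(5)),
            g(6),
            paste(g(7), "and", g(8)),
            paste(g(9), "or", g(10)),
            g(11), g(12), g(13))
  rid <- function(x) paste0(toupper(prefix), x)
  list(
    reactions = data.frame(
      id = c(paste0("EX_", a), rid("_Tin"),
             rid(1:7), rid("_Tout"), paste0("EX_", e)),
      lower_bound = c(-1000, rep(0, 9), -1000),
      upper_bound = c(1000, rep(20, 9), 1000),
      gpr = c("", gprs, ""),
      subsystem = c("Exchange", rep(label, 9), "Exchange"),
      stringsAsFactors = FALSE),
    stoich = stats::setNames(list(
      stats::setNames(-1, paste0(a, "_s")),
      stats::setNames(c(-1, 1), c(paste0(a, "_s"), cc(a))),
      stats::setNames(c(-1, 1), cc(c(a, b))),
      stats::setNames(c(-1, 1), cc(c(b, cm))),
      stats::setNames(c(-1, 1), cc(c(a, cm))),
      stats::setNames(c(-1, 1), cc(c(b, d))),
      stats::setNames(c(-1, 1), cc(c(cm, d))),
      stats::setNames(c(-1, 1), cc(c(cm, e))),
      stats::setNames(c(-1, 1), cc(c(d, e))),
      stats::setNames(c(-1, 1), c(cc(e), paste0(e, "_s"))),
      stats::setNames(-1, paste0(e, "_s"))),
      c(paste0("EX_", a), rid("_Tin"), rid(1:7), rid("_Tout"),
        paste0("EX_", e))))
}

.CORE_PATHWAYS <- data.frame(
  prefix = c("glp", "chs", "ker", "ino", "aam", "fac", "nuc", "fol"),
  label = c("Glycerolipid metabolism", "Chondroitin biosynthesis",
            "Keratan biosynthesis", "Inositol phosphate metabolism",
            "Amino acid metabolism", "Fatty acid activation",
            "Nucleotide metabolism", "Folate metabolism"),
  comp = c("c", "g", "g", "c", "c", "c", "c", "c"),
  stringsAsFactors = FALSE)

.COMPARTMENTS <- c(c = "cytosol", m = "mitochondria", g = "golgi",
                   s = "extracellular")

#' Generate a toy metabolic model
#'
#' Two deterministic templates:
#' \describe{
#'   \item{mini}{12 reactions: glucose and alanine uptake, a two-step
#'     glycolysis, lactate fermentation, a mitochondrial ATP demand
#'     (objective) and a three-precursor biomass reaction.}
#'   \item{core}{about 113 reactions over cytosol, mitochondria, golgi and
#'     the extracellular space: central glycolysis/TCA/oxidative
#'     phosphorylation with cytosolic and mitochondrial ATP/NAD cycles, a
#'     biomass reaction draining four precursors, a dedicated marker
#'     pathway feeding an exchange metabolite, and eight labelled
#'     peripheral pathways (dense five-metabolite motifs) whose capacity
#'     is expression-limited (bounds of 20 versus a media uptake of 50),
#'     so E-Flux caps are the binding constraints.}
#' }
#' Both templates are dead-end free, feasible under [toyMedia()], and mix
#' AND/OR GPR rules.
#'
#' @param template \code{"mini"} or \code{"core"}.
#' @param seed RNG seed (the structure is fully deterministic; the seed is
#'   accepted for interface uniformity and reserved for future randomized
#'   variants).
#' @return a \linkS4class{MetabolicModel}.
#' @export
makeToyModel <- function(template = c("mini", "core"), seed = 1) {
  template <- match.arg(template)
  if (template == "mini") .miniModel() else .coreModel()
}

#' @rdname makeToyModel
#' @return [toyMedia()]: the [mediaSpec()] matching the template.
#' @export
toyMedia <- function(template = c("mini", "core")) {
  template <- match.arg(template)
  if (template == "mini") return(mediaSpec(c("glc", "ala"), uptake = 10))
  mediaSpec(c("glc", "ala", "mk", paste0(.CORE_PATHWAYS$prefix, "a")),
            uptake = 50)
}

.miniModel <- function() {
  rxn <- data.frame(
    id = c("EX_glc", "EX_ala", "EX_lac", "TGLC", "TALA", "GLYC", "LDH",
           "TLAC", "TPYRM", "ATPS", "DM_ATPM", "BIOMASS"),
    lower_bound = c(rep(-1000, 3), rep(0, 9)),
    upper_bound = c(rep(1000, 3), rep(20, 9)),
    gpr = c("", "", "", "g1", "g2", "g3 and g4", "g5 or g6", "", "g7",
            "g8", "", ""),
    subsystem = c(rep("Exchange", 3), "Transport", "Transport",
                  "Glycolysis", "Fermentation", "Transport", "Transport",
                  "Energy metabolism", "Energy metabolism", "Biomass"),
    stringsAsFactors = FALSE)
  stoich <- list(
    EX_glc = c(glc_s = -1), EX_ala = c(ala_s = -1), EX_lac = c(lac_s = -1),
    TGLC = c(glc_s = -1, glc_c = 1),
    TALA = c(ala_s = -1, ala_c = 1),
    GLYC = c(glc_c = -1, pyr_c = 2),
    LDH = c(pyr_c = -1, lac_c = 1),
    TLAC = c(lac_c = -1, lac_s = 1),
    TPYRM = c(pyr_c = -1, pyr_m = 1),
    ATPS = c(pyr_m = -1, atp_m = 3),
    DM_ATPM = c(atp_m = -1),
    BIOMASS = c(ala_c = -1, pyr_c = -1, glc_c = -1))
  mets <- unique(unlist(lapply(stoich, names)))
  metabolicModel(data.frame(id = mets), rxn, stoich, .COMPARTMENTS,
                 biomassId = "BIOMASS", objectiveId = "DM_ATPM")
}

.coreModel <- function() {
  rxn <- data.frame(
    id = c("EX_glc", "TGLC", "GLK", "PFK", "PYK", "TPYR", "PDH", "TCA",
           "ATPS", "DM_ATPM", "TCO2M", "TCO2", "EX_co2",
           "EX_ala", "TALA", "SERS", "FAS", "LIPS", "BIOMASS",
           "EX_mk", "MK_Tin", "MKA", "MKB", "MK_Tout", "EX_mkc"),
    lower_bound = c(-1000, rep(0, 11), -1000,
                    -1000, rep(0, 4), 0,
                    -1000, rep(0, 4), -1000),
    upper_bound = c(1000, rep(1000, 11), 1000,
                    1000, rep(1000, 4), 1000,
                    1000, rep(20, 4), 1000),
    gpr = c("", "gt1", "gc1 or gc2", "gc3 and gc4", "gc5", "gc6",
            "gc7 and gc8", "gc9", "gc10 and gc11", "", "", "", "",
            "", "gb1", "gb2 and gb3", "gb4 or gb5", "gb6", "",
            "", "gmk1", "gmk2 and gmk3", "gmk4", "gmk5", ""),
    subsystem = c("Exchange", "Transport", "Glycolysis", "Glycolysis",
                  "Glycolysis", "Transport", "TCA cycle", "TCA cycle",
                  "Oxidative phosphorylation", "Oxidative phosphorylation",
                  "Transport", "Transport", "Exchange",
                  "Exchange", "Transport", "Serine biosynthesis",
                  "Lipid biosynthesis", "Lipid biosynthesis", "Biomass",
                  "Exchange", "Marker metabolism", "Marker metabolism",
                  "Marker metabolism", "Marker metabolism", "Exchange"),
    stringsAsFactors = FALSE)
  stoich <- list(
    EX_glc = c(glc_s = -1),
    TGLC = c(glc_s = -1, glc_c = 1),
    GLK = c(glc_c = -1, atp_c = -1, g6p_c = 1, adp_c = 1),
    PFK = c(g6p_c = -1, atp_c = -1, fdp_c = 1, adp_c = 1),
    PYK = c(fdp_c = -1, adp_c = -4, pyr_c = 2, atp_c = 4),
    TPYR = c(pyr_c = -1, pyr_m = 1),
    PDH = c(pyr_m = -1, nad_m = -1, accoa_m = 1, nadh_m = 1, co2_m = 1),
    TCA = c(accoa_m = -1, nad_m = -2, nadh_m = 2, co2_m = 2),
    ATPS = c(nadh_m = -1, adp_m = -2, nad_m = 1, atp_m = 2),
    DM_ATPM = c(atp_m = -1, adp_m = 1),
    TCO2M = c(co2_m = -1, co2_c = 1),
    TCO2 = c(co2_c = -1, co2_s = 1),
    EX_co2 = c(co2_s = -1),
    EX_ala = c(ala_s = -1),
    TALA = c(ala_s = -1, ala_c = 1),
    SERS = c(fdp_c = -1, ser_c = 2),
    FAS = c(pyr_c = -2, atp_c = -1, fa_c = 1, adp_c = 1),
    LIPS = c(fa_c = -1, g6p_c = -1, lipid_c = 1),
    BIOMASS = c(ala_c = -0.3, ser_c = -0.2, lipid_c = -0.2, g6p_c = -0.3,
                atp_c = -1, adp_c = 1),
    EX_mk = c(mk_s = -1),
    MK_Tin = c(mk_s = -1, mk_c = 1),
    MKA = c(mk_c = -1, mkb_c = 1),
    MKB = c(mkb_c = -1, mkc_c = 1),
    MK_Tout = c(mkc_c = -1, mkc_s = 1),
    EX_mkc = c(mkc_s = -1))
  for (p in seq_len(nrow(.CORE_PATHWAYS))) {
    mot <- .pathwayMotif(.CORE_PATHWAYS$prefix[p], .CORE_PATHWAYS$label[p],
                         .CORE_PATHWAYS$comp[p], 0L)
    rxn <- rbind(rxn, mot$reactions)
    stoich <- c(stoich, mot$stoich)
  }
  ## one null pathway exercises cytosolic currency coupling
  stoich$FAC2 <- c(stoich$FAC2, c(atp_c = -1, adp_c = 1))
  mets <- unique(unlist(lapply(stoich, names)))
  metabolicModel(data.frame(id = mets), rxn, stoich, .COMPARTMENTS,
                 biomassId = "BIOMASS", objectiveId = "DM_ATPM")
}

.pathwayGenes <- function(model, pathways) {
  rxn <- model@reactions
  miss <- setdiff(pathways, rxn$subsystem)
  if (length(miss))
    stop("pathway not in model: ", paste(miss, collapse = ", "))
  sel <- rxn$id[rxn$subsystem %in% pathways]
  sort(unique(unlist(lapply(model@gprs[sel], gprGenes))))
}

.exchangePathway <- function(model, exchangeId) {
  j <- match(exchangeId, model@reactions$id)
  if (is.na(j) || model@reactions$kind[j] != "exchange")
    stop("'", exchangeId, "' is not an exchange reaction of the model")
  base <- model@metabolites$base_id[which(model@stoichiometry[, j] != 0)]
  touching <- which(Matrix::colSums(
    model@stoichiometry[model@metabolites$base_id == base, , drop = FALSE]
    != 0) > 0)
  ## the pathway label comes from internal chemistry, not from generic
  ## transport/exchange bookkeeping reactions
  internal <- touching[model@reactions$kind[touching] == "internal"]
  subs <- setdiff(unique(model@reactions$subsystem[internal]),
                  c("Exchange", "Transport", ""))
  if (!length(subs))
    stop("no gene-bearing pathway feeds exchange '", exchangeId, "'")
  subs
}

#' Simulate a two-group RNA-Seq cohort over a toy model
#'
#' Counts are negative binomial with gene-specific means drawn log-
#' uniformly over \code{meanRange} and a common dispersion. The disease
#' effect is planted at the \emph{gene} level: genes of the
#' \code{perturbedPathways} have their disease-group means multiplied by
#' \code{effectSize}; genes of the pathway feeding
#' \code{separatingExchange} are multiplied by \code{markerEffect},
#' creating a cleanly shifted exchange flux. Gene lengths are uniform
#' over \code{lengthRange}. Optional \code{nLowGenes} extra non-model
#' genes with near-zero expression exercise the low-count filter.
#'
#' @param model a toy \linkS4class{MetabolicModel} from [makeToyModel()].
#' @param nHealthy,nDisease samples per group (>= 2 each).
#' @param perturbedPathways subsystem labels to knock down.
#' @param effectSize multiplicative knockdown of disease-group means,
#'   in (0, 1]; 1 means no effect (exchangeable groups).
#' @param separatingExchange optional exchange reaction id to plant a
#'   marker signal on.
#' @param markerEffect knockdown factor for the marker pathway's genes.
#' @param dispersion negative-binomial dispersion (default 0.1).
#' @param meanRange range of gene mean counts (log-uniform draw).
#' @param lengthRange gene length range in bp.
#' @param nLowGenes extra planted low-expression genes (default 0).
#' @param seed mandatory RNG seed.
#' @return list with \code{cohort} (raw-stage
#'   \linkS4class{ExpressionCohort}) and \code{truth} (planted genes,
#'   reactions, pathways, marker records, confounders).
#' @export
makeCohort <- function(model, nHealthy = 20, nDisease = 20,
                       perturbedPathways = character(), effectSize = 1,
                       separatingExchange = NULL, markerEffect = 0.1,
                       dispersion = 0.1, meanRange = c(50, 500),
                       lengthRange = c(500, 3000), nLowGenes = 0, seed) {
  if (missing(seed)) stop("a seed is required for cohort generation")
  stopifnot(nHealthy >= 2, nDisease >= 2, effectSize > 0, effectSize <= 1)
  set.seed(seed)
  genes <- geneIds(model)
  plantedGenes <- if (length(perturbedPathways))
    .pathwayGenes(model, perturbedPathways) else character()
  markerGenes <- character()
  markerPathways <- character()
  if (!is.null(separatingExchange)) {
    markerPathways <- .exchangePathway(model, separatingExchange)
    markerGenes <- .pathwayGenes(model, markerPathways)
  }
  nGenes <- length(genes) + nLowGenes
  allGenes <- c(genes, if (nLowGenes > 0) sprintf("low%03d", seq_len(nLowGenes)))
  mu <- exp(stats::runif(nGenes, log(meanRange[1]), log(meanRange[2])))
  names(mu) <- allGenes
  if (nLowGenes > 0) mu[seq.int(length(genes) + 1L, nGenes)] <- 1
  lengths <- stats::setNames(
    round(stats::runif(nGenes, lengthRange[1], lengthRange[2])), allGenes)
  samples <- c(sprintf("H%02d", seq_len(nHealthy)),
               sprintf("D%02d", seq_len(nDisease)))
  groups <- stats::setNames(rep(c("healthy", "disease"),
                                c(nHealthy, nDisease)), samples)
  counts <- matrix(0L, nGenes, length(samples),
                   dimnames = list(allGenes, samples))
  for (s in samples) {
    m <- mu
    if (groups[s] == "disease") {
      m[plantedGenes] <- m[plantedGenes] * effectSize
      m[markerGenes] <- m[markerGenes] * markerEffect
    }
    counts[, s] <- stats::rnbinom(nGenes, mu = m, size = 1 / dispersion)
  }
  plantedReactions <- model@reactions$id[
    vapply(model@gprs, function(t) any(gprGenes(t) %in% plantedGenes),
           logical(1))]
  truth <- list(plantedGenes = plantedGenes,
                plantedReactions = plantedReactions,
                plantedPathways = perturbedPathways,
                markerGenes = markerGenes,
                markerPathways = markerPathways,
                markerExchange = separatingExchange,
                lowGenes = if (nLowGenes > 0)
                  sprintf("low%03d", seq_len(nLowGenes)) else character(),
                confounders = character())
  list(cohort = expressionCohort(counts, lengths, groups), truth = truth)
}

#' Simulate an external validation cohort with an optional confounder
#' subgroup
#'
#' Draws a fresh cohort from the same generative process and optionally
#' relabels a fraction of the healthy-labelled samples as coming from the
#' disease generative process -- emulating a normoglycemic but
#' insulin-resistant subgroup that degrades validation accuracy until it
#' is excluded.
#'
#' @inheritParams makeCohort
#' @param shiftFraction fraction of healthy-labelled samples drawn from
#'   the disease process, in [0, 1].
#' @return as [makeCohort()]; \code{truth$confounders} names the
#'   mislabelled samples.
#' @export
makeExternalCohort <- function(model, nHealthy = 12, nDisease = 12,
                               shiftFraction = 0,
                               perturbedPathways = character(),
                               effectSize = 1, separatingExchange = NULL,
                               markerEffect = 0.1, dispersion = 0.1,
                               meanRange = c(50, 500),
                               lengthRange = c(500, 3000), seed) {
  if (missing(seed)) stop("a seed is required for cohort generation")
  if (shiftFraction < 0 || shiftFraction > 1)
    stop("shiftFraction must lie in [0, 1]")
  out <- makeCohort(model, nHealthy = nHealthy, nDisease = nDisease,
                    perturbedPathways = perturbedPathways,
                    effectSize = effectSize,
                    separatingExchange = separatingExchange,
                    markerEffect = markerEffect, dispersion = dispersion,
                    meanRange = meanRange, lengthRange = lengthRange,
                    seed = seed)
  k <- round(shiftFraction * nHealthy)
  if (k > 0) {
    conf <- sprintf("H%02d", seq_len(k))
    a <- SummarizedExperiment::assay(out$cohort, "counts")
    genes <- rownames(a)
    set.seed(seed + 1L)
    ## redraw the confounders from the disease process, keep the healthy label
    for (s in conf) {
      m <- .cohortMeans(out, genes)
      a[, s] <- stats::rnbinom(length(genes), mu = m, size = 1 / dispersion)
    }
    out$cohort <- expressionCohort(a, geneLengths(out$cohort),
                                   cohortGroups(out$cohort))
    out$truth$confounders <- conf
  }
  out
}

## disease-process mean vector reconstructed from the cohort's truth;
## used to redraw confounder samples
.cohortMeans <- function(out, genes) {
  a <- SummarizedExperiment::assay(out$cohort, "counts")
  grp <- cohortGroups(out$cohort)
  rowMeans(a[genes, names(grp)[grp == "disease"], drop = FALSE])
}
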