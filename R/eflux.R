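#' Per-reaction expression activities
#'
#' Maps a gene expression profile through every reaction's GPR rule with
#' [gprActivity()] (AND = min, OR = sum by default). Reactions without a
#' GPR get \code{NA}, the "unconstrained" sentinel: E-Flux leaves their
#' bounds untouched.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param expr named numeric vector of non-negative (log-scale) expression
#'   values.
#' @param orMode passed to [gprActivity()].
#' @return named numeric vector of activities (NA = unconstrained).
#' @export
reactionActivity <- function(model, expr, orMode = c("sum", "max")) {
  orMode <- match.arg(orMode)
  vapply(model@gprs, gprActivity, numeric(1), expr = expr, orMode = orMode)
}

#' Scale reaction bounds by expression (E-Flux)
#'
#' Each gene-associated reaction's bounds are scaled by
#' \code{activity / max(activity)}, the maximum running over the
#' gene-associated reactions of this sample, so scales lie in [0, 1] and
#' are invariant to rescaling all activities. Reversible reactions are
#' scaled symmetrically. Reactions without a GPR and exchange reactions
#' (no enzyme) keep their original bounds; media constraints alone govern
#' exchanges.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param activities named numeric from [reactionActivity()].
#' @return the model with scaled bounds (stoichiometry untouched).
#' @export
applyEflux <- function(model, activities) {
  rxn <- model@reactions
  activities <- activities[rxn$id]
  scalable <- !is.na(activities) & rxn$kind != "exchange"
  if (!any(scalable)) stop("no gene-associated reactions to scale")
  amax <- max(activities[scalable])
  if (amax <= 0)
    stop("degenerate expression: maximum reaction activity is 0")
  scale <- pmin(activities / amax, 1)
  lb <- rxn$lower_bound
  ub <- rxn$upper_bound
  lb[scalable] <- lb[scalable] * scale[scalable]
  ub[scalable] <- ub[scalable] * scale[scalable]
  model@reactions$lower_bound <- lb
  model@reactions$upper_bound <- ub
  model
}

#' Media specification
#'
#' The growth medium is the set of extracellular metabolites available for
#' uptake, mirroring body-fluid composition in tissue models. Uptake of
#' every other exchanged metabolite is closed.
#'
#' @param metabolites character vector of metabolite base ids permitted
#'   for uptake.
#' @param uptake default maximum uptake rate (mmol/gDW/h), default 10.
#' @return list of class \code{MediaSpec}.
#' @export
mediaSpec <- function(metabolites, uptake = 10) {
  stopifnot(length(metabolites) >= 1, uptake > 0)
  structure(list(metabolites = metabolites, uptake = uptake),
            class = "MediaSpec")
}

#' Read a media specification from YAML
#'
#' Expects fields \code{metabolites} (list of base ids) and optional
#' \code{uptake}.
#' @param path YAML file path.
#' @return a [mediaSpec()].
#' @export
readMedia <- function(path) {
  raw <- yaml::read_yaml(path)
  mediaSpec(unlist(raw$metabolites),
            uptake = if (is.null(raw$uptake)) 10 else raw$uptake)
}

#' Apply media constraints to exchange reactions
#'
#' Sets the uptake (lower) bound of each exchange reaction: \code{-uptake}
#' for media metabolites, 0 for all others. Secretion (upper) bounds are
#' untouched. Negative exchange flux is uptake. Idempotent.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param media a [mediaSpec()].
#' @return the constrained model.
#' @export
applyMedia <- function(model, media) {
  rxn <- model@reactions
  exch <- which(rxn$kind == "exchange")
  if (!length(exch)) stop("model has no exchange reactions")
  exch_base <- vapply(exch, function(j) {
    model@metabolites$base_id[which(model@stoichiometry[, j] != 0)]
  }, character(1))
  unknown <- setdiff(media$metabolites, exch_base)
  if (length(unknown))
    stop("media metabolites without exchange reactions: ",
         paste(unknown, collapse = ", "))
  lb <- rxn$lower_bound
  lb[exch] <- ifelse(exch_base %in% media$metabolites, -abs(media$uptake), 0)
  model@reactions$lower_bound <- lb
  model
}

#' Build a personalized (or group-average) model
#'
#' Integrates one individual's normalized expression profile -- or the
#' per-gene mean profile of a group -- into the template model:
#' GPR activities are computed, E-Flux scales the bounds, and the media
#' constraints are applied. Personalized models differ from the template
#' only in bounds, never in stoichiometry.
#'
#' @param model the template \linkS4class{MetabolicModel}.
#' @param cohort a normalized-stage \linkS4class{ExpressionCohort}.
#' @param media a [mediaSpec()].
#' @param sample sample id (mutually exclusive with \code{group}).
#' @param group group label: uses the arithmetic mean of the group's
#'   normalized profiles.
#' @param orMode passed to [reactionActivity()].
#' @return a bound-constrained copy of \code{model}.
#' @export
personalizeModel <- function(model, cohort, media, sample = NULL,
                             group = NULL, orMode = c("sum", "max")) {
  orMode <- match.arg(orMode)
  if (cohortStage(cohort) != "normalized")
    stop("personalization requires normalized expression")
  if (is.null(sample) == is.null(group))
    stop("supply exactly one of 'sample' or 'group'")
  a <- SummarizedExperiment::assay(cohort, "normalized")
  if (!is.null(sample)) {
    if (!sample %in% colnames(a)) stop("unknown sample: ", sample)
    expr <- a[, sample]
  } else {
    grp <- cohortGroups(cohort)
    if (!group %in% grp) stop("unknown group: ", group)
    expr <- rowMeans(a[, names(grp)[grp == group], drop = FALSE])
  }
  act <- reactionActivity(model, expr, orMode = orMode)
  applyMedia(applyEflux(model, act), media)
}

#' Personalized models for every sample in a cohort
#'
#' @inheritParams personalizeModel
#' @return named list of models, one per sample.
#' @export
personalizeCohort <- function(model, cohort, media,
                              orMode = c("sum", "max")) {
  orMode <- match.arg(orMode)
  samples <- colnames(cohort)
  stats::setNames(lapply(samples, function(s)
    personalizeModel(model, cohort, media, sample = s, orMode = orMode)),
    samples)
}
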