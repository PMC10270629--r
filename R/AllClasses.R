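#' MetabolicModel: a stoichiometric metabolic network
#'
#' S4 container for a (toy or genome-scale) metabolic network: metabolites
#' with compartment annotations, reactions with flux bounds, gene-protein-
#' reaction (GPR) boolean rules and subsystem (pathway) labels, a sparse
#' stoichiometric matrix, and designated biomass and objective reactions.
#'
#' Reaction \emph{kinds} are derived from structure and the designated ids:
#' \describe{
#'   \item{exchange}{exactly one metabolite, extracellular; negative flux is
#'     uptake (COBRA convention).}
#'   \item{transport}{participants span two or more compartments.}
#'   \item{biomass}{the designated biomass pseudo-reaction.}
#'   \item{objective-demand}{the designated objective (e.g. a mitochondrial
#'     ATP demand).}
#'   \item{internal}{everything else.}
#' }
#'
#' @slot metabolites data.frame with columns \code{id}, \code{name},
#'   \code{compartment}, \code{base_id} (id with the compartment suffix
#'   stripped -- the "unique" metabolite form).
#' @slot reactions data.frame with columns \code{id}, \code{lower_bound},
#'   \code{upper_bound} (mmol/gDW/h), \code{gpr} (normalized rule string),
#'   \code{subsystem}, \code{kind}.
#' @slot stoichiometry sparse metabolite x reaction matrix; negative
#'   coefficients are substrates.
#' @slot gprs named list of parsed GPR trees (see [parseGpr()]).
#' @slot compartments named character vector, single-letter codes to names;
#'   the code \code{"s"} denotes the extracellular space.
#' @slot biomassId,objectiveId reaction ids of the biomass and objective
#'   (demand) reactions.
#'
#' @seealso [metabolicModel()], [readModel()], [removeDeadEnds()], [fba()]
#' @export
setClass("MetabolicModel",
  representation(
    metabolites   = "data.frame",
    reactions     = "data.frame",
    stoichiometry = "Matrix",
    gprs          = "list",
    compartments  = "character",
    biomassId     = "character",
    objectiveId   = "character"
  )
)

.EXTRACELLULAR <- "s"

.validMetabolicModel <- function(object) {
  msgs <- character()
  met <- object@metabolites
  rxn <- object@reactions
  S <- object@stoichiometry
  need_met <- c("id", "name", "compartment", "base_id")
  need_rxn <- c("id", "lower_bound", "upper_bound", "gpr", "subsystem", "kind")
  if (!all(need_met %in% names(met)))
    return("metabolites must have columns id, name, compartment, base_id")
  if (!all(need_rxn %in% names(rxn)))
    return("reactions must have columns id, lower_bound, upper_bound, gpr, subsystem, kind")
  if (anyDuplicated(met$id)) msgs <- c(msgs, "duplicated metabolite ids")
  if (anyDuplicated(rxn$id)) msgs <- c(msgs, "duplicated reaction ids")
  if (!identical(rownames(S), met$id) || !identical(colnames(S), rxn$id))
    msgs <- c(msgs, "stoichiometry dimnames must match metabolite/reaction ids")
  if (any(rxn$lower_bound > rxn$upper_bound))
    msgs <- c(msgs, "lower_bound > upper_bound for some reaction")
  if (!all(met$compartment %in% names(object@compartments)))
    msgs <- c(msgs, "metabolite compartment outside the declared compartment set")
  if (length(object@biomassId) != 1L || !(object@biomassId %in% rxn$id))
    msgs <- c(msgs, "biomassId must name one reaction")
  if (length(object@objectiveId) != 1L || !(object@objectiveId %in% rxn$id))
    msgs <- c(msgs, "objectiveId must name one reaction")
  if (!identical(names(object@gprs), rxn$id))
    msgs <- c(msgs, "gprs must be named by reaction id, in reaction order")
  ## every reaction must touch at least one metabolite
  nz <- Matrix::colSums(S != 0)
  if (any(nz == 0L)) msgs <- c(msgs, "reaction with empty stoichiometry")
  ## kind consistency
  for (j in seq_len(ncol(S))) {
    mets_j <- met[S[, j] != 0, , drop = FALSE]
    ncomp <- length(unique(mets_j$compartment))
    kind <- rxn$kind[j]
    is_exch <- nrow(mets_j) == 1L &&
      mets_j$compartment[1] == .EXTRACELLULAR &&
      !(rxn$id[j] %in% c(object@biomassId, object@objectiveId))
    if (is_exch && kind != "exchange") {
      msgs <- c(msgs, sprintf("%s should be kind 'exchange'", rxn$id[j])); break
    }
    if (!is_exch && kind == "exchange") {
      msgs <- c(msgs, sprintf("%s wrongly marked 'exchange'", rxn$id[j])); break
    }
    if (ncomp >= 2L && !(kind %in% "transport")) {
      msgs <- c(msgs, sprintf("%s spans %d compartments but kind is '%s'",
                              rxn$id[j], ncomp, kind)); break
    }
    if (kind == "transport" && ncomp < 2L) {
      msgs <- c(msgs, sprintf("%s marked transport but spans one compartment",
                              rxn$id[j])); break
    }
  }
  if (length(msgs)) msgs else TRUE
}

setValidity("MetabolicModel", .validMetabolicModel)

#' ExpressionCohort: a gene x sample expression matrix with group labels
#'
#' Extends \linkS4class{SummarizedExperiment}. Rows are genes with a
#' \code{length} (bp) column in \code{rowData}; columns are samples with a
#' two-level \code{group} factor in \code{colData}. The processing stage
#' (\code{"raw"} counts or \code{"normalized"} log2 values) is tracked in
#' \code{metadata(x)$stage}.
#'
#' @seealso [expressionCohort()], [filterLowExpressed()], [normalizeCohort()]
#' @export
setClass("ExpressionCohort", contains = "SummarizedExperiment")

.validExpressionCohort <- function(object) {
  msgs <- character()
  a <- SummarizedExperiment::assay(object, 1L)
  if (any(a < 0, na.rm = TRUE)) msgs <- c(msgs, "negative expression values")
  rd <- SummarizedExperiment::rowData(object)
  if (!"length" %in% names(rd) || any(rd$length <= 0))
    msgs <- c(msgs, "rowData$length must be positive for every gene")
  cd <- SummarizedExperiment::colData(object)
  if (!"group" %in% names(cd))
    msgs <- c(msgs, "colData$group is required")
  stage <- S4Vectors::metadata(object)$stage
  if (is.null(stage) || !stage %in% c("raw", "normalized"))
    msgs <- c(msgs, "metadata$stage must be 'raw' or 'normalized'")
  if (length(msgs)) msgs else TRUE
}

setValidity("ExpressionCohort", .validExpressionCohort)

#' MetaboliteNetwork: metabolite-centric network of perturbed reactions
#'
#' Undirected network whose nodes are base (compartment-collapsed)
#' metabolite ids and whose edges connect a substrate and a product of the
#' same perturbed reaction, after removal of currency metabolites.
#'
#' @slot nodes data.frame with columns \code{id} and optionally \code{q}
#'   (metabolite-enrichment adjusted p-value).
#' @slot edges data.frame with columns \code{from}, \code{to},
#'   \code{reactions} (comma-joined supporting reaction ids).
#' @seealso [buildNetwork()], [filterSignificant()], [networkComponents()]
#' @export
setClass("MetaboliteNetwork",
  representation(nodes = "data.frame", edges = "data.frame"))

.validMetaboliteNetwork <- function(object) {
  msgs <- character()
  if (nrow(object@edges)) {
    if (!all(c(object@edges$from, object@edges$to) %in% object@nodes$id))
      msgs <- c(msgs, "edge endpoints missing from node table")
    if (any(object@edges$from == object@edges$to))
      msgs <- c(msgs, "self-loops are not allowed")
  }
  if (length(msgs)) msgs else TRUE
}

setValidity("MetaboliteNetwork", .validMetaboliteNetwork)

#' MarkerPanel: GA-SVM flux-marker selection result
#'
#' @slot candidates candidate exchange reaction ids (flux-range-shifted
#'   between the group-average models).
#' @slot featureFrequency named numeric, selection frequency (percent) of
#'   each \code{<reaction>|min} / \code{<reaction>|max} feature across GA
#'   repeats.
#' @slot reactionFrequency named numeric, per-reaction frequency (max over
#'   its two features).
#' @slot topRanked reaction ids with frequency at or above the threshold.
#' @slot threshold frequency threshold in percent (default 80).
#' @slot nRepeats number of GA repeats the frequencies were computed over.
#' @slot cvMetrics list of cross-validation metric summaries (accuracy,
#'   sensitivity, specificity) for the full and top-ranked feature sets.
#' @seealso [rankFeatures()], [validatePanel()]
#' @export
setClass("MarkerPanel",
  representation(
    candidates        = "character",
    featureFrequency  = "numeric",
    reactionFrequency = "numeric",
    topRanked         = "character",
    threshold         = "numeric",
    nRepeats          = "numeric",
    cvMetrics         = "list"
  )
)

setValidity("MarkerPanel", function(object) {
  msgs <- character()
  if (any(object@featureFrequency < 0 | object@featureFrequency > 100))
    msgs <- c(msgs, "frequencies must lie in [0, 100]")
  if (!all(object@topRanked %in% object@candidates))
    msgs <- c(msgs, "topRanked must be a subset of candidates")
  if (length(msgs)) msgs else TRUE
})
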