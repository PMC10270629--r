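#' Construct a MetabolicModel
#'
#' @param metabolites data.frame with column \code{id} (compartmentalized,
#'   e.g. \code{"glc_c"}); optional \code{name} and \code{compartment}
#'   (derived from the id suffix when absent).
#' @param reactions data.frame with columns \code{id}, \code{lower_bound},
#'   \code{upper_bound}; optional \code{gpr} (rule string, default none) and
#'   \code{subsystem} (default \code{""}).
#' @param stoich named list (one entry per reaction id, in reaction order)
#'   of named numeric coefficient vectors; negative = substrate.
#' @param compartments named character vector of compartment codes to names;
#'   code \code{"s"} is the extracellular space.
#' @param biomassId,objectiveId reaction ids of the biomass and objective
#'   (demand) reactions.
#' @return a validated \linkS4class{MetabolicModel}.
#' @export
metabolicModel <- function(metabolites, reactions, stoich, compartments,
                           biomassId, objectiveId) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  if (is.null(metabolites$compartment))
    metabolites$compartment <- .compartmentOf(metabolites$id, compartments)
  metabolites$base_id <- baseId(metabolites$id, compartments)
  if (is.null(reactions$gpr)) reactions$gpr <- ""
  reactions$gpr[is.na(reactions$gpr)] <- ""
  if (is.null(reactions$subsystem)) reactions$subsystem <- ""
  if (!identical(names(stoich), reactions$id))
    stoich <- stoich[reactions$id]
  bad <- setdiff(unique(unlist(lapply(stoich, names))), metabolites$id)
  if (length(bad))
    stop("stoichiometry references unknown metabolites: ",
         paste(bad, collapse = ", "))

  i <- unlist(lapply(stoich, function(s) match(names(s), metabolites$id)),
              use.names = FALSE)
  j <- rep(seq_along(stoich), lengths(stoich))
  x <- unlist(stoich, use.names = FALSE)
  S <- Matrix::sparseMatrix(i = i, j = j, x = x,
                            dims = c(nrow(metabolites), nrow(reactions)),
                            dimnames = list(metabolites$id, reactions$id))

  gprs <- lapply(reactions$gpr, parseGpr)
  names(gprs) <- reactions$id
  reactions$gpr <- vapply(gprs, gprToString, character(1))
  reactions$kind <- .deriveKinds(metabolites, reactions, S,
                                 biomassId, objectiveId)
  rownames(metabolites) <- NULL
  rownames(reactions) <- NULL
  new("MetabolicModel", metabolites = metabolites, reactions = reactions,
      stoichiometry = S, gprs = gprs, compartments = compartments,
      biomassId = biomassId, objectiveId = objectiveId)
}

#' Strip the compartment suffix from metabolite ids
#'
#' \code{"glc_c"} becomes \code{"glc"}; ids without a recognized suffix are
#' returned unchanged. This is the "unique" (compartment-collapsed) form
#' used for metabolite-centric networks.
#'
#' @param ids character vector of metabolite ids.
#' @param compartments named character vector of valid compartment codes.
#' @return character vector of base ids.
#' @export
baseId <- function(ids, compartments) {
  suf <- sub("^.*_([^_]+)$", "\\1", ids)
  has <- grepl("_", ids) & suf %in% names(compartments)
  ifelse(has, sub("_[^_]+$", "", ids), ids)
}

.compartmentOf <- function(ids, compartments) {
  suf <- sub("^.*_([^_]+)$", "\\1", ids)
  ok <- grepl("_", ids) & suf %in% names(compartments)
  if (!all(ok))
    stop("cannot derive compartment for: ",
         paste(ids[!ok], collapse = ", "))
  suf
}

.deriveKinds <- function(met, rxn, S, biomassId, objectiveId) {
  kind <- character(nrow(rxn))
  for (jj in seq_len(nrow(rxn))) {
    idx <- which(S[, jj] != 0)
    comps <- unique(met$compartment[idx])
    if (rxn$id[jj] == biomassId) kind[jj] <- "biomass"
    else if (rxn$id[jj] == objectiveId) kind[jj] <- "objective-demand"
    else if (length(idx) == 1L && comps == .EXTRACELLULAR) kind[jj] <- "exchange"
    else if (length(comps) >= 2L) kind[jj] <- "transport"
    else kind[jj] <- "internal"
  }
  kind
}

#' @rdname MetabolicModel-class
#' @export
setMethod("reactions", "MetabolicModel", function(x) x@reactions)

#' @rdname MetabolicModel-class
#' @export
setMethod("metabolites", "MetabolicModel", function(x) x@metabolites)

#' @rdname MetabolicModel-class
#' @export
setMethod("stoichiometry", "MetabolicModel", function(x) x@stoichiometry)

#' @rdname MetabolicModel-class
#' @export
setMethod("geneIds", "MetabolicModel", function(x)
  sort(unique(unlist(lapply(x@gprs, gprGenes), use.names = FALSE))))

#' @rdname MetabolicModel-class
#' @export
setMethod("compartments", "MetabolicModel", function(x) x@compartments)

#' @rdname MetabolicModel-class
#' @export
setMethod("biomassId", "MetabolicModel", function(x) x@biomassId)

#' @rdname MetabolicModel-class
#' @export
setMethod("objectiveId", "MetabolicModel", function(x) x@objectiveId)

setMethod("show", "MetabolicModel", function(object) {
  st <- modelStats(object)
  cat("MetabolicModel:", st$reactions, "reactions,", st$metabolites,
      "metabolites,", st$genes, "genes\n")
  cat("  compartments:", paste(names(object@compartments), collapse = " "),
      "\n")
  cat("  kinds:", paste(names(table(object@reactions$kind)),
                        table(object@reactions$kind),
                        collapse = ", "), "\n")
  cat("  biomass:", object@biomassId, " objective:", object@objectiveId, "\n")
})

#' Model size statistics
#'
#' Counts of reactions, metabolites and genes (genes are the union of GPR
#' leaves), the usual summary row for a reconstructed model.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @return list with elements \code{reactions}, \code{metabolites},
#'   \code{genes}.
#' @export
modelStats <- function(model) {
  list(reactions = nrow(model@reactions),
       metabolites = nrow(model@metabolites),
       genes = length(geneIds(model)))
}

#' Subset a model to a set of reactions
#'
#' Keeps the given reactions, drops metabolites and genes that no longer
#' occur. Internal building block for pruning.
#' @keywords internal
.subsetModel <- function(model, keep_rxn) {
  rxn <- model@reactions[model@reactions$id %in% keep_rxn, , drop = FALSE]
  if (!nrow(rxn)) stop("subset would remove every reaction")
  S <- model@stoichiometry[, rxn$id, drop = FALSE]
  keep_met <- Matrix::rowSums(S != 0) > 0
  met <- model@metabolites[keep_met, , drop = FALSE]
  S <- S[keep_met, , drop = FALSE]
  rownames(rxn) <- NULL
  rownames(met) <- NULL
  new("MetabolicModel", metabolites = met, reactions = rxn,
      stoichiometry = S, gprs = model@gprs[rxn$id],
      compartments = model@compartments,
      biomassId = model@biomassId, objectiveId = model@objectiveId)
}

#' Remove dead-end metabolites and their reactions
#'
#' A dead-end metabolite is one that is only produced or only consumed
#' across the whole network, so no steady-state flux can traverse it.
#' Detection is topological: reversible reactions count their metabolites
#' on both sides, and exchange reactions count as both producer and
#' consumer of their metabolite. Pruning iterates to a fixed point (a
#' removal can orphan further metabolites); reactions touching a dead-end
#' metabolite are removed, then orphaned metabolites and genes are dropped.
#' The operation is idempotent.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @return the pruned model; an error is raised if pruning would remove the
#'   biomass or objective reaction, or empty the model.
#' @export
removeDeadEnds <- function(model) {
  if (!nrow(model@reactions)) stop("empty model")
  repeat {
    S <- model@stoichiometry
    rxn <- model@reactions
    rev <- rxn$lower_bound < 0 & rxn$upper_bound > 0
    both <- rev | rxn$kind == "exchange"
    prod <- (S > 0) | (S != 0 & matrix(both, nrow(S), ncol(S), byrow = TRUE))
    cons <- (S < 0) | (S != 0 & matrix(both, nrow(S), ncol(S), byrow = TRUE))
    dead <- (Matrix::rowSums(prod) == 0) | (Matrix::rowSums(cons) == 0)
    if (!any(dead)) return(model)
    touch <- Matrix::colSums(S[dead, , drop = FALSE] != 0) > 0
    drop_rxn <- rxn$id[touch]
    if (model@biomassId %in% drop_rxn)
      stop("dead-end pruning would remove the biomass reaction '",
           model@biomassId, "'")
    if (model@objectiveId %in% drop_rxn)
      stop("dead-end pruning would remove the objective reaction '",
           model@objectiveId, "'")
    if (all(touch)) stop("dead-end pruning would empty the model")
    model <- .subsetModel(model, rxn$id[!touch])
  }
}

#' Define a metabolic task
#'
#' A task asks whether the network can produce each required output from a
#' restricted set of inputs: all exchanges are closed, the allowed inputs
#' are opened for uptake, and each required output is tested by LP for
#' feasible production at or above its minimum rate.
#'
#' @param id task identifier.
#' @param inputs named numeric: extracellular metabolite ids to maximum
#'   uptake rates (mmol/gDW/h).
#' @param outputs named numeric: extracellular metabolite ids to minimum
#'   production rates.
#' @param description free-text description.
#' @return a \code{MetabolicTask} list.
#' @export
metabolicTask <- function(id, inputs, outputs, description = "") {
  stopifnot(is.numeric(inputs), !is.null(names(inputs)),
            is.numeric(outputs), !is.null(names(outputs)))
  structure(list(id = id, inputs = inputs, outputs = outputs,
                 description = description), class = "MetabolicTask")
}

#' Check metabolic tasks by linear programming
#'
#' For each task, closes every exchange reaction, opens uptake for the
#' task's allowed inputs, and maximizes production of each required output;
#' the task passes iff every output can reach its minimum rate. Model
#' bounds are never altered in place (a modified copy is solved).
#'
#' @param model a \linkS4class{MetabolicModel} (solvable: with all
#'   exchanges open it must admit a steady-state solution).
#' @param tasks list of [metabolicTask()] objects.
#' @return data.frame with columns \code{task}, \code{passed} and
#'   \code{detail}.
#' @export
checkTasks <- function(model, tasks) {
  if (inherits(tasks, "MetabolicTask")) tasks <- list(tasks)
  exch <- model@reactions$id[model@reactions$kind == "exchange"]
  exch_met <- vapply(exch, function(r) {
    names(which(model@stoichiometry[, r] != 0))
  }, character(1))
  ## diagnostic: base model must be solvable with everything open
  base <- fba(model, model@objectiveId)
  if (base$status != "optimal")
    stop("base model is not solvable (status: ", base$status, ")")
  res <- lapply(tasks, function(task) {
    refs <- c(names(task$inputs), names(task$outputs))
    missing <- setdiff(refs, model@metabolites$id)
    if (length(missing))
      stop("task '", task$id, "' references metabolites absent from the ",
           "model: ", paste(missing, collapse = ", "))
    no_ex <- setdiff(refs, exch_met)
    if (length(no_ex))
      stop("task '", task$id, "' references metabolites without exchange ",
           "reactions: ", paste(no_ex, collapse = ", "))
    m <- model
    idx <- match(exch, m@reactions$id)
    m@reactions$lower_bound[idx] <- 0
    m@reactions$upper_bound[idx] <- 0
    for (metid in names(task$inputs)) {
      r <- exch[match(metid, exch_met)]
      m@reactions$lower_bound[match(r, m@reactions$id)] <- -abs(task$inputs[[metid]])
    }
    out_rxn <- exch[match(names(task$outputs), exch_met)]
    m@reactions$upper_bound[match(out_rxn, m@reactions$id)] <- .FLUX_CAP
    ok <- logical(length(out_rxn))
    got <- numeric(length(out_rxn))
    for (t in seq_along(out_rxn)) {
      sol <- fba(m, out_rxn[t], sense = "max")
      got[t] <- if (sol$status == "optimal") sol$objective else NA_real_
      ok[t] <- sol$status == "optimal" &&
        sol$objective >= task$outputs[[t]] - 1e-6
    }
    data.frame(task = task$id, passed = all(ok),
               detail = paste(sprintf("%s=%.4g", names(task$outputs), got),
                              collapse = "; "))
  })
  do.call(rbind, res)
}

#' Read task definitions from YAML
#'
#' Expects a list of entries with fields \code{id}, \code{inputs},
#' \code{outputs} (metabolite id to rate maps) and optional
#' \code{description}.
#'
#' @param path YAML file path.
#' @return list of [metabolicTask()] objects.
#' @export
readTasks <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(x)
    metabolicTask(x$id, unlist(x$inputs), unlist(x$outputs),
                  description = if (is.null(x$description)) "" else x$description))
}
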