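## Default cap replacing infinite bounds before the LP (HMR-style).
.FLUX_CAP <- 1000

.lpParts <- function(model) {
  Tm <- as(model@stoichiometry, "TsparseMatrix")
  lb <- pmax(model@reactions$lower_bound, -.FLUX_CAP)
  ub <- pmin(model@reactions$upper_bound, .FLUX_CAP)
  list(i = Tm@i + 1L, j = Tm@j + 1L, x = Tm@x,
       m = nrow(Tm), n = ncol(Tm), lb = lb, ub = ub)
}

.LP_STATUS <- c("optimal", "infeasible", "unbounded", "failed")

#' Flux balance analysis
#'
#' Solves the steady-state LP \eqn{\max c'v} subject to \eqn{Sv = 0},
#' \eqn{lb \le v \le ub} with the GLPK simplex solver (dual simplex with
#' primal fallback). Infinite bounds are capped at \eqn{\pm 1000}
#' mmol/gDW/h before solving. An infeasible model yields a typed status,
#' not an error, so cohort runs can continue.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param objective reaction id to optimize (default the model's designated
#'   objective).
#' @param sense \code{"max"} or \code{"min"}.
#' @return list with \code{status} (\code{"optimal"}, \code{"infeasible"},
#'   \code{"unbounded"}, \code{"failed"}), \code{objective} (optimal value)
#'   and \code{fluxes} (one optimal flux vector, named by reaction).
#' @export
fba <- function(model, objective = objectiveId(model),
                sense = c("max", "min")) {
  sense <- match.arg(sense)
  p <- .lpParts(model)
  jobj <- match(objective, model@reactions$id)
  if (is.na(jobj)) stop("unknown objective reaction: ", objective)
  obj <- numeric(p$n)
  obj[jobj] <- 1
  ans <- .Call("fc_glpk_fba", p$i, p$j, p$x, p$m, p$n, p$lb, p$ub, obj,
               sense == "max", PACKAGE = "FluxCohort")
  flux <- ans[[3]]
  names(flux) <- model@reactions$id
  list(status = .LP_STATUS[ans[[1]] + 1L], objective = ans[[2]],
       fluxes = flux)
}

#' FVA configuration
#'
#' @param gamma fraction of the model's own objective optimum the objective
#'   flux must retain during FVA, in (0, 1]; default 1 fixes the objective
#'   at its optimum.
#' @param beta biomass viability floor: biomass flux must reach at least
#'   \code{beta * biomassRef}; default 0.8.
#' @param biomassRef reference biomass rate, normally the biomass optimum
#'   of the healthy group-average model so that every individual is held to
#'   the same viability floor; \code{NULL} uses the model's own optimum.
#' @param tol numeric tolerance for feasibility comparisons.
#' @return list of class \code{FvaConfig}.
#' @export
fvaConfig <- function(gamma = 1.0, beta = 0.8, biomassRef = NULL,
                      tol = 1e-6) {
  stopifnot(gamma > 0, gamma <= 1, beta > 0, beta <= 1)
  structure(list(gamma = gamma, beta = beta, biomassRef = biomassRef,
                 tol = tol), class = "FvaConfig")
}

#' Flux variability analysis
#'
#' Constrains biomass to \code{beta * biomassRef} and the objective to
#' \code{gamma} times its own optimum, then minimizes and maximizes every
#' requested reaction's flux, reusing one warm-started GLPK problem.
#'
#' @inheritParams fba
#' @param config an [fvaConfig()].
#' @param reactions reaction ids to analyse (default all).
#' @return data.frame with columns \code{reaction}, \code{min}, \code{max},
#'   \code{status}. If the objective LP or the biomass floor is infeasible
#'   the frame carries attribute \code{feasible = FALSE} and every row
#'   status reflects it.
#' @export
fva <- function(model, config = fvaConfig(), reactions = NULL) {
  rxn <- model@reactions
  if (is.null(reactions)) reactions <- rxn$id
  cols <- match(reactions, rxn$id)
  if (anyNA(cols)) stop("unknown reactions: ",
                        paste(reactions[is.na(cols)], collapse = ", "))
  p <- .lpParts(model)
  jobj <- match(model@objectiveId, rxn$id)
  jbio <- match(model@biomassId, rxn$id)

  ## biomass viability floor first ...
  ref <- config$biomassRef
  if (is.null(ref)) {
    objb <- numeric(p$n); objb[jbio] <- 1
    bopt <- .Call("fc_glpk_fba", p$i, p$j, p$x, p$m, p$n, p$lb, p$ub, objb,
                  TRUE, PACKAGE = "FluxCohort")
    if (bopt[[1]] != 0L) stop("biomass optimum could not be computed")
    ref <- bopt[[2]]
  }
  lb <- p$lb; ub <- p$ub
  lb[jbio] <- max(lb[jbio], config$beta * ref)
  infeasibleOut <- function(status) {
    out <- data.frame(reaction = reactions, min = NA_real_, max = NA_real_,
                      status = status)
    attr(out, "feasible") <- FALSE
    out
  }
  if (lb[jbio] > ub[jbio] + config$tol) return(infeasibleOut("infeasible"))

  ## ... then fix the objective at gamma times its floored optimum
  obj <- numeric(p$n); obj[jobj] <- 1
  opt <- .Call("fc_glpk_fba", p$i, p$j, p$x, p$m, p$n, lb, ub, obj,
               TRUE, PACKAGE = "FluxCohort")
  if (opt[[1]] != 0L) return(infeasibleOut(.LP_STATUS[opt[[1]] + 1L]))
  zopt <- opt[[2]]
  ofloor <- if (zopt >= 0) config$gamma * zopt else zopt
  lb[jobj] <- max(lb[jobj], min(ofloor, ub[jobj]))
  ans <- .Call("fc_glpk_fva", p$i, p$j, p$x, p$m, p$n, lb, ub,
               as.integer(cols), PACKAGE = "FluxCohort")
  status <- .LP_STATUS[ans[[1]] + 1L]
  vmin <- pmin(pmax(ans[[2]], lb[cols]), ub[cols])
  vmax <- pmin(pmax(ans[[3]], lb[cols]), ub[cols])
  out <- data.frame(reaction = reactions, min = vmin, max = vmax,
                    status = status)
  attr(out, "feasible") <- !any(status == "infeasible")
  if (any(status == "infeasible")) {
    out$min <- NA_real_; out$max <- NA_real_
    out$status <- "infeasible"
    attr(out, "feasible") <- FALSE
  }
  out
}

#' FVA across a cohort of personalized models
#'
#' Runs [fva()] on every personalized model and stacks the results into a
#' tidy table. Individuals whose biomass floor cannot be met are recorded
#' as infeasible, excluded from the table, and reported via a warning and
#' the \code{infeasible} attribute; a group with no feasible individuals
#' aborts the run.
#'
#' @param models named list of \linkS4class{MetabolicModel}s, one per
#'   sample.
#' @param groups named character/factor mapping sample ids to groups.
#' @param config an [fvaConfig()]; supply a shared \code{biomassRef} so all
#'   individuals face the same viability floor.
#' @param reactions reaction ids to analyse (default all).
#' @return data.frame with columns \code{sample}, \code{group},
#'   \code{reaction}, \code{min}, \code{max}, \code{status}; attribute
#'   \code{infeasible} lists excluded samples.
#' @export
cohortFva <- function(models, groups, config = fvaConfig(),
                      reactions = NULL) {
  stopifnot(length(models) >= 1, !is.null(names(models)))
  groups <- as.character(groups[names(models)])
  res <- vector("list", length(models))
  infeasible <- character()
  for (k in seq_along(models)) {
    r <- fva(models[[k]], config = config, reactions = reactions)
    if (!isTRUE(attr(r, "feasible"))) {
      infeasible <- c(infeasible, names(models)[k])
      next
    }
    r$sample <- names(models)[k]
    r$group <- groups[k]
    res[[k]] <- r
  }
  out <- do.call(rbind, res)
  if (length(infeasible))
    warning(length(infeasible), " infeasible individual(s) excluded: ",
            paste(infeasible, collapse = ", "))
  kept <- unique(out$group)
  lost <- setdiff(unique(groups), kept)
  if (is.null(out) || length(lost))
    stop("no feasible individuals left in group(s): ",
         paste(lost, collapse = ", "))
  out <- out[, c("sample", "group", "reaction", "min", "max", "status")]
  rownames(out) <- NULL
  attr(out, "infeasible") <- infeasible
  out
}

#' Write / read a cohort flux-range table as TSV
#' @param ranges data.frame from [cohortFva()].
#' @param path file path.
#' @export
writeFluxRanges <- function(ranges, path) {
  utils::write.table(ranges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeFluxRanges
#' @export
readFluxRanges <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
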