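#' Welch two-sample t-test with degenerate-case conventions
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom,
#' two-sided. FVA fluxes are often constant across individuals (pinched
#' ranges), so the degenerate cases are defined rather than erroring: zero
#' variance in both groups with equal means gives \code{t = 0, p = 1};
#' zero variance with different means gives \code{p = 0} (an
#' infinitely-confident sentinel).
#'
#' @param x,y numeric vectors (each of length >= 2).
#' @return list with \code{t}, \code{df}, \code{p}.
#' @export
welchT <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    stop("each group needs at least 2 values")
  vx <- stats::var(x); vy <- stats::var(y)
  degenerate <- function() {
    if (isTRUE(all.equal(mean(x), mean(y)))) list(t = 0, df = NA_real_, p = 1)
    else list(t = sign(mean(x) - mean(y)) * Inf, df = NA_real_, p = 0)
  }
  if (vx == 0 && vy == 0) return(degenerate())
  ht <- tryCatch(stats::t.test(x, y, var.equal = FALSE),
                 error = function(e) NULL)  # "data are essentially constant"
  if (is.null(ht)) return(degenerate())
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up adjusted values \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} m / j},
#' capped at 1, returned in the input order.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted values, \code{q >= p} elementwise.
#' @export
bhAdjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Call perturbed reactions from cohort flux ranges
#'
#' For every reaction, Welch-tests the per-individual minimum fluxes and
#' the maximum fluxes between the two groups; BH adjustment is applied
#' within the min family and the max family separately, and a reaction is
#' called perturbed when either adjusted value falls below \code{alpha}
#' (union rule). Reactions missing in some individuals (infeasible
#' samples) are tested on the available ones when both groups retain at
#' least 2, otherwise skipped with \code{NA} statistics.
#'
#' @param ranges tidy data.frame from [cohortFva()] (columns sample,
#'   group, reaction, min, max).
#' @param alpha FDR threshold, default 0.1.
#' @return data.frame with one row per reaction: \code{t_min, p_min,
#'   q_min, t_max, p_max, q_max, perturbed}.
#' @export
callPerturbed <- function(ranges, alpha = 0.1) {
  grps <- unique(ranges$group)
  if (length(grps) != 2)
    stop("exactly two groups are required, got: ",
         paste(grps, collapse = ", "))
  rxns <- unique(ranges$reaction)
  res <- data.frame(reaction = rxns,
                    t_min = NA_real_, p_min = NA_real_,
                    t_max = NA_real_, p_max = NA_real_)
  for (k in seq_along(rxns)) {
    sub <- ranges[ranges$reaction == rxns[k], ]
    a <- sub[sub$group == grps[1], ]
    b <- sub[sub$group == grps[2], ]
    if (nrow(a) < 2 || nrow(b) < 2) next
    tmin <- welchT(a$min, b$min)
    tmax <- welchT(a$max, b$max)
    res$t_min[k] <- tmin$t; res$p_min[k] <- tmin$p
    res$t_max[k] <- tmax$t; res$p_max[k] <- tmax$p
  }
  ok <- !is.na(res$p_min)
  res$q_min <- res$q_max <- NA_real_
  res$q_min[ok] <- bhAdjust(res$p_min[ok])
  res$q_max[ok] <- bhAdjust(res$p_max[ok])
  res$perturbed <- !is.na(res$q_min) &
    (res$q_min < alpha | res$q_max < alpha)
  res
}

#' Write a differential-flux table as TSV
#' @param diff data.frame from [callPerturbed()].
#' @param model optional \linkS4class{MetabolicModel} to annotate
#'   subsystems.
#' @param path output path.
#' @export
writeDiffFlux <- function(diff, path, model = NULL) {
  if (!is.null(model))
    diff$subsystem <- model@reactions$subsystem[
      match(diff$reaction, model@reactions$id)]
  utils::write.table(diff, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
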