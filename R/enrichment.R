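#' Upper-tail hypergeometric probability
#'
#' Exact one-sided enrichment p-value \eqn{P(X \ge k)} for drawing \code{n}
#' reactions from a universe of \code{N} of which \code{K} belong to the
#' set.
#'
#' @param N universe size.
#' @param K set size within the universe.
#' @param n number of drawn (perturbed) elements.
#' @param k overlap between set and drawn.
#' @return numeric(1) in (0, 1].
#' @export
hypergeomP <- function(N, K, n, k) {
  if (K > N || n > N || k > min(K, n) || any(c(N, K, n, k) < 0))
    stop("inconsistent hypergeometric counts (need k <= min(K, n), ",
         "K <= N, n <= N)")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Build reaction sets from model annotations
#'
#' \describe{
#'   \item{pathway}{one set per subsystem label.}
#'   \item{metabolite}{one set per metabolite (compartmentalized id or
#'     collapsed base id), containing every reaction in which it
#'     participates as substrate or product.}
#'   \item{compartment}{one set per compartment code (non-transport
#'     reactions only, each of which lies in exactly one compartment).}
#' }
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param kind set kind.
#' @param collapse for metabolite sets, collapse compartmentalized ids to
#'   base ids (the "unique" metabolite form), default TRUE.
#' @return named list of reaction-id vectors.
#' @export
reactionSets <- function(model, kind = c("pathway", "metabolite",
                                         "compartment"),
                         collapse = TRUE) {
  kind <- match.arg(kind)
  rxn <- model@reactions
  S <- model@stoichiometry
  if (kind == "pathway") {
    lab <- rxn$subsystem
    keep <- nzchar(lab)
    return(split(rxn$id[keep], lab[keep]))
  }
  if (kind == "metabolite") {
    key <- if (collapse) model@metabolites$base_id else model@metabolites$id
    Tm <- as(S, "TsparseMatrix")
    df <- unique(data.frame(met = key[Tm@i + 1L], rxn = rxn$id[Tm@j + 1L]))
    return(split(df$rxn, df$met))
  }
  keep <- rxn$kind != "transport"
  comp <- vapply(which(keep), function(j) {
    model@metabolites$compartment[which(S[, j] != 0)][1]
  }, character(1))
  split(rxn$id[keep], comp)
}

#' Hypergeometric enrichment of perturbed reactions
#'
#' For each reaction set, computes the overlap with the perturbed
#' reactions, the enrichment score (percentage of the set's reactions that
#' are perturbed, \code{100 k / K}), a one-sided hypergeometric p-value
#' against the universe, and BH-adjusted q-values across the tested sets.
#' Results are sorted by q, then by decreasing score.
#'
#' @param perturbed character vector of perturbed reaction ids (subset of
#'   \code{universe}).
#' @param sets named list of reaction-id vectors (see [reactionSets()]).
#' @param universe character vector of all testable reaction ids.
#' @return data.frame with columns \code{set, N, K, n, k, score, p, q}.
#' @export
enrich <- function(perturbed, sets, universe) {
  if (length(setdiff(perturbed, universe)))
    stop("perturbed reactions outside the universe")
  if (!length(perturbed)) {
    warning("empty perturbed set; nothing to enrich")
    return(data.frame(set = character(), N = integer(), K = integer(),
                      n = integer(), k = integer(), score = numeric(),
                      p = numeric(), q = numeric()))
  }
  N <- length(universe)
  n <- length(perturbed)
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(sets[[nm]], universe)
    K <- length(members)
    if (!K) return(NULL)
    k <- length(intersect(members, perturbed))
    data.frame(set = nm, N = N, K = K, n = n, k = k,
               score = 100 * k / K,
               p = hypergeomP(N, K, n, k))
  })
  out <- do.call(rbind, rows)
  out$q <- bhAdjust(out$p)
  out <- out[order(out$q, -out$score, out$set), ]
  rownames(out) <- NULL
  out
}

#' Perturbed reactions by subcellular compartment
#'
#' Summarizes where in the cell the perturbation falls: the raw count of
#' perturbed reactions per compartment, and the adjusted percentage (raw
#' count divided by the number of that compartment's reactions). Transport
#' reactions, which span compartments, are excluded from both numerator
#' and denominator; every remaining reaction lies in exactly one
#' compartment (a multi-compartment reaction not flagged as transport is a
#' consistency error).
#'
#' @param perturbed character vector of perturbed reaction ids.
#' @param model a \linkS4class{MetabolicModel}.
#' @return data.frame with columns \code{compartment, total, perturbed,
#'   percentage}, sorted by decreasing percentage.
#' @export
compartmentSummary <- function(perturbed, model) {
  rxn <- model@reactions
  S <- model@stoichiometry
  keep <- which(rxn$kind != "transport")
  comp <- vapply(keep, function(j) {
    cs <- unique(model@metabolites$compartment[which(S[, j] != 0)])
    if (length(cs) > 1)
      stop("reaction '", rxn$id[j], "' spans several compartments but is ",
           "not flagged as transport")
    cs
  }, character(1))
  total <- table(comp)
  pert <- table(factor(comp[rxn$id[keep] %in% perturbed],
                       levels = names(total)))
  out <- data.frame(compartment = names(total),
                    total = as.integer(total),
                    perturbed = as.integer(pert))
  out$percentage <- 100 * out$perturbed / out$total
  out <- out[order(-out$percentage, out$compartment), ]
  rownames(out) <- NULL
  out
}
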