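## Hand-built toy models and independent oracles shared across tests.

## 3-reaction chain: uptake of a (<= 10) -> conversion -> export of b.
## biomass/objective both designated on the export reaction; tests that
## do not exercise the viability floor pass a tiny beta.
chainModel <- function(uptake = 10) {
  metabolicModel(
    metabolites = data.frame(id = c("a_s", "b_s")),
    reactions = data.frame(
      id = c("EX_a", "CONV", "EX_b"),
      lower_bound = c(-uptake, 0, 0),
      upper_bound = c(0, 1000, 1000)),
    stoich = list(EX_a = c(a_s = -1),
                  CONV = c(a_s = -1, b_s = 1),
                  EX_b = c(b_s = -1)),
    compartments = c(c = "cytosol", s = "extracellular"),
    biomassId = "EX_b", objectiveId = "EX_b")
}

## glucose -> ATP with branches yielding 2 vs 3 ATP per glucose
branchModel <- function() {
  metabolicModel(
    metabolites = data.frame(id = c("glc_s", "atp_s")),
    reactions = data.frame(
      id = c("EX_glc", "LOWY", "HIGHY", "EX_atp"),
      lower_bound = c(-10, 0, 0, 0),
      upper_bound = c(0, 1000, 1000, 1000)),
    stoich = list(EX_glc = c(glc_s = -1),
                  LOWY = c(glc_s = -1, atp_s = 2),
                  HIGHY = c(glc_s = -1, atp_s = 3),
                  EX_atp = c(atp_s = -1)),
    compartments = c(c = "cytosol", s = "extracellular"),
    biomassId = "EX_atp", objectiveId = "EX_atp")
}

## chain with a reversible middle reaction, for oracle comparisons
revModel <- function() {
  metabolicModel(
    metabolites = data.frame(id = c("a_s", "b_s")),
    reactions = data.frame(
      id = c("EX_a", "REV", "EX_b"),
      lower_bound = c(-5, -8, -4),
      upper_bound = c(5, 8, 6)),
    stoich = list(EX_a = c(a_s = -1),
                  REV = c(a_s = -1, b_s = 1),
                  EX_b = c(b_s = -1)),
    compartments = c(c = "cytosol", s = "extracellular"),
    biomassId = "REV", objectiveId = "REV")
}

## diamond: two routes of different capacity plus a side branch
diamondModel <- function() {
  metabolicModel(
    metabolites = data.frame(id = c("a_s", "b_s", "c_s", "d_s")),
    reactions = data.frame(
      id = c("EX_a", "AB", "AC", "BD", "CD", "EX_d"),
      lower_bound = c(-10, 0, 0, 0, 0, 0),
      upper_bound = c(0, 4, 7, 1000, 1000, 1000)),
    stoich = list(EX_a = c(a_s = -1),
                  AB = c(a_s = -1, b_s = 1),
                  AC = c(a_s = -1, c_s = 1),
                  BD = c(b_s = -1, d_s = 1),
                  CD = c(c_s = -1, d_s = 1),
                  EX_d = c(d_s = -1)),
    compartments = c(c = "cytosol", s = "extracellular"),
    biomassId = "EX_d", objectiveId = "EX_d")
}

## Independent FVA oracle: enumerate the vertices of
## {v : S v = 0, lb <= v <= ub} (bounded polytope) by fixing every
## possible set of n - rank(S) coordinates at a bound and solving the
## remaining square system; per-reaction min/max over feasible vertices.
oracleFva <- function(S, lb, ub, tol = 1e-7) {
  S <- as.matrix(S)
  n <- ncol(S)
  r <- qr(S)$rank
  d <- n - r
  verts <- list()
  if (d == 0) {
    v <- rep(0, n)
    if (all(v >= lb - tol & v <= ub + tol)) verts <- list(v)
  } else {
    for (F in utils::combn(n, d, simplify = FALSE)) {
      rest <- setdiff(seq_len(n), F)
      A <- S[, rest, drop = FALSE]
      if (qr(A)$rank < length(rest)) next
      corners <- expand.grid(rep(list(c(FALSE, TRUE)), d))
      for (ci in seq_len(nrow(corners))) {
        vF <- ifelse(unlist(corners[ci, ]), ub[F], lb[F])
        rhs <- -S[, F, drop = FALSE] %*% vF
        vR <- tryCatch(qr.solve(A, rhs), error = function(e) NULL)
        if (is.null(vR)) next
        if (max(abs(A %*% vR - rhs)) > tol) next
        v <- numeric(n)
        v[F] <- vF
        v[rest] <- vR
        if (all(v >= lb - tol & v <= ub + tol))
          verts[[length(verts) + 1L]] <- v
      }
    }
  }
  if (!length(verts)) return(NULL)   # infeasible
  V <- do.call(rbind, verts)
  list(min = apply(V, 2, min), max = apply(V, 2, max))
}

## oracle applied with the same floors fva() imposes (biomass floor from
## the oracle's own vertex optimum, then the objective fixed likewise)
oracleFvaFloored <- function(model, gamma = 1, beta = 1e-9) {
  S <- as.matrix(stoichiometry(model))
  rxn <- reactions(model)
  lb <- pmax(rxn$lower_bound, -1000)
  ub <- pmin(rxn$upper_bound, 1000)
  jb <- match(biomassId(model), rxn$id)
  jo <- match(objectiveId(model), rxn$id)
  base <- oracleFva(S, lb, ub)
  if (is.null(base)) return(NULL)
  lb[jb] <- max(lb[jb], beta * base$max[jb])
  step1 <- oracleFva(S, lb, ub)
  if (is.null(step1)) return(NULL)
  zopt <- step1$max[jo]
  lb[jo] <- max(lb[jo], if (zopt >= 0) gamma * zopt else zopt)
  oracleFva(S, lb, ub)
}

## brute-force connected components by breadth-first search
bfsComponents <- function(nodes, edges) {
  adj <- lapply(stats::setNames(vector("list", length(nodes)), nodes),
                function(x) character())
  for (k in seq_len(nrow(edges))) {
    adj[[edges$from[k]]] <- c(adj[[edges$from[k]]], edges$to[k])
    adj[[edges$to[k]]] <- c(adj[[edges$to[k]]], edges$from[k])
  }
  seen <- character()
  comps <- list()
  for (start in nodes) {
    if (start %in% seen) next
    queue <- start
    comp <- character()
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      if (v %in% comp) next
      comp <- c(comp, v)
      queue <- c(queue, setdiff(adj[[v]], comp))
    }
    seen <- c(seen, comp)
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps[order(-lengths(comps),
              vapply(comps, `[`, character(1), 1L))]
}

## random GPR tree generator for round-trip properties; gene ids include
## the letter "s" on purpose (regression guard for tokenizer handling)
randomGprTree <- function(depth = 3, genes = c("gsk1", "hsa2", "g3",
                                               "ins4", "g5s", "g6")) {
  if (depth == 0 || stats::runif(1) < 0.4)
    return(sample(genes, 1))
  op <- sample(c("and", "or"), 1)
  nargs <- sample(2:3, 1)
  args <- lapply(seq_len(nargs), function(i) randomGprTree(depth - 1, genes))
  ## flatten the way the parser does
  flat <- list()
  for (a in args) {
    if (is.list(a) && identical(a$op, op)) flat <- c(flat, a$args)
    else flat <- c(flat, list(a))
  }
  if (length(flat) == 1L) flat[[1L]] else list(op = op, args = flat)
}
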