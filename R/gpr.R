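#' Parse a gene-protein-reaction (GPR) boolean rule
#'
#' GPR rules link genes to the reaction they catalyse: \code{and} between
#' genes denotes an enzyme complex (all subunits required), \code{or}
#' denotes isozymes (any suffices). The grammar accepts gene identifiers,
#' parentheses and case-insensitive \code{and}/\code{or}; \code{and} binds
#' tighter than \code{or}. An empty or blank rule yields the empty tree
#' (\code{NULL}), meaning the reaction is not gene-associated.
#'
#' Trees are plain lists: a leaf is a gene id (character), an internal node
#' is \code{list(op = "and"|"or", args = list(...))}, flattened so that no
#' node has a child with the same operator.
#'
#' @param rule character(1) rule string.
#' @return a GPR tree, or \code{NULL} for a blank rule.
#' @examples
#' parseGpr("(g1 and g2) or g3")
#' @export
parseGpr <- function(rule) {
  if (is.null(rule) || length(rule) == 0L || is.na(rule) ||
      !nzchar(trimws(rule))) return(NULL)
  toks <- .gprTokenize(rule)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  tree <- .gprParseOr(st, rule)
  if (st$pos <= length(st$toks$type))
    stop(sprintf("GPR parse error in '%s': unexpected token '%s' at position %d",
                 rule, st$toks$text[st$pos], st$toks$at[st$pos]))
  tree
}

.gprTokenize <- function(rule) {
  chars <- strsplit(rule, "", fixed = TRUE)[[1]]
  space <- c(" ", "\t", "\n", "\r")
  stopchar <- c(space, "(", ")")
  type <- character(); text <- character(); at <- integer()
  i <- 1L; n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% space) { i <- i + 1L; next }
    if (ch == "(" || ch == ")") {
      type <- c(type, ch); text <- c(text, ch); at <- c(at, i)
      i <- i + 1L
      next
    }
    j <- i
    while (j <= n && !chars[j] %in% stopchar) j <- j + 1L
    word <- paste(chars[i:(j - 1L)], collapse = "")
    lw <- tolower(word)
    type <- c(type, if (lw %in% c("and", "or")) lw else "gene")
    text <- c(text, word)
    at <- c(at, i)
    i <- j
  }
  list(type = type, text = text, at = at)
}

.gprPeek <- function(st) {
  if (st$pos > length(st$toks$type)) "" else st$toks$type[st$pos]
}

.gprParseOr <- function(st, rule) {
  args <- list(.gprParseAnd(st, rule))
  while (.gprPeek(st) == "or") {
    st$pos <- st$pos + 1L
    args <- c(args, list(.gprParseAnd(st, rule)))
  }
  .gprNode("or", args)
}

.gprParseAnd <- function(st, rule) {
  args <- list(.gprParseAtom(st, rule))
  while (.gprPeek(st) == "and") {
    st$pos <- st$pos + 1L
    args <- c(args, list(.gprParseAtom(st, rule)))
  }
  .gprNode("and", args)
}

.gprParseAtom <- function(st, rule) {
  tt <- .gprPeek(st)
  if (tt == "gene") {
    g <- st$toks$text[st$pos]
    st$pos <- st$pos + 1L
    return(g)
  }
  if (tt == "(") {
    open_at <- st$toks$at[st$pos]
    st$pos <- st$pos + 1L
    inner <- .gprParseOr(st, rule)
    if (.gprPeek(st) != ")")
      stop(sprintf("GPR parse error in '%s': unbalanced '(' at position %d",
                   rule, open_at))
    st$pos <- st$pos + 1L
    return(inner)
  }
  at <- if (st$pos <= length(st$toks$at)) st$toks$at[st$pos] else nchar(rule) + 1L
  stop(sprintf("GPR parse error in '%s': dangling operator or missing gene at position %d",
               rule, at))
}

## flatten nested same-operator nodes; collapse single-child nodes
.gprNode <- function(op, args) {
  if (length(args) == 1L) return(args[[1L]])
  flat <- list()
  for (a in args) {
    if (is.list(a) && identical(a$op, op)) flat <- c(flat, a$args)
    else flat <- c(flat, list(a))
  }
  list(op = op, args = flat)
}

#' Serialize a GPR tree back to a normalized rule string
#'
#' Inverse of [parseGpr()]: \code{parseGpr(gprToString(t))} reproduces
#' \code{t}. \code{or}-children of an \code{and} node are parenthesized;
#' \code{and}-children of an \code{or} node need no parentheses because
#' \code{and} binds tighter.
#'
#' @param tree a GPR tree (or \code{NULL}).
#' @return character(1); \code{""} for the empty tree.
#' @export
gprToString <- function(tree) {
  if (is.null(tree)) return("")
  if (is.character(tree)) return(tree)
  sep <- paste0(" ", tree$op, " ")
  parts <- vapply(tree$args, function(a) {
    s <- gprToString(a)
    if (is.list(a) && tree$op == "and" && a$op == "or") paste0("(", s, ")")
    else s
  }, character(1))
  paste(parts, collapse = sep)
}

#' Genes referenced by a GPR tree
#' @param tree a GPR tree.
#' @return character vector of unique gene ids.
#' @export
gprGenes <- function(tree) {
  if (is.null(tree)) return(character())
  if (is.character(tree)) return(tree)
  unique(unlist(lapply(tree$args, gprGenes), use.names = FALSE))
}

#' Evaluate a GPR tree against expression values
#'
#' Recursive evaluation with the E-Flux convention: an \code{and} node takes
#' the minimum of its children (a complex is limited by its scarcest
#' subunit), an \code{or} node sums them (isozymes add capacity; set
#' \code{orMode = "max"} for the max alternative). Genes absent from
#' \code{expr} are dropped from their parent node; a node whose children are
#' all missing evaluates as missing (\code{NA}); the empty tree evaluates as
#' \code{NA}, meaning "unconstrained".
#'
#' @param tree a GPR tree from [parseGpr()].
#' @param expr named numeric vector of non-negative expression values
#'   (log2-scale normalized values are non-negative by construction).
#' @param orMode \code{"sum"} (default) or \code{"max"}.
#' @return numeric(1) activity, or \code{NA_real_} if unconstrained/missing.
#' @examples
#' gprActivity(parseGpr("(g1 and g2) or g3"), c(g1 = 2, g2 = 4, g3 = 5))  # 7
#' @export
gprActivity <- function(tree, expr, orMode = c("sum", "max")) {
  orMode <- match.arg(orMode)
  if (any(expr < 0, na.rm = TRUE))
    stop("expression values must be non-negative")
  .gprEval(tree, expr, orMode)
}

.gprEval <- function(tree, expr, orMode) {
  if (is.null(tree)) return(NA_real_)
  if (is.character(tree)) {
    v <- expr[tree]
    return(if (length(v) == 0L || is.na(v)) NA_real_ else unname(v))
  }
  vals <- vapply(tree$args, .gprEval, numeric(1), expr = expr, orMode = orMode)
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) return(NA_real_)
  if (tree$op == "and") min(vals)
  else if (orMode == "sum") sum(vals) else max(vals)
}
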