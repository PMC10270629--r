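#' Default currency metabolites
#'
#' Ubiquitous cofactors excluded from metabolite-network edges to avoid
#' spurious connectivity (base ids, compartment-independent).
#' @return character vector.
#' @export
defaultCurrency <- function() {
  c("h2o", "h", "atp", "adp", "amp", "pi", "ppi",
    "nad", "nadh", "nadp", "nadph", "fad", "fadh2",
    "coa", "co2", "o2")
}

#' Build the metabolite-centric network of perturbed reactions
#'
#' Nodes are base (compartment-collapsed) metabolite ids; for every
#' perturbed reaction an edge links each substrate to each product.
#' Transport and exchange reactions are excluded (they connect the same
#' chemical species across membranes), as are currency metabolites. Edges
#' are undirected; the node set is the endpoints of the surviving edges.
#'
#' @param perturbed character vector of perturbed reaction ids (non-empty).
#' @param model a \linkS4class{MetabolicModel}.
#' @param currency character vector of currency base ids to drop (default
#'   [defaultCurrency()]).
#' @return a \linkS4class{MetaboliteNetwork} (possibly empty, with a
#'   warning).
#' @export
buildNetwork <- function(perturbed, model, currency = defaultCurrency()) {
  if (!length(perturbed)) stop("perturbed set is empty")
  rxn <- model@reactions
  S <- model@stoichiometry
  use <- rxn$id[rxn$id %in% perturbed &
                !rxn$kind %in% c("transport", "exchange")]
  edges <- list()
  for (r in sort(use)) {
    s <- S[, r]
    subs <- unique(model@metabolites$base_id[which(s < 0)])
    prods <- unique(model@metabolites$base_id[which(s > 0)])
    subs <- setdiff(subs, currency)
    prods <- setdiff(prods, currency)
    if (!length(subs) || !length(prods)) next
    pairs <- expand.grid(from = subs, to = prods, stringsAsFactors = FALSE)
    pairs <- pairs[pairs$from != pairs$to, , drop = FALSE]
    if (nrow(pairs)) {
      pairs$reaction <- r
      edges[[length(edges) + 1L]] <- pairs
    }
  }
  if (!length(edges)) {
    warning("no edges survive currency/transport filtering")
    return(new("MetaboliteNetwork",
               nodes = data.frame(id = character(), q = numeric()),
               edges = data.frame(from = character(), to = character(),
                                  reactions = character())))
  }
  e <- do.call(rbind, edges)
  key <- ifelse(e$from < e$to, paste(e$from, e$to, sep = "\r"),
                paste(e$to, e$from, sep = "\r"))
  agg <- stats::aggregate(e$reaction, by = list(key = key),
                          FUN = function(r)
                            paste(sort(unique(r)), collapse = ","))
  parts <- strsplit(agg$key, "\r", fixed = TRUE)
  edges <- data.frame(from = vapply(parts, `[`, character(1), 1L),
                      to = vapply(parts, `[`, character(1), 2L),
                      reactions = agg$x, stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to), ]
  rownames(edges) <- NULL
  nodes <- data.frame(id = sort(unique(c(edges$from, edges$to))),
                      q = NA_real_, stringsAsFactors = FALSE)
  new("MetaboliteNetwork", nodes = nodes, edges = edges)
}

#' Filter the network to significantly enriched metabolites
#'
#' Removes nodes whose metabolite-enrichment adjusted p-value is missing
#' or above \code{qThreshold}, together with their incident edges.
#' Components can only split, never merge.
#'
#' @param net a \linkS4class{MetaboliteNetwork}.
#' @param enrichment data.frame from [enrich()] over metabolite sets built
#'   with \code{collapse = TRUE} (column \code{set} = base id, column
#'   \code{q}).
#' @param qThreshold keep nodes with \code{q <= qThreshold} (default 0.05).
#' @return the filtered network, with \code{q} attached to the nodes.
#' @export
filterSignificant <- function(net, enrichment, qThreshold = 0.05) {
  q <- stats::setNames(enrichment$q, enrichment$set)[net@nodes$id]
  keep <- !is.na(q) & q <= qThreshold
  nodes <- net@nodes[keep, , drop = FALSE]
  nodes$q <- q[keep]
  edges <- net@edges[net@edges$from %in% nodes$id &
                     net@edges$to %in% nodes$id, , drop = FALSE]
  rownames(nodes) <- rownames(edges) <- NULL
  new("MetaboliteNetwork", nodes = nodes, edges = edges)
}

#' Connected components of the metabolite network
#'
#' @param net a \linkS4class{MetaboliteNetwork}.
#' @return list of character vectors (sorted node ids), ordered by
#'   decreasing size with ties broken by the lexicographically smallest
#'   member.
#' @export
networkComponents <- function(net) {
  if (!nrow(net@nodes)) return(list())
  g <- igraph::graph_from_data_frame(net@edges[, c("from", "to")],
                                     directed = FALSE,
                                     vertices = net@nodes$id)
  comp <- igraph::components(g)
  sets <- split(names(comp$membership), comp$membership)
  sets <- lapply(sets, function(s) sort(unname(s)))
  ord <- order(-lengths(sets), vapply(sets, `[`, character(1), 1L))
  unname(sets[ord])
}

setMethod("show", "MetaboliteNetwork", function(object) {
  comps <- networkComponents(object)
  cat("MetaboliteNetwork:", nrow(object@nodes), "metabolites,",
      nrow(object@edges), "edges,", length(comps), "components\n")
  if (length(comps))
    cat("  largest component:", paste(utils::head(comps[[1]], 8),
                                      collapse = ", "),
        if (length(comps[[1]]) > 8) "..." else "", "\n")
})

#' Export the network for Cytoscape
#'
#' \code{writeSif} writes a simple interaction file (\code{A rp B}, one
#' row per edge); \code{writeGraphml} writes GraphML with the enrichment
#' q-value as a node attribute.
#'
#' @param net a \linkS4class{MetaboliteNetwork}.
#' @param path output path.
#' @export
writeSif <- function(net, path) {
  lines <- sprintf("%s\trp\t%s", net@edges$from, net@edges$to)
  iso <- setdiff(net@nodes$id, c(net@edges$from, net@edges$to))
  writeLines(c(lines, iso), path)
  invisible(path)
}

#' @rdname writeSif
#' @export
writeGraphml <- function(net, path) {
  g <- igraph::graph_from_data_frame(net@edges[, c("from", "to")],
                                     directed = FALSE,
                                     vertices = net@nodes)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
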