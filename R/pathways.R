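#' @include prs.R
NULL

#' Build a residue contact graph from a CA trace
#'
#' Edge (i, j) exists iff the CA-CA distance is at most
#' \code{contactCutoff} and i != j. Restricting the graph to spatial
#' contacts keeps extracted paths physically contiguous; a complete
#' PRS-weighted graph would make every route a trivial single hop.
#' Weights are 1 until \code{assignEdgeWeights}.
#'
#' @param caModel CA-only \linkS4class{StructureModel} (or N x 3 matrix).
#' @param contactCutoff CA-CA cutoff in Angstrom (default 10).
#' @return a \linkS4class{ResidueGraph} with unit weighting
#' @export
buildContactGraph <- function(caModel, contactCutoff = 10) {
  pos <- if (is(caModel, "StructureModel")) coords(caModel) else as.matrix(caModel)
  if (nrow(pos) == 0) stop("empty model")
  if (contactCutoff <= 0) stop("contactCutoff must be positive")
  pairs <- .contact_pairs(pos, contactCutoff)
  e <- data.frame(i = as.integer(pairs$i), j = as.integer(pairs$j),
                  weight = rep(1, nrow(pairs)))
  new("ResidueGraph", nNodes = nrow(pos), edges = e,
      contactCutoff = contactCutoff, weighting = "unit")
}

#' Weight contact edges by PRS coupling
#'
#' The coupling of a contacting pair is the symmetrized normalized
#' response p_ij = max(Z[i,j], Z[j,i]), clipped to [epsilon, 1]; the edge
#' weight is -ln(p_ij), so strong coupling gives a cheap edge and path
#' weights add as couplings multiply along the route.
#'
#' @param graph \linkS4class{ResidueGraph}.
#' @param prs \linkS4class{PRSResult} over the same N residues.
#' @param epsilon clip floor in (0, 1), default 1e-6.
#' @return the graph reweighted, weighting set to "prs"
#' @export
assignEdgeWeights <- function(graph, prs, epsilon = 1e-6) {
  if (epsilon <= 0 || epsilon >= 1) stop("epsilon must be in (0, 1)")
  Z <- prs@normalized
  if (nrow(Z) != graph@nNodes)
    stop(sprintf("graph has %d nodes but PRS has %d residues",
                 graph@nNodes, nrow(Z)))
  e <- graph@edges
  p <- pmax(Z[cbind(e$i, e$j)], Z[cbind(e$j, e$i)])
  p <- pmin(pmax(p, epsilon), 1)
  e$weight <- -log(p)
  out <- graph
  out@edges <- e
  out@weighting <- "prs"
  out
}

.as_igraph <- function(graph) {
  g <- igraph::make_empty_graph(n = graph@nNodes, directed = FALSE)
  if (nrow(graph@edges) > 0) {
    g <- igraph::add_edges(g, rbind(graph@edges$i, graph@edges$j))
    igraph::E(g)$weight <- graph@edges$weight
  }
  g
}

## adjacency list of (neighbor, weight) per node
.adj_list <- function(graph) {
  adj <- vector("list", graph@nNodes)
  e <- graph@edges
  for (k in seq_len(nrow(e))) {
    adj[[e$i[k]]] <- rbind(adj[[e$i[k]]], c(e$j[k], e$weight[k]))
    adj[[e$j[k]]] <- rbind(adj[[e$j[k]]], c(e$i[k], e$weight[k]))
  }
  adj
}

#' Shortest allosteric path between two residues
#'
#' Minimum-total-weight path by Dijkstra's algorithm; ties are broken
#' deterministically by fewer nodes, then by the lexicographically
#' smallest node sequence, so results are reproducible across platforms.
#'
#' @param graph \linkS4class{ResidueGraph}.
#' @param source source residue index.
#' @param sink sink residue index.
#' @return an \linkS4class{AllostericPath}
#' @export
shortestPath <- function(graph, source, sink) {
  n <- graph@nNodes
  if (source == sink) stop("source and sink must differ")
  if (source < 1 || source > n || sink < 1 || sink > n)
    stop("source/sink out of range")
  g <- .as_igraph(graph)
  ds <- as.numeric(igraph::distances(g, v = source, algorithm = "dijkstra"))
  dt <- as.numeric(igraph::distances(g, v = sink, algorithm = "dijkstra"))
  total <- ds[sink]
  if (!is.finite(total))
    stop(sprintf("disconnected: no path from residue %d to residue %d",
                 source, sink))
  tol <- 1e-9 * max(1, total)
  ## tight directed graph: edges that lie on some shortest path
  e <- graph@edges
  tight <- vector("list", n)
  add_tight <- function(u, v, w) {
    if (abs(ds[u] + w - ds[v]) <= tol && abs(ds[v] + dt[v] - total) <= tol &&
        abs(ds[u] + dt[u] - total) <= tol)
      tight[[u]] <<- c(tight[[u]], v)
  }
  for (k in seq_len(nrow(e))) {
    add_tight(e$i[k], e$j[k], e$weight[k])
    add_tight(e$j[k], e$i[k], e$weight[k])
  }
  ## reverse BFS from sink: minimum hops to sink within the tight graph
  hb <- rep(NA_integer_, n)
  hb[sink] <- 0L
  frontier <- sink
  ## reverse adjacency of the tight graph
  rtight <- vector("list", n)
  for (u in seq_len(n)) for (v in tight[[u]]) rtight[[v]] <- c(rtight[[v]], u)
  while (length(frontier) > 0) {
    nxt <- integer(0)
    for (v in frontier) for (u in rtight[[v]]) {
      if (is.na(hb[u])) { hb[u] <- hb[v] + 1L; nxt <- c(nxt, u) }
    }
    frontier <- unique(nxt)
  }
  ## greedy lexicographic walk along decreasing hop count
  path <- source
  u <- source
  while (u != sink) {
    cand <- tight[[u]]
    cand <- cand[!is.na(hb[cand]) & hb[cand] == hb[u] - 1L]
    u <- min(cand)
    path <- c(path, u)
  }
  ## recompute the weight from the edges actually traversed
  w <- 0
  key <- paste(pmin(e$i, e$j), pmax(e$i, e$j))
  wmap <- stats::setNames(e$weight, key)
  for (k in seq_len(length(path) - 1)) {
    w <- w + unname(wmap[paste(min(path[k], path[k + 1]),
                               max(path[k], path[k + 1]))])
  }
  new("AllostericPath", nodes = as.integer(path), totalWeight = w)
}

#' Shortest paths for every (source, sink) pair
#'
#' One path per pair in source-major order. Unreachable pairs are reported
#' as warnings and skipped; computation continues for the rest. By
#' convention the sinks are the active-site anchor residues and the
#' sources the binding-site residues.
#'
#' @param graph \linkS4class{ResidueGraph}.
#' @param sources integer vector (or selection string) of source residues.
#' @param sinks integer vector (or selection string) of sink residues;
#'   must be disjoint from sources as sets.
#' @return named list of \linkS4class{AllostericPath} ("source->sink")
#' @export
allPairsPaths <- function(graph, sources, sinks) {
  sources <- parseResidueSelection(sources)
  sinks <- parseResidueSelection(sinks)
  if (length(sources) == 0 || length(sinks) == 0)
    stop("sources and sinks must be non-empty")
  if (length(intersect(sources, sinks)) > 0)
    stop("sources and sinks must be disjoint sets")
  out <- list()
  for (s in sources) for (t in sinks) {
    p <- tryCatch(shortestPath(graph, s, t), error = function(e) {
      warning(sprintf("pair %d -> %d: %s", s, t, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    if (!is.null(p)) out[[sprintf("%d->%d", s, t)]] <- p
  }
  out
}

#' Mediator-residue profile over a set of paths
#'
#' Counts, for each residue, the number of paths in which it appears as an
#' interior node (strictly between source and sink). The residue with the
#' highest count is the most-mediated site of the allosteric network.
#'
#' @param paths list of \linkS4class{AllostericPath}.
#' @param nNodes number of residues in the underlying graph.
#' @return a \linkS4class{MediationProfile}
#' @export
mediationProfile <- function(paths, nNodes) {
  if (length(paths) == 0) stop("paths must be non-empty")
  counts <- integer(nNodes)
  for (p in paths) {
    nd <- p@nodes
    if (any(nd > nNodes)) stop("path node index beyond nNodes")
    interior <- nd[-c(1, length(nd))]
    for (r in interior) counts[r] <- counts[r] + 1L
  }
  new("MediationProfile", counts = counts, nPaths = length(paths))
}

#' Most-mediated residues
#'
#' @param profile \linkS4class{MediationProfile}.
#' @return integer vector of argmax residues (ties all listed)
#' @export
topMediators <- function(profile) {
  m <- max(profile@counts)
  if (m == 0L) return(integer(0))
  which(profile@counts == m)
}
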