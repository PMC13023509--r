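# Nine-measure topological centrality suite and the tie-aware top-k
# consensus used for hub screening. Degree, Betweenness, harmonic Closeness
# and the clique/component primitives come from igraph; MCC, MNC, EPC,
# Stress, EcCentricity and Radiality are assembled here from their
# definitions.

#' The nine supported centrality measures
#' @export
centrality_methods <- c("Degree", "MNC", "MCC", "EPC", "Betweenness",
                        "Stress", "EcCentricity", "Closeness", "Radiality")

#' Topological centrality scores
#'
#' Per-node scores for one of the nine hub-screening measures:
#' \describe{
#'   \item{Degree}{number of incident edges.}
#'   \item{MNC}{maximum neighborhood component: size of the largest
#'     connected component of the subgraph induced by the node's neighbors
#'     (the node itself excluded).}
#'   \item{MCC}{maximal clique centrality: sum of `(|C| - 1)!` over maximal
#'     cliques `C` containing the node; a node whose maximal cliques are all
#'     single edges therefore scores its degree.}
#'   \item{Betweenness}{sum over unordered pairs `s != t != v` of the
#'     fraction of shortest s-t paths passing through v (unnormalised).}
#'   \item{Stress}{count of shortest s-t paths passing through v.}
#'   \item{EcCentricity}{component size divided by the node's eccentricity
#'     within its component; isolated nodes score 0.}
#'   \item{Closeness}{harmonic closeness `sum_w 1/d(v, w)`; unreachable
#'     nodes contribute 0. `closeness = "classic"` instead scores
#'     `1 / sum_w d(v, w)` over the node's component.}
#'   \item{Radiality}{`sum_w (D + 1 - d(v, w)) / (n - 1)` over nodes `w`
#'     reachable from v, with `D` the diameter of v's component and `n` the
#'     number of graph nodes.}
#'   \item{EPC}{edge percolated component: over `epc_iters` random
#'     realizations in which each edge is independently retained with
#'     probability `epc_keep`, the mean of `|component(v)| / n`.}
#' }
#'
#' @param graph an igraph network (see [ppi_network()]).
#' @param method one of [centrality_methods].
#' @param epc_iters,epc_keep EPC Monte Carlo parameters.
#' @param seed seed for the EPC realizations (ignored by the deterministic
#'   measures).
#' @param closeness `"harmonic"` (default) or `"classic"`.
#' @return a [ranked_scores()] table over all graph nodes.
#' @export
centrality_scores <- function(graph, method, epc_iters = 1000L,
                              epc_keep = 0.5, seed = 1L,
                              closeness = c("harmonic", "classic")) {
  if (igraph::vcount(graph) == 0L) stop("graph is empty", call. = FALSE)
  if (!is.character(method) || length(method) != 1L ||
      !method %in% centrality_methods) {
    stop("unknown centrality method '", paste(method, collapse = ","),
         "'; expected one of: ", paste(centrality_methods, collapse = ", "),
         call. = FALSE)
  }
  closeness <- match.arg(closeness)
  nodes <- igraph::V(graph)$name
  score <- switch(method,
    Degree = igraph::degree(graph),
    MNC = mnc_scores(graph),
    MCC = mcc_scores(graph),
    EPC = epc_scores(graph, epc_iters, epc_keep, seed),
    Betweenness = igraph::betweenness(graph, directed = FALSE),
    Stress = stress_scores(graph),
    EcCentricity = eccentricity_scores(graph),
    Closeness = closeness_scores(graph, closeness),
    Radiality = radiality_scores(graph))
  ranked_scores(nodes, as.numeric(score))
}

mnc_scores <- function(graph) {
  vapply(seq_len(igraph::vcount(graph)), function(v) {
    nb <- as.integer(igraph::neighbors(graph, v))
    if (length(nb) == 0L) return(0)
    sub <- igraph::induced_subgraph(graph, nb)
    max(igraph::components(sub)$csize)
  }, numeric(1L))
}

mcc_scores <- function(graph) {
  n <- igraph::vcount(graph)
  score <- numeric(n)
  for (clique in igraph::max_cliques(graph)) {
    idx <- as.integer(clique)
    score[idx] <- score[idx] + factorial(length(idx) - 1L)
  }
  score
}

# All-pairs shortest-path distance and path-count matrices by layered BFS.
shortest_path_counts <- function(graph) {
  n <- igraph::vcount(graph)
  adj <- igraph::as_adj_list(graph)
  adj <- lapply(adj, as.integer)
  d <- matrix(Inf, n, n)
  sig <- matrix(0, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    sigma <- numeric(n)
    dist[s] <- 0
    sigma[s] <- 1
    frontier <- s
    while (length(frontier) > 0L) {
      nxt <- integer(0L)
      for (v in frontier) {
        for (w in adj[[v]]) {
          if (is.infinite(dist[w])) {
            dist[w] <- dist[v] + 1
            sigma[w] <- sigma[w] + sigma[v]
            nxt <- c(nxt, w)
          } else if (dist[w] == dist[v] + 1) {
            sigma[w] <- sigma[w] + sigma[v]
          }
        }
      }
      frontier <- unique(nxt)
    }
    d[s, ] <- dist
    sig[s, ] <- sigma
  }
  list(d = d, sig = sig)
}

stress_scores <- function(graph) {
  n <- igraph::vcount(graph)
  sp <- shortest_path_counts(graph)
  vapply(seq_len(n), function(v) {
    a <- sp$sig[, v]              # sigma(s, v), symmetric in undirected graphs
    dv <- sp$d[, v]
    on_path <- is.finite(sp$d) & (outer(dv, dv, "+") == sp$d)
    keep <- rep(TRUE, n)
    keep[v] <- FALSE
    on_path <- on_path & outer(keep, keep) & !diag(n)
    sum(outer(a, a)[on_path]) / 2
  }, numeric(1L))
}

eccentricity_scores <- function(graph) {
  comp <- igraph::components(graph)
  d <- igraph::distances(graph)
  vapply(seq_len(igraph::vcount(graph)), function(v) {
    same <- comp$membership == comp$membership[v]
    csize <- sum(same)
    if (csize == 1L) return(0)
    csize / max(d[v, same])
  }, numeric(1L))
}

closeness_scores <- function(graph, mode) {
  d <- igraph::distances(graph)
  if (mode == "harmonic") {
    vapply(seq_len(nrow(d)), function(v) {
      dv <- d[v, -v]
      sum(1 / dv[is.finite(dv)])
    }, numeric(1L))
  } else {
    vapply(seq_len(nrow(d)), function(v) {
      dv <- d[v, -v]
      tot <- sum(dv[is.finite(dv)])
      if (tot == 0) 0 else 1 / tot
    }, numeric(1L))
  }
}

radiality_scores <- function(graph) {
  n <- igraph::vcount(graph)
  if (n == 1L) return(0)
  comp <- igraph::components(graph)
  d <- igraph::distances(graph)
  diam <- vapply(seq_len(comp$no), function(cc) {
    idx <- comp$membership == cc
    if (sum(idx) == 1L) 0 else max(d[idx, idx])
  }, numeric(1L))
  vapply(seq_len(n), function(v) {
    same <- comp$membership == comp$membership[v]
    dv <- d[v, same & seq_len(n) != v]
    if (length(dv) == 0L) return(0)
    sum(diam[comp$membership[v]] + 1 - dv) / (n - 1)
  }, numeric(1L))
}

# Canonical edge order for the EPC realizations: endpoints sorted within an
# edge, edges sorted lexicographically. Each realization retains edge e iff
# runif()[e] < epc_keep, drawn in this order.
canonical_edge_index <- function(graph) {
  el <- igraph::as_edgelist(graph, names = FALSE)
  if (nrow(el) == 0L) return(cbind(integer(0L), integer(0L)))
  i <- pmin(el[, 1L], el[, 2L])
  j <- pmax(el[, 1L], el[, 2L])
  ord <- order(i, j)
  cbind(i[ord], j[ord])
}

epc_scores <- function(graph, epc_iters, epc_keep, seed) {
  stopifnot(epc_iters >= 1L, epc_keep >= 0, epc_keep <= 1)
  n <- igraph::vcount(graph)
  edges <- canonical_edge_index(graph)
  m <- nrow(edges)
  with_seed(substream_seed(seed, "epc"), {
    acc <- numeric(n)
    for (iter in seq_len(epc_iters)) {
      keep <- stats::runif(m) < epc_keep
      sizes <- component_sizes_per_node(n, edges[keep, 1L], edges[keep, 2L])
      acc <- acc + sizes / n
    }
    acc / epc_iters
  })
}

# Union-find component size per node for an edge subset.
component_sizes_per_node <- function(n, ei, ej) {
  parent <- seq_len(n)
  find_root <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (e in seq_along(ei)) {
    ra <- find_root(ei[e])
    rb <- find_root(ej[e])
    if (ra != rb) parent[rb] <- ra
  }
  roots <- vapply(seq_len(n), function(v) as.integer(find_root(v)),
                  integer(1L))
  sizes <- tabulate(roots, n)
  sizes[roots]
}

#' Tie-expanded top-k genes of a score table
#'
#' The `k` highest-scoring genes; if the k-th score is tied, every gene tied
#' at that score is included, so the result can exceed `k` genes. This keeps
#' the consensus deterministic without an arbitrary order among ties.
#'
#' @param scores a [ranked_scores()] table.
#' @param k number of top genes (default 3).
#' @return character vector of genes, in ranking order.
#' @export
top_k <- function(scores, k = 3L) {
  stopifnot(is.data.frame(scores), all(c("gene", "score") %in% names(scores)),
            k >= 1L)
  if (k >= nrow(scores)) return(scores$gene)
  threshold <- sort(scores$score, decreasing = TRUE)[k]
  scores$gene[scores$score >= threshold]
}

#' Centrality consensus for hub nomination
#'
#' Runs every requested centrality measure, takes the tie-expanded top-k
#' genes per measure, and intersects the per-measure sets. Genes surviving
#' every measure are the consensus hub candidates.
#'
#' @inheritParams centrality_scores
#' @param methods centrality measures to run (default: all nine).
#' @param k per-method top-k cutoff (default 3).
#' @return a list of class `consensus_report` with elements `scores` (named
#'   list of [ranked_scores()] tables), `top_sets` (named list of character
#'   vectors), `consensus` (character vector, sorted) and `k`.
#' @export
consensus <- function(graph, methods = centrality_methods, k = 3L,
                      epc_iters = 1000L, epc_keep = 0.5, seed = 1L) {
  stopifnot(length(methods) >= 1L, all(methods %in% centrality_methods))
  scores <- lapply(methods, function(m) {
    centrality_scores(graph, m, epc_iters = epc_iters, epc_keep = epc_keep,
                      seed = seed)
  })
  names(scores) <- methods
  top_sets <- lapply(scores, top_k, k = k)
  out <- list(scores = scores, top_sets = top_sets,
              consensus = sort(Reduce(intersect, top_sets)), k = as.integer(k))
  class(out) <- "consensus_report"
  out
}

#' @export
print.consensus_report <- function(x, ...) {
  cat("Centrality consensus over", length(x$scores), "methods (k =", x$k,
      "):", if (length(x$consensus)) paste(x$consensus, collapse = ", ")
      else "<empty>", "\n")
  invisible(x)
}
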