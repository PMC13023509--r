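# Monte Carlo random walk with restart and its closed-form personalized
# PageRank counterpart. The walker convention: every occupied position is
# tallied, including the start and post-restart positions, so the visit
# fractions estimate the occupancy measure that the stationary PPR vector
# describes.

#' Monte Carlo random walk with restart
#'
#' From each source node, `n_walks` independent walks of `max_steps`
#' transitions are simulated. At every transition the walker returns to its
#' source with probability `restart_prob`, otherwise it moves to a uniformly
#' random neighbor of its current node; a node with no neighbors forces a
#' restart. Each walk tallies `1 + max_steps` occupied positions (the start
#' plus one per transition, restart landings included); `visit_fraction` is
#' the tally normalised over all sources and walks. Genes are ranked by
#' visit fraction, descending, with a lexicographic tie-break.
#'
#' Per-source random substreams are derived from `(seed, source)`, so
#' results are reproducible and independent of source evaluation order.
#'
#' @param graph an igraph network.
#' @param n_walks walks per source (default 10000).
#' @param max_steps transitions per walk (default 100).
#' @param restart_prob restart probability, strictly inside (0, 1)
#'   (default 0.1).
#' @param seed integer master seed.
#' @param source_mode `"each_node"` (every node is a source),
#'   `"single_random"` (one uniformly chosen source) or `"given_set"`
#'   (caller-supplied `sources`).
#' @param sources character vector of source nodes for
#'   `source_mode = "given_set"`.
#' @return a list of class `rwr_result` with `visit_fraction` (named numeric
#'   over all nodes, summing to 1), `ranking` (a [ranked_scores()] table),
#'   `total_steps_counted`, `sources` and `config`.
#' @export
mc_rwr <- function(graph, n_walks = 10000L, max_steps = 100L,
                   restart_prob = 0.1, seed = 1L,
                   source_mode = c("each_node", "single_random", "given_set"),
                   sources = NULL) {
  source_mode <- match.arg(source_mode)
  if (igraph::vcount(graph) == 0L) stop("graph is empty", call. = FALSE)
  if (!is.numeric(restart_prob) || length(restart_prob) != 1L ||
      restart_prob <= 0 || restart_prob >= 1) {
    stop("restart_prob must lie strictly inside (0, 1)", call. = FALSE)
  }
  stopifnot(n_walks >= 1L, max_steps >= 1L)
  nodes <- igraph::V(graph)$name
  src_nodes <- switch(source_mode,
    each_node = nodes,
    single_random = with_seed(substream_seed(seed, "source_choice"),
                              sample(nodes, 1L)),
    given_set = {
      if (is.null(sources) || length(sources) == 0L) {
        stop("source_mode = 'given_set' requires a non-empty `sources`",
             call. = FALSE)
      }
      bad <- setdiff(sources, nodes)
      if (length(bad) > 0L) {
        stop("source node(s) not in the graph: ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
      unique(as.character(sources))
    })
  csr <- adjacency_csr(graph)
  n <- length(nodes)
  tally <- numeric(n)
  for (src in src_nodes) {
    si <- match(src, nodes)
    tally <- tally + with_seed(substream_seed(seed, paste0("walks:", src)), {
      state <- rep.int(si, n_walks)
      tl <- numeric(n)
      tl[si] <- n_walks
      for (step in seq_len(max_steps)) {
        restart <- stats::runif(n_walks) < restart_prob
        move <- !restart & csr$deg[state] > 0L
        if (any(move)) {
          st <- state[move]
          dg <- csr$deg[st]
          pick <- csr$ptr[st] + pmin(dg, 1L + as.integer(stats::runif(length(st)) * dg))
          state[move] <- csr$nbr[pick]
        }
        state[!move] <- si
        tl <- tl + tabulate(state, nbins = n)
      }
      tl
    })
  }
  visit_fraction <- stats::setNames(tally / sum(tally), nodes)
  out <- list(
    visit_fraction = visit_fraction,
    ranking = ranked_scores(nodes, visit_fraction),
    total_steps_counted = sum(tally),
    sources = src_nodes,
    config = list(n_walks = as.integer(n_walks),
                  max_steps = as.integer(max_steps),
                  restart_prob = restart_prob, seed = as.integer(seed),
                  source_mode = source_mode))
  class(out) <- "rwr_result"
  out
}

#' @export
print.rwr_result <- function(x, ...) {
  cat("RWR over", length(x$sources), "source(s):",
      format(x$total_steps_counted, big.mark = ","), "positions tallied; top:",
      paste(utils::head(x$ranking$gene, 3L), collapse = ", "), "\n")
  invisible(x)
}

# Compressed adjacency: neighbors of node v are
# nbr[(ptr[v] + 1):(ptr[v] + deg[v])], neighbor lists sorted for determinism.
adjacency_csr <- function(graph) {
  n <- igraph::vcount(graph)
  el <- igraph::as_edgelist(graph, names = FALSE)
  from <- c(el[, 1L], el[, 2L])
  to <- c(el[, 2L], el[, 1L])
  ord <- order(from, to)
  deg <- tabulate(from, n)
  list(nbr = as.integer(to[ord]), deg = as.integer(deg),
       ptr = c(0L, cumsum(deg))[seq_len(n)])
}

#' Exact personalized PageRank by power iteration
#'
#' Solves `pi = restart_prob * s + (1 - restart_prob) * t(W) pi` where `W`
#' is the row-stochastic uniform-neighbor transition matrix and `s` the
#' source distribution; nodes without neighbors redirect their mass to `s`.
#' This is the stationary occupancy of the restart walk and serves as the
#' closed-form oracle for [mc_rwr()].
#'
#' @param graph an igraph network.
#' @param sources character vector of source nodes (uniform distribution
#'   over them) or a named numeric vector giving the source distribution.
#' @param restart_prob restart probability in (0, 1).
#' @param tol L1 convergence tolerance (default 1e-12).
#' @param max_iter iteration cap; exceeding it is an error reporting the
#'   residual.
#' @return a [ranked_scores()] table whose scores are the stationary
#'   probabilities (summing to 1).
#' @export
ppr_exact <- function(graph, sources, restart_prob = 0.1, tol = 1e-12,
                      max_iter = 10000L) {
  if (igraph::vcount(graph) == 0L) stop("graph is empty", call. = FALSE)
  if (restart_prob <= 0 || restart_prob >= 1) {
    stop("restart_prob must lie strictly inside (0, 1)", call. = FALSE)
  }
  nodes <- igraph::V(graph)$name
  n <- length(nodes)
  s <- numeric(n)
  if (is.numeric(sources)) {
    if (is.null(names(sources))) stop("numeric `sources` must be named",
                                      call. = FALSE)
    idx <- match(names(sources), nodes)
    if (anyNA(idx)) stop("source node(s) not in the graph", call. = FALSE)
    if (any(sources < 0) || sum(sources) <= 0) {
      stop("source distribution must be non-negative with positive mass",
           call. = FALSE)
    }
    s[idx] <- sources / sum(sources)
  } else {
    idx <- match(unique(as.character(sources)), nodes)
    if (length(idx) == 0L || anyNA(idx)) {
      stop("source node(s) not in the graph", call. = FALSE)
    }
    s[idx] <- 1 / length(idx)
  }
  el <- igraph::as_edgelist(graph, names = FALSE)
  from <- c(el[, 1L], el[, 2L])
  to <- c(el[, 2L], el[, 1L])
  deg <- tabulate(from, n)
  pi_vec <- s
  for (iter in seq_len(max_iter)) {
    spread <- numeric(n)
    if (length(from) > 0L) {
      flow <- pi_vec[from] / deg[from]
      agg <- rowsum(flow, to)
      spread[as.integer(rownames(agg))] <- agg[, 1L]
    }
    dangling <- sum(pi_vec[deg == 0L])
    new_pi <- restart_prob * s + (1 - restart_prob) * (spread + dangling * s)
    delta <- sum(abs(new_pi - pi_vec))
    pi_vec <- new_pi
    if (delta < tol) {
      return(ranked_scores(nodes, stats::setNames(pi_vec, nodes)))
    }
  }
  stop("power iteration did not converge within ", max_iter,
       " iterations (L1 residual ", format(delta), ")", call. = FALSE)
}
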