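# Brute-force oracles for the centrality suite, built from first principles
# (simple-path enumeration, subset enumeration, reachability closure) so
# they share no code path with the implementation.

# Reachability closure of an adjacency matrix (TRUE on the diagonal).
oracle_reach <- function(A) {
  n <- nrow(A)
  R <- (A > 0) | diag(n) > 0
  repeat {
    R2 <- ((R %*% R) > 0) | R
    if (all(R2 == R)) return(R)
    R <- R2
  }
}

# Component membership labels from the closure.
oracle_components <- function(A) {
  R <- oracle_reach(A)
  match(apply(R, 1L, function(r) paste(which(r), collapse = ",")),
        unique(apply(R, 1L, function(r) paste(which(r), collapse = ","))))
}

# All simple paths from s to t, as vertex vectors (including endpoints).
oracle_simple_paths <- function(A, s, t) {
  paths <- list()
  walk <- function(v, visited, path) {
    if (v == t) {
      paths[[length(paths) + 1L]] <<- path
      return(invisible(NULL))
    }
    for (w in which(A[v, ] > 0)) {
      if (!visited[w]) {
        visited[w] <- TRUE
        walk(w, visited, c(path, w))
        visited[w] <- FALSE
      }
    }
  }
  visited <- rep(FALSE, nrow(A))
  visited[s] <- TRUE
  walk(s, visited, s)
  paths
}

# Distances, shortest-path counts and per-vertex pass-through tallies from
# exhaustive path enumeration.
oracle_shortest_paths <- function(A) {
  n <- nrow(A)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  sigma <- matrix(0, n, n)
  diag(sigma) <- 1
  betweenness <- numeric(n)
  stress <- numeric(n)
  for (s in seq_len(n - 1L)) {
    for (t in seq.int(s + 1L, n)) {
      paths <- oracle_simple_paths(A, s, t)
      if (length(paths) == 0L) next
      lens <- lengths(paths)
      shortest <- paths[lens == min(lens)]
      d[s, t] <- d[t, s] <- min(lens) - 1L
      sigma[s, t] <- sigma[t, s] <- length(shortest)
      inner <- unlist(lapply(shortest, function(p) p[-c(1L, length(p))]))
      if (length(inner) > 0L) {
        tab <- table(inner)
        idx <- as.integer(names(tab))
        betweenness[idx] <- betweenness[idx] + as.numeric(tab) / length(shortest)
        stress[idx] <- stress[idx] + as.numeric(tab)
      }
    }
  }
  list(d = d, sigma = sigma, betweenness = betweenness, stress = stress)
}

# Maximal cliques by subset enumeration.
oracle_maximal_cliques <- function(A) {
  n <- nrow(A)
  cliques <- list()
  for (mask in seq_len(2^n - 1L)) {
    S <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
    is_clique <- all(A[S, S][upper.tri(matrix(0, length(S), length(S)))] > 0)
    if (!is_clique) next
    outside <- setdiff(seq_len(n), S)
    maximal <- !any(vapply(outside, function(v) all(A[v, S] > 0), logical(1L)))
    if (maximal) cliques[[length(cliques) + 1L]] <- S
  }
  cliques
}

# All nine centrality scores for an adjacency matrix, independently of the
# package implementation. EPC reproduces the documented mask protocol
# (canonical edge order, runif < keep under the derived seed) but computes
# component sizes by its own reachability closure.
oracle_centralities <- function(A, epc_iters, epc_keep, seed) {
  n <- nrow(A)
  sp <- oracle_shortest_paths(A)
  comp <- oracle_components(A)
  degree <- rowSums(A)

  mnc <- vapply(seq_len(n), function(v) {
    nb <- which(A[v, ] > 0)
    if (length(nb) == 0L) return(0)
    sub <- A[nb, nb, drop = FALSE]
    as.numeric(max(table(oracle_components(sub))))
  }, numeric(1L))

  mcc <- numeric(n)
  for (S in oracle_maximal_cliques(A)) {
    mcc[S] <- mcc[S] + factorial(length(S) - 1L)
  }

  ecc <- vapply(seq_len(n), function(v) {
    same <- comp == comp[v]
    if (sum(same) == 1L) return(0)
    sum(same) / max(sp$d[v, same])
  }, numeric(1L))

  harmonic <- vapply(seq_len(n), function(v) {
    dv <- sp$d[v, -v]
    sum(1 / dv[is.finite(dv)])
  }, numeric(1L))

  radiality <- vapply(seq_len(n), function(v) {
    same <- comp == comp[v] & seq_len(n) != v
    if (!any(same)) return(0)
    diam <- max(sp$d[comp == comp[v], comp == comp[v]])
    sum(diam + 1 - sp$d[v, same]) / (n - 1)
  }, numeric(1L))

  # canonical edge order: i < j, sorted by (i, j)
  idx <- which(A > 0, arr.ind = TRUE)
  idx <- idx[idx[, 1L] < idx[, 2L], , drop = FALSE]
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  m <- nrow(idx)
  epc <- local({
    set.seed(netprior:::substream_seed(seed, "epc"))
    acc <- numeric(n)
    for (it in seq_len(epc_iters)) {
      keep <- stats::runif(m) < epc_keep
      Ak <- matrix(0L, n, n)
      if (any(keep)) {
        kept <- idx[keep, , drop = FALSE]
        Ak[kept] <- 1L
        Ak[kept[, c(2L, 1L), drop = FALSE]] <- 1L
      }
      ck <- oracle_components(Ak)
      sizes <- as.numeric(table(ck))[ck]
      acc <- acc + sizes / n
    }
    acc / epc_iters
  })

  list(Degree = degree, MNC = mnc, MCC = mcc, EPC = epc,
       Betweenness = sp$betweenness, Stress = sp$stress,
       EcCentricity = ecc, Closeness = harmonic, Radiality = radiality)
}

# Seeded random connected graph on 2..7 nodes, returned as an adjacency
# matrix with vertex names g1..gn.
random_connected_adjacency <- function(seed) {
  set.seed(seed)
  repeat {
    n <- sample(2:7, 1L)
    p <- stats::runif(1L, 0.3, 0.8)
    A <- matrix(0L, n, n)
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        if (stats::runif(1L) < p) A[i, j] <- A[j, i] <- 1L
      }
    }
    if (all(oracle_reach(A)[1L, ])) {
      dimnames(A) <- list(paste0("g", seq_len(n)), paste0("g", seq_len(n)))
      return(A)
    }
  }
}

# Adjacency matrix -> package network, preserving vertex order so igraph
# vertex ids line up with matrix indices.
adjacency_to_network <- function(A) {
  idx <- which(A > 0, arr.ind = TRUE)
  idx <- idx[idx[, 1L] < idx[, 2L], , drop = FALSE]
  nodes <- rownames(A)
  ppi_network(nodes[idx[, 1L]], nodes[idx[, 2L]], nodes = nodes)
}

# Extract a plain named score vector in vertex order from a ranked_scores
# table.
scores_in_order <- function(ranked, nodes) {
  stats::setNames(ranked$score[match(nodes, ranked$gene)], nodes)
}

# Independent Benjamini-Hochberg step-up used as the screening oracle.
oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj <- p[ord] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[ord] <- pmin(adj, 1)
  out
}

# Exhaustive hypergeometric upper tail by enumerating every query subset.
oracle_ora_tail <- function(N, m, q, k) {
  subsets <- utils::combn(N, q)
  overlaps <- colSums(subsets <= m)
  mean(overlaps >= k)
}
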