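# Enrichment stage: hypergeometric over-representation, weighted-KS GSEA
# with a gene-label permutation null, Barbie-style ssGSEA per-sample scores,
# and a two-group score comparison.

#' Hypergeometric over-representation analysis
#'
#' For each gene set, tests whether the query set overlaps it more than
#' expected by chance: `pvalue = P(X >= overlap)` for hypergeometric X with
#' population `universe_size`, successes `set_size` (the set intersected
#' with the universe) and draws `query_size`. Adjusted p-values are BH
#' across terms. Query members outside the universe are dropped with a
#' warning; results are sorted by p-value ascending with term-name
#' tie-break.
#'
#' @param query character vector of query genes.
#' @param sets a gene-set collection (named list, see [read_gmt()]).
#' @param universe character vector: the gene universe.
#' @return a data.frame with columns `term`, `overlap_size`, `set_size`,
#'   `query_size`, `universe_size`, `pvalue`, `padj`.
#' @export
ora <- function(query, sets, universe) {
  universe <- unique(as.character(universe))
  query <- unique(as.character(query))
  if (length(universe) == 0L) stop("universe is empty", call. = FALSE)
  if (length(query) == 0L) stop("query is empty", call. = FALSE)
  outside <- setdiff(query, universe)
  if (length(outside) > 0L) {
    warning("dropped ", length(outside),
            " query gene(s) outside the universe", call. = FALSE)
    query <- intersect(query, universe)
    if (length(query) == 0L) stop("no query genes left in the universe",
                                  call. = FALSE)
  }
  N <- length(universe)
  q <- length(query)
  rows <- lapply(names(sets), function(term) {
    members <- intersect(unique(sets[[term]]), universe)
    m <- length(members)
    k <- length(intersect(members, query))
    p <- stats::phyper(k - 1L, m, N - m, q, lower.tail = FALSE)
    data.frame(term = term, overlap_size = k, set_size = m, query_size = q,
               universe_size = N, pvalue = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$padj <- bh_adjust(res$pvalue)
  res <- res[order(res$pvalue, res$term, method = "radix"), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Weighted Kolmogorov-Smirnov GSEA enrichment score
#'
#' Walks the ranked gene list accumulating a running sum: at a set member
#' ("hit") the sum increases by `|score|^exponent` normalised by the total
#' hit weight; at a non-member it decreases by `1 / (N - N_hits)`. The
#' enrichment score is the signed maximum deviation of the running sum from
#' zero. With `exponent = 0` this is the classic equal-weight KS statistic.
#'
#' When every ranked gene is a set member the statistic degenerates (there
#' are no misses); the score is then `+1` by convention. If all hit weights
#' are zero (every member has score 0 with `exponent > 0`), hits fall back
#' to equal weights.
#'
#' @param ranked a [ranked_scores()] table covering the full gene list.
#' @param set_members character vector; must intersect the ranked genes.
#' @param exponent weight exponent `p` (default 1).
#' @return the enrichment score, a number in `[-1, 1]`.
#' @export
gsea_es <- function(ranked, set_members, exponent = 1) {
  stopifnot(is.data.frame(ranked), all(c("gene", "score") %in% names(ranked)))
  hit <- ranked$gene %in% set_members
  n <- nrow(ranked)
  n_hit <- sum(hit)
  if (n_hit == 0L) stop("gene set has no members in the ranked list",
                        call. = FALSE)
  if (n_hit == n) return(1)
  running_sum_max(ranked$score, hit, exponent)
}

# Signed maximum deviation of the GSEA running sum; `hit` is a logical
# vector aligned with the (already ordered) scores.
running_sum_max <- function(score, hit, exponent) {
  n <- length(score)
  n_hit <- sum(hit)
  w <- abs(score[hit])^exponent
  total <- sum(w)
  steps <- numeric(n)
  steps[hit] <- if (total > 0) w / total else 1 / n_hit
  steps[!hit] <- -1 / (n - n_hit)
  running <- cumsum(steps)
  running[which.max(abs(running))]
}

#' GSEA permutation p-value
#'
#' Gene-label permutation null: the hit/miss labels are shuffled over the
#' ranked positions `n_perm` times and the two-sided p-value is
#' `(1 + #\{|ES_perm| >= |ES_obs|\}) / (n_perm + 1)`.
#'
#' @inheritParams gsea_es
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed for the permutation stream.
#' @return a list with `es`, `perm_pvalue`, `n_perm`, `n_hits`.
#' @export
gsea_permutation_p <- function(ranked, set_members, exponent = 1,
                               n_perm = 999L, seed = 1L) {
  es_obs <- gsea_es(ranked, set_members, exponent)
  n <- nrow(ranked)
  n_hit <- sum(ranked$gene %in% set_members)
  if (n_hit == n) {
    return(list(es = es_obs, perm_pvalue = 1, n_perm = as.integer(n_perm),
                n_hits = n_hit))
  }
  perm_es <- with_seed(substream_seed(seed, "gsea_perm"), {
    vapply(seq_len(n_perm), function(i) {
      hit <- logical(n)
      hit[sample.int(n, n_hit)] <- TRUE
      running_sum_max(ranked$score, hit, exponent)
    }, numeric(1L))
  })
  p <- (1 + sum(abs(perm_es) >= abs(es_obs))) / (n_perm + 1)
  list(es = es_obs, perm_pvalue = p, n_perm = as.integer(n_perm),
       n_hits = n_hit)
}

#' Single-sample GSEA scores
#'
#' For each sample, genes are ordered by expression descending (lexicographic
#' gene tie-break for positions; average ranks for weights) and ranks `N..1`
#' are converted to weights `rank^alpha`. The score for a set is the
#' integrated difference between the weighted empirical distribution of
#' member positions and the unweighted empirical distribution of non-member
#' positions, accumulated down the list. Scores depend only on within-sample
#' ranks, so any strictly monotone per-sample transform of the expression
#' values leaves them unchanged. No cross-sample rescaling is applied.
#'
#' @param mat numeric genes-by-samples matrix (see [read_expression()]).
#' @param sets named list of gene sets.
#' @param alpha rank-weight exponent (default 0.25).
#' @return a terms-by-samples numeric matrix with an `alpha` attribute.
#' @export
ssgsea_score <- function(mat, sets, alpha = 0.25) {
  stopifnot(is.matrix(mat), is.numeric(mat), !is.null(rownames(mat)))
  if (nrow(mat) < 2L) stop("expression matrix needs >= 2 genes", call. = FALSE)
  genes <- rownames(mat)
  n <- length(genes)
  member <- lapply(names(sets), function(term) {
    inset <- genes %in% sets[[term]]
    if (!any(inset)) {
      stop("gene set '", term, "' has no genes in the expression matrix",
           call. = FALSE)
    }
    if (all(inset)) {
      stop("gene set '", term, "' covers every gene in the matrix; ",
           "the non-member distribution is undefined", call. = FALSE)
    }
    inset
  })
  names(member) <- names(sets)
  scores <- matrix(NA_real_, nrow = length(sets), ncol = ncol(mat),
                   dimnames = list(names(sets), colnames(mat)))
  for (j in seq_len(ncol(mat))) {
    x <- mat[, j]
    ord <- order(-x, genes, method = "radix")
    # average ranks, largest expression -> rank n
    r <- (n + 1) - rank(x, ties.method = "average")
    w <- ((n + 1) - r)^alpha        # weight of the gene at its list position
    w_ord <- w[ord]
    for (t in seq_along(member)) {
      inset <- member[[t]][ord]
      p_in <- cumsum(ifelse(inset, w_ord, 0)) / sum(w_ord[inset])
      p_out <- cumsum(!inset) / sum(!inset)
      scores[t, j] <- sum(p_in - p_out)
    }
  }
  attr(scores, "alpha") <- alpha
  scores
}

#' Compare per-sample enrichment scores between two groups
#'
#' Two-sided Welch t-test (default) or Mann-Whitney on the per-sample
#' scores of each term. Both groups must have >= 2 samples. When both
#' groups are constant with equal values the statistic is 0 and p = 1.
#'
#' @param scores a terms-by-samples matrix from [ssgsea_score()].
#' @param labels named character vector (sample -> group) or a vector
#'   aligned with the columns of `scores`; exactly two groups.
#' @param test `"welch"` or `"wilcoxon"`.
#' @return a data.frame with columns `term`, `statistic`, `pvalue`.
#' @export
compare_group_scores <- function(scores, labels, test = c("welch", "wilcoxon")) {
  test <- match.arg(test)
  stopifnot(is.matrix(scores))
  if (!is.null(names(labels))) {
    missing <- setdiff(colnames(scores), names(labels))
    if (length(missing) > 0L) {
      stop("no group label for sample(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    labels <- labels[colnames(scores)]
  }
  labels <- as.character(labels)
  groups <- sort(unique(labels))
  if (length(groups) != 2L) stop("exactly two groups are required",
                                 call. = FALSE)
  a <- labels == groups[1L]
  b <- labels == groups[2L]
  if (sum(a) < 2L || sum(b) < 2L) {
    stop("each group needs >= 2 samples (variance undefined otherwise)",
         call. = FALSE)
  }
  rows <- lapply(rownames(scores), function(term) {
    x <- scores[term, a]
    y <- scores[term, b]
    if (test == "welch") {
      if (stats::sd(x) == 0 && stats::sd(y) == 0 && mean(x) == mean(y)) {
        stat <- 0
        p <- 1
      } else {
        fit <- stats::t.test(x, y)
        stat <- unname(fit$statistic)
        p <- fit$p.value
      }
    } else {
      fit <- stats::wilcox.test(x, y, exact = FALSE)
      stat <- unname(fit$statistic)
      p <- fit$p.value
    }
    data.frame(term = term, statistic = stat, pvalue = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rank a DE table for GSEA
#'
#' The default GSEA ranking metric over the full gene list: log2 fold
#' change, descending, with the deterministic gene tie-break of
#' [ranked_scores()].
#'
#' @param table a DE table.
#' @param metric `"log2fc"` (default) or `"signed_logp"`
#'   (`sign(log2fc) * -log10(pvalue)`).
#' @return a [ranked_scores()] table.
#' @export
rank_de_table <- function(table, metric = c("log2fc", "signed_logp")) {
  metric <- match.arg(metric)
  validate_de_table(table)
  score <- switch(metric,
    log2fc = table$log2fc,
    signed_logp = sign(table$log2fc) * -log10(pmax(table$pvalue, 1e-300)))
  ranked_scores(table$gene, score)
}
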