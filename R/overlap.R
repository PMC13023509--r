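# Target-integration stage: multi-source union with deduplication and
# intersection with the DEG screen.

#' Union of predicted-target sources
#'
#' Set union over >= 1 source lists after optional symbol uppercasing (the
#' harmonisation mechanism for cross-database matching); duplicates within
#' and across sources collapse.
#'
#' @param sources list of character vectors (one per source).
#' @param uppercase uppercase symbols before the union.
#' @return character vector: the deduplicated union.
#' @export
union_targets <- function(sources, uppercase = FALSE) {
  stopifnot(is.list(sources), length(sources) >= 1L)
  sources <- lapply(sources, function(s) {
    s <- as.character(s)
    if (uppercase) toupper(s) else s
  })
  out <- unique(unlist(sources, use.names = FALSE))
  if (length(out) == 0L) stop("all target sources are empty", call. = FALSE)
  out
}

#' Intersect compound targets with differentially expressed genes
#'
#' @param targets character vector (e.g. the output of [union_targets()]).
#' @param degs a `deg_partition` from [screen_degs()] or a character vector
#'   of DEG symbols.
#' @return character vector: `targets` intersected with the DEGs.
#' @export
intersect_with_degs <- function(targets, degs) {
  deg_genes <- if (inherits(degs, "deg_partition")) degs$all_degs
               else as.character(degs)
  intersect(as.character(targets), deg_genes)
}

#' Build a target-integration report
#'
#' Per-source sizes, the deduplicated union, the intersection with the
#' DEGs, a pairwise source-overlap matrix, and (when a full `deg_partition`
#' is supplied) the up/down status of each intersected target.
#'
#' @inheritParams union_targets
#' @inheritParams intersect_with_degs
#' @return a list of class `overlap_report` with elements `source_sizes`,
#'   `union`, `intersection_with_degs`, `pairwise`, `direction`.
#' @export
overlap_report <- function(sources, degs, uppercase = FALSE) {
  union <- union_targets(sources, uppercase = uppercase)
  norm <- lapply(sources, function(s) {
    s <- unique(as.character(s))
    if (uppercase) unique(toupper(s)) else s
  })
  if (is.null(names(norm))) {
    names(norm) <- sprintf("source_%d", seq_along(norm))
  }
  k <- length(norm)
  pairwise <- matrix(0L, k, k, dimnames = list(names(norm), names(norm)))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      pairwise[i, j] <- length(intersect(norm[[i]], norm[[j]]))
    }
  }
  inter <- intersect_with_degs(union, degs)
  direction <- NULL
  if (inherits(degs, "deg_partition")) {
    direction <- stats::setNames(
      ifelse(inter %in% degs$up, "up", "down"), inter)
  }
  out <- list(source_sizes = lengths(norm), union = union,
              intersection_with_degs = inter, pairwise = pairwise,
              direction = direction)
  class(out) <- "overlap_report"
  out
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("Target integration:", length(x$union), "unique targets from",
      length(x$source_sizes), "sources;",
      length(x$intersection_with_degs), "intersect the DEGs\n")
  invisible(x)
}
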