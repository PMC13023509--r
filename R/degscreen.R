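# Differential-expression screening: multiple-testing adjustment and the
# |log2FC| / adjusted-p cutoff rule.

#' Adjust p-values for multiple testing
#'
#' Benjamini-Hochberg step-up by default (the adjustment implied by the
#' standard DESeq2-style workflow this stage consumes); Bonferroni and a
#' pass-through are available for sensitivity analyses. Values are returned
#' in input order and are elementwise >= the raw p-values.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @param method one of `"bh"`, `"bonferroni"`, `"none"`.
#' @return numeric vector of adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues, method = c("bh", "bonferroni", "none")) {
  method <- match.arg(method)
  if (length(pvalues) == 0L) stop("pvalues must be non-empty", call. = FALSE)
  assert_probabilities(pvalues, "pvalues")
  stats::p.adjust(pvalues, method = switch(method, bh = "BH",
                                           bonferroni = "bonferroni",
                                           none = "none"))
}

#' Screen differentially expressed genes
#'
#' Applies the cutoff rule `|log2fc| > lfc_cut` and `padj < alpha` with both
#' inequalities strict. If the table has no `padj` column, adjusted p-values
#' are computed first with [bh_adjust()] over all retained rows. Rows with
#' missing p-values are excluded before adjustment (mirroring independent
#' filtering in upstream DE tools); the number excluded is reported via
#' `message()`.
#'
#' @param table a DE table (see [read_de_table()]).
#' @param lfc_cut log2 fold-change cutoff (default 0.5).
#' @param alpha adjusted-p cutoff (default 0.05).
#' @param adjust adjustment method passed to [bh_adjust()] when `padj` is
#'   absent.
#' @return a list of class `deg_partition` with elements `up`, `down`,
#'   `all_degs` (character vectors; `up` and `down` are disjoint) and
#'   `table` (the screened table with `padj` and `status` columns).
#' @export
screen_degs <- function(table, lfc_cut = 0.5, alpha = 0.05,
                        adjust = c("bh", "bonferroni", "none")) {
  adjust <- match.arg(adjust)
  validate_de_table(table)
  drop <- is.na(table$pvalue) | is.na(table$log2fc)
  if (any(drop)) {
    message("screen_degs: excluded ", sum(drop),
            " gene(s) with missing log2fc or p-value before adjustment")
    table <- table[!drop, , drop = FALSE]
  }
  if (nrow(table) == 0L) stop("no genes left after removing missing values",
                              call. = FALSE)
  if (!"padj" %in% names(table)) {
    table$padj <- bh_adjust(table$pvalue, method = adjust)
  }
  up <- table$log2fc > lfc_cut & table$padj < alpha
  down <- table$log2fc < -lfc_cut & table$padj < alpha
  table$status <- ifelse(up, "up", ifelse(down, "down", "ns"))
  out <- list(up = table$gene[up], down = table$gene[down],
              all_degs = table$gene[up | down], table = table)
  class(out) <- "deg_partition"
  out
}

#' @export
print.deg_partition <- function(x, ...) {
  cat("DEG partition:", length(x$all_degs), "DEGs (",
      length(x$up), "up,", length(x$down), "down ) of",
      nrow(x$table), "genes\n")
  invisible(x)
}
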