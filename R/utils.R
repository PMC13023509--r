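# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a deterministic 31-bit substream seed
#'
#' Combines a master seed with a stream label so that independent stages
#' (DE table, expression matrix, network growth, per-source walks, ...) get
#' reproducible, non-interfering random streams.
#'
#' @param seed integer master seed.
#' @param label character stream label.
#' @return an integer in `[0, 2^31 - 2]` suitable for [set.seed()].
#' @keywords internal
substream_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed),
            is.character(label), length(label) == 1L)
  h <- 0
  for (code in utf8ToInt(label)) h <- (h * 131 + code) %% 2147483647
  as.integer((h + (as.numeric(seed) %% 2147483647) * 48271) %% 2147483647)
}

# Evaluate `code` under set.seed(seed) without disturbing the caller's RNG.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  code
}

assert_probabilities <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    stop(what, " must be numeric in [0, 1] with no missing values",
         call. = FALSE)
  }
  invisible(x)
}

write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Number formatting used by all score writers: round-trips through read.delim
# to at least 12 significant digits.
format_score <- function(x) formatC(x, digits = 15, format = "g")
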