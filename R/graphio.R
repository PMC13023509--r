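# Readers/writers for the external formats and the in-memory containers
# shared by every stage. Networks are undirected simple igraph objects with
# gene symbols as vertex names; tables are plain data.frames.

#' Construct a PPI network from an edge table
#'
#' Builds an undirected, unweighted, simple graph over gene-symbol nodes.
#' Self-loops and duplicate edges (regardless of endpoint order) are
#' rejected; isolated nodes are permitted via `nodes`.
#'
#' @param from,to character vectors of equal length: edge endpoints.
#' @param nodes optional character vector of node names; must contain every
#'   endpoint. Extra names become isolated nodes.
#' @return an [igraph::igraph] object (undirected, simple, named vertices).
#' @export
ppi_network <- function(from, to, nodes = NULL) {
  stopifnot(is.character(from), is.character(to), length(from) == length(to))
  if (any(!nzchar(from)) || any(!nzchar(to))) {
    stop("gene symbols must be non-empty strings", call. = FALSE)
  }
  if (any(from == to)) stop("self-loops are not allowed", call. = FALSE)
  key <- paste(pmin(from, to), pmax(from, to), sep = "\r")
  if (anyDuplicated(key)) stop("duplicate edges are not allowed", call. = FALSE)
  endpoints <- unique(c(from, to))
  nodes <- if (is.null(nodes)) endpoints else unique(as.character(nodes))
  if (!all(endpoints %in% nodes)) {
    stop("every edge endpoint must be listed in `nodes`", call. = FALSE)
  }
  igraph::graph_from_data_frame(
    data.frame(from = from, to = to, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE)
  )
}

#' Read an undirected PPI edge list
#'
#' Parses a whitespace-delimited text file with one undirected edge per line
#' (first two tokens are the endpoints). Blank lines and lines starting with
#' `#` are skipped. Duplicate edges are collapsed regardless of endpoint
#' order; self-loop lines are dropped with a warning; extra tokens after the
#' first two (e.g. an interaction score column) are ignored with a warning.
#'
#' @param path path to the edge-list file.
#' @param uppercase if `TRUE`, gene symbols are uppercased at read time (for
#'   cross-source matching).
#' @return an undirected simple [igraph::igraph] with named vertices.
#' @export
read_edge_list <- function(path, uppercase = FALSE) {
  lines <- read_text_lines(path)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  if (length(keep) == 0L) {
    stop("edge-list file '", path, "' contains no edges", call. = FALSE)
  }
  tokens <- strsplit(trimws(lines[keep]), "[ \t]+")
  n_tok <- lengths(tokens)
  if (any(n_tok < 2L)) {
    bad <- keep[which(n_tok < 2L)[1L]]
    stop("malformed edge line ", bad, " in '", path,
         "': expected at least two whitespace-separated tokens",
         call. = FALSE)
  }
  if (any(n_tok > 2L)) {
    warning(sum(n_tok > 2L), " edge line(s) carried extra tokens; ",
            "only the first two (the endpoints) were used", call. = FALSE)
  }
  from <- vapply(tokens, `[`, character(1L), 1L)
  to <- vapply(tokens, `[`, character(1L), 2L)
  if (uppercase) {
    from <- toupper(from)
    to <- toupper(to)
  }
  loops <- from == to
  if (any(loops)) {
    warning("dropped ", sum(loops), " self-loop line(s)", call. = FALSE)
    from <- from[!loops]
    to <- to[!loops]
  }
  if (length(from) == 0L) {
    stop("edge-list file '", path, "' contains no valid edges", call. = FALSE)
  }
  key <- paste(pmin(from, to), pmax(from, to), sep = "\r")
  first <- !duplicated(key)
  ppi_network(from[first], to[first])
}

#' Write a network as a whitespace-delimited edge list
#' @param graph an igraph network.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  el <- igraph::as_edgelist(graph, names = TRUE)
  writeLines(paste(el[, 1L], el[, 2L]), path)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard Broad GMT dialect: one set per line,
#' `name <TAB> description <TAB> member1 <TAB> member2 ...`.
#' Members are deduplicated; empty sets and duplicate set names are errors.
#'
#' @param path path to the `.gmt` file.
#' @param uppercase uppercase member symbols at read time.
#' @return a named list of character vectors with a `descriptions` attribute
#'   (named character vector parallel to the sets).
#' @export
read_gmt <- function(path, uppercase = FALSE) {
  lines <- read_text_lines(path)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0L) stop("GMT file '", path, "' is empty", call. = FALSE)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  sets <- vector("list", length(fields))
  descs <- character(length(fields))
  names_out <- character(length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    members <- unique(f[-(1:2)][nzchar(f[-(1:2)])])
    if (length(f) < 3L || length(members) == 0L) {
      stop("GMT line ", keep[i], " in '", path,
           "': expected name, description and at least one member",
           call. = FALSE)
    }
    names_out[i] <- f[1L]
    descs[i] <- f[2L]
    sets[[i]] <- if (uppercase) unique(toupper(members)) else members
  }
  if (anyDuplicated(names_out)) {
    stop("duplicate gene-set name(s) in '", path, "': ",
         paste(unique(names_out[duplicated(names_out)]), collapse = ", "),
         call. = FALSE)
  }
  names(sets) <- names_out
  names(descs) <- names_out
  attr(sets, "descriptions") <- descs
  sets
}

#' Write a gene-set collection in GMT format
#' @param sets named list of character vectors; an optional `descriptions`
#'   attribute supplies the second column (defaults to `"na"`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  descs <- attr(sets, "descriptions") %||%
    stats::setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, descs[[nm]] %||% "na", sets[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a differential-expression summary table
#'
#' Tab-separated with a header; required columns `gene`, `log2fc`, `pvalue`;
#' optional `padj`. Gene symbols must be unique and p-values in `[0, 1]`.
#'
#' @param path path to the TSV file.
#' @return a data.frame with columns `gene`, `log2fc`, `pvalue` and, when
#'   present in the file, `padj`.
#' @export
read_de_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("gene", "log2fc", "pvalue")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("DE table '", path, "' is missing required column(s) ",
         paste(missing, collapse = ", "), "; found columns: ",
         paste(names(df), collapse = ", "), call. = FALSE)
  }
  keep <- intersect(c("gene", "log2fc", "pvalue", "padj"), names(df))
  df <- df[, keep, drop = FALSE]
  df$gene <- as.character(df$gene)
  validate_de_table(df)
  df
}

validate_de_table <- function(df) {
  if (nrow(df) == 0L) stop("DE table is empty", call. = FALSE)
  if (anyDuplicated(df$gene)) {
    stop("duplicate gene symbol(s) in DE table: ",
         paste(unique(df$gene[duplicated(df$gene)]), collapse = ", "),
         call. = FALSE)
  }
  ok <- is.na(df$pvalue) | (df$pvalue >= 0 & df$pvalue <= 1)
  if (!all(ok)) stop("pvalue outside [0, 1] in DE table", call. = FALSE)
  if ("padj" %in% names(df)) {
    ok <- is.na(df$padj) | (df$padj >= 0 & df$padj <= 1)
    if (!all(ok)) stop("padj outside [0, 1] in DE table", call. = FALSE)
  }
  invisible(df)
}

#' Read a plain-text gene list
#'
#' One symbol per line; blank lines and `#` comments skipped; duplicates
#' collapsed.
#'
#' @inheritParams read_edge_list
#' @return a character vector (a gene set).
#' @export
read_gene_list <- function(path, uppercase = FALSE) {
  lines <- trimws(read_text_lines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (uppercase) lines <- toupper(lines)
  unique(lines)
}

#' Write a gene list, one symbol per line
#' @param genes character vector.
#' @param path output path.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}

#' Construct a ranked gene score table
#'
#' Canonical ordering for all score outputs (centralities, RWR visitation,
#' GSEA ranking metrics): descending score with lexicographic gene-symbol
#' tie-break, so the order is deterministic.
#'
#' @param gene character vector of unique gene symbols.
#' @param score numeric vector of scores.
#' @return a data.frame with columns `gene` and `score`, ordered.
#' @export
ranked_scores <- function(gene, score) {
  stopifnot(length(gene) == length(score))
  gene <- as.character(gene)
  if (anyDuplicated(gene)) {
    stop("ranked scores require unique gene symbols", call. = FALSE)
  }
  score <- as.numeric(score)
  if (anyNA(score)) stop("scores must not be missing", call. = FALSE)
  ord <- order(-score, gene, method = "radix")
  out <- data.frame(gene = gene[ord], score = score[ord],
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("ranked_scores", "data.frame")
  out
}

#' Write ranked scores as TSV (rank, gene, score)
#'
#' Scores are written with 15 significant digits so a write/read round trip
#' preserves them to at least 12 significant digits.
#'
#' @param scores a [ranked_scores()] table.
#' @param path output path.
#' @export
write_ranked_scores <- function(scores, path) {
  stopifnot(is.data.frame(scores), all(c("gene", "score") %in% names(scores)))
  out <- data.frame(rank = seq_len(nrow(scores)), gene = scores$gene,
                    score = format_score(scores$score),
                    stringsAsFactors = FALSE)
  write_tsv_plain(out, path)
}

#' Read ranked scores written by [write_ranked_scores()]
#' @param path input path.
#' @return a [ranked_scores()] table (re-validated and re-ordered).
#' @export
read_ranked_scores <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("gene", "score")
  if (!all(required %in% names(df))) {
    stop("ranked-score file '", path, "' must have columns gene and score; ",
         "found: ", paste(names(df), collapse = ", "), call. = FALSE)
  }
  ranked_scores(df$gene, df$score)
}

#' Read an expression matrix (genes x samples)
#'
#' TSV with a header; the first column holds gene symbols, remaining columns
#' one sample each. Duplicate gene or sample identifiers are errors.
#'
#' @param path path to the TSV file.
#' @return a numeric matrix with gene rownames and sample colnames; if the
#'   matrix was written by [write_expression()] with group labels, a `groups`
#'   attribute (named character vector sample -> group) is attached when a
#'   sibling `<path>.groups` file exists.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2L) stop("expression table needs >= 1 sample column",
                          call. = FALSE)
  genes <- as.character(df[[1L]])
  if (anyDuplicated(genes)) stop("duplicate gene symbols in expression table",
                                 call. = FALSE)
  samples <- names(df)[-1L]
  if (anyDuplicated(samples)) stop("duplicate sample identifiers", call. = FALSE)
  mat <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- genes
  groups_path <- paste0(path, ".groups")
  if (file.exists(groups_path)) {
    g <- utils::read.delim(groups_path, stringsAsFactors = FALSE)
    attr(mat, "groups") <- stats::setNames(as.character(g$group),
                                           as.character(g$sample))
  }
  mat
}

#' Write an expression matrix (and optional group labels) as TSV
#' @param mat numeric matrix, gene rownames, sample colnames.
#' @param path output path; group labels (the `groups` attribute, if any) go
#'   to `<path>.groups`.
#' @export
write_expression <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_plain(df, path)
  groups <- attr(mat, "groups")
  if (!is.null(groups)) {
    write_tsv_plain(
      data.frame(sample = names(groups), group = unname(groups),
                 stringsAsFactors = FALSE),
      paste0(path, ".groups"))
  }
  invisible(path)
}

read_text_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: '", path, "'", call. = FALSE)
  readLines(path, warn = FALSE)
}
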