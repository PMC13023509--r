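# Config-driven orchestration of the full run:
# simulate -> deg -> overlap -> rank -> rwr -> enrich.
# Pre-flight validation happens before any output is written; every stage
# records input/output checksums and wall time in the run manifest.

#' Default pipeline configuration
#'
#' All stage parameters default to the screening and walk parameters the
#' pipeline is built around: |log2FC| cutoff 0.5, adjusted-p cutoff 0.05,
#' 10,000 walks of at most 100 steps with restart probability 0.1, and a
#' per-method top-3 consensus. Any element can be overridden via `...`
#' using nested lists, e.g. `pipeline_config(deg = list(alpha = 0.01))`.
#'
#' @param outdir output directory for all stage artifacts.
#' @param seed global master seed.
#' @param ... nested overrides merged over the defaults.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir = "netprior_run", seed = 1L, ...) {
  config <- list(
    version = 1L,
    seed = as.integer(seed),
    outdir = outdir,
    stages = list(simulate = TRUE, deg = TRUE, overlap = TRUE, rank = TRUE,
                  rwr = TRUE, enrich = TRUE),
    inputs = list(edge_list = NULL, de_table = NULL, expression = NULL,
                  gmt = NULL, target_lists = NULL, deg_list = NULL),
    simulate = list(n_genes = 5000L, frac_de = 0.1, effect_mu = 2,
                    null_sd = 0.5, n_samples_per_group = 4L, set_shift = 5,
                    n_nodes = 20L, attach_m = 2L, hub_extra_edges = 12L,
                    n_sources = 4L, per_source_size = 30L,
                    n_gene_sets = 5L, gene_set_size = 50L),
    deg = list(lfc_cut = 0.5, alpha = 0.05, adjust = "bh"),
    overlap = list(uppercase = FALSE),
    rank = list(k = 3L, epc_iters = 1000L, epc_keep = 0.5,
                methods = centrality_methods),
    rwr = list(n_walks = 10000L, max_steps = 100L, restart_prob = 0.1,
               source_mode = "each_node"),
    enrich = list(gsea_exponent = 1, gsea_n_perm = 999L,
                  ssgsea_alpha = 0.25, group_test = "welch"))
  config <- merge_config(config, list(...))
  class(config) <- "pipeline_config"
  config
}

merge_config <- function(base, overrides) {
  for (nm in names(overrides)) {
    if (is.list(base[[nm]]) && is.list(overrides[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], overrides[[nm]])
    } else {
      base[[nm]] <- overrides[[nm]]
    }
  }
  base
}

#' Read / write a pipeline configuration as YAML
#'
#' Configurations round-trip through serialization unchanged (up to YAML's
#' canonical scalar types).
#'
#' @param path YAML file path.
#' @return for `read_pipeline_config`, a `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  config <- do.call(pipeline_config, c(list(outdir = raw$outdir %||% "netprior_run",
                                            seed = raw$seed %||% 1L),
                                       raw[setdiff(names(raw),
                                                   c("outdir", "seed"))]))
  config
}

#' @rdname read_pipeline_config
#' @param config a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the end-to-end prioritization pipeline
#'
#' Executes the enabled stages in dependency order. Before any computation,
#' a pre-flight check verifies that every enabled stage can obtain its
#' inputs either from `config$inputs` (existing files) or from an enabled
#' upstream stage; a failure aborts with the stage name before anything is
#' written. Each stage logs its parameters via `message()` and records
#' input/output MD5 checksums and wall time in the returned manifest
#' (also written to `manifest.json` in the output directory).
#'
#' @param config a [pipeline_config()] (or a path to a YAML config).
#' @return the run manifest (a list), invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  enabled <- names(Filter(isTRUE, config$stages))

  provides <- list(
    simulate = c("edge_list", "de_table", "expression", "gmt", "target_lists",
                 "deg_truth", "hub"),
    deg = "deg_list", overlap = "target_intersection",
    rank = "consensus", rwr = "rwr_ranking", enrich = character(0L))
  requires <- list(
    simulate = character(0L),
    deg = "de_table",
    overlap = c("target_lists", "deg_list"),
    rank = "edge_list",
    rwr = "edge_list",
    enrich = c("de_table", "gmt", "expression"))

  available <- names(Filter(function(p) !is.null(p) && all(file.exists(unlist(p))),
                            config$inputs))
  for (stage in c("simulate", "deg", "overlap", "rank", "rwr", "enrich")) {
    if (!stage %in% enabled) next
    missing <- setdiff(requires[[stage]], available)
    if (length(missing) > 0L) {
      stop("pre-flight: stage '", stage, "' is missing input(s): ",
           paste(missing, collapse = ", "),
           " (not on disk and not produced by an enabled upstream stage)",
           call. = FALSE)
    }
    available <- union(available, provides[[stage]])
  }

  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  for (nm in names(config$inputs)) {
    if (!is.null(config$inputs[[nm]])) paths[[nm]] <- config$inputs[[nm]]
  }
  manifest <- list(tool = "netprior",
                   version = as.character(utils::packageVersion("netprior")),
                   config = unclass(config), stages = list())

  run_stage <- function(name, fn) {
    if (!name %in% enabled) return(invisible(NULL))
    message("[", name, "] starting")
    t0 <- proc.time()[["elapsed"]]
    in_files <- unlist(paths[requires[[name]]], use.names = FALSE)
    out_files <- fn()
    manifest$stages[[name]] <<- list(
      inputs = as.list(tools::md5sum(in_files %||% character(0L))),
      outputs = as.list(tools::md5sum(out_files)),
      elapsed_s = round(proc.time()[["elapsed"]] - t0, 3L))
    invisible(NULL)
  }

  run_stage("simulate", function() stage_simulate(config, paths, environment()))
  run_stage("deg", function() stage_deg(config, paths, environment()))
  run_stage("overlap", function() stage_overlap(config, paths, environment()))
  run_stage("rank", function() stage_rank(config, paths, environment()))
  run_stage("rwr", function() stage_rwr(config, paths, environment()))
  run_stage("enrich", function() stage_enrich(config, paths, environment()))

  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# Each stage_* helper reads the shared `paths` list from the calling
# environment chain and writes back the artifact paths it produced.
set_path <- function(env, name, value) {
  p <- get("paths", envir = parent.env(env))
  p[[name]] <- value
  assign("paths", p, envir = parent.env(env))
  value
}

get_path <- function(env, name) {
  get("paths", envir = parent.env(env))[[name]]
}

stage_simulate <- function(config, paths, env) {
  sim <- config$simulate
  spec <- synthetic_spec(seed = config$seed, n_genes = sim$n_genes,
                         frac_de = sim$frac_de, effect_mu = sim$effect_mu,
                         null_sd = sim$null_sd,
                         n_samples_per_group = sim$n_samples_per_group,
                         set_shift = sim$set_shift, n_nodes = sim$n_nodes,
                         attach_m = sim$attach_m,
                         hub_extra_edges = sim$hub_extra_edges)
  message("[simulate] n_genes=", sim$n_genes, " frac_de=", sim$frac_de,
          " n_nodes=", sim$n_nodes, " seed=", config$seed)
  od <- config$outdir
  de <- gen_de_table(spec)
  genes <- de$table$gene

  # Gene sets: set_1 is the planted (expression-shifted) set, drawn from the
  # planted DE genes so the DE and expression signals agree.
  sets <- with_seed(substream_seed(config$seed, "simulate_sets"), {
    out <- lapply(seq_len(sim$n_gene_sets), function(i) {
      pool <- if (i == 1L && length(de$truth) >= sim$gene_set_size)
        de$truth else genes
      sample(pool, min(sim$gene_set_size, length(pool)))
    })
    names(out) <- sprintf("set_%d", seq_len(sim$n_gene_sets))
    out
  })
  expr <- gen_expression(spec, sets[["set_1"]])

  # Network over target genes: the node names of the grown graph are
  # relabelled with the target core (planted DE genes), so the planted hub
  # is a gene the DEG screen and target intersection can both recover.
  net <- gen_ppi(spec)
  core <- with_seed(substream_seed(config$seed, "simulate_core"),
                    sort(sample(de$truth, sim$n_nodes)))
  graph <- net$graph
  igraph::V(graph)$name <- core[match(igraph::V(graph)$name,
                                      sort(igraph::V(graph)$name))]
  hub_gene <- core[match(net$hub, sort(igraph::V(net$graph)$name))]
  targets <- gen_target_lists(config$seed, universe = genes,
                              n_sources = sim$n_sources,
                              per_source_size = sim$per_source_size,
                              core = core)

  out <- character(0L)
  out <- c(out, set_path(env, "de_table", {
    p <- file.path(od, "de_table.tsv")
    write_tsv_plain(de$table, p)
    p
  }))
  out <- c(out, set_path(env, "deg_truth", {
    p <- file.path(od, "de_truth.txt")
    write_gene_list(de$truth, p)
    p
  }))
  out <- c(out, set_path(env, "expression", {
    p <- file.path(od, "expression.tsv")
    write_expression(expr, p)
    p
  }), file.path(od, "expression.tsv.groups"))
  out <- c(out, set_path(env, "gmt", {
    p <- file.path(od, "gene_sets.gmt")
    write_gmt(sets, p)
    p
  }))
  out <- c(out, set_path(env, "edge_list", {
    p <- file.path(od, "network.edges")
    write_edge_list(graph, p)
    p
  }))
  out <- c(out, set_path(env, "hub", {
    p <- file.path(od, "planted_hub.txt")
    write_gene_list(hub_gene, p)
    p
  }))
  target_paths <- vapply(names(targets), function(nm) {
    p <- file.path(od, paste0("targets_", nm, ".txt"))
    write_gene_list(targets[[nm]], p)
    p
  }, character(1L))
  set_path(env, "target_lists", unname(target_paths))
  c(out, unname(target_paths))
}

stage_deg <- function(config, paths, env) {
  prm <- config$deg
  message("[deg] lfc_cut=", prm$lfc_cut, " alpha=", prm$alpha,
          " adjust=", prm$adjust)
  tab <- read_de_table(get_path(env, "de_table"))
  part <- screen_degs(tab, lfc_cut = prm$lfc_cut, alpha = prm$alpha,
                      adjust = prm$adjust)
  od <- config$outdir
  annotated <- file.path(od, "deg_annotated.tsv")
  part$table$padj <- format_score(part$table$padj)
  part$table$log2fc <- format_score(part$table$log2fc)
  part$table$pvalue <- format_score(part$table$pvalue)
  write_tsv_plain(part$table, annotated)
  up <- file.path(od, "deg_up.txt")
  down <- file.path(od, "deg_down.txt")
  all <- file.path(od, "deg_all.txt")
  write_gene_list(part$up, up)
  write_gene_list(part$down, down)
  write_gene_list(part$all_degs, all)
  set_path(env, "deg_list", all)
  set_path(env, "deg_up", up)
  set_path(env, "deg_down", down)
  c(annotated, up, down, all)
}

stage_overlap <- function(config, paths, env) {
  message("[overlap] uppercase=", isTRUE(config$overlap$uppercase))
  target_files <- get_path(env, "target_lists")
  sources <- lapply(target_files, read_gene_list,
                    uppercase = isTRUE(config$overlap$uppercase))
  names(sources) <- sub("\\.txt$", "", basename(target_files))
  degs <- read_gene_list(get_path(env, "deg_list"))
  rep <- overlap_report(sources, degs,
                        uppercase = isTRUE(config$overlap$uppercase))
  od <- config$outdir
  report_path <- file.path(od, "overlap_report.tsv")
  write_tsv_plain(
    data.frame(source = names(rep$source_sizes),
               size = as.integer(rep$source_sizes),
               stringsAsFactors = FALSE),
    report_path)
  inter_path <- file.path(od, "target_intersection.txt")
  write_gene_list(rep$intersection_with_degs, inter_path)
  union_path <- file.path(od, "target_union.txt")
  write_gene_list(rep$union, union_path)
  set_path(env, "target_intersection", inter_path)
  c(report_path, inter_path, union_path)
}

stage_rank <- function(config, paths, env) {
  prm <- config$rank
  message("[rank] k=", prm$k, " methods=", length(prm$methods),
          " epc_iters=", prm$epc_iters, " epc_keep=", prm$epc_keep)
  graph <- read_edge_list(get_path(env, "edge_list"))
  rep <- consensus(graph, methods = prm$methods, k = prm$k,
                   epc_iters = prm$epc_iters, epc_keep = prm$epc_keep,
                   seed = config$seed)
  od <- config$outdir
  method_paths <- vapply(names(rep$scores), function(m) {
    p <- file.path(od, paste0("centrality_", m, ".tsv"))
    write_ranked_scores(rep$scores[[m]], p)
    p
  }, character(1L))
  consensus_path <- file.path(od, "consensus_hubs.txt")
  write_gene_list(rep$consensus, consensus_path)
  set_path(env, "consensus", consensus_path)
  c(unname(method_paths), consensus_path)
}

stage_rwr <- function(config, paths, env) {
  prm <- config$rwr
  message("[rwr] n_walks=", prm$n_walks, " max_steps=", prm$max_steps,
          " restart_prob=", prm$restart_prob, " source_mode=",
          prm$source_mode)
  graph <- read_edge_list(get_path(env, "edge_list"))
  sources <- NULL
  if (identical(prm$source_mode, "given_set")) {
    inter_path <- get_path(env, "target_intersection")
    if (is.null(inter_path)) {
      stop("rwr stage with source_mode = 'given_set' needs the overlap ",
           "stage (or explicit sources)", call. = FALSE)
    }
    sources <- intersect(read_gene_list(inter_path),
                         igraph::V(graph)$name)
  }
  res <- mc_rwr(graph, n_walks = prm$n_walks, max_steps = prm$max_steps,
                restart_prob = prm$restart_prob, seed = config$seed,
                source_mode = prm$source_mode, sources = sources)
  od <- config$outdir
  rank_path <- file.path(od, "rwr_ranking.tsv")
  write_ranked_scores(res$ranking, rank_path)
  meta_path <- file.path(od, "rwr_meta.json")
  jsonlite::write_json(c(res$config, list(sources = res$sources,
                                          total_steps_counted =
                                            res$total_steps_counted)),
                       meta_path, auto_unbox = TRUE, digits = NA)
  set_path(env, "rwr_ranking", rank_path)
  c(rank_path, meta_path)
}

stage_enrich <- function(config, paths, env) {
  prm <- config$enrich
  message("[enrich] gsea_exponent=", prm$gsea_exponent, " n_perm=",
          prm$gsea_n_perm, " ssgsea_alpha=", prm$ssgsea_alpha)
  tab <- read_de_table(get_path(env, "de_table"))
  sets <- read_gmt(get_path(env, "gmt"))
  od <- config$outdir
  out <- character(0L)

  # ORA of the target/DEG intersection (falling back to the DEGs) against
  # the DE gene universe.
  query_path <- get_path(env, "target_intersection") %||%
    get_path(env, "deg_list")
  if (!is.null(query_path)) {
    query <- read_gene_list(query_path)
    if (length(query) > 0L) {
      res <- ora(query, sets, universe = tab$gene)
      res$pvalue <- format_score(res$pvalue)
      res$padj <- format_score(res$padj)
      p <- file.path(od, "ora.tsv")
      write_tsv_plain(res, p)
      out <- c(out, p)
    }
  }

  # Full-gene-list GSEA, ranked by log2 fold change.
  ranked <- rank_de_table(tab)
  gsea_rows <- lapply(names(sets), function(term) {
    r <- gsea_permutation_p(ranked, sets[[term]],
                            exponent = prm$gsea_exponent,
                            n_perm = prm$gsea_n_perm,
                            seed = substream_seed(config$seed,
                                                  paste0("gsea:", term)))
    data.frame(term = term, es = format_score(r$es),
               perm_pvalue = format_score(r$perm_pvalue),
               n_perm = r$n_perm, n_hits = r$n_hits,
               stringsAsFactors = FALSE)
  })
  p <- file.path(od, "gsea.tsv")
  write_tsv_plain(do.call(rbind, gsea_rows), p)
  out <- c(out, p)

  # Per-sample ssGSEA plus the two-group score comparison.
  expr <- read_expression(get_path(env, "expression"))
  scores <- ssgsea_score(expr, sets, alpha = prm$ssgsea_alpha)
  p <- file.path(od, "ssgsea.tsv")
  score_df <- data.frame(term = rownames(scores),
                         apply(scores, 2L, format_score),
                         check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_plain(score_df, p)
  out <- c(out, p)
  groups <- attr(expr, "groups")
  if (!is.null(groups)) {
    tests <- compare_group_scores(scores, groups, test = prm$group_test)
    tests$statistic <- format_score(tests$statistic)
    tests$pvalue <- format_score(tests$pvalue)
    p <- file.path(od, "ssgsea_tests.tsv")
    write_tsv_plain(tests, p)
    out <- c(out, p)
  }
  out
}
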