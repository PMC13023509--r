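# Seeded generators producing inputs with the statistical structure the
# pipeline assumes: a DE table with a planted fraction of shifted genes, an
# expression matrix with a planted gene-set shift between two small groups,
# a scale-free-like PPI network with a planted hub, and overlapping target
# lists from several pseudo-sources. All generators are pure functions of
# their spec: the master seed is split into named substreams so each stage
# is reproducible independently of the others.

#' Specification for the synthetic study conditions
#'
#' Defaults encode the emulated study design: a two-group comparison with
#' four samples per group, a differential-expression screen at |log2FC| >
#' 0.5 / adjusted p < 0.05, and a small protein-interaction network with a
#' single dominant hub to recover.
#'
#' @param seed integer master seed.
#' @param n_genes number of genes in the DE table / expression matrix.
#' @param frac_de fraction of genes planted as differentially expressed.
#' @param effect_mu mean |log2 fold change| of planted DE genes.
#' @param null_sd standard deviation of null log2 fold changes (also the
#'   scale used to convert planted effects into z-scores and p-values).
#' @param n_samples_per_group samples per group in the expression matrix.
#' @param set_shift additive expression shift applied to planted gene-set
#'   members in group B.
#' @param n_nodes number of network nodes.
#' @param attach_m edges added per incoming node during preferential
#'   attachment (must be `< n_nodes`).
#' @param hub_extra_edges extra edges wired into the planted hub after
#'   growth, making it the unique maximum-degree node.
#' @return a list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L, n_genes = 5000L, frac_de = 0.1,
                           effect_mu = 2, null_sd = 0.5,
                           n_samples_per_group = 4L, set_shift = 5,
                           n_nodes = 20L, attach_m = 2L,
                           hub_extra_edges = 12L) {
  spec <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
               frac_de = frac_de, effect_mu = effect_mu, null_sd = null_sd,
               n_samples_per_group = as.integer(n_samples_per_group),
               set_shift = set_shift, n_nodes = as.integer(n_nodes),
               attach_m = as.integer(attach_m),
               hub_extra_edges = as.integer(hub_extra_edges))
  stopifnot(spec$n_genes >= 1L, spec$frac_de >= 0, spec$frac_de <= 1,
            spec$null_sd > 0, spec$n_samples_per_group >= 1L,
            spec$n_nodes >= 2L, spec$attach_m >= 1L,
            spec$attach_m < spec$n_nodes, spec$hub_extra_edges >= 0L)
  class(spec) <- "synthetic_spec"
  spec
}

synthetic_gene_names <- function(n) {
  sprintf("G%0*d", max(4L, nchar(as.character(n))), seq_len(n))
}

#' Generate a differential-expression summary table with planted signal
#'
#' Null genes receive `log2fc ~ Normal(0, null_sd)` and independent
#' `p ~ Uniform(0, 1)`. Planted genes receive `log2fc = s * effect_mu +
#' Normal(0, null_sd)` with a random sign `s`, and a p-value equal to the
#' two-sided normal tail of the z-score `|log2fc| / null_sd`, so larger
#' effects give smaller p-values. The adjusted-p column is left absent; it
#' is computed downstream by the screening stage.
#'
#' @param spec a [synthetic_spec()].
#' @return a list with `table` (data.frame: gene, log2fc, pvalue) and
#'   `truth` (character vector of planted DE genes).
#' @export
gen_de_table <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(substream_seed(spec$seed, "de_table"), {
    genes <- synthetic_gene_names(spec$n_genes)
    n_de <- round(spec$frac_de * spec$n_genes)
    planted <- if (n_de > 0L) sort(sample(genes, n_de)) else character(0L)
    is_de <- genes %in% planted
    lfc <- stats::rnorm(spec$n_genes, 0, spec$null_sd)
    sgn <- sample(c(-1, 1), spec$n_genes, replace = TRUE)
    lfc[is_de] <- lfc[is_de] + sgn[is_de] * spec$effect_mu
    p <- stats::runif(spec$n_genes)
    p[is_de] <- 2 * stats::pnorm(-abs(lfc[is_de]) / spec$null_sd)
    tab <- data.frame(gene = genes, log2fc = lfc, pvalue = p,
                      stringsAsFactors = FALSE)
    list(table = tab, truth = planted)
  })
}

#' Generate a two-group expression matrix with a planted gene-set shift
#'
#' Baseline values are `Normal(0, 1)`; members of `gene_set` have
#' `set_shift` added in every group-B sample. Group labels are attached as
#' the `groups` attribute (`"A"` = control-like, `"B"` = exposed-like).
#'
#' @param spec a [synthetic_spec()].
#' @param gene_set character vector of planted-set members; must be a subset
#'   of the generated gene universe.
#' @return a numeric genes-by-samples matrix with a `groups` attribute.
#' @export
gen_expression <- function(spec, gene_set) {
  stopifnot(inherits(spec, "synthetic_spec"), is.character(gene_set))
  genes <- synthetic_gene_names(spec$n_genes)
  if (!all(gene_set %in% genes)) {
    stop("gene_set contains symbols outside the generated gene universe",
         call. = FALSE)
  }
  k <- spec$n_samples_per_group
  samples <- c(sprintf("ctrl_%d", seq_len(k)), sprintf("expo_%d", seq_len(k)))
  with_seed(substream_seed(spec$seed, "expression"), {
    mat <- matrix(stats::rnorm(spec$n_genes * 2L * k), nrow = spec$n_genes,
                  dimnames = list(genes, samples))
    mat[rownames(mat) %in% gene_set, k + seq_len(k)] <-
      mat[rownames(mat) %in% gene_set, k + seq_len(k)] + spec$set_shift
    attr(mat, "groups") <- stats::setNames(rep(c("A", "B"), each = k), samples)
    mat
  })
}

#' Generate a scale-free-like PPI network with a planted hub
#'
#' Growth: `attach_m` seed nodes with no edges; each incoming node attaches
#' `attach_m` edges to distinct existing nodes sampled with probability
#' proportional to degree + 1, giving exactly `attach_m * (n_nodes -
#' attach_m)` edges and a connected graph. Hub planting: a node is chosen
#' uniformly among non-maximum-degree nodes that (a) have at least
#' `hub_extra_edges` non-neighbors and (b) will strictly exceed every other
#' degree even if the current maximum-degree node gains one edge; it then
#' receives `hub_extra_edges` edges to uniformly chosen non-neighbors,
#' making it the unique maximum-degree node.
#'
#' @param spec a [synthetic_spec()].
#' @return a list with `graph` (igraph) and `hub` (the planted hub's name).
#' @export
gen_ppi <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_nodes
  m <- spec$attach_m
  nodes <- sprintf("N%02d", seq_len(n))
  with_seed(substream_seed(spec$seed, "ppi"), {
    deg <- integer(n)
    from <- character(0L)
    to <- character(0L)
    for (i in seq.int(m + 1L, n)) {
      existing <- seq_len(i - 1L)
      targets <- if (length(existing) == m) existing else
        sample(existing, m, prob = deg[existing] + 1)
      from <- c(from, rep(nodes[i], m))
      to <- c(to, nodes[targets])
      deg[i] <- deg[i] + m
      deg[targets] <- deg[targets] + 1L
    }
    maxdeg <- max(deg)
    candidates <- which(deg < maxdeg &
                          (n - 1L - deg) >= spec$hub_extra_edges &
                          deg + spec$hub_extra_edges > maxdeg + 1L)
    if (spec$hub_extra_edges > 0L && length(candidates) == 0L) {
      stop("hub_extra_edges is too large to keep the graph simple (or too ",
           "small to make the hub the unique maximum-degree node)",
           call. = FALSE)
    }
    hub_idx <- if (spec$hub_extra_edges > 0L) {
      candidates[sample.int(length(candidates), 1L)]
    } else {
      which.max(deg)
    }
    if (spec$hub_extra_edges > 0L) {
      hub <- nodes[hub_idx]
      nbr <- unique(c(to[from == hub], from[to == hub]))
      non_nbr <- setdiff(nodes[-hub_idx], nbr)
      new_to <- sample(non_nbr, spec$hub_extra_edges)
      from <- c(from, rep(hub, spec$hub_extra_edges))
      to <- c(to, new_to)
    }
    list(graph = ppi_network(from, to, nodes = nodes), hub = nodes[hub_idx])
  })
}

#' Generate overlapping target lists from several pseudo-sources
#'
#' Every source contains `core`; the remaining members are sampled without
#' replacement from `universe` minus `core`, independently per source, so
#' the lists overlap partially (as predicted-target databases do).
#'
#' @param seed integer seed.
#' @param universe character vector of candidate symbols.
#' @param n_sources number of pseudo-sources.
#' @param per_source_size total size of each source list (>= `length(core)`).
#' @param core character vector planted into every source.
#' @return a named list (`source_1`, ...) of character vectors.
#' @export
gen_target_lists <- function(seed, universe, n_sources = 4L,
                             per_source_size, core = character(0L)) {
  universe <- unique(as.character(universe))
  core <- unique(as.character(core))
  if (!all(core %in% universe)) {
    stop("core must be a subset of universe", call. = FALSE)
  }
  if (per_source_size < length(core) || per_source_size > length(universe)) {
    stop("per_source_size must lie in [length(core), length(universe)]",
         call. = FALSE)
  }
  pool <- setdiff(universe, core)
  with_seed(substream_seed(seed, "target_lists"), {
    out <- lapply(seq_len(n_sources), function(i) {
      extras <- if (per_source_size > length(core)) {
        sample(pool, per_source_size - length(core))
      } else {
        character(0L)
      }
      c(core, extras)
    })
    names(out) <- sprintf("source_%d", seq_len(n_sources))
    out
  })
}
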