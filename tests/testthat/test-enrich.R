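test_that("ORA reproduces the exact hypergeometric tail", {
  u <- paste0("x", 1:10)
  sets <- list(S = u[1:5])
  res <- ora(u[1:5], sets, u)
  expect_equal(res$pvalue, 1 / 252, tolerance = 1e-12)  # 1 / C(10, 5)
  expect_equal(res$overlap_size, 5)

  disjoint <- ora(u[6:10], sets, u)
  expect_equal(disjoint$pvalue, 1)

  # query = universe: overlap is forced, the event is certain
  full <- ora(u, list(S = u[1:5], T = u[2:4]), u)
  expect_equal(full$pvalue, c(1, 1))
})

test_that("ORA p-values equal exhaustive subset enumeration on small universes", {
  for (cfg in list(c(N = 8, m = 3, q = 4), c(N = 10, m = 5, q = 5),
                   c(N = 12, m = 6, q = 3), c(N = 15, m = 7, q = 6))) {
    N <- cfg[["N"]]; m <- cfg[["m"]]; q <- cfg[["q"]]
    u <- paste0("g", seq_len(N))
    for (k in 0:min(m, q)) {
      if (q - k > N - m) next
      query <- c(u[seq_len(k)], u[m + seq_len(q - k)])
      res <- ora(query, list(S = u[seq_len(m)]), u)
      expect_equal(res$pvalue, oracle_ora_tail(N, m, q, k), tolerance = 1e-12)
    }
  }
})

test_that("ORA validates inputs, drops out-of-universe genes, and sorts results", {
  u <- paste0("g", 1:20)
  sets <- list(B = u[1:5], A = u[1:5], C = u[15:20])
  expect_warning(res <- ora(c(u[1:5], "zz"), sets, u), "outside the universe")
  expect_equal(res$term, c("A", "B", "C"))  # p tie broken by term name
  expect_true(all(diff(res$pvalue) >= 0))
  expect_true(all(res$padj >= res$pvalue))
  expect_error(ora(character(0), sets, u), "query is empty")
  expect_error(ora(u[1], sets, character(0)), "universe is empty")
})

test_that("GSEA enrichment score matches hand-walked running sums", {
  r <- ranked_scores(paste0("g", 1:4), c(4, 3, 2, 1))
  # set = top gene, p = 0: +1 at position 1, then -1/3 per miss
  expect_equal(gsea_es(r, "g1", exponent = 0), 1)
  # set at the bottom: running sum -1/3, -2/3, -1, 0
  expect_equal(gsea_es(r, "g4", exponent = 0), -1)
  expect_equal(gsea_es(r, paste0("g", 1:4)), 1)  # degenerate all-member set
  expect_error(gsea_es(r, "absent"), "no members")
})

test_that("GSEA enrichment score agrees with fgsea's statistic", {
  skip_if_not_installed("fgsea")
  set.seed(31)
  for (i in 1:10) {
    n <- 50
    scores <- sort(rnorm(n), decreasing = TRUE)
    genes <- paste0("g", seq_len(n))
    r <- ranked_scores(genes, scores)
    members <- sample(genes, 8)
    ours <- gsea_es(r, members, exponent = 1)
    theirs <- fgsea::calcGseaStat(setNames(scores, genes),
                                  selectedStats = which(genes %in% members),
                                  gseaParam = 1)
    expect_equal(ours, theirs, tolerance = 1e-9)
  }
})

test_that("GSEA permutation p-values are deterministic and detect planted signal", {
  set.seed(5)
  n <- 200
  genes <- paste0("g", 1:n)
  scores <- rnorm(n)
  members <- sample(genes, 20)
  scores[genes %in% members] <- scores[genes %in% members] + 2
  r <- ranked_scores(genes, scores)
  a <- gsea_permutation_p(r, members, n_perm = 199, seed = 42)
  b <- gsea_permutation_p(r, members, n_perm = 199, seed = 42)
  expect_identical(a, b)
  expect_lt(a$perm_pvalue, 0.05)
  expect_gt(a$es, 0)

  # a null set is not flagged
  null_set <- sample(setdiff(genes, members), 20)
  null_scores <- rnorm(n)
  null_p <- gsea_permutation_p(ranked_scores(genes, null_scores), null_set,
                               n_perm = 199, seed = 1)
  expect_gt(null_p$perm_pvalue, 0.001)
})

test_that("ssGSEA matches the two-position hand computation and flags degenerate sets", {
  m <- matrix(c(2, 1), nrow = 2, dimnames = list(c("hi", "lo"), "s1"))
  expect_equal(ssgsea_score(m, list(t = "hi"), alpha = 0)[1, 1], 1)
  expect_equal(ssgsea_score(m, list(t = "lo"), alpha = 0)[1, 1], -1)
  expect_error(ssgsea_score(m, list(t = c("hi", "lo"))), "covers every gene")
  expect_error(ssgsea_score(m, list(bad = "zz")), "'bad'")
})

test_that("ssGSEA is invariant under strictly monotone per-sample transforms", {
  set.seed(8)
  mat <- matrix(rnorm(200 * 6), 200, 6,
                dimnames = list(paste0("g", 1:200), paste0("s", 1:6)))
  sets <- list(a = paste0("g", 1:20), b = paste0("g", 50:70))
  base <- ssgsea_score(mat, sets)
  warped <- mat
  warped[, 1] <- exp(mat[, 1])          # strictly increasing
  warped[, 2] <- mat[, 2] * 7 + 100     # affine positive
  expect_equal(ssgsea_score(warped, sets), base, tolerance = 1e-12)
})

test_that("group comparison handles degenerate, swapped and planted cases", {
  scores <- matrix(c(1, 1, 1, 1, 1, 1, 1, 1), nrow = 1,
                   dimnames = list("t", paste0("s", 1:8)))
  labels <- setNames(rep(c("A", "B"), each = 4), paste0("s", 1:8))
  res <- compare_group_scores(scores, labels)
  expect_equal(res$statistic, 0)
  expect_equal(res$pvalue, 1)

  scores2 <- matrix(c(1, 2, 3, 4, 10, 11, 12, 13), nrow = 1,
                    dimnames = list("t", paste0("s", 1:8)))
  fwd <- compare_group_scores(scores2, labels)
  swapped <- setNames(rep(c("B", "A"), each = 4), paste0("s", 1:8))
  rev <- compare_group_scores(scores2, swapped)
  expect_equal(fwd$statistic, -rev$statistic, tolerance = 1e-12)
  expect_equal(fwd$pvalue, rev$pvalue, tolerance = 1e-12)

  small <- setNames(c("A", "B", "B", "B", "B", "B", "B", "B"),
                    paste0("s", 1:8))
  expect_error(compare_group_scores(scores2, small), ">= 2 samples")

  wil <- compare_group_scores(scores2, labels, test = "wilcoxon")
  expect_lt(wil$pvalue, 0.05)
})

test_that("a planted expression shift is detected by the ssGSEA group test", {
  hits <- 0L
  for (s in 1:20) {
    spec <- synthetic_spec(seed = s, n_genes = 1000, set_shift = 5)
    genes <- sprintf("G%04d", 1:1000)
    set <- list(planted = genes[1:50])
    mat <- gen_expression(spec, set$planted)
    sc <- ssgsea_score(mat, set)
    p <- compare_group_scores(sc, attr(mat, "groups"))$pvalue
    if (p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 19)
})

test_that("DE tables rank deterministically for GSEA", {
  tab <- data.frame(gene = c("a", "b", "c"), log2fc = c(1, 2, 1),
                    pvalue = c(0.5, 0.01, 0.2))
  r <- rank_de_table(tab)
  expect_equal(r$gene, c("b", "a", "c"))
  r2 <- rank_de_table(tab, metric = "signed_logp")
  expect_equal(r2$gene[1], "b")
})
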