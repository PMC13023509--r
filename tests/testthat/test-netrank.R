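star5 <- ppi_network(rep("c", 4), paste0("l", 1:4))
triangle <- ppi_network(c("A", "B", "A"), c("B", "C", "C"))
path3 <- ppi_network(c("A", "B"), c("B", "C"))

test_that("centralities reproduce the worked small-graph cases", {
  deg <- scores_in_order(centrality_scores(star5, "Degree"),
                         igraph::V(star5)$name)
  expect_equal(unname(deg["c"]), 4)
  expect_true(all(deg[paste0("l", 1:4)] == 1))

  mcc <- centrality_scores(triangle, "MCC")
  expect_true(all(mcc$score == 2))  # single maximal clique K3: (3-1)! = 2

  btw <- scores_in_order(centrality_scores(path3, "Betweenness"),
                         c("A", "B", "C"))
  expect_equal(unname(btw), c(0, 1, 0))
  stress <- scores_in_order(centrality_scores(path3, "Stress"),
                            c("A", "B", "C"))
  expect_equal(unname(stress), c(0, 1, 0))

  mnc <- scores_in_order(centrality_scores(star5, "MNC"),
                         igraph::V(star5)$name)
  expect_equal(unname(mnc["c"]), 1)  # 4 isolated leaves in the neighborhood

  # a node whose maximal cliques are all edges scores its degree under MCC
  mcc_star <- scores_in_order(centrality_scores(star5, "MCC"),
                              igraph::V(star5)$name)
  expect_equal(unname(mcc_star["c"]), 4)
})

test_that("EPC with full edge retention equals the component-fraction closed form", {
  g <- ppi_network(c("A", "B", "D"), c("B", "C", "E"),
                   nodes = c("A", "B", "C", "D", "E", "F"))
  sc <- scores_in_order(centrality_scores(g, "EPC", epc_iters = 5,
                                          epc_keep = 1, seed = 1),
                        igraph::V(g)$name)
  expect_equal(unname(sc), c(3, 3, 3, 2, 2, 1) / 6)
})

test_that("unknown centrality names are rejected listing the nine methods", {
  expect_error(centrality_scores(star5, "PageRank"), "EcCentricity")
  expect_length(centrality_methods, 9)
})

test_that("all nine centralities match the brute-force oracle on random graphs", {
  for (s in 1:30) {
    A <- random_connected_adjacency(1000 + s)
    g <- adjacency_to_network(A)
    nodes <- rownames(A)
    expected <- oracle_centralities(A, epc_iters = 50, epc_keep = 0.5,
                                    seed = s)
    for (method in centrality_methods) {
      got <- scores_in_order(
        centrality_scores(g, method, epc_iters = 50, epc_keep = 0.5,
                          seed = s), nodes)
      expect_equal(unname(got), unname(expected[[method]]),
                   tolerance = 1e-10,
                   label = sprintf("%s on seed %d", method, s))
    }
  }
})

test_that("top_k expands ties at the k-th score", {
  expect_setequal(top_k(ranked_scores(c("A", "B", "C", "D"), c(3, 2, 1, 0))),
                  c("A", "B", "C"))
  expect_setequal(top_k(ranked_scores(c("A", "B", "C", "D"), c(3, 1, 1, 1))),
                  c("A", "B", "C", "D"))
  expect_setequal(top_k(ranked_scores(c("A", "B"), c(1, 0)), k = 5),
                  c("A", "B"))
})

test_that("consensus keeps the star center, totals full ties, and ignores method order", {
  cons <- consensus(star5, k = 1, seed = 1)
  expect_true("c" %in% cons$consensus)
  for (m in centrality_methods) {
    expect_true("c" %in% cons$top_sets[[m]],
                label = paste("star center under", m))
  }

  edgeless <- ppi_network(character(0), character(0),
                          nodes = c("A", "B", "C"))
  all3 <- consensus(edgeless, k = 3, seed = 1)
  expect_setequal(all3$consensus, c("A", "B", "C"))

  fwd <- consensus(triangle, methods = centrality_methods, seed = 4)
  bwd <- consensus(triangle, methods = rev(centrality_methods), seed = 4)
  expect_equal(fwd$consensus, bwd$consensus)
})

test_that("random walks obey the forced, closed-form and symmetric cases", {
  lonely <- ppi_network(character(0), character(0), nodes = "only")
  res <- mc_rwr(lonely, n_walks = 50, max_steps = 10, seed = 1)
  expect_equal(unname(res$visit_fraction), 1)

  g2 <- ppi_network("A", "B")
  mc <- mc_rwr(g2, source_mode = "given_set", sources = "A", seed = 3)
  expect_equal(unname(mc$visit_fraction["A"]), 0.1 / 0.19, tolerance = 0.05)
  expect_lt(abs(mc$visit_fraction[["A"]] - 0.1 / 0.19), 0.02)
  expect_equal(sum(mc$visit_fraction), 1, tolerance = 1e-9)
  expect_equal(mc$total_steps_counted, 10000 * 101)

  tri <- mc_rwr(triangle, source_mode = "given_set", sources = "A", seed = 5)
  expect_lt(abs(tri$visit_fraction[["B"]] - tri$visit_fraction[["C"]]), 0.02)

  expect_error(mc_rwr(g2, restart_prob = 0), "strictly inside")
  expect_error(mc_rwr(g2, restart_prob = 1), "strictly inside")
  expect_error(mc_rwr(g2, source_mode = "given_set", sources = character(0)),
               "non-empty")
  expect_error(mc_rwr(g2, source_mode = "given_set", sources = "Z"),
               "not in the graph")
})

test_that("walk results are reproducible and source-order independent", {
  net <- gen_ppi(synthetic_spec(seed = 12))
  a <- mc_rwr(net$graph, n_walks = 500, max_steps = 20, seed = 9)
  b <- mc_rwr(net$graph, n_walks = 500, max_steps = 20, seed = 9)
  expect_identical(a$visit_fraction, b$visit_fraction)

  nodes <- igraph::V(net$graph)$name
  fwd <- mc_rwr(net$graph, n_walks = 200, max_steps = 20, seed = 9,
                source_mode = "given_set", sources = nodes[1:5])
  rev <- mc_rwr(net$graph, n_walks = 200, max_steps = 20, seed = 9,
                source_mode = "given_set", sources = rev(nodes[1:5]))
  expect_equal(fwd$visit_fraction, rev$visit_fraction)
})

test_that("exact personalized PageRank solves its stationary equation", {
  g2 <- ppi_network("A", "B")
  pp <- ppr_exact(g2, "A", restart_prob = 0.1)
  expect_equal(pp$score[pp$gene == "A"], 0.1 / 0.19, tolerance = 1e-9)
  expect_equal(pp$score[pp$gene == "B"], 0.09 / 0.19, tolerance = 1e-9)
  expect_equal(sum(pp$score), 1, tolerance = 1e-9)

  # restart -> 1 limit returns the source distribution
  lim <- ppr_exact(g2, "A", restart_prob = 1 - 1e-9)
  expect_equal(lim$score[lim$gene == "A"], 1, tolerance = 1e-6)

  # complete graph with uniform sources is uniform
  k4 <- ppi_network(c("A", "A", "A", "B", "B", "C"),
                    c("B", "C", "D", "C", "D", "D"))
  uni <- ppr_exact(k4, c("A", "B", "C", "D"), restart_prob = 0.3)
  expect_equal(uni$score, rep(0.25, 4), tolerance = 1e-9)

  expect_error(ppr_exact(g2, "Z"), "not in the graph")
  expect_error(ppr_exact(g2, "A", restart_prob = 0), "strictly inside")
  expect_error(ppr_exact(g2, "A", tol = 0, max_iter = 3), "did not converge")
})

test_that("exact PPR agrees with igraph's personalized PageRank", {
  net <- gen_ppi(synthetic_spec(seed = 21))
  nodes <- igraph::V(net$graph)$name
  src <- nodes[4]
  ours <- scores_in_order(ppr_exact(net$graph, src, restart_prob = 0.1),
                          nodes)
  reset <- as.numeric(nodes == src)
  theirs <- igraph::page_rank(net$graph, damping = 0.9,
                              personalized = reset)$vector
  expect_equal(unname(ours), unname(theirs[nodes]), tolerance = 1e-8)
})

test_that("Monte Carlo visitation converges to the exact distribution", {
  net <- gen_ppi(synthetic_spec(seed = 33, n_nodes = 15))
  nodes <- igraph::V(net$graph)$name
  src <- nodes[2]
  mc <- mc_rwr(net$graph, n_walks = 4000, max_steps = 100, seed = 2,
               source_mode = "given_set", sources = src)
  exact <- scores_in_order(ppr_exact(net$graph, src, 0.1), nodes)
  tv <- sum(abs(mc$visit_fraction[nodes] - exact)) / 2
  expect_lt(tv, 0.05)
  expect_gt(cor(mc$visit_fraction[nodes], exact, method = "spearman"), 0.9)
})
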