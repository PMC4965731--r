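test_that("degree, coreness, and clustering match hand-derived values", {
  p3 <- g_path(3)
  expect_equal(unname(degree(p3)), c(1, 2, 1))
  expect_equal(sum(degree(g_complete(4))), 2 * 6)

  tri_pendant <- network(rbind(c("a", "b"), c("b", "c"), c("c", "a"),
                               c("c", "d")))
  expect_equal(unname(coreness(tri_pendant)), c(2, 2, 2, 1))
  expect_equal(unname(coreness(tri_pendant)), as.numeric(oracle_coreness(tri_pendant)))
  expect_equal(unname(coreness(g_path(4))), rep(1, 4))
  expect_equal(unname(coreness(g_complete(4))), rep(3, 4))

  expect_equal(unname(clustering_coefficient(g_complete(3))), rep(1, 3))
  expect_equal(unname(clustering_coefficient(g_path(3)))[2], 0)
  k4_minus <- network(rbind(c("a", "b"), c("a", "c"), c("a", "d"),
                            c("b", "c"), c("c", "d")))  # K4 minus edge b-d
  expect_equal(unname(clustering_coefficient(k4_minus))[1], 2 / 3)
})

test_that("shortest-path summary counts geodesics exactly", {
  sp <- shortest_paths(g_path(3))
  expect_equal(sp$dist["a", "c"], 2)
  expect_equal(sp$count["a", "c"], 1)
  expect_equal(geodesic_through_count(sp, "a", "c", "b"), 1)

  sp4 <- shortest_paths(g_cycle(4))
  expect_equal(sp4$count["a", "c"], 2)

  disc <- network(cbind("a", "b"), vertices = c("a", "b", "z"))
  expect_equal(shortest_paths(disc)$dist["a", "z"], Inf)
})

test_that("betweenness follows the ordered-pair convention", {
  expect_equal(unname(betweenness(g_path(3))), c(0, 2, 0))
  expect_equal(unname(betweenness(g_complete(3))), rep(0, 3))
  st <- g_star(3)
  expect_equal(betweenness(st)[["hub"]], 6)
  expect_equal(unname(betweenness(st, halve = TRUE))[1], 3)
  # cross-check against igraph's unordered-pair betweenness
  rg <- random_connected_graph(101)
  expect_equal(unname(betweenness(rg)),
               2 * unname(igraph::betweenness(as_igraph(rg), weights = NA)),
               tolerance = 1e-9)
})

test_that("closeness is the harmonic sum with unreachable terms = 0", {
  expect_equal(closeness(g_path(3))[["b"]], 2)
  expect_equal(unname(closeness(g_complete(4))), rep(3, 4))
  disc <- network(cbind("a", "b"), vertices = c("a", "b", "z"))
  expect_equal(closeness(disc)[["z"]], 0)
  expect_equal(closeness(disc)[["a"]], 1)
})

test_that("proximity prestige and barycenter follow their formulas", {
  expect_equal(unname(proximity_prestige(g_complete(4))), rep(1, 4))
  expect_equal(proximity_prestige(g_path(3))[["a"]], 2 / 3)
  expect_equal(barycenter(g_path(3))[["b"]], 1 / 2)
  expect_equal(unname(barycenter(g_complete(4))), rep(1 / 3, 4))
  disc <- network(cbind("a", "b"), vertices = c("a", "b", "z"))
  expect_equal(proximity_prestige(disc)[["z"]], 0)
  expect_equal(barycenter(disc)[["z"]], 0)
})

test_that("eigenvector centrality matches closed forms and dense eigen", {
  for (n in c(3, 5)) {
    expect_equal(unname(eigenvector_centrality(g_complete(n))),
                 rep(1 / sqrt(n), n), tolerance = 1e-8)
  }
  ev <- eigenvector_centrality(g_star(3))
  expect_equal(ev[["hub"]], 1 / sqrt(2), tolerance = 1e-8)
  expect_equal(ev[["leaf1"]], 1 / sqrt(6), tolerance = 1e-8)
  edgeless <- network(matrix(character(), ncol = 2), vertices = c("a", "b"))
  expect_error(eigenvector_centrality(edgeless), "edgeless")
  # bipartite graph: power iteration must still converge
  bip <- g_cycle(4)
  expect_equal(unname(eigenvector_centrality(bip)), rep(0.5, 4),
               tolerance = 1e-8)
})

test_that("Katz index solves the walk series and enforces convergence", {
  k2 <- g_complete(2)
  expect_equal(unname(katz_index(k2, alpha = 0.5)), c(1, 1))
  expect_error(katz_index(k2, alpha = 1.5), "diverges")
  disc <- network(cbind("a", "b"), vertices = c("a", "b", "z"))
  expect_equal(katz_index(disc, alpha = 0.3)[["z"]], 0)
  rg <- random_connected_graph(7)
  expect_equal(unname(katz_index(rg, alpha = 0.1)),
               oracle_katz(rg, 0.1), tolerance = 1e-10)
})

test_that("subgraph centrality equals the closed-walk series", {
  iso <- network(matrix(character(), ncol = 2), vertices = "a")
  expect_equal(subgraph_centrality(iso)[["a"]], 1)
  expect_equal(subgraph_centrality(g_complete(2))[["a"]], cosh(1),
               tolerance = 1e-12)
  expect_equal(subgraph_centrality(g_complete(3))[["a"]],
               (exp(2) + 2 * exp(-1)) / 3, tolerance = 1e-9)
})

test_that("module detection separates cliques and components", {
  two_tri <- network(rbind(c("a", "b"), c("b", "c"), c("c", "a"),
                           c("x", "y"), c("y", "z"), c("z", "x")))
  mc <- detect_modules(two_tri, method = "components")
  expect_equal(length(unique(mc)), 2L)
  expect_equal(length(unique(detect_modules(g_path(4), "components"))), 1L)

  # two K5s joined by one edge: the greedy method separates the cliques,
  # and the 2-block partition beats the 1-block partition on modularity
  v1 <- paste0("a", 1:5); v2 <- paste0("b", 1:5)
  edges <- rbind(t(combn(v1, 2)), t(combn(v2, 2)), c(v1[1], v2[1]))
  barbell <- network(edges)
  mg <- detect_modules(barbell)
  expect_equal(length(unique(mg[v1])), 1L)
  expect_equal(length(unique(mg[v2])), 1L)
  expect_true(mg[[v1[1]]] != mg[[v2[1]]])
  two_block <- ifelse(barbell$vertices %in% v1, 1L, 2L)
  expect_gt(oracle_modularity(barbell, two_block),
            oracle_modularity(barbell, rep(1L, 10)))
})

test_that("within-module z-score standardizes within-module degree", {
  st <- g_star(3)
  mods <- detect_modules(st, "components")
  z <- within_module_zscore(st, mods)
  expect_equal(z[["hub"]], 1.5 / sqrt(0.75), tolerance = 1e-12)  # pop. sd
  expect_equal(sum(z), 0, tolerance = 1e-12)
  # equal within-degrees => zero spread => all z = 0
  expect_equal(unname(within_module_zscore(g_cycle(4),
                                           detect_modules(g_cycle(4), "components"))),
               rep(0, 4))
  expect_error(within_module_zscore(st, c(hub = 1L)), "every vertex")
})

test_that("k-step Markov is a probability vector with known fixed points", {
  expect_equal(unname(k_step_markov(g_complete(2), k = 5)), c(0.5, 0.5))
  expect_equal(unname(k_step_markov(g_star(3), k = 6)), rep(0.25, 4))
  expect_error(k_step_markov(g_path(3), k = -1), "nonnegative")
  for (seed in 1:5) {
    rg <- random_connected_graph(seed)
    p <- k_step_markov(rg, k = sample(0:8, 1))
    expect_true(all(p >= 0))
    expect_equal(sum(p), 1, tolerance = 1e-12)
  }
  # start-set restriction and absorbing isolated vertices
  disc <- network(cbind("a", "b"), vertices = c("a", "b", "z"))
  p <- k_step_markov(disc, k = 3, start = "z")
  expect_equal(p[["z"]], 1)
})

test_that("structural-hole constraint matches the aggregate formula", {
  expect_equal(unname(structural_holes(g_complete(2))), c(1, 1))
  st <- g_star(3)
  expect_equal(structural_holes(st)[["hub"]], 1 / 3)
  expect_equal(structural_holes(st)[["leaf1"]], 1)
  expect_equal(structural_holes(g_complete(3))[["a"]], 1.125)
  iso <- network(matrix(character(), ncol = 2), vertices = "a")
  expect_equal(structural_holes(iso)[["a"]], 0)
})

test_that("compute_all returns the 13 columns in fixed order", {
  ft <- compute_all(g_path(3))
  expect_identical(names(ft), c("vertex", feature_names()))
  expect_equal(ft$degree, c(1, 2, 1))
  expect_equal(compute_all(g_complete(4))$betweenness, rep(0, 4))
  expect_true(all(vapply(ft[feature_names()], is.numeric, logical(1))))
  expect_true(all(is.finite(as.matrix(ft[feature_names()]))))
})

test_that("all measures are equivariant under vertex relabeling", {
  for (seed in c(3, 17)) {
    net <- random_connected_graph(seed)
    ft <- compute_all(net)
    set.seed(seed)
    new_names <- sprintf("w%02d", sample(vcount(net)))
    eperm <- sample(ecount(net))
    pnet <- network(cbind(new_names[net$edges[eperm, 1]],
                          new_names[net$edges[eperm, 2]]),
                    vertices = sample(new_names))
    pft <- compute_all(pnet)
    idx <- match(new_names, pft$vertex)
    for (col in setdiff(feature_names(), "within_module_z")) {
      expect_equal(pft[[col]][idx], ft[[col]], tolerance = 1e-8,
                   label = paste("relabeled", col))
    }
  }
})

test_that("adding an edge never decreases endpoint degree or coreness", {
  for (seed in c(5, 9, 21)) {
    net <- random_connected_graph(seed)
    A <- adjacency_matrix(net)
    miss <- which(upper.tri(A) & A == 0, arr.ind = TRUE)
    if (nrow(miss) == 0L) next
    pick <- miss[1L, ]
    v <- net$vertices
    bigger <- network(rbind(cbind(v[net$edges[, 1]], v[net$edges[, 2]]),
                            c(v[pick[1]], v[pick[2]])), vertices = v)
    expect_true(all(degree(bigger) >= degree(net)))
    expect_true(all(coreness(bigger) >= coreness(net)))
  }
})
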