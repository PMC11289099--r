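# Weighted PPI construction, greedy dense-module search, normalization,
# top selection, overlap and permutation enrichment.

test_that("weighted PPI drops self-loops and duplicate edges, assigns
           conservative weights to unscored nodes", {
  edges <- data.frame(from = c("a", "b", "a"), to = c("b", "a", "a"))
  g <- suppressMessages(build_weighted_ppi(
    edges, data.frame(gene = "a", z_gene = 1.5)))
  expect_identical(igraph::ecount(g), 1)
  z <- setNames(igraph::V(g)$z, igraph::V(g)$name)
  expect_equal(unname(z["a"]), 1.5)
  expect_equal(unname(z["b"]), -8.2)
  expect_error(build_weighted_ppi(edges[0, ]), "empty")
})

test_that("star graph with a heavy center keeps the module at the seed", {
  edges <- data.frame(from = "c0", to = paste0("l", 1:5))
  gs <- data.frame(gene = c("c0", paste0("l", 1:5)), z_gene = c(3, rep(0, 5)))
  g <- build_weighted_ppi(edges, gs)
  mods <- dense_module_search(g, d = 2, r = 0.1, seeds = "c0")
  expect_identical(module_members(mods)[[1]], "c0")
  expect_equal(mods$Zm, 3)
})

test_that("equal weights stop module growth once sqrt(k) gains fall below
           1 + r", {
  # chain of equal z: Zm = z*sqrt(k). With single-node additions (strict
  # adjacency) the growth factor sqrt((k+1)/k) drops below 1.1 at k = 5;
  # with distance-2 admission each step adds two nodes, so the factor
  # sqrt((k+2)/k) sustains growth to k = 11.
  edges <- data.frame(from = paste0("n", sprintf("%02d", 1:19)),
                      to = paste0("n", sprintf("%02d", 2:20)))
  gs <- data.frame(gene = paste0("n", sprintf("%02d", 1:20)), z_gene = 1)
  g <- build_weighted_ppi(edges, gs)
  strict <- dense_module_search(g, d = 1, r = 0.1, strict_adjacent = TRUE)
  expect_true(all(strict$k <= 5))
  expect_equal(max(strict$Zm), sqrt(max(strict$k)), tolerance = 1e-12)
  mods <- dense_module_search(g, d = 2, r = 0.1)
  expect_true(all(mods$k <= 11))
  expect_equal(max(mods$Zm), sqrt(max(mods$k)), tolerance = 1e-12)
})

test_that("greedy search matches the independent step-by-step oracle on
           random small graphs", {
  n_match <- 0L
  n_graphs <- 300L
  for (i in seq_len(n_graphs)) {
    gr <- random_small_graph(5000 + i)
    g <- build_weighted_ppi(gr$edges, gr$z)
    seed_node <- sort(igraph::V(g)$name)[1]
    mods <- dense_module_search(g, d = 2, r = 0.1, seeds = seed_node)
    oracle <- oracle_module_search(gr$edges, gr$z, seed_node, d = 2, r = 0.1)
    expect_identical(module_members(mods)[[1]], oracle$members)
    expect_equal(mods$Zm, oracle$zm, tolerance = 1e-12)
    n_match <- n_match + 1L
  }
  expect_identical(n_match, n_graphs)
})

test_that("every emitted module satisfies the stopping criterion and Zm is
           reconstructable", {
  set.seed(30)
  ppi <- simulate_ppi(80, 2, 8, seed = 8)
  gs <- data.frame(gene = ppi$nodes, z_gene = rnorm(80))
  g <- build_weighted_ppi(ppi$edges, gs)
  z <- setNames(igraph::V(g)$z, igraph::V(g)$name)
  adj <- lapply(igraph::adjacent_vertices(g, igraph::V(g)$name),
                function(v) v$name)
  names(adj) <- igraph::V(g)$name
  mods <- dense_module_search(g, d = 2, r = 0.1)
  members <- module_members(mods)
  for (i in seq_len(nrow(mods))) {
    mem <- members[[i]]
    expect_lt(abs(mods$Zm[i] - sum(z[mem]) / sqrt(length(mem))), 1e-12)
    # no distance-1 or distance-2 candidate may still beat Zm * (1 + r)
    n1 <- setdiff(unique(unlist(adj[mem])), mem)
    s <- sum(z[mem]); k <- length(mem)
    if (length(n1))
      expect_true(all((s + z[n1]) / sqrt(k + 1) <= mods$Zm[i] * 1.1 + 1e-12))
    n2 <- setdiff(unique(unlist(adj[n1])), c(mem, n1))
    for (v in n2) {
      ints <- intersect(adj[[v]], n1)
      best_int <- max(z[ints])
      expect_lte((s + z[v] + best_int) / sqrt(k + 2),
                 mods$Zm[i] * 1.1 + 1e-12)
    }
  }
})

test_that("module normalization centers no-signal networks and flags planted
           signal", {
  ppi <- simulate_ppi(60, 2, 6, seed = 12)
  # all weights equal: Zn approximately 0 everywhere
  g_eq <- build_weighted_ppi(ppi$edges,
                             data.frame(gene = ppi$nodes, z_gene = 0.7))
  mods_eq <- dense_module_search(g_eq, d = 2, r = 0.1)
  mods_eq <- normalize_modules(mods_eq, g_eq, B_norm = 10000, seed = 5)
  expect_true(all(abs(mods_eq$Zn) < 0.2))
  # planted high-z module scores above the random-set 99th percentile
  set.seed(13)
  z <- rnorm(60)
  names(z) <- ppi$nodes
  z[ppi$planted] <- z[ppi$planted] + 4
  g_pl <- build_weighted_ppi(ppi$edges, z)
  mods <- dense_module_search(g_pl, d = 2, r = 0.1)
  mods <- normalize_modules(mods, g_pl, B_norm = 2000, seed = 5)
  k_best <- mods$k[which.max(mods$Zn)]
  null_zn <- replicate(2000, sum(sample(z, k_best)) / sqrt(k_best))
  null_zn <- (null_zn - mean(null_zn)) / sd(null_zn)
  expect_gt(max(mods$Zn), quantile(null_zn, 0.99))
  # determinism under the same seed
  mods2 <- normalize_modules(dense_module_search(g_pl, d = 2, r = 0.1),
                             g_pl, B_norm = 2000, seed = 5)
  expect_identical(mods$Zn, mods2$Zn)
})

test_that("top-percent selection uses the ceiling and deterministic
           tie-breaks", {
  n <- 13897
  mods <- data.frame(seed = sprintf("s%05d", seq_len(n)),
                     members = sprintf("s%05d", seq_len(n)),
                     k = 1L, Zm = rev(seq_len(n)) / n,
                     Zn = rev(seq_len(n)) / n)
  class(mods) <- c("pg_modules", "data.frame")
  top <- top_percent_modules(mods, q = 0.01)
  expect_identical(nrow(top$modules), 139L)
  expect_identical(nrow(top_percent_modules(mods, q = 1)$modules),
                   as.integer(n))
  # Zn ties resolved by Zm then seed name
  tie <- data.frame(seed = c("b", "a", "c"), members = c("b", "a", "c"),
                    k = 1L, Zm = c(2, 1, 2), Zn = c(1, 1, 1))
  class(tie) <- c("pg_modules", "data.frame")
  sel <- top_percent_modules(tie, q = 0.5)
  expect_identical(sel$modules$seed, c("b", "c"))
})

test_that("overlap test equals brute-force hypergeometric enumeration", {
  t1 <- overlap_test(n_a = 577, n_b = 175, n_overlap = 14,
                     universe_size = 16420)
  expect_equal(t1$p, hyper_tail_oracle(14, 577, 175, 16420),
               tolerance = 1e-12)
  # 2x2 table of ones: enumeration gives 5/6
  t2 <- overlap_test(n_a = 2, n_b = 2, n_overlap = 1, universe_size = 4)
  expect_equal(t2$p, 5 / 6, tolerance = 1e-12)
  expect_equal(t2$p, hyper_tail_oracle(1, 2, 2, 4), tolerance = 1e-12)
  # complete overlap: point-mass probability, the minimum attainable
  t3 <- overlap_test(n_a = 5, n_b = 5, n_overlap = 5, universe_size = 20)
  expect_equal(t3$p, 1 / choose(20, 5), tolerance = 1e-12)
  expect_error(overlap_test(n_a = 30, n_b = 2, n_overlap = 1,
                            universe_size = 20), "universe")
})

test_that("first-degree network extracts loci plus direct neighbors", {
  edges <- data.frame(from = c("hub", "hub", "hub", "x"),
                      to = c("a", "b", "c", "y"))
  g <- build_weighted_ppi(edges)
  sub <- first_degree_network(g, "hub")
  expect_setequal(igraph::V(sub)$name, c("hub", "a", "b", "c"))
  # isolated risk node: subnetwork is itself
  sub2 <- first_degree_network(g, c("x"), pqtl_proteins = "y")
  expect_setequal(igraph::V(sub2)$name, c("x", "y"))
  # shared neighbors appear once
  edges3 <- data.frame(from = c("r1", "r2"), to = c("n", "n"))
  sub3 <- first_degree_network(build_weighted_ppi(edges3), c("r1", "r2"))
  expect_identical(sum(igraph::V(sub3)$name == "n"), 1L)
  expect_error(first_degree_network(g, "absent"), "no risk locus")
})

test_that("permutation enrichment honors the add-one convention and its
           extremes", {
  ppi <- simulate_ppi(50, 2, 5, seed = 14)
  g <- build_weighted_ppi(ppi$edges)
  nodes <- igraph::V(g)$name
  # reference set = all nodes: every permutation ties, empirical p = 1
  pe_all <- permutation_enrichment(g, nodes[1:10], nodes, B = 200, seed = 3)
  expect_equal(pe_all$empirical_p, 1)
  # observed overlap beats every permutation: p = 1/(B+1)
  # (a neighbor set equal to the pqtl set of size 25 in a 50-node universe
  #  has overlap 25; random sets of size 25 essentially never reach that)
  pe_min <- permutation_enrichment(g, nodes[1:25], nodes[1:25], B = 1000,
                                   seed = 4)
  expect_equal(pe_min$empirical_p, 1 / 1001)
  # invariance to node relabeling
  relab <- setNames(sprintf("R%02d", seq_along(nodes)), nodes)
  edges_r <- data.frame(from = relab[ppi$edges$from],
                        to = relab[ppi$edges$to])
  g_r <- build_weighted_ppi(edges_r)
  pe_r <- permutation_enrichment(g_r, unname(relab[nodes[1:25]]),
                                 unname(relab[nodes[1:25]]), B = 1000,
                                 seed = 4)
  expect_equal(pe_r$empirical_p, pe_min$empirical_p)
})

test_that("an overwhelming planted signal is recovered by the best module", {
  jacc <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  ok <- 0L
  reps <- 50L
  for (i in seq_len(reps)) {
    ppi <- simulate_ppi(150, 2, 8, seed = 100 + i)
    set.seed(100 + i)
    z <- setNames(rnorm(150), ppi$nodes)
    z[ppi$planted] <- 5              # planted weight 5 SD above the null
    g <- build_weighted_ppi(ppi$edges, z)
    mods <- dense_module_search(g, d = 2, r = 0.1)
    mods <- normalize_modules(mods, g, B_norm = 500, seed = i)
    best <- module_members(mods)[[which.max(mods$Zn)]]
    if (jacc(best, ppi$planted) >= 0.6) ok <- ok + 1L
  }
  expect_gte(ok / reps, 0.80)
})

test_that("permutation enrichment is calibrated under the null", {
  ppi <- simulate_ppi(100, 2, 5, seed = 15)
  g <- build_weighted_ppi(ppi$edges)
  nodes <- igraph::V(g)$name
  B <- 199
  reps <- 200
  set.seed(16)
  emp <- vapply(seq_len(reps), function(i) {
    nb <- sample(nodes, 20)
    pq <- sample(nodes, 30)
    permutation_enrichment(g, nb, pq, B = B, seed = 9000 + i)$empirical_p
  }, numeric(1))
  frac05 <- mean(emp <= 0.05)
  expect_gte(frac05, 0.02)
  expect_lte(frac05, 0.08)
})
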