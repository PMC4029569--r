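test_that("generate_network is seeded, simple, connected, heavy-tailed", {
  n1 <- generate_network(100, seed = 5)
  n2 <- generate_network(100, seed = 5)
  expect_identical(n1, n2)
  expect_false(identical(n1, generate_network(100, seed = 6)))
  g <- as_igraph(n1)
  expect_true(igraph::is_connected(g))
  expect_false(igraph::any_multiple(g))
  # hubs exist under preferential attachment
  expect_gte(max(igraph::degree(g)), 7)
  # erdos-renyi p = 1 on 10 nodes is complete
  full <- generate_network(10, model = "erdos-renyi", er_p = 1, seed = 1)
  expect_equal(nrow(full$edges), choose(10, 2))
  expect_error(generate_network(5), ">= 10")
})

test_that("plant_modules wires edge-disjoint spanning trees into the graph", {
  base <- generate_network(50, seed = 2)
  pl <- plant_modules(base, list(list(n_genes = 13, trajectory = rep(0, 5),
                                      name = "m1"),
                                 list(n_genes = 6, trajectory = rep(0, 5),
                                      name = "m2")), seed = 3)
  tr <- pl$truth
  expect_length(tr$groups$m1$edges, 12L)
  expect_length(tr$groups$m2$edges, 5L)
  # planted edges exist in the network; the groups are edge-disjoint
  expect_true(all(tr$groups$m1$edges %in% pl$net$edges$key))
  expect_length(intersect(tr$groups$m1$edges, tr$groups$m2$edges), 0L)
  # each group's edge set forms one connected tree
  comp <- seed_components(tr$groups$m1$edges, pl$net)
  expect_length(comp, 1L)
  expect_error(plant_modules(base, list(list(n_genes = 3,
                                             trajectory = c(0.999, 0, 0, 0, 0)))),
               "0.99")
})

test_that("generate_expression hits the planted correlation targets", {
  sizes <- c(a = 200L, b = 200L, c = 200L)
  sim <- simulate_dataset(n_background_nodes = 40, stage_sizes = sizes,
                          groups = list(list(n_genes = 8,
                                             trajectory = c(0.7, 0, -0.5),
                                             name = "m1")),
                          seed = 12)
  pr <- edge_profiles(sim$expr, sim$design, sim$net)
  planted <- pr[pr$key %in% sim$truth$groups$m1$edges, ]
  for (k in 1:3) {
    got <- planted[[paste0("r_", names(sizes)[k])]]
    # per-group calibration at n = 200 per stage
    expect_lt(abs(mean(got) - sim$truth$groups$m1$trajectory[k]), 0.05)
  }
  # background edges stay near zero (n = 200 -> tight)
  bg <- pr[!grepl("^m1", pr$key), ]
  expect_lt(max(abs(bg$r_a)), 0.3)
  # determinism end to end
  sim2 <- simulate_dataset(n_background_nodes = 40, stage_sizes = sizes,
                           groups = list(list(n_genes = 8,
                                              trajectory = c(0.7, 0, -0.5),
                                              name = "m1")),
                           seed = 12)
  expect_identical(sim$expr, sim2$expr)
  expect_identical(sim$net, sim2$net)
})

test_that("target r = 0.9 in one stage yields the expected dC signature", {
  sizes <- c(s1 = 200L, s2 = 200L, s3 = 200L, s4 = 200L, s5 = 200L)
  sim <- simulate_dataset(n_background_nodes = 40, stage_sizes = sizes,
                          groups = list(list(n_genes = 6,
                                             trajectory = c(0, 0.9, 0, 0, 0),
                                             name = "m1")),
                          seed = 8)
  pr <- edge_profiles(sim$expr, sim$design, sim$net)
  planted <- pr[pr$key %in% sim$truth$groups$m1$edges, ]
  dc <- as.matrix(planted[, paste0("dC_", 1:4)])
  target <- c(fisher_transform(0.9), -fisher_transform(0.9), 0, 0)
  expect_equal(fisher_transform(0.9), 1.47222, tolerance = 1e-5)
  expect_lt(max(abs(sweep(dc, 2, target))), 0.25)
})

test_that("opposite planted trajectories separate under clustering", {
  sim <- simulate_dataset(
    n_background_nodes = 60,
    stage_sizes = c(s1 = 50L, s2 = 50L, s3 = 50L, s4 = 50L, s5 = 50L),
    groups = list(list(n_genes = 8, trajectory = c(0, 0.9, 0.9, 0, 0),
                       name = "up"),
                  list(n_genes = 8, trajectory = c(0.9, 0, 0, 0.9, 0.9),
                       name = "dn")),
    seed = 42)
  pr <- edge_profiles(sim$expr, sim$design, sim$net)
  keys <- c(sim$truth$groups$up$edges, sim$truth$groups$dn$edges)
  dc <- as.matrix(pr[match(keys, pr$key), paste0("dC_", 1:4)])
  rownames(dc) <- keys
  cl <- cluster_edges(dc, k = 2)
  m <- recovery_metrics(sim$truth, cl)
  expect_equal(m$rand, 1.0)
})

test_that("recovery_metrics computes set arithmetic correctly", {
  base <- generate_network(30, seed = 9)
  pl <- plant_modules(base, list(list(n_genes = 5, trajectory = rep(0, 2),
                                      name = "m1")), seed = 9)
  tr_edges <- pl$truth$groups$m1$edges  # 4 edges
  perfect <- recovery_metrics(pl$truth, tr_edges)
  expect_equal(perfect[c("precision", "recall", "jaccard")],
               list(precision = 1, recall = 1, jaccard = 1))
  none <- recovery_metrics(pl$truth, base$edges$key[1:5])
  expect_equal(none$precision, 0)
  expect_equal(none$recall, 0)
  half <- recovery_metrics(pl$truth, c(tr_edges[1:2], "zz|zz2", "zz3|zz4"))
  expect_equal(half$precision, 0.5)
  expect_equal(half$recall, 0.5)
  expect_equal(half$jaccard, 2 / 6)
})

test_that("mock gene sets enrich planted genes by the stated factor", {
  base <- generate_network(400, seed = 14)
  pl <- plant_modules(base, list(list(n_genes = 40, trajectory = rep(0, 2),
                                      name = "m1")), seed = 14)
  sets <- mock_gene_sets(pl$net, pl$truth, background_rate = 0.05,
                         enrichment_factor = 5, seed = 15)
  planted <- pl$truth$groups$m1$genes
  rate_planted <- mean(planted %in% sets$markersA)
  rate_bg <- mean(setdiff(pl$net$nodes, planted) %in% sets$markersA)
  expect_gt(rate_planted, rate_bg)  # direction, given sampling noise
})

test_that("simulate_dataset writes a readable text bundle", {
  dir <- withr::local_tempdir()
  sim <- simulate_dataset(n_background_nodes = 50,
                          stage_sizes = c(x = 4L, y = 4L),
                          groups = list(list(n_genes = 4,
                                             trajectory = c(0, 0.8),
                                             name = "m1")),
                          seed = 77, out_dir = dir)
  got <- read_expression(sim$paths$expression, sim$paths$design)
  expect_equal(got$expr, sim$expr, tolerance = 1e-9)
  expect_equal(got$design$stages, c("x", "y"))
  net <- read_network(sim$paths$network)
  expect_identical(net$edges$key, sim$net$edges$key)
  sets <- read_gene_sets(sim$paths$gene_sets)
  expect_equal(sets, sim$gene_sets)
  truth <- jsonlite::fromJSON(sim$paths$truth)
  expect_equal(sort(truth$m1$edges), sim$truth$groups$m1$edges)
})
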