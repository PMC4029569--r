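test_that("fisher_transform matches the closed form and its properties", {
  expect_equal(fisher_transform(0), 0)
  expect_equal(fisher_transform(0.5), 0.54931, tolerance = 1e-5)
  expect_equal(fisher_transform(-0.5), -fisher_transform(0.5))
  expect_error(fisher_transform(1.2), "outside")
  # clamping keeps +/-1 finite
  expect_true(is.finite(fisher_transform(1)))
  expect_equal(fisher_transform(1), -fisher_transform(-1))
  # strictly increasing and expanding on a grid
  grid <- seq(-0.95, 0.95, by = 0.05)
  z <- fisher_transform(grid)
  expect_true(all(diff(z) > 0))
  expect_true(all(abs(z) >= abs(grid) - 1e-12))
})

test_that("correlation_pvalue follows the exact t null", {
  expect_equal(correlation_pvalue(0, 10), 1)
  expect_equal(correlation_pvalue(0.76, 10), 0.0107385274, tolerance = 1e-8)
  expect_equal(correlation_pvalue(1, 10), 0)
  expect_equal(correlation_pvalue(-0.76, 10), correlation_pvalue(0.76, 10))
  expect_error(correlation_pvalue(0.5, 2), "n >= 3")
  # agrees with cor.test on random draws
  set.seed(11)
  for (i in 1:5) {
    x <- rnorm(12); y <- rnorm(12)
    ct <- cor.test(x, y)
    expect_equal(correlation_pvalue(unname(ct$estimate), 12), ct$p.value,
                 tolerance = 1e-10)
  }
})

test_that("edge_profiles fills r, R and dC per the model", {
  design <- toy_design(c(s1 = 3L, s2 = 3L, s3 = 3L))
  net <- toy_net(c("A", "B"), c("C", "D"))
  # A == B exactly (r = 1 everywhere); C vs D varies
  expr <- rbind(A = c(1, 2, 3, 4, 5, 6, 7, 8, 9),
                B = c(1, 2, 3, 4, 5, 6, 7, 8, 9),
                C = c(1, 2, 3, 3, 2, 1, 1, 3, 2),
                D = c(1, 2, 3, 1, 2, 3, 1, 2, 3))
  colnames(expr) <- names(design$assignment)
  pr <- edge_profiles(expr, design, net)
  expect_s3_class(pr, "edge_profiles")
  expect_equal(nrow(pr), 2L)
  # perfect correlation rows clamped but finite
  ab <- pr[pr$key == "A|B", ]
  expect_equal(unlist(ab[paste0("r_", c("s1", "s2", "s3"))]),
               c(r_s1 = 1, r_s2 = 1, r_s3 = 1))
  expect_true(all(is.finite(attr(pr, "R"))))
  # constant R trajectory -> zero dC
  expect_equal(unname(unlist(ab[c("dC_1", "dC_2")])), c(0, 0))
  # K stages -> K-1 dC entries
  expect_equal(sum(grepl("^dC_", names(pr))), 2L)
  # hand-check C|D at stage 2: cor((3,2,1),(1,2,3)) = -1
  cd <- pr[pr$key == "C|D", ]
  expect_equal(cd$r_s2, -1)
})

test_that("dC is antisymmetric under stage reversal and telescopes", {
  design <- toy_design(c(s1 = 4L, s2 = 4L, s3 = 4L, s4 = 4L, s5 = 4L))
  set.seed(3)
  genes <- sprintf("n%02d", 1:8)  # same namespace as random_toy_net
  expr <- matrix(rnorm(8 * 20), 8, 20,
                 dimnames = list(genes, names(design$assignment)))
  net <- restrict_network(random_toy_net(8, 10), expr)
  pr <- edge_profiles(expr, design, net)
  dc <- pr[, grep("^dC_", names(pr))]
  # telescoping: sum of dC = R_K - R_1
  R <- attr(pr, "R")
  expect_equal(rowSums(dc), R[, 5] - R[, 1], tolerance = 1e-12,
               ignore_attr = TRUE)
  # reversal negates and flips each dC entry
  rev_design <- stage_design(design$assignment, stages = rev(design$stages))
  pr_rev <- edge_profiles(expr, rev_design, net)
  dc_rev <- pr_rev[, grep("^dC_", names(pr_rev))]
  expect_equal(as.matrix(dc_rev), -as.matrix(dc)[, 4:1],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("zero-variance genes yield r = 0 with a flag, keeping dC complete", {
  design <- toy_design(c(s1 = 3L, s2 = 3L))
  net <- toy_net(c("A", "B"))
  expr <- rbind(A = c(5, 5, 5, 1, 2, 3), B = c(1, 2, 3, 4, 5, 6))
  colnames(expr) <- names(design$assignment)
  pr <- edge_profiles(expr, design, net)
  expect_true(pr$zero_var[1])
  expect_equal(pr$r_s1[1], 0)
  expect_equal(pr$dC_1[1], fisher_transform(1) - 0)
})

test_that("sample r converges to the planted target as n grows", {
  sizes <- rep(200L, 5); names(sizes) <- c("N", "C", "D", "E", "A")
  sim <- simulate_dataset(n_background_nodes = 60, stage_sizes = sizes,
                          groups = list(list(n_genes = 6,
                                             trajectory = c(0, 0.9, -0.6, 0.3, 0),
                                             name = "mod1")),
                          seed = 21)
  pr <- edge_profiles(sim$expr, sim$design, sim$net)
  planted <- pr[pr$key %in% sim$truth$groups$mod1$edges, ]
  rmat <- as.matrix(planted[, paste0("r_", c("N", "C", "D", "E", "A"))])
  # per-group calibration: the group's mean r per stage tracks the target
  expect_lt(max(abs(colMeans(rmat) - c(0, 0.9, -0.6, 0.3, 0))), 0.05)
})

test_that("ks_background_test is one-sided in the stated direction", {
  set.seed(5)
  bg <- runif(400)
  same <- ks_background_test(bg, bg)
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  up <- pmin(bg + 0.3, 1)
  expect_lt(ks_background_test(up, bg)$p.value, 1e-6)
  # background above the edges: the "greater" alternative sees nothing
  expect_gt(ks_background_test(bg, up)$p.value, 0.9)
  expect_error(ks_background_test(numeric(), bg), "non-empty")
})

test_that("background_abs_r draws seeded non-edge pairs", {
  design <- toy_design(c(s1 = 10L, s2 = 10L))
  set.seed(2)
  genes <- sprintf("G%02d", 1:30)
  expr <- matrix(rnorm(30 * 20), 30, 20,
                 dimnames = list(genes, names(design$assignment)))
  net <- ppi_network(genes[1:10], genes[11:20])
  b1 <- background_abs_r(expr, design, net, "s1", n_pairs = 50, seed = 9)
  b2 <- background_abs_r(expr, design, net, "s1", n_pairs = 50, seed = 9)
  expect_identical(b1, b2)
  expect_true(all(b1 >= 0 & b1 <= 1))
  expect_lte(length(b1), 50L)
})

test_that("cross-dataset dC agreement behaves at the limits and replicates", {
  design <- toy_design(c(s1 = 30L, s2 = 30L))
  set.seed(13)
  sim <- simulate_dataset(n_background_nodes = 80,
                          stage_sizes = c(s1 = 60L, s2 = 60L),
                          groups = list(list(n_genes = 10,
                                             trajectory = c(0, 0.9),
                                             name = "mod1")),
                          seed = 31)
  prA <- edge_profiles(sim$expr, sim$design, sim$net)
  # self-correlation r = 1; negated profiles r = -1
  edges <- prA$key[1:20]
  expect_equal(cross_dataset_dc_correlation(prA, prA, edges, 1)$r, 1)
  prNeg <- prA
  prNeg$dC_1 <- -prNeg$dC_1
  expect_equal(cross_dataset_dc_correlation(prA, prNeg, edges, 1)$r, -1)
  expect_error(cross_dataset_dc_correlation(prA, prA, edges[1:2], 1), ">= 3")
  # an independent replicate of the same truth correlates positively on
  # the planted edges
  exprB <- generate_expression(sim$net, sim$design, sim$truth, seed = 99)
  prB <- edge_profiles(exprB, sim$design, sim$net)
  mixed <- c(sim$truth$groups$mod1$edges,
             setdiff(prA$key, sim$truth$groups$mod1$edges)[1:30])
  out <- cross_dataset_dc_correlation(prA, prB, mixed, 1)
  expect_gt(out$r, 0)
  expect_lt(out$p.value, 0.01)
})

test_that("edge-profile tables round-trip through TSV", {
  design <- toy_design(c(s1 = 4L, s2 = 4L))
  set.seed(8)
  expr <- matrix(rnorm(6 * 8), 6, 8,
                 dimnames = list(sprintf("G%d", 1:6), names(design$assignment)))
  net <- ppi_network(c("G1", "G2", "G3"), c("G4", "G5", "G6"))
  pr <- edge_profiles(expr, design, net)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_edge_profiles(pr, path)
  back <- read_edge_profiles(path)
  expect_equal(attr(back, "stages"), attr(pr, "stages"))
  expect_equal(back$dC_1, pr$dC_1, tolerance = 1e-9)
})
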