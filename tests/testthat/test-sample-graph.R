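test_that("graph weights follow the mean-absolute-difference metric", {
  vals <- matrix(c(0.5, 0.1,   # probe1: s1, s2, s3
                   0.5, 0.3,
                   0.5, 0.5), byrow = TRUE, nrow = 3, ncol = 2)
  vals <- cbind(vals, vals[, 1])  # s3 identical to s1
  dimnames(vals) <- list(c("cg1", "cg2", "cg3"), c("s1", "s2", "s3"))
  g <- build_sample_graph(beta_matrix(vals), c("cg1", "cg2"))
  # |0.5-0.1| = 0.4 and |0.5-0.3| = 0.2 -> w = 1 - 0.3 = 0.7
  expect_equal(g$weights["s1", "s2"], 0.7)
  expect_equal(g$weights["s1", "s3"], 1)  # identical samples
  expect_equal(g$weights, t(g$weights))
  expect_true(all(diag(g$weights) == 1))

  # completely opposite samples score 0
  v2 <- matrix(c(0, 0, 1, 1), 2, 2,
               dimnames = list(c("cg1", "cg2"), c("a", "b")))
  g2 <- build_sample_graph(beta_matrix(v2), c("cg1", "cg2"))
  expect_equal(g2$weights["a", "b"], 0)

  expect_error(build_sample_graph(beta_matrix(v2), character(0)), "empty")
  expect_error(build_sample_graph(beta_matrix(v2), "cgX"), "not in matrix")
})

test_that("pairs sharing no non-missing panel probes are an error", {
  v <- matrix(c(0.1, NA, NA, 0.2), 2, 2,
              dimnames = list(c("cg1", "cg2"), c("a", "b")))
  expect_error(build_sample_graph(beta_matrix(v), c("cg1", "cg2")),
               "share no non-missing")
})

test_that("thresholding keeps vertices and is monotone in t", {
  set.seed(9)
  bm <- random_beta_matrix(20, 8)
  g <- build_sample_graph(bm, rownames(bm))
  full <- threshold_graph(g, 0)
  expect_true(all(full$adjacency[upper.tri(full$adjacency)]))
  none <- threshold_graph(g, 1)
  expect_false(any(none$adjacency))
  edges <- function(t) sum(threshold_graph(g, t)$adjacency) / 2
  ts <- seq(0, 1, by = 0.05)
  expect_true(all(diff(vapply(ts, edges, numeric(1))) <= 0))
})

test_that("maximal_cliques matches brute-force subset enumeration", {
  # trivial shapes
  adj <- matrix(TRUE, 5, 5,
                dimnames = list(letters[1:5], letters[1:5]))
  expect_equal(maximal_cliques(adj), list(sort(letters[1:5])))
  path <- matrix(FALSE, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  path["a", "b"] <- path["b", "a"] <- TRUE
  path["b", "c"] <- path["c", "b"] <- TRUE
  expect_equal(maximal_cliques(path), list(c("a", "b"), c("b", "c")))

  set.seed(10)
  for (i in 1:40) {
    n <- sample(4:10, 1)
    adj <- random_adjacency(n, runif(1, 0.2, 0.8))
    expect_identical(maximal_cliques(adj), bf_maximal_cliques(adj),
                     label = paste("instance", i))
  }
})

test_that("maximal cliques cover non-isolated vertices and are complete", {
  set.seed(11)
  adj <- random_adjacency(9, 0.4)
  cliques <- maximal_cliques(adj)
  non_isolated <- rownames(adj)[rowSums(adj) > 0]
  expect_true(all(non_isolated %in% unlist(cliques)))
  for (cl in cliques) {
    if (length(cl) >= 2) {
      sub <- adj[cl, cl]
      expect_true(all(sub[upper.tri(sub)]))
    }
  }
})

test_that("homogeneity_check verdicts follow tissue classes", {
  sheet <- paired_sheet(4)
  ab <- sheet$sample_id[sheet$tissue == "AB"]
  om <- sheet$sample_id[sheet$tissue == "OM"]
  hom <- homogeneity_check(list(ab[1:3], om[1:2]), sheet)
  expect_true(hom$pass)
  expect_equal(hom$per_clique$homogeneous, c(TRUE, TRUE))

  mixed <- homogeneity_check(list(c(ab[1], om[1:2])), sheet)
  expect_false(mixed$pass)
  # size-2 mixed cliques do not fail the overall verdict by default
  small <- homogeneity_check(list(c(ab[1], om[1])), sheet)
  expect_true(small$pass)
  expect_false(small$per_clique$homogeneous)
})

test_that("well-separated classes split into two homogeneous components", {
  cfg <- sim_config(n_individuals = 10, n_probes = 30,
                    n_discriminating = 30, delta_levels = 0.5,
                    precision = 300, timepoints = "before", seed = 12)
  sim <- simulate_cohort(cfg)
  g <- build_sample_graph(sim$beta, rownames(sim$beta))
  t <- choose_threshold(g, sim$sheet)
  thr <- threshold_graph(g, t)
  cliques <- maximal_cliques(thr)
  hom <- homogeneity_check(cliques, sim$sheet)
  expect_true(hom$pass)
  # the largest clique is exactly one full tissue class
  cls1 <- unique(sim$sheet$tissue[match(cliques[[1]], sim$sheet$sample_id)])
  expect_length(cls1, 1)
  expect_setequal(cliques[[1]],
                  sim$sheet$sample_id[sim$sheet$tissue == cls1])
})
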