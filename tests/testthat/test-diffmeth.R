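test_that("paired_t_test matches the textbook formula and t.test", {
  d <- c(0.2, 0.1, 0.3, 0.2)
  res <- paired_t_test(d)
  expect_equal(res$t, mean(d) / (sd(d) / 2), tolerance = 1e-12)
  expect_equal(res$t, 4.89898, tolerance = 1e-4)
  expect_equal(res$df, 3L)

  set.seed(1)
  for (i in 1:20) {
    d <- rnorm(sample(3:20, 1))
    res <- paired_t_test(d)
    ref <- t.test(d)
    expect_equal(res$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(res$p_raw, ref$p.value, tolerance = 1e-10)
    # antisymmetry
    neg <- paired_t_test(-d)
    expect_equal(neg$t, -res$t)
    expect_equal(neg$p_raw, res$p_raw)
  }

  expect_error(paired_t_test(c(1, 1, 1)), "zero variance")
  expect_error(paired_t_test(c(0.3)), "at least 2")
})

test_that("bonferroni_adjust multiplies and caps", {
  expect_equal(bonferroni_adjust(0.01, 5), 0.05)
  expect_equal(bonferroni_adjust(0.5, 10), 1)
  # adjusted values at 450K scale imply raw p = adjusted / n
  n <- 473864
  expect_equal(bonferroni_adjust(2.32e-4 / n, n), 2.32e-4, tolerance = 1e-12)
})

test_that("delta_beta reproduces printed class-mean differences", {
  expect_equal(delta_beta(0.53, 0.96), -0.43)
  expect_equal(delta_beta(0.45, 0.04), 0.41)
  expect_equal(delta_beta(0.3, 0.3), 0)
  # antisymmetric under class swap
  expect_equal(delta_beta(0.2, 0.7), -delta_beta(0.7, 0.2))
})

test_that("diff_meth recovers planted signal and drops degenerate probes", {
  cfg <- sim_config(n_individuals = 15, n_probes = 500,
                    n_discriminating = 10, delta_levels = 0.4,
                    precision = 200, timepoints = "before", seed = 31)
  sim <- simulate_cohort(cfg)
  rec <- diff_meth(sim$beta, sim$sheet, "before")
  expect_equal(attr(rec, "n_tests"), nrow(rec))
  expect_true(all(rec$p_adjusted >= rec$p_raw - 1e-15))
  expect_equal(rec$delta_beta, rec$mean_AB - rec$mean_OM)

  sig <- significant_sites(rec, 1e-7)
  planted <- sim$truth$probe_id[sim$truth$is_discriminating &
                                  sim$truth$timepoint == "before"]
  expect_true(all(planted %in% sig$probe_id))
  expect_equal(sort(sig$rank_p), seq_len(nrow(sig)))
  expect_equal(sort(sig$rank_delta), seq_len(nrow(sig)))

  # missingness: a probe below min_pairs is dropped
  vals <- unclass(sim$beta)
  vals[1, sim$sheet$sample_id[sim$sheet$tissue == "OM"][1:13]] <- NA
  rec2 <- diff_meth(beta_matrix(vals), sim$sheet, "before")
  expect_false(rownames(vals)[1] %in% rec2$probe_id)
  expect_equal(attr(rec2, "n_dropped"), 1L)
})

test_that("significant_sites with no survivors returns an empty table", {
  rec <- data.frame(probe_id = c("cg01", "cg02"), t_stat = c(1, -1),
                    p_raw = c(0.5, 0.6), p_adjusted = c(1, 1),
                    mean_AB = c(0.5, 0.5), mean_OM = c(0.5, 0.5),
                    delta_beta = c(0, 0), n_pairs = c(15L, 15L))
  expect_equal(nrow(significant_sites(rec)), 0)
})

test_that("bin_by_delta counts signed magnitudes with nesting", {
  rec <- data.frame(delta_beta = c(0.06, -0.12, 0.3))
  bins <- bin_by_delta(rec)
  expect_equal(bins$n_pos, c(2L, 1L, 1L, 0L))
  expect_equal(bins$n_neg, c(1L, 1L, 0L, 0L))
  expect_equal(bins$n_total, bins$n_pos + bins$n_neg)

  expect_equal(bin_by_delta(rec[0, , drop = FALSE])$n_total, rep(0L, 4))

  set.seed(2)
  rnd <- data.frame(delta_beta = runif(200, -1, 1))
  b <- bin_by_delta(rnd)
  expect_true(all(diff(b$n_pos) <= 0))  # monotone non-increasing
  expect_true(all(diff(b$n_neg) <= 0))
  expect_true(all(b$n_total <= nrow(rnd)))
})

test_that("overlap_timepoints intersects and flags widened probes", {
  before <- data.frame(probe_id = c("cg01", "cg02", "cg03"),
                       delta_beta = c(-0.43, 0.10, 0.20))
  after <- data.frame(probe_id = c("cg01", "cg02", "cg04"),
                      delta_beta = c(-0.64, 0.12, 0.50))
  ov <- overlap_timepoints(before, after)
  expect_equal(ov$probe_id, c("cg01", "cg02"))
  expect_equal(ov$greater_delta_post, c(TRUE, FALSE))
  expect_equal(ov$widening[1], 0.21)
  expect_lte(sum(ov$greater_delta_post), nrow(ov))

  disjoint <- overlap_timepoints(before,
                                 data.frame(probe_id = "cg09",
                                            delta_beta = 0.3))
  expect_equal(nrow(disjoint), 0)
})

test_that("m-value scale testing is offered and agrees on strong signal", {
  cfg <- sim_config(n_individuals = 15, n_probes = 100,
                    n_discriminating = 5, delta_levels = 0.4,
                    precision = 200, timepoints = "before", seed = 13)
  sim <- simulate_cohort(cfg)
  beta_scale <- significant_sites(diff_meth(sim$beta, sim$sheet, "before"))
  m_scale <- significant_sites(diff_meth(sim$beta, sim$sheet, "before",
                                         scale = "mvalue"))
  planted <- sim$truth$probe_id[sim$truth$is_discriminating &
                                  sim$truth$timepoint == "before"]
  expect_true(all(planted %in% beta_scale$probe_id))
  expect_true(all(planted %in% m_scale$probe_id))
  # means are reported on the beta scale in both modes
  expect_equal(m_scale$mean_AB[order(m_scale$probe_id)],
               beta_scale$mean_AB[order(beta_scale$probe_id)])
})
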