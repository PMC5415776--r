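test_that("simulated cohort honours the dimensional contract and seed", {
  cfg <- sim_config(n_individuals = 15, n_probes = 200, seed = 7)
  sim <- simulate_cohort(cfg)
  expect_equal(dim(sim$beta), c(200L, 60L))  # 15 x 2 tissues x 2 timepoints
  expect_equal(nrow(sim$sheet), 60)
  expect_true(all(unclass(sim$beta) >= 0 & unclass(sim$beta) <= 1))
  expect_equal(nrow(sim$truth), 400)  # per probe per timepoint

  sim2 <- simulate_cohort(cfg)
  expect_identical(unclass(sim$beta), unclass(sim2$beta))
  sim3 <- simulate_cohort(sim_config(n_individuals = 15, n_probes = 200,
                                     seed = 8))
  expect_false(identical(unclass(sim$beta), unclass(sim3$beta)))
})

test_that("configured tissue delta is recovered empirically", {
  cfg <- sim_config(n_individuals = 150, n_probes = 5, n_discriminating = 1,
                    delta_levels = 0.6, precision = 200,
                    timepoints = "before", seed = 11)
  sim <- simulate_cohort(cfg)
  ab <- sim$sheet$sample_id[sim$sheet$tissue == "AB"]
  om <- sim$sheet$sample_id[sim$sheet$tissue == "OM"]
  probe <- sim$truth$probe_id[sim$truth$is_discriminating][1]
  emp <- mean(sim$beta[probe, ab]) - mean(sim$beta[probe, om])
  truth <- sim$truth$delta[sim$truth$probe_id == probe]
  expect_lt(abs(abs(emp) - abs(truth)), 0.03)

  # non-discriminating probes drift to zero difference
  null_probes <- sim$truth$probe_id[!sim$truth$is_discriminating]
  emp_null <- rowMeans(unclass(sim$beta)[null_probes, ab]) -
    rowMeans(unclass(sim$beta)[null_probes, om])
  se <- apply(unclass(sim$beta)[null_probes, ab] -
                unclass(sim$beta)[null_probes, om], 1,
              function(d) sd(d) / sqrt(length(d)))
  expect_true(all(abs(emp_null) < 3 * se + 1e-9))
})

test_that("probe spread shrinks as the precision parameter grows", {
  sd_at <- function(phi, seed) {
    sim <- simulate_cohort(sim_config(n_individuals = 60, n_probes = 20,
                                      n_discriminating = 0, precision = phi,
                                      individual_sd = 0, seed = seed,
                                      timepoints = "before"))
    mean(apply(unclass(sim$beta), 1, sd))
  }
  expect_lt(sd_at(2000, 3), sd_at(20, 3))
})

test_that("after-timepoint widening enlarges the planted delta", {
  cfg <- sim_config(n_individuals = 40, n_probes = 5, n_discriminating = 2,
                    delta_levels = 0.3, delta_widen = 1.3, seed = 5)
  sim <- simulate_cohort(cfg)
  tr <- sim$truth[sim$truth$is_discriminating, ]
  before <- tr$delta[tr$timepoint == "before"]
  after <- tr$delta[tr$timepoint == "after"]
  expect_equal(abs(after), pmin(abs(before) * 1.3, 0.96), tolerance = 1e-6)
})

test_that("trait construction approaches the target correlation", {
  cfg <- sim_config(
    n_individuals = 200, n_probes = 10, n_discriminating = 2,
    delta_levels = 0.4, seed = 9,
    trait_specs = list(
      list(name = "hdl", r = 0.9),
      list(name = "exact", r = 0.7, noise_sd = 0)))
  sim <- simulate_cohort(cfg)
  db <- individual_delta_beta(sim$beta, sim$sheet, "after",
                              probes = "cg00000001")
  for (spec in list(c("hdl", 0.9, 0.1), c("exact", 1, 0.02))) {
    dt <- delta_trait(sim$clinical, spec[1])
    r <- pearson_r(db[1, names(dt)], dt)$r
    expect_lt(abs(abs(r) - as.numeric(spec[2])), as.numeric(spec[3]))
  }
})

test_that("SNP probe is trimodal by genotype and flagged in annotation", {
  cfg <- sim_config(n_individuals = 100, n_probes = 10,
                    n_discriminating = 0, precision = 500,
                    individual_sd = 0, timepoints = "before", seed = 21,
                    snp_probe = list(maf = 0.4,
                                     meth = c(0.9, 0.5, 0.1)))
  sim <- simulate_cohort(cfg)
  snp_id <- sim$annotation$probe_id[sim$annotation$snp_flag]
  expect_length(snp_id, 1)
  vals <- unclass(sim$beta)[snp_id, ]
  # three well-separated modes: counts in the three genotype bands
  bands <- c(sum(vals < 0.3), sum(vals >= 0.3 & vals < 0.7),
             sum(vals >= 0.7))
  expect_true(all(bands > 0))
})

test_that("inject_perfect_marker yields disjoint class supports", {
  set.seed(4)
  sheet <- paired_sheet(15)
  bm <- random_beta_matrix(50, 30)
  colnames_ok <- sheet$sample_id
  dimnames(bm)[[2]] <- colnames_ok  # align sample ids with the sheet
  bm <- beta_matrix(unclass(bm))
  out <- inject_perfect_marker(bm, sheet, "cg00000001",
                               low = 0.34, high = 0.97)
  ab <- out["cg00000001", sheet$sample_id[sheet$tissue == "AB"]]
  om <- out["cg00000001", sheet$sample_id[sheet$tissue == "OM"]]
  expect_true(all(abs(ab - 0.34) <= 0.02))
  expect_true(all(abs(om - 0.97) <= 0.02))
  expect_lt(max(ab), min(om))  # disjoint supports

  expect_error(inject_perfect_marker(bm, sheet, "cg00000001", 0.5, 0.5),
               "low")
  expect_error(inject_perfect_marker(bm, sheet, "cg00000001", 0.50, 0.53),
               "overlap")
  expect_error(inject_perfect_marker(bm, sheet, "nope", 0.2, 0.8),
               "not found")

  # the injected probe attains the maximum merit in the panel
  tab <- candidate_filter(out, sheet, "before")
  expect_equal(tab$probe_id[tab$rank == 1], "cg00000001")
})

test_that("infeasible delta configurations are rejected", {
  expect_error(sim_config(delta_levels = 0.97), "attainable")
})
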