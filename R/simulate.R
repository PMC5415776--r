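#' Configuration for the paired-cohort methylation simulator
#'
#' Describes a synthetic two-tissue (AB/OM), two-timepoint 450K-style cohort
#' with known ground truth. Beta values are drawn from beta distributions
#' whose means combine a bimodal probe baseline, a tissue shift for
#' discriminating probes, and a per-individual logit-scale random effect
#' shared across that individual's samples.
#'
#' @param n_individuals Number of individuals (default 15, the discovery
#'   cohort size).
#' @param n_probes Total number of probes.
#' @param n_discriminating Number of true tissue-discriminating probes.
#' @param delta_levels True tissue mean differences (beta-scale fractions)
#'   assigned cyclically to discriminating probes.
#' @param precision Beta-distribution concentration (shape1 + shape2) of the
#'   observation model; larger means tighter probes.
#' @param individual_sd SD of the per-individual random effect on the logit
#'   scale.
#' @param baseline_mix Length-3 numeric: low mode mean, high mode mean, and
#'   the mixing weight of the low mode, describing the bimodal baseline of
#'   array probes.
#' @param baseline_concentration Concentration of the beta distribution from
#'   which probe baselines are drawn around each mode.
#' @param delta_widen Multiplicative widening of the tissue difference at the
#'   "after" timepoint (default 1.3; weight loss tends to sharpen the
#'   tissue contrast).
#' @param timepoints Character subset of `c("before", "after")`.
#' @param snp_probe Optional list describing one trimodal SNP-disrupted
#'   probe: `list(maf = minor allele frequency, meth = methylation mean per
#'   genotype count of the disrupting allele, c(hom_ref, het, hom_alt))`.
#' @param trait_specs Optional list of trait constructions, each
#'   `list(name =, probe = probe id or NULL for the first discriminating
#'   probe, r = target Pearson correlation with that probe's per-individual
#'   delta-beta, noise_sd = residual SD on the standardised scale, base =
#'   trait baseline value, scale = units per standardised delta)`. With
#'   `noise_sd = sqrt(1 - r^2)` (the default) the empirical correlation
#'   converges to `r`; as `noise_sd -> 0` it converges to 1.
#' @param seed Integer seed; the whole cohort is deterministic given it.
#' @return A list of class `SimConfig`.
#' @export
sim_config <- function(n_individuals = 15,
                       n_probes = 1000,
                       n_discriminating = 20,
                       delta_levels = c(0.4, 0.6),
                       precision = 200,
                       individual_sd = 0.15,
                       baseline_mix = c(0.15, 0.85, 0.5),
                       baseline_concentration = 10,
                       delta_widen = 1.3,
                       timepoints = c("before", "after"),
                       snp_probe = NULL,
                       trait_specs = NULL,
                       seed = 1L) {
  stopifnot(n_individuals >= 1, n_probes >= 1,
            n_discriminating >= 0, n_discriminating <= n_probes,
            precision > 0, individual_sd >= 0,
            length(baseline_mix) == 3,
            baseline_mix[1] > 0, baseline_mix[1] < 1,
            baseline_mix[2] > 0, baseline_mix[2] < 1,
            baseline_mix[3] >= 0, baseline_mix[3] <= 1,
            delta_widen > 0,
            all(timepoints %in% c("before", "after")),
            length(timepoints) >= 1)
  if (any(abs(delta_levels) >= 0.96)) {
    stop("delta levels must be attainable within the clipped mean range [0.02, 0.98]",
         call. = FALSE)
  }
  if (!is.null(trait_specs)) {
    for (ts in trait_specs) {
      if (abs(ts$r) > 1) stop("|target r| must be <= 1", call. = FALSE)
    }
  }
  structure(list(
    n_individuals = as.integer(n_individuals),
    n_probes = as.integer(n_probes),
    n_discriminating = as.integer(n_discriminating),
    delta_levels = delta_levels,
    precision = precision,
    individual_sd = individual_sd,
    baseline_mix = baseline_mix,
    baseline_concentration = baseline_concentration,
    delta_widen = delta_widen,
    timepoints = timepoints,
    snp_probe = snp_probe,
    trait_specs = trait_specs,
    seed = as.integer(seed)
  ), class = "SimConfig")
}

# clip a beta-scale mean away from the degenerate boundary
.clip_mean <- function(x, lo = 0.02, hi = 0.98) pmin(pmax(x, lo), hi)

#' Simulate a paired two-tissue methylation cohort
#'
#' Generates a beta-value matrix, sample sheet, probe annotation, clinical
#' table and a truth table recording each probe's configured class means and
#' delta-beta. Deterministic for a fixed `config$seed`.
#'
#' Discriminating probes shift the OM mean away from the AB baseline by the
#' assigned delta (alternating direction, clipped to \[0.02, 0.98\]); at the
#' "after" timepoint the shift is widened by `delta_widen`. Trait changes
#' are built as a linear function of a named probe's per-individual
#' delta-beta (AB - OM, "after" timepoint if simulated, else "before") plus
#' Gaussian noise.
#'
#' @param config A [sim_config()].
#' @return A list with elements `beta` ([beta_matrix()]), `sheet`
#'   ([sample_sheet()]), `annotation`, `clinical` (possibly `NULL`) and
#'   `truth` (data frame: `probe_id`, `timepoint`, `mu_AB`, `mu_OM`,
#'   `delta`, `is_discriminating`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  n_ind <- config$n_individuals
  n_probes <- config$n_probes
  probe_ids <- sprintf("cg%08d", seq_len(n_probes))
  ind_ids <- sprintf("ind%02d", seq_len(n_ind))

  # bimodal baseline means
  mix <- config$baseline_mix
  c0 <- config$baseline_concentration
  is_low <- stats::runif(n_probes) < mix[3]
  mode_mean <- ifelse(is_low, mix[1], mix[2])
  mu_base <- stats::rbeta(n_probes, mode_mean * c0, (1 - mode_mean) * c0)
  mu_base <- .clip_mean(mu_base)

  # discriminating probes: shift the OM mean on the beta-mean scale
  n_disc <- config$n_discriminating
  disc_idx <- seq_len(n_disc)
  deltas <- numeric(n_probes)
  if (n_disc > 0) {
    lev <- rep_len(config$delta_levels, n_disc)
    sgn <- rep_len(c(1, -1), n_disc)
    # the OM mean must stay inside [0.02, 0.98] at every timepoint,
    # including the widened "after" shift
    w_max <- if ("after" %in% config$timepoints) {
      max(1, config$delta_widen)
    } else 1
    feasible <- function(mu, d) {
      om <- mu - d * w_max
      om >= 0.02 && om <= 0.98
    }
    for (k in seq_len(n_disc)) {
      d <- lev[k] * sgn[k]
      if (!feasible(mu_base[k], d)) d <- -d
      if (!feasible(mu_base[k], d)) {
        # re-anchor the baseline symmetrically around 0.5 so the widened
        # delta is attainable
        mu_base[k] <- .clip_mean(0.5 + d * w_max / 2)
        if (!feasible(mu_base[k], d)) {
          stop("infeasible delta level ", lev[k], call. = FALSE)
        }
      }
      deltas[k] <- d
    }
  }

  ind_effect <- stats::rnorm(n_ind, 0, config$individual_sd)

  timepoints <- config$timepoints
  sheet <- expand.grid(individual_id = ind_ids,
                       tissue = c("AB", "OM"),
                       timepoint = timepoints,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  sheet$sample_id <- paste(sheet$individual_id, sheet$tissue,
                           sheet$timepoint, sep = "_")
  sheet <- sample_sheet(sheet[, c("sample_id", "individual_id",
                                  "tissue", "timepoint")])

  values <- matrix(NA_real_, n_probes, nrow(sheet),
                   dimnames = list(probe_ids, sheet$sample_id))
  truth_list <- list()
  phi <- config$precision
  for (tp in timepoints) {
    widen <- if (tp == "after") config$delta_widen else 1
    mu_ab <- mu_base
    mu_om <- .clip_mean(mu_base - deltas * widen)
    truth_list[[tp]] <- data.frame(
      probe_id = probe_ids, timepoint = tp,
      mu_AB = mu_ab, mu_OM = mu_om, delta = mu_ab - mu_om,
      is_discriminating = seq_len(n_probes) %in% disc_idx,
      stringsAsFactors = FALSE)
    for (tis in c("AB", "OM")) {
      mu_t <- if (tis == "AB") mu_ab else mu_om
      for (i in seq_len(n_ind)) {
        sid <- paste(ind_ids[i], tis, tp, sep = "_")
        mu_i <- stats::plogis(stats::qlogis(mu_t) + ind_effect[i])
        values[, sid] <- stats::rbeta(n_probes, mu_i * phi, (1 - mu_i) * phi)
      }
    }
  }

  snp_flags <- rep(FALSE, n_probes)
  if (!is.null(config$snp_probe)) {
    sp <- config$snp_probe
    j <- n_probes  # last probe carries the SNP disruption
    snp_flags[j] <- TRUE
    geno <- stats::rbinom(n_ind, 2, sp$maf)
    g_mu <- .clip_mean(sp$meth[geno + 1])
    for (i in seq_len(n_ind)) {
      sids <- sheet$sample_id[sheet$individual_id == ind_ids[i]]
      values[j, sids] <- stats::rbeta(length(sids), g_mu[i] * phi,
                                      (1 - g_mu[i]) * phi)
    }
    for (tp in timepoints) {
      truth_list[[tp]][j, c("mu_AB", "mu_OM", "delta")] <-
        c(mean(g_mu), mean(g_mu), 0)
    }
  }

  annotation <- probe_annotation(data.frame(
    probe_id = probe_ids,
    chr = as.character(rep_len(c(1:22, "X"), n_probes)),
    pos = seq_len(n_probes) * 1000L,
    gene = ifelse(seq_len(n_probes) %% 3 == 0, "Intergenic",
                  sprintf("GENE%04d", (seq_len(n_probes) - 1) %/% 3)),
    region = rep_len(c("Body", "TSS1500", "TSS200", "5'UTR", "3'UTR"),
                     n_probes),
    snp_flag = snp_flags,
    stringsAsFactors = FALSE))

  bm <- beta_matrix(values)

  clinical <- NULL
  if (!is.null(config$trait_specs)) {
    trait_tp <- if ("after" %in% timepoints) "after" else timepoints[1]
    pairs <- pair_samples(sheet, trait_tp)
    rows <- list()
    for (ts in config$trait_specs) {
      probe <- if (is.null(ts$probe)) probe_ids[1] else ts$probe
      noise_sd <- if (is.null(ts$noise_sd)) sqrt(max(0, 1 - ts$r^2)) else ts$noise_sd
      base <- if (is.null(ts$base)) 100 else ts$base
      scale_u <- if (is.null(ts$scale)) 10 else ts$scale
      d <- values[probe, pairs$sample_AB] - values[probe, pairs$sample_OM]
      z <- if (stats::sd(d) > 0) (d - mean(d)) / stats::sd(d) else d * 0
      dt <- ts$r * z + noise_sd * stats::rnorm(n_ind)
      rows[[length(rows) + 1]] <- data.frame(
        individual_id = rep(pairs$individual_id, 2),
        trait = ts$name,
        timepoint = rep(c("before", "after"), each = n_ind),
        value = c(base + scale_u * dt, rep(base, n_ind)),
        stringsAsFactors = FALSE)
    }
    clinical <- clinical_table(do.call(rbind, rows))
  }

  list(beta = bm, sheet = sheet, annotation = annotation,
       clinical = clinical, truth = do.call(rbind, c(truth_list,
                                                     make.row.names = FALSE)))
}

#' Inject a perfectly discriminating marker into a cohort
#'
#' Overwrites one probe so that AB samples take values near `low` and OM
#' samples values near `high` (uniform within +/- 0.02, intersected with
#' \[0, 1\]). When `high - low > 0.04` the class supports are disjoint and a
#' singleton panel of this probe separates the classes completely -- the
#' behaviour of the strongest single-site tissue marker.
#'
#' Uses the current RNG stream; seed before calling for reproducibility.
#'
#' @param matrix A [beta_matrix()].
#' @param sheet The matching [sample_sheet()].
#' @param probe_id Probe to overwrite (must exist).
#' @param low,high Target class means for AB and OM, `low < high`.
#' @return The modified `BetaMatrix`.
#' @export
inject_perfect_marker <- function(matrix, sheet, probe_id, low, high) {
  stopifnot(inherits(matrix, "BetaMatrix"))
  if (!probe_id %in% rownames(matrix)) {
    stop("probe not found: ", probe_id, call. = FALSE)
  }
  if (!(low < high)) stop("`low` must be < `high`", call. = FALSE)
  if (high - low < 0.04) {
    stop("target ranges [low +/- 0.02] and [high +/- 0.02] overlap",
         call. = FALSE)
  }
  draw <- function(centre, n) {
    lo <- max(centre - 0.02, 0)
    hi <- min(centre + 0.02, 1)
    stats::runif(n, lo, hi)
  }
  ab <- sheet$sample_id[sheet$tissue == "AB"]
  om <- sheet$sample_id[sheet$tissue == "OM"]
  matrix[probe_id, ab] <- draw(low, length(ab))
  matrix[probe_id, om] <- draw(high, length(om))
  beta_matrix(unclass(matrix))
}
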