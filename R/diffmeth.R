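#' Paired t test on a vector of per-individual differences
#'
#' Computes `t = mean(d) / (sd(d) / sqrt(n))` with `df = n - 1` and a
#' two-sided p value from the t distribution; `sd` uses the n-1 denominator.
#'
#' @param diffs Numeric vector of paired differences; `NA`s are dropped.
#' @return List with `t`, `df`, `p_raw`, `n`.
#' @export
paired_t_test <- function(diffs) {
  d <- diffs[!is.na(diffs)]
  n <- length(d)
  if (n < 2) stop("need at least 2 non-missing differences", call. = FALSE)
  s <- stats::sd(d)
  if (s == 0) stop("degenerate input: zero variance in differences",
                   call. = FALSE)
  t <- mean(d) / (s / sqrt(n))
  list(t = t, df = n - 1L, p_raw = 2 * stats::pt(-abs(t), df = n - 1),
       n = n)
}

#' Bonferroni adjustment
#' @param p_raw Raw p values in \[0, 1\].
#' @param n_tests Number of tests in the family (>= 1).
#' @return `min(1, p_raw * n_tests)`, vectorised.
#' @export
bonferroni_adjust <- function(p_raw, n_tests) {
  stopifnot(n_tests >= 1, all(p_raw >= 0 & p_raw <= 1, na.rm = TRUE))
  pmin(1, p_raw * n_tests)
}

#' Signed mean methylation difference between classes
#'
#' Convention: AB minus OM, so sites hypomethylated in subcutaneous (AB)
#' relative to omental (OM) adipose have negative delta-beta.
#'
#' @param mean_AB,mean_OM Class mean beta values in \[0, 1\].
#' @return `mean_AB - mean_OM`, vectorised.
#' @export
delta_beta <- function(mean_AB, mean_OM) {
  stopifnot(all(mean_AB >= 0 & mean_AB <= 1, na.rm = TRUE),
            all(mean_OM >= 0 & mean_OM <= 1, na.rm = TRUE))
  mean_AB - mean_OM
}

#' Per-probe paired differential methylation
#'
#' Runs a paired t test (AB - OM within individual) for every probe at one
#' timepoint, with Bonferroni adjustment over the probes actually tested.
#' Probes with fewer than `min_pairs` complete pairs, or zero variance in
#' the paired differences, are dropped (counts reported in attributes).
#'
#' @param matrix A [beta_matrix()].
#' @param sheet A [sample_sheet()].
#' @param timepoint `"before"` or `"after"`.
#' @param scale `"beta"` (default; means and delta-beta reported on the
#'   beta scale) or `"mvalue"` (test on M-values, means still on beta
#'   scale).
#' @param min_pairs Minimum complete pairs per probe (default 3).
#' @return Data frame with columns `probe_id`, `t_stat`, `p_raw`,
#'   `p_adjusted`, `mean_AB`, `mean_OM`, `delta_beta`, `n_pairs`.
#'   Attribute `n_tests` records the Bonferroni family size;
#'   `n_dropped` the excluded probe count.
#' @export
diff_meth <- function(matrix, sheet, timepoint, scale = c("beta", "mvalue"),
                      min_pairs = 3) {
  scale <- match.arg(scale)
  pairs <- pair_samples(sheet, timepoint)
  if (nrow(pairs) < 2) stop("need at least 2 complete pairs", call. = FALSE)
  ab <- unclass(matrix)[, pairs$sample_AB, drop = FALSE]
  om <- unclass(matrix)[, pairs$sample_OM, drop = FALSE]
  test_ab <- if (scale == "mvalue") m_transform(ab) else ab
  test_om <- if (scale == "mvalue") m_transform(om) else om

  d <- test_ab - test_om
  ok <- !is.na(d)
  n_pairs <- rowSums(ok)
  d0 <- ifelse(ok, d, 0)
  m <- rowSums(d0) / n_pairs
  ss <- rowSums(ifelse(ok, (d - m)^2, 0))
  sd_d <- sqrt(ss / pmax(n_pairs - 1, 1))
  keep <- n_pairs >= min_pairs & sd_d > 0
  n_dropped <- sum(!keep)

  t_stat <- (m / (sd_d / sqrt(n_pairs)))[keep]
  df <- n_pairs[keep] - 1
  p_raw <- 2 * stats::pt(-abs(t_stat), df = df)
  n_tests <- sum(keep)

  okb <- !is.na(ab) & !is.na(om)
  mean_ab <- rowSums(ifelse(okb, ab, 0)) / rowSums(okb)
  mean_om <- rowSums(ifelse(okb, om, 0)) / rowSums(okb)

  res <- data.frame(
    probe_id = rownames(matrix)[keep],
    t_stat = t_stat,
    p_raw = p_raw,
    p_adjusted = bonferroni_adjust(p_raw, n_tests),
    mean_AB = mean_ab[keep],
    mean_OM = mean_om[keep],
    delta_beta = (mean_ab - mean_om)[keep],
    n_pairs = n_pairs[keep],
    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "n_tests") <- n_tests
  attr(res, "n_dropped") <- n_dropped
  res
}

#' Filter and rank significant differentially methylated sites
#'
#' @param records Output of [diff_meth()].
#' @param alpha_adjusted Threshold on the Bonferroni-adjusted p value
#'   (default 1e-7, applied to the adjusted value).
#' @return The significant records with two ranking columns: `rank_p`
#'   (p_adjusted ascending) and `rank_delta` (absolute delta-beta
#'   descending); rows ordered by `rank_p`. Ties broken by probe id.
#' @export
significant_sites <- function(records, alpha_adjusted = 1e-7) {
  keep <- records$p_adjusted <= alpha_adjusted
  res <- records[keep, , drop = FALSE]
  if (nrow(res) > 0) {
    res$rank_p <- rank_with_ties(res$p_adjusted, res$probe_id)
    res$rank_delta <- rank_with_ties(-abs(res$delta_beta), res$probe_id)
    res <- res[order(res$rank_p), , drop = FALSE]
  } else {
    res$rank_p <- integer(0)
    res$rank_delta <- integer(0)
  }
  rownames(res) <- NULL
  res
}

# deterministic 1..k ranking: primary key ascending, probe id breaks ties
rank_with_ties <- function(key, probe_id) {
  ord <- order(key, probe_id)
  r <- integer(length(key))
  r[ord] <- seq_along(key)
  r
}

#' Count significant sites by signed delta-beta magnitude
#'
#' Summary of how many sites exceed each absolute delta-beta threshold,
#' split by sign (positive: hypermethylated in AB; negative: hypomethylated
#' in AB relative to OM).
#'
#' @param records Data frame with a `delta_beta` column (typically from
#'   [significant_sites()]).
#' @param thresholds Ascending vector of magnitude thresholds.
#' @return Data frame: `threshold`, `n_pos`, `n_neg`, `n_total`.
#' @export
bin_by_delta <- function(records, thresholds = c(0.05, 0.10, 0.20, 0.50)) {
  d <- records$delta_beta
  out <- data.frame(
    threshold = thresholds,
    n_pos = vapply(thresholds, function(t) sum(d >= t), integer(1)),
    n_neg = vapply(thresholds, function(t) sum(d <= -t), integer(1)))
  out$n_total <- out$n_pos + out$n_neg
  out
}

#' Overlap of significant sites between the two timepoints
#'
#' Intersects two significant-site tables by probe id and flags probes whose
#' absolute tissue difference widened by at least `widen_min` after weight
#' loss.
#'
#' @param before,after Outputs of [significant_sites()] for the two
#'   timepoints (same probe universe).
#' @param widen_min Minimum increase in `abs(delta_beta)` to flag a probe
#'   (default 0.05, i.e. 5 percentage points of methylation).
#' @return Data frame: `probe_id`, `delta_before`, `delta_after`,
#'   `widening`, `greater_delta_post` (logical flag).
#' @export
overlap_timepoints <- function(before, after, widen_min = 0.05) {
  common <- intersect(before$probe_id, after$probe_id)
  b <- before[match(common, before$probe_id), , drop = FALSE]
  a <- after[match(common, after$probe_id), , drop = FALSE]
  widening <- abs(a$delta_beta) - abs(b$delta_beta)
  out <- data.frame(
    probe_id = common,
    delta_before = b$delta_beta,
    delta_after = a$delta_beta,
    widening = widening,
    greater_delta_post = widening >= widen_min,
    stringsAsFactors = FALSE)
  out <- out[order(out$probe_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
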