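#' Class-separation merit score of a methylation site
#'
#' The merit of a site is the absolute difference between the intra-class
#' median beta values, less the sum of the two within-class standard
#' deviations (n-1 denominator). Positive merit indicates the class medians
#' are further apart than the combined spread, i.e. the site separates the
#' classes.
#'
#' @param values_A,values_B Numeric beta values for the two classes; `NA`s
#'   dropped. At least 2 non-missing values per class.
#' @return The merit score (unitless, beta scale).
#' @examples
#' merit_score(c(0.1, 0.2, 0.3), c(0.7, 0.8, 0.9))  # 0.4
#' @export
merit_score <- function(values_A, values_B) {
  a <- values_A[!is.na(values_A)]
  b <- values_B[!is.na(values_B)]
  if (length(a) < 2 || length(b) < 2) {
    stop("need at least 2 non-missing values per class", call. = FALSE)
  }
  abs(stats::median(a) - stats::median(b)) - (stats::sd(a) + stats::sd(b))
}

# Exact null distribution of the positive-rank sum W+ for a multiset of
# (possibly tied, half-integer) ranks. Works on doubled ranks so all weights
# are integers; returns counts over W2 = 0 .. sum(2r).
.wilcox_exact_counts <- function(ranks2) {
  total <- sum(ranks2)
  counts <- numeric(total + 1)
  counts[1] <- 1
  for (r in ranks2) {
    shifted <- c(rep(0, r), counts[seq_len(total + 1 - r)])
    counts <- counts + shifted
  }
  counts
}

#' Wilcoxon signed-rank test on paired differences
#'
#' Zero differences are dropped (classic handling). For effective n <= 25
#' the exact null distribution of the positive-rank sum is enumerated by
#' convolution (ties handled through average ranks, which keeps the
#' enumeration exact for the observed rank multiset); above that a normal
#' approximation with tie-corrected variance and continuity correction is
#' used. Two-sided.
#'
#' @param paired_diffs Numeric vector of per-individual differences; `NA`s
#'   dropped.
#' @param exact_limit Largest effective n for exact enumeration
#'   (default 25).
#' @param .cache Optional environment memoising exact distributions across
#'   calls (used by [candidate_filter()] when testing many probes).
#' @return List with `p` (two-sided), `statistic` (positive-rank sum W+),
#'   `n_effective`, and `method` ("exact" or "normal").
#' @examples
#' wilcoxon_signed_rank(rep(1, 15))$p  # 2 * 2^-15
#' @export
wilcoxon_signed_rank <- function(paired_diffs, exact_limit = 25,
                                 .cache = NULL) {
  d <- paired_diffs[!is.na(paired_diffs)]
  if (length(d) == 0) stop("no non-missing differences", call. = FALSE)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(list(p = 1, statistic = NA_real_, n_effective = 0L,
                method = "degenerate"))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= exact_limit) {
    r2 <- as.integer(round(2 * r))
    key <- paste(sort(r2), collapse = ",")
    counts <- if (!is.null(.cache) && !is.null(.cache[[key]])) {
      .cache[[key]]
    } else {
      cts <- .wilcox_exact_counts(r2)
      if (!is.null(.cache)) .cache[[key]] <- cts
      cts
    }
    w2 <- as.integer(round(2 * w))
    tot <- 2^n
    p_le <- sum(counts[seq_len(w2 + 1)]) / tot
    p_ge <- sum(counts[seq.int(w2 + 1, length(counts))]) / tot
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- sum(r) / 2
    sigma <- sqrt(sum(r^2) / 4)
    z <- (w - mu - sign(w - mu) * 0.5) / sigma
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  list(p = p, statistic = w, n_effective = as.integer(n), method = method)
}

# row medians without extra dependencies; NA-aware
.row_medians <- function(m) {
  apply(m, 1, stats::median, na.rm = TRUE)
}

.row_sds <- function(m) {
  n <- rowSums(!is.na(m))
  mu <- rowMeans(m, na.rm = TRUE)
  ss <- rowSums((m - mu)^2, na.rm = TRUE)
  sqrt(ss / pmax(n - 1, 1))
}

#' Merit-and-Wilcoxon candidate biomarker filter
#'
#' Scores every probe by [merit_score()] (AB vs OM at one timepoint) and a
#' paired [wilcoxon_signed_rank()] test across individuals, then retains
#' probes with positive merit and Wilcoxon p below `p_threshold`. The
#' retained probes are ranked by merit descending, ties broken
#' lexicographically by probe id.
#'
#' @param matrix A [beta_matrix()].
#' @param sheet A [sample_sheet()].
#' @param timepoint `"before"` or `"after"`.
#' @param p_threshold Wilcoxon p threshold (default 0.001; with unanimous
#'   direction this is attainable from n = 11 pairs upwards).
#' @param min_pairs Minimum complete pairs per probe (default 3).
#' @return Data frame (`MeritTable`): `probe_id`, `merit`, `wilcoxon_p`,
#'   `rank`, `mean_AB`, `mean_OM`, sorted by rank. Attribute `n_scored`
#'   records how many probes were evaluated.
#' @export
candidate_filter <- function(matrix, sheet, timepoint, p_threshold = 0.001,
                             min_pairs = 3) {
  pairs <- pair_samples(sheet, timepoint)
  if (nrow(pairs) < 2) stop("need at least 2 complete pairs", call. = FALSE)
  ab <- unclass(matrix)[, pairs$sample_AB, drop = FALSE]
  om <- unclass(matrix)[, pairs$sample_OM, drop = FALSE]
  n_complete <- rowSums(!is.na(ab) & !is.na(om))
  n_ab <- rowSums(!is.na(ab))
  n_om <- rowSums(!is.na(om))
  scorable <- n_complete >= min_pairs & n_ab >= 2 & n_om >= 2

  med_ab <- .row_medians(ab)
  med_om <- .row_medians(om)
  merit <- abs(med_ab - med_om) - (.row_sds(ab) + .row_sds(om))

  cache <- new.env(parent = emptyenv())
  d <- ab - om
  idx <- which(scorable & merit > 0)
  wp <- rep(NA_real_, nrow(matrix))
  for (j in idx) {
    wp[j] <- wilcoxon_signed_rank(d[j, ], .cache = cache)$p
  }

  keep <- which(scorable & merit > 0 & !is.na(wp) & wp < p_threshold)
  res <- data.frame(
    probe_id = rownames(matrix)[keep],
    merit = merit[keep],
    wilcoxon_p = wp[keep],
    mean_AB = rowMeans(ab, na.rm = TRUE)[keep],
    mean_OM = rowMeans(om, na.rm = TRUE)[keep],
    stringsAsFactors = FALSE)
  res$rank <- rank_with_ties(-res$merit, res$probe_id)
  res <- res[order(res$rank),
             c("probe_id", "merit", "wilcoxon_p", "rank",
               "mean_AB", "mean_OM")]
  rownames(res) <- NULL
  attr(res, "n_scored") <- sum(scorable)
  res
}
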