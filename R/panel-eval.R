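#' Panel-based similarity score between two samples
#'
#' `1 - mean(abs(beta_p - beta_q))` over the panel probes, with pairwise
#' deletion of missing values. Bounded in \[0, 1\]; 1 for identical
#' profiles.
#'
#' @param matrix A [beta_matrix()].
#' @param sample_p,sample_q Sample ids.
#' @param panel Character vector of probe ids.
#' @return Scalar score in \[0, 1\].
#' @export
inter_sample_score <- function(matrix, sample_p, sample_q, panel) {
  a <- unclass(matrix)[panel, sample_p]
  b <- unclass(matrix)[panel, sample_q]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) stop("empty effective panel for this pair", call. = FALSE)
  1 - mean(abs(a[ok] - b[ok]))
}

#' Within- vs between-class separation of a biomarker panel
#'
#' Computes the inter-sample score for every unordered pair of samples at
#' one timepoint, classifies pairs as within_AB, within_OM or between, and
#' reports whether the panel achieves complete separation: every
#' between-class pair scoring strictly below every within-class pair
#' (ties count as overlap).
#'
#' @param matrix A [beta_matrix()].
#' @param sheet A [sample_sheet()].
#' @param panel Character vector of panel probe ids.
#' @param timepoint `"before"` or `"after"`.
#' @param bins Number of fixed-width histogram bins on \[0, 1\]
#'   (default 30).
#' @return A `SeparationReport`: list with `panel`, `pairs` (data frame:
#'   `sample_p`, `sample_q`, `score`, `pair_type`), `summary` (list:
#'   `min_within`, `max_between`, `complete_separation`) and `histogram`
#'   (data frame of bin edges and per-type counts).
#' @export
separation_report <- function(matrix, sheet, panel, timepoint, bins = 30) {
  sub <- sheet[sheet$timepoint == timepoint, , drop = FALSE]
  if (sum(sub$tissue == "AB") < 2 || sum(sub$tissue == "OM") < 2) {
    stop("need at least 2 samples per class", call. = FALSE)
  }
  ids <- sub$sample_id
  cls <- sub$tissue
  n <- length(ids)
  rows <- vector("list", n * (n - 1) / 2)
  k <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      k <- k + 1
      type <- if (cls[i] != cls[j]) "between"
              else if (cls[i] == "AB") "within_AB" else "within_OM"
      rows[[k]] <- data.frame(
        sample_p = ids[i], sample_q = ids[j],
        score = inter_sample_score(matrix, ids[i], ids[j], panel),
        pair_type = type, stringsAsFactors = FALSE)
    }
  }
  pairs <- do.call(rbind, rows)
  within <- pairs$score[pairs$pair_type != "between"]
  between <- pairs$score[pairs$pair_type == "between"]
  summary <- list(min_within = min(within), max_between = max(between),
                  complete_separation = max(between) < min(within))

  edges <- seq(0, 1, length.out = bins + 1)
  bin_of <- pmin(pmax(findInterval(pairs$score, edges,
                                   rightmost.closed = TRUE), 1), bins)
  histogram <- data.frame(bin_lo = edges[-(bins + 1)], bin_hi = edges[-1])
  for (type in c("within_AB", "within_OM", "between")) {
    histogram[[type]] <- tabulate(bin_of[pairs$pair_type == type],
                                  nbins = bins)
  }
  structure(list(panel = panel, pairs = pairs, summary = summary,
                 histogram = histogram, timepoint = timepoint),
            class = "SeparationReport")
}

#' @export
print.SeparationReport <- function(x, ...) {
  cat(sprintf(
    "SeparationReport: %d-probe panel, %d pairs (%s timepoint)\n",
    length(x$panel), nrow(x$pairs), x$timepoint))
  cat(sprintf("  min within-class score:  %.4f\n", x$summary$min_within))
  cat(sprintf("  max between-class score: %.4f\n", x$summary$max_between))
  cat(sprintf("  complete separation:     %s\n",
              x$summary$complete_separation))
  invisible(x)
}

#' Reduce a ranked shortlist to its top-k panel
#'
#' @param shortlist Character vector of probe ids in rank order, or a data
#'   frame with `probe_id` ordered by rank.
#' @param k Panel size, `1 <= k <= length(shortlist)`.
#' @return Character vector of the top-k probe ids (a prefix, so panels are
#'   nested in k).
#' @export
reduce_panel <- function(shortlist, k) {
  ids <- if (is.data.frame(shortlist)) shortlist$probe_id else shortlist
  if (k < 1 || k > length(ids)) {
    stop("k must be between 1 and the shortlist size", call. = FALSE)
  }
  ids[seq_len(k)]
}
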