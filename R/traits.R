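#' Per-individual change in a clinical trait
#'
#' Convention: before minus after, so weight loss gives positive changes
#' for weight-like traits. Individuals missing either timepoint are
#' excluded.
#'
#' @param clinical A [clinical_table()].
#' @param trait Trait name.
#' @param individuals Optional individual ids to restrict to.
#' @return Named numeric vector of changes, names = individual ids, sorted.
#' @export
delta_trait <- function(clinical, trait, individuals = NULL) {
  sub <- clinical[clinical$trait == trait, , drop = FALSE]
  if (!is.null(individuals)) {
    sub <- sub[sub$individual_id %in% individuals, , drop = FALSE]
  }
  before <- sub[sub$timepoint == "before", ]
  after <- sub[sub$timepoint == "after", ]
  common <- sort(intersect(before$individual_id, after$individual_id))
  out <- before$value[match(common, before$individual_id)] -
    after$value[match(common, after$individual_id)]
  names(out) <- common
  out
}

#' Pearson correlation with a t-distribution p value
#'
#' Product-moment correlation computed from first principles, with the
#' two-sided p value from `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2
#' degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length >= 3; pairs with any `NA`
#'   are dropped.
#' @return List with `r`, `p`, `n`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  xc <- x - mean(x)
  yc <- y - mean(y)
  sx <- sqrt(sum(xc^2))
  sy <- sqrt(sum(yc^2))
  if (sx == 0 || sy == 0) stop("zero variance input", call. = FALSE)
  r <- sum(xc * yc) / (sx * sy)
  r <- max(-1, min(1, r))
  p <- if (abs(r) == 1) 0 else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(t), df = n - 2)
  }
  list(r = r, p = p, n = n)
}

#' Per-individual tissue methylation difference for each probe
#'
#' For each probe, the AB minus OM beta difference within each individual
#' at one timepoint.
#'
#' @param matrix A [beta_matrix()].
#' @param sheet A [sample_sheet()].
#' @param timepoint `"before"` or `"after"`.
#' @param probes Optional probe subset (default all).
#' @return Matrix probes x individuals of paired differences.
#' @export
individual_delta_beta <- function(matrix, sheet, timepoint, probes = NULL) {
  pairs <- pair_samples(sheet, timepoint)
  if (is.null(probes)) probes <- rownames(matrix)
  d <- unclass(matrix)[probes, pairs$sample_AB, drop = FALSE] -
    unclass(matrix)[probes, pairs$sample_OM, drop = FALSE]
  colnames(d) <- pairs$individual_id
  d
}

#' Screen probe methylation changes against clinical trait changes
#'
#' Tests every probe x trait pair with [pearson_r()] between the
#' per-individual tissue delta-beta and the per-individual trait change,
#' retaining pairs with p at or below the threshold. No multiple-testing
#' correction is applied (the screen filters on raw p).
#'
#' @param delta_betas Probes x individuals matrix from
#'   [individual_delta_beta()].
#' @param delta_traits Named list of per-individual trait changes (each as
#'   returned by [delta_trait()]), or a single named vector.
#' @param p_threshold Raw p threshold (default 0.001).
#' @return Data frame (`CorrelationRecord`s): `probe_id`, `trait`, `r`,
#'   `p`, `n`, sorted by `abs(r)` descending (probe id breaks ties).
#' @export
correlation_screen <- function(delta_betas, delta_traits,
                               p_threshold = 0.001) {
  if (!is.list(delta_traits)) delta_traits <- list(trait = delta_traits)
  rows <- list()
  for (trait in names(delta_traits)) {
    dt <- delta_traits[[trait]]
    common <- intersect(colnames(delta_betas), names(dt))
    if (length(common) < 3) {
      stop("fewer than 3 individuals with both methylation and trait data",
           call. = FALSE)
    }
    dtc <- dt[common]
    for (probe in rownames(delta_betas)) {
      db <- delta_betas[probe, common]
      if (stats::sd(db, na.rm = TRUE) == 0) next
      res <- pearson_r(db, dtc)
      if (res$p <= p_threshold) {
        rows[[length(rows) + 1]] <- data.frame(
          probe_id = probe, trait = trait, r = res$r, p = res$p,
          n = res$n, stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(probe_id = character(0), trait = character(0),
               r = numeric(0), p = numeric(0), n = integer(0))
  out <- out[order(-abs(out$r), out$probe_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
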