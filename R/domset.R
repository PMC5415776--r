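#' Coverage relation between candidate biomarker sites
#'
#' Site u covers site v when the absolute Pearson correlation of their
#' beta-value profiles across all samples is at least `tau`: a covered site
#' carries (nearly) the same class information as its coverer and can be
#' eliminated from the shortlist. Self-cover always holds; zero-variance
#' probes cover only themselves.
#'
#' @param matrix A [beta_matrix()].
#' @param candidates A `MeritTable` from [candidate_filter()] (or any data
#'   frame with `probe_id` and `merit` columns).
#' @param tau Agreement threshold in (0, 1\] (default 0.9).
#' @param samples Optional subset of sample ids.
#' @return A `CoverGraph`: list with `probes`, `merit`, logical symmetric
#'   `covers` matrix (diagonal TRUE), and `tau`.
#' @export
coverage_relation <- function(matrix, candidates, tau = 0.9,
                              samples = NULL) {
  stopifnot(nrow(candidates) > 0, tau > 0, tau <= 1)
  probes <- candidates$probe_id
  if (is.null(samples)) samples <- colnames(matrix)
  sub <- t(unclass(matrix)[probes, samples, drop = FALSE])
  suppressWarnings(
    cc <- stats::cor(sub, use = "pairwise.complete.obs"))
  covers <- !is.na(cc) & abs(cc) >= tau
  diag(covers) <- TRUE
  dimnames(covers) <- list(probes, probes)
  structure(list(probes = probes, merit = candidates$merit,
                 covers = covers, tau = tau),
            class = "CoverGraph")
}

# exact minimum dominating set by increasing-cardinality subset search,
# after forcing nodes whose only dominator is themselves
.domset_exact <- function(covers) {
  n <- nrow(covers)
  nodes <- seq_len(n)
  # forced: v dominated only by itself
  dominators <- lapply(nodes, function(v) which(covers[, v]))
  forced <- nodes[lengths(dominators) == 1]
  selected <- forced
  uncovered <- nodes[!apply(covers[selected, , drop = FALSE], 2, any)]
  if (length(selected) > 0 && length(uncovered) == 0) return(selected)
  if (length(selected) == 0) uncovered <- nodes
  # candidates that cover at least one uncovered node
  cand <- nodes[apply(covers[, uncovered, drop = FALSE], 1, any)]
  for (k in seq_len(length(cand))) {
    combos <- utils::combn(cand, k, simplify = FALSE)
    for (s in combos) {
      if (all(apply(covers[s, uncovered, drop = FALSE], 2, any))) {
        return(sort(c(selected, s)))
      }
    }
  }
  sort(nodes)  # unreachable: self-cover guarantees feasibility
}

# greedy set cover: most new coverage first; merit then id break ties
.domset_greedy <- function(covers, merit) {
  n <- nrow(covers)
  uncovered <- rep(TRUE, n)
  selected <- integer(0)
  ids <- rownames(covers)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  while (any(uncovered)) {
    gain <- rowSums(covers[, uncovered, drop = FALSE])
    gain[selected] <- -1
    best <- order(-gain, -merit, ids)[1]
    selected <- c(selected, best)
    uncovered <- uncovered & !covers[best, ]
  }
  sort(selected)
}

#' Red/blue dominating-set reduction of the candidate list
#'
#' Instantiates red/blue dominating set with red (potential dominators) and
#' blue (sites to be covered) both equal to the candidate set, which
#' reduces to classical dominating set on the cover graph: find a smallest
#' set S of sites such that every candidate is covered by some member of S.
#' Sites outside S are "best covered by others" and eliminated.
#'
#' Exact minimum search is used when the instance (after forcing
#' self-only-covered nodes) has at most `exact_limit` candidates; otherwise
#' a greedy most-coverage-first heuristic with merit tie-breaks.
#'
#' @param cover A `CoverGraph` from [coverage_relation()].
#' @param exact_limit Largest instance solved exactly (default 20).
#' @return Data frame of the selected sites: `probe_id`, `merit`, `rank`
#'   (merit order within the selection), `covered_sites` (number of
#'   candidates each selected site covers), ordered by rank. Attributes:
#'   `method` ("exact"/"greedy"), `eliminated` (probe ids not selected, in
#'   merit order).
#' @export
redblue_dominating_set <- function(cover, exact_limit = 20) {
  stopifnot(inherits(cover, "CoverGraph"))
  covers <- cover$covers
  n <- nrow(covers)
  method <- if (n <= exact_limit) "exact" else "greedy"
  sel <- if (method == "exact") .domset_exact(covers)
         else .domset_greedy(covers, cover$merit)
  # feasibility assertion: every candidate dominated
  stopifnot(all(apply(covers[sel, , drop = FALSE], 2, any)))
  merit <- cover$merit[sel]
  ord <- order(-merit, cover$probes[sel])
  sel <- sel[ord]
  out <- data.frame(
    probe_id = cover$probes[sel],
    merit = cover$merit[sel],
    rank = seq_along(sel),
    covered_sites = rowSums(covers[sel, , drop = FALSE]),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  elim <- setdiff(seq_len(n), sel)
  elim <- elim[order(-cover$merit[elim], cover$probes[elim])]
  attr(out, "method") <- method
  attr(out, "eliminated") <- cover$probes[elim]
  out
}
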