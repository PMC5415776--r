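#' Build the sample-similarity graph over a biomarker panel
#'
#' Vertices are samples; the weight of each unordered pair is a bounded
#' similarity computed over the panel probes. The default metric is
#' `1 - mean(abs(beta_p - beta_q))` (missing values pairwise-deleted);
#' `metric = "correlation"` uses `(1 + Pearson r) / 2` instead.
#'
#' @param matrix A [beta_matrix()].
#' @param panel Character vector of panel probe ids (non-empty, all
#'   present).
#' @param samples Optional subset of sample ids (default all columns).
#' @param metric `"meanabs"` (default) or `"correlation"`.
#' @return A `SampleGraph`: list with `samples` and symmetric `weights`
#'   matrix in \[0, 1\] (diagonal 1).
#' @export
build_sample_graph <- function(matrix, panel, samples = NULL,
                               metric = c("meanabs", "correlation")) {
  metric <- match.arg(metric)
  if (length(panel) == 0) stop("panel is empty", call. = FALSE)
  missing_probes <- setdiff(panel, rownames(matrix))
  if (length(missing_probes) > 0) {
    stop("panel probes not in matrix: ",
         paste(utils::head(missing_probes, 3), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(samples)) samples <- colnames(matrix)
  sub <- unclass(matrix)[panel, samples, drop = FALSE]
  n <- length(samples)
  w <- diag(1, n)
  dimnames(w) <- list(samples, samples)
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      a <- sub[, i]
      b <- sub[, j]
      ok <- !is.na(a) & !is.na(b)
      if (!any(ok)) {
        stop(sprintf("samples '%s' and '%s' share no non-missing panel probes",
                     samples[i], samples[j]), call. = FALSE)
      }
      w[i, j] <- w[j, i] <- if (metric == "meanabs") {
        1 - mean(abs(a[ok] - b[ok]))
      } else {
        if (stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) {
          0.5  # uninformative: centre of the correlation-similarity scale
        } else {
          (1 + stats::cor(a[ok], b[ok])) / 2
        }
      }
    }
  }
  structure(list(samples = samples, weights = w, metric = metric),
            class = "SampleGraph")
}

#' Threshold a weighted sample graph into a simple graph
#'
#' @param graph A `SampleGraph` from [build_sample_graph()].
#' @param t Similarity threshold in \[0, 1\]; an edge is kept iff its
#'   weight is >= `t`. The vertex set is unchanged.
#' @return List with `samples` and logical `adjacency` matrix (no
#'   self-edges).
#' @export
threshold_graph <- function(graph, t) {
  stopifnot(inherits(graph, "SampleGraph"), t >= 0, t <= 1)
  adj <- graph$weights >= t
  diag(adj) <- FALSE
  structure(list(samples = graph$samples, adjacency = adj, threshold = t),
            class = "ThresholdedGraph")
}

#' Data-driven similarity threshold from class labels
#'
#' The clique-homogeneity step is diagnostic (labels are known), so the
#' default threshold is the midpoint between the mean within-class and mean
#' between-class edge weights.
#'
#' @param graph A `SampleGraph`.
#' @param sheet A [sample_sheet()] covering the graph's samples.
#' @return Scalar threshold.
#' @export
choose_threshold <- function(graph, sheet) {
  cls <- sheet$tissue[match(graph$samples, sheet$sample_id)]
  if (anyNA(cls)) stop("graph samples missing from sheet", call. = FALSE)
  w <- graph$weights
  same <- outer(cls, cls, "==")
  ut <- upper.tri(w)
  (mean(w[ut & same]) + mean(w[ut & !same])) / 2
}

#' Enumerate all maximal cliques (Bron-Kerbosch with pivoting)
#'
#' @param graph A `ThresholdedGraph` from [threshold_graph()], or a logical
#'   adjacency matrix with dimnames.
#' @return List of character vectors, each a maximal clique, sorted by size
#'   descending then lexicographic membership; members sorted within each
#'   clique.
#' @export
maximal_cliques <- function(graph) {
  adj <- if (inherits(graph, "ThresholdedGraph")) graph$adjacency else graph
  stopifnot(is.matrix(adj), is.logical(adj), nrow(adj) == ncol(adj))
  diag(adj) <- FALSE
  if (!isTRUE(all(adj == t(adj)))) stop("adjacency must be symmetric",
                                        call. = FALSE)
  n <- nrow(adj)
  ids <- rownames(adj)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  out <- list()
  nb <- lapply(seq_len(n), function(i) which(adj[i, ]))

  bk <- function(R, P, X) {
    if (length(P) == 0 && length(X) == 0) {
      out[[length(out) + 1]] <<- R
      return(invisible())
    }
    # pivot: vertex of P union X with most neighbours in P
    cand <- c(P, X)
    deg <- vapply(cand, function(u) length(intersect(nb[[u]], P)), integer(1))
    pivot <- cand[which.max(deg)]
    for (v in setdiff(P, nb[[pivot]])) {
      bk(c(R, v), intersect(P, nb[[v]]), intersect(X, nb[[v]]))
      P <- setdiff(P, v)
      X <- c(X, v)
    }
  }
  bk(integer(0), seq_len(n), integer(0))

  cliques <- lapply(out, function(ix) sort(ids[ix]))
  keys <- vapply(cliques, paste, character(1), collapse = "\r")
  sizes <- lengths(cliques)
  cliques[order(-sizes, keys)]
}

#' Tissue-class homogeneity of maximal cliques
#'
#' A clique is homogeneous iff all members share the same tissue class.
#' The overall verdict considers cliques of at least `min_size` members
#' (size-2 cliques are bare edges and carry little evidence).
#'
#' @param cliques List of cliques from [maximal_cliques()].
#' @param sheet A [sample_sheet()] covering all clique members.
#' @param min_size Minimum clique size entering the overall verdict
#'   (default 3).
#' @return List with `per_clique` (data frame: `clique`, `size`, `classes`,
#'   `homogeneous`) and `pass` (logical: all cliques of size >= `min_size`
#'   homogeneous).
#' @export
homogeneity_check <- function(cliques, sheet, min_size = 3) {
  cls_of <- function(ids) sheet$tissue[match(ids, sheet$sample_id)]
  rows <- lapply(seq_along(cliques), function(k) {
    cls <- cls_of(cliques[[k]])
    if (anyNA(cls)) stop("clique member missing from sheet", call. = FALSE)
    data.frame(clique = paste(cliques[[k]], collapse = ","),
               size = length(cliques[[k]]),
               classes = paste(sort(unique(cls)), collapse = ","),
               homogeneous = length(unique(cls)) == 1,
               stringsAsFactors = FALSE)
  })
  per <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(clique = character(0), size = integer(0),
               classes = character(0), homogeneous = logical(0))
  big <- per$size >= min_size
  list(per_clique = per, pass = all(per$homogeneous[big]))
}
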