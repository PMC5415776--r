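# Independent brute-force oracles and fixture builders used across tests.

# Exact two-sided Wilcoxon signed-rank p by enumeration of all 2^n sign
# assignments (zeros dropped first, average ranks for ties).
bf_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  w_all <- vapply(seq_len(2^n) - 1, function(mask) {
    pos <- bitwAnd(mask, 2^(seq_len(n) - 1)) > 0
    sum(r[pos])
  }, numeric(1))
  p_le <- mean(w_all <= w_obs)
  p_ge <- mean(w_all >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# All maximal cliques by enumeration of every vertex subset.
bf_maximal_cliques <- function(adj) {
  n <- nrow(adj)
  ids <- rownames(adj)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  is_clique <- function(s) {
    if (length(s) <= 1) return(TRUE)
    sub <- adj[s, s, drop = FALSE]
    all(sub[upper.tri(sub)])
  }
  cliques <- list()
  for (mask in seq_len(2^n - 1)) {
    s <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (!is_clique(s)) next
    extendable <- any(vapply(setdiff(seq_len(n), s), function(v) {
      all(adj[v, s])
    }, logical(1)))
    if (!extendable) cliques[[length(cliques) + 1]] <- sort(ids[s])
  }
  keys <- vapply(cliques, paste, character(1), collapse = "\r")
  sizes <- lengths(cliques)
  cliques[order(-sizes, keys)]
}

# Minimum dominating-set cardinality by exhaustive subset search.
bf_min_domset_size <- function(covers) {
  n <- nrow(covers)
  for (k in seq_len(n)) {
    combos <- utils::combn(n, k, simplify = FALSE)
    for (s in combos) {
      if (all(apply(covers[s, , drop = FALSE], 2, any))) return(k)
    }
  }
  n
}

random_adjacency <- function(n, p) {
  adj <- matrix(FALSE, n, n)
  adj[upper.tri(adj)] <- stats::runif(n * (n - 1) / 2) < p
  adj <- adj | t(adj)
  rownames(adj) <- colnames(adj) <- sprintf("v%02d", seq_len(n))
  adj
}

random_cover_graph <- function(n, p) {
  covers <- random_adjacency(n, p)
  diag(covers) <- TRUE
  probes <- sprintf("cg%08d", seq_len(n))
  dimnames(covers) <- list(probes, probes)
  structure(list(probes = probes,
                 merit = stats::runif(n),
                 covers = covers, tau = 0.9),
            class = "CoverGraph")
}

# Small valid beta matrix of uniform noise with cg-style ids.
random_beta_matrix <- function(n_probes, n_samples) {
  vals <- matrix(stats::runif(n_probes * n_samples), n_probes, n_samples,
                 dimnames = list(sprintf("cg%08d", seq_len(n_probes)),
                                 sprintf("s%02d", seq_len(n_samples))))
  beta_matrix(vals)
}

# Paired sheet: n individuals x AB/OM at one or both timepoints, sample ids
# matching simulate_cohort's convention.
paired_sheet <- function(n_ind, timepoints = "before") {
  ind <- sprintf("ind%02d", seq_len(n_ind))
  grid <- expand.grid(individual_id = ind, tissue = c("AB", "OM"),
                      timepoint = timepoints, stringsAsFactors = FALSE)
  grid$sample_id <- paste(grid$individual_id, grid$tissue, grid$timepoint,
                          sep = "_")
  sample_sheet(grid[, c("sample_id", "individual_id", "tissue",
                        "timepoint")])
}

# Paired-noise beta matrix matching a paired_sheet (no tissue signal).
null_paired_cohort <- function(n_probes, n_ind, timepoints = "before") {
  sheet <- paired_sheet(n_ind, timepoints)
  vals <- matrix(stats::rbeta(n_probes * nrow(sheet), 5, 5),
                 n_probes, nrow(sheet),
                 dimnames = list(sprintf("cg%08d", seq_len(n_probes)),
                                 sheet$sample_id))
  list(beta = beta_matrix(vals), sheet = sheet)
}
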