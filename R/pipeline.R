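#' Run configuration for the discovery pipeline
#'
#' Bundles every stage parameter; serialised verbatim (JSON) into each
#' output directory so runs can be reproduced bit-identically.
#'
#' @param timepoint Timepoint analysed by [run_discovery()].
#' @param p_wilcoxon Wilcoxon p threshold of the candidate filter.
#' @param panel_m Number of top-merit sites used to build the sample graph.
#' @param graph_threshold `"auto"` (midpoint rule of [choose_threshold()])
#'   or a fixed numeric in \[0, 1\].
#' @param graph_metric Similarity metric for [build_sample_graph()].
#' @param tau Coverage agreement threshold of [coverage_relation()].
#' @param exact_limit Largest dominating-set instance solved exactly.
#' @param k_values Reduced panel sizes evaluated in addition to the full
#'   shortlist (default `c(10, 1)`).
#' @param bins Histogram bins of [separation_report()].
#' @param alpha_adjusted Bonferroni-adjusted threshold of
#'   [run_diffmeth_compare()].
#' @param widen_min Delta-beta widening flag threshold.
#' @param min_clique_size Minimum clique size entering the homogeneity
#'   verdict.
#' @param seed Seed recorded with the run (the pipeline itself is
#'   deterministic; the seed matters when the inputs are simulated).
#' @return A list of class `RunConfig`.
#' @export
run_config <- function(timepoint = "before", p_wilcoxon = 0.001,
                       panel_m = 100, graph_threshold = "auto",
                       graph_metric = "meanabs", tau = 0.9,
                       exact_limit = 20, k_values = c(10, 1), bins = 30,
                       alpha_adjusted = 1e-7, widen_min = 0.05,
                       min_clique_size = 3, seed = 1L) {
  stopifnot(p_wilcoxon >= 0, p_wilcoxon <= 1, panel_m >= 1,
            tau > 0, tau <= 1, alpha_adjusted >= 0, alpha_adjusted <= 1,
            bins >= 1)
  if (is.numeric(graph_threshold)) {
    stopifnot(graph_threshold >= 0, graph_threshold <= 1)
  } else {
    stopifnot(identical(graph_threshold, "auto"))
  }
  structure(as.list(environment()), class = "RunConfig")
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full combinatorial biomarker discovery chain
#'
#' merit + Wilcoxon candidate filter -> sample graph over the top-merit
#' panel -> threshold + maximal cliques + class-homogeneity gate ->
#' coverage relation + red/blue dominating set -> ranked shortlist ->
#' separation reports for the full shortlist and each reduced top-k panel.
#' All intermediate tables, the serialised config and a JSON run summary
#' with per-stage counts are written to `out_dir`.
#'
#' A failed homogeneity gate does not stop the pipeline; it is recorded in
#' the summary (`homogeneity_pass = FALSE`) so callers can distinguish the
#' outcome.
#'
#' @param matrix A [beta_matrix()].
#' @param sheet A [sample_sheet()].
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed), or `NULL` to skip
#'   writing files.
#' @return Invisibly, a list with `candidates`, `graph`, `cliques`,
#'   `homogeneity`, `cover`, `shortlist`, `reports` (named list of
#'   `SeparationReport`s) and `summary`.
#' @export
run_discovery <- function(matrix, sheet, config = run_config(),
                          out_dir = NULL) {
  stopifnot(inherits(config, "RunConfig"))
  tp <- config$timepoint
  candidates <- candidate_filter(matrix, sheet, tp,
                                 p_threshold = config$p_wilcoxon)
  counts <- list(n_probes = nrow(matrix),
                 n_scored = attr(candidates, "n_scored"),
                 n_candidates = nrow(candidates))

  empty <- nrow(candidates) == 0
  graph <- cliques <- homog <- cover <- NULL
  shortlist <- data.frame(probe_id = character(0), merit = numeric(0),
                          rank = integer(0), covered_sites = integer(0))
  reports <- list()
  if (!empty) {
    panel_m <- min(config$panel_m, nrow(candidates))
    graph_panel <- candidates$probe_id[seq_len(panel_m)]
    tp_samples <- sheet$sample_id[sheet$timepoint == tp]
    graph <- build_sample_graph(matrix, graph_panel, samples = tp_samples,
                                metric = config$graph_metric)
    t <- if (identical(config$graph_threshold, "auto")) {
      choose_threshold(graph, sheet)
    } else config$graph_threshold
    thr <- threshold_graph(graph, t)
    cliques <- maximal_cliques(thr)
    homog <- homogeneity_check(cliques, sheet,
                               min_size = config$min_clique_size)

    cover <- coverage_relation(matrix, candidates, tau = config$tau,
                               samples = tp_samples)
    shortlist <- redblue_dominating_set(cover,
                                        exact_limit = config$exact_limit)
    reports$full <- separation_report(matrix, sheet, shortlist$probe_id,
                                      tp, bins = config$bins)
    for (k in config$k_values) {
      if (k <= nrow(shortlist)) {
        reports[[paste0("top", k)]] <- separation_report(
          matrix, sheet, reduce_panel(shortlist, k), tp,
          bins = config$bins)
      }
    }
  }
  counts$n_shortlist <- nrow(shortlist)
  summary <- list(
    timepoint = tp,
    counts = counts,
    graph_threshold = if (!empty) thr$threshold else NA,
    homogeneity_pass = if (!empty) homog$pass else NA,
    domset_method = if (!empty) attr(shortlist, "method") else NA,
    separation = lapply(reports, function(r) r$summary),
    seed = config$seed)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(unclass(config), file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, null = "null", digits = NA)
    .write_tsv(candidates, file.path(out_dir, "merit_table.tsv"))
    .write_tsv(shortlist, file.path(out_dir, "shortlist.tsv"))
    if (!empty) {
      w <- graph$weights
      ut <- which(upper.tri(w), arr.ind = TRUE)
      .write_tsv(data.frame(sample_a = rownames(w)[ut[, 1]],
                            sample_b = colnames(w)[ut[, 2]],
                            weight = w[ut]),
                 file.path(out_dir, "graph_edges.tsv"))
      .write_tsv(homog$per_clique, file.path(out_dir, "cliques.tsv"))
      for (nm in names(reports)) {
        .write_tsv(reports[[nm]]$pairs,
                   file.path(out_dir, paste0("separation_", nm, ".tsv")))
      }
    }
    jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                         auto_unbox = TRUE, null = "null", digits = NA,
                         na = "null")
  }
  invisible(list(candidates = candidates, graph = graph, cliques = cliques,
                 homogeneity = homog, cover = cover, shortlist = shortlist,
                 reports = reports, summary = summary))
}

#' Run the traditional differential-methylation comparison
#'
#' Per-timepoint paired t tests with Bonferroni control, significant-site
#' tables ranked by adjusted p and by absolute delta-beta, signed
#' delta-beta bin summaries, the two-timepoint overlap report with
#' widening flags, and a cross-reference of traditional ranks to
#' combinatorial biomarker ranks (`NA` when a site was not seen by the
#' biomarker analysis).
#'
#' @param matrix A [beta_matrix()].
#' @param sheet A [sample_sheet()] with both timepoints.
#' @param config A [run_config()].
#' @param out_dir Output directory or `NULL`.
#' @return Invisibly, a list with `records` (per timepoint),
#'   `significant` (per timepoint), `bins` (per timepoint), `overlap`
#'   and `summary`.
#' @export
run_diffmeth_compare <- function(matrix, sheet, config = run_config(),
                                 out_dir = NULL) {
  stopifnot(inherits(config, "RunConfig"))
  tps <- c("before", "after")
  if (!all(tps %in% sheet$timepoint)) {
    stop("both timepoints required", call. = FALSE)
  }
  records <- significant <- bins <- list()
  for (tp in tps) {
    records[[tp]] <- diff_meth(matrix, sheet, tp)
    significant[[tp]] <- significant_sites(records[[tp]],
                                           config$alpha_adjusted)
    bins[[tp]] <- bin_by_delta(significant[[tp]])
  }
  overlap <- overlap_timepoints(significant$before, significant$after,
                                widen_min = config$widen_min)
  # cross-reference combinatorial biomarker ranks per timepoint
  for (tp in tps) {
    cand <- candidate_filter(matrix, sheet, tp,
                             p_threshold = config$p_wilcoxon)
    significant[[tp]]$rank_biomarker <-
      cand$rank[match(significant[[tp]]$probe_id, cand$probe_id)]
    significant[[tp]]$overlap_cpg <-
      significant[[tp]]$probe_id %in% overlap$probe_id
    significant[[tp]]$greater_delta_post <-
      overlap$greater_delta_post[match(significant[[tp]]$probe_id,
                                       overlap$probe_id)]
  }
  summary <- list(
    n_significant = lapply(significant, nrow),
    n_overlap = nrow(overlap),
    n_widened = sum(overlap$greater_delta_post),
    alpha_adjusted = config$alpha_adjusted,
    n_tests = lapply(records, attr, "n_tests"),
    seed = config$seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(unclass(config), file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, null = "null", digits = NA)
    for (tp in tps) {
      .write_tsv(significant[[tp]],
                 file.path(out_dir, paste0("significant_", tp, ".tsv")))
      .write_tsv(bins[[tp]], file.path(out_dir, paste0("bins_", tp, ".tsv")))
    }
    .write_tsv(overlap, file.path(out_dir, "overlap.tsv"))
    jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                         auto_unbox = TRUE, null = "null", digits = NA)
  }
  invisible(list(records = records, significant = significant, bins = bins,
                 overlap = overlap, summary = summary))
}
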