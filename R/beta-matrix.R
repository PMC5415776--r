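#' Construct a validated beta-value matrix
#'
#' A `BetaMatrix` holds methylation fractions (beta values) for a set of CpG
#' probes (rows) across samples (columns). Beta values are bounded in
#' \[0, 1\]; missing observations are stored as `NA`.
#'
#' @param values Numeric matrix, probes x samples. Row names are probe ids,
#'   column names are sample ids; both must be unique and non-empty.
#' @param probe_ids,sample_ids Optional character vectors overriding the
#'   dimnames of `values`.
#' @return An object of class `BetaMatrix`: a numeric matrix with validated
#'   dimnames and range.
#' @examples
#' m <- matrix(c(0.1, 0.9, 0.5, 0.5), nrow = 2,
#'             dimnames = list(c("cg01", "cg02"), c("s1", "s2")))
#' bm <- beta_matrix(m)
#' dim(bm)
#' @export
beta_matrix <- function(values, probe_ids = NULL, sample_ids = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (!is.null(probe_ids)) rownames(values) <- probe_ids
  if (!is.null(sample_ids)) colnames(values) <- sample_ids
  pid <- rownames(values)
  sid <- colnames(values)
  if (is.null(pid) || is.null(sid)) {
    stop("BetaMatrix requires probe ids (rownames) and sample ids (colnames)",
         call. = FALSE)
  }
  if (anyDuplicated(pid)) stop("duplicate probe ids", call. = FALSE)
  if (anyDuplicated(sid)) stop("duplicate sample ids", call. = FALSE)
  bad <- which(!is.na(values) & (values < 0 | values > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "beta value out of [0,1] at probe '%s', sample '%s' (value %g)",
      pid[bad[1, 1]], sid[bad[1, 2]], values[bad[1, , drop = FALSE]]),
      call. = FALSE)
  }
  structure(values, class = c("BetaMatrix", class(values)))
}

#' @export
print.BetaMatrix <- function(x, ...) {
  cat(sprintf("BetaMatrix: %d probes x %d samples (%d missing values)\n",
              nrow(x), ncol(x), sum(is.na(x))))
  invisible(x)
}

#' Read a beta-value matrix from delimited text
#'
#' The file layout is probes as rows with the probe id in the first column,
#' and a header row of sample ids. Values outside \[0, 1\] are an error;
#' `na_string` tokens become `NA`.
#'
#' @param path Path to the delimited file.
#' @param sep Field delimiter (default tab).
#' @param na_string Token encoding a missing value (default `"NA"`).
#' @return A [beta_matrix()].
#' @export
read_beta_matrix <- function(path, sep = "\t", na_string = "NA") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          na.strings = na_string, check.names = FALSE,
                          colClasses = NA, stringsAsFactors = FALSE,
                          comment.char = "")
  if (ncol(df) < 2) stop("malformed beta matrix: need probe id column plus at least one sample column", call. = FALSE)
  probe_ids <- as.character(df[[1]])
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(vals)) stop("malformed beta matrix: non-numeric values", call. = FALSE)
  storage.mode(vals) <- "double"
  rownames(vals) <- probe_ids
  beta_matrix(vals)
}

#' Write a beta-value matrix to delimited text
#'
#' Round-trips losslessly with [read_beta_matrix()] at 15 significant digits.
#'
#' @param x A `BetaMatrix`.
#' @param path Output path.
#' @param sep Field delimiter (default tab).
#' @export
write_beta_matrix <- function(x, path, sep = "\t") {
  stopifnot(inherits(x, "BetaMatrix"))
  df <- data.frame(probe_id = rownames(x),
                   format(unclass(x), digits = 15, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("probe_id", colnames(x))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Logit-2 (M-value) transform of beta values
#'
#' Computes `log2(b / (1 - b))` after clipping `b` into
#' `[epsilon, 1 - epsilon]` so that boundary betas map to finite M-values.
#' The transform is strictly increasing on the clipped range and
#' antisymmetric about beta = 0.5.
#'
#' @param beta Numeric vector of methylation fractions in \[0, 1\].
#' @param epsilon Clipping bound, in (0, 0.5).
#' @return Numeric vector of M-values (log2 scale).
#' @examples
#' m_transform(c(0.5, 0.8))  # 0 and 2
#' @export
m_transform <- function(beta, epsilon = 1e-6) {
  if (!is.numeric(epsilon) || length(epsilon) != 1 ||
      epsilon <= 0 || epsilon >= 0.5) {
    stop("`epsilon` must be a single value in (0, 0.5)", call. = FALSE)
  }
  if (any(beta < 0 | beta > 1, na.rm = TRUE)) {
    stop("beta values must lie in [0, 1]", call. = FALSE)
  }
  b <- pmin(pmax(beta, epsilon), 1 - epsilon)
  log2(b / (1 - b))
}

#' Construct a validated sample sheet
#'
#' Maps each array sample to its individual, tissue class and timepoint.
#' The paired design assumes at most one sample per
#' (individual, tissue, timepoint) cell.
#'
#' @param df Data frame with columns `sample_id`, `individual_id`, `tissue`
#'   (values in `c("AB", "OM")`) and `timepoint` (values in
#'   `c("before", "after")`).
#' @return A `SampleSheet` data frame.
#' @export
sample_sheet <- function(df) {
  need <- c("sample_id", "individual_id", "tissue", "timepoint")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("sample sheet missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(df)[need]
  for (col in need) df[[col]] <- as.character(df[[col]])
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids", call. = FALSE)
  if (!all(df$tissue %in% c("AB", "OM"))) {
    stop("tissue must be 'AB' or 'OM'", call. = FALSE)
  }
  if (!all(df$timepoint %in% c("before", "after"))) {
    stop("timepoint must be 'before' or 'after'", call. = FALSE)
  }
  key <- paste(df$individual_id, df$tissue, df$timepoint)
  if (anyDuplicated(key)) {
    stop("more than one sample per (individual, tissue, timepoint)",
         call. = FALSE)
  }
  class(df) <- c("SampleSheet", "data.frame")
  df
}

#' Read a sample sheet from delimited text
#' @param path Path to the delimited file with the named columns of
#'   [sample_sheet()].
#' @param sep Field delimiter (default tab).
#' @export
read_sample_sheet <- function(path, sep = "\t") {
  sample_sheet(utils::read.table(path, header = TRUE, sep = sep,
                                 stringsAsFactors = FALSE))
}

#' Write a sample sheet to delimited text
#' @param x A `SampleSheet`.
#' @param path Output path.
#' @param sep Field delimiter.
#' @export
write_sample_sheet <- function(x, path, sep = "\t") {
  utils::write.table(as.data.frame(x), path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Pair AB and OM samples of each individual at a timepoint
#'
#' Individuals lacking either tissue at the requested timepoint are skipped.
#'
#' @param sheet A [sample_sheet()].
#' @param timepoint `"before"` or `"after"`.
#' @return Data frame with columns `individual_id`, `sample_AB`, `sample_OM`,
#'   ordered by individual id.
#' @export
pair_samples <- function(sheet, timepoint) {
  stopifnot(timepoint %in% c("before", "after"))
  sub <- sheet[sheet$timepoint == timepoint, , drop = FALSE]
  ab <- sub[sub$tissue == "AB", c("individual_id", "sample_id")]
  om <- sub[sub$tissue == "OM", c("individual_id", "sample_id")]
  names(ab)[2] <- "sample_AB"
  names(om)[2] <- "sample_OM"
  pairs <- merge(ab, om, by = "individual_id")
  pairs <- pairs[order(pairs$individual_id), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

#' Read a probe annotation table
#'
#' Manifest-style annotation: probe id, chromosome label, 1-based position
#' (GRCh37), gene symbol (`"Intergenic"` when unannotated), region feature,
#' and a SNP flag.
#'
#' @param path Path to the delimited file with columns `probe_id`, `chr`,
#'   `pos`, `gene`, `region` and optionally `snp_flag`.
#' @param sep Field delimiter.
#' @return A data frame of class `ProbeAnnotation`.
#' @export
read_probe_annotation <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  probe_annotation(df)
}

#' Construct a validated probe annotation table
#' @param df Data frame with columns `probe_id`, `chr`, `pos`, `gene`,
#'   `region` and optionally `snp_flag`.
#' @return A data frame of class `ProbeAnnotation`.
#' @export
probe_annotation <- function(df) {
  need <- c("probe_id", "chr", "pos", "gene", "region")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("probe annotation missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(df)
  if (!"snp_flag" %in% names(df)) df$snp_flag <- FALSE
  if (anyDuplicated(df$probe_id)) stop("duplicate probe ids", call. = FALSE)
  if (any(df$pos < 1)) stop("positions must be >= 1 (1-based)", call. = FALSE)
  df$gene[is.na(df$gene) | df$gene == ""] <- "Intergenic"
  class(df) <- c("ProbeAnnotation", "data.frame")
  df
}

#' Construct a validated clinical trait table
#'
#' Long format: one row per (individual, trait, timepoint) with the measured
#' value in the trait's own units (kg, mmol/L, ...).
#'
#' @param df Data frame with columns `individual_id`, `trait`, `timepoint`,
#'   `value`.
#' @return A data frame of class `ClinicalTable`.
#' @export
clinical_table <- function(df) {
  need <- c("individual_id", "trait", "timepoint", "value")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("clinical table missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(df)[need]
  df$value <- as.numeric(df$value)
  key <- paste(df$individual_id, df$trait, df$timepoint)
  if (anyDuplicated(key)) {
    stop("more than one value per (individual, trait, timepoint)",
         call. = FALSE)
  }
  class(df) <- c("ClinicalTable", "data.frame")
  df
}

#' Read a clinical trait table from delimited text
#' @param path Path to file with columns `individual_id`, `trait`,
#'   `timepoint`, `value`.
#' @param sep Field delimiter.
#' @export
read_clinical_table <- function(path, sep = "\t") {
  clinical_table(utils::read.table(path, header = TRUE, sep = sep,
                                   stringsAsFactors = FALSE))
}
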