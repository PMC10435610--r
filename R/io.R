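# Readers and writers for the plain-text formats the pipeline exchanges:
# labeled square matrices (TSV), time series (TSV + JSON sidecar for the
# sampling frequency), node-set files, and cohort tables (CSV).

#' Write a labeled square matrix as TSV
#'
#' Full matrix (not a triangle), tab-delimited, UTF-8, with a header row
#' and an index column of labels. Default 6 significant digits; supra
#' and eigenvector artifacts consumed downstream use 12.
#'
#' @param m Matrix (or `connectivity_matrix` / `spanning_tree_layer`).
#' @param path Output file path.
#' @param digits Significant digits (default 6).
#' @export
write_matrix_tsv <- function(m, path, digits = 6L) {
  if (inherits(m, "connectivity_matrix")) m <- m$weights
  if (inherits(m, "spanning_tree_layer")) m <- m$adjacency
  m <- as.matrix(m)
  if (is.null(rownames(m))) {
    rownames(m) <- colnames(m) <- paste0("R", seq_len(nrow(m)))
  }
  df <- data.frame(label = rownames(m),
                   signif(m, digits),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a labeled square matrix from TSV
#'
#' Validates squareness and row/column label agreement. Asymmetry within
#' 1e-9 is silently symmetrized by averaging; larger asymmetry is an
#' error naming the worst cell (override with `require_symmetric =
#' FALSE` for non-symmetric artifacts).
#'
#' @param path File path.
#' @param require_symmetric Enforce symmetry (default TRUE).
#' @return Numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path, require_symmetric = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  labels <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric entries in matrix file ", path)
  if (nrow(m) != ncol(m)) {
    stop("matrix in ", path, " is not square: ", nrow(m), " rows x ",
         ncol(m), " columns")
  }
  if (!identical(labels, colnames(m))) {
    bad <- which(labels != colnames(m))[1]
    stop("row/column label mismatch in ", path, " at position ", bad, ": '",
         labels[bad], "' vs '", colnames(m)[bad], "'")
  }
  rownames(m) <- labels
  if (require_symmetric) {
    d <- abs(m - t(m))
    if (max(d) > 1e-9) {
      w <- which(d == max(d), arr.ind = TRUE)[1, ]
      stop("matrix in ", path, " is asymmetric beyond 1e-9; worst cell (",
           labels[w[1]], ", ", labels[w[2]], ") differs by ", format(max(d)))
    }
    m <- (m + t(m)) / 2
  }
  m
}

#' Write a multichannel time series as TSV with a sampling-rate sidecar
#'
#' Samples in rows, regions in columns, one header row of region labels;
#' the sampling frequency goes to `<path>.json` under key `fs_hz`.
#'
#' @param ts A [time_series].
#' @param path Output TSV path.
#' @param digits Significant digits (default 8).
#' @export
write_timeseries_tsv <- function(ts, path, digits = 8L) {
  stopifnot(inherits(ts, "time_series"))
  utils::write.table(signif(ts$samples, digits), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  jsonlite::write_json(list(fs_hz = ts$fs), paste0(path, ".json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' Read a multichannel time series from TSV
#'
#' @param path TSV path (header row of region labels). The sampling
#'   frequency is taken from `fs_hz`, or from the JSON sidecar
#'   `<path>.json` (key `fs_hz`) when omitted.
#' @param fs_hz Sampling frequency in Hz (optional if a sidecar exists).
#' @return A [time_series].
#' @export
read_timeseries_tsv <- function(path, fs_hz = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(fs_hz)) {
    sidecar <- paste0(path, ".json")
    if (!file.exists(sidecar)) {
      stop("no fs_hz given and no sidecar ", sidecar)
    }
    fs_hz <- jsonlite::read_json(sidecar)$fs_hz
    if (is.null(fs_hz)) stop("sidecar ", sidecar, " lacks key 'fs_hz'")
  }
  m <- as.matrix(utils::read.delim(path, check.names = FALSE))
  time_series(m, fs = as.numeric(fs_hz))
}

#' Read a node-set file
#'
#' One region label per line; blank lines and `#` comments ignored.
#'
#' @param path File path.
#' @return Character vector of labels.
#' @export
read_node_set <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- trimws(readLines(path, encoding = "UTF-8"))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("node-set file ", path, " is empty")
  if (anyDuplicated(lines)) stop("duplicate labels in node-set file ", path)
  lines
}

#' Read a cohort table from CSV
#'
#' Expects columns `subject_id`, `timepoint` and the measure/covariate
#' columns described in [simulate_cohort()].
#'
#' @param path CSV path.
#' @return Data frame.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "timepoint")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("cohort CSV lacks column(s): ",
                            paste(missing, collapse = ", "))
  df
}

#' Default frontoparietal node-set for an N-region parcellation
#'
#' A synthetic stand-in list of frontoparietal regions (superior frontal,
#' middle frontal, inferior parietal, superior parietal, precuneus and
#' angular labels, bilaterally) for use with the generator's default
#' `R1..RN` labels; real analyses should supply their own node-set file
#' matched to their atlas.
#'
#' @param n_regions Parcellation size (default 78).
#' @param fraction Fraction of nodes in the subnetwork (default 0.2).
#' @return Character vector of region labels (every 5th region by
#'   default, deterministic).
#' @export
default_fpn_nodes <- function(n_regions = 78L, fraction = 0.2) {
  k <- max(1L, round(n_regions * fraction))
  idx <- unique(round(seq(1, n_regions, length.out = k)))
  paste0("R", idx)
}
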