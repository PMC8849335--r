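#' Read an index-sort table
#'
#' TSV or CSV with a header; required columns `plate_id`, `well_id`,
#' `colony_count`, plus at least one marker column. Intensity columns are
#' auto-detected as every non-reserved column and must be numeric.
#'
#' @param path file path; `.csv` is comma-separated, anything else
#'   tab-separated.
#' @return index-sort data.frame.
#' @export
read_index_sort <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c("plate_id", "well_id", "colony_count")) {
    if (is.null(df[[col]])) stop("missing required column: ", col)
  }
  markers <- setdiff(names(df), .reserved_cols)
  if (!length(markers)) stop("no marker columns found")
  for (m in markers) {
    x <- suppressWarnings(as.numeric(df[[m]]))
    bad <- which(is.na(x) & !is.na(df[[m]]))
    if (length(bad)) {
      stop("non-numeric intensity in column '", m, "' at row(s): ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
    df[[m]] <- x
  }
  df
}

#' Write an index-sort table as TSV
#'
#' @param dataset index-sort data.frame.
#' @param path output path.
#' @export
write_index_sort <- function(dataset, path) {
  utils::write.table(dataset, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix (Matrix Market + sidecars, or dense CSV)
#'
#' With a `.mtx` path, `features` and `barcodes` are one-name-per-line
#' files whose lengths must match the matrix dimensions (genes x cells).
#' Any other extension is read as a dense CSV with gene row names and cell
#' column headers.
#'
#' @param path matrix path (`.mtx` or dense CSV).
#' @param features,barcodes sidecar paths (MTX only).
#' @return genes x cells `Matrix` sparse matrix.
#' @export
read_expression <- function(path, features = NULL, barcodes = NULL) {
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    if (is.null(features) || is.null(barcodes)) {
      stop("MTX input needs features and barcodes sidecar paths")
    }
    m <- Matrix::readMM(path)
    f <- readLines(features)
    b <- readLines(barcodes)
    if (nrow(m) != length(f) || ncol(m) != length(b)) {
      stop("matrix dimensions (", nrow(m), " x ", ncol(m),
           ") do not match sidecars (", length(f), " genes, ",
           length(b), " cells)")
    }
    dimnames(m) <- list(f, b)
  } else {
    df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
    m <- Matrix::Matrix(as.matrix(df), sparse = TRUE)
  }
  if (nrow(m) == 0L || ncol(m) == 0L) stop("empty expression matrix")
  methods::as(m, "CsparseMatrix")
}

#' Write an expression matrix as Matrix Market with sidecars
#'
#' @param counts genes x cells matrix.
#' @param dir output directory (created if needed); writes `matrix.mtx`,
#'   `features.tsv`, `barcodes.tsv`.
#' @return the directory, invisibly.
#' @export
write_expression <- function(counts, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  m <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts) %||% sprintf("gene%d", seq_len(nrow(counts))),
             file.path(dir, "features.tsv"))
  writeLines(colnames(counts) %||% sprintf("cell%d", seq_len(ncol(counts))),
             file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Write a gating panel as JSON
#'
#' Schema: an array of `{"marker": str, "direction": "hi"|"lo",
#' "percentile": float}` objects in gate order.
#'
#' @param panel a `gating_panel`.
#' @param path output path.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "gating_panel"))
  jsonlite::write_json(panel$gates, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a gating panel from JSON
#'
#' @param path JSON path written by [write_panel()].
#' @return a `gating_panel`.
#' @export
read_panel <- function(path) {
  gating_panel(jsonlite::read_json(path, simplifyVector = TRUE))
}
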