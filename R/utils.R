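#' Apply a single percentile gate to a vector of intensities
#'
#' A gate keeps the top (`direction = "hi"`) or bottom (`direction = "lo"`)
#' fraction `p` of the supplied values. Ties at the percentile boundary are
#' included, so the kept fraction can slightly exceed `p` when values repeat.
#'
#' @param values numeric vector of marker intensities (any monotone scale).
#' @param direction `"hi"` to keep high expressors, `"lo"` to keep low ones.
#' @param p fraction of values to retain, in (0, 1].
#' @return logical vector, `TRUE` for retained entries.
#' @export
apply_gate <- function(values, direction = c("hi", "lo"), p) {
  direction <- match.arg(direction)
  stopifnot(is.numeric(values), length(values) > 0L)
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p <= 0 || p > 1) {
    stop("gate percentile must be a single value in (0, 1]")
  }
  if (p == 1) {
    return(rep(TRUE, length(values)))
  }
  if (direction == "hi") {
    values >= stats::quantile(values, 1 - p, names = FALSE)
  } else {
    values <= stats::quantile(values, p, names = FALSE)
  }
}

#' Log-normalize a count matrix (counts per 10k, log1p)
#'
#' Each cell (column) is scaled to `scale_factor` total counts, then
#' `log1p`-transformed. Cells with zero total counts are left at zero.
#'
#' @param counts genes x cells matrix (dense or `Matrix` sparse) of
#'   non-negative counts.
#' @param scale_factor library-size target per cell (default 1e4).
#' @return matrix of the same class and dimensions, log-normalized.
#' @export
normalize_counts <- function(counts, scale_factor = 1e4) {
  totals <- Matrix::colSums(counts)
  totals[totals == 0] <- 1
  if (inherits(counts, "sparseMatrix")) {
    out <- counts %*% Matrix::Diagonal(x = scale_factor / totals)
    out@x <- log1p(out@x)
    dimnames(out) <- dimnames(counts)
    out
  } else {
    log1p(sweep(counts, 2, totals, "/") * scale_factor)
  }
}

# Reserved (non-marker) column names of an index-sort table.
.reserved_cols <- c("plate_id", "well_id", "colony_count", "outcome")

# Marker columns of an index-sort data.frame.
marker_names <- function(dataset) {
  setdiff(names(dataset), .reserved_cols)
}

# Outcome as logical (TRUE = positive); errors if outcomes unset.
positive_outcomes <- function(dataset) {
  if (is.null(dataset$outcome) || anyNA(dataset$outcome)) {
    stop("well outcomes are not set; run score_wells() first")
  }
  dataset$outcome == "positive"
}

`%||%` <- function(a, b) if (is.null(a)) b else a
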