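#' Per-cell quality-control metrics
#'
#' Computes, for every cell (column), the number of detected genes, the
#' total UMI count, and the percentage of counts on mitochondrial and
#' ribosomal-protein genes. Gene sets default to the usual naming
#' conventions (`MT-` prefix; `RPS`/`RPL` prefixes) and can be overridden
#' with explicit gene lists. All-zero cells have their percentages defined
#' as 0.
#'
#' @param counts genes x cells count matrix (dense or sparse) with gene
#'   row names.
#' @param mt_genes character vector of mitochondrial gene names; default:
#'   rows whose name starts with `"MT-"`.
#' @param rp_genes character vector of ribosomal-protein gene names;
#'   default: rows starting with `"RPS"` or `"RPL"`.
#' @param total_reads optional per-cell read counts (Smart-Seq style); adds
#'   a `total_reads` column used by the `"smartseq"` filter mode.
#' @return data.frame with one row per cell: `cell_id`, `n_features`,
#'   `n_umis`, `mt_pct`, `rp_pct` and optionally `total_reads`.
#' @export
compute_qc_metrics <- function(counts, mt_genes = NULL, rp_genes = NULL,
                               total_reads = NULL) {
  if (is.null(dim(counts)) || nrow(counts) == 0L || ncol(counts) == 0L) {
    stop("empty expression matrix")
  }
  genes <- rownames(counts)
  if (is.null(genes)) stop("count matrix must have gene row names")
  mt_genes <- mt_genes %||% grep("^MT-", genes, value = TRUE)
  rp_genes <- rp_genes %||% grep("^RP[SL]", genes, value = TRUE)
  if (length(setdiff(mt_genes, genes)) || length(setdiff(rp_genes, genes))) {
    stop("MT/RP gene sets must be subsets of the matrix genes")
  }
  n_umis <- Matrix::colSums(counts)
  n_features <- Matrix::colSums(counts > 0)
  safe_pct <- function(part) ifelse(n_umis == 0, 0, 100 * part / n_umis)
  mt <- if (length(mt_genes)) {
    Matrix::colSums(counts[genes %in% mt_genes, , drop = FALSE])
  } else 0
  rp <- if (length(rp_genes)) {
    Matrix::colSums(counts[genes %in% rp_genes, , drop = FALSE])
  } else 0
  out <- data.frame(
    cell_id = colnames(counts) %||% sprintf("cell%04d", seq_len(ncol(counts))),
    n_features = as.integer(n_features),
    n_umis = as.numeric(n_umis),
    mt_pct = as.numeric(safe_pct(mt)),
    rp_pct = as.numeric(safe_pct(rp)),
    stringsAsFactors = FALSE
  )
  if (!is.null(total_reads)) {
    stopifnot(length(total_reads) == ncol(counts))
    out$total_reads <- as.numeric(total_reads)
  }
  rownames(out) <- NULL
  out
}

#' Cell-filtering policy for one experiment mode
#'
#' The four modes encode the filtering rules of the three sequencing
#' experiments the pipeline supports, with the inequality senses pinned to
#' the wording of each rule:
#' \describe{
#'   \item{`timecourse`}{discard cells with <1000 detected genes, >60,000
#'     UMIs or >10% mitochondrial counts (keep `>= 1000`, `<= 60000`,
#'     `<= 10`).}
#'   \item{`invivo`}{retain cells with >1000 features, <10% MT and >20% RP
#'     (all strict).}
#'   \item{`sorted_mkp`}{discard cells with <1000 features or >10% MT
#'     (keep `>= 1000`, `<= 10`); no UMI cap.}
#'   \item{`smartseq`}{exclude cells with fewer than 200,000 reads (keep
#'     `>= 200000`).}
#' }
#' Pass `NA` to disable a threshold.
#'
#' @param mode one of `"timecourse"`, `"invivo"`, `"sorted_mkp"`,
#'   `"smartseq"`, or `"custom"` (all thresholds off unless supplied).
#' @param min_features,max_umis,max_mt_pct,min_rp_pct,min_reads threshold
#'   overrides; defaults follow the mode.
#' @param min_cells_per_gene gene-level floor used by [filter_genes()]
#'   (default 3).
#' @return a `filter_policy` list.
#' @export
qc_policy <- function(mode = c("timecourse", "invivo", "sorted_mkp",
                               "smartseq", "custom"),
                      min_features = NULL, max_umis = NULL,
                      max_mt_pct = NULL, min_rp_pct = NULL,
                      min_reads = NULL, min_cells_per_gene = 3) {
  mode <- match.arg(mode)
  defaults <- switch(mode,
    timecourse = list(min_features = 1000, max_umis = 60000, max_mt_pct = 10,
                      min_rp_pct = NA, min_reads = NA,
                      strict = FALSE),
    invivo = list(min_features = 1000, max_umis = NA, max_mt_pct = 10,
                  min_rp_pct = 20, min_reads = NA,
                  strict = TRUE),
    sorted_mkp = list(min_features = 1000, max_umis = NA, max_mt_pct = 10,
                      min_rp_pct = NA, min_reads = NA,
                      strict = FALSE),
    smartseq = list(min_features = NA, max_umis = NA, max_mt_pct = NA,
                    min_rp_pct = NA, min_reads = 200000,
                    strict = FALSE),
    custom = list(min_features = NA, max_umis = NA, max_mt_pct = NA,
                  min_rp_pct = NA, min_reads = NA,
                  strict = FALSE)
  )
  pol <- list(
    mode = mode,
    min_features = min_features %||% defaults$min_features,
    max_umis = max_umis %||% defaults$max_umis,
    max_mt_pct = max_mt_pct %||% defaults$max_mt_pct,
    min_rp_pct = min_rp_pct %||% defaults$min_rp_pct,
    min_reads = min_reads %||% defaults$min_reads,
    strict = defaults$strict,
    min_cells_per_gene = min_cells_per_gene
  )
  thresholds <- unlist(pol[c("min_features", "max_umis", "max_mt_pct",
                             "min_rp_pct", "min_reads")])
  if (any(!is.na(thresholds) & thresholds < 0)) {
    stop("thresholds must be nonnegative")
  }
  structure(pol, class = "filter_policy")
}

#' Filter cells by a QC policy
#'
#' A cell is retained iff it violates no active threshold of the policy's
#' mode. The `invivo` mode uses strict inequalities (cells are *retained*
#' when strictly inside each bound); the discard-style modes keep cells at
#' the boundary (see [qc_policy()]).
#'
#' @param metrics data.frame from [compute_qc_metrics()].
#' @param policy a [qc_policy()].
#' @return character vector of retained `cell_id`s.
#' @export
filter_cells <- function(metrics, policy) {
  stopifnot(inherits(policy, "filter_policy"), is.data.frame(metrics))
  if (!all(c("cell_id", "n_features", "n_umis", "mt_pct") %in% names(metrics))) {
    stop("metrics must come from compute_qc_metrics()")
  }
  keep <- rep(TRUE, nrow(metrics))
  cmp_ge <- function(x, thr) if (policy$strict) x > thr else x >= thr
  cmp_le <- function(x, thr) if (policy$strict) x < thr else x <= thr
  if (!is.na(policy$min_features)) {
    keep <- keep & cmp_ge(metrics$n_features, policy$min_features)
  }
  if (!is.na(policy$max_umis)) {
    keep <- keep & cmp_le(metrics$n_umis, policy$max_umis)
  }
  if (!is.na(policy$max_mt_pct)) {
    keep <- keep & cmp_le(metrics$mt_pct, policy$max_mt_pct)
  }
  if (!is.na(policy$min_rp_pct)) {
    if (is.null(metrics$rp_pct)) stop("policy needs rp_pct but metrics lack it")
    keep <- keep & cmp_ge(metrics$rp_pct, policy$min_rp_pct)
  }
  if (!is.na(policy$min_reads)) {
    if (is.null(metrics$total_reads)) {
      stop("mode '", policy$mode, "' requires total_reads in the metrics")
    }
    keep <- keep & metrics$total_reads >= policy$min_reads
  }
  metrics$cell_id[keep]
}

#' Filter genes expressed in too few cells
#'
#' @param counts genes x cells count matrix with gene row names.
#' @param min_cells_per_gene a gene is retained iff it has a nonzero count
#'   in at least this many cells (default 3, i.e. genes seen in fewer than
#'   three cells are excluded).
#' @return character vector of retained gene names.
#' @export
filter_genes <- function(counts, min_cells_per_gene = 3) {
  if (is.null(dim(counts)) || is.null(rownames(counts))) {
    stop("counts must be a matrix with gene row names")
  }
  n_cells <- Matrix::rowSums(counts > 0)
  rownames(counts)[n_cells >= min_cells_per_gene]
}
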