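#' Cluster marker genes by ROC discriminative power
#'
#' For each cluster, genes are first filtered by absolute natural-log fold
#' change (`|ln(FC)| > ln_fc_min`), then ranked by one-vs-rest
#' discriminative power (`2 |AUC - 0.5|`, ties broken by `|ln_fc|` then
#' gene name) and truncated to the `top_n` best. The defaults match
#' droplet time-course analysis (top 25); plate-based (Smart-Seq style)
#' experiments conventionally use `top_n = 20` restricted to positive
#' markers.
#'
#' @param counts genes x cells raw count matrix.
#' @param cluster_labels per-cell cluster assignments.
#' @param ln_fc_min absolute ln fold-change floor (default 1.0).
#' @param top_n markers kept per cluster (default 25).
#' @param positive_only keep only positive markers (`ln_fc > 0`), as in the
#'   plate-based variant (default FALSE).
#' @return data.frame: `cluster`, `gene`, `power`, `ln_fc`, `rank` (within
#'   cluster). Clusters with fewer than 2 cells are skipped with a warning.
#' @export
cluster_markers <- function(counts, cluster_labels, ln_fc_min = 1.0,
                            top_n = 25, positive_only = FALSE) {
  cluster_labels <- factor(cluster_labels)
  if (nlevels(cluster_labels) < 2) stop("need at least two clusters")
  stopifnot(ncol(counts) == length(cluster_labels))
  norm <- normalize_counts(counts)
  out <- list()
  for (cl in levels(cluster_labels)) {
    in_mask <- cluster_labels == cl
    if (sum(in_mask) < 2 || sum(!in_mask) < 2) {
      warning("cluster '", cl, "' has fewer than 2 cells on one side of ",
              "the one-vs-rest split; skipped")
      next
    }
    st <- .roc_stats(norm, in_mask)
    st <- st[abs(st$ln_fc) > ln_fc_min, , drop = FALSE]
    if (positive_only) st <- st[st$ln_fc > 0, , drop = FALSE]
    if (!nrow(st)) next
    st <- st[order(-st$power, -abs(st$ln_fc), st$gene), , drop = FALSE]
    st <- utils::head(st, top_n)
    out[[cl]] <- data.frame(cluster = cl, gene = st$gene, power = st$power,
                            ln_fc = st$ln_fc, rank = seq_len(nrow(st)),
                            stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(cluster = character(0), gene = character(0),
                      power = numeric(0), ln_fc = numeric(0),
                      rank = integer(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Restrict candidate markers to plasma-membrane gene products
#'
#' Intersects a marker list with a supplied membrane-associated gene set
#' (for example genes carrying plasma-membrane GO annotations), preserving
#' the input order. The set is a plain gene-name list; no live ontology
#' lookup is performed.
#'
#' @param markers character vector of candidate genes, ranked.
#' @param membrane_gene_set nonempty character vector of membrane genes.
#' @return the ordered intersection.
#' @export
surface_filter <- function(markers, membrane_gene_set) {
  if (!length(membrane_gene_set)) {
    stop("membrane gene set is empty; refusing to silently return nothing")
  }
  markers[markers %in% membrane_gene_set]
}

#' Rank genes by temporal variation along a pseudotime
#'
#' Fits, per gene, the ordinary least squares model
#' `expression ~ 1 + t + t^2` on the log-normalized expression and the
#' pseudotime `t`, computes two-sided t-test p-values for the linear and
#' quadratic coefficients, and scores each gene by the smaller of the two.
#' Genes are ranked by ascending score; the top `top_n` are returned with
#' both p-values. The score is invariant to rescaling (including sign
#' flips) of the pseudotime, but not to shifts, which reparameterize the
#' linear term.
#'
#' @param counts genes x cells raw count matrix (log-normalized
#'   internally).
#' @param pseudotime finite numeric pseudotime per cell (>= 4 cells, not
#'   constant).
#' @param top_n genes returned (default 100).
#' @return data.frame ordered by `p_min`: `gene`, `p_linear`,
#'   `p_quadratic`, `p_min`.
#' @export
temporally_varying_genes <- function(counts, pseudotime, top_n = 100) {
  stopifnot(ncol(counts) == length(pseudotime))
  if (any(!is.finite(pseudotime))) stop("pseudotime must be finite")
  n <- length(pseudotime)
  if (n < 4) stop("need at least 4 cells for a quadratic fit")
  if (stats::var(pseudotime) == 0) {
    stop("constant pseudotime: design matrix is singular")
  }
  y <- t(as.matrix(normalize_counts(counts)))  # cells x genes
  X <- cbind(1, pseudotime, pseudotime^2)
  XtX_inv <- tryCatch(solve(crossprod(X)), error = function(e) {
    stop("singular design matrix (degenerate pseudotime values)")
  })
  beta <- XtX_inv %*% crossprod(X, y)                  # 3 x genes
  resid <- y - X %*% beta
  df <- n - 3L
  sigma2 <- colSums(resid^2) / df
  se <- sqrt(outer(diag(XtX_inv), sigma2))             # 3 x genes
  tstat <- beta / se
  pv <- 2 * stats::pt(-abs(tstat), df)
  pv[is.nan(pv)] <- 1
  # constant genes carry no temporal signal; their numerically-degenerate
  # fits (0/0 t ratios) are pinned to p = 1 so they rank last
  constant <- apply(y, 2, stats::var) == 0
  pv[, constant] <- 1
  out <- data.frame(gene = colnames(y),
                    p_linear = pv[2, ], p_quadratic = pv[3, ],
                    p_min = pmin(pv[2, ], pv[3, ]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_min, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, top_n)
}
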