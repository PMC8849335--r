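# Per-gene one-vs-rest discrimination statistics on a log-normalized
# matrix: rank-based AUC, power = 2|AUC - 0.5|, and natural-log fold change
# of the expm1'd mean normalized expression with pseudocount 1.
.roc_stats <- function(norm, in_mask) {
  norm <- as.matrix(norm)
  n1 <- sum(in_mask); n2 <- sum(!in_mask)
  stopifnot(n1 >= 2, n2 >= 2)
  auc <- apply(norm, 1, function(x) {
    r <- rank(x)
    (sum(r[in_mask]) - n1 * (n1 + 1) / 2) / (n1 * n2)
  })
  m_in <- rowMeans(expm1(norm[, in_mask, drop = FALSE]))
  m_out <- rowMeans(expm1(norm[, !in_mask, drop = FALSE]))
  ln_fc <- log((m_in + 1) / (m_out + 1))
  data.frame(gene = rownames(norm), auc = unname(auc),
             power = unname(2 * abs(auc - 0.5)), ln_fc = unname(ln_fc),
             stringsAsFactors = FALSE)
}

#' ROC discrimination power of every gene for one cell type
#'
#' For each gene, computes the one-vs-rest AUC by rank statistics (the
#' probability that a random cell of the target type exceeds a random
#' other cell, ties counted half), the discriminative power
#' `2 |AUC - 0.5|`, and the natural-log fold change of mean expression
#' (pseudocount 1 on the expm1'd log-normalized means). A gene is a
#' *positive marker* of the type when its fold change is at least `min_fc`
#' and its AUC exceeds 0.5.
#'
#' @param counts genes x cells raw count matrix (log-normalized internally
#'   with [normalize_counts()]).
#' @param labels per-cell type labels.
#' @param target_type the type tested one-vs-rest; needs >= 2 cells on each
#'   side.
#' @param min_fc positive-marker fold-change floor (default 2).
#' @return data.frame: `gene`, `auc`, `power`, `ln_fc`, `positive_marker`.
#' @export
roc_marker_power <- function(counts, labels, target_type, min_fc = 2.0) {
  stopifnot(ncol(counts) == length(labels))
  in_mask <- labels == target_type
  if (sum(in_mask) < 2 || sum(!in_mask) < 2) {
    stop("need >= 2 cells in the target type and in the complement")
  }
  out <- .roc_stats(normalize_counts(counts), in_mask)
  out$positive_marker <- out$ln_fc >= log(min_fc) & out$auc > 0.5
  out
}

#' Union of positive marker genes across cell types
#'
#' Runs [roc_marker_power()] one-vs-rest for every type and takes the union
#' of positive markers (fold change >= `min_fc`, AUC > 0.5), deduplicated
#' and ordered by descending maximum power (ties by gene name).
#'
#' @inheritParams roc_marker_power
#' @return character vector of discriminative genes.
#' @export
select_discriminative_genes <- function(counts, labels, min_fc = 2.0) {
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("need at least two cell types")
  norm <- normalize_counts(counts)
  hits <- list()
  for (tp in levels(labels)) {
    st <- .roc_stats(norm, labels == tp)
    sel <- st[st$ln_fc >= log(min_fc) & st$auc > 0.5, c("gene", "power")]
    if (nrow(sel)) hits[[tp]] <- sel
  }
  if (!length(hits)) {
    stop("no gene passes the positive-marker criteria (fold change >= ",
         min_fc, ", AUC > 0.5) for any type; lower min_fc or check ",
         "normalization and labels")
  }
  all <- do.call(rbind, hits)
  best <- tapply(all$power, all$gene, max)
  genes <- names(best)
  genes[order(-as.numeric(best), genes)]
}

# Normalize query counts and align rows to the model's marker genes,
# imputing absent genes as zero (with a message).
.align_features <- function(model, counts) {
  norm <- as.matrix(normalize_counts(counts))
  missing <- setdiff(model$marker_genes, rownames(norm))
  if (length(missing)) {
    message(length(missing), " model gene(s) absent from query; imputed as 0")
    zero <- matrix(0, nrow = length(missing), ncol = ncol(norm),
                   dimnames = list(missing, colnames(norm)))
    norm <- rbind(norm, zero)
  }
  t(norm[model$marker_genes, , drop = FALSE])
}

# Per-cell class probabilities (fraction of trees voting for each class).
.model_probs <- function(model, counts) {
  x <- .align_features(model, counts)
  if (model$n_classes == 1L) {
    p <- matrix(1, nrow = nrow(x), ncol = 1,
                dimnames = list(rownames(x), model$class_labels))
    return(p)
  }
  p <- stats::predict(model$classifier, newdata = x, type = "prob")
  matrix(as.numeric(p), nrow = nrow(p), dimnames = dimnames(p))
}

#' Train a reference cell-type classifier on marker genes
#'
#' Fits a random forest (bootstrap-aggregated decision trees with random
#' feature subsetting, `mtry = ceiling(sqrt(#genes))`) on the
#' log-normalized expression of the supplied marker genes. Class
#' probabilities are the fraction of trees voting for each class. The
#' training-error-versus-trees curve (cumulative majority vote over tree
#' prefixes 1..`n_trees`) is stored for convergence inspection. The
#' assignment threshold is left unset until [calibrate_threshold()].
#'
#' @param counts genes x cells raw reference counts.
#' @param labels per-cell type annotations.
#' @param genes marker genes to train on (subset of the matrix genes),
#'   typically from [select_discriminative_genes()].
#' @param n_trees trees in the forest (default 100).
#' @param seed optional integer seed.
#' @return a `celltype_model`: `marker_genes`, `classifier`,
#'   `class_labels`, `threshold` (NA), `n_trees`, `train_error_curve`.
#' @export
train_celltype_model <- function(counts, labels, genes, n_trees = 100,
                                 seed = NULL) {
  labels <- factor(labels)
  labels <- droplevels(labels)
  stopifnot(ncol(counts) == length(labels), length(genes) >= 1)
  missing <- setdiff(genes, rownames(counts))
  if (length(missing)) {
    stop("genes absent from the matrix: ", paste(missing, collapse = ", "))
  }
  small <- names(which(table(labels) < 2))
  if (length(small)) {
    stop("class(es) with fewer than 2 cells: ", paste(small, collapse = ", "))
  }
  model <- structure(list(
    marker_genes = genes, classifier = NULL,
    class_labels = levels(labels), n_classes = nlevels(labels),
    threshold = NA_real_, n_trees = as.integer(n_trees),
    train_error_curve = NULL
  ), class = "celltype_model")
  x <- .align_features(model, counts)
  if (nlevels(labels) == 1L) {
    model$train_error_curve <- rep(0, n_trees)
    return(model)
  }
  if (!is.null(seed)) set.seed(seed)
  rf <- randomForest::randomForest(
    x = x, y = labels, ntree = n_trees,
    mtry = ceiling(sqrt(length(genes)))
  )
  model$classifier <- rf
  ind <- stats::predict(rf, newdata = x, predict.all = TRUE)$individual
  votes <- array(0L, dim = c(nrow(x), n_trees, nlevels(labels)))
  for (ci in seq_len(nlevels(labels))) {
    votes[, , ci] <- t(apply(ind == levels(labels)[ci], 1, cumsum))
  }
  err <- vapply(seq_len(n_trees), function(t) {
    pred <- levels(labels)[apply(votes[, t, , drop = FALSE], 1, which.max)]
    mean(pred != as.character(labels))
  }, numeric(1))
  model$train_error_curve <- err
  model
}

#' @export
print.celltype_model <- function(x, ...) {
  cat("Cell-type projection model:", x$n_classes, "classes,",
      length(x$marker_genes), "marker genes,", x$n_trees, "trees\n")
  cat("Classes:", paste(x$class_labels, collapse = ", "), "\n")
  cat("Assignment threshold:",
      if (is.na(x$threshold)) "unset (run calibrate_threshold)" else
        sprintf("%.2f", x$threshold), "\n")
  invisible(x)
}

#' @export
summary.celltype_model <- function(object, ...) {
  print(object)
  if (!is.null(object$train_error_curve)) {
    cat(sprintf("Final training error: %.4f (converged curve over %d trees)\n",
                utils::tail(object$train_error_curve, 1), object$n_trees))
  }
  invisible(object)
}

#' Stratified k-fold cross-validation of the projection model
#'
#' @inheritParams train_celltype_model
#' @param k number of folds (default 10).
#' @return list with `accuracies` (length `k`) and `summary`
#'   (min, median, max, sd).
#' @export
cross_validate <- function(counts, labels, genes, k = 10, n_trees = 100,
                           seed = NULL) {
  if (k < 2) stop("k must be at least 2")
  labels <- factor(labels)
  n <- length(labels)
  stopifnot(ncol(counts) == n)
  if (!is.null(seed)) set.seed(seed)
  folds <- integer(n)
  for (tp in levels(labels)) {
    idx <- which(labels == tp)
    if (length(idx) < k) {
      warning("class '", tp, "' has fewer cells (", length(idx),
              ") than folds; fold ids sampled with replacement")
      folds[idx] <- sample.int(k, length(idx), replace = TRUE)
    } else {
      folds[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
    }
  }
  acc <- vapply(seq_len(k), function(f) {
    test <- folds == f
    if (!any(test) || !any(!test)) return(NA_real_)
    model <- train_celltype_model(counts[, !test, drop = FALSE],
                                  droplevels(labels[!test]), genes,
                                  n_trees = n_trees)
    probs <- .model_probs(model, counts[, test, drop = FALSE])
    pred <- model$class_labels[apply(probs, 1, which.max)]
    mean(pred == as.character(labels[test]))
  }, numeric(1))
  list(accuracies = acc,
       summary = c(min = min(acc, na.rm = TRUE),
                   median = stats::median(acc, na.rm = TRUE),
                   max = max(acc, na.rm = TRUE),
                   sd = stats::sd(acc, na.rm = TRUE)))
}

#' Calibrate the assignment threshold on a negative-control population
#'
#' Scans the grid `{0, grid_step, ..., 1}` and returns the smallest
#' threshold at which fewer than `max_assign_frac` of the control cells
#' are assigned, where a cell is *assigned* when its maximum class
#' probability is at or above the threshold. The control population must
#' contain cells with no true reference type (for instance pluripotent
#' cells when the reference covers adult blood types), so the criterion
#' caps the rate of spurious assignments.
#'
#' @param model a trained `celltype_model`.
#' @param control_counts genes x cells counts of the control population
#'   (disjoint from training data).
#' @param max_assign_frac tolerated assigned fraction (default 0.01).
#' @param grid_step threshold grid resolution (default 0.01).
#' @return the threshold (numeric scalar); the achieved assigned fraction
#'   is attached as attribute `"assign_frac"`.
#' @export
calibrate_threshold <- function(model, control_counts,
                                max_assign_frac = 0.01, grid_step = 0.01) {
  stopifnot(inherits(model, "celltype_model"),
            max_assign_frac >= 0, grid_step > 0, grid_step <= 1)
  max_prob <- apply(.model_probs(model, control_counts), 1, max)
  .scan_threshold(max_prob, max_assign_frac, grid_step)
}

# Grid scan behind calibrate_threshold: smallest grid threshold whose
# assigned fraction (max_prob >= threshold, with a 1e-12 slack so vote
# fractions k/ntree landing exactly on a grid point count as assigned)
# falls below max_assign_frac.
.scan_threshold <- function(max_prob, max_assign_frac = 0.01,
                            grid_step = 0.01) {
  grid <- seq(0, 1, by = grid_step)
  if (utils::tail(grid, 1) < 1) grid <- c(grid, 1)
  frac <- vapply(grid, function(t) mean(max_prob >= t - 1e-12), numeric(1))
  ok <- which(frac < max_assign_frac)
  if (!length(ok)) {
    stop("no grid threshold keeps the assigned fraction below ",
         max_assign_frac)
  }
  structure(grid[ok[1L]], assign_frac = frac[ok[1L]])
}

#' Predict cell types for a query, with rejection below the threshold
#'
#' Each query cell receives the class with the largest vote fraction when
#' that fraction is at or above the model's assignment threshold, and
#' `"UNASSIGNED"` otherwise.
#'
#' @param model a `celltype_model` with a set (calibrated) threshold.
#' @param query_counts genes x cells query counts; model genes absent from
#'   the query are imputed as zero (with a message).
#' @param threshold optional override of `model$threshold`.
#' @return data.frame: `cell_id`, `label`, `max_prob`, `assigned`.
#' @export
predict_types <- function(model, query_counts, threshold = NULL) {
  threshold <- threshold %||% model$threshold
  if (is.na(threshold)) {
    stop("model threshold unset; run calibrate_threshold() or pass one")
  }
  probs <- .model_probs(model, query_counts)
  max_prob <- apply(probs, 1, max)
  label <- model$class_labels[apply(probs, 1, which.max)]
  assigned <- max_prob >= threshold - 1e-12
  label[!assigned] <- "UNASSIGNED"
  data.frame(cell_id = rownames(probs) %||% seq_along(max_prob),
             label = label, max_prob = as.numeric(max_prob),
             assigned = assigned, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' @export
#' @rdname predict_types
#' @param object,newdata,type,... S3 method interface: `type = "types"`
#'   gives the [predict_types()] table, `type = "prob"` the per-class vote
#'   fractions.
predict.celltype_model <- function(object, newdata,
                                   type = c("types", "prob"),
                                   threshold = NULL, ...) {
  type <- match.arg(type)
  if (type == "prob") return(.model_probs(object, newdata))
  predict_types(object, newdata, threshold = threshold)
}
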