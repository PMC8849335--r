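#' Fit a bagged decision-tree classifier on index-sort features
#'
#' Bootstrap-aggregated CART trees with every feature eligible at every
#' split (bagging rather than a feature-subsetted forest), Gini impurity,
#' grown to purity (terminal node size 1). Built on the randomForest
#' engine with `mtry` set to the full feature count, which reduces the
#' forest to plain bagging.
#'
#' @param features numeric matrix/data.frame of observations x markers
#'   (typically rank-normalized, SMOTE-augmented intensities).
#' @param outcomes two-class outcome vector.
#' @param n_trees number of trees (default 1000).
#' @param seed optional integer seed for the bootstrap.
#' @return a `bag_ensemble` object (fields: `forest`, `markers`, `n_trees`).
#' @export
fit_bagging <- function(features, outcomes, n_trees = 1000, seed = NULL) {
  features <- as.data.frame(features)
  y <- factor(outcomes)
  if (nlevels(y) < 2L) stop("outcomes contain a single class; nothing to fit")
  stopifnot(nrow(features) == length(y), n_trees >= 1)
  if (!is.null(seed)) set.seed(seed)
  rf <- randomForest::randomForest(
    x = features, y = y, ntree = n_trees,
    mtry = ncol(features), nodesize = 1, replace = TRUE
  )
  structure(list(forest = rf, markers = colnames(features),
                 n_trees = as.integer(n_trees)),
            class = "bag_ensemble")
}

#' @export
print.bag_ensemble <- function(x, ...) {
  cat("Bagged decision-tree ensemble:", x$n_trees, "trees on",
      length(x$markers), "markers\n")
  cat("Markers:", paste(x$markers, collapse = ", "), "\n")
  invisible(x)
}

#' @export
predict.bag_ensemble <- function(object, newdata, type = c("response", "prob"),
                                 ...) {
  type <- match.arg(type)
  stats::predict(object$forest, newdata = as.data.frame(newdata),
                 type = type, ...)
}

# Normalize one tree to a plain data.frame with columns left, right, var
# (var = marker name, NA at leaves). Accepts randomForest::getTree output
# (split var as column index) or hand-built tables with those columns.
.as_tree_table <- function(tree, markers) {
  tree <- as.data.frame(tree)
  if (all(c("left daughter", "right daughter", "split var") %in% names(tree))) {
    var_idx <- tree[["split var"]]
    var <- ifelse(var_idx == 0, NA_character_, markers[var_idx])
    return(data.frame(left = tree[["left daughter"]],
                      right = tree[["right daughter"]],
                      var = var, stringsAsFactors = FALSE))
  }
  if (!all(c("left", "right", "var") %in% names(tree))) {
    stop("tree table must have columns left/right/var")
  }
  tree$var <- as.character(tree$var)
  tree$var[!is.na(tree$var) & tree$var == ""] <- NA_character_
  tree[c("left", "right", "var")]
}

# Preorder depth-first traversal (node, then condition-true/left child,
# then right child); returns the distinct split variables in first-use order.
.dfs_first_use <- function(tree) {
  order <- character(0)
  stack <- 1L
  while (length(stack)) {
    node <- stack[1L]
    stack <- stack[-1L]
    v <- tree$var[node]
    if (is.na(v)) next  # leaf
    if (!(v %in% order)) order <- c(order, v)
    stack <- c(tree$left[node], tree$right[node], stack)
  }
  order
}

#' First-occurrence ranks of markers in an ensemble's trees
#'
#' Traverses each tree depth first in preorder (a node before its children,
#' the condition-true / left child before the right child). The i-th
#' distinct marker encountered in a tree receives rank i in that tree;
#' markers a tree never splits on contribute no rank but lower that
#' marker's usage fraction. Low median rank across trees marks a feature
#' the ensemble consistently uses early, i.e. a discriminative marker.
#'
#' @param x a [fit_bagging()] ensemble, or a list of tree tables (each a
#'   data.frame/matrix with columns `left`, `right`, `var`, 0 meaning "no
#'   child" and `NA` var meaning leaf; `randomForest::getTree()` output is
#'   also accepted).
#' @param markers marker names; taken from the ensemble when omitted.
#' @return a `rank_profile` object: `ranks` (named list of per-tree rank
#'   vectors), `n_trees`, and `summary` (data.frame with `marker`,
#'   `median_rank`, `mean_rank`, `usage_fraction`).
#' @export
first_occurrence_ranks <- function(x, markers = NULL) {
  if (inherits(x, "bag_ensemble")) {
    markers <- markers %||% x$markers
    trees <- lapply(seq_len(x$n_trees), function(k) {
      .as_tree_table(randomForest::getTree(x$forest, k, labelVar = FALSE),
                     markers)
    })
  } else if (is.list(x)) {
    trees <- lapply(x, .as_tree_table, markers = markers)
    if (is.null(markers)) {
      markers <- sort(unique(unlist(lapply(trees, function(t)
        t$var[!is.na(t$var)]))))
    }
  } else {
    stop("x must be a bag_ensemble or a list of tree tables")
  }
  ranks <- stats::setNames(
    lapply(markers, function(m) integer(0)), markers)
  for (tr in trees) {
    used <- .dfs_first_use(tr)
    for (i in seq_along(used)) {
      ranks[[used[i]]] <- c(ranks[[used[i]]], i)
    }
  }
  n_trees <- length(trees)
  summary <- data.frame(
    marker = markers,
    median_rank = vapply(ranks, function(r)
      if (length(r)) stats::median(r) else NA_real_, numeric(1)),
    mean_rank = vapply(ranks, function(r)
      if (length(r)) mean(r) else NA_real_, numeric(1)),
    usage_fraction = vapply(ranks, length, numeric(1)) / n_trees,
    stringsAsFactors = FALSE
  )
  rownames(summary) <- NULL
  structure(list(ranks = ranks, n_trees = n_trees, summary = summary),
            class = "rank_profile")
}

#' @export
print.rank_profile <- function(x, ...) {
  cat("First-occurrence rank profile over", x$n_trees, "trees\n")
  print(x$summary, ...)
  invisible(x)
}

#' Aggregate rank profiles across replicates into a marker ordering
#'
#' When Wilcoxon p-values are supplied, markers are ordered by ascending
#' p-value — the rank-sum statistic pools every well of every replicate
#' and is the stable choice of gating anchor when outcome-label noise
#' makes the per-replicate root-split winner a coin flip — with the
#' replicate-level profile statistics (median-rank-1 wins descending,
#' mean of per-replicate median ranks ascending, marker name) breaking
#' ties and providing the ordering when no p-values are given. In
#' low-noise data the two keys agree. Replicates where a marker never
#' appears contribute no median to the mean-median statistic.
#'
#' @param profiles list of `rank_profile` objects, one per replicate.
#' @param p_values optional data.frame from [wilcoxon_marker_test()] (or a
#'   named numeric vector) used as tie-break key.
#' @return a `rank_summary` data.frame: `marker`, `n_median_rank1`,
#'   `mean_median_rank`, `mean_usage`, `p_value`, ordered best first.
#' @export
rank_summary <- function(profiles, p_values = NULL) {
  if (inherits(profiles, "rank_profile")) profiles <- list(profiles)
  stopifnot(length(profiles) >= 1,
            all(vapply(profiles, inherits, logical(1), "rank_profile")))
  markers <- profiles[[1L]]$summary$marker
  med <- sapply(profiles, function(p) {
    p$summary$median_rank[match(markers, p$summary$marker)]
  })
  med <- matrix(med, nrow = length(markers))
  use <- sapply(profiles, function(p) {
    p$summary$usage_fraction[match(markers, p$summary$marker)]
  })
  use <- matrix(use, nrow = length(markers))
  if (is.data.frame(p_values)) {
    p_values <- stats::setNames(p_values$p_value, p_values$marker)
  }
  out <- data.frame(
    marker = markers,
    n_median_rank1 = apply(med, 1, function(r) sum(r == 1, na.rm = TRUE)),
    mean_median_rank = apply(med, 1, function(r)
      if (all(is.na(r))) NA_real_ else mean(r, na.rm = TRUE)),
    mean_usage = rowMeans(use),
    p_value = if (is.null(p_values)) NA_real_ else
      as.numeric(p_values[markers]),
    stringsAsFactors = FALSE
  )
  ord <- order(ifelse(is.na(out$p_value), Inf, out$p_value),
               -out$n_median_rank1,
               ifelse(is.na(out$mean_median_rank), Inf, out$mean_median_rank),
               out$marker)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("rank_summary", "data.frame")
  out
}
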