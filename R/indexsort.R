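#' Score index-sort wells by colony outcome
#'
#' A well is a positive observation when its colony grew to more than three
#' cells, and negative otherwise. Colonies of exactly three cells are not
#' covered by either rule and are scored negative (conservative reading).
#'
#' @param dataset index-sort data.frame with a `colony_count` column.
#' @return the dataset with an `outcome` factor column
#'   (`"positive"`/`"negative"`).
#' @export
score_wells <- function(dataset) {
  stopifnot(is.data.frame(dataset))
  if (is.null(dataset$colony_count)) stop("dataset lacks a colony_count column")
  missing <- which(is.na(dataset$colony_count))
  if (length(missing)) {
    stop("colony_count missing for well(s): ",
         paste(dataset$well_id[missing] %||% missing, collapse = ", "))
  }
  dataset$outcome <- factor(ifelse(dataset$colony_count > 3,
                                   "positive", "negative"),
                            levels = c("negative", "positive"))
  dataset
}

#' Exclude replicates with too few colonies
#'
#' Replicates (plates) whose positive-well count falls below the floor are
#' dropped before augmentation and ensemble training; sparse replicates
#' carry too little signal for the minority class.
#'
#' @param dataset scored index-sort data.frame (or list of per-replicate
#'   data.frames, which is row-bound first).
#' @param min_colonies minimum positive wells a replicate must contain
#'   (default 5; replicates with 4 or fewer colonies are excluded).
#' @return filtered dataset; the per-replicate decision log is attached as
#'   attribute `"exclusion_log"`.
#' @export
exclude_replicates <- function(dataset, min_colonies = 5) {
  if (is.list(dataset) && !is.data.frame(dataset)) {
    dataset <- do.call(rbind, dataset)
  }
  pos <- positive_outcomes(dataset)
  counts <- tapply(pos, dataset$plate_id, sum)
  log <- data.frame(plate_id = names(counts),
                    n_positive = as.integer(counts),
                    retained = as.integer(counts) >= min_colonies,
                    stringsAsFactors = FALSE)
  out <- dataset[dataset$plate_id %in% log$plate_id[log$retained], ,
                 drop = FALSE]
  rownames(out) <- NULL
  attr(out, "exclusion_log") <- log
  out
}

#' Exclude outlier wells by robust log-intensity deviation
#'
#' Within each replicate, a well is excluded when any marker's log intensity
#' deviates from the plate median by more than `k_mad` robust standard
#' deviations (MAD x 1.4826). Markers with zero MAD on a plate are skipped
#' for outlier testing (with a warning).
#'
#' @param dataset index-sort data.frame.
#' @param k_mad deviation threshold in robust SD units (default 5).
#' @return filtered dataset; excluded wells logged in attribute
#'   `"exclusion_log"`.
#' @export
exclude_outliers <- function(dataset, k_mad = 5) {
  stopifnot(is.data.frame(dataset), k_mad > 0)
  markers <- marker_names(dataset)
  drop <- rep(FALSE, nrow(dataset))
  reason <- character(nrow(dataset))
  for (pid in unique(dataset$plate_id)) {
    idx <- which(dataset$plate_id == pid)
    for (m in markers) {
      x <- log(dataset[[m]][idx])
      med <- stats::median(x)
      s <- stats::mad(x)  # constant 1.4826 by default
      if (s == 0) {
        warning("marker ", m, " has zero MAD on ", pid,
                "; skipped for outlier testing")
        next
      }
      out <- abs(x - med) > k_mad * s
      newly <- idx[out & !drop[idx]]
      drop[idx[out]] <- TRUE
      reason[newly] <- m
    }
  }
  log <- data.frame(well_id = dataset$well_id[drop],
                    plate_id = dataset$plate_id[drop],
                    marker = reason[drop], stringsAsFactors = FALSE)
  out <- dataset[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "exclusion_log") <- log
  out
}

#' Rank-normalize marker intensities within replicates and combine
#'
#' Each replicate's intensities are mapped, marker by marker, to fractional
#' ranks in (0, 1] (average ranks for ties, divided by the replicate's well
#' count). Rank normalization is invariant to any monotone transform of a
#' replicate's intensities, which removes plate-level gain and shift
#' differences while preserving the within-plate ordering that percentile
#' gates act on.
#'
#' @param dataset index-sort data.frame (or list of per-replicate
#'   data.frames); replicates are identified by `plate_id`.
#' @return combined data.frame with the same columns, marker intensities
#'   replaced by fractional ranks.
#' @export
normalize_replicates <- function(dataset) {
  if (is.list(dataset) && !is.data.frame(dataset)) {
    shared <- lapply(dataset, marker_names)
    if (length(unique(lapply(shared, sort))) > 1L) {
      stop("replicates do not share a common marker set")
    }
    dataset <- do.call(rbind, dataset)
  }
  markers <- marker_names(dataset)
  if (!length(markers)) stop("dataset has no marker columns")
  for (pid in unique(dataset$plate_id)) {
    idx <- which(dataset$plate_id == pid)
    for (m in markers) {
      x <- dataset[[m]][idx]
      if (anyNA(x)) stop("marker ", m, " has missing values in ", pid)
      dataset[[m]][idx] <- rank(x, ties.method = "average") / length(idx)
    }
  }
  rownames(dataset) <- NULL
  dataset
}

#' SMOTE class augmentation
#'
#' Balances a two-class dataset by interpolating synthetic minority
#' observations: a random minority point `x` and one of its `k` nearest
#' minority neighbours `x'` (Euclidean distance) yield `x + u (x' - x)`
#' with `u ~ Uniform(0, 1)`. Originals are preserved verbatim and the
#' majority class is never downsampled.
#'
#' @param features numeric matrix or data.frame of observations x features.
#' @param outcomes two-class factor/character/logical vector.
#' @param target_ratio desired minority / majority count ratio (default 1,
#'   i.e. a 1:1 class balance).
#' @param k_neighbors nearest-neighbour pool size (default 5; clipped to
#'   minority size - 1).
#' @param seed optional integer seed.
#' @return list with `features` (original rows first, then synthetic) and
#'   `outcomes`; synthetic rows are flagged in attribute `"synthetic"`.
#' @export
smote_augment <- function(features, outcomes, target_ratio = 1.0,
                          k_neighbors = 5, seed = NULL) {
  features <- as.matrix(features)
  stopifnot(is.numeric(features), nrow(features) == length(outcomes),
            target_ratio > 0, k_neighbors >= 1)
  cls <- table(outcomes)
  if (length(cls) != 2L) stop("outcomes must have exactly two classes")
  minority <- names(cls)[which.min(cls)]
  n_min <- min(cls); n_maj <- max(cls)
  need <- round(target_ratio * n_maj) - n_min
  if (need <= 0) {
    return(structure(list(features = features, outcomes = outcomes),
                     synthetic = rep(FALSE, nrow(features))))
  }
  if (n_min < 2L) stop("need at least 2 minority observations to interpolate")
  if (!is.null(seed)) set.seed(seed)
  min_idx <- which(outcomes == minority)
  xm <- features[min_idx, , drop = FALSE]
  k <- min(k_neighbors, n_min - 1L)
  d <- as.matrix(stats::dist(xm))
  diag(d) <- Inf
  nn <- matrix(apply(d, 1, function(r) order(r)[seq_len(k)]),
               nrow = n_min, ncol = k, byrow = TRUE)
  i <- sample.int(n_min, need, replace = TRUE)
  j <- nn[cbind(i, sample.int(k, need, replace = TRUE))]
  u <- stats::runif(need)
  synth <- xm[i, , drop = FALSE] + u * (xm[j, , drop = FALSE] -
                                          xm[i, , drop = FALSE])
  out_features <- rbind(features, synth)
  rownames(out_features) <- NULL
  out_outcomes <- c(as.character(outcomes), rep(minority, need))
  if (is.factor(outcomes)) {
    out_outcomes <- factor(out_outcomes, levels = levels(outcomes))
  }
  structure(list(features = out_features, outcomes = out_outcomes),
            synthetic = c(rep(FALSE, nrow(features)), rep(TRUE, need)))
}

# Exact two-sided rank-sum p-value by exhaustive enumeration of all
# C(n1+n2, n1) group assignments (ties handled through average ranks).
wilcoxon_exact_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  expect <- n1 * (n1 + n2 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  w_all <- colSums(matrix(r[combos], nrow = n1))
  mean(abs(w_all - expect) >= abs(w_obs - expect) - 1e-12)
}

#' Per-marker Wilcoxon rank-sum test between outcome classes
#'
#' Tests each marker's intensities in positive versus negative wells.
#' When both classes have at most 8 wells the two-sided p-value is computed
#' by exhaustive enumeration of all group assignments (valid under ties);
#' otherwise the Mann-Whitney normal approximation with tie correction
#' (`stats::wilcox.test`) is used.
#'
#' @param dataset scored index-sort data.frame.
#' @param exact_max largest per-class size for the exact branch (default 8).
#' @return data.frame with `marker` and `p_value`, ordered as in the input.
#' @export
wilcoxon_marker_test <- function(dataset, exact_max = 8) {
  pos <- positive_outcomes(dataset)
  if (!any(pos) || all(pos)) stop("both outcome classes must be nonempty")
  markers <- marker_names(dataset)
  p <- vapply(markers, function(m) {
    x <- dataset[[m]][pos]
    y <- dataset[[m]][!pos]
    if (length(unique(c(x, y))) == 1L) return(1)  # degenerate: no ordering
    if (length(x) <= exact_max && length(y) <= exact_max) {
      wilcoxon_exact_p(x, y)
    } else {
      stats::wilcox.test(x, y, exact = FALSE)$p.value
    }
  }, numeric(1))
  data.frame(marker = markers, p_value = unname(p), stringsAsFactors = FALSE)
}
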