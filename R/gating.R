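#' Binned cumulative colony-enrichment curve for one marker
#'
#' Wells are ordered by marker value (decreasing for `direction = "hi"`,
#' increasing for `"lo"`), divided into `n_bins` equal-frequency bins, and
#' accumulated from the extreme-expression end inward. For the k-th bin the
#' curve records `x` = cumulative fraction of wells in this and
#' more-extreme bins, and `y` = 1 - cumulative colony-formation fraction
#' among those wells. At the extreme end (small `x`) `y` is low when high
#' (or low, for `"lo"`) expressors are colony-rich; the curve rises to
#' `1 -` the overall colony rate at `x = 1`.
#'
#' @param values numeric marker intensities, one per well.
#' @param outcomes logical (TRUE = colony-positive) or a
#'   `"positive"`/`"negative"` factor.
#' @param n_bins number of bins (default 60); reduced to the well count
#'   with a warning when there are fewer wells than bins.
#' @param direction `"hi"` or `"lo"`: which end of the marker's range is
#'   accumulated first.
#' @return an `enrichment_curve` data.frame: `bin`, `threshold` (the least
#'   extreme value included through this bin), `x`, `y`.
#' @export
enrichment_curve <- function(values, outcomes, n_bins = 60,
                             direction = c("hi", "lo")) {
  direction <- match.arg(direction)
  if (is.factor(outcomes) || is.character(outcomes)) {
    outcomes <- outcomes == "positive"
  }
  stopifnot(is.numeric(values), length(values) == length(outcomes))
  n <- length(values)
  if (length(unique(values)) == 1L) {
    stop("all marker values identical: no ordering to bin on")
  }
  if (n < n_bins) {
    warning("fewer wells (", n, ") than bins; using ", n, " bins")
    n_bins <- n
  }
  ord <- order(values, decreasing = (direction == "hi"))
  v <- values[ord]
  pos <- outcomes[ord]
  bin <- ceiling(seq_len(n) * n_bins / n)
  cum_n <- cumsum(tabulate(bin, n_bins))
  cum_pos <- cumsum(as.numeric(
    tapply(pos, factor(bin, levels = seq_len(n_bins)), sum)))
  thresholds <- v[cum_n]
  out <- data.frame(bin = seq_len(n_bins),
                    threshold = as.numeric(thresholds),
                    x = cum_n / n,
                    y = 1 - as.numeric(cum_pos) / cum_n)
  attr(out, "direction") <- direction
  attr(out, "n_wells") <- n
  class(out) <- c("enrichment_curve", "data.frame")
  out
}

#' Select a gating cutoff at the inflection of an enrichment curve
#'
#' The curve's inflection is where the per-bin colony rate changes from
#' the enriched level near the extreme-expression end to the baseline
#' level — a change point in a sequence of binomial counts. The default
#' `"step"` method fits, for every candidate boundary, a two-segment
#' binomial model (one colony rate inside the candidate gate, one
#' outside) and returns the boundary maximizing the profile likelihood,
#' restricted to boundaries where the inside rate exceeds the outside
#' rate. This reads the cumulative curve's slope change directly from the
#' binned counts and stays reliable when the colony-rate contrast is
#' small (percent-level prevalence), where chord-based knee detection is
#' dominated by the noise of the first curve point.
#'
#' An informativeness guard rejects curves whose best candidate does not
#' separate colony rates (two-proportion test at level `alpha` at the
#' selected boundary), returning 1.0 (retain everything) with a warning;
#' exactly flat or linear curves have no rate change and are rejected the
#' same way.
#'
#' `method = "chord"` gives the classical knee instead: isotonic
#' smoothing, rescaling to the unit square, then the point of maximum
#' perpendicular distance below the chord joining the first and last
#' points; `"curvature"` the maximum discrete second difference of the
#' smoothed rescaled curve. Both share the guard.
#'
#' @param curve an [enrichment_curve()].
#' @param method `"step"` (default), `"chord"`, or `"curvature"`.
#' @param alpha significance level of the informativeness guard
#'   (default 0.003).
#' @return retained fraction in (0, 1].
#' @export
find_cutoff <- function(curve, method = c("step", "chord", "curvature"),
                        alpha = 0.003) {
  method <- match.arg(method)
  cp <- .curve_changepoint(curve, method = method, alpha = alpha)
  if (!cp$informative) {
    warning(cp$reason, "; returning 1.0")
    return(1.0)
  }
  cp$x
}

# The core of find_cutoff, also used by greedy panel building: locate the
# candidate boundary, its two-segment profile-likelihood gain over the
# single-rate model, and the guard p-value. Returns a list with fields
# informative/x/gain/p/reason.
.curve_changepoint <- function(curve, method = "step", alpha = 0.003) {
  stopifnot(inherits(curve, "enrichment_curve"), nrow(curve) >= 3)
  x <- curve$x
  k <- nrow(curve)
  n <- attr(curve, "n_wells")
  if (is.null(n)) stop("curve lacks well counts (not from enrichment_curve)")
  cum_n <- round(curve$x * n)
  cum_pos <- round((1 - curve$y) * cum_n)
  tot_n <- cum_n[k]; tot_pos <- cum_pos[k]

  flat <- function(reason) {
    list(informative = FALSE, x = 1.0, gain = 0, p = NA_real_,
         reason = reason)
  }
  if (tot_pos == 0 || tot_pos == tot_n) {
    return(flat("curve carries no colony-rate contrast"))
  }

  bll <- function(pos, size) {  # binomial log-likelihood at the MLE rate
    r <- pos / size
    ifelse(pos > 0, pos * log(r), 0) +
      ifelse(size - pos > 0, (size - pos) * log(1 - r), 0)
  }
  cand <- seq_len(k - 1L)
  ll <- vapply(cand, function(j) {
    bll(cum_pos[j], cum_n[j]) + bll(tot_pos - cum_pos[j], tot_n - cum_n[j])
  }, numeric(1))

  i <- if (method == "step") {
    enriched <- cum_pos[cand] / cum_n[cand] >
      (tot_pos - cum_pos[cand]) / (tot_n - cum_n[cand])
    if (!any(enriched)) {
      return(flat("no boundary with an enriched inside rate"))
    }
    cand[enriched][which.max(ll[enriched])]
  } else {
    y <- stats::isoreg(curve$x, curve$y)$yf
    if (y[k] == y[1]) return(flat("flat curve"))
    u <- (x - x[1]) / (x[k] - x[1])
    v <- (y - y[1]) / (y[k] - y[1])
    dist <- (u - v) / sqrt(2)  # perpendicular distance below the unit chord
    if (max(dist) < 1e-6) {
      return(flat("curve has no knee below its chord"))
    }
    if (method == "chord") which.max(dist) else
      which.max(c(NA, diff(diff(v)), NA))
  }

  gain <- ll[i] - bll(tot_pos, tot_n)
  n_in <- cum_n[i]; n_out <- tot_n - n_in
  pos_in <- cum_pos[i]; pos_out <- tot_pos - pos_in
  p <- if (n_out > 0) {
    suppressWarnings(
      stats::prop.test(c(pos_in, pos_out), c(n_in, n_out),
                       correct = FALSE)$p.value
    )
  } else NA_real_
  if (!is.na(p) && (!is.finite(p) || p >= alpha)) {
    out <- flat(paste0(
      "colony rates inside/outside the candidate cutoff do not differ ",
      "(p = ", signif(p, 3), ")"))
    out$gain <- gain; out$p <- p
    return(out)
  }
  list(informative = TRUE, x = x[i], gain = gain, p = p, reason = NULL)
}

#' Build a gating panel by sequential cutoff discovery
#'
#' Discovers an ordered percentile panel on the wells surviving each
#' previously recorded gate. Positive-selection (`hi`) markers are always
#' gated before negative (`lo`) markers, which deplete the population the
#' positive gates selected — the standard sort design, and the only place
#' a depletion cutoff nested at the end of a panel is identifiable.
#' Iteration stops when the surviving subset falls below `2 * n_bins`
#' wells, runs out of colonies, or no remaining marker is informative.
#'
#' With `select = "greedy"` (the default), every remaining marker of the
#' current phase is evaluated on the current subset and the one whose
#' two-segment change point yields the largest profile-likelihood gain is
#' gated next; `marker_order` supplies the candidate set and the
#' tie-break preference. The conditional gain tracks the nesting
#' structure of the data directly, which keeps discovery stable when two
#' markers' marginal associations are too close for a fixed ordering to
#' separate reliably. With `select = "ordered"` the markers are processed
#' exactly in the order given (within the hi-before-lo phases); a marker
#' whose curve carries no informative inflection within the current
#' subset contributes no gate, and an uninformative *first* marker is an
#' error, since the whole ordering is then suspect.
#'
#' Directions default to the sign of the positive-vs-negative median
#' intensity difference (`hi` when positives run higher).
#'
#' @param dataset scored (and typically normalized, outlier-excluded)
#'   index-sort data.frame.
#' @param marker_order character vector of candidate markers, best first —
#'   usually `rank_summary(...)$marker`.
#' @param directions optional named character vector (`"hi"`/`"lo"`) per
#'   marker; inferred when omitted.
#' @param n_bins bins per enrichment curve (default 60).
#' @param alpha informativeness guard passed to the change-point test.
#' @param select `"greedy"` (default) or `"ordered"`; see Details.
#' @return a `gating_panel` object: `gates` (data.frame marker/direction/
#'   percentile), `curves` (the per-gate enrichment curves), `subset_sizes`,
#'   `n_bins`.
#' @export
build_panel <- function(dataset, marker_order, directions = NULL,
                        n_bins = 60, alpha = 0.003,
                        select = c("greedy", "ordered")) {
  select <- match.arg(select)
  pos <- positive_outcomes(dataset)
  stopifnot(length(marker_order) >= 1,
            all(marker_order %in% marker_names(dataset)))
  if (is.null(directions)) {
    directions <- vapply(marker_order, function(m) {
      d <- stats::median(dataset[[m]][pos]) - stats::median(dataset[[m]][!pos])
      if (d >= 0) "hi" else "lo"
    }, character(1))
  }
  stopifnot(all(marker_order %in% names(directions)))
  keep <- rep(TRUE, nrow(dataset))
  gates <- list(); curves <- list(); sizes <- integer(0)

  eval_marker <- function(m, idx) {
    curve <- enrichment_curve(dataset[[m]][idx], pos[idx], n_bins,
                              directions[[m]])
    cp <- .curve_changepoint(curve, alpha = alpha)
    cp$curve <- curve
    cp
  }
  record_gate <- function(m, cp, idx) {
    gates[[m]] <<- gate_spec(m, directions[[m]], cp$x)
    curves[[m]] <<- cp$curve
    sizes <<- c(sizes, length(idx))
    pass <- apply_gate(dataset[[m]][idx], directions[[m]], cp$x)
    keep[idx[!pass]] <<- FALSE
  }
  subset_ok <- function(idx) {
    if (length(idx) < 2 * n_bins) {
      warning("stopping: surviving subset (", length(idx),
              " wells) smaller than 2 x n_bins")
      return(FALSE)
    }
    if (!any(pos[idx])) {
      warning("stopping: no colonies left in the surviving subset")
      return(FALSE)
    }
    TRUE
  }

  # positive-selection phase first, then depletion markers
  for (phase in c("hi", "lo")) {
    remaining <- marker_order[directions[marker_order] == phase]
    if (select == "ordered") {
      for (m in remaining) {
        idx <- which(keep)
        if (!subset_ok(idx)) break
        cp <- eval_marker(m, idx)
        if (!cp$informative) {
          warning("marker '", m, "': ", cp$reason, "; no gate recorded")
          if (m == marker_order[1L]) {
            stop("first marker '", m, "' has no informative cutoff; ",
                 "inspect the marker ordering and enrichment curves")
          }
          next
        }
        record_gate(m, cp, idx)
      }
    } else {
      repeat {
        if (!length(remaining)) break
        idx <- which(keep)
        if (!subset_ok(idx)) break
        cps <- lapply(remaining, eval_marker, idx = idx)
        names(cps) <- remaining
        ok <- remaining[vapply(cps, `[[`, logical(1), "informative")]
        if (!length(ok)) break
        best <- ok[which.max(vapply(cps[ok], `[[`, numeric(1), "gain"))]
        record_gate(best, cps[[best]], idx)
        remaining <- setdiff(remaining, best)
      }
    }
  }
  if (!length(gates)) {
    stop("no marker has an informative cutoff; inspect the enrichment ",
         "curves and the outcome scoring")
  }
  structure(list(
    gates = data.frame(
      marker = vapply(gates, `[[`, character(1), "marker"),
      direction = vapply(gates, `[[`, character(1), "direction"),
      percentile = vapply(gates, `[[`, numeric(1), "percentile"),
      stringsAsFactors = FALSE, row.names = NULL
    ),
    curves = curves, subset_sizes = sizes, n_bins = n_bins
  ), class = "gating_panel")
}

#' Construct a gating panel from explicit gates
#'
#' @param gates list of [gate_spec()] objects (or a data.frame with columns
#'   `marker`, `direction`, `percentile`).
#' @return a `gating_panel`.
#' @export
gating_panel <- function(gates) {
  if (is.data.frame(gates)) {
    df <- gates[c("marker", "direction", "percentile")]
    gates <- Map(gate_spec, df$marker, df$direction, df$percentile)
  }
  df <- data.frame(
    marker = vapply(gates, `[[`, character(1), "marker"),
    direction = vapply(gates, `[[`, character(1), "direction"),
    percentile = vapply(gates, `[[`, numeric(1), "percentile"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (anyDuplicated(df$marker)) stop("panel markers must be unique")
  structure(list(gates = df, curves = list(), subset_sizes = integer(0),
                 n_bins = NA_integer_),
            class = "gating_panel")
}

#' Apply a gating panel to an index-sort dataset
#'
#' Gates are applied sequentially; each gate's percentile is re-evaluated
#' within the subset surviving the previous gates (the same semantics the
#' discovery step uses), with boundary ties included.
#'
#' @param panel a `gating_panel`.
#' @param dataset index-sort data.frame containing every panel marker.
#' @return logical selection mask over the dataset's rows.
#' @export
apply_panel <- function(panel, dataset) {
  stopifnot(inherits(panel, "gating_panel"))
  missing <- setdiff(panel$gates$marker, marker_names(dataset))
  if (length(missing)) {
    stop("dataset lacks panel marker(s): ", paste(missing, collapse = ", "))
  }
  keep <- rep(TRUE, nrow(dataset))
  for (i in seq_len(nrow(panel$gates))) {
    idx <- which(keep)
    if (!length(idx)) {
      warning("subset emptied before gate ", i, "; returning empty mask")
      break
    }
    g <- panel$gates[i, ]
    pass <- apply_gate(dataset[[g$marker]][idx], g$direction, g$percentile)
    keep[idx[!pass]] <- FALSE
  }
  keep
}

#' @export
predict.gating_panel <- function(object, newdata, ...) {
  apply_panel(object, newdata)
}

#' @export
coef.gating_panel <- function(object, ...) {
  stats::setNames(object$gates$percentile, object$gates$marker)
}

#' @export
print.gating_panel <- function(x, ...) {
  cat("Gating panel (", nrow(x$gates), " sequential gates)\n", sep = "")
  for (i in seq_len(nrow(x$gates))) {
    g <- x$gates[i, ]
    cat(sprintf("  %d. %s^%s: %s %.0f%%\n", i, g$marker, g$direction,
                if (g$direction == "hi") "top" else "bottom",
                100 * g$percentile))
  }
  invisible(x)
}

#' @export
summary.gating_panel <- function(object, dataset = NULL, ...) {
  cat("Gating panel with", nrow(object$gates), "gates; expected retained",
      sprintf("fraction %.3f (product of nested percentiles)\n",
              prod(object$gates$percentile)))
  print(object)
  if (!is.null(dataset)) print(evaluate_panel(object, dataset))
  invisible(object)
}

#' Plot the per-gate enrichment curves of a discovered panel
#'
#' @param x a `gating_panel` built by [build_panel()] (panels constructed
#'   directly carry no curves).
#' @param ... passed to `plot()`.
#' @export
plot.gating_panel <- function(x, ...) {
  if (!length(x$curves)) {
    stop("panel carries no curves (constructed, not discovered)")
  }
  old <- graphics::par(mfrow = c(1, length(x$curves)))
  on.exit(graphics::par(old))
  for (m in names(x$curves)) {
    curve <- x$curves[[m]]
    g <- x$gates[x$gates$marker == m, ]
    plot(curve$x, curve$y, type = "l", xlab = "cumulative fraction of wells",
         ylab = "1 - cumulative colony fraction", main = m, ...)
    graphics::abline(v = g$percentile, lty = 2)
  }
  invisible(x)
}

#' Evaluate a panel's selection against colony outcomes
#'
#' @param panel a `gating_panel`.
#' @param dataset scored index-sort data.frame.
#' @param per_marker also compute single-gate metrics for each panel
#'   marker applied alone (default TRUE).
#' @return data.frame with rows `panel` (and one per single gate):
#'   `enrichment` (colony rate in selection / overall rate; NA when no
#'   colonies), `sensitivity`, `specificity`, `selected_fraction`.
#' @export
evaluate_panel <- function(panel, dataset, per_marker = TRUE) {
  pos <- positive_outcomes(dataset)
  metrics <- function(mask) {
    overall <- mean(pos)
    sel_rate <- if (any(mask)) mean(pos[mask]) else NA_real_
    data.frame(
      enrichment = if (overall == 0) NA_real_ else sel_rate / overall,
      sensitivity = if (sum(pos) == 0) NA_real_ else
        sum(pos & mask) / sum(pos),
      specificity = if (sum(!pos) == 0) NA_real_ else
        sum(!pos & !mask) / sum(!pos),
      selected_fraction = mean(mask)
    )
  }
  out <- cbind(gate = "panel", metrics(apply_panel(panel, dataset)))
  if (per_marker) {
    for (i in seq_len(nrow(panel$gates))) {
      g <- panel$gates[i, ]
      mask <- apply_gate(dataset[[g$marker]], g$direction, g$percentile)
      out <- rbind(out, cbind(gate = g$marker, metrics(mask)))
    }
  }
  rownames(out) <- NULL
  out
}

#' Compare candidate panels replicate by replicate
#'
#' Applies [evaluate_panel()] to each panel on each replicate (split by
#' `plate_id`) and ranks panels by median enrichment.
#'
#' @param panels named list of `gating_panel` objects.
#' @param dataset scored index-sort data.frame (replicates = plates).
#' @return list with `table` (per panel x replicate metrics) and `summary`
#'   (per panel median enrichment, best first).
#' @export
compare_panels <- function(panels, dataset) {
  stopifnot(length(panels) >= 1)
  if (is.null(names(panels))) {
    names(panels) <- sprintf("panel%d", seq_along(panels))
  }
  rows <- list()
  for (nm in names(panels)) {
    for (pid in unique(dataset$plate_id)) {
      sub <- dataset[dataset$plate_id == pid, , drop = FALSE]
      ev <- evaluate_panel(panels[[nm]], sub, per_marker = FALSE)
      rows[[length(rows) + 1L]] <- cbind(panel = nm, plate_id = pid,
                                         ev[, -1, drop = FALSE])
    }
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  med <- tapply(table$enrichment, table$panel, stats::median, na.rm = TRUE)
  summary <- data.frame(panel = names(med),
                        median_enrichment = as.numeric(med),
                        stringsAsFactors = FALSE)
  summary <- summary[order(-summary$median_enrichment), , drop = FALSE]
  rownames(summary) <- NULL
  list(table = table, summary = summary)
}
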