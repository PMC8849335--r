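#' Specify one percentile gate
#'
#' A gate keeps the top (`"hi"`) or bottom (`"lo"`) `percentile` fraction of
#' cells for one marker, evaluated within the subset surviving all previous
#' gates of a panel.
#'
#' @param marker marker name.
#' @param direction `"hi"` or `"lo"`.
#' @param percentile fraction of cells retained, in (0, 1].
#' @return a `gate_spec` list.
#' @export
gate_spec <- function(marker, direction = c("hi", "lo"), percentile) {
  direction <- match.arg(direction)
  stopifnot(is.character(marker), length(marker) == 1L, nzchar(marker))
  if (!is.numeric(percentile) || length(percentile) != 1L ||
      is.na(percentile) || percentile <= 0 || percentile > 1) {
    stop("percentile must be in (0, 1]")
  }
  structure(list(marker = marker, direction = direction,
                 percentile = as.numeric(percentile)),
            class = "gate_spec")
}

#' The published MKP sort panel, as nested percentile gates
#'
#' Top 20% PVR, top 50% MICB, top 85% CD51, top 62% CD168 and bottom 25%
#' VEGFR1, in discovery order, each percentile nested within the cells
#' passing the preceding gates.
#'
#' @return list of [gate_spec()] objects.
#' @export
mkp_reference_panel <- function() {
  list(
    gate_spec("PVR", "hi", 0.20),
    gate_spec("MICB", "hi", 0.50),
    gate_spec("CD51", "hi", 0.85),
    gate_spec("CD168", "hi", 0.62),
    gate_spec("VEGFR1", "lo", 0.25)
  )
}

#' Configuration for the index-sort plate simulator
#'
#' @param n_plates number of plates (replicates).
#' @param wells_per_plate wells per plate, typically 96 or 384; must be at
#'   least twice the number of markers.
#' @param markers character vector of marker names measured per well.
#' @param truth_panel ordered list of [gate_spec()] gates defining the
#'   ground-truth progenitor population (nested percentiles).
#' @param label_flip_rate probability that a well's colony outcome disagrees
#'   with its ground-truth gate membership, in [0, 0.5).
#' @param batch_shift_sd standard deviation of the per-plate, per-marker
#'   log-intensity shift (plate batch effect).
#' @param marker_correlation pairwise marker correlation on the log scale,
#'   imposed through a single shared latent factor, in [0, 1).
#' @param seed integer seed; the simulator is deterministic given the config.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_plates = 20,
                       wells_per_plate = 384,
                       markers = c("MICB", "PVR", "CD41", "CD42", "ANXA1",
                                   "CD51", "CD168", "VEGFR1"),
                       truth_panel = mkp_reference_panel(),
                       label_flip_rate = 0.0,
                       batch_shift_sd = 0.0,
                       marker_correlation = 0.3,
                       seed = 1L) {
  stopifnot(n_plates >= 1, wells_per_plate >= 2,
            is.character(markers), length(markers) >= 1)
  if (anyDuplicated(markers)) stop("marker names must be unique")
  if (wells_per_plate < 2 * length(markers)) {
    stop("wells_per_plate must be at least twice the number of markers")
  }
  if (label_flip_rate < 0 || label_flip_rate >= 0.5) {
    stop("label_flip_rate must be in [0, 0.5)")
  }
  if (marker_correlation < 0 || marker_correlation >= 1) {
    stop("marker_correlation must be in [0, 1)")
  }
  panel_markers <- vapply(truth_panel, `[[`, character(1), "marker")
  if (anyDuplicated(panel_markers)) stop("truth_panel markers must be unique")
  missing <- setdiff(panel_markers, markers)
  if (length(missing)) {
    stop("truth_panel references markers absent from `markers`: ",
         paste(missing, collapse = ", "))
  }
  structure(list(n_plates = as.integer(n_plates),
                 wells_per_plate = as.integer(wells_per_plate),
                 markers = markers, truth_panel = truth_panel,
                 label_flip_rate = label_flip_rate,
                 batch_shift_sd = batch_shift_sd,
                 marker_correlation = marker_correlation,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Evaluate an ordered gate list with nested percentiles; returns logical.
apply_nested_gates <- function(intensities, panel) {
  keep <- rep(TRUE, nrow(intensities))
  for (g in panel) {
    idx <- which(keep)
    if (!length(idx)) break
    pass <- apply_gate(intensities[idx, g$marker], g$direction, g$percentile)
    keep[idx[!pass]] <- FALSE
  }
  keep
}

#' Simulate index-sorted plates with a nested ground-truth gating panel
#'
#' Per-well marker intensities are correlated log-normals (a single shared
#' latent factor gives every marker pair the configured correlation) with a
#' per-plate, per-marker batch shift on the log scale. The ground-truth
#' progenitor label of a well is membership in the nested truth panel,
#' evaluated percentile-by-percentile *within each plate* (each gate's
#' percentile is computed within the subset passing all previous gates,
#' mirroring how index sorts are gated per sort). The colony outcome flips
#' the ground-truth label with probability `label_flip_rate`; colony counts
#' are drawn uniformly from 4..50 for positive outcomes and 0..3 for
#' negative ones.
#'
#' @details Ground truth is defined so that sequential discovery is its
#'   exact inverse: intensities are first reduced to within-plate
#'   fractional ranks (the scale plate-batch effects cannot touch and the
#'   one the discovery pipeline reconstructs via
#'   [normalize_replicates()]), plates are pooled, and the nested gates
#'   are applied to the pooled rank table.
#'
#' @param config a [sim_config()].
#' @return a data.frame with columns `plate_id`, `well_id`, one numeric
#'   column per marker, and `colony_count`; the ground-truth labels are
#'   attached as attribute `"truth"` (logical) and the panel as `"truth_panel"`.
#' @export
simulate_index_sort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  m <- length(config$markers)
  w <- config$wells_per_plate
  rho <- config$marker_correlation
  plates <- vector("list", config$n_plates)
  ranks <- vector("list", config$n_plates)
  for (p in seq_len(config$n_plates)) {
    z <- stats::rnorm(w)
    eps <- matrix(stats::rnorm(w * m), w, m)
    log_int <- sqrt(rho) * matrix(z, w, m) + sqrt(1 - rho) * eps
    shift <- stats::rnorm(m, 0, config$batch_shift_sd)
    log_int <- sweep(log_int, 2, shift, "+") + 4  # arbitrary-unit baseline
    colnames(log_int) <- config$markers
    plates[[p]] <- data.frame(
      plate_id = sprintf("plate%02d", p),
      well_id = sprintf("P%02d_W%03d", p, seq_len(w)),
      exp(log_int),
      stringsAsFactors = FALSE
    )
    ranks[[p]] <- apply(log_int, 2, rank) / w
  }
  pooled_ranks <- do.call(rbind, ranks)
  truth <- apply_nested_gates(pooled_ranks, config$truth_panel)
  flips <- stats::runif(length(truth)) < config$label_flip_rate
  positive <- xor(truth, flips)
  counts <- integer(length(truth))
  counts[positive] <- sample(4:50, sum(positive), replace = TRUE)
  counts[!positive] <- sample(0:3, sum(!positive), replace = TRUE)
  out <- do.call(rbind, plates)
  out$colony_count <- counts
  rownames(out) <- NULL
  attr(out, "truth") <- truth
  attr(out, "truth_panel") <- config$truth_panel
  out
}

#' Configuration for the reference/query expression simulator
#'
#' @param n_types number of reference cell types (>= 2).
#' @param cells_per_type reference cells per type.
#' @param markers_per_type private marker genes per type.
#' @param n_genes total genes; must accommodate all type markers plus the
#'   unknown population's markers.
#' @param effect_size mean log-fold elevation (natural log) of a type's
#'   marker genes within that type.
#' @param query_unknown_fraction fraction of query cells drawn from a
#'   population absent from the reference, in [0, 1].
#' @param query_cells total query cells (default: reference size).
#' @param dispersion negative-binomial size parameter of counts.
#' @param seed integer seed.
#' @return a `ref_query_config` list.
#' @export
ref_query_config <- function(n_types = 4,
                             cells_per_type = 500,
                             markers_per_type = 25,
                             n_genes = 1000,
                             effect_size = 2,
                             query_unknown_fraction = 0.25,
                             query_cells = n_types * cells_per_type,
                             dispersion = 2,
                             seed = 1L) {
  stopifnot(n_types >= 2, cells_per_type >= 2, markers_per_type >= 1,
            effect_size >= 0, dispersion > 0, query_cells >= 1)
  if (query_unknown_fraction < 0 || query_unknown_fraction > 1) {
    stop("query_unknown_fraction must be in [0, 1]")
  }
  # one extra marker block for the reference-absent (unknown) population
  if ((n_types + 1) * markers_per_type > n_genes) {
    stop("markers_per_type x (n_types + 1) exceeds n_genes")
  }
  structure(list(n_types = as.integer(n_types),
                 cells_per_type = as.integer(cells_per_type),
                 markers_per_type = as.integer(markers_per_type),
                 n_genes = as.integer(n_genes),
                 effect_size = effect_size,
                 query_unknown_fraction = query_unknown_fraction,
                 query_cells = as.integer(query_cells),
                 dispersion = dispersion,
                 seed = as.integer(seed)),
            class = "ref_query_config")
}

# NB counts for one population: base gene means times a per-type multiplier
# on its private markers.
.nb_population <- function(n_cells, base_mu, boost_idx, effect, dispersion,
                           prefix) {
  mu <- base_mu
  mu[boost_idx] <- mu[boost_idx] * exp(effect)
  counts <- matrix(
    stats::rnbinom(length(mu) * n_cells, mu = rep(mu, n_cells),
                   size = dispersion),
    nrow = length(mu), ncol = n_cells
  )
  colnames(counts) <- sprintf("%s_c%04d", prefix, seq_len(n_cells))
  counts
}

#' Simulate an annotated reference and a query with an unknown population
#'
#' Reference cells have negative-binomial counts; each type elevates its
#' private marker block by `effect_size` on the natural-log scale. The query
#' mixes reference-like cells (uniformly over types) with an "unknown"
#' population whose own marker block is elevated instead, so that no query
#' cell of that population matches any reference type's signature. With
#' `query_unknown_fraction = 1` the query is a pure negative-control
#' population, the in-silico analogue of pluripotent day-0 cells that no
#' adult reference type represents.
#'
#' @param config a [ref_query_config()].
#' @return list with elements `reference` (list: `counts` genes x cells,
#'   `labels` factor), `query` (list: `counts`, `truth` character labels with
#'   `"unknown"` for the reference-absent population) and `marker_genes`
#'   (list of planted marker-gene names per type and for `"unknown"`).
#' @export
simulate_reference_query <- function(config) {
  stopifnot(inherits(config, "ref_query_config"))
  set.seed(config$seed)
  genes <- sprintf("gene%04d", seq_len(config$n_genes))
  types <- sprintf("type%d", seq_len(config$n_types))
  base_mu <- exp(stats::rnorm(config$n_genes, mean = 0, sd = 0.5))
  blocks <- split(
    seq_len((config$n_types + 1) * config$markers_per_type),
    rep(seq_len(config$n_types + 1), each = config$markers_per_type)
  )
  marker_genes <- lapply(blocks, function(i) genes[i])
  names(marker_genes) <- c(types, "unknown")

  ref <- lapply(seq_len(config$n_types), function(t) {
    .nb_population(config$cells_per_type, base_mu, blocks[[t]],
                   config$effect_size, config$dispersion,
                   prefix = paste0("ref_", types[t]))
  })
  ref_counts <- do.call(cbind, ref)
  rownames(ref_counts) <- genes
  ref_labels <- factor(rep(types, each = config$cells_per_type), levels = types)

  n_unknown <- round(config$query_cells * config$query_unknown_fraction)
  n_known <- config$query_cells - n_unknown
  q_truth <- character(0)
  q_parts <- list()
  if (n_known > 0) {
    known_types <- sample(types, n_known, replace = TRUE)
    tab <- table(factor(known_types, levels = types))
    for (t in seq_len(config$n_types)) {
      if (tab[t] == 0) next
      q_parts[[length(q_parts) + 1L]] <-
        .nb_population(tab[t], base_mu, blocks[[t]], config$effect_size,
                       config$dispersion, prefix = paste0("qry_", types[t]))
      q_truth <- c(q_truth, rep(types[t], tab[t]))
    }
  }
  if (n_unknown > 0) {
    q_parts[[length(q_parts) + 1L]] <-
      .nb_population(n_unknown, base_mu, blocks[[config$n_types + 1L]],
                     config$effect_size, config$dispersion, prefix = "qry_unk")
    q_truth <- c(q_truth, rep("unknown", n_unknown))
  }
  query_counts <- do.call(cbind, q_parts)
  rownames(query_counts) <- genes

  list(reference = list(counts = ref_counts, labels = ref_labels),
       query = list(counts = query_counts, truth = q_truth),
       marker_genes = marker_genes)
}

#' Simulate cells with planned QC violations
#'
#' Generates a count matrix whose baseline cells comfortably pass every
#' filtering mode (about half the genes detected, moderate depth, ~2%
#' mitochondrial and ~30% ribosomal-protein counts, deep reads), then plants
#' the requested violations cell by cell. The realized violator set is
#' recorded as ground truth.
#'
#' @param n_cells number of cells.
#' @param violation_spec named list mapping cell index (as character) to a
#'   character vector of violations among `"low_features"`, `"high_umis"`,
#'   `"high_mt"`, `"low_rp"`, `"low_reads"`; or `NULL` for none.
#' @param seed integer seed.
#' @param n_genes total genes (default 2500, of which 13 are "MT-" and 80
#'   are "RPS"/"RPL" genes).
#' @return list with `counts` (genes x cells), `total_reads` (per-cell read
#'   counts for the read-depth mode) and `violations` (the planned spec,
#'   normalized).
#' @export
simulate_qc_cells <- function(n_cells, violation_spec = NULL, seed = 1L,
                              n_genes = 2500) {
  stopifnot(n_cells >= 1, n_genes >= 200)
  allowed <- c("low_features", "high_umis", "high_mt", "low_rp", "low_reads")
  violation_spec <- violation_spec %||% list()
  for (v in violation_spec) {
    bad <- setdiff(v, allowed)
    if (length(bad)) stop("unknown violation(s): ", paste(bad, collapse = ", "))
    if (all(c("low_features", "high_umis") %in% v)) {
      stop("contradictory violations: a cell cannot have few detected genes ",
           "and an implausibly high UMI total in this generator")
    }
  }
  set.seed(seed)
  mt_genes <- sprintf("MT-G%02d", 1:13)
  rp_genes <- c(sprintf("RPS%02d", 1:40), sprintf("RPL%02d", 1:40))
  other <- sprintf("GENE%04d", seq_len(n_genes - length(mt_genes) - length(rp_genes)))
  genes <- c(mt_genes, rp_genes, other)
  counts <- matrix(0L, nrow = length(genes), ncol = n_cells,
                   dimnames = list(genes, sprintf("cell%04d", seq_len(n_cells))))
  total_reads <- integer(n_cells)
  for (i in seq_len(n_cells)) {
    viol <- violation_spec[[as.character(i)]] %||% character(0)
    n_detected <- if ("low_features" %in% viol) 500L else
      round(length(genes) * 0.55)
    # baseline composition: ~2% MT, ~30% RP of the detected genes
    n_mt <- if ("high_mt" %in% viol) length(mt_genes) else 5L
    n_rp <- if ("low_rp" %in% viol) 3L else min(60L, n_detected - n_mt - 1L)
    pick_other <- sample(other, max(0L, n_detected - n_mt - n_rp))
    pick <- c(sample(mt_genes, n_mt), sample(rp_genes, n_rp), pick_other)
    vals <- stats::rpois(length(pick), lambda = 5) + 1L
    names(vals) <- pick
    # RP genes carry ~30% of baseline counts so unviolated cells pass the
    # in-vivo RP floor; MT violations are boosted well past the 10% cap
    vals[names(vals) %in% rp_genes] <- vals[names(vals) %in% rp_genes] * 10L
    if ("high_mt" %in% viol) vals[names(vals) %in% mt_genes] <-
      vals[names(vals) %in% mt_genes] + 195L
    if ("high_umis" %in% viol) vals <- vals * 10L
    counts[pick, i] <- as.integer(vals)
    total_reads[i] <- if ("low_reads" %in% viol) 150000L else 500000L
  }
  list(counts = counts, total_reads = total_reads,
       violations = violation_spec)
}
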