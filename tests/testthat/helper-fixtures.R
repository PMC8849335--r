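# Shared fixture builders for the suite. Everything is generated in code;
# no files are read.

# A minimal index-sort data.frame from explicit marker columns and counts.
make_wells <- function(markers, colony_count, plate_id = "plateA") {
  df <- as.data.frame(markers)
  n <- nrow(df)
  cbind(data.frame(plate_id = rep_len(plate_id, n),
                   well_id = sprintf("W%03d", seq_len(n)),
                   stringsAsFactors = FALSE),
        df,
        data.frame(colony_count = colony_count))
}

# Hand-built decision-tree tables (columns left/right/var; NA var = leaf).
leaf_row <- function() data.frame(left = 0L, right = 0L, var = NA_character_)

# root splits A; left child splits B (two leaves); right child splits C.
hand_tree_abc <- function() {
  data.frame(
    left  = c(2L, 4L, 6L, 0L, 0L, 0L, 0L),
    right = c(3L, 5L, 7L, 0L, 0L, 0L, 0L),
    var   = c("A", "B", "C", NA, NA, NA, NA),
    stringsAsFactors = FALSE
  )
}

# root splits A; left leaf; right child splits A again (first occurrence only).
hand_tree_reuse_a <- function() {
  data.frame(
    left  = c(2L, 0L, 4L, 0L, 0L),
    right = c(3L, 0L, 5L, 0L, 0L),
    var   = c("A", NA, "A", NA, NA),
    stringsAsFactors = FALSE
  )
}

# root splits B; left child splits C; right leaf. A absent from this tree.
hand_tree_bc <- function() {
  data.frame(
    left  = c(2L, 4L, 0L, 0L, 0L),
    right = c(3L, 5L, 0L, 0L, 0L),
    var   = c("B", "C", NA, NA, NA),
    stringsAsFactors = FALSE
  )
}

# Independent brute-force recount of QC metrics (scalar loops, no matrix ops).
brute_qc_metrics <- function(counts, mt_genes, rp_genes) {
  out <- data.frame(cell_id = colnames(counts), n_features = NA_integer_,
                    n_umis = NA_real_, mt_pct = NA_real_, rp_pct = NA_real_,
                    stringsAsFactors = FALSE)
  for (j in seq_len(ncol(counts))) {
    feats <- 0L; total <- 0; mt <- 0; rp <- 0
    for (i in seq_len(nrow(counts))) {
      v <- counts[i, j]
      if (v > 0) feats <- feats + 1L
      total <- total + v
      if (rownames(counts)[i] %in% mt_genes) mt <- mt + v
      if (rownames(counts)[i] %in% rp_genes) rp <- rp + v
    }
    out$n_features[j] <- feats
    out$n_umis[j] <- total
    out$mt_pct[j] <- if (total == 0) 0 else 100 * mt / total
    out$rp_pct[j] <- if (total == 0) 0 else 100 * rp / total
  }
  out
}

# Well-by-well sequential gate evaluation (loop form of the nested
# percentile definition: "top p" keeps values >= the (1-p) quantile of the
# surviving subset, ties included).
brute_apply_panel <- function(gates, dataset) {
  alive <- seq_len(nrow(dataset))
  for (i in seq_len(nrow(gates))) {
    v <- dataset[[gates$marker[i]]][alive]
    p <- gates$percentile[i]
    thr <- if (gates$direction[i] == "hi") {
      stats::quantile(v, 1 - p, names = FALSE)
    } else {
      stats::quantile(v, p, names = FALSE)
    }
    pass <- logical(length(alive))
    for (w in seq_along(alive)) {
      pass[w] <- if (gates$direction[i] == "hi") v[w] >= thr else v[w] <= thr
    }
    alive <- alive[pass]
  }
  mask <- rep(FALSE, nrow(dataset))
  mask[alive] <- TRUE
  mask
}

# Exhaustive concordant-pair AUC (ties count one half).
brute_auc <- function(x_in, x_out) {
  s <- 0
  for (a in x_in) for (b in x_out) {
    s <- s + (a > b) + 0.5 * (a == b)
  }
  s / (length(x_in) * length(x_out))
}
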