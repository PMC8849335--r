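test_that("enrichment curves match hand computation and endpoint contract", {
  # 6 wells, values 1..6, positives at 5 and 6, 3 bins
  cv <- enrichment_curve(1:6, c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
                         n_bins = 3, direction = "hi")
  expect_equal(cv$x, c(1, 2, 3) / 3)
  expect_equal(cv$y, c(0, 1 / 2, 2 / 3))

  # degenerate outcome mixes
  all_pos <- enrichment_curve(rnorm(100), rep(TRUE, 100), 10, "hi")
  expect_true(all(all_pos$y == 0))
  none <- enrichment_curve(rnorm(100), rep(FALSE, 100), 10, "hi")
  expect_true(all(none$y == 1))

  # endpoint invariant on random data: x strictly increasing,
  # last point exactly (1, 1 - overall colony rate)
  set.seed(301)
  for (r in 1:5) {
    v <- rnorm(173)
    pos <- runif(173) < 0.3
    cv <- enrichment_curve(v, pos, 60, sample(c("hi", "lo"), 1))
    expect_true(all(diff(cv$x) > 0))
    expect_equal(cv$x[nrow(cv)], 1)
    expect_equal(cv$y[nrow(cv)], 1 - mean(pos))
  }

  expect_error(enrichment_curve(rep(1, 50), rep(TRUE, 50)), "identical")
  expect_warning(enrichment_curve(rnorm(30), rep(c(TRUE, FALSE), 15), 60),
                 "fewer wells")
})

test_that("cutoff detection finds step boundaries and rejects flat curves", {
  set.seed(302)
  n <- 600
  v <- seq_len(n)  # highest value = strongest expressor
  pos <- c(runif(480) < 0.01, runif(120) < 0.6)  # top 20% enriched
  cv <- enrichment_curve(v, pos, 60, "hi")
  expect_equal(find_cutoff(cv), 0.2, tolerance = 0.05)

  # on a noiseless step (every top-20% well positive) all three methods
  # agree on the corner
  sharp <- enrichment_curve(v, c(rep(FALSE, 480), rep(TRUE, 120)), 60, "hi")
  expect_equal(find_cutoff(sharp), 0.2, tolerance = 0.02)
  expect_equal(find_cutoff(sharp, method = "chord"), 0.2, tolerance = 0.02)
  expect_equal(find_cutoff(sharp, method = "curvature"), 0.2,
               tolerance = 0.02)

  # exactly linear cumulative curve: constant rate, no change point
  lin <- enrichment_curve(seq_len(300), rep(c(TRUE, FALSE), 150), 30, "hi")
  expect_warning(c_lin <- find_cutoff(lin), "returning 1")
  expect_equal(c_lin, 1.0)

  # pure-noise marker: informativeness guard rejects
  noise <- enrichment_curve(rnorm(800), runif(800) < 0.05, 60, "hi")
  expect_warning(c_noise <- find_cutoff(noise), "returning 1")
  expect_equal(c_noise, 1.0)

  # a lo-direction step is found at the same retained fraction
  pos_lo <- c(runif(150) < 0.6, runif(450) < 0.01)  # bottom 25% enriched
  cv_lo <- enrichment_curve(v, pos_lo, 60, "lo")
  expect_equal(find_cutoff(cv_lo), 0.25, tolerance = 0.05)
})

test_that("sequential discovery recovers a noiseless nested panel", {
  cfg <- sim_config(n_plates = 6, wells_per_plate = 384,
                    truth_panel = list(gate_spec("PVR", "hi", 0.3),
                                       gate_spec("MICB", "hi", 0.5),
                                       gate_spec("VEGFR1", "lo", 0.4)),
                    label_flip_rate = 0, batch_shift_sd = 0.3, seed = 33)
  ds <- normalize_replicates(score_wells(simulate_index_sort(cfg)))
  panel <- build_panel(ds, marker_order = c("PVR", "MICB", "VEGFR1"))
  got <- coef(panel)
  expect_equal(unname(got["PVR"]), 0.3, tolerance = 0.051)
  expect_equal(unname(got["MICB"]), 0.5, tolerance = 0.051)
  expect_equal(unname(got["VEGFR1"]), 0.4, tolerance = 0.051)
  expect_identical(panel$gates$direction,
                   c("hi", "hi", "lo"))  # inferred, lo marker gated last

  # round trip: the discovered panel re-selects nearly all true positives
  mask <- apply_panel(panel, ds)
  pos <- ds$outcome == "positive"
  expect_gt(sum(mask & pos) / sum(pos), 0.95)

  # single-marker order reduces to find_cutoff on the full table
  single <- build_panel(ds, marker_order = "PVR")
  cv <- enrichment_curve(ds$PVR, pos, 60, "hi")
  expect_equal(unname(coef(single)["PVR"]), find_cutoff(cv))

  # ordered mode: an uninformative first marker aborts discovery
  ds$DUD <- runif(nrow(ds))
  expect_error(
    suppressWarnings(build_panel(ds, marker_order = c("DUD", "PVR"),
                                 directions = c(DUD = "hi", PVR = "hi"),
                                 select = "ordered")),
    "no informative cutoff")
  # greedy mode gates the informative marker and leaves the dud ungated
  greedy <- suppressWarnings(
    build_panel(ds, marker_order = c("DUD", "PVR"),
                directions = c(DUD = "hi", PVR = "hi")))
  expect_false("DUD" %in% greedy$gates$marker)
  expect_true("PVR" %in% greedy$gates$marker)
})

test_that("panel application matches well-by-well evaluation and its invariances", {
  set.seed(303)
  ds <- make_wells(data.frame(A = rnorm(50), B = rnorm(50), C = rnorm(50)),
                   colony_count = rbinom(50, 1, 0.3) * 6)
  panel <- gating_panel(list(gate_spec("A", "hi", 0.6),
                             gate_spec("B", "lo", 0.5),
                             gate_spec("C", "hi", 0.4)))
  expect_identical(apply_panel(panel, ds),
                   brute_apply_panel(panel$gates, ds))

  # empty panel selects everything
  empty <- gating_panel(list())
  expect_true(all(apply_panel(empty, ds)))

  # negating a lo marker and flipping its direction leaves the mask unchanged
  flipped <- ds
  flipped$B <- -flipped$B
  panel_fl <- gating_panel(list(gate_spec("A", "hi", 0.6),
                                gate_spec("B", "hi", 0.5),
                                gate_spec("C", "hi", 0.4)))
  expect_identical(apply_panel(panel, ds), apply_panel(panel_fl, flipped))

  # tie-free continuous data: selected fraction ~ product of percentiles
  big <- make_wells(data.frame(A = runif(4000), B = runif(4000)),
                    colony_count = rep(0, 4000))
  p2 <- gating_panel(list(gate_spec("A", "hi", 0.5), gate_spec("B", "hi", 0.4)))
  expect_equal(mean(apply_panel(p2, big)), 0.2, tolerance = 0.01)

  expect_error(apply_panel(panel, ds[setdiff(names(ds), "C")]), "lacks")
  expect_identical(apply_panel(panel, ds), predict(panel, ds))
})

test_that("panel evaluation equals the contingency-table oracle", {
  set.seed(304)
  ds <- score_wells(make_wells(data.frame(A = rnorm(200)),
                               colony_count = rbinom(200, 1, 0.25) * 7))
  panel <- gating_panel(list(gate_spec("A", "hi", 0.3)))
  ev <- evaluate_panel(panel, ds, per_marker = FALSE)

  mask <- apply_panel(panel, ds)
  pos <- ds$outcome == "positive"
  tp <- sum(mask & pos); fp <- sum(mask & !pos)
  fn <- sum(!mask & pos); tn <- sum(!mask & !pos)
  expect_equal(ev$enrichment, (tp / (tp + fp)) / ((tp + fn) / 200))
  expect_equal(ev$sensitivity, tp / (tp + fn))
  expect_equal(ev$specificity, tn / (tn + fp))
  expect_equal(ev$selected_fraction, (tp + fp) / 200)

  # select-all panel: enrichment 1, sensitivity 1, specificity 0
  all_ev <- evaluate_panel(gating_panel(list(gate_spec("A", "hi", 1))), ds,
                           per_marker = FALSE)
  expect_equal(all_ev[, c("enrichment", "sensitivity", "specificity")],
               data.frame(enrichment = 1, sensitivity = 1, specificity = 0))

  # no colonies at all: enrichment undefined
  none <- score_wells(make_wells(data.frame(A = rnorm(20)), rep(0, 20)))
  expect_true(is.na(evaluate_panel(panel, none, per_marker = FALSE)$enrichment))
})

test_that("noiseless true panel attains perfect sensitivity and 1/prevalence enrichment", {
  cfg <- sim_config(n_plates = 4, wells_per_plate = 384,
                    truth_panel = list(gate_spec("PVR", "hi", 0.4),
                                       gate_spec("MICB", "hi", 0.5)),
                    label_flip_rate = 0, seed = 35)
  ds <- normalize_replicates(score_wells(simulate_index_sort(cfg)))
  panel <- gating_panel(attr(ds, "truth_panel"))
  ev <- evaluate_panel(panel, ds, per_marker = FALSE)
  expect_equal(ev$sensitivity, 1)
  expect_equal(ev$enrichment, 1 / mean(ds$outcome == "positive"),
               tolerance = 0.02)
})

test_that("the true panel outperforms a random panel across replicates", {
  wins <- 0L
  for (seed in 41:45) {
    cfg <- sim_config(n_plates = 4, wells_per_plate = 192,
                      truth_panel = list(gate_spec("PVR", "hi", 0.3),
                                         gate_spec("MICB", "hi", 0.5)),
                      label_flip_rate = 0.02, seed = seed)
    ds <- normalize_replicates(score_wells(simulate_index_sort(cfg)))
    cp <- compare_panels(
      list(true = gating_panel(attr(ds, "truth_panel")),
           random = gating_panel(list(gate_spec("CD41", "hi", 0.3),
                                      gate_spec("ANXA1", "hi", 0.5)))),
      ds)
    expect_equal(nrow(cp$table), 8)  # 2 panels x 4 replicates
    wins <- wins + (cp$summary$median_enrichment[cp$summary$panel == "true"] >
                      cp$summary$median_enrichment[cp$summary$panel == "random"])
  }
  expect_equal(wins, 5L)
})
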