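test_that("colony scoring pins the more-than-three boundary", {
  ds <- make_wells(data.frame(M = rnorm(11)), colony_count = 0:10)
  scored <- score_wells(ds)
  expect_identical(which(scored$outcome == "positive"), 5:11)  # counts 4..10
  expect_identical(which(scored$outcome == "negative"), 1:4)   # counts 0..3

  ds$colony_count[3] <- NA
  expect_error(score_wells(ds), "W003")
  no_counts <- data.frame(plate_id = "p", well_id = "w", M = 1)
  expect_error(score_wells(no_counts), "colony_count")
})

test_that("replicates with too few colonies are excluded", {
  mk_plate <- function(id, n_pos) {
    make_wells(data.frame(M = rnorm(40)),
               colony_count = rep(c(10, 0), c(n_pos, 40 - n_pos)),
               plate_id = id)
  }
  ds <- score_wells(rbind(mk_plate("p1", 2), mk_plate("p2", 4),
                          mk_plate("p3", 6)))
  kept <- exclude_replicates(ds)
  expect_identical(unique(kept$plate_id), "p3")
  log <- attr(kept, "exclusion_log")
  expect_identical(log$retained, c(FALSE, FALSE, TRUE))
  expect_identical(log$n_positive, c(2L, 4L, 6L))

  all_kept <- exclude_replicates(ds, min_colonies = 0)
  expect_equal(nrow(all_kept), nrow(ds))
})

test_that("outlier exclusion removes exactly a planted robust-SD spike", {
  set.seed(201)
  ds <- make_wells(data.frame(A = exp(rnorm(60)), B = exp(rnorm(60))),
                   colony_count = rbinom(60, 1, 0.2) * 5)
  logA <- log(ds$A)
  ds$A[7] <- exp(stats::median(logA) + 10 * stats::mad(logA))
  filt <- exclude_outliers(ds, k_mad = 5)
  expect_equal(nrow(filt), 59)
  expect_identical(attr(filt, "exclusion_log")$well_id, "W007")
  expect_identical(attr(filt, "exclusion_log")$marker, "A")

  # idempotent on its own output
  again <- exclude_outliers(filt, k_mad = 5)
  expect_equal(again[names(ds)], filt[names(ds)])

  # zero-MAD marker is skipped with a warning, not an error
  ds$B <- 1
  expect_warning(exclude_outliers(ds), "zero MAD")
})

test_that("rank normalization is monotone-invariant and matches hand ranks", {
  ds <- make_wells(data.frame(M = c(5, 1, 9, 9, 2)), colony_count = rep(0, 5))
  norm <- normalize_replicates(ds)
  expect_equal(norm$M, c(3, 1, 4.5, 4.5, 2) / 5)  # average ranks for ties

  # distinct values: a permutation of (1:n)/n
  ds2 <- make_wells(data.frame(M = rnorm(17)), colony_count = rep(0, 17))
  expect_setequal(normalize_replicates(ds2)$M, (1:17) / 17)

  # any monotone transform of one replicate leaves its ranks unchanged
  ds3 <- ds2
  ds3$M <- exp(2 * ds3$M + 1)
  expect_equal(normalize_replicates(ds3)$M, normalize_replicates(ds2)$M)

  # two replicates are ranked independently, then concatenated
  two <- rbind(make_wells(data.frame(M = c(3, 1, 2)), rep(0, 3), "p1"),
               make_wells(data.frame(M = c(10, 30)), rep(0, 2), "p2"))
  expect_equal(normalize_replicates(two)$M, c(3/3, 1/3, 2/3, 1/2, 2/2))

  ds_na <- ds
  ds_na$M[2] <- NA
  expect_error(normalize_replicates(ds_na), "missing")
})

test_that("SMOTE balances classes by convex interpolation only", {
  # canonical imbalance: 5 positives, 200 negatives, 8 markers
  set.seed(202)
  X <- matrix(runif(205 * 8), 205, 8)
  y <- rep(c("positive", "negative"), c(5, 200))
  aug <- smote_augment(X, y, target_ratio = 1, k_neighbors = 5, seed = 17)
  expect_equal(sum(aug$outcomes == "positive"), 200)
  expect_equal(sum(aug$outcomes == "negative"), 200)
  # originals preserved verbatim, majority untouched
  expect_equal(aug$features[1:205, ], unname(X))
  expect_identical(aug$outcomes[1:205], y)

  # every synthetic point is a convex combination of two original positives
  minority <- X[1:5, , drop = FALSE]
  synth <- aug$features[attr(aug, "synthetic"), , drop = FALSE]
  for (s in seq_len(nrow(synth))) {
    found <- FALSE
    for (i in 1:5) for (j in setdiff(1:5, i)) {
      d <- minority[j, ] - minority[i, ]
      u <- (synth[s, ] - minority[i, ]) / d
      if (all(abs(u - u[1]) < 1e-8) && u[1] >= -1e-12 && u[1] <= 1 + 1e-12) {
        found <- TRUE
      }
    }
    expect_true(found, label = sprintf("synthetic row %d", s))
  }

  # balanced input returned unchanged
  bal <- smote_augment(X[1:10, ], rep(c("positive", "negative"), each = 5))
  expect_equal(bal$features, X[1:10, ])

  # one-dimensional minority {0, 1}: synthetics stay inside [0, 1]
  one <- smote_augment(matrix(c(0, 1, 5, 6, 7, 8), ncol = 1),
                       rep(c("a", "b"), c(2, 4)), k_neighbors = 1, seed = 3)
  expect_true(all(one$features[attr(one, "synthetic"), 1] >= 0 &
                    one$features[attr(one, "synthetic"), 1] <= 1))

  expect_error(smote_augment(matrix(1:10, ncol = 1),
                             rep(c("a", "b"), c(1, 9))), "minority")
})

test_that("Wilcoxon marker test: exact enumeration, degenerate and approximate branches", {
  ds <- score_wells(make_wells(data.frame(M = c(4, 5, 6, 1, 2, 3)),
                               colony_count = c(9, 9, 9, 0, 0, 0)))
  expect_equal(wilcoxon_marker_test(ds)$p_value, 0.1)

  same <- score_wells(make_wells(data.frame(M = rep(2, 8)),
                                 colony_count = rep(c(9, 0), 4)))
  expect_equal(wilcoxon_marker_test(same)$p_value, 1)

  # tie-free exact branch agrees with wilcox.test's exact p-value
  set.seed(203)
  for (r in 1:10) {
    x <- rnorm(6); y <- rnorm(7)
    expect_equal(gatefinder:::wilcoxon_exact_p(x, y),
                 stats::wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }

  # exact and normal-approximation branches agree closely at n = 8 + 8
  for (r in 1:10) {
    x <- sample(1:20, 8, replace = TRUE)  # moderate ties
    y <- sample(1:20, 8, replace = TRUE) + r %% 3
    p_exact <- gatefinder:::wilcoxon_exact_p(x, y)
    p_approx <- stats::wilcox.test(x, y, exact = FALSE)$p.value
    expect_lt(abs(p_exact - p_approx), 0.02)
  }

  onesided <- score_wells(make_wells(data.frame(M = rnorm(5)),
                                     colony_count = rep(9, 5)))
  expect_error(wilcoxon_marker_test(onesided), "nonempty")
})

test_that("null markers produce uniform Wilcoxon p-values", {
  set.seed(204)
  p <- replicate(200, {
    ds <- score_wells(make_wells(data.frame(M = rnorm(45)),
                                 colony_count = rep(c(9, 0), c(15, 30))))
    wilcoxon_marker_test(ds)$p_value
  })
  # exact enumeration yields discrete p-values; KS ties warning is expected
  expect_gt(suppressWarnings(stats::ks.test(p, "punif")$p.value), 0.001)
})

test_that("bagging uses a perfectly separating feature at every root", {
  set.seed(205)
  n <- 60
  X <- data.frame(good = c(rnorm(n / 2, 5), rnorm(n / 2, 0)),
                  noise1 = rnorm(n), noise2 = rnorm(n))
  y <- rep(c("positive", "negative"), each = n / 2)
  ens <- fit_bagging(X, y, n_trees = 25, seed = 6)
  prof <- first_occurrence_ranks(ens)
  expect_identical(unname(prof$ranks$good), rep(1L, 25))
  expect_equal(prof$summary$median_rank[prof$summary$marker == "good"], 1)

  # training accuracy on a separable fixture is perfect
  expect_equal(mean(predict(ens, X) == y), 1)

  # reproducible given the seed
  ens2 <- fit_bagging(X, y, n_trees = 25, seed = 6)
  expect_identical(first_occurrence_ranks(ens2)$ranks, prof$ranks)

  expect_error(fit_bagging(X, rep("positive", n)), "single class")
})

test_that("first-occurrence ranks match manual preorder traversal", {
  prof <- first_occurrence_ranks(
    list(hand_tree_abc(), hand_tree_reuse_a(), hand_tree_bc()),
    markers = c("A", "B", "C"))
  # tree 1: A=1 B=2 C=3; tree 2: A=1 only (reuse keeps first occurrence);
  # tree 3: B=1 C=2, A absent
  expect_equal(prof$ranks$A, c(1, 1))
  expect_equal(prof$ranks$B, c(2, 1))
  expect_equal(prof$ranks$C, c(3, 2))
  s <- prof$summary
  expect_equal(s$usage_fraction, c(2, 2, 2) / 3)
  expect_equal(s$median_rank, c(1, 1.5, 2.5))
  expect_equal(s$mean_rank, c(1, 1.5, 2.5))
})

test_that("every tree assigns ranks 1..m to the distinct features it uses", {
  set.seed(206)
  X <- data.frame(matrix(rnorm(80 * 5), 80, 5))
  y <- factor(rep(c("a", "b"), 40))
  ens <- fit_bagging(X, y, n_trees = 30, seed = 7)
  for (k in 1:30) {
    tree <- gatefinder:::.as_tree_table(
      randomForest::getTree(ens$forest, k), ens$markers)
    used <- gatefinder:::.dfs_first_use(tree)
    expect_false(anyDuplicated(used) > 0)
    expect_true(all(used %in% ens$markers))
  }
  # aggregated rank multisets cover each tree exactly once per used marker
  prof <- first_occurrence_ranks(ens)
  per_tree_counts <- table(unlist(prof$ranks))
  expect_equal(unname(per_tree_counts[["1"]]), 30)  # every tree has a root
})

test_that("rank summaries order markers by p-value, profiles breaking ties", {
  mk_prof <- function(medians, usage = rep(1, length(medians))) {
    structure(list(
      ranks = list(), n_trees = 10,
      summary = data.frame(marker = names(medians),
                           median_rank = unname(medians),
                           mean_rank = unname(medians),
                           usage_fraction = usage,
                           stringsAsFactors = FALSE)),
      class = "rank_profile")
  }
  profs <- list(mk_prof(c(A = 1, B = 2, C = 3)),
                mk_prof(c(A = 1, B = 1, C = 2)),
                mk_prof(c(A = 2, B = 1, C = 1)))
  p <- data.frame(marker = c("A", "B", "C"),
                  p_value = c(0.5, 1e-6, 1e-3))
  s <- rank_summary(profs, p)
  # with p-values supplied, ascending p decides the gating order
  expect_identical(s$marker, c("B", "C", "A"))
  expect_equal(s$n_median_rank1, c(2L, 1L, 2L))
  expect_equal(s$mean_median_rank, c(4 / 3, 2, 4 / 3))

  # without p-values the replicate profiles decide: rank-1 wins first
  s2 <- rank_summary(profs)
  expect_identical(s2$marker, c("A", "B", "C"))

  # identical markers tie-break deterministically by name
  dup <- list(mk_prof(c(X = 1, Y = 1)))
  expect_identical(rank_summary(dup)$marker, c("X", "Y"))
})
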