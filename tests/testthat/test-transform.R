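test_that("p = 1 with zero ridge matches the closed-form solution", {
  orig <- matrix(c(1, 2, 3, 4, 5), ncol = 1)
  targ <- matrix(7, 3, 1)
  tm <- fit_tm(orig, targ, ridge = 0)
  # constant response: minimum-norm solution reproduces the target mean
  expect_equal(apply_tm(tm, 3), 7, tolerance = 1e-10)
  expect_equal(apply_tm(tm, colMeans(orig)), 7, tolerance = 1e-10)
})

test_that("the fitted TM reproduces the target-state mean", {
  set.seed(40)
  orig <- matrix(rpois(15 * 8, 20), 15, 8)
  targ <- matrix(rpois(20 * 8, 35), 20, 8)
  for (ridge in c(0, 1)) {
    tm <- fit_tm(orig, targ, ridge = ridge)
    expect_equal(apply_tm(tm, colMeans(orig)), colMeans(targ),
                 tolerance = 1e-8)
  }
})

test_that("ridge makes the underdetermined 200-bin system solvable", {
  set.seed(41)
  orig <- matrix(rpois(15 * 200, 5), 15, 200)
  targ <- matrix(rpois(15 * 200, 8), 15, 200)
  tm <- fit_tm(orig, targ, ridge = 1)
  expect_true(all(is.finite(tm$weights)))
  expect_true(all(is.finite(tm$intercept)))
  expect_equal(dim(tm$weights), c(200L, 200L))
  out <- apply_tm(tm, orig[1, ])
  expect_true(all(out >= 0))
})

test_that("apply_tm is affine before clamping and clamps after", {
  set.seed(42)
  tm <- fit_tm(matrix(rnorm(10 * 4), 10, 4), matrix(rnorm(10 * 4), 10, 4),
               ridge = 0.5)
  tm$weights <- matrix(rnorm(16), 4, 4)  # arbitrary affine map
  tm$intercept <- rnorm(4)
  x <- rpois(4, 10); y <- rpois(4, 10); al <- 0.3
  lhs <- apply_tm(tm, al * x + (1 - al) * y, clamp = FALSE)
  rhs <- al * apply_tm(tm, x, clamp = FALSE) +
    (1 - al) * apply_tm(tm, y, clamp = FALSE)
  expect_equal(lhs, rhs, tolerance = 1e-10)
  tm$intercept <- rep(-1e6, 4)
  expect_true(all(apply_tm(tm, x) == 0))
})

test_that("identity and constant TMs behave as documented", {
  tm <- structure(
    list(weights = diag(3), intercept = rep(0, 3),
         original_state = "A", target_state = "A", ridge = 0,
         has_intercept = TRUE, n_train = 2, target_mean = rep(0, 3)),
    class = "transform_matrix")
  x <- c(4, 2, 1)
  expect_equal(apply_tm(tm, x), x)
  tm$weights <- matrix(0, 3, 3)
  tm$intercept <- c(9, 3, 1)
  expect_equal(apply_tm(tm, rpois(3, 5)), c(9, 3, 1))
  expect_error(apply_tm(tm, 1:4), "dimension")
})

test_that("two-level transition on well-separated states is complete", {
  coh <- generate_degree_cohort(four_state_profiles(c(1.2, 1.8, 2.4, 3.0)),
                                20, seed = 43)
  ft <- feature_table(coh, 200)
  sel <- chi2_select(ft$x, ft$labels)
  xs <- ft$x[, sel$selected, drop = FALSE]
  tree <- build_tree(xs, ft$labels)
  fts <- structure(list(x = xs, labels = ft$labels, sample_id = ft$sample_id),
                   class = "feature_table")
  res <- transition_protocol(fts, from = "LS", to = "LW", tree,
                             train_n = 15, seed = 43)
  expect_equal(res$accuracy, 1.0)
  expect_length(res$predicted, 5)
  expect_equal(res$scheme, "two_level")
})

test_that("identity transition does not degrade same-state classification", {
  coh <- generate_degree_cohort(four_state_profiles(c(1.2, 1.8, 2.4, 3.0)),
                                20, seed = 44)
  ft <- feature_table(coh, 200)
  sel <- chi2_select(ft$x, ft$labels)
  xs <- ft$x[, sel$selected, drop = FALSE]
  tree <- build_tree(xs, ft$labels)
  fts <- structure(list(x = xs, labels = ft$labels, sample_id = ft$sample_id),
                   class = "feature_table")
  res <- transition_protocol(fts, from = "LS", to = "LS", tree,
                             train_n = 15, seed = 44)
  test_idx <- attr(res, "test")
  baseline <- mean(predict(tree, xs[test_idx, , drop = FALSE])$class == "LS")
  expect_gte(res$accuracy, baseline)
})

test_that("transition toward an untrained state is an error", {
  xs <- matrix(rpois(40 * 5, 10), 40, 5,
               dimnames = list(NULL, paste0("bin_", 1:5)))
  labs <- factor(rep(c("A", "B"), each = 20))
  tree <- build_tree(xs, labs)
  tm <- fit_tm(xs[1:15, ], xs[21:35, ], original_state = "A",
               target_state = "Z")
  expect_error(evaluate_transition(tm, xs[16:20, ], tree), "not trained")
})

test_that("four-level circuit validates the cycle and reports per-hop accuracy", {
  coh <- generate_degree_cohort(four_state_profiles(c(1.2, 1.8, 2.4, 3.0)),
                                20, seed = 45)
  ft <- feature_table(coh, 200)
  sel <- chi2_select(ft$x, ft$labels)
  xs <- ft$x[, sel$selected, drop = FALSE]
  tree <- build_tree(xs, ft$labels)
  cycle <- c("HS", "HW", "LS", "LW")
  tms <- lapply(seq_along(cycle), function(i) {
    from <- cycle[i]
    to <- cycle[if (i == 4) 1 else i + 1]
    fit_tm(xs[ft$labels == from, ][1:15, ], xs[ft$labels == to, , drop = FALSE],
           original_state = from, target_state = to)
  })
  start <- xs[ft$labels == "HS", ][16:20, , drop = FALSE]
  circ <- four_level_circuit(tms, start, tree)
  acc <- attr(circ, "accuracy")
  expect_length(acc, 4)
  expect_true(all(acc >= 0 & acc <= 1))
  expect_gte(acc[1], acc[4])  # error never improves around the circle
  expect_equal(names(circ)[1], "HS->HW")
  # mismatched ordering is rejected
  expect_error(four_level_circuit(tms[c(1, 3, 2, 4)], start, tree),
               "cycle mismatch")
})

test_that("TM CSV/JSON export writes weights, intercept and metadata", {
  set.seed(46)
  tm <- fit_tm(matrix(rpois(10 * 3, 5), 10, 3), matrix(rpois(10 * 3, 9), 10, 3),
               ridge = 1, original_state = "LS", target_state = "LW")
  csv <- tempfile(fileext = ".csv")
  meta <- tempfile(fileext = ".json")
  write_tm(tm, csv, meta)
  m <- as.matrix(utils::read.csv(csv))
  expect_equal(dim(m), c(3L, 4L))
  expect_equal(unname(m[, 4]), tm$intercept, tolerance = 1e-6)
  info <- jsonlite::read_json(meta)
  expect_equal(info$original_state, "LS")
  expect_equal(info$ridge, 1)
  unlink(c(csv, meta))
})
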