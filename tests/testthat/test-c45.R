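test_that("entropy matches hand evaluations and its bounds", {
  expect_equal(entropy(c(A = 5, B = 5)), 1.0)
  expect_equal(entropy(c(A = 10, B = 0)), 0.0)
  expect_equal(entropy(c(A = 1, B = 3)), 0.8112781, tolerance = 1e-6)
  expect_error(entropy(c(0, 0)), "positive")
  expect_error(entropy(c(-1, 2)), "non-negative")
  set.seed(30)
  for (i in 1:20) {
    k <- sample(2:5, 1)
    cc <- rpois(k, 4) + 1
    h <- entropy(cc)
    expect_gte(h, 0)
    expect_lte(h, log2(k) + 1e-12)
  }
})

test_that("information gain matches the printed-formula evaluations", {
  expect_equal(information_gain(c(2, 2), list(c(2, 0), c(0, 2))), 1.0)
  expect_equal(information_gain(c(4, 4), list(c(2, 2), c(2, 2))), 0.0)
  expect_equal(information_gain(c(3, 3), list(c(3, 1), c(0, 2))), 0.4591479,
               tolerance = 1e-6)
  expect_error(information_gain(c(3, 3), list(c(2, 1), c(0, 2))), "partition")
})

test_that("gain ratio normalizes by split information", {
  expect_equal(gain_ratio(1.0, c(5, 5)), 1.0)
  expect_equal(gain_ratio(0.4591479, c(4, 2)), 0.5, tolerance = 1e-6)
  expect_true(is.na(gain_ratio(0.3, c(6, 0))))
  # same gain, more unbalanced split -> smaller split info -> larger ratio
  expect_gt(gain_ratio(0.5, c(9, 1)), gain_ratio(0.5, c(5, 5)))
})

test_that("best_continuous_split finds the separating midpoint", {
  s <- best_continuous_split(c(1, 2, 3, 4), factor(c("A", "A", "B", "B")))
  expect_equal(s$threshold, 2.5)
  expect_equal(s$gain, 1.0)
  expect_null(best_continuous_split(rep(2, 6), factor(rep(c("A", "B"), 3))))
  s2 <- best_continuous_split(c(1, 5), factor(c("A", "B")))
  expect_equal(s2$threshold, 3)
})

test_that("best_continuous_split matches the exhaustive-scan oracle", {
  set.seed(31)
  for (i in 1:60) {
    n <- sample(4:20, 1)
    vals <- sample(1:8, n, replace = TRUE) + round(runif(n), 2)
    labs <- factor(sample(letters[1:sample(2:3, 1)], n, replace = TRUE))
    if (nlevels(droplevels(labs)) < 2) next
    got <- best_continuous_split(vals, labs)
    want <- oracle_best_split(vals, labs)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$threshold, want$threshold)
      expect_equal(got$gain, want$gain, tolerance = 1e-10)
      expect_equal(got$gain_ratio, want$gain_ratio, tolerance = 1e-10)
    }
  }
})

test_that("build_tree handles separable and degenerate inputs", {
  x <- matrix(c(1, 2, 3, 10, 11, 12), ncol = 1, dimnames = list(NULL, "f"))
  y <- factor(c("A", "A", "A", "B", "B", "B"))
  tree <- build_tree(x, y)
  expect_equal(tree$root$type, "split")
  expect_equal(tree$root$threshold, 6.5)
  expect_equal(as.character(predict(tree, x)$class), as.character(y))
  # all one class -> single leaf
  leafy <- build_tree(x, factor(rep("A", 6)))
  expect_equal(leafy$root$type, "leaf")
  expect_equal(leafy$root$class, "A")
})

test_that("pruning never increases the node count", {
  set.seed(32)
  for (i in 1:5) {
    x <- matrix(rnorm(60 * 3), 60, 3, dimnames = list(NULL, c("a", "b", "c")))
    y <- factor(sample(c("u", "v"), 60, TRUE))
    raw <- build_tree(x, y, prune_confidence = NULL)
    pruned <- build_tree(x, y, prune_confidence = 0.25)
    expect_lte(powerstate:::n_nodes(pruned$root),
               powerstate:::n_nodes(raw$root))
  }
})

test_that("the root split lands on a strongly state-separating bin", {
  # two 'high-dose' states vs two 'low-dose' states, mirroring the
  # iso >= 2.0 root of the reference tree
  coh <- generate_degree_cohort(four_state_profiles(), 20, seed = 33)
  ft <- feature_table(coh, 200)
  sel <- chi2_select(ft$x, ft$labels)
  xs <- ft$x[, sel$selected, drop = FALSE]
  tree <- build_tree(xs, ft$labels)
  expect_equal(tree$root$type, "split")
  iso <- factor(ifelse(ft$labels %in% c("HS", "HW"), "high", "low"))
  smd <- between_state_smd(xs, iso)
  # root attribute among the top quartile of iso-separating bins
  expect_gte(smd[[tree$root$attribute]],
             stats::quantile(smd, 0.75, names = FALSE))
})

test_that("prediction routes boundaries left and exposes leaf probabilities", {
  x <- matrix(c(1, 2, 3, 10, 11, 12), ncol = 1, dimnames = list(NULL, "f"))
  y <- factor(c("A", "A", "A", "B", "B", "B"))
  tree <- build_tree(x, y)
  thr <- tree$root$threshold
  at_boundary <- matrix(thr, 1, 1, dimnames = list(NULL, "f"))
  expect_equal(as.character(predict(tree, at_boundary)$class), "A")
  expect_equal(unname(predict(tree, x)$prob[1, ]), c(1, 0))
  # single-leaf tree returns the class prior
  leafy <- build_tree(x, factor(c("A", "A", "A", "A", "B", "B")),
                      min_leaf = 10)
  expect_equal(leafy$root$type, "leaf")
  expect_equal(unname(predict(leafy, x)$prob[1, ]), c(4, 2) / 6)
  # missing attribute is an error
  bad <- matrix(1, 1, 1, dimnames = list(NULL, "other"))
  expect_error(predict(tree, bad), "missing tested attribute")
})

test_that("cross-validation is deterministic and perfect when separable", {
  set.seed(34)
  x <- matrix(c(rnorm(30, 0), rnorm(30, 20)), ncol = 1,
              dimnames = list(NULL, "f"))
  y <- factor(rep(c("A", "B"), each = 30))
  cv1 <- tenfold_cv(x, y, seed = 9)
  cv2 <- tenfold_cv(x, y, seed = 9)
  expect_identical(cv1$fold, cv2$fold)
  expect_identical(cv1$roc, cv2$roc)
  expect_equal(cv1$roc, 1.0)
  expect_equal(cv1$accuracy, 1.0)
  cv3 <- tenfold_cv(x, y, seed = 10)
  expect_false(identical(cv1$fold, cv3$fold))
})

test_that("folds are stratified by class", {
  x <- matrix(rnorm(40), ncol = 1, dimnames = list(NULL, "f"))
  y <- factor(rep(c("A", "B"), each = 20))
  cv <- tenfold_cv(x, y, seed = 1)
  for (f in 1:10) {
    expect_equal(sum(cv$fold == f & y == "A"), 2)
    expect_equal(sum(cv$fold == f & y == "B"), 2)
  }
  expect_warning(tenfold_cv(rbind(x, x[1, , drop = FALSE]),
                            factor(c(as.character(y), "C")), seed = 1),
                 "fewer than")
})

test_that("structureless data scores near chance ROC", {
  set.seed(35)
  rocs <- vapply(1:50, function(i) {
    x <- matrix(rnorm(40 * 3), 40, 3, dimnames = list(NULL, c("a", "b", "c")))
    y <- factor(sample(rep(c("u", "v"), each = 20)))
    tenfold_cv(x, y, seed = i)$roc
  }, numeric(1))
  expect_lt(abs(mean(rocs) - 0.5), 0.1)
})

test_that("tree JSON and DOT exports are well formed", {
  x <- matrix(c(1, 2, 3, 10, 11, 12), ncol = 1, dimnames = list(NULL, "f"))
  tree <- build_tree(x, factor(c("A", "A", "A", "B", "B", "B")))
  jpath <- tempfile(fileext = ".json")
  dpath <- tempfile(fileext = ".dot")
  write_tree_json(tree, jpath)
  node <- jsonlite::read_json(jpath)
  expect_equal(node$type, "split")
  expect_equal(node$left$type, "leaf")
  write_tree_dot(tree, dpath)
  dot <- readLines(dpath)
  expect_true(grepl("^digraph", dot[1]))
  expect_true(any(grepl("f <= 6.5", dot, fixed = TRUE)))
  unlink(c(jpath, dpath))
})
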