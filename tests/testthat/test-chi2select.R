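test_that("chi2_statistic matches hand evaluations of the formula", {
  expect_equal(chi2_statistic(rbind(c(5, 5), c(5, 5))), 0)
  expect_equal(chi2_statistic(rbind(c(10, 0), c(0, 10))), 20)
  expect_equal(chi2_statistic(rbind(c(8, 2), c(2, 8))), 7.2)
  expect_error(chi2_statistic(rbind(c(-1, 2), c(3, 4))), "non-negative")
  expect_error(chi2_statistic(matrix(0, 2, 2)), "positive")
})

test_that("chi2_statistic agrees with the direct-formula oracle on random tables", {
  set.seed(20)
  for (i in 1:100) {
    nr <- sample(2:5, 1)
    nc <- sample(2:4, 1)
    tab <- matrix(rpois(nr * nc, 6), nrow = nr)
    if (sum(tab) == 0) tab[1, 1] <- 1
    expect_equal(chi2_statistic(tab), oracle_chi2(tab), tolerance = 1e-12)
  }
})

test_that("chi2_statistic is zero iff observed equals expected", {
  # outer product of margins -> exact independence
  tab <- outer(c(2, 3, 5), c(1, 4)) / 10
  expect_equal(chi2_statistic(tab), 0)
  tab[1, 1] <- tab[1, 1] + 0.5
  expect_gt(chi2_statistic(tab), 0)
})

test_that("chimerge collapses a constant attribute and splits a separator", {
  expect_length(chimerge_pass(rep(3, 8), rep(c("a", "b"), 4), 0.05), 0)
  # 6 samples perfectly separated at value 3.5: one cutpoint survives
  vals <- c(1, 2, 3, 4, 5, 6)
  labs <- c("a", "a", "a", "b", "b", "b")
  cuts <- chimerge_pass(vals, labs, sig_level = 0.05)
  expect_equal(cuts, 3.5)
})

test_that("a significance level near 1 freezes all intervals", {
  vals <- c(1, 2, 3, 4, 5, 6)
  labs <- c("a", "b", "a", "b", "a", "b")
  cuts <- chimerge_pass(vals, labs, sig_level = 0.999)
  expect_equal(cuts, c(1.5, 2.5, 3.5, 4.5, 5.5))
})

test_that("inconsistency_rate counts duplicate patterns with split classes", {
  x <- matrix(c(1, 2, 3, 4), ncol = 1)
  expect_equal(inconsistency_rate(x, c("a", "a", "b", "b"), list(numeric())), 0.5)
  expect_equal(inconsistency_rate(x, c("a", "a", "b", "b"), list(2.5)), 0)
  # two identical patterns, different classes, n = 2
  x2 <- matrix(c(1, 1), ncol = 1)
  expect_equal(inconsistency_rate(x2, c("a", "b"), list(numeric())), 0.5)
  # 10 samples, one 3-way collision (2 majority + 1 minority) -> 0.1
  x3 <- matrix(c(5, 5, 5, 1, 2, 3, 4, 6, 7, 8), ncol = 1)
  labs <- c("a", "a", "b", rep("a", 7))
  expect_equal(inconsistency_rate(x3, labs, list(c(0.5 + 1:7))), 0.1)
})

test_that("all-distinct discretized patterns are consistent", {
  set.seed(21)
  x <- matrix(rnorm(20), ncol = 2)
  cuts <- lapply(1:2, function(j) sort(unique(x[, j]))[-10] + 1e-9)
  expect_equal(inconsistency_rate(x, rep(c("a", "b"), 5), cuts), 0)
})

test_that("chi2_select keeps the informative attribute and drops pure noise", {
  set.seed(22)
  n <- 40
  labs <- rep(c("a", "b"), each = n / 2)
  informative <- ifelse(labs == "a", 0, 5) + rnorm(n, sd = 0.3)
  noise <- rnorm(n)
  x <- cbind(informative = informative, noise = noise)
  res <- chi2_select(x, labs, delta = 0.05)
  expect_true("informative" %in% res$selected)
  expect_false("noise" %in% res$selected)
  expect_length(res$cutpoints$noise, 0)
  expect_gte(length(res$cutpoints$informative), 1)
})

test_that("selection invariants hold: delta respected, selected <=> >=2 intervals", {
  coh <- generate_degree_cohort(four_state_profiles(), 10, seed = 23)
  ft <- feature_table(coh, 60)
  for (delta in c(0, 0.05)) {
    res <- chi2_select(ft$x, ft$labels, delta = delta)
    expect_lte(res$inconsistency, delta)
    expect_lte(inconsistency_rate(ft$x, ft$labels, res$cutpoints), delta)
    n_int <- vapply(res$cutpoints, length, integer(1)) + 1L
    expect_setequal(res$selected, colnames(ft$x)[n_int >= 2L])
  }
})

test_that("a single class-determining attribute is retained", {
  labs <- rep(c("a", "b", "c"), each = 4)
  x <- matrix(rep(c(1, 5, 9), each = 4) + rep(c(0, 0.1, 0.2, 0.3), 3), ncol = 1)
  colnames(x) <- "det"
  res <- chi2_select(x, labs)
  expect_equal(res$selected, "det")
  expect_gte(length(res$cutpoints$det), 2)
  expect_equal(res$inconsistency, 0)
})

test_that("merging an attribute further never lowers inconsistency", {
  set.seed(24)
  x <- matrix(sample(1:6, 30, TRUE), ncol = 1)
  labs <- sample(c("a", "b"), 30, TRUE)
  full <- sort(unique(x[, 1]))
  cuts_fine <- list((full[-length(full)] + full[-1]) / 2)
  rate_prev <- inconsistency_rate(x, labs, cuts_fine)
  # progressively remove cutpoints (merge adjacent intervals)
  cuts <- cuts_fine[[1]]
  while (length(cuts)) {
    cuts <- cuts[-1]
    rate <- inconsistency_rate(x, labs, list(cuts))
    expect_gte(rate, rate_prev)
    rate_prev <- rate
  }
})

test_that("config validation rejects bad ladders and tolerances", {
  x <- matrix(rnorm(20), ncol = 2)
  labs <- rep(c("a", "b"), 5)
  expect_error(chi2_select(x, labs, sig_ladder = numeric()), "ladder")
  expect_error(chi2_select(x, labs, sig_ladder = c(0.1, 0.5)), "decreasing")
  expect_error(chi2_select(x, labs, delta = 1), "delta")
  expect_error(chi2_select(x, rep("a", 10)), "classes")
})

test_that("selected bins separate states at least as well as the median bin", {
  coh <- generate_degree_cohort(four_state_profiles(), 20, seed = 25)
  ft <- feature_table(coh, 200)
  res <- chi2_select(ft$x, ft$labels)
  smd <- between_state_smd(ft$x, ft$labels)
  expect_gte(stats::median(smd[res$selected]), stats::median(smd))
})

test_that("feature tables are rectangular with zero-filled missing bins", {
  coh <- generate_degree_cohort(four_state_profiles(), 3, seed = 26)
  ft <- feature_table(coh, 200)
  expect_equal(dim(ft$x), c(12L, 200L))
  s <- coh$samples[coh$samples$sample_id == ft$sample_id[1], ]
  expect_equal(unname(ft$x[1, s$degree]), as.numeric(s$count))
  absent <- setdiff(1:200, s$degree)
  expect_true(all(ft$x[1, absent] == 0))
  # CSV round-trip
  path <- tempfile(fileext = ".csv")
  write_feature_csv(ft, path)
  back <- read_feature_csv(path)
  expect_equal(unname(back$x), unname(ft$x))
  expect_equal(back$labels, ft$labels)
  unlink(path)
})
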