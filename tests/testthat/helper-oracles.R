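# Independent oracles used across the suite. These deliberately avoid the
# package's fast paths: plain double loops, stats::cor, and adjacency-matrix
# algebra.

# All-pairs degree oracle via stats::cor on every voxel pair.
oracle_degrees <- function(values, threshold = 0.7) {
  v <- nrow(values)
  deg <- integer(v)
  for (i in seq_len(v)) {
    for (j in seq_len(v)) {
      if (i == j) next
      r <- suppressWarnings(stats::cor(values[i, ], values[j, ]))
      if (!is.na(r) && r > threshold) deg[i] <- deg[i] + 1L
    }
  }
  deg
}

# Direct cell-by-cell evaluation of X^2 = sum (f0 - fe)^2 / fe.
oracle_chi2 <- function(observed) {
  total <- sum(observed)
  rs <- rowSums(observed)
  cs <- colSums(observed)
  s <- 0
  for (i in seq_len(nrow(observed))) {
    for (j in seq_len(ncol(observed))) {
      fe <- rs[i] * cs[j] / total
      if (fe > 0) s <- s + (observed[i, j] - fe)^2 / fe
    }
  }
  s
}

oracle_entropy <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

# Exhaustive scan over every midpoint threshold, replicating the C4.5
# mean-gain guard and the smallest-threshold tie-break.
oracle_best_split <- function(values, labels) {
  labels <- factor(labels)
  sv <- sort(unique(values))
  if (length(sv) < 2L) return(NULL)
  thr <- (sv[-length(sv)] + sv[-1]) / 2
  parent <- table(labels)
  cand <- lapply(thr, function(t) {
    l <- table(labels[values <= t])
    r <- table(labels[values > t])
    nl <- sum(l); nr <- sum(r)
    n <- nl + nr
    gain <- oracle_entropy(parent) -
      nl / n * oracle_entropy(l) - nr / n * oracle_entropy(r)
    si <- oracle_entropy(c(nl, nr))
    list(threshold = t, gain = max(0, gain), split_info = si,
         gain_ratio = if (si > 0) max(0, gain) / si else NA_real_)
  })
  gains <- vapply(cand, `[[`, 0, "gain")
  ok <- which(!is.na(vapply(cand, `[[`, 0, "gain_ratio")) &
                gains >= mean(gains) - 1e-12)
  if (!length(ok)) return(NULL)
  ratios <- vapply(cand[ok], `[[`, 0, "gain_ratio")
  cand[[ok[which(ratios >= max(ratios) - 1e-10)[1]]]]
}

# BFS distances by repeated adjacency-matrix products.
oracle_path_stats <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  m <- adj
  for (len in seq_len(n)) {
    newly <- (m > 0) & !is.finite(d)
    d[newly] <- len
    if (!any(newly)) break
    m <- m %*% adj
  }
  off <- d[row(d) != col(d)]
  fin <- off[is.finite(off)]
  list(average_L = mean(fin), max_L = max(fin))
}

# Local clustering via diag(A^3) triangle counts.
oracle_clustering <- function(adj) {
  k <- rowSums(adj)
  tri <- diag(adj %*% adj %*% adj)
  ci <- ifelse(k >= 2, tri / (k * (k - 1)), 0)
  list(local = ci,
       average = if (any(k >= 1)) mean(ci[k >= 1]) else 0)
}

# Noisy log-log power-law samples used by the fitting tests.
gen_powerlaw_dist <- function(seed, n_bins = 200, gamma = 1.9, amplitude = 1000,
                              sigma = 0.1) {
  set.seed(seed)
  k <- seq_len(n_bins)
  data.frame(degree = k,
             count = amplitude * k^(-gamma) * exp(stats::rnorm(n_bins, 0, sigma)))
}

gen_broken_dist <- function(seed, n_bins = 200, gamma_low = 1.2,
                            gamma_high = 3.0, breakpoint = 20,
                            amplitude = 5000, sigma = 0.1) {
  set.seed(seed)
  k <- seq_len(n_bins)
  mu <- ifelse(k <= breakpoint,
               amplitude * k^(-gamma_low),
               amplitude * breakpoint^(gamma_high - gamma_low) * k^(-gamma_high))
  data.frame(degree = k, count = mu * exp(stats::rnorm(n_bins, 0, sigma)))
}

# Four-state cohorts matching the reference study design: 20 samples/state,
# 200 degree bins, amplitude 500, Poisson count noise.
four_state_profiles <- function(exponents = c(1.6, 1.9, 2.2, 2.5),
                                states = c("HS", "HW", "LS", "LW"),
                                amplitude = 500, max_degree = 200L) {
  unname(Map(function(nm, g) state_profile(nm, g, amplitude, max_degree),
             states, exponents))
}

# Standardized between-state separation of each feature-table column:
# sd of state means over pooled within-state sd.
between_state_smd <- function(x, labels) {
  apply(x, 2, function(col) {
    mu <- tapply(col, labels, mean)
    wsd <- sqrt(mean(tapply(col, labels, stats::var), na.rm = TRUE))
    if (!is.finite(wsd) || wsd == 0) return(0)
    stats::sd(mu) / wsd
  })
}
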