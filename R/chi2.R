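#' Chi-squared statistic of a contingency table
#'
#' \eqn{X^2 = \sum (f_0 - f_e)^2 / f_e} over cells, where \eqn{f_0} is the
#' observed count and \eqn{f_e = \mathrm{row\ total} \times \mathrm{column\
#' total} / \mathrm{grand\ total}} is the expected count under independence.
#' Cells with \eqn{f_e = 0} contribute 0 (an empty row or column carries no
#' evidence). No continuity correction is applied — this is the raw statistic
#' driving interval merging.
#'
#' @param observed Non-negative numeric matrix (intervals x classes) with a
#'   positive grand total.
#' @return Non-negative scalar; 0 iff observed equals expected in every cell.
#' @export
#' @examples
#' chi2_statistic(rbind(c(10, 0), c(0, 10)))  # 20
chi2_statistic <- function(observed) {
  observed <- as.matrix(observed)
  if (any(observed < 0)) stop("counts must be non-negative", call. = FALSE)
  total <- sum(observed)
  if (total <= 0) stop("table total must be positive", call. = FALSE)
  fe <- outer(rowSums(observed), colSums(observed)) / total
  ok <- fe > 0
  sum((observed[ok] - fe[ok])^2 / fe[ok])
}

# chi2_statistic specialized to a 2-row table (an adjacent interval pair);
# avoids matrix/outer overhead inside the merge loop. Agreement with the
# general form is covered by tests.
pair_chi2 <- function(a, b) {
  cs <- a + b
  total <- sum(cs)
  ra <- sum(a); rb <- sum(b)
  fea <- ra * cs / total
  feb <- rb * cs / total
  s <- 0
  ok <- fea > 0
  if (any(ok)) s <- s + sum((a[ok] - fea[ok])^2 / fea[ok])
  ok <- feb > 0
  if (any(ok)) s <- s + sum((b[ok] - feb[ok])^2 / feb[ok])
  s
}

# Class-count matrix (distinct sorted values x classes) for one attribute.
value_class_counts <- function(values, labels) {
  vals <- sort(unique(values))
  counts <- table(factor(values, levels = vals), labels)
  list(values = vals, counts = matrix(as.numeric(counts), nrow = length(vals),
                                      dimnames = NULL))
}

#' One ChiMerge pass over a numeric attribute
#'
#' Initializes one interval per distinct attribute value, then repeatedly
#' merges the adjacent interval pair with the lowest \eqn{X^2} while that
#' statistic stays below the chi-squared critical value at the given
#' significance level with (number of classes - 1) degrees of freedom. Ties
#' in the lowest pair go to the leftmost pair. Returns the strictly
#' increasing cutpoints (midpoints between the boundary values of the
#' surviving adjacent intervals); an attribute merged to one interval yields
#' no cutpoints.
#'
#' @param values Numeric attribute values, one per sample.
#' @param labels Class labels (factor or character), one per sample.
#' @param sig_level Significance level in (0, 1). Smaller values raise the
#'   critical value and merge more aggressively; as \code{sig_level} tends to
#'   1 the critical value tends to 0 and nothing merges.
#' @return Numeric vector of cutpoints (possibly empty).
#' @export
chimerge_pass <- function(values, labels, sig_level) {
  if (length(values) != length(labels) || !length(values)) {
    stop("'values' and 'labels' must be non-empty and equal length", call. = FALSE)
  }
  if (!is.numeric(sig_level) || sig_level <= 0 || sig_level >= 1) {
    stop("'sig_level' must lie in (0, 1)", call. = FALSE)
  }
  labels <- factor(labels)
  df <- max(1L, nlevels(labels) - 1L)
  crit <- stats::qchisq(1 - sig_level, df = df)
  vc <- value_class_counts(values, labels)
  counts <- vc$counts
  lo <- vc$values  # first value of each interval
  hi <- vc$values  # last value of each interval

  if (nrow(counts) > 1L) {
    m <- nrow(counts)
    stat <- vapply(seq_len(m - 1L), function(i) {
      pair_chi2(counts[i, ], counts[i + 1L, ])
    }, numeric(1))
    while (m > 1L) {
      i <- which.min(stat)  # leftmost minimum
      if (stat[i] >= crit) break
      counts[i, ] <- counts[i, ] + counts[i + 1L, ]
      counts <- counts[-(i + 1L), , drop = FALSE]
      hi[i] <- hi[i + 1L]
      lo <- lo[-(i + 1L)]
      hi <- hi[-(i + 1L)]
      stat <- stat[-i]
      m <- m - 1L
      # refresh the statistics of the pairs touching the merged interval
      if (i > 1L) stat[i - 1L] <- pair_chi2(counts[i - 1L, ], counts[i, ])
      if (i < m) stat[i] <- pair_chi2(counts[i, ], counts[i + 1L, ])
    }
  }
  if (length(lo) < 2L) return(numeric())
  (hi[-length(hi)] + lo[-1L]) / 2
}

# Discretized pattern codes for a sample x attribute matrix under a cutpoint
# list; interval code = number of cutpoints at or below the value + 1.
discretize_matrix <- function(x, cutpoints) {
  codes <- vapply(seq_len(ncol(x)), function(j) {
    findInterval(x[, j], cutpoints[[j]]) + 1L
  }, integer(nrow(x)))
  if (is.null(dim(codes))) codes <- matrix(codes, nrow = nrow(x))
  codes
}

#' Inconsistency rate of a discretized feature table
#'
#' After discretizing every attribute by its cutpoints, samples with the same
#' discretized pattern but different classes are inconsistent: each pattern
#' contributes its count minus its majority-class count, and the rate is the
#' total over patterns divided by the number of samples.
#'
#' @param x Numeric sample x attribute matrix.
#' @param labels Class labels, one per sample.
#' @param cutpoints List of numeric cutpoint vectors, one per attribute.
#' @return Rate in \code{[0, 1]}.
#' @export
inconsistency_rate <- function(x, labels, cutpoints) {
  x <- as.matrix(x)
  stopifnot(length(cutpoints) == ncol(x), length(labels) == nrow(x))
  if (!nrow(x)) return(0)
  codes <- discretize_matrix(x, cutpoints)
  pattern <- do.call(paste, c(as.data.frame(codes), sep = "\r"))
  bad <- vapply(split(as.character(labels), pattern), function(cls) {
    length(cls) - max(tabulate(factor(cls)))
  }, numeric(1))
  sum(bad) / nrow(x)
}

#' Two-phase chi2 discretization and feature selection
#'
#' Phase 1 walks down a ladder of decreasing significance levels, at each
#' level re-merging every attribute from scratch with
#' \code{\link{chimerge_pass}}, and stops before the first level whose merged
#' table violates the inconsistency tolerance \code{delta}; the last
#' admissible level is \code{sig_level0}. Phase 2 refines per attribute:
#' starting from the Phase-1 state each attribute takes turns attempting the
#' next (stricter) ladder level, keeping the merge only while the table-wide
#' inconsistency stays within \code{delta}, until no attribute can merge
#' further. Attributes merged to a single interval are not relevant to the
#' class and are dropped — this is the feature selection.
#'
#' @param x Numeric sample x attribute matrix (e.g. degree-bin counts), with
#'   column names.
#' @param labels Class labels, one per sample; at least 2 classes.
#' @param sig_ladder Strictly decreasing significance levels in (0, 1),
#'   starting high.
#' @param delta Inconsistency-rate tolerance in \code{[0, 1)}.
#' @return Object of class \code{"chi2_result"}: list with \code{cutpoints}
#'   (per attribute), \code{selected} (attribute names with >= 2 intervals),
#'   \code{sig_level} (final per-attribute level, NA where never merged),
#'   \code{sig_level0}, \code{inconsistency}.
#' @export
chi2_select <- function(x, labels,
                        sig_ladder = c(0.5, 0.1, 0.05, 0.01, 0.005, 0.001,
                                       1e-4, 1e-5),
                        delta = 0.05) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("attr_", seq_len(ncol(x)))
  labels <- factor(labels)
  if (nlevels(labels) < 2L) stop("need at least 2 classes", call. = FALSE)
  if (!length(sig_ladder) || any(diff(sig_ladder) >= 0) ||
      any(sig_ladder <= 0 | sig_ladder >= 1)) {
    stop("'sig_ladder' must be strictly decreasing within (0, 1)", call. = FALSE)
  }
  if (!is.numeric(delta) || delta < 0 || delta >= 1) {
    stop("'delta' must lie in [0, 1)", call. = FALSE)
  }
  p <- ncol(x)

  # initial state: one interval per distinct value (no merging at all)
  all_cuts <- function(v) {
    sv <- sort(unique(v))
    if (length(sv) < 2L) numeric() else (sv[-length(sv)] + sv[-1L]) / 2
  }
  cuts <- lapply(seq_len(p), function(j) all_cuts(x[, j]))
  level_idx <- rep(0L, p)  # index into sig_ladder of the last applied level

  # Phase 1: global ladder descent
  sig0_idx <- 0L
  for (li in seq_along(sig_ladder)) {
    cand <- lapply(seq_len(p), function(j) {
      chimerge_pass(x[, j], labels, sig_ladder[li])
    })
    if (inconsistency_rate(x, labels, cand) <= delta) {
      cuts <- cand
      level_idx <- rep(li, p)
      sig0_idx <- li
    } else {
      break
    }
  }

  # Phase 2: per-attribute refinement at stricter levels
  active <- rep(sig0_idx < length(sig_ladder), p)
  while (any(active)) {
    progressed <- FALSE
    for (j in which(active)) {
      li <- level_idx[j] + 1L
      if (li > length(sig_ladder)) {
        active[j] <- FALSE
        next
      }
      cand_j <- chimerge_pass(x[, j], labels, sig_ladder[li])
      trial <- cuts
      trial[[j]] <- cand_j
      if (inconsistency_rate(x, labels, trial) <= delta) {
        cuts <- trial
        level_idx[j] <- li
        progressed <- TRUE
      } else {
        active[j] <- FALSE
      }
    }
    if (!progressed) break
  }

  n_intervals <- vapply(cuts, length, integer(1)) + 1L
  selected <- colnames(x)[n_intervals >= 2L]
  names(cuts) <- colnames(x)
  structure(
    list(cutpoints = cuts,
         selected = selected,
         sig_level = ifelse(level_idx > 0L, sig_ladder[pmax(level_idx, 1L)], NA_real_),
         sig_level0 = if (sig0_idx > 0L) sig_ladder[sig0_idx] else NA_real_,
         inconsistency = inconsistency_rate(x, labels, cuts)),
    class = "chi2_result"
  )
}

#' @export
print.chi2_result <- function(x, ...) {
  cat(sprintf("chi2 discretization: %d/%d attributes selected (inconsistency %.4f, sigLevel0 = %s)\n",
              length(x$selected), length(x$cutpoints), x$inconsistency,
              format(x$sig_level0)))
  invisible(x)
}

#' Tabulate a degree cohort into a rectangular feature table
#'
#' One row per sample, one numeric column per degree bin \code{1..n_bins}
#' (named \code{bin_1}, \code{bin_2}, ...), holding the counted number of
#' voxels at that degree. Bins absent from a sample are filled with 0, so
#' ragged distributions become a rectangular table; degrees beyond
#' \code{n_bins} are ignored.
#'
#' @param cohort A \code{degree_cohort} (or its long \code{samples} data
#'   frame).
#' @param n_bins Number of degree bins; default 200.
#' @return List of class \code{"feature_table"} with \code{x} (numeric
#'   matrix, rownames = sample ids), \code{labels} (factor of states) and
#'   \code{sample_id}.
#' @export
feature_table <- function(cohort, n_bins = 200L) {
  samples <- if (inherits(cohort, "degree_cohort")) cohort$samples else as.data.frame(cohort)
  need <- c("sample_id", "state", "degree", "count")
  if (!all(need %in% names(samples))) {
    stop("expected columns sample_id, state, degree, count", call. = FALSE)
  }
  n_bins <- as.integer(n_bins)
  stopifnot(n_bins >= 1L)
  ids <- unique(samples$sample_id)
  x <- matrix(0, nrow = length(ids), ncol = n_bins,
              dimnames = list(ids, paste0("bin_", seq_len(n_bins))))
  keep <- samples$degree >= 1L & samples$degree <= n_bins
  s <- samples[keep, ]
  x[cbind(match(s$sample_id, ids), s$degree)] <- s$count
  labels <- factor(samples$state[match(ids, samples$sample_id)])
  structure(list(x = x, labels = labels, sample_id = ids),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("Feature table: %d samples x %d degree bins, classes: %s\n",
              nrow(x$x), ncol(x$x),
              paste(levels(x$labels), collapse = ", ")))
  invisible(x)
}

#' Write a feature table (with labels) as CSV
#' @param ft A \code{feature_table}.
#' @param path Output path.
#' @export
write_feature_csv <- function(ft, path) {
  stopifnot(inherits(ft, "feature_table"))
  out <- data.frame(sample_id = ft$sample_id, state = as.character(ft$labels),
                    ft$x, check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("sample_id", "state") %in% names(d))) {
    stop("feature CSV must have sample_id and state columns", call. = FALSE)
  }
  bins <- setdiff(names(d), c("sample_id", "state"))
  x <- as.matrix(d[bins])
  rownames(x) <- d$sample_id
  structure(list(x = x, labels = factor(d$state), sample_id = d$sample_id),
            class = "feature_table")
}
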