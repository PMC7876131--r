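#' Fit a state-transition transformation matrix (TM)
#'
#' The TM maps degree-bin vectors of an original state toward the mean
#' degree-bin vector of a target state. Following the construction from the
#' per-bin regression equations: the dependent variable for bin \eqn{j} is
#' the target-state mean count \eqn{\bar y_j} (constant across the
#' \eqn{n} original-state training samples), regressed on the full
#' original-state bin vectors. With far fewer samples than bins the system is
#' underdetermined, so a ridge penalty (default 1.0) makes the solution
#' unique; at \code{ridge = 0} the minimum-norm (pseudo-inverse) solution is
#' used, the ridge-to-zero limit.
#'
#' @param original n x p matrix of original-state bin vectors (rows =
#'   training samples).
#' @param target m x p matrix of target-state bin vectors; the regression
#'   target is \code{colMeans(target)}.
#' @param ridge Ridge penalty \code{>= 0}; default 1.
#' @param intercept Include an (unpenalized) intercept? Default \code{TRUE}.
#' @param original_state,target_state State labels stored for bookkeeping.
#' @return Object of class \code{"transform_matrix"} with \code{weights}
#'   (p x p, target bin x original bin), \code{intercept} (length p),
#'   \code{original_state}, \code{target_state}, \code{ridge},
#'   \code{target_mean}.
#' @export
fit_tm <- function(original, target, ridge = 1, intercept = TRUE,
                   original_state = "original", target_state = "target") {
  original <- as.matrix(original)
  target <- as.matrix(target)
  n <- nrow(original)
  p <- ncol(original)
  if (p < 1L) stop("at least one degree bin is required", call. = FALSE)
  if (n < 2L) stop("need at least 2 original-state samples", call. = FALSE)
  if (ncol(target) != p) stop("bin dimension mismatch between states", call. = FALSE)
  if (!is.numeric(ridge) || ridge < 0) stop("'ridge' must be >= 0", call. = FALSE)

  target_mean <- colMeans(target)
  z <- if (intercept) cbind(original, 1) else original
  q <- ncol(z)
  gram <- crossprod(z)
  if (ridge > 0) {
    pen <- diag(ridge, q)
    if (intercept) pen[q, q] <- 0  # intercept unpenalized
    inv <- solve(gram + pen)
  } else {
    inv <- MASS::ginv(gram)
  }
  # one shared design, p constant responses: solve all bins at once
  y <- matrix(target_mean, nrow = n, ncol = p, byrow = TRUE)
  theta <- inv %*% crossprod(z, y)   # q x p; column j = coefficients for bin j
  weights <- t(theta[seq_len(p), , drop = FALSE])
  b <- if (intercept) as.numeric(theta[q, ]) else numeric(p)
  structure(
    list(weights = weights, intercept = b,
         original_state = original_state, target_state = target_state,
         ridge = ridge, has_intercept = intercept, n_train = n,
         target_mean = target_mean),
    class = "transform_matrix"
  )
}

#' @export
print.transform_matrix <- function(x, ...) {
  cat(sprintf("Transformation matrix %s -> %s: %d x %d weights, ridge = %g, intercept = %s, n_train = %d\n",
              x$original_state, x$target_state, nrow(x$weights),
              ncol(x$weights), x$ridge, x$has_intercept, x$n_train))
  invisible(x)
}

#' Apply a transformation matrix to a degree-bin vector
#'
#' Affine map \code{weights \%*\% x + intercept}; negative outputs are
#' clamped to 0 since bin entries are voxel counts.
#'
#' @param tm A \code{\link{fit_tm}} result.
#' @param distribution Bin vector of length p, or an n x p matrix of vectors
#'   (rows transformed independently).
#' @param clamp Clamp negatives to zero? Default \code{TRUE}.
#' @return Transformed vector or matrix, same shape as the input.
#' @export
apply_tm <- function(tm, distribution, clamp = TRUE) {
  stopifnot(inherits(tm, "transform_matrix"))
  p <- ncol(tm$weights)
  if (is.matrix(distribution)) {
    if (ncol(distribution) != p) stop("dimension mismatch", call. = FALSE)
    out <- distribution %*% t(tm$weights) +
      matrix(tm$intercept, nrow(distribution), p, byrow = TRUE)
    if (clamp) out[out < 0] <- 0
    dimnames(out) <- dimnames(distribution)
    return(out)
  }
  if (length(distribution) != p) stop("dimension mismatch", call. = FALSE)
  out <- as.numeric(tm$weights %*% distribution) + tm$intercept
  if (clamp) out <- pmax(out, 0)
  names(out) <- names(distribution)
  out
}

#' Evaluate a two-level state transition with a decision tree
#'
#' Transforms held-out original-state samples through the TM and classifies
#' the transformed vectors with a tree trained on all states; the transition
#' accuracy is the fraction classified as the target state ("complete
#' transition" = 1).
#'
#' @param tm A \code{transform_matrix}.
#' @param test_samples k x p matrix of held-out original-state bin vectors
#'   (the reference protocol holds out 5 of 20).
#' @param tree A \code{\link{build_tree}} tree trained on all states.
#' @return Object of class \code{"transition_result"} with \code{predicted},
#'   \code{accuracy}, \code{scheme = "two_level"}, \code{target_state}.
#' @export
evaluate_transition <- function(tm, test_samples, tree) {
  stopifnot(inherits(tm, "transform_matrix"), inherits(tree, "c45_tree"))
  if (!(tm$target_state %in% tree$classes)) {
    stop(sprintf("tree was not trained on target state '%s'", tm$target_state),
         call. = FALSE)
  }
  test_samples <- as.matrix(test_samples)
  if (is.null(colnames(test_samples))) {
    colnames(test_samples) <- tree$attributes[seq_len(ncol(test_samples))]
  }
  moved <- apply_tm(tm, test_samples)
  pred <- predict(tree, moved)$class
  structure(
    list(predicted = pred, accuracy = mean(pred == tm$target_state),
         scheme = "two_level",
         original_state = tm$original_state, target_state = tm$target_state),
    class = "transition_result"
  )
}

#' @export
print.transition_result <- function(x, ...) {
  cat(sprintf("%s transition %s -> %s: accuracy %.2f (%d/%d as target)\n",
              x$scheme, x$original_state, x$target_state, x$accuracy,
              sum(x$predicted == x$target_state), length(x$predicted)))
  invisible(x)
}

#' Evaluate the four-level (circle) transition scheme
#'
#' Starting from held-out samples of one state, applies the four TMs of the
#' state cycle in sequence and classifies after every hop; classification
#' error compounds along the circle.
#'
#' @param tms List of 4 \code{transform_matrix} objects forming a cycle: the
#'   target state of each must be the original state of the next, and the
#'   last must return to the first.
#' @param test_samples k x p matrix of held-out samples of
#'   \code{tms[[1]]$original_state}.
#' @param tree Tree trained on all states.
#' @return List of class \code{"circuit_result"}: one
#'   \code{transition_result} per hop (named \code{"A->B"} etc.), with
#'   attribute fields \code{cycle} and \code{accuracy} (per-hop vector).
#' @export
four_level_circuit <- function(tms, test_samples, tree) {
  if (length(tms) != 4L || !all(vapply(tms, inherits, TRUE, "transform_matrix"))) {
    stop("'tms' must be a list of 4 transform_matrix objects", call. = FALSE)
  }
  for (i in seq_len(4L)) {
    nxt <- tms[[if (i == 4L) 1L else i + 1L]]
    if (!identical(tms[[i]]$target_state, nxt$original_state)) {
      stop(sprintf("cycle mismatch: TM %d targets '%s' but TM %d starts from '%s'",
                   i, tms[[i]]$target_state, if (i == 4L) 1L else i + 1L,
                   nxt$original_state), call. = FALSE)
    }
  }
  current <- as.matrix(test_samples)
  if (is.null(colnames(current))) {
    colnames(current) <- tree$attributes[seq_len(ncol(current))]
  }
  hops <- vector("list", 4L)
  acc <- numeric(4L)
  for (i in seq_len(4L)) {
    tm <- tms[[i]]
    if (!(tm$target_state %in% tree$classes)) {
      stop(sprintf("tree was not trained on target state '%s'", tm$target_state),
           call. = FALSE)
    }
    current <- apply_tm(tm, current)
    pred <- predict(tree, current)$class
    hops[[i]] <- structure(
      list(predicted = pred, accuracy = mean(pred == tm$target_state),
           scheme = "four_level",
           original_state = tm$original_state, target_state = tm$target_state),
      class = "transition_result"
    )
    acc[i] <- hops[[i]]$accuracy
    names(hops)[i] <- sprintf("%s->%s", tm$original_state, tm$target_state)
  }
  structure(hops, class = "circuit_result",
            cycle = vapply(tms, `[[`, "", "original_state"), accuracy = acc)
}

#' @export
print.circuit_result <- function(x, ...) {
  cat("Four-level (circle) transition:\n")
  for (h in x) print(h)
  invisible(x)
}

#' Run the standard two-level transition protocol on a feature table
#'
#' Convenience wrapper for the canonical experiment: split the original
#' state's samples into training and held-out sets (by default 15 train and
#' the rest — 5 of 20 — test), fit the TM from the training vectors to the
#' target-state mean, transform the held-out vectors, and classify them with
#' the supplied tree.
#'
#' @param ft A \code{\link{feature_table}} covering all states (columns may
#'   already be restricted to selected bins).
#' @param from,to Original and target state labels.
#' @param tree Tree trained on all states (on the same columns as
#'   \code{ft$x}).
#' @param train_n Training samples from the original state; default 15.
#' @param ridge,intercept Passed to \code{\link{fit_tm}}.
#' @param seed Seed for the train/test split.
#' @return The \code{\link{evaluate_transition}} result, with the fitted
#'   \code{tm} and the split attached as attributes.
#' @export
transition_protocol <- function(ft, from, to, tree, train_n = 15L, ridge = 1,
                                intercept = TRUE, seed = 42L) {
  stopifnot(inherits(ft, "feature_table"))
  idx_from <- which(ft$labels == from)
  idx_to <- which(ft$labels == to)
  if (!length(idx_from) || !length(idx_to)) {
    stop("both states must be present in the feature table", call. = FALSE)
  }
  train_n <- as.integer(train_n)
  if (train_n < 2L || train_n >= length(idx_from)) {
    stop("'train_n' must leave at least one held-out original-state sample",
         call. = FALSE)
  }
  train <- with_seed(seed, sample(idx_from, train_n))
  test <- setdiff(idx_from, train)
  tm <- fit_tm(ft$x[train, , drop = FALSE], ft$x[idx_to, , drop = FALSE],
               ridge = ridge, intercept = intercept,
               original_state = from, target_state = to)
  res <- evaluate_transition(tm, ft$x[test, , drop = FALSE], tree)
  attr(res, "tm") <- tm
  attr(res, "train") <- train
  attr(res, "test") <- test
  res
}

#' Write a transformation matrix as CSV weights plus JSON metadata
#'
#' @param tm A \code{transform_matrix}.
#' @param csv_path Path for the weight matrix CSV (last column holds the
#'   intercept).
#' @param meta_path Optional path for JSON metadata (states, ridge, n_train).
#' @export
write_tm <- function(tm, csv_path, meta_path = NULL) {
  stopifnot(inherits(tm, "transform_matrix"))
  m <- cbind(tm$weights, intercept = tm$intercept)
  utils::write.csv(m, csv_path, row.names = FALSE)
  if (!is.null(meta_path)) {
    jsonlite::write_json(
      list(original_state = tm$original_state, target_state = tm$target_state,
           ridge = tm$ridge, intercept = tm$has_intercept, n_train = tm$n_train),
      meta_path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(csv_path)
}
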