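#' Shannon entropy of a class-count vector
#'
#' \eqn{\mathrm{Entropy}(S) = \sum_i -p_i \log_2 p_i} over classes with
#' \eqn{p_i > 0}; bits (log base 2) throughout the tree code.
#'
#' @param class_counts Non-negative counts with a positive total.
#' @return Value in \code{[0, log2(n_classes)]}.
#' @export
#' @examples
#' entropy(c(A = 5, B = 5))  # 1 bit
entropy <- function(class_counts) {
  if (any(class_counts < 0)) stop("counts must be non-negative", call. = FALSE)
  total <- sum(class_counts)
  if (total <= 0) stop("total count must be positive", call. = FALSE)
  p <- class_counts[class_counts > 0] / total
  -sum(p * log2(p))
}

#' Information gain of a partition
#'
#' \eqn{\mathrm{Gain}(S, A) = \mathrm{Entropy}(S) - \sum_V (|S_V|/|S|)\,
#' \mathrm{Entropy}(S_V)}: the expected reduction in entropy from splitting
#' the parent set into the given children.
#'
#' @param parent_counts Class counts of the parent set.
#' @param children_counts List of class-count vectors, one per child; they
#'   must sum (class-wise) to the parent counts.
#' @return Gain in bits, \code{>= 0}.
#' @export
information_gain <- function(parent_counts, children_counts) {
  tot <- Reduce(`+`, children_counts)
  if (length(tot) != length(parent_counts) || any(tot != parent_counts)) {
    stop("children do not partition the parent counts", call. = FALSE)
  }
  n <- sum(parent_counts)
  child_term <- sum(vapply(children_counts, function(cc) {
    m <- sum(cc)
    if (m == 0) 0 else (m / n) * entropy(cc)
  }, numeric(1)))
  max(0, entropy(parent_counts) - child_term)
}

#' Gain ratio of a split
#'
#' \eqn{\mathrm{GainRatio} = \mathrm{Gain} / \mathrm{SplitInfo}} where
#' SplitInfo is the entropy of the child-size proportions; the ratio
#' penalizes splits that fragment the data into many (or extreme) pieces.
#' Undefined when SplitInfo is 0 (all samples in one child) — such
#' candidates are rejected.
#'
#' @param gain Information gain of the split.
#' @param split_sizes Sizes of the children (at least 2 non-empty).
#' @return Gain ratio, or \code{NA} if SplitInfo is 0.
#' @export
gain_ratio <- function(gain, split_sizes) {
  split_sizes <- split_sizes[split_sizes > 0]
  if (length(split_sizes) < 2L) return(NA_real_)
  si <- entropy(split_sizes)
  if (si <= 0) return(NA_real_)
  gain / si
}

#' Best binary split of a continuous attribute
#'
#' Scans every midpoint between consecutive distinct sorted values as a
#' candidate threshold (samples with value \code{<= threshold} go left).
#' Following C4.5's guard against many weak thresholds, only candidates whose
#' gain is at least the mean gain over all candidates are admissible; among
#' those the maximum gain ratio wins, ties going to the smallest threshold.
#'
#' @param values Numeric attribute values.
#' @param labels Class labels (factor), one per value.
#' @return List with \code{threshold}, \code{gain}, \code{split_info},
#'   \code{gain_ratio}, or \code{NULL} for a constant attribute (no split).
#' @export
best_continuous_split <- function(values, labels) {
  labels <- factor(labels)
  ord <- order(values)
  v <- values[ord]
  y <- as.integer(labels)[ord]
  n <- length(v)
  k <- nlevels(labels)
  distinct_at <- which(diff(v) > 0)  # split after position i
  if (!length(distinct_at)) return(NULL)

  # cumulative class counts -> left/right counts at every candidate in one pass
  cum <- apply(vapply(seq_len(k), function(cl) as.numeric(y == cl),
                      numeric(n)), 2, cumsum)
  if (is.null(dim(cum))) cum <- matrix(cum, nrow = n)
  parent <- cum[n, ]
  h_parent <- entropy(parent)
  ent_rows <- function(m) {
    tot <- rowSums(m)
    p <- m / ifelse(tot > 0, tot, 1)
    lp <- ifelse(p > 0, log2(p), 0)
    -rowSums(p * lp)
  }
  left <- cum[distinct_at, , drop = FALSE]
  right <- matrix(parent, nrow = nrow(left), ncol = k, byrow = TRUE) - left
  nl <- rowSums(left); nr <- rowSums(right)
  gain <- pmax(0, h_parent - (nl / n) * ent_rows(left) - (nr / n) * ent_rows(right))
  pl <- nl / n
  split_info <- -(pl * log2(pl) + (1 - pl) * log2(1 - pl))
  ratio <- ifelse(split_info > 0, gain / split_info, NA_real_)

  admissible <- !is.na(ratio) & gain >= mean(gain) - 1e-12
  if (!any(admissible)) return(NULL)
  # ties on ratio (within fp tolerance) -> smallest threshold: candidates are
  # in increasing threshold order, so take the first near-maximal one
  amax <- max(ratio[admissible])
  best <- which(admissible & ratio >= amax - 1e-10)[1]
  i <- distinct_at[best]
  list(threshold = (v[i] + v[i + 1L]) / 2,
       gain = gain[best], split_info = split_info[best],
       gain_ratio = ratio[best])
}

#' Build a C4.5 decision tree on continuous attributes
#'
#' Divide and conquer: at each node, evaluate the best binary split of every
#' attribute by gain ratio (with C4.5's mean-gain admissibility guard) and
#' recurse on the winner until the node is pure, too small, or no admissible
#' split remains. Grown trees are then simplified by pessimistic (error-based)
#' pruning: a subtree collapses to a leaf when the leaf's upper-confidence
#' error estimate does not exceed the sum over its leaves.
#'
#' @param x Numeric sample x attribute matrix with column names.
#' @param labels Class labels (factor), one per row.
#' @param min_leaf Minimum samples in each child of a split; default 2.
#' @param prune_confidence Confidence level CF for the pessimistic error
#'   upper bound (Clopper-Pearson upper limit); default 0.25, Quinlan's
#'   default. Use \code{NULL} to skip pruning.
#' @return Object of class \code{"c45_tree"}.
#' @export
build_tree <- function(x, labels, min_leaf = 2L, prune_confidence = 0.25) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("attr_", seq_len(ncol(x)))
  labels <- factor(labels)
  stopifnot(nrow(x) == length(labels), nrow(x) >= 1L)
  lev <- levels(labels)

  make_leaf <- function(counts) {
    list(type = "leaf", class = lev[which.max(counts)], counts = counts)
  }
  grow <- function(idx) {
    counts <- tabulate(labels[idx], nbins = length(lev))
    names(counts) <- lev
    if (sum(counts > 0) <= 1L || length(idx) < 2L * min_leaf) {
      return(make_leaf(counts))
    }
    best <- NULL
    for (a in colnames(x)) {
      cand <- best_continuous_split(x[idx, a], labels[idx])
      if (is.null(cand)) next
      go_left <- x[idx, a] <= cand$threshold
      if (sum(go_left) < min_leaf || sum(!go_left) < min_leaf) next
      if (is.null(best) || cand$gain_ratio > best$gain_ratio + 1e-12) {
        best <- c(cand, list(attribute = a))
      }
    }
    if (is.null(best)) return(make_leaf(counts))
    go_left <- x[idx, best$attribute] <= best$threshold
    list(type = "split", attribute = best$attribute,
         threshold = best$threshold, counts = counts,
         gain = best$gain, gain_ratio = best$gain_ratio,
         left = grow(idx[go_left]), right = grow(idx[!go_left]))
  }
  root <- grow(seq_len(nrow(x)))
  if (!is.null(prune_confidence)) {
    root <- prune_node(root, cf = prune_confidence)
  }
  structure(list(root = root, classes = lev, attributes = colnames(x),
                 min_leaf = min_leaf, prune_confidence = prune_confidence),
            class = "c45_tree")
}

# Upper confidence limit on the error rate of a leaf that misclassifies e of
# n training cases (Clopper-Pearson upper bound at confidence cf; for e = 0
# this reduces to 1 - cf^(1/n), the C4.5 textbook form).
ucf_error <- function(e, n, cf) {
  if (n == 0) return(0)
  stats::qbeta(1 - cf, e + 1, n - e)
}

# Bottom-up pessimistic pruning; returns the (possibly collapsed) node.
prune_node <- function(node, cf) {
  if (node$type == "leaf") return(node)
  node$left <- prune_node(node$left, cf)
  node$right <- prune_node(node$right, cf)
  n <- sum(node$counts)
  e_leaf <- n - max(node$counts)
  est_leaf <- n * ucf_error(e_leaf, n, cf)
  est_sub <- subtree_error(node$left, cf) + subtree_error(node$right, cf)
  if (est_leaf <= est_sub) {
    lev <- names(node$counts)
    return(list(type = "leaf", class = lev[which.max(node$counts)],
                counts = node$counts))
  }
  node
}

subtree_error <- function(node, cf) {
  if (node$type == "leaf") {
    n <- sum(node$counts)
    if (n == 0) return(0)
    return(n * ucf_error(n - max(node$counts), n, cf))
  }
  subtree_error(node$left, cf) + subtree_error(node$right, cf)
}

n_nodes <- function(node) {
  if (node$type == "leaf") return(1L)
  1L + n_nodes(node$left) + n_nodes(node$right)
}

#' @export
print.c45_tree <- function(x, ...) {
  cat(sprintf("C4.5 tree: %d nodes, classes: %s\n", n_nodes(x$root),
              paste(x$classes, collapse = ", ")))
  show <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (node$type == "leaf") {
      cat(sprintf("%s-> %s (%s)\n", pad, node$class,
                  paste(node$counts, collapse = "/")))
    } else {
      cat(sprintf("%s%s <= %.4g ?\n", pad, node$attribute, node$threshold))
      show(node$left, indent + 1L)
      show(node$right, indent + 1L)
    }
  }
  show(x$root, 0L)
  invisible(x)
}

#' Predict classes and class probabilities from a C4.5 tree
#'
#' Routes each sample by the split thresholds (values equal to a threshold go
#' left) to a leaf; probabilities are the leaf's training class counts
#' normalized. Samples missing a tested attribute are an error — feature
#' tables are complete after zero-fill, so missing-value fractioning is not
#' supported.
#'
#' @param object A \code{c45_tree}.
#' @param newdata Numeric matrix/data frame with the attributes the tree
#'   tests.
#' @param ... Unused.
#' @return List with \code{class} (factor) and \code{prob} (matrix, one
#'   column per class).
#' @export
predict.c45_tree <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  route <- function(node, row) {
    if (node$type == "leaf") return(node)
    if (!(node$attribute %in% colnames(newdata)) ||
        is.na(row[[node$attribute]])) {
      stop(sprintf("sample is missing tested attribute '%s'", node$attribute),
           call. = FALSE)
    }
    val <- row[[node$attribute]]
    if (val <= node$threshold) route(node$left, row) else route(node$right, row)
  }
  k <- length(object$classes)
  prob <- matrix(0, nrow(newdata), k, dimnames = list(rownames(newdata),
                                                      object$classes))
  cls <- character(nrow(newdata))
  for (i in seq_len(nrow(newdata))) {
    row <- newdata[i, , drop = FALSE]
    leaf <- route(object$root, stats::setNames(as.list(as.numeric(row)),
                                               colnames(newdata)))
    tot <- sum(leaf$counts)
    prob[i, ] <- if (tot > 0) leaf$counts / tot else 1 / k
    cls[i] <- leaf$class
  }
  list(class = factor(cls, levels = object$classes), prob = prob)
}

#' Stratified tenfold cross-validation with macro one-vs-rest ROC
#'
#' Assigns samples to folds stratified by class under a fixed seed, trains a
#' C4.5 tree on each training split, pools the held-out class-probability
#' predictions, and reports per-fold confusion matrices, pooled accuracy and
#' the macro-averaged one-vs-rest ROC area ("ROC"): for each class, the AUC
#' of that class's pooled probability against the binary is/is-not-class
#' truth, averaged over classes.
#'
#' @param x Numeric sample x attribute matrix.
#' @param labels Class labels, one per row.
#' @param folds Number of folds; default 10.
#' @param seed Integer seed for fold assignment.
#' @param ... Passed to \code{\link{build_tree}}.
#' @return Object of class \code{"cv_report"}: list with \code{fold}
#'   (assignment), \code{confusion} (pooled), \code{per_fold_confusion},
#'   \code{accuracy}, \code{auc} (per class), \code{roc} (macro average).
#' @export
tenfold_cv <- function(x, labels, folds = 10L, seed = 42L, ...) {
  x <- as.matrix(x)
  labels <- factor(labels)
  n <- nrow(x)
  folds <- as.integer(folds)
  stopifnot(n >= folds, folds >= 2L)
  small <- table(labels) < folds
  if (any(small)) {
    warning(sprintf("class(es) %s have fewer than %d members; their folds cannot all be stratified",
                    paste(names(which(small)), collapse = ", "), folds))
  }
  fold <- integer(n)
  with_seed(seed, {
    for (cl in levels(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })

  prob <- matrix(NA_real_, n, nlevels(labels),
                 dimnames = list(rownames(x), levels(labels)))
  pred <- factor(rep(NA_character_, n), levels = levels(labels))
  per_fold <- vector("list", folds)
  for (f in seq_len(folds)) {
    test <- fold == f
    tree <- build_tree(x[!test, , drop = FALSE], labels[!test], ...)
    out <- predict(tree, x[test, , drop = FALSE])
    # a class absent from this training fold is absent from the tree: align
    # its probability columns into the full class set (missing class -> 0)
    p <- matrix(0, sum(test), nlevels(labels),
                dimnames = list(NULL, levels(labels)))
    p[, colnames(out$prob)] <- out$prob
    prob[test, ] <- p
    pred[test] <- out$class
    per_fold[[f]] <- table(truth = labels[test], predicted = out$class)
  }

  auc <- vapply(levels(labels), function(cl) {
    truth <- as.integer(labels == cl)
    as.numeric(pROC::auc(pROC::roc(truth, prob[, cl], quiet = TRUE,
                                   direction = "<", levels = c(0, 1))))
  }, numeric(1))
  structure(
    list(fold = fold, per_fold_confusion = per_fold,
         confusion = table(truth = labels, predicted = pred),
         accuracy = mean(pred == labels),
         auc = auc, roc = mean(auc), seed = seed, folds = folds),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation: accuracy %.3f, macro one-vs-rest ROC area %.3f\n",
              x$folds, x$accuracy, x$roc))
  cat("Per-class AUC:\n")
  print(round(x$auc, 4))
  cat("Pooled confusion:\n")
  print(x$confusion)
  invisible(x)
}

#' Export a C4.5 tree as nested JSON or Graphviz DOT
#'
#' @param tree A \code{c45_tree}.
#' @param path Output path.
#' @export
write_tree_json <- function(tree, path) {
  stopifnot(inherits(tree, "c45_tree"))
  jsonlite::write_json(tree$root, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_tree_json
#' @export
write_tree_dot <- function(tree, path) {
  stopifnot(inherits(tree, "c45_tree"))
  lines <- c("digraph c45 {", "  node [shape=box];")
  counter <- new.env()
  counter$i <- 0L
  emit <- function(node) {
    counter$i <- counter$i + 1L
    id <- sprintf("n%d", counter$i)
    if (node$type == "leaf") {
      lines <<- c(lines, sprintf("  %s [label=\"%s\\n(%s)\"];", id, node$class,
                                 paste(node$counts, collapse = "/")))
    } else {
      lines <<- c(lines, sprintf("  %s [label=\"%s <= %.4g\"];", id,
                                 node$attribute, node$threshold))
      lid <- emit(node$left)
      rid <- emit(node$right)
      lines <<- c(lines, sprintf("  %s -> %s [label=\"yes\"];", id, lid),
                  sprintf("  %s -> %s [label=\"no\"];", id, rid))
    }
    id
  }
  emit(tree$root)
  writeLines(c(lines, "}"), path)
  invisible(path)
}
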