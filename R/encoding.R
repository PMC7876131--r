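#' Flatten a 4D fMRI volume to a voxel-by-time matrix
#'
#' Disassembles an \code{X x Y x Z x T} array into its two-dimensional form:
#' a \code{V x T} matrix with \code{V = X*Y*Z} voxels as rows, in x-fastest
#' raster order (x varies quickest, then y, then z — R's native array order,
#' so the reshape is copy-free). The voxel index maps each row back to its
#' original \code{(x, y, z)} coordinate.
#'
#' @param volume 4D numeric array \code{[X, Y, Z, T]}.
#'
#' @return An object of class \code{"voxel_time_series"}: list with
#'   \code{values} (\code{V x T} matrix), \code{voxel_index} (\code{V x 3}
#'   integer matrix of coordinates), \code{spatial_dim}.
#' @export
#' @examples
#' v <- array(rnorm(2 * 2 * 1 * 3), c(2, 2, 1, 3))
#' ts <- flatten_volume(v)
#' dim(ts$values)  # 4 x 3
flatten_volume <- function(volume) {
  d <- dim(volume)
  if (is.null(d) || length(d) != 4L) {
    stop("'volume' must be a 4-dimensional array [X, Y, Z, T]", call. = FALSE)
  }
  if (any(d < 1L)) stop("all dimensions must be >= 1", call. = FALSE)
  v <- prod(d[1:3])
  values <- volume
  dim(values) <- c(v, d[4])
  structure(
    list(values = values,
         voxel_index = arrayInd(seq_len(v), .dim = d[1:3]),
         spatial_dim = d[1:3]),
    class = "voxel_time_series"
  )
}

#' @export
print.voxel_time_series <- function(x, ...) {
  cat(sprintf("Voxel time series: %d voxels (%s grid) x %d timepoints\n",
              nrow(x$values), paste(x$spatial_dim, collapse = "x"),
              ncol(x$values)))
  invisible(x)
}

#' Pearson correlation between two voxel time series
#'
#' Implements \eqn{r = (\overline{ab} - \bar a \bar b) / (\sigma_a \sigma_b)}
#' with population (1/N) standard deviations — the moment form used to decide
#' voxel linking. (The sample-vs-population choice cancels in \eqn{r}; the
#' population form matches the overbar-mean definition.) A zero-variance
#' input makes the correlation undefined: \code{NA} is returned so callers
#' can exclude the voxel from linking rather than treating it as 0.
#'
#' @param a,b Numeric vectors of equal length \code{>= 2}.
#' @return Correlation in \code{[-1, 1]}, or \code{NA} if either input has
#'   zero variance.
#' @export
#' @examples
#' pearson_correlation(c(1, 2, 3, 4), c(1, 2, 3, 5))  # ~0.9827
pearson_correlation <- function(a, b) {
  if (length(a) != length(b)) stop("series must have equal length", call. = FALSE)
  if (length(a) < 2L) stop("series must have length >= 2", call. = FALSE)
  ma <- mean(a); mb <- mean(b)
  sa <- sqrt(mean(a^2) - ma^2)
  sb <- sqrt(mean(b^2) - mb^2)
  if (!is.finite(sa) || !is.finite(sb) || sa == 0 || sb == 0) return(NA_real_)
  r <- (mean(a * b) - ma * mb) / (sa * sb)
  max(-1, min(1, r))
}

#' Per-voxel degree of the thresholded correlation network
#'
#' Two voxels are linked when their Pearson correlation exceeds the threshold
#' (strictly \code{r > threshold}; only positive correlation counts). The
#' degree of a voxel is its number of links. Correlations are computed in
#' blocks of voxel rows against the full standardized matrix, so peak memory
#' is \code{O(block_size * V)} rather than \code{O(V^2)}; the result is
#' independent of the block size. Voxels with temporal variance at or below
#' \code{var_eps}, or excluded by \code{mask}, form no links and have
#' degree 0.
#'
#' @param ts A \code{\link{flatten_volume}} result (or a bare \code{V x T}
#'   matrix).
#' @param threshold Linking threshold in \code{(-1, 1)}; default 0.7.
#' @param mask Optional logical vector of length \code{V}; \code{FALSE}
#'   voxels are excluded from linking.
#' @param var_eps Temporal-variance floor below which a voxel is treated as
#'   empty (background/air) and excluded.
#' @param block_size Number of voxel rows per correlation block.
#'
#' @return Integer vector of degrees, length \code{V}.
#' @export
build_degree_vector <- function(ts, threshold = 0.7, mask = NULL,
                                var_eps = 1e-12, block_size = 2048L) {
  values <- if (inherits(ts, "voxel_time_series")) ts$values else as.matrix(ts)
  if (ncol(values) < 2L) stop("at least 2 timepoints are required", call. = FALSE)
  if (!is.numeric(threshold) || threshold <= -1 || threshold >= 1) {
    stop("'threshold' must lie in (-1, 1)", call. = FALSE)
  }
  v <- nrow(values)
  keep <- rep(TRUE, v)
  if (!is.null(mask)) {
    if (length(mask) != v) stop("'mask' must have one flag per voxel", call. = FALSE)
    keep <- keep & as.logical(mask)
  }
  ctr <- values - rowMeans(values)
  ss <- rowSums(ctr^2)
  keep <- keep & (ss / ncol(values) > var_eps)
  degree <- integer(v)
  rows <- which(keep)
  if (length(rows) < 2L) return(degree)

  z <- ctr[rows, , drop = FALSE] / sqrt(ss[rows])
  n <- length(rows)
  block_size <- max(1L, as.integer(block_size))
  for (start in seq(1L, n, by = block_size)) {
    idx <- start:min(start + block_size - 1L, n)
    r <- z[idx, , drop = FALSE] %*% t(z)
    # subtract the self-correlation (exactly 1 > threshold for any valid cut)
    degree[rows[idx]] <- as.integer(rowSums(r > threshold) - (threshold < 1))
  }
  degree
}

#' Tally a degree vector into a degree distribution
#'
#' Counts how many voxels attain each degree. Degree-0 voxels (background and
#' unlinked voxels) are excluded by default: on whole-head grids they would
#' dominate the counts, and the distribution is the "degree vs counted
#' number" encoding over linked voxels. Set \code{include_zero = TRUE} to
#' keep the zero bin, in which case the counts sum to the number of voxels.
#'
#' @param dv Integer degree vector.
#' @param include_zero Keep the degree-0 bin? Default \code{FALSE}.
#' @return Object of class \code{"degree_distribution"}: data frame with
#'   columns \code{degree} and \code{count}, sorted by degree, only degrees
#'   with count \code{>= 1}.
#' @export
#' @examples
#' degree_distribution(c(2L, 1L, 1L))  # {1: 2, 2: 1}
degree_distribution <- function(dv, include_zero = FALSE) {
  dv <- as.integer(dv)
  if (anyNA(dv) || any(dv < 0L)) stop("degrees must be non-negative integers", call. = FALSE)
  if (!include_zero) dv <- dv[dv > 0L]
  if (!length(dv)) {
    return(structure(data.frame(degree = integer(), count = integer()),
                     class = c("degree_distribution", "data.frame")))
  }
  tab <- table(dv)
  structure(
    data.frame(degree = as.integer(names(tab)), count = as.integer(tab)),
    class = c("degree_distribution", "data.frame")
  )
}

#' @export
print.degree_distribution <- function(x, ...) {
  cat(sprintf("Degree distribution: %d degree bins, %d voxels, degree range [%s, %s]\n",
              nrow(x), sum(x$count),
              if (nrow(x)) min(x$degree) else NA, if (nrow(x)) max(x$degree) else NA))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}

#' Encode one fMRI sample as a degree distribution
#'
#' The full encoding of a scan: flatten the 4D volume to voxel-by-time form,
#' build the thresholded Pearson-correlation network, and tally the degree
#' distribution. Deterministic composition of \code{\link{flatten_volume}},
#' \code{\link{build_degree_vector}} and \code{\link{degree_distribution}}.
#'
#' @param volume 4D array or path to a 4D NIfTI file.
#' @param threshold Linking threshold; default 0.7.
#' @param mask Optional logical voxel mask (x-fastest raster order).
#' @param include_zero Keep the degree-0 bin? Default \code{FALSE}.
#' @inheritParams build_degree_vector
#' @return A \code{\link{degree_distribution}}.
#' @export
encode_sample <- function(volume, threshold = 0.7, mask = NULL,
                          include_zero = FALSE, var_eps = 1e-12,
                          block_size = 2048L) {
  if (is.character(volume)) volume <- read_volume_nifti(volume)
  ts <- flatten_volume(volume)
  dv <- build_degree_vector(ts, threshold = threshold, mask = mask,
                            var_eps = var_eps, block_size = block_size)
  degree_distribution(dv, include_zero = include_zero)
}

#' Write a degree distribution as a two-column CSV (degree, count)
#' @param dist A \code{degree_distribution}.
#' @param path Output path.
#' @export
write_distribution_csv <- function(dist, path) {
  utils::write.csv(as.data.frame(dist)[c("degree", "count")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_distribution_csv
#' @export
read_distribution_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("degree", "count") %in% names(d))) {
    stop("distribution CSV must have columns degree, count", call. = FALSE)
  }
  structure(data.frame(degree = as.integer(d$degree), count = as.integer(d$count)),
            class = c("degree_distribution", "data.frame"))
}
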