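#' State profile for synthetic degree-distribution cohorts
#'
#' A state profile describes the generative power law for one experimental
#' state (e.g. the four anesthesia/strain states HS, HW, LS, LW): the expected
#' voxel count at degree \eqn{k} is \eqn{c \, k^{-\gamma}} with amplitude
#' \eqn{c} and exponent \eqn{\gamma}.
#'
#' @param name State label, a non-empty string (e.g. \code{"LS"}).
#' @param exponent Power-law exponent \eqn{\gamma > 0} (dimensionless).
#' @param amplitude Expected count at degree 1, \eqn{c > 0}.
#' @param max_degree Largest degree bin generated; integer \code{>= 2}.
#' @param noise Count-noise model: \code{"poisson"} draws each count from a
#'   Poisson with mean \eqn{c k^{-\gamma}}; \code{"none"} rounds the mean to
#'   the nearest integer (round-half-to-even).
#'
#' @return An object of class \code{"state_profile"}.
#' @export
#' @examples
#' state_profile("LS", exponent = 1.6, amplitude = 500)
state_profile <- function(name, exponent, amplitude, max_degree = 200L,
                          noise = c("poisson", "none")) {
  noise <- match.arg(noise)
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("'name' must be a non-empty string", call. = FALSE)
  }
  if (!is.numeric(exponent) || length(exponent) != 1L || !is.finite(exponent) ||
      exponent <= 0) {
    stop("invalid profile: 'exponent' must be a positive number", call. = FALSE)
  }
  if (!is.numeric(amplitude) || length(amplitude) != 1L ||
      !is.finite(amplitude) || amplitude <= 0) {
    stop("invalid profile: 'amplitude' must be a positive number", call. = FALSE)
  }
  max_degree <- as.integer(max_degree)
  if (is.na(max_degree) || max_degree < 2L) {
    stop("invalid profile: 'max_degree' must be an integer >= 2", call. = FALSE)
  }
  structure(
    list(name = name, exponent = exponent, amplitude = amplitude,
         max_degree = max_degree, noise = noise),
    class = "state_profile"
  )
}

#' @export
print.state_profile <- function(x, ...) {
  cat(sprintf("State profile '%s': E[count(k)] = %g * k^(-%g), k = 1..%d, noise = %s\n",
              x$name, x$amplitude, x$exponent, x$max_degree, x$noise))
  invisible(x)
}

#' Generate a labeled cohort of synthetic degree distributions
#'
#' Draws \code{n_per_state} degree distributions per state profile. For each
#' sample the count in degree bin \eqn{k} has expectation
#' \eqn{c \, k^{-\gamma}}; under Poisson noise the count is a Poisson draw
#' with that mean, otherwise the mean is rounded half-to-even. Bins whose
#' realized count is zero are dropped (a degree distribution only stores
#' degrees actually observed), mirroring the ragged support of encoded scans.
#'
#' @param profiles List of \code{\link{state_profile}} objects with distinct
#'   names.
#' @param n_per_state Number of samples per state, \code{>= 1}.
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#'
#' @return An object of class \code{"degree_cohort"}: a list with
#'   \code{samples} (long data frame with columns \code{sample_id},
#'   \code{state}, \code{degree}, \code{count}), \code{profiles},
#'   \code{n_per_state} and \code{seed}.
#' @seealso \code{\link{feature_table}} to tabulate a cohort into the
#'   rectangular form consumed by \code{\link{chi2_select}}.
#' @export
#' @examples
#' profs <- list(state_profile("A", 1.6, 500), state_profile("B", 2.4, 500))
#' coh <- generate_degree_cohort(profs, n_per_state = 5, seed = 1)
#' head(coh$samples)
generate_degree_cohort <- function(profiles, n_per_state, seed) {
  if (inherits(profiles, "state_profile")) profiles <- list(profiles)
  if (!length(profiles) || !all(vapply(profiles, inherits, TRUE, "state_profile"))) {
    stop("'profiles' must be a non-empty list of state_profile objects",
         call. = FALSE)
  }
  nms <- vapply(profiles, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("profile names must be distinct", call. = FALSE)
  n_per_state <- as.integer(n_per_state)
  if (is.na(n_per_state) || n_per_state < 1L) {
    stop("'n_per_state' must be >= 1", call. = FALSE)
  }

  samples <- with_seed(seed, {
    out <- vector("list", length(profiles) * n_per_state)
    idx <- 1L
    for (pr in profiles) {
      k <- seq_len(pr$max_degree)
      mu <- pr$amplitude * k^(-pr$exponent)
      for (i in seq_len(n_per_state)) {
        counts <- if (pr$noise == "poisson") stats::rpois(length(mu), mu) else round(mu)
        keep <- counts >= 1
        out[[idx]] <- data.frame(
          sample_id = sprintf("%s_%02d", pr$name, i),
          state = pr$name,
          degree = k[keep],
          count = as.integer(counts[keep]),
          stringsAsFactors = FALSE
        )
        idx <- idx + 1L
      }
    }
    do.call(rbind, out)
  })
  rownames(samples) <- NULL
  structure(
    list(samples = samples, profiles = profiles,
         n_per_state = n_per_state, seed = seed),
    class = "degree_cohort"
  )
}

#' @export
print.degree_cohort <- function(x, ...) {
  cat(sprintf("Synthetic degree cohort: %d states x %d samples (seed %s)\n",
              length(x$profiles), x$n_per_state, format(x$seed)))
  cat("States:", paste(vapply(x$profiles, `[[`, "", "name"), collapse = ", "), "\n")
  invisible(x)
}

#' Write/read a degree cohort as CSV
#'
#' The on-disk form is the long table (\code{sample_id, state, degree, count});
#' profile metadata can be stored alongside as JSON via
#' \code{write_cohort_meta}.
#'
#' @param cohort A \code{degree_cohort}.
#' @param path Output CSV path.
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(inherits(cohort, "degree_cohort"))
  utils::write.csv(cohort$samples, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  samples <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "state", "degree", "count")
  if (!all(need %in% names(samples))) {
    stop("cohort CSV must have columns sample_id, state, degree, count",
         call. = FALSE)
  }
  structure(list(samples = samples[need], profiles = NULL,
                 n_per_state = NA_integer_, seed = NA_integer_),
            class = "degree_cohort")
}

#' @rdname write_cohort_csv
#' @export
write_cohort_meta <- function(cohort, path) {
  stopifnot(inherits(cohort, "degree_cohort"))
  meta <- list(
    seed = cohort$seed,
    n_per_state = cohort$n_per_state,
    profiles = lapply(cohort$profiles, function(p) p[c("name", "exponent",
                                                       "amplitude", "max_degree",
                                                       "noise")])
  )
  jsonlite::write_json(meta, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' State-average degree distribution of a cohort
#'
#' Averages the counts of all samples of one state into a single degree
#' distribution (zero counts included in the average), the per-state average
#' curve that the exponent of a state is usually read from. Tail degree bins
#' observed in only a few samples carry mostly zero-truncated Poisson noise;
#' \code{min_support} drops bins seen in less than that fraction of the
#' state's samples so a log-log fit is not biased by the sparse tail.
#'
#' @param cohort A \code{degree_cohort}.
#' @param state State label to average.
#' @param min_support Minimum fraction of samples a degree bin must appear in
#'   to be kept; default 0.5.
#' @return A \code{\link{degree_distribution}} with fractional counts.
#' @export
state_mean_distribution <- function(cohort, state, min_support = 0.5) {
  samples <- if (inherits(cohort, "degree_cohort")) cohort$samples else as.data.frame(cohort)
  s <- samples[samples$state == state, ]
  if (!nrow(s)) stop(sprintf("no samples with state '%s'", state), call. = FALSE)
  n_samples <- length(unique(s$sample_id))
  tot <- tapply(s$count, s$degree, sum)
  seen <- tapply(s$count, s$degree, function(x) sum(x > 0))
  keep <- seen >= min_support * n_samples
  structure(
    data.frame(degree = as.integer(names(tot))[keep],
               count = as.numeric(tot)[keep] / n_samples),
    class = c("degree_distribution", "data.frame")
  )
}

#' Generate 4D volumes with planted correlated voxel clusters
#'
#' Emulates the raw input of the encoding step: a 4D array (three spatial
#' dimensions and time) in which voxels belonging to a planted cluster share a
#' common latent time series, so that their pairwise Pearson correlation
#' exceeds the 0.7 linking threshold in expectation, while background voxels
#' are independent noise. Each cluster voxel is
#' \eqn{v = \sqrt{\rho}\, z + \sqrt{1-\rho}\, \epsilon} with \eqn{z} the
#' cluster latent and \eqn{\epsilon} voxel noise, giving expected pairwise
#' correlation \eqn{\rho =} \code{within_corr}.
#'
#' @param shape Integer vector \code{c(X, Y, Z, T)}; \code{T >= 10}.
#' @param cluster_sizes Integer vector of planted cluster sizes (possibly
#'   empty for a pure-background volume); clusters are disjoint random voxel
#'   sets and must fit in the grid.
#' @param within_corr Target within-cluster correlation, in \code{(0.7, 1)};
#'   values at or below the 0.7 linking threshold are rejected because links
#'   would not form reliably.
#' @param n_volumes Number of volumes to generate (cluster positions are drawn
#'   once and shared, so the ground truth applies to every volume).
#' @param seed Integer seed.
#'
#' @return A list of class \code{"fmri_cohort"} with \code{volumes} (list of
#'   4D arrays), \code{cluster_map} (integer vector over voxels in
#'   x-fastest raster order: 0 = background, 1.. = cluster id), \code{shape},
#'   \code{within_corr} and \code{seed}.
#' @export
#' @examples
#' sim <- generate_fmri_cohort(c(6, 6, 1, 40), cluster_sizes = 5,
#'                             within_corr = 0.95, seed = 1)
#' dim(sim$volumes[[1]])
generate_fmri_cohort <- function(shape, cluster_sizes = integer(),
                                 within_corr = 0.95, n_volumes = 1L, seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 4L || anyNA(shape) || any(shape < 1L)) {
    stop("'shape' must be four positive integers c(X, Y, Z, T)", call. = FALSE)
  }
  if (shape[4] < 10L) stop("at least 10 timepoints are required", call. = FALSE)
  if (!is.numeric(within_corr) || within_corr <= 0.7 || within_corr >= 1) {
    stop("'within_corr' must lie in (0.7, 1): at or below the 0.7 linking ",
         "threshold planted links would not form reliably", call. = FALSE)
  }
  cluster_sizes <- as.integer(cluster_sizes)
  if (anyNA(cluster_sizes) || any(cluster_sizes < 2L)) {
    stop("cluster sizes must be integers >= 2", call. = FALSE)
  }
  v_total <- prod(shape[1:3])
  if (sum(cluster_sizes) > v_total) {
    stop("clusters do not fit in the voxel grid", call. = FALSE)
  }
  n_volumes <- as.integer(n_volumes)
  stopifnot(n_volumes >= 1L)

  tt <- shape[4]
  rho <- within_corr
  res <- with_seed(seed, {
    cluster_map <- integer(v_total)
    if (length(cluster_sizes)) {
      pos <- sample.int(v_total, sum(cluster_sizes))
      cluster_map[pos] <- rep(seq_along(cluster_sizes), cluster_sizes)
    }
    vols <- lapply(seq_len(n_volumes), function(i) {
      mat <- matrix(stats::rnorm(v_total * tt), v_total, tt)
      for (cl in seq_along(cluster_sizes)) {
        z <- stats::rnorm(tt)
        rows <- which(cluster_map == cl)
        mat[rows, ] <- sqrt(rho) * matrix(z, length(rows), tt, byrow = TRUE) +
          sqrt(1 - rho) * mat[rows, , drop = FALSE]
      }
      array(mat, dim = shape)
    })
    list(volumes = vols, cluster_map = cluster_map)
  })
  structure(
    list(volumes = res$volumes, cluster_map = res$cluster_map, shape = shape,
         within_corr = within_corr, seed = seed),
    class = "fmri_cohort"
  )
}

#' @export
print.fmri_cohort <- function(x, ...) {
  cat(sprintf("Synthetic fMRI cohort: %d volume(s) of %s, %d planted cluster(s), rho = %g\n",
              length(x$volumes), paste(x$shape, collapse = "x"),
              max(x$cluster_map), x$within_corr))
  invisible(x)
}

#' Write a 4D volume to NIfTI-1
#'
#' @param volume 4D numeric array.
#' @param path Output path (\code{.nii} or \code{.nii.gz}).
#' @export
write_volume_nifti <- function(volume, path) {
  stopifnot(is.array(volume), length(dim(volume)) == 4L)
  RNifti::writeNifti(RNifti::asNifti(volume), path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(path) {
  vol <- as.array(RNifti::readNifti(path))
  if (length(dim(vol)) != 4L) stop("expected a 4D NIfTI volume", call. = FALSE)
  vol
}
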