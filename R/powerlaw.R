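# Log-log least squares on one segment; returns slope/intercept/rss.
# Closed form rather than lm(): these fits sit inside breakpoint grids and
# replicate loops, so the constant factor matters.
ols_loglog <- function(lx, ly) {
  n <- length(lx)
  mx <- mean(lx); my <- mean(ly)
  sxx <- sum((lx - mx)^2)
  slope <- if (sxx > 0) sum((lx - mx) * (ly - my)) / sxx else 0
  intercept <- my - slope * mx
  resid <- ly - (intercept + slope * lx)
  list(slope = slope, intercept = intercept, rss = sum(resid^2), n = n)
}

# Gaussian-residual AIC on the log-count scale: n*ln(rss/n) + 2p, where p
# counts slopes, intercepts, and the residual variance. A residual sum at
# the floating-point floor (rss/n below ~1e-20, i.e. residuals at sqrt(eps)
# scale) is treated as an exact fit and mapped to -Inf; otherwise rounding
# noise in a perfect fit would make AIC differences between nested exact
# fits arbitrary.
aic_from_rss <- function(rss, n, p) {
  if (rss <= n * 1e-20) return(-Inf)
  n * log(rss / n) + 2 * p
}

as_dist_df <- function(dist) {
  d <- as.data.frame(dist)
  if (!all(c("degree", "count") %in% names(d))) {
    stop("expected a degree distribution with columns degree and count",
         call. = FALSE)
  }
  d <- d[d$count > 0 & d$degree >= 1, c("degree", "count")]
  d[order(d$degree), ]
}

#' Fit a single power law to a degree distribution
#'
#' Ordinary least squares on \eqn{(\log k, \log \mathrm{count})}: the model is
#' \eqn{\mathrm{count} = c\,k^{-\gamma}}, so the fitted exponent is minus the
#' log-log slope and the amplitude is \eqn{e^{\mathrm{intercept}}}. The AIC is
#' computed from the Gaussian residual form \eqn{n\ln(\mathrm{rss}/n) + 2p}
#' with \eqn{p = 3} (slope, intercept, residual variance).
#'
#' @param dist A \code{\link{degree_distribution}} (or data frame with
#'   \code{degree}, \code{count}); needs at least 3 distinct degrees with
#'   positive counts.
#' @return Object of class \code{"powerlaw_fit"} with fields
#'   \code{exponent}, \code{amplitude}, \code{n_points}, \code{rss},
#'   \code{aic}.
#' @export
#' @examples
#' d <- data.frame(degree = 1:50, count = 1000 * (1:50)^-2)
#' fit_single_power(d)$exponent  # 2
fit_single_power <- function(dist) {
  d <- as_dist_df(dist)
  if (nrow(d) < 3L) {
    stop("insufficient data: need >= 3 distinct degrees with positive counts",
         call. = FALSE)
  }
  f <- ols_loglog(log(d$degree), log(d$count))
  structure(
    list(exponent = -f$slope, amplitude = exp(f$intercept),
         n_points = f$n, rss = f$rss, aic = aic_from_rss(f$rss, f$n, 3L)),
    class = "powerlaw_fit"
  )
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf("Single power law: count = %.4g * k^(-%.4g)  [n = %d, rss = %.4g, AIC = %.4g]\n",
              x$amplitude, x$exponent, x$n_points, x$rss, x$aic))
  invisible(x)
}

#' Fit a broken (double) power law to a degree distribution
#'
#' Fits two unconstrained log-log segments — one for degrees at or below a
#' breakpoint, one above — for every candidate breakpoint with at least 3
#' observed degrees on each side, and keeps the breakpoint minimizing the
#' total residual sum of squares (ties go to the smallest breakpoint). The
#' AIC uses \eqn{p = 5} (two slopes, two intercepts, residual variance).
#'
#' @inheritParams fit_single_power
#' @return Object of class \code{"double_powerlaw_fit"} with
#'   \code{exponent_low}, \code{exponent_high}, \code{breakpoint},
#'   \code{amplitude} (low-degree segment), \code{amplitude_high},
#'   \code{n_points}, \code{rss}, \code{aic}.
#' @export
fit_double_power <- function(dist) {
  d <- as_dist_df(dist)
  n <- nrow(d)
  if (n < 6L) {
    stop("insufficient data: need >= 6 distinct degrees with positive counts",
         call. = FALSE)
  }
  lx <- log(d$degree); ly <- log(d$count)
  # candidate breakpoints: observed degrees with >= 3 points on each side
  cand <- d$degree[seq(3L, n - 3L)]
  best <- NULL
  for (b in cand) {
    left <- d$degree <= b
    fl <- ols_loglog(lx[left], ly[left])
    fr <- ols_loglog(lx[!left], ly[!left])
    rss <- fl$rss + fr$rss
    if (is.null(best) || rss < best$rss - 1e-12) {
      best <- list(b = b, fl = fl, fr = fr, rss = rss)
    }
  }
  structure(
    list(exponent_low = -best$fl$slope, exponent_high = -best$fr$slope,
         breakpoint = best$b,
         amplitude = exp(best$fl$intercept),
         amplitude_high = exp(best$fr$intercept),
         n_points = n, rss = best$rss, aic = aic_from_rss(best$rss, n, 5L)),
    class = "double_powerlaw_fit"
  )
}

#' @export
print.double_powerlaw_fit <- function(x, ...) {
  cat(sprintf("Double power law: gamma_low = %.4g (k <= %d), gamma_high = %.4g (k > %d)  [n = %d, rss = %.4g, AIC = %.4g]\n",
              x$exponent_low, x$breakpoint, x$exponent_high, x$breakpoint,
              x$n_points, x$rss, x$aic))
  invisible(x)
}

#' Choose between single and double power law by AIC
#'
#' Returns the model with the lower AIC; ties favour the single power law
#' (fewer parameters). Both fits must describe the same distribution.
#'
#' @param single A \code{\link{fit_single_power}} result.
#' @param double A \code{\link{fit_double_power}} result.
#' @return List with \code{selected} (\code{"single"} or \code{"double"}) and
#'   \code{delta_aic} (\code{double$aic - single$aic}; negative favours
#'   double).
#' @export
compare_aic <- function(single, double) {
  stopifnot(inherits(single, "powerlaw_fit"),
            inherits(double, "double_powerlaw_fit"))
  if (single$n_points != double$n_points) {
    stop("fits describe different distributions (n_points mismatch)",
         call. = FALSE)
  }
  delta <- double$aic - single$aic
  list(selected = if (isTRUE(delta < 0)) "double" else "single",
       delta_aic = delta)
}
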