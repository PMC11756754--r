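#' Normalize a positive series to its first value
#'
#' @param values Numeric vector; `values[1]` must be positive.
#' @return `values / values[1]`; first element exactly 1.
#' @export
normalize_series <- function(values) {
  stopifnot(is.numeric(values), length(values) >= 1)
  if (!is.finite(values[1]) || values[1] <= 0) {
    stop("First value must be positive to normalize.", call. = FALSE)
  }
  values / values[1]
}

#' Fit exponential growth and the population doubling time
#'
#' Ordinary least squares of `log(value)` on time over the fit window.
#' The growth rate `k` (per hour) is the slope and the population doubling
#' time is `PDT = ln(2) / k`. Log-linear OLS is exact on noiseless
#' exponential data and numerically stable; an optional nonlinear
#' least-squares refinement of `V0 * exp(k t)` is available for data with
#' large multiplicative noise.
#'
#' @param times Time in hours.
#' @param values Positive series (volume, radius^3, ...), same length.
#' @param t_start,t_end Fit window in hours; points with
#'   `t_start <= t <= t_end` are used. Defaults cover all points.
#' @param refine_nls If `TRUE`, refine by nonlinear least squares on the
#'   original scale, starting from the log-linear solution. Default `FALSE`.
#' @return An object of class `growth_fit` with fields `k` (/h), `pdt` (h),
#'   `v0`, `log_residual_sd`, `k_se`, `pdt_se`, `n`, `window`.
#'   [generics::tidy()] and [generics::glance()] methods return tibbles.
#' @examples
#' t <- 0:48
#' fit <- fit_exponential(t, 2^(t / 15))
#' fit$pdt # 15
#' @export
fit_exponential <- function(times, values, t_start = -Inf, t_end = Inf,
                            refine_nls = FALSE) {
  stopifnot(length(times) == length(values))
  keep <- is.finite(times) & times >= t_start & times <= t_end
  t <- times[keep]
  v <- values[keep]
  if (length(t) < 4) {
    stop("Need at least 4 points inside the fit window.", call. = FALSE)
  }
  if (any(!is.finite(v)) || any(v <= 0)) {
    stop("All values inside the fit window must be positive and finite.",
         call. = FALSE)
  }
  fit <- stats::lm(log(v) ~ t)
  k <- unname(stats::coef(fit)[2])
  v0 <- exp(unname(stats::coef(fit)[1]))
  # vcov warns on machine-precision residuals (noiseless data); harmless
  k_se <- suppressWarnings(unname(sqrt(diag(stats::vcov(fit)))[2]))
  if (isTRUE(refine_nls)) {
    nls_fit <- try(stats::nls(v ~ a * exp(b * t),
                              start = list(a = v0, b = k)), silent = TRUE)
    if (!inherits(nls_fit, "try-error")) {
      co <- stats::coef(nls_fit)
      v0 <- unname(co["a"])
      k <- unname(co["b"])
      k_se <- unname(sqrt(diag(stats::vcov(nls_fit)))["b"])
    }
  }
  pdt <- log(2) / k
  structure(
    list(
      k = k,
      pdt = pdt,
      v0 = v0,
      k_se = k_se,
      pdt_se = abs(log(2) / k^2) * k_se, # delta method
      log_residual_sd = stats::sigma(fit),
      n = length(t),
      window = c(t_start = min(t), t_end = max(t)),
      data = tibble::tibble(time = t, value = v)
    ),
    class = "growth_fit"
  )
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("<growth_fit>\n")
  cat(sprintf("  rate k  : %.5g /h (se %.3g)\n", x$k, x$k_se))
  cat(sprintf("  PDT     : %.4g h (se %.3g)\n", x$pdt, x$pdt_se))
  cat(sprintf("  V0      : %.5g\n", x$v0))
  cat(sprintf("  n, window: %d points over [%.3g, %.3g] h\n",
              x$n, x$window[1], x$window[2]))
  invisible(x)
}

#' @rdname fit_exponential
#' @param x A `growth_fit` object.
#' @param ... Unused.
#' @export
tidy.growth_fit <- function(x, ...) {
  tibble::tibble(
    term = c("k", "pdt", "v0"),
    estimate = c(x$k, x$pdt, x$v0),
    std.error = c(x$k_se, x$pdt_se, NA_real_)
  )
}

#' @rdname fit_exponential
#' @export
glance.growth_fit <- function(x, ...) {
  tibble::tibble(
    k = x$k, pdt = x$pdt, v0 = x$v0,
    log_residual_sd = x$log_residual_sd,
    nobs = x$n,
    t_start = x$window[1], t_end = x$window[2]
  )
}

# RSS of the continuous two-segment model with breakpoint psi.
# Model: y = a + b1 * x + (b2 - b1) * (x - psi)_+  (continuous at psi).
two_segment_rss <- function(x, y, psi) {
  hinge <- pmax(x - psi, 0)
  fit <- stats::lm(y ~ x + hinge)
  list(rss = sum(stats::residuals(fit)^2), fit = fit)
}

#' Continuous two-segment (breakpoint) regression
#'
#' Fits `thickness = a + slope1 * r` below the breakpoint `r*` and a second
#' slope above it, with the two segments constrained to meet at `r*`. The
#' breakpoint is found by exhaustive search over the interior observed radii,
#' then refined by golden-section minimization of the residual sum of
#' squares. If an F-test comparing the two-segment fit against a single line
#' is not significant at `alpha`, the fit falls back to a single slope and
#' the breakpoint is flagged undefined. Used for the thickness-versus-lumen-
#' radius relation of growing epithelial cysts, where thickening accelerates
#' beyond a critical lumen radius (around 40 um).
#'
#' @param radii Predictor (lumen radius, um), >= 8 distinct-spanning points.
#' @param thickness Response (cell-layer thickness, um).
#' @param alpha Significance level of the slope-change F-test. Default 0.05.
#' @param min_per_side Minimum data points strictly on each side of a
#'   candidate breakpoint. Default 3.
#' @return An object of class `breakpoint_fit`: `breakpoint` (um, `NA` on
#'   fallback), `slope1`, `slope2`, `intercept`, `residual_sd`, `p_value` of
#'   the slope change, `single_line` flag, `n`.
#' @examples
#' r <- seq(10, 80, length.out = 40)
#' th <- 10 + 0.1 * pmin(r, 40) * 0 + 0.1 * r + 0.2 * pmax(r - 40, 0)
#' fit_breakpoint(r, th)$breakpoint # 40
#' @export
fit_breakpoint <- function(radii, thickness, alpha = 0.05, min_per_side = 3) {
  stopifnot(length(radii) == length(thickness))
  keep <- is.finite(radii) & is.finite(thickness)
  x <- radii[keep]
  y <- thickness[keep]
  if (length(x) < 8) {
    stop("Need at least 8 points to fit a breakpoint model.", call. = FALSE)
  }
  if (diff(range(x)) == 0) {
    stop("All radii are equal; breakpoint model is undefined.", call. = FALSE)
  }
  one_fit <- stats::lm(y ~ x)
  rss1 <- sum(stats::residuals(one_fit)^2)

  grid <- sort(unique(x))
  grid <- grid[vapply(grid, function(g) {
    sum(x < g) >= min_per_side && sum(x > g) >= min_per_side
  }, logical(1))]
  if (length(grid) == 0) {
    stop("Too few interior points for any candidate breakpoint.",
         call. = FALSE)
  }
  grid_rss <- vapply(grid, function(g) two_segment_rss(x, y, g)$rss,
                     numeric(1))
  best <- grid[which.min(grid_rss)]

  # golden-section refinement between the neighbouring grid points
  i <- match(best, grid)
  lo <- if (i > 1) grid[i - 1] else min(x)
  hi <- if (i < length(grid)) grid[i + 1] else max(x)
  opt <- stats::optimize(function(p) two_segment_rss(x, y, p)$rss,
                         lower = lo, upper = hi, tol = 1e-6)
  psi <- if (opt$objective < min(grid_rss)) opt$minimum else best
  two <- two_segment_rss(x, y, psi)
  rss2 <- two$rss

  # F-test: 2 extra parameters (breakpoint + second slope) vs single line
  df2 <- length(x) - 4
  f_stat <- if (rss2 > 0) ((rss1 - rss2) / 2) / (rss2 / df2) else Inf
  p_value <- stats::pf(f_stat, 2, df2, lower.tail = FALSE)

  if (p_value > alpha) {
    co <- stats::coef(one_fit)
    return(structure(
      list(
        breakpoint = NA_real_,
        slope1 = unname(co[2]), slope2 = unname(co[2]),
        intercept = unname(co[1]),
        residual_sd = stats::sigma(one_fit),
        p_value = p_value, single_line = TRUE, n = length(x),
        data = tibble::tibble(radius = x, thickness = y)
      ),
      class = "breakpoint_fit"
    ))
  }
  co <- stats::coef(two$fit)
  structure(
    list(
      breakpoint = psi,
      slope1 = unname(co["x"]),
      slope2 = unname(co["x"] + co["hinge"]),
      intercept = unname(co["(Intercept)"]),
      residual_sd = sqrt(rss2 / max(df2, 1)),
      p_value = p_value, single_line = FALSE, n = length(x),
      data = tibble::tibble(radius = x, thickness = y)
    ),
    class = "breakpoint_fit"
  )
}

#' @export
print.breakpoint_fit <- function(x, ...) {
  cat("<breakpoint_fit>\n")
  if (x$single_line) {
    cat(sprintf("  single line (slope change not significant, p = %.3g)\n",
                x$p_value))
    cat(sprintf("  slope %.4g, intercept %.4g\n", x$slope1, x$intercept))
  } else {
    cat(sprintf("  breakpoint r* : %.4g um (p = %.3g)\n",
                x$breakpoint, x$p_value))
    cat(sprintf("  slopes        : %.4g -> %.4g\n", x$slope1, x$slope2))
  }
  cat(sprintf("  residual sd %.3g um on %d points\n", x$residual_sd, x$n))
  invisible(x)
}

#' @rdname fit_breakpoint
#' @param x A `breakpoint_fit` object.
#' @param ... Unused.
#' @export
tidy.breakpoint_fit <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope1", "slope2", "breakpoint"),
    estimate = c(x$intercept, x$slope1, x$slope2, x$breakpoint)
  )
}

#' @rdname fit_breakpoint
#' @export
glance.breakpoint_fit <- function(x, ...) {
  tibble::tibble(
    breakpoint = x$breakpoint,
    slope1 = x$slope1, slope2 = x$slope2,
    residual_sd = x$residual_sd,
    p_value = x$p_value,
    single_line = x$single_line,
    nobs = x$n
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
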