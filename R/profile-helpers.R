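# Shared radial-profiling machinery used by cyst and tube morphometry.

# Bilinear interpolation of a frame at fractional pixel coordinates (um).
interp_frame <- function(frame, x_um, y_um, pixel_equiv) {
  cx <- x_um / pixel_equiv + 1
  cy <- y_um / pixel_equiv + 1
  x0 <- floor(cx); y0 <- floor(cy)
  fx <- cx - x0; fy <- cy - y0
  x0 <- clamp(x0, 1, ncol(frame) - 1)
  y0 <- clamp(y0, 1, nrow(frame) - 1)
  i00 <- frame[cbind(y0, x0)]
  i01 <- frame[cbind(y0, x0 + 1)]
  i10 <- frame[cbind(y0 + 1, x0)]
  i11 <- frame[cbind(y0 + 1, x0 + 1)]
  (1 - fy) * ((1 - fx) * i00 + fx * i01) + fy * ((1 - fx) * i10 + fx * i11)
}

# Gaussian smoothing of a 1D profile (sigma in samples), edge-normalized.
gaussian_smooth <- function(v, sigma) {
  if (sigma <= 0) return(v)
  r <- ceiling(3 * sigma)
  k <- stats::dnorm(-r:r, sd = sigma)
  n <- length(v)
  padded <- c(rep(v[1], r), v, rep(v[n], r))
  stats::convolve(padded, rev(k / sum(k)), type = "filter")
}

# Parabolic sub-sample refinement of an extremum at index i of d.
refine_extremum <- function(d, i) {
  if (i <= 1 || i >= length(d)) return(i)
  denom <- d[i - 1] - 2 * d[i] + d[i + 1]
  if (abs(denom) < .Machine$double.eps) return(i)
  i + 0.5 * (d[i - 1] - d[i + 1]) / denom
}

# Inner/outer boundary from a derivative profile d (counts/um) at
# distances s: inner = strongest bright-to-dark transition (gradient
# minimum), outer = strongest dark-to-bright transition beyond it.
band_from_deriv <- function(s, d, bg, pixel_equiv, edge_margin = 3) {
  step <- s[2] - s[1]
  thresh <- 0.01 * bg # counts per um; real edges are far steeper
  i_in <- which.min(d)
  if (d[i_in] > -thresh) return(NULL)
  after <- seq(i_in, length(d))
  i_out <- after[which.max(d[after])]
  if (d[i_out] < thresh) return(NULL)
  inner <- s[1] + (refine_extremum(d, i_in) - 1) * step
  outer <- s[1] + (refine_extremum(d, i_out) - 1) * step
  if (outer > s[length(s)] - edge_margin * pixel_equiv) return(NULL)
  if (outer <= inner) return(NULL)
  c(inner = inner, outer = outer)
}

# Locate a dark band along an intensity profile sampled at distances s.
# Returns c(inner, outer) in the units of s, or NULL when no credible band
# exists or the band runs off the sampled range.
find_dark_band <- function(s, v, bg, sigma_samples = NULL, pixel_equiv = 1,
                           edge_margin = 3) {
  step <- s[2] - s[1]
  if (is.null(sigma_samples)) sigma_samples <- 2 * pixel_equiv / step
  sm <- gaussian_smooth(v, sigma_samples)
  d <- c(0, diff(sm)) / step
  band_from_deriv(s, d, bg, pixel_equiv, edge_margin)
}

# Cast all rays at once: sample profiles along `angles` from (cx, cy) out
# to max_r, smooth columnwise, and locate the dark band on each ray.
# Returns a tibble (angle, r_i, t_i, valid).
cast_rays <- function(frame, cx, cy, angles, max_r, pixel_equiv, bg) {
  s <- seq(0, max_r, by = pixel_equiv / 2)
  step <- s[2] - s[1]
  xs <- cx + outer(s, cos(angles))
  ys <- cy + outer(s, sin(angles))
  v <- matrix(interp_frame(frame, as.vector(xs), as.vector(ys),
                           pixel_equiv),
              nrow = length(s))
  sigma <- 2 * pixel_equiv / step
  r <- ceiling(3 * sigma)
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  padded <- rbind(v[rep(1, r), , drop = FALSE], v,
                  v[rep(nrow(v), r), , drop = FALSE])
  sm <- stats::filter(padded, k, sides = 2)
  sm <- sm[(r + 1):(r + length(s)), , drop = FALSE]
  d <- rbind(0, diff(sm)) / step
  purrr::map_dfr(seq_along(angles), function(j) {
    band <- band_from_deriv(s, d[, j], bg, pixel_equiv)
    if (is.null(band)) {
      tibble::tibble(angle = angles[j], r_i = NA_real_, t_i = NA_real_,
                     valid = FALSE)
    } else {
      tibble::tibble(angle = angles[j], r_i = band[["inner"]],
                     t_i = band[["outer"]] - band[["inner"]], valid = TRUE)
    }
  })
}

# Sample an intensity profile along a ray from (cx, cy) (um, physical
# coordinates) in direction `angle`, out to max_r, at half-pixel steps.
ray_profile <- function(frame, cx, cy, angle, max_r, pixel_equiv) {
  s <- seq(0, max_r, by = pixel_equiv / 2)
  x <- cx + s * cos(angle)
  y <- cy + s * sin(angle)
  list(s = s, v = interp_frame(frame, x, y, pixel_equiv))
}
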