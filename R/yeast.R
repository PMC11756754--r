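#' Estimate the incident illumination intensity
#'
#' Median intensity of the background pixels outside all capsules. The
#' median is robust to the progressive darkening caused by free-floating
#' yeast; strongly tilted illumination (which would invalidate per-pixel
#' Beer-Lambert inversion) is flagged through the background standard
#' deviation.
#'
#' @param frame Intensity matrix (counts).
#' @param capsules Capsule table ([detect_capsules()] output); pixels within
#'   `margin_um` beyond each capsule's outer radius are excluded.
#' @param pixel_equiv Pixel size, um/px.
#' @param margin_um Exclusion margin around capsules, um. Default 10.
#' @param min_background Minimum number of background pixels. Default 500.
#' @param tilt_tol Background sd / median above which the homogeneity flag
#'   is raised. Default 0.05.
#' @return A one-row tibble: `i0`, `bg_sd`, `n_background`,
#'   `inhomogeneous`.
#' @export
estimate_incident_intensity <- function(frame, capsules, pixel_equiv,
                                        margin_um = 10,
                                        min_background = 500,
                                        tilt_tol = 0.05) {
  outside <- matrix(TRUE, nrow(frame), ncol(frame))
  co <- frame_coords(ncol(frame), nrow(frame), pixel_equiv)
  for (i in seq_len(nrow(capsules))) {
    cap <- capsules[i, ]
    rho2 <- dist2_sub(co$x, co$y, cap$cx_um, cap$cy_um)
    outside <- outside & rho2 > (cap$outer_r_um + margin_um)^2
  }
  n_bg <- sum(outside)
  if (n_bg < min_background) {
    stop("Only ", n_bg, " background pixels outside capsules; need >= ",
         min_background, ".", call. = FALSE)
  }
  vals <- frame[outside]
  i0 <- stats::median(vals)
  bg_sd <- stats::sd(vals)
  tibble::tibble(
    i0 = i0, bg_sd = bg_sd, n_background = n_bg,
    inhomogeneous = bg_sd / i0 > tilt_tol
  )
}

#' Per-pixel optical depth by Beer-Lambert inversion
#'
#' Inverts the Beer-Lambert law `I = I0 * exp(-mu * d)` to a characteristic
#' absorber depth per pixel: `d = -log(I / I0) / mu`. The intensity ratio is
#' clipped to `[floor_ratio, 1]`; pixels at or above `I0` get `d = 0` and
#' pixels at the clip floor (in saturation, where depth information is lost)
#' are counted and reported.
#'
#' @param frame Intensity matrix (counts).
#' @param i0 Incident intensity, counts (> 0).
#' @param mu Absorption coefficient, per um (> 0). Default 0.05.
#' @param floor_ratio Lower clip on `I / I0`. Default `exp(-6)`.
#' @return An `optical_depth_map`: list with `depth` (matrix, um),
#'   `clipped_fraction`, `mu`, `i0`.
#' @export
optical_depth <- function(frame, i0, mu = 0.05, floor_ratio = exp(-6)) {
  stopifnot(i0 > 0, mu > 0, floor_ratio > 0, floor_ratio < 1)
  ratio <- frame / i0
  clipped <- ratio <= floor_ratio
  d <- -log(clamp(ratio, floor_ratio, 1)) / mu
  structure(
    list(depth = d, clipped_fraction = mean(clipped), mu = mu, i0 = i0),
    class = "optical_depth_map"
  )
}

#' @export
print.optical_depth_map <- function(x, ...) {
  cat(sprintf("<optical_depth_map> %d x %d px, mu = %g /um, I0 = %g, %.2f%% clipped\n",
              nrow(x$depth), ncol(x$depth), x$mu, x$i0,
              100 * x$clipped_fraction))
  invisible(x)
}

#' Integrate an optical-depth map into an aggregate volume
#'
#' Each pixel contributes an elementary volume `d * pixel_equiv^2`; their
#' sum over the aggregate mask is the aggregate volume. By default the mask
#' keeps pixels whose depth exceeds `d_floor`, which suppresses the
#' spurious positive volume that zero-mean detector noise would otherwise
#' rectify into over the large clear area of the capsule.
#'
#' @param depth_map An [optical_depth()] result (or a bare depth matrix).
#' @param pixel_equiv Pixel size, um/px.
#' @param mask Logical matrix restricting the integration (e.g. the capsule
#'   core); `NULL` for the whole map.
#' @param d_floor Depth threshold, um, applied inside `mask`. Default 5.
#' @return Volume in um^3 (0, with a warning, for an empty mask).
#' @export
aggregate_volume <- function(depth_map, pixel_equiv, mask = NULL,
                             d_floor = 5) {
  d <- if (inherits(depth_map, "optical_depth_map")) depth_map$depth
       else depth_map
  keep <- d > d_floor
  if (!is.null(mask)) keep <- keep & mask
  if (!any(keep)) {
    warning("Empty aggregate mask; volume is 0.")
    return(0)
  }
  sum(d[keep]) * pixel_equiv^2
}

#' Beer-Lambert volume series of encapsulated yeast aggregates
#'
#' For every timepoint of a single-plane time-lapse: estimate the incident
#' intensity from the out-of-capsule background (per frame, robust to
#' progressive darkening), invert Beer-Lambert to a depth map, and integrate
#' the aggregate volume inside each capsule core. Each capsule's series is
#' normalized to its first value, under which both `mu` and `i0` rescalings
#' cancel.
#'
#' @param tl A `timelapse` (single plane).
#' @param capsules Capsule table; detected on the first frame when `NULL`.
#' @param mu Absorption coefficient used for the inversion, per um.
#'   Default 0.05 (cancels in the normalized series).
#' @param d_floor Depth floor for the aggregate mask, um. Default 5.
#' @param core_fraction Fallback fraction of the capsule outer radius taken
#'   as the core integration region when the capsule table carries no
#'   measured core radius. Default 0.52.
#' @return A tibble: `capsule_id`, `time`, `volume_um3`, `norm_volume`,
#'   `clipped_fraction` (of the capsule core).
#' @export
track_yeast <- function(tl, capsules = NULL, mu = 0.05, d_floor = 5,
                        core_fraction = 0.52) {
  stopifnot(inherits(tl, "timelapse"))
  pe <- tl$pixel_equiv
  if (is.null(capsules)) {
    capsules <- detect_capsules(get_stack(tl, 1)[[1]], pe)
  }
  if (nrow(capsules) == 0) stop("No capsules found.", call. = FALSE)
  out <- purrr::map_dfr(seq_len(n_timepoints(tl)), function(i) {
    frame <- get_stack(tl, i)[[1]]
    i0 <- estimate_incident_intensity(frame, capsules, pe)$i0
    dm <- optical_depth(frame, i0, mu)
    co <- frame_coords(ncol(frame), nrow(frame), pe)
    purrr::map_dfr(seq_len(nrow(capsules)), function(ci) {
      cap <- capsules[ci, ]
      core_r <- if (!is.null(cap$core_r_um) && is.finite(cap$core_r_um)) {
        cap$core_r_um - 12 # stay clear of the blurred inner wall edge
      } else {
        core_fraction * cap$outer_r_um
      }
      rho2 <- dist2_sub(co$x, co$y, cap$cx_um, cap$cy_um)
      core <- rho2 < core_r^2
      tibble::tibble(
        capsule_id = cap$capsule_id,
        time = tl$times[i],
        volume_um3 = aggregate_volume(dm, pe, mask = core,
                                      d_floor = d_floor),
        clipped_fraction = mean((dm$depth[core]) >=
                                  -log(exp(-6)) / mu * 0.999)
      )
    })
  })
  out |>
    dplyr::group_by(.data$capsule_id) |>
    dplyr::arrange(.data$time, .by_group = TRUE) |>
    dplyr::mutate(norm_volume = .data$volume_um3 / .data$volume_um3[1]) |>
    dplyr::ungroup() |>
    dplyr::select("capsule_id", "time", "volume_um3", "norm_volume",
                  "clipped_fraction")
}

#' Doubling-time fits of yeast volume series
#'
#' Fits [fit_exponential()] to each capsule's normalized volume series from
#' `t_fit_start` on, and reports the doubling time in minutes.
#'
#' @param series Output of [track_yeast()].
#' @param t_fit_start Start of the fit window, hours (typically the end of
#'   the lag phase). Default 4.
#' @return A tibble: `capsule_id`, `doubling_min`, `k_per_h`, `n`.
#' @export
yeast_doubling_times <- function(series, t_fit_start = 4) {
  series |>
    dplyr::group_by(.data$capsule_id) |>
    dplyr::group_modify(function(df, key) {
      fit <- fit_exponential(df$time, df$norm_volume,
                             t_start = t_fit_start)
      tibble::tibble(doubling_min = fit$pdt * 60, k_per_h = fit$k,
                     n = fit$n)
    }) |>
    dplyr::ungroup()
}
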