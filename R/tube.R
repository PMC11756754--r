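#' Estimate the axis and inner diameter of a tubular capsule
#'
#' The tube wall pixels (intensity in a band between the dark cell layer and
#' the bright medium) are extracted, pixels bordering the cell layer are
#' excluded, and the axis direction is the principal direction of the wall
#' pixel cloud. Wall offsets come from the near-edge quantiles of the signed
#' normal distances on either side of the axis; their gap is the inner
#' (core) diameter.
#'
#' @param frame Intensity matrix (counts).
#' @param pixel_equiv Pixel size, um/px.
#' @param bg Background intensity; default the 75th percentile of the frame
#'   (robust when the tube occupies a large fraction of the image).
#' @return A list: `angle_rad` (in (-pi/2, pi/2]), `inner_d_um`,
#'   `wall_offsets` (signed distances of the two inner wall edges, um),
#'   `centre_um`.
#' @export
estimate_tube_axis <- function(frame, pixel_equiv, bg = NULL) {
  if (is.null(bg)) bg <- stats::quantile(frame, 0.75, names = FALSE)
  wall_mask <- frame > 0.7 * bg & frame < 0.87 * bg
  # drop the blurred rim of the cell layer, which falls in the same band
  cell <- EBImage::dilate(EBImage::Image(frame < 0.6 * bg),
                          EBImage::makeBrush(9, "disc"))
  wall_mask <- wall_mask & !(as.matrix(cell) > 0)
  px <- which(wall_mask, arr.ind = TRUE)
  if (nrow(px) < 200) {
    stop("No tube wall found (too few wall-band pixels).", call. = FALSE)
  }
  x <- (px[, 2] - 1) * pixel_equiv
  y <- (px[, 1] - 1) * pixel_equiv
  # joint PCA gives a first direction, but the two offset bands get clipped
  # differently by the frame borders, which tilts a single fit; refining
  # each band separately removes that bias
  principal_angle <- function(xx, yy) {
    u <- stats::prcomp(cbind(xx, yy))$rotation[, 1]
    atan2(u[2], u[1])
  }
  angle <- principal_angle(x, y)
  ctr <- c(mean(x), mean(y))
  for (iter in 1:2) {
    nrm <- c(-sin(angle), cos(angle))
    nd <- (x - ctr[1]) * nrm[1] + (y - ctr[2]) * nrm[2]
    pos <- nd > 0
    if (sum(pos) < 50 || sum(!pos) < 50) {
      stop("Could not find two parallel wall bands.", call. = FALSE)
    }
    a1 <- principal_angle(x[pos], y[pos])
    a2 <- principal_angle(x[!pos], y[!pos])
    # average the two band directions (directions are defined modulo pi)
    angle <- atan2(sin(2 * a1) + sin(2 * a2), cos(2 * a1) + cos(2 * a2)) / 2
  }
  if (angle <= -pi / 2) angle <- angle + pi
  if (angle > pi / 2) angle <- angle - pi
  nrm <- c(-sin(angle), cos(angle))
  nd <- (x - ctr[1]) * nrm[1] + (y - ctr[2]) * nrm[2]
  off_pos <- stats::quantile(nd[nd > 0], 0.02, names = FALSE)
  off_neg <- stats::quantile(nd[nd < 0], 0.98, names = FALSE)
  list(
    angle_rad = unname(angle),
    inner_d_um = off_pos - off_neg,
    wall_offsets = c(off_neg, off_pos),
    centre_um = ctr
  )
}

#' Measure a confined cylindrical cyst
#'
#' Segments the dark cell layer, fills the enclosed lumen, and measures the
#' solid footprint: length `L` along the tube axis, width `D` across it,
#' projected area `A`, and the projection-based volume `V = A x D`. Tip
#' (axial) and lateral (radial) cell-layer thicknesses are measured by
#' casting rays from the centroid along and across the axis and taking the
#' dark-band width at each crossing; the two free ends and the two
#' wall-contact sides are averaged separately. Measures of a cyst touching
#' the frame edge are flagged `partial`.
#'
#' @param frame Intensity matrix (counts).
#' @param axis Tube axis from [estimate_tube_axis()] (or a list with
#'   `angle_rad`).
#' @param pixel_equiv Pixel size, um/px.
#' @param bg Background intensity; default the 75th percentile.
#' @return A one-row tibble: `l_um`, `d_um`, `area_um2`, `v_um3`, `ha_um`,
#'   `hr_um`, `centroid_axial_um`, `centroid_radial_um` (centroid position
#'   projected on the axis/normal, relative to the frame centre), `partial`.
#' @export
measure_tubular_cyst <- function(frame, axis, pixel_equiv, bg = NULL) {
  if (is.null(bg)) bg <- stats::quantile(frame, 0.75, names = FALSE)
  # outer boundary at the half-amplitude of the layer/medium step
  mask <- frame < 0.72 * bg
  labels <- EBImage::bwlabel(EBImage::Image(mask))
  if (max(labels) == 0) stop("No cyst found in the frame.", call. = FALSE)
  sizes <- tabulate(as.integer(labels[labels > 0]))
  solid <- as.matrix(EBImage::fillHull(labels == which.max(sizes))) > 0
  px <- which(solid, arr.ind = TRUE)
  x <- (px[, 2] - 1) * pixel_equiv
  y <- (px[, 1] - 1) * pixel_equiv
  a <- axis$angle_rad
  u <- c(cos(a), sin(a))
  nrm <- c(-sin(a), cos(a))
  proj_u <- x * u[1] + y * u[2]
  proj_n <- x * nrm[1] + y * nrm[2]
  l_um <- diff(range(proj_u)) + pixel_equiv
  d_um <- diff(range(proj_n)) + pixel_equiv
  area <- nrow(px) * pixel_equiv^2
  cx <- mean(x); cy <- mean(y)
  partial <- any(px[, 1] %in% c(1, nrow(frame))) ||
    any(px[, 2] %in% c(1, ncol(frame)))

  band_width <- function(angle) {
    pr <- ray_profile(frame, cx, cy, angle, 0.75 * max(l_um, d_um),
                      pixel_equiv)
    band <- find_dark_band(pr$s, pr$v, bg, pixel_equiv = pixel_equiv)
    if (is.null(band)) return(NA_real_)
    band[["outer"]] - band[["inner"]]
  }
  ha <- mean(c(band_width(a), band_width(a + pi)), na.rm = TRUE)
  hr <- mean(c(band_width(a + pi / 2), band_width(a - pi / 2)), na.rm = TRUE)
  ctr_frame <- c((ncol(frame) - 1) / 2, (nrow(frame) - 1) / 2) * pixel_equiv
  tibble::tibble(
    l_um = l_um, d_um = d_um, area_um2 = area, v_um3 = area * d_um,
    ha_um = ha, hr_um = hr,
    centroid_axial_um = (cx - ctr_frame[1]) * u[1] +
      (cy - ctr_frame[2]) * u[2],
    centroid_radial_um = (cx - ctr_frame[1]) * nrm[1] +
      (cy - ctr_frame[2]) * nrm[2],
    partial = partial
  )
}

#' Track a tubular cyst across a time-lapse
#'
#' Estimates the tube axis on the first frame (capsules are static) and
#' measures the cyst on every timepoint's first plane (tubular acquisitions
#' are effectively single-plane: the cyst fills the tube core).
#'
#' @param tl A `timelapse`.
#' @param axis Optional axis (estimated from frame 1 when `NULL`).
#' @return A tibble of per-timepoint [measure_tubular_cyst()] rows with a
#'   `time` column.
#' @export
track_tube <- function(tl, axis = NULL) {
  stopifnot(inherits(tl, "timelapse"))
  pe <- tl$pixel_equiv
  if (is.null(axis)) {
    axis <- estimate_tube_axis(get_stack(tl, 1)[[1]], pe)
  }
  purrr::map_dfr(seq_len(n_timepoints(tl)), function(i) {
    dplyr::bind_cols(
      tibble::tibble(time = tl$times[i]),
      measure_tubular_cyst(get_stack(tl, i)[[1]], axis, pe)
    )
  })
}

#' Normalized trajectories of a tubular-cyst time series
#'
#' Divides each measure by its value at the first timepoint (the reference
#' time t = 0): `L/L0`, `D/D0`, `V/V0` and the tip/lateral thickness ratios
#' `ha/h0`, `hr/h0`.
#'
#' @param measures Output of [track_tube()] (>= 2 timepoints).
#' @return A tibble: `time`, `l_rel`, `d_rel`, `v_rel`, `ha_rel`, `hr_rel`.
#' @export
relative_series <- function(measures) {
  stopifnot(nrow(measures) >= 2)
  ref <- measures[1, ]
  for (col in c("l_um", "d_um", "v_um3", "ha_um", "hr_um")) {
    if (!is.finite(ref[[col]]) || ref[[col]] <= 0) {
      stop("Reference value of ", col, " at t = 0 is zero or missing.",
           call. = FALSE)
    }
  }
  tibble::tibble(
    time = measures$time,
    l_rel = measures$l_um / ref$l_um,
    d_rel = measures$d_um / ref$d_um,
    v_rel = measures$v_um3 / ref$v_um3,
    ha_rel = measures$ha_um / ref$ha_um,
    hr_rel = measures$hr_um / ref$hr_um
  )
}
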