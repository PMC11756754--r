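#' Concentric-shell volume of a lumenized cyst
#'
#' Volume of the cell layer of a spherical cyst modelled as concentric
#' spheres: `(4/3) * pi * ((r + t)^3 - r^3)` for lumen radius `r` and layer
#' thickness `t`.
#'
#' @param r Lumen radius, um (>= 0).
#' @param t Cell-layer thickness, um (>= 0).
#' @return Volume in um^3.
#' @examples
#' shell_volume(0, 50) # solid sphere of radius 50
#' shell_volume(40, 10)
#' @export
shell_volume <- function(r, t) {
  stopifnot(is.numeric(r), is.numeric(t))
  if (any(r < 0) || any(t < 0)) {
    stop("`r` and `t` must be non-negative.", call. = FALSE)
  }
  4 / 3 * pi * ((r + t)^3 - r^3)
}

#' Detect alginate capsules in a calibrated frame
#'
#' Finds the circular capsule wall rings: pixels darker than the background
#' are labelled into connected components, and components whose radial
#' extent matches a capsule wall (outer radius within `radius_range` and a
#' clear central opening) are kept. Centres come from the wall-pixel
#' centroid, which for a closed ring coincides with the circle centre.
#' Deterministic; returns capsules sorted by position.
#'
#' @param frame Intensity matrix (counts).
#' @param pixel_equiv Pixel size, um/px.
#' @param radius_range Acceptable capsule outer radius, um. Default
#'   `c(180, 280)` (nominal 225 um radius, +/-10% capsule variation plus
#'   margin).
#' @param bg Background intensity; default the frame median.
#' @return A tibble of capsule ROIs: `capsule_id`, `cx_um`, `cy_um`,
#'   `outer_r_um`. Empty when nothing is found.
#' @export
detect_capsules <- function(frame, pixel_equiv, radius_range = c(180, 280),
                            bg = NULL) {
  if (is.null(bg)) bg <- stats::median(frame)
  mask <- frame < 0.875 * bg
  if (!any(mask)) return(empty_capsules())
  labels <- EBImage::bwlabel(mask)
  n <- max(labels)
  out <- purrr::map_dfr(seq_len(n), function(id) {
    px <- which(labels == id, arr.ind = TRUE)
    if (nrow(px) < 50) return(NULL)
    cx <- mean(px[, 2] - 1) * pixel_equiv
    cy <- mean(px[, 1] - 1) * pixel_equiv
    rad <- sqrt(((px[, 2] - 1) * pixel_equiv - cx)^2 +
                  ((px[, 1] - 1) * pixel_equiv - cy)^2)
    outer_r <- stats::quantile(rad, 0.98, names = FALSE)
    core_r <- stats::quantile(rad, 0.02, names = FALSE)
    # a wall ring has an open centre; a filled blob does not
    ringness <- mean(rad > 0.5 * outer_r)
    if (outer_r < radius_range[1] || outer_r > radius_range[2]) return(NULL)
    if (ringness < 0.8) return(NULL)
    tibble::tibble(cx_um = cx, cy_um = cy, outer_r_um = outer_r,
                   core_r_um = core_r)
  })
  if (nrow(out) == 0) return(empty_capsules())
  out <- dplyr::arrange(out, .data$cy_um, .data$cx_um)
  dplyr::mutate(out, capsule_id = dplyr::row_number(),
                .before = "cx_um")
}

empty_capsules <- function() {
  tibble::tibble(capsule_id = integer(), cx_um = numeric(),
                 cy_um = numeric(), outer_r_um = numeric(),
                 core_r_um = numeric())
}

#' Radial 70-ray profile of a lumenized cyst
#'
#' Measures the cyst inside one capsule ROI by casting `n_rays` equally
#' spaced rays from the intensity-weighted centroid of the dark cell layer.
#' Along each smoothed radial intensity profile the lumen-to-layer boundary
#' is the strongest negative gradient extremum and the layer-to-medium
#' boundary the strongest positive extremum beyond it, giving a per-ray
#' lumen radius `r_i` and thickness `t_i`. The centroid is re-estimated once
#' from the mid-layer points and the rays re-cast. The shell volume uses the
#' spatially averaged radius and thickness,
#' `V = (4/3) pi ((rbar + tbar)^3 - rbar^3)`.
#'
#' Solid (pre-lumen) clusters are flagged and reported with zero lumen
#' radius and a thickness
#' equal to the equivalent radius of the dark area. Rays whose outer
#' boundary runs off the profiling range are excluded from the means and
#' counted.
#'
#' @param frame Intensity matrix (counts) at acceptable focus.
#' @param roi One capsule ROI (a row of [detect_capsules()] output, or any
#'   list with `cx_um`, `cy_um`, `outer_r_um`).
#' @param pixel_equiv Pixel size, um/px.
#' @param n_rays Number of rays. Default 70.
#' @param bg Background intensity; default the frame median.
#' @return A one-row tibble: `cx_um`, `cy_um` (cyst centroid), `r_um`,
#'   `t_um` (means over valid rays), `v_um3`, `n_valid_rays`, `pre_lumen`,
#'   and a `rays` list-column holding the per-ray tibble (`angle`, `r_i`,
#'   `t_i`, `valid`).
#' @export
profile_cyst <- function(frame, roi, pixel_equiv, n_rays = 70, bg = NULL) {
  if (is.null(bg)) bg <- stats::median(frame)
  search_r <- 0.62 * roi$outer_r_um
  if (!is.null(roi$core_r_um) && is.finite(roi$core_r_um)) {
    # keep rays off the capsule's inner wall
    search_r <- min(search_r, roi$core_r_um - 10)
  }
  co <- frame_coords(ncol(frame), nrow(frame), pixel_equiv)
  cols <- which(abs(co$x - roi$cx_um) <= search_r)
  rows <- which(abs(co$y - roi$cy_um) <= search_r)
  sub <- frame[rows, cols, drop = FALSE]
  rho2 <- dist2_sub(co$x[cols], co$y[rows], roi$cx_um, roi$cy_um)
  dark <- sub < 0.6 * bg & rho2 < search_r^2
  if (sum(dark) < 20) {
    return(cyst_profile_row(NA, NA, NA, NA, NA, 0L, FALSE, NULL))
  }
  w <- (bg - sub) * dark
  cx <- sum(outer(rep(1, length(rows)), co$x[cols]) * w) / sum(w)
  cy <- sum(outer(co$y[rows], rep(1, length(cols))) * w) / sum(w)

  # solid cluster: dark right at the centroid, no lumen yet
  ctr_val <- interp_frame(frame, cx, cy, pixel_equiv)
  if (ctr_val < 0.6 * bg) {
    area <- sum(dark) * pixel_equiv^2
    return(cyst_profile_row(cx, cy, 0, sqrt(area / pi),
                            shell_volume(0, sqrt(area / pi)),
                            0L, TRUE, NULL))
  }

  angles <- 2 * pi * (seq_len(n_rays) - 1) / n_rays
  cast <- function(cx, cy) {
    cast_rays(frame, cx, cy, angles, search_r, pixel_equiv, bg)
  }
  rays <- cast(cx, cy)
  ok <- rays$valid
  if (sum(ok) >= max(6, n_rays / 4)) {
    # re-centre on the mid-layer points and re-profile once
    mid <- rays$r_i[ok] + rays$t_i[ok] / 2
    cx2 <- cx + mean(mid * cos(rays$angle[ok]))
    cy2 <- cy + mean(mid * sin(rays$angle[ok]))
    rays <- cast(cx2, cy2)
    cx <- cx2; cy <- cy2
    ok <- rays$valid
  }
  if (sum(ok) < 3) {
    return(cyst_profile_row(cx, cy, NA, NA, NA, sum(ok), FALSE, rays))
  }
  rbar <- mean(rays$r_i[ok])
  tbar <- mean(rays$t_i[ok])
  cyst_profile_row(cx, cy, rbar, tbar, shell_volume(rbar, tbar),
                   as.integer(sum(ok)), FALSE, rays)
}

cyst_profile_row <- function(cx, cy, r, t, v, n_valid, pre_lumen, rays) {
  tibble::tibble(
    cx_um = cx, cy_um = cy, r_um = r, t_um = t, v_um3 = v,
    n_valid_rays = n_valid, pre_lumen = pre_lumen,
    rays = list(rays)
  )
}

#' Track cysts across a spherical-capsule time-lapse
#'
#' Capsules are detected once (they are adherent and the stage never moves),
#' then at every timepoint each capsule's cyst is profiled on its best-focus
#' plane ([best_plane()] within the capsule's bounding box). Detections are
#' linked over time by capsule; two cyst centroids closer than `ambiguity_um`
#' inside one capsule would be ambiguous and are flagged.
#'
#' @param tl A `timelapse`.
#' @param capsules Optional capsule table ([detect_capsules()] output); by
#'   default detected on the first page of the first stack.
#' @param n_rays Rays per profile. Default 70.
#' @param ambiguity_um Linkage ambiguity distance, um. Default 30.
#' @return A tibble with one row per cyst and timepoint: `cyst_id`, `time`,
#'   `z_um` (chosen plane), the [profile_cyst()] measures, and `flagged`.
#' @export
track_cysts <- function(tl, capsules = NULL, n_rays = 70,
                        ambiguity_um = 30) {
  stopifnot(inherits(tl, "timelapse"))
  pe <- tl$pixel_equiv
  if (is.null(capsules)) {
    capsules <- detect_capsules(get_stack(tl, 1)[[1]], pe)
  }
  if (nrow(capsules) == 0) {
    stop("No capsules to track; provide `capsules` or check the frames.",
         call. = FALSE)
  }
  out <- purrr::map_dfr(seq_len(n_timepoints(tl)), function(i) {
    stack <- get_stack(tl, i)
    purrr::map_dfr(seq_len(nrow(capsules)), function(ci) {
      cap <- capsules[ci, ]
      half <- 0.7 * cap$outer_r_um / pe
      roi <- c(cap$cx_um / pe + 1 - half, cap$cx_um / pe + 1 + half,
               cap$cy_um / pe + 1 - half, cap$cy_um / pe + 1 + half)
      if (length(stack) >= 2) {
        bp <- best_plane(stack, roi, z = tl$z_planes)
        plane <- stack[[bp$index]]
        z_sel <- bp$z
      } else {
        plane <- stack[[1]]
        z_sel <- tl$z_planes[1]
      }
      prof <- profile_cyst(plane, cap, pe, n_rays = n_rays)
      dplyr::bind_cols(
        tibble::tibble(cyst_id = cap$capsule_id, time = tl$times[i],
                       z_um = z_sel),
        prof
      )
    })
  })
  # flag ambiguous pairs: distinct cysts too close at the same timepoint
  out |>
    dplyr::group_by(.data$time) |>
    dplyr::mutate(flagged = vapply(seq_len(dplyr::n()), function(j) {
      d <- sqrt((.data$cx_um - .data$cx_um[j])^2 +
                  (.data$cy_um - .data$cy_um[j])^2)
      any(d < ambiguity_um & seq_along(d) != j, na.rm = TRUE)
    }, logical(1))) |>
    dplyr::ungroup()
}
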