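#' Synthetic bright-field scenes with ground truth
#'
#' The scene generators render ground-truthed bright-field z-stack
#' time-lapses of the three sample classes grown in hollow alginate capsules,
#' so that every measurement stage of the package can be validated by
#' ground-truth recovery without a microscope:
#'
#' * [spherical_scene()] — spherical capsules (outer diameter ~450 um, core
#'   ~300 um, each varied by about +/-10%) containing lumenized epithelial
#'   cysts: a dark cell layer of thickness `t` around a bright lumen of
#'   radius `r`, shell volume growing exponentially with a configurable
#'   population doubling time (default 15 h).
#' * [tubular_scene()] — a hollow alginate tube (outer diameter ~260 um)
#'   confining a spherocylindrical cyst that elongates axially much faster
#'   than it widens (defaults reach +90% length and +10% width in 18 h).
#' * [yeast_scene()] — capsules containing absorbing yeast aggregates;
#'   transmitted intensity follows the Beer-Lambert law
#'   `I = I0 * exp(-mu * d)` with `d` the chord length through the aggregate.
#'   Aggregate volume doubles every `tau` (default 330 min) after a lag
#'   (default 4 h).
#'
#' Photometry is relative to the incident intensity `I0`: cell layers at
#' 0.45 x I0, cyst lumens at 0.9 x I0, alginate walls at 0.8 x I0. Objects
#' away from the imaged plane are blurred with a Gaussian kernel of width
#' `sigma(z) = sigma0 + defocus_rate * |z - z_object|`; additive Gaussian
#' detector noise (default sd 2% of I0) is applied last. All randomness is
#' controlled by the scene `seed`.
#'
#' @name synthetic_scenes
NULL

scene_photometry <- function() {
  list(cell = 0.45, lumen = 0.9, wall = 0.8)
}

# piecewise-linear thickness-vs-lumen-radius law used by the growth
# partition; clamped away from zero so the epithelium never vanishes when
# the law is evaluated far from the configured starting geometry
thickness_law <- function(r, r0, t0, slope1 = 0.1, slope2 = 0.3,
                          r_break = 40) {
  hinge <- function(x) pmax(x - r_break, 0)
  pmax(t0 + slope1 * (r - r0) + (slope2 - slope1) * (hinge(r) - hinge(r0)),
       0.1)
}

# invert V(t) = V0 * 2^(t/pdt) for r, holding thickness to thickness_law(r)
cyst_radius_at <- function(time, r0, t0, pdt, slope1, slope2, r_break,
                           r_max = 160) {
  v0 <- shell_volume(r0, t0)
  target <- v0 * 2^(time / pdt)
  vol_of_r <- function(r) {
    shell_volume(r, thickness_law(r, r0, t0, slope1, slope2, r_break))
  }
  vapply(target, function(v) {
    if (v <= vol_of_r(0)) return(0)
    stats::uniroot(function(r) vol_of_r(r) - v,
                   lower = 0, upper = r_max, tol = 1e-8)$root
  }, numeric(1))
}

#' Spherical-capsule cyst scene
#'
#' @param n_capsules Number of capsules, laid out on a grid. Default 1.
#' @param pdt Population doubling time of the cyst shell volume, hours.
#'   Default 15.
#' @param r0,t0 Initial lumen radius and layer thickness, um. Defaults 30
#'   and 12.
#' @param slope1,slope2,r_break Parameters of the thickness-vs-radius growth
#'   partition: thickness grows linearly with lumen radius at `slope1`
#'   (default 0.1) and at `slope2` (default 0.3) beyond the critical radius
#'   `r_break` (default 40 um).
#' @param capsule_outer_d,capsule_core_d Nominal capsule outer and core
#'   diameters, um (each capsule varies by `capsule_var`). Defaults 450, 300.
#' @param capsule_var Fractional capsule-to-capsule size variation.
#'   Default 0.1.
#' @param cyst_z Focal depths of the cysts, um (recycled over capsules);
#'   `NULL` (default) draws them uniformly in `z_range`.
#' @param z_range Range of cyst depths when `cyst_z` is `NULL`. Default
#'   `c(0, 240)`.
#' @param pixel_equiv Sample-plane pixel size, um/px. Default 1.08 (4X).
#' @param i0 Incident intensity, counts. Default 30000.
#' @param noise_sd Detector noise sd as a fraction of `i0`. Default 0.02.
#' @param sigma0_px,defocus_rate Defocus model: in-focus blur (px) and blur
#'   growth per um of defocus (px/um). Defaults 1 and 0.05.
#' @param seed Integer seed controlling capsule variation, cyst placement
#'   and rendering noise. Default 1.
#' @return A `spherical_scene` object (also class `capsmorph_scene`).
#' @export
spherical_scene <- function(n_capsules = 1, pdt = 15, r0 = 30, t0 = 12,
                            slope1 = 0.1, slope2 = 0.3, r_break = 40,
                            capsule_outer_d = 450, capsule_core_d = 300,
                            capsule_var = 0.1,
                            cyst_z = NULL, z_range = c(0, 240),
                            pixel_equiv = 1.08, i0 = 30000, noise_sd = 0.02,
                            sigma0_px = 1, defocus_rate = 0.05, seed = 1) {
  stopifnot(n_capsules >= 1, pdt > 0, r0 >= 0, t0 > 0)
  n_cols <- ceiling(sqrt(n_capsules))
  n_rows <- ceiling(n_capsules / n_cols)
  cell_um <- capsule_outer_d * (1 + capsule_var) + 60
  width_px <- ceiling(n_cols * cell_um / pixel_equiv)
  height_px <- ceiling(n_rows * cell_um / pixel_equiv)

  caps <- with_local_seed(seed, {
    purrr::map_dfr(seq_len(n_capsules), function(i) {
      row <- (i - 1) %/% n_cols
      col <- (i - 1) %% n_cols
      tibble::tibble(
        capsule_id = i,
        cx = (col + 0.5) * cell_um,
        cy = (row + 0.5) * cell_um,
        outer_r = capsule_outer_d / 2 * stats::runif(1, 1 - capsule_var,
                                                     1 + capsule_var),
        core_r = capsule_core_d / 2 * stats::runif(1, 1 - capsule_var,
                                                   1 + capsule_var),
        # cyst sits near the capsule centre; its own focal depth below
        cyst_dx = stats::runif(1, -15, 15),
        cyst_dy = stats::runif(1, -15, 15),
        cyst_z = if (is.null(cyst_z)) {
          stats::runif(1, z_range[1], z_range[2])
        } else {
          rep(cyst_z, length.out = n_capsules)[i]
        }
      )
    })
  })

  structure(
    list(
      kind = "spherical",
      capsules = caps,
      pdt = pdt, r0 = r0, t0 = t0,
      slope1 = slope1, slope2 = slope2, r_break = r_break,
      width_px = width_px, height_px = height_px,
      pixel_equiv = pixel_equiv, i0 = i0, noise_sd = noise_sd,
      sigma0_px = sigma0_px, defocus_rate = defocus_rate,
      seed = as.integer(seed),
      cache = new.env(parent = emptyenv())
    ),
    class = c("spherical_scene", "capsmorph_scene")
  )
}

#' Tubular-capsule cyst scene
#'
#' @param angle_deg Tube axis angle from the image x-axis, degrees.
#'   Default 0.
#' @param tube_outer_d,tube_inner_d Tube outer and inner (core) diameters,
#'   um. Defaults 260 and 190.
#' @param l0,d0 Initial cyst length and width, um. Defaults 400 and 170.
#' @param length_gain,width_gain Fractional growth of length and width over
#'   `growth_window` hours; the trajectories are exponential in time.
#'   Defaults 0.9 and 0.1 over 18 h.
#' @param growth_window Hours over which the gains are realised. Default 18.
#' @param ha0,hr0 Tip (axial) and lateral (radial) cell-layer thickness, um.
#'   Defaults 16 and 16.
#' @param cyst_z Focal depth of the cyst, um. Default 0 (single-plane use).
#' @inheritParams spherical_scene
#' @return A `tubular_scene` object (also class `capsmorph_scene`).
#' @export
tubular_scene <- function(angle_deg = 0, tube_outer_d = 260,
                          tube_inner_d = 190, l0 = 400, d0 = 170,
                          length_gain = 0.9, width_gain = 0.1,
                          growth_window = 18, ha0 = 16, hr0 = 16,
                          cyst_z = 0, pixel_equiv = 1.08, i0 = 30000,
                          noise_sd = 0.02, sigma0_px = 1,
                          defocus_rate = 0.05, seed = 1) {
  stopifnot(l0 >= d0, d0 > 0, tube_inner_d > 0, ha0 > 0, hr0 > 0)
  l_max <- l0 * (1 + length_gain) * 1.15
  width_px <- ceiling((l_max + 160) / pixel_equiv)
  height_px <- ceiling((tube_outer_d + 220) / pixel_equiv)
  structure(
    list(
      kind = "tubular",
      angle = angle_deg * pi / 180,
      tube_outer_d = tube_outer_d, tube_inner_d = tube_inner_d,
      l0 = l0, d0 = d0,
      length_gain = length_gain, width_gain = width_gain,
      growth_window = growth_window,
      ha0 = ha0, hr0 = hr0, cyst_z = cyst_z,
      width_px = width_px, height_px = height_px,
      pixel_equiv = pixel_equiv, i0 = i0, noise_sd = noise_sd,
      sigma0_px = sigma0_px, defocus_rate = defocus_rate,
      seed = as.integer(seed),
      cache = new.env(parent = emptyenv())
    ),
    class = c("tubular_scene", "capsmorph_scene")
  )
}

#' Yeast-aggregate capsule scene
#'
#' @param n_capsules Number of capsules on a grid. Default 6.
#' @param tau_min Aggregate volume doubling time, minutes. Default 330.
#' @param lag_h Lag before exponential growth starts, hours. Default 4.
#' @param radius0 Initial aggregate radius, um. Default 50.
#' @param mu Absorption coefficient of the aggregate, per um. Default 0.01.
#' @inheritParams spherical_scene
#' @return A `yeast_scene` object (also class `capsmorph_scene`).
#' @export
yeast_scene <- function(n_capsules = 6, tau_min = 330, lag_h = 4,
                        radius0 = 50, mu = 0.01,
                        capsule_outer_d = 450, capsule_core_d = 300,
                        capsule_var = 0.1, pixel_equiv = 1.08, i0 = 30000,
                        noise_sd = 0.02, sigma0_px = 1, defocus_rate = 0.05,
                        seed = 1) {
  stopifnot(tau_min > 0, lag_h >= 0, radius0 > 0, mu > 0)
  n_cols <- ceiling(sqrt(n_capsules))
  n_rows <- ceiling(n_capsules / n_cols)
  cell_um <- capsule_outer_d * (1 + capsule_var) + 60
  caps <- with_local_seed(seed, {
    purrr::map_dfr(seq_len(n_capsules), function(i) {
      row <- (i - 1) %/% n_cols
      col <- (i - 1) %% n_cols
      tibble::tibble(
        capsule_id = i,
        cx = (col + 0.5) * cell_um,
        cy = (row + 0.5) * cell_um,
        outer_r = capsule_outer_d / 2 * stats::runif(1, 1 - capsule_var,
                                                     1 + capsule_var),
        core_r = capsule_core_d / 2 * stats::runif(1, 1 - capsule_var,
                                                   1 + capsule_var),
        agg_dx = stats::runif(1, -10, 10),
        agg_dy = stats::runif(1, -10, 10),
        # per-capsule biological variability of the growth rate (~5%)
        tau_min = tau_min * stats::rnorm(1, 1, 0.05)
      )
    })
  })
  structure(
    list(
      kind = "yeast",
      capsules = caps,
      tau_min = tau_min, lag_h = lag_h, radius0 = radius0, mu = mu,
      width_px = ceiling(n_cols * cell_um / pixel_equiv),
      height_px = ceiling(n_rows * cell_um / pixel_equiv),
      pixel_equiv = pixel_equiv, i0 = i0, noise_sd = noise_sd,
      sigma0_px = sigma0_px, defocus_rate = defocus_rate,
      seed = as.integer(seed),
      cache = new.env(parent = emptyenv())
    ),
    class = c("yeast_scene", "capsmorph_scene")
  )
}

#' @export
print.capsmorph_scene <- function(x, ...) {
  cat(sprintf("<%s_scene> %d x %d px @ %g um/px, I0 = %g, noise %g%%\n",
              x$kind, x$width_px, x$height_px, x$pixel_equiv, x$i0,
              100 * x$noise_sd))
  invisible(x)
}

#' Ground truth of a scene
#'
#' True object geometry and volumes at the requested times, in the units the
#' measurement stages report (um, um^2, um^3, hours).
#'
#' @param scene A scene from [spherical_scene()], [tubular_scene()] or
#'   [yeast_scene()].
#' @param times Times in hours.
#' @return A tibble; columns depend on the scene kind (lumen radius `r_um`,
#'   thickness `t_um` and shell volume `v_um3` for spherical scenes; `l_um`,
#'   `d_um`, `area_um2`, `v_um3`, `ha_um`, `hr_um` for tubular; aggregate
#'   `radius_um` and `v_um3` for yeast).
#' @export
scene_truth <- function(scene, times) {
  UseMethod("scene_truth")
}

#' @export
scene_truth.spherical_scene <- function(scene, times) {
  tidyr::crossing(scene$capsules, tibble::tibble(time = times)) |>
    dplyr::mutate(
      r_um = cyst_radius_at(.data$time, scene$r0, scene$t0, scene$pdt,
                            scene$slope1, scene$slope2, scene$r_break),
      t_um = thickness_law(.data$r_um, scene$r0, scene$t0, scene$slope1,
                           scene$slope2, scene$r_break),
      v_um3 = shell_volume(.data$r_um, .data$t_um),
      cyst_cx = .data$cx + .data$cyst_dx,
      cyst_cy = .data$cy + .data$cyst_dy
    ) |>
    dplyr::select("capsule_id", "time", "cyst_cx", "cyst_cy", "cyst_z",
                  "r_um", "t_um", "v_um3")
}

tubular_dims_at <- function(scene, time) {
  s <- time / scene$growth_window
  l <- scene$l0 * (1 + scene$length_gain)^s
  d <- scene$d0 * (1 + scene$width_gain)^s
  area <- (l - d) * d + pi * (d / 2)^2 # stadium footprint
  tibble::tibble(
    time = time, l_um = l, d_um = d, area_um2 = area,
    v_um3 = area * d, ha_um = scene$ha0, hr_um = scene$hr0
  )
}

#' @export
scene_truth.tubular_scene <- function(scene, times) {
  ctr <- frame_centre(scene)
  tubular_dims_at(scene, times) |>
    dplyr::mutate(cyst_cx = ctr[1], cyst_cy = ctr[2], cyst_z = scene$cyst_z,
                  angle_rad = scene$angle)
}

yeast_radius_at <- function(scene, time, tau_min) {
  tau_h <- tau_min / 60
  scene$radius0 * 2^(pmax(time - scene$lag_h, 0) / (3 * tau_h))
}

#' @export
scene_truth.yeast_scene <- function(scene, times) {
  tidyr::crossing(scene$capsules, tibble::tibble(time = times)) |>
    dplyr::mutate(
      radius_um = yeast_radius_at(scene, .data$time, .data$tau_min),
      v_um3 = 4 / 3 * pi * .data$radius_um^3,
      agg_cx = .data$cx + .data$agg_dx,
      agg_cy = .data$cy + .data$agg_dy
    ) |>
    dplyr::select("capsule_id", "time", "agg_cx", "agg_cy",
                  "radius_um", "v_um3")
}

frame_centre <- function(scene) {
  c(scene$width_px, scene$height_px) / 2 * scene$pixel_equiv
}

defocus_sigma <- function(scene, dz) {
  scene$sigma0_px + scene$defocus_rate * abs(dz)
}

# Multiply a transmission layer into `total`, blurred with the object's
# defocus kernel. The layer is evaluated and blurred only on a bounding box
# around the object (centre cx/cy, half-extent `extent_um`, plus blur
# margin); `layer_fn(x_um, y_um)` returns the sub-matrix of transmissions.
# Time-invariant layers (capsule/tube walls) pass a `cache_key`: the blurred
# sub-matrix is then memoized in the scene's cache environment, since the
# same wall is re-composited at every timepoint of a time-lapse.
apply_layer <- function(total, scene, cx, cy, extent_um, sigma_px,
                        layer_fn, cache_key = NULL) {
  pe <- scene$pixel_equiv
  margin <- extent_um + (6 * sigma_px + 2) * pe
  cols <- which(abs((seq_len(scene$width_px) - 1) * pe - cx) <= margin)
  rows <- which(abs((seq_len(scene$height_px) - 1) * pe - cy) <= margin)
  if (length(cols) == 0 || length(rows) == 0) return(total)
  key <- if (!is.null(cache_key) && is.environment(scene$cache)) {
    sprintf("%s-%.3f", cache_key, sigma_px)
  }
  sub_blurred <- if (!is.null(key) && !is.null(scene$cache[[key]])) {
    scene$cache[[key]]
  } else {
    sb <- blur_px(layer_fn((cols - 1) * pe, (rows - 1) * pe), sigma_px)
    if (!is.null(key)) scene$cache[[key]] <- sb
    sb
  }
  total[rows, cols] <- total[rows, cols] * sub_blurred
  total
}

# squared distance of pixels at coordinates (x_um, y_um) to a point (um^2)
dist2_sub <- function(x_um, y_um, cx, cy) {
  outer((y_um - cy)^2, (x_um - cx)^2, "+")
}

# distance of pixels to a segment through (cx, cy) at `angle`, half-length hl
seg_dist_sub <- function(x_um, y_um, cx, cy, angle, hl) {
  u <- c(cos(angle), sin(angle))
  dx <- outer(rep(1, length(y_um)), x_um - cx)
  dy <- outer(y_um - cy, rep(1, length(x_um)))
  proj <- clamp(dx * u[1] + dy * u[2], -hl, hl)
  sqrt((dx - proj * u[1])^2 + (dy - proj * u[2])^2)
}

# Transmission layer of a spherical capsule's alginate wall
wall_layer_fn <- function(cap) {
  function(x_um, y_um) {
    rho2 <- dist2_sub(x_um, y_um, cap$cx, cap$cy)
    layer <- matrix(1, length(y_um), length(x_um))
    layer[rho2 >= cap$core_r^2 & rho2 <= cap$outer_r^2] <-
      scene_photometry()$wall
    layer
  }
}

#' Render one bright-field frame of a scene
#'
#' Forward model: each object contributes a multiplicative transmission
#' layer (dark cell layers, bright lumens, faint alginate walls, or
#' Beer-Lambert attenuation for yeast aggregates); each layer is blurred
#' with the defocus kernel for its distance to the imaged plane, the layers
#' are composited onto the uniform illumination `i0`, and Gaussian detector
#' noise is added. Deterministic for a fixed scene seed, plane and time.
#'
#' @param scene A scene object.
#' @param z Imaged plane, um.
#' @param time Acquisition time, hours.
#' @param noise If `FALSE`, skip detector noise (useful for oracles).
#' @return A numeric matrix of intensities in counts (rows = image y).
#' @export
render_frame <- function(scene, z = 0, time = 0, noise = TRUE) {
  UseMethod("render_frame")
}

finish_frame <- function(scene, transmission, z, time, noise) {
  img <- transmission * scene$i0
  if (noise && scene$noise_sd > 0) {
    with_local_seed(derive_seed(scene$seed, z, time), {
      img <- img + stats::rnorm(length(img), 0, scene$noise_sd * scene$i0)
    })
  }
  # quantize to integer counts like the 16-bit detector; also matches the
  # TIFF round-trip, so in-memory and on-disk pipelines agree exactly
  img <- round(clamp(matrix(img, nrow(transmission), ncol(transmission)),
                     0, 65535))
  storage.mode(img) <- "integer"
  img
}

#' @export
render_frame.spherical_scene <- function(scene, z = 0, time = 0,
                                         noise = TRUE) {
  phot <- scene_photometry()
  truth <- scene_truth(scene, time)
  total <- matrix(1, scene$height_px, scene$width_px)
  for (i in seq_len(nrow(scene$capsules))) {
    cap <- scene$capsules[i, ]
    tr <- truth[truth$capsule_id == cap$capsule_id, ]
    dz <- z - tr$cyst_z
    # capsule wall: use the cyst depth as the capsule's sharp plane so the
    # wall ring is crisp wherever the cyst is in focus
    total <- apply_layer(total, scene, cap$cx, cap$cy, cap$outer_r,
                         defocus_sigma(scene, dz), wall_layer_fn(cap),
                         cache_key = sprintf("wall-%d", cap$capsule_id))
    r_out <- tr$r_um + tr$t_um
    if (abs(dz) < r_out) {
      out_rz <- sqrt(r_out^2 - dz^2)
      in_rz <- sqrt(max(tr$r_um^2 - dz^2, 0))
      total <- apply_layer(
        total, scene, tr$cyst_cx, tr$cyst_cy, out_rz,
        defocus_sigma(scene, dz),
        function(x_um, y_um) {
          rho2 <- dist2_sub(x_um, y_um, tr$cyst_cx, tr$cyst_cy)
          layer <- matrix(1, length(y_um), length(x_um))
          layer[rho2 <= out_rz^2] <- phot$cell
          if (in_rz > 0) layer[rho2 <= in_rz^2] <- phot$lumen
          layer
        }
      )
    }
  }
  finish_frame(scene, total, z, time, noise)
}

#' @export
render_frame.tubular_scene <- function(scene, z = 0, time = 0, noise = TRUE) {
  phot <- scene_photometry()
  ctr <- frame_centre(scene)
  dims <- tubular_dims_at(scene, time)
  sig <- defocus_sigma(scene, z - scene$cyst_z)
  co <- frame_coords(scene$width_px, scene$height_px, scene$pixel_equiv)

  # tube walls: band between inner and outer radius on both sides of the
  # axis; time-invariant, so the blurred layer is memoized per sigma
  wall_key <- sprintf("tube-wall-%.3f", sig)
  total <- if (!is.null(scene$cache[[wall_key]])) {
    scene$cache[[wall_key]]
  } else {
    axis_d <- seg_dist_sub(co$x, co$y, ctr[1], ctr[2], scene$angle, 1e6)
    wall <- matrix(1, scene$height_px, scene$width_px)
    wall[axis_d >= scene$tube_inner_d / 2 &
           axis_d <= scene$tube_outer_d / 2] <- phot$wall
    scene$cache[[wall_key]] <- blur_px(wall, sig)
    scene$cache[[wall_key]]
  }

  # cyst: outer stadium (half-width d/2) minus lumen stadium
  hl_out <- (dims$l_um - dims$d_um) / 2
  lum_r <- dims$d_um / 2 - dims$hr_um
  hl_lum <- dims$l_um / 2 - dims$ha_um - lum_r
  total <- apply_layer(
    total, scene, ctr[1], ctr[2], dims$l_um / 2, sig,
    function(x_um, y_um) {
      d_out <- seg_dist_sub(x_um, y_um, ctr[1], ctr[2], scene$angle, hl_out)
      layer <- matrix(1, length(y_um), length(x_um))
      layer[d_out <= dims$d_um / 2] <- phot$cell
      if (lum_r > 0 && hl_lum > -lum_r) {
        d_lum <- seg_dist_sub(x_um, y_um, ctr[1], ctr[2], scene$angle,
                              max(hl_lum, 0))
        layer[d_lum <= lum_r] <- phot$lumen
      }
      layer
    }
  )
  finish_frame(scene, total, z, time, noise)
}

#' @export
render_frame.yeast_scene <- function(scene, z = 0, time = 0, noise = TRUE) {
  total <- matrix(1, scene$height_px, scene$width_px)
  truth <- scene_truth(scene, time)
  sig <- defocus_sigma(scene, 0)
  for (i in seq_len(nrow(scene$capsules))) {
    cap <- scene$capsules[i, ]
    tr <- truth[truth$capsule_id == cap$capsule_id, ]
    total <- apply_layer(total, scene, cap$cx, cap$cy, cap$outer_r, sig,
                         wall_layer_fn(cap),
                         cache_key = sprintf("wall-%d", cap$capsule_id))
    # Beer-Lambert: chord length through the spherical aggregate
    total <- apply_layer(
      total, scene, tr$agg_cx, tr$agg_cy, tr$radius_um, sig,
      function(x_um, y_um) {
        rho2 <- dist2_sub(x_um, y_um, tr$agg_cx, tr$agg_cy)
        exp(-scene$mu * 2 * sqrt(pmax(tr$radius_um^2 - rho2, 0)))
      }
    )
  }
  finish_frame(scene, total, z, time, noise)
}
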