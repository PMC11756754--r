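fake_capsule <- function(cx, cy, outer_r, core_r = outer_r * 2 / 3) {
  tibble::tibble(capsule_id = 1L, cx_um = cx, cy_um = cy,
                 outer_r_um = outer_r, core_r_um = core_r)
}

test_that("incident intensity comes from the out-of-capsule median", {
  flat <- matrix(1000, 300, 300)
  caps <- fake_capsule(150, 150, 80)
  ii <- estimate_incident_intensity(flat, caps, pixel_equiv = 1)
  expect_equal(ii$i0, 1000)
  expect_false(ii$inhomogeneous)

  # darkened capsule interior does not bias the background median
  sc <- yeast_scene(n_capsules = 1, noise_sd = 0, seed = 2)
  fr <- render_frame(sc, 0, 2, noise = FALSE)
  caps2 <- detect_capsules(fr, sc$pixel_equiv)
  expect_equal(estimate_incident_intensity(fr, caps2, sc$pixel_equiv)$i0,
               sc$i0)

  # tilted illumination raises the homogeneity flag
  tilt <- matrix(rep(seq(800, 1200, length.out = 300), each = 300), 300,
                 byrow = FALSE)
  expect_true(estimate_incident_intensity(tilt, caps, 1)$inhomogeneous)

  small <- matrix(1000, 40, 40)
  expect_error(estimate_incident_intensity(small, fake_capsule(20, 20, 25), 1),
               "background")
})

test_that("optical depth inverts the Beer-Lambert law with clipping", {
  frame <- matrix(c(1000, 1000 * exp(-1), 1000 * exp(-9), 1500), 2, 2)
  dm <- optical_depth(frame, i0 = 1000, mu = 0.01)
  expect_equal(dm$depth[1, 1], 0)
  expect_equal(dm$depth[2, 1], 100)
  expect_equal(dm$depth[1, 2], 600) # clipped at the exp(-6) floor
  expect_equal(dm$depth[2, 2], 0)   # brighter than I0
  expect_equal(dm$clipped_fraction, 0.25)
  expect_error(optical_depth(frame, i0 = -5, mu = 0.01))
})

test_that("maximum optical depth of a rendered ball approaches its diameter", {
  sc <- yeast_scene(n_capsules = 1, noise_sd = 0, seed = 7)
  fr <- render_frame(sc, 0, 0, noise = FALSE)
  dm <- optical_depth(fr, sc$i0, sc$mu)
  expect_equal(max(dm$depth), 2 * sc$radius0, tolerance = 0.03)
})

test_that("aggregate volume integrates elementary pixel volumes", {
  d <- matrix(0, 60, 60)
  d[1:50] <- 100
  expect_equal(aggregate_volume(d, pixel_equiv = 1.08), 50 * 100 * 1.08^2)
  expect_warning(v0 <- aggregate_volume(matrix(0, 10, 10), 1.08), "Empty")
  expect_equal(v0, 0)
})

test_that("ball volumes are recovered within 5% over the working radius range", {
  for (R in c(40, 70, 100, 140)) {
    # keep the centre optical depth well below the clip floor at large R
    mu <- 0.005
    sc <- yeast_scene(n_capsules = 1, radius0 = R, mu = mu, noise_sd = 0,
                      capsule_outer_d = 520, capsule_core_d = 380,
                      seed = 100 + R)
    fr <- render_frame(sc, 0, 0, noise = FALSE)
    dm <- optical_depth(fr, sc$i0, mu)
    # integrate inside the capsule core only, as the tracker does: the
    # absorbing alginate wall is not part of the aggregate
    cap <- sc$capsules
    co <- frame_coords(ncol(fr), nrow(fr), sc$pixel_equiv)
    core <- dist2_sub(co$x, co$y, cap$cx, cap$cy) < (cap$core_r - 12)^2
    v <- aggregate_volume(dm, sc$pixel_equiv, mask = core, d_floor = 2)
    expect_equal(v, 4 / 3 * pi * R^3, tolerance = 0.05)
  }
})

test_that("saturated aggregates are reported and under-estimated", {
  sc <- yeast_scene(n_capsules = 1, radius0 = 100, mu = 0.05, noise_sd = 0,
                    seed = 11)
  fr <- render_frame(sc, 0, 0, noise = FALSE)
  dm <- optical_depth(fr, sc$i0, sc$mu)
  expect_gt(dm$clipped_fraction, 0)
  v <- aggregate_volume(dm, sc$pixel_equiv)
  expect_lt(v, 4 / 3 * pi * 100^3)
})

test_that("normalized series are invariant to mu and intensity rescaling", {
  sc <- yeast_scene(n_capsules = 1, seed = 15)
  tl <- make_timelapse(sc, 3, 1)$timelapse
  caps <- detect_capsules(get_stack(tl, 1)[[1]], sc$pixel_equiv)
  s1 <- track_yeast(tl, caps, mu = 0.01)
  s2 <- track_yeast(tl, caps, mu = 0.02)
  expect_equal(s2$norm_volume, s1$norm_volume, tolerance = 0.01)
  expect_equal(s2$volume_um3, s1$volume_um3 / 2, tolerance = 0.01)

  # doubled illumination with per-frame I0 re-estimation changes nothing
  tl2 <- tl
  tl2$frames <- lapply(tl$frames, function(st) list(st[[1]] * 2L))
  s3 <- track_yeast(tl2, caps, mu = 0.01)
  expect_equal(s3$norm_volume, s1$norm_volume, tolerance = 0.005)
})

test_that("noiseless growth reproduces the configured doubling law", {
  sc <- yeast_scene(n_capsules = 1, noise_sd = 0, seed = 17)
  tl <- make_timelapse(sc, 12, 1)$timelapse
  series <- track_yeast(tl, mu = sc$mu)
  tau_h <- sc$capsules$tau_min[1] / 60
  expected <- 2^(pmax(series$time - sc$lag_h, 0) / tau_h)
  expect_equal(series$norm_volume, expected, tolerance = 0.03)
  expect_true(all(series$clipped_fraction < 0.01))
  dt <- yeast_doubling_times(series, t_fit_start = sc$lag_h)
  expect_equal(dt$doubling_min, sc$capsules$tau_min[1], tolerance = 0.02)
})
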