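test_that("spherical ground truth follows the exponential shell-volume law", {
  sc <- quiet_spherical()
  tr <- scene_truth(sc, c(0, 10, 25, 48))
  v0 <- shell_volume(sc$r0, sc$t0)
  expect_equal(tr$v_um3, v0 * 2^(tr$time / sc$pdt), tolerance = 1e-6)
  # thickness stays on the piecewise-linear law in the recovered radii
  expect_equal(
    tr$t_um,
    sc$t0 + sc$slope1 * (tr$r_um - sc$r0) +
      (sc$slope2 - sc$slope1) * pmax(tr$r_um - sc$r_break, 0),
    tolerance = 1e-8
  )
})

test_that("doubling the generator PDT halves the downstream fitted rate", {
  t <- seq(0, 48, by = 3)
  k1 <- fit_exponential(t, scene_truth(quiet_spherical(pdt = 15), t)$v_um3)$k
  k2 <- fit_exponential(t, scene_truth(quiet_spherical(pdt = 30), t)$v_um3)$k
  expect_equal(k1 / k2, 2, tolerance = 1e-6)
})

test_that("rendered frames have the stated photometry", {
  sc <- quiet_spherical()
  fr <- render_frame(sc, z = 0, time = 10, noise = FALSE)
  # far corner: plain background at I0
  expect_equal(fr[1, 1], sc$i0)
  expect_equal(max(fr), sc$i0)
  tr <- scene_truth(sc, 10)
  # mid cell layer is dark, lumen centre bright
  mid <- interp_frame(fr, tr$cyst_cx + tr$r_um + tr$t_um / 2, tr$cyst_cy,
                      sc$pixel_equiv)
  expect_lt(mid / sc$i0, 0.55)
  ctr <- interp_frame(fr, tr$cyst_cx, tr$cyst_cy, sc$pixel_equiv)
  expect_gt(ctr / sc$i0, 0.85)
})

test_that("yeast pixels follow the forward Beer-Lambert attenuation", {
  sc <- yeast_scene(n_capsules = 1, noise_sd = 0, seed = 2)
  fr <- render_frame(sc, 0, 0, noise = FALSE)
  tr <- scene_truth(sc, 0)
  centre <- interp_frame(fr, tr$agg_cx, tr$agg_cy, sc$pixel_equiv)
  expected <- sc$i0 * exp(-sc$mu * 2 * tr$radius_um)
  expect_equal(centre, expected, tolerance = 0.02)
})

test_that("rendering is deterministic under the scene seed", {
  sc <- spherical_scene(seed = 5)
  f1 <- render_frame(sc, z = 40, time = 3)
  f2 <- render_frame(sc, z = 40, time = 3)
  expect_identical(f1, f2)
  # a different plane or time draws different noise
  expect_false(identical(f1, render_frame(sc, z = 80, time = 3)))
})

test_that("time-lapse layout matches the acquisition plan", {
  sc <- yeast_scene(n_capsules = 1, seed = 3)
  dir <- withr::local_tempdir()
  out <- make_timelapse(sc, duration_h = 12, cadence_h = 0.25, dir = dir)
  files <- list.files(dir, pattern = "\\.tif$")
  expect_length(files, 12 * 4 + 1) # 15-min cadence over 12 h
  expect_equal(files[1], "t0000.tif")

  sc2 <- spherical_scene(seed = 4, cyst_z = 80)
  dir2 <- withr::local_tempdir()
  make_timelapse(sc2, 0, 1.5, stack_plan = c(0, 80, 160, 240), dir = dir2)
  pages <- tiff::readTIFF(file.path(dir2, "t0000.tif"), all = TRUE)
  expect_length(pages, 4)
})

test_that("written time-lapses are byte-identical across runs", {
  sc <- spherical_scene(seed = 8)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  make_timelapse(sc, 3, 1.5, stack_plan = c(0, 80), dir = d1)
  make_timelapse(sc, 3, 1.5, stack_plan = c(0, 80), dir = d2)
  f1 <- list.files(d1, full.names = TRUE)
  f2 <- list.files(d2, full.names = TRUE)
  expect_equal(basename(f1), basename(f2))
  expect_equal(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})
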