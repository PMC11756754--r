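test_that("shell volume evaluates the concentric-sphere formula", {
  expect_equal(shell_volume(0, 50), 4 / 3 * pi * 50^3)
  expect_equal(shell_volume(0, 50), 523598.8, tolerance = 1e-6)
  expect_equal(shell_volume(40, 10), 255516.1, tolerance = 1e-6)
  expect_equal(shell_volume(30, 0), 0)
  expect_error(shell_volume(-1, 5), "non-negative")
})

test_that("shell volume matches cross-section integration and is monotone", {
  # oracle: integrate the annular cross-section area over z
  oracle <- function(r, t) {
    R <- r + t
    f <- function(z) {
      outer_a <- pmax(R^2 - z^2, 0)
      inner_a <- pmax(r^2 - z^2, 0)
      pi * (outer_a - inner_a)
    }
    stats::integrate(f, -R, R, rel.tol = 1e-10)$value
  }
  set.seed(3)
  for (i in 1:10) {
    r <- runif(1, 0, 80)
    t <- runif(1, 1, 30)
    expect_equal(shell_volume(r, t), oracle(r, t), tolerance = 1e-6)
    eps <- 0.5
    expect_gt(shell_volume(r + eps, t), shell_volume(r, t))
    expect_gt(shell_volume(r, t + eps), shell_volume(r, t))
  }
})

test_that("capsules are detected where the generator put them", {
  sc <- spherical_scene(n_capsules = 3, cyst_z = 0, noise_sd = 0.02,
                        seed = 12)
  fr <- render_frame(sc, 0, 6)
  caps <- detect_capsules(fr, sc$pixel_equiv)
  expect_equal(nrow(caps), 3)
  for (i in seq_len(3)) {
    j <- which.min((sc$capsules$cx - caps$cx_um[i])^2 +
                     (sc$capsules$cy - caps$cy_um[i])^2)
    expect_lt(abs(caps$cx_um[i] - sc$capsules$cx[j]), 5)
    expect_lt(abs(caps$cy_um[i] - sc$capsules$cy[j]), 5)
    expect_lt(abs(caps$outer_r_um[i] - sc$capsules$outer_r[j]), 5)
    expect_lt(abs(caps$core_r_um[i] - sc$capsules$core_r[j]), 5)
  }

  blank <- matrix(30000L, 200, 200)
  expect_equal(nrow(detect_capsules(blank, 1.08)), 0)
})

test_that("a full-field density of capsules is recovered", {
  sc <- spherical_scene(n_capsules = 10, cyst_z = 0, noise_sd = 0.02,
                        seed = 13)
  fr <- render_frame(sc, 0, 6)
  caps <- detect_capsules(fr, sc$pixel_equiv)
  expect_gte(nrow(caps), 10)
})

test_that("radial profiling recovers radius and thickness within a pixel", {
  sc <- quiet_spherical(seed = 21)
  sf <- spherical_frame_at(sc, time = 24)
  caps <- detect_capsules(sf$frame, sc$pixel_equiv)
  p <- profile_cyst(sf$frame, caps[1, ], sc$pixel_equiv)
  expect_equal(p$n_valid_rays, 70)
  expect_lt(abs(p$r_um - sf$truth$r_um), sc$pixel_equiv)
  expect_lt(abs(p$t_um - sf$truth$t_um), sc$pixel_equiv)
  # symmetric input: nearly constant radius across rays
  expect_lt(sd(p$rays[[1]]$r_i), sc$pixel_equiv)
  # centroid lands on the cyst centre
  expect_lt(abs(p$cx_um - sf$truth$cyst_cx), sc$pixel_equiv)
  expect_lt(abs(p$cy_um - sf$truth$cyst_cy), sc$pixel_equiv)
})

test_that("profiling is invariant under 90-degree frame rotation", {
  sc <- quiet_spherical(seed = 22)
  sf <- spherical_frame_at(sc, time = 30)
  caps <- detect_capsules(sf$frame, sc$pixel_equiv)
  p1 <- profile_cyst(sf$frame, caps[1, ], sc$pixel_equiv)
  rot <- rotate90(sf$frame)
  caps_rot <- detect_capsules(rot, sc$pixel_equiv)
  p2 <- profile_cyst(rot, caps_rot[1, ], sc$pixel_equiv)
  expect_lt(abs(p1$r_um - p2$r_um), sc$pixel_equiv)
  expect_lt(abs(p1$t_um - p2$t_um), sc$pixel_equiv)
})

test_that("solid pre-lumen clusters are flagged with an equivalent radius", {
  sc <- quiet_spherical(seed = 23, r0 = 0, t0 = 25)
  sf <- spherical_frame_at(sc, time = 0)
  caps <- detect_capsules(sf$frame, sc$pixel_equiv)
  p <- profile_cyst(sf$frame, caps[1, ], sc$pixel_equiv)
  expect_true(p$pre_lumen)
  expect_equal(p$r_um, 0)
  expect_equal(p$t_um, 25, tolerance = 0.1)
})

test_that("shell volume is recovered within 5% across random geometries", {
  set.seed(31)
  ratios <- vapply(1:20, function(i) {
    sc <- spherical_scene(
      r0 = runif(1, 20, 70), t0 = runif(1, 8, 25),
      cyst_z = 0, noise_sd = 0, seed = 1000 + i
    )
    sf <- spherical_frame_at(sc, time = 0)
    caps <- detect_capsules(sf$frame, sc$pixel_equiv)
    p <- profile_cyst(sf$frame, caps[1, ], sc$pixel_equiv)
    p$v_um3 / sf$truth$v_um3
  }, numeric(1))
  expect_true(all(ratios > 0.95 & ratios < 1.05))
})

test_that("tracking links one series per cyst across the time-lapse", {
  sc <- spherical_scene(n_capsules = 2, cyst_z = c(40, 120),
                        noise_sd = 0.02, seed = 41)
  tl <- make_timelapse(sc, duration_h = 6, cadence_h = 3,
                       stack_plan = c(0, 40, 80, 120, 160))
  res <- track_cysts(tl$timelapse)
  expect_equal(dplyr::n_distinct(res$cyst_id), 2)
  expect_equal(nrow(res), 2 * 3)
  expect_true(all(is.finite(res$v_um3)))
  expect_false(any(res$flagged))

  # single timepoint gives a series of length one
  tl1 <- make_timelapse(sc, duration_h = 0, cadence_h = 1,
                        stack_plan = c(0, 40, 80, 120, 160))
  res1 <- track_cysts(tl1$timelapse)
  expect_equal(nrow(res1), 2)
})
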