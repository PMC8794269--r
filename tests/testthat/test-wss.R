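test_that("linear-profile shear reproduces hand arithmetic on a straight wall", {
  # wall along y = 0; particle at (50, 5) moving parallel at 100 um/s
  wall <- wall_geometry(times = c(0, 0.01),
                        contours = list(list(cbind(c(0, 100), c(0, 0))),
                                        list(cbind(c(0, 100), c(0, 0)))))
  tracks <- data.frame(frame = c(1, 2), particle_id = 1,
                       x_um = c(50, 51), y_um = c(5, 5),
                       vx_um_s = 100, vy_um_s = 0)
  tr <- near_wall_shear(tracks, wall, viscosity = 1.5, near_wall_cutoff = 10)
  expect_equal(tr$samples$shear_rate[1], 20, tolerance = 1e-12)   # 100/5 s^-1
  expect_equal(tr$samples$shear_stress[1], 0.03, tolerance = 1e-12) # Pa
})

test_that("purely wall-normal motion contributes no shear under tangential projection", {
  wall <- wall_geometry(times = c(0, 0.01),
                        contours = list(list(cbind(c(0, 100), c(0, 0))),
                                        list(cbind(c(0, 100), c(0, 0)))))
  tracks <- data.frame(frame = c(1, 2), particle_id = 1,
                       x_um = 50, y_um = c(5, 5),
                       vx_um_s = 0, vy_um_s = -80)
  tr <- near_wall_shear(tracks, wall, viscosity = 1.5, near_wall_cutoff = 10)
  expect_equal(tr$samples$shear_rate[1], 0, tolerance = 1e-12)
  # under the magnitude convention the same motion does count
  tr2 <- near_wall_shear(tracks, wall, viscosity = 1.5, near_wall_cutoff = 10,
                         projection = "magnitude")
  expect_equal(tr2$samples$shear_rate[1], 80 / 5, tolerance = 1e-12)
})

test_that("near-wall estimates track the analytic Poiseuille wall shear", {
  sc <- tube_flow_scenario(n_frames = 60, seed = 13)
  mov <- generate_tube_movie(sc, render_images = FALSE)
  tr <- near_wall_shear(mov$tracks, mov$wall, viscosity = sc$viscosity)
  errs <- frame_rel_errors(tr$samples$shear_rate, mov$shear_gt$shear_rate_s)
  # linear profile at d < 0.15 R: Taylor error below 15%
  expect_lt(max(errs), 0.15)
  # missing-value handling: no qualifying particle ever becomes a zero
  expect_false(any(tr$samples$shear_rate == 0 & mov$shear_gt$shear_rate_s > 0,
                   na.rm = TRUE))
})

test_that("near-wall shear errors on degenerate input", {
  wall <- wall_geometry(times = c(0, 0.01),
                        contours = list(list(cbind(c(0, 10), c(0, 0))),
                                        list(cbind(c(0, 10), c(0, 0)))))
  # particle exactly on the wall
  on_wall <- data.frame(frame = 1, particle_id = 1, x_um = 5, y_um = 0,
                        vx_um_s = 10, vy_um_s = 0)
  expect_error(near_wall_shear(on_wall, wall, 1.5, near_wall_cutoff = 5),
               "d = 0")
  # no particle ever near the wall
  far <- data.frame(frame = 1, particle_id = 1, x_um = 5, y_um = 50,
                    vx_um_s = 10, vy_um_s = 0)
  expect_error(near_wall_shear(far, wall, 1.5, near_wall_cutoff = 5),
               "qualified")
})

test_that("flow rate from volume is exact on affine traces and validates input", {
  t <- seq(0, 1, by = 0.05)
  affine <- data.frame(t_s = t, volume_nl = 5 - 0.3 * t)
  Q <- flow_rate_from_volume(affine)
  expect_equal(Q$Q_nl_s, rep(0.3, length(t)), tolerance = 1e-12)
  const <- data.frame(t_s = t, volume_nl = rep(2, length(t)))
  expect_true(all(flow_rate_from_volume(const)$Q_nl_s == 0))
  bad <- data.frame(t_s = c(0, 0.2, 0.1), volume_nl = c(1, 2, 3))
  expect_error(flow_rate_from_volume(bad), "increasing")
  expect_error(flow_rate_from_volume(affine[1:2, ]), "3 samples")
})

test_that("parabolic wall shear does the unit bookkeeping correctly", {
  # dimensional oracle worked by hand: Q = 1 nl/s = 1e6 um^3/s, r = 10 um
  # gamma = 4e6 / (pi * 1000) s^-1 = 1273.2395...; tau = 1.5e-3 * gamma Pa
  tr <- parabolic_wall_shear(Q = 1, radius = 10, viscosity = 1.5, time = 0)
  expect_equal(tr$samples$shear_rate, 4e6 / (pi * 1e3), tolerance = 1e-12)
  expect_equal(tr$samples$shear_stress, 1.5e-3 * 4e6 / (pi * 1e3),
               tolerance = 1e-12)
  # identity in a coherent unit system
  expect_equal(poiseuille_wall_shear(pi / 4, 1), 1, tolerance = 1e-15)
  # cubic scaling in the radius
  expect_equal(poiseuille_wall_shear(1, 2), poiseuille_wall_shear(1, 1) / 8,
               tolerance = 1e-15)
  expect_error(parabolic_wall_shear(1, -1, 1.5), "radius")
})

test_that("parabolic wall shear is invariant under coherent unit rescaling", {
  # lengths x k, volumes x k^3 leave the shear rate unchanged
  k <- 1e-3 # um -> mm
  q <- c(0.5, 1, 2)
  r <- c(8, 10, 12)
  expect_equal(poiseuille_wall_shear(q * k^3, r * k),
               poiseuille_wall_shear(q, r), tolerance = 1e-12)
})

test_that("stress equals viscosity times rate at every sample of every trace", {
  sc <- tube_flow_scenario(n_frames = 40, seed = 21)
  mov <- generate_tube_movie(sc, render_images = FALSE)
  for (tr in list(near_wall_shear(mov$tracks, mov$wall, viscosity = 2.2),
                  parabolic_wall_shear(flow_rate_from_volume(mov$volume),
                                       25, viscosity = 2.2))) {
    s <- tr$samples
    expect_equal(s$shear_stress, 2.2e-3 * s$shear_rate, tolerance = 1e-12)
  }
})

test_that("envelope smoothing conserves the mean and reproduces the impulse response", {
  # impulse of value 5, halfwidth 2 -> flat 1.0 over 5 frames, sum conserved
  g <- c(rep(0, 7), 5, rep(0, 12))
  tr <- shear_trace(seq_along(g) * 0.01, g, viscosity = 1.5, method = "other")
  sm <- postprocess_trace(tr, envelope_halfwidth = 2)
  expect_equal(sort(unique(round(sm$samples$shear_rate, 12))), c(0, 1))
  expect_equal(sum(sm$samples$shear_rate == 1), 5)
  expect_equal(sum(sm$samples$shear_rate), sum(g), tolerance = 1e-12)
  expect_equal(mean(sm$samples$shear_rate), mean(g), tolerance = 1e-12)
  # halfwidth 0 is the identity
  id <- postprocess_trace(tr, envelope_halfwidth = 0)
  expect_equal(id$samples$shear_rate, g)
  # constant traces keep all aggregates at the constant
  ct <- shear_trace(1:10, rep(3, 10), 1.5, method = "other")
  sct <- summary(postprocess_trace(ct, envelope_halfwidth = 2))
  expect_equal(sct$max_rate, 3)
  expect_equal(sct$p95_rate, 3)
})

test_that("alignment shifts the periodic trace so the event lands on target", {
  g <- sin(2 * pi * (0:99) / 100) + 2
  tr <- shear_trace((0:99) * 0.005, g, 1.5, method = "other")
  # peak currently at t = 0.125 s; align it to 0.250 s
  al <- postprocess_trace(tr, align_at = 0.25, event_time = 0.125,
                          envelope_halfwidth = 0)
  expect_equal(which.max(al$samples$shear_rate), 51)
  expect_equal(al$samples$time, tr$samples$time)
})

test_that("trace comparison reports fold changes with guarded ratios", {
  g <- abs(sin(2 * pi * (0:49) / 50)) + 0.1
  a <- shear_trace((0:49) * 0.01, g, viscosity = 3, method = "other")
  b <- shear_trace((0:49) * 0.01, g, viscosity = 1, method = "other")
  cmp <- compare_traces(a, b)
  # identical kinematics, viscosities mu and mu/3: stress ratio 3, rate ratio 1
  expect_equal(cmp$max_stress_ratio, 3, tolerance = 1e-12)
  expect_equal(cmp$p95_stress_ratio, 3, tolerance = 1e-12)
  expect_equal(cmp$max_rate_ratio, 1, tolerance = 1e-12)
  self <- compare_traces(a, a)
  expect_equal(self$max_stress_ratio, 1)
  expect_true(all(self$pointwise$stress_ratio == 1))
  # halving b pointwise doubles the max ratio
  half <- shear_trace((0:49) * 0.01, g / 2, viscosity = 3, method = "other")
  expect_equal(compare_traces(a, half)$max_rate_ratio, 2, tolerance = 1e-12)
  # zero denominators become missing markers
  z <- shear_trace((0:49) * 0.01, rep(0, 50), viscosity = 3, method = "other")
  expect_true(all(is.na(compare_traces(a, z)$pointwise$stress_ratio)))
})

test_that("volume from lumen slices follows the disk summation", {
  # two unit-square slices 2 um apart: V = 2 * (10x10) * 2 um^3 -> nl
  sq <- cbind(c(0, 10, 10, 0), c(0, 0, 10, 10))
  v <- volume_from_slices(list(sq, sq), slice_spacing = 2)
  expect_equal(v, 2 * 100 * 2 / 1e6, tolerance = 1e-12)
})

test_that("shear traces round-trip through CSV", {
  path <- withr::local_tempfile(fileext = ".csv")
  tr <- parabolic_wall_shear(Q = c(1, 2, 3), radius = 10, viscosity = 1.5,
                             time = c(0, 0.1, 0.2))
  write_shear_csv(tr, path)
  back <- read_shear_csv(path)
  expect_equal(back$samples$shear_rate, tr$samples$shear_rate)
  expect_equal(back$viscosity, tr$viscosity)
  expect_equal(back$method, tr$method)
})
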