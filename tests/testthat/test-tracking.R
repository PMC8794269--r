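test_that("segmentation finds planted blobs and handles empty cases", {
  img <- matrix(0.05, 80, 120)
  centers <- cbind(x = c(20, 60, 100, 30, 90), y = c(20, 15, 60, 65, 35))
  img <- valveflow:::add_gaussian_blobs(img, centers[, 1], centers[, 2],
                                        amplitude = 1, sigma = 2)
  seg <- segment_particles(img, threshold = 0.3)
  expect_equal(nrow(seg), 5)
  # centroids within 0.5 px of ground truth (match by nearest)
  for (i in seq_len(5)) {
    d <- sqrt((seg$x_um - centers[i, 1])^2 + (seg$y_um - centers[i, 2])^2)
    expect_lt(min(d), 0.5)
  }
  # blank image and above-max threshold give empty sets, not errors
  expect_equal(nrow(segment_particles(matrix(0, 10, 10), 0.5)), 0)
  expect_equal(nrow(segment_particles(img, max(img) + 1)), 0)
  # area filters
  expect_equal(nrow(segment_particles(img, 0.3, min_area = 1e4)), 0)
  expect_equal(nrow(segment_particles(img, 0.3, max_area = 1)), 0)
})

test_that("registration of an identical pair returns a near-zero field", {
  fixed <- textured_image(n = 128)
  fld <- register_pair(fixed, fixed)
  pts <- as.matrix(expand.grid(seq(10, 117, by = 7), seq(10, 117, by = 7)))
  u <- predict(fld, pts)
  expect_lt(max(abs(u)), 0.05)
  expect_true(fld$converged)
})

test_that("registration recovers a pure translation within a quarter pixel", {
  fixed <- textured_image(n = 256)
  moving <- textured_image(dx = 2.0, dy = -1.5, n = 256)
  fld <- register_pair(fixed, moving)
  pts <- as.matrix(expand.grid(seq(20, 235, by = 5), seq(20, 235, by = 5)))
  u <- predict(fld, pts)
  expect_lt(abs(mean(u[, "ux"]) - 2.0), 0.25)
  expect_lt(abs(mean(u[, "uy"]) + 1.5), 0.25)
  # objective decreases from the zero-field start
  expect_true(all(fld$objective$final <= fld$objective$init + 1e-15))
})

test_that("registration recovers a smooth single-bump warp", {
  pair <- bump_pair(n = 256)
  fld <- register_pair(pair$fixed, pair$moving)
  pts <- as.matrix(expand.grid(seq(20, 235, by = 5), seq(20, 235, by = 5)))
  u <- predict(fld, pts)
  w <- bump_warp(pts[, 1], pts[, 2])
  epe <- sqrt((u[, "ux"] - w[, 1])^2 + (u[, "uy"] - w[, 2])^2)
  expect_lt(median(epe), 0.5)
})

test_that("the deformation model represents constant displacement exactly", {
  # partition of unity: constant control coefficients give a constant field
  fld <- structure(list(coef_x = matrix(1.7, 10, 12),
                        coef_y = matrix(-0.6, 10, 12),
                        spacing_um = 5.6, um_per_px = 1, dim = c(40, 50),
                        objective = NULL, converged = TRUE),
                   class = "deformation_field")
  pts <- as.matrix(expand.grid(seq(0, 39, by = 3.7), seq(0, 29, by = 2.3)))
  u <- predict(fld, pts)
  expect_equal(unname(u[, "ux"]), rep(1.7, nrow(pts)), tolerance = 1e-12)
  expect_equal(unname(u[, "uy"]), rep(-0.6, nrow(pts)), tolerance = 1e-12)
})

test_that("velocity estimates are equivariant under global image translation", {
  sc <- tube_flow_scenario(n_frames = 3, peak_flow = 0.6, tracer_count = 25,
                           noise_sd = 0, seed = 9)
  mov <- generate_tube_movie(sc)
  est <- track_movie(mov$images, threshold = 0.35, max_area = 100,
                     frame_interval = sc$frame_interval)
  # shift both frames down-right by whole pixels
  shift <- function(im, k) {
    out <- matrix(0.1, nrow(im), ncol(im))
    out[(k + 1):nrow(im), (k + 1):ncol(im)] <-
      im[1:(nrow(im) - k), 1:(ncol(im) - k)]
    out
  }
  est2 <- track_movie(lapply(mov$images, shift, k = 5), threshold = 0.35,
                      max_area = 100, frame_interval = sc$frame_interval)
  a <- est[est$frame == 1, ]
  b <- est2[est2$frame == 1, ]
  expect_equal(nrow(a), nrow(b))
  a <- a[order(a$x_um), ]; b <- b[order(b$x_um), ]
  expect_equal(b$x_um, a$x_um + 5, tolerance = 1e-6)
  expect_equal(b$vx_um_s, a$vx_um_s, tolerance = max(abs(a$vx_um_s)) * 0.05)
})

test_that("tracking a synthetic movie recovers velocities and flow reversal", {
  sc <- tube_flow_scenario(n_frames = 110, peak_flow = 0.6, tracer_count = 40,
                           noise_sd = 0.01, seed = 5)
  mov <- generate_tube_movie(sc)
  # velocity accuracy around the forward-flow peak (frames 21..30;
  # displacements stay below 2 px/frame)
  offset <- 20L
  est <- track_movie(mov$images[offset + (1:10)], threshold = 0.35,
                     max_area = 100, frame_interval = sc$frame_interval,
                     rel_tol = 1e-7, max_iter = 150)
  vmax <- max(sqrt(mov$tracks$vx_um_s^2 + mov$tracks$vy_um_s^2))
  yc <- 32; R <- 25
  rel <- unlist(lapply(unique(est$frame[!is.na(est$vx_um_s)]), function(k) {
    ek <- est[est$frame == k & !is.na(est$vx_um_s), ]
    tk <- mov$tracks[mov$tracks$frame == k + offset, ]
    vapply(seq_len(nrow(ek)), function(i) {
      j <- which.min((tk$x_um - ek$x_um[i])^2 + (tk$y_um - ek$y_um[i])^2)
      sp <- sqrt(tk$vx_um_s[j]^2 + tk$vy_um_s[j]^2)
      if (sp < 0.3 * vmax || abs(ek$y_um[i] - yc) > 0.7 * R) return(NA_real_)
      sqrt((ek$vx_um_s[i] - tk$vx_um_s[j])^2 +
             (ek$vy_um_s[i] - tk$vy_um_s[j])^2) / sp
    }, numeric(1))
  }))
  expect_lt(median(rel, na.rm = TRUE), 0.10)

  # static movie: all velocities ~ 0
  static <- lapply(1:3, function(i) mov$images[[1]])
  est0 <- track_movie(static, threshold = 0.35, max_area = 100,
                      frame_interval = sc$frame_interval)
  expect_lt(max(abs(c(est0$vx_um_s, est0$vy_um_s)), na.rm = TRUE),
            0.02 / sc$frame_interval) # < 0.02 px/frame

  # flow reversal (sinusoidal zero crossing at t = period/2) flips the sign
  est_f <- track_movie(mov$images[40:42], threshold = 0.35, max_area = 100,
                       frame_interval = sc$frame_interval)
  est_r <- track_movie(mov$images[90:92], threshold = 0.35, max_area = 100,
                       frame_interval = sc$frame_interval)
  vf <- mean(est_f$vx_um_s, na.rm = TRUE)
  vr <- mean(est_r$vx_um_s, na.rm = TRUE)
  expect_true(sign(vf) != sign(vr))
  expect_gt(abs(vf), 50)
  expect_gt(abs(vr), 50)
})

test_that("warm-start halving never worsens the final objective on a steady pair", {
  sc <- tube_flow_scenario(n_frames = 3, peak_flow = 0.6, tracer_count = 25,
                           noise_sd = 0.01, seed = 15)
  mov <- generate_tube_movie(sc)
  cold <- register_pair(mov$images[[2]], mov$images[[3]])
  prev <- register_pair(mov$images[[1]], mov$images[[2]])
  warm <- register_pair(mov$images[[2]], mov$images[[3]],
                        init = valveflow:::halve_field(prev))
  expect_lte(tail(warm$objective$final, 1),
             tail(cold$objective$final, 1) * 1.05)
})

test_that("track tables round-trip through CSV", {
  path <- withr::local_tempfile(fileext = ".csv")
  tracks <- data.frame(frame = c(1, 1, 2), particle_id = c(1, 2, 1),
                       x_um = c(1.5, 2.5, 3.5), y_um = c(0.5, 1.5, 2.5),
                       vx_um_s = c(10, NA, 20), vy_um_s = c(0, NA, -5))
  write_tracks_csv(tracks, path)
  expect_equal(read_tracks_csv(path), tracks)
})
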