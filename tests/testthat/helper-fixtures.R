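# Shared fixtures, all built in code at test time.

# Smooth analytic texture; `dx`, `dy` shift the scene so the displacement
# mapping a fixed frame to the shifted frame is exactly (dx, dy).
textured_image <- function(dx = 0, dy = 0, n = 256) {
  f <- function(x, y) {
    0.5 + 0.15 * sin(0.11 * x + 0.23 * y) +
      0.12 * cos(0.31 * x - 0.07 * y) +
      0.1 * sin(0.065 * x + 0.17 * y + 1)
  }
  outer(0:(n - 1), 0:(n - 1), function(y, x) f(x - dx, y - dy))
}

# Single-control-point-style smooth bump displacement (px).
bump_warp <- function(x, y, ax = 3, ay = -2, c = 128, s = 40) {
  g <- exp(-((x - c)^2 + (y - c)^2) / (2 * s^2))
  cbind(ax * g, ay * g)
}

# Fixed frame warped by the bump: F(x) = f(x + w(x)), to be registered
# against the unwarped moving frame M = f.
bump_pair <- function(n = 256) {
  f0 <- textured_image(n = n)
  fx <- function(x, y) {
    f <- function(x, y) {
      0.5 + 0.15 * sin(0.11 * x + 0.23 * y) +
        0.12 * cos(0.31 * x - 0.07 * y) +
        0.1 * sin(0.065 * x + 0.17 * y + 1)
    }
    w <- bump_warp(x, y)
    f(x + w[, 1], y + w[, 2])
  }
  fixed <- outer(0:(n - 1), 0:(n - 1), function(y, x) fx(x, y))
  list(fixed = fixed, moving = f0)
}

# Spot-image fixture with planted per-region counts {0, 12, 30, 90}, a
# 20-dot calibration region and a dot-free background region.  SNR
# (amplitude / noise sd) is 50.
spot_fixture_spec <- function(seed, noise_sd = 0.02) {
  rois <- list(
    zero = cbind(c(10, 80, 80, 10), c(10, 10, 80, 80)),
    low = cbind(c(100, 200, 200, 100), c(10, 10, 110, 110)),
    mid = cbind(c(220, 315, 315, 220), c(10, 10, 110, 110)),
    high = cbind(c(10, 150, 150, 10), c(130, 130, 270, 270)),
    calibration = cbind(c(170, 315, 315, 170), c(130, 130, 270, 270)),
    background = cbind(c(10, 315, 315, 10), c(285, 285, 350, 350)))
  spot_image_spec(c(360, 330), background_level = 0.1,
                  dot_counts = c(low = 12, mid = 30, high = 90,
                                 calibration = 20),
                  dot_amplitude = 1, dot_sigma = 1.5,
                  roi_polygons = rois, noise_sd = noise_sd, seed = seed)
}

# Run the full dot pipeline on one seeded spot fixture; returns recovered
# counts for the planted regions plus the background-only region.
recover_spot_counts <- function(seed, noise_sd = 0.02) {
  spec <- spot_fixture_spec(seed, noise_sd)
  img <- generate_spot_image(spec)
  led <- img$ledger[img$ledger$region == "calibration", ]
  cal <- data.frame(intensity = led$intensity_raw, area = led$area)
  res <- quantify_slices(list(img$image),
                         spec$roi_polygons[c("zero", "low", "mid", "high")],
                         cal, spec$roi_polygons$background)
  stats::setNames(res$count, res$region)
}

# Exhaustive signed-rank two-sided p-value over all 2^n sign assignments
# (independent oracle; n must be small and |x| tie-free).
signed_rank_p_enum <- function(x, mu = 0) {
  d <- x - mu
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.numeric(signs %*% r)
  p_lo <- mean(v_all <= v_obs)
  p_hi <- mean(v_all >= v_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# Relative errors of a per-frame estimate against the analytic wall shear,
# restricted to frames carrying meaningful flow.
frame_rel_errors <- function(est, truth, floor_frac = 0.05, frames = NULL) {
  keep <- !is.na(est) & truth > floor_frac * max(truth)
  if (!is.null(frames)) keep <- keep & seq_along(truth) %in% frames
  abs(est[keep] - truth[keep]) / truth[keep]
}
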