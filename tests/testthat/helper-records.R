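# Small synthetic records built in code for the unit tests.

# Noiseless, stationary record: gravity only, flat depth, optional device
# tilt and body pitch (radians).
gravity_record <- function(duration = 60, tilt = 0, noise = 0, depth = 0,
                           id = "grav") {
  n <- duration * 20
  a <- cbind(ax = rep(0, n), ay = rep(0, n), az = rep(1, n))
  g <- matrix(0, n, 3)
  if (tilt != 0) {
    a <- diveseg:::rotate_about_sway(a, tilt)
    g <- diveseg:::rotate_about_sway(g, tilt)
  }
  if (noise > 0) {
    a <- a + matrix(rnorm(3 * n, 0, noise), ncol = 3)
    g <- g + matrix(rnorm(3 * n, 0, noise), ncol = 3)
  }
  sensor_record(a, g, rep(depth, duration), individual_id = id)
}

# Interval frame in the layout the signal synthesizer expects.
make_intervals <- function(start, end, category, phase, d0, d1) {
  data.frame(start = start, end = end, category = category,
             .phase = phase, .d0 = d0, .d1 = d1,
             stringsAsFactors = FALSE)
}

# Square dive with distinct regimes: surface, swimming descent, bottom
# resting with an optional feeding burst, swimming ascent, surface.
square_dive_intervals <- function(surface1 = 10, descent = 20, bottom = 60,
                                  ascent = 20, surface2 = 10, depth = 5,
                                  burst = NULL) {
  t1 <- surface1; t2 <- t1 + descent; t3 <- t2 + bottom; t4 <- t3 + ascent
  rows <- list(
    make_intervals(0, t1, "StayingAtSurface", "surface", 0.05, 0.05),
    make_intervals(t1, t2, "Swimming", "descent", 0.4, depth))
  if (is.null(burst)) {
    rows <- c(rows, list(make_intervals(t2, t3, "Resting", "bottom",
                                        depth, depth)))
  } else {
    b0 <- t2 + burst[1]; b1 <- t2 + burst[2]
    rows <- c(rows, list(
      make_intervals(t2, b0, "Resting", "bottom", depth, depth),
      make_intervals(b0, b1, "Feeding", "bottom", depth, depth),
      make_intervals(b1, t3, "Resting", "bottom", depth, depth)))
  }
  rows <- c(rows, list(
    make_intervals(t3, t4, "Swimming", "ascent", depth, 0.4),
    make_intervals(t4, t4 + surface2, "StayingAtSurface", "surface",
                   0.05, 0.05)))
  do.call(rbind, rows)
}

# A quiet regime spec (no noise) for deterministic signal checks.
quiet_spec <- function() {
  spec <- default_regime_spec()
  spec$noise <- list(acc_sd = 0, gyro_sd = 0, depth_sd = 0, depth_quantum = 0)
  spec
}
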