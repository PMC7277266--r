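#' Default behavioural regime specification
#'
#' Parameterizes the synthetic-signal generator: per-category depth
#' dynamics, dynamic-acceleration and pitch-rate oscillation regimes,
#' channel noise, bout-duration distributions and the semi-Markov
#' transition weights between diving behaviours. The defaults emulate the
#' qualitative regimes of shallow-water green-turtle records: surface
#' episodes bounded by the 0.3 m / 5 s dive rule, flat low-DBA resting,
#' periodic flipper-beat swimming near 0.7 Hz, low-DBA gliding during
#' depth changes, intermittent 3 Hz pitch-rate bursts during feeding
#' (duty cycle ~50%), and irregular high-DBA scratching. Category signal
#' overlap is deliberately moderate (gliding and resting share low DBA but
#' differ in vertical speed) so the segmentation stages have real contrasts
#' to resolve.
#'
#' @return A nested list of class `regime_spec`.
#' @export
default_regime_spec <- function() {
  structure(list(
    surface = list(
      breathing_prob = 0.6,          # else StayingAtSurface
      breathing_dur = c(2, 5.5),     # s, uniform; must stay < 6 s
      staying_dur = c(6.5, 40),      # s, uniform; must stay > 6 s
      depth = 0.05                   # m, below the 0.3 m dive threshold
    ),
    dive = list(
      depth_range = c(1.5, 6),       # m, bottom depth
      entry_depth = 0.4,             # m, depth at dive start/end
      vspeed_range = c(0.25, 0.45),  # m s^-1 descent/ascent rate
      bottom_dur = c(40, 150),       # s, uniform total bottom time
      descent_modes = c(Swimming = 0.7, Gliding = 0.3),
      ascent_modes = c(Swimming = 0.6, Gliding = 0.4)
    ),
    bottom = list(
      weights = c(Resting = 0.34, Feeding = 0.22, Scratching = 0.12,
                  Swimming = 0.22, Other = 0.10),
      # log-normal bout durations (meanlog, sdlog), seconds
      dur = list(Resting = c(log(60), 0.5), Feeding = c(log(25), 0.4),
                 Scratching = c(log(20), 0.4), Swimming = c(log(20), 0.4),
                 Other = c(log(12), 0.4)),
      min_bout = 5,                  # s
      # rapid Swimming/Other alternation: behaviour switches faster than
      # the flat-stage changepoint can resolve (the two share the same
      # pitch-rate variance), the natural source of Transition bouts
      mixed_prob = 0.15,
      mixed_dur = c(12, 25),         # s, total alternation block
      mixed_piece = c(1.5, 2.5)      # s, single alternation piece
    ),
    signal = list(
      swim_freq = 0.7,   swim_amp = 0.10,   # Hz, g: flipper-beat surge
      swim_gy_amp = 0.15,                   # rad s^-1
      feed_freq = 3,     feed_gy_amp = 0.8, # pitch-rate burst
      feed_acc_amp = 0.03, feed_duty_block = 2,  # s on / s off
      feed_off_frac = 0.35,  # residual handling movement between grabs
      scratch_acc_sd = 0.12, scratch_gyro_sd = 0.5,
      other_gx_amp = 0.35, other_freq = 0.3,
      other_gy_amp = 0.15,  # matches the swimming pitch-rate variance, so
                            # the variance-only flat stage cannot separate
                            # adjacent Swimming/Other bouts (a real source
                            # of Transition segments)
      breath_az_amp = 0.06, breath_freq = 0.5,
      surface_sway_amp = 0.02,
      pitch_angle = 0.35                    # rad body pitch on ramps
    ),
    noise = list(acc_sd = 0.01, gyro_sd = 0.02, depth_sd = 0.03,
                 depth_quantum = 0.2)       # 0.2 m sensor accuracy
  ), class = "regime_spec")
}

rln <- function(p) stats::rlnorm(1, p[1], p[2])

#' Sample a semi-Markov behaviour sequence
#'
#' Generates ground-truth behaviour intervals tiling `[0, duration)`:
#' dive cycles (surface bout, descent, bottom bouts, ascent) drawn from the
#' regime spec, with every dive bracketed by surface bouts and the
#' remainder of the record padded with a final surface bout. Bottom
#' behaviours follow the spec's transition weights without immediate
#' self-repeats. Besides the `(start, end, category)` interval columns the
#' result carries the generator's phase and depth waypoints (columns
#' `.phase`, `.d0`, `.d1`) that [synthesize_signals()] turns into a depth
#' profile.
#'
#' @param spec A `regime_spec`.
#' @param duration Record duration (s).
#' @param seed Integer seed.
#' @return A `data.frame` of intervals with generator columns.
#' @export
sample_behavior_sequence <- function(spec = default_regime_spec(),
                                     duration = 3600, seed = 1) {
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  set.seed(seed)
  rows <- list()
  push <- function(t0, t1, cat, phase, d0, d1) {
    rows[[length(rows) + 1]] <<- data.frame(
      start = t0, end = t1, category = cat, .phase = phase,
      .d0 = d0, .d1 = d1, stringsAsFactors = FALSE)
  }
  t <- 0
  su <- spec$surface; dv <- spec$dive; bt <- spec$bottom
  repeat {
    # surface bout
    if (stats::runif(1) < su$breathing_prob) {
      sdur <- stats::runif(1, su$breathing_dur[1], su$breathing_dur[2])
      scat <- "Breathing"
    } else {
      sdur <- stats::runif(1, su$staying_dur[1], su$staying_dur[2])
      scat <- "StayingAtSurface"
    }
    # plan the next dive to know whether the whole cycle fits
    D <- stats::runif(1, dv$depth_range[1], dv$depth_range[2])
    v1 <- stats::runif(1, dv$vspeed_range[1], dv$vspeed_range[2])
    v2 <- stats::runif(1, dv$vspeed_range[1], dv$vspeed_range[2])
    desc_dur <- (D - dv$entry_depth) / v1
    asc_dur <- (D - dv$entry_depth) / v2
    bot_dur <- stats::runif(1, dv$bottom_dur[1], dv$bottom_dur[2])
    cycle <- sdur + desc_dur + bot_dur + asc_dur
    if (t + cycle + 1 > duration) {
      # pad the remainder with a final surface bout and stop
      if (duration - t > 1e-9) {
        cat_pad <- if (duration - t <= su$breathing_dur[2]) "Breathing"
                   else "StayingAtSurface"
        push(t, duration, cat_pad, "surface", su$depth, su$depth)
      }
      break
    }
    push(t, t + sdur, scat, "surface", su$depth, su$depth)
    t <- t + sdur
    dmode <- sample(names(dv$descent_modes), 1, prob = dv$descent_modes)
    push(t, t + desc_dur, dmode, "descent", dv$entry_depth, D)
    t <- t + desc_dur
    # bottom: semi-Markov bouts, no immediate self-repeat
    bend <- t + bot_dur
    prev <- NA_character_
    while (t < bend - 1e-9) {
      if (!is.null(bt$mixed_prob) && stats::runif(1) < bt$mixed_prob &&
          bend - t > bt$mixed_dur[1] + bt$min_bout) {
        # rapid alternation block
        mend <- t + stats::runif(1, bt$mixed_dur[1],
                                 min(bt$mixed_dur[2], bend - t - bt$min_bout))
        pair <- c("Swimming", "Other")
        k <- sample(1:2, 1)
        while (t < mend - 1e-9) {
          pdur <- min(stats::runif(1, bt$mixed_piece[1], bt$mixed_piece[2]),
                      mend - t)
          push(t, t + pdur, pair[k], "bottom", D, D)
          t <- t + pdur
          k <- 3 - k
        }
        prev <- pair[3 - k]
        next
      }
      w <- bt$weights
      if (!is.na(prev) && length(w[w > 0]) > 1) w[prev] <- 0
      if (all(w <= 0)) w <- bt$weights
      cat_b <- sample(names(w), 1, prob = w)
      bdur <- max(bt$min_bout, rln(bt$dur[[cat_b]]))
      if (t + bdur > bend - bt$min_bout) bdur <- bend - t  # absorb remainder
      push(t, t + bdur, cat_b, "bottom", D, D)
      t <- t + bdur
      prev <- cat_b
    }
    amode <- sample(names(dv$ascent_modes), 1, prob = dv$ascent_modes)
    push(t, t + asc_dur, amode, "ascent", D, dv$entry_depth)
    t <- t + asc_dur
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Synthesize 20 Hz IMU and 1 Hz depth signals for a behaviour sequence
#'
#' Builds the multi-rate logger channels implied by the interval sequence:
#' a gravity vector oriented by the body pitch (pitched down on descents,
#' up on ascents), per-category dynamic oscillations and noise, a depth
#' profile following the intervals' waypoints, quantized to the sensor's
#' 0.2 m accuracy, and finally the device-tilt rotation applied to both the
#' accelerometer and the gyroscope (so that preprocessing must undo it).
#'
#' @param intervals Output of [sample_behavior_sequence()].
#' @param spec A `regime_spec`.
#' @param tilt Device tilt angle (radians) about the sway axis.
#' @param seed Integer seed.
#' @param individual_id Identifier stored in the record.
#' @return A `sensor_record` (raw, i.e. tilted and unprocessed).
#' @export
synthesize_signals <- function(intervals, spec = default_regime_spec(),
                               tilt = 0, seed = 1, individual_id = "sim") {
  set.seed(seed)
  duration <- max(intervals$end)
  n <- round(duration * 20)
  tm <- (seq_len(n) - 1) / 20
  sg <- spec$signal
  if (is.null(intervals$.phase)) {
    intervals$.phase <- ifelse(intervals$category %in% surface_categories(),
                               "surface", "bottom")
    intervals$.d0 <- ifelse(intervals$.phase == "surface",
                            spec$surface$depth, 3)
    intervals$.d1 <- intervals$.d0
  }
  depth_c <- numeric(n)
  ax <- numeric(n); ay <- numeric(n); az <- numeric(n)
  gx <- numeric(n); gy <- numeric(n); gz <- numeric(n)
  pitch <- numeric(n)
  for (i in seq_len(nrow(intervals))) {
    sel <- tm >= intervals$start[i] - 1e-9 & tm < intervals$end[i] - 1e-9
    if (!any(sel)) next
    tau <- tm[sel] - intervals$start[i]
    len <- intervals$end[i] - intervals$start[i]
    depth_c[sel] <- intervals$.d0[i] +
      (intervals$.d1[i] - intervals$.d0[i]) * tau / len
    ph <- intervals$.phase[i]
    pitch[sel] <- if (ph == "descent") -sg$pitch_angle
                  else if (ph == "ascent") sg$pitch_angle else 0
    cat_i <- intervals$category[i]
    if (cat_i == "Swimming") {
      ax[sel] <- ax[sel] + sg$swim_amp * sin(2 * pi * sg$swim_freq * tau)
      az[sel] <- az[sel] +
        0.6 * sg$swim_amp * sin(2 * pi * sg$swim_freq * tau + 1)
      gy[sel] <- gy[sel] + sg$swim_gy_amp * sin(2 * pi * sg$swim_freq * tau)
    } else if (cat_i == "Feeding") {
      mask <- ifelse((floor(tau / sg$feed_duty_block) %% 2) == 0, 1,
                     sg$feed_off_frac)
      osc <- sin(2 * pi * sg$feed_freq * tau) * mask
      gy[sel] <- gy[sel] + sg$feed_gy_amp * osc
      gx[sel] <- gx[sel] + 0.3 * sg$feed_gy_amp *
        sin(2 * pi * sg$feed_freq * tau + 0.7) * mask
      ax[sel] <- ax[sel] + sg$feed_acc_amp * osc
      ay[sel] <- ay[sel] + sg$feed_acc_amp *
        sin(2 * pi * sg$feed_freq * tau + 1.1) * mask
    } else if (cat_i == "Scratching") {
      m <- sum(sel)
      ax[sel] <- ax[sel] + stats::rnorm(m, 0, sg$scratch_acc_sd)
      ay[sel] <- ay[sel] + stats::rnorm(m, 0, sg$scratch_acc_sd)
      az[sel] <- az[sel] + stats::rnorm(m, 0, sg$scratch_acc_sd)
      gx[sel] <- gx[sel] + stats::rnorm(m, 0, sg$scratch_gyro_sd)
      gy[sel] <- gy[sel] + stats::rnorm(m, 0, sg$scratch_gyro_sd)
      gz[sel] <- gz[sel] + stats::rnorm(m, 0, sg$scratch_gyro_sd)
    } else if (cat_i == "Other") {
      gx[sel] <- gx[sel] + sg$other_gx_amp * sin(2 * pi * sg$other_freq * tau)
      gy[sel] <- gy[sel] + sg$other_gy_amp *
        sin(2 * pi * sg$other_freq * tau + 0.3)
      ay[sel] <- ay[sel] + 0.05 * sin(2 * pi * sg$other_freq * tau)
      gz[sel] <- gz[sel] + 0.2 * sin(2 * pi * sg$other_freq * tau + 0.5)
    } else if (cat_i == "Breathing") {
      az[sel] <- az[sel] + sg$breath_az_amp * sin(2 * pi * sg$breath_freq * tau)
    } else if (cat_i == "StayingAtSurface") {
      ax[sel] <- ax[sel] + sg$surface_sway_amp * sin(2 * pi * 0.25 * tau)
    }
    # Resting and Gliding: no dynamic component beyond noise
  }
  # gravity in the body frame, oriented by body pitch
  ax <- ax + sin(pitch)
  az <- az + cos(pitch)
  no <- spec$noise
  a <- cbind(ax, ay, az) +
    matrix(stats::rnorm(3 * n, 0, no$acc_sd), ncol = 3)
  g <- cbind(gx, gy, gz) +
    matrix(stats::rnorm(3 * n, 0, no$gyro_sd), ncol = 3)
  # device tilt: rotate the body-frame signals into the logger frame
  a <- rotate_about_sway(a, tilt)
  g <- rotate_about_sway(g, tilt)
  # 1 Hz depth: mid-second sample, noise, 0.2 m quantization
  n1 <- round(duration)
  tdep <- pmin((seq_len(n1) - 1) + 0.5, duration - 1e-6)
  di <- pmin(n, floor(tdep * 20) + 1)
  depth <- depth_c[di] + stats::rnorm(n1, 0, no$depth_sd)
  if (no$depth_quantum > 0)
    depth <- round(depth / no$depth_quantum) * no$depth_quantum
  depth <- pmax(depth, 0)
  sensor_record(a, g, depth, imu_rate = 20,
                individual_id = individual_id)
}

#' Generate a synthetic multi-individual dataset
#'
#' Draws `n` individuals with independent per-individual seeds derived from
#' the master seed, a random device tilt within +/-35 degrees each, and
#' heterogeneous diving-behaviour prevalence (log-normal jitter of the
#' bottom-behaviour weights, with one individual expressing Scratching at
#' roughly an order of magnitude above the base weight) so that the
#' split-representation filter of the validation protocol has something to
#' filter.
#'
#' @param n Number of individuals (default 13).
#' @param mean_duration Mean record duration (s); individual durations vary
#'   uniformly within +/-20%.
#' @param spec A `regime_spec`.
#' @param seed Master seed.
#' @return List of class `synthetic_dataset` with `records` (raw
#'   `sensor_record`s), `intervals` (ground-truth interval frames), `tilts`
#'   (radians), `seed` and `spec`.
#' @export
make_dataset <- function(n = 13, mean_duration = 3600,
                         spec = default_regime_spec(), seed = 42) {
  if (n < 2) stop("need at least two individuals", call. = FALSE)
  set.seed(seed)
  tilts <- stats::runif(n, -35, 35) * pi / 180
  durations <- round(mean_duration * stats::runif(n, 0.8, 1.2))
  sub_seeds <- sample.int(2^30, n)
  jitter <- matrix(stats::rlnorm(n * length(spec$bottom$weights), 0, 0.5),
                   nrow = n)
  scratcher <- sample.int(n, 1)
  feeder_boost <- sample.int(n, 2)   # a couple of feeding-heavy individuals
  records <- vector("list", n)
  intervals <- vector("list", n)
  ids <- sprintf("ind%02d", seq_len(n))
  for (i in seq_len(n)) {
    spec_i <- spec
    w <- spec$bottom$weights * jitter[i, ]
    if (i == scratcher) {
      # the scratching specialist: more and markedly longer scratching bouts
      w["Scratching"] <- w["Scratching"] * 10
      spec_i$bottom$dur$Scratching[1] <- spec$bottom$dur$Scratching[1] + log(3)
    }
    if (i %in% feeder_boost) w["Feeding"] <- w["Feeding"] * 3
    spec_i$bottom$weights <- w / sum(w)
    iv <- sample_behavior_sequence(spec_i, durations[i], seed = sub_seeds[i])
    records[[i]] <- synthesize_signals(iv, spec_i, tilt = tilts[i],
                                       seed = sub_seeds[i] %% 2^30 + 1,
                                       individual_id = ids[i])
    intervals[[i]] <- iv
  }
  structure(list(records = stats::setNames(records, ids),
                 intervals = stats::setNames(intervals, ids),
                 tilts = stats::setNames(tilts, ids),
                 seed = seed, spec = spec),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("<synthetic_dataset>", length(x$records), "individuals, seed",
      x$seed, "\n")
  durs <- vapply(x$records, record_duration, numeric(1))
  cat(sprintf("  durations: %.0f-%.0f s (total %.1f h)\n",
              min(durs), max(durs), sum(durs) / 3600))
  invisible(x)
}

#' Run the full pipeline on one synthetic individual
#'
#' Convenience wrapper: preprocess the raw record, segment it, assign
#' ground truth from the simulated intervals and build the feature table.
#'
#' @param record A raw `sensor_record`.
#' @param intervals The matching ground-truth intervals.
#' @param cfg A `diveseg_config`.
#' @return A `feature_table`.
#' @export
process_individual <- function(record, intervals, cfg = diveseg_config()) {
  rec <- preprocess_record(record, cfg)
  seg <- segment_record(rec, cfg)
  seg <- assign_ground_truth(seg, intervals, cfg)
  featurize_segments(seg, rec, cfg)
}

#' Pipeline feature tables for a whole synthetic dataset
#'
#' @param dataset A `synthetic_dataset`.
#' @param cfg A `diveseg_config`.
#' @return A pooled `feature_table` over all individuals.
#' @export
process_dataset <- function(dataset, cfg = diveseg_config()) {
  out <- lapply(seq_along(dataset$records), function(i)
    process_individual(dataset$records[[i]], dataset$intervals[[i]], cfg))
  res <- do.call(rbind, out)
  class(res) <- c("feature_table", "data.frame")
  res
}
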