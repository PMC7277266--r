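test_that("dive detection applies the 0.3 m / 5 s rule and tiles the span", {
  cfg <- diveseg_config()
  out <- detect_dives(rep(0, 100), cfg)
  expect_equal(nrow(out), 1)
  expect_equal(out$kind, "surface")
  expect_equal(c(out$start, out$end), c(0, 100))

  d <- c(rep(0, 10), rep(1, 20), rep(0, 10))
  out <- detect_dives(d, cfg)
  expect_equal(out$kind, c("surface", "dive", "surface"))
  expect_equal(out$start, c(0, 10, 30))
  expect_equal(out$end, c(10, 30, 40))

  # 3 s excursion above threshold fails the 5 s rule -> absorbed
  d2 <- c(rep(0, 10), rep(0.5, 3), rep(0, 10))
  out2 <- detect_dives(d2, cfg)
  expect_equal(nrow(out2), 1)
  expect_equal(out2$kind, "surface")

  # tiling on random depth traces
  set.seed(2)
  for (i in 1:10) {
    d3 <- pmax(0, cumsum(rnorm(200, 0, 0.3)))
    out3 <- detect_dives(d3, cfg)
    expect_equal(out3$start[1], 0)
    expect_equal(out3$end[nrow(out3)], 200)
    if (nrow(out3) > 1)
      expect_equal(out3$start[-1], out3$end[-nrow(out3)])
  }
})

test_that("the 6 s surface rule maps durations to Breathing/StayingAtSurface", {
  cfg <- diveseg_config()
  expect_equal(classify_surface(3, cfg), "Breathing")
  expect_equal(classify_surface(30, cfg), "StayingAtSurface")
  expect_equal(classify_surface(6, cfg), "Breathing")   # boundary: <= 6 s
})

test_that("a square dive is cut near the true regime switches", {
  iv <- square_dive_intervals(descent = 20, bottom = 60, ascent = 20)
  rec <- preprocess_record(synthesize_signals(iv, default_regime_spec(),
                                              tilt = 0.2, seed = 31))
  seg <- segment_record(rec)
  dive <- seg[seg$kind != "surface", ]
  expect_gte(nrow(dive), 3)
  expect_setequal(unique(dive$kinematic_tag) %in%
                    c("ascending", "descending", "flat"), TRUE)
  # boundaries of descent->bottom (t=30) and bottom->ascent (t=90)
  bounds <- sort(unique(c(dive$start, dive$end)))
  expect_lte(min(abs(bounds - 30)), 3)
  expect_lte(min(abs(bounds - 90)), 3)
})

test_that("a pitch-rate burst inside a flat dive is isolated by the
           variance stage", {
  iv <- square_dive_intervals(bottom = 60, burst = c(25, 35))
  rec <- preprocess_record(synthesize_signals(iv, default_regime_spec(),
                                              tilt = 0, seed = 17))
  seg <- segment_record(rec)
  bounds <- sort(unique(c(seg$start, seg$end)))
  expect_lte(min(abs(bounds - 55)), 1)   # burst start 30 + 25
  expect_lte(min(abs(bounds - 65)), 1)   # burst end
})

test_that("a DBA step inside a descent is split by the meanvar stage", {
  # swimming then gliding on one continuous descent ramp
  iv <- rbind(
    make_intervals(0, 10, "StayingAtSurface", "surface", 0.05, 0.05),
    make_intervals(10, 22, "Swimming", "descent", 0.4, 4),
    make_intervals(22, 34, "Gliding", "descent", 4, 7.6),
    make_intervals(34, 94, "Resting", "bottom", 7.6, 7.6),
    make_intervals(94, 114, "Swimming", "ascent", 7.6, 0.4),
    make_intervals(114, 124, "StayingAtSurface", "surface", 0.05, 0.05))
  rec <- preprocess_record(synthesize_signals(iv, default_regime_spec(),
                                              tilt = 0, seed = 8))
  seg <- segment_record(rec)
  bounds <- sort(unique(c(seg$start, seg$end)))
  expect_lte(min(abs(bounds - 22)), 1)
  glide <- seg[seg$start >= 21 & seg$end <= 35 & seg$kind != "surface", ]
  expect_gte(nrow(glide), 1)
})

test_that("ground-truth labelling follows the 3/5 majority rule", {
  cfg <- diveseg_config()
  seg <- data.frame(individual_id = "x", start = c(0, 10, 20, 30),
                    end = c(10, 20, 30, 40),
                    kind = "dive-flat", kinematic_tag = "flat",
                    ground_truth = NA_character_, predicted = NA_character_)
  iv <- behavior_intervals(
    start = c(0, 15, 27, 30),
    end = c(15, 27, 30, 40),
    category = c("Feeding", "Swimming", "Resting", "Resting"))
  out <- assign_ground_truth(seg, iv, cfg)
  expect_equal(out$ground_truth[1], "Feeding")      # fully inside
  expect_equal(out$ground_truth[2], "Transition")   # 50/50 split
  expect_equal(out$ground_truth[3], "Swimming")     # 70/30
  expect_equal(out$ground_truth[4], "Resting")

  # exactly 3/5 counts as the category
  seg2 <- seg[1, ]
  iv2 <- behavior_intervals(c(0, 6), c(6, 10), c("Gliding", "Resting"))
  expect_equal(assign_ground_truth(seg2, iv2, cfg)$ground_truth, "Gliding")

  # uncovered time counts as Other
  seg3 <- seg[1, ]
  iv3 <- behavior_intervals(0, 3, "Feeding")
  expect_equal(assign_ground_truth(seg3, iv3, cfg)$ground_truth, "Other")
})

test_that("segments tile the record exactly and surface bouts never carry
           dive categories", {
  iv <- sample_behavior_sequence(duration = 900, seed = 12)
  rec <- preprocess_record(synthesize_signals(iv, tilt = 0.3, seed = 13))
  seg <- segment_record(rec)
  expect_equal(seg$start[1], 0)
  expect_equal(seg$end[nrow(seg)], record_duration(rec))
  expect_equal(seg$start[-1], seg$end[-nrow(seg)], tolerance = 1e-9)
  expect_true(all(seg$kinematic_tag[seg$kind == "surface"] %in%
                    surface_categories()))
  expect_true(all(!seg$kinematic_tag[seg$kind != "surface"] %in%
                    surface_categories()))
})

test_that("raising the depth penalty never increases depth-stage segments", {
  set.seed(6)
  agg <- c(rnorm(10, 1), rnorm(10, 4), rnorm(10, 2))  # 3 s window means
  counts <- vapply(c(1, 5, 20, 100), function(p)
    length(pelt(agg, "mean", p)$changepoints), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("most segments on well-separated simulated regimes are label-pure", {
  iv <- sample_behavior_sequence(duration = 1200, seed = 41)
  rec <- preprocess_record(synthesize_signals(iv, tilt = -0.2, seed = 42))
  seg <- segment_record(rec)
  seg <- assign_ground_truth(seg,
                             behavior_intervals(iv$start, iv$end, iv$category))
  expect_gte(mean(seg$ground_truth != "Transition"), 0.9)
})
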