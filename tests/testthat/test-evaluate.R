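test_that("split enumeration counts combinations and orders them
           deterministically", {
  ids13 <- sprintf("ind%02d", 1:13)
  sp <- enumerate_splits(ids13, 4)
  expect_length(sp, choose(13, 4))    # the 715 possible combinations
  expect_length(enumerate_splits(c("a", "b", "c"), 1), 3)
  one <- enumerate_splits(c("a", "b", "c"), 0)
  expect_length(one, 1)
  expect_equal(one[[1]]$train, c("a", "b", "c"))
  expect_error(enumerate_splits(c("a", "b"), 2), "below the number")
  expect_identical(sp[[1]]$test, ids13[1:4])   # lexicographic order
  # train and test always partition the ids
  for (s in sp[c(1, 300, 715)])
    expect_setequal(c(s$train, s$test), ids13)
})

test_that("the representation filter keeps splits with > 60% focal
           segments in training", {
  counts <- matrix(c(10, 10, 80, 5, 5, 5), nrow = 3,
                   dimnames = list(c("i1", "i2", "i3"),
                                   c("Feeding", "Scratching")))
  sp <- enumerate_splits(c("i1", "i2", "i3"), 1)
  kept <- filter_splits(sp, counts, threshold = 0.6)
  expect_length(kept, 2)   # testing on i3 leaves only 20% of Feeding
  expect_false(any(vapply(kept, function(s) "i3" %in% s$test, logical(1))))
  expect_length(filter_splits(sp, counts, threshold = 0), 3)
  expect_length(filter_splits(sp, counts, threshold = 1), 0)
  # superset property when the threshold decreases
  for (th in c(0.8, 0.6, 0.3)) {
    hi <- filter_splits(sp, counts, threshold = th)
    lo <- filter_splits(sp, counts, threshold = th - 0.2)
    expect_true(all(vapply(hi, function(s)
      any(vapply(lo, function(t) identical(s$test, t$test), logical(1))),
      logical(1))))
  }
  expect_error(filter_splits(sp, counts[, 1, drop = FALSE]),
               "absent from counts")
})

test_that("confusion metrics reproduce the printed formulas", {
  cl <- c("A", "B")
  # perfect predictions
  mr <- confusion_and_metrics(rep(cl, 5), rep(cl, 5), cl)
  expect_equal(mr$accuracy, 1)
  expect_equal(mr$metrics$sensitivity, c(1, 1))
  expect_equal(mr$metrics$precision, c(1, 1))
  expect_equal(mr$metrics$specificity, c(1, 1))

  # TP=8 FN=2 FP=1 TN=89 for class A
  truth <- rep(c("A", "B"), c(10, 90))
  pred <- c(rep("A", 8), rep("B", 2), "A", rep("B", 89))
  mr <- confusion_and_metrics(truth, pred, cl)
  a <- mr$metrics[mr$metrics$class == "A", ]
  expect_equal(a$sensitivity, 0.8)
  expect_equal(a$precision, 8 / 9)
  expect_equal(a$specificity, 89 / 90)
  expect_equal(mr$accuracy, 0.97)

  # class never predicted: precision undefined, sensitivity 0
  mr <- confusion_and_metrics(truth, rep("B", 100), cl)
  a <- mr$metrics[mr$metrics$class == "A", ]
  expect_true(is.nan(a$precision))
  expect_equal(a$sensitivity, 0)
  expect_error(confusion_and_metrics(c("A", "B"), "A"), "differ in length")
})

test_that("confusion counts are conserved: TP+FN per class and total", {
  set.seed(23)
  cl <- dive_classes()
  for (i in 1:10) {
    n <- sample(50:200, 1)
    truth <- sample(cl, n, replace = TRUE)
    pred <- ifelse(runif(n) < 0.7, truth, sample(cl, n, replace = TRUE))
    mr <- confusion_and_metrics(truth, pred, cl)
    expect_equal(mr$metrics$tp + mr$metrics$fn,
                 as.integer(table(factor(truth, levels = cl))))
    expect_equal(sum(mr$confusion), n)
    expect_equal(mr$accuracy, sum(diag(mr$confusion)) / n)
  }
})

test_that("activity budgets sum durations per category and conserve time", {
  # 100% surface, all intervals <= 6 s -> pure Breathing
  seg <- data.frame(individual_id = "x", start = c(0, 5), end = c(5, 10),
                    kind = "surface", kinematic_tag = "Breathing",
                    ground_truth = NA_character_, predicted = NA_character_)
  b <- activity_budget(seg, 10)
  expect_equal(b$fraction[b$category == "Breathing"], 1)

  # 600 s record: 60 s staying at the surface + 540 s resting dives
  seg2 <- data.frame(individual_id = "x", start = c(0, 60),
                     end = c(60, 600),
                     kind = c("surface", "dive-flat"),
                     kinematic_tag = c("StayingAtSurface", "flat"),
                     ground_truth = NA_character_,
                     predicted = c(NA, "Resting"))
  b2 <- activity_budget(seg2, 600)
  expect_equal(b2$fraction[b2$category == "StayingAtSurface"], 0.1)
  expect_equal(b2$fraction[b2$category == "Resting"], 0.9)
  expect_equal(sum(b2$fraction), 1, tolerance = 1e-9)
  expect_equal(sum(b2$seconds), 600)

  # tiling violations are refused
  seg3 <- seg2; seg3$start[2] <- 70
  expect_error(activity_budget(seg3, 600), "do not tile")
})

test_that("budget comparison reports the documented difference scales", {
  b0 <- data.frame(category = budget_categories(),
                   seconds = c(100, 200, 0, 0, 960, 0, 2340, 0, 0))
  b0$fraction <- b0$seconds / 3600
  b1 <- b0
  b1$seconds[b1$category == "Resting"] <- 900
  b1$seconds[b1$category == "Swimming"] <- 2400
  b1$fraction <- b1$seconds / 3600
  cmp <- compare_budgets(b1, b0)
  r <- cmp[cmp$category == "Resting", ]
  expect_equal(r$delta_s, -60)
  expect_equal(r$pct_total, -60 / 3600 * 100, tolerance = 1e-9)
  expect_equal(r$pct_behavior, -6.25)
  expect_true(is.nan(cmp$pct_behavior[cmp$category == "Feeding"]))
  ident <- compare_budgets(b0, b0)
  expect_true(all(ident$delta_s == 0))
})

test_that("predicted and observed budgets agree on well-classified
           synthetic data", {
  ds <- make_dataset(4, mean_duration = 900, seed = 31)
  cfg <- diveseg_config(n_test_individuals = 1, precision_folds = 3)
  ft <- process_dataset(ds, cfg)
  train <- balance_training(ft[ft$kind != "surface" &
                                 ft$individual_id != "ind01", ], 1000, 1)
  ens <- train_ensemble(train, cfg, seed = 2)
  test <- ft[ft$individual_id == "ind01", ]
  dive <- test$kind != "surface"
  test$predicted <- NA_character_
  test$predicted[dive] <- as.character(predict(ens, test[dive, ], "WS"))
  dur <- record_duration(ds$records$ind01)
  pb <- activity_budget(test, dur, "predicted")
  # observed budget through the same code path, ground-truth source
  test$ground_truth[!dive] <- test$kinematic_tag[!dive]
  ob <- activity_budget(test, dur, "ground_truth")
  expect_equal(sum(pb$fraction), 1, tolerance = 1e-9)
  expect_equal(sum(ob$fraction), 1, tolerance = 1e-9)
  expect_lt(max(abs(pb$fraction - ob$fraction)), 0.1)
})

test_that("the validation loop is deterministic under a fixed seed", {
  ds <- make_dataset(5, mean_duration = 700, seed = 17)
  ft <- process_dataset(ds)
  cfg <- diveseg_config(n_test_individuals = 1, precision_folds = 3)
  v1 <- run_validation(ft, cfg, n_splits = 1, seed = 3)
  v2 <- run_validation(ft, cfg, n_splits = 1, seed = 3)
  expect_equal(v1$summary, v2$summary)
  expect_equal(v1$per_split$accuracy, v2$per_split$accuracy)
  expect_true(all(v1$summary$mean_accuracy >= 0 &
                    v1$summary$mean_accuracy <= 1))
})
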