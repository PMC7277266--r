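# Small separable feature set: blobs in two informative dimensions,
# remaining feature columns near-constant noise.
blob_rows <- function(n_per_class, classes = c("A", "B", "C"), sep = 8,
                      seed = 1) {
  set.seed(seed)
  fn <- feature_names()
  k <- length(classes)
  n <- n_per_class * k
  x <- matrix(rnorm(n * 42, 0, 0.5), n, 42, dimnames = list(NULL, fn))
  lab <- rep(classes, each = n_per_class)
  for (i in seq_len(k)) {
    sel <- lab == classes[i]
    x[sel, 1] <- x[sel, 1] + sep * cos(2 * pi * i / k)
    x[sel, 2] <- x[sel, 2] + sep * sin(2 * pi * i / k)
  }
  data.frame(ground_truth = lab, x, check.names = FALSE)
}

test_that("training balancing caps large classes and keeps small ones whole", {
  rows <- data.frame(ground_truth = rep(c("A", "B"), c(1500, 400)),
                     junk = rnorm(1900))
  out <- balance_training(rows, cap = 1000, seed = 3)
  expect_equal(as.vector(table(out$ground_truth)), c(1000, 400))
  # identity when nothing exceeds the cap
  rows2 <- rows[1:900, ]
  expect_equal(nrow(balance_training(rows2, cap = 1000, seed = 3)),
               nrow(rows2))
  # determinism
  a <- balance_training(rows, 1000, seed = 7)
  b <- balance_training(rows, 1000, seed = 7)
  expect_identical(rownames(a), rownames(b))
  c2 <- balance_training(rows, 1000, seed = 8)
  expect_false(identical(rownames(a), rownames(c2)))
})

test_that("every base family fits separable blobs perfectly and is
           seed-reproducible", {
  rows <- blob_rows(60)
  for (fam in c("CART", "RF", "EGB", "SVM", "LDA")) {
    m <- train_base(fam, rows, seed = 5)
    expect_equal(mean(as.character(predict(m, rows)) == rows$ground_truth),
                 1, info = fam)
  }
  for (fam in c("RF", "EGB")) {
    m1 <- train_base(fam, rows, seed = 11)
    m2 <- train_base(fam, rows, seed = 11)
    expect_identical(as.character(predict(m1, rows)),
                     as.character(predict(m2, rows)))
  }
  expect_error(train_base("RF", rows[rows$ground_truth == "A", ]),
               "at least two classes")
})

test_that("per-class precision is the TP/(TP+FP) of each member", {
  rows <- blob_rows(40, classes = c("A", "B", "C", "D"))
  perfect <- train_base("RF", rows, seed = 2)
  w <- estimate_class_precision(list(perfect), rows,
                                classes = c("A", "B", "C", "D"))
  expect_equal(unname(w[1, ]), rep(1, 4))
  expect_true(all(w >= 0 & w <= 1))
  # degenerate member that always answers A: precision(A) = share of A
  registerS3method("predict", "constant_model",
                   function(object, newdata, ...)
                     factor(rep("A", nrow(newdata)), levels = object$classes),
                   envir = asNamespace("stats"))
  always_a <- structure(list(family = "CONST",
                             classes = c("A", "B", "C", "D")),
                        class = "constant_model")
  w2 <- estimate_class_precision(list(always_a), rows,
                                 classes = c("A", "B", "C", "D"))
  expect_equal(unname(w2[1, ]), c(0.25, 0, 0, 0))
})

test_that("voting retains the modal member prediction", {
  cl <- c("A", "B", "C")
  expect_equal(predict_voting(matrix(c("A", "A", "A", "B", "B"), 1), NULL, cl),
               "A")
  expect_equal(predict_voting(matrix(rep("C", 5), 1), NULL, cl), "C")
  # tie broken by the higher mean member precision
  w <- matrix(c(0.9, 0.9, 0.7, 0.7, 0.5,
                0.7, 0.7, 0.7, 0.7, 0.7,
                0.2, 0.2, 0.2, 0.2, 0.2), 5, 3,
              dimnames = list(NULL, cl))
  expect_equal(predict_voting(matrix(c("A", "A", "B", "B", "C"), 1), w, cl),
               "A")
})

test_that("the weighted sum scores classes by summed member precision", {
  cl <- c("A", "B")
  w <- matrix(c(0.9, 0.9, 0.1, 0.1, 0.1,
                0.3, 0.3, 0.3, 0.3, 0.3), 5, 2,
              dimnames = list(NULL, cl))
  # two A votes at 0.9 beat three B votes at 0.3
  expect_equal(predict_weighted_sum(matrix(c("A", "A", "B", "B", "B"), 1),
                                    w, cl), "A")
  # one confident member overrides four zero-weight members
  w2 <- matrix(c(0.8, 0, 0, 0, 0, 0, 0, 0, 0, 0), 5, 2,
               dimnames = list(NULL, cl))
  expect_equal(predict_weighted_sum(matrix(c("A", "B", "B", "B", "B"), 1),
                                    w2, cl), "A")
})

test_that("weighted sum with uniform weights reduces to voting", {
  cl <- c("A", "B", "C", "D")
  w <- matrix(0.5, 5, 4, dimnames = list(NULL, cl))
  set.seed(19)
  for (i in 1:50) {
    pred <- matrix(sample(cl, 5 * 7, replace = TRUE), 7, 5)
    expect_equal(predict_weighted_sum(pred, w, cl),
                 predict_voting(pred, w, cl))
  }
})

test_that("the trained ensemble predicts only training classes and WS does
           not collapse below its members", {
  rows <- blob_rows(50, classes = c("A", "B", "C"))
  ens <- train_ensemble(rows, diveseg_config(precision_folds = 3), seed = 4)
  expect_s3_class(ens, "diveseg_ensemble")
  expect_true(all(ens$weights >= 0 & ens$weights <= 1))
  test <- blob_rows(30, classes = c("A", "B", "C"), seed = 99)
  for (mode in c("WS", "VE", "RF")) {
    p <- predict(ens, test, mode = mode)
    expect_true(all(as.character(p) %in% c("A", "B", "C")))
  }
  acc <- function(mode) mean(as.character(predict(ens, test, mode)) ==
                               test$ground_truth)
  base_best <- max(vapply(c("CART", "RF", "EGB", "SVM", "LDA"), acc,
                          numeric(1)))
  expect_gte(acc("WS"), base_best - 0.02)
})
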