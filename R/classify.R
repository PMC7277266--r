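#' Balance a training set by capping class counts
#'
#' Classes with more rows than `cap` are downsampled uniformly without
#' replacement (deterministically under `seed`); smaller classes are kept
#' whole. Nothing is ever upsampled.
#'
#' @param rows A data frame with a `ground_truth` column.
#' @param cap Maximum rows per class (default 1000).
#' @param seed Integer seed.
#' @return The balanced data frame.
#' @export
balance_training <- function(rows, cap = 1000, seed = 1) {
  if (cap <= 0) stop("cap must be positive", call. = FALSE)
  lab <- rows$ground_truth
  if (any(is.na(lab))) stop("training rows must be labelled", call. = FALSE)
  counts <- table(lab)
  if (any(counts == 0))
    warning("classes absent from training: ",
            paste(names(counts)[counts == 0], collapse = ", "), call. = FALSE)
  keep <- logical(nrow(rows))
  set.seed(seed)
  for (cl in sort(names(counts))) {
    idx <- which(lab == cl)
    if (length(idx) > cap) idx <- sort(sample(idx, cap))
    keep[idx] <- TRUE
  }
  rows[keep, , drop = FALSE]
}

feature_matrix <- function(rows) {
  fn <- feature_names()
  miss <- setdiff(fn, names(rows))
  if (length(miss))
    stop("rows lack feature columns: ", paste(miss[1:min(3, length(miss))],
                                              collapse = ", "), call. = FALSE)
  as.matrix(rows[, fn])
}

#' Train one base classifier
#'
#' Fits one of the five supervised learners on 42-feature rows: CART
#' (rpart; cp 0.01, minsplit 20), RF (randomForest; 300 trees, 14 candidate
#' variables per split), EGB (xgboost; softmax over the present classes,
#' learning rate 0.3, depth 3, 50 rounds), SVM (e1071; RBF kernel, cost 1,
#' gamma 1/42, standardized features) or LDA (MASS; pooled-covariance
#' discriminant on standardized features, constant columns dropped).
#' Stochastic fits are reproducible under `seed`.
#'
#' @param family One of `"CART"`, `"RF"`, `"EGB"`, `"SVM"`, `"LDA"`.
#' @param rows Feature rows with a `ground_truth` column.
#' @param cfg A `diveseg_config` (hyper-parameters under `cfg$classifiers`).
#' @param seed Integer seed.
#' @return An object of class `diveseg_model`.
#' @export
train_base <- function(family = c("CART", "RF", "EGB", "SVM", "LDA"),
                       rows, cfg = diveseg_config(), seed = 1) {
  family <- match.arg(family)
  y <- factor(rows$ground_truth)
  if (nlevels(y) < 2)
    stop("need at least two classes to train, got ", nlevels(y), call. = FALSE)
  x <- feature_matrix(rows)
  hp <- cfg$classifiers
  set.seed(seed)
  fit <- extra <- NULL
  if (family == "CART") {
    df <- data.frame(.y = y, x, check.names = FALSE)
    fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                        control = rpart::rpart.control(
                          cp = hp$cart$cp, minsplit = hp$cart$minsplit))
  } else if (family == "RF") {
    fit <- randomForest::randomForest(
      x = x, y = y, ntree = hp$rf$ntree,
      mtry = min(hp$rf$mtry, ncol(x)))
  } else if (family == "EGB") {
    dtrain <- xgboost::xgb.DMatrix(x, label = as.integer(y) - 1L)
    fit <- xgboost::xgb.train(
      params = list(objective = "multi:softprob",
                    num_class = nlevels(y),
                    eta = hp$egb$eta, max_depth = hp$egb$max_depth,
                    nthread = 1, seed = seed),
      data = dtrain, nrounds = hp$egb$nrounds, verbose = 0)
  } else if (family == "SVM") {
    nzv <- apply(x, 2, stats::sd) > 0
    gamma <- if (is.null(hp$svm$gamma)) 1 / ncol(x) else hp$svm$gamma
    fit <- e1071::svm(x[, nzv, drop = FALSE], y, kernel = "radial",
                      cost = hp$svm$cost, gamma = gamma, scale = TRUE)
    extra <- list(keep = nzv)
  } else if (family == "LDA") {
    mu <- colMeans(x); sd <- apply(x, 2, stats::sd)
    keep <- sd > 0
    xs <- scale(x[, keep, drop = FALSE], center = mu[keep], scale = sd[keep])
    fit <- suppressWarnings(MASS::lda(xs, grouping = y))
    extra <- list(keep = keep, center = mu[keep], scale = sd[keep])
  }
  structure(list(family = family, fit = fit, classes = levels(y),
                 feature_version = FEATURE_VERSION, extra = extra),
            class = "diveseg_model")
}

#' @export
print.diveseg_model <- function(x, ...) {
  cat("<diveseg_model>", x$family, "over", length(x$classes), "classes:",
      paste(x$classes, collapse = ", "), "\n")
  invisible(x)
}

#' Predict behaviour categories with a base classifier
#'
#' @param object A `diveseg_model`.
#' @param newdata Feature rows (data frame with the 42 feature columns).
#' @param ... Unused.
#' @return Factor of predicted classes (levels: the training classes).
#' @export
predict.diveseg_model <- function(object, newdata, ...) {
  x <- feature_matrix(as.data.frame(newdata))
  cls <- object$classes
  out <- switch(object$family,
    CART = {
      p <- predict(object$fit, data.frame(x, check.names = FALSE),
                   type = "class")
      as.character(p)
    },
    RF = as.character(predict(object$fit, x)),
    EGB = {
      p <- predict(object$fit, xgboost::xgb.DMatrix(x))
      if (is.null(dim(p))) p <- matrix(p, ncol = length(cls), byrow = TRUE)
      cls[max.col(p, ties.method = "first")]
    },
    SVM = as.character(predict(object$fit,
                               x[, object$extra$keep, drop = FALSE])),
    LDA = {
      xs <- scale(x[, object$extra$keep, drop = FALSE],
                  center = object$extra$center, scale = object$extra$scale)
      as.character(predict(object$fit, xs)$class)
    })
  factor(out, levels = cls)
}

#' Per-class precision of fitted members on calibration rows
#'
#' Precision = TP / (TP + FP) of each member for each class, computed from
#' the members' predictions on rows none of them was fitted on. Classes a
#' member never predicts get weight 0.
#'
#' @param members List of `diveseg_model`s.
#' @param rows Labelled calibration feature rows.
#' @param classes Class list (default [dive_classes()]).
#' @return Matrix, members x classes, entries in `[0, 1]`.
#' @export
estimate_class_precision <- function(members, rows,
                                     classes = dive_classes()) {
  truth <- factor(rows$ground_truth, levels = classes)
  w <- matrix(0, nrow = length(members), ncol = length(classes),
              dimnames = list(vapply(members, `[[`, "", "family"), classes))
  for (m in seq_along(members)) {
    pred <- factor(as.character(predict(members[[m]], rows)),
                   levels = classes)
    for (cl in classes) {
      np <- sum(pred == cl, na.rm = TRUE)
      w[m, cl] <- if (np == 0) 0 else
        sum(pred == cl & truth == cl, na.rm = TRUE) / np
    }
  }
  w
}

# shared tie-breaking: highest mean member precision for the tied classes,
# then fixed (alphabetical) class order
break_tie <- function(tied, weights, classes) {
  if (length(tied) == 1) return(tied)
  if (!is.null(weights)) {
    mp <- colMeans(weights[, tied, drop = FALSE])
    tied <- tied[mp == max(mp)]
  }
  tied[order(match(tied, classes))][1]
}

#' Voting-ensemble prediction
#'
#' Retains the most frequently predicted behaviour across the member
#' predictions of each row; ties go to the tied class with the highest mean
#' member precision, then to the fixed class order.
#'
#' @param pred Character matrix, rows x members, of member predictions.
#' @param weights Optional member x class precision matrix (tie-breaks).
#' @param classes Class list.
#' @return Character vector of labels.
#' @export
predict_voting <- function(pred, weights = NULL, classes = dive_classes()) {
  apply(pred, 1, function(p) {
    tab <- table(factor(p, levels = classes))
    tied <- names(tab)[tab == max(tab)]
    break_tie(tied, weights, classes)
  })
}

#' Precision-weighted-sum ensemble prediction
#'
#' Each row's score for a class is the sum, over members predicting that
#' class, of the member's precision for it; the argmax wins, ties broken as
#' in [predict_voting()].
#'
#' @inheritParams predict_voting
#' @param weights Member x class precision matrix.
#' @export
predict_weighted_sum <- function(pred, weights, classes = dive_classes()) {
  nm <- ncol(pred)
  apply(pred, 1, function(p) {
    score <- stats::setNames(numeric(length(classes)), classes)
    for (m in seq_len(nm)) score[p[m]] <- score[p[m]] + weights[m, p[m]]
    tied <- names(score)[score >= max(score) - 1e-12]
    break_tie(tied, weights, classes)
  })
}

#' Train the five base classifiers and their ensembles
#'
#' Fits CART, RF, EGB, SVM and LDA on the (already balanced) training rows
#' and estimates the precision weight matrix for the weighted-sum ensemble
#' by k-fold out-of-fold prediction within the training rows (the test
#' individuals are never touched). The returned object predicts with any
#' member, the voting ensemble (VE) or the precision-weighted sum (WS).
#'
#' @param rows Balanced, labelled feature rows.
#' @param cfg A `diveseg_config`.
#' @param seed Integer seed.
#' @return An object of class `diveseg_ensemble`.
#' @export
train_ensemble <- function(rows, cfg = diveseg_config(), seed = 1) {
  fams <- c("CART", "RF", "EGB", "SVM", "LDA")
  members <- lapply(seq_along(fams), function(i)
    train_base(fams[i], rows, cfg, seed = seed + i))
  classes <- sort(unique(rows$ground_truth))
  # out-of-fold precision weights
  k <- cfg$precision_folds
  set.seed(seed + 100)
  fold <- sample(rep_len(seq_len(k), nrow(rows)))
  oof <- matrix(NA_character_, nrow(rows), length(fams))
  for (f in seq_len(k)) {
    tr <- rows[fold != f, , drop = FALSE]
    if (length(unique(tr$ground_truth)) < 2) next
    for (i in seq_along(fams)) {
      m <- train_base(fams[i], tr, cfg, seed = seed + 10 * f + i)
      oof[fold == f, i] <- as.character(predict(m, rows[fold == f, ,
                                                        drop = FALSE]))
    }
  }
  truth <- factor(rows$ground_truth, levels = classes)
  weights <- matrix(0, length(fams), length(classes),
                    dimnames = list(fams, classes))
  for (i in seq_along(fams)) {
    pred <- factor(oof[, i], levels = classes)
    for (cl in classes) {
      np <- sum(pred == cl, na.rm = TRUE)
      weights[i, cl] <- if (np == 0) 0 else
        sum(!is.na(pred) & pred == cl & truth == cl) / np
    }
  }
  structure(list(members = stats::setNames(members, fams),
                 weights = weights, classes = classes),
            class = "diveseg_ensemble")
}

#' @export
print.diveseg_ensemble <- function(x, ...) {
  cat("<diveseg_ensemble> members:", paste(names(x$members), collapse = ", "),
      "\n  classes:", paste(x$classes, collapse = ", "), "\n")
  cat("  precision weights:\n")
  print(round(x$weights, 3))
  invisible(x)
}

#' Predict with the ensemble
#'
#' @param object A `diveseg_ensemble`.
#' @param newdata Feature rows.
#' @param mode `"WS"` (precision-weighted sum), `"VE"` (voting) or the name
#'   of a base member.
#' @param ... Unused.
#' @return Factor of predicted classes.
#' @export
predict.diveseg_ensemble <- function(object, newdata,
                                     mode = c("WS", "VE", "CART", "RF",
                                              "EGB", "SVM", "LDA"), ...) {
  mode <- match.arg(mode)
  if (mode %in% names(object$members))
    return(factor(as.character(predict(object$members[[mode]], newdata)),
                  levels = object$classes))
  pred <- vapply(object$members, function(m)
    as.character(predict(m, newdata)), character(nrow(newdata)))
  if (nrow(newdata) == 1) pred <- matrix(pred, nrow = 1)
  lab <- if (mode == "VE")
    predict_voting(pred, object$weights, object$classes)
  else
    predict_weighted_sum(pred, object$weights, object$classes)
  factor(lab, levels = object$classes)
}
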