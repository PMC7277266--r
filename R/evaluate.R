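#' Enumerate individual-level train/test splits
#'
#' All unordered choices of `n_test` test individuals out of the supplied
#' ids, each paired with the complementary training set, in deterministic
#' lexicographic order. Thirteen individuals with four held out give the
#' 715 possible combinations.
#'
#' @param ids Character vector of individual ids.
#' @param n_test Number of test individuals (default 4).
#' @return List of `list(train, test)` pairs.
#' @export
enumerate_splits <- function(ids, n_test = 4) {
  ids <- as.character(ids)
  n <- length(ids)
  if (n_test >= n) stop("n_test must be below the number of individuals",
                        call. = FALSE)
  if (n_test == 0) return(list(list(train = ids, test = character(0))))
  cmb <- utils::combn(ids, n_test, simplify = FALSE)
  lapply(cmb, function(te) list(train = setdiff(ids, te), test = te))
}

#' Filter splits by focal-class representation
#'
#' A split is kept only when, for every focal class (Feeding and
#' Scratching by default), the training individuals hold strictly more
#' than `threshold` (60%) of that class's total segments.
#'
#' @param splits List from [enumerate_splits()].
#' @param counts Matrix or data frame of segment counts, rows named by
#'   individual, columns by class.
#' @param focal Focal class names.
#' @param threshold Fraction in `[0, 1]`.
#' @return The retained subset of `splits`.
#' @export
filter_splits <- function(splits, counts, focal = c("Feeding", "Scratching"),
                          threshold = 0.6) {
  counts <- as.matrix(counts)
  miss <- setdiff(focal, colnames(counts))
  if (length(miss))
    stop("focal classes absent from counts: ", paste(miss, collapse = ", "),
         call. = FALSE)
  tot <- colSums(counts[, focal, drop = FALSE])
  if (any(tot == 0))
    stop("focal class with zero segments everywhere: ",
         paste(focal[tot == 0], collapse = ", "), call. = FALSE)
  keep <- vapply(splits, function(sp) {
    tr <- colSums(counts[sp$train, focal, drop = FALSE])
    all(tr > threshold * tot)
  }, logical(1))
  splits[keep]
}

#' Confusion matrix and per-class metrics
#'
#' Builds the K x K confusion matrix (rows = truth, columns = prediction)
#' and derives, per class in one-vs-rest form, sensitivity TP/(TP+FN),
#' precision TP/(TP+FP) and specificity TN/(TN+FP), plus the global
#' accuracy trace/total. Ratios with zero denominator are reported as
#' `NaN` and excluded from any averaging.
#'
#' @param truth,predicted Vectors of class labels (same length).
#' @param classes Class list.
#' @return List of class `metrics_report`: `confusion`, `metrics`
#'   (data frame per class), `accuracy`.
#' @export
confusion_and_metrics <- function(truth, predicted,
                                  classes = dive_classes()) {
  if (length(truth) != length(predicted))
    stop("truth and predicted differ in length", call. = FALSE)
  truth <- factor(as.character(truth), levels = classes)
  predicted <- factor(as.character(predicted), levels = classes)
  if (any(is.na(truth)) || any(is.na(predicted)))
    stop("labels outside the class list", call. = FALSE)
  cm <- table(truth = truth, predicted = predicted)
  n <- sum(cm)
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  tn <- n - tp - fn - fp
  ratio <- function(a, b) ifelse(b == 0, NaN, a / b)
  metrics <- data.frame(
    class = classes,
    tp = as.integer(tp), fn = as.integer(fn), fp = as.integer(fp),
    tn = as.integer(tn),
    sensitivity = ratio(tp, tp + fn),
    precision = ratio(tp, tp + fp),
    specificity = ratio(tn, tn + fp),
    row.names = NULL)
  structure(list(confusion = cm, metrics = metrics,
                 accuracy = sum(tp) / n),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report> global accuracy:", round(x$accuracy, 4), "\n")
  print(x$metrics[, c("class", "sensitivity", "precision", "specificity")],
        digits = 3)
  invisible(x)
}

#' Activity budget from a labelled segment table
#'
#' Summed duration and fraction of record time per behavioural category
#' over the nine reporting categories. Surface bouts always contribute via
#' their depth-derived kinematic tag; dive bouts via the chosen label
#' source (classifier predictions for the predicted budget, annotation
#' ground truth for the observed one). The segments must tile the record.
#'
#' @param segments A segment table.
#' @param duration Record duration (s).
#' @param source `"predicted"` or `"ground_truth"` for the dive labels.
#' @return `data.frame(category, seconds, fraction)` of class
#'   `activity_budget`.
#' @export
activity_budget <- function(segments, duration,
                            source = c("predicted", "ground_truth")) {
  source <- match.arg(source)
  seg <- segments[order(segments$start), , drop = FALSE]
  gaps <- which(abs(seg$start[-1] - seg$end[-nrow(seg)]) > 1e-6)
  if (length(gaps) || abs(seg$start[1]) > 1e-6 ||
      abs(seg$end[nrow(seg)] - duration) > 1e-6) {
    where <- if (length(gaps)) paste0("at t = ", seg$end[gaps[1]])
             else "at the record boundary"
    stop("segments do not tile the record (gap/overlap ", where, ")",
         call. = FALSE)
  }
  lab <- ifelse(seg$kind == "surface", seg$kinematic_tag, seg[[source]])
  if (any(is.na(lab)))
    stop("unlabelled dive segments; fill '", source, "' first", call. = FALSE)
  secs <- tapply(seg$end - seg$start, factor(lab, levels = budget_categories()),
                 sum, default = 0)
  out <- data.frame(category = budget_categories(),
                    seconds = as.numeric(secs),
                    fraction = as.numeric(secs) / duration,
                    row.names = NULL)
  structure(out, class = c("activity_budget", "data.frame"))
}

#' Compare predicted and observed activity budgets
#'
#' Per-category differences expressed in seconds, as a percentage of the
#' total record duration and as a percentage of the observed time of the
#' behaviour itself (`NaN` when the behaviour was never observed).
#'
#' @param predicted,observed `activity_budget`s over the same duration.
#' @return Data frame with `delta_s`, `pct_total`, `pct_behavior`.
#' @export
compare_budgets <- function(predicted, observed) {
  dp <- sum(predicted$seconds); do <- sum(observed$seconds)
  if (abs(dp - do) > 1e-6)
    stop("budgets cover different durations (", dp, " vs ", do, " s)",
         call. = FALSE)
  stopifnot(identical(predicted$category, observed$category))
  delta <- predicted$seconds - observed$seconds
  data.frame(category = predicted$category,
             predicted_s = predicted$seconds,
             observed_s = observed$seconds,
             delta_s = delta,
             pct_total = 100 * delta / dp,
             pct_behavior = ifelse(observed$seconds == 0, NaN,
                                   100 * delta / observed$seconds),
             row.names = NULL)
}

#' Individual-level validation of the classification workflow
#'
#' Enumerates the train/test splits of the individuals, drops splits where
#' a focal class is under-represented in training, and for each retained
#' split balances the training rows, fits the five base classifiers and
#' both ensembles, and scores the test individuals' segments. Only dive
#' segments enter classification. Reports per-classifier mean and standard
#' deviation of the global accuracy over splits (unweighted across splits)
#' and the per-class metric distributions.
#'
#' @param features A `feature_table` pooling all individuals (ground truth
#'   filled in).
#' @param cfg A `diveseg_config`.
#' @param n_splits Optional cap on the number of retained splits actually
#'   evaluated (a deterministic subsample under `seed`); `NULL` runs all.
#' @param seed Integer seed.
#' @return List of class `validation_summary`: `per_split` (split x
#'   classifier accuracies), `summary` (mean/sd per classifier),
#'   `per_class` (per-class mean metrics for each classifier),
#'   `n_retained`, `n_total`.
#' @export
run_validation <- function(features, cfg = diveseg_config(),
                           n_splits = NULL, seed = cfg$rng_seed) {
  rows <- features[features$kind != "surface" & !is.na(features$ground_truth), ,
                   drop = FALSE]
  ids <- sort(unique(rows$individual_id))
  if (length(ids) <= cfg$n_test_individuals)
    stop("need more individuals than n_test_individuals", call. = FALSE)
  counts <- table(rows$individual_id, rows$ground_truth)
  splits <- enumerate_splits(ids, cfg$n_test_individuals)
  n_total <- length(splits)
  splits <- filter_splits(splits, counts, cfg$focal_classes,
                          cfg$representation_threshold)
  if (!length(splits))
    stop("no split passes the representation filter; lower ",
         "representation_threshold", call. = FALSE)
  n_retained <- length(splits)
  if (!is.null(n_splits) && n_splits < length(splits)) {
    set.seed(seed)
    splits <- splits[sort(sample(length(splits), n_splits))]
  }
  classifiers <- c("CART", "RF", "EGB", "SVM", "LDA", "VE", "WS")
  per_split <- list()
  per_class <- list()
  for (k in seq_along(splits)) {
    sp <- splits[[k]]
    train <- rows[rows$individual_id %in% sp$train, , drop = FALSE]
    test <- rows[rows$individual_id %in% sp$test, , drop = FALSE]
    train <- balance_training(train, cfg$train_cap, seed = seed + k)
    ens <- train_ensemble(train, cfg, seed = seed + 1000 * k)
    for (cl in classifiers) {
      pred <- predict(ens, test, mode = cl)
      mr <- confusion_and_metrics(test$ground_truth, as.character(pred),
                                  classes = sort(unique(c(ens$classes,
                                                          test$ground_truth))))
      per_split[[length(per_split) + 1]] <-
        data.frame(split = k, classifier = cl, accuracy = mr$accuracy,
                   n_test = nrow(test))
      pc <- mr$metrics
      pc$split <- k; pc$classifier <- cl
      per_class[[length(per_class) + 1]] <- pc
    }
  }
  per_split <- do.call(rbind, per_split)
  per_class <- do.call(rbind, per_class)
  agg <- do.call(rbind, lapply(split(per_split, per_split$classifier),
    function(d) data.frame(classifier = d$classifier[1],
                           mean_accuracy = mean(d$accuracy),
                           sd_accuracy = stats::sd(d$accuracy))))
  agg <- agg[match(classifiers, agg$classifier), ]
  rownames(agg) <- NULL
  structure(list(per_split = per_split, per_class = per_class,
                 summary = agg, n_retained = n_retained, n_total = n_total,
                 n_evaluated = length(splits)),
            class = "validation_summary")
}

#' @export
print.validation_summary <- function(x, ...) {
  cat("<validation_summary>", x$n_evaluated, "of", x$n_retained,
      "retained splits evaluated (", x$n_total, "enumerated )\n")
  cat("  global accuracy (mean +/- sd over splits):\n")
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("    %-4s %.3f +/- %.3f\n", s$classifier[i],
                s$mean_accuracy[i], s$sd_accuracy[i]))
  invisible(x)
}
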