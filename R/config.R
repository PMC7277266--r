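#' Behaviour categories
#'
#' The eight behavioural categories used throughout the package: two surface
#' categories identified from depth alone (`Breathing`, `StayingAtSurface`)
#' and six diving categories (`Feeding`, `Gliding`, `Resting`, `Scratching`,
#' `Swimming`, `Other`). Segmentation adds a ninth label, `Transition`, for
#' bouts in which no single category reaches the majority fraction of the
#' bout duration.
#'
#' @return Character vector of category names.
#' @export
behavior_categories <- function() {
  c("Breathing", "Feeding", "Gliding", "Resting", "Scratching",
    "StayingAtSurface", "Swimming", "Other")
}

#' @rdname behavior_categories
#' @export
surface_categories <- function() c("Breathing", "StayingAtSurface")

#' @rdname behavior_categories
#' @details `dive_classes()` returns the seven classes the supervised
#'   learners distinguish, in the fixed (alphabetical) order used for
#'   deterministic tie-breaking in the ensembles.
#' @export
dive_classes <- function() {
  c("Feeding", "Gliding", "Other", "Resting", "Scratching", "Swimming",
    "Transition")
}

#' @rdname behavior_categories
#' @details `budget_categories()` returns the nine categories an activity
#'   budget is reported over.
#' @export
budget_categories <- function() {
  c("Breathing", "StayingAtSurface", "Feeding", "Gliding", "Resting",
    "Scratching", "Swimming", "Other", "Transition")
}

#' Pipeline configuration
#'
#' Builds the configuration list that parameterizes every stage of the
#' workflow. Defaults are the values used for green-turtle records: dives
#' are depths exceeding 0.3 m for at least 5 s; surface intervals of at most
#' 6 s are Breathing; the depth changepoint stage uses penalty 5 on 3 s
#' depth aggregates, the DBA (mean+variance) stage penalty 50 and the
#' pitch-rate variance stage penalty 20; the static acceleration vector is
#' a 2 s centred running mean; a bout is labelled with a category only when
#' that category covers at least 3/5 of its duration.
#'
#' @param ... Named overrides of any default entry.
#' @return A list of class `diveseg_config`.
#' @examples
#' cfg <- diveseg_config(pen_dba = 30)
#' cfg$pen_dba
#' @export
diveseg_config <- function(...) {
  cfg <- list(
    dive_depth_threshold = 0.3,   # m; strict >
    dive_min_duration    = 5,     # s; inclusive >=
    surface_breathing_max = 6,    # s; <= 6 -> Breathing
    depth_window         = 3,     # s; depth aggregation / vertical speed
    vspeed_threshold     = 0.1,   # m s^-1
    vspeed_sign          = 1,     # +1: depth positive down, v>0 descending
    pen_depth            = 5,
    pen_dba              = 50,
    pen_gy               = 20,
    minseglen            = 2,     # samples, changepoint minimum segment
    static_window        = 2,     # s, static-acceleration running mean
    smooth_window        = 1,     # s, oscillation-feature running mean
    min_subsegment       = 1,     # s, shorter sub-bouts merged into neighbour
    majority_fraction    = 3 / 5,
    train_cap            = 1000,  # max segments per class in training
    representation_threshold = 0.6,
    focal_classes        = c("Feeding", "Scratching"),
    n_test_individuals   = 4,
    precision_folds      = 5,     # out-of-fold protocol for WS weights
    rng_seed             = 1,
    classifiers = list(
      cart = list(cp = 0.01, minsplit = 20),
      rf   = list(ntree = 300, mtry = 14),
      egb  = list(eta = 0.3, max_depth = 3, nrounds = 50),
      svm  = list(cost = 1, gamma = NULL),  # NULL -> 1/n_features
      lda  = list()
    )
  )
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == ""))
      stop("configuration overrides must be named", call. = FALSE)
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown))
      stop("unknown configuration entries: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    cfg[names(dots)] <- dots
  }
  validate_config(cfg)
  structure(cfg, class = "diveseg_config")
}

validate_config <- function(cfg) {
  pos <- c("dive_depth_threshold", "dive_min_duration", "surface_breathing_max",
           "depth_window", "vspeed_threshold", "pen_depth", "pen_dba",
           "pen_gy", "static_window", "smooth_window", "train_cap")
  for (nm in pos) {
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1L || cfg[[nm]] <= 0)
      stop("config entry '", nm, "' must be a positive scalar", call. = FALSE)
  }
  if (cfg$majority_fraction <= 0.5 || cfg$majority_fraction > 1)
    stop("majority_fraction must lie in (0.5, 1]", call. = FALSE)
  if (!cfg$vspeed_sign %in% c(-1, 1))
    stop("vspeed_sign must be +1 or -1", call. = FALSE)
  invisible(cfg)
}

#' Read or write a pipeline configuration as YAML
#'
#' @param path Path to a YAML file.
#' @return `read_config()` returns a `diveseg_config`; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$focal_classes)) vals$focal_classes <- as.character(vals$focal_classes)
  do.call(diveseg_config, vals)
}

#' @rdname read_config
#' @param cfg A `diveseg_config`.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Behaviour alias table
#'
#' Fine-grained ethogram labels (as produced during video annotation) are
#' mapped onto the eight analysis categories through an editable alias
#' table: a named character vector, names being lower-cased fine labels and
#' values the target categories. The default table covers common sea-turtle
#' ethogram entries; `read_behavior_intervals()` falls back to `Other` (with
#' a warning) for labels found in neither the categories nor the table. A
#' YAML copy ships under `inst/extdata/behavior_aliases.yaml`.
#'
#' @return Named character vector.
#' @export
default_alias_table <- function() {
  c("grazing on seagrass"  = "Feeding",
    "grazing"              = "Feeding",
    "grabbing"             = "Feeding",
    "jellyfish capture"    = "Feeding",
    "catching of jellyfish" = "Feeding",
    "biting"               = "Feeding",
    "flipper beating"      = "Swimming",
    "swimming ascent"      = "Swimming",
    "swimming descent"     = "Swimming",
    "travelling"           = "Swimming",
    "gliding ascent"       = "Gliding",
    "gliding descent"      = "Gliding",
    "passive ascent"       = "Gliding",
    "resting on the bottom" = "Resting",
    "motionless"           = "Resting",
    "self-scratching"      = "Scratching",
    "rubbing"              = "Scratching",
    "breath"               = "Breathing",
    "surfacing"            = "Breathing",
    "floating"             = "StayingAtSurface",
    "staying at the surface" = "StayingAtSurface")
}
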