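#' Multi-rate logger record
#'
#' Container for one individual's synchronized logger channels: tri-axial
#' acceleration (g units; surge `ax`, sway `ay`, heave `az`) and tri-axial
#' angular velocity (rad s^-1; roll `gx`, pitch `gy`, yaw `gz`) at the IMU
#' rate (20 or 50 Hz), plus depth (m, positive downward) at 1 Hz. The i-th
#' depth sample covers the half-open second `[i-1, i)`. Derived channels
#' (static/dynamic acceleration, DBA, RA, vertical speed) are attached by
#' [preprocess_record()].
#'
#' @param a Numeric matrix with 3 columns (ax, ay, az), units g.
#' @param g Numeric matrix with 3 columns (gx, gy, gz), units rad s^-1.
#' @param depth Numeric vector at `depth_rate` Hz, metres, >= 0.
#' @param imu_rate Sampling rate of `a` and `g` in Hz; 20 or 50.
#' @param depth_rate Depth sampling rate in Hz (1).
#' @param individual_id Identifier string.
#' @param t0 Absolute start time (seconds or POSIXct); record times are
#'   seconds from `t0`.
#' @return An object of class `sensor_record`.
#' @export
sensor_record <- function(a, g, depth, imu_rate = 20, depth_rate = 1,
                          individual_id = "ind", t0 = 0) {
  a <- as.matrix(a); g <- as.matrix(g)
  if (ncol(a) != 3L || ncol(g) != 3L)
    stop("a and g must each have three columns", call. = FALSE)
  if (nrow(a) != nrow(g))
    stop("acceleration and gyroscope channels differ in length", call. = FALSE)
  if (!imu_rate %in% c(20, 50))
    stop("imu_rate must be 20 or 50 Hz, got ", imu_rate, call. = FALSE)
  depth <- as.numeric(depth)
  if (any(!is.finite(depth)) || any(!is.finite(a)) || any(!is.finite(g)))
    stop("non-finite values in sensor channels", call. = FALSE)
  colnames(a) <- c("ax", "ay", "az")
  colnames(g) <- c("gx", "gy", "gz")
  dur_imu <- nrow(a) / imu_rate
  dur_dep <- length(depth) / depth_rate
  if (abs(dur_imu - dur_dep) > 2)
    stop("depth span (", dur_dep, " s) inconsistent with IMU span (",
         dur_imu, " s)", call. = FALSE)
  structure(list(individual_id = individual_id, t0 = t0,
                 imu_rate = imu_rate, depth_rate = depth_rate,
                 a = a, g = g, depth = depth, derived = NULL, tilt = NULL),
            class = "sensor_record")
}

#' @export
print.sensor_record <- function(x, ...) {
  cat("<sensor_record> individual", x$individual_id, "\n")
  cat(sprintf("  IMU: %d samples at %g Hz (%.1f s)\n",
              nrow(x$a), x$imu_rate, record_duration(x)))
  cat(sprintf("  depth: %d samples at %g Hz, range %.1f-%.1f m\n",
              length(x$depth), x$depth_rate, min(x$depth), max(x$depth)))
  if (!is.null(x$derived))
    cat("  derived channels:", paste(names(x$derived), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname sensor_record
#' @param record A `sensor_record`.
#' @return `record_duration()` returns the record span in seconds.
#' @export
record_duration <- function(record) nrow(record$a) / record$imu_rate

#' @rdname sensor_record
#' @return `imu_times()` returns the sample times (s from record start).
#' @export
imu_times <- function(record) (seq_len(nrow(record$a)) - 1) / record$imu_rate

default_logger_schema <- function() {
  list(time = "time", ax = "ax", ay = "ay", az = "az",
       gx = "gx", gy = "gy", gz = "gz", depth = "depth")
}

#' Read a logger CSV
#'
#' Reads a plain-CSV logger dump: one row per IMU sample with a `time`
#' column (seconds from record start) and the six IMU channels; depth either
#' as an extra column that is non-NA once per second (single-file layout) or
#' in a separate 1 Hz CSV (`depth_path`, columns time + depth). The IMU rate
#' is inferred from the time column and must be 20 or 50 Hz; 50 Hz records
#' are flagged for later subsampling.
#'
#' @param path CSV path.
#' @param depth_path Optional path of a separate 1 Hz depth CSV.
#' @param schema Named list mapping the canonical channel names
#'   (`time`, `ax`, ..., `gz`, `depth`) to the column names in the file.
#' @param individual_id Identifier; defaults to the file name stem.
#' @return A `sensor_record`.
#' @export
read_logger_csv <- function(path, depth_path = NULL,
                            schema = default_logger_schema(),
                            individual_id = NULL) {
  if (!file.exists(path)) stop("logger file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("time", "ax", "ay", "az", "gx", "gy", "gz")
  for (nm in need) {
    col <- schema[[nm]]
    if (is.null(col) || !col %in% names(df))
      stop("logger schema error: missing column '", nm,
           "' (expected file column '", col, "')", call. = FALSE)
  }
  tm <- as.numeric(df[[schema$time]])
  bad <- which(diff(tm) <= 0)
  if (length(bad))
    stop("non-monotone time column at row ", bad[1] + 1L, call. = FALSE)
  dt <- stats::median(diff(tm))
  rate <- round(1 / dt)
  if (!rate %in% c(20, 50))
    stop("inferred IMU rate ", rate, " Hz is not supported (20 or 50 Hz)",
         call. = FALSE)
  a <- as.matrix(df[, unlist(schema[c("ax", "ay", "az")])])
  g <- as.matrix(df[, unlist(schema[c("gx", "gy", "gz")])])
  if (!is.null(depth_path)) {
    dd <- utils::read.csv(depth_path, check.names = FALSE)
    if (!schema$depth %in% names(dd))
      stop("logger schema error: missing column 'depth' in ", depth_path,
           call. = FALSE)
    depth <- as.numeric(dd[[schema$depth]])
  } else {
    if (!schema$depth %in% names(df))
      stop("logger schema error: missing column 'depth' ",
           "(supply depth_path for the two-file layout)", call. = FALSE)
    depth <- as.numeric(df[[schema$depth]])
    depth <- depth[!is.na(depth)]
  }
  if (is.null(individual_id))
    individual_id <- sub("\\.[^.]*$", "", basename(path))
  sensor_record(a, g, depth, imu_rate = rate, individual_id = individual_id,
                t0 = tm[1])
}

#' @rdname read_logger_csv
#' @param record A `sensor_record` to write (single-file layout: depth
#'   NA-padded onto the IMU grid).
#' @export
write_logger_csv <- function(record, path) {
  n <- nrow(record$a)
  tm <- imu_times(record)
  depth_col <- rep(NA_real_, n)
  idx <- round((seq_along(record$depth) - 1) * record$imu_rate /
                 record$depth_rate) + 1L
  keep <- idx >= 1 & idx <= n
  depth_col[idx[keep]] <- record$depth[keep]
  df <- data.frame(time = tm, record$a, record$g, depth = depth_col)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Behaviour intervals
#'
#' A set of labelled, non-overlapping, half-open time intervals
#' `[start, end)` in seconds from record start, at 0.1 s resolution, with a
#' category per interval.
#'
#' @param start,end Numeric vectors (s).
#' @param category Character vector of category names.
#' @return A `data.frame` of class `behavior_intervals`, sorted by start.
#' @export
behavior_intervals <- function(start, end, category) {
  df <- data.frame(start = as.numeric(start), end = as.numeric(end),
                   category = as.character(category),
                   stringsAsFactors = FALSE)
  if (any(df$end <= df$start)) {
    i <- which(df$end <= df$start)[1]
    stop("interval ", i, " has end <= start (", df$start[i], ", ",
         df$end[i], ")", call. = FALSE)
  }
  df <- df[order(df$start), , drop = FALSE]
  rownames(df) <- NULL
  if (nrow(df) > 1) {
    ov <- which(df$start[-1] < df$end[-nrow(df)] - 1e-9)
    if (length(ov))
      stop("overlapping intervals: rows ", ov[1], " and ", ov[1] + 1,
           " ([", df$start[ov[1]], ",", df$end[ov[1]], ") and [",
           df$start[ov[1] + 1], ",", df$end[ov[1] + 1], "))", call. = FALSE)
  }
  class(df) <- c("behavior_intervals", "data.frame")
  df
}

#' Read behaviour-annotation intervals from CSV
#'
#' Expects columns `start`, `end`, `label` (seconds; 0.1 s resolution).
#' Labels equal to a category name are used as-is; otherwise they are looked
#' up (case-insensitively) in the alias table; anything else maps to `Other`
#' with a warning.
#'
#' @param path CSV path.
#' @param aliases Named character vector, see [default_alias_table()].
#' @return A `behavior_intervals` data frame.
#' @export
read_behavior_intervals <- function(path, aliases = default_alias_table()) {
  if (!file.exists(path)) stop("annotation file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  for (nm in c("start", "end", "label"))
    if (!nm %in% names(df))
      stop("annotation schema error: missing column '", nm, "'", call. = FALSE)
  cats <- c(behavior_categories(), "Transition")
  lab <- as.character(df$label)
  mapped <- character(length(lab))
  names(aliases) <- tolower(names(aliases))
  for (i in seq_along(lab)) {
    if (lab[i] %in% cats) {
      mapped[i] <- lab[i]
    } else if (tolower(lab[i]) %in% names(aliases)) {
      mapped[i] <- aliases[[tolower(lab[i])]]
    } else {
      warning("unknown behaviour label '", lab[i], "' mapped to Other",
              call. = FALSE)
      mapped[i] <- "Other"
    }
  }
  behavior_intervals(df$start, df$end, mapped)
}

#' @rdname read_behavior_intervals
#' @param intervals A `behavior_intervals` data frame.
#' @export
write_behavior_intervals <- function(intervals, path) {
  out <- data.frame(start = intervals$start, end = intervals$end,
                    label = intervals$category)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

segment_table_cols <- function() {
  c("individual_id", "start", "end", "kind", "kinematic_tag",
    "ground_truth", "predicted")
}

empty_segment_table <- function() {
  df <- data.frame(individual_id = character(), start = numeric(),
                   end = numeric(), kind = character(),
                   kinematic_tag = character(), ground_truth = character(),
                   predicted = character(), stringsAsFactors = FALSE)
  class(df) <- c("segment_table", "data.frame")
  df
}

as_segment_table <- function(df) {
  for (nm in setdiff(segment_table_cols(), names(df)))
    df[[nm]] <- NA_character_
  df <- df[, segment_table_cols(), drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("segment_table", "data.frame")
  df
}

#' Segment-table round trip
#'
#' Segments are stored as a flat CSV with one row per bout: individual id,
#' half-open boundaries in seconds, structural kind (surface,
#' dive-ascending, dive-descending, dive-flat, dive-flat-sub,
#' dive-swimglide-sub), kinematic tag and the optional ground-truth and
#' predicted categories (empty field when unset). Writing then reading is
#' lossless.
#'
#' @param segments A segment table (`data.frame`).
#' @param path CSV path.
#' @export
write_segment_table <- function(segments, path) {
  seg <- as_segment_table(as.data.frame(segments))
  num <- vapply(seg, is.numeric, logical(1))
  out <- seg
  # full double precision; fields never contain separators, so no quoting
  out[num] <- lapply(seg[num], function(x) sprintf("%.17g", x))
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open segment table for writing: ", path, call. = FALSE))
  on.exit(close(con))
  utils::write.csv(out, con, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' @rdname write_segment_table
#' @export
read_segment_table <- function(path) {
  if (!file.exists(path)) stop("segment table not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = c(individual_id = "character",
                                       start = "numeric", end = "numeric",
                                       kind = "character",
                                       kinematic_tag = "character",
                                       ground_truth = "character",
                                       predicted = "character"))
  if (!all(segment_table_cols() %in% names(df)))
    stop("segment table schema error in ", path, call. = FALSE)
  chr <- vapply(df, is.character, logical(1))
  df[chr] <- lapply(df[chr], function(x) replace(x, !is.na(x) & x == "", NA))
  as_segment_table(df)
}
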