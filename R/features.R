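#' Names and order of the 42 per-segment variables
#'
#' Fixed, versioned feature order: mean, minimum, maximum and variance of
#' the eight 20 Hz channels (ax, ay, az, gx, gy, gz, DBA, RA; 32 values),
#' then the last-minus-first depth difference and the segment duration,
#' then the oscillation pair (mean and maximum of the squared centred
#' high-frequency deviation) for gx, gy, ax and ay (8 values).
#'
#' @return Character vector of length 42.
#' @export
feature_names <- function() {
  ch <- c("ax", "ay", "az", "gx", "gy", "gz", "dba", "ra")
  stats <- as.vector(t(outer(ch, c("mean", "min", "max", "var"), paste,
                             sep = "_")))
  osc <- as.vector(t(outer(c("gx", "gy", "ax", "ay"),
                           c("osc_mean", "osc_max"), paste, sep = "_")))
  c(stats, "depth_diff", "duration", osc)
}

FEATURE_VERSION <- 1L

#' Per-channel summary statistics
#'
#' Sample mean, minimum, maximum and variance (population form, denominator
#' n) for each column of a channel matrix.
#'
#' @param m Numeric matrix, one column per channel, >= 2 rows.
#' @return Numeric vector: 4 values per channel in column order.
#' @export
summary_stats <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2) stop("need at least two samples per channel", call. = FALSE)
  mu <- colMeans(m)
  v <- colMeans(m^2) - mu^2
  out <- rbind(mean = mu, min = apply(m, 2, min), max = apply(m, 2, max),
               var = pmax(v, 0))
  as.vector(out)
}

#' Oscillation features of a high-frequency channel
#'
#' Quantifies the high-frequency oscillations that distinguish feeding
#' (pitch-rate bursts when the animal pulls on seagrass): (i) the raw
#' signal is smoothed with a centred 1 s running mean; (ii) the deviation
#' `d` of the raw signal from the running mean is taken; (iii) the segment
#' mean `m(d)` of the deviations; (iv) the mean and maximum of the squared
#' centred deviations `(d - m(d))^2` are returned.
#'
#' @param x Raw channel values clipped to the segment.
#' @param rate Sampling rate (Hz).
#' @param window Smoothing window (s, default 1).
#' @return `c(osc_mean, osc_max)`, both >= 0.
#' @export
oscillation_features <- function(x, rate = 20, window = 1) {
  d <- x - running_mean(x, round(window * rate))
  sq <- (d - mean(d))^2
  c(osc_mean = mean(sq), osc_max = max(sq))
}

#' Build the 42-variable feature vector of one segment
#'
#' Channels are clipped to the segment's half-open interval on the 20 Hz
#' grid; acceleration and angular velocity are the tilt-corrected signals,
#' DBA and RA the derived channels. The depth difference uses the 1 Hz
#' depth samples nearest the segment boundaries.
#'
#' @param record A preprocessed `sensor_record`.
#' @param start,end Segment boundaries (s).
#' @param cfg A `diveseg_config`.
#' @return Named numeric vector of length 42 in [feature_names()] order.
#' @export
featurize <- function(record, start, end, cfg = diveseg_config()) {
  if (is.null(record$derived))
    stop("record has no derived channels; run preprocess_record() first",
         call. = FALSE)
  span <- record_duration(record)
  if (start < -1e-9 || end > span + 1e-9 || end <= start)
    stop("segment [", start, ", ", end, ") outside record span [0, ",
         span, ")", call. = FALSE)
  idx <- imu_index_range(start, end, record$imu_rate)
  if (length(idx) < 2)
    stop("segment [", start, ", ", end, ") clips fewer than two IMU samples",
         call. = FALSE)
  ch <- cbind(record$a[idx, , drop = FALSE], record$g[idx, , drop = FALSE],
              dba = record$derived$dba[idx], ra = record$derived$ra[idx])
  stats32 <- summary_stats(ch)
  nd <- length(record$depth)
  di0 <- min(nd, max(1L, floor(start + 1e-9) + 1L))
  di1 <- min(nd, max(1L, floor(end - 1e-9) + 1L))
  depth_diff <- record$depth[di1] - record$depth[di0]
  osc <- c(
    oscillation_features(record$g[idx, 1], record$imu_rate, cfg$smooth_window),
    oscillation_features(record$g[idx, 2], record$imu_rate, cfg$smooth_window),
    oscillation_features(record$a[idx, 1], record$imu_rate, cfg$smooth_window),
    oscillation_features(record$a[idx, 2], record$imu_rate, cfg$smooth_window))
  out <- c(stats32, depth_diff, end - start, osc)
  names(out) <- feature_names()
  out
}

#' Feature table for a set of segments
#'
#' One row per segment: identifiers, boundaries, structural kind, kinematic
#' tag, ground truth (when present) and the 42 feature columns.
#'
#' @param segments A segment table.
#' @param record The preprocessed `sensor_record` the segments refer to.
#' @param cfg A `diveseg_config`.
#' @return A `data.frame` of class `feature_table`.
#' @export
featurize_segments <- function(segments, record, cfg = diveseg_config()) {
  feats <- t(vapply(seq_len(nrow(segments)), function(i)
    featurize(record, segments$start[i], segments$end[i], cfg),
    numeric(42)))
  meta <- segments[, c("individual_id", "start", "end", "kind",
                       "kinematic_tag", "ground_truth")]
  out <- cbind(meta, as.data.frame(feats))
  rownames(out) <- NULL
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Feature-table round trip
#'
#' The CSV carries a comment header line recording the frozen feature-order
#' version, so that models trained on one table are only applied to tables
#' with the same layout.
#'
#' @param features A `feature_table`.
#' @param path CSV path.
#' @export
write_feature_table <- function(features, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# diveseg_feature_version: %d", FEATURE_VERSION), con)
  utils::write.csv(features, con, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("feature table not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1)
  ver <- suppressWarnings(as.integer(sub(".*: *", "", first)))
  if (!grepl("diveseg_feature_version", first) || is.na(ver))
    stop("feature table lacks a version header: ", path, call. = FALSE)
  if (ver != FEATURE_VERSION)
    stop("feature table version ", ver, " does not match ", FEATURE_VERSION,
         call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  chr <- vapply(df, is.character, logical(1))
  df[chr] <- lapply(df[chr], function(x) replace(x, !is.na(x) & x == "", NA))
  class(df) <- c("feature_table", "data.frame")
  df
}
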