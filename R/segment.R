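#' Dive detection from the 1 Hz depth channel
#'
#' Splits the record span into dives and surface periods. A dive is a
#' maximal run of depth samples exceeding the depth threshold (strictly
#' > 0.3 m by default) lasting at least the minimum duration (5 s);
#' shallower or shorter excursions are absorbed into the surrounding
#' surface period. The i-th depth sample covers the half-open second
#' `[i-1, i)`, so boundaries are integers and the output tiles the record.
#'
#' @param depth 1 Hz depth vector (m, >= 0).
#' @param cfg A `diveseg_config`.
#' @return `data.frame(start, end, kind)` with kind `"dive"` or
#'   `"surface"`, tiling `[0, length(depth))`.
#' @export
detect_dives <- function(depth, cfg = diveseg_config()) {
  n <- length(depth)
  deep <- depth > cfg$dive_depth_threshold
  r <- rle(deep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  is_dive <- r$values & r$lengths >= cfg$dive_min_duration
  # merge everything that is not a dive into surface runs
  kind <- ifelse(is_dive, "dive", "surface")
  out <- data.frame(start = as.numeric(starts), end = as.numeric(ends),
                    kind = kind, stringsAsFactors = FALSE)
  if (nrow(out) > 1) {
    merged <- out[1, , drop = FALSE]
    for (i in 2:nrow(out)) {
      if (out$kind[i] == "surface" &&
          merged$kind[nrow(merged)] == "surface") {
        merged$end[nrow(merged)] <- out$end[i]
      } else {
        merged <- rbind(merged, out[i, ])
      }
    }
    out <- merged
  }
  rownames(out) <- NULL
  out
}

#' Surface-interval behaviour rule
#'
#' Surface periods are attributed from depth alone: `Breathing` when the
#' animal stays at the surface for at most 6 s, `StayingAtSurface` when
#' longer. Exactly 6 s counts as Breathing.
#'
#' @param duration Surface-interval duration (s).
#' @param cfg A `diveseg_config`.
#' @return `"Breathing"` or `"StayingAtSurface"`.
#' @export
classify_surface <- function(duration, cfg = diveseg_config()) {
  ifelse(duration <= cfg$surface_breathing_max, "Breathing",
         "StayingAtSurface")
}

# Standardize a series to zero mean / unit variance; constant series map
# to zero. Applied to the per-dive vertical speed before the depth-stage
# changepoint so the penalty acts on a scale-free series (deep and shallow
# dives alike).
standardize <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s < 1e-8) return(rep(0, length(x)))
  (x - mean(x)) / s
}

# IMU sample indices covering the half-open time interval [start, end).
imu_index_range <- function(start, end, rate) {
  i0 <- ceiling(start * rate + 1 - 1e-9)
  i1 <- ceiling(end * rate + 1 - 1e-9) - 1L
  if (i1 < i0) integer(0) else seq.int(i0, i1)
}

# Merge pieces shorter than min_dur (s) into their longer neighbour.
merge_short_pieces <- function(bounds, min_dur) {
  # bounds: numeric vector of boundaries, length >= 2
  repeat {
    durs <- diff(bounds)
    if (length(durs) <= 1) break
    short <- which(durs < min_dur - 1e-9)
    if (!length(short)) break
    i <- short[which.min(durs[short])]
    # remove the boundary shared with the longer neighbour
    left <- if (i == 1) -Inf else durs[i - 1]
    right <- if (i == length(durs)) -Inf else durs[i + 1]
    if (right >= left) bounds <- bounds[-(i + 1)] else bounds <- bounds[-i]
  }
  bounds
}

#' Hierarchical segmentation of one dive
#'
#' Implements the three-stage changepoint hierarchy within a dive:
#' \enumerate{
#'   \item the depth change over 3 s (the 1 Hz vertical-speed series,
#'     standardized within the dive) is segmented for changes in mean
#'     (penalty `pen_depth`) — a steady descent is a constant positive
#'     change and the bottom phase a constant zero, so the changepoint
#'     evidence concentrates at the true phase switches and the penalty
#'     acts on a scale-free series regardless of dive depth; each piece is
#'     tagged ascending / descending / flat from its mean vertical speed
#'     (threshold 0.1 m s^-1);
#'   \item ascending and descending pieces are re-segmented on the 20 Hz
#'     DBA for changes in mean and variance (penalty `pen_dba`), separating
#'     active swimming from gliding;
#'   \item flat pieces are re-segmented on the 20 Hz pitch rate `gy` for
#'     changes in variance (penalty `pen_gy`), isolating the pitch
#'     oscillation bursts typical of feeding.
#' }
#' Sub-bouts shorter than `min_subsegment` (1 s) are merged into their
#' longer neighbour. The returned segments tile `[start, end)`.
#'
#' @param record A preprocessed `sensor_record` (see [preprocess_record()]).
#' @param start,end Dive boundaries (s, integers from [detect_dives()]).
#' @param cfg A `diveseg_config`.
#' @return A segment table (`data.frame`).
#' @export
segment_dive <- function(record, start, end, cfg = diveseg_config()) {
  if (is.null(record$derived))
    stop("record has no derived channels; run preprocess_record() first",
         call. = FALSE)
  dur <- end - start
  dsel <- (start + 1):end                     # 1 Hz samples in the dive
  vsp <- record$derived$vspeed
  vsp_d <- vsp[dsel]                          # 3 s vertical speed, 1 Hz
  if (length(vsp_d) >= 2 * cfg$minseglen) {
    s1 <- pelt(standardize(vsp_d), "mean", cfg$pen_depth, cfg$minseglen)
    bounds <- start + c(0, s1$changepoints)
    bounds[length(bounds)] <- end
  } else {
    bounds <- c(start, end)                   # too short: single flat piece
  }
  bounds <- unique(bounds)
  rows <- list()
  for (i in seq_len(length(bounds) - 1)) {
    ps <- bounds[i]; pe <- bounds[i + 1]
    v <- mean(vsp[(floor(ps) + 1):floor(pe)])
    tag <- if (v > cfg$vspeed_threshold) "descending"
           else if (v < -cfg$vspeed_threshold) "ascending"
           else "flat"
    if (tag == "flat") {
      sig <- record$g[imu_index_range(ps, pe, record$imu_rate), 2]
      kind0 <- "dive-flat"; kind1 <- "dive-flat-sub"
      pen <- cfg$pen_gy; ck <- "var"
    } else {
      sig <- record$derived$dba[imu_index_range(ps, pe, record$imu_rate)]
      kind0 <- paste0("dive-", tag); kind1 <- "dive-swimglide-sub"
      pen <- cfg$pen_dba; ck <- "meanvar"
    }
    if (length(sig) >= 2 * cfg$minseglen) {
      sub <- pelt(sig, ck, pen, cfg$minseglen)
      sb <- ps + c(0, sub$changepoints) / record$imu_rate
      sb[length(sb)] <- pe
      sb <- merge_short_pieces(unique(sb), cfg$min_subsegment)
    } else {
      sb <- c(ps, pe)
    }
    kind <- if (length(sb) > 2) kind1 else kind0
    for (j in seq_len(length(sb) - 1)) {
      rows[[length(rows) + 1]] <- data.frame(
        individual_id = record$individual_id,
        start = sb[j], end = sb[j + 1], kind = kind,
        kinematic_tag = tag, ground_truth = NA_character_,
        predicted = NA_character_, stringsAsFactors = FALSE)
    }
  }
  as_segment_table(do.call(rbind, rows))
}

#' Segment a whole record into behavioural bouts
#'
#' Applies the dive/surface split, the surface-behaviour rule and the
#' per-dive changepoint hierarchy; the returned segments tile the record.
#' Surface segments carry their depth-derived behaviour as the kinematic
#' tag; filling in annotation-based ground truth is left to
#' [assign_ground_truth()].
#'
#' @param record A preprocessed `sensor_record`.
#' @param cfg A `diveseg_config`.
#' @return A segment table (`data.frame`).
#' @export
segment_record <- function(record, cfg = diveseg_config()) {
  phases <- detect_dives(record$depth, cfg)
  out <- list()
  for (i in seq_len(nrow(phases))) {
    if (phases$kind[i] == "surface") {
      dur <- phases$end[i] - phases$start[i]
      out[[length(out) + 1]] <- data.frame(
        individual_id = record$individual_id,
        start = phases$start[i], end = phases$end[i], kind = "surface",
        kinematic_tag = classify_surface(dur, cfg),
        ground_truth = NA_character_, predicted = NA_character_,
        stringsAsFactors = FALSE)
    } else {
      out[[length(out) + 1]] <-
        segment_dive(record, phases$start[i], phases$end[i], cfg)
    }
  }
  seg <- as_segment_table(do.call(rbind, out))
  # clip the final boundary to the exact record span (the last depth second
  # may be partial relative to the IMU span)
  span <- record_duration(record)
  seg$end[nrow(seg)] <- span
  seg
}

#' Ground-truth labelling of segments (3/5 majority rule)
#'
#' Each segment receives the behavioural category that covers at least the
#' majority fraction (3/5) of its duration, computed as half-open interval
#' overlap against the annotation; when no category reaches the fraction
#' the segment is labelled `Transition`. Time not covered by any annotation
#' interval counts as `Other`.
#'
#' @param segments A segment table.
#' @param intervals A `behavior_intervals` data frame.
#' @param cfg A `diveseg_config`.
#' @return The segment table with `ground_truth` filled in.
#' @export
assign_ground_truth <- function(segments, intervals,
                                cfg = diveseg_config()) {
  cats <- unique(intervals$category)
  for (i in seq_len(nrow(segments))) {
    s <- segments$start[i]; e <- segments$end[i]
    ov <- pmax(0, pmin(intervals$end, e) - pmax(intervals$start, s))
    tot <- tapply(ov, intervals$category, sum)
    covered <- sum(ov)
    other <- (e - s) - covered          # uncovered time counts as Other
    tot <- tot[!is.na(tot)]
    if (other > 1e-9)
      tot["Other"] <- (if ("Other" %in% names(tot)) tot[["Other"]] else 0) + other
    best <- which.max(tot)
    segments$ground_truth[i] <-
      if (tot[[best]] >= cfg$majority_fraction * (e - s) - 1e-9)
        names(tot)[best] else "Transition"
  }
  segments
}
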