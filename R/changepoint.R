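#' Gaussian segment costs for changepoint detection
#'
#' Three per-segment cost functions under a Gaussian model, matching the
#' likelihood-based costs the penalty values of the segmentation workflow
#' were tuned against:
#' \describe{
#'   \item{mean}{change in mean, unit variance: `C = sum((y - mean_seg)^2)`.}
#'   \item{var}{change in variance with the mean fixed at the series mean
#'     `mu`: `C = m * log(sigma2)`, `sigma2 = sum((y - mu)^2) / m`.}
#'   \item{meanvar}{change in mean and variance:
#'     `C = m * (log(2*pi) + log(sigma2) + 1)` with `sigma2` the segment
#'     MLE variance.}
#' }
#' Variances are floored at 1e-12 so the log stays finite on constant
#' segments. Every cost is additive over a partition.
#'
#' @name cost_model
NULL

VAR_FLOOR <- 1e-12

# Precompute sufficient statistics for O(1) segment costs.
cost_setup <- function(y, kind) {
  n <- length(y)
  env <- list(kind = kind, n = n,
              s1 = c(0, cumsum(y)), s2 = c(0, cumsum(y^2)))
  if (kind == "var") {
    mu <- mean(y)
    env$s2c <- c(0, cumsum((y - mu)^2))
  }
  env
}

# Cost of segments (i..j) for vectorized i (or j); 1-based inclusive.
seg_cost <- function(st, i, j) {
  m <- j - i + 1
  switch(st$kind,
    mean = {
      s1 <- st$s1[j + 1] - st$s1[i]
      (st$s2[j + 1] - st$s2[i]) - s1^2 / m
    },
    var = {
      v <- pmax((st$s2c[j + 1] - st$s2c[i]) / m, VAR_FLOOR)
      m * log(v)
    },
    meanvar = {
      s1 <- st$s1[j + 1] - st$s1[i]
      v <- pmax(((st$s2[j + 1] - st$s2[i]) - s1^2 / m) / m, VAR_FLOOR)
      m * (log(2 * pi) + log(v) + 1)
    },
    stop("unknown cost kind: ", st$kind, call. = FALSE))
}

# Deterministic selection among near-tied candidates: minimal value, then
# fewest segments so far, then earliest last changepoint.
select_candidate <- function(vals, nseg, s, tol = 1e-9) {
  best <- min(vals)
  idx <- which(vals <= best + tol)
  if (length(idx) > 1) {
    idx <- idx[nseg[idx] == min(nseg[idx])]
    idx <- idx[which.min(s[idx])]
  }
  idx[1]
}

check_cpt_input <- function(y, minseglen) {
  if (!is.numeric(y)) stop("series must be numeric", call. = FALSE)
  if (any(!is.finite(y))) stop("series contains non-finite values", call. = FALSE)
  if (minseglen < 1) stop("minseglen must be >= 1", call. = FALSE)
  if (length(y) < minseglen)
    stop("series shorter than minseglen (", length(y), " < ", minseglen, ")",
         call. = FALSE)
}

new_segmentation <- function(cps, cost, n, kind, penalty) {
  structure(list(changepoints = cps, total_cost = cost, n = n,
                 kind = kind, penalty = penalty),
            class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat("<segmentation> n =", x$n, "cost kind =", x$kind,
      "penalty =", x$penalty, "\n")
  cat("  segment ends:", paste(x$changepoints, collapse = ", "), "\n")
  cat("  penalized cost:", format(x$total_cost), "\n")
  invisible(x)
}

#' Exact penalized changepoint detection (PELT)
#'
#' Minimizes `sum(C(segment)) + penalty * (number of changepoints)` exactly
#' over all partitions of the series that respect `minseglen`, using the
#' pruned-exact-linear-time recursion. Pruning is lossless for these
#' likelihood costs, so the result equals the brute-force optimal
#' partitioning ([brute_force_segmentation()]). Ties between equal-cost
#' partitions are broken toward fewer changepoints, then toward the
#' earliest last changepoint.
#'
#' @param y Numeric series.
#' @param cost One of `"mean"`, `"var"`, `"meanvar"` (see [cost_model]).
#' @param penalty Non-negative penalty per additional changepoint.
#' @param minseglen Minimum segment length in samples (default 2).
#' @return An object of class `segmentation`: `changepoints` (last index of
#'   each segment, the final entry being `length(y)`) and `total_cost`.
#' @examples
#' y <- c(rep(0, 20), rep(10, 20))
#' pelt(y, "mean", penalty = 5)$changepoints
#' @export
pelt <- function(y, cost = c("mean", "var", "meanvar"), penalty,
                 minseglen = 2) {
  cost <- match.arg(cost)
  check_cpt_input(y, minseglen)
  if (penalty < 0) stop("penalty must be >= 0", call. = FALSE)
  n <- length(y)
  st <- cost_setup(y, cost)
  if (n < 2 * minseglen)
    return(new_segmentation(n, seg_cost(st, 1, n), n, cost, penalty))
  # F[t + 1]: optimal penalized cost of y[1..t]; F[1] = -penalty so the
  # first segment carries no penalty.
  F <- rep(Inf, n + 1); F[1] <- -penalty
  prev <- integer(n + 1)          # chosen last changepoint before t
  nseg <- integer(n + 1)          # segments in the optimum up to t
  cand <- 0L                      # candidate last-changepoint positions
  drop_at <- vector("list", n + 1)  # removals deferred until the dominating
                                    # candidate t is itself admissible
  for (t in minseglen:n) {
    if (!is.null(drop_at[[t]])) cand <- setdiff(cand, drop_at[[t]])
    v <- cand[cand <= t - minseglen]   # old enough to close a segment at t
    costs <- seg_cost(st, v + 1, t)
    vals <- F[v + 1] + costs + penalty
    pick <- select_candidate(vals, nseg[v + 1], v)
    F[t + 1] <- vals[pick]
    prev[t + 1] <- v[pick]
    nseg[t + 1] <- nseg[v[pick] + 1] + 1L
    # prune (lossless, K = 0): s with F[s] + C(s+1, t) > F[t] is dominated
    # by candidate t, which only becomes admissible at t + minseglen.
    bad <- v[(F[v + 1] + costs) > F[t + 1] + 1e-9]
    if (length(bad) && t + minseglen <= n)
      drop_at[[t + minseglen]] <- c(drop_at[[t + minseglen]], bad)
    cand <- c(cand, t)
  }
  cps <- integer(0); t <- n
  while (t > 0) { cps <- c(t, cps); t <- prev[t + 1] }
  new_segmentation(cps, F[n + 1], n, cost, penalty)
}

#' Brute-force optimal partitioning (test oracle)
#'
#' Solves the same penalized minimization as [pelt()] by dynamic
#' programming over all admissible split points without pruning, computing
#' each segment cost directly from the raw data. Quadratic in the series
#' length; intended as an independent oracle on short series.
#'
#' @inheritParams pelt
#' @return A `segmentation`.
#' @export
brute_force_segmentation <- function(y, cost = c("mean", "var", "meanvar"),
                                     penalty, minseglen = 2) {
  cost <- match.arg(cost)
  check_cpt_input(y, minseglen)
  if (penalty < 0) stop("penalty must be >= 0", call. = FALSE)
  n <- length(y)
  mu <- mean(y)
  cfun <- switch(cost,
    mean = function(seg) sum((seg - mean(seg))^2),
    var = function(seg) length(seg) * log(max(mean((seg - mu)^2), VAR_FLOOR)),
    meanvar = function(seg) {
      v <- max(mean((seg - mean(seg))^2), VAR_FLOOR)
      length(seg) * (log(2 * pi) + log(v) + 1)
    })
  if (n < 2 * minseglen)
    return(new_segmentation(n, cfun(y), n, cost, penalty))
  F <- rep(Inf, n + 1); F[1] <- -penalty
  prev <- integer(n + 1)
  nseg <- integer(n + 1)
  for (t in minseglen:n) {
    s <- c(0L, seq_len(t - minseglen))
    s <- s[s == 0L | s >= minseglen]
    s <- s[t - s >= minseglen]
    if (!length(s)) next
    vals <- vapply(s, function(si) F[si + 1] + cfun(y[(si + 1):t]) + penalty,
                   numeric(1))
    pick <- select_candidate(vals, nseg[s + 1], s)
    F[t + 1] <- vals[pick]
    prev[t + 1] <- s[pick]
    nseg[t + 1] <- nseg[s[pick] + 1] + 1L
  }
  cps <- integer(0); t <- n
  while (t > 0) { cps <- c(t, cps); t <- prev[t + 1] }
  new_segmentation(cps, F[n + 1], n, cost, penalty)
}
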