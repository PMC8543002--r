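# Movement-cycle detection from the chest mediolateral acceleration.  A cycle
# starts where the upper body is in the "left-position": a local minimum of
# the Gaussian-smoothed mediolateral channel.  Only minima with sufficient
# topographic prominence count, so aperiodic segments yield no cycles.

#' Detect movement-cycle boundaries from chest acceleration
#'
#' @param chest A `sensor_stream` with an `acc_y` (mediolateral) channel, or
#'   a numeric vector.
#' @param rate Sampling rate, Hz (taken from the stream if omitted).
#' @param sigma Gaussian smoothing kernel width, s.
#' @param prominence_k Minima are kept when their prominence exceeds
#'   `prominence_k` times the SD of the smoothed signal.
#' @param time Sample times when `chest` is a bare vector; defaults to the
#'   stream's master-clock times.
#' @return Ascending boundary times (s) on the same clock as `time`.
#' @export
detect_cycles <- function(chest, rate = NULL, sigma = 0.15,
                          prominence_k = 0.3, time = NULL) {
  if (inherits(chest, "sensor_stream")) {
    rate <- chest$rate
    time <- time %||% master_time(chest)
    x <- chest$data$acc_y
  } else {
    x <- chest
    if (is.null(rate)) stopf("rate is required for a bare numeric signal")
    time <- time %||% ((seq_along(x) - 1) / rate)
  }
  if (!length(x)) stopf("empty signal")
  if (sigma <= 0) stopf("sigma must be > 0")
  xs <- gaussian_smooth(x, sigma * rate)
  cand <- local_minima(xs)
  if (!length(cand)) return(numeric(0))
  prom <- peak_prominence(-xs, cand)
  thr <- prominence_k * stats::sd(xs)
  sort(time[cand[prom >= thr]])
}

#' Cycle table from boundary times
#'
#' @param boundaries Ascending cycle-start times from [detect_cycles()].
#' @return Data frame `start`, `end`: one row per cycle between consecutive
#'   boundaries.
#' @export
cycles_from_boundaries <- function(boundaries) {
  if (length(boundaries) < 2) {
    return(data.frame(start = numeric(0), end = numeric(0)))
  }
  data.frame(start = boundaries[-length(boundaries)], end = boundaries[-1])
}

#' Cycle length and rate from boundaries and treadmill speed
#'
#' Cycle rate is `60 / duration` (cycles/min); cycle length is the mean
#' treadmill speed over the cycle (m/s) times the duration (s), so that
#' `CL * CR / 60` equals the mean speed exactly.
#'
#' @param cycles Data frame with `start`, `end` (s).
#' @param speed Either a single speed (m/s), a per-second speed series
#'   (m/s, second k at index k+1), or a function of time.
#' @return `cycles` with `duration`, `cr` (cycles/min) and `cl` (m) added.
#' @export
cycle_kinematics <- function(cycles, speed) {
  d <- cycles$end - cycles$start
  if (any(d <= 0)) stopf("zero- or negative-duration cycle")
  v <- if (is.function(speed)) {
    vapply(seq_len(nrow(cycles)),
           function(i) mean(speed(seq(cycles$start[i], cycles$end[i], length.out = 32))),
           numeric(1))
  } else if (length(speed) == 1) {
    rep(speed, nrow(cycles))
  } else {
    vapply(seq_len(nrow(cycles)), function(i) {
      idx <- (floor(cycles$start[i]):ceiling(cycles$end[i] - 1e-9)) + 1
      idx <- idx[idx >= 1 & idx <= length(speed)]
      mean(speed[idx])
    }, numeric(1))
  }
  cycles$duration <- d
  cycles$cr <- 60 / d
  cycles$cl <- v * d
  cycles
}

#' Match detected cycle boundaries against reference boundaries
#'
#' Greedy nearest-neighbour matching within a tolerance; used to score
#' detection against ground truth and to transfer reference labels onto
#' detected cycles.
#'
#' @param detected,reference Ascending boundary times (s).
#' @param tol Matching tolerance, s.
#' @return A list: `matches` (data frame `detected`, `reference`, both times),
#'   `recall`, `precision`, `f1`.
#' @export
match_boundaries <- function(detected, reference, tol = 0.1) {
  used <- rep(FALSE, length(detected))
  pairs <- lapply(seq_along(reference), function(i) {
    free <- which(!used)
    if (!length(free)) return(NULL)
    j <- free[which.min(abs(detected[free] - reference[i]))]
    if (abs(detected[j] - reference[i]) <= tol) {
      used[j] <<- TRUE
      data.frame(detected = detected[j], reference = reference[i])
    } else NULL
  })
  matches <- do.call(rbind, pairs[!vapply(pairs, is.null, logical(1))])
  n_match <- if (is.null(matches)) 0 else nrow(matches)
  recall <- if (length(reference)) n_match / length(reference) else NA_real_
  precision <- if (length(detected)) n_match / length(detected) else NA_real_
  f1 <- if (isTRUE(recall + precision > 0)) 2 * recall * precision / (recall + precision) else 0
  list(matches = matches %||% data.frame(detected = numeric(0), reference = numeric(0)),
       recall = recall, precision = precision, f1 = f1)
}

#' Apply manual label corrections to a cycle table
#'
#' Mirrors the manual review step in which automatically classified cycles
#' are corrected against video: an override table keyed by cycle start time
#' replaces labels verbatim.
#'
#' @param cycles Cycle table with `start` and `label`.
#' @param overrides Data frame with `start` and `label`.
#' @param tol Start-time matching tolerance, s.
#' @return The cycle table with overridden labels.
#' @export
apply_label_overrides <- function(cycles, overrides, tol = 1e-6) {
  if (is.null(overrides) || !nrow(overrides)) return(cycles)
  for (i in seq_len(nrow(overrides))) {
    j <- which(abs(cycles$start - overrides$start[i]) <= tol)
    if (length(j) == 1) cycles$label[j] <- overrides$label[i]
  }
  cycles
}
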