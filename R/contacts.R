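# Pole and ski ground-contact detection from wrist and ski inertial units.
#
# Pole: initial contact is the first acceleration peak at the onset of the
# high-frequency vibration induced by the pole hitting the ground; terminal
# contact is the highest acceleration peak close to the minimum angular speed
# (the hand changing direction to bring the pole back).
#
# Ski: ski-on-ground shows as a long phase of low pitch angular velocity;
# initial contact is the last pitch-rate peak before that phase and terminal
# contact the last negative vertical-acceleration peak after it.

.acc_mag <- function(data) {
  acc <- as.matrix(data[, c("acc_x", "acc_y", "acc_z")])
  med <- apply(acc, 2, stats::median)
  sqrt(rowSums(sweep(acc, 2, med)^2))
}

.gyro_mag <- function(data) {
  sqrt(rowSums(as.matrix(data[, c("gyro_x", "gyro_y", "gyro_z")])^2))
}

#' Detect pole ground-contact events from a wrist inertial stream
#'
#' @param wrist A `sensor_stream` with channels `acc_x/y/z` and `gyro_x/y/z`.
#' @param band High-frequency vibration band, Hz.
#' @param energy_window Moving-SD window for the vibration energy, s.
#' @param threshold_k Vibration-onset threshold in baseline (MAD) units.
#' @param terminal_window Half-width of the terminal search window around the
#'   angular-speed minimum, s.
#' @param refractory Minimum separation between vibration onsets, s.
#' @return Data frame `initial`, `terminal` (master-clock s), one row per
#'   poling action; the number of onsets dropped because no terminal peak
#'   qualified is attached as attribute `skipped` (with a warning).
#' @export
detect_pole_contacts <- function(wrist, band = c(20, 60), energy_window = 0.02,
                                 threshold_k = 4, terminal_window = 0.075,
                                 refractory = 0.3) {
  rate <- wrist$rate
  time <- master_time(wrist)
  mag <- .acc_mag(wrist$data)
  gmag <- .gyro_mag(wrist$data)
  bf <- signal::butter(2, band / (rate / 2), type = "pass")
  bp <- signal::filtfilt(bf, mag)
  env <- moving_sd(bp, max(3L, as.integer(round(energy_window * rate))))
  thr <- threshold_k * stats::mad(bp)
  above <- env > thr
  starts <- which(above & !c(FALSE, above[-length(above)]))
  if (length(starts) > 1) {
    keep <- c(TRUE, diff(time[starts]) >= refractory)
    starts <- starts[keep]
  }
  n <- length(mag)
  w_init <- as.integer(round(0.08 * rate))
  gsm <- as.numeric(stats::filter(gmag, rep(0.2, 5), sides = 2))
  gsm[is.na(gsm)] <- gmag[is.na(gsm)]
  skipped <- 0L
  events <- list()
  last_terminal <- -Inf
  for (k in seq_along(starts)) {
    i0 <- starts[k]
    # the terminal acceleration peak excites the vibration band too; onsets
    # inside or just after the previous push belong to that push, not a new one
    if (time[i0] < last_terminal + refractory) next
    i1 <- min(n, i0 + w_init)
    ii <- i0 - 1L + which.max(mag[i0:i1])
    # terminal: angular-speed minimum after the push, before the next onset
    j0 <- min(n, ii + as.integer(round(0.05 * rate)))
    j1 <- if (k < length(starts)) starts[k + 1] - 1L else
      min(n, ii + as.integer(round(2 * rate)))
    if (j1 <= j0) { skipped <- skipped + 1L; next }
    jm <- j0 - 1L + which.min(gsm[j0:j1])
    w <- as.integer(round(terminal_window * rate))
    k0 <- max(j0, jm - w)
    k1 <- min(n, jm + w)
    if (k1 <= k0) { skipped <- skipped + 1L; next }
    jt <- k0 - 1L + which.max(mag[k0:k1])
    last_terminal <- time[jt]
    events[[length(events) + 1L]] <- data.frame(initial = time[ii],
                                                terminal = time[jt])
  }
  events <- do.call(rbind, events)
  if (is.null(events)) events <- data.frame(initial = numeric(0), terminal = numeric(0))
  if (skipped > 0) warnf("%d poling onset(s) skipped: empty terminal window", skipped)
  attr(events, "skipped") <- skipped
  events
}

#' Detect ski ground-contact events from a ski inertial stream
#'
#' @param ski A `sensor_stream` with channels `acc_x/y/z` and `gyro_x/y/z`
#'   (`gyro_y` is the pitch axis).
#' @param low_threshold Pitch-rate magnitude below which the ski counts as
#'   on the ground, deg/s.
#' @param min_dwell Minimum duration of the low-angular-velocity phase, s.
#' @param peak_min Minimum height of the initial pitch-rate peak, deg/s.
#' @param neg_threshold Terminal peaks must dip at least this far below the
#'   vertical-acceleration baseline (stream units).
#' @return Data frame `initial`, `terminal` (master-clock s).
#' @export
detect_ski_contacts <- function(ski, low_threshold = 30, min_dwell = 0.1,
                                peak_min = 100, neg_threshold = 1.5) {
  rate <- ski$rate
  time <- master_time(ski)
  p <- abs(ski$data$gyro_y)
  psm <- as.numeric(stats::filter(p, rep(0.2, 5), sides = 2))
  psm[is.na(psm)] <- p[is.na(psm)]
  az <- ski$data$acc_z - stats::median(ski$data$acc_z)
  low <- psm < low_threshold
  r <- rle(low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values & r$lengths >= min_dwell * rate)
  n <- length(p)
  back <- as.integer(round(0.2 * rate))
  fwd <- as.integer(round(0.05 * rate))
  events <- lapply(runs, function(k) {
    a <- starts[k]
    b <- ends[k]
    # initial: last qualifying pitch-rate peak just before the phase
    i0 <- max(1L, a - back)
    if (a - 1L < i0) return(NULL)
    seg <- psm[i0:(a - 1L)]
    pk <- local_maxima(seg)
    pk <- pk[seg[pk] >= peak_min]
    if (!length(pk)) return(NULL)
    ii <- i0 - 1L + pk[length(pk)]
    # terminal: last negative vertical-acceleration peak at the end of the phase
    j0 <- max(1L, b - as.integer(round(0.15 * rate)))
    j1 <- min(n, b + fwd)
    seg2 <- az[j0:j1]
    tr <- local_minima(seg2)
    tr <- tr[seg2[tr] <= -neg_threshold]
    if (!length(tr)) return(NULL)
    # measurement noise can split the deceleration peak into several local
    # minima; the deepest one marks the peak itself
    jt <- j0 - 1L + tr[which.min(seg2[tr])]
    if (time[jt] <= time[ii]) return(NULL)
    data.frame(initial = time[ii], terminal = time[jt])
  })
  events <- do.call(rbind, events[!vapply(events, is.null, logical(1))])
  if (is.null(events)) events <- data.frame(initial = numeric(0), terminal = numeric(0))
  events
}

#' Per-cycle contact-time metrics
#'
#' Events are assigned to the cycle containing their initial contact;
#' `CT = terminal - initial` and `%CT = 100 * CT / cycle duration`.  When both
#' sides are present their values are averaged; cycles without an event carry
#' `NA` (never zero).
#'
#' @param events Data frame `side`, `initial`, `terminal` (one contact kind).
#' @param cycles Cycle table with `start`, `end`.
#' @return Data frame with one row per cycle: `ct` (s) and `pct_ct` (% of
#'   cycle duration), side-averaged.
#' @export
contact_metrics <- function(events, cycles) {
  nc <- nrow(cycles)
  acc <- matrix(NA_real_, nc, 2, dimnames = list(NULL, c("L", "R")))
  if (nrow(events)) {
    idx <- findInterval(events$initial, cycles$start)
    for (e in seq_len(nrow(events))) {
      i <- idx[e]
      if (i < 1 || events$initial[e] >= cycles$end[i]) next
      if (i + 1 <= nc && events$terminal[e] > cycles$end[min(i + 1, nc)]) {
        stopf("contact event at %.2f s spans more than two cycles", events$initial[e])
      }
      side <- as.character(events$side[e])
      ct <- events$terminal[e] - events$initial[e]
      acc[i, side] <- if (is.na(acc[i, side])) ct else mean(c(acc[i, side], ct))
    }
  }
  ct <- rowMeans(acc, na.rm = TRUE)
  ct[is.nan(ct)] <- NA_real_
  data.frame(ct = ct, pct_ct = 100 * ct / (cycles$end - cycles$start))
}
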