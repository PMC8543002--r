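# Sensor streams: one uniformly sampled multichannel signal per device
# placement, plus CSV round-trip, synchronisation-jump detection and the
# reduction of aligned streams to per-second values.

.placements <- c("chest", "wrist_L", "wrist_R", "ski_L", "ski_R",
                 "pole_L", "pole_R", "markers", "hr", "vo2",
                 "tsi_arm", "tsi_leg")

#' Construct a sensor stream
#'
#' @param placement One of `"chest"`, `"wrist_L"`, `"wrist_R"`, `"ski_L"`,
#'   `"ski_R"`, `"pole_L"`, `"pole_R"`, `"markers"`, `"hr"`, `"vo2"`,
#'   `"tsi_arm"`, `"tsi_leg"`.
#' @param rate Sampling rate, Hz.
#' @param data Data frame with a uniform `time_s` column (the stream's local
#'   clock) and one column per channel.
#' @param t0 Offset (s) from the local clock to the master clock:
#'   `master = time_s + t0`.
#' @return An object of class `sensor_stream`.
#' @export
sensor_stream <- function(placement, rate, data, t0 = 0) {
  placement <- match.arg(placement, .placements)
  if (!is.numeric(rate) || rate <= 0) stopf("rate must be > 0")
  if (!is.data.frame(data) || is.null(data$time_s) || ncol(data) < 2) {
    stopf("data must have a 'time_s' column and at least one channel column")
  }
  .check_uniform(data$time_s, rate)
  structure(list(placement = placement, rate = rate, t0 = t0, data = data),
            class = "sensor_stream")
}

.check_uniform <- function(time_s, rate) {
  if (length(time_s) > 1) {
    d <- diff(time_s)
    if (any(d <= 0) || any(abs(d - 1 / rate) > 0.1 / rate)) {
      stopf("timestamps are not uniform at %g Hz (jitter > 10%% of the sample period)",
            rate)
    }
  }
  invisible(TRUE)
}

#' @export
print.sensor_stream <- function(x, ...) {
  cat(sprintf("<sensor_stream %s: %g Hz, %d samples, %d channel(s), t0 = %g s>\n",
              x$placement, x$rate, nrow(x$data), ncol(x$data) - 1, x$t0))
  invisible(x)
}

#' Channel names of a stream
#' @param stream A `sensor_stream`.
#' @export
stream_channels <- function(stream) setdiff(names(stream$data), "time_s")

#' Stream sample times on the master clock
#' @param stream A `sensor_stream`.
#' @export
master_time <- function(stream) stream$data$time_s + stream$t0

#' Write / read a sensor stream as CSV
#'
#' The CSV carries the stream metadata in `#`-prefixed header lines
#' (`placement`, `rate`, `t0`) followed by a `time_s` column and one column
#' per channel.  `read_stream(write_stream(s))` preserves values to full
#' double precision and metadata exactly.
#'
#' @param stream A `sensor_stream`.
#' @param path File path.
#' @export
write_stream <- function(stream, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# skifuse-stream: 1",
               sprintf("# placement: %s", stream$placement),
               sprintf("# rate: %.17g", stream$rate),
               sprintf("# t0: %.17g", stream$t0)), con)
  utils::write.csv(stream$data, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stream
#' @param placement Expected placement; validated against the file header
#'   when given.
#' @export
read_stream <- function(path, placement = NULL) {
  header <- readLines(path, n = 4)
  if (length(header) < 4 || !startsWith(header[1], "# skifuse-stream")) {
    stopf("'%s' is not a skifuse stream CSV", path)
  }
  meta <- function(i) trimws(sub("^# [a-z0-9]+:", "", header[i]))
  file_placement <- meta(2)
  rate <- as.numeric(meta(3))
  t0 <- as.numeric(meta(4))
  if (!is.null(placement) && !identical(placement, file_placement)) {
    stopf("stream file is '%s', expected '%s'", file_placement, placement)
  }
  data <- utils::read.csv(path, comment.char = "#")
  if (is.null(data$time_s)) stopf("stream CSV is missing the 'time_s' column")
  if (ncol(data) < 2) stopf("stream CSV has no channel columns")
  sensor_stream(file_placement, rate, data, t0)
}

#' Detect the three synchronisation jumps in a calibration window
#'
#' The calibration routine before each session contains three jumps that show
#' up as large vertical-acceleration spikes on every body-worn inertial unit.
#' Peaks are found on the absolute deviation from the window median, with a
#' threshold of `threshold_k` times the median absolute deviation and a
#' refractory gap between accepted peaks.  If more than three peaks qualify,
#' the three largest are kept.
#'
#' @param x Vertical acceleration, either a numeric vector or a
#'   `sensor_stream` (channel `acc_z`).
#' @param rate Sampling rate, Hz (taken from the stream if omitted).
#' @param window Local-clock search window `c(from, to)` in s; defaults to
#'   the full signal.
#' @param threshold_k Threshold in MADs above the median.
#' @param refractory Minimum separation between jumps, s.
#' @return Three ascending local-clock peak times (s).
#' @export
detect_sync_jumps <- function(x, rate = NULL, window = NULL,
                              threshold_k = 5, refractory = 0.5) {
  if (inherits(x, "sensor_stream")) {
    rate <- x$rate
    time <- x$data$time_s
    x <- x$data$acc_z
  } else {
    if (is.null(rate)) stopf("rate is required for a bare numeric signal")
    time <- (seq_along(x) - 1) / rate
  }
  keep <- if (is.null(window)) rep(TRUE, length(x)) else
    time >= window[1] & time < window[2]
  xs <- x[keep]
  ts <- time[keep]
  dev <- abs(xs - stats::median(xs))
  thr <- threshold_k * stats::mad(xs)
  cand <- local_maxima(dev)
  cand <- cand[dev[cand] > thr]
  cand <- cand[order(-dev[cand])]
  picked <- integer(0)
  for (i in cand) {
    if (all(abs(ts[i] - ts[picked]) >= refractory)) picked <- c(picked, i)
  }
  if (length(picked) < 3) {
    stopf("sync-jump detection found %d peak(s), expected 3", length(picked))
  }
  sort(ts[picked[1:3]])
}

#' Master-clock offset from detected sync jumps
#'
#' @param detected Three local-clock jump times from [detect_sync_jumps()].
#' @param expected_master The known master-clock times of the jumps.
#' @return The offset `t0` such that `master = local + t0`.
#' @export
sync_offset <- function(detected, expected_master) {
  if (length(detected) != length(expected_master)) {
    stopf("detected and expected jump counts differ")
  }
  mean(expected_master) - mean(detected)
}

#' Align a stream to the master clock via its sync jumps
#'
#' Detects the calibration jumps on the stream's vertical acceleration and
#' sets `t0` accordingly.
#'
#' @param stream A `sensor_stream` with an `acc_z` channel.
#' @param expected_master Master-clock times of the three jumps.
#' @param window Local-clock calibration search window (defaults to the
#'   pre-session part, i.e. everything before `max(expected_master) + 5` s
#'   on the uncorrected clock).
#' @return The stream with `t0` set.
#' @export
align_stream <- function(stream, expected_master, window = NULL) {
  if (is.null(window)) {
    window <- c(min(stream$data$time_s),
                min(stream$data$time_s) + diff(range(expected_master)) + 10)
  }
  jumps <- detect_sync_jumps(stream, window = window)
  stream$t0 <- sync_offset(jumps, expected_master)
  stream
}

#' Reduce an aligned signal to per-second values
#'
#' The value at second `k` is the mean of all samples with master time in
#' `[k, k + window)`; empty bins give `NA`.  The default window is 1 s; NIRS
#' tissue-saturation streams use a 2 s window.
#'
#' @param stream A `sensor_stream`, or a numeric vector with `time` given.
#' @param channel Channel to reduce (defaults to the first channel).
#' @param window Averaging window, 1 or 2 s.
#' @param n_seconds Number of output seconds (defaults to cover the data).
#' @param time Master-clock sample times when `stream` is a bare vector.
#' @return Numeric vector of length `n_seconds`; element `k + 1` is the mean
#'   over `[k, k + window)`.
#' @export
resample_1hz <- function(stream, channel = NULL, window = 1,
                         n_seconds = NULL, time = NULL) {
  if (!window %in% c(1, 2)) stopf("window must be 1 or 2 s")
  if (inherits(stream, "sensor_stream")) {
    channel <- channel %||% stream_channels(stream)[1]
    x <- stream$data[[channel]]
    time <- master_time(stream)
  } else {
    x <- stream
    if (is.null(time)) stopf("time is required for a bare numeric signal")
  }
  keep <- time >= 0 & !is.na(x)
  x <- x[keep]
  time <- time[keep]
  n_seconds <- n_seconds %||% (floor(max(time)) + 1)
  sec <- floor(time)
  sums <- counts <- numeric(n_seconds)
  tab <- rowsum(cbind(x, 1), sec)
  idx <- as.integer(rownames(tab)) + 1
  ok <- idx >= 1 & idx <= n_seconds
  sums[idx[ok]] <- tab[ok, 1]
  counts[idx[ok]] <- tab[ok, 2]
  if (window == 2) {
    s2 <- sums + c(sums[-1], 0)
    c2 <- counts + c(counts[-1], 0)
    sums <- s2
    counts <- c2
  }
  out <- ifelse(counts > 0, sums / counts, NA_real_)
  as.numeric(out)
}

#' Step-hold 10 s mixing-chamber values to a per-second series
#'
#' Each 10 s chamber value is repeated for the ten seconds it covers.
#'
#' @param values Chamber values (one per 10 s interval).
#' @param n_seconds Output length.
#' @export
step_hold_10s <- function(values, n_seconds = length(values) * 10) {
  rep(values, each = 10)[seq_len(n_seconds)]
}

#' Centred moving average for plotting (e.g. 30 s smoothed oxygen uptake)
#'
#' @param x Per-second series.
#' @param width Window width, s.
#' @export
moving_average <- function(x, width = 30) {
  as.numeric(stats::filter(x, rep(1 / width, width), sides = 2))
}
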