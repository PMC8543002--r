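# Lap/segment protocol model: a session is `laps` identical laps, each a fixed
# sequence of terrain segments with an incline and one treadmill speed per
# intensity.  The session clock starts at 0 s and segment windows are half-open
# [start, end), so they tile the session exactly.

#' Build a validated session protocol
#'
#' A protocol describes the repeated lap structure of a treadmill session:
#' the number of laps, the ordered terrain segments within a lap (incline,
#' low- and high-intensity treadmill speed, duration), and the downhill
#' "display" speeds used when whole-session distance and mean speed are
#' reported (the simulated downhill is skied at a safe treadmill speed, so a
#' more realistic descent speed is substituted for reporting).
#'
#' @param config Either a path to a YAML/JSON protocol file or an equivalent
#'   named list with keys `laps`, `lap_duration_s`,
#'   `downhill_display_speed_li_kmh`, `downhill_display_speed_hi_kmh` and
#'   `segments` (a list of `{incline_pct, speed_li_kmh, speed_hi_kmh,
#'   duration_s}`).
#' @return An object of class `ski_protocol`.
#' @examples
#' p <- default_protocol()
#' session_distance_and_speed(p, "LI")
#' @export
build_protocol <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stopf("config must be a list or a path to a YAML file")
  for (key in c("laps", "lap_duration_s", "segments",
                "downhill_display_speed_li_kmh", "downhill_display_speed_hi_kmh")) {
    if (is.null(config[[key]])) stopf("protocol config is missing '%s'", key)
  }
  laps <- as.integer(config$laps)
  lap_duration <- as.numeric(config$lap_duration_s)
  if (laps < 1) stopf("'laps' must be >= 1")
  if (lap_duration <= 0) stopf("'lap_duration_s' must be > 0")
  segs <- config$segments
  if (length(segs) != 4) {
    stopf("'segments' must list exactly 4 segments, got %d", length(segs))
  }
  seg_df <- do.call(rbind, lapply(seq_along(segs), function(i) {
    s <- segs[[i]]
    for (key in c("incline_pct", "speed_li_kmh", "speed_hi_kmh", "duration_s")) {
      if (is.null(s[[key]])) stopf("segment %d is missing '%s'", i, key)
    }
    data.frame(index = i,
               incline = as.numeric(s$incline_pct) / 100,
               speed_li = as.numeric(s$speed_li_kmh),
               speed_hi = as.numeric(s$speed_hi_kmh),
               duration = as.numeric(s$duration_s))
  }))
  if (any(seg_df$duration <= 0)) stopf("'duration_s' must be > 0 for every segment")
  if (any(seg_df$speed_li <= 0) || any(seg_df$speed_hi <= 0)) {
    stopf("segment speeds must be > 0")
  }
  if (any(abs(seg_df$incline) > 0.20)) {
    stopf("'incline_pct' must lie in [-20, 20]")
  }
  if (abs(sum(seg_df$duration) - lap_duration) > 1e-9) {
    stopf("segment 'duration_s' values sum to %g, not 'lap_duration_s' = %g",
          sum(seg_df$duration), lap_duration)
  }
  structure(
    list(laps = laps,
         lap_duration = lap_duration,
         segments = seg_df,
         downhill_display_speed_li = as.numeric(config$downhill_display_speed_li_kmh),
         downhill_display_speed_hi = as.numeric(config$downhill_display_speed_hi_kmh)),
    class = "ski_protocol")
}

#' Default packaged protocol (7 x 3 min laps, four segments)
#'
#' Inclines 5/2/12 % plus a simulated downhill, with treadmill speeds chosen so
#' that the time-weighted mean session speed (with the downhill display-speed
#' substitution) is 16.7 km/h at LI and 21.3 km/h at HI.
#'
#' @return A `ski_protocol`.
#' @export
default_protocol <- function() {
  build_protocol(system.file("extdata", "protocol_default.yaml",
                             package = "skifuse", mustWork = TRUE))
}

#' @export
print.ski_protocol <- function(x, ...) {
  cat(sprintf("Session protocol: %d laps x %g s (%g s total)\n",
              x$laps, x$lap_duration, total_duration(x)))
  print(x$segments, row.names = FALSE)
  cat(sprintf("Downhill display speed LI/HI: %g/%g km/h\n",
              x$downhill_display_speed_li, x$downhill_display_speed_hi))
  invisible(x)
}

#' Total session duration in seconds
#' @param protocol A `ski_protocol`.
#' @export
total_duration <- function(protocol) protocol$laps * protocol$lap_duration

#' All lap x segment windows of a session
#'
#' @param protocol A `ski_protocol`.
#' @return A data frame with columns `lap`, `segment`, `start`, `end`
#'   (half-open windows tiling `[0, total_duration)`).
#' @export
segment_windows <- function(protocol) {
  seg <- protocol$segments
  offs <- cumsum(c(0, seg$duration))[seq_len(nrow(seg))]
  out <- do.call(rbind, lapply(seq_len(protocol$laps), function(l) {
    data.frame(lap = l, segment = seg$index,
               start = (l - 1) * protocol$lap_duration + offs,
               end = (l - 1) * protocol$lap_duration + offs + seg$duration)
  }))
  rownames(out) <- NULL
  out
}

#' Locate the lap/segment window containing time t
#'
#' Vectorised over `t`; windows are half-open `[start, end)`.
#'
#' @param protocol A `ski_protocol`.
#' @param t Session time(s) in seconds, `0 <= t < total_duration`.
#' @return A data frame with one row per `t`: `lap`, `segment`, `start`, `end`.
#' @export
segment_at <- function(protocol, t) {
  tot <- total_duration(protocol)
  if (any(t < 0 | t >= tot)) {
    stopf("t must lie in [0, %g); got values outside the session", tot)
  }
  lap <- floor(t / protocol$lap_duration) + 1
  tin <- t - (lap - 1) * protocol$lap_duration
  ends <- cumsum(protocol$segments$duration)
  # findInterval on [a, b) boundaries: segment i covers [ends[i-1], ends[i])
  segment <- findInterval(tin, c(0, ends[-length(ends)]))
  start <- (lap - 1) * protocol$lap_duration + c(0, ends)[segment]
  end <- (lap - 1) * protocol$lap_duration + ends[segment]
  data.frame(lap = as.integer(lap), segment = as.integer(segment),
             start = start, end = end)
}

#' Per-segment treadmill (or display) speeds for one intensity
#'
#' @param protocol A `ski_protocol`.
#' @param intensity `"LI"` or `"HI"`.
#' @param display If `TRUE`, substitute the downhill display speed for
#'   segment 4 (used when reporting whole-session distance/speed).
#' @return Numeric vector of km/h, one per segment.
#' @export
segment_speeds <- function(protocol, intensity = c("LI", "HI"), display = FALSE) {
  intensity <- match.arg(intensity)
  v <- if (intensity == "LI") protocol$segments$speed_li else protocol$segments$speed_hi
  if (display) {
    v[length(v)] <- if (intensity == "LI") protocol$downhill_display_speed_li
                    else protocol$downhill_display_speed_hi
  }
  v
}

#' Treadmill belt speed at time t (km/h)
#'
#' @inheritParams segment_at
#' @param intensity `"LI"` or `"HI"`.
#' @export
treadmill_speed <- function(protocol, intensity, t) {
  v <- segment_speeds(protocol, intensity, display = FALSE)
  v[segment_at(protocol, t)$segment]
}

#' Whole-session distance and mean speed
#'
#' Distance is the time integral of segment speed over all laps, using the
#' downhill display speed for segment 4; mean speed is distance over total
#' duration.  Both are reported to one decimal (half-up), with raw values
#' retained.
#'
#' @param protocol A `ski_protocol`.
#' @param intensity `"LI"` or `"HI"`.
#' @return A list: `distance_km`, `mean_speed_kmh` (one decimal) and the
#'   unrounded `distance_km_raw`, `mean_speed_kmh_raw`.
#' @export
session_distance_and_speed <- function(protocol, intensity = c("LI", "HI")) {
  intensity <- match.arg(intensity)
  v <- segment_speeds(protocol, intensity, display = TRUE)
  km_s_per_h <- sum(v * protocol$segments$duration) * protocol$laps
  dist <- km_s_per_h / 3600
  speed <- dist / (total_duration(protocol) / 3600)
  list(distance_km = round_half_up(dist, 1),
       mean_speed_kmh = round_half_up(speed, 1),
       distance_km_raw = dist,
       mean_speed_kmh_raw = speed)
}
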