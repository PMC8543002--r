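# Pole and ski power.  Pole power is the dot product of the pole force vector
# (axial magnitude times the pole's unit direction) with the centre-of-mass
# velocity, per side; total cycle work rate against gravity and rolling
# friction on the incline is P = m g v (sin(theta) + mu cos(theta)); the
# residual P_ski = P_cycle - P_pole is attributed to the ski push-offs.

#' Reduced body-segment parameter table
#'
#' A configurable five-segment reduction (trunk incl. head and arms, thighs,
#' shanks incl. feet) with mass fractions summing to 1 and a CoM position
#' fraction along each segment's proximal-to-distal marker axis, in the style
#' of standard anthropometric segment tables.  The `offset_*` and `length_m`
#' columns describe where the synthetic generator places the marker pairs
#' relative to the whole-body CoM.
#'
#' @return Data frame with columns `segment`, `mass_fraction`,
#'   `com_fraction`, `prox_marker`, `dist_marker`, `offset_x/y/z`, `length_m`.
#' @export
default_segment_params <- function() {
  data.frame(
    segment = c("trunk", "thigh_L", "thigh_R", "shank_L", "shank_R"),
    mass_fraction = c(0.50, 0.14, 0.14, 0.11, 0.11),
    com_fraction = c(0.45, 0.41, 0.41, 0.44, 0.44),
    prox_marker = c("trunk_prox", "thigh_L_prox", "thigh_R_prox",
                    "shank_L_prox", "shank_R_prox"),
    dist_marker = c("trunk_dist", "thigh_L_dist", "thigh_R_dist",
                    "shank_L_dist", "shank_R_dist"),
    offset_x = c(0, 0, 0, 0, 0),
    offset_y = c(0, 0.10, -0.10, 0.10, -0.10),
    offset_z = c(0.498, -0.30, -0.30, -0.75, -0.75),
    length_m = c(0.50, 0.40, 0.40, 0.45, 0.45))
}

#' Read a segment parameter table from YAML
#'
#' @param path YAML file with a `segments` list of
#'   `{segment, mass_fraction, com_fraction, prox_marker, dist_marker}`.
#' @export
read_segment_params <- function(path) {
  cfg <- yaml::read_yaml(path)
  tab <- do.call(rbind, lapply(cfg$segments, as.data.frame))
  .check_segment_params(tab)
  tab
}

.check_segment_params <- function(table) {
  if (abs(sum(table$mass_fraction) - 1) > 1e-6) {
    stopf("segment mass fractions sum to %.8f, not 1", sum(table$mass_fraction))
  }
  invisible(table)
}

.marker_xyz <- function(markers, name) {
  cols <- paste0(name, "_", c("x", "y", "z"))
  missing <- setdiff(cols, names(markers))
  if (length(missing)) stopf("missing marker column(s): %s",
                             paste(missing, collapse = ", "))
  as.matrix(markers[, cols])
}

#' Whole-body centre of mass from marker positions
#'
#' `CoM = sum_s mass_fraction_s * (prox_s + com_fraction_s * (dist_s - prox_s))`
#' per time sample.
#'
#' @param markers Data frame with `time_s` and `<marker>_x/_y/_z` columns
#'   (or a `markers` `sensor_stream`).
#' @param params Segment parameter table, see [default_segment_params()].
#' @return Data frame `time_s`, `x`, `y`, `z`.
#' @export
com_from_markers <- function(markers, params = default_segment_params()) {
  if (inherits(markers, "sensor_stream")) markers <- markers$data
  .check_segment_params(params)
  com <- matrix(0, nrow(markers), 3)
  for (i in seq_len(nrow(params))) {
    prox <- .marker_xyz(markers, params$prox_marker[i])
    dist <- .marker_xyz(markers, params$dist_marker[i])
    com <- com + params$mass_fraction[i] *
      (prox + params$com_fraction[i] * (dist - prox))
  }
  data.frame(time_s = markers$time_s, x = com[, 1], y = com[, 2], z = com[, 3])
}

# apply f to each contiguous non-NA run of x (marker data exist on odd laps
# only, so series are interrupted by NA blocks)
.by_runs <- function(x, f) {
  out <- rep(NA_real_, length(x))
  ok <- !is.na(x)
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in which(r$values)) {
    idx <- starts[k]:ends[k]
    out[idx] <- f(x[idx])
  }
  out
}

#' Centre-of-mass velocity by numerical differentiation
#'
#' Central differences in the interior, one-sided at the edges, applied per
#' contiguous data block (marker gaps stay `NA`).  An optional Butterworth
#' low-pass is applied to the positions before differentiation.
#'
#' @param pos Data frame `time_s`, `x`, `y`, `z` from [com_from_markers()].
#' @param rate Sampling rate, Hz.
#' @param cutoff Optional low-pass cutoff, Hz (`NULL`, the default, skips
#'   smoothing; per-cycle averaging downstream already suppresses marker
#'   noise).  Positions are detrended by their chord line before filtering
#'   so the zero-phase filter does not ring against the large travelled
#'   distance.
#' @return Data frame `time_s`, `vx`, `vy`, `vz` (m/s).
#' @export
com_velocity <- function(pos, rate, cutoff = NULL) {
  if (nrow(pos) < 3) stopf("need at least 3 samples to differentiate")
  diff1 <- function(x) {
    n <- length(x)
    if (n < 3) return(rep(NA_real_, n))
    if (!is.null(cutoff)) {
      bf <- signal::butter(2, cutoff / (rate / 2), type = "low")
      chord <- x[1] + (x[n] - x[1]) * (0:(n - 1)) / (n - 1)
      x <- chord + signal::filtfilt(bf, x - chord)
    }
    d <- numeric(n)
    d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * rate / 2
    d[1] <- (x[2] - x[1]) * rate
    d[n] <- (x[n] - x[n - 1]) * rate
    d
  }
  data.frame(time_s = pos$time_s,
             vx = .by_runs(pos$x, diff1),
             vy = .by_runs(pos$y, diff1),
             vz = .by_runs(pos$z, diff1))
}

#' Unit pole direction from tip and grip markers
#'
#' @param markers Marker data (frame or stream) with
#'   `pole_<side>_tip_*` and `pole_<side>_grip_*` columns.
#' @param side `"L"` or `"R"`.
#' @return n x 3 matrix of unit vectors pointing tip-to-grip (the direction
#'   of the axial force on the skier).
#' @export
pole_direction <- function(markers, side = c("L", "R")) {
  side <- match.arg(side)
  if (inherits(markers, "sensor_stream")) markers <- markers$data
  tip <- .marker_xyz(markers, paste0("pole_", side, "_tip"))
  grip <- .marker_xyz(markers, paste0("pole_", side, "_grip"))
  d <- grip - tip
  d / sqrt(rowSums(d^2))
}

#' Instantaneous pole power for one side
#'
#' Force components are the axial magnitude times the unit direction;
#' power is their dot product with the CoM velocity:
#' `P = F_x V_x + F_y V_y + F_z V_z`.
#'
#' @param force Axial force magnitude series, N.
#' @param direction n x 3 matrix of unit pole directions.
#' @param velocity n x 3 matrix (or `vx/vy/vz` data frame) of CoM velocity,
#'   m/s.
#' @return Instantaneous power series, W.
#' @export
pole_power <- function(force, direction, velocity) {
  if (is.data.frame(velocity)) velocity <- as.matrix(velocity[, c("vx", "vy", "vz")])
  direction <- as.matrix(direction)
  if (length(force) != nrow(direction) || length(force) != nrow(velocity)) {
    stopf("force, direction and velocity must be aligned")
  }
  norms <- sqrt(rowSums(direction^2))
  ok <- is.finite(norms)
  if (any(abs(norms[ok] - 1) > 1e-3)) stopf("pole direction is not unit-norm")
  rowSums((force * direction) * velocity)
}

#' Treadmill work rate against gravity and rolling friction
#'
#' `P = m g v (sin(theta) + mu cos(theta))` with `theta = atan(grade)` and
#' `g = 9.81 m/s^2`; air resistance and kinetic-energy fluctuation terms are
#' excluded (constant-speed indoor treadmill).
#'
#' @param mass Body (plus equipment) mass, kg.
#' @param speed Treadmill speed, m/s.
#' @param grade Incline as a grade fraction (rise/run).
#' @param mu Rolling-friction coefficient.
#' @return Work rate, W (vectorised over `speed`/`grade`).
#' @export
cycle_work_rate <- function(mass, speed, grade, mu = 0.016) {
  if (any(mass <= 0)) stopf("mass must be > 0")
  if (any(speed < 0)) stopf("speed must be >= 0")
  if (any(mu < 0)) stopf("mu must be >= 0")
  theta <- atan(grade)
  mass * 9.81 * speed * (sin(theta) + mu * cos(theta))
}

#' Partition cycle power into pole and ski contributions
#'
#' `P_ski = P_cycle - P_pole`; `%P_pole = 100 P_pole / P_cycle`,
#' `%P_ski = 100 - %P_pole`, and the left/right shares are percentages of
#' `P_pole`, so `%P_pole + %P_ski` and `%P_poleleft + %P_poleright` are both
#' exactly 100.
#'
#' @param p_cycle Cycle work rate, W (> 0).
#' @param p_pole Cycle-average total pole power, W.
#' @param p_pole_left,p_pole_right Per-side cycle averages, W.
#' @return Data frame with `p_cycle`, `p_pole`, `p_ski`, `pct_p_pole`,
#'   `pct_p_ski`, `pct_p_poleleft`, `pct_p_poleright` (vectorised).
#' @export
partition_power <- function(p_cycle, p_pole, p_pole_left = NA_real_,
                            p_pole_right = NA_real_) {
  if (any(p_cycle <= 0, na.rm = TRUE)) {
    stopf("P_cycle must be > 0 for the power partition to be defined")
  }
  pct_pole <- 100 * p_pole / p_cycle
  tot_lr <- p_pole_left + p_pole_right
  pct_left <- ifelse(!is.na(tot_lr) & tot_lr != 0, 100 * p_pole_left / tot_lr,
                     NA_real_)
  data.frame(p_cycle = p_cycle, p_pole = p_pole, p_ski = p_cycle - p_pole,
             pct_p_pole = pct_pole, pct_p_ski = 100 - pct_pole,
             pct_p_poleleft = pct_left, pct_p_poleright = 100 - pct_left)
}

#' Per-cycle power for a session's cycle table
#'
#' Runs the full marker/force route: CoM from markers, CoM velocity,
#' per-side instantaneous pole power interpolated onto the 100 Hz force
#' grid, cycle averages, treadmill work rate from the cycle's belt speed and
#' incline, and the pole/ski partition.  Downhill (segment 4) cycles and
#' cycles without marker coverage (even laps when the motion-capture system
#' measures every second lap) carry `NA`.
#'
#' @param session A `ski_session` with `pole`, `markers` streams.
#' @param cycles Cycle table with `start`, `end` (master clock) and
#'   optionally `segment` (recomputed if absent).
#' @param params Segment parameter table.
#' @param cutoff Optional low-pass cutoff for [com_velocity()], Hz.
#' @return `cycles` with the [partition_power()] columns appended.
#' @export
session_power <- function(session, cycles, params = default_segment_params(),
                          cutoff = NULL) {
  protocol <- session$protocol
  tot <- total_duration(protocol)
  mid <- pmin((cycles$start + cycles$end) / 2, tot - 1e-9)
  seg <- segment_at(protocol, mid)
  cycles$lap <- seg$lap
  cycles$segment <- seg$segment
  markers <- session$streams$markers
  if (is.null(markers)) stopf("session has no marker stream")
  com <- com_from_markers(markers, params)
  vel <- com_velocity(com, markers$rate, cutoff)
  pf <- session$streams$pole_L
  tf <- master_time(pf)
  # linear interpolation onto the force grid; samples falling inside marker
  # gaps (e.g. unmeasured laps) must stay missing, not be bridged
  interp <- function(tsrc, y) stats::approx(tsrc, y, tf)$y
  gap <- interp(vel$time_s, as.numeric(is.na(vel$vx)))
  gap <- is.na(gap) | gap > 1e-9
  v100 <- cbind(vx = interp(vel$time_s, vel$vx),
                vy = interp(vel$time_s, vel$vy),
                vz = interp(vel$time_s, vel$vz))
  v100[gap, ] <- NA_real_
  p_inst <- list()
  for (side in c("L", "R")) {
    dirm <- pole_direction(markers, side)
    d100 <- cbind(interp(markers$data$time_s, dirm[, 1]),
                  interp(markers$data$time_s, dirm[, 2]),
                  interp(markers$data$time_s, dirm[, 3]))
    d100[gap, ] <- NA_real_
    nrm <- sqrt(rowSums(d100^2))
    d100 <- d100 / nrm
    force <- session$streams[[paste0("pole_", side)]]$data$force_n
    p <- rep(NA_real_, length(tf))
    ok <- !is.na(nrm) & !is.na(v100[, 1])
    if (any(ok)) {
      p[ok] <- pole_power(force[ok], d100[ok, , drop = FALSE],
                          v100[ok, , drop = FALSE])
    }
    p_inst[[side]] <- p
  }
  nc <- nrow(cycles)
  idx <- findInterval(tf, cycles$start)
  valid <- idx >= 1 & tf < cycles$end[pmax(idx, 1)]
  cycle_mean <- function(p) {
    ok <- valid & !is.na(p)
    out <- rep(NA_real_, nc)
    cover <- rep(0, nc)
    if (any(ok)) {
      s <- rowsum(cbind(p[ok], 1), idx[ok])
      out[as.integer(rownames(s))] <- s[, 1] / s[, 2]
    }
    tot_n <- tabulate(idx[valid], nbins = nc)
    got_n <- tabulate(idx[ok], nbins = nc)
    # a cycle only counts as measured if its force grid is ~fully covered
    out[got_n < 0.9 * tot_n] <- NA_real_
    out
  }
  p_left <- cycle_mean(p_inst$L)
  p_right <- cycle_mean(p_inst$R)
  v_cyc <- segment_speeds(protocol, session$intensity)[cycles$segment] / 3.6
  grade <- protocol$segments$incline[cycles$segment]
  p_cycle <- cycle_work_rate(session$profile$body_mass, v_cyc, grade,
                             session$params$mu %||% 0.016)
  # downhill cycles are excluded from the partition (rope-assisted tuck)
  measurable <- cycles$segment != 4 & !is.na(p_left) & !is.na(p_right)
  res <- data.frame(p_cycle = rep(NA_real_, nc), p_pole = NA_real_,
                    p_ski = NA_real_, pct_p_pole = NA_real_,
                    pct_p_ski = NA_real_, pct_p_poleleft = NA_real_,
                    pct_p_poleright = NA_real_)
  if (any(measurable)) {
    res[measurable, ] <- partition_power(p_cycle[measurable],
                                         (p_left + p_right)[measurable],
                                         p_left[measurable], p_right[measurable])
  }
  cbind(cycles, res)
}
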