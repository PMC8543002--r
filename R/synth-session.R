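# Full synthetic session: every sensor stream the laboratory setup records,
# plus the ground truth needed to test each downstream stage.  One seeded RNG
# drives the whole session; regeneration under the same seed is
# bit-reproducible.
#
# Stream clocks: physiological, pole-force and marker streams are recorded on
# the master clock (t0 = 0).  Inertial units run on their own clocks: each IMU
# stream starts `calib_s` seconds before the session plus an unknown
# per-stream offset, and the three synchronisation jumps (master times -8, -6,
# -4 s) appear as large vertical-acceleration spikes on every IMU.

# contact-phase geometry per gear, as fractions of the cycle duration;
# poling is shorter than ski contact in every gear
.contact_fracs <- function() {
  data.frame(label = c("G2", "G3", "G4"),
             pole_on = c(0.06, 0.06, 0.06),
             pole_ct = c(0.32, 0.30, 0.38),
             ski_on_R = c(0.10, 0.10, 0.10),
             ski_on_L = c(0.60, 0.60, 0.60),
             ski_ct = c(0.55, 0.50, 0.62))
}

# peak pole force (N) per gear at LI; scaled by intensity and per-side
# factors.  Calibrated so the cycle-average pole share of the work rate is
# ~60% in G3 on the moderate ascent, ~65% in G4 on the flat and ~40% in G2
# on the steep ascent (more ski than pole power on steep terrain).
.pole_fmax <- c(G2 = 200, G3 = 150, G4 = 75)

.snap <- function(t, rate) round(t * rate) / rate

.idx_of <- function(t, t1, rate, n) pmin(pmax(round((t - t1) * rate) + 1, 1), n)

.add_bump <- function(x, t1, rate, center, amp, sd) {
  n <- length(x)
  i0 <- max(1L, as.integer(floor((center - 4 * sd - t1) * rate)) + 1L)
  i1 <- min(n, as.integer(ceiling((center + 4 * sd - t1) * rate)) + 1L)
  if (i1 < i0) return(x)
  tt <- t1 + (i0:i1 - 1) / rate
  x[i0:i1] <- x[i0:i1] + amp * exp(-0.5 * ((tt - center) / sd)^2)
  x
}

# per-sample phase (cycle fraction) and frequency under a gear schedule
.schedule_phase <- function(schedule, time) {
  phi <- numeric(length(time))
  f <- numeric(length(time))
  for (w in seq_len(nrow(schedule))) {
    s <- schedule[w, ]
    idx <- which(time >= s$start & time < s$end)
    if (!length(idx)) next
    f[idx] <- s$cr / 60
    phi[idx] <- (time[idx] - s$start) * s$cr / 60
  }
  list(phi = phi, f = f)
}

# ground-truth contact events from the ground-truth cycle table
.contact_truth <- function(cycles, rate = 256) {
  fr <- .contact_fracs()
  keep <- cycles$label %in% fr$label
  cyc <- cycles[keep, , drop = FALSE]
  if (!nrow(cyc)) {
    empty <- data.frame(side = character(0), initial = numeric(0),
                        terminal = numeric(0), label = character(0))
    return(list(pole = empty, ski = empty))
  }
  m <- match(cyc$label, fr$label)
  d <- cyc$end - cyc$start
  pole <- do.call(rbind, lapply(c("L", "R"), function(side) {
    data.frame(side = side,
               initial = .snap(cyc$start + fr$pole_on[m] * d, rate),
               terminal = .snap(cyc$start + (fr$pole_on[m] + fr$pole_ct[m]) * d, rate),
               label = cyc$label)
  }))
  ski <- do.call(rbind, lapply(c("L", "R"), function(side) {
    on <- if (side == "R") fr$ski_on_R[m] else fr$ski_on_L[m]
    data.frame(side = side,
               initial = .snap(cyc$start + on * d, rate),
               terminal = .snap(cyc$start + (on + fr$ski_ct[m]) * d, rate),
               label = cyc$label)
  }))
  rownames(pole) <- rownames(ski) <- NULL
  list(pole = pole, ski = ski)
}

# prepend the calibration window (noise + sync jumps) and wrap as a local-clock
# IMU stream; session_data columns are on the master grid [0, duration)
.imu_stream <- function(placement, session_data, delta, calib_s, sync_master,
                        noise_sd, rate = 256) {
  pre_s <- calib_s + delta
  ncal <- as.integer(round(pre_s * rate))
  n <- nrow(session_data)
  cal <- as.data.frame(lapply(session_data, function(col) {
    stats::rnorm(ncal, mean = stats::median(col[seq_len(min(n, 1000))]), sd = noise_sd)
  }))
  cal_time_master <- ((0:(ncal - 1)) / rate) - pre_s
  for (mj in sync_master) {
    cal$acc_z <- .add_bump(cal$acc_z, cal_time_master[1], rate, mj, 4, 0.03)
  }
  data <- rbind(cal, session_data)
  data <- cbind(time_s = (0:(nrow(data) - 1)) / rate, data)
  sensor_stream(placement, rate, data, t0 = 0)
}

.wrist_session <- function(tm, events, noise, rate = 256) {
  n <- length(tm)
  t1 <- tm[1]
  acc_x <- 0.25 * sin(2 * pi * 0.9 * tm)
  acc_y <- numeric(n)
  acc_z <- rep(1, n)
  gyro_x <- rep(250, n)
  for (e in seq_len(nrow(events))) {
    ti <- events$initial[e]
    tt <- events$terminal[e]
    # initial contact: high-frequency vibration burst, first peak exactly at ti
    i0 <- .idx_of(ti, t1, rate, n)
    i1 <- .idx_of(min(ti + 0.08, tt), t1, rate, n)
    tr <- tm[i0:i1] - ti
    acc_y[i0:i1] <- acc_y[i0:i1] + 2.5 * exp(-tr / 0.02) * cos(2 * pi * 45 * tr)
    # terminal contact: single sharp acceleration peak at the angular-speed minimum
    acc_z <- .add_bump(acc_z, t1, rate, tt, 3, 0.008)
    ip <- .idx_of(ti, t1, rate, n):.idx_of(tt, t1, rate, n)
    gyro_x[ip] <- seq(150, 5, length.out = length(ip))
    ir <- .idx_of(tt, t1, rate, n):.idx_of(tt + 0.1, t1, rate, n)
    gyro_x[ir] <- seq(5, 250, length.out = length(ir))
  }
  data.frame(acc_x = acc_x + stats::rnorm(n, 0, noise$wrist_acc),
             acc_y = acc_y + stats::rnorm(n, 0, noise$wrist_acc),
             acc_z = acc_z + stats::rnorm(n, 0, noise$wrist_acc),
             gyro_x = gyro_x + stats::rnorm(n, 0, noise$wrist_gyro),
             gyro_y = stats::rnorm(n, 0, noise$wrist_gyro),
             gyro_z = stats::rnorm(n, 0, noise$wrist_gyro))
}

.ski_session <- function(tm, events, schedule, noise, rate = 256) {
  n <- length(tm)
  t1 <- tm[1]
  gyro_y <- 150 * sin(2 * pi * 2.5 * tm)   # leg swing pitch oscillation
  acc_z <- rep(1, n)
  # tuck / transition windows: skis stay on the ground, no swing
  for (w in which(schedule$label == "other")) {
    idx <- .idx_of(schedule$start[w], t1, rate, n):.idx_of(schedule$end[w], t1, rate, n)
    gyro_y[idx] <- 0
  }
  for (e in seq_len(nrow(events))) {
    ti <- events$initial[e]
    tt <- events$terminal[e]
    # swing dies out just before the ski lands, then a long low-angular-velocity
    # phase while the ski is on the ground
    ip <- .idx_of(ti - 0.03, t1, rate, n):.idx_of(tt, t1, rate, n)
    gyro_y[ip] <- 0
    # initial contact: last pitch-rate peak before the low phase
    gyro_y <- .add_bump(gyro_y, t1, rate, ti, 250, 0.01)
    # terminal contact: last negative vertical-acceleration peak after the phase
    acc_z <- .add_bump(acc_z, t1, rate, tt, -3, 0.008)
  }
  data.frame(acc_x = stats::rnorm(n, 0, noise$ski_acc),
             acc_y = stats::rnorm(n, 0, noise$ski_acc),
             acc_z = acc_z + stats::rnorm(n, 0, noise$ski_acc),
             gyro_x = stats::rnorm(n, 0, noise$ski_gyro),
             gyro_y = gyro_y + stats::rnorm(n, 0, noise$ski_gyro),
             gyro_z = stats::rnorm(n, 0, noise$ski_gyro))
}

# pole inclination (deg from vertical) over time: 15 deg at plant, raking back
# to 50 deg at release, 15 deg during the return swing
.pole_theta <- function(time, events) {
  th <- rep(15, length(time))
  t1 <- time[1]
  rate <- 1 / (time[2] - time[1])
  n <- length(time)
  for (e in seq_len(nrow(events))) {
    ip <- .idx_of(events$initial[e], t1, rate, n):.idx_of(events$terminal[e], t1, rate, n)
    th[ip] <- seq(15, 50, length.out = length(ip))
  }
  th * pi / 180
}

.pole_dir <- function(theta, side) {
  y0 <- if (side == "L") 0.05 else -0.05
  d <- cbind(sin(theta), y0, cos(theta))
  d / sqrt(rowSums(d^2))
}

# true pole axial force (N) on a time grid; half-sine within each push
.pole_force_true <- function(time, events, intensity, lap_duration,
                             pole_fatigue_rate, side) {
  f <- numeric(length(time))
  t1 <- time[1]
  rate <- 1 / (time[2] - time[1])
  n <- length(time)
  # most of the higher HI pole power comes through the faster CoM, so the
  # peak force itself rises only slightly; this keeps the relative pole/ski
  # distribution nearly intensity-independent, as observed on treadmill data
  iscale <- if (intensity == "HI") 1.03 else 1
  sscale <- if (side == "L") 0.95 else 1.05
  for (e in seq_len(nrow(events))) {
    ti <- events$initial[e]
    tt <- events$terminal[e]
    lap <- floor(ti / lap_duration) + 1
    fmax <- .pole_fmax[[events$label[e]]] * iscale * sscale *
      max(0, 1 - pole_fatigue_rate * (lap - 1))
    ip <- .idx_of(ti, t1, rate, n):.idx_of(tt, t1, rate, n)
    f[ip] <- fmax * sin(pi * (time[ip] - ti) / (tt - ti))
  }
  f
}

# true centre-of-mass velocity (m/s, treadmill-belt frame) on a time grid
.com_velocity_true <- function(protocol, intensity, schedule, time) {
  ph <- .schedule_phase(schedule, time)
  tot <- total_duration(protocol)
  v_belt <- treadmill_speed(protocol, intensity, pmin(time, tot - 1e-9)) / 3.6
  cbind(vx = v_belt + 0.25 * sin(2 * pi * ph$phi),
        vy = 0.08 * cos(2 * pi * ph$phi),
        vz = 0.12 * sin(4 * pi * ph$phi))
}

#' Generate a complete synthetic session recording
#'
#' Produces every sensor stream of the laboratory setup (chest/wrist/ski
#' inertial units at 256 Hz, pole axial forces at 100 Hz, reflective markers
#' at 200 Hz, heart rate at 1 Hz, 10 s mixing-chamber oxygen uptake, and two
#' 10 Hz muscle-oximetry streams) together with the ground truth: cycle
#' boundaries and gear labels, pole/ski contact events, true centre-of-mass
#' velocity, per-cycle pole/ski power, per-stream clock offsets and the
#' synchronisation-jump times.
#'
#' Physiological series follow first-order kinetics toward terrain-dependent
#' setpoints; at HI the heart-rate setpoint additionally drifts upward at
#' `profile$hr_drift_rate` %-points of max per minute.  Markers are recorded
#' on odd laps only (`odd_lap_mask`), as in a motion-capture setup that
#' measures every second lap.
#'
#' @param protocol A `ski_protocol`.
#' @param intensity `"LI"` or `"HI"`.
#' @param profile A [skier_profile()].
#' @param seed Integer seed; the whole session derives from one seeded RNG.
#' @param streams Which stream groups to generate (subset of
#'   `c("chest", "wrist", "ski", "pole", "markers", "physio")`); generating
#'   only what an analysis needs keeps large simulation studies fast.
#' @param calib_s Pre-session calibration window on the IMU clocks, s.
#' @param g3_fraction_hi Passed to [subtech_schedule()].
#' @param jitter Gear-transition jitter (s), passed to [subtech_schedule()].
#' @param pole_fatigue_rate Fractional decline of peak pole force per lap,
#'   emulating the gradual shift of propulsion from poles to skis.
#' @param mu Rolling-friction coefficient used for the true work rate.
#' @param odd_lap_mask If `TRUE`, marker data exist on odd laps only.
#' @return An object of class `ski_session`: `streams` (named list of
#'   [sensor_stream()]s), `truth`, `profile`, `protocol`, `intensity`,
#'   `seed`, `params`.
#' @export
generate_session <- function(protocol, intensity = c("LI", "HI"),
                             profile = skier_profile(), seed = 1L,
                             streams = c("chest", "wrist", "ski", "pole",
                                         "markers", "physio"),
                             calib_s = 10, g3_fraction_hi = 0.4, jitter = 0,
                             pole_fatigue_rate = 0.02, mu = 0.016,
                             odd_lap_mask = TRUE) {
  intensity <- match.arg(intensity)
  streams <- match.arg(streams, several.ok = TRUE)
  with_seed(seed, {
    rate_imu <- 256
    tot <- total_duration(protocol)
    lap_dur <- protocol$lap_duration
    noise <- profile$noise
    sync_master <- c(-8, -6, -4)
    schedule <- subtech_schedule(protocol, intensity, g3_fraction_hi, jitter)
    deltas <- .snap(stats::runif(5, -0.25, 0.25), rate_imu)
    names(deltas) <- c("chest", "wrist_L", "wrist_R", "ski_L", "ski_R")

    chest_raw <- generate_chest_signal(schedule, rate = rate_imu, amp = 0.35,
                                       noise_sd = noise$chest)
    cycles <- chest_raw$cycles
    seg_info <- segment_at(protocol, pmin((cycles$start + cycles$end) / 2, tot - 1e-9))
    cycles$lap <- seg_info$lap
    cycles$segment <- seg_info$segment
    ev <- .contact_truth(cycles, rate_imu)

    out_streams <- list()
    if ("chest" %in% streams) {
      out_streams$chest <- .imu_stream(
        "chest", as.data.frame(chest_raw$acc), deltas[["chest"]], calib_s,
        sync_master, noise$chest, rate_imu)
    }
    tm <- chest_raw$time
    if ("wrist" %in% streams) {
      for (side in c("L", "R")) {
        dat <- .wrist_session(tm, ev$pole[ev$pole$side == side, ], noise, rate_imu)
        out_streams[[paste0("wrist_", side)]] <- .imu_stream(
          paste0("wrist_", side), dat, deltas[[paste0("wrist_", side)]],
          calib_s, sync_master, noise$wrist_acc, rate_imu)
      }
    }
    if ("ski" %in% streams) {
      for (side in c("L", "R")) {
        dat <- .ski_session(tm, ev$ski[ev$ski$side == side, ], schedule, noise,
                            rate_imu)
        out_streams[[paste0("ski_", side)]] <- .imu_stream(
          paste0("ski_", side), dat, deltas[[paste0("ski_", side)]],
          calib_s, sync_master, noise$ski_acc, rate_imu)
      }
    }

    # force, direction and CoM velocity on the 100 Hz force grid (truth)
    tf <- (0:(tot * 100 - 1)) / 100
    v100 <- .com_velocity_true(protocol, intensity, schedule, tf)
    force_true <- dir100 <- list()
    for (side in c("L", "R")) {
      evs <- ev$pole[ev$pole$side == side, ]
      force_true[[side]] <- .pole_force_true(tf, evs, intensity, lap_dur,
                                             pole_fatigue_rate, side)
      dir100[[side]] <- .pole_dir(.pole_theta(tf, evs), side)
      if ("pole" %in% streams) {
        out_streams[[paste0("pole_", side)]] <- sensor_stream(
          paste0("pole_", side), 100,
          data.frame(time_s = tf,
                     force_n = force_true[[side]] +
                       stats::rnorm(length(tf), 0, noise$pole)))
      }
    }

    # per-cycle true power: mean instantaneous pole power over the cycle and
    # the treadmill work rate at the cycle's belt speed and incline
    cyc_idx <- findInterval(tf, cycles$start)
    valid <- cyc_idx >= 1 & tf < cycles$end[pmax(cyc_idx, 1)]
    p_side <- lapply(c("L", "R"), function(side) {
      rowSums(dir100[[side]] * v100) * force_true[[side]]
    })
    mean_by_cycle <- function(p) {
      s <- rowsum(cbind(p[valid], 1), cyc_idx[valid])
      out <- rep(NA_real_, nrow(cycles))
      out[as.integer(rownames(s))] <- s[, 1] / s[, 2]
      out
    }
    p_left <- mean_by_cycle(p_side[[1]])
    p_right <- mean_by_cycle(p_side[[2]])
    mid_seg <- segment_at(protocol, pmin((cycles$start + cycles$end) / 2, tot - 1e-9))
    grade <- protocol$segments$incline[mid_seg$segment]
    v_cyc <- segment_speeds(protocol, intensity)[mid_seg$segment] / 3.6
    p_cycle <- cycle_work_rate(profile$body_mass, v_cyc, grade, mu)
    power_truth <- data.frame(start = cycles$start, end = cycles$end,
                              label = cycles$label, lap = cycles$lap,
                              segment = cycles$segment,
                              p_pole_left = p_left, p_pole_right = p_right,
                              p_pole = p_left + p_right,
                              p_cycle = p_cycle,
                              p_ski = p_cycle - (p_left + p_right))

    if ("markers" %in% streams) {
      t200 <- (0:(tot * 200 - 1)) / 200
      v200 <- .com_velocity_true(protocol, intensity, schedule, t200)
      com <- apply(v200, 2, cumsum) / 200
      params <- default_segment_params()
      mk <- data.frame(time_s = t200)
      for (i in seq_len(nrow(params))) {
        off <- c(params$offset_x[i], params$offset_y[i], params$offset_z[i])
        u <- c(0, 0, 1)
        len <- params$length_m[i]
        prox <- sweep(com, 2, off - params$com_fraction[i] * len * u, "+")
        dist <- sweep(prox, 2, len * u, "+")
        for (j in 1:3) {
          ax <- c("x", "y", "z")[j]
          mk[[paste0(params$prox_marker[i], "_", ax)]] <- prox[, j]
          mk[[paste0(params$dist_marker[i], "_", ax)]] <- dist[, j]
        }
      }
      for (side in c("L", "R")) {
        evs <- ev$pole[ev$pole$side == side, ]
        d200 <- .pole_dir(.pole_theta(t200, evs), side)
        grip <- sweep(com, 2, c(0.3, if (side == "L") 0.35 else -0.35, -0.1), "+")
        tip <- grip - 1.45 * d200
        for (j in 1:3) {
          ax <- c("x", "y", "z")[j]
          mk[[paste0("pole_", side, "_grip_", ax)]] <- grip[, j]
          mk[[paste0("pole_", side, "_tip_", ax)]] <- tip[, j]
        }
      }
      ch <- setdiff(names(mk), "time_s")
      for (nm in ch) mk[[nm]] <- mk[[nm]] + stats::rnorm(nrow(mk), 0, noise$markers)
      if (odd_lap_mask) {
        lap200 <- floor(t200 / lap_dur) + 1
        mk[lap200 %% 2 == 0, ch] <- NA_real_
      }
      out_streams$markers <- sensor_stream("markers", 200, mk)
    }

    # physiological streams: first-order kinetics toward terrain setpoints
    sec <- 0:(tot - 1)
    seg_sec <- segment_at(protocol, sec)$segment
    hr_tab <- if (intensity == "HI") c(82, 88, 92, 78) else c(70, 76, 81, 60)
    vo2_tab <- if (intensity == "HI") c(72, 80, 90, 55) else c(55, 62, 70, 40)
    dip_arm <- c(12, 14, 18, 3) * if (intensity == "HI") 1.6 else 1
    dip_leg <- c(8, 9, 12, 2) * if (intensity == "HI") 1.6 else 1
    hr_set <- hr_tab[seg_sec]
    if (intensity == "HI") {
      hr_set <- pmin(hr_set + profile$hr_drift_rate * sec / 60, 100)
    }
    hr_true <- first_order_response(hr_set, profile$hr_tau, y0 = 45)
    vo2_true <- first_order_response(vo2_tab[seg_sec], profile$vo2_tau, y0 = 20)
    tsi_arm_true <- first_order_response(profile$tsi_baseline_arm - dip_arm[seg_sec],
                                         profile$tsi_tau,
                                         y0 = profile$tsi_baseline_arm)
    tsi_leg_true <- first_order_response(profile$tsi_baseline_leg - dip_leg[seg_sec],
                                         profile$tsi_tau,
                                         y0 = profile$tsi_baseline_leg)
    if ("physio" %in% streams) {
      out_streams$hr <- sensor_stream("hr", 1, data.frame(
        time_s = sec,
        hr_bpm = hr_true / 100 * profile$hr_max + stats::rnorm(tot, 0, noise$hr)))
      vo2_chamber <- colMeans(matrix(vo2_true, nrow = 10)) / 100 * profile$vo2max
      out_streams$vo2 <- sensor_stream("vo2", 0.1, data.frame(
        time_s = seq(0, tot - 10, by = 10),
        vo2_ml_kg_min = vo2_chamber + stats::rnorm(length(vo2_chamber), 0, noise$vo2)))
      t10 <- (0:(tot * 10 - 1)) / 10
      for (nm in c("tsi_arm", "tsi_leg")) {
        tru <- if (nm == "tsi_arm") tsi_arm_true else tsi_leg_true
        out_streams[[nm]] <- sensor_stream(nm, 10, data.frame(
          time_s = t10,
          tsi_pct = rep(tru, each = 10) + stats::rnorm(length(t10), 0, noise$tsi)))
      }
    }

    truth <- list(cycles = cycles,
                  pole_events = ev$pole,
                  ski_events = ev$ski,
                  com_velocity = data.frame(time_s = tf, v100),
                  power = power_truth,
                  offsets = -(calib_s + deltas),
                  sync_master = sync_master,
                  hr_pct = hr_true, vo2_pct = vo2_true,
                  tsi_arm = tsi_arm_true, tsi_leg = tsi_leg_true,
                  schedule = schedule)
    structure(list(streams = out_streams, truth = truth, profile = profile,
                   protocol = protocol, intensity = intensity,
                   seed = as.integer(seed),
                   params = list(calib_s = calib_s,
                                 g3_fraction_hi = g3_fraction_hi,
                                 jitter = jitter,
                                 pole_fatigue_rate = pole_fatigue_rate,
                                 mu = mu, odd_lap_mask = odd_lap_mask)),
              class = "ski_session")
  })
}

#' @export
print.ski_session <- function(x, ...) {
  cat(sprintf("<ski_session %s, seed %d: %d stream(s), %d ground-truth cycles>\n",
              x$intensity, x$seed, length(x$streams), nrow(x$truth$cycles)))
  invisible(x)
}
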