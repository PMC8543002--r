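# The 1 Hz master timeline: every physiological and biomechanical variable
# aligned to the session clock, one row per second, annotated with lap and
# segment.  Cycle-level quantities are broadcast to the seconds their cycle
# spans; seconds without a measurement carry NA, never zero.

.cycle_cols <- c("cl", "cr", "ct_pole", "ct_ski", "pct_ct_pole", "pct_ct_ski",
                 "p_cycle", "pct_p_pole", "pct_p_ski", "pct_p_poleleft",
                 "pct_p_poleright")

#' Build the 1 Hz master timeline
#'
#' @param protocol A `ski_protocol`.
#' @param intensity `"LI"` or `"HI"`.
#' @param pct_hr,pct_vo2 Per-second series in % of the individual maximum
#'   (heart rate, oxygen uptake); must cover the whole session.
#' @param tsi_arm,tsi_leg Per-second tissue saturation index, %.
#' @param cycles Cycle table with `start`, `end`, `label` and any of the
#'   cycle-level columns `cl`, `cr`, `ct_pole`, `ct_ski`, `pct_ct_pole`,
#'   `pct_ct_ski`, `p_cycle`, `pct_p_pole`, `pct_p_ski`, `pct_p_poleleft`,
#'   `pct_p_poleright` (missing ones are filled with `NA`).
#' @return Data frame with one row per session second: `second`, `lap`,
#'   `segment`, `intensity`, `subtech`, the physiological columns and the
#'   broadcast cycle-level columns.
#' @export
build_master_timeline <- function(protocol, intensity, pct_hr, pct_vo2,
                                  tsi_arm, tsi_leg, cycles) {
  tot <- total_duration(protocol)
  for (nm in c("pct_hr", "pct_vo2", "tsi_arm", "tsi_leg")) {
    x <- get(nm)
    if (length(x) < tot) {
      stopf("'%s' covers %d s but the session lasts %d s", nm, length(x), tot)
    }
  }
  sec <- 0:(tot - 1)
  ann <- segment_at(protocol, sec)
  out <- data.frame(second = sec, lap = ann$lap, segment = ann$segment,
                    intensity = intensity,
                    pct_hr = pct_hr[seq_len(tot)],
                    pct_vo2 = pct_vo2[seq_len(tot)],
                    tsi_leg = tsi_leg[seq_len(tot)],
                    tsi_arm = tsi_arm[seq_len(tot)],
                    subtech = NA_character_)
  for (nm in .cycle_cols) out[[nm]] <- NA_real_
  if (!is.null(cycles) && nrow(cycles)) {
    mid <- sec + 0.5
    idx <- findInterval(mid, cycles$start)
    hit <- idx >= 1 & mid < cycles$end[pmax(idx, 1)]
    out$subtech[hit] <- as.character(cycles$label[idx[hit]])
    for (nm in .cycle_cols) {
      if (!is.null(cycles[[nm]])) out[[nm]][hit] <- cycles[[nm]][idx[hit]]
    }
  }
  pct_cols <- c("pct_hr", "pct_vo2", "pct_ct_pole", "pct_ct_ski",
                "pct_p_poleleft", "pct_p_poleright")
  for (nm in pct_cols) {
    bad <- !is.na(out[[nm]]) & (out[[nm]] < 0 | out[[nm]] > 110)
    if (any(bad)) warnf("%d value(s) of %s outside [0, 110]", sum(bad), nm)
  }
  out
}

#' Write / read a master timeline as CSV
#' @param master A master timeline data frame.
#' @param path File path.
#' @export
write_master_timeline <- function(master, path) {
  utils::write.csv(master, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_master_timeline
#' @export
read_master_timeline <- function(path) {
  utils::read.csv(path)
}

#' Run the full analysis pipeline on a session
#'
#' Aligns the inertial streams via their calibration jumps, detects and
#' (optionally) classifies movement cycles, derives cycle kinematics,
#' detects pole and ski contacts, partitions power, reduces the
#' physiological streams to 1 Hz and assembles the master timeline.
#'
#' @param session A `ski_session` (streams may be a subset; stages without
#'   their input streams are skipped and their columns stay `NA`).
#' @param model A trained `subtech_model`, or `NULL` to transfer
#'   ground-truth labels onto detected cycles (synthetic sessions only).
#' @param overrides Optional manual label-override table
#'   (see [apply_label_overrides()]).
#' @param sync_master Master-clock times of the calibration jumps.
#' @param sigma,prominence_k Cycle-detection parameters.
#' @return A list: `master` (the 1 Hz timeline), `cycles` (the per-cycle
#'   table), `pole_events`, `ski_events`.
#' @export
analyze_session <- function(session, model = NULL, overrides = NULL,
                            sync_master = c(-8, -6, -4),
                            sigma = 0.15, prominence_k = 0.3) {
  protocol <- session$protocol
  intensity <- session$intensity
  profile <- session$profile
  tot <- total_duration(protocol)
  st <- session$streams
  aligned <- lapply(st, function(s) {
    if (s$placement %in% c("chest", "wrist_L", "wrist_R", "ski_L", "ski_R")) {
      align_stream(s, sync_master)
    } else s
  })

  cycles <- NULL
  if (!is.null(aligned$chest)) {
    bounds <- detect_cycles(aligned$chest, sigma = sigma,
                            prominence_k = prominence_k)
    bounds <- bounds[bounds >= 0 & bounds < tot]
    cycles <- cycles_from_boundaries(bounds)
    speed <- function(t) treadmill_speed(protocol, intensity,
                                         pmin(pmax(t, 0), tot - 1e-9)) / 3.6
    cycles <- cycle_kinematics(cycles, speed)
    feats <- cycle_features(aligned$chest, cycles)
    if (!is.null(model)) {
      cycles$label <- classify_subtech(model, feats)
    } else {
      truth <- session$truth$cycles
      j <- findInterval((cycles$start + cycles$end) / 2, truth$start)
      ok <- j >= 1 & (cycles$start + cycles$end) / 2 < truth$end[pmax(j, 1)]
      cycles$label <- NA_character_
      cycles$label[ok] <- truth$label[j[ok]]
    }
    cycles <- apply_label_overrides(cycles, overrides)
  }

  pole_events <- ski_events <- data.frame(side = character(0),
                                          initial = numeric(0),
                                          terminal = numeric(0))
  for (side in c("L", "R")) {
    w <- aligned[[paste0("wrist_", side)]]
    if (!is.null(w)) {
      ev <- detect_pole_contacts(w)
      if (nrow(ev)) pole_events <- rbind(pole_events, cbind(side = side, ev))
    }
    s <- aligned[[paste0("ski_", side)]]
    if (!is.null(s)) {
      ev <- detect_ski_contacts(s)
      if (nrow(ev)) ski_events <- rbind(ski_events, cbind(side = side, ev))
    }
  }
  if (!is.null(cycles) && nrow(cycles)) {
    if (nrow(pole_events)) {
      cm <- contact_metrics(pole_events, cycles)
      cycles$ct_pole <- cm$ct
      cycles$pct_ct_pole <- cm$pct_ct
    }
    if (nrow(ski_events)) {
      cm <- contact_metrics(ski_events, cycles)
      cycles$ct_ski <- cm$ct
      cycles$pct_ct_ski <- cm$pct_ct
    }
    if (!is.null(st$markers) && !is.null(st$pole_L)) {
      cycles <- session_power(session, cycles)
    }
  }

  nas <- rep(NA_real_, tot)
  pct_hr <- if (!is.null(st$hr)) {
    pct_of_max(resample_1hz(st$hr, n_seconds = tot), profile$hr_max)
  } else nas
  pct_vo2 <- if (!is.null(st$vo2)) {
    pct_of_max(step_hold_10s(st$vo2$data$vo2_ml_kg_min, tot), profile$vo2max)
  } else nas
  tsi_arm <- if (!is.null(st$tsi_arm)) {
    resample_1hz(st$tsi_arm, window = 2, n_seconds = tot)
  } else nas
  tsi_leg <- if (!is.null(st$tsi_leg)) {
    resample_1hz(st$tsi_leg, window = 2, n_seconds = tot)
  } else nas

  master <- build_master_timeline(protocol, intensity, pct_hr, pct_vo2,
                                  tsi_arm, tsi_leg, cycles)
  list(master = master, cycles = cycles, pole_events = pole_events,
       ski_events = ski_events)
}
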