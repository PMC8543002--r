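# Chest-IMU signal synthesis.  Movement cycles appear as periodic mediolateral
# sway of the upper body; the cycle starts at the "left-position" minimum of
# the mediolateral channel.  Each gear has a distinct waveform:
#   G2 - sway with every-other-cycle amplitude asymmetry (double pole on every
#        other leg push),
#   G3 - near-sinusoidal symmetric sway with a weak 2nd harmonic,
#   G4 - strong 2nd harmonic (two distinct pushes per sway cycle),
#   other - weak slow rocking (tuck/transitions).
# Harmonics use even (cosine) terms only so the cycle-start minimum stays
# exactly at phase 0.

.gear_wave <- function(label, phi, cyc_idx) {
  switch(label,
    G3 = -cos(2 * pi * phi) - 0.05 * cos(4 * pi * phi),
    G4 = -cos(2 * pi * phi) + 0.20 * cos(4 * pi * phi),
    G2 = -ifelse(cyc_idx %% 2 == 0, 1, 0.65) * cos(2 * pi * phi),
    other = -0.25 * cos(2 * pi * phi),
    stopf("unknown sub-technique label '%s'", label))
}

.gear_vert <- function(label, phi) {
  switch(label,
    G3 = 0.30 * cos(4 * pi * phi),
    G4 = 0.35 * cos(2 * pi * phi),
    G2 = 0.30 * cos(2 * pi * phi + 1),
    other = 0.04 * cos(2 * pi * phi),
    0)
}

#' Generate a synthetic chest acceleration signal with ground-truth cycles
#'
#' @param schedule Labelled gear windows (`start`, `end`, `label`, `cr`),
#'   e.g. from [subtech_schedule()]; windows must not overlap.
#' @param rate Sampling rate, Hz.
#' @param amp Mediolateral sway amplitude scale, m/s^2.
#' @param noise_sd White measurement-noise SD, m/s^2.
#' @param seed Optional seed; if `NULL`, the active RNG stream is used.
#' @return A list: `time` (s, uniform grid over the schedule span), `acc`
#'   (n x 3 matrix, columns `acc_x` forward, `acc_y` mediolateral, `acc_z`
#'   vertical incl. 1 g), and `cycles` — the ground-truth cycle table
#'   (`start`, `end`, `label`, `cr`) with boundaries snapped to the sample
#'   grid at the mediolateral minima.
#' @export
generate_chest_signal <- function(schedule, rate = 256, amp = 1.0,
                                  noise_sd = 0.05, seed = NULL) {
  schedule <- .check_schedule(schedule)
  if (!is.null(seed)) {
    return(with_seed(seed, generate_chest_signal(schedule, rate, amp, noise_sd)))
  }
  t0 <- min(schedule$start)
  t1 <- max(schedule$end)
  n <- floor((t1 - t0) * rate + 1e-9)
  time <- t0 + (0:(n - 1)) / rate
  ml <- numeric(n)
  fwd <- numeric(n)
  vert <- numeric(n)
  cyc <- vector("list", nrow(schedule))
  for (w in seq_len(nrow(schedule))) {
    s <- schedule[w, ]
    i0 <- ceiling((s$start - t0) * rate - 1e-9) + 1
    i1 <- min(n, ceiling((s$end - t0) * rate - 1e-9))
    if (i1 < i0) next
    idx <- i0:i1
    f <- s$cr / 60
    phi <- (time[idx] - s$start) * f
    k <- floor(phi)
    ml[idx] <- amp * .gear_wave(s$label, phi, k)
    fwd[idx] <- 0.2 * amp * sin(2 * pi * phi)
    vert[idx] <- amp * .gear_vert(s$label, phi)
    # ground-truth boundaries: integer-phase minima, snapped to the grid
    nb <- floor((s$end - s$start) * f + 1e-9)
    if (nb >= 1) {
      b <- s$start + (0:nb) / f
      b <- b[b <= s$end + 1e-9]
      b <- t0 + round((b - t0) * rate) / rate
      if (length(b) >= 2) {
        cyc[[w]] <- data.frame(start = b[-length(b)], end = b[-1],
                               label = s$label, cr = s$cr)
      }
    }
  }
  acc <- cbind(acc_x = fwd + stats::rnorm(n, 0, noise_sd),
               acc_y = ml + stats::rnorm(n, 0, noise_sd),
               acc_z = 1 + vert + stats::rnorm(n, 0, noise_sd))
  cycles <- do.call(rbind, cyc[!vapply(cyc, is.null, logical(1))])
  rownames(cycles) <- NULL
  list(time = time, acc = acc, cycles = cycles)
}
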