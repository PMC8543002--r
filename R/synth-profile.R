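# Skier profile: anthropometrics, test-day maxima and the kinetic/noise
# parameters that shape the synthetic physiological responses.

#' Skier profile for synthetic sessions
#'
#' Defaults mirror the study population means of elite male skiers
#' (body mass 80.1 kg, HRmax 191.7 beats/min, VO2max 70.6 mL/min/kg).
#' Time constants govern the first-order heart-rate, oxygen-uptake and
#' muscle-oxygenation kinetics of the generator; `hr_drift_rate` is the
#' cardiovascular drift (in %-points of HRmax per minute) applied during
#' high-intensity sessions only.
#'
#' @param body_mass Body mass, kg.
#' @param hr_max Maximal heart rate, beats/min (must lie in 150-220).
#' @param vo2max Maximal oxygen uptake, mL/min/kg.
#' @param hr_tau,vo2_tau,tsi_tau First-order time constants, s.
#' @param hr_drift_rate HI heart-rate drift, %-points of max per minute.
#' @param tsi_baseline_arm,tsi_baseline_leg Resting tissue saturation index, %.
#' @param noise Named list of per-stream noise SDs overriding the defaults:
#'   `chest`, `wrist_acc`, `ski_acc` (g), `wrist_gyro`, `ski_gyro` (deg/s),
#'   `pole` (N), `markers` (m), `hr` (beats/min), `vo2` (mL/kg/min),
#'   `tsi` (%).
#' @return An object of class `skier_profile`.
#' @export
skier_profile <- function(body_mass = 80.1,
                          hr_max = 191.7,
                          vo2max = 70.6,
                          hr_tau = 25,
                          vo2_tau = 30,
                          tsi_tau = 20,
                          hr_drift_rate = 0.35,
                          tsi_baseline_arm = 68,
                          tsi_baseline_leg = 75,
                          noise = list()) {
  if (body_mass <= 0) stopf("body_mass must be > 0")
  if (hr_max < 150 || hr_max > 220) stopf("hr_max must lie in [150, 220]")
  if (vo2max <= 0) stopf("vo2max must be > 0")
  if (hr_tau <= 0 || vo2_tau <= 0 || tsi_tau <= 0) stopf("time constants must be > 0")
  if (tsi_baseline_arm <= 0 || tsi_baseline_arm >= 100 ||
      tsi_baseline_leg <= 0 || tsi_baseline_leg >= 100) {
    stopf("TSI baselines must lie in (0, 100)")
  }
  default_noise <- list(chest = 0.02, wrist_acc = 0.05, wrist_gyro = 2,
                        ski_acc = 0.05, ski_gyro = 3, pole = 1,
                        markers = 3e-4, hr = 0.8, vo2 = 0.8, tsi = 0.5)
  noise <- utils::modifyList(default_noise, noise)
  structure(list(body_mass = body_mass, hr_max = hr_max, vo2max = vo2max,
                 hr_tau = hr_tau, vo2_tau = vo2_tau, tsi_tau = tsi_tau,
                 hr_drift_rate = hr_drift_rate,
                 tsi_baseline_arm = tsi_baseline_arm,
                 tsi_baseline_leg = tsi_baseline_leg,
                 noise = noise),
            class = "skier_profile")
}

#' @export
print.skier_profile <- function(x, ...) {
  cat(sprintf(
    "Skier profile: %.1f kg, HRmax %.1f bpm, VO2max %.1f mL/min/kg\n",
    x$body_mass, x$hr_max, x$vo2max))
  cat(sprintf("  tau HR/VO2/TSI: %g/%g/%g s, HI HR drift %g pp/min\n",
              x$hr_tau, x$vo2_tau, x$tsi_tau, x$hr_drift_rate))
  invisible(x)
}
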