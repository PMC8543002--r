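# First-order response kinetics used to couple the synthetic physiological
# series (heart rate, oxygen uptake, muscle oxygenation) to the terrain.

#' First-order response to a per-second setpoint series
#'
#' Discrete first-order relaxation toward a time-varying target:
#' `y[t+1] = y[t] + (target[t] - y[t]) * (1 - exp(-dt/tau)) + drift * dt / 60`,
#' with the output clamped to `[0, 100]` (values are % of an individual
#' maximum).  A step from 0 toward 100 with `tau = 30` s reaches
#' `100 * (1 - exp(-1)) ~ 63.2` after 30 s, the classical one-tau landmark.
#'
#' @param target Per-second setpoint series, in % of max (values in `[0, 100]`).
#' @param tau Time constant, s (> 0).
#' @param y0 Initial value; defaults to the first setpoint.
#' @param drift Additive drift, %-points per minute (applied per step).
#' @param dt Time step, s.
#' @return Numeric series of `length(target)`: the response sampled at the
#'   same per-second instants, starting at `y0`.
#' @export
first_order_response <- function(target, tau, y0 = target[[1]], drift = 0,
                                 dt = 1) {
  if (!is.numeric(tau) || length(tau) != 1 || tau <= 0) {
    stopf("tau must be a single value > 0")
  }
  if (any(target < 0 | target > 100)) stopf("targets must lie in [0, 100]")
  n <- length(target)
  a <- 1 - exp(-dt / tau)
  y <- numeric(n)
  y[1] <- min(max(y0, 0), 100)
  if (n > 1) {
    for (i in 1:(n - 1)) {
      yi <- y[i] + (target[i] - y[i]) * a + drift * dt / 60
      y[i + 1] <- min(max(yi, 0), 100)
    }
  }
  y
}
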