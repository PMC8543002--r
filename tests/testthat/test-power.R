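test_that("two equal segments average their centres of mass", {
  params <- data.frame(segment = c("a", "b"), mass_fraction = c(0.5, 0.5),
                       com_fraction = c(0.5, 0.5),
                       prox_marker = c("a_p", "b_p"), dist_marker = c("a_d", "b_d"))
  mk <- data.frame(time_s = 0,
                   a_p_x = 0, a_p_y = 0, a_p_z = 0,
                   a_d_x = 0, a_d_y = 0, a_d_z = 0,
                   b_p_x = 2, b_p_y = 0, b_p_z = 0,
                   b_d_x = 2, b_d_y = 0, b_d_z = 0)
  com <- com_from_markers(mk, params)
  expect_equal(unlist(com[1, c("x", "y", "z")]), c(x = 1, y = 0, z = 0))
})

test_that("a single segment's CoM sits at its com_fraction", {
  params <- data.frame(segment = "s", mass_fraction = 1, com_fraction = 0.5,
                       prox_marker = "s_p", dist_marker = "s_d")
  mk <- data.frame(time_s = 0, s_p_x = 0, s_p_y = 0, s_p_z = 0,
                   s_d_x = 0, s_d_y = 0, s_d_z = 2)
  com <- com_from_markers(mk, params)
  expect_equal(unlist(com[1, c("x", "y", "z")]), c(x = 0, y = 0, z = 1))
})

test_that("a random five-segment body matches the brute-force weighted sum", {
  set.seed(10)
  params <- default_segment_params()
  n <- 20
  mk <- data.frame(time_s = seq_len(n) - 1)
  for (nm in c(params$prox_marker, params$dist_marker)) {
    for (ax in c("x", "y", "z")) mk[[paste0(nm, "_", ax)]] <- rnorm(n)
  }
  com <- com_from_markers(mk, params)
  # oracle: explicit weighted sum per sample and axis
  for (ax in c("x", "y", "z")) {
    oracle <- rep(0, n)
    for (i in seq_len(nrow(params))) {
      p <- mk[[paste0(params$prox_marker[i], "_", ax)]]
      d <- mk[[paste0(params$dist_marker[i], "_", ax)]]
      oracle <- oracle + params$mass_fraction[i] *
        (p + params$com_fraction[i] * (d - p))
    }
    expect_equal(com[[ax]], oracle, tolerance = 1e-9)
  }
  bad <- params
  bad$mass_fraction[1] <- 0.6
  expect_error(com_from_markers(mk, bad), "sum")
  expect_error(com_from_markers(mk[, 1:10], params), "missing marker")
})

test_that("numerical differentiation recovers linear and sinusoidal velocities", {
  rate <- 200
  t <- (0:(2 * rate - 1)) / rate
  pos <- data.frame(time_s = t, x = 2 * t, y = rep(1, length(t)),
                    z = sin(2 * pi * 1.5 * t))
  v <- com_velocity(pos, rate)
  inner <- 3:(length(t) - 2)
  expect_equal(v$vx[inner], rep(2, length(inner)), tolerance = 1e-9)
  expect_equal(v$vy[inner], rep(0, length(inner)), tolerance = 1e-9)
  # analytic oracle: d/dt sin(wt) = w cos(wt)
  w <- 2 * pi * 1.5
  expect_equal(v$vz[inner], w * cos(w * t[inner]), tolerance = 0.01 * w)
  expect_error(com_velocity(pos[1:2, ], rate), "3 samples")
})

test_that("pole power is the force-velocity dot product", {
  expect_equal(pole_power(10, matrix(c(1, 0, 0), 1), matrix(c(2, 0, 0), 1)), 20)
  expect_equal(pole_power(10, matrix(c(0, 0, 1), 1), matrix(c(2, 0, 0), 1)), 0)
  set.seed(11)
  n <- 50
  f <- runif(n, 0, 200)
  th <- runif(n, 0, pi / 3)
  dirm <- cbind(sin(th), 0, cos(th))
  vel <- matrix(rnorm(3 * n), ncol = 3)
  p <- pole_power(f, dirm, vel)
  oracle <- f * dirm[, 1] * vel[, 1] + f * dirm[, 2] * vel[, 2] +
    f * dirm[, 3] * vel[, 3]
  expect_equal(p, oracle, tolerance = 1e-9)
  # bilinearity in the force
  expect_equal(pole_power(3 * f, dirm, vel), 3 * p, tolerance = 1e-9)
  expect_error(pole_power(f, dirm * 1.01, vel), "unit-norm")
})

test_that("treadmill work rate matches the closed-form expression", {
  expect_equal(cycle_work_rate(80, 3, 0, mu = 0), 0)
  # oracle: hand evaluation of m g v sin(atan(grade)) (+ mu cos term)
  th <- atan(0.12)
  expect_equal(cycle_work_rate(80, 3, 0.12, mu = 0),
               80 * 9.81 * 3 * sin(th), tolerance = 1e-12)
  expect_equal(cycle_work_rate(80, 3, 0.12, mu = 0), 280.5, tolerance = 0.1)
  expect_equal(cycle_work_rate(80, 3, 0.12, mu = 0.016),
               80 * 9.81 * 3 * (sin(th) + 0.016 * cos(th)), tolerance = 1e-12)
  expect_equal(cycle_work_rate(80, 3, 0.12, mu = 0.016), 318.0, tolerance = 0.1)
  expect_error(cycle_work_rate(80, -1, 0), "speed")
})

test_that("the power partition reproduces worked percentages and conserves", {
  rec <- partition_power(100, 55.7)
  expect_equal(rec$pct_p_pole, 55.7)
  expect_equal(rec$pct_p_ski, 44.3)
  expect_equal(partition_power(100, 0)$pct_p_ski, 100)
  set.seed(12)
  p_cycle <- runif(200, 50, 400)
  p_left <- runif(200, 0, 150)
  p_right <- runif(200, 0, 150)
  rec <- partition_power(p_cycle, p_left + p_right, p_left, p_right)
  expect_equal(rec$pct_p_pole + rec$pct_p_ski, rep(100, 200))
  expect_equal(rec$pct_p_poleleft + rec$pct_p_poleright, rep(100, 200))
  expect_equal(rec$p_ski, p_cycle - p_left - p_right, tolerance = 1e-12)
  expect_error(partition_power(0, 10), "P_cycle")
})

test_that("session power recovers the generator's per-cycle pole power", {
  s <- fixture_power_session()
  pw <- session_power(s, s$truth$cycles[, c("start", "end", "label")])
  tr <- s$truth$power
  ok <- !is.na(pw$p_pole)
  # power exists exactly on the measured (odd) laps outside the downhill
  expect_true(all(pw$lap[ok] %% 2 == 1))
  expect_true(all(pw$segment[ok] != 4))
  expect_gt(sum(ok), 0.9 * sum(tr$lap %% 2 == 1 & tr$segment != 4))
  rel <- abs(pw$p_pole[ok] - tr$p_pole[ok]) / tr$p_pole[ok]
  expect_lt(max(rel), 0.03)
})
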