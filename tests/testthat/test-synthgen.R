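test_that("first-order response matches the analytic one-tau landmark", {
  y <- first_order_response(rep(100, 61), tau = 30, y0 = 0)
  expect_equal(y[31], 100 * (1 - exp(-1)), tolerance = 1e-9)
})

test_that("a constant target is a fixed point of the response", {
  y <- first_order_response(rep(42, 50), tau = 10)
  expect_equal(y, rep(42, 50))
})

test_that("response equals the closed-form recursion elementwise", {
  target <- rep(c(30, 80), each = 60, times = 3)
  tau <- 22
  drift <- 0.5
  y <- first_order_response(target, tau, y0 = 40, drift = drift)
  # oracle: direct evaluation of the exponential recursion
  a <- 1 - exp(-1 / tau)
  yo <- numeric(length(target))
  yo[1] <- 40
  for (i in seq_len(length(target) - 1)) {
    yo[i + 1] <- min(100, max(0, yo[i] + (target[i] - yo[i]) * a + drift / 60))
  }
  expect_equal(y, yo, tolerance = 1e-9)
})

test_that("invalid kinetics parameters are rejected and output stays in range", {
  expect_error(first_order_response(rep(50, 10), tau = 0), "tau")
  expect_error(first_order_response(rep(120, 10), tau = 5), "0, 100")
  y <- first_order_response(rep(100, 2000), tau = 5, y0 = 90, drift = 5)
  expect_true(all(y >= 0 & y <= 100))
})

test_that("chest generator lays down the scheduled number of cycles", {
  sched <- data.frame(start = 0, end = 60, label = "G3", cr = 40)
  g <- generate_chest_signal(sched, seed = 5)
  expect_equal(nrow(g$cycles), 40)
  expect_equal(g$cycles$end - g$cycles$start, rep(60 / 40, 40), tolerance = 0.01)
})

test_that("chest generation is deterministic under a fixed seed", {
  sched <- data.frame(start = 0, end = 30, label = "G4", cr = 35)
  a <- generate_chest_signal(sched, seed = 9)
  b <- generate_chest_signal(sched, seed = 9)
  expect_identical(a, b)
})

test_that("the G3 sway period matches the cycle rate (autocorrelation oracle)", {
  cr <- 48
  sched <- data.frame(start = 0, end = 60, label = "G3", cr = cr)
  g <- generate_chest_signal(sched, seed = 3)
  ml <- g$acc[, "acc_y"] - mean(g$acc[, "acc_y"])
  ac <- stats::acf(ml, lag.max = 2 * 256, plot = FALSE)$acf[-1]
  # first prominent autocorrelation peak = one period
  lag <- which.max(ac[100:512]) + 99
  expect_lte(abs(lag - 60 / cr * 256), 1)
})

test_that("overlapping schedule windows are rejected", {
  sched <- data.frame(start = c(0, 20), end = c(30, 50),
                      label = c("G3", "G4"), cr = c(40, 35))
  expect_error(generate_chest_signal(sched, seed = 1), "overlap")
})

test_that("session generation is bit-reproducible and seed-sensitive", {
  p <- fixture_protocol()
  a <- generate_session(p, "LI", seed = 7, streams = "physio")
  b <- generate_session(p, "LI", seed = 7, streams = "physio")
  expect_identical(a$streams, b$streams)
  expect_identical(a$truth, b$truth)
  # different seeds decorrelate the measurement noise
  c <- generate_session(p, "LI", seed = 8, streams = "physio")
  na <- a$streams$hr$data$hr_bpm - a$truth$hr_pct / 100 * a$profile$hr_max
  nc <- c$streams$hr$data$hr_bpm - c$truth$hr_pct / 100 * c$profile$hr_max
  expect_lt(abs(cor(na, nc)), 0.2)
})

test_that("HI raises the heart-rate response above LI for the same profile", {
  p <- fixture_protocol()
  li <- generate_session(p, "LI", seed = 11, streams = "physio")
  hi <- generate_session(p, "HI", seed = 11, streams = "physio")
  expect_gt(mean(hi$truth$hr_pct), mean(li$truth$hr_pct))
  expect_gt(mean(li$truth$tsi_leg), mean(hi$truth$tsi_leg))
})

test_that("physiological truth stays within physical bounds", {
  p <- fixture_protocol()
  s <- generate_session(p, "HI", seed = 12, streams = "physio")
  for (v in list(s$truth$hr_pct, s$truth$vo2_pct)) {
    expect_true(all(v >= 0 & v <= 100))
  }
  for (v in list(s$truth$tsi_arm, s$truth$tsi_leg)) {
    expect_true(all(v > 0 & v < 100))
  }
})

test_that("truth pole contacts enumerate one push per poling cycle and side", {
  s <- fixture_chest_session()
  n_poling <- sum(s$truth$cycles$label %in% c("G2", "G3", "G4"))
  expect_equal(sum(s$truth$pole_events$side == "L"), n_poling)
  expect_equal(sum(s$truth$pole_events$side == "R"), n_poling)
  expect_true(all(s$truth$pole_events$terminal > s$truth$pole_events$initial))
  # events of one side never overlap
  for (side in c("L", "R")) {
    e <- s$truth$pole_events[s$truth$pole_events$side == side, ]
    e <- e[order(e$initial), ]
    expect_true(all(e$initial[-1] >= e$terminal[-nrow(e)]))
  }
})

test_that("injected contact signatures coincide with truth events", {
  s <- fixture_contact_session()
  w <- s$streams$wrist_L
  t0 <- s$truth$offsets[["wrist_L"]]
  ev <- s$truth$pole_events[s$truth$pole_events$side == "L", ]
  # the vibration burst makes |acc_y| large at the initial-contact sample
  idx <- round((ev$initial[1:50] - t0) * 256) + 1
  expect_true(all(abs(w$data$acc_y[idx]) > 1.5))
  k <- s$streams$ski_R
  t0k <- s$truth$offsets[["ski_R"]]
  evk <- s$truth$ski_events[s$truth$ski_events$side == "R", ]
  idxk <- round((evk$terminal[1:50] - t0k) * 256) + 1
  expect_true(all(k$data$acc_z[idxk] < -1.5))
})
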