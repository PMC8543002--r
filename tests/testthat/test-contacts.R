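# builds a minimal wrist stream containing hand-placed poling signatures
make_wrist <- function(events, dur = 20, rate = 256, noise = 0.03, seed = 1,
                       offset = 0) {
  set.seed(seed)
  t <- (0:(dur * rate - 1)) / rate
  acc_y <- rnorm(length(t), 0, noise)
  acc_z <- 1 + rnorm(length(t), 0, noise)
  gyro_x <- rep(250, length(t))
  for (i in seq_len(nrow(events))) {
    ti <- events$initial[i]
    tt <- events$terminal[i]
    burst <- t >= ti & t <= ti + 0.08
    acc_y[burst] <- acc_y[burst] +
      2.5 * exp(-(t[burst] - ti) / 0.02) * cos(2 * pi * 45 * (t[burst] - ti))
    acc_z <- acc_z + 3 * exp(-0.5 * ((t - tt) / 0.008)^2)
    push <- which(t >= ti & t <= tt)
    gyro_x[push] <- seq(150, 5, length.out = length(push))
    rise <- which(t > tt & t <= tt + 0.1)
    gyro_x[rise] <- seq(5, 250, length.out = length(rise))
  }
  sensor_stream("wrist_L", rate,
                data.frame(time_s = t, acc_x = 0, acc_y = acc_y,
                           acc_z = acc_z + offset,
                           gyro_x = gyro_x, gyro_y = 0, gyro_z = 0))
}

test_that("a hand-placed poling action is detected at its construction times", {
  ev <- data.frame(initial = 10.00, terminal = 10.35)
  out <- detect_pole_contacts(make_wrist(ev))
  expect_equal(nrow(out), 1)
  expect_equal(out$initial, 10.00, tolerance = 0.01)
  expect_equal(out$terminal, 10.35, tolerance = 0.01)
  expect_equal(out$terminal - out$initial, 0.35, tolerance = 0.015)
})

test_that("a quiet wrist signal yields no pole contacts", {
  set.seed(2)
  t <- (0:(10 * 256 - 1)) / 256
  s <- sensor_stream("wrist_L", 256,
                     data.frame(time_s = t, acc_x = rnorm(length(t), 0, 0.03),
                                acc_y = rnorm(length(t), 0, 0.03),
                                acc_z = 1 + rnorm(length(t), 0, 0.03),
                                gyro_x = 250, gyro_y = 0, gyro_z = 0))
  expect_equal(nrow(detect_pole_contacts(s)), 0)
})

test_that("pole detection is invariant to a gravity-like constant offset", {
  ev <- data.frame(initial = c(5, 8), terminal = c(5.4, 8.35))
  a <- detect_pole_contacts(make_wrist(ev, seed = 3))
  b <- detect_pole_contacts(make_wrist(ev, seed = 3, offset = 2.5))
  expect_equal(a, b)
})

test_that("continuous rotation yields no ski contacts", {
  t <- (0:(10 * 256 - 1)) / 256
  s <- sensor_stream("ski_L", 256,
                     data.frame(time_s = t, acc_x = 0, acc_y = 0, acc_z = 1,
                                gyro_x = 0, gyro_y = 200 * sin(2 * pi * 3 * t) + 100,
                                gyro_z = 0))
  expect_equal(nrow(detect_ski_contacts(s)), 0)
})

test_that("session pole contacts hit the stated precision against truth", {
  s <- align_imus(fixture_contact_session())
  for (side in c("L", "R")) {
    det <- detect_pole_contacts(s$streams[[paste0("wrist_", side)]])
    truth <- s$truth$pole_events[s$truth$pole_events$side == side, ]
    m <- match_events(det, truth)
    expect_gte(nrow(m), 0.95 * nrow(truth))
    ct_err <- (m$det_terminal - m$det_initial) - (m$ref_terminal - m$ref_initial)
    expect_lte(mean(abs(ct_err)), 0.018)
  }
})

test_that("session ski contacts hit the stated precision against truth", {
  s <- align_imus(fixture_contact_session())
  for (side in c("L", "R")) {
    det <- detect_ski_contacts(s$streams[[paste0("ski_", side)]])
    truth <- s$truth$ski_events[s$truth$ski_events$side == side, ]
    m <- match_events(det, truth)
    expect_gte(nrow(m), 0.95 * nrow(truth))
    ct_err <- (m$det_terminal - m$det_initial) - (m$ref_terminal - m$ref_initial)
    expect_lte(mean(abs(ct_err)), 0.007)
  }
})

test_that("exactly one ski contact per cycle and side on G3 segments", {
  s <- align_imus(fixture_contact_session())
  det <- detect_ski_contacts(s$streams$ski_R)
  cyc <- s$truth$cycles
  g3 <- cyc[cyc$label == "G3" & cyc$start > 2, ]
  hits <- vapply(seq_len(nrow(g3)), function(i) {
    sum(det$initial >= g3$start[i] & det$initial < g3$end[i])
  }, numeric(1))
  expect_gte(mean(hits == 1), 0.98)
})

test_that("detected pole contact times are ordered and non-overlapping", {
  s <- align_imus(fixture_contact_session())
  det <- detect_pole_contacts(s$streams$wrist_R)
  expect_true(all(det$terminal > det$initial))
  expect_true(all(det$initial[-1] >= det$terminal[-nrow(det)]))
})

test_that("poling time is shorter than ski contact time in every gear", {
  s <- align_imus(fixture_contact_session())
  cyc <- s$truth$cycles
  pole <- contact_metrics(detect_pole_contacts(s$streams$wrist_L) |>
                            (\(d) cbind(side = "L", d))(), cyc)
  ski <- contact_metrics(detect_ski_contacts(s$streams$ski_L) |>
                           (\(d) cbind(side = "L", d))(), cyc)
  for (lab in c("G2", "G3", "G4")) {
    i <- cyc$label == lab
    expect_lt(mean(pole$ct[i], na.rm = TRUE), mean(ski$ct[i], na.rm = TRUE))
  }
})

test_that("contact metrics assign events to cycles and average sides", {
  cyc <- data.frame(start = c(0, 1), end = c(1, 2))
  ev <- data.frame(side = c("L", "R"), initial = c(0.1, 0.15),
                   terminal = c(0.4, 0.5))
  cm <- contact_metrics(ev, cyc)
  expect_equal(cm$ct[1], mean(c(0.3, 0.35)))
  expect_equal(cm$pct_ct[1], 100 * mean(c(0.3, 0.35)))
  expect_true(is.na(cm$ct[2]))
  ev_l <- ev[1, ]
  expect_equal(contact_metrics(ev_l, cyc)$ct[1], 0.3)
  expect_equal(contact_metrics(ev_l, cyc)$pct_ct[1], 30)
  span <- data.frame(side = "L", initial = 0.5, terminal = 2.5)
  expect_error(contact_metrics(span, cyc), "spans")
})
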