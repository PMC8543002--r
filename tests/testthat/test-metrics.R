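test_that("terrain-dependent fluctuation handles degenerate and forced cases", {
  p <- fixture_protocol()
  expect_equal(tdf(rep(70, 1260), p), 0)
  s <- rep(70, 1260)
  for (l in 1:7) s[(l - 1) * 180 + 1:2] <- c(90, 70)
  expect_equal(tdf(s, p), 20)
  expect_error(tdf(rep(70, 1000), p), "cover")
  s[1081:1260] <- NA
  expect_error(tdf(s, p), "lap 7")
})

test_that("time-dependent change is the difference of lap means", {
  p <- fixture_protocol()
  s <- rep(72, 1260)
  s[1081:1260] <- 79.8
  expect_equal(tdc(s, p, c(2, 7)), 7.8)
  expect_equal(tdc(rep(55, 1260), p, c(2, 7)), 0)
  expect_equal(tdc(rep(55, 1260), p, c(1, 7)), 0)
})

test_that("fluctuation statistics equal their brute-force oracles", {
  p <- fixture_protocol()
  set.seed(13)
  for (i in 1:25) {
    s <- cumsum(rnorm(1260, 0, 0.5)) + 70
    expect_equal(tdf(s, p), brute_tdf(s), tolerance = 1e-12)
    expect_equal(tdc(s, p, c(2, 7)), brute_tdc(s, c(2, 7)), tolerance = 1e-12)
    expect_equal(tdc(s, p, c(1, 7)), brute_tdc(s, c(1, 7)), tolerance = 1e-12)
  }
})

test_that("tdf is invariant to permuting seconds within laps and to rescaling", {
  p <- fixture_protocol()
  set.seed(14)
  s <- runif(1260, 50, 90)
  sp <- s
  for (l in 1:7) {
    idx <- (l - 1) * 180 + 1:180
    sp[idx] <- sample(sp[idx])
  }
  expect_equal(tdf(sp, p), tdf(s, p), tolerance = 1e-12)
  expect_equal(tdc(sp, p, c(2, 7)), tdc(s, p, c(2, 7)), tolerance = 1e-12)
  # % of max normalisation is scale invariant
  expect_equal(tdf(pct_of_max(3 * s), p), tdf(pct_of_max(s), p),
               tolerance = 1e-12)
})

test_that("generator heart-rate drift is recovered by the time-dependent change", {
  p <- fixture_protocol()
  drift <- 0.35
  target <- 15 * drift
  vals <- vapply(1:6, function(sd) {
    s <- generate_session(p, "HI", seed = 400 + sd, streams = "physio")
    hr <- pct_of_max(resample_1hz(s$streams$hr, n_seconds = 1260),
                     s$profile$hr_max)
    tdc(hr, p, c(2, 7))
  }, numeric(1))
  expect_true(all(abs(vals - target) / target < 0.15))
})

test_that("short sub-technique exposures are excluded from grouped means", {
  p <- fixture_protocol()
  cyc <- data.frame(start = c(0, 5, 100), end = c(5, 11, 110),
                    label = c("G2", "G3", "G4"))
  m <- build_master_timeline(p, "LI", rep(70, 1260), rep(55, 1260),
                             rep(60, 1260), rep(65, 1260), cyc)
  agg <- aggregate_by(m, c("segment", "subtech"), variables = "pct_hr")
  expect_false("G2" %in% agg$subtech)   # 5 s only
  expect_true("G3" %in% agg$subtech)    # exactly 6 s
  expect_true(all(agg$mean[agg$variable == "pct_hr"] == 70))
  expect_error(aggregate_by(m, character(0)), "grouping key")
  expect_error(aggregate_by(m, "nope"), "unknown")
})

test_that("grouped means ignore missing values instead of zero-filling", {
  p <- fixture_protocol()
  cyc <- data.frame(start = 0, end = 20, label = "G3",
                    pct_p_pole = 60)
  m <- build_master_timeline(p, "LI", rep(70, 1260), rep(55, 1260),
                             rep(60, 1260), rep(65, 1260), cyc)
  agg <- aggregate_by(m, "segment", variables = "pct_p_pole")
  seg1 <- agg[agg$segment == 1 & agg$variable == "pct_p_pole", ]
  expect_equal(seg1$mean, 60)   # the NA seconds do not dilute the mean
})

test_that("sub-technique time distribution sums to 100 over covered time", {
  cyc <- data.frame(start = c(0, 30), end = c(30, 60),
                    label = c("G2", "G3"))
  win <- data.frame(id = 1, start = 0, end = 60)
  d <- subtech_distribution(cyc, win)
  expect_equal(d$pct_time[d$label == "G2"], 50)
  expect_equal(d$pct_time[d$label == "G3"], 50)
  all_g3 <- subtech_distribution(data.frame(start = 0, end = 60, label = "G3"),
                                 win)
  expect_equal(all_g3$pct_time[all_g3$label == "G3"], 100)
  set.seed(15)
  rc <- data.frame(start = seq(0, 99), end = seq(1, 100),
                   label = sample(c("G2", "G3", "G4", "other"), 100, TRUE))
  rw <- data.frame(id = 1:4, start = c(0, 25, 50, 75), end = c(25, 50, 75, 100))
  rd <- subtech_distribution(rc, rw)
  sums <- as.numeric(tapply(rd$pct_time, rd$id, sum))
  expect_equal(sums, rep(100, 4), tolerance = 1e-9)
})

test_that("session deltas reproduce printed-style difference arithmetic", {
  li <- data.frame(variable = c("vo2", "rpe"), mean = c(41.1, 12.7),
                   sd = c(0.8, 1.2), scale = "ratio")
  hi <- data.frame(variable = c("vo2", "rpe"), mean = c(55.9, 17.2),
                   sd = c(1.7, 1.5), scale = "ratio")
  d <- session_summary_delta(li, hi)
  expect_equal(d$delta, c(14.8, 4.5))
  expect_equal(d$pct_change, c(36, 35))
  same <- session_summary_delta(li, li)
  expect_equal(same$delta, c(0, 0))
  expect_equal(same$pct_change, c(0, 0))
  bad <- hi
  bad$variable[1] <- "other_var"
  expect_error(session_summary_delta(li, bad), "same variables")
})
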