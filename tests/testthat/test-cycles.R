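test_that("a pure sinusoid yields one boundary per period at the minima", {
  rate <- 256
  t <- (0:(60 * rate - 1)) / rate
  f <- 40 / 60
  phase <- 0.75
  x <- -cos(2 * pi * f * (t - phase))
  b <- detect_cycles(x, rate)
  expect_equal(length(b), 40)
  # boundaries sit at the minima of the sway
  period_err <- abs((b - phase) - round((b - phase) * f) / f)
  expect_lt(max(period_err), 0.02)
})

test_that("constant or empty signals yield no cycles", {
  expect_equal(length(detect_cycles(rep(1, 2560), 256)), 0)
  expect_error(detect_cycles(numeric(0), 256), "empty")
})

test_that("boundaries are invariant to a constant mediolateral offset", {
  rate <- 256
  t <- (0:(30 * rate - 1)) / rate
  set.seed(4)
  x <- -cos(2 * pi * 0.7 * t) + rnorm(length(t), 0, 0.05)
  expect_equal(detect_cycles(x, rate), detect_cycles(x + 5, rate))
})

test_that("session cycle detection recovers the ground-truth boundaries", {
  s <- fixture_chest_session()
  ch <- align_stream(s$streams$chest, s$truth$sync_master)
  b <- detect_cycles(ch)
  b <- b[b >= 0 & b < total_duration(s$protocol)]
  truth_b <- unique(c(s$truth$cycles$start, s$truth$cycles$end))
  m <- match_boundaries(b, truth_b, tol = 0.1)
  expect_gte(m$recall, 0.95)
  expect_gte(m$f1, 0.95)
})

test_that("per-segment cycle rates are recovered within 2% of the schedule", {
  s <- fixture_chest_session()
  ch <- align_stream(s$streams$chest, s$truth$sync_master)
  b <- detect_cycles(ch)
  cyc <- cycle_kinematics(cycles_from_boundaries(b), 1)
  sched <- s$truth$schedule
  for (w in seq_len(nrow(sched))) {
    inside <- cyc$start >= sched$start[w] + 2 & cyc$end <= sched$end[w] - 2
    if (sum(inside) < 3) next
    # mean over the window: alternating-amplitude gears (G2) alternate the
    # detected minima slightly early/late, which the mean cancels
    expect_lt(abs(mean(cyc$cr[inside]) - sched$cr[w]) / sched$cr[w], 0.02)
  }
})

test_that("feature extraction is deterministic and scales as variances", {
  set.seed(5)
  win <- data.frame(acc_x = rnorm(300), acc_y = rnorm(300), acc_z = rnorm(300))
  f1 <- extract_features(win)
  f2 <- extract_features(win)
  expect_identical(f1, f2)
  expect_length(f1, 12)
  fc <- extract_features(data.frame(acc_x = rep(1, 100), acc_y = rep(2, 100),
                                    acc_z = rep(3, 100)))
  expect_equal(unname(fc[c("var_x", "var_y", "var_z")]), c(0, 0, 0))
  # doubling the amplitude quadruples the variance features (oracle: direct
  # recomputation of var(2x) = 4 var(x))
  fd <- extract_features(win * 2)
  expect_equal(unname(fd[c("var_x", "var_y", "var_z")]),
               4 * unname(f1[c("var_x", "var_y", "var_z")]), tolerance = 1e-9)
  expect_error(extract_features(win[1:3, ]), "4 samples")
})

test_that("cycle kinematics satisfy the speed identity", {
  cyc <- data.frame(start = c(0, 1, 2), end = c(1, 2, 3))
  k <- cycle_kinematics(cyc, 5)
  expect_equal(k$cr, rep(60, 3))
  expect_equal(k$cl, rep(5, 3))
  set.seed(6)
  cyc <- data.frame(start = cumsum(c(0, runif(20, 0.8, 2))))
  cyc$end <- c(cyc$start[-1], max(cyc$start) + 1.3)
  v <- runif(1, 2, 6)
  k <- cycle_kinematics(cyc, v)
  expect_equal(k$cl * k$cr / 60, rep(v, nrow(k)), tolerance = 1e-9)
  expect_error(cycle_kinematics(data.frame(start = 0, end = 0), 5), "duration")
})

test_that("a separable training set is memorised and misuse is rejected", {
  set.seed(7)
  n <- 40
  feats <- do.call(rbind, lapply(0:3, function(k) {
    matrix(rnorm(n * 12, mean = 3 * k, sd = 0.2), ncol = 12)
  }))
  colnames(feats) <- sprintf("f%02d", 1:12)
  labels <- rep(c("G2", "G3", "G4", "other"), each = n)
  m <- train_subtech_model(feats, labels)
  expect_equal(mean(classify_subtech(m, feats) == labels), 1)
  expect_error(train_subtech_model(feats, rep("G2", nrow(feats))), "2 classes")
  few <- c(1:5, n + 1:5)
  expect_error(train_subtech_model(feats[few, ], labels[few]), ">= 10")
  expect_error(classify_subtech(m, feats[, 1:5]), "dimension mismatch")
})

test_that("randomly permuted labels reduce held-out accuracy to chance", {
  set.seed(8)
  n <- 100
  feats <- do.call(rbind, lapply(0:3, function(k) {
    matrix(rnorm(n * 12, mean = 3 * k, sd = 0.2), ncol = 12)
  }))
  colnames(feats) <- sprintf("f%02d", 1:12)
  labels <- sample(rep(c("G2", "G3", "G4", "other"), each = n))
  idx <- sample(nrow(feats), 0.8 * nrow(feats))
  m <- train_subtech_model(feats[idx, ], labels[idx])
  acc <- mean(classify_subtech(m, feats[-idx, ]) == labels[-idx])
  # oracle: a permutation null with 4 balanced classes concentrates at 25%
  expect_gt(acc, 0.15)
  expect_lt(acc, 0.35)
})

test_that("model serialisation round-trips and rejects foreign files", {
  set.seed(9)
  feats <- matrix(rnorm(480), ncol = 12,
                  dimnames = list(NULL, sprintf("f%02d", 1:12)))
  labels <- rep(c("G3", "G4"), each = 20)
  m <- train_subtech_model(feats, labels)
  path <- withr::local_tempfile(fileext = ".rds")
  save_subtech_model(m, path)
  m2 <- load_subtech_model(path)
  expect_identical(classify_subtech(m2, feats), classify_subtech(m, feats))
  saveRDS(list(a = 1), path)
  expect_error(load_subtech_model(path), "version-1")
})

test_that("manual label overrides appear verbatim downstream", {
  cyc <- data.frame(start = c(0, 1.3, 2.6), end = c(1.3, 2.6, 3.9),
                    label = c("G3", "G3", "G3"))
  ov <- data.frame(start = 1.3, label = "other")
  out <- apply_label_overrides(cyc, ov)
  expect_equal(out$label, c("G3", "other", "G3"))
  p <- fixture_protocol()
  m <- build_master_timeline(p, "LI", rep(70, 1260), rep(55, 1260),
                             rep(60, 1260), rep(65, 1260), out)
  expect_equal(m$subtech[2], "other")
})
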