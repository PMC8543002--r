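# Independent brute-force references shared across test files.

# per-lap scan versions of the fluctuation statistics
brute_tdf <- function(series, laps = 2:7, lap_dur = 180) {
  mean(vapply(laps, function(l) {
    v <- series[((l - 1) * lap_dur + 1):(l * lap_dur)]
    max(v, na.rm = TRUE) - min(v, na.rm = TRUE)
  }, numeric(1)))
}

brute_tdc <- function(series, lap_ref, lap_dur = 180) {
  m <- vapply(lap_ref, function(l) {
    mean(series[((l - 1) * lap_dur + 1):(l * lap_dur)], na.rm = TRUE)
  }, numeric(1))
  m[2] - m[1]
}

# explicit sums-of-squares decomposition for the balanced two-way
# repeated-measures design (oracle for rm_anova2)
ss_oracle <- function(d) {
  gm <- mean(d$y)
  ma <- tapply(d$y, d$A, mean)
  mb <- tapply(d$y, d$B, mean)
  ms <- tapply(d$y, d$subject, mean)
  mab <- tapply(d$y, list(d$A, d$B), mean)
  msa <- tapply(d$y, list(d$subject, d$A), mean)
  msb <- tapply(d$y, list(d$subject, d$B), mean)
  n <- nlevels(d$subject); a <- nlevels(d$A); b <- nlevels(d$B)
  ss_a <- n * b * sum((ma - gm)^2)
  ss_b <- n * a * sum((mb - gm)^2)
  ss_ab <- n * sum((mab - outer(ma, rep(1, b)) - outer(rep(1, a), mb) + gm)^2)
  ss_sa <- b * sum((msa - outer(ms, rep(1, a)) - outer(rep(1, n), ma) + gm)^2)
  ss_sb <- a * sum((msb - outer(ms, rep(1, b)) - outer(rep(1, n), mb) + gm)^2)
  ss_tot <- sum((d$y - gm)^2)
  ss_s <- a * b * sum((ms - gm)^2)
  ss_sab <- ss_tot - ss_a - ss_b - ss_ab - ss_s - ss_sa - ss_sb
  f_a <- (ss_a / (a - 1)) / (ss_sa / ((n - 1) * (a - 1)))
  f_b <- (ss_b / (b - 1)) / (ss_sb / ((n - 1) * (b - 1)))
  f_ab <- (ss_ab / ((a - 1) * (b - 1))) / (ss_sab / ((n - 1) * (a - 1) * (b - 1)))
  list(ss = c(ss_a, ss_b, ss_ab), F = c(f_a, f_b, f_ab))
}

# balanced long-format repeated-measures dataset
rm_data <- function(n = 6, a = 4, b = 3, fun = function(s, i, j) rnorm(1)) {
  d <- expand.grid(subject = factor(seq_len(n)), lap = factor(seq_len(a)),
                   segment = factor(seq_len(b)))
  d$value <- mapply(fun, as.integer(d$subject), as.integer(d$lap),
                    as.integer(d$segment))
  d
}
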