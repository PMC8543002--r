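# Internal helpers shared across modules.

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Half-up rounding: the convention used when quantities are "reported to one
# decimal" (avoids round-to-even at exact .x5 values).
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Indices of strict local maxima (first sample of a tie counts).
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  i <- 2:(n - 1)
  i[x[i] > x[i - 1] & x[i] >= x[i + 1]]
}

local_minima <- function(x) local_maxima(-x)

# Topographic prominence of the given local maxima of x.  Works on the reduced
# peak/valley sequence so the cost is ~O(number of peaks) for periodic signals.
peak_prominence <- function(x, peaks) {
  m <- length(peaks)
  if (m == 0) return(numeric(0))
  # valley minima between consecutive peaks, plus the two end segments
  valleys <- numeric(m + 1)
  valleys[1] <- min(x[1:peaks[1]])
  if (m > 1) {
    for (i in 1:(m - 1)) valleys[i + 1] <- min(x[peaks[i]:peaks[i + 1]])
  }
  valleys[m + 1] <- min(x[peaks[m]:length(x)])
  h <- x[peaks]
  prom <- numeric(m)
  for (i in seq_len(m)) {
    # walk left until a higher peak (or the signal edge), tracking the lowest
    # intervening valley; same to the right
    col_l <- valleys[i]
    j <- i - 1
    while (j >= 1 && h[j] <= h[i]) {
      col_l <- min(col_l, valleys[j])
      j <- j - 1
    }
    if (j < 1) col_l <- min(col_l, valleys[1])
    col_r <- valleys[i + 1]
    j <- i + 1
    while (j <= m && h[j] <= h[i]) {
      col_r <- min(col_r, valleys[j + 1])
      j <- j + 1
    }
    if (j > m) col_r <- min(col_r, valleys[m + 1])
    prom[i] <- h[i] - max(col_l, col_r)
  }
  prom
}

# Gaussian smoothing with edge replication; sigma in samples.
gaussian_smooth <- function(x, sigma_samples) {
  if (sigma_samples <= 0) stopf("sigma must be > 0")
  half <- max(1L, as.integer(ceiling(4 * sigma_samples)))
  k <- stats::dnorm(seq(-half, half), sd = sigma_samples)
  k <- k / sum(k)
  n <- length(x)
  xp <- c(rep(x[1], half), x, rep(x[n], half))
  out <- stats::filter(xp, k, sides = 2)
  as.numeric(out[(half + 1):(half + n)])
}

# Centred moving standard deviation over w samples (w odd recommended).
moving_sd <- function(x, w) {
  k <- rep(1 / w, w)
  m1 <- as.numeric(stats::filter(x, k, sides = 2))
  m2 <- as.numeric(stats::filter(x * x, k, sides = 2))
  v <- pmax(m2 - m1^2, 0)
  v[is.na(v)] <- 0
  sqrt(v)
}

# Run RNG-dependent code under a seed without clobbering the caller's stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
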