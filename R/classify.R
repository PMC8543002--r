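# Per-cycle feature extraction and sub-technique classification.  The
# classifier family (margin-based, radial kernel, one-vs-one multiclass with
# feature standardisation) is standard for IMU-based gear recognition; the
# 12-dimensional feature set below is this package's own design and is
# configurable in the sense that any fixed-length per-cycle descriptor can be
# supplied to the same training interface.

.feature_names <- c("mean_x", "mean_y", "mean_z", "var_x", "var_y", "var_z",
                    "domfreq_ratio", "harm2_ratio", "half_asym",
                    "neighbor_asym", "duration", "ml_range")

#' Extract the per-cycle feature vector
#'
#' Features: per-axis mean and variance of the three chest channels, the
#' dominant-frequency power ratio and 2nd-harmonic ratio of the mediolateral
#' channel, the RMS asymmetry of the two half-cycles, the amplitude asymmetry
#' against the following cycle (how G2's every-other-cycle pattern shows up),
#' the cycle duration and the mediolateral range.
#'
#' @param window Matrix or data frame with columns `acc_x`, `acc_y`, `acc_z`
#'   covering one cycle.
#' @param rate Sampling rate, Hz.
#' @param next_ml_sd Mediolateral SD of the following cycle (for the
#'   between-cycle asymmetry feature); `NA` gives a neutral 0.
#' @return Named numeric vector of length 12.
#' @export
extract_features <- function(window, rate = 256, next_ml_sd = NA_real_) {
  window <- as.data.frame(window)
  n <- nrow(window)
  if (n < 4) stopf("cycle window must contain at least 4 samples")
  x <- window$acc_x; y <- window$acc_y; z <- window$acc_z
  if (anyNA(c(x, y, z))) stopf("cycle window contains missing samples")
  yc <- y - mean(y)
  spec <- Mod(stats::fft(yc))^2
  half <- spec[2:max(2, floor(n / 2))]
  dom <- which.max(half)
  dom_ratio <- if (sum(half) > 0) half[dom] / sum(half) else 0
  h2_bins <- setdiff(unique(pmin(length(half), pmax(1, 2 * dom + (-1:1)))), dom)
  harm2 <- if (half[dom] > 0 && length(h2_bins)) max(half[h2_bins]) / half[dom] else 0
  h1 <- yc[1:floor(n / 2)]
  h2 <- yc[(floor(n / 2) + 1):n]
  rms <- function(v) sqrt(mean(v^2))
  half_asym <- if (rms(h1) + rms(h2) > 0) {
    abs(rms(h1) - rms(h2)) / (rms(h1) + rms(h2))
  } else 0
  ml_sd <- stats::sd(y)
  neigh <- if (is.na(next_ml_sd) || ml_sd == 0 || next_ml_sd == 0) 0 else
    abs(log(ml_sd / next_ml_sd))
  out <- c(mean(x), mean(y), mean(z),
           stats::var(x), stats::var(y), stats::var(z),
           dom_ratio, harm2, half_asym, neigh, n / rate, diff(range(y)))
  names(out) <- .feature_names
  out
}

#' Per-cycle features for a whole session
#'
#' @param chest A chest `sensor_stream` (channels `acc_x/y/z`).
#' @param cycles Cycle table with `start`, `end` on the stream's master clock.
#' @return Data frame of features, one row per cycle.
#' @export
cycle_features <- function(chest, cycles) {
  tmaster <- master_time(chest)
  rate <- chest$rate
  t1 <- tmaster[1]
  n <- nrow(chest$data)
  idx_of <- function(t) pmin(pmax(as.integer(round((t - t1) * rate)) + 1L, 1L), n)
  ml_sd <- vapply(seq_len(nrow(cycles)), function(i) {
    stats::sd(chest$data$acc_y[idx_of(cycles$start[i]):(idx_of(cycles$end[i]) - 1L)])
  }, numeric(1))
  feats <- lapply(seq_len(nrow(cycles)), function(i) {
    win <- chest$data[idx_of(cycles$start[i]):(idx_of(cycles$end[i]) - 1L),
                      c("acc_x", "acc_y", "acc_z")]
    nxt <- if (i < nrow(cycles) &&
               abs(cycles$start[i + 1] - cycles$end[i]) < 0.5) ml_sd[i + 1] else NA_real_
    extract_features(win, rate, nxt)
  })
  as.data.frame(do.call(rbind, feats))
}

#' Train the sub-technique classifier
#'
#' Support vector machine with a radial kernel, one-vs-one multiclass and
#' feature standardisation from the training data.
#'
#' @param features Data frame or matrix of per-cycle features.
#' @param labels Sub-technique labels (one per row of `features`).
#' @param cost,gamma SVM hyperparameters (`gamma` defaults to
#'   1/n_features).
#' @param seed Seed for the (deterministic up to ties) fit.
#' @return An object of class `subtech_model`.
#' @importFrom e1071 svm
#' @export
train_subtech_model <- function(features, labels, cost = 10, gamma = NULL,
                                seed = 1L) {
  features <- as.matrix(features)
  if (!all(is.finite(features))) stopf("features must be finite")
  labels <- factor(labels)
  if (nlevels(labels) < 2) stopf("training needs at least 2 classes")
  counts <- table(labels)
  if (any(counts < 10)) {
    stopf("every class needs >= 10 training examples (worst: %s with %d)",
          names(counts)[which.min(counts)], min(counts))
  }
  gamma <- gamma %||% (1 / ncol(features))
  fit <- with_seed(seed, e1071::svm(x = features, y = labels,
                                    kernel = "radial", cost = cost,
                                    gamma = gamma, scale = TRUE))
  structure(list(fit = fit, feature_names = colnames(features),
                 levels = levels(labels), version = 1L),
            class = "subtech_model")
}

#' Classify cycles with a trained model
#'
#' @param model A `subtech_model`.
#' @param features Feature rows as used in training (same columns, same
#'   order).
#' @return Character vector of predicted labels.
#' @export
classify_subtech <- function(model, features) {
  features <- as.matrix(features)
  if (ncol(features) != length(model$feature_names)) {
    stopf("feature dimension mismatch: model expects %d, got %d",
          length(model$feature_names), ncol(features))
  }
  as.character(stats::predict(model$fit, features))
}

#' Save / load a sub-technique model
#'
#' Models are serialised with a format version so stale files are rejected.
#'
#' @param model A `subtech_model`.
#' @param path File path.
#' @export
save_subtech_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_subtech_model
#' @export
load_subtech_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "subtech_model") || !identical(model$version, 1L)) {
    stopf("'%s' is not a version-1 subtech model file", path)
  }
  model
}

#' Detected-cycle training data with ground-truth labels
#'
#' Aligns a synthetic session's chest stream, detects cycles, extracts
#' per-cycle features and transfers the ground-truth gear labels onto the
#' detected cycles (a detected cycle inherits the label of the truth cycle
#' covering the majority of it; unmatched cycles are dropped).  This is the
#' corpus builder for training and benchmarking the classifier.
#'
#' @param session A `ski_session` with a chest stream.
#' @param sigma,prominence_k Cycle-detection parameters.
#' @return Data frame: the 12 feature columns plus `label`.
#' @export
session_training_data <- function(session, sigma = 0.15, prominence_k = 0.3) {
  chest <- align_stream(session$streams$chest, session$truth$sync_master)
  tot <- total_duration(session$protocol)
  b <- detect_cycles(chest, sigma = sigma, prominence_k = prominence_k)
  b <- b[b >= 0 & b < tot]
  cyc <- cycles_from_boundaries(b)
  truth <- session$truth$cycles
  # match by midpoint: boundary jitter of a few ms must not slip a cycle
  # into its predecessor's slot
  j <- findInterval((cyc$start + cyc$end) / 2, truth$start)
  jj <- pmax(j, 1)
  overlap <- pmin(cyc$end, truth$end[jj]) - pmax(cyc$start, truth$start[jj])
  ok <- j >= 1 & overlap > 0.5 * (cyc$end - cyc$start)
  feats <- cycle_features(chest, cyc[ok, ])
  feats$label <- truth$label[j[ok]]
  feats
}
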