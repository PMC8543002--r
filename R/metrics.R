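# Summary statistics over the 1 Hz master timeline: terrain-dependent
# fluctuations (mean over laps 2-7 of the within-lap peak-to-minimum span of a
# %-of-max series), time-dependent changes (difference of within-lap means
# between a late and an early reference lap), grouped aggregations,
# sub-technique time distributions and LI-vs-HI session deltas.

#' Express a series in % of its maximum level
#'
#' @param values Numeric series.
#' @param max_value Individual maximum (e.g. HRmax, VO2max); defaults to the
#'   in-series maximum (used for tissue-saturation series, whose true
#'   maximum is not measured).
#' @return Series in %, with attribute `basis` recording the normalisation.
#' @export
pct_of_max <- function(values, max_value = NULL) {
  basis <- if (is.null(max_value)) "session-max" else "individual-max"
  max_value <- max_value %||% max(values, na.rm = TRUE)
  if (!is.finite(max_value) || max_value <= 0) stopf("invalid maximum level")
  structure(100 * values / max_value, basis = basis)
}

.lap_values <- function(series, protocol, lap) {
  ld <- protocol$lap_duration
  idx <- seq.int((lap - 1) * ld + 1, lap * ld)
  if (max(idx) > length(series)) {
    stopf("series does not cover lap %d (need %d seconds, have %d)",
          lap, max(idx), length(series))
  }
  v <- series[idx]
  if (all(is.na(v))) stopf("lap %d contains no data", lap)
  v
}

#' Terrain-dependent fluctuation of a %-of-max series
#'
#' The mean over the reference laps (2-7 by default; lap 1 is excluded
#' because it starts from rest) of the within-lap difference between the peak
#' and minimum per-second value.
#'
#' @param series Per-second values in % of max (element k+1 = second k).
#' @param protocol A `ski_protocol`.
#' @param laps Laps included (default 2:7).
#' @return Fluctuation in %-points.
#' @export
tdf <- function(series, protocol, laps = 2:7) {
  spans <- vapply(laps, function(l) {
    v <- .lap_values(series, protocol, l)
    max(v, na.rm = TRUE) - min(v, na.rm = TRUE)
  }, numeric(1))
  mean(spans)
}

#' Time-dependent change of a %-of-max series
#'
#' Difference between the within-lap means of the late and early reference
#' laps: laps (2, 7) for physiological series (lap 1 starts from rest) and
#' (1, 7) for biomechanical/power series.
#'
#' @inheritParams tdf
#' @param lap_ref `c(early, late)` reference laps.
#' @return Change in %-points (late minus early).
#' @export
tdc <- function(series, protocol, lap_ref = c(2, 7)) {
  if (length(lap_ref) != 2) stopf("lap_ref must be c(early, late)")
  late <- mean(.lap_values(series, protocol, lap_ref[2]), na.rm = TRUE)
  early <- mean(.lap_values(series, protocol, lap_ref[1]), na.rm = TRUE)
  late - early
}

#' Grouped means over the master timeline
#'
#' Groups the per-second rows by any subset of lap, segment and sub-technique;
#' groups totalling less than `min_duration` seconds are dropped (a skier who
#' spent under 6 s in a gear within a segment or lap is not representative of
#' it).  Missing values are ignored, never treated as zeros.
#'
#' @param master A master timeline data frame (see
#'   [build_master_timeline()]).
#' @param keys Character subset of `c("lap", "segment", "subtech")`.
#' @param variables Numeric columns to summarise; defaults to all numeric
#'   non-key columns.
#' @param min_duration Minimum group duration, s.
#' @return Long data frame: key columns, `variable`, `mean`, `sd`,
#'   `n_seconds`.
#' @export
aggregate_by <- function(master, keys, variables = NULL, min_duration = 6) {
  keys <- unique(keys)
  if (!length(keys)) stopf("at least one grouping key is required")
  bad <- setdiff(keys, c("lap", "segment", "subtech"))
  if (length(bad)) stopf("unknown grouping key(s): %s", paste(bad, collapse = ", "))
  variables <- variables %||% setdiff(
    names(master)[vapply(master, is.numeric, logical(1))],
    c("second", "lap", "segment"))
  groups <- split(master, master[keys], drop = TRUE)
  rows <- lapply(groups, function(g) {
    if (nrow(g) < min_duration) return(NULL)
    do.call(rbind, lapply(variables, function(v) {
      x <- g[[v]]
      x <- x[!is.na(x)]
      cbind(g[1, keys, drop = FALSE],
            data.frame(variable = v,
                       mean = if (length(x)) mean(x) else NA_real_,
                       sd = if (length(x) > 1) stats::sd(x) else NA_real_,
                       n_seconds = nrow(g)))
    }))
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Sub-technique time distribution per window
#'
#' Percentage of the covered time spent in each gear within each window
#' (e.g. laps or segments); percentages sum to 100 over the time covered by
#' labelled cycles.
#'
#' @param cycles Cycle table with `start`, `end`, `label`.
#' @param windows Data frame of windows with `start`, `end` (any id columns
#'   are carried through).
#' @param labels Label set to report.
#' @return Long data frame: window id columns, `label`, `pct_time`.
#' @export
subtech_distribution <- function(cycles, windows,
                                 labels = c("G2", "G3", "G4", "other")) {
  id_cols <- setdiff(names(windows), c("start", "end"))
  rows <- lapply(seq_len(nrow(windows)), function(w) {
    ov <- pmax(0, pmin(cycles$end, windows$end[w]) - pmax(cycles$start, windows$start[w]))
    tot <- sum(ov)
    pct <- vapply(labels, function(l) {
      if (tot > 0) 100 * sum(ov[cycles$label == l]) / tot else NA_real_
    }, numeric(1))
    cbind(windows[rep(w, length(labels)), id_cols, drop = FALSE],
          data.frame(label = labels, pct_time = pct))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' LI-vs-HI session summary deltas
#'
#' Pairs two per-variable session summaries and reports the raw difference
#' (HI minus LI) plus, for ratio-scaled variables, the percent change
#' relative to the LI mean rounded to the nearest integer percent; for
#' percentage-scaled variables the delta is a %-point difference and no
#' percent change is reported.
#'
#' @param li,hi Data frames with columns `variable`, `mean`, `sd` and
#'   `scale` (`"ratio"` or `"percent"`); variable sets must match.
#' @return Data frame: `variable`, `li_mean`, `li_sd`, `hi_mean`, `hi_sd`,
#'   `delta`, `delta_unit` (`"pp"` or `"native"`), `pct_change` (integer %,
#'   `NA` for percentage-scaled variables) and `pct_change_raw`.
#' @export
session_summary_delta <- function(li, hi) {
  for (df in list(li, hi)) {
    if (!all(c("variable", "mean", "sd", "scale") %in% names(df))) {
      stopf("summaries need columns variable, mean, sd, scale")
    }
  }
  if (!setequal(li$variable, hi$variable) ||
      anyDuplicated(li$variable) || anyDuplicated(hi$variable)) {
    stopf("LI and HI summaries must cover the same variables exactly once")
  }
  hi <- hi[match(li$variable, hi$variable), ]
  delta <- hi$mean - li$mean
  is_pct <- li$scale == "percent"
  pct_raw <- ifelse(is_pct, NA_real_, 100 * delta / li$mean)
  data.frame(variable = li$variable,
             li_mean = li$mean, li_sd = li$sd,
             hi_mean = hi$mean, hi_sd = hi$sd,
             delta = delta,
             delta_unit = ifelse(is_pct, "pp", "native"),
             pct_change = round_half_up(pct_raw),
             pct_change_raw = pct_raw)
}
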