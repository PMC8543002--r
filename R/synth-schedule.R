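# Sub-technique schedule: which gear is skied when, and at what cycle rate.
# Terrain mapping follows skate-skiing practice: G3 on the moderate ascent
# (segment 1), G4 on the flat (segment 2), G2 on the steep ascent (segment 3,
# with a configurable fraction of G3 at high intensity, where skiers keep G3
# longer on steep terrain), and "other" (tuck/transitions) on the simulated
# downhill (segment 4).

# cycle rates in cycles/min per gear and intensity; "other" is the slow
# residual body rocking in the tuck
.cr_table <- function() {
  data.frame(label = c("G2", "G3", "G4", "other"),
             LI = c(56, 46, 34, 25),
             HI = c(66, 54, 41, 25))
}

#' Sub-technique schedule for a session
#'
#' Builds the labelled gear windows covering `[0, total_duration)` from the
#' protocol's terrain profile, with per-gear cycle rates.
#'
#' @param protocol A `ski_protocol`.
#' @param intensity `"LI"` or `"HI"`.
#' @param g3_fraction_hi Fraction of the steep-ascent segment skied in G3
#'   instead of G2 at HI (placed at the start of the segment); 0 at LI.
#' @param jitter Uniform jitter (s) applied to interior window boundaries,
#'   emulating that gear transitions do not land exactly on segment edges.
#'   Requires an active RNG when > 0.
#' @return A data frame with columns `start`, `end`, `label`, `cr`
#'   (cycles/min), windows non-overlapping and covering the session.
#' @export
subtech_schedule <- function(protocol, intensity = c("LI", "HI"),
                             g3_fraction_hi = 0.4, jitter = 0) {
  intensity <- match.arg(intensity)
  if (g3_fraction_hi < 0 || g3_fraction_hi > 1) {
    stopf("g3_fraction_hi must lie in [0, 1]")
  }
  cr <- .cr_table()
  cr_of <- function(label) cr[[intensity]][match(label, cr$label)]
  win <- segment_windows(protocol)
  rows <- lapply(seq_len(nrow(win)), function(i) {
    w <- win[i, ]
    label <- switch(w$segment, "G3", "G4", "G2", "other")
    if (w$segment == 3 && intensity == "HI" && g3_fraction_hi > 0) {
      split <- w$start + g3_fraction_hi * (w$end - w$start)
      return(data.frame(start = c(w$start, split), end = c(split, w$end),
                        label = c("G3", "G2"),
                        cr = cr_of(c("G3", "G2"))))
    }
    data.frame(start = w$start, end = w$end, label = label, cr = cr_of(label))
  })
  sched <- do.call(rbind, rows)
  rownames(sched) <- NULL
  if (jitter > 0) {
    n <- nrow(sched)
    shift <- stats::runif(n - 1, -jitter, jitter)
    sched$end[-n] <- sched$end[-n] + shift
    sched$start[-1] <- sched$start[-1] + shift
  }
  sched
}

.check_schedule <- function(schedule) {
  for (key in c("start", "end", "label", "cr")) {
    if (is.null(schedule[[key]])) stopf("schedule is missing column '%s'", key)
  }
  o <- order(schedule$start)
  schedule <- schedule[o, , drop = FALSE]
  if (any(schedule$end <= schedule$start)) stopf("schedule windows must have end > start")
  if (nrow(schedule) > 1 &&
      any(schedule$start[-1] < schedule$end[-nrow(schedule)] - 1e-9)) {
    stopf("schedule windows overlap")
  }
  if (any(schedule$cr < 20 | schedule$cr > 120)) {
    stopf("cycle rates must lie in [20, 120] cycles/min")
  }
  schedule
}
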