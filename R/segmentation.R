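#' Phase map: labelled task segments
#'
#' An ordered set of non-overlapping sample segments labelling the task
#' phases (e.g. bending / position_holding / rising_up, or lifting /
#' lowering). Segments use 1-based inclusive `[start, end]` indices, must be
#' strictly increasing, and each must span at least 2 samples.
#'
#' @param label Character vector of phase names.
#' @param start,end Integer sample indices (1-based, inclusive).
#' @return A `data.frame` of class `phase_map` with columns `label`, `start`,
#'   `end`.
#' @seealso [detect_phases()], [timed_phases()]
#' @export
#' @examples
#' phase_map(c("bending", "position_holding", "rising_up"),
#'           start = c(1, 301, 1101), end = c(300, 1100, 1400))
phase_map <- function(label = character(0), start = integer(0),
                      end = integer(0)) {
  label <- as.character(label)
  start <- as.integer(start)
  end <- as.integer(end)
  if (length(label) != length(start) || length(start) != length(end)) {
    abort_iba("label, start, end must have equal length", "iba_validation")
  }
  if (length(start) > 0L) {
    if (anyNA(start) || anyNA(end) || any(start < 1L)) {
      abort_iba("segment indices must be positive integers", "iba_validation")
    }
    if (any(end - start + 1L < 2L)) {
      abort_iba("every segment must span at least 2 samples",
                "iba_degenerate")
    }
    if (length(start) > 1L && any(start[-1] <= end[-length(end)])) {
      abort_iba("segments must be strictly increasing and non-overlapping",
                "iba_validation")
    }
  }
  structure(data.frame(label = label, start = start, end = end,
                       stringsAsFactors = FALSE),
            class = c("phase_map", "data.frame"))
}

#' Segment a task by joint-rotation thresholds
#'
#' Detects bent-over intervals with a hysteresis comparator on the joint
#' angle (enter when the angle exceeds `threshold_deg + hysteresis_deg`,
#' leave when it drops below `threshold_deg - hysteresis_deg`), merges states
#' shorter than `min_dwell_s` into their neighbour, and splits every bent
#' interval into `bending` (angle rising), `position_holding` (angular rate
#' magnitude below `plateau_rate_deg_s`), and `rising_up` (angle falling).
#' Intervals below threshold are labelled `upright`. The angular rate is a
#' central difference of the angle smoothed over `rate_smooth_s`.
#'
#' If the angle never crosses the threshold the whole record is returned as a
#' single `upright` segment. If a bent interval has no detectable plateau it
#' is split at its angle maximum into `bending` and `rising_up`.
#'
#' @param angle An [angle_signal()].
#' @param threshold_deg Bending threshold in degrees (default 15, the angle
#'   at which back-support devices typically engage).
#' @param hysteresis_deg Hysteresis half-width in degrees (default 2).
#' @param min_dwell_s Minimum duration of an upright/bent state in seconds;
#'   shorter states are merged into their neighbour (default 0.25).
#' @param plateau_rate_deg_s Angular-rate threshold (deg/s) below which a
#'   bent sample counts as position holding (default 2).
#' @param rate_smooth_s Smoothing window for the rate estimate in seconds
#'   (default 0.05).
#' @return A [phase_map()] covering the record.
#' @export
detect_phases <- function(angle,
                          threshold_deg = 15,
                          hysteresis_deg = 2,
                          min_dwell_s = 0.25,
                          plateau_rate_deg_s = 2,
                          rate_smooth_s = 0.05) {
  stopifnot(inherits(angle, "angle_signal"))
  if (!(threshold_deg > hysteresis_deg && hysteresis_deg >= 0)) {
    abort_iba("need threshold_deg > hysteresis_deg >= 0", "iba_validation")
  }
  if (min_dwell_s < 0) abort_iba("min_dwell_s must be >= 0", "iba_validation")
  v <- angle$values
  n <- length(v)
  if (n < 2L) abort_iba("angle signal too short to segment", "iba_degenerate")
  dt <- angle$dt

  # hysteresis comparator, vectorised via last-observation-carried-forward
  s <- rep(NA_integer_, n)
  s[v > threshold_deg + hysteresis_deg] <- 1L
  s[v < threshold_deg - hysteresis_deg] <- 0L
  if (is.na(s[1])) s[1] <- 0L
  filled <- cummax(ifelse(is.na(s), 0L, seq_len(n)))
  bent <- s[filled] == 1L

  if (!any(bent)) {
    return(phase_map("upright", 1L, n))
  }

  # merge states shorter than the dwell into a neighbour
  r <- rle(bent)
  min_len <- max(1L, as.integer(round(min_dwell_s / dt)))
  while (length(r$lengths) > 1L && any(r$lengths < min_len)) {
    j <- which(r$lengths < min_len)[1]
    r$values[j] <- if (j > 1L) r$values[j - 1L] else r$values[j + 1L]
    r <- rle(inverse.rle(r))
  }
  bent <- inverse.rle(r)
  r <- rle(bent)

  rate <- angle_rate(v, dt, rate_smooth_s)

  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  lab <- character(0); seg_s <- integer(0); seg_e <- integer(0)
  add <- function(l, a, b) {
    lab <<- c(lab, l); seg_s <<- c(seg_s, a); seg_e <<- c(seg_e, b)
  }
  for (k in seq_along(r$values)) {
    a <- starts[k]; b <- ends[k]
    if (!r$values[k]) {
      add("upright", a, b)
      next
    }
    sub <- split_bent_interval(a, b, v, rate, plateau_rate_deg_s)
    for (row in sub) add(row[[1]], row[[2]], row[[3]])
  }
  phase_map(lab, seg_s, seg_e)
}

angle_rate <- function(v, dt, rate_smooth_s) {
  sm <- smooth_ma(v, round(rate_smooth_s / dt))
  n <- length(sm)
  rate <- numeric(n)
  rate[2:(n - 1)] <- (sm[3:n] - sm[1:(n - 2)]) / (2 * dt)
  rate[1] <- rate[2]
  rate[n] <- rate[n - 1]
  rate
}

# Split one bent interval [a, b] into bending / position_holding / rising_up
# using the longest below-rate plateau run; sub-segments too short to stand
# alone are absorbed by the plateau.
split_bent_interval <- function(a, b, v, rate, plateau_rate) {
  idx <- a:b
  pl <- abs(rate[idx]) < plateau_rate
  runs <- rle(pl)
  if (any(runs$values & runs$lengths >= 2L)) {
    run_end <- cumsum(runs$lengths)
    run_start <- run_end - runs$lengths + 1L
    cand <- which(runs$values)
    best <- cand[which.max(runs$lengths[cand])]
    p1 <- a + run_start[best] - 1L
    p2 <- a + run_end[best] - 1L
    out <- list()
    if (p1 - a >= 2L) {
      out <- c(out, list(list("bending", a, p1 - 1L)))
    } else {
      p1 <- a
    }
    if (b - p2 >= 2L) {
      out <- c(out, list(list("position_holding", p1, p2),
                         list("rising_up", p2 + 1L, b)))
    } else {
      out <- c(out, list(list("position_holding", p1, b)))
    }
    return(out)
  }
  # no plateau: split at the angle maximum
  m <- a + which.max(v[a:b]) - 1L
  if (m - a + 1L >= 2L && b - m >= 2L) {
    list(list("bending", a, m), list("rising_up", m + 1L, b))
  } else {
    list(list("bending", a, b))
  }
}

#' Build a phase map from timed boundaries
#'
#' For tasks whose sub-phases are timed rather than derived from kinematics.
#' Times are converted to sample indices with round-half-down starts and
#' exclusive ends, so that contiguous time intervals produce contiguous,
#' non-overlapping segments.
#'
#' @param boundaries A `data.frame` with columns `label`, `start_s`, `end_s`
#'   (seconds), strictly increasing and non-overlapping.
#' @param dt Sampling interval of the signal the map will index (seconds).
#' @return A [phase_map()].
#' @export
#' @examples
#' timed_phases(data.frame(label = "hold", start_s = 0, end_s = 1), dt = 0.1)
timed_phases <- function(boundaries, dt) {
  dt <- check_dt(dt)
  need <- c("label", "start_s", "end_s")
  if (!is.data.frame(boundaries) || !all(need %in% names(boundaries))) {
    abort_iba("boundaries needs columns label, start_s, end_s",
              "iba_format_error")
  }
  if (nrow(boundaries) == 0L) return(phase_map())
  st <- as.numeric(boundaries$start_s)
  en <- as.numeric(boundaries$end_s)
  if (any(en <= st)) {
    abort_iba("reversed interval: end_s must exceed start_s",
              "iba_validation")
  }
  if (nrow(boundaries) > 1L && any(st[-1] < en[-length(en)])) {
    abort_iba("overlapping timed boundaries", "iba_validation")
  }
  rhd <- function(x) as.integer(ceiling(x / dt - 0.5))  # round half down
  phase_map(boundaries$label, start = rhd(st) + 1L, end = rhd(en))
}

#' Durations (s) of the segments of a phase map
#' @param phases A [phase_map()].
#' @param dt Sampling interval in seconds.
#' @return Numeric vector of segment durations.
#' @export
phase_durations <- function(phases, dt) {
  (phases$end - phases$start + 1L) * check_dt(dt)
}

#' @export
print.phase_map <- function(x, ...) {
  cat(sprintf("<phase_map> %d segment(s)\n", nrow(x)))
  print.data.frame(x)
  invisible(x)
}
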