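## Fixation/saccade detection (I-VT), pupil change, state-wise aggregation.

#' Construct a gaze recording
#'
#' @param time strictly increasing timestamps (s), nominally 60 Hz.
#' @param x,y gaze position in degrees of visual angle.
#' @param pupilLeft,pupilRight pupil diameters (mm).
#' @param valid logical validity flags (default all TRUE).
#' @return a [GazeRecording-class].
#' @export
gazeRecording <- function(time, x, y, pupilLeft, pupilRight,
                          valid = rep(TRUE, length(time))) {
  new("GazeRecording", time = time, x = x, y = y,
      pupilLeft = pupilLeft, pupilRight = pupilRight, valid = valid)
}

setMethod("show", "GazeRecording", function(object) {
  cat(sprintf("GazeRecording: %d samples over %.1f s, %d invalid\n",
              length(object@time), diff(range(object@time)),
              sum(!object@valid)))
})

#' Convert pixel gaze coordinates to degrees of visual angle
#'
#' Uses the viewing geometry of a 27-inch 16:9 display at 1 m: pixels are
#' mapped to on-screen centimetres, then to visual angle by
#' `atan(cm / viewing_distance)` about the screen centre.
#'
#' @param px,py pixel coordinates.
#' @param resolution c(width, height) in pixels (default 1920 x 1080).
#' @param diagonalIn display diagonal in inches (default 27).
#' @param distanceM viewing distance in metres (default 1).
#' @return list with `x`, `y` in degrees.
#' @export
pixelsToDegrees <- function(px, py, resolution = c(1920, 1080),
                            diagonalIn = 27, distanceM = 1) {
  aspect <- resolution[1] / resolution[2]
  heightCm <- diagonalIn * 2.54 / sqrt(1 + aspect^2)
  cmPerPx <- heightCm / resolution[2]
  cx <- (px - resolution[1] / 2) * cmPerPx
  cy <- (py - resolution[2] / 2) * cmPerPx
  list(x = atan(cx / (100 * distanceM)) * 180 / pi,
       y = atan(cy / (100 * distanceM)) * 180 / pi)
}

.runmed3 <- function(v, k) {
  if (length(v) < k) return(v)
  as.numeric(stats::runmed(v, k, endrule = "keep"))
}

#' Detect fixations and saccades (velocity threshold)
#'
#' I-VT segmentation: gaze is median-filtered (3 samples), per-sample
#' angular velocity is computed from consecutive positions, and samples
#' moving faster than `velThresh` deg/s form saccades. Maximal valid runs
#' between saccades lasting at least `minFix` s form fixations. Invalid
#' samples split events. Saccade amplitude is the start-to-end angular
#' distance; fixation dispersion is the diagonal of the position bounding
#' box.
#'
#' @param g a [GazeRecording-class] with at least 0.5 s of valid samples.
#' @param velThresh saccade velocity threshold in deg/s (default 30).
#' @param minFix minimum fixation duration in s (default 0.1).
#' @param medianK odd median pre-filter width in samples (default 3).
#' @return data.frame of events: `kind` (fixation/saccade), `start`, `end`,
#'   `duration` (s), `amplitude` (deg; dispersion for fixations),
#'   `cx`, `cy` (centroid, deg).
#' @export
detectEvents <- function(g, velThresh = 30, minFix = 0.1, medianK = 3) {
  v <- g@valid
  if (!any(v)) stop("all gaze samples invalid")
  if (sum(v) / 60 < 0.5) stop("need at least 0.5 s of valid samples")
  x <- .runmed3(g@x, medianK)
  y <- .runmed3(g@y, medianK)
  n <- length(x)
  # central-difference angular velocity (deg/s): a two-sample span halves
  # the jitter-induced velocity noise, which single-sample differences at
  # 60 Hz would push past any usable threshold
  vel <- numeric(n)
  if (n >= 3) {
    span <- g@time[3:n] - g@time[1:(n - 2)]
    vel[2:(n - 1)] <- sqrt((x[3:n] - x[1:(n - 2)])^2 +
                           (y[3:n] - y[1:(n - 2)])^2) / span
  }
  sac <- vel > velThresh & v & c(TRUE, v[-n])     # invalid neighbours split
  state <- ifelse(!v, "invalid", ifelse(sac, "saccade", "fixation"))
  r <- rle(state)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  ev <- list()
  for (i in seq_along(r$values)) {
    kind <- r$values[i]
    if (kind == "invalid") next
    i0 <- starts[i]; i1 <- ends[i]
    if (kind == "saccade") {
      # amplitude between the flanking fixation positions, each averaged
      # over up to 5 samples so endpoint jitter does not bias it
      pre <- if (i > 1 && r$values[i - 1] == "fixation")
        max(starts[i - 1], i0 - 5L):(i0 - 1L) else max(1L, i0 - 1L)
      post <- if (i < length(r$values) && r$values[i + 1] == "fixation")
        (i1 + 1L):min(ends[i + 1], i1 + 5L) else min(n, i1)
      amp <- sqrt((mean(x[post]) - mean(x[pre]))^2 +
                  (mean(y[post]) - mean(y[pre]))^2)
      p0 <- max(1L, i0 - 1L)
      ev[[length(ev) + 1L]] <- data.frame(
        kind = "saccade", start = g@time[p0], end = g@time[i1],
        duration = g@time[i1] - g@time[p0], amplitude = amp,
        cx = mean(x[i0:i1]), cy = mean(y[i0:i1]))
    } else {
      dur <- g@time[i1] - g@time[i0]
      if (dur < minFix) next
      disp <- sqrt(diff(range(x[i0:i1]))^2 + diff(range(y[i0:i1]))^2)
      ev[[length(ev) + 1L]] <- data.frame(
        kind = "fixation", start = g@time[i0], end = g@time[i1],
        duration = dur, amplitude = disp,
        cx = mean(x[i0:i1]), cy = mean(y[i0:i1]))
    }
  }
  if (!length(ev))
    return(data.frame(kind = character(), start = numeric(),
                      end = numeric(), duration = numeric(),
                      amplitude = numeric(), cx = numeric(), cy = numeric()))
  out <- do.call(rbind, ev)
  rownames(out) <- NULL
  out
}

#' Baseline-referenced pupil change
#'
#' Percent change of the mean pupil diameter in a segment relative to a
#' baseline window, per eye:
#' `100 * (mean(segment) - mean(baseline)) / mean(baseline)`. A ratio
#' metric, so it is invariant to uniform diameter rescaling and removes
#' inter-individual diameter offsets.
#'
#' @param g a [GazeRecording-class].
#' @param baseline c(start, end) of the baseline window (s).
#' @param segment c(start, end) of the evaluation window (s).
#' @param minSamples minimum valid samples required in each window
#'   (default 10).
#' @return named numeric: `left`, `right` (percent).
#' @export
pupilChange <- function(g, baseline, segment, minSamples = 10) {
  sel <- function(win) {
    i <- g@time >= win[1] & g@time < win[2] & g@valid
    if (sum(i) < minSamples)
      stop("fewer than ", minSamples, " valid samples in window [",
           win[1], ", ", win[2], ")")
    i
  }
  bi <- sel(baseline); si <- sel(segment)
  c(left  = 100 * (mean(g@pupilLeft[si]) - mean(g@pupilLeft[bi])) /
            mean(g@pupilLeft[bi]),
    right = 100 * (mean(g@pupilRight[si]) - mean(g@pupilRight[bi])) /
            mean(g@pupilRight[bi]))
}

#' Aggregate eye features by condition and emotional state
#'
#' Assigns each detected event to the state segment containing its
#' midpoint, and summarizes per state: mean fixation duration, fixation
#' count, saccade rate (per second of state time), mean saccade amplitude,
#' and baseline-referenced pupil change over the state's segments. Cells
#' with no events are reported as missing (NA), not zero. The gaze and EEG
#' clocks must share a time origin; a coverage mismatch beyond
#' `maxSkew` s is an error.
#'
#' @param events event table from [detectEvents()].
#' @param g the [GazeRecording-class] the events came from.
#' @param labels a [StateLabels-class] (after [labelEmotional()]).
#' @param condition condition label attached to the output rows.
#' @param baseline pupil baseline window c(start, end) (s); default the
#'   first 5 s.
#' @param maxSkew largest tolerated clock/coverage mismatch (s),
#'   default 0.5.
#' @return data.frame, one row per state, with columns `condition`,
#'   `state`, `mean_fix_duration`, `fix_count`, `saccade_rate`,
#'   `mean_saccade_amplitude`, `pupil_change_left`, `pupil_change_right`,
#'   `state_time_s`.
#' @export
aggregateByState <- function(events, g, labels, condition,
                             baseline = c(0, 5), maxSkew = 0.5) {
  segs <- stateSegments(labels)
  gSpan <- range(g@time)
  if (gSpan[1] < segs$start_s[1] - maxSkew ||
      gSpan[2] > segs$end_s[nrow(segs)] + maxSkew)
    stop("gaze span [", round(gSpan[1], 2), ", ", round(gSpan[2], 2),
         "] not covered by state labels (skew > ", maxSkew, " s)")
  mid <- (events$start + events$end) / 2
  segIdx <- findInterval(mid, segs$start_s)
  segIdx[segIdx < 1 | segIdx > nrow(segs)] <- NA
  evState <- segs$emotional[segIdx]
  out <- lapply(c(FALSE, TRUE), function(st) {
    stSegs <- segs[segs$emotional == st, , drop = FALSE]
    tTot <- sum(pmin(stSegs$end_s, gSpan[2]) - pmax(stSegs$start_s, gSpan[1]))
    tTot <- max(tTot, 0)
    fx <- events[!is.na(evState) & evState == st & events$kind == "fixation", ]
    sc <- events[!is.na(evState) & evState == st & events$kind == "saccade", ]
    pc <- c(left = NA_real_, right = NA_real_)
    if (tTot > 0 && nrow(stSegs)) {
      i <- rep(FALSE, length(g@time))
      for (k in seq_len(nrow(stSegs)))
        i <- i | (g@time >= stSegs$start_s[k] & g@time < stSegs$end_s[k])
      i <- i & g@valid
      bi <- g@time >= baseline[1] & g@time < baseline[2] & g@valid
      if (sum(i) >= 10 && sum(bi) >= 10)
        pc <- c(left = 100 * (mean(g@pupilLeft[i]) - mean(g@pupilLeft[bi])) /
                       mean(g@pupilLeft[bi]),
                right = 100 * (mean(g@pupilRight[i]) - mean(g@pupilRight[bi])) /
                        mean(g@pupilRight[bi]))
    }
    data.frame(
      condition = condition,
      state = if (st) "emotional" else "non-emotional",
      mean_fix_duration = if (nrow(fx)) mean(fx$duration) else NA_real_,
      fix_count = if (tTot > 0) nrow(fx) else NA_integer_,
      saccade_rate = if (tTot > 0) nrow(sc) / tTot else NA_real_,
      mean_saccade_amplitude = if (nrow(sc)) mean(sc$amplitude) else NA_real_,
      pupil_change_left = unname(pc["left"]),
      pupil_change_right = unname(pc["right"]),
      state_time_s = tTot,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
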