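## Ground-truth synthetic sessions: coupled EEG, gaze streams, study bundles.

.conditions <- c("pleasant-aroused", "pleasant-relaxed",
                 "unpleasant-relaxed", "unpleasant-aroused")

#' The four conditions of the 2x2 valence-arousal design
#' @return character vector of condition labels.
#' @export
studyConditions <- function() .conditions

#' Session configuration for the synthetic generator
#'
#' Bundles everything a session realization needs: the condition label,
#' duration, sampling rates, the two-state temporal schedule, the gaze
#' event schedule, the pupil excursion schedule, and the seed. Defaults
#' emulate a stimulus-viewing session: a non-emotional first half and an
#' emotional second half, a saccade every 2 s, and a 10% pupil dilation
#' during emotional segments.
#'
#' @param condition one of [studyConditions()].
#' @param duration session length in s (default 24).
#' @param eegRate EEG sampling rate (default 500 Hz).
#' @param gazeRate gaze sampling rate (default 60 Hz).
#' @param stateSchedule data.frame `start`, `end`, `state`
#'   ("non-emotional"/"emotional") tiling `[0, duration]`; default the
#'   half/half split.
#' @param gazeEvents data.frame of scheduled saccades: `time`,
#'   `amplitude` (deg), optional `angle` (radians); default one saccade
#'   every 2 s with amplitudes drawn in 4-10 deg at realization time.
#' @param pupilSchedule data.frame `start`, `end`, `pct_left`,
#'   `pct_right`; default +10% both eyes during emotional segments.
#' @param pupilBaseline baseline pupil diameter (mm, default 3.5).
#' @param seed RNG seed for the realization.
#' @return a `SessionConfig` list (class "SessionConfig").
#' @export
sessionConfig <- function(condition = .conditions[1], duration = 24,
                          eegRate = 500, gazeRate = 60,
                          stateSchedule = NULL, gazeEvents = NULL,
                          pupilSchedule = NULL, pupilBaseline = 3.5,
                          seed = 1) {
  if (!condition %in% .conditions)
    stop("condition must be one of: ", paste(.conditions, collapse = ", "))
  if (duration <= 0 || eegRate <= 0 || gazeRate <= 0)
    stop("duration and rates must be positive")
  if (is.null(stateSchedule))
    stateSchedule <- data.frame(
      start = c(0, duration / 2), end = c(duration / 2, duration),
      state = c("non-emotional", "emotional"), stringsAsFactors = FALSE)
  if (abs(stateSchedule$start[1]) > 1e-9 ||
      abs(stateSchedule$end[nrow(stateSchedule)] - duration) > 1e-9 ||
      any(abs(stateSchedule$end[-nrow(stateSchedule)] -
              stateSchedule$start[-1]) > 1e-9))
    stop("stateSchedule must tile [0, duration]")
  if (is.null(gazeEvents)) {
    tms <- if (duration > 3) seq(2, duration - 1, by = 2) else numeric(0)
    gazeEvents <- data.frame(time = tms,
                             amplitude = rep(NA_real_, length(tms)))
  }
  if (nrow(gazeEvents) > 1 && any(diff(gazeEvents$time) < 0.2))
    stop("scheduled gaze events overlap (closer than 0.2 s)")
  if (is.null(pupilSchedule)) {
    emo <- stateSchedule[stateSchedule$state == "emotional", , drop = FALSE]
    pupilSchedule <- if (nrow(emo))
      data.frame(start = emo$start, end = emo$end,
                 pct_left = 10, pct_right = 10)
    else data.frame(start = numeric(), end = numeric(),
                    pct_left = numeric(), pct_right = numeric())
  }
  structure(list(condition = condition, duration = duration,
                 eegRate = eegRate, gazeRate = gazeRate,
                 stateSchedule = stateSchedule, gazeEvents = gazeEvents,
                 pupilSchedule = pupilSchedule,
                 pupilBaseline = pupilBaseline, seed = seed),
            class = "SessionConfig")
}

#' Cross-channel coupling specification
#'
#' Each entry plants one shared band-limited source into a channel pair or
#' a whole pair group: `signal = sqrt(strength) * common +
#' sqrt(1 - strength) * private`, with the second channel's common part
#' delayed by `phaseLag` radians and the first channel's band amplitude
#' scaled by `sqrt(powerRatio)`, active only during the listed schedule
#' states. Shared-source mixing gives the planted phase-locking value a
#' closed-form expectation to test against.
#'
#' @param ... coupling entries, each a list with fields `pair`
#'   (c(ch1, ch2)) or `group` ("LD_OF"/"LD_PF"/"SD"), `band`, `phaseLag`
#'   (rad), `strength` in \[0, 1\], `powerRatio` > 0, and `states`
#'   (character vector of schedule states, or "all").
#' @return a `CouplingSpec` list.
#' @export
couplingSpec <- function(...) {
  entries <- list(...)
  for (e in entries) {
    if (is.null(e$pair) && is.null(e$group))
      stop("each coupling entry needs 'pair' or 'group'")
    s <- if (is.null(e$strength)) 1 else e$strength
    if (s < 0 || s > 1) stop("coupling strength must lie in [0, 1]")
    pr <- if (is.null(e$powerRatio)) 1 else e$powerRatio
    if (pr <= 0) stop("powerRatio must be positive")
  }
  structure(entries, class = "CouplingSpec")
}

# 1/f-shaped broadband noise via spectral shaping, unit sd
.pinkNoise <- function(n, rate) {
  X <- stats::fft(stats::rnorm(n))
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1) * rate / n          # two-sided frequency axis
  X <- X / sqrt(pmax(f, 0.5))
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  (x - mean(x)) / stats::sd(x)
}

# band-limited unit-sd noise
.bandNoise <- function(n, rate, lo, hi) {
  x <- .bandFilterVec(stats::rnorm(n), lo, hi, rate)
  (x - mean(x)) / stats::sd(x)
}

# analytic signal via FFT (Hilbert construction)
.analytic <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) { h[c(1, n / 2 + 1)] <- 1; h[2:(n / 2)] <- 2 }
  else { h[1] <- 1; h[2:((n + 1) / 2)] <- 2 }
  stats::fft(X * h, inverse = TRUE) / n
}

# per-sample schedule state names
.stateMaskFun <- function(schedule, t) {
  st <- rep(schedule$state[nrow(schedule)], length(t))
  idx <- findInterval(t, schedule$start)
  ok <- idx >= 1 & idx <= nrow(schedule)
  st[ok] <- schedule$state[idx[ok]]
  st
}

#' Generate a coupled multichannel EEG session
#'
#' Each channel is the sum of 1/f broadband noise and four band-limited
#' oscillations. Coupling entries replace the band component of the
#' affected channels with a shared-source mixture (see [couplingSpec()])
#' during their active schedule states. Deterministic given the config
#' seed.
#'
#' Regional power gains (see `regionGains`) scale a band's amplitude per
#' scalp region during the emotional schedule states, emulating regional
#' activation differences — the generative mechanism behind the
#' power-difference eigenvalues — without disturbing phase structure.
#'
#' @param cfg a [sessionConfig()].
#' @param coupling a [couplingSpec()] or NULL for fully independent
#'   channels.
#' @param montage a [Montage-class] (default [buildMontage()]).
#' @param pinkSd broadband noise sd (uV, default 3).
#' @param bandSd named numeric, per-band oscillation sd (uV).
#' @param regionGains optional named numeric of per-region amplitude
#'   gains applied to `gainBand` during `gainStates`.
#' @param gainBand band the regional gains act on (default "beta").
#' @param gainStates schedule states the gains are active in (default
#'   "emotional").
#' @return list with `rec` (an [EEGRecording-class]) and `truth`
#'   (state schedule, resolved couplings, per-channel band roles).
#' @export
generateEEG <- function(cfg, coupling = NULL, montage = buildMontage(),
                        pinkSd = 3,
                        bandSd = c(delta = 3, theta = 2.5, alpha = 4,
                                   beta = 4),
                        regionGains = NULL, gainBand = "beta",
                        gainStates = "emotional") {
  set.seed(cfg$seed)
  ch <- channels(montage)
  n <- round(cfg$duration * cfg$eegRate)
  t <- (seq_len(n) - 1) / cfg$eegRate
  bands <- eegBands()
  stateNames <- .stateMaskFun(cfg$stateSchedule, t)

  # private components
  base <- matrix(0, length(ch), n, dimnames = list(ch, NULL))
  priv <- list()
  for (bi in seq_len(nrow(bands))) {
    bn <- bands$name[bi]
    priv[[bn]] <- matrix(0, length(ch), n, dimnames = list(ch, NULL))
    for (ci in seq_along(ch))
      priv[[bn]][ci, ] <- bandSd[bn] *
        .bandNoise(n, cfg$eegRate, max(bands$lo[bi], 0.5), bands$hi[bi])
  }
  for (ci in seq_along(ch))
    base[ci, ] <- pinkSd * .pinkNoise(n, cfg$eegRate)

  # band components start as the private signals
  comp <- lapply(priv, function(m) m)
  resolved <- list()
  if (!is.null(coupling)) {
    pg <- classifyPairs(montage)
    for (e in coupling) {
      bn <- e$band
      if (!bn %in% bands$name) stop("unknown band '", bn, "' in coupling")
      prs <- if (!is.null(e$pair)) {
        bad <- setdiff(e$pair, ch)
        if (length(bad))
          stop("coupling references channel(s) not in montage: ",
               paste(bad, collapse = ", "))
        data.frame(ch1 = e$pair[1], ch2 = e$pair[2],
                   stringsAsFactors = FALSE)
      } else pg[pg$group == e$group, c("ch1", "ch2")]
      if (!nrow(prs)) stop("coupling group '", e$group, "' is empty")
      s <- if (is.null(e$strength)) 1 else e$strength
      pr <- if (is.null(e$powerRatio)) 1 else e$powerRatio
      lag <- if (is.null(e$phaseLag)) 0 else e$phaseLag
      act <- if (is.null(e$states) || identical(e$states, "all"))
        rep(TRUE, n) else stateNames %in% e$states
      bi <- which(bands$name == bn)
      common <- bandSd[bn] *
        .bandNoise(n, cfg$eegRate, max(bands$lo[bi], 0.5), bands$hi[bi])
      z <- .analytic(common)
      lead <- Re(z)                      # first channel: unlagged
      follow <- Re(z * exp(-1i * lag))   # second channel trails by lag
      # power ratio realized symmetrically (sqrt(pr) up, 1/sqrt(pr) down)
      # so total band power stays level while the planted ratio holds
      side1 <- unique(prs$ch1); side2 <- setdiff(unique(prs$ch2), side1)
      for (c1 in side1) {
        mix <- sqrt(s) * lead + sqrt(1 - s) * priv[[bn]][c1, ]
        comp[[bn]][c1, act] <- (pr^0.25 * mix)[act]
      }
      for (c2 in side2) {
        mix <- sqrt(s) * follow + sqrt(1 - s) * priv[[bn]][c2, ]
        comp[[bn]][c2, act] <- (pr^-0.25 * mix)[act]
      }
      resolved[[length(resolved) + 1L]] <-
        list(pairs = prs, band = bn, phaseLag = lag, strength = s,
             powerRatio = pr,
             states = if (is.null(e$states)) "all" else e$states)
    }
  }
  if (!is.null(regionGains)) {
    bad <- setdiff(names(regionGains), unique(channelRegions(montage)))
    if (length(bad)) stop("unknown region(s): ", paste(bad, collapse = ", "))
    act <- stateNames %in% gainStates
    reg <- channelRegions(montage)
    for (ci in seq_along(ch)) {
      gn <- regionGains[reg[ch[ci]]]
      if (!is.na(gn) && gn != 1)
        comp[[gainBand]][ci, act] <- gn * comp[[gainBand]][ci, act]
    }
  }
  samples <- base
  for (bn in bands$name) samples <- samples + comp[[bn]]
  rec <- eegRecording(samples, rate = cfg$eegRate, t0 = 0)
  list(rec = rec,
       truth = list(stateSchedule = cfg$stateSchedule,
                    couplings = resolved, regionGains = regionGains,
                    seed = cfg$seed))
}

# minimum-jerk displacement profile on [0, 1]
.minJerk <- function(u) 10 * u^3 - 15 * u^4 + 6 * u^5

#' Generate a gaze and pupil session
#'
#' Piecewise scan path: fixation epochs with Gaussian jitter (sd 0.2 deg)
#' around a drifting fixation point, saccades as minimum-jerk transitions
#' at the scheduled times and amplitudes (duration 20 ms + 2 ms/deg).
#' Pupil = baseline, scaled by the scheduled excursions, plus AR(1) noise
#' (phi = 0.95) mimicking slow pupil dynamics. Deterministic given the
#' config seed.
#'
#' @param cfg a [sessionConfig()].
#' @param jitterSd fixation jitter sd in deg (default 0.2).
#' @param pupilNoiseSd stationary AR(1) noise sd in mm (default 0.02).
#' @return list with `rec` (a [GazeRecording-class]) and `truth`
#'   (planted saccades with realized amplitudes, fixation centres, pupil
#'   schedule).
#' @export
generateGaze <- function(cfg, jitterSd = 0.2, pupilNoiseSd = 0.02) {
  set.seed(cfg$seed + 1L)
  tms <- seq(0, cfg$duration - 1 / cfg$gazeRate, by = 1 / cfg$gazeRate)
  n <- length(tms)
  ev <- cfg$gazeEvents
  ev <- ev[order(ev$time), , drop = FALSE]
  if (nrow(ev)) {
    if (any(is.na(ev$amplitude)))
      ev$amplitude[is.na(ev$amplitude)] <-
        stats::runif(sum(is.na(ev$amplitude)), 4, 10)
    if (is.null(ev$angle)) ev$angle <- NA_real_
    if (any(is.na(ev$angle)))
      ev$angle[is.na(ev$angle)] <-
        stats::runif(sum(is.na(ev$angle)), 0, 2 * pi)
  }
  x <- numeric(n); y <- numeric(n)
  pos <- c(0, 0)
  centres <- list(data.frame(start = 0, cx = 0, cy = 0))
  ampReal <- numeric(nrow(ev))
  cur <- 1L
  for (k in seq_len(nrow(ev))) {
    dur <- 0.020 + 0.002 * ev$amplitude[k]
    if (ev$time[k] + dur > cfg$duration)
      stop("scheduled saccade at ", ev$time[k], " s overruns the session")
    tgt <- pos + ev$amplitude[k] * c(cos(ev$angle[k]), sin(ev$angle[k]))
    # keep the path on a +-15 deg screen by reflecting the direction
    for (d in 1:2) if (abs(tgt[d]) > 15)
      tgt[d] <- sign(tgt[d]) * 30 - tgt[d]
    ampReal[k] <- sqrt(sum((tgt - pos)^2))
    i0 <- which(tms >= ev$time[k])[1]
    i1 <- which(tms <= ev$time[k] + dur); i1 <- i1[length(i1)]
    while (cur < i0) { x[cur] <- pos[1]; y[cur] <- pos[2]; cur <- cur + 1L }
    if (i1 >= i0) {
      u <- (tms[i0:i1] - ev$time[k]) / dur
      x[i0:i1] <- pos[1] + (tgt[1] - pos[1]) * .minJerk(pmin(u, 1))
      y[i0:i1] <- pos[2] + (tgt[2] - pos[2]) * .minJerk(pmin(u, 1))
      cur <- i1 + 1L
    }
    pos <- tgt
    centres[[length(centres) + 1L]] <-
      data.frame(start = ev$time[k] + dur, cx = pos[1], cy = pos[2])
  }
  while (cur <= n) { x[cur] <- pos[1]; y[cur] <- pos[2]; cur <- cur + 1L }
  # fixation jitter everywhere except mid-saccade samples
  inSac <- rep(FALSE, n)
  for (k in seq_len(nrow(ev))) {
    dur <- 0.020 + 0.002 * ev$amplitude[k]
    inSac <- inSac | (tms >= ev$time[k] & tms <= ev$time[k] + dur)
  }
  x[!inSac] <- x[!inSac] + stats::rnorm(sum(!inSac), sd = jitterSd)
  y[!inSac] <- y[!inSac] + stats::rnorm(sum(!inSac), sd = jitterSd)

  ar1 <- function() {
    innov <- stats::rnorm(n, sd = pupilNoiseSd * sqrt(1 - 0.95^2))
    as.numeric(stats::filter(innov, 0.95, method = "recursive"))
  }
  scaleL <- rep(1, n); scaleR <- rep(1, n)
  ps <- cfg$pupilSchedule
  for (k in seq_len(nrow(ps))) {
    i <- tms >= ps$start[k] & tms < ps$end[k]
    scaleL[i] <- scaleL[i] * (1 + ps$pct_left[k] / 100)
    scaleR[i] <- scaleR[i] * (1 + ps$pct_right[k] / 100)
  }
  rec <- gazeRecording(tms, x, y,
                       pupilLeft = cfg$pupilBaseline * scaleL + ar1(),
                       pupilRight = cfg$pupilBaseline * scaleR + ar1())
  if (nrow(ev)) ev$amplitude_realized <- ampReal
  list(rec = rec,
       truth = list(saccades = ev,
                    fixationCentres = do.call(rbind, centres),
                    pupilSchedule = ps, seed = cfg$seed))
}

#' Default per-condition effect profile
#'
#' Score means follow the 2x2 design (aroused conditions score high on
#' arousal, pleasant conditions high on valence, 9-point scales). The
#' emotional-state schedule switches on per-region beta amplitude gains
#' whose pattern differs by condition, echoing the qualitative
#' connectivity findings (frontal dominance when unpleasant-aroused,
#' prefrontal dominance when pleasant, strong central-parietal activity
#' when relaxed), plus a long-distance occipital-frontal beta phase
#' coupling; the pupil excursion is largest when pleasant-aroused.
#' `nullProfile()` makes every condition identical with unit gains, for
#' type-I-error checks.
#'
#' @return named list, one entry per condition with fields `arousal`,
#'   `valence`, `regionGains` (named numeric over scalp regions),
#'   `couplingStrength`, `pupilPct`.
#' @export
defaultProfile <- function() {
  list(
    "pleasant-aroused"   = list(arousal = 7, valence = 7,
                                regionGains = c(prefrontal = 1.5,
                                                occipital = 1.3,
                                                temporal = 0.9,
                                                central = 0.9,
                                                parietal = 0.9),
                                couplingStrength = 0.7, pupilPct = 12),
    "pleasant-relaxed"   = list(arousal = 4, valence = 7,
                                regionGains = c(prefrontal = 1.5,
                                                occipital = 1.4,
                                                central = 1.2,
                                                parietal = 1.2,
                                                frontal = 0.9),
                                couplingStrength = 0.7, pupilPct = 8),
    "unpleasant-relaxed" = list(arousal = 4.5, valence = 3.5,
                                regionGains = c(central = 1.3,
                                                parietal = 1.3,
                                                prefrontal = 0.8,
                                                occipital = 1.1),
                                couplingStrength = 0.5, pupilPct = 6),
    "unpleasant-aroused" = list(arousal = 6, valence = 3,
                                regionGains = c(frontal = 1.4,
                                                prefrontal = 0.8,
                                                occipital = 0.9),
                                couplingStrength = 0.7, pupilPct = 4))
}

#' @rdname defaultProfile
#' @export
nullProfile <- function() {
  one <- list(arousal = 5, valence = 5,
              regionGains = c(prefrontal = 1),
              couplingStrength = 0.6, pupilPct = 8)
  stats::setNames(rep(list(one), 4), .conditions)
}

#' Generate a synthetic study bundle
#'
#' Per-participant sessions for all four conditions, with participant
#' random effects (sd 0.5 on score means, sd 0.05 on coupling strength),
#' and subjective arousal/valence scores drawn from the effect profile
#' (sd 1, clamped to the 1-9 scale). Fully reproducible given `seed`.
#' When `dir` is given, each participant x condition session is written
#' as EEG and gaze CSV files with a study manifest.
#'
#' @param nParticipants number of participants (>= 2; the reference study
#'   size is 47).
#' @param profile per-condition parameter map ([defaultProfile()] or
#'   [nullProfile()]).
#' @param seed study seed.
#' @param duration session length in s (default 24).
#' @param dir optional output directory for session files.
#' @param sessions logical: realize EEG/gaze sessions (default TRUE when
#'   `dir` is given, FALSE otherwise — score-only studies are enough for
#'   score statistics).
#' @param montage a [Montage-class].
#' @return list with `scores` (data.frame participant, condition, arousal,
#'   valence), `configs` (per participant x condition [sessionConfig()]s),
#'   `profile`, `seed`, and `dir` when written.
#' @export
generateStudy <- function(nParticipants, profile = defaultProfile(),
                          seed = 1, duration = 24, dir = NULL,
                          sessions = !is.null(dir),
                          montage = buildMontage()) {
  if (nParticipants < 2) stop("need at least 2 participants")
  if (!all(.conditions %in% names(profile)))
    stop("profile must cover all four conditions")
  set.seed(seed)
  pid <- sprintf("P%02d", seq_len(nParticipants))
  # participant random effects act on physiology (coupling strength, pupil
  # responsiveness), not on the score draws
  ranefC <- stats::rnorm(nParticipants, sd = 0.05)
  ranefP <- stats::rnorm(nParticipants, sd = 1)
  sessionSeeds <- matrix(sample.int(.Machine$integer.max %/% 2,
                                    nParticipants * 4),
                         nParticipants, 4)
  rows <- list(); configs <- list()
  for (i in seq_len(nParticipants)) {
    configs[[pid[i]]] <- list()
    for (j in seq_along(.conditions)) {
      cond <- .conditions[j]
      pf <- profile[[cond]]
      rows[[length(rows) + 1L]] <- data.frame(
        participant = pid[i], condition = cond,
        arousal = pmin(9, pmax(1, stats::rnorm(1, pf$arousal))),
        valence = pmin(9, pmax(1, stats::rnorm(1, pf$valence))),
        stringsAsFactors = FALSE)
      cfg <- sessionConfig(condition = cond, duration = duration,
                           seed = sessionSeeds[i, j])
      s <- min(1, max(0, pf$couplingStrength + ranefC[i]))
      cfg$coupling <- couplingSpec(
        list(group = "LD_OF", band = "beta", strength = s,
             powerRatio = 1, phaseLag = pi / 6, states = "emotional"))
      cfg$regionGains <- pf$regionGains
      cfg$pupilSchedule$pct_left <- pf$pupilPct + ranefP[i]
      cfg$pupilSchedule$pct_right <- pf$pupilPct + ranefP[i]
      configs[[pid[i]]][[cond]] <- cfg
    }
  }
  scores <- do.call(rbind, rows)
  bundle <- list(scores = scores, configs = configs, profile = profile,
                 seed = seed)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    writeStudyCsv(scores, file.path(dir, "scores.csv"))
    manifest <- list(seed = seed, n_participants = nParticipants,
                     duration_s = duration, conditions = .conditions,
                     participants = pid)
    if (sessions) {
      for (i in seq_len(nParticipants)) for (cond in .conditions) {
        cfg <- configs[[pid[i]]][[cond]]
        sdir <- file.path(dir, pid[i], cond)
        dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
        ee <- generateEEG(cfg, coupling = cfg$coupling, montage = montage,
                          regionGains = cfg$regionGains)
        gz <- generateGaze(cfg)
        writeEEGcsv(ee$rec, file.path(sdir, "eeg.csv"))
        writeGazeCsv(gz$rec, file.path(sdir, "gaze.csv"))
      }
    }
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    bundle$dir <- dir
  }
  bundle
}

#' Per-window true states of a session schedule
#'
#' @param cfg a [sessionConfig()].
#' @param windowStart window start times (s).
#' @param window window length (s).
#' @return character vector of schedule states at the window midpoints.
#' @export
trueStates <- function(cfg, windowStart, window = 1) {
  .stateMaskFun(cfg$stateSchedule, windowStart + window / 2)
}
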