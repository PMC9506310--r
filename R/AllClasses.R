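#' @import methods
NULL

#' Scalp montage on a spherical head model
#'
#' An 18-channel 10-20 electrode montage. Positions are stored as spherical
#' coordinates (azimuth measured from the nasion, positive towards the right
#' ear; elevation measured up from the equatorial ring) on a sphere of radius
#' `headRadius` centimetres. Each channel belongs to exactly one scalp region.
#'
#' @slot channels ordered character vector of channel labels.
#' @slot azimuth named numeric, azimuth in radians per channel.
#' @slot elevation named numeric, elevation in radians per channel.
#' @slot region named character, region per channel; one of
#'   `prefrontal`, `frontal`, `temporal`, `central`, `parietal`, `occipital`.
#' @slot headRadius numeric scalar, sphere radius in cm.
#'
#' @seealso [buildMontage()], [pairDistance()], [classifyPairs()]
#' @export
setClass("Montage",
  representation(
    channels   = "character",
    azimuth    = "numeric",
    elevation  = "numeric",
    region     = "character",
    headRadius = "numeric"
  )
)

.regionLevels <- c("prefrontal", "frontal", "temporal",
                   "central", "parietal", "occipital")

setValidity("Montage", function(object) {
  msg <- character()
  if (length(object@channels) != 18L)
    msg <- c(msg, "montage must have exactly 18 channels")
  if (anyDuplicated(object@channels))
    msg <- c(msg, "channel labels must be unique")
  for (slotnm in c("azimuth", "elevation", "region")) {
    v <- slot(object, slotnm)
    if (!identical(names(v), object@channels))
      msg <- c(msg, sprintf("'%s' must be named exactly by channels", slotnm))
  }
  if (!all(object@region %in% .regionLevels))
    msg <- c(msg, "unknown region label")
  if (length(object@headRadius) != 1L || !is.finite(object@headRadius) ||
      object@headRadius <= 0)
    msg <- c(msg, "headRadius must be a positive scalar")
  if (length(msg)) msg else TRUE
})

#' Multichannel EEG recording
#'
#' Raw or conditioned EEG. Samples are a channels-by-time matrix in
#' microvolts; `mask` marks samples rejected as artifacts (TRUE = rejected).
#' Data values under the mask are left untouched; downstream windowing
#' drops windows dominated by masked samples.
#'
#' @slot samples numeric matrix, channels x time (microvolts); rownames are
#'   channel labels.
#' @slot rate sampling rate in Hz.
#' @slot t0 start time in seconds.
#' @slot mask logical vector, one flag per time sample.
#'
#' @seealso [resampleEEG()], [maskArtifacts()], [bandFilter()]
#' @export
setClass("EEGRecording",
  representation(
    samples = "matrix",
    rate    = "numeric",
    t0      = "numeric",
    mask    = "logical"
  )
)

setValidity("EEGRecording", function(object) {
  msg <- character()
  if (length(object@rate) != 1L || object@rate <= 0)
    msg <- c(msg, "rate must be a positive scalar")
  if (is.null(rownames(object@samples)))
    msg <- c(msg, "samples must have channel rownames")
  if (length(object@mask) != ncol(object@samples))
    msg <- c(msg, "mask length must equal the number of time samples")
  keep <- !object@mask
  if (any(keep) && !all(is.finite(object@samples[, keep, drop = FALSE])))
    msg <- c(msg, "retained (unmasked) samples must be finite")
  if (length(msg)) msg else TRUE
})

#' Gaze and pupil recording
#'
#' A 60 Hz (nominal) eye-tracking stream: gaze position in degrees of visual
#' angle, left/right pupil diameter in millimetres, and per-sample validity.
#'
#' @slot time numeric, strictly increasing timestamps (s).
#' @slot x,y numeric, gaze position (degrees of visual angle).
#' @slot pupilLeft,pupilRight numeric, pupil diameters (mm).
#' @slot valid logical, per-sample validity flag.
#'
#' @seealso [detectEvents()], [pupilChange()]
#' @export
setClass("GazeRecording",
  representation(
    time       = "numeric",
    x          = "numeric",
    y          = "numeric",
    pupilLeft  = "numeric",
    pupilRight = "numeric",
    valid      = "logical"
  )
)

setValidity("GazeRecording", function(object) {
  msg <- character()
  n <- length(object@time)
  if (any(diff(object@time) <= 0))
    msg <- c(msg, "timestamps must be strictly increasing")
  for (s in c("x", "y", "pupilLeft", "pupilRight", "valid"))
    if (length(slot(object, s)) != n)
      msg <- c(msg, sprintf("'%s' must have the same length as 'time'", s))
  v <- object@valid
  if (any(v) && (any(object@pupilLeft[v] <= 0) || any(object@pupilRight[v] <= 0)))
    msg <- c(msg, "valid pupil diameters must be positive")
  if (n >= 2) {
    r <- (n - 1) / (object@time[n] - object@time[1])
    if (r < 54 || r > 66)
      msg <- c(msg, "mean sampling rate must be within 10% of 60 Hz")
  }
  if (length(msg)) msg else TRUE
})

#' Windowed band-specific phase and power series
#'
#' Per-channel instantaneous phase at the band's centre wavelet scale
#' (sample resolution) together with per-window band power, the mean squared
#' wavelet magnitude over the band's scales within the window.
#'
#' @slot band band name (delta/theta/alpha/beta).
#' @slot phase channels x time numeric matrix of wrapped phases (radians).
#' @slot power channels x window numeric matrix of band power (uV^2).
#' @slot windowStart numeric, start time (s) of each retained window.
#' @slot window,hop window length and hop (s).
#' @slot rate sampling rate of the phase matrix (Hz).
#' @slot mask logical per-sample artifact mask aligned with `phase`.
#' @slot t0 recording start time (s).
#' @export
setClass("WindowedBandSeries",
  representation(
    band        = "character",
    phase       = "matrix",
    power       = "matrix",
    windowStart = "numeric",
    window      = "numeric",
    hop         = "numeric",
    rate        = "numeric",
    mask        = "logical",
    t0          = "numeric"
  )
)

setValidity("WindowedBandSeries", function(object) {
  msg <- character()
  ph <- object@phase[is.finite(object@phase)]
  if (length(ph) && (max(ph) > pi + 1e-9 || min(ph) <= -pi - 1e-9))
    msg <- c(msg, "phases must be wrapped into (-pi, pi]")
  if (any(object@power < 0))
    msg <- c(msg, "band powers must be non-negative")
  if (ncol(object@power) != length(object@windowStart))
    msg <- c(msg, "one power column per retained window")
  if (length(msg)) msg else TRUE
})

#' Per-window pairwise connectivity table
#'
#' One row per (window, pair): phase-locking value, circular-mean phase
#' difference, signed band-power difference (first minus second channel in
#' canonical pair order), and the strong/weak flag. A pair is marked strong
#' when its absolute power difference is below the mean absolute power
#' difference over all pairs in the same window and band.
#'
#' @slot table data.frame with columns `window_start`, `band`, `ch1`, `ch2`,
#'   `group`, `plv`, `mean_phase_diff`, `signed_power_diff`, `strong`.
#' @seealso [pairwiseConnectivity()], [groupEigenvalues()]
#' @export
setClass("ConnectivityFrame", representation(table = "data.frame"))

setValidity("ConnectivityFrame", function(object) {
  need <- c("window_start", "band", "ch1", "ch2", "group",
            "plv", "mean_phase_diff", "signed_power_diff", "strong")
  msg <- character()
  if (!all(need %in% names(object@table)))
    msg <- c(msg, paste("table must have columns:", paste(need, collapse = ", ")))
  else {
    if (any(object@table$plv < -1e-9 | object@table$plv > 1 + 1e-9))
      msg <- c(msg, "plv must lie in [0, 1]")
    mpd <- object@table$mean_phase_diff
    if (any(is.finite(mpd) & (mpd > pi + 1e-9 | mpd <= -pi - 1e-9)))
      msg <- c(msg, "mean_phase_diff must be wrapped into (-pi, pi]")
  }
  if (length(msg)) msg else TRUE
})

#' Distance-grouped connectivity eigenvalue series
#'
#' Per window, the signed "eigenvalue" of each channel-pair group: the mean
#' over the group's pairs of the signed power difference, with absolute-value
#' variants alongside. The sign encodes directionality under the montage's
#' canonical pair order (positive long-distance occipital-frontal means
#' occipital power exceeds frontal power).
#'
#' @slot table data.frame with columns `window_start`, `band`, one signed
#'   column per group (`LD_OF`, `LD_PF`, `SD`) and `abs_*` companions.
#' @slot groups character, group names present.
#' @export
setClass("EigenvalueSeries",
  representation(table = "data.frame", groups = "character"))

setValidity("EigenvalueSeries", function(object) {
  msg <- character()
  if (!all(object@groups %in% names(object@table)))
    msg <- c(msg, "every group must have a column")
  ab <- paste0("abs_", object@groups)
  if (!all(ab %in% names(object@table)))
    msg <- c(msg, "every group must have an abs_ column")
  else if (length(object@groups)) {
    d <- abs(abs(as.matrix(object@table[object@groups])) -
             as.matrix(object@table[ab]))
    if (any(d > 1e-9)) msg <- c(msg, "abs_ columns must equal |signed| columns")
  }
  if (length(msg)) msg else TRUE
})

#' K-means state labelling of an eigenvalue series
#'
#' Result of incremental k-means over chronological eigenvalue triplets:
#' per-window cluster assignment, the chosen number of states, centroids in
#' standardized feature space, per-candidate-k inertia, and the binary
#' emotional flag set by [labelEmotional()].
#'
#' @slot windowStart numeric, window start times (s).
#' @slot cluster integer cluster id per window (1..chosenK).
#' @slot emotional logical per window.
#' @slot chosenK integer, selected number of states.
#' @slot centroids numeric matrix, chosenK x features (standardized space).
#' @slot inertia named numeric, total within-cluster sum of squares per k.
#' @slot features numeric matrix, standardized feature rows used for
#'   clustering (kept for baseline-referenced state labelling).
#' @slot window,hop window length and hop (s).
#' @export
setClass("StateLabels",
  representation(
    windowStart = "numeric",
    cluster     = "integer",
    emotional   = "logical",
    chosenK     = "integer",
    centroids   = "matrix",
    inertia     = "numeric",
    features    = "matrix",
    window      = "numeric",
    hop         = "numeric"
  )
)

setValidity("StateLabels", function(object) {
  msg <- character()
  if (object@chosenK < 1L) msg <- c(msg, "chosenK must be >= 1")
  if (any(object@cluster < 1L | object@cluster > object@chosenK))
    msg <- c(msg, "cluster ids must lie in 1..chosenK")
  if (length(object@cluster) != length(object@windowStart))
    msg <- c(msg, "one cluster id per window")
  if (length(object@emotional) != length(object@windowStart))
    msg <- c(msg, "one emotional flag per window")
  if (length(object@inertia) > 1 && any(diff(object@inertia) > 1e-8))
    msg <- c(msg, "inertia must be non-increasing in k")
  if (length(msg)) msg else TRUE
})
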