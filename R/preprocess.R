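## EEG conditioning: resampling, artifact masking, band filtering, spectrum.

#' Construct an EEG recording
#'
#' @param samples channels x time numeric matrix (microvolts) with channel
#'   rownames, or a named list of equal-length channel vectors.
#' @param rate sampling rate (Hz).
#' @param t0 start time (s).
#' @param mask optional logical artifact mask (TRUE = rejected).
#' @return an [EEGRecording-class].
#' @export
eegRecording <- function(samples, rate, t0 = 0, mask = NULL) {
  if (is.list(samples))
    samples <- do.call(rbind, samples)
  if (is.null(mask)) mask <- rep(FALSE, ncol(samples))
  new("EEGRecording", samples = samples, rate = rate, t0 = t0, mask = mask)
}

#' @rdname channels
#' @export
setMethod("channels", "EEGRecording", function(x) rownames(x@samples))

#' @rdname samplingRate
#' @export
setMethod("samplingRate", "EEGRecording", function(x) x@rate)

#' @rdname nSamples
#' @export
setMethod("nSamples", "EEGRecording", function(x) ncol(x@samples))

#' @rdname artifactMask
#' @export
setMethod("artifactMask", "EEGRecording", function(x) x@mask)

#' Sample matrix of a recording
#' @param rec an [EEGRecording-class].
#' @return channels x time matrix (microvolts).
#' @export
eegSamples <- function(rec) rec@samples

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf("EEGRecording: %d channels x %d samples @ %g Hz (%.1f s), %d masked\n",
              nrow(object@samples), ncol(object@samples), object@rate,
              ncol(object@samples) / object@rate, sum(object@mask)))
})

#' Canonical EEG frequency bands
#'
#' The four classical bands restricted to 0-30 Hz: delta 0-4, theta 4-8,
#' alpha 8-12, beta 12-30 Hz.
#'
#' @param name optional band name; if omitted all four are returned.
#' @return a data.frame with columns `name`, `lo`, `hi` (Hz), or a one-row
#'   subset.
#' @export
eegBands <- function(name = NULL) {
  b <- data.frame(name = c("delta", "theta", "alpha", "beta"),
                  lo = c(0, 4, 8, 12), hi = c(4, 8, 12, 30),
                  stringsAsFactors = FALSE)
  if (is.null(name)) return(b)
  out <- b[b$name == name, ]
  if (!nrow(out)) stop("unknown band '", name, "'")
  out
}

#' Resample an EEG recording
#'
#' Rational-ratio Fourier resampling of every channel: the spectrum is
#' truncated (or zero-extended) at the new Nyquist frequency, which keeps
#' the passband gain exactly one for band-limited content; the signal is
#' reflect-padded so the method's periodicity assumption does not bleed
#' ringing into the retained span. The artifact mask is carried over by
#' logical OR across the input samples contributing to each output sample,
#' so no rejected data is silently rehabilitated. Duration is preserved to
#' within one sample period.
#'
#' @param rec an [EEGRecording-class].
#' @param targetRate new rate (Hz).
#' @return an [EEGRecording-class] at `targetRate`.
#' @export
resampleEEG <- function(rec, targetRate) {
  if (ncol(rec@samples) == 0L) stop("empty recording")
  if (targetRate <= 0) stop("targetRate must be positive")
  if (targetRate == rec@rate) return(rec)
  fr <- .ratApprox(targetRate / rec@rate)
  p <- fr[1]; q <- fr[2]
  n <- ncol(rec@samples)
  nOut <- ceiling(n * p / q)
  # paddings divisible by q so padded lengths map to integer output lengths
  padIn <- q * (min(n - 1, round(rec@rate)) %/% q)
  nUp <- q * ceiling(n / q)          # right-extend to a multiple of q
  padR <- padIn + (nUp - n)
  padOut <- padIn * p / q
  out <- t(apply(rec@samples, 1, function(x) {
    n1 <- length(x)
    xp <- c(if (padIn > 0) x[(padIn + 1):2],
            x,
            if (padR > 0) x[(n1 - 1):(n1 - padR)])
    L <- length(xp)
    M <- L * p / q
    X <- stats::fft(xp)
    half <- floor(min(L, M) / 2)
    Y <- complex(M)
    Y[seq_len(half + 1)] <- X[seq_len(half + 1)]
    if (half > 1) Y[M - (1:(half - 1)) + 1] <- X[L - (1:(half - 1)) + 1]
    (Re(stats::fft(Y, inverse = TRUE)) / L)[(padOut + 1):(padOut + nOut)]
  }))
  rownames(out) <- rownames(rec@samples)
  # OR-resample the mask: output sample j draws on inputs ((j-1)q/p, jq/p]
  mask <- vapply(seq_len(nOut), function(j) {
    lo <- max(1L, floor((j - 1) * q / p) + 1L)
    hi <- min(n, ceiling(j * q / p))
    any(rec@mask[lo:hi])
  }, logical(1))
  new("EEGRecording", samples = out, rate = targetRate, t0 = rec@t0,
      mask = mask)
}

# small-denominator rational approximation of a positive ratio
.ratApprox <- function(r, maxDen = 1000L) {
  best <- c(round(r), 1L); err <- abs(r - best[1])
  for (q in seq_len(maxDen)) {
    p <- round(r * q)
    if (p < 1) next
    e <- abs(r - p / q)
    if (e < err - 1e-15) { best <- c(p, q); err <- e }
    if (err < 1e-12) break
  }
  as.integer(best)
}

#' Mask amplitude artifacts
#'
#' Flags every sample whose absolute amplitude on any channel exceeds
#' `ampThresh`, dilates the flags by `pad` seconds on both sides, and ORs
#' them into the existing mask. Data values are untouched.
#'
#' @param rec an [EEGRecording-class].
#' @param ampThresh amplitude threshold in microvolts (default 100).
#' @param pad dilation around each flagged sample in seconds (default 0.2).
#' @return an [EEGRecording-class] with an updated mask.
#' @export
maskArtifacts <- function(rec, ampThresh = 100, pad = 0.2) {
  if (ampThresh <= 0) stop("ampThresh must be positive")
  if (pad < 0) stop("pad must be non-negative")
  hit <- apply(abs(rec@samples) > ampThresh, 2, any)
  if (any(hit) && pad > 0) {
    w <- round(pad * rec@rate)
    idx <- which(hit)
    for (i in idx) {
      lo <- max(1L, i - w); hi <- min(length(hit), i + w)
      hit[lo:hi] <- TRUE
    }
  }
  rec@mask <- rec@mask | hit
  validObject(rec)
  rec
}

# squared magnitude response of a digital Butterworth filter (bilinear
# transform, prewarped edges) in closed form; stable for arbitrarily
# narrow bands where the coefficient polynomials are ill-conditioned
.butterMag2 <- function(f, lo, hi, rate, order = 4) {
  W <- tan(pi * f / rate)
  if (lo <= 0) {
    Wc <- tan(pi * hi / rate)
    1 / (1 + (W / Wc)^(2 * order))
  } else {
    W1 <- tan(pi * lo / rate); W2 <- tan(pi * hi / rate)
    x <- (W^2 - W1 * W2) / (W * (W2 - W1))
    x[!is.finite(x)] <- Inf                       # DC and Nyquist
    1 / (1 + x^(2 * order))
  }
}

# zero-phase band-pass: the squared (forward-backward) 4th-order
# Butterworth magnitude applied on the FFT grid; reflect padding keeps
# wrap-around out of the retained span
.bandFilterVec <- function(x, lo, hi, rate, order = 4) {
  n <- length(x)
  p <- min(n - 1, 2L * round(rate))
  xp <- if (p > 0) c(x[(p + 1):2], x, x[(n - 1):(n - p)]) else x
  m <- length(xp)
  f <- pmin(seq_len(m) - 1, m - (seq_len(m) - 1)) * rate / m
  H2 <- .butterMag2(f, lo, hi, rate, order = order)^2
  y <- Re(stats::fft(stats::fft(xp) * H2, inverse = TRUE)) / m
  y[(p + 1):(p + n)]
}

#' Zero-phase band-pass filter
#'
#' Applies the squared magnitude response of a 4th-order Butterworth design
#' to every channel on the FFT grid with reflect padding — the zero-phase
#' (forward-backward) response of that filter, computed without the IIR
#' recursion. Zero phase matters because downstream pairwise phase
#' differences are the measurement; a causal filter would add
#' frequency-dependent lags. The delta band (0-4 Hz) is realized as a
#' low-pass since a 0 Hz band edge is not a realizable band-pass.
#'
#' @param rec an [EEGRecording-class].
#' @param band a band name (see [eegBands()]) or a one-row band data.frame.
#' @param order Butterworth order per pass (default 4).
#' @return a filtered [EEGRecording-class] (mask unchanged).
#' @export
bandFilter <- function(rec, band, order = 4) {
  if (is.character(band)) band <- eegBands(band)
  if (band$hi >= rec@rate / 2)
    stop("band upper edge ", band$hi, " Hz violates Nyquist at rate ",
         rec@rate, " Hz")
  out <- t(apply(rec@samples, 1, .bandFilterVec,
                 lo = band$lo, hi = band$hi, rate = rec@rate, order = order))
  rownames(out) <- rownames(rec@samples)
  new("EEGRecording", samples = out, rate = rec@rate, t0 = rec@t0,
      mask = rec@mask)
}

#' Broadband pre-filter
#'
#' Convenience 0.5-30 Hz zero-phase band-pass applied before artifact
#' masking and connectivity analysis.
#'
#' @param rec an [EEGRecording-class].
#' @return filtered recording.
#' @export
broadbandFilter <- function(rec) {
  bandFilter(rec, data.frame(name = "broad", lo = 0.5, hi = 30))
}

#' Per-channel magnitude spectrum restricted to low frequencies
#'
#' Hann-windowed one-sided FFT magnitude spectrum of the longest unmasked
#' run, truncated to `[0, fmax]` Hz.
#'
#' @param rec an [EEGRecording-class] with at least 2 s of unmasked data.
#' @param fmax upper frequency bound (default 30 Hz).
#' @return list with `freq` (Hz) and `magnitude` (channels x frequency
#'   matrix).
#' @export
eegSpectrum <- function(rec, fmax = 30) {
  runs <- rle(!rec@mask)
  if (!any(runs$values)) stop("no unmasked data")
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  ok <- which(runs$values)
  best <- ok[which.max(runs$lengths[ok])]
  idx <- starts[best]:ends[best]
  if (length(idx) < 2 * rec@rate)
    stop("need at least 2 s of contiguous unmasked data")
  n <- length(idx)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))   # Hann
  freq <- (seq_len(n) - 1) / n * rec@rate
  keep <- freq <= fmax
  mag <- t(apply(rec@samples[, idx, drop = FALSE], 1, function(x) {
    abs(stats::fft((x - mean(x)) * w))[keep] * 2 / sum(w)
  }))
  rownames(mag) <- rownames(rec@samples)
  list(freq = freq[keep], magnitude = mag)
}
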