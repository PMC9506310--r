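## Complex Morlet continuous wavelet transform and windowed phase/power.

#' Complex Morlet mother wavelet
#'
#' `psi(t) = (pi*B)^(-1/2) exp(-t^2/B) exp(2*pi*i*fc*t)` with bandwidth
#' parameter `B` (s^2) and centre frequency `fc` (Hz at unit scale).
#'
#' @param t time points (s).
#' @param bandwidth Gaussian bandwidth parameter B in s^2 (default 1.5).
#' @param fc centre frequency at unit scale (default 1 Hz, so a scale `a`
#'   analyses frequency `fc / a`).
#' @return complex vector.
#' @export
morletWavelet <- function(t, bandwidth = 1.5, fc = 1) {
  (pi * bandwidth)^(-0.5) * exp(-t^2 / bandwidth) * exp(2i * pi * fc * t)
}

#' Wavelet analysis specification for one EEG band
#'
#' Fixes the band's analysis frequencies: `nScales` log-spaced frequencies
#' spanning the band (the delta band's 0 Hz edge is floored at 1 Hz), plus
#' the band's centre frequency (delta 2, theta 6, alpha 10, beta 21 Hz)
#' whose scale supplies the instantaneous phase. With a unit-frequency
#' mother wavelet, scale `a = fc / f`.
#'
#' @param band band name or one-row band data.frame (see [eegBands()]).
#' @param bandwidth Morlet bandwidth parameter (s^2), default 1.5.
#' @param nScales number of log-spaced scales per band, default 8.
#' @return list with `band`, `centerFreq`, `freqs`, `scales`,
#'   `centerScaleIndex`, `bandwidth`, `fc`.
#' @export
waveletSpec <- function(band, bandwidth = 1.5, nScales = 8) {
  if (is.character(band)) band <- eegBands(band)
  centerFreq <- (band$lo + band$hi) / 2
  lo <- max(band$lo, 1)
  freqs <- exp(seq(log(lo), log(band$hi), length.out = nScales))
  if (!any(abs(freqs - centerFreq) < 1e-9)) {
    freqs <- sort(c(freqs, centerFreq))
  }
  fc <- 1
  list(band = band$name, centerFreq = centerFreq, freqs = freqs,
       scales = fc / freqs,
       centerScaleIndex = which.min(abs(freqs - centerFreq)),
       bandwidth = bandwidth, fc = fc)
}

#' Complex Morlet continuous wavelet transform
#'
#' Discrete evaluation of
#' `X(a, b) = |a|^(-1/2) * sum_n x(t_n) * Conj(psi((t_n - b)/a)) * dt`
#' at every shift `b` on the signal's own sample grid, for each scale `a`.
#' Computed by FFT-based linear convolution with the (conjugated,
#' time-reversed) scaled wavelet, which is exactly the Riemann sum of the
#' transform integral with the signal taken as zero outside its support;
#' the wavelet kernel is truncated where its Gaussian envelope falls below
#' 1e-12 of its peak. Linear in the signal.
#'
#' @param x numeric signal vector (finite values).
#' @param rate sampling rate (Hz).
#' @param scales positive scale factors `a` (s); frequency analysed at
#'   scale `a` is `fc / a`.
#' @param bandwidth Morlet bandwidth parameter (s^2).
#' @param fc mother-wavelet centre frequency (Hz at unit scale).
#' @return complex matrix, `length(scales)` x `length(x)`, rows named by
#'   scale.
#' @export
cwtMorlet <- function(x, rate, scales, bandwidth = 1.5, fc = 1) {
  if (!all(is.finite(x))) stop("signal must be finite")
  if (any(scales <= 0)) stop("scales must be positive")
  if (any(fc / scales > rate / 2))
    stop("scale too small: analysis frequency exceeds Nyquist (",
         rate / 2, " Hz)")
  dt <- 1 / rate
  n <- length(x)
  out <- matrix(0i, nrow = length(scales), ncol = n,
                dimnames = list(vapply(scales, format, "", digits = 8), NULL))
  for (si in seq_along(scales)) {
    a <- scales[si]
    halfw <- a * sqrt(bandwidth * log(1e12))          # envelope < 1e-12 peak
    L <- ceiling(halfw / dt)
    tk <- (-L:L) * dt
    # kernel h[k] = Conj(psi(-k*dt / a)): X(b) = (x * h)(b) (convolution)
    h <- Conj(morletWavelet(-tk / a, bandwidth = bandwidth, fc = fc))
    nf <- stats::nextn(n + length(h) - 1L, 2)
    X <- stats::fft(stats::fft(c(x, rep(0, nf - n))) *
                    stats::fft(c(h, rep(0, nf - length(h)))), inverse = TRUE) / nf
    # convolution index L+1 .. L+n aligns with sample positions 1..n
    out[si, ] <- X[(L + 1):(L + n)] * dt / sqrt(a)
  }
  out
}

#' Windowed band phase and power
#'
#' Runs the complex Morlet CWT on every channel of a band-filtered
#' recording and reduces it to the band's windowed series: instantaneous
#' phase at the band's centre scale (sample resolution, wrapped to
#' `(-pi, pi]`) and per-window band power, the mean squared wavelet
#' magnitude over the band's scales within each window. Windows with more
#' than half their samples masked are dropped.
#'
#' @param rec an [EEGRecording-class] (normally already band-filtered).
#' @param band band name or one-row band data.frame.
#' @param window window length in s (default 1).
#' @param hop hop between window starts in s (default 0.5).
#' @param spec optional [waveletSpec()] (defaults to the band's).
#' @return a [WindowedBandSeries-class]; zero retained windows raises a
#'   warning.
#' @export
phaseAndPower <- function(rec, band, window = 1, hop = 0.5, spec = NULL) {
  if (is.character(band)) band <- eegBands(band)
  if (is.null(spec)) spec <- waveletSpec(band)
  nch <- nrow(rec@samples)
  n <- ncol(rec@samples)
  phase <- matrix(NA_real_, nch, n, dimnames = list(rownames(rec@samples), NULL))
  mag2 <- vector("list", nch)
  for (ci in seq_len(nch)) {
    W <- cwtMorlet(rec@samples[ci, ], rec@rate, spec$scales,
                   bandwidth = spec$bandwidth, fc = spec$fc)
    phase[ci, ] <- Arg(W[spec$centerScaleIndex, ])
    mag2[[ci]] <- Mod(W)^2
  }
  wlen <- round(window * rec@rate)
  hlen <- round(hop * rec@rate)
  starts <- seq(1L, n - wlen + 1L, by = hlen)
  keep <- vapply(starts, function(s)
    mean(rec@mask[s:(s + wlen - 1L)]) <= 0.5, logical(1))
  starts <- starts[keep]
  if (!length(starts))
    warning("all windows masked; returning an empty series")
  power <- matrix(0, nch, length(starts),
                  dimnames = list(rownames(rec@samples), NULL))
  for (ci in seq_len(nch))
    power[ci, ] <- vapply(starts, function(s)
      mean(mag2[[ci]][, s:(s + wlen - 1L)]), numeric(1))
  new("WindowedBandSeries",
      band = band$name, phase = phase, power = power,
      windowStart = rec@t0 + (starts - 1L) / rec@rate,
      window = window, hop = hop, rate = rec@rate, mask = rec@mask,
      t0 = rec@t0)
}

#' @rdname samplingRate
#' @export
setMethod("samplingRate", "WindowedBandSeries", function(x) x@rate)

setMethod("show", "WindowedBandSeries", function(object) {
  cat(sprintf("WindowedBandSeries (%s): %d channels, %d windows (%g s / %g s hop)\n",
              object@band, nrow(object@phase), length(object@windowStart),
              object@window, object@hop))
})
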