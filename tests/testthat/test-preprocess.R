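fftAmp <- function(x, rate, f) {
  # single-bin FFT amplitude at frequency f (oracle for filter tests)
  n <- length(x)
  2 * Mod(stats::fft(x))[round(f * n / rate) + 1] / n
}

test_that("resampling preserves duration and sinusoid amplitude", {
  t <- seq(0, 10 - 1e-3, by = 1e-3)                      # 10 s at 1000 Hz
  x <- sin(2 * pi * 5 * t)
  rec <- eegRecording(rbind(ch1 = x), rate = 1000)
  out <- resampleEEG(rec, 500)
  expect_equal(samplingRate(out), 500)
  expect_equal(nSamples(out), 5000L)
  # amplitude at 5 Hz preserved within 1% (FFT oracle)
  a0 <- fftAmp(x, 1000, 5)
  a1 <- fftAmp(eegSamples(out)[1, ], 500, 5)
  expect_lt(abs(a1 - a0) / a0, 0.01)
  # identity at the native rate
  expect_identical(eegSamples(resampleEEG(rec, 1000)), eegSamples(rec))
  expect_error(resampleEEG(eegRecording(matrix(0, 1, 0,
    dimnames = list("a", NULL)), 100), 50), "empty")
})

test_that("a 500->250->500 round trip keeps a 5 Hz sinusoid within 2%", {
  t <- seq(0, 8 - 1 / 500, by = 1 / 500)
  rec <- eegRecording(rbind(ch1 = sin(2 * pi * 5 * t)), rate = 500)
  back <- resampleEEG(resampleEEG(rec, 250), 500)
  a0 <- fftAmp(eegSamples(rec)[1, ], 500, 5)
  a1 <- fftAmp(eegSamples(back)[1, seq_len(nSamples(rec))], 500, 5)
  expect_lt(abs(a1 - a0) / a0, 0.02)
})

test_that("resampling carries the artifact mask by logical OR", {
  x <- rep(0, 1000)
  mask <- rep(FALSE, 1000); mask[501:520] <- TRUE
  rec <- eegRecording(rbind(a = x), rate = 1000, mask = mask)
  out <- resampleEEG(rec, 500)
  expect_true(any(artifactMask(out)[250:262]))
  expect_false(any(artifactMask(out)[1:240]))
})

test_that("artifact masking flags spikes with exact padding", {
  rate <- 500
  x <- rep(0, 5 * rate)
  recZero <- eegRecording(rbind(a = x), rate = rate)
  expect_equal(sum(artifactMask(maskArtifacts(recZero))), 0L)
  x[1250] <- 500                                          # one 500 uV spike
  rec <- eegRecording(rbind(a = x), rate = rate)
  out <- maskArtifacts(rec, ampThresh = 100, pad = 0.1)
  # masked run of exactly 0.2 s plus the spike sample
  expect_equal(sum(artifactMask(out)), round(0.2 * rate) + 1L)
  expect_true(all(which(artifactMask(out)) == 1200:1300))
  # an unreachable threshold changes nothing
  expect_equal(artifactMask(maskArtifacts(rec, ampThresh = 1e9)),
               artifactMask(rec))
  expect_error(maskArtifacts(rec, ampThresh = -1), "positive")
})

test_that("band filtering passes in-band and rejects out-of-band tones", {
  rate <- 500
  t <- seq(0, 8 - 1 / rate, by = 1 / rate)
  x <- sin(2 * pi * 10 * t)
  rec <- eegRecording(rbind(a = x), rate = rate)
  rms <- function(v) sqrt(mean(v^2))
  inb <- eegSamples(bandFilter(rec, "alpha"))[1, ]
  out <- eegSamples(bandFilter(rec, "beta"))[1, ]
  expect_gte(rms(inb), 0.9 * rms(x))
  expect_lte(rms(out), 0.1 * rms(x))
  z <- eegSamples(bandFilter(eegRecording(rbind(a = rep(0, 1000)), rate),
                             "theta"))
  expect_equal(max(abs(z)), 0)
  expect_error(bandFilter(eegRecording(rbind(a = x), rate = 50), "beta"),
               "Nyquist")
})

test_that("band filtering is linear", {
  set.seed(4)
  rate <- 500
  x <- rnorm(2000); y <- rnorm(2000)
  f <- function(v) eegSamples(bandFilter(eegRecording(rbind(a = v), rate),
                                         "alpha"))[1, ]
  lhs <- f(2 * x + 3 * y)
  rhs <- 2 * f(x) + 3 * f(y)
  expect_lt(max(abs(lhs - rhs)) / max(abs(lhs)), 1e-8)
})

test_that("the four bands partition 0-30 Hz power within filter roll-off", {
  set.seed(11)
  rate <- 500
  x <- rnorm(20 * rate)
  rec <- eegRecording(rbind(a = x), rate = rate)
  broad <- eegSamples(bandFilter(rec, data.frame(name = "all", lo = 0,
                                                 hi = 30)))[1, ]
  tot <- mean(broad^2)
  parts <- sum(vapply(c("delta", "theta", "alpha", "beta"), function(b)
    mean(eegSamples(bandFilter(rec, b))[1, ]^2), numeric(1)))
  expect_lt(abs(parts - tot) / tot, 0.15)
})

test_that("the restricted spectrum finds tones and respects fmax", {
  rate <- 500
  t <- seq(0, 4 - 1 / rate, by = 1 / rate)
  rec <- eegRecording(rbind(a = sin(2 * pi * 10 * t)), rate = rate)
  sp <- eegSpectrum(rec)
  expect_true(all(sp$freq <= 30))
  expect_equal(sp$freq[which.max(sp$magnitude[1, ])], 10, tolerance = 0.3)
  short <- eegRecording(rbind(a = rnorm(100)), rate = rate)
  expect_error(eegSpectrum(short), "2 s")
})

test_that("half-split spectra of the same noise correlate positively", {
  set.seed(21)
  rate <- 250
  x <- as.numeric(stats::filter(rnorm(20 * rate), rep(1, 5), sides = 1))
  x[is.na(x)] <- 0
  s1 <- eegSpectrum(eegRecording(rbind(a = x[1:(10 * rate)]), rate))
  s2 <- eegSpectrum(eegRecording(rbind(a = x[(10 * rate + 1):(20 * rate)]),
                                 rate))
  expect_gt(cor(s1$magnitude[1, ], s2$magnitude[1, ]), 0)
})
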