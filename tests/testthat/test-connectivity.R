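# brute-force transform oracle: direct Riemann sum of the CWT integral
directCWT <- function(x, rate, a, b) {
  tt <- (seq_along(x) - 1) / rate
  sum(x * Conj(morletWavelet((tt - b) / a))) / rate / sqrt(a)
}

test_that("the fast transform equals the direct integral evaluation", {
  set.seed(2)
  rate <- 500
  t <- (0:1999) / rate
  x <- sin(2 * pi * 10 * t) + 0.2 * rnorm(2000)
  scales <- c(0.04, 0.1, 0.25)
  W <- cwtMorlet(x, rate, scales)
  for (k in 1:20) {
    si <- sample(3, 1)
    bi <- sample(2000, 1)
    fast <- W[si, bi]
    direct <- directCWT(x, rate, scales[si], t[bi])
    expect_lt(Mod(fast - direct) / Mod(direct), 1e-6)
  }
})

test_that("transform linearity, impulse response and error paths hold", {
  rate <- 500
  z <- cwtMorlet(rep(0, 600), rate, 0.1)
  expect_equal(max(Mod(z)), 0)
  # sifting: unit impulse picks out the conjugated wavelet
  x <- rep(0, 600); i0 <- 300; x[i0] <- 1
  W <- cwtMorlet(x, rate, 0.1)
  b <- (seq_len(600) - 1) / rate
  t0 <- (i0 - 1) / rate
  expected <- Conj(morletWavelet((t0 - b) / 0.1)) / rate / sqrt(0.1)
  expect_lt(max(Mod(W[1, ] - expected)), 1e-10)
  expect_error(cwtMorlet(rnorm(100), rate, 1 / 300), "Nyquist")
  expect_error(cwtMorlet(c(1, NA, 3), rate, 0.1), "finite")
})

test_that("instantaneous phase advances at the analysed frequency", {
  rate <- 500
  t <- seq(0, 6 - 1 / rate, by = 1 / rate)
  f0 <- 10
  rec <- eegRecording(rbind(a = sin(2 * pi * f0 * t)), rate = rate)
  ser <- phaseAndPower(rec, "alpha")
  ph <- ser@phase[1, ]
  interior <- 500:2500
  unwrapped <- cumsum(c(ph[interior[1]],
                        emoconn:::.wrapPhase(diff(ph[interior]))))
  slope <- stats::coef(stats::lm(unwrapped ~ t[interior]))[2]
  expect_lt(abs(slope - 2 * pi * f0) / (2 * pi * f0), 0.01)
})

test_that("band power scales quadratically and vanishes for silence", {
  rate <- 500
  set.seed(8)
  x <- rnorm(4 * rate)
  p1 <- phaseAndPower(eegRecording(rbind(a = x), rate), "beta")@power
  p2 <- phaseAndPower(eegRecording(rbind(a = 2 * x), rate), "beta")@power
  expect_equal(as.vector(p2), as.vector(4 * p1), tolerance = 1e-6)
  p0 <- phaseAndPower(eegRecording(rbind(a = rep(0, 4 * rate)), rate),
                      "beta")@power
  expect_equal(max(p0), 0)
})

test_that("windows dominated by masked samples are dropped", {
  rate <- 500
  mask <- rep(FALSE, 4 * rate); mask[1:rate] <- TRUE
  rec <- eegRecording(rbind(a = rnorm(4 * rate)), rate, mask = mask)
  ser <- phaseAndPower(rec, "alpha")
  expect_true(all(ser@windowStart >= 0.5))
})

test_that("a duplicated channel shows perfect self-coherence", {
  rate <- 500
  set.seed(3)
  x <- rnorm(4 * rate)
  rec <- twoChannelRec(x, x, rate)
  ser <- phaseAndPower(bandFilter(rec, "beta"), "beta")
  tab <- connTable(pairwiseConnectivity(
    ser, data.frame(ch1 = "A", ch2 = "B", group = "X")))
  expect_equal(tab$plv, rep(1, nrow(tab)))
  expect_equal(tab$mean_phase_diff, rep(0, nrow(tab)))
  expect_equal(tab$signed_power_diff, rep(0, nrow(tab)))
})

test_that("an imposed quarter-pi lag between sinusoids is recovered", {
  rate <- 500
  t <- seq(0, 6 - 1 / rate, by = 1 / rate)
  f0 <- 21
  lag <- pi / 4
  rec <- twoChannelRec(sin(2 * pi * f0 * t),
                       sin(2 * pi * f0 * t - lag), rate)
  tab <- connTable(pairwiseConnectivity(
    phaseAndPower(rec, "beta"),
    data.frame(ch1 = "A", ch2 = "B", group = "X")))
  expect_true(all(tab$plv > 0.99))
  expect_lt(max(abs(tab$mean_phase_diff - lag)), 0.02)
})

test_that("reversing pair order negates signed quantities only", {
  rate <- 500
  set.seed(9)
  rec <- twoChannelRec(rnorm(3 * rate), rnorm(3 * rate), rate)
  ser <- phaseAndPower(bandFilter(rec, "alpha"), "alpha")
  fwd <- connTable(pairwiseConnectivity(
    ser, data.frame(ch1 = "A", ch2 = "B", group = "X")))
  rev <- connTable(pairwiseConnectivity(
    ser, data.frame(ch1 = "B", ch2 = "A", group = "X")))
  expect_equal(rev$signed_power_diff, -fwd$signed_power_diff)
  expect_equal(rev$mean_phase_diff,
               emoconn:::.wrapPhase(-fwd$mean_phase_diff))
  expect_equal(rev$plv, fwd$plv)
  expect_equal(rev$strong, fwd$strong)
})

test_that("the full montage yields 153 pair records per window", {
  cfg <- sessionConfig(duration = 6, seed = 12)
  g <- generateEEG(cfg)
  ser <- phaseAndPower(bandFilter(g$rec, "beta"), "beta")
  tab <- connTable(pairwiseConnectivity(ser, classifyPairs(buildMontage())))
  perWindow <- table(tab$window_start)
  expect_true(all(perWindow == 153))
  # strong/weak rule: below the window mean of absolute differences
  w0 <- tab[tab$window_start == tab$window_start[1], ]
  expect_equal(w0$strong,
               abs(w0$signed_power_diff) < mean(abs(w0$signed_power_diff)))
  expect_true(all(tab$plv >= 0 & tab$plv <= 1))
})

test_that("phase locking of independent phases falls with sample count", {
  # circular-mean property behind the windowed estimator
  set.seed(14)
  plvOf <- function(n) Mod(mean(exp(1i * runif(n, -pi, pi))))
  short <- replicate(50, plvOf(100))
  long <- replicate(50, plvOf(1000))
  expect_gt(median(short), median(long))
})

test_that("group eigenvalues are group means with fixed sign convention", {
  # toy frame, hand-computed expectations
  tab <- data.frame(
    window_start = rep(c(0, 0.5), each = 3),
    band = "beta",
    ch1 = rep(c("O1", "O2", "Fp1"), 2),
    ch2 = rep(c("F3", "F4", "T3"), 2),
    group = rep(c("LD_OF", "LD_OF", "LD_PF"), 2),
    plv = 0.5, mean_phase_diff = 0,
    signed_power_diff = c(2, 4, 1, -2, -4, -1),
    strong = FALSE)
  fr <- new("ConnectivityFrame", table = tab)
  ev <- connTable(groupEigenvalues(fr, groups = c("LD_OF", "LD_PF")))
  expect_equal(ev$LD_OF, c(3, -3))          # mean of (2,4) then (-2,-4)
  expect_equal(ev$LD_PF, c(1, -1))
  expect_equal(ev$abs_LD_OF, c(3, 3))       # |mean| variant
  # antisymmetry: negating differences flips eigenvalue signs only
  tab2 <- tab; tab2$signed_power_diff <- -tab2$signed_power_diff
  ev2 <- connTable(groupEigenvalues(new("ConnectivityFrame", table = tab2),
                                    groups = c("LD_OF", "LD_PF")))
  expect_equal(ev2$LD_OF, -ev$LD_OF)
  expect_equal(ev2$abs_LD_OF, ev$abs_LD_OF)
  expect_error(groupEigenvalues(fr, groups = "SD"), "no pairs")
})

test_that("occipital power excess drives a positive LD_OF eigenvalue", {
  cfg <- sessionConfig(duration = 8, seed = 31,
    stateSchedule = data.frame(start = 0, end = 8, state = "emotional"))
  g <- generateEEG(cfg, regionGains = c(occipital = 1.6))
  ser <- phaseAndPower(bandFilter(g$rec, "beta"), "beta")
  ev <- connTable(groupEigenvalues(
    pairwiseConnectivity(ser, classifyPairs(buildMontage()))))
  expect_gt(mean(ev$LD_OF), 0)
})
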