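# shared fixtures built in code

# two-channel recording holding arbitrary signals under montage-free labels
twoChannelRec <- function(a, b, rate = 500) {
  eegRecording(rbind(A = a, B = b), rate = rate)
}

# planted two-state eigenvalue triplet series (windows x 3), alternating
# schedule, all-axis separation `sep` (in units of within-cluster sd)
plantedStateSeries <- function(n = 94, sep = 6, sd = 1, seed = 1,
                               hop = 0.5) {
  set.seed(seed)
  truth <- rep(c(0L, 1L), length.out = n)
  X <- matrix(stats::rnorm(n * 3, sd = sd), n, 3) +
    outer(truth, rep(sep * sd, 3))
  attr(X, "windowStart") <- (seq_len(n) - 1) * hop
  list(X = X, truth = truth)
}

# best window-level agreement over the two possible label matchings
labelAgreement <- function(cluster, truth) {
  a <- mean((cluster == cluster[1]) == (truth == truth[1]))
  max(a, 1 - a)
}

# deterministic stationary-gaze recording (no jitter)
stillGaze <- function(duration = 5, rate = 60, pupil = 3.5) {
  t <- seq(0, duration - 1 / rate, by = 1 / rate)
  gazeRecording(t, rep(0, length(t)), rep(0, length(t)),
                rep(pupil, length(t)), rep(pupil, length(t)))
}
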