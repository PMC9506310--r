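test_that("sessions are deterministic given the seed", {
  cfg <- sessionConfig(duration = 4, seed = 99)
  a <- generateEEG(cfg); b <- generateEEG(cfg)
  expect_identical(eegSamples(a$rec), eegSamples(b$rec))
  ga <- generateGaze(cfg); gb <- generateGaze(cfg)
  expect_identical(ga$rec@x, gb$rec@x)
  expect_identical(ga$rec@pupilLeft, gb$rec@pupilLeft)
})

test_that("configs validate their schedules", {
  expect_error(sessionConfig(condition = "nope"), "condition")
  expect_error(sessionConfig(duration = 10,
    stateSchedule = data.frame(start = 0, end = 7, state = "emotional")),
    "tile")
  expect_error(sessionConfig(duration = 10,
    gazeEvents = data.frame(time = c(2, 2.05), amplitude = 5)), "overlap")
  expect_error(generateEEG(sessionConfig(duration = 2),
    couplingSpec(list(pair = c("O1", "QQ7"), band = "beta"))),
    "QQ7")
  expect_error(couplingSpec(list(pair = c("O1", "F3"), strength = 2)),
               "strength")
})

test_that("uncoupled channels show only residual phase locking", {
  # independence baseline at long (10 s) windows
  plvs <- c()
  pairs <- classifyPairs(buildMontage())
  for (s in 1:3) {
    cfg <- sessionConfig(duration = 30, seed = 200 + s)
    g <- generateEEG(cfg)                      # no coupling anywhere
    ser <- phaseAndPower(bandFilter(g$rec, "beta"), "beta",
                         window = 10, hop = 10)
    plvs <- c(plvs, connTable(pairwiseConnectivity(ser, pairs))$plv)
  }
  expect_lt(median(plvs), 0.3)
})

test_that("a fully coupled pair reproduces its planted phase lag", {
  cfg <- sessionConfig(duration = 20, seed = 42,
    stateSchedule = data.frame(start = 0, end = 20, state = "emotional"))
  g <- generateEEG(cfg, couplingSpec(
    list(pair = c("O1", "F3"), band = "beta", phaseLag = pi / 4,
         strength = 1, states = "all")))
  ser <- phaseAndPower(bandFilter(g$rec, "beta"), "beta")
  tab <- connTable(pairwiseConnectivity(
    ser, data.frame(ch1 = "O1", ch2 = "F3", group = "LD_OF")))
  recovered <- Arg(mean(exp(1i * tab$mean_phase_diff)))
  expect_lt(abs(recovered - pi / 4), 0.05)
  expect_gt(mean(tab$plv), 0.7)
})

test_that("a planted occipital-frontal power ratio yields positive LD_OF", {
  pairs <- classifyPairs(buildMontage())
  hits <- 0
  for (s in 1:20) {
    cfg <- sessionConfig(duration = 10, seed = 300 + s,
      stateSchedule = data.frame(start = 0, end = 10, state = "emotional"))
    g <- generateEEG(cfg, couplingSpec(
      list(group = "LD_OF", band = "beta", strength = 0.6,
           powerRatio = 2, states = "all")))
    ser <- phaseAndPower(bandFilter(g$rec, "beta"), "beta")
    ev <- connTable(groupEigenvalues(pairwiseConnectivity(ser, pairs)))
    hits <- hits + (mean(ev$LD_OF) > 0)
  }
  expect_gte(hits / 20, 0.95)
})

test_that("planted schedules drive recoverable session states", {
  # a strongly lateralized emotional half must separate the eigenvalues
  # cleanly enough for the state machinery to segment the session
  pairs <- classifyPairs(buildMontage())
  cfg <- sessionConfig(duration = 24, seed = 77)
  g <- generateEEG(cfg, regionGains = c(prefrontal = 2.0, occipital = 1.8,
                                        central = 1.4, parietal = 1.4,
                                        frontal = 0.7, temporal = 0.7))
  ser <- phaseAndPower(bandFilter(g$rec, "beta"), "beta")
  evs <- groupEigenvalues(pairwiseConnectivity(ser, pairs))
  lab <- labelEmotional(incrementalKmeans(evs, kMax = 6, seed = 17))
  truth <- trueStates(cfg, connTable(evs)$window_start) == "emotional"
  expect_equal(chosenK(lab), 2L)
  expect_gte(mean(emotionalFlag(lab) == truth), 0.9)
})

test_that("coupling planted in LD_OF pairs surfaces as its group's locking", {
  # phase coupling at high strength in exactly the LD_OF pairs must give
  # that group the highest mean phase-locking value of the three
  pairs <- classifyPairs(buildMontage())
  wins <- 0
  for (s in 1:20) {
    cfg <- sessionConfig(duration = 8, seed = 600 + s,
      stateSchedule = data.frame(start = 0, end = 8, state = "emotional"))
    g <- generateEEG(cfg, couplingSpec(
      list(group = "LD_OF", band = "beta", strength = 0.9, states = "all")))
    tab <- connTable(pairwiseConnectivity(
      phaseAndPower(bandFilter(g$rec, "beta"), "beta"), pairs))
    mplv <- tapply(tab$plv, tab$group, mean)
    wins <- wins + (names(which.max(mplv[c("LD_OF", "LD_PF", "SD")])) ==
                    "LD_OF")
  }
  expect_gte(wins / 20, 0.95)
})

test_that("an empty event schedule is one session-long fixation", {
  cfg <- sessionConfig(duration = 6, seed = 5,
    gazeEvents = data.frame(time = numeric(), amplitude = numeric()))
  ev <- detectEvents(generateGaze(cfg)$rec)
  expect_equal(sum(ev$kind == "saccade"), 0L)
  expect_equal(sum(ev$kind == "fixation"), 1L)
})

test_that("study bundles have the full design shape and reproduce", {
  b <- generateStudy(5, seed = 9)
  expect_equal(nrow(b$scores), 20L)
  expect_equal(sort(unique(b$scores$condition)), sort(studyConditions()))
  expect_length(b$configs, 5L)
  expect_length(b$configs[[1]], 4L)
  b2 <- generateStudy(5, seed = 9)
  expect_identical(b$scores, b2$scores)
  expect_identical(b$configs[[3]][[2]]$seed, b2$configs[[3]][[2]]$seed)
  expect_error(generateStudy(1), "at least 2")
  # the reference study size scales without sessions being realized
  big <- generateStudy(47, seed = 1)
  expect_equal(nrow(big$scores), 47L * 4L)
})

test_that("null profiles do not manufacture spurious score effects", {
  # integration sanity at study scale; the calibrated type-I check over
  # many families lives with the acceptance suite
  rejects <- 0
  for (r in 1:30) {
    b <- generateStudy(24, profile = nullProfile(), seed = 500 + r)
    th <- tukeyHsd(split(b$scores$arousal, b$scores$condition))
    rejects <- rejects + any(th$reject)
  }
  expect_lte(rejects / 30, 0.2)
})
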