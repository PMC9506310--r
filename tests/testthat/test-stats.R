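test_that("the F statistic matches hand-computed sums of squares", {
  g <- list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(10, 11, 12))
  # oracle: manual between/within decomposition
  y <- unlist(g)
  gm <- mean(y)
  ssb <- sum(vapply(g, function(v) length(v) * (mean(v) - gm)^2, 1))
  ssw <- sum(vapply(g, function(v) sum((v - mean(v))^2), 1))
  Fo <- (ssb / 2) / (ssw / 6)
  fit <- oneWayAnova(g)
  expect_equal(fit$F, Fo, tolerance = 1e-10)
  expect_equal(unname(fit$df), c(2, 6))
  expect_lt(fit$p, 0.001)
})

test_that("degenerate and permuted inputs behave as contracts say", {
  expect_warning(z <- oneWayAnova(list(a = c(5, 5), b = c(5, 5))),
                 "zero variance")
  expect_equal(c(z$F, z$p), c(0, 1))
  set.seed(1)
  g <- list(a = rnorm(10), b = rnorm(10), c = rnorm(10))
  gp <- lapply(g, sample)
  expect_equal(oneWayAnova(g)$F, oneWayAnova(gp)$F, tolerance = 1e-12)
  expect_error(oneWayAnova(list(a = 1, b = c(1, 2))), "at least 2")
})

test_that("with two groups F equals the squared pooled-t statistic", {
  set.seed(2)
  a <- rnorm(12, 1); b <- rnorm(15)
  tt <- stats::t.test(a, b, var.equal = TRUE)$statistic
  expect_equal(oneWayAnova(list(a = a, b = b))$F, unname(tt^2),
               tolerance = 1e-10)
})

test_that("Tukey HSD emits six oriented rows for four groups", {
  set.seed(3)
  g <- stats::setNames(lapply(c(2, 0, 3, 1), function(m) rnorm(20, m)),
                       studyConditions())
  th <- tukeyHsd(g)
  expect_equal(nrow(th), 6L)
  expect_true(all(th$lower <= th$mean_difference))
  expect_true(all(th$mean_difference <= th$upper))
  # orientation: difference is mean(condition_2) - mean(condition_1)
  r <- th[th$condition_1 == studyConditions()[1] &
          th$condition_2 == studyConditions()[2], ]
  expect_equal(r$mean_difference,
               mean(g[[2]]) - mean(g[[1]]), tolerance = 1e-12)
  # reject flag mirrors the interval excluding zero
  expect_equal(th$reject, th$lower > 0 | th$upper < 0)
  expect_equal(attr(th, "per_test_alpha"), 0.0125)
  # identical groups give a null row
  same <- tukeyHsd(list(a = c(1, 2, 3, 2), b = c(1, 2, 3, 2)))
  expect_equal(same$mean_difference, 0)
  expect_false(same$reject)
})

test_that("planted offsets are rejected and intervals cover the truth", {
  off <- c(2, 0, 3, 1)
  hit <- 0; total <- 0; covered <- 0
  for (r in 1:30) {
    set.seed(100 + r)
    g <- stats::setNames(lapply(off, function(m) rnorm(48, m, 1)),
                         paste0("c", 1:4))
    th <- tukeyHsd(g)
    truth <- apply(utils::combn(off, 2), 2, function(p) p[2] - p[1])
    covered <- covered + sum(th$lower <= truth & truth <= th$upper)
    total <- total + length(truth)
    # the widely separated pairs must reject (|true diff| >= 2)
    hit <- hit + all(th$reject[abs(truth) >= 2])
  }
  expect_gte(covered / total, 0.93)
  expect_equal(hit, 30)
})

test_that("rejections are monotone in the family alpha", {
  set.seed(5)
  g <- stats::setNames(lapply(c(0, 0.5, 1, 1.5), function(m) rnorm(25, m)),
                       paste0("c", 1:4))
  r01 <- tukeyHsd(g, familyAlpha = 0.01)$reject
  r05 <- tukeyHsd(g, familyAlpha = 0.05)$reject
  expect_true(all(!r01 | r05))      # rejections at 0.01 subset of 0.05
})

test_that("reversing the group order negates differences only", {
  set.seed(6)
  g <- list(a = rnorm(10, 1), b = rnorm(10))
  f <- tukeyHsd(g); r <- tukeyHsd(rev(g))
  expect_equal(r$mean_difference, -f$mean_difference, tolerance = 1e-12)
  expect_equal(r$lower, -f$upper, tolerance = 1e-12)
  expect_equal(r$reject, f$reject)
})

test_that("the per-test alpha is the family alpha over the test count", {
  expect_identical(adjustedAlpha(0.05, 4), 0.0125)
  expect_identical(adjustedAlpha(0.3, 1), 0.3)
  expect_identical(adjustedAlpha(0.05, 5), 0.01)
  expect_error(adjustedAlpha(0.05, 0), "nTests")
  expect_error(adjustedAlpha(1.2, 4), "familyAlpha")
})

test_that("profile concordance reproduces the rank correlation", {
  conds <- studyConditions()
  eig <- matrix(c(1, 2, 3, 4), 1, dimnames = list("LD_OF", conds))
  same <- matrix(c(10, 20, 30, 40), 1, dimnames = list("saccade", conds))
  expect_equal(compareProfiles(eig, same)$rho, 1)
  revd <- matrix(c(4, 3, 2, 1), 1, dimnames = list("saccade", conds))
  expect_equal(compareProfiles(eig, revd)$rho, -1)
  # oracle: direct Spearman formula on 4 untied points
  swap <- matrix(c(1, 3, 2, 4), 1, dimnames = list("saccade", conds))
  d <- rank(c(1, 2, 3, 4)) - rank(c(1, 3, 2, 4))
  rhoOracle <- 1 - 6 * sum(d^2) / (4 * (16 - 1))
  expect_equal(compareProfiles(eig, swap)$rho, rhoOracle)
  expect_equal(rhoOracle, 0.8)
  bad <- matrix(1:3, 1, dimnames = list("x", conds[1:3]))
  expect_error(compareProfiles(eig, bad), "missing")
})
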