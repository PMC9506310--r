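## One-way ANOVA, Tukey HSD tables, adjusted alpha, profile concordance.

.asGroupList <- function(groups) {
  if (is.data.frame(groups))
    groups <- split(groups$value, groups$group)
  if (!is.list(groups) || length(groups) < 2)
    stop("need at least two groups")
  ns <- vapply(groups, length, integer(1))
  if (any(ns < 2))
    stop("every group needs at least 2 observations; got sizes ",
         paste(ns, collapse = ", "))
  groups
}

#' One-way ANOVA
#'
#' Standard between/within sums-of-squares decomposition via [stats::aov()].
#' When every observation is identical (zero total variance) the F
#' statistic is undefined; it is reported as `F = 0`, `p = 1` with a
#' warning.
#'
#' @param groups a named list of numeric vectors (one per group), or a
#'   data.frame with columns `value` and `group`.
#' @return list with `F`, `p`, `df` (c(between, within)), `ss`
#'   (c(between, within)).
#' @export
oneWayAnova <- function(groups) {
  groups <- .asGroupList(groups)
  y <- unlist(groups, use.names = FALSE)
  f <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  dfb <- nlevels(f) - 1L
  dfw <- length(y) - nlevels(f)
  if (stats::var(y) < .Machine$double.eps * max(1, mean(y)^2)) {
    warning("zero variance in every group; reporting F = 0, p = 1")
    return(list(F = 0, p = 1, df = c(between = dfb, within = dfw),
                ss = c(between = 0, within = 0)))
  }
  fit <- stats::aov(y ~ f)
  tab <- summary(fit)[[1]]
  list(F = tab[["F value"]][1], p = tab[["Pr(>F)"]][1],
       df = c(between = tab[["Df"]][1], within = tab[["Df"]][2]),
       ss = c(between = tab[["Sum Sq"]][1], within = tab[["Sum Sq"]][2]))
}

#' Tukey HSD pairwise comparisons
#'
#' All pairwise mean differences with studentized-range family-wise
#' confidence intervals (via [stats::TukeyHSD()] on a one-way fit). Rows
#' are oriented so `mean_difference = mean(condition_2) - mean(condition_1)`
#' with conditions in their given (factor) order; four groups yield six
#' rows. The reject flag is TRUE when the interval excludes zero at the
#' family alpha. The Bonferroni-style per-test alpha
#' ([adjustedAlpha()]) is reported alongside as an attribute, not applied
#' on top of the Tukey correction.
#'
#' @param groups named list of numeric vectors or `value`/`group`
#'   data.frame.
#' @param familyAlpha family-wise error rate (default 0.05).
#' @param nTests number of ANOVA tests in the family for the reported
#'   per-test alpha (default 4, the 2x2 design's score tests).
#' @return data.frame with columns `condition_1`, `condition_2`,
#'   `mean_difference`, `lower`, `upper`, `reject`; attributes
#'   `family_alpha` and `per_test_alpha`.
#' @export
tukeyHsd <- function(groups, familyAlpha = 0.05, nTests = 4) {
  groups <- .asGroupList(groups)
  nms <- names(groups)
  if (is.null(nms)) nms <- paste0("group", seq_along(groups))
  y <- unlist(groups, use.names = FALSE)
  f <- factor(rep(nms, vapply(groups, length, integer(1))), levels = nms)
  if (stats::var(y) < .Machine$double.eps * max(1, mean(y)^2)) {
    cmb <- utils::combn(nms, 2)
    out <- data.frame(condition_1 = cmb[1, ], condition_2 = cmb[2, ],
                      mean_difference = 0, lower = 0, upper = 0,
                      reject = FALSE, stringsAsFactors = FALSE)
  } else {
    hsd <- stats::TukeyHSD(stats::aov(y ~ f), conf.level = 1 - familyAlpha)$f
    # TukeyHSD row order equals combn(levels, 2) order, reported as
    # "later minus earlier"; pair positionally (condition names may
    # themselves contain hyphens)
    cmb <- utils::combn(nms, 2)
    out <- data.frame(
      condition_1 = cmb[1, ],
      condition_2 = cmb[2, ],
      mean_difference = hsd[, "diff"],
      lower = hsd[, "lwr"], upper = hsd[, "upr"],
      reject = hsd[, "lwr"] > 0 | hsd[, "upr"] < 0,
      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "family_alpha") <- familyAlpha
  attr(out, "per_test_alpha") <- adjustedAlpha(familyAlpha, nTests)
  out
}

#' Bonferroni-adjusted per-test alpha
#'
#' `familyAlpha / nTests`; with the four score ANOVAs of the 2x2 design,
#' 0.05 / 4 = 0.0125.
#'
#' @param familyAlpha family-wise error rate in (0, 1).
#' @param nTests number of tests, >= 1.
#' @return per-test alpha.
#' @examples adjustedAlpha(0.05, 4)   # 0.0125
#' @export
adjustedAlpha <- function(familyAlpha, nTests) {
  if (length(familyAlpha) != 1 || familyAlpha <= 0 || familyAlpha >= 1)
    stop("familyAlpha must lie in (0, 1)")
  if (length(nTests) != 1 || nTests < 1)
    stop("nTests must be >= 1")
  familyAlpha / nTests
}

#' Rank concordance between eigenvalue and eye-feature condition profiles
#'
#' Spearman rank correlation across the four condition means for every
#' (eigenvalue feature, eye feature) combination. Purely descriptive: with
#' four points per profile no inference is attempted, and ties are handled
#' by midranks (reported in the `ties` column).
#'
#' @param eigMeans matrix or data.frame, eigenvalue features x conditions.
#' @param eyeMeans matrix or data.frame, eye features x conditions (same
#'   condition columns).
#' @return data.frame with columns `eig_feature`, `eye_feature`, `rho`,
#'   `ties`.
#' @export
compareProfiles <- function(eigMeans, eyeMeans) {
  eig <- as.matrix(eigMeans); eye <- as.matrix(eyeMeans)
  if (is.null(colnames(eig)) || is.null(colnames(eye)))
    stop("both inputs need condition column names")
  miss <- union(setdiff(colnames(eig), colnames(eye)),
                setdiff(colnames(eye), colnames(eig)))
  if (length(miss))
    stop("condition(s) missing from one input: ", paste(miss, collapse = ", "))
  eye <- eye[, colnames(eig), drop = FALSE]
  out <- expand.grid(eig_feature = rownames(eig), eye_feature = rownames(eye),
                     stringsAsFactors = FALSE)
  out$rho <- mapply(function(i, j)
    stats::cor(eig[i, ], eye[j, ], method = "spearman"),
    out$eig_feature, out$eye_feature)
  out$ties <- mapply(function(i, j)
    anyDuplicated(eig[i, ]) > 0 || anyDuplicated(eye[j, ]) > 0,
    out$eig_feature, out$eye_feature)
  out
}
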