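## Incremental k-means state segmentation of the eigenvalue series.

#' Incremental k-means over a chronological eigenvalue series
#'
#' Z-scores each eigenvalue column (groups differ in pair count and
#' magnitude), then runs k-means for k = 1..`kMax`. Each k >= 2 takes the
#' best of `nstart` random starts and a warm start seeded with the previous
#' solution's centroids plus the point worst-fit by them, which guarantees
#' inertia is non-increasing in k (the "incremental" part). The number of
#' states is chosen by an elbow rule: the first k whose relative inertia
#' improvement over k-1 falls below `relTol` marks the stall, and the
#' preceding k is chosen; a zero-variance series yields one state.
#' Deterministic given `seed`.
#'
#' @param series an [EigenvalueSeries-class], or a windows x features
#'   numeric matrix with a `windowStart` attribute (optional).
#' @param kMax largest candidate number of states (default 6).
#' @param seed RNG seed (required for reproducibility).
#' @param relTol elbow threshold on the relative inertia improvement
#'   (default 0.5; see the methods vignette for the calibration).
#' @param nstart random restarts per k (default 10).
#' @param window,hop window geometry (s), taken from the series when given.
#' @return a [StateLabels-class] (emotional flags all FALSE until
#'   [labelEmotional()]).
#' @export
incrementalKmeans <- function(series, kMax = 6, seed, relTol = 0.5,
                              nstart = 10, window = 1, hop = 0.5) {
  if (is(series, "EigenvalueSeries")) {
    X <- eigenvalueMatrix(series)
    ws <- series@table$window_start
  } else {
    if (is.data.frame(series)) {
      ws <- series$window_start
      series <- series[vapply(series, is.numeric, logical(1))]
      series$window_start <- NULL
    } else ws <- attr(series, "windowStart")
    X <- as.matrix(series)
    if (is.null(ws)) ws <- (seq_len(nrow(X)) - 1) * hop
  }
  n <- nrow(X)
  if (kMax < 1) stop("kMax must be >= 1")
  if (n < kMax) stop("need at least kMax (", kMax, ") windows, got ", n)
  set.seed(seed)
  sdev <- apply(X, 2, stats::sd)
  sdev[sdev == 0 | !is.finite(sdev)] <- 1
  Z <- scale(X, center = TRUE, scale = sdev)
  attr(Z, "scaled:center") <- NULL; attr(Z, "scaled:scale") <- NULL

  inertia <- numeric(0)
  inertia[1] <- sum(sweep(Z, 2, colMeans(Z))^2)
  assign1 <- rep(1L, n)
  cents <- list(matrix(colMeans(Z), 1))
  labels <- list(assign1)
  if (inertia[1] < 1e-12 * max(1, sum(Z^2))) {
    km <- 1L
  } else {
    kEff <- min(kMax, nrow(unique(Z)))
    for (k in 2:kEff) {
      fit <- stats::kmeans(Z, centers = k, nstart = nstart, iter.max = 50)
      # warm start: previous centroids + the worst-fit point
      prev <- cents[[k - 1]]
      d2 <- rowSums((Z - prev[labels[[k - 1]], , drop = FALSE])^2)
      warm0 <- rbind(prev, Z[which.max(d2), ])
      warm <- tryCatch(
        stats::kmeans(Z, centers = warm0, iter.max = 50),
        error = function(e) NULL)
      if (!is.null(warm) && warm$tot.withinss < fit$tot.withinss) fit <- warm
      inertia[k] <- min(fit$tot.withinss, inertia[k - 1])
      cents[[k]] <- fit$centers
      labels[[k]] <- fit$cluster
    }
    if (kEff < kMax) inertia[(kEff + 1):kMax] <- inertia[kEff]
    imp <- -diff(inertia[1:kEff]) / pmax(inertia[1:(kEff - 1)], 1e-300)
    stall <- which(imp < relTol)
    km <- if (length(stall)) as.integer(stall[1]) else as.integer(kEff)
  }
  names(inertia) <- paste0("k", seq_along(inertia))
  if (length(ws) >= 2) hop <- ws[2] - ws[1]
  new("StateLabels",
      windowStart = as.numeric(ws),
      cluster = as.integer(labels[[km]]),
      emotional = rep(FALSE, n),
      chosenK = km,
      centroids = as.matrix(cents[[km]]),
      inertia = inertia,
      features = Z[, , drop = FALSE],
      window = window, hop = hop)
}

#' @rdname chosenK
#' @export
setMethod("chosenK", "StateLabels", function(x) x@chosenK)

#' @rdname emotionalFlag
#' @export
setMethod("emotionalFlag", "StateLabels", function(x) x@emotional)

#' Cluster assignment per window
#' @param x a [StateLabels-class].
#' @return integer vector of cluster ids.
#' @export
stateClusters <- function(x) x@cluster

setMethod("show", "StateLabels", function(object) {
  cat(sprintf("StateLabels: %d windows, chosen k = %d, %d emotional\n",
              length(object@cluster), object@chosenK, sum(object@emotional)))
})

#' Flag the emotional cluster
#'
#' With two states, the cluster whose centroid is farther (Euclidean, in
#' the standardized eigenvalue space) from the mean of the first
#' `baselineWindows` windows is flagged emotional; sessions start
#' pre-stimulus, so the early windows anchor the non-emotional state. With
#' any other number of states, every window is flagged non-emotional and a
#' warning is raised.
#'
#' @param labels a [StateLabels-class] from [incrementalKmeans()].
#' @param baselineWindows number of initial windows forming the baseline
#'   (default 10); must be fewer than the total.
#' @return the [StateLabels-class] with the `emotional` slot filled.
#' @export
labelEmotional <- function(labels, baselineWindows = 10) {
  n <- length(labels@cluster)
  if (baselineWindows >= n)
    stop("baselineWindows (", baselineWindows,
         ") must be smaller than the number of windows (", n, ")")
  if (labels@chosenK != 2L) {
    warning("chosen k is ", labels@chosenK,
            "; flagging all windows non-emotional")
    labels@emotional <- rep(FALSE, n)
    return(labels)
  }
  base <- colMeans(labels@features[seq_len(baselineWindows), , drop = FALSE])
  d <- sqrt(rowSums(sweep(labels@centroids, 2, base)^2))
  emoCluster <- which.max(d)
  labels@emotional <- labels@cluster == emoCluster
  labels
}

#' Run-length state segments
#'
#' Collapses per-window emotional flags into maximal constant-flag
#' segments tiling the session chronologically. Each window is taken to
#' own `[start, start + hop)`; the final segment is closed at the last
#' window's start plus the window length.
#'
#' @param labels a [StateLabels-class].
#' @return data.frame with columns `start_s`, `end_s`, `emotional`.
#' @export
stateSegments <- function(labels) {
  ws <- labels@windowStart
  fl <- labels@emotional
  r <- rle(fl)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  segEnd <- c(ws[starts[-1]], ws[length(ws)] + labels@window)
  data.frame(start_s = ws[starts], end_s = segEnd, emotional = r$values)
}
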