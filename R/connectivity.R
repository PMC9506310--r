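## Pairwise phase/power connectivity and distance-grouped eigenvalues.

.wrapPhase <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y <= -pi] <- pi           # wrap to (-pi, pi]
  y
}

#' Pairwise band connectivity over windows
#'
#' For each retained window and each channel pair (in the montage's
#' canonical order), computes from the windowed band series:
#' \describe{
#'   \item{plv}{phase-locking value, the modulus of the circular mean of
#'     the per-sample phase differences `wrap(phi_first - phi_second)`
#'     over the window's unmasked samples; 1 = perfect locking.}
#'   \item{mean_phase_diff}{the argument of that circular mean, in
#'     `(-pi, pi]`.}
#'   \item{signed_power_diff}{band power of the first channel minus the
#'     second (uV^2); the sign is the directionality convention.}
#'   \item{strong}{TRUE when `|signed_power_diff|` is below the mean of
#'     `|signed_power_diff|` over all pairs in the same window and band
#'     (power differences lower than the mean mark relatively strong
#'     connectivity).}
#' }
#'
#' @param series a [WindowedBandSeries-class].
#' @param pairs a pair table from [classifyPairs()] (columns `ch1`, `ch2`,
#'   `group`), or any subset of it.
#' @return a [ConnectivityFrame-class] with one row per window x pair.
#' @export
pairwiseConnectivity <- function(series, pairs) {
  chs <- rownames(series@phase)
  miss <- setdiff(unique(c(pairs$ch1, pairs$ch2)), chs)
  if (length(miss))
    stop("pair channels absent from the series: ", paste(miss, collapse = ", "))
  nW <- length(series@windowStart)
  nP <- nrow(pairs)
  wlen <- round(series@window * series@rate)
  startIdx <- round((series@windowStart - series@t0) * series@rate) + 1L
  i1 <- match(pairs$ch1, chs); i2 <- match(pairs$ch2, chs)

  plv <- mpd <- spd <- matrix(NA_real_, nW, nP)
  for (w in seq_len(nW)) {
    idx <- startIdx[w]:(startIdx[w] + wlen - 1L)
    idx <- idx[!series@mask[idx]]
    ph <- series@phase[, idx, drop = FALSE]
    for (p in seq_len(nP)) {
      z <- mean(exp(1i * (ph[i1[p], ] - ph[i2[p], ])))
      plv[w, p] <- Mod(z)
      mpd[w, p] <- .wrapPhase(Arg(z))
      spd[w, p] <- series@power[i1[p], w] - series@power[i2[p], w]
    }
  }
  strong <- t(apply(spd, 1, function(row) abs(row) < mean(abs(row))))
  tab <- data.frame(
    window_start = rep(series@windowStart, nP),
    band = series@band,
    ch1 = rep(pairs$ch1, each = nW),
    ch2 = rep(pairs$ch2, each = nW),
    group = rep(pairs$group, each = nW),
    plv = as.vector(plv),
    mean_phase_diff = as.vector(mpd),
    signed_power_diff = as.vector(spd),
    strong = as.vector(strong),
    stringsAsFactors = FALSE)
  tab <- tab[order(tab$window_start), , drop = FALSE]
  rownames(tab) <- NULL
  new("ConnectivityFrame", table = tab)
}

#' @rdname connTable
#' @export
setMethod("connTable", "ConnectivityFrame", function(x) x@table)

setMethod("show", "ConnectivityFrame", function(object) {
  t <- object@table
  cat(sprintf("ConnectivityFrame: %d pairs x %d windows (band %s)\n",
              length(unique(paste(t$ch1, t$ch2))),
              length(unique(t$window_start)), unique(t$band)[1]))
})

#' Distance-grouped connectivity eigenvalues
#'
#' Reduces a connectivity frame to one scalar per pair group per window:
#' the mean over the group's pairs of the signed power difference (the
#' group "eigenvalue", uV^2). The sign encodes directionality under the
#' canonical pair order (e.g. positive LD_OF: occipital power exceeds
#' frontal). Absolute-value variants (`abs_*`) are emitted alongside.
#'
#' @param frame a [ConnectivityFrame-class].
#' @param groups group names to summarize (default the three distance
#'   groups LD_OF, LD_PF, SD).
#' @return an [EigenvalueSeries-class].
#' @export
groupEigenvalues <- function(frame, groups = c("LD_OF", "LD_PF", "SD")) {
  tab <- frame@table
  for (g in groups)
    if (!any(tab$group == g))
      stop("group '", g, "' has no pairs in the connectivity frame")
  ws <- sort(unique(tab$window_start))
  out <- data.frame(window_start = ws, band = tab$band[1],
                    stringsAsFactors = FALSE)
  for (g in groups) {
    sub <- tab[tab$group == g, ]
    e <- tapply(sub$signed_power_diff, factor(sub$window_start, levels = ws),
                mean)
    out[[g]] <- as.numeric(e)
    out[[paste0("abs_", g)]] <- abs(as.numeric(e))
  }
  new("EigenvalueSeries", table = out, groups = groups)
}

#' @rdname connTable
#' @export
setMethod("connTable", "EigenvalueSeries", function(x) x@table)

setMethod("show", "EigenvalueSeries", function(object) {
  cat(sprintf("EigenvalueSeries: %d windows, groups %s\n",
              nrow(object@table), paste(object@groups, collapse = ", ")))
})

#' Eigenvalue feature matrix
#'
#' The windows x groups numeric matrix of signed eigenvalues, the feature
#' space clustered by [incrementalKmeans()].
#'
#' @param series an [EigenvalueSeries-class].
#' @return numeric matrix with one column per group.
#' @export
eigenvalueMatrix <- function(series) {
  m <- as.matrix(series@table[series@groups])
  rownames(m) <- NULL
  m
}
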