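## 18-channel 10-20 montage: geometry, distances, pair groups.

# Idealized 10-20 placement. The outer ring (Fp1/2, F7/8, T3/4, T5/6, O1/2)
# sits on the equator; Cz at the vertex; midline/central electrodes at 45 deg
# elevation. F3/F4, C3/C4 and P3/P4 are great-circle arc midpoints of
# (Fz,F7), (Cz,T3), (Pz,T5) and mirrors, matching how the 10-20 system
# places them between midline and ring. Fz/Pz are construction points only;
# Pz is a channel here, Fz is not (18-channel cap).
.montage1020_18 <- function(headRadius = 9.2) {
  deg <- pi / 180
  # construction table: label, azimuth (deg from nasion, +right), elevation
  base <- rbind(
    Fp1 = c(-18, 0), Fp2 = c(18, 0),
    F7  = c(-54, 0), F8  = c(54, 0),
    T3  = c(-90, 0), T4  = c(90, 0),
    T5  = c(-126, 0), T6 = c(126, 0),
    O1  = c(-162, 0), O2 = c(162, 0),
    Cz  = c(0, 90),
    Pz  = c(180, 45)
  )
  fz <- c(0, 45)
  xyz <- function(a, e) c(cos(e * deg) * sin(a * deg),   # x: right
                          cos(e * deg) * cos(a * deg),   # y: front
                          sin(e * deg))                  # z: up
  mid <- function(p, q) {        # great-circle arc midpoint on the unit sphere
    m <- (p + q) / sqrt(sum((p + q)^2))
    c(atan2(m[1], m[2]) / deg, asin(m[3]) / deg)
  }
  derived <- rbind(
    F3 = mid(xyz(fz[1], fz[2]), xyz(base["F7", 1], base["F7", 2])),
    F4 = mid(xyz(fz[1], fz[2]), xyz(base["F8", 1], base["F8", 2])),
    C3 = mid(xyz(base["Cz", 1], base["Cz", 2]), xyz(base["T3", 1], base["T3", 2])),
    C4 = mid(xyz(base["Cz", 1], base["Cz", 2]), xyz(base["T4", 1], base["T4", 2])),
    P3 = mid(xyz(base["Pz", 1], base["Pz", 2]), xyz(base["T5", 1], base["T5", 2])),
    P4 = mid(xyz(base["Pz", 1], base["Pz", 2]), xyz(base["T6", 1], base["T6", 2]))
  )
  pos <- rbind(base, derived)
  region <- c(
    Fp1 = "prefrontal", Fp2 = "prefrontal",
    F7 = "frontal", F3 = "frontal", F4 = "frontal", F8 = "frontal",
    T3 = "temporal", T4 = "temporal", T5 = "temporal", T6 = "temporal",
    C3 = "central", Cz = "central", C4 = "central",
    P3 = "parietal", Pz = "parietal", P4 = "parietal",
    O1 = "occipital", O2 = "occipital"
  )
  ord <- names(region)                       # montage order
  new("Montage",
      channels   = ord,
      azimuth    = stats::setNames(pos[ord, 1] * deg, ord),
      elevation  = stats::setNames(pos[ord, 2] * deg, ord),
      region     = region,
      headRadius = headRadius)
}

.coordinateSets <- list("1020-18" = .montage1020_18)

#' Build a built-in scalp montage
#'
#' Constructs the 18-channel 10-20 montage used throughout the pipeline:
#' the standard 19-electrode 10-20 set minus Fz, on a spherical head of
#' radius 9.2 cm. This yields `choose(18, 2) = 153` unordered channel pairs.
#'
#' @param coordinateSet name of a registered coordinate set; currently
#'   `"1020-18"`.
#' @param headRadius sphere radius in cm (default 9.2, a conventional adult
#'   head).
#' @return a [Montage-class].
#' @examples
#' m <- buildMontage()
#' length(channels(m))            # 18
#' nrow(classifyPairs(m))         # 153
#' @export
buildMontage <- function(coordinateSet = "1020-18", headRadius = 9.2) {
  fn <- .coordinateSets[[coordinateSet]]
  if (is.null(fn))
    stop("unknown coordinate set '", coordinateSet, "'; registered: ",
         paste(names(.coordinateSets), collapse = ", "))
  fn(headRadius = headRadius)
}

#' @describeIn buildMontage read a montage from a plain-text table with
#'   columns `channel`, `azimuth_deg`, `elevation_deg`, `region`.
#' @param path file path of a montage table (TSV or CSV).
#' @export
readMontage <- function(path, headRadius = 9.2) {
  df <- utils::read.table(path, header = TRUE, sep = "",
                          stringsAsFactors = FALSE)
  need <- c("channel", "azimuth_deg", "elevation_deg", "region")
  if (!all(need %in% names(df)))
    stop("montage table must have columns: ", paste(need, collapse = ", "))
  ch <- df$channel
  new("Montage",
      channels = ch,
      azimuth = stats::setNames(df$azimuth_deg * pi / 180, ch),
      elevation = stats::setNames(df$elevation_deg * pi / 180, ch),
      region = stats::setNames(df$region, ch),
      headRadius = headRadius)
}

#' Write a montage as a plain-text table
#' @param m a [Montage-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeMontage <- function(m, path) {
  df <- data.frame(channel = m@channels,
                   azimuth_deg = round(m@azimuth / pi * 180, 6),
                   elevation_deg = round(m@elevation / pi * 180, 6),
                   region = unname(m@region))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname channels
#' @export
setMethod("channels", "Montage", function(x) x@channels)

#' Region assignment of montage channels
#' @param m a [Montage-class].
#' @return named character vector, region per channel.
#' @export
channelRegions <- function(m) m@region

setMethod("show", "Montage", function(object) {
  cat("Montage:", length(object@channels), "channels on a",
      object@headRadius, "cm sphere\n")
  tab <- table(factor(object@region, levels = .regionLevels))
  cat(paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
})

.checkChannel <- function(m, ch) {
  bad <- setdiff(ch, m@channels)
  if (length(bad))
    stop("unknown channel(s): ", paste(bad, collapse = ", "))
}

#' Geodesic scalp distance between two electrodes
#'
#' Great-circle distance on the montage's spherical head model:
#' `headRadius` times the central angle between the two electrode positions
#' (spherical law of cosines). Symmetric in its channel arguments.
#'
#' @param m a [Montage-class].
#' @param a,b distinct channel labels.
#' @return distance in cm.
#' @examples
#' m <- buildMontage()
#' pairDistance(m, "C3", "Cz")
#' @export
pairDistance <- function(m, a, b) {
  .checkChannel(m, c(a, b))
  if (identical(a, b)) stop("channels must be distinct")
  e1 <- m@elevation[a]; e2 <- m@elevation[b]
  da <- m@azimuth[a] - m@azimuth[b]
  cosc <- sin(e1) * sin(e2) + cos(e1) * cos(e2) * cos(da)
  unname(m@headRadius * acos(pmin(1, pmax(-1, cosc))))
}

# region precedence for canonical pair ordering (fixes the eigenvalue sign):
# higher-precedence region is listed first within a pair
.regionPrecedence <- c(occipital = 1, prefrontal = 2, frontal = 3,
                       temporal = 4, central = 5, parietal = 6)

.sdAdjacent <- list(c("frontal", "temporal"), c("frontal", "central"),
                    c("temporal", "parietal"), c("parietal", "central"))

#' Classify all channel pairs into distance groups
#'
#' Enumerates every unordered channel pair of the montage in canonical
#' order and assigns each to exactly one connectivity group:
#' \describe{
#'   \item{LD_OF}{long distance, occipital to frontal or prefrontal.}
#'   \item{LD_PF}{long distance, prefrontal to temporal, central or
#'     parietal.}
#'   \item{SD}{short distance: adjacent-region pairs (frontal-temporal,
#'     frontal-central, temporal-parietal, parietal-central) closer than
#'     `sdThreshold` cm on the scalp.}
#'   \item{OTHER}{everything else.}
#' }
#' Canonical order puts the channel of the higher-precedence region first
#' (occipital > prefrontal > frontal > temporal > central > parietal);
#' within a region, montage order decides.
#'
#' @param m a [Montage-class].
#' @param sdThreshold short-distance cutoff in cm (default 10).
#' @return data.frame with columns `ch1`, `ch2`, `group`, `distance_cm`;
#'   one row per unordered pair (153 rows for the 18-channel montage).
#' @examples
#' pg <- classifyPairs(buildMontage())
#' table(pg$group)
#' @export
classifyPairs <- function(m, sdThreshold = 10) {
  ch <- m@channels
  idx <- utils::combn(seq_along(ch), 2)
  a <- ch[idx[1, ]]; b <- ch[idx[2, ]]
  ra <- m@region[a]; rb <- m@region[b]
  # canonical ordering
  swap <- .regionPrecedence[rb] < .regionPrecedence[ra] |
    (ra == rb & match(b, ch) < match(a, ch))
  ch1 <- ifelse(swap, b, a); ch2 <- ifelse(swap, a, b)
  r1 <- m@region[ch1]; r2 <- m@region[ch2]
  d <- mapply(pairDistance, a = ch1, b = ch2, MoreArgs = list(m = m))
  grp <- rep("OTHER", length(ch1))
  grp[r1 == "occipital" & r2 %in% c("frontal", "prefrontal")] <- "LD_OF"
  grp[r1 == "prefrontal" & r2 %in% c("temporal", "central", "parietal")] <- "LD_PF"
  adjKey <- vapply(.sdAdjacent, function(p) paste(sort(p), collapse = "|"), "")
  pairKey <- paste(pmin(r1, r2), pmax(r1, r2), sep = "|")
  sd <- grp == "OTHER" & pairKey %in% adjKey & d < sdThreshold
  grp[sd] <- "SD"
  data.frame(ch1 = unname(ch1), ch2 = unname(ch2), group = grp,
             distance_cm = unname(d), stringsAsFactors = FALSE)
}
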