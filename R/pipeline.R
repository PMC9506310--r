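## Umbrella pipeline: preprocess -> connectivity -> states -> eye features
## -> statistics, with manifested, checksummed outputs.

#' Pipeline run configuration
#'
#' Central record of every tunable the pipeline uses; all defaults in one
#' place so a run is reproducible from its manifest.
#'
#' @param studyDir directory written by [generateStudy()] (contains
#'   `manifest.json`, `scores.csv`, per-participant session files).
#' @param outDir output directory.
#' @param band analysis band for connectivity (default "beta").
#' @param window,hop connectivity window geometry (s).
#' @param kMax largest candidate state count (default 6).
#' @param relTol elbow threshold (default 0.5).
#' @param velThresh,minFix I-VT detector thresholds (deg/s, s).
#' @param ampThresh,pad artifact mask parameters (uV, s).
#' @param alpha family-wise alpha (default 0.05).
#' @param baselineWindows state-baseline window count (default 10).
#' @param seed run seed (clustering restarts).
#' @return a `RunConfig` list.
#' @export
runConfig <- function(studyDir, outDir, band = "beta", window = 1,
                      hop = 0.5, kMax = 6, relTol = 0.5, velThresh = 30,
                      minFix = 0.1, ampThresh = 100, pad = 0.2,
                      alpha = 0.05, baselineWindows = 10, seed = 17) {
  structure(list(studyDir = studyDir, outDir = outDir, band = band,
                 window = window, hop = hop, kMax = kMax, relTol = relTol,
                 velThresh = velThresh, minFix = minFix,
                 ampThresh = ampThresh, pad = pad, alpha = alpha,
                 baselineWindows = baselineWindows, seed = seed),
            class = "RunConfig")
}

#' Read a run configuration from JSON
#' @param path JSON file with any subset of [runConfig()] fields
#'   (`studyDir` and `outDir` required).
#' @return a `RunConfig`.
#' @export
readRunConfig <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(runConfig, j)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline halted at stage '", name, "': ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline on a simulated study
#'
#' Executes, per participant and condition: preprocessing (artifact mask,
#' band filter), complex-Morlet connectivity, grouped eigenvalues,
#' incremental k-means state segmentation, and state-conditioned eye
#' features; then participant-level aggregation, one-way ANOVA and Tukey
#' HSD on the subjective scores, and an eigenvalue-versus-eye-feature
#' rank-concordance table. Every output is CSV/TSV plus a JSON manifest
#' recording inputs, parameters, seed and md5 checksums. Idempotent: a
#' rerun with the same config produces byte-identical outputs.
#'
#' @param cfg a [runConfig()].
#' @param montage a [Montage-class].
#' @return the manifest list, invisibly.
#' @export
runPipeline <- function(cfg, montage = buildMontage()) {
  sm <- file.path(cfg$studyDir, "manifest.json")
  if (!file.exists(sm)) stop("no study manifest at ", sm)
  study <- jsonlite::read_json(sm, simplifyVector = TRUE)
  dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
  pairs <- classifyPairs(montage)
  scores <- .stage("load", {
    s <- data.table::fread(file.path(cfg$studyDir, "scores.csv"))
    as.data.frame(s)
  })

  eig <- list(); states <- list(); eye <- list()
  for (p in study$participants) for (cond in study$conditions) {
    sdir <- file.path(cfg$studyDir, p, cond)
    rec <- .stage("preprocess", {
      r <- readEEGcsv(file.path(sdir, "eeg.csv"), montage = montage)
      maskArtifacts(r, ampThresh = cfg$ampThresh, pad = cfg$pad)
    })
    series <- .stage("connectivity",
      phaseAndPower(bandFilter(rec, cfg$band), cfg$band,
                    window = cfg$window, hop = cfg$hop))
    frame <- .stage("connectivity", pairwiseConnectivity(series, pairs))
    ev <- .stage("connectivity", groupEigenvalues(frame))
    et <- connTable(ev)
    et <- cbind(participant = p, condition = cond, et)
    eig[[paste(p, cond)]] <- et
    lab <- .stage("states", {
      l <- incrementalKmeans(ev, kMax = cfg$kMax, seed = cfg$seed,
                             relTol = cfg$relTol, window = cfg$window)
      suppressWarnings(labelEmotional(l, cfg$baselineWindows))
    })
    states[[paste(p, cond)]] <- data.frame(
      participant = p, condition = cond,
      window_start = lab@windowStart, cluster = lab@cluster,
      emotional = lab@emotional, chosen_k = lab@chosenK)
    eye[[paste(p, cond)]] <- .stage("eyetrack", {
      gpath <- file.path(sdir, "gaze.csv")
      if (!file.exists(gpath)) stop("missing gaze file: ", gpath)
      g <- readGazeCsv(gpath)
      evts <- detectEvents(g, velThresh = cfg$velThresh,
                           minFix = cfg$minFix)
      cbind(participant = p,
            aggregateByState(evts, g, lab, condition = cond))
    })
  }
  eigAll <- do.call(rbind, c(eig, make.row.names = FALSE))
  stAll <- do.call(rbind, c(states, make.row.names = FALSE))
  eyeAll <- do.call(rbind, c(eye, make.row.names = FALSE))

  rep_ <- .stage("stats_report", {
    aro <- tukeyHsd(split(scores$arousal, scores$condition),
                    familyAlpha = cfg$alpha)
    val <- tukeyHsd(split(scores$valence, scores$condition),
                    familyAlpha = cfg$alpha)
    # participant-level eigenvalue means per condition
    agg <- stats::aggregate(eigAll[c("LD_OF", "LD_PF", "SD")],
                            by = eigAll[c("participant", "condition")],
                            FUN = mean)
    eigMeans <- t(as.matrix(stats::aggregate(
      agg[c("LD_OF", "LD_PF", "SD")], by = agg["condition"],
      FUN = mean)[, -1]))
    colnames(eigMeans) <- sort(unique(agg$condition))
    eyeAgg <- stats::aggregate(
      eyeAll[c("mean_fix_duration", "saccade_rate",
               "pupil_change_left", "pupil_change_right")],
      by = eyeAll["condition"], FUN = function(x) mean(x, na.rm = TRUE))
    eyeMeans <- t(as.matrix(eyeAgg[, -1]))
    colnames(eyeMeans) <- eyeAgg$condition
    list(arousal = aro, valence = val,
         concordance = compareProfiles(eigMeans, eyeMeans),
         eigMeans = eigMeans)
  })

  out <- function(f) file.path(cfg$outDir, f)
  .writeTable(eigAll, out("eigenvalues.csv"))
  .writeTable(stAll, out("states.csv"))
  .writeTable(eyeAll, out("eye_features.csv"))
  .writeTable(rep_$arousal, out("tukey_arousal.csv"))
  .writeTable(rep_$valence, out("tukey_valence.csv"))
  .writeTable(rep_$concordance, out("concordance.csv"))
  segs <- stAll[c("participant", "condition", "window_start", "emotional")]
  .writeTable(segs, out("state_windows.tsv"))

  files <- c("eigenvalues.csv", "states.csv", "eye_features.csv",
             "tukey_arousal.csv", "tukey_valence.csv", "concordance.csv",
             "state_windows.tsv")
  .stage("validate", {
    for (f in files) {
      if (!file.exists(out(f))) stop("missing output ", f)
      hd <- names(data.table::fread(out(f), nrows = 0))
      if (!length(hd)) stop("empty output ", f)
    }
  })
  manifest <- list(
    study_dir = cfg$studyDir,
    parameters = unclass(cfg)[order(names(unclass(cfg)))],
    per_test_alpha = adjustedAlpha(cfg$alpha, 4),
    outputs = as.list(stats::setNames(
      unname(tools::md5sum(vapply(files, out, ""))), files)))
  jsonlite::write_json(manifest, out("run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
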