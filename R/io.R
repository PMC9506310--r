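## Readers and writers: EEG long-form CSV, minimal 16-bit EDF, gaze CSV,
## result tables. All numeric output is formatted explicitly so repeated
## runs are byte-identical.

#' Write an EEG recording as long-format CSV
#'
#' Columns `time`, `channel`, `value_uV`; one row per sample per channel.
#' Values are written with 6 significant digits.
#'
#' @param rec an [EEGRecording-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeEEGcsv <- function(rec, path) {
  n <- ncol(rec@samples)
  ch <- rownames(rec@samples)
  dt <- data.table::data.table(
    time = rep(rec@t0 + (seq_len(n) - 1) / rec@rate, each = length(ch)),
    channel = rep(ch, n),
    value_uV = as.vector(rec@samples))
  dt[, `:=`(time = sprintf("%.6f", time),
            value_uV = sprintf("%.6g", value_uV))]
  data.table::fwrite(dt, path)
  invisible(path)
}

#' Read EEG from long-format CSV
#'
#' Expects columns `time`, `channel`, `value_uV`. Channel labels are
#' matched case-insensitively against the montage when one is given;
#' unknown labels are an error naming the offenders.
#'
#' @param path CSV path.
#' @param montage optional [Montage-class] to validate/normalize labels.
#' @return an [EEGRecording-class].
#' @export
readEEGcsv <- function(path, montage = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- data.table::fread(path)
  need <- c("time", "channel", "value_uV")
  if (!all(need %in% names(dt)))
    stop("EEG CSV must have columns: ", paste(need, collapse = ", "))
  ch <- unique(dt$channel)
  if (!is.null(montage)) {
    m <- match(tolower(ch), tolower(channels(montage)))
    if (anyNA(m))
      stop("unknown channel(s) in ", path, ": ",
           paste(ch[is.na(m)], collapse = ", "))
    lut <- stats::setNames(channels(montage)[m], ch)
    dt[, channel := lut[channel]]
    ch <- channels(montage)[sort(m)]
  }
  times <- sort(unique(dt$time))
  rate <- round(1 / stats::median(diff(times)), 6)
  wide <- data.table::dcast(dt, channel ~ time, value.var = "value_uV")
  mat <- as.matrix(wide, rownames = "channel")
  mat <- mat[match(ch, rownames(mat)), , drop = FALSE]
  mat <- mat[, order(as.numeric(colnames(mat))), drop = FALSE]
  colnames(mat) <- NULL
  eegRecording(mat, rate = rate, t0 = times[1])
}

## ---- minimal EDF (European Data Format, 16-bit) ----------------------

.edfPad <- function(s, w) {
  s <- substr(s, 1, w)
  paste0(s, strrep(" ", w - nchar(s)))
}

#' Write an EEG recording as a 16-bit EDF file
#'
#' Minimal EDF writer: one data record per second, common sampling rate,
#' physical range set per channel from the data. Sub-second remainders
#' are truncated to whole records, as EDF requires.
#'
#' @param rec an [EEGRecording-class] with an integer sampling rate.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeEDF <- function(rec, path) {
  ns <- nrow(rec@samples)
  spr <- round(rec@rate)                      # samples per 1 s record
  nrec <- floor(ncol(rec@samples) / spr)
  if (nrec < 1) stop("recording shorter than one EDF record (1 s)")
  ch <- rownames(rec@samples)
  pmin_ <- pmax_ <- numeric(ns)
  dig <- matrix(0L, ns, nrec * spr)
  for (i in seq_len(ns)) {
    x <- rec@samples[i, seq_len(nrec * spr)]
    r <- range(x); pad <- max(diff(r), 1e-6) * 0.01
    pmin_[i] <- r[1] - pad; pmax_[i] <- r[2] + pad
    dig[i, ] <- as.integer(round((x - pmin_[i]) / (pmax_[i] - pmin_[i]) *
                                 65535 - 32768))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edfPad("0", 8), .edfPad("synthetic", 80), .edfPad("synthetic", 80),
    .edfPad("01.01.00", 8), .edfPad("00.00.00", 8),
    .edfPad(as.character(256 * (ns + 1)), 8), .edfPad("", 44),
    .edfPad(as.character(nrec), 8), .edfPad("1", 8),
    .edfPad(as.character(ns), 4))
  writeChar(hdr, con, eos = NULL)
  fld <- function(vals, w) writeChar(paste0(vapply(vals, .edfPad, "", w = w),
                                            collapse = ""), con, eos = NULL)
  fld(ch, 16)
  fld(rep("", ns), 80)                         # transducer
  fld(rep("uV", ns), 8)
  fld(sprintf("%.6g", pmin_), 8)
  fld(sprintf("%.6g", pmax_), 8)
  fld(rep("-32768", ns), 8)
  fld(rep("32767", ns), 8)
  fld(rep("", ns), 80)                         # prefiltering
  fld(rep(as.character(spr), ns), 8)
  fld(rep("", ns), 32)                         # reserved
  for (r in seq_len(nrec)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    for (i in seq_len(ns))
      writeBin(dig[i, idx], con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read a 16-bit EDF file
#'
#' Minimal reader for continuous EDF with a common sampling rate across
#' signals.
#'
#' @param path EDF path.
#' @param montage optional [Montage-class] for label validation (matched
#'   case-insensitively).
#' @return an [EEGRecording-class].
#' @export
readEDF <- function(path, montage = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  ver <- rd(8)
  if (ver != "0") stop("corrupt EDF: bad version field '", ver, "'")
  rd(80); rd(80); rd(8); rd(8)
  hdrBytes <- as.integer(rd(8)); rd(44)
  nrec <- as.integer(rd(8)); recDur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (anyNA(c(hdrBytes, nrec, recDur, ns))) stop("corrupt EDF header")
  lab <- vapply(seq_len(ns), function(i) rd(16), "")
  vapply(seq_len(ns), function(i) rd(80), "")
  vapply(seq_len(ns), function(i) rd(8), "")
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  vapply(seq_len(ns), function(i) rd(80), "")
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  vapply(seq_len(ns), function(i) rd(32), "")
  if (length(unique(spr)) != 1)
    stop("mixed per-signal rates not supported")
  mat <- matrix(0, ns, nrec * spr[1], dimnames = list(lab, NULL))
  for (r in seq_len(nrec)) for (i in seq_len(ns)) {
    d <- readBin(con, integer(), n = spr[i], size = 2, endian = "little")
    mat[i, ((r - 1) * spr[i] + 1):(r * spr[i])] <-
      (d - dmin[i]) / (dmax[i] - dmin[i]) * (pmax_[i] - pmin_[i]) + pmin_[i]
  }
  if (!is.null(montage)) {
    m <- match(tolower(lab), tolower(channels(montage)))
    if (anyNA(m))
      stop("unknown channel(s) in ", path, ": ",
           paste(lab[is.na(m)], collapse = ", "))
    rownames(mat) <- channels(montage)[m]
  }
  eegRecording(mat, rate = spr[1] / recDur, t0 = 0)
}

## ---- gaze and tabular results ---------------------------------------

#' Write/read gaze CSV
#'
#' Columns `timestamp`, `x`, `y`, `pupil_l`, `pupil_r`, `valid`.
#'
#' @param rec a [GazeRecording-class].
#' @param path file path.
#' @return `path` (writer) / a [GazeRecording-class] (reader).
#' @export
writeGazeCsv <- function(rec, path) {
  dt <- data.table::data.table(
    timestamp = sprintf("%.6f", rec@time),
    x = sprintf("%.5f", rec@x), y = sprintf("%.5f", rec@y),
    pupil_l = sprintf("%.5f", rec@pupilLeft),
    pupil_r = sprintf("%.5f", rec@pupilRight),
    valid = as.integer(rec@valid))
  data.table::fwrite(dt, path)
  invisible(path)
}

#' @rdname writeGazeCsv
#' @export
readGazeCsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- data.table::fread(path)
  need <- c("timestamp", "x", "y", "pupil_l", "pupil_r", "valid")
  if (!all(need %in% names(dt)))
    stop("gaze CSV must have columns: ", paste(need, collapse = ", "))
  gazeRecording(dt$timestamp, dt$x, dt$y, dt$pupil_l, dt$pupil_r,
                as.logical(dt$valid))
}

# deterministic table writer (fixed digits, no row names)
.writeTable <- function(df, path, digits = 6) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf(paste0("%.", digits, "g"), x))
  data.table::fwrite(df, path)
  invisible(path)
}

#' Write the subjective-score table
#' @param scores data.frame from [generateStudy()].
#' @param path output path.
#' @export
writeStudyCsv <- function(scores, path) .writeTable(scores, path)
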