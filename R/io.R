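#' @include AllClasses.R
NULL

## ---- CSV dialect ----

#' Read / write recordings (CSV and EDF dialects)
#'
#' `writeRecording()` serialises an [EEGRecording-class] to disk and
#' `readRecording()` restores it. Two dialects are supported:
#'
#' * `"csv"`: a plain text file with `#`-prefixed metadata header lines
#'   (sampling rate, subject, group, condition, trial), a channel-label
#'   row, then one row per sample. Values are written with 17 significant
#'   digits, so the round trip is exact.
#' * `"edf"`: European Data Format, 16-bit; one data record per second.
#'   Subject/group and condition/trial are stored in the patient and
#'   recording identification fields. The round trip is exact up to the
#'   16-bit amplitude quantisation, and the recording must span a whole
#'   number of seconds.
#'
#' @param recording an [EEGRecording-class].
#' @param path file path.
#' @param dialect `"csv"` or `"edf"`; `readRecording()` infers it from the
#'   file extension when omitted.
#' @return `readRecording()` returns an [EEGRecording-class];
#'   `writeRecording()` returns `path` invisibly.
#' @examples
#' rec <- EEGRecording(matrix(rnorm(2 * 512), 2), fs = 256)
#' f <- tempfile(fileext = ".csv")
#' writeRecording(rec, f)
#' rec2 <- readRecording(f)
#' @name recording-io
NULL

#' @rdname recording-io
#' @export
writeRecording <- function(recording, path, dialect = c("csv", "edf")) {
  stopifnot(is(recording, "EEGRecording"))
  dialect <- match.arg(dialect)
  if (dialect == "csv") .writeRecordingCSV(recording, path)
  else .writeRecordingEDF(recording, path)
  invisible(path)
}

#' @rdname recording-io
#' @export
readRecording <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(dialect))
    dialect <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf"
               else "csv"
  dialect <- match.arg(dialect, c("csv", "edf"))
  if (dialect == "csv") .readRecordingCSV(path) else .readRecordingEDF(path)
}

.writeRecordingCSV <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# eegdeficits recording",
    sprintf("# fs: %.10g", rec@fs),
    sprintf("# subject_id: %s", rec@subjectId),
    sprintf("# group: %s", rec@group),
    sprintf("# condition: %s", rec@condition),
    sprintf("# trial: %d", rec@trial),
    paste(rec@channelLabels, collapse = ",")), con)
  m <- t(rec@data)
  lines <- apply(m, 1, function(r)
    paste(sprintf("%.17g", r), collapse = ","))
  writeLines(lines, con)
}

.readRecordingCSV <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  if (!length(hdr) || !any(grepl("^# fs:", lines)))
    stop("malformed CSV recording header in ", path,
         ": missing '# fs:' line")
  getField <- function(key, default = NA) {
    ln <- grep(sprintf("^# %s:", key), lines, value = TRUE)
    if (!length(ln)) return(default)
    trimws(sub(sprintf("^# %s:", key), "", ln[1]))
  }
  fs <- as.numeric(getField("fs"))
  labels <- strsplit(lines[max(hdr) + 1L], ",")[[1]]
  body <- lines[(max(hdr) + 2L):length(lines)]
  dat <- t(vapply(strsplit(body, ","), as.numeric,
                  numeric(length(labels))))
  EEGRecording(t(dat), fs = fs, channelLabels = labels,
               subjectId = getField("subject_id", "S1"),
               group = getField("group", "healthy"),
               condition = getField("condition", "EO"),
               trial = as.integer(getField("trial", "1")))
}

## ---- EDF dialect ----

.edfPad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)  # left-justified, space padded
}

.writeRecordingEDF <- function(rec, path) {
  fs <- round(rec@fs)
  n <- ncol(rec@data)
  if (n %% fs != 0)
    stop("EDF export requires a whole number of seconds")
  nrec <- n %/% fs
  ns <- nrow(rec@data)
  physMax <- max(1e-6, max(abs(rec@data)))
  physMax <- signif(physMax * 1.0001, 8)
  digMax <- 32767L
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(.edfPad(x, width), con, width,
                                     eos = NULL)
  wr("0", 8)
  wr(sprintf("%s %s", rec@subjectId, rec@group), 80)
  wr(sprintf("%s %d", rec@condition, rec@trial), 80)
  wr("01.01.00", 8)
  wr("00.00.00", 8)
  wr(256 * (ns + 1), 8)
  wr("", 44)
  wr(nrec, 8)
  wr("1", 8)
  wr(ns, 4)
  for (lab in rec@channelLabels) wr(lab, 16)
  for (i in seq_len(ns)) wr("", 80)          # transducer
  for (i in seq_len(ns)) wr("uV", 8)         # physical dimension
  for (i in seq_len(ns)) wr(sprintf("%.6g", -physMax), 8)
  for (i in seq_len(ns)) wr(sprintf("%.6g", physMax), 8)
  for (i in seq_len(ns)) wr(-digMax - 1L, 8)
  for (i in seq_len(ns)) wr(digMax, 8)
  for (i in seq_len(ns)) wr("", 80)          # prefiltering
  for (i in seq_len(ns)) wr(fs, 8)
  for (i in seq_len(ns)) wr("", 32)
  # exact inverse of the reader's linear map phys(dig)
  digMin <- -digMax - 1L
  scale <- (digMax - digMin) / (2 * physMax)
  for (r in seq_len(nrec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (ch in seq_len(ns)) {
      dig <- as.integer(round(digMin + (rec@data[ch, idx] + physMax) *
                                scale))
      dig[dig > digMax] <- digMax
      dig[dig < digMin] <- digMin
      writeBin(dig, con, size = 2L, endian = "little")
    }
  }
}

.readRecordingEDF <- function(path) {
  sz <- file.size(path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  if (sz < 256)
    stop(sprintf("truncated EDF file %s: %d bytes, need at least 256",
                 path, sz))
  rd(8)                                   # version
  patient <- rd(80)
  recording <- rd(80)
  rd(8); rd(8)                            # date, time
  headerBytes <- as.integer(rd(8))
  rd(44)
  nrec <- as.integer(rd(8))
  recDur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)            # physical dimension
  physMin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  physMax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  digMin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  digMax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1L)
    stop("EDF signals with differing sampling rates are not supported")
  fs <- spr[1] / recDur
  expected <- headerBytes + nrec * sum(spr) * 2
  if (sz < expected)
    stop(sprintf(
      "truncated EDF file %s: %d bytes, expected %d (data end at byte %d)",
      path, sz, expected, expected))
  dat <- matrix(0, nrow = ns, ncol = nrec * spr[1])
  for (r in seq_len(nrec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[ch], size = 2L,
                     endian = "little")
      phys <- physMin[ch] + (dig - digMin[ch]) *
        (physMax[ch] - physMin[ch]) / (digMax[ch] - digMin[ch])
      dat[ch, ((r - 1) * spr[ch] + 1):(r * spr[ch])] <- phys
    }
  }
  pt <- strsplit(patient, " +")[[1]]
  rc <- strsplit(recording, " +")[[1]]
  EEGRecording(dat, fs = fs, channelLabels = labels,
               subjectId = if (length(pt) >= 1) pt[1] else "S1",
               group = if (length(pt) >= 2) pt[2] else "healthy",
               condition = if (length(rc) >= 1) rc[1] else "EO",
               trial = if (length(rc) >= 2) as.integer(rc[2]) else 1L)
}

## ---- cohort manifest ----

#' Write / read a cohort of recordings with a JSON manifest
#'
#' `writeCohort()` writes one file per recording (CSV or EDF dialect,
#' see [writeRecording()]) into `dir` plus a `manifest.json` listing file
#' name, subject, group, condition, trial, sampling rate and channel
#' count. `readCohort()` restores the list of recordings from a manifest
#' (or a directory containing one), verifying that every referenced file
#' exists and that (subject, condition, trial) tuples are unique.
#'
#' @param recordings list of [EEGRecording-class] objects.
#' @param dir output directory (created if needed).
#' @param dialect `"csv"` or `"edf"`.
#' @param path manifest file or directory containing `manifest.json`.
#' @return `writeCohort()` the manifest path invisibly; `readCohort()` a
#'   list of [EEGRecording-class] objects.
#' @name cohort-io
NULL

#' @rdname cohort-io
#' @export
writeCohort <- function(recordings, dir, dialect = c("csv", "edf")) {
  dialect <- match.arg(dialect)
  stopifnot(length(recordings) > 0)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- vector("list", length(recordings))
  for (i in seq_along(recordings)) {
    rec <- recordings[[i]]
    fname <- sprintf("%s_%s_t%d.%s", rec@subjectId, rec@condition,
                     rec@trial, dialect)
    writeRecording(rec, file.path(dir, fname), dialect)
    entries[[i]] <- list(file = fname, subject_id = rec@subjectId,
                         group = rec@group, condition = rec@condition,
                         trial = rec@trial, fs = rec@fs,
                         n_channels = nrow(rec@data), dialect = dialect)
  }
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(entries, manifest, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' @rdname cohort-io
#' @export
readCohort <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "manifest.json")
  if (!file.exists(path)) stop("manifest not found: ", path)
  entries <- jsonlite::read_json(path)
  if (!length(entries)) stop("empty cohort manifest: ", path)
  keys <- vapply(entries, function(e)
    paste(e$subject_id, e$condition, e$trial), "")
  if (anyDuplicated(keys))
    stop("duplicate (subject, condition, trial) tuples in manifest")
  base <- dirname(path)
  lapply(entries, function(e) {
    f <- file.path(base, e$file)
    if (!file.exists(f)) stop("manifest references missing file: ", f)
    rec <- readRecording(f, dialect = e$dialect)
    if (!is.null(e$fs) && abs(rec@fs - e$fs) > 1e-6)
      stop(sprintf("fs mismatch for %s: file %g, manifest %g",
                   e$file, rec@fs, e$fs))
    rec
  })
}
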