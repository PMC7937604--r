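# Recording I/O: plain CSV with a JSON sidecar, and minimal classic EDF
# (European Data Format, 16-bit integer records). The CSV dialect is one
# column per channel with a header row of labels; the sidecar carries fs,
# subject and condition.

sidecar_path <- function(path) sub("\\.[Cc][Ss][Vv]$", ".json", path)

#' Read an EEG recording
#'
#' Reads a 16-channel recording from EDF or from the package's CSV dialect
#' (one column per channel, header row of labels, JSON sidecar with the
#' sampling rate). Channel labels must resolve to the expected 16-channel
#' 10-20 set, case-insensitively; T7/T8/P7/P8 are accepted as synonyms of
#' T3/T4/T5/T6. Relabeled (`FP_A`-style) files are accepted as-is.
#'
#' @param path File path (`.edf` or `.csv`).
#' @param dialect `"auto"` (by extension), `"edf"` or `"csv"`.
#' @return An [eeg_recording()].
#' @export
read_recording <- function(path, dialect = c("auto", "edf", "csv")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "edf") read_recording_edf(path) else read_recording_csv(path)
}

resolve_labels <- function(labels) {
  if (all(labels %in% relabeled_channels())) return(labels)
  match_1020(labels)
}

read_recording_csv <- function(path) {
  side <- sidecar_path(path)
  if (!file.exists(side))
    stop("CSV sidecar not found: ", side,
         " (expected JSON with fs, subject_id, condition)")
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (is.null(meta$fs)) stop("sidecar missing sampling rate 'fs'")
  df <- read.csv(path, check.names = FALSE)
  labels <- resolve_labels(colnames(df))
  eeg_recording(subject_id = meta$subject_id %||% "unknown",
                condition = meta$condition %||% "eyes_closed",
                fs = meta$fs, channel_labels = labels,
                data = t(as.matrix(df)))
}

#' Write an EEG recording
#'
#' Counterpart of [read_recording()]: writes the CSV dialect (plus JSON
#' sidecar) or a minimal classic EDF file (16-bit integers, so round-trips
#' are exact only up to the per-channel quantization step).
#'
#' @param rec An [eeg_recording()].
#' @param path Output path (`.edf` or `.csv`).
#' @param dialect `"auto"`, `"edf"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, dialect = c("auto", "edf", "csv")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  if (dialect == "edf") write_recording_edf(rec, path)
  else write_recording_csv(rec, path)
  invisible(path)
}

write_recording_csv <- function(rec, path) {
  df <- as.data.frame(t(rec$data))
  colnames(df) <- rec$channel_labels
  write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(subject_id = rec$subject_id,
                            condition = rec$condition, fs = rec$fs),
                       sidecar_path(path), auto_unbox = TRUE)
}

# ---- minimal classic EDF ----

edf_pad <- function(x, width) {
  x <- substr(format(x, scientific = FALSE, trim = TRUE), 1L, width)
  formatC(x, width = width, flag = "-")
}

write_recording_edf <- function(rec, path) {
  ns <- 16L
  n <- ncol(rec$data)
  fs <- rec$fs
  # 1-second records when the length divides evenly, else one whole record
  if (n %% fs == 0 && fs == round(fs)) {
    n_rec <- n %/% fs
    spr <- as.integer(fs)
    dur <- 1
  } else {
    n_rec <- 1L
    spr <- n
    dur <- n / fs
  }
  pmin <- apply(rec$data, 1L, min)
  pmax <- apply(rec$data, 1L, max)
  pmax[pmax <= pmin] <- pmin[pmax <= pmin] + 1
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(paste0(edf_pad(x, width),
                                            collapse = ""),
                                     con, nchars = width * length(x),
                                     eos = NULL)
  wr("0", 8)                                        # version
  wr(rec$subject_id, 80)                            # patient id
  wr(rec$condition, 80)                             # recording id
  wr("01.01.00", 8); wr("00.00.00", 8)              # start date/time
  wr(256L + ns * 256L, 8)                           # header bytes
  wr("", 44)                                        # reserved
  wr(n_rec, 8)
  wr(format(dur, digits = 8), 8)
  wr(ns, 4)
  wr(rec$channel_labels, 16)
  wr(rep("", ns), 80)                               # transducer
  wr(rep("uV", ns), 8)                              # physical dimension
  wr(format(pmin, digits = 7), 8)
  wr(format(pmax, digits = 7), 8)
  wr(rep(dmin, ns), 8)
  wr(rep(dmax, ns), 8)
  wr(rep("", ns), 80)                               # prefiltering
  wr(rep(spr, ns), 8)
  wr(rep("", ns), 32)                               # reserved

  scale <- (dmax - dmin) / (pmax - pmin)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * spr + 1L):(r * spr)
    for (ch in seq_len(ns)) {
      dig <- round((rec$data[ch, idx] - pmin[ch]) * scale[ch] + dmin)
      writeBin(as.integer(dig), con, size = 2L, endian = "little")
    }
  }
}

read_recording_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width, k = 1L) {
    out <- character(k)
    for (i in seq_len(k)) out[i] <- trimws(readChar(con, width, useBytes = TRUE))
    out
  }
  rd(8)                       # version
  subject_id <- rd(80)
  condition <- rd(80)
  rd(8); rd(8); rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (ns != 16L) stop("expected 16 signals in EDF, found ", ns)
  labels <- rd(16, ns)
  rd(80, ns)
  rd(8, ns)                   # physical dimension
  pmin <- as.numeric(rd(8, ns))
  pmax <- as.numeric(rd(8, ns))
  dmin <- as.numeric(rd(8, ns))
  dmax <- as.numeric(rd(8, ns))
  rd(80, ns)
  spr <- as.integer(rd(8, ns))
  rd(32, ns)
  if (length(unique(spr)) != 1L)
    stop("non-uniform sampling across EDF signals is not supported")
  fs <- spr[1] / dur
  n <- n_rec * spr[1]
  data <- matrix(0, nrow = ns, ncol = n)
  scale <- (pmax - pmin) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * spr[1] + 1L):(r * spr[1])
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[1], size = 2L,
                     endian = "little")
      data[ch, idx] <- (dig - dmin[ch]) * scale[ch] + pmin[ch]
    }
  }
  labels <- resolve_labels(labels)
  condition <- if (condition %in% c("eyes_closed", "pain")) condition
               else "eyes_closed"
  eeg_recording(subject_id = subject_id, condition = condition, fs = fs,
                channel_labels = labels, data = data)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a cohort to disk
#'
#' Writes subject metadata as CSV, one file per subject and condition
#' (EDF or CSV dialect), and a manifest JSON mapping subject x condition to
#' file.
#'
#' @param cohort A `doc_cohort` from [generate_cohort()] (with signals).
#' @param dir Output directory (created if needed).
#' @param format `"edf"` or `"csv"`.
#' @return The manifest, invisibly.
#' @export
write_cohort <- function(cohort, dir, format = c("edf", "csv")) {
  format <- match.arg(format)
  if (is.null(cohort$recordings))
    stop("cohort has no signals (generated with signals = FALSE)")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(cohort$subjects, file.path(dir, "subjects.csv"),
            row.names = FALSE)
  manifest <- list()
  for (sid in names(cohort$recordings)) {
    for (cond in names(cohort$recordings[[sid]])) {
      fn <- sprintf("%s_%s.%s", sid, cond, format)
      write_recording(cohort$recordings[[sid]][[cond]],
                      file.path(dir, fn), dialect = format)
      manifest[[sid]][[cond]] <- fn
    }
  }
  jsonlite::write_json(list(seed = cohort$config$seed,
                            fs = cohort$config$fs,
                            epoch_len = cohort$config$epoch_len,
                            files = manifest),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(manifest)
}

#' Read a cohort directory
#'
#' Loads the metadata table and all recordings referenced by a cohort
#' manifest written by [write_cohort()].
#'
#' @param dir Directory containing `subjects.csv` and `manifest.json`.
#' @return List with `subjects`, `recordings`, `epoch_len` and `fs`.
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  subjects <- read.csv(file.path(dir, "subjects.csv"),
                       stringsAsFactors = FALSE)
  recordings <- list()
  for (sid in names(manifest$files)) {
    for (cond in names(manifest$files[[sid]])) {
      recordings[[sid]][[cond]] <-
        read_recording(file.path(dir, manifest$files[[sid]][[cond]]))
    }
  }
  list(subjects = subjects, recordings = recordings,
       epoch_len = manifest$epoch_len, fs = manifest$fs)
}
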