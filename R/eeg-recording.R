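#' EEG recording container
#'
#' One subject-by-condition multichannel recording: a 16 x n-samples matrix
#' in microvolts with its sampling rate and ordered channel labels (either
#' the 10-20 names or the affected/unaffected relabeling).
#'
#' @param subject_id Subject identifier.
#' @param condition `"eyes_closed"` or `"pain"`.
#' @param fs Sampling rate in Hz.
#' @param channel_labels Character vector of 16 unique labels, one per row.
#' @param data Numeric matrix, channels x samples, all finite.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(subject_id, condition, fs, channel_labels, data) {
  if (!is.matrix(data)) data <- as.matrix(data)
  if (nrow(data) != 16L)
    stop("expected exactly 16 channels, got ", nrow(data))
  if (length(channel_labels) != 16L || anyDuplicated(channel_labels))
    stop("channel_labels must be 16 unique labels")
  if (!is.finite(fs) || fs <= 0) stop("fs must be positive")
  if (!all(is.finite(data))) stop("recording contains non-finite samples")
  condition <- match.arg(condition, c("eyes_closed", "pain"))
  structure(list(subject_id = as.character(subject_id),
                 condition = condition, fs = fs,
                 channel_labels = as.character(channel_labels),
                 data = data),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "EEG recording %s [%s]: 16 channels x %d samples @ %g Hz (%.3f s)\n",
    x$subject_id, x$condition, ncol(x$data), x$fs, ncol(x$data) / x$fs))
  cat("  channels:", paste(x$channel_labels, collapse = " "), "\n")
  invisible(x)
}

# Accepted 10-20 label synonyms (modern temporal names map to the classic
# ones used here).
canonicalize_labels <- function(labels) {
  up <- toupper(trimws(labels))
  syn <- c(T7 = "T3", T8 = "T4", P7 = "T5", P8 = "T6")
  hit <- up %in% names(syn)
  up[hit] <- syn[up[hit]]
  up
}

# Validate that labels resolve to the canonical 16-channel montage; returns
# the canonicalized labels in the input order.
match_1020 <- function(labels) {
  lab <- canonicalize_labels(labels)
  want <- canonical_channels()
  missing <- setdiff(want, lab)
  extra <- setdiff(lab, want)
  if (length(missing) || length(extra))
    stop("channel mismatch: missing [",
         paste(missing, collapse = ", "), "], unexpected [",
         paste(extra, collapse = ", "), "]")
  lab
}

#' Montage map between 10-20 and affected/unaffected labels
#'
#' Builds the relabeling for a given affected hemisphere: each region's
#' left/right electrode pair maps to `_A` (affected) and `_U` (unaffected),
#' with AT/MT/PT taken from F7/F8, T3/T4, T5/T6.
#'
#' @param affected `"left"` or `"right"`.
#' @param source How the side was determined: `"imaging"` or
#'   `"apen_tiebreak"`.
#' @return Object of class `montage_map`: list with `affected`, `source`,
#'   `relabeled` (the canonical 16-label order) and `mapping` (named
#'   character vector, relabeled name -> 10-20 name).
#' @export
montage_map <- function(affected = c("left", "right"),
                        source = c("imaging", "apen_tiebreak")) {
  affected <- match.arg(affected)
  source <- match.arg(source)
  mapping <- relabel_table(affected)
  structure(list(affected = affected, source = source,
                 relabeled = relabeled_channels(), mapping = mapping),
            class = "montage_map")
}

#' @export
print.montage_map <- function(x, ...) {
  cat(sprintf("Montage map: affected = %s (source: %s)\n",
              x$affected, x$source))
  invisible(x)
}

#' Determine the affected hemisphere
#'
#' Uses the imaging finding when available. When imaging is equivocal
#' (`"unknown"`), falls back to the eyes-closed EEG: the hemisphere with the
#' lower mean ApEn over its 8 channels is labeled affected (lower average
#' complexity indicating more serious impairment). An exact tie goes to the
#' left with a warning.
#'
#' @param imaging_side `"left"`, `"right"` or `"unknown"`.
#' @param eyes_closed_rec An [eeg_recording()] with 10-20 labels; required
#'   when `imaging_side` is `"unknown"`.
#' @param params [apen_params()] for the tie-break computation.
#' @return A [montage_map()].
#' @export
determine_affected_side <- function(imaging_side = c("left", "right",
                                                     "unknown"),
                                    eyes_closed_rec = NULL,
                                    params = apen_params()) {
  imaging_side <- match.arg(imaging_side)
  if (imaging_side != "unknown")
    return(montage_map(imaging_side, source = "imaging"))
  if (is.null(eyes_closed_rec))
    stop("imaging side unknown: an eyes-closed recording is required ",
         "for the ApEn tie-break")
  rec <- eyes_closed_rec
  lab <- match_1020(rec$channel_labels)
  left <- unname(relabel_table("left")[grepl("_A$",
                                             names(relabel_table("left")))])
  vals <- apply(rec$data, 1L, apen, m = params$m, r_factor = params$r_factor)
  mean_left <- mean(vals[lab %in% left])
  mean_right <- mean(vals[!(lab %in% left)])
  if (mean_left == mean_right) {
    warning("hemispheric mean ApEn exactly tied: affected side set to left")
    side <- "left"
  } else side <- if (mean_left < mean_right) "left" else "right"
  montage_map(side, source = "apen_tiebreak")
}

#' Remap a recording to affected/unaffected labels
#'
#' Reorders the channels of a 10-20-labeled recording into the canonical
#' relabeled order (`FP_A, FP_U, ..., PT_U`) given a montage map. Data are
#' permuted, never altered. Applying a map to an already-relabeled recording
#' inverts it back to 10-20 labels.
#'
#' @param rec An [eeg_recording()].
#' @param map A [montage_map()].
#' @return The relabeled recording.
#' @export
remap_montage <- function(rec, map) {
  if (all(rec$channel_labels %in% map$relabeled)) {
    # inverse direction: relabeled -> 10-20
    rev <- stats::setNames(names(map$mapping), unname(map$mapping))
    sel <- match(unname(rev[canonical_channels()]), rec$channel_labels)
    new_labels <- canonical_channels()
  } else {
    lab <- match_1020(rec$channel_labels)
    sel <- match(unname(map$mapping), lab)
    if (anyNA(sel))
      stop("unmappable labels: ",
           paste(map$mapping[is.na(sel)], collapse = ", "))
    new_labels <- names(map$mapping)
  }
  rec$data <- rec$data[sel, , drop = FALSE]
  rec$channel_labels <- new_labels
  rec
}
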