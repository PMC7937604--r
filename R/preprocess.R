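#' Zero-phase 50 Hz notch filter
#'
#' Removes mains interference with a second-order IIR notch (biquad,
#' Q = 30 by default) applied forward and backward per channel
#' ([signal::filtfilt()]), so the output is zero-phase and the length is
#' unchanged. DC and frequencies away from the notch pass essentially
#' untouched; re-applying the filter to an already-notched signal changes it
#' only marginally.
#'
#' @param rec An [eeg_recording()].
#' @param freq Notch frequency in Hz (default 50); must be below Nyquist.
#' @param q Quality factor (notch width = freq / q).
#' @return The filtered recording.
#' @export
notch_filter <- function(rec, freq = 50, q = 30) {
  if (freq >= rec$fs / 2)
    stop("notch frequency ", freq, " Hz is not below Nyquist (",
         rec$fs / 2, " Hz)")
  w0 <- 2 * pi * freq / rec$fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  for (ch in seq_len(nrow(rec$data)))
    rec$data[ch, ] <- signal::filtfilt(b, a, rec$data[ch, ])
  rec
}

#' Select the artifact-free analysis epoch
#'
#' Returns the earliest window of `n_points` consecutive samples in which no
#' channel exceeds the absolute amplitude limit -- an automated proxy for
#' the visual artifact-free epoch selection of clinical practice. The chosen
#' start index (1-based) and the window duration in seconds are attached as
#' attributes.
#'
#' @param rec An [eeg_recording()].
#' @param n_points Window length in samples (default 32768; 65.536 s at
#'   500 Hz).
#' @param amplitude_limit Absolute amplitude threshold in microvolts
#'   (default 100).
#' @return The windowed recording with attributes `start_index` and
#'   `duration_s`.
#' @export
select_epoch <- function(rec, n_points = 32768L, amplitude_limit = 100) {
  n <- ncol(rec$data)
  n_points <- as.integer(n_points)
  if (n < n_points)
    stop("recording has ", n, " samples; ", n_points, " required")
  bad <- which(apply(abs(rec$data) > amplitude_limit, 2L, any))
  start <- NA_integer_
  if (length(bad) == 0L) {
    start <- 1L
  } else {
    # candidate starts: beginning of the recording and one past each bad
    # sample; the window must end before the next bad sample
    bounds <- c(0L, bad, n + 1L)
    for (i in seq_len(length(bounds) - 1L)) {
      s <- bounds[i] + 1L
      gap <- bounds[i + 1L] - s
      if (gap >= n_points) { start <- s; break }
    }
    if (is.na(start)) {
      runs <- diff(bounds) - 1L
      stop("no artifact-free window of ", n_points,
           " samples; longest clean run is ", max(runs), " samples")
    }
  }
  rec$data <- rec$data[, start:(start + n_points - 1L), drop = FALSE]
  attr(rec, "start_index") <- start
  attr(rec, "duration_s") <- n_points / rec$fs
  rec
}
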