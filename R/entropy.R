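#' Entropy parameters
#'
#' Bundle of the template-matching parameters used throughout the pipeline:
#' embedding dimension `m`, tolerance `r_factor` (as a fraction of the series
#' standard deviation for ApEn, of unit SD for the internally standardized
#' C-ApEn), and the analysis epoch length `n_points`.
#'
#' The defaults (`m = 2`, `r_factor = 0.2`, `n_points = 32768`) are the
#' canonical ApEn settings for EEG complexity work; 32768 samples at 500 Hz
#' span 65.536 s.
#'
#' @param m Integer embedding dimension, `>= 1`.
#' @param r_factor Positive tolerance as a fraction of the SD.
#' @param n_points Epoch length in samples; must exceed `m + 1`.
#' @return An object of class `apen_params`.
#' @export
apen_params <- function(m = 2L, r_factor = 0.2, n_points = 32768L) {
  m <- as.integer(m)
  n_points <- as.integer(n_points)
  stopifnot(is.finite(m), m >= 1L,
            is.finite(r_factor), r_factor > 0,
            is.finite(n_points), n_points > m + 1L)
  structure(list(m = m, r_factor = r_factor, n_points = n_points),
            class = "apen_params")
}

#' @export
print.apen_params <- function(x, ...) {
  cat(sprintf("Entropy parameters: m = %d, r = %.3g * SD, n_points = %d\n",
              x$m, x$r_factor, x$n_points))
  invisible(x)
}

#' Approximate entropy of a time series
#'
#' Classical approximate entropy ApEn(m, r, N): with templates
#' \eqn{x_i = (u_i, \dots, u_{i+m-1})} and Chebyshev distance,
#' \eqn{C_i^m(r)} is the fraction of templates (self-match included) within
#' `r` of \eqn{x_i}, \eqn{\Phi^m(r)} the mean of \eqn{\ln C_i^m(r)}, and
#' \eqn{ApEn = \Phi^m(r) - \Phi^{m+1}(r)}. Larger values indicate a more
#' irregular (less predictable) series. `r` is taken as
#' `r_factor * sd(u)`, so the statistic is invariant to affine rescaling of
#' the input.
#'
#' A constant series (zero SD) has zero complexity by convention and returns
#' 0 with a warning.
#'
#' @param u Numeric series.
#' @param m Embedding dimension (default 2).
#' @param r_factor Tolerance as a fraction of `sd(u)` (default 0.2).
#' @return A single non-negative number (non-negativity holds for all
#'   practical inputs because self-matches are included).
#' @seealso [apen_naive()] for the transparent double-loop reference,
#'   [capen()] for the two-series analogue.
#' @export
#' @examples
#' set.seed(1)
#' apen(rnorm(500))                    # irregular: high
#' apen(sin(2 * pi * 10 * (1:500) / 500))  # quasi-periodic: low
apen <- function(u, m = 2L, r_factor = 0.2) {
  u <- as.numeric(u)
  if (anyNA(u) || any(!is.finite(u))) stop("series contains non-finite values")
  m <- as.integer(m)
  if (!is.finite(r_factor) || r_factor <= 0) stop("r_factor must be positive")
  if (length(u) < m + 2L) stop("series too short: need length > m + 1")
  s <- sd(u)
  if (s == 0) {
    warning("constant series: ApEn defined as 0")
    return(0)
  }
  apen_cpp(u, m, r_factor * s)
}

#' Naive reference implementation of approximate entropy
#'
#' Direct O(N^2 m) double-loop transcription of the ApEn definition, kept as
#' an independent check on the box-assisted implementation in [apen()].
#' Suitable only for short series.
#'
#' @inheritParams apen
#' @return Same value as [apen()] (to floating-point roundoff).
#' @export
apen_naive <- function(u, m = 2L, r_factor = 0.2) {
  u <- as.numeric(u)
  s <- sd(u)
  if (s == 0) {
    warning("constant series: ApEn defined as 0")
    return(0)
  }
  r <- r_factor * s
  phi <- function(mm) {
    n <- length(u) - mm + 1L
    logC <- numeric(n)
    for (i in seq_len(n)) {
      cnt <- 0L
      for (j in seq_len(n)) {
        d <- max(abs(u[i:(i + mm - 1L)] - u[j:(j + mm - 1L)]))
        if (d <= r) cnt <- cnt + 1L
      }
      logC[i] <- log(cnt / n)
    }
    mean(logC)
  }
  phi(m) - phi(m + 1L)
}

#' Cross-approximate entropy between two series
#'
#' Two-series analogue of [apen()] measuring asynchrony: templates are drawn
#' from `u` and compared against targets from `v`. Both series are
#' standardized to mean 0, SD 1 before matching and the tolerance is
#' `r_factor` in standardized units, so channels with different amplitudes
#' are comparable. Lower values indicate more synchronized dynamics.
#'
#' Because there is no guaranteed self-match, a template may have no match
#' within `r`; such templates are excluded from the per-level averages and
#' counted. If more than 10\% of templates at either level are excluded, the
#' result carries `unreliable = TRUE`. `capen(u, u)` reproduces
#' `apen(standardize(u))` exactly, since cross-matching a series against
#' itself restores the self-inclusive counts.
#'
#' @param u Template series (by convention the central electrode of a pair).
#' @param v Target series of the same length.
#' @inheritParams apen
#' @return A number with attributes `n_zero_m`, `n_zero_m1` (zero-match
#'   template counts at the two levels) and `unreliable` (logical).
#' @export
capen <- function(u, v, m = 2L, r_factor = 0.2) {
  u <- as.numeric(u); v <- as.numeric(v)
  if (length(u) != length(v)) stop("series lengths differ")
  if (anyNA(u) || anyNA(v) || any(!is.finite(u)) || any(!is.finite(v)))
    stop("series contain non-finite values")
  m <- as.integer(m)
  if (length(u) < m + 2L) stop("series too short: need length > m + 1")
  su <- sd(u); sv <- sd(v)
  if (su == 0 || sv == 0) stop("constant series: C-ApEn undefined")
  zu <- (u - mean(u)) / su
  zv <- (v - mean(v)) / sv
  res <- capen_cpp(zu, zv, m, r_factor)
  unreliable <- (res$n_zero_m > 0.1 * res$n_templates_m) ||
    (res$n_zero_m1 > 0.1 * res$n_templates_m1)
  if (is.na(res$value))
    warning("no matching templates at some level: C-ApEn undefined (NA)")
  structure(res$value, n_zero_m = res$n_zero_m, n_zero_m1 = res$n_zero_m1,
            unreliable = unreliable)
}

#' Naive reference implementation of cross-approximate entropy
#'
#' Direct double-loop transcription of the C-ApEn definition with the same
#' conventions as [capen()] (standardization, zero-match exclusion). Kept as
#' an independent check; use only on short series.
#'
#' @inheritParams capen
#' @return Same value as [capen()] (to floating-point roundoff).
#' @export
capen_naive <- function(u, v, m = 2L, r_factor = 0.2) {
  u <- (u - mean(u)) / sd(u)
  v <- (v - mean(v)) / sd(v)
  r <- r_factor
  phi <- function(mm) {
    n <- length(u) - mm + 1L
    logC <- numeric(0)
    for (i in seq_len(n)) {
      cnt <- 0L
      for (j in seq_len(n)) {
        d <- max(abs(u[i:(i + mm - 1L)] - v[j:(j + mm - 1L)]))
        if (d <= r) cnt <- cnt + 1L
      }
      if (cnt > 0L) logC <- c(logC, log(cnt / n))
    }
    mean(logC)
  }
  phi(m) - phi(m + 1L)
}

#' Designated C-ApEn channel pairs
#'
#' The ten ordered electrode pairs over which C-ApEn is computed, grouped
#' into local (central electrode with its F, P, MT neighbours) and distant
#' (central with FP and O) sets per hemisphere. The central electrode
#' (`C_A` / `C_U`) is always the first element and supplies the templates.
#'
#' @return An object of class `pair_spec`: a list with character vectors
#'   `local_affected`, `local_unaffected`, `distant_affected`,
#'   `distant_unaffected`, and `all` (the ten `"C_A-F_A"`-style pair names).
#' @export
pair_spec <- function() {
  local_affected <- c("C_A-F_A", "C_A-P_A", "C_A-MT_A")
  local_unaffected <- c("C_U-F_U", "C_U-P_U", "C_U-MT_U")
  distant_affected <- c("C_A-FP_A", "C_A-O_A")
  distant_unaffected <- c("C_U-FP_U", "C_U-O_U")
  structure(list(local_affected = local_affected,
                 local_unaffected = local_unaffected,
                 distant_affected = distant_affected,
                 distant_unaffected = distant_unaffected,
                 all = c(local_affected, distant_affected,
                         local_unaffected, distant_unaffected)),
            class = "pair_spec")
}

pair_channels <- function(pair) {
  # "C_A-FP_A" -> c("C_A", "FP_A"); channel names contain one underscore only
  strsplit(pair, "-", fixed = TRUE)[[1]]
}

#' Batch ApEn over cohort recordings
#'
#' Computes one ApEn value per subject, condition and channel from a nested
#' list of preprocessed (epoch-selected, remapped) recordings.
#'
#' @param recordings Named list: `recordings[[subject_id]][[condition]]` is an
#'   [eeg_recording()]. Subjects missing a condition are skipped with a
#'   message.
#' @param params An [apen_params()] object; `n_points` must match the epoch
#'   length of every recording.
#' @return A data frame (`entropy_table`) with columns `subject_id`,
#'   `condition`, `channel`, `apen`.
#' @export
apen_matrix <- function(recordings, params = apen_params()) {
  rows <- list()
  for (sid in names(recordings)) {
    conds <- recordings[[sid]]
    if (!all(c("eyes_closed", "pain") %in% names(conds))) {
      message("subject ", sid, ": missing condition, skipped")
      next
    }
    for (cond in c("eyes_closed", "pain")) {
      rec <- conds[[cond]]
      if (ncol(rec$data) != params$n_points)
        stop("subject ", sid, ": epoch length ", ncol(rec$data),
             " does not match params n_points ", params$n_points)
      vals <- apply(rec$data, 1L, apen, m = params$m,
                    r_factor = params$r_factor)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = sid, condition = cond,
        channel = rec$channel_labels, apen = unname(vals),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("entropy_table", "data.frame")
  out
}

#' Batch C-ApEn over the designated channel pairs
#'
#' Computes one C-ApEn value per subject, condition and designated pair
#' (templates from the central electrode), plus per-subject local/distant
#' means per hemisphere.
#'
#' @inheritParams apen_matrix
#' @param spec A [pair_spec()].
#' @return A list with `pairs` (data frame: `subject_id`, `condition`,
#'   `pair`, `capen`, `n_zero`, `unreliable`) and `summaries` (data frame of
#'   local/distant means per hemisphere per subject and condition).
#' @export
capen_pairs <- function(recordings, spec = pair_spec(),
                        params = apen_params()) {
  rows <- list()
  for (sid in names(recordings)) {
    conds <- recordings[[sid]]
    if (!all(c("eyes_closed", "pain") %in% names(conds))) {
      message("subject ", sid, ": missing condition, skipped")
      next
    }
    for (cond in c("eyes_closed", "pain")) {
      rec <- conds[[cond]]
      for (pr in spec$all) {
        ch <- pair_channels(pr)
        iu <- match(ch[1], rec$channel_labels)
        iv <- match(ch[2], rec$channel_labels)
        if (anyNA(c(iu, iv)))
          stop("pair ", pr, ": channel not present in recording for ", sid)
        val <- capen(rec$data[iu, ], rec$data[iv, ],
                     m = params$m, r_factor = params$r_factor)
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = sid, condition = cond, pair = pr,
          capen = as.numeric(val),
          n_zero = attr(val, "n_zero_m1"),
          unreliable = attr(val, "unreliable"),
          stringsAsFactors = FALSE)
      }
    }
  }
  pairs <- do.call(rbind, rows)
  rownames(pairs) <- NULL

  groups <- list(local_affected = spec$local_affected,
                 local_unaffected = spec$local_unaffected,
                 distant_affected = spec$distant_affected,
                 distant_unaffected = spec$distant_unaffected)
  srows <- list()
  for (g in names(groups)) {
    sub <- pairs[pairs$pair %in% groups[[g]], ]
    agg <- stats::aggregate(capen ~ subject_id + condition, data = sub, FUN = mean)
    agg$summary <- g
    srows[[g]] <- agg
  }
  summaries <- do.call(rbind, srows)
  rownames(summaries) <- NULL
  list(pairs = pairs, summaries = summaries[, c("subject_id", "condition",
                                                "summary", "capen")])
}
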