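# Synthetic DOC cohort generator.
#
# Signal model: each channel is a mixture
#   (1 - irregularity) * band-limited oscillation + irregularity * filtered noise
# so ApEn is a controlled monotone function of one parameter. Group,
# condition and hemisphere effects enter through per-channel irregularity
# values; cross-channel coupling through a shared latent noise source per
# hemisphere. Irregularity-scale constants below were calibrated once so the
# resulting ApEn tables sit on the clinically reported scale (eyes-closed
# group means near 0.60/0.68, between-subject SD near 0.1); see the methods
# vignette.

mgos_levels <- function() c("death", "VS", "MCS", "severe", "moderate", "good")

#' @rdname canonical_channels
#' @export
relabeled_channels <- function() {
  c("FP_A", "FP_U", "F_A", "F_U", "C_A", "C_U", "P_A", "P_U",
    "O_A", "O_U", "AT_A", "AT_U", "MT_A", "MT_U", "PT_A", "PT_U")
}

#' Channel name sets
#'
#' The 16-channel 10-20 montage used throughout (`canonical_channels()`) and
#' its affected/unaffected relabeling (`relabeled_channels()`): `_A` =
#' affected hemisphere, `_U` = unaffected; AT/MT/PT (anterior/middle/
#' posterior temporal) correspond to F7/F8, T3/T4, T5/T6.
#'
#' @return Character vector of 16 channel labels.
#' @export
canonical_channels <- function() {
  c("FP1", "FP2", "F3", "F4", "C3", "C4", "P3", "P4",
    "O1", "O2", "F7", "F8", "T3", "T4", "T5", "T6")
}

# per-region irregularity offsets (frontal-polar lowest, temporal highest),
# reproducing the anterior-posterior complexity gradient of resting EEG
region_offsets <- c(FP = -0.024, F = -0.014, C = 0, P = 0,
                    O = 0.007, AT = 0.005, MT = 0.019, PT = 0.024)

channel_region <- function(labels) {
  # relabeled "FP_A" -> "FP"; 10-20 handled via the relabel tables
  sub("_[AU]$", "", labels)
}

#' Configuration of a synthetic cohort
#'
#' Collects the generative parameters for [generate_cohort()]: group sizes,
#' acquisition settings, group-level signal irregularity, pain-stimulation
#' gains by hemisphere, channel coupling, the CRS-R score model, the outcome
#' model coefficients and the diagnosis mix.
#'
#' Irregularity parameters are on the mixture-weight scale (fraction of
#' filtered-noise power, in `[0, 1]`). Pain gains are additive irregularity
#' shifts; named per group (`UWS`, `MCS`), scalars are recycled. The default
#' configuration encodes the clinical structure the analysis expects: lower
#' complexity in UWS than MCS, a positive pain response on the unaffected
#' hemisphere that is larger in MCS, a near-zero (slightly negative) response
#' on the affected hemisphere equal across groups, and MCS CRS-R scores
#' stochastically dominating UWS scores.
#'
#' @param n_uws,n_mcs Subjects per group (default 98 and 64).
#' @param fs Sampling rate in Hz (default 500).
#' @param epoch_len Samples per recording (default 32768, i.e. 65.536 s).
#' @param irregularity_uws,irregularity_mcs Group baseline irregularity.
#' @param irregularity_subject_sd SD of the subject-level complexity factor
#'   shared across channels.
#' @param irregularity_channel_sd SD of independent per-channel variation.
#' @param pain_gain_unaffected,pain_gain_affected Additive irregularity change
#'   under pain on each hemisphere; named per group.
#' @param pain_subject_sd,pain_channel_sd SDs of the subject-level (shared per
#'   hemisphere) and channel-level pain-response variation.
#' @param affected_rest_shift Resting irregularity shift of the affected
#'   hemisphere (slightly negative: the damaged side is less complex).
#' @param coupling_uws,coupling_mcs Weight in `[0, 1]` of the shared
#'   per-hemisphere latent noise source (higher = more synchronized channels,
#'   lower C-ApEn).
#' @param crs_r_mean,crs_r_sd Per-group mean/SD of the integer CRS-R score
#'   (truncated to 0..23).
#' @param outcome_coefficients Named numeric vector of the linear-probability
#'   outcome model: `intercept`, `CRS-R`, and optionally channel / pair names
#'   whose pain-minus-rest irregularity responses enter the model.
#' @param diagnosis_mix Proportions over TBI/stroke/other; either one vector
#'   or a list with per-group vectors. A small "other" category keeps both
#'   diagnosis dummies estimable alongside an intercept.
#' @param p_male Per-group probability of male sex.
#' @param p_unknown_side Fraction of subjects whose affected side is not
#'   determined by imaging (resolved downstream by the ApEn tie-break).
#' @param amplitude_uv Signal scale (SD) in microvolts.
#' @param recording_margin_s Extra recording length in seconds beyond
#'   `epoch_len`, giving the artifact-rejection stage room to shift the
#'   analysis window (default 2).
#' @param pain_mode `"bilateral"` (one pain recording, default) or
#'   `"per_side"` (two pain epochs, affected-leg then unaffected-leg).
#' @param seed Master seed; per-subject streams are derived from it by a
#'   counter-based split, so a subject's data do not depend on cohort order.
#' @return An object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(n_uws = 98L, n_mcs = 64L,
                          fs = 500, epoch_len = 32768L,
                          irregularity_uws = 0.155,
                          irregularity_mcs = 0.190,
                          irregularity_subject_sd = 0.038,
                          irregularity_channel_sd = 0.028,
                          pain_gain_unaffected = c(UWS = 0.024, MCS = 0.042),
                          pain_gain_affected = c(UWS = -0.012, MCS = -0.012),
                          pain_subject_sd = 0.024,
                          pain_channel_sd = 0.038,
                          affected_rest_shift = -0.005,
                          coupling_uws = 0.5, coupling_mcs = 0.3,
                          crs_r_mean = c(UWS = 5, MCS = 9.5),
                          crs_r_sd = c(UWS = 2.5, MCS = 3),
                          outcome_coefficients = c(intercept = -0.23,
                                                   "CRS-R" = 0.087,
                                                   "P_A" = 2, "C_U-MT_U" = 2),
                          diagnosis_mix = list(
                            UWS = c(TBI = 0.43, stroke = 0.52, other = 0.05),
                            MCS = c(TBI = 0.58, stroke = 0.37, other = 0.05)),
                          p_male = c(UWS = 0.67, MCS = 0.78),
                          p_unknown_side = 0,
                          amplitude_uv = 20,
                          recording_margin_s = 2,
                          pain_mode = c("bilateral", "per_side"),
                          seed = 1L) {
  pain_mode <- match.arg(pain_mode)
  per_group <- function(x) {
    if (length(x) == 1L) x <- c(UWS = unname(x), MCS = unname(x))
    stopifnot(all(c("UWS", "MCS") %in% names(x)))
    x[c("UWS", "MCS")]
  }
  pain_gain_unaffected <- per_group(pain_gain_unaffected)
  pain_gain_affected <- per_group(pain_gain_affected)
  crs_r_mean <- per_group(crs_r_mean)
  crs_r_sd <- per_group(crs_r_sd)
  p_male <- per_group(p_male)
  if (!is.list(diagnosis_mix))
    diagnosis_mix <- list(UWS = diagnosis_mix, MCS = diagnosis_mix)
  for (g in c("UWS", "MCS")) {
    dm <- diagnosis_mix[[g]]
    stopifnot(setequal(names(dm), c("TBI", "stroke", "other")),
              all(dm >= 0), abs(sum(dm) - 1) < 1e-8)
  }
  cfg <- list(n_uws = as.integer(n_uws), n_mcs = as.integer(n_mcs),
              fs = fs, epoch_len = as.integer(epoch_len),
              irregularity = c(UWS = irregularity_uws, MCS = irregularity_mcs),
              irregularity_subject_sd = irregularity_subject_sd,
              irregularity_channel_sd = irregularity_channel_sd,
              pain_gain_unaffected = pain_gain_unaffected,
              pain_gain_affected = pain_gain_affected,
              pain_subject_sd = pain_subject_sd,
              pain_channel_sd = pain_channel_sd,
              affected_rest_shift = affected_rest_shift,
              coupling = c(UWS = coupling_uws, MCS = coupling_mcs),
              crs_r_mean = crs_r_mean, crs_r_sd = crs_r_sd,
              outcome_coefficients = outcome_coefficients,
              diagnosis_mix = diagnosis_mix, p_male = p_male,
              p_unknown_side = p_unknown_side,
              amplitude_uv = amplitude_uv,
              recording_margin_s = recording_margin_s,
              pain_mode = pain_mode,
              seed = as.integer(seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  num_ok <- function(x) all(is.finite(x))
  stopifnot(cfg$n_uws >= 1L, cfg$n_mcs >= 1L,
            num_ok(cfg$fs), cfg$fs > 0,
            cfg$epoch_len >= 1000L,
            num_ok(cfg$irregularity),
            all(cfg$irregularity >= 0), all(cfg$irregularity <= 1),
            num_ok(cfg$coupling),
            all(cfg$coupling >= 0), all(cfg$coupling <= 1),
            num_ok(cfg$pain_gain_unaffected), num_ok(cfg$pain_gain_affected),
            all(abs(cfg$pain_gain_unaffected) <= 1),
            all(abs(cfg$pain_gain_affected) <= 1),
            num_ok(cfg$irregularity_subject_sd),
            cfg$irregularity_subject_sd >= 0,
            cfg$irregularity_channel_sd >= 0,
            cfg$pain_subject_sd >= 0, cfg$pain_channel_sd >= 0,
            cfg$p_unknown_side >= 0, cfg$p_unknown_side <= 1,
            cfg$recording_margin_s >= 0,
            num_ok(cfg$outcome_coefficients),
            "intercept" %in% names(cfg$outcome_coefficients))
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort config: %d UWS + %d MCS, %d samples @ %g Hz, seed %d\n",
    x$n_uws, x$n_mcs, x$epoch_len, x$fs, x$seed))
  cat(sprintf("  irregularity UWS %.3f / MCS %.3f; coupling %.2f / %.2f\n",
              x$irregularity["UWS"], x$irregularity["MCS"],
              x$coupling["UWS"], x$coupling["MCS"]))
  invisible(x)
}

# counter-based per-subject seed split: a subject's stream depends only on
# the master seed and its index
subject_seed <- function(master, idx) {
  as.integer((as.numeric(master) + as.numeric(idx) * 9973) %% 2147483629)
}

#' Band-limited Gaussian noise
#'
#' Unit-SD Gaussian noise restricted to `[f_lo, f_hi]` Hz by spectral
#' masking, the acquisition bandwidth of the emulated recordings. Used as
#' the irregular component of the signal model and as a latent source shared
#' between coupled channels.
#'
#' @param n Number of samples.
#' @param fs Sampling rate in Hz.
#' @param f_lo,f_hi Band edges in Hz (defaults 0.3 and 100).
#' @return Numeric series of length `n` with unit SD.
#' @export
band_noise <- function(n, fs, f_lo = 0.3, f_hi = 100) {
  spec <- stats::fft(stats::rnorm(n))
  freq <- (seq_len(n) - 1) / n * fs
  freq <- pmin(freq, fs - freq)         # two-sided spectrum
  spec[freq < f_lo | freq > f_hi] <- 0i
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  x / sd(x)
}

# Quasi-periodic oscillation: one delta-band and one alpha-band tone with
# random frequency and phase, unit SD.
osc_component <- function(n, fs) {
  t <- (seq_len(n) - 1) / fs
  x <- sin(2 * pi * runif(1, 1, 4) * t + runif(1, 0, 2 * pi)) +
       sin(2 * pi * runif(1, 8, 12) * t + runif(1, 0, 2 * pi))
  x / sd(x)
}

#' Generate one synthetic EEG channel
#'
#' One channel of the generative signal model: a convex mixture of a
#' quasi-periodic oscillation (random delta- and alpha-band tones) and
#' band-limited (0.3-100 Hz) Gaussian noise, weighted by `irregularity`.
#' ApEn of the output is strictly increasing in `irregularity` (in
#' expectation): at 0 the signal is purely quasi-periodic, at 1 pure
#' filtered noise.
#'
#' Uses the current RNG state; seed the session (or pass `seed`) for
#' reproducibility.
#'
#' @param irregularity Mixture weight in `[0, 1]`.
#' @param epoch_len Number of samples.
#' @param fs Sampling rate in Hz.
#' @param noise Optional pre-drawn unit-SD noise series (used to share a
#'   latent source between coupled channels).
#' @param amplitude_uv Output SD in microvolts.
#' @param seed Optional integer seed applied before drawing.
#' @return Zero-mean numeric series of length `epoch_len`.
#' @export
generate_channel_signal <- function(irregularity, epoch_len, fs = 500,
                                    noise = NULL, amplitude_uv = 20,
                                    seed = NULL) {
  if (!is.finite(irregularity) || irregularity < 0 || irregularity > 1)
    stop("irregularity must be a finite fraction in [0, 1]")
  if (!is.finite(epoch_len) || epoch_len < 4)
    stop("epoch_len must be a finite sample count")
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(epoch_len)
  if (is.null(noise)) noise <- band_noise(n, fs)
  x <- (1 - irregularity) * osc_component(n, fs) + irregularity * noise
  x <- x - mean(x)
  x / sd(x) * amplitude_uv
}

clamp01 <- function(x, lo = 0.02, hi = 0.98) pmin(pmax(x, lo), hi)

# Relabel tables between 10-20 and affected/unaffected space for a given
# affected side.
relabel_table <- function(affected = c("left", "right")) {
  affected <- match.arg(affected)
  left <- c(FP = "FP1", F = "F3", C = "C3", P = "P3", O = "O1",
            AT = "F7", MT = "T3", PT = "T5")
  right <- c(FP = "FP2", F = "F4", C = "C4", P = "P4", O = "O2",
             AT = "F8", MT = "T4", PT = "T6")
  a <- if (affected == "left") left else right
  u <- if (affected == "left") right else left
  new <- relabeled_channels()
  old <- character(16)
  for (i in seq_along(new)) {
    reg <- channel_region(new[i])
    old[i] <- if (grepl("_A$", new[i])) a[[reg]] else u[[reg]]
  }
  names(old) <- new
  old   # named: relabeled -> 10-20
}

# Latent per-channel irregularity tables for one subject, in relabeled space.
#
# Coupling semantics: C-ApEn detects mismatch between the two series'
# dynamics, not sample-level correlation, so the coupling weight acts by
# shrinking the idiosyncratic per-channel irregularity dispersion within a
# hemisphere -- strongly coupled cortical areas share a dynamical state
# (similar complexity, low pair C-ApEn), decoupled islands drift apart.
subject_latents <- function(cfg, group) {
  g <- group
  w <- cfg$coupling[[g]]
  chans <- relabeled_channels()
  reg <- channel_region(chans)
  side <- ifelse(grepl("_A$", chans), "A", "U")
  b <- rnorm(1, 0, cfg$irregularity_subject_sd)
  rest <- cfg$irregularity[[g]] + b + region_offsets[reg] +
    ifelse(side == "A", cfg$affected_rest_shift, 0) +
    (1 - w) * rnorm(16, 0, cfg$irregularity_channel_sd)
  rest <- clamp01(rest)
  gain <- ifelse(side == "A", cfg$pain_gain_affected[[g]],
                 cfg$pain_gain_unaffected[[g]])
  d_side <- rnorm(2, 0, cfg$pain_subject_sd)        # shared within hemisphere
  names(d_side) <- c("A", "U")
  pain <- rest + gain + d_side[side] +
    (1 - w) * rnorm(16, 0, cfg$pain_channel_sd)
  pain <- clamp01(pain)
  names(rest) <- names(pain) <- chans
  list(rest = rest, pain = pain)
}

# Latent pair features (irregularity scale): mean of the member channels
# plus a little independent variation.
pair_latents <- function(rest, pain) {
  prs <- pair_spec()$all
  out_rest <- out_pain <- numeric(length(prs))
  for (i in seq_along(prs)) {
    ch <- pair_channels(prs[i])
    eps <- rnorm(2, 0, 0.005)
    out_rest[i] <- mean(rest[ch]) + eps[1]
    out_pain[i] <- mean(pain[ch]) + eps[2]
  }
  names(out_rest) <- names(out_pain) <- prs
  list(rest = out_rest, pain = out_pain)
}

# Render one condition's 16-channel recording from relabeled-space latent
# irregularities, with per-hemisphere shared latent noise (coupling).
render_recording <- function(subject_id, condition, irr, cfg, group,
                             affected) {
  n <- cfg$epoch_len + round(cfg$recording_margin_s * cfg$fs)
  w <- cfg$coupling[[group]]
  tab <- relabel_table(affected)     # relabeled -> 10-20
  latent <- list(A = band_noise(n, cfg$fs), U = band_noise(n, cfg$fs))
  data <- matrix(0, nrow = 16L, ncol = n)
  labels_1020 <- unname(tab)
  for (i in seq_along(tab)) {
    side <- if (grepl("_A$", names(tab)[i])) "A" else "U"
    own <- band_noise(n, cfg$fs)
    noise <- sqrt(1 - w^2) * own + w * latent[[side]]
    data[i, ] <- generate_channel_signal(irr[[names(tab)[i]]], n, cfg$fs,
                                         noise = noise,
                                         amplitude_uv = cfg$amplitude_uv)
  }
  eeg_recording(subject_id = subject_id, condition = condition,
                fs = cfg$fs, channel_labels = labels_1020, data = data)
}

#' Generate one synthetic subject
#'
#' Draws a subject record (demographics, CRS-R, diagnosis, affected side,
#' 12-month mGOS), the latent per-channel irregularities for both
#' conditions, and, optionally, the eyes-closed and pain recordings.
#'
#' @param config A [cohort_config()].
#' @param group `"UWS"` or `"MCS"`.
#' @param idx Subject counter used for the seed split and the subject id.
#' @param signals If `FALSE`, skip signal rendering (metadata and latent
#'   features only; used for large outcome-model studies).
#' @return A list with `record` (one-row data frame), `features` (named
#'   vector of latent pain-minus-rest responses plus rest levels) and
#'   `recordings` (named list of [eeg_recording()] objects, or `NULL`).
#' @export
generate_subject <- function(config, group = c("UWS", "MCS"), idx = 1L,
                             signals = TRUE) {
  group <- match.arg(group)
  cfg <- config
  set.seed(subject_seed(cfg$seed, idx))
  subject_id <- sprintf("S%03d", idx)

  sex <- if (runif(1) < cfg$p_male[[group]]) "male" else "female"
  age <- round(min(max(rnorm(1, 46, 14), 17), 73))
  duration <- round(min(max(rnorm(1, 145, 90), 60), 400))
  dm <- cfg$diagnosis_mix[[group]]
  diagnosis <- sample(names(dm), 1L, prob = dm)
  affected_true <- sample(c("left", "right"), 1L)
  affected_known <- runif(1) >= cfg$p_unknown_side
  crs_r <- as.integer(min(max(round(rnorm(1, cfg$crs_r_mean[[group]],
                                          cfg$crs_r_sd[[group]])), 0), 23))

  lat <- subject_latents(cfg, group)
  plat <- pair_latents(lat$rest, lat$pain)
  diffs <- c(lat$pain - lat$rest, plat$pain - plat$rest)
  features <- c(diffs, "CRS-R" = crs_r)

  record <- data.frame(
    subject_id = subject_id, group = group, age = age, sex = sex,
    duration = duration, diagnosis = diagnosis,
    crs_r = crs_r,
    affected_side = if (affected_known) affected_true else "unknown",
    stringsAsFactors = FALSE)

  out <- generate_outcome(record, features, cfg$outcome_coefficients)
  record$mgos_12m <- out$mgos_12m
  record$improved_true <- out$improved

  recordings <- NULL
  if (signals) {
    recordings <- list(
      eyes_closed = render_recording(subject_id, "eyes_closed", lat$rest,
                                     cfg, group, affected_true),
      pain = render_recording(subject_id, "pain", lat$pain,
                              cfg, group, affected_true))
    if (cfg$pain_mode == "per_side") {
      # optional two-epoch mode: affected-leg then unaffected-leg epochs,
      # drawn from the same pain process
      recordings$pain_affected_leg <- recordings$pain
      recordings$pain_unaffected_leg <-
        render_recording(subject_id, "pain", lat$pain, cfg, group,
                         affected_true)
      recordings$pain_unaffected_leg$condition <- "pain"
    }
  }

  list(record = record,
       features = features,
       latent = list(rest = c(lat$rest, plat$rest),
                     pain = c(lat$pain, plat$pain)),
       recordings = recordings)
}

#' Draw a 12-month mGOS outcome
#'
#' Linear-probability outcome model: the improvement probability is
#' `intercept + sum(coefficients * features)` over the named predictors,
#' clamped to `[0, 1]` (clamping is counted and reported via an attribute).
#' Improvement is a Bernoulli draw; the mGOS category is then drawn from an
#' empirical upgrade/non-upgrade profile consistent with the subject's
#' baseline group (UWS baseline VS; MCS baseline MCS; death only as a
#' non-improvement).
#'
#' @param subject One-row subject data frame (needs `group`).
#' @param entropy_features Named numeric vector of predictor values
#'   (`"CRS-R"` plus channel/pair responses).
#' @param coefficients Named numeric vector with an `intercept` entry;
#'   remaining names must be present in `entropy_features`.
#' @return List with `improved` (0/1), `mgos_12m` (category string) and
#'   `p` (the clamped probability, with attribute `clamped`).
#' @export
generate_outcome <- function(subject, entropy_features, coefficients) {
  stopifnot("intercept" %in% names(coefficients))
  nm <- setdiff(names(coefficients), "intercept")
  missing <- setdiff(nm, names(entropy_features))
  if (length(missing))
    stop("outcome coefficients name unknown predictors: ",
         paste(missing, collapse = ", "))
  p <- unname(coefficients["intercept"] +
                sum(coefficients[nm] * entropy_features[nm]))
  clamped <- p < 0 || p > 1
  p_used <- min(max(p, 0), 1)
  improved <- rbinom(1, 1, p_used)

  group <- subject$group
  prof <- if (group == "UWS") {
    if (improved == 1) c(MCS = 12, severe = 13)
    else c(death = 1, VS = 72)
  } else {
    if (improved == 1) c(severe = 35, moderate = 5, good = 2)
    else c(MCS = 1)
  }
  mgos <- sample(names(prof), 1L, prob = prof)
  list(improved = improved, mgos_12m = mgos,
       p = structure(p_used, clamped = clamped))
}

#' Generate a synthetic cohort
#'
#' Draws `n_uws + n_mcs` subjects with per-condition recordings. Purely a
#' function of the configuration: the same config (including seed)
#' reproduces bit-identical metadata and signals, and each subject's stream
#' is independent of cohort ordering.
#'
#' @param config A [cohort_config()].
#' @param signals If `FALSE`, skip signal rendering (fast; metadata and
#'   latent features only).
#' @return An object of class `doc_cohort`: list with `subjects` (data
#'   frame), `features` (wide data frame of latent pain-minus-rest responses
#'   and CRS-R), `recordings` (per-subject condition lists, or `NULL`) and
#'   `config`.
#' @export
generate_cohort <- function(config, signals = TRUE) {
  cfg <- if (inherits(config, "cohort_config")) config
         else do.call(cohort_config, config)
  groups <- c(rep("UWS", cfg$n_uws), rep("MCS", cfg$n_mcs))
  n <- length(groups)
  subs <- vector("list", n)
  feats <- vector("list", n)
  recs <- if (signals) vector("list", n) else NULL
  n_clamped <- 0L
  for (i in seq_len(n)) {
    s <- generate_subject(cfg, groups[i], idx = i, signals = signals)
    subs[[i]] <- s$record
    feats[[i]] <- s$features
    if (signals) recs[[i]] <- s$recordings
  }
  subjects <- do.call(rbind, subs)
  features <- as.data.frame(do.call(rbind, feats), check.names = FALSE)
  features <- cbind(subject_id = subjects$subject_id, features)
  rownames(features) <- NULL
  if (signals) names(recs) <- subjects$subject_id
  structure(list(subjects = subjects, features = features,
                 recordings = recs, config = cfg),
            class = "doc_cohort")
}

#' @export
print.doc_cohort <- function(x, ...) {
  tab <- table(x$subjects$group)
  cat(sprintf("Synthetic DOC cohort: %d subjects (UWS %d, MCS %d), %s\n",
              nrow(x$subjects), tab[["UWS"]], tab[["MCS"]],
              if (is.null(x$recordings)) "metadata only"
              else sprintf("recordings %d samples @ %g Hz",
                           x$config$epoch_len, x$config$fs)))
  invisible(x)
}

#' Inject amplitude spikes into a recording
#'
#' Test utility for the artifact-rejection stage: adds short rectangular
#' spikes of the given amplitude at the requested sample positions.
#'
#' @param rec An [eeg_recording()].
#' @param at Integer sample positions (1-based).
#' @param amplitude_uv Spike amplitude in microvolts (default 500).
#' @param channels Channel indices receiving the spikes (default 1).
#' @param width Spike width in samples (default 5).
#' @return The modified recording.
#' @export
inject_spikes <- function(rec, at, amplitude_uv = 500, channels = 1L,
                          width = 5L) {
  for (a in at) {
    idx <- a:min(a + width - 1L, ncol(rec$data))
    rec$data[channels, idx] <- rec$data[channels, idx] + amplitude_uv
  }
  rec
}
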