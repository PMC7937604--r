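test_that("cohort config validates its invariants", {
  expect_s3_class(cohort_config(), "cohort_config")
  expect_error(cohort_config(epoch_len = 500))
  expect_error(cohort_config(n_uws = 0))
  expect_error(cohort_config(irregularity_uws = 1.4))
  expect_error(cohort_config(coupling_uws = -0.1))
  expect_error(cohort_config(diagnosis_mix = c(TBI = 0.6, stroke = 0.6,
                                               other = 0.1)))
})

test_that("channel signal rejects invalid parameters and has exact length", {
  expect_error(generate_channel_signal(-0.1, 1024), "irregularity")
  expect_error(generate_channel_signal(NaN, 1024), "irregularity")
  x <- generate_channel_signal(0.4, 32768, fs = 500, seed = 1)
  expect_length(x, 32768)
  expect_equal(length(x) / 500, 65.536)   # the analysis-window duration
  expect_lt(abs(mean(x)), 1e-9)
})

test_that("ApEn increases monotonically with the irregularity parameter", {
  means <- vapply(c(0.2, 0.5, 0.8), function(irr) {
    mean(vapply(1:20, function(s)
      apen(generate_channel_signal(irr, 1024, seed = 1000 + s)),
      numeric(1)))
  }, numeric(1))
  expect_lt(means[1], means[2])
  expect_lt(means[2], means[3])
  # endpoint ordering on a shared seed
  expect_lt(apen(generate_channel_signal(0, 2048, seed = 3)),
            apen(generate_channel_signal(1, 2048, seed = 3)))
})

test_that("cohort generation is a pure function of its config", {
  args <- tiny_cohort_args(2, 2)
  a <- generate_cohort(do.call(cohort_config, args))
  b <- generate_cohort(do.call(cohort_config, args))
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$recordings[["S001"]]$pain$data,
                   b$recordings[["S001"]]$pain$data)
  # different seed: same schema, different signals
  c2 <- generate_cohort(do.call(cohort_config, tiny_cohort_args(2, 2,
                                                                seed = 43)))
  expect_identical(dim(a$recordings[["S001"]]$pain$data),
                   dim(c2$recordings[["S001"]]$pain$data))
  expect_false(identical(a$recordings[["S001"]]$pain$data,
                         c2$recordings[["S001"]]$pain$data))
  expect_equal(nrow(a$subjects), 4)
})

test_that("a subject's draw does not depend on cohort composition", {
  cfg <- do.call(cohort_config, tiny_cohort_args(3, 3))
  s5a <- generate_subject(cfg, "MCS", idx = 5, signals = FALSE)
  junk <- generate_subject(cfg, "UWS", idx = 2, signals = FALSE)
  s5b <- generate_subject(cfg, "MCS", idx = 5, signals = FALSE)
  expect_identical(s5a$record, s5b$record)
  expect_identical(s5a$features, s5b$features)
})

test_that("zero pain gains make both conditions draws of one process", {
  args <- tiny_cohort_args(4, 4, epoch_len = 1024,
                           pain_gain_unaffected = 0, pain_gain_affected = 0,
                           pain_subject_sd = 0, pain_channel_sd = 0)
  coh <- generate_cohort(do.call(cohort_config, args), signals = FALSE)
  chans <- relabeled_channels()
  diffs <- as.matrix(coh$features[, chans])
  expect_true(all(abs(diffs) < 1e-12))
})

test_that("MCS pain response on unaffected channels exceeds UWS in expectation", {
  cfg <- do.call(cohort_config, tiny_cohort_args(1, 1))
  chans_u <- grep("_U$", relabeled_channels(), value = TRUE)
  d <- vapply(1:30, function(i) {
    u <- generate_subject(cfg, "UWS", idx = i, signals = FALSE)
    m <- generate_subject(cfg, "MCS", idx = 1000 + i, signals = FALSE)
    mean(m$features[chans_u]) - mean(u$features[chans_u])
  }, numeric(1))
  expect_gt(mean(d), 0)
  expect_gt(t.test(d)$statistic, 2)
})

test_that("fully coupled noise channels are identical series", {
  set.seed(8)
  latent <- band_noise(1024, 500)
  x1 <- generate_channel_signal(1, 1024, noise = latent)
  x2 <- generate_channel_signal(1, 1024, noise = latent)
  expect_identical(x1, x2)
  z <- (x1 - mean(x1)) / sd(x1)
  expect_identical(as.numeric(capen(x1, x2)), apen(z))
})

test_that("outcome model respects its probability and upgrade rules", {
  subj_uws <- data.frame(group = "UWS")
  subj_mcs <- data.frame(group = "MCS")
  # intercept-only model at 0.5
  set.seed(11)
  rate <- mean(vapply(1:1000, function(i)
    generate_outcome(subj_uws, c("CRS-R" = 5), c(intercept = 0.5))$improved,
    numeric(1)))
  expect_gt(rate, 0.45); expect_lt(rate, 0.55)
  # strong CRS-R effect raises CRS-R among improved subjects
  set.seed(12)
  crs <- runif(1000, 0, 23)
  imp <- vapply(seq_along(crs), function(i)
    generate_outcome(subj_uws, c("CRS-R" = crs[i]),
                     c(intercept = 0, "CRS-R" = 1 / 23))$improved,
    numeric(1))
  expect_gt(mean(crs[imp == 1]), mean(crs[imp == 0]))
  # upgrade rule: categories consistent with the improvement indicator
  lv <- mgos_categories()
  for (i in 1:40) {
    o <- generate_outcome(subj_uws, c("CRS-R" = 5),
                          c(intercept = i %% 2))
    if (o$improved == 1) expect_gt(match(o$mgos_12m, lv), match("VS", lv))
    else expect_lte(match(o$mgos_12m, lv), match("VS", lv))
    o <- generate_outcome(subj_mcs, c("CRS-R" = 5),
                          c(intercept = i %% 2))
    if (o$improved == 1) expect_gt(match(o$mgos_12m, lv), match("MCS", lv))
    else expect_lte(match(o$mgos_12m, lv), match("MCS", lv))
  }
  # out-of-range probabilities are clamped and flagged
  o <- generate_outcome(subj_uws, c("CRS-R" = 23),
                        c(intercept = 0.9, "CRS-R" = 0.1))
  expect_identical(as.numeric(o$p), 1)
  expect_true(attr(o$p, "clamped"))
  expect_error(generate_outcome(subj_uws, c(x = 1),
                                c(intercept = 0, y = 2)),
               "unknown predictors")
})

test_that("cohort sizes and metadata schema match the configuration", {
  coh <- generate_cohort(do.call(cohort_config,
                                 tiny_cohort_args(5, 3)), signals = FALSE)
  expect_equal(table(coh$subjects$group)[["UWS"]], 5)
  expect_equal(table(coh$subjects$group)[["MCS"]], 3)
  expect_true(all(c("subject_id", "group", "age", "sex", "duration",
                    "diagnosis", "crs_r", "affected_side", "mgos_12m") %in%
                    colnames(coh$subjects)))
  expect_true(all(coh$subjects$duration > 0))
  expect_true(all(coh$subjects$crs_r >= 0 & coh$subjects$crs_r <= 23))
  expect_true(all(coh$subjects$mgos_12m %in% mgos_categories()))
})

test_that("MCS CRS-R scores stochastically dominate UWS scores", {
  coh <- generate_cohort(do.call(cohort_config,
                                 tiny_cohort_args(200, 200)),
                         signals = FALSE)
  q_u <- quantile(coh$subjects$crs_r[coh$subjects$group == "UWS"],
                  c(0.25, 0.5, 0.75))
  q_m <- quantile(coh$subjects$crs_r[coh$subjects$group == "MCS"],
                  c(0.25, 0.5, 0.75))
  expect_true(all(q_m >= q_u))
  expect_gt(mean(coh$subjects$crs_r[coh$subjects$group == "MCS"]),
            mean(coh$subjects$crs_r[coh$subjects$group == "UWS"]))
})

test_that("per-side pain mode returns the optional second epoch", {
  cfg <- do.call(cohort_config, tiny_cohort_args(1, 1,
                                                 pain_mode = "per_side"))
  s <- generate_subject(cfg, "UWS", idx = 1)
  expect_true(all(c("pain_affected_leg", "pain_unaffected_leg") %in%
                    names(s$recordings)))
})
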