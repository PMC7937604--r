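test_that("improvement is a strict upgrade over the baseline category", {
  expect_identical(classify_improvement("UWS", "severe"), 1L)
  expect_identical(classify_improvement("UWS", "VS"), 0L)
  expect_identical(classify_improvement("UWS", "death"), 0L)
  expect_identical(classify_improvement("MCS", "MCS"), 0L)
  expect_identical(classify_improvement("MCS", "severe"), 1L)
  expect_identical(classify_improvement("MCS", "death"), 0L)
  expect_error(classify_improvement("UWS", "cured"), "unknown")
  # monotone in the outcome scale
  for (g in c("UWS", "MCS")) {
    lab <- classify_improvement(rep(g, 6), mgos_categories())
    expect_true(all(diff(lab) >= 0))
  }
})

test_that("outcome summaries reproduce count-and-percentage arithmetic", {
  g <- c(rep("UWS", 10), rep("MCS", 4))
  l <- c(rep(1, 3), rep(0, 7), rep(1, 3), 0)
  s <- outcome_summary(l, g)
  expect_equal(s$improved[s$group == "UWS"], 3)
  expect_equal(s$pct[s$group == "UWS"], 30)
  expect_equal(s$pct[s$group == "MCS"], 75)
  s0 <- outcome_summary(rep(0, 14), g)
  expect_true(all(s0$improved == 0) && all(s0$pct == 0))
})

test_that("design matrices have the reported column structure", {
  coh <- generate_cohort(cohort_config(n_uws = 98, n_mcs = 64, seed = 2),
                         signals = FALSE)
  X <- build_design_matrix(coh$subjects, coh$features, "apen_affected")
  expect_equal(dim(X), c(162, 14))      # + intercept = 15 parameters
  Xc <- build_design_matrix(coh$subjects, coh$features, "capen_unaffected")
  expect_equal(ncol(Xc), 11)            # + intercept = 12 parameters
  expect_true(all(c("sex", "age", "duration", "TBI", "stroke", "crs_r")
                  %in% colnames(X)))
  expect_true(all(grepl("_A$", setdiff(colnames(X),
                                       c("sex", "age", "duration", "TBI",
                                         "stroke", "crs_r")))))
})

test_that("exhaustive diagnosis coding is reported as rank deficiency", {
  coh <- generate_cohort(
    cohort_config(n_uws = 30, n_mcs = 30, seed = 3,
                  diagnosis_mix = c(TBI = 0.5, stroke = 0.5, other = 0)),
    signals = FALSE)
  expect_error(build_design_matrix(coh$subjects, coh$features,
                                   "apen_affected"),
               "rank deficient.*(TBI|stroke|Intercept)")
})

test_that("noiseless labels are interpolated exactly", {
  coh <- generate_cohort(cohort_config(n_uws = 40, n_mcs = 40, seed = 4),
                         signals = FALSE)
  X <- build_design_matrix(coh$subjects, coh$features, "apen_affected")
  labels <- X$sex                       # deterministic 0/1 function of X
  fit <- suppressWarnings(fit_improvement_model(X, labels))
  expect_equal(unname(coef(fit)["sex"]), 1, tolerance = 1e-8)
  expect_equal(unname(coef(fit)["(Intercept)"]), 0, tolerance = 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-8)
})

test_that("OLS output matches an independent pseudo-inverse solution", {
  coh <- generate_cohort(cohort_config(n_uws = 50, n_mcs = 50, seed = 5),
                         signals = FALSE)
  X <- build_design_matrix(coh$subjects, coh$features, "capen_affected")
  labels <- classify_improvement(coh$subjects$group,
                                 coh$subjects$mgos_12m)
  labels <- labels[match(rownames(X), coh$subjects$subject_id)]
  fit <- fit_improvement_model(X, labels)

  Xm <- cbind(1, as.matrix(X))
  sv <- svd(Xm)
  beta <- sv$v %*% ((t(sv$u) %*% labels) / sv$d)
  expect_equal(unname(coef(fit)), drop(beta), tolerance = 1e-8)
  # residual-df identity
  expect_equal(fit$df_residual, nrow(X) - ncol(X) - 1L)
  # summary table is consistent with the estimates
  expect_equal(fit$table$estimate, unname(coef(fit)), tolerance = 1e-12)
  expect_equal(fit$table$t, fit$table$estimate / fit$table$std_error,
               tolerance = 1e-9)
})

test_that("logistic alternative is available behind a flag", {
  coh <- generate_cohort(cohort_config(n_uws = 60, n_mcs = 60, seed = 6),
                         signals = FALSE)
  X <- build_design_matrix(coh$subjects, coh$features, "capen_unaffected")
  labels <- classify_improvement(coh$subjects$group, coh$subjects$mgos_12m)
  labels <- labels[match(rownames(X), coh$subjects$subject_id)]
  fit <- fit_improvement_model(X, labels, method = "logistic")
  expect_s3_class(fit$fit, "glm")
  expect_equal(fit$df_residual, nrow(X) - ncol(X) - 1L)
})

test_that("response features carry differences or pain levels", {
  coh <- generate_cohort(do.call(cohort_config, tiny_cohort_args(2, 2)))
  pre <- lapply(names(coh$recordings), function(sid) {
    m <- montage_map(coh$subjects$affected_side[coh$subjects$subject_id ==
                                                  sid])
    lapply(coh$recordings[[sid]], remap_montage, map = m)
  })
  names(pre) <- names(coh$recordings)
  p <- apen_params(n_points = 1024)
  at <- apen_matrix(pre, p)
  ct <- capen_pairs(pre, params = p)
  fd <- response_features(at, ct$pairs, source = "difference")
  fl <- response_features(at, ct$pairs, source = "pain_level")
  expect_equal(nrow(fd), 4)
  expect_true(all(relabeled_channels() %in% colnames(fd)))
  expect_true(all(pair_spec()$all %in% colnames(fd)))
  s1 <- at[at$subject_id == "S001" & at$channel == "C_A", ]
  expect_equal(fd$C_A[fd$subject_id == "S001"],
               s1$apen[s1$condition == "pain"] -
                 s1$apen[s1$condition == "eyes_closed"])
  expect_equal(fl$C_A[fl$subject_id == "S001"],
               s1$apen[s1$condition == "pain"])
})
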