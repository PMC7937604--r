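make_levels_table <- function(values_by_subject, measure = "M1") {
  do.call(rbind, lapply(names(values_by_subject), function(sid)
    data.frame(subject_id = sid, measure = measure,
               value = values_by_subject[[sid]],
               stringsAsFactors = FALSE)))
}

test_that("condition differences are pain minus eyes-closed per subject", {
  tbl <- expand.grid(subject_id = c("a", "b"),
                     condition = c("eyes_closed", "pain"),
                     channel = c("C_A", "C_U"),
                     stringsAsFactors = FALSE)
  tbl$apen <- ifelse(tbl$condition == "pain", 0.7, 0.6)
  d <- condition_difference(tbl)
  expect_equal(nrow(d), 4)
  expect_true(all(abs(d$difference - 0.1) < 1e-12))

  # identical conditions give zero differences
  tbl$apen <- 0.5
  expect_true(all(condition_difference(tbl)$difference == 0))

  # a subject with one condition is dropped with a message
  tbl2 <- tbl[!(tbl$subject_id == "b" & tbl$condition == "pain"), ]
  expect_message(d2 <- condition_difference(tbl2), "b")
  expect_setequal(unique(d2$subject_id), "a")

  # single subject: one row per measure
  one <- tbl[tbl$subject_id == "a", ]
  expect_equal(nrow(suppressMessages(condition_difference(one))), 2)
})

test_that("per-measure t tests separate shifted groups and flag degenerate ones", {
  set.seed(21)
  groups <- data.frame(subject_id = sprintf("s%02d", 1:40),
                       group = rep(c("UWS", "MCS"), each = 20))
  x <- rnorm(20)
  vals <- make_levels_table(stats::setNames(as.list(c(x, x + 5)),
                                            groups$subject_id))
  r <- ttest_by_measure(vals, groups)
  expect_lt(r$p, 0.001)
  expect_equal(r$mean_mcs - r$mean_uws, 5, tolerance = 1e-9)
  expect_equal(r$n_uws, 20)

  # identical values in both groups: degenerate, flagged
  vals0 <- make_levels_table(stats::setNames(as.list(rep(1, 40)),
                                             groups$subject_id))
  r0 <- ttest_by_measure(vals0, groups)
  expect_identical(r0$flag, "degenerate")
  expect_true(is.na(r0$p))

  # same values in both groups with nonzero variance: t = 0
  vals1 <- make_levels_table(stats::setNames(as.list(c(x, x)),
                                             groups$subject_id))
  r1 <- ttest_by_measure(vals1, groups)
  expect_equal(r1$t, 0, tolerance = 1e-12)

  # pooled variant agrees with stats::t.test(var.equal = TRUE)
  vals2 <- make_levels_table(stats::setNames(as.list(rnorm(40)),
                                             groups$subject_id))
  r2 <- ttest_by_measure(vals2, groups, var_equal = TRUE)
  ref <- t.test(vals2$value[21:40], vals2$value[1:20], var.equal = TRUE)
  expect_equal(r2$t, unname(ref$statistic), tolerance = 1e-9)
})

test_that("Welch t test holds its nominal size under the null", {
  set.seed(31)
  rej <- mean(vapply(1:400, function(i) {
    t.test(rnorm(30), rnorm(30))$p.value < 0.05
  }, logical(1)))
  expect_gt(rej, 0.02); expect_lt(rej, 0.09)
})

test_that("Hotelling reduces to the squared pooled t at k = 1", {
  set.seed(41)
  x <- matrix(rnorm(40), ncol = 1)
  g <- rep(c("A", "B"), each = 20)
  h <- hotelling_two_sample(x, g)
  tt <- t.test(x[g == "A"], x[g == "B"], var.equal = TRUE)
  expect_equal(h$F, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(h$p, tt$p.value, tolerance = 1e-9)
})

test_that("Hotelling matches a direct matrix-algebra computation", {
  set.seed(42)
  n1 <- 8; n2 <- 7; k <- 3
  x <- rbind(matrix(rnorm(n1 * k), n1), matrix(rnorm(n2 * k, 0.5), n2))
  g <- rep(c("A", "B"), c(n1, n2))
  h <- hotelling_two_sample(x, g)
  d <- colMeans(x[1:n1, ]) - colMeans(x[-(1:n1), ])
  sp <- ((n1 - 1) * var(x[1:n1, ]) + (n2 - 1) * var(x[-(1:n1), ])) /
    (n1 + n2 - 2)
  t2 <- (n1 * n2 / (n1 + n2)) * drop(t(d) %*% solve(sp, d))
  expect_equal(h$T2, t2, tolerance = 1e-9)
  expect_equal(h$df2, n1 + n2 - k - 1)
})

test_that("Hotelling T2 is invariant under invertible linear maps", {
  set.seed(43)
  x <- matrix(rnorm(60 * 4), 60)
  g <- rep(c("A", "B"), each = 30)
  a <- matrix(rnorm(16), 4) + diag(4)
  y <- x %*% a + matrix(rep(rnorm(4), each = 60), 60)
  expect_equal(hotelling_two_sample(x, g)$T2,
               hotelling_two_sample(y, g)$T2, tolerance = 1e-9)
})

test_that("Hotelling validates group sizes and covariance rank", {
  x <- matrix(rnorm(40), ncol = 5)
  expect_error(hotelling_two_sample(x, rep(c("A", "B"), each = 4)),
               "more subjects than measures")
  x2 <- matrix(rnorm(60), ncol = 2)
  x2 <- cbind(x2, x2[, 1])       # aliased measure
  expect_error(hotelling_two_sample(x2, rep(c("A", "B"), each = 15)),
               "singular")
})

test_that("comparison tables use the clinical star convention", {
  expect_identical(signif_stars(c(0.004, 0.03, 0.07, 0.2)),
                   c("***", "**", "*", ""))
  r <- data.frame(measure = "C_A", mean_uws = 0.601, sd_uws = 0.08,
                  mean_mcs = 0.671, sd_mcs = 0.11, p = 0.004)
  tab <- render_comparison_tables(r)
  expect_match(tab$UWS, "0.60 ± 0.08", fixed = TRUE)
  expect_match(tab$p, "0.004\\*\\*\\*")
  r$p <- 2e-5
  expect_match(render_comparison_tables(r)$p, "<0.001\\*\\*\\*")
})

test_that("cohort description reports demographic comparisons", {
  coh <- generate_cohort(do.call(cohort_config, tiny_cohort_args(40, 40)),
                         signals = FALSE)
  desc <- describe_cohort(coh$subjects)
  expect_true(all(c("age", "duration", "sex", "diagnosis", "mgos_12m") %in%
                    names(desc)))
  expect_true(desc$age$p > 0 && desc$age$p <= 1)
  expect_s3_class(desc$diagnosis$counts, "table")
})
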