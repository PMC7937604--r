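#' Pain-minus-rest condition differences
#'
#' Per-subject differences between the pain-stimulation and eyes-closed
#' values of each measure (channel ApEn or pair C-ApEn). Subjects missing a
#' condition are dropped with a message.
#'
#' @param tbl Long table with columns `subject_id`, `condition`, a measure
#'   name column (`channel` or `pair`), and a value column (`apen` or
#'   `capen`).
#' @return Data frame with columns `subject_id`, `measure`, `difference`.
#' @export
condition_difference <- function(tbl) {
  mcol <- intersect(c("channel", "pair"), colnames(tbl))[1]
  vcol <- intersect(c("apen", "capen", "value"), colnames(tbl))[1]
  if (is.na(mcol) || is.na(vcol))
    stop("expected an entropy table with channel/pair and apen/capen columns")
  wide_pain <- tbl[tbl$condition == "pain", c("subject_id", mcol, vcol)]
  wide_rest <- tbl[tbl$condition == "eyes_closed", c("subject_id", mcol, vcol)]
  m <- merge(wide_rest, wide_pain, by = c("subject_id", mcol),
             suffixes = c("_rest", "_pain"))
  complete <- table(m$subject_id)
  n_meas <- length(unique(tbl[[mcol]]))
  drop <- names(complete)[complete < n_meas]
  incomplete <- setdiff(unique(tbl$subject_id), unique(m$subject_id))
  drop <- union(drop, incomplete)
  if (length(drop)) {
    message("dropping subjects without both conditions: ",
            paste(drop, collapse = ", "))
    m <- m[!(m$subject_id %in% drop), ]
  }
  out <- data.frame(subject_id = m$subject_id, measure = m[[mcol]],
                    difference = m[[paste0(vcol, "_pain")]] -
                      m[[paste0(vcol, "_rest")]],
                    stringsAsFactors = FALSE)
  out[order(out$subject_id, out$measure), , drop = FALSE]
}

#' Per-measure two-sample t tests
#'
#' Welch (default) or pooled two-sample t test of UWS vs MCS for each
#' measure, with per-group mean and SD in the clinical-table layout. The t
#' statistic is signed as MCS minus UWS.
#'
#' @param values Long data frame with `subject_id`, `measure`, and a value
#'   column (`difference` or `value`).
#' @param groups Data frame with `subject_id` and `group` (`UWS`/`MCS`).
#' @param var_equal Use the pooled-variance t test instead of Welch.
#' @return Data frame: one row per measure with group n/mean/sd, `t`, `df`,
#'   `p`, and `flag` (`"degenerate"` when both groups have zero variance).
#' @export
ttest_by_measure <- function(values, groups, var_equal = FALSE) {
  vcol <- intersect(c("difference", "value"), colnames(values))[1]
  if (is.na(vcol)) stop("no value column (difference/value) found")
  v <- merge(values, groups[, c("subject_id", "group")], by = "subject_id")
  rows <- lapply(split(v, v$measure), function(d) {
    x <- d[[vcol]][d$group == "UWS"]
    y <- d[[vcol]][d$group == "MCS"]
    if (length(x) < 2L || length(y) < 2L)
      stop("need at least 2 subjects per group")
    base <- data.frame(measure = d$measure[1],
                       n_uws = length(x), n_mcs = length(y),
                       mean_uws = mean(x), sd_uws = sd(x),
                       mean_mcs = mean(y), sd_mcs = sd(y),
                       stringsAsFactors = FALSE)
    tt <- tryCatch(t.test(y, x, var.equal = var_equal),
                   error = function(e) NULL)
    if (is.null(tt)) {
      base$t <- NA_real_; base$df <- NA_real_; base$p <- NA_real_
      base$flag <- "degenerate"
    } else {
      base$t <- unname(tt$statistic)
      base$df <- unname(tt$parameter)
      base$p <- tt$p.value
      base$flag <- ""
    }
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Two-sample Hotelling T-squared test
#'
#' Multivariate comparison of the k-dimensional mean vectors of two groups,
#' the correction for multiple comparisons used over channel blocks:
#' \deqn{T^2 = \frac{n_1 n_2}{n_1 + n_2}
#'   (\bar x_1 - \bar x_2)' S_p^{-1} (\bar x_1 - \bar x_2)}
#' with pooled covariance \eqn{S_p}, transformed to
#' \eqn{F = \frac{n_1 + n_2 - k - 1}{k (n_1 + n_2 - 2)} T^2}
#' on \eqn{(k,\; n_1 + n_2 - k - 1)} degrees of freedom. Both the T-squared
#' and F statistics are reported.
#'
#' @param x Numeric matrix, subjects x k measures.
#' @param groups Factor or character vector of length `nrow(x)` with two
#'   levels.
#' @return Object of class `hotelling_test`: list with `T2`, `F`, `df1`,
#'   `df2`, `p`, `k`, `n1`, `n2`.
#' @export
hotelling_two_sample <- function(x, groups) {
  x <- as.matrix(x)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop("exactly two groups required")
  g1 <- x[groups == levels(groups)[1], , drop = FALSE]
  g2 <- x[groups == levels(groups)[2], , drop = FALSE]
  k <- ncol(x)
  n1 <- nrow(g1); n2 <- nrow(g2)
  if (n1 <= k || n2 <= k)
    stop("need more subjects than measures in each group (k = ", k, ")")
  d <- colMeans(g1) - colMeans(g2)
  sp <- ((n1 - 1) * stats::cov(g1) + (n2 - 1) * stats::cov(g2)) /
    (n1 + n2 - 2)
  si <- tryCatch(solve(sp), error = function(e)
    stop("pooled covariance is singular; drop collinear measures or add a ",
         "ridge before testing"))
  t2 <- (n1 * n2 / (n1 + n2)) * drop(t(d) %*% si %*% d)
  df1 <- k
  df2 <- n1 + n2 - k - 1
  f <- df2 / (k * (n1 + n2 - 2)) * t2
  structure(list(T2 = t2, F = f, df1 = df1, df2 = df2,
                 p = pf(f, df1, df2, lower.tail = FALSE),
                 k = k, n1 = n1, n2 = n2),
            class = "hotelling_test")
}

#' @export
print.hotelling_test <- function(x, ...) {
  cat(sprintf(
    "Two-sample Hotelling test: T2 = %.4g, F(%d, %d) = %.4g, p = %.4g\n",
    x$T2, x$df1, x$df2, x$F, x$p))
  invisible(x)
}

#' Significance stars for comparison tables
#'
#' Footnote convention of the clinical tables: `*` for p < 0.1, `**` for
#' p < 0.05, `***` for p < 0.01.
#'
#' @param p Numeric vector of p values.
#' @return Character vector of star strings.
#' @export
signif_stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.01, "***", ifelse(p < 0.05, "**",
                                        ifelse(p < 0.1, "*", ""))))
}

#' Render a group-comparison table
#'
#' Formats [ttest_by_measure()] output in the clinical layout: one row per
#' measure with "mean +/- SD" per group and the p value with significance
#' stars.
#'
#' @param results Data frame from [ttest_by_measure()].
#' @param digits Decimals for means and SDs (default 2).
#' @return Data frame with columns `measure`, `UWS`, `MCS`, `p`.
#' @export
render_comparison_tables <- function(results, digits = 2) {
  fmt <- function(m, s) sprintf("%.*f ± %.*f", digits, m, digits, s)
  data.frame(
    measure = results$measure,
    UWS = fmt(results$mean_uws, results$sd_uws),
    MCS = fmt(results$mean_mcs, results$sd_mcs),
    p = ifelse(is.na(results$p), "NA",
               paste0(ifelse(results$p < 0.001, "<0.001",
                             sprintf("%.3f", results$p)),
                      signif_stars(results$p))),
    stringsAsFactors = FALSE)
}

#' Cohort demographics table
#'
#' Table-1-style cohort description: t tests for age and duration,
#' chi-squared tests for sex and diagnosis, and the per-group 12-month mGOS
#' median (range).
#'
#' @param subjects Subject metadata data frame (needs `group`, `age`,
#'   `duration`, `sex`, `diagnosis`, and optionally `mgos_12m`).
#' @return List of comparison entries.
#' @export
describe_cohort <- function(subjects) {
  s <- subjects
  out <- list()
  for (v in c("age", "duration")) {
    tt <- t.test(s[[v]][s$group == "MCS"], s[[v]][s$group == "UWS"])
    out[[v]] <- data.frame(
      variable = v,
      UWS = sprintf("%.1f ± %.1f", mean(s[[v]][s$group == "UWS"]),
                    sd(s[[v]][s$group == "UWS"])),
      MCS = sprintf("%.1f ± %.1f", mean(s[[v]][s$group == "MCS"]),
                    sd(s[[v]][s$group == "MCS"])),
      p = tt$p.value, stringsAsFactors = FALSE)
  }
  for (v in c("sex", "diagnosis")) {
    tab <- table(s[[v]], s$group)
    ct <- suppressWarnings(chisq.test(tab))
    out[[v]] <- list(counts = tab, p = ct$p.value)
  }
  if ("mgos_12m" %in% colnames(s)) {
    code <- match(s$mgos_12m, mgos_levels())
    out$mgos_12m <- vapply(c("UWS", "MCS"), function(g) {
      x <- code[s$group == g]
      sprintf("%d (%d-%d)", round(median(x)), min(x), max(x))
    }, character(1))
  }
  out
}
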