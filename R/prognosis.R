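# 12-month outcome classification and prognostic regression.
#
# Outcome scale: modified Glasgow Outcome Scale (mGOS), six ordered
# categories death < VS < MCS < severe < moderate < good. Improvement is a
# strict upgrade from the baseline category (VS for UWS subjects, MCS for
# MCS subjects). The prognostic model is a linear probability model: OLS of
# the 0/1 improvement indicator on demographics, CRS-R and the entropy
# responses of one channel/pair block.

#' mGOS categories
#'
#' The six ordered outcome categories, worst to best.
#'
#' @return Character vector `death, VS, MCS, severe, moderate, good`.
#' @export
mgos_categories <- function() mgos_levels()

#' Classify 12-month improvement
#'
#' Improvement is a strict upgrade of the 12-month mGOS category over the
#' baseline category implied by the admission diagnosis (VS for UWS
#' subjects, MCS for MCS subjects). Death is never an improvement.
#'
#' @param group Character vector of baseline groups (`UWS`/`MCS`).
#' @param mgos_12m Character vector of 12-month categories (see
#'   [mgos_categories()]).
#' @return Integer vector: 1 = improved, 0 = not improved.
#' @export
classify_improvement <- function(group, mgos_12m) {
  lv <- mgos_levels()
  code <- match(mgos_12m, lv)
  if (anyNA(code))
    stop("unknown mGOS categories: ",
         paste(unique(mgos_12m[is.na(code)]), collapse = ", "))
  baseline <- ifelse(group == "UWS", match("VS", lv), match("MCS", lv))
  as.integer(code > baseline)
}

#' Per-group improvement summary
#'
#' Improved count and percentage (rounded to the nearest integer) per
#' baseline group.
#'
#' @param labels 0/1 improvement labels from [classify_improvement()].
#' @param groups Baseline group per subject.
#' @return Data frame with `group`, `n`, `improved`, `pct`.
#' @export
outcome_summary <- function(labels, groups) {
  out <- do.call(rbind, lapply(unique(groups), function(g) {
    n <- sum(groups == g)
    k <- sum(labels[groups == g])
    data.frame(group = g, n = n, improved = k, pct = round(100 * k / n),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# predictor blocks of the four regression designs
model_blocks <- function() {
  sp <- pair_spec()
  list(
    apen_affected = relabeled_channels()[grepl("_A$", relabeled_channels())],
    apen_unaffected = relabeled_channels()[grepl("_U$",
                                                 relabeled_channels())],
    capen_affected = c(sp$local_affected, sp$distant_affected),
    capen_unaffected = c(sp$local_unaffected, sp$distant_unaffected))
}

#' Wide entropy-response features per subject
#'
#' Reshapes the long entropy tables into one row per subject with a column
#' per channel and pair, holding either the pain-minus-rest difference
#' (default; the quantity interpreted as activation under pain stimulation)
#' or the raw pain-condition level.
#'
#' @param apen_tbl Long channel table from [apen_matrix()].
#' @param capen_tbl Long pair table (`$pairs` from [capen_pairs()]).
#' @param source `"difference"` or `"pain_level"`.
#' @return Wide data frame keyed by `subject_id`.
#' @export
response_features <- function(apen_tbl, capen_tbl,
                              source = c("difference", "pain_level")) {
  source <- match.arg(source)
  get_wide <- function(tbl) {
    mcol <- intersect(c("channel", "pair"), colnames(tbl))[1]
    vcol <- intersect(c("apen", "capen"), colnames(tbl))[1]
    if (source == "difference") {
      d <- condition_difference(tbl)
      stats::reshape(d, idvar = "subject_id", timevar = "measure",
                     direction = "wide")
    } else {
      d <- tbl[tbl$condition == "pain", c("subject_id", mcol, vcol)]
      names(d) <- c("subject_id", "measure", "difference")
      stats::reshape(d, idvar = "subject_id", timevar = "measure",
                     direction = "wide")
    }
  }
  a <- get_wide(apen_tbl)
  names(a) <- sub("^difference\\.", "", names(a))
  b <- get_wide(capen_tbl)
  names(b) <- sub("^difference\\.", "", names(b))
  out <- merge(a, b, by = "subject_id")
  rownames(out) <- NULL
  out
}

#' Build a prognostic design matrix
#'
#' Assembles the regression design of one model: intercept, sex (male = 1),
#' age, duration, diagnosis dummies (TBI and stroke against an "other"
#' reference), CRS-R, and the model's entropy block (8 channels for the
#' ApEn designs, 5 pairs for the C-ApEn designs). A full-rank check names
#' any aliased columns.
#'
#' @param meta Subject metadata (needs `subject_id`, `sex`, `age`,
#'   `duration`, `diagnosis`, `crs_r`).
#' @param features Wide response table from [response_features()] (or the
#'   `features` element of a synthetic cohort).
#' @param model One of `"apen_affected"`, `"apen_unaffected"`,
#'   `"capen_affected"`, `"capen_unaffected"`.
#' @return Data frame of predictors (without intercept; the fit adds it),
#'   with attributes `predictors` and `model`; `subject_id` kept as row
#'   names.
#' @export
build_design_matrix <- function(meta, features,
                                model = c("apen_affected", "apen_unaffected",
                                          "capen_affected",
                                          "capen_unaffected")) {
  model <- match.arg(model)
  block <- model_blocks()[[model]]
  missing <- setdiff(block, colnames(features))
  if (length(missing))
    stop("features table lacks columns: ", paste(missing, collapse = ", "))
  d <- merge(meta, features, by = "subject_id")
  X <- data.frame(
    sex = as.integer(d$sex == "male"),
    age = d$age,
    duration = d$duration,
    TBI = as.integer(d$diagnosis == "TBI"),
    stroke = as.integer(d$diagnosis == "stroke"),
    crs_r = d$crs_r,
    check.names = FALSE)
  for (b in block) X[[b]] <- d[[b]]
  rownames(X) <- d$subject_id

  qx <- qr(cbind(1, as.matrix(X)))
  if (qx$rank < ncol(X) + 1L) {
    aliased <- c("(Intercept)", colnames(X))[qx$pivot[-seq_len(qx$rank)]]
    stop("design matrix is rank deficient; aliased columns: ",
         paste(aliased, collapse = ", "))
  }
  attr(X, "predictors") <- colnames(X)
  attr(X, "model") <- model
  X
}

#' Fit the prognostic improvement model
#'
#' Ordinary least squares of the 0/1 improvement indicator on a design from
#' [build_design_matrix()] -- a linear probability model, matching the
#' summary-table layout (estimate/SE/t/p per predictor, residual SE, R-squared,
#' F) used to report such models. A logistic alternative is available via
#' `method = "logistic"`.
#'
#' @param design Data frame from [build_design_matrix()].
#' @param labels 0/1 improvement labels aligned with the design rows.
#' @param method `"lpm"` (default) or `"logistic"`.
#' @return Object of class `prognosis_fit` with coefficient table and fit
#'   summary; supports `print`, `summary`, `coef`, `predict`, `residuals`.
#' @export
fit_improvement_model <- function(design, labels,
                                  method = c("lpm", "logistic")) {
  method <- match.arg(method)
  stopifnot(length(labels) == nrow(design), all(labels %in% c(0L, 1L)))
  d <- cbind(improved = labels, design)
  n <- nrow(d)
  p <- ncol(design) + 1L
  if (n <= p) stop("need more subjects than parameters")
  if (method == "lpm") {
    fit <- lm(improved ~ ., data = d)
    sm <- summary(fit)
    tab <- as.data.frame(sm$coefficients)
    names(tab) <- c("estimate", "std_error", "t", "p")
    fstat <- sm$fstatistic
    out <- list(fit = fit, method = method,
                model = attr(design, "model"),
                table = tab,
                residual_se = sm$sigma,
                df_residual = fit$df.residual,
                r_squared = sm$r.squared,
                adj_r_squared = sm$adj.r.squared,
                f_statistic = unname(fstat[1]),
                f_df = unname(fstat[2:3]),
                f_p = pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE),
                n = n)
  } else {
    fit <- stats::glm(improved ~ ., data = d, family = stats::binomial())
    sm <- summary(fit)
    tab <- as.data.frame(sm$coefficients)
    names(tab) <- c("estimate", "std_error", "t", "p")
    out <- list(fit = fit, method = method, model = attr(design, "model"),
                table = tab, df_residual = fit$df.residual, n = n)
  }
  # residual-df identity: n minus estimated parameters including intercept
  stopifnot(out$df_residual == n - p)
  class(out) <- "prognosis_fit"
  out
}

#' @export
print.prognosis_fit <- function(x, ...) {
  cat(sprintf("Prognostic %s model (%s), n = %d\n",
              if (x$method == "lpm") "linear-probability" else "logistic",
              x$model %||% "custom", x$n))
  tab <- x$table
  tab$stars <- signif_stars(tab$p)
  print(format(tab, digits = 4))
  if (x$method == "lpm") {
    cat(sprintf("Residual standard error: %.4f on %d degrees of freedom\n",
                x$residual_se, x$df_residual))
    cat(sprintf("Multiple R-squared: %.4f, Adjusted R-squared: %.4f\n",
                x$r_squared, x$adj_r_squared))
    cat(sprintf("F-statistic: %.4g on %d and %d DF, p-value: %.4g\n",
                x$f_statistic, x$f_df[1], x$f_df[2], x$f_p))
  }
  invisible(x)
}

#' @export
summary.prognosis_fit <- function(object, ...) object$table

#' @export
coef.prognosis_fit <- function(object, ...) coef(object$fit)

#' @export
predict.prognosis_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(predict(object$fit))
  predict(object$fit, newdata = newdata, ...)
}

#' @export
residuals.prognosis_fit <- function(object, ...) residuals(object$fit)
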