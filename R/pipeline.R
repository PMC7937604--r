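# End-to-end orchestration: simulate (or load) -> preprocess -> entropy ->
# group statistics -> prognosis, as one reproducible run.

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config, f)
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline
#'
#' Executes every stage in order on either a synthetic cohort (config with a
#' `simulate` block) or a recording directory written by [write_cohort()]
#' (config with `input_dir`): 50 Hz notch filter, artifact-free epoch
#' selection, affected/unaffected remapping, ApEn and C-ApEn tables,
#' pain-minus-rest differences, per-measure Welch t tests, Hotelling
#' T-squared channel blocks, outcome summary and the four prognostic
#' regressions. All randomness flows from the simulation seed; the same
#' config reproduces identical numeric output.
#'
#' @param config A list (or path to a YAML file) with components:
#'   * `simulate`: arguments for [cohort_config()], or an existing
#'     `doc_cohort`; alternatively `input_dir` for on-disk data.
#'   * `analysis` (optional): `m`, `r_factor`, `n_points`,
#'     `amplitude_limit`, `notch` (Hz; `NULL` to skip),
#'     `entropy_source` (`"difference"` or `"pain_level"`).
#' @return Object of class `doc_analysis` with the cohort table, entropy
#'   comparison tables, Hotelling block results, difference tables, outcome
#'   summary, regression fits and a run manifest.
#' @export
run_full_analysis <- function(config) {
  t0 <- Sys.time()
  if (is.character(config)) config <- yaml::read_yaml(config)
  an <- config$analysis %||% list()

  # ---- stage: cohort ----
  if (!is.null(config$simulate)) {
    cohort <- if (inherits(config$simulate, "doc_cohort")) config$simulate
              else generate_cohort(do.call(cohort_config, config$simulate))
    subjects <- cohort$subjects
    recordings <- cohort$recordings
    seed <- cohort$config$seed
    default_n_points <- cohort$config$epoch_len
  } else if (!is.null(config$input_dir)) {
    loaded <- read_cohort(config$input_dir)
    subjects <- loaded$subjects
    recordings <- loaded$recordings
    seed <- NA_integer_
    default_n_points <- loaded$epoch_len
  } else stop("config needs either a 'simulate' block or 'input_dir'")
  if (is.null(recordings)) stop("stage cohort: no recordings available")
  message(sprintf("cohort: %d subjects", nrow(subjects)))

  n_points <- an$n_points %||% default_n_points %||%
    min(vapply(recordings, function(r) ncol(r[[1]]$data), numeric(1)))
  params <- apen_params(m = an$m %||% 2L, r_factor = an$r_factor %||% 0.2,
                        n_points = n_points)
  amplitude_limit <- an$amplitude_limit %||% 100
  notch <- if (is.null(an$notch)) 50 else an$notch
  entropy_source <- an$entropy_source %||% "difference"

  # ---- stage: preprocess (notch, epoch, remap) ----
  pre <- recordings
  for (sid in names(pre)) {
    row <- subjects[subjects$subject_id == sid, ]
    res <- tryCatch({
      conds <- pre[[sid]][intersect(c("eyes_closed", "pain"),
                                    names(pre[[sid]]))]
      conds <- lapply(conds, function(r) {
        if (!is.null(notch)) r <- notch_filter(r, freq = notch)
        select_epoch(r, n_points = n_points,
                     amplitude_limit = amplitude_limit)
      })
      map <- determine_affected_side(row$affected_side %||% "unknown",
                                     eyes_closed_rec = conds$eyes_closed,
                                     params = params)
      lapply(conds, remap_montage, map = map)
    }, error = function(e)
      stop("stage preprocess, subject ", sid, ": ", conditionMessage(e)))
    pre[[sid]] <- res
  }
  message("preprocess: done")

  # ---- stage: entropy ----
  apen_tbl <- apen_matrix(pre, params)
  capen_tbl <- capen_pairs(pre, params = params)
  message("entropy: done")

  # ---- stage: group statistics ----
  grp <- subjects[, c("subject_id", "group")]
  rest_apen <- apen_tbl[apen_tbl$condition == "eyes_closed",
                        c("subject_id", "channel", "apen")]
  names(rest_apen) <- c("subject_id", "measure", "value")
  rest_capen <- capen_tbl$pairs[capen_tbl$pairs$condition == "eyes_closed",
                                c("subject_id", "pair", "capen")]
  names(rest_capen) <- c("subject_id", "measure", "value")
  baseline_tests <- list(apen = ttest_by_measure(rest_apen, grp),
                         capen = ttest_by_measure(rest_capen, grp))

  diff_apen <- condition_difference(apen_tbl)
  diff_capen <- condition_difference(capen_tbl$pairs)
  diff_tests <- list(apen = ttest_by_measure(diff_apen, grp),
                     capen = ttest_by_measure(diff_capen, grp))

  blocks <- list(apen_affected = model_blocks()$apen_affected,
                 apen_unaffected = model_blocks()$apen_unaffected,
                 capen_affected = model_blocks()$capen_affected,
                 capen_unaffected = model_blocks()$capen_unaffected)
  hotelling <- lapply(blocks, function(meas) {
    d <- rbind(diff_apen, diff_capen)
    d <- d[d$measure %in% meas, ]
    wide <- stats::reshape(d, idvar = "subject_id", timevar = "measure",
                           direction = "wide")
    x <- as.matrix(wide[, -1, drop = FALSE])
    g <- grp$group[match(wide$subject_id, grp$subject_id)]
    tryCatch(hotelling_two_sample(x, g), error = function(e) {
      warning("Hotelling block skipped: ", conditionMessage(e))
      NULL
    })
  })
  message("group statistics: done")

  # ---- stage: prognosis ----
  prognosis <- NULL
  outcome <- NULL
  if ("mgos_12m" %in% colnames(subjects) &&
      !all(is.na(subjects$mgos_12m))) {
    labels <- classify_improvement(subjects$group, subjects$mgos_12m)
    outcome <- outcome_summary(labels, subjects$group)
    feats <- response_features(apen_tbl, capen_tbl$pairs,
                               source = entropy_source)
    prognosis <- lapply(names(model_blocks()), function(mod) {
      tryCatch({
        X <- build_design_matrix(subjects, feats, model = mod)
        fit_improvement_model(X, labels[match(rownames(X),
                                              subjects$subject_id)])
      }, error = function(e) {
        warning("prognosis model ", mod, " skipped: ",
                conditionMessage(e))
        NULL
      })
    })
    names(prognosis) <- names(model_blocks())
    message("prognosis: done")
  } else {
    warning("no 12-month outcomes available; prognosis stage skipped")
  }

  manifest <- list(config_hash = config_hash(config), seed = seed,
                   n_subjects = nrow(subjects),
                   n_points = n_points,
                   params = unclass(params),
                   package_version = as.character(packageVersion("docentropy")),
                   started = format(t0), finished = format(Sys.time()))

  structure(list(subjects = subjects,
                 cohort_table = describe_cohort(subjects),
                 apen_table = apen_tbl, capen_table = capen_tbl,
                 baseline_tests = baseline_tests,
                 diff_tests = diff_tests,
                 hotelling = hotelling,
                 outcome = outcome,
                 prognosis = prognosis,
                 manifest = manifest),
            class = "doc_analysis")
}

#' @export
print.doc_analysis <- function(x, ...) {
  cat("== DOC nonlinear EEG analysis ==\n")
  cat(sprintf("%d subjects; seed %s; %d-sample epochs\n\n",
              nrow(x$subjects), x$manifest$seed, x$manifest$n_points))
  cat("-- Eyes-closed ApEn by group --\n")
  print(render_comparison_tables(x$baseline_tests$apen))
  cat("\n-- Eyes-closed C-ApEn by group --\n")
  print(render_comparison_tables(x$baseline_tests$capen))
  cat("\n-- Hotelling blocks (pain-minus-rest differences) --\n")
  for (b in names(x$hotelling)) {
    cat(sprintf("%-18s ", b)); print(x$hotelling[[b]])
  }
  cat("\n-- ApEn differences (pain minus eyes-closed) --\n")
  print(render_comparison_tables(x$diff_tests$apen))
  cat("\n-- C-ApEn differences --\n")
  print(render_comparison_tables(x$diff_tests$capen))
  if (!is.null(x$outcome)) {
    cat("\n-- 12-month mGOS improvement --\n")
    print(x$outcome)
  }
  if (!is.null(x$prognosis)) {
    for (m in names(x$prognosis)) {
      cat("\n")
      print(x$prognosis[[m]])
    }
  }
  invisible(x)
}
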