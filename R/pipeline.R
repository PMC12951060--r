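#' Study-level configuration
#'
#' Bundles every stage's settings: cohort composition, acquisition,
#' feature extraction, candidate policy, search methods and validation.
#' One global `seed` governs all stages (it overrides the cohort
#' config's seed and seeds the per-subject waveform generators and the
#' bootstrap).
#'
#' @param cohort a [cohort_config()].
#' @param acquisition an [acquisition_config()].
#' @param beat_length resampled points per beat (default 256).
#' @param min_beats minimum accepted beats per record (default 5).
#' @param candidate_policy which difference features enter selection:
#'   `"both"` (signed and absolute, the default), `"signed"`, or
#'   `"absolute"`.
#' @param include_dcv include the energy-CV (`DnCV`) difference features
#'   among candidates (default TRUE).
#' @param methods search methods to run (default all three).
#' @param n_resamples bootstrap resamples (default 2000).
#' @param n_groups Hosmer-Lemeshow / calibration groups (default 10).
#' @param seed global integer seed.
#' @param output_dir optional directory; when given, the cohort CSV,
#'   feature table and per-stratum model JSONs are written there.
#' @return object of class `study_config`.
#' @export
study_config <- function(cohort = cohort_config(),
                         acquisition = acquisition_config(),
                         beat_length = 256L, min_beats = 5L,
                         candidate_policy = c("both", "signed", "absolute"),
                         include_dcv = TRUE,
                         methods = c("forward", "backward", "stepwise"),
                         n_resamples = 2000L, n_groups = 10L,
                         seed = 1L, output_dir = NULL) {
  stopifnot(inherits(cohort, "cohort_config"),
            inherits(acquisition, "acquisition_config"))
  candidate_policy <- match.arg(candidate_policy)
  methods <- match.arg(methods, several.ok = TRUE)
  check_scalar(beat_length, "beat_length", lower = 24, integer = TRUE)
  check_scalar(min_beats, "min_beats", lower = 5, integer = TRUE)
  check_scalar(n_resamples, "n_resamples", lower = 1, integer = TRUE)
  check_scalar(n_groups, "n_groups", lower = 2, integer = TRUE)
  check_scalar(seed, "seed", integer = TRUE)
  cohort$seed <- seed
  structure(list(cohort = cohort, acquisition = acquisition,
                 beat_length = beat_length, min_beats = min_beats,
                 candidate_policy = candidate_policy,
                 include_dcv = include_dcv, methods = methods,
                 n_resamples = n_resamples, n_groups = n_groups,
                 seed = seed, output_dir = output_dir),
            class = "study_config")
}

#' Extract the per-subject inter-hand feature table for a cohort
#'
#' Generates both hands' waveforms for every subject (seeded
#' deterministically from the global seed and the subject index), runs
#' segmentation, harmonic decomposition and inter-hand differencing, and
#' returns the metadata-joined feature table.
#'
#' @param cohort list of `subject_truth` objects.
#' @param acquisition an `acquisition_config`.
#' @param beat_length,min_beats extraction settings.
#' @param include_dcv include `DnCV` feature columns.
#' @param seed global seed.
#' @param waveform_dir optional directory to write per-subject-hand
#'   waveform CSVs into.
#' @return data frame: `subject_id`, `sex`, `age`, `syntax_score`,
#'   `label`, then feature columns.
#' @export
extract_cohort_features <- function(cohort, acquisition,
                                    beat_length = 256L, min_beats = 5L,
                                    include_dcv = TRUE, seed = 1L,
                                    waveform_dir = NULL) {
  meta <- cohort_table(cohort)
  rows <- vector("list", length(cohort))
  for (i in seq_along(cohort)) {
    sub <- cohort[[i]]
    wf <- tryCatch(
      generate_subject_waveforms(sub, acquisition, seed = seed + i),
      error = function(e) stop(sprintf(
        "stage simulate, subject %s: %s", sub$subject_id,
        conditionMessage(e)), call. = FALSE))
    if (!is.null(waveform_dir)) {
      write_waveform(wf$left, file.path(
        waveform_dir, sprintf("%s_left.csv", sub$subject_id)))
      write_waveform(wf$right, file.path(
        waveform_dir, sprintf("%s_right.csv", sub$subject_id)))
    }
    fv <- tryCatch(
      extract_features(wf$left, wf$right, beat_length = beat_length,
                       min_beats = min_beats),
      error = function(e) stop(sprintf(
        "stage extract, subject %s: %s", sub$subject_id,
        conditionMessage(e)), call. = FALSE))
    rows[[i]] <- feature_row(fv, include_dcv = include_dcv)
  }
  feats <- do.call(rbind, rows)
  merge(meta, feats, by = "subject_id", sort = FALSE)
}

# feature columns allowed by the candidate policy
policy_columns <- function(nms, policy) {
  is_feat <- grepl("^(absd|d)[CPD]\\d+(CV)?$", nms)
  is_abs <- startsWith(nms, "absd")
  keep <- switch(policy,
                 both = is_feat,
                 signed = is_feat & !is_abs,
                 absolute = is_feat & is_abs)
  nms[keep]
}

#' Run the full study pipeline
#'
#' simulate -> extract -> per-sex candidate preparation and the three
#' AIC searches -> minimum-AIC model -> validation (apparent AUC,
#' Hosmer-Lemeshow, bootstrap), assembled into a study report. Strata
#' with few events still run but carry the events-per-variable advisory
#' prominently. Fully deterministic given the global seed.
#'
#' @param config a [study_config()].
#' @param features optional precomputed feature table (as returned by
#'   [extract_cohort_features()] or [read_feature_table()]); when given,
#'   simulation and extraction are skipped and the analysis is re-run
#'   from the table.
#' @param quiet suppress stage progress messages.
#' @return object of class `study_report`: list with `strata` (per sex:
#'   `search_aics`, `method`, `selected`, `model`, `coefficients` table,
#'   `aic`, `validation`, `epv`), `features`, `config`, `provenance`.
#' @export
run_pipeline <- function(config, features = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "study_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- proc.time()[["elapsed"]]

  if (is.null(features)) {
    say("stage simulate: generating cohort (seed %d)", config$seed)
    cohort <- generate_cohort(config$cohort)
    say("stage extract: %d subjects x 2 hands at %g Hz / %g s",
        length(cohort), config$acquisition$sampling_rate,
        config$acquisition$duration)
    features <- extract_cohort_features(
      cohort, config$acquisition, beat_length = config$beat_length,
      min_beats = config$min_beats, include_dcv = config$include_dcv,
      seed = config$seed)
  }
  stopifnot(all(c("subject_id", "sex", "label") %in% names(features)))

  strata <- list()
  for (sx in c("male", "female")) {
    df <- features[features$sex == sx, , drop = FALSE]
    if (nrow(df) == 0L) next
    labels <- as.numeric(df$label)
    cand_cols <- policy_columns(names(df), config$candidate_policy)
    cands <- prepare_candidates(df[, cand_cols, drop = FALSE],
                                quiet = quiet)
    say("stage fit [%s]: n = %d, events = %d, candidates = %d",
        sx, nrow(df), sum(labels), ncol(cands))
    epv <- withCallingHandlers(
      epv_check(sum(labels), ncol(cands)),
      warning = function(w) invokeRestart("muffleWarning"))

    searches <- tryCatch(
      run_searches(cands, labels, methods = config$methods),
      error = function(e) stop(sprintf("stage fit, stratum %s: %s", sx,
                                       conditionMessage(e)), call. = FALSE))
    best <- select_best(searches)
    say("stage fit [%s]: best method %s, %d variables, AIC %.2f",
        sx, best$method, length(best$selected), best$model$aic)
    epv_fit <- withCallingHandlers(
      epv_check(sum(labels), length(best$selected)),
      warning = function(w) invokeRestart("muffleWarning"))
    if (!epv_fit$ok) say("stage fit [%s]: %s", sx, epv_fit$message)

    say("stage validate [%s]: %d bootstrap resamples", sx,
        config$n_resamples)
    val <- tryCatch(
      validate_model(best$model, df, labels,
                     n_resamples = config$n_resamples,
                     n_groups = config$n_groups,
                     seed = config$seed + match(sx, c("male", "female"))),
      error = function(e) stop(sprintf("stage validate, stratum %s: %s",
                                       sx, conditionMessage(e)),
                               call. = FALSE))
    strata[[sx]] <- list(
      sex = sx, n = nrow(df), n_events = sum(labels),
      n_candidates = ncol(cands),
      search_aics = vapply(searches, function(s) s$model$aic, numeric(1)),
      method = best$method, selected = best$selected,
      model = best$model, coefficients = coef_table(best$model),
      aic = best$model$aic, validation = val,
      epv = epv_fit)
  }

  report <- structure(list(
    strata = strata, features = features, config = config,
    provenance = list(seed = config$seed,
                      config_hash = config_hash(config),
                      version = as.character(utils::packageVersion("pulseharmonics")),
                      elapsed_s = proc.time()[["elapsed"]] - t0)),
    class = "study_report")

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    write_feature_table(features,
                        file.path(config$output_dir, "features.csv"))
    for (sx in names(strata))
      write_model_json(strata[[sx]][setdiff(names(strata[[sx]]),
                                            "validation")],
                       file.path(config$output_dir,
                                 sprintf("model_%s.json", sx)))
  }
  report
}

# md5 of the canonical JSON form of the config
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass_deep(config), tmp, auto_unbox = TRUE,
                       digits = NA, na = "null")
  unname(tools::md5sum(tmp))
}

#' Coefficient table of a fitted model
#'
#' One row per predictor with the reporting schema Coefficient / SE /
#' tStat / P Value; the intercept is returned as an attribute row, kept
#' separate from the predictors.
#'
#' @param model a `fitted_model`.
#' @param digits optional rounding for display (default NULL: full
#'   precision).
#' @return data frame with columns `term`, `Coefficient`, `SE`, `tStat`,
#'   `P Value`, `sig` (`"*"` at P < 0.05); attribute `"intercept"` holds
#'   the intercept row.
#' @export
coef_table <- function(model, digits = NULL) {
  stopifnot(inherits(model, "fitted_model"))
  tab <- data.frame(
    term = names(model$coefficients),
    Coefficient = unname(model$coefficients),
    SE = unname(model$standard_errors),
    tStat = unname(model$t_statistics),
    `P Value` = unname(model$p_values),
    check.names = FALSE, stringsAsFactors = FALSE)
  tab$sig <- ifelse(tab$`P Value` < 0.05, "*", "")
  if (!is.null(digits))
    for (cn in c("Coefficient", "SE", "tStat", "P Value"))
      tab[[cn]] <- round(tab[[cn]], digits)
  out <- tab[tab$term != "(Intercept)", , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "intercept") <- tab[tab$term == "(Intercept)", , drop = FALSE]
  out
}

#' Formatted per-stratum coefficient tables of a study report
#'
#' @param report a `study_report`.
#' @param digits rounding for display (default 2, the reporting
#'   precision of the schema).
#' @return named list (per stratum) of coefficient tables as in
#'   [coef_table()].
#' @export
report_tables <- function(report, digits = 2) {
  stopifnot(inherits(report, "study_report"))
  lapply(report$strata, function(s) coef_table(s$model, digits = digits))
}

#' @export
print.study_report <- function(x, ...) {
  cat("Study report (seed", x$provenance$seed, ")\n")
  for (s in x$strata) {
    cat(sprintf(
      "\n[%s] n = %d, events = %d | %s selection, AIC = %.2f\n",
      s$sex, s$n, s$n_events, s$method, s$aic))
    cat(sprintf(
      "  apparent AUC = %.3f | HL = %.2f (P = %.2f) | bootstrap AUC = %.3f [%.3f, %.3f]\n",
      s$validation$auc, s$validation$hl_statistic, s$validation$hl_p,
      s$validation$bootstrap_mean_auc, s$validation$bootstrap_ci[1],
      s$validation$bootstrap_ci[2]))
    if (!s$epv$ok) cat("  !! ", s$epv$message, "\n", sep = "")
    tab <- coef_table(s$model, digits = 2)
    if (nrow(tab)) print(tab, row.names = FALSE) else
      cat("  (intercept-only model)\n")
  }
  invisible(x)
}
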