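#' Read and write trial tables
#'
#' Trial tables are comma-separated text with a header row and columns
#' `subject_id`, `stage_label`, `trial_type` ("pro"/"anti"), `response`
#' ("correct"/"error") and `rt_seconds` (positive, in seconds). `read_trials`
#' validates the vocabulary and RT sign and reports offending rows by data
#' line number.
#'
#' @param path file path.
#' @param trials a trial table data frame.
#' @return `read_trials` returns the validated data frame; `write_trials`
#'   returns `path` invisibly.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("subject_id", "stage_label", "trial_type", "response",
                "rt_seconds")
  missing <- setdiff(required, names(d))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  bad_row <- function(ok, what) {
    if (all(ok)) return(invisible())
    stop(what, " in row(s) ", paste(utils::head(which(!ok), 5), collapse = ", "),
         call. = FALSE)
  }
  bad_row(d$trial_type %in% c("pro", "anti"),
          "invalid trial_type (expected 'pro' or 'anti')")
  bad_row(d$response %in% c("correct", "error"),
          "invalid response (expected 'correct' or 'error')")
  bad_row(is.finite(d$rt_seconds) & d$rt_seconds > 0,
          "non-positive or missing rt_seconds")
  d
}

#' @rdname read_trials
#' @export
write_trials <- function(trials, path) {
  required <- c("subject_id", "stage_label", "trial_type", "response",
                "rt_seconds")
  stopifnot(all(required %in% names(trials)))
  utils::write.csv(trials[required], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write per-subject tables
#'
#' One row per subject: identifiers, stage, true or fitted parameters and
#' clinical scores. Plain CSV with a header row.
#'
#' @param path file path.
#' @param subjects a subject table data frame (must contain `subject_id`).
#' @export
read_subjects <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"subject_id" %in% names(d))
    stop("missing required column 'subject_id'", call. = FALSE)
  d
}

#' @rdname read_subjects
#' @export
write_subjects <- function(subjects, path) {
  stopifnot("subject_id" %in% names(subjects))
  utils::write.csv(subjects, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

config_fingerprint <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f)
  unname(tools::md5sum(f))
}

#' Run the full staging pipeline on a synthetic cohort
#'
#' End-to-end convenience driver: generate a cohort from `spec`, write the
#' trial and subject tables, fit every subject, run the stage and clinical
#' regressions, the breakpoint analysis on `v_inhib` and `v_exec`, and the
#' control-versus-presymptomatic feature-set comparison. All artifacts are
#' written under `out_dir` together with a run manifest recording the seed
#' and a fingerprint of the configuration, so any reported number can be
#' regenerated.
#'
#' @param spec a [cohort_spec()].
#' @param fit_cfg a [fit_config()].
#' @param cls_cfg a [classify_config()].
#' @param out_dir output directory (created if absent). `NULL` skips all
#'   file output.
#' @param seed integer seed for cohort generation.
#' @param progress print per-subject fitting progress.
#' @return list with `cohort`, `fits` (subject table with fitted parameter
#'   columns prefixed `fit_`), `stage_ols`, `mars_v_inhib`, `mars_v_exec`,
#'   `clinical`, `comparison` (control vs presymptomatic feature sets).
#' @export
run_pipeline <- function(spec = default_cohort_spec(),
                         fit_cfg = fit_config(), cls_cfg = classify_config(),
                         out_dir = NULL, seed = 1, progress = FALSE) {
  cohort <- generate_cohort(spec, seed)
  fits <- fit_cohort(cohort$trials, fit_cfg, progress = progress)
  names(fits)[match(param_names(), names(fits))] <-
    paste0("fit_", param_names())
  subjects <- merge(cohort$subjects, fits, by = "subject_id", sort = FALSE)

  fitted_pars <- subjects[paste0("fit_", param_names())]
  names(fitted_pars) <- param_names()
  staged <- cbind(subjects[c("subject_id", "stage", "tms", "tfc", "cag")],
                  fitted_pars)
  stage_ols <- stage_regression(staged)
  mars_vi <- mars_fit(staged$stage, staged$v_inhib)
  mars_ve <- mars_fit(staged$stage, staged$v_exec)
  clinical <- clinical_regressions(staged)

  pre <- staged$stage %in% 0:2
  y <- factor(ifelse(staged$stage[pre] == 0, "control", "preHD"),
              levels = c("control", "preHD"))
  summ <- do.call(rbind, lapply(split(cohort$trials, cohort$trials$subject_id),
                                summary_stats))
  summ <- summ[match(subjects$subject_id, rownames(summ)), ]
  sets <- list(
    summary = summ[pre, c("pro_rt_mean", "pro_rt_sd", "anti_correct_rt_mean",
                          "anti_correct_rt_sd", "anti_accuracy")],
    all_params = fitted_pars[pre, c("v_pre", "v_inhib", "v_exec", "a_mean",
                                    "t", "t_exec")],
    v_exec = fitted_pars[pre, "v_exec", drop = FALSE])
  sets$summary[is.na(sets$summary)] <- 0   # empty error cells
  comparison <- compare_feature_sets(sets, y, cls_cfg)

  out <- list(cohort = cohort, fits = subjects, stage_ols = stage_ols,
              mars_v_inhib = mars_vi, mars_v_exec = mars_ve,
              clinical = clinical, comparison = comparison, seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_trials(cohort$trials, file.path(out_dir, "trials.csv"))
    write_subjects(subjects, file.path(out_dir, "subjects.csv"))
    utils::write.csv(comparison$summary,
                     file.path(out_dir, "classification.csv"),
                     row.names = FALSE)
    manifest <- c(
      sprintf("seed: %d", seed),
      sprintf("config_fingerprint: %s",
              config_fingerprint(list(spec, fit_cfg, cls_cfg))),
      sprintf("generated: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
    writeLines(manifest, file.path(out_dir, "run_manifest.txt"))
  }
  out
}
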