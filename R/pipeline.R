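# End-to-end orchestration: generate/load -> cohort -> dose series ->
# trajectory models (baseline and covariate) -> association statistics,
# with reproducible delimited outputs and a run manifest.

#' Pipeline configuration
#'
#' @param input `"synthetic"` (generate from `sim`) or a directory holding
#'   the four claims tables written by [write_dataset()].
#' @param sim A [sim_config()] (required when `input = "synthetic"`).
#' @param rules An [eligibility_rules()].
#' @param dose_mode Windowing mode for [dose_series_table()].
#' @param K_grid Candidate group counts for model selection.
#' @param poly_order Polynomial order of the trajectories.
#' @param transform Dose transform.
#' @param predictor_set Predictor columns for the membership regression
#'   (`NULL` = every column built by [build_predictor_table()]).
#' @param reference_group,target_group Trajectory groups compared in the
#'   membership regression; `NULL` picks the steepest-decreasing and
#'   steepest-increasing fitted groups.
#' @param seed Global seed (generation and fitting).
#' @param n_starts EM restarts per candidate model.
#' @param output_dir Output directory.
#' @param log_level `"info"` or `"quiet"`.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(input = "synthetic", sim = NULL,
                            rules = eligibility_rules(),
                            dose_mode = "dispense_date",
                            K_grid = c(1L, 2L, 3L, 4L, 5L),
                            poly_order = 2L,
                            transform = "log1p",
                            predictor_set = NULL,
                            reference_group = NULL, target_group = NULL,
                            seed = 1L, n_starts = 5L,
                            output_dir = tempfile("rxtraj_run_"),
                            log_level = c("info", "quiet")) {
  log_level <- match.arg(log_level)
  if (length(K_grid) < 1L) stop_config("K_grid", "must be nonempty")
  if (identical(input, "synthetic")) {
    if (is.null(sim)) stop_config("sim", "required for synthetic input")
    if (!inherits(sim, "sim_config")) sim <- do.call(sim_config, sim)
  } else if (!dir.exists(input)) {
    stop_config("input", "must be 'synthetic' or an existing directory")
  }
  structure(list(input = input, sim = sim, rules = rules,
                 dose_mode = dose_mode, K_grid = as.integer(K_grid),
                 poly_order = as.integer(poly_order), transform = transform,
                 predictor_set = predictor_set,
                 reference_group = reference_group,
                 target_group = target_group,
                 seed = check_count(seed, "seed", 0L),
                 n_starts = as.integer(n_starts),
                 output_dir = output_dir, log_level = log_level),
            class = "pipeline_config")
}

# canonical hash of a config: stable under field reordering; paths and
# logging verbosity do not change the analysis and are excluded
config_hash <- function(config) {
  canon <- function(x) {
    if (is.list(x)) {
      x <- x[order(names(x) %||% seq_along(x))]
      lapply(x, canon)
    } else x
  }
  cfg <- unclass(config)
  cfg$output_dir <- NULL
  cfg$log_level <- NULL
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(canon(cfg[sort(names(cfg))]), tmp)
  unname(tools::md5sum(tmp))
}

#' Label fitted groups by dose level and trend
#'
#' Classifies each fitted group from its predicted start/end doses:
#' the direction is the sign of the fitted change over the horizon, the
#' level comes from the starting dose.  Used to pick the decreasing
#' (reference) and increasing (target) groups for the membership
#' regression.
#'
#' @param model A converged `gbtm_fit`.
#' @return Data frame: `group`, `start_dose`, `end_dose`, `change`,
#'   `trend` (`"decreasing"`, `"stable"`, `"increasing"`).
#' @export
classify_trajectories <- function(model) {
  K <- model$spec$n_groups
  curves <- lapply(seq_len(K), function(j)
    predicted_trajectory(model, j, level = 0))
  start <- vapply(curves, function(cv) cv$mean[1L], 0)
  end <- vapply(curves, function(cv) cv$mean[nrow(cv)], 0)
  change <- end - start
  rel <- change / pmax(start, 1)
  data.frame(group = seq_len(K), start_dose = start, end_dose = end,
             change = change,
             trend = ifelse(rel > 0.15, "increasing",
                            ifelse(rel < -0.15, "decreasing", "stable")),
             stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: data generation or loading, cohort construction
#' with attrition, dose-series and covariate construction, BIC selection
#' of the opioid baseline model (no covariate) and of the opioid-stimulant
#' model (time-varying cumulative stimulant covariate) on the identical
#' cohort and series, posterior assignment under both models, descriptive
#' tables, rank-based subgroup comparisons, and the trajectory-membership
#' logistic regression.  All outputs are written as delimited or YAML
#' text files; the run is a pure function of (input data, config, seed).
#'
#' @param config A [pipeline_config()].
#' @return A `run_manifest` list: `config_hash`, `stage_counts`, `files`
#'   (with md5 checksums), `versions`, `timings_s`, and in-memory
#'   `results`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (config$log_level == "info")
    message(sprintf(...))
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[[stage]] <<- round(t1 - t0, 2)
    t0 <<- t1
  }
  out_files <- character(0)
  emit <- function(df, name) {
    f <- file.path(config$output_dir, name)
    utils::write.csv(df, f, row.names = FALSE)
    out_files <<- c(out_files, f)
  }

  # stage 1: data
  if (identical(config$input, "synthetic")) {
    dataset <- generate_population(config$sim)
    write_dataset(dataset, file.path(config$output_dir, "data"))
    out_files <- c(out_files,
                   list.files(file.path(config$output_dir, "data"),
                              full.names = TRUE))
  } else {
    dataset <- read_dataset(config$input)
  }
  say("data: %d patients, %d fills", nrow(dataset$patients),
      nrow(dataset$prescriptions))
  tick("data")

  # stage 2: cohort
  cres <- build_cohort(dataset, config$rules)
  emit(cres$cohort, "cohort.csv")
  emit(cres$attrition, "attrition.csv")
  say("cohort: %d in -> %d eligible", cres$n_input, nrow(cres$cohort))
  tick("cohort")
  if (nrow(cres$cohort) == 0L) stop("empty cohort; nothing to model")

  # stage 3: dose series + covariates
  doses <- dose_series_table(cres$cohort, dataset$prescriptions,
                             dataset$drug_catalog, mode = config$dose_mode)
  covs <- covariate_table(cres$cohort, dataset$prescriptions)
  comorb <- comorbidity_table(cres$cohort, dataset$diagnoses)
  summaries <- dose_summary_table(doses)
  emit(doses, "doses.csv")
  emit(covs$series, "covariates.csv")
  emit(covs$counts, "stimulant_counts.csv")
  emit(summaries, "dose_summaries.csv")
  say("doses: %d patient-windows", nrow(doses))
  tick("doses")

  # stage 4: trajectory models (baseline, then identical data + covariate)
  ctrl <- gbtm_control(n_starts = config$n_starts, seed = config$seed)
  sel_base <- select_model(doses, NULL, config$K_grid, config$poly_order,
                           include_covariate = FALSE,
                           transform = config$transform, control = ctrl)
  model_base <- attr(sel_base, "chosen_fit")
  sel_cov <- select_model(doses, covs$series, config$K_grid,
                          config$poly_order, include_covariate = TRUE,
                          transform = config$transform, control = ctrl)
  model_cov <- attr(sel_cov, "chosen_fit")
  emit(as.data.frame(sel_base), "selection_baseline.csv")
  emit(as.data.frame(sel_cov), "selection_covariate.csv")
  for (nm in c("baseline", "covariate")) {
    mdl <- if (nm == "baseline") model_base else model_cov
    f <- file.path(config$output_dir, sprintf("model_%s.yaml", nm))
    yaml::write_yaml(list(
      n_groups = mdl$spec$n_groups, poly_order = mdl$spec$poly_order,
      include_covariate = mdl$spec$include_covariate,
      transform = mdl$spec$transform,
      beta = apply(mdl$beta, 1L, as.numeric, simplify = FALSE),
      alpha = as.numeric(mdl$alpha %||% numeric(0)),
      sigma = mdl$sigma, pi = as.numeric(mdl$pi),
      log_likelihood = mdl$log_likelihood, bic = mdl$bic,
      converged = mdl$converged, n_iter = mdl$n_iter), f)
    out_files <- c(out_files, f)
  }
  asg_base <- posterior_assign(model_base, doses)
  asg_cov <- posterior_assign(model_cov, doses, covs$series)
  emit(asg_base, "assignments_baseline.csv")
  emit(asg_cov, "assignments_covariate.csv")
  curves <- do.call(rbind, lapply(seq_len(model_cov$spec$n_groups),
                                  function(j) {
    cv <- predicted_trajectory(model_cov, j, level = 0)
    cv$group <- j
    cv
  }))
  emit(curves, "trajectories_covariate.csv")
  say("models: baseline K = %d, covariate K = %d",
      model_base$spec$n_groups, model_cov$spec$n_groups)
  tick("models")

  # stage 5: association statistics
  feat <- build_predictor_table(cres$cohort, covs$counts, comorb)
  feat2 <- merge(feat, summaries, by = "patient_id")
  feat2$trajectory_group <-
    asg_cov$modal_group[match(feat2$patient_id, asg_cov$patient_id)]
  feat2$stimulant_exposure <-
    ifelse(covs$counts$stim_count_between[
      match(feat2$patient_id, covs$counts$patient_id)] > 0,
      "w/STM", "w/o STM")
  feat2$sex <- cres$cohort$sex[match(feat2$patient_id,
                                     cres$cohort$patient_id)]
  feat2$region <- cres$cohort$region[match(feat2$patient_id,
                                           cres$cohort$patient_id)]
  measures <- c("age_at_index", "prsc_no", "avg_mme", "total_mme")
  cmp <- list()
  for (gv in c("region", "sex", "stimulant_exposure", "trajectory_group")) {
    if (length(unique(feat2[[gv]])) >= 2L)
      cmp[[gv]] <- subgroup_compare(feat2, gv, measures)
  }
  comparisons <- do.call(rbind, cmp)
  if (!is.null(comparisons)) {
    rownames(comparisons) <- NULL
    emit(comparisons, "comparisons.csv")
  }
  desc <- descriptive_table(
    feat2, "trajectory_group",
    c("age_at_index", "prsc_no", "avg_mme", "total_mme", "sex", "region"))
  emit(desc, "descriptive_by_group.csv")

  trends <- classify_trajectories(model_cov)
  emit(trends, "trajectory_trends.csv")
  ref <- config$reference_group %||% trends$group[which.min(trends$change)]
  tgt <- config$target_group %||% trends$group[which.max(trends$change)]
  regression <- NULL
  if (ref != tgt &&
      sum(asg_cov$modal_group == ref) > 0L &&
      sum(asg_cov$modal_group == tgt) > 0L) {
    pred_cols <- config$predictor_set %||% setdiff(names(feat), "patient_id")
    px <- feat[, c("patient_id", pred_cols), drop = FALSE]
    # drop constant predictors (inestimable in the restricted sample)
    sub <- px$patient_id %in%
      asg_cov$patient_id[asg_cov$modal_group %in% c(ref, tgt)]
    keep <- vapply(pred_cols, function(cn)
      length(unique(px[[cn]][sub])) > 1L, TRUE)
    px <- px[, c("patient_id", pred_cols[keep]), drop = FALSE]
    regression <- tryCatch(
      membership_regression(px, asg_cov, ref, tgt),
      error = function(e) {
        say("membership regression skipped: %s", conditionMessage(e))
        NULL
      })
    if (!is.null(regression)) {
      regression$reference_group <- ref
      regression$target_group <- tgt
      emit(regression, "membership_regression.csv")
    }
  }
  say("associations: %d comparisons, regression %s",
      if (is.null(comparisons)) 0L else nrow(comparisons),
      if (is.null(regression)) "skipped" else
        sprintf("%d -> %d", ref, tgt))
  tick("associations")

  manifest <- list(
    config_hash = config_hash(config),
    stage_counts = list(
      patients_in = nrow(dataset$patients),
      cohort = nrow(cres$cohort),
      patient_windows = nrow(doses),
      baseline_groups = model_base$spec$n_groups,
      covariate_groups = model_cov$spec$n_groups),
    files = data.frame(file = basename(out_files),
                       md5 = unname(tools::md5sum(out_files)),
                       stringsAsFactors = FALSE),
    versions = list(rxtraj = as.character(utils::packageVersion("rxtraj")),
                    R = paste(R.version$major, R.version$minor, sep = ".")),
    timings_s = as.list(timings),
    results = list(cohort = cres, doses = doses, covariates = covs,
                   selection_baseline = sel_base,
                   selection_covariate = sel_cov,
                   model_baseline = model_base, model_covariate = model_cov,
                   assignments_baseline = asg_base,
                   assignments_covariate = asg_cov,
                   comparisons = comparisons, regression = regression,
                   trends = trends, summaries = summaries))
  class(manifest) <- "run_manifest"
  yaml::write_yaml(list(config_hash = manifest$config_hash,
                        stage_counts = manifest$stage_counts,
                        files = list(file = manifest$files$file,
                                     md5 = manifest$files$md5),
                        versions = manifest$versions,
                        timings_s = manifest$timings_s),
                   file.path(config$output_dir, "manifest.yaml"))
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("rxtraj pipeline run\n")
  cat(sprintf("  config %s\n", x$config_hash))
  for (nm in names(x$stage_counts))
    cat(sprintf("  %-18s %s\n", nm, x$stage_counts[[nm]]))
  cat(sprintf("  %d output files\n", nrow(x$files)))
  invisible(x)
}
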