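#' Run the bundled synthetic-cohort experiment
#'
#' Simulates a multi-terrain walking protocol for a synthetic cohort, trains
#' the two-stage pipeline and evaluates it under the repeated-trials
#' protocol: one walking-condition classifier shared across subjects, one
#' phase estimator per subject (so own- versus cross-subject transfer can be
#' measured), the designated trial of every scenario held out for testing.
#' At evaluation time the estimators always consume stage-1 predictions.
#'
#' The default network sizes are reduced relative to [wc_config()] /
#' [gpe_config()] defaults so the whole experiment runs in minutes on one
#' CPU core; the synthetic task is comfortably learnable at these sizes.
#'
#' @param n_subjects Cohort size.
#' @param seed Master seed: drives the cohort draw, every simulation and all
#'   training randomness.
#' @param scenarios List of [scenario_script()]s.
#' @param trials_per_script Repetitions per (subject, scenario).
#' @param wc_cfg,gpe_cfg Optional [bilstm_config()] overrides for the two
#'   stages.
#' @param eval_hop Evaluation hop in samples.
#' @param verbose Print progress.
#' @return List with `wc_accuracy`, `confusion` ([wc_confusion()]), `grid`
#'   ([cross_subject_evaluation()] result), `aggregates`
#'   ([aggregate_phase_grid()] result), `n_test_windows` and the fitted
#'   `wc_model` / `phase_models`.
#' @export
run_synthetic_study <- function(n_subjects = 4L, seed = 1L,
                                scenarios = default_scenarios(),
                                trials_per_script = 3L,
                                wc_cfg = NULL, gpe_cfg = NULL,
                                eval_hop = 3L, verbose = FALSE) {
  seed <- as.integer(seed) %% 2100000000L
  cohort <- make_cohort(n_subjects, base_seed = seed)
  dataset <- simulate_protocol(cohort, scenarios, trials_per_script)
  split_all <- make_split(dataset)
  if (is.null(wc_cfg))
    wc_cfg <- wc_config(hidden = c(24L, 12L), dense = 16L, folds = 1L,
                        hop = 12L, max_epochs = 12L, patience = 4L,
                        seed = seed + 1L)
  if (is.null(gpe_cfg))
    gpe_cfg <- gpe_config(variant = 1L, hidden = c(24L, 12L), dense = 4L,
                          hop = 4L, max_epochs = 12L, patience = 4L,
                          seed = seed + 2L)
  if (verbose) message("training walking-condition classifier")
  wc_model <- fit_wc_classifier(split_all, wc_cfg, verbose = verbose)

  subjects <- names(cohort)
  phase_models <- list()
  test_data <- list()
  for (s in subjects) {
    recs_s <- Filter(function(r) r$subject == s, dataset)
    split_s <- make_split(recs_s)
    cfg_s <- gpe_cfg
    cfg_s$seed <- gpe_cfg$seed + match(s, subjects)
    if (verbose) message("training phase estimator for ", s)
    phase_models[[s]] <- fit_phase_estimator(split_s, cfg_s)
    test_data[[s]] <- split_s$test
  }

  # stage-1 accuracy on held-out trials
  wc_true <- character(0); wc_pred <- character(0); subj <- character(0)
  for (s in subjects) {
    for (rec in test_data[[s]]) {
      pr <- predict(wc_model, rec, type = "class", hop = eval_hop)
      ends <- attr(pr, "end_idx")
      wc_true <- c(wc_true, rec$wc[ends])
      wc_pred <- c(wc_pred, pr)
      subj <- c(subj, rep(s, length(ends)))
    }
  }
  confusion <- wc_confusion(wc_true, wc_pred, subject = subj)

  if (verbose) message("evaluating own/cross-subject grid")
  grid <- cross_subject_evaluation(phase_models, test_data, wc_model = wc_model,
                                   hop = eval_hop)
  list(wc_accuracy = confusion$accuracy, confusion = confusion,
       grid = grid, aggregates = aggregate_phase_grid(grid),
       n_test_windows = length(wc_true),
       wc_model = wc_model, phase_models = phase_models)
}
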