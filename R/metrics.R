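#' Circular phase error
#'
#' Signed difference between estimated and true phase on the 0-100 cycle,
#' wrapped to (-50, 50\]: an estimate of 0.5 against a truth of 99.5 is an
#' error of 1, not 99.
#'
#' @param true,est Numeric phase vectors (0-100 scale).
#' @param circular Wrap the difference (default); FALSE gives the plain
#'   difference for comparison.
#' @return Numeric vector of errors.
#' @export
phase_error <- function(true, est, circular = TRUE) {
  if (circular) ((est - true + 50) %% 100) - 50 else est - true
}

metric_row <- function(true, est, csf_true, csf_est, circular) {
  e <- phase_error(true, est, circular)
  rmse <- sqrt(mean(e^2))
  ss_res <- sum((csf_est - csf_true)^2)
  ss_tot <- sum(sweep(csf_true, 2L, colMeans(csf_true))^2)
  r2 <- 1 - ss_res / ss_tot
  mean_est <- mean(est)
  data.frame(
    n = length(e), rmse = rmse, r2 = r2,
    rrmse = if (mean_est > 0) rmse / mean_est * 100 else NA_real_,
    apee = mean(abs(e)),        # % of the 100-unit cycle
    nrmse = rmse / 100 * 100    # phase range is 100 by construction
  )
}

#' Phase-error summary metrics
#'
#' Computes, per walking condition and overall: circular RMSE (phase units on
#' the 0-100 scale), the R-squared of the sine-cosine regression targets
#' (pooled over both components, matching the model's loss), relative RMSE
#' (RMSE / mean estimate x 100, undefined when the mean estimate is 0),
#' average phase-estimation error (mean absolute circular error, in % of the
#' cycle) and range-normalized RMSE (RMSE / 100 x 100%, numerically equal to
#' the RMSE since the phase range is 100 by construction).
#'
#' @param true Ground-truth phase (0-100), NA where invalid.
#' @param est Estimated phase, NA where invalid.
#' @param wc Optional per-sample condition labels for the per-condition rows.
#' @param csf_est Optional raw estimated (cos, sin) matrix; the R-squared is
#'   computed on it when supplied, otherwise on `encode_phase(est)`.
#' @param circular Use the circular error (default TRUE).
#' @return Object of class `phase_error_summary`: data frame with one row per
#'   condition present plus `"overall"`, columns `n`, `rmse`, `r2`, `rrmse`,
#'   `apee`, `nrmse`.
#' @export
phase_error_metrics <- function(true, est, wc = NULL, csf_est = NULL,
                                circular = TRUE) {
  ok <- !is.na(true) & !is.na(est)
  if (!is.null(wc)) ok <- ok & !is.na(wc)
  if (!any(ok)) stop_arg("no overlapping valid samples to evaluate")
  true <- true[ok]; est <- est[ok]
  csf_true <- encode_phase(true)
  if (is.null(csf_est)) csf_est <- encode_phase(est) else csf_est <- csf_est[ok, , drop = FALSE]
  groups <- if (is.null(wc)) list() else split(seq_along(true), factor(wc[ok], levels = WC_LEVELS), drop = TRUE)
  rows <- lapply(groups, function(idx)
    metric_row(true[idx], est[idx], csf_true[idx, , drop = FALSE],
               csf_est[idx, , drop = FALSE], circular))
  rows$overall <- metric_row(true, est, csf_true, csf_est, circular)
  out <- do.call(rbind, rows)
  out <- cbind(condition = names(rows), out)
  rownames(out) <- NULL
  class(out) <- c("phase_error_summary", "data.frame")
  out
}

#' @export
print.phase_error_summary <- function(x, digits = 3, ...) {
  cat("Phase-error summary (phase units, 0-100 cycle):\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Walking-condition confusion matrix
#'
#' Tallies predicted against true conditions. With per-window subject ids,
#' each subject's row-normalized percentage matrix is computed and the
#' across-subject mean and SD are reported, as in per-subject protocol
#' summaries.
#'
#' @param true,pred Character/factor vectors of condition labels.
#' @param subject Optional per-window subject ids.
#' @return Object of class `wc_confusion`: list with `counts` (5 x 5),
#'   `percent` (row-normalized mean %, rows sum to 100 for observed rows),
#'   `percent_sd` (across-subject SD, NULL without subjects) and `accuracy`.
#' @export
wc_confusion <- function(true, pred, subject = NULL) {
  true <- as.character(true); pred <- as.character(pred)
  bad <- setdiff(unique(c(true, pred)), WC_LEVELS)
  if (length(bad)) stop_arg("unknown condition label: %s", paste(bad, collapse = ", "))
  tf <- factor(true, levels = WC_LEVELS); pf <- factor(pred, levels = WC_LEVELS)
  counts <- table(true = tf, pred = pf)
  row_pct <- function(m) {
    rs <- rowSums(m)
    p <- sweep(m, 1L, pmax(rs, 1L), `/`) * 100
    p[rs == 0, ] <- NA
    p
  }
  if (is.null(subject)) {
    percent <- row_pct(unclass(counts)); percent_sd <- NULL
  } else {
    per_subj <- lapply(split(seq_along(true), subject), function(idx)
      row_pct(unclass(table(factor(true[idx], WC_LEVELS), factor(pred[idx], WC_LEVELS)))))
    arr <- simplify2array(per_subj)
    percent <- apply(arr, c(1L, 2L), mean, na.rm = TRUE)
    percent_sd <- apply(arr, c(1L, 2L), sd, na.rm = TRUE)
    dimnames(percent) <- dimnames(percent_sd) <- list(true = WC_LEVELS, pred = WC_LEVELS)
  }
  structure(list(counts = unclass(counts), percent = percent,
                 percent_sd = percent_sd,
                 accuracy = mean(true == pred)),
            class = "wc_confusion")
}

#' @export
print.wc_confusion <- function(x, digits = 1, ...) {
  cat(sprintf("Condition confusion matrix (accuracy %.1f%%)\n", 100 * x$accuracy))
  print(round(x$percent, digits))
  invisible(x)
}

#' Own- versus cross-subject evaluation grid
#'
#' Evaluates every per-subject phase estimator on every subject's held-out
#' test recordings. Diagonal cells are own-subject results; off-diagonal
#' cells are cross-subject. The condition feature fed to each estimator comes
#' from a shared classifier when `wc_model` is given, otherwise from the
#' ground-truth labels.
#'
#' @param models Named list of `phase_estimator`s, one per training subject.
#' @param test_data Named list (per test subject) of lists of raw
#'   `fsr_recording`s.
#' @param wc_model Optional shared `wc_classifier`.
#' @param hop Evaluation hop in samples.
#' @return Object of class `cross_subject_grid`: data frame with columns
#'   `train_subject`, `test_subject`, `condition`, `rmse`, `r2`.
#' @export
cross_subject_evaluation <- function(models, test_data, wc_model = NULL, hop = 1L) {
  if (length(models) < 1L || length(test_data) < 1L) stop_arg("need models and test data")
  missing_td <- setdiff(names(models), names(test_data))
  if (length(missing_td))
    stop_arg("missing test data for subject %s", paste(missing_td, collapse = ", "))
  rows <- list()
  for (tr_s in names(models)) {
    model <- models[[tr_s]]
    for (te_s in names(test_data)) {
      ev <- evaluate_phase_model(model, test_data[[te_s]], wc_model = wc_model, hop = hop)
      per_wc <- ev[ev$condition != "overall", c("condition", "rmse", "r2")]
      rows[[length(rows) + 1L]] <- data.frame(
        train_subject = tr_s, test_subject = te_s, per_wc,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cross_subject_grid", "data.frame")
  out
}

#' Evaluate a phase estimator on test recordings
#'
#' Runs the estimator (optionally behind a condition classifier) over whole
#' recordings and scores the decoded phase against ground truth.
#'
#' @param model A `phase_estimator`.
#' @param recordings List of raw `fsr_recording`s with ground-truth phase.
#' @param wc_model Optional `wc_classifier`; ground-truth condition labels
#'   are used when NULL (and for variants without the condition feature the
#'   argument is ignored).
#' @param hop Evaluation hop in samples.
#' @return A [phase_error_metrics()] summary.
#' @export
evaluate_phase_model <- function(model, recordings, wc_model = NULL, hop = 1L) {
  if (inherits(recordings, "fsr_recording")) recordings <- list(recordings)
  true_all <- numeric(0); est_all <- numeric(0); wc_all <- character(0)
  csf_all <- NULL
  needs_wc <- model$variant %in% c(1L, 3L, 4L, 5L)
  for (rec in recordings) {
    normed <- apply_minmax(rec, model$stats)
    wc_in <- if (!needs_wc) NULL
             else if (is.null(wc_model)) normed$wc
             else predict_wc_per_sample(wc_model, rec, hop = hop)$onehot
    feat <- build_feature_matrix(normed$forces, model$stats, model$variant, wc = wc_in)
    w <- build_windows(feat, model$config$seq_len, hop, labels = normed$phase)
    if (!length(w$end_idx)) next
    csf <- bilstm_predict(model$params, w$x, model$config)
    est <- decode_phase(csf)
    keep <- !is.na(w$labels)
    true_all <- c(true_all, w$labels[keep])
    est_all <- c(est_all, est[keep])
    wc_all <- c(wc_all, normed$wc[w$end_idx][keep])
    csf_all <- rbind(csf_all, csf[keep, , drop = FALSE])
  }
  phase_error_metrics(true_all, est_all, wc = wc_all, csf_est = csf_all)
}

#' Aggregate a cross-subject grid
#'
#' Per-condition means over the own-subject (diagonal) and cross-subject
#' (off-diagonal) cells, and overall means computed as the average of the
#' five per-condition means.
#'
#' @param grid A `cross_subject_grid` (or any data frame with columns
#'   `train_subject`, `test_subject`, `condition`, `rmse`, `r2`).
#' @return List with data frame `per_condition` (columns `condition`,
#'   `own_rmse`, `own_r2`, `cross_rmse`, `cross_r2`) and numeric `overall`
#'   (`own_rmse`, `own_r2`, `cross_rmse`, `cross_r2`).
#' @export
aggregate_phase_grid <- function(grid) {
  own <- grid$train_subject == grid$test_subject
  agg <- function(sub, col) {
    m <- tapply(sub[[col]], factor(sub$condition, levels = WC_LEVELS), mean)
    as.numeric(m)
  }
  per <- data.frame(
    condition = WC_LEVELS,
    own_rmse = agg(grid[own, ], "rmse"), own_r2 = agg(grid[own, ], "r2"),
    cross_rmse = if (any(!own)) agg(grid[!own, ], "rmse") else NA_real_,
    cross_r2 = if (any(!own)) agg(grid[!own, ], "r2") else NA_real_
  )
  overall <- c(own_rmse = mean(per$own_rmse), own_r2 = mean(per$own_r2),
               cross_rmse = mean(per$cross_rmse), cross_r2 = mean(per$cross_r2))
  list(per_condition = per, overall = overall)
}

#' Overall metric from per-condition values
#'
#' The aggregate reported for a five-condition evaluation is the unweighted
#' mean of the five per-condition values.
#'
#' @param x Numeric vector of per-condition values.
#' @return Their mean.
#' @export
overall_from_conditions <- function(x) mean(as.numeric(x))

#' Range-normalized RMSE
#'
#' NRMSE divides the RMSE by the range of the quantity; for gait phase the
#' range is 100 by construction, so the NRMSE in percent equals the RMSE in
#' phase units.
#'
#' @param rmse RMSE in phase units (0-100 scale).
#' @param range Phase range (default 100).
#' @return NRMSE in percent.
#' @export
nrmse_from_rmse <- function(rmse, range = 100) rmse / range * 100

#' Bundled reference evaluation tables
#'
#' `reference_crosssubject_grid()` returns a published own/cross-subject
#' evaluation grid from a ten-subject, five-condition insole gait study
#' (RMSE and R-squared per train-subject x test-subject x condition cell),
#' bundled as a worked example for [aggregate_phase_grid()].
#' `reference_condition_summary()` returns the study's per-condition summary
#' (own/cross RMSE and R-squared, rRMSE, APEE and NRMSE percentages).
#'
#' @return A data frame.
#' @export
reference_crosssubject_grid <- function() {
  path <- system.file("extdata", "reference_crosssubject_grid.csv", package = "gaitphase")
  g <- read.csv(path, stringsAsFactors = FALSE)
  g$train_subject <- as.character(g$train_subject)
  g$test_subject <- as.character(g$test_subject)
  class(g) <- c("cross_subject_grid", "data.frame")
  g
}

#' @rdname reference_crosssubject_grid
#' @export
reference_condition_summary <- function() {
  path <- system.file("extdata", "reference_percondition_summary.csv", package = "gaitphase")
  read.csv(path, stringsAsFactors = FALSE)
}

#' Input-feature ablation report
#'
#' Retrains the phase estimator once per input variant on identical splits
#' and seeds and evaluates each on the test recordings, yielding a
#' per-variant metric table. Variants without the condition feature ignore
#' the classifier entirely.
#'
#' @param split A [make_split()] object.
#' @param variants Integer vector of variants to compare (subset of 1:5).
#' @param config Base [gpe_config()]; its width is recomputed per variant.
#' @param wc_model Optional classifier used at evaluation time.
#' @param hop Evaluation hop.
#' @param verbose Print training progress.
#' @return Data frame with columns `variant`, `width`, `condition`, `n`,
#'   `rmse`, `r2`, `rrmse`, `apee`, `nrmse`.
#' @export
ablation_report <- function(split, variants = 1:5, config = gpe_config(),
                            wc_model = NULL, hop = 1L, verbose = FALSE) {
  rows <- list()
  for (v in variants) {
    cfg <- config
    cfg$variant <- as.integer(v)
    cfg$input_width <- feature_width(v)
    model <- fit_phase_estimator(split, cfg, verbose = verbose)
    ev <- evaluate_phase_model(model, split$test, wc_model = wc_model, hop = hop)
    rows[[length(rows) + 1L]] <- cbind(variant = v, width = feature_width(v),
                                       as.data.frame(ev))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
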