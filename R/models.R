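# Concatenate window arrays (d, n, t) along the window dimension.
cat_windows <- function(lst) {
  lst <- Filter(function(a) dim(a)[2L] > 0L, lst)
  if (!length(lst)) stop_arg("no windows to combine")
  d <- dim(lst[[1L]])[1L]; tt <- dim(lst[[1L]])[3L]
  n <- sum(vapply(lst, function(a) dim(a)[2L], integer(1)))
  out <- array(0, dim = c(d, n, tt))
  at <- 0L
  for (a in lst) {
    k <- dim(a)[2L]
    if (k > 0L) out[, at + seq_len(k), ] <- a
    at <- at + k
  }
  out
}

block_rows <- function(block) block$range[1L]:block$range[2L]

# Sub-recording restricted to a sample range (keeps labels/phase aligned).
crop_recording <- function(rec, rows) {
  rec$forces <- rec$forces[rows, , drop = FALSE]
  rec$times <- rec$times[rows]
  rec$wc <- rec$wc[rows]
  rec$phase <- rec$phase[rows]
  rec
}

collect_wc_windows <- function(blocks, cfg, stats) {
  xs <- list(); ys <- character(0)
  for (b in blocks) {
    rec <- crop_recording(b$recording, block_rows(b))
    normed <- apply_minmax(rec, stats)
    w <- build_windows(normed$forces, cfg$seq_len, cfg$hop, labels = normed$wc)
    if (length(w$end_idx)) {
      xs[[length(xs) + 1L]] <- w$x
      ys <- c(ys, w$labels)
    }
  }
  list(x = cat_windows(xs), y = ys)
}

#' Fit the walking-condition classifier
#'
#' Trains the first pipeline stage: a bidirectional LSTM that maps a sliding
#' window of the ten normalized FSR channels to one of the five walking
#' conditions. Normalization statistics are fit on the training blocks only
#' and frozen into the model. With `config$folds > 1`, training runs k-fold
#' cross-validation over contiguous window blocks with early stopping on
#' each held-out fold; the fold with the lowest validation loss supplies the
#' final weights.
#'
#' @param split A [make_split()] object.
#' @param config A [wc_config()].
#' @param stats Optional pre-fit [fit_norm_stats()]; fitted from the training
#'   blocks when NULL.
#' @param verbose Print per-epoch losses.
#' @return Object of class `c("wc_classifier", "bilstm_model")` with elements
#'   `params`, `config`, `stats`, `history` (one data frame per fold),
#'   `best_fold` and `levels`.
#' @export
fit_wc_classifier <- function(split, config = wc_config(), stats = NULL,
                              verbose = FALSE) {
  if (is.null(stats)) {
    train_recs <- lapply(split$train, function(b)
      list(forces = b$recording$forces[block_rows(b), , drop = FALSE]))
    stats <- fit_norm_stats(lapply(train_recs, structure, class = "fsr_recording"))
  }
  tr <- collect_wc_windows(split$train, config, stats)
  va <- if (length(split$validation))
    collect_wc_windows(split$validation, config, stats) else NULL
  missing_cls <- setdiff(WC_LEVELS, unique(tr$y))
  if (length(missing_cls))
    stop_arg("class absent from training data: %s", paste(missing_cls, collapse = ", "))
  y_tr <- prepare_targets(tr$y, config)
  histories <- list(); fits <- list()
  if (config$folds > 1L) {
    # pool train + validation windows, keep temporal order, cut k contiguous folds
    x_all <- if (is.null(va)) tr$x else cat_windows(list(tr$x, va$x))
    y_all_lab <- c(tr$y, if (is.null(va)) character(0) else va$y)
    y_all <- prepare_targets(y_all_lab, config)
    n <- dim(x_all)[2L]
    fold_id <- cut(seq_len(n), breaks = config$folds, labels = FALSE)
    for (f in seq_len(config$folds)) {
      in_f <- fold_id == f
      cfg_f <- config; cfg_f$seed <- config$seed + f
      fit <- bilstm_train(x_all[, !in_f, , drop = FALSE], y_all[, !in_f, drop = FALSE],
                          x_all[, in_f, , drop = FALSE], y_all[, in_f, drop = FALSE],
                          cfg_f, verbose = verbose)
      histories[[f]] <- fit$history
      fits[[f]] <- fit
    }
    best <- which.min(vapply(fits, `[[`, numeric(1), "best_val"))
    params <- fits[[best]]$params
  } else {
    fit <- bilstm_train(tr$x, y_tr,
                        if (is.null(va)) NULL else va$x,
                        if (is.null(va)) NULL else prepare_targets(va$y, config),
                        config, verbose = verbose)
    histories[[1L]] <- fit$history
    params <- fit$params
    best <- 1L
  }
  structure(list(params = params, config = config, stats = stats,
                 history = histories, best_fold = best, levels = WC_LEVELS),
            class = c("wc_classifier", "bilstm_model"))
}

#' Predict walking conditions
#'
#' @param object A [fit_wc_classifier()] model.
#' @param newdata A window array (width x n x seq_len), a normalized-or-raw
#'   `fsr_recording`, or a samples x 10 force matrix (raw; it is normalized
#'   with the model's frozen statistics).
#' @param type `"prob"` for the per-window class-probability matrix (rows sum
#'   to 1), `"class"` for argmax labels.
#' @param hop Window hop when `newdata` is a recording/matrix.
#' @param ... Unused.
#' @return Probability matrix or character vector, with attribute `end_idx`
#'   giving the final sample of each window when windows were cut here.
#' @export
predict.wc_classifier <- function(object, newdata, type = c("prob", "class"),
                                  hop = 1L, ...) {
  type <- match.arg(type)
  cfg <- object$config
  end_idx <- NULL
  if (is.array(newdata) && length(dim(newdata)) == 3L) {
    x <- newdata
  } else {
    mat <- if (inherits(newdata, "fsr_recording")) {
      if (isTRUE(newdata$normalized)) newdata$forces
      else apply_minmax(newdata, object$stats)$forces
    } else apply_minmax(newdata, object$stats)
    w <- build_windows(mat, cfg$seq_len, hop)
    x <- w$x; end_idx <- w$end_idx
  }
  if (dim(x)[1L] != cfg$input_width)
    stop_arg("window width %d does not match model input width %d",
             dim(x)[1L], cfg$input_width)
  prob <- bilstm_predict(object$params, x, cfg)
  colnames(prob) <- object$levels
  out <- if (type == "class") object$levels[max.col(prob, ties.method = "first")]
         else prob
  attr(out, "end_idx") <- end_idx
  out
}

# Feature windows + CSF targets for one recording block of a split.
collect_gpe_windows <- function(blocks, cfg, stats, wc_provider) {
  xs <- list(); ys <- list()
  for (b in blocks) {
    rec <- crop_recording(b$recording, block_rows(b))
    normed <- apply_minmax(rec, stats)
    wc_in <- wc_provider(rec) # raw: a classifier provider applies its own stats
    feat <- build_feature_matrix(normed$forces, stats, cfg$variant %||% 1L, wc = wc_in)
    w <- build_windows(feat, cfg$seq_len, cfg$hop, labels = normed$phase)
    keep <- !is.na(w$labels)
    if (any(keep)) {
      xs[[length(xs) + 1L]] <- w$x[, keep, , drop = FALSE]
      ys[[length(ys) + 1L]] <- encode_phase(w$labels[keep])
    }
  }
  list(x = cat_windows(xs), y = do.call(rbind, ys))
}

#' Fit the continuous gait-phase estimator
#'
#' Trains the second pipeline stage: a bidirectional LSTM regressing the
#' sine-cosine encoding of the gait phase at the final sample of each sliding
#' feature window (MSE loss). During training the walking-condition feature
#' uses ground-truth labels by default (teacher forcing, decoupling the two
#' stages); pass a fitted classifier as `wc_model` to train on stage-1
#' predictions instead. Ground-truth phase comes from the recordings'
#' phase channel where present, otherwise from heel-strike detection and
#' linear labelling.
#'
#' @param split A [make_split()] object.
#' @param config A [gpe_config()]; its `variant` picks the input features.
#' @param stats Optional pre-fit normalization statistics.
#' @param wc_model Optional `wc_classifier` supplying the condition feature
#'   during training (default: ground-truth labels).
#' @param verbose Print per-epoch losses.
#' @return Object of class `c("phase_estimator", "bilstm_model")`.
#' @export
fit_phase_estimator <- function(split, config = gpe_config(), stats = NULL,
                                wc_model = NULL, verbose = FALSE) {
  if (is.null(stats)) {
    train_recs <- lapply(split$train, function(b)
      list(forces = b$recording$forces[block_rows(b), , drop = FALSE]))
    stats <- fit_norm_stats(lapply(train_recs, structure, class = "fsr_recording"))
  }
  variant <- config$variant %||% 1L
  wc_provider <- function(rec) {
    if (!variant %in% c(1L, 3L, 4L, 5L)) return(NULL)
    if (is.null(wc_model)) rec$wc
    else predict_wc_per_sample(wc_model, rec, hop = max(1L, config$hop))$onehot
  }
  get_phase <- function(rec) {
    if (!is.null(rec$phase) && any(!is.na(rec$phase))) return(rec)
    ev <- detect_heel_strikes(rec$forces[, "R_heel"])
    rec$phase <- label_gait_phase(length(rec$times), ev)$phase
    rec
  }
  prep <- function(blocks) {
    blocks <- lapply(blocks, function(b) {
      b$recording <- get_phase(b$recording); b
    })
    collect_gpe_windows(blocks, config, stats, wc_provider)
  }
  tr <- prep(split$train)
  va <- if (length(split$validation)) prep(split$validation) else NULL
  fit <- bilstm_train(tr$x, t(tr$y),
                      if (is.null(va)) NULL else va$x,
                      if (is.null(va)) NULL else t(va$y),
                      config, verbose = verbose)
  structure(list(params = fit$params, config = config, stats = stats,
                 history = list(fit$history), best_fold = 1L,
                 variant = variant, teacher_forced = is.null(wc_model)),
            class = c("phase_estimator", "bilstm_model"))
}

#' Predict gait phase from feature windows
#'
#' @param object A [fit_phase_estimator()] model.
#' @param newdata Feature window array (width x n x seq_len) or a per-sample
#'   feature matrix (windows are cut here with hop 1).
#' @param type `"phase"` for decoded phase in \[0, 100), `"csf"` for the raw
#'   (cos, sin) output pair.
#' @param ... Unused.
#' @return Numeric phase vector (with attribute `csf`), or the raw 2-column
#'   matrix.
#' @export
predict.phase_estimator <- function(object, newdata, type = c("phase", "csf"), ...) {
  type <- match.arg(type)
  cfg <- object$config
  x <- if (is.array(newdata) && length(dim(newdata)) == 3L) newdata
       else build_windows(newdata, cfg$seq_len, 1L)$x
  if (dim(x)[1L] != cfg$input_width)
    stop_arg("feature width %d does not match variant %d width %d",
             dim(x)[1L], object$variant, cfg$input_width)
  csf <- bilstm_predict(object$params, x, cfg)
  colnames(csf) <- c("cos", "sin")
  if (type == "csf") return(csf)
  phase <- decode_phase(csf)
  attr(phase, "csf") <- csf
  phase
}

# Per-sample condition predictions from windowed classifier output: each
# window's label is assigned to its final sample and held until the next
# evaluated sample; samples before the first full window are backfilled but
# flagged invalid.
predict_wc_per_sample <- function(wc_model, recording, hop = 1L, soft = FALSE) {
  prob <- predict(wc_model, recording, type = "prob", hop = hop)
  ends <- attr(prob, "end_idx")
  n <- length(recording$times)
  lab_win <- wc_model$levels[max.col(prob, ties.method = "first")]
  labels <- character(n); onehot <- matrix(0, n, 5L, dimnames = list(NULL, WC_LEVELS))
  valid <- logical(n)
  if (length(ends)) {
    idx <- findInterval(seq_len(n), ends)
    idx_f <- pmax(idx, 1L) # backfill before the first window
    labels <- lab_win[idx_f]
    if (soft) onehot <- prob[idx_f, , drop = FALSE]
    else onehot[cbind(seq_len(n), match(labels, WC_LEVELS))] <- 1
    valid <- idx >= 1L
  }
  list(labels = labels, onehot = onehot, valid = valid, ends = ends)
}

#' Run the serial two-stage pipeline on a recording
#'
#' Applies the walking-condition classifier, injects its per-sample output
#' into the phase-estimator features exactly as the model's input variant
#' dictates (hard one-hot of the argmax by default, class probabilities with
#' `soft = TRUE`), and decodes the estimated sine-cosine pair to a phase in
#' \[0, 100). Samples before the first full window of either stage are
#' flagged invalid rather than extrapolated.
#'
#' @param recording A raw `fsr_recording`.
#' @param wc_model A `wc_classifier` (may be NULL for variants without the
#'   condition feature; supplying one anyway raises a warning).
#' @param phase_model A `phase_estimator`.
#' @param hop Evaluation hop in samples (1 = every sample).
#' @param soft Feed stage-2 the stage-1 class probabilities instead of a
#'   hard one-hot.
#' @return Data frame with one row per sample: `time`, `wc_pred`,
#'   `phase_pred`, `valid`.
#' @export
run_pipeline <- function(recording, wc_model, phase_model, hop = 1L, soft = FALSE) {
  variant <- phase_model$variant
  needs_wc <- variant %in% c(1L, 3L, 4L, 5L)
  if (!needs_wc && !is.null(wc_model))
    warning("input variant ", variant, " ignores the condition feature; wc_model unused")
  normed <- apply_minmax(recording, phase_model$stats)
  n <- length(normed$times)
  if (needs_wc) {
    if (is.null(wc_model)) stop_arg("variant %d needs a wc_model", variant)
    # stage 1 normalizes the raw recording with its own frozen statistics
    wcp <- predict_wc_per_sample(wc_model, recording, hop = hop, soft = soft)
    wc_in <- wcp$onehot
  } else {
    wcp <- NULL
    wc_in <- NULL
  }
  feat <- build_feature_matrix(normed$forces, phase_model$stats, variant, wc = wc_in)
  w <- build_windows(feat, phase_model$config$seq_len, hop)
  csf <- bilstm_predict(phase_model$params, w$x, phase_model$config)
  phase_win <- decode_phase(csf)
  phase_pred <- rep(NA_real_, n)
  wc_pred <- rep(NA_character_, n)
  valid <- logical(n)
  phase_pred[w$end_idx] <- phase_win
  valid[w$end_idx] <- TRUE
  if (needs_wc) {
    wc_pred <- wcp$labels
    # a prediction only counts once both stages have seen a full window
    first_ok <- if (length(wcp$ends)) wcp$ends[1L] else Inf
    valid <- valid & seq_len(n) >= first_ok
  }
  data.frame(time = normed$times, wc_pred = wc_pred, phase_pred = phase_pred,
             valid = valid, stringsAsFactors = FALSE)
}

# --- shared S3 methods for fitted networks --------------------------------

#' @export
print.bilstm_model <- function(x, ...) {
  cfg <- x$config
  kind <- if (inherits(x, "wc_classifier")) "Walking-condition classifier"
          else sprintf("Gait-phase estimator (input variant %d)", x$variant)
  cat(sprintf("%s (bidirectional LSTM)\n", kind))
  cat(sprintf("  stack: BiLSTM(%d) -> dropout %.2f -> BiLSTM(%d) -> dropout %.2f -> dense(%d) -> %s(%d)\n",
              cfg$hidden[1L], cfg$dropout[1L], cfg$hidden[2L], cfg$dropout[2L],
              cfg$dense, if (cfg$task == "classification") "softmax" else "linear",
              cfg$output))
  cat(sprintf("  input %d x %d, %s parameters\n", cfg$seq_len, cfg$input_width,
              format(bilstm_param_count(cfg)[["total"]], big.mark = ",")))
  h <- x$history[[x$best_fold]]
  if (nrow(h))
    cat(sprintf("  trained %d epochs, final val loss %.5f\n", nrow(h),
                h$val_loss[nrow(h)]))
  invisible(x)
}

#' @export
summary.bilstm_model <- function(object, ...) {
  print(object)
  cat(sprintf("  folds: %d (best fold %d)\n", length(object$history), object$best_fold))
  pc <- bilstm_param_count(object$config)
  cat("  parameters per layer:\n")
  for (nm in setdiff(names(pc), "total"))
    cat(sprintf("    %-8s %s\n", nm, format(pc[[nm]], big.mark = ",")))
  invisible(object)
}

#' @export
coef.bilstm_model <- function(object, ...) object$params

#' Plot training curves
#' @param x A fitted `bilstm_model`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.bilstm_model <- function(x, ...) {
  h <- x$history[[x$best_fold]]
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("black", "red"), xlab = "epoch",
                    ylab = "loss", ...)
  graphics::legend("topright", legend = c("train", "validation"),
                   col = c("black", "red"), lty = 1, bty = "n")
  invisible(x)
}
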