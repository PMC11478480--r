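#' Bi-LSTM network configuration
#'
#' Shared configuration of the two-layer bidirectional LSTM stack used by
#' both pipeline stages: two stacked bidirectional recurrent layers with
#' dropout after each, a ReLU dense layer and a task head (softmax over the
#' five walking conditions, or a linear 2-unit output regressing the
#' sine-cosine phase encoding). Training uses Adam with early stopping on
#' validation loss.
#'
#' @param input_width Features per timestep.
#' @param seq_len Window length in samples.
#' @param task `"classification"` or `"regression"`.
#' @param output Output width (5 classes or 2 regression targets).
#' @param hidden Widths of the two recurrent layers.
#' @param dropout Dropout rates after each recurrent layer.
#' @param dense Dense-layer width.
#' @param batch_size,lr,max_epochs,patience Optimizer settings (Adam).
#' @param folds Cross-validation folds for training (1 = plain split).
#' @param hop Window hop used when cutting training windows from series.
#' @param seed Integer seed controlling initialization, shuffling, dropout.
#' @return Object of class `bilstm_config`.
#' @export
bilstm_config <- function(input_width, seq_len, task = c("classification", "regression"),
                          output = if (task == "classification") 5L else 2L,
                          hidden = c(128L, 64L), dropout = c(0.25, 0.25),
                          dense = 64L, batch_size = 100L, lr = 0.001,
                          max_epochs = 100L, patience = 5L, folds = 1L,
                          hop = 1L, seed = 1L) {
  task <- match.arg(task)
  if (any(hidden < 1) || dense < 1 || output < 1) stop_arg("layer widths must be positive")
  if (any(dropout < 0 | dropout >= 1)) stop_arg("dropout rates must lie in [0, 1)")
  if (task == "classification" && output != 5L)
    stop_arg("the condition classifier has 5 output classes")
  if (task == "regression" && output != 2L)
    stop_arg("the phase estimator has a 2-unit output (cos, sin)")
  structure(list(
    input_width = as.integer(input_width), seq_len = as.integer(seq_len),
    task = task, output = as.integer(output), hidden = as.integer(hidden),
    dropout = dropout, dense = as.integer(dense),
    batch_size = as.integer(batch_size), lr = lr,
    max_epochs = as.integer(max_epochs), patience = as.integer(patience),
    folds = as.integer(folds), hop = as.integer(hop), seed = as.integer(seed)
  ), class = "bilstm_config")
}

#' Walking-condition classifier configuration
#'
#' Defaults: Bi-LSTM widths 128 and 64, dropout 0.25 after each, dense 64,
#' softmax over 5 classes, sequence length 100 on the 10 FSR channels, batch
#' 100, Adam at 0.001, categorical cross-entropy, early-stop patience 5,
#' five-fold cross-validation.
#'
#' @param ... Overrides passed to [bilstm_config()].
#' @return A `bilstm_config` for the classifier stage.
#' @export
wc_config <- function(...) {
  defaults <- list(input_width = 10L, seq_len = 100L, task = "classification",
                   output = 5L, hidden = c(128L, 64L), dropout = c(0.25, 0.25),
                   dense = 64L, folds = 5L)
  do.call(bilstm_config, utils::modifyList(defaults, list(...)))
}

#' Phase-estimator configuration
#'
#' Defaults: Bi-LSTM widths 128 and 32, dropout 0.25 after each, dense 2,
#' linear 2-unit output regressing the sine-cosine phase pair with MSE,
#' sequence length 25, batch 100, Adam at 0.001, early-stop patience 5.
#' The input width follows the chosen feature variant (see
#' [feature_width()]).
#'
#' @param variant Input-feature variant 1-5.
#' @param ... Overrides passed to [bilstm_config()].
#' @return A `bilstm_config` for the phase-estimation stage, with a
#'   `variant` attribute.
#' @export
gpe_config <- function(variant = 1L, ...) {
  defaults <- list(input_width = feature_width(variant), seq_len = 25L,
                   task = "regression", output = 2L, hidden = c(128L, 32L),
                   dropout = c(0.25, 0.25), dense = 2L, folds = 1L)
  cfg <- do.call(bilstm_config, utils::modifyList(defaults, list(...)))
  cfg$variant <- as.integer(variant)
  cfg
}

# Glorot-uniform initial weights; forget-gate biases start at 1.
bilstm_init <- function(cfg, seed = cfg$seed) {
  set.seed(seed)
  glorot <- function(nr, nc) {
    lim <- sqrt(6 / (nr + nc))
    matrix(runif(nr * nc, -lim, lim), nr, nc)
  }
  lstm_block <- function(d_in, h) {
    b <- numeric(4 * h)
    b[(h + 1):(2 * h)] <- 1 # forget gate
    list(W = glorot(4 * h, d_in), U = glorot(4 * h, h), b = b)
  }
  d <- cfg$input_width; h1 <- cfg$hidden[1L]; h2 <- cfg$hidden[2L]
  l1f <- lstm_block(d, h1); l1b <- lstm_block(d, h1)
  l2f <- lstm_block(2 * h1, h2); l2b <- lstm_block(2 * h1, h2)
  list(W1f = l1f$W, U1f = l1f$U, b1f = l1f$b,
       W1b = l1b$W, U1b = l1b$U, b1b = l1b$b,
       W2f = l2f$W, U2f = l2f$U, b2f = l2f$b,
       W2b = l2b$W, U2b = l2b$U, b2b = l2b$b,
       Wd = glorot(cfg$dense, 2 * h2), bd = numeric(cfg$dense),
       Wo = glorot(cfg$output, cfg$dense), bo = numeric(cfg$output))
}

#' Number of trainable parameters of a configuration
#'
#' Computed layer-by-layer from the widths: each bidirectional recurrent
#' layer contributes `2 * (4h (d + h) + 4h)` parameters, the dense and output
#' layers their weight matrices plus biases.
#'
#' @param cfg A [bilstm_config()].
#' @return Named integer vector per layer plus `total`.
#' @export
bilstm_param_count <- function(cfg) {
  d <- cfg$input_width; h1 <- cfg$hidden[1L]; h2 <- cfg$hidden[2L]
  lstm_n <- function(d_in, h) 2 * (4 * h * (d_in + h) + 4 * h)
  c(bilstm1 = lstm_n(d, h1), bilstm2 = lstm_n(2 * h1, h2),
    dense = cfg$dense * (2 * h2 + 1), output = cfg$output * (cfg$dense + 1),
    total = lstm_n(d, h1) + lstm_n(2 * h1, h2) +
      cfg$dense * (2 * h2 + 1) + cfg$output * (cfg$dense + 1))
}

# Targets in the K x B layout the C++ code expects.
prepare_targets <- function(labels, cfg) {
  if (cfg$task == "classification") {
    idx <- if (is.factor(labels) || is.character(labels)) match(as.character(labels), WC_LEVELS)
           else as.integer(labels)
    if (anyNA(idx)) stop_arg("unknown class label")
    y <- matrix(0, nrow = cfg$output, ncol = length(idx))
    y[cbind(idx, seq_along(idx))] <- 1
    y
  } else {
    y <- if (is.null(dim(labels))) matrix(labels, ncol = 2L) else labels
    t(y) # -> 2 x B
  }
}

adam_state <- function(params) {
  list(m = lapply(params, function(p) p * 0), v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_update <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] - lr * (state$m[[nm]] / bc1) /
      (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

eval_loss <- function(params, x, y, cfg, batch = 512L) {
  n <- dim(x)[2L]
  if (n == 0L) return(NA_real_)
  task <- if (cfg$task == "classification") 0L else 1L
  tot <- 0
  for (start in seq(1L, n, by = batch)) {
    idx <- start:min(start + batch - 1L, n)
    tot <- tot + length(idx) *
      cpp_bilstm_loss(params, x[, idx, , drop = FALSE], y[, idx, drop = FALSE], task)
  }
  tot / n
}

# Core training loop: Adam over shuffled mini-batches, inverted dropout,
# early stopping on validation loss with best-weight restore.
bilstm_train <- function(x, y, x_val = NULL, y_val = NULL, cfg,
                         params = NULL, verbose = FALSE) {
  stopifnot(length(dim(x)) == 3L)
  n <- dim(x)[2L]
  if (n < 1L) stop_arg("no training windows")
  set.seed(cfg$seed)
  if (is.null(params)) params <- bilstm_init(cfg, seed = cfg$seed)
  state <- adam_state(params)
  task <- if (cfg$task == "classification") 0L else 1L
  has_val <- !is.null(x_val) && dim(x_val)[2L] > 0L
  best_val <- Inf; best_params <- params; bad_epochs <- 0L
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  h1 <- cfg$hidden[1L]; h2 <- cfg$hidden[2L]; T_len <- dim(x)[3L]
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      xb <- x[, idx, , drop = FALSE]
      yb <- y[, idx, drop = FALSE]
      b <- length(idx)
      m1 <- m2 <- NULL
      if (cfg$dropout[1L] > 0) {
        m1 <- array((runif(2 * h1 * b * T_len) >= cfg$dropout[1L]) /
                      (1 - cfg$dropout[1L]), dim = c(2 * h1, b, T_len))
      }
      if (cfg$dropout[2L] > 0) {
        m2 <- matrix((runif(2 * h2 * b) >= cfg$dropout[2L]) /
                       (1 - cfg$dropout[2L]), nrow = 2 * h2)
      }
      res <- cpp_bilstm_grad(params, xb, yb, task, m1, m2)
      upd <- adam_update(params, res$grads, state, cfg$lr)
      params <- upd$params; state <- upd$state
      ep_loss <- ep_loss + res$loss * b
    }
    ep_loss <- ep_loss / n
    val_loss <- if (has_val) eval_loss(params, x_val, y_val, cfg) else NA_real_
    history <- rbind(history, data.frame(epoch = epoch, train_loss = ep_loss,
                                         val_loss = val_loss))
    if (verbose)
      message(sprintf("epoch %d: train %.5f val %.5f", epoch, ep_loss, val_loss))
    if (has_val) {
      if (val_loss < best_val - 1e-12) {
        best_val <- val_loss; best_params <- params; bad_epochs <- 0L
      } else {
        bad_epochs <- bad_epochs + 1L
        if (bad_epochs >= cfg$patience) break
      }
    } else best_params <- params
  }
  list(params = best_params, history = history,
       best_val = if (has_val) best_val else NA_real_)
}

# Forward pass over windows in evaluation mode (no dropout).
bilstm_predict <- function(params, x, cfg, batch = 512L) {
  n <- dim(x)[2L]
  task <- if (cfg$task == "classification") 0L else 1L
  out <- matrix(NA_real_, nrow = n, ncol = cfg$output)
  if (n == 0L) return(out)
  for (start in seq(1L, n, by = batch)) {
    idx <- start:min(start + batch - 1L, n)
    o <- cpp_bilstm_forward(params, x[, idx, , drop = FALSE], task)$output
    out[idx, ] <- t(o)
  }
  out
}
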