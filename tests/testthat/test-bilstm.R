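# The recurrent stack is implemented in compiled code; these tests pin its
# correctness against numerical differentiation and basic learning behaviour.

tiny_net_cfg <- function(task) {
  bilstm_config(input_width = 3, seq_len = 4, task = task, hidden = c(3, 2),
                dropout = c(0, 0), dense = 3, seed = 42)
}

test_that("analytic gradients agree with central differences", {
  for (task in c("classification", "regression")) {
    cfg <- tiny_net_cfg(task)
    params <- gaitphase:::bilstm_init(cfg)
    set.seed(9)
    B <- 3
    x <- array(rnorm(3 * B * 4), dim = c(3, B, 4))
    y <- if (task == "classification") {
      m <- matrix(0, 5, B); m[cbind(c(2, 4, 5), 1:B)] <- 1; m
    } else matrix(rnorm(2 * B), 2, B)
    tk <- if (task == "classification") 0L else 1L
    res <- gaitphase:::cpp_bilstm_grad(params, x, y, tk, NULL, NULL)
    eps <- 1e-6
    for (nm in names(params)) {
      p <- params[[nm]]
      for (i in sample(length(p), min(5, length(p)))) {
        pp <- params; pp[[nm]][i] <- p[i] + eps
        pm <- params; pm[[nm]][i] <- p[i] - eps
        num <- (gaitphase:::cpp_bilstm_loss(pp, x, y, tk) -
                  gaitphase:::cpp_bilstm_loss(pm, x, y, tk)) / (2 * eps)
        expect_equal(res$grads[[nm]][i], num, tolerance = 1e-4,
                     label = sprintf("%s grad [%s, %d]", task, nm, i))
      }
    }
  }
})

test_that("initialization and training are deterministic given the seed", {
  cfg <- tiny_net_cfg("regression")
  expect_identical(gaitphase:::bilstm_init(cfg), gaitphase:::bilstm_init(cfg))
  set.seed(1)
  x <- array(rnorm(3 * 30 * 4), dim = c(3, 30, 4))
  y <- t(encode_phase(runif(30, 0, 100)))
  cfg$max_epochs <- 3L
  f1 <- gaitphase:::bilstm_train(x, y, cfg = cfg)
  f2 <- gaitphase:::bilstm_train(x, y, cfg = cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$params, f2$params)
})

test_that("parameter counts follow the layer widths", {
  cfg <- wc_config()
  pc <- bilstm_param_count(cfg)
  params <- gaitphase:::bilstm_init(cfg)
  expect_equal(unname(pc["total"]), sum(lengths(params)))
  # first bidirectional layer: 2 * (4*128*(10+128) + 4*128)
  expect_equal(unname(pc["bilstm1"]), 2 * (4 * 128 * (10 + 128) + 4 * 128))
})

test_that("early stopping waits out the patience window", {
  cfg <- tiny_net_cfg("regression")
  cfg$lr <- 0          # no learning: validation loss never improves
  cfg$max_epochs <- 30L
  cfg$patience <- 5L
  set.seed(2)
  x <- array(rnorm(3 * 20 * 4), dim = c(3, 20, 4))
  y <- matrix(rnorm(40), 2, 20)
  fit <- gaitphase:::bilstm_train(x, y, x, y, cfg = cfg)
  # epoch 1 sets the best; five non-improving epochs follow
  expect_equal(nrow(fit$history), 6L)
})

test_that("the classifier learns a separable fixture", {
  # class = which input channel carries the offset
  set.seed(4)
  n <- 150
  cls <- sample(1:5, n, replace = TRUE)
  x <- array(rnorm(5 * n * 6, sd = 0.3), dim = c(5, n, 6))
  for (i in seq_len(n)) x[cls[i], i, ] <- x[cls[i], i, ] + 2
  cfg <- bilstm_config(input_width = 5, seq_len = 6, task = "classification",
                       hidden = c(8, 6), dropout = c(0, 0), dense = 8,
                       max_epochs = 25, lr = 0.01, batch_size = 32, seed = 3)
  y <- gaitphase:::prepare_targets(wc_levels()[cls], cfg)
  fit <- gaitphase:::bilstm_train(x, y, cfg = cfg)
  expect_lt(fit$history$train_loss[nrow(fit$history)], fit$history$train_loss[1])
  prob <- gaitphase:::bilstm_predict(fit$params, x, cfg)
  expect_equal(rowSums(prob), rep(1, n), tolerance = 1e-6)
  expect_gt(mean(max.col(prob) == cls), 0.95)
})

test_that("the regressor fits a smooth phase target", {
  # windows of a noiseless sinusoid predicting the phase at the window end
  set.seed(5)
  phase <- (seq_len(400) * 0.9) %% 100
  feats <- cbind(encode_phase(phase), encode_phase(phase * 2))
  w <- build_windows(feats, seq_len = 8, hop = 2, labels = phase)
  cfg <- bilstm_config(input_width = 4, seq_len = 8, task = "regression",
                       hidden = c(8, 6), dropout = c(0, 0), dense = 4,
                       max_epochs = 40, lr = 0.01, batch_size = 32, seed = 6)
  y <- gaitphase:::prepare_targets(encode_phase(w$labels), cfg)
  n <- dim(w$x)[2]
  val <- seq_len(n) %% 5 == 0
  fit <- gaitphase:::bilstm_train(w$x[, !val, , drop = FALSE], y[, !val],
                                  w$x[, val, , drop = FALSE], y[, val], cfg = cfg)
  expect_lt(min(fit$history$val_loss), 0.05)
})
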