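test_that("identical series give zero error and perfect fit", {
  p <- runif(500, 0, 100)
  m <- phase_error_metrics(p, p)
  ov <- m[m$condition == "overall", ]
  expect_equal(ov$rmse, 0)
  expect_equal(ov$r2, 1)
  expect_equal(ov$apee, 0)
  expect_equal(ov$nrmse, 0)
})

test_that("errors wrap around the 0/100 boundary", {
  expect_equal(phase_error(99.5, 0.5), 1)
  expect_equal(phase_error(0.5, 99.5), -1)
  expect_equal(phase_error(99.5, 0.5, circular = FALSE), -99)
  m <- phase_error_metrics(c(99.5), c(0.5))
  expect_equal(m$rmse[m$condition == "overall"], 1)
})

test_that("a constant circular offset yields RMSE equal to the offset", {
  p <- seq(0, 99.5, by = 0.5)
  for (delta in c(0.5, 3, 17, 49.5)) {
    est <- (p + delta) %% 100
    m <- phase_error_metrics(p, est)
    expect_equal(m$rmse[m$condition == "overall"], delta, tolerance = 1e-9)
    expect_equal(m$apee[m$condition == "overall"], delta, tolerance = 1e-9)
  }
})

test_that("metrics match brute-force recomputation on random series", {
  set.seed(77)
  for (rep in 1:4) {
    n <- 250
    true <- runif(n, 0, 100)
    est <- (true + rnorm(n, 0, 8)) %% 100
    m <- phase_error_metrics(true, est)
    ov <- m[m$condition == "overall", ]
    # brute-force, element by element
    e <- numeric(n)
    for (i in seq_len(n)) {
      d <- est[i] - true[i]
      while (d > 50) d <- d - 100
      while (d <= -50) d <- d + 100
      e[i] <- d
    }
    expect_equal(ov$rmse, sqrt(sum(e^2) / n), tolerance = 1e-9)
    expect_equal(ov$apee, sum(abs(e)) / n, tolerance = 1e-9)
    expect_equal(ov$rrmse, sqrt(sum(e^2) / n) / (sum(est) / n) * 100, tolerance = 1e-9)
    ct <- cbind(cos(true * 2 * pi / 100), sin(true * 2 * pi / 100))
    ce <- cbind(cos(est * 2 * pi / 100), sin(est * 2 * pi / 100))
    ss_res <- sum((ce - ct)^2)
    ss_tot <- sum((ct[, 1] - mean(ct[, 1]))^2) + sum((ct[, 2] - mean(ct[, 2]))^2)
    expect_equal(ov$r2, 1 - ss_res / ss_tot, tolerance = 1e-9)
  }
})

test_that("undefined relative error is flagged rather than inverted", {
  m <- phase_error_metrics(c(5, 10), c(0, 0))
  expect_true(is.na(m$rrmse[m$condition == "overall"]))
})

test_that("confusion matrices tally counts exactly", {
  set.seed(12)
  n <- 400
  true <- sample(wc_levels(), n, replace = TRUE)
  pred <- ifelse(runif(n) < 0.8, true, sample(wc_levels(), n, replace = TRUE))
  cm <- wc_confusion(true, pred)
  # brute-force tally
  for (a in wc_levels()) for (b in wc_levels()) {
    expect_equal(unname(cm$counts[a, b]), sum(true == a & pred == b))
  }
  expect_equal(sum(cm$counts), n)
  rs <- rowSums(cm$percent)
  expect_true(all(abs(rs[!is.na(rs)] - 100) < 0.5))
  expect_equal(cm$accuracy, mean(true == pred))

  perfect <- wc_confusion(true, true)
  expect_equal(unname(diag(perfect$percent)), rep(100, 5))

  subj <- rep(c("a", "b"), length.out = n)
  cms <- wc_confusion(true, pred, subject = subj)
  expect_false(is.null(cms$percent_sd))
  expect_equal(dim(cms$percent_sd), c(5, 5))

  expect_error(wc_confusion(c("LW", "??"), c("LW", "LW")), "unknown condition")
})

test_that("grid aggregation averages diagonal and off-diagonal cells per condition", {
  # two subjects, hand-built grid
  g <- expand.grid(train_subject = c("a", "b"), test_subject = c("a", "b"),
                   condition = wc_levels(), stringsAsFactors = FALSE)
  g$rmse <- ifelse(g$train_subject == g$test_subject, 1, 3)
  g$r2 <- ifelse(g$train_subject == g$test_subject, 0.9, 0.6)
  expect_equal(nrow(g), 20)
  agg <- aggregate_phase_grid(g)
  expect_equal(unname(agg$overall["own_rmse"]), 1)
  expect_equal(unname(agg$overall["cross_rmse"]), 3)
  expect_equal(unname(agg$overall["own_r2"]), 0.9)
  expect_equal(agg$per_condition$cross_r2, rep(0.6, 5))
})

test_that("the bundled reference grid reproduces its published aggregates", {
  grid <- reference_crosssubject_grid()
  expect_equal(nrow(grid), 500L)
  agg <- aggregate_phase_grid(grid)
  # own-subject per-condition means reproduce the published per-condition RMSEs
  expect_equal(round(agg$per_condition$own_rmse, 3),
               c(0.658, 0.939, 0.917, 0.682, 0.775))
  expect_equal(round(agg$per_condition$own_r2, 3),
               c(0.922, 0.889, 0.892, 0.920, 0.908))
  expect_equal(round(agg$per_condition$cross_rmse, 3),
               c(1.845, 3.365, 2.842, 2.144, 1.974))
  expect_equal(round(unname(agg$overall["own_rmse"]), 3), 0.794)
  expect_equal(round(unname(agg$overall["cross_rmse"]), 3), 2.434)
  expect_equal(round(unname(agg$overall["own_r2"]), 3), 0.906)
})

test_that("NRMSE on a 100-unit phase range equals the RMSE in percent", {
  expect_equal(nrmse_from_rmse(0.658), 0.658)
  expect_equal(round(nrmse_from_rmse(0.658), 2), 0.66)
  expect_equal(nrmse_from_rmse(5, range = 50), 10)
})

test_that("cross-subject evaluation covers every train-test pair", {
  # reuse the tiny fitted models: evaluate the same model for 2 "subjects"
  gpm <- tiny_gpe_model()
  models <- list(S01 = gpm, S02 = gpm)
  test_sets <- split(tiny_split()$test,
                     vapply(tiny_split()$test, `[[`, character(1), "subject"))
  grid <- cross_subject_evaluation(models, test_sets, hop = 8)
  expect_s3_class(grid, "cross_subject_grid")
  expect_equal(sort(unique(paste(grid$train_subject, grid$test_subject))),
               c("S01 S01", "S01 S02", "S02 S01", "S02 S02"))
  expect_true(all(grid$rmse >= 0))
  expect_error(cross_subject_evaluation(models, test_sets["S01"]), "missing test data")
})

test_that("the ablation report spans the requested variants at their widths", {
  cfg <- tiny_gpe_cfg()
  cfg$max_epochs <- 2L
  tab <- ablation_report(tiny_split(), variants = c(2, 4), config = cfg, hop = 10)
  expect_setequal(unique(tab$variant), c(2, 4))
  expect_equal(unique(tab$width[tab$variant == 2]), 14)
  expect_equal(unique(tab$width[tab$variant == 4]), 9)
  expect_true(all(wc_levels() %in% tab$condition))
})
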