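test_that("min-max normalization matches a per-column oracle and clips held-out data", {
  set.seed(21)
  layout <- sensor_layout()
  train <- matrix(runif(200, 0, 4), 20, 10, dimnames = list(NULL, layout$channel))
  stats <- fit_norm_stats(list(structure(list(forces = train), class = "fsr_recording")))
  out <- apply_minmax(train, stats)
  oracle <- train
  for (j in 1:10) {
    oracle[, j] <- (train[, j] - min(train[, j])) / (max(train[, j]) - min(train[, j]))
  }
  expect_equal(out, oracle, tolerance = 1e-12)

  # a channel spanning [0, 4]: value 1 maps to 0.25
  tr2 <- train; tr2[1, 1] <- 0; tr2[2, 1] <- 4
  st2 <- fit_norm_stats(list(structure(list(forces = tr2), class = "fsr_recording")))
  probe <- tr2[1, , drop = FALSE]; probe[1, 1] <- 1
  expect_equal(unname(apply_minmax(probe, st2)[1, 1]), 0.25)

  # held-out values outside the training range are clipped
  hi <- train[1, , drop = FALSE] * 0 + 99
  expect_true(all(apply_minmax(hi, stats) == 1))
  lo <- train[1, , drop = FALSE] * 0 - 99
  expect_true(all(apply_minmax(lo, stats) == 0))

  flat <- train; flat[, 4] <- 2
  expect_error(
    fit_norm_stats(list(structure(list(forces = flat), class = "fsr_recording"))),
    "degenerate.*L_cuboid")
})

test_that("regional sums follow the forefoot/backfoot definitions", {
  layout <- sensor_layout()
  stats <- structure(list(fore_max = c(L = 1, R = 1), back_max = c(L = 1, R = 1)),
                     class = "norm_stats")
  x <- matrix(0, 1, 10, dimnames = list(NULL, layout$channel))
  x[, "R_toe"] <- 0.2; x[, "R_meta1"] <- 0.3; x[, "R_meta5"] <- 0.1
  expect_equal(unname(region_sums(x, stats)[1, "fore_R"]), 0.6)
  expect_equal(unname(region_sums(x * 0, stats)[1, ]), c(0, 0, 0, 0),
               ignore_attr = TRUE)

  set.seed(33)
  xr <- matrix(runif(50), 5, 10, dimnames = list(NULL, layout$channel))
  s2 <- structure(list(fore_max = c(L = 1.7, R = 2.1), back_max = c(L = 0.9, R = 1.3)),
                  class = "norm_stats")
  got <- region_sums(xr, s2)
  oracle <- cbind(
    (xr[, "L_toe"] + xr[, "L_meta1"] + xr[, "L_meta5"]) / 1.7,
    (xr[, "L_cuboid"] + xr[, "L_heel"]) / 0.9,
    (xr[, "R_toe"] + xr[, "R_meta1"] + xr[, "R_meta5"]) / 2.1,
    (xr[, "R_cuboid"] + xr[, "R_heel"]) / 1.3)
  expect_equal(unname(got), unname(oracle), tolerance = 1e-12)
})

test_that("centre of pressure is the force-weighted site coordinate with hold-over", {
  layout <- sensor_layout()
  x <- matrix(0, 3, 10, dimnames = list(NULL, layout$channel))
  x[1, "R_heel"] <- 0.8                       # heel only -> coordinate 0
  x[2, "R_heel"] <- 0.5; x[2, "R_toe"] <- 0.5 # equal heel/toe -> 0.5
  # row 3 is all zero: right COP holds the previous value
  cop <- compute_cop(x, layout)
  expect_equal(unname(cop[, "cop_R"]), c(0, 0.5, 0.5))
  expect_equal(unname(cop[, "cop_L"]), c(0, 0, 0)) # never loaded -> 0 from start

  set.seed(8)
  xr <- matrix(runif(40, 0.1, 1), 4, 10, dimnames = list(NULL, layout$channel))
  got <- compute_cop(xr, layout)
  for (i in 1:4) for (f in c("L", "R")) {
    cols <- layout$channel[layout$foot == f]
    coords <- layout$ap_coord[layout$foot == f]
    expect_equal(unname(got[i, paste0("cop_", f)]),
                 sum(xr[i, cols] * coords) / sum(xr[i, cols]), tolerance = 1e-12)
  }
})

test_that("heel-strike detection finds pulse onsets and honours the refractory period", {
  # clean pulse train: 10 pulses of 30 samples every 110 samples
  onsets <- 50 + 110 * (0:9)
  x <- numeric(1200)
  for (o in onsets) x[o + seq_len(30)] <- 0.9 # rise begins after sample o
  ev <- detect_heel_strikes(x)
  expect_length(ev, 10L)
  expect_equal(ev, onsets)

  expect_length(detect_heel_strikes(numeric(500)), 0L)
  expect_length(detect_heel_strikes(numeric(0)), 0L)

  # two crossings 50 ms apart collapse under a 300 ms refractory period
  y <- numeric(200)
  y[100:102] <- 0.5
  y[105:140] <- 0.5
  expect_length(detect_heel_strikes(y, refractory_s = 0.3), 1L)
  expect_length(detect_heel_strikes(y, refractory_s = 0.01), 2L)
})

test_that("phase labelling interpolates linearly between events", {
  gp <- label_gait_phase(150, c(1L, 101L))
  expect_equal(gp$phase[51], 50)
  expect_equal(gp$phase[1], 0)
  expect_equal(gp$phase[26], 25)
  expect_true(all(is.na(gp$phase[101:150])))  # at/after last event: invalid
  expect_false(any(gp$valid[101:150]))
  expect_error(label_gait_phase(100, c(5L)), "at least 2")

  # labelling a noiseless simulation recovers the generator's phase
  rec <- noiseless_recording()
  stats <- fit_norm_stats(list(rec))
  ev <- detect_heel_strikes(apply_minmax(rec, stats)$forces[, "R_heel"])
  gp2 <- label_gait_phase(length(rec$times), ev)
  err <- abs(circ_err(rec$phase[gp2$valid], gp2$phase[gp2$valid]))
  expect_lt(max(err), 1)
})

test_that("phase encoding and decoding are mutually inverse and unit norm", {
  expect_equal(unname(encode_phase(0)), matrix(c(1, 0), 1), ignore_attr = TRUE)
  expect_equal(unname(encode_phase(25)), matrix(c(0, 1), 1), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(unname(encode_phase(50)), matrix(c(-1, 0), 1), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(decode_phase(c(1, 0)), 0)
  expect_equal(decode_phase(c(0, 1)), 25)

  p <- seq(0, 99.9, by = 0.1)
  enc <- encode_phase(p)
  expect_equal(sqrt(rowSums(enc^2)), rep(1, length(p)), tolerance = 1e-12)
  expect_lt(max(abs(decode_phase(enc) - p)), 1e-9)
  expect_error(decode_phase(c(0, 0)), "zero vector")
})

test_that("windowing is causal with the documented count and end labels", {
  x <- matrix(seq_len(300), 100, 3)
  w <- build_windows(x, seq_len = 25, hop = 1, labels = seq_len(100))
  expect_equal(dim(w$x), c(3, 76, 25))
  expect_equal(w$end_idx, 25:100)
  expect_equal(w$labels, 25:100)
  # window content: trailing samples ending at end_idx
  expect_equal(w$x[, 1, ], t(x[1:25, ]))
  expect_equal(w$x[, 76, ], t(x[76:100, ]))

  w0 <- build_windows(matrix(1, 24, 3), seq_len = 25)
  expect_equal(dim(w0$x)[2], 0L)
  expect_length(w0$end_idx, 0L)

  wh <- build_windows(x, seq_len = 10, hop = 7)
  expect_equal(wh$end_idx, seq(10, 100, by = 7))
  expect_equal(length(wh$end_idx), (100 - 10) %/% 7 + 1)
})

test_that("stride normalization resamples onto the fixed grid", {
  # 120-sample stride of a linear ramp: grid interpolation equals the oracle
  x <- matrix(c(seq(0, 1, length.out = 121), rep(1, 121)), ncol = 2)
  sn <- stride_normalize(x, events = c(1L, 121L), grid_len = 101L)
  expect_equal(dim(sn$all$curves), c(1, 101, 2))
  expect_equal(sn$all$curves[1, , 2], rep(1, 101))
  pos <- 1 + seq(0, 100, length.out = 101) / 100 * 120
  oracle <- approx(seq_len(121), x[, 1], xout = pos)$y
  expect_equal(sn$all$curves[1, , 1], oracle, tolerance = 1e-12)

  # per-condition grouping on a simulated recording
  rec <- noiseless_recording()
  sn2 <- stride_normalize(rec, rec$stride_starts)
  expect_setequal(names(sn2), c("LW", "RA", "RD"))
  expect_equal(ncol(sn2$LW$mean), 10L)
  expect_equal(nrow(sn2$LW$mean), 101L)
})

test_that("feature variants have the documented widths", {
  rec <- tiny_dataset()[[1]]
  stats <- fit_norm_stats(list(rec))
  normed <- apply_minmax(rec, stats)
  widths <- c(19L, 14L, 15L, 9L, 21L)
  for (v in 1:5) {
    fm <- build_feature_matrix(normed$forces, stats, v, wc = normed$wc)
    expect_equal(ncol(fm), widths[v])
    expect_equal(feature_width(v), widths[v])
  }
  expect_error(build_feature_matrix(normed$forces, stats, 1, wc = NULL),
               "needs walking-condition")
  expect_error(build_feature_matrix(normed$forces, stats, 1,
                                    wc = rep("XX", nrow(normed$forces))),
               "unknown walking-condition")
})
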