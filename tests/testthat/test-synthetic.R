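test_that("cohort generation is deterministic and validates arguments", {
  a <- make_cohort(10, base_seed = 7)
  b <- make_cohort(10, base_seed = 7)
  expect_length(a, 10)
  expect_identical(a, b)
  expect_length(make_cohort(1, base_seed = 0), 1)
  seeds <- vapply(a, `[[`, integer(1), "seed")
  expect_equal(anyDuplicated(seeds), 0L)
  expect_error(make_cohort(0), "positive count")
  expect_error(make_cohort(-3), "positive count")
})

test_that("subject profiles enforce their invariants", {
  p <- make_cohort(1, base_seed = 1)[[1]]
  expect_error(subject_profile("x", p$amp_scale, -1, p$stance_frac, p$center_shift),
               "cadence")
  bad_stance <- p$stance_frac; bad_stance[1] <- 0.9
  expect_error(subject_profile("x", p$amp_scale, 55, bad_stance, p$center_shift),
               "stance")
  bad_amp <- p$amp_scale; bad_amp[3] <- 0
  expect_error(subject_profile("x", bad_amp, 55, p$stance_frac, p$center_shift),
               "positive")
  bad_shift <- p$center_shift; bad_shift["R_heel"] <- 2
  expect_error(subject_profile("x", p$amp_scale, 55, p$stance_frac, bad_shift),
               "right-heel")
})

test_that("trial duration follows cadence and the 100 Hz grid", {
  p <- make_cohort(1, base_seed = 2, jitter_sd_ms = 0, noise_sd = 0)[[1]]
  p$cadence <- 60 # exactly 1 s per stride
  script <- scenario_script(list(list(wc = "LW", strides = 10)))
  rec <- simulate_trial(p, script)
  expect_equal(length(rec$times), 1000L)
  expect_equal(rec$fs, 100)
  expect_equal(diff(rec$times), rep(0.01, 999))
  expect_error(simulate_trial(p, scenario_script(list())), "at least one segment")
})

test_that("simulated forces are non-negative and phase is anchored at heel strikes", {
  rec <- noiseless_recording()
  expect_true(all(rec$forces >= 0))
  expect_true(all(rec$phase >= 0 & rec$phase < 100))
  expect_equal(max(abs(rec$phase[rec$stride_starts])), 0, tolerance = 1e-9)
  # phase advances monotonically within each stride
  for (k in seq_len(length(rec$stride_starts) - 1)) {
    idx <- rec$stride_starts[k]:(rec$stride_starts[k + 1] - 1L)
    expect_true(all(diff(rec$phase[idx]) > 0))
  }
})

test_that("condition markers match the script's transitions", {
  rec <- simulate_trial(make_cohort(1, base_seed = 4)[[1]], default_scenarios()$s2)
  # LW-SA-LW-SD-LW course: 4 transitions
  expect_length(rec$markers, 4L)
  expect_equal(rec$wc[rec$markers], c("SA", "LW", "SD", "LW"))
  # labels change exactly at the marker samples
  changes <- which(rec$wc[-1] != rec$wc[-length(rec$wc)]) + 1L
  expect_equal(changes, rec$markers)
})

test_that("the right heel rises exactly once per stride", {
  rec <- noiseless_recording()
  stats <- fit_norm_stats(list(rec))
  heel <- apply_minmax(rec, stats)$forces[, "R_heel"]
  above <- heel >= 0.05
  rising <- sum(above & !c(TRUE, above[-length(above)]))
  expect_equal(rising, length(rec$stride_starts))
})

test_that("per-condition mean stride curves are pairwise distinct", {
  grid <- seq(0, 99.5, by = 0.5)
  curves <- lapply(wc_levels(), function(w) template_matrix(grid, w))
  for (i in 1:4) for (j in (i + 1):5) {
    d <- sqrt(mean((curves[[i]] - curves[[j]])^2))
    expect_gt(d, 0.02)
  }
})

test_that("left and right feet are offset by half a cycle on level walk", {
  p <- make_cohort(1, base_seed = 9, jitter_sd_ms = 0, noise_sd = 0)[[1]]
  rec <- simulate_trial(p, scenario_script(list(list(wc = "LW", strides = 12))))
  stats <- fit_norm_stats(list(rec))
  nf <- apply_minmax(rec, stats)$forces
  ev_r <- detect_heel_strikes(nf[, "R_heel"])
  ev_l <- detect_heel_strikes(nf[, "L_heel"])
  gp <- label_gait_phase(length(rec$times), ev_r)
  offs <- gp$phase[ev_l]
  offs <- offs[!is.na(offs)]
  expect_true(all(abs(offs - 50) < 5))
})

test_that("the protocol yields one recording per subject-scenario-trial", {
  recs <- tiny_dataset()
  expect_length(recs, 2 * 3 * 3)
  meta <- t(vapply(recs, function(r) c(r$subject, r$scenario, r$trial), character(3)))
  expect_equal(anyDuplicated(meta), 0L)
  expect_setequal(unique(meta[, 3]), c("1", "2", "3"))
  expect_error(simulate_protocol(make_cohort(1), tiny_scenarios(), 0), ">= 1")
})

test_that("repeated trials are identical when noise and jitter vanish", {
  p <- make_cohort(1, base_seed = 6, jitter_sd_ms = 0, noise_sd = 0)[[1]]
  recs <- simulate_protocol(list(p), tiny_scenarios()["s2"], trials_per_script = 2)
  expect_equal(recs[[1]]$forces, recs[[2]]$forces)
  # and simulation is deterministic given the same inputs
  again <- simulate_trial(p, tiny_scenarios()$s2, trial = 1L)
  expect_identical(recs[[1]]$forces, again$forces)
})
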