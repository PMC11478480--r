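# Shared fixtures, built once per test run. Small cohorts and short
# scenarios keep the suite fast; network sizes are far below the production
# defaults because the synthetic task is easy.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

tiny_scenarios <- function() default_scenarios(level_strides = 2L, task_strides = 3L)

# 2 subjects x 3 scenarios x 3 trials, mild noise
tiny_dataset <- function() fixture("tiny_dataset", function() {
  cohort <- make_cohort(2, base_seed = 11)
  simulate_protocol(cohort, tiny_scenarios(), trials_per_script = 3)
})

tiny_split <- function() fixture("tiny_split", function() make_split(tiny_dataset()))

# noiseless, jitter-free single subject walking the ramp course
noiseless_recording <- function() fixture("noiseless_recording", function() {
  p <- make_cohort(1, base_seed = 3, jitter_sd_ms = 0, noise_sd = 0)[[1]]
  simulate_trial(p, default_scenarios()$s3)
})

tiny_wc_cfg <- function(...) {
  wc_config(hidden = c(16L, 8L), dense = 8L, seq_len = 50L, folds = 1L,
            hop = 10L, max_epochs = 6L, patience = 3L, seed = 5L, ...)
}

tiny_gpe_cfg <- function(...) {
  gpe_config(variant = 1L, hidden = c(16L, 8L), dense = 4L, seq_len = 25L,
             hop = 6L, max_epochs = 8L, patience = 3L, seed = 5L, ...)
}

# models fitted once and reused by model/pipeline tests
tiny_wc_model <- function() fixture("tiny_wc_model", function()
  fit_wc_classifier(tiny_split(), tiny_wc_cfg()))

tiny_gpe_model <- function() fixture("tiny_gpe_model", function()
  fit_phase_estimator(tiny_split(), tiny_gpe_cfg(), stats = tiny_wc_model()$stats))

circ_err <- function(true, est) ((est - true + 50) %% 100) - 50
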