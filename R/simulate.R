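#' Simulate one walking trial
#'
#' Generates a bilateral 10-channel FSR recording at 100 Hz for one subject
#' walking one scenario. Each stride of the script advances the global gait
#' phase 0 to 100 (anchored at right heel strike); walking-condition changes
#' happen at right-foot stride boundaries so the phase stays well defined.
#' Left-foot curves are the right-foot curves shifted by half a cycle.
#' Ground-truth phase, per-sample condition labels, stride starts and
#' condition-transition markers are stored alongside the force matrix.
#'
#' @param profile A [subject_profile()].
#' @param script A [scenario_script()].
#' @param layout A [sensor_layout()].
#' @param trial Trial index (1-based), stored as metadata.
#' @param fs Sampling rate in Hz; the recording grid is exactly `1/fs` s.
#' @return An object of class `fsr_recording`: list with elements `subject`,
#'   `scenario`, `trial`, `fs`, `times`, `forces` (n x 10 matrix), `wc`
#'   (character per sample), `phase` (ground truth, 0-100), `stride_starts`
#'   (sample indices of right heel strikes), `markers` (sample indices of
#'   condition transitions) and `normalized` (flag).
#' @examples
#' p <- make_cohort(1, base_seed = 1)[[1]]
#' rec <- simulate_trial(p, default_scenarios()$s2)
#' dim(rec$forces)
#' @export
simulate_trial <- function(profile, script, layout = sensor_layout(),
                           trial = 1L, fs = 100) {
  if (!inherits(profile, "subject_profile")) stop_arg("profile must be a subject_profile")
  if (!inherits(script, "scenario_script")) stop_arg("script must be a scenario_script")
  seg <- script$segments
  if (nrow(seg) < 1L) stop_arg("empty scenario script")

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  trial_seed <- (profile$seed + 13L * as.integer(trial) +
                   7L * sum(utf8ToInt(script$id)) +
                   (script$direction == "reverse")) %% 2147483647L
  set.seed(trial_seed)

  stride_wc <- rep(seg$wc, seg$strides)
  n_strides <- length(stride_wc)
  base_dur <- 60 / profile$cadence
  durs <- base_dur + rnorm(n_strides, 0, profile$jitter_sd_ms / 1000)
  # snap stride boundaries to the sampling grid so heel strikes fall exactly
  # on samples and ground-truth phase is 0 there by construction
  durs <- pmax(round(durs * fs), 0.4 * fs) / fs
  starts <- cumsum(c(0, durs))            # stride start times, length n_strides + 1
  total <- starts[n_strides + 1L]
  n <- round(total * fs)
  times <- (seq_len(n) - 1L) / fs

  stride_idx <- findInterval(times, starts, rightmost.closed = FALSE)
  stride_idx <- pmin(pmax(stride_idx, 1L), n_strides)
  phase <- 100 * (times - starts[stride_idx]) / durs[stride_idx]
  phase <- pmin(pmax(phase, 0), 100 - 1e-9)
  wc <- stride_wc[stride_idx]

  forces <- matrix(0, nrow = n, ncol = 10L, dimnames = list(NULL, layout$channel))
  for (w in unique(wc)) {
    sel <- wc == w
    stance_scale <- profile$stance_frac[[w]] / 0.62
    tm <- template_matrix(phase[sel], w, layout, stance_scale = stance_scale,
                          center_shift = profile$center_shift)
    forces[sel, ] <- tm
  }
  forces <- sweep(forces, 2L, profile$amp_scale[colnames(forces)], `*`)
  if (profile$noise_sd > 0)
    forces <- forces + matrix(rnorm(length(forces), 0, profile$noise_sd), nrow = n)
  forces <- pmax(forces, 0)

  stride_starts <- vapply(seq_len(n_strides), function(k)
    which(stride_idx == k)[1L], integer(1))
  transitions <- which(diff(match(stride_wc, WC_LEVELS)) != 0) + 1L
  markers <- stride_starts[transitions]

  structure(list(
    subject = profile$id, scenario = script$id, trial = as.integer(trial),
    fs = fs, times = times, forces = forces, wc = wc, phase = phase,
    stride_starts = stride_starts, markers = as.integer(markers),
    normalized = FALSE
  ), class = "fsr_recording")
}

#' @export
print.fsr_recording <- function(x, ...) {
  cat(sprintf("FSR recording: subject %s, scenario %s, trial %d\n",
              x$subject, x$scenario, x$trial))
  cat(sprintf("  %d samples @ %g Hz (%.1f s), conditions: %s\n",
              length(x$times), x$fs, length(x$times) / x$fs,
              paste(unique(x$wc), collapse = ", ")))
  cat(sprintf("  %d strides, %d condition transitions, %s\n",
              length(x$stride_starts), length(x$markers),
              if (isTRUE(x$normalized)) "normalized" else "raw"))
  invisible(x)
}

#' Simulate a full experimental protocol
#'
#' Runs every subject of a cohort through every scenario script
#' `trials_per_script` times, mirroring a repeated-trials walking protocol.
#'
#' @param cohort List of [subject_profile()]s.
#' @param scripts List of [scenario_script()]s (e.g. [default_scenarios()]).
#' @param trials_per_script Number of repetitions per (subject, scenario).
#' @param layout A [sensor_layout()].
#' @return List of [simulate_trial()] recordings, one per
#'   (subject, scenario, trial), named `subject.scenario.trial`.
#' @export
simulate_protocol <- function(cohort, scripts = default_scenarios(),
                              trials_per_script = 3L, layout = sensor_layout()) {
  if (trials_per_script < 1) stop_arg("trials_per_script must be >= 1")
  out <- list()
  for (p in cohort) {
    for (s in scripts) {
      for (tr in seq_len(trials_per_script)) {
        rec <- simulate_trial(p, s, layout, trial = tr)
        out[[paste(p$id, s$id, tr, sep = ".")]] <- rec
      }
    }
  }
  out
}
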