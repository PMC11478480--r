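#' Detect heel strikes on a heel-channel series
#'
#' A heel strike is an upward crossing of a rise threshold by the (normalized)
#' heel force, with a refractory interval suppressing re-triggers within the
#' same stance. To place the event at the onset of loading rather than a
#' threshold-dependent instant partway up the rise, each crossing is walked
#' back (at most `max_back` samples) to the last sample at or below the
#' signal floor; if the signal never dips to the floor inside that window,
#' the local minimum is used. Thresholds are configurable; the defaults
#' (0.05 normalized units, 300 ms) are robust for 100 Hz gait at comfortable
#' cadence.
#'
#' @param x Numeric heel-force series (normalized to \[0, 1\]).
#' @param threshold Rise threshold in normalized force units.
#' @param refractory_s Minimum separation between events, seconds.
#' @param fs Sampling rate, Hz.
#' @param onset_floor Signal floor for onset backtracking.
#' @param max_back Maximum backtrack, samples.
#' @return Integer vector of event sample indices (possibly empty).
#' @export
detect_heel_strikes <- function(x, threshold = 0.05, refractory_s = 0.3, fs = 100,
                                onset_floor = 0.02, max_back = 10L) {
  if (!length(x)) return(integer(0))
  above <- x >= threshold
  rising <- which(above & !c(TRUE, above[-length(above)]))
  if (!length(rising)) return(integer(0))
  refractory <- refractory_s * fs
  keep <- rising[1L]
  for (i in rising[-1L]) if (i - keep[length(keep)] >= refractory) keep <- c(keep, i)
  onset <- vapply(keep, function(c_idx) {
    lo <- max(1L, c_idx - max_back)
    win <- x[lo:(c_idx - 1L)]
    if (c_idx == 1L || !length(win)) return(c_idx)
    at_floor <- which(win <= onset_floor)
    if (length(at_floor)) lo + at_floor[length(at_floor)] - 1L
    else lo + which.min(win) - 1L
  }, integer(1))
  as.integer(onset)
}

#' Label gait phase from heel-strike events
#'
#' Between consecutive right heel strikes the phase ramps linearly from 0
#' (inclusive) to 100 (exclusive); samples before the first and at/after the
#' last event carry no defined phase and are flagged invalid.
#'
#' @param n Number of samples, or an `fsr_recording` (its length is used).
#' @param events Integer sample indices of heel strikes (>= 2 required).
#' @return An object of class `gait_phase_series`: list with numeric `phase`
#'   (NA where invalid) and logical `valid`.
#' @export
label_gait_phase <- function(n, events) {
  if (inherits(n, "fsr_recording")) n <- length(n$times)
  events <- sort(unique(as.integer(events)))
  if (length(events) < 2L)
    stop_arg("need at least 2 heel-strike events to label phase, got %d", length(events))
  phase <- rep(NA_real_, n)
  for (k in seq_len(length(events) - 1L)) {
    a <- events[k]; b <- events[k + 1L]
    idx <- a:(b - 1L)
    phase[idx] <- 100 * (idx - a) / (b - a)
  }
  valid <- !is.na(phase)
  structure(list(phase = phase, valid = valid, events = events),
            class = "gait_phase_series")
}

#' @export
print.gait_phase_series <- function(x, ...) {
  cat(sprintf("Gait phase series: %d samples, %d valid, %d anchor events\n",
              length(x$phase), sum(x$valid), length(x$events)))
  invisible(x)
}

#' Sine-cosine (continuous sinusoidal) phase encoding
#'
#' Maps a phase `p` in \[0, 100) to the pair (cos theta, sin theta) with
#' theta = p * 2 * pi / 100. The encoding removes the wrap-around
#' discontinuity at 0/100 and is the regression target of the phase
#' estimator.
#'
#' @param phase Numeric vector of phases (any finite value; taken mod 100).
#' @return Matrix with columns `cos` and `sin`, one row per phase.
#' @seealso [decode_phase()]
#' @export
encode_phase <- function(phase) {
  theta <- (phase %% 100) * (2 * pi / 100)
  cbind(cos = cos(theta), sin = sin(theta))
}

#' Decode a sine-cosine pair back to phase
#'
#' Uses the four-quadrant arctangent mapped to \[0, 2 pi), so
#' `decode_phase(encode_phase(p)) == p` for all p in \[0, 100). The decode is
#' invariant to radial scaling of its input, so model outputs need not be
#' unit norm.
#'
#' @param csf Matrix with columns (cos, sin), or a length-2 vector.
#' @return Numeric vector of phases in \[0, 100).
#' @export
decode_phase <- function(csf) {
  if (is.null(dim(csf))) csf <- matrix(csf, ncol = 2L)
  if (ncol(csf) != 2L) stop_arg("csf must have two columns (cos, sin)")
  if (any(csf[, 1L] == 0 & csf[, 2L] == 0))
    stop_arg("phase undefined for the zero vector")
  theta <- atan2(csf[, 2L], csf[, 1L]) %% (2 * pi)
  theta * (100 / (2 * pi))
}

#' Resample strides onto a common phase grid
#'
#' Cuts a multichannel series at heel-strike events and linearly interpolates
#' every stride onto a fixed 0-100% grid, grouping strides by walking
#' condition, so that per-condition mean and SD loading curves can be
#' computed and compared.
#'
#' @param x Numeric matrix (samples x channels) or an `fsr_recording`
#'   (its `forces` are used, and its per-sample `wc` labels if `wc` is NULL).
#' @param events Heel-strike sample indices (>= 2).
#' @param wc Optional per-sample condition labels; each stride takes the
#'   label at its first sample.
#' @param grid_len Number of grid points over 0-100% (default 101).
#' @return List keyed by condition; each entry has `curves` (array
#'   strides x grid x channels), `mean` and `sd` (grid x channels), and
#'   `grid` (phase coordinates).
#' @export
stride_normalize <- function(x, events, wc = NULL, grid_len = 101L) {
  if (inherits(x, "fsr_recording")) {
    if (is.null(wc)) wc <- x$wc
    x <- x$forces
  }
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
  events <- sort(unique(as.integer(events)))
  if (length(events) < 2L) stop_arg("need at least 2 events to cut strides")
  grid <- seq(0, 100, length.out = grid_len)
  n_ch <- ncol(x)
  per_wc <- list()
  for (k in seq_len(length(events) - 1L)) {
    a <- events[k]; b <- events[k + 1L]
    pos <- a + grid / 100 * (b - a)   # fractional sample positions
    cur <- vapply(seq_len(n_ch), function(j)
      approx(seq_len(nrow(x)), x[, j], xout = pos)$y, numeric(grid_len))
    w <- if (is.null(wc)) "all" else as.character(wc[a])
    per_wc[[w]] <- c(per_wc[[w]], list(cur))
  }
  lapply(per_wc, function(lst) {
    arr <- array(unlist(lst), dim = c(grid_len, n_ch, length(lst)),
                 dimnames = list(NULL, colnames(x), NULL))
    arr <- aperm(arr, c(3L, 1L, 2L))
    m <- apply(arr, c(2L, 3L), mean)
    s <- apply(arr, c(2L, 3L), sd)
    list(curves = arr, mean = m, sd = s, grid = grid)
  })
}
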