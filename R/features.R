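#' Fit min-max normalization statistics
#'
#' Computes per-channel minima and maxima over a set of training recordings,
#' plus the training-set maxima of the forefoot and backfoot regional sums
#' (per foot) used to normalize those sums. Statistics are fit on training
#' data only and frozen, so held-out data may fall outside \[0, 1\] and is
#' clipped on application.
#'
#' @param recordings A list of `fsr_recording`s, or a single recording.
#' @return An object of class `norm_stats`: list with `ch_min`, `ch_max`
#'   (named length-10 vectors), `fore_max` and `back_max` (named `c(L =, R =)`).
#' @export
fit_norm_stats <- function(recordings) {
  if (inherits(recordings, "fsr_recording")) recordings <- list(recordings)
  if (!length(recordings)) stop_arg("no training recordings supplied")
  all_forces <- do.call(rbind, lapply(recordings, `[[`, "forces"))
  ch_min <- apply(all_forces, 2L, min)
  ch_max <- apply(all_forces, 2L, max)
  flat <- which(ch_max - ch_min <= 0)
  if (length(flat))
    stop_arg("degenerate (constant) channel: %s", paste(names(ch_min)[flat], collapse = ", "))
  normed <- sweep(sweep(all_forces, 2L, ch_min), 2L, ch_max - ch_min, `/`)
  fore <- function(foot) rowSums(normed[, paste0(foot, c("_toe", "_meta1", "_meta5")), drop = FALSE])
  back <- function(foot) rowSums(normed[, paste0(foot, c("_cuboid", "_heel")), drop = FALSE])
  structure(list(
    ch_min = ch_min, ch_max = ch_max,
    fore_max = c(L = max(fore("L")), R = max(fore("R"))),
    back_max = c(L = max(back("L")), R = max(back("R")))
  ), class = "norm_stats")
}

#' @export
print.norm_stats <- function(x, ...) {
  cat("Min-max normalization statistics (10 channels)\n")
  cat(sprintf("  fore max L/R: %.3f/%.3f, back max L/R: %.3f/%.3f\n",
              x$fore_max[["L"]], x$fore_max[["R"]], x$back_max[["L"]], x$back_max[["R"]]))
  invisible(x)
}

#' Apply min-max normalization
#'
#' Maps each channel through `(x - min) / (max - min)` using frozen training
#' statistics and clips to \[0, 1\]. No smoothing or filtering is applied.
#'
#' @param recording An `fsr_recording` (raw), or a samples x 10 force matrix.
#' @param stats A [fit_norm_stats()] object.
#' @return The recording (or matrix) with normalized forces; recordings get
#'   `normalized = TRUE`.
#' @export
apply_minmax <- function(recording, stats) {
  mat <- if (inherits(recording, "fsr_recording")) recording$forces else recording
  rng <- stats$ch_max - stats$ch_min
  normed <- sweep(sweep(mat, 2L, stats$ch_min[colnames(mat)]), 2L,
                  rng[colnames(mat)], `/`)
  normed <- pmin(pmax(normed, 0), 1)
  if (inherits(recording, "fsr_recording")) {
    recording$forces <- normed
    recording$normalized <- TRUE
    recording
  } else normed
}

#' Regional force sums
#'
#' Per foot, the forefoot sum is toe + first metatarsal + fifth metatarsal
#' and the backfoot sum is cuboid + heel, each divided by its training-set
#' maximum from [fit_norm_stats()].
#'
#' @param x Normalized force matrix (samples x 10) or a normalized recording.
#' @param stats A [fit_norm_stats()] object.
#' @return Matrix (samples x 4) with columns `fore_L`, `back_L`, `fore_R`,
#'   `back_R`.
#' @export
region_sums <- function(x, stats) {
  if (inherits(x, "fsr_recording")) x <- x$forces
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L, dimnames = list(NULL, names(x)))
  out <- cbind(
    fore_L = rowSums(x[, c("L_toe", "L_meta1", "L_meta5"), drop = FALSE]) / stats$fore_max[["L"]],
    back_L = rowSums(x[, c("L_cuboid", "L_heel"), drop = FALSE]) / stats$back_max[["L"]],
    fore_R = rowSums(x[, c("R_toe", "R_meta1", "R_meta5"), drop = FALSE]) / stats$fore_max[["R"]],
    back_R = rowSums(x[, c("R_cuboid", "R_heel"), drop = FALSE]) / stats$back_max[["R"]]
  )
  out
}

#' Centre of pressure along the foot
#'
#' Force-weighted mean of the anterior-posterior site coordinates, per foot
#' (heel = 0, toe = 1). During swing the total force vanishes; below `eps`
#' the previous valid value is held (0 at the start of the series).
#'
#' @param x Normalized force matrix (samples x 10) or recording.
#' @param layout A [sensor_layout()].
#' @param eps Total-force threshold below which the COP is held.
#' @return Matrix (samples x 2) with columns `cop_L`, `cop_R`.
#' @export
compute_cop <- function(x, layout = sensor_layout(), eps = 1e-6) {
  if (inherits(x, "fsr_recording")) x <- x$forces
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L, dimnames = list(NULL, names(x)))
  out <- matrix(0, nrow = nrow(x), ncol = 2L, dimnames = list(NULL, c("cop_L", "cop_R")))
  for (f in c("L", "R")) {
    cols <- layout$channel[layout$foot == f]
    coords <- layout$ap_coord[layout$foot == f]
    sub <- x[, cols, drop = FALSE]
    tot <- rowSums(sub)
    cop <- as.numeric(sub %*% coords)
    valid <- tot >= eps
    cop[valid] <- cop[valid] / tot[valid]
    cop[!valid] <- NA_real_
    # hold previous valid value; 0 before the first valid sample
    idx <- cummax(ifelse(valid, seq_along(cop), 0L))
    held <- ifelse(idx == 0L, 0, cop[pmax(idx, 1L)])
    out[, paste0("cop_", f)] <- held
  }
  out
}

#' Feature width of an input variant
#'
#' The five input-feature variants of the phase estimator: #1 = 10 FSR
#' channels + 4 regional sums + 5-dim one-hot walking condition (19); #2
#' drops the condition (14); #3 drops the sums (15); #4 keeps only sums +
#' condition (9); #5 = #1 + the two per-foot COP values (21).
#'
#' @param variant Integer 1-5.
#' @return Integer feature width.
#' @export
feature_width <- function(variant) {
  w <- c(19L, 14L, 15L, 9L, 21L)
  if (!variant %in% 1:5) stop_arg("variant must be 1..5")
  w[variant]
}

#' Assemble the per-sample feature matrix for a variant
#'
#' @param recording A normalized `fsr_recording` (or samples x 10 matrix).
#' @param stats A [fit_norm_stats()] object.
#' @param variant Input variant 1-5 (see [feature_width()]).
#' @param wc One of: a character vector of per-sample condition labels, a
#'   samples x 5 probability/one-hot matrix, or NULL (only valid for
#'   variant 2). Character labels are one-hot encoded.
#' @param layout A [sensor_layout()] (used for COP in variant 5).
#' @return Matrix samples x [feature_width()]`(variant)`.
#' @export
build_feature_matrix <- function(recording, stats, variant = 1L, wc = NULL,
                                 layout = sensor_layout()) {
  x <- if (inherits(recording, "fsr_recording")) recording$forces else recording
  needs_wc <- variant %in% c(1L, 3L, 4L, 5L)
  if (needs_wc && is.null(wc)) {
    if (inherits(recording, "fsr_recording") && !is.null(recording$wc)) wc <- recording$wc
    else stop_arg("variant %d needs walking-condition input", variant)
  }
  wc_mat <- NULL
  if (needs_wc) {
    if (is.matrix(wc)) {
      if (ncol(wc) != 5L) stop_arg("wc matrix must have 5 columns")
      wc_mat <- wc
    } else {
      idx <- match(as.character(wc), WC_LEVELS)
      if (anyNA(idx)) stop_arg("unknown walking-condition label")
      wc_mat <- matrix(0, nrow = length(idx), ncol = 5L,
                       dimnames = list(NULL, WC_LEVELS))
      wc_mat[cbind(seq_along(idx), idx)] <- 1
    }
  }
  sums <- if (variant %in% c(1L, 2L, 4L, 5L)) region_sums(x, stats) else NULL
  cop <- if (variant == 5L) compute_cop(x, layout) else NULL
  out <- switch(as.character(variant),
    "1" = cbind(x, sums, wc_mat),
    "2" = cbind(x, sums),
    "3" = cbind(x, wc_mat),
    "4" = cbind(sums, wc_mat),
    "5" = cbind(x, sums, wc_mat, cop),
    stop_arg("variant must be 1..5"))
  stopifnot(ncol(out) == feature_width(variant))
  out
}

#' Cut a feature matrix into causal sliding windows
#'
#' Window `k` (1-based) covers samples `(k-1)*hop + 1` through
#' `(k-1)*hop + seq_len`; each window is paired with the label at its final
#' sample, so predictions are causal. `floor((N - seq_len)/hop) + 1` windows
#' are produced; a series shorter than `seq_len` yields none.
#'
#' @param x Feature matrix (samples x width).
#' @param seq_len Window length in samples.
#' @param hop Stride between successive window ends, in samples.
#' @param labels Optional per-sample labels to attach (vector or matrix).
#' @return List with `x` (array width x n_windows x seq_len, the layout the
#'   network code consumes), `end_idx` (final sample of each window) and
#'   `labels` (labels at `end_idx`, if supplied).
#' @export
build_windows <- function(x, seq_len, hop = 1L, labels = NULL) {
  if (seq_len < 1L || hop < 1L) stop_arg("seq_len and hop must be >= 1")
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
  n <- nrow(x); d <- ncol(x)
  if (n < seq_len)
    return(list(x = array(0, dim = c(d, 0L, seq_len)), end_idx = integer(0), labels = NULL))
  n_win <- (n - seq_len) %/% hop + 1L
  ends <- seq_len + hop * (seq_len(n_win) - 1L)
  arr <- array(0, dim = c(d, n_win, seq_len))
  for (tt in seq_len(seq_len))
    arr[, , tt] <- t(x[ends - seq_len + tt, , drop = FALSE])
  lab <- NULL
  if (!is.null(labels)) {
    lab <- if (is.matrix(labels)) labels[ends, , drop = FALSE] else labels[ends]
  }
  list(x = arr, end_idx = as.integer(ends), labels = lab)
}
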