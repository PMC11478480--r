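#' Write an FSR recording to a plain-text file
#'
#' The on-disk dialect is a comma-separated table preceded by `#`-prefixed
#' metadata lines (subject, scenario, trial, sampling rate, channel order,
#' normalization flag, marker and stride-start indices). Data rows hold the
#' sample time, the ten force channels in canonical order, the per-sample
#' walking-condition code (or `NA`) and the ground-truth phase (or `NA`).
#'
#' @param recording An `fsr_recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_recording()]
#' @export
write_recording <- function(recording, path) {
  r <- recording
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c(
    "# gaitphase-recording v1",
    sprintf("# subject: %s", r$subject),
    sprintf("# scenario: %s", r$scenario),
    sprintf("# trial: %d", r$trial),
    sprintf("# fs: %g", r$fs),
    sprintf("# normalized: %s", isTRUE(r$normalized)),
    sprintf("# channels: %s", paste(colnames(r$forces), collapse = ",")),
    sprintf("# markers: %s", paste(r$markers, collapse = ",")),
    sprintf("# stride_starts: %s", paste(r$stride_starts, collapse = ","))
  )
  writeLines(meta, con)
  df <- data.frame(time = r$times, r$forces,
                   wc = if (is.null(r$wc)) NA else r$wc,
                   phase = if (is.null(r$phase)) NA else r$phase,
                   check.names = FALSE)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

fmt_error <- function(line, ...) {
  stop(sprintf("recording format error at line %d: %s", line, sprintf(...)),
       call. = FALSE)
}

parse_meta <- function(lines, key, default = NULL) {
  pat <- sprintf("^# %s: ?", key)
  hit <- grep(pat, lines)
  if (!length(hit)) return(default)
  sub(pat, "", lines[hit[1L]])
}

#' Read an FSR recording
#'
#' Parses the dialect written by [write_recording()], validating the header,
#' the column count (exactly 10 force channels), row raggedness and the
#' monotone 100 Hz time grid; violations raise a format error naming the
#' offending line.
#'
#' @param path File path.
#' @return An `fsr_recording`.
#' @export
read_recording <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) fmt_error(1L, "empty file")
  is_meta <- startsWith(lines, "#")
  n_meta <- match(FALSE, is_meta, nomatch = length(lines) + 1L) - 1L
  meta <- lines[seq_len(n_meta)]
  if (!length(meta) || !grepl("^# gaitphase-recording", meta[1L]))
    fmt_error(1L, "missing 'gaitphase-recording' signature")
  body <- lines[(n_meta + 1L):length(lines)]
  if (length(body) < 2L) fmt_error(n_meta + 1L, "no data rows")

  header <- strsplit(body[1L], ",", fixed = TRUE)[[1L]]
  n_col <- length(header)
  force_cols <- setdiff(header, c("time", "wc", "phase"))
  if (length(force_cols) != 10L)
    fmt_error(n_meta + 1L, "expected 10 force columns, found %d", length(force_cols))

  fields <- strsplit(body[-1L], ",", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != n_col)
  if (length(bad))
    fmt_error(n_meta + 1L + bad[1L], "row has %d fields, expected %d", nf[bad[1L]], n_col)

  mat <- matrix(unlist(fields), ncol = n_col, byrow = TRUE)
  colnames(mat) <- header
  times <- as.numeric(mat[, "time"])
  fs <- as.numeric(parse_meta(meta, "fs", "100"))
  dt <- diff(times)
  if (any(is.na(times)) || any(dt <= 0) || any(abs(dt - 1 / fs) > 1e-6)) {
    bad_t <- which(is.na(times) | c(FALSE, dt <= 0 | abs(dt - 1 / fs) > 1e-6))[1L]
    fmt_error(n_meta + 1L + bad_t, "non-monotone or off-grid sample times")
  }
  forces <- apply(mat[, force_cols, drop = FALSE], 2L, as.numeric)
  wc <- mat[, "wc"]
  wc[wc == "NA"] <- NA_character_
  phase <- suppressWarnings(as.numeric(mat[, "phase"]))

  int_vec <- function(key) {
    s <- parse_meta(meta, key, "")
    if (!nzchar(s)) integer(0) else as.integer(strsplit(s, ",", fixed = TRUE)[[1L]])
  }
  trial <- as.integer(parse_meta(meta, "trial", "1"))
  if (is.na(trial) || trial < 1L) fmt_error(1L, "invalid trial index")
  structure(list(
    subject = parse_meta(meta, "subject", "unknown"),
    scenario = parse_meta(meta, "scenario", "unknown"),
    trial = trial, fs = fs, times = times, forces = forces,
    wc = as.character(wc), phase = phase,
    stride_starts = int_vec("stride_starts"), markers = int_vec("markers"),
    normalized = identical(parse_meta(meta, "normalized", "FALSE"), "TRUE")
  ), class = "fsr_recording")
}

#' Train/validation/test split of a recording set
#'
#' Implements the repeated-trials protocol split: every recording whose trial
#' index equals `test_trial_index` goes to the test set whole; each remaining
#' recording is cut into a leading training block and a trailing validation
#' block of `val_fraction` of its samples. Contiguous blocks (rather than
#' shuffled windows) keep overlapping windows from leaking between training
#' and validation.
#'
#' @param dataset List of `fsr_recording`s (e.g. from [simulate_protocol()]).
#' @param test_trial_index Trial index reserved for testing.
#' @param val_fraction Fraction of each remaining recording's samples held
#'   out for validation (0 disables validation).
#' @return An object of class `data_split`: list with elements `train`,
#'   `validation` (each a list of `list(recording =, range = c(first, last))`)
#'   and `test` (list of whole recordings).
#' @export
make_split <- function(dataset, test_trial_index = 3L, val_fraction = 0.2) {
  if (val_fraction < 0 || val_fraction >= 1) stop_arg("val_fraction must be in [0, 1)")
  key <- vapply(dataset, function(r) paste(r$subject, r$scenario), character(1))
  trial <- vapply(dataset, function(r) r$trial, integer(1))
  for (k in unique(key)) {
    if (!any(trial[key == k] == test_trial_index))
      stop_arg("no trial %d for %s", test_trial_index, k)
  }
  train <- list(); validation <- list(); test <- list()
  for (r in dataset) {
    if (r$trial == test_trial_index) {
      test[[length(test) + 1L]] <- r
      next
    }
    n <- length(r$times)
    n_val <- as.integer(floor(n * val_fraction))
    n_train <- n - n_val
    train[[length(train) + 1L]] <- list(recording = r, range = c(1L, n_train))
    if (n_val > 0L)
      validation[[length(validation) + 1L]] <- list(recording = r, range = c(n_train + 1L, n))
  }
  structure(list(train = train, validation = validation, test = test,
                 test_trial_index = as.integer(test_trial_index),
                 val_fraction = val_fraction),
            class = "data_split")
}

#' @export
print.data_split <- function(x, ...) {
  nsamp <- function(blocks) sum(vapply(blocks, function(b) diff(b$range) + 1L, integer(1)))
  cat(sprintf("Data split: %d train blocks (%d samples), %d validation blocks (%d samples), %d test recordings\n",
              length(x$train), nsamp(x$train), length(x$validation), nsamp(x$validation),
              length(x$test)))
  invisible(x)
}
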