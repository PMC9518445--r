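## Preprocessing: resample to 100 Hz, standardize, cut into 1-s epochs -------

#' Resample a signal to 100 Hz by filtered decimation
#'
#' For an integer reduction factor `s = fs/100` the signal is filtered with a
#' zero-phase (forward-backward) Chebyshev type I lowpass of order 8, 0.05 dB
#' passband ripple and normalized cut-off `0.8/s` (i.e. 40 Hz), then every
#' `s`-th sample is kept. For non-integer ratios the same anti-alias filter
#' is applied at the original rate (equivalent 40 Hz cut-off) and the
#' band-limited result is interpolated onto the 100 Hz sample grid.
#' Zero-phase filtering is used so that events are not delayed relative to
#' the second-aligned labels.
#'
#' @param x Numeric signal vector.
#' @param fs Original sampling rate in Hz; must be `>= 100` (upsampling is
#'   out of scope).
#' @return Numeric vector of length `floor(length(x) * 100 / fs)`.
#' @export
#' @examples
#' y <- resample_to_100hz(sin(2 * pi * 5 * seq(0, 1, by = 1/200)), 200)
resample_to_100hz <- function(x, fs) {
  if (fs < 100) stopf("fs must be >= 100 Hz (upsampling out of scope), got %s", fs)
  if (fs == 100) return(x)
  n_out <- floor(length(x) * 100 / fs)
  s <- fs / 100
  if (abs(s - round(s)) < 1e-9) {
    s <- as.integer(round(s))
    flt <- signal::cheby1(8, 0.05, 0.8 / s)
    y <- signal::filtfilt(flt, x)
    head(y[seq(1, length(y), by = s)], n_out)
  } else {
    # anti-alias at the original rate: cut-off 40 Hz = 0.8 * (100 / fs) * Nyquist
    flt <- signal::cheby1(8, 0.05, 0.8 * 100 / fs)
    y <- signal::filtfilt(flt, x)
    t_in <- (seq_along(y) - 1) / fs
    t_out <- (seq_len(n_out) - 1) / 100
    stats::spline(t_in, y, xout = t_out, method = "fmm")$y
  }
}

#' Standardize a signal to zero mean and unit variance
#'
#' @param x Numeric vector with non-zero variance.
#' @return `(x - mean(x)) / sd(x)`.
#' @export
standardize <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0)
    stopf("cannot standardize a constant (zero-variance) signal")
  (x - mean(x)) / s
}

#' Preprocess a recording for the classifier
#'
#' Resamples every channel to 100 Hz and standardizes each channel over the
#' whole recording (per-recording, per-channel scope).
#'
#' @param rec A `cap_recording`.
#' @param scale Standardize each channel after resampling (default `TRUE`).
#' @return The recording with `fs = 100` and standardized signals.
#' @export
preprocess_recording <- function(rec, scale = TRUE) {
  sig <- apply(rec$signals, 2, resample_to_100hz, fs = rec$fs)
  if (scale) sig <- apply(sig, 2, standardize)
  colnames(sig) <- rec$channel_names
  rec$signals <- sig
  rec$fs <- 100
  rec
}

#' Cut a 100 Hz recording into per-second epoch windows
#'
#' Each window stacks `T` consecutive 1-s epochs (100 samples each) per
#' channel; its label is the database label of the *last* epoch. The first
#' `T - 1` epochs of a recording yield no window (no zero padding), so an
#' `N`-second recording yields `N - T + 1` windows.
#'
#' @param rec A preprocessed `cap_recording` at 100 Hz.
#' @param time_steps Number of epochs `T >= 1` per window.
#' @return A `cap_windows` object: list with `x` (list of 3 arrays of
#'   dimension `n_windows x T x 100`, one per channel), `y` (labels),
#'   `subject` (subject id per window), `epoch` (0-based index of the
#'   labelled epoch), `time_steps`, `input_points`.
#' @export
#' @examples
#' rec <- generate_recording(cap_sim_params(duration_s = 30, seed = 1), 1)
#' w <- make_windows(preprocess_recording(rec), time_steps = 10)
#' dim(w$x[[1]])  # 21 x 10 x 100
make_windows <- function(rec, time_steps) {
  stopifnot(time_steps >= 1)
  if (rec$fs != 100) stopf("make_windows expects a 100 Hz recording; call preprocess_recording() first")
  I <- 100L
  n_sec <- min(floor(nrow(rec$signals) / I), length(rec$labels))
  n_win <- n_sec - time_steps + 1L
  if (n_win < 1)
    return(empty_windows(time_steps, I))
  idx <- seq_len(n_win) + time_steps - 1L        # 1-based index of last epoch
  x <- lapply(seq_along(rec$channel_names), function(ch) {
    sig <- rec$signals[seq_len(n_sec * I), ch]
    ep <- matrix(sig, nrow = I)                  # I x n_sec, column = epoch
    arr <- array(0, dim = c(n_win, time_steps, I))
    for (t in seq_len(time_steps))
      arr[, t, ] <- t(ep[, idx - time_steps + t, drop = FALSE])
    arr
  })
  names(x) <- rec$channel_names
  structure(list(x = x, y = rec$labels[idx],
                 subject = rep(rec$subject_id, n_win),
                 epoch = idx - 1L,
                 time_steps = as.integer(time_steps), input_points = I),
            class = "cap_windows")
}

empty_windows <- function(time_steps, I = 100L) {
  x <- lapply(CAP_CHANNELS, function(ch) array(0, dim = c(0, time_steps, I)))
  names(x) <- CAP_CHANNELS
  structure(list(x = x, y = integer(0), subject = character(0),
                 epoch = integer(0), time_steps = as.integer(time_steps),
                 input_points = I),
            class = "cap_windows")
}

#' @export
print.cap_windows <- function(x, ...) {
  cat(sprintf("cap_windows: %d windows of %d step(s) x %d points, %d subject(s), %.1f%% positive\n",
              length(x$y), x$time_steps, x$input_points,
              length(unique(x$subject)),
              if (length(x$y)) 100 * mean(x$y) else NA_real_))
  invisible(x)
}

#' Combine window sets from several recordings
#'
#' @param ... `cap_windows` objects (or a single list of them).
#' @return A single `cap_windows` object.
#' @export
bind_windows <- function(...) {
  ws <- list(...)
  if (length(ws) == 1 && !inherits(ws[[1]], "cap_windows")) ws <- ws[[1]]
  ws <- Filter(function(w) length(w$y) > 0, ws)
  if (!length(ws)) stopf("no non-empty window sets to bind")
  T <- unique(vapply(ws, function(w) w$time_steps, 1L))
  if (length(T) != 1) stopf("window sets have differing time_steps")
  x <- lapply(seq_along(ws[[1]]$x), function(ch) {
    arrs <- lapply(ws, function(w) w$x[[ch]])
    out <- array(0, dim = c(sum(vapply(arrs, function(a) dim(a)[1], 1L)),
                            T, ws[[1]]$input_points))
    at <- 0L
    for (a in arrs) {
      if (dim(a)[1] > 0) out[at + seq_len(dim(a)[1]), , ] <- a
      at <- at + dim(a)[1]
    }
    out
  })
  names(x) <- names(ws[[1]]$x)
  structure(list(x = x,
                 y = unlist(lapply(ws, function(w) w$y), use.names = FALSE),
                 subject = unlist(lapply(ws, function(w) w$subject), use.names = FALSE),
                 epoch = unlist(lapply(ws, function(w) w$epoch), use.names = FALSE),
                 time_steps = T, input_points = ws[[1]]$input_points),
            class = "cap_windows")
}

## subset windows by a logical/integer index
slice_windows <- function(w, i) {
  structure(list(x = lapply(w$x, function(a) a[i, , , drop = FALSE]),
                 y = w$y[i], subject = w$subject[i], epoch = w$epoch[i],
                 time_steps = w$time_steps, input_points = w$input_points),
            class = "cap_windows")
}

#' Resample, standardize and window a cohort
#'
#' Convenience wrapper running [preprocess_recording()] and [make_windows()]
#' over a list of recordings.
#'
#' @param cohort List of `cap_recording` objects.
#' @param time_steps Epochs per window.
#' @return List of `cap_windows`, one per recording.
#' @export
prepare_cohort <- function(cohort, time_steps) {
  lapply(cohort, function(r) make_windows(preprocess_recording(r), time_steps))
}

#' Parse a CAP scoring annotation file into per-second labels
#'
#' Reads a plain-text scoring file with tab- or comma-separated columns, as
#' distributed with public CAP scorings: a header row naming at least an
#' event/description column, a time or position column (`hh:mm:ss` clock time
#' or plain seconds) and a duration column in seconds. Every row whose event
#' field matches an A-phase pattern (e.g. `MCAP-A1`, `A2`, `A3`) marks its
#' onset..onset+duration span; a second is labelled 1 when covered by at
#' least half.
#'
#' @param path Annotation file path.
#' @param total_seconds Length of the label vector to produce.
#' @param start_time Clock time (`"hh:mm:ss"`) of recording start, needed when
#'   the time column holds clock times; crossing midnight is handled.
#' @param a_phase_pattern Regular expression identifying A-phase rows.
#' @return Integer vector of 0/1 labels, one per second.
#' @export
read_cap_annotations <- function(path, total_seconds,
                                 start_time = NULL,
                                 a_phase_pattern = "(MCAP-)?A[123]\\b|A-phase") {
  lines <- readLines(path, warn = FALSE)
  sep <- if (any(grepl("\t", lines))) "\t" else ","
  hdr_i <- grep("event", lines, ignore.case = TRUE)[1]
  if (is.na(hdr_i)) stopf("no header row naming an Event column in %s", path)
  tab <- utils::read.table(text = lines[hdr_i:length(lines)], sep = sep,
                           header = TRUE, fill = TRUE, check.names = TRUE,
                           stringsAsFactors = FALSE, comment.char = "")
  nm <- tolower(names(tab))
  ev_col <- which(grepl("event|description", nm))[1]
  t_col <- which(grepl("time", nm))[1]            # prefer a time column
  if (is.na(t_col)) t_col <- which(grepl("position", nm))[1]
  d_col <- which(grepl("duration", nm))[1]
  if (any(is.na(c(ev_col, t_col, d_col))))
    stopf("annotation file must provide event, time/position and duration columns")
  rows <- grepl(a_phase_pattern, tab[[ev_col]], perl = TRUE)
  to_sec <- function(v) {
    if (all(grepl("^\\s*[0-9.]+\\s*$", v))) return(as.numeric(v))
    if (is.null(start_time))
      stopf("clock times found; supply start_time = \"hh:mm:ss\"")
    hms <- function(s) {
      p <- as.numeric(strsplit(s, "[:.]")[[1]][1:3])
      p[1] * 3600 + p[2] * 60 + p[3]
    }
    t0 <- hms(start_time)
    t <- vapply(as.character(v), hms, 0)
    ifelse(t >= t0, t - t0, t - t0 + 86400)   # midnight wrap
  }
  onset <- to_sec(tab[[t_col]][rows])
  dur <- as.numeric(tab[[d_col]][rows])
  events <- cbind(onset = onset, duration = dur)
  events <- events[is.finite(onset) & is.finite(dur) & dur > 0, , drop = FALSE]
  events_to_labels(events, total_seconds)
}
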