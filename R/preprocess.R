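#' Design the default low-pass filter
#'
#' 4th-order Butterworth low-pass; applied forward and backward
#' (zero-phase), so the effective amplitude response is the squared
#' magnitude of the single-pass design.
#'
#' @param cutoff_hz Cutoff frequency in Hz.
#' @param sampling_rate Sampling rate in Hz.
#' @param order Filter order of the single pass.
#' @return A list with `b`, `a` polynomial coefficients and the design
#'   parameters.
#' @export
design_lowpass <- function(cutoff_hz = 0.2, sampling_rate = 10, order = 4) {
  stop_if_not_positive(cutoff_hz, "cutoff_hz")
  if (cutoff_hz >= sampling_rate / 2) {
    stop("`cutoff_hz` must be below the Nyquist frequency")
  }
  bt <- signal::butter(order, cutoff_hz / (sampling_rate / 2), type = "low")
  list(b = bt$b, a = bt$a, order = order, cutoff_hz = cutoff_hz,
       sampling_rate = sampling_rate)
}

#' Single-pass magnitude response of a designed filter
#'
#' Evaluates |H(e^{i w})| of the rational transfer function at the given
#' frequencies; the zero-phase (two-pass) response is this squared.
#'
#' @param filt A [design_lowpass()] filter.
#' @param freq_hz Frequencies at which to evaluate, in Hz.
#' @return Magnitude per frequency.
#' @export
filter_magnitude <- function(filt, freq_hz) {
  w <- 2 * pi * freq_hz / filt$sampling_rate
  H <- vapply(w, function(wi) {
    z <- exp(-1i * wi * (seq_along(filt$b) - 1))
    num <- sum(filt$b * z)
    den <- sum(filt$a * exp(-1i * wi * (seq_along(filt$a) - 1)))
    abs(num / den)
  }, numeric(1))
  H
}

#' Zero-phase filtering of one series
#'
#' Forward and backward pass over an odd-reflection pad sized to a few
#' filter time constants; the pad-edge value is subtracted before each pass
#' (and its DC response restored) so start-up transients vanish and a
#' constant series passes through exactly.
#' @noRd
filtfilt_reflect <- function(filt, x) {
  n <- length(x)
  np <- min(max(3 * (filt$order + 1),
                ceiling(3 * filt$sampling_rate / filt$cutoff_hz)),
            n - 1)
  pre <- 2 * x[1] - x[seq(np + 1, 2)]
  post <- 2 * x[n] - x[seq(n - 1, n - np)]
  xp <- c(pre, x, post)
  dc <- sum(filt$b) / sum(filt$a)
  one_pass <- function(z) {
    z0 <- z[1]
    signal::filter(filt$b, filt$a, z - z0) + z0 * dc
  }
  y <- rev(one_pass(rev(one_pass(xp))))
  y[seq(np + 1, np + n)]
}

#' Low-pass filter a haemoglobin recording
#'
#' Applies the zero-phase Butterworth low-pass independently to every
#' channel and chromophore. The default 0.2 Hz cutoff keeps the slow
#' haemodynamic response while rejecting respiration, cardiac pulsation and
#' instrument noise. Output length equals input length; a provenance flag is
#' set on the result.
#'
#' @param hemo A `hemo_recording`.
#' @param cutoff_hz Cutoff frequency in Hz (must be below Nyquist).
#' @param order Butterworth order of the single pass.
#' @return The filtered `hemo_recording` with `filtered = TRUE`.
#' @export
lowpass_filter <- function(hemo, cutoff_hz = 0.2, order = 4) {
  stopifnot(inherits(hemo, "hemo_recording"))
  filt <- design_lowpass(cutoff_hz, hemo$sampling_rate, order)
  d <- dim(hemo$data)
  for (ch in seq_len(d[1])) {
    for (cr in seq_len(d[2])) {
      hemo$data[ch, cr, ] <- filtfilt_reflect(filt, hemo$data[ch, cr, ])
    }
  }
  hemo$filtered <- TRUE
  hemo$filter <- list(cutoff_hz = cutoff_hz, order = order,
                      family = "butterworth", zero_phase = TRUE)
  hemo
}

#' Cut labelled sliding-window examples from a recording
#'
#' Slides a window of `window_s` seconds with step `step_s` inside every
#' labelled segment of the schedule; windows never straddle a segment
#' boundary, inherit the segment's label, and record their subject and
#' series index for leakage-safe splitting. In `"3class"` mode only the
#' workload segments are used; `"4class"` adds the rest segments. The 2 s
#' instruction segments are never epoched. Windows can optionally be
#' decimated by an integer factor (safe after the 0.2 Hz low-pass, whose
#' passband is far below the decimated Nyquist).
#'
#' @param hemo A `hemo_recording`.
#' @param schedule The recording's [build_schedule()]; defaults to the one
#'   attached to the recording.
#' @param window_s Window length, seconds.
#' @param step_s Step between window onsets, seconds.
#' @param class_mode `"3class"` (workload levels only) or `"4class"`
#'   (workload + rest).
#' @param decimate Integer subsampling factor applied within each window.
#' @return An `epoch_set`: `x` is an examples x channels x chromophores x
#'   samples array; `labels` a factor; `series` and `subject_id` give the
#'   grouping of each example.
#' @export
segment_epochs <- function(hemo, schedule = hemo$schedule,
                           window_s = 10, step_s = 5,
                           class_mode = c("3class", "4class"),
                           decimate = 1L) {
  stopifnot(inherits(hemo, "hemo_recording"),
            inherits(schedule, "block_schedule"))
  class_mode <- match.arg(class_mode)
  stop_if_not_positive(window_s, "window_s")
  stop_if_not_positive(step_s, "step_s")
  decimate <- stop_if_not_count(decimate, "decimate")
  fs <- schedule$sampling_rate
  wlen <- round(window_s * fs)
  step <- round(step_s * fs)
  if (step < 1) stop("`step_s` is below one sample")

  keep <- schedule$series_labels
  if (class_mode == "4class") keep <- c(keep, "rest")

  track <- schedule$label_track
  series_track <- schedule$series_track
  # contiguous labelled segments
  runs <- rle(paste(track, series_track, sep = "\r"))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  seg_lab <- sub("\r.*$", "", runs$values)
  seg_ser <- as.integer(sub("^.*\r", "", runs$values))

  onsets <- list(); labs <- character(0); sers <- integer(0)
  for (s in seq_along(starts)) {
    if (!(seg_lab[s] %in% keep)) next
    seg_len <- runs$lengths[s]
    if (seg_len < wlen) next
    k <- floor((seg_len - wlen) / step) + 1
    on <- starts[s] + (seq_len(k) - 1) * step
    onsets[[length(onsets) + 1]] <- on
    labs <- c(labs, rep(seg_lab[s], k))
    sers <- c(sers, rep(seg_ser[s], k))
  }
  onsets <- unlist(onsets)
  if (length(onsets) == 0) {
    stop("window length exceeds every labelled segment; no epochs")
  }

  idx <- seq(1, wlen, by = decimate)
  d <- dim(hemo$data)
  x <- array(0, dim = c(length(onsets), d[1], d[2], length(idx)))
  for (e in seq_along(onsets)) {
    x[e, , , ] <- hemo$data[, , onsets[e] + idx - 1]
  }
  out <- list(x = x,
              labels = factor(labs, levels = keep),
              series = sers,
              subject_id = rep(hemo$subject_id %||% NA_character_,
                               length(onsets)),
              onset_sample = onsets,
              window_s = window_s, step_s = step_s,
              sampling_rate = fs / decimate,
              class_mode = class_mode,
              normalized = "none")
  class(out) <- "epoch_set"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$x)
  cat(sprintf(
    "epoch set: %d examples (%d ch x %d chromophores x %d samples), classes: %s\n",
    d[1], d[2], d[3], d[4],
    paste(sprintf("%s=%d", levels(x$labels), table(x$labels)),
          collapse = ", ")))
  invisible(x)
}

#' Bind epoch sets from several subjects
#' @param sets List of `epoch_set` objects with identical geometry.
#' @return One pooled `epoch_set`.
#' @export
bind_epoch_sets <- function(sets) {
  stopifnot(length(sets) >= 1)
  d <- dim(sets[[1]]$x)
  n <- sum(vapply(sets, function(s) dim(s$x)[1], integer(1)))
  x <- array(0, dim = c(n, d[2], d[3], d[4]))
  labels <- character(0); series <- integer(0); subj <- character(0)
  at <- 0
  for (s in sets) {
    k <- dim(s$x)[1]
    x[at + seq_len(k), , , ] <- s$x
    labels <- c(labels, as.character(s$labels))
    series <- c(series, s$series)
    subj <- c(subj, as.character(s$subject_id))
    at <- at + k
  }
  out <- sets[[1]]
  out$x <- x
  out$labels <- factor(labels, levels = levels(sets[[1]]$labels))
  out$series <- series
  out$subject_id <- subj
  out$onset_sample <- NULL
  out
}

#' Normalize epoched examples without information leakage
#'
#' With `scheme = "zscore"`, per-channel mean and sd are estimated from the
#' training examples only and applied to all examples, so held-out data
#' never influence the statistics. Zero-variance channels are guarded with a
#' small epsilon and flagged with a warning.
#'
#' @param epochs An `epoch_set`.
#' @param scheme `"none"` or `"zscore"`.
#' @param train_idx Indices of the training examples that define the
#'   statistics (default: all examples).
#' @param stats Optional precomputed statistics (as returned in the
#'   `norm_stats` field) to apply, e.g. train statistics applied to a test
#'   set.
#' @return The transformed `epoch_set` with `norm_stats` attached.
#' @export
normalize_examples <- function(epochs, scheme = c("zscore", "none"),
                               train_idx = NULL, stats = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  scheme <- match.arg(scheme)
  if (scheme == "none") {
    epochs$normalized <- "none"
    return(epochs)
  }
  d <- dim(epochs$x)
  if (is.null(stats)) {
    if (is.null(train_idx)) train_idx <- seq_len(d[1])
    xt <- epochs$x[train_idx, , , , drop = FALSE]
    mu <- apply(xt, c(2, 3), mean)
    sdv <- apply(xt, c(2, 3), sd)
    if (any(sdv < 1e-12)) {
      warning("zero-variance channel(s); epsilon-guarded normalization")
      sdv <- pmax(sdv, 1e-12)
    }
    stats <- list(mean = mu, sd = sdv)
  }
  for (ch in seq_len(d[2])) {
    for (cr in seq_len(d[3])) {
      epochs$x[, ch, cr, ] <-
        (epochs$x[, ch, cr, ] - stats$mean[ch, cr]) / stats$sd[ch, cr]
    }
  }
  epochs$normalized <- "zscore"
  epochs$norm_stats <- stats
  epochs
}

#' Subset an epoch set by example index
#' @noRd
subset_epochs <- function(epochs, idx) {
  epochs$x <- epochs$x[idx, , , , drop = FALSE]
  epochs$labels <- epochs$labels[idx]
  epochs$series <- epochs$series[idx]
  epochs$subject_id <- epochs$subject_id[idx]
  if (!is.null(epochs$onset_sample)) {
    epochs$onset_sample <- epochs$onset_sample[idx]
  }
  epochs
}
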