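# Continuous-to-epochs EEG preprocessing: bandpass filtering, blink
# detection/rejection, epoching with baseline correction, amplitude-based
# trial rejection, and bad-channel flagging + interpolation.

#' Continuous multichannel recording container
#'
#' @param data channels x samples matrix, microvolts.
#' @param srate sampling rate, Hz.
#' @param events data.frame with columns `sample` (1-based onset sample) and
#'   `label` (0 = standard, 1 = deviant).
#' @param channels data.frame with `name`, `x`, `y`, `role`.
#' @return object of class `continuous_recording`.
#' @export
continuous_recording <- function(data, srate, events, channels) {
  stopifnot(is.matrix(data), nrow(data) == nrow(channels), srate > 0)
  if (nrow(events) && (min(events$sample) < 1 || max(events$sample) > ncol(data)))
    stop("event samples outside the recording", call. = FALSE)
  structure(list(data = data, srate = srate, events = events,
                 channels = channels),
            class = "continuous_recording")
}

#' Zero-phase Butterworth bandpass filter
#'
#' Applies a forward-backward (zero-phase) Butterworth bandpass per channel,
#' implemented as a cascade of an order-`order` high-pass at `low` Hz and an
#' order-`order` low-pass at `high` Hz (numerically robust for very low
#' high-pass corners relative to the sampling rate). The channel mean (DC)
#' is removed before filtering.
#'
#' @param rec a `continuous_recording`.
#' @param low,high band edges, Hz (defaults 0.5 and 30).
#' @param order Butterworth order of each cascade section (default 4).
#' @return filtered `continuous_recording`.
#' @export
eeg_bandpass <- function(rec, low = 0.5, high = 30, order = 4) {
  stopifnot(inherits(rec, "continuous_recording"))
  nyq <- rec$srate / 2
  if (!(low > 0 && low < high && high < nyq))
    stop(sprintf("band (%g, %g) Hz invalid for Nyquist %g Hz", low, high, nyq),
         call. = FALSE)
  hp <- signal::butter(order, low / nyq, type = "high")
  lp <- signal::butter(order, high / nyq, type = "low")
  x <- rec$data
  for (ch in seq_len(nrow(x))) {
    v <- x[ch, ] - mean(x[ch, ])
    v <- signal::filtfilt(hp, v)
    v <- signal::filtfilt(lp, v)
    x[ch, ] <- v
  }
  rec$data <- x
  rec
}

#' Detect blink intervals on the vertical EOG channel
#'
#' Contiguous runs where |EOG| exceeds `threshold` are taken as blinks,
#' padded by `pad_ms` on both sides, and overlapping intervals are merged.
#'
#' @param rec a `continuous_recording` with an `eog`-role channel.
#' @param threshold microvolts (default 250).
#' @param pad_ms padding on each side, ms (default 100).
#' @return data.frame with columns `start`, `end` (sample indices, inclusive).
#' @export
detect_blinks <- function(rec, threshold = 250, pad_ms = 100) {
  stopifnot(inherits(rec, "continuous_recording"))
  eog <- which(rec$channels$role == "eog")
  if (length(eog) == 0) stop("no EOG-role channel in recording", call. = FALSE)
  v <- abs(rec$data[eog[1], ]) > threshold
  if (!any(v)) return(data.frame(start = integer(0), end = integer(0)))
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  pad <- round(pad_ms / 1000 * rec$srate)
  s <- pmax(1L, starts[keep] - pad)
  e <- pmin(ncol(rec$data), ends[keep] + pad)
  # merge overlaps
  o <- order(s)
  s <- s[o]; e <- e[o]
  ms <- s[1]; me <- e[1]; out_s <- integer(0); out_e <- integer(0)
  for (i in seq_along(s)[-1]) {
    if (s[i] <= me + 1L) me <- max(me, e[i])
    else { out_s <- c(out_s, ms); out_e <- c(out_e, me); ms <- s[i]; me <- e[i] }
  }
  data.frame(start = c(out_s, ms), end = c(out_e, me))
}

#' Epoch a continuous recording and baseline-correct
#'
#' Cuts fixed-length segments around each event, subtracts the per-trial,
#' per-channel mean over the baseline interval, and marks trials overlapping
#' any supplied blink interval as rejected (reason `"blink"`). Events whose
#' epoch would run past the record edge are dropped with reason `"edge"`.
#'
#' @param rec a `continuous_recording`.
#' @param window epoch limits, ms (default c(-100, 400)).
#' @param baseline baseline interval, ms (default c(-100, 0)); must lie
#'   inside `window`.
#' @param blinks optional data.frame from [detect_blinks()].
#' @return an `epoch_set` (see [gen_subject_eeg()] for the layout); dropped
#'   edge events are recorded in the `dropped_edge` field.
#' @export
epoch_and_baseline <- function(rec, window = c(-100, 400),
                               baseline = c(-100, 0), blinks = NULL) {
  stopifnot(inherits(rec, "continuous_recording"))
  if (baseline[1] < window[1] || baseline[2] > window[2])
    stop("baseline must lie inside the epoch window", call. = FALSE)
  sr <- rec$srate
  s0 <- round(window[1] / 1000 * sr)
  s1 <- round(window[2] / 1000 * sr)
  offs <- s0:s1
  times <- offs * 1000 / sr
  n_ch <- nrow(rec$data)
  ok <- rec$events$sample + s0 >= 1 & rec$events$sample + s1 <= ncol(rec$data)
  dropped <- which(!ok)
  ev <- rec$events[ok, , drop = FALSE]
  n_tr <- nrow(ev)
  data <- array(0, dim = c(n_tr, n_ch, length(offs)))
  for (i in seq_len(n_tr))
    data[i, , ] <- rec$data[, ev$sample[i] + offs, drop = FALSE]
  bl <- which(times >= baseline[1] & times <= baseline[2])
  bmean <- apply(data[, , bl, drop = FALSE], c(1, 2), mean)
  data <- data - array(rep(bmean, length(offs)), dim = dim(data))
  reason <- rep("none", n_tr)
  if (!is.null(blinks) && nrow(blinks)) {
    for (i in seq_len(n_tr)) {
      a <- ev$sample[i] + s0; b <- ev$sample[i] + s1
      if (any(blinks$start <= b & blinks$end >= a)) reason[i] <- "blink"
    }
  }
  chan <- rec$channels
  if (is.null(chan$bad)) chan$bad <- FALSE
  structure(list(data = data, times = times, channels = chan, srate = sr,
                 tone = ev$label, kept = reason == "none",
                 reject_reason = reason, blink_trials = which(reason == "blink"),
                 dropped_edge = dropped),
            class = "epoch_set")
}

#' Mark blink-contaminated epochs by EOG threshold
#'
#' Epoch-level analogue of [detect_blinks()] for data that arrive already
#' epoched (e.g. the synthetic generator): any trial whose EOG channel
#' exceeds `threshold` in absolute value is rejected with reason `"blink"`.
#'
#' @param epochs an `epoch_set` containing an `eog`-role channel.
#' @param threshold microvolts (default 250).
#' @return `epoch_set` with updated `kept` / `reject_reason`.
#' @export
reject_blinks <- function(epochs, threshold = 250) {
  stopifnot(inherits(epochs, "epoch_set"))
  eog <- which(epochs$channels$role == "eog")
  if (length(eog) == 0) stop("no EOG-role channel in epochs", call. = FALSE)
  peak <- apply(abs(epochs$data[, eog[1], , drop = FALSE]), 1, max)
  hit <- peak > threshold & epochs$reject_reason == "none"
  epochs$reject_reason[hit] <- "blink"
  epochs$kept <- epochs$reject_reason == "none"
  epochs
}

# (trial, channel) artefact indicator: |amplitude| above threshold anywhere
artefact_matrix <- function(epochs, threshold) {
  apply(abs(epochs$data), c(1, 2), max) > threshold
}

#' Reject trials by amplitude threshold
#'
#' A (trial, channel) pair is artefactual if the absolute amplitude exceeds
#' `threshold` anywhere in the epoch; a trial is rejected (reason
#' `"amplitude"`) if any good scalp channel is artefactual. Already-rejected
#' trials keep their original reason. Per-channel artefact fractions
#' (computed over trials not rejected for blinks) are stored in
#' `channels$artefact_fraction` for the bad-channel rule.
#'
#' @param epochs an `epoch_set`.
#' @param threshold microvolts (default 100).
#' @return `epoch_set` with updated rejection bookkeeping.
#' @export
reject_amplitude <- function(epochs, threshold = 100) {
  stopifnot(inherits(epochs, "epoch_set"))
  art <- artefact_matrix(epochs, threshold)
  scalp_good <- epochs$channels$role == "scalp" & !epochs$channels$bad
  eligible <- epochs$reject_reason %in% c("none", "amplitude")
  epochs$channels$artefact_fraction <-
    colMeans(art[eligible, , drop = FALSE])
  bad_trial <- rowSums(art[, scalp_good, drop = FALSE]) > 0
  epochs$reject_reason[eligible] <- ifelse(bad_trial[eligible], "amplitude", "none")
  epochs$kept <- epochs$reject_reason == "none"
  attr(epochs, "amplitude_threshold") <- threshold
  epochs
}

#' Flag artefact-prone channels and interpolate them
#'
#' Scalp channels artefactual in more than `max_fraction` of trials are
#' flagged bad, removed from the trial-rejection rule, and replaced by
#' inverse-distance-weighted interpolation from the remaining good scalp
#' channels. Trial rejection (reason `"amplitude"`) is then recomputed over
#' the good channels only.
#'
#' @param epochs an `epoch_set` that has been through [reject_amplitude()]
#'   (or raw; the artefact fractions are recomputed here).
#' @param max_fraction flagging threshold on the artefact fraction
#'   (default 0.20; strictly-greater comparison).
#' @param threshold amplitude threshold, microvolts (default 100).
#' @param idw_power inverse-distance weighting exponent (default 2).
#' @return `epoch_set` with `channels$bad` set, bad channels interpolated,
#'   and trial rejection recomputed.
#' @export
flag_and_interpolate_channels <- function(epochs, max_fraction = 0.20,
                                          threshold = 100, idw_power = 2) {
  stopifnot(inherits(epochs, "epoch_set"))
  art <- artefact_matrix(epochs, threshold)
  eligible <- epochs$reject_reason %in% c("none", "amplitude")
  frac <- colMeans(art[eligible, , drop = FALSE])
  scalp <- epochs$channels$role == "scalp"
  bad <- scalp & frac > max_fraction
  good <- scalp & !bad
  if (sum(good) < 4) stop("fewer than 4 good scalp channels remain", call. = FALSE)
  epochs$channels$bad <- bad
  epochs$channels$artefact_fraction <- frac
  if (any(bad)) {
    pos <- epochs$channels[, c("x", "y")]
    for (b in which(bad)) {
      d <- sqrt((pos$x[which(good)] - pos$x[b])^2 + (pos$y[which(good)] - pos$y[b])^2)
      w <- 1 / pmax(d, 1e-6)^idw_power
      w <- w / sum(w)
      gi <- which(good)
      interp_vals <- array(0, dim = dim(epochs$data[, b, , drop = FALSE]))
      for (j in seq_along(gi))
        interp_vals <- interp_vals + w[j] * epochs$data[, gi[j], , drop = FALSE]
      epochs$data[, b, ] <- interp_vals[, 1, ]
    }
  }
  # recompute amplitude rejection over good channels only
  art <- artefact_matrix(epochs, threshold)
  bad_trial <- rowSums(art[, good, drop = FALSE]) > 0
  eligible <- epochs$reject_reason %in% c("none", "amplitude")
  epochs$reject_reason[eligible] <- ifelse(bad_trial[eligible], "amplitude", "none")
  epochs$kept <- epochs$reject_reason == "none"
  epochs
}

#' Write a rejection log to TSV
#' @param epochs an `epoch_set`.
#' @param path output path.
#' @export
write_rejection_log <- function(epochs, path) {
  utils::write.table(
    data.frame(trial = seq_along(epochs$kept), tone = epochs$tone,
               kept = epochs$kept, reason = epochs$reject_reason),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
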