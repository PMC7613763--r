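# AP and FP feature extraction. All features share one onset convention:
# the last upward crossing of `onset_frac` (default 10%) of the peak before
# the peak, with linear interpolation between samples for sub-sample
# precision. APD90 runs from that onset to the first downward crossing of
# 10% of peak after the peak; depolarization time runs from onset to peak.

# resolve (samples, fs, peak index, baseline) from waveform-ish input
.wf <- function(waveform, fs_hz) {
  if (inherits(waveform, "ap_waveform")) {
    x <- waveform$samples_uv
    fs <- waveform$fs_hz
    baseline <- 0             # representative waveforms are offset-corrected
  } else if (inherits(waveform, "beat_snippet")) {
    x <- waveform$samples_uv
    fs <- waveform$fs_hz
    baseline <- 0
  } else if (inherits(waveform, "ap_template")) {
    x <- waveform$samples_mv * 1000
    fs <- waveform$fs_hz
    baseline <- 0
  } else {
    stopifnot(is.numeric(waveform))
    if (is.null(fs_hz)) stop("fs_hz required for plain numeric waveforms")
    x <- waveform
    fs <- fs_hz
    m <- which.max(x)
    nb <- max(1L, floor(0.25 * (m - 1L)))
    baseline <- if (m > 1) stats::median(x[seq_len(nb)]) else 0
  }
  # peak-plateau convention: the peak is the first sample reaching 98% of
  # the maximum above baseline, so that peak timing is stable on the
  # near-flat early plateau of the AP (where noise, not shape, decides the
  # argmax); for sharp waveforms this coincides with the argmax
  amp <- max(x) - baseline
  peak_i <- which(x - baseline >= 0.98 * amp)[1]
  list(x = x, fs = fs, peak_i = peak_i, peak_uv = max(x), amp = amp,
       baseline = baseline, t = (seq_along(x) - 1) / fs * 1000)
}

#' AP amplitude
#'
#' Peak minus pre-onset baseline, reported in mV (inputs are in uV except
#' `ap_template`, which is in mV and converted internally).
#'
#' @param waveform `ap_waveform`, `beat_snippet`, `ap_template`, or plain
#'   numeric vector in uV.
#' @param fs_hz sampling rate (plain vectors only).
#' @return amplitude, mV.
#' @export
ap_amplitude <- function(waveform, fs_hz = NULL) {
  w <- .wf(waveform, fs_hz)
  if (w$amp <= 0) stop("ap_amplitude: undefined (no positive peak)")
  w$amp / 1000
}

# onset time (ms): last upward crossing of level before peak; NULL if the
# waveform never sits below the level before the peak
.onset_t <- function(w, frac) {
  lev <- w$baseline + frac * w$amp
  pre <- seq_len(w$peak_i - 1L)
  below <- pre[w$x[pre] < lev]
  if (length(below) == 0) return(NULL)
  i <- max(below)
  .cross_t(w$t, w$x, i, lev)
}

#' AP duration at 90% repolarization (APD90)
#'
#' @param waveform waveform input (see [ap_amplitude]); must have a single
#'   dominant positive peak.
#' @param fs_hz sampling rate (plain vectors only).
#' @param onset_frac onset level as a fraction of peak (default 0.1, shared
#'   with [depolarization_time]).
#' @return APD90 in ms. Errors with "apd90 undefined" if the waveform never
#'   falls back below 10% of peak within the window.
#' @export
apd90 <- function(waveform, fs_hz = NULL, onset_frac = 0.1) {
  w <- .wf(waveform, fs_hz)
  on_t <- .onset_t(w, onset_frac)
  if (is.null(on_t)) stop("apd90: onset undefined (waveform starts above onset level)")
  lev <- w$baseline + 0.1 * w$amp
  post <- seq(w$peak_i, length(w$x))
  below <- post[w$x[post] < lev]
  if (length(below) == 0) stop("apd90 undefined: waveform never repolarizes below 10% of peak")
  j <- min(below) - 1L
  end_t <- .cross_t(w$t, w$x, j, lev)
  end_t - on_t
}

#' Depolarization time (onset to peak)
#'
#' @inheritParams apd90
#' @return depolarization time in ms.
#' @export
depolarization_time <- function(waveform, fs_hz = NULL, onset_frac = 0.1) {
  w <- .wf(waveform, fs_hz)
  on_t <- .onset_t(w, onset_frac)
  if (is.null(on_t))
    stop("depolarization_time: onset undefined")
  w$t[w$peak_i] - on_t
}

#' Field-potential amplitude of an extracellular beat
#'
#' Max minus min of the offset-corrected snippet within `+/- win_ms` of the
#' detected peak.
#'
#' @param snippet `beat_snippet` or plain numeric vector (uV).
#' @param fs_hz sampling rate (plain vectors only).
#' @param peak_i peak sample index (plain vectors; default absolute maximum).
#' @param win_ms half-window, ms (default 10).
#' @return FP amplitude, uV.
#' @export
fp_amplitude <- function(snippet, fs_hz = NULL, peak_i = NULL, win_ms = 10) {
  if (inherits(snippet, "beat_snippet")) {
    x <- snippet$samples_uv
    fs <- snippet$fs_hz
    p <- snippet$peak_i
  } else {
    stopifnot(is.numeric(snippet), !is.null(fs_hz))
    x <- snippet
    fs <- fs_hz
    p <- peak_i %||% which.max(abs(x))
  }
  hw <- round(win_ms / 1000 * fs)
  win <- max(1L, p - hw):min(length(x), p + hw)
  max(x[win]) - min(x[win])
}

#' Percentage of synchronously beating electrodes
#'
#' Pooled beat times are clustered by single linkage (a gap larger than
#' `tol_ms` starts a new cluster); clusters containing beats from more than
#' half of the active electrodes are "network beats". An electrode is
#' synchronous if it participates in at least `min_participation` of the
#' network beats.
#'
#' @param beat_time_lists list of numeric vectors of beat times (s), one per
#'   electrode.
#' @param tol_ms clustering tolerance, ms.
#' @param min_participation participation fraction required.
#' @return percentage (0-100) of active electrodes that beat synchronously.
#' @export
percent_synchronous <- function(beat_time_lists, tol_ms = 50,
                                min_participation = 0.8) {
  if (length(beat_time_lists) == 0) stop("percent_synchronous: empty input")
  active <- which(vapply(beat_time_lists, length, integer(1)) > 0)
  if (length(active) == 0) stop("percent_synchronous: no active electrodes")
  el <- rep(active, vapply(beat_time_lists[active], length, integer(1)))
  tt <- unlist(beat_time_lists[active])
  ord <- order(tt)
  tt <- tt[ord]
  el <- el[ord]
  cl <- cumsum(c(1, diff(tt) > tol_ms / 1000))
  n_active <- length(active)
  network <- which(tapply(el, cl, function(e) length(unique(e))) > n_active / 2)
  if (length(network) == 0) return(0)
  part <- vapply(active, function(e) {
    mean(vapply(network, function(cid) any(el[cl == cid] == e), logical(1)))
  }, numeric(1))
  100 * sum(part >= min_participation) / n_active
}
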