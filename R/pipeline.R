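# Waveform pipeline: beat detection, offset correction, classification of
# beats as extracellular vs intracellular-like, and selection/averaging of
# representative waveforms per channel.

#' Classifier and snippet configuration
#'
#' The two classification criteria follow the published rule: a beat is
#' intracellular-like iff its peak amplitude exceeds `min_peak_uv` (strictly)
#' AND its peak width exceeds `min_width_ms` (strictly). Width is measured as
#' full width at `width_frac` of the peak (default half maximum; the level is
#' configurable because the published rule does not define it).
#'
#' @param min_peak_uv amplitude criterion, uV (default 500).
#' @param min_width_ms width criterion, ms (default 25).
#' @param yield_min_amp_mv amplitude floor for yield counting, mV (default 1).
#' @param snippet_pre_ms,snippet_post_ms snippet window around the detected
#'   peak, ms.
#' @param snippet_baseline_ms extra window preceding the snippet used for
#'   the baseline (offset) estimate, ms.
#' @param stabilization_drift_uv_per_s offset-drift tolerance defining
#'   "channel stabilization", uV/s.
#' @param settle_delay_s representative waveforms are taken from beats at
#'   least this long after poration end (default 9 s).
#' @param width_frac fraction of peak at which width is measured.
#' @param onset_frac fraction of peak defining the AP onset for features.
#' @param detect_thresh_sd detection threshold in robust-noise units.
#' @param detect_floor_uv absolute detection floor, uV.
#' @param refractory_ms merge window / minimum event spacing, ms.
#' @param detrend_window_s running-median detrend window, s.
#' @return named list of class `classifier_config`.
#' @export
classifier_config <- function(min_peak_uv = 500, min_width_ms = 25,
                              yield_min_amp_mv = 1, snippet_pre_ms = 25,
                              snippet_post_ms = 600, snippet_baseline_ms = 25,
                              stabilization_drift_uv_per_s = 200,
                              settle_delay_s = 9, width_frac = 0.5,
                              onset_frac = 0.1, detect_thresh_sd = 6,
                              detect_floor_uv = 50, refractory_ms = 100,
                              detrend_window_s = 1) {
  stopifnot(min_peak_uv > 0, min_width_ms > 0,
            snippet_post_ms > min_width_ms)
  structure(as.list(environment()), class = "classifier_config")
}

# running-median detrend (removes offsets and slow drift; ~0.5 Hz cutoff at
# the default 1 s window). The median is computed on a decimated copy (~100
# points per window) and interpolated back: the trend is sub-Hz by
# construction, so decimation does not change it, but it makes the filter
# O(n) instead of O(n * window).
.detrend <- function(x, fs, window_s) {
  n <- length(x)
  k <- round(fs * window_s)
  d <- max(1L, k %/% 101L)
  idx <- seq(1L, n, by = d)
  kd <- length(idx) %/% 2L * 2L - 1L
  kd <- max(3L, min((k %/% d) %/% 2L * 2L + 1L, kd))
  if (length(idx) < 3L) return(x - stats::median(x))
  trend <- stats::runmed(x[idx], kd, endrule = "median")
  x - stats::approx(idx, trend, xout = seq_len(n), rule = 2)$y
}

#' Detect beats in a single-channel trace
#'
#' Robust threshold detector: the trace is detrended with a running median,
#' noise is estimated as `1.4826 * median(|x - median(x)|)` of the detrended
#' copy, candidate samples exceed
#' `max(detect_thresh_sd * sigma, detect_floor_uv)` in absolute value,
#' candidates within the refractory window merge into one event, and the
#' event's peak is the sample of maximal absolute detrended amplitude.
#'
#' @param trace numeric trace, uV.
#' @param fs_hz sampling rate, Hz.
#' @param config [classifier_config].
#' @return numeric vector of peak times, s (strictly increasing; empty if
#'   nothing crosses threshold).
#' @export
detect_beats <- function(trace, fs_hz, config = classifier_config()) {
  if (length(trace) < fs_hz) stop("detect_beats: trace too short (< 1 s)")
  filt <- .detrend(trace, fs_hz, config$detrend_window_s)
  sigma <- stats::mad(filt)
  thr <- max(config$detect_thresh_sd * sigma, config$detect_floor_uv)
  above <- which(abs(filt) > thr)
  if (length(above) == 0) return(numeric(0))
  refr <- round(config$refractory_ms / 1000 * fs_hz)
  brk <- c(0, which(diff(above) > refr), length(above))
  peaks <- vapply(seq_len(length(brk) - 1L), function(i) {
    idx <- above[(brk[i] + 1L):brk[i + 1L]]
    # peak = first sample reaching 98% of the event maximum: identical to
    # argmax for sharp spikes, but stable under noise on the near-flat
    # plateau of intracellular-like waveforms
    a <- abs(filt[idx])
    idx[which(a >= 0.98 * max(a))[1]]
  }, numeric(1))
  (peaks - 1) / fs_hz
}

#' Correct amplifier offset
#'
#' For snippets (numeric vector with a known pre-peak segment) the median of
#' the pre-onset baseline window is subtracted; for whole traces a running
#' median (1 s window) is subtracted. Idempotent on already-corrected input.
#'
#' @param x numeric snippet or trace, uV.
#' @param fs_hz sampling rate, Hz.
#' @param baseline_n for snippets: number of leading samples forming the
#'   pre-onset baseline window; `NULL` treats `x` as a whole trace.
#' @param config [classifier_config].
#' @return corrected numeric vector.
#' @export
correct_offset <- function(x, fs_hz, baseline_n = NULL,
                           config = classifier_config()) {
  if (is.null(baseline_n)) return(.detrend(x, fs_hz, config$detrend_window_s))
  x - stats::median(x[seq_len(min(baseline_n, length(x)))])
}

#' Extract offset-corrected beat snippets
#'
#' Each snippet spans `[-snippet_pre_ms, +snippet_post_ms]` around a detected
#' peak. The baseline is the median of the `snippet_baseline_ms` window
#' *preceding* the snippet (so the upstroke foot never contaminates it); the
#' offset drift (uV/s) over that window is recorded for the stabilization
#' check. Peaks too close to either trace edge are dropped.
#'
#' @param trace numeric trace, uV.
#' @param fs_hz sampling rate, Hz.
#' @param peak_times_s from [detect_beats].
#' @param config [classifier_config].
#' @param electrode_id carried into each snippet.
#' @param poration_times_s poration instants: a snippet whose window (or
#'   baseline window) contains one records the stimulation transient, not a
#'   beat, and is pre-labelled `"mixed_reject"` (skipped by classification
#'   and representative-waveform selection).
#' @return list of `beat_snippet` objects: `samples_uv` (corrected),
#'   `t_peak_s`, `peak_i` (index of the peak within the snippet), `fs_hz`,
#'   `electrode_id`, `beat_index`, `drift_uv_per_s`, `baseline_uv`, `label`
#'   (`NA` until classified).
#' @export
extract_snippets <- function(trace, fs_hz, peak_times_s,
                             config = classifier_config(),
                             electrode_id = NA_integer_,
                             poration_times_s = numeric(0)) {
  pre_n <- round(config$snippet_pre_ms / 1000 * fs_hz)
  post_n <- round(config$snippet_post_ms / 1000 * fs_hz)
  base_n <- round(config$snippet_baseline_ms / 1000 * fs_hz)
  out <- list()
  prev_baseline <- NA_real_
  prev_t <- NA_real_
  for (b in seq_along(peak_times_s)) {
    p <- round(peak_times_s[b] * fs_hz) + 1L
    i0 <- p - pre_n - base_n
    i1 <- p + post_n
    if (i0 < 1 || i1 > length(trace)) next
    baseline <- stats::median(trace[i0:(i0 + base_n - 1L)])
    # offset drift across consecutive beats: the within-beat window is too
    # short for a noise-robust slope, the baseline medians of neighbouring
    # beats are not
    drift <- if (is.na(prev_baseline)) Inf
             else (baseline - prev_baseline) / (peak_times_s[b] - prev_t)
    prev_baseline <- baseline
    prev_t <- peak_times_s[b]
    t0 <- (i0 - 1) / fs_hz
    t1 <- (i1 - 1) / fs_hz
    lab <- if (length(poration_times_s) > 0 &&
               any(poration_times_s >= t0 & poration_times_s <= t1))
      "mixed_reject" else NA_character_
    out[[length(out) + 1L]] <- structure(
      list(samples_uv = trace[(p - pre_n):i1] - baseline,
           t_peak_s = peak_times_s[b], peak_i = pre_n + 1L, fs_hz = fs_hz,
           electrode_id = electrode_id, beat_index = b,
           drift_uv_per_s = drift, baseline_uv = baseline,
           label = lab),
      class = "beat_snippet")
  }
  out
}

# full width at `frac` of peak (ms) of the positive deflection around peak_i,
# with linear interpolation at the crossings
.peak_width_ms <- function(x, fs, peak_i, frac, amp = NULL) {
  lev <- frac * (amp %||% x[peak_i])
  t <- (seq_along(x) - 1) / fs * 1000
  left <- peak_i
  while (left > 1 && x[left - 1] >= lev) left <- left - 1
  tl <- if (left == 1) t[1] else .cross_t(t, x, left - 1L, lev)
  right <- peak_i
  n <- length(x)
  while (right < n && x[right + 1] >= lev) right <- right + 1
  tr <- if (right == n) t[n] else .cross_t(t, x, right, lev)
  tr - tl
}

#' Classify one beat snippet
#'
#' Peak amplitude is `max(samples) - baseline` (snippets are already
#' baseline-corrected, so simply the maximum); width is the full width at
#' `width_frac` of peak. The label is `"intracellular_like"` iff amplitude
#' strictly exceeds `min_peak_uv` AND width strictly exceeds `min_width_ms`,
#' else `"extracellular"`.
#'
#' @param snippet `beat_snippet` (or plain numeric vector, offset-corrected).
#' @param config [classifier_config].
#' @param fs_hz required if `snippet` is a plain vector.
#' @return label string.
#' @export
classify_waveform <- function(snippet, config = classifier_config(),
                              fs_hz = NULL) {
  if (inherits(snippet, "beat_snippet")) {
    x <- snippet$samples_uv
    fs <- snippet$fs_hz
  } else {
    stopifnot(is.numeric(snippet), !is.null(fs_hz))
    x <- snippet
    fs <- fs_hz
  }
  amp <- max(x)
  if (!(amp > config$min_peak_uv)) return("extracellular")
  peak_i <- which(x >= 0.98 * amp)[1]   # peak-plateau convention
  width <- .peak_width_ms(x, fs, peak_i, config$width_frac, amp)
  if (width > config$min_width_ms) "intracellular_like" else "extracellular"
}

# classify a list of snippets in place (mixed_reject pre-labels stand)
.classify_all <- function(snippets, config) {
  lapply(snippets, function(s) {
    if (is.na(s$label)) s$label <- classify_waveform(s, config)
    s
  })
}

#' Select and average the representative waveform of a channel
#'
#' Takes the first three consecutive intracellular-like beats whose peaks
#' fall at least `settle_delay_s` after poration end and whose pre-beat
#' offset drift is below `stabilization_drift_uv_per_s` (whichever happens
#' later), aligns them at the peak sample and averages pointwise.
#' "Consecutive" means adjacent detected beats with no other beat between
#' them. Channels with fewer than three qualifying beats are excluded with a
#' reason rather than raising an error.
#'
#' @param snippets classified snippets of one channel (see
#'   [extract_snippets]; unlabeled snippets are classified on the fly).
#' @param poration_end_s poration end time, s.
#' @param config [classifier_config].
#' @return list with either `waveform` (class `ap_waveform`: `samples_uv`,
#'   `fs_hz`, `peak_i`, `n_averaged`, `t_measure_s`) or `excluded = TRUE`
#'   plus `reason`.
#' @export
select_and_average <- function(snippets, poration_end_s = 0,
                               config = classifier_config()) {
  if (length(snippets) == 0)
    return(list(excluded = TRUE, reason = "no_beats"))
  if (any(vapply(snippets, function(s) is.na(s$label), logical(1))))
    snippets <- .classify_all(snippets, config)
  ok <- vapply(snippets, function(s) {
    s$label == "intracellular_like" &&
      s$t_peak_s >= poration_end_s + config$settle_delay_s &&
      abs(s$drift_uv_per_s) <= config$stabilization_drift_uv_per_s
  }, logical(1))
  bi <- vapply(snippets, function(s) s$beat_index, numeric(1))
  run <- NULL
  idx <- which(ok)
  for (i in idx) {
    j <- match(bi[i] + 1, bi)
    k <- match(bi[i] + 2, bi)
    if (!is.na(j) && !is.na(k) && ok[j] && ok[k]) {
      run <- c(i, j, k)
      break
    }
  }
  if (is.null(run))
    return(list(excluded = TRUE, reason = "insufficient_beats"))
  mats <- vapply(snippets[run], function(s) s$samples_uv,
                 numeric(length(snippets[[run[1]]]$samples_uv)))
  list(waveform = structure(
    list(samples_uv = rowMeans(mats), fs_hz = snippets[[run[1]]]$fs_hz,
         peak_i = snippets[[run[1]]]$peak_i, n_averaged = 3L,
         t_measure_s = snippets[[run[1]]]$t_peak_s),
    class = "ap_waveform"))
}

#' Normalize a waveform in amplitude
#'
#' Subtracts the pre-onset baseline and divides by the peak, so the output
#' peaks at 1 with baseline ~0. Used before overlaying AP waveforms whose
#' absolute amplitudes are attenuated nonuniformly across electrodes.
#'
#' @param waveform `ap_waveform` or plain numeric vector.
#' @return normalized numeric vector (attributes preserved for
#'   `ap_waveform` input).
#' @export
normalize_amplitude <- function(waveform) {
  x <- if (inherits(waveform, "ap_waveform")) waveform$samples_uv else waveform
  peak_i <- which.max(x)
  nb <- max(1L, floor(0.25 * (peak_i - 1L)))
  baseline <- if (peak_i > 1) stats::median(x[seq_len(nb)]) else 0
  peak <- x[peak_i] - baseline
  if (peak <= 0) stop("normalize_amplitude: zero peak")
  out <- (x - baseline) / peak
  if (inherits(waveform, "ap_waveform")) {
    waveform$samples_uv <- out
    waveform
  } else out
}

#' Analyze one channel trace into a feature row
#'
#' Runs detection, snippet extraction, classification, representative-
#' waveform selection and feature extraction for a single electrode.
#'
#' @param trace numeric trace, uV.
#' @param fs_hz sampling rate, Hz.
#' @param electrode_id electrode index.
#' @param poration_end_s poration end time (`-Inf` for passive recordings:
#'   every beat then qualifies for selection).
#' @param config [classifier_config].
#' @param repeat_idx,phase provenance columns copied into the row.
#' @return list with `row` (one-row data.frame in the feature-table schema)
#'   and `exclusion` (NULL or a reason string).
#' @export
analyze_channel <- function(trace, fs_hz, electrode_id = 0L,
                            poration_end_s = -Inf,
                            config = classifier_config(),
                            repeat_idx = 1L, phase = "baseline1") {
  peaks <- detect_beats(trace, fs_hz, config)
  snips <- .classify_all(
    extract_snippets(trace, fs_hz, peaks, config, electrode_id,
                     poration_times_s = poration_end_s[is.finite(poration_end_s)]),
    config)
  labels <- vapply(snips, function(s) s$label, character(1))
  # FP amplitude: median over extracellular beats before poration end (or all
  # extracellular beats when none precede it)
  ec <- snips[labels == "extracellular"]
  if (length(ec) > 0) {
    pre_ec <- Filter(function(s) s$t_peak_s < poration_end_s, ec)
    if (length(pre_ec) == 0) pre_ec <- ec
    fp <- stats::median(vapply(pre_ec, fp_amplitude, numeric(1)))
  } else fp <- NA_real_
  sel <- select_and_average(snips, poration_end_s, config)
  if (is.null(sel$waveform)) {
    row <- data.frame(electrode_id = electrode_id, repeat_idx = repeat_idx,
                      phase = phase, label = "extracellular",
                      ap_amplitude_mv = NA_real_, apd90_ms = NA_real_,
                      tdep_ms = NA_real_, fp_amplitude_uv = fp,
                      n_beats_averaged = 0L, t_measure_s = NA_real_)
    return(list(row = row, exclusion = sel$reason))
  }
  w <- sel$waveform
  amp <- ap_amplitude(w)
  a90 <- tryCatch(apd90(w, onset_frac = config$onset_frac),
                  error = function(e) NA_real_)
  td <- tryCatch(depolarization_time(w, onset_frac = config$onset_frac),
                 error = function(e) NA_real_)
  row <- data.frame(electrode_id = electrode_id, repeat_idx = repeat_idx,
                    phase = phase, label = "intracellular_like",
                    ap_amplitude_mv = amp, apd90_ms = a90, tdep_ms = td,
                    fp_amplitude_uv = fp, n_beats_averaged = w$n_averaged,
                    t_measure_s = w$t_measure_s)
  list(row = row, exclusion = NULL)
}

#' Analyze a full recording into a feature table
#'
#' @param recording `mea_recording`.
#' @param config [classifier_config].
#' @param repeat_idx,phase provenance columns.
#' @return list with `features` (data.frame, one row per channel) and
#'   `exclusions` (data.frame of electrode_id + reason).
#' @export
analyze_recording <- function(recording, config = classifier_config(),
                              repeat_idx = 1L, phase = "baseline1") {
  ev <- recording$poration_events
  rows <- list()
  excl <- list()
  for (i in seq_len(nrow(recording$signals))) {
    eid <- recording$channel_meta$electrode_id[i]
    e_ev <- ev[ev$electrode_id == eid & ev$success, , drop = FALSE]
    p_end <- if (nrow(e_ev) > 0) max(e_ev$t_end_s) else -Inf
    res <- analyze_channel(recording$signals[i, ], recording$fs_hz, eid,
                           p_end, config, repeat_idx, phase)
    rows[[i]] <- res$row
    if (!is.null(res$exclusion))
      excl[[length(excl) + 1L]] <- data.frame(electrode_id = eid,
                                              reason = res$exclusion)
  }
  list(features = do.call(rbind, rows),
       exclusions = if (length(excl)) do.call(rbind, excl)
                    else data.frame(electrode_id = integer(0),
                                    reason = character(0)))
}
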