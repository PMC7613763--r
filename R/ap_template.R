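# Parametric cardiomyocyte action-potential templates.
#
# The template is a product of an upstroke factor and a repolarization
# factor, designed so that the headline AP parameters are exact, testable
# properties of the waveform:
#   * the 10%-of-peak upstroke crossing sits at t = 0 (the AP "onset"),
#   * the peak is reached exactly t_dep_ms after onset,
#   * the waveform crosses 0.1 * amplitude at t = apd90_ms (APD90).
# Upstroke: cubic smoothstep s(u) = 3u^2 - 2u^3 rescaled so s = 0.1 at t = 0
# and s = 1 at t = t_dep_ms.  Repolarization: falling sigmoid
# f(t) = 1 / (1 + exp((t - m)/w)) with midpoint m = apd90 - w*ln 9, which
# makes f cross 0.1 exactly at apd90.

# u with smoothstep(u) = 0.1 (root of 3u^2 - 2u^3 = 0.1)
.u10 <- local({
  stats::uniroot(function(u) 3 * u^2 - 2 * u^3 - 0.1,
                 c(0.05, 0.4), tol = 1e-13)$root
})

.smoothstep <- function(u) {
  u <- pmin(1, pmax(0, u))
  u * u * (3 - 2 * u)
}

#' Action-potential shape parameters
#'
#' @param amplitude_mv membrane AP amplitude in mV (>= 0; 0 gives an all-zero
#'   template).
#' @param t_dep_ms depolarization time, onset (10% of peak) to peak, ms.
#' @param apd90_ms AP duration at 90% repolarization, ms.
#' @param rep_width_ms width `w` of the repolarization sigmoid, ms.
#' @param baseline_mv resting level, mV (stored as 0 in rendered traces;
#'   offsets are added downstream by the electrode model).
#' @return object of class `ap_params`.
#' @export
ap_params <- function(amplitude_mv = 100, t_dep_ms = 10, apd90_ms = 300,
                      rep_width_ms = 20, baseline_mv = 0) {
  stopifnot(is_scalar_num(amplitude_mv), is_scalar_num(t_dep_ms),
            is_scalar_num(apd90_ms), is_scalar_num(rep_width_ms))
  if (amplitude_mv < 0) stop("ap_params: amplitude_mv must be >= 0")
  if (t_dep_ms <= 0) stop("ap_params: t_dep_ms must be > 0")
  if (rep_width_ms <= 0) stop("ap_params: rep_width_ms must be > 0")
  if (apd90_ms <= t_dep_ms) stop("ap_params: apd90_ms must exceed t_dep_ms")
  if (apd90_ms - rep_width_ms * log(9) <= t_dep_ms)
    stop("ap_params: repolarization midpoint (apd90_ms - w*ln 9) must lie after the peak")
  structure(list(amplitude_mv = amplitude_mv, t_dep_ms = t_dep_ms,
                 apd90_ms = apd90_ms, rep_width_ms = rep_width_ms,
                 baseline_mv = baseline_mv),
            class = "ap_params")
}

#' @export
print.ap_params <- function(x, ...) {
  cat(sprintf("<ap_params> A=%.3g mV, t_dep=%.3g ms, APD90=%.3g ms, w=%.3g ms\n",
              x$amplitude_mv, x$t_dep_ms, x$apd90_ms, x$rep_width_ms))
  invisible(x)
}

#' Ground-truth landmarks of an AP template
#'
#' Closed-form event times (in ms, relative to AP onset = the 10% upstroke
#' crossing) used by recovery tests: the AP peak, the time of the maximal
#' upstroke slope (where the extracellular field-potential spike peaks), and
#' the maximal upstroke slope itself in mV/ms.
#'
#' @param params [ap_params].
#' @return list with `t_peak_ms`, `t_fp_peak_ms`, `max_slope_mv_ms`,
#'   `apd90_ms`.
#' @export
ap_truth <- function(params) {
  stopifnot(inherits(params, "ap_params"))
  s_tot <- params$t_dep_ms / (1 - .u10)
  list(t_peak_ms = params$t_dep_ms,
       t_fp_peak_ms = (0.5 - .u10) * s_tot,
       max_slope_mv_ms = 1.5 * params$amplitude_mv / s_tot,
       apd90_ms = params$apd90_ms)
}

#' Render one action-potential template
#'
#' Returns an `ap_template` object: a sampled waveform (mV) covering a short
#' zero "foot" before onset plus the full repolarization tail. Index
#' `onset_i` marks t = 0 (the 10% upstroke crossing); `t_pre_ms` is the
#' length of the pre-onset segment.
#'
#' @param params [ap_params].
#' @param fs_hz sampling rate, Hz (>= 1000).
#' @param duration_ms window length after onset; default
#'   `apd90_ms + 7 * rep_width_ms` so the tail decays below 1e-4 of peak.
#' @return object of class `ap_template` with fields `samples_mv`, `fs_hz`,
#'   `t_ms` (sample times relative to onset), `onset_i`, `t_pre_ms`,
#'   `params`.
#' @export
make_ap_template <- function(params, fs_hz = 20000, duration_ms = NULL) {
  stopifnot(inherits(params, "ap_params"), is_scalar_num(fs_hz))
  if (fs_hz < 1000) stop("make_ap_template: fs_hz must be >= 1 kHz")
  w <- params$rep_width_ms
  duration_ms <- duration_ms %||% (params$apd90_ms + 7 * w)
  if (duration_ms < params$apd90_ms + 5 * w)
    stop("make_ap_template: duration_ms must be >= apd90_ms + 5*rep_width_ms")
  s_tot <- params$t_dep_ms / (1 - .u10)   # full smoothstep span
  t_pre <- .u10 * s_tot + 5               # foot + 5 ms zero pad
  dt <- 1000 / fs_hz
  t <- seq(-t_pre, duration_ms, by = dt)
  if (params$amplitude_mv == 0) {
    v <- numeric(length(t))
  } else {
    r <- .smoothstep((t + .u10 * s_tot) / s_tot)
    m <- params$apd90_ms - w * log(9)
    f <- 1 / (1 + exp((t - m) / w))
    v <- params$amplitude_mv * r * f
  }
  structure(list(samples_mv = v, fs_hz = fs_hz, t_ms = t,
                 onset_i = which.min(abs(t)), t_pre_ms = t_pre,
                 params = params),
            class = "ap_template")
}

#' Template value at a time relative to AP onset
#'
#' @param template [make_ap_template] result.
#' @param t_ms time in ms relative to onset (10% upstroke crossing).
#' @return interpolated value in mV.
#' @export
template_value_at <- function(template, t_ms) {
  stopifnot(inherits(template, "ap_template"))
  stats::approx(template$t_ms, template$samples_mv, xout = t_ms)$y
}

#' Drug effect on AP shape parameters
#'
#' Multiplicative modifiers applied per cell. Presets carry the mean percent
#' changes reported for the reference compounds (APD90 -36.9% and
#' depolarization time +15.5% for nifedipine; +32.7% and +46.4% for
#' quinidine); the DMSO vehicle is the identity.
#'
#' @param name label; one of `"nifedipine"`, `"quinidine"`, `"dmso_vehicle"`,
#'   or `"custom"`.
#' @param apd90_factor multiplicative APD90 modifier (> 0).
#' @param tdep_factor multiplicative depolarization-time modifier (> 0).
#' @param cell_sd sd of the per-cell lognormal dispersion of each factor.
#' @return object of class `drug_effect`.
#' @export
drug_effect <- function(name = "custom", apd90_factor = 1, tdep_factor = 1,
                        cell_sd = 0) {
  stopifnot(is_scalar_num(apd90_factor), is_scalar_num(tdep_factor),
            is_scalar_num(cell_sd), cell_sd >= 0)
  if (apd90_factor <= 0 || tdep_factor <= 0)
    stop("drug_effect: factors must be > 0")
  if (name == "dmso_vehicle" && (apd90_factor != 1 || tdep_factor != 1))
    stop("drug_effect: dmso_vehicle must have identity factors")
  structure(list(name = name, apd90_factor = apd90_factor,
                 tdep_factor = tdep_factor, cell_sd = cell_sd),
            class = "drug_effect")
}

#' Built-in drug presets
#'
#' @param cell_sd per-cell lognormal dispersion applied to every preset.
#' @return named list of [drug_effect] objects.
#' @export
drug_presets <- function(cell_sd = 0.05) {
  list(
    nifedipine   = drug_effect("nifedipine", apd90_factor = 0.631,
                               tdep_factor = 1.155, cell_sd = cell_sd),
    quinidine    = drug_effect("quinidine", apd90_factor = 1.327,
                               tdep_factor = 1.464, cell_sd = cell_sd),
    dmso_vehicle = drug_effect("dmso_vehicle", 1, 1, cell_sd = cell_sd)
  )
}

#' Apply a drug effect to AP parameters
#'
#' `apd90` and `t_dep` are multiplied by their factors times per-cell
#' lognormal(0, cell_sd) draws. Draws violating the `ap_params` invariants
#' are rejected and resampled.
#'
#' @param params [ap_params].
#' @param effect [drug_effect].
#' @param seed optional integer seed (per-cell draw).
#' @return modified [ap_params].
#' @export
apply_drug_effect <- function(params, effect, seed = NULL) {
  stopifnot(inherits(params, "ap_params"), inherits(effect, "drug_effect"))
  with_seed(seed, {
    for (try in 1:200) {
      l <- if (effect$cell_sd > 0) exp(stats::rnorm(2, 0, effect$cell_sd)) else c(1, 1)
      apd90 <- params$apd90_ms * effect$apd90_factor * l[1]
      tdep <- params$t_dep_ms * effect$tdep_factor * l[2]
      ok <- apd90 > tdep && (apd90 - params$rep_width_ms * log(9)) > tdep
      if (ok)
        return(ap_params(params$amplitude_mv, tdep, apd90,
                         params$rep_width_ms, params$baseline_mv))
      if (effect$cell_sd == 0) break
    }
    stop("apply_drug_effect: factors make apd90 <= t_dep structurally impossible")
  })
}

#' Schedule spontaneous beats
#'
#' Inter-beat intervals are Gaussian with mean `60/rate_bpm` and coefficient
#' of variation `cv`; intervals shorter than `min_interval_s` are rejected
#' and redrawn so beats never overlap. The first beat is at t = 0.
#'
#' @param rate_bpm mean beat rate, 10-200 bpm.
#' @param cv coefficient of variation of inter-beat intervals.
#' @param duration_s schedule length, s.
#' @param seed optional integer seed.
#' @param min_interval_s hard floor on inter-beat intervals (default 0.5 s;
#'   must exceed the AP duration plus 100 ms for the cultures simulated).
#' @return object of class `beat_schedule` with `onset_times_s`, `rate_bpm`,
#'   `cv`, `seed`.
#' @export
schedule_beats <- function(rate_bpm = 30, cv = 0.05, duration_s = 60,
                           seed = NULL, min_interval_s = 0.5) {
  stopifnot(is_scalar_num(rate_bpm), is_scalar_num(cv), is_scalar_num(duration_s))
  if (rate_bpm < 10 || rate_bpm > 200)
    stop("schedule_beats: rate_bpm must be in [10, 200]")
  if (duration_s <= 0) stop("schedule_beats: duration_s must be > 0")
  mu <- 60 / rate_bpm
  if (mu <= min_interval_s && cv == 0)
    stop("schedule_beats: mean interval below min_interval_s")
  onsets <- with_seed(seed, {
    t <- 0
    out <- numeric(0)
    while (t < duration_s) {
      out <- c(out, t)
      if (cv == 0) {
        iv <- mu
      } else {
        repeat {
          iv <- stats::rnorm(1, mu, cv * mu)
          if (iv > min_interval_s) break
        }
      }
      t <- t + iv
    }
    out
  })
  structure(list(onset_times_s = onsets, rate_bpm = rate_bpm, cv = cv,
                 seed = seed),
            class = "beat_schedule")
}

#' Render the membrane-voltage ground truth of one cell
#'
#' Superposition of the AP template at every scheduled onset; the trace is 0
#' between beats (resting level is added downstream).
#'
#' @param params [ap_params].
#' @param schedule [beat_schedule].
#' @param fs_hz sampling rate, Hz.
#' @param duration_s trace length, s.
#' @return numeric vector of length `round(duration_s * fs_hz)`, mV.
#' @export
render_membrane_trace <- function(params, schedule, fs_hz = 20000,
                                  duration_s = 60) {
  stopifnot(inherits(params, "ap_params"), inherits(schedule, "beat_schedule"))
  n <- round(duration_s * fs_hz)
  v <- numeric(n)
  if (params$amplitude_mv == 0 || length(schedule$onset_times_s) == 0)
    return(v)
  tmpl <- make_ap_template(params, fs_hz)
  w <- tmpl$samples_mv
  pre_n <- tmpl$onset_i - 1L
  for (t0 in schedule$onset_times_s) {
    i0 <- round(t0 * fs_hz) + 1L - pre_n   # index of first template sample
    src <- seq_along(w)
    keep <- (i0 + src - 1L) >= 1L & (i0 + src - 1L) <= n
    if (!any(keep)) next
    idx <- i0 + src[keep] - 1L
    v[idx] <- v[idx] + w[keep]
  }
  v
}
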