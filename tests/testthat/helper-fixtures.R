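# Shared fixtures, all built in code.

# Hann (raised-cosine) pulse: peak `amp_uv`, full width at half maximum
# exactly `width_ms * 2` / 2 = width of the window / 2. Returns a
# beat_snippet-like object with `pad_ms` of zero baseline on both sides.
hann_snippet <- function(amp_uv, fwhm_ms, fs_hz = 2000, pad_ms = 60) {
  T_ms <- 2 * fwhm_ms
  n_pulse <- round(T_ms / 1000 * fs_hz) + 1L
  tt <- seq(0, T_ms, length.out = n_pulse)
  pulse <- amp_uv * 0.5 * (1 - cos(2 * pi * tt / T_ms))
  pad <- numeric(round(pad_ms / 1000 * fs_hz))
  x <- c(pad, pulse, pad)
  structure(list(samples_uv = x, t_peak_s = 0, peak_i = which.max(x),
                 fs_hz = fs_hz, electrode_id = 0L, beat_index = 1L,
                 drift_uv_per_s = 0, baseline_uv = 0, label = NA_character_),
            class = "beat_snippet")
}

# minimal snippet constructor for selection-logic tests
fake_snippet <- function(samples, t_peak_s, beat_index, fs_hz = 2000,
                         label = "intracellular_like", drift = 0) {
  structure(list(samples_uv = samples, t_peak_s = t_peak_s,
                 peak_i = which.max(samples), fs_hz = fs_hz,
                 electrode_id = 0L, beat_index = beat_index,
                 drift_uv_per_s = drift, baseline_uv = 0, label = label),
            class = "beat_snippet")
}

# one simulated channel: porated (or not) cardiomyocyte on an electrode
sim_channel <- function(g0 = 0.27, poration_at_s = 0, noise_sd_uv = 10,
                        offset_mv = 10, fs_hz = 1000, duration_s = 20,
                        params = ap_params(), seed = 7, rate_bpm = 30,
                        cv = 0.05) {
  sch <- schedule_beats(rate_bpm, cv, duration_s, seed = seed)
  st <- electrode_state(0L, noise_sd_uv = noise_sd_uv)
  ev <- if (is.null(g0)) NULL else
    data.frame(electrode_id = 0L, t_end_s = poration_at_s, success = g0 > 0,
               g0_realized = g0, offset_mv = offset_mv, offset_tau_s = 2)
  v <- render_membrane_trace(params, sch, fs_hz, duration_s)
  list(trace = couple_to_electrode(v, st, ev, fs_hz, seed = seed + 1),
       schedule = sch, state = st, events = ev, membrane = v)
}

# brute-force two-sided Mann-Whitney p by enumeration over all C(n+m, n)
# group assignments of the pooled observed values (midranks throughout)
mwu_enum_oracle <- function(x, y) {
  n <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - n * (n + 1) / 2
  u_obs <- u_of(seq_len(n))
  us <- apply(utils::combn(length(pooled), n), 2, u_of)
  lo <- mean(us <= u_obs + 1e-9)
  hi <- mean(us >= u_obs - 1e-9)
  min(1, 2 * min(lo, hi))
}
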