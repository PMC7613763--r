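# Cell-electrode interface model: extracellular coupling, stochastic
# electroporation outcome, pore resealing, amplifier offset/saturation,
# noise. The recorded trace is a linear mix
#   y(t) = 1000 * g(t) * k_ic * V(t) + k_ec * dV/dt + offset(t) + noise,
# clipped at +/- v_sat: with pore coupling g = 0 only the derivative term
# remains (extracellular field potential); after a successful poration g
# jumps to g0 and decays exponentially as the membrane reseals.

#' Simulator constants of the electrode interface
#'
#' All values are configurable; defaults are chosen so that (i) extracellular
#' field-potential peaks are ~300 uV, (ii) the maximal recordable
#' intracellular-like amplitude is ~50 mV, and (iii) the electroporation
#' success model reproduces the qualitative protocol orderings (more charge,
#' less unit loading and smaller electrodes all increase yield) with a yield
#' around 80% at the optimized reference protocol (1 Vpp, 200 us phase,
#' 1 ms IPI, 25,000 pulses, 12.6 um2 electrodes).
#'
#' @param a0,a1,a2 logistic coefficients of the success model
#'   `p = plogis(a0 + a1*log1p(Q/q_ref) + a2*seal_quality)`.
#' @param c_load slew-rate derating per extra electrode on a stimulation
#'   unit: `V_eff = vpp / (1 + c_load*(n_on_unit - 1))`.
#' @param g_max,gamma pore-coupling ceiling: on success
#'   `g0 = g_max * (Q/q_ref)^gamma` (lognormal jitter `g_jitter_sd`).
#' @param q_ref reference charge proxy: Q of the optimized protocol on a
#'   12.6 um2 electrode (V*s/um2).
#' @param g_jitter_sd lognormal sd of per-electrode g0 jitter.
#' @param v_sat_uv amplifier saturation, uV.
#' @param n_units number of on-chip stimulation units.
#' @param units_local number of units reachable by a spatially clustered
#'   selection (the switch matrix routes nearby electrodes to few units).
#' @param offset_mv,offset_tau_s post-stimulation amplifier offset scale and
#'   settling time constant.
#' @return named list of constants.
#' @export
interface_constants <- function(a0 = -6, a1 = 8.8, a2 = 3, c_load = 0.05,
                                g_max = 0.3, gamma = 0.5,
                                q_ref = 1 * 200e-6 * 25000 / 12.6,
                                g_jitter_sd = 0.3, v_sat_uv = 50000,
                                n_units = 32, units_local = 8,
                                offset_mv = 10, offset_tau_s = 2) {
  as.list(environment())
}

#' Per-electrode coupling state
#'
#' @param electrode_id integer index (0-based).
#' @param x_um,y_um electrode position, um.
#' @param seal_quality dimensionless seal quality in (0, 1].
#' @param k_ec extracellular gain, uV per (mV/ms) of membrane slope.
#' @param k_ic intracellular coupling ceiling (<= 1).
#' @param tau_reseal_s pore resealing time constant, s.
#' @param noise_sd_uv white-noise sd, uV.
#' @return object of class `electrode_state`.
#' @export
electrode_state <- function(electrode_id, x_um = 0, y_um = 0,
                            seal_quality = 0.75, k_ec = 25, k_ic = 0.5,
                            tau_reseal_s = 900, noise_sd_uv = 10) {
  stopifnot(is_scalar_num(seal_quality), seal_quality > 0, seal_quality <= 1,
            is_scalar_num(tau_reseal_s), tau_reseal_s > 0,
            is_scalar_num(noise_sd_uv), noise_sd_uv >= 0,
            is_scalar_num(k_ic), k_ic <= 1)
  structure(list(electrode_id = as.integer(electrode_id), x_um = x_um,
                 y_um = y_um, seal_quality = seal_quality, k_ec = k_ec,
                 k_ic = k_ic, tau_reseal_s = tau_reseal_s,
                 noise_sd_uv = noise_sd_uv),
            class = "electrode_state")
}

#' Generate a set of electrode states on a grid
#'
#' Positions follow a 17.5 um pitch grid (HD-MEA-like); seal qualities are
#' uniform in `seal_range`.
#'
#' @param n number of electrodes.
#' @param seed integer seed.
#' @param pitch_um electrode pitch.
#' @param seal_range range of seal qualities.
#' @param ... further arguments passed to [electrode_state].
#' @return list of `electrode_state` objects.
#' @export
make_electrode_states <- function(n, seed = NULL, pitch_um = 17.5,
                                  seal_range = c(0.5, 1), ...) {
  ncol_grid <- ceiling(sqrt(n))
  seals <- with_seed(seed, stats::runif(n, seal_range[1], seal_range[2]))
  lapply(seq_len(n) - 1L, function(i) {
    electrode_state(i,
                    x_um = (i %% ncol_grid) * pitch_um,
                    y_um = (i %/% ncol_grid) * pitch_um,
                    seal_quality = seals[i + 1L], ...)
  })
}

#' Stimulation pulse-train protocol
#'
#' Rectangular biphasic pulse trains: two phases of `phase_us` each per
#' pulse, one interpulse interval per cycle.
#'
#' @param vpp_v peak-to-peak amplitude, V (0.5-2.5).
#' @param phase_us phase duration, us (50-1000).
#' @param ipi_ms interpulse interval, ms.
#' @param n_pulses pulse count (>= 0; 0 allowed for degenerate protocols).
#' @param electrode_ids electrodes receiving the train (0-based).
#' @param selection_strategy `"random"` or `"high_amp"` (spatially clustered
#'   selection of high-amplitude electrodes).
#' @param electrode_area_um2 electrode area, um2.
#' @return object of class `poration_protocol`.
#' @export
poration_protocol <- function(vpp_v = 1, phase_us = 200, ipi_ms = 1,
                              n_pulses = 25000, electrode_ids = 0:199,
                              selection_strategy = c("random", "high_amp"),
                              electrode_area_um2 = 12.6) {
  selection_strategy <- match.arg(selection_strategy)
  stopifnot(is_scalar_num(vpp_v), is_scalar_num(phase_us),
            is_scalar_num(ipi_ms), is_scalar_num(n_pulses))
  if (vpp_v < 0.5 || vpp_v > 2.5) stop("poration_protocol: vpp_v outside [0.5, 2.5] V")
  if (phase_us < 50 || phase_us > 1000)
    stop("poration_protocol: phase_us outside [50, 1000] us")
  if (n_pulses < 0) stop("poration_protocol: n_pulses must be >= 0")
  if (electrode_area_um2 <= 0) stop("poration_protocol: electrode_area_um2 must be > 0")
  structure(list(vpp_v = vpp_v, phase_us = phase_us, ipi_ms = ipi_ms,
                 n_pulses = n_pulses,
                 electrode_ids = as.integer(electrode_ids),
                 selection_strategy = selection_strategy,
                 electrode_area_um2 = electrode_area_um2),
            class = "poration_protocol")
}

#' Assign protocol electrodes to stimulation units
#'
#' `"random"` selections are shuffled and distributed round-robin over all
#' `n_units` units (balanced loading). `"high_amp"` selections are spatially
#' clustered, so only `units_local` nearby units are reachable: electrodes
#' are sorted by position and chunked onto those units, concentrating the
#' capacitive load.
#'
#' @param protocol [poration_protocol].
#' @param states list of [electrode_state] covering every protocol electrode.
#' @param constants [interface_constants].
#' @param seed integer seed (shuffle order for `"random"`).
#' @return integer vector of unit indices, one per protocol electrode.
#' @export
assign_stim_units <- function(protocol, states, constants = interface_constants(),
                              seed = NULL) {
  ids <- protocol$electrode_ids
  st <- .states_by_id(states, ids, "assign_stim_units")
  n <- length(ids)
  if (protocol$selection_strategy == "random") {
    ord <- with_seed(seed, sample.int(n))
    units <- integer(n)
    units[ord] <- ((seq_len(n) - 1L) %% constants$n_units) + 1L
  } else {
    xy <- vapply(st, function(s) c(s$x_um, s$y_um), numeric(2))
    ord <- order(xy[1, ], xy[2, ])
    chunk <- ceiling(n / constants$units_local)
    units <- integer(n)
    units[ord] <- ((seq_len(n) - 1L) %/% chunk) + 1L
  }
  units
}

.states_by_id <- function(states, ids, ctx) {
  sid <- vapply(states, function(s) s$electrode_id, integer(1))
  pos <- match(ids, sid)
  if (anyNA(pos))
    stop(sprintf("%s: no electrode_state for electrode(s) %s", ctx,
                 paste(ids[is.na(pos)], collapse = ", ")))
  states[pos]
}

#' Simulate the outcome of one electroporation train
#'
#' Effective amplitude is derated by unit loading,
#' `V_eff = vpp / (1 + c_load*(n_on_unit - 1))`; the charge proxy is
#' `Q = V_eff * t_phase * n_pulses / area`; success probability is
#' `plogis(a0 + a1*log1p(Q/q_ref) + a2*seal_quality)`; on success the
#' initial pore coupling is `g0 = min(1, g_max * (Q/q_ref)^gamma)` with
#' lognormal jitter.
#'
#' @param protocol [poration_protocol].
#' @param states list of [electrode_state].
#' @param routing optional unit assignment from [assign_stim_units]
#'   (computed if `NULL`).
#' @param t_end_s poration end time within the recording, s.
#' @param seed integer seed.
#' @param constants [interface_constants].
#' @return data.frame of poration events: `electrode_id`, `t_end_s`,
#'   `success`, `g0_realized`, `offset_mv`, `offset_tau_s`, `unit`,
#'   `p_success`, `q_charge`.
#' @export
simulate_poration_outcome <- function(protocol, states, routing = NULL,
                                      t_end_s = 0, seed = NULL,
                                      constants = interface_constants()) {
  stopifnot(inherits(protocol, "poration_protocol"))
  ids <- protocol$electrode_ids
  st <- .states_by_id(states, ids, "simulate_poration_outcome")
  if (is.null(routing))
    routing <- assign_stim_units(protocol, states, constants,
                                 seed = if (is.null(seed)) NULL else derive_seed(seed, 1))
  stopifnot(length(routing) == length(ids))
  load <- tabulate(routing, nbins = max(routing))[routing]
  v_eff <- protocol$vpp_v / (1 + constants$c_load * (load - 1))
  q <- v_eff * protocol$phase_us * 1e-6 * protocol$n_pulses /
    protocol$electrode_area_um2
  seal <- vapply(st, function(s) s$seal_quality, numeric(1))
  p <- stats::plogis(constants$a0 + constants$a1 * log1p(q / constants$q_ref) +
                       constants$a2 * seal)
  with_seed(seed, {
    success <- stats::runif(length(ids)) < p
    jit <- exp(stats::rnorm(length(ids), 0, constants$g_jitter_sd))
    g0 <- ifelse(success,
                 pmin(1, constants$g_max * (q / constants$q_ref)^constants$gamma * jit),
                 0)
    off <- constants$offset_mv * stats::runif(length(ids), 0.5, 1.5)
    data.frame(electrode_id = ids, t_end_s = t_end_s, success = success,
               g0_realized = g0, offset_mv = off,
               offset_tau_s = constants$offset_tau_s, unit = routing,
               p_success = p, q_charge = q)
  })
}

#' Pore-coupling fraction over time
#'
#' Sum over past successful porations of `g0 * exp(-(t - t_end)/tau)`,
#' clipped to <= 1; zero before the first event.
#'
#' @param t_s time(s) at which to evaluate, s.
#' @param events data.frame of poration events for one electrode
#'   (columns `t_end_s`, `success`, `g0_realized`).
#' @param tau_reseal_s resealing time constant, s.
#' @return numeric vector, coupling in `[0, 1]`.
#' @export
pore_coupling <- function(t_s, events, tau_reseal_s = 900) {
  g <- numeric(length(t_s))
  if (is.null(events) || nrow(events) == 0) return(g)
  ev <- events[events$success, , drop = FALSE]
  for (k in seq_len(nrow(ev))) {
    dt <- t_s - ev$t_end_s[k]
    on <- dt >= 0
    g[on] <- g[on] + ev$g0_realized[k] * exp(-dt[on] / tau_reseal_s)
  }
  pmin(g, 1)
}

#' Couple a membrane trace to one electrode
#'
#' @param membrane_mv membrane voltage trace, mV.
#' @param state [electrode_state].
#' @param events poration events for this electrode (may be `NULL`).
#' @param fs_hz sampling rate of `membrane_mv`, Hz.
#' @param t0_s time of the first sample, s.
#' @param constants [interface_constants].
#' @param seed integer seed for the noise stream (`NULL` = noiseless noise
#'   stream from the current RNG).
#' @return recorded trace in uV, clipped at `+/- v_sat_uv`.
#' @export
couple_to_electrode <- function(membrane_mv, state, events = NULL,
                                fs_hz = 20000, t0_s = 0,
                                constants = interface_constants(),
                                seed = NULL) {
  stopifnot(inherits(state, "electrode_state"), is_scalar_num(fs_hz))
  n <- length(membrane_mv)
  t <- t0_s + (seq_len(n) - 1) / fs_hz
  g <- pore_coupling(t, events, state$tau_reseal_s)
  # central-difference derivative, mV/ms
  dv <- numeric(n)
  if (n >= 3) {
    dt_ms <- 1000 / fs_hz
    dv[2:(n - 1)] <- (membrane_mv[3:n] - membrane_mv[1:(n - 2)]) / (2 * dt_ms)
    dv[1] <- (membrane_mv[2] - membrane_mv[1]) / dt_ms
    dv[n] <- (membrane_mv[n] - membrane_mv[n - 1]) / dt_ms
  }
  offset <- numeric(n)
  if (!is.null(events) && nrow(events) > 0) {
    for (k in seq_len(nrow(events))) {
      dt <- t - events$t_end_s[k]
      on <- dt >= 0
      offset[on] <- offset[on] +
        1000 * events$offset_mv[k] * exp(-dt[on] / events$offset_tau_s[k])
    }
  }
  noise <- if (state$noise_sd_uv > 0)
    with_seed(seed, stats::rnorm(n, 0, state$noise_sd_uv)) else numeric(n)
  y <- 1000 * g * state$k_ic * membrane_mv + state$k_ec * dv + offset + noise
  pmin(constants$v_sat_uv, pmax(-constants$v_sat_uv, y))
}

#' Culture model bundle
#'
#' @param params [ap_params] of the (synchronized) culture.
#' @param rate_bpm,cv beat statistics (see [schedule_beats]).
#' @return object of class `culture_model`.
#' @export
culture_model <- function(params = ap_params(), rate_bpm = 30, cv = 0.05) {
  stopifnot(inherits(params, "ap_params"))
  structure(list(params = params, rate_bpm = rate_bpm, cv = cv),
            class = "culture_model")
}

#' Render the recorded trace of a single channel
#'
#' Convenience wrapper used both by [assemble_recording] and by streaming
#' study drivers: membrane ground truth from a shared beat schedule, coupled
#' through one electrode's state and poration events.
#'
#' @param culture [culture_model] (or one with per-cell `params` substituted).
#' @param state [electrode_state].
#' @param schedule shared [beat_schedule].
#' @param events poration events for this electrode (may be `NULL`).
#' @param fs_hz sampling rate, Hz.
#' @param duration_s trace length, s.
#' @param constants [interface_constants].
#' @param seed noise seed.
#' @param params optional per-cell [ap_params] override.
#' @return numeric trace, uV.
#' @export
render_channel <- function(culture, state, schedule, events = NULL,
                           fs_hz = 20000, duration_s = 60,
                           constants = interface_constants(), seed = NULL,
                           params = NULL) {
  v <- render_membrane_trace(params %||% culture$params, schedule, fs_hz,
                             duration_s)
  couple_to_electrode(v, state, events, fs_hz, t0_s = 0,
                      constants = constants, seed = seed)
}

#' Assemble a full multichannel recording
#'
#' One shared beat schedule drives all electrodes (synchronous culture).
#' Refuses to build matrices larger than `max_elements` (use the streaming
#' drivers in that regime).
#'
#' @param culture [culture_model].
#' @param states list of [electrode_state].
#' @param protocol [poration_protocol] (or `NULL` for a passive recording).
#' @param poration_t_end_s numeric vector of poration end times (one
#'   simulated outcome per time); empty for no porations.
#' @param duration_s recording length, s.
#' @param fs_hz sampling rate, Hz.
#' @param seed integer master seed.
#' @param constants [interface_constants].
#' @param max_elements memory guard on `channels * samples`.
#' @return object of class `mea_recording`: `signals` (channels x samples
#'   matrix, uV), `fs_hz`, `t0_s`, `channel_meta` (data.frame),
#'   `poration_events` (data.frame), `protocol`, `extra` (list).
#' @export
assemble_recording <- function(culture, states, protocol = NULL,
                               poration_t_end_s = numeric(0),
                               duration_s = 60, fs_hz = 20000, seed = 1,
                               constants = interface_constants(),
                               max_elements = 1.5e8) {
  n_ch <- length(states)
  n_samp <- round(duration_s * fs_hz)
  if (as.numeric(n_ch) * n_samp > max_elements)
    stop(sprintf("assemble_recording: %d x %d exceeds max_elements=%g; use streaming drivers",
                 n_ch, n_samp, max_elements))
  if (any(poration_t_end_s < 0 | poration_t_end_s > duration_s))
    stop("assemble_recording: poration times outside recording")
  schedule <- schedule_beats(culture$rate_bpm, culture$cv, duration_s,
                             seed = derive_seed(seed, 0))
  events <- NULL
  if (!is.null(protocol) && length(poration_t_end_s) > 0) {
    evs <- lapply(seq_along(poration_t_end_s), function(r) {
      simulate_poration_outcome(protocol, states, t_end_s = poration_t_end_s[r],
                                seed = derive_seed(seed, r),
                                constants = constants)
    })
    events <- do.call(rbind, evs)
  }
  signals <- matrix(0, n_ch, n_samp)
  for (i in seq_len(n_ch)) {
    st <- states[[i]]
    ev <- if (is.null(events)) NULL
          else events[events$electrode_id == st$electrode_id, , drop = FALSE]
    signals[i, ] <- render_channel(culture, st, schedule, ev, fs_hz,
                                   duration_s, constants,
                                   seed = derive_seed(seed, 1000L + i))
  }
  meta <- do.call(rbind, lapply(states, function(s)
    data.frame(electrode_id = s$electrode_id, x_um = s$x_um, y_um = s$y_um,
               seal_quality = s$seal_quality, k_ec = s$k_ec, k_ic = s$k_ic,
               tau_reseal_s = s$tau_reseal_s, noise_sd_uv = s$noise_sd_uv)))
  structure(list(signals = signals, fs_hz = fs_hz, t0_s = 0,
                 channel_meta = meta,
                 poration_events = events %||% .empty_events(),
                 protocol = protocol, extra = list(),
                 truth = list(schedule = schedule, params = culture$params)),
            class = "mea_recording")
}

.empty_events <- function() {
  data.frame(electrode_id = integer(0), t_end_s = numeric(0),
             success = logical(0), g0_realized = numeric(0),
             offset_mv = numeric(0), offset_tau_s = numeric(0),
             unit = integer(0), p_success = numeric(0), q_charge = numeric(0))
}

#' @export
print.mea_recording <- function(x, ...) {
  cat(sprintf("<mea_recording> %d channels x %d samples @ %g Hz (%.1f s), %d poration events\n",
              nrow(x$signals), ncol(x$signals), x$fs_hz,
              ncol(x$signals) / x$fs_hz, nrow(x$poration_events)))
  invisible(x)
}
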