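# High-level study drivers. These stream channel by channel (no full
# channels x samples matrix), so electrode counts of several hundred stay
# within desktop memory even at 20 kHz.

# per-electrode cell parameters: multiplicative lognormal dispersion around
# the culture template (cardiomyocyte cultures show ~10% cell-to-cell spread
# in AP duration and upstroke timing)
.draw_cell_params <- function(base, n, seed, apd90_cv = 0.08, tdep_cv = 0.1,
                              amp_cv = 0.1) {
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      for (try in 1:100) {
        p <- try(ap_params(base$amplitude_mv * exp(stats::rnorm(1, 0, amp_cv)),
                           base$t_dep_ms * exp(stats::rnorm(1, 0, tdep_cv)),
                           base$apd90_ms * exp(stats::rnorm(1, 0, apd90_cv)),
                           base$rep_width_ms), silent = TRUE)
        if (!inherits(p, "try-error")) return(p)
      }
      base
    })
  })
}

#' Simulate one electroporation run and analyze its yield
#'
#' Porates every protocol electrode at `t_end_s = 0` (the recording starts
#' when the stimulation units disconnect), renders each channel, runs the
#' waveform pipeline and computes the electroporation yield.
#'
#' @param protocol [poration_protocol].
#' @param states list of [electrode_state] (defaults to a fresh set covering
#'   the protocol electrodes).
#' @param seed master integer seed.
#' @param fs_hz sampling rate (reduced default for desk-scale studies).
#' @param duration_s recording length after poration end.
#' @param culture [culture_model].
#' @param constants [interface_constants].
#' @param config [classifier_config].
#' @return list with `features`, `events`, `yield` (see [poration_yield])
#'   and `exclusions`.
#' @export
run_yield_experiment <- function(protocol, states = NULL, seed = 1,
                                 fs_hz = 1000, duration_s = 20,
                                 culture = culture_model(),
                                 constants = interface_constants(),
                                 config = classifier_config()) {
  n <- length(protocol$electrode_ids)
  if (is.null(states))
    states <- make_electrode_states(n, seed = derive_seed(seed, 101))
  events <- simulate_poration_outcome(protocol, states, t_end_s = 0,
                                      seed = derive_seed(seed, 102),
                                      constants = constants)
  schedule <- schedule_beats(culture$rate_bpm, culture$cv, duration_s,
                             seed = derive_seed(seed, 103))
  cells <- .draw_cell_params(culture$params, n, derive_seed(seed, 104))
  st <- .states_by_id(states, protocol$electrode_ids, "run_yield_experiment")
  rows <- vector("list", n)
  excl <- list()
  for (i in seq_len(n)) {
    ev <- events[i, , drop = FALSE]
    trace <- render_channel(culture, st[[i]], schedule, ev, fs_hz, duration_s,
                            constants, seed = derive_seed(seed, 200L + i),
                            params = cells[[i]])
    res <- analyze_channel(trace, fs_hz, st[[i]]$electrode_id,
                           poration_end_s = 0, config = config)
    rows[[i]] <- res$row
    if (!is.null(res$exclusion))
      excl[[length(excl) + 1L]] <- data.frame(
        electrode_id = st[[i]]$electrode_id, reason = res$exclusion)
  }
  features <- do.call(rbind, rows)
  list(features = features, events = events,
       yield = poration_yield(features, events, config$yield_min_amp_mv),
       exclusions = if (length(excl)) do.call(rbind, excl) else NULL)
}

#' Simulate repeated electroporations on the same culture
#'
#' `k_repeats` porations of the same electrodes at `interval_s` spacing.
#' Each repeat is recorded for `duration_s` with the poration at
#' `poration_at_s` into the recording, so extracellular (FP) beats before
#' and intracellular-like beats after each poration are both captured.
#' Residual pore coupling from earlier repeats (interval >> reseal time
#' constant at the defaults) is negligible and each repeat is rendered
#' independently.
#'
#' @param n_electrodes electrodes porated each repeat.
#' @param k_repeats number of repeats (default 6).
#' @param interval_s spacing between repeats (default 3600 s).
#' @param seed master seed.
#' @param fs_hz,duration_s,poration_at_s recording geometry.
#' @param protocol [poration_protocol] template (electrode set is replaced).
#' @param culture,constants,config model settings.
#' @return list with `features` (rows for all repeats), `yield`,
#'   `summary` ([repeat_summary]) and `events`.
#' @export
run_repeat_study <- function(n_electrodes = 60, k_repeats = 6,
                             interval_s = 3600, seed = 1, fs_hz = 1000,
                             duration_s = 30, poration_at_s = 10,
                             protocol = NULL, culture = culture_model(),
                             constants = interface_constants(),
                             config = classifier_config()) {
  ids <- seq_len(n_electrodes) - 1L
  if (is.null(protocol)) {
    protocol <- poration_protocol(electrode_ids = ids)
  } else {
    protocol$electrode_ids <- ids
  }
  states <- make_electrode_states(n_electrodes, seed = derive_seed(seed, 1))
  cells <- .draw_cell_params(culture$params, n_electrodes, derive_seed(seed, 2))
  all_feat <- list()
  all_ev <- list()
  for (r in seq_len(k_repeats)) {
    events <- simulate_poration_outcome(protocol, states,
                                        t_end_s = poration_at_s,
                                        seed = derive_seed(seed, 10L + r),
                                        constants = constants)
    schedule <- schedule_beats(culture$rate_bpm, culture$cv, duration_s,
                               seed = derive_seed(seed, 100L + r))
    rows <- vector("list", n_electrodes)
    for (i in seq_len(n_electrodes)) {
      trace <- render_channel(culture, states[[i]], schedule,
                              events[i, , drop = FALSE], fs_hz, duration_s,
                              constants,
                              seed = derive_seed(seed, 1000L * r + i),
                              params = cells[[i]])
      res <- analyze_channel(trace, fs_hz, states[[i]]$electrode_id,
                             poration_end_s = poration_at_s, config = config,
                             repeat_idx = r)
      rows[[i]] <- res$row
    }
    all_feat[[r]] <- do.call(rbind, rows)
    events$t_end_s <- (r - 1) * interval_s + poration_at_s
    all_ev[[r]] <- events
  }
  features <- do.call(rbind, all_feat)
  events <- do.call(rbind, all_ev)
  list(features = features,
       yield = poration_yield(features, events, config$yield_min_amp_mv),
       summary = repeat_summary(features), events = events)
}

#' Simulate a drug experiment (three baselines + postdose) and report it
#'
#' Emulates the pharmacology workflow: three baseline measurements, drug
#' administration, one postdose measurement, all on the same matched
#' electrodes. Each phase porates at `t_end_s = 0` and records
#' `duration_s`. Poration success is forced (the study analyses electrodes
#' that do record intracellular-like signals, as the published cohorts do);
#' coupling strength, offsets and noise remain stochastic per electrode and
#' phase. The drug preset multiplies each cell's APD90 and depolarization
#' time by its factors with per-cell lognormal dispersion `cell_sd`.
#'
#' @param n_electrodes cohort size (default 150).
#' @param drug preset name (see [drug_presets]) or a [drug_effect].
#' @param cell_sd per-cell dispersion of the drug factors.
#' @param seed master seed.
#' @param fs_hz,duration_s recording geometry.
#' @param culture,constants,config model settings.
#' @return list with `phases` (named list of feature tables: ctrl1, ctrl2,
#'   ctrl3, postdose) and `report` ([drug_report]).
#' @export
run_drug_study <- function(n_electrodes = 150, drug = "nifedipine",
                           cell_sd = 0.05, seed = 1, fs_hz = 1000,
                           duration_s = 25, culture = culture_model(),
                           constants = interface_constants(),
                           config = classifier_config()) {
  effect <- if (inherits(drug, "drug_effect")) drug
            else {
              pres <- drug_presets(cell_sd)[[drug]]
              if (is.null(pres)) stop("run_drug_study: unknown drug preset: ", drug)
              pres
            }
  states <- make_electrode_states(n_electrodes, seed = derive_seed(seed, 1),
                                  seal_range = c(0.8, 1))
  cells <- .draw_cell_params(culture$params, n_electrodes, derive_seed(seed, 2))
  phases <- c("baseline1", "baseline2", "baseline3", "postdose")
  feat <- vector("list", length(phases))
  names(feat) <- c("ctrl1", "ctrl2", "ctrl3", "postdose")
  for (ph in seq_along(phases)) {
    dosed <- phases[ph] == "postdose"
    schedule <- schedule_beats(culture$rate_bpm, culture$cv, duration_s,
                               seed = derive_seed(seed, 10L + ph))
    g0 <- with_seed(derive_seed(seed, 20L + ph),
                    pmin(1, 0.27 * exp(stats::rnorm(n_electrodes, 0,
                                                    constants$g_jitter_sd))))
    off <- with_seed(derive_seed(seed, 30L + ph),
                     constants$offset_mv * stats::runif(n_electrodes, 0.5, 1.5))
    rows <- vector("list", n_electrodes)
    for (i in seq_len(n_electrodes)) {
      p <- cells[[i]]
      if (dosed)
        p <- apply_drug_effect(p, effect, seed = derive_seed(seed, 40L, i))
      ev <- data.frame(electrode_id = states[[i]]$electrode_id, t_end_s = 0,
                       success = TRUE, g0_realized = g0[i],
                       offset_mv = off[i],
                       offset_tau_s = constants$offset_tau_s)
      trace <- render_channel(culture, states[[i]], schedule, ev, fs_hz,
                              duration_s, constants,
                              seed = derive_seed(seed, 1000L * ph + i),
                              params = p)
      rows[[i]] <- analyze_channel(trace, fs_hz, states[[i]]$electrode_id,
                                   poration_end_s = 0, config = config,
                                   repeat_idx = ph, phase = phases[ph])$row
    }
    feat[[ph]] <- do.call(rbind, rows)
  }
  list(phases = feat,
       report = drug_report(feat[c("ctrl1", "ctrl2", "ctrl3")],
                            feat$postdose))
}
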