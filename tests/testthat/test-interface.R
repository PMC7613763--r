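# electrode-interface module: poration outcome model, pore coupling,
# electrode coupling, recording assembly

test_that("poration outcome is deterministic and monotone in dose", {
  st <- make_electrode_states(50, seed = 1)
  pr <- poration_protocol(electrode_ids = 0:49)
  e1 <- simulate_poration_outcome(pr, st, seed = 4)
  e2 <- simulate_poration_outcome(pr, st, seed = 4)
  expect_identical(e1, e2)
  p_of <- function(pr) mean(simulate_poration_outcome(pr, st, seed = 4)$p_success)
  base <- p_of(pr)
  expect_gt(p_of(poration_protocol(vpp_v = 1.4, electrode_ids = 0:49)), base)
  expect_gt(p_of(poration_protocol(phase_us = 400, electrode_ids = 0:49)), base)
  expect_lt(p_of(poration_protocol(n_pulses = 12500, electrode_ids = 0:49)), base)
  expect_lt(p_of(poration_protocol(electrode_ids = 0:49,
                                   electrode_area_um2 = 50.7)), base)
})

test_that("zero-pulse trains porate (almost) nothing", {
  st <- make_electrode_states(50, seed = 1)
  pr0 <- poration_protocol(n_pulses = 0, electrode_ids = 0:49)
  ev <- simulate_poration_outcome(pr0, st, seed = 4)
  expect_true(all(ev$p_success < 0.05))
})

test_that("unit loading lowers the success probability", {
  # two identical electrodes, one alone on its unit and one sharing with 15
  st <- lapply(0:16, function(i) electrode_state(i, seal_quality = 0.8))
  pr <- poration_protocol(electrode_ids = 0:16)
  routing <- c(1L, rep(2L, 16))
  ev <- simulate_poration_outcome(pr, st, routing = routing, seed = 2)
  expect_gt(ev$p_success[1], ev$p_success[2])
  expect_true(all(ev$p_success[-1] == ev$p_success[2]))
})

test_that("random routing balances load; clustered routing concentrates it", {
  st <- make_electrode_states(200, seed = 5)
  pr_r <- poration_protocol(electrode_ids = 0:199)
  pr_h <- poration_protocol(electrode_ids = 0:199,
                            selection_strategy = "high_amp")
  co <- interface_constants()
  u_r <- assign_stim_units(pr_r, st, co, seed = 1)
  u_h <- assign_stim_units(pr_h, st, co, seed = 1)
  expect_true(max(tabulate(u_r)) <= ceiling(200 / co$n_units))
  expect_lte(length(unique(u_h)), co$units_local)
  expect_error(simulate_poration_outcome(pr_r, st[1:100], seed = 1),
               "no electrode_state")
})

test_that("pore coupling decays exponentially and superposes", {
  expect_equal(pore_coupling(c(0, 100), NULL), c(0, 0))
  ev <- data.frame(t_end_s = 0, success = TRUE, g0_realized = 0.5)
  expect_equal(pore_coupling(600, ev, tau_reseal_s = 600), 0.5 / exp(1),
               tolerance = 1e-12)
  ev2 <- rbind(ev, data.frame(t_end_s = 300, success = TRUE, g0_realized = 0.3))
  t <- seq(300, 1000, by = 50)
  expect_true(all(pore_coupling(t, ev2, 600) >=
                    pore_coupling(t, ev2[2, ], 600)))
  # clipping at 1
  ev3 <- data.frame(t_end_s = 0, success = TRUE, g0_realized = 5)
  expect_equal(pore_coupling(1, ev3, 600), 1)
})

test_that("electrode coupling mixes AP, derivative, offset and noise", {
  st <- electrode_state(0, noise_sd_uv = 0)
  fs <- 2000
  # constant membrane voltage -> offset only
  ev <- data.frame(electrode_id = 0L, t_end_s = 0, success = TRUE,
                   g0_realized = 0, offset_mv = 5, offset_tau_s = 2)
  y <- couple_to_electrode(rep(3, fs), st, ev, fs)
  t <- (seq_len(fs) - 1) / fs
  expect_equal(y, 5000 * exp(-t / 2), tolerance = 1e-9)
  # linear scaling of the intracellular term: g*k_ic*A = 1 mV dominates
  ch <- sim_channel(g0 = 0.02, noise_sd_uv = 0, offset_mv = 0, fs_hz = fs,
                    params = ap_params(), seed = 3)
  st1 <- electrode_state(0, noise_sd_uv = 0, k_ic = 1, k_ec = 0)
  y1 <- couple_to_electrode(ch$membrane, st1, ch$events, fs)
  # tolerance covers the slow reseal decay between poration and first peak
  expect_equal(max(y1), 1000 * 0.02 * 1 * max(ch$membrane), tolerance = 1e-4)
  # symmetric triangular pulse integrates to ~0 through the derivative path
  v <- c(numeric(100), seq(0, 1, length.out = 50),
         seq(1, 0, length.out = 50), numeric(100))
  st2 <- electrode_state(0, noise_sd_uv = 0, k_ec = 25)
  y2 <- couple_to_electrode(v, st2, NULL, fs)
  expect_lt(abs(sum(y2)), 1e-6 * sum(abs(y2)))
  # saturation clamp
  st3 <- electrode_state(0, noise_sd_uv = 0, k_ic = 1)
  ev3 <- data.frame(electrode_id = 0L, t_end_s = 0, success = TRUE,
                    g0_realized = 1, offset_mv = 40, offset_tau_s = 5)
  y3 <- couple_to_electrode(ch$membrane, st3, ev3, fs)
  expect_lte(max(abs(y3)), interface_constants()$v_sat_uv)
  expect_equal(max(y3), interface_constants()$v_sat_uv)
})

test_that("per-beat amplitude is non-increasing while the pore reseals", {
  ch <- sim_channel(g0 = 0.27, noise_sd_uv = 0, fs_hz = 1000,
                    duration_s = 60, seed = 5)
  pk <- detect_beats(ch$trace, 1000)
  sn <- extract_snippets(ch$trace, 1000, pk)
  amps <- vapply(sn, function(s) max(s$samples_uv), numeric(1))
  tt <- vapply(sn, function(s) s$t_peak_s, numeric(1))
  amps <- amps[tt > 2]
  expect_true(all(diff(amps) <= 1e-6))
})

test_that("recordings assemble with the right geometry and symmetry", {
  cu <- culture_model(ap_params(), rate_bpm = 30, cv = 0)
  st <- make_electrode_states(10, seed = 1, noise_sd_uv = 0,
                              seal_range = c(0.8, 0.8))
  rec <- assemble_recording(cu, st, duration_s = 5, fs_hz = 2000, seed = 3)
  expect_equal(dim(rec$signals), c(10, 10000))
  # identical states + zero noise -> identical channels
  expect_true(all(apply(rec$signals, 2, function(col) all(col == col[1]))))
  expect_error(assemble_recording(cu, st, duration_s = 5, fs_hz = 2000,
                                  max_elements = 1e4), "max_elements")
  expect_error(assemble_recording(cu, st, protocol = poration_protocol(electrode_ids = 0:9),
                                  poration_t_end_s = 10, duration_s = 5),
               "outside recording")
})
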