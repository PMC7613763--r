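# synthetic cardiomyocyte module: AP templates, beat schedules, drug effects,
# membrane traces

test_that("AP template matches its closed-form landmarks", {
  p <- ap_params(amplitude_mv = 100, t_dep_ms = 10, apd90_ms = 300,
                 rep_width_ms = 20)
  tm <- make_ap_template(p, fs_hz = 20000)
  # value at t = apd90 is 10% of amplitude (10 mV here, within 1 mV)
  expect_equal(template_value_at(tm, 300), 10, tolerance = 0.1)
  # peak within [0.95 A, A]
  expect_gte(max(tm$samples_mv), 95)
  expect_lte(max(tm$samples_mv), 100)
  # onset convention: value at t = 0 is 10% of amplitude
  expect_equal(template_value_at(tm, 0), 10, tolerance = 0.1)
  # zero before the upstroke foot
  expect_true(all(tm$samples_mv[tm$t_ms < -tm$t_pre_ms + 4] == 0))
})

test_that("zero-amplitude template is all zero", {
  tm <- make_ap_template(ap_params(amplitude_mv = 0), fs_hz = 2000)
  expect_true(all(tm$samples_mv == 0))
})

test_that("doubling w while keeping m = apd90 - w*ln 9 fixes the 0.1A crossing", {
  cross_t <- function(w_ms) {
    tm <- make_ap_template(ap_params(rep_width_ms = w_ms), fs_hz = 20000)
    v <- tm$samples_mv
    i <- max(which(v >= 10 & tm$t_ms > 50))   # last sample above 0.1A
    stats::approx(v[c(i + 1, i)], tm$t_ms[c(i + 1, i)], xout = 10)$y
  }
  expect_equal(cross_t(20), cross_t(40), tolerance = 0.5)
  expect_equal(cross_t(20), 300, tolerance = 0.5)
})

test_that("ap_params rejects invalid shapes", {
  expect_error(ap_params(t_dep_ms = -1), "t_dep_ms")
  expect_error(ap_params(apd90_ms = 9, t_dep_ms = 10), "apd90_ms")
  expect_error(ap_params(apd90_ms = 60, t_dep_ms = 10, rep_width_ms = 40),
               "midpoint")
  expect_error(make_ap_template(ap_params(), fs_hz = 500), "1 kHz")
  expect_error(make_ap_template(ap_params(), duration_ms = 100), "duration_ms")
})

test_that("beat schedules: zero variance, determinism, counting", {
  s <- schedule_beats(60, 0, 10)
  expect_equal(s$onset_times_s, 0:9)
  s1 <- schedule_beats(60, 0.1, 60, seed = 42)
  s2 <- schedule_beats(60, 0.1, 60, seed = 42)
  expect_identical(s1$onset_times_s, s2$onset_times_s)
  s3 <- schedule_beats(30, 0.05, 600, seed = 1)
  expect_gte(length(s3$onset_times_s), 290)
  expect_lte(length(s3$onset_times_s), 310)
  # mean inter-beat interval within 5% of 60/rate for >= 200 beats
  ibi <- diff(s3$onset_times_s)
  expect_equal(mean(ibi), 2, tolerance = 0.05)
  # rejection keeps every interval above the floor even at large cv
  s4 <- schedule_beats(100, 0.5, 120, seed = 3, min_interval_s = 0.5)
  expect_true(all(diff(s4$onset_times_s) > 0.5))
  expect_error(schedule_beats(5, 0, 10), "rate_bpm")
})

test_that("drug effects are multiplicative and invariant for the vehicle", {
  p <- ap_params()
  pres <- drug_presets(cell_sd = 0)
  expect_equal(apply_drug_effect(p, pres$dmso_vehicle), p)
  eff <- drug_effect("custom", apd90_factor = 0.63, cell_sd = 0)
  expect_equal(apply_drug_effect(p, eff)$apd90_ms, 189)
  eff2 <- drug_effect("custom", tdep_factor = 1.46, cell_sd = 0)
  expect_equal(apply_drug_effect(p, eff2)$t_dep_ms, 14.6)
  # determinism under seed with dispersion
  effd <- drug_effect("custom", apd90_factor = 0.8, cell_sd = 0.1)
  expect_equal(apply_drug_effect(p, effd, seed = 5),
               apply_drug_effect(p, effd, seed = 5))
  # structurally impossible factors error out
  bad <- drug_effect("custom", apd90_factor = 0.02, cell_sd = 0)
  expect_error(apply_drug_effect(p, bad), "impossible")
  expect_error(drug_effect("dmso_vehicle", apd90_factor = 2), "identity")
})

test_that("membrane traces superpose templates and stay bounded", {
  p <- ap_params()
  fs <- 2000
  one <- schedule_beats(60, 0, 1.2)   # single beat at t = 0 fits; use offset
  sched1 <- structure(list(onset_times_s = 1, rate_bpm = 30, cv = 0,
                           seed = NULL), class = "beat_schedule")
  v <- render_membrane_trace(p, sched1, fs, 3)
  tm <- make_ap_template(p, fs)
  i0 <- round(1 * fs) + 1L - (tm$onset_i - 1L)
  expect_equal(v[i0:(i0 + length(tm$samples_mv) - 1L)], tm$samples_mv)
  # empty schedule -> zeros
  sched0 <- structure(list(onset_times_s = numeric(0)), class = "beat_schedule")
  expect_true(all(render_membrane_trace(p, sched0, fs, 2) == 0))
  # beats 1 s apart do not overlap above 1% of amplitude
  sched2 <- structure(list(onset_times_s = c(1, 2)), class = "beat_schedule")
  v2 <- render_membrane_trace(p, sched2, fs, 4)
  v_a <- render_membrane_trace(p, sched1, fs, 4)
  v_b <- v2 - v_a
  expect_false(any(v_a > 0.01 * 100 & v_b > 0.01 * 100))
  # bounded and finite
  sched3 <- schedule_beats(30, 0.05, 30, seed = 2)
  v3 <- render_membrane_trace(p, sched3, fs, 30)
  expect_true(all(is.finite(v3)))
  expect_lte(max(v3), p$amplitude_mv)
})
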