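# study statistics: pulse-train arithmetic, yield, Mann-Whitney, drug report

test_that("pulse-train duration follows the two-phases-plus-IPI convention", {
  expect_equal(train_duration_s(25000, phase_us = 200, ipi_ms = 1), 35)
  expect_equal(train_duration_s(12500, phase_us = 200, ipi_ms = 1), 17.5)
  expect_equal(train_duration_s(0, phase_us = 200, ipi_ms = 1), 0)
  pr <- poration_protocol()
  expect_equal(train_duration_s(pr), 35)
})

test_that("electrode areas are geometric", {
  expect_equal(electrode_area_um2("circle", diameter_um = 4), 12.566,
               tolerance = 1e-4)
  expect_equal(electrode_area_um2("rectangle", width_um = 5.5,
                                  height_um = 9.3), 51.15)
  expect_error(electrode_area_um2("circle", diameter_um = 0), "diameter")
  expect_error(electrode_area_um2("rectangle", width_um = 5), "height")
})

test_that("percent change reproduces the worked examples", {
  expect_equal(round(percent_change(96.9, 62.2), 1), -35.8)
  expect_equal(round(percent_change(97.4, 72.9), 1), -25.2)
  expect_equal(percent_change(5, 5), 0)
  # sign flips but magnitude does not when pre/post are exchanged
  expect_equal(sign(percent_change(62.2, 96.9)), 1)
  expect_false(abs(percent_change(62.2, 96.9)) ==
                 abs(percent_change(96.9, 62.2)))
  expect_error(percent_change(0, 1), "nonzero")
})

test_that("Mann-Whitney U: exact small-sample behaviour", {
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r$u, 0)
  expect_equal(r$p_value, 1 / 3)
  expect_equal(r$method, "exact")
  # identical multisets -> U = nm/2, p = 1
  r2 <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r2$u, 4.5)
  expect_equal(r2$p_value, 1)
  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
})

test_that("Mann-Whitney U matches the enumeration oracle on small cases", {
  set.seed(202)
  for (i in 1:25) {
    n <- sample(1:6, 1)
    m <- sample(1:6, 1)
    v <- sample(1:500, n + m)   # distinct values: exact path
    x <- v[seq_len(n)]
    y <- v[-seq_len(n)]
    r <- mann_whitney_u(x, y)
    expect_equal(r$method, "exact")
    expect_equal(r$p_value, mwu_enum_oracle(x, y), tolerance = 1e-12)
  }
})

test_that("tie-corrected normal approximation matches the reference test", {
  set.seed(7)
  for (i in 1:10) {
    x <- sample(1:6, 15, replace = TRUE)
    y <- sample(2:7, 18, replace = TRUE)
    r <- mann_whitney_u(x, y)
    expect_equal(r$method, "normal_approx")
    ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                               correct = TRUE))
    expect_equal(r$p_value, ref$p.value, tolerance = 1e-10)
    expect_equal(r$u, unname(ref$statistic))
  }
})

test_that("yield counts intracellular electrodes above threshold", {
  feats <- data.frame(electrode_id = 0:9, repeat_idx = 1,
                      label = c(rep("intracellular_like", 8),
                                rep("extracellular", 2)),
                      ap_amplitude_mv = c(5, 8, 3, 2, 9, 4, 6, 0.5, NA, NA))
  events <- data.frame(electrode_id = 0:9, success = NA)
  y <- poration_yield(feats, events)
  expect_equal(y$yield_pct, 70)   # 7 of 10 above 1 mV
  expect_equal(y$n_intracellular, 7)
  # ordering invariance and indifference to unpulsed electrodes
  y2 <- poration_yield(feats[sample(10), ], events)
  expect_equal(y2, y)
  extra <- rbind(feats, data.frame(electrode_id = 99, repeat_idx = 1,
                                   label = "intracellular_like",
                                   ap_amplitude_mv = 50))
  expect_equal(poration_yield(extra, events), y)
  # threshold above every amplitude -> 0%
  expect_equal(poration_yield(feats, events, amp_threshold_mv = 100)$yield_pct, 0)
  expect_error(poration_yield(feats, events[0, ]), "no stimulated")
})

test_that("repeat summaries are stable for identical repeats and NA when empty", {
  one <- data.frame(electrode_id = 0:4, repeat_idx = 1,
                    label = "intracellular_like",
                    apd90_ms = c(290, 300, 310, 305, 295),
                    tdep_ms = c(9, 10, 11, 10, 10),
                    ap_amplitude_mv = c(10, 12, 9, 11, 10),
                    fp_amplitude_uv = c(300, 310, 290, 305, 295))
  two <- one
  two$repeat_idx <- 2
  s <- repeat_summary(rbind(one, two))
  expect_equal(s$apd90_median, c(300, 300))
  expect_equal(s$tdep_iqr[1], s$tdep_iqr[2])
  empty <- one
  empty$repeat_idx <- 3
  empty$label <- "extracellular"
  s2 <- repeat_summary(rbind(one, empty))
  expect_true(is.na(s2$apd90_median[2]))
  expect_equal(s2$n[2], 0)
})

test_that("drug report: identity postdose gives zero change and p = 1", {
  tab <- data.frame(electrode_id = 0:19, repeat_idx = 1, phase = "x",
                    label = "intracellular_like",
                    apd90_ms = seq(250, 350, length.out = 20),
                    tdep_ms = seq(8, 12, length.out = 20))
  rep <- drug_report(list(tab, tab, tab), tab)
  post <- rep$comparisons[rep$comparisons$comparison == "postdose_vs_ctrl3", ]
  expect_equal(post$mean_pct_change, c(0, 0))
  expect_equal(post$sd_pct_change, c(0, 0))
  expect_equal(post$p_value, c(1, 1))
  expect_false(any(post$significant))
  # unmatched electrodes are dropped and listed
  post_tab <- tab[tab$electrode_id < 15, ]
  rep2 <- drug_report(list(tab, tab, tab), post_tab)
  expect_equal(rep2$comparisons$n_pre[1], 15)
  expect_true(all(15:19 %in% rep2$dropped))
})
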