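# recording/feature-table/manifest I/O

make_small_recording <- function(n_ch = 3, seed = 2) {
  cu <- culture_model(ap_params(), rate_bpm = 30, cv = 0.05)
  st <- make_electrode_states(n_ch, seed = seed)
  pr <- poration_protocol(electrode_ids = seq_len(n_ch) - 1L)
  assemble_recording(cu, st, pr, poration_t_end_s = 1, duration_s = 4,
                     fs_hz = 2000, seed = seed)
}

test_that("recording round trip is lossless for float32 payloads", {
  rec <- make_small_recording()
  path <- withr::local_tempfile(fileext = ".mear")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_identical(back$signals, float32(rec$signals))
  expect_equal(back$fs_hz, rec$fs_hz)
  expect_equal(back$channel_meta$seal_quality, rec$channel_meta$seal_quality)
  expect_equal(back$poration_events$g0_realized,
               rec$poration_events$g0_realized)
  expect_equal(back$protocol$n_pulses, rec$protocol$n_pulses)
  # second round trip is bit-identical
  path2 <- withr::local_tempfile(fileext = ".mear")
  write_recording(back, path2)
  expect_identical(read_recording(path2)$signals, back$signals)
})

test_that("unknown extra keys survive a round trip", {
  rec <- make_small_recording()
  rec$extra <- list(instrument = "sim-rig", gain_db = 12)
  path <- withr::local_tempfile(fileext = ".mear")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_equal(back$extra$instrument, "sim-rig")
  expect_equal(back$extra$gain_db, 12)
})

test_that("missing poration events read back as an empty table", {
  rec <- make_small_recording()
  rec$poration_events <- NULL
  path <- withr::local_tempfile(fileext = ".mear")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_s3_class(back$poration_events, "data.frame")
  expect_equal(nrow(back$poration_events), 0)
})

test_that("structural corruption is rejected with a named key", {
  rec <- make_small_recording()
  path <- withr::local_tempfile(fileext = ".mear")
  # channel_meta claims 4 channels, payload has 3
  rec$channel_meta <- rbind(rec$channel_meta, rec$channel_meta[1, ])
  write_recording(rec, path)
  expect_error(read_recording(path), "channel_meta")
  # truncated payload
  rec2 <- make_small_recording()
  write_recording(rec2, path)
  sz <- file.size(path)
  con <- file(path, "r+b")
  truncate_to <- sz - 100
  raw_all <- readBin(con, raw(), n = truncate_to)
  close(con)
  writeBin(raw_all, path)
  expect_error(read_recording(path), "signals")
  expect_error(suppressWarnings(
    read_recording(withr::local_tempfile(fileext = ".mear"))),
    "cannot open")
})

test_that("feature tables round-trip with stable column order", {
  tab <- data.frame(electrode_id = c(0L, 5L), repeat_idx = c(1L, 1L),
                    phase = c("baseline1", "postdose"),
                    label = c("extracellular", "intracellular_like"),
                    ap_amplitude_mv = c(NA, 12.5), apd90_ms = c(NA, 301.2),
                    tdep_ms = c(NA, 9.1), fp_amplitude_uv = c(310.5, NA),
                    n_beats_averaged = c(0L, 3L), t_measure_s = c(NA, 11.5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(tab, path)
  back <- read_feature_table(path)
  expect_equal(back, tab)
  expect_equal(names(back), names(tab))
  # empty table -> header-only CSV
  write_feature_table(tab[0, ], path)
  expect_equal(length(readLines(path)), 1L)
  expect_equal(nrow(read_feature_table(path)), 0)
  # non-ASCII drug names survive
  tab$phase <- c("baseéline", "postdose µM")
  write_feature_table(tab, path)
  expect_equal(read_feature_table(path)$phase, tab$phase)
})

test_that("config hashes ignore key order but not values", {
  a <- list(x = 1, nested = list(b = 2, a = 3))
  b <- list(nested = list(a = 3, b = 2), x = 1)
  expect_identical(config_hash(a), config_hash(b))
  expect_false(config_hash(a) == config_hash(list(x = 2, nested = list(b = 2, a = 3))))
  man <- run_manifest("test", 1, a, outputs = "x.csv")
  expect_equal(man$config_hash, config_hash(b))
  path <- withr::local_tempfile(fileext = ".json")
  write_manifest(man, path)
  expect_equal(jsonlite::fromJSON(path)$run_id, "test")
})
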