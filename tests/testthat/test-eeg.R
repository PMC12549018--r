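test_that("band-pass filtering attenuates out-of-band power, keeps in-band", {
  fs <- 256
  set.seed(23)
  rec <- eeg_recording(matrix(stats::rnorm(4 * fs * 8), 4), fs)
  out <- preprocess_eeg(rec, hp = 0.5, lp = 60)
  bandpower <- function(x, lo, hi) {
    sp <- stats::spec.pgram(stats::ts(x, frequency = fs), plot = FALSE,
                            taper = 0)
    mean(sp$spec[sp$freq >= lo & sp$freq <= hi])
  }
  inband <- bandpower(out$signals[1, ], 5, 40)
  outband <- bandpower(out$signals[1, ], 90, 120)
  expect_gt(10 * log10(inband / outband), 20)
  # pure 10 Hz tone passes nearly unchanged
  t <- seq_len(fs * 8) / fs
  tone <- eeg_recording(matrix(rep(sin(2 * pi * 10 * t), 2), 2,
                               byrow = TRUE), fs)
  tf <- preprocess_eeg(tone, 0.5, 60)
  core <- (2 * fs):(6 * fs)
  expect_lt(abs(stats::sd(tf$signals[1, core]) /
                  stats::sd(tone$signals[1, core]) - 1), 0.05)
  expect_error(preprocess_eeg(rec, lp = 128), "fs/2")
})

test_that("bootstrap segmentation is seeded and validates lengths", {
  fs <- 100
  rec <- eeg_recording(matrix(stats::rnorm(2 * fs * 600), 2), fs)
  a <- bootstrap_segments(rec, n = 50, seg_len_s = 60, seed = 4)
  b <- bootstrap_segments(rec, n = 50, seg_len_s = 60, seed = 4)
  expect_equal(length(a), 50)
  expect_identical(a[[7]]$signals, b[[7]]$signals)
  expect_true(all(vapply(a, function(s) ncol(s$signals), numeric(1)) ==
                    60 * fs))
  short <- eeg_recording(matrix(stats::rnorm(2 * fs * 30), 2), fs)
  expect_error(bootstrap_segments(short, 10, 60), "shorter")
})

test_that("synthetic EEG is reproducible and state-dependent", {
  a <- generate_synthetic_eeg(8, 128, 10, "wake-like", seed = 5)
  b <- generate_synthetic_eeg(8, 128, 10, "wake-like", seed = 5)
  expect_identical(a$signals, b$signals)
  expect_false(identical(
    a$signals, generate_synthetic_eeg(8, 128, 10, "wake-like",
                                      seed = 6)$signals))
  bs <- generate_synthetic_eeg(8, 128, 10, "burst-suppression", seed = 5)
  expect_false(identical(dim(a$signals), NULL))
  expect_equal(dim(bs$signals), c(8, 1280))
})

test_that("pattern switching drives fluidity above the static generator", {
  # full montage: smaller montages sit at the finite-pair noise floor
  fl <- function(state, sr, seed) {
    rec <- generate_synthetic_eeg(60, 256, 30, state, switch_rate = sr,
                                  seed = seed)
    ph <- instantaneous_phase(rec$signals)
    fluidity_of(ph, rec$fs, fc_window_spec(0.55, 0.05, "circular"))
  }
  seeds <- 1:3
  wake <- vapply(seeds, function(s) fl("wake-like", 0.2, s), numeric(1))
  frozen <- vapply(seeds, function(s) fl("wake-like", 0, s), numeric(1))
  anes <- vapply(seeds, function(s) fl("anesthesia-like", 0, s), numeric(1))
  expect_gt(mean(wake), 1.5 * mean(anes))
  # switch_rate -> 0 degenerates to anesthesia-like (static) statistics
  expect_lt(abs(mean(frozen) - mean(anes)), abs(mean(wake) - mean(frozen)))
})

test_that("metric table emits per-segment and normalized full rows", {
  rec1 <- generate_synthetic_eeg(10, 128, 30, "wake-like", seed = 7,
                                 subject_id = "s1")
  tab <- metric_table(list(rec1, rec1),
                      fc_spec = fc_window_spec(0.55, 0.1, "circular"),
                      n_boot = 3, seg_len_s = 10, seed = 2)
  expect_equal(nrow(tab), 2 * 4)
  full <- tab[tab$segment_id == "full", ]
  expect_true(all(full$normalized))
  # identical recordings give identical rows
  expect_equal(tab[1:4, -1], tab[5:8, -1], ignore_attr = TRUE)
  # normalization: full-recording repertoire divided by minutes
  raster <- suppressWarnings(zscore_binarize(rec1$signals, 3))
  rep_raw <- functional_repertoire_eeg(extract_avalanches(raster, 1))
  expect_equal(full$repertoire[1], rep_raw / rec1$duration_min)
  # constant recording: LZ missing, not an error
  const <- eeg_recording(matrix(0, 3, 128 * 20), 128)
  tc <- suppressWarnings(
    metric_table(list(const), n_boot = 2, seg_len_s = 5,
                 fc_spec = fc_window_spec(0.55, 0.1, "circular")))
  expect_true(all(is.na(tc$lz_complexity)))
})

test_that("delimited EEG round-trips through the reader", {
  rec <- generate_synthetic_eeg(4, 64, 5, "anesthesia-like", seed = 9)
  f <- tempfile(); cf <- tempfile()
  utils::write.table(rec$signals, f, row.names = FALSE, col.names = FALSE)
  writeLines(rec$channel_names, cf)
  back <- read_eeg_delim(f, 64, cf)
  expect_equal(back$signals, rec$signals, tolerance = 1e-6)
  expect_equal(back$channel_names, rec$channel_names)
})
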