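small_cfg <- function(seed = 1, ...) {
  base <- utils::modifyList(benchmark_cohort_args(), list(
    n_channels = 2, duration = 300, n_seizures = 2,
    seizure_duration = c(8, 12), n_seizure_subtypes = 2,
    n_background_subtypes = 2, clean_frac = 0.5, seed = seed))
  do.call(synth_config, utils::modifyList(base, list(...)))
}

test_that("windowing yields floor((T-Wlen)/Wstep)+1 windows and exact labels", {
  rec <- eeg_recording(matrix(0, 2, 60 * 256), fs = 256,
                       seizures = data.frame(onset = 20, offset = 30))
  w <- segment_and_label(rec)
  expect_equal(nrow(w), 53)
  expect_equal(w$start, 0:52)
  # >= 50% overlap rule: starts 16..26 overlap [20,30) by >= 4 s
  expect_identical(w$label == "ictal", w$start %in% 16:26)
  # no seizures -> all interictal; whole-record seizure -> all ictal
  rec0 <- eeg_recording(matrix(0, 2, 20 * 256), fs = 256)
  expect_true(all(segment_and_label(rec0)$label == "interictal"))
  rec1 <- eeg_recording(matrix(0, 2, 20 * 256), fs = 256,
                        seizures = data.frame(onset = 0, offset = 20))
  expect_true(all(segment_and_label(rec1)$label == "ictal"))
  expect_error(segment_and_label(
    eeg_recording(matrix(0, 2, 256), fs = 256)), "shorter")
})

test_that("window time ranges reconstruct bit-exactly from indices", {
  rec <- generate_synthetic_recording(small_cfg(3))
  w <- segment_and_label(rec)
  for (i in c(1, 50, nrow(w))) {
    ws <- window_samples(rec, w$start[i], 8)
    i0 <- round(w$start[i] * rec$fs)
    expect_identical(ws, rec$signal[, (i0 + 1):(i0 + 8 * rec$fs)])
  }
})

test_that("synthetic generation is seed-reproducible with exact annotations", {
  cfg <- small_cfg(11)
  r1 <- generate_synthetic_recording(cfg)
  r2 <- generate_synthetic_recording(cfg)
  expect_identical(r1$signal, r2$signal)
  expect_identical(r1$seizures, r2$seizures)
  expect_equal(nrow(r1$seizures), 2)
  expect_true(all(r1$seizures$offset > r1$seizures$onset))
  expect_true(all(r1$seizures$onset[-1] >= r1$seizures$offset[-2]))
  # different seed, different signal
  expect_false(identical(
    generate_synthetic_recording(small_cfg(12))$signal, r1$signal))
  # infeasible packing errors out
  expect_error(generate_synthetic_recording(
    small_cfg(1, n_seizures = 12)), "cannot pack")
})

test_that("well-separated seizure sub-types form distinct feature clusters", {
  cfg <- small_cfg(21, duration = 500, n_seizures = 4,
                   n_seizure_subtypes = 2)
  rec <- generate_synthetic_recording(cfg)
  assign <- attr(rec, "subtype_log")$seizure
  w <- segment_and_label(rec)
  # fully ictal windows only, tagged by the sub-type of their seizure
  feats <- list(); tags <- integer(0)
  for (k in seq_len(nrow(rec$seizures))) {
    sel <- w$start >= rec$seizures$onset[k] &
      w$start + 8 <= rec$seizures$offset[k]
    for (s in w$start[sel]) {
      bp <- rbind(
        compute_band_power_features(window_samples(rec, s, 8)[1, ], cfg$fs),
        compute_band_power_features(window_samples(rec, s, 8)[2, ], cfg$fs))
      feats[[length(feats) + 1L]] <- colMeans(bp)
      tags <- c(tags, assign[k])
    }
  }
  fm <- do.call(rbind, feats)
  expect_true(all(1:2 %in% tags))
  c1 <- colMeans(fm[tags == 1, , drop = FALSE])
  c2 <- colMeans(fm[tags == 2, , drop = FALSE])
  within_sd <- mean(c(apply(fm[tags == 1, , drop = FALSE], 2, sd),
                      apply(fm[tags == 2, , drop = FALSE], 2, sd)),
                    na.rm = TRUE)
  expect_gt(sqrt(sum((c1 - c2)^2)), 3 * within_sd)
})

test_that("balancing draws the exact interictal budget outside exclusion zones", {
  cfg <- small_cfg(31, duration = 900, clean_frac = 0.55)
  rec <- generate_synthetic_recording(cfg)
  for (f in c(1, 10)) {
    files <- build_balanced_files(rec, balancing_config(factor = f, seed = 5))
    expect_equal(length(files), nrow(rec$seizures))
    for (k in seq_along(files)) {
      bf <- files[[k]]
      expect_equal(nrow(bf$seizures), 1)
      seiz_dur <- bf$seizures$offset - bf$seizures$onset
      expect_equal(seiz_dur,
                   rec$seizures$offset[k] - rec$seizures$onset[k],
                   tolerance = 1 / rec$fs)
      inter_dur <- ncol(bf$signal) / bf$fs - seiz_dur
      expect_equal(inter_dur, f * seiz_dur, tolerance = 2 / rec$fs)
      # the ictal samples are carried over untouched
      on_i <- round(rec$seizures$onset[k] * rec$fs)
      bf_on <- round(bf$seizures$onset * bf$fs)
      n_ict <- round(seiz_dur * rec$fs)
      expect_identical(bf$signal[, (bf_on + 1):(bf_on + n_ict)],
                       rec$signal[, (on_i + 1):(on_i + n_ict)])
    }
    # reproducibility of the draw
    files2 <- build_balanced_files(rec, balancing_config(factor = f, seed = 5))
    expect_identical(files[[1]]$signal, files2[[1]]$signal)
  }
  # shortfall is a clear error
  expect_error(
    build_balanced_files(rec, balancing_config(factor = 50, seed = 5)),
    "insufficient eligible")
})

test_that("interictal segments avoid every pre/post-ictal exclusion zone", {
  # verify sample-exactly by fingerprinting: zero out all eligible samples
  # in the source; a correctly balanced file is then zero outside its
  # seizure interval
  cfg <- small_cfg(41, duration = 900, clean_frac = 0.55)
  rec <- generate_synthetic_recording(cfg)
  marked <- rec
  for (k in seq_len(nrow(rec$seizures))) {
    z0 <- max(0, rec$seizures$onset[k] - 60)
    z1 <- min(ncol(rec$signal) / rec$fs, rec$seizures$offset[k] + 900)
    cols <- (round(z0 * rec$fs) + 1):round(z1 * rec$fs)
    marked$signal[, cols] <- 1e6          # poison the exclusion zones
  }
  files <- build_balanced_files(marked, balancing_config(factor = 5, seed = 9))
  for (bf in files) {
    out_cols <- setdiff(seq_len(ncol(bf$signal)),
                        (round(bf$seizures$onset * bf$fs) + 1):
                          round(bf$seizures$offset * bf$fs))
    expect_true(all(bf$signal[, out_cols] < 1e6))
  }
})

test_that("EDF files round-trip within format precision, canonical order", {
  rec <- generate_synthetic_recording(small_cfg(51))
  path <- tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_edf(path)
  expect_equal(back$fs, rec$fs)
  expect_equal(dim(back$signal), dim(rec$signal))
  rng <- diff(range(rec$signal))
  expect_lt(max(abs(back$signal - rec$signal)), rng / 65000 * 2)
  expect_equal(back$seizures$onset, rec$seizures$onset, tolerance = 1e-5)
  # channel selection is canonical regardless of file order
  sub <- read_edf(path, channels = rev(rec$channels))
  expect_identical(sub$channels, rev(rec$channels))
  expect_equal(sub$signal[1, ], back$signal[nrow(back$signal), ])
  expect_error(read_edf(path, channels = c("FP1-F7", "NOPE-1", "NOPE-2")),
               "NOPE-1, NOPE-2")
  expect_error(read_edf(tempfile()), "no such file")
  unlink(c(path, paste0(path, ".seizures.txt")))
})

test_that("recording container round-trips with JSON metadata", {
  rec <- generate_synthetic_recording(small_cfg(61))
  path <- tempfile(fileext = ".rds")
  save_recording(rec, path, config = small_cfg(61))
  back <- load_recording(path)
  expect_identical(back$signal, rec$signal)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$fs, rec$fs)
  expect_equal(meta$config$seed, 61)
  unlink(c(path, paste0(path, ".json")))
})

test_that("benchmark bundle writes consistent files and manifest", {
  dir <- tempfile("bench")
  mf <- make_subject_benchmark(dir, n_subjects = 2, seed = 3,
                               factors = c(1, 5),
                               n_channels = 2, duration = 600,
                               n_seizures = 2, seizure_duration = c(8, 12),
                               clean_frac = 0.55)
  expect_equal(nrow(mf), 2 * 2 * 2)    # subjects x factors x seizures
  expect_true(file.exists(file.path(dir, "manifest.json")))
  # same seizures appear in both balancing variants of one subject
  f1 <- read_edf(file.path(dir, "sub01_F1_seiz01.edf"))
  f5 <- read_edf(file.path(dir, "sub01_F5_seiz01.edf"))
  d1 <- f1$seizures$offset - f1$seizures$onset
  d5 <- f5$seizures$offset - f5$seizures$onset
  expect_equal(d1, d5, tolerance = 1e-5)
  # manifest window counts equal recomputed counts
  for (i in seq_len(nrow(mf))) {
    rec <- read_edf(file.path(dir, mf$file[i]))
    expect_equal(nrow(segment_and_label(rec)), mf$n_windows[i])
  }
  unlink(dir, recursive = TRUE)
})

test_that("feature CSV export writes manifest-ordered columns", {
  rec <- generate_synthetic_recording(small_cfg(71, duration = 300))
  files <- build_balanced_files(rec, balancing_config(factor = 1, seed = 2))
  cfg <- feature_config()
  ff <- compute_file_features(files[[1]], cfg)
  path <- tempfile(fileext = ".csv")
  write_feature_csv(list(ff), path, channels = files[[1]]$channels)
  tab <- utils::read.csv(path, check.names = FALSE)
  expect_equal(nrow(tab), length(ff$features))
  expect_equal(ncol(tab), 3 + 2 * 46)
  manifest <- readLines(paste0(path, ".manifest.txt"))
  expect_equal(length(manifest), 2 * 46)
  expect_identical(colnames(tab)[-(1:3)], manifest)
  expect_equal(as.numeric(tab[1, "ch01_mean_amplitude"]),
               unname(ff$features[[1]][1, "mean_amplitude"]))
  unlink(c(path, paste0(path, ".manifest.txt")))
})
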