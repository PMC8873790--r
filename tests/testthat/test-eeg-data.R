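make_test_recording <- function(n_trials = 3, fs = 160, trial_s = 4,
                                n_ch = 4, gap_s = 0, labels = NULL,
                                extra_s = 0) {
  if (is.null(labels)) labels <- rep(c("L", "R", "B", "F"),
                                     length.out = n_trials)
  total <- n_trials * (trial_s + gap_s) + extra_s
  sig <- matrix(rnorm(n_ch * total * fs), n_ch)
  ann <- data.frame(onset = (seq_len(n_trials) - 1) * (trial_s + gap_s),
                    duration = trial_s, code = labels,
                    stringsAsFactors = FALSE)
  raw_recording(sig, fs, paste0("C", seq_len(n_ch)), ann,
                subject_id = "S1", run_id = "04")
}

test_that("trial extraction yields one event per non-rest annotation", {
  rec <- make_test_recording(n_trials = 21, labels = rep("L", 21))
  tr <- extract_trials(rec, trial_seconds = 4)
  expect_equal(nrow(tr), 21)
  expect_true(all(tr$n_samples == 640))
  expect_true(all(tr$label == "L"))
  # rest annotations are excluded; unknown codes raise
  rec$annotations$code[3] <- "T0"
  expect_equal(nrow(extract_trials(rec)), 20)
  rec$annotations$code[4] <- "XX"
  expect_error(extract_trials(rec), "XX")
})

test_that("trials running past the record end are dropped with a warning", {
  rec <- make_test_recording(n_trials = 3)
  # shift last onset so only 100 samples remain
  rec$annotations$onset[3] <- ncol(rec$signal) / rec$fs - 100 / rec$fs
  expect_warning(tr <- extract_trials(rec), "dropped")
  expect_equal(nrow(tr), 2)
})

test_that("physionet run map routes codes by run id", {
  map <- physionet_run_map()
  expect_equal(map("4", "T1"), "L")
  expect_equal(map("4", "T2"), "R")
  expect_equal(map("10", "T1"), "B")
  expect_equal(map("14", "T2"), "F")
  expect_equal(map("4", "T0"), "rest")
  expect_equal(map("1", "T1"), "rest")   # baseline run
  expect_error(map("8", "T9"), "unknown")
})

test_that("segmentation arithmetic matches the sliding-window count", {
  rec <- make_test_recording(n_trials = 1, n_ch = 64)
  tr <- extract_trials(rec)
  segs <- segment_trial(rec, tr[1, ], 0.4)
  expect_length(segs, 10)                         # 640 %/% 64
  expect_equal(dim(segs[[1]]$data), c(64, 64))
  expect_equal(vapply(segs, function(s) s$segment_index, numeric(1)), 0:9)
  expect_true(all(vapply(segs, function(s) s$label, character(1)) == tr$label[1]))
  # overlapping windows: floor((640 - 64) / 32) + 1 = 19
  expect_length(segment_trial(rec, tr[1, ], 0.4, 0.2), 19)
  # trial of exactly one segment
  tr1 <- tr[1, ]; tr1$n_samples <- 64L
  expect_length(segment_trial(rec, tr1, 0.4), 1)
  # segment longer than trial
  expect_error(segment_trial(rec, tr1, 0.8), "longer")
})

test_that("segments tile trials without crossing boundaries", {
  rec <- make_test_recording(n_trials = 2, labels = c("L", "R"))
  tr <- extract_trials(rec)
  for (i in 1:2) {
    segs <- segment_trial(rec, tr[i, ], 0.4, trial_id = i)
    recon <- do.call(cbind, lapply(segs, function(s) s$data))
    span <- tr$onset_sample[i] + seq_len(640)
    expect_identical(recon, rec$signal[, span])
  }
})

test_that("splits have the requested sizes and are seed-deterministic", {
  spec <- tiny_synth_spec(n_trials_per_class = 5)
  ds <- generate_dataset(spec)            # 4 * 5 * 10 = 200 segments
  expect_length(ds$segments, 200)
  ds1 <- make_splits(ds, 0.1, 10, seed = 42)
  expect_equal(dim(ds1$splits), c(200, 10))
  expect_true(all(colSums(ds1$splits == "test") == 20))
  ds2 <- make_splits(ds, 0.1, 10, seed = 42)
  expect_identical(ds1$splits, ds2$splits)
  ds3 <- make_splits(ds, 0.1, 10, seed = 43)
  expect_false(identical(ds1$splits, ds3$splits))
  expect_error(make_splits(ds, 0, 1, 1), "test_fraction")
  expect_error(make_splits(ds, 1, 1, 1), "test_fraction")
})

test_that("trial-disjoint splits keep whole trials on one side", {
  spec <- tiny_synth_spec(n_trials_per_class = 5)
  ds <- make_splits(generate_dataset(spec), 0.2, 3, seed = 9,
                    mode = "trial_disjoint")
  for (r in 1:3) {
    sides <- tapply(ds$splits[, r], ds$meta$trial_id,
                    function(x) length(unique(x)))
    expect_true(all(sides == 1))
  }
})

test_that("label and count conservation hold across segmentation", {
  spec <- tiny_synth_spec(n_trials_per_class = 3)
  ds <- generate_dataset(spec)
  # per-trial label sets are singletons equal to the trial label
  per_trial <- tapply(ds$meta$label, ds$meta$trial_id, unique)
  expect_true(all(lengths(per_trial) == 1))
  # count: trials x segments-per-trial
  expect_equal(length(ds$segments), 4 * 3 * 10)
  expect_equal(as.vector(table(factor(ds$meta$label, c("L", "R", "B", "F")))),
               rep(30, 4))
})

test_that("channel z-scoring standardizes using training statistics", {
  spec <- tiny_synth_spec(n_trials_per_class = 2)
  ds <- generate_dataset(spec)
  idx <- 1:40
  z <- channel_zscore(ds, idx)
  tr <- do.call(cbind, lapply(z$segments[idx], function(s) s$data))
  expect_equal(rowMeans(tr), rep(0, 8), tolerance = 1e-10)
  expect_equal(apply(tr, 1, sd), rep(1, 8), tolerance = 1e-10)
})
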