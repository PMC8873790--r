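# Trial extraction and segmentation for four-class motor-imagery EEG.
#
# The classification sample unit is a short fixed-length window ("segment",
# default 0.4 s x 64 channels) cut from a labeled 4-s trial. Labels are the
# four imagery tasks: L (left fist), R (right fist), B (both fists),
# F (both feet). Sample indices are 0-based with half-open intervals
# [onset, onset + n).

MI_CLASSES <- c("L", "R", "B", "F")

#' Construct a raw recording object
#'
#' @param signal channels x samples numeric matrix (microvolts).
#' @param fs sampling rate (Hz).
#' @param channel_names ordered channel labels, one per row.
#' @param annotations data.frame with `onset` (s), `duration` (s), `code`.
#' @param subject_id,run_id provenance identifiers.
#' @return object of class `raw_recording`.
#' @export
raw_recording <- function(signal, fs, channel_names, annotations,
                          subject_id = NA, run_id = NA) {
  stopifnot(is.matrix(signal), fs > 0,
            nrow(signal) == length(channel_names))
  stopifnot_finite(signal, "signal")
  if (nrow(annotations) > 0) {
    dur <- ncol(signal) / fs
    if (is.unsorted(annotations$onset)) {
      stop("annotation onsets must be non-decreasing")
    }
    if (any(annotations$onset < 0 | annotations$onset > dur)) {
      stop("annotation onset outside record duration")
    }
  }
  structure(list(signal = signal, fs = fs, channel_names = channel_names,
                 annotations = annotations, subject_id = subject_id,
                 run_id = run_id),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("raw_recording: %d ch x %d samples @ %g Hz, %d annotations (subject %s, run %s)\n",
              nrow(x$signal), ncol(x$signal), x$fs, nrow(x$annotations),
              x$subject_id, x$run_id))
  invisible(x)
}

#' Load an EDF recording with event annotations
#'
#' @param path EDF file path.
#' @param expected_fs if given, an error is raised when the file's sampling
#'   rate differs (configuration guard).
#' @param subject_id,run_id provenance identifiers attached to the result.
#' @return a [raw_recording].
#' @export
load_recording <- function(path, expected_fs = NULL,
                           subject_id = NA, run_id = NA) {
  rec <- read_edf(path)
  if (!is.null(expected_fs) && abs(rec$fs - expected_fs) > 1e-9) {
    stop("sampling rate mismatch: file has ", rec$fs, " Hz, expected ",
         expected_fs, " Hz")
  }
  if (nrow(rec$annotations) == 0) {
    stop("no events: recording at ", path, " carries no annotations")
  }
  raw_recording(rec$signal, rec$fs, rec$channel_names, rec$annotations,
                subject_id = subject_id, run_id = run_id)
}

#' Run/annotation-code to task mapping for the public motor-imagery dataset
#'
#' Imagery runs 4, 8, 12 map T1 -> L (left fist) and T2 -> R (right fist);
#' runs 6, 10, 14 map T1 -> B (both fists) and T2 -> F (both feet). T0 (rest)
#' is excluded. This follows the dataset's published run protocol and lives
#' in configuration, not hard-wired into the extraction code.
#'
#' @return a function (run_id, code) -> one of "L","R","B","F","rest".
#' @export
physionet_run_map <- function() {
  function(run_id, code) {
    if (code == "T0") return("rest")
    run <- suppressWarnings(as.integer(run_id))
    if (is.na(run)) stop("unknown run id: ", run_id)
    if (run %in% c(4L, 8L, 12L)) {
      switch(code, T1 = "L", T2 = "R",
             stop("unknown annotation code: ", code))
    } else if (run %in% c(6L, 10L, 14L)) {
      switch(code, T1 = "B", T2 = "F",
             stop("unknown annotation code: ", code))
    } else {
      "rest"   # baseline / executed-movement runs are not imagery
    }
  }
}

# A trivially simple map: annotation code IS the class label.
identity_task_map <- function() {
  function(run_id, code) {
    if (code %in% MI_CLASSES) code
    else if (code %in% c("T0", "rest")) "rest"
    else stop("unknown annotation code: ", code)
  }
}

#' Extract labeled fixed-length trials from a recording
#'
#' @param rec a [raw_recording].
#' @param run_task_map function (run_id, code) -> class label or "rest";
#'   see [physionet_run_map()]. Default treats codes L/R/B/F as labels.
#' @param trial_seconds trial duration in seconds (default 4).
#' @return data.frame of trial events: `label`, `onset_sample`, `n_samples`.
#' @export
extract_trials <- function(rec, run_task_map = identity_task_map(),
                           trial_seconds = 4) {
  n_samples <- as.integer(round(trial_seconds * rec$fs))
  ann <- rec$annotations
  keep <- list()
  n_dropped <- 0L
  for (i in seq_len(nrow(ann))) {
    lab <- run_task_map(rec$run_id, ann$code[i])
    if (lab %in% c("rest", "ignore")) next
    if (!lab %in% MI_CLASSES) stop("mapped label not a task class: ", lab)
    onset <- as.integer(round(ann$onset[i] * rec$fs))
    if (onset + n_samples > ncol(rec$signal)) {
      n_dropped <- n_dropped + 1L
      next
    }
    keep[[length(keep) + 1L]] <- data.frame(label = lab,
                                            onset_sample = onset,
                                            n_samples = n_samples,
                                            stringsAsFactors = FALSE)
  }
  if (n_dropped > 0L) {
    warning(n_dropped, " trial(s) extending past the record end were dropped")
  }
  if (!length(keep)) {
    return(data.frame(label = character(0), onset_sample = integer(0),
                      n_samples = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, keep)
}

#' Slice one trial into fixed-length segments
#'
#' Non-overlapping by default (stride = segment length); a shorter stride
#' gives sliding windows. Every segment inherits the trial label.
#'
#' @param rec a [raw_recording].
#' @param trial one row of the [extract_trials()] result (or a list with
#'   `label`, `onset_sample`, `n_samples`).
#' @param segment_seconds window length in seconds (default 0.4).
#' @param stride_seconds hop between window starts (default: window length).
#' @param trial_id identifier stored on each segment.
#' @return list of `segment` objects: `data` (channels x timesteps), `label`,
#'   `subject_id`, `trial_id`, `segment_index` (0-based).
#' @export
segment_trial <- function(rec, trial, segment_seconds = 0.4,
                          stride_seconds = segment_seconds, trial_id = NA) {
  win <- as.integer(round(segment_seconds * rec$fs))
  hop <- as.integer(round(stride_seconds * rec$fs))
  stopifnot(win > 0, hop > 0)
  if (win > trial$n_samples) stop("segment longer than trial")
  n_seg <- (trial$n_samples - win) %/% hop + 1L
  lapply(seq_len(n_seg) - 1L, function(k) {
    start <- trial$onset_sample + k * hop          # 0-based
    structure(list(data = rec$signal[, (start + 1L):(start + win),
                                     drop = FALSE],
                   label = trial$label, subject_id = rec$subject_id,
                   trial_id = trial_id, segment_index = k),
              class = "segment")
  })
}

#' Bundle segments into a dataset
#'
#' @param segments list of `segment` objects.
#' @return object of class `segment_dataset` with the segment list, an index
#'   data.frame (`subject_id`, `trial_id`, `segment_index`, `label`) and an
#'   empty split-assignment slot filled in by [make_splits()].
#' @export
segment_dataset <- function(segments) {
  stopifnot(length(segments) > 0)
  meta <- data.frame(
    subject_id = vapply(segments, function(s) as.character(s$subject_id),
                        character(1)),
    trial_id = vapply(segments, function(s) as.character(s$trial_id),
                      character(1)),
    segment_index = vapply(segments, function(s) s$segment_index, numeric(1)),
    label = vapply(segments, function(s) s$label, character(1)),
    stringsAsFactors = FALSE)
  if (!all(meta$label %in% MI_CLASSES)) stop("labels must be in L/R/B/F")
  structure(list(segments = segments, meta = meta, splits = NULL),
            class = "segment_dataset")
}

#' @export
print.segment_dataset <- function(x, ...) {
  d <- dim(x$segments[[1]]$data)
  cat(sprintf("segment_dataset: %d segments of %d ch x %d steps; classes: %s\n",
              length(x$segments), d[1], d[2],
              paste(sprintf("%s=%d", MI_CLASSES,
                            as.vector(table(factor(x$meta$label,
                                                   MI_CLASSES)))),
                    collapse = " ")))
  if (!is.null(x$splits)) {
    cat(sprintf("  %d split repeat(s), test fraction %.2f\n",
                ncol(x$splits), attr(x$splits, "test_fraction")))
  }
  invisible(x)
}

#' Integer class index (0..3) for segment labels
#' @param labels character vector of L/R/B/F labels.
#' @return integer vector, L=0, R=1, B=2, F=3.
#' @export
label_index <- function(labels) {
  match(labels, MI_CLASSES) - 1L
}

#' Assign repeated random train/test partitions
#'
#' The validation protocol: for each repeat an independent random partition
#' holding out `test_fraction` of the segments (round(test_fraction * n)
#' test segments). A trial-disjoint mode keeps all segments of a trial on
#' the same side, avoiding within-trial leakage.
#'
#' @param ds a [segment_dataset()].
#' @param test_fraction held-out proportion, in (0, 1).
#' @param n_repeats number of independent partitions.
#' @param seed RNG seed; identical (dataset, seed) gives identical splits.
#' @param mode `"random"` (segment-level draws, the default) or
#'   `"trial_disjoint"`.
#' @return the dataset with a `splits` character matrix (n x n_repeats,
#'   entries "train"/"test").
#' @export
make_splits <- function(ds, test_fraction = 0.1, n_repeats = 10, seed = 1,
                        mode = c("random", "trial_disjoint")) {
  mode <- match.arg(mode)
  if (!(test_fraction > 0 && test_fraction < 1)) {
    stop("test_fraction must be strictly between 0 and 1")
  }
  counts <- table(factor(ds$meta$label, MI_CLASSES))
  if (any(counts < 1)) stop("every class needs at least one segment")
  n <- length(ds$segments)
  splits <- matrix("train", n, n_repeats)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  for (r in seq_len(n_repeats)) {
    if (mode == "random") {
      n_test <- round(test_fraction * n)
      splits[sample.int(n, n_test), r] <- "test"
    } else {
      trials <- unique(ds$meta$trial_id)
      n_test_tr <- max(1L, round(test_fraction * length(trials)))
      test_trials <- sample(trials, n_test_tr)
      splits[ds$meta$trial_id %in% test_trials, r] <- "test"
    }
  }
  attr(splits, "test_fraction") <- test_fraction
  attr(splits, "seed") <- seed
  attr(splits, "mode") <- mode
  ds$splits <- splits
  ds
}

# Time-major array (timesteps x batch x channels) for a subset of segments;
# the extractor consumes each 64x64 segment as 64 time steps of 64-channel
# input vectors.
segments_to_array <- function(ds, idx = seq_along(ds$segments)) {
  d <- dim(ds$segments[[idx[1]]]$data)
  out <- array(0, c(d[2], length(idx), d[1]))
  for (b in seq_along(idx)) {
    out[, b, ] <- t(ds$segments[[idx[b]]]$data)
  }
  out
}

#' Optional per-channel z-scoring using training statistics
#'
#' Off by default in the pipeline (the method consumes raw signals); when
#' used, means/sds are estimated on the training partition only and applied
#' to every segment.
#'
#' @param ds a [segment_dataset()].
#' @param train_idx indices of training segments used for the statistics.
#' @return the dataset with standardized segment matrices.
#' @export
channel_zscore <- function(ds, train_idx) {
  tr <- do.call(cbind, lapply(ds$segments[train_idx], function(s) s$data))
  mu <- rowMeans(tr)
  sd <- apply(tr, 1L, stats::sd)
  sd[sd < 1e-12] <- 1
  ds$segments <- lapply(ds$segments, function(s) {
    s$data <- (s$data - mu) / sd
    s
  })
  ds
}
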