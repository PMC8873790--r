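# Synthetic motor-imagery-like EEG and small random graphs.
#
# Emulates the regime of the public 64-channel 160 Hz four-class imagery
# recordings: each class is a band-limited oscillation with a class-specific
# spatial mixing pattern, amplitude-modulated by a raised-cosine envelope,
# buried in white or 1/f noise at a configurable linear SNR. The generator
# exists so the whole pipeline is testable without any download; it makes no
# claim of physiological realism (no volume conduction, no artifacts).

#' Specification for the synthetic EEG generator
#'
#' Defaults mirror the study conditions: 64 channels, 160 Hz, 4-s trials,
#' four balanced classes, 50 trials per class, SNR 1 with pink noise. Each
#' class oscillates in its own narrow band (defaults 9-11, 11-13, 19-21 and
#' 25-27 Hz, i.e. mu/beta-range rhythms) through a class-specific random
#' spatial pattern drawn once from `seed`.
#'
#' @param n_channels,fs,trial_seconds,n_trials_per_class recording geometry.
#' @param class_bands list of 4 numeric `c(lo, hi)` bands in Hz.
#' @param snr linear signal-to-noise power ratio; 0 means pure noise
#'   (signal amplitude zero), `Inf` means noiseless.
#' @param noise_model `"pink"` (1/f amplitude shaping) or `"white"`.
#' @param seed RNG seed controlling patterns, phases and noise.
#' @return object of class `synth_spec`.
#' @export
synth_spec <- function(n_channels = 64, fs = 160, trial_seconds = 4,
                       n_trials_per_class = 50,
                       class_bands = list(c(9, 11), c(11, 13),
                                          c(19, 21), c(25, 27)),
                       snr = 1, noise_model = c("pink", "white"),
                       seed = 7) {
  noise_model <- match.arg(noise_model)
  stopifnot(snr >= 0, length(class_bands) == 4)
  for (b in class_bands) {
    if (b[2] >= fs / 2 || b[1] <= 0) stop("class band outside (0, fs/2)")
  }
  structure(list(n_channels = n_channels, fs = fs,
                 trial_seconds = trial_seconds,
                 n_trials_per_class = n_trials_per_class,
                 class_bands = class_bands, snr = snr,
                 noise_model = noise_model, seed = seed),
            class = "synth_spec")
}

# 1/f-amplitude ("pink") noise of length n, unit variance.
pink_noise <- function(n) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- c(1, seq_len(n - 1))                # DC treated as f = 1
  f <- pmin(f, n - f + 1)                  # mirror for negative frequencies
  x <- Re(stats::fft(W / f, inverse = TRUE)) / n
  (x - mean(x)) / stats::sd(x)
}

# Raised-cosine amplitude envelope over the trial with partial modulation
# depth: the class oscillation waxes and wanes but never vanishes, so every
# within-trial segment carries class signal (a full-depth envelope would
# leave the first and last segments signal-free, breaking the generator's
# noiseless-limit contract that each segment equals its spatially mixed
# class template).
raised_cosine <- function(n, depth = 0.5) {
  (1 - depth) + depth * 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
}

#' Generate one synthetic multi-trial recording
#'
#' All trials are concatenated into a single continuous recording with one
#' annotation per trial (code = class label), so the result exercises the
#' same extraction path as real EDF data.
#'
#' @param spec a [synth_spec()].
#' @param subject_id identifier stamped on the recording.
#' @return a [raw_recording].
#' @export
generate_recording <- function(spec, subject_id = "synth01") {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(spec$seed))

  n_ch <- spec$n_channels
  n_t <- as.integer(round(spec$trial_seconds * spec$fs))
  n_classes <- length(spec$class_bands)
  n_trials <- n_classes * spec$n_trials_per_class

  # class-specific spatial mixing patterns, unit norm
  patterns <- lapply(seq_len(n_classes), function(k) {
    v <- stats::rnorm(n_ch)
    v / sqrt(sum(v^2))
  })

  labels <- sample(rep(MI_CLASSES[seq_len(n_classes)],
                       spec$n_trials_per_class))
  env <- raised_cosine(n_t)
  tt <- (seq_len(n_t) - 1) / spec$fs
  signal <- matrix(0, n_ch, n_trials * n_t)
  for (i in seq_len(n_trials)) {
    k <- match(labels[i], MI_CLASSES)
    band <- spec$class_bands[[k]]
    freq <- stats::runif(1, band[1], band[2])
    phase <- stats::runif(1, 0, 2 * pi)
    osc <- sin(2 * pi * freq * tt + phase) * env
    clean <- outer(patterns[[k]], osc)             # n_ch x n_t
    if (spec$snr == 0) clean <- clean * 0
    sig_rms <- sqrt(mean(clean^2))
    noise <- matrix(0, n_ch, n_t)
    if (is.finite(spec$snr)) {
      for (ch in seq_len(n_ch)) {
        noise[ch, ] <- if (spec$noise_model == "pink") pink_noise(n_t)
                       else stats::rnorm(n_t)
      }
      noise_sd <- if (spec$snr > 0) sig_rms / sqrt(spec$snr) else 1
      noise <- noise * noise_sd
    }
    cols <- ((i - 1L) * n_t + 1L):(i * n_t)
    signal[, cols] <- clean + noise
  }
  ann <- data.frame(onset = (seq_len(n_trials) - 1L) * spec$trial_seconds,
                    duration = spec$trial_seconds, code = labels,
                    stringsAsFactors = FALSE)
  raw_recording(signal, spec$fs,
                sprintf("SYN%03d", seq_len(n_ch)), ann,
                subject_id = subject_id, run_id = "synth")
}

#' Generate a segmented synthetic dataset
#'
#' Runs the standard extraction path (trial events, then fixed windows) on a
#' [generate_recording()] output.
#'
#' @param spec a [synth_spec()].
#' @param segment_seconds,stride_seconds window geometry passed to
#'   [segment_trial()].
#' @return a [segment_dataset()].
#' @export
generate_dataset <- function(spec, segment_seconds = 0.4,
                             stride_seconds = segment_seconds) {
  rec <- generate_recording(spec)
  trials <- extract_trials(rec, identity_task_map(),
                           trial_seconds = spec$trial_seconds)
  segs <- list()
  for (i in seq_len(nrow(trials))) {
    segs <- c(segs, segment_trial(rec, trials[i, ], segment_seconds,
                                  stride_seconds,
                                  trial_id = sprintf("t%04d", i)))
  }
  segment_dataset(segs)
}

#' Write a synthetic recording to EDF
#'
#' @param spec a [synth_spec()].
#' @param path output EDF path.
#' @param subject_id identifier.
#' @return the path, invisibly.
#' @export
write_synth_edf <- function(spec, path, subject_id = "synth01") {
  rec <- generate_recording(spec, subject_id)
  write_edf(path, rec$signal, rec$fs, rec$channel_names, rec$annotations)
}

#' Random weighted graph fixture
#'
#' Symmetric nonnegative weights in [0, 1] with a zero diagonal — the same
#' invariants as the feature-graph adjacency |P| - I — for exercising the
#' Laplacian, filtering and coarsening code on arbitrary graphs.
#'
#' @param n_nodes number of nodes (>= 2).
#' @param seed RNG seed.
#' @param p_edge probability that a node pair is connected.
#' @return an `n_nodes` x `n_nodes` weight matrix.
#' @export
generate_random_graph <- function(n_nodes, seed = 1, p_edge = 0.8) {
  stopifnot(n_nodes >= 2)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  W <- matrix(0, n_nodes, n_nodes)
  ut <- upper.tri(W)
  w <- stats::runif(sum(ut)) * (stats::runif(sum(ut)) < p_edge)
  W[ut] <- w
  W + t(W)
}
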