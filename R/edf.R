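# Minimal EDF+C (16-bit European Data Format) I/O with EDF+ annotations.
#
# Covers exactly what the pipeline needs: continuous multichannel records at a
# single sampling rate plus a "EDF Annotations" channel carrying event TALs
# (time-stamped annotation lists). Signals are stored as int16 with per-channel
# physical scaling, so a write/read round trip is exact up to the format's
# 16-bit quantization of the channel's physical range.

pad_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x, type = "bytes") > width) x <- substr(x, 1L, width)
  formatC(x, width = -width, flag = " ")
}

num_field <- function(x, width) {
  s <- formatC(x, format = "fg", width = -1, digits = 8)
  if (nchar(s) > width) s <- substr(s, 1L, width)
  pad_field(s, width)
}

#' Write a multichannel recording to an EDF+C file
#'
#' @param path output file path.
#' @param signal channels x samples numeric matrix (physical units, e.g. uV).
#' @param fs sampling rate in Hz. Total samples per channel must be a whole
#'   number of 1-second data records; the signal is zero-padded to the next
#'   full second with a warning otherwise.
#' @param channel_names character vector, one label per row of `signal`.
#' @param annotations data.frame with columns `onset` (seconds), `duration`
#'   (seconds) and `code` (character), or NULL for none.
#' @return `path`, invisibly.
#' @export
write_edf <- function(path, signal, fs, channel_names,
                      annotations = NULL) {
  stopifnot(is.matrix(signal), nrow(signal) == length(channel_names), fs > 0)
  n_ch <- nrow(signal)
  n_samp <- ncol(signal)
  rec_samp <- as.integer(round(fs))        # 1-second records
  if (n_samp %% rec_samp != 0L) {
    pad <- rec_samp - n_samp %% rec_samp
    warning("signal padded with ", pad, " zero samples to fill the last 1-s record")
    signal <- cbind(signal, matrix(0, n_ch, pad))
    n_samp <- ncol(signal)
  }
  n_rec <- n_samp %/% rec_samp

  # per-channel physical scaling to the full int16 range
  pmin <- apply(signal, 1L, min)
  pmax <- apply(signal, 1L, max)
  flat <- pmax - pmin < 1e-12
  pmin[flat] <- pmin[flat] - 1
  pmax[flat] <- pmax[flat] + 1
  dmin <- -32768; dmax <- 32767

  # annotation TALs grouped by the record containing their onset
  ann_by_rec <- vector("list", n_rec)
  if (!is.null(annotations) && nrow(annotations) > 0) {
    for (i in seq_len(nrow(annotations))) {
      on <- annotations$onset[i]
      rec <- min(max(floor(on), 0), n_rec - 1L) + 1L
      tal <- paste0(sprintf("%+g", on), "\x15", sprintf("%g", annotations$duration[i]),
                    "\x14", annotations$code[i], "\x14")
      ann_by_rec[[rec]] <- c(ann_by_rec[[rec]], tal)
    }
  }
  rec_ann_bytes <- vapply(seq_len(n_rec), function(r) {
    ts <- paste0(sprintf("%+d", r - 1L), "\x14\x14")   # record timestamp TAL
    tals <- c(ts, ann_by_rec[[r]])                     # each NUL-terminated
    sum(nchar(tals, type = "bytes") + 1L)
  }, integer(1))
  ann_samp <- as.integer(ceiling(max(rec_ann_bytes, 16L) / 2))  # int16 "samples"

  ns <- n_ch + 1L                          # + annotations channel
  header_bytes <- 256L + 256L * ns

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, eos = NULL)
  wr(pad_field("0", 8))
  wr(pad_field("X X X X", 80))
  wr(pad_field("Startdate X X X X", 80))
  wr(pad_field("01.01.00", 8))
  wr(pad_field("00.00.00", 8))
  wr(pad_field(header_bytes, 8))
  wr(pad_field("EDF+C", 44))
  wr(pad_field(n_rec, 8))
  wr(num_field(1, 8))                      # record duration: 1 s
  wr(pad_field(ns, 4))
  labels <- c(channel_names, "EDF Annotations")
  for (l in labels) wr(pad_field(l, 16))
  for (l in labels) wr(pad_field("", 80))
  wr(pad_field("uV", 8)); for (i in seq_len(n_ch - 1L)) wr(pad_field("uV", 8))
  wr(pad_field("", 8))
  for (i in seq_len(n_ch)) wr(num_field(pmin[i], 8)); wr(num_field(-1, 8))
  for (i in seq_len(n_ch)) wr(num_field(pmax[i], 8)); wr(num_field(1, 8))
  for (i in seq_len(ns)) wr(pad_field(dmin, 8))
  for (i in seq_len(ns)) wr(pad_field(dmax, 8))
  for (i in seq_len(ns)) wr(pad_field("", 80))
  for (i in seq_len(n_ch)) wr(pad_field(rec_samp, 8)); wr(pad_field(ann_samp, 8))
  for (i in seq_len(ns)) wr(pad_field("", 32))

  scale <- (dmax - dmin) / (pmax - pmin)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * rec_samp + 1L):(r * rec_samp)
    for (ch in seq_len(n_ch)) {
      dig <- round((signal[ch, cols] - pmin[ch]) * scale[ch]) + dmin
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con, size = 2L,
               endian = "little")
    }
    tals <- c(paste0(sprintf("%+d", r - 1L), "\x14\x14"), ann_by_rec[[r]])
    raw_tal <- unlist(lapply(tals, function(s) c(charToRaw(s), as.raw(0L))))
    raw_tal <- c(raw_tal, raw(ann_samp * 2L - length(raw_tal)))
    writeBin(raw_tal, con)
  }
  invisible(path)
}

#' Read an EDF/EDF+ file
#'
#' Parses the header, all ordinary signals (rescaled to physical units) and
#' any "EDF Annotations" channels (TAL event lists).
#'
#' @param path path to an EDF file.
#' @return list with `signal` (channels x samples matrix), `fs`,
#'   `channel_names`, and `annotations` (data.frame onset/duration/code).
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) {
    s <- readChar(con, n, useBytes = TRUE)
    if (length(s) == 0) stop("unexpected end of EDF header in ", path)
    trimws(s)
  }
  version <- rd(8)
  if (version != "0") stop("not an EDF file (version field '", version, "')")
  rd(80); rd(80); rd(8); rd(8)
  rd(8)                                      # header bytes (recomputed below)
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1L) stop("EDF file declares no signals")
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  pmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(ns)) rd(80)
  nsamp <- vapply(seq_len(ns), function(i) as.integer(rd(8)), integer(1))
  for (i in seq_len(ns)) rd(32)

  is_ann <- labels == "EDF Annotations"
  sig_idx <- which(!is_ann)
  sig <- lapply(sig_idx, function(i) numeric(n_rec * nsamp[i]))
  names(sig) <- as.character(sig_idx)
  ann_raw <- list()
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      if (is_ann[i]) {
        ann_raw[[length(ann_raw) + 1L]] <- readBin(con, raw(),
                                                   n = 2L * nsamp[i])
        next
      }
      raw_vals <- readBin(con, integer(), n = nsamp[i], size = 2L,
                          endian = "little", signed = TRUE)
      {
        phys <- (raw_vals - dmin[i]) * (pmax[i] - pmin[i]) /
                (dmax[i] - dmin[i]) + pmin[i]
        k <- as.character(i)
        sig[[k]][((r - 1L) * nsamp[i] + 1L):(r * nsamp[i])] <- phys
      }
    }
  }

  ann <- parse_tals(do.call(c, c(list(raw(0)), ann_raw)))
  fs <- if (length(sig_idx)) nsamp[sig_idx[1]] / rec_dur else NA_real_
  signal <- if (length(sig_idx)) do.call(rbind, sig) else
    matrix(numeric(0), 0, 0)
  dimnames(signal) <- NULL
  list(signal = signal, fs = fs,
       channel_names = labels[sig_idx], annotations = ann,
       n_records = n_rec, record_duration = rec_dur)
}

# Split a raw TAL byte stream into (onset, duration, code) rows.
# Record-timestamp TALs (empty annotation text) are dropped.
parse_tals <- function(bytes) {
  nul <- which(bytes == as.raw(0L))
  starts <- c(1L, nul + 1L)
  ends <- c(nul - 1L, length(bytes))
  tals <- character(0)
  for (k in seq_along(starts)) {
    if (starts[k] <= ends[k]) {
      tals <- c(tals, rawToChar(bytes[starts[k]:ends[k]]))
    }
  }
  out <- list()
  for (tal in tals) {
    if (!nzchar(tal)) next
    parts <- strsplit(tal, "\x14", fixed = TRUE)[[1]]
    if (length(parts) < 2L || !nzchar(paste0(parts[-1], collapse = ""))) next
    head <- strsplit(parts[1], "\x15", fixed = TRUE)[[1]]
    onset <- as.numeric(head[1])
    duration <- if (length(head) > 1L) as.numeric(head[2]) else 0
    for (code in parts[-1]) {
      if (!nzchar(code)) next
      out[[length(out) + 1L]] <- data.frame(onset = onset, duration = duration,
                                            code = code,
                                            stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(onset = numeric(0), duration = numeric(0),
                      code = character(0), stringsAsFactors = FALSE))
  }
  ann <- do.call(rbind, out)
  ann[order(ann$onset), , drop = FALSE]
}
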