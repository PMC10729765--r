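# Minimal EDF (European Data Format) reader/writer: fixed-layout ASCII
# header, one set of per-signal header fields, then data records of 16-bit
# little-endian samples with per-signal linear calibration. Continuous
# recordings only; annotation signals are not supported.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width, flag = " ")
}

edf_num <- function(x, width) {
  for (d in seq(7, 1)) {
    s <- formatC(x, width = 1, format = "g", digits = d)
    if (nchar(s) <= width) return(edf_pad(s, width))
  }
  stop("cannot represent ", x, " in ", width, " EDF header characters",
       call. = FALSE)
}

#' Write a recording as 16-bit EDF
#'
#' Samples are linearly quantized per channel to the int16 range between
#' the channel's physical minimum and maximum (microvolts); the
#' quantization step is `(max - min) / 65535`. Data records are 1 s long,
#' so the sampling rate must be a positive integer; a trailing partial
#' second is dropped with a warning.
#'
#' @param rec An [eeg_recording()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @seealso [read_edf()]
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9 || fs < 1) {
    stop("EDF writer requires an integer sampling rate (1-s data records)",
         call. = FALSE)
  }
  fs <- as.integer(round(fs))
  n <- ncol(rec$data)
  n_rec <- n %/% fs
  if (n_rec < 1L) stop("recording shorter than one 1-s data record",
                       call. = FALSE)
  if (n_rec * fs < n) {
    warning(sprintf("dropping trailing %d samples (< 1 data record)",
                    n - n_rec * fs))
  }
  ns <- nrow(rec$data)
  pmin_ <- apply(rec$data, 1, min)
  pmax_ <- apply(rec$data, 1, max)
  flat <- pmax_ - pmin_ < 1e-12
  pmax_[flat] <- pmin_[flat] + 1  # avoid zero calibration span
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr_bytes <- 256L + 256L * ns
  header <- paste0(
    edf_pad("0", 8), edf_pad("X X X X", 80),
    edf_pad("Startdate 01-JAN-2000 X X X", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_num(hdr_bytes, 8), edf_pad("", 44),
    edf_num(n_rec, 8), edf_num(1, 8), edf_num(ns, 4))
  field <- function(vals, width) paste(
    vapply(vals, edf_pad, "", width = width), collapse = "")
  header <- paste0(header,
    field(rec$channel_names, 16),
    field(rep("", ns), 80),
    field(rep("uV", ns), 8),
    paste(vapply(pmin_, edf_num, "", width = 8), collapse = ""),
    paste(vapply(pmax_, edf_num, "", width = 8), collapse = ""),
    field(rep(dmin, ns), 8),
    field(rep(dmax, ns), 8),
    field(rep("", ns), 80),
    field(rep(fs, ns), 8),
    field(rep("", ns), 32))
  writeChar(header, con, eos = NULL, useBytes = TRUE)

  scale <- (dmax - dmin) / (pmax_ - pmin_)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    block <- t(rec$data[, idx, drop = FALSE])  # samples x channels
    dig <- round(sweep(block, 2, pmin_, "-") %*% diag(scale, ns) + dmin)
    dig <- pmin(pmax(dig, dmin), dmax)
    writeBin(as.integer(as.vector(dig)), con, size = 2L, endian = "little")
  }
  invisible(path)
}

read_edf_str <- function(con, width, n = 1L) {
  raw <- readChar(con, rep(width, n), useBytes = TRUE)
  trimws(raw)
}

#' Read an EDF recording
#'
#' Loads every signal with its per-channel linear calibration applied
#' (digital to physical units). All signals must share one sampling rate;
#' mixed rates are rejected.
#'
#' @param path Path to an EDF file.
#' @return An [eeg_recording()] in the file's physical units.
#' @seealso [write_edf()]
#' @export
read_edf <- function(path) {
  size <- file.info(path)$size
  if (is.na(size) || size < 256) {
    stop("not a valid EDF file (missing or truncated header): ", path,
         call. = FALSE)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  version <- read_edf_str(con, 8)
  if (version != "0") stop("unreadable EDF header (version field '",
                           version, "')", call. = FALSE)
  invisible(read_edf_str(con, 80, 2))     # patient / recording id
  invisible(read_edf_str(con, 8, 2))      # date / time
  hdr_bytes <- as.integer(read_edf_str(con, 8))
  invisible(read_edf_str(con, 44))
  n_rec <- as.integer(read_edf_str(con, 8))
  rec_dur <- as.numeric(read_edf_str(con, 8))
  ns <- as.integer(read_edf_str(con, 4))
  if (is.na(ns) || ns < 1) stop("EDF file declares no signals", call. = FALSE)
  if (is.na(n_rec) || n_rec < 1) {
    stop("EDF file contains zero data records", call. = FALSE)
  }
  if (size < 256 + 256 * ns) {
    stop("EDF header truncated: file declares ", ns,
         " signals but is only ", size, " bytes", call. = FALSE)
  }
  labels <- read_edf_str(con, 16, ns)
  invisible(read_edf_str(con, 80, ns))    # transducer
  invisible(read_edf_str(con, 8, ns))     # physical dimension
  pmin_ <- as.numeric(read_edf_str(con, 8, ns))
  pmax_ <- as.numeric(read_edf_str(con, 8, ns))
  dmin <- as.numeric(read_edf_str(con, 8, ns))
  dmax <- as.numeric(read_edf_str(con, 8, ns))
  invisible(read_edf_str(con, 80, ns))    # prefiltering
  spr <- as.integer(read_edf_str(con, 8, ns))
  invisible(read_edf_str(con, 32, ns))

  rates <- unique(spr / rec_dur)
  if (length(rates) > 1) {
    stop("EDF signals have differing sampling rates: ",
         paste(sort(rates), collapse = " vs "), " Hz", call. = FALSE)
  }
  fs <- rates[1]
  seek(con, hdr_bytes)
  total <- sum(spr) * n_rec
  dig <- readBin(con, "integer", n = total, size = 2L, endian = "little")
  if (length(dig) < total) {
    stop("EDF data section truncated (expected ", total, " samples, got ",
         length(dig), ")", call. = FALSE)
  }
  data <- matrix(0, nrow = ns, ncol = spr[1] * n_rec)
  pos <- 0L
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      chunk <- dig[(pos + 1L):(pos + spr[s])]
      pos <- pos + spr[s]
      phys <- (chunk - dmin[s]) * (pmax_[s] - pmin_[s]) / (dmax[s] - dmin[s]) +
        pmin_[s]
      data[s, ((r - 1L) * spr[s] + 1L):(r * spr[s])] <- phys
    }
  }
  eeg_recording(data, fs, labels)
}

#' Plain-text recording round-trip (TSV)
#'
#' Samples x channels with a header row of channel names; the sampling
#' rate is stored in a `# fs=<Hz>` comment on the first line.
#'
#' @param rec An [eeg_recording()].
#' @param path File path.
#' @return `write_eeg_tsv()` returns `path` invisibly; `read_eeg_tsv()` an
#'   [eeg_recording()].
#' @export
write_eeg_tsv <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%.10g", rec$fs), con)
  df <- as.data.frame(t(rec$data))
  names(df) <- rec$channel_names
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_eeg_tsv
#' @export
read_eeg_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  if (!grepl("^# fs=", first)) {
    stop("TSV recording must start with a '# fs=<Hz>' line", call. = FALSE)
  }
  fs <- as.numeric(sub("^# fs=", "", first))
  df <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1L,
                          check.names = FALSE)
  eeg_recording(t(as.matrix(df)), fs, names(df))
}
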