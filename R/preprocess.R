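# Channel label dialects differ between EDF exports ("EEG Fp1-REF",
# "FP1", ...); matching is case-insensitive after stripping the common
# affixes.
normalize_label <- function(x) {
  x <- sub("^\\s*EEG[ _]", "", x, ignore.case = TRUE)
  x <- sub("[-_ ](REF|LE|AVG|A1|A2)\\s*$", "", x, ignore.case = TRUE)
  toupper(trimws(x))
}

#' Select and reorder channels
#'
#' Returns the recording restricted to the requested channels, in the
#' requested order. Matching is case-insensitive and tolerant of common
#' EDF label affixes (`"EEG "` prefix, `"-REF"` suffix and similar).
#'
#' @param rec An [eeg_recording()].
#' @param names Character vector of channel names to keep, in output order.
#' @return An [eeg_recording()] whose channels are exactly `names`.
#' @examples
#' rec <- simulate_recording(4, 100, 2, seed = 1,
#'                           channel_names = c("Fp1", "Fp2", "C3", "C4"))
#' select_channels(rec, c("C4", "Fp1"))
#' @export
select_channels <- function(rec, names) {
  stopifnot(inherits(rec, "eeg_recording"))
  have <- normalize_label(rec$channel_names)
  want <- normalize_label(names)
  idx <- match(want, have)
  if (anyNA(idx)) {
    stop("channel(s) not found in recording: ",
         paste(names[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(idx)) {
    stop("requested channels resolve to duplicate recording channels",
         call. = FALSE)
  }
  eeg_recording(rec$data[idx, , drop = FALSE], rec$fs, names)
}

# Butterworth bandpass design shared by the filter and its analytic
# frequency response.
design_bandpass <- function(band, fs, order = 4L) {
  check_band_fs(band, fs)
  signal::butter(order, c(band$low, band$high) / (fs / 2), type = "pass")
}

#' Zero-phase Butterworth bandpass filter
#'
#' 4th-order Butterworth bandpass applied forward and backward
#' (`signal::filtfilt`), giving zero phase distortion and an effective
#' 8th-order magnitude response. Output length equals input length.
#'
#' @param rec An [eeg_recording()].
#' @param band Target band (object or canonical name).
#' @param order Filter order of each pass.
#' @return Filtered [eeg_recording()].
#' @export
bandpass_filter <- function(rec, band, order = 4L) {
  stopifnot(inherits(rec, "eeg_recording"))
  band <- as_band(band)
  bf <- design_bandpass(band, rec$fs, order)
  out <- t(apply(rec$data, 1, function(x) signal::filtfilt(bf, x)))
  eeg_recording(out, rec$fs, rec$channel_names)
}

#' Magnitude response of the zero-phase bandpass
#'
#' Evaluates `|H(f)|^2` of the forward-backward Butterworth filter used by
#' [bandpass_filter()] at the given frequencies — the steady-state gain a
#' sinusoid at `f` experiences.
#'
#' @param band Target band.
#' @param fs Sampling rate in Hz.
#' @param f Frequencies (Hz) at which to evaluate.
#' @param order Filter order of each pass.
#' @return Numeric vector of gains.
#' @export
bandpass_gain <- function(band, fs, f, order = 4L) {
  band <- as_band(band)
  bf <- design_bandpass(band, fs, order)
  vapply(f, function(fi) {
    zi <- exp(-1i * 2 * pi * fi / fs)
    h <- sum(bf$b * zi^(seq_along(bf$b) - 1)) /
      sum(bf$a * zi^(seq_along(bf$a) - 1))
    Mod(h)^2
  }, 0)
}

#' Common average reference
#'
#' Subtracts the instantaneous mean across channels from every channel, so
#' the per-sample channel mean of the output is zero. Idempotent.
#'
#' @param rec An [eeg_recording()] with at least two channels.
#' @return Re-referenced [eeg_recording()].
#' @export
rereference_average <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (nrow(rec$data) < 2L) {
    stop("average reference requires at least two channels", call. = FALSE)
  }
  out <- sweep(rec$data, 2, colMeans(rec$data), "-")
  eeg_recording(out, rec$fs, rec$channel_names)
}

#' Cut a recording into fixed-length non-overlapping epochs
#'
#' Epochs start at sample 1 and are consecutive; a trailing remainder
#' shorter than one epoch is dropped.
#'
#' @param rec An [eeg_recording()].
#' @param epoch_length Epoch length in seconds (default 2).
#' @param band_name Band label carried on the result.
#' @return An [eeg_epochs()] block (epochs x channels x samples).
#' @examples
#' rec <- simulate_recording(2, 100, 5, seed = 1)
#' segment_epochs(rec, 2)  # 2 epochs; 100 samples dropped
#' @export
segment_epochs <- function(rec, epoch_length = 2, band_name = "full") {
  stopifnot(inherits(rec, "eeg_recording"))
  spe <- epoch_length * rec$fs
  if (abs(spe - round(spe)) > 1e-9) {
    stop("epoch_length * fs must be an integer sample count", call. = FALSE)
  }
  spe <- as.integer(round(spe))
  n <- ncol(rec$data)
  n_ep <- n %/% spe
  if (n_ep < 1L) {
    stop(sprintf("recording (%g s) is shorter than one epoch (%g s)",
                 n / rec$fs, epoch_length), call. = FALSE)
  }
  used <- rec$data[, seq_len(n_ep * spe), drop = FALSE]
  # epochs x channels x samples
  arr <- aperm(array(used, dim = c(nrow(used), spe, n_ep)), c(3, 1, 2))
  eeg_epochs(arr, rec$fs, epoch_length, rec$channel_names, band_name)
}
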