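#' Multichannel EEG recording container
#'
#' Holds a continuous multichannel recording as a channels x samples matrix
#' of physical values (microvolts), its sampling rate, and ordered channel
#' names. All preprocessing functions take and return this container.
#'
#' @param data Numeric matrix, channels x samples.
#' @param fs Sampling rate in Hz.
#' @param channel_names Character vector, one name per row of `data`.
#' @return An `eeg_recording` object.
#' @examples
#' rec <- eeg_recording(matrix(rnorm(200), 2), fs = 100, c("C3", "C4"))
#' rec
#' @export
eeg_recording <- function(data, fs, channel_names) {
  if (!is.matrix(data) || !is.numeric(data)) {
    stop("data must be a numeric channels x samples matrix", call. = FALSE)
  }
  if (anyNA(data) || any(!is.finite(data))) {
    stop("recording contains non-finite samples", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("fs must be a single positive number", call. = FALSE)
  }
  channel_names <- as.character(channel_names)
  if (length(channel_names) != nrow(data)) {
    stop("length of channel_names (", length(channel_names),
         ") must equal the number of data rows (", nrow(data), ")",
         call. = FALSE)
  }
  rownames(data) <- channel_names
  structure(list(data = data, fs = fs, channel_names = channel_names),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
    nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  cat("  channels:", paste(utils::head(x$channel_names, 8), collapse = ", "),
      if (length(x$channel_names) > 8) "..." else "", "\n")
  invisible(x)
}

#' Number of samples / duration helpers
#' @param x An `eeg_recording`.
#' @return `n_samples()` the sample count; `duration()` seconds.
#' @export
n_samples <- function(x) ncol(x$data)

#' @rdname n_samples
#' @export
duration <- function(x) ncol(x$data) / x$fs

#' @method as_tibble eeg_recording
#' @export
as_tibble.eeg_recording <- function(x, ...) {
  tibble::tibble(
    time = rep(seq_len(ncol(x$data)) / x$fs, each = nrow(x$data)),
    channel = rep(x$channel_names, times = ncol(x$data)),
    value = as.vector(x$data)
  )
}

#' Epoched EEG recording
#'
#' A block of fixed-length non-overlapping epochs cut from a continuous
#' recording: an epochs x channels x samples array plus the sampling rate,
#' epoch length, channel names and the band label of the signal it holds.
#'
#' @param data Numeric array, epochs x channels x samples.
#' @param fs Sampling rate in Hz.
#' @param epoch_length Epoch length in seconds.
#' @param channel_names Character vector of channel names.
#' @param band_name Label of the frequency band the data was filtered to
#'   (`"full"` for broadband).
#' @return An `eeg_epochs` object.
#' @export
eeg_epochs <- function(data, fs, epoch_length, channel_names,
                       band_name = "full") {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (dim(data)[3] != round(epoch_length * fs)) {
    stop("samples per epoch must equal epoch_length * fs exactly",
         call. = FALSE)
  }
  if (dim(data)[2] != length(channel_names)) {
    stop("channel dimension does not match channel_names", call. = FALSE)
  }
  structure(list(data = data, fs = fs, epoch_length = epoch_length,
                 channel_names = as.character(channel_names),
                 band_name = band_name),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<eeg_epochs> %d epochs x %d channels x %d samples @ %g Hz (%g-s epochs, band %s)\n",
    d[1], d[2], d[3], x$fs, x$epoch_length, x$band_name))
  invisible(x)
}

#' @export
n_epochs <- function(x) UseMethod("n_epochs")

#' Number of epochs in an epoched object
#' @param x An `eeg_epochs` or `wpli_connectivity` object.
#' @export
n_epochs.eeg_epochs <- function(x) dim(x$data)[1]
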