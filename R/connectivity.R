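#' Analytic signal via the Hilbert transform
#'
#' Returns the complex analytic signal of a real series: real part equal to
#' the input, imaginary part its Hilbert transform. Computed in the Fourier
#' domain by zeroing negative-frequency components (positive frequencies
#' doubled; DC and Nyquist kept as-is).
#'
#' @param x Finite real numeric vector.
#' @return Complex vector of the same length.
#' @examples
#' z <- analytic_signal(cos(2 * pi * 0.1 * (0:99)))
#' all.equal(Re(z), cos(2 * pi * 0.1 * (0:99)))
#' @export
analytic_signal <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop("analytic_signal requires finite real input", call. = FALSE)
  }
  n <- length(x)
  h <- rep(0, n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    if (n > 1) h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

# Analytic signals of all channels of one epoch (channels x samples).
analytic_epoch <- function(m) {
  n <- ncol(m)
  h <- rep(0, n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    if (n > 1) h[2:((n + 1) / 2)] <- 2
  }
  t(stats::mvfft(stats::mvfft(t(m)) * h, inverse = TRUE)) / n
}

#' Weighted phase lag index of two analytic signals
#'
#' The wPLI weights the sign of each phase difference by the magnitude of
#' the imaginary part of the cross-spectrum: with `Y(t) = a_i(t) *
#' Conj(a_j(t))`, the statistic is `|mean(Im Y)| / mean(|Im Y|)` over time
#' samples. It lies in `[0, 1]`, is 0 for purely zero-lag (volume-
#' conduction-like) coupling, and 1 when the imaginary cross-spectrum never
#' changes sign. When every `Im Y` term vanishes the index is defined as 0
#' (no evidence of lagged synchronization).
#'
#' @param a_i,a_j Complex analytic signals of equal length (>= 2).
#' @return wPLI value in `[0, 1]`.
#' @examples
#' z <- analytic_signal(rnorm(512))
#' wpli_pair(z, z)                    # zero lag -> 0
#' wpli_pair(z, z * exp(1i * pi / 2)) # quarter-cycle rotation -> 1
#' @export
wpli_pair <- function(a_i, a_j) {
  if (length(a_i) != length(a_j)) {
    stop("analytic signals must have equal length", call. = FALSE)
  }
  if (length(a_i) < 2L) stop("need at least 2 samples", call. = FALSE)
  im_y <- Im(a_i * Conj(a_j))
  den <- mean(abs(im_y))
  if (den == 0) return(0)
  abs(mean(im_y)) / den
}

#' Epoch-resolved wPLI connectivity of an epoched recording
#'
#' For every epoch, computes the analytic signal of each channel and the
#' wPLI of every unordered channel pair; the subject-level matrix is the
#' mean over epochs. The first and last `edge_trim` fraction of samples of
#' each epoch are excluded from the expectation to suppress Hilbert edge
#' artifacts.
#'
#' @param epochs An [eeg_epochs()] block with >= 1 epoch and >= 2 channels.
#' @param edge_trim Fraction of samples trimmed from each epoch end
#'   (default 0.05).
#' @return A `wpli_connectivity` object: `weights` (channels x channels,
#'   symmetric, zero diagonal, entries in `[0, 1]`), `epoch_stack`
#'   (epochs x channels x channels), `band_name`, `n_epochs`,
#'   `channel_names`.
#' @export
wpli_matrix <- function(epochs, edge_trim = 0.05) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  d <- dim(epochs$data)
  if (d[1] < 1L) stop("empty epoch stack", call. = FALSE)
  if (d[2] < 2L) stop("wPLI needs at least two channels", call. = FALSE)
  n_ep <- d[1]; n_ch <- d[2]; n_s <- d[3]
  trim <- floor(edge_trim * n_s)
  keep <- (trim + 1L):(n_s - trim)
  pairs <- utils::combn(n_ch, 2)
  stack <- array(0, dim = c(n_ep, n_ch, n_ch))
  for (e in seq_len(n_ep)) {
    z <- analytic_epoch(epochs$data[e, , , drop = TRUE])[, keep, drop = FALSE]
    w <- matrix(0, n_ch, n_ch)
    for (k in seq_len(ncol(pairs))) {
      i <- pairs[1, k]; j <- pairs[2, k]
      im_y <- Im(z[i, ] * Conj(z[j, ]))
      den <- mean(abs(im_y))
      w[i, j] <- w[j, i] <- if (den == 0) 0 else abs(mean(im_y)) / den
    }
    stack[e, , ] <- w
  }
  weights <- apply(stack, c(2, 3), mean)
  dimnames(weights) <- list(epochs$channel_names, epochs$channel_names)
  structure(list(weights = weights, epoch_stack = stack,
                 band_name = epochs$band_name, n_epochs = n_ep,
                 channel_names = epochs$channel_names),
            class = "wpli_connectivity")
}

#' @export
print.wpli_connectivity <- function(x, ...) {
  off <- x$weights[upper.tri(x$weights)]
  cat(sprintf(
    "<wpli_connectivity> %d channels, band %s, %d epochs; mean wPLI %.3f\n",
    length(x$channel_names), x$band_name, x$n_epochs, mean(off)))
  invisible(x)
}

#' @export
n_epochs.wpli_connectivity <- function(x) x$n_epochs

#' Tidy a connectivity matrix into an edge table
#'
#' @param x A `wpli_connectivity` object.
#' @param ... Unused.
#' @return A tibble with one row per unordered channel pair: `ch1`, `ch2`,
#'   `edge` (`"ch1--ch2"`), `band`, `wpli`.
#' @method tidy wpli_connectivity
#' @export
tidy.wpli_connectivity <- function(x, ...) {
  n <- length(x$channel_names)
  pairs <- utils::combn(n, 2)
  tibble::tibble(
    ch1 = x$channel_names[pairs[1, ]],
    ch2 = x$channel_names[pairs[2, ]],
    edge = paste(x$channel_names[pairs[1, ]],
                 x$channel_names[pairs[2, ]], sep = "--"),
    band = x$band_name,
    wpli = x$weights[cbind(pairs[1, ], pairs[2, ])]
  )
}

#' @rdname tidy.wpli_connectivity
#' @param x A `wpli_connectivity` object.
#' @return `glance()`: one-row tibble with `band`, `n_channels`, `n_epochs`,
#'   `mean_wpli`.
#' @method glance wpli_connectivity
#' @export
glance.wpli_connectivity <- function(x, ...) {
  tibble::tibble(
    band = x$band_name,
    n_channels = length(x$channel_names),
    n_epochs = x$n_epochs,
    mean_wpli = mean(x$weights[upper.tri(x$weights)])
  )
}

#' Write / read a subject-level connectivity matrix as TSV
#'
#' The matrix is written with channel names as header row and first
#' column; a JSON sidecar (`<path>.json`) stores the band and epoch count.
#' The epoch stack is not persisted.
#'
#' @param x A `wpli_connectivity` object.
#' @param path Output TSV path.
#' @return Invisibly, `path`; `read_connectivity_tsv()` returns a
#'   `wpli_connectivity` with an empty epoch stack.
#' @export
write_connectivity_tsv <- function(x, path) {
  df <- data.frame(channel = x$channel_names, x$weights,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(band = x$band_name, n_epochs = x$n_epochs),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_connectivity_tsv
#' @export
read_connectivity_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE)
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  w <- as.matrix(df[, -1, drop = FALSE])
  dimnames(w) <- list(df$channel, df$channel)
  structure(list(weights = w,
                 epoch_stack = array(w, dim = c(1, nrow(w), nrow(w))),
                 band_name = meta$band, n_epochs = meta$n_epochs,
                 channel_names = df$channel),
            class = "wpli_connectivity")
}
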