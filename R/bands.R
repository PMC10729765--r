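#' Frequency band definitions
#'
#' A band is a named frequency interval in Hz. The canonical clinical bands
#' used throughout the package are delta (0.5--4), theta (4--8), alpha
#' (8--13), beta (13--30) and gamma (30--45), plus the broadband interval
#' `full` (0.5--45) on which the broadband analysis runs.
#'
#' @param name Band label, e.g. `"alpha"`.
#' @param low,high Band edges in Hz, `0 < low < high`.
#' @return A `band` object (list with `name`, `low`, `high`).
#' @examples
#' band("alpha", 8, 13)
#' eeg_bands()
#' @export
band <- function(name, low, high) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(low) || !is.numeric(high) || length(low) != 1L ||
      length(high) != 1L || !is.finite(low) || !is.finite(high)) {
    stop("band edges must be single finite numbers", call. = FALSE)
  }
  if (!(low > 0 && high > low)) {
    stop("band requires 0 < low < high (got [", low, ", ", high, "] Hz)",
         call. = FALSE)
  }
  structure(list(name = name, low = low, high = high), class = "band")
}

#' @rdname band
#' @export
eeg_bands <- function() {
  list(
    delta = band("delta", 0.5, 4),
    theta = band("theta", 4, 8),
    alpha = band("alpha", 8, 13),
    beta  = band("beta", 13, 30),
    gamma = band("gamma", 30, 45),
    full  = band("full", 0.5, 45)
  )
}

#' Resolve a band argument
#'
#' Accepts a `band` object or the name of a canonical band.
#' @param x A `band` or a character name among the canonical bands.
#' @return A `band` object.
#' @keywords internal
as_band <- function(x) {
  if (inherits(x, "band")) return(x)
  if (is.character(x) && length(x) == 1L) {
    bands <- eeg_bands()
    if (x %in% names(bands)) return(bands[[x]])
    stop("unknown band name '", x, "'; known bands: ",
         paste(names(bands), collapse = ", "), call. = FALSE)
  }
  stop("band must be a band object or a canonical band name", call. = FALSE)
}

#' @export
print.band <- function(x, ...) {
  cat(sprintf("<band> %s: %g-%g Hz\n", x$name, x$low, x$high))
  invisible(x)
}

#' Check a band against a sampling rate
#' @keywords internal
check_band_fs <- function(band, fs) {
  if (band$high >= fs / 2) {
    stop(sprintf(
      "band '%s' upper edge %g Hz is not below the Nyquist frequency %g Hz",
      band$name, band$high, fs / 2), call. = FALSE)
  }
  invisible(band)
}

#' Standard 19-electrode montage of the 10-20 system
#'
#' The 19 scalp electrodes used for the network analysis, in the fixed
#' order adopted for all matrices and tables.
#' @return Character vector of 19 channel names.
#' @export
montage_1020 <- function() {
  c("Fp1", "Fp2", "F3", "F4", "F7", "F8", "Fz",
    "T3", "T4", "T5", "T6", "C3", "C4", "Cz",
    "P3", "P4", "Pz", "O1", "O2")
}
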