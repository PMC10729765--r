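#' Band-limited coupling specification
#'
#' Describes one phase-lagged shared source planted between two channels in
#' one frequency band. The band components of the two channels are mixed as
#' `sqrt(1 - strength) * private + sqrt(strength) * shared`, with the second
#' channel's copy of the shared source rotated in the analytic domain by
#' `lag` radians, so that the inter-channel phase lag is constant across the
#' band and the limiting wPLI values are analytic (0 at `strength = 0`,
#' 1 at `strength = 1` for `lag` away from 0 and pi).
#'
#' @param pair Integer vector of length 2: the coupled channel indices.
#' @param band Band (object or canonical name) the coupling lives in.
#' @param lag Phase offset in radians, in `(-pi, pi]`.
#' @param strength Mixing fraction of the shared source, in `[0, 1]`.
#' @return A `coupling_spec` object.
#' @examples
#' coupling_spec(c(1, 2), "alpha", lag = pi / 2, strength = 0.8)
#' @export
coupling_spec <- function(pair, band, lag = pi / 2, strength = 0.5) {
  pair <- as.integer(pair)
  if (length(pair) != 2L || anyNA(pair) || pair[1] == pair[2] ||
      any(pair < 1L)) {
    stop("pair must be two distinct positive channel indices", call. = FALSE)
  }
  if (!is.numeric(lag) || length(lag) != 1L || lag <= -pi || lag > pi) {
    stop("lag must be a single value in (-pi, pi]", call. = FALSE)
  }
  if (!is.numeric(strength) || length(strength) != 1L ||
      strength < 0 || strength > 1) {
    stop("strength must be in [0, 1]", call. = FALSE)
  }
  structure(list(pair = pair, band = as_band(band), lag = lag,
                 strength = strength),
            class = "coupling_spec")
}

# 1/f^exponent background noise by spectral shaping of white noise,
# rescaled to unit variance.
pink_noise <- function(n, fs, exponent = 1) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  freqs <- seq(0, n - 1) * fs / n
  freqs <- pmin(freqs, fs - freqs)  # two-sided
  shape <- rep(0, n)
  pos <- freqs > 0
  shape[pos] <- freqs[pos]^(-exponent / 2)
  y <- Re(stats::fft(X * shape, inverse = TRUE)) / n
  y / stats::sd(y)
}

# Narrowband Gaussian process: white noise restricted to [low, high] Hz by
# Fourier masking, rescaled to unit variance.
narrowband_noise <- function(n, fs, band) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  freqs <- seq(0, n - 1) * fs / n
  freqs <- pmin(freqs, fs - freqs)
  mask <- freqs >= band$low & freqs <= band$high
  if (!any(mask)) {
    stop(sprintf("no Fourier bins fall inside band '%s' for n = %d, fs = %g",
                 band$name, n, fs), call. = FALSE)
  }
  y <- Re(stats::fft(X * mask, inverse = TRUE)) / n
  y / stats::sd(y)
}

# Rotate a real narrowband series by `lag` radians in the analytic domain.
rotate_phase <- function(x, lag) {
  Re(analytic_signal(x) * exp(1i * lag))
}

#' Simulate one multichannel EEG-like recording
#'
#' Each channel is a sum over the five canonical bands of narrowband
#' Gaussian processes plus 1/f background noise. Couplings plant a shared
#' narrowband source in one band between one channel pair, phase-shifted by
#' a fixed lag in the second channel; the mixing fraction `strength`
#' controls how much of the band component is shared (see
#' [coupling_spec()]). Output is deterministic given `seed`.
#'
#' @param n_channels Number of channels.
#' @param fs Sampling rate in Hz.
#' @param duration Duration in seconds; `duration * fs` must be an integer.
#' @param couplings List of [coupling_spec()] objects. Within one band a
#'   channel may take part in at most one coupling.
#' @param noise_exponent Slope of the 1/f background (power ~ 1/f^exponent).
#' @param seed Integer RNG seed; same seed and config give bitwise-identical
#'   output.
#' @param band_amplitudes Named numeric vector of per-band component
#'   amplitudes (standard deviations, before the microvolt scale).
#' @param noise_amplitude Amplitude of the 1/f background.
#' @param scale_uv Overall output scale in microvolts.
#' @param channel_names Optional channel names; defaults to the 10-20
#'   montage when `n_channels` is 19, else `Ch01`, `Ch02`, ...
#' @return An [eeg_recording()].
#' @examples
#' rec <- simulate_recording(4, fs = 250, duration = 10,
#'   couplings = list(coupling_spec(c(1, 2), "alpha", pi / 2, 0.9)),
#'   seed = 1)
#' rec
#' @export
simulate_recording <- function(n_channels, fs, duration,
                               couplings = list(),
                               noise_exponent = 1,
                               seed = 1L,
                               band_amplitudes = c(delta = 1.0, theta = 0.8,
                                                   alpha = 0.8, beta = 0.6,
                                                   gamma = 0.5),
                               noise_amplitude = 1,
                               scale_uv = 20,
                               channel_names = NULL) {
  n <- duration * fs
  if (abs(n - round(n)) > 1e-9) {
    stop("duration * fs must be an integer sample count", call. = FALSE)
  }
  n <- as.integer(round(n))
  bands <- eeg_bands()[c("delta", "theta", "alpha", "beta", "gamma")]
  stopifnot(all(names(bands) %in% names(band_amplitudes)))

  for (cp in couplings) {
    if (!inherits(cp, "coupling_spec")) {
      stop("couplings must be a list of coupling_spec objects", call. = FALSE)
    }
    if (any(cp$pair > n_channels)) {
      stop(sprintf("coupling pair (%d, %d) exceeds n_channels = %d",
                   cp$pair[1], cp$pair[2], n_channels), call. = FALSE)
    }
  }
  # at most one coupling per (channel, band): keeps the variance algebra exact
  keys <- unlist(lapply(couplings, function(cp)
    paste(cp$band$name, cp$pair, sep = ":")))
  if (anyDuplicated(keys)) {
    stop("a channel may take part in at most one coupling per band",
         call. = FALSE)
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(seed))

  data <- matrix(0, nrow = n_channels, ncol = n)
  # fixed draw order: background per channel, then per band private
  # components, then shared sources per coupling (determinism contract)
  for (ch in seq_len(n_channels)) {
    data[ch, ] <- noise_amplitude * pink_noise(n, fs, noise_exponent)
  }
  private <- lapply(names(bands), function(bn) {
    m <- matrix(0, nrow = n_channels, ncol = n)
    for (ch in seq_len(n_channels)) m[ch, ] <- narrowband_noise(n, fs, bands[[bn]])
    m
  })
  names(private) <- names(bands)

  shared_frac <- matrix(0, nrow = n_channels, ncol = length(bands),
                        dimnames = list(NULL, names(bands)))
  for (cp in couplings) {
    bn <- cp$band$name
    if (!bn %in% names(bands)) {
      stop("couplings must use one of the five canonical sub-bands",
           call. = FALSE)
    }
    s <- narrowband_noise(n, fs, bands[[bn]])
    i <- cp$pair[1]; j <- cp$pair[2]
    private[[bn]][i, ] <- sqrt(1 - cp$strength) * private[[bn]][i, ] +
      sqrt(cp$strength) * s
    private[[bn]][j, ] <- sqrt(1 - cp$strength) * private[[bn]][j, ] +
      sqrt(cp$strength) * rotate_phase(s, cp$lag)
    shared_frac[c(i, j), bn] <- cp$strength
  }
  for (bn in names(bands)) {
    data <- data + band_amplitudes[[bn]] * private[[bn]]
  }
  data <- data * scale_uv

  if (is.null(channel_names)) {
    channel_names <- if (n_channels == 19L) montage_1020() else
      sprintf("Ch%02d", seq_len(n_channels))
  }
  eeg_recording(data, fs, channel_names)
}

#' Cohort configuration for the two-group simulator
#'
#' Bundles the study design the simulator emulates: subject counts per
#' group, recording geometry, and per-band coupling strengths for each
#' group. The default `band_effects` encode the direction pattern the
#' pipeline is designed to detect: group A has weaker delta coupling,
#' unchanged theta coupling, and stronger alpha, beta and gamma coupling
#' than group B.
#'
#' @param n_group_a,n_group_b Subject counts (defaults 10 and 5).
#' @param n_channels,fs,duration Recording geometry. The `"study"` preset is
#'   19 channels, 500 Hz, 1200 s; the `"fast"` preset (8 channels, 250 Hz,
#'   120 s) is sized for quick runs.
#' @param band_effects Tibble with columns `band`, `strength_a`,
#'   `strength_b` and list-column `pairs` (each a list of 2-vectors of
#'   channel indices). `NULL` gives the default effect pattern.
#' @param lag Phase lag (radians) used for every planted coupling.
#' @param noise_exponent 1/f slope of the background noise.
#' @param seed Master seed; per-subject sub-seeds are derived from it.
#' @param preset `"fast"` or `"study"`; sets geometry defaults that explicit
#'   arguments override.
#' @return A `cohort_config` object.
#' @examples
#' cohort_config(preset = "fast")
#' @export
cohort_config <- function(n_group_a = 10, n_group_b = 5,
                          n_channels = NULL, fs = NULL, duration = NULL,
                          band_effects = NULL, lag = pi / 2,
                          noise_exponent = 1, seed = 1L,
                          preset = c("fast", "study")) {
  preset <- match.arg(preset)
  geom <- switch(preset,
    study = list(n_channels = 19L, fs = 500, duration = 1200),
    fast  = list(n_channels = 8L, fs = 250, duration = 120))
  n_channels <- if (is.null(n_channels)) geom$n_channels else as.integer(n_channels)
  fs <- if (is.null(fs)) geom$fs else fs
  duration <- if (is.null(duration)) geom$duration else duration
  if (n_group_a < 1 || n_group_b < 1) {
    stop("both groups need at least one subject", call. = FALSE)
  }
  if (abs(duration * fs - round(duration * fs)) > 1e-9) {
    stop("duration * fs must be an integer sample count", call. = FALSE)
  }
  if (is.null(band_effects)) {
    band_effects <- default_band_effects(n_channels)
  }
  stopifnot(all(c("band", "strength_a", "strength_b", "pairs") %in%
                  names(band_effects)))
  if (any(band_effects$strength_a < 0 | band_effects$strength_a > 1 |
          band_effects$strength_b < 0 | band_effects$strength_b > 1)) {
    stop("all coupling strengths must be in [0, 1]", call. = FALSE)
  }
  structure(list(n_group_a = as.integer(n_group_a),
                 n_group_b = as.integer(n_group_b),
                 n_channels = n_channels, fs = fs, duration = duration,
                 band_effects = band_effects, lag = lag,
                 noise_exponent = noise_exponent, seed = as.integer(seed),
                 preset = preset),
            class = "cohort_config")
}

#' Default per-band group effects
#'
#' Disjoint coupled pairs `(1,2), (3,4), ...` are assigned to every
#' sub-band; group A strengths encode the target direction pattern
#' (delta down, theta unchanged, alpha/beta/gamma up relative to group B).
#' @param n_channels Channel count; determines how many disjoint pairs fit
#'   (at most 6).
#' @return A tibble with columns `band`, `strength_a`, `strength_b`, `pairs`.
#' @export
default_band_effects <- function(n_channels) {
  n_pairs <- min(6L, n_channels %/% 2L)
  pairs <- lapply(seq_len(n_pairs), function(k) c(2L * k - 1L, 2L * k))
  tibble::tibble(
    band = c("delta", "theta", "alpha", "beta", "gamma"),
    strength_a = c(0.15, 0.35, 0.55, 0.55, 0.55),
    strength_b = c(0.55, 0.35, 0.15, 0.15, 0.15),
    pairs = list(pairs, pairs, pairs, pairs, pairs)
  )
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(
    "<cohort_config> %d vs %d subjects, %d ch @ %g Hz, %g s (preset %s, seed %d)\n",
    x$n_group_a, x$n_group_b, x$n_channels, x$fs, x$duration, x$preset,
    x$seed))
  print(x$band_effects)
  invisible(x)
}

# Deterministic per-subject sub-seed from the master seed and a subject
# counter; kept below 2^31.
subject_seed <- function(master_seed, index) {
  as.integer((as.numeric(master_seed) %% 1e6) * 2048 + 104729 + index) %%
    .Machine$integer.max
}

#' Simulate a labeled two-group cohort
#'
#' Generates one recording per subject. Group A recordings use
#' `strength_a` for each band effect, group B `strength_b`; every other
#' aspect of the generative model is identical across groups. Per-subject
#' seeds are derived deterministically from the master seed, so any single
#' subject can be regenerated in isolation.
#'
#' @param config A [cohort_config()].
#' @return A tibble with columns `subject_id`, `group` (`"A"`/`"B"`),
#'   `seed`, and list-column `recording` of [eeg_recording()] objects.
#' @examples
#' cfg <- cohort_config(n_group_a = 2, n_group_b = 2, duration = 10,
#'                      preset = "fast")
#' simulate_cohort(cfg)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  groups <- c(rep("A", config$n_group_a), rep("B", config$n_group_b))
  purrr::imap_dfr(groups, function(grp, idx) {
    couplings <- cohort_couplings(config, grp)
    seed_i <- subject_seed(config$seed, idx)
    rec <- simulate_recording(
      n_channels = config$n_channels, fs = config$fs,
      duration = config$duration, couplings = couplings,
      noise_exponent = config$noise_exponent, seed = seed_i)
    tibble::tibble(
      subject_id = sprintf("S%02d", idx), group = grp, seed = seed_i,
      recording = list(rec))
  })
}

# Expand a cohort config into the coupling list for one group.
cohort_couplings <- function(config, group) {
  eff <- config$band_effects
  out <- list()
  for (r in seq_len(nrow(eff))) {
    strength <- if (group == "A") eff$strength_a[r] else eff$strength_b[r]
    for (pair in eff$pairs[[r]]) {
      out[[length(out) + 1L]] <-
        coupling_spec(pair, eff$band[r], lag = config$lag,
                      strength = strength)
    }
  }
  out
}

#' Write a cohort to disk
#'
#' Writes one EDF file per subject plus a JSON manifest
#' (`manifest.json`: subject id, group, seed, file name).
#'
#' @param cohort Tibble from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @param format `"edf"` or `"tsv"`.
#' @return Invisibly, the manifest tibble.
#' @export
write_cohort <- function(cohort, dir, format = c("edf", "tsv")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- format
  manifest <- dplyr::mutate(
    dplyr::select(cohort, "subject_id", "group", "seed"),
    file = paste0(.data$subject_id, ".", ext))
  for (r in seq_len(nrow(cohort))) {
    path <- file.path(dir, manifest$file[r])
    if (format == "edf") write_edf(cohort$recording[[r]], path)
    else write_eeg_tsv(cohort$recording[[r]], path)
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a cohort written by [write_cohort()]
#' @param dir Directory containing `manifest.json` and the recordings.
#' @return Tibble like [simulate_cohort()]'s output.
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  manifest <- tibble::as_tibble(manifest)
  manifest$recording <- lapply(file.path(dir, manifest$file), function(p) {
    if (grepl("\\.edf$", p, ignore.case = TRUE)) read_edf(p)
    else read_eeg_tsv(p)
  })
  manifest
}
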