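#' Preprocess one recording
#'
#' The fixed preprocessing order: optional channel selection, broadband
#' (0.5--45 Hz) zero-phase bandpass, common average reference. Band
#' decomposition and epoching happen downstream in [band_epochs()].
#'
#' @param rec An [eeg_recording()].
#' @param channels Channel names to keep (`NULL` keeps all).
#' @return Preprocessed [eeg_recording()].
#' @export
preprocess_recording <- function(rec, channels = NULL) {
  if (!is.null(channels)) rec <- select_channels(rec, channels)
  rec <- bandpass_filter(rec, "full")
  rereference_average(rec)
}

#' Band-filter and epoch a preprocessed recording
#'
#' For a sub-band, filters the recording to the band and cuts it into
#' epochs; for `"full"` the (already broadband-filtered) input is epoched
#' directly.
#'
#' @param rec Preprocessed [eeg_recording()].
#' @param band Band object or canonical name.
#' @param epoch_length Epoch length in seconds.
#' @return An [eeg_epochs()] block labeled with the band.
#' @export
band_epochs <- function(rec, band, epoch_length = 2) {
  band <- as_band(band)
  if (band$name != "full") rec <- bandpass_filter(rec, band)
  segment_epochs(rec, epoch_length, band_name = band$name)
}

#' Pipeline run configuration
#'
#' Gathers everything one end-to-end run needs; serializable to JSON so a
#' run directory always carries the resolved configuration it was produced
#' from.
#'
#' @param cohort A [cohort_config()] (simulated input) or `NULL` when
#'   `input_dir` points at a cohort on disk.
#' @param input_dir Directory with `manifest.json` + recordings (used when
#'   `cohort` is `NULL`).
#' @param channels Channel names to analyze (`NULL`: all channels).
#' @param bands Character vector of band names to analyze.
#' @param epoch_length Epoch length in seconds.
#' @param level Aggregation level for edgewise tests: `"subject"` or
#'   `"epoch"`.
#' @param q FDR level for edgewise decisions.
#' @param top_fraction Fraction for [top_fraction_edges()].
#' @param seed Seed for any randomness (overrides the cohort seed).
#' @return A `run_config` object.
#' @export
run_config <- function(cohort = NULL, input_dir = NULL, channels = NULL,
                       bands = c("full", "delta", "theta", "alpha",
                                 "beta", "gamma"),
                       epoch_length = 2, level = c("subject", "epoch"),
                       q = 0.05, top_fraction = 0.10, seed = 1L) {
  level <- match.arg(level)
  known <- names(eeg_bands())
  bad <- setdiff(bands, known)
  if (length(bad)) {
    stop("unknown band name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(cohort) && is.null(input_dir)) {
    stop("provide either a cohort_config or an input_dir", call. = FALSE)
  }
  if (!is.null(cohort)) {
    stopifnot(inherits(cohort, "cohort_config"))
    cohort$seed <- as.integer(seed)
  }
  structure(list(cohort = cohort, input_dir = input_dir,
                 channels = channels, bands = bands,
                 epoch_length = epoch_length, level = level, q = q,
                 top_fraction = top_fraction, seed = as.integer(seed)),
            class = "run_config")
}

run_config_json <- function(config) {
  cc <- config$cohort
  cohort_json <- if (is.null(cc)) NULL else list(
    n_group_a = cc$n_group_a, n_group_b = cc$n_group_b,
    n_channels = cc$n_channels, fs = cc$fs, duration = cc$duration,
    lag = cc$lag, noise_exponent = cc$noise_exponent, seed = cc$seed,
    preset = cc$preset,
    band_effects = lapply(seq_len(nrow(cc$band_effects)), function(r) list(
      band = cc$band_effects$band[r],
      strength_a = cc$band_effects$strength_a[r],
      strength_b = cc$band_effects$strength_b[r],
      pairs = cc$band_effects$pairs[[r]])))
  list(cohort = cohort_json, input_dir = config$input_dir,
       channels = config$channels, bands = config$bands,
       epoch_length = config$epoch_length, level = config$level,
       q = config$q, top_fraction = config$top_fraction,
       seed = config$seed)
}

#' Run the full two-group network comparison
#'
#' simulate (or load) -> preprocess -> band-resolved wPLI -> network
#' metrics -> group statistics, as one deterministic run. When `out_dir`
#' is given, all tables (TSV), the per-subject connectivity matrices, the
#' significant-edge lists (JSON), a per-band direction summary and the
#' resolved configuration are written there; outputs are identical for
#' identical configuration and seed.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory, or `NULL` for an in-memory run.
#' @param keep_connectivity Keep the connectivity objects on the result
#'   (memory-heavy for large cohorts).
#' @return A `network_comparison` object: list with `subjects` (tibble),
#'   `metrics` (per subject x band), `edge_stats` (per band), `top_edges`,
#'   `metric_stats`, `summary` (per-band direction table), `config`.
#' @export
run_pipeline <- function(config, out_dir = NULL, keep_connectivity = FALSE) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  cohort <- if (!is.null(config$cohort)) {
    simulate_cohort(config$cohort)
  } else {
    read_cohort(config$input_dir)
  }
  message(sprintf("[pipeline] cohort: %d subjects (%s)", nrow(cohort),
                  paste(table(cohort$group), collapse = " vs ")))

  bands <- config$bands
  conns <- vector("list", nrow(cohort))
  metrics <- vector("list", nrow(cohort))
  for (s in seq_len(nrow(cohort))) {
    rec <- preprocess_recording(cohort$recording[[s]], config$channels)
    per_band <- lapply(bands, function(bn) {
      wpli_matrix(band_epochs(rec, bn, config$epoch_length))
    })
    names(per_band) <- bands
    conns[[s]] <- per_band
    metrics[[s]] <- purrr::map_dfr(per_band, function(cn) {
      dplyr::bind_cols(
        tibble::tibble(band = cn$band_name),
        suppressWarnings(network_metrics(cn)))
    })
    message(sprintf("[pipeline] %s (%s): wPLI + metrics in %d bands",
                    cohort$subject_id[s], cohort$group[s], length(bands)))
  }
  metrics_tbl <- dplyr::bind_cols(
    tidyr::uncount(dplyr::select(cohort, "subject_id", "group"),
                   length(bands)),
    dplyr::bind_rows(metrics))

  idx_a <- which(cohort$group == "A")
  idx_b <- which(cohort$group == "B")
  edge_stats <- purrr::map_dfr(bands, function(bn) {
    va <- edge_values(lapply(idx_a, function(s) conns[[s]][[bn]]),
                      level = config$level)
    vb <- edge_values(lapply(idx_b, function(s) conns[[s]][[bn]]),
                      level = config$level)
    dplyr::bind_cols(tibble::tibble(band = bn),
                     edgewise_ttest(va, vb, q = config$q))
  })
  top_edges <- edge_stats |>
    dplyr::group_by(.data$band) |>
    dplyr::group_modify(function(df, key) {
      class(df) <- c("edge_stats", class(df))
      top_fraction_edges(df, config$top_fraction)
    }) |>
    dplyr::ungroup()
  metric_stats <- compare_metrics(metrics_tbl, alpha = config$q)
  summary_tbl <- summarize_directions(edge_stats, metric_stats)

  result <- structure(list(
    subjects = dplyr::select(cohort, -"recording"),
    metrics = metrics_tbl, edge_stats = edge_stats,
    top_edges = top_edges, metric_stats = metric_stats,
    summary = summary_tbl, config = config,
    connectivity = if (keep_connectivity) conns else NULL,
    level = config$level), class = "network_comparison")

  if (!is.null(out_dir)) {
    write_run(result, conns, cohort, out_dir)
  }
  message(sprintf("[pipeline] done in %.1f s",
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  result
}

# Per-band significant direction summary across the edge and metric layers.
summarize_directions <- function(edge_stats, metric_stats) {
  edges <- edge_stats |>
    dplyr::group_by(.data$band) |>
    dplyr::summarize(
      n_edges = dplyr::n(),
      n_significant = sum(.data$significant),
      n_increase = sum(.data$significant & .data$direction == "increase"),
      n_decrease = sum(.data$significant & .data$direction == "decrease"),
      connectivity_direction = dplyr::case_when(
        n_significant == 0 ~ "none",
        n_increase > n_decrease ~ "increase",
        n_decrease > n_increase ~ "decrease",
        TRUE ~ "mixed"),
      .groups = "drop")
  mets <- metric_stats |>
    dplyr::mutate(lab = ifelse(.data$significant,
                               paste0(.data$metric, ":", .data$direction),
                               NA_character_)) |>
    dplyr::group_by(.data$band) |>
    dplyr::summarize(
      significant_metrics = paste(stats::na.omit(.data$lab),
                                  collapse = ", "),
      .groups = "drop")
  dplyr::left_join(edges, mets, by = "band")
}

write_run <- function(result, conns, cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name) readr::write_tsv(df, file.path(out_dir, name))
  tsv(result$metrics, "metrics.tsv")
  tsv(result$edge_stats, "edge_stats.tsv")
  tsv(result$top_edges, "top_edges.tsv")
  tsv(result$metric_stats, "metric_stats.tsv")
  tsv(result$summary, "summary.tsv")
  conn_dir <- file.path(out_dir, "connectivity")
  dir.create(conn_dir, showWarnings = FALSE)
  for (s in seq_along(conns)) {
    for (bn in names(conns[[s]])) {
      write_connectivity_tsv(conns[[s]][[bn]], file.path(
        conn_dir, sprintf("%s_%s.tsv", cohort$subject_id[s], bn)))
    }
  }
  edges_json <- result$top_edges |>
    dplyr::select("band", "ch1", "ch2", "direction", "p_adj")
  jsonlite::write_json(edges_json, file.path(out_dir, "top_edges.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(run_config_json(result$config),
                       file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

#' @export
print.network_comparison <- function(x, ...) {
  cat(sprintf(
    "<network_comparison> %d subjects, %d bands, level = %s\n",
    nrow(x$subjects), length(unique(x$edge_stats$band)), x$level))
  print(x$summary)
  invisible(x)
}

#' @method tidy network_comparison
#' @export
tidy.network_comparison <- function(x, ...) x$edge_stats

#' @method glance network_comparison
#' @export
glance.network_comparison <- function(x, ...) {
  x$edge_stats |>
    dplyr::group_by(.data$band) |>
    dplyr::summarize(n_edges = dplyr::n(),
                     n_significant = sum(.data$significant),
                     .groups = "drop")
}

#' Epoch-length and sampling-rate sensitivity of the wPLI
#'
#' For every requested sampling rate, regenerates uncoupled (null)
#' recordings from the simulator (resampling is deliberately avoided) and
#' computes the mean delta-band wPLI at each epoch length, across several
#' seeds. Under independent noise the wPLI is a positively biased estimate
#' of zero, and the bias shrinks with the number of effectively
#' independent samples per epoch — so it falls as epochs lengthen and is
#' insensitive to the sampling rate at a fixed epoch length.
#'
#' @param n_channels Channels per null recording.
#' @param duration Recording duration in seconds (must fit the longest
#'   epoch).
#' @param epoch_lengths Epoch lengths in seconds.
#' @param rates Sampling rates in Hz.
#' @param band Band to analyze (default delta).
#' @param n_seeds Number of independent recordings per rate.
#' @param seed Master seed.
#' @return A `sensitivity_table` tibble: one row per (rate, epoch length)
#'   with `mean_wpli` and the across-seed standard deviation `sd_wpli`,
#'   plus a `per_seed` attribute holding the raw values.
#' @export
sensitivity_harness <- function(n_channels = 8, duration = 64,
                                epoch_lengths = c(2, 4, 8),
                                rates = c(500, 256, 128),
                                band = "delta", n_seeds = 5, seed = 1L) {
  band <- as_band(band)
  if (duration < max(epoch_lengths)) {
    stop("duration must cover the longest epoch", call. = FALSE)
  }
  cells <- tidyr::expand_grid(rate = rates, seed_i = seq_len(n_seeds))
  per_seed <- purrr::pmap_dfr(cells, function(rate, seed_i) {
    rec <- simulate_recording(n_channels, rate, duration,
                              couplings = list(),
                              seed = subject_seed(seed, seed_i * 131))
    filt <- bandpass_filter(rereference_average(rec), band)
    purrr::map_dfr(epoch_lengths, function(el) {
      cn <- wpli_matrix(segment_epochs(filt, el, band_name = band$name))
      tibble::tibble(
        rate = rate, epoch_length = el, seed = seed_i,
        mean_wpli = mean(cn$weights[upper.tri(cn$weights)]))
    })
  })
  out <- per_seed |>
    dplyr::group_by(.data$rate, .data$epoch_length) |>
    dplyr::summarize(sd_wpli = stats::sd(.data$mean_wpli),
                     mean_wpli = mean(.data$mean_wpli),
                     .groups = "drop") |>
    dplyr::select("rate", "epoch_length", "mean_wpli", "sd_wpli")
  attr(out, "per_seed") <- per_seed
  class(out) <- c("sensitivity_table", class(out))
  out
}
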