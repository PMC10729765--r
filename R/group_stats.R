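#' Extract per-observation edge values from connectivity objects
#'
#' Builds the observations x edges matrix the edgewise tests run on.
#' At `level = "subject"` each connectivity object contributes one row (its
#' epoch-mean weights); at `level = "epoch"` every epoch contributes a row.
#'
#' @param conns List of `wpli_connectivity` objects sharing one channel set.
#' @param level `"subject"` or `"epoch"`.
#' @return Numeric matrix, observations x edges, with `"ch1--ch2"` column
#'   names.
#' @export
edge_values <- function(conns, level = c("subject", "epoch")) {
  level <- match.arg(level)
  stopifnot(length(conns) >= 1L)
  ch <- conns[[1]]$channel_names
  pairs <- utils::combn(length(ch), 2)
  edge_names <- paste(ch[pairs[1, ]], ch[pairs[2, ]], sep = "--")
  rows <- lapply(conns, function(cn) {
    stopifnot(identical(cn$channel_names, ch))
    if (level == "subject") {
      matrix(cn$weights[cbind(pairs[1, ], pairs[2, ])], nrow = 1)
    } else {
      t(apply(cn$epoch_stack, 1,
              function(w) w[cbind(pairs[1, ], pairs[2, ])]))
    }
  })
  out <- do.call(rbind, rows)
  colnames(out) <- edge_names
  out
}

# Vectorized Welch t-test over the columns of two matrices.
welch_columns <- function(a, b) {
  na <- nrow(a); nb <- nrow(b)
  ma <- unname(colMeans(a)); mb <- unname(colMeans(b))
  va <- unname(apply(a, 2, stats::var)); vb <- unname(apply(b, 2, stats::var))
  se2 <- va / na + vb / nb
  t_stat <- ifelse(se2 > 0, (ma - mb) / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
               se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1)),
               NA_real_)
  p <- ifelse(se2 > 0, 2 * stats::pt(-abs(t_stat), df), 1)
  degenerate <- se2 == 0
  # zero variance in both groups but different means: evidence is infinite
  diff0 <- degenerate & abs(ma - mb) > 0
  t_stat[diff0] <- sign(ma - mb)[diff0] * Inf
  p[diff0] <- 0
  list(mean_a = ma, mean_b = mb, t = t_stat, df = df, p = p,
       degenerate = degenerate & !diff0)
}

#' Edgewise two-group comparison with FDR control
#'
#' Welch (unequal-variance) two-sample t-test per edge, two-sided, with
#' Benjamini-Hochberg adjustment across all edges of the family (one band).
#' An edge with zero variance in both groups and equal means is flagged and
#' reported as `t = 0, p = 1`.
#'
#' @param values_a,values_b Observations x edges matrices (from
#'   [edge_values()]) with matching columns.
#' @param q FDR level for the rejection decision (default 0.05).
#' @return An `edge_stats` tibble: `edge`, `ch1`, `ch2`, `mean_a`,
#'   `mean_b`, `t`, `df`, `p`, `p_adj`, `significant`, `direction`
#'   (`"increase"`/`"decrease"` of group A relative to B), `degenerate`.
#' @export
edgewise_ttest <- function(values_a, values_b, q = 0.05) {
  if (!identical(colnames(values_a), colnames(values_b))) {
    stop("edge sets of the two groups differ", call. = FALSE)
  }
  if (nrow(values_a) < 2L || nrow(values_b) < 2L) {
    stop("need at least 2 observations per group", call. = FALSE)
  }
  wt <- welch_columns(values_a, values_b)
  fdr <- fdr_correct(wt$p, q = q)
  edge <- colnames(values_a)
  ch <- strsplit(edge, "--", fixed = TRUE)
  out <- tibble::tibble(
    edge = edge,
    ch1 = vapply(ch, `[`, "", 1),
    ch2 = vapply(ch, `[`, "", 2),
    mean_a = wt$mean_a, mean_b = wt$mean_b,
    t = wt$t, df = wt$df, p = wt$p,
    p_adj = fdr$p_adj, significant = fdr$significant,
    direction = ifelse(wt$mean_a >= wt$mean_b, "increase", "decrease"),
    degenerate = wt$degenerate
  )
  class(out) <- c("edge_stats", class(out))
  attr(out, "q") <- q
  out
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Step-up adjustment: `p_adj` is the BH-adjusted p value (monotone
#' non-decreasing in the raw-p rank) and `significant` is `p_adj <= q`,
#' which reproduces the step-up rule rejecting the `k` smallest raw p
#' values where `k` is the largest rank with `p_(k) <= k q / m`.
#'
#' @param p Vector of p values in `[0, 1]`.
#' @param q FDR level.
#' @return Tibble with `p`, `p_adj`, `significant`.
#' @export
fdr_correct <- function(p, q = 0.05) {
  if (length(p) == 0) stop("empty p-value vector", call. = FALSE)
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p values must lie in [0, 1]", call. = FALSE)
  }
  p_adj <- stats::p.adjust(p, method = "BH")
  tibble::tibble(p = p, p_adj = p_adj, significant = p_adj <= q)
}

#' Keep the strongest differential edges
#'
#' Among FDR-significant edges, ranks by adjusted p ascending (ties broken
#' by `|t|` descending) and keeps at most `ceiling(fraction * n_edges)`;
#' when fewer edges are significant, all of them are kept.
#'
#' @param stats An `edge_stats` tibble from [edgewise_ttest()].
#' @param fraction Fraction of the total edge count to keep (default 0.10).
#' @return The selected rows of `stats`, ranked.
#' @export
top_fraction_edges <- function(stats, fraction = 0.10) {
  cap <- ceiling(fraction * nrow(stats))
  sig <- dplyr::filter(stats, .data$significant)
  sig <- dplyr::arrange(sig, .data$p_adj, dplyr::desc(abs(.data$t)))
  utils::head(sig, cap)
}

# Exact two-sided Mann-Whitney p by enumeration of all group-A index sets
# over the pooled sample (handles ties).
ranksum_exact_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); na <- length(a)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  sets <- utils::combn(n, na)
  u_all <- apply(sets, 2, function(idx) sum(r[idx]) - na * (na + 1) / 2)
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  min(p, 1)
}

#' Wilcoxon-Mann-Whitney rank-sum test
#'
#' Two-sided test of a location difference between two samples. With both
#' group sizes at most 8 the p value is exact, by full enumeration of the
#' `choose(n, n_a)` group labelings of the pooled sample (valid under
#' ties), and likewise whenever the pooled size is at most 10; otherwise a
#' normal approximation with mid-ranks, tie-corrected variance and
#' continuity correction is used. If every pooled value is
#' identical the test is degenerate and `p = 1` is reported with a flag.
#'
#' @param values_a,values_b Numeric vectors, at least one value each.
#' @param exact_max Largest per-group size for which enumeration is used.
#' @return One-row tibble: `statistic` (Mann-Whitney U of group A), `p`,
#'   `method` (`"exact"`/`"normal"`/`"degenerate"`), `median_a`, `median_b`,
#'   `direction`.
#' @examples
#' metric_ranksum(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
metric_ranksum <- function(values_a, values_b, exact_max = 8L) {
  na <- length(values_a); nb <- length(values_b)
  if (na < 1L || nb < 1L) stop("both groups need observations", call. = FALSE)
  pooled <- c(values_a, values_b)
  r <- rank(pooled)
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  med_a <- stats::median(values_a); med_b <- stats::median(values_b)
  direction <- ifelse(med_a >= med_b, "increase", "decrease")
  if (length(unique(pooled)) == 1L) {
    return(tibble::tibble(statistic = u, p = 1, method = "degenerate",
                          median_a = med_a, median_b = med_b,
                          direction = direction))
  }
  if ((na <= exact_max && nb <= exact_max) || na + nb <= 10L) {
    p <- ranksum_exact_p(values_a, values_b)
    method <- "exact"
  } else {
    n <- na + nb
    mu <- na * nb / 2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / ((n) * (n - 1))
    sigma2 <- na * nb / 12 * ((n + 1) - tie_term)
    z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    p <- min(p, 1)
    method <- "normal"
  }
  tibble::tibble(statistic = u, p = p, method = method,
                 median_a = med_a, median_b = med_b, direction = direction)
}

#' Rank-sum tests on a metrics table
#'
#' Runs [metric_ranksum()] for every `(band, metric)` combination of a
#' per-subject network-metrics table.
#'
#' @param metrics Tibble with columns `subject_id`, `group`, `band` and the
#'   metric columns `D`, `CC`, `CPL`, `GE` (as produced by the pipeline).
#' @param alpha Significance level for the `significant` flag.
#' @return A `metric_stats` tibble: one row per band x metric with the
#'   rank-sum statistic, p value, group medians and direction.
#' @export
compare_metrics <- function(metrics, alpha = 0.05) {
  long <- tidyr::pivot_longer(metrics, cols = c("D", "CC", "CPL", "GE"),
                              names_to = "metric", values_to = "value")
  out <- long |>
    dplyr::group_by(.data$band, .data$metric) |>
    dplyr::group_modify(function(df, key) {
      metric_ranksum(df$value[df$group == "A"], df$value[df$group == "B"])
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(significant = .data$p < alpha)
  class(out) <- c("metric_stats", class(out))
  out
}
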