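edge_matrix <- function(rows, edges = paste0("e", seq_len(ncol(rows)))) {
  colnames(rows) <- edges
  rows
}

test_that("edgewise Welch t matches stats::t.test and hand formulas", {
  a <- edge_matrix(cbind(c(0.1, 0.2, 0.3, 0.4), c(1, 2, 3, 4)),
                   c("x--y", "y--z"))
  b <- edge_matrix(cbind(c(0.5, 0.6, 0.7, 0.8), c(1, 2, 3, 4)),
                   c("x--y", "y--z"))
  st <- edgewise_ttest(a, b)
  ref <- stats::t.test(a[, 1], b[, 1], var.equal = FALSE)
  expect_equal(st$t[1], unname(ref$statistic), tolerance = 1e-12)
  expect_equal(st$df[1], unname(ref$parameter), tolerance = 1e-12)
  expect_equal(st$p[1], ref$p.value, tolerance = 1e-12)
  expect_equal(st$direction[1], "decrease")
  # identical samples: t = 0, p = 1
  expect_equal(st$t[2], 0)
  expect_equal(st$p[2], 1)
  expect_equal(st$ch1, c("x", "y"))
  expect_equal(st$ch2, c("y", "z"))
})

test_that("degenerate zero-variance edges are flagged", {
  a <- edge_matrix(cbind(rep(0.5, 3), rep(0.2, 3)))
  b <- edge_matrix(cbind(rep(0.5, 3), rep(0.7, 3)))
  st <- edgewise_ttest(a, b)
  expect_true(st$degenerate[1])
  expect_equal(st$t[1], 0)
  expect_equal(st$p[1], 1)
  expect_false(st$degenerate[2])  # zero variance but different means
  expect_equal(st$p[2], 0)
  expect_equal(st$direction[2], "decrease")
})

test_that("BH adjustment and decisions match the definitional step-up scan", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  fd <- fdr_correct(p, q = 0.05)
  expect_true(all(fd$significant))  # p_(4) = 0.04 <= 4 * 0.05 / 4
  expect_equal(fd$p_adj, stats::p.adjust(p, "BH"))
  expect_true(all(fd$p_adj >= fd$p))
  none <- fdr_correct(rep(1, 5))
  expect_false(any(none$significant))
  set.seed(31)
  for (k in 1:20) {
    p <- stats::runif(40)^2
    fd <- fdr_correct(p, q = 0.05)
    expect_equal(fd$significant, oracle_bh_reject(p, 0.05))
    # monotone: decisions consistent with adjusted-p ordering
    expect_true(all(fd$p_adj[fd$significant] <= min(c(
      fd$p_adj[!fd$significant], Inf))))
  }
  expect_error(fdr_correct(numeric(0)), "empty")
  expect_error(fdr_correct(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("top-fraction selection applies the ceiling cap and ranking", {
  n_edges <- 171
  set.seed(32)
  stats_tbl <- tibble::tibble(
    edge = paste0("e", 1:n_edges),
    ch1 = "a", ch2 = "b",
    mean_a = 0, mean_b = 0,
    t = stats::rnorm(n_edges), df = 10,
    p = stats::runif(n_edges),
    p_adj = stats::runif(n_edges),
    significant = c(rep(TRUE, 40), rep(FALSE, n_edges - 40)),
    direction = "increase", degenerate = FALSE)
  kept <- top_fraction_edges(stats_tbl, 0.10)
  expect_equal(nrow(kept), 18)  # ceiling(17.1)
  expect_true(all(kept$significant))
  expect_true(!is.unsorted(kept$p_adj))
  few <- stats_tbl
  few$significant <- c(rep(TRUE, 5), rep(FALSE, n_edges - 5))
  expect_equal(nrow(top_fraction_edges(few, 0.10)), 5)
  none <- stats_tbl
  none$significant <- FALSE
  expect_equal(nrow(top_fraction_edges(none, 0.10)), 0)
})

test_that("rank-sum: U = 0 example and exactness against pair counting", {
  res <- metric_ranksum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 0.1, tolerance = 1e-12)  # 2/20 labelings as extreme
  expect_equal(res$method, "exact")
  expect_equal(res$direction, "decrease")

  same <- metric_ranksum(c(2, 2, 2), c(2, 2))
  expect_equal(same$p, 1)
  expect_equal(same$method, "degenerate")
})

test_that("exact rank-sum p equals full enumeration for all sizes <= 10", {
  set.seed(33)
  for (na in 1:5) {
    for (nb in na:(10 - na)) {
      a <- stats::rnorm(na)
      b <- stats::rnorm(nb)
      expect_equal(metric_ranksum(a, b)$p, oracle_ranksum_p(a, b),
                   tolerance = 1e-12)
      # with ties
      at <- round(stats::rnorm(na))
      bt <- round(stats::rnorm(nb))
      expect_equal(metric_ranksum(at, bt)$p, oracle_ranksum_p(at, bt),
                   tolerance = 1e-12)
    }
  }
})

test_that("normal approximation agrees with exact p at the study group sizes", {
  set.seed(34)
  for (k in 1:10) {
    a <- stats::rnorm(10, mean = 0.5)
    b <- stats::rnorm(5)
    approx <- metric_ranksum(a, b)          # 10 > 8 -> normal path
    expect_equal(approx$method, "normal")
    exact <- wplinet:::ranksum_exact_p(a, b)
    expect_lt(abs(approx$p - exact), 0.02)
    # and the normal path matches base R's tie-corrected approximation
    ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
    expect_equal(approx$p, ref$p.value, tolerance = 1e-9)
  }
})

test_that("compare_metrics tests every band x metric with directions", {
  set.seed(35)
  subjects <- tibble::tibble(
    subject_id = sprintf("S%02d", 1:15),
    group = rep(c("A", "B"), c(10, 5)))
  metrics <- tidyr::expand_grid(subjects, band = c("delta", "alpha"))
  metrics$D <- stats::rnorm(30, ifelse(metrics$group == "A", 2, 1))
  metrics$CC <- stats::runif(30)
  metrics$CPL <- stats::rnorm(30, 3)
  metrics$GE <- stats::rnorm(30, 0.4, 0.01)
  ms <- compare_metrics(metrics)
  expect_equal(nrow(ms), 8)
  expect_setequal(unique(ms$metric), c("D", "CC", "CPL", "GE"))
  d_alpha <- ms[ms$band == "alpha" & ms$metric == "D", ]
  expect_equal(d_alpha$direction, "increase")
})

test_that("planted directional effects are reported with correct direction", {
  set.seed(36)
  base <- matrix(stats::rnorm(15 * 6, 0.4, 0.05), 15)
  a <- edge_matrix(base[1:10, ]); b <- edge_matrix(base[11:15, ])
  a[, 3] <- a[, 3] + 0.3  # planted increase in group A on edge 3
  st <- edgewise_ttest(a, b)
  expect_true(st$significant[3])
  expect_equal(st$direction[3], "increase")
})
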