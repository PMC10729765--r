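# Independent brute-force oracles, written as literal transcriptions of the
# defining formulas. They deliberately avoid the package's optimized paths.

# wPLI term by term: |E[Im Y]| / E[|Im Y|] with Y_t = a_i(t) conj(a_j(t)).
oracle_wpli <- function(a_i, a_j) {
  num <- 0
  den <- 0
  n <- length(a_i)
  for (t in seq_len(n)) {
    y <- a_i[t] * Conj(a_j[t])
    num <- num + Im(y)
    den <- den + abs(Im(y))
  }
  if (den == 0) 0 else abs(num / n) / (den / n)
}

# All-pairs shortest paths by Floyd-Warshall on lengths 1/w.
oracle_floyd_warshall <- function(w) {
  n <- nrow(w)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && w[i, j] > 0) d[i, j] <- 1 / w[i, j]
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

# Weighted clustering coefficient by explicit triple enumeration on
# max-normalized weights.
oracle_clustering <- function(w) {
  n <- nrow(w)
  if (n < 3 || max(w) == 0) return(0)
  wn <- w / max(w)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    nbr <- which(w[i, ] > 0)
    k <- length(nbr)
    if (k < 2) next
    s <- 0
    for (j in nbr) for (h in nbr) {
      if (j != h) s <- s + (wn[i, j] * wn[i, h] * wn[j, h])^(1 / 3)
    }
    ci[i] <- s / (k * (k - 1))
  }
  mean(ci)
}

# BH decisions by scanning every threshold k (definitional step-up rule).
oracle_bh_reject <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  k_max <- 0
  for (k in seq_len(m)) {
    if (p[ord[k]] <= k * q / m) k_max <- k
  }
  rej <- rep(FALSE, m)
  if (k_max > 0) rej[ord[seq_len(k_max)]] <- TRUE
  rej
}

# Exact two-sided rank-sum p by direct pair counting over all labelings:
# U(A) = #{(a, b): a > b} + 0.5 * #{a == b}.
oracle_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  na <- length(a)
  u_of <- function(x, y) {
    s <- 0
    for (xi in x) for (yi in y) {
      s <- s + (xi > yi) + 0.5 * (xi == yi)
    }
    s
  }
  u_obs <- u_of(a, b)
  sets <- utils::combn(n, na)
  u_all <- apply(sets, 2, function(idx) u_of(pooled[idx], pooled[-idx]))
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# Random symmetric non-negative weight matrix with zero diagonal.
random_weight_matrix <- function(n, density = 0.7) {
  w <- matrix(0, n, n)
  up <- upper.tri(w)
  vals <- stats::runif(sum(up))
  vals[stats::runif(sum(up)) > density] <- 0
  w[up] <- vals
  w <- w + t(w)
  w
}

# Analytic signal of a complex tone at frequency f (cycles/sample).
tone_analytic <- function(n, f, phase = 0) {
  exp(1i * (2 * pi * f * seq_len(n) + phase))
}
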