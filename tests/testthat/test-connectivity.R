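test_that("analytic signal reproduces closed-form identities", {
  n <- 1024
  f <- 10 / n  # integer number of cycles
  x <- cos(2 * pi * 10 * seq_len(n) / n)
  z <- analytic_signal(x)
  expect_equal(Re(z), x, tolerance = 1e-10)
  # modulus constant, phase advances by 2*pi*f per sample (interior)
  interior <- 100:900
  expect_true(all(abs(Mod(z[interior]) - 1) < 0.02))
  dphi <- diff(Arg(z[interior]))
  dphi <- (dphi + pi) %% (2 * pi) - pi
  expect_equal(mean(dphi), 2 * pi * 10 / n, tolerance = 1e-6)
  # quadrature: sin is cos delayed by a quarter cycle
  y <- sin(2 * pi * 10 * seq_len(n) / n)
  zy <- analytic_signal(y)
  dp <- Arg(z[interior] * Conj(zy[interior]))
  expect_equal(mean(dp), pi / 2, tolerance = 1e-6)
  expect_equal(analytic_signal(rep(0, 8)), rep(0 + 0i, 8))
  expect_error(analytic_signal(c(1, NA)), "finite")
})

test_that("wPLI hits its analytic limits", {
  set.seed(2)
  z <- analytic_signal(rnorm(512))
  expect_identical(wpli_pair(z, z), 0)              # zero lag -> 0/0 guard
  expect_equal(wpli_pair(z, z * exp(1i * pi / 2)), 1, tolerance = 1e-12)
  expect_error(wpli_pair(z, z[-1]), "equal length")
})

test_that("wPLI equals the literal term-by-term transcription", {
  set.seed(7)
  for (k in 1:20) {
    a <- complex(real = rnorm(64), imaginary = rnorm(64))
    b <- complex(real = rnorm(64), imaginary = rnorm(64))
    expect_equal(wpli_pair(a, b), oracle_wpli(a, b), tolerance = 1e-12)
  }
})

test_that("connectivity matrices satisfy range, symmetry and stack identities", {
  set.seed(3)
  rec <- simulate_recording(5, 128, 16, seed = 3)
  cn <- wpli_matrix(segment_epochs(bandpass_filter(rec, "alpha"), 2,
                                   band_name = "alpha"))
  w <- cn$weights
  expect_equal(w, t(w))
  expect_true(all(diag(w) == 0))
  off <- w[row(w) != col(w)]
  expect_true(all(off >= 0 & off <= 1))
  expect_equal(unname(w), apply(cn$epoch_stack, c(2, 3), mean))
  expect_equal(n_epochs(cn), 8)
})

test_that("a single epoch of identical channels gives an all-zero matrix", {
  x <- matrix(rep(sin(2 * pi * 10 * seq_len(256) / 128), 3), nrow = 3,
              byrow = TRUE)
  ep <- eeg_epochs(array(x, dim = c(1, 3, 256)), 128, 2,
                   c("a", "b", "c"), "alpha")
  # all three channels hold the same series
  ep$data[1, , ] <- matrix(x[1, ], 3, 256, byrow = TRUE)
  cn <- wpli_matrix(ep)
  expect_true(all(cn$weights == 0))
})

test_that("a strongly coupled quarter-cycle pair is detected near 1", {
  rec <- simulate_recording(
    8, 250, 120, couplings = list(coupling_spec(c(1, 2), "alpha", pi / 2, 1)),
    seed = 7)
  cn <- wpli_matrix(segment_epochs(bandpass_filter(rec, "alpha"), 2,
                                   band_name = "alpha"))
  expect_gte(n_epochs(cn), 60)
  expect_gte(cn$weights[1, 2], 0.9)
})

test_that("instantaneous mixing does not inflate wPLI", {
  # adding a common zero-lag source to both channels must not raise the
  # index above its unmixed value plus tolerance
  set.seed(13)
  fs <- 128
  n <- fs * 16
  b <- eeg_bands()$alpha
  x1 <- wplinet:::narrowband_noise(n, fs, b)
  x2 <- wplinet:::narrowband_noise(n, fs, b)
  common <- wplinet:::narrowband_noise(n, fs, b)
  base <- wpli_pair(analytic_signal(x1), analytic_signal(x2))
  mixed <- wpli_pair(analytic_signal(x1 + 2 * common),
                     analytic_signal(x2 + 2 * common))
  expect_lt(mixed, base + 0.1)
})

test_that("across-seed spread of subject-level wPLI shrinks with more epochs", {
  seeds <- 1:6
  spread <- vapply(c(4, 32), function(n_ep) {
    vals <- vapply(seeds, function(s) {
      rec <- simulate_recording(
        2, 128, 2 * n_ep,
        couplings = list(coupling_spec(c(1, 2), "alpha", pi / 2, 0.5)),
        seed = 100 + s)
      cn <- wpli_matrix(segment_epochs(bandpass_filter(rec, "alpha"), 2,
                                       band_name = "alpha"))
      cn$weights[1, 2]
    }, 0)
    stats::sd(vals)
  }, 0)
  expect_lt(spread[2], spread[1])
})

test_that("tidy/glance expose the edge table and summary", {
  rec <- simulate_recording(3, 128, 8, seed = 2)
  cn <- wpli_matrix(segment_epochs(rec, 2))
  td <- tidy(cn)
  expect_equal(nrow(td), 3)
  expect_named(td, c("ch1", "ch2", "edge", "band", "wpli"))
  expect_equal(td$wpli[td$edge == "Ch01--Ch02"], cn$weights[1, 2])
  gl <- glance(cn)
  expect_equal(gl$n_epochs, 4)
  expect_equal(gl$mean_wpli, mean(cn$weights[upper.tri(cn$weights)]))
})

test_that("connectivity TSV round-trips weights and metadata", {
  rec <- simulate_recording(3, 128, 8, seed = 2)
  cn <- wpli_matrix(segment_epochs(rec, 2, band_name = "full"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_connectivity_tsv(cn, f)
  back <- read_connectivity_tsv(f)
  expect_equal(back$weights, cn$weights, tolerance = 1e-9)
  expect_equal(back$band_name, "full")
  expect_equal(back$n_epochs, 4)
})
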