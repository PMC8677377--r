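test_that("carousel rotation matches its index definition", {
  expect_equal(rotate(c(1, 2, 3), 1), c(3, 1, 2))
  expect_equal(rotate(c(1, 2, 3), 0), c(1, 2, 3))
  expect_equal(rotate(c(1, 2, 3), 3), c(1, 2, 3))  # full rotation = identity
  v <- rnorm(20)
  expect_equal(rotate(rotate(v, 7), 13), v)        # rotations compose mod n
})

test_that("pearson_correlation is the standard coefficient with guards", {
  expect_equal(pearson_correlation(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(pearson_correlation(c(1, 2, 3), c(5, 3, 1)), -1)
  # covariance / sigma formula oracle
  a <- c(1, 2, 3); b <- c(1, 2, 4)
  oracle <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(pearson_correlation(a, b), oracle, tolerance = 1e-12)
  expect_equal(oracle, 0.98198, tolerance = 1e-4)
  expect_error(pearson_correlation(c(2, 2, 2), c(1, 2, 3)), "constant")
  expect_error(pearson_correlation(1:3, 1:4), "equal-length")
})

test_that("FFT profile equals the literal shift-and-correlate definition", {
  set.seed(42)
  for (x in list(rnorm(64), as.numeric(sine_series(20, 5, noise_sd = 5)),
                 rnorm(101))) {                    # odd length too
    expect_equal(pearson_iterations(x, method = "fft")$p_values,
                 reference_profile(x), tolerance = 1e-9)
    expect_equal(pearson_iterations(x, method = "direct")$p_values,
                 reference_profile(x), tolerance = 1e-12)
  }
})

test_that("profile is symmetric, bounded, and ends at one", {
  set.seed(7)
  for (trial in 1:5) {
    x <- rnorm(80) + sin(2 * pi * (1:80) / 16)
    p <- pearson_iterations(x)$p_values
    n <- length(p)
    expect_true(all(p >= -1 - 1e-12 & p <= 1 + 1e-12))
    expect_equal(p[n], 1, tolerance = 1e-9)
    k <- 1:(n - 1)
    expect_equal(p[k], p[n - k], tolerance = 1e-9)  # circular symmetry
  }
})

test_that("noiseless periodic signals peak at every period multiple", {
  v <- sine_series(50, 10)                         # n = 500
  prof <- pearson_iterations(v)
  expect_equal(prof$maxima, seq(50L, 500L, by = 50L))
  expect_true(all(abs(prof$p_values[seq(50, 500, 50)] - 1) < 1e-9))
  per <- estimate_period(prof)
  expect_identical(per$spacing, 50L)
  expect_identical(per$period, 49L)                # printed-case convention
})

test_that("period recovery holds on noisy seeded sinusoids", {
  ok <- 0L; trials <- 100L
  set.seed(2026)
  for (i in seq_len(trials)) {
    p <- sample(c(20L, 50L, 124L), 1L)
    v <- sine_series(p, 10L, noise_sd = 10, seed = i)  # sigma = 10% amplitude
    per <- tryCatch(estimate_period(pearson_iterations(v)),
                    error = function(e) NULL)
    if (!is.null(per) && per$spacing == p) ok <- ok + 1L
  }
  expect_gte(ok / trials, 0.95)
})

test_that("aperiodic and degenerate inputs are refused", {
  set.seed(99)
  noise <- magnitude_series(abs(rnorm(400, 100, 10)))
  expect_error(estimate_period(pearson_iterations(noise)), "aperiodic")
  expect_error(pearson_iterations(rep(5, 50)), "constant")
})

test_that("period equality is a strict integer gate", {
  expect_true(periods_equal(124, 124))
  expect_true(periods_equal(125, 125))
  expect_false(periods_equal(13, 124))
})

test_that("profile exports one correlation per shift", {
  v <- sine_series(20, 4)
  prof <- pearson_iterations(v)
  f <- tempfile(fileext = ".csv")
  write_profile_csv(prof, f)
  got <- as.numeric(readLines(f))
  expect_length(got, length(v))
  expect_equal(got, prof$p_values, tolerance = 1e-12)
})
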