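# Independent oracles, kept deliberately naive.

# Literal shift-and-correlate circular autocorrelation profile.
reference_profile <- function(x) {
  n <- length(x)
  vapply(seq_len(n), function(k) {
    idx <- ((seq_len(n) - 1 - k) %% n) + 1
    stats::cor(x, x[idx])
  }, numeric(1))
}

# Minimal total cost over ALL monotone unit-step paths (1,1) -> (n,n),
# by plain recursion (no memoization) — only usable for small matrices.
brute_force_min_cost <- function(cm) {
  n <- ncol(cm)
  rec <- function(i, j) {
    if (i == n && j == n) return(cm[j, i])
    best <- Inf
    if (i < n && j < n) best <- min(best, rec(i + 1, j + 1))
    if (i < n) best <- min(best, rec(i + 1, j))
    if (j < n) best <- min(best, rec(i, j + 1))
    cm[j, i] + best
  }
  rec(1L, 1L)
}

# Structural validity of a warp path over an n x n matrix.
expect_valid_path <- function(path, n) {
  pts <- path$points
  expect_identical(pts[1, ], c(i = 1L, j = 1L))
  expect_identical(pts[nrow(pts), ], c(i = n, j = n))
  if (nrow(pts) > 1) {
    di <- diff(pts[, "i"]); dj <- diff(pts[, "j"])
    expect_true(all(di %in% 0:1), info = "i steps by 0 or 1")
    expect_true(all(dj %in% 0:1), info = "j steps by 0 or 1")
    expect_true(all(di + dj >= 1), info = "every step moves")
  }
}

# A quiet sine series for quick periodicity checks.
sine_series <- function(period, n_cycles, noise_sd = 0, seed = 1) {
  generate_signal(signal_spec(period_samples = period, n_cycles = n_cycles,
                              waveform = "sine", amplitude = 100,
                              baseline = 200, noise_sd = noise_sd,
                              seed = seed))
}
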