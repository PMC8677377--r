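test_that("generation is deterministic and spec-shaped", {
  sp <- signal_spec(seed = 5)
  a <- generate_signal(sp)
  b <- generate_signal(sp)
  expect_identical(as.numeric(a), as.numeric(b))
  expect_length(a, 124L * 24L)
  expect_true(all(as.numeric(a) >= 0))
  c_ <- generate_signal(signal_spec(seed = 6))
  expect_false(identical(as.numeric(a), as.numeric(c_)))
})

test_that("noiseless signals are exactly periodic with the spec's period", {
  for (wf in c("sine", "harmonics", "gait")) {
    v <- as.numeric(generate_signal(signal_spec(period_samples = 50L,
                                                n_cycles = 6L, waveform = wf,
                                                noise_sd = 0)))
    expect_equal(v[1:50], v[51:100], tolerance = 1e-12)
    per <- estimate_period(pearson_iterations(v))
    expect_identical(per$spacing, 50L)
  }
})

test_that("tempo factor rescales the cycle length", {
  v <- generate_signal(signal_spec(tempo_factor = 0.5, noise_sd = 0))
  expect_length(v, 62L * 24L)
  per <- estimate_period(pearson_iterations(v))
  expect_identical(per$spacing, 62L)
})

test_that("amplitude-zero input exercises the degenerate guards", {
  v <- generate_signal(signal_spec(amplitude = 0, noise_sd = 0))
  expect_error(pearson_iterations(v), "constant")
  expect_error(min_max_normalize(v), "zero range")
})

test_that("a construction phase offset is recovered by synchronization", {
  sp <- signal_spec(noise_sd = 0)
  v <- generate_signal(sp)
  spu <- sp; spu$phase_shift_samples <- 7L
  u <- generate_signal(spu)
  ss <- sync_shift(first_cycle(v, 124L), first_cycle(u, 124L))
  u2 <- apply_shift(u, ss$shift)
  n <- min(length(v), length(u2))
  expect_equal(cor(as.numeric(v)[1:n], as.numeric(u2)[1:n]), 1,
               tolerance = 1e-9)
})

test_that("pair labels encode what the pipeline should tolerate", {
  expect_identical(generate_pair(perturbation = "none")$truth_label,
                   "similar")
  expect_identical(generate_pair(perturbation = "phase")$truth_label,
                   "similar")
  expect_identical(generate_pair(perturbation = "amplitude")$truth_label,
                   "similar")
  expect_identical(generate_pair(perturbation = "tempo")$truth_label,
                   "different")
  expect_identical(generate_pair(perturbation = "shape")$truth_label,
                   "different")

  # amplitude scaling alone is removed by normalization: noiseless sine pair
  sp <- signal_spec(waveform = "sine", noise_sd = 0)
  pr <- generate_pair(sp, perturbation = "amplitude", magnitude = 1.8,
                      seed = 2)
  rep <- compare_movements(pr$expert, pr$learner, seed = 2)
  expect_identical(rep$verdict, "similar")

  # tempo halving trips the period gate
  pr2 <- generate_pair(signal_spec(noise_sd = 0), perturbation = "tempo",
                       magnitude = 0.5, seed = 2)
  rep2 <- compare_movements(pr2$expert, pr2$learner, seed = 2)
  expect_identical(rep2$verdict, "different")
  expect_true("period" %in% rep2$reasons)
  expect_identical(rep2$period_learner, 61L)     # spacing 62, convention -1
})

test_that("synthetic CSVs flow through the standard reader", {
  v <- generate_signal(signal_spec(seed = 12))
  f <- tempfile(fileext = ".csv")
  write_magnitude_csv(v, f)
  back <- read_recording(f, layout = "magnitude")
  expect_identical(as.numeric(back), as.numeric(v))
})
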