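test_that("cycle-window arithmetic reproduces the printed windows", {
  w1 <- select_cycle_window(2976, 124, k = 3)
  expect_identical(c(w1$initial_sample, w1$final_sample), c(372L, 496L))
  w2 <- select_cycle_window(2976, 124, k = 6)
  expect_identical(c(w2$initial_sample, w2$final_sample), c(744L, 868L))
  w3 <- select_cycle_window(2871, 125, k = 13)
  expect_identical(c(w3$initial_sample, w3$final_sample), c(1625L, 1750L))
})

test_that("random cycle choice is seeded, in range, and spans one period", {
  for (seed in 1:25) {
    w <- select_cycle_window(2976, 124, seed = seed)
    expect_identical(w$final_sample - w$initial_sample, 124L)
    expect_true(w$k >= 1L && w$k <= w$sample_limit)
    w2 <- select_cycle_window(2976, 124, seed = seed)
    expect_identical(w$k, w2$k)                   # reproducible draw
  }
  expect_identical(select_cycle_window(2976, 124, seed = 1)$sample_limit, 23L)
  expect_error(select_cycle_window(200, 124, seed = 1), "shorter than two")
})

test_that("path regression, R-squared and line difference match oracles", {
  ident <- greedy_path(cost_matrix(as.numeric(sine_series(10, 2)),
                                   as.numeric(sine_series(10, 2))))
  fit <- fit_path_line(ident)
  expect_equal(fit$m, 1, tolerance = 1e-12)
  expect_equal(fit$b, 0, tolerance = 1e-9)
  expect_equal(r_squared(ident, fit), 1)
  expect_equal(mean_line_difference(fit, ident), 0, tolerance = 1e-9)

  collinear <- movewarp:::new_warp_path(1:3, c(2, 4, 6), "dp", 0)
  fit2 <- fit_path_line(collinear)
  expect_equal(fit2$m, 2, tolerance = 1e-12)
  expect_equal(fit2$b, 0, tolerance = 1e-12)
  expect_equal(r_squared(collinear, fit2), 1)

  # hand-computed OLS on {(1,1),(2,3),(3,2),(4,4)}: m=0.8, b=0.5, R2=0.64
  p4 <- movewarp:::new_warp_path(1:4, c(1, 3, 2, 4), "dp", 0)
  fit4 <- fit_path_line(p4)
  expect_equal(fit4$m, 0.8, tolerance = 1e-12)
  expect_equal(fit4$b, 0.5, tolerance = 1e-12)
  expect_equal(r_squared(p4, fit4), 0.64, tolerance = 1e-12)

  # constant-offset line: difference equals the offset regardless of path
  expect_equal(mean_line_difference(list(m = 1, b = 5), p4), 5)
  # direct-summation oracle on the printed fit over i = 372..496
  i <- 372:496
  oracle <- mean(abs(-0.0102 * i + 24.4590))
  expect_equal(mean_line_difference(list(m = 0.9898, b = 24.4590),
                                    movewarp:::new_warp_path(i, i, "dp", 0)),
               oracle, tolerance = 1e-12)
  expect_error(fit_path_line(movewarp:::new_warp_path(c(2, 2, 2), 1:3,
                                                      "dp", 0)),
               "undefined slope")
})

test_that("line difference depends only on the fit and the i-range", {
  i <- 10:40
  fit <- list(m = 0.95, b = 3)
  a <- movewarp:::new_warp_path(i, i, "dp", 0)
  b <- movewarp:::new_warp_path(i, rev(i), "dp", 0)
  expect_identical(mean_line_difference(fit, a), mean_line_difference(fit, b))
})

test_that("verdict applies the three operational criteria", {
  v1 <- verdict(TRUE, 0.9867, 0.903803)
  expect_identical(v1$verdict, "similar")
  expect_length(v1$reasons, 0L)
  v2 <- verdict(TRUE, 0.8482, 6.355008)
  expect_identical(v2$verdict, "different")
  expect_identical(v2$reasons, "r_squared")
  v3 <- verdict(TRUE, 0.9099, 15.80045)
  expect_identical(v3$verdict, "different")
  expect_identical(v3$reasons, "line_difference")
  v4 <- verdict(FALSE, 0.5407, 2.126166)
  expect_identical(v4$verdict, "different")
  expect_true("period" %in% v4$reasons)
})

test_that("self-comparison end to end is the exact identity", {
  v <- generate_signal(signal_spec(seed = 9))
  rep <- compare_movements(v, v, seed = 1)
  expect_identical(rep$verdict, "similar")
  expect_equal(rep$m, 1, tolerance = 1e-12)
  expect_equal(rep$b, 0, tolerance = 1e-9)
  expect_equal(rep$r_squared, 1)
  expect_equal(rep$mean_line_diff, 0, tolerance = 1e-9)
  expect_identical(rep$shift_applied, 0L)
  expect_identical(nrow(rep$discrepant_segments), 0L)
})

test_that("discrepancy localization finds an injected mid-cycle distortion", {
  v <- as.numeric(condition_series(generate_signal(
    signal_spec(noise_sd = 0))))[1:125]
  u <- v
  u[50:75] <- rev(u[50:75]) * 1.8 + 2000        # distort only samples 50..75
  path <- greedy_path(cost_matrix(v, u))
  seg <- localize_discrepancy(v, u, path)
  expect_gt(nrow(seg), 0L)
  expect_true(any(seg$start <= 75 & seg$end >= 50))  # overlaps the injection
  expect_identical(nrow(localize_discrepancy(v, v,
                                             greedy_path(cost_matrix(v, v)))),
                   0L)
  w <- rep(c(0, 10000), length.out = 125)       # nothing in common
  segall <- localize_discrepancy(v, w, greedy_path(cost_matrix(v, w)))
  expect_gt(nrow(segall), 0L)
})

test_that("period gate yields a different verdict with reason period", {
  pr <- generate_pair(perturbation = "tempo", seed = 3)
  rep <- compare_movements(pr$expert, pr$learner, seed = 3)
  expect_identical(rep$verdict, "different")
  expect_true("period" %in% rep$reasons)
  expect_false(rep$periods_equal)
  # gate-stop variant returns NA regression fields
  rep2 <- compare_movements(pr$expert, pr$learner, seed = 3,
                            continue_on_period_mismatch = FALSE)
  expect_true(is.na(rep2$r_squared))
  expect_identical(rep2$verdict, "different")
})

test_that("undistorted pairs pass and strongly distorted pairs fail", {
  # endpoints and top quarter of a shape-distortion ladder: mild noise alone
  # never fails the pair, and a distortion at 80-100 % strength never passes
  for (seed in 1:10) {
    base <- generate_pair(perturbation = "none", seed = seed)
    shaped <- generate_pair(perturbation = "shape", seed = seed)
    expect_identical(compare_movements(base$expert, base$learner,
                                       seed = seed)$verdict, "similar")
    for (alpha in c(0.8, 0.9, 1)) {
      u <- magnitude_series((1 - alpha) * as.numeric(base$learner) +
                              alpha * as.numeric(shaped$learner))
      expect_identical(compare_movements(base$expert, u, seed = seed)$verdict,
                       "different")
    }
  }
})

test_that("reports serialize to schema-valid JSON", {
  pr <- generate_pair(perturbation = "phase", seed = 11)
  rep <- compare_movements(pr$expert, pr$learner, seed = 11)
  js <- report_to_json(rep)
  expect_silent(validate_report(js))
  f <- tempfile(fileext = ".json")
  report_to_json(rep, f)
  expect_silent(validate_report(paste(readLines(f), collapse = "\n")))
  parsed <- jsonlite::fromJSON(f)
  expect_identical(parsed$verdict, rep$verdict)
  expect_equal(parsed$thresholds$diff_max, 10)
})
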