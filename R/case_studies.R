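#' Recompute the salsa-step case studies from a local dataset clone
#'
#' The reference recordings (salsa dance steps captured at the ankle,
#' magnitudes in m/s^2 x 100, ~3000 samples each) are published at
#' <https://github.com/mfburbano/SalsaDanceDataSet>. Given a local clone,
#' this recomputes the documented checkpoints: the period of User 2's
#' step-forward-backward sample 1, the synchronization shift between User 2
#' and User 3's first cycles, the first-cycle self-warping regression, and
#' the four expert-vs-learner case studies with their fixed cycle windows.
#'
#' @param dataset_dir path to a clone of the SalsaDanceDataSet repository.
#' @return list with `period_user2_fwdback`, `sync_shift_user2_user3`,
#'   `first_cycle_fit` (m, b), and `cases` (one `comparison_report` per case:
#'   `similar`, `low_r2`, `high_diff`, `period_mismatch`).
#' @export
reproduce_case_studies <- function(dataset_dir) {
  if (!dir.exists(dataset_dir)) {
    stop(sprintf("dataset directory not found: %s", dataset_dir),
         call. = FALSE)
  }
  rd <- function(...) {
    read_recording(file.path(dataset_dir, ..., "AnalysisData_raw_0.csv"),
                   layout = "magnitude", unit = "m/s2x100")
  }
  u2_fb1 <- rd("User2SetepForwardBackward", "Sample_1")
  u3_fb1 <- rd("User3SetepForwardBackward", "Sample_1")

  per_u2 <- estimate_period(pearson_iterations(u2_fb1))
  cyc <- per_u2$spacing                  # cycles repeat every `spacing` samples
  ss <- sync_shift(first_cycle(u2_fb1, cyc), first_cycle(u3_fb1, cyc))

  # first-cycle self/neighbour warping regression on the raw series
  vw <- as.numeric(u2_fb1)[seq_len(cyc)]
  uw <- as.numeric(u3_fb1)[seq_len(cyc)]
  path <- greedy_path(cost_matrix(vw, uw))
  fit <- fit_path_line(path)

  run <- function(expert, learner, k) {
    compare_movements(rd(expert[1L], expert[2L]), rd(learner[1L], learner[2L]),
                      window_k = k)
  }
  cases <- list(
    similar = run(c("User1BackBack", "Sample_1"),
                  c("User2BackBack", "Sample_3"), k = 3L),
    low_r2 = run(c("User1BackBack", "Sample_1"),
                 c("User2BackBack", "Sample_1"), k = 6L),
    high_diff = run(c("User1SetepForwardBackward", "Sample_1"),
                    c("User3SetepForwardBackward", "Sample_2"), k = 13L),
    period_mismatch = run(c("User1SetepForwardBackward", "Sample_3"),
                          c("User2SetepForwardBackward", "Sample_2"), k = 1L))

  list(period_user2_fwdback = per_u2$period,
       spacing_user2_fwdback = per_u2$spacing,
       sync_shift_user2_user3 = ss,
       first_cycle_fit = fit,
       cases = cases)
}
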