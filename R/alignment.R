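#' Extract the first movement cycle
#'
#' The leading `period` samples of a series, used as the template for phase
#' synchronization.
#'
#' @param v a [magnitude_series()] or numeric vector.
#' @param period cycle length in samples; must not exceed `length(v)`.
#' @return The first-cycle slice, same class as `v`.
#' @export
first_cycle <- function(v, period) {
  period <- as.integer(period)
  if (period < 1L) stop("period must be positive", call. = FALSE)
  if (length(v) < period) {
    stop(sprintf("series has %d samples, shorter than one period (%d)",
                 length(v), period), call. = FALSE)
  }
  if (is_magnitude_series(v)) series_like(as.numeric(v)[seq_len(period)], v)
  else v[seq_len(period)]
}

#' Phase offset between two first cycles
#'
#' Holds the expert cycle `v1` fixed and correlates it with every carousel
#' rotation of the learner cycle `u1`, producing the synchronization profile
#' `R` (`r_profile[k + 1] = cor(v1, rotate(u1, k))`, `k = 0..n'-1`). The
#' rotation at the profile's maximum aligns the learner's phase onto the
#' expert's; the returned `shift` is the equivalent number of samples to
#' discard from the learner's head (`(n' - argmax) mod n'`), which is what
#' [apply_shift()] consumes. Ties go to the smallest rotation.
#'
#' @param v1,u1 equal-length first-cycle series, neither constant.
#' @return list with `shift` (head-drop count), `k_max` (0-based rotation at
#'   the maximum), `r_max` (the maximum correlation), `r_profile`, and
#'   `low_confidence` (`TRUE` when `r_max < 0.2`).
#' @export
sync_shift <- function(v1, u1) {
  v1 <- as.numeric(v1); u1 <- as.numeric(u1)
  n <- length(v1)
  if (length(u1) != n) stop("first cycles must have equal length", call. = FALSE)
  if (n < 2L) stop("cycles too short to synchronize", call. = FALSE)
  if (stats::sd(v1) == 0 || stats::sd(u1) == 0) {
    stop("cannot synchronize a constant cycle", call. = FALSE)
  }
  r <- vapply(0:(n - 1L), function(k) pearson_correlation(v1, rotate(u1, k)),
              numeric(1))
  k_max <- which.max(r) - 1L              # which.max takes the first tie
  shift <- (n - k_max) %% n
  list(shift = shift, k_max = k_max, r_max = r[k_max + 1L], r_profile = r,
       low_confidence = r[k_max + 1L] < 0.2)
}

#' Discard leading samples from the learner series
#'
#' The synchronization shift is applied as a head-drop on the learner only —
#' the expert is never moved — so the learner's retained samples start on the
#' expert's phase.
#'
#' @param u a [magnitude_series()] or numeric vector.
#' @param shift number of leading samples to drop, `0 <= shift < length(u)`.
#' @return The trimmed series.
#' @export
apply_shift <- function(u, shift) {
  shift <- as.integer(shift)
  if (shift < 0L || shift >= length(u)) {
    stop(sprintf("shift %d out of range for a series of %d samples",
                 shift, length(u)), call. = FALSE)
  }
  if (shift == 0L) return(u)
  idx <- (shift + 1L):length(u)
  if (is_magnitude_series(u)) series_like(as.numeric(u)[idx], u) else u[idx]
}

#' Trim a series to start at its first-cycle maximum
#'
#' Drops everything before the largest raw value within the first cycle, so
#' both recordings open on the same salient movement event. Ties go to the
#' earliest sample.
#'
#' @param v a [magnitude_series()] or numeric vector.
#' @param period cycle length in samples.
#' @return The trimmed series.
#' @export
start_at_first_maximum <- function(v, period) {
  period <- as.integer(period)
  if (length(v) < period) {
    stop("series shorter than one period", call. = FALSE)
  }
  pos <- which.max(as.numeric(v)[seq_len(period)])  # first tie wins
  if (pos == 1L) return(v)
  idx <- pos:length(v)
  if (is_magnitude_series(v)) series_like(as.numeric(v)[idx], v) else v[idx]
}

#' Truncate two series to their common length
#'
#' Both series are cut to the shorter one's length so the comparison sees the
#' same number of samples from each.
#'
#' @param v,u series (expert, learner).
#' @param shift_applied the head-drop already applied to the learner
#'   (bookkeeping for the report).
#' @param r_profile the synchronization profile (bookkeeping).
#' @param low_confidence logical flag from [sync_shift()].
#' @return An object of class `sync_result`: list with `expert_aligned`,
#'   `learner_aligned`, `common_length`, `shift_applied`, `r_profile`,
#'   `low_confidence`.
#' @export
truncate_common <- function(v, u, shift_applied = 0L, r_profile = NULL,
                            low_confidence = FALSE) {
  stopifnot(length(v) >= 1L, length(u) >= 1L)
  p <- min(length(v), length(u))
  cut <- function(s) {
    if (length(s) == p) return(s)
    if (is_magnitude_series(s)) series_like(as.numeric(s)[seq_len(p)], s)
    else s[seq_len(p)]
  }
  structure(list(expert_aligned = cut(v), learner_aligned = cut(u),
                 common_length = p, shift_applied = as.integer(shift_applied),
                 r_profile = r_profile, low_confidence = low_confidence),
            class = "sync_result")
}

#' @export
print.sync_result <- function(x, ...) {
  cat(sprintf("<sync_result> shift %d, common length %d%s\n",
              x$shift_applied, x$common_length,
              if (isTRUE(x$low_confidence)) " (low confidence)" else ""))
  invisible(x)
}

#' Synchronize a learner recording to an expert recording
#'
#' The full alignment stage: estimate the phase offset from the two first
#' cycles, drop the learner's leading samples accordingly, trim both series to
#' start at their first-cycle maximum, and truncate to a common length.
#'
#' @param v expert [magnitude_series()].
#' @param u learner [magnitude_series()].
#' @param period shared cycle length in samples ("Cicle Equal").
#' @return A `sync_result` (see [truncate_common()]).
#' @export
synchronize <- function(v, u, period) {
  ss <- sync_shift(first_cycle(v, period), first_cycle(u, period))
  u2 <- if (ss$shift > 0L) apply_shift(u, ss$shift) else u
  if (length(u2) < period) {
    stop("learner series too short after synchronization", call. = FALSE)
  }
  v3 <- start_at_first_maximum(v, period)
  u3 <- start_at_first_maximum(u2, period)
  truncate_common(v3, u3, shift_applied = ss$shift, r_profile = ss$r_profile,
                  low_confidence = ss$low_confidence)
}
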