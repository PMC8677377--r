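#' Circular (carousel) rotation of a series
#'
#' Shifts the samples right by `k` positions, wrapping the tail around to the
#' front: `out[i] = v[(i - k) mod n]`. `rotate(v, n)` is the identity.
#'
#' @param v a numeric vector or [magnitude_series()].
#' @param k non-negative integer number of positions.
#' @return The rotated series (same class and metadata as `v`).
#' @export
#' @examples
#' rotate(c(1, 2, 3), 1)  # 3 1 2
rotate <- function(v, k) {
  n <- length(v)
  stopifnot(n >= 1L, k >= 0)
  k <- as.integer(k) %% n
  if (k == 0L) return(v)
  idx <- c((n - k + 1L):n, 1L:(n - k))
  if (is_magnitude_series(v)) series_like(as.numeric(v)[idx], v) else v[idx]
}

#' Pearson correlation between two equal-length series
#'
#' The standard sample Pearson coefficient, guaranteed in \[-1, 1\]. Constant
#' (zero-variance) input is an error rather than `NA`: a flat accelerometer
#' trace carries no periodicity information.
#'
#' @param a,b numeric vectors of equal length >= 2.
#' @return The correlation coefficient.
#' @export
pearson_correlation <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  n <- length(a)
  if (n < 2L || length(b) != n) {
    stop("pearson_correlation needs two equal-length series of length >= 2",
         call. = FALSE)
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("correlation undefined for a constant series (flat signal)",
         call. = FALSE)
  }
  stats::cor(a, b)
}

#' Pearson-iteration profile (circular autocorrelation)
#'
#' Correlates a series with every circular rotation of itself:
#' `p_values[k] = cor(v, rotate(v, k))` for `k = 1..n`. For a periodic
#' movement the profile peaks each time the rotation completes a whole number
#' of cycles, so the spacing of its maxima measures the period.
#'
#' The `"fft"` method evaluates the same quantity through the circular
#' autocovariance (a single FFT pair); because rotation preserves the mean and
#' variance, it is algebraically identical to the direct shift-and-correlate
#' definition (`method = "direct"`), which is retained as the literal form and
#' as a cross-check.
#'
#' @param v a [magnitude_series()] or numeric vector, length >= 2, not
#'   constant.
#' @param method `"fft"` (default) or `"direct"`.
#' @param peak_params list with `min_height` and `min_separation` forwarded to
#'   [find_profile_maxima()].
#' @return An object of class `pearson_profile`: list with `p_values`
#'   (length n, in \[-1, 1\], entry n == 1), `maxima` (1-based shift positions)
#'   and `n`.
#' @export
pearson_iterations <- function(v, method = c("fft", "direct"),
                               peak_params = list(min_height = 0.5,
                                                  min_separation = 3L)) {
  method <- match.arg(method)
  x <- as.numeric(v)
  n <- length(x)
  if (n < 2L) stop("need at least 2 samples", call. = FALSE)
  if (stats::sd(x) == 0) {
    stop("Pearson iterations undefined for a constant series", call. = FALSE)
  }
  if (method == "direct") {
    p <- vapply(seq_len(n), function(k) pearson_correlation(x, rotate(x, k)),
                numeric(1))
  } else {
    x0 <- x - mean(x)
    # circular autocovariance at every lag via one FFT pair;
    # c[j + 1] = sum_i x0[i] * x0[(i + j) mod n], symmetric in j <-> n - j,
    # so it serves lag k = shift directly. Normalize by lag-0.
    f <- stats::fft(x0)
    ac <- Re(stats::fft(f * Conj(f), inverse = TRUE)) / n
    p <- ac[c(2:n, 1L)] / ac[1L]
    p <- pmin(1, pmax(-1, p))
  }
  maxima <- find_profile_maxima(p, peak_params)
  structure(list(p_values = p, maxima = maxima, n = n),
            class = "pearson_profile")
}

#' @export
print.pearson_profile <- function(x, ...) {
  cat(sprintf("<pearson_profile> n = %d, %d maxima%s\n", x$n, length(x$maxima),
              if (length(x$maxima) >= 2L)
                sprintf(", median spacing %g", stats::median(diff(x$maxima)))
              else ""))
  invisible(x)
}

#' Locate maxima of a Pearson-iteration profile
#'
#' Local peaks with a minimum height and a minimum separation between
#' neighbouring peaks. The profile's final entry (the full rotation, always 1)
#' is included as a peak when it clears the height bound, since it marks the
#' last whole cycle.
#'
#' @param p numeric profile values.
#' @param peak_params list with `min_height` (correlation floor, default 0.5)
#'   and `min_separation` (shifts, default 3).
#' @return Increasing 1-based shift positions of the maxima.
#' @export
find_profile_maxima <- function(p, peak_params = list(min_height = 0.5,
                                                      min_separation = 3L)) {
  h <- peak_params$min_height %||% 0.5
  s <- peak_params$min_separation %||% 3L
  n <- length(p)
  pk <- pracma::findpeaks(p, minpeakheight = h, minpeakdistance = s)
  pos <- if (is.null(pk)) integer(0) else sort(as.integer(pk[, 2]))
  # endpoint: shift n is the identity rotation (p = 1) but findpeaks cannot
  # see a boundary maximum; count it when separated from the last interior one
  if (p[n] >= h && (length(pos) == 0L || n - pos[length(pos)] >= s)) {
    pos <- c(pos, n)
  }
  pos
}

#' Estimate the period of a series from its Pearson profile
#'
#' The raw spacing is the median gap between consecutive profile maxima (the
#' number of rotations from one whole-cycle alignment to the next). The
#' reported `period` follows the convention used for the printed case studies,
#' spacing − 1 (a 125-iteration spacing is read as a 124-sample period); both
#' numbers are returned so callers can use either.
#'
#' @param profile a `pearson_profile` from [pearson_iterations()].
#' @return list with `period` (spacing − 1), `spacing` (raw median gap) and
#'   `maxima`.
#' @export
estimate_period <- function(profile) {
  stopifnot(inherits(profile, "pearson_profile"))
  m <- profile$maxima
  if (length(m) < 2L) {
    stop("aperiodic signal: fewer than two maxima in the Pearson profile",
         call. = FALSE)
  }
  spacing <- as.integer(round(stats::median(diff(m))))
  list(period = spacing - 1L, spacing = spacing, maxima = m)
}

#' Test strict equality of two estimated periods
#'
#' The similarity pipeline's first gate: learners moving with a different
#' cycle length than the expert are declared different before any warping.
#'
#' @param p1,p2 integer periods.
#' @return `TRUE` iff the two integers are equal.
#' @export
periods_equal <- function(p1, p2) {
  stopifnot(is.finite(p1), is.finite(p2))
  as.integer(p1) == as.integer(p2)
}

#' Write a Pearson profile as a single-column CSV
#'
#' One correlation value per circular shift, matching the deposited profile
#' files' shape.
#'
#' @param profile a `pearson_profile`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "pearson_profile"))
  writeLines(formatC(profile$p_values, format = "g", digits = 17), path)
  invisible(path)
}
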