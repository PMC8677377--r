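#' Moving-average (sliding-window mean) filter
#'
#' Smooths a series with a window of `window` consecutive samples:
#' `out[i] = mean(v[i .. i + window - 1])`. The output is `window - 1`
#' samples shorter than the input (2989 samples filter to 2985 at the default
#' width of 5, a 0.1338 % loss).
#'
#' @param v a [magnitude_series()] or numeric vector with
#'   `length(v) >= window`.
#' @param window window width in samples; default 5. Even widths shift the
#'   phase by half a sample and draw a warning.
#' @return The filtered series, length `length(v) - window + 1`.
#' @export
#' @examples
#' moving_average_filter(1:5)  # 3
moving_average_filter <- function(v, window = 5L) {
  window <- as.integer(window)
  if (window < 1L) stop("window must be >= 1", call. = FALSE)
  if (window %% 2L == 0L) {
    warning("even filter window shifts the signal phase by half a sample; ",
            "odd widths preserve symmetry", call. = FALSE)
  }
  n <- length(v)
  if (n < window) {
    stop(sprintf("series of %d samples is shorter than the %d-sample window",
                 n, window), call. = FALSE)
  }
  x <- as.numeric(v)
  # stats::filter with sides = 1 puts mean(v[i-w+1 .. i]) at position i
  f <- as.numeric(stats::filter(x, rep(1 / window, window), sides = 1))
  out <- f[window:n]
  if (is_magnitude_series(v)) series_like(out, v) else out
}

#' Min-max normalization to a common 0..scale range
#'
#' Linearly rescales so the minimum maps to 0 and the maximum to `scale`
#' (default 10000): `out = scale * (v - min) / (max - min)`. This removes
#' amplitude differences between people (lighter and heavier movers produce
#' different accelerations for the same movement) so the warping stage
#' compares shape, not force.
#'
#' @param v a [magnitude_series()] or numeric vector, not constant.
#' @param scale upper end of the target range; default 10000.
#' @return The rescaled series, same length.
#' @export
#' @examples
#' min_max_normalize(c(2, 4, 6))  # 0 5000 10000
min_max_normalize <- function(v, scale = 10000) {
  stopifnot(scale > 0)
  x <- as.numeric(v)
  lo <- min(x); hi <- max(x)
  if (hi == lo) {
    stop("zero range: cannot normalize a constant series", call. = FALSE)
  }
  out <- scale * (x - lo) / (hi - lo)
  if (is_magnitude_series(v)) series_like(out, v) else out
}

#' Condition an aligned series for warping
#'
#' Normalization to the common 0..scale range followed by the moving-average
#' filter, the order the decision pipeline applies them in.
#'
#' @param v a [magnitude_series()] or numeric vector.
#' @param window filter width, default 5.
#' @param scale normalization scale, default 10000.
#' @return The conditioned series.
#' @export
condition_series <- function(v, window = 5L, scale = 10000) {
  moving_average_filter(min_max_normalize(v, scale = scale), window = window)
}
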