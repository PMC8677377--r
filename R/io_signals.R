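#' Acceleration-magnitude series
#'
#' The univariate container every stage of the pipeline operates on: a
#' non-negative numeric vector of acceleration magnitudes sqrt(x^2+y^2+z^2)
#' in a declared unit, with the sampling rate kept as metadata only (the
#' comparison algorithm is index-based throughout).
#'
#' @param values numeric vector of magnitudes; must be finite and >= 0.
#' @param unit unit tag, one of `"g"`, `"m/s2"`, `"m/s2x100"`.
#' @param rate_hz sampling rate in Hz, or `NA` if unknown. Metadata only.
#' @param source character label recording where the series came from.
#'
#' @return An object of class `magnitude_series`: the numeric vector with
#'   `unit`, `rate_hz` and `source` attributes.
#' @export
#' @examples
#' magnitude_series(c(3, 4, 5), unit = "m/s2")
magnitude_series <- function(values, unit = "m/s2x100", rate_hz = NA_real_,
                             source = "") {
  values <- as.numeric(values)
  if (length(values) < 1L) {
    stop("a magnitude series needs at least one sample", call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("magnitude values must all be finite", call. = FALSE)
  }
  if (any(values < 0)) {
    stop("magnitudes are moduli and cannot be negative", call. = FALSE)
  }
  unit <- match.arg(unit, c("g", "m/s2", "m/s2x100"))
  structure(values,
            unit = unit,
            rate_hz = as.numeric(rate_hz),
            source = as.character(source),
            class = c("magnitude_series", "numeric"))
}

#' @export
print.magnitude_series <- function(x, ...) {
  cat(sprintf("<magnitude_series> %d samples, unit %s%s\n",
              length(x), series_unit(x),
              if (is.na(series_rate(x))) "" else sprintf(", %g Hz", series_rate(x))))
  utils::str(as.numeric(utils::head(x, 10)))
  invisible(x)
}

#' @rdname magnitude_series
#' @param x object to test or query.
#' @export
is_magnitude_series <- function(x) inherits(x, "magnitude_series")

#' @rdname magnitude_series
#' @export
series_unit <- function(x) attr(x, "unit") %||% "m/s2x100"

#' @rdname magnitude_series
#' @export
series_rate <- function(x) {
  r <- attr(x, "rate_hz")
  if (is.null(r)) NA_real_ else r
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Rebuild a magnitude_series carrying over unit/rate metadata from a template.
# Internal: derived series (filtered, normalized, sliced) keep provenance.
series_like <- function(values, template) {
  structure(as.numeric(values),
            unit = series_unit(template),
            rate_hz = series_rate(template),
            source = attr(template, "source") %||% "",
            class = c("magnitude_series", "numeric"))
}

#' Tri-axial accelerometer recording
#'
#' Raw capture before reduction to a univariate magnitude series: one (x, y, z)
#' triplet per sampling instant.
#'
#' @param x,y,z numeric vectors of equal length, finite.
#' @param unit unit tag (`"g"`, `"m/s2"`, `"m/s2x100"`).
#' @param rate_hz sampling rate in Hz or `NA`.
#' @param source character label.
#' @return An object of class `accel_recording` (a data.frame with columns
#'   x, y, z and unit/rate attributes).
#' @export
accel_recording <- function(x, y, z, unit = "m/s2x100", rate_hz = NA_real_,
                            source = "") {
  x <- as.numeric(x); y <- as.numeric(y); z <- as.numeric(z)
  n <- length(x)
  if (n < 1L || length(y) != n || length(z) != n) {
    stop("x, y, z must be non-empty vectors of equal length", call. = FALSE)
  }
  if (any(!is.finite(c(x, y, z)))) {
    stop("accelerometer samples must all be finite", call. = FALSE)
  }
  unit <- match.arg(unit, c("g", "m/s2", "m/s2x100"))
  structure(data.frame(x = x, y = y, z = z),
            unit = unit, rate_hz = as.numeric(rate_hz), source = source,
            class = c("accel_recording", "data.frame"))
}

#' Reduce a tri-axial recording to its magnitude series
#'
#' Computes the modulus sqrt(x^2 + y^2 + z^2) per sample, the
#' placement-invariant univariate series the comparison algorithm consumes.
#' Using the modulus avoids compensating for how the wearable was oriented on
#' the body.
#'
#' @param rec an [accel_recording()].
#' @return A [magnitude_series()] of the same length.
#' @export
#' @examples
#' compute_magnitude(accel_recording(3, 4, 0))  # 5
compute_magnitude <- function(rec) {
  stopifnot(inherits(rec, "accel_recording"))
  magnitude_series(sqrt(rec$x^2 + rec$y^2 + rec$z^2),
                   unit = series_unit(rec), rate_hz = series_rate(rec),
                   source = attr(rec, "source") %||% "")
}

#' Read an accelerometer CSV
#'
#' Reads either a tri-axial file (columns x, y, z; extra columns such as a
#' timestamp are ignored) or a single-column precomputed-magnitude file, in
#' the layout of the public salsa-step dataset. A single header row is
#' auto-detected by a non-numeric first row; the decimal separator is a point.
#'
#' @param path path to a CSV file.
#' @param layout `"triaxial"` or `"magnitude"`.
#' @param unit unit tag declared for the file (`"g"`, `"m/s2"`, `"m/s2x100"`).
#' @param rate_hz sampling rate metadata, `NA` if unknown.
#' @return An [accel_recording()] (triaxial) or [magnitude_series()]
#'   (magnitude), rows in file order.
#' @export
read_recording <- function(path, layout = c("magnitude", "triaxial"),
                           unit = "m/s2x100", rate_hz = NA_real_) {
  layout <- match.arg(layout)
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  raw <- tryCatch(
    utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE,
                    strip.white = TRUE, blank.lines.skip = TRUE),
    error = function(e) stop(sprintf("empty file: %s", path), call. = FALSE))
  if (nrow(raw) == 0L) stop(sprintf("empty file: %s", path), call. = FALSE)

  # header auto-detection: drop the first row when it is not fully numeric
  first_numeric <- suppressWarnings(!anyNA(as.numeric(unlist(raw[1L, ]))))
  header_rows <- if (first_numeric) 0L else 1L
  if (header_rows == 1L) raw <- raw[-1L, , drop = FALSE]
  if (nrow(raw) == 0L) stop(sprintf("no data rows in: %s", path), call. = FALSE)

  need <- if (layout == "triaxial") 3L else 1L
  if (ncol(raw) < need) {
    stop(sprintf("%s layout needs %d numeric column(s); %s has %d",
                 layout, need, path, ncol(raw)), call. = FALSE)
  }
  num <- lapply(seq_len(need), function(j) {
    v <- suppressWarnings(as.numeric(raw[[j]]))
    bad <- which(is.na(v))
    if (length(bad) > 0L) {
      stop(sprintf("non-numeric value in %s, column %d, data row %d",
                   path, j, bad[1L] + header_rows), call. = FALSE)
    }
    v
  })
  if (layout == "triaxial") {
    accel_recording(num[[1L]], num[[2L]], num[[3L]],
                    unit = unit, rate_hz = rate_hz, source = path)
  } else {
    magnitude_series(num[[1L]], unit = unit, rate_hz = rate_hz, source = path)
  }
}

#' Write a magnitude series as a single-column CSV
#'
#' The written file round-trips bit-identically through
#' [read_recording()] with `layout = "magnitude"` (values are printed at full
#' double precision).
#'
#' @param v a [magnitude_series()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_magnitude_csv <- function(v, path) {
  stopifnot(is_magnitude_series(v))
  writeLines(formatC(as.numeric(v), format = "g", digits = 17), path)
  invisible(path)
}

#' Check that two recordings are comparable
#'
#' Two series may enter a comparison only if they are in the same unit and —
#' when both rates are known — were captured at the same sampling rate.
#'
#' @param a,b [magnitude_series()] objects.
#' @return `list(a, b)` invisibly if comparable; otherwise an error.
#' @export
validate_pair <- function(a, b) {
  stopifnot(is_magnitude_series(a), is_magnitude_series(b))
  if (!identical(series_unit(a), series_unit(b))) {
    stop(sprintf("unit mismatch: %s vs %s — convert explicitly first",
                 series_unit(a), series_unit(b)), call. = FALSE)
  }
  ra <- series_rate(a); rb <- series_rate(b)
  if (!is.na(ra) && !is.na(rb) && ra != rb) {
    stop(sprintf("sampling-rate mismatch: %g Hz vs %g Hz", ra, rb),
         call. = FALSE)
  }
  invisible(list(a = a, b = b))
}

#' Convert a magnitude series between acceleration units
#'
#' Explicit conversion using 1 g = 9.80665 m/s^2 (and the dataset's
#' m/s^2 x 100 convention). Never applied implicitly: the pipeline requires
#' matching units and refuses otherwise.
#'
#' @param v a [magnitude_series()].
#' @param to target unit tag.
#' @return The converted [magnitude_series()].
#' @export
convert_unit <- function(v, to = c("m/s2", "g", "m/s2x100")) {
  stopifnot(is_magnitude_series(v))
  to <- match.arg(to)
  # factors to m/s2
  to_ms2 <- c("g" = 9.80665, "m/s2" = 1, "m/s2x100" = 0.01)
  out <- as.numeric(v) * to_ms2[[series_unit(v)]] / to_ms2[[to]]
  magnitude_series(out, unit = to, rate_hz = series_rate(v),
                   source = attr(v, "source") %||% "")
}
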