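# Run an expression with a locally seeded RNG, restoring the caller's state.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Choose the movement cycle to compare
#'
#' The comparison deliberately analyses a single cycle: over a whole
#' recording the warping path always hugs the ideal line and differences
#' wash out. The cycle multiple `k` is drawn uniformly from
#' `1..sample_limit` where `sample_limit = floor(total_length / period) - 1`;
#' the window then runs from sample `k * period` to `k * period + period`,
#' inclusive (`period + 1` samples, 1-based).
#'
#' @param total_length length of the conditioned, aligned series.
#' @param period cycle length in samples.
#' @param seed integer seed for the draw (`NULL` = current RNG state).
#' @param k optional explicit cycle multiple, overriding the random draw
#'   (used to reproduce a printed window).
#' @return An object of class `cycle_window`: list with `initial_sample`,
#'   `final_sample`, `k`, `sample_limit`, `seed`.
#' @export
#' @examples
#' select_cycle_window(2976, 124, k = 3)  # samples 372..496
select_cycle_window <- function(total_length, period, seed = NULL, k = NULL) {
  period <- as.integer(period)
  total_length <- as.integer(total_length)
  if (total_length < 2L * period) {
    stop(sprintf("series of %d samples is shorter than two cycles (period %d)",
                 total_length, period), call. = FALSE)
  }
  sample_limit <- total_length %/% period - 1L
  if (is.null(k)) {
    k <- with_local_seed(seed, sample(seq_len(sample_limit), 1L))
  }
  k <- as.integer(k)
  if (k < 1L || k > sample_limit) {
    stop(sprintf("cycle multiple k = %d outside 1..%d", k, sample_limit),
         call. = FALSE)
  }
  initial <- k * period
  structure(list(initial_sample = initial, final_sample = initial + period,
                 k = k, sample_limit = sample_limit,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
            class = "cycle_window")
}

#' Least-squares line through a warping path
#'
#' Ordinary least squares of the learner index `j` on the expert index `i`
#' over the path's points, giving the line `y = m x + b` that summarizes how
#' the warped correspondence deviates from the ideal `y = x`.
#'
#' @param path a `warp_path`.
#' @return list with slope `m` and intercept `b`.
#' @export
fit_path_line <- function(path) {
  stopifnot(inherits(path, "warp_path"))
  pts <- path$points
  if (nrow(pts) < 3L) stop("path too short to regress", call. = FALSE)
  if (length(unique(pts[, "i"])) < 2L) {
    stop("undefined slope: all path points share one expert index",
         call. = FALSE)
  }
  fit <- stats::lm(j ~ i, data = as.data.frame(pts))
  co <- stats::coef(fit)
  list(m = unname(co[["i"]]), b = unname(co[["(Intercept)"]]))
}

#' Coefficient of determination of a path fit
#'
#' `1 - SS_res / SS_tot` of the fitted line over the path points: 1 when the
#' warped correspondence is perfectly linear, falling toward 0 as path points
#' scatter around the line (the learner hitting movement events at
#' inconsistent times).
#'
#' @param path a `warp_path`.
#' @param fit list with `m` and `b` from [fit_path_line()].
#' @return R-squared in \[0, 1\].
#' @export
r_squared <- function(path, fit) {
  stopifnot(inherits(path, "warp_path"))
  i <- path$points[, "i"]; j <- path$points[, "j"]
  res <- j - (fit$m * i + fit$b)
  ss_tot <- sum((j - mean(j))^2)
  if (ss_tot == 0) {
    if (all(abs(res) < 1e-9)) return(1)
    stop("degenerate path: no variance in learner indices yet nonzero ",
         "residuals", call. = FALSE)
  }
  1 - sum(res^2) / ss_tot
}

#' Mean absolute gap between the fitted line and the ideal line
#'
#' Averages `|(m * i + b) - i|` over the path's expert indices: the
#' difference measure between the regression line and `y = x`. It depends
#' only on the fit and the i-range, not on the path's j-values.
#'
#' @param fit list with `m` and `b`.
#' @param path a `warp_path` supplying the i-coordinates.
#' @return Non-negative mean absolute difference.
#' @export
mean_line_difference <- function(fit, path) {
  stopifnot(inherits(path, "warp_path"))
  i <- path$points[, "i"]
  mean(abs(fit$m * i + fit$b - i))
}

#' Localize where two aligned windows disagree
#'
#' Flags the expert-side sample ranges where the per-point warping cost
#' `|u[j] - v[i]|` exceeds `band_fraction` of the windows' value spread, and
#' merges flagged runs separated by fewer than `merge_gap` samples. This is
#' the feedback extension: it turns the verdict into "fix the movement
#' between samples a and b".
#'
#' @param expert_window,learner_window the compared windows (numeric).
#' @param path the `warp_path` through their cost matrix.
#' @param band_fraction cost threshold as a fraction of the windows' combined
#'   value range; default 0.25.
#' @param merge_gap flagged runs closer than this many samples are merged;
#'   default 5.
#' @return data.frame with columns `start`, `end`: 1-based expert-side sample
#'   ranges within the window. Zero rows when nothing exceeds the band.
#' @export
localize_discrepancy <- function(expert_window, learner_window, path,
                                 band_fraction = 0.25, merge_gap = 5L) {
  stopifnot(inherits(path, "warp_path"))
  v <- as.numeric(expert_window); u <- as.numeric(learner_window)
  spread <- max(c(v, u)) - min(c(v, u))
  thr <- band_fraction * spread
  i <- path$points[, "i"]; j <- path$points[, "j"]
  cost <- abs(u[j] - v[i])
  flagged <- sort(unique(i[cost > thr]))
  if (length(flagged) == 0L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  brk <- which(diff(flagged) >= merge_gap)
  start <- flagged[c(1L, brk + 1L)]
  end <- flagged[c(brk, length(flagged))]
  data.frame(start = start, end = end)
}

#' Three-criterion similarity verdict
#'
#' Two movements are declared similar iff their periods are equal, the path
#' regression's R-squared exceeds `r2_min`, and the mean absolute difference
#' between the fitted line and `y = x` is below `diff_max`. The operational
#' thresholds are `r2_min = 0.9` and `diff_max = 10`; the idealized rule
#' (difference exactly 0 and R-squared exactly 1) is recovered by setting
#' `diff_max = 0` tolerance-free thresholds.
#'
#' @param periods_equal logical from the period gate.
#' @param r2 R-squared of the path fit (may be `NA` if the gate stopped the
#'   pipeline).
#' @param mean_diff mean line difference (may be `NA`).
#' @param diff_max,r2_min thresholds.
#' @return list with `verdict` (`"similar"` or `"different"`) and `reasons`
#'   (character vector of failed criteria, empty when similar).
#' @export
verdict <- function(periods_equal, r2, mean_diff, diff_max = 10,
                    r2_min = 0.9) {
  reasons <- character(0)
  if (!isTRUE(periods_equal)) reasons <- c(reasons, "period")
  if (is.na(r2) || r2 <= r2_min) reasons <- c(reasons, "r_squared")
  if (is.na(mean_diff) || mean_diff >= diff_max) {
    reasons <- c(reasons, "line_difference")
  }
  ok <- isTRUE(periods_equal) && !is.na(r2) && r2 > r2_min &&
    !is.na(mean_diff) && mean_diff < diff_max
  list(verdict = if (ok) "similar" else "different",
       reasons = if (ok) character(0) else reasons)
}

#' Compare two periodic movement recordings
#'
#' The full pipeline: unit/rate validation, period estimation by Pearson
#' iterations for each recording, the period-equality gate, phase
#' synchronization of the learner to the expert, start-at-maximum trimming
#' and common-length truncation, min-max normalization and moving-average
#' filtering, selection of one movement cycle, dynamic time warping over that
#' window, least-squares regression of the warping path against the ideal
#' line `y = x`, and the three-criterion verdict with discrepancy
#' localization.
#'
#' @param expert,learner [magnitude_series()] objects in the same unit.
#' @param path_method `"greedy"` (default, the adjacent-side walker) or
#'   `"dp"` (optimal dynamic programming).
#' @param diff_max,r2_min verdict thresholds (defaults 10 and 0.9).
#' @param filter_window moving-average width, default 5.
#' @param normalize_scale min-max target range top, default 10000.
#' @param seed integer seed driving the random cycle choice.
#' @param window_k explicit cycle multiple overriding the random choice.
#' @param peak_params maxima-detection parameters, see
#'   [find_profile_maxima()].
#' @param profile_method `"fft"` or `"direct"` Pearson-iteration evaluation.
#' @param band_fraction,merge_gap discrepancy-localization parameters.
#' @param continue_on_period_mismatch when `TRUE` (default) the pipeline
#'   still warps and regresses using the expert's period after an unequal
#'   period gate (the verdict is already "different"); when `FALSE` it stops
#'   at the gate and the regression fields are `NA`.
#' @return An object of class `comparison_report`; see
#'   [report_to_json()] for the serialized schema.
#' @export
compare_movements <- function(expert, learner,
                              path_method = c("greedy", "dp"),
                              diff_max = 10, r2_min = 0.9,
                              filter_window = 5L, normalize_scale = 10000,
                              seed = NULL, window_k = NULL,
                              peak_params = list(min_height = 0.5,
                                                 min_separation = 3L),
                              profile_method = c("fft", "direct"),
                              band_fraction = 0.25, merge_gap = 5L,
                              continue_on_period_mismatch = TRUE) {
  path_method <- match.arg(path_method)
  profile_method <- match.arg(profile_method)
  validate_pair(expert, learner)

  per1 <- estimate_period(pearson_iterations(expert, method = profile_method,
                                             peak_params = peak_params))
  per2 <- estimate_period(pearson_iterations(learner, method = profile_method,
                                             peak_params = peak_params))
  pe <- periods_equal(per1$period, per2$period)
  period <- per1$period                       # "Cicle Equal"

  base <- list(period_expert = per1$period, period_learner = per2$period,
               spacing_expert = per1$spacing, spacing_learner = per2$spacing,
               periods_equal = pe,
               thresholds = list(diff_max = diff_max, r2_min = r2_min),
               path_method = path_method)

  if (!pe && !continue_on_period_mismatch) {
    vd <- verdict(pe, NA_real_, NA_real_, diff_max, r2_min)
    return(structure(c(base, list(
      m = NA_real_, b = NA_real_, r_squared = NA_real_,
      mean_line_diff = NA_real_, verdict = vd$verdict, reasons = vd$reasons,
      shift_applied = NA_integer_, common_length = NA_integer_,
      low_confidence = NA, window = NULL,
      discrepant_segments = data.frame(start = integer(0), end = integer(0)))),
      class = "comparison_report"))
  }

  sync <- synchronize(expert, learner, period)
  ve <- condition_series(sync$expert_aligned, window = filter_window,
                         scale = normalize_scale)
  ue <- condition_series(sync$learner_aligned, window = filter_window,
                         scale = normalize_scale)
  win <- select_cycle_window(length(ve), period, seed = seed, k = window_k)
  idx <- win$initial_sample:win$final_sample
  vw <- as.numeric(ve)[idx]; uw <- as.numeric(ue)[idx]

  cm <- cost_matrix(vw, uw)
  path <- warp_path(cm, method = path_method)
  fit <- fit_path_line(path)
  r2 <- r_squared(path, fit)
  md <- mean_line_difference(fit, path)
  vd <- verdict(pe, r2, md, diff_max, r2_min)
  seg <- localize_discrepancy(vw, uw, path, band_fraction = band_fraction,
                              merge_gap = merge_gap)
  if (nrow(seg) > 0L) {       # window-local -> absolute 1-based sample numbers
    seg$start <- seg$start + win$initial_sample - 1L
    seg$end <- seg$end + win$initial_sample - 1L
  }

  structure(c(base, list(
    m = fit$m, b = fit$b, r_squared = r2, mean_line_diff = md,
    verdict = vd$verdict, reasons = vd$reasons,
    shift_applied = sync$shift_applied, common_length = sync$common_length,
    low_confidence = sync$low_confidence, window = win,
    discrepant_segments = seg, path = path)),
    class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report>\n")
  cat(sprintf("  periods: expert %d, learner %d (%s)\n",
              x$period_expert, x$period_learner,
              if (x$periods_equal) "equal" else "different"))
  if (!is.null(x$window)) {
    cat(sprintf("  window: samples %d..%d (cycle k = %d)\n",
                x$window$initial_sample, x$window$final_sample, x$window$k))
  }
  if (!is.na(x$r_squared)) {
    cat(sprintf("  fit: y = %.4fx + %.4f, R-squared = %.4f, line diff = %.6f\n",
                x$m, x$b, x$r_squared, x$mean_line_diff))
  }
  cat(sprintf("  verdict: %s%s\n", x$verdict,
              if (length(x$reasons)) paste0(" (", paste(x$reasons,
                                                        collapse = ", "), ")")
              else ""))
  if (!is.null(x$discrepant_segments) && nrow(x$discrepant_segments) > 0L) {
    cat(sprintf("  discrepant segments: %s\n",
                paste(sprintf("%d-%d", x$discrepant_segments$start,
                              x$discrepant_segments$end), collapse = ", ")))
  }
  invisible(x)
}

#' Serialize a comparison report to JSON
#'
#' All scalar fields plus the window, thresholds and discrepant segments,
#' with 1-based sample indices. The schema shipped at
#' `system.file("schema", "report-schema.json", package = "movewarp")`
#' documents the fields; [validate_report()] checks a report against it.
#'
#' @param report a `comparison_report`.
#' @param path optional file to write to.
#' @return The JSON string (invisibly when `path` is given).
#' @export
report_to_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "comparison_report"))
  x <- unclass(report)
  x$path <- NULL                              # the full path is CSV territory
  x$reasons <- as.list(x$reasons)             # keep [] not null when empty
  if (!is.null(x$window)) x$window <- unclass(x$window)
  x$discrepant_segments <- if (nrow(report$discrepant_segments) > 0L) {
    unname(apply(report$discrepant_segments, 1L,
                 function(r) as.list(r), simplify = FALSE))
  } else list()
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Validate a serialized report against the shipped schema
#'
#' Checks that every required field of the report schema is present and has
#' the expected JSON type.
#'
#' @param json a JSON string, a path to a JSON file, or a parsed list.
#' @return `TRUE` invisibly, or an error naming the first violation.
#' @export
validate_report <- function(json) {
  x <- if (is.list(json)) json else jsonlite::fromJSON(json,
                                                       simplifyVector = FALSE)
  schema_path <- system.file("schema", "report-schema.json",
                             package = "movewarp")
  sch <- jsonlite::fromJSON(schema_path, simplifyVector = FALSE)
  for (field in names(sch$properties)) {
    spec <- sch$properties[[field]]
    required <- field %in% unlist(sch$required)
    if (is.null(x[[field]])) {
      if (required && !isTRUE(spec$nullable)) {
        stop(sprintf("report missing required field '%s'", field),
             call. = FALSE)
      }
      next
    }
    ok <- switch(spec$type,
                 number = is.numeric(x[[field]]) || is.na(x[[field]]),
                 integer = (is.numeric(x[[field]]) &&
                              (is.na(x[[field]]) ||
                                 x[[field]] == round(x[[field]]))),
                 string = is.character(x[[field]]),
                 boolean = is.logical(x[[field]]) || is.na(x[[field]]),
                 array = is.list(x[[field]]) || is.vector(x[[field]]),
                 object = is.list(x[[field]]),
                 TRUE)
    if (!ok) {
      stop(sprintf("report field '%s' is not of type %s", field, spec$type),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}
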