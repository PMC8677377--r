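#' Specification of a synthetic accelerometer-like periodic signal
#'
#' Describes one recording for the generator. The defaults emulate the salsa
#' step recordings the pipeline was designed around: 124-sample cycles, 24
#' cycles (~3000 samples), a gait-like waveform with one sharp impact peak and
#' one broad swing hump per cycle, magnitudes on the m/s^2 x 100 scale
#' (baseline 1000 ~ gravity, amplitude 400) and additive Gaussian sensor
#' noise at 5 % of the movement amplitude.
#'
#' @param period_samples samples per movement cycle (>= 4); default 124.
#' @param n_cycles number of cycles (>= 2); default 24.
#' @param waveform `"gait"` (asymmetric peak + hump), `"sine"`, or
#'   `"harmonics"` (three-harmonic sum).
#' @param amplitude movement amplitude in signal units; default 400.
#' @param baseline additive offset (resting magnitude); default 1000.
#' @param noise_sd additive Gaussian noise standard deviation; default 20.
#' @param phase_shift_samples circular phase offset applied to the waveform,
#'   in samples; default 0.
#' @param tempo_factor cycle-length multiplier: the effective period is
#'   `round(period_samples * tempo_factor)` (0.5 halves the cycle, i.e. the
#'   mover goes twice as fast); default 1.
#' @param seed integer RNG seed for the noise; default 1.
#' @return An object of class `signal_spec`.
#' @export
signal_spec <- function(period_samples = 124L, n_cycles = 24L,
                        waveform = c("gait", "sine", "harmonics"),
                        amplitude = 400, baseline = 1000, noise_sd = 20,
                        phase_shift_samples = 0L, tempo_factor = 1,
                        seed = 1L) {
  waveform <- match.arg(waveform)
  period_samples <- as.integer(period_samples)
  n_cycles <- as.integer(n_cycles)
  stopifnot(period_samples >= 4L, n_cycles >= 2L, noise_sd >= 0,
            tempo_factor > 0, amplitude >= 0)
  structure(list(period_samples = period_samples, n_cycles = n_cycles,
                 waveform = waveform, amplitude = amplitude,
                 baseline = baseline, noise_sd = noise_sd,
                 phase_shift_samples = as.integer(phase_shift_samples),
                 tempo_factor = tempo_factor, seed = as.integer(seed)),
            class = "signal_spec")
}

# Unit-amplitude waveform templates on phase in [0, 1).
# The gait template's constants are fixed: a sharp impact peak at phase 0.25
# (width 0.05) and a broad swing hump at phase 0.65 (width 0.18), weighted
# 1.6 : 0.7 — one asymmetric event pair per cycle, which a pure sine lacks.
waveform_template <- function(phase, waveform) {
  switch(waveform,
         sine = sin(2 * pi * phase),
         harmonics = sin(2 * pi * phase) + 0.5 * sin(4 * pi * phase) +
           0.25 * sin(6 * pi * phase),
         gait = 1.6 * exp(-((phase - 0.25) / 0.05)^2) +
           0.7 * exp(-((phase - 0.65) / 0.18)^2))
}

#' Generate a synthetic periodic magnitude series
#'
#' Evaluates the spec's waveform over `n_cycles` cycles of the effective
#' period (`round(period_samples * tempo_factor)`), applies the phase offset,
#' adds seeded Gaussian noise, and clamps at zero (magnitudes are moduli).
#' Identical specs produce bit-identical series; with `noise_sd = 0` the
#' signal is exactly periodic.
#'
#' @param spec a [signal_spec()].
#' @return A [magnitude_series()] of length
#'   `round(period_samples * tempo_factor) * n_cycles`, unit `"m/s2x100"`.
#' @export
generate_signal <- function(spec) {
  stopifnot(inherits(spec, "signal_spec"))
  p_eff <- max(4L, as.integer(round(spec$period_samples * spec$tempo_factor)))
  n <- p_eff * spec$n_cycles
  t <- seq_len(n) - 1L
  phase <- ((t + spec$phase_shift_samples) %% p_eff) / p_eff
  clean <- spec$baseline + spec$amplitude * waveform_template(phase,
                                                              spec$waveform)
  noise <- if (spec$noise_sd > 0) {
    with_local_seed(spec$seed, stats::rnorm(n, 0, spec$noise_sd))
  } else {
    numeric(n)
  }
  magnitude_series(pmax(0, clean + noise), unit = "m/s2x100",
                   source = sprintf("synthetic:%s", spec$waveform))
}

#' Generate an expert/learner pair with a labeled perturbation
#'
#' The expert is drawn from `expert_spec`; the learner is the same movement
#' with one controlled perturbation and independent noise. The label states
#' what the algorithm should conclude: phase offsets, amplitude scaling and
#' mild noise are tolerated (synchronization and normalization remove them,
#' label `"similar"`), while tempo changes (a different cycle length, caught
#' by the period gate) and large mid-cycle shape distortions are not (label
#' `"different"`).
#'
#' Perturbation magnitudes default to realistic severities: a quarter-cycle
#' phase offset, amplitude x 1.8, tempo x 0.5, and a shape distortion that
#' replaces the middle 40 % of every cycle with its time-reverse scaled by
#' the magnitude (default 2).
#'
#' @param expert_spec a [signal_spec()] for the expert.
#' @param perturbation one of `"none"`, `"phase"`, `"amplitude"`, `"tempo"`,
#'   `"shape"`.
#' @param magnitude perturbation strength: samples for `"phase"`
#'   (default `period/4`), scale factor for `"amplitude"` (default 1.8),
#'   tempo factor for `"tempo"` (default 0.5), distortion scale for
#'   `"shape"` (default 2).
#' @param seed integer seed; the learner's noise stream is derived from it.
#' @return list with `expert`, `learner` ([magnitude_series()]) and
#'   `truth_label` (`"similar"` or `"different"`).
#' @export
generate_pair <- function(expert_spec = signal_spec(),
                          perturbation = c("none", "phase", "amplitude",
                                           "tempo", "shape"),
                          magnitude = NULL, seed = 1L) {
  stopifnot(inherits(expert_spec, "signal_spec"))
  perturbation <- match.arg(perturbation)
  seed <- as.integer(seed)

  es <- expert_spec
  es$seed <- seed
  expert <- generate_signal(es)

  ls <- es
  ls$seed <- seed + 1000003L                  # independent learner noise
  label <- "similar"
  if (perturbation == "phase") {
    ls$phase_shift_samples <- ls$phase_shift_samples +
      as.integer(magnitude %||% (es$period_samples %/% 4L))
  } else if (perturbation == "amplitude") {
    ls$amplitude <- ls$amplitude * (magnitude %||% 1.8)
  } else if (perturbation == "tempo") {
    ls$tempo_factor <- ls$tempo_factor * (magnitude %||% 0.5)
    label <- "different"
  }
  learner <- generate_signal(ls)
  if (perturbation == "shape") {
    learner <- distort_shape(learner, es$period_samples,
                             scale = magnitude %||% 2)
    label <- "different"
  }
  list(expert = expert, learner = learner, truth_label = label)
}

# Replace the middle span of every cycle with its time-reverse, scaled about
# the cycle mean: the learner starts and ends each cycle correctly but
# performs the central movement wrong.
distort_shape <- function(v, period, scale = 2, span = c(0.30, 0.70)) {
  x <- as.numeric(v)
  n <- length(x)
  lo <- max(1L, as.integer(floor(span[1] * period)))
  hi <- min(period, as.integer(ceiling(span[2] * period)))
  for (c0 in seq(0L, n - 1L, by = period)) {
    idx <- (c0 + lo):min(c0 + hi, n)
    seg <- x[idx]
    x[idx] <- mean(seg) + scale * (rev(seg) - mean(seg))
  }
  series_like(pmax(0, x), v)
}

#' Run the labeled-pair benchmark
#'
#' Generates `n_pairs` expert/learner pairs — half from the tolerated
#' (similar-class) perturbations none/phase/amplitude, half from the
#' rejected (different-class) perturbations tempo/shape — runs the full
#' pipeline on each, and reports how often the verdict agrees with the truth
#' label.
#'
#' @param n_pairs total number of pairs (split evenly between classes);
#'   default 200.
#' @param seed integer seed; pair `i` uses `seed + i`.
#' @param expert_spec base [signal_spec()] for every expert.
#' @param ... passed to [compare_movements()].
#' @return list with `agreement` (fraction in \[0, 1\]), `n_pairs`, and a
#'   data.frame `results` (perturbation, truth, verdict, agree).
#' @export
label_fidelity_benchmark <- function(n_pairs = 200L, seed = 20260921L,
                                     expert_spec = signal_spec(), ...) {
  similar_kinds <- c("none", "phase", "amplitude")
  different_kinds <- c("tempo", "shape")
  half <- n_pairs %/% 2L
  kinds <- c(rep_len(similar_kinds, half), rep_len(different_kinds,
                                                   n_pairs - half))
  rows <- vector("list", n_pairs)
  for (i in seq_len(n_pairs)) {
    pr <- generate_pair(expert_spec, perturbation = kinds[i],
                        seed = seed + i)
    rep <- compare_movements(pr$expert, pr$learner, seed = seed + i, ...)
    rows[[i]] <- data.frame(perturbation = kinds[i], truth = pr$truth_label,
                            verdict = rep$verdict,
                            agree = rep$verdict == pr$truth_label)
  }
  results <- do.call(rbind, rows)
  list(agreement = mean(results$agree), n_pairs = n_pairs, results = results)
}
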