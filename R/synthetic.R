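# Seeded generators for every input the analysis pipeline consumes, so all
# stages are testable without instrument data or downloads. Each generator
# is the right-inverse of its analyzer at zero noise.

#' Generate a protein sequence realizing a composition row
#'
#' Reconstructs integer counts from a printed percentage row (see
#' [reconstruct_counts()]) and emits a uniformly shuffled sequence with
#' exactly those counts, so `count_residues()` recovers them and
#' re-rounded percentages reproduce the row (up to the row's own printing
#' inconsistencies). Identical `(length, row, seed)` gives an identical
#' sequence.
#'
#' @param length Chain length.
#' @param composition_row Named percentage row over the 20 residues.
#' @param seed Integer seed (mandatory for reproducibility).
#' @param id Record id for the returned `ssb_records` row.
#' @param ... Passed to [reconstruct_counts()].
#' @return A one-row `ssb_records` data frame.
#' @export
generate_protein <- function(length, composition_row, seed, id = "synthetic",
                             ...) {
  counts <- reconstruct_counts(composition_row, length, ...)
  pool <- rep(names(counts), times = unclass(counts))
  seq <- paste(with_seed(seed, sample(pool)), collapse = "")
  out <- data.frame(id = id,
                    description = paste0("synthetic realization, seed ", seed),
                    residues = seq, stringsAsFactors = FALSE)
  class(out) <- c("ssb_records", "data.frame")
  out
}

#' Generate a synthetic inverse-titration curve
#'
#' Thin wrapper over [simulate_titration()] with the defaults of the
#' emulated experiment: 1.5 nmol of tetramer titrated with a 76-nucleotide
#' oligo.
#'
#' @inheritParams simulate_titration
#' @return An `ssb_titration`.
#' @export
generate_titration <- function(n, Q, K = Inf, P = 1.5, L = 76,
                               grid = seq(0, 2.4, by = 0.1),
                               noise_sd = 0, seed = NULL, salt_mM = 100) {
  simulate_titration(n = n, Q = Q, K = K, P = P, L = L, grid = grid,
                     noise_sd = noise_sd, seed = seed, salt_mM = salt_mM)
}

#' Generate a synthetic two-state melting curve
#'
#' A two-state sigmoid between two linear baselines:
#' `signal = lower(T) + (upper(T) - lower(T)) / (1 + exp(-(T - tm)/width))`
#' plus seeded Gaussian noise. The default grid emulates a 25-95 degC UV
#' melt read every 0.5 degC.
#'
#' @param tm True melting temperature (degC), strictly inside the grid.
#' @param width Transition width parameter (degC); ~2.5 is typical of a
#'   short duplex.
#' @param baseline_low,baseline_high `(intercept, slope)` of the lower and
#'   upper baselines.
#' @param noise_sd Gaussian noise s.d. in signal units.
#' @param grid Temperatures (degC), strictly increasing.
#' @param seed Optional integer seed.
#' @return List of class `ssb_melting`: `temperature`, `signal`, `tm_true`.
#' @export
generate_melting <- function(tm, width = 2.5,
                             baseline_low = c(0.60, 0.0005),
                             baseline_high = c(0.95, 0.0005),
                             noise_sd = 0, grid = seq(25, 95, by = 0.5),
                             seed = NULL) {
  if (tm <= min(grid) || tm >= max(grid)) fail("tm must lie inside the temperature grid")
  lower <- baseline_low[1] + baseline_low[2] * grid
  upper <- baseline_high[1] + baseline_high[2] * grid
  sig <- lower + (upper - lower) / (1 + exp(-(grid - tm) / width))
  if (noise_sd > 0) sig <- with_seed(seed, sig + stats::rnorm(length(sig), 0, noise_sd))
  structure(list(temperature = grid, signal = sig, tm_true = tm),
            class = "ssb_melting")
}

#' Generate a synthetic DSC thermogram
#'
#' A single Gaussian excess-heat-capacity peak on a flat baseline, the
#' minimal trace from which a peak-maximum Tm can be read.
#'
#' @param tm Peak temperature (degC), inside the grid.
#' @param width Peak s.d. (degC).
#' @param height Peak height (arbitrary units).
#' @param noise_sd Gaussian noise s.d.
#' @param grid Temperatures (degC).
#' @param seed Optional integer seed.
#' @return List of class `ssb_melting`.
#' @export
generate_thermogram <- function(tm, width = 4, height = 1, noise_sd = 0,
                                grid = seq(20, 110, by = 0.5), seed = NULL) {
  if (tm <= min(grid) || tm >= max(grid)) fail("tm must lie inside the temperature grid")
  sig <- height * exp(-(grid - tm)^2 / (2 * width^2))
  if (noise_sd > 0) sig <- with_seed(seed, sig + stats::rnorm(length(sig), 0, noise_sd))
  structure(list(temperature = grid, signal = sig, tm_true = tm),
            class = "ssb_melting")
}

#' Generate a synthetic thermal-inactivation time course
#'
#' First-order decay of binding activity, `exp(-t * log(2) / half_life)`,
#' on the incubation grid of the emulated experiment (0, 1, 2.5, 5, 10, 15,
#' 30, 45, 60 min), plus seeded Gaussian noise clipped to `[0, 1]`.
#'
#' @param half_life True half-life (minutes).
#' @param grid Incubation times (minutes), increasing from 0.
#' @param noise_sd Gaussian noise s.d. on the fraction scale.
#' @param seed Optional integer seed.
#' @param temperature_label Incubation temperature label (degC).
#' @return List of class `ssb_timecourse`: `times`, `fraction_bound`,
#'   `temperature_label`, `half_life_true`.
#' @export
generate_timecourse <- function(half_life,
                                grid = c(0, 1, 2.5, 5, 10, 15, 30, 45, 60),
                                noise_sd = 0, seed = NULL,
                                temperature_label = NA) {
  stopifnot(half_life > 0, grid[1] == 0, all(diff(grid) > 0))
  fb <- exp(-grid * log(2) / half_life)
  if (noise_sd > 0) {
    fb <- with_seed(seed, fb + stats::rnorm(length(fb), 0, noise_sd))
    fb <- pmin(pmax(fb, 0), 1)
  }
  structure(list(times = grid, fraction_bound = fb,
                 temperature_label = temperature_label,
                 half_life_true = half_life),
            class = "ssb_timecourse")
}

#' Generate synthetic gel-filtration standards
#'
#' Retention times placed on a chosen log-linear line,
#' `rt = (log10(mass) - intercept) / slope`, with optional seeded jitter.
#' The default masses are the classic four-protein calibration kit
#' (beta-amylase 200, alcohol dehydrogenase 150, bovine albumin 66,
#' carbonic anhydrase 29 kDa); default line places them at realistic
#' analytical-column retention times (~15-28 min).
#'
#' @param masses Standard masses (kDa).
#' @param slope,intercept The generating line `log10(kDa) = slope * rt +
#'   intercept`.
#' @param jitter_sd Gaussian jitter s.d. on retention times (min).
#' @param seed Optional integer seed.
#' @return Data frame `mass_kda`, `retention_min`, with the generating line
#'   in attributes `slope`/`intercept`.
#' @export
generate_calibration <- function(masses = c(200, 150, 66, 29),
                                 slope = -0.065, intercept = 3.3,
                                 jitter_sd = 0, seed = NULL) {
  stopifnot(slope != 0, all(masses > 0))
  rt <- (log10(masses) - intercept) / slope
  if (jitter_sd > 0) rt <- with_seed(seed, rt + stats::rnorm(length(rt), 0, jitter_sd))
  structure(data.frame(mass_kda = masses, retention_min = rt),
            slope = slope, intercept = intercept)
}
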