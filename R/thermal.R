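# Melting-curve Tm extraction, duplex destabilization, thermal-inactivation
# half-lives, and DSC peak read-off.

.check_melting <- function(temperature, signal) {
  if (length(temperature) < 10L) fail("melting curve needs at least 10 points")
  if (any(diff(temperature) <= 0)) fail("temperature must increase strictly")
  if (length(signal) != length(temperature)) fail("temperature/signal length mismatch")
}

#' Extract a melting temperature from an instrument trace
#'
#' Three read-off rules:
#'
#' * `"midpoint"` (default for UV melting): linear baselines are fitted to
#'   the first and last `baseline_frac` of the temperature range, the signal
#'   is normalized between them, and Tm is the temperature at which the
#'   normalized transition crosses 0.5 (linear interpolation). Invariant to
#'   affine rescaling of the signal.
#' * `"derivative"`: Tm at the extremum of the centered finite-difference
#'   dS/dT after 3-point smoothing.
#' * `"dsc-peak"` (for DSC thermograms): temperature of the signal maximum.
#'
#' @param temperature Strictly increasing temperatures (degrees C), at least
#'   10 points; alternatively an `ssb_melting` curve (then `signal` is
#'   ignored).
#' @param signal A260 (or excess heat capacity) at each temperature.
#' @param method `"midpoint"`, `"derivative"` or `"dsc-peak"`.
#' @param baseline_frac Fraction of the temperature range used for each
#'   baseline fit (midpoint method).
#' @return List of class `ssb_tm`: `value` (degrees C), `method`.
#' @export
extract_tm <- function(temperature, signal = NULL,
                       method = c("midpoint", "derivative", "dsc-peak"),
                       baseline_frac = 0.2) {
  method <- match.arg(method)
  if (inherits(temperature, "ssb_melting")) {
    signal <- temperature$signal
    temperature <- temperature$temperature
  }
  .check_melting(temperature, signal)
  np <- length(temperature)

  value <- switch(method,
    "dsc-peak" = {
      i <- which.max(signal)
      if (i == 1L || i == np) fail("no transition detected: peak at trace edge")
      temperature[i]
    },
    "derivative" = {
      sm <- stats::filter(signal, rep(1 / 3, 3), sides = 2)
      sm[1] <- signal[1]; sm[np] <- signal[np]
      d <- (sm[c(2:np, np)] - sm[c(1, 1:(np - 1))]) /
           (temperature[c(2:np, np)] - temperature[c(1, 1:(np - 1))])
      i <- which.max(abs(d))
      if (i == 1L || i == np) fail("no transition detected: extremum at trace edge")
      temperature[i]
    },
    "midpoint" = {
      # locate the transition from the smoothed derivative, then fit the
      # baselines outside it (one full width at half maximum on each side,
      # so the two windows sit symmetrically about the transition and
      # residual tail curvature cancels); fall back to fixed end windows
      # when the transition leaves too few points on a side
      sm <- stats::filter(signal, rep(1 / 3, 3), sides = 2)
      sm[1] <- signal[1]; sm[np] <- signal[np]
      d <- (sm[c(2:np, np)] - sm[c(1, 1:(np - 1))]) /
           (temperature[c(2:np, np)] - temperature[c(1, 1:(np - 1))])
      i0 <- which.max(abs(d))
      W <- diff(range(temperature[abs(d) >= abs(d[i0]) / 2]))
      # equal-span windows on both sides so residual tail curvature cancels
      span <- min(temperature[i0] - W - temperature[1],
                  temperature[np] - (temperature[i0] + W))
      lo_idx <- which(temperature >= temperature[i0] - W - span &
                      temperature <= temperature[i0] - W)
      hi_idx <- which(temperature >= temperature[i0] + W &
                      temperature <= temperature[i0] + W + span)
      k <- max(3L, ceiling(baseline_frac * np))
      if (length(lo_idx) < 3L) lo_idx <- seq_len(k)
      if (length(hi_idx) < 3L) hi_idx <- seq(np - k + 1L, np)
      lo_fit <- lm(signal[lo_idx] ~ temperature[lo_idx])
      hi_fit <- lm(signal[hi_idx] ~ temperature[hi_idx])
      lower <- coef(lo_fit)[1] + coef(lo_fit)[2] * temperature
      upper <- coef(hi_fit)[1] + coef(hi_fit)[2] * temperature
      amp <- upper - lower
      mid_amp <- stats::median(amp)
      resid_sd <- max(stats::sd(stats::residuals(lo_fit)),
                      stats::sd(stats::residuals(hi_fit)), 1e-12)
      if (abs(mid_amp) < 4 * resid_sd) fail("no transition detected: baselines coincide")
      norm <- (signal - lower) / amp
      if (norm[1] > norm[np]) norm <- 1 - norm   # accept either direction
      crossing <- which(norm[-np] < 0.5 & norm[-1] >= 0.5)
      if (!length(crossing)) fail("no transition detected: no 0.5 crossing")
      i <- crossing[1]
      t0 <- temperature[i]; t1 <- temperature[i + 1]
      y0 <- norm[i]; y1 <- norm[i + 1]
      t0 + (0.5 - y0) / (y1 - y0) * (t1 - t0)
    })
  structure(list(value = unname(value), method = method), class = "ssb_tm")
}

#' @export
print.ssb_tm <- function(x, ...) {
  cat(sprintf("Tm = %.1f degC (%s)\n", x$value, x$method)); invisible(x)
}

#' Duplex destabilization by an ssDNA-binding protein
#'
#' `Tm(free duplex) - Tm(duplex + SSB)`; positive values mean the protein
#' lowers the duplex melting temperature, the thermodynamic signature of
#' selective ssDNA binding.
#'
#' @param tm_free,tm_complex `ssb_tm` objects or plain temperatures (degC).
#' @return Destabilization in degrees C (antisymmetric under swap).
#' @export
delta_tm <- function(tm_free, tm_complex) {
  v <- function(x) if (inherits(x, "ssb_tm")) x$value else as.numeric(x)
  v(tm_free) - v(tm_complex)
}

#' Half-life of binding activity from an inactivation time course
#'
#' The incubation time at which the bound fraction crosses 0.5, by linear
#' interpolation between the bracketing observations. If the final point is
#' still at or above 0.5 the half-life is right-censored at the last
#' observation time (printed as e.g. `> 60 min`), which is a first-class
#' outcome on a finite incubation grid.
#'
#' @param times Increasing incubation times (minutes), starting at 0;
#'   alternatively an `ssb_timecourse` (then `fraction_bound` is ignored).
#' @param fraction_bound Bound fraction in `[0, 1]` at each time; the first
#'   value is the uninactivated reference and must be at least 0.5.
#' @return List of class `ssb_half_life`: `minutes`, `censored`.
#' @examples
#' half_life(c(0, 15), c(1.0, 0.5))        # 15 min
#' half_life(c(0, 10), c(1.0, 0.0))        # 5 min by interpolation
#' @export
half_life <- function(times, fraction_bound = NULL) {
  if (inherits(times, "ssb_timecourse")) {
    fraction_bound <- times$fraction_bound
    times <- times$times
  }
  if (length(times) != length(fraction_bound)) fail("length mismatch")
  if (length(times) < 2L || times[1] != 0 || any(diff(times) <= 0)) {
    fail("times must increase strictly from 0")
  }
  if (fraction_bound[1] < 0.5) fail("already inactivated: first point below 0.5")
  below <- which(fraction_bound < 0.5)
  if (!length(below)) {
    exact <- which(abs(fraction_bound - 0.5) < 1e-12)
    if (length(exact)) {
      return(structure(list(minutes = times[exact[1]], censored = FALSE),
                       class = "ssb_half_life"))
    }
    return(structure(list(minutes = times[length(times)], censored = TRUE),
                     class = "ssb_half_life"))
  }
  i <- below[1]
  f0 <- fraction_bound[i - 1]; f1 <- fraction_bound[i]
  t <- times[i - 1] + (f0 - 0.5) / (f0 - f1) * (times[i] - times[i - 1])
  structure(list(minutes = unname(t), censored = FALSE), class = "ssb_half_life")
}

#' @export
print.ssb_half_life <- function(x, ...) {
  cat(if (x$censored) sprintf("half-life > %g min (censored)\n", x$minutes)
      else sprintf("half-life = %g min\n", x$minutes))
  invisible(x)
}

#' @export
format.ssb_half_life <- function(x, ...) {
  if (x$censored) paste0(">", format(x$minutes)) else format(x$minutes)
}
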