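# Gel-filtration calibration, native-mass estimation and oligomer calls.

#' Fit a gel-filtration calibration curve
#'
#' Ordinary least squares of `log10(mass)` on retention time over the
#' standard proteins, the standard size-exclusion calibration. The slope is
#' negative on a gel-filtration column (larger proteins elute earlier).
#'
#' @param standards Data frame with columns `mass_kda` and `retention_min`,
#'   at least three standards with distinct retention times.
#' @return List of class `ssb_calibration`: `slope`, `intercept`,
#'   `r_squared`, `standards`.
#' @export
fit_calibration <- function(standards) {
  stopifnot(is.data.frame(standards),
            all(c("mass_kda", "retention_min") %in% names(standards)))
  if (nrow(standards) < 3L || length(unique(standards$retention_min)) < 3L) {
    fail("need at least 3 standards with distinct retention times")
  }
  fit <- lm(log10(mass_kda) ~ retention_min, data = standards)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = summary(fit)$r.squared,
                 standards = standards),
            class = "ssb_calibration")
}

#' @export
print.ssb_calibration <- function(x, ...) {
  cat(sprintf("Gel-filtration calibration: log10(kDa) = %.4f * rt + %.3f (R^2 = %.4f, %d standards)\n",
              x$slope, x$intercept, x$r_squared, nrow(x$standards)))
  invisible(x)
}

#' Native mass from a retention time
#'
#' `10^(slope * retention + intercept)`, in kDa at one decimal place.
#' Retention times outside the standards' range are extrapolations and are
#' flagged via the `"extrapolated"` attribute.
#'
#' @param curve An `ssb_calibration`.
#' @param retention Retention time(s), minutes.
#' @return Mass(es) in kDa (1 dp), with attribute `extrapolated`.
#' @export
estimate_native_mass <- function(curve, retention) {
  stopifnot(inherits(curve, "ssb_calibration"))
  mass <- round_half_up(10^(curve$slope * retention + curve$intercept), 1)
  rng <- range(curve$standards$retention_min)
  attr(mass, "extrapolated") <- retention < rng[1] | retention > rng[2]
  mass
}

#' Oligomeric-state call from native and monomer mass
#'
#' The native-to-monomer mass ratio, rounded to one decimal, classified
#' against integer assembly states: `"homotetramer"` for ratios within
#' `window` of 4, `"dimer"` within `window` of 2, `"monomer"` within
#' `window` of 1, otherwise `"ambiguous"`. The default window of 0.5
#' accommodates the calibration uncertainty of analytical gel filtration
#' (observed tetramer ratios for this family span 3.8-4.4).
#'
#' @param native_mass,monomer_mass Masses in kDa (any common unit).
#' @param window Half-width of the acceptance band around each integer
#'   state.
#' @return List of class `ssb_oligomer_call`: `native_mass_kda`,
#'   `monomer_mass_kda`, `ratio` (1 dp), `state_label`.
#' @examples
#' oligomer_state(59, 15.6)  # ratio 3.8, homotetramer
#' @export
oligomer_state <- function(native_mass, monomer_mass, window = 0.5) {
  stopifnot(native_mass > 0, monomer_mass > 0, window > 0)
  ratio <- round_half_up(native_mass / monomer_mass, 1)
  state <- if (abs(ratio - 4) <= window) "homotetramer"
           else if (abs(ratio - 2) <= window) "dimer"
           else if (abs(ratio - 1) <= window) "monomer"
           else "ambiguous"
  structure(list(native_mass_kda = native_mass,
                 monomer_mass_kda = monomer_mass,
                 ratio = ratio, state_label = state),
            class = "ssb_oligomer_call")
}

#' @export
print.ssb_oligomer_call <- function(x, ...) {
  cat(sprintf("%.1f kDa native / %.1f kDa monomer = %.1f -> %s\n",
              x$native_mass_kda, x$monomer_mass_kda, x$ratio, x$state_label))
  invisible(x)
}
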