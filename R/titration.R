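# Inverse fluorescence titration: forward model and site-size fitting.
#
# Geometry matches the experiment: a fixed amount of SSB tetramer (1.5 nmol
# in 2 ml) is titrated with increasing amounts of an oligonucleotide of L
# nucleotides; intrinsic Trp fluorescence is quenched in proportion to the
# fraction of tetramer bound. An oligonucleotide of length L carries L/n
# tetramer-equivalents of binding capacity, where n is the occluded site
# size in nucleotides per tetramer. Bound tetramer B at total protein P and
# total capacity S satisfies the single-site mass-action equilibrium
#   B = K (P - B)(S - B),
# whose physical root is
#   B = ((KP + KS + 1) - sqrt((KP + KS + 1)^2 - 4 K^2 P S)) / (2K).
# K -> Inf gives the stoichiometric (tight-binding) limit B = min(P, S),
# i.e. a piecewise-linear titration with breakpoint at D = n P / L.

.theta_bound <- function(D, n, K, P, L) {
  S <- D * L / n
  if (is.infinite(K)) return(pmin(P, S) / P)
  a <- K * P + K * S + 1
  B <- (a - sqrt(pmax(a^2 - 4 * K^2 * P * S, 0))) / (2 * K)
  B / P
}

#' Simulate an inverse fluorescence titration
#'
#' Forward model for a protein-fixed, DNA-added titration: relative
#' fluorescence `1 - Q * theta(D)` where `theta` is the bound-tetramer
#' fraction under a capacity-based single-site equilibrium (see source
#' comments), plus optional Gaussian noise, clipped to `[0, 1]`.
#'
#' @param n Occluded site size, nucleotides per tetramer.
#' @param Q Maximal fractional fluorescence quench at saturation, in
#'   `[0, 1]`.
#' @param K Association constant (per nmol in the fixed reaction volume);
#'   `Inf` (default) is the tight-binding limit.
#' @param P Total protein (tetramer), nmol.
#' @param L Oligonucleotide length, nucleotides.
#' @param grid Cumulative added oligonucleotide amounts (nmol), strictly
#'   increasing from 0.
#' @param noise_sd Gaussian noise s.d. on the relative fluorescence scale.
#' @param seed Optional integer seed; the caller's RNG stream is untouched.
#' @param salt_mM NaCl label carried on the curve (2, 100 or 300 in the
#'   emulated experiment).
#' @return List of class `ssb_titration`: `protein_nmol`, `oligo_length`,
#'   `added_oligo`, `relative_fluorescence`, `salt_mM`.
#' @examples
#' tc <- simulate_titration(n = 32, Q = 0.93)
#' fit_site_size(tc)
#' @export
simulate_titration <- function(n, Q, K = Inf, P = 1.5, L = 76,
                               grid = seq(0, 2.4, by = 0.1),
                               noise_sd = 0, seed = NULL, salt_mM = 100) {
  stopifnot(n > 0, Q >= 0, Q <= 1, K > 0, P > 0, L > 0, noise_sd >= 0)
  if (grid[1] != 0 || any(diff(grid) <= 0)) {
    fail("oligo grid must start at 0 and increase strictly")
  }
  f <- 1 - Q * .theta_bound(grid, n, K, P, L)
  if (noise_sd > 0) {
    f <- with_seed(seed, f + stats::rnorm(length(f), 0, noise_sd))
  }
  structure(list(protein_nmol = P, oligo_length = L, added_oligo = grid,
                 relative_fluorescence = pmin(pmax(f, 0), 1),
                 salt_mM = salt_mM),
            class = "ssb_titration")
}

#' Estimate binding site size from a titration curve
#'
#' Two estimators of the occluded site size n (nucleotides per tetramer)
#' and saturation quench Q:
#'
#' * `"breakpoint"` (default): least-squares fit of the tight-binding
#'   piecewise form `F(D) = 1 - Q * min(D, Db) / Db` (a line through (0, 1)
#'   meeting a plateau); `n = L * Db / P`. This is the classical graphical
#'   breakpoint read-off made objective.
#' * `"equilibrium"`: nonlinear least squares on the full forward model,
#'   additionally estimating the association constant K (a nuisance
#'   parameter; the experiment determines only n and Q well when binding is
#'   tight).
#'
#' The curve must reach saturation: if the final two points are still
#' declining by more than `sat_tol`, the fit is refused.
#'
#' @param curve An `ssb_titration`.
#' @param mode `"breakpoint"` or `"equilibrium"`.
#' @param sat_tol Maximal tail decline (mean of the last two points vs the
#'   two before) compatible with saturation, in relative fluorescence
#'   units; the default is three times a typical 2% instrument noise.
#' @return List of class `ssb_binding_fit`: `site_size_n`, `quench_Q`,
#'   `k_obs`, `ci_n` (half-width of the 95% interval on n), `mode`,
#'   `salt_mM`.
#' @export
fit_site_size <- function(curve, mode = c("breakpoint", "equilibrium"),
                          sat_tol = 0.06) {
  mode <- match.arg(mode)
  stopifnot(inherits(curve, "ssb_titration"))
  D <- curve$added_oligo
  fl <- curve$relative_fluorescence
  m <- length(D)
  if (m < 6L) fail("need at least 6 titration points")
  # still declining at the end? compare the mean of the last two points with
  # the mean of the two before them, which is robust to point-level noise
  if (mean(fl[(m - 3):(m - 2)]) - mean(fl[(m - 1):m]) > sat_tol) {
    fail("titration not saturated")
  }
  P <- curve$protein_nmol; L <- curve$oligo_length

  # start values from the geometry: plateau ~ min F, breakpoint where the
  # curve first comes within noise of the plateau
  plateau0 <- min(fl)
  Q0 <- min(max(1 - plateau0, 0.05), 1)
  Db0 <- D[which(fl <= plateau0 + 0.02)[1]]
  if (!is.finite(Db0) || Db0 <= 0) Db0 <- stats::median(D)

  if (mode == "breakpoint") {
    fit <- minpack.lm::nlsLM(
      fl ~ 1 - Q * pmin(D, Db) / Db,
      start = list(Q = Q0, Db = Db0),
      lower = c(0, D[2] / 2), upper = c(1, max(D) * 2),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    est <- coef(fit)
    se <- sqrt(diag(vcov(fit)))
    n_hat <- L * est[["Db"]] / P
    ci_n <- 1.96 * se[["Db"]] * L / P
    k_obs <- Inf
    Q_hat <- est[["Q"]]
  } else {
    fit <- minpack.lm::nlsLM(
      fl ~ 1 - Q * .theta_bound(D, n, exp(logK), P, L),
      start = list(Q = Q0, n = L * Db0 / P, logK = log(50)),
      lower = c(0, 1, log(1e-3)), upper = c(1, 10 * L, log(1e8)),
      control = minpack.lm::nls.lm.control(maxiter = 500))
    est <- coef(fit)
    se <- sqrt(diag(vcov(fit)))
    n_hat <- est[["n"]]
    ci_n <- 1.96 * se[["n"]]
    k_obs <- exp(est[["logK"]])
    Q_hat <- est[["Q"]]
  }
  structure(list(site_size_n = unname(n_hat), quench_Q = unname(Q_hat),
                 k_obs = unname(k_obs), ci_n = unname(ci_n), mode = mode,
                 salt_mM = curve$salt_mM),
            class = "ssb_binding_fit")
}

#' @export
print.ssb_binding_fit <- function(x, ...) {
  cat(sprintf("Binding fit (%s mode, %s mM NaCl): n = %.1f +/- %.1f nt, Q = %.2f\n",
              x$mode, format(x$salt_mM), x$site_size_n, x$ci_n, x$quench_Q))
  invisible(x)
}

#' Compare site-size fits across salt concentrations
#'
#' SSBs can switch between ssDNA binding modes with ionic strength (the
#' EcoSSB's 35- vs 65-nucleotide modes are the classic case). Given fits at
#' two or more salt labels, the verdict is `"salt-independent"` when all
#' estimates agree pairwise within their combined uncertainties, otherwise
#' `"mode transition"`, reporting the low- and high-salt estimates.
#'
#' @param fits List of `ssb_binding_fit` objects with distinct `salt_mM`.
#' @return List of class `ssb_salt_comparison`: `verdict`, `estimates`
#'   (data frame of salt, n, ci), and for a transition `low_salt_n` /
#'   `high_salt_n`.
#' @export
compare_salt_modes <- function(fits) {
  if (inherits(fits, "ssb_binding_fit")) fits <- list(fits)
  if (length(fits) < 2L) fail("need fits at two or more salt concentrations")
  est <- data.frame(
    salt_mM = vapply(fits, function(f) as.numeric(f$salt_mM), numeric(1)),
    site_size_n = vapply(fits, function(f) f$site_size_n, numeric(1)),
    ci_n = vapply(fits, function(f) f$ci_n, numeric(1)))
  est <- est[order(est$salt_mM), ]
  pairs <- utils::combn(nrow(est), 2)
  incompatible <- apply(pairs, 2, function(ij) {
    abs(est$site_size_n[ij[1]] - est$site_size_n[ij[2]]) >
      est$ci_n[ij[1]] + est$ci_n[ij[2]]
  })
  out <- list(estimates = est)
  if (any(incompatible)) {
    out$verdict <- "mode transition"
    out$low_salt_n <- est$site_size_n[1]
    out$high_salt_n <- est$site_size_n[nrow(est)]
  } else {
    out$verdict <- "salt-independent"
  }
  structure(out, class = "ssb_salt_comparison")
}

#' @export
print.ssb_salt_comparison <- function(x, ...) {
  cat("Salt-dependence verdict:", x$verdict, "\n")
  print(x$estimates, row.names = FALSE)
  invisible(x)
}
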