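# Monomer mass, isoelectric point and aliphatic index from residue counts.

# Average (isotope-abundance-weighted) residue masses in Da, i.e. amino acid
# minus water; one water is added back per chain.
.RESIDUE_MASS <- c(
  A = 71.0788,  I = 113.1594, L = 113.1594, V = 99.1326,  M = 131.1926,
  G = 57.0519,  P = 97.1167,  K = 128.1741, R = 156.1875, D = 115.0886,
  E = 129.1155, Q = 128.1307, N = 114.1038, S = 87.0782,  T = 101.1051,
  H = 137.1411, W = 186.2132, F = 147.1766, Y = 163.1760, C = 103.1388)

.WATER_DA <- 18.02

#' Average residue masses
#'
#' @return Named vector of average residue masses (Da) for the 20 canonical
#'   amino acids (residue = amino acid minus one water).
#' @export
residue_masses <- function() .RESIDUE_MASS

#' Monomer molecular mass
#'
#' Average (not monoisotopic) chain mass: sum of count-weighted average
#' residue masses plus one water (18.02 Da), in kDa at one decimal place.
#'
#' @param counts `ssb_counts`, or a sequence/record.
#' @param digits Decimal places for the returned kDa value.
#' @return Mass in kDa.
#' @examples
#' monomer_mass("G")  # 0.1 kDa: one glycine residue plus water
#' @export
monomer_mass <- function(counts, digits = 1) {
  counts <- .as_counts(counts)
  if (sum(counts) == 0L) fail("empty composition")
  round_half_up((sum(unclass(counts) * .RESIDUE_MASS[names(counts)]) + .WATER_DA) / 1000,
                digits)
}

#' Aliphatic index
#'
#' Ikai's thermostability correlate: the relative volume occupied by
#' aliphatic side chains,
#' `100 * (nAla + 2.9 * nVal + 3.9 * (nIle + nLeu)) / length`,
#' reported at two decimals. Ranges from 0 to 390 (poly-Ile/Leu).
#'
#' @param counts `ssb_counts`, or a sequence/record.
#' @return Aliphatic index (2 dp).
#' @examples
#' aliphatic_index("AAAA")  # 100
#' @export
aliphatic_index <- function(counts) {
  counts <- .as_counts(counts)
  n <- sum(counts)
  if (n == 0L) fail("empty composition")
  round_half_up(100 * (counts["A"] + 2.9 * counts["V"] +
                       3.9 * (counts["I"] + counts["L"])) / n, 2)[[1]]
}

#' Bjellqvist pKa set
#'
#' The pKa values used by the standard web calculators for protein pI
#' (Bjellqvist's immobilized-pH-gradient calibration): side chains D 4.05,
#' E 4.45, C 9.0, Y 10.0, H 5.98, K 10.0, R 12.0, and termini 7.5 (alpha
#' amino) / 3.55 (alpha carboxyl). Cysteines are treated as fully reduced
#' (all ionizable).
#'
#' @return List with named vectors `positive` and `negative`.
#' @export
pka_bjellqvist <- function() {
  list(positive = c(Nterm = 7.50, H = 5.98, K = 10.00, R = 12.00),
       negative = c(Cterm = 3.55, D = 4.05, E = 4.45, C = 9.00, Y = 10.00))
}

# Net charge at a given pH from Henderson-Hasselbalch occupancies; strictly
# decreasing in pH, so the pI (its unique root) is found by bisection.
net_charge <- function(pH, counts, pka = pka_bjellqvist()) {
  counts <- .as_counts(counts)
  npos <- c(Nterm = 1, counts[intersect(names(pka$positive), names(counts))])
  nneg <- c(Cterm = 1, counts[intersect(names(pka$negative), names(counts))])
  pos <- sum(npos * 1 / (1 + 10^(pH - pka$positive[names(npos)])))
  neg <- sum(nneg * 1 / (1 + 10^(pka$negative[names(nneg)] - pH)))
  pos - neg
}

#' Isoelectric point
#'
#' pH at which the net charge of the chain is zero, from
#' Henderson-Hasselbalch occupancies of the ionizable side chains (D, E, C,
#' Y, H, K, R) plus one amino and one carboxyl terminus. The root is found
#' by bisection on `[0, 14]` to a tolerance of 0.001 and reported at two
#' decimals. The pKa set is exchangeable; the default is [pka_bjellqvist()].
#'
#' @param counts `ssb_counts`, or a sequence/record.
#' @param pka A pKa set shaped like [pka_bjellqvist()].
#' @param tol Bisection tolerance in pH units.
#' @return pI (2 dp).
#' @export
isoelectric_point <- function(counts, pka = pka_bjellqvist(), tol = 1e-3) {
  counts <- .as_counts(counts)
  lo <- 0; hi <- 14
  if (net_charge(lo, counts, pka) < 0) return(round_half_up(lo, 2))
  if (net_charge(hi, counts, pka) > 0) return(round_half_up(hi, 2))
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (net_charge(mid, counts, pka) > 0) lo <- mid else hi <- mid
  }
  round_half_up((lo + hi) / 2, 2)
}

#' Sequence-derived physicochemical report
#'
#' Monomer mass, pI, aliphatic index and cysteine count, the four
#' sequence-derived characteristics tabulated for each SSB.
#'
#' @param counts `ssb_counts`, or a sequence/record.
#' @param pka pKa set for the pI computation.
#' @return A one-row data frame with columns `monomer_mass_kda`, `pi`,
#'   `aliphatic_index`, `cys_count`.
#' @export
physchem_report <- function(counts, pka = pka_bjellqvist()) {
  counts <- .as_counts(counts)
  data.frame(monomer_mass_kda = monomer_mass(counts),
             pi = isoelectric_point(counts, pka),
             aliphatic_index = aliphatic_index(counts),
             cys_count = unname(unclass(counts)["C"]))
}
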