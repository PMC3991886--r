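---
title: "Methods: characterization statistics for psychrophilic SSBs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: characterization statistics for psychrophilic SSBs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psychrossb)
```

# Scope and design

`psychrossb` implements the analytical layer of a biochemical
characterization of bacterial single-stranded DNA-binding proteins (SSBs)
from cold-adapted bacteria: everything that turns raw tables and
instrument-style traces into the quantities such a study reports. The
wet-lab side (cloning, expression, purification, electrophoresis imaging)
is out of scope, as are BLAST-style domain searches and the construction of
multiple alignments — pre-aligned sequences are accepted as input.

The package is organized as an analysis workflow: the numbered scripts
under `analysis/` are thin narrative drivers that each run one stage of the
characterization and write their tables under `results/`; every actual
computation lives in the package functions so that the tests and the
acceptance script exercise identical code.

# Composition statistics and count reconstruction

Published composition tables print per-residue percentages at one decimal
place, and the original sequences are not part of the tables. The package
therefore reconstructs integer counts from a printed row and the chain
length: round `pct * L / 100` to the nearest integer, then repair any
deficit or surplus in the total by largest-remainder apportionment (each
residue moved at most one step; ties broken by descending fractional part,
then alphabetically, so the result is deterministic). Rounding throughout
the package is half-away-from-zero, the convention of the printed tables
(11.267 prints as 11.3).

Reconstruction is verified by re-rounding: percentages recomputed from the
reconstructed counts must reproduce the printed row. Two rows of the
packaged table fail this check for reasons internal to the published
table itself: one row sums to 102.1% and contains a Ser entry that no
integer count at its stated length can produce, and another contains an
unrealizable Thr entry. Because these are transcription-level slips in the
source material rather than reconstruction failures, the verification
*warns* by default (`check = "error"` restores strictness), and the
affected derived values are treated as approximate below.

The cold-adaptation statistics follow the field's group definitions:
charged {D, E, K, H, R}, polar {N, Q, S, T, Y}, aromatic {F, W, Y}, Gly,
Pro, amide {Q, N}, and Arg/(Arg+Lys) at two decimals. The hydrophobic set
{A, I, L, V, M, G, P, F, W} reproduces the published hydrophobic contents
for all ten proteins exactly and is fixed. Two published statistics are
deliberately *not* asserted against: the "tiny plus small" contents, whose
published values are not reproducible from the composition table under any
standard tiny/small definition (the default here is Taylor's small set,
reported as indicative), and the amide (Gln+Asn) figures, which disagree
with the table sums by a few tenths and were evidently computed from
unrounded counts or mistyped.

# Physicochemical indices

**Monomer mass** is the count-weighted sum of average residue masses plus
one water (18.02 Da), reported in kDa at one decimal. From reconstructed
counts this reproduces six of the eight published masses exactly; the two
exceptions (off by exactly 0.1 kDa) are the proteins with corrupt
composition rows. A reconstruction from percentages rounded to 0.05% of
the chain length carries an intrinsic mass uncertainty of several tens of
daltons, so agreement to within one unit in the last printed digit is the
supported resolution, and that is what the acceptance tests assert (the
hand-verified value, 15.6 kDa, is asserted exactly).

**Aliphatic index** is Ikai's volume-weighted aliphatic content,
`100 (nA + 2.9 nV + 3.9 (nI + nL)) / L`, at two decimals. It depends only
on four counts that reconstruct unambiguously, and reproduces all eight
published values exactly.

**Isoelectric point** finds the root of the net-charge function built from
Henderson–Hasselbalch occupancies of D, E, C, Y, H, K, R and the two
termini. The charge function is strictly decreasing in pH, so bisection on
[0, 14] (tolerance 0.001, reported at two decimals) converges to the unique
root. The default pKa set is Bjellqvist's, the set behind the common web
calculators, with cysteines treated as fully reduced; the set is a
configurable argument because published pI values rarely state their pKa
source. Six of eight published values are matched within ±0.05 (the
hand-verified one exactly). The two outliers are documented rather than
absorbed by a looser tolerance: one is the protein with the corrupt
composition row (reconstructed charged-residue counts are off), and the
other was computed at 7.99 against a printed 7.79 — with counts
reconstructed from rounded percentages a ±1 error in a His or Lys count
shifts a near-neutral pI by about this much, so the discrepancy cannot be
attributed to the pKa set alone.

# Alignment identity and similarity

Pairwise identity/similarity percentages use an end-to-end global
alignment (affine gap cost `open + L * extend`, BLOSUM62 with 10/0.5 by
default; PAM-series matrices selectable). The dynamic programming is
delegated to Biostrings and is verified in the tests against exhaustive
enumeration of all alignments for short pairs. The published percentages
were produced with unstated alignment parameters, so exact reproduction is
not promised anywhere; the single published-value check is tolerance-based
(±5 points) and requires the real public sequence records, which are not
distributed with the package.

Similarity is defined by the study's six residue groups (V L I M / W F Y /
E D / K R / Q D / S T; D intentionally sits in two groups). The default
denominator for both percentages is the full alignment length, which makes
them symmetric in the two sequences; the shorter-sequence denominator is
available as an option. Percentages are reported as integers, matching the
published table.

MSA conservation shading computes, per column, the largest fraction of
sequences carrying mutually similar residues (gaps never count as
similar), classed at the conventional 100% / ≥80% / ≥60% editor bands. The
published figure legend phrases the lower bands as "<80%"/"<60%"; this is
read as the conventional ≥ bands, as in standard alignment editors.

# Binding-site size from inverse titrations

The titration geometry is protein-fixed: 1.5 nmol of SSB tetramer in a
fixed volume, titrated with a 76-mer oligonucleotide, tracking intrinsic
tryptophan fluorescence. The published analysis cites a cooperative
binding model whose equations the study does not reproduce; the forward
model here is a deliberately simpler capacity-based single-site
equilibrium — an oligonucleotide of length `L` carries `L/n` tetramer
binding equivalents, bound tetramer solves one mass-action quadratic, and
relative fluorescence is `1 − Q·θ` — which is sufficient to define and
recover the two estimands the study reports (site size `n` and saturation
quench `Q`) and honest about what the source specifies. The association
constant `K` is a nuisance parameter; `K = Inf` is the tight-binding
(stoichiometric) limit, a piecewise-linear curve with breakpoint at
`D = nP/L`.

Two estimators are provided. The default breakpoint estimator fits the
tight-binding piecewise form (a declining line anchored at (0, 1) meeting a
plateau) by nonlinear least squares; `n = L·Db/P`, `Q = 1 − plateau`. The
equilibrium estimator fits the full model including `log K` and converges
to the breakpoint estimate as `K → ∞`. Saturation is required before
fitting: if the mean of the last two points is still more than `sat_tol`
below the mean of the two preceding points the fit is refused. The default
`sat_tol = 0.06` is three times a typical 2% instrument noise level — a
tail decline that large is incompatible with a reached plateau but well
clear of noise-induced false alarms.

Simulated recovery at the study's conditions (n ∈ {30…65}, Q ∈
{0.53…0.93}, 2% noise, 25-point grid to 2.4 nmol) returns the site size
within ±2 nt and the quench within ±0.03 — the precisions the study
quotes — in ≥95% of replicates across that grid. The hardest corner
(large site, shallow quench) is individually noisier because the
pre-breakpoint slope carries less information; this is a property of the
experiment, not of the estimator. Salt-dependence verdicts compare fits at
different NaCl labels: estimates pairwise compatible within their combined
95% half-widths are "salt-independent", otherwise a "mode transition" is
reported with the low- and high-salt sizes.

# Melting curves, half-lives, DSC

UV melting curves are analyzed by the midpoint rule: linear baselines are
fitted below and above the transition, the signal is normalized between
them, and Tm is the 0.5 crossing (linear interpolation). The transition is
located first from the smoothed derivative, and the two baseline windows
are placed symmetrically around it (one full width at half maximum away,
equal spans on both sides) so that residual sigmoid tail curvature cancels;
on symmetric synthetic curves the midpoint is then recovered exactly at
zero noise, and within half a 0.5 °C grid step at 1% noise. The method is
invariant to affine rescaling of the signal. A derivative read-off and a
DSC peak-maximum read-off are also provided; the published study does not
state which rule produced its duplex values, and midpoint is the
conventional default for UV melts. Destabilization is
`ΔTm = Tm(free) − Tm(complex)`, positive for destabilization.

Inactivation half-lives interpolate the 0.5 crossing of the bound fraction
on the experimental incubation grid (0, 1, 2.5, 5, 10, 15, 30, 45, 60
min). A series still at or above 0.5 at the last point yields a
right-censored value, printed as e.g. `>60` — a first-class outcome, since
the experimental grid tops out at 60 min.

# Gel-filtration calibration and oligomer calls

Calibration is ordinary least squares of `log10(mass)` on retention time
over the standards; native mass is read back through the fitted line, with
extrapolation flagged. Because the study's retention times are
unpublished, the calibration path is exercised on synthetic standards (the
classic 200/150/66/29-kDa kit placed on a chosen line), and oligomer calls
for the study's proteins are made directly from the published native
masses. The native-to-monomer ratio is classified with a ±0.5 band around
integer assembly states; the tetramer band then contains all seven
published ratios (3.8–4.4), and the bands for dimer and monomer are
analogous. The window is configurable; widening it trades specificity for
tolerance of calibration error.

# Synthetic data: what it does and does not show

Every instrument input has a seeded generator (`generate_titration`,
`generate_melting`, `generate_thermogram`, `generate_timecourse`,
`generate_calibration`, `generate_protein`), each a right-inverse of its
analyzer at zero noise and within stated tolerance at the documented noise
levels. Noise is independent Gaussian on the reported scale (2% relative
fluorescence for titrations, ~1% of amplitude for melts, 0.02 bound
fraction for time courses, 0.15 min retention jitter), seeds are explicit
arguments everywhere, and no call touches the global RNG stream. Default
scenario parameters mirror the published panel (site sizes 30–32 with one
31→45 salt switcher, quenches 0.81–0.93, duplex Tm 75 °C dropping to
58–70 °C, the 60–100 °C half-life grid).

What passing these tests shows is that the estimators are correct and
precise under their own forward models. What they cannot show is
instrument realism: real titrations have inner-filter effects and drift,
real melts have sloped, curved baselines and partially reversible
transitions, real time courses are not single-exponential. Conclusions
about the real proteins rest on the published measurements; the synthetic
layer validates the arithmetic applied to them.

# Problem sizes and numerical choices

All simulations run at desk scale: the recovery study is 600 fits on
25-point curves (about a second), melting grids are 141 points, and the
alignment oracle enumerates all alignments for pairs up to length 7. pI
bisection tolerance is 0.001 pH; nonlinear fits use Levenberg–Marquardt
with box constraints and geometry-derived starting values; degenerate
inputs (empty sequences, unsaturated titrations, transitionless traces,
sub-3-point calibrations, ragged alignments) are refused with specific
messages rather than silently absorbed.

# Known limitations

* Published identity/similarity values cannot be reproduced without the
  real sequence records and the original alignment parameters; the
  similarity machinery is instead verified by enumeration and invariants.
* The titration forward model omits cooperativity and overlap-lattice
  statistics; `K` from the equilibrium mode is an effective constant, not
  comparable to literature association constants.
* The two corrupt composition rows propagate into mass (±0.1 kDa) and pI
  (up to ±0.2) for the affected proteins; the package reports these
  discrepancies instead of repairing rows it cannot verify.
* Thermogram analysis is peak read-off only: no deconvolution, reversibility
  analysis, or van't Hoff enthalpies.
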