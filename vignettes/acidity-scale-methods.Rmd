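---
title: "Methods: building an acidity scale in a low-permittivity solvent"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building an acidity scale in a low-permittivity solvent}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acidscale)
```

## The measurement model

In a solvent of low relative permittivity such as 1,2-difluorobenzene
(ε~r~ = 13.4), deprotonation of an acid HA by a base B produces the ion pair
BH⁺A⁻ rather than free ions, and the solvated-proton activity is not
experimentally accessible. The package therefore works entirely with
*relative* acidities, in three layers.

**Spectral layer.** When two acids share a solution and a titrant, the
equilibrium HA₁ + BH⁺A₂⁻ ⇌ HA₂ + BH⁺A₁⁻ links their dissociation degrees
α = [A⁻]/([A⁻]+[HA]). Under the Hammett assumption (activity-coefficient
ratios of anion/neutral pairs are equal for structurally similar acids in
the same solution — adopted here as an untested modelling assumption,
appropriate for the delocalised anions this chemistry uses), the ion-pair
acidity difference is

$$\Delta pK_{ip} = pK_{ip}(HA_2) - pK_{ip}(HA_1)
  = \log_{10}\frac{\alpha_1(1-\alpha_2)}{\alpha_2(1-\alpha_1)}.$$

`unmix_spectra()` obtains the α values by modelling each mixture spectrum
as a linear combination of the four pure-form basis spectra (HA₁, A₁⁻, HA₂,
A₂⁻) and solving by unweighted linear least squares over all wavelengths.
Normalising each acid's deprotonated coefficient by the sum of its two
coefficients cancels dilution, so explicit titrant-volume tracking is
unnecessary.

**Ion-pairing layer.** The measured ΔpK~ip~ differs from the free-ion
ΔpK~a~ by the difference of the two salts' ion-pair dissociation constants.
`fuoss_pkd()` evaluates the Fuoss sphere-in-continuum model in CGS units
exactly as its constants are conventionally written
(q = 4.80 × 10⁻¹⁰ cm^3/2^ g^1/2^ s⁻¹, k = 1.38 × 10⁻¹⁶ cm² g s⁻² K⁻¹,
N = 6.02 × 10²³ mol⁻¹), taking interionic distances in Ångström at the
public interface; computing internally in CGS avoids silent SI conversion
mistakes. Two algebraically equivalent routes (direct exponential form and
expanded logarithmic form) are both implemented and are required by the
test suite to agree to 10⁻¹⁰ — an internal-consistency guard, not a
physical claim. Ionic radii enter as the arithmetic mean of up to three
estimators (equivalent sphere, bounding cuboid, surface-segment distance);
radii for real compounds are user inputs, never recomputed from structures.
The model assumes spherical ions with delocalised charge; for the radius
ranges typical of these systems the whole correction stays within about
0.2 pK units, so moderate nonsphericity shifts individual compounds
slightly without stretching or compressing the scale.

**Ladder layer.** `fit_ladder()` assigns one value per node from the graph
of pairwise differences by minimising
$SS = \sum_i \{\Delta_i - [x(b_i) - x(a_i)]\}^2$ on the graph incidence
structure (QR-based solve of the reduced normal equations; a disconnected
graph is an error listing the components rather than a silent per-component
fit). The consistency standard deviation $s = \sqrt{SS/(n_m - n_c)}$
summarises internal scatter; it does not include anchoring uncertainty.

## Anchoring and degrees of freedom

Three anchoring modes cover the ways a floating relative scale is pinned:
one node fixed (`fixed_single`, e.g. picric acid at 0 for a relative
scale); several externally computed reference values with a fitted common
offset (`offset_multi` — the offset minimising the squared differences is
their mean difference); and bridging solutions of known
pH~abs~^H2O^ (`bridging`, arithmetically identical, used to align a
potentiometric ladder with the aqueous pH scale; defaults 6.0 and 8.9 for
the two bridging solutions used in 1,2-DFB work).

The counting of $n_c$ when anchors are pinned is genuinely ambiguous
("number of assigned values" can include or exclude pinned nodes). The
default counts only freely fitted parameters — free nodes, plus one for the
offset in the offset modes — which is the defensible degrees-of-freedom
definition; `nc_counts_anchors = TRUE` reproduces the alternative reading.
Both conventions are exposed because published consistency values cannot
always be attributed to one of them.

## Exclusion of inconsistent series

Measurement series that pass instrumental QC can still be systematically
off. `exclude_inconsistent()` removes them greedily: fit, find the worst
absolute residual, exclude that edge if it reaches the threshold (default
0.75 pH/pK units), refit, repeat; ties are broken by input order, excluded
edges are retained in the report, and an exclusion that would disconnect
the graph stops the process with a warning instead. Greedy worst-first is
documented as the tie-break because the alternative (manual removal of
whole series) is not reproducible.

A caveat the test suite makes explicit: an outlier's least-squares residual
is its size times one minus the leverage of its edge. On a bridge edge
(leverage 1) an outlier is statistically invisible, and in sparse graphs
leverage is high enough that ±1.0 outliers routinely fall below a 0.75
threshold. The exclusion tests therefore use well-connected graphs
(20 nodes / 120 edges) and assess detection across replicates, while
requiring that clean edges are *never* excluded. Practically: redundancy in
the measurement plan, not the exclusion rule, is what buys outlier
detectability.

## Potentiometry QC

`select_stable_window()` slides a 15-minute window over the trace
(time-based, so the nominal 10 s cadence may wobble by a couple of
seconds), selects the window of minimum standard deviation, and estimates
drift as the least-squares slope within that window — window-local rather
than whole-record, since the stable segment is what is averaged. A series
passes QC if the window standard deviation is below 1 mV and |drift| is
below 4 mV h⁻¹. Potential differences convert to acidity differences via
the calibrated mean slope (−58.35 mV per pH unit); the cell polarity
convention is explicit metadata because the cell diagram alone does not fix
the sign. Uncertainty components combine by root sum of squares, with the
recommended value rounded upward to one decimal as the conservative choice.

## Transfer regressions and recommended values

`fit_transfer()` is unweighted OLS of target-solvent on source-solvent
pK~a~ values (delegated to `stats::lm`; the closed-form identities are
verified independently in the tests), with the residual standard deviation
on n − 2 degrees of freedom — the interpretation adopted for published
regression σ values, with the n-denominator RMSE as the documented
alternative. Regressions are fitted on printed (one-decimal) table values;
slopes reproduced from printed values can differ from published ones in the
second decimal, which is why the tests compare slopes within their quoted
standard errors rather than digit-for-digit.

Recommended values for indirectly characterised compounds follow two rules:
with estimates from both source solvents, the recommendation is their mean
and the uncertainty is max(baseline, |difference|/2 + 0.1); with one
estimate, the value is taken as is with uncertainty 1.0. The baseline
(default 0.5) is the RMS of the dual-row individual uncertainties and is
recomputed from the user's table by default; passing a fixed value
reproduces a published table even if the input rows differ. The
"arylmalononitrile" subset shipped with the packaged table is the ten
ArCH(CN)₂ compounds with MeCN values — an inference, since no explicit
membership list exists for the published subset regression.

All reported pK~a~/pH values and uncertainties round half-away-from-zero to
one decimal. Published tables are internally inconsistent in a couple of
borderline .x5 cells; that inconsistency is documented, not replicated.

## Unified acidity conversion

For an equimolar buffer the solvent-scale pH equals the acid's pK~a~
(ideal-solution assumption; activity and homoconjugation corrections are
deliberately not modelled — aggregation effects are a known source of
discrepancy between the spectrophotometric and potentiometric routes, and
the package reports that discrepancy rather than absorbing it). Alignment
to the aqueous scale adds the constant
$(\Delta_{solv}G^\circ_w(H^+) - \Delta_{solv}G^\circ_S(H^+)) / (RT\ln 10)$,
about −36.1 pH units for 1,2-DFB with the default energies (−899 and
−1105 kJ mol⁻¹). RT ln 10 uses 298.15 K by default (the measurement
campaign mixes 24.1 °C titrations and 25.0 °C potentiometry; the
spectrophotometric temperature 297.25 K remains the Fuoss-layer default,
and both are overridable). A 10 kJ mol⁻¹ uncertainty on either solvation
energy maps to 10/5.708 ≈ 1.75 pH units, which dwarfs every experimental
term — absolute placement of the unified scale is theory-limited.

## Synthetic data: what it emulates, what it does not

The generators produce data with the statistical structure each stage
assumes, so the pipeline is testable without instrument files:

* `gen_ladder()` — true values on a span, spanning tree plus extra edges
  (single-link nodes get a second connection first, as each compound on a
  real scale should), Gaussian edge noise, optional planted outliers.
  Defaults mirror the experimental graph: 33 nodes, 64 measurements,
  σ = 0.07 over a 15.6-unit span.
* `gen_titration()` — Beer–Lambert mixture spectra from Gaussian
  absorptivity bands (1–3 per form, randomised within ranges keeping the
  four-form basis well conditioned), dissociation states from the exact
  two-acid equilibrium, additive absorbance noise (default σ = 0.002) at
  the 10⁻⁴–10⁻⁵ mol L⁻¹ concentrations of real titrations.
* `gen_trace()` — baseline + linear drift + white noise at 10 s cadence.
* `gen_radii()` — anion radii 4.0–5.5 Å and cation radii 4.25–4.75 Å,
  the ranges over which pairwise Fuoss corrections stay within 0.2 units.

Every generator is a pure function of its arguments including the seed
(the caller's RNG stream is restored). What they do *not* emulate:
homoconjugation and ion aggregation, triple ions, baseline drift and
turbidity in spectra, electrode kinetics, and wavelength-dependent noise.
Passing tests on synthetic data therefore validate the estimators under
their stated assumptions; they do not certify behaviour on real spectra
with structured artefacts.

## Numerical choices

* Two-acid equilibrium: parameterised by the log-odds of acid 2, which
  makes the mass balance strictly monotone; solved with `uniroot` to
  10⁻¹² on the log-odds (overflow-safe logistic evaluation). Endpoints
  (no base, full neutralisation) are returned exactly.
* Unmixing: coefficients unconstrained by default (plain multilinear
  regression); a nonnegativity option (`pracma::lsqnonneg`) exists for
  noisy data. Negative coefficients beyond 5 % of an acid's total flag the
  point rather than being clipped. An optional flat-baseline regressor is
  off by default. Wavelength weighting is uniform; no defensible
  alternative weighting is documented for this chemistry.
* Usable-α window: [0.05, 0.95] on both acids. Near the endpoints the
  log-odds estimate has unbounded variance, so endpoint spectra are
  excluded from aggregation (they still appear, flagged, in the output).
* Aggregation across a titration: unweighted mean of per-spectrum
  estimates (median selectable); the simplest defensible default absent a
  published aggregation rule.
* Basis conditioning: the stacked molar-absorptivity matrix must have
  condition number below 10⁸ or unmixing errors out naming the pair.
* Ladder solver: exact QR on the reduced incidence system; rank deficiency
  raises an error rather than falling back to a minimum-norm solution,
  because with a connected, anchored graph it can only indicate a modelling
  mistake.
* Reported precision: one decimal for scale values, matching how such
  scales are tabulated; full precision is kept internally.

## Problem sizes

The test suite and acceptance script run at desk scale by design: ladder
oracle comparisons on all random connected graphs of up to 5 nodes,
consistency-recovery at the experimental 33-node/64-edge dimensions over
50–100 seeded replicates, titrations of 12–20 spectra on 200-point
wavelength grids, and hour-long synthetic traces at 10 s cadence. These
sizes exercise every code path in seconds while matching the dimensions of
the real measurement campaign.

## Known limitations

Activity coefficients, homoconjugation and aggregation are outside the
model; the Fuoss correction assumes spherical ions; anchoring to computed
pK~a~ values inherits their (large) uncertainty, which the consistency
statistic deliberately excludes; and the unified-scale placement is limited
by the proton solvation energies, not by anything this package computes.
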