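---
title: "Methods: FRET characterization with fretkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: FRET characterization with fretkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fretkit)
```

## Scope

fretkit implements the complete quantitative workflow used to characterize
a green donor fluorescent protein (mNeonGreen) paired with red acceptor
proteins (mRuby3, mScarlet-I, mCherry, mScarlet): Förster-theory
calculations from spectra, FRET efficiency from spectral unmixing of
sensitized emission, FRET efficiency from donor-lifetime shortening in
TCSPC/FLIM data, per-cell red-versus-green intensity slopes quantifying
tandem-construct expression heterogeneity, a two-state acceptor-maturation
model explaining that heterogeneity, and the permutation tests used for
significance. Because no raw microscope data accompany the published
characterization, a synthetic-data module generates every input type with
known ground truth; it is first-class, tested code and defines the
conditions under which the analysis stages are validated.

## Förster theory

The spectral overlap integral is

$$J(\lambda) = \int \bar f_D(\lambda)\, \varepsilon_A(\lambda)\, \lambda^4\, d\lambda,$$

with $\bar f_D$ the donor emission spectrum area-normalized over its
tabulated range (units nm$^{-1}$) and $\varepsilon_A$ the acceptor molar
absorption spectrum scaled so its peak equals the acceptor's extinction
coefficient (M$^{-1}$cm$^{-1}$), the standard convention since extinction
coefficients are defined at the absorption maximum. Spectra are linearly
interpolated onto the union of their wavelength grids restricted to the
overlapping range and integrated by the trapezoid rule; spectra are
smooth and typically tabulated at 1 nm, where the trapezoid error is
around 0.1% — adequate given that published extinction coefficients carry
a few percent uncertainty. Disjoint spectra give $J = 0$ with a warning
rather than an error, since zero overlap is physically meaningful.

The Förster radius follows

$$R_0^6 = 8.79\times 10^{-5}\,\kappa^2 n^{-4}\, QY_D\, J \quad [\text{Å}^6,\ J \text{ in M}^{-1}\text{cm}^{-1}\text{nm}^4],$$

the standard wavelength-in-nm form of the Förster expression. The choice
of constant was fixed by requiring that the published (J, R0) pairs for
all three acceptor pairings round-trip exactly (64, 61, 57 Å), which they
do; the unit test `test-spectra.R` verifies this for every acceptor in
the bundled fluorophore table. Defaults $\kappa^2 = 0.6667$ (freely
rotating dipoles, quoted to four figures) and $n = 1.33$ (aqueous medium)
match the published table's stated assumptions.

## Spectral FRET (linear unmixing)

A mixed emission scan collected at donor-only excitation (490–750 nm at
470 nm excitation) is decomposed as
$y(\lambda) \approx W_D \bar f_D(\lambda) + W_A \bar f_A(\lambda) + c$,
with both references area-normalized on the scan grid so the weights are
comparable across scans. Weights are constrained non-negative: they
represent photon contributions, and the published component fits are
non-negative by construction. With only two constrained coefficients the
non-negative least-squares problem is solved exactly by enumerating the
active sets (each candidate subproblem is an ordinary least-squares fit),
which also allows the optional baseline $c$ to remain unconstrained. The
baseline is off by default — cuvette scans of washed cell suspensions
have low, flat background — but is available because background levels
vary between preparations. Near-collinear reference pairs are rejected
with the condition number named in the error.

The efficiency formula has two algebraically inequivalent readings of the
same weight-ratio expression; fretkit adopts

$$E = 100 \cdot \frac{W_A}{W_A + W_D\,QY_A/QY_D},$$

the sensitized-emission form, as the default. It is the physically
consistent reading: it is exactly inverted by the forward model in which
a fraction $E$ of donor excitations is re-emitted by the acceptor
(weighted by $QY_A$) and $1-E$ by the donor (weighted by $QY_D$), so the
generator round-trip returns the generating efficiency to numerical
precision. The literal reading
$E = 100\,W_A (QY_A/QY_D)/(W_D + W_A)$ is available via
`variant = "literal"` for comparison. Direct acceptor excitation at the
donor excitation wavelength is deliberately *not* subtracted — the
efficiency definition used in the characterization has no such term — but
the generator can inject it (`direct_excitation_fraction`) so the
resulting upward bias can be quantified; a unit test does exactly that.

A `shift_nm` option on the acceptor reference accommodates in-cell
spectral shifts relative to purified-protein references (a 6 nm blue
shift of mRuby3 in tandem constructs was reported); no particular shift
is asserted.

## FLIM / TCSPC lifetime fitting

Decays are photon-count histograms in uniform bins, by default 256 bins
over 12.5 ns — one period of an 80 MHz pulsed Ti:Sapphire source. Cell
decays are formed by summing all pixels of a region of interest whose
total count exceeds a threshold; photon conservation of this step is
tested against a brute-force loop.

Tail fitting minimizes the Neyman-weighted squared residual of
$\sum_i a_i e^{-t/\tau_i} + c$ with $\sigma^2 = \max(\text{counts}, 1)$,
standard TCSPC practice that stays well-behaved for empty bins. The
window starts two bins past the histogram peak (tail fitting discards the
rising edge, avoiding instrument-response deconvolution) and ends at the
last non-empty bin. Optimization is Levenberg–Marquardt with positivity
bounds on amplitudes and lifetimes; starting values come from a
log-linear regression of the offset-subtracted tail, with the offset
initialized to the mean of the last 5% of bins. Because the integral of
an exponential over a bin is proportional to the exponential at the bin
center, fitting bin centers introduces no lifetime bias. Non-convergence
is reported as a flagged result (`success = FALSE`), not an exception, so
batch runs continue.

Two numerical caveats are documented deliberately. First, Neyman
weighting is known to bias fitted lifetimes low when bins hold few
counts; at $10^5$–$10^6$ photons per decay (the regime of summed cell
ROIs) the ensemble bias is below 1% and 0.5% respectively (verified by
simulation in the test suite), but per-pixel fits need an ample budget —
the lifetime-map tests use thousands of photons per pixel and 64 bins,
where the map is uniform to within a few percent. Second, the reduced
$\chi^2$ of a fit to noiseless model data is 0, and values $\lesssim 1.5$
flag an acceptable fit; the published criterion ("well described by a
single exponential") is not quantitative, so model selection here returns
two components only when the biexponential fit improves reduced $\chi^2$
by more than 20% (relative, configurable).

Efficiency from lifetimes is $E = 100\,(1 - \tau_{DA}/\tau_D)$. Negative
efficiencies (quenched lifetime above the donor-only reference) are
reported as-is with a message, never clipped, so day-matched donor
variability remains visible. Acceptor-photobleach comparisons simply
apply the formula before and after bleaching; a full bleach should return
$E \approx 0$.

## Per-cell heterogeneity (red-versus-green slopes)

For each segmented cell, red pixel intensity is regressed on green by
ordinary least squares after per-channel background subtraction (median
outside all cell masks; 5th percentile when no masks exist; negatives
clipped to zero). Red is the response because the diagnostic phenotype —
cells with measurable donor but immature, dark acceptor — manifests as a
slope near zero, which only the red-on-green orientation expresses. OLS
rather than total least squares matches the published description
("linear regression") and keeps the estimator simple; Poisson noise in
the green predictor attenuates slopes by roughly the noise-to-signal
variance ratio (about 2–3% under the generator's default conditions),
which is immaterial for the cohort-contrast conclusions the slopes
support. A 50-pixel minimum per cell stabilizes the regressions (no
minimum was published; 50 is conservative for cells tens of pixels
across). Segmentation is an automated surrogate — thresholded connected
components with deterministic raster-order labels — because the original
regions were drawn by hand; external label masks are accepted everywhere.

Slope histograms use Freedman–Diaconis bin widths by default
(overridable), with left-closed bins so a slope exactly on an edge falls
in the bin to its right.

## Maturation model

Chromophore maturation is modeled as first-order kinetics parameterized
by the half-time, $f(t) = 1 - 2^{-t/t_{1/2}}$ — only half-times are
published, and first-order approach is the standard minimal model. A
tandem population with mature fraction $f$ yields an
*amplitude-weighted* donor decay mixture
$(1-f)\,e^{-t/\tau_D} + f\,e^{-t/\tau_{DA}}$: each tandem molecule
carries exactly one donor, so molecule fractions are amplitude fractions.
Dark acceptors are assumed fully non-absorbing (no partial quenching
states). The apparent efficiency of such a mixture is what the standard
analysis would report: a single-exponential tail fit of the mixture decay
converted through the lifetime-ratio formula. It is 0 at $f=0$, equals
the fully mature efficiency at $f=1$, and increases strictly and
continuously in between — but always understates the fully mature value,
since dark acceptors only dilute the signal.

Composed with the kinetics, this reproduces the qualitative multi-day
phenotype: apparent efficiency rising steeply over days 1–5 post
transfection. Note that the published *in-cell* rise (4% → 21% over five
days) is far slower than the purified-protein half-time of 136.5 min
would predict — with that value, maturation would be complete within a
day. This is the published data's own tension (maturation "is likely not
the only contributing factor"), and fretkit does not hide it: the
scenario half-time defaults to the table value, and the cohort generator
accepts an explicit effective half-time (the package's multi-day examples
use ~6200 min, which places day-1 apparent efficiency near 4%) so users
can model the effective in-cell timescale separately from the purified
kinetics. No additional dark-state mechanisms are modeled.

## Permutation tests

Group comparisons use a two-sample permutation test with the difference
of group means as the default statistic (difference of medians
available), two-sided throughout. Pooled samples of fewer than 10
observations are enumerated exactly over all
$\binom{n_a+n_b}{n_a}$ assignments; larger problems use Monte Carlo with
the add-one correction $p = (b+1)/(N+1)$, which avoids zero p-values and
keeps the test valid. For the mean statistic only the permuted group-a
sum is needed, so a million draws complete in seconds. The test is
location-invariant, exactly symmetric under group swap in enumeration
mode, and its type-I error at $\alpha = 0.05$ is calibrated to within
[0.04, 0.06] by simulation in the test suite.

## Synthetic data: what it emulates, and what it does not

The generators are parameterized by the published photophysical table, so
scenario names like mRuby3 or mScarlet-I configure realistic half-times,
quantum yields and extinction coefficients. Shot noise is Poisson in
decays and images; Gaussian read noise is optional; per-cell mature
fractions in cohorts follow a Beta distribution centred on the kinetic
mean (concentration 30 by default — visible but moderate cell-to-cell
spread, chosen once as a plausible level; the real distribution of
per-cell maturation states is unknown and the Beta form is a convenience,
not a claim). Cells are non-overlapping ellipses with a smooth radial
expression profile; images carry no optical point-spread function, no
spectral bleed-through (the characterization's filter choices were
designed to eliminate it), and no instrument response function in decays
(tail fitting makes the IRF largely irrelevant, which is why the
generators start decays at the pulse). Passing tests therefore establish
that the analysis inverts its own forward models and obeys the published
worked examples — they cannot establish robustness to IRF tails, pile-up,
detector afterpulsing, or segmentation errors on real morphologies.

Every generator returns a machine-readable truth table sufficient to
score recovery of each downstream estimate, and all are bit-reproducible
under a fixed seed.

## Problem sizes and runtime choices

The test suite validates lifetime recovery with 100 seeded decays at each
of $10^5$ and $10^6$ photons, permutation calibration with $10^4$ null
simulations of 12-versus-12 samples at 999 draws each, and cohort
contrasts with 36-cell image batches at 60×60 pixels — sizes chosen so
the full suite runs in under two minutes on one core while keeping Monte
Carlo standard errors well inside the asserted tolerances. Larger
simulations only tighten the same comparisons.

## Known limitations

- The overlap-integral pipeline reproduces published $J$ values only as
  well as the supplied spectra match the (unstated) spectra behind them;
  the bundled table values are used directly where exactness matters.
- Neyman-weighted tail fits are biased at low photon budgets; use
  model-based or maximum-likelihood weighting if per-pixel lifetimes at
  low counts are the goal (out of scope here).
- The maturation model intentionally omits protein turnover,
  photochromism and partial quenching; it is a single-mechanism
  explanation tool, not a complete kinetic model.
- Vendor microscope formats are not read; inputs are CSV, TIFF and JSON.
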