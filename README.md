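# fretkit

Tools for characterizing Förster resonance energy transfer (FRET) between
green donor and red acceptor fluorescent proteins — the workflow used to
evaluate mNeonGreen as a donor for mRuby3, mScarlet-I and mCherry. It is
aimed at microscopists and protein engineers who need to turn spectra,
TCSPC decay histograms and two-channel confocal images into FRET
efficiencies and expression-heterogeneity metrics, with a synthetic-data
module standing in for the microscope so every stage can be validated
against known ground truth.

## What it computes

**Förster theory.** The spectral overlap integral
J(λ) = ∫ f̄_D(λ) ε_A(λ) λ⁴ dλ (donor emission area-normalized, acceptor
absorption scaled to its extinction coefficient) and the Förster radius
R₀⁶ = 8.79×10⁻⁵ κ² n⁻⁴ QY_D J (Å⁶, J in M⁻¹cm⁻¹nm⁴), with defaults
κ² = 0.6667 and n = 1.33.

**Spectral FRET.** Non-negative linear unmixing of a mixed emission scan
into donor and acceptor reference components (optional baseline), then
E = 100 · W_A / (W_A + W_D · QY_A/QY_D).

**FLIM FRET.** Poisson-weighted exponential tail fitting of TCSPC decays
(mono- or bi-exponential, Levenberg–Marquardt), reduced-χ² model
selection, per-pixel lifetime maps, acceptor-photobleach comparisons, and
E = 100 · (1 − τ_DA/τ_D).

**Expression heterogeneity.** Per-cell ordinary least-squares slopes of
red versus green pixel intensity after background subtraction, and slope
histograms: tandem constructs should give every cell the same slope, so
the spread of slopes — and a mode near zero — diagnoses immature (dark)
acceptors.

**Maturation model.** First-order chromophore maturation
f(t) = 1 − 2^(−t/t½) feeding an amplitude-weighted two-lifetime donor
decay mixture, predicting how apparent FLIM efficiency rises with
expression time.

**Statistics.** Two-sample permutation tests: exact enumeration for
pooled samples under 10 points, Monte Carlo (default 10⁶ draws, add-one
corrected) otherwise.

**Synthetic data.** Seeded generators for reference spectra, mixed
emission scans, TCSPC histograms, FLIM stacks, two-channel cell images
and multi-day cohorts, each returning a ground-truth table.

## Worked example

```r
library(fretkit)

# Förster radius of the mNeonGreen/mRuby3 pair from its overlap integral
forster_radius(4.65e15, fluorophore("mNeonGreen")$quantum_yield)
#> [1] 64.14694     # Å; rounds to the published 64 Å

# Spectral FRET on a simulated scan with true E = 27%
donor_ref    <- gen_spectrum(517, 15, skew = 2)
acceptor_ref <- gen_spectrum(593, 20, skew = 2)
scan <- gen_emission_scan(0.27, donor_ref, acceptor_ref,
                          quantum_yield_donor = 0.8,
                          quantum_yield_acceptor = 0.54,
                          noise_sigma = 0.05, seed = 42)
res <- linear_unmix(scan, donor_ref, acceptor_ref)
res
#> <unmix_result> W_D = 583.6, W_A = 145.6, r^2 = 0.9999
spectral_fret_efficiency(res, 0.8, 0.54)
#> [1] 26.98488     # percent, recovering the generating 27%

# FLIM FRET on a simulated quenched-donor decay (tau_DA = 2.22 ns)
decay <- gen_tcspc_decay(lifetimes = 2.22, amplitudes = 1,
                         total_photons = 2e5, seed = 42)
fit <- tail_fit(decay)
fit
#> <lifetime_fit> 1 component(s): tau = 2.2090 ns, chi2_red = 0.972
flim_fret_efficiency(fit$lifetimes_ns[1], 3.05)
#> [1] 27.57358     # percent, against the 3.05 ns donor-only lifetime

# Are quenched and donor-only lifetimes distinguishable? (8 points: exact)
permutation_test(c(2.20, 2.25, 2.21, 2.24), c(3.02, 3.08, 3.05, 3.04))
#> <permutation_result> exact, p = 0.02857 (stat = -0.8225, 70 perms)
```

The unmixing weights are the donor and acceptor photon contributions to
the scan; r² near 1 says the two references explain the scan. The fitted
2.209 ns lifetime sits within shot-noise error of the simulated 2.22 ns,
and the resulting 27.6% efficiency matches the 27% that the generating
lifetimes imply. The exact permutation p-value (2/70) is the smallest
two-sided value attainable at these sample sizes.

Higher-level batch drivers — `run_spectral_pipeline()`,
`run_flim_pipeline()` (per-cell lifetimes, group summaries and pairwise
permutation tests) and `run_heterogeneity_pipeline()` (per-cell slopes
and histograms) — operate on lists of scans, FLIM stacks and images, and
optionally write CSV tables plus a JSON run log. See the methods
vignette (`vignettes/fretkit-methods.Rmd`) for the models, parameter
choices and limitations.

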