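---
title: "Models and methods behind lovtherm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lovtherm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lovtherm)
```

`lovtherm` implements the computational analysis layer of a thermostability
engineering campaign on a dimeric flavin-based fluorescent protein (FbFP, a
LOV-domain scaffold binding FMN): free-energy estimation from alchemical
molecular-dynamics output, thermodynamic-cycle assembly of mutational
stability changes, thermal-denaturation curve fitting, screening statistics,
and consensus sequence analysis. The expensive physical stages (MD sampling,
structure-based screening, fluorimetry, database searches) are out of its
scope; the package consumes their outputs — energy-difference samples, melt
curves, screening tables, alignments — and ships generators that emulate
those outputs with known ground truth so every estimator is testable at the
desk.

## Alchemical free energies

A point mutation X→Y is scored by the folding free-energy difference
ΔΔG = ΔG₄ − ΔG₃, where ΔG₄ and ΔG₃ are the free energies of alchemically
transforming X into Y in the folded protein and in an unfolded model
peptide. Because direct transformations between large side chains converge
poorly, each is split through a pseudo-alanine intermediate I (a CH1 Cβ
with zero charge): ΔG(X→Y) = ΔG(X→I) − ΔG(Y→I), separately for the
Coulomb-switching (charges off first) and van der Waals-switching
(soft-core annihilation) components. Charge removal uses a 21-window linear
λ schedule (λ = 0.05n); the van der Waals stage uses 41 windows
(λ = 0.025n).

### BAR estimator

For each adjacent window pair the package solves Bennett's acceptance-ratio
self-consistency condition: with forward samples ΔH (evaluated on the
lower-λ ensemble) and reverse samples ΔH (upper-λ ensemble), both stored as
H(λ_high) − H(λ_low), the estimate ΔG solves

$$\sum_i \frac{1}{1+e^{\,M+\beta(\Delta H^f_i-\Delta G)}} =
  \sum_j \frac{1}{1+e^{\,-M-\beta(\Delta H^r_j-\Delta G)}}$$

with `M = log(n_f/n_r)` (internally the reverse samples are negated into
work space). The left-minus-right difference is strictly increasing in ΔG,
so the root is found by bracketed root finding (`uniroot`, tolerance
1e-12 kcal/mol) with automatic bracket expansion — no damping or iteration
schedule to tune. Exact antisymmetry under reversal of the transformation
holds at the work level and is exposed through `reverse_pair()`.
Non-overlapping forward/reverse distributions (range gap above 10 kT) are
flagged with a warning rather than silently returned, since BAR is
uninformative without phase-space overlap.

One-sided exponential (Zwanzig) averages, `exp_average()`, are provided
only as diagnostics: both directions are reported in the low→high
convention, where they bracket the BAR estimate on well-overlapped data.

### Errors and correlation

Per-pair errors divide each direction's time series into five contiguous
blocks (so 200 ps of production data yields five 40 ps blocks), re-estimate
BAR per block pair, and report the standard deviation of the five block
values. Blocks are contiguous, not interleaved, because the error source is
serial correlation in time. Leg totals combine pair estimates by summation
and pair errors in quadrature; the quadrature choice (rather than linear
summation) treats window pairs as independent, which the block construction
supports when the correlation time is short compared with the block
length. When a mutation is applied simultaneously in both subunits of the
dimer, leg free energies carry `subunit_scale = 0.5` to report the
per-mutation value.

The `autocorr_time()` diagnostic uses the integrated autocorrelation time,
`τ = Δt (1 + 2 Σ ρ(k))`, truncating the sum at the first non-positive
empirical autocorrelation. The integrated form was chosen over an
exponential fit because it is estimator-simple and matches the AR(1)
generator's closed-form τ; the first-negative truncation keeps the noisy
tail of ρ out of the sum at the cost of a small negative bias, well inside
the 20% tolerance the recovery tests assert.

### Cycle assembly

`assemble_cycle()` takes the eight legs (2 components × 2 states × 2
transformations) and forms ΔΔG_ele and ΔΔG_vdw as folded-minus-unfolded
differences of the X→Y component transforms; ΔΔG_total = ΔΔG_ele + ΔΔG_vdw
holds exactly by construction (the decomposition is path-dependent, the sum
is not), and the total error is the quadrature over all eight leg errors —
the simplest propagation consistent with independent legs. Negative ΔΔG
means the Y variant is more stable. When X or Y is alanine its leg is still
supplied by the caller (alanine and the intermediate differ by the Cβ atom
type, so the leg free energy is small but not identically zero).

## Thermal denaturation of a dissociating dimer

FbFP unfolds as N₂ ⇌ 2U, so stability is concentration dependent. With
total monomer concentration $C_t$ and unfolded fraction $f$, mass action
gives $K = 2 C_t f^2/(1-f)$, and the melting temperature $T_m$ — where half
the monomers are unfolded — satisfies $K(T_m) = C_t$. The package's
free-energy expression is the Gibbs–Helmholtz form with constant ΔC_p,
anchored by that condition:

$$\Delta G(T) = \Delta H\left(1-\frac{T}{T_m}\right) +
\Delta C_p\left(T - T_m - T\ln\frac{T}{T_m}\right) - R T \ln C_t .$$

The anchoring is the binding contract of the model: the last term is fixed
by requiring `frac_unfolded(Tm) = 0.5` exactly at the stated concentration,
not chosen independently. Two concentrations appear in the API: `Ct_ref`,
the concentration at which `Tm` is defined (it enters ΔG), and `Ct`, the
concentration of the sample whose equilibrium is being evaluated. They
coincide by default and in every fitting situation (the data that define
`Tm` are the data being fitted); separating them lets one predict how the
half-transition moves when the same protein is measured at another
concentration — raising `Ct` above `Ct_ref` stabilizes the dimer and pushes
the half-point above `Tm`. The unfolded fraction is evaluated in the
overflow-safe closed form $f = 2/(1+\sqrt{1+8C_t/K})$.

The observable is a linear-baseline mixture,
$I(T) = (\alpha_F+\beta_F T)(1-f) + (\alpha_U+\beta_U T)f$, fitted after
scaling the curve so its maximum is 100. The full model has seven
parameters (ΔH, T_m, ΔC_p, α_F, α_U, β_F, β_U); the five-parameter variant
pins β_F = β_U = 0.

### Fitting, model selection, errors

`fit_melt()` uses weighted Levenberg–Marquardt least squares
(`minpack.lm`), with χ² = Σ((obs−model)/σ)², σ being the per-point
measurement error when available and 1 otherwise. Starting values are taken
from the curve itself — `Tm` at the steepest descent of a 3-point
moving-average smooth, baselines from the terminal plateaus, generic
ΔH = 50 kcal/mol and ΔC_p = 0.5 kcal/mol/K — with five jittered restarts by
default, keeping the lowest-χ² converged fit. Wide box bounds (e.g. `Tm`
within one grid span of the measured range) only prevent divergence into
unidentifiable regions.

Nested 5- vs 7-parameter fits are compared with
`F = ((χ²₅−χ²₇)/2)/(χ²₇/(N−7))` against the F(2, N−7) critical value at
α = 0.05. The χ² values enter as residual sums of squares: that is the
only reading under which the canonical worked example (χ² = 17.9 vs 14.7
with N = 19 giving F = 1.31 against F(2,12) = 3.88) is reproduced, even
though such fits are often quoted as "reduced χ²". A complex fit that lands
above the simple one — possible when the two nonlinear optimizations are
run independently — floors F at 0 with a warning; in simulation studies the
complex fit should be started from the simple solution, which guarantees
nesting.

Parameter errors come from `mc_errors()`: 100 synthetic data sets built by
adding Gaussian noise (at the measurement error) to the fitted model curve,
each refitted starting from the original solution (fast, and avoids
restart-jitter variance contaminating the error estimate); the reported
error is the across-refit standard deviation. Refit failures are counted
and more than 20% aborts. The derived ΔG error at a reference temperature
is also reported; it is characteristically much smaller than the ΔH and
ΔC_p errors, which compensate each other strongly. Experimental ΔΔG between
two variants is `fit_dG(ref, T_ref) − fit_dG(variant, T_ref)`; `T_ref`
defaults to the reference fit's `Tm` but is configurable, since any choice
in the overlap of the fitted ranges is defensible and the difference is
second order in (T_ref − Tm).

## Screening statistics

`sign_agreement()`, `regression_line()`, `mae()` and `stability_count()`
operate on the packaged screening tables (`load_screen_ddg()`,
`load_screen_tm()`), which carry the predicted ΔΔG components, the
experimental ΔΔG from melt-curve fits, and the measured melting
temperatures. Missing values (a mutant losing fluorescence) are explicit
`NA`s, excluded from numerators and regressions but kept in stability-count
denominators. Zero ΔΔG counts as positive in sign comparisons (no zero
occurs in the shipped table; the convention only pins the degenerate case).
Ordinary least squares is of predicted on experimental, and the
linear-corrected MAE measures scatter of the predictions about that fitted
line — i.e. what the error would be after removing the predictor's
systematic slope and offset. Note that statistics recomputed from a table
printed at 0.1 kcal/mol resolution can differ in the second decimal from
the same statistics computed on unrounded data; the package reports what
its inputs support.

## Consensus analysis

`pairwise_identity()` counts matches over aligned columns, dropping
columns gapped in both sequences from the denominator and counting
one-sided gaps as mismatches. `filter_by_identity()` mirrors the usual
homolog-collection protocol: sequences below 45% identity to the reference
are dropped, then near-duplicates are removed greedily in input order
(reference kept first, a candidate discarded when its identity to any kept
sequence reaches 90%). Greedy mutual-redundancy removal — rather than
filtering against the reference alone — was chosen because the purpose of
the 90% rule is de-duplication of near-identical database entries. Both
thresholds are inclusive, so `(max_id = 1, min_id = 0)` degenerates to
exact-duplicate removal. Per-site frequencies are raw occurrence counts
divided by the number of sequences, with the gap as its own symbol, so
column frequencies always sum to 1. `consensus_report()` maps mutation
labels such as `V120I` onto alignment columns through the ungapped
coordinates of a designated reference sequence (or treats sites as raw
columns when no reference is given) and flags whether the mutated-to
residue is the column consensus.

## Synthetic data: what it does and does not emulate

* **Alchemy windows.** Forward work per pair is Gaussian N(μ, σ²) and the
  reverse distribution is N(μ−βσ², σ²), the unique equal-variance Gaussian
  pair satisfying the Crooks fluctuation relation; the pair free energy is
  then μ − βσ²/2 in closed form, which is what makes BAR exactly testable.
  Serial correlation is injected by a stationary AR(1) process with
  coefficient φ = (τ−Δt)/(τ+Δt), whose integrated autocorrelation time is
  exactly the requested τ (default 3 ps at 1 ps sampling, a typical ΔH
  correlation time). Real ΔH distributions can be skewed and
  non-stationary, so passing recovery tests here demonstrates estimator
  correctness, not robustness to anharmonic sampling pathologies.
* **Melt curves.** The generator evaluates the exact dimer model on a
  19-point grid from 287 to 341 K (the working range of a fluorescence melt
  on a protein melting near 316 K) and adds homoscedastic Gaussian noise
  (default sd 1 on the 0–100 intensity scale, matching duplicate-based
  measurement errors), with defaults ΔH = 100 kcal/mol, ΔC_p = 1 kcal/mol/K
  and C_t = 4.2 µM monomer. Instrument drift, irreversible aggregation
  above the transition and wavelength effects are not modelled.
* **Alignments.** Column compositions are specified exactly and assigned
  to sequences by seeded permutation, so site frequencies are known by
  construction; inter-column covariation (phylogenetic structure) is
  deliberately absent, which is irrelevant for per-column frequency
  statistics but means the generator cannot test identity-filter behaviour
  on realistic phylogenies — those tests use hand-constructed sets.

All generators take an explicit integer seed and are byte-reproducible
under it.

## Problem sizes and numerical choices

The shipped test suite runs BAR recovery at 10⁵ samples per direction,
autocorrelation recovery at 10⁵ samples, 500 null replicates for the F-test
type-I calibration, 50-seed melt-fit recovery against 100-set Monte-Carlo
errors, and the full screening/consensus worked examples; the whole suite
completes in about a minute on one core. Degenerate inputs are handled
explicitly: zero-variance samples give exact free energies with zero block
error, constant series flag their autocorrelation time as degenerate,
identical nested fits give F = 0 (simple model preferred), and zero
injected Monte-Carlo noise returns zero errors.

## Known limitations

* BAR is applied per window pair; a multi-state estimator across all
  windows simultaneously (MBAR) would use the same samples more
  efficiently but is out of scope.
* The five-block error assumes the block length comfortably exceeds the
  correlation time; with τ ≈ 3 ps and 40 ps blocks that holds, but slow
  conformational modes outside the sampled window are invisible to it.
* The dimer model assumes full reversibility and a temperature-independent
  ΔC_p; ΔC_p from fluorescence melts is weakly identified, which is
  exactly why the derived ΔG — not ΔH or ΔC_p — is the quantity carried
  into the screening comparison.
* Identity filtering is order-dependent by design (greedy, documented);
  permuting the input can change which member of a near-duplicate cluster
  survives, never how many clusters do.
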