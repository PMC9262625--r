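---
title: "Methyl CPMG relaxation dispersion analysis with cpmgdisp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methyl CPMG relaxation dispersion analysis with cpmgdisp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpmgdisp)
```

## The model

`cpmgdisp` analyses single-quantum ¹³C methyl CPMG relaxation dispersion
under a two-site exchange model, A ⇌ B, with forward and reverse rates
k_AB = p_B·k_ex and k_BA = p_A·k_ex (so p_A·k_AB = p_B·k_BA holds by
construction).  The ground state A is heavily populated (p_B < 0.5, in
practice a few percent), and the excited state differs in methyl ¹³C
chemical shift by Δω (rad/s).  In the ground-state rotating frame the
transverse magnetisation of the two states evolves under

```
L = | −R₂₀ − k_AB        k_BA          |
    |  k_AB        −R₂₀ − k_BA − iΔω  |
```

During a constant-time CPMG element of total length T_relax, the train
of n 180° pulses (n even) alternates free evolution with complex
conjugation of the magnetisation.  The package propagates the pair of
echoes (τ–180–τ)(τ–180–τ) as the linear operator `Q = E·Ē·Ē·E` with
`E = expm(Lτ)`, raises it to the power n/2, and reports

R₂,eff(ν) = −(1/T_relax) · ln( |M_A(T_relax)| / M_A(0) ),

starting from the exchange-equilibrated condition M(0) ∝ (p_A, p_B),
the natural reference state of a constant-time experiment.

### Assumptions

- **One R₂,0 per field, shared by both states.**  CPMG data cannot
  separately determine the intrinsic rates of a state populated at a few
  percent; a shared baseline is the standard identifiability constraint.
- **Only |Δω| is determined.**  Single-quantum CPMG is insensitive to the
  sign of the shift difference, so `dw_ppm ≥ 0`.
- **Δω in ppm is field-independent.**  Both static fields are fitted
  jointly with one `dw_ppm` per methyl; the per-field rad/s values follow
  from the ¹³C Larmor frequencies (125.7 and 201.2 MHz at 11.7 and
  18.8 T).
- **Even echo counts.**  For each ν the implied pulse number
  n = 2νT_relax is rounded to the nearest even integer; frequencies
  implying n < 2 are rejected.  The schedule axis is taken to be
  ν_CPMG = 1/(2t) with t the inter-pulse delay.  Plot conventions differ
  between groups — some plot 1/τ_CP = 2ν_CPMG — and with the alternative
  reading all frequencies would simply halve; the generator and the
  fits use one consistent axis throughout, so the choice does not affect
  parameter recovery, only the labelling of the grid.

### The closed-form cross check

`carver_richards_r2eff()` evaluates the closed-form solution of the same
model.  The classic Carver–Richards expression keeps only the dominant
eigenvalue of the echo-pair propagator; that approximation is excellent
in fast and intermediate exchange but degrades when slow exchange meets
a large population-weighted shift difference (errors of several s⁻¹ at
k_ex ≈ 1600 s⁻¹, p_B = 0.15, Δω = 2 ppm at 18.8 T).  The default
(`exact = TRUE`) therefore adds the exact second-eigenmode and
initial-condition amplitude, which makes the closed form exact for equal
baseline rates; `exact = FALSE` exposes the classic expression.  The
test suite verifies the numerical propagator against a third,
independent implementation (scaling-and-squaring Taylor matrix
exponential with pulse-by-pulse conjugation) and asserts
closed-form/propagation agreement below 0.1 s⁻¹ across a grid covering
k_ex ∈ {200 … 4000} s⁻¹, p_B ∈ {0.01 … 0.15}, Δω ∈ {0.3 … 2} ppm at
both fields.

One property worth noting: R₂,eff(ν) is monotonically non-increasing in
the intermediate-to-fast regimes that dominate methyl work, but in deep
slow exchange (k_ex ≪ Δω) the exact solution develops genuine
oscillatory dips as a function of ν.  The monotonicity checks in the
test suite are therefore restricted to the realistic regimes.

## From intensities to profiles

Constant-time intensities convert to rates as
R₂,eff = −ln(I(ν)/I_ref)/T_relax.  Point errors are estimated from
duplicate measurements — in the emulated design the reference and the
ν = 200 and 6000 s⁻¹ points are acquired twice — by pooling squared
half-differences per field (a pair differing by 2δ implies a
per-measurement σ of δ√2).  Duplicates are too sparse to support
per-point errors, so one σ per field is applied uniformly, with a floor
of 0.1 s⁻¹.  The observed exchange contribution R_ex is read as the mean
of the two lowest-ν points minus the mean of the two highest; two-point
means damp single-point noise (the estimator used for the published
displacement is not stated, so this choice is the package's own).
Residues with R_ex > 5 s⁻¹ at the higher field — where Δω in rad/s, and
hence R_ex, is largest — pass the dispersion screen; a residue passes if
any of its methyls passes.

## Fitting and clustering

Each methyl is fitted by weighted Levenberg–Marquardt least squares
(`minpack.lm::nls.lm`) over {k_ex, p_B, dw_ppm, R₂,0 per field} against
both fields jointly.  Initialisation is multi-start on the grid
k_ex ∈ {200, 600, 1600, 4000} s⁻¹ × p_B ∈ {0.01, 0.05, 0.15} ×
dw_ppm ∈ {0.3, 1.0, 2.0}, with R₂,0 started from the mean of the three
highest-frequency points; the objective is evaluated at every grid
point and full optimisation is run from the eight most promising starts,
which in practice always includes the basin of the global optimum while
keeping the cost of ~50 methyl fits modest.  Bounds are physical ranges
for methyl ¹³C: k_ex ∈ [10, 2·10⁴] s⁻¹, p_B ∈ (10⁻⁴, 0.5),
dw_ppm ∈ (0, 6], R₂,0 ∈ (0, 200] s⁻¹.  A flat (exchange-free) model is
fitted alongside, and the exchange model is retained only when an F-test
on the χ² reduction is significant at α = 0.01 *and* the observed R_ex
clears the screening threshold — the second condition guards against
statistically significant but physically negligible dispersions.

Methyls retained with the exchange model are grouped by rate:
single-linkage on log₁₀(k_ex) with a gap cutoff of 0.25 (a factor ≈1.8),
chosen to separate the regimes seen in practice (e.g. ~1600 vs
~420 s⁻¹) while tolerating the scatter of individual-fit rates.  Groups
must span at least two residues: the two prochiral methyls of one Leu or
Val report on the same site, so a single-residue group is no evidence of
a collective process.  Each candidate is refitted globally — one shared
(k_ex, p_B), per-member dw and per-field baselines — and members whose
reduced χ² under the shared parameters is at least twice their
individual-fit value are ejected (worst first, refitting until stable).
The ratio's denominator is floored at 10⁻⁹ so that numerically perfect
individual fits on noiseless data do not defeat the rule.  Ejected or
initially unclustered methyls are then offered to each fitted cluster
with the shared parameters held fixed; a methyl satisfying the ratio
rule in more than one cluster goes to the one where its cluster χ² is
lowest, and clusters that gain members are refitted under the same
ejection rule.

Parameter uncertainties come from Monte Carlo resampling: 100 synthetic
replicates of best-fit curve plus Gaussian noise at the per-point σ,
each refitted from the converged parameters; the reported σ is the
standard deviation over converged replicates, and replicate failure
above 20% attaches a warning.  All resampling is seeded and
reproducible.

## The synthetic-data generator

The generator emulates the acquisition design of a two-field ILV-methyl
study: fields of 11.7 and 18.8 T, a 20-ms constant relaxation period,
18 refocusing frequencies (17 values spanning 100–3000 s⁻¹ plus
6000 s⁻¹, all multiples of 50 s⁻¹ so the even pulse count is exact), and
duplicate acquisitions at 200 and 6000 s⁻¹.  Gaussian noise with
σ = 0.3 s⁻¹ — consistent with tight error bars on well-resolved methyl
data — is added to noiseless Bloch–McConnell curves.

The built-in presets plant the published exchange regimes: the isolated
DNA-binding domain at 300 K carries 18 dispersing residues — a main
cluster of 14 residues at k_ex = 1640 s⁻¹, p_B = 0.042, a second cluster
(I139, V210, L212) at 420 s⁻¹, p_B = 0.146, and L106 dispersing at an
off-cluster rate (the published account left it fitting neither
cluster); the full-length homodimer moves I139 into the main cluster
(k_ex = 1600 s⁻¹, p_B = 0.051, 16 residues) and keeps V210/L212 separate
(660 s⁻¹, p_B = 0.14); at 290 K all dispersing residues follow one
global slower process (480 s⁻¹, p_B = 0.029).  The DNA-bound preset is
measured at 18.8 T only — mirroring a complex stable enough for a single
field — with all loop-proximal residues exchange-free and two surface
residues (I104, V233) retaining free-like dispersion.

Design choices worth making explicit:

- **Non-dispersing residues are generated with p_B = 0**, not with a
  small Δω, so the flat/exchange ground truth is unambiguous.
- **Per-methyl |Δω| is drawn uniformly from [0.4, 1.6] ppm** with a
  fixed structural seed per preset, and redrawn until the noiseless
  observed R_ex at 18.8 T exceeds 8 s⁻¹.  The rejection step makes
  "planted dispersing" well defined: without it, a draw near 0.4 ppm in
  the fast main cluster would sit right at the 5 s⁻¹ screening threshold
  and the planted count would not be a stable property of the preset.
  Baselines are drawn per methyl from 10–16 s⁻¹ (11.7 T) and
  12–20 s⁻¹ (18.8 T).
- **Structure and noise are seeded separately**: the planted truth is a
  property of the preset; the user seed only controls the noise
  realisation (and downstream Monte Carlo).

What the generator does *not* emulate: peak overlap and resolvability,
intensity-dependent noise, partial or erroneous assignments,
field-dependent noise levels, pulse imperfections and off-resonance
effects, or any deviation from ideal two-site behaviour.  Passing the
recovery tests therefore shows that the estimator chain is correct and
well calibrated under the stated noise model — not that real spectra of
a 74-kDa complex would yield parameters of this precision.

The peak-list scenarios place methyl cross peaks on a per-amino-acid
lattice whose spacing is far beyond the matching tolerances, then apply
per-scenario offsets: 10-bp duplex scenarios split several residues into
two bound components with unequal planted intensities, the symmetric
11-bp scenarios shift peaks without splitting, and the asymmetric 11-bp
mutant scenario splits peaks such that the two components coincide
exactly with the two single-conformer scenarios' positions, emulating
binding in two orientations.

## Peak-list analytics

Assignment transfer minimises the scaled elliptical distance
d = √((ΔδH/tol_H)² + (ΔδC/tol_C)²) with defaults tol_H = 0.05 and
tol_C = 0.3 ppm (typical methyl linewidths), greedy in order of
increasing d; target peaks are consumed once but a reference assignment
may acquire several targets — a split.  The combined shift perturbation
uses the conventional carbon weight w_C = 0.25.  A complex is called
`multiple_conformations` when at least two assignments split; requiring
two avoids calling a verdict on a single accidental match.  Split-peak
intensity fractions are reported as conformer populations with the
explicit caveat that intensity tracks population only under comparable
relaxation of the components.

## Problem sizes and numerical notes

The shipped tests and the acceptance script run the pipeline on the
presets as generated: 31 residues (54 methyls) per temperature preset,
two fields × 20 measurements per methyl, 100 Monte Carlo replicates per
cluster, and a 20-seed repetition of the screening count.  The
propagator is vectorised across the frequency axis (Sylvester form of
the 2×2 matrix exponential, binary exponentiation of the echo-pair
propagator), and the cluster-global Jacobian exploits the block
structure of per-member parameters, so a full preset analysis completes
in well under a minute.  Degenerate cases are handled explicitly:
dw = 0 or p_B = 0 short-circuit to exactly R₂,0; near-degenerate
eigenvalues of the echo-pair propagator fall back to a first-order
expansion.

## Known limitations

- Two-site exchange only; no three-site or linear multi-site models.
- Single-quantum ¹³C only; multiple-quantum and ¹H dispersions, and
  off-resonance R₁ρ, are out of scope.
- The two temperatures are treated as independent datasets; no van 't
  Hoff/Eyring linkage across them.
- K_d extraction from titrations is out of scope — for tight binders in
  slow exchange the peak positions carry no affinity information.
- Conformer "populations" from split-peak intensities inherit the equal
  relaxation assumption stated above.
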