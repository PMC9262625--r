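# cpmgdisp

Analysis of single-quantum methyl (¹³C) CPMG relaxation dispersion data
under two-site chemical exchange, written for ILV-methyl studies of large
proteins and their DNA complexes.

Proteins often exchange between a heavily populated ground state and
sparsely populated excited conformations on the µs–ms timescale.  In a
constant-time CPMG experiment the effective transverse relaxation rate
R₂,eff is measured as a function of the refocusing frequency
ν_CPMG = 1/(2t) (t the delay between consecutive 180° pulses): exchange
broadening is progressively quenched as ν_CPMG grows, and the resulting
dispersion profile encodes the exchange rate k_ex = k_AB + k_BA, the
excited-state population p_B, and the absolute chemical-shift difference
|Δω| between the states.  `cpmgdisp` covers the full workflow:

- **Forward model** — numerical propagation of the two-site
  Bloch–McConnell equations through the echo train
  (`bm_r2eff()`), with the evolution matrix
  `L = [[−R₂₀ − k_AB, k_BA], [k_AB, −R₂₀ − k_BA − iΔω]]` and
  `R₂,eff = −ln(|M_A(T)|/M_A(0))/T`; an independent closed-form solution
  (`carver_richards_r2eff()`, Carver–Richards family) and the
  fast-exchange limit `R_ex = p_A p_B Δω²/k_ex` serve as cross checks.
- **Data preparation** — R₂,eff from constant-time peak intensities
  (`r2eff_from_intensities()`), pooled point errors from duplicate
  measurements (`estimate_sigma_from_duplicates()`), and screening of
  residues with observed R_ex above 5 s⁻¹ (`screen_dispersing()`).
- **Fitting** — per-methyl weighted least squares jointly over both
  static fields (`fit_individual()`), F-test selection against a flat
  model (`model_select()`), grouping by k_ex (`cluster_by_kex()`), and
  cluster-global fits sharing one (k_ex, p_B) across members subject to
  the acceptance rule χ²_cluster/χ²_individual < 2
  (`fit_cluster_global()`), with Monte Carlo parameter uncertainties
  (`monte_carlo_sigmas()`).
- **Synthetic data** — `preset()` / `make_dispersion_dataset()` generate
  two-field ILV dispersion datasets with known ground truth, and
  `make_peaklists()` generates free/bound methyl HMQC peak lists with
  planted shifted and split cross peaks.
- **Peak-list analytics** — assignment transfer by elliptical proximity
  (`transfer_assignments()`), combined ¹H/¹³C shift perturbations
  (`combined_csp()`), split-peak detection, conformer populations and the
  single- vs multiple-conformation verdict (`classify_complex()`).

## Worked example

Simulate the isolated DNA-binding-domain preset (two fields, 18 CPMG
frequencies, T_relax = 20 ms, σ = 0.3 s⁻¹ noise) and run the full
pipeline:

```r
library(cpmgdisp)
cfg <- run_config(preset = "dbd_300K", seed = 1, n_reps = 100)
res <- run_dispersion_pipeline(cfg)
print(res)
#> <pipeline_result> 18 residues screened, 2 clusters, 2 unclustered exchange methyls
#>   cluster 1 (24 methyls): k_ex = 1645 +/- 11 s-1, p_B = 0.042 +/- 0.000
#>   cluster 2 (5 methyls): k_ex = 414 +/- 7 s-1, p_B = 0.148 +/- 0.002
```

18 residues pass the R_ex > 5 s⁻¹ screen.  The global fits recover the
planted exchange regimes — a fast main cluster (true k_ex = 1640 s⁻¹,
p_B = 4.2%) spanning 24 methyls and a slower, more populated cluster
(true k_ex = 420 s⁻¹, p_B = 14.6%) — while the two prochiral methyls of
L106, planted with an off-cluster rate, are correctly reported
unclustered.  Per-methyl results live in `res$fits`:

```r
head(res$fits[, c("key", "model", "k_ex", "p_B", "dw_ppm", "cluster")])
#>       key    model      k_ex        p_B    dw_ppm cluster
#> 1 I104.d1 exchange 1501.1365 0.03847256 0.8944781       1
#> 2 I118.d1 exchange 1434.5212 0.02361485 0.9025009       1
#> 3 I139.d1 exchange  445.9686 0.16727951 0.4208831       2
#> 4 I185.d1 exchange 1660.7226 0.04255775 1.5652583       1
#> 5 I237.d1 exchange 1628.8235 0.04124804 1.4319912       1
#> 6  L106.a exchange 5128.1976 0.12950444 1.3402489      NA
```

Peak-list comparison of a DNA complex against the free protein:

```r
run_peaks_pipeline(scenario = "kB_proto")$classification
#> [1] "multiple_conformations"
run_peaks_pipeline(scenario = "MHC_H2")$classification
#> [1] "single_conformation"
```

A thin command-line wrapper is installed under
`inst/scripts/cpmgdisp-cli` (subcommands `simulate`, `fit`, `peaks`).

## Documentation

The methods vignette (`vignettes/methyl-cpmg-analysis.Rmd`) describes
the model and its assumptions, the fitting and clustering procedure, the
design of the synthetic-data generator, numerical choices and known
limitations.
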