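# timesig

Forward simulation and inverse analysis of **transient induced
molecular electronic spectroscopy (TIMES)** signals — a label-free,
immobilisation-free microfluidic readout of protein–ligand binding.

## The problem

When a protein (or protein–ligand complex) diffuses to an electrode at
the wall of a microfluidic channel, the interfacial field orients its
dipole and induces a transient charge on the electrode. The recorded
current `i(t)` encodes, without any labelling:

* the single-molecule induced-charge kernel `q(t)` (the "Green's
  function" of one arrival, in Coulomb),
* the surface dwell time `τ_s` (the relaxation time of the Langmuir
  adsorption transient, `τ_s = N_s / (K₊ γ n_o + K₋)`), and
* the equilibrium dissociation constant `K_D = n_P n_L / n_C` of the
  binding reaction, from signals of mixtures at known loadings.

The forward chain is: 1-D diffusion across the channel half-height
(`∂n/∂t = D ∂²n/∂x²`, Dirichlet at the channel centre, reactive flux
at the electrode), a Boltzmann surface partition
`γ = exp(−Ze ζ / k_B T)`, Langmuir adsorption/desorption
`N_s dθ/dt = K₊ γ n(0,t)(1−θ) − K₋ θ`, and the convolution
`i = d/dt [A (q ∗ J)]`. In the dilute regime the mixture signal is the
superposition `i(t) = n_P G_P(t) + n_L G_L(t) + n_C G_C(t)`, and four
measured conditions (protein-only, ligand-only, 2:1 and 1:2 mixtures)
determine `K_D` at every timepoint; the estimate is the mode of the
histogram of per-timepoint values. The package implements the full
chain, a seeded synthetic instrument, and the three inversions
(`deconvolve_kernel()`, `fit_tau()`, `fit_kd()`). See the methods
vignette (`vignettes/times-methods.Rmd`) for the model, the estimator
design and the numerical choices.

This is a research-code reimplementation for simulation studies: no
instrument data ship with it, and the synthetic generator is the only
data source.

## Worked example

Simulate the trypsin/p-ABA-like reference experiment (100 µM protein
with 0/50/100/200 µM ligand, ground-truth K_D = 34.7 µM, 1 kHz × 1 s,
SNR 20 dB) and invert it:

```r
library(timesig)
scen <- reference_scenarios()$trypsin_paba
expt <- generate_experiment_set(scen, seed = 7)
fit  <- fit_kd(expt)
summary(fit)
#> TIMES dissociation-constant fit
#>   K_D (histogram mode): 35.51 uM
#>   per-timepoint K_D quartiles: 27.86 uM / 35.2 uM / 43.88 uM
#>   timepoints: 1000 analyzed, 999 retained, 1 discarded
#>   ...
```

The modal K_D of 35.51 µM recovers the generating 34.7 µM within ~2 %;
the 1000 per-timepoint values come from solving the four-condition
mixture equations at each of the 1000 samples of the 1 s record, and
the one discarded timepoint is a noise spike with no bracketed root.

Dwell times across a flow sweep (desorption shear-activated through a
Bell model; wall shear from plane Poiseuille flow, 30 µL/min ↔ 6.67 Pa
in the default 30 µm × 0.5 mm channel):

```r
sw   <- shear_sweep(reference_scenarios()$shear_sweep, seed = 7)
taus <- vapply(sw, function(s) fit_tau(s$trace)$tau_s, numeric(1))
#>   flow_ul_min tau_w_pa  tau_s
#> 1          30   6.6667 0.5345
#> 2          60  13.3333 0.4212
#> 3         120  26.6667 0.2870
#> 4         240  53.3333 0.1622
#> 5         350  77.7778 0.0822
#> 6         450 100.0000 0.0340
```

The fitted dwell time decreases monotonically with shear stress, the
signature of shear-activated desorption.

A thin command-line layer wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/times.R", package = "timesig"))')
Rscript "$CLI" simulate --scenario trypsin_paba --seed 7 --out run1/
Rscript "$CLI" infer    --manifest run1/manifest.yaml --out run1/result.json
Rscript "$CLI" fit-tau  --trace run1/condition_1.csv
```

Traces are two-column CSV (`time_s,current_A`) with JSON metadata
sidecars; experiments are described by a YAML manifest; results are
JSON documents with the histogram, dwell-time table, discard
diagnostics and provenance.

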