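# parbcage

Nucleation-and-caging analysis of ParB partition-complex ChIP-seq
profiles.

## The problem

Bacterial ParABS systems segregate plasmids and chromosomes. ParB binds
the centromere-like *parS* site specifically, then accumulates over more
than 10 kbp of flanking DNA — far more than footprinting or 1D
nearest-neighbour spreading can explain. High-resolution ChIP-seq shows
the flanking enrichment decays as a power law, not exponentially. The
nucleation-and-caging model accounts for this quantitatively: *parS*-bound
ParB nucleates a spatially confined cluster of radius σ in which the ParB
concentration is Gaussian, `C(r) = κ·exp(−r²/2σ²)`, and a flanking locus
at genomic distance *s* (in Kuhn monomers of length *a*) is bound whenever
polymer looping carries it into the cluster. Integrating looping
statistics against the cluster concentration gives the occupancy law

    P_NC(s) = κ · (1 + a²s/3σ²)^(−3/2)

with `P_NC(0) = κ` (the drop height between the specific plateau and the
non-specific flank) and an asymptotic −3/2 power law. A one-sided integral
of `P_NC` over the enriched length `L` ties κ to the total number of
cluster-bound ParB, `N_t`.

The package is aimed at anyone modeling protein-spreading profiles around
nucleation sites: it provides the closed-form model and its κ↔N_t
normalization, a freely-jointed-chain Monte Carlo benchmark with
triangular fragment-size smoothing, coverage-track processing (bedGraph
I/O, input normalization, background subtraction, anchor normalization,
dip detection, amplitude rescaling), nonlinear fitting of the decay to
recover (κ, a, N_t), schematic competing-model baselines (1D spreading,
spreading-and-bridging), and a synthetic ChIP-seq generator with known
ground truth.

## Worked example

Simulate ParB occupancy on a 15-kbp freely jointed chain with the
F-plasmid parameter set, then fit the decay to recover the parameters:

```r
library(parbcage)

params <- params_f_plasmid()
params
#> Nucleation-and-caging model parameters
#>   sigma   = 75 nm (cluster radius)
#>   a       = 10 bp = 3.4 nm (Kuhn length)
#>   kappa   = 0.41 (cluster-centre binding probability)
#>   N_t     = 356.4 ParB (total cluster-bound, one-sided over 15 kbp)

cfg <- simulation_config(n_monomers = 1500, n_conformations = 20000, seed = 75)
mc  <- simulate_profile(list(pars_site(0, 20, center_bp = 0)), params, cfg)
fit <- fit_nc(mc, sigma_nm = 75, window_bp = c(10, 10000))
fit
#> Nucleation-and-caging fit
#>   A0 (= kappa) = 0.4104
#>   A1           = 0.0002033 nm^-1
#>   Kuhn length  = 3.43 nm (10.1 bp)
#>   N_t          = 352.3 ParB
#>   window       = 10-10000 bp, SSE = 0.000201 (1000 points)
```

The fit recovers the generating parameters: κ ≈ 0.41 (the cluster-centre
binding probability, equal to the model amplitude A0), a Kuhn length of
≈ 10 bp from `a = 3σ²A1`, and ≈ 350–360 cluster-bound ParB from the
closed-form normalization — and the log-log slope of the simulated decay
is −1.51, the model's −3/2 signature.

## Analysis workflow

The `analysis/` scripts run the full study at desk scale and write their
tables under `results/`:

1. `01_simulate_fjc.R` — Monte Carlo vs. analytic benchmark.
2. `02_generate_synthetic.R` — synthetic IP/input datasets (bedGraph/BED/
   JSON), with and without fragment smoothing.
3. `03_fit_decay.R` — track → normalized decay profile → dip masking →
   parameter fit.
4. `04_model_comparison.R` — amount-variation scenarios, baseline
   discrimination, replicate dip conservation.
5. `05_multi_pars.R` — three-site (V. cholerae-like) simulation and
   union-model fit.

The methods vignette (`vignettes/nucleation-caging.Rmd`) documents the
model, conventions (anchors, background, kernels) and design choices.

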