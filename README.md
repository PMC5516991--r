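# phasemix

Latent-class change-point models for longitudinal biomarker trajectories.

Clinical biomarker series — tumor burden, M-protein, viral load — rarely
follow one straight line for every patient. Some patients decline steadily
(*mono-phasic*); others decline fast and then slowly, switching slope at an
unknown time (*bi-phasic*). Treating such a cohort as homogeneous and linear
biases both the population estimates and any patient-level conclusions.
phasemix is for biostatisticians analyzing longitudinal trial data who want
to (a) classify each subject as mono- or bi-phasic, (b) estimate population
and per-subject regression parameters, and (c) quantify posterior
uncertainty — without assuming any functional form beyond piecewise
linearity.

## The model

For subject *i* with observations *y<sub>ij</sub>* at days *t<sub>ij</sub>*,
a latent indicator η<sub>i</sub> ∈ {0, 1} selects between

* η<sub>i</sub> = 0: &nbsp; y<sub>ij</sub> = s<sub>0i</sub> + s<sub>1i</sub> t<sub>ij</sub> + ε<sub>ij</sub>
* η<sub>i</sub> = 1: &nbsp; y<sub>ij</sub> = b<sub>0i</sub> + b<sub>1i</sub> t<sub>ij</sub> + ε<sub>ij</sub> for j ≤ k<sub>i</sub>, and
  y<sub>ij</sub> = b′<sub>0i</sub> + b′<sub>1i</sub> t<sub>ij</sub> + ε<sub>ij</sub> after the latent change point k<sub>i</sub>,

with ε<sub>ij</sub> ~ N(0, σ²), hierarchical normals s<sub>i</sub> ~ N(S, Σ<sub>S</sub>),
b<sub>i</sub> ~ N(B, Σ<sub>B</sub>), η<sub>i</sub> ~ Bernoulli(λ), and per-subject
Dirichlet-weighted candidate change points π<sub>ij</sub>, j = 1..M<sub>i</sub>−1.

Fitting proceeds in two stages:

1. **EM** (`fit_em`): closed-form empirical-Bayes individual estimators,
   per-subject BIC penalization of the phasicity posterior (the bi-phasic
   model pays its extra two parameters), and a cohort-level *phasic
   transition density* that pools change-point information across subjects
   whose visit days are jittered.
2. **Gibbs** (`run_chain`): an eleven-step conditional sweep from the EM
   mode (multinomial design draws, Bernoulli phasicity, Dirichlet π, Beta
   λ, normal means, inverse-Wishart covariances, scaled inverse-χ² for σ²),
   plus simultaneous rectangular credible regions
   (`simultaneous_credible_region`).

A synthetic-cohort simulator (`make_scenario`, `simulate_cohort`) generates
the three standard test scenarios (no / independent / correlated
between-patient variability), and an evaluation harness
(`run_recovery_experiment`, `run_coverage_experiment`) replicates the
parameter-recovery, classification and coverage experiments.

See the methods vignette (`vignettes/phasemix-methods.Rmd`) for the full
model account, numerical choices and known limitations.

## Worked example

```r
library(phasemix)

sim <- simulate_cohort(make_scenario(2, seed = 21))  # N = 100, 18 visits
fit <- fit_em(sim$cohort)
fit
#> <em_result> converged after 251 iterations (objective -6132.9597)
#> <population_parameters>
#>   S  = (89.68, -0.2571)   sigma = 4.845   lambda = 0.4534
#>   B  = (92.25, -0.3515, 55.49, -0.1425)
#>   45/100 patients classified bi-phasic at the 0.5 cutoff

confusion_metrics(sim$truth$eta, classify(fit))
#> <classification_report>
#>          truth
#> predicted mono bi
#>      mono   43 12
#>      bi      0 45
#>   sensitivity (mono|mono) 100.00%, specificity (bi|bi) 78.95%
```

The fitted mixing weight (0.45) sits below the generating 0.60: under
between-patient variability the transition time is a heavy-tailed Gaussian
ratio, so some bi-phasic patients transition late (or have slopes close to
the mono-phasic one) and their observed series are practically straight
lines — the BIC-penalized classifier deliberately calls those mono. Every
true mono-phasic patient is recovered (sensitivity 100%); 45 of the 57
bi-phasic patients are detected.

Posterior simulation from the EM mode:

```r
chain <- run_chain(sim$cohort, gibbs_options(n_iter = 5000, burn_in = 1000,
                                             seed = 21, init = fit))
simultaneous_credible_region(chain, 0.95, params = 1:8)
```

## Command line

A thin CLI wraps the same functions (`inst/cli/phasemix`):

```sh
phasemix simulate --scenario 2 --seed 7 --out-dir sim/
phasemix fit-em   --input sim/cohort.csv --seed 1 --out-dir fit/
phasemix fit-gibbs --input sim/cohort.csv --iterations 5000 --out-dir gibbs/
phasemix evaluate --experiment table3 --scenario 2 --scale reduced --out-dir eval/
```

Every run writes a JSON manifest (options, seed, package version,
convergence summary) beside its outputs.

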