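# metahet

Tools for asking when genome-wide genetic diversity predicts extinction
in the wild. The motivating system is a classical butterfly
metapopulation: thousands of discrete host-plant meadows, ~20% occupied
in any year, local populations of 1–94 overwintering larval nests
(median 3) that rarely persist more than a couple of years, frequent
local extinction balanced by recolonization, and larvae genotyped at a
245-SNP panel. In such a system heterozygosity, demography, and
dispersal are confounded — populations that are small are also inbred,
and declining patches can be rescued by immigration between censuses —
so naive heterozygosity–extinction regressions mislead. `metahet`
provides the whole analysis chain, with a synthetic-data generator in
place of field data so that every stage is testable end to end.

## What it computes

* **Synthetic metapopulation data** (`generator_config()`,
  `generate_patches()`, `simulate_dynamics()`, `write_dataset()`):
  stochastic patch-occupancy dynamics with an inbreeding-load
  overwinter survival process S = S₀·e^(−B·F), full-sib nest genotypes
  with Mendelian segregation and heterozygote deficit 2pq(1−F), per-call
  missingness, merged nests, and a rescue (recolonization) process
  between the spring and fall censuses.
* **Heterozygosity** (`heterozygosity()`, with `filter_individuals()`
  and `filter_units()`): observed heterozygosity and Nei–Chesser
  small-sample-corrected expected heterozygosity
  Hₑ = n/(n−1)·(1 − Σpₐ² − Hₒ/2n), per nest or per patch-year
  population, under the ≥95% call-rate and ≥2-genotypes-per-unit
  inclusion rules.
* **Demographic covariates** (`connectivity()`, `ntrend()`,
  `classify_trend()`, `build_analysis_table()`): incidence-function
  connectivity Sᵢ = Σⱼ e^(−α·dᵢⱼ)·Nⱼ,ₜ₋₁ (α = 1 km⁻¹), its
  year-over-year trend, strict 1- and 2-generation population-trend
  categories, log transforms, and per-model z-standardization for three
  responses: annual extinction, overwinter extinction, nest mortality.
* **Model structures** (`build_model_spec()`, `fit_model()`,
  `fit_logistic()`): the six fixed-effect binomial logit designs used to
  probe context dependence (heterozygosity alone; plus covariates; plus
  interactions with population size and connectivity; with year; with
  population trend), on a self-contained IRLS engine with Wald
  inference and explicit separation flagging.
* **Inbreeding load** (`fh()`, `survival_under_load()`, `estimate_b()`):
  Fₕ = (H₀ − H)/H₀ relative to the most heterozygous nest, and haploid
  lethal equivalents B = −log(S_Fmax / S_F0)/Fmax from fitted or
  empirical extreme survival.
* **Power analysis** (`power_scenario()`, `power_nest_mortality()`,
  `power_extinction()`, `power_report()`): 5,000-replicate Monte-Carlo
  power to detect heterozygosity effects on nest mortality (B = 1, 2.5,
  5) and on extinction under the logistic model L = 1.58 − 6.14·H, per
  year and pooled.

## A worked example

```r
library(metahet)

cfg <- generator_config(seed = 1)          # the calibrated study conditions
patches <- generate_patches(cfg)
sim <- simulate_dynamics(patches, cfg)

gt <- filter_individuals(sim$genotypes)    # >= 95% call rate
pop_het <- heterozygosity(filter_units(gt, "population"), "population")

tab <- build_analysis_table(patches, sim$survey, pop_het,
                            response = "overwinter_ext", model_id = 2)
fit_model(tab, 2)
```

```
Binomial logit fit (IRLS): n = 636 deviance = 502.293
                      estimate        se            z            p
(Intercept)        -1.83348468 0.1413818 -12.96831893 1.850442e-38
z_he               -0.71719102 0.1332380  -5.38278259 7.334311e-08
z_log_nest_count   -0.81286323 0.1610691  -5.04667359 4.495684e-07
z_ntrend            0.06920583 0.1228724   0.56323345 5.732759e-01
...
```

On this synthetic decade (636 occupied patch-years), overwinter
extinction risk falls by e^0.72 ≈ 2.0× per standard deviation of
population heterozygosity and by e^0.81 ≈ 2.3× per SD of log population
size — the expected signature of an inbreeding load acting alongside
demographic extinction of small populations. The load itself:

```r
f <- runif(5000, 0, 0.5)
y <- rbinom(5000, 1, survival_under_load(f, b = 2.5, s0 = 0.7))
estimate_b(y, f)
#> Inbreeding load (fitted_logistic): B = 2.531 haploid lethal equivalents
#>   S(Fh=0) = 0.645, S(Fh=0.500) = 0.182, n = 5000 nests
```

See `vignettes/metapopulation-heterozygosity.Rmd` for the model details,
the generator's design choices, and its known limitations.

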