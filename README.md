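# grazediv

Statistical pipeline for asking how the **cessation of livestock grazing**
changes the diversity of soil food webs — nematodes, springtails, mites,
protists, fungi, bacteria, plants — in paired grazed/exclosure plot studies
across many sites. It is written for community ecologists and soil
biologists analysing multi-site paired designs with wide community tables
(plots × taxa) per organism group, and it ships a synthetic study
generator so every estimator can be validated by parameter recovery
without field data.

## What it computes

**Response ratios.** Per site, α-diversity is plot-level taxon richness;
the effect of grazing removal is

    Δα = (α_ungrazed − α_grazed) / α_ungrazed

β-diversity per site × treatment is the mean of all C(n,2) pairwise
Bray–Curtis dissimilarities on presence–absence data among that
treatment's plots (on 0/1 data Bray–Curtis equals Sørensen,
(b + c)/(2a + b + c)), and

    Δdissimilarity = (d_ungrazed − d_grazed) / d_ungrazed

Negative values mean richness loss / biotic homogenization. Per-site
ratios are pooled as their mean across sites (± cross-site s.d.), with
treatment significance from a Gaussian linear mixed model
`response ~ treatment + (1 | site)`.

**Rarity cohorts.** Taxa are classified by occupancy across all plots:
rare (< 25 %), common (25–75 %), widespread (> 75 %); Δα is recomputed
within each cohort.

**Drivers.** For each group, all-subsets Gaussian mixed models (random
site intercept, ML) over treatment, soil/vegetation covariates and their
treatment interactions are ranked by
AICc = −2ℓ + 2k + 2k(k+1)/(n−k−1); Akaike weights
w_i = exp(−Δ_i/2) / Σ_r exp(−Δ_r/2); models with Δ_i < 4 are combined by
conditional model averaging with cumulative per-term weights, and
marginal/conditional pseudo-R² (variance partition) summarises fit. The
mixed-model engine profiles the variance ratio λ = σ²_site/σ² and is
cross-checked against lme4 and closed-form ANOVA estimators in the test
suite.

**Synthetic worlds.** `synthetic_config()` describes a study (default:
12 sites × 4 grazed + 4 ungrazed plots, seven organism groups with
realistic taxon-pool sizes); `generate_dataset()` draws right-skewed
occupancies, applies a calibrated rarity-biased richness loss under
cessation, and moves β-diversity with a marginal-preserving
convergence/patchiness knob, recording the ground truth.

## Worked example

```r
library(grazediv)

cfg <- synthetic_config(
  n_sites = 12, plots_per_treatment = 4,
  group_specs = list(
    nematodes = group_spec("nematodes", 30, richness_loss = 0.2126,
                           rarity_bias = 0.5, beta_effect = 1)),
  seed = 42)
ds <- generate_dataset(cfg)
rr <- response_ratio_table(ds$communities, ds$metadata)
print(rr$pooled[, c("group", "response", "estimate", "sd",
                    "significance")], digits = 2, row.names = FALSE)
```

```
     group            response estimate   sd significance
 nematodes         delta_alpha    -0.30 0.28          ***
 nematodes delta_dissimilarity     0.32 0.15          ***
```

The configured world removes 21 % of expected per-plot richness under
cessation (a true Δα of −0.2126/0.7874 ≈ −0.27) and makes taxa patchy
across ungrazed plots; the pipeline estimates a 30 % ± 28 % richness
loss (cross-site s.d.) and a 32 % divergence in composition, both with
mixed-model support — the emulated "soil fauna diverge while losing
species" signature.

The numbered drivers in `analysis/` run the full narrative:
`01_simulate.R` (generate and persist the default world), `02_diversity.R`
(response-ratio and cohort tables), `03_drivers.R` (AICc-averaged driver
tables for α and β), `04_recovery.R` (parameter-recovery report). Each
writes its tables under `results/`.

## Acceptance script

`scripts/acceptance.R` regenerates the default seven-group synthetic
world from the given seed and runs the complete pipeline — validation,
α/β response ratios with significance, rarity cohorts and the AICc
driver models — then writes the acceptance JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
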