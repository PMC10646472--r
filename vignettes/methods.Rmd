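---
title: "Methods: diversity responses to cessation of grazing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity responses to cessation of grazing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grazediv)
```

# The scientific setting

Extensively grazed semi-natural grasslands are being taken out of
production across Europe, and there is concern that fencing grazers out
("exclosures") erodes biodiversity below ground. The design this package
analyses is a multi-site paired comparison: at each of several
independent sites, a set of grazed plots sits next to a set of plots from
which livestock have been excluded for years to decades. For each of
several organism groups — from tens of nematode taxa to thousands of
microbial phylotypes — the data are a wide community table (plots ×
taxa, non-negative abundances or read counts) plus plot metadata (site,
treatment, soil and vegetation covariates).

Two components of diversity can move independently: local richness
(α) and compositional variation among plots (β). A treatment can reduce
both (homogenization with species loss), reduce one while raising the
other (divergent but poorer communities), and so on. The pipeline
quantifies both axes per organism group and then asks which
environmental properties the changes track.

# Diversity statistics

**α-diversity** is plot-level taxon richness: the count of taxa with
abundance strictly greater than `presence_threshold` (default 0, so any
positive abundance counts — read-count data have no natural unit, and
Shannon/Simpson-type indices are deliberately avoided because primer
choice distorts relative phylotype abundances). Per site,

$$\Delta\alpha = \frac{\bar\alpha_{\mathrm{ungrazed}} -
\bar\alpha_{\mathrm{grazed}}}{\bar\alpha_{\mathrm{ungrazed}}}$$

with plot richness averaged within site × treatment first. Negative
values mean cessation of grazing lost species.

**β-diversity** per site × treatment is the unweighted mean of all
$\binom{n}{2}$ pairwise Bray–Curtis dissimilarities among that
treatment's plots, computed on presence–absence (where Bray–Curtis
equals Sørensen, $(b+c)/(2a+b+c)$). The response ratio
$\Delta\mathrm{dissimilarity}$ has the same form as $\Delta\alpha$;
negative values are biotic homogenization. An abundance-weighted variant
exists behind `method = "abundance"` but is not the default, for the
same primer-bias reason.

**Pooling.** The per-site ratios are the analysis unit. The pooled
estimate per group is their mean across sites and the reported error bar
is the cross-site s.d. Significance of the treatment effect is taken by
default from the Gaussian mixed model `response ~ treatment + (1|site)`
fitted to the plot-level response (richness) or to the site × treatment
mean dissimilarity — this matches the stated estimation procedure of the
study design the package emulates. A one-sample t-test on the per-site
ratios (`method = "ratio_t"`) is available as the simpler alternative;
the two agree on direction and usually on the significance class.

Degenerate denominators are excluded, not clamped: a site whose ungrazed
mean richness (or dissimilarity) is zero would give an infinite ratio,
so it is flagged and dropped from pooling with a logged count; the
all-zero/all-zero case is defined as 0. A pair of two all-absent plots
has dissimilarity defined as 0 with a warning.

**Rarity cohorts.** Occupancy is the fraction of all plots (both
treatments) in which a taxon is present. Taxa strictly below 25 % are
"rare", strictly above 75 % "widespread", everything else — including
exact boundary values — "common" (the wording "less than 25 %", "25 to
75 %", "more than 75 %" makes the boundaries common-inclusive). Cohort
Δα repeats the α analysis counting only the cohort's taxa. β is
deliberately not computed per cohort: dissimilarity restricted to an
occupancy stratum is hard to interpret. An empty cohort (e.g. no
widespread springtails) is reported as absent, never as zero.

# The mixed-model engine

All inference runs through one Gaussian linear mixed model with a single
random site intercept:
$y = X\beta + u_{\mathrm{site}} + \varepsilon$,
$u \sim N(0, \sigma^2_s)$, $\varepsilon \sim N(0, \sigma^2)$. The
implementation profiles $\beta$ and $\sigma^2$ out of the (restricted)
likelihood and maximises the one-dimensional profile over the variance
ratio $\lambda = \sigma^2_s/\sigma^2$ with a bracketed scalar search on
$\log\lambda$ over $[10^{-10}, 10^8]$ (tolerance $10^{-9}$ on the log
scale, i.e. relative $10^{-9}$ on $\lambda$), always comparing the
interior optimum against the admissible boundary $\lambda = 0$, where
the fit reduces exactly to OLS. The fit is deterministic — no random
initialisation — and the test suite verifies exact agreement with lme4
(coefficients, variance components, log-likelihoods) and with the
closed-form ANOVA estimators $\hat\sigma^2_s = (MSB - MSW)/m$,
$\hat\sigma^2 = MSW$ on balanced one-way designs.

Wald t-tests on coefficients use containment degrees of freedom
$n - p - G$ (observations minus fixed coefficients minus sites). This is
an approximation — not Satterthwaite or Kenward–Roger — and the
simulation tests therefore check the significance *classes* and the
realised type-I error (nominal 5 % test rejects in 3–7 % of null
replicates at the default design), not exact p-values.

Pseudo-R² follows the variance-partition definition for Gaussian
identity-link models: with $\sigma^2_f$ the variance of the fixed-effect
linear predictor over the data,
$R^2_m = \sigma^2_f / (\sigma^2_f + \sigma^2_s + \sigma^2)$ and
$R^2_c = (\sigma^2_f + \sigma^2_s) / (\sigma^2_f + \sigma^2_s +
\sigma^2)$; their difference is the variance share of site.

# Model selection and averaging

The driver analysis standardises the response and all continuous
covariates once on the analysis subset (so every candidate model shares
one scale), enumerates all subsets of {treatment, covariates,
treatment × covariate interactions} under marginality (an interaction
enters only with both parents), fits each by **ML** — AICc comparison
across models differing in fixed effects is invalid under REML — and
ranks by $AICc = -2\ell + 2k + 2k(k+1)/(n-k-1)$ with $k$ counting fixed
coefficients plus both variance parameters. Akaike weights use the
max-subtraction trick; Δ = 0 ties break stably by the canonical term
string.

Models with $\Delta_i < 4$ are averaged. The default is **conditional
("natural") averaging**: each term is averaged only over retained models
containing it, with unconditional standard error
$\sqrt{\sum_i w_i\,(se_i^2 + (\hat\beta_i - \bar\beta)^2)}$, alongside
its cumulative Akaike weight and occurrence count — the combination the
emulated study tabulates. Zero-substitution ("full") averaging is one
switch away. The choice matters: conditional estimates are larger in
magnitude for weakly supported terms; reporting them next to the
cumulative weight keeps that visible. Enumeration is guarded by a hard
cap (default 20,000 candidate models) with an instruction to lower
`max_terms`, because eleven covariates with interactions would generate
$3^{11} \cdot 2$ candidates.

Samples hit by configured exclusion rules — by default plots with an
organic layer deeper than 100 cm, where no carbon stock can be
estimated — are removed from the driver models only; the diversity
statistics retain them.

# The synthetic world

`generate_dataset()` draws a complete study so estimators can be judged
against known truth. Its defaults are the emulated design: 12 sites ×
(4 grazed + 4 ungrazed) plots (the clean factorial; the real study's 98
plots arise from one three-pair and one six-pair site, which the
generator does not reproduce — the analysed-plot count is exposed as
configuration instead) and seven groups whose taxon pools match the
published counts (30 nematode taxa up to 10,336 bacterial phylotypes).

Per group:

* **Occupancy** per taxon is Beta(0.5, 1.5) — right-skewed, many rare
  taxa — floored at $10^{-4}$. The shape is a configuration knob; any
  right-skewed law serves.
* **Site turnover** (default 0.3): that fraction of the pool is
  site-specific rather than shared, generating between-site composition
  differences and site-level richness variation (the random intercept
  the models assume).
* **Richness loss** under cessation: each taxon's retention probability
  is multiplied by $c\, e^{-\mathrm{rarity\_bias}\,(1 - p_j)}$ with $c$
  solved per site so expected per-plot richness shrinks by exactly
  `richness_loss`; with `rarity_bias = 0` this reduces to $c = 1 - L$
  exactly. Loss fractions are back-solved from the published per-group
  response ratios via $L = -d/(1-d)$.
* **β reallocation**: negative `beta_effect` mixes each ungrazed plot's
  draw with a site-shared core vector (convergence); positive values
  make selected taxa *patchy* — concentrated in one randomly assigned
  home plot and depleted elsewhere with probabilities that exactly
  preserve each taxon's marginal occupancy (rare taxa become
  plot-private). Both directions leave expected richness and the rarity
  structure untouched, so the α and β knobs are separable.
* **Abundance** given presence is lognormal(0, 1); since β uses
  presence–absence, the abundance law only matters for positive presence
  thresholds.

Covariates are site mean (uniform in a field-realistic range) +
treatment shift (ungrazed only; litter biomass carries the study's +28 %
multiplier) + Gaussian plot noise, with declared floors for
positive-only quantities (truncations are counted and logged). A
separate Gaussian layer, `simulate_response()`, draws an
already-standardised response $y = X\gamma + u + \varepsilon$ from the
design for validating the model-selection machinery with known
coefficients.

Seeding: one master seed; each (stage, group) derives a child seed by a
documented hash, so adding a group or a covariate never perturbs the
draws of the others, and identical configurations are bit-identical.

**Two emergent properties worth knowing.** First, the pooled ratio
estimator has a small negative Jensen bias of order
$-\mathrm{CV}^2(\bar\alpha_u)$ (about −0.01 at four plots per mean),
because the site-level denominator is itself a noisy mean; the null
calibration therefore centres within ±0.02 of zero rather than exactly
on it. Second, rarity-concentrated richness loss *by itself*
homogenizes: the rare, plot-patchy taxa it removes are what made plots
differ, so realized Δdissimilarity is the net of that convergence and
the `beta_effect` mechanism. The default knob values were calibrated
once against the published per-group β changes (fauna +5 to +15 %,
fungal/protist communities about −5 %) and are not revisited; at the
patchiness mechanism's ceiling (`beta_effect = 1`, the maximum negative
cross-plot correlation achievable with fixed marginals) realized
divergence saturates around +15 %.

**What the generator does not emulate** — and hence what a green
recovery test does not establish: spatial structure within plots,
sequencing noise and primer bias, qPCR quantification error, unequal
plot counts per site, covariate-driven β effects, and taxon abundance
dynamics. Recovery results validate the estimators under the model's own
assumptions, not the field protocol.

# Numerical and design choices

* Presence is *strictly greater than* the threshold; threshold 0 admits
  any positive abundance.
* Community tables are wide TSV (CSV accepted), samples in rows; floats
  are written with round-trip precision so write∘read is the identity.
* Missing covariate cells are explicit `NA`; driver models drop
  incomplete cases with a logged count.
* Occupancy denominators use all plots with data for the group.
* The pooled response ratio is the mean of per-site ratios (the
  intercept of an intercept-only across-site model, which with one ratio
  per site is the mean); significance comes from the plot-level mixed
  model by default because the ratio-scale and richness-scale models
  answer the same directional question and the latter is the stated
  procedure of the emulated study.
* ML for all ranked candidate fits; REML for standalone coefficient
  reporting.

# Limitations

Single random intercept only (no crossed or nested structures); Gaussian
responses only; containment df is an approximation that can be liberal
for very small site counts; conditional averaging inflates coefficients
of rarely selected terms relative to full averaging (both are available,
and the cumulative weight should always be read alongside the
estimate); the β driver analysis aggregates covariates to site ×
treatment means, which discards within-site covariate variation.
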