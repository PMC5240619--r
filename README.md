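# divcarbon

Multi-scale analysis of tropical-forest tree diversity and aboveground
live-carbon stocks, from stem-level inventory tables to stand-scale and
within-plot inference and mechanism tests — for forest ecologists and
macroecologists working with 1 ha inventory plot networks.

Whether carbon-dense tropical forests are also diverse ones is a
scale-dependent question. Among 1 ha stands, carbon per unit area and tree
diversity can vary independently once climate, soil and spatial
autocorrelation are accounted for, while within stands — among 0.04 ha
subplots, where environmental differences largely vanish — a weak positive
diversity effect on carbon can emerge. `divcarbon` implements the full
analysis chain needed to ask that question of any stem table, plus a
ground-truthed synthetic inventory generator so that every estimator can be
validated by parameter recovery.

## What it computes

**Carbon pipeline.** Per-stem aboveground biomass from the moist-forest
allometry AGB = 0.0673 (ρD²H)^0.976 (ρ wood density in g cm⁻³, D diameter
in cm, H height in m from regional Weibull models H = a(1 − e^(−bD^c))),
carbon as 47.1% of biomass, aggregated per plot or 0.04 ha subplot together
with basal area, basal-area-weighted wood density, stem density and the
Gini index of stem basal areas. Wood density resolves species → genus →
family → plot mean.

**Alpha diversity.** Corrected taxon richness
S = S_obs + round(U·S_obs/N_identified), individual-based rarefaction
E[Sₙ] = Σᵢ (1 − C(N−Nᵢ, n)/C(N, n)), Fisher's α from S = α ln(1 + N/α),
Shannon and Gini–Simpson indices, genus/family richness.

**Beta diversity.** Pairwise Sørensen similarity 2a/(2a+b+c) and
great-circle distances; distance decay ln(similarity) = α + β·distance via
a log-link binomial GLM with plot-bootstrap 95% envelopes; gamma-diversity
null models (uniform, closed-form hypergeometric; or frequency-weighted,
Monte-Carlo).

**Stand scale.** Kendall τ correlations; minimum detectable effect sizes
(Fisher-z power analysis with Kendall conversion τ = (2/π) asin r);
all-subsets regression of ln(carbon) on diversity + CWD, MAT, MAP, TEB,
C:N, texture with AICc weights, 95% confidence sets and full-model
averaging; simultaneous autoregressive (SAR) error models
y = Xβ + u, u = λWu + ε fitted by profiled maximum likelihood; bootstrap
continent summaries with Tukey letters.

**Within plot.** Per-plot OLS of ln(carbon) on ln(richness) + poly(ln
stems, 2); cross-plot summary (bootstrap CI, Wilcoxon signed-rank, sign
counts, % carbon change per richness doubling = (2^β − 1)·100); a
random-coefficients mixed model.

**Mechanisms.** Basal-area-weighted community trait means, functional
dispersion, exact null curves for P(community of S species contains a
species with max diameter ≥ 70 cm or wood density ≥ 0.8 g cm⁻³), and
binomial GLMMs for observed occurrence — the selection-effect and
complementarity diagnostics.

## Worked example

```r
library(divcarbon)

cfg <- sim_config(n_plots_per_continent = c(SouthAmerica = 20, Africa = 20,
                                            Asia = 20), seed = 2026)
rep <- run_all(cfg, n_boot = 1000)
print(rep)
#> Pipeline run: 32174 stems, 60 plots; stages: carbon, diversity, beta, stand, within, mechanisms (14.8 s)
#> Within-plot diversity-carbon slopes, 60 plots
#>   mean beta = 0.1073 +/- 0.0655 SE, 95% CI [-0.0183, 0.2379]
#>   Wilcoxon P = 0.1126; 34 positive (56.7%), 26 negative
#>   doubling richness changes carbon by 7.7%
```

The generator injected a true within-subplot coupling of 0.096 ln carbon
per ln species; the within-plot pipeline estimates 0.107 ± 0.066, i.e. a
7.7% carbon gain per doubling of subplot richness, with 57% of plots
showing a positive slope. At 60 plots the bootstrap CI still includes 0 —
detecting a coupling this weak needs a few hundred plots, which is exactly
what the power analysis says:

```r
print(detectable_effect(158))
#> Detectable effect at n = 158 (alpha = 0.05, power = 0.80):
#>   r = 0.221, tau = 0.142

print(rep$stand$Africa$modelset)
#> AICc all-subsets model set: 128 models, n = 20
#>   confidence set (95%): 47 models
#>              coef     se sum_weight
#> diversity  0.0045 0.0165      0.166
#> cwd        0.1567 0.0802      0.863
#> mat        0.0012 0.0100      0.147
#> map_      -0.0108 0.0249      0.204
#> teb        0.0424 0.0620      0.405
#> cn        -0.0050 0.0153      0.164
#> texture   -0.0065 0.0183      0.178
```

At stand scale the model-averaged diversity coefficient is ~0 while water
deficit carries the summed AICc weight — the generator couples plot-level
carbon to CWD, not to diversity, and the averaging recovers that.

See `vignettes/divcarbon-methods.Rmd` for the model, the generator design
and all numerical choices.

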