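---
title: "Meta-analysis of grazing-exclusion experiments with grazemeta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meta-analysis of grazing-exclusion experiments with grazemeta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grazemeta)
```

## The problem

Fencing livestock out of a grassland and comparing the exclosure with the
adjacent grazed land is the standard experiment for measuring what grazing
does to plant communities. Any one exclosure study is small and noisy;
synthesis across studies is done by meta-analysis of *paired comparisons*
(one exclosure-vs-grazed contrast at one site and time), typically for
three response variables: plant species richness, Shannon diversity, and
aboveground biomass. grazemeta implements that synthesis pipeline for small
ecological literatures — the regime of a dozen studies and a few dozen
comparisons, incomplete reporting of dispersions, and one or two long-term
experiments that can dominate every duration trend.

## The model

For a comparison with exclusion-arm mean $\bar X_t$ and grazed-arm mean
$\bar X_c$, the effect size is the log response ratio

$$\mathrm{LRR} = \ln(\bar X_t / \bar X_c),$$

with delta-method sampling variance

$$v = \frac{s_t^2}{n_t \bar X_t^2} + \frac{s_c^2}{n_c \bar X_c^2}.$$

Comparisons are pooled by inverse-variance weighting, $w = 1/v$:

$$RR_{++} = \frac{\sum w\,\mathrm{LRR}}{\sum w}, \qquad
  S(RR_{++}) = \sqrt{1/\textstyle\sum w},$$

with the 95% CI $RR_{++} \pm 1.96\, S(RR_{++})$ and a two-sided normal
p-value. An effect is called significant only when $p < .05$ *and* the CI
excludes zero. Heterogeneity is summarized by Cochran's
$Q = \sum w (\mathrm{LRR} - RR_{++})^2$ on $k-1$ df and
$I^2 = \max\{0, (Q - df)/Q\} \times 100$. A random-effects variant
estimates the between-comparison variance $\tau^2$ by DerSimonian–Laird
moments and re-pools with $w^* = 1/(v + \tau^2)$; both fits are always
available side by side, because in this literature the printed weighting
formulas are fixed-effect while the software conventionally reports both.
Significant pooled effects back-transform to a percent change,
$(e^{RR_{++}} - 1) \times 100\%$.

Moderators are handled two ways. Categorical moderators (climatic zone,
grazing intensity) use subgroup pooling with a between-groups test from the
fixed-weight partition $Q_{total} = Q_{between} + \sum_g Q_{within,g}$;
$Q_{between}$ is $\chi^2_{m-1}$ under the null. Continuous moderators
(years of exclusion) use weighted least squares of LRR on $[1, x]$ with
coefficient covariance $(X'WX)^{-1}$; `method = "mixed_mom"` adds a
method-of-moments residual $\tau^2$. The relationship between two response
variables (richness change vs biomass change) is the same regression after
an inner join on `comparison_id`.

## Data handling choices

**Dispersion imputation.** Field studies under-report variability, so SDs
are completed by a fixed ladder, per arm: reported SD; else
$SD = SE\sqrt{n}$ using that arm's own $n$; else $SD = \text{mean}/10$.
Each arm carries a provenance flag (`reported_sd`, `from_se`,
`tenth_of_mean`) so sensitivity analyses can drop the coarsest rung. The
ladder is idempotent and never touches means, sample sizes or moderators.
The final rung also guarantees $v > 0$, which is why zero-variance records
are treated as data errors in `effect_sizes()`.

**Category harmonization.** Author-reported labels collapse to closed
vocabularies: *extensive* grazing reads as `low` intensity, *overgrazing*
as `high`; Pampa / Jarillal / mountain grassland / "pastizal en filo"
collapse to `tall_grassland`, meadow and peatland to `bofedal` (the Andean
wet meadow). Where the evolutionary grazing history is unreported it is
derived from biogeography: tropical Andean sites dominated by camelids
(millennia of llama/alpaca grazing) are `long`; subtropical sites grazed by
introduced European livestock are `short` (under 500 years). Anything
unmappable is an error, not a silent pass-through — with 27 comparisons a
single miscoded row matters.

**Duration zero** ("initial state" measurements) is retained as a
legitimate covariate value, not dropped.

## The synthetic generator

`generate_comparisons()` draws tables with known ground truth so every
downstream stage can be tested without any field data. Its defaults mirror
the study conditions the package targets: 13 studies contributing ~27
comparisons; true mean log ratios of $-0.14$ (richness), $-0.24$
(Shannon), $+0.41$ (biomass); between-comparison variance
$\tau^2 = 0.08$, which at the default weights produces $I^2$ in the
80–96% band; durations 0–15 years from a discrete mixture concentrated at
0–5 years with a small tail mass at the maximum (the influential-point
geometry of real long-term exclosures); 4–10 replicate plots per arm with
arm CVs of 0.05–0.25; and SD missingness of 24/49 with 7/24 of those also
lacking an SE, the under-reporting rate typical of this literature.

Design choices worth stating: grazed-arm means are log-normal around a
per-variable baseline (20 species, Shannon 2.2, 250 g/m²) so positivity is
guaranteed; sampling noise is added on the arithmetic-mean scale with
$SD = CV \cdot \text{mean}/\sqrt n$, the way study-level means arise from
plot replicates; reported SDs are $CV \times$ the observed mean, so the
computed $v$ matches the noise actually injected and CI coverage is
testable; each record draws from its own deterministically derived PRNG
substream, so enlarging a table never perturbs earlier records. Because
both arms share the CV range, the small delta-method biases of
$\ln \bar X$ cancel between arms and the pooled estimators are unbiased
for $\mu$ to the order the tests can see — the recovery tests therefore
compare against $\mu$ itself.

What the generator does *not* emulate: species identities or community
composition, spatial or temporal autocorrelation between comparisons from
the same study, correlated reporting of the three response variables, and
publication bias. Passing tests show the estimators are correct under the
stated sampling model, not that any field inference is robust to those
omissions.

`example_comparisons()` is different in kind: a deterministic, engineered
table (13 studies, 27 comparisons, 49 records) whose effect values are
chosen so the full pipeline exhibits the canonical behaviour of such a
synthesis — diversity down, biomass up, strong heterogeneity, and a single
15-year comparison (`c15`) whose removal flips the significance of the
richness and biomass duration slopes and of the richness-on-biomass
regression. It is synthetic and labelled as such; it reproduces geometry,
not any published numbers.

## Numerical and interface decisions

- 95% intervals use the literal 1.96 rather than `qnorm(0.975)`, matching
  the field's reporting convention; the difference is below $10^{-3}$.
- $I^2$ truncates at 0 and is reported from the fixed-effect $Q$ in both
  models; DerSimonian–Laird $\tau^2$ truncates at 0, and when $Q \le df$
  the random-effects fit collapses to the fixed fit exactly.
- The between-groups subgroup test always uses the fixed-weight partition
  (the identity $Q_b + \sum Q_w = Q_t$ is exact there, and is tested to
  1e-8); level estimates can still be pooled random-effects. Singleton
  levels are pooled but flagged.
- Weighted regression solves the normal equations directly
  ($2 \times 2$); rank deficiency (a constant covariate) is an error,
  never a silent zero slope. Two points are allowed (interpolation,
  $QE = 0$); the cross-response regression additionally refuses joins
  below `min_pairs = 5`, because a slope from four pairs is anecdote.
- The influence threshold defaults to an estimate shift of one base-fit SE
  or a significance flip; the literature states no numeric criterion, so
  the threshold is exposed as `se_multiple`. Ties on "max duration"
  exclude all tied comparisons, with a log line.
- No small-sample correction to the LRR by default (the plain ratio is
  the standard in this literature); `bias_correct = TRUE` applies the
  delta-method correction. No multiplicity adjustment is applied across
  the three response variables.

## Problem sizes in the test suite

The oracle-equivalence tests run ~120 randomized instances of $k \le 10$
against brute-force summation at 1e-10 relative tolerance, and against
metafor as an independent implementation. Parameter recovery uses 500
replicate syntheses of $k = 27$ with $\mu = 0.4$, $\tau^2 = 0.05$ (mean
fixed- and random-effects estimates within 3 Monte-Carlo SEs of 0.4, mean
DL $\tau^2$ within 3 SEs of 0.05) and 1000 replicates at $\tau^2 = 0$ for
95% CI coverage within 93–97%. These sizes keep the full suite around a
minute while leaving the Monte-Carlo SEs well below the tolerances they
gate.

## A worked run

```{r}
tab <- example_comparisons()
eff <- effect_sizes(harmonize_categories(impute_dispersion(tab)))
rich <- eff[eff$response_variable == "species_richness", ]
pool_fixed(rich)
```

```{r}
exclude_and_refit(rich, rule = "max-duration",
                  analysis = "metareg", covariate = "duration_years")
```

`run_pipeline()` wires all stages together and writes `effects.csv`,
`pooled.json`, `subgroups.json`, `metareg.json`, `forest.csv`,
`bubble.csv`, `sensitivity.json` and a re-run manifest.

## Known limitations

Comparisons from the same study are treated as independent (no multilevel
or robust-variance structure), as is conventional in this literature but
optimistic when one study contributes five comparisons. The normal
approximation behind CIs and subgroup tests is rough for levels with
$n = 2$; those levels are reported, flagged, and should be read
descriptively. The dispersion ladder's mean/10 rung fabricates precision
for the affected rows — the provenance flags exist precisely so such rows
can be down-weighted or dropped in sensitivity runs.
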