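---
title: "Cross-ome interaction screening: models, diagnostics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-ome interaction screening: models, diagnostics, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omescreen)
```

## The screening problem

Multi-omic cohort studies routinely pair 16S rRNA microbiome profiles with
host immune measurements — ELISA cytokine panels, CyTOF immune-cell subset
frequencies — across disease and control groups. The analytical question
is rarely "is this one microbe associated with this one cytokine" but
"which of the hundreds-to-thousands of cross-ome pairs show a relationship,
and does that relationship differ by disease state?". omescreen answers it
by brute force: one small, identical regression model per pair, a nested
model comparison to rank pairs, multiplicity correction, and enough
per-pair geometry and diagnostics that a microbiologist or immunologist
can vet each candidate by eye rather than trust a bare p-value.

## The model and its assumptions

For a pair (microbe `Mb`, immune readout `IR`) with cohort factor `C`
(reference level absorbed into the intercept; treatment coding), the full
model is

$$\mathrm{Mb}_i = \beta_0 + \beta_c \mathbb{1}[C_i = c] + \beta_x \mathrm{IR}_i
  + \beta_{cx} \mathbb{1}[C_i = c]\,\mathrm{IR}_i + \varepsilon_i$$

with one offset $\beta_c$ and one interaction $\beta_{cx}$ per
non-reference cohort, and the reduced model drops every term involving
`IR`. The partial F statistic compares them; with $K$ cohorts the full
model has $2K$ parameters, the reduced $K$, so the numerator has $K$
degrees of freedom and the denominator $n - 2K$. The microbe is always the
response and the readout the predictor; the fitted per-cohort line for
cohort $c$ is $(\beta_0 + \beta_c,\; \beta_x + \beta_{cx})$, which is also
what the microplots draw.

Assumptions worth stating plainly: homoscedastic Gaussian errors on the
(possibly transformed) abundance scale, independence across samples, one
shared model form for every pair, and no compositional constraint across
microbes — each pair is fitted in isolation. Relative abundances are
bounded in $[0,1]$ and often zero-inflated, so the Gaussian error model is
an approximation; the screen treats it as a ranking device, with the
detailed plots and influence diagnostics as the corrective.

### Interaction p-values

Per non-reference cohort, the two-sided t-test of $\beta_{cx} = 0$ with the
full model's residual degrees of freedom: "does this cohort's slope differ
from the reference cohort's?". Sidedness is a package choice (two-sided);
slope *differences*, not slopes, are what these test.

### Influence: DFFITS

$\mathrm{DFFITS}_i = (\hat y_i - \hat y_{i,(i)}) / (s_{(i)} \sqrt{h_{ii}})$
— the standardized change in the $i$-th fitted value when observation $i$
is deleted. The implementation uses the leverage/studentized-residual
closed form $t_i \sqrt{h_{ii}/(1-h_{ii})}$; the test suite verifies it
against literal leave-one-out refits to 1e−10 relative tolerance.
Observations with exactly zero residual are assigned DFFITS 0 by
convention. When $n - 2K \le 1$ the deletion fit is undefined and
diagnostics are skipped with a classed warning. `max_influence` (the
largest $|\mathrm{DFFITS}_i|$) is carried into the top table and encoded
as point radius in the report's detail plots, so single-sample-driven
relationships are visible at a glance.

## Degenerate pairs and numerical edge cases

A screen over thousands of automatically generated pairs must not die on
the inevitable pathological ones. The rules, in order:

- constant response, singular full design (readout constant within every —
  or any — cohort), or a cohort with fewer than 2 samples, or
  $n < 2K + 1$: the pair is excluded and logged with its reason; it
  contributes no p-value and does not count toward the BH `m`;
- reduced model already exact (`RSS_reduced` ≈ 0 relative to the total sum
  of squares, at 1e−12): the models coincide, so `F = 0`, `p = 1`, and all
  residuals being zero forces DFFITS to 0;
- full model exact but reduced not (`RSS_full ≤ 1e−12 · RSS_reduced`):
  flagged degenerate-perfect and excluded from the screen — an exactly
  interpolating fit carries no usable error estimate.

Missing values are deleted pairwise (per pair, not per table), preserving
the maximal $n$ for every pair; each pair's `n` is recorded and exported.

## Multiplicity and the top table

Benjamini–Hochberg step-up over all non-degenerate fits (`m` = computed
tests, not attempted pairs: only tests that produced a p-value are
corrected). Thresholding is *strict* (`p < t`), supporting both raw-p and
FDR-p modes because realistic screens use both conventions (raw p < 0.05
for small screens, FDR < 0.05 or < 0.1 for larger ones). Rows sort by p
ascending with lexicographic (microbe, immune) tie-breaks — ties are rare
but determinism is a contract: identical input and configuration produce a
byte-identical exported document. Keys `1..R` are assigned after sorting
and join the top table to its sample-level data records.

## Export formats

The JSON screen document (config + top table + per-key sample arrays) is
written by a canonical serializer: fixed key order, integers as integers,
doubles in round-trip-exact `%.17g`, so serialize → parse → serialize is
byte-identical — a property the suite asserts, and the reason the writer
is bespoke rather than a generic pretty-printer. Parsing is jsonlite's. A
JSON-Schema file documenting the format ships under `inst/schema/`, and
`validate_document()` enforces the same contracts structurally (required
config fields, key↔record bijection, equal array lengths). Sample-level
`x`/`y` are the *post-transform* values, so exported plots match the
fitted models. The HTML report is one static file of inline SVG — no
scripts, no links, no external fonts — rendered by deterministic text
generation; the network layout is igraph's Fruchterman–Reingold under a
caller-set seed, with iteration count fixed at 500.

## Tunable parameters

| parameter | default | units / range | why |
|---|---|---|---|
| `reference_cohort` | — | cohort label | the baseline whose slope the interactions are measured against; use the control group |
| `threshold_type`, `threshold_value` | `fdr_p`, 0.05 | (0, 1] | strict inclusion cutoff for the top table |
| `min_nonzero` | 0 (off) | samples | prevalence filter: keep a microbe only if > 0 in at least this many samples (inclusive); immune features are never filtered |
| `immune_transform` | `none` | — | `sqrt` compresses heavy-tailed cytokine readouts and damps extreme readings |
| `metric_columns` | all | — | which optional metrics the top table carries |
| `seed` | 1 | int | network-layout determinism |

## What the synthetic generator emulates — and does not

`synthetic_spec()` defaults mirror a 4-cohort human study: cohorts
HC/CD/SpA/UC with 10/9/9/9 samples (37 total), 70 microbes, 6 immune
readouts. Null microbes are zero-inflated Beta draws (zero with
probability 0.3, else Beta(2, 18), mean abundance ≈ 0.1 — a typical
moderately prevalent gut genus). Immune readouts are i.i.d. lognormal,
unit scale by default (meanlog 0, sdlog 0.5): regression is equivariant to
the readout scale, so nothing statistical depends on whether values are
printed in pg/ml hundreds or near 1, and unit scale keeps planted slopes
interpretable against the unit abundance interval. Planted pairs are
per-cohort linear responses plus Gaussian noise, clipped into $[0,1]$ with
the clipped fraction reported in the truth record; a spec that would clip
more than half the values of any planted feature is rejected as
unrealistic for the unit interval. Clipping (not a logistic link) keeps
the generating model aligned with the fitted linear model so that
parameter recovery is exactly defined — at the price that recovery tests
must keep clipping negligible (the suite pins the planted readout spread
to sdlog 0.25 and asserts the realized clip fraction stays under 2%).

What it does **not** emulate: compositionality (no renormalization across
microbes — the fitted models don't use it either, and independent features
keep planted effects interpretable), readout magnitudes in physical units,
correlated immune panels, repeated measures, or covariates such as age and
sex. Passing tests on this generator therefore demonstrate the screen's
statistical mechanics — calibration, power, bookkeeping, determinism — not
robustness to compositional artefacts or confounding in real data.

## Calibration facts the suite measures

Under a Gaussian cohort-mean global null the partial-F p-values are
exactly uniform; the suite checks the rejection fraction at 0.05 over
2000 simulated pairs. On zero-inflated null abundances with the 2-cohort,
35-sample shape, the realized level stays within the binomial band around
0.05; with 4 small cohorts (9–10 samples each, an 8-parameter model) the
test runs mildly hot (rejection ≈ 0.06 at nominal 0.05 in exploratory
runs) — a known small-sample/non-normality limitation worth remembering
when reading 4-cohort top tables near the threshold. With four planted
large-effect pairs among 32 (n = 20 per cohort, slopes ±0.2–0.4, noise sd
0.02) the FDR-0.05 screen recovers essentially all planted pairs with mean
realized false-discovery proportion well under 0.10 over 100 replicates.
Problem sizes used throughout the suite (2000 null pairs, 100 replicates,
500 recovery fits, the 43×17 / 70×6 / 54×103 bookkeeping shapes) were
chosen to estimate these operating characteristics tightly at desk scale.

## Known limitations

- One fixed linear model form for all pairs; no per-pair model selection,
  no negative-binomial or zero-inflated likelihoods for the abundance
  response.
- Two omes only; no covariate adjustment in v1.
- BH assumes the usual positive-dependence conditions; cross-pair
  correlation (shared microbes/readouts across pairs) is not modelled.
- The exported document schema is this package's own documented format;
  it is designed for, but not tested against, external viewers.
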