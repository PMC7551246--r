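---
title: "Methods: distributional cost-effectiveness of the Ying Yang Bao package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: distributional cost-effectiveness of the Ying Yang Bao package}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(yybecea)
library(dplyr)
```

## The model

Ying Yang Bao (YYB) is a soybean-based micronutrient supplement for Chinese
children aged 6–36 months, delivered as one pack per day over a 12-month
programme. `yybecea` implements an *extended* cost-effectiveness analysis
(ECEA) of a hypothetical rural rollout: rather than a single national
cost-effectiveness number, every quantity is disaggregated by province and
by wealth group (below/above the World Bank $5.50/day line, ¥19.4/day in
2011 RMB), so the distributional and equity consequences are visible.

The causal model is a static height shift. For child $i$ in province $p$
and wealth group $k$ with pre-intervention height $H_{p,k,i}$, coverage
$\mathrm{Cov}_p$ and mean height effect $\mathrm{Eff}$ (cm):

$$H^{post}_{p,k,i} = H_{p,k,i} + \mathrm{Eff} \cdot \mathrm{Cov}_p .$$

Heights are standardised into height-for-age Z-scores,
$\mathrm{HAZ} = (H - \mathrm{median}_{sex,age})/\mathrm{SD}_{sex,age}$,
and a child is stunted when $\mathrm{HAZ} < -2$ (strictly). With subgroup
stunting prevalences $S^{pre}_{p,k}$ and $S^{post}_{p,k}$ and population
$\mathrm{POP}_{p,k}$ aged 6–36 months, the health gain is

$$\mathrm{AVERT}_{p,k} = \mathrm{POP}_{p,k}\,(S^{pre}_{p,k} - S^{post}_{p,k}),$$

carried as a real number (a population-scaled expectation) and rounded only
for presentation. The cost per stunting case averted (the ICER) is the
subgroup's total programme cost divided by $\mathrm{AVERT}_{p,k}$, reported
as `NA` — never infinity — when nothing is averted.

The default effect size is $\mathrm{Eff} = 2.46$ cm (95% CI 0.96–3.97), the
pooled height gain across YYB evaluation studies. It enters the model as an
input parameter; re-estimating it is out of scope.

### Expected shift versus Bernoulli coverage

`apply_effect()` has two modes. The default `expected_shift` applies
$\mathrm{Eff}\cdot\mathrm{Cov}$ to *every* child — the expected-height
model above, which is what the published per-province tables follow. The
`bernoulli` mode instead covers each child with probability
$\mathrm{Cov}$ (seeded) and gives covered children the full
$\mathrm{Eff}$. The two are not equivalent: a partial uniform shift moves
everyone a little, while a Bernoulli mixture moves a fraction a lot, and
the post-shift mass below $-2$ differs. For HAZ $\sim N(\mu, 1)$ and
reference SD $s$, the expected averted fraction is
$\Phi(-2-\mu) - \Phi(-2-\mu-\mathrm{Eff}\cdot\mathrm{Cov}/s)$ under the
expected shift, but
$\mathrm{Cov}\,[\Phi(-2-\mu) - \Phi(-2-\mu-\mathrm{Eff}/s)]$ under
Bernoulli coverage. Both closed forms are verified in the test suite.

## The cost model

Per-pack costs are carried in RMB cents. Three components are fixed:
procurement/manufacturing $M = 35.0$, implementation $F = 17.9$ and
advertisement $A = 16.7$ cents/pack. Transport varies. The
manufacturer-to-township leg is a linear function of provincial road
density $R_p$ (km per 100 km²):

$$TM_p = 13.5 - \frac{13.5 - 0.9}{208 - 31}\,(R_p - 31),$$

anchored so the best-connected province (208) pays 0.9 and the
least-connected (31) pays 13.5 cents/pack. Outside $[31, 208]$ the cost is
clamped to the anchor values rather than extrapolated — the linear form is
only supported on the observed range and extrapolation could go negative.

The township-to-household leg depends on the delivery type. Under
**Delivery Type 1** village doctors collect packs monthly (a fixed
$TV = 0.9$ cents/pack, government-borne) and caregivers collect from the
village health post, contributing time cost $TH_{p,k}$; under **Delivery
Type 2** caregivers travel to the township hospital themselves, time cost
$TO_{p,k}$. So $T_{p,k} = TM_p + TV + TH_{p,k}$ (Type 1) or
$TM_p + TO_{p,k}$ (Type 2), $PP_{p,k} = M + F + A + T_{p,k}$, and the
subgroup total is $PP_{p,k}\cdot\mathrm{POP}_{p,k}\cdot\mathrm{Cov}\cdot 365$.
Both wealth groups' time costs use the group-mean travel time, applied
uniformly within the group. International-dollar figures are a presentation
conversion through the poverty-line equivalence ¥19.4/day ≡ $5.50/day
(2011 PPP); internally everything stays in RMB.

### Valuing caregiver time

"Travel time times GDP per capita" fixes no unit basis, so the package
makes the dimensional analysis explicit and tunable:

$$\text{cents/pack} = 100 \cdot
  \frac{\texttt{trips\_per\_year} \times 2 \times t \times
        \mathrm{GDP}/\texttt{hours\_per\_workyear}}{\texttt{packs\_per\_year}},$$

with defaults of 12 monthly round trips, an hourly value of annual GDP per
capita over 2,000 work hours, and 365 packs/year. All three are
`cost_params()` knobs. With the realistic default travel times in the
generator (about 0.1 h one-way to a health post, 0.5 h to town) this
yields per-pack time costs of tens of cents — larger than published
appendix-level averages of under a cent (health post) and a few cents
(town), which imply either much shorter effective travel times or a
different amortisation. Because the time basis is genuinely unidentified
from the published description, we keep the explicit formula and realistic
times rather than back-solving travel times to tiny values; users wanting
a different basis change the knobs, not the code. The qualitative
structure the analysis relies on — Type 1 cheaper than Type 2 wherever
$TV + TH < TO$, i.e. wherever towns are farther than health posts — is
unaffected and is asserted in the tests.

## The synthetic world

The real analysis used restricted household-survey microdata (CFPS).
`sim_config()` + `simulate_provinces()` + `simulate_children()` generate a
seeded stand-in with the statistical structure the method consumes:

* 25 provinces × 640 children (≈16,000 households over 25 provinces);
* road density uniform on [31, 208] km/100 km²; GDP per capita uniform on
  [¥28,000, ¥95,000] (the observed span from the poorest to the richest
  province); populations aged 6–36 months uniform on [10⁵, 10⁶] per
  province, split by the province poverty fraction;
* HAZ drawn from $N(\mu_{p,k}, 1.1)$ with national means −1.2 (poor) and
  −0.6 (non-poor) plus a shared province offset with SD 0.35, then
  truncated at ±6 SD and converted to height by inverting the growth
  reference ($H = \mathrm{median} + \mathrm{HAZ}\cdot\mathrm{SD}$). HAZ is
  simulated directly — rather than simulating raw heights — so the
  synthetic world is exactly consistent with the anthropometry module.
  These settings give subgroup prevalences from near zero in
  well-off provinces up to roughly a quarter in poor groups of poor
  provinces, the observed span in rural China;
* wealth group drawn first (Bernoulli at the province poverty fraction,
  default 0.4 with logit-scale province jitter), then income per capita
  sampled from a log-normal calibrated so its below-line mass equals the
  poverty fraction, *truncated to the drawn group's side of the ¥19.4
  line*. Income-based classification therefore reproduces the group
  exactly — including at the boundary configurations (fraction 0 or 1) —
  while the unconditional income distribution keeps the configured
  below-line mass;
* log-normal one-way travel times (medians 0.1 h to the health post,
  0.5 h to town) and unit survey weights (weighted aggregation is
  supported throughout but is not the default, since the original
  weighting scheme is unknown).

What the generator does **not** emulate: the survey's sampling design and
panel structure, real provincial estimates, urban populations,
within-province spatial clustering, or any correlation between income and
travel time. Passing tests therefore demonstrate that the *method* is
implemented correctly and behaves as the model predicts on data with the
assumed structure — not that the synthetic tables reproduce any real
province's numbers, which is impossible without the restricted microdata.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `eff_cm` | 2.46 | cm | pooled height effect of 12 months of YYB |
| `coverage` | 0.25 / 0.75 | — | the low/high rollout scenarios |
| `m_cents`, `f_cents`, `a_cents` | 35.0, 17.9, 16.7 | RMB cents/pack | fixed cost components |
| `tv_cents` | 0.9 | RMB cents/pack | village-doctor collection, Type 1 |
| `tm_min/max_cents`, `r_min/max` | 0.9/13.5, 31/208 | cents; km/100 km² | transport interpolation anchors |
| `ppp_rmb_per_intl` | 19.4/5.5 | ¥ per intl $ | 2011 PPP poverty-line equivalence |
| `transport_multiplier` | 1 | — | sensitivity hook, scales the whole T term |
| `haz_sd` | 1.1 | SD units | within-group HAZ spread |

The sensitivity suite is the fixed labelled grid {`base`, `eff_halved`,
`eff_ci_lower` (0.96 cm), `transport_halved`, `transport_doubled`} ×
{coverage 0.25, 0.75} × {Delivery Type 1, 2}, so runs are diffable.

## Numerical choices

* **Threshold ties.** Stunting is *strictly* HAZ < −2; HAZ exactly −2 is
  not stunted. Ties have probability zero for continuous heights, but the
  rule must be fixed for reproducibility. Note the height→HAZ round trip
  is floating-point exact only when median and SD are exactly
  representable; with e.g. two-decimal reference values a child placed
  exactly at −2 can land at −2 ± 1 ulp.
* **Zero-averted groups.** ICER is `NA`, never `Inf`, and such groups sort
  last in `rank_groups()`; ties break stably by province then wealth label.
* **Empty subgroups.** `prevalence()` errors on an empty group (the
  quantity is undefined); group-level reporting propagates `NA` instead.
* **Clamping.** Transport cost clamps outside [31, 208]; simulated HAZ
  truncates at ±6 SD so generated heights stay inside the 40–120 cm
  plausibility window.
* **Determinism.** Every stochastic step (province draws, child draws,
  Bernoulli coverage) takes an explicit seed through `withr::with_seed()`,
  leaving the caller's RNG state untouched; identical seeds give
  byte-identical CSV outputs end to end.
* **Currency.** RMB cents per pack and yuan for totals internally;
  international dollars only at presentation; machine CSVs unrounded.

## Design choices on genuinely open points

* **Coverage is one scalar per scenario**, shared across wealth groups and
  identical in the benefit and cost formulas; nothing in the published
  description distinguishes group-specific coverages.
* **Survey weights** are supported in every aggregation (`weight_col`
  argument) but default to unit weights; whether the original prevalence
  estimates were survey-weighted is not stated, so the generator's default
  makes the two choices coincide.
* **Delivery-type costs are societal** for both types: caregiver time is
  included in the total whoever bears it, with the government/caregiver
  split recoverable from the per-pack components (`tv` vs `th`/`to`).
* **Growth reference as input.** The reference is a plain (sex, month) →
  (median, SD) table; the bundled file is synthetic and clearly labelled
  so, and any WHO-standard table in the same format can be substituted.
  Skewness-corrected (LMS) standardisation is deliberately out of scope.

## Problem sizes

The test suite and the acceptance script use the default synthetic world
(25 × 640 = 16,000 children) for pipeline-level results, n = 10,000 for
closed-form Monte-Carlo comparisons (three Monte-Carlo standard errors),
and ≤ 50-child instances for brute-force oracle equivalence. These sizes
give Monte-Carlo error well under the effect sizes being detected while
keeping a full run in seconds.

## Known limitations

* The height effect is uniform across ages, provinces and baseline HAZ; no
  duration–response or adherence mechanism (adherence enters only through
  the halved-effect sensitivity).
* Transport costs scale linearly with road density and with the flat
  multiplier; no mode-switching or economies-of-scale curve.
* No optimal-coverage search and no outcomes beyond stunting (anaemia,
  cognition, financial-risk protection are out of scope).
* Synthetic provinces are exchangeable draws, not named Chinese provinces;
  per-province results are illustrative of the method only.

## A worked run

```{r}
cfg <- sim_config()
provinces <- simulate_provinces(cfg, seed = 1)
children  <- simulate_children(cfg, provinces, seed = 1)

res <- run_scenario(children, provinces,
                    scen = scenario(coverage = 0.75, delivery_type = 1))
glance(res)
head(rank_groups(res))
```

```{r, fig.width = 6, fig.height = 5}
autoplot(res)
```

```{r}
suite <- sensitivity_suite(children, provinces, seed = 1)
suite |> dplyr::select(-result) |> head(10)
```
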