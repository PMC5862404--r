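---
title: "Methods: classifying climate-suitability trends and community change in protected areas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying climate-suitability trends and community change in protected areas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avichange)
library(dplyr)
```

## The problem

Species distribution models (SDMs) relate bird occurrence to climate and can
be projected onto future climate surfaces. For a protected-area system, the
practical question is not the continental map but the park: for each species
in each park, is the climate becoming more or less suitable, and does
suitability cross the species' suitable/unsuitable threshold between now and
mid-century? `avichange` implements that post-processing layer. Its inputs
are park-averaged climate suitability values in $[0,1]$ — one value per
species $\times$ park $\times$ season $\times$ emissions pathway (RCP)
$\times$ GCM ensemble member $\times$ time period — together with
species-specific seasonal suitability thresholds (derived upstream by
maximizing the true skill statistic, and taken as given here) and park
metadata (region, latitude). Everything upstream of those tables — SDM
fitting, climate-surface processing, the spatial averaging of raster cells
over each park — is out of scope.

## Trend model and five-way classification

For one species in one park (one season, one RCP) the data are twelve
suitability values: four GCMs at each of three periods, the present
(2000–2010), 2011–2040, and 2041–2070. We fit

$$ y = \beta_0 + \beta_1 \,\mathrm{year} + \varepsilon $$

by ordinary least squares, pooling the GCM values at each period, so
$\hat\beta_1$ is the average suitability trend across the ensemble and the
intermediate period serves only to stabilize the trend estimate. The slope's
two-sided $t$ test ($n-2$ df) at level $\alpha$ decides whether the trend is
significant. Suitability status is assessed on across-GCM means:
$\bar y_{\mathrm{present}}$ and $\bar y_{\mathrm{mid}}$ compared with the
species threshold $t$. The decision order in `classify()` is:

1. $\bar y_{\mathrm{present}} < t \le \bar y_{\mathrm{mid}}$ →
   **potential colonization**;
2. $\bar y_{\mathrm{present}} \ge t > \bar y_{\mathrm{mid}}$ with
   $\hat\beta_1 < 0$ significant → **potential extirpation**;
3. significant $\hat\beta_1 > 0$ → **improving**;
4. significant $\hat\beta_1 < 0$ → **worsening**;
5. otherwise **stable**.

Potential extirpation is deliberately a *subset of the worsening trend*: a
downward crossing without a significant negative slope falls through to the
trend test. Potential colonization, by contrast, is triggered by the
crossing alone; requiring a significant positive slope as well is available
via `classifier_settings(colonization_requires_trend = TRUE)` but is off by
default, because the colonization definition rests on the threshold
transition, not on trend significance. A species enters the analysis for a
park only if the park is suitable for it at present or by mid-century
(`species_included()`); the same present/mid means are used for this rule
and for the crossing tests, so there is a single operational definition of
"suitable at present".

### Choices the trend layer had to make

* **Time coding.** Periods are coded at their calendar midpoints (2005,
  2025.5, 2055.5), making $\hat\beta_1$ interpretable in suitability units
  per year and preserving the unequal spacing of the periods. An ordinal
  0/1/2 coding is available (`time_coding = "ordinal"`) for sensitivity
  checks; on noiseless data the classification is identical because only the
  slope's sign and significance enter the decision.
* **$\alpha$ = 0.05** by default — the conventional level; it is a free
  parameter of `classifier_settings()`.
* **Degenerate fits.** Twelve identical values give a slope of exactly 0 and
  the $p$-value is set to 1 (stable); an exact nonconstant linear fit gives
  $p = 0$. Both avoid undefined $t$ statistics; the tolerance is relative
  ($\mathrm{RSS} \le 10^{-12}\,S_{yy}$) so the policy is scale-free.
* **Year-round detection.** A species currently suitable in summer whose
  winter suitability is below threshold now but at/above it by mid-century
  is counted by `year_round_counts()` per park $\times$ RCP.

## Community change

Assuming every potential colonization and extirpation is realized, the
future species list of a park is the present list minus extirpations plus
colonizations. Turnover is the binary Bray–Curtis (equivalently Sørensen)
dissimilarity of the two lists,

$$ d_{BC} = \frac{|P \setminus F| + |F \setminus P|}{|P| + |F|}
   = \frac{n_{col} + n_{ext}}{2\,r_{present} + n_{col} - n_{ext}}, $$

0 for no change, 1 for complete turnover. The count form on the right is an
identity here because an extirpation is by definition currently suitable and
a colonization currently unsuitable; the tests verify the set form against
an independent vector-form Bray–Curtis implementation. Colonization and
extirpation *proportions* use present richness as the denominator (the
current species count), so colonizing species do not inflate their own
denominator. System-wide summaries report means with standard errors
(sample SD/$\sqrt n$), strict (">25%") park counts, and the mean per-park
realization fraction $n_{ext}/n_{col}$ — the share of colonizations that
must be realized for a net richness gain — excluding (and counting) parks
with no colonizations. Whether the Bray–Curtis index is computed over the
union of the two lists or over the full inclusion-rule universe makes no
difference for presence/absence data, since species absent from both lists
contribute nothing.

## Park trend groups

With one point per park — colonization proportion against extirpation
proportion, canonically for summer under the high-emissions pathway — the
cohort's medians and quartiles cut the plane into five sectors: the
axis-aligned interquartile rectangle around the joint median is
*intermediate change*; outside it, the median lines yield *high turnover*
(above both), *high colonization*, *high extirpation*, and *low change*.
The rectangle is evaluated before the median splits, so a park at the joint
median is intermediate. Two genuinely open geometric readings exist for the
central region (an axis-aligned IQR rectangle versus a rotated diamond); we
implement the axis-aligned reading, which follows directly from "within a
quartile of the median along the two axes", and keep the decision isolated
in `assign_group()` so an alternative geometry is a local change. Quantiles
use the linear-interpolation estimator (type 7, the common default); ties
at a median resolve to the low-change side and only affect parks exactly on
a boundary.

## Comparative statistics

* **Seasonal contrasts** (`compare_seasons()`): Shapiro–Wilk at 0.05 on each
  sample gates a two-sided $t$ test versus a Wilcoxon test. The default is
  the unpaired rank-sum form; a paired option exists because the same parks
  appear in both seasons, a genuinely ambiguous design choice — rank-sum
  magnitudes of the reported $W$ statistics are consistent with the unpaired
  form, hence the default.
* **Latitudinal regressions** (`latitude_regression()`): OLS of a park
  metric on latitude, with Alaska excluded by default because the sampled
  latitudinal gradient is interrupted at the Canadian border; $r^2$ equals
  the squared Pearson correlation (verified in tests).
* **Regional ANOVA** (`regional_anova()`): one-way fixed effects across the
  seven NPS regions, df $(k-1, n-k)$, with a median-centered Levene test
  reported alongside as a heteroscedasticity screen — informative, not
  blocking, since unequal region sizes are inherent to the system.
* **Region versus rest** (`region_vs_overall()`): two-sided Wilcoxon
  rank-sum of a region's parks against all other parks; comparing a rank
  test against a constant "overall mean" is not well-defined, so the
  rest-of-system sample stands in for the systemwide level. Wilcoxon
  $p$-values are exact when both samples have $n \le 25$ and no ties,
  otherwise the normal approximation with continuity correction is used.
* **No multiple-testing correction** is applied by default, matching how
  such park-system analyses are conventionally reported; `p.adjust` can be
  applied downstream by the user.

## The synthetic-data generator

`generate_scenario()` exists so every downstream stage is testable with
known ground truth. For each species $\times$ park $\times$ season $\times$
RCP key it draws a threshold $t \sim U(0.2, 0.6)$ per species and season,
assigns one of the five classes, builds a noiseless mean trajectory over the
period midpoints consistent with that class (slope $\pm$ 0.002/yr for
trending classes; crossing classes straddle $t$ symmetrically; non-crossing
classes keep a 0.05 clearance from $t$), and adds independent Gaussian noise
(SD 0.01) to each of the 12 GCM $\times$ period cells, clipping to $[0,1]$.
Park metadata apportions parks over the seven regions by largest-remainder
apportionment with weights proportional to the regions' actual park counts
(16, 39, 82, 36, 44, 18, 39 — so 274 parks reproduce those counts exactly)
and draws latitudes within region-typical bands, Alaska strictly above
54°N.

Default scale and mix are the study conditions the package targets: 274
parks, 100 species (the scale of a park's summer species list), both
seasons, both emissions pathways. The class mix (improving 0.2625, stable
0.10, worsening 0.2625, colonization 0.21875, extirpation 0.15625) is
calibrated so a park's expected extirpation and colonization proportions are
0.20 and 0.28 of present richness, which implies a mean binary turnover of
$0.48/2.08 \approx 0.23$ — the magnitudes characteristic of the summer
high-emissions stratum of such park-system analyses. The stable share is
deliberately small: a planted zero-slope key is misclassified whenever the
slope test commits a type-I error, so recovery of the stable class is
bounded by $1-\alpha$ regardless of the noise level, and the mix keeps the
aggregate recovery ceiling above 99%.

What the generator does *not* emulate: spatial autocorrelation among parks,
latitudinal or regional gradients in change rates (classes are assigned
independently of geography, so latitude regressions on synthetic data are
null), correlations among GCMs, species traits, or logit-scale noise. Tests
passing on synthetic data therefore validate the algebra and inference of
the pipeline, not the ecological realism of any particular projection.
Additive Gaussian noise with clipping was chosen over a logit-normal model
as the simplest bounded-data model; the noise model is an isolated extension
point.

## Numerical and I/O choices

* CSV is the interchange format, with a fixed documented header and a
  column-mapping option to absorb dialect differences in upstream tables.
  Period labels are calendar ranges on disk and short codes in memory.
* Reals are written at full precision (not rounded), so a write/read round
  trip reproduces the exact record multiset — a property the tests enforce —
  while output remains byte-deterministic for identical inputs and
  configuration.
* Incomplete GCM $\times$ period ensembles are a hard error by default; a
  permissive flag drops the affected keys with a warning, never silently,
  because a regression on fewer than 12 points silently changes the
  inference.
* The pipeline's run manifest records input/output MD5 hashes, settings, and
  package version, so identical inputs and configuration are verifiably
  byte-identical.

## Problem sizes

The test suite runs scenarios of 2–32 parks and 5–40 species (up to ~5,000
keys for the recovery checks, 1,000 replicates for type-I error
simulations); the acceptance script uses the full default conditions (274
parks, 100 species, ~110,000 keys). These sizes give stable estimates of
every reported rate while keeping a full run in the minutes range on one
CPU.

## Known limitations

* The classification inherits the upstream SDM's assumptions; threshold
  quality (a TSS maximizer balancing omission and commission) bounds the
  meaning of "suitable".
* Pooling GCMs treats ensemble members as exchangeable replicates; per-GCM
  classification or model-averaging is a non-goal.
* The typology is relative to its cohort: group labels change when the
  cohort changes, by design.
* Turnover assumes full realization of potential colonizations and
  extirpations and is therefore an upper envelope of community change.

## A worked example

```{r example}
sc <- generate_scenario(scenario_config(n_parks = 12, n_species = 30, seed = 7))
cls <- classify_all(sc$suitability, sc$thresholds)
ps <- summarize_parks(cls)
systemwide_summary(ps) |>
  filter(rcp == "RCP8.5") |>
  select(season, mean_bray_curtis, mean_prop_extirpation,
         mean_prop_colonization, pct_parks_col_exceeds_ext)
table(classify_parks(ps)$group)
```
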