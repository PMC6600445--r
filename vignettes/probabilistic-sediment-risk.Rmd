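---
title: "Probabilistic ecological risk assessment of sediment PTEs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic ecological risk assessment of sediment PTEs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(sedrisk)
library(dplyr)
```

sedrisk assesses the ecological risk posed by potentially toxic elements
(PTEs) accumulated in river sediments. It combines three layers that are
usually scattered across spreadsheets in this field: speciation summaries
from five-step sequential extraction, the deterministic Håkanson risk
indices, and a Monte Carlo layer that replaces single-point risk numbers
with class probabilities and exceedance curves. This vignette explains the
models, the tunable parameters, the numerical choices, and what the
synthetic-study generator can and cannot stand in for.

## Sequential extraction and the retention contamination factor

A modified Tessier scheme partitions each element's content into five
operationally defined fractions of decreasing mobility: F1
(ion-exchangeable), F2 (carbonate-bound and easily reducible), F3 (Fe-oxide,
moderately reducible), F4 (organic matter and sulfides) and F5 (residual,
aqua regia). `fraction_percentages()` expresses each step relative to the
*summed extracted content* — not the independent total digest, which is
reserved for recovery QC (`recovery_qc()`, default acceptance band 80–120 %,
motivated by the certified-reference accuracy range of the assay
(81.5–114 %); out-of-band samples are flagged, never dropped).

Two quantities both called "contamination factor" circulate in this
literature, and the package keeps them strictly apart:

* the **retention contamination factor** (`retention_cf()`),
  $C_f = (c_1 + c_2 + c_3 + c_4)/c_5$ — mobile over residual content. Lower
  means better retained. A zero residual step raises an error rather than
  returning infinity, because downstream statistics (means over samples,
  rankings) must never mix finite and infinite values;
* the **Håkanson contamination factor** (`hakanson_cf()`),
  $C_f^i = C^i / C_n^i$ — concentration over background.

`mobility_order()` renders a percentage profile as an ordering such as
`F5 > F2 > F1 > F4 > F3`, joining neighbours closer than `tie_threshold`
percentage points with "≈". The threshold defaults to 2 points: published
orderings use "≈" without defining it, and 2 points is small relative to the
5-point gaps that separate genuinely distinct fractions in this kind of
data while absorbing the sampling noise of a ~30-sample study mean. With
threshold 0 the ordering is the strict sort; raising the threshold can only
merge neighbours, never reorder them (a property the test suite exercises).
`ordering_equal()` compares orderings treating tie groups as sets.

## The Håkanson indices

For element $i$ with measured concentration $C^i$, background $C_n^i$ and
toxic response factor $T_r^i$:

$$E_r^i = T_r^i \cdot \frac{C^i}{C_n^i}, \qquad RI = \sum_{i=1}^{m} E_r^i.$$

Class boundaries are half-open on the right — a value exactly at a
threshold belongs to the upper class, matching the conventional
"$40 \le E_r < 80$" table layout:

| $E_r$ | class | | $RI$ | class |
|---|---|---|---|---|
| < 40 | Low | | < 150 | Low |
| [40, 80) | Lower | | [150, 300) | Lower |
| [80, 160) | Median | | [300, 600) | Median |
| [160, 320) | High | | ≥ 600 | High |
| ≥ 320 | Extremely high | | | |

Both scales live in a `risk_scheme()` object, so other Håkanson variants
(different thresholds, more classes) are expressible without touching code.

The packaged reference table (`read_reference()`) carries the eleven
elements of the Serbian river-sediment survey the defaults emulate. Its
backgrounds are the study minima. Crucially, **absence is explicit**: Ni and
As have no background, and Co, Fe, Mn and V have no toxic response factor.
Such elements are *excluded* from $E_r$ and $RI$ and listed in an exclusion
report — never silently zero-filled, which would deflate $RI$ without
anyone noticing. $m$ is therefore the count of eligible elements (five under
the packaged table: Cd, Cr, Cu, Pb, Zn), not the number of elements
measured. Users who have defensible Ni or As backgrounds supply them
explicitly in their own reference YAML.

## The Monte Carlo layer

`simulate_element_risk()` and `simulate_total_risk()` propagate a
concentration *distribution* through the index: draws
$C_j \sim \hat F_i$ give $E_{r,j}^i = T_r^i C_j / C_n^i$, and
$RI_j = \sum_i E_{r,j}^i$ per iteration. Outputs are class-probability
tables (percentage of draws per class) and exceedance curves
$v \mapsto P(X \ge v)$, which start at 1 and are nonincreasing.

**Distribution families.** Concentrations can be fitted from raw samples
(`fit_from_samples()`) or from printed summaries (`fit_from_summary()`,
for the common situation where only min/max/mean survive into a
publication). The default family is a *truncated normal on the observed
range*: a plain normal generator is the field's habit, but an unbounded
normal emits negative concentrations and mass beyond the observed support.
Truncation to [min, max] keeps the printed support exactly; a plain normal
with rejection of negatives remains available (`family = "normal"`) for
users who want the literal convention, along with lognormal, point-mass and
empirical (bootstrap) families.

**The range-rule SD.** When only min/max/mean are known the scale is taken
as $(max - min)/4$, the standard range rule; it is a convention, not an
estimate, and is configurable via `sd_rule` (any function of min, max,
mean).

**Moment matching under truncation.** `fit_from_samples()` with
`family = "truncated_normal"` uses the sample min/max as support and then
solves the two nonlinear equations that make the *truncated* law's mean and
SD equal the sample moments (Nelder–Mead on $(\mu, \log\sigma)$, relative
tolerance $10^{-14}$). Setting $\mu$ to the sample mean directly would be
badly biased: under asymmetric truncation the truncated mean can sit more
than 15 % away from the parent location.

**Identifiability caveat.** When the truncation removes a large share of
the parent mass (observed min far above the parent's lower tail — in the
packaged defaults, Cu is the extreme case), the parent $(\mu, \sigma)$ sit
on a flat likelihood/moment ridge: many parameter pairs produce nearly the
same truncated law. The fitted *distribution* is then still accurate (its
truncated moments match the sample almost exactly, and class probabilities
are unaffected), but the parent `location` itself can be off by ~10 % even
at $n = 10{,}000$. Maximum likelihood does not help — the information is
simply not in the data. Parameter-recovery checks should therefore be read
as statements about the well-identified laws, and distribution-level
comparisons used for the heavily truncated ones.

**Seeding.** One master seed spawns a deterministic substream per element
(polynomial string hash folded into the seed modulo $2^{31}-1$), so
identical inputs are bitwise reproducible and adding an element to a
simulation never perturbs another element's draws. Iterations default to
100,000, at which the binomial standard error of a reported class
probability is at most $\sqrt{0.25/10^5} \approx 0.16$ percentage points.

**Rounding.** All internal arithmetic is unrounded; probabilities are
rounded half-even (R's `round()`) only in the reporting layer
(`class_prob_table()`, default 2 decimals).

**Independence.** Elements are sampled independently; no inter-element
correlation model is fitted (none is identifiable from printed summaries).
The total-risk simulation therefore gets the mean of $RI$ right by
linearity but would understate (or overstate) $RI$'s spread if real
concentrations co-vary strongly across elements at the same site — a known
limitation for multi-element hotspots, where Cd/Zn/Pb tend to rise
together.

**Pooling.** Distributions are fitted per element over all sites; no
stratification by river. Per-river fits would need far more than ~30
samples to be stable.

## The synthetic-study generator

No per-sample data ship with the reference survey, so `generate_study()`
builds a study with *known ground truth*, sized and shaped like the real
one, against which every pipeline stage is tested:

* **32 sites** on a 15-river layout (Tisa through Toplica, recycled for
  other `n_sites`), 11 elements;
* **totals** drawn from per-element truncated normals anchored to the
  published min/max/mean via `fit_from_summary()` (the range rule supplies
  the SD — a convention, since the survey printed no SDs);
* **fraction profiles** drawn around per-element mean profiles shaped to
  reproduce the published mobility orderings, with per-step noise of SD 3
  percentage points and renormalisation to 100. Tied fractions ("≈" in the
  published orderings) are encoded as *exactly equal* means — the natural
  reading of approximate equality, and the encoding under which a
  2-point tie threshold recovers the ties stably at $n = 32$; strict
  neighbours are separated by at least 5 points;
* **recovery**: each sample gets a recovery factor drawn uniformly in
  [0.815, 1.14] (the assay's certified accuracy range), drawn per sample
  rather than per element for simplicity; fraction steps are rescaled so
  they sum to `total × recovery` exactly, which the suite asserts row by
  row;
* **hotspots**: the survey's critical sites (Ibar: Cd/Zn/Pb/Ni; Pek:
  Cu/Zn; Porečka: Cu; West Morava: Pb; South Morava: Mn) are planted as
  `multiplier ×` the element's analytic law mean (multipliers 3–10) at the
  first site of the named river. Applying the multiplier to the law mean
  rather than to the site's random draw makes the outlier behaviour
  deterministic — a planted hotspot always exceeds the base law's 99th
  percentile. Planted rows are recorded in `ground_truth$hotspots`, so
  law-recovery analyses can exclude the known contamination (recovering a
  base law from data that includes planted outliers is a robustness
  exercise, not a parameter-recovery one — with min/max support, one
  outlier redefines the fitted support).

What the generator does **not** emulate: spatial correlation between
sites, inter-element correlation within a site, analytical error structure
beyond the scalar recovery factor, censored values below detection limits,
and any real skewness beyond what the truncated normal induces. Tests that
pass on synthetic studies validate the *computational pipeline* — formulas,
orderings, determinism, statistical convergence — not claims about any real
river basin.

## Numerical and degenerate-input choices

* All five fraction steps zero → degenerate-profile error (no 0/0
  percentages); residual step zero → retention-factor error, not `Inf`.
* A constant sample (or a min = max = mean summary) fits as a point mass;
  fitting a scale from fewer than two values is an error.
* A normal spec whose mass is ≥ 99 % negative is rejected as infeasible
  rather than looping in rejection sampling.
* Truncated-normal draws use the inverse-CDF transform, so they respect the
  support exactly (no rejection loop) and are monotone in the underlying
  uniforms.
* Equal percentages in an ordering are tie-broken by fraction index purely
  for display; comparisons treat tie groups as sets.
* Validation errors are classed conditions (`sedrisk_error_validation`,
  `sedrisk_error_format`, `sedrisk_error_usage`) naming the offending rows
  and fields; readers never receive a partially validated table.

## Problem sizes used by the test suite

The suite exercises convergence claims at the sizes where they are sharp
but cheap: law-of-large-numbers checks on profiles at $n = 10{,}000$;
parameter recovery on a 10,000-site synthetic study; closed-form-CDF
agreement of class probabilities at 100,000 iterations (within three
binomial standard errors per class); ordering reproduction on the default
32-site study. The acceptance script reruns the three summary-fitted
elements whose lowest-class probability is provably 100 % (even their
observed maxima give $E_r$ of 16.4, 27.5 and 7.4 — all below 40) at
100,000 iterations.

## Known limitations

* Risk classes inherit all the caveats of Håkanson-style indices:
  backgrounds and toxic response factors are conventions, and $RI$ depends
  on which elements are eligible ($m$ is reported for exactly this reason).
* Independence across elements (above) biases $RI$'s tails when
  concentrations co-vary.
* The range-rule SD can be far from the real SD for skewed data; when raw
  samples are available, `fit_from_samples()` should always be preferred.
* Parent-parameter recovery is weakly identified under heavy truncation
  (above); the package reports the fitted law's moments so users can check
  identifiability on their own data.
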