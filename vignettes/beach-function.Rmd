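---
title: "Scoring beach function below feeder bluffs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring beach function below feeder bluffs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bluffbeach)
```

## The assessment problem

Feeder bluffs are actively eroding coastal cliffs that supply sediment to
the beaches beneath and downdrift of them. Where the bluff toe is armored
(seawall, bulkhead, riprap), sediment delivery and upper-beach habitat are
disrupted. Management programs in glacially carved fjord systems such as
Puget Sound rank bluffs for *protection* (unarmored, keep it that way) or
*restoration* (armored, candidate for armor removal), each at *high* or
*low* priority for potential sediment-supply benefit. `bluffbeach`
implements a reproducible pipeline that asks whether those landscape-scale
priorities line up with locally realized ecological function: it aggregates
raw beach-survey records into 30 site metrics spanning the bluff top to the
low shore, scores them on a common 0–1 scale per treatment, and provides the
permutation statistics used to compare treatments.

The four treatments are `ProtectHigh`, `ProtectLow`, `RestoreHigh`,
`RestoreLow`; the sampling design crosses them with five geographic regions,
one site per treatment and region (20 sites).

## The scale bar

The headline statistic is a composite "scale bar" of beach function:

1. average each metric over a treatment's sites (unweighted; missing values
   excluded pairwise, never imputed as zero);
2. min–max scale each metric's four treatment means to [0, 1]:
   $s = (x - \min x) / (\max x - \min x)$, inverting ($s \leftarrow 1 - s$)
   metrics for which lower raw values indicate greater function;
3. average the scaled values across the 30 metrics, giving one score per
   treatment, with a standard error taken across the 30 scaled values.

Two numerical conventions matter. If a metric's four means are all equal,
every treatment receives 0.5 — the metric is neutral but stays in the
30-metric denominator rather than silently dropping out. And scaling is
affine-invariant: changing a metric's units cannot change any score.

By default only *Relative Encroachment* is inverted: positive encroachment
means the bluff or armor toe sits below Mean Higher High Water, truncating
upper-beach habitat, so lower is better. The right orientation for a few
other metrics is a judgement call (beach slope; fallout-trap density when
the catch is dominated by non-insect taxa; percent sand, which favors
eelgrass but not infaunal diversity), so every orientation is overridable
via `metric_definitions()`. The Protect-to-Restore score ratio computed from
the packaged reference means is ≈ 2.4 and stays above 2 when the beach-slope
orientation is flipped, so the headline conclusion does not hinge on these
choices.

## Geomorphic metrics

Cross-shore elevation profiles run seaward from the bluff/armor toe (an
input point, not detected by the package) to below MLLW, with tidal datums
supplied in the same vertical frame (no datum conversion is attempted).

* *Relative encroachment* = MHHW − toe elevation (m, signed).
* *Beach slope (toe–MSL)* = vertical drop from toe to MSL over the
  horizontal distance to the first seaward MSL crossing, linearly
  interpolated between bracketing points; reported as a positive magnitude.
* *Beach width (toe–MLLW)* = horizontal distance from toe to the first
  seaward MLLW crossing.

Profiles with bars can recross a datum; the first seaward crossing is used,
matching the beach-face intent of the metrics. Bluff height and exposed
bluff-face area are imagery-derived pass-through inputs, validated
non-negative but never computed from profiles.

## Wave hindcast

Each site's storm wind is assigned from its shoreline facing: 20 km/h for
southerly sites (169–214° true), 15 km/h for northerly sites (349–34°,
wrapping through north), 10 km/h otherwise, always as a 6-h event. With wind
speed $U$ in m/s, the deep-water simplified method of the Shore Protection
Manual (1984) gives the wind-stress factor $U_A = 0.71\,U^{1.23}$ and the
fetch-limited growth laws

$$H_s = 1.6\times10^{-3}\left(\frac{gF}{U_A^2}\right)^{1/2}\frac{U_A^2}{g},
\qquad
T = 0.2857\left(\frac{gF}{U_A^2}\right)^{1/3}\frac{U_A}{g},$$

valid when the event lasts at least
$t = 68.8\,(gF/U_A^2)^{2/3}\,U_A/g$; shorter events use the
duration-equivalent fetch, and both quantities are capped at the fully
developed limits $H_s = 0.2433\,U_A^2/g$, $T = 8.134\,U_A/g$
($g = 9.81$ m/s²). Wind speeds are converted from km/h inside `smb_wave()`,
so passing unconverted speeds is impossible by construction. A 20 km/h wind
over 25 km of fetch yields $H_s \approx 0.47$ m, $T \approx 3.3$ s,
fetch-limited (minimum duration ≈ 4.2 h). No shallow-water transformation or
refraction is attempted, and alongshore transport capacity is reported only
as the ($H_s$, $T$, shoreline-angle) triple — no transport formula is
applied.

## Grain-size statistics

Sediment is described by percent-by-class tables over a descending ladder of
sieve diameters. Statistics follow the Folk & Ward graphical (logarithmic)
method on the phi scale ($\phi = -\log_2 d_{mm}$): a cumulative
percent-coarser curve is built at the class bounds and percentiles are
interpolated linearly in $\phi$. Then

$$M_z = \tfrac{1}{3}(\phi_{16}+\phi_{50}+\phi_{84}), \qquad
\sigma_I = \tfrac{\phi_{84}-\phi_{16}}{4} + \tfrac{\phi_{95}-\phi_5}{6.6},$$

with the standard inclusive skewness and graphical kurtosis, geometric
sorting $\sigma_G = 2^{\sigma_I}$ (unitless, 1 = perfectly sorted), and
median diameter $D_{50} = 2^{-\phi_{50}}$ mm. The "normalized sorting"
metric in the site table is interpreted as $\sigma_G$, the conventional
unitless sorting measure; whether any further normalization was intended by
the original field protocol is not recoverable, so this interpretation is
stated prominently rather than guessed around. Percent sand sums classes
inside the Wentworth window 0.0625–2 mm, with straddling classes
contributing pro-rata by their $\phi$-linear fraction. Open-ended extreme
classes are closed one phi unit beyond the outer bound before any
computation.

## Community statistics

The multivariate and univariate treatment comparisons are implemented
in-package as permutation procedures:

* abundance transforms ($\ln(x+1)$ for supratidal invertebrates,
  $\sqrt{x}$ for low-shore biota) after removing taxa that never reach 3%
  relative abundance in any single sample;
* Bray–Curtis dissimilarity
  $d_{ik} = \sum_j |x_{ij}-x_{kj}| / \sum_j (x_{ij}+x_{kj})$, with two
  all-zero samples assigned distance 0 by convention;
* one-way PERMANOVA: with squared distances,
  $SS_T = \sum_{i<k} d_{ik}^2/N$,
  $SS_W = \sum_g \sum_{i<k \in g} d_{ik}^2/n_g$, and
  pseudo-$F = \frac{(SS_T-SS_W)/(a-1)}{SS_W/(N-a)}$, with
  $p = (1 + \#\{F_{perm} \ge F_{obs}\})/(1 + n_{perm})$;
* pairwise PERMANOVA per treatment pair, reporting unadjusted and
  Holm-adjusted p-values (the adjustment family is a package choice; the
  unadjusted values are always reported alongside);
* a Pearson chi-squared independence test (no continuity correction) for
  the feeding/not-feeding by treatment contingency table;
* a stratified permutation test on univariate site metrics
  (difference of treatment means, labels permuted within strata,
  Holm-adjusted across the six pairs) as the package's nonparametric
  substitute for mixed-model marginal-means contrasts, which are out of
  scope here.

Region is handled as permutation *strata*: labels are shuffled only within
regions, the standard restricted-permutation analogue of a region random
effect. A practical consequence worth knowing: with five regions of one
site per treatment, a two-group restricted null has only $2^5 = 32$
relabelings, so the smallest achievable two-sided p-value is 1/16. Pairwise
significance at $\alpha = 0.05$ under full restriction therefore needs more
replication than one site per cell; the global four-group test does not
suffer this (the within-region relabeling space is $24^5$). Default
$n_{perm}$ is 9999 for analyses (the package's tests use smaller values,
99–999, chosen to keep the suite fast while leaving the p-value grid fine
enough for the assertions made). For $N \le 8$ an exhaustive-enumeration
mode computes the exact permutation p-value.

## The synthetic generator

No raw field records ship with the package; `simulate_sites()` generates
them with the hierarchical structure the analysis assumes, so every
pipeline stage is testable end to end.

* Site-level expected metric = treatment target mean (default: the packaged
  reference table) + a mean-zero normal region effect with SD equal to
  `region_sd` (default 0.12) times the metric's mean magnitude. Structural
  zeros (e.g. no logs at `RestoreLow`) stay exactly zero.
* Replicate-level draws mirror the families a field analyst would fit:
  logit-normal for bounded percentages (median-parameterised), negative
  binomial for counts (variance $\mu + \text{dispersion}\,\mu^2$),
  truncated normal for continuous positive quantities, binomial feeding
  events, multinomial assemblage composition with per-treatment taxon
  profiles (the `RestoreLow` fallout profile is dominated by non-flying
  arthropods — mites and springtails — so that over 80% of its individuals
  are non-flying, versus insect-dominated profiles elsewhere).
* Replicate counts default to the field protocol: 10 wrack quadrats, 5
  log-line points, 7 fallout traps, 10 low-shore quadrats, 4 snorkel
  transects in each of two seasons.
* Elevation profiles are piecewise linear and constructed so that the
  derived encroachment, slope and width equal the site's expected values
  exactly (optional seeded vertical jitter); infeasible geometries (toe at
  or below MLLW/MSL) are refused.
* Grain-size tables are phi-normal distributions discretized to a half-phi
  ladder (256–0.0625 mm) and tuned by Nelder–Mead so the recovered
  $\sigma_G$ is within 10% and percent sand within 5 points of target;
  unattainable targets raise a diagnostic error. Finite class widths impose
  a sorting floor of about 1.2 on this ladder, so targets are clamped to
  1.25 — "well sorted" is representable, "perfectly sorted" is not.
* Wind/fetch inputs are placed by inverting the fetch-limited growth law so
  the hindcast wave height equals the site's expected value.

At zero noise (`region_sd = cv = logit_sd = dispersion = 0`) every draw
collapses to a deterministic expected-value allocation: counts become
integers summing to `round(n * mu)` per site (and, for site-level counts
such as fallen trees, per treatment across its five sites). This keeps the
records schema-valid integers while making exact parameter recovery
possible: with enlarged replicate counts (20 wrack quadrats, 600 log
points, 50 traps and quadrats, 1200 transects per season — sizes chosen so
integer-allocation error is below 1% of the smallest nonzero target) the
aggregated treatment means recover the configured table to within 1% and
the scale bar reproduces the reference scores. All randomness flows from a
single integer seed; fixed-seed reruns are byte-identical.

What the generator does **not** emulate: spatial or temporal
autocorrelation, within-region treatment placement effects, taxonomic
misidentification, observer effects, and any dependence among metrics
beyond their shared region effect. Passing recovery tests therefore show
that the *pipeline arithmetic* is faithful, not that real surveys would
produce these distributions. Within-site variances in the wild are
unpublished; the default noise levels (`cv = 0.25`, `logit_sd = 0.4`,
`dispersion = 0.5`) are order-of-magnitude choices exposed in the
configuration.

The table of reference treatment means ships as a plain CSV fixture and is
also accepted directly by `scale_bar()` as a pre-averaged table, so the
headline scores can be reproduced without simulation.

## Known limitations and open interpretation points

* The reference table's juvenile-salmon feeding percentage row (5.9, 0,
  28.6, 50) is not arithmetically consistent with the feeding contingency
  counts carried alongside it (1/16, 0/7, 4/10, 6/12); the counts are
  treated as authoritative for the chi-squared test and the percentage row
  is kept as-is in the metric table. The Pearson statistic on those counts
  is 10.69 (df 3, p ≈ 0.014).
* Treatment-level wave heights cannot be reproduced exactly without
  per-site fetch maps; the generator instead solves fetch from the target
  height, which keeps the hindcast round-trip exact by construction.
* The toe is an input; no slope-break detection is attempted.
* "Total fish" and the group-specific fish densities are carried as
  independent metrics; no additivity is imposed between them.
* Fish seasons are averaged into one site value for the metric table; raw
  seasonal records are retained for the statistics.
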