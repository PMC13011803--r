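---
title: "Methods: linking microbial community dynamics to DOM molecular composition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking microbial community dynamics to DOM molecular composition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domlink)
```

# The problem

Heterotrophic bacteria rework dissolved organic matter (DOM), consuming some
molecular species and producing others. Ultrahigh-resolution mass
spectrometry resolves DOM into thousands of molecular formulae, and amplicon
sequencing resolves the bacterial community into relative species
abundances. `domlink` implements the statistical machinery for coupling the
two in a bottle-incubation design: several DOM sources, each inoculated with
the same small community, sampled in triplicate over a few weeks. The
package covers four layers:

1. **Formula chemistry** — annotating CHNOSP formulae with van Krevelen
   metrics and putative compound classes, and summarizing samples by
   intensity-weighted bulk descriptors.
2. **Distance-based community ecology** — Bray–Curtis, PCoA, PERMANOVA,
   vector fitting, Procrustes/PROTEST and dbRDA, implemented from first
   principles.
3. **Correlation screens** — formula-by-time and species-by-formula Spearman
   correlations with dataset-wide percentile thresholds, compound-class
   enrichment via exact multinomial and binomial tests, and joint
   species-and-time depletion counts read as putative resource use.
4. **A consumer–resource microcosm simulator** with planted
   consumption/production links, which stands in for deposited experimental
   data and gives every screen a ground truth to be validated against.

# Formula chemistry

For a neutral formula $\mathrm{C}_c\mathrm{H}_h\mathrm{N}_n\mathrm{O}_o
\mathrm{S}_s\mathrm{P}_p$ the package computes the saturation ratio
$\mathrm{H/C} = h/c$, the oxidation ratio $\mathrm{O/C} = o/c$, the neutral
monoisotopic mass, and the modified aromaticity index

$$\mathrm{AI_{mod}} \;=\; \frac{1 + c - \tfrac{1}{2}o - s - \tfrac{1}{2}(n + h)}
{c - \tfrac{1}{2}o - s - n - p},$$

the standard DOM-aromaticity score in which half the oxygen is treated as
carbonyl-bound. Values are reported on $[0,1]$: a negative numerator or a
non-positive denominator yields 0 (no aromatic character attributable), and
the rare raw values above 1 (possible at extreme stoichiometries such as
$\mathrm{C}_{10}\mathrm{H}_1$) are capped at 1 so the index keeps its
interpretation as a degree of aromaticity.

A formula is **biolabile** when $\mathrm{H/C} \ge 1.5$ (the cutoff is a
configuration knob; the boundary itself counts as biolabile). Compound
classes are assigned by rectangles in the (H/C, O/C) plane — lipid-,
protein-, amino sugar-, carbohydrate-, unsaturated hydrocarbon-, lignin-,
tannin- and condensed aromatic-like, applied in that precedence order with
`unassigned` as the fallback. Published class schemes differ in their exact
boundaries; the table in `vk_class_table()` is a conventional scheme chosen
for unambiguous, testable edges, and can be overridden wholesale.

Peak tables are TIC-normalized (each sample divided by its own total, an
idempotent operation), then passed through the **replicate presence
filter**: within each (source, day) group a formula is kept only when it is
present (intensity > 0) in at least 2 of 3 replicate bottles, otherwise it
is zeroed for the whole group; columns are re-normalized afterwards. Bulk
descriptors per sample are intensity-weighted means of H/C, O/C,
$\mathrm{AI_{mod}}$ and mass, plus the summed relative intensity of
biolabile formulae and of each compound class. Because the weights sum to
one, every weighted mean is a convex combination of per-formula values —
a property the test suite checks directly.

# Distance-based community analyses

All multivariate machinery is written against the dissimilarity matrix
itself:

* **Bray–Curtis**: $d_{ij} = \sum_k |x_{ik} - x_{jk}| / \sum_k (x_{ik} +
  x_{jk})$, bounded in $[0,1]$ for compositional profiles.
* **PCoA**: Gower double-centering of $-d^2/2$ followed by an
  eigendecomposition; axes are scaled by $\sqrt{\lambda}$. Bray–Curtis is
  not generally Euclidean-embeddable, so negative eigenvalues can occur;
  they are counted, warned about, and excluded from the
  variance-explained denominator, with no Lingoes/Cailliez correction
  (matching the uncorrected axis percentages practitioners usually report).
* **PERMANOVA** in the McArdle–Anderson form: with $G$ the Gower-centered
  matrix and $H$ the hat matrix of the model,
  $F = [\mathrm{tr}(HGH)/q] \,/\, [\mathrm{tr}((I-H)G(I-H))/(n-q-1)]$ and
  $R^2 = \mathrm{tr}(HGH)/\mathrm{tr}(G)$. Terms are assessed sequentially
  in formula order. The permutation p-value uses the add-one convention
  $(1 + \#\{F^\ast \ge F\})/(1 + n_\mathrm{perm})$, so it can never fall
  below $1/(n_\mathrm{perm}+1)$; ties are counted with a $10^{-12}$
  tolerance so exchangeable data give $p = 1$. Permutations are
  unrestricted by default; a `strata` argument supports repeated-measures
  designs.
* **Vector fitting**: each candidate variable is regressed on the first two
  axis scores; the arrow is the unit coefficient vector, $r^2$ the
  regression fit, and significance comes from permuting the variable.
* **Procrustes/PROTEST**: both configurations are centered and scaled to
  unit sum of squares (symmetric scaling), the rotation comes from the SVD
  of the cross-product, and $m^2 = 1 - (\sum_i \sigma_i)^2 \in [0,1]$ with
  $r_\mathrm{PROTEST} = \sqrt{1 - m^2}$; the narrower configuration is
  zero-padded. Significance permutes the row order of one configuration.
* **dbRDA** re-uses the PERMANOVA engine with one constrained block of
  numeric predictors, so $R^2$ is the constrained inertia fraction. For the
  question "does DOM composition explain community composition" the
  predictor block is the DOM PCoA axes cumulatively covering at least 90%
  of positive inertia (`pcoa_predictors()`); the coverage target is a
  configuration knob, since the choice of predictor parameterization is
  not canonical.

The test suite pins each of these against an independent route: the direct
group-sum one-factor PERMANOVA formula, `vegan::adonis2`, `vegan::vegdist`,
`stats::cmdscale`, `vegan::procrustes`, and null-calibration simulations.

# Correlation screens and enrichment

Spearman correlations are computed as Pearson correlations of midranks, so
tied values (including the repeated day values when replicate bottles are
pooled) are handled exactly; constant series are flagged undefined and
excluded rather than propagated as NaN. Replicates are pooled per source
(12 points for 3 replicates x 4 days) rather than averaged: midranks absorb
the repeated x-values naturally, and pooling keeps replicate-level noise in
the null. Only formulae present in at least 2 replicates at *every* time
point of a source enter the time screen.

Selection thresholds are **realized percentiles**, i.e. order statistics of
the pooled correlations in scope: the two-sided "top 5%" rule takes the
$\lceil 0.05 N \rceil$-th largest $|\rho|$ as the cutoff and keeps every
correlation at or beyond it (ties kept); the one-sided "strongest 2.5%
negative" rule takes the $\lceil 0.025 N \rceil$-th smallest signed $\rho$.
Cutoffs are always recomputed from the data at hand — fixed published
cutoffs are themselves realized percentiles of a particular dataset — and
the scope defaults to dataset-wide pooling.

Class enrichment uses a three-category exact multinomial null per (source,
class): with selection fraction $f$, a tested formula is
selected-positive, selected-negative, or unselected with probabilities
$(f/2,\, f/2,\, 1-f)$ — the equal-split null. The exact p-value sums the
probabilities of all outcomes no more probable than the observed one (full
enumeration up to 60 counts, a seeded $10^5$-draw Monte-Carlo estimate
above, flagged in the result). Classes with a multinomial deviation at
$\alpha = 0.05$ get post hoc one-sided binomial tests of each direction
against $\mathrm{Bin}(n, f/2)$, which set the verdict (preferentially
consumed / produced / both). No multiplicity correction is applied by
default, mirroring common practice of reporting raw $P < .05$ decisions
for this screen; a Benjamini–Hochberg switch exists. A two-category
variant (positive vs negative among selected only) is available, but the
three-category model is the default because it is the one that makes the
multinomial + post hoc binomial pairing coherent.

The species screen correlates each species with every formula per source,
takes the strongest 2.5% of negative correlations over the full signed,
pooled distribution as putative resource use, and summarizes proportions of
used formulae per (species, source, class) cell. Positive species-formula
correlations are tabulated but draw no verdict. `joint_depletion()`
intersects these links with the time-declining formula set. The natural
follow-up — do species differ in resource use? — is answered by a stratified
permutation test (`species_difference_test()`): the statistic is the
between-species variance of cell-averaged proportions, and the null
shuffles species labels within each (class, source) stratum, preserving
every cell's denominator. This deliberately replaces a binomial mixed
model with a permutation test of the same scientific question.

# The synthetic microcosm

`simulate_microcosm()` emulates the incubation design: 7 DOM sources in
three lability groups (one fresh-labile leachate; three worked-labile lake
and river sources rich in lignin-like formulae; three recalcitrant sources
rich in tannin- and condensed aromatic-like formulae), 3 replicate bottles,
sampling days 1/4/7/14, 6 species, and ~500 formulae per source drawn from
a pool with a shared core (40%) plus source-specific unique sets, so every
compound class is populated and sources overlap only partially.

Dynamics are intentionally simple — the goal is planted monotone signals
with controllable noise, which is exactly what a rank-correlation screen
can detect, not a mechanistic chemostat. Between consecutive sampled days
(step $\Delta t$ = the gap in days):

* a consumed formula's raw intensity is multiplied by
  $1 - r\,\Delta t\,a_s(t)$, clipped at zero with a warning ($r$ the link
  rate, $a_s$ the consumer's relative abundance);
* a produced formula gains the mirror factor $1 + r\,\Delta t\,a_s(t)$;
* each species then grows in a replicator update by `growth_yield` times
  its summed consumption flux, with per-step lognormal **process noise**
  (sd 0.12) so each replicate bottle follows its own community trajectory,
  as real replicate incubations do;
* sampled profiles receive mean-preserving multiplicative lognormal
  measurement noise ($\sigma^2 = \ln(1+\mathrm{CV}^2)$, $\mu = -\sigma^2/2$;
  CV 0.05 for intensities, 0.10 for amplicon-derived abundances), then
  **detection-limit dropout**: a formula is recorded as zero with
  probability $p_0 \min\{1, (q_{25}/x)^2\}$, where $q_{25}$ is the lower
  quartile of the sample's nonzero intensities — rare peaks drop out at
  rate $\ge p_0$, abundant peaks essentially never do, which is how
  presence/absence behaves in real peak tables and gives the replicate
  presence filter real work;
* every sample is closed to sum 1.

Planted structure: each source has a single consuming species — the
bioavailable-specialist on its fresh-labile home source, otherwise one
generalist — whose links are concentrated in one small labile target class
(7 formulae; rotation lipid-/amino sugar-/carbohydrate-like). One
generalist is the **broadest linked**: it is the main consumer on two
sources with two lean labile classes each at 1.7x density. Four
lignin-/condensed aromatic-like formulae per source carry production links.
A single consumer per source keeps the planted truth identifiable by rank
screens: in a replicator with closure every grower is monotone increasing,
so two growers on one source would be rank-indistinguishable as consumers
of the same declining resources.

`labile_preset()` raises `consumed_intensity_boost` to 20, emulating a
fresh leachate whose biolabile target compounds dominate the intensity
budget; their depletion is then visible in the bulk descriptors (weighted
H/C falls day over day, the summed intensity of less-bioavailable classes
rises). At the default boost of 1 the consumed mass share is small, which
keeps the compositional drift of unconsumed formulae below the measurement
noise — the regime in which the correlation screens are well calibrated.

## What passing tests do and do not show

The simulator provides monotone planted signals, compositional closure,
replicate-level structure, class-structured libraries and detection-limit
dropout. It does **not** emulate: mass-measurement error or formula
misassignment, isotopes and adducts, sequencing depth or 16S copy-number
effects, non-monotone successional dynamics, cross-feeding chains, or
environmental covariates. Recovery results on the simulator therefore
demonstrate that the screens detect what they are designed to detect under
controlled noise; they do not certify performance on real incubation data,
where effect shapes are richer and noise is structured.

Two honest structural observations, visible in the package's own outputs:

* The percentile screens select a fixed quota (e.g. 2.5% of ~21,000
  species-formula pairs), while the planted truth occupies well under 1% —
  so most selections are necessarily noise in *any* parameterization. The
  per-species mean use proportions sit close to the selection fraction,
  and the broadest generalist tops the ranking in expectation but not in
  every random realization; the corresponding regression test averages
  over seeds.
* `species_difference_test()` conditions on the observed cell proportions;
  because each species' noise captures trade off against its true links
  under a fixed quota, the observed between-species variance can fall
  below the exchangeable null at default noise, making the global test
  conservative there. It has clear power when density differences are
  large (the 10x-density case in the tests).

# Numerical and design choices

* Permutation p-values: add-one convention everywhere; comparisons with a
  $10^{-12}$ tolerance so exact ties count.
* Exact multinomial: enumeration limit 60 total counts (1891 outcomes at
  $k=3$); Monte-Carlo above with $10^5$ seeded draws; outcome probabilities
  compared with a $1+10^{-7}$ relative tolerance, the usual guard against
  floating-point misordering in small-probability orderings.
* Degenerate inputs: all-zero samples are an error in TIC normalization; a
  distance matrix with no variation yields $p = 1$ with a warning;
  constant correlation series are excluded, not NaN-propagated; an empty
  resource-use selection returns a zero profile with a warning.
* The day grid validates against {1, 4, 7, 14} by default and is
  overridable; all randomness flows from one root seed through fixed
  per-stage offsets, and every stochastic result records its seed.
* Problem sizes used by the test and acceptance runs (chosen to exercise
  the full design at desk scale): the default simulated experiment
  (7 sources x 3 replicates x 4 days, 500 formulae per source), 20-seed
  recovery ensembles, 1000 PERMANOVA null simulations at 199 permutations,
  200 link-free enrichment simulations, and 300-sample oracle sweeps.

# Known limitations

* The van Krevelen class table is a documented stand-in for supplementary
  published boundaries; results at class level depend on it, which is why
  it is override-able and version-pinned in code.
* Bulk metrics treat the `unassigned` class like any other; no attempt is
  made to redistribute unassigned mass.
* The dbRDA predictor parameterization (axes to 90% of positive inertia)
  is one reasonable convention among several.
* The simulator's replicator dynamics cannot express non-monotone resource
  trajectories (e.g. transient intermediates of cross-feeding); screens
  that rely on monotone ranks would miss such compounds on real data too.
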