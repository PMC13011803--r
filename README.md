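# domlink

Links microbial community dynamics to the molecular composition of
dissolved organic matter (DOM) in incubation experiments. The intended
user has two tables from the same bottles — molecular formulae with
per-sample peak intensities (FT-MS) and species relative abundances
(amplicon sequencing) — plus sample metadata (DOM source, replicate, day),
and wants to know which compound classes the community consumes or
produces, and which species use which resources.

## What it computes

**Formula chemistry.** Each CHNOSP formula gets its van Krevelen
coordinates (H/C, O/C), neutral monoisotopic mass, the modified
aromaticity index

    AI_mod = (1 + C - O/2 - S - (N + H)/2) / (C - O/2 - S - N - P),

a putative compound class from a rectangle scheme in the (H/C, O/C) plane,
and a biolability flag (H/C >= 1.5). Samples are TIC-normalized, passed
through a 2-of-3 replicate presence filter, and summarized by
intensity-weighted bulk descriptors.

**Community ecology from first principles.** Bray–Curtis dissimilarity
`d_ij = Σ|x_i − x_j| / Σ(x_i + x_j)`, PCoA (Gower centering, negative
eigenvalues counted and excluded from variance explained), PERMANOVA in
the McArdle–Anderson trace form `F = [tr(HGH)/q] / [tr((I−H)G(I−H))/(n−q−1)]`
with add-one permutation p-values, envfit-style vector fitting, symmetric
Procrustes with PROTEST (`m² = 1 − (Σσ)²`), and dbRDA (same engine, one
constrained predictor block). `vegan` is used only as an independent
cross-check in the tests.

**Correlation screens.** Midrank Spearman correlations of every formula
with time and with every species, per source, replicates pooled.
Thresholds are realized percentiles: the top 5% of |ρ| (two-sided) for the
time screen, the strongest 2.5% of negative ρ for resource use. Per
(source, class), selected counts are tested against the equal-split null
(f/2 positive, f/2 negative, 1−f unselected) with an exact multinomial
test and post hoc exact binomial tests, yielding "preferentially
consumed / produced" verdicts. Joint species-and-time depletion counts
read strong double-negatives as putative resource use; a stratified
permutation test asks whether species differ in use.

**Synthetic microcosm.** `simulate_microcosm()` generates the full paired
dataset — 7 sources in three lability groups, 3 replicate bottles with
independent trajectories, days 1/4/7/14, 6 species (a biolabile
specialist, generalists, one broadest-linked), ~500 formulae per source —
with planted consumption/production links recorded as ground truth, so
every screen can be validated end to end (`recovery_metrics()`).

## Worked example

```r
library(domlink)

sim <- simulate_microcosm(simulation_config(seed = 1))
sim$intensity
#> <intensity_matrix> 2300 features x 112 samples (normalized)
#> sources: leaf_leachate, boreal_lake, subarctic_lake, subarctic_river, ...
#> days: 1, 4, 7, 14

head(sim$annotations[, c("formula_id", "hc", "oc", "ai_mod",
                         "compound_class", "bioavailable")], 3)
#>   formula_id   hc   oc ai_mod    compound_class bioavailable
#> 1     F00001 1.56 0.44 0.0513      protein-like         TRUE
#> 2     F00002 1.00 0.90 0.1515       tannin-like        FALSE
#> 3     F00003 1.60 1.00 0.0000 carbohydrate-like         TRUE

rep <- run_pipeline(pipeline_config(seed = 1))
rep
#> <pipeline_report>
#>   DOM PERMANOVA by source: F = 5231.15, p = 0.001
#>   Procrustes m2 = 0.714 (p = 0.001); dbRDA R2 = 0.549
#>   time screen cutoff |rho| >= 0.691; 13 enrichment verdicts
#>   planted-link recovery: precision 0.91, recall 0.90
```

Reading this: bacterial and DOM composition both separate strongly by
source (PERMANOVA p = 0.001, the smallest value 999 permutations can
give); the two ordinations are coupled (Procrustes m² = 0.714, p = 0.001),
with DOM axes explaining ~55% of community dissimilarity (dbRDA); the
top-5% time screen realized a cutoff of |ρ| ≥ 0.691; and the joint
resource-use screen recovered the planted consumption links with
precision 0.91 and recall 0.90 against the simulator's ground truth.

```r
subset(rep$enrichment, verdict != "none")[1:3, ]
#>        source   compound_class n_class k_pos k_neg p_multinomial   verdict
#> 1 boreal_lake amino sugar-like      32     0    12      2.93e-11  preferentially consumed
#> 4 boreal_lake      lignin-like     168     9     0      5.67e-03  preferentially produced
#> 5 boreal_lake       lipid-like      40     2    11      2.03e-09  preferentially consumed

rep$resource_use$profile
#> <resource_use_profile> mean proportion used per species:
#> generalist_1 generalist_4 generalist_2 generalist_5   specialist generalist_3
#>       0.0318       0.0272       0.0259       0.0253       0.0240       0.0239
#> realized cutoff rho <= -0.6713
```

The planted consumed classes (amino sugar- and lipid-like on this source)
are flagged consumed; lignin-like formulae, rising under compositional
closure, are flagged produced; and the broadest-linked generalist tops the
mean resource-use ranking.

To analyse your own data instead, point `pipeline_config(input = ...)` at
the CSV interfaces (`formulae.csv`, `intensity.csv`, `metadata.csv`,
`abundance.csv`; see `?read_tables`), or call the layer functions
directly.

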