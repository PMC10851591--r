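---
title: "Quantifying intra- and extracellular DAB immunostaining: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying intra- and extracellular DAB immunostaining: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dabquant)
```

## The measurement problem

Immunohistochemistry with a DAB chromogen reports where an antibody bound,
but a brown pixel does not say *how the protein is distributed*: basement-
membrane proteins such as collagen IV can sit in the extracellular matrix
(diffuse, moderate staining density) or accumulate inside cells (punctate,
high staining density). `dabquant` turns RGB photomicrographs of
hematoxylin-counterstained, DAB-stained tissue into per-patient profiles
that separate these two compartments operationally — by staining density,
not by cell segmentation — and then groups patients by expression
phenotype.

## Stain separation and the inverted DAB map

Brightfield stains absorb light multiplicatively, so analysis happens in
optical density (OD) space where they add linearly (Beer–Lambert). Each
pixel is transformed channelwise as

$$\mathrm{OD}_c = -\log_{10}\!\frac{I_c + 1}{255},$$

with the +1 guarding against $\log 0$ at fully absorbing pixels; the
slightly negative value this produces at $I_c = 255$ is clipped to zero.
The OD vector is then unmixed with the inverse of a stain matrix whose
rows are unit-norm OD vectors for hematoxylin and DAB (the widely used
Ruifrok–Johnston H-DAB values by default; any calibrated pair can be
supplied through the project configuration). Negative unmixed
concentrations — pixels that fall below the stain plane because of noise —
are clipped to zero.

The DAB concentration map is scaled to an *inverted* 8-bit image,
`round(255 * min(c, c_max) / c_max)`, so that higher intensity means more
chromogen. `c_max` (default 2.0 OD) is deliberately a project-level
constant: using one saturation point for every image of a project is what
keeps intensities comparable between images, the same role stack-based
processing plays in an interactive workflow. Rounding is half-up
throughout; R's default round-half-even would make 8-bit values depend on
bin parity, which is hostile to bit-exact testing.

Tissue is segmented on the original RGB image: a pixel is tissue when its
channel mean falls below `tissue_threshold` (default 220 of 255). Channel
mean is used because the criterion only needs to separate near-white
empty slide from absorbing tissue.

## The dual thresholds and the 12 parameters

Two intensity cutoffs on the inverted DAB map define the compartments: the
*low* threshold delimits all specific staining, the *high* threshold the
high-density staining that is treated as intracellular. With $T$ the
tissue mask, $L$ the low-threshold mask and $H$ the high-threshold mask
($H \subseteq L \subseteq T$ by construction), the twelve per-image
parameters are the mean/mode/median intensity over $L$ and over $H$, the
area fractions $|L|/|T|$, $|H|/|T|$ and $(|L|-|H|)/|T|$, the two
tissue-normalized mean intensities (sums over $L$, resp. $H$, divided by
$|T|$), and the ratio $|H|/(|L|-|H|)$.

Conventions for degenerate inputs, fixed so that clustering always
receives finite values:

* statistics of an empty mask are 0;
* the mode is computed on the discrete 0–255 histogram, smallest value
  winning ties;
* the median of an even-sized multiset is the mean of the two central
  order statistics;
* when $|L| = |H|$ the ratio denominator is floored at one pixel and the
  row is flagged (`ratio_flagged`) rather than dropped;
* the tissue-normalized means count sub-threshold tissue pixels as 0 —
  the reading under which they measure something the masked means do not
  (staining level *and* extent together);
* an image with no detected tissue is an error, reported in the run
  manifest, never silently skipped.

Per-patient values are the arithmetic means over that patient's images
(three in a standard project). Thresholds are not estimated from data;
they are frozen in the project configuration and applied to every image,
which is the whole point of the design — the subjective step happens once,
not per image.

## Clustering and phenotype labels

The patient × 12-parameter table is z-scored per column (sample SD;
constant columns are set to 0 and flagged) because the parameters mix
8-bit intensities, fractions in [0,1] and an unbounded ratio. Both
dimensions are clustered agglomeratively with average linkage.

The default similarity is **uncentered correlation** (cosine). This was a
genuinely open choice and the one place we deviated from the obvious
default: centered Pearson correlation is invariant to shifting a
patient's whole profile, so a patient with *uniformly low* values and one
with *uniformly high* values look identical to it — precisely the
distinction between the "low" and "both" phenotypes. On z-scored
features, cosine similarity keeps that level information. (Uncentered
correlation is also the historical default of the Cluster 3.0 program
whose CDT/GTR/ATR file format this package exports for Java TreeView.)
Centered Pearson and Euclidean distance remain available via the
configuration.

The patient tree is cut into `k` groups (default 4; the group count is a
parameter, not a constant of nature), renumbered in dendrogram leaf order
for reproducibility. Each group is labeled by a rule on the group means
of two discriminating z-scored parameters: elevated
`intra_extra_ratio` alone → *intracellular*; elevated `pct_area_extra`
alone → *extracellular*; both elevated → *both*; neither → *low*.
"Elevated" means exceeding `tau` (default 0.5 z-units), a deliberately
mild cutoff: group means of well-separated clusters sit far from zero,
while an indifferent group hovers near it.

## Group statistics

Between-group comparisons use the classical tools: pooled-variance
two-sided Student's t-test (Welch by flag), one-way ANOVA followed by all
pairwise pooled t-tests with Bonferroni multiplication capped at 1, and
Pearson correlation matrices on pairwise-complete observations with
|r| > 0.7 flagged. Zero-variance degeneracies have fixed conventions
(equal means → p = 1; unequal means with zero variance → p = 0, flagged).

The postnatal-age stratification crosses the phenotype pairs (groups 1∪2 =
low-intracellular, groups 3∪4 = high-intracellular) with postnatal age at
death: A/B for death before day 1, C/D for days 1–7. Day 1 and day 7
belong to the 1–7-day bin; unknown ages and deaths after day 7 are
excluded (recorded as such, still present in the output). The planned
contrast is gestational age in C vs D.

Cohort summaries round percentages half-up to the precision clinical
tables print: whole percent for sex and maturity, one decimal for
postnatal-age bins and treatment rates, over the non-missing total of
each variable.

## The synthetic cohort generator

Because the pipeline's validity cannot be demonstrated on unavailable
autopsy material, the package ships a forward model that generates
hematoxylin+DAB lung-like images *with exact ground truth*, and the test
suite measures the pipeline against that truth.

A tissue mask is a smoothed Gaussian random field thresholded at the
porosity quantile (default porosity 0.45 → 55 % tissue coverage, the lacy
look of sectioned parenchyma at the default correlation length of 6 px).
Extracellular staining is a smooth blob field covering a requested
fraction of tissue; intracellular staining is cell-scale disks (radius
3–8 px) dropped inside tissue. Both placements are trimmed to the target
pixel count, so recorded ground-truth fractions are exact. Rendering
applies the Beer–Lambert forward model with the same stain matrix the
detection stage inverts, adds optional Gaussian OD noise (default SD
0.05), and converts to 8-bit as `round(255 * 10^-OD) - 1`. The −1 offset
is the exact counterpart of the +1 guard in the OD transform: with it, a
noise-free render/unmix round trip is limited only by 8-bit quantization
(measured worst error ≈ 0.003 OD; without the offset the bias reaches
0.027 OD at OD 1.2, which would swamp any downstream claim of accuracy).

Four archetypes mirror the phenotypes the pipeline must separate, with
stain fractions (extracellular of tissue / intracellular of tissue):
extracellular 0.40/0.03, low 0.06/0.01, intracellular 0.05/0.09, both
0.30/0.42, shared ODs (hematoxylin 0.4, extracellular DAB 0.6,
intracellular DAB 1.2). These values were fixed by a design-time z-score
analysis: they place each archetype on the correct side of the phenotype
rule with ≥ 0.1 z-units of margin after standardization, the analogue of
the separation visible between the four observed patient groups. Each
patient's three images jitter the fractions by ±10 % relative, so
per-patient averaging is doing real work. Each patient also carries a DAB
density multiplier (archetype means 0.9–1.2, log-normal jitter SD 0.04):
in real cohorts staining intensity covaries with stained area (observed
pairwise correlations above 0.7 between the area and intensity
parameters), and without this the six intensity parameters would be
constant up to quantization noise — z-scoring would then amplify that
noise to unit variance and clustering would split on it.

Synthetic clinical covariates follow the structure of a neonatal autopsy
cohort: GA ~ N(29, 2.5²) weeks truncated to [21, 41]; birth weight
increasing with GA; postnatal age drawn from three bins (36.5 % / 41 % /
22.5 % for < 1 day, 1–7 days, > 7 days); 37 % female; steroid-treatment
rates 14.8 % / 6.1 %. The within-stratum GA spread of 2.5 weeks reflects
the relative homogeneity of cause-of-death strata rather than the full
cohort range. An optional planted effect shifts GA (default −3.5 weeks)
for high-intracellular patients dying on days 1–7, so power to detect the
postnatal-age-dependent association can be measured; at 20 patients per
archetype the C-vs-D t-test detects it in ≈ 94 % of seeds, and in ≈ 3–5 %
under a zero effect.

What the generator does *not* emulate — and therefore what passing tests
do not show about real data: chromatic aberration and uneven
illumination, partial-volume mixing at compartment boundaries, true cell
geometry (intracellular staining is density-defined disks, matching the
operational definition, not biology), scanner-specific color response,
and any misfit between the assumed and actual stain vectors. Equivalence
with any specific interactive analysis of real slides is a structural
claim, not a pixel-level one.

## Problem sizes and numerical choices

Default synthetic images are 160×160 px (96×96 or 128×128 where a test
needs less), chosen so that a planted fraction of 0.01 still spans
hundreds of pixels while whole-cohort experiments (4 archetypes × 20
patients × 3 images × 20 seeds) remain comfortable on a single core.
Thresholds calibrated to the simulator ODs sit halfway between the class
levels (low = 38, high = 115 on the 8-bit scale at `c_max` 2.0), several
noise standard deviations from either class. All generation flows from
one integer seed; identical seeds give bit-identical images, tables and
trees. Agglomeration ties are resolved by `stats::hclust`'s deterministic
ordering, and group numbering follows dendrogram leaf order, so permuting
input rows changes labels but not the partition.

## Known limitations

* The stain matrix is assumed, not estimated from the slide; a
  miscalibrated matrix biases DAB concentrations and thus every
  downstream parameter. `separate_stains` accepts any calibrated model.
* The tissue criterion (channel-mean threshold) will misclassify heavily
  stained background debris as tissue.
* The phenotype rule reads two parameters; phenotypes defined by other
  aspects of the profile would need a different rule (`tau` and the rule
  inputs are isolated in `label_phenotypes`).
* `intra_extra_ratio` is unbounded and right-skewed; with the one-pixel
  floor it is finite but can dominate its z-scored column when
  extracellular staining vanishes. The `ratio_flagged` column exists so
  such patients can be audited.
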