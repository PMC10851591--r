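# dabquant

Digital image analysis for DAB immunohistochemistry of hematoxylin-
counterstained tissue, built for studies that ask not just *how much* of a
protein is present but *where it sits*: in the extracellular matrix or
accumulated inside cells. The motivating application is basement-membrane
collagen (COL4A1) in neonatal lung autopsy material, where the balance
between diffuse extracellular staining and punctate intracellular
accumulation distinguishes patient phenotypes — but the pipeline applies to
any hematoxylin+DAB brightfield project with exported region images.

## What it computes

1. **Stain separation.** RGB pixels are converted to optical density,
   `OD_c = -log10((I_c + 1)/255)`, and unmixed with the inverse of a
   unit-norm H-DAB stain matrix (Ruifrok–Johnston vectors by default).
   The DAB channel becomes an inverted 8-bit map,
   `round(255 · min(c, c_max)/c_max)`, so brighter = more chromogen;
   tissue is segmented by a channel-mean threshold on the original image.
2. **Dual-threshold quantification.** A project-wide *low* threshold
   delimits total specific staining (mask `L`), a *high* threshold the
   high-density staining treated operationally as intracellular (`H`),
   inside the tissue mask `T`. Twelve parameters per image: mean/mode/
   median intensity over `L` and `H`; area fractions `|L|/|T|`, `|H|/|T|`,
   `(|L|-|H|)/|T|`; tissue-normalized mean intensities; and the
   intracellular/extracellular area ratio `|H|/(|L|-|H|)`. Per-patient
   values are means over three images.
3. **Phenotype clustering.** The patients × 12 matrix is z-scored and
   clustered in both dimensions (uncentered correlation, average linkage),
   cut into k groups (default 4), each labeled extracellular / low /
   intracellular / both from its z-profile. Results export as
   CDT/GTR/ATR files for Java TreeView.
4. **Cohort statistics.** Pearson correlation matrices with |r| > 0.7
   flags, pooled t-tests, one-way ANOVA with Bonferroni-corrected pairwise
   comparisons, postnatal-age stratification (groups A–D: phenotype pair ×
   death before day 1 vs days 1–7), and demographic summaries at printed
   precision.
5. **Synthetic cohorts.** A seed-reproducible generator renders
   hematoxylin+DAB lung-like images from four staining archetypes with
   exact ground-truth masks, so every stage above is verifiable without
   the original autopsy material.

## Worked example

Simulate a small cohort, quantify it, cluster it, and stratify:

```r
library(dabquant)

dir <- tempfile(); img_dir <- file.path(dir, "images")
co <- generate_cohort(n_per_archetype = 5, seed = 1, dir = img_dir)

cfg <- default_config()
cfg$image_dir    <- img_dir
cfg$clinical_path <- file.path(img_dir, "clinical.tsv")
cfg$output_dir   <- file.path(dir, "out")

res <- run_all(cfg)
table(res$cluster$assignments$phenotype)
#>
#>          both extracellular intracellular           low
#>             5             5             5             5

res$quantify$patient_features[1, c("patient", "pct_area_total",
                                   "pct_area_intra", "intra_extra_ratio")]
#>   patient pct_area_total pct_area_intra intra_extra_ratio
#> 1    P001      0.3958119      0.0304025        0.08321352
```

Patient `P001` belongs to the extracellular archetype: ~40 % of its tissue
is stained but only ~3 % at high density, giving a low
intracellular/extracellular ratio — exactly the profile the clustering
labels "extracellular". The printed `groups.tsv`, `clustered.cdt/.gtr/.atr`
and `statistics.txt` land in `cfg$output_dir`. A thin command-line wrapper
with `simulate / quantify / cluster / stats / all` subcommands is installed
at `inst/scripts/dabquant.R`.

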