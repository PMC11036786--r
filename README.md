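# ibsmorph

Region-wise morphometry of grey-matter density volumes through
adjacent-voxel structural patterns and the information-based similarity
(IBS) distance.

Conventional voxel-based morphometry compares intensity levels; `ibsmorph`
instead compares the *spatial arrangement* of grey matter. It is aimed at
neuroimaging researchers who work with segmented grey-matter density maps
(e.g. SPM/CAT-style outputs normalised to a common space) and an atlas
parcellation, and who want individual-level morphological similarity
networks, per-region measures of structural organisation, and the
accompanying group statistics — all runnable on synthetic phantoms without
any external data.

## The method

**Structural pattern index.** For each retained voxel *x*, its grey-matter
intensity *v<sub>x</sub>* is compared with its six face-adjacent neighbours
in the fixed order right, left, anterior, posterior, superior, inferior:

&nbsp;&nbsp;&nbsp;&nbsp;*S<sub>n</sub>* = 1 if *v<sub>x</sub>* ≥ *v<sub>n</sub>*, else 0.

The six symbols, read with the first (right) symbol as the most significant
bit, form an integer code in 0..63 — one of 64 local "words" describing the
micro-structural pattern around the voxel. The working grid carries a
one-voxel zero pad (and zeros outside the grey-matter mask) so every mask
voxel has six defined neighbours and boundary contrast is preserved.

**Information-based similarity.** A brain region is summarised by the
occurrence probabilities *p(w)* of its 64 words, ranked in descending
order (*R(w)* = 1 for the most common word). Two regions — or two groups'
average distributions — are compared with the entropy-weighted rank
distance over their *N₁₂* shared words:

&nbsp;&nbsp;&nbsp;&nbsp;*D* = (1/*N₁₂*) Σ<sub>k</sub> |*R₁*(w<sub>k</sub>) − *R₂*(w<sub>k</sub>)| · *F*(w<sub>k</sub>),

with *F*(w<sub>k</sub>) ∝ −*p₁* log *p₁* − *p₂* log *p₂* normalised so
Σ *F* = 1. *D* = 0 for identical distributions; small *D* means similar
pattern organisation. The C(90,2) = 4005 pairwise distances over a
90-region atlas form a subject's individual morphological network.

**Structural nonrandomness.** A region's organisation is scored as the
mean IBS distance between its original pattern distribution and the
distributions of 10 surrogates in which the region's intensities are
spatially shuffled (multiset preserved, arrangement destroyed). High
values indicate regular organisation, low values random-like structure.

**Statistics.** The package flags regions whose group-level dissimilarity
stands out (leave-one-out one-sample *t*, right-tailed), screens all
inter-regional pairs with independent *t*-tests at a fixed threshold,
compares nonrandomness between groups under Bonferroni correction
(0.05/90 = 5.56 × 10⁻⁴), and relates cognition (an MMSE-like score) to
regional nonrandomness via a univariate prescreen (*p* < 0.1), p-based
forward–backward stepwise selection on z-scored indices, and a final
age/sex/education-adjusted linear model.

## Worked example

Generate a labelled phantom (an ellipsoidal "brain" tiled into 6 regions:
one i.i.d. noise region, one +x gradient region, four smoothed-noise
regions), encode it, and inspect the similarity network and nonrandomness
profile:

```r
library(ibsmorph)

ph <- generate_phantom(phantom_spec(shape = c(24, 24, 24), n_regions = 6,
                                    structure = c("iid", "gradient:+x",
                                                  rep("smoothed:1", 4)),
                                    seed = 11))
pm <- compute_pattern_map(ph$volume, ph$mask)
pm
#> <pattern_map> 24 x 24 x 24 grid, 4776 coded voxels
#>   bit order (MSB first): right, left, anterior, posterior, superior, inferior

sm <- interregional_matrix(pm, ph$atlas, subject_id = "demo")
sm
#> <similarity_matrix> 6 regions, 15 region pairs, subject demo
#>   IBS distance: median 0.2225, range [0.1774, 0.2966]

nonrandomness_profile(ph$volume, mask = ph$mask, atlas = ph$atlas, seed = 11)
#> <nonrandomness_profile> 6 regions, 10 surrogates, seed 11
#>   subject region     index n_surrogates seed
#> 1    <NA>      1 0.1512670           10   11
#> 2    <NA>      2 0.2250910           10   11
#> 3    <NA>      3 0.1723278           10   11
#> ...
```

The gradient region (label 2) scores the highest nonrandomness index
(0.225): a monotone ramp is maximally regular, so shuffling its voxels
changes its pattern distribution the most. The i.i.d. region (label 1)
scores lowest (0.151) — shuffling an unstructured region reproduces, up to
rank noise among equally probable codes, the same distribution.

For file-based cohorts, `run_pipeline()` (or the CLI subcommands `encode`,
`similarity`, `randomness`, `compare`, `regress`, `simulate`, `run-all`)
reads NIfTI volumes, an atlas and a covariate table from a YAML config and
writes all maps, tables, the regression report and a provenance record.

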