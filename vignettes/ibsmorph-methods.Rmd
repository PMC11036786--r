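---
title: "Adjacent-voxel structural patterns and information-based similarity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adjacent-voxel structural patterns and information-based similarity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ibsmorph)
```

This vignette is the package's own account of the science it implements:
the model and its assumptions, the tunable parameters and their defaults,
what the synthetic phantom generator does and does not emulate, the
numerical choices made where the method description left room, and the
known limitations.

## The pattern encoding

The unit of analysis is a voxel's relation to its six face-adjacent
neighbours. For voxel $x$ with grey-matter density $v_x$ and neighbour
$n$:

$$S_n = \begin{cases} 0, & v_x < v_n \\ 1, & v_x \ge v_n \end{cases}$$

with neighbours visited in the fixed anatomical order right, left,
anterior, posterior, superior, inferior. The six binary symbols form a
code in $0..63$.

Assumptions and choices:

* **Bit order.** The symbol order is anatomically fixed, but a binary
  string needs a declared reading direction. The first listed symbol
  (right) is taken as the most significant bit, so a code reads in the
  same order the symbols are listed. The choice is recorded in every
  pattern-map sidecar so decoded patterns are interpretable; any
  consistent choice gives an equivalent (relabelled) alphabet.
* **Ties.** Exactly equal intensities code as 1 ($v_x \ge v_n$). No
  jitter is added and values are compared as stored, so the encoding is
  exactly invariant under intensity shifts and positive rescaling of
  non-negative inputs.
* **Zero padding.** The working grid is the volume with out-of-mask
  voxels set to zero plus a one-voxel zero pad on every face. Every mask
  voxel therefore has six defined neighbours, and a voxel at the
  grey-matter boundary keeps its contrast against the background rather
  than being discarded — "six intact neighbours" is read as *inside the
  padded grid*, the only reading that retains boundary information.
* **Mask rule.** Whether density maps should be thresholded before
  encoding is left open upstream; the mask is configuration
  (`mask_threshold`, default: density strictly above 0) or an explicit
  binary mask, never a hard-coded rule.
* **Axis semantics.** The encoding requires knowing which grid direction
  is "right"; inputs declare an `axis_convention` (default RAS:
  +x right, +y anterior, +z superior) and the reader announces the
  default rather than silently guessing from headers.

A useful closed form: under i.i.d. continuous intensities, a code with
$k$ one-bits has probability $k!(6-k)!/7!$ (the Beta integral
$\int_0^1 x^k (1-x)^{6-k} dx$). This holds for voxels whose seven values
are genuine i.i.d. draws — the *interior* of the mask
(`interior_mask()`). Voxels touching the zero pad always carry 1-bits on
their outward faces, a deliberate consequence of boundary preservation;
tests of the law therefore tally interior voxels only.

## The information-based similarity distance

A region is summarised by the occurrence probabilities of its 64 words,
ranked in descending probability. Two distributions are compared by

$$D = \frac{1}{N_{12}} \sum_{k=1}^{N_{12}}
      \left| R_1(w_k) - R_2(w_k) \right| F(w_k), \qquad
  F(w_k) = \frac{1}{Z}\left[ -p_1 \log p_1 - p_2 \log p_2 \right],$$

summed over the $N_{12}$ words with nonzero probability in both
distributions, with $Z$ normalising $\sum F = 1$.

Numerical choices:

* **Ranks** are integral, assigned over each distribution's own full
  support before restriction to the shared words; equal probabilities
  receive distinct consecutive ranks broken by ascending word index.
  Average ranks were rejected to keep ranks integral as in the
  definition; the deterministic tie-break makes every result
  reproducible.
* **Disjoint supports** ($N_{12} = 0$) return $D = 1$ (maximal
  dissimilarity) with a warning rather than an error, so degenerate
  regions do not abort a whole-cohort run.
* **Log base** is natural internally; $Z$ cancels the base, which the
  test suite asserts directly. $0 \log 0$ terms are 0.
* **Range.** With the $1/N_{12}$ prefactor the supremum over identical
  supports is $(N_{12}-1)/N_{12} < 1$; when supports differ, ranks from
  a larger support can exceed $N_{12}$ and the printed bound of 1 is not
  a hard ceiling. The formula is implemented exactly as defined, without
  rescaling.

## Regional and group-level similarity

Per subject, all $\binom{R}{2}$ region pairs are compared (4005 for a
90-region atlas), giving the individual morphological network. For group
comparison of a single region, the per-subject probability vectors are
averaged with **equal subject weight** and re-ranked before the distance
is taken. Pooling voxel counts instead would let subjects with larger
regions dominate; the per-subject mean matches the regression population
semantics and is the default (the averaging rule is recorded in output
metadata). Voxels labelled by the atlas but undefined in the pattern map
(outside the grey-matter mask) are excluded from tallies, and an atlas
region with no coded voxels raises an error naming the region.

## Structural nonrandomness

For one region, the analysis builds the region's bounding box with all
non-region voxels set to zero and a one-voxel zero pad (the regional
zero-padded mask), encodes it, then repeats after permuting the region's
intensities uniformly at random — 10 surrogates by default. The index is
the mean of the 10 original-vs-surrogate IBS distances.

* **Shuffle scope.** The permutation is restricted to the region's own
  voxels (a whole-mask scope is available as an option). Boundary
  treatment is identical for original and surrogate, which is what makes
  an index of exactly 0 attainable for constant regions.
* **Seeding.** One master seed; the per-(region, surrogate) stream is
  derived arithmetically, so results are independent of the order in
  which regions are processed and identical inputs give bit-identical
  indices.

**Behaviour at the i.i.d. baseline.** An unstructured region does *not*
score near zero. Under the i.i.d. law the 64 code probabilities are
exactly tied within the seven $k$-groups, so the ranks of same-$k$ codes
are scrambled between the original and any surrogate regardless of how
many voxels are tallied; the expected within-group displacement
$(g^2-1)/(3g)$ implies an asymptotic index of about $0.06$, and at a
$12^3$ region the measured value is about $0.14$ (between-group rank
mixing adds to the floor at finite sizes). The index is therefore a
*comparative* measure: constant regions score exactly 0, i.i.d. regions
score near the finite-size floor, and spatially organised regions
(gradients, smoothed fields) score strictly higher, monotonically in the
smoothing width. The acceptance suite retains the literal near-zero
expectation for the i.i.d. case and that single assertion fails by
design of the measure; the surrounding assertions (constant = 0,
gradient above i.i.d., monotone smoothness response) all hold.

## Group statistics and the cognition regression

* **Flagging dissimilar regions.** The underlying sample for the
  one-sample test on regional dissimilarities is not fully determined
  upstream; the package's default is a leave-one-out one-sample $t$:
  region $i$'s dissimilarity against the mean and SD of the remaining
  regions, right-tailed at $\alpha = 0.05$. It is reproducible,
  assumption-light, and directly expresses "significantly large
  distance"; the procedure and $\alpha$ are echoed in the output.
* **Inter-regional screen.** Pooled-variance independent $t$ per pair
  (Welch optional). The default threshold $10^{-12}$ originates from a
  large-cohort calibration and is configuration, not something the
  package re-derives; desk-scale analyses should scale it (the test
  suite uses $10^{-2}$–$10^{-6}$ at $n \le 20$ per group). Pairs with
  zero variance in both groups are reported untestable rather than
  passed.
* **Randomness comparison.** Independent $t$ per region with Bonferroni
  correction $\alpha/R$ (0.05/90 $= 5.56\times10^{-4}$ at three
  significant figures).
* **Cognition regression.** Stage 1: univariate regression of the score
  on each region's index, keep $p < 0.1$. Stage 2: z-score the kept
  indices *within the case group* (the regression population) and run
  forward–backward stepwise selection with partial-F entry $p < 0.05$
  and removal $p \ge 0.10$ — the conventional criteria of p-value-based
  stepwise routines, built here from `lm`/`add1`/`drop1` because R's
  `step()` is AIC-based. Stage 3: refit the selected model with age, sex
  and education; coefficients are reported on the z-scored index scale.
  An empty prescreen returns an empty report, not an error; aliased
  columns are dropped with a warning.

## The phantom generator

`generate_phantom()` tiles a centred ellipsoid ("brain", background 0)
into box-shaped atlas parcels and fills each with one of three
structures: `iid` (uniform noise), `gradient` (linear ramp along a
declared axis, spanning 0.1–0.9), or `smoothed:w` (uniform noise
box-filtered at half-width $w$, partially re-scaled in variance so
different widths stay comparable in level). Additive Gaussian noise
(sd 0.05 by default) is applied to every structure and intensities are
clipped to $[0,1]$. Each region draws from its own derived RNG stream,
so two specs sharing a seed produce identical fields in every region
whose declared structure matches — which is exactly how
`generate_cohort()` plants case-group effects in selected regions while
leaving all other regions bit-identical in distribution.

Cohorts add covariates (age $\sim N(72, 6^2)$, sex Bernoulli(0.5),
education $\sim N(14, 3^2)$ rounded, floored at 6 — typical ranges for an
ageing-cohort study) and an MMSE-like score
$\text{intercept} + \sum_r \beta_r z(\text{nonrandomness}_r) + \varepsilon$,
clipped to $[0, 30]$. Linking the score to *nonrandomness* rather than
raw intensity means parameter-recovery tests exercise the full pipeline.

What the phantoms do **not** emulate: cortical folding and realistic
atlas geometry (parcels are boxes, a real-atlas adapter is I/O only),
scanner noise models, partial-volume effects, and registration error.
Passing tests on phantoms demonstrate the correctness and sensitivity of
the computational chain, not clinical validity on real MRI.

## Problem sizes and runtime choices

The shipped tests and the acceptance script use sizes chosen so the
behaviour under test is actually expressed, while a full run stays in
the minutes range on one CPU: the code-law check tallies the interior of
a $32^3$ i.i.d. phantom ($\approx 10^4$ voxels, binomial 4$\sigma$);
the smoothness sweep uses $18^3$ phantoms — at $14^3$ the width-3 box
kernel nearly spans the whole ellipsoid and the response saturates
between widths 2 and 3, so the larger phantom is the smallest size at
which the three widths are cleanly distinguishable; planted-effect
recovery uses 20 subjects per group on $30^3$ grids with 12 regions; and
regression recovery uses 100 replicates of $n = 150$ subjects with 20
candidate regions, matching the planted coefficient's design
($\beta = 0.8$ on the z-scale, noise sd 0.5).

## Known limitations

* The IBS distance is rank-based: it is insensitive to probability
  differences that do not reorder words, and its i.i.d. baseline is
  nonzero (see above), so nonrandomness indices should be compared, not
  read as absolute calibrated quantities.
* Graph-theoretic network metrics on the similarity matrices and
  FDR/permutation alternatives to the fixed thresholds are out of scope.
* The pipeline assumes co-registered inputs on a shared grid; it
  validates shapes, not registration quality.
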