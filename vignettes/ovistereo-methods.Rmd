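---
title: "Stereological maturity assessment of fish ovaries: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stereological maturity assessment of fish ovaries: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ovistereo)
```

## The problem

Maturity ogives — the proportion of mature females as a function of length —
feed directly into stock-assessment models, and the length at 50% maturity
(L50) is one of their most consequential parameters. Visual (macroscopic)
maturity staging of gonads is fast but unreliable around the
immature/developing boundary. Histology resolves individual germ-cell
stages, and point-count stereology turns a histological section into
numbers: the fraction of systematically sampled points hitting a structure
estimates that structure's area fraction. `ovistereo` implements this
chain — segmentation, gridding, counting, staging, ogive — together with a
synthetic-data module that provides exact ground truth for every link.

## Point-count stereology

### Model

For a structure occupying area fraction $p$ of the germ-cell surface, a
systematic uniform random sample of $n$ points among germ-cell hits gives a
count $X$ with $\mathbb{E}[X/n] = p$. We report

$$\%GCS_i = 100 \cdot \frac{n_i}{n_{germ}}, \qquad
  n_{germ} = \sum_{i \in \text{germ}} n_i,$$

over the ten germ structures (og, po1, po2, cao, vit1–vit3, pho, ho, POF).
Atresia (`ao_alpha`, `ao_beta`), lysis areas and somatic structures (wall,
epithelium, lumen, blood vessels) are counted but excluded from the
denominator. Because the percentages share one denominator they sum to 100
exactly whenever $n_{germ} > 0$; a reading with no germ-cell point is an
error (the record is flagged and excluded from staging rather than silently
zeroed).

### Grid construction

"Equidistant points with a random starting point" is implemented as the
classical square lattice with a systematic uniform random offset: spacing
$s = \sqrt{A/n_{target}}$ for tissue area $A$ (default target 550), offset
drawn uniformly in $[0,s)^2$. The sample loci are pixel centres; points take
the label of their pixel; coordinates are 0-based (x = column, y = row). If
the realized in-mask count falls outside the contracted 500–600 range
(irregular masks), the spacing is adjusted by bisection — the count range is
the contract, the spacing is not. The offset is stored as a *fraction* of
the spacing, so the same seed yields a coherent family of grids across the
bisection. At spacing 1 with zero offset the grid enumerates every pixel and
the estimate equals the exhaustive pixel fraction exactly; the test suite
asserts this identity.

### Segmentation

Tissue is extracted from the gray-level image by thresholding (Otsu by
default, between-class variance over a 256-bin histogram; a fixed threshold
is available), keeping the largest 4-connected component and filling
enclosed holes, so the mask covers the whole cross-section including the
lumen. Connected components are computed in a small compiled routine.

### Numerical choices

* A zona pellucida annulus is counted as its oocyte's stage: the counted
  unit is the whole follicle. This is switchable
  (`annotate_points(..., zp_as_stage = FALSE)`) for sensitivity analysis.
* Points landing exactly on a structure boundary take the label of their
  pixel — there is no tie to break once loci are pixel centres.
* `replicate_composition()` re-grids a section with independent offsets to
  quantify the sampling error of a single 500–600-point reading; for a
  structure near 50% of the germ surface this error is roughly ±3
  percentage points (1 SD) — worth knowing before interpreting small
  month-to-month composition differences.

## Staging rules

The most advanced stage present (≥ 1 point by default; `min_count` guards
against annotation noise) summarises the ovary on the ordinal scale og <
po1 < po2 < cao < vit1 < vit2 < vit3 < pho < ho < POF. POF is placed at the
top as the terminal category: a post-ovulatory follicle is direct evidence
of spawning, which outranks any developmental stage still present. This is
a convention (switchable via `pof_terminal = FALSE`), not a developmental
ordering.

Two binary maturity rules are first-class because the biology supports
both: cortical alveoli formation is the first gonadotropin-dependent event
(the earliest defensible maturity marker), while vitellogenesis presence is
the operational criterion usually matched to ogive assumptions. The two
differ by about 2 cm in size at first maturity in plaice; which one a given
study used for its published L50 is often ambiguous, so `run_pipeline()`
reports both. Monotonicity (mature under the vit rule implies mature under
the cao rule) is enforced by construction and verified by exhaustive
enumeration over all $2^{10}-1$ presence patterns.

Phases A–D are assigned by precedence D > C > B > A from histological
features only. A genuine limitation: a regenerating ovary (Db) contains
only precortical stages and is indistinguishable from an immature one (A)
on germ cells alone — the discriminating features are a thick ovarian wall
and muscle bundles. Composition-only calls therefore default to A, with an
optional `wall_features` input to flip pca-only ovaries to D. Phases E
(omitted spawning) and F (abnormal) are out of scope.

## Maturity ogive

`fit_ogive()` is a maximum-likelihood logit fit of maturity on raw length
(1-cm class midpoints behind `class_midpoints = TRUE`), with
$L50 = -\hat a/\hat b$. Goodness of fit is Nagelkerke's
$R^2 = \frac{1 - \exp(2(\ell_0 - \ell_1)/n)}{1 - \exp(2\ell_0/n)}$.
The bootstrap is case (pairs) resampling with percentile 2.5/97.5
intervals — the convention of maturity-assessment packages such as SizeMat;
1000 replications by default; per-replicate L50 values are retained for
audit. Replicates that separate, fail, or yield a non-positive slope are
dropped and counted; more than 20% dropped raises a warning flag.

Complete separation (all immature fish shorter than all mature ones) is
common in small or steep datasets: the MLE then diverges, so the fit is
flagged non-converged and L50 is reported as the midpoint of the separation
gap. This is an honest, deterministic fallback, not an MLE.

## The synthetic stated world

The generator's defaults are fixed once and describe a concrete world:

* **Stage morphometry**: follicle diameters are truncated normals with the
  measured plaice means and SDs (og 14.3 ± 4.6 µm through ho 958.7 ±
  60.7 µm; zp thickness 9.2 µm at vit2, 53.81 µm at vit3, 33.1 µm at pho,
  40.4 µm at ho), truncated at mean − 3 SD with a 1 µm floor so draws are
  always positive. POF has no measured size; its 400 µm rendering default
  is plumbing, not biology.
* **Section geometry**: an elliptical ovary with a 150 µm wall, a 20 µm
  germinal epithelium, scattered blood vessels, and oocytes as
  non-overlapping discs (POF as thin open shells) at 1 px = 2 µm by
  default. Circles keep the area bookkeeping exact, which is the point:
  `truth` is recomputed by exhaustively tabulating the final label matrix.
  Discs are placed by rejection sampling; the last disc of a structure may
  be shrunk to close the remaining area deficit, trading strict
  diameter-distribution fidelity for exact composition targets (tolerance
  ±2 percentage points per structure; unreachable targets raise an error
  reporting achieved fractions). The germ area budget defaults to 45% of
  the interior: sequential random placement of non-overlapping discs jams
  near 55% coverage, so higher targets are unreachable for single-stage
  compositions.
* **Population**: n = 151 females (the study-scale sampling frame), lengths
  uniform on [14, 35] cm, true L50 = 20.6 cm. The logistic slope default
  (0.55 cm⁻¹) was calibrated once, by pilot simulation, to the stated
  target that a 151-fish bootstrap CI spans ≈ 2 cm, and then frozen.
  Mature fish draw their composition from a monthly template cycle
  (November build-up → January spawning peak with POF 38% → March
  resorption) anchored to the reported monthly composition percentages;
  immature fish carry precortical stages only. A mature fish is "caught
  spawning" (phase C profile: pho 70%, vit 14%, ho 15%, POF 1%) with
  probability 0.02 — actively spawning females are rarely landed intact.
* **GSI**: no per-phase GSI distributions are published beyond means, so
  the generator uses a configurable phase → mean-GSI profile (A 0.5%, B 4%,
  C 22%, D 3%) with lognormal individual scatter (CV 0.3) on top of a
  standard length–weight allometry ($W = 0.0085\,L^{3.05}$ g). The A/B/D
  levels are realistic choices, not claimed study values; only the C level
  (22%) matches a published mean.

What a green test does **not** establish: the generator renders flat-gray,
noise-free-to-mildly-noisy structures with ideal circular geometry. Real
slides have staining variation, folds, cutting artefacts, touching
follicles and genuinely ambiguous structures; the pipeline consumes *human*
annotations in real mode precisely because automatic recognition is out of
scope. Green stereology tests certify the estimator and its bookkeeping,
not slide reading.

## Verification strategy

* **Exact oracles**: truth-vs-pixel-count identity; exhaustive-grid
  equality; %GCS normalization; `2^10 − 1` staging patterns enumerated.
* **Independent fit oracle**: logistic MLE cross-checked against a
  hand-written iterative grid search over (intercept, slope) to 1e-4 on
  small datasets; Nagelkerke against its closed form to 1e-10.
* **Monte Carlo**: estimator unbiasedness over 200 independent offsets on
  three seeded sections (mean within 3 SE of truth per structure); L50
  recovery (median absolute error < 0.5 cm at n = 151 over 500 trials for
  true L50 ∈ {19, 20.6, 22}); 200-rep bootstrap CI coverage of the true
  L50 within 3 binomial SE of 95% over 500 trials.
* **Determinism**: identical seeds give bit-identical sections, grids,
  populations, bootstrap draws and pipeline manifests.

## Known limitations

* The annotation-CSV reader ships a configurable label-mapping table (e.g.
  the `cap` → `cao` spelling); matching any particular archive's column
  dialect is a reproduction-time configuration task.
* Phase calls from composition alone cannot separate regenerating from
  immature ovaries (see above) and do not use atresia sub-classification
  beyond carrying the labels.
* Label images are written as ASCII PGM + JSON sidecar (no TIFF library in
  the supported dependency set); grayscale output uses PNG when available.
* The open-shell POF rendering and the within-group stage splits (og/po1/
  po2 at 10/30/60 within pca; equal thirds within vit) are invented
  plumbing with no measured counterpart.
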