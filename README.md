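# ovistereo

Quantitative histology for assessing female maturity in teleost fish from
ovarian cross-sections, built around the European plaice ovary.

Assessing whether a female fish is sexually mature from the naked-eye
appearance of its gonad is notoriously unreliable — misclassification rates
of 30–50% around the immature/maturing boundary are common, and they
propagate straight into the maturity ogives used for stock management.
`ovistereo` implements the quantitative alternative: point-count
**stereology** on whole-section histology, followed by rule-based maturity
staging and **L50** estimation.

## What it computes

**Point-count stereology (Glagolev).** A square lattice with a systematic
uniform random offset is laid over the thresholded tissue area of a scanned
section, sized so that 500–600 points fall inside the mask. Each point is
assigned the single structure beneath it. For the germ-cell structures
(oogonia `og`, primary-growth `po1`/`po2`, cortical alveoli `cao`,
vitellogenic `vit1`–`vit3`, partially hydrated `pho`, hydrated `ho`,
post-ovulatory follicle `POF`), the share of points estimates the fraction
of germ-cell surface:

    %GCS_i = 100 · n_i / n_germ,   n_germ = Σ_i n_i  (germ structures only)

with `og + po1 + po2` reported as `pca` and `vit1..vit3` as `vit`.

**Staging.** The most advanced stage present (one point suffices) summarises
each ovary; a single `POF` point is evidence the fish has already spawned.
Binary maturity uses either the *vitellogenesis-presence* rule (`vit1` or
later ⇒ mature; used for the ogive) or the *cao-presence* rule (first
gonadotropin-dependent stage ⇒ mature) — the two differ by ~2 cm in size at
first maturity, so both are always reported. ICES phases A–D are assigned by
precedence: D (POF, or atresia with a regressing wall), else C
(`vit3`/`pho`/`ho`), else B (`cao`/`vit1`/`vit2`), else A.

**Biometrics.** Gonadosomatic index `GSI = 100 · W_gonad / (W_ungutted −
W_gonad)` and the nuclear/cytoplasmic ratio `N/C = d_nucleus / d_follicle`
(≈0.8 for oogonia; 0.5 separates `po1` from `po2`).

**Maturity ogive.** Maximum-likelihood logistic regression of maturity on
length, `L50 = −intercept/slope`, with a 1000-replicate case bootstrap
(percentile 2.5/97.5 CI) and Nagelkerke's R².

**Synthetic data.** Because annotated slides are bulky and hand-read, the
package ships a generator for (a) labelled ovarian sections — discs with
stage-specific diameter distributions (e.g. `og` 14.3 ± 4.6 µm up to `ho`
958.7 ± 60.7 µm), zona pellucida annuli, POF shells, wall/epithelium/lumen —
with *exact* pixel-count ground truth, and (b) fish populations whose
maturity-by-length follows a configurable logistic curve. Every stage of the
pipeline is tested against these exact truths.

## Worked example

```r
library(ovistereo)

## a spawning-phase (C) section: pho 70%, vit 14%, ho 15%, POF 1%
spec <- section_spec(width = 900, height = 700, px_per_um = 0.15,
                     composition = c(pho = 0.70, vit = 0.14, ho = 0.15, POF = 0.01),
                     seed = 2)
img  <- generate_section(spec)
gray <- render_grayscale(img, noise_sd = 6, seed = 3)
mask <- segment_tissue(gray)          # Otsu threshold + largest component
grid <- make_grid(mask, seed = 4)     # 500-600 points, random offset
est  <- estimate_composition(annotate_points(grid, img))
print(est)
#> <composition_estimate> 218 germ points / 550 total
#> %GCS: vit1 5.0, vit2 5.0, vit3 4.6, pho 68.8, ho 16.1, POF 0.5
#> aggregates: pca 0.0, vit 14.7
```

The 550-point reading recovers the section's known composition to within
binomial sampling error (truth: pho 70.0, vit 14.0, ho 15.0, POF 1.0). One
POF point is enough to call the fish spawned:

```r
most_advanced_stage(est)   # "POF"
is_mature(est)             # TRUE  (vitellogenesis-presence rule)
assign_phase(est)
#> <phase_call> phase D (rule D_pof; evidence: POF)
```

A population with known maturity structure closes the loop on the ogive:

```r
pop  <- generate_population(population_spec(seed = 5))  # n = 151, L50 = 20.6
fit  <- fit_ogive(pop$length_cm, pop$true_mature)
boot <- bootstrap_L50(pop$length_cm, pop$true_mature, reps = 1000, seed = 6)
print(fit)
#> <ogive_fit> n = 151, L50 = 19.48 cm, slope = 0.5405 per cm
#> Nagelkerke R2 = 0.652; converged: TRUE
print(boot)
#> <bootstrap_result> 1000 reps (0 dropped)
#> L50 median 19.48 cm, 95% CI [18.48, 20.45] cm
```

With only 151 fish the point estimate scatters around the true 20.6 cm with
a standard error of ~0.5 cm — exactly what the CI width says it should.

## Pipeline and CLI

`run_pipeline(config)` ties everything together (synthetic mode, or
`annotations` mode reading point-annotation + biometrics CSVs) and writes
staged records, monthly summaries, an ogive report under both maturity
rules, and a seed/config-hash manifest. `inst/cli/ovistereo` exposes the
subcommands `simulate-section`, `simulate-population`, `estimate`, `stage`,
`summarize`, `ogive`, `run`.

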