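---
title: "Methods: synthetic epidermal morphometry and surrogate-model scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic epidermal morphometry and surrogate-model scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skinmorph)
```

## What the package models

Skin-irritation testing compares human skin against surrogate models — a
reconstructed human epidermis (RHE) grown from keratinocytes, ex vivo pig
skin, and the historically used rabbit skin. One line of evidence for
choosing a surrogate is purely structural: how closely each model's
epidermal architecture (total thickness, the four strata, their relative
proportions, basal proliferation) matches human skin. `skinmorph`
implements that comparison as a reproducible pipeline and, because the
underlying slide scans of such studies are generally not shared, pairs it
with a synthetic-section generator that emulates the relevant structure
and carries exact ground truth.

The epidermis is modeled as four stacked strata — cornified, granular,
spinous, basal — over dermis, with rete-ridge undulation in human and pig
skin, a flat RHE, and a very thin (flat) rabbit epidermis.

## The synthetic-section generator

`generate_section()` renders a vertical section as an integer label
raster (row 0 at top; codes in `layer_labels()`). Per column at position
$x$ (µm), the thickness of layer $l$ is

$$ t_l(x) = m_l + A\,\frac{m_l}{\sum_k m_k}\,
   \sin\!\left(\frac{2\pi x}{P}\right) + \varepsilon_l,\qquad
   \varepsilon_l \sim N(0, (c\,m_l)^2), $$

quantized to pixels and clipped at one pixel. $m_l$ is the layer's mean
thickness, $A$ the profile's undulation amplitude, $P$ the period and $c$
the coefficient of variation. Design choices worth stating explicitly:

* **Undulation is shared across layers in proportion to their means**
  (amplitudes sum to $A$), so the whole epidermis undulates with exactly
  the configured amplitude. Applying the full amplitude to each layer
  independently would undulate the epidermis with $4A$ and drive thin
  layers into the one-pixel clip at the troughs, biasing mean thickness
  upward. With proportional shares the clip probability is negligible
  (worst case ≈ $10^{-3}$ per column for the human granular layer).
* **A single sine** stands in for irregular rete ridges. It captures the
  feature that matters for the measurement statistics — periodic
  thickness variation that integrates out over full periods — but not the
  irregularity of real ridges.
* **Noise is independent per layer**, each with sd $c\,m_l$. Summed over
  layers the epidermis consequently has a smaller coefficient of
  variation than $c$; per-field *measurement* noise at the configured
  $c$ is modeled directly by `sample_field_thicknesses()` (truncated at
  zero).
* **Ground truth is read back from the rendered pixel runs**, not from
  the analytic formula, so morphometry can be checked against it
  *exactly* (pixel-run equality, not approximate agreement).
* **Nuclei** are placed uniformly over the basal + spinous pixels
  (proliferating keratinocytes are basal/parabasal; the compartment is
  configurable only through the label filter at measurement time), with
  density 0.02 nuclei/µm² — about one nucleus per 50 µm², a realistic
  keratinocyte packing. Each nucleus is DAB (MKI67) positive
  independently with the profile's positive fraction, else hematoxylin.
* **Determinism**: each operation takes a seed and restores the RNG state
  afterwards; batch operations derive per-section child seeds. The same
  seed yields a bit-identical section.

Geometry defaults: width 400 px at 0.5 µm/px = 200 µm — exactly two
undulation periods ($P$ = 100 µm), so the discrete sine sums to zero over
the columns and the column-averaged epidermal thickness is an unbiased
estimate of $\sum_l m_l$.

## The default profile library

Total epidermal means are fixed by the reported values: 51.64 µm (human),
90.33 µm (RHE), 75.47 µm (pig); the rabbit epidermis is one third of the
human value by the documented ratio (exact division). MKI67-positive
fractions are 1.45 % (human), 8.47 % (RHE), 1.73 % (pig), 2.75 %
(rabbit). The marker panel encodes that the RHE expresses all three human
barrier markers (FLG, CLDN1, CDH1), pig skin lacks FLG, and rabbit skin
lacks all three.

Per-layer means are not individually reported anywhere, only as ratios and
ranks, so the library fixes them by construction, once, from three
simultaneous requirements:

1. each model's four layer means sum **exactly** to its epidermal mean,
   so measured total thickness recovers the configured value;
2. the documented ratios hold: RHE cornified = 2 × human, RHE granular =
   4.4 × human (">4×"), rabbit spinous = human/5, rabbit basal = human/2,
   rabbit cornified the thinnest of the four, pig cornified close to
   human;
3. the rank-similarity grid computed from the configured means reproduces
   the full reference scoring table — all 5 strata × 4 perspectives —
   not just the epidermis row.

The resulting defaults (µm):

| layer | human | keraskin | pig | rabbit |
|---|---|---|---|---|
| cornified | 15.00 | 30.00 | 16.30 | 2.893 |
| granular  |  5.00 | 22.00 | 16.50 | 4.50 |
| spinous   | 20.00 | 26.00 | 25.70 | 4.00 |
| basal     | 11.64 | 12.33 | 16.97 | 5.82 |

These satisfy all three requirements simultaneously (requirement 3 is
property-tested). One tension is acknowledged: the source figures mark
some human-vs-pig layer contrasts as non-significant, while the rank table
simultaneously places pig's granular and spinous layers closer to the RHE
than to human skin. With $c = 0.2$ and $n = 20$ the library's means make
several of those contrasts significant. The rank structure is the
quantity this package reproduces and tests; per-contrast significance
patterns are figure-only and are not calibrated. Everything is overridable
via the YAML schema (`inst/extdata/default_profiles.yaml`;
`read_profile_library()` / `write_profile_library()`).

$c$ defaults to 0.2: the source data report only mean ± SEM, so the noise
model (truncated normal, common CV) is a generator assumption, chosen as
a typical field-to-field spread for histological thickness measurements.
Undulation amplitudes (human 8 µm, pig 12 µm, RHE and rabbit 0) encode
"undulating vs flat" qualitatively; only their zero/non-zero status, not
their magnitude, affects any reproduced statistic.

## Morphometry conventions

A "field of view" is operationalized as a single image column; the field
count defaults to 20 per group, matching the reported group sizes. Columns
are sampled uniformly without replacement. Thickness is the contiguous
pixel run of the layer's label scanned bottom to top (the bottom-most run
if an imported mask carries several disjoint runs in one column);
epidermal thickness spans all four epidermal labels as one extent, and
equals the column-wise sum of the layer runs. Measurements on generated
sections equal the stored ground truth exactly, which the tests assert as
identity, not approximation. Imported masks must use the documented label
codes with 0-based pixel indexing, row 0 at top.

Summaries report mean, SEM with the $n-1$ denominator, and $n$; SEM is
`NA` (undefined), never 0, for a single measurement.

## Scoring

Deposition percentages divide each of the granular/spinous/basal means by
their sum; the cornified layer is excluded by definition (an option
includes it). Rank scores are computed from mean thicknesses only — no
variance weighting — exactly as the scoring rule prescribes; ties in the
absolute differences (measure-zero under the noise model, but possible
with hand-entered means) break by fixed model order with a warning, so
scores are always a permutation of {1, 2, 3}. Totals over the five strata
lie in [5, 15] and sum to 30 across the three comparators. The heatmap
uses a fixed model order and a monotone white→red ramp so rendered output
is reproducible.

## Proliferation

Zones are four equal-width vertical bands with half-open intervals
(zone geometry is not specified in the source; vertical bands are this
package's documented choice). The overall index is total DAB over total
nuclei — the nucleus-count-weighted mean of zone indices, which the tests
assert as an exact identity. The denominator counts all generated
(basal + spinous) nuclei.

## Statistics

The test is the classical pooled-variance Student's t-test, because that
is what the study names; Welch's correction is available behind
`var_equal = FALSE`. Degenerate zero-variance inputs return $t = 0,
p = 1$ when means agree and error otherwise. No multiple-testing
correction is applied (none is applied in the source design). Star
buckets follow the conventional GraphPad scheme, including the `***`
(p < 0.001) bucket for completeness; the source legends are inconsistent
about thresholds between figures, and the conventional scheme is used
throughout.

Type-I error calibration (two groups simulated from the same profile,
n = 20, 2000 replicates, fixed seed) is asserted at 0.05 ± 0.01 in the
test suite.

## Problem sizes and what the tests show

The recovery checks simulate 200 sections per model with 20 measured
columns each (4000 fields per model) for thickness, and pool nucleus
fields to ≥ 10,000 nuclei per model for the proliferation index —
sizes at which the Monte-Carlo standard error is comfortably below the
assertion tolerances (2 % relative for thickness means; 3 binomial SD for
the index). Property suites run 1000 random matrices against a
brute-force sorting oracle for the rank scores.

Passing these tests shows that the pipeline's operations are correct on
data matching the generator's assumptions: four ordered strata, sinusoidal
undulation, Gaussian field noise, uniform nucleus placement, binomial
MKI67 labeling. They do not show robustness to what real slides add —
irregular ridge geometry, segmentation error, staining artifacts, oblique
sectioning, nucleus clustering — none of which the generator emulates.
Real-image segmentation and stain deconvolution are out of scope by
design; the morphometry accepts imported label masks in the documented
convention as its bridge to real data.

## Known limitations

* The rabbit per-layer means beyond the documented ratios, and all
  human/pig layer means, are package defaults constrained by ranks and
  ratios, not measured values; analyses depending on their exact
  magnitudes (rather than ranks, sums or proportions) inherit that
  uncertainty.
* The similarity score has no uncertainty attached — ranks of near-tied
  means flip easily under sampling noise, as the README's worked example
  shows for measured (rather than configured) means.
* One-column fields make within-field averaging trivial; real fields
  average over a region, so the configured CV conflates field-to-field
  and within-field variability.
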