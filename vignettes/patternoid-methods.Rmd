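---
title: "Quantifying patternoid invasion: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying patternoid invasion: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patternoid)
```

## The assay and what this package computes

Patternoids are organoids grown from a controlled number of tumor cells
seeded into cylindrical collagen microcavities (100 µm diameter, 200 µm
deep, 600 µm pitch, 25 × 26 = 650 cavities per gel). Because every
patternoid starts from the same geometry, differences in how cells escape
the cavity into the surrounding matrix can be attributed to the cells'
phenotype — here, pancreatic cancer (PDAC) subtypes spanning the
epithelial–mesenchymal transition (EMT): epithelial (E-9591), hybrid
(Mlow-8028), and mesenchymal (M-16992).

The computational pipeline this package implements takes segmented binary
masks of day-3 patternoids (or grayscale stacks that it projects, denoises
and thresholds itself) and extracts five invasive parameters:

* **invasive area** — foreground area outside the cavity circle (µm²);
* **non-invasive area** — foreground inside the cavity, also reported as a
  fraction of the cavity's projected area `A = πr² ≈ 7854 µm²`;
* **maximum invasive distance** — the deepest penetration beyond the
  cavity boundary (distance from the center minus the radius; a
  center-referenced variant is available, the boundary reference is the
  default because it measures penetration into the matrix);
* **invasive roots** — distinct crossings of the cavity boundary, counted
  as 8-connected components of the mask intersected with a thin annulus on
  the boundary circle that continue outward;
* **invasive tips** — endpoints of the pruned skeleton outside the cavity;
  the **branching factor** is tips/roots, undefined (and excluded from
  cohort means, rather than set to zero) when a patternoid has no roots.

Around the morphometry sit the assay's bookkeeping and statistics:
starting-cell-number (c0) classification into ±10 % tolerance bands with
inclusive boundaries and no pre-rounding (a count of 22 belongs to class
20, 23 to none), stage-wise QC exclusion (day 0: uncountable or crowded
seeding; day 1: already invasive at drug addition; day 3: staining
failure, conjoined neighbours, planar outgrowth, collapse), pooling of
batches to identical c0-class compositions (per-class minimum across
batches, seeded sampling without replacement), exponential growth rates
`r = log(c_t/c0)/t`, and unpaired two-tailed equal-variance t-tests at
α = 0.05 with the degenerate-data conventions (zero pooled variance with
equal means gives p = 1; with unequal means it is an error).

## The synthetic-data generator

No public imaging data accompany the assay, so the package ships a
generator that produces every input the pipeline consumes, with exact
ground truth. It is first-class, tested code — the study conditions are
its defaults, and the acceptance analyses run the *measurement* pipeline
on its output rather than reading the ground truth back.

**Seeding.** Cell deposition is Poisson per cavity
(`simulate_seeding()`); day-0 overview scans with injected, labelled QC
defects are produced by `generate_overview_scan()`. The default defect
rates (25 % agglomeration, 20 % excess cells, 15 % staining failure, 15 %
conjoined, 10 % planar growth, 5 % collapse) were set once so that QC
filtering plus c0 classification retains 10–25 % of seeded cavities, the
yield range typical of the assay.

**Invasion masks.** `generate_patternoid_mask()` builds a binary mask
from explicit geometry: a filled disk (the in-cavity body, radius set by a
truncated-normal draw of the covered-area fraction) plus branch trees
anchored at well-separated boundary angles. Per mask it draws

* roots ~ round(Normal(µ, σ)) truncated at zero, with the published
  subtype means/SDs (E 7.5 ± 3.725, Mlow 4.15 ± 2.492, M 4.8 ± 1.699);
* branching factor ~ `1 + Gamma` with moments matched to (µ − 1, σ) of
  the published values (E 1.56 ± 0.507, Mlow 1.61 ± 0.530,
  M 3.15 ± 0.965). A truncated normal would shift the epithelial mean
  from 1.56 to ≈ 1.69 because the support is bounded below by 1 (every
  root carries at least one tip); the shifted-Gamma law preserves both
  printed moments exactly;
* maximum invasive distance ~ Normal with the published mesenchymal
  moments (379.7 ± 96.1 µm). The epithelial and hybrid distance means are
  not published; 120 ± 40 µm (E) and 320 ± 90 µm (Mlow) were fixed once
  to respect the subtype ordering of invasive potential.

The total tip count is `round(roots × BF)`; tips are distributed over
roots and realized as binary trees whose junctions lie on the ray of the
subset's farthest tip — monopodial growth, a radial leader shedding side
branches. This specific choice is load-bearing: centering junctions
between their tips lets the ray to a far tip run quasi-collinear past a
short sibling tip, the two strokes merge in the rasterized mask, and the
skeleton loses an endpoint. Branch widths are subtype-specific (thick
11 µm for the hybrid's collective strands, thin 5–6 µm for the
mesenchymal/epithelial protrusions).

Because the acceptance analyses compare *measured* cohort means against
the configured truth, the construction enforces measurability margins:
root anchors are confined to disjoint angular sectors sized by each
root's tip demand (so boundary crossings never merge), tip endpoints are
spaced by at least one branch width plus 12 µm, terminal segments exceed
the skeleton-pruning length with a reserve, and every tip lies at least
≈ 60–70 µm beyond the boundary. Draws the circle cannot hold (a rare
root-rich mask whose tip demand exceeds the angular budget) shed tips
from the most demanding roots; the returned ground truth is always the
realized topology. The residual systematic error of the full
generate → rasterize → skeletonize → count chain is below 1 % of the
cohort mean for every reported metric.

**Emergent quantities.** The invasive area of a geometric mask is
emergent (branch topology × width), not drawn from a distribution; the
log-normal invasive-area law in the profiles (σ matched to the published
23 971 ± 102 507 µm², whose SD > mean indicates strong right skew — a
normal law would generate negative areas) parameterizes the area-valued
dose–response cohorts instead.

**Dynamics and dose–response.** `generate_timeseries()` models the
non-invasive fraction as saturating growth
`f(t) = plateau − (plateau − f₀)e^{−rt}` (hybrid: plateau 0.40 reached by
27 h; epithelial: steepest trajectory, ≈ 0.70 at 38 h; mesenchymal
intermediate) and the invasive signal as zero before a subtype-specific
onset, rising monotonically after.
`generate_dose_response_cohort()` draws replicates around a decreasing
Hill curve with mean-preserving multiplicative log-normal noise. The Hill
coefficient defaults to 1 — no value is published — and is a free
generator parameter.

## Numerical choices

**Pixel conventions.** Pixel centers sit at integer coordinates; a pixel
belongs to a circle when its center is strictly inside. All metrics are
computed in µm after calibration, so masks at the two imaging
calibrations (0.569 and 2.27 µm/px) yield comparable results.

**Working calibration (1.135 µm/px).** Synthetic cohorts are generated
and measured at 1.135 µm/px by default. The constraint is thinning
stability, not biology: Zhang–Suen thinning deletes 2-px-wide diagonal
strokes outright, so the thinnest branch (5 µm) must span ≥ 4 px. At
coarser calibrations the generator widens strokes to ≥ 4.4 px instead and
documents the effective width; at 0.569 µm/px nothing changes but cohorts
cost ~16× the pixels.

**Skeleton operators.** Thinning is Zhang–Suen (topology-preserving,
8-connected), followed by a blunt-end cleanup (terminal triangle caps
carry no degree-1 pixel; removing pixels with crossing number 1 but
degree ≥ 2 restores a proper endpoint) and spur pruning: from each
endpoint, walk to the first *true* junction — crossing number ≥ 3, so
staircase corners are walked through, not mistaken for branch points —
and delete the path if it is shorter than `min_branch_um` (default 10 µm,
well below a cell diameter). Roots use a 2-px-wide annulus by default,
the thinnest band that still bridges a crossing at both calibrations;
crossings closer than about one annulus width merge, which is the
operator's resolution limit and is covered by a test.

**Hill fitting.** `fit_hill()` does nonlinear least squares
(Levenberg–Marquardt) on per-dose means, with EC50 on the log scale,
multi-start over an EC50 grid spanning the tested range, and `top`
parameterized as `bottom + span` with `span ≥ 0` so a decreasing fit
cannot silently invert. The Hill coefficient and the floor can each be
fixed; the recovery analyses fix h = 1 and bottom = 0 — the generating
model — because with a free floor the EC50 is poorly identified, and
systematically underestimated (by ~14 % in our simulations), when the
true EC50 lies near the top of the tested 10–2500 nM range. Linear
low-dose fits use ordinary least squares on per-dose means at
concentrations ≤ 500 nM; data above the cutoff cannot influence them.

**Longitudinal model.** `fit_longitudinal_trend()` fits
`value ~ time × subtype + (1 | replicate)` with lmerTest
(Satterthwaite p-values). Degenerate designs (one subtype, one replicate,
fewer than three timepoints) raise errors naming the deficient factor.
The interaction test holds its nominal 5 % size under the null within
Monte-Carlo error (500 simulations in the test suite).

## Problem sizes

The test suite and the acceptance script use cohorts of 200 masks per
morphometric target, 50 simulations × 7 doses × 20 replicates per EC50
recovery, 10⁴ null simulations for t-test calibration and 500 for the
mixed-model interaction — sizes at which every Monte-Carlo standard error
is far below the decision band it guards.

## What passing tests do and do not show

The generator reproduces the *statistical structure* the analysis assumes:
Poisson seeding, subtype-specific branch topology, saturating in-cavity
growth, Hill-shaped drug response. It does not simulate collagen
mechanics, protease biochemistry, cell migration, imaging point-spread,
or segmentation errors beyond additive/multiplicative noise. Passing
recovery tests therefore validate the measurement and inference chain —
that the operators measure what they claim on masks with known truth —
not the biological fidelity of any particular mask. Known limitations:
tip counting merges branches closer than one stroke width plus two
pixels (≲ 1 % of tips at the default calibration); masks are 2D
projections, as in the assay, so overlapping branches in z are
indistinguishable; and the c0 ±10 % boundary convention (inclusive,
unrounded) is one of several defensible readings of a tolerance band.
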