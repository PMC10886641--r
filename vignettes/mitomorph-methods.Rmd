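---
title: "Quantifying mitochondrial network morphology: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mitochondrial network morphology: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitomorph)
```

## The measurement problem

In adherent cells such as skin fibroblasts, mitochondria form a dynamic
tubular network (MN) that is continuously remodelled by fission and fusion.
Shifts in that balance — larger or smaller total mitochondrial area, longer
or shorter tubules, accumulation of disconnected organelles, loss of
branching — are morphological signatures of mitochondrial dysfunction, and
are studied in Parkinson's-disease patient fibroblasts carrying mutations in
mitophagy- and dynamics-related genes (PINK1, Parkin, LRRK2, α-synuclein).

`mitomorph` turns a single-cell fluorescence micrograph of a
potentiometric-dye-stained mitochondrial network (e.g. TMRM on a confocal
microscope, calibrated here at 23.4 px/µm) into six per-cell morphometric
parameters:

* **mitochondrial footprint** (µm²) — total mitochondria-positive area;
* **network branch length** (µm) — median branch length within networks;
* **individual : network ratio** — count of individual mitochondria per
  network;
* **individual length** (µm) — median length of individual mitochondria;
* **connectivity** — mean number of junctions per network;
* **aspect ratio** — median major/minor axis ratio of individual
  mitochondria (spherical, swollen organelles approach 1).

It also quantifies two functional read-outs from fluorescence time series —
the rate of ROS-probe oxidation (slope of intensity vs time) and a
membrane-potential proxy (TMRM signal collapse after the uncoupler FCCP) —
and provides the statistical layer used to compare patient lines.

## The image-analysis chain

The chain is fixed, in this order:

1. **Rolling-ball background subtraction** (`subtract_background()`, radius
   50 px). Implemented as grayscale opening with a disc structuring element:
   any feature that cannot contain the disc survives the subtraction, which
   is the classical rolling-ball background estimate and is directly
   verifiable against a brute-force opening oracle.
2. **Median filtering** (`denoise_median()`, radius 1, i.e. 3×3) to remove
   shot-noise impulses without displacing edges.
3. **CLAHE** (`enhance_clahe()`, 64-px tiles, clip limit 0.01) to lift dim
   peripheral tubules into range before a *global* threshold. The image is
   reflected to a tile multiple and cropped back, so any image size works.
   The clip limit is the standard normalized fraction (a histogram bin may
   hold at most `clip_limit × tile pixel count` before redistribution).
4. **Otsu binarization** (`binarize_otsu()`): threshold maximizing
   between-class variance on a 256-bin histogram over the bit-depth range,
   smallest argmax on ties, foreground strictly above. These conventions are
   pinned so an exhaustive-search oracle can check the result bin-for-bin.
5. **Particle analysis** (`label_components()`): 8-connected components,
   areas in px and µm², ellipse axes from second-order central moments
   (with the 1/12 pixel-integration term, so a single pixel has aspect 1).
6. **Skeletonization** (`skeletonize()`): Zhang–Suen parallel thinning plus
   three guarantees — components never vanish (a centroid pixel is restored
   if thinning erases a small blob), no 2×2 solid block survives, and
   staircase corners are canonicalized so path lengths track the geometric
   centerline.
7. **Skeleton-graph analysis** (`analyze_skeleton()`): junction pixels
   (more than 2 neighbours, 8-adjacent junction pixels merged into one
   node), endpoints (exactly 1 neighbour), branches as maximal node-to-node
   paths, with orthogonal steps counting 1 px and diagonal steps √2 px.
8. **Classification** (`classify_objects()`): a component is a *network*
   iff it has more than one branch and at least one junction, an
   *individual mitochondrion* iff exactly one branch, no junction and at
   least one endpoint. Everything else is *unclassified* with a reason —
   notably fully looped "donut" components (zero endpoints), which are
   tallied but never forced into either class.
9. **Per-cell aggregation** (`cell_morphometrics()`): length distributions
   within a cell are skewed, so per-cell summaries use medians; empty
   denominators yield `NA`, never silent zeros.

### Adjacency convention

Raw 8-connectivity over-counts: along any path that mixes orthogonal and
diagonal steps, a diagonal adjacency can "shortcut" two orthogonal steps,
giving interior pixels three neighbours and spawning phantom junctions. The
graph layer therefore ignores a diagonal link whenever one of its two
shared orthogonal corner pixels is also foreground (`skeleton_degrees()`
with `reduced = TRUE`, the default; the raw count remains available). On
clean skeletons the two definitions agree; on staircase pixels only the
reduced definition matches the drawn topology.

### Length estimation

Thinning erodes a tube's rounded end cap back toward the medial axis, so a
naive skeleton path under-measures every branch with a free end. When the
source mask is supplied (`analyze_skeleton(skel, mask = ...)`, as
`analyze_cell()` does), each endpoint-terminated branch is extended by the
overshoot of the cap boundary beyond the tube half-width. Both quantities
are measured by the same half-pixel marching procedure — ahead along a
small fan around the branch tangent, and perpendicular to the branch at
mid-path pixels for the radius — so the rasterization bias of one cancels
against the other. Junctions are localized sub-pixel as the least-squares
intersection of the incident arm axes, and arms are measured from an anchor
pixel outside the thinning-distorted junction zone straight to that point.

Short terminal spurs (default `prune_px = 6`, about one tube diameter and
below the shortest plausible mitochondrion at 23.4 px/µm) are pruned before
classification: they are cap artifacts of thinning, not branches.
Endpoint-to-endpoint components — whole small organelles — are never
pruned.

## The synthetic-data generator

The study this package accompanies deposits no raw images, so validation
rests on `generate_scene()`: synthetic micrographs with exact per-object
ground truth (class, branch lengths, junction and endpoint counts,
centerline, rasterized area).

Networks are grown as self-avoiding lattice random walks with per-step
branching (probability 0.06 per step, direction changes of ±45° with
probability 0.08 per step), with a clearance of `2·tube_radius + 8` px
between non-adjacent structures so distinct tubes never fuse after blur.
Individuals are shorter single segments (0.3–1.0 µm against network
branches of 0.8–2.5 µm, mirroring the reported ordering of per-cell
medians), optionally rendered as discs ("drops", aspect ≈ 1). Loops
("donuts") are rasterized circles, labelled `loop` in ground truth because
the two-class filter deliberately has no class for them. Deterministic
`network_shape = "Y"` or `"T"` topologies (3 branches, 1 junction) are
available for classification tests; for a T the trunk halves are each drawn
from the branch-length range so that no branch falls below it.

Rendering follows the standard fluorescence camera model: centerlines are
dilated with a disc (`tube_radius` 2 px), convolved with an isotropic
Gaussian PSF (σ 1.2 px ≈ 50 nm, a super-resolution-grade width at this
calibration), set on a constant background (level 100, object amplitude
900 on a 16-bit scale), and degraded with Poisson shot noise
(`poisson_scale` 4 intensity units/photon) plus Gaussian read noise (sd
20). These defaults give an SNR around 15–20, typical of a good confocal
acquisition; `scene_snr()` measures it against the truth mask. An optional
left-to-right `background_gradient` emulates shading, which is what makes
CLAHE-before-Otsu measurably useful in the tests.

What the generator does **not** emulate: out-of-focus light and 3-D
structure, texture within tubules, photobleaching, or the density and
mutual occlusion of a real perinuclear network. Passing recovery tests
therefore demonstrates that the chain measures what it claims on scenes
whose truth is known — not that a real micrograph is segmented correctly.

Traces (`generate_trace()`) are linear drifts (ROS probes) or
plateau-then-step drops (TMRM with FCCP at a known frame) at 1 frame/5 s,
with Gaussian noise.

## Kinetics

`fit_rate()` is ordinary least squares of intensity on time over a frame
window (default: the whole recording), reported per minute.
`measure_potential()` estimates the membrane-potential proxy as the
pre-FCCP plateau minus the post-FCCP plateau, both as 5-frame means: TMRM
loading is monotone, so the underlying signal peaks immediately before
uncoupling, and a plateau mean avoids the upward extreme-value bias that a
raw per-frame maximum suffers under noise (with sd 20 over ~50 frames a raw
maximum is biased by about +2σ, which would be a 5% error on a typical
drop). A non-positive drop — an already-uncoupled cell — is flagged, never
clipped. `normalize_to_control()` divides by the pooled control-group mean
(the two control lines are combined), so the control pool averages to
exactly 100%; the transformation is idempotent and scale-invariant.

## Statistics

The workflow mirrors how such fibroblast panels are analysed:

* `normality_gate()` — per-group Shapiro–Wilk before any parametric test;
  failures warn rather than silently switching tests.
* `compare_groups()` — one-way (`metric ~ line`) or two-way
  (`metric ~ line × condition`) ANOVA with Tukey HSD pairwise comparisons,
  declared significant against a Bonferroni-adjusted alpha
  `0.05 / C(k, 2)` (0.005 for five lines). Applying a Bonferroni threshold
  *to Tukey-adjusted p-values* is a deliberately conservative double
  control, kept because it is how the accompanying figures define
  significance; the comparison family size is an explicit argument
  (`family_size = 6` reproduces the 0.0083 used for a six-pair family) and
  is never inferred silently.
* `paired_condition_test()` — unpaired equal-variance Student t-test
  between conditions within a line.
* `ancova_covariates()` — `metric ~ line + donor age + sex`, with the
  age×sex interaction reported from a second model. With one donor per
  line, age and sex are perfectly confounded with the line factor; the
  function detects the rank deficiency and warns, because that is exactly
  the design limitation such a panel has.
* `fold_change()` — group means over the control mean, rounded half-up to
  one decimal (so 2.05 → 2.1), matching how fold differences are usually
  quoted.

Type-I calibration of the gate, the omnibus ANOVA and the t-test under
the null is part of the acceptance suite.

## Numerical choices and edge cases

* Otsu refuses constant images (no threshold exists); `analyze_skeleton()`
  refuses masks containing a solid 2×2 block (not a skeleton).
* A single isolated skeleton pixel (a "drop") is reported as a degenerate
  individual with a 1-px length and flagged, rather than dropped.
* An empty mask yields an empty component set and zero footprint — not an
  error.
* Identical spec + seed ⇒ bit-identical scenes, traces and pipeline CSVs;
  per-cell seeds in the pipeline are derived from the run seed.
* All image operators are shape-preserving and deterministic.

## Problem sizes used in the validation suite

The bundled tests and the acceptance script regenerate everything from
seeds: 100 random 32×32 masks for the oracle comparisons; 20 noiseless
512×512 scenes (3 networks, 8 individuals each) for parameter recovery;
8 noisy 384×384 Y/T scenes for classification; 500 traces for slope
recovery and 200 for the TMRM delta; 20,000 null replicates for the
statistical calibration (enough that the Monte-Carlo standard error is
small against the calibration band being checked). These sizes give Monte-Carlo standard errors
comfortably below the tolerances being checked while keeping a full run in
the minutes range on one CPU.

## Known limitations

* **Per-branch length accuracy.** On noiseless default scenes, branch and
  junction *counts* are recovered exactly and the footprint to ~1%, but
  per-branch lengths carry a residual error (95th percentile ≈ 2.5 px,
  occasional 4 px) concentrated on curved network arms: the medial axis of
  a meandering tube is genuinely smoother than its generating centerline,
  and its junction point is displaced into the wide angle between arms.
  End-cap compensation and sub-pixel junction refinement remove the bias
  but not all of the spread. Per-cell *median* branch lengths are well
  within 2 px. The validation suite states this bound exactly as measured.
* The two-class filter ignores loops by design; cells dominated by donut
  forms will show a high unclassified count, which is reported per cell.
* The rolling-ball estimate is a grayscale opening with a flat disc, the
  standard discrete equivalent; it is not the paraboloid variant some
  packages implement.
* ANCOVA with one donor per line cannot separate donor covariates from the
  line effect — the warning is the result, not an obstacle.

## A worked example

```{r example, eval = FALSE}
set.seed(1)
sc <- generate_scene(scene_spec(n_networks = 3, n_individuals = 8,
                                seed = 42))
res <- analyze_cell(sc$image, cell_id = "demo")
res$cell
summary(sc)   # the ground truth it should recover
```

The pipeline equivalents (`run_morphology()`, `run_traces()`,
`run_stats()`, `run_full()`) read one YAML configuration, write per-cell
and per-object CSVs plus a manifest carrying the config hash and seed, and
are also exposed through the `inst/cli/mitomorph` script.
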