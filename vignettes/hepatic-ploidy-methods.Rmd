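---
title: "Hepatic ploidy quantification: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hepatic ploidy quantification: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hepaploidy)
```

This vignette is the package's account of the science it implements: the
two models at its core, the assumptions behind them, the tunable parameters
and why their defaults are what they are, and the places where the design
was genuinely open and a choice had to be made.

## Two layers of ploidy

Hepatocyte polyploidy combines **cellular ploidy** — how many nuclei a cell
carries — with **nuclear ploidy** — the DNA content class of each nucleus
(2n, 4n, 8n). On an H&E section neither is directly observable: membranes
are invisible, and DNA content must be inferred from nuclear cross-section
area. The package solves each layer with a dedicated model and combines
them into a per-cell total (a binuclear cell with two 2n nuclei is a 4n
cell).

## Cellular ploidy: the relative-distance classifier

For nuclei with centroid distance $d$ and equivalent radii $r_1, r_2$, the
relative distance is $d - r_1 - r_2$: the clear gap between the two
(idealized circular) footprints, negative if they overlap. The working
assumption is that two nuclei of one hepatocyte sit much closer together
than nuclei of adjacent cells, so a single threshold separates the two
populations.

**Calibration.** On fluorescence patches a membrane marker provides true
cell boundaries. Nuclei and membranes are segmented by watershed, each
nucleus is assigned to the membrane-bound region containing its rounded
centroid, and two samples are collected per the sampling scheme: for every
nucleus, the relative distance to its closest nucleus in a *different* cell
(RDNDC); for every nucleus of a polynuclear cell, the relative distance to
its closest *same-cell* nucleus (RDNSC). Sampling is per nucleus, so an
unordered pair can legitimately appear twice. "Closest" is measured in
relative distance, not absolute distance — the classifier thresholds
relative distance, and keeping the neighbour metric on the same scale keeps
calibration and inference consistent; `collect_calibration_pairs()` exposes
`metric = "absolute"` for the alternative reading.

**Threshold selection.** `select_threshold()` treats same-cell as the
positive class, predicts positive when `rd < t`, and sweeps candidate
thresholds at the midpoints between consecutive distinct observed distances
(plus sentinels outside the range) — every achievable confusion table is
visited and candidates never coincide with observations, which makes the
strict-inequality tie rule immaterial in practice. The smallest F1-maximizer
is returned so the result is deterministic. The ROC over the same sweep is
integrated by the trapezoidal rule; the suite checks it coincides with the
Mann–Whitney statistic to numerical precision.

**Resolution transfer.** A pixel threshold moves between magnifications by
the resolution ratio: 5.5 px at 0.65 μm/px becomes
$5.5 \times 0.65 / 0.23 = 15.54$ px at 0.23 μm/px — the package default for
H&E-scale grouping.

**Grouping.** At inference, an edge joins every nucleus pair below
threshold and cells are the connected components — the only partition
consistent with the pairwise decisions. How chains of three or more nuclei
should be treated is genuinely open (real hepatocytes are mono- or
binuclear); components larger than two are allowed and surface in
`summarize_cellular_ploidy()` as the `>=3` row, because silently breaking
chains would hide a misconfigured threshold rather than flag it.

## Nuclear ploidy: the two-stage mixture

Nuclear area distributions of ploidy classes overlap heavily: a section
cuts a near-spherical nucleus at a random height, so even a fixed-radius
sphere yields areas spread over $(0, \pi R^2]$. In normal liver the pooled
histogram shows a single obvious peak (diploids dominate), which defeats
naive three-cluster initialization. The fit is therefore staged:

1. a one-component Gaussian locates the dominant peak $k$ (its mean);
2. EM for a three-component univariate mixture starts from means
   $(k,\, 1.4k,\, 1.4^2k)$, uniform weights, and the stage-1 variance for
   every component.

The initialization is fully specified, so the fit is deterministic and no
random restarts are used. EM specifics the method leaves open were fixed
as: per-component variances (heteroscedastic), convergence when the mean
log-likelihood improvement per observation drops below $10^{-4}$, an
iteration cap of 500 (non-convergence is an error carrying the trace), and
a variance floor of $10^{-8}$ times the data variance against component
collapse. Components sorted by mean map to 2n/4n/8n; nuclei are classified
by maximum posterior — the most direct reading of "belonging to the first
mixture component" — rather than by fixed area cutpoints, which would
discard the posterior information the report carries (`p_2n`, `p_4n`,
`p_8n`).

The suite cross-checks the EM against `mclust::em()` started from the
identical initialization (agreement to numerical precision). Notably,
`mclust::Mclust`'s own hierarchical initialization finds a *worse* local
optimum on a well-separated three-cluster fixture, which is why the
cross-check pins the starting point: the two-stage initialization is part
of the method, not an implementation detail.

**Reference model and resolution.** The intended workflow freezes a model
fitted on pooled normal-liver areas (`write_gmm_model()` /
`read_gmm_model()`, plain JSON) and applies it to new samples. A frozen
model is resolution-bound — areas are pixel counts — so
`classify_nuclei()` rescales query areas by the squared ratio of
micrometers-per-pixel when the training and query resolutions differ.
Without this the model could not be applied across scanners; with it the
rescaling is exact for ideal areas.

## The sphere-slicing simulation

`simulate_areas()` validates the mixture model against stereological ground
truth. Per class, sphere radii are normal with the three-sigma shape rule
$3\sigma = a\mu$ ($a = 0.3$, so $\mu_{di} = 9$ gives $\sigma_{di} = 0.9$);
class mean radii scale geometrically per ploidy step. Exact volume doubling
gives the theoretical multiplier $2^{1/3} \approx 1.26$; the default is the
empirically merged value 1.18. Cut offsets are uniform on $[0, R]$ (by
symmetry identical to uniform on $[-R, R]$), areas are $\pi(R^2 - h^2)$,
and sections below 200 area units are censored, mimicking the detection
floor for tiny slices. Default class counts 600²/350²/250² give
360,000/122,500/62,500 sections (66.05/22.48/11.47%). Radii are in pixels
at H&E scale; the simulation is dimensionally self-consistent and
unit-agnostic. Non-positive radius draws are resampled — at coefficient of
variation 0.1 a practically impossible event, documented for completeness.

**Censoring.** "Dropped proportionally" is implemented as the deterministic
removal of every section below the floor — the same rule in every class,
thinning each in proportion to its sub-threshold mass. The alternative
reading (random subsampling of equal size per class) adds an unstated
randomness source; it is available as `strategy = "random"` but not the
default.

**The merge search.** `search_merge_multiplier()` decreases the multiplier
from $2^{1/3}$ and reports the largest candidate whose pooled distribution
is unimodal, judging modes on a Silverman-bandwidth kernel density with a
1% relative-prominence floor (shallow sampling wiggles are not modes; the
prominence is topographic). Applied to the pooled *areas* — the default,
and the observable quantity — the criterion turns out to be unimodal over
the entire candidate grid at these parameters: uniform slicing smears each
class far below its maximal area and the 66% diploid flank swallows the 4n
and 8n bumps. That is itself a faithful reflection of the single-peak
histograms of real normal liver, but it means the area-based search cannot
localize a merge point; it simply returns the largest candidate. The merge
structure lives in the underlying sphere sizes, so a `variable = "radius"`
mode evaluates the known normal class densities analytically
(deterministic, no sampling), and `weighting = "balanced"` normalizes the
classes so the merge point reflects component separation, not prevalence.
The balanced radius criterion merges at 1.24 at the default shape
parameters. The published merged value 1.18 is treated as a reported
constant — the visual "histograms merge" judgement it came from is not
reproducible as stated — and the simulation default uses it as such.

## The synthetic-tissue generator

The generator is the package's ground-truth source and defines the regime
every downstream test runs in. It emulates: two-channel IF-like patches
(360×360 px; a nuclear channel with bright elliptical nuclei and a membrane
channel with bright ridges along cell boundaries) and H&E-like labelled
masks (500×500 px with per-label class tables including non-hepatocyte
classes). Cells are mono- or binuclear with the binuclear count fixed by
deterministic quota (`round(fraction × n)`) so tests can assert exact
counts. Nuclei are ellipses with axis ratio drawn in [0.8, 1.0] —
exercising the equivalent-radius definition, since real nuclei are not
circles — with area exactly $\pi r^2$ by construction. Sibling nuclei are
placed at a relative distance of 50–100% of `intra_cell_nucleus_gap` with
their major axes perpendicular to the joining line (footprints can then
never overlap); nuclei of different cells keep relative distance at least
`min_inter_cell_gap`. Placement is rejection sampling with a hard cap of
10,000 attempts per cell and an explicit "cannot place" error naming the
constraint, so runtime is bounded and overcrowded specifications fail
loudly. Intensities are 0.8 foreground / 0.1 background with Gaussian noise
of sd 0.05 on a [0, 1] scale — comfortably above any Otsu split, keeping
segmentation tests stable. Default geometry mirrors the calibration regime:
mean radius 9 px with the three-sigma shape rule (sd 0.9), sibling gaps up
to 4 px and inter-cell gaps at least 12 px (straddling the 5.5 px
calibrated threshold), and ploidy fractions 66.05/22.48/11.47%.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: staining texture and colour, nuclear shape
irregularity beyond mild eccentricity, karyorrhexis morphology, touching or
overlapping nuclei, segmentation errors of the upstream deep-learning
model, and section-thickness effects. End-to-end "exact recovery" results
are statements about the algorithmic pipeline in a separable regime, not
about segmenter accuracy on tissue.

## Segmentation recipe and conventions

The watershed recipe (parameters the method names but does not specify):
Gaussian smoothing (sd 1.5 px), Otsu foreground threshold, Euclidean
distance transform, watershed seeded at distance-transform maxima with
minimum seed separation 5 px; membranes are segmented as catchment basins
of the inverted smoothed intensity with merging tolerance 0.2 (several
times the noise level). All are exposed as arguments. The equivalent radius
is $\sqrt{A/\pi}$ — the only rotation-invariant radius consistent with
using area everywhere else. Coordinates are 0-based (row, col) with pixel
centers at integers; the central-region rule is half-open,
$p \le x < \text{size} - p$, so a 360-px patch with padding 30 keeps
exactly 300×300 and a 500-px patch with padding 85 keeps 330×330. Nuclei
touching the patch border are retained at segmentation and removed only via
the central-region filter on cell centroids, applied after grouping.
Nuclei whose centroid lands on an unresolved watershed-line pixel (label 0)
are reported as unassigned rather than force-assigned. A minimum region
area of 30 px² suppresses noise specks — far below any simulated nucleus.

## Numerical and testing notes

Test problem sizes were chosen to exercise each property at the smallest
scale where it is statistically meaningful: calibration oracles on 2,000
pairs, EM recovery at n = 3,000–5,000, the simulation at its full default
545,000 sections (it is vectorized and takes about a second), segmentation
on 360×360 patches of 10–20 cells, and end-to-end quantification on
500×500 masks of ~30 cells. Two measurement subtleties surfaced while
freezing expected values and are worth recording. First, the closed form
for uniform slicing, $E[\text{area} \mid R] = \tfrac{2}{3}\pi R^2$, is
tested *conditional on the drawn radii*: the octoploid class has only 250
distinct radii, so the marginal comparison against
$\tfrac{2}{3}\pi(\mu^2 + \sigma^2)$ carries ~1.3% radius-sampling error and
would fail a 1% band for a large fraction of seeds, while the conditional
comparison isolates the slicing mechanism at ~0.1% error. Second, the
three mixture components fitted to the pooled simulation areas track the
per-class empirical mean areas only to about 10%, not better: the class
densities are skewed and heavily overlapping, so mixture components are not
estimators of class means — the model's job is classification, and its
validation is the end-to-end recovery tests, not component-mean agreement.

## Limitations

The package deliberately consumes segmenter *output* (label image + class
table); it does not segment H&E colour images and does not include any
deep-learning inference. The nuclear-ploidy model caps at 8n — no >8n
components and no model selection over component count. Calibration pools
all patches into one threshold; no per-slide thresholds and no bootstrap
confidence intervals on the AUC. The stereological simulation uses ideal
spheres and zero-thickness cutting planes.
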