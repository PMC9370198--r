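---
title: "Modeling global receptor nearest-neighbor spacing from calibrated immunofluorescence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling global receptor nearest-neighbor spacing from calibrated immunofluorescence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(respace)
```

## The problem

Designing multivalent ligands that bind a cell only when its surface
receptors are dense enough requires an estimate of the typical
nearest-neighbor distance between receptors. Super-resolution microscopy
gives that distance directly but is expensive; `respace` implements a
low-technology alternative that needs only a plate reader and a standard
fluorescence microscope: an immuno-staining assay calibrated by a serial
dilution of the labeled secondary antibody gives a *total* receptor count
per well, and diffraction-limited images tell how that total is distributed
over the cell. The package models the adhesion receptor integrin
$\alpha_5\beta_1$ as its running example, but nothing in the code is
specific to it — any receptor with a specific antibody fits the workflow.

The package has two halves:

1. a **spacing model** that converts a calibrated stained image into a
   receptor-count-weighted distribution of within-pixel nearest-neighbor
   spacings, plus percentile-capped density heatmaps; and
2. a **selectivity pipeline** that quantifies how strongly bivalent,
   spacing-controlled DNA Y-scaffold ligands bind cells whose receptor
   spacings do or do not match the scaffold span, across activation states
   and cell types.

Because no raw microscopy data ship with the package, a fully seeded
synthetic-image generator reproduces every input the pipelines consume,
with known ground truth, and every claim below is backed by a test that
computes it.

## The spacing model

### Calibration

Calibration wells carry known amounts $a$ of the dye-conjugated secondary
antibody; their fluorescence is fit by ordinary least squares,

$$I = \beta_1 a + \beta_0,$$

with an intercept because poly-L-lysine-coated wells fluoresce weakly on
their own. Under a 1:1 secondary-antibody-to-receptor binding assumption
the receptor total of a stained specimen with summed fluorescence $I$ is

$$\hat N = \max\!\left(0, \frac{I/g - \hat\beta_0}{\hat\beta_1}\right) \Big/ r,$$

where $r$ is the binding ratio (default 1) and $g$ the imaging-to-plate-reader
gain ratio. The instruments' relative gain is rarely published, so $g$ is an
explicit configuration value defaulting to 1 (both devices on one scale);
any cross-instrument calibration a lab performs slots in here. Negative
back-calculated counts are clamped to zero with a warning: a count cannot
be negative, and intensities below the intercept are background-dominated.

### Segmentation

Cell-versus-background pixel classification follows the trainable-
segmentation approach popular in interactive image-analysis tools: a
compact feature stack — raw intensity, Gaussian smoothings at $\sigma \in
\{1, 2, 4, 8\}$ pixels, and the gradient magnitude of each smoothing
($1 + 2 \times 4 = 9$ features) — feeds a bagged decision-tree ensemble
(random forest, 50 trees), with a logistic-regression fallback when fewer
than 200 labeled pixels are available. The decision threshold is 0.5 on
the cell-class score. Three labeled images per condition are enough in
practice; on synthetic scenes held-out pixel accuracy exceeds 0.95 and
mask intersection-over-union with the generating ellipse exceeds 0.9 (see
`test-segmentation.R`). Masks may also come from plain Otsu thresholding
plus morphology (`threshold_mask()`), or be supplied externally — the
spacing pipeline accepts any mask. Object labeling uses 8-connectivity
throughout, fixing tie cases explicitly.

### Allocation under the jamming limit

The calibrated total $\hat N$ is distributed over cell pixels
proportionally to background-subtracted intensity. The background is the
mean intensity outside a 5-pixel dilation of the cell mask (the margin is
configurable); the dilation keeps the blurred halo of the cell out of the
background estimate.

A pixel cannot hold arbitrarily many receptors. Random sequential
adsorption of non-overlapping discs jams at a coverage fraction of
$\varphi \approx 0.55$, so a pixel of side $s$ nm holds at most

$$n_{\max} = \frac{\varphi\, s^2}{\pi (d/2)^2}$$

receptors of footprint diameter $d$. At the default 3.115 pixels per
micrometer ($s = 321.0$ nm) and $d = 5$ nm, $n_{\max} \approx 2886.8$.
The footprint default is the lower end of the 5–10 nm integrin headpiece
diameter; with $d = 5$ nm the cap sits safely above the per-pixel counts
of even the densest ($\sim 10^4\ \mu m^{-2}$) regime studied, so capping
changes nothing there, while $d = 10$ nm would cut that regime off — the
choice is exposed in `spacing_config()`. Excess from capped pixels is
redistributed proportionally over uncapped ones (water-filling, at most
100 iterations, convergence to $10^{-6}$ of the total), because a
single-pass clip would silently lose part of the calibrated total. When
the total exceeds the mask's entire capacity, the map saturates at the cap
and is flagged rather than silently truncated. The cap is applied
per pixel, not as a global ceiling: the jamming argument is local, and a
global ceiling would let individual pixels exceed physical packing.
Counts stay real-valued end to end; rounding would quantize the spacing
distribution for no physical reason.

### Within-pixel spacing

A pixel with $n$ receptors contributes one spacing value, assuming an even
distribution within the pixel. Two standard readings of "even" are
implemented and flagged in every output:

* **lattice** (default): $n$ points on a square lattice inside the pixel
  give $d = s / \sqrt{n}$;
* **poisson**: the mean nearest-neighbor distance of a homogeneous Poisson
  process of the same density, $d = 0.5\, s / \sqrt{n}$.

The lattice rule is the default because it is the direct geometric reading
of an even (regular) arrangement and reproduces the identity
$d = 1/\sqrt{\rho}$ that ties the package's three reference regimes
($\rho = 10^4, 2.5 \times 10^3, 1.11 \times 10^3\ \mu m^{-2}$) to spacings
of 10, 20 and 30 nm. Each pixel's spacing is weighted by its receptor
count — the distribution describes receptors, not pixels — and weights are
normalized to one. The weighted median is the headline summary; the mode
is computed after aggregating weights over 0.1 nm bins (reported as the
weighted mean of the winning bin, so a degenerate distribution returns its
exact value).

This within-pixel model is diffraction-limited by construction: receptor
clusters smaller than a pixel are homogenized, so for nanoclustered
receptors the global spacing is an *overestimate*. That bias is inherent
to the method, not a defect of the implementation; the Thomas-process
generator exists precisely to let users quantify it.

### Heatmaps

Density and intensity heatmaps are capped at the 98th percentile and
divided by that value before colormap lookup, which keeps a handful of
saturated pixels from compressing the display range. The reference
colormap is a nine-anchor viridis ramp with linear interpolation;
`render_heatmap()` accepts any user table of (value, RGB) anchors.

## The selectivity pipeline

Confocal stacks (default 15 slices, 0.2 µm apart) arrive in three
channels: receptor antibody, ligand label, nucleus. Masks are built on the
summed Z-projections: the cell mask from the antibody channel and the
nucleus mask from the nucleus channel, both by Otsu thresholding, closing
(3-pixel disc), hole filling and removal of objects under 50 pixels. The
ligand signal is summed across slices, averaged over the cell-minus-nucleus
region, and corrected by subtracting the mean background outside a
5-pixel dilation of the cell mask. The nucleus mask is used raw (no
dilation): only signal *in* the nucleus is excluded. Records whose region
mean does not strictly exceed the background are removed before analysis;
the survivors are divided by the maximum corrected value of the full
comparison set (all scaffolds and states of a cell type), so the strongest
condition reads 1. Statistics follow the two questions the design asks:
a one-way ANOVA across activation states per (cell type, scaffold), and
Welch t-tests between scaffolds within each state. Raw p-values are
reported by default with optional Holm adjustment.

## Scaffold geometry

The bivalent Y-scaffold presents two ligands at the tips of dsDNA arms.
With $L_i = \mathrm{bp}_i \times 0.34$ nm (B-DNA rise) the tip-to-tip
span at arm angle $\theta$ is the law-of-cosines distance
$\sqrt{L_1^2 + L_2^2 - 2 L_1 L_2 \cos\theta}$ plus an optional junction
gap (default 0; the junction's own geometry is construction-specific).
At the maximal 180° conformation a symmetric 10+10 bp design spans
6.8 nm. Because "round up" and "round to nearest" disagree in general,
both the exact value and both roundings are always reported. The inverse
problem (`arms_for_spacing()`) returns the symmetric design minimizing the
absolute spacing error, e.g. 10 bp per arm for a 7 nm target and 35 bp
for 24 nm. Arms are treated as rigid rods while their contour length
stays below the dsDNA persistence length of ~50 nm (~150 bp);
`rigidity_check()` flags designs at or beyond that boundary. Thermal
fluctuation statistics of the junction are out of scope — the geometric
calculation plus the persistence-length criterion is the package's model.

## The synthetic-data generator

The generator emulates, with explicit seeds everywhere and no global RNG
state leakage:

* **Receptor fields**: homogeneous Poisson (the random-surface regime) or
  Thomas cluster processes (nanoclusters: Poisson parents, Poisson
  offspring counts, Gaussian displacements). Activation states are
  represented only as different density/cluster parameter sets.
* **Cells**: an elliptical cell (default semi-axes 35%/28% of the field)
  containing a concentric nucleus ellipse (one third of the cell's axes).
* **Imaging**: isotropic Gaussian PSF ($\sigma$ = 200 nm default),
  expected photon yield per labeled receptor (20), uniform background
  (20 photons/pixel), Poisson shot noise then additive Gaussian read noise
  (s.d. 3) — the standard confocal/camera approximation. Labeling
  efficiency defaults to 1, consistent with the saturating-stain reading
  of the 1:1 assumption. The nucleus channel is rendered as a bright areal
  stain (500 photons/pixel) so nuclear segmentation is contrast-limited.
  Z-stacks attenuate the in-focus signal as a Gaussian in slice offset
  (s.d. 0.5 µm).
* **Calibration series**: linear in antibody amount with Gaussian well
  noise.
* **Bivalent binding**: a scaffold of span $b$ bridges a receptor pair
  that (i) are mutual nearest neighbors and (ii) whose separation is
  within a reach tolerance (default 2 nm, the order of the end-to-end
  spread of rigid Y-scaffolds) of $b$; each bound scaffold contributes one
  dye source at the pair midpoint. Mutual-NN pairs are disjoint, so the
  one-scaffold-per-receptor constraint is automatic. This rule was chosen
  over the simpler "any pair at matching distance" criterion deliberately:
  in a homogeneous field the number of *arbitrary* pairs at separation
  $r$ grows like $2\pi\rho^2 r t$ per unit area — larger scaffolds would
  always find more partners, the opposite of the avidity physics being
  emulated, where a bivalent ligand competes for the *nearest* available
  partner of its anchor receptor. Under the mutual-NN rule the matched
  count tracks the local nearest-neighbor spacing distribution, so dense
  fields prefer short scaffolds and sparse fields longer ones, and the
  count is non-decreasing in density at fixed span. This is an emulation
  for testing the quantification pipeline, not a mechanistic claim.

Scenes store either explicit coordinates (needed for binding simulations)
or only per-pixel Poisson counts — the same process marginalized to the
pixel grid — which keeps 512×512 scenes at $10^4$ receptors/µm²
($\approx 8 \times 10^7$ receptors) tractable. Pixel $(i, j)$ covers the
half-open interval $[(j\!-\!1)/s, j/s) \times [(i\!-\!1)/s, i/s)$ µm with
origin at the top-left, fixing the binning convention.

What the generator does **not** emulate: fluorophore photophysics
(blinking, bleaching), 3-D membrane topography, glycocalyx effects,
activation biochemistry, or receptor mobility. Passing the recovery tests
therefore shows the *computational* pipeline is unbiased under its own
forward model, not that real images are free of those confounders.

## Validation and problem sizes

The test suite ties every operation to an independent oracle (closed-form
arithmetic, brute-force loops, or classical identities) and checks the
end-to-end properties at these sizes, chosen to exercise the same regimes
as the reference workflow while staying desk-scale:

* Poisson nearest-neighbor law $\bar d \to 0.5/\sqrt\rho$ at
  $\rho = 10^4\ \mu m^{-2}$ on 10×10 µm ($\sim 10^6$ points, within 2%).
* Full-pipeline spacing recovery at 512×512 pixels, 10 seeds per regime:
  weighted medians within ±15% of $1/\sqrt\rho$ for
  $\rho \in \{10^4, 2.5\times10^3, 1.11\times10^3\}\ \mu m^{-2}$
  (observed: within ~0.1%).
* Conservation and jamming bound on 100 random allocation fixtures.
* Selectivity ranking on 40×40-pixel dense scenes ($\rho = 10^4$, ~500k
  receptors), scaffolds {7, 24, 36} nm, 5 seeds: the 7 nm scaffold's
  normalized signal is maximal in every seed.
* Calibration round-trip within 3 delta-method standard errors, 20 seeds.

`scripts/acceptance.R` re-runs the spacing recovery and scaffold geometry
from scratch against the installed package and writes the summary numbers
as JSON.

## Known limitations

* Sub-pixel clustering is invisible; global spacings overestimate true
  NN distances for nanoclustered receptors (by design of the method).
* The calibration transfer between plate reader and microscope is a single
  gain factor; nonlinear detector response is not modeled (no 4PL fit).
* The pixel classifier is binary (cell/background); no multi-class or
  deep-learning segmentation.
* The binding emulation is geometric; no kinetics, no monovalent
  contribution, no glycocalyx sterics.
* Per-cell instance segmentation is out of scope — signal is quantified
  over the whole-field mask, as in the reference workflow.
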