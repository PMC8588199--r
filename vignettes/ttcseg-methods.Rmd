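---
title: "Methods: automatic segmentation of TTC-stained rat brain photographs"
author: "ttcseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automatic segmentation of TTC-stained rat brain photographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In rodent stroke research the middle cerebral artery occlusion (MCAO) model
produces an infarct whose extent is read out by 2,3,5-triphenyltetrazolium
chloride (TTC) staining: viable tissue turns cardinal red, infarcted tissue
stays pale. A stained brain is cut into eight coronal slices that are
photographed together with a scale bar and a subject label. Two segmentation
tasks precede any quantitative analysis:

1. **Brain extraction** — isolate each slice from the raw compound
   photograph, which also contains clutter, specular reflections from the
   moist tissue, a nonuniform background and blurred slice boundaries.
2. **Hemisphere segmentation** — split each extracted slice into left and
   right hemispheres along the interhemispheric midline, which is low
   contrast, possibly curved (brain distortion after infarction) and almost
   never vertical (slices are placed by hand).

`ttcseg` implements both pipelines, a synthetic phantom generator with exact
ground truth, and the full evaluation metric suite.

## Brain extraction pipeline

The extraction stage runs five phases:

**SLIC oversegmentation.** The photograph is partitioned into
$K = 65$ superpixels by simple linear iterative clustering — k-means in
CIELab + position space with a compactness weight (default 10 in Lab units)
followed by connectivity enforcement. $K = 65$ is the published setting for
this image family; at roughly 900 × 1600 px it makes each slice span a
handful of superpixels while the background is carved into large coherent
regions.

**Saliency features.** Each superpixel $z_i$ carries a 6-D colour vector
$c_i$ (channel-normalized mean RGB concatenated with range-normalized mean
CIELab — the simplest reading of a six-dimensional colour distance), a
normalized position $p_i \in [0,1]^2$ and a 64-bin quantized RGB histogram
$h_i$. Four features are computed:

* global colour saliency $\mathrm{GCS}(z_i) = \sum_{j \ne i} \Delta(c_i, c_j)$;
* local colour saliency $\mathrm{LCS}(z_i) = \sum_{j\ne i} \alpha(p_i,p_j)\,
  \Delta(c_i,c_j)$ with a Gaussian proximity weight
  ($\sigma_p = 0.25$ in normalized coordinates) normalized to unit sum;
* colour histogram contrast $\mathrm{CHC}(z_i) = \sum_j \chi^2(h_i, h_j)$
  with an $\varepsilon = 10^{-12}$ denominator guard;
* spatial colour distribution $\mathrm{SCD}(z_i) = \sum_j \beta(c_i,c_j)\,
  \lVert p_j - \mu_i \rVert^2$, the colour-affinity-weighted spatial spread
  ($\sigma_c = 0.2$ in normalized colour units), where $\mu_i$ is the
  $\beta$-weighted *mean position*. (The printed form of the weighted-mean
  equation in the source material reduces to a scalar; the accompanying text
  calls it a position, and the position reading is what we implement.)

The bandwidths $\sigma_p$, $\sigma_c$ and the per-image min–max scaling of
each feature to $[0,1]$ are our choices — the source states neither — made
once so that features are comparable across images of different contrast.
Stained tissue is rare, saturated and concentrated, so it scores high on the
contrast features and low on SCD.

**Random-forest trimap.** A 200-tree random forest maps the four features to
a foreground score (fraction of trees voting foreground). Scores above
$T_f = 0.7$ become foreground, below $T_b = 0.3$ background, the rest
unknown. The thresholds and forest size are documented defaults (the source
names the classifier but no values). Because the 40-rat photograph corpus is
not deposited, the forest is trained on compound phantoms (below),
labelling superpixels by ground-truth purity: ≥ 80 % inside a slice mask →
foreground, ≤ 20 % → background, otherwise dropped.

**Iterative salient region extraction.** The trimap initializes a
GrabCut-style segmentation: 5-component full-covariance Gaussian mixtures
(k-means initialized, five hard assign/refit passes) model foreground and
background colours; a graph cut on the 4-connected pixel grid minimizes the
usual data + contrast-modulated Potts energy ($\lambda = 50$,
$\beta = 1/(2\langle\lVert x_p - x_q\rVert^2\rangle)$). Before cutting,
background superpixel regions fully enclosed by salient superpixels are
demoted to unknown — a region surrounded by the salient object is
presumably part of it (a pale infarct patch, typically). On the first pass
the trimap seeds the colour models — background superpixels as background
evidence, everything else as probable foreground (high recall) — but is
deliberately *not* a hard constraint: a single misclassified superpixel
would otherwise be unrecoverable, defeating the purpose of iterative
refinement. After each pass the trimap is re-derived from the
segmentation — a 10 px erosion becomes hard foreground, the 10 px
dilation band unknown, the rest hard background — and the loop stops when
the mask changes by less than 0.05 % of the pixels or after four passes.
The max-flow solver is a Boykov–Kolmogorov implementation in C++ (validated
against an independent max-flow library in the tests).

**Hole filling and snake refinement.** Reflections inside slices leave
holes, which are filled by the border-connected-component equivalent of
conditional dilation with a 3 × 3 cross: a complement component that does
not touch the image border is a hole. This single-pass formulation is the
exact fixed point of the iterative dilation recursion and is tested against
a literal conditional-dilation oracle. Each surviving component (area
≥ 500 px, not touching the border, moment eccentricity ≤ 0.95 — the scale
bar fails this gate) is cropped into a 480 × 320 frame and refined by a
closed parametric snake:

* the crop is transformed to the red-dominance map
  $\hat I = 2I_r - I_g \mp I_b$ (branch on $|I_r - I_b| \le T_s$, default
  $T_s = 50$), kept in native 8-bit units so that the published
  $\gamma = 1$ weighting applies directly;
* the external energy is $-\gamma\,\lvert\nabla(G_\sigma * \hat I)\rvert^2$
  with $\sigma = 2$ px;
* the snake (200 snaxels, $\alpha = \beta = 1.4$, semi-implicit update with
  time step 1, force clamped at 2 px per iteration, uniform arclength
  resampling every 10 iterations, tolerance 0.1 px, at most 300 iterations)
  starts at the mask boundary and descends the discrete energy; a step that
  would increase the energy is damped by successive halving, which makes the
  energy trace non-increasing by construction.

The snake is a *local* boundary refiner, so a corridor penalty — a quadratic
cost on straying more than 2 px from the initial boundary, built from the
distance transform of that boundary — is added to the external energy.
Without it the contour abandons weak outer edges (e.g. where a pale infarct
reaches the slice surface) for the much stronger interior tissue/infarct
edge, which is exactly the failure the refinement-safety property in the
test-suite guards against.

## Hemisphere segmentation pipeline

**Medial subimage.** The slice mask is deskewed by its principal axis
(second central moments) so the midline is near vertical; the rotation is
stored and inverted exactly when results are mapped back. A strip of width
$w = 36$ px (the published setting) centred on the mass-centre column and
spanning the mask rows is cut out; its red channel is contrast-enhanced by
clip-limited adaptive histogram equalization (4 × 4 tiles over the strip —
a 36 px strip cannot hold more tiles across — with the library's default
clip limit) and a Sobel edge map is computed.

**Endpoint detection and initialization.** The superior groove is the
deepest point of the top boundary lying between the two lobe peaks (notch
depth ≥ 3 px; single-lobe masks fall back to the mass-centre column and are
flagged); the inferior concave point is the deepest upward indentation of
the bottom boundary. A straight line with 60 equally spaced snaxels joins
them.

**GVF evolution.** The gradient vector flow field of the (Gaussian-smoothed,
$\sigma = 1$) Sobel map is computed by explicit gradient descent on the GVF
Euler equations with regularization $\mu_g = 0.2$ (published value), 80
iterations at the stability-limited time step
$\min\{1/(4\mu_g),\, 1/\max\lvert\nabla S_g\rvert^2\}$ (the second bound,
from the data term, matters on strong-edge maps). The open snake is advected
by the GVF vector at each snaxel, normalized to
$\lvert v\rvert/(\lvert v\rvert + 0.02)$ pixels per step — the usual
magnitude normalization of GVF forces, regularized so displacement decays
linearly (and stably) across field zeros. Interior snaxels also feel the
tension/rigidity regularizer ($\alpha = \beta = 1.4$); endpoint rows stay
pinned to the superior/inferior boundary and endpoints slide laterally under
the external force only, so with a zero field the curve relaxes to the
straight chord between its endpoints. Convergence is declared when the
maximum displacement falls below 0.05 px (the stopping rule is not specified
in the source; a displacement tolerance is assumed), with a 400-iteration cap.

**Splitting.** The evolved curve is mapped back through the deskew
transform, extended along its end tangents so it fully transects the mask,
rasterized, thinned to unit width (two-subiteration thinning plus
longest-chain extraction and diagonal pruning), and removed from the mask;
the two remaining 4-connected components become the left and right
hemispheres by centroid column. Left, right and path partition the slice
mask exactly, by construction.

## The phantom generator

Real photographs from the 40-rat study are not publicly deposited, so every
claim the package makes is exercised on synthetic phantoms with exact ground
truth. The generator emulates the documented challenges of the imaging
setup:

* **Compound phantoms** (default 900 × 1600, eight slices on a 2 × 4 grid):
  reddish elliptical slices around RGB (200, 60, 70) with radial shading and
  per-slice jitter; pale infarct patches around (235, 225, 215) covering 15 %
  of each slice; a straight dark midline band per slice; a scale bar and a
  label patch around (235, 235, 230) in the bottom band; specular
  reflection disks (250, 250, 250), half placed inside slices — these
  create the interior holes the hole-filling stage exists for — and half on
  the background; a background plane around (90, 95, 105) with a linear
  ramp (amplitude 25); Gaussian boundary softening ($\sigma = 1$ px)
  applied in a band around every drawn object; i.i.d. Gaussian pixel noise
  ($\sigma = 3$).
* **Slice phantoms** (320 × 480): a two-lobed slice built from two ellipses
  (lobe semi-axes 130 × 110 px, centres 0.9 lobe-widths apart), giving a
  superior groove notch ~14 px deep and an inferior concavity; a dark
  midline band whose lateral bow (sinusoidal, zero at both ends, amplitude
  up to 4 px) and tilt (up to 10°) are parameters; the same infarct,
  reflection, background and noise model.

All geometry is evaluated analytically per pixel, so truth masks are exact,
the truth midline is a one-pixel 8-connected chain, and left ∪ right ∪
midline partitions each slice mask identically. Output is byte-identical
for a fixed (spec, seed).

What the phantoms do *not* model: realistic tissue texture, the double
contour produced by slice thickness (the top and bottom faces of a 2 mm
slice both appear near the boundary), olfactory-bulb geometry, and camera
effects beyond Gaussian noise. Passing the phantom suite therefore
demonstrates the correctness and robustness of the algorithms under the
documented challenge model, not clinical-grade accuracy on real
photographs — on real data the thickness contour in particular is a known
failure mode that no component here addresses.

## Evaluation metrics

From pixel confusion counts $\theta_{TP}, \theta_{FP}, \theta_{FN}$ the
package reports conformity
$\kappa_c = (1 - (\theta_{FP}+\theta_{FN})/\theta_{TP}) \times 100$
(undefined at $\theta_{TP} = 0$, surfaced as NA rather than 0), Jaccard
$\kappa_J$, Dice $\kappa_D$, sensitivity $\eta_{st}$, sensibility
$\eta_{sb} = (1 - \theta_{FP}/(\theta_{TP}+\theta_{FN})) \times 100$ — note
the denominator is the gold pixel count, exactly as printed in the source,
which is unusual for a specificity-like measure and can go negative — and
the pixel-count errors $\Delta_N = |N_s - N_g|$,
$\Delta_F = \theta_{FP} + \theta_{FN}$,
$\varepsilon_F = \Delta_F / N_g \times 100$. Stack-level ("volumetric")
metrics are computed from summed counts, not averaged per-slice metrics;
both modes are exposed because they differ on unbalanced stacks.

## Numerical and design choices

* **Graph cut:** Boykov–Kolmogorov max-flow written in C++; an installed
  graph library solves the same instances ~300× slower at this grid size,
  which would make the multi-pass refinement impractical. It remains the
  independent oracle in the tests.
* **SLIC:** implemented in C++ (k-means with a 2S search window, 10 passes,
  orphan merging below S²/4), as no installed package provides superpixels.
* **Snake numerics:** the pentadiagonal internal-energy operator is solved
  implicitly via a precomputed dense inverse (n ≤ 200 makes this cheap);
  energy-descent damping guarantees monotonicity; contour collapse (< 3
  distinct snaxels) is an error.
* **Degenerate inputs:** all-foreground trimaps return an all-ones mask (no
  background evidence), empty trimaps an empty mask with a warning; masks
  narrower than the strip clamp the strip width with a warning; notch-free
  masks fall back to mass-centre endpoints and are flagged.
* **Problem sizes:** the test suite and the acceptance script run compound
  phantoms at 450 × 800 with all eight slices (the phantom default remains
  900 × 1600); slice phantoms always use the native 320 × 480 frame. Twenty
  phantoms per pipeline are evaluated, with training on twenty more.
* **Randomness:** every stochastic step (phantom rendering, k-means inside
  SLIC and the GMMs, forest construction) derives from explicit seeds;
  pipelines are byte-reproducible, which the suite asserts.

## Known limitations

* Real-photograph performance is unverified here: the published corpus is
  available only on request, and the forest is trained on phantoms.
* The slice-thickness double contour and the olfactory-bulb top/bottom
  ambiguity are acknowledged failure modes of the approach, not handled.
* JPEG input is not supported in this build (no JPEG reader among the
  available libraries); images should be provided as PNG.
* The sensibility metric follows the printed formula; users wanting a
  true-negative-based specificity should derive it from the counts.
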