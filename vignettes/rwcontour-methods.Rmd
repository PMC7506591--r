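---
title: "Random-walker organ contouring: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random-walker organ contouring: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements: the
segmentation model and its assumptions, the parameters that matter, what the
synthetic phantom does and does not emulate, and the numerical and design
choices made where more than one reasonable option existed.

## The segmentation model

`rwcontour` contours six categories on thoracic CT — lungs, airway, heart
(with neighbouring mediastinal vessels), spinal cord, body and gross tumour
volume — starting from labelled seed pixels on one slice. Segmentation of a
slice is the seeded random walker: the windowed image is a 4-connected
lattice whose edge weights

$$\omega_{ij} = \exp\!\big(-\beta\,(g_i - g_j)^2\big)$$

decay with the squared grey-level step, so a random walk diffuses freely
through homogeneous tissue and is blocked by intensity edges. For label $k$
with seed indicator $m^k$, the probability $x^k_i$ that a walk from pixel $i$
first reaches a $k$-seed is harmonic: it solves $L_U x^k = -B^\top m^k$,
where $L$ is the combinatorial Laplacian (degree minus weighted adjacency)
restricted to unseeded pixels. The model's central assumption is that every
organ section is a connected, roughly homogeneous region whose boundary
carries a measurable grey-level gradient — or, where it does not (weak
edges), that seeds on both sides are close enough for first-arrival
probabilities to place the boundary sensibly. Pixels take the argmax label;
seeded pixels keep their seed.

Only $K-1$ of the $K$ harmonic systems are solved; the last field is the
complement, since the fields sum to one at every pixel. The linear systems
share one sparse Cholesky factorisation per slice.

## Slice propagation and the seed engine

Consecutive CT slices (2–2.5 mm apart) intersect organs in nearly congruent
cross-sections, so the current slice's result seeds the next. The volume is
processed bidirectionally from the initial slice — superior and inferior —
because the user seeds a mid-thorax slice and both directions carry
anatomy. Three mechanisms generate and veto seeds:

* **Boundary erosion.** Each connected region is eroded with a disk — radius
  12 px for regions above 1000 px, radius 1 px below — and candidates are
  sampled on the eroded boundary, keeping them clear of the true boundary on
  the next slice.
* **Skeleton sampling.** Every region is also thinned (Zhang–Suen) to a
  one-pixel skeleton, spur branches shorter than 5 px are pruned, and
  skeleton points join the candidate pool. The skeleton is what keeps thin
  regions (a 2-px muscle sheet; an organ tip a slice before it vanishes)
  seeded when erosion annihilates them, and what covers interior pockets of
  large regions (the mediastinal fat between the lungs) that the eroded
  outer boundary never visits. Both sources are always active; making
  erosion primary with the skeleton only as a failure fallback was tried
  first and under-seeded exactly those pockets, letting neighbouring labels
  flood them.
* **Grey-level knowledge filter.** A candidate whose windowed grey level on
  the *target* slice contradicts its label is a bad seed and is dropped:
  lungs/airway/background demand grey 0–10 (air), body/GTV/heart demand
  grey ≥ 10 (soft tissue), the cord rejects 255 (bone). If a sampled batch
  is wiped out but some candidate in the component would pass, admissible
  candidates are re-admitted — a category only starves when it has truly
  vanished, which is the intended terminal condition for organs that end
  inside the volume.

Sampling is systematic (every $n/k$-th candidate in scan order with a
seed-derived random start): each candidate has equal inclusion probability,
but the picks spread evenly over the boundary and skeleton instead of
clustering, which matters when 20 seeds must cover an 800-px boundary.

Two anatomical toggles come from the user (they are part of the method's
initial settings, not estimated): the heart label exists only between its
appear/disappear slices, and below the trachea–bronchus junction slice the
airway is held to at most two connected components (the main bronchi); extra
components are absorbed into their surroundings.

The spinal cord is special-cased: its section on thoracic vertebrae is
quasi-circular, so after each slice's random-walker pass the cord label is
replaced outright by a disk fitted with a Hough circle transform on Sobel
edge points inside a small window tracking the previous centre. We always
replace (rather than only on disagreement) because the circle model is the
stated clinical contouring convention for the cord; pixels the disk vacates
revert to body.

## Parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `beta` | 70 | — (on grey in [0,1]) | weak-edge sensitivity; results are flat for values above ~30–40, verified by the β-sweep test |
| window | [-140, 260] | HU | soft-tissue display window; fixes the grey scale the HU table is expressed in |
| erosion radii | 12 / 1 | px | large/small targets split at 1000 px area |
| `count_ratio` | 0.05 | — | fraction of candidates sampled as seeds, min 1, max 20 per component (the manual protocol uses 1–20 seeds per category) |
| pruning length | 5 | px | spur branches shorter than this are noise of the thinning, not anatomy |
| spine `r_min`..`r_max` | 4–12 | px | anatomically plausible cord calibers at ~1 mm pixels |
| spine window half-width | 25 | px | covers cord plus vertebral ring at ~1 mm pixels |
| edge percentile | 0.90 | — | keeps the strongest decile of Sobel magnitudes as edge points |
| `max_drift` | 10 | px | the cord centre shifts slowly; larger jumps are fit failures |
| `min_component` | 5 | px | argmax speckle absorbed into surroundings |
| phantom noise | 20 | HU sd | typical soft-tissue CT noise |

Grey levels are normalised to $[0,1]$ before the Gaussian weight: with raw
8-bit differences, $\beta = 70$ drives every non-zero gradient to
$e^{-70}$ — numerically indistinguishable from zero — so the documented
$\beta$ is only meaningful on normalised intensities.

## The phantom: what it emulates, and what it does not

The generator builds an 80 × 256 × 256 volume at 2.5/1/1 mm (proportionally
rescaled for other shapes) from geometric primitives: an elliptic-cylinder
body with a muscle/skin rim over a fat interior, two ellipsoidal lungs
wrapped in a thin pleural/chest-wall muscle shell, a trachea bifurcating
into two bronchi (each with a soft-tissue wall), an ellipsoidal heart
embedded in pericardial fat and confined to its slice range, a cylindrical
cord inside a bright vertebral ring, a tumour inside the left lung, and a
two-pixel muscle sheet along the chest wall inside the right lung whose sole
purpose is to force the erosion-annihilation rescue path. Tissue HU means
sit in the standard anatomical ranges (air −1000, lung −500, fat −60,
muscle/soft tissue 30–40, bone 700) with additive Gaussian noise; masks are
exact by construction. `phantom_degrade()` blurs boundaries and raises noise
to emulate weak edges.

What the phantom does **not** emulate: partial-volume mixtures, scanner
reconstruction texture and streak artifacts, anatomical irregularity
(lobulated tumours, vessels entering the hila, cardiac motion), and — most
importantly — the genuinely ambiguous soft-tissue/soft-tissue interfaces
that dominate clinical difficulty, such as a tumour invading the
mediastinum. Passing the phantom thresholds therefore demonstrates that the
machinery is implemented correctly and is stable over 80 slices from a
single seeded slice; it does not predict clinical accuracy, where reported
Dice values for such methods are substantially lower (GTV especially,
because tumour extent on CT alone under-determines the clinical target).
Phantom thresholds are intentionally stricter than clinically reported
values because the phantom is easier than patient anatomy.

## Numerical choices and degenerate inputs

* **Rounding** in the window transform is half-away-from-zero
  (`floor(x + 0.5)` on the non-negative range), not banker's rounding.
* **Weight floor**: $\varepsilon = 10^{-6}$ is added to every edge weight so
  flat-zero regions (air against clamped lung) never disconnect the graph;
  probabilities are clipped to $[0,1]$ after the solve, and conservation
  holds to $10^{-6}$ per pixel.
* **Solver**: sparse CHOLMOD Cholesky; the dense oracle in the test suite
  agrees to $10^{-8}$. A singular system triggers a connectivity check and
  an error naming a disconnected unseeded component.
* **Argmax ties** break by the fixed order body < lungs < airway < heart <
  spinal_cord < gtv < background.
* **Hough peak ties** break toward the smallest radius, then the smallest
  centre index; the reported radius is the median distance of supporting
  edge points, which is robust to the two-pixel band a Sobel step response
  produces (a raw accumulator argmax alternates between the inner and outer
  rim of that band).
* **Degenerate masks**: a one-pixel region erodes to empty (signalling the
  skeleton path); thinning can annihilate blobs of a few pixels, in which
  case the most central mask pixel stands in for the skeleton; an empty
  reference mask yields `NA` metrics (never 0); a constant spine window
  yields no edge points and falls back to the previous circle.
* **Monte-Carlo validation**: the solver is checked against simulated
  absorption (10⁵ walks per pixel). Across the ~10⁴ per-pixel comparisons of
  the oracle suite, about 0.3 % must exceed 3σ by chance alone, so the test
  asserts ≥ 99 % of pixels within 3σ and every pixel within 5σ — the
  faithful statistical reading of "agrees within sampling error".

## Design choices where the design was open

* **FPR/FNR normalisation.** Both rates divide by the reference-positive
  count. The alternative (FP over true negatives) is inconsistent with
  over-segmentation rates above 0.5 coexisting with Dice near 0.77 in
  published comparisons of cord contouring, which the chosen normalisation
  reproduces naturally.
* **Hausdorff for stacks** is evaluated slice-wise in 2D (maximum over
  slices), the common convention for contour review in radiotherapy; the
  point-set function itself is dimension-agnostic and is the unit checked
  against the brute-force oracle.
* **Windowing** is one global transform for the volume, not per-slice
  recalibration: HU is already a calibrated scale.
* **Heart seeds and the heart range.** The pipeline requires the initial
  slice to lie inside the heart range when the heart is among the seeded
  categories and drops heart seeds outside it; a heart that appears on a
  slice the propagation reaches from outside its range would need a seed
  origination rule the method does not define.
* **Test problem sizes.** The full end-to-end checks run the 80 × 256 × 256
  phantom (one run ≈ 30 s); the β-sweep runs three pipelines on a
  40 × 160 × 160 phantom, which is ample to detect any β-sensitivity of lung
  Dice at a fraction of the cost. The Hough radius search [4, 12] px is
  matched to ~1 mm pixels; on coarser grids (≤ 0.75 mm-equivalent scaling)
  the vertebral ring itself enters the search range and the fit locks onto
  it — visible in the reduced-size phantom's cord scores, and the reason
  cord quality is asserted at full scale.

## Known limitations

* DICOM series are not read directly; volumes come in as NIfTI (convert
  upstream). The stored-value rescale (`hu_from_stored()`) is provided for
  pipelines that do their own unpacking.
* The random walker is strictly 2D slice-by-slice by design; no volumetric
  26-neighbour variant, no GPU path.
* Contour export traces outer boundaries only; interior holes of a region
  are filled on rasterisation.
* No DICOM-RT structure-set export, no dose or DVH computation, and no
  interactive correction loop: the package covers the automated segment of
  the workflow between seeding and contour hand-off.
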