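# rwcontour

Semi-automated contouring of thoracic organs at risk on CT for radiotherapy
treatment planning. From a single manually seeded slice, `rwcontour` delineates
the lungs, airway, heart (with neighbouring vessels), spinal cord, body
outline and gross tumour volume (GTV) through a whole CT volume, and scores
the result against reference contours. It is aimed at medical-image-analysis
researchers who need a transparent, fully scriptable baseline for
interactive organ-at-risk segmentation — every stage is an ordinary R
function with a testable contract.

## Method

Each windowed slice is segmented with the seeded **random walker**: the image
becomes a 4-connected pixel graph with Gaussian edge weights

    w_ij = exp(-beta * (g_i - g_j)^2),   beta = 70,

where `g_i, g_j` are grey levels rescaled to [0, 1] after the soft-tissue
window ([-140, 260] HU mapped linearly onto 0..255). For each label, the
probability that a random walk started at a pixel first reaches a seed of
that label is the harmonic function solving the combinatorial Dirichlet
problem `L_U x = -B^T m` on unseeded pixels; the package solves it by sparse
Cholesky factorisation of the graph Laplacian and assigns each pixel the
argmax label. Slices then seed each other outward from the initial slice:

* each segmented region is eroded (disk radius 12 for regions over 1000 px,
  radius 1 otherwise) and seed points are sampled on the eroded boundary;
* the pruned morphological skeleton of every region supplies a second seed
  source, which keeps thin structures alive when erosion annihilates them;
* candidate seeds whose grey level on the next slice contradicts their
  label's admissible HU range (air-like labels 0..10, soft tissue >= 10,
  cord != 255) are discarded as bad seeds.

The heart label exists only between its user-declared appear/disappear
slices; below the trachea-bronchus junction slice the airway is tracked as
two bronchial components. The quasi-circular spinal cord is re-fitted on
every slice by a Hough circle transform on Sobel edge points inside a small
tracking window. Agreement between two label stacks is quantified with the
Dice coefficient `2TP / (FP + 2TP + FN)`, false-positive/negative rates
(normalised by the reference-positive count) and the symmetric Hausdorff
distance `max(h(A,B), h(B,A))`, `h(A,B) = max_a min_b d(a,b)`.

No patient data ships with the package. A phantom generator builds synthetic
thoracic CT volumes (lungs, bifurcating airway, heart, spinal cord inside a
vertebral ring, body with fat/muscle layers, a tumour, and a deliberately
thin muscle sheet) with exact ground-truth masks and realistic Hounsfield
means plus Gaussian noise, so the whole pipeline is testable end to end.

## Worked example

```r
library(rwcontour)

phantom <- phantom_generate(phantom_spec())          # 80 x 256 x 256, 2.5/1/1 mm
result  <- rw_run(phantom$volume, phantom$seeds, phantom$config)
report  <- compare_stacks(result$labels, phantom$truth,
                          spacing = phantom$volume$spacing)
print(report, digits = 4)
```

```
     category   dice       fpr       fnr  hd_px  hd_mm n_slices
1        body 0.9967 9.962e-05 6.387e-03 21.587 21.587       80
2       lungs 0.9993 1.316e-03 6.680e-06  7.071  7.071       63
3      airway 1.0000 0.000e+00 0.000e+00  0.000  0.000       65
4       heart 0.9498 1.037e-01 1.796e-03 19.799 19.799       34
5 spinal_cord 0.9846 3.121e-02 0.000e+00  1.000  1.000       80
6         gtv 1.0000 0.000e+00 0.000e+00  0.000  0.000       15
```

Each row scores one category against the phantom's ground truth over the
slices where the reference delineates it: `dice` is overlap (1 = perfect),
`fpr`/`fnr` are over- and under-segmentation relative to the reference
volume, and `hd_px`/`hd_mm` the worst per-slice boundary mismatch. The body
Hausdorff value comes from the chest-wall muscle sheet on its terminal
slices; the cord's 1 px reflects the rasterised Hough disk against the true
cylinder. A full run takes well under a minute on one core.

The command-line front end under `inst/cli/` wraps the same functions:

```sh
Rscript inst/cli/rwcontour phantom --out phantom_dir --seed 1
Rscript inst/cli/rwcontour run --volume phantom_dir/volume.nii.gz \
    --seeds phantom_dir/seeds.json --config phantom_dir/run.json --out seg
Rscript inst/cli/rwcontour evaluate --pred seg/labels.nii.gz \
    --ref phantom_dir/truth.nii.gz --out metrics.csv
```

Input volumes are NIfTI (`.nii`/`.nii.gz`) in Hounsfield units; outputs are a
multi-label NIfTI (with a plain-text code/category sidecar), per-slice
contour polygons as JSON (0-based row/col coordinates), and CSV metric
tables.

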