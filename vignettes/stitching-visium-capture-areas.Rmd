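---
title: "Stitching Visium capture areas: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stitching Visium capture areas: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stitchspot)
```

## The problem

A standard 10x Genomics Visium capture area is 6.5 mm x 6.5 mm. Tissue
structures larger than that must be split across several capture areas —
sometimes partially overlapping sections, sometimes sections placed adjacent
across a physical score line. Treating each capture area as an independent
sample discards the spatial relationship between them. `stitchspot`
integrates the imaging and gene-expression data of such a group of capture
areas into one coherent sample: one coordinate frame, one image, one
Visium-like array, with nothing discarded in regions of overlap.

Image alignment itself is manual and external: the per-area images are
stitched interactively (e.g. in Fiji), which is unavoidable for adjacent
sections separated by a physical gap, where no automatic overlap-based
registration can work. `stitchspot` prepares the inputs for that step and
consumes its outputs — one rigid affine transform per capture area plus the
composite image.

## Uniform physical rescaling

SpaceRanger's `tissue_hires_image.png` has up to 2,000 pixels on its longest
side regardless of the microscope's resolution, so one hires pixel does not
represent the same physical distance in different capture areas. Stitching
requires that it does. For area $i$, let $d_i$ be `spot_diameter_fullres`
(the 55 µm spot diameter in full-resolution pixels) and $h_i$ the
`tissue_hires_scalef`. A spot then spans $d_i h_i$ hires pixels, and each
area's image is upscaled by

$$ s_i = \frac{\max_j\, d_j h_j}{d_i h_i}, $$

which is the unique choice that makes the rendered spot diameter $d_i h_i
s_i$ identical across areas while never downscaling ($\min_i s_i = 1$). The
area attaining the maximum is the *reference*; ties go to the
lexicographically smallest area id so the choice is deterministic.
Resampling is bilinear and output dimensions round half-up.

## Coordinate frames

Three frames are kept explicit throughout:

* `FULLRES_i` — area $i$'s full-resolution pixel frame, in which
  `tissue_positions.csv` stores spot centroids (`pxl_col_in_fullres` is $x$,
  `pxl_row_in_fullres` is $y$).
* `NORMHIRES` — the shared stitching canvas where all rescaled images live;
  `FULLRES_i` maps into it by multiplication with $h_i s_i$. The affine
  transform $A_i$ estimated during stitching acts in this frame, because
  this is the frame the stitching software saw.
* `GROUP_FULLRES` — the output frame: `NORMHIRES` divided by the reference's
  normalized scale $h_{ref} s_{ref}$. Its µm-per-pixel equals the reference
  area's full-resolution µm-per-pixel, so the group's
  `spot_diameter_fullres` is simply $d_{ref}$.

A spot maps as $(x,y)_{group} = A_i\!\left((x,y)_{fullres}\, h_i s_i\right) /
(h_{ref} s_{ref})$. The net scalar on the linear part is $d_{ref}/d_i$,
which is what makes distances physically consistent across areas even when
their microscopes differed. Formulating this as frame conversions rather
than a single post-hoc scalar removes any ambiguity about whether the
transform's translation is expressed before or after scaling.

The stitched composite is resized to 1,200 pixels on its longest side by
default — sized so a 2x2 arrangement of capture areas gets about the same
per-area resolution as SpaceRanger's own 600-px `tissue_lowres_image.png`;
for other group shapes the target is configurable. The accompanying
`tissue_lowres_scalef` is `(target / longest canvas dimension) * h_ref
s_ref`, so `GROUP_FULLRES` coordinates times that factor land on the lowres
raster, exactly as in an unstitched SpaceRanger output.

## The artificial hexagonal array

Spatially-aware clustering methods for Visium (BayesSpace, PRECAST) find a
spot's neighbours through the integer array coordinates, assuming the
standard hexagonal layout: neighbours 100 µm apart, `array_col` stepping by
2 within a row (50 µm per column-index unit), adjacent rows
$100\sqrt{3}/2$ µm apart and offset by one column unit, so
`array_row + array_col` is always even. After stitching, the original
per-area indices are meaningless — areas have been rotated and translated —
so the package lays a fresh Visium-like lattice over the whole group:

* **Scale.** The µm-per-pixel of the group frame is estimated as
  $100 / \mathrm{median}$ nearest-neighbour distance of one area's
  transformed spots. The median makes this robust to jitter; using a single
  area (the reference) is deliberate, since at overlaps spots from
  *different* areas sit arbitrarily close together and would corrupt the
  statistic. With fewer than two spots the fallback is
  $55 / d$.
* **Anchoring.** The minimum `pxl_row_in_fullres` over all the group's
  spots maps to `array_row = 0`, the minimum `pxl_col_in_fullres` to
  `array_col = 0` — the same orientation convention SpaceRanger uses. Rows
  and columns are added until the lattice spans past the maximum
  coordinates, generally well beyond the 77/127 maxima of a single area.
* **Snapping.** Every spot receives the indices of its Euclidean-nearest
  lattice point. Only the two lattice rows bracketing a spot, and within
  each the two parity-valid columns bracketing it, can contain the nearest
  point, so the assignment is $O(1)$ per spot; the test suite verifies it
  against exhaustive search on instances up to 5,000 spots. Exact ties —
  a spot equidistant from two lattice points — go to the lexicographically
  smallest `(array_row, array_col)`, which is deterministic and independent
  of input order. No spot can move farther than the lattice circumradius
  $100/\sqrt{3} \approx 57.7$ µm.

Several spots may legitimately share one artificial coordinate — that is
precisely how overlapping capture areas coexist on one array, and the
downstream clustering methods tolerate it.

## Overlaps: keep everything, flag for display

Spots of one group sharing a redefined array coordinate across two or more
capture areas form a *collision*. No data are removed; instead an
`exclude_overlapping` flag marks, in each collision, every spot except the
one from the capture area with the highest mean UMI count (mean of per-spot
total raw counts over that area's in-tissue spots — out-of-tissue spots are
background and excluded from the mean). Ties break by lexicographic area
id, then spot key, so exactly one spot per collision is always retained.
Defining overlap through array-coordinate collisions rather than a raw
distance threshold uses the only spot-level equivalence the artificial
array itself constructs; a geometric criterion could be added for
sensitivity analyses but is not the default.

The agreement statistic summarises how often a clustering assigns
overlapping spots the same label: over all collision groups with at least
two labeled members, the fraction in which all members agree (a pairwise
variant is available; the two coincide when every collision hosts exactly
two spots). With no collisions the statistic is undefined and returned as
`NA`, not 0.

## The simulator and what passing tests mean

`simulate_capture_area()` fabricates a complete SpaceRanger-style output:
hexagonal spot grid (defaults 78 rows x 128 column indices = 4,992 spots,
100 µm pitch, 55 µm spots, 1 µm per full-resolution pixel), an elliptical
tissue region, a hires image (2,000 px longest side, like SpaceRanger's)
rendering the tissue, spot-scale texture and one calibration disc of
exactly one spot diameter, and sparse Poisson counts whose in-tissue
per-spot totals have mean `depth` (default 1,158, a realistic median UMI
per spot for human brain Visium). `simulate_group()` arranges three such
areas in the canonical multi-area design: two partially overlapping
(default 30 % of columns; the translation is an even number of
column-index units so overlapping spots coincide *exactly*) and a third
adjacent across a 200 µm gap, never overlapping. Depth multipliers
(1, 1.5, 0.8) make the second area the deepest so mean-UMI precedence has
a known right answer. The known transforms are written in a
TrakEM2-style XML, the canvas is composited from the transformed images,
and ground-truth coincident pairs (ε = 10 µm) are tabulated from the true
geometry.

What this does and does not show: the simulation exercises the geometry,
formats and bookkeeping of the workflow under exact rigid transforms. Real
data add manual-alignment error (spots then coincide only approximately),
tissue-dependent image content, and spatially structured expression — none
of which the Poisson model attempts to emulate. Passing the ground-truth
closure tests therefore validates the coordinate arithmetic and the
overlap logic, not the biological quality of any particular manual
alignment.

## Numerical choices and degenerate inputs

* Dimension rounding is half-up everywhere; resampling is bilinear.
* Rescale equalisation holds to 1e-9 relative; rigidity of transforms is
  asserted to 1e-6 (orthogonal linear part, determinant +1). Non-rigid
  transforms parse with a warning — stitching software can emit them — and
  are rejected only when the caller demands rigidity.
* Tissue-position dialects (headered vs headerless CSV) are detected from
  the first line; gzipped variants are transparent. Malformed rows fail
  hard with a line number; duplicate barcodes fail hard.
* An empty capture-area group, a zero-sized image, a non-positive scale and
  a parity-violating array coordinate are all hard errors; negative
  transformed coordinates only warn, since stitching canvases can include
  margins.
* Filtering (undetected genes; out-of-tissue or zero-count spots) is a
  separate, optional step — the stitched object itself always keeps every
  spot, and filtering everything is treated as an error rather than an
  empty success.
* A single spot yields a 1x1 lattice; `overlap_agreement` with no
  collisions returns `NA` with a message.

## Problem sizes used in the checks

The bundled tests run the full workflow on a small seeded group (three
areas of 16 x 24 indices each, 192 spots per area) for speed, and the
acceptance checks additionally simulate standard-size areas (78 x 128,
4,992 spots) and a full three-area standard-size group — the same
geometry the defaults produce — to verify the analytic lattice quantities,
index maxima and ground-truth recovery at realistic scale. Snapping is
cross-checked against exhaustive search at 5,000 spots.

## Known limitations

* Transforms are rigid affine; no shear, scaling or diffeomorphic warping,
  and no alignment against an atlas.
* Image work is done at hires scale (≤ 2,000 px); full-resolution image
  analyses must happen upstream.
* The artificial array is hexagonal only; square-grid platforms (Visium HD,
  the original ST arrays) would need a square lattice, which the snapping
  machinery does not currently provide.
* Export writes SpaceRanger-style text + MatrixMarket outputs; no HDF5
  container is produced.

## A worked call

```{r example, eval = FALSE}
library(stitchspot)

sim <- simulate_group("sim_demo", n_rows = 16, n_cols = 24, h = 0.15,
                      depth = 60, n_genes = 30, seed = 42)
g <- build_stitched_group(sim$sample_info, target_longest = 300)
glance(g)
tidy(g)
autoplot(g)
overlap_agreement(tidy(g) |> dplyr::mutate(label = "one-cluster"))
```
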