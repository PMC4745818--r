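---
title: "Methods: automatic ascending-aorta segmentation by Hough initialization and geodesic distance transforms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automatic ascending-aorta segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

In a mid-thoracic axial CT slice of a contrast-enhanced cardiac scan, the
ascending and descending aorta appear as two bright, nearly circular
cross-sections; the ascending one has the larger caliber. The package
segments the ascending aorta over the whole stack without any user
annotation, by composing three ideas: a circle detector to find a
trustworthy starting cross-section, a seeded geodesic segmentation of one
slice at a time, and a seed-transfer rule that walks the segmentation up and
down the stack and knows when to stop.

The design deliberately avoids 3D level-set evolution: the ascending aorta
is an obtuse, slowly varying tube, so accumulating 2D per-slice
segmentations is both faster and sufficient.

### Initialization: stable circles, not just strong circles

`detect_circles()` runs a standard circular Hough transform per axial
slice: pixels with gradient magnitude above `hough.edge_threshold` vote for
every possible centre at every radius in `[r_min, r_max]`; votes are
normalised by circumference so radii compete fairly; peaks are extracted
greedily, each picked circle suppressing further centres inside its own
radius (arcs of an already-found circle would otherwise reappear as
high-scoring interior candidates). Circles touching the image border are
discarded.

Two cues then pick the aortic pair on a slice (`select_aorta_pair()`): the
interior intensity ratio — the fraction of interior pixels inside the
contrast-agent window `[intensity_lo, intensity_hi]` — ranks candidates,
and of the two best, the larger radius is labelled ascending, with a
configurable position prior (ascending = smaller x, i.e. patient-right /
anterior) deciding near-ties. A published alternative uses the position of
the trachea carina as an anatomical anchor; that is a detection subsystem of
its own, and the simple position prior substitutes for it here.

Single-slice detections can still be fooled by other round bright
structures (vessel ostia, atrial appendage sections). The selector
therefore scores every admissible slice k by the stability energy

$$E(k) = \sum_{i=k-5}^{k+5} \left( |\oslash C_i - \oslash C_k| +
\lVert C_i(x,y) - C_k(x,y)\rVert \right)$$

over an 11-slice window (half-width `hough.window_halfwidth = 5`) and
starts from the argmin. The two bars are read as the absolute diameter
difference plus the Euclidean centre distance: both must be nonnegative
penalties in pixel units (a signed reading would cancel and make the energy
degenerate). A distractor present on only a few slices destroys the windows
it touches but cannot win one. In strict mode, windows containing a slice
with no detected pair are inadmissible (infinite energy); if no window is
admissible the selector re-scores in a best-effort mode that skips missing
slices and normalises by the count present.

### Volume of interest

The VOI is a box padded three circle-diameters from the detected centre in
x and y — generous because the ascending aorta slants in x as it
approaches the chamber — clamped to the image, spanning the full z range.
One symmetric formula is applied on each side of the centre; bounds are
stored half-open after floor/ceiling rounding so they compose with array
slicing. The VOI is an optimisation, not semantics: the suite checks that
segmenting without it changes the phantom DSC by less than 0.01.

### Per-slice geodesic segmentation

Given aorta seeds $\Omega_A$ and background seeds $\Omega_B$, each pixel x
receives two geodesic distances $D_A(x), D_B(x)$ — the minimum accumulated
path cost to each seed set — and takes the label of the nearer set, with
ties going to background (the conservative side: the known failure mode of
this family of methods is leakage into the ventricle, not undersegmentation).

The path cost discretises the squared-gradient path integral: a step of
length $l \in \{1, \sqrt2\}$ between intensities $I_a, I_b$ costs
$((I_b - I_a)/l)^2 \, l$. The finite difference along the step (rather than
the full image gradient) is the common choice in geodesic segmentation and
reduces exactly to pure path length when the weight is one, which is the
variant the seed-transfer stage uses. Squared-gradient weighting makes
paths that stay inside a homogeneous region nearly free while any path
across the vessel wall pays the full squared intensity step, so the label
boundary settles on the strongest gradient between the seed sets.

Distances are computed by the multi-pass raster-scan (chamfer) algorithm:
a forward sweep relaxes each pixel from its four causal neighbours
(left, up-left, up, up-right), a backward sweep from the mirrored set,
alternating until a full forward+backward cycle changes no pixel by more
than `geodesic.tolerance` (default 1e-8) or `geodesic.max_passes` sweeps
run. With nonnegative weights the sweeps converge to the exact shortest
path distances on the 8-connected graph; the suite enforces equivalence
with an independent Dijkstra oracle to 1e-6 on random images rather than
trusting any fixed pass count. The default sweep limit is 64: alternating
sweeps resolve one more "direction reversal" of the shortest-path tree per
cycle, and rough weight fields can need more than the handful of sweeps
that smooth images require; each sweep is O(N), so the headroom is cheap
and the convergence check exits early (phantom slices typically converge in
40–60 sweeps).

The initial slice is seeded from the detected circle: its centre pixel is
the single aorta seed, and a 1-px ring at 1.5 diameters from the centre —
comfortably outside any plausible aortic cross-section, yet inside the VOI
— is the background seed set, clipped to the slice.

### Adaptive seed transfer and termination

Adjacent slices share most of their labels; only pixels near the boundary
are uncertain. The transfer rule marks, at the same (x, y) coordinates of
the next slice:

- **aorta seeds** where the reference pixel is aorta and lies deeper than
  `T_A` from the boundary;
- **background seeds** where the reference pixel is background and sits in
  the `(T_min, T_max)` distance band outside the boundary;
- everything else unlabeled, to be decided by the geodesic segmentation of
  the new slice.

Distances here are unit-weight chamfer distances — a fast approximation of
Euclidean distance (overestimate bounded by ~8.2% on the 8-connected
grid). Each pixel's distance is measured to the *opposite* class: for a
foreground pixel, to the nearest background pixel. Measured this way,
thresholding at `T_A` is exactly morphological erosion of the foreground by
a disc of radius `T_A`, and the background band is the annulus
`T_min`–`T_max` px outside the boundary; measuring to the two-sided border
set itself would shift both thresholds by one pixel and make the erosion
radius `T_A + 1`. (`border_distance()` still exposes the literal
distance-to-border transform for inspection.)

Propagation runs downward (toward the valve) first, then upward (toward the
arch), each direction independently from the initial slice; the order is
immaterial and fixed only for determinism. A direction stops when the
transferred aorta seed class is empty (`no_foreground_seed`) or the volume
ends (`volume_boundary`). No anatomical stopping rule is used: seed
exhaustion is the only intrinsic terminator, which matches how the transfer
thresholds behave — once the cross-section becomes small, erosion by `T_A`
leaves nothing to transfer.

Each segmented slice keeps only the foreground component 8-connected to its
seeds, so the assembled 3D mask is a single 26-connected tube.

## Parameters that matter

| key | default | units | why |
|---|---|---|---|
| `hough.r_min_px`, `r_max_px` | 8, 30 | px | aortic caliber range at 0.38 mm pixels; rescaled by `0.38/dx` when spacing is known |
| `hough.edge_threshold` | 40 | intensity/px | gradient magnitude above CT noise but far below the contrast step (~200+) |
| `hough.intensity_lo`, `hi` | 200, 600 | HU | contrast-agent window; both aortae must fill it |
| `hough.min_intensity_ratio` | 0.8 | — | eligibility for the aortic pair; tolerates partial-volume rims |
| `hough.min_score` | 0.3 | — | minimum fraction of a circle's circumference supported by edge votes |
| `hough.window_halfwidth` | 5 | slices | 11-slice stability window; larger windows add cost with little accuracy gain |
| `transfer.t_a_fraction` | 0.25 | — | erosion threshold scales with the equivalent radius so small sections are not killed prematurely |
| `transfer.t_a_min_px` | 4 | px | erosion floor; see below |
| `transfer.t_min_px`, `t_max_px` | 2, 10 | px | background band: near the moving boundary but never on it |
| `geodesic.max_passes`, `tolerance` | 64, 1e-8 | sweeps, cost | convergence guard for the chamfer sweeps |
| `pipeline.leak_guard_ratio` | off | — | optional per-slice area cap (× initial disc area) against chamber flooding |

The erosion floor deserves a note, because it is what makes termination
crisp. Where the image offers no confining gradient (past the true vessel
end), the segmentation of a transferred seed set reproduces roughly the
seeded geometry: the boundary settles between the eroded foreground seeds
and the background band, so the foreground shrinks by only about
`(T_A − T_min)/2` per slice. With a 2 px floor that is ~0 px/slice and
propagation coasts for many slices past a tapered vessel end; with a 4 px
floor, transfer stops as soon as the cross-section's inradius falls below
4 px (1.5 mm at 0.38 mm pixels — far below any real ascending aorta), and
within gradient-bounded sections the geodesic step simply regrows the
eroded margin, so the choice has no effect on well-bounded slices.

## The phantom: what it emulates, what it does not

`default_aorta_phantom()` builds an 80 × 128 × 128 volume with unit
spacing: an ascending-aorta-like tube (radius 14 px, intensity 350,
slanting +0.3 px/slice in x) that merges into a large, more weakly
enhanced ventricle-like blob (intensity 260) at the low-z end and tapers
out (14 → 3 px over six slices) before the high-z end; a parallel
descending-aorta tube (radius 9 px, same intensity); a dark distractor disc
(intensity 120, below the contrast window); a bright distractor disc that
matches the aortic intensity but exists for only 3 slices (to exercise the
stability energy); background 50; Gaussian blur sigma 1 px; additive
Gaussian noise sigma 8 (about 2.7% of the 300 contrast step). The tube
taper exercises seed-exhaustion termination; the blob exercises bounded
leakage at an imperfect border.

Ground truth is the set of ascending-tube discs, rasterized by the
centre-distance test, never blurred or noised.

The phantom deliberately omits: beam hardening, step artifacts and motion
(the image-quality grading axis of clinical data), anisotropic voxels in
the test default, elliptical or crescent cross-sections, neighbouring
enhancing structures in contact with the aortic wall, and the partial
volume texture of real CT. Passing the phantom suite therefore demonstrates
the pipeline's mechanics — detection, stability selection, geodesic
boundary placement, transfer geometry, termination — not clinical-grade
robustness; on real CCTA the contrast window and radius bounds are the
knobs most likely to need a site-specific look.

## Numerical choices and degenerate inputs

- Internal axis order is `(z, y, x)` everywhere; per-slice coordinates are
  0-based with x = column, so every formula involving centres and radii
  works in pixel units on the native grid. Radii are rescaled from the
  0.38 mm reference only when the volume's spacing says otherwise.
- Ties `D_A = D_B` label background. On a perfectly constant slice all
  gradient costs are zero, so the whole zero-cost component is background —
  the documented degenerate case; constant slices also yield no edge
  pixels, hence no circle candidates, hence a clean detection failure
  rather than garbage.
- Circle candidates are integer-valued (accumulator cells); the 2 px
  recovery tolerance of the detection stage reflects that resolution.
- If the transferred background class comes back empty while foreground
  seeds exist (possible when the band falls outside the VOI crop), the
  pipeline warns and falls back to the initial-slice rule: a ring of
  background seeds at 1.5 equivalent diameters from the foreground
  centroid.
- The isosurface of a mask is extracted by marching tetrahedra (six
  tetrahedra per cell, face diagonals chosen consistently across cells), at
  level 0.5 on the zero-padded mask: watertight by construction, verified
  in the suite by edge-pairing and Euler characteristic. No installed
  isosurface extractor was available, so the package carries its own.

## Problem sizes used by the suite

The suite and the acceptance script run entirely on generated data:
32 × 32 images for the Dijkstra-equivalence checks (50 random fields),
64 × 64 shapes for transfer geometry, 24 × 96 × 96 volumes for the
twenty detection phantoms, and five 80 × 128 × 128 standard phantoms for
the end-to-end runs. These sizes keep a full run in the minutes range on a
single CPU while every stage still crosses its asymptotic behaviour
(multi-component slices, clamped VOIs, window truncation, both termination
reasons).

## Known limitations

- Termination is purely seed exhaustion; where the aorta meets the valve
  with an unclear border the mask may either leak a few slices into the
  chamber or stop early — both observed, both bounded, and the optional
  leak guard can cap the former.
- The position prior (ascending = smaller x) assumes standard patient
  orientation; flip it via config for nonstandard acquisitions.
- The DICOM reader is minimal (explicit-VR little-endian, uncompressed,
  single series per directory) — adequate for converter output, not a
  general DICOM stack.
- Slices are processed independently given the transferred seeds; there is
  no global 3D regularity term, by design.
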