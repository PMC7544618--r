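---
title: "Wide-field pRF mapping: model, simulation and analysis choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wide-field pRF mapping: model, simulation and analysis choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prfmapr)
```

# The mapping problem

Higher-order visual areas — posterior parietal cortex in particular —
contain neurons with large, coarsely organised receptive fields. Their
visuotopic organisation is hard to see with the classical 10–15°
checkerboard stimuli, but becomes measurable with *wide-field*
stimulation (about 80° of visual angle) combined with population
receptive field (pRF) modelling. `prfmapr` implements that analysis
chain end to end, together with a synthetic-data generator with known
ground truth, so every stage can be validated quantitatively.

The chain is:

1. **Stimulus** — binary aperture movies: a wedge (radius ~40°, angular
   extent 49°) rotating once per 44 s cycle, and a ring (constant width
   11°) whose mean eccentricity sweeps 0–40° per cycle. A run is a 10 s
   lead-in (the last 10 s of a cycle, so the response is in its
   periodic steady state) plus 5 full cycles: 230 s. A block-design
   motion localizer (four 6 s conditions × 3 repeats, 10 s baselines,
   202 s) is also provided.
2. **BOLD model** — the neural drive of a node with an isotropic
   Gaussian pRF $g(x, y) = \frac{1}{2\pi\sigma^2}
   e^{-((x-x_0)^2+(y-y_0)^2)/2\sigma^2}$ is its overlap with the
   aperture $A_t$: $d(t) = \sum_{x,y} A_t(x,y)\, g(x,y)\,\Delta^2$.
   The drive is convolved with a haemodynamic response function and
   sampled at the TR (2 s).
3. **Preprocessing** — PCA nuisance regressors from high-variance
   out-of-brain voxels, surface sampling at 7 points along the node
   normal (±0.75 mm) with percent-signal-change conversion, run
   averaging, harmonic filtering, and concatenation of the four run
   types into 88-sample vectors (22 TR per cycle × 4 types).
4. **pRF fit** — exhaustive grid search over positions × sizes;
   the candidate whose predicted 88-sample time course has the highest
   Pearson correlation with the data wins. $r > 0.5$ ($t = 5.35$,
   one-tailed $p < 10^{-6}$ at 86 df) thresholds the maps; pRFs outside
   the contralateral hemifield are discarded unless within 5° of the
   vertical meridian or within 2° of fixation.
5. **Maps and statistics** — polar-angle/eccentricity/size maps,
   profiles along paths, around 24 spokes and across 5 eccentric
   rings, border detection by gradient reversals, split-half
   reliability, and visual-field coverage as the 95% highest-density
   region of summed unit-mass Gaussians.

# Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| wedge radius / extent | 40 / 49 | deg | wide-field design; dwell = 49/360 × 44 ≈ 6 s per cycle |
| ring sweep / width | 0–40 / 11 | deg | matching eccentricity design |
| cycle / lead-in / cycles | 44 / 10 / 5 | s | 230 s runs, 22 TR per cycle |
| TR | 2 | s | sampling interval |
| HRF peak / undershoot / ratio | 4 / 10 / 6 | s, s, – | macaque BOLD peaks earlier than the human default; every routine takes the HRF as a parameter |
| position lattice | 201×201 over ±40 | deg | 40401 positions, 0.4° steps (full scale) |
| sigma lattice | 55 in [0.25, 35] | deg | log-spaced (resolves small pRFs; the spacing is configurable) |
| threshold | r > 0.5 | – | t = 5.35, p < 1e-6 at 86 df |
| PCA components | 18 | – | nuisance regressors from the top 10% variance out-of-brain voxels |

A note on the ring dwell: the literal geometry of an 11°-wide ring
sweeping 40° in 44 s stimulates a mid-eccentricity point for
11/(40/44) ≈ 12.1 s per cycle, not 6 s; `dwell_time()` reports the
geometric value and the test suite asserts it.

# The synthetic generator

`cluster_layout()` + `make_cluster_sheet()` build a "cloverleaf"
cluster: a disc of flattened cortex whose sectors each hold a
mirror-symmetric map of the contralateral field, sharing a foveal
confluence at the centre. Eccentricity grows linearly away from the
confluence (4 deg/mm over a 10 mm disc, reaching the 40° stimulus
edge); the polar-angle gradient flips sign at every sector border, so
a spoke profile around the centre shows exactly `n_sectors` gradient
reversals. Two sector styles set the size law: *sloped* sectors
(CIP-like) have σ = 2 + 0.25·eccentricity; *flat* sectors (PIP-like)
have constant σ = 8. These values give the large (several-degree) pRFs
typical of parietal cortex and make the size–eccentricity correlation
a discriminating statistic between the styles.

Noise is white Gaussian plus a low-order cosine drift plus shared
smooth nuisance components with random per-node weights (emulating
postural artefacts that also dominate out-of-brain voxels).
`noise_preset("moderate")` (white SD 4.5 in PSC units, drift SD 1.5,
nuisance SD 1) was calibrated once so that the default session — 24
runs per stimulus type, averaged before fitting — yields a median
goodness of fit of r ≈ 0.70 across the sheet, a realistic operating
point for parietal data; it is not revisited per experiment. The
split-half reliability experiment gives *each half* 24 runs so both
halves sit at that operating point.

What the generator does **not** emulate: cortical folding and
curvature (the sheet is flat; normals are parallel), spatial
correlation of noise within the grey matter, subject motion beyond the
shared nuisance components, physiological (cardiac/respiratory)
aliasing, and the irregular node spacing of real meshes. Passing tests
therefore validate the *analysis machinery* — they do not certify
performance on real data with those additional nuisances.

# Numerical choices

* **Aperture rasters.** Aperture geometry is defined in degrees and is
  resolution independent; analyses use small rasters (41–101 px)
  rather than the 700 px display raster. All four movies entering a
  grid build must share one raster geometry; ring movies are generated
  on the wedge raster, clipping the outer border.
* **TR binning before convolution.** Frames are averaged within each
  TR before the Gaussian overlap and HRF convolution (all linear
  operations, so the order is immaterial), which makes the 2.2-million
  candidate repertory a chain of matrix products.
* **Harmonic filter ≡ cycle averaging.** Retaining exactly the Fourier
  bins at multiples of the cycle frequency (DC excluded, harmonics up
  to Nyquist) and averaging the 5 cycles equals direct cycle averaging
  of the demeaned series; the FFT route is the reference
  implementation and the identity is asserted to 1e-10. The grid
  builder exploits the identity to express the whole
  data-processing chain as a single 22×T operator per run type.
  Lead-in samples (5 TRs) are dropped before filtering so exactly
  5 × 22 TRs remain. Because all operations are linear, averaging runs
  before or after filtering is equivalent (asserted in the tests).
* **Fitting.** Candidate predictions are stored standardised, so the
  Pearson correlation is a single matrix product; amplitude and offset
  are absorbed by the correlation, and no gain parameter is fitted.
  Candidates are scanned in blocks with a running maximum; the blocked
  scan is bit-identical to a single pass. Ties are broken toward the
  smallest σ, then the smallest eccentricity, then the lowest
  candidate index; constant series are flagged invalid rather than
  fitted.
* **Reduced grid.** Tests and demos use a 41×41 position lattice
  (2° steps) with 10 log-spaced σ values; the full 201×201×55 grid is
  available through `prf_grid_spec()`. Recovery oracles that demand
  exact recovery snap the ground truth to the search lattice first
  (`snap_sheet_to_grid()`): with on-lattice truth and no noise the
  pipeline must return every node's parameters exactly with r = 1,
  which is a sensitive end-to-end consistency check. Off-lattice truth
  is separately required to be recovered within one grid step.
* **Reversal detection.** Profiles are optionally smoothed by a moving
  average; zero gradients inherit the preceding sign; a sign change
  counts only if the new sign persists for `min_run` steps. Circular
  profiles (spokes) are scanned over two laps so runs crossing the
  wrap point are merged correctly.
* **Coverage.** "The area containing 95% of the density" is computed
  as a highest-density region (smallest superlevel set), which is
  well defined for multimodal sums, rather than a bounding box;
  Gaussians are summed with unit mass (an explicit choice — unit
  amplitude would up-weight large pRFs). The grid extends 3·max(σ)
  beyond the most eccentric centre so that truncated mass is < 1%.
* **Polar-angle averaging** in profiles uses the plain arithmetic mean:
  within a hemifield representation values are bounded in ±90° and do
  not wrap. Split-half angle differences are wrapped to ±180°.
* **Localizer GLM.** The baseline is modelled implicitly (no baseline
  column), so the "all conditions > baseline" contrast is the mean of
  the condition betas against zero — the standard identifiable
  parameterisation. Boxcars are built with fractional TR occupancy and
  convolved with the same configurable HRF.

# Known limitations

* σ is weakly identified at moderate SNR: at the median r ≈ 0.7
  operating point its split-half correlation stays low (~0.2) even
  with the fine σ lattice, because the predicted time course changes
  slowly with σ and the generator's flat-σ sectors leave little
  between-node variance. Position parameters (polar angle,
  eccentricity, x/y) are far more reliable, which mirrors practice:
  position maps drive delineation, size maps are secondary.
* The grid search is exhaustive by design (matching the analysed
  method); no gradient refinement, CSS exponent or
  difference-of-Gaussians variants are provided.
* Paths for path profiles must be supplied by the user or derived from
  the layout; the package does not infer them from the data.
* Volume-space preprocessing that real data would need upstream
  (slice-time correction, template registration, mesh construction) is
  out of scope; synthetic volumes are generated aligned.

# Problem sizes used in the shipped experiments

The test and acceptance experiments use a 200-node sheet, 61 px
aperture rasters, the 41×41×10 reduced grid and 24 runs per type
(48 for the split-half experiment); these sizes keep the full
validation chain comfortably on a laptop-class machine while leaving
every algorithmic path identical to the full-scale configuration.
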