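---
title: "Methods: lattice-referenced spatial statistics of signaling patches on micropillar arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lattice-referenced spatial statistics of signaling patches on micropillar arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pillarpatch)
```

## The problem

Developing hippocampal neurons plated at the interface between a flat
substrate and a bed of microfabricated pillars polarize toward the
topography: the N-cadherin crescent, the Golgi-centrosome complex, the first
sprout and eventually the axon all orient preferentially toward the pillar
side, and punctate phosphotyrosine (PY) signaling patches along the neurites
accumulate near pillar contacts for some pillar spacings. `pillarpatch`
implements the quantitative side of that analysis as a reusable, testable
pipeline:

1. recover the pillar lattice from a substrate-reflectance channel;
2. segment neurites (tubulin channel) and PY patches (punctate channel),
   excluding cell bodies;
3. test whether patches are attracted to, repelled by, or independent of the
   pillar lattice, using nearest point-to-event distances under a masked
   Monte Carlo null;
4. score ON/OFF polarity cohorts with binomial and chi-square inference;
5. measure neurite lengths and growth-cone areas.

Because no raw imaging data are distributed with this line of work, the
package also contains a first-class synthetic-scene generator with known
ground truth; every pipeline stage is validated against that truth.

## The spatial model

Each PY patch centroid is an *event*; the pillar centres are fixed
*observation points*. The statistic of interest is the distance from each
event to its nearest pillar centre. Under complete spatial randomness (CSR,
a homogeneous Poisson process of intensity $\lambda$ in the unbounded
plane), the nearest-distance CDF is closed-form:

$$G(r) \;=\; 1 - e^{-\lambda \pi r^2},$$

implemented in `csr_closed_form()`. Real neurites, however, confine the
events to a union of thin, disjoint regions (the soma-excluded neurite
mask), for which $G$ is intractable. The null model is therefore *patched
CSR* (pCSR): CSR restricted to the mask. `simulate_pcsr()` realizes it by
drawing patch centres uniformly over the mask -- a mask pixel is sampled and
the centre jittered uniformly within that pixel, so placement is
continuous-uniform over the masked region -- and recording exact nearest
pillar distances.

Per image, `analyze_image()`:

* computes the observed nearest-distance CDF and summarizes it by the
  distance at its 50% level (`d50`); the mean distance is always reported
  alongside, and a `statistic` switch selects which one drives the
  inference, since condition summaries in this literature are printed as
  mean distances while per-image envelopes are read off at the 50% CDF
  level;
* simulates `n_reps` pCSR replicates with the observed patch count on the
  observed mask;
* forms a 95% envelope from the 2.5th/97.5th linear-interpolation
  percentiles of the replicate statistic, and one-sided Monte Carlo rank
  p-values
  $p = \bigl(1 + \#\{\text{replicates} \le \text{observed}\}\bigr)/(m+1)$
  (ties counted as exceedances, i.e. conservatively).

Across the images of one spacing condition, `aggregate_condition()` averages
the observed statistic and both envelope borders -- each border is a random
variable whose sample mean estimates its population value -- and calls
*attraction* when the mean observed statistic falls below the mean lower
border, *repulsion* above the mean upper border, *neutral* otherwise.

### Validation oracle

`lattice_distance_cdf()` is an analytic oracle used only for validation: the
exact CDF of the distance from a uniform random point to the nearest centre
of a perfect square or hexagonal lattice, from circle-segment geometry on
one Voronoi cell (apothem $p/2$; circumradius $p/\sqrt2$ square, $p/\sqrt3$
hexagonal). With a full-frame mask, `simulate_pcsr()` must reproduce it; the
test suite requires sup-norm agreement better than 0.02 at $10^4$
placements, and the same analytic curve is checked against brute-force
quadrature.

## The synthetic generator and what it does (not) emulate

The generator encodes the study conditions the analysis assumes:

* **Lattice** (`lattice_spec()`/`make_lattice()`): pillar diameter 1--5.6 um
  and edge-to-edge spacing 0.6--15 um, hexagonal by default (square
  available, since fabricated arrays appear in both arrangements); pillars
  occupy the half plane beyond a flat/pillar interface. Pixel size defaults
  to 0.1 um/px, a typical confocal sampling; neither the original
  magnification nor noise statistics are published, so these defaults are
  asserted, not derived.
* **Neurites** (`generate_neurite_mask()`): disk somata (radius 5 um) with
  2--4 smooth random-walk tubes of width 2 um, a realistic hippocampal
  neurite calibre at this scale. Real tuj-1 morphology (branching, varying
  calibre, crossing fascicles) is not emulated; the mask only needs the
  statistical property the null requires -- a thin, disjoint, soma-free
  domain.
* **Patches** (`patch_model()`/`place_patches()`): mean area 0.331 um^2 with
  mildly right-skewed Gamma(shape 4) areas, and a patch count set so total
  patch area is ~15% of neurite area (observed densities run 13--18%).
  `mode = "pcsr"` places centres uniformly over the mask (the null);
  `mode = "attraction"` draws a fraction `alpha` of centres with Gaussian
  weights $e^{-d^2/2\sigma^2}$ in the nearest-pillar distance $d$,
  restricted to the mask -- an implementation of a truncated-Gaussian pull
  toward pillar centres, used as the alternative-hypothesis generator.
  Centres are mask-bound; disks may overhang the mask edge, as real patches
  abut neurite boundaries. Consequently the *clipped* coverage reported by
  `patch_density()` sits slightly below the generator's target.
* **Rendering** (`render_scene()`): three channels (pillar disks, cell mask,
  patch disks) with optional additive Gaussian noise; amplitude 1, so
  `noise_sd = 0.1` is SNR 10. Photophysics, PSF blur and background
  gradients are out of scope, so passing segmentation tests demonstrate
  correctness of the machinery, not robustness to every real-world imaging
  artefact.

Every generator takes an explicit seed and is a pure function of it; there
is no hidden global random state.

## Segmentation choices

Thresholds default to Otsu (the original analysis states only
"thresholded"); connected components use 8-connectivity; objects under 10 px
and patches under two pixels' area are discarded as noise. Cell bodies are
excluded by a width criterion -- regions whose distance-transform half-width
exceeds 1.5 um (half of `max_neurite_width_um = 3`) seed a soma that is
grown back to the cell outline and removed if larger than 20 um^2 -- since
the original soma "cut out" rule is unpublished. Pillar components smaller
than 25% of the nominal pillar area are treated as noise, which keeps
partially visible edge pillars.

## Polarity inference

`score_onoff()` formalizes visual ON/OFF scoring: a marker is ON when its
centroid lies more than `tie_epsilon_um` (default 0.1 um) past the line
through the soma centroid parallel to the interface, on the pillar side;
cells inside the dead zone are unclassified, mirroring cells "not
sufficiently polarized" that the original cohorts excluded.
`proportion_sem()` reports the ON percentage with the binomial standard
error $\sqrt{\hat p(1-\hat p)/n}$; `chisq_gof()` applies a 1-df chi-square
against the null fraction (0.5 at an interface; 0.25 for
`quadrant_golgi_test()`, where ON means the Golgi falls within 45 degrees of
the axon direction) *without* continuity correction -- that choice
reproduces the published significance pattern exactly (e.g. 73/112 gives
p < 0.05 while 64/109 gives 0.05 < p < 0.1). The bundled
`polarity_cohorts()` table carries the published cohort sizes and
percentages; the first-sprout "±" values in that table equal $100-\hat p$
rather than any binomial SEM -- the package reports binomial SEMs and
documents the discrepancy instead of replicating it.

## Morphometry

The original neurite-length numbers came from a proprietary semi-automated
tracer whose algorithm is not public; `pillarpatch` substitutes a documented
definition: the cell mask is thinned to a topology-preserving skeleton
(Zhang-Suen), path lengths are geodesic distances along the skeleton graph
(diagonal steps $\sqrt2$ px) from the soma region to each tip, plus the
distance-transform radius at the tip (thinning erodes blunt ends by about
their half-width). The longest path stands for the axon; the mean is over
all root-to-tip paths. Absolute published lengths are therefore matched only
qualitatively on synthetic data -- fixtures with known geometry are matched
to within one pixel. Tips closer than 1 um to the soma are suppressed as
skeletonization whiskers; detached mask fragments without a soma are
skipped.

## Numerical and design choices

* Replicate count per image is configurable (`n_reps`, default 999; the
  original count is unpublished). Batch experiments in the test suite and
  acceptance script use 199 replicates, which fixes the p-value granularity
  at 1/200 and keeps hundreds of images cheap; a 95% envelope requires at
  least 40 replicates (2/(1-level)).
* Distances are measured patch centroid to pillar *centre*; the pillar
  radius is retained in the lattice object so edge distances can be derived.
* Pixel centres sit at $(i+0.5, j+0.5)\cdot$`pixel_size` (0-based indices);
  all distances are exact Euclidean distances in micrometres -- no
  approximate nearest-neighbour search.
* Problem sizes used in the validation experiments: type-I calibration uses
  200 synthetic null images (spacing 2 um, density 15%) and checks the 5%
  attraction test rejects in 2--9% of them; power uses attraction scenes
  (`alpha = 0.5`, `sigma = 0.3` um), 11 images per condition, 50 repeats,
  requiring the attraction verdict in at least 90%; oracle equivalence uses
  $10^4$ placements. These sizes give the experiments stable Monte Carlo
  behaviour at desk scale.
* The published condition-level distance table cannot be reproduced
  numerically without the original confocal images, which were never
  deposited; the package instead proves the *properties* of the method
  (oracle equivalence, calibration, power, monotonicity of mean distance in
  spacing) on synthetic data.

## Known limitations

* The soma-exclusion width rule and the Otsu defaults are stand-ins for
  unpublished manual steps; on real images they would need checking against
  a few hand-annotated cells.
* The attraction generator biases patch centres by nearest-pillar distance
  only; it does not model attraction to pillar *edges* or anisotropic
  growth-cone geometry.
* The "touching" vs "covering" soma classification is taken as an input
  label; no geometric rule is implemented for it.
* Skeleton-based lengths differ from proprietary-tracer lengths on real,
  noisy masks; only the definition, not the original implementation, is
  reproduced.
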