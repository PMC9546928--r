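---
title: "Cortical bone fluorescence morphometry: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cortical bone fluorescence morphometry: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(osteomorph)
```

# Scope and scientific setting

Cortical bone in larger laboratory species remodels through basic
multicellular units organized around Haversian canals, and its osteocytes
can themselves resorb perilacunar and pericanalicular matrix ("osteocytic
osteolysis"), visible as enlargement of the lacuno-canalicular system
(LCS). Frequent intermittent dosing of PTH-class anabolic agents produces a
characteristic cortical phenotype — increased porosity with rough pore
margins, endosteal new bone (bone area up, marrow area down, multiple
calcein labels on the endosteal surface), expanded Haversian canals, and an
inner-lamella-specific expansion of lacunae and canaliculi — while
infrequent dosing leaves the cortex largely unchanged.

`osteomorph` implements the measurement side of that biology as a tested
pipeline over calibrated fluorescence images: rule-based and
classifier-based segmentation, 2D and 3D shape morphometry, cortical layer
partitioning, calcein surface classification, and many-to-one Dunnett
statistics. Because animal imagery of this kind is rarely shareable, the
package also ships a parametric phantom generator whose outputs carry exact
ground truth; all quantitative claims in the test suite are claims about
the pipeline's behaviour on phantoms and on analytic geometry, not about
any animal dataset.

# The phantom generator

`phantom_spec()` describes one synthetic specimen. A 2D "section" is a
wavy cortical annulus (low-order Fourier perturbations of the endosteal
and periosteal radii) populated with:

* **Lacunae** — ellipses with semi-axis statistics per layer (defaults
  4.5 × 2.1 µm mean, tangentially oriented with von-Mises-like wobble,
  several hundred per mm² of cortex). Absolute lacunar density and size
  are configurable order-of-magnitude presets; published values vary
  widely across species and sites.
* **Haversian canals** — circles (default mean radius 11 µm) confined to
  the mid-cortical band and placed around cluster centers, reflecting the
  clustered appearance of remodeling canals.
* **Cortical pores** — larger irregular voids (Fourier-roughened
  boundaries). A pore `area_fraction` may be requested directly; the
  generator then solves for the pore count/radius and records the analytic
  boundary polygon of every pore, so truth areas are exact up to
  rasterization.
* **Calcein bands** — curves parallel to each surface at configured
  offsets. Each surface is divided into angular sectors whose label class
  (quiescent, eroded, single, double, multiple) is sampled with spatial
  persistence; labelling fronts are contiguous, so isolated single-sector
  runs are absorbed. Eroded sectors scallop the surface itself
  (amplitude 2.5 µm, wavelength 14 µm). Multiple labels are rendered only
  when the effect profile enables them.
* **Rendering** — structures are painted at configured gray levels over a
  constant-plus-gradient background, Gaussian-blurred (default 0.5 µm),
  and given additive Gaussian noise, clipped to 8-bit (sections) or 12-bit
  (stacks). Poisson shot noise is deliberately omitted: additive noise
  already stresses thresholding without modelling the microscope.

A 3D "stack" is a block of mineralized matrix with ellipsoid lacunae and
tubular canaliculi (straight to gently curved, constant diameter per tube,
defaults 0.5 ± 0.08 µm diameter and 15 ± 4 µm length) radiating from their
surfaces. Truth records every canaliculus path, length and diameter as
generative values. Explicit object tables (`lacuna_params$explicit`,
`canaliculi_params$explicit`) allow constructing exact test geometries
through the same rendering path.

`effect_profile()` carries the treatment phenotype: per-layer multipliers
on lacunar volume and canalicular diameter, a Haversian-canal area
multiplier, a porosity-rate multiplier, an endosteal new-bone band width,
and a multiple-label probability. The control profile is the identity.
Volume multipliers act on each semi-axis as the cube root, so group mean
volumes scale exactly by the multiplier in expectation.

`generate_cohort()` derives independent per-specimen seeds from a master
seed. `render = "none"` samples exactly the same geometry tables without
rasterizing, which makes large statistical simulations on cohort truth
cheap; the tables are identical to those of a rendered specimen with the
same seed because geometry sampling and rendering consume separate RNG
streams.

**What the phantoms do not emulate:** optical point-spread physics,
spectral properties of the Villanueva stain, vascular content of canals,
lamellar collagen texture, and spatial correlation of noise. Passing tests
therefore demonstrate correctness of the measurement algorithms under a
plausible image-formation model, not robustness to every microscope
artifact.

# Segmentation

`binarize_by_rule()` implements interactive-style binarization: foreground
strictly above an intensity threshold, then removal of components below a
physical minimum size. The reference rules are threshold 12 with
size > 90 µm for cortical porosity and threshold 200 with size > 15 µm for
calcein. The size is interpreted as an *equivalent circular diameter*: an
area reading of "90 µm²" would remove almost nothing at the 0.64 µm pixel
scale, whereas a 90 µm diameter cleanly separates resorption-scale pores
from canals and lacunae. An `area` mode is available.

The trainable recognizer is a multiscale-feature random forest: per-pixel
Gaussian smoothings, gradient magnitudes and differences of Gaussians at
0.5–4 µm scales (physical units, so models transfer across calibrations),
trained on a balanced pixel sample from `n_train` images chosen
deterministically from a seed, with `num.threads = 1` so predictions are
bit-reproducible. There is deliberately no per-image intensity
normalization: trainable-segmentation tools of this class operate on raw
feature stacks, and it is exactly the section-to-section staining and
exposure variability that makes recognition quality grow with the number
of training images. `phantom_pool()` emulates that variability by drawing
background, matrix autofluorescence, lacuna brightness (with per-lacuna
jitter), blur and noise per image from wide, overlapping ranges.

"Successful recognition" is defined at the object level: a truth object
counts as recognized if a predicted component reaches IoU ≥ 0.5 with it
under greedy one-to-one matching (ties broken by higher IoU, then lower
truth label). The pixelwise F1 is reported alongside as a secondary
metric. `training_curve()` evaluates fresh deterministic training subsets
per size and replicate on held-out images and compares each size against
the smallest by the package's own Dunnett test.

# 2D morphometry

Boundaries are traced at sub-pixel resolution: the object mask is smoothed
with a 1-pixel Gaussian and its 0.5 iso-contour extracted by marching
squares. This estimator was chosen over chain-code perimeters because no
step-weighting scheme satisfies both calibration identities at once —
√2-weighted chains overestimate smooth perimeters by ~5 % (disk
circularity ≈ 0.90), and corner-count corrections break the square. The
iso-contour estimator measures disk circularity 0.990 and square
circularity 0.792 (π/4 = 0.785) at the rasters used in the tests.

Axis lengths come from the second-moment best-fit ellipse (length/width =
4√eigenvalue), with the pixel variance term added so single-pixel objects
remain finite; Feret-style measures were rejected as noisier on rasters.
Smoothness is the convex-hull perimeter divided by the outer perimeter: 1
for convex shapes (the hull of the traced contour equals the contour),
lower for scalloped margins. Perimeters are outer-only; hole boundaries do
not contribute. Objects clipped by a region-of-interest border are
excluded from per-object statistics but keep their pixels in total-area
ratios, which keeps shape statistics unbiased without losing area.

# Layers

The marrow cavity is identified topologically (largest enclosed cavity of
the ring) rather than by intensity, for robustness to staining variation.
The cortex is partitioned by the normalized transmural coordinate
`u = d_endo / (d_endo + d_peri)` from Euclidean distance transforms to the
marrow and to the outside; inner lamella `u < f_in`, outer lamella
`u > 1 − f_out`, Haversian lamella between, with defaults
`f_in = f_out = 0.25`. The boundaries of the anatomical lamellae are not
operationally defined in histology; distance-normalized bands are the
reproducible choice, the fractions are configuration, and user-supplied
layer masks can override the partition entirely. The "Haversian lamella"
is taken as the geometric mid-band rather than "wherever canals occur";
with clustered canals a canal-presence definition would be unstable at
this sample size.

# Calcein surface classification

Surfaces are resampled at a fixed arc-length step (default 2 µm; the step
divides the perimeter exactly, so class lengths sum to the total by
construction). At each sample an inward probe (default depth 10 µm)
counts distinct calcein bands as runs of foreground along the normal;
≥3 bands → mL, 2 → dL, 1 → sL. Unlabelled samples are eroded (E) when the
standard deviation of signed curvature in a 20 µm window exceeds a
threshold, else quiescent (Q). Neither the probe depth nor the roughness
rule has a published operational definition, so both are configuration;
the default threshold 0.055 µm⁻¹ was calibrated on phantoms, where
scalloped sectors separate cleanly from smooth ones (5th percentile of
eroded roughness 0.071 vs 95th percentile of smooth roughness 0.047 at
2-pixel contour smoothing). Band identity is resolved by connected runs,
so labels that touch merge into one band — the conservative reading.

Dynamic rates (mineral apposition, bone formation rate) are deliberately
not computed: they require inter-label interval semantics per surface that
a static section cannot certify.

# 3D morphometry

Lacunae and canaliculi are separated by local thickness. The distance
transform supplies a thickness proxy 2·EDT; voxels above the start
set-point `d_start` (default 0.6 µm) seed lacuna cores, which a dilation
by `d_start/2` (computed as a distance threshold to the core set) closes
back to the true boundary; the remainder is canalicular, except components
whose maximal thickness stays below the end set-point `d_end` (default
0.3 µm, with a half-voxel guard for unfavourable grid phases) or whose
volume is below 0.02 µm³ (rasterization crumbs at junctions). The two
set-points are an operational reinterpretation of commercial filament-
tracing start/end diameters as thickness bounds — faithful in effect, not
in mechanism. Note the definition's inherent boundary: a tube whose
diameter reaches `d_start` *is* a lacunar body under this rule, so
validation sweeps over 0.4–1.0 µm diameters run with the set-points
bracketing the sweep (`d_start = 1.5`), while 0.6/0.3 remain the defaults
for real LCS acquisitions.

Surface areas are measured by meshing the 0.5 iso-surface of the 1-voxel
Gaussian-smoothed indicator with marching tetrahedra; bare voxel-face
counting overestimates smooth surfaces by up to ~1.5× and would destroy
sphericity. At the test rasters the mesh reproduces a sphere's area to
0.3 % and a 12 µm cube's sphericity within 1.5 % of (π/6)^(1/3).

Canaliculi are traced on the 26-connected voxel graph of each component,
edge weights scaled toward medial (high-EDT) voxels. Paths are extracted
by iterative geodesic farthest-point sweeps from the lacuna-adjacent seed
set (free-floating tubes first locate a true endpoint by a double sweep);
each branch-free path is one canaliculus, so a Y-shaped tree yields two
records — the count convention is documented rather than guessed, and
whole-tree accounting can be recovered by grouping records on their parent
lacuna. Length is the chord-resampled centerline arc length (0.5 µm
chords remove lattice zig-zag; a straight tube of any orientation measures
within 2.5 %). Diameter is twice the mean centerline EDT: near-axis
voxels read slightly below the radius and the lattice reads slightly
above, and the two nearly cancel (bias −0.02…−0.09 µm over 0.3–1.2 µm
cylinders; mean absolute error 0.075 µm at 0.1 µm voxels in the
validation sweep). Component voxels are apportioned to their geodesically
nearest path, so branch volumes conserve the mask volume exactly.
Anisotropic stacks are handled by physical-unit distance transforms and
graph weights throughout; no resampling is performed.

Orientation statistics treat axes as undirected: angles are folded to
[0°, 90°] before the standard deviation is taken, and the statistic is
equivariant under joint rotation of axes and reference.

# Statistics

Group summaries use the n−1 standard error; singleton groups report a
missing SE rather than zero. The many-to-one comparisons are classical
equal-variance Dunnett: pooled variance, one t statistic per treatment
against the shared control, familywise adjustment through the exact
multivariate-t dependence of the contrasts (correlation
√(nᵢnⱼ/((nᵢ+n₀)(nⱼ+n₀)))), evaluated by deterministic-seeded numerical
integration. With a single treatment the procedure reduces to the pooled
two-sample t test (verified to 10⁻³), and the simulated familywise error
at four groups of ten is 0.050 ± 0.005. Zero-variance degeneracies are
reported at the floating-point floor rather than as NaN.

Object-level rows are aggregated to per-specimen means before testing by
default — specimens are the experimental units; per-object testing (a
pseudo-replication choice the user must own) is available by flag.

# Validation design and problem sizes

The test suite and `scripts/acceptance.R` compute everything from code at
run time. Problem sizes were chosen to keep the full suite near five
minutes on one CPU: 0.1–0.2 µm rasters for shape identities, 50 random
ellipses against Ramanujan's perimeter approximation, four-diameter
sweeps on ~260×140×90 stacks, a 40-image training pool with 10 held-out
images and five replicates, 10⁴ null simulations for the familywise
error, and 20 seeded cohort replicates of 4 groups × 10 specimens for the
layer-specificity power property.

That last property deserves its exact statement: with a 1.5× inner-lamella
lacunar-volume effect in the frequent-dosing group, the pipeline must flag
that group's contrast in the inner lamella (power) while leaving the same
contrast unflagged in the other two lamellae (specificity). The power
simulation runs on cohort ground-truth tables through the layer and
statistics modules: the sampling, aggregation and testing chain is what
carries the statistical property, while the accuracy of the measurement
chain that would feed it is validated separately (measured lacunar volumes
track truth to within rasterization error, a far smaller perturbation than
the biological variance simulated here). Rasterizing and re-measuring 800
confocal stacks per run would add hours of compute without changing what
the property tests.

# Known limitations

* The phantom's image-formation model is additive-Gaussian on ideal
  geometry; classifier performance on real Villanueva-stained material
  will differ, and the 16-image training recommendation is a property of
  the phantom pool's variability, not a universal constant.
* Local-thickness separation is undefined at diameters near `d_start`;
  real canaliculi approaching 0.6 µm will fragment between the two
  compartments.
* The marching-squares/tetrahedra estimators are calibrated for structures
  ≥ ~10 pixels/voxels across; single-digit-voxel objects carry
  rasterization error larger than the quoted tolerances.
* Dunnett assumes equal variances; an unequal-variance variant is not
  implemented, matching the classical procedure.
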