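---
title: "Quantifying blood–brain-barrier leakage along the arteriovenous axis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying blood–brain-barrier leakage along the arteriovenous axis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

avleak analyses 3D two-photon image stacks of fluorescent-tracer-filled
cortical vasculature: it separates intraluminal from extravasated tracer,
quantifies leakage and perfused vessel density, and resolves diameters,
leak sites and constriction along the arteriovenous (AV) axis. This
vignette explains the models behind each stage, the tunable parameters and
their defaults, what the synthetic phantoms do and do not emulate, and the
design decisions taken where the problem left real choices open.

## The measurement model

### Tracing

Vessels are traced semi-automatically: the analyst supplies waypoints
(seeds) per vessel, and consecutive seeds are connected by the minimum-cost
path on the 26-connected voxel graph of the Gaussian-smoothed stack. The
cost of stepping into a voxel with intensity $I$ is

$$c = \ell \, \bigl(1 + \kappa / \max(I, \epsilon)\bigr),$$

where $\ell$ is the physical step length in µm (anisotropy-aware: the grid
is 0.58 × 0.58 × 1 µm by default), $\kappa$ defaults to the 99.9th
intensity percentile, and the floor $\epsilon$ (1 % of $\kappa$) prevents
blow-up in dark voxels. Bright lumen costs about $2\ell$ per step, dark
tissue about $100\ell$, so the optimal path follows the vessel rather than
the straight chord; inside a homogeneous lumen, all intensities tie and the
geometrically shortest (centered) path wins. Paths are resampled to ≤ 2 µm
spacing (default 1 µm). Seeds placed in dark voxels only warn — occluded
vessels are traced on the endothelial-reporter channel, where the lumen is
dark but the wall is labeled.

Smoothing uses a separable Gaussian with σ = 1 xy pixel by default; the z
sigma is scaled by the voxel anisotropy so the physical smoothing scale is
isotropic. The kernel is applied with half-sample-reflected boundaries,
which preserves flat fields exactly and conserves total intensity.

### Lumen filling

Filling grows a region from the traced centerline over 26-neighbours. A
voxel joins when its smoothed intensity is at least `thresholdFraction`
(default 0.3) of the median intensity along the path, and its geodesic
distance from the path, through accepted voxels, stays within `reachFactor`
(default 3) local radii. The threshold-fraction rule makes the fill
self-calibrating to the vessel's own brightness; the geodesic bound stops
bleed-through where strong extraluminal signal defeats edge detection —
the situation that in practice requires supervised correction, which enters
here as force-include/force-exclude voxel lists. The default 0.3 was fixed
so that noise-free phantom cylinders are recovered within 10 % of their
analytic volume; the threshold used is echoed into the output metadata.
When several vessels' fills overlap (branch points, touching vessels), each
voxel is owned by the vessel with the nearest centerline in µm, ties going
to the lower vessel id.

### Leakage ratio and compartments

`splitSignal()` partitions the stack voxel-exactly into luminal and
extraluminal components. The leakage measure is the ratio of
background-subtracted intensity sums,
$R = \sum I_{\mathrm{extra}} / \sum I_{\mathrm{lumen}}$, over the whole
z-stack. Normalizing extraluminal to luminal signal cancels global
intensity scale, hence tracer dose and day-to-day imaging quality. Sums
(volume-weighted) are the default aggregation; a mean-based variant is a
config switch. Because the point-spread function (PSF) smears luminal
signal a voxel or so past any segmentation boundary, a one-voxel guard ring
around the lumen is excluded from the extraluminal sum by default — without
it the pre-occlusion baseline of a perfectly tight vessel would not be
zero; even with it, a small positive noise floor remains in noisy stacks,
which is the expected behaviour of this measure in vivo.

Image planes near the meninges contain both brain parenchyma and
subarachnoid space because the brain surface is curved. Closed per-plane
region-of-interest polygons (rasterized on voxel centers, point-in-polygon
via `mgcv::in.out`) label the subarachnoid side; lumen voxels override the
ROI label, and the ratio is reported per compartment with the luminal
normalizer taken from the same compartment.

Perfused vessel density is the summed centerline length of perfused paths
divided by the imaged volume (µm/µm³). A path counts as perfused when the
median luminal intensity along it exceeds the background by a configured
factor (default 2; with zero background, 5 % of the stack maximum). Length
per volume (not per projected area) was chosen as the density definition
and is flagged in the output.

### Diameters and the AV axis

Diameter is the full width at half maximum (FWHM) of the intensity profile
along the in-plane line perpendicular to the local path tangent, averaged
over three adjacent perpendiculars 1 µm apart; the half level is relative
to the local profile peak after background subtraction (tails of the
profile), so the estimate is invariant under intensity scaling. Crossings
are located with sub-pixel linear interpolation. A profile that never falls
to half maximum (vessel leaving the field) is flagged unmeasurable rather
than guessed.

Axial optical sectioning biases in-plane FWHM low on small vessels: the z
blur mixes in planes where the circular cross-section is narrower, pulling
each half-maximum crossing inward by about $\sigma_z^2/d$. With
$\sigma_z = 0.5$ µm and capillary calibres this is ≈ 0.08 µm — negligible
for arteries, but a measurable fraction of a 6 µm capillary. When the
axial PSF sigma is known, `measureDiameter(axialSigma =)` removes the bias
by solving $d_{\mathrm{meas}} = d - 2\sigma_z^2/d$ for $d$; the recovery
experiments use this correction with the phantom PSF.

Classification applies the printed diameter bands — A > 45 µm, Ae 10–45 µm,
C < 10 µm, Ve 10–50 µm, V > 50 µm — treating the bounds strictly as
printed; because the bands overlap (10–45 is both Ae and Ve territory,
45–50 both A-adjacent and Ve/V), endothelial morphology (elongated =
arterial side, irregular = venous side, single-cell = capillary) and
topology (branches off an artery = Ae, converges to a vein = Ve) resolve
the ambiguity. Exact boundary diameters return the ambiguous candidate set
for flag resolution instead of an arbitrary pick. Morphology flags are
inputs (from the analyst or the phantom truth); extracting them from the
reporter channel automatically is out of scope.

Constriction is the post/pre diameter ratio of the same segment (a vessel
that branches counts as two new segments), reported as percent decrease
$(1 - d_{\mathrm{post}}/d_{\mathrm{pre}}) \times 100$.

### Local leak sites

Leak sites are 26-connected components of above-threshold extraluminal
signal (components smaller than 5 voxels are dropped as noise; a one-voxel
guard ring around the lumen is excluded so the wall-hugging PSF bleed does
not merge all sites into one). Each site is attributed to the vessel whose
wall is nearest to the site's intensity-weighted centroid, with wall
distance = centerline distance − local radius, clamped at zero. When the
two nearest walls differ by at most `tieToleranceUm` the attribution is
genuinely ambiguous and both vessels are returned; the default tolerance is
0.58 µm — one xy pixel — since sub-pixel wall localization is not
meaningful. Sites farther than `maxAttributionUm` (default 50 µm) from
every wall stay unattributed and are logged.

The spreading distance measures how far tracer has penetrated the
parenchyma: above-threshold site voxels are kept only if 26-connected,
through above-threshold voxels, to the wall (continuity — a detached bright
blob does not count); the site's length axis is the projection of its
support onto the attributed vessel's centerline; stations are placed every
`sampleInterval` µm (1–2 µm allowed, default 1 µm) along that axis; at
each station the maximal wall-to-voxel distance of continuous signal is
taken, and the station maxima are averaged. Distances are 3D physical µm
by default; a 2D in-plane mode is available since in-plane measurement is
what a single-plane analysis would produce. The default detection
threshold is background + 3 background-sd.

Progression compares matched site ids across two timepoints: strictly
increased spreading is persistent leakage, decreased is reduced or stopped
leakage; ties are reported separately, unmatched sites are excluded and
counted, and a paired t-test accompanies the summary as reporting plumbing.

### Infarct volumetry

For serial coronal sections of uniform thickness,
$V_{\%stroke} = \sum(\text{infarct area}) / \sum(\text{hemisphere area})
\times 100$; the thickness cancels and is only recorded. Masks are inputs;
color thresholding of stained photographs is out of scope, and no edema
correction is applied.

## The phantom model

The simulator produces stacks with complete ground truth so that every
operation above can be validated by parameter recovery.

**Geometry.** The default desk-scale volume is 256 × 256 × 64 voxels at
0.58 × 0.58 × 1 µm — the acquisition pixel size with the field scaled down
4× in xy; the full 1024 × 1024 field is available by configuration. The
vascular tree follows the cortical hierarchy: pial trunks (arteries and
veins) run roughly parallel near the surface in interdigitated lateral
lanes, penetrating arterioles and ascending venules dive from them into
the depth, and capillary paths spring from the distal arterioles and drain
into nearby venules (falling back to blind-ended segments where the
corridors are too crowded; phantom capillary paths stand for short chains
of capillary segments). Centerlines get a low-amplitude sinusoidal
tortuosity (1.2 µm amplitude, 45 µm period). Tubes may not intersect:
centerlines keep a clearance of the two radii plus 1 µm except at their
junctions, and placement failure raises an explicit error. Per-vessel
diameters are drawn from per-class normal distributions truncated to the
class band; generation is deterministic given the seed.

**Rendering.** Perfused lumina carry the tracer intensity, unperfused
lumina are dark; the reporter channel, when requested, renders a ~1.5 µm
wall shell for every vessel regardless of perfusion, mimicking an
endothelial cytosolic reporter. The lumen edge uses partial-volume
weights (the approximate voxel fraction inside the tube) rather than
binary center-in-tube voxelization, emulating detector integration over
the voxel and removing grid-phase artifacts. Each leak site adds a halo
decaying from the wall as a half-Gaussian of scale $S/2$ for planned
spreading distance $S$, clipped at the intensity floor
$A e^{-2}$ (where $A$ is the wall amplitude, default half the tracer
intensity) — so the most distant rendered signal sits exactly at $S$, and
a detection threshold of half the clipping floor recovers $S$ unbiasedly
from the blurred render. The volume is then convolved with a normalized
Gaussian PSF — default σ = (0.25, 0.25, 0.5) µm, the scale of a
high-numerical-aperture two-photon system — and optionally carries Poisson
shot noise and additive Gaussian read noise (default sd: 5 % of the tracer
intensity; no noise figures are standard, so this is a package default).
Compartment ground truth labels voxels above a spherical-cap brain surface
(sag `curvatureDepth`, default 0 = flat) as subarachnoid.

**Timepoints.** `applyTimepoint()` advances the truth: an exact count of
leak sites grows (factors 1.15–1.6) and the rest recede (0.5–0.85), and
every vessel constricts by a factor drawn from its class constriction
distribution truncated to (0, 1]. Planted directions are recorded so
progression calls can be scored against truth.

**What the phantoms do not emulate.** Hemodynamics, red-blood-cell
shadows, photobleaching, tracer washout over a session (luminal intensity
is constant per timepoint), motion artifacts, depth-dependent attenuation,
and endothelial-cell-scale texture. Passing the recovery suite therefore
demonstrates correctness of the geometric and photometric measurement
chain under controlled conditions — not robustness to every in vivo
nuisance; on real data the supervised-correction hooks (force
include/exclude, analyst seeds and ROIs) carry that load.

## Recovery experiments and study conditions

The acceptance surface treats published per-class statistics as generating
parameters and asks the chain to give them back:

* **Diameters** (`diameterRecovery`): cohorts of 29/28/236/190/29 cylinder
  phantoms per class with means 74.1/26.8/6.1/21.3/76.7 µm (sd
  14.5/8.0/1.2/8.9/25.0); draws follow these statistics directly, truncated
  only at a 1 µm physical floor — band truncation would shift the
  generating mean (by +6.6 µm for veins) and the class label is metadata
  for the geometry. Tolerance: two standard errors of the generating
  distribution.
* **Attribution** (`attributionRecovery`): 200 sites with class shares
  48 % Ve / 25 % C / 12.5 % Ae / 6.5 % A / 8 % V planted 1–8 µm outside
  their host wall in a 600 × 600 × 300 µm scene (planted positions are
  rejection-sampled to be genuinely nearest their host — a "leak from
  vessel X" placed inside vessel Y is not a valid ground truth site);
  recovered shares within ±5 points.
* **Spreading** (`spreadingRecovery`): 50 halos per class from
  14.1 ± 5.4 µm (artery), 13.9 ± 5.8 (vein), 6.0 ± 3.0 (capillary),
  measured through fill → split → extract → spreading; tolerance two
  standard errors. Renders are noise-free: these experiments isolate the
  geometric chain, and the noise floor is characterized separately by the
  leakage-ratio tests.
* **Constriction** (`constrictionRecovery`): per-class factors with mean
  decreases 26.5 (Ae) / 21.8 (A) / 20.6 (V) / 13.1 (Ve) / 11.3 (C) percent
  and sd 0.05 (a package choice; no per-class dispersions are standard),
  n = 14/7/16/128/113; recovered mean percent decrease within ±3 points.
* **Progression** (`progressionRecovery`): 100 matched two-timepoint
  sites, 67 planted increasing; recovered fraction within ±0.03.

Arteriole and venule spreading distributions are not separately published
for the acute phase; the generator defaults (10 ± 4 µm) interpolate between
the arterial/venous and capillary figures and are used only where a leak is
planted on those classes.

Problem sizes here are the published cohort sizes; the oracle-equivalence
suites (tracing vs. exhaustive Dijkstra, filling vs. exhaustive flood
fill) run 200 randomized trials on small stacks where the exhaustive
oracles are exact.

## Numerical choices and degenerate inputs

* Distances are physical µm everywhere; connectivity is 26-neighbour in
  all graph operations.
* Voxel centers sit at (index − ½) × pitch; arrays are ordered
  [y, x, z] (a TIFF page is one z-plane).
* Identical seed points are an error (degenerate path); a single-section
  mask set with zero hemisphere area is an error; a zero luminal sum flags
  the ratio undefined (NA) rather than erroring, since an all-dark stack
  is a legitimate (fully occluded) observation.
* Station binning uses `floor((arc - min(arc)) / interval)`; the final
  partial station counts.
* TIFF stacks are stored as 16-bit samples with the intensity scale and
  voxel sizes in a JSON sidecar (the TIFF writer does not expose
  resolution tags); a missing sidecar falls back to 0.58/0.58/1 µm with a
  warning. Masks are 8-bit label volumes with the id scale in the sidecar.
* Fill thresholds, tie tolerances and detection thresholds are echoed into
  output metadata for provenance; `pipelineRun()` writes the fully
  resolved configuration next to its outputs.

## Known limitations

* The fill acceptance rule (fraction of path-median intensity, geodesic
  reach bound) is this package's concrete formulation of
  edge-detection-based lumen filling; the stopping rule of interactive
  tools it emulates is not published, and filling operates on smoothed
  intensities (raw-intensity filling is a config switch).
* Strong wall-hugging extravasation can be captured by the fill (it is
  brighter than the acceptance threshold); this mirrors the in vivo
  situation where post-occlusion filling needs supervision, and the
  force-exclude hook is the remedy.
* In-plane FWHM underestimates small calibres without the axial-PSF
  correction; with an unknown instrument PSF the bias (≈ $2\sigma_z^2/d$)
  should be treated as part of the measurement.
* Whether spreading distances are best taken in 3D or in-plane is a
  protocol decision; both modes exist, 3D is the default.
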