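# avleak

Quantification of blood–brain-barrier (BBB) leakage, perfused vessel
density, and vessel-type-resolved hemodynamics along the arteriovenous (AV)
axis in 3D intravital two-photon image stacks, as acquired after
photothrombotic occlusion of a cortical artery in the mouse. The package is
aimed at labs analysing longitudinal two-photon z-stacks of
fluorescent-tracer-filled cortical vasculature who want the whole analysis —
tracing, lumen filling, signal separation, per-vessel statistics — as
scripted, reproducible R instead of interactive image-processing sessions.

## What it computes

* **Leakage ratio.** Vessels are traced semi-automatically (seed-guided
  minimum-cost paths on the 26-connected voxel graph of the
  Gaussian-smoothed stack), lumina are filled by intensity-constrained
  region growing from the traced centerlines, and the stack is split
  voxel-exactly into luminal and extraluminal signal. Leakage is the
  background-subtracted extraluminal-to-luminal intensity ratio over the
  whole z-stack, `R = Σ I_extra / Σ I_lumen` — invariant under global
  intensity scaling, so tracer dose and day-to-day imaging quality cancel.
  Per-plane region-of-interest polygons split the ratio between brain
  parenchyma and subarachnoid space.
* **Perfused vessel density.** Total centerline length of tracer-perfused
  vessels per imaged volume (µm/µm³).
* **AV-axis classification.** The five cortical vessel classes by diameter
  band — arteries (A) > 45 µm, arterioles (Ae) 10–45 µm, capillaries (C)
  < 10 µm, venules (Ve) 10–50 µm, veins (V) > 50 µm — with
  endothelial-morphology and topology flags resolving the overlapping
  bands. Diameters are full-width-at-half-maximum (FWHM) of the
  perpendicular in-plane intensity profile; constriction is the post/pre
  diameter ratio of the same segment.
* **Local leak sites.** Connected extraluminal components are attributed to
  the vessel with the nearest wall (centerline distance minus local radius;
  two vessels when equally close within one pixel), and their spreading
  distance is the station-averaged maximal wall-to-signal distance of
  continuous tracer, sampled every 1–2 µm along the site.
* **Leak progression.** Matched sites at two timepoints are classified
  increased/decreased; the fraction still increasing quantifies persistent
  leakage.
* **Infarct volumetry.** `V_%stroke = Σ(infarct area) / Σ(hemisphere area) × 100`
  over serial coronal sections.
* **Synthetic phantoms.** A first-class simulator renders 3D
  two-photon-like stacks — tubular vessel trees with the cortical hierarchy
  (pial trunks, penetrating arterioles/ascending venules, capillary bed),
  intraluminal tracer, extravascular leak halos, occlusion, constriction,
  PSF blur and noise — with complete ground truth, so every stage of the
  chain is testable without microscope data.

## Worked example

```r
library(avleak)

# a phantom with one arteriole feeding three capillaries draining into a
# venule, one of which leaks
spec <- phantomSpec(vesselCount = c(Ae = 1, C = 3, Ve = 1), seed = 42,
                    leaks = data.frame(vessel = "C", position = 0.5,
                                       spreading_um = 6, site_length_um = 15,
                                       onset = "t1"))
truth <- generateTree(spec)
stack <- renderStack(truth, spec, seed = 42)

# trace every vessel from its endpoints, fill, split, quantify
smoothed <- smoothStack(stack, 1)
paths <- lapply(truthPaths(truth), function(p) {
  ep <- pathPoints(p)
  traceVessel(smoothed, ep[c(1, nrow(ep)), ], vesselId = p@vesselId)
})
lumen <- mergeLumen(lapply(paths, function(p) fillLumen(smoothed, p)), paths)
s <- splitSignal(stack, lumen)
res <- leakageRatio(s$luminal, s$extraluminal, background = 5)
res
#> LeakageResult [t0]
#>   ratio total        : 0.0799
vol <- prod(dim(intensities(stack))) * prod(voxelSize(stack))
perfusedDensity(truthPaths(truth), vol, stack = s$luminal)
#> [1] 0.0001671358
```

The ratio (0.080) is the extraluminal tracer — here one planted 6 µm halo
plus the noise floor — normalized to the intraluminal signal; the density
(1.7 × 10⁻⁴ µm/µm³) is the perfused centerline length per volume of the
148 × 148 × 64 µm stack. Classification and per-site leak measurements work
the same way from `measureDiameter()`, `classifyVessel()`,
`extractLeakSites()` and `spreadingDistance()`; `pipelineRun()` chains all
stages and writes CSV/JSON reports, and `inst/scripts/avleak` exposes each
stage as a shell subcommand.

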