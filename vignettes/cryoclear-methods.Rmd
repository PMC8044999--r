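---
title: "Models and methods in cryoclear"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in cryoclear}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

cryoclear re-creates, as tested software, the analysis chain of an episcopic
cryomicrotome tracer-clearance experiment: two fluorescently labeled
dextrans (3 kDa Texas Red, 500 kDa fluorescein, 30 mg/mL in artificial CSF)
are co-infused into the mouse hippocampus (1.0 µL at 0.1 µL/min), the animal
is frozen and shaved in 45 µm slices with the block face photographed after
every cut (4096² pixels, 16-bit, 15 µm in-plane), and the reconstructed
volumes are segmented at a fixed per-tracer threshold to quantify where the
tracers went. Because no raw image data are deposited with the study, the
package ships a synthetic phantom that emulates the whole acquisition, so
that every downstream stage — artifact repair, isotropic reconstruction,
segmentation, volumetry, presence scoring, and the clustered-binary and
rank statistics — runs end to end against data with known ground truth.

This vignette explains the models, the defaults, and the design decisions
that the function reference only states.

## The phantom

### Stylized anatomy

`build_anatomy()` paints a primitive assembly — ellipsoids, boxes, cylinders
and shells — onto an isotropic voxel grid whose axis 1 is the cutting axis
(index 0 at the thorax, increasing toward the nose; voxel centres at
`(i + 0.5) × pitch`). It is *not* a real atlas: the goal is a label volume
with the right topology and calibrated volumes, not realistic shapes. Two
volumes are calibrated against published morphometry for the mouse strain
involved: whole-brain parenchyma (453.2 mm³) and hippocampus (25.7 mm³).
The brain's lateral semi-axis and the hippocampal primitive were sized
analytically so that, after the internal CSF spaces are carved out, the
painted label volumes land within the voxelization error of those targets.

Precedence is a fixed paint order in which later primitives overwrite
earlier ones; in particular all CSF labels override parenchyma ("CSF wins"),
which is what carves ventricles and cisterns out of the brain. The CSF
system is built to satisfy a connectivity contract, checked by
`csf_path_connected()`: one 6-connected CSF component touches the
hippocampus border (the interpeduncular cistern, which abuts the ventral
hippocampus), the nasal turbinates (via a cribriform channel through the
skull base), and the spinal nerves (via a spinal subarachnoid sleeve around
the cord). The ventricular chain lateral → third → fourth likewise drains
into the subarachnoid space. Beyond the 13 scored structures the atlas
carries auxiliary labels — residual brain, skull, muscle, blood vessels, a
spinal SAS sleeve, embedding medium — needed for threshold calibration,
autofluorescence, and transport.

The default grid is a desk-scale phantom: geometry at `scale = 0.5` on a
90 µm isotropic grid (≈ 700k voxels), which keeps a full 10-mouse cohort
simulation plus reconstruction in the minutes range on one core. All
geometry is stored at full scale in mm and scaled at paint time, so
`phantom_spec(scale = 1)` gives the full-size mouse (used for the
volumetric calibration checks), and `pitch_um = 45` with
`render_upsample = 3` reproduces the instrument's native geometry when
memory allows.

### Infusion

Infusion is modeled as instantaneous filling of the extracellular space
(ECS) of a spherical tissue region: infusing volume $V$ into tissue with
ECS fraction $\alpha$ (default 0.2) replaces the interstitial fluid of
$V/\alpha$ of tissue — 5.0 mm³ for the study's 1.0 µL. No cavity or
backflow is modeled. Concentrations are stored as bulk (tissue-homogenised)
values and the deposited concentration is normalised so that the
grid-summed mass equals the infused mass exactly, making mass bookkeeping
sharp from the first step. The infused volume scales with `scale³` so that
scaled phantoms receive a geometrically consistent bolus.

### Transport

`simulate_spread()` advances each tracer with an explicit 6-neighbour
finite-difference diffusion scheme (harmonic-mean face diffusivities, so a
zero-diffusivity neighbour blocks flux; no-flux outer boundaries) plus two
advective mechanisms:

* **Compartment-graph transfer.** First-order transfer across the voxel
  interfaces of a directed graph: hippocampus → interpeduncular cistern →
  subarachnoid spaces → {nasal turbinates, spinal cord → spinal nerves},
  and lateral → third → fourth ventricle → SAS. The per-pair rate is
  `csf_transport_rate_s` (default 0.02 /s).
* **Bulk SAS flow.** Upwind drift along the cutting axis within the
  subarachnoid labels — rostrally toward the cribriform plate, caudally
  toward the spine — at `csf_flow_um_s` (default 8 µm/s full scale, scaled
  with the phantom). This emulates the directional CSF bulk flow that
  carries solutes to the exits; without it the thin SAS shell is
  dispersion-limited and tracer never reaches the nose within 90 min.

Default diffusivities follow a Stokes–Einstein-style $MW^{-1/3}$ scaling
anchored at 70 µm²/s for the 3 kDa dextran (free diffusivity reduced by
tortuosity); the 500 kDa tracer gets ≈ 12.7 µm²/s. Within CSF an effective
dispersion coefficient of 1500 µm²/s (size-independent, mixing-dominated)
applies to both tracers; muscle gets 0.3× the parenchymal value; bone,
vessels and embedding medium are impermeable. These absolute values are
configuration, not claims about tissue physics; what the tests rely on is
their ordering (small > large; CSF ≫ parenchyma), which produces the
study's qualitative pattern: the small tracer distributes further, and
distal structures are reached during the additional 80 min, not during
infusion.

The time step defaults to 0.9× the explicit-scheme stability bound
$h^2/(6 D_{max})$; a user-supplied `dt` above the bound is refused with the
bound in the error message. Mass is conserved to floating-point rounding on
a closed domain (asserted to < 10⁻⁶ relative over 90 simulated minutes);
optional first-order absorption in the exit structures is book-kept on the
returned field so that the balance still closes.

### Rendering

`render_slices()` converts concentration fields into the instrument's raw
output: per slice and channel,
`intensity = gain × concentration × exposure + autofluorescence(structure) + N(0, σ)`,
clipped to [0, 65535] and quantised; stuck pixels are then overwritten.
Exposures default to the study's 6000 ms (green/fluorescein), 8000 ms
(red/Texas Red) and 500 ms (reflection). Autofluorescence is per structure
and channel, with the short-wavelength channel strongly elevated in the
nasal turbinates and blood vessels — the feature that forces a high green
threshold, exactly as in the real experiment. The in-plane pixel grid is
`render_upsample = 3`× finer than the simulation grid, reproducing the
3:1 pitch ratio (15 µm pixels under 45 µm slices) that the reconstruction
stage must undo. With a fixed seed the rendering is bit-identical across
runs; camera defects (default 5 hot pixels at 65535) are placed once per
"camera" in `run_experiment()`, so all mice of a cohort share them.

The gain default (6 counts per mg/mL·ms) puts the detection limit — the
calibrated threshold translated back into concentration — near 0.01 mg/mL
in the red channel and 0.09 mg/mL in the green channel. The near-site
signal saturates the 16-bit range, as it plausibly did in the original
acquisitions; saturation is harmless to threshold segmentation.

## Reconstruction

The pre-processing contract is: repair stuck pixels on the raw slices,
then block-average in-plane to the slice thickness, then stack — in that
order (a test asserts that reversing repair and rescale leaks defects into
segmented volumes). Stuck-pixel repair assigns the median of the 8
neighbours, edge-truncated, excluding other flagged pixels; the median of
an even count is the mean of the central order statistics. Detection (for
when no camera defect map exists) flags pixels that are constant across
all slices *and* deviate from their per-slice 8-neighbour median by more
than `k = 10` MADs in ≥ 90% of slices; image borders are never flagged.
The 15 → 45 µm reduction is non-overlapping 3×3 block averaging — not
decimation or interpolation — because block means preserve total signal,
which is what volumetry integrates; results stay floating point until
export. Means are preserved exactly, and the reduction factor must be an
integer (anything else is refused rather than resampled).

## Segmentation and quantification

The threshold rule formalises what the study describes qualitatively:
examine tracer-free regions and set a fixed per-channel threshold high
enough that autofluorescence is never segmented. `estimate_threshold()`
takes the `q = 99.95` percentile of intensities in the background labels —
bone, muscle, and the autofluorescent vessels and nasal turbinates — and
multiplies by a safety factor `s = 1.1`. Including the autofluorescent
structures in the calibration set is what guarantees the green channel
excludes nasal autofluorescence (verified by a test in which no tracer has
reached the nose and zero nasal voxels segment). The threshold is estimated
once per channel (on the first mouse processed) and reused unchanged for
every mouse, mirroring the study's constant-threshold policy.

Segmentation is pure thresholding with the boundary rule `intensity ≥
threshold` (voxels *below* the threshold are excluded, so equality is
kept). No component filtering is applied by default; `min_component`
exists as an explicit opt-in. The dispersion volume is voxel count ×
voxel volume, exactly.

Meshes are the 0.5-level isosurface of the binary mask under
nearest-neighbour interpolation — equivalently the boundary surface of the
voxel set — with vertices at voxel corners in physical µm and outward
winding. This choice (rather than a smoothing marching-cubes variant) ties
the mesh to the voxel volumetry exactly: the signed-volume sum over faces
equals count × voxel volume, so the two volume estimates cross-validate
sharply. The surface is watertight per connected component provided no two
mask voxels touch only along an edge or corner; such non-manifold contacts
are possible for adversarial masks and are a known limitation.

## Presence scoring

Observer scoring is replaced by an explicit rule: a structure is present
when at least `min_voxels = 2` segmented voxels fall inside its label. One
voxel would let a single residual noise voxel score a structure; two is
the smallest count robust to that. Blinding and inter-observer agreement
are not emulated — the rule is deterministic. `tabulate_proportions()`
reports per-cell proportions to 2 decimals, and
`counts_from_proportions()` inverts printed proportions back to integer
counts, flagging any cell whose printed value no feasible count reproduces
(deviation > 0.01) instead of silently resolving it. The reference table
contains exactly one such cell (fourth ventricle, small tracer, 10-min
group, printed 0.14 under n = 3); the worked reproduction resolves it to
count 1, the value consistent with the reference analysis's own reported
odds ratio, and records the override in its output.

## Statistics

### Binary GEE

`fit_gee_binary()` implements the marginal logistic model
$\operatorname{logit} P(y_{ij} = 1) = \beta_0 + \beta_1 x_i$ for presence
outcomes clustered by mouse, solved by Fisher scoring on the GEE score
equations with an exchangeable working correlation re-estimated each
iteration by the moment estimator from Pearson residuals. Choices that the
original SPSS analysis leaves unstated, and how they were fixed:

* **Working correlation: exchangeable** — the conventional default for
  repeated binary measures. The choice is deliberately low-stakes: for a
  cluster-level covariate with equal cluster sizes the GEE point estimate
  collapses to the pooled 2×2 odds ratio *regardless of ρ*, a closed-form
  identity the suite asserts to 10⁻⁶ on the reference fixtures and on
  random tables.
* **Dispersion fixed at 1** (binomial), matching the usual binary-outcome
  default. This also makes the sandwich estimator reduce *exactly* to the
  model-based covariance in the saturated single-covariate model with
  singleton clusters (for binary y, $\sum (y-\bar y)^2 = n\bar y(1-\bar y)$),
  which the suite asserts numerically.
* **Errors: cluster-robust sandwich**, with Wald 95% CIs as
  $\exp(\hat\beta_1 \pm 1.96\,SE)$ and a two-sided Wald p. No small-sample
  correction is applied. The reported CIs and p-values depend on which
  mouse carried which structure — information a proportion table does not
  contain — so the package asserts point estimates only and treats its own
  CI/p output as assignment-dependent.
* **Separation**: a covariate group with all-equal outcomes has no finite
  estimate and is refused with an explicit error, as is a covariate that
  varies within a cluster.

When expanding count tables to mouse-level outcomes, positives are
assigned to the lowest-numbered mice of each group. Any assignment yields
the same point estimate (above); the correlation and SEs vary with it.

### Exact Mann–Whitney

`mann_whitney_exact()` enumerates all $\binom{n_1+n_2}{n_1}$ assignments of
the pooled observations — the right regime for 3 + 7 samples — computing
$U_1$ from mid-ranks and reporting $U = \min(U_1, U_2)$. The default
two-sided p doubles the exact lower-tail probability
$P(U_1 \le U_{obs})$ and caps at 1, the usual convention for small exact
tests (the null distribution of $U_1$ is symmetric under enumeration, with
or without ties, so this equals R's exact Wilcoxon p for tie-free data —
asserted in the suite). Summing both tails of the min-statistic is exposed
as `method = "min_statistic"`. Samples beyond $n_1+n_2 = 15$ are refused
with a pointer to normal-approximation tests rather than silently
approximated. The test's attainable p-values are discrete; at $n_1 = 3,
n_2 = 7$ the smallest two-sided p is 2/120 ≈ 0.017, and a 10,000-replicate
null simulation in the suite confirms the size at nominal 0.05 stays
conservative.

## The cohort runner

`run_experiment()` glues the stages into the full two-group, two-tracer
design. Per-mouse seeds derive from the master seed as
`seed × 1000 + counter`, so enlarging the cohort never reshuffles earlier
mice. Per-mouse variability comprises the infusion-site jitter (SD 0.1 mm
per axis), a lognormal diffusivity multiplier (CV 0.15) shared by both
tracers of a mouse (it is one brain), and rendering noise; the atlas and
the camera-defect map are cohort-level. Group durations are total time
since infusion start (10 and 90 min), treating the infusion bolus as
deposited at t = 0 — during-infusion spreading is emulated by the first
10 min of transport rather than by a moving source. Outputs (volume and
presence tables, proportions, GEE and rank-test results, PLY meshes, JSON
manifest with every seed and threshold) are byte-reproducible from
(config, seed).

## What the phantom does and does not show

Tests passing on the phantom establish that the *pipeline* is faithful:
pre-processing implements the stated operators exactly, volumetry recovers
known ground truth to voxelization error, the threshold rule excludes
autofluorescence, presence scoring and the statistics reproduce the
reference effect sizes from the reference inputs, and the simulated cohort
reproduces the qualitative pattern (ubiquitous hippocampal presence;
further spread of the small tracer; distal structures reached only after
the additional spreading period). They do *not* validate the biology: the
anatomy is stylized, transport is a three-mechanism caricature
(diffusion + compartment graph + uniform SAS drift) without perivascular
microstructure, optics are a linear gain without PSF or shine-through, and
the absolute dispersion volumes of the real study (its Fig. 3) depend on
unpublished instrument thresholds and are deliberately not targeted.
Problem sizes in the shipped tests — half-scale geometry on a 90 µm grid,
20-seed Monte-Carlo for the size-ordering property — are the package's
default desk-scale conditions; the full-resolution configuration is
config-gated, not test-gated.
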