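---
title: "Mapping excitatory striatal inputs: models, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping excitatory striatal inputs: models, parameters, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(striomap)
```

This vignette documents the models behind each stage of `striomap`, the
parameters that matter, the numerical choices made where the design was
genuinely open, and what the synthetic validation does and does not
demonstrate about real tracing data.

## The data model

The quantitative substrate is the `projection_volume`: a 3D grid in which
each voxel holds the fraction of full-resolution imaging voxels inside it
that contained fluorescent axons, so values live in [0, 1]. The package
convention is axis 1 = anterior→posterior section index, axis 2 =
dorsal→ventral, axis 3 = medial→lateral, with voxel centers at
`(i - 0.5) * voxel_size_um` and the reference grid at 100 µm isotropic.
Binary masks (striatum outline, atlas nuclei, injection volumes) share the
same convention and are checked for grid compatibility at every operation
boundary. An `injection` pairs a *full* injection mask with its *core* — the
full mask eroded by 100 µm — and with the striatal projection field that the
injection produced. Fluorescence from fasciculated axons traveling through
the striatum without synapsing is assumed to have been excluded from the
projection fields upstream (`subtract_mask()` is the primitive for removing
any residual contamination by mask).

## Graded densities

Corticostriatal fields have a compact core of densely packed terminals and a
much wider sparse halo. `classify_density()` encodes this as an ordinal
scale: a voxel is **dense** when its fluorescence fraction exceeds 0.2,
**moderate** above 0.05, **diffuse** above 0.005, else **none**. All
comparisons are strictly greater-than, reading "over 20 %" literally; the
boundary fraction 0.2 itself is therefore moderate, which the test suite
pins down by bisection. Tier masks are cumulative by default (the diffuse
field includes moderate and dense voxels, making it the outer envelope);
`tier_mask(..., cumulative = FALSE)` switches to exclusive tiers.

## Sectioning alignment

A cut brain enters the pipeline as a stack of coronal sections that can be
rolled (rotated in-plane), pitched and yawed (aberrant sectioning angles
about the M-L and D-V axes), scaled per axis, and jittered section-by-section
in-plane. `correct_misalignment()` follows the classical recipe:

1. **Roll** is estimated per section from the midline — reconstructed as the
   perpendicular bisector of the segment joining the two hemisphere centers
   of mass — and undone in-plane, which cannot disturb per-section jitter.
2. **Pitch and yaw** are estimated against the template: yaw from the A-P
   offset between hemisphere centers of mass, pitch from the principal-axis
   angle of the A-P/D-V second-moment tensor. Both statistics transform
   exactly under rotation for any shape and are insensitive to zero-mean
   per-section jitter. The *template* is then rotated into the stack's
   sectioning frame. This ordering is essential: per-section jitter is only
   a per-section translation in the frame in which the brain was actually
   cut, so jitter removal must happen there, not after rotating the stack.
3. **Scales** are the per-axis ratios of spatial standard deviations between
   stack and rotated template. Moment-based extents were chosen over
   first/last-section spans and top-of-mask widths because they respond
   linearly to the planted scale and are unaffected by the ragged boundaries
   that repeated nearest-neighbor resampling produces.
4. **Per-section alignment** against the rotated template: the D-V shift
   from the section's center of mass (anchored by the anterior-commissure
   surrogate landmark where present, since anterior striatal sections are
   too variable to align on the striatum itself), the M-L shift from the
   center of mass of the dorsal half only. Shifts are rounded to whole
   voxels and iterated for two rounds. Sections with fewer than 10 % of the
   largest section's voxels are left untouched — end slivers otherwise
   produce unstable centers of mass.
5. The aligned stack is resampled back into template coordinates and given
   one more round of per-section alignment.

Alignment operates at 25 µm (the analysis grid upsampled fourfold),
reflecting that registration runs on section images, not on the 100 µm
voxelized data; at 100 µm a 2° pitch displaces most of the volume by less
than half a voxel and is unmeasurable in principle.

Two identifiability facts shape the validation. First, a linear-in-A-P trend
in the per-section shifts *is* a pitch/yaw rotation to first order, so the
generator defines jitter as trend-free (`random_section_jitter()` detrends
its white noise); otherwise the planted decomposition into "angle" and
"jitter" would not be unique. Second, the A-P scale renumbers sections, so
recovered shifts are compared to the planted jitter through the true section
remapping, at the tolerance of one 100 µm data voxel; the jitter-only round
trip recovers shifts exactly at the fine grid.

## Confidence maps

The thalamic origin of a projection to a target striatal field is localized
below injection size by exploiting heavily overlapping injections. Each
injection is scored against an ordered criteria set:

* graded targets (6-level map): projection covers ≥ 10 % of the diffuse
  target field; ≥ 5 % of the dense field; ≥ 50 % of the dense field;
* binary targets (8-level map): covers ≥ 10 % of the target; ≥ 10 % of the
  projection lies within the target; the same two at 25 %.

"Meets its cutoff" is at-or-above; the density tiers and network thresholds,
which quote "over"/">" wording, remain strictly greater-than. For each
criterion, four union masks are formed across injections — satisfying fulls,
satisfying cores, non-satisfying cores, non-satisfying fulls — and the map
gains +1 for each positive mask and −1 for the negative core mask; the
negative *full* mask is subtracted only for the two easiest criteria
(subtracting full volumes of failing injections is informative only while
the criterion is permissive enough that failure is surprising). "Easiest" is
determined empirically per run as the descending count of satisfying
injections, ties broken by the declared criteria order, and the ranking is
recorded on the returned object. After summation, thalamic volume inside
cores of injections that satisfied *no* criterion is zeroed, negative values
are clipped, and the map is restricted to the thalamus. A location inside
the cores of injections satisfying all criteria therefore reaches level
2 × (number of criteria): 6 or 8. Level sets are nested by construction, and
"covered by confidence level ℓ" in `nuclear_coverage()` means value ≥ ℓ.

The implementation is exercised against an independent per-voxel
accumulation oracle (explicit loops over voxels, injections and criteria)
with exact integer equality on 50 random scenes.

## Convergence and parcellation

`convergence_count()` counts, per voxel, how many subregion fields cover it;
`split_high_low()` splits the striatum at the mean count over striatal
voxels of the analyzed hemisphere, sending voxels exactly at the mean to the
low compartment. Diffuse convergence dominates dense convergence in the
mean by construction (diffuse fields are supersets); the elementwise version
of that dominance holds exactly on noiseless scenes but can break at
full-overlap ties by single noisy voxels, which is why the tests assert it
elementwise only at zero noise.

For parcellation the striatum is regridded to 150 µm: each fine voxel is
assigned to the coarse voxel containing its center (so the non-integral
100→150 ratio is handled), a coarse voxel is striatal if at least half its
fine voxels are, and its category per subregion is the plurality category
with ties resolved upward, preserving dense cores at boundaries. Voxels are
clustered on 1 − Spearman rank correlation between their 15-dimensional
signatures with average linkage; `select_distance_metric()` reproduces the
metric-selection step by comparing cophenetic correlation coefficients
across candidate metrics. Rows with zero variance (e.g. all-zero border
voxels) have no defined rank correlation; they get distance 0 to identical
rows and the maximal distance 1 to everything else, so they stay
clusterable. Dendrogram cuts drop single-voxel clusters and flag their
voxels unassigned. Sources are clustered identically on the transposed
matrix. Input-label permutation invariance and exact agreement with a naive
O(n³) average-linkage oracle (via cophenetic distance matrices, n ≤ 50) are
both under test.

## Circuit graphs

Primary cortical inputs to a striatal subdivision qualify by occupancy
(dense field covers > 20 % of the subdivision) or containment (> 50 % of the
dense field lies inside it). Corticocortical edges require projection
density > 15 % in the target; thalamic edges (thalamostriatal,
thalamocortical, corticothalamic) require > 20 % nuclear coverage; primary
convergent subregions require tier-averaged convergence > 50 %, where the
average runs over density-matched tiers and a tier whose target field is
empty is omitted from the mean (and recorded in `n_tiers`). All graph
cutoffs are strict, so edge sets are anti-monotone in every cutoff. Edges
are typed and checked against the legal node-class pairs; graphs round-trip
through edge-list CSV and GraphML.

## EPSC metrics

Traces are negative-going voltage-clamp currents. A recording is a
responder when any post-stimulus peak exceeds 6 × the baseline SD (strict);
a zero-variance synthetic baseline falls back to a configurable absolute
floor. Peaks are searched within [onset, onset + inter-stimulus interval)
to prevent bleed-through between train stimuli. Rise and decay times are
10 %–90 % crossing intervals, the decay measured relative to the post-EPSC
plateau so a sustained slow current does not inflate it; a plateau below
2 % of the peak is treated as zero to avoid biasing ordinary traces. The
paired-pulse ratio measures the second amplitude against the extrapolated
single-exponential tail of the first EPSC (fitted on [onset + 20 ms,
onset2)), switchable to a plain pre-stimulus mean; cells with first EPSC
weaker than −100 pA (inclusive bound) are excluded. Train dynamics report
per-stimulus amplitudes (local 2 ms pre-stimulus baselines) and 50 ms
charge-transfer episodes, both normalized to the first stimulus, and the
slow current as the change in the mean current 10 ms before the tenth
stimulus relative to 10 ms before the first, normalized to the first peak.
All metrics are invariant to a constant holding-current offset.

## What the synthetic generator emulates — and what it does not

`make_scene()` builds a bilateral striatum (tapered ellipsoids, wider
dorsally) with an anterior-commissure surrogate landmark; plants contiguous
subdivisions as Voronoi cells of k-means centers at the 150 µm working
resolution, so subdivision boundaries are exactly representable on the
clustering grid; paints each cortical subregion's field with a dense core
over its assigned subdivision, a moderate field over a second subdivision,
and a diffuse halo across the ipsilateral striatum (mirroring the
observation that diffuse projections span most of the striatal volume), plus
truncated Gaussian noise; and places thalamic injections (300 µm radius,
200 µm lattice spacing, jittered) whose union covers essentially the whole
thalamus, each with a 100 µm-eroded core and a projection field generated by
a planted linear thalamus→striatum map. Misalignment defaults are roll 3°,
pitch 2°, yaw −2°, scales 1.05/0.95/1.08, jitter SD one voxel — typical
histology-scale errors, fixed once.

Passing round trips on these scenes demonstrates that the *algorithms*
recover planted structure under category noise, heavy injection overlap and
realistic misalignment magnitudes. They do not demonstrate robustness to
what the generator omits: curved axon trajectories and fasciculated-bundle
segmentation errors, non-rigid tissue deformation, inter-animal anatomical
variability, partial-volume effects at the striatal boundary, or injection
volumes that leak outside the thalamus. The headline group statistics of
real datasets (mean convergent inputs per voxel, subdivision volumes,
cophenetic coefficients) depend on those real-data properties and are not
targets of the synthetic validation.

## Problem sizes and numerical conventions

The reference scene is a 32 × 26 × 40 grid at 100 µm (≈ 2 200 ipsilateral
striatal voxels, ≈ 700 voxels at 150 µm, 15 subregions, ≈ 100 thalamic
injections on a 16 × 12 × 14 thalamic grid with 6 nuclei); alignment runs on
the fourfold-upsampled stack. Validation uses 10 seeded scenes for the
alignment round trip, 20 for parcellation recovery (noise SD up to 0.05),
and 50 for the confidence-map oracle. Erosion/dilation use the discrete
ball under the weighted L1 metric (the 6-connected unit ball per voxel of
distance on an isotropic grid), honoring anisotropic voxel sizes per axis;
connected components use 6-connectivity with labels ordered by smallest
linear index; masks are resampled nearest-neighbor (preserving binarity)
and graded volumes trilinearly; empty coverage targets raise errors rather
than returning silent zeros; and voxels with no input everywhere are kept
in the clustering (they form a "none" cluster) rather than being dropped.
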