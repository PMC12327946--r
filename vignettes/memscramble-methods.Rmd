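---
title: "Methods: detecting and quantifying lipid scrambling in coarse-grained trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and quantifying lipid scrambling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`memscramble` measures how a membrane protein scrambles lipids in a
coarse-grained (Martini-style) trajectory. This vignette documents the
measurement models, the parameters that matter, the synthetic-data
generator that backs the test suite, and the numerical choices made
where the procedures admitted more than one reasonable reading.

## The orientation-angle model of flip-flop

A phospholipid's position between leaflets is summarized by one angle:
θ(t) is the angle between the mean of the two choline-to-terminal-tail
vectors (NC3→C4A and NC3→C4B) and the +z membrane normal. A lipid
resting in the upper leaflet points its tails down, θ ≈ 150°; a
lower-leaflet lipid has θ ≈ 30°. The raw series is denoised with a
centered 100 ns running average, truncated at the trace edges (a
trailing window was rejected because it systematically biases the
detected completion time late).

Events are found by a two-state hysteresis machine on the smoothed
trace. The initial state is `upper` if the first smoothed value exceeds
90° and `lower` otherwise — lipids that happen to start inside the
intermediate band are assigned by the same rule rather than excluded,
which keeps the bookkeeping deterministic. An upper→lower event fires at
the first frame the smoothed angle drops below θ_low = 35°; a
lower→upper event fires above θ_high = 145°. These thresholds are
deliberately stringent: excursions that reach the middle of the band and
return ("partial" insertions into the groove) emit nothing. Each
completed crossing counts as one event, so a lipid that flips and later
flips back contributes two events, one per direction.

Two consequences of the smoothing are worth keeping in mind:

* the reported completion time lags the physical transit by up to about
  half the smoothing window (~50 ns at the defaults);
* events completing within roughly half a window of the trace ends are
  not resolvable, so the synthetic generator refuses to plant events
  within 80 ns of either end.

### Leaflet labels for surface averaging

Membrane-surface reconstruction needs a per-frame leaflet label for
every lipid. The label is the state of the same 35°/145° hysteresis
walk, but run on the **raw** angle trace. Running it on the smoothed
trace would be self-consistent with detection but delays every label
switch by the smoothing lag, during which a freshly flipped lipid
deposits dozens of glycerol observations onto the wrong leaflet's
surface, biasing the minimal thickness by several Ångström. The raw
walk switches at the end of the physical transit (where the raw angle
crosses the destination threshold), keeps the one-label-per-frame
invariant, and matches the planted transit ends of the generator to
within a frame or two. Resting-lipid noise cannot flip the raw state:
at the default noise level the raw angle sits ~20σ away from the
opposite threshold.

## Membrane surfaces and minimal thickness

Per frame, every glycerol bead (GL1, GL2) contributes its z coordinate
to the 1 Å × 1 Å xy cell containing it, split by leaflet label. The
cell height is the mean over frames of per-frame cell means, and the
occupancy is the fraction of frames with at least one contributing
bead. Cells below 2 % occupancy are discarded, then every retained cell
outside the largest 8-connected component of its leaflet is discarded
(isolated patches — e.g. a lipid parked in a protein vestibule — are not
membrane surface). Scatter-to-grid binning is used instead of a full
per-frame Delaunay interpolation; on smooth synthetic fields the two
differ by well under the grid noise, at a fraction of the cost.

The minimal membrane thickness is the **exact** minimum over all
retained upper×lower cell pairs of the 3D Euclidean distance between
cell centers — a point-pair distance, not a vertical thickness, because
at deep pinches the closest approach between the surfaces is oblique. A
pruned neighborhood search (seeded by co-located cell pairs, then
scanning only lateral offsets that can still beat the current best)
makes the exact minimum affordable on 10⁴-cell grids; the test suite
checks it against a literal all-pairs oracle. Both a global minimum and
a minimum restricted to a disk around the groove center are reported,
since the thinnest point of a scrambling system is typically at the
groove.

Because transiting lipids genuinely drag glycerol beads through the
membrane core, the global minimum of a system with planted flips dips
below the geometric deformation field near the transit corridors. That
is method behavior, not an artifact — vestibule and groove lipids are
exactly what thins these membranes in real systems. When the validator
compares against the generator's closed-form field value it therefore
excludes 12 Å disks around the planted corridors; the pipeline report
itself always carries the unexcluded values.

## Groove dilation and the competence gate

The groove width is the per-frame minimum distance over all bead pairs
between the TM4 and TM6 residue windows (backbone and side chains alike
— the most inclusive reading). The raw series feeds the median and
Q1/Q3 quartiles; a recursive exponentially weighted moving average
s_t = 0.1·x_t + 0.9·s_{t−1} (s_1 = x_1) feeds the open/closed flag at
the 6 Å threshold, so slow breathing is scored without frame noise
flicker. For a step input the EWMA reaches 95 % of the step in 29
frames, which sets the resolution of the open-fraction statistic.

A structure is classified scrambling-competent iff the minimal membrane
thickness is **below 14 Å** and the median groove width is **above
6 Å**. Both inequalities are strict; values exactly at a gate classify
as non-competent (arbitrary but documented, and configurable).

Default TM4/TM6 residue windows for the five structurally characterized
homologs ship with `grooveResidueDefaults()`. The TMEM16F TM4 window is
widely printed as "512–424", an apparent typo; the table uses 512–524
and says so in its documentation.

## Density pathways

Bead densities (headgroups, water, ions) are accumulated on a 0.5 Å
grid of default extent 100 × 100 × 150 Å centered on the groove (the
midpoint of the TM4/TM6 window centroids), after rigid per-subunit
alignment of every frame onto the first; grids from symmetric subunits
are averaged in this groove-local frame (averaging can be disabled for
asymmetric structures).

The membrane-spanning maximum-density pathway is extracted slab-wise:
within each one-cell-thick z slab the candidate is the densest cell
within 15 Å of the previous node, refined to the density-weighted
centroid of its 3×3 in-plane neighborhood. The walk starts at the
midplane slab and proceeds outward in both directions: at the membrane
core the groove is the only density and anchors the walk, whereas the
headgroup bands are laterally uniform and would let a band-seeded walk
drift before it reaches the core. Empty slabs are linearly interpolated
with a warning; more than 20 % empty slabs is an error. The extraction
is deterministic for a fixed grid.

The 4.7 Å capture radius then classifies each event: in-groove iff the
PO4 bead comes within 4.7 Å of any pathway node while its height is in
the middle half of the membrane span during the transit window
[t_enter_band, t_complete]. t_enter_band — the last frame still in the
origin band before the completing excursion — is this package's
operational definition of the transit start.

## Contacts and dwell times

A contact is a distance strictly below 7 Å between a residue's
outermost side-chain bead and a lipid's NC3 or PO4 bead. "Outermost" is
defined operationally as the side-chain bead with the largest mean
distance from the residue's backbone bead over the trajectory (topology
order breaks ties); glycine, having no side-chain bead, uses its
backbone bead. Contact runs separated by gaps of at most 6 ns merge
into one dwell, and dwell durations are inclusive of both endpoint
frames ((last − first + 1)·dt). Per residue, dwell lists are computed
against both headgroup beads and the bead with the higher mean dwell is
kept; with equal means the choline bead wins by convention. The
top-50 % summary averages the ⌈n/2⌉ longest dwells. Contact frequency
counts frames with ≥ 1 lipid in contact (lipid-wise accounting is
available through the per-lipid boolean matrix) and averages over the
monomers carrying the residue.

## Permeation and selectivity

Permeation uses a per-particle zone machine over below / inside /
above, with the membrane span (taken from the average surface heights)
widened by a 5 Å margin. A directed event is recorded when a particle
that last occupied one outer zone exits to the opposite one while being
within the 8 Å pathway tube at its midplane crossing; re-crossings
count separately, and particles that reach the midplane and retreat
count nothing. Totals and net flux are both derivable from the
up/down counts; the cation-to-anion selectivity P_Na/P_Cl is the ratio
of total counts (+∞ when only cations crossed, undefined when neither
did — markers, not errors). Martini water beads represent four waters;
counts are reported in bead events without rescaling.

## In-groove energetics and kinetics

The free-energy profile along the pathway is the Boltzmann inversion
G(s) = −kT·ln(ρ(s)/ρ_max) of the in-tube PO4 density, binned at 1 Å;
empty bins are flagged NA, never silently interpolated, and the barrier
is the maximum G over the membrane-spanning region (min G = 0 by
normalization). kT = 1 by default so barriers read in thermal units.

The transit dwell of an event is the contiguous in-tube stretch
containing its midplane crossing. The diffusion coefficient along the
pathway comes from the pooled mean-squared displacement of the
projected coordinate at lag times 1–10 ns inside transit windows,
fitted as MSD = 2Dτ through the origin with weights proportional to the
number of displacement pairs per lag. Both constructions are standard
reconstructions; the corresponding published analyses did not specify
their estimators, so bin width, lag range and tube radius are all
exposed in the configuration rather than fixed.

## The synthetic generator

`buildSystem()` renders a fully kinematic bilayer: no force field, no
energetics — every bead follows a script, which is what makes ground
truth exact.

* **Resting lipids** sit on a jittered lattice (area per lipid ≥ 40 Å²
  enforced), tilted 30° from the normal so resting angles are 150°/30°
  rather than degenerate 180°/0°, with the glycerol midpoint riding the
  leaflet surface field. The two glycerol beads share the anchor depth
  (small lateral branch offsets keep them distinct), so the glycerol
  surface sits exactly at ±bulk_thickness/2 (default ±15 Å) and the
  deformation minima have closed forms.
* **Noise** is isotropic per-bead Gaussian jitter (default σ = 1 Å),
  which induces ~5° of raw angle noise — comfortably inside the
  hysteresis band, so jitter alone produces no events. Lipids also
  diffuse laterally (wrapped 2D random walk, default 5 Å²/ns); without
  lateral diffusion a static lattice leaves most surface-grid cells
  empty and the occupancy/connectivity filters have nothing to work on.
* **Planted flips** move the headgroup along a declared pathway
  polyline (groove axis, dimer cleft, or custom) with the tails
  trailing, so θ sweeps 150° → 30° over the transit (default 20 ns);
  partial excursions turn around at ~55°/125° and return. Events are
  scheduled explicitly or by a Poisson process (exponential gaps,
  uniformly chosen resting lipids); completed flips hand the lipid over
  to the destination leaflet.
* **Deformations** are analytic: a Gaussian pinch of amplitude A gives
  an exact minimal thickness of bulk_thickness − 2A, and a sinusoidal
  field is available for non-radial shapes.
* **Tracers** transit the pathway tube monotonically at scheduled
  times; decoys oscillate near one face and may dip past the midplane
  without crossing, exercising the permeation counter's retreat logic.
* **Contact probes** are jitter-free scripted lipids parked at exact
  distances from a dedicated two-bead "contact post" residue placed at
  the membrane core, far from the transit corridors. Core residues of
  the TM scaffold itself genuinely collect contacts from transiting
  lipids — as in real systems — so exact interval recovery needs a
  residue only the probe can reach.
* The **scaffold** is rigid (two bead columns for TM4 and TM6, one
  glycine included to exercise the backbone fallback); a breathing mode
  oscillates the column separation as a square wave with a programmed
  duty cycle for open-fraction statistics.

What the generator does **not** emulate: collective membrane
undulations, correlated lipid motion, protein flexibility, solvent
hydrodynamics, realistic transit-path stochasticity, or any energetics.
Passing the suite therefore demonstrates that the estimators recover
what they are defined to measure under realistic geometry, sampling and
noise — not that the defaults are optimal for any particular real
force field or protein.

## Problem sizes and determinism

The test and acceptance workloads use systems the package's own
analyses were designed around: a 10 μs, 1 ns-per-frame detection
benchmark with 240 lipids (50 planted flips + 50 partials), a 100-flip
classification benchmark, 2.5–9 μs surface benchmarks at ~64 Å² per
lipid, a 6 μs breathing-groove series, ~60 k-sample Boltzmann
inversions and 50-seed Brownian ensembles. Everything stochastic flows
from a single integer seed; identical specifications rebuild bitwise
identical trajectories, and deterministic stages are byte-stable across
reruns.

## Known limitations

* Only PDB/GRO topologies and DCD/GRO/PDB trajectories are read;
  compressed GROMACS formats (XTC/TRR) must be converted first.
* PDB output truncates residue names to the format's 3 characters
  ("DOPC" → "DOP").
* The pathway extraction assumes a z-monotone, tube-like route; wildly
  tilted or branched pathways would need the (configurable) tube radius
  and z range adjusted.
* The diffusion estimator is an MSD reconstruction; published values
  obtained with a different (unspecified) estimator may differ
  systematically.
* Leaflet labels come from lipid orientation, not local midplane
  geometry; for strongly curved membranes (beyond the deformations
  studied here) a geometric assignment might be preferable.
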