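# memscramble

Quantitative analysis of lipid scrambling in coarse-grained molecular
dynamics trajectories of TMEM16-family scramblases — and of any membrane
protein that moves lipids between leaflets through a membrane-spanning
hydrophilic pathway.

TMEM16 scramblases collapse lipid asymmetry by letting phospholipid
headgroups slide between leaflets along the hydrated TM4/TM6 groove (the
"credit card" mechanism). Simulation studies of these proteins all need
the same measurements: when did a lipid actually flip, did it flip
through the groove or elsewhere, how far is the groove open, how much
does the protein thin the membrane, how long do lipids dwell on which
residues, and how many waters and ions leak through. `memscramble`
implements this analysis stack for Martini-style coarse-grained
trajectories (beads NC3, PO4, GL1/GL2, C4A/C4B; BB/SC protein beads),
together with a seeded synthetic-trajectory generator that plants every
one of those observables as ground truth, so the whole pipeline is
testable without running molecular dynamics.

## What it computes

* **Flip-flop detection.** Per lipid, the orientation angle θ(t) between
  the mean of the two choline-to-tail vectors (NC3→C4A, NC3→C4B) and the
  membrane normal, smoothed with a centered 100 ns running average.
  Upper-leaflet lipids rest near 150°, lower-leaflet lipids near 30°; a
  scrambling event is a hysteresis crossing of the stringent 35°/145°
  thresholds (partial excursions into the intermediate band count
  nothing). Rates are block-averaged (1 μs blocks, mean ± population SD)
  and tested against a Poisson process (KS on inter-event gaps +
  dispersion index of block counts).
* **In/out-of-groove classification.** An event is "in the groove" when
  its PO4 bead passes within 4.7 Å of the maximum-density pathway while
  crossing the middle half of the membrane.
* **Membrane deformation.** Ensemble-averaged leaflet surfaces from the
  glycerol beads on a 1 Å grid with per-frame leaflet assignment, a 2 %
  occupancy filter and removal of disconnected patches; the minimal
  membrane thickness is the exact minimum 3D distance between any two
  points of the opposing surfaces.
* **Groove dilation.** Minimum TM4–TM6 bead distance per frame, smoothed
  with a recursive EWMA (α = 0.1); the groove counts as open above 6 Å,
  and a structure is scrambling-competent when it thins the membrane
  below 14 Å *and* holds a median groove width above 6 Å.
* **Density pathways.** 3D bead densities on a 0.5 Å grid in a
  subunit-aligned groove-local frame, with a slab-wise maximum-density
  pathway extraction.
* **Contacts and dwells.** Per-residue lipid contacts (outermost
  side-chain bead vs NC3/PO4, 7 Å cutoff), dwell times with 6 ns gap
  tolerance, choline-vs-phosphate bead choice by higher mean dwell, and
  top-50 % dwell summaries (exportable as B-factor-colored PDB).
* **Permeation and energetics.** Directed water/Na/Cl permeation counts
  through the pathway tube, P_Na/P_Cl selectivity from total counts,
  Boltzmann-inverted free-energy profiles G(s) = −kT ln ρ(s)/ρ_max of
  in-groove headgroups, and an MSD-based in-groove diffusion
  coefficient.

## Worked example

Build a small synthetic system with twelve planted flips (ten through
the groove, two at the dimer cleft) and run the core analyses:

```r
library(memscramble)

spec <- syntheticSpec(
  n_lipids_per_leaflet = 80, box = c(72, 72, 100), duration = 3000,
  seed = 11,
  flip_schedule = data.frame(t_start = seq(150, 2800, length.out = 12),
                             pathway = c(rep("groove_axis", 10),
                                         rep("dimer_cleft", 2))))
sys  <- buildSystem(spec)
traj <- sys$trajectory

angles <- lipidOrientationAngles(traj)   # theta(t) + 100 ns smoothing
events <- detectEvents(angles)           # 35/145 deg hysteresis
events <- classifyPathway(events, traj, syntheticPathway(spec), r = 4.7)
head(events, 3)
#>    lipid_id      direction t_complete t_enter_band pathway_class subunit
#> 7        95 lower_to_upper        209          112     in_groove       A
#> 10      128 lower_to_upper        450          352     in_groove       A
#> 12      160 lower_to_upper        690          593     in_groove       A

blockRate(events, duration = 3000)
#> Scrambling rate: 4.00 +/- 0.00 events/us (3 blocks of 1 us)

labels <- assignLeaflets(angles)
sp <- averageSurfaces(traj, labels)
mt <- minimalThickness(sp)
gs <- grooveStats(grooveDistanceSeries(traj, "A"), events)
classifyCompetence(mt$value, gs$median)
#> min thickness 27.8 A, median groove width 8.0 A -> "non_competent"
```

All twelve planted flips are recovered with their lipid identities and
directions; completion times lag the scripted transits by roughly half
the smoothing window, which is inherent to the 100 ns running average.
The scaffold here holds an 8 Å groove but rests in a flat bilayer, so it
is (correctly) not scrambling-competent by the thickness–width gate: the
global minimum thickness (27.8 Å, pulled slightly below the 30 Å bulk by
lipids transiting the groove corridor) stays far above the 14 Å
thinning criterion.

The end-to-end pipeline runs from one configuration:

```r
cfg <- readConfig(system.file("extdata", "fixture_config.yaml",
                              package = "memscramble"))
cfg$outdir <- "run1"
report <- runAll(cfg)            # writes events.json, groove.csv, ...
validateAgainstTruth(report)     # per-metric checks vs planted truth
```

A thin command-line front-end with per-stage subcommands is installed at
`inst/scripts/scramble-pipeline.R`.

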