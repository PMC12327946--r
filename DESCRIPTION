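Package: memscramble
Title: Lipid Scrambling and Membrane Deformation Analysis for Coarse-Grained Trajectories
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for quantifying lipid scrambling by TMEM16-family
    proteins in coarse-grained molecular dynamics trajectories. Detects
    per-lipid flip-flop events from headgroup-to-tail orientation angles with
    hysteresis thresholds, reconstructs ensemble-averaged leaflet surfaces and
    minimal membrane thickness from glycerol beads, tracks TM4-TM6 groove
    dilation, extracts maximum-density pathways from 3D bead densities,
    quantifies protein-lipid contact dwell times, counts directed water and ion
    permeation events, and profiles in-groove lipid energetics and kinetics.
    Includes a seeded synthetic-trajectory generator with planted ground truth
    so every stage can be validated without running molecular dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    bio3d,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'roles.R'
    'formats.R'
    'core_io.R'
    'synthetic.R'
    'scrambling.R'
    'surface.R'
    'groove.R'
    'density.R'
    'contacts.R'
    'permeation.R'
    'kinetics.R'
    'config.R'
    'pipeline.R'
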