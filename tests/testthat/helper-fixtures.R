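# Shared synthetic fixtures, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]]))
    .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

# small system with a few planted flips on both pathways
small_flip_system <- function() fixture("small_flips", function() {
  spec <- syntheticSpec(
    n_lipids_per_leaflet = 40, box = c(60, 60, 100), duration = 800,
    seed = 7,
    flip_schedule = data.frame(
      t_start = c(100, 250, 400, 550),
      pathway = c("groove_axis", "dimer_cleft", "groove_axis", "groove_axis")),
    n_partials = 2)
  c(buildSystem(spec), list(spec = spec))
})

# quiescent system (no events)
quiet_system <- function() fixture("quiet", function() {
  spec <- syntheticSpec(n_lipids_per_leaflet = 30, box = c(56, 56, 100),
                        duration = 400, seed = 5)
  c(buildSystem(spec), list(spec = spec))
})

# minimal hand-built trajectory: one protein residue (BB + SC1) and one
# lipid whose bead positions are scripted per frame by the caller
probe_residue_trajectory <- function(nc3_xyz, po4_xyz, nf) {
  beads <- data.frame(
    name = c("BB", "SC1", "NC3", "PO4", "GL1", "GL2", "C4A", "C4B"),
    residue_index = c(10L, 10L, rep(2L, 6)),
    residue_name = c("LEU", "LEU", rep("DOPC", 6)),
    chain_id = c("A", "A", rep("M", 6)))
  coords <- array(0, dim = c(8, 3, nf))
  coords[1, , ] <- c(0, 0, 0)
  coords[2, , ] <- c(0, 0, 1)
  for (f in seq_len(nf)) {
    coords[3, , f] <- nc3_xyz[f, ]
    coords[4, , f] <- po4_xyz[f, ]
    coords[5, , f] <- po4_xyz[f, ] + c(0, 0, -3)
    coords[6, , f] <- po4_xyz[f, ] + c(0, 0, -4.5)
    coords[7, , f] <- po4_xyz[f, ] + c(1, 0, -12)
    coords[8, , f] <- po4_xyz[f, ] + c(-1, 0, -12)
  }
  newTrajectory(beads, coords, 1, c(100, 100, 100))
}
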