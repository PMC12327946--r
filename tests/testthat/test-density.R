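# 3D density accumulation, pathway extraction, OpenDX round-trips.

static_bead_traj <- function(xyz, nf = 50, role_name = "PO4") {
  beads <- data.frame(name = role_name, residue_index = 1L,
                      residue_name = "DOPC", chain_id = "M")
  coords <- array(rep(xyz, each = 1), dim = c(1, 3, nf))
  coords[1, 1, ] <- xyz[1]; coords[1, 2, ] <- xyz[2]; coords[1, 3, ] <- xyz[3]
  tr <- newTrajectory(beads, coords, 1, c(60, 60, 60))
  tr@aligned <- "A"
  tr
}

test_that("a static bead lands all its counts in exactly one cell", {
  tr <- static_bead_traj(c(3.1, -2.2, 7.4))
  g <- accumulateDensity(tr, "lipid_phosphate", c(0, 0, 0),
                         extent = c(40, 40, 40))
  expect_equal(sum(g@counts), 50)
  expect_equal(sum(g@counts > 0), 1)
  # unaligned input is refused with an instruction
  tr@aligned <- character(0)
  expect_error(accumulateDensity(tr, "lipid_phosphate", c(0, 0, 0)),
               "alignSubunit")
})

test_that("density is invariant to frame order and additive in frames", {
  sys <- quiet_system()
  traj <- sys$trajectory
  ctr <- c(28, 28, 0)
  g1 <- accumulateDensity(traj, "lipid_head", ctr, extent = c(60, 60, 60),
                          spacing = 1)
  perm <- sample(nFrames(traj))
  tr2 <- newTrajectory(traj@beads, traj@coords[, , perm],
                       seq_along(perm) - 1, traj@box)
  tr2@aligned <- "A"
  g2 <- accumulateDensity(tr2, "lipid_head", ctr, extent = c(60, 60, 60),
                          spacing = 1)
  expect_equal(g1@counts, g2@counts)
  # doubling frames doubles every count
  tr3 <- newTrajectory(traj@beads,
                       array(c(traj@coords, traj@coords),
                             dim = c(nBeads(traj), 3, 2 * nFrames(traj))),
                       seq_len(2 * nFrames(traj)) - 1,
                       rbind(traj@box, traj@box))
  tr3@aligned <- "A"
  g3 <- accumulateDensity(tr3, "lipid_head", ctr, extent = c(60, 60, 60),
                          spacing = 1)
  expect_equal(g3@counts, 2 * g1@counts)
})

test_that("two mirrored subunits average to the single-subunit grid", {
  beads <- data.frame(name = c("PO4", "PO4"), residue_index = 1:2,
                      residue_name = "DOPC", chain_id = "M")
  coords <- array(0, dim = c(2, 3, 20))
  coords[1, , ] <- c(10, 10, 5); coords[2, , ] <- c(-10, -10, 5)
  tr <- newTrajectory(beads, coords, 1, c(60, 60, 60))
  tr@aligned <- c("A", "B")
  g2 <- accumulateDensity(tr, "lipid_phosphate",
                          list(c(10, 10, 0), c(-10, -10, 0)),
                          extent = c(20, 20, 20))
  g1 <- accumulateDensity(tr, "lipid_phosphate", list(c(10, 10, 0)),
                          extent = c(20, 20, 20))
  expect_equal(g2@counts, g1@counts)
})

# analytic Gaussian tube density around a lateral centerline cx(z), cy(z)
tube_grid <- function(cx, cy, sigma = 2, extent = c(40, 40, 40),
                      spacing = 0.5, weight = 1) {
  dims <- as.integer(extent / spacing)
  org <- -extent / 2
  xs <- org[1] + (seq_len(dims[1]) - 0.5) * spacing
  ys <- org[2] + (seq_len(dims[2]) - 0.5) * spacing
  zs <- org[3] + (seq_len(dims[3]) - 0.5) * spacing
  counts <- array(0, dim = dims)
  for (k in seq_along(zs)) {
    d2 <- outer((xs - cx(zs[k]))^2, (ys - cy(zs[k]))^2, "+")
    counts[, , k] <- weight * 1000 * exp(-d2 / (2 * sigma^2))
  }
  new("DensityGrid", origin = org, spacing = spacing, counts = counts,
      n_frames = 1, n_chains = 1)
}

test_that("pathway extraction follows straight and curved density tubes", {
  g <- tube_grid(function(z) 1.2, function(z) -0.8)
  p <- extractPathway(g, z_range = c(-15, 15), tube_radius = 10)
  expect_lt(max(abs(p@nodes[, 1] - 1.2)), 0.5)
  expect_lt(max(abs(p@nodes[, 2] + 0.8)), 0.5)
  expect_true(all(diff(p@nodes[, 3]) > 0))
  # helical arc with 8 A lateral excursion
  gh <- tube_grid(function(z) 8 * cos(z / 8), function(z) 8 * sin(z / 8))
  ph <- extractPathway(gh, z_range = c(-15, 15), tube_radius = 10,
                       start = c(8, 0))  # tube center at the midplane
  err <- sqrt((ph@nodes[, 1] - 8 * cos(ph@nodes[, 3] / 8))^2 +
              (ph@nodes[, 2] - 8 * sin(ph@nodes[, 3] / 8))^2)
  expect_lt(max(err), 1.0)
})

test_that("of two parallel tubes the denser one is followed at every slab", {
  g1 <- tube_grid(function(z) -6, function(z) 0, weight = 2)
  g2 <- tube_grid(function(z) 6, function(z) 0, weight = 1)
  g <- g1; g@counts <- g1@counts + g2@counts
  p <- extractPathway(g, z_range = c(-15, 15), tube_radius = 15)
  expect_true(all(p@nodes[, 1] < 0))
  expect_lt(max(abs(p@nodes[, 1] + 6)), 0.6)
})

test_that("OpenDX grids round-trip bit-compatibly", {
  set.seed(3)
  g <- new("DensityGrid", origin = c(-5, -5, -5), spacing = 0.5,
           counts = array(rpois(8 * 6 * 10, 3), dim = c(8, 6, 10)),
           n_frames = 10, n_chains = 1)
  f <- tempfile(fileext = ".dx")
  exportGrid(g, f)
  back <- readDX(f)
  expect_identical(back@counts, g@counts + 0)
  expect_equal(back@origin, g@origin)
  expect_equal(back@spacing, g@spacing)
  # an empty grid writes a valid all-zero field
  gz <- new("DensityGrid", origin = c(0, 0, 0), spacing = 1,
            counts = array(0, dim = c(3, 3, 3)), n_frames = 0, n_chains = 1)
  fz <- tempfile(fileext = ".dx")
  exportGrid(gz, fz)
  expect_equal(sum(readDX(fz)@counts), 0)
})
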