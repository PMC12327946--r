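# Trajectory I/O, subunit alignment and equilibration trimming.

test_that("GRO round-trip preserves coordinates to format precision", {
  sys <- quiet_system()
  traj <- sys$trajectory
  sub <- newTrajectory(traj@beads, traj@coords[, , 1:3], traj@times[1:3],
                       traj@box[1:3, ])
  f <- tempfile(fileext = ".gro")
  writeGRO(sub, f)
  back <- loadTrajectory(f)
  expect_equal(nBeads(back), nBeads(sub))
  expect_equal(nFrames(back), 3)
  # GRO stores nm with 3 decimals: 0.01 Angstrom precision
  expect_lt(max(abs(back@coords - sub@coords)), 0.0051)
  expect_equal(back@times, sub@times, tolerance = 1e-6)
})

test_that("the same coordinates read back identically via GRO+DCD and PDB", {
  sys <- quiet_system()
  traj <- sys$trajectory
  sub <- newTrajectory(traj@beads, traj@coords[, , 1:4], traj@times[1:4],
                       traj@box[1:4, ])
  gro <- tempfile(fileext = ".gro"); dcd <- tempfile(fileext = ".dcd")
  pdb <- tempfile(fileext = ".pdb")
  writeTrajectory(sub, gro, dcd)
  writeTrajectory(sub, pdb)
  via_dcd <- loadTrajectory(gro, dcd)
  via_pdb <- loadTrajectory(pdb)
  expect_equal(nFrames(via_dcd), 4)
  # DCD is float32: ~1e-4 relative precision at these magnitudes
  expect_lt(max(abs(via_dcd@coords - sub@coords)), 1e-3)
  # PDB stores 3 decimals in Angstrom
  expect_lt(max(abs(via_pdb@coords[, , 1] - sub@coords[, , 1])), 0.0011)
  expect_equal(via_pdb@beads$name, sub@beads$name)
})

test_that("unknown bead names fail loudly, naming the offenders", {
  beads <- data.frame(name = c("NC3", "XYZ"), residue_index = c(1L, 1L),
                      residue_name = "DOPC", chain_id = "M")
  expect_error(assignRoles(beads), "XYZ")
  f <- tempfile(fileext = ".gro")
  writeLines(c("bad", "1",
               sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", 1L, "DOPC", "XYZ",
                       1L, 1, 1, 1),
               "  10.0 10.0 10.0"), f)
  expect_error(loadTrajectory(f), "XYZ")
})

test_that("alignment inverts rigid translations and rotations exactly", {
  sys <- quiet_system()
  traj <- sys$trajectory
  sub <- newTrajectory(traj@beads, traj@coords[, , 1:5], traj@times[1:5],
                       traj@box[1:5, ])
  ref <- sub@coords[, , 1]
  # translate later frames
  moved <- sub
  for (f in 2:5) moved@coords[, , f] <- ref + rep(c(5, 0, 0), each = nBeads(sub))
  al <- alignSubunit(moved, "A")
  for (f in 2:5) expect_lt(max(abs(al@coords[, , f] - ref)), 1e-6)
  # rotate 90 degrees about z around the selection centroid
  R <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3)
  rot <- sub
  for (f in 2:5) rot@coords[, , f] <- ref %*% R
  al2 <- alignSubunit(rot, "A")
  idx <- which(sub@beads$chain_id == "A" & sub@beads$name == "BB")
  for (f in 2:5)
    expect_lt(sqrt(mean((al2@coords[idx, , f] - ref[idx, ])^2)), 1e-6)
})

test_that("alignment matches the bio3d least-squares fit on noisy motions", {
  set.seed(31)
  sys <- quiet_system()
  traj <- sys$trajectory
  sub <- newTrajectory(traj@beads, traj@coords[, , 1:6], traj@times[1:6],
                       traj@box[1:6, ])
  idx <- which(sub@beads$chain_id == "A" & sub@beads$name == "BB")
  ref <- sub@coords[, , 1]
  for (f in 2:6) {
    th <- runif(1, 0, pi)
    R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
    sub@coords[, , f] <- ref %*% R +
      rep(runif(3, -8, 8), each = nBeads(sub)) +
      rnorm(3 * nBeads(sub), 0, 0.5)
  }
  al <- alignSubunit(sub, "A")
  for (f in 2:6) {
    ours <- sqrt(mean(rowSums((al@coords[idx, , f] - ref[idx, ])^2)))
    fit <- suppressWarnings(  # bio3d notes it fits all non-NA positions
      bio3d::fit.xyz(as.vector(t(ref[idx, ])),
                     as.vector(t(sub@coords[idx, , f]))))
    oracle <- sqrt(mean(rowSums(
      (matrix(fit, ncol = 3, byrow = TRUE) - ref[idx, ])^2)))
    expect_equal(ours, oracle, tolerance = 1e-6)
  }
})

test_that("alignment is idempotent and rejects collinear selections", {
  sys <- quiet_system()
  traj <- sys$trajectory
  sub <- newTrajectory(traj@beads, traj@coords[, , 1:4], traj@times[1:4],
                       traj@box[1:4, ])
  once <- alignSubunit(sub, "A")
  twice <- alignSubunit(once, "A")
  expect_lt(max(abs(twice@coords - once@coords)), 1e-9)
  expect_error(kabsch(cbind(1:5, 0, 0), cbind(2 * (1:5), 0, 0)),
               "collinear")
})

test_that("equilibration trimming keeps the right frames and composes", {
  sys <- quiet_system()
  traj <- sys$trajectory
  expect_equal(nFrames(discardEquilibration(traj, 100)), nFrames(traj) - 100)
  expect_identical(discardEquilibration(traj, 0), traj)
  expect_error(discardEquilibration(traj, trajectoryDuration(traj)))
  ab <- discardEquilibration(discardEquilibration(traj, 60), 40)
  once <- discardEquilibration(traj, 100)
  expect_equal(ab@times, once@times)
  expect_equal(ab@coords, once@coords)
  # 10 us at 1 ns with the first 1 us discarded leaves 9000 frames
  toy <- newTrajectory(traj@beads[1:2, ],
                       array(1, dim = c(2, 3, 10000)), 1, c(10, 10, 10))
  expect_equal(nFrames(discardEquilibration(toy, 1000)), 9000)
})
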