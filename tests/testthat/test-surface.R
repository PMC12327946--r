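# Leaflet assignment, surface averaging, filters, minimal thickness.

test_that("leaflet labels follow planted flips and stay exclusive", {
  sys <- small_flip_system()
  ang <- lipidOrientationAngles(sys$trajectory)
  lab <- assignLeaflets(ang)
  tr <- sys$truth@events
  times <- sys$trajectory@times
  for (i in which(tr$complete)) {
    r <- match(tr$lipid_id[i], as.integer(rownames(lab)))
    sgn <- if (tr$direction[i] == "upper_to_lower") 1 else -1
    expect_equal(unname(lab[r, 1]), sgn)
    expect_equal(unname(lab[r, length(times)]), -sgn)
    # the switch lands at the physical end of the scripted transit
    sw <- times[which(diff(lab[r, ]) != 0)[1] + 1]
    expect_lt(abs(sw - tr$t_complete[i]), 5)
  }
  # static lipids keep their geometric placement
  quiet <- quiet_system()
  angq <- lipidOrientationAngles(quiet$trajectory)
  labq <- assignLeaflets(angq)
  expect_true(all(labq[1:30, ] == 1))
  expect_true(all(labq[31:60, ] == -1))
})

test_that("flat zero-noise leaflets average to their exact heights", {
  spec <- syntheticSpec(n_lipids_per_leaflet = 30, box = c(56, 56, 100),
                        duration = 300, seed = 3, jitter_sigma = 0)
  sys <- buildSystem(spec)
  ang <- lipidOrientationAngles(sys$trajectory)
  sp <- averageSurfaces(sys$trajectory, assignLeaflets(ang))
  expect_lt(max(abs(sp@upper_z[sp@mask_upper] - 15)), 1e-6)
  expect_lt(max(abs(sp@lower_z[sp@mask_lower] + 15)), 1e-6)
  mt <- minimalThickness(sp)
  expect_equal(mt$value, 30, tolerance = 1e-6)
})

test_that("rarely visited cells are discarded by the occupancy rule", {
  nf <- 1000L
  beads <- data.frame(name = rep(c("NC3", "GL1", "GL2"), 2),
                      residue_index = rep(1:2, each = 3),
                      residue_name = "DOPC", chain_id = "M")
  coords <- array(0, dim = c(6, 3, nf))
  coords[1:3, 3, ] <- 15; coords[4:6, 3, ] <- -15
  coords[, 1, ] <- 10.5; coords[, 2, ] <- 10.5
  # one lipid visits a remote corner cell in exactly 1 of 1000 frames
  coords[2:3, 1, 500] <- 55.5; coords[2:3, 2, 500] <- 55.5
  traj <- newTrajectory(beads, coords, 1, c(60, 60, 60))
  lab <- matrix(rep(c(1L, -1L), nf), nrow = 2)
  rownames(lab) <- 1:2
  sp <- averageSurfaces(traj, lab)
  expect_false(sp@mask_upper[56, 56])
  expect_equal(unname(sp@occ_upper[56, 56]), 0.001)
  expect_true(sp@mask_upper[11, 11])
})

test_that("disconnected surface patches are removed, the bulk kept", {
  nf <- 100L
  mk_bead <- function(id, x, y, z) {
    list(beads = data.frame(name = c("NC3", "GL1", "GL2"),
                            residue_index = id, residue_name = "DOPC",
                            chain_id = "M"),
         xyz = c(x, y, z))
  }
  # a 3x3 bulk patch of lipids plus one isolated far cell, both leaflets
  specs <- list()
  id <- 0
  for (x in c(10, 11, 12)) for (y in c(10, 11, 12)) {
    id <- id + 1; specs[[id]] <- mk_bead(id, x + 0.5, y + 0.5, 15)
  }
  specs[[id + 1]] <- mk_bead(id + 1, 40.5, 40.5, 15)
  n <- length(specs)
  beads <- do.call(rbind, lapply(specs, `[[`, "beads"))
  coords <- array(0, dim = c(3 * n, 3, nf))
  for (i in seq_len(n)) {
    coords[(3 * i - 2):(3 * i), 1, ] <- specs[[i]]$xyz[1]
    coords[(3 * i - 2):(3 * i), 2, ] <- specs[[i]]$xyz[2]
    coords[(3 * i - 2):(3 * i), 3, ] <- specs[[i]]$xyz[3]
  }
  # mirror into the lower leaflet
  beads2 <- beads; beads2$residue_index <- beads2$residue_index + n
  coords2 <- coords; coords2[, 3, ] <- -coords2[, 3, ]
  allc <- array(0, dim = c(6 * n, 3, nf))
  allc[seq_len(3 * n), , ] <- coords
  allc[3 * n + seq_len(3 * n), , ] <- coords2
  traj <- newTrajectory(rbind(beads, beads2), allc, 1, c(60, 60, 60))
  lab <- matrix(rep(c(1L, -1L), each = n), nrow = 2 * n, ncol = nf)
  rownames(lab) <- 1:(2 * n)
  sp <- averageSurfaces(traj, lab)
  expect_equal(sum(sp@mask_upper), 9)   # isolated cell dropped
  expect_false(sp@mask_upper[41, 41])
})

test_that("minimal thickness equals the all-pairs oracle on rough surfaces", {
  set.seed(23)
  for (rep in 1:4) {
    n <- sample(20:40, 1)
    up <- matrix(15 + rnorm(n * n, 0, 2), n, n)
    lo <- matrix(-15 + rnorm(n * n, 0, 2), n, n)
    sp <- surface_pair(up, lo)
    expect_equal(minimalThickness(sp)$value, oracle_min_thickness(sp),
                 tolerance = 1e-9)
  }
  # masked variant (random holes)
  n <- 30
  sp <- surface_pair(matrix(15 + rnorm(n * n), n, n),
                     matrix(-15 + rnorm(n * n), n, n))
  sp@mask_upper[sample(n * n, 200)] <- FALSE
  sp@mask_lower[sample(n * n, 200)] <- FALSE
  sp@upper_z[!sp@mask_upper] <- NA; sp@lower_z[!sp@mask_lower] <- NA
  expect_equal(minimalThickness(sp)$value, oracle_min_thickness(sp),
               tolerance = 1e-9)
  # the reported value is the distance between the reported points
  mt <- minimalThickness(sp)
  expect_equal(mt$value, sqrt(sum((mt$point_upper - mt$point_lower)^2)))
})

test_that("deeper pinches strictly decrease the minimal thickness", {
  vals <- sapply(c(2, 5, 8), function(A) {
    spec <- syntheticSpec(n_lipids_per_leaflet = 60, box = c(64, 64, 100),
                          duration = 500, seed = 6,
                          deformation = list(type = "gaussian", amplitude = A,
                                             width = 12))
    sys <- buildSystem(spec)
    ang <- lipidOrientationAngles(sys$trajectory)
    minimalThickness(averageSurfaces(sys$trajectory,
                                     assignLeaflets(ang)))$value
  })
  expect_true(all(diff(vals) < 0))
})

test_that("the bilayer recovers bulk thickness far from the pinch", {
  spec <- syntheticSpec(n_lipids_per_leaflet = 100, box = c(80, 80, 100),
                        duration = 2500, seed = 13,
                        deformation = list(type = "gaussian", amplitude = 9,
                                           width = 8))
  sys <- buildSystem(spec)
  ang <- lipidOrientationAngles(sys$trajectory)
  sp <- averageSurfaces(sys$trajectory, assignLeaflets(ang))
  h <- sp@spacing
  cx <- (row(sp@upper_z) - 0.5) * h; cy <- (col(sp@upper_z) - 0.5) * h
  far <- sqrt((cx - 40)^2 + (cy - 40)^2) > 32 &
    sp@mask_upper & sp@mask_lower
  gap <- sp@upper_z[far] - sp@lower_z[far]
  expect_lt(max(abs(gap - 30)), 1)
  # recovered heights track the analytic field on every retained cell
  ok <- sp@mask_upper
  expect_gt(sum(ok), 1000)
  hu <- 15 - 9 * exp(-((cx - 40)^2 + (cy - 40)^2) / (2 * 8^2))
  expect_lt(max(abs(sp@upper_z[ok] - hu[ok])), 1.0)
})
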