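# Generator: determinism, planted events, deformation fields, tracers.

test_that("identical specs build bitwise-identical systems", {
  spec <- syntheticSpec(n_lipids_per_leaflet = 20, box = c(48, 48, 100),
                        duration = 400, seed = 12, flip_rate = 5,
                        n_partials = 1)
  a <- buildSystem(spec); b <- buildSystem(spec)
  expect_identical(a$trajectory@coords, b$trajectory@coords)
  expect_identical(a$truth@events, b$truth@events)
})

test_that("a zero-rate, zero-jitter system is static with constant angles", {
  spec <- syntheticSpec(n_lipids_per_leaflet = 16, box = c(48, 48, 100),
                        duration = 60, seed = 2, jitter_sigma = 0,
                        lateral_D = 0)
  sys <- buildSystem(spec)
  ang <- lipidOrientationAngles(sys$trajectory, window = 10)
  expect_lt(max(abs(ang@theta_raw - ang@theta_raw[, 1])), 1e-9)
  upper <- ang@theta_raw[1:16, 1]
  expect_true(all(abs(upper - 150) < 1e-6))
  expect_true(all(abs(ang@theta_raw[17:32, 1] - 30) < 1e-6))
  # conservation: no NaN, constant bead count by construction
  expect_false(anyNA(sys$trajectory@coords))
})

test_that("Poisson scheduling follows its law over seeds", {
  counts <- sapply(1:50, function(s)
    length(scheduleFlips(10, 10000, seed = s)))
  expect_lt(abs(mean(counts) - 100), 3 * sqrt(100 / 50))
})

test_that("planted complete flips cross the detection threshold and partials do not", {
  sys <- small_flip_system()
  ang <- lipidOrientationAngles(sys$trajectory)
  tr <- sys$truth@events
  for (i in which(tr$complete)) {
    r <- match(tr$lipid_id[i], ang@lipid_ids)
    s <- ang@theta_smooth[r, ]
    if (tr$direction[i] == "upper_to_lower") expect_lt(min(s), 35)
    else expect_gt(max(s), 145)
  }
  for (i in which(!tr$complete)) {
    r <- match(tr$lipid_id[i], ang@lipid_ids)
    s <- ang@theta_smooth[r, ]
    if (tr$direction[i] == "upper_to_lower") {
      expect_lt(min(s), 145)   # enters the band...
      expect_gt(min(s), 45)    # ...but turns around well above the threshold
    } else {
      expect_gt(max(s), 35)
      expect_lt(max(s), 135)
    }
  }
})

test_that("groove-axis flips stay within the capture radius of the axis", {
  sys <- small_flip_system()
  tr <- sys$truth@events
  pw <- syntheticPathway(sys$spec, "groove_axis")
  li <- lipidIndex(sys$trajectory)
  for (i in which(tr$complete & tr$pathway == "groove_axis")) {
    row <- li[match(tr$lipid_id[i], li$lipid_id), ]
    win <- which(sys$trajectory@times >= tr$t_start[i] &
                 sys$trajectory@times <= tr$t_complete[i])
    po4 <- sys$trajectory@coords[row$i_po4, , win]
    mid <- abs(po4[3, ]) < 7.5
    d <- sqrt((po4[1, mid] - pw@nodes[1, 1])^2 +
              (po4[2, mid] - pw@nodes[1, 2])^2)
    expect_lt(min(d), 4.7)
  }
})

test_that("overlapping planted flips on one lipid are rejected", {
  sys <- quiet_system()
  spec <- sys$spec
  traj <- plantFlip(sys$trajectory, spec, lipid_id = 3, t_start = 150)
  expect_error(plantFlip(traj, spec, lipid_id = 3, t_start = 160),
               "overlap")
})

test_that("deformation fields have the advertised closed-form minima", {
  none <- applyDeformation(quiet_system()$trajectory,
                           list(type = "none", amplitude = 0))
  expect_equal(none$analytic_min_thickness, 30)
  pinch <- applyDeformation(quiet_system()$trajectory,
                            list(type = "gaussian", amplitude = 9,
                                 width = 10, center = c(28, 28)))
  expect_equal(pinch$analytic_min_thickness, 12)
  # sinusoid: closed form matches dense numerical minimization of the field
  spec <- syntheticSpec(box = c(60, 60, 100),
                        deformation = list(type = "sinusoid", amplitude = 5,
                                           width = 30, center = c(30, 30)))
  xg <- seq(0, 60, by = 0.01)
  hu <- memscramble:::.surfHeight(spec, xg, rep(30, length(xg)), 1)
  expect_equal(2 * min(hu), 30 - 2 * 5, tolerance = 1e-4)
})

test_that("planted tracers carry their schedule; decoys never cross", {
  spec <- syntheticSpec(n_lipids_per_leaflet = 16, box = c(48, 48, 100),
                        duration = 300, seed = 4,
                        tracer_spec = data.frame(
                          species = c("Na", "Na", "Cl", "water"),
                          t_cross = c(60, 120, 180, 240),
                          direction = c("up", "up", "down", "up")),
                        n_decoys = 3)
  sys <- buildSystem(spec)
  expect_equal(nrow(sys$truth@crossings), 4)
  expect_equal(sum(sys$truth@crossings$species == "Na"), 2)
  b <- beadData(sys$trajectory)
  dec <- which(b$role %in% c("water", "ion_cation", "ion_anion"))
  dec <- tail(dec, 9)  # the decoys
  z <- sys$trajectory@coords[dec, 3, ]
  # a decoy may dip past the midplane but never reaches the far face
  expect_true(all(apply(z, 1, function(v) min(v) > -27 | max(v) < 27)))
  # determinism of the tracer schedule
  sys2 <- buildSystem(spec)
  expect_identical(sys$trajectory@coords[dec, , ],
                   sys2$trajectory@coords[dec, , ])
})

test_that("overfilled boxes are rejected", {
  expect_error(buildSystem(syntheticSpec(n_lipids_per_leaflet = 200,
                                         box = c(40, 40, 80))),
               "incompatible")
})
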