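# Orientation angles, hysteresis event detection, rates, Poisson checks.

test_that("orientation angle handles the canonical geometries", {
  nf <- 1L
  mk <- function(nc3, c4a, c4b) {
    beads <- data.frame(name = c("NC3", "PO4", "GL1", "GL2", "C4A", "C4B"),
                        residue_index = 1L, residue_name = "DOPC",
                        chain_id = "M")
    coords <- array(0, dim = c(6, 3, 2))
    for (f in 1:2) {
      coords[1, , f] <- nc3
      coords[2, , f] <- nc3 + 1
      coords[3, , f] <- nc3 + 2; coords[4, , f] <- nc3 + 2.5
      coords[5, , f] <- c4a; coords[6, , f] <- c4b
    }
    newTrajectory(beads, coords, 1, c(50, 50, 50))
  }
  down <- lipidOrientationAngles(mk(c(0, 0, 20), c(0, 0, 10), c(0, 0, 10)),
                                 window = 1)
  expect_equal(down@theta_raw[1, 1], 180)
  flat <- lipidOrientationAngles(mk(c(0, 0, 0), c(10, 0, 0), c(10, 0, 0)),
                                 window = 1)
  expect_equal(flat@theta_raw[1, 1], 90)
  up <- lipidOrientationAngles(mk(c(0, 0, 0), c(1, 0, 1), c(-1, 0, 1)),
                               window = 1)
  expect_equal(up@theta_raw[1, 1], 0)
})

test_that("lipids missing tail beads are reported by id", {
  beads <- data.frame(name = c("NC3", "PO4"), residue_index = 7L,
                      residue_name = "DOPC", chain_id = "M")
  traj <- newTrajectory(beads, array(1, dim = c(2, 3, 2)), 1, c(10, 10, 10))
  expect_error(lipidOrientationAngles(traj), "7")
})

test_that("the centered truncated running mean matches its literal oracle", {
  set.seed(9)
  for (w in c(3, 11, 101)) {
    x <- rnorm(500)
    expect_equal(runningMean(x, w), oracle_running_mean(x, w),
                 tolerance = 1e-12)
  }
})

test_that("hysteresis detection handles canonical traces", {
  # monotone descent: exactly one event at the first frame below 35
  tr <- seq(150, 30, length.out = 200)
  ev <- detectEvents(angle_set(tr))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$direction, "upper_to_lower")
  expect_equal(ev$t_complete, which(tr < 35)[1] - 1)
  # repeated partial excursions emit nothing
  part <- rep(c(seq(150, 50, length.out = 20),
                seq(50, 150, length.out = 20)), 5)
  expect_equal(nrow(detectEvents(angle_set(part))), 0)
  # full oscillation: alternating events
  osc <- c(seq(150, 30, length.out = 50), seq(30, 150, length.out = 50),
           seq(150, 30, length.out = 50))
  ev3 <- detectEvents(angle_set(osc))
  expect_equal(nrow(ev3), 3)
  expect_equal(ev3$direction,
               c("upper_to_lower", "lower_to_upper", "upper_to_lower"))
})

test_that("detection equals the explicit state-machine oracle on random traces", {
  set.seed(17)
  for (rep in 1:5) {
    traces <- matrix(runif(200 * 300, 0, 180), nrow = 200)
    ev <- detectEvents(angle_set(traces))
    n_oracle <- 0L
    for (r in 1:200) {
      o <- oracle_detect(traces[r, ])
      n_oracle <- n_oracle + nrow(o)
      er <- ev[ev$lipid_id == r, ]
      expect_equal(er$t_complete, o$frame - 1)
      expect_equal(er$direction, o$direction)
    }
    expect_equal(nrow(ev), n_oracle)
  }
})

test_that("event counts are invariant under time reversal up to direction swap", {
  sys <- small_flip_system()
  ang <- lipidOrientationAngles(sys$trajectory)
  fwd <- detectEvents(ang)
  rev_set <- angle_set(ang@theta_smooth[, rev(seq_along(ang@t))])
  bwd <- detectEvents(rev_set)
  expect_equal(nrow(fwd), nrow(bwd))
  expect_equal(sort(table(fwd$direction)),
               sort(table(bwd$direction)))
})

test_that("planted events are recovered with matching ids and directions", {
  sys <- small_flip_system()
  ev <- detectEvents(lipidOrientationAngles(sys$trajectory))
  tr <- sys$truth@events[sys$truth@events$complete, ]
  expect_equal(nrow(ev), nrow(tr))
  expect_setequal(paste(ev$lipid_id, ev$direction),
                  paste(tr$lipid_id, tr$direction))
})

test_that("pathway classification separates groove and cleft transits", {
  sys <- small_flip_system()
  ev <- detectEvents(lipidOrientationAngles(sys$trajectory))
  pws <- list(A = syntheticPathway(sys$spec, "groove_axis"))
  ev <- classifyPathway(ev, sys$trajectory, pws)
  tr <- sys$truth@events[sys$truth@events$complete, ]
  m <- merge(ev, tr[, c("lipid_id", "pathway")], by = "lipid_id")
  expect_equal(m$pathway_class == "in_groove", m$pathway == "groove_axis")
  expect_true(all(m$subunit[m$pathway_class == "in_groove"] == "A"))
  # no pathway: unclassified with a warning, totals preserved
  expect_warning(un <- classifyPathway(ev, sys$trajectory, NULL))
  expect_true(all(un$pathway_class == "unclassified"))
})

test_that("block rates reproduce hand arithmetic", {
  counts <- c(2, 3, 1, 4, 2, 3, 2, 3, 2)
  tt <- unlist(lapply(seq_along(counts), function(b)
    seq(0, 999, length.out = counts[b] + 2)[2:(counts[b] + 1)] +
      (b - 1) * 1000))
  r <- blockRate(tt, 9000)
  expect_equal(r$counts, counts)
  expect_equal(r$mean, mean(counts))
  expect_equal(r$sd, sqrt(mean((counts - mean(counts))^2)))
  z <- blockRate(numeric(0), 5000)
  expect_equal(z$mean, 0); expect_equal(z$sd, 0)
  expect_error(blockRate(tt, 500), "block")
  # trailing partial block discarded
  r2 <- blockRate(tt, 9400)
  expect_equal(r2$n_blocks, 9)
})

test_that("Poisson diagnostics reject periodic schedules and flag tiny samples", {
  per <- seq(100, 9000, by = 100)
  p <- poissonTest(per, 9000)
  expect_equal(p$verdict, "inconsistent")
  expect_lt(p$dispersion_index, 0.5)
  expect_equal(poissonTest(c(42), 1000)$verdict, "undefined")
  set.seed(8)
  ok <- sapply(1:10, function(s) {
    tt <- cumsum(rexp(90, 0.01))
    poissonTest(tt[tt < 9000], 9000)$verdict
  })
  expect_gte(mean(ok == "consistent"), 0.8)
})
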