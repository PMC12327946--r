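# Protein-lipid contacts: cutoff semantics, dwell merging, bead choice.

test_that("contact booleans use a strict 7 Angstrom cutoff", {
  nf <- 10
  nc3 <- matrix(rep(c(0, 0, 5), each = nf), ncol = 3)     # 5 A from BB
  po4 <- matrix(rep(c(0, 0, 8), each = nf), ncol = 3)     # 7 A from SC1
  traj <- probe_residue_trajectory(nc3, po4, nf)
  cs_nc3 <- contactSeries(traj, 10, bead = "NC3")
  expect_true(all(cs_nc3$contact))
  # exactly 7.0 A is not a contact
  cs_po4 <- contactSeries(traj, 10, bead = "PO4")
  expect_false(any(cs_po4$contact))
})

test_that("contact thresholding matches per-frame brute force on jittered input", {
  set.seed(27)
  nf <- 400
  nc3 <- cbind(0, 0, 7 + rnorm(nf, 0, 1.5))
  po4 <- nc3 + rep(c(0, 0, -3), each = nf)
  traj <- probe_residue_trajectory(nc3, po4, nf)
  cs <- contactSeries(traj, 10, bead = "NC3")
  ref <- traj@coords[2, , ]   # SC1 bead
  manual <- sqrt(colSums((traj@coords[3, , ] - ref)^2)) < 7
  expect_equal(as.vector(cs$contact[1, ]), manual)
})

test_that("dwell merging follows the worked examples and the inclusive convention", {
  x <- rep(FALSE, 30)
  x[1:11] <- TRUE; x[17:21] <- TRUE   # frames 0-10 and 16-20, gap 5 ns
  expect_equal(dwellTimes(x, dt = 1, gap_tolerance = 6), 21)
  y <- rep(FALSE, 30)
  y[1:11] <- TRUE; y[19:21] <- TRUE   # gap 7 ns > 6: two dwells
  expect_equal(dwellTimes(y, dt = 1, gap_tolerance = 6), c(11, 3))
  expect_equal(dwellTimes(logical(20)), numeric(0))
})

test_that("dwell merging equals the literal oracle on 1000 random series", {
  set.seed(29)
  for (i in 1:1000) {
    x <- runif(60) < 0.4
    expect_identical(dwellTimes(x, 1, 6), oracle_dwells(x, 1, 6))
  }
})

test_that("merging is monotone in the gap tolerance and conserves frames", {
  set.seed(30)
  for (i in 1:50) {
    x <- runif(200) < 0.3
    d0 <- dwellTimes(x, 1, 0)
    expect_equal(sum(d0), sum(x))   # unmerged durations = contact frames
    prev <- d0
    for (g in c(2, 6, 12)) {
      d <- dwellTimes(x, 1, g)
      expect_lte(length(d), length(prev))
      if (length(prev) && length(d)) expect_gte(max(d), max(prev))
      prev <- d
    }
  }
})

test_that("the bead with the higher mean dwell is chosen and top-50% summarized", {
  nf <- 60
  far <- c(0, 0, 30)
  nc3 <- matrix(rep(far, each = nf), ncol = 3)
  po4 <- matrix(rep(far, each = nf), ncol = 3)
  # NC3 dwells: frames 1-10 and 20-21 (gap > 6 from 10) -> 10 and 2
  nc3[c(1:10, 20:21), ] <- rep(c(0, 0, 4), each = 12)
  # PO4 dwells: 4 and 4
  po4[c(30:33, 45:48), ] <- rep(c(0, 0, 4), each = 8)
  traj <- probe_residue_trajectory(nc3, po4, nf)
  s <- residueSummary(traj, 10)
  expect_equal(s$chosen_bead, "NC3")
  expect_equal(sort(s$dwell_list), c(2, 10))
  expect_equal(s$mean_dwell, 6)
  expect_equal(s$top50_mean_dwell, 10)
  expect_equal(s$contact_frequency, 12 / 60)
  # no contacts at all
  none <- probe_residue_trajectory(matrix(rep(far, each = 5), ncol = 3),
                                   matrix(rep(far, each = 5), ncol = 3), 5)
  s0 <- residueSummary(none, 10)
  expect_true(s0$no_contact)
  expect_equal(s0$contact_frequency, 0)
  expect_length(s0$dwell_list, 0)
})

test_that("glycine residues fall back to the backbone bead", {
  sys <- quiet_system()
  traj <- sys$trajectory
  b <- beadData(traj)
  i <- outermostSideChainBead(traj, 333)
  expect_equal(b$name[i], "BB")
  j <- outermostSideChainBead(traj, 334)
  expect_equal(b$name[j], "SC1")
})

test_that("planted contact intervals are recovered exactly after merging", {
  iv <- matrix(c(50, 120, 200, 204, 209, 300, 500, 530), ncol = 2,
               byrow = TRUE)
  spec <- syntheticSpec(n_lipids_per_leaflet = 24, box = c(52, 52, 100),
                        duration = 700, seed = 15,
                        contact_spec = list(list(residue_index = 900,
                                                 chain_id = "A",
                                                 intervals = iv)))
  sys <- buildSystem(spec)
  s <- residueSummary(sys$trajectory, 900)
  # intervals 2 and 3 are separated by 4 ns <= 6: merged
  expect_equal(sort(s$dwell_list), sort(c(71, 101, 31)))
  expect_equal(s$contact_frequency, (71 + 5 + 92 + 31) / 700)
})

test_that("a symmetric dimer yields equal per-monomer frequencies", {
  spec <- syntheticSpec(n_lipids_per_leaflet = 60, box = c(72, 72, 100),
                        duration = 800, seed = 22, two_subunits = TRUE)
  sys <- buildSystem(spec)
  fr <- sapply(c("A", "B"), function(ch) {
    cs <- contactSeries(sys$trajectory, 452, ch, bead = "NC3")
    mean(colSums(cs$contact) > 0)
  })
  expect_lt(abs(fr["A"] - fr["B"]), 0.08)
})
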