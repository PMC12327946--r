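# Seeded synthetic CG-like bilayer + protein scaffold generator with
# fully known ground truth. Lipids follow kinematic scripts (no force
# field): resting lipids sit on a jittered, laterally diffusing layout
# with a fixed 30 degree chain tilt (resting orientation angles near
# 150/30 degrees); planted events move the headgroup along a declared
# pathway polyline with the tails trailing.

# bead arc positions along the head-to-tail chain (Angstrom from NC3);
# the two glycerol beads share the anchor depth (small lateral branch
# offsets keep them distinct) so the glycerol surface sits exactly at
# +-bulk_thickness/2, matching the closed-form deformation minima
.BEAD_S <- c(NC3 = 0, PO4 = 3, GL1 = 6.75, GL2 = 6.75, C4A = 15, C4B = 15)
.GL_MID <- 6.75          # glycerol midpoint arc position, anchors the leaflet surface
.REST_TILT <- 30         # degrees between chain and membrane normal
.EDGE_MARGIN <- 80       # ns kept free of events at both trace ends so the
                         # 100 ns smoother can resolve every planted event

#' Construct a synthetic-system specification
#'
#' See [SyntheticSpec-class] for the meaning of every field. Defaults are
#' the package's reference study conditions: a 30 Angstrom
#' glycerol-to-glycerol DOPC-like bilayer sampled every 1 ns with
#' 1 Angstrom bead jitter and lateral lipid diffusion of 5 Angstrom^2/ns.
#'
#' @param n_lipids_per_leaflet,box,bulk_thickness,duration,dt,jitter_sigma,lateral_D,seed
#'   see [SyntheticSpec-class]
#' @param flip_rate,flip_schedule,n_partials,transit_time,pathway_spec see
#'   [SyntheticSpec-class]
#' @param deformation,tracer_spec,n_decoys,breathing,groove_sep,contact_spec,two_subunits
#'   see [SyntheticSpec-class]
#' @return a validated [SyntheticSpec-class]
#' @export
syntheticSpec <- function(n_lipids_per_leaflet = 100,
                          box = c(80, 80, 100),
                          bulk_thickness = 30,
                          duration = 1000, dt = 1,
                          jitter_sigma = 1, lateral_D = 5, seed = 1,
                          flip_rate = 0,
                          flip_schedule = data.frame(t_start = numeric(0),
                                                     pathway = character(0)),
                          n_partials = 0, transit_time = 20,
                          pathway_spec = "groove_axis",
                          deformation = list(type = "none", amplitude = 0,
                                             width = 10, center = NULL),
                          tracer_spec = data.frame(species = character(0),
                                                   t_cross = numeric(0),
                                                   direction = character(0)),
                          n_decoys = 0,
                          breathing = list(enabled = FALSE, d_closed = 4,
                                           d_open = 9, period = 500, duty = 0.5),
                          groove_sep = 8,
                          contact_spec = list(),
                          two_subunits = FALSE) {
  def <- utils::modifyList(list(type = "none", amplitude = 0, width = 10,
                                center = NULL), deformation)
  if (is.null(def$center)) def$center <- box[1:2] / 2
  br <- utils::modifyList(list(enabled = FALSE, d_closed = 4, d_open = 9,
                               period = 500, duty = 0.5), breathing)
  new("SyntheticSpec",
      n_lipids_per_leaflet = n_lipids_per_leaflet, box = as.numeric(box),
      bulk_thickness = bulk_thickness, duration = duration, dt = dt,
      jitter_sigma = jitter_sigma, lateral_D = lateral_D, seed = seed,
      flip_rate = flip_rate, flip_schedule = flip_schedule,
      n_partials = n_partials, transit_time = transit_time,
      pathway_spec = pathway_spec, deformation = def,
      tracer_spec = tracer_spec, n_decoys = n_decoys,
      breathing = br, groove_sep = groove_sep,
      contact_spec = contact_spec, two_subunits = two_subunits)
}

# groove center of a subunit (xy, Angstrom)
.grooveCenter <- function(spec, chain = "A") {
  gc <- spec@box[1:2] / 2
  if (chain == "B") gc <- gc + c(0, -28)
  gc
}

#' Declared membrane-spanning pathways of a synthetic system
#'
#' The groove axis is the vertical line midway between the TM4 and TM6
#' scaffold columns; the dimer cleft is a vertical line 20 Angstrom away
#' in y, mimicking the subunit-interface site.
#'
#' @param spec a [SyntheticSpec-class]
#' @param which "groove_axis", "dimer_cleft", or an (n x 3) polyline matrix
#' @param chain subunit chain id
#' @return a [Pathway-class]
#' @export
syntheticPathway <- function(spec, which = "groove_axis", chain = "A") {
  B <- spec@bulk_thickness
  z <- seq(-B / 2 - 10, B / 2 + 10, by = 1)
  if (is.matrix(which))
    return(new("Pathway", nodes = which, source = "synthetic"))
  gc <- .grooveCenter(spec, chain)
  xy <- switch(which,
    groove_axis = gc,
    dimer_cleft = gc + c(0, 20),
    stop("unknown pathway_spec: ", which))
  new("Pathway",
      nodes = cbind(rep(xy[1], length(z)), rep(xy[2], length(z)), z),
      source = "synthetic")
}

# leaflet surface height field; sign = +1 upper, -1 lower
.surfHeight <- function(spec, x, y, sign) {
  B <- spec@bulk_thickness
  def <- spec@deformation
  amp <- switch(def$type,
    none = 0,
    gaussian = def$amplitude *
      exp(-((x - def$center[1])^2 + (y - def$center[2])^2) / (2 * def$width^2)),
    sinusoid = def$amplitude *
      (1 + sin(2 * pi * (x - def$center[1]) / def$width)) / 2,
    stop("unknown deformation type: ", def$type))
  sign * (B / 2 - amp)
}

# TM4/TM6 separation schedule (Angstrom, per frame time t)
.grooveSep <- function(spec, t) {
  br <- spec@breathing
  if (!isTRUE(br$enabled)) return(rep(spec@groove_sep, length(t)))
  phase <- (t %% br$period) / br$period
  ifelse(phase < br$duty, br$d_open, br$d_closed)
}

# is the groove scheduled open (with a safety pad, ns) around time t?
.openAround <- function(spec, t, pad_lo = 10, pad_hi = 70) {
  br <- spec@breathing
  if (!isTRUE(br$enabled)) return(rep(TRUE, length(t)))
  w <- br$period * br$duty
  phase <- t %% br$period
  phase >= pad_lo & (phase + pad_hi) <= w
}

# resting layout of one lipid over frames: lat (nf x 2), leaf sign, psi
.restLipid <- function(spec, lat, leaf, psi) {
  nf <- nrow(lat)
  surfz <- .surfHeight(spec, lat[, 1], lat[, 2], leaf)
  alpha <- if (leaf > 0) 180 - .REST_TILT else .REST_TILT
  .layoutFromAnchor(lat, surfz, rep(alpha, nf), psi)
}

# place the 6 beads given glycerol-midpoint anchor, chain angle alpha
# (degrees from +z of the NC3 -> tail direction) and azimuth psi.
# returns array (6, 3, nf); bead order NC3 PO4 GL1 GL2 C4A C4B
.layoutFromAnchor <- function(lat, anchor_z, alpha, psi) {
  nf <- nrow(lat)
  a <- alpha * pi / 180
  u <- cbind(sin(a) * cos(psi), sin(a) * sin(psi), cos(a))
  w <- c(-sin(psi), cos(psi), 0)     # branch offset direction
  out <- array(0, dim = c(6, 3, nf))
  s <- .BEAD_S - .GL_MID
  for (k in 1:6) {
    br <- c(0, 0, 0.5, -0.5, 1, -1)[k]
    out[k, 1, ] <- lat[, 1] + u[, 1] * s[k] + br * w[1]
    out[k, 2, ] <- lat[, 2] + u[, 2] * s[k] + br * w[2]
    out[k, 3, ] <- anchor_z + u[, 3] * s[k]
  }
  out
}

# head-driven layout: NC3 at (head_xy, head_z), beads trail along u(alpha)
.layoutFromHead <- function(head_xy, head_z, alpha, psi) {
  nf <- length(head_z)
  a <- alpha * pi / 180
  u <- cbind(sin(a) * cos(psi), sin(a) * sin(psi), cos(a))
  w <- c(-sin(psi), cos(psi), 0)
  out <- array(0, dim = c(6, 3, nf))
  for (k in 1:6) {
    s <- .BEAD_S[k]
    br <- c(0, 0, 0.5, -0.5, 1, -1)[k]
    out[k, 1, ] <- head_xy[, 1] + u[, 1] * s + br * w[1]
    out[k, 2, ] <- head_xy[, 2] + u[, 2] * s + br * w[2]
    out[k, 3, ] <- head_z + u[, 3] * s
  }
  out
}

#' Draw a Poisson schedule of flip times
#'
#' Exponential inter-event gaps at the requested rate; the law the
#' generator uses for Poisson-scheduled leaflet transitions.
#'
#' @param rate_per_us event rate (events/us)
#' @param duration_ns schedule span (ns)
#' @param seed optional seed (set by the caller otherwise)
#' @return numeric vector of event times (ns), possibly empty
#' @export
scheduleFlips <- function(rate_per_us, duration_ns, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (rate_per_us <= 0) return(numeric(0))
  rate <- rate_per_us / 1000
  n_guess <- max(10, ceiling(rate * duration_ns * 2 + 10 * sqrt(rate * duration_ns)))
  t <- cumsum(stats::rexp(n_guess, rate))
  while (length(t) && t[length(t)] < duration_ns)
    t <- c(t, t[length(t)] + cumsum(stats::rexp(n_guess, rate)))
  t[t < duration_ns]
}

#' Build a synthetic trajectory with known ground truth
#'
#' Places \code{n_lipids_per_leaflet} CG-like lipids per leaflet on a
#' jittered lattice, lets them diffuse laterally, rides them on the
#' analytic deformation field, plants complete flips and partial
#' excursions along the declared pathways, adds tracer/decoy particles and
#' scripted contact probes, and erects a rigid (optionally breathing)
#' two-column TM4/TM6 scaffold. Deterministic for a fixed spec.
#'
#' @param spec a [SyntheticSpec-class]
#' @return list with elements \code{trajectory} ([Trajectory-class]) and
#'   \code{truth} ([GroundTruth-class])
#' @export
buildSystem <- function(spec) {
  validObject(spec)
  set.seed(spec@seed %% .Machine$integer.max)
  nL <- spec@n_lipids_per_leaflet
  Lx <- spec@box[1]; Ly <- spec@box[2]
  if (Lx * Ly / nL < 40)
    stop("lipid count incompatible with box area (", round(Lx * Ly / nL, 1),
         " Angstrom^2 per lipid; need >= 40)")
  nf <- floor(spec@duration / spec@dt)
  times <- seq(0, by = spec@dt, length.out = nf)
  dur <- spec@duration

  # --- lipid bookkeeping -------------------------------------------------
  n_probe <- length(spec@contact_spec)
  n_lip <- 2L * nL + n_probe
  lip_leaf <- rep(c(1, -1), each = nL)          # initial leaflet sign
  # lattice placement
  nx <- ceiling(sqrt(nL * Lx / Ly)); ny <- ceiling(nL / nx)
  site <- expand.grid(ix = seq_len(nx), iy = seq_len(ny))[seq_len(nL), ]
  base_xy <- cbind((site$ix - 0.5) * Lx / nx, (site$iy - 0.5) * Ly / ny)
  psi <- stats::runif(n_lip, 0, 2 * pi)

  # lateral diffusion traces (wrapped)
  sd_step <- sqrt(2 * spec@lateral_D * spec@dt)
  lat <- vector("list", n_lip)
  for (i in seq_len(2L * nL)) {
    x0 <- base_xy[(i - 1) %% nL + 1, ] + stats::runif(2, -2, 2)
    steps <- matrix(stats::rnorm(2 * (nf - 1), 0, sd_step), ncol = 2)
    tr <- rbind(x0, sweep(apply(steps, 2, cumsum), 2, x0, "+"))
    tr[, 1] <- tr[, 1] %% Lx; tr[, 2] <- tr[, 2] %% Ly
    lat[[i]] <- tr
  }

  # --- event scheduling --------------------------------------------------
  Tt <- spec@transit_time
  lo <- .EDGE_MARGIN; hi <- dur - Tt - .EDGE_MARGIN
  wants_events <- spec@n_partials > 0 || spec@flip_rate > 0
  if (wants_events && hi <= lo)
    stop("duration too short to plant events away from the trace edges ",
         "(need > ", 2 * .EDGE_MARGIN + Tt, " ns)")
  if (nrow(spec@flip_schedule)) {
    sched <- spec@flip_schedule
    if (is.null(sched$pathway)) sched$pathway <- "groove_axis"
    if (any(sched$t_start + Tt > dur))
      stop("flip schedule extends past the trajectory duration")
  } else if (spec@flip_rate > 0) {
    tt <- scheduleFlips(spec@flip_rate, dur)
    tt <- tt[tt >= lo & tt <= hi & .openAround(spec, tt + Tt)]
    sched <- data.frame(t_start = tt,
                        pathway = rep("groove_axis", length(tt)))
  } else sched <- data.frame(t_start = numeric(0), pathway = character(0))
  sched <- sched[order(sched$t_start), , drop = FALSE]

  # partial excursions: uniform times in the allowed span
  if (spec@n_partials > 0) {
    pt <- sort(stats::runif(spec@n_partials, lo, hi))
  } else pt <- numeric(0)

  # assign lipids: uniformly among lipids resting at t_start
  busy_until <- rep(-Inf, 2L * nL)
  cur_leaf <- lip_leaf[seq_len(2L * nL)]
  ev <- list(); k <- 0L
  all_ev <- rbind(
    data.frame(t_start = sched$t_start, pathway = as.character(sched$pathway),
               complete = rep(TRUE, nrow(sched))),
    data.frame(t_start = pt, pathway = rep("none", length(pt)),
               complete = rep(FALSE, length(pt))))
  all_ev <- all_ev[order(all_ev$t_start), , drop = FALSE]
  for (r in seq_len(nrow(all_ev))) {
    t0 <- all_ev$t_start[r]
    avail <- which(busy_until < t0)
    if (!length(avail)) {
      warning("no resting lipid available at t = ", t0, "; event dropped")
      next
    }
    lid <- avail[sample.int(length(avail), 1L)]
    k <- k + 1L
    dir <- if (cur_leaf[lid] > 0) "upper_to_lower" else "lower_to_upper"
    ev[[k]] <- data.frame(lipid_id = lid, direction = dir,
                          t_start = t0, t_complete = t0 + Tt,
                          pathway = all_ev$pathway[r],
                          complete = all_ev$complete[r])
    busy_until[lid] <- t0 + Tt + 2 * .EDGE_MARGIN
    if (all_ev$complete[r]) cur_leaf[lid] <- -cur_leaf[lid]
  }
  events <- if (k) do.call(rbind, ev) else
    data.frame(lipid_id = integer(0), direction = character(0),
               t_start = numeric(0), t_complete = numeric(0),
               pathway = character(0), complete = logical(0))

  # --- bead table --------------------------------------------------------
  lip_names <- names(.BEAD_S)
  beads <- data.frame(
    name = rep(lip_names, n_lip),
    residue_index = rep(seq_len(n_lip), each = 6L),
    residue_name = "DOPC", chain_id = "M",
    stringsAsFactors = FALSE)

  chains <- if (spec@two_subunits) c("A", "B") else "A"
  scaf <- do.call(rbind, lapply(chains, function(ch) .scaffoldBeads(ch)))
  # dedicated contact-post residues for contact_spec entries that name a
  # residue outside the TM4/TM6 scaffold: a two-bead (BB + SC1) stub at a
  # lateral position far from the transit corridors, near the membrane
  # core, so the scripted probe's contacts are the only ones there
  post_xy <- list()
  if (n_probe > 0) {
    gcA <- .grooveCenter(spec, "A")
    for (p in seq_len(n_probe)) {
      cs <- spec@contact_spec[[p]]
      ch <- if (is.null(cs$chain_id)) "A" else cs$chain_id
      if (!cs$residue_index %in% scaf$residue_index[scaf$chain_id == ch]) {
        xy <- (gcA + c(26, -26 + 8 * (p - 1))) %% spec@box[1:2]
        post_xy[[p]] <- xy
        scaf <- rbind(scaf, data.frame(
          name = c("BB", "SC1"), residue_index = cs$residue_index,
          residue_name = "LEU", chain_id = ch, tm = "POST",
          z = c(0, 1.2), stringsAsFactors = FALSE))
      }
    }
  }
  tr_spec <- spec@tracer_spec
  n_tr <- nrow(tr_spec)
  n_dec <- spec@n_decoys * 3L  # per species
  tracer_names <- c(water = "W", Na = "NA", Cl = "CL")
  tb <- data.frame(name = character(0), residue_index = integer(0),
                   residue_name = character(0), chain_id = character(0))
  if (n_tr + n_dec > 0) {
    species <- c(as.character(tr_spec$species),
                 rep(c("water", "Na", "Cl"), each = spec@n_decoys))
    tb <- data.frame(
      name = tracer_names[species],
      residue_index = n_lip + seq_along(species),
      residue_name = ifelse(species == "water", "W", "ION"),
      chain_id = "M", stringsAsFactors = FALSE)
  }
  beads <- rbind(beads, tb,
                 scaf[, c("name", "residue_index", "residue_name", "chain_id")])
  beads$role <- assignRoles(beads)
  n_bead <- nrow(beads)

  coords <- array(0, dim = c(n_bead, 3, nf))

  # --- resting lipids ----------------------------------------------------
  for (i in seq_len(2L * nL)) {
    rows <- (i - 1L) * 6L + 1:6
    coords[rows, , ] <- .restLipid(spec, lat[[i]], lip_leaf[i], psi[i])
  }
  # bead jitter on ordinary lipids
  jrows <- seq_len(2L * nL * 6L)
  if (spec@jitter_sigma > 0)
    coords[jrows, , ] <- coords[jrows, , ] +
      stats::rnorm(length(jrows) * 3 * nf, 0, spec@jitter_sigma)

  # --- planted events ----------------------------------------------------
  paths <- list(groove_axis = syntheticPathway(spec, "groove_axis"),
                dimer_cleft = syntheticPathway(spec, "dimer_cleft"))
  if (is.matrix(spec@pathway_spec))
    paths$custom <- syntheticPathway(spec, spec@pathway_spec)
  for (r in seq_len(nrow(events))) {
    e <- events[r, ]
    pw <- if (e$complete) paths[[e$pathway]] else NULL
    leaf <- if (e$direction == "upper_to_lower") 1 else -1
    sc <- .scriptExcursion(spec, lat[[e$lipid_id]], psi[e$lipid_id], e, pw,
                           times, leaf)
    rows <- (e$lipid_id - 1L) * 6L + 1:6
    coords[rows, , sc$win] <- sc$blk
    if (!is.null(sc$blk2)) coords[rows, , sc$post] <- sc$blk2
  }

  # --- tracers and decoys ------------------------------------------------
  if (n_tr + n_dec > 0) {
    gax <- paths$groove_axis
    zt <- spec@bulk_thickness / 2 + 12
    tau <- 10  # tracer transit duration (ns)
    for (j in seq_len(n_tr + n_dec)) {
      row <- n_lip * 6L + j
      if (j <= n_tr) {
        dirsgn <- if (tr_spec$direction[j] == "up") 1 else -1
        tc <- tr_spec$t_cross[j]
        zline <- dirsgn * pmin(pmax((times - tc) / (tau / 2), -1), 1) * zt
        xy <- pathwayAt(gax, zline)
        coords[row, 1, ] <- xy[, 1]; coords[row, 2, ] <- xy[, 2]
        coords[row, 3, ] <- zline
      } else {
        # decoy: oscillates near one face, occasionally dips past midplane
        side <- sample(c(-1, 1), 1)
        depth <- stats::runif(1, 0.3, 1.1) * zt
        ph <- stats::runif(1, 0, 2 * pi)
        per <- stats::runif(1, 120, 400)
        zline <- side * (zt - depth * (1 + sin(2 * pi * times / per + ph)) / 2)
        xy <- pathwayAt(gax, zline)
        coords[row, 1, ] <- xy[, 1] + stats::rnorm(nf, 0, 0.5)
        coords[row, 2, ] <- xy[, 2] + stats::rnorm(nf, 0, 0.5)
        coords[row, 3, ] <- zline
      }
    }
  }

  # --- scaffold ----------------------------------------------------------
  sep <- .grooveSep(spec, times)
  off <- n_lip * 6L + nrow(tb)
  post_seen <- 0L
  for (q in seq_len(nrow(scaf))) {
    row <- off + q
    if (scaf$tm[q] == "POST") {
      post_seen <- post_seen + (scaf$name[q] == "BB")
      xy <- post_xy[[post_seen]]
      coords[row, 1, ] <- xy[1]; coords[row, 2, ] <- xy[2]
      coords[row, 3, ] <- scaf$z[q]
    } else {
      gc <- .grooveCenter(spec, scaf$chain_id[q])
      sgn <- if (scaf$tm[q] == "TM4") -1 else 1
      coords[row, 1, ] <- gc[1] + sgn * sep / 2
      coords[row, 2, ] <- gc[2]
      coords[row, 3, ] <- scaf$z[q]
    }
  }

  # --- contact probes ----------------------------------------------------
  contacts <- list()
  if (n_probe > 0) {
    for (p in seq_len(n_probe)) {
      cs <- spec@contact_spec[[p]]
      lid <- 2L * nL + p
      rows <- (lid - 1L) * 6L + 1:6
      ch <- if (is.null(cs$chain_id)) "A" else cs$chain_id
      ref_row <- which(beads$residue_index == cs$residue_index &
                       beads$chain_id == ch & beads$role == "protein" &
                       beads$name != "BB")
      if (!length(ref_row))
        ref_row <- which(beads$residue_index == cs$residue_index &
                         beads$chain_id == ch & beads$role == "protein")
      if (!length(ref_row)) stop("contact_spec residue not in scaffold: ",
                                 cs$residue_index)
      ref_row <- ref_row[1]
      sc_xy <- t(coords[ref_row, 1:2, ])
      sc_z <- coords[ref_row, 3, ]
      in_iv <- rep(FALSE, nf)
      for (v in seq_len(nrow(cs$intervals)))
        in_iv <- in_iv | (times >= cs$intervals[v, 1] &
                          times <= cs$intervals[v, 2])
      # horizontal probe lipid, scripted without jitter so planted contact
      # intervals are exact: during an interval the PO4 bead sits 4 A from
      # the residue's outermost bead (NC3 at 5 A), otherwise it parks 24 A
      # away in the dimer-cleft corridor. Choose a residue near the
      # membrane core (|z| small) so resting headgroups can never reach it
      # and the probe's contacts are the only ones at that residue; both
      # probe stations lie in the groove/cleft corridors, where transit
      # traffic is expected anyway.
      head_xy <- cbind(sc_xy[, 1] - 3, sc_xy[, 2] + ifelse(in_iv, 4, 24))
      coords[rows, , ] <- .layoutFromHead(head_xy, sc_z,
                                          rep(90, nf), 0)
      contacts[[p]] <- list(residue_index = cs$residue_index, chain_id = ch,
                            lipid_id = lid, intervals = cs$intervals,
                            stations = rbind(c(sc_xy[1, 1] - 3, sc_xy[1, 2] + 4),
                                             c(sc_xy[1, 1] - 3, sc_xy[1, 2] + 24)))
    }
  }

  B <- spec@bulk_thickness
  amin <- if (spec@deformation$type == "none") B else
    B - 2 * spec@deformation$amplitude
  open_sched <- if (isTRUE(spec@breathing$enabled))
    data.frame(t = times, open = .grooveSep(spec, times) > 6) else
    data.frame(t = numeric(0), open = logical(0))
  crossings <- if (n_tr) data.frame(species = as.character(tr_spec$species),
                                    direction = as.character(tr_spec$direction),
                                    t_cross = tr_spec$t_cross) else
    data.frame(species = character(0), direction = character(0),
               t_cross = numeric(0))

  traj <- newTrajectory(beads, coords, times, spec@box)
  traj@aligned <- chains   # the scaffold is rigid: frames share its frame
  truth <- new("GroundTruth", events = events,
               analytic_min_thickness = amin,
               crossings = crossings, contacts = contacts,
               open_schedule = open_sched, spec = spec)
  list(trajectory = traj, truth = truth)
}

# scaffold bead table for one chain: TM4 residues 327-339 (z -18..18 by 3),
# TM6 residues 430-452 (z -22..22 by 2); BB + one SC1 bead per residue
# except residue 333 (glycine: backbone only)
.scaffoldBeads <- function(chain) {
  tm4 <- data.frame(tm = "TM4", residue_index = 327:339,
                    z = seq(-18, 18, by = 3))
  tm6 <- data.frame(tm = "TM6", residue_index = 430:452,
                    z = seq(-22, 22, by = 2))
  res <- rbind(tm4, tm6)
  out <- do.call(rbind, lapply(seq_len(nrow(res)), function(q) {
    r <- res[q, ]
    gly <- r$residue_index == 333
    data.frame(name = if (gly) "BB" else c("BB", "SC1"),
               residue_index = r$residue_index,
               residue_name = if (gly) "GLY" else "LEU",
               chain_id = chain,
               tm = r$tm, z = if (gly) r$z else c(r$z, r$z + 1.2),
               stringsAsFactors = FALSE)
  }))
  out
}

# scripted excursion of one lipid: returns the coordinate blocks to
# splice in (window and, for complete flips, all post-flip frames)
.scriptExcursion <- function(spec, lat_i, psi_i, e, pathway, times, leaf) {
  Tt <- e$t_complete - e$t_start
  win <- which(times >= e$t_start & times <= e$t_complete)
  post <- which(times > e$t_complete)
  if (!length(win)) return(list(win = integer(0), blk = NULL, blk2 = NULL))
  f0 <- max(1L, win[1] - 1L)
  a_start <- if (leaf > 0) 180 - .REST_TILT else .REST_TILT
  a_end <- 180 - a_start
  # head height at window start (from the unjittered layout geometry)
  z_h0 <- .surfHeight(spec, lat_i[f0, 1], lat_i[f0, 2], leaf) -
    .GL_MID * cos(a_start * pi / 180)
  p <- (times[win] - e$t_start) / Tt
  if (e$complete) {
    alpha <- a_start + (a_end - a_start) * p
    z_head <- z_h0 * (1 - 2 * p)
    blend <- pmin(1, p / 0.15, (1 - p) / 0.15)
    pxy <- pathwayAt(pathway, z_head)
    head_xy <- (1 - blend) * lat_i[win, , drop = FALSE] + blend * pxy
  } else {
    q <- 1 - abs(2 * p - 1)              # triangle 0 -> 1 -> 0
    turn <- if (leaf > 0) 55 else 125    # aborted excursions turn at ~55/125 deg
    alpha <- a_start + (turn - a_start) * q
    z_head <- z_h0 * (1 - 0.7 * q)
    head_xy <- lat_i[win, , drop = FALSE]
  }
  blk <- .layoutFromHead(head_xy, z_head, alpha, psi_i)
  if (spec@jitter_sigma > 0)
    blk <- blk + stats::rnorm(length(blk), 0, spec@jitter_sigma)
  blk2 <- NULL
  if (e$complete && length(post)) {
    blk2 <- .restLipid(spec, lat_i[post, , drop = FALSE], -leaf, psi_i)
    if (spec@jitter_sigma > 0)
      blk2 <- blk2 + stats::rnorm(length(blk2), 0, spec@jitter_sigma)
  }
  list(win = win, post = post, blk = blk, blk2 = blk2)
}

#' Plant a single flip (or partial excursion) into an existing trajectory
#'
#' Overwrites the lipid's bead coordinates: the headgroup translates along
#' the pathway polyline with the tails trailing so the orientation angle
#' sweeps from its resting value through 90 degrees to the opposite
#' leaflet's band (complete) or turns around near 55/125 degrees
#' (incomplete). After a complete flip the lipid continues as a resident
#' of the destination leaflet. Assumes mirror-symmetric leaflet surfaces.
#'
#' @param traj a [Trajectory-class] produced by [buildSystem()]
#' @param spec the matching [SyntheticSpec-class]
#' @param lipid_id lipid residue index
#' @param t_start excursion start (ns)
#' @param pathway a [Pathway-class] (required when \code{complete})
#' @param transit_time scripted transit duration (ns)
#' @param complete logical: full flip or aborted excursion
#' @return modified [Trajectory-class]; planted windows are tracked in the
#'   \code{"planted"} attribute, and overlapping windows on one lipid are
#'   an error
#' @export
plantFlip <- function(traj, spec, lipid_id, t_start,
                      pathway = syntheticPathway(spec),
                      transit_time = spec@transit_time, complete = TRUE) {
  if (t_start + transit_time > traj@times[nFrames(traj)])
    stop("flip window extends past the trajectory")
  planted <- attr(traj, "planted")
  if (!is.null(planted)) {
    ov <- planted$lipid_id == lipid_id &
      t_start <= planted$t1 & (t_start + transit_time) >= planted$t0
    if (any(ov)) stop("overlapping flips planted on lipid ", lipid_id)
  }
  li <- lipidIndex(traj)
  if (!lipid_id %in% li$lipid_id) stop("no such lipid: ", lipid_id)
  rows <- (lipid_id - 1L) * 6L + 1:6
  # reconstruct lateral trace from the glycerol midpoint
  lat1 <- t((traj@coords[rows[3], 1:2, ] + traj@coords[rows[4], 1:2, ]) / 2)
  lat <- stats::setNames(vector("list", lipid_id), NULL)
  lat[[lipid_id]] <- lat1
  psi <- rep(0, lipid_id)
  psi[lipid_id] <- atan2(
    mean(traj@coords[rows[5:6], 2, 1]) - traj@coords[rows[1], 2, 1],
    mean(traj@coords[rows[5:6], 1, 1]) - traj@coords[rows[1], 1, 1])
  f0 <- max(1L, max(which(traj@times < t_start), 1L))
  leaf <- sign(mean(traj@coords[rows[3:4], 3, f0]))
  e <- data.frame(lipid_id = lipid_id,
                  direction = if (leaf > 0) "upper_to_lower" else "lower_to_upper",
                  t_start = t_start, t_complete = t_start + transit_time,
                  pathway = "custom", complete = complete)
  sc <- .scriptExcursion(spec, lat1, psi[lipid_id], e, pathway, traj@times,
                         leaf)
  traj@coords[rows, , sc$win] <- sc$blk
  if (!is.null(sc$blk2)) traj@coords[rows, , sc$post] <- sc$blk2
  attr(traj, "planted") <- rbind(planted,
    data.frame(lipid_id = lipid_id, t0 = t_start, t1 = t_start + transit_time))
  traj
}

#' Apply an analytic deformation field to a flat synthetic bilayer
#'
#' Shifts every lipid vertically by the leaflet-dependent field
#' \code{h+-(x, y) = +-B/2 -+ amp(x, y)} evaluated at the lipid's own
#' lateral position per frame (leaflet from the sign of its glycerol
#' midpoint). For a centered Gaussian pinch of amplitude A the analytic
#' minimal leaflet-to-leaflet distance is \code{bulk_thickness - 2 A}.
#'
#' @param traj a [Trajectory-class] with a flat bilayer
#' @param deformation list(type, amplitude, width, center) as in
#'   [SyntheticSpec-class]
#' @param bulk_thickness glycerol-to-glycerol thickness of the flat input
#' @return list(trajectory, analytic_min_thickness)
#' @export
applyDeformation <- function(traj, deformation, bulk_thickness = 30) {
  spec <- syntheticSpec(bulk_thickness = bulk_thickness,
                        deformation = deformation,
                        box = c(max(traj@box[, 1]), max(traj@box[, 2]),
                                max(traj@box[, 3])))
  li <- lipidIndex(traj, require = "lipid_head")
  for (r in seq_len(nrow(li))) {
    rows <- which(traj@beads$residue_index == li$lipid_id[r] &
                  traj@beads$chain_id == traj@beads$chain_id[li$i_nc3[r]] &
                  startsWith(traj@beads$role, "lipid"))
    glz <- (traj@coords[li$i_gl1[r], 3, ] + traj@coords[li$i_gl2[r], 3, ]) / 2
    leaf <- sign(glz)
    latx <- (traj@coords[li$i_gl1[r], 1, ] + traj@coords[li$i_gl2[r], 1, ]) / 2
    laty <- (traj@coords[li$i_gl1[r], 2, ] + traj@coords[li$i_gl2[r], 2, ]) / 2
    shift <- .surfHeight(spec, latx, laty, leaf) - leaf * bulk_thickness / 2
    for (b in rows) traj@coords[b, 3, ] <- traj@coords[b, 3, ] + shift
  }
  amin <- if (deformation$type == "none") bulk_thickness else
    bulk_thickness - 2 * deformation$amplitude
  list(trajectory = traj, analytic_min_thickness = amin)
}

#' Plant tracer particles with scheduled membrane crossings
#'
#' Appends water/ion beads: each planted transit moves its tracer
#' monotonically from beyond one membrane face to beyond the other through
#' the pathway tube over ~10 ns centered on the scheduled crossing time;
#' decoys oscillate near one face (some dip past the midplane and retreat)
#' and are never counted in the ground truth.
#'
#' @param traj a [Trajectory-class]
#' @param tracer_spec data.frame(species, t_cross, direction)
#' @param pathway a [Pathway-class] the transits follow
#' @param n_decoys decoys per species
#' @param z_top parking height above/below the membrane faces (Angstrom)
#' @return list(trajectory, crossings) with \code{crossings} the planted
#'   directed schedule
#' @export
plantTracers <- function(traj, tracer_spec, pathway, n_decoys = 0,
                         z_top = 27) {
  nf <- nFrames(traj); times <- traj@times
  if (nrow(tracer_spec) && any(tracer_spec$t_cross > times[nf] |
                               tracer_spec$t_cross < times[1]))
    stop("tracer crossing times outside the trajectory span")
  tracer_names <- c(water = "W", Na = "NA", Cl = "CL")
  species <- c(as.character(tracer_spec$species),
               rep(c("water", "Na", "Cl"), each = n_decoys))
  if (!length(species)) return(list(trajectory = traj,
                                    crossings = tracer_spec))
  id0 <- max(traj@beads$residue_index) + 1L
  tb <- data.frame(name = tracer_names[species],
                   residue_index = id0 + seq_along(species) - 1L,
                   residue_name = ifelse(species == "water", "W", "ION"),
                   chain_id = "M", stringsAsFactors = FALSE)
  tb$role <- assignRoles(tb)
  tau <- 10
  newc <- array(0, dim = c(length(species), 3, nf))
  n_tr <- nrow(tracer_spec)
  for (j in seq_along(species)) {
    if (j <= n_tr) {
      dirsgn <- if (tracer_spec$direction[j] == "up") 1 else -1
      tc <- tracer_spec$t_cross[j]
      zline <- dirsgn * pmin(pmax((times - tc) / (tau / 2), -1), 1) * z_top
    } else {
      side <- sample(c(-1, 1), 1)
      depth <- stats::runif(1, 0.3, 1.1) * z_top
      ph <- stats::runif(1, 0, 2 * pi)
      per <- stats::runif(1, 120, 400)
      zline <- side * (z_top - depth * (1 + sin(2 * pi * times / per + ph)) / 2)
    }
    xy <- pathwayAt(pathway, zline)
    newc[j, 1, ] <- xy[, 1]; newc[j, 2, ] <- xy[, 2]; newc[j, 3, ] <- zline
  }
  coords <- array(0, dim = c(nBeads(traj) + length(species), 3, nf))
  coords[seq_len(nBeads(traj)), , ] <- traj@coords
  coords[nBeads(traj) + seq_along(species), , ] <- newc
  out <- newTrajectory(rbind(traj@beads, tb), coords, times, traj@box)
  out@aligned <- traj@aligned
  list(trajectory = out, crossings = tracer_spec)
}

#' One-bead trajectory whose z samples a prescribed equilibrium profile
#'
#' Builds a minimal trajectory containing a single PO4 bead whose height
#' is drawn i.i.d. from the Boltzmann density \code{exp(-G(z)/kT)} on
#' \code{z_range} (rejection sampling). Used to validate the free-energy
#' inversion against a planted profile.
#'
#' @param n_samples number of frames
#' @param G_fun vectorized function of z returning the profile in kT
#' @param z_range length-2 support (Angstrom)
#' @param center lateral position of the bead (on the pathway)
#' @param dt frame spacing (ns)
#' @return a [Trajectory-class]
#' @export
equilibriumProfileTrajectory <- function(n_samples, G_fun,
                                         z_range = c(-20, 20),
                                         center = c(0, 0), dt = 1) {
  zs <- numeric(0)
  gmaxd <- max(exp(-G_fun(seq(z_range[1], z_range[2], length.out = 2001))))
  while (length(zs) < n_samples) {
    cand <- stats::runif(2 * n_samples, z_range[1], z_range[2])
    keep <- stats::runif(length(cand)) < exp(-G_fun(cand)) / gmaxd
    zs <- c(zs, cand[keep])
  }
  zs <- zs[seq_len(n_samples)]
  beads <- data.frame(name = "PO4", residue_index = 1L,
                      residue_name = "DOPC", chain_id = "M")
  coords <- array(0, dim = c(1, 3, n_samples))
  coords[1, 1, ] <- center[1]; coords[1, 2, ] <- center[2]
  coords[1, 3, ] <- zs
  newTrajectory(beads, coords, dt, c(100, 100, 100))
}

#' Trajectory of planted 1D Brownian transits along a vertical pathway
#'
#' One PO4 bead per transit window performs unconstrained Brownian motion
#' with diffusion coefficient \code{D} along z (lateral position fixed on
#' the pathway); outside its window the bead parks far from the tube.
#' Used to validate the MSD-based diffusion estimator.
#'
#' @param n_transits number of windows
#' @param D diffusion coefficient (Angstrom^2/ns)
#' @param window_length window duration (ns)
#' @param dt frame spacing (ns)
#' @param center lateral position of the tube
#' @return list(trajectory, windows) with \code{windows} a data.frame
#'   (lipid_id, t_start, t_end)
#' @export
brownianTransitTrajectory <- function(n_transits = 5, D = 12,
                                      window_length = 200, dt = 1,
                                      center = c(0, 0)) {
  wf <- round(window_length / dt)
  nf <- n_transits * wf
  beads <- do.call(rbind, lapply(seq_len(n_transits), function(i)
    data.frame(name = "PO4", residue_index = i, residue_name = "DOPC",
               chain_id = "M")))
  coords <- array(0, dim = c(n_transits, 3, nf))
  coords[, 1, ] <- 1e4  # parked far away by default
  windows <- data.frame(lipid_id = seq_len(n_transits),
                        t_start = (seq_len(n_transits) - 1) * wf * dt,
                        t_end = seq_len(n_transits) * wf * dt - dt)
  for (i in seq_len(n_transits)) {
    fr <- ((i - 1) * wf + 1):(i * wf)
    z <- cumsum(c(0, stats::rnorm(wf - 1, 0, sqrt(2 * D * dt))))
    coords[i, 1, fr] <- center[1]; coords[i, 2, fr] <- center[2]
    coords[i, 3, fr] <- z
  }
  list(trajectory = newTrajectory(beads, coords, dt, c(100, 100, 4000)),
       windows = windows)
}
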