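#' @import methods
#' @importFrom stats median quantile sd var ks.test rnorm runif rexp rpois filter approx setNames lm coef
#' @importFrom utils head tail write.csv read.csv
#' @importFrom tools file_ext
#' @importFrom data.table data.table
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Trajectory: coarse-grained bead coordinates over time
#'
#' The central container of the package: a time-ordered set of bead
#' coordinates with topology labels. Coordinates are always stored in
#' Angstrom and times in nanoseconds, whatever the source format used.
#'
#' @slot beads data.frame with one row per bead: \code{name} (bead name,
#'   e.g. NC3, PO4, GL1, GL2, C4A, C4B, BB, SC1), \code{residue_index}
#'   (1-based, as in the source file), \code{residue_name},
#'   \code{chain_id}, \code{role} (see [defaultRoleMap()]).
#' @slot coords numeric array of dimension (n_beads, 3, n_frames), Angstrom.
#' @slot times numeric vector of frame times in ns, strictly increasing.
#' @slot box matrix (n_frames x 3) of periodic box lengths in Angstrom.
#' @slot aligned character vector of chain ids that have been aligned with
#'   [alignSubunit()] (empty if none).
#'
#' @seealso [loadTrajectory()], [newTrajectory()], [buildSystem()]
#' @export
setClass("Trajectory",
  representation(
    beads = "data.frame",
    coords = "array",
    times = "numeric",
    box = "matrix",
    aligned = "character"
  ),
  prototype(aligned = character(0))
)

setValidity("Trajectory", function(object) {
  d <- dim(object@coords)
  msg <- character(0)
  if (length(d) != 3L || d[2] != 3L)
    msg <- c(msg, "coords must be an (n_beads, 3, n_frames) array")
  else {
    if (d[1] != nrow(object@beads))
      msg <- c(msg, "bead count differs between beads table and coords")
    if (d[3] != length(object@times))
      msg <- c(msg, "frame count differs between coords and times")
    if (d[3] != nrow(object@box))
      msg <- c(msg, "frame count differs between coords and box")
  }
  if (anyNA(object@coords) || any(!is.finite(object@coords)))
    msg <- c(msg, "coords contain non-finite values")
  if (length(object@times) > 1 && any(diff(object@times) <= 0))
    msg <- c(msg, "times must be strictly increasing")
  if (any(object@box <= 0))
    msg <- c(msg, "box lengths must be positive")
  need <- c("name", "residue_index", "residue_name", "chain_id", "role")
  if (!all(need %in% names(object@beads)))
    msg <- c(msg, paste("beads table must have columns:",
                        paste(need, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a Trajectory from in-memory components
#'
#' Low-level constructor used by the readers and the synthetic generator;
#' also convenient for building small test systems programmatically.
#'
#' @param beads data.frame of bead metadata (see [Trajectory-class]); a
#'   missing \code{role} column is filled from \code{role_map}.
#' @param coords array (n_beads, 3, n_frames) in Angstrom.
#' @param times frame times in ns; or a single \code{dt} expanded to
#'   \code{(0, dt, 2 dt, ...)} when \code{length(times) == 1} and
#'   there is more than one frame.
#' @param box periodic box lengths, either length-3 vector (constant box)
#'   or (n_frames x 3) matrix, Angstrom.
#' @param role_map named character vector mapping bead names to roles.
#' @return A [Trajectory-class] object.
#' @export
newTrajectory <- function(beads, coords, times, box, role_map = defaultRoleMap()) {
  if (length(dim(coords)) == 2L) coords <- array(coords, dim = c(dim(coords), 1L))
  nf <- dim(coords)[3]
  if (length(times) == 1L && nf > 1L) times <- seq(0, by = times, length.out = nf)
  if (is.null(dim(box))) box <- matrix(rep(as.numeric(box), each = nf), nrow = nf)
  if (is.null(beads$role)) beads$role <- assignRoles(beads, role_map)
  beads$role <- as.character(beads$role)
  new("Trajectory", beads = as.data.frame(beads, stringsAsFactors = FALSE),
      coords = coords, times = as.numeric(times), box = box)
}

#' @describeIn Trajectory-class number of frames
#' @param traj,object a \code{Trajectory}
#' @export
nFrames <- function(traj) dim(traj@coords)[3]

#' @describeIn Trajectory-class number of beads
#' @export
nBeads <- function(traj) dim(traj@coords)[1]

#' @describeIn Trajectory-class frame times (ns)
#' @export
frameTimes <- function(traj) traj@times

#' @describeIn Trajectory-class frame spacing dt (ns), the median time step
#' @export
timeStep <- function(traj) {
  if (nFrames(traj) < 2L) return(NA_real_)
  stats::median(diff(traj@times))
}

#' @describeIn Trajectory-class bead metadata table
#' @export
beadData <- function(traj) traj@beads

#' @describeIn Trajectory-class coordinates of selected beads
#' @param beads_idx integer indices of beads (default all)
#' @export
beadCoords <- function(traj, beads_idx = seq_len(nBeads(traj))) {
  traj@coords[beads_idx, , , drop = FALSE]
}

setMethod("show", "Trajectory", function(object) {
  d <- dim(object@coords)
  cat("Trajectory:", d[1], "beads,", d[3], "frames\n")
  cat("  time: ", object@times[1], " .. ", object@times[d[3]],
      " ns (dt = ", timeStep(object), " ns)\n", sep = "")
  cat("  roles:", paste(sprintf("%s=%d", names(table(object@beads$role)),
                                table(object@beads$role)), collapse = " "), "\n")
  if (length(object@aligned))
    cat("  aligned chains:", paste(object@aligned, collapse = ", "), "\n")
})

#' Per-lipid orientation angle series
#'
#' Raw and smoothed lipid orientation angles (degrees from the +z axis) on
#' the trajectory time grid, for every lipid in the system. The orientation
#' of a lipid is the angle between the average of the two choline-to-tail
#' vectors (NC3 to C4A and NC3 to C4B) and +z; upper-leaflet lipids rest
#' near 150 degrees, lower-leaflet lipids near 30 degrees.
#'
#' @slot t time grid (ns)
#' @slot lipid_ids residue indices identifying each lipid
#' @slot theta_raw matrix (n_lipids x n_frames) of raw angles, degrees
#' @slot theta_smooth matrix of angles after the centered running average
#' @slot window smoothing window length (ns)
#' @export
setClass("AngleSeriesSet",
  representation(t = "numeric", lipid_ids = "integer",
                 theta_raw = "matrix", theta_smooth = "matrix",
                 window = "numeric"))

setValidity("AngleSeriesSet", function(object) {
  msg <- character(0)
  if (!identical(dim(object@theta_raw), dim(object@theta_smooth)))
    msg <- c(msg, "raw and smoothed angle matrices differ in shape")
  if (nrow(object@theta_raw) != length(object@lipid_ids))
    msg <- c(msg, "lipid id count differs from angle matrix rows")
  if (ncol(object@theta_raw) != length(object@t))
    msg <- c(msg, "time grid length differs from angle matrix columns")
  rng <- range(object@theta_raw)
  if (rng[1] < -1e-9 || rng[2] > 180 + 1e-9)
    msg <- c(msg, "angles must lie in [0, 180] degrees")
  if (length(msg)) msg else TRUE
})

setMethod("show", "AngleSeriesSet", function(object) {
  cat("AngleSeriesSet:", length(object@lipid_ids), "lipids,",
      length(object@t), "frames, smoothing window", object@window, "ns\n")
})

#' @describeIn AngleSeriesSet-class extract one lipid's angle trace
#' @param set an \code{AngleSeriesSet}
#' @param lipid_id lipid residue index
#' @return data.frame with columns t, theta_raw, theta_smooth
#' @export
angleSeries <- function(set, lipid_id) {
  i <- match(lipid_id, set@lipid_ids)
  if (is.na(i)) stop("no angle series for lipid ", lipid_id)
  data.frame(t = set@t, theta_raw = set@theta_raw[i, ],
             theta_smooth = set@theta_smooth[i, ])
}

#' Ensemble-averaged leaflet surface pair
#'
#' Gridded mean glycerol-bead height fields for the upper and lower leaflet
#' on a common rectilinear xy grid, with per-cell occupancies and the masks
#' remaining after the occupancy and connectivity filters.
#'
#' @slot origin xy origin of the grid (Angstrom)
#' @slot spacing grid spacing (Angstrom, default 1)
#' @slot upper_z,lower_z matrices of mean surface heights (NA outside mask)
#' @slot occ_upper,occ_lower matrices of per-cell occupancy (fraction of frames)
#' @slot mask_upper,mask_lower logical matrices of retained cells
#' @export
setClass("SurfacePair",
  representation(origin = "numeric", spacing = "numeric",
                 upper_z = "matrix", lower_z = "matrix",
                 occ_upper = "matrix", occ_lower = "matrix",
                 mask_upper = "matrix", mask_lower = "matrix"))

setValidity("SurfacePair", function(object) {
  msg <- character(0)
  dims <- dim(object@upper_z)
  for (s in c("lower_z", "occ_upper", "occ_lower", "mask_upper", "mask_lower"))
    if (!identical(dim(slot(object, s)), dims))
      msg <- c(msg, paste("slot", s, "has inconsistent dimensions"))
  if (object@spacing <= 0) msg <- c(msg, "spacing must be positive")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SurfacePair", function(object) {
  cat("SurfacePair:", paste(dim(object@upper_z), collapse = " x "),
      "cells at", object@spacing, "Angstrom spacing\n")
  cat("  retained cells: upper", sum(object@mask_upper),
      "lower", sum(object@mask_lower), "\n")
})

#' 3D bead density grid
#'
#' Raw per-cell bead counts accumulated over frames (and averaged over
#' subunits when several are mapped into a common groove-local frame).
#'
#' @slot origin grid origin (Angstrom, corner of the first cell)
#' @slot spacing cell edge (Angstrom, default 0.5)
#' @slot counts 3D array of (possibly subunit-averaged) counts
#' @slot n_frames number of frames accumulated
#' @slot n_chains number of subunits averaged
#' @export
setClass("DensityGrid",
  representation(origin = "numeric", spacing = "numeric",
                 counts = "array", n_frames = "numeric", n_chains = "numeric"))

setValidity("DensityGrid", function(object) {
  msg <- character(0)
  if (length(dim(object@counts)) != 3L) msg <- c(msg, "counts must be 3D")
  if (object@spacing <= 0) msg <- c(msg, "spacing must be positive")
  if (any(object@counts < 0)) msg <- c(msg, "counts must be non-negative")
  if (length(msg)) msg else TRUE
})

setMethod("show", "DensityGrid", function(object) {
  cat("DensityGrid:", paste(dim(object@counts), collapse = " x "),
      "cells at", object@spacing, "Angstrom;",
      object@n_frames, "frames,", object@n_chains, "chain(s); total counts",
      sum(object@counts), "\n")
})

#' Membrane-spanning maximum-density pathway
#'
#' Ordered polyline of 3D nodes with strictly increasing z, running from
#' below the lower leaflet surface to above the upper one. Used to classify
#' scrambling events as in- or out-of-groove and to count permeation.
#'
#' @slot nodes matrix (n x 3) of node coordinates, Angstrom
#' @slot source one of "lipid_density", "water_density", "synthetic"
#' @export
setClass("Pathway",
  representation(nodes = "matrix", source = "character"))

setValidity("Pathway", function(object) {
  msg <- character(0)
  if (ncol(object@nodes) != 3L) msg <- c(msg, "nodes must be (n x 3)")
  if (nrow(object@nodes) >= 2L && any(diff(object@nodes[, 3]) <= 0))
    msg <- c(msg, "node z must be strictly increasing")
  if (length(msg)) msg else TRUE
})

setMethod("show", "Pathway", function(object) {
  z <- object@nodes[, 3]
  cat("Pathway (", object@source, "): ", nrow(object@nodes),
      " nodes, z ", min(z), " .. ", max(z), " Angstrom\n", sep = "")
})

#' @describeIn Pathway-class lateral (x, y) position of the pathway at a
#'   given z, linearly interpolated between nodes (clamped at the ends)
#' @param pathway a \code{Pathway}
#' @param z heights at which to interpolate (Angstrom)
#' @export
pathwayAt <- function(pathway, z) {
  nd <- pathway@nodes
  x <- stats::approx(nd[, 3], nd[, 1], xout = z, rule = 2)$y
  y <- stats::approx(nd[, 3], nd[, 2], xout = z, rule = 2)$y
  cbind(x = x, y = y)
}

#' Ground truth of a synthetic system
#'
#' Everything the generator planted, for validating analysis output.
#'
#' @slot events data.frame of planted scrambling excursions: lipid_id,
#'   direction, t_start, t_complete, pathway (label), complete (logical)
#' @slot analytic_min_thickness closed-form minimal leaflet-to-leaflet
#'   distance implied by the deformation field (Angstrom)
#' @slot crossings data.frame of planted permeation transits:
#'   species, direction, t_cross
#' @slot contacts list of planted per-residue contact interval tables
#' @slot open_schedule data.frame (t, open) of the programmed groove state,
#'   or a 0-row data.frame when the scaffold does not breathe
#' @slot spec the [SyntheticSpec-class] used
#' @export
setClass("GroundTruth",
  representation(events = "data.frame",
                 analytic_min_thickness = "numeric",
                 crossings = "data.frame",
                 contacts = "list",
                 open_schedule = "data.frame",
                 spec = "ANY"))

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:", sum(object@events$complete), "complete flips,",
      sum(!object@events$complete), "partial excursions,",
      nrow(object@crossings), "planted crossings\n")
  cat("  analytic min thickness:", object@analytic_min_thickness, "Angstrom\n")
})

#' Synthetic bilayer + scaffold specification
#'
#' Parameters of the seeded generator. Defaults emulate the coarse-grained
#' DOPC systems the analyses target: 30 Angstrom glycerol-to-glycerol bulk
#' thickness, resting orientation angles near 150/30 degrees (a fixed 30
#' degree chain tilt), 1 Angstrom isotropic positional jitter, 1 ns frames.
#'
#' @slot n_lipids_per_leaflet lipids per leaflet
#' @slot box (Lx, Ly, Lz) Angstrom
#' @slot bulk_thickness glycerol-to-glycerol leaflet separation (Angstrom)
#' @slot duration trajectory length (ns)
#' @slot dt frame spacing (ns)
#' @slot jitter_sigma per-bead isotropic Gaussian noise (Angstrom)
#' @slot lateral_D lateral lipid diffusion coefficient (Angstrom^2/ns) for
#'   the wrapped 2D random walk that makes lipids sample the surface grid
#' @slot seed RNG seed
#' @slot flip_rate Poisson rate of complete flips (events/us); ignored when
#'   \code{flip_schedule} is given
#' @slot flip_schedule explicit schedule data.frame (t_start, pathway) or
#'   0-row for none
#' @slot n_partials number of planted partial (aborted) excursions
#' @slot transit_time scripted transit duration (ns)
#' @slot pathway_spec "groove_axis", "dimer_cleft", or an (n x 3) polyline
#' @slot deformation list(type = "none"|"gaussian"|"sinusoid",
#'   amplitude, width, center)
#' @slot tracer_spec data.frame(species, t_cross, direction) of planted
#'   permeation transits; species in water/Na/Cl, direction in up/down
#' @slot n_decoys non-crossing decoy particles per species
#' @slot breathing list(enabled, d_closed, d_open, period, duty) for the
#'   oscillating TM4-TM6 scaffold separation
#' @slot groove_sep TM4-TM6 column separation (Angstrom) when not breathing
#' @slot contact_spec list of list(residue_index, chain_id, intervals) with
#'   intervals an (n x 2) matrix of ns; a probe lipid is parked within
#'   contact range during each interval
#' @slot two_subunits logical; add a mirrored second subunit (chain B)
#' @export
setClass("SyntheticSpec",
  representation(
    n_lipids_per_leaflet = "numeric", box = "numeric",
    bulk_thickness = "numeric", duration = "numeric", dt = "numeric",
    jitter_sigma = "numeric", lateral_D = "numeric", seed = "numeric",
    flip_rate = "numeric", flip_schedule = "data.frame",
    n_partials = "numeric", transit_time = "numeric",
    pathway_spec = "ANY", deformation = "list",
    tracer_spec = "data.frame", n_decoys = "numeric",
    breathing = "list", groove_sep = "numeric",
    contact_spec = "list", two_subunits = "logical"
  ))

setValidity("SyntheticSpec", function(object) {
  msg <- character(0)
  if (object@flip_rate < 0) msg <- c(msg, "flip_rate must be >= 0")
  if (object@transit_time <= 0) msg <- c(msg, "transit_time must be > 0")
  if (object@dt <= 0 || object@duration <= 0)
    msg <- c(msg, "dt and duration must be > 0")
  def <- object@deformation
  if (!identical(def$type, "none") &&
      def$amplitude >= object@bulk_thickness / 2)
    msg <- c(msg, "deformation amplitude must be < bulk_thickness/2")
  if (nrow(object@tracer_spec) &&
      !all(object@tracer_spec$species %in% c("water", "Na", "Cl")))
    msg <- c(msg, "tracer species must be water, Na or Cl")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SyntheticSpec", function(object) {
  cat("SyntheticSpec:", object@n_lipids_per_leaflet, "lipids/leaflet,",
      object@duration, "ns at dt =", object@dt, "ns, seed", object@seed, "\n")
})
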