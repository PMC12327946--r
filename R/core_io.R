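# Trajectory loading, alignment and trimming.

#' Load a trajectory from standard structure/trajectory formats
#'
#' Reads the topology (bead names, residue numbering, chains) from a PDB or
#' GRO file, and coordinates either from the same file (multi-frame GRO or
#' multi-model PDB) or from a separate DCD or multi-frame GRO trajectory.
#' All coordinates are converted to Angstrom and all times to ns.
#'
#' DCD files carry no absolute times; frames are spaced by \code{dt}.
#' DCD files written without a unit cell also carry no box; the box then
#' defaults to the coordinate extent per axis (override with \code{box}).
#'
#' @param topology_path PDB or GRO file
#' @param trajectory_path optional DCD or GRO trajectory; when NULL the
#'   frames of the topology file are used
#' @param role_map named character vector mapping bead names to roles;
#'   unknown bead names are a hard error listing the offenders
#' @param dt frame spacing in ns for formats without time stamps
#' @param box optional length-3 box override (Angstrom)
#' @return a [Trajectory-class]
#' @export
loadTrajectory <- function(topology_path, trajectory_path = NULL,
                           role_map = defaultRoleMap(), dt = 1, box = NULL) {
  if (!file.exists(topology_path)) stop("topology file not found: ", topology_path)
  ext <- tolower(tools::file_ext(topology_path))
  if (ext == "gro") {
    g <- readGRO(topology_path)
    beads <- g$beads; coords <- g$coords; times <- g$times; boxm <- g$box
  } else if (ext == "pdb") {
    multi <- any(grepl("^MODEL", readLines(topology_path, n = 2000L)))
    pdb <- bio3d::read.pdb(topology_path, multi = multi)
    a <- pdb$atom
    beads <- data.frame(residue_index = a$resno, residue_name = a$resid,
                        name = a$elety,
                        chain_id = ifelse(is.na(a$chain) | a$chain == "", "A", a$chain),
                        stringsAsFactors = FALSE)
    xyz <- pdb$xyz
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
    nf <- nrow(xyz)
    coords <- array(0, dim = c(nrow(beads), 3, nf))
    for (f in seq_len(nf))
      coords[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
    times <- seq(0, by = dt, length.out = nf)
    boxm <- NULL
  } else stop("unsupported topology format: ", ext)

  if (!is.null(trajectory_path)) {
    if (!file.exists(trajectory_path)) stop("trajectory file not found: ", trajectory_path)
    text <- tolower(tools::file_ext(trajectory_path))
    if (text == "dcd") {
      xyz <- bio3d::read.dcd(trajectory_path, verbose = FALSE)
      if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
      if (ncol(xyz) != 3 * nrow(beads))
        stop("frame/bead count mismatch: trajectory has ", ncol(xyz) / 3,
             " beads, topology has ", nrow(beads))
      nf <- nrow(xyz)
      coords <- array(0, dim = c(nrow(beads), 3, nf))
      for (f in seq_len(nf))
        coords[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
      times <- seq(0, by = dt, length.out = nf)
      boxm <- NULL
    } else if (text == "gro") {
      g <- readGRO(trajectory_path)
      if (dim(g$coords)[1] != nrow(beads))
        stop("frame/bead count mismatch between topology and trajectory")
      coords <- g$coords; times <- g$times; boxm <- g$box
    } else stop("unsupported trajectory format: ", text)
  }
  if (!is.null(box)) boxm <- matrix(rep(box, each = dim(coords)[3]), ncol = 3)
  if (is.null(boxm)) {
    ext3 <- apply(coords, 2, function(m) diff(range(m)))
    boxm <- matrix(rep(pmax(ext3, 1), each = dim(coords)[3]), ncol = 3)
  }
  newTrajectory(beads, coords, times, boxm, role_map = role_map)
}

#' Write a trajectory back to disk
#'
#' @param traj a [Trajectory-class]
#' @param topology_path output PDB or GRO (frame 1, or all frames for GRO
#'   when no separate trajectory is requested)
#' @param trajectory_path optional DCD output for the coordinate frames
#' @export
writeTrajectory <- function(traj, topology_path, trajectory_path = NULL) {
  ext <- tolower(tools::file_ext(topology_path))
  if (ext == "gro") {
    writeGRO(traj, topology_path,
             frames = if (is.null(trajectory_path)) seq_len(nFrames(traj)) else 1L)
  } else if (ext == "pdb") {
    b <- traj@beads
    # PDB's residue-name field is 3 characters; longer CG residue names
    # (DOPC) are truncated on output
    bio3d::write.pdb(file = topology_path,
                     xyz = as.vector(t(traj@coords[, , 1])),
                     resno = b$residue_index,
                     resid = substr(b$residue_name, 1, 3),
                     elety = b$name, chain = b$chain_id)
  } else stop("unsupported topology format: ", ext)
  if (!is.null(trajectory_path)) writeDCD(traj, trajectory_path)
  invisible(topology_path)
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares rotation + translation mapping \code{moving} onto
#' \code{ref}. Used frame-by-frame by [alignSubunit()].
#'
#' @param moving,ref (n x 3) coordinate matrices, n >= 3
#' @return list(R = 3x3 rotation, center_moving, center_ref); apply as
#'   \code{sweep(X, 2, center_moving) \%*\% t(R) + center_ref}
#' @export
kabsch <- function(moving, ref) {
  if (nrow(moving) < 3L) stop("superposition needs at least 3 beads")
  cm <- colMeans(moving); cr <- colMeans(ref)
  P <- sweep(moving, 2, cm); Q <- sweep(ref, 2, cr)
  H <- crossprod(P, Q)
  s <- svd(H)
  if (s$d[2] < 1e-8 * max(s$d[1], 1))
    stop("degenerate (collinear) alignment selection")
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(R = R, center_moving = cm, center_ref = cr)
}

#' Align each frame onto the first frame by a subunit selection
#'
#' Rigid-body least-squares superposition of every frame's selection onto
#' the frame-1 selection; the fitted transformation is applied to all
#' beads. Frame 1 is left unchanged. By default the selection is the
#' backbone (BB) beads of the chosen residues; if none exist, all beads of
#' the selection are used.
#'
#' @param traj a [Trajectory-class]
#' @param chain_id chain to align on
#' @param residues optional residue-index vector restricting the selection
#' @param bead_names bead names used for fitting (default backbone)
#' @return the aligned [Trajectory-class], with the chain recorded in the
#'   \code{aligned} slot
#' @export
alignSubunit <- function(traj, chain_id, residues = NULL, bead_names = "BB") {
  b <- traj@beads
  sel <- b$chain_id == chain_id
  if (!is.null(residues)) sel <- sel & b$residue_index %in% residues
  fit <- sel & b$name %in% bead_names
  if (sum(fit) < 3L) fit <- sel
  if (sum(fit) < 3L)
    stop("alignment selection resolves to fewer than 3 beads")
  idx <- which(fit)
  ref <- traj@coords[idx, , 1]
  for (f in seq_len(nFrames(traj))[-1]) {
    k <- kabsch(traj@coords[idx, , f], ref)
    traj@coords[, , f] <-
      sweep(sweep(traj@coords[, , f], 2, k$center_moving) %*% t(k$R),
            2, k$center_ref, "+")
  }
  traj@aligned <- union(traj@aligned, chain_id)
  validObject(traj)
  traj
}

#' Discard the equilibration span at the start of a trajectory
#'
#' Removes all frames earlier than \code{t_eq} ns after the first retained
#' frame; absolute frame times are preserved so downstream durations are
#' computed from the retained span.
#'
#' @param traj a [Trajectory-class]
#' @param t_eq equilibration time to discard (ns), 0 <= t_eq < duration
#' @return trimmed [Trajectory-class]
#' @export
discardEquilibration <- function(traj, t_eq) {
  if (t_eq < 0) stop("t_eq must be non-negative")
  if (t_eq == 0) return(traj)
  span <- traj@times[nFrames(traj)] - traj@times[1]
  if (t_eq >= span + timeStep(traj))
    stop("t_eq (", t_eq, " ns) is not shorter than the trajectory")
  keep <- traj@times >= traj@times[1] + t_eq
  if (!any(keep)) stop("t_eq removes every frame")
  traj@coords <- traj@coords[, , keep, drop = FALSE]
  traj@times <- traj@times[keep]
  traj@box <- traj@box[keep, , drop = FALSE]
  validObject(traj)
  traj
}

#' Retained duration of a trajectory (ns)
#' @param traj a [Trajectory-class]
#' @export
trajectoryDuration <- function(traj) {
  diff(range(traj@times)) + timeStep(traj)
}

#' Make molecules whole across periodic boundaries
#'
#' Applies the minimum-image convention within each residue relative to its
#' first bead, so intra-lipid vectors (orientation angles, bead spans) are
#' meaningful when the source trajectory is wrapped.
#'
#' @param traj a [Trajectory-class]
#' @return unwrapped [Trajectory-class]
#' @export
makeWhole <- function(traj) {
  b <- traj@beads
  first <- !duplicated(paste(b$chain_id, b$residue_index))
  anchor <- cumsum(first)          # residue group per bead
  a_idx <- which(first)[anchor]    # index of each bead's anchor bead
  for (f in seq_len(nFrames(traj))) {
    L <- traj@box[f, ]
    d <- traj@coords[, , f] - traj@coords[a_idx, , f]
    shift <- sweep(round(sweep(d, 2, L, "/")), 2, L, "*")
    traj@coords[, , f] <- traj@coords[, , f] - shift
  }
  traj
}

#' Write a PDB colored by a per-residue value (B-factor column)
#'
#' Standard trick for visualizing per-residue statistics (e.g. top-50%
#' mean dwell times) on the structure.
#'
#' @param traj a [Trajectory-class] (frame 1 is written)
#' @param values named numeric vector: names are residue indices
#' @param path output PDB path
#' @param chain_id restrict to one chain (default all protein beads)
#' @export
writeBFactorPDB <- function(traj, values, path, chain_id = NULL) {
  b <- traj@beads
  sel <- b$role == "protein"
  if (!is.null(chain_id)) sel <- sel & b$chain_id %in% chain_id
  bb <- b[sel, ]
  bvals <- values[as.character(bb$residue_index)]
  bvals[is.na(bvals)] <- 0
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(traj@coords[sel, , 1])),
                   resno = bb$residue_index,
                   resid = substr(bb$residue_name, 1, 3),
                   elety = bb$name, chain = bb$chain_id, b = bvals)
  invisible(path)
}
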