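# 3D bead-density accumulation in a groove-local frame and extraction of
# a membrane-spanning maximum-density pathway.

#' Accumulate a 3D bead-density grid
#'
#' Per frame, each selected bead increments the count of the cell
#' containing it. The grid is centered laterally/vertically on the groove
#' center of each subunit (typically the midpoint of the TM4 and TM6
#' residue-range centroids near the midplane); grids from several
#' subunits are averaged after mapping into this common groove-local
#' frame. The trajectory must have been aligned per subunit first
#' ([alignSubunit()]) so that the protein frame is static.
#'
#' @param traj a [Trajectory-class]
#' @param role bead role to accumulate (e.g. "lipid_head",
#'   "lipid_phosphate", "water")
#' @param centers list of xyz groove centers (one per subunit), or a
#'   single numeric xyz
#' @param extent grid extent (Lx, Ly, Lz) in Angstrom, default
#'   c(100, 100, 150)
#' @param spacing cell edge (Angstrom), default 0.5
#' @return a [DensityGrid-class] with origin relative to the groove center
#' @export
accumulateDensity <- function(traj, role, centers,
                              extent = c(100, 100, 150), spacing = 0.5) {
  if (!length(traj@aligned))
    stop("trajectory is not subunit-aligned; run alignSubunit() first")
  if (is.numeric(centers)) centers <- list(centers)
  sel <- which(traj@beads$role == role)
  if (!length(sel)) stop("no beads with role ", role)
  dims <- as.integer(round(extent / spacing))
  origin <- -extent / 2
  counts <- array(0, dim = dims)
  nf <- nFrames(traj)
  for (ctr in centers) {
    x <- as.vector(traj@coords[sel, 1, ]) - ctr[1] - origin[1]
    y <- as.vector(traj@coords[sel, 2, ]) - ctr[2] - origin[2]
    z <- as.vector(traj@coords[sel, 3, ]) - ctr[3] - origin[3]
    ix <- floor(x / spacing); iy <- floor(y / spacing); iz <- floor(z / spacing)
    ok <- ix >= 0 & ix < dims[1] & iy >= 0 & iy < dims[2] &
      iz >= 0 & iz < dims[3]
    lin <- ix[ok] + dims[1] * (iy[ok] + dims[2] * iz[ok]) + 1
    tab <- tabulate(lin, nbins = prod(dims))
    counts <- counts + array(tab, dim = dims)
  }
  new("DensityGrid", origin = origin, spacing = spacing,
      counts = counts / length(centers), n_frames = nf,
      n_chains = length(centers))
}

#' Extract a membrane-spanning maximum-density pathway
#'
#' Slab-wise constrained argmax: for each z slab (one cell thick), the
#' candidate is the highest-density cell within \code{tube_radius} of the
#' previous node (of the slab center for the first slab); the node is the
#' density-weighted centroid of the candidate's 3x3 in-plane
#' neighborhood. Empty slabs are interpolated linearly between flanking
#' slabs (with a warning); more than 20 percent empty slabs is an error.
#'
#' @param grid a [DensityGrid-class]
#' @param z_range span of slab centers to walk, in grid coordinates
#'   (Angstrom, same frame as \code{grid@origin}); default the full grid
#' @param tube_radius lateral search radius (Angstrom), default 15
#' @param start optional xy center anchoring the walk at its starting
#'   (midplane) slab; defaults to the lateral grid center, i.e. the
#'   groove center
#' @return a [Pathway-class] with source "lipid_density"
#' @export
extractPathway <- function(grid, z_range = NULL, tube_radius = 15,
                           start = NULL) {
  d <- dim(grid@counts); h <- grid@spacing
  cxs <- grid@origin[1] + (seq_len(d[1]) - 0.5) * h
  cys <- grid@origin[2] + (seq_len(d[2]) - 0.5) * h
  czs <- grid@origin[3] + (seq_len(d[3]) - 0.5) * h
  if (is.null(z_range)) z_range <- range(czs)
  slabs <- which(czs >= z_range[1] & czs <= z_range[2])
  if (!length(slabs)) stop("z_range contains no slabs")
  if (is.null(start)) start <- c(0, 0)
  xs <- matrix(rep(cxs, d[2]), d[1], d[2])
  ys <- matrix(rep(cys, each = d[1]), d[1], d[2])
  nodes <- matrix(NA_real_, length(slabs), 3)
  n_empty <- 0L
  step <- function(si, prev) {
    sl <- grid@counts[, , slabs[si]]
    inr <- (xs - prev[1])^2 + (ys - prev[2])^2 <= tube_radius^2
    slm <- sl; slm[!inr] <- 0
    if (max(slm) <= 0) { n_empty <<- n_empty + 1L; return(prev) }
    w <- which(slm == max(slm), arr.ind = TRUE)[1, ]
    # density-weighted centroid of the 3x3 in-plane neighborhood
    xi <- max(1, w[1] - 1):min(d[1], w[1] + 1)
    yi <- max(1, w[2] - 1):min(d[2], w[2] + 1)
    nb <- sl[xi, yi, drop = FALSE]
    node <- c(sum(xs[xi, yi] * nb), sum(ys[xi, yi] * nb)) / sum(nb)
    nodes[si, ] <<- c(node, czs[slabs[si]])
    node
  }
  # walk outward from the midplane slab: at the membrane core the groove
  # is the only density, which anchors the walk before it meets the
  # laterally uniform headgroup bands
  s0 <- which.min(abs(czs[slabs] - mean(z_range)))
  prev <- step(s0, start)
  for (si in seq_along(slabs)[-seq_len(s0)]) prev <- step(si, prev)
  prev <- nodes[s0, 1:2]
  if (anyNA(prev)) prev <- start
  for (si in rev(seq_len(s0 - 1))) prev <- step(si, prev)
  if (n_empty > 0.2 * length(slabs))
    stop("more than 20% of slabs carry no density along the tube")
  if (n_empty > 0) {
    warning(n_empty, " empty slab(s) interpolated")
    miss <- is.na(nodes[, 1])
    nodes[miss, 3] <- czs[slabs[miss]]
    for (ax in 1:2)
      nodes[miss, ax] <- stats::approx(czs[slabs[!miss]], nodes[!miss, ax],
                                       xout = czs[slabs[miss]], rule = 2)$y
  }
  new("Pathway", nodes = nodes, source = "lipid_density")
}

#' Export a density grid as OpenDX
#'
#' Thin wrapper over [writeDX()] kept as the module's named export.
#'
#' @param grid a [DensityGrid-class]
#' @param path output .dx path
#' @export
exportGrid <- function(grid, path) writeDX(grid, path)
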