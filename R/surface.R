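# Ensemble-averaged leaflet surfaces from glycerol beads, with per-frame
# leaflet assignment, occupancy/connectivity filters, and the minimal
# leaflet-to-leaflet distance.

#' Per-frame leaflet labels from the scrambling state machine
#'
#' The label of a lipid at a frame is its current hysteresis state (upper
#' or lower), so labels change only at completed threshold crossings and
#' a scrambling lipid never contributes to both leaflets in one frame.
#' The walk runs on the raw angle trace (same 35/145 hysteresis): the raw
#' angle crosses the destination threshold at the end of the physical
#' transit, whereas the smoothed trace used for event detection crosses
#' roughly half a smoothing window later, which would leave freshly
#' flipped lipids accumulating on their origin leaflet's surface.
#'
#' @param set an [AngleSeriesSet-class]
#' @param theta_low,theta_high hysteresis thresholds (degrees)
#' @return integer matrix (n_lipids x n_frames), +1 upper / -1 lower, with
#'   lipid ids as rownames
#' @export
assignLeaflets <- function(set, theta_low = 35, theta_high = 145) {
  nf <- length(set@t)
  lab <- matrix(0L, nrow = length(set@lipid_ids), ncol = nf)
  for (r in seq_along(set@lipid_ids)) {
    wk <- .hysteresisWalk(set@theta_raw[r, ], theta_low, theta_high)
    states <- rep(wk$state0, nf)
    if (length(wk$frames))
      for (j in seq_along(wk$frames))
        states[wk$frames[j]:nf] <- wk$states[j]
    lab[r, ] <- states
  }
  rownames(lab) <- set@lipid_ids
  lab
}

#' Ensemble-averaged leaflet surfaces on a 1 Angstrom grid
#'
#' Per frame, each glycerol bead (GL1, GL2) contributes its z to the xy
#' grid cell containing it, split by the lipid's per-frame leaflet label.
#' The cell height is the mean over frames of the per-frame cell means;
#' occupancy is the fraction of frames with at least one contributing
#' bead. Cells with occupancy below \code{occupancy_min} are discarded,
#' then every retained cell outside the largest 8-connected component of
#' its leaflet is discarded (isolated patches are not membrane surface).
#'
#' @param traj a [Trajectory-class]
#' @param labels matrix from [assignLeaflets()] (rownames = lipid ids)
#' @param spacing grid spacing (Angstrom), default 1
#' @param occupancy_min minimum cell occupancy, default 0.02
#' @return a [SurfacePair-class]
#' @export
averageSurfaces <- function(traj, labels, spacing = 1, occupancy_min = 0.02) {
  li <- lipidIndex(traj, require = "lipid_head")
  if (anyNA(li$i_gl1) || anyNA(li$i_gl2))
    stop("lipid(s) missing glycerol beads GL1/GL2")
  ord <- match(li$lipid_id, as.integer(rownames(labels)))
  if (anyNA(ord)) stop("labels matrix does not cover all lipids")
  nf <- nFrames(traj)
  Lx <- max(traj@box[, 1]); Ly <- max(traj@box[, 2])
  nxc <- ceiling(Lx / spacing); nyc <- ceiling(Ly / spacing)

  # long-format observations: one row per glycerol bead per frame
  gl_rows <- c(li$i_gl1, li$i_gl2)
  lip_of <- rep(ord, 2L)
  x <- as.vector(traj@coords[gl_rows, 1, ]) %% Lx
  y <- as.vector(traj@coords[gl_rows, 2, ]) %% Ly
  z <- as.vector(traj@coords[gl_rows, 3, ])
  frame <- rep(seq_len(nf), each = length(gl_rows))
  # labels[lip_of, ] is (n_obs_rows x nf); column-major flattening matches
  # the frame-slowest layout of x/y/z above
  leaf <- as.vector(labels[lip_of, , drop = FALSE])
  ix <- pmin(pmax(floor(x / spacing), 0L), nxc - 1L)
  iy <- pmin(pmax(floor(y / spacing), 0L), nyc - 1L)
  dt_obs <- data.table::data.table(cell = ix + nxc * iy, frame = frame,
                                   leaf = leaf, z = z)
  build <- function(sign) {
    ob <- dt_obs[leaf == sign]
    if (!nrow(ob)) stop("empty leaflet: no glycerol observations")
    per_frame <- ob[, list(zm = mean(z)), by = c("cell", "frame")]
    per_cell <- per_frame[, list(height = mean(zm), nocc = .N), by = "cell"]
    hz <- matrix(NA_real_, nxc, nyc)
    occ <- matrix(0, nxc, nyc)
    hz[per_cell$cell + 1L] <- per_cell$height
    occ[per_cell$cell + 1L] <- per_cell$nocc / nf
    mask <- occ >= occupancy_min
    mask <- .largestComponent(mask)
    hz[!mask] <- NA_real_
    list(z = hz, occ = occ, mask = mask)
  }
  up <- build(1L); lo <- build(-1L)
  new("SurfacePair", origin = c(0, 0), spacing = spacing,
      upper_z = up$z, lower_z = lo$z,
      occ_upper = up$occ, occ_lower = lo$occ,
      mask_upper = up$mask, mask_lower = lo$mask)
}

# largest 8-connected component of a logical matrix (iterative label
# propagation; grids are small enough that simplicity wins)
.largestComponent <- function(mask) {
  if (!any(mask)) return(mask)
  nx <- nrow(mask); ny <- ncol(mask)
  lab <- matrix(0L, nx, ny)
  lab[mask] <- seq_len(sum(mask))
  repeat {
    old <- lab
    for (dx in -1:1) for (dy in -1:1) {
      if (dx == 0 && dy == 0) next
      xs <- max(1, 1 + dx):min(nx, nx + dx)
      xt <- max(1, 1 - dx):min(nx, nx - dx)
      ys <- max(1, 1 + dy):min(ny, ny + dy)
      yt <- max(1, 1 - dy):min(ny, ny - dy)
      nb <- lab[xs, ys, drop = FALSE]
      cur <- lab[xt, yt, drop = FALSE]
      upd <- nb > 0 & cur > 0 & nb < cur
      if (any(upd)) {
        cur[upd] <- nb[upd]
        lab[xt, yt] <- cur
      }
    }
    if (identical(old, lab)) break
  }
  sizes <- table(lab[lab > 0])
  keep <- as.integer(names(sizes)[which.max(sizes)])
  mask & lab == keep
}

#' Minimal leaflet-to-leaflet distance
#'
#' Exact minimum over all retained upper x lower cell pairs of the 3D
#' Euclidean distance between cell centers (at the mean surface heights).
#' This is a full point-pair distance, not a vertical thickness: at deep
#' pinches the closest approach between the two surfaces is oblique.
#' A pruned neighborhood search makes the exact minimum affordable on
#' large grids; restrict to a groove neighborhood via \code{center} and
#' \code{radius} for the local variant.
#'
#' @param sp a [SurfacePair-class]
#' @param center optional xy center (Angstrom) restricting both masks to a
#'   disk before minimizing
#' @param radius disk radius (Angstrom) when \code{center} is given
#' @param exclude list of xy centers whose disk neighborhoods are removed
#'   from both masks (e.g. transit corridors when comparing against a
#'   bulk reference)
#' @param exclude_radius radius of the excluded disks (Angstrom)
#' @return list(value, point_upper, point_lower)
#' @export
minimalThickness <- function(sp, center = NULL, radius = Inf,
                             exclude = NULL, exclude_radius = 12) {
  mu <- sp@mask_upper; ml <- sp@mask_lower
  if (!any(mu) || !any(ml)) stop("empty surface mask")
  nx <- nrow(mu); ny <- ncol(mu); h <- sp@spacing
  cx <- sp@origin[1] + (row(mu) - 0.5) * h
  cy <- sp@origin[2] + (col(mu) - 0.5) * h
  if (!is.null(center)) {
    disk <- (cx - center[1])^2 + (cy - center[2])^2 <= radius^2
    mu <- mu & disk; ml <- ml & disk
    if (!any(mu) || !any(ml)) stop("no retained cells within the radius")
  }
  if (!is.null(exclude)) {
    for (e in exclude) {
      disk <- (cx - e[1])^2 + (cy - e[2])^2 <= exclude_radius^2
      mu <- mu & !disk; ml <- ml & !disk
    }
    if (!any(mu) || !any(ml)) stop("exclusion removed every retained cell")
  }
  zu <- sp@upper_z; zl <- sp@lower_z
  # initial upper bound from co-located cells (or a coarse sample)
  both <- mu & ml
  if (any(both)) {
    d0 <- min(abs(zu[both] - zl[both]))
  } else {
    iu <- which(mu); il <- which(ml)
    su <- iu[seq(1, length(iu), length.out = min(200, length(iu)))]
    sl <- il[seq(1, length(il), length.out = min(200, length(il)))]
    d0 <- min(sqrt(outer(cx[su], cx[sl], "-")^2 +
                   outer(cy[su], cy[sl], "-")^2 +
                   outer(zu[su], zl[sl], "-")^2))
  }
  best <- d0 + 1e-9
  bi <- NA; bj <- NA
  rmax <- ceiling(best / h)
  for (dx in -rmax:rmax) for (dy in -rmax:rmax) {
    lat2 <- (dx^2 + dy^2) * h^2
    if (lat2 > best^2) next
    xs <- max(1, 1 + dx):min(nx, nx + dx)
    xt <- max(1, 1 - dx):min(nx, nx - dx)
    ys <- max(1, 1 + dy):min(ny, ny + dy)
    yt <- max(1, 1 - dy):min(ny, ny - dy)
    ok <- mu[xt, yt, drop = FALSE] & ml[xs, ys, drop = FALSE]
    if (!any(ok)) next
    dz <- zu[xt, yt, drop = FALSE] - zl[xs, ys, drop = FALSE]
    d2 <- lat2 + dz^2
    d2[!ok] <- Inf
    m <- min(d2)
    if (m < best^2) {
      best <- sqrt(m)
      w <- which(d2 == m, arr.ind = TRUE)[1, ]
      bi <- c(xt[1] + w[1] - 1L, yt[1] + w[2] - 1L)            # upper cell
      bj <- c(xs[1] + w[1] - 1L, ys[1] + w[2] - 1L)            # lower cell
    }
  }
  pu <- c(cx[bi[1], bi[2]], cy[bi[1], bi[2]], zu[bi[1], bi[2]])
  pl <- c(cx[bj[1], bj[2]], cy[bj[1], bj[2]], zl[bj[1], bj[2]])
  list(value = best, point_upper = pu, point_lower = pl)
}

#' Write a surface pair as CSV (x, y, upper_z, lower_z, occupancies)
#' @param sp a [SurfacePair-class]
#' @param path output .csv
#' @export
writeSurfaces <- function(sp, path) {
  h <- sp@spacing
  df <- data.frame(
    x = sp@origin[1] + (as.vector(row(sp@upper_z)) - 0.5) * h,
    y = sp@origin[2] + (as.vector(col(sp@upper_z)) - 0.5) * h,
    upper_z = as.vector(sp@upper_z), lower_z = as.vector(sp@lower_z),
    occ_upper = as.vector(sp@occ_upper), occ_lower = as.vector(sp@occ_lower))
  utils::write.csv(df[!is.na(df$upper_z) | !is.na(df$lower_z), ], path,
                   row.names = FALSE)
  invisible(path)
}
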