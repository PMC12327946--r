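# Directed water/ion permeation counting through a membrane-spanning
# pathway tube, and selectivity ratios from total counts.

#' Count directed permeation events through a pathway tube
#'
#' Zone-based state machine per particle over zones below / inside /
#' above, with the membrane span \code{z_bounds} widened by
#' \code{z_margin} on each side. A directed event is recorded when a
#' particle that last came from one outer zone exits to the opposite
#' outer zone while being within \code{tube_radius} of the pathway at its
#' midplane crossing. Re-crossings count separately; particles that reach
#' the midplane and retreat count nothing.
#'
#' @param traj a [Trajectory-class]
#' @param species "water", "Na" or "Cl"
#' @param pathway a [Pathway-class]
#' @param tube_radius lateral capture radius (Angstrom), default 8
#' @param z_bounds c(z_lower, z_upper) membrane span (Angstrom), e.g. the
#'   average leaflet surface heights; default from the pathway's inner span
#' @param z_margin widening of the span (Angstrom), default 5
#' @return object of class \code{PermeationCounts}: list(species,
#'   up_count, down_count, total, rate_per_us, tube_radius, z_bounds)
#' @export
countPermeation <- function(traj, species = c("water", "Na", "Cl"),
                            pathway, tube_radius = 8, z_bounds = NULL,
                            z_margin = 5) {
  species <- match.arg(species)
  if (missing(pathway) || is.null(pathway)) stop("pathway is required")
  role <- switch(species, water = "water", Na = "ion_cation",
                 Cl = "ion_anion")
  sel <- which(traj@beads$role == role)
  if (is.null(z_bounds)) {
    zr <- range(pathway@nodes[, 3])
    z_bounds <- c(zr[1] + z_margin, zr[2] - z_margin)
  }
  zlo <- z_bounds[1] - z_margin; zhi <- z_bounds[2] + z_margin
  zmid <- mean(z_bounds)
  up <- 0L; down <- 0L
  for (i in sel) {
    z <- traj@coords[i, 3, ]
    lat <- pathwayAt(pathway, z)
    r <- sqrt((traj@coords[i, 1, ] - lat[, 1])^2 +
              (traj@coords[i, 2, ] - lat[, 2])^2)
    zone <- ifelse(z < zlo, -1L, ifelse(z > zhi, 1L, 0L))
    from <- 0L  # outer zone the particle last occupied
    for (f in seq_along(z)) {
      if (zone[f] == 0L) next
      if (from != 0L && zone[f] == -from) {
        # walked the slab from one side to the other: locate the midplane
        # crossing inside the traversal and check the tube constraint
        seg <- which(traj@times > t_enter & traj@times <= traj@times[f])
        cross <- seg[which(sign(z[seg] - zmid) != sign(from))[1]]
        if (!is.na(cross) && r[cross] <= tube_radius) {
          if (from < 0L) up <- up + 1L else down <- down + 1L
        }
      }
      if (zone[f] != from) t_enter <- traj@times[f]
      from <- zone[f]
    }
  }
  dur <- trajectoryDuration(traj)
  structure(list(species = species, up_count = up, down_count = down,
                 total = up + down, rate_per_us = (up + down) / (dur / 1000),
                 tube_radius = tube_radius, z_bounds = z_bounds),
            class = "PermeationCounts")
}

#' @export
print.PermeationCounts <- function(x, ...) {
  cat(sprintf("%s permeation: %d up, %d down (total %d; %.2f events/us)\n",
              x$species, x$up_count, x$down_count, x$total, x$rate_per_us))
  invisible(x)
}

#' Cation-to-anion selectivity from total permeation counts
#'
#' \code{P_Na / P_Cl} as the ratio of total counted events. With no anion
#' events but some cation events the ratio is +Inf; with neither it is
#' NaN (undefined) -- markers, not errors.
#'
#' @param counts_na,counts_cl \code{PermeationCounts} for Na and Cl (or
#'   bare totals)
#' @return list(p_na_over_cl, n_na, n_cl)
#' @export
selectivity <- function(counts_na, counts_cl) {
  n_na <- if (is.list(counts_na)) counts_na$total else counts_na
  n_cl <- if (is.list(counts_cl)) counts_cl$total else counts_cl
  ratio <- if (n_cl > 0) n_na / n_cl else if (n_na > 0) Inf else NaN
  list(p_na_over_cl = ratio, n_na = n_na, n_cl = n_cl)
}
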