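# In-groove lipid energetics and kinetics: Boltzmann-inverted free-energy
# profile of the in-tube headgroup density, per-event transit dwell
# times, and an MSD-based diffusion coefficient along the pathway.

#' Free-energy profile along the pathway by Boltzmann inversion
#'
#' Histograms the z coordinate (projected onto the pathway, which is
#' parameterized by z) of phosphate beads found within the pathway tube,
#' and inverts: \code{G(s) = -kT log(rho(s) / max rho)}, so the minimum
#' of G is 0 at the densest bin. Zero-count bins are flagged (G = NA),
#' never silently interpolated. The barrier height is the maximum G over
#' the membrane-spanning region.
#'
#' @param traj a [Trajectory-class]
#' @param pathway a [Pathway-class]
#' @param lipid_ids restrict to these lipids (default all)
#' @param tube_radius lateral capture radius (Angstrom), default 8
#' @param bin bin width along the pathway (Angstrom), default 1
#' @param kT thermal energy unit, default 1 (profile in kT)
#' @param span c(z_lower, z_upper) membrane-spanning region for the
#'   barrier (default: the inner 80 percent of the pathway's z range)
#' @return object of class \code{FreeEnergyProfile}: data.frame (s, G,
#'   counts) plus \code{barrier_height} attribute-style list fields
#' @export
freeEnergyProfile <- function(traj, pathway, lipid_ids = NULL,
                              tube_radius = 8, bin = 1, kT = 1,
                              span = NULL) {
  li <- .po4Index(traj)
  if (!is.null(lipid_ids)) li <- li[li$lipid_id %in% lipid_ids, ]
  x <- as.vector(traj@coords[li$i_po4, 1, ])
  y <- as.vector(traj@coords[li$i_po4, 2, ])
  z <- as.vector(traj@coords[li$i_po4, 3, ])
  lat <- pathwayAt(pathway, z)
  keep <- (x - lat[, 1])^2 + (y - lat[, 2])^2 <= tube_radius^2
  zr <- range(pathway@nodes[, 3])
  keep <- keep & z >= zr[1] & z <= zr[2]
  z <- z[keep]
  if (!length(z)) stop("no in-tube headgroup observations")
  edges <- seq(zr[1], zr[2] + bin, by = bin)
  counts <- tabulate(findInterval(z, edges), nbins = length(edges) - 1)
  s <- (utils::head(edges, -1) + edges[-1]) / 2
  G <- ifelse(counts > 0, -kT * log(counts / max(counts)), NA_real_)
  if (is.null(span)) span <- zr + c(0.1, -0.1) * diff(zr)
  inside <- s >= span[1] & s <= span[2]
  barrier <- max(G[inside], na.rm = TRUE) - min(G[inside], na.rm = TRUE)
  structure(list(profile = data.frame(s = s, G = G, counts = counts),
                 barrier_height = barrier, kT = kT,
                 n_obs = length(z), span = span),
            class = "FreeEnergyProfile")
}

#' @export
print.FreeEnergyProfile <- function(x, ...) {
  cat(sprintf(
    "Free-energy profile: %d observations, %d bins, barrier %.2f kT\n",
    x$n_obs, nrow(x$profile), x$barrier_height))
  invisible(x)
}

#' Transit dwell times and in-groove diffusion coefficient
#'
#' Per event, the transit dwell is the contiguous stretch of frames the
#' lipid's phosphate bead stays inside the pathway tube around its
#' midplane crossing. The diffusion coefficient is estimated from the
#' pooled mean-squared displacement of the tube-projected coordinate over
#' lag times \code{lags} within the transit windows, by a weighted
#' least-squares fit of MSD = 2 D tau through the origin (1D diffusion
#' along the pathway).
#'
#' @param events events data.frame ([detectEvents()]); may be empty when
#'   \code{windows} is supplied
#' @param traj a [Trajectory-class]
#' @param pathway a [Pathway-class]
#' @param tube_radius lateral capture radius (Angstrom), default 8
#' @param lags lag times for the MSD fit (ns), default 1:10
#' @param windows optional explicit windows data.frame (lipid_id,
#'   t_start, t_end) overriding the event-derived transit windows
#' @param min_events minimum number of windows for a D estimate
#' @return object of class \code{TransitKinetics}: list(transit_dwell,
#'   D_estimate, D_se, msd = data.frame(tau, msd, n))
#' @export
transitKinetics <- function(events, traj, pathway, tube_radius = 8,
                            lags = 1:10, windows = NULL, min_events = 5) {
  li <- .po4Index(traj)
  dt <- timeStep(traj)
  zr <- range(pathway@nodes[, 3])
  zmid <- mean(zr)
  segments <- list(); dwells <- numeric(0)
  if (is.null(windows)) {
    for (i in seq_len(nrow(events))) {
      row <- li[match(events$lipid_id[i], li$lipid_id), ]
      z <- traj@coords[row$i_po4, 3, ]
      lat <- pathwayAt(pathway, z)
      inside <- (traj@coords[row$i_po4, 1, ] - lat[, 1])^2 +
        (traj@coords[row$i_po4, 2, ] - lat[, 2])^2 <= tube_radius^2
      inside <- inside & z > zr[1] & z < zr[2]
      # the contiguous in-tube run containing the midplane crossing
      fc <- which(traj@times <= events$t_complete[i] &
                  traj@times >= events$t_enter_band[i] & z >= zmid - 5 &
                  z <= zmid + 5)
      fc <- fc[inside[fc]][1]
      if (is.na(fc)) next
      runs <- rle(inside)
      ends <- cumsum(runs$lengths)
      ri <- which(ends >= fc)[1]
      f1 <- ends[ri] - runs$lengths[ri] + 1L; f2 <- ends[ri]
      dwells <- c(dwells, (f2 - f1 + 1L) * dt)
      segments[[length(segments) + 1L]] <- z[f1:f2]
    }
  } else {
    for (i in seq_len(nrow(windows))) {
      row <- li[match(windows$lipid_id[i], li$lipid_id), ]
      fr <- which(traj@times >= windows$t_start[i] &
                  traj@times <= windows$t_end[i])
      dwells <- c(dwells, length(fr) * dt)
      segments[[length(segments) + 1L]] <- traj@coords[row$i_po4, 3, fr]
    }
  }
  lagf <- round(lags / dt)
  msd <- rep(0, length(lags)); npairs <- rep(0, length(lags))
  for (seg in segments) {
    n <- length(seg)
    for (j in seq_along(lagf)) {
      L <- lagf[j]
      if (n > L) {
        dz <- seg[(L + 1):n] - seg[1:(n - L)]
        msd[j] <- msd[j] + sum(dz^2)
        npairs[j] <- npairs[j] + length(dz)
      }
    }
  }
  ok <- npairs > 0
  D <- NA_real_; Dse <- NA_real_
  if (length(segments) >= min_events && sum(ok) >= 2) {
    mtab <- data.frame(tau = lags[ok], msd = msd[ok] / npairs[ok],
                       n = npairs[ok])
    fit <- stats::lm(msd ~ 0 + tau, data = mtab, weights = mtab$n)
    D <- unname(coef(fit)[1] / 2)
    Dse <- unname(sqrt(diag(stats::vcov(fit)))[1] / 2)
  } else {
    mtab <- data.frame(tau = lags[ok], msd = ifelse(npairs[ok] > 0,
                                                    msd[ok] / npairs[ok], NA),
                       n = npairs[ok])
  }
  structure(list(transit_dwell = dwells, D_estimate = D, D_se = Dse,
                 msd = mtab, n_windows = length(segments)),
            class = "TransitKinetics")
}

#' @export
print.TransitKinetics <- function(x, ...) {
  cat(sprintf("Transit kinetics: %d windows, mean dwell %.1f ns, D = %s\n",
              x$n_windows,
              if (length(x$transit_dwell)) mean(x$transit_dwell) else NA,
              if (is.na(x$D_estimate)) "undefined" else
                sprintf("%.1f +/- %.1f A^2/ns", x$D_estimate, 2 * x$D_se)))
  invisible(x)
}
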