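# Flip-flop (scrambling) event detection from per-lipid orientation
# angles, in/out-of-groove classification, block-averaged rates and
# Poisson diagnostics.

#' Centered running mean with edge truncation
#'
#' Window of \code{w} points centered on each sample; at the series edges
#' the window is truncated to the available samples (no padding).
#'
#' @param x numeric vector
#' @param w odd window length in samples
#' @return smoothed vector, same length
#' @export
runningMean <- function(x, w) {
  n <- length(x)
  if (w <= 1 || n == 1) return(x)
  h <- floor(w / 2)
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - h, 1L); hi <- pmin(i + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Per-lipid orientation angle series
#'
#' For every lipid, the angle between the mean of the two choline-to-tail
#' vectors (NC3 to C4A and NC3 to C4B) and the +z axis, in degrees, on the
#' trajectory time grid, plus a centered running average over
#' \code{window} ns (truncated at the edges). Upper-leaflet lipids rest
#' near 150 degrees, lower-leaflet lipids near 30 degrees.
#'
#' @param traj a [Trajectory-class]
#' @param window smoothing window (ns), default 100
#' @return an [AngleSeriesSet-class]
#' @export
lipidOrientationAngles <- function(traj, window = 100) {
  li <- lipidIndex(traj)
  nf <- nFrames(traj)
  nlip <- nrow(li)
  vx <- (traj@coords[li$i_c4a, 1, ] + traj@coords[li$i_c4b, 1, ]) / 2 -
    traj@coords[li$i_nc3, 1, ]
  vy <- (traj@coords[li$i_c4a, 2, ] + traj@coords[li$i_c4b, 2, ]) / 2 -
    traj@coords[li$i_nc3, 2, ]
  vz <- (traj@coords[li$i_c4a, 3, ] + traj@coords[li$i_c4b, 3, ]) / 2 -
    traj@coords[li$i_nc3, 3, ]
  if (nlip == 1) { vx <- rbind(vx); vy <- rbind(vy); vz <- rbind(vz) }
  cosang <- vz / sqrt(vx^2 + vy^2 + vz^2)
  theta <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  dimnames(theta) <- NULL
  dt <- timeStep(traj)
  wf <- max(1L, round(window / dt))
  if (wf %% 2 == 0) wf <- wf + 1L
  smooth <- t(apply(theta, 1, runningMean, w = wf))
  new("AngleSeriesSet", t = traj@times, lipid_ids = as.integer(li$lipid_id),
      theta_raw = theta, theta_smooth = smooth, window = window)
}

# hysteresis walk over one smoothed trace; returns data.frame of crossings
# (frame index + new state) and the initial state (1 = upper, -1 = lower)
.hysteresisWalk <- function(s, theta_low, theta_high) {
  state0 <- if (s[1] > 90) 1 else -1
  cand <- which(s < theta_low | s > theta_high)
  state <- state0
  res_frame <- integer(0); res_state <- integer(0)
  for (i in cand) {
    if (state > 0 && s[i] < theta_low) {
      state <- -1L
      res_frame <- c(res_frame, i); res_state <- c(res_state, state)
    } else if (state < 0 && s[i] > theta_high) {
      state <- 1L
      res_frame <- c(res_frame, i); res_state <- c(res_state, state)
    }
  }
  list(state0 = state0, frames = res_frame, states = res_state)
}

#' Detect completed scrambling events with hysteresis thresholds
#'
#' State machine on the smoothed angle of each lipid: the initial leaflet
#' state is upper when the first smoothed value exceeds 90 degrees, else
#' lower. An upper-to-lower event fires at the first frame the smoothed
#' angle drops below \code{theta_low} while the state is upper (the state
#' flips); symmetrically a lower-to-upper event fires above
#' \code{theta_high}. Excursions into the intermediate band that return
#' emit nothing, which is the point of the stringent 35/145 thresholds.
#'
#' @param set an [AngleSeriesSet-class]
#' @param theta_low lower threshold (degrees), default 35
#' @param theta_high upper threshold (degrees), default 145
#' @return data.frame with one row per event: lipid_id, direction
#'   (upper_to_lower / lower_to_upper), t_complete (ns, threshold-crossing
#'   frame), t_enter_band (ns, last frame still in the origin band),
#'   pathway_class (NA until [classifyPathway()]), subunit (NA)
#' @export
detectEvents <- function(set, theta_low = 35, theta_high = 145) {
  out <- list(); k <- 0L
  for (r in seq_along(set@lipid_ids)) {
    s <- set@theta_smooth[r, ]
    wk <- .hysteresisWalk(s, theta_low, theta_high)
    if (!length(wk$frames)) next
    state_before <- c(wk$state0, utils::head(wk$states, -1))
    for (j in seq_along(wk$frames)) {
      fi <- wk$frames[j]
      from_upper <- state_before[j] > 0
      # last frame still in the origin band before this completion
      prev_end <- if (j > 1) wk$frames[j - 1] else 1L
      seg <- prev_end:fi
      in_origin <- if (from_upper) which(s[seg] > theta_high) else
        which(s[seg] < theta_low)
      t_enter <- if (length(in_origin))
        set@t[seg[max(in_origin)]] else set@t[prev_end]
      k <- k + 1L
      out[[k]] <- data.frame(
        lipid_id = set@lipid_ids[r],
        direction = if (from_upper) "upper_to_lower" else "lower_to_upper",
        t_complete = set@t[fi], t_enter_band = t_enter,
        pathway_class = NA_character_, subunit = NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  if (!k) return(data.frame(lipid_id = integer(0), direction = character(0),
                            t_complete = numeric(0), t_enter_band = numeric(0),
                            pathway_class = character(0),
                            subunit = character(0)))
  ev <- do.call(rbind, out)
  ev[order(ev$t_complete), , drop = FALSE]
}

#' Classify events as in- or out-of-groove
#'
#' An event is in-groove when, during its transit window
#' \code{[t_enter_band, t_complete]}, the lipid's phosphate (PO4) bead
#' comes within \code{r} of any node of a groove pathway while its height
#' lies in the middle half of the membrane span. The nearest subunit's
#' chain id is recorded; ties break by chain-id order.
#'
#' @param events data.frame from [detectEvents()]
#' @param traj the [Trajectory-class]
#' @param pathways a [Pathway-class] or named list of them (one per
#'   subunit); NULL labels all events "unclassified" with a warning
#' @param r capture radius (Angstrom), default 4.7
#' @param membrane_span optional c(z_lower, z_upper); estimated from the
#'   glycerol beads when NULL
#' @return events with pathway_class and subunit filled in
#' @export
classifyPathway <- function(events, traj, pathways, r = 4.7,
                            membrane_span = NULL) {
  if (is.null(pathways) || !length(pathways)) {
    warning("no pathway supplied; events labeled unclassified")
    events$pathway_class <- "unclassified"
    return(events)
  }
  if (is(pathways, "Pathway")) pathways <- list(A = pathways)
  if (is.null(names(pathways)))
    names(pathways) <- LETTERS[seq_along(pathways)]
  pathways <- pathways[order(names(pathways))]
  li <- lipidIndex(traj, require = "lipid_head")
  if (is.null(membrane_span)) {
    glz <- traj@coords[c(li$i_gl1, li$i_gl2), 3, 1]
    membrane_span <- c(mean(glz[glz < 0]), mean(glz[glz > 0]))
  }
  span <- diff(membrane_span)
  zmid <- c(membrane_span[1] + span / 4, membrane_span[2] - span / 4)
  for (i in seq_len(nrow(events))) {
    row <- li[match(events$lipid_id[i], li$lipid_id), ]
    if (is.na(row$i_po4)) { events$pathway_class[i] <- "unclassified"; next }
    win <- which(traj@times >= events$t_enter_band[i] &
                 traj@times <= events$t_complete[i])
    po4 <- traj@coords[row$i_po4, , win, drop = FALSE]
    z <- po4[1, 3, ]
    mid <- z >= zmid[1] & z <= zmid[2]
    best <- Inf; best_chain <- NA_character_
    for (ch in names(pathways)) {
      nd <- pathways[[ch]]@nodes
      if (!any(mid)) next
      px <- po4[1, 1, mid]; py <- po4[1, 2, mid]; pz <- po4[1, 3, mid]
      # nearest node distance per frame, minimized over the window
      dmin <- min(vapply(seq_along(px), function(f)
        sqrt(min((nd[, 1] - px[f])^2 + (nd[, 2] - py[f])^2 +
                 (nd[, 3] - pz[f])^2)), numeric(1)))
      if (dmin < best) { best <- dmin; best_chain <- ch }
    }
    events$pathway_class[i] <- if (best < r) "in_groove" else "out_of_groove"
    events$subunit[i] <- if (best < r) best_chain else NA_character_
  }
  events
}

#' Block-averaged scrambling rate
#'
#' Partitions the retained span into non-overlapping blocks (default 1 us),
#' counts events per block, and reports mean and population standard
#' deviation in events/us. The trailing partial block is discarded.
#'
#' @param events data.frame from [detectEvents()] (or a numeric vector of
#'   event times in ns)
#' @param duration retained span (ns)
#' @param block block length (ns), default 1000
#' @param t0 start of the retained span (ns)
#' @return object of class \code{RateEstimate}: list(mean, sd, n_blocks,
#'   block_length_us, counts)
#' @export
blockRate <- function(events, duration, block = 1000, t0 = 0) {
  if (duration < block)
    stop("duration (", duration, " ns) shorter than one block")
  tt <- if (is.data.frame(events)) events$t_complete else events
  n_blocks <- floor(duration / block)
  idx <- floor((tt - t0) / block)
  idx <- idx[idx >= 0 & idx < n_blocks]
  counts <- tabulate(idx + 1L, nbins = n_blocks)
  per_us <- counts / (block / 1000)
  structure(list(mean = mean(per_us),
                 sd = sqrt(mean((per_us - mean(per_us))^2)),
                 n_blocks = n_blocks, block_length_us = block / 1000,
                 counts = counts),
            class = "RateEstimate")
}

#' @export
print.RateEstimate <- function(x, ...) {
  cat(sprintf("Scrambling rate: %.2f +/- %.2f events/us (%d blocks of %g us)\n",
              x$mean, x$sd, x$n_blocks, x$block_length_us))
  invisible(x)
}

#' Poisson-process diagnostics for event times
#'
#' Two complementary checks that completed events arrive as a Poisson
#' process: a Kolmogorov-Smirnov test of the inter-event gaps against an
#' exponential with rate n/duration, and the dispersion index
#' (variance/mean) of per-block counts. The verdict is "consistent" when
#' the KS p-value is at least 0.05.
#'
#' @param events data.frame from [detectEvents()] or numeric event times (ns)
#' @param duration retained span (ns)
#' @param block block length for the dispersion index (ns)
#' @param t0 start of the retained span (ns)
#' @return object of class \code{PoissonTestResult}: list(n_events,
#'   ks_statistic, p_value, dispersion_index, verdict); verdict is
#'   "undefined" with fewer than 2 events
#' @export
poissonTest <- function(events, duration, block = 1000, t0 = 0) {
  tt <- sort(if (is.data.frame(events)) events$t_complete else events)
  n <- length(tt)
  if (n < 2)
    return(structure(list(n_events = n, ks_statistic = NA_real_,
                          p_value = NA_real_, dispersion_index = NA_real_,
                          verdict = "undefined"),
                     class = "PoissonTestResult"))
  gaps <- diff(tt)
  ks <- suppressWarnings(stats::ks.test(gaps, "pexp", rate = n / duration))
  counts <- blockRate(tt, duration, block, t0)$counts * (block / 1000)
  disp <- if (mean(counts) > 0) stats::var(counts) / mean(counts) else NA_real_
  structure(list(n_events = n, ks_statistic = unname(ks$statistic),
                 p_value = ks$p.value, dispersion_index = disp,
                 verdict = if (ks$p.value >= 0.05) "consistent" else
                   "inconsistent"),
            class = "PoissonTestResult")
}

#' @export
print.PoissonTestResult <- function(x, ...) {
  cat(sprintf(
    "Poisson diagnostics: n = %d, KS p = %.3g, dispersion = %.2f -> %s\n",
    x$n_events, x$p_value, x$dispersion_index, x$verdict))
  invisible(x)
}
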