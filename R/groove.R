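# TM4-TM6 groove dilation: minimum-distance time series, recursive EWMA
# smoothing, open-state statistics, and the thickness-width competence
# classification.

#' Default TM4/TM6 residue ranges per TMEM16 homolog
#'
#' Residue windows flanking the groove constriction used for the
#' TM4-TM6 minimum-distance measurement. Note: the TMEM16F TM4 range is
#' widely printed as "512-424", an apparent typo; this table uses 512-524.
#'
#' @return data.frame: homolog, tm4 (range string), tm6 (range string)
#' @export
grooveResidueDefaults <- function() {
  data.frame(
    homolog = c("nhTMEM16", "afTMEM16", "TMEM16K", "TMEM16F", "TMEM16A"),
    tm4_from = c(327, 319, 365, 512, 541),
    tm4_to = c(339, 331, 377, 524, 553),
    tm6_from = c(430, 426, 434, 613, 635),
    tm6_to = c(452, 438, 446, 625, 647))
}

#' Recursive exponentially weighted moving average
#'
#' \code{s_t = alpha x_t + (1 - alpha) s_(t-1)}, \code{s_1 = x_1}.
#'
#' @param x numeric vector
#' @param alpha smoothing factor in (0, 1], default 0.1
#' @return smoothed vector
#' @export
ewma <- function(x, alpha = 0.1) {
  if (length(x) <= 1) return(x)
  c(x[1], stats::filter(alpha * x[-1], 1 - alpha, method = "recursive",
                        init = x[1]))
}

#' TM4-TM6 minimum-distance series for one subunit
#'
#' Per frame, the minimum over all bead pairs (one bead from each residue
#' range, backbone and side chains alike) of the Euclidean distance,
#' smoothed with the recursive EWMA (smoothing factor \code{alpha});
#' the groove counts as open when the smoothed distance exceeds
#' \code{open_threshold}.
#'
#' @param traj a [Trajectory-class]
#' @param chain_id subunit chain
#' @param tm4_residues,tm6_residues residue-index vectors
#' @param alpha EWMA smoothing factor, default 0.1
#' @param open_threshold open-groove threshold (Angstrom), default 6
#' @return data.frame: t, d_raw, d_smooth, open_flag; chain in attribute
#'   \code{"chain_id"}
#' @export
grooveDistanceSeries <- function(traj, chain_id = "A",
                                 tm4_residues = 327:339,
                                 tm6_residues = 430:452,
                                 alpha = 0.1, open_threshold = 6) {
  b <- traj@beads
  i4 <- which(b$chain_id == chain_id & b$residue_index %in% tm4_residues)
  i6 <- which(b$chain_id == chain_id & b$residue_index %in% tm6_residues)
  if (!length(i4) || !length(i6))
    stop("residue range resolves to no beads (chain ", chain_id, ")")
  nf <- nFrames(traj)
  d_raw <- numeric(nf)
  for (f in seq_len(nf)) {
    a <- traj@coords[i4, , f, drop = FALSE][, , 1, drop = TRUE]
    c2 <- traj@coords[i6, , f, drop = FALSE][, , 1, drop = TRUE]
    if (is.null(dim(a))) a <- matrix(a, nrow = 1)
    if (is.null(dim(c2))) c2 <- matrix(c2, nrow = 1)
    d2 <- outer(rowSums(a^2), rowSums(c2^2), "+") - 2 * tcrossprod(a, c2)
    d_raw[f] <- sqrt(max(min(d2), 0))
  }
  d_smooth <- ewma(d_raw, alpha)
  out <- data.frame(t = traj@times, d_raw = d_raw, d_smooth = d_smooth,
                    open_flag = d_smooth > open_threshold)
  attr(out, "chain_id") <- chain_id
  out
}

#' Groove width statistics and open-state bookkeeping
#'
#' Quartiles of the raw width (the reported error bars are Q1/Q3 of the
#' measured width, so the unsmoothed series feeds them), the fraction of
#' frames the smoothed series is open, and the number of events completed
#' while the groove is open.
#'
#' @param series data.frame from [grooveDistanceSeries()]
#' @param events optional events data.frame ([detectEvents()])
#' @return list: median, q1, q3, open_fraction, events_while_open
#' @export
grooveStats <- function(series, events = NULL) {
  qs <- stats::quantile(series$d_raw, c(0.25, 0.5, 0.75), names = FALSE)
  ew <- 0L
  if (!is.null(events) && nrow(events)) {
    fi <- findInterval(events$t_complete, series$t)
    fi[fi < 1] <- 1L
    ew <- sum(series$open_flag[fi])
  }
  list(median = qs[2], q1 = qs[1], q3 = qs[3],
       open_fraction = mean(series$open_flag), events_while_open = ew)
}

#' Scrambling-competence classification on the thickness-width plane
#'
#' A structure is scrambling-competent when it thins the membrane below
#' 14 Angstrom and holds a median TM4-TM6 width above 6 Angstrom; both
#' inequalities are strict (values exactly at the gates classify as
#' non-competent).
#'
#' @param min_thickness minimal membrane thickness (Angstrom)
#' @param median_width median groove width (Angstrom)
#' @param thickness_gate thinning gate (Angstrom), default 14
#' @param width_gate dilation gate (Angstrom), default 6
#' @return "competent" or "non_competent"
#' @export
classifyCompetence <- function(min_thickness, median_width,
                               thickness_gate = 14, width_gate = 6) {
  stopifnot(min_thickness > 0, median_width > 0)
  if (min_thickness < thickness_gate && median_width > width_gate)
    "competent" else "non_competent"
}
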