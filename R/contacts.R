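# Protein-lipid headgroup contacts: per-residue contact frequency and
# dwell times with gap tolerance, the bead-selection rule (choline vs
# phosphate, whichever dwells longer) and top-50% summarization.

#' Outermost side-chain bead of a residue
#'
#' The side-chain bead with the largest mean distance from the residue's
#' backbone bead over the trajectory; glycine (no side-chain bead) falls
#' back to the backbone bead. Ties break by topology order.
#'
#' @param traj a [Trajectory-class]
#' @param residue_id residue index
#' @param chain_id chain
#' @return bead row index
#' @export
outermostSideChainBead <- function(traj, residue_id, chain_id = "A") {
  b <- traj@beads
  rows <- which(b$residue_index == residue_id & b$chain_id == chain_id &
                b$role == "protein")
  if (!length(rows)) stop("residue ", residue_id, " (chain ", chain_id,
                          ") has no protein beads")
  bb <- rows[b$name[rows] == "BB"]
  sc <- rows[startsWith(b$name[rows], "SC")]
  if (!length(sc)) return(bb[1])
  if (!length(bb)) return(sc[length(sc)])
  md <- vapply(sc, function(i)
    mean(sqrt(colSums((traj@coords[i, , ] - traj@coords[bb[1], , ])^2))),
    numeric(1))
  sc[which.max(md)]
}

#' Per-lipid contact series for one residue
#'
#' Per-frame booleans: distance between the residue's outermost
#' side-chain bead and the chosen headgroup bead of each lipid strictly
#' below \code{cutoff}.
#'
#' @param traj a [Trajectory-class]
#' @param residue_id residue index
#' @param chain_id chain
#' @param bead headgroup bead, "NC3" or "PO4"
#' @param cutoff contact cutoff (Angstrom), default 7
#' @return list: \code{contact} logical matrix (n_lipids x n_frames,
#'   rownames lipid ids), \code{ref_bead} bead row index used
#' @export
contactSeries <- function(traj, residue_id, chain_id = "A",
                          bead = c("PO4", "NC3"), cutoff = 7) {
  bead <- match.arg(bead)
  ref <- outermostSideChainBead(traj, residue_id, chain_id)
  li <- lipidIndex(traj, require = "lipid_head")
  col <- if (bead == "PO4") li$i_po4 else li$i_nc3
  if (anyNA(col)) stop("lipid(s) missing ", bead, " bead")
  dx <- traj@coords[col, 1, , drop = FALSE] - rep(traj@coords[ref, 1, ],
                                                  each = length(col))
  dy <- traj@coords[col, 2, , drop = FALSE] - rep(traj@coords[ref, 2, ],
                                                  each = length(col))
  dz <- traj@coords[col, 3, , drop = FALSE] - rep(traj@coords[ref, 3, ],
                                                  each = length(col))
  d2 <- (dx^2 + dy^2 + dz^2)[, 1, ]
  if (length(col) == 1) d2 <- matrix(d2, nrow = 1)
  contact <- d2 < cutoff^2
  rownames(contact) <- li$lipid_id
  list(contact = contact, ref_bead = ref)
}

#' Merge contact runs into dwell times with gap tolerance
#'
#' Contact runs separated by gaps of at most \code{gap_tolerance} ns are
#' merged into a single dwell; the dwell duration is inclusive of both
#' endpoint frames, \code{(last - first + 1) dt}.
#'
#' @param x logical vector (one lipid's contact series) or logical matrix
#'   (lipids x frames; dwells are pooled over rows)
#' @param dt frame spacing (ns)
#' @param gap_tolerance maximum bridged break (ns), default 6
#' @return numeric vector of dwell durations (ns), possibly empty
#' @export
dwellTimes <- function(x, dt = 1, gap_tolerance = 6) {
  if (is.matrix(x))
    return(unlist(lapply(seq_len(nrow(x)), function(r)
      dwellTimes(x[r, ], dt, gap_tolerance)), use.names = FALSE))
  idx <- which(x)
  if (!length(idx)) return(numeric(0))
  gap_frames <- (diff(idx) - 1L) * dt
  brk <- which(gap_frames > gap_tolerance)
  starts <- idx[c(1L, brk + 1L)]
  ends <- idx[c(brk, length(idx))]
  (ends - starts + 1L) * dt
}

#' Per-residue contact/dwell summary
#'
#' Computes dwell lists against both the choline (NC3) and phosphate
#' (PO4) beads, keeps the bead with the higher mean dwell time, and
#' reports the contact frequency (fraction of frames with at least one
#' lipid in contact, averaged over the monomers carrying the residue)
#' plus the mean of the top 50 percent (ceiling(n/2)) longest dwells.
#'
#' @param traj a [Trajectory-class]
#' @param residue_id residue index
#' @param chains chain ids carrying the residue (frequencies are averaged
#'   over them); defaults to every protein chain containing it
#' @param cutoff contact cutoff (Angstrom)
#' @param gap_tolerance dwell gap tolerance (ns)
#' @return list: residue_id, chosen_bead, contact_frequency, dwell_list,
#'   mean_dwell, top50_mean_dwell, no_contact flag
#' @export
residueSummary <- function(traj, residue_id, chains = NULL, cutoff = 7,
                           gap_tolerance = 6) {
  b <- traj@beads
  if (is.null(chains))
    chains <- sort(unique(b$chain_id[b$residue_index == residue_id &
                                     b$role == "protein"]))
  if (!length(chains)) stop("residue ", residue_id, " not found")
  dt <- timeStep(traj)
  per_bead <- lapply(c("NC3", "PO4"), function(bd) {
    dw <- numeric(0); freq <- numeric(0)
    for (ch in chains) {
      cs <- contactSeries(traj, residue_id, ch, bead = bd, cutoff = cutoff)
      dw <- c(dw, dwellTimes(cs$contact, dt, gap_tolerance))
      freq <- c(freq, mean(colSums(cs$contact) > 0))
    }
    list(dwells = dw, freq = mean(freq))
  })
  names(per_bead) <- c("NC3", "PO4")
  means <- vapply(per_bead, function(p)
    if (length(p$dwells)) mean(p$dwells) else 0, numeric(1))
  chosen <- names(which.max(means))  # ties: first (NC3) by convention
  dw <- per_bead[[chosen]]$dwells
  no_contact <- length(dw) == 0
  top50 <- if (no_contact) NA_real_ else
    mean(sort(dw, decreasing = TRUE)[seq_len(ceiling(length(dw) / 2))])
  list(residue_id = residue_id, chosen_bead = chosen,
       contact_frequency = per_bead[[chosen]]$freq,
       dwell_list = dw,
       mean_dwell = if (no_contact) NA_real_ else mean(dw),
       top50_mean_dwell = top50, no_contact = no_contact)
}

#' Contact summary table over residues
#'
#' @param traj a [Trajectory-class]
#' @param residue_ids residues to summarize (default: all protein residues)
#' @param ... passed to [residueSummary()]
#' @return data.frame: residue, frequency, mean_dwell, top50_mean_dwell,
#'   chosen_bead
#' @export
contactTable <- function(traj, residue_ids = NULL, ...) {
  b <- traj@beads
  if (is.null(residue_ids))
    residue_ids <- sort(unique(b$residue_index[b$role == "protein"]))
  rows <- lapply(residue_ids, function(rid) {
    s <- residueSummary(traj, rid, ...)
    data.frame(residue = rid, frequency = s$contact_frequency,
               mean_dwell = s$mean_dwell,
               top50_mean_dwell = s$top50_mean_dwell,
               chosen_bead = s$chosen_bead)
  })
  do.call(rbind, rows)
}
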