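#' Default bead-name to role mapping (Martini 3 PC lipids)
#'
#' Maps Martini 3 bead names for DOPC/POPC lipids, protein backbone and
#' side-chain beads, water and monatomic ions to the analysis roles used
#' throughout the package. Every bead of a trajectory must resolve to
#' exactly one role; extend the returned vector (or pass your own) for
#' non-standard naming.
#'
#' Roles: \code{lipid_head} (choline NC3), \code{lipid_phosphate} (PO4),
#' \code{lipid_glycerol} (GL1/GL2), \code{lipid_tail_terminal} (C4A/C4B),
#' \code{protein} (BB, SC1..SC4), \code{water} (W), \code{ion_cation}
#' (NA/NA+/SOD), \code{ion_anion} (CL/CL-/CLA), \code{other} (interior
#' tail beads and anything mapped there explicitly).
#'
#' @return named character vector: bead name -> role
#' @export
defaultRoleMap <- function() {
  c(
    NC3 = "lipid_head",
    PO4 = "lipid_phosphate",
    GL1 = "lipid_glycerol", GL2 = "lipid_glycerol",
    C4A = "lipid_tail_terminal", C4B = "lipid_tail_terminal",
    C1A = "other", D2A = "other", C2A = "other", C3A = "other",
    C1B = "other", D2B = "other", C2B = "other", C3B = "other",
    BB = "protein",
    SC1 = "protein", SC2 = "protein", SC3 = "protein", SC4 = "protein",
    W = "water", WN = "water",
    `NA` = "ion_cation", `NA+` = "ion_cation", SOD = "ion_cation",
    CL = "ion_anion", `CL-` = "ion_anion", CLA = "ion_anion"
  )
}

#' Assign analysis roles to beads
#'
#' @param beads data.frame with at least a \code{name} column
#' @param role_map named character vector (bead name -> role)
#' @return character vector of roles, one per bead
#' @export
assignRoles <- function(beads, role_map = defaultRoleMap()) {
  roles <- unname(role_map[beads$name])
  if (anyNA(roles)) {
    offenders <- sort(unique(beads$name[is.na(roles)]))
    stop("bead name(s) with no role_map entry: ",
         paste(offenders, collapse = ", "))
  }
  roles
}

#' Identify lipids in a trajectory
#'
#' A lipid is a residue that carries a choline (\code{lipid_head}) bead.
#' Returns per-lipid bead indices for the beads the analyses need.
#'
#' @param traj a [Trajectory-class]
#' @param require character vector of roles every lipid must have
#' @return data.frame: lipid_id (residue index), and bead row indices
#'   \code{i_nc3}, \code{i_po4}, \code{i_gl1}, \code{i_gl2}, \code{i_c4a},
#'   \code{i_c4b} (NA when absent, unless required)
#' @export
# phosphate-bead index only: enough for pathway-projected analyses
.po4Index <- function(traj) {
  i <- which(traj@beads$name == "PO4")
  if (!length(i)) stop("trajectory contains no PO4 beads")
  data.frame(lipid_id = traj@beads$residue_index[i], i_po4 = i)
}

lipidIndex <- function(traj,
                       require = c("lipid_head", "lipid_tail_terminal")) {
  b <- traj@beads
  heads <- which(b$role == "lipid_head")
  if (!length(heads)) stop("trajectory contains no lipid_head (NC3) beads")
  ids <- b$residue_index[heads]
  pick1 <- function(nm) {
    idx <- which(b$name == nm)
    idx[match(ids, b$residue_index[idx])]
  }
  out <- data.frame(
    lipid_id = ids,
    i_nc3 = heads,
    i_po4 = pick1("PO4"),
    i_gl1 = pick1("GL1"), i_gl2 = pick1("GL2"),
    i_c4a = pick1("C4A"), i_c4b = pick1("C4B")
  )
  if ("lipid_tail_terminal" %in% require &&
      (anyNA(out$i_c4a) || anyNA(out$i_c4b))) {
    bad <- out$lipid_id[is.na(out$i_c4a) | is.na(out$i_c4b)]
    stop("lipid(s) missing terminal tail beads C4A/C4B: ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  out
}
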