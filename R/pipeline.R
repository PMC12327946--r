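# End-to-end orchestration: run every stage in dependency order from a
# single configuration, write all intermediates, and validate against a
# synthetic system's ground truth.

#' Run the full analysis pipeline
#'
#' Stages, in dependency order: input (load files or build the synthetic
#' system), equilibration trimming, orientation angles, event detection,
#' density + pathway extraction, event classification, rates and Poisson
#' diagnostics, leaflet surfaces and minimal thickness, groove dilation
#' and competence, contacts/dwells, permeation and selectivity, and
#' in-groove kinetics. All intermediates are written under
#' \code{cfg$outdir}; a stage failure aborts with the stage name while
#' earlier outputs remain on disk.
#'
#' @param cfg an \code{AnalysisConfig} ([analysisConfig()] /
#'   [readConfig()]); supply either \code{topology}/\code{trajectory}
#'   paths or a \code{synthetic} [SyntheticSpec-class] (or argument list)
#' @param write logical: write stage outputs (default TRUE)
#' @return object of class \code{Report} (list of per-stage results)
#' @export
runAll <- function(cfg, write = TRUE) {
  stage <- "input"
  res <- list(config = cfg)
  out <- function(...) file.path(cfg$outdir, ...)
  if (write) dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  tryCatch({
    truth <- NULL
    if (!is.null(cfg$synthetic)) {
      spec <- if (is(cfg$synthetic, "SyntheticSpec")) cfg$synthetic else
        do.call(syntheticSpec, cfg$synthetic)
      sys <- buildSystem(spec)
      traj <- sys$trajectory; truth <- sys$truth
    } else {
      if (is.null(cfg$topology)) stop("no topology path and no synthetic spec")
      if (!file.exists(cfg$topology)) stop("missing topology: ", cfg$topology)
      if (!is.null(cfg$trajectory) && !file.exists(cfg$trajectory))
        stop("missing trajectory: ", cfg$trajectory)
      traj <- loadTrajectory(cfg$topology, cfg$trajectory)
    }
    if (write) writeConfigEcho(cfg, out("config_echo.yaml"))

    stage <- "equilibration"
    t_eq <- min(cfg$t_eq, trajectoryDuration(traj) * 0.1)
    if (t_eq > 0) traj <- discardEquilibration(traj, t_eq)
    dur <- trajectoryDuration(traj)
    res$duration <- dur

    stage <- "scrambling"
    angles <- lipidOrientationAngles(traj, window = cfg$smooth_window)
    events <- detectEvents(angles, cfg$theta_low, cfg$theta_high)

    stage <- "density"
    chains <- sort(unique(traj@beads$chain_id[traj@beads$role == "protein"]))
    centers <- lapply(chains, function(ch) .grooveCenterFromScaffold(traj, ch, cfg))
    grid <- accumulateDensity(traj, "lipid_phosphate", centers,
                              spacing = cfg$density_grid)
    # walk the slabs between the two headgroup bands (with a small pad)
    po4z <- traj@coords[traj@beads$role == "lipid_phosphate", 3, 1]
    zspan <- c(stats::median(po4z[po4z < 0]), stats::median(po4z[po4z > 0]))
    pw <- tryCatch({
      p <- extractPathway(grid, z_range = zspan - centers[[1]][3],
                          tube_radius = 15)
      # map back from the groove-local frame to absolute coordinates
      p@nodes[, 1] <- p@nodes[, 1] + centers[[1]][1]
      p@nodes[, 2] <- p@nodes[, 2] + centers[[1]][2]
      p@nodes[, 3] <- p@nodes[, 3] + centers[[1]][3]
      p
    }, error = function(e) NULL)
    pathways <- NULL
    if (!is.null(pw)) {
      pathways <- stats::setNames(lapply(seq_along(chains), function(ci) {
        q <- pw
        if (ci > 1) {
          q@nodes[, 1] <- q@nodes[, 1] - centers[[1]][1] + centers[[ci]][1]
          q@nodes[, 2] <- q@nodes[, 2] - centers[[1]][2] + centers[[ci]][2]
        }
        q
      }), chains)
    }
    res$pathway <- pw
    if (write && !is.null(pw))
      jsonlite::write_json(as.data.frame(pw@nodes), out("pathway.json"))

    stage <- "classification"
    events <- suppressWarnings(
      classifyPathway(events, traj, pathways, r = cfg$pathway_radius))
    res$events <- events
    if (write) jsonlite::write_json(events, out("events.json"), dataframe = "rows")

    stage <- "rates"
    res$rate <- blockRate(events, dur, block = cfg$block, t0 = traj@times[1])
    res$poisson <- poissonTest(events, dur, block = cfg$block,
                               t0 = traj@times[1])
    if (write)
      utils::write.csv(data.frame(block = seq_along(res$rate$counts),
                                  count = res$rate$counts),
                       out("rates.csv"), row.names = FALSE)

    stage <- "surfaces"
    labels <- assignLeaflets(angles, cfg$theta_low, cfg$theta_high)
    sp <- averageSurfaces(traj, labels, spacing = cfg$surface_grid,
                          occupancy_min = cfg$occupancy_min)
    res$surfaces <- sp
    res$groove_centers <- centers
    res$min_thickness <- minimalThickness(sp)
    res$min_thickness_groove <- tryCatch(
      minimalThickness(sp, center = centers[[1]][1:2], radius = 15),
      error = function(e) NULL)
    if (write) {
      writeSurfaces(sp, out("surfaces.csv"))
      jsonlite::write_json(
        list(global = res$min_thickness$value,
             near_groove = res$min_thickness_groove$value),
        out("min_thickness.json"), auto_unbox = TRUE)
    }

    stage <- "groove"
    res$groove <- lapply(stats::setNames(chains, chains), function(ch)
      grooveDistanceSeries(traj, ch, cfg$groove$tm4, cfg$groove$tm6,
                           alpha = cfg$ewma_alpha,
                           open_threshold = cfg$groove_open))
    res$groove_stats <- lapply(res$groove, grooveStats, events = events)
    gs1 <- res$groove_stats[[1]]
    res$competence <- classifyCompetence(res$min_thickness$value,
                                         gs1$median, cfg$thickness_gate,
                                         cfg$width_gate)
    if (write) {
      utils::write.csv(do.call(rbind, lapply(names(res$groove), function(ch)
        cbind(chain = ch, res$groove[[ch]]))), out("groove.csv"),
        row.names = FALSE)
      jsonlite::write_json(res$groove_stats, out("groove_stats.json"),
                           auto_unbox = TRUE)
      jsonlite::write_json(list(min_thickness = res$min_thickness$value,
                                median_width = gs1$median,
                                competence = res$competence),
                           out("competence.json"), auto_unbox = TRUE)
    }

    stage <- "contacts"
    rid <- cfg$contact_residues
    if (is.null(rid) && !is.null(truth) && length(truth@contacts))
      rid <- vapply(truth@contacts, `[[`, numeric(1), "residue_index")
    if (!is.null(rid)) {
      res$contacts <- contactTable(traj, rid, cutoff = cfg$contact_cutoff,
                                   gap_tolerance = cfg$gap_tolerance)
      res$contact_summaries <- stats::setNames(lapply(rid, function(r)
        residueSummary(traj, r, cutoff = cfg$contact_cutoff,
                       gap_tolerance = cfg$gap_tolerance)),
        as.character(rid))
      if (write) utils::write.csv(res$contacts, out("contacts.csv"),
                                  row.names = FALSE)
    }

    stage <- "permeation"
    if (!is.null(pw)) {
      zb <- c(mean(sp@lower_z[sp@mask_lower]), mean(sp@upper_z[sp@mask_upper]))
      res$permeation <- lapply(
        stats::setNames(c("water", "Na", "Cl"), c("water", "Na", "Cl")),
        function(spp) countPermeation(traj, spp, pw,
                                      tube_radius = cfg$tube_radius,
                                      z_bounds = zb,
                                      z_margin = cfg$z_margin))
      res$selectivity <- selectivity(res$permeation$Na, res$permeation$Cl)
      if (write) {
        utils::write.csv(do.call(rbind, lapply(res$permeation, function(p)
          data.frame(species = p$species, up = p$up_count, down = p$down_count,
                     total = p$total, rate_per_us = p$rate_per_us))),
          out("permeation.csv"), row.names = FALSE)
        jsonlite::write_json(res$selectivity, out("selectivity.json"),
                             auto_unbox = TRUE)
      }
    }

    stage <- "kinetics"
    ing <- events[!is.na(events$pathway_class) &
                  events$pathway_class == "in_groove", , drop = FALSE]
    if (!is.null(pw) && nrow(ing)) {
      res$free_energy <- tryCatch(
        freeEnergyProfile(traj, pw, lipid_ids = ing$lipid_id,
                          tube_radius = cfg$tube_radius),
        error = function(e) NULL)
      res$kinetics <- transitKinetics(ing, traj, pw,
                                      tube_radius = cfg$tube_radius)
      if (write) {
        if (!is.null(res$free_energy))
          utils::write.csv(res$free_energy$profile, out("free_energy.csv"),
                           row.names = FALSE)
        jsonlite::write_json(
          list(transit_dwell = res$kinetics$transit_dwell,
               D_estimate = res$kinetics$D_estimate),
          out("kinetics.json"), auto_unbox = TRUE)
      }
    }

    stage <- "report"
    res$truth <- truth
    res$table <- data.frame(
      n_events = nrow(events),
      in_groove = sum(events$pathway_class == "in_groove", na.rm = TRUE),
      out_of_groove = sum(events$pathway_class == "out_of_groove",
                          na.rm = TRUE),
      rate_per_us = res$rate$mean, rate_sd = res$rate$sd,
      median_width = gs1$median, q1 = gs1$q1, q3 = gs1$q3,
      open_fraction = gs1$open_fraction,
      min_thickness = res$min_thickness$value,
      competence = res$competence)
    if (write) utils::write.csv(res$table, out("report.csv"),
                                row.names = FALSE)
    class(res) <- "Report"
    res
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

# groove center: midpoint of the TM4 and TM6 residue-range centroids
.grooveCenterFromScaffold <- function(traj, chain, cfg) {
  b <- traj@beads
  i4 <- which(b$chain_id == chain & b$residue_index %in% cfg$groove$tm4)
  i6 <- which(b$chain_id == chain & b$residue_index %in% cfg$groove$tm6)
  if (!length(i4) || !length(i6))
    stop("groove residue ranges not found on chain ", chain)
  (colMeans(traj@coords[i4, , 1]) + colMeans(traj@coords[i6, , 1])) / 2
}

#' @export
print.Report <- function(x, ...) {
  cat("memscramble pipeline report\n")
  print(x$table)
  invisible(x)
}

#' Validate a pipeline report against synthetic ground truth
#'
#' Per-metric checks of the report against what the generator planted:
#' event count, lipid identities and directions, completion-time
#' recovery (within half the smoothing window plus the transit script),
#' pathway classification of complete flips, minimal thickness against
#' the analytic value, open fraction against the programmed duty cycle,
#' and exact permeation counts per species and direction.
#'
#' @param report a \code{Report} from [runAll()]
#' @param truth a [GroundTruth-class] (defaults to the one embedded in
#'   the report for synthetic runs)
#' @param tol list of tolerances: t_complete (ns), thickness (Angstrom),
#'   open_fraction
#' @return object of class \code{ValidationSummary}: data.frame of checks
#'   with a \code{pass} column; attribute \code{passed} gives the overall
#'   verdict
#' @export
validateAgainstTruth <- function(report, truth = report$truth,
                                 tol = list(t_complete = 60, thickness = 1.5,
                                            open_fraction = 0.02)) {
  if (is.null(truth) || !nrow(truth@events) && !nrow(truth@crossings)) {
    warning("empty ground truth; validation skipped")
    return(invisible(NULL))
  }
  checks <- list()
  add <- function(name, value, expected, pass)
    checks[[length(checks) + 1L]] <<- data.frame(
      check = name, value = as.character(value),
      expected = as.character(expected), pass = pass)
  planted <- truth@events[truth@events$complete, , drop = FALSE]
  ev <- report$events
  add("n_events", nrow(ev), nrow(planted), nrow(ev) == nrow(planted))
  # one-to-one greedy match of detected to planted events on
  # (lipid, direction), nearest completion time first
  matched <- rep(NA_integer_, nrow(planted))
  used <- rep(FALSE, nrow(ev))
  for (i in order(planted$t_complete)) {
    cand <- which(!used & ev$lipid_id == planted$lipid_id[i] &
                  ev$direction == planted$direction[i])
    if (!length(cand)) next
    j <- cand[which.min(abs(ev$t_complete[cand] - planted$t_complete[i]))]
    matched[i] <- j; used[j] <- TRUE
  }
  add("event_identity", sum(!is.na(matched)), nrow(planted),
      !anyNA(matched) && nrow(ev) == nrow(planted))
  dtc <- abs(ev$t_complete[matched] - planted$t_complete)
  add("t_complete_recovery", round(max(c(dtc, 0), na.rm = TRUE), 1),
      paste("<=", tol$t_complete),
      !anyNA(dtc) && all(dtc <= tol$t_complete))
  if (any(!is.na(ev$pathway_class)) && !anyNA(matched)) {
    want <- ifelse(planted$pathway == "groove_axis", "in_groove",
                   "out_of_groove")
    okc <- sum(ev$pathway_class[matched] == want, na.rm = TRUE)
    add("pathway_classification", okc, nrow(planted), okc == nrow(planted))
  }
  if (!is.null(report$min_thickness)) {
    # planted transits drag glycerol beads through the membrane core, so
    # the recovered minimum near those corridors legitimately undershoots
    # the geometric field; compare bulk-vs-analytic away from them
    mt <- report$min_thickness$value
    if (nrow(planted) && !is.null(report$surfaces) &&
        is(truth@spec, "SyntheticSpec")) {
      excl <- list(.grooveCenter(truth@spec, "A"),
                   .grooveCenter(truth@spec, "A") + c(0, 20))
      if (truth@spec@two_subunits)
        excl <- c(excl, list(.grooveCenter(truth@spec, "B"),
                             .grooveCenter(truth@spec, "B") + c(0, 20)))
      for (ctc in truth@contacts)
        if (!is.null(ctc$stations))
          excl <- c(excl, split(ctc$stations, seq_len(nrow(ctc$stations))))
      mt <- tryCatch(minimalThickness(report$surfaces, exclude = excl)$value,
                     error = function(e) mt)
    }
    dv <- abs(mt - truth@analytic_min_thickness)
    add("min_thickness", round(mt, 2),
        truth@analytic_min_thickness, dv <= tol$thickness)
  }
  if (length(truth@contacts)) {
    for (ctc in truth@contacts) {
      s <- report$contact_summaries[[as.character(ctc$residue_index)]]
      if (is.null(s)) next
      iv <- ctc$intervals
      k <- 1L
      merged <- iv[1, , drop = FALSE]
      for (v in seq_len(nrow(iv))[-1]) {
        if (iv[v, 1] - merged[k, 2] - 1 <= 6) merged[k, 2] <- iv[v, 2]
        else { merged <- rbind(merged, iv[v, ]); k <- k + 1L }
      }
      want_dw <- sort(merged[, 2] - merged[, 1] + 1)
      got_dw <- sort(s$dwell_list)
      add(paste0("contact_dwells_res", ctc$residue_index),
          paste(got_dw, collapse = "/"), paste(want_dw, collapse = "/"),
          isTRUE(all.equal(as.numeric(got_dw), as.numeric(want_dw))))
    }
  }
  if (nrow(truth@open_schedule)) {
    duty <- truth@spec@breathing$duty
    gofs <- report$groove_stats[[1]]$open_fraction
    add("open_fraction", round(gofs, 3), duty,
        abs(gofs - duty) <= tol$open_fraction)
  }
  if (nrow(truth@crossings) && !is.null(report$permeation)) {
    for (spp in unique(truth@crossings$species)) {
      tc <- truth@crossings[truth@crossings$species == spp, ]
      p <- report$permeation[[spp]]
      add(paste0("permeation_", spp, "_up"), p$up_count,
          sum(tc$direction == "up"), p$up_count == sum(tc$direction == "up"))
      add(paste0("permeation_", spp, "_down"), p$down_count,
          sum(tc$direction == "down"),
          p$down_count == sum(tc$direction == "down"))
    }
  }
  out <- do.call(rbind, checks)
  attr(out, "passed") <- all(out$pass)
  class(out) <- c("ValidationSummary", "data.frame")
  out
}

#' @export
print.ValidationSummary <- function(x, ...) {
  print.data.frame(x)
  cat(if (isTRUE(attr(x, "passed"))) "ALL CHECKS PASSED\n" else
    "VALIDATION FAILED\n")
  invisible(x)
}
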