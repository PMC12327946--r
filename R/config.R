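# Analysis configuration: every threshold the pipeline uses, with a
# provenance tag naming the measurement it belongs to, YAML round-trip,
# and a config echo for reproducibility.

.THRESHOLD_PROVENANCE <- c(
  theta_low = "scrambling: lower hysteresis threshold (deg)",
  theta_high = "scrambling: upper hysteresis threshold (deg)",
  smooth_window = "scrambling: running-average window (ns)",
  block = "rates: block-averaging length (ns)",
  groove_open = "groove: open-state threshold on smoothed TM4-TM6 distance (A)",
  ewma_alpha = "groove: EWMA smoothing factor",
  thickness_gate = "competence: membrane-thinning gate (A)",
  width_gate = "competence: median groove-width gate (A)",
  pathway_radius = "classification: capture radius around density pathway (A)",
  contact_cutoff = "contacts: protein-lipid distance cutoff (A)",
  gap_tolerance = "contacts: dwell-merging gap tolerance (ns)",
  surface_grid = "surfaces: rectilinear grid spacing (A)",
  occupancy_min = "surfaces: minimum cell occupancy",
  density_grid = "density: 3D grid spacing (A)",
  tube_radius = "permeation/kinetics: pathway tube radius (A)",
  z_margin = "permeation: membrane-span margin (A)",
  t_eq = "io: equilibration span discarded (ns)"
)

#' Default analysis configuration
#'
#' All pipeline thresholds with their defaults; override any field via
#' \code{...}. Each threshold carries a provenance tag printed by
#' [echoConfig()].
#'
#' @param ... named overrides (unknown names are an error)
#' @return list of class \code{AnalysisConfig}
#' @export
analysisConfig <- function(...) {
  cfg <- list(
    theta_low = 35, theta_high = 145, smooth_window = 100,
    block = 1000, groove_open = 6, ewma_alpha = 0.1,
    thickness_gate = 14, width_gate = 6, pathway_radius = 4.7,
    contact_cutoff = 7, gap_tolerance = 6,
    surface_grid = 1, occupancy_min = 0.02, density_grid = 0.5,
    tube_radius = 8, z_margin = 5, t_eq = 1000,
    seed = 1,
    topology = NULL, trajectory = NULL, synthetic = NULL,
    groove = list(chain_id = "A", tm4 = 327:339, tm6 = 430:452),
    contact_residues = NULL,
    outdir = "."
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(ov)] <- ov
  if (cfg$theta_low >= 90 || cfg$theta_high <= 90)
    stop("need theta_low < 90 < theta_high")
  num <- unlist(cfg[names(.THRESHOLD_PROVENANCE)])
  if (any(num <= 0) && !"occupancy_min" %in% names(num)[num <= 0])
    stop("thresholds must be positive")
  class(cfg) <- "AnalysisConfig"
  cfg
}

#' Read an analysis configuration from YAML
#'
#' Unknown keys are rejected; a nested \code{synthetic:} section is
#' passed to [syntheticSpec()].
#'
#' @param path YAML file
#' @return an \code{AnalysisConfig}
#' @export
readConfig <- function(path) {
  y <- yaml::read_yaml(path)
  y$provenance <- NULL
  if (!is.null(y$groove)) {
    y$groove$tm4 <- .parseRange(y$groove$tm4)
    y$groove$tm6 <- .parseRange(y$groove$tm6)
  }
  if (!is.null(y$synthetic)) {
    s <- y$synthetic
    for (f in c("flip_schedule", "tracer_spec"))
      if (!is.null(s[[f]])) s[[f]] <- as.data.frame(s[[f]])
    if (!is.null(s$contact_spec))
      s$contact_spec <- lapply(s$contact_spec, function(cs) {
        cs$intervals <- matrix(unlist(cs$intervals), ncol = 2, byrow = TRUE)
        cs
      })
    y$synthetic <- s
  }
  do.call(analysisConfig, y)
}

.parseRange <- function(x) {
  if (is.character(x) && grepl("-", x[1])) {
    p <- as.integer(strsplit(x[1], "-")[[1]])
    return(p[1]:p[2])
  }
  as.integer(x)
}

#' Write a configuration echo (values + provenance tags) as YAML
#'
#' The emitted file re-parses with [readConfig()] to an equivalent
#' configuration; the \code{provenance} section documents what each
#' threshold controls.
#'
#' @param cfg an \code{AnalysisConfig}
#' @param path output YAML path
#' @export
writeConfigEcho <- function(cfg, path) {
  out <- unclass(cfg)
  out <- out[!vapply(out, is.null, logical(1))]
  if (!is.null(out$synthetic) && is(out$synthetic, "SyntheticSpec"))
    out$synthetic <- NULL  # spec objects echo separately
  out$provenance <- as.list(.THRESHOLD_PROVENANCE)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Print every threshold with its provenance tag
#'
#' @param cfg an \code{AnalysisConfig}
#' @export
echoConfig <- function(cfg) {
  for (k in names(.THRESHOLD_PROVENANCE))
    cat(sprintf("%-15s = %-8g  [%s]\n", k, cfg[[k]],
                .THRESHOLD_PROVENANCE[[k]]))
  invisible(cfg)
}

#' @export
print.AnalysisConfig <- function(x, ...) {
  cat("AnalysisConfig (seed ", x$seed, ")\n", sep = "")
  echoConfig(x)
  invisible(x)
}
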