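# Readers/writers for formats without an installed R implementation:
# GROMACS .gro (fixed-width text, nm), CHARMM-style .dcd (binary, written
# here, read back through bio3d::read.dcd), and OpenDX scalar grids.

#' Read a (possibly multi-frame) GROMACS .gro file
#'
#' @param path file path
#' @return list with \code{beads} (data.frame: residue_index, residue_name,
#'   name, chain_id), \code{coords} array (n, 3, n_frames) in Angstrom,
#'   \code{box} (n_frames x 3) in Angstrom, \code{times} (ns; frame index
#'   when the title carries no \code{t=} tag)
#' @export
readGRO <- function(path) {
  lines <- readLines(path)
  frames <- list(); boxes <- list(); times <- numeric(0)
  beads <- NULL
  i <- 1L; k <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    title <- lines[i]
    nat <- as.integer(trimws(lines[i + 1L]))
    at <- lines[(i + 2L):(i + 1L + nat)]
    k <- k + 1L
    if (is.null(beads)) {
      beads <- data.frame(
        residue_index = as.integer(substr(at, 1, 5)),
        residue_name = trimws(substr(at, 6, 10)),
        name = trimws(substr(at, 11, 15)),
        chain_id = "A",
        stringsAsFactors = FALSE
      )
    }
    xyz <- cbind(as.numeric(substr(at, 21, 28)),
                 as.numeric(substr(at, 29, 36)),
                 as.numeric(substr(at, 37, 44)))
    frames[[k]] <- xyz * 10  # nm -> Angstrom
    bx <- as.numeric(strsplit(trimws(lines[i + 2L + nat]), "\\s+")[[1]])[1:3]
    boxes[[k]] <- bx * 10
    tm <- regmatches(title, regexec("t=\\s*([0-9eE+.-]+)", title))[[1]]
    times <- c(times, if (length(tm) == 2) as.numeric(tm[2]) / 1000 else NA)
    i <- i + 3L + nat
  }
  if (anyNA(times)) times <- seq_along(frames) - 1
  coords <- array(0, dim = c(nrow(beads), 3, length(frames)))
  for (f in seq_along(frames)) coords[, , f] <- frames[[f]]
  list(beads = beads, coords = coords,
       box = do.call(rbind, boxes), times = times)
}

#' Write a Trajectory as a (multi-frame) GROMACS .gro file
#'
#' Coordinates are converted from Angstrom to nm with the format's native
#' 0.001 nm (0.01 Angstrom) precision.
#'
#' @param traj a [Trajectory-class]
#' @param path output path
#' @param frames frame indices to write (default all)
#' @export
writeGRO <- function(traj, path, frames = seq_len(nFrames(traj))) {
  b <- traj@beads
  con <- file(path, "w")
  on.exit(close(con))
  for (f in frames) {
    xyz <- traj@coords[, , f] / 10
    writeLines(sprintf("memscramble t= %.3f", traj@times[f] * 1000), con)
    writeLines(sprintf("%5d", nBeads(traj)), con)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       b$residue_index %% 100000L, b$residue_name, b$name,
                       seq_len(nrow(b)) %% 100000L,
                       xyz[, 1], xyz[, 2], xyz[, 3]), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", traj@box[f, 1] / 10,
                       traj@box[f, 2] / 10, traj@box[f, 3] / 10), con)
  }
  invisible(path)
}

#' Write trajectory coordinates as a CHARMM-style DCD file
#'
#' Single-precision binary trajectory readable by \code{bio3d::read.dcd}
#' and the usual MD tool chains. The frame spacing (ns) is stored in the
#' DELTA header field.
#'
#' @param traj a [Trajectory-class]
#' @param path output path
#' @export
writeDCD <- function(traj, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  nf <- nFrames(traj); nat <- nBeads(traj)
  rec <- function(writer) {
    # Fortran unformatted record: byte count, payload, byte count
    raw <- writer()
    writeBin(length(raw), con, size = 4L)
    writeBin(raw, con)
    writeBin(length(raw), con, size = 4L)
  }
  icntrl <- integer(20)
  icntrl[1] <- nf; icntrl[2] <- 1L; icntrl[3] <- 1L; icntrl[4] <- nf
  dt <- timeStep(traj); if (is.na(dt)) dt <- 1
  icntrl[10] <- readBin(writeBinRaw(as.numeric(dt), size = 4L), "integer", size = 4L)
  icntrl[20] <- 24L
  rec(function() c(charToRaw("CORD"), writeBinRaw(icntrl, size = 4L)))
  title <- sprintf("%-80s", "memscramble trajectory")
  rec(function() c(writeBinRaw(1L, size = 4L), charToRaw(title)))
  rec(function() writeBinRaw(nat, size = 4L))
  for (f in seq_len(nf)) {
    for (ax in 1:3)
      rec(function() writeBinRaw(as.numeric(traj@coords[, ax, f]), size = 4L))
  }
  invisible(path)
}

writeBinRaw <- function(x, size) {
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  writeBin(x, con, size = size)
  rawConnectionValue(con)
}

#' Write a density grid as an OpenDX scalar field
#'
#' @param grid a [DensityGrid-class]
#' @param path output path (.dx)
#' @export
writeDX <- function(grid, path) {
  d <- dim(grid@counts)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# OpenDX density written by memscramble",
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.6f %.6f %.6f", grid@origin[1], grid@origin[2], grid@origin[3]),
    sprintf("delta %.6f 0 0", grid@spacing),
    sprintf("delta 0 %.6f 0", grid@spacing),
    sprintf("delta 0 0 %.6f", grid@spacing),
    sprintf("object 2 class gridconnections counts %d %d %d", d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(d))), con)
  # DX stores with z fastest
  v <- aperm(grid@counts, c(3, 2, 1))
  vals <- as.vector(v)
  n3 <- (length(vals) %/% 3) * 3
  if (n3 > 0) {
    m <- matrix(vals[seq_len(n3)], ncol = 3, byrow = TRUE)
    writeLines(sprintf("%.10g %.10g %.10g", m[, 1], m[, 2], m[, 3]), con)
  }
  if (n3 < length(vals))
    writeLines(paste(sprintf("%.10g", vals[(n3 + 1):length(vals)]),
                     collapse = " "), con)
  writeLines(c('attribute "dep" string "positions"',
               'object "density" class field',
               'component "positions" value 1',
               'component "connections" value 2',
               'component "data" value 3'), con)
  invisible(path)
}

#' Read an OpenDX scalar field written by [writeDX()]
#'
#' @param path .dx file path
#' @return a [DensityGrid-class] (n_frames and n_chains set to NA)
#' @export
readDX <- function(path) {
  lines <- readLines(path)
  cnt <- lines[grep("gridpositions counts", lines)[1]]
  d <- as.integer(strsplit(cnt, "\\s+")[[1]][6:8])
  org <- as.numeric(strsplit(lines[grep("^origin", lines)[1]], "\\s+")[[1]][2:4])
  del <- as.numeric(strsplit(lines[grep("^delta", lines)[1]], "\\s+")[[1]][2])
  i0 <- grep("data follows", lines)[1] + 1L
  vals <- numeric(0)
  i <- i0
  while (length(vals) < prod(d)) {
    vals <- c(vals, as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    i <- i + 1L
  }
  counts <- aperm(array(vals, dim = rev(d)), c(3, 2, 1))
  new("DensityGrid", origin = org, spacing = del, counts = counts,
      n_frames = NA_real_, n_chains = NA_real_)
}
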