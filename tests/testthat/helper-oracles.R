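# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use the slowest, most literal formulation.

# centered truncated running mean, literal
oracle_running_mean <- function(x, w) {
  h <- floor(w / 2)
  sapply(seq_along(x), function(i)
    mean(x[max(1, i - h):min(length(x), i + h)]))
}

# hysteresis event scan with explicit state bookkeeping
oracle_detect <- function(s, lo = 35, hi = 145) {
  state <- if (s[1] > 90) "upper" else "lower"
  out <- data.frame(frame = integer(0), direction = character(0))
  for (i in seq_along(s)) {
    if (state == "upper" && s[i] < lo) {
      out <- rbind(out, data.frame(frame = i, direction = "upper_to_lower"))
      state <- "lower"
    } else if (state == "lower" && s[i] > hi) {
      out <- rbind(out, data.frame(frame = i, direction = "lower_to_upper"))
      state <- "upper"
    }
  }
  out
}

# recursive EWMA, literal loop
oracle_ewma <- function(x, alpha = 0.1) {
  s <- numeric(length(x))
  s[1] <- x[1]
  for (t in seq_along(x)[-1]) s[t] <- alpha * x[t] + (1 - alpha) * s[t - 1]
  s
}

# all-pairs minimal 3D distance between two gridded surfaces
oracle_min_thickness <- function(sp) {
  h <- sp@spacing
  iu <- which(sp@mask_upper, arr.ind = TRUE)
  il <- which(sp@mask_lower, arr.ind = TRUE)
  pu <- cbind(sp@origin[1] + (iu[, 1] - 0.5) * h,
              sp@origin[2] + (iu[, 2] - 0.5) * h,
              sp@upper_z[sp@mask_upper])
  pl <- cbind(sp@origin[1] + (il[, 1] - 0.5) * h,
              sp@origin[2] + (il[, 2] - 0.5) * h,
              sp@lower_z[sp@mask_lower])
  best <- Inf
  for (i in seq_len(nrow(pu))) {
    d <- sqrt((pu[i, 1] - pl[, 1])^2 + (pu[i, 2] - pl[, 2])^2 +
              (pu[i, 3] - pl[, 3])^2)
    best <- min(best, min(d))
  }
  best
}

# run-length dwell merging, literal
oracle_dwells <- function(x, dt = 1, gap = 6) {
  idx <- which(x)
  if (!length(idx)) return(numeric(0))
  dwells <- numeric(0)
  start <- idx[1]; prev <- idx[1]
  for (i in idx[-1]) {
    if ((i - prev - 1) * dt > gap) {
      dwells <- c(dwells, (prev - start + 1) * dt)
      start <- i
    }
    prev <- i
  }
  c(dwells, (prev - start + 1) * dt)
}

# make an AngleSeriesSet directly from a matrix of smoothed traces
# (raw = smooth), for state-machine tests that need full control
angle_set <- function(traces, dt = 1) {
  if (is.null(dim(traces))) traces <- matrix(traces, nrow = 1)
  new("AngleSeriesSet", t = seq(0, by = dt, length.out = ncol(traces)),
      lipid_ids = seq_len(nrow(traces)), theta_raw = traces,
      theta_smooth = traces, window = 0)
}

# SurfacePair from two height matrices (full masks, occupancy 1)
surface_pair <- function(upper, lower, spacing = 1, origin = c(0, 0)) {
  ones <- matrix(1, nrow(upper), ncol(upper))
  new("SurfacePair", origin = origin, spacing = spacing,
      upper_z = upper, lower_z = lower,
      occ_upper = ones, occ_lower = ones,
      mask_upper = ones > 0, mask_lower = ones > 0)
}
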