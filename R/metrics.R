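# The thirteen trajectory-based exploration measures.
#
# All metrics operate on a uniformly resampled planar trajectory. Free
# parameters (grid size, pause threshold, landmark radius, turn window,
# ruler scales) live in a metric_config; defaults are scale-relative so the
# measures stay comparable across environments with different world units.

#' Metric configuration
#'
#' Holds every free parameter of the exploration measures. Parameters left
#' `NULL` are resolved per trajectory/environment: `cell_size` from the
#' environment, `landmark_radius` and `flight_min_len` as twice the cell
#' size, `pause_speed` as 5% of the participant's median moving speed, and
#' `divider_scales` as 8 geometric steps from twice the median step length
#' up to a quarter of the trajectory diameter.
#'
#' @param dt resampling interval in seconds.
#' @param pause_speed speed below which the agent counts as not moving
#'   (world units/s).
#' @param pause_min minimal duration of a pause (s).
#' @param landmark_radius visit radius around a landmark (world units).
#' @param turn_window sliding window over which heading change accumulates
#'   for turnaround detection (s).
#' @param flight_min_len minimal length of a flight segment (world units).
#' @param divider_scales strictly increasing vector of at least 4 ruler
#'   lengths for the divider fractal dimension.
#' @param cell_size occupancy grid edge length (world units).
#' @param min_step steps shorter than this are treated as standing still
#'   when computing headings (world units).
#' @return an object of class `metric_config`.
#' @export
metric_config <- function(dt = 1 / 15, pause_speed = NULL, pause_min = 1,
                          landmark_radius = NULL, turn_window = 3,
                          flight_min_len = NULL, divider_scales = NULL,
                          cell_size = NULL, min_step = 1e-6) {
  stopifnot(dt > 0, pause_min > 0, turn_window > 0, min_step > 0)
  if (!is.null(pause_speed)) stopifnot(pause_speed > 0)
  if (!is.null(landmark_radius)) stopifnot(landmark_radius > 0)
  if (!is.null(flight_min_len)) stopifnot(flight_min_len > 0)
  if (!is.null(cell_size)) stopifnot(cell_size > 0)
  if (!is.null(divider_scales)) {
    if (length(divider_scales) < 4 || any(divider_scales <= 0) ||
        any(diff(divider_scales) <= 0)) {
      et_error("divider_scales must be positive, strictly increasing, length >= 4",
               "et_config_error")
    }
  }
  structure(
    list(dt = dt, pause_speed = pause_speed, pause_min = pause_min,
         landmark_radius = landmark_radius, turn_window = turn_window,
         flight_min_len = flight_min_len, divider_scales = divider_scales,
         cell_size = cell_size, min_step = min_step),
    class = "metric_config")
}

# fill the data-dependent defaults for one trajectory + environment
resolve_config <- function(traj, env, cfg = metric_config()) {
  out <- unclass(cfg)
  if (is.null(out$cell_size)) {
    short_edge <- min(env$bounds$xmax - env$bounds$xmin,
                      env$bounds$ymax - env$bounds$ymin)
    out$cell_size <- short_edge / 20
  }
  if (is.null(out$landmark_radius)) out$landmark_radius <- 2 * out$cell_size
  if (is.null(out$flight_min_len)) out$flight_min_len <- 2 * out$cell_size
  len <- step_lengths(traj)
  moving <- len >= out$min_step
  med_speed <- if (any(moving)) median(len[moving]) / out$dt else 0
  if (is.null(out$pause_speed)) {
    # stationary trajectory: every step counts as pausing
    out$pause_speed <- if (med_speed > 0) 0.05 * med_speed else Inf
  }
  if (is.null(out$divider_scales)) {
    d_min <- 2 * out$dt * med_speed
    d_max <- trajectory_diameter(traj) / 4
    if (!is.finite(d_min) || d_min <= 0) d_min <- out$cell_size / 10
    if (!is.finite(d_max) || d_max <= d_min) d_max <- d_min * 16
    out$divider_scales <- exp(seq(log(d_min), log(d_max), length.out = 8))
  }
  structure(out, class = "metric_config")
}

step_lengths <- function(traj) {
  s <- traj$samples
  sqrt(diff(s$x)^2 + diff(s$y)^2)
}

trajectory_diameter <- function(traj) {
  s <- traj$samples
  hull <- unique(grDevices::chull(s$x, s$y))
  if (length(hull) < 2) return(0)
  hx <- s$x[hull]; hy <- s$y[hull]
  max(as.matrix(stats::dist(cbind(hx, hy))))
}

#' Total path length
#'
#' Sum of Euclidean step lengths over consecutive samples.
#'
#' @param traj a resampled [trajectory].
#' @return length in world units.
#' @export
path_length <- function(traj) {
  sum(step_lengths(traj))
}

# logical mask over steps: TRUE for steps inside a detected pause
# (maximal run of sub-threshold speed lasting at least pause_min)
pause_step_mask <- function(traj, cfg) {
  len <- step_lengths(traj)
  slow <- (len / cfg$dt) < cfg$pause_speed
  mask <- logical(length(len))
  r <- rle(slow)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & (r$lengths * cfg$dt >= cfg$pause_min)
  for (i in which(keep)) mask[starts[i]:ends[i]] <- TRUE
  mask
}

#' Time spent without movement
#'
#' Total duration of maximal intervals in which instantaneous speed stays
#' below `pause_speed` for at least `pause_min` seconds.
#'
#' @param traj a resampled [trajectory].
#' @param cfg a [metric_config] (resolved against `traj`; pass an
#'   environment via [compute_features()] for scale-relative defaults).
#' @return seconds.
#' @export
pausing <- function(traj, cfg = metric_config()) {
  cfg <- resolve_free(traj, cfg)
  sum(pause_step_mask(traj, cfg)) * cfg$dt
}

# resolve only the trajectory-dependent defaults when no environment is at
# hand (single-metric calls)
resolve_free <- function(traj, cfg) {
  if (is.null(cfg$pause_speed) || is.null(cfg$divider_scales)) {
    dummy_env <- list(bounds = list(xmin = 0, xmax = 20, ymin = 0, ymax = 20))
    cfg <- resolve_config(traj, dummy_env,
                          metric_config_fill_cell(cfg))
  }
  cfg
}

metric_config_fill_cell <- function(cfg) {
  if (is.null(cfg$cell_size)) cfg$cell_size <- 1
  cfg
}

#' Grid occupancy of a trajectory
#'
#' Divides the environment bounds into square cells of edge `cell_size`
#' (half-open: a sample exactly on an interior edge belongs to the
#' higher-index cell) and counts, per cell, the number of samples and the
#' number of maximal contiguous sample runs ("visits"). Out-of-bounds
#' samples are clamped into the nearest boundary cell with a warning.
#'
#' @param traj a resampled [trajectory].
#' @param env an [environment_spec].
#' @param cfg a [metric_config].
#' @return an object of class `grid_occupancy`: occupied-cell table
#'   (`ix`, `iy`, `count`, `runs`) plus grid dimensions and `K_total`, the
#'   total number of cells inside the bounds.
#' @export
grid_occupancy <- function(traj, env, cfg = metric_config()) {
  cfg <- resolve_config(traj, env, cfg)
  cs <- cfg$cell_size
  b <- env$bounds
  nx <- max(1L, as.integer(ceiling((b$xmax - b$xmin) / cs - 1e-9)))
  ny <- max(1L, as.integer(ceiling((b$ymax - b$ymin) / cs - 1e-9)))
  s <- traj$samples
  ix <- floor((s$x - b$xmin) / cs)
  iy <- floor((s$y - b$ymin) / cs)
  clamped <- sum(ix < 0 | ix >= nx | iy < 0 | iy >= ny)
  if (clamped > 0) {
    et_warn(sprintf("%d out-of-bounds sample(s) clamped to boundary cells",
                    clamped), "et_quality_warning")
  }
  ix <- pmin(pmax(ix, 0L), nx - 1L)
  iy <- pmin(pmax(iy, 0L), ny - 1L)
  id <- ix + nx * iy
  uid <- sort(unique(id))
  f <- match(id, uid)
  counts <- tabulate(f, nbins = length(uid))
  run_first <- c(TRUE, id[-1] != id[-length(id)])
  runs <- tabulate(f[run_first], nbins = length(uid))
  cells <- data.frame(
    ix = uid %% nx,
    iy = uid %/% nx,
    count = counts,
    runs = runs)
  structure(
    list(cells = cells, nx = nx, ny = ny, K_total = as.numeric(nx) * ny,
         cell_size = cs, n_samples = nrow(s), n_clamped = clamped),
    class = "grid_occupancy")
}

#' Area covered during exploration
#'
#' Number of occupied grid cells times the cell area.
#'
#' @param occ a [grid_occupancy].
#' @return area in squared world units.
#' @export
area_covered <- function(occ) {
  nrow(occ$cells) * occ$cell_size^2
}

#' Roaming entropy
#'
#' Shannon entropy of the time-occupancy distribution over grid cells,
#' normalized by `ln(K_total)` so that 0 means all time in one cell and 1
#' means uniform use of the whole arena.
#'
#' @param occ a [grid_occupancy].
#' @return a value in `[0, 1]`.
#' @export
roaming_entropy <- function(occ) {
  if (occ$K_total < 2) {
    et_error("roaming entropy needs a grid with at least 2 cells",
             "et_config_error")
  }
  if (nrow(occ$cells) == 1) return(0)
  p <- occ$cells$count / sum(occ$cells$count)
  -sum(p * log(p)) / log(occ$K_total)
}

#' Average number of returns to already visited places
#'
#' Mean over occupied cells of (number of maximal visit runs - 1): 0 for a
#' self-avoiding path, large when the same places are entered repeatedly.
#'
#' @param occ a [grid_occupancy].
#' @return dimensionless.
#' @export
revisiting <- function(occ) {
  mean(occ$cells$runs - 1)
}

# per-landmark number of visit events: maximal intervals with
# distance(agent, landmark) < landmark_radius
landmark_event_counts <- function(traj, env, cfg) {
  s <- traj$samples
  n <- nrow(s)
  lx <- env$landmarks$x
  ly <- env$landmarks$y
  r2 <- cfg$landmark_radius^2
  inside <- (outer(s$x, lx, "-")^2 + outer(s$y, ly, "-")^2) < r2
  # an event starts at sample 1 or on a FALSE -> TRUE transition
  starts <- inside & rbind(TRUE, !inside[-n, , drop = FALSE])
  colSums(starts)
}

#' Landmark visits and revisits
#'
#' A visit event is a maximal interval spent within `landmark_radius` of a
#' landmark. `landmark_visits` counts distinct landmarks with at least one
#' event; `landmark_revisits` counts surplus events (returns).
#'
#' @param traj a resampled [trajectory].
#' @param env an [environment_spec].
#' @param cfg a [metric_config].
#' @return a count.
#' @export
landmark_visits <- function(traj, env, cfg = metric_config()) {
  cfg <- resolve_config(traj, env, cfg)
  sum(landmark_event_counts(traj, env, cfg) > 0)
}

#' @rdname landmark_visits
#' @export
landmark_revisits <- function(traj, env, cfg = metric_config()) {
  cfg <- resolve_config(traj, env, cfg)
  ev <- landmark_event_counts(traj, env, cfg)
  sum(pmax(ev - 1, 0))
}

#' Unwrapped heading series of the movement steps
#'
#' Headings of all steps longer than `min_step`, unwrapped (cumulative sum
#' of wrapped step-to-step differences) so that full turns accumulate
#' instead of jumping across the \eqn{\pm\pi} branch.
#'
#' @param traj a resampled [trajectory].
#' @param cfg a [metric_config].
#' @return data frame with `step` (index of the step among all steps),
#'   `t` (time at the end of the step) and `heading` (unwrapped, radians).
#' @export
heading_series <- function(traj, cfg = metric_config()) {
  as.data.frame(heading_series_core(traj, cfg$min_step))
}

heading_series_core <- function(traj, min_step) {
  s <- traj$samples
  dx <- diff(s$x); dy <- diff(s$y)
  len <- sqrt(dx^2 + dy^2)
  keep <- which(len >= min_step)
  if (length(keep) == 0) {
    return(list(step = integer(0), t = numeric(0), heading = numeric(0)))
  }
  h <- atan2(dy[keep], dx[keep])
  unwrapped <- h[1] + c(0, cumsum(wrap_pi(diff(h))))
  list(step = keep, t = s$t[keep + 1], heading = unwrapped)
}

#' Turnarounds: turns accumulating more than 180 degrees
#'
#' Counts events in which the magnitude of cumulative (unwrapped) heading
#' change within a sliding window of `turn_window` seconds reaches \eqn{\pi}.
#' After an event the accumulator resets at the event's end, so one physical
#' U-turn is counted once. (A single inter-step angle can never exceed
#' \eqn{\pi}; only cumulative turning can.)
#'
#' @param traj a resampled [trajectory].
#' @param cfg a [metric_config].
#' @return a count.
#' @export
turnarounds <- function(traj, cfg = metric_config()) {
  hs <- heading_series_core(traj, cfg$min_step)
  turnaround_events(hs, cfg$turn_window)$count
}

# two-pointer scan over the unwrapped heading series; returns both the
# event count and the step indices at which events complete
turnaround_events <- function(hs, turn_window, tol = 1e-8) {
  n <- length(hs$t)
  if (n < 2) return(list(count = 0L, steps = integer(0)))
  tt <- hs$t
  hh <- hs$heading
  step <- hs$step
  count <- 0L
  ev_steps <- integer(0)
  thresh <- pi - tol
  s <- 1L
  for (i in 2:n) {
    while (s < i && tt[i] - tt[s] > turn_window) s <- s + 1L
    if (abs(hh[i] - hh[s]) >= thresh) {
      count <- count + 1L
      ev_steps <- c(ev_steps, step[i])
      s <- i  # reset accumulation at the event's end
    }
  }
  list(count = count, steps = ev_steps)
}

#' Flight segmentation and flight-scale turnarounds
#'
#' Splits the trajectory into flights: straight-ish movement segments
#' bounded by pauses (per the pausing criteria) and by turnaround events.
#' Segments shorter than `flight_min_len` are merged into their neighbors.
#' Each flight's heading is the direction from its start to its end point,
#' lifted onto the unwrapped heading scale of its member steps so that the
#' turning sense across consecutive flights is preserved.
#'
#' @param traj a resampled [trajectory].
#' @param cfg a [metric_config].
#' @param pausemask,hs,ev optional precomputed internals (pause-step mask,
#'   heading series, turnaround events) so batch feature extraction avoids
#'   recomputing them; normally left `NULL`.
#' @return an object of class `flight_sequence`: data frame with
#'   `start`, `end` (sample indices), `length` and `heading` (lifted).
#' @export
segment_flights <- function(traj, cfg = metric_config(),
                            pausemask = NULL, hs = NULL, ev = NULL) {
  cfg <- metric_config_fill_cell(cfg)
  cfg <- resolve_free(traj, cfg)
  if (is.null(cfg$flight_min_len)) cfg$flight_min_len <- 2 * cfg$cell_size
  len <- step_lengths(traj)
  n_steps <- length(len)
  if (is.null(pausemask)) pausemask <- pause_step_mask(traj, cfg)
  if (is.null(hs)) hs <- heading_series_core(traj, cfg$min_step)
  if (is.null(ev)) ev <- turnaround_events(hs, cfg$turn_window)
  # boundaries after steps: pause runs and turnaround event ends split
  cut_after <- logical(n_steps)
  if (length(ev$steps)) cut_after[ev$steps] <- TRUE
  moving <- !pausemask
  # segments are maximal runs of moving steps, further cut at event ends
  seg_id <- integer(n_steps)
  cur <- 0L
  open <- FALSE
  for (i in seq_len(n_steps)) {
    if (!moving[i]) { open <- FALSE; next }
    if (!open) { cur <- cur + 1L; open <- TRUE }
    seg_id[i] <- cur
    if (cut_after[i]) open <- FALSE
  }
  if (cur == 0L) {
    return(structure(
      data.frame(start = integer(0), end = integer(0),
                 length = numeric(0), heading = numeric(0)),
      class = c("flight_sequence", "data.frame")))
  }
  segs <- lapply(seq_len(cur), function(k) range(which(seg_id == k)))
  lens <- vapply(segs, function(r) sum(len[r[1]:r[2]]), numeric(1))
  # merge short segments into a neighbor (previous if any, else next)
  repeat {
    short <- which(lens < cfg$flight_min_len)
    if (length(short) == 0 || length(lens) == 1) break
    i <- short[1]
    j <- if (i > 1) i - 1 else i + 1
    segs[[j]] <- c(min(segs[[i]][1], segs[[j]][1]),
                   max(segs[[i]][2], segs[[j]][2]))
    lens[j] <- lens[j] + lens[i]
    segs[[i]] <- NULL
    lens <- lens[-i]
  }
  s <- traj$samples
  start <- vapply(segs, `[`, numeric(1), 1)   # first step index
  end <- vapply(segs, `[`, numeric(1), 2)     # last step index
  # step i connects samples i and i+1
  hx <- s$x[end + 1] - s$x[start]
  hy <- s$y[end + 1] - s$y[start]
  heading <- atan2(hy, hx)
  # lift onto the unwrapped scale via the mean unwrapped heading of the
  # flight's member steps
  lifted <- vapply(seq_along(segs), function(k) {
    idx <- hs$step >= start[k] & hs$step <= end[k]
    if (!any(idx)) return(heading[k])
    m <- mean(hs$heading[idx])
    heading[k] + 2 * pi * round((m - heading[k]) / (2 * pi))
  }, numeric(1))
  structure(
    data.frame(start = as.integer(start), end = as.integer(end) + 1L,
               length = lens, heading = lifted),
    class = c("flight_sequence", "data.frame"))
}

#' @rdname segment_flights
#' @param flights a `flight_sequence` from [segment_flights()].
#' @param tol numeric tolerance on the pi threshold so that perfectly
#'   collinear reversals count.
#' @export
flight_turnarounds <- function(flights, tol = 1e-8) {
  if (nrow(flights) < 2) return(0L)
  sum(abs(diff(flights$heading)) >= pi - tol)
}

#' Fractal dimension of the trajectory (divider method)
#'
#' Walks the polyline with rulers of decreasing length \eqn{\delta} and
#' regresses \eqn{\ln N(\delta)} on \eqn{\ln \delta}; the dimension is the
#' negative slope: 1 for a straight line, approaching 2 for a plane-filling
#' path. Estimates outside `[1, 2]` are clamped with a warning.
#'
#' @param traj a resampled [trajectory].
#' @param cfg a [metric_config]; `divider_scales` defaults to 8 geometric
#'   steps between twice the median step length and a quarter of the
#'   trajectory diameter.
#' @return the dimension, or `NA` for degenerate (stationary or too short)
#'   trajectories.
#' @export
fractal_dimension <- function(traj, cfg = metric_config()) {
  if (nrow(traj$samples) < 10) return(NA_real_)
  if (path_length(traj) <= 0) return(NA_real_)
  cfg <- resolve_free(traj, cfg)
  s <- traj$samples
  n_delta <- vapply(cfg$divider_scales, function(d) {
    divider_count(s$x, s$y, d)
  }, numeric(1))
  ok <- is.finite(n_delta) & n_delta > 0
  if (sum(ok) < 2) return(NA_real_)
  lx <- log(cfg$divider_scales[ok])
  ly <- log(n_delta[ok])
  d <- -sum((lx - mean(lx)) * (ly - mean(ly))) / sum((lx - mean(lx))^2)
  if (d < 1 || d > 2) {
    et_warn(sprintf("fractal dimension %.3f outside [1, 2]; clamped", d),
            "et_quality_warning")
    d <- min(max(d, 1), 2)
  }
  d
}

#' Corrected sinuosity of the trajectory
#'
#' Benhamou-style corrected sinuosity
#' \deqn{S = 2\,[\,p\,(1+c)/(1-c) + b^2\,]^{-1/2}}
#' with \eqn{p} the mean step length, \eqn{c} the mean cosine of turning
#' angles between consecutive movement steps and \eqn{b} the coefficient of
#' variation of step length. Pause steps are removed first. Units are
#' (world units)\eqn{^{-1/2}}.
#'
#' @param traj a resampled [trajectory].
#' @param cfg a [metric_config].
#' @param pausemask optional precomputed pause-step mask.
#' @return sinuosity; 0 (flagged via attribute `straight`) in the perfectly
#'   straight limit; `NA` when fewer than 3 movement steps remain.
#' @export
sinuosity <- function(traj, cfg = metric_config(), pausemask = NULL) {
  cfg <- resolve_free(traj, cfg)
  len <- step_lengths(traj)
  if (is.null(pausemask)) pausemask <- pause_step_mask(traj, cfg)
  keep <- !pausemask & len >= cfg$min_step
  if (sum(keep) < 3) return(NA_real_)
  s <- traj$samples
  dx <- diff(s$x)[keep]
  dy <- diff(s$y)[keep]
  l <- len[keep]
  h <- atan2(dy, dx)
  turn <- wrap_pi(diff(h))
  cc <- mean(cos(turn))
  p <- mean(l)
  b <- sd(l) / p
  if (cc >= 1 - 1e-9) {
    return(structure(0, straight = TRUE))
  }
  2 / sqrt(p * (1 + cc) / (1 - cc) + b^2)
}

#' Exploration efficiencies
#'
#' `area_efficiency` is area covered per unit distance traveled;
#' `landmark_efficiency` is landmarks visited per unit distance.
#'
#' @param area_covered,landmark_visits,path_length raw measure values.
#' @return the ratio, or `NA` when `path_length` is 0.
#' @export
area_efficiency <- function(area_covered, path_length) {
  if (!is.finite(path_length) || path_length <= 0) return(NA_real_)
  area_covered / path_length
}

#' @rdname area_efficiency
#' @export
landmark_efficiency <- function(landmark_visits, path_length) {
  if (!is.finite(path_length) || path_length <= 0) return(NA_real_)
  landmark_visits / path_length
}

#' Compute all thirteen exploration measures for one trajectory
#'
#' Resamples the trajectory to the configured uniform time base, resolves
#' all scale-relative defaults against the environment, and evaluates every
#' measure on its raw scale (no inversion, no z-scoring). Deterministic for
#' fixed inputs.
#'
#' @param traj a [trajectory] (raw time base is fine).
#' @param env an [environment_spec].
#' @param cfg a [metric_config].
#' @param resample resample to `cfg$dt` first (default `TRUE`).
#' @return a one-row data frame: `participant_id` plus the 13 measures in
#'   [measure_names()] order.
#' @export
compute_features <- function(traj, env, cfg = metric_config(),
                             resample = TRUE) {
  if (traj$duration < 10) {
    et_warn(sprintf("participant %s: trajectory shorter than 10 s",
                    traj$participant_id), "et_quality_warning")
  }
  if (resample) traj <- resample_uniform(traj, cfg$dt)
  cfg <- resolve_config(traj, env, cfg)
  occ <- grid_occupancy(traj, env, cfg)
  pl <- path_length(traj)
  ac <- area_covered(occ)
  lm_events <- landmark_event_counts(traj, env, cfg)
  lv <- sum(lm_events > 0)
  pausemask <- pause_step_mask(traj, cfg)
  hs <- heading_series_core(traj, cfg$min_step)
  ev <- turnaround_events(hs, cfg$turn_window)
  flights <- segment_flights(traj, cfg, pausemask = pausemask,
                             hs = hs, ev = ev)
  data.frame(
    participant_id = traj$participant_id,
    path_length = pl,
    pausing = sum(pausemask) * cfg$dt,
    area_covered = ac,
    roaming_entropy = roaming_entropy(occ),
    landmark_visits = lv,
    fractal_dimension = as.numeric(fractal_dimension(traj, cfg)),
    sinuosity = as.numeric(sinuosity(traj, cfg, pausemask = pausemask)),
    landmark_revisits = sum(pmax(lm_events - 1, 0)),
    revisiting = revisiting(occ),
    turnarounds = as.numeric(ev$count),
    flight_turnarounds = as.numeric(flight_turnarounds(flights)),
    area_efficiency = area_efficiency(ac, pl),
    landmark_efficiency = landmark_efficiency(lv, pl),
    stringsAsFactors = FALSE)
}

#' Compute the feature table for a set of trajectories
#'
#' @param trajs list of [trajectory] objects (or a `sim_panel`).
#' @param env an [environment_spec].
#' @param cfg a [metric_config].
#' @return a feature table data frame (one row per participant).
#' @export
compute_feature_table <- function(trajs, env, cfg = metric_config()) {
  if (inherits(trajs, "sim_panel")) {
    env <- trajs$environment
    trajs <- trajs$trajectories
  }
  rows <- lapply(trajs, compute_features, env = env, cfg = cfg)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
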