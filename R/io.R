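# Reading, writing and time-base preprocessing of trajectory logs,
# environment descriptions and participant metadata.
#
# Formats (all plain text, UTF-8, "." decimal separator):
#   * trajectory CSV:  participant_id,t,x,y[,h]
#   * environment JSON: {name, landmarks:[{id,x,y}], spawn:{x,y},
#                        bounds:{xmin,xmax,ymin,ymax}, cell_size}
#   * metadata CSV:    participant_id,sex,age,environment

#' Construct a trajectory
#'
#' A trajectory is one participant's timestamped ground-plane positions:
#' a data frame of samples (`t`, `x`, `y` and optionally `h`, the vertical
#' coordinate) plus the participant id. Timestamps must be strictly
#' increasing and all coordinates finite.
#'
#' @param participant_id single character id.
#' @param t numeric vector of timestamps (seconds from session start).
#' @param x,y numeric ground-plane coordinates (world units).
#' @param h optional vertical coordinate.
#' @return an object of class `trajectory`: a list with `participant_id`,
#'   `samples` (data frame), `nominal_rate` (samples/s) and `duration` (s).
#' @export
trajectory <- function(participant_id, t, x, y, h = NULL) {
  if (length(t) < 2L) {
    et_error("a trajectory needs at least 2 samples", "et_data_error")
  }
  if (anyNA(t) || anyNA(x) || anyNA(y) || (!is.null(h) && anyNA(h))) {
    et_error("trajectory contains missing values", "et_data_error")
  }
  if (!all(is.finite(t)) || !all(is.finite(x)) || !all(is.finite(y))) {
    et_error("trajectory coordinates must be finite", "et_data_error")
  }
  if (any(t < 0)) et_error("timestamps must be non-negative", "et_data_error")
  if (any(diff(t) <= 0)) {
    et_error("timestamps must be strictly increasing", "et_data_error")
  }
  samples <- data.frame(t = as.numeric(t), x = as.numeric(x),
                        y = as.numeric(y))
  if (!is.null(h)) samples$h <- as.numeric(h)
  duration <- t[length(t)] - t[1]
  structure(
    list(participant_id = as.character(participant_id),
         samples = samples,
         nominal_rate = (length(t) - 1) / duration,
         duration = duration),
    class = "trajectory")
}

#' @exportS3Method base::print
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory %s: %d samples, %.1f s, ~%.1f Hz>\n",
              x$participant_id, nrow(x$samples), x$duration,
              x$nominal_rate))
  invisible(x)
}

#' Read trajectory logs from a delimited text file
#'
#' Expects header columns `participant_id`, `t`, `x`, `y` and optionally
#' `h`. Rows are grouped by participant and sorted by time; duplicated
#' timestamps within a participant are collapsed to their first occurrence
#' with a warning.
#'
#' @param path file path.
#' @return a named list of [trajectory] objects, one per participant.
#' @export
read_trajectories <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("participant_id", "t", "x", "y")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    et_error(paste0("trajectory file lacks required column(s): ",
                    paste(missing_cols, collapse = ", ")),
             "et_format_error")
  }
  for (col in intersect(c("t", "x", "y", "h"), names(df))) {
    if (!is.numeric(df[[col]])) {
      suppressWarnings(df[[col]] <- as.numeric(df[[col]]))
    }
    if (anyNA(df[[col]])) {
      et_error(sprintf("non-numeric or missing values in column '%s'", col),
               "et_data_error")
    }
  }
  has_h <- "h" %in% names(df)
  out <- lapply(split(df, df$participant_id), function(g) {
    g <- g[order(g$t), , drop = FALSE]
    dup <- duplicated(g$t)
    if (any(dup)) {
      et_warn(sprintf(
        "participant %s: %d duplicate timestamp(s) collapsed to first",
        g$participant_id[1], sum(dup)), "et_quality_warning")
      g <- g[!dup, , drop = FALSE]
    }
    trajectory(g$participant_id[1], g$t, g$x, g$y,
               h = if (has_h) g$h else NULL)
  })
  out[unique(df$participant_id)]
}

#' Write trajectories to CSV
#'
#' @param trajs a list of [trajectory] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(trajs, path) {
  if (inherits(trajs, "trajectory")) trajs <- list(trajs)
  rows <- lapply(trajs, function(tr) {
    cbind(participant_id = tr$participant_id, tr$samples)
  })
  df <- do.call(rbind, rows)
  write_numeric_csv(df, path)
}

#' Construct / validate an environment description
#'
#' An environment is the arena the agent moves in: a rectangular walkable
#' extent, a spawn point, a set of uniquely identified landmarks inside the
#' bounds, and the grid edge length used by occupancy-based measures.
#'
#' @param name environment name.
#' @param landmarks data frame with columns `id`, `x`, `y`.
#' @param spawn numeric length-2 (x, y).
#' @param bounds named numeric vector/list with `xmin`, `xmax`, `ymin`,
#'   `ymax`.
#' @param cell_size grid edge length in world units (> 0).
#' @return an object of class `environment_spec`.
#' @export
environment_spec <- function(name, landmarks, spawn, bounds, cell_size) {
  bounds <- as.list(bounds)[c("xmin", "xmax", "ymin", "ymax")]
  if (any(vapply(bounds, is.null, logical(1)))) {
    et_error("bounds must provide xmin, xmax, ymin, ymax",
             "et_validation_error")
  }
  bounds <- lapply(bounds, as.numeric)
  if (bounds$xmax <= bounds$xmin || bounds$ymax <= bounds$ymin) {
    et_error("bounds must span a non-empty rectangle", "et_validation_error")
  }
  cell_size <- as.numeric(cell_size)
  if (!is.finite(cell_size) || cell_size <= 0) {
    et_error("cell_size must be positive", "et_validation_error")
  }
  landmarks <- as.data.frame(landmarks)[, c("id", "x", "y")]
  landmarks$id <- as.character(landmarks$id)
  if (anyDuplicated(landmarks$id)) {
    et_error("duplicate landmark id(s)", "et_validation_error")
  }
  inside <- landmarks$x >= bounds$xmin & landmarks$x <= bounds$xmax &
    landmarks$y >= bounds$ymin & landmarks$y <= bounds$ymax
  if (!all(inside)) {
    et_error(sprintf("landmark(s) outside bounds: %s",
                     paste(landmarks$id[!inside], collapse = ", ")),
             "et_validation_error")
  }
  spawn <- as.numeric(unlist(spawn))[1:2]
  structure(
    list(name = as.character(name), landmarks = landmarks,
         spawn = c(x = spawn[1], y = spawn[2]), bounds = bounds,
         cell_size = cell_size),
    class = "environment_spec")
}

#' @exportS3Method base::print
print.environment_spec <- function(x, ...) {
  cat(sprintf("<environment '%s': %d landmarks, [%g,%g]x[%g,%g], cell %g>\n",
              x$name, nrow(x$landmarks), x$bounds$xmin, x$bounds$xmax,
              x$bounds$ymin, x$bounds$ymax, x$cell_size))
  invisible(x)
}

#' Read an environment description from JSON
#'
#' @param path JSON file path (see package README for the schema).
#' @return an [environment_spec] object.
#' @export
read_environment <- function(path) {
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (key in c("name", "landmarks", "spawn", "bounds", "cell_size")) {
    if (is.null(spec[[key]])) {
      et_error(sprintf("environment file lacks key '%s'", key),
               "et_format_error")
    }
  }
  environment_spec(spec$name, spec$landmarks,
                   c(spec$spawn$x, spec$spawn$y), spec$bounds,
                   spec$cell_size)
}

#' Write an environment description to JSON
#'
#' @param env an [environment_spec].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_environment <- function(env, path) {
  obj <- list(
    name = env$name,
    landmarks = env$landmarks,
    spawn = list(x = unname(env$spawn["x"]), y = unname(env$spawn["y"])),
    bounds = env$bounds,
    cell_size = env$cell_size)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Read participant metadata
#'
#' CSV with header `participant_id,sex,age,environment`. Sex must be
#' `male`/`female`; ages outside the plausible range are rejected.
#'
#' @param path file path.
#' @param age_range allowed age interval in years.
#' @return data frame of metadata.
#' @export
read_metadata <- function(path, age_range = c(5, 100)) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("participant_id", "sex", "age")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    et_error(paste0("metadata file lacks required column(s): ",
                    paste(missing_cols, collapse = ", ")),
             "et_format_error")
  }
  validate_metadata(df, age_range)
}

validate_metadata <- function(df, age_range = c(5, 100)) {
  df$participant_id <- as.character(df$participant_id)
  df$sex <- tolower(as.character(df$sex))
  if (!all(df$sex %in% c("male", "female"))) {
    et_error("sex must be 'male' or 'female'", "et_validation_error")
  }
  df$age <- as.numeric(df$age)
  bad <- !is.finite(df$age) | df$age < age_range[1] | df$age > age_range[2]
  if (any(bad)) {
    et_error(sprintf("age outside plausible range [%g, %g] for: %s",
                     age_range[1], age_range[2],
                     paste(df$participant_id[bad], collapse = ", ")),
             "et_validation_error")
  }
  if (anyDuplicated(df$participant_id)) {
    et_error("duplicate participant_id in metadata", "et_validation_error")
  }
  df
}

#' Resample a trajectory to a uniform time base
#'
#' Raw logs are sampled at only approximately constant rate; step-length
#' sensitive measures (sinuosity, turnarounds) assume a uniform time base.
#' Samples are linearly interpolated at `t0, t0 + dt, ...` up to the last
#' timestamp.
#'
#' @param traj a [trajectory].
#' @param dt target sampling interval in seconds (default 1/15).
#' @return a resampled [trajectory].
#' @export
resample_uniform <- function(traj, dt = 1 / 15) {
  if (!is.numeric(dt) || dt <= 0) {
    et_error("dt must be positive", "et_data_error")
  }
  if (dt > traj$duration) {
    et_error("dt exceeds trajectory duration", "et_data_error")
  }
  s <- traj$samples
  tt <- seq(s$t[1], s$t[nrow(s)], by = dt)
  x <- approx(s$t, s$x, xout = tt)$y
  y <- approx(s$t, s$y, xout = tt)$y
  h <- if ("h" %in% names(s)) approx(s$t, s$h, xout = tt)$y else NULL
  trajectory(traj$participant_id, tt, x, y, h = h)
}

#' Project a 3-coordinate trajectory onto the ground plane
#'
#' Logs record three world axes in order (x, y, h); which one is "up"
#' depends on the engine. The configured vertical axis is dropped and the
#' remaining two become the planar (x, y).
#'
#' @param traj a [trajectory] whose samples carry three coordinates.
#' @param up_axis `"second"` (default; common game-engine convention, the
#'   recorded `y` is height) or `"third"` (the recorded `h` is height).
#' @return a 2-coordinate [trajectory].
#' @export
project_ground_plane <- function(traj, up_axis = c("second", "third")) {
  up_axis <- match.arg(up_axis)
  s <- traj$samples
  if (!("h" %in% names(s))) return(traj)  # already planar
  if (up_axis == "second") {
    trajectory(traj$participant_id, s$t, s$x, s$h)
  } else {
    trajectory(traj$participant_id, s$t, s$x, s$y)
  }
}

# write a data frame with full numeric precision (round-trips to 12+
# significant digits); missing values become empty fields
write_numeric_csv <- function(df, path) {
  out <- df
  for (col in names(out)) {
    if (is.numeric(out[[col]])) {
      v <- vapply(out[[col]], function(z) {
        if (is.na(z)) "" else format(z, digits = 15, scientific = FALSE,
                                     trim = TRUE)
      }, character(1))
      out[[col]] <- v
    }
  }
  ok <- tryCatch({
    write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) et_error(sprintf("cannot write to '%s'", path), "et_io_error")
  invisible(path)
}

#' Write / read a feature table
#'
#' Feature tables are participants-by-measures data frames with a
#' `participant_id` column followed by the thirteen measure columns on their
#' raw scale. Values round-trip to at least 12 significant digits; missing
#' values are written as empty fields.
#'
#' @param table feature table data frame.
#' @param path file path.
#' @return `path` (write) or the table (read).
#' @export
write_feature_table <- function(table, path) {
  write_numeric_csv(table, path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$participant_id <- as.character(df$participant_id)
  for (col in setdiff(names(df), "participant_id")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  df
}

#' Write analysis results to JSON
#'
#' @param results a list as produced by [run_pipeline()] (any JSON-able
#'   list works).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(path)
}
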