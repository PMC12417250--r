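# Synthetic study generator: environments with landmarks on a jittered
# node grid, demographic panels, and correlated-random-walk trajectories
# with controllable sex/age effects on the behavioral parameters. The
# generator exists so that every pipeline stage is testable end-to-end
# without human data; it makes no claim of cognitive realism.

#' Simulation configuration
#'
#' Defines the study conditions: 3-minute sessions sampled at 15 Hz on a
#' bounded arena with 20 landmarks, a panel of 424 participants (218 male /
#' 206 female) aged 7-77, and an effect profile mapping sex and
#' standardized age onto the behavioral parameters of the walk.
#'
#' Behavioral parameters (each with a population `base` and a
#' between-subject `sd`): `speed` (world units/s), `pause_rate` (pause
#' initiations per second), `pause_mean` (mean pause duration, s),
#' `turn_sd` (heading diffusion, rad/sqrt(s)), `attraction` (steering gain
#' toward the goal landmark, 1/s), `revisit_bias` (probability that the
#' next goal is an already-visited landmark). Effects are additive on the
#' standardized parameter scale: realized z = sex_coef * s + age_coef *
#' z_age + individual noise, with s = +1/2 (male) / -1/2 (female).
#'
#' Shipped profiles: `"demographic"` (males faster, fewer pauses, stronger
#' landmark attraction, higher revisit bias; turning noise decreasing with
#' age; no sex-age interaction) and `"null"` (no demographic effects).
#'
#' @param seed integer seed; fully determines the output.
#' @param n_participants panel size.
#' @param p_male probability/proportion of males.
#' @param exact_counts if `TRUE` (default) the sex counts are exactly
#'   `round(n * p_male)` males.
#' @param age_range truncation interval for ages, years.
#' @param age_meanlog,age_sdlog log-normal age distribution parameters
#'   (defaults approximate mean 23.9, sd 16.8 before truncation).
#' @param duration session length in seconds.
#' @param dt sampling interval in seconds.
#' @param bounds arena rectangle (named list xmin/xmax/ymin/ymax).
#' @param n_landmarks number of landmarks.
#' @param cell_size occupancy grid edge stored in the environment.
#' @param behavior named list of `c(base, sd)` behavioral parameters.
#' @param speed_cv within-trajectory speed variability.
#' @param profile `"demographic"`, `"null"`, or a custom effect list:
#'   per-parameter `c(sex = ..., age = ...)` coefficients.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_participants = 424L,
                       p_male = 218 / 424,
                       exact_counts = TRUE,
                       age_range = c(7, 77),
                       age_meanlog = 2.974,
                       age_sdlog = 0.632,
                       duration = 180,
                       dt = 1 / 15,
                       bounds = list(xmin = 0, xmax = 100,
                                     ymin = 0, ymax = 100),
                       n_landmarks = 20L,
                       cell_size = NULL,
                       behavior = list(
                         speed        = c(base = 3.0,  sd = 0.50),
                         pause_rate   = c(base = 0.06, sd = 0.020),
                         pause_mean   = c(base = 2.0,  sd = 0.40),
                         turn_sd      = c(base = 1.0,  sd = 0.25),
                         attraction   = c(base = 1.2,  sd = 0.30),
                         revisit_bias = c(base = 0.25, sd = 0.08)),
                       speed_cv = 0.15,
                       profile = "demographic") {
  if (duration / dt < 100) {
    et_error("duration/dt must yield at least 100 samples",
             "et_config_error")
  }
  if (is.character(profile)) {
    profile <- switch(
      profile,
      demographic = list(
        speed        = c(sex = 0.6, age = 0),
        pause_rate   = c(sex = -0.6, age = 0),
        attraction   = c(sex = 0.6, age = 0),
        revisit_bias = c(sex = 0.45, age = 0),
        turn_sd      = c(sex = 0.45, age = -0.8)),
      null = list(),
      et_error(sprintf("unknown profile '%s'", profile),
               "et_config_error"))
  }
  if (is.null(cell_size)) {
    short_edge <- min(bounds$xmax - bounds$xmin, bounds$ymax - bounds$ymin)
    cell_size <- short_edge / 20
  }
  structure(
    list(seed = as.integer(seed), n_participants = as.integer(n_participants),
         p_male = p_male, exact_counts = exact_counts,
         age_range = age_range, age_meanlog = age_meanlog,
         age_sdlog = age_sdlog, duration = duration, dt = dt,
         bounds = bounds, n_landmarks = as.integer(n_landmarks),
         cell_size = cell_size, behavior = behavior, speed_cv = speed_cv,
         profile = profile),
    class = "sim_config")
}

#' Generate an environment with landmarks on a jittered node grid
#'
#' Nodes are laid out on a jittered square grid (a sparse stand-in for a
#' path network); landmarks occupy a subset of nodes with maximal spread,
#' and the spawn point is the free node nearest the arena center.
#'
#' @param cfg a [sim_config].
#' @param seed seed (`NULL` to draw from the current RNG stream; defaults
#'   to `cfg$seed` so repeated standalone calls are identical).
#' @return an [environment_spec].
#' @export
make_environment <- function(cfg = sim_config(), seed = cfg$seed) {
  if (!is.null(seed)) set.seed(seed)
  b <- cfg$bounds
  g <- ceiling(sqrt(2 * cfg$n_landmarks)) + 1
  sx <- (b$xmax - b$xmin) / g
  sy <- (b$ymax - b$ymin) / g
  gx <- b$xmin + (rep(seq_len(g), g) - 0.5) * sx
  gy <- b$ymin + (rep(seq_len(g), each = g) - 0.5) * sy
  nodes <- data.frame(
    x = gx + runif(g * g, -0.3, 0.3) * sx,
    y = gy + runif(g * g, -0.3, 0.3) * sy)
  nodes$x <- pmin(pmax(nodes$x, b$xmin), b$xmax)
  nodes$y <- pmin(pmax(nodes$y, b$ymin), b$ymax)
  pick <- sample(nrow(nodes), cfg$n_landmarks)
  landmarks <- data.frame(id = sprintf("L%02d", seq_len(cfg$n_landmarks)),
                          x = nodes$x[pick], y = nodes$y[pick])
  free <- setdiff(seq_len(nrow(nodes)), pick)
  cx <- (b$xmin + b$xmax) / 2
  cy <- (b$ymin + b$ymax) / 2
  spawn_node <- free[which.min((nodes$x[free] - cx)^2 +
                                 (nodes$y[free] - cy)^2)]
  environment_spec(name = "synthetic-arena", landmarks = landmarks,
                   spawn = c(nodes$x[spawn_node], nodes$y[spawn_node]),
                   bounds = b, cell_size = cfg$cell_size)
}

#' Sample a demographic panel
#'
#' Sexes per `p_male` (exact counts by default), ages from a truncated
#' log-normal on `age_range`.
#'
#' @param cfg a [sim_config].
#' @param seed seed (`NULL` to use the current RNG stream).
#' @return metadata data frame (`participant_id`, `sex`, `age`,
#'   `environment`).
#' @export
sample_panel <- function(cfg = sim_config(), seed = cfg$seed) {
  if (!is.null(seed)) set.seed(seed)
  n <- cfg$n_participants
  if (cfg$exact_counts) {
    n_male <- round(n * cfg$p_male)
    sex <- sample(rep(c("male", "female"), c(n_male, n - n_male)))
  } else {
    sex <- ifelse(runif(n) < cfg$p_male, "male", "female")
  }
  age <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    draw <- rlnorm(length(need), cfg$age_meanlog, cfg$age_sdlog)
    ok <- draw >= cfg$age_range[1] & draw <= cfg$age_range[2]
    age[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  data.frame(participant_id = sprintf("P%04d", seq_len(n)),
             sex = sex, age = age, environment = "synthetic-arena",
             stringsAsFactors = FALSE)
}

# realize the behavioral parameters of one participant:
# base + sd * (sex_coef * s + age_coef * z_age + N(0,1))
realize_parameters <- function(sex, z_age, cfg) {
  s <- if (sex == "male") 0.5 else -0.5
  out <- numeric(0)
  for (pn in names(cfg$behavior)) {
    base <- cfg$behavior[[pn]]["base"]
    bsd <- cfg$behavior[[pn]]["sd"]
    eff <- cfg$profile[[pn]]
    z <- rnorm(1)
    if (!is.null(eff)) {
      z <- z + eff[["sex"]] * s + eff[["age"]] * z_age
    }
    out[pn] <- base + bsd * z
  }
  # physical clamps
  out["speed"] <- max(out["speed"], 0.2)
  out["pause_rate"] <- max(out["pause_rate"], 0)
  out["pause_mean"] <- max(out["pause_mean"], 0.2)
  out["turn_sd"] <- max(out["turn_sd"], 0.05)
  out["attraction"] <- max(out["attraction"], 0)
  out["revisit_bias"] <- min(max(out["revisit_bias"], 0), 1)
  out
}

#' Simulate one exploration trajectory
#'
#' A correlated random walk starting at the spawn point: heading diffuses
#' with concentration set by `turn_sd`, relaxes toward the current goal
#' landmark, pauses start as a Poisson process with exponential durations,
#' and the goal switches on arrival (nearest unvisited landmark, or an
#' already-visited one with probability `revisit_bias`). The walk reflects
#' at the arena bounds.
#'
#' @param meta one metadata row (`sex`, `age`, `participant_id`).
#' @param env an [environment_spec].
#' @param cfg a [sim_config].
#' @param params named parameter vector (from [realize_parameters];
#'   `NULL` realizes them from `meta` and the effect profile).
#' @param z_age standardized age (used only when `params` is `NULL`).
#' @param seed seed (`NULL` to use the current RNG stream).
#' @return a [trajectory] with attribute `params`.
#' @export
simulate_trajectory <- function(meta, env, cfg = sim_config(),
                                params = NULL, z_age = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(params)) params <- realize_parameters(meta$sex, z_age, cfg)
  n_steps <- round(cfg$duration / cfg$dt)
  b <- env$bounds
  xy <- crw_simulate(
    n_steps = n_steps, dt = cfg$dt,
    x0 = unname(env$spawn["x"]), y0 = unname(env$spawn["y"]),
    xmin = b$xmin, xmax = b$xmax, ymin = b$ymin, ymax = b$ymax,
    lm_x = env$landmarks$x, lm_y = env$landmarks$y,
    landmark_radius = 2 * env$cell_size,
    speed_mean = params[["speed"]], speed_cv = cfg$speed_cv,
    pause_rate = params[["pause_rate"]],
    pause_mean = params[["pause_mean"]],
    turn_sd = params[["turn_sd"]], attraction = params[["attraction"]],
    revisit_bias = params[["revisit_bias"]])
  tr <- trajectory(meta$participant_id,
                   t = seq(0, by = cfg$dt, length.out = n_steps + 1),
                   x = xy[, 1], y = xy[, 2])
  attr(tr, "params") <- params
  tr
}

#' Simulate a complete study
#'
#' Environment + panel + one trajectory per participant, all drawn from a
#' single RNG stream seeded once with `cfg$seed` (so the whole panel is a
#' pure function of the configuration). The realized behavioral parameters
#' are kept in `truth` for parameter-recovery tests.
#'
#' @param cfg a [sim_config].
#' @return an object of class `sim_panel`: list with `meta`,
#'   `trajectories`, `environment`, `truth`, `config`.
#' @export
simulate_study <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  env <- make_environment(cfg, seed = NULL)
  meta <- sample_panel(cfg, seed = NULL)
  z_age <- (meta$age - mean(meta$age)) / sd(meta$age)
  trajs <- vector("list", nrow(meta))
  truth <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    params <- realize_parameters(meta$sex[i], z_age[i], cfg)
    trajs[[i]] <- simulate_trajectory(meta[i, ], env, cfg,
                                      params = params, seed = NULL)
    truth[[i]] <- c(list(participant_id = meta$participant_id[i]),
                    as.list(params))
  }
  names(trajs) <- meta$participant_id
  structure(
    list(meta = meta, trajectories = trajs, environment = env,
         truth = do.call(rbind, lapply(truth, as.data.frame)),
         config = cfg),
    class = "sim_panel")
}

#' @exportS3Method base::print
print.sim_panel <- function(x, ...) {
  cat(sprintf("<sim_panel: %d participants (%d male / %d female), %s>\n",
              nrow(x$meta), sum(x$meta$sex == "male"),
              sum(x$meta$sex == "female"), x$environment$name))
  invisible(x)
}

#' Simulate a block-correlated feature table
#'
#' Draws a participants-by-13 Gaussian table whose correlation matrix has
#' the reference three-block structure (within-block correlation
#' `r_within`, between-block `r_between`): the substrate for
#' cluster-recovery tests with known ground truth.
#'
#' @param n number of participants.
#' @param r_within,r_between block correlation levels.
#' @param seed seed (`NULL` to use the current RNG stream).
#' @return feature table data frame (raw scale = z scale here).
#' @export
simulate_feature_table <- function(n = 424, r_within = 0.6,
                                   r_between = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  blocks <- reference_clusters()
  measures <- unlist(blocks, use.names = FALSE)
  p <- length(measures)
  block_of <- rep(names(blocks), lengths(blocks))
  sigma <- matrix(r_between, p, p)
  for (b in names(blocks)) {
    idx <- which(block_of == b)
    sigma[idx, idx] <- r_within
  }
  diag(sigma) <- 1
  m <- MASS::mvrnorm(n, mu = rep(0, p), Sigma = sigma)
  colnames(m) <- measures
  out <- data.frame(participant_id = sprintf("P%04d", seq_len(n)),
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(m)[, measure_names()])
}

#' Simulate compound scores directly (score-level generator)
#'
#' Draws a demographic panel and trivariate-normal compound scores with
#' optional planted sex differences and age slopes, bypassing the
#' trajectory level. Used for statistical calibration (type-I error,
#' power, structural dfs) where thousands of replicates are needed.
#'
#' @param n panel size.
#' @param d_sex named vector of standardized male-minus-female differences
#'   per exploration type.
#' @param age_slope named vector of per-SD-of-age standardized slopes.
#' @param rho common correlation between the three scores.
#' @param p_male male proportion (exact counts).
#' @param seed seed (`NULL` to use the current RNG stream).
#' @return list with `scores` (wide data frame) and `meta`.
#' @export
simulate_scores <- function(n = 424,
                            d_sex = c(activity = 0, shape = 0,
                                      efficiency = 0),
                            age_slope = c(activity = 0, shape = 0,
                                          efficiency = 0),
                            rho = 0.2, p_male = 218 / 424, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_male <- round(n * p_male)
  sex <- sample(rep(c("male", "female"), c(n_male, n - n_male)))
  age <- pmin(pmax(rlnorm(n, 2.974, 0.632), 7), 77)
  z_age <- (age - mean(age)) / sd(age)
  s <- ifelse(sex == "male", 0.5, -0.5)
  sigma <- matrix(rho, 3, 3); diag(sigma) <- 1
  e <- MASS::mvrnorm(n, mu = rep(0, 3), Sigma = sigma)
  types <- exploration_types()
  scores <- data.frame(participant_id = sprintf("P%04d", seq_len(n)),
                       stringsAsFactors = FALSE)
  for (j in seq_along(types)) {
    tp <- types[j]
    scores[[tp]] <- e[, j] + d_sex[[tp]] * s + age_slope[[tp]] * z_age
  }
  meta <- data.frame(participant_id = scores$participant_id, sex = sex,
                     age = age, environment = "score-level",
                     stringsAsFactors = FALSE)
  list(scores = scores, meta = meta)
}
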