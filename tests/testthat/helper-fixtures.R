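# Fixture builders shared across test files. Everything is generated in
# code; no data files.

# small square arena with a regular 2 x 2-ish landmark layout
fixture_env <- function(n_landmarks = 4, extent = 20, cell_size = 1) {
  g <- ceiling(sqrt(n_landmarks))
  sp <- extent / (g + 1)
  lx <- rep(seq_len(g) * sp, length.out = n_landmarks)
  ly <- rep(seq_len(g) * sp, each = g)[seq_len(n_landmarks)]
  environment_spec(
    name = "test-arena",
    landmarks = data.frame(id = paste0("L", seq_len(n_landmarks)),
                           x = lx, y = ly),
    spawn = c(extent / 2, extent / 2),
    bounds = list(xmin = 0, xmax = extent, ymin = 0, ymax = extent),
    cell_size = cell_size)
}

# fully specified config so oracles and implementation resolve identically
fixture_cfg <- function(dt = 1 / 15, pause_speed = 0.5, pause_min = 1,
                        landmark_radius = 2, turn_window = 3,
                        flight_min_len = 2,
                        divider_scales = c(0.5, 1, 2, 4),
                        cell_size = 1) {
  metric_config(dt = dt, pause_speed = pause_speed, pause_min = pause_min,
                landmark_radius = landmark_radius,
                turn_window = turn_window,
                flight_min_len = flight_min_len,
                divider_scales = divider_scales, cell_size = cell_size)
}

# random walk with embedded pauses on a uniform time base, kept inside
# the fixture arena
random_traj <- function(n = 200, dt = 1 / 15, id = "R1", extent = 20,
                        speed = 8, pause_p = 0.05) {
  x <- numeric(n); y <- numeric(n)
  x[1] <- extent / 2; y[1] <- extent / 2
  heading <- runif(1, -pi, pi)
  pause_left <- 0
  for (i in 2:n) {
    if (pause_left > 0) {
      pause_left <- pause_left - 1
      x[i] <- x[i - 1]; y[i] <- y[i - 1]
      next
    }
    if (runif(1) < pause_p) pause_left <- sample(5:30, 1)
    heading <- heading + rnorm(1, 0, 0.6)
    x[i] <- x[i - 1] + cos(heading) * speed * dt
    y[i] <- y[i - 1] + sin(heading) * speed * dt
    if (x[i] < 0.5 || x[i] > extent - 0.5) {
      heading <- pi - heading
      x[i] <- min(max(x[i], 0.5), extent - 0.5)
    }
    if (y[i] < 0.5 || y[i] > extent - 0.5) {
      heading <- -heading
      y[i] <- min(max(y[i], 0.5), extent - 0.5)
    }
  }
  trajectory(id, t = (seq_len(n) - 1) * dt, x = x, y = y)
}

# straight constant-speed trajectory along +x
straight_traj <- function(n = 50, dt = 1 / 15, step = 0.5, id = "S1") {
  trajectory(id, t = (seq_len(n) - 1) * dt,
             x = (seq_len(n) - 1) * step, y = rep(0, n))
}

# Koch snowflake edge iterated `iter` times, as a polyline trajectory
koch_traj <- function(iter = 4, dt = 1 / 15) {
  pts <- matrix(c(0, 0, 1, 0), ncol = 2, byrow = TRUE)
  for (k in seq_len(iter)) {
    out <- NULL
    for (i in 1:(nrow(pts) - 1)) {
      p <- pts[i, ]; q <- pts[i + 1, ]
      v <- (q - p) / 3
      a <- p + v; b <- p + 2 * v
      rot <- c(v[1] * cos(pi / 3) - v[2] * sin(pi / 3),
               v[1] * sin(pi / 3) + v[2] * cos(pi / 3))
      m <- a + rot
      out <- rbind(out, p, a, m, b)
    }
    pts <- rbind(out, pts[nrow(pts), ])
  }
  trajectory("koch", t = (seq_len(nrow(pts)) - 1) * dt,
             x = pts[, 1], y = pts[, 2])
}

# score-level long data with planted effects, for statistics tests
fixture_long <- function(n = 60, seed = 1, ...) {
  sim <- simulate_scores(n, seed = seed, ...)
  to_long(sim$scores, sim$meta)
}
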