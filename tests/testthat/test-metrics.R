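# The thirteen exploration measures against closed forms and brute-force
# oracles.

test_that("path length matches closed forms and the step-sum oracle", {
  sq <- trajectory("sq", t = 0:4, x = c(0, 1, 1, 0, 0),
                   y = c(0, 0, 1, 1, 0))
  expect_equal(path_length(sq), 4.0)

  set.seed(1)
  rw <- random_traj(1000)
  expect_equal(path_length(rw), o_path_length(rw), tolerance = 1e-9)
})

test_that("pausing totals the qualifying sub-threshold intervals", {
  cfg <- fixture_cfg(dt = 0.1, pause_speed = 0.5, pause_min = 1)
  # move 10 s, freeze 5 s, move 10 s
  seg <- function(n, v) rep(v, n)
  v <- c(seg(100, 0.2), seg(50, 0), seg(100, 0.2))   # step lengths
  tr <- trajectory("p", t = seq(0, by = 0.1, length.out = length(v) + 1),
                   x = cumsum(c(0, v)), y = rep(0, length(v) + 1))
  expect_equal(pausing(tr, cfg), 5.0)

  # continuous motion above threshold
  tr2 <- straight_traj(100, dt = 0.1, step = 0.2)
  expect_equal(pausing(tr2, cfg), 0)

  # sub-threshold runs of 0.5 s, 2 s, 3 s -> only the latter two count
  v3 <- c(seg(20, 0.2), seg(5, 0), seg(20, 0.2), seg(20, 0),
          seg(20, 0.2), seg(30, 0), seg(20, 0.2))
  tr3 <- trajectory("p3", t = seq(0, by = 0.1, length.out = length(v3) + 1),
                    x = cumsum(c(0, v3)), y = rep(0, length(v3) + 1))
  expect_equal(pausing(tr3, cfg), 5.0)
  expect_equal(pausing(tr3, cfg), o_pausing(tr3, cfg))
})

test_that("grid occupancy follows the half-open cell convention", {
  env <- fixture_env()
  cfg <- fixture_cfg()
  # trajectory confined to one cell
  tr <- trajectory("c", t = 0:3, x = c(5.1, 5.3, 5.2, 5.4),
                   y = rep(5.5, 4))
  occ <- grid_occupancy(tr, env, cfg)
  expect_equal(nrow(occ$cells), 1)
  expect_equal(occ$cells$runs, 1)
  expect_equal(occ$K_total, 400)

  # A -> B -> A across a cell boundary: runs per the run-length oracle
  tr2 <- trajectory("ab", t = 0:6,
                    x = c(5.5, 6.5, 7.5, 6.5, 5.5, 6.5, 7.5),
                    y = rep(5.5, 7))
  occ2 <- grid_occupancy(tr2, env, cfg)
  o <- o_occupancy(tr2, env, 1)
  expect_equal(sum(occ2$cells$count), 7)
  expect_equal(sort(occ2$cells$runs), sort(unname(o$runs)))

  # sample exactly on an interior edge goes to the higher-index cell
  tr3 <- trajectory("e", t = 0:1, x = c(6, 6), y = c(3.5, 3.6))
  occ3 <- grid_occupancy(tr3, env, cfg)
  expect_equal(occ3$cells$ix, 6)
})

test_that("area covered counts occupied cells times cell area", {
  env <- fixture_env(cell_size = 2)
  cfg <- fixture_cfg(cell_size = 2)
  tr <- trajectory("c", t = 0:2, x = c(5, 5.5, 5.2), y = rep(5, 3))
  expect_equal(area_covered(grid_occupancy(tr, env, cfg)), 4.0)

  # straight line crossing k distinct cells
  tr2 <- straight_traj(n = 100, step = 0.17)
  tr2$samples$x <- tr2$samples$x + 1
  tr2$samples$y <- tr2$samples$y + 1
  occ2 <- grid_occupancy(tr2, fixture_env(), fixture_cfg())
  o2 <- o_occupancy(tr2, fixture_env(), 1)
  expect_equal(area_covered(occ2), length(o2$counts) * 1)

  # uniform sweep over a 3 x 4 block of unit cells
  xs <- rep(seq(0.5, 3.5, by = 1), 4)
  ys <- rep(seq(0.5, 3.5, by = 1), each = 4)[1:12]
  ys <- rep(c(0.5, 1.5, 2.5, 3.5), each = 3)
  xs <- rep(c(0.5, 1.5, 2.5), 4)
  trs <- trajectory("sweep", t = seq_along(xs) - 1, x = xs, y = ys)
  expect_equal(area_covered(grid_occupancy(trs, fixture_env(),
                                           fixture_cfg())), 12)
})

test_that("roaming entropy hits its endpoints and the direct formula", {
  env <- fixture_env()  # 20 x 20 unit cells
  cfg <- fixture_cfg()
  one <- trajectory("one", t = 0:9, x = rep(5.5, 10) + 0.01 * (0:9),
                    y = rep(5.5, 10))
  expect_equal(roaming_entropy(grid_occupancy(one, env, cfg)), 0)

  # equal time in every cell of a 10 x 10 arena -> 1
  env10 <- environment_spec("u", data.frame(id = "L1", x = 5, y = 5),
                            c(5, 5),
                            list(xmin = 0, xmax = 10, ymin = 0, ymax = 10),
                            cell_size = 1)
  xs <- rep(seq(0.5, 9.5), 10)
  ys <- rep(seq(0.5, 9.5), each = 10)
  uni <- trajectory("u", t = seq_along(xs) - 1, x = xs, y = ys)
  expect_equal(roaming_entropy(grid_occupancy(uni, env10, cfg)), 1)

  # counts {30, 10, 10} on a 100-cell grid, hand-rolled entropy
  xs2 <- c(rep(0.5, 30), rep(1.5, 10), rep(2.5, 10))
  tr2 <- trajectory("h", t = seq_along(xs2) - 1, x = xs2,
                    y = rep(0.5, 50))
  occ2 <- grid_occupancy(tr2, env10, cfg)
  p <- c(30, 10, 10) / 50
  expect_equal(roaming_entropy(occ2), -sum(p * log(p)) / log(100))
})

test_that("landmark visit events count entries, revisits count returns", {
  env <- fixture_env(n_landmarks = 4)  # landmarks on a grid, radius 2
  cfg <- fixture_cfg(landmark_radius = 2)
  lx <- env$landmarks$x; ly <- env$landmarks$y

  # one pass by three distinct landmarks
  path_x <- c(15, lx[1], lx[2], 15)
  path_y <- c(15, ly[1], ly[2], 15)
  tr <- trajectory("v", t = 0:3, x = c(15, lx[1], lx[2], lx[3]),
                   y = c(15, ly[1], ly[2], ly[3]))
  expect_equal(landmark_visits(tr, env, cfg), 3)
  expect_equal(landmark_revisits(tr, env, cfg), 0)

  # L1 entered 4 times; L2 entered once and never left
  far <- c(15, 15)
  xs <- c(rep(c(lx[1], far[1]), 4), rep(lx[2], 3))
  ys <- c(rep(c(ly[1], far[2]), 4), rep(ly[2], 3))
  tr2 <- trajectory("r", t = seq_along(xs) - 1, x = xs, y = ys)
  ev <- o_landmark_events(tr2, env, cfg$landmark_radius)
  expect_equal(landmark_visits(tr2, env, cfg), sum(ev > 0))
  expect_equal(landmark_revisits(tr2, env, cfg), sum(pmax(ev - 1, 0)))
  expect_equal(landmark_visits(tr2, env, cfg), 2)
  expect_equal(landmark_revisits(tr2, env, cfg), 3)

  # never near any landmark
  tr3 <- trajectory("n", t = 0:3, x = rep(17, 4) + 0.01 * (0:3),
                    y = rep(17, 4))
  expect_equal(landmark_visits(tr3, env, cfg), 0)
  expect_equal(landmark_revisits(tr3, env, cfg), 0)
})

test_that("revisiting averages surplus visit runs over occupied cells", {
  env <- fixture_env()
  cfg <- fixture_cfg()
  # self-avoiding path
  tr <- trajectory("sa", t = 0:4, x = c(0.5, 1.5, 2.5, 3.5, 4.5),
                   y = rep(0.5, 5))
  expect_equal(revisiting(grid_occupancy(tr, env, cfg)), 0)

  # looping a 4-cell circuit 3 times: every cell has 3 runs
  loop_x <- rep(c(0.5, 1.5, 1.5, 0.5), 3)
  loop_y <- rep(c(0.5, 0.5, 1.5, 1.5), 3)
  tr2 <- trajectory("lp", t = seq_along(loop_x) - 1, x = loop_x,
                    y = loop_y)
  expect_equal(revisiting(grid_occupancy(tr2, env, cfg)), 2.0)

  # two cells with runs {1, 3}
  xs <- c(0.5, 1.5, 0.5, 1.5, 1.5)
  tr3 <- trajectory("m", t = 0:4, x = xs, y = rep(0.5, 5))
  expect_equal(revisiting(grid_occupancy(tr3, env, cfg)), 1.0)
})

test_that("heading series unwraps cumulative turning", {
  cfg <- fixture_cfg()
  st <- straight_traj(20)
  hs <- heading_series(st, cfg)
  expect_equal(hs$heading, rep(0, 19))

  # full counter-clockwise circle accumulates 2*pi
  th <- seq(0, 2 * pi, length.out = 100)
  circ <- trajectory("c", t = seq_along(th) - 1, x = cos(th), y = sin(th))
  hs2 <- heading_series(circ, cfg)
  expect_equal(hs2$heading[length(hs2$heading)] - hs2$heading[1],
               2 * pi * (98 / 99), tolerance = 1e-6)

  # noisy path equals the cumulative-sum-of-wrapped-differences oracle
  set.seed(2)
  rw <- random_traj(300)
  hs3 <- heading_series(rw, cfg)
  o <- o_heading_series(rw, cfg$min_step)
  expect_equal(hs3$heading, o$heading, tolerance = 1e-9)
  expect_equal(hs3$step, o$step)
})

test_that("turnarounds count windowed pi-exceeding events once each", {
  cfg <- fixture_cfg(dt = 0.1, turn_window = 3)
  expect_equal(turnarounds(straight_traj(100, dt = 0.1), cfg), 0)

  # east, west, east, west: three reversals -> three events
  v <- c(rep(0.3, 20), rep(-0.3, 20), rep(0.3, 20), rep(-0.3, 20))
  tr <- trajectory("z", t = seq(0, by = 0.1, length.out = length(v) + 1),
                   x = cumsum(c(0, v)), y = rep(0, length(v) + 1))
  expect_equal(turnarounds(tr, cfg), 3)
  expect_equal(turnarounds(tr, cfg), o_turnarounds(tr, cfg))

  # smooth slow circle: per-window turning stays below pi
  th <- seq(0, 2 * pi, length.out = 600)   # 60 s for one revolution
  circ <- trajectory("c", t = seq_along(th) * 0.1,
                     x = 10 * cos(th), y = 10 * sin(th))
  expect_equal(turnarounds(circ, cfg), 0)
})

test_that("flight segmentation and flight-scale turnarounds", {
  cfg <- fixture_cfg(dt = 0.1, pause_speed = 0.5, pause_min = 1,
                     flight_min_len = 2)
  # single straight run
  fl <- segment_flights(straight_traj(100, dt = 0.1), cfg)
  expect_equal(nrow(fl), 1)
  expect_equal(flight_turnarounds(fl), 0)

  # out and back with a pause at the far end
  v <- c(rep(0.3, 30), rep(0, 15), rep(-0.3, 30))
  tr <- trajectory("ob", t = seq(0, by = 0.1, length.out = length(v) + 1),
                   x = cumsum(c(0, v)), y = rep(0, length(v) + 1))
  fl2 <- segment_flights(tr, cfg)
  expect_equal(nrow(fl2), 2)
  expect_equal(flight_turnarounds(fl2), 1)
  expect_equal(flight_turnarounds(fl2), o_flight_turnarounds(tr, cfg))

  # three collinear flights separated by pauses
  v3 <- c(rep(0.3, 30), rep(0, 15), rep(0.3, 30), rep(0, 15), rep(0.3, 30))
  tr3 <- trajectory("3f", t = seq(0, by = 0.1, length.out = length(v3) + 1),
                    x = cumsum(c(0, v3)), y = rep(0, length(v3) + 1))
  fl3 <- segment_flights(tr3, cfg)
  expect_equal(nrow(fl3), 3)
  expect_equal(flight_turnarounds(fl3), 0)
})

test_that("fractal dimension: line, Koch curve, Brownian-like walk", {
  cfg_line <- fixture_cfg(divider_scales = c(0.25, 0.5, 1, 2, 4))
  expect_equal(fractal_dimension(straight_traj(200, step = 0.1), cfg_line),
               1.0, tolerance = 0.05)

  # Koch polyline, 4 iterations: D = ln 4 / ln 3
  kt <- koch_traj(4)
  cfg_koch <- metric_config(
    divider_scales = exp(seq(log(0.01), log(0.25), length.out = 8)),
    pause_speed = 1e-9, cell_size = 0.05)
  expect_equal(fractal_dimension(kt, cfg_koch), log(4) / log(3),
               tolerance = 0.08)

  # dense isotropic random walk exceeds the straight-line dimension
  set.seed(3)
  n <- 1e4
  rw <- trajectory("b", t = seq_len(n) - 1,
                   x = cumsum(rnorm(n)), y = cumsum(rnorm(n)))
  span <- max(dist(cbind(range(rw$samples$x), range(rw$samples$y))))
  cfg_rw <- metric_config(
    divider_scales = exp(seq(log(2), log(span / 4), length.out = 8)),
    pause_speed = 1e-9, cell_size = 1)
  d_rw <- fractal_dimension(rw, cfg_rw)
  expect_gt(d_rw, 1.3)
  expect_lte(d_rw, 2.0)

  # divider-walk oracle agreement at every ruler
  set.seed(5)
  tr <- random_traj(200)
  for (delta in c(0.5, 1, 2)) {
    expect_equal(
      exploretrace:::divider_count(tr$samples$x, tr$samples$y, delta),
      o_divider_count(tr$samples$x, tr$samples$y, delta),
      tolerance = 1e-9)
  }
})

test_that("sinuosity follows the corrected estimator and its scaling law", {
  cfg <- fixture_cfg(dt = 1, pause_speed = 0.01)
  expect_equal(as.numeric(sinuosity(straight_traj(50, dt = 1, step = 1),
                                    cfg)), 0)
  expect_true(isTRUE(attr(sinuosity(straight_traj(50, dt = 1, step = 1),
                                    cfg), "straight")))

  # unit steps turning +-90 degrees: c = 0, b = 0 -> S = 2
  n <- 40
  dirs <- rep(c(0, pi / 2), n / 2)
  xs <- cumsum(c(0, cos(dirs)))
  ys <- cumsum(c(0, sin(dirs)))
  zig <- trajectory("zig", t = 0:n, x = xs, y = ys)
  expect_equal(as.numeric(sinuosity(zig, cfg)), 2.0, tolerance = 1e-9)

  # scaling coordinates by 4 halves S
  zig4 <- trajectory("zig4", t = 0:n, x = 4 * xs, y = 4 * ys)
  cfg4 <- fixture_cfg(dt = 1, pause_speed = 0.01)
  expect_equal(as.numeric(sinuosity(zig4, cfg4)), 1.0, tolerance = 1e-9)
})

test_that("efficiencies are ratios with missing-value guards", {
  expect_equal(area_efficiency(100, 50), 2.0)
  expect_equal(landmark_efficiency(0, 50), 0.0)
  expect_true(is.na(area_efficiency(100, 0)))

  set.seed(6)
  tr <- random_traj(300)
  env <- fixture_env(n_landmarks = 9)
  cfg <- fixture_cfg()
  f <- compute_features(tr, env, cfg, resample = FALSE)
  ev <- o_landmark_events(tr, env, cfg$landmark_radius)
  o_area <- length(o_occupancy(tr, env, 1)$counts)
  expect_equal(f$area_efficiency, o_area / o_path_length(tr),
               tolerance = 1e-9)
  expect_equal(f$landmark_efficiency, sum(ev > 0) / o_path_length(tr),
               tolerance = 1e-9)
})

test_that("compute_features handles the degenerate stationary session", {
  env <- fixture_env()
  cfg <- fixture_cfg()
  still <- trajectory("still", t = seq(0, 180, by = 1 / 15),
                      x = rep(10, 2701), y = rep(10, 2701))
  f <- compute_features(still, env, cfg = metric_config(cell_size = 1),
                        resample = FALSE)
  expect_equal(f$path_length, 0)
  expect_equal(f$pausing, 180, tolerance = 0.1)
  expect_equal(f$area_covered, 1)
  expect_equal(f$roaming_entropy, 0)
  expect_equal(f$landmark_visits, 0)
  expect_equal(f$turnarounds, 0)
  expect_equal(f$flight_turnarounds, 0)
  expect_true(is.na(f$fractal_dimension))
  expect_true(is.na(f$sinuosity))
  expect_true(is.na(f$area_efficiency))
})

test_that("compute_features is deterministic for fixed inputs", {
  panel <- simulate_study(sim_config(seed = 1, n_participants = 2))
  f1 <- compute_features(panel$trajectories[[1]], panel$environment)
  f2 <- compute_features(panel$trajectories[[1]], panel$environment)
  expect_identical(f1, f2)
})

test_that("rigid motions leave the geometric measures unchanged", {
  set.seed(8)
  tr <- random_traj(400)
  env <- fixture_env(n_landmarks = 4)
  cfg <- fixture_cfg()
  f0 <- compute_features(tr, env, cfg, resample = FALSE)

  # rotate trajectory + environment about the arena center, then
  # translate both; re-center into fresh bounds
  phi <- 0.7; cx <- 10; cy <- 10; sh <- c(3, -2)
  rot <- function(x, y) {
    list(x = cx + cos(phi) * (x - cx) - sin(phi) * (y - cy) + sh[1],
         y = cy + sin(phi) * (x - cx) + cos(phi) * (y - cy) + sh[2])
  }
  p <- rot(tr$samples$x, tr$samples$y)
  tr2 <- trajectory(tr$participant_id, tr$samples$t, p$x, p$y)
  l <- rot(env$landmarks$x, env$landmarks$y)
  env2 <- environment_spec(
    env$name, data.frame(id = env$landmarks$id, x = l$x, y = l$y),
    spawn = unlist(rot(env$spawn["x"], env$spawn["y"])),
    bounds = list(xmin = -20, xmax = 40, ymin = -20, ymax = 40),
    cell_size = 1)
  f1 <- compute_features(tr2, env2, cfg, resample = FALSE)
  for (m in c("path_length", "sinuosity", "fractal_dimension",
              "turnarounds", "flight_turnarounds", "pausing",
              "landmark_visits", "landmark_revisits")) {
    expect_equal(f1[[m]], f0[[m]], tolerance = 1e-6, label = m)
  }

  # grid measures are invariant under translations by whole cells
  tr3 <- trajectory(tr$participant_id, tr$samples$t,
                    tr$samples$x + 3, tr$samples$y + 5)
  env3 <- environment_spec(
    env$name,
    data.frame(id = env$landmarks$id, x = env$landmarks$x + 3,
               y = env$landmarks$y + 5),
    spawn = env$spawn + c(3, 5),
    bounds = list(xmin = 3, xmax = 23, ymin = 5, ymax = 25),
    cell_size = 1)
  f3 <- compute_features(tr3, env3, cfg, resample = FALSE)
  for (m in c("area_covered", "roaming_entropy", "revisiting")) {
    expect_equal(f3[[m]], f0[[m]], tolerance = 1e-9, label = m)
  }
})

test_that("adding a detour loop never decreases length or revisiting", {
  env <- fixture_env()
  cfg <- fixture_cfg(dt = 0.1)
  base_x <- seq(0.5, 10, by = 0.3)
  tr <- trajectory("b", t = seq_along(base_x) * 0.1 - 0.1,
                   x = base_x, y = rep(0.5, length(base_x)))
  # splice in a loop revisiting earlier cells
  loop_x <- c(rev(seq(4.5, 9.9, by = 0.3)), seq(4.5, 9.9, by = 0.3))
  det_x <- c(base_x, loop_x + 0.05)
  tr_det <- trajectory("d", t = seq_along(det_x) * 0.1 - 0.1,
                       x = det_x, y = rep(0.5, length(det_x)))
  f0 <- suppressWarnings(compute_features(tr, env, cfg, resample = FALSE))
  f1 <- suppressWarnings(compute_features(tr_det, env, cfg,
                                          resample = FALSE))
  expect_gte(f1$path_length, f0$path_length)
  expect_gte(f1$revisiting, f0$revisiting)
  expect_gte(f1$turnarounds, f0$turnarounds)
})
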