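# Independent brute-force oracles for the exploration measures, coded as
# plain per-sample loops so they share no code path with the package
# implementations.

o_wrap <- function(a) {
  while (a >= pi) a <- a - 2 * pi
  while (a < -pi) a <- a + 2 * pi
  a
}

o_path_length <- function(traj) {
  s <- traj$samples
  total <- 0
  for (i in 2:nrow(s)) {
    total <- total + sqrt((s$x[i] - s$x[i - 1])^2 + (s$y[i] - s$y[i - 1])^2)
  }
  total
}

o_speeds <- function(traj, dt) {
  s <- traj$samples
  v <- numeric(nrow(s) - 1)
  for (i in seq_along(v)) {
    v[i] <- sqrt((s$x[i + 1] - s$x[i])^2 + (s$y[i + 1] - s$y[i])^2) / dt
  }
  v
}

# run-length scan over the speed series
o_pause_mask <- function(traj, cfg) {
  v <- o_speeds(traj, cfg$dt)
  slow <- v < cfg$pause_speed
  mask <- logical(length(v))
  i <- 1
  while (i <= length(slow)) {
    if (slow[i]) {
      j <- i
      while (j < length(slow) && slow[j + 1]) j <- j + 1
      if ((j - i + 1) * cfg$dt >= cfg$pause_min) mask[i:j] <- TRUE
      i <- j + 1
    } else i <- i + 1
  }
  mask
}

o_pausing <- function(traj, cfg) sum(o_pause_mask(traj, cfg)) * cfg$dt

# per-sample cell labeling + run-length encoding
o_occupancy <- function(traj, env, cell_size) {
  s <- traj$samples
  b <- env$bounds
  nx <- max(1, ceiling((b$xmax - b$xmin) / cell_size - 1e-9))
  ny <- max(1, ceiling((b$ymax - b$ymin) / cell_size - 1e-9))
  key <- character(nrow(s))
  for (i in seq_len(nrow(s))) {
    ix <- floor((s$x[i] - b$xmin) / cell_size)
    iy <- floor((s$y[i] - b$ymin) / cell_size)
    ix <- min(max(ix, 0), nx - 1)
    iy <- min(max(iy, 0), ny - 1)
    key[i] <- paste(ix, iy)
  }
  counts <- list(); runs <- list()
  prev <- ""
  for (i in seq_len(nrow(s))) {
    k <- key[i]
    counts[[k]] <- (counts[[k]] %||% 0) + 1
    if (k != prev) runs[[k]] <- (runs[[k]] %||% 0) + 1
    prev <- k
  }
  list(counts = unlist(counts), runs = unlist(runs),
       K_total = nx * ny)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

o_entropy <- function(counts, K_total) {
  if (length(counts) == 1) return(0)
  p <- counts / sum(counts)
  h <- 0
  for (pi_ in p) h <- h - pi_ * log(pi_)
  h / log(K_total)
}

o_landmark_events <- function(traj, env, radius) {
  s <- traj$samples
  sapply(seq_len(nrow(env$landmarks)), function(j) {
    lx <- env$landmarks$x[j]; ly <- env$landmarks$y[j]
    events <- 0; inside_prev <- FALSE
    for (i in seq_len(nrow(s))) {
      inside <- sqrt((s$x[i] - lx)^2 + (s$y[i] - ly)^2) < radius
      if (inside && !inside_prev) events <- events + 1
      inside_prev <- inside
    }
    events
  })
}

# cumulative-sum-of-wrapped-differences unwrap, via while-loop wrapping
o_heading_series <- function(traj, min_step) {
  s <- traj$samples
  out_step <- integer(0); out_t <- numeric(0); out_h <- numeric(0)
  prev_wrapped <- NULL; cum <- NULL
  for (i in 2:nrow(s)) {
    dx <- s$x[i] - s$x[i - 1]; dy <- s$y[i] - s$y[i - 1]
    if (sqrt(dx^2 + dy^2) < min_step) next
    h <- atan2(dy, dx)
    if (is.null(cum)) cum <- h
    else cum <- cum + o_wrap(h - prev_wrapped)
    prev_wrapped <- h
    out_step <- c(out_step, i - 1)
    out_t <- c(out_t, s$t[i])
    out_h <- c(out_h, cum)
  }
  list(step = out_step, t = out_t, heading = out_h)
}

# windowed cumulative-turn scan with reset; linear search for the window
# start (independent of the package's two-pointer version)
o_turnaround_steps <- function(hs, turn_window, tol = 1e-8) {
  n <- length(hs$t)
  ev <- integer(0)
  reset <- 1
  if (n < 2) return(ev)
  for (i in 2:n) {
    s <- reset
    while (s < i && hs$t[i] - hs$t[s] > turn_window) s <- s + 1
    if (abs(hs$heading[i] - hs$heading[s]) >= pi - tol) {
      ev <- c(ev, hs$step[i])
      reset <- i
    }
  }
  ev
}

o_turnarounds <- function(traj, cfg) {
  hs <- o_heading_series(traj, cfg$min_step)
  length(o_turnaround_steps(hs, cfg$turn_window))
}

# chord-stepping divider walk, quadratic crossing solved per segment
o_divider_count <- function(x, y, delta) {
  n <- length(x)
  px <- x[1]; py <- y[1]
  sx <- x[1]; sy <- y[1]
  count <- 0; j <- 2
  while (j <= n) {
    de <- sqrt((x[j] - px)^2 + (y[j] - py)^2)
    if (de < delta) {
      sx <- x[j]; sy <- y[j]; j <- j + 1
      next
    }
    ux <- x[j] - sx; uy <- y[j] - sy
    wx <- sx - px; wy <- sy - py
    a <- ux^2 + uy^2
    b <- 2 * (wx * ux + wy * uy)
    cc <- wx^2 + wy^2 - delta^2
    t <- if (a <= 0) 0 else {
      max(min((-b + sqrt(max(b^2 - 4 * a * cc, 0))) / (2 * a), 1), 0)
    }
    px <- sx + t * ux; py <- sy + t * uy
    sx <- px; sy <- py
    count <- count + 1
  }
  count + sqrt((x[n] - px)^2 + (y[n] - py)^2) / delta
}

o_fractal_dimension <- function(traj, scales) {
  s <- traj$samples
  lx <- log(scales)
  ly <- log(sapply(scales, function(d) o_divider_count(s$x, s$y, d)))
  ok <- is.finite(ly)
  lx <- lx[ok]; ly <- ly[ok]
  d <- -sum((lx - mean(lx)) * (ly - mean(ly))) / sum((lx - mean(lx))^2)
  min(max(d, 1), 2)
}

o_sinuosity <- function(traj, cfg) {
  s <- traj$samples
  mask <- o_pause_mask(traj, cfg)
  lens <- numeric(0); heads <- numeric(0)
  for (i in 2:nrow(s)) {
    dx <- s$x[i] - s$x[i - 1]; dy <- s$y[i] - s$y[i - 1]
    l <- sqrt(dx^2 + dy^2)
    if (mask[i - 1] || l < cfg$min_step) next
    lens <- c(lens, l); heads <- c(heads, atan2(dy, dx))
  }
  if (length(lens) < 3) return(NA_real_)
  turns <- numeric(length(heads) - 1)
  for (i in seq_along(turns)) turns[i] <- o_wrap(heads[i + 1] - heads[i])
  cc <- mean(cos(turns))
  if (cc >= 1 - 1e-9) return(0)
  p <- mean(lens)
  b <- sd(lens) / p
  2 / sqrt(p * (1 + cc) / (1 - cc) + b^2)
}

# explicit flight segmentation: split moving runs at pauses and after
# turnaround events, merge short segments left-to-right, lift headings
o_flight_turnarounds <- function(traj, cfg, tol = 1e-8) {
  s <- traj$samples
  n_steps <- nrow(s) - 1
  mask <- o_pause_mask(traj, cfg)
  hs <- o_heading_series(traj, cfg$min_step)
  ev <- o_turnaround_steps(hs, cfg$turn_window)
  segs <- list()
  cur <- NULL
  for (i in seq_len(n_steps)) {
    if (mask[i]) { if (!is.null(cur)) { segs <- c(segs, list(cur)); cur <- NULL }; next }
    cur <- c(cur, i)
    if (i %in% ev) { segs <- c(segs, list(cur)); cur <- NULL }
  }
  if (!is.null(cur)) segs <- c(segs, list(cur))
  if (length(segs) == 0) return(0)
  seg_len <- function(idx) {
    tot <- 0
    for (i in idx) tot <- tot + sqrt((s$x[i + 1] - s$x[i])^2 +
                                       (s$y[i + 1] - s$y[i])^2)
    tot
  }
  lens <- sapply(segs, seg_len)
  repeat {
    short <- which(lens < cfg$flight_min_len)
    if (!length(short) || length(segs) == 1) break
    i <- short[1]
    j <- if (i > 1) i - 1 else i + 1
    segs[[j]] <- sort(c(segs[[j]], segs[[i]]))
    lens[j] <- lens[j] + lens[i]
    segs[[i]] <- NULL; lens <- lens[-i]
  }
  lifted <- sapply(segs, function(idx) {
    a <- min(idx); b <- max(idx)
    th <- atan2(s$y[b + 1] - s$y[a], s$x[b + 1] - s$x[a])
    mem <- hs$heading[hs$step >= a & hs$step <= b]
    if (!length(mem)) return(th)
    th + 2 * pi * round((mean(mem) - th) / (2 * pi))
  })
  if (length(lifted) < 2) return(0)
  sum(abs(diff(lifted)) >= pi - tol)
}

# O(n^3) agglomerative average linkage over a dissimilarity matrix;
# returns the merge heights in order
o_average_linkage_heights <- function(d) {
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- Inf; bi <- bj <- 0
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        tot <- 0; cnt <- 0
        for (a in clusters[[i]]) for (b in clusters[[j]]) {
          tot <- tot + d[a, b]; cnt <- cnt + 1
        }
        avg <- tot / cnt
        if (avg < best) { best <- avg; bi <- i; bj <- j }
      }
    }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  heights
}

o_average_linkage_partition <- function(d, k) {
  clusters <- as.list(seq_len(nrow(d)))
  while (length(clusters) > k) {
    best <- Inf; bi <- bj <- 0
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        tot <- 0; cnt <- 0
        for (a in clusters[[i]]) for (b in clusters[[j]]) {
          tot <- tot + d[a, b]; cnt <- cnt + 1
        }
        avg <- tot / cnt
        if (avg < best) { best <- avg; bi <- i; bj <- j }
      }
    }
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  lapply(clusters, sort)
}
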