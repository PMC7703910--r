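# Shared fixtures and independent oracle implementations used across tests.
# Oracles are deliberately written in a different style from the package
# internals (per-element loops, rectangle geometry) so agreement is evidence,
# not tautology.

# -- fix sequence builders ---------------------------------------------------

make_fixes <- function(x, y, start = "2015-03-01 00:00:00",
                       interval_hours = 1) {
  t0 <- as.POSIXct(start, tz = "UTC")
  data.frame(timestamp = t0 + (seq_along(x) - 1) * interval_hours * 3600,
             x = x, y = y)
}

# A square contour centered at (0, 0) with the given half-width, built from
# grid cells (cell size 100 m).
square_contour <- function(half_width = 500, cell = 100) {
  n <- 2 * half_width / cell
  g <- grid_spec(-half_width, -half_width, cell, n, n)
  cells <- as.matrix(expand.grid(row = 1:n, col = 1:n))
  hr_contour(g, cells)
}

# -- brute-force geometry oracles --------------------------------------------

# Membership by looping over member cells with explicit half-open bounds.
oracle_in_contour <- function(px, py, contour) {
  g <- contour$grid
  cs <- g$cell_size
  out <- logical(length(px))
  for (i in seq_along(px)) {
    for (k in seq_len(nrow(contour$cells))) {
      r <- contour$cells[k, 1]; c <- contour$cells[k, 2]
      x0 <- g$origin_x + (c - 1) * cs
      y0 <- g$origin_y + (r - 1) * cs
      if (px[i] >= x0 && px[i] < x0 + cs &&
          py[i] >= y0 && py[i] < y0 + cs) {
        out[i] <- TRUE
        break
      }
    }
  }
  out
}

# Distance to the union of closed member cells: min over cells of the
# point-to-rectangle distance (equals distance to the union's boundary for
# exterior points).
oracle_dist_contour <- function(px, py, contour) {
  g <- contour$grid
  cs <- g$cell_size
  out <- numeric(length(px))
  for (i in seq_along(px)) {
    best <- Inf
    for (k in seq_len(nrow(contour$cells))) {
      r <- contour$cells[k, 1]; c <- contour$cells[k, 2]
      x0 <- g$origin_x + (c - 1) * cs
      y0 <- g$origin_y + (r - 1) * cs
      dx <- max(x0 - px[i], 0, px[i] - (x0 + cs))
      dy <- max(y0 - py[i], 0, py[i] - (y0 + cs))
      best <- min(best, sqrt(dx^2 + dy^2))
    }
    out[i] <- best
  }
  out
}

# Smallest descending-mass prefix reaching `level`, by exhaustive scan.
oracle_contour_cells <- function(mass, level) {
  df <- data.frame(m = as.vector(mass),
                   row = as.vector(row(mass)), col = as.vector(col(mass)))
  df <- df[order(-df$m, df$row, df$col), ]
  cum <- 0
  k <- 0
  while (cum < level - 1e-12) {
    k <- k + 1
    cum <- cum + df$m[k]
  }
  df[seq_len(k), c("row", "col")]
}

# Independent row-by-row EHRM scan implementing the bracketing rule.
oracle_detect <- function(fixes, contour, min_points = 3, min_distance = 500) {
  inside <- oracle_in_contour(fixes$x, fixes$y, contour)
  n <- length(inside)
  res <- list()
  i <- 1
  while (i <= n) {
    if (inside[i]) { i <- i + 1; next }
    j <- i
    while (j < n && !inside[j + 1]) j <- j + 1
    s <- i - 1; e <- j + 1
    d <- oracle_dist_contour(fixes$x[i:j], fixes$y[i:j], contour)
    closed <- s >= 1 && e <= n
    n_fixes <- (j - i + 1) + (s >= 1) + (e <= n)
    need <- if (closed) min_points else min_points - 1
    if (n_fixes >= need && max(d) >= min_distance)
      res[[length(res) + 1]] <- data.frame(
        start_idx = max(s, i), end_idx = min(e, n),
        n_fixes = n_fixes, max_distance_m = max(d),
        open_ended = e > n, open_start = s < 1)
    i <- j + 1
  }
  if (length(res)) do.call(rbind, res) else NULL
}

# -- random EHRM tables for the criteria engine ------------------------------

random_ehrms <- function(n, seed) {
  set.seed(seed)
  t0 <- as.POSIXct("2015-03-01", tz = "UTC")
  s <- t0 + sort(runif(n, 0, 300 * 86400))
  dur <- runif(n, 2, 80)
  data.frame(animal_id = "a", method = "moving_window",
             start_time = s, end_time = s + dur * 3600,
             initiation_time = s + 3600,
             n_fixes = sample(3:40, n, replace = TRUE),
             max_distance_m = exp(runif(n, log(300), log(9000))),
             duration_h = dur,
             open_ended = FALSE, open_start = FALSE,
             start_idx = 1L, end_idx = 2L)
}
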