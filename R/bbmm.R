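# Brownian bridge movement model: utilization distribution on a grid and
# 95% isopleth contour extraction.
#
# Per-cell mass is the time-weighted integral, over every consecutive-fix
# bridge, of the bridge's isotropic Gaussian density: mean linearly
# interpolated between the bridge endpoints; variance at interior fraction
# a of an elapsed-time-T bridge
#     sigma2_m * T * a * (1 - a) + delta^2 * (1 - a)^2 + delta^2 * a^2
# with sigma2_m the Brownian motion variance (m^2/s) and delta the telemetry
# error SD (m).  Bridges spanning time gaps longer than max_gap are skipped.

#' BBMM parameters
#'
#' @param sigma2_m Brownian motion variance in m^2/s (estimate with
#'   [estimate_sigma2m()]).
#' @param delta telemetry error SD in meters (default 15).
#' @param max_gap longest bridge to integrate, in seconds; consecutive fixes
#'   farther apart contribute nothing.  Default `Inf`; drivers set it to 8x
#'   the median fix interval.
#' @return list of class `bbmm_params`.
#' @export
bbmm_params <- function(sigma2_m, delta = 15, max_gap = Inf) {
  stopifnot(sigma2_m >= 0, delta >= 0, max_gap > 0)
  structure(list(sigma2_m = sigma2_m, delta = delta, max_gap = max_gap),
            class = "bbmm_params")
}

#' Grid specification for the utilization distribution
#'
#' Cells are half-open squares `[x0, x0 + s) x [y0, y0 + s)`; cell (1, 1) has
#' its lower-left corner at the origin, rows advance in y, columns in x.
#'
#' @param origin_x,origin_y lower-left corner in meters.
#' @param cell_size cell edge length in meters (default 100).
#' @param n_cols,n_rows grid dimensions.
#' @return list of class `ehrm_grid`.
#' @export
grid_spec <- function(origin_x, origin_y, cell_size = 100, n_cols, n_rows) {
  stopifnot(cell_size > 0, n_cols >= 1, n_rows >= 1)
  structure(list(origin_x = origin_x, origin_y = origin_y,
                 cell_size = cell_size,
                 n_cols = as.integer(n_cols), n_rows = as.integer(n_rows)),
            class = "ehrm_grid")
}

.grid_x_centers <- function(g) g$origin_x + (seq_len(g$n_cols) - 0.5) * g$cell_size
.grid_y_centers <- function(g) g$origin_y + (seq_len(g$n_rows) - 0.5) * g$cell_size

#' Fit a grid around a set of fixes
#'
#' The extent is the bounding box of the fixes buffered by
#' `max(3 * sqrt(sigma2_m * T_max / 4 + delta^2), 5 * cell_size)` where T_max
#' is the longest usable bridge, snapped outward to cell multiples, so that
#' effectively all bridge mass falls on the grid.
#'
#' @param x,y fix coordinates (meters).
#' @param cell_size cell edge (default 100 m).
#' @param params [bbmm_params()] used for the buffer width.
#' @param t_max longest usable bridge duration in seconds (0 if unknown).
#' @return an `ehrm_grid`.
#' @export
fit_grid <- function(x, y, cell_size = 100, params = bbmm_params(0), t_max = 0) {
  buf <- max(3 * sqrt(params$sigma2_m * t_max / 4 + params$delta^2),
             5 * cell_size)
  x0 <- floor((min(x) - buf) / cell_size) * cell_size
  y0 <- floor((min(y) - buf) / cell_size) * cell_size
  nc <- ceiling((max(x) + buf - x0) / cell_size)
  nr <- ceiling((max(y) + buf - y0) / cell_size)
  grid_spec(x0, y0, cell_size, nc, nr)
}

.bridges <- function(fixes, max_gap) {
  n <- nrow(fixes)
  if (n < 2) return(NULL)
  tt <- as.numeric(fixes$timestamp)
  dt <- diff(tt)
  use <- dt > 0 & dt <= max_gap
  if (!any(use)) return(NULL)
  i <- which(use)
  list(x0 = fixes$x[i], y0 = fixes$y[i], x1 = fixes$x[i + 1],
       y1 = fixes$y[i + 1], T = dt[i])
}

#' Estimate the Brownian motion variance by leave-one-out likelihood
#'
#' Every second fix is predicted from its temporal neighbours: the observed
#' middle location of a triplet is modelled as Gaussian around the linear
#' interpolation of the bracketing fixes, with the bridge variance above.
#' The returned `sigma2_m` maximizes the product of these densities over a
#' bounded positive interval.
#'
#' @param fixes fix data.frame (or `ehrm_traj`) with `x`, `y`, `timestamp`;
#'   at least 3 fixes.
#' @param delta telemetry error SD in meters.
#' @param max_gap skip triplets whose bracketing interval exceeds this
#'   (seconds).
#' @return sigma2_m in m^2/s (>= 0); 0 with a warning if all fixes coincide.
#' @export
estimate_sigma2m <- function(fixes, delta = 15, max_gap = Inf) {
  if (inherits(fixes, "ehrm_traj")) fixes <- fixes$fixes
  n <- nrow(fixes)
  if (n < 3) stop("need at least 3 fixes to estimate sigma2_m")
  tt <- as.numeric(fixes$timestamp)
  mid <- seq(2, n - 1, by = 2)
  Tt <- tt[mid + 1] - tt[mid - 1]
  ok <- Tt > 0 & Tt <= 2 * max_gap
  mid <- mid[ok]; Tt <- Tt[ok]
  if (!length(mid)) stop("no usable leave-one-out triplets")
  a <- (tt[mid] - tt[mid - 1]) / Tt
  mx <- fixes$x[mid - 1] + a * (fixes$x[mid + 1] - fixes$x[mid - 1])
  my <- fixes$y[mid - 1] + a * (fixes$y[mid + 1] - fixes$y[mid - 1])
  d2 <- (fixes$x[mid] - mx)^2 + (fixes$y[mid] - my)^2
  w <- Tt * a * (1 - a)                    # coefficient of sigma2_m
  err <- delta^2 * ((1 - a)^2 + a^2)
  if (all(d2 == 0) && delta == 0) {
    warning("all fixes coincide; sigma2_m = 0")
    return(0)
  }
  nll <- function(s2) {
    v <- s2 * w + err
    if (any(v <= 0)) return(Inf)
    sum(log(v) + d2 / (2 * v))             # isotropic bivariate normal, x2
  }
  upper <- max(d2 / pmax(w, 1e-12), 1e-6)
  opt <- stats::optimize(nll, c(0, upper), tol = upper * 1e-10)
  # check the boundary at 0 (optimize never evaluates exactly at endpoints)
  s2 <- if (nll(0) <= opt$objective) 0 else opt$minimum
  if (s2 == 0 && all(d2 == 0)) warning("all deviations zero; sigma2_m = 0")
  s2
}

#' Compute the BBMM utilization distribution on a grid
#'
#' Each usable bridge is integrated over time by the midpoint rule.  The
#' number of nodes is at least `max(10, ceiling(T / 300))` (one per five
#' minutes) and additionally scales with the bridge displacement relative to
#' the kernel width, because the integrand seen by a cell near the path is a
#' Gaussian bump of width about `delta / length` in bridge time; node
#' spacing below that width makes the midpoint rule effectively exact.  The
#' Gaussian density at each node is evaluated at all cell centers and
#' accumulated with weight proportional to the bridge's elapsed time, then
#' the whole surface is normalized to sum to one.
#'
#' @param fixes fix data.frame (or `ehrm_traj`) with `x`, `y`, `timestamp`.
#' @param grid an `ehrm_grid` covering the fixes.
#' @param params a `bbmm_params`.
#' @return object of class `ehrm_ud`: list with `grid`, `mass`
#'   (n_rows x n_cols matrix summing to 1), `params`, `period`, `n_fixes`.
#' @export
compute_ud <- function(fixes, grid, params) {
  if (inherits(fixes, "ehrm_traj")) fixes <- fixes$fixes
  stopifnot(inherits(grid, "ehrm_grid"), inherits(params, "bbmm_params"))
  br <- .bridges(fixes, params$max_gap)
  if (is.null(br)) stop("no usable bridges (check timestamps and max_gap)")
  len <- sqrt((br$x1 - br$x0)^2 + (br$y1 - br$y0)^2)
  sd_ref <- max(params$delta, sqrt(params$sigma2_m * max(br$T)) / 4, 1)
  nq <- pmin(pmax(10, ceiling(br$T / 300), ceiling(3 * len / sd_ref)), 2000)
  alpha <- unlist(lapply(nq, function(k) (seq_len(k) - 0.5) / k))
  idx <- rep(seq_along(nq), nq)
  w <- (br$T / nq)[idx]
  mux <- br$x0[idx] + alpha * (br$x1[idx] - br$x0[idx])
  muy <- br$y0[idx] + alpha * (br$y1[idx] - br$y0[idx])
  v <- params$sigma2_m * br$T[idx] * alpha * (1 - alpha) +
    params$delta^2 * ((1 - alpha)^2 + alpha^2)
  sdv <- sqrt(pmax(v, 1e-12))
  xc <- .grid_x_centers(grid)
  yc <- .grid_y_centers(grid)
  # mass[r, c] = sum_q w_q / v_q * phi((yc_r - muy_q)/sd_q) * phi((xc_c - mux_q)/sd_q)
  A <- stats::dnorm(sweep(outer(yc, muy, "-"), 2, sdv, "/"))
  A <- sweep(A, 2, w / v, "*")
  B <- stats::dnorm(sweep(outer(mux, xc, "-"), 1, sdv, "/"))
  mass <- A %*% B
  tot <- sum(mass)
  if (tot <= 0) stop("utilization distribution has zero mass on the grid")
  mass <- mass / tot
  structure(list(grid = grid, mass = mass, params = params,
                 period = range(fixes$timestamp), n_fixes = nrow(fixes)),
            class = "ehrm_ud")
}

#' @export
print.ehrm_ud <- function(x, ...) {
  cat("<ehrm_ud>", x$grid$n_rows, "x", x$grid$n_cols, "cells of",
      x$grid$cell_size, "m;", x$n_fixes, "fixes\n")
  invisible(x)
}

#' Home-range contour constructor
#'
#' Builds a contour object directly from a grid and a member-cell set.  Used
#' internally by [extract_contour()] and handy for constructing known
#' geometries in tests and worked examples.
#'
#' @param grid an `ehrm_grid`.
#' @param cells two-column integer matrix of (row, col) member cells.
#' @param level nominal isopleth level.
#' @param period optional time span the contour represents.
#' @param source `"fixed_period"` or `"prehr"`.
#' @return object of class `ehrm_contour`.
#' @export
hr_contour <- function(grid, cells, level = 0.95, period = NULL,
                       source = "fixed_period") {
  stopifnot(inherits(grid, "ehrm_grid"))
  cells <- matrix(as.integer(cells), ncol = 2,
                  dimnames = list(NULL, c("row", "col")))
  if (nrow(cells) == 0) stop("contour has no member cells")
  member <- matrix(FALSE, grid$n_rows, grid$n_cols)
  member[cells] <- TRUE
  structure(list(level = level, cells = cells, member = member, grid = grid,
                 boundary = .boundary_segments(member, grid),
                 period = period, source = source),
            class = "ehrm_contour")
}

# Exterior edges of the member-cell union as a 4-column segment matrix
# (x1, y1, x2, y2): edges not shared by two member cells.
.boundary_segments <- function(member, g) {
  nr <- nrow(member); nc <- ncol(member)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- member
  segs <- list()
  cs <- g$cell_size
  idx <- which(member, arr.ind = TRUE)
  r <- idx[, 1]; c <- idx[, 2]
  x0 <- g$origin_x + (c - 1) * cs; x1 <- x0 + cs
  y0 <- g$origin_y + (r - 1) * cs; y1 <- y0 + cs
  # neighbour lookup in padded matrix (offset +1)
  south <- !pad[cbind(r, c + 1)]
  north <- !pad[cbind(r + 2, c + 1)]
  west  <- !pad[cbind(r + 1, c)]
  east  <- !pad[cbind(r + 1, c + 2)]
  segs <- rbind(
    cbind(x0, y0, x1, y0)[south, , drop = FALSE],
    cbind(x0, y1, x1, y1)[north, , drop = FALSE],
    cbind(x0, y0, x0, y1)[west, , drop = FALSE],
    cbind(x1, y0, x1, y1)[east, , drop = FALSE])
  colnames(segs) <- c("x1", "y1", "x2", "y2")
  segs
}

#' Extract the isopleth contour of a utilization distribution
#'
#' The contour is the smallest prefix of cells, sorted by descending mass,
#' whose cumulative mass reaches `level`.  Ties are broken by ascending
#' (row, col) index so the result is bit-reproducible.  The geometry is the
#' union of the member cells (the grid resolution is the native precision).
#'
#' @param ud an `ehrm_ud`.
#' @param level isopleth level in (0, 1], default 0.95.
#' @param source provenance tag carried on the contour.
#' @return an `ehrm_contour`.
#' @export
extract_contour <- function(ud, level = 0.95, source = "fixed_period") {
  stopifnot(inherits(ud, "ehrm_ud"))
  if (!(level > 0 && level <= 1)) stop("level must be in (0, 1]")
  g <- ud$grid
  idx <- which(ud$mass >= 0, arr.ind = TRUE)      # all cells, (row, col)
  m <- ud$mass[idx]
  o <- order(-m, idx[, 1], idx[, 2])
  cum <- cumsum(m[o])
  k <- which(cum >= level - 1e-12)[1]
  if (is.na(k)) k <- length(o)
  cells <- idx[o[seq_len(k)], , drop = FALSE]
  hr_contour(g, cells, level = level, period = ud$period, source = source)
}

#' @export
print.ehrm_contour <- function(x, ...) {
  cat("<ehrm_contour>", nrow(x$cells), "cells at level", x$level,
    "; area", nrow(x$cells) * x$grid$cell_size^2 / 1e6, "km^2\n")
  invisible(x)
}

#' Contour area in square meters
#' @param contour an `ehrm_contour`.
#' @export
contour_area <- function(contour) nrow(contour$cells) * contour$grid$cell_size^2

#' Point-in-contour test
#'
#' Cells are half-open `[x0, x0+s) x [y0, y0+s)`, so points on shared edges
#' are assigned deterministically to the cell on their upper-right side.
#'
#' @param px,py point coordinates (vectors, meters, same CRS as the contour).
#' @param contour an `ehrm_contour`.
#' @return logical vector.
#' @export
point_in_contour <- function(px, py, contour) {
  g <- contour$grid
  col <- floor((px - g$origin_x) / g$cell_size) + 1
  row <- floor((py - g$origin_y) / g$cell_size) + 1
  ok <- col >= 1 & col <= g$n_cols & row >= 1 & row <= g$n_rows
  out <- logical(length(px))
  if (any(ok)) out[ok] <- contour$member[cbind(row[ok], col[ok])]
  out
}

#' Euclidean distance from points to the contour edge
#'
#' Zero for points inside the contour (or exactly on cell edges that are
#' inside under the half-open rule); otherwise the minimum distance to any
#' boundary segment of any patch of the (possibly disjoint) contour.
#'
#' @inheritParams point_in_contour
#' @return numeric vector of distances in meters.
#' @export
distance_to_contour <- function(px, py, contour) {
  inside <- point_in_contour(px, py, contour)
  d <- numeric(length(px))
  if (all(inside)) return(d)
  segs <- contour$boundary
  sx <- segs[, "x2"] - segs[, "x1"]
  sy <- segs[, "y2"] - segs[, "y1"]
  len2 <- sx^2 + sy^2
  for (i in which(!inside)) {
    tpar <- ((px[i] - segs[, "x1"]) * sx + (py[i] - segs[, "y1"]) * sy) / len2
    tpar <- pmin(pmax(tpar, 0), 1)
    dx <- segs[, "x1"] + tpar * sx - px[i]
    dy <- segs[, "y1"] + tpar * sy - py[i]
    d[i] <- sqrt(min(dx^2 + dy^2))
  }
  d
}

#' Export a contour as GeoJSON
#'
#' One Feature with a MultiPolygon of the member cells (each cell one
#' polygon ring); the CRS label and provenance are recorded as properties.
#'
#' @param contour an `ehrm_contour`.
#' @param path output file.
#' @param crs CRS descriptor written into the properties.
#' @export
contour_to_geojson <- function(contour, path, crs = "planar") {
  g <- contour$grid
  cs <- g$cell_size
  polys <- lapply(seq_len(nrow(contour$cells)), function(i) {
    r <- contour$cells[i, 1]; c <- contour$cells[i, 2]
    x0 <- g$origin_x + (c - 1) * cs; y0 <- g$origin_y + (r - 1) * cs
    list(list(list(x0, y0), list(x0 + cs, y0), list(x0 + cs, y0 + cs),
              list(x0, y0 + cs), list(x0, y0)))
  })
  obj <- list(type = "FeatureCollection", features = list(list(
    type = "Feature",
    properties = list(level = contour$level, source = contour$source,
                      crs = .crs_label(crs),
                      cell_size_m = cs),
    geometry = list(type = "MultiPolygon", coordinates = polys))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export a utilization distribution as CSV
#'
#' Writes one row per cell: `row`, `col`, `x_center`, `y_center`, `mass`.
#'
#' @param ud an `ehrm_ud`.
#' @param path output file.
#' @export
write_ud <- function(ud, path) {
  g <- ud$grid
  idx <- which(ud$mass >= 0, arr.ind = TRUE)
  df <- data.frame(row = idx[, 1], col = idx[, 2],
                   x_center = .grid_x_centers(g)[idx[, 2]],
                   y_center = .grid_y_centers(g)[idx[, 1]],
                   mass = ud$mass[idx])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
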