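# Brownian bridge UD estimation, contour extraction and contour geometry.

test_that("sigma2_m is recovered from pure Brownian motion", {
  set.seed(11)
  n <- 500
  dt <- 3600                       # 1-h steps
  s2_true <- 0.05                  # m^2/s
  x <- cumsum(c(0, rnorm(n - 1, 0, sqrt(s2_true * dt))))
  y <- cumsum(c(0, rnorm(n - 1, 0, sqrt(s2_true * dt))))
  fx <- make_fixes(x, y)
  est <- estimate_sigma2m(fx, delta = 0)
  expect_lt(abs(est - s2_true) / s2_true, 0.15)
})

test_that("degenerate sigma2_m inputs behave as specified", {
  fx <- make_fixes(rep(0, 10), rep(0, 10))
  expect_warning(est <- estimate_sigma2m(fx, delta = 0), "coincide")
  expect_equal(est, 0)
  # with telemetry error the coincident-fix estimate is still 0
  expect_warning(est15 <- estimate_sigma2m(fx, delta = 15), "zero")
  expect_equal(est15, 0)
  expect_error(estimate_sigma2m(make_fixes(0:1, 0:1), delta = 15),
               "at least 3")
})

test_that("UD mass is normalized and nonnegative for any valid input", {
  set.seed(12)
  for (k in 1:5) {
    fx <- make_fixes(cumsum(rnorm(30, 0, 150)), cumsum(rnorm(30, 0, 150)),
                     interval_hours = 3.5)
    par <- bbmm_params(sigma2_m = runif(1, 0.01, 0.5), delta = 15)
    g <- fit_grid(fx$x, fx$y, 100, par, 3.5 * 3600)
    ud <- compute_ud(fx, g, par)
    expect_lt(abs(sum(ud$mass) - 1), 1e-9)
    expect_true(all(ud$mass >= 0))
  }
})

test_that("per-cell masses match dense numerical quadrature on one bridge", {
  # single bridge across a coarse 5x5 grid, independent fine-step oracle
  fx <- make_fixes(c(120, 380), c(130, 310), interval_hours = 1)
  par <- bbmm_params(sigma2_m = 0.05, delta = 15)
  g <- grid_spec(0, 0, 100, 5, 5)
  ud <- compute_ud(fx, g, par)
  T <- 3600
  nq <- 40000
  a <- (seq_len(nq) - 0.5) / nq
  oracle <- matrix(0, 5, 5)
  for (r in 1:5) for (c in 1:5) {
    cx <- (c - 0.5) * 100; cy <- (r - 0.5) * 100
    mx <- 120 + a * (380 - 120); my <- 130 + a * (310 - 130)
    v <- par$sigma2_m * T * a * (1 - a) + par$delta^2 * ((1 - a)^2 + a^2)
    oracle[r, c] <- mean(exp(-((cx - mx)^2 + (cy - my)^2) / (2 * v)) /
                           (2 * pi * v))
  }
  oracle <- oracle / sum(oracle)
  expect_lt(max(abs(ud$mass - oracle)), 1e-4)
})

test_that("coincident endpoints with zero motion variance give a symmetric
           error kernel at the fix", {
  fx <- make_fixes(c(250, 250), c(250, 250), interval_hours = 1)
  par <- bbmm_params(sigma2_m = 0, delta = 30)
  g <- grid_spec(0, 0, 100, 5, 5)
  ud <- compute_ud(fx, g, par)
  expect_equal(which(ud$mass == max(ud$mass)), 13)  # central cell
  expect_equal(ud$mass, ud$mass[5:1, ], tolerance = 1e-12)  # symmetry
  expect_equal(ud$mass, t(ud$mass), tolerance = 1e-12)
})

test_that("bridge variance collapses to the squared telemetry error at the
           endpoints", {
  delta <- 15; s2 <- 0.3; T <- 12600
  v <- function(a) s2 * T * a * (1 - a) + delta^2 * ((1 - a)^2 + a^2)
  expect_equal(v(0), delta^2)
  expect_equal(v(1), delta^2)
})

test_that("contour is the minimal descending-mass prefix, ties broken by
           grid index", {
  set.seed(13)
  for (k in 1:3) {
    mass <- matrix(rexp(400), 20, 20)
    mass <- mass / sum(mass)
    ud <- structure(list(grid = grid_spec(0, 0, 100, 20, 20), mass = mass,
                         params = bbmm_params(0.1), period = NULL,
                         n_fixes = 0L), class = "ehrm_ud")
    ctr <- extract_contour(ud, 0.95)
    orc <- oracle_contour_cells(mass, 0.95)
    got <- ctr$cells[order(ctr$cells[, 1], ctr$cells[, 2]), ]
    want <- as.matrix(orc[order(orc$row, orc$col), ])
    dimnames(want) <- dimnames(got)
    expect_equal(got, want)
    # minimality: dropping the smallest member cell goes below the level
    msum <- sum(mass[ctr$cells])
    expect_gte(msum, 0.95)
    expect_lt(msum - min(mass[ctr$cells]), 0.95)
  }
})

test_that("uniform UD at level 0.95 keeps exactly 95 of 100 cells", {
  mass <- matrix(1 / 100, 10, 10)
  ud <- structure(list(grid = grid_spec(0, 0, 100, 10, 10), mass = mass,
                       params = bbmm_params(0), period = NULL, n_fixes = 0L),
                  class = "ehrm_ud")
  expect_equal(nrow(extract_contour(ud, 0.95)$cells), 95)
  ctr1 <- extract_contour(ud, 0.95)
  expect_equal(nrow(ctr1$cells) * 100^2, contour_area(ctr1))
  # one dominant cell
  mass2 <- matrix(0.04 / 99, 10, 10); mass2[5, 5] <- 0.96
  ud$mass <- mass2 / sum(mass2)
  expect_equal(unname(extract_contour(ud, 0.95)$cells[1, ]), c(5L, 5L))
  expect_equal(nrow(extract_contour(ud, 0.95)$cells), 1)
  expect_error(extract_contour(ud, 1.2), "level")
})

test_that("contour cell sets are nested in the level", {
  set.seed(14)
  mass <- matrix(rexp(100), 10, 10); mass <- mass / sum(mass)
  ud <- structure(list(grid = grid_spec(0, 0, 100, 10, 10), mass = mass,
                       params = bbmm_params(0), period = NULL, n_fixes = 0L),
                  class = "ehrm_ud")
  key <- function(cl) paste(cl[, 1], cl[, 2])
  c50 <- key(extract_contour(ud, 0.5)$cells)
  c80 <- key(extract_contour(ud, 0.8)$cells)
  c95 <- key(extract_contour(ud, 0.95)$cells)
  expect_true(all(c50 %in% c80))
  expect_true(all(c80 %in% c95))
})

test_that("UD is invariant under rigid translation of the fixes", {
  set.seed(15)
  fx <- make_fixes(cumsum(rnorm(20, 0, 120)), cumsum(rnorm(20, 0, 120)),
                   interval_hours = 1)
  par <- bbmm_params(0.1, delta = 15)
  g1 <- fit_grid(fx$x, fx$y, 100, par, 3600)
  ud1 <- compute_ud(fx, g1, par)
  fx2 <- fx; fx2$x <- fx$x + 5300; fx2$y <- fx$y - 2700  # cell multiples
  g2 <- grid_spec(g1$origin_x + 5300, g1$origin_y - 2700, 100,
                  g1$n_cols, g1$n_rows)
  ud2 <- compute_ud(fx2, g2, par)
  expect_equal(ud1$mass, ud2$mass, tolerance = 1e-12)
})

test_that("point membership matches the exhaustive per-cell check", {
  set.seed(16)
  mass <- matrix(rexp(225), 15, 15); mass <- mass / sum(mass)
  ud <- structure(list(grid = grid_spec(-700, -700, 100, 15, 15),
                       mass = mass, params = bbmm_params(0), period = NULL,
                       n_fixes = 0L), class = "ehrm_ud")
  ctr <- extract_contour(ud, 0.8)
  px <- runif(1000, -900, 1000)
  py <- runif(1000, -900, 1000)
  expect_identical(point_in_contour(px, py, ctr),
                   oracle_in_contour(px, py, ctr))
  # points exactly on shared edges are assigned deterministically
  edge <- point_in_contour(c(-700, -600), c(-700, -600), ctr)
  expect_identical(edge, oracle_in_contour(c(-700, -600), c(-700, -600), ctr))
})

test_that("distance to contour matches segment enumeration", {
  set.seed(17)
  mass <- matrix(rexp(225), 15, 15); mass <- mass / sum(mass)
  ud <- structure(list(grid = grid_spec(-700, -700, 100, 15, 15),
                       mass = mass, params = bbmm_params(0), period = NULL,
                       n_fixes = 0L), class = "ehrm_ud")
  ctr <- extract_contour(ud, 0.6)
  px <- runif(300, -3000, 3000)
  py <- runif(300, -3000, 3000)
  got <- distance_to_contour(px, py, ctr)
  want <- oracle_dist_contour(px, py, ctr)
  want[oracle_in_contour(px, py, ctr)] <- 0
  expect_lt(max(abs(got - want)), 1e-6)
  # zero distance exactly for inside-or-boundary points
  expect_true(all((got == 0) == (want == 0)))
})

test_that("a point due east of a rectangular contour is at the edge
           distance", {
  ctr <- square_contour(500)
  expect_equal(distance_to_contour(1000, 0, ctr), 500)
  expect_equal(distance_to_contour(0, 0, ctr), 0)
  expect_true(point_in_contour(0, 0, ctr))
  expect_false(point_in_contour(500, 0, ctr))  # half-open: on the east edge
})
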