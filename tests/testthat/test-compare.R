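# Availability filtering, pairing and the paired-distance contrast.

test_that("availability filter excludes first-PreHR and short-season
           detections", {
  sim <- simulate_trajectory(scenario_config("stationary", seed = 51))
  tr <- sim$traj
  mk <- function(day) {
    e <- random_ehrms(1, seed = day)
    t0 <- as.POSIXct("2015-03-01", tz = "UTC")
    e$initiation_time <- t0 + (day - 1) * 86400 + 6 * 3600
    e$start_time <- e$initiation_time - 3600
    e$end_time <- e$initiation_time + 5 * 3600
    e
  }
  # fixed-period EHRM on day 30 is inside the first 60-day PreHR
  f <- rbind(mk(30), mk(100))
  # the record is 130 days from 1 Mar: the summer segment (from 1 Jul,
  # day 123) holds < 60 days, so a moving EHRM there is unavailable to the
  # Fixed-Period method
  m <- rbind(mk(100), mk(126))
  av <- availability_filter(f, m, tr)
  expect_equal(nrow(av$fixed), 1)
  expect_equal(nrow(av$excluded_fixed), 1)
  expect_equal(av$excluded_fixed$initiation_time, f$initiation_time[1])
  expect_equal(nrow(av$moving), 1)
  expect_equal(av$excluded_moving$initiation_time, m$initiation_time[2])
  # partition: nothing lost or duplicated
  expect_equal(nrow(av$fixed) + nrow(av$excluded_fixed), nrow(f))
  expect_equal(nrow(av$moving) + nrow(av$excluded_moving), nrow(m))
})

test_that("identical detections pair; disjoint ones stay unique", {
  e <- random_ehrms(3, seed = 52)
  m <- match_ehrms(e[1, ], e[1, ])
  expect_equal(nrow(m$paired), 1)
  expect_equal(nrow(m$unique_fixed), 0)
  m2 <- match_ehrms(e[1, ], e[3, ])   # far apart in time
  expect_equal(nrow(m2$paired), 0)
  expect_equal(nrow(m2$unique_fixed), 1)
  expect_equal(nrow(m2$unique_moving), 1)
})

test_that("greedy interval pairing attains the optimal pair count on small
           random sets", {
  # exhaustive optimal matching oracle over all injections
  optimal_pairs <- function(fs, fe, ms, me) {
    nf <- length(fs); nm <- length(ms)
    best <- 0
    idx <- seq_len(nm)
    rec <- function(i, used, count) {
      if (i > nf) { best <<- max(best, count); return() }
      rec(i + 1, used, count)
      for (j in idx[!used]) {
        if (ms[j] <= fe[i] && me[j] >= fs[i]) {
          used[j] <- TRUE
          rec(i + 1, used, count + 1)
          used[j] <- FALSE
        }
      }
    }
    rec(1, rep(FALSE, nm), 0)
    best
  }
  for (seed in 53:57) {
    set.seed(seed)
    t0 <- as.POSIXct("2015-03-01", tz = "UTC")
    mk <- function(n) {
      s <- t0 + sort(runif(n, 0, 40)) * 86400
      e <- s + runif(n, 0.5, 8) * 86400
      ehrm <- random_ehrms(n, seed = seed + 100)
      ehrm$start_time <- s; ehrm$end_time <- e
      ehrm$initiation_time <- s + 3600
      ehrm
    }
    f <- mk(sample(3:7, 1)); m <- mk(sample(3:7, 1))
    got <- match_ehrms(f, m)
    want <- optimal_pairs(as.numeric(f$start_time), as.numeric(f$end_time),
                          as.numeric(m$start_time), as.numeric(m$end_time))
    expect_equal(nrow(got$paired), want)
    # symmetry of the pair count
    expect_equal(nrow(match_ehrms(m, f)$paired), want)
    # partition of both inputs
    expect_equal(nrow(got$paired) + nrow(got$unique_fixed), nrow(f))
    expect_equal(nrow(got$paired) + nrow(got$unique_moving), nrow(m))
  }
})

test_that("the paired t statistic matches a hand computation", {
  pairs <- data.frame(fixed_distance_m = c(700, 900, 1200, 1500, 600),
                      moving_distance_m = c(800, 950, 1250, 1700, 580),
                      fixed_duration_h = 1:5, moving_duration_h = 1:5)
  s <- paired_distance_summary(pairs)
  d <- pairs$moving_distance_m - pairs$fixed_distance_m
  expect_equal(s$mean_difference_m, mean(d), tolerance = 1e-12)
  expect_equal(s$t_statistic, mean(d) / (sd(d) / sqrt(5)), tolerance = 1e-9)
  expect_equal(s$df, 4)
  expect_equal(s$mean_percent_difference,
               100 * mean(d) / mean(pairs$fixed_distance_m),
               tolerance = 1e-12)
  # cross-check against the standard paired t test
  tt <- t.test(pairs$moving_distance_m, pairs$fixed_distance_m,
               paired = TRUE)
  expect_equal(s$t_statistic, unname(tt$statistic), tolerance = 1e-9)
  expect_equal(s$p_value, tt$p.value, tolerance = 1e-9)
})

test_that("identical paired metrics give a zero difference with a warning", {
  pairs <- data.frame(fixed_distance_m = c(700, 900),
                      moving_distance_m = c(700, 900) + 50,
                      fixed_duration_h = 1:2, moving_duration_h = 1:2)
  expect_warning(s <- paired_distance_summary(pairs), "identical")
  expect_equal(s$t_statistic, 0)
  expect_error(paired_distance_summary(pairs[1, ]), "at least 2")
})

test_that("the comparison table buckets unique EHRMs into distance bands", {
  f <- random_ehrms(6, seed = 58)
  m <- random_ehrms(8, seed = 59)
  f$max_distance_m <- c(600, 800, 900, 1200, 2000, 700)
  m$max_distance_m <- c(600, 800, 900, 1200, 2000, 700, 5000, 550)
  av <- list(fixed = f, moving = m)
  mt <- match_ehrms(f, m)
  tab <- method_comparison_table(f, m, av, mt)
  expect_equal(tab$fixed_n[1], 6)
  expect_equal(tab$moving_n[1], 8)
  expect_equal(tab$fixed_n[3] , nrow(mt$unique_fixed))
  expect_equal(tab$moving_n[4] + tab$moving_n[5], tab$moving_n[3])
})
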