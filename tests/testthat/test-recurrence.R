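test_that("a noiseless circle is recurrent everywhere at one period minus the ball width", {
  orb <- spiral_trajectory(period = 10, duration = 60, dt = 0.01)
  rec <- find_recurrence(orb$P, t = orb$t, scan = c(5, 50))
  expect_true(all(rec$recurrent))
  ## delta = period minus the one-sided contiguous-run width: the first
  ## return enters the theta-ball one ball transit early
  w <- (10 / pi) * asin(rec$theta / 2)   # chord -> arc time at radius 1
  expect_equal(mean(rec$delta), 10 - w, tolerance = 0.005)
  expect_lt(diff(range(rec$delta)), 0.03)
  ## and the detected orbit period is within one histogram bin of the truth
  rec <- detect_periodic_orbit(rec)
  expect_lt(abs(rec$period - 10), 1)
})

test_that("a straight line has no recurrent points", {
  P <- cbind(seq(0, 100, by = 0.01), 0)
  rec <- find_recurrence(P, t = seq(0, 100, by = 0.01) / 10, scan = c(1, 8))
  expect_false(any(rec$recurrent))
})

test_that("recurrence flags and delays match the brute-force reference exactly", {
  set.seed(11)
  tt <- seq(0, 18, by = 0.01)
  P <- cbind(cos(2 * pi * tt / 4), sin(2 * pi * tt / 4)) * (1 + 0.05 * rnorm(length(tt)))
  rec <- find_recurrence(P, t = tt, scan = c(2, 7))
  idx <- which(tt >= 2 & tt <= 7)
  expect_equal(rec$theta, bf_theta(P[idx, ], 10), tolerance = 1e-10)
  bf <- bf_recurrence(P, rec$theta, idx)
  expect_identical(rec$recurrent, !is.na(bf))
  expect_equal(rec$delta, bf * 0.01, tolerance = 1e-12)
  ## and after the minimum-delay re-scan
  rec2 <- detect_periodic_orbit(rec, min_delay = 2, min_peak_points = 10)
  bf2 <- bf_recurrence(P, rec$theta, idx, min_steps = 200)
  expect_identical(rec2$recurrent, !is.na(bf2))
  expect_equal(rec2$delta, bf2 * 0.01, tolerance = 1e-12)
})

test_that("the recurrent set only grows with the threshold percentile", {
  set.seed(12)
  tt <- seq(0, 30, by = 0.01)
  P <- cbind(cos(2 * pi * tt / 6), sin(2 * pi * tt / 6)) * (1 + 0.1 * rnorm(length(tt)))
  r5 <- find_recurrence(P, t = tt, scan = c(3, 20), theta_percentile = 5)
  r10 <- find_recurrence(P, t = tt, scan = c(3, 20), theta_percentile = 10)
  expect_lt(r5$theta, r10$theta)
  expect_true(all(r10$recurrent[r5$recurrent]))
})

test_that("orbit detection follows the histogram rules", {
  set.seed(13)
  ## 1000 delays uniform in [9.5, 10.5] plus 80 at 20 s
  delta <- c(runif(1000, 9.5, 10.5), rep(20, 80))
  rec <- fake_recurrence(sample(delta))
  rec <- detect_periodic_orbit(rec, bin = 1, min_delay = 5, min_peak_points = 100)
  expect_equal(nrow(rec$peaks[rec$peaks$n_points > 100, ]), nrow(rec$peaks))
  expect_equal(nrow(rec$peaks), 1)            # the 80-point peak fails the cut
  expect_equal(rec$period, 10, tolerance = 0.05)
  ## delays all below the exclusion floor leave the program aperiodic
  rec2 <- detect_periodic_orbit(fake_recurrence(runif(500, 1, 4)))
  expect_true(is.na(rec2$dominant))
  expect_true(is.na(rec2$period))
  ## dominant-peak tie resolves to the smaller mean delay
  d3 <- c(runif(300, 6, 6.9), runif(300, 12, 12.9))
  rec3 <- detect_periodic_orbit(fake_recurrence(d3), min_peak_points = 100)
  expect_equal(rec3$peaks$n_points[rec3$dominant],
               max(rec3$peaks$n_points))
  expect_lt(rec3$period, 8)
})

test_that("window density reflects the recurrent fraction", {
  delta <- rep(c(10, NA), 500)
  rec <- fake_recurrence(delta, dt = 0.05)
  dens <- window_density(rec, win = 5, step = 1)
  expect_true(all(abs(dens$density - 0.5) < 0.02))
  rec_all <- fake_recurrence(rep(10, 1000), dt = 0.05)
  dens_all <- window_density(rec_all, win = 5, step = 1)
  expect_true(all(dens_all$density == 1))
  expect_true(all(dens_all$mean_delay == 10))
})

test_that("coalescence is the midpoint of the first dense window", {
  delta <- c(rep(NA, 600), rep(10, 1400))   # recurrent from t = 30 s at dt 0.05
  rec <- fake_recurrence(delta, dt = 0.05)
  dens <- window_density(rec, win = 5, step = 1)
  co <- coalescence_time(dens, threshold = 0.9)
  expect_equal(co, dens$win_mid[which(dens$density >= 0.9)[1]])
  expect_gte(co, 30)
  expect_lte(co, 35)
  ## immediately dense series coalesces at the first window
  dens1 <- window_density(fake_recurrence(rep(8, 1000), dt = 0.05))
  expect_equal(coalescence_time(dens1), dens1$win_mid[1])
  ## never-dense series yields NA
  expect_true(is.na(coalescence_time(window_density(
    fake_recurrence(rep(c(10, NA, NA), 400), dt = 0.05)))))
})

test_that("perturbation events follow the density thresholds and horizon rule", {
  ## recurrent everywhere except a deep dip around t = 30-38 s
  n <- 2000; dt <- 0.05
  tt <- (seq_len(n) - 1) * dt
  delta <- rep(10, n)
  delta[tt >= 30 & tt < 38] <- NA
  ## points just before the dip recur only after it ends (the orbit resumes)
  pre <- tt >= 20 & tt < 30
  delta[pre] <- 45 - tt[pre]
  rec <- fake_recurrence(delta, dt = dt)
  dens <- window_density(rec)
  ev <- detect_perturbations(rec, dens, period = 10, coalescence = 5)
  expect_equal(nrow(ev), 1)
  expect_lt(ev$span_lo, 33)
  expect_gt(ev$span_hi, 35)
  expect_equal(ev$outcome, "returned_same")   # pre-dip delays span the dip
  ## a dip ending at the recording edge is dropped by the two-cycle rule
  delta2 <- rep(10, n)
  delta2[tt >= 85] <- NA
  rec2 <- fake_recurrence(delta2, dt = dt)
  ev2 <- detect_perturbations(rec2, window_density(rec2), period = 10,
                              coalescence = 5)
  expect_equal(nrow(ev2), 0)
  ## a dip with no recovery is not_returned
  delta3 <- rep(10, n)
  delta3[tt >= 60] <- NA
  delta3[tt >= 50 & tt < 60] <- rep(c(10, NA), length.out = sum(tt >= 50 & tt < 60))
  rec3 <- fake_recurrence(delta3, dt = dt)
  ev3 <- detect_perturbations(rec3, window_density(rec3), period = 2,
                              coalescence = 5)
  expect_true(nrow(ev3) >= 1)
  expect_equal(ev3$outcome[nrow(ev3)], "not_returned")
})
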