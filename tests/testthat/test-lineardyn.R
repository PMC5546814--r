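## trajectory of the exact per-step linear map x <- M x
linmap_traj <- function(M, n = 4000, x0 = c(1, 0)) {
  X <- matrix(NA_real_, n, 2)
  X[1, ] <- x0
  for (k in 2:n) X[k, ] <- M %*% X[k - 1, ]
  X
}

test_that("local fits recover a known per-step linear map exactly", {
  rot <- 0.00628
  M <- 0.9995 * matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2)
  X <- linmap_traj(M)
  ev_true <- eigen(M)$values[1] - 1    # oracle: generating map minus identity
  f <- fit_local_linear(X, 2000, theta = 0.4)
  expect_true(f$valid)
  expect_equal(Re(f$eigvals[1]), Re(ev_true), tolerance = abs(Re(ev_true)) * 0.01)
  expect_equal(abs(Im(f$eigvals[1])), abs(Im(ev_true)),
               tolerance = abs(Im(ev_true)) * 0.01)
  ## and the oracle lands at the expected order: a ~ -5e-4, b ~ 6.28e-3
  expect_equal(Re(ev_true), -0.0005, tolerance = 0.05)
  expect_equal(abs(Im(ev_true)), 0.00628, tolerance = 0.001)
})

test_that("recovery holds across random stable rotating maps", {
  errs <- sapply(1:20, function(s) {
    set.seed(s)
    rot <- runif(1, 0.002, 0.02)
    mod <- runif(1, 0.995, 0.9999)
    M <- mod * matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2)
    X <- linmap_traj(M)
    ev <- eigen(M)$values[1] - 1
    f <- fit_local_linear(X, 2000, theta = 0.4)
    Xn <- X + matrix(rnorm(length(X), 0, 0.05 * sd(X)), nrow(X))
    bs <- sapply(seq(500, 3500, by = 250), function(a) {
      fn <- fit_local_linear(Xn, a, theta = 0.4)
      if (fn$valid) abs(Im(fn$eigvals[1])) else NA
    })
    c(abs(Re(f$eigvals[1]) - Re(ev)) / abs(Re(ev)),
      abs(abs(Im(f$eigvals[1])) - abs(Im(ev))) / abs(Im(ev)),
      abs(mean(bs, na.rm = TRUE) - abs(Im(ev))) / abs(Im(ev)))
  })
  expect_lt(max(errs[1, ]), 0.02)       # noiseless: within 2%
  expect_lt(max(errs[2, ]), 0.02)
  expect_lt(median(errs[3, ]), 0.10)    # rotation robust at 5% noise
})

test_that("degenerate neighbourhoods are flagged invalid", {
  X <- matrix(1, 500, 2)
  f <- fit_local_linear(X, 250, theta = 1)
  expect_false(f$valid)
  ## a 1-D line embedded in 2-D is rank deficient
  X2 <- cbind(seq(0, 1, length.out = 500), 0.5)
  f2 <- fit_local_linear(X2, 250, theta = 10)
  expect_false(f2$valid)
})

test_that("attractor summary converts eigenvalues to period and contraction", {
  ## decaying latent spiral with known parameters, via the full chain
  orb <- spiral_trajectory(period = 10, contraction_per_s = 0.98,
                           duration = 95, dt = 0.01)
  rec <- detect_periodic_orbit(find_recurrence(orb$P, t = orb$t, scan = c(5, 85)))
  anchors <- seq(rec$scan[1], rec$scan[2])[rec$recurrent]
  anchors <- anchors[seq(1, length(anchors), by = 10)]
  att <- summarize_attractor(local_linear_fits(orb$P, anchors, rec$theta), rec)
  expect_equal(att$classification, "stable_spiral")
  expect_equal(att$period_est, 10, tolerance = 0.05 * 10)
  expect_equal(att$contraction_pct_per_s, 98, tolerance = 0.5)
  expect_gt(att$rotation_fraction, 0.95)
  ## estimates are invariant to an orthogonal rotation of the axes
  set.seed(20)
  th <- runif(1, 0, 2 * pi)
  Q <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  attQ <- summarize_attractor(local_linear_fits(orb$P %*% Q, anchors, rec$theta),
                              rec)
  expect_equal(attQ$period_est, att$period_est, tolerance = 1e-6)
  expect_equal(attQ$contraction_pct_per_s, att$contraction_pct_per_s,
               tolerance = 1e-6)
})

test_that("a non-decaying limit cycle reads as ~100% contraction", {
  orb <- spiral_trajectory(period = 10, contraction_per_s = 1,
                           duration = 95, dt = 0.01)
  rec <- detect_periodic_orbit(find_recurrence(orb$P, t = orb$t, scan = c(5, 85)))
  anchors <- seq(rec$scan[1], rec$scan[2])[rec$recurrent]
  anchors <- anchors[seq(1, length(anchors), by = 10)]
  att <- summarize_attractor(local_linear_fits(orb$P, anchors, rec$theta), rec)
  expect_lt(abs(att$contraction_pct_per_s - 100), 0.5)
})

test_that("nodes are classified from real eigenvalue spectra", {
  ## contracting node trajectory; recurrence is faked so the summary runs
  M <- diag(c(0.999, 0.997))
  X <- linmap_traj(M, n = 3000, x0 = c(1, 1))
  rec <- fake_recurrence(rep(10, 3000))
  rec <- detect_periodic_orbit(rec, min_peak_points = 100)
  fits <- local_linear_fits(X, seq(200, 2800, by = 100), theta = 0.4)
  att <- summarize_attractor(fits, rec)
  expect_equal(att$classification, "stable_node")
  expect_true(is.na(att$period_est))
  expect_lt(att$a_mean, 0)
})

test_that("weighted Spearman reduces to Spearman and obeys symmetry", {
  set.seed(21)
  x <- rnorm(30)
  y <- rnorm(30)
  expect_equal(weighted_spearman(x, y, rep(1, 30)),
               cor(x, y, method = "spearman"), tolerance = 1e-12)
  expect_equal(weighted_spearman(x, 2 * x^3 + 5), 1)
  expect_equal(weighted_spearman(x, y), -weighted_spearman(x, -y),
               tolerance = 1e-12)
  ## 6-point weighted case against the written-out formula
  x6 <- c(3, 1, 4, 1, 5, 9); y6 <- c(2, 7, 1, 8, 2, 8); w6 <- c(2, 1, 1, 1, 1, 2)
  rho_hand <- {
    rx <- rank(x6); ry <- rank(y6)
    mx <- sum(w6 * rx) / sum(w6); my <- sum(w6 * ry) / sum(w6)
    sxy <- sum(w6 * (rx - mx) * (ry - my)) / sum(w6)
    sxx <- sum(w6 * (rx - mx)^2) / sum(w6)
    syy <- sum(w6 * (ry - my)^2) / sum(w6)
    sxy / sqrt(sxx * syy)
  }
  expect_equal(weighted_spearman(x6, y6, w6), rho_hand, tolerance = 1e-12)
  expect_error(weighted_spearman(x6, y6, rep(0, 6)), "weights")
  expect_error(weighted_spearman(1:2, 1:2, 1:2), "length")
})

test_that("period drift detects constructed slowing and degrades gracefully", {
  set.seed(22)
  d <- data.frame(win_mid = 1:30, density = runif(30, 0.92, 1),
                  mean_delay = seq(9, 11, length.out = 30) + rnorm(30, 0, 0.05),
                  delay_sd = runif(30, 0.2, 0.4))
  class(d) <- c("window_density", "data.frame")
  attr(d, "win") <- 5; attr(d, "step") <- 1
  dr <- period_drift(d, coalescence = 1, n_perm = 1000, seed = 1)
  expect_gt(dr$rho, 0)
  expect_lt(dr$p, 0.01)
  ## constant delays: zero variance reported as rho 0, p 1
  d2 <- d
  d2$mean_delay <- 10
  dr2 <- period_drift(d2, coalescence = 1, n_perm = 100, seed = 1)
  expect_equal(dr2$rho, 0)
  expect_equal(dr2$p, 1)
  ## zero-SD windows get capped weights rather than infinities
  d3 <- d
  d3$delay_sd[5] <- 0
  dr3 <- period_drift(d3, coalescence = 1, n_perm = 100, seed = 1)
  expect_true(all(is.finite(dr3$weights)))
})
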