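test_that("uncoupled Matsuoka neuron converges to the closed-form fixed point", {
  for (cc in c(1, 3, 5)) {
    for (gam in c(0, 2)) {
      p <- matsuoka_params(W = matrix(0, 1, 1), c = cc, gamma = gam)
      sim <- simulate_matsuoka(p, duration = 3)
      expect_equal(tail(sim$r[, 1], 1), cc / (1 + gam), tolerance = 1e-3)
    }
  }
})

test_that("coupled Matsuoka network oscillates and integration converges in dt", {
  sim <- simulate_matsuoka(matsuoka_params(), duration = 10)
  x <- sim$r[sim$t >= 5, 1]
  pk <- which(diff(sign(diff(x))) == -2) + 1
  pkv <- x[pk][x[pk] > 0.5 * max(x)]
  expect_gt(length(pkv), 4)
  expect_lt(sd(pkv) / mean(pkv), 0.05)          # sustained amplitude
  expect_gt(diff(range(sim$r[sim$t >= 5, ])), 1) # genuinely oscillating

  fine <- simulate_matsuoka(matsuoka_params(), duration = 10, dt = 5e-4)
  m1 <- colMeans(sim$r[sim$t >= 9, ])
  m2 <- colMeans(fine$r[fine$t >= 9, ])
  expect_lt(max(abs(m1 - m2) / m1), 0.01)
})

test_that("decaying drive shrinks oscillation amplitude but not its period", {
  dur <- 6
  ramp_down <- function(t) pmax(0, 3 * (1 - t / (2 * dur)))
  base <- simulate_matsuoka(matsuoka_params(), duration = dur)
  dec <- simulate_matsuoka(matsuoka_params(c = function(t) rep(ramp_down(t), 3)),
                           duration = dur)
  ## oracle: zero-crossing intervals of a dt/10 reference integration
  ref <- simulate_matsuoka(matsuoka_params(c = function(t) rep(ramp_down(t), 3)),
                           duration = dur, dt = 1e-4)
  cross_iv <- function(sim) {
    x <- sim$r[sim$t >= 2, 1] - mean(sim$r[sim$t >= 2, 1])
    tt <- sim$t[sim$t >= 2]
    up <- which(x[-1] > 0 & x[-length(x)] <= 0)
    diff(tt[up])
  }
  expect_equal(mean(cross_iv(dec)), mean(cross_iv(ref)), tolerance = 0.02)
  amp_early <- diff(range(dec$r[dec$t >= 2 & dec$t < 3, 1]))
  amp_late <- diff(range(dec$r[dec$t >= 5, 1]))
  expect_lt(amp_late, 0.8 * amp_early)
  expect_equal(mean(cross_iv(dec)), mean(cross_iv(base)), tolerance = 0.1 * mean(cross_iv(base)))
})

test_that("Matsuoka parameter validation rejects bad networks", {
  expect_error(matsuoka_params(W = matrix(1, 2, 2)), "diagonal")
  W <- matrix(c(0, 1, -1, 0), 2)
  expect_error(matsuoka_params(W = W), "inhibition")
  expect_error(simulate_matsuoka(matsuoka_params(), 10, dt = 0.02), "tau_a/5")
})

test_that("spiral population spike counts follow the intensity", {
  ## Poisson special case: baseline-only count lands in the 99.7% band
  p <- spiral_params(n_neurons = 2, baseline_rate = 10, gains = c(0, 0),
                     pre_s = 0, post_s = 100, regularity = 1, seed = 3)
  pop <- generate_spiral_population(p)
  n1 <- length(pop$spikes$spikes[[1]])
  expect_lt(abs(n1 - 1000), 3 * sqrt(1000))
  ## zero intensity, zero spikes
  p0 <- spiral_params(n_neurons = 2, baseline_rate = 0, gains = c(0, 0), seed = 1)
  expect_equal(sum(lengths(generate_spiral_population(p0)$spikes$spikes)), 0)
})

test_that("spiral ground truth encodes period and contraction consistently", {
  p <- spiral_params(period = 10, contraction_per_s = 0.98, seed = 2)
  tr <- generate_spiral_population(p)$truth
  expect_equal(tr$true_eigen_imag, 2 * pi * 0.01 / 10, tolerance = 1e-12)
  expect_equal(2 * pi * 0.01 / tr$true_eigen_imag, tr$true_period,
               tolerance = 1e-9)
  expect_equal(exp(tr$true_eigen_real / 0.01), 0.98, tolerance = 1e-12)
  ## amplitude envelope really decays at the stated per-second ratio
  tau <- c(30, 40, 50)
  env <- spiralscope:::spiral_envelope(tau, 10, 0.98, 10)
  expect_equal(env[2] / env[1], 0.98^10, tolerance = 1e-6)
})

test_that("generators are bit-identical under a fixed seed", {
  p <- spiral_params(n_neurons = 20, post_s = 20, seed = 99)
  a <- generate_spiral_population(p)
  b <- generate_spiral_population(p)
  expect_identical(a$spikes$spikes, b$spikes$spikes)
  orb <- spiral_trajectory(radial_noise = 0.05, seed = 5, duration = 10)
  orb2 <- spiral_trajectory(radial_noise = 0.05, seed = 5, duration = 10)
  expect_identical(orb$P, orb2$P)
})

test_that("nerve output follows the log-link history model", {
  orb <- spiral_trajectory(period = 10, duration = 50, dt = 0.01)
  ## intercept-only: homogeneous train at 5 Hz
  nv <- generate_nerve_output(orb$P, beta0 = log(5),
                              beta = matrix(0, 2, 5), seed = 8)
  expect_equal(nv$rate[!is.na(nv$rate)][1], 5)
  n <- length(nv$spike_times)
  expect_lt(abs(n - 5 * 50), 4 * sqrt(250))
  ## phase locking: rate correlates with the lagged first dimension
  beta <- matrix(0, 2, 5); beta[1, ] <- 0.2
  nv2 <- generate_nerve_output(orb$P, beta0 = log(10), beta = beta, seed = 8)
  ok <- !is.na(nv2$rate)
  expect_gt(cor(log(nv2$rate[ok]), orb$P[ok, 1]), 0.9)
  ## errors
  expect_error(generate_nerve_output(orb$P[0, , drop = FALSE], 0, beta),
               "empty")
  expect_error(generate_nerve_output(orb$P, 1000, beta), "rescale")
})

test_that("perturbation injection edits only the window", {
  pop <- small_cycle_pop(seed = 4)
  sup <- inject_perturbation(pop$spikes, c(30, 40), "suppress", prob = 1)
  for (id in names(sup$spikes)) {
    s0 <- pop$spikes$spikes[[id]]
    s1 <- sup$spikes[[id]]
    expect_identical(s1, s0[s0 < 30 | s0 >= 40])
  }
  ## zero-length window is a no-op
  expect_identical(inject_perturbation(pop$spikes, c(30, 30), "remap"),
                   pop$spikes)
  ## remap keeps per-neuron counts, changes in-window times only
  rem <- inject_perturbation(pop$spikes, c(30, 40), "remap", seed = 1)
  expect_identical(lengths(rem$spikes), lengths(pop$spikes$spikes))
  for (id in names(rem$spikes)) {
    out0 <- pop$spikes$spikes[[id]]
    expect_identical(rem$spikes[[id]][rem$spikes[[id]] < 30], out0[out0 < 30])
  }
  expect_error(inject_perturbation(pop$spikes, c(60, 80), "suppress"),
               "inside")
})
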