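test_that("motorneuron screen finds constructed locking and chance levels", {
  set.seed(23)
  s <- sort(runif(300, 0, 100))
  echo <- s + 0.005                      # every spike echoed at +5 ms
  indep <- sort(runif(400, 0, 100))      # 4 Hz, unrelated
  nerve <- sort(c(echo, runif(2000, 0, 100)))   # echoes + 20 Hz background
  x <- spike_data(list(locked = s, indep = indep), duration = 100)
  scr <- screen_motorneurons(x, nerve)
  expect_equal(scr$p_max[1], 1)
  ## the +/-2 ms jitter makes delays 3-7 ms all perfect; any of them may win
  expect_gte(scr$best_delay[1], 0.003)
  expect_lte(scr$best_delay[1], 0.007)
  expect_equal(unname(attr(scr, "prob")[1, 6]), 1)   # delay = 5 ms exactly
  ## independent neuron: chance = 1 - exp(-rate * 4 ms) within 3 binomial SD
  rate <- length(nerve) / 100
  p0 <- 1 - exp(-rate * 0.004)
  expect_lt(abs(scr$p_max[2] - p0), 3 * sqrt(p0 * (1 - p0) / 400) + 0.05)
  ## silent neuron reported missing
  x2 <- spike_data(list(a = s, none = numeric(0)), duration = 100)
  scr2 <- screen_motorneurons(x2, nerve)
  expect_true(is.na(scr2$p_max[2]))
})

test_that("intercept-only decoding matches the analytic optimum", {
  tt <- seq(0, 60, by = 0.01)
  P <- cbind(sin(tt), cos(tt))
  mod <- fit_decoder(P * 0, rep(5, length(tt)), tt, window = c(5, 55),
                     history_ms = 100)
  expect_equal(mod$beta0, log(5), tolerance = 1e-3)
  expect_true(all(abs(mod$beta) < 1e-6))
})

test_that("decoder recovers generating coefficients from the true rate", {
  orb <- spiral_trajectory(period = 10, contraction_per_s = 1,
                           duration = 80, dt = 0.01)
  m <- 10
  beta <- matrix(0, 2, m)
  beta[1, ] <- seq(0.3, 0.1, length.out = m) / m * 10
  beta[2, ] <- 0.05
  nv <- generate_nerve_output(orb$P, beta0 = log(20), beta = beta, seed = 24)
  mod <- fit_decoder(orb$P, nv$rate, orb$t, window = c(2, 70), history_ms = 100)
  cosine <- sum(mod$beta * beta) / sqrt(sum(mod$beta^2) * sum(beta^2))
  expect_gt(cosine, 0.95)
  expect_equal(mod$beta0, log(20), tolerance = 0.05)
})

test_that("forecasts use the trajectory alone and score sensibly", {
  orb <- spiral_trajectory(period = 10, contraction_per_s = 1,
                           duration = 80, dt = 0.01)
  m <- 10
  beta <- matrix(0, 2, m); beta[1, ] <- 0.15
  nv <- generate_nerve_output(orb$P, beta0 = log(20), beta = beta, seed = 25)
  mod <- fit_decoder(orb$P, nv$rate, orb$t, window = c(2, 50), history_ms = 100)
  fc <- forecast(mod, orb$P, orb$t, window = c(50, 60), observed = nv$rate)
  expect_gt(fc$R, 0.99)                   # exact model, noiseless target
  expect_lt(fc$MAE, 0.5)
  ## constant observed series: R undefined, MAE kept
  fc2 <- forecast(mod, orb$P, orb$t, window = c(50, 60),
                  observed = rep(20, length(orb$t)))
  expect_true(is.na(fc2$R))
  expect_true(is.finite(fc2$MAE))
  expect_warning(forecast(mod, orb$P, orb$t, window = c(75, 95)), "truncated")
})

test_that("sliding evaluation selects history by median absolute error", {
  orb <- spiral_trajectory(period = 10, contraction_per_s = 1,
                           duration = 75, dt = 0.01)
  beta <- matrix(0, 2, 10); beta[1, ] <- 0.15
  nv <- generate_nerve_output(orb$P, beta0 = log(30), beta = beta, seed = 26)
  nr <- spike_density(spike_data(list(p10 = nv$spike_times), duration = 75),
                      dt = 0.01, sigma = 0.1)
  ev <- evaluate_decoding(orb$P, nr$F[, 1], orb$t,
                          history_grid = c(50, 100), start_t = 1)
  expect_equal(ev$best_history,
               ev$summary$history_ms[which.min(ev$summary$median_MAE)])
  best <- ev$scores[ev$scores$history_ms == ev$best_history, ]
  expect_gt(median(best$R, na.rm = TRUE), 0.9)
  ## negative control: a block-scrambled rate carries no decodable dynamics
  set.seed(45)
  y <- nr$F[, 1]
  blocks <- split(y, rep(seq_len(75), each = 100)[seq_along(y)])
  y_scr <- unlist(blocks[sample(length(blocks))], use.names = FALSE)
  ev0 <- evaluate_decoding(orb$P, y_scr, orb$t, history_grid = 100,
                           start_t = 1)
  expect_lt(median(ev0$scores$R, na.rm = TRUE),
            0.5 * median(best$R, na.rm = TRUE))
})

test_that("adding noise dimensions does not change forecast error much", {
  set.seed(27)
  orb <- spiral_trajectory(period = 10, contraction_per_s = 1,
                           duration = 70, dt = 0.01)
  beta <- matrix(0, 2, 10); beta[1, ] <- 0.15
  nv <- generate_nerve_output(orb$P, beta0 = log(30), beta = beta, seed = 28)
  nr <- spike_density(spike_data(list(p10 = nv$spike_times), duration = 70),
                      dt = 0.01, sigma = 0.1)
  P_wide <- cbind(orb$P, matrix(rnorm(2 * nrow(orb$P), 0, 0.2), ncol = 2))
  ev2 <- evaluate_decoding(orb$P, nr$F[, 1], orb$t, history_grid = 100, start_t = 1)
  ev4 <- evaluate_decoding(P_wide, nr$F[, 1], orb$t, history_grid = 100, start_t = 1)
  ratio <- median(ev4$scores$MAE) / median(ev2$scores$MAE)
  expect_gt(ratio, 0.8)
  expect_lt(ratio, 1.2)
})
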