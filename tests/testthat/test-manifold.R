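test_that("Hausdorff distance matches brute force and its metric properties", {
  set.seed(14)
  A <- matrix(runif(100), 50, 2)
  B <- matrix(runif(80), 40, 2)
  h <- hausdorff_distance(A, B)
  expect_equal(h, bf_hausdorff(A, B), tolerance = 1e-14)
  expect_equal(h, hausdorff_distance(B, A), tolerance = 1e-14)  # symmetric
  expect_equal(hausdorff_distance(A, A), 0)
  expect_equal(hausdorff_distance(matrix(c(0, 0), 1), matrix(c(1, 0), 1)), 1)
  ## translated clouds: exact agreement with the double loop again
  B2 <- A + matrix(rep(c(3, 0), each = 50), 50)
  expect_equal(hausdorff_distance(A, B2), bf_hausdorff(A, B2),
               tolerance = 1e-14)
  expect_lte(hausdorff_distance(A, B2), 3 + 1e-12)
  expect_error(hausdorff_distance(A[0, , drop = FALSE], B), "empty")
})

test_that("similarity null model conserves totals and matches hand arithmetic", {
  set.seed(15)
  tt <- seq(0, 20, by = 0.01)
  F_A <- cbind(sin(tt), sin(tt + 0.3), cos(tt)) + 2 +
    0.1 * matrix(rnorm(3 * length(tt)), ncol = 3)
  F_B <- cbind(sin(tt), sin(tt + 0.5), cos(tt + 0.1)) + 2 +
    0.1 * matrix(rnorm(3 * length(tt)), ncol = 3)
  colnames(F_A) <- colnames(F_B) <- c("a", "b", "c")
  sc <- similarity_null_test(as_rate_matrix(F_A, tt), as_rate_matrix(F_B, tt))
  ## row-sum conservation of the null
  s <- rowSums(abs(sc$S_B))
  expect_equal(rowSums(sc$E), s, tolerance = 1e-8, ignore_attr = TRUE)
  ## hand arithmetic for a 3-neuron case: correlations over the 6 off-diagonal
  ## entries, written out from the definition
  off <- which(row(sc$S_A) != col(sc$S_A))
  r_hand <- {
    x <- sc$S_A[off]; y <- sc$S_B[off]
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  expect_equal(sc$r_data, r_hand, tolerance = 1e-12)
  e <- tcrossprod(s) / sum(s)
  r_ctrl_hand <- {
    x <- sc$S_A[off]; y <- e[off]
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  expect_equal(sc$r_control, r_ctrl_hand, tolerance = 1e-12)
})

test_that("a rank-one similarity structure makes data and control agree", {
  ## if S_B equals the null E built from its own totals, r_data = r_control
  tt <- seq(0, 20, by = 0.02)
  set.seed(16)
  F_A <- 2 + matrix(rnorm(4 * length(tt)), ncol = 4) +
    cbind(sin(tt), sin(tt), sin(tt), sin(tt))
  colnames(F_A) <- paste0("n", 1:4)
  sc <- similarity_null_test(as_rate_matrix(F_A, tt), as_rate_matrix(F_A, tt))
  ## here S_B = S_A, so r_data = 1; the control differs
  expect_equal(sc$r_data, 1, tolerance = 1e-12)
  expect_lt(sc$r_control, 1)
})

test_that("a program compared with itself is at zero normalized distance", {
  pop <- small_cycle_pop(seed = 17, contraction_per_s = 1)
  rm <- spike_density(pop$spikes, sigma = 0.1)
  emb <- embed_population(rm, window = c(10, 70))
  cm <- compare_manifolds(rm, rm, emb, n_shuffles = 10, seed = 1,
                          recurrence_args = list(scan = c(15, 55)))
  expect_equal(cm$hausdorff, 0)
  expect_equal(cm$normalized, 0)
  expect_gt(cm$control_mean, 0)
})

test_that("programs on a shared orbit are closer than shuffled projections", {
  par1 <- spiral_params(seed = 18, n_neurons = 60, pre_s = 10, post_s = 60,
                        contraction_per_s = 1)
  pop1 <- generate_spiral_population(par1)
  par2 <- par1
  par2$seed <- 181
  par2$gains <- pop1$truth$gains
  par2$phases <- pop1$truth$phases
  pop2 <- generate_spiral_population(par2)
  rm1 <- spike_density(pop1$spikes, sigma = 0.1)
  rm2 <- spike_density(pop2$spikes, sigma = 0.1)
  emb <- embed_population(rm1, window = c(10, 70))
  cm <- compare_manifolds(rm1, rm2, emb, n_shuffles = 20, seed = 2,
                          recurrence_args = list(scan = c(15, 55)))
  expect_lt(cm$normalized, 1)
})

test_that("state distances vanish for identical programs and order correctly", {
  pop <- small_cycle_pop(seed = 19, contraction_per_s = 1)
  rm <- spike_density(pop$spikes, sigma = 0.1)
  emb <- embed_population(rm, window = c(10, 70))
  rec <- detect_periodic_orbit(find_recurrence(emb, scan = c(15, 55)),
                               min_peak_points = 50)
  dens <- window_density(rec)
  co <- coalescence_time(dens)
  sd3 <- state_distances(emb$P, emb$P, emb$t, stim_on = 10,
                         coalA = co, coalB = co, recA = rec, recB = rec)
  expect_equal(unname(sd3), c(0, 0, 0))
  expect_error(state_distances(emb$P, emb$P, emb$t, 10, NA, co, rec, rec),
               "coalescence")
})
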