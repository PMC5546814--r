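## Independent brute-force references and small fixture builders.
## Oracles deliberately follow the written procedure step by step in plain R,
## sharing no code with the package internals they check.

## recurrence oracle: for each scanned index, walk forward past the
## contiguous within-theta run, then to the first re-entry (optionally
## skipping re-entries closer than min_steps)
bf_recurrence <- function(P, theta, scan_idx, min_steps = 0) {
  n <- nrow(P)
  delta <- rep(NA_integer_, length(scan_idx))
  for (k in seq_along(scan_idx)) {
    i <- scan_idx[k]
    j <- i + 1
    while (j <= n && sqrt(sum((P[j, ] - P[i, ])^2)) < theta) j <- j + 1
    repeat {
      while (j <= n && sqrt(sum((P[j, ] - P[i, ])^2)) >= theta) j <- j + 1
      if (j > n) break
      if (j - i >= min_steps) { delta[k] <- j - i; break }
      while (j <= n && sqrt(sum((P[j, ] - P[i, ])^2)) < theta) j <- j + 1
    }
  }
  delta
}

bf_hausdorff <- function(A, B) {
  h <- function(X, Y) {
    mx <- 0
    for (i in seq_len(nrow(X))) {
      mn <- Inf
      for (j in seq_len(nrow(Y)))
        mn <- min(mn, sqrt(sum((X[i, ] - Y[j, ])^2)))
      mx <- max(mx, mn)
    }
    mx
  }
  max(h(A, B), h(B, A))
}

## theta oracle through R's own machinery (independent of the C++ path)
bf_theta <- function(P, percentile) {
  quantile(dist(P), percentile / 100, names = FALSE, type = 7)
}

## rate_matrix from a plain matrix, for tests that bypass spike data
as_rate_matrix <- function(F, t, sigma = 0.01) {
  structure(list(t = t, F = as.matrix(F), sigma = sigma,
                 dt = if (length(t) > 1) t[2] - t[1] else 0.01,
                 window = range(t),
                 neuron_ids = colnames(F) %||% paste0("n", seq_len(ncol(F)))),
            class = "rate_matrix")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

## hand-built recurrence object (no trajectory: histogram logic only)
fake_recurrence <- function(delta, t = NULL, dt = 0.01) {
  n <- length(delta)
  if (is.null(t)) t <- (seq_len(n) - 1) * dt
  structure(list(t = t, scan = c(1L, n), scan_t = t, theta = 1,
                 theta_percentile = 10, recurrent = !is.na(delta),
                 delta = delta, dt = dt, trajectory = NULL),
            class = "recurrence")
}

small_cycle_pop <- function(seed = 1, ...) {
  generate_spiral_population(spiral_params(seed = seed, n_neurons = 60,
                                           pre_s = 10, post_s = 60, ...))
}
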