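#' Local linear model of the trajectory around one point
#'
#' Takes the run of trajectory points contiguous in time around the anchor
#' that stays within `radius_mult * theta` of it as the local neighbourhood;
#' if at least `min_points` qualify, fits the local dynamical model
#' \eqn{\dot P^* = A P^*} by least squares, with the neighbourhood
#' time-series as \eqn{P^*} and its first-order difference as
#' \eqn{\dot P^*} (both centred on the neighbourhood, so the local model is
#' affine and `A` is a per-step Jacobian). The eigenvalues of `A` carry the
#' local dynamics: sign of the real part = contraction/expansion, nonzero
#' imaginary part = rotation.
#'
#' @param P trajectory matrix (time x d) or `embedding`.
#' @param anchor anchor row index.
#' @param theta recurrence distance threshold (trajectory units).
#' @param radius_mult neighbourhood radius in units of `theta`.
#' @param min_points minimum neighbourhood size for a valid fit.
#' @return class `local_linear_fit`: list with `anchor`, `A`, complex
#'   `eigvals` (sorted by decreasing real part), `n_points`, `valid`.
#' @export
fit_local_linear <- function(P, anchor, theta, radius_mult = 2.5,
                             min_points = 100) {
  M <- traj_matrix(P)
  n <- nrow(M)
  if (anchor < 1 || anchor > n) ss_stop("ss_validation", "anchor out of range")
  run <- cpp_neighbourhood_run(M, anchor - 1L, radius_mult * theta)
  idx <- (run[1] + 1L):(run[2] + 1L)
  fit <- list(anchor = anchor, A = NULL, eigvals = NULL,
              n_points = length(idx), valid = FALSE)
  class(fit) <- "local_linear_fit"
  if (length(idx) < min_points + 1) return(fit)
  X <- M[idx[-length(idx)], , drop = FALSE]
  Y <- M[idx[-1], , drop = FALSE] - X
  X <- sweep(X, 2, colMeans(X))
  Y <- sweep(Y, 2, colMeans(Y))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    ss_log("rank-deficient neighbourhood at anchor %d (condition ~ %g)",
           anchor, kappa(X))
    return(fit)
  }
  A <- t(qr.coef(qx, Y))
  ev <- eigen(A, only.values = TRUE)$values
  fit$A <- A
  fit$eigvals <- as.complex(ev[order(-Re(ev), abs(Im(ev)))])
  fit$valid <- TRUE
  fit
}

#' Fit local linear models at many anchors
#'
#' @param P trajectory matrix or `embedding`.
#' @param anchors anchor row indices.
#' @inheritParams fit_local_linear
#' @return list of `local_linear_fit` objects (class `local_linear_fits`).
#' @export
local_linear_fits <- function(P, anchors, theta, radius_mult = 2.5,
                              min_points = 100) {
  M <- traj_matrix(P)
  fits <- lapply(anchors, function(a)
    fit_local_linear(M, a, theta, radius_mult, min_points))
  class(fits) <- "local_linear_fits"
  fits
}

#' Summarise the attractor from local linear fits
#'
#' Averages the real part \eqn{a} and (absolute) imaginary part \eqn{b} of
#' the maximum eigenvalue — the eigenvalue with the largest real part,
#' conjugate resolved to \eqn{b \ge 0} — over the valid fits anchored at
#' recurrent points of the dominant periodic orbit. Converts the per-step
#' eigenvalue to physical attractor parameters: orbital period
#' \eqn{2\pi\Delta t / b} (s) and contraction rate
#' \eqn{100\,\exp(a/\Delta t)} (% of amplitude retained per second), and
#' classifies the attractor by the sign pattern (`stable_spiral`,
#' `unstable_spiral`, `stable_node`, `unstable_node`).
#'
#' @param fits a `local_linear_fits` list whose anchors index the scanned
#'   points of `rec`... anchors must be trajectory row indices.
#' @param rec a `recurrence` result carrying the dominant orbit (see
#'   [detect_periodic_orbit()]).
#' @param dt trajectory time step (s).
#' @param min_fits minimum number of valid dominant-orbit fits.
#' @return class `attractor_estimate`: `a_mean`, `a_sem`, `b_mean`, `b_sem`,
#'   `period_est`, `contraction_pct_per_s`, `classification`,
#'   `per_dim_real` (mean real eigenvalue per unique dimension, conjugate
#'   pairs counted once), `rotation_fraction` (fraction of fits whose top
#'   two eigenvalues include a complex pair), `n_fits`.
#' @export
summarize_attractor <- function(fits, rec, dt = 0.01, min_fits = 10) {
  stopifnot(inherits(rec, "recurrence"))
  if (is.null(rec$peaks))
    ss_stop("ss_validation", "run detect_periodic_orbit() before summarising")
  if (is.na(rec$dominant))
    ss_stop("ss_aperiodic", "no dominant periodic orbit: program is aperiodic")
  pk <- rec$peaks[rec$dominant, ]
  scan_idx <- seq(rec$scan[1], rec$scan[2])
  on_orbit <- rec$recurrent & rec$delta >= pk$lo & rec$delta < pk$hi
  orbit_rows <- scan_idx[on_orbit]
  sel <- vapply(fits, function(f) f$valid && f$anchor %in% orbit_rows,
                logical(1))
  fits <- fits[sel]
  if (length(fits) < min_fits)
    ss_stop("ss_insufficient",
            "only %d valid fits at dominant-orbit recurrent points (need >= %d)",
            length(fits), min_fits)
  amax <- vapply(fits, function(f) Re(f$eigvals[1]), numeric(1))
  bmax <- vapply(fits, function(f) abs(Im(f$eigvals[1])), numeric(1))
  a_mean <- mean(amax); b_mean <- mean(bmax)
  nf <- length(fits)
  ## per unique dimension: conjugate pairs counted once
  pdr <- lapply(fits, function(f) {
    ev <- f$eigvals
    keep <- Im(ev) >= 0
    sort(Re(ev[keep]), decreasing = TRUE)
  })
  dmax <- max(lengths(pdr))
  per_dim <- colMeans(do.call(rbind, lapply(pdr, function(v)
    c(v, rep(NA_real_, dmax - length(v))))), na.rm = TRUE)
  rot <- mean(vapply(fits, function(f) any(Im(f$eigvals[1:min(2, length(f$eigvals))]) != 0),
                     logical(1)))
  b_tol <- 1e-10
  classification <- if (b_mean > b_tol) {
    if (a_mean < 0) "stable_spiral" else "unstable_spiral"
  } else {
    if (a_mean < 0) "stable_node" else "unstable_node"
  }
  structure(list(a_mean = a_mean, a_sem = sd(amax) / sqrt(nf),
                 b_mean = b_mean, b_sem = sd(bmax) / sqrt(nf),
                 period_est = if (b_mean > b_tol) 2 * pi * dt / b_mean else NA_real_,
                 contraction_pct_per_s = 100 * exp(a_mean / dt),
                 classification = classification,
                 per_dim_real = per_dim, rotation_fraction = rot,
                 n_fits = nf, dt = dt),
            class = "attractor_estimate")
}

#' @export
print.attractor_estimate <- function(x, ...) {
  cat(sprintf("attractor estimate (%d local fits): %s\n", x$n_fits,
              x$classification))
  cat(sprintf("  max eigenvalue a = %.3g +/- %.2g, b = %.3g +/- %.2g (per step, 2 SEM)\n",
              x$a_mean, 2 * x$a_sem, x$b_mean, 2 * x$b_sem))
  if (!is.na(x$period_est))
    cat(sprintf("  orbital period %.2f s, contraction %.2f%%/s\n",
                x$period_est, x$contraction_pct_per_s))
  else
    cat(sprintf("  no rotation; contraction %.2f%%/s\n",
                x$contraction_pct_per_s))
  invisible(x)
}

#' @export
summary.attractor_estimate <- function(object, ...) {
  print(object)
  cat("  mean real eigenvalue per dimension:",
      paste(sprintf("%.3g", object$per_dim_real), collapse = ", "), "\n")
  cat(sprintf("  rotation dominance: %.0f%% of fits\n",
              100 * object$rotation_fraction))
  invisible(object)
}

#' @export
coef.attractor_estimate <- function(object, ...) {
  c(a = object$a_mean, b = object$b_mean,
    period_s = object$period_est,
    contraction_pct_per_s = object$contraction_pct_per_s)
}

#' Weighted Spearman rank correlation
#'
#' Ranks both inputs (average ranks for ties), then computes the weighted
#' correlation \eqn{\rho = \sigma_{xy} / \sqrt{\sigma_{xx}\sigma_{yy}}} with
#' weighted means \eqn{m = \sum_i w_i x_i / \sum_i w_i} and covariances
#' \eqn{\sigma_{xy} = \sum_i w_i (x_i - m_x)(y_i - m_y) / \sum_i w_i}.
#' Uniform weights reduce it to the classical Spearman coefficient.
#'
#' @param x,y numeric vectors, equal length `>= 3`.
#' @param w non-negative weights, not all zero.
#' @return \eqn{\rho} in \eqn{[-1, 1]}; `NA` if either ranking has zero
#'   weighted variance.
#' @export
weighted_spearman <- function(x, y, w = rep(1, length(x))) {
  if (length(x) != length(y) || length(x) != length(w) || length(x) < 3)
    ss_stop("ss_validation", "x, y, w must have equal length >= 3")
  if (any(w < 0) || sum(w) == 0)
    ss_stop("ss_undefined", "weights must be >= 0 and not all zero")
  rx <- rank(x); ry <- rank(y)
  weighted_rank_cor(rx, ry, w)
}

## core on pre-computed ranks (used by the permutation loop)
weighted_rank_cor <- function(rx, ry, w) {
  sw <- sum(w)
  mx <- sum(w * rx) / sw
  my <- sum(w * ry) / sw
  sxy <- sum(w * (rx - mx) * (ry - my)) / sw
  sxx <- sum(w * (rx - mx)^2) / sw
  syy <- sum(w * (ry - my)^2) / sw
  if (sxx == 0 || syy == 0) return(NA_real_)
  sxy / sqrt(sxx * syy)
}

#' Drift of the orbital period over a program
#'
#' Correlates the mean recurrence delay in sliding windows against window
#' time, over the windows between coalescence and the final window with at
#' least 90% recurrent points, using the weighted Spearman correlation with
#' weights \eqn{w_i = s_i^{-1} Q_i} (inverse delay SD times recurrent
#' fraction), which favours windows where the trajectory is clearly on the
#' orbit. Significance by permutation of the delay series (default 10000
#' permutations; p includes the observed ordering so it lies in (0, 1]).
#' A window with zero delay SD would get infinite weight; its weight is
#' capped at the 99th percentile of the finite weights.
#'
#' @param densities a `window_density` series.
#' @param coalescence coalescence time (s).
#' @param n_perm number of permutations.
#' @param seed RNG seed for the permutations.
#' @param tail `"two"` (default; slowing and speeding both count),
#'   `"greater"` (slowing), `"less"` (speeding).
#' @param density_min windows qualify up to the last one with at least this
#'   recurrent fraction.
#' @return class `drift_result`: list with `rho`, `p`, `n_windows`,
#'   `weights`.
#' @export
period_drift <- function(densities, coalescence, n_perm = 10000, seed = NULL,
                         tail = c("two", "greater", "less"),
                         density_min = 0.90) {
  stopifnot(inherits(densities, "window_density"))
  tail <- match.arg(tail)
  if (is.na(coalescence)) ss_stop("ss_validation", "coalescence undefined")
  hi <- which(densities$density >= density_min)
  if (!length(hi)) ss_stop("ss_validation", "no window reaches density_min")
  t_hi <- densities$win_mid[hi[length(hi)]]
  rows <- densities$win_mid >= coalescence & densities$win_mid <= t_hi &
    !is.na(densities$mean_delay)
  dd <- densities[rows, , drop = FALSE]
  if (nrow(dd) < 3)
    ss_stop("ss_validation", "need >= 3 qualifying windows, got %d", nrow(dd))
  w <- dd$density / dd$delay_sd
  bad <- !is.finite(w)
  if (any(bad)) {
    cap <- if (all(bad)) 1 else quantile(w[!bad], 0.99, names = FALSE)
    ss_log("capping %d infinite window weights at %.3g", sum(bad), cap)
    w[bad] <- cap
  }
  rx <- rank(dd$win_mid)
  ry <- rank(dd$mean_delay)
  rho <- weighted_rank_cor(rx, ry, w)
  if (is.na(rho))
    return(structure(list(rho = 0, p = 1, n_windows = nrow(dd), weights = w),
                     class = "drift_result"))
  if (!is.null(seed)) set.seed(seed)
  stat <- function(r) switch(tail, two = abs(r), greater = r, less = -r)
  obs <- stat(rho)
  exceed <- 0L
  for (k in seq_len(n_perm)) {
    rp <- weighted_rank_cor(rx, sample(ry), w)
    if (!is.na(rp) && stat(rp) >= obs) exceed <- exceed + 1L
  }
  structure(list(rho = rho, p = (1 + exceed) / (1 + n_perm),
                 n_windows = nrow(dd), weights = w),
            class = "drift_result")
}

#' @export
print.drift_result <- function(x, ...) {
  cat(sprintf("period drift: weighted Spearman rho = %.3f, p = %.4g (%d windows)\n",
              x$rho, x$p, x$n_windows))
  invisible(x)
}
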