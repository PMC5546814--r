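## helpers to accept either an embedding or a bare trajectory matrix
traj_matrix <- function(P) {
  if (inherits(P, "embedding")) return(P$P)
  as.matrix(P)
}
traj_times <- function(P, t = NULL, dt = NULL) {
  if (!is.null(t)) return(t)
  if (inherits(P, "embedding")) return(P$t)
  tt <- attr(P, "t")
  if (!is.null(tt)) return(tt)
  if (is.null(dt)) ss_stop("ss_validation", "supply t or dt for a bare trajectory")
  (seq_len(nrow(as.matrix(P))) - 1) * dt
}

#' Recurrence of a low-dimensional trajectory
#'
#' A point \eqn{P(t)} is recurrent if the trajectory later re-enters the ball
#' of Euclidean radius \eqn{\theta} around it; its recurrence time
#' \eqn{\delta} is the delay to the first such return, after first leaving
#' the contiguous run of points around \eqn{t} that stay within
#' \eqn{\theta}. The threshold \eqn{\theta} is data-scaled: a percentile
#' (default the 10% value) of the distribution of all pairwise distances
#' between scanned points.
#'
#' Every time point in the scan range is tested; the default range runs from
#' 5 s after the start of the scanned span to 10 s before the end of the
#' trajectory, so each scanned point has future left in which to recur.
#' Future returns are searched over the whole remaining trajectory.
#'
#' @param P an `embedding` or a trajectory matrix (time x d, with times in
#'   `attr(,"t")` or supplied via `t`).
#' @param t optional time grid (s).
#' @param theta_percentile percentile (in %) of the pairwise-distance
#'   distribution used as \eqn{\theta}.
#' @param scan `(from, to)` in seconds; default `c(min(t) + 5, max(t) - 10)`.
#' @param theta optional explicit \eqn{\theta}, bypassing the percentile.
#' @return class `recurrence`: list with `t`, `scan` (index range), `theta`,
#'   `theta_percentile`, logical `recurrent` and numeric `delta` (s, `NA`
#'   where not recurrent), both over the scanned points, plus `scan_t` (their
#'   times) and `dt`.
#' @examples
#' orb <- spiral_trajectory(period = 10, duration = 60)
#' rec <- find_recurrence(orb$P, t = orb$t)
#' mean(rec$recurrent)
#' @export
find_recurrence <- function(P, t = NULL, theta_percentile = 10, scan = NULL,
                            theta = NULL) {
  M <- traj_matrix(P)
  tt <- traj_times(P, t)
  if (length(tt) != nrow(M)) ss_stop("ss_validation", "t must match trajectory rows")
  if (is.null(scan)) scan <- c(min(tt) + 5, max(tt) - 10)
  idx <- which(tt >= scan[1] & tt <= scan[2])
  if (length(idx) < 2)
    ss_stop("ss_degenerate", "fewer than 2 points in the scan range")
  if (is.null(theta))
    theta <- cpp_pairwise_quantile(M[idx, , drop = FALSE],
                                   theta_percentile / 100)
  dt <- median(diff(tt))
  steps <- cpp_recurrence_scan(M, theta, idx[1] - 1L, idx[length(idx)] - 1L)
  delta <- steps * dt
  structure(list(t = tt, scan = range(idx), scan_t = tt[idx], theta = theta,
                 theta_percentile = theta_percentile,
                 recurrent = !is.na(delta), delta = delta, dt = dt,
                 trajectory = M),
            class = "recurrence")
}

#' @export
print.recurrence <- function(x, ...) {
  cat(sprintf("recurrence: %d scanned points, theta = %.4g (%.0f%%), %.1f%% recurrent\n",
              length(x$delta), x$theta, x$theta_percentile,
              100 * mean(x$recurrent)))
  if (!is.null(x$period))
    cat(sprintf("  dominant orbit: period %.2f s (%d peaks)\n",
                x$period, nrow(x$peaks)))
  invisible(x)
}

#' Detect periodic orbits from the recurrence-time histogram
#'
#' Bins the recurrence times \eqn{\delta \ge} `min_delay` into 1 s bins.
#' Delays below `min_delay` are quasi-periodic returns of a noisy but
#' otherwise contiguous trajectory, not orbits: the trajectory is re-scanned
#' treating such re-entries as part of the contiguous neighbourhood, so
#' \eqn{\delta} becomes the first return at least `min_delay` after the
#' anchor (raw first-return delays are kept in `delta_raw`), and points with
#' no such return are re-flagged as non-recurrent. Downstream density,
#' coalescence and perturbation measures therefore count only genuine
#' periodic returns. Peaks are maximal contiguous runs of
#' non-empty bins; those holding more than `min_peak_points` recurrent points
#' qualify as periodic orbits. The dominant orbit is the qualifying peak with
#' the most points (ties broken toward the smaller mean delay), and the
#' program's orbital period is the mean \eqn{\delta} within it.
#'
#' @param rec a `recurrence` result.
#' @param bin histogram bin width (s).
#' @param min_delay smallest delay retained (s).
#' @param min_peak_points minimum recurrent points for a qualifying peak.
#' @return the `recurrence` object augmented with `histogram` (data frame of
#'   bin lo/hi/count), `peaks` (lo, hi, n_points, mean_delay), `dominant`
#'   (row index into `peaks`, `NA` if no qualifying peak — an aperiodic
#'   program) and `period` (s).
#' @export
detect_periodic_orbit <- function(rec, bin = 1, min_delay = 5,
                                  min_peak_points = 100) {
  stopifnot(inherits(rec, "recurrence"))
  if (is.null(rec$delta_raw)) rec$delta_raw <- rec$delta
  if (!is.null(rec$trajectory)) {
    min_steps <- as.integer(round(min_delay / rec$dt))
    steps <- cpp_recurrence_scan(rec$trajectory, rec$theta,
                                 rec$scan[1] - 1L, rec$scan[2] - 1L, min_steps)
    rec$delta <- steps * rec$dt
    rec$recurrent <- !is.na(rec$delta)
  } else {
    ## delay-only input (no trajectory to re-scan): plain exclusion
    drop <- rec$recurrent & rec$delta < min_delay
    rec$recurrent[drop] <- FALSE
    rec$delta[drop] <- NA_real_
  }
  d <- rec$delta[rec$recurrent]
  rec$min_delay <- min_delay
  if (!length(d)) {
    rec$histogram <- data.frame(lo = numeric(0), hi = numeric(0),
                                count = integer(0))
    rec$peaks <- data.frame(lo = numeric(0), hi = numeric(0),
                            n_points = integer(0), mean_delay = numeric(0))
    rec$dominant <- NA_integer_
    rec$period <- NA_real_
    return(rec)
  }
  edges <- seq(min_delay, max(d) + bin, by = bin)
  counts <- as.integer(table(cut(d, edges, right = FALSE,
                                 include.lowest = FALSE)))
  hist_df <- data.frame(lo = edges[-length(edges)], hi = edges[-1],
                        count = counts)
  nonempty <- counts > 0
  runs <- rle(nonempty)
  stops <- cumsum(runs$lengths)
  starts <- stops - runs$lengths + 1
  peaks <- data.frame(lo = numeric(0), hi = numeric(0), n_points = integer(0),
                      mean_delay = numeric(0))
  for (k in which(runs$values)) {
    b0 <- starts[k]; b1 <- stops[k]
    lo <- hist_df$lo[b0]; hi <- hist_df$hi[b1]
    inpk <- d >= lo & d < hi
    if (sum(inpk) > min_peak_points)
      peaks <- rbind(peaks, data.frame(lo = lo, hi = hi,
                                       n_points = sum(inpk),
                                       mean_delay = mean(d[inpk])))
  }
  rec$histogram <- hist_df
  rec$peaks <- peaks
  if (nrow(peaks) == 0) {
    rec$dominant <- NA_integer_
    rec$period <- NA_real_
  } else {
    best <- which(peaks$n_points == max(peaks$n_points))
    if (length(best) > 1) {
      ss_log("dominant-peak tie; choosing smaller mean delay")
      best <- best[which.min(peaks$mean_delay[best])]
    }
    rec$dominant <- best
    rec$period <- peaks$mean_delay[best]
  }
  rec
}

#' Windowed recurrence density
#'
#' Fraction of recurrent points, and the mean and SD of their recurrence
#' times, in sliding windows (default 5 s advanced by 1 s) across the scan
#' range. This is the quantity whose rise marks coalescence onto the
#' attractor and whose dips mark perturbations.
#'
#' @param rec a `recurrence` result.
#' @param win,step window length and advance (s).
#' @return class `window_density`: data frame with `win_mid`, `density`,
#'   `mean_delay`, `delay_sd` (the delay columns are `NA` in windows with no
#'   recurrent point), with `win` and `step` as attributes.
#' @export
window_density <- function(rec, win = 5, step = 1) {
  stopifnot(inherits(rec, "recurrence"))
  t0 <- min(rec$scan_t)
  t1 <- max(rec$scan_t)
  starts <- seq(t0, t1 - win, by = step)
  if (!length(starts)) starts <- t0
  out <- do.call(rbind, lapply(starts, function(s) {
    inw <- rec$scan_t >= s & rec$scan_t < s + win
    d <- rec$delta[inw & rec$recurrent]
    data.frame(win_mid = s + win / 2,
               density = if (any(inw)) mean(rec$recurrent[inw]) else NA_real_,
               mean_delay = if (length(d)) mean(d) else NA_real_,
               delay_sd = if (length(d) > 1) sd(d) else NA_real_)
  }))
  structure(out, win = win, step = step, class = c("window_density",
                                                   "data.frame"))
}

#' Coalescence time
#'
#' Midpoint of the first sliding window in which at least `threshold`
#' (default 90%) of the trajectory points are recurrent — the moment the
#' trajectory is read as having arrived on the attractor.
#'
#' @param densities a `window_density` series.
#' @param threshold density threshold.
#' @return time in seconds, or `NA` if the threshold is never reached.
#' @export
coalescence_time <- function(densities, threshold = 0.90) {
  stopifnot(inherits(densities, "window_density"))
  hit <- which(densities$density >= threshold)
  if (!length(hit)) NA_real_ else densities$win_mid[hit[1]]
}

#' Detect spontaneous perturbations and classify their outcome
#'
#' Candidate perturbations are maximal runs of post-coalescence windows with
#' recurrence density below `diverge_high` (default 90%) that dip below
#' `diverge_low` (default 50%) at least once. The window of lowest density is
#' the divergent point; candidates whose divergent point lies within two
#' orbital periods of the end of the recording are discarded (the drop could
#' be the finite horizon alone). A surviving event is `not_returned` if the
#' density never again reaches `diverge_high`; otherwise it returned, and it
#' returned to the *same* manifold if at least `same_manifold_min` of the
#' recurrence delays in the final pre-divergence window extend beyond the
#' end of the divergent period (the pre-perturbation trajectory recurs after
#' the divergence).
#'
#' @param rec a `recurrence` result.
#' @param densities the matching `window_density` series.
#' @param period orbital period (s), e.g. from [detect_periodic_orbit()].
#' @param coalescence coalescence time (s); events are sought after it.
#' @param diverge_high,diverge_low density thresholds.
#' @param same_manifold_min minimal fraction of pre-divergence delays
#'   spanning the event for a `returned_same` call.
#' @return data frame of events: `span_lo`, `span_hi`, `divergent_point`,
#'   `outcome` (`returned_same` / `returned_different` / `not_returned`),
#'   `same_manifold_fraction`.
#' @export
detect_perturbations <- function(rec, densities, period, coalescence,
                                 diverge_high = 0.90, diverge_low = 0.50,
                                 same_manifold_min = 0.10) {
  stopifnot(inherits(rec, "recurrence"), inherits(densities, "window_density"))
  if (is.na(coalescence))
    ss_stop("ss_validation", "coalescence must be defined before perturbation detection")
  ev <- data.frame(span_lo = numeric(0), span_hi = numeric(0),
                   divergent_point = numeric(0), outcome = character(0),
                   same_manifold_fraction = numeric(0))
  dn <- densities[densities$win_mid > coalescence, , drop = FALSE]
  if (!nrow(dn)) return(ev)
  low <- dn$density < diverge_high
  low[is.na(low)] <- FALSE
  runs <- rle(low)
  stops <- cumsum(runs$lengths)
  starts <- stops - runs$lengths + 1
  t_end <- max(rec$t)
  win <- attr(densities, "win")
  for (k in which(runs$values)) {
    rows <- starts[k]:stops[k]
    if (!any(dn$density[rows] < diverge_low, na.rm = TRUE)) next
    div_pt <- dn$win_mid[rows[which.min(dn$density[rows])]]
    if (!is.na(period) && div_pt > t_end - 2 * period) next
    span <- c(dn$win_mid[rows[1]], dn$win_mid[rows[length(rows)]])
    after <- dn$win_mid > span[2]
    returned <- any(dn$density[after] >= diverge_high, na.rm = TRUE)
    ## final full window before the divergent period
    pre_rows <- which(densities$win_mid < span[1])
    frac <- NA_real_
    if (length(pre_rows)) {
      wmid <- densities$win_mid[pre_rows[length(pre_rows)]]
      inw <- rec$scan_t >= wmid - win / 2 & rec$scan_t < wmid + win / 2
      sel <- inw & rec$recurrent
      if (any(sel))
        frac <- mean(rec$scan_t[sel] + rec$delta[sel] > span[2])
    }
    outcome <- if (!returned) "not_returned"
               else if (!is.na(frac) && frac >= same_manifold_min) "returned_same"
               else "returned_different"
    ev <- rbind(ev, data.frame(span_lo = span[1], span_hi = span[2],
                               divergent_point = div_pt, outcome = outcome,
                               same_manifold_fraction = frac))
  }
  ev
}
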