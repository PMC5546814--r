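#' Screen the population for putative motorneurons locked to the nerve
#'
#' For each neuron and each delay on a 0-25 ms grid, the fraction of its
#' spikes followed by a nerve spike at that delay within a +/-2 ms jitter;
#' reported per neuron as the maximum over delays. A motorneuron with an
#' axon in the nerve shows ~1:1 locking (probability near 1 at its
#' conduction delay); chance level for independent trains is
#' \eqn{1 - \exp(-\lambda_{nerve} \cdot 4\,\mathrm{ms})}.
#'
#' @param x a [spike_data] object.
#' @param nerve nerve spike times (s).
#' @param delays delay grid (s).
#' @param jitter allowed jitter around each delay (s).
#' @return class `locking_screen`: data frame with `neuron`, `n_spikes`,
#'   `p_max` (`NA` for silent neurons), `best_delay` (s); full probability
#'   matrix in `attr(, "prob")`.
#' @export
screen_motorneurons <- function(x, nerve, delays = seq(0, 0.025, by = 0.001),
                                jitter = 0.002) {
  stopifnot(inherits(x, "spike_data"))
  nerve <- sort(as.numeric(nerve))
  prob <- matrix(NA_real_, length(x$spikes), length(delays),
                 dimnames = list(x$neuron_ids, NULL))
  for (i in seq_along(x$spikes)) {
    s <- x$spikes[[i]]
    if (!length(s)) next
    for (k in seq_along(delays)) {
      lo <- s + delays[k] - jitter
      hi <- s + delays[k] + jitter
      hit <- findInterval(hi, nerve) > findInterval(lo, nerve)
      prob[i, k] <- mean(hit)
    }
  }
  p_max <- apply(prob, 1, function(p) if (all(is.na(p))) NA_real_ else max(p))
  best <- apply(prob, 1, function(p) if (all(is.na(p))) NA_real_
                                     else delays[which.max(p)])
  out <- data.frame(neuron = x$neuron_ids, n_spikes = lengths(x$spikes),
                    p_max = p_max, best_delay = best)
  structure(out, prob = prob, delays = delays, jitter = jitter,
            class = c("locking_screen", "data.frame"))
}

## lagged design matrix: columns beta_{i,h}, h = 1..m steps of the grid
decoder_design <- function(P, m) {
  n <- nrow(P); d <- ncol(P)
  X <- matrix(NA_real_, n, d * m)
  for (h in seq_len(m)) {
    rows <- (h + 1):n
    X[rows, ((h - 1) * d + 1):(h * d)] <- P[rows - h, , drop = FALSE]
  }
  colnames(X) <- paste0("d", rep(seq_len(d), m), "_h", rep(seq_len(m), each = d))
  X
}

#' Fit the log-link history decoder of nerve firing rate
#'
#' Fits \eqn{f(t) = \exp(\beta_0 + \sum_{i=1}^d \sum_{h=1}^m \beta_{i,h}
#' P_i(t-h))}: the nerve rate as a function of the recent history of the
#' low-dimensional population trajectory, with lags in 10 ms steps of the
#' trajectory grid. Estimation is iteratively reweighted least squares with
#' log link and Poisson-type variance on the binned rate (a Gaussian fit to
#' the log rate is available as `family = "gaussian_log"`), with a mild
#' ridge penalty (default 1e-6) on the slope coefficients for numerical
#' stability; collinear lag columns therefore fall back to the ridge
#' solution rather than failing.
#'
#' @param P trajectory matrix (time x d) on the nerve-rate grid.
#' @param nerve_rate nerve firing rate (spikes/s) on the same grid, e.g.
#'   from [spike_density()] of the nerve train with the program's sigma.
#' @param t time grid (s).
#' @param window fit window `(t0, t1)` in seconds.
#' @param history_ms history duration (ms), a multiple of `lag_step_ms`.
#' @param lag_step_ms lag step (ms); must match the grid step.
#' @param ridge ridge penalty on slope coefficients.
#' @param family `"poisson"` (IRLS, default) or `"gaussian_log"`.
#' @param max_iter,tol IRLS iteration cap and relative deviance tolerance.
#' @return class `decoding_model`: list with `beta0`, `beta` (d x m matrix),
#'   `history_ms`, `lag_step_ms`, `window`, `d`, `family`, `iterations`.
#' @export
fit_decoder <- function(P, nerve_rate, t, window, history_ms = 100,
                        lag_step_ms = 10, ridge = 1e-6,
                        family = c("poisson", "gaussian_log"),
                        max_iter = 100, tol = 1e-6) {
  family <- match.arg(family)
  P <- as.matrix(P)
  d <- ncol(P)
  m <- as.integer(round(history_ms / lag_step_ms))
  dt_grid <- median(diff(t)) * 1000
  if (abs(dt_grid - lag_step_ms) > 1e-6)
    ss_stop("ss_validation", "lag_step_ms (%g) must equal the grid step (%g ms)",
            lag_step_ms, dt_grid)
  X <- decoder_design(P, m)
  rows <- which(t >= window[1] & t < window[2] & !rowSums(is.na(X)))
  if (length(rows) < 2 * (d * m + 1))
    ss_stop("ss_validation", "fit window too short for %d coefficients", d * m + 1)
  Xw <- cbind(1, X[rows, , drop = FALSE])
  y <- nerve_rate[rows]
  pen <- c(0, rep(ridge, d * m))   # intercept unpenalised
  if (family == "gaussian_log") {
    z <- log(pmax(y, 1e-8))
    beta <- solve(crossprod(Xw) + diag(pen), crossprod(Xw, z))
    iter <- 1L
  } else {
    eta <- rep(log(mean(y) + 1e-8), length(y))
    beta <- c(eta[1], rep(0, d * m))
    dev_old <- Inf
    for (iter in seq_len(max_iter)) {
      mu <- exp(eta)
      wts <- mu
      z <- eta + (y - mu) / mu
      beta_old <- beta
      beta <- solve(crossprod(Xw * wts, Xw) + diag(pen),
                    crossprod(Xw * wts, z))
      eta <- as.vector(Xw %*% beta)
      if (any(eta > 700))
        ss_stop("ss_convergence", "decoder diverged at iteration %d", iter)
      mu <- exp(eta)
      dev <- 2 * sum(ifelse(y > 0, y * log(y / mu), 0) - (y - mu))
      if ((is.finite(dev_old) && abs(dev - dev_old) < tol * (abs(dev) + 0.1)) ||
          max(abs(beta - beta_old)) < 1e-10)
        break
      dev_old <- dev
    }
    if (iter == max_iter)
      ss_stop("ss_convergence",
              "IRLS did not converge in %d iterations (deviance %.4g)",
              max_iter, dev)
  }
  beta <- as.vector(beta)
  structure(list(beta0 = beta[1],
                 beta = matrix(beta[-1], nrow = d,
                               dimnames = list(paste0("dim", seq_len(d)),
                                               paste0("h", seq_len(m)))),
                 history_ms = history_ms, lag_step_ms = lag_step_ms,
                 window = window, d = d, family = family, iterations = iter),
            class = "decoding_model")
}

#' @export
print.decoding_model <- function(x, ...) {
  cat(sprintf("decoding model: %d dims x %d lags (%d ms history), beta0 = %.3f (%s, %d iter)\n",
              x$d, ncol(x$beta), x$history_ms, x$beta0, x$family, x$iterations))
  invisible(x)
}

#' Forecast the nerve rate from the trajectory alone
#'
#' Evaluates the fitted decoder over a window using only the trajectory as
#' input — no nerve data from the forecast window enters the prediction.
#' When the observed rate is supplied the forecast is scored by the
#' correlation R and the median absolute error; R is undefined (`NA`) if
#' either series has zero variance, the MAE is kept.
#'
#' @param model a `decoding_model`.
#' @param P trajectory matrix on the grid `t`.
#' @param t time grid (s).
#' @param window forecast window `(t0, t1)` (s); truncated with a warning if
#'   it exceeds the recording.
#' @param observed optional observed nerve rate on the same grid.
#' @return class `forecast_score`: list with `t`, `rate` (forecast), and if
#'   observed was given `R` and `MAE`.
#' @export
forecast <- function(model, P, t, window, observed = NULL) {
  stopifnot(inherits(model, "decoding_model"))
  P <- as.matrix(P)
  m <- ncol(model$beta)
  if (window[2] > max(t) + 1e-9) {
    warning("forecast window exceeds recording; truncated")
    window[2] <- max(t)
  }
  X <- decoder_design(P, m)
  rows <- which(t >= window[1] & t < window[2] & !rowSums(is.na(X)))
  eta <- model$beta0 + as.vector(X[rows, , drop = FALSE] %*% as.vector(model$beta))
  out <- list(t = t[rows], rate = exp(eta), window = window)
  if (!is.null(observed)) {
    y <- observed[rows]
    out$MAE <- median(abs(out$rate - y))
    out$R <- if (sd(y) == 0 || sd(out$rate) == 0) NA_real_
             else cor(out$rate, y)
  }
  structure(out, class = "forecast_score")
}

#' Sliding fit/forecast evaluation over history durations
#'
#' Cross-validates the decoder: for each history duration on the grid, fit
#' on a 40 s window, forecast the next 10 s from the trajectory alone, score
#' (R, median absolute error), then advance both windows by 1 s until the
#' recording is exhausted. The best history is the one with the smallest
#' median MAE over forecast windows.
#'
#' @param P trajectory matrix on grid `t`.
#' @param nerve_rate observed nerve rate on the same grid.
#' @param t time grid (s).
#' @param history_grid history durations to try (ms).
#' @param fit_s,forecast_s,step_s window lengths and advance (s).
#' @param start_t first fit-window start (s); default `min(t)`.
#' @param ... further arguments to [fit_decoder()].
#' @return class `decoding_evaluation`: list with `scores` (data frame:
#'   history_ms, window_start, R, MAE), `summary` (per history: mean R,
#'   2 SEM, median MAE), `best_history` (ms).
#' @export
evaluate_decoding <- function(P, nerve_rate, t, history_grid = seq(50, 200, by = 10),
                              fit_s = 40, forecast_s = 10, step_s = 1,
                              start_t = NULL, ...) {
  P <- as.matrix(P)
  if (is.null(start_t)) start_t <- min(t)
  t_end <- max(t)
  starts <- seq(start_t, t_end - fit_s - forecast_s, by = step_s)
  if (!length(starts))
    ss_stop("ss_validation", "recording too short for one fit+forecast pair")
  rows_list <- list()
  scores <- do.call(rbind, lapply(history_grid, function(hm) {
    do.call(rbind, lapply(starts, function(s0) {
      mod <- fit_decoder(P, nerve_rate, t, window = c(s0, s0 + fit_s),
                         history_ms = hm, ...)
      fc <- forecast(mod, P, t, window = c(s0 + fit_s, s0 + fit_s + forecast_s),
                     observed = nerve_rate)
      data.frame(history_ms = hm, window_start = s0, R = fc$R, MAE = fc$MAE)
    }))
  }))
  summ <- do.call(rbind, lapply(split(scores, scores$history_ms), function(df) {
    data.frame(history_ms = df$history_ms[1],
               mean_R = mean(df$R, na.rm = TRUE),
               sem2_R = 2 * sd(df$R, na.rm = TRUE) / sqrt(sum(!is.na(df$R))),
               median_MAE = median(df$MAE, na.rm = TRUE))
  }))
  best <- summ$history_ms[which.min(summ$median_MAE)]
  structure(list(scores = scores, summary = summ, best_history = best),
            class = "decoding_evaluation")
}

#' @export
print.decoding_evaluation <- function(x, ...) {
  b <- x$summary[x$summary$history_ms == x$best_history, ]
  cat(sprintf("decoding evaluation over %d histories; best %d ms: median MAE %.3g, mean R %.3f\n",
              nrow(x$summary), x$best_history, b$median_MAE, b$mean_R))
  invisible(x)
}
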