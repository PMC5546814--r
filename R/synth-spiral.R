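#' Parameters of the latent decaying-spiral population model
#'
#' Ground-truth generator for validating the full analysis chain. A 2-D
#' latent orbit \eqn{z(\tau) = A(\tau)(\cos\omega\tau, \sin\omega\tau)} with
#' \eqn{\omega = 2\pi/\mathrm{period}} and amplitude
#' \eqn{A(\tau) = \mathrm{ramp}(\tau)\, e^{-\kappa\tau}} decays at a known
#' contraction rate (`contraction_per_s` = fraction of amplitude retained per
#' second, so \eqn{\kappa = -\log(\mathrm{contraction})}); the logistic ramp
#' reaches the orbit over `transient` seconds so that coalescence detection
#' has something to find. Each neuron couples to the orbit through its own
#' gain and preferred phase, giving intensity
#' \eqn{\lambda_i(t) = \mathrm{baseline} + g_i \max\{0, \cos(\omega\tau -
#' \phi_i)\} A(\tau)}. Spikes are drawn as an inhomogeneous renewal process
#' by time rescaling: increments of the integrated intensity are
#' Gamma(shape = `regularity`, rate = `regularity`), so `regularity = 1` is
#' the inhomogeneous Poisson special case and larger values give the
#' sub-Poisson inter-spike regularity of rhythmically driven neurons.
#'
#' Default sizes emulate a pedal-ganglion recording: 150 neurons, 30 s of
#' spontaneous activity followed by 95 s of evoked activity, a 10 s orbit
#' period and 98%/s amplitude retention. The default coupling is long
#' tailed, as in such recordings, where a minority of neurons dominates the
#' population dynamics: a `strong_fraction` of neurons draw gains with mean
#' `gain_mean` (the rhythm carriers) and the rest with mean
#' `weak_gain_mean` (a slow, weakly modulated majority, which also sets the
#' population inter-spike interval statistics and hence the kernel width
#' that downstream spike-density analysis infers).
#'
#' @param period orbit period (s), `> 0`.
#' @param contraction_per_s fraction of amplitude retained per second, in
#'   (0, 1].
#' @param n_neurons number of neurons, `>= 2`.
#' @param baseline_rate spontaneous rate (spikes/s).
#' @param gains,phases per-neuron coupling gains (spikes/s) and preferred
#'   phases (rad); by default phases are uniform on \eqn{[0, 2\pi)} and
#'   gains come from the two-component mixture below.
#' @param gain_mean mean gain of the strong (rhythm-carrying) component
#'   (spikes/s; Gamma with shape 2).
#' @param weak_gain_mean mean gain of the weak majority (spikes/s).
#' @param strong_fraction fraction of strongly coupled neurons.
#' @param regularity renewal shape parameter (ISI CV = `1/sqrt(regularity)`
#'   at constant rate); 1 = Poisson, default 6.
#' @param transient pre-coalescence approach duration (s).
#' @param pre_s,post_s spontaneous and evoked spans (s); the stimulus is on
#'   during `[pre_s, pre_s + 2.5]`.
#' @param dt latent time step (s).
#' @param seed RNG seed for gains, phases and spikes.
#' @return an object of class `spiral_params`.
#' @export
spiral_params <- function(period = 10, contraction_per_s = 0.98,
                          n_neurons = 150, baseline_rate = 0.3,
                          gains = NULL, phases = NULL, gain_mean = 10,
                          weak_gain_mean = 0.5, strong_fraction = 0.1,
                          regularity = 6, transient = 10, pre_s = 30,
                          post_s = 95, dt = 0.01, seed = 1) {
  if (period <= 0) ss_stop("ss_validation", "period must be > 0")
  if (!(contraction_per_s > 0 && contraction_per_s <= 1))
    ss_stop("ss_validation", "contraction_per_s must be in (0, 1]")
  if (n_neurons < 2) ss_stop("ss_validation", "n_neurons must be >= 2")
  if (regularity < 1) ss_stop("ss_validation", "regularity must be >= 1")
  structure(list(period = period, contraction_per_s = contraction_per_s,
                 n_neurons = n_neurons, baseline_rate = baseline_rate,
                 gains = gains, phases = phases, gain_mean = gain_mean,
                 weak_gain_mean = weak_gain_mean,
                 strong_fraction = strong_fraction,
                 regularity = regularity, transient = transient,
                 pre_s = pre_s, post_s = post_s, dt = dt, seed = seed),
            class = "spiral_params")
}

## inhomogeneous renewal spikes by time rescaling of the integrated
## intensity (grid-wise trapezoid-free cumulative sum at step dt); gamma
## increments with mean 1 preserve the rate, shape = 1 recovers Poisson
draw_renewal_spikes <- function(lambda, tt, dt, shape) {
  Lam <- cumsum(lambda) * dt
  total <- Lam[length(Lam)]
  if (total <= 0) return(numeric(0))
  s <- numeric(0)
  last <- 0
  repeat {
    n_draw <- ceiling(total - last + 4 * sqrt((total + 1) / shape) + 10)
    s <- c(s, last + cumsum(rgamma(n_draw, shape = shape, rate = shape)))
    last <- s[length(s)]
    if (last >= total) break
  }
  s <- s[s <= total]
  if (!length(s)) return(numeric(0))
  ## invert Lambda; nudge flat (zero-rate) stretches to keep x strictly sorted
  x <- c(0, Lam) + seq_len(length(Lam) + 1) * 1e-12
  stats::approx(x, c(tt[1], tt), xout = s, rule = 2)$y
}

## long-tailed coupling: strong minority + weakly modulated majority
draw_mixture_gains <- function(p) {
  strong <- runif(p$n_neurons) < p$strong_fraction
  g <- rgamma(p$n_neurons, shape = 2, scale = p$weak_gain_mean / 2)
  g[strong] <- rgamma(sum(strong), shape = 2, scale = p$gain_mean / 2)
  g
}

## amplitude envelope on post-stimulus time tau (vectorised); the logistic
## approach reaches half the orbit radius at 0.8*transient and ~90% at
## `transient` itself, so the parameter names the arrival time on the orbit
spiral_envelope <- function(tau, period, contraction, transient) {
  kappa <- -log(contraction)
  ramp <- if (transient > 0)
    1 / (1 + exp(-(tau - 0.8 * transient) / (transient / 10)))
  else 1
  ifelse(tau > 0, ramp * exp(-kappa * tau), 0)
}

#' Bare spiral / circular orbit trajectory
#'
#' Convenience generator of a low-dimensional trajectory on a (optionally
#' decaying, optionally noisy) planar orbit, used to exercise recurrence and
#' local-linear estimation directly, without the spike-level machinery.
#'
#' @param period orbit period (s).
#' @param contraction_per_s amplitude retained per second (1 = pure circle).
#' @param duration length (s).
#' @param dt time step (s).
#' @param radial_noise multiplicative radial noise SD (e.g. 0.05 for 5%).
#' @param radius initial orbit radius.
#' @param transient optional approach duration (s): the trajectory reaches
#'   ~90% of the orbit radius at `transient` through the same logistic ramp
#'   the population generator uses (0 = start on the orbit).
#' @param seed RNG seed (only used when `radial_noise > 0`).
#' @return list with `t` and trajectory matrix `P` (time x 2).
#' @export
spiral_trajectory <- function(period = 10, contraction_per_s = 1,
                              duration = 95, dt = 0.01, radial_noise = 0,
                              radius = 1, transient = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tt <- seq(0, duration, by = dt)
  om <- 2 * pi / period
  r <- radius * spiral_envelope(pmax(tt, dt / 2), period, contraction_per_s,
                                transient)
  if (radial_noise > 0) r <- r * (1 + radial_noise * rnorm(length(tt)))
  list(t = tt, P = cbind(r * cos(om * tt), r * sin(om * tt)))
}

#' Generate a synthetic spiral-attractor population recording
#'
#' Draws a population spike-train recording from the latent decaying-spiral
#' model described in [spiral_params()], together with the ground truth
#' needed for parameter-recovery tests.
#'
#' @param params a [spiral_params] object.
#' @return list with elements `spikes` (a [spike_data]) and `truth`, where
#'   `truth` holds the per-step dominant eigenvalue parts (`true_eigen_real`
#'   \eqn{a = \Delta t \log(\mathrm{contraction})}, `true_eigen_imag`
#'   \eqn{b = 2\pi\Delta t/\mathrm{period}}), `true_period` (s),
#'   `true_contraction` (%/s), the latent trajectory (`t`, `latent`), the
#'   per-neuron `gains` and `phases`, and `perturbation_windows` (empty; see
#'   [inject_perturbation()]).
#' @examples
#' pop <- generate_spiral_population(spiral_params(n_neurons = 20, post_s = 30))
#' pop$spikes
#' @export
generate_spiral_population <- function(params) {
  stopifnot(inherits(params, "spiral_params"))
  p <- params
  set.seed(p$seed)
  gains <- p$gains
  phases <- p$phases
  if (is.null(gains)) gains <- draw_mixture_gains(p)
  if (is.null(phases)) phases <- runif(p$n_neurons, 0, 2 * pi)
  gains <- rep_len(gains, p$n_neurons)
  phases <- rep_len(phases, p$n_neurons)
  duration <- p$pre_s + p$post_s
  om <- 2 * pi / p$period
  env <- function(t) spiral_envelope(t - p$pre_s, p$period,
                                     p$contraction_per_s, p$transient)
  n_clipped <- 0L
  spikes <- vector("list", p$n_neurons)
  tt_grid <- seq(0, duration, by = p$dt)
  envv <- env(tt_grid)
  for (i in seq_len(p$n_neurons)) {
    lam <- p$baseline_rate +
      gains[i] * pmax(0, cos(om * (tt_grid - p$pre_s) - phases[i])) * envv
    neg <- lam < 0
    if (any(neg)) {
      n_clipped <- n_clipped + sum(neg)
      lam[neg] <- 0
    }
    spikes[[i]] <- draw_renewal_spikes(lam, tt_grid, p$dt, p$regularity)
  }
  if (n_clipped > 0) ss_log("clipped %d negative rate values at 0", n_clipped)
  names(spikes) <- sprintf("n%03d", seq_len(p$n_neurons))
  sd_obj <- spike_data(spikes, duration = duration, stim_on = p$pre_s,
                       stim_off = min(p$pre_s + 2.5, duration))
  tt <- seq(0, duration, by = p$dt)
  tau <- tt - p$pre_s
  A <- spiral_envelope(tau, p$period, p$contraction_per_s, p$transient)
  latent <- cbind(A * cos(om * tau), A * sin(om * tau))
  truth <- list(
    true_eigen_real = p$dt * log(p$contraction_per_s),
    true_eigen_imag = 2 * pi * p$dt / p$period,
    true_period = p$period,
    true_contraction = 100 * p$contraction_per_s,
    true_beta = NULL,
    perturbation_windows = list(),
    t = tt, latent = latent, gains = gains, phases = phases,
    transient = p$transient, stim_on = p$pre_s)
  list(spikes = sd_obj, truth = truth)
}

#' Generate phase-locked nerve output from a trajectory
#'
#' Draws a synthetic motor-nerve spike train whose intensity is the log-link
#' history model \eqn{g(t) = \exp(\beta_0 + \sum_i \sum_h \beta_{i,h}
#' P_i(t-h))} evaluated on the trajectory grid, the same functional form the
#' decoder fits, so decoding-recovery tests have an exact ground truth.
#' Spikes are drawn as an inhomogeneous Poisson process with the grid-wise
#' intensity (per-bin Poisson counts, uniform placement within bins).
#'
#' @param P trajectory matrix (time x d).
#' @param beta0 intercept (log spikes/s).
#' @param beta coefficient matrix, d rows x `history_steps` columns; column h
#'   multiplies `P[t - h, ]`.
#' @param dt grid step (s).
#' @param t0 time of the first trajectory row (s), used for spike times.
#' @param seed RNG seed.
#' @return list with `spike_times` (s), `rate` (true intensity, spikes/s) and
#'   `t` (grid, s); rows before the history is complete have `NA` rate and
#'   emit no spikes.
#' @export
generate_nerve_output <- function(P, beta0, beta, dt = 0.01, t0 = 0,
                                  seed = NULL) {
  P <- as.matrix(P)
  if (nrow(P) == 0) ss_stop("ss_validation", "empty projection")
  beta <- as.matrix(beta)
  m <- ncol(beta)
  if (nrow(P) <= m)
    ss_stop("ss_validation", "projection must be longer than history_steps")
  if (nrow(beta) != ncol(P))
    ss_stop("ss_validation", "beta must have one row per trajectory dimension")
  if (!is.null(seed)) set.seed(seed)
  eta <- rep(beta0, nrow(P))
  for (h in seq_len(m)) {
    lag <- rbind(matrix(NA_real_, h, ncol(P)), P[seq_len(nrow(P) - h), , drop = FALSE])
    eta <- eta + as.vector(lag %*% beta[, h])
  }
  if (any(eta > 700, na.rm = TRUE))
    ss_stop("ss_validation",
            "exp overflow in nerve intensity; rescale beta (max eta = %.1f)",
            max(eta, na.rm = TRUE))
  g <- exp(eta)
  counts <- rpois(nrow(P), ifelse(is.na(g), 0, g) * dt)
  tt <- t0 + (seq_len(nrow(P)) - 1) * dt
  st <- sort(rep(tt, counts) + runif(sum(counts), 0, dt))
  st <- st[st <= tt[length(tt)]]   # keep spikes inside the grid span
  list(spike_times = st, rate = g, t = tt)
}

#' Inject a perturbation into a population recording
#'
#' Modifies spikes inside a time window, leaving everything outside intact:
#' `suppress` thins spikes (probability `prob` of deletion), `remap`
#' re-assigns each neuron's in-window spikes to a shifted phase pattern (an
#' independent full-range cyclic time shift of the window per neuron, with
#' the in-window order reversed for a random half of the neurons), which
#' breaks the population phase relations and pushes the trajectory off the
#' orbit while preserving each neuron's rate.
#'
#' @param x a [spike_data] object.
#' @param window numeric `(t0, t1)` inside the recording.
#' @param mode `"suppress"` or `"remap"`.
#' @param prob suppression probability for `mode = "suppress"`.
#' @param seed RNG seed.
#' @return a [spike_data] with the perturbation applied; the window is
#'   recorded in `attr(, "perturbation")`.
#' @export
inject_perturbation <- function(x, window, mode = c("suppress", "remap"),
                                prob = 1, seed = NULL) {
  stopifnot(inherits(x, "spike_data"))
  mode <- match.arg(mode)
  if (length(window) != 2 || window[1] < 0 || window[2] > x$duration ||
      window[1] > window[2])
    ss_stop("ss_validation", "window must lie inside the recording")
  if (diff(window) == 0) return(x)
  if (!is.null(seed)) set.seed(seed)
  len <- diff(window)
  out <- x
  for (id in names(x$spikes)) {
    s <- x$spikes[[id]]
    inside <- s >= window[1] & s < window[2]
    if (!any(inside)) next
    if (mode == "suppress") {
      drop <- inside & (runif(length(s)) < prob)
      out$spikes[[id]] <- s[!drop]
    } else {
      ## independent full-range cyclic shift, plus time reversal for half
      ## the neurons: minimises any residual coherent (on-orbit) component
      shift <- runif(1, 0, 1) * len
      rel <- s[inside] - window[1]
      if (runif(1) < 0.5) rel <- len - rel
      s[inside] <- window[1] + (rel + shift) %% len
      out$spikes[[id]] <- sort(s)
    }
  }
  attr(out, "perturbation") <- list(window = window, mode = mode)
  out
}
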