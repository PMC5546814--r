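#' Parameters of the Matsuoka mutual-inhibition oscillator
#'
#' A small network of neurons with membrane time constant `tau_a`, adaptation
#' time constant `tau_y` and adaptation strength `gamma`, coupled by an
#' inhibitory weight matrix `W` (off-diagonal entries `<= 0`, zero diagonal)
#' and driven by input `c`. With constant drive the network produces
#' self-sustained alternating oscillation of its firing rates even though no
#' neuron is an endogenous oscillator: the canonical minimal model of a
#' central pattern generator realising a periodic attractor.
#'
#' Defaults are the demonstration values `tau_a = 0.025` s, `tau_y = 0.2` s,
#' `gamma = 2`, drive `c = 3`, with all-pairs mutual inhibition of weight
#' `-2` (the weight is a modelling choice, exposed here).
#'
#' @param tau_a membrane time constant (s), `> 0`.
#' @param tau_y adaptation time constant (s), `> 0`.
#' @param gamma adaptation strength (dimensionless), `>= 0`.
#' @param W inhibitory weight matrix; entry `W[j, i]` is the weight from
#'   neuron j onto neuron i. Off-diagonal entries must be `<= 0`, the
#'   diagonal 0. Default: 3 neurons, all pairs at `-2`.
#' @param c drive: a scalar, a per-neuron vector, or a function of time
#'   returning the per-neuron drive.
#' @return an object of class `matsuoka_params`.
#' @export
matsuoka_params <- function(tau_a = 0.025, tau_y = 0.2, gamma = 2,
                            W = NULL, c = 3) {
  if (is.null(W)) {
    W <- matrix(-2, 3, 3)
    diag(W) <- 0
  }
  W <- as.matrix(W)
  n <- nrow(W)
  if (ncol(W) != n) ss_stop("ss_validation", "W must be square")
  if (any(diag(W) != 0)) ss_stop("ss_validation", "diagonal of W must be 0")
  if (any(W > 0)) ss_stop("ss_validation", "W entries must be <= 0 (inhibition)")
  if (!(tau_a > 0 && tau_y > 0 && gamma >= 0))
    ss_stop("ss_validation", "need tau_a > 0, tau_y > 0, gamma >= 0")
  if (!is.function(c)) {
    c <- rep_len(as.numeric(c), n)
  }
  structure(list(tau_a = tau_a, tau_y = tau_y, gamma = gamma, W = W, c = c,
                 n = n),
            class = "matsuoka_params")
}

#' Simulate the Matsuoka oscillator
#'
#' Integrates the rate model
#' \deqn{\tau_a \dot a_i = -a_i + c_i + \sum_j w_{ji} r_j - \gamma y_i,
#'       \qquad \tau_y \dot y_i = -y_i + r_i,
#'       \qquad r_i = \max\{0, a_i\}}
#' with fixed-step 4th-order Runge-Kutta (via \pkg{deSolve}) on the `dt`
#' grid. Deterministic given its inputs. A single uncoupled neuron converges
#' to the fixed point `r* = c / (1 + gamma)`; coupled neurons with constant
#' drive settle onto a limit cycle of alternating bursts.
#'
#' @param params a [matsuoka_params] object.
#' @param duration simulated span (s).
#' @param dt integration step (s); must satisfy `dt <= tau_a / 5` so the
#'   fastest time constant is resolved.
#' @param initial optional list with numeric vectors `a` and `y` (defaults:
#'   small distinct positive `a` to break symmetry, `y = 0`).
#' @return class `matsuoka_sim`: list with `t`, rate matrix `r` (time x
#'   neuron), activations `a`, adaptation `y`, and `params`.
#' @examples
#' sim <- simulate_matsuoka(matsuoka_params(), duration = 2)
#' matplot(sim$t, sim$r, type = "l", lty = 1, xlab = "s", ylab = "rate")
#' @export
simulate_matsuoka <- function(params, duration, dt = 0.001, initial = NULL) {
  stopifnot(inherits(params, "matsuoka_params"))
  if (duration <= 0) ss_stop("ss_validation", "duration must be > 0")
  if (dt > params$tau_a / 5)
    ss_stop("ss_validation", "dt must be <= tau_a/5 = %g s", params$tau_a / 5)
  n <- params$n
  if (is.null(initial))
    initial <- list(a = 0.1 * seq_len(n), y = rep(0, n))
  y0 <- c(initial$a, initial$y)
  drive <- if (is.function(params$c)) params$c else function(t) params$c
  Wt <- t(params$W)
  rhs <- function(t, s, p) {
    a <- s[1:n]
    y <- s[(n + 1):(2 * n)]
    r <- pmax(0, a)
    list(c((-a + drive(t) + as.vector(Wt %*% r) - params$gamma * y) / params$tau_a,
           (-y + r) / params$tau_y))
  }
  times <- seq(0, duration, by = dt)
  out <- deSolve::ode(y0, times, rhs, parms = NULL, method = "rk4")
  bad <- which(!apply(is.finite(out[, -1, drop = FALSE]), 1, all))
  if (length(bad))
    ss_stop("ss_integration", "non-finite state at t = %g s", out[bad[1], 1])
  a <- out[, 1 + (1:n), drop = FALSE]
  y <- out[, 1 + n + (1:n), drop = FALSE]
  structure(list(t = out[, 1], r = pmax(a, 0), a = a, y = y, params = params),
            class = "matsuoka_sim")
}

#' @export
print.matsuoka_sim <- function(x, ...) {
  cat(sprintf("matsuoka_sim: %d neurons, %.2f s at dt = %g s\n",
              ncol(x$r), max(x$t), x$t[2] - x$t[1]))
  invisible(x)
}
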