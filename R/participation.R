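#' Single-neuron participation in the low-dimensional trajectory
#'
#' A neuron's participation in program m is the eigenvalue-weighted L1 norm
#' of its loadings on the retained principal axes,
#' \eqn{\rho_i^m = \sum_{j=1}^d |\lambda_j^m W_j^m(i)|}, normalised within
#' the program to the maximum participation (%) so programs are comparable.
#'
#' @param embedding an `embedding` (see [embed_population()]).
#' @return data frame (class `participation`) with `neuron`, `rho`,
#'   `rho_norm` (0-100, exactly one neuron at 100).
#' @export
participation_scores <- function(embedding) {
  stopifnot(inherits(embedding, "embedding"))
  d <- embedding$d
  W <- embedding$axes[, seq_len(d), drop = FALSE]
  lam <- embedding$eigvals[seq_len(d)]
  rho <- rowSums(abs(sweep(W, 2, lam, `*`)))
  structure(data.frame(neuron = embedding$neuron_ids, rho = rho,
                       rho_norm = 100 * rho / max(rho), row.names = NULL),
            class = c("participation", "data.frame"))
}

#' Participation across the programs of a preparation
#'
#' @param embeddings list of `embedding`s over the same neurons (programs in
#'   evocation order).
#' @return list with `table` (per neuron: rho_norm per program,
#'   `max_over_programs`, `max_change_between_consecutive`), `per_program`
#'   (list of [participation_scores()] frames) and `changes` (per-neuron
#'   participation deltas between all program pairs, for the noise model).
#' @export
participation_table <- function(embeddings) {
  per <- lapply(embeddings, participation_scores)
  ids <- per[[1]]$neuron
  M <- sapply(per, function(p) p$rho_norm)
  colnames(M) <- paste0("program", seq_along(per))
  cons <- if (ncol(M) > 1)
    apply(abs(M[, -1, drop = FALSE] - M[, -ncol(M), drop = FALSE]), 1, max)
  else rep(NA_real_, nrow(M))
  pairs <- utils::combn(ncol(M), 2)
  changes <- as.vector(apply(pairs, 2, function(pr) M[, pr[2]] - M[, pr[1]]))
  list(table = data.frame(neuron = ids, M,
                          max_over_programs = apply(M, 1, max),
                          max_change_between_consecutive = cons),
       per_program = per, changes = changes)
}

#' Gaussian noise model for participation changes, with outlier detection
#'
#' Fits a Gaussian to the distribution of between-program participation
#' changes by iterative elimination: fit mean and SD, eliminate the point
#' furthest from the mean, refit, and continue while the eliminated point is
#' implausible under the current fit — its log density below that of the
#' mean +/- 3 SD level (equivalently, while the furthest point lies outside
#' 3 SD). The final model is the fit once no retained point is that extreme.
#' Changes beyond `mean +/- sd_mult * SD` of the final model mark strongly
#' variable neurons.
#'
#' @param changes numeric vector of participation deltas, length `>= 10`.
#' @param sd_mult outlier threshold in SDs of the final model.
#' @return class `noise_model`: list with `mu`, `sd`, `threshold_lo`,
#'   `threshold_hi`, `outliers` (indices into `changes`), `n_iterations`,
#'   `loglik` trace.
#' @export
fit_noise_model <- function(changes, sd_mult = 3) {
  x <- as.numeric(changes)
  if (length(x) < 10)
    ss_stop("ss_insufficient", "need >= 10 participation changes, got %d",
            length(x))
  keep <- rep(TRUE, length(x))
  ll <- numeric(0)
  iter <- 0L
  repeat {
    mu <- mean(x[keep])
    s <- sqrt(mean((x[keep] - mu)^2))   # ML variance
    ll <- c(ll, sum(dnorm(x[keep], mu, s, log = TRUE)))
    far <- which.max(abs(x - mu) * keep)
    if (s == 0 || abs(x[far] - mu) <= sd_mult * s || sum(keep) <= 3) break
    keep[far] <- FALSE
    iter <- iter + 1L
  }
  out <- which(x < mu - sd_mult * s | x > mu + sd_mult * s)
  structure(list(mu = mu, sd = s,
                 threshold_lo = mu - sd_mult * s,
                 threshold_hi = mu + sd_mult * s,
                 outliers = out, n_iterations = iter, loglik = ll,
                 n_retained = sum(keep)),
            class = "noise_model")
}

#' @export
print.noise_model <- function(x, ...) {
  cat(sprintf("noise model: N(%.3g, %.3g^2), thresholds [%.3g, %.3g], %d outliers (%d iterations)\n",
              x$mu, x$sd, x$threshold_lo, x$threshold_hi,
              length(x$outliers), x$n_iterations))
  invisible(x)
}

#' Hellinger distance between two binned participation distributions
#'
#' @param a,b numeric vectors of normalised participation (0-100).
#' @param bins number of equal-width bins over `range`.
#' @param range binning range.
#' @return distance in [0, 1]; 0 iff the binned distributions coincide, 1
#'   for non-overlapping histograms.
#' @export
hellinger_distance <- function(a, b, bins = 20, range = c(0, 100)) {
  edges <- seq(range[1], range[2], length.out = bins + 1)
  p <- tabulate(findInterval(a, edges, rightmost.closed = TRUE), bins)
  q <- tabulate(findInterval(b, edges, rightmost.closed = TRUE), bins)
  p <- p / sum(p); q <- q / sum(q)
  sqrt(max(0, 1 - sum(sqrt(p * q))))
}

#' Relate participation variability to manifold distance
#'
#' For each program pair: the total participation change
#' \eqn{\sum_i |\Delta\rho_i|} (normalised scale), the Hellinger distance
#' between the two per-program participation distributions, and the
#' normalized manifold distance of the pair; then the Pearson correlations
#' of distance against both variability measures across pairs.
#'
#' @param per_program list of [participation_scores()] frames.
#' @param pairs 2-row matrix of program index pairs (default: all pairs).
#' @param normalized_distance numeric vector, one normalized Hausdorff
#'   distance per pair (e.g. `compare_manifolds()$normalized`).
#' @param bins Hellinger bin count.
#' @return class `variability_vs_distance`: data frame per pair
#'   (`total_change`, `hellinger`, `normalized_distance`) with correlations
#'   in `attr(, "correlations")`.
#' @export
variability_vs_distance <- function(per_program, normalized_distance,
                                    pairs = NULL, bins = 20) {
  if (is.null(pairs)) pairs <- utils::combn(length(per_program), 2)
  if (ncol(pairs) != length(normalized_distance))
    ss_stop("ss_validation", "one normalized distance per pair required")
  tab <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    a <- per_program[[pairs[1, k]]]$rho_norm
    b <- per_program[[pairs[2, k]]]$rho_norm
    data.frame(program_a = pairs[1, k], program_b = pairs[2, k],
               total_change = sum(abs(b - a)),
               hellinger = hellinger_distance(a, b, bins = bins),
               normalized_distance = normalized_distance[k])
  }))
  cors <- c(
    change = if (nrow(tab) >= 3 && sd(tab$total_change) > 0 &&
                 sd(tab$normalized_distance) > 0)
      cor(tab$total_change, tab$normalized_distance) else NA_real_,
    hellinger = if (nrow(tab) >= 3 && sd(tab$hellinger) > 0 &&
                    sd(tab$normalized_distance) > 0)
      cor(tab$hellinger, tab$normalized_distance) else NA_real_)
  structure(tab, correlations = cors,
            class = c("variability_vs_distance", "data.frame"))
}

#' Correlates of participation: firing rate and synchrony
#'
#' Within a program, correlates each neuron's participation with its
#' post-stimulus firing rate (time-mean of the spike-density function from
#' stimulus offset onward) and with its synchrony (total absolute pairwise
#' SDF correlation with all other neurons). Across a pair of programs,
#' correlates the participation change with the rate and synchrony changes.
#'
#' @param participation a [participation_scores()] frame (or a list of them
#'   for the pairwise part).
#' @param rates a `rate_matrix` (or list of them, matching `participation`).
#' @param from time (s) from which the rate is computed (stimulus offset).
#' @return for a single program: list with per-neuron `rate`, `synchrony`
#'   and correlations `r_rate`, `r_synchrony`; for lists: additionally
#'   `pairwise` (data frame of delta correlations per pair).
#' @export
participation_correlates <- function(participation, rates, from = NULL) {
  single <- function(part, rm) {
    rows <- if (is.null(from)) seq_along(rm$t) else which(rm$t >= from)
    F <- rm$F[rows, , drop = FALSE]
    rate <- colMeans(F)
    ok <- apply(F, 2, sd) > 0
    if (any(!ok)) ss_log("excluding %d zero-variance neurons", sum(!ok))
    syn <- rep(NA_real_, ncol(F))
    C <- cor(F[, ok, drop = FALSE])
    syn[ok] <- colSums(abs(C)) - 1
    list(rate = rate, synchrony = syn,
         r_rate = cor(part$rho[ok], rate[ok]),
         r_synchrony = cor(part$rho[ok], syn[ok]))
  }
  if (inherits(participation, "participation"))
    return(single(participation, rates))
  res <- Map(single, participation, rates)
  pairs <- utils::combn(length(res), 2)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    drho <- participation[[j]]$rho_norm - participation[[i]]$rho_norm
    drate <- res[[j]]$rate - res[[i]]$rate
    dsyn <- res[[j]]$synchrony - res[[i]]$synchrony
    ok <- is.finite(drho) & is.finite(drate) & is.finite(dsyn)
    data.frame(program_a = i, program_b = j,
               r_delta_rate = cor(drho[ok], drate[ok]),
               r_delta_synchrony = cor(drho[ok], dsyn[ok]))
  }))
  list(per_program = res, pairwise = pw)
}
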