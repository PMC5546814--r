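#' Principal-component embedding of a population rate matrix
#'
#' Eigendecomposition of the neuron-by-neuron covariance of the spike-density
#' functions. The retained dimension `d` is the smallest count whose
#' cumulative variance share reaches `var_threshold` (default 0.80). The
#' trajectory `P` is the mean-centred rate matrix projected onto the `d`
#' leading axes, \eqn{p_i(t) = \sum_k W_{ik} f_k(t)}. The sign of each axis
#' is fixed by forcing its largest-magnitude loading positive, so repeated
#' runs are bit-identical.
#'
#' Variance (and centring) can be computed over a sub-window — by convention
#' the post-stimulus span — while the trajectory is still returned for every
#' row of `rates`.
#'
#' @param rates a `rate_matrix` (see [spike_density()]).
#' @param var_threshold cumulative variance fraction for choosing `d`.
#' @param window optional `(t0, t1)`: rows with `t0 <= t < t1` define the
#'   covariance and the centring means (default: all rows).
#' @return class `embedding`: list with orthonormal `axes` (neuron x
#'   component, all components), `eigvals` (descending), `var_explained`
#'   (cumulative fractions), `d`, trajectory `P` (time x d), grid `t`,
#'   centring means `center`, `window`, `neuron_ids`, `source`.
#' @examples
#' sdat <- generate_spiral_population(spiral_params(n_neurons = 20, post_s = 30))
#' rm <- spike_density(sdat$spikes, sigma = 0.1)
#' emb <- embed_population(rm, window = c(30, 60))
#' emb$d
#' @export
embed_population <- function(rates, var_threshold = 0.80, window = NULL) {
  stopifnot(inherits(rates, "rate_matrix"))
  rows <- if (is.null(window)) seq_along(rates$t)
          else which(rates$t >= window[1] & rates$t < window[2])
  F <- rates$F[rows, , drop = FALSE]
  v <- apply(F, 2, var)
  if (sum(v > 0) < 2)
    ss_stop("ss_degenerate", "need >= 2 neurons with nonzero variance")
  C <- stats::cov(F)
  eg <- eigen(C, symmetric = TRUE)
  eigvals <- pmax(eg$values, 0)
  axes <- eg$vectors
  ## sign convention: largest-|loading| entry positive
  for (j in seq_len(ncol(axes))) {
    k <- which.max(abs(axes[, j]))
    if (axes[k, j] < 0) axes[, j] <- -axes[, j]
  }
  cum <- cumsum(eigvals) / sum(eigvals)
  d <- which(cum >= var_threshold)[1]
  mu <- colMeans(F)
  P <- sweep(rates$F, 2, mu) %*% axes[, seq_len(d), drop = FALSE]
  rownames(axes) <- rates$neuron_ids
  structure(list(axes = axes, eigvals = eigvals, var_explained = cum, d = d,
                 P = P, t = rates$t, center = mu,
                 window = if (is.null(window)) rates$window else window,
                 var_threshold = var_threshold,
                 neuron_ids = rates$neuron_ids, source = NULL),
            class = "embedding")
}

#' @export
print.embedding <- function(x, ...) {
  cat(sprintf("embedding: d = %d of %d (%.1f%% variance at threshold %.0f%%), %d time points\n",
              x$d, length(x$eigvals), 100 * x$var_explained[x$d],
              100 * x$var_threshold, nrow(x$P)))
  invisible(x)
}

#' Project a rate matrix onto an existing embedding
#'
#' Returns the new program's trajectory in the reference program's principal
#' axes. The neuron set and order must match exactly. Centring follows
#' `centering`: `"self"` (default) centres the new program on its own means
#' over the embedding's analysis window; `"reference"` reuses the reference
#' program's means.
#'
#' @param embedding an `embedding` (the reference axes).
#' @param rates a `rate_matrix` for the program to project.
#' @param centering `"self"` or `"reference"`.
#' @return trajectory matrix (time x d) with the grid as attribute `t`.
#' @export
project_onto <- function(embedding, rates, centering = c("self", "reference")) {
  stopifnot(inherits(embedding, "embedding"), inherits(rates, "rate_matrix"))
  centering <- match.arg(centering)
  if (!identical(embedding$neuron_ids, rates$neuron_ids)) {
    bad <- union(setdiff(embedding$neuron_ids, rates$neuron_ids),
                 setdiff(rates$neuron_ids, embedding$neuron_ids))
    if (!length(bad)) bad <- "(same ids, different order)"
    ss_stop("ss_alignment", "neuron sets do not align: %s",
            paste(bad, collapse = ", "))
  }
  mu <- if (centering == "reference") embedding$center
        else {
          rows <- which(rates$t >= embedding$window[1] &
                        rates$t < embedding$window[2])
          if (!length(rows)) rows <- seq_along(rates$t)
          colMeans(rates$F[rows, , drop = FALSE])
        }
  P <- sweep(rates$F, 2, mu) %*% embedding$axes[, seq_len(embedding$d), drop = FALSE]
  attr(P, "t") <- rates$t
  P
}

#' Common principal axes for several programs
#'
#' Applies the embedding of [embed_population()] to the time-concatenated
#' rate matrices of several programs, yielding a single set of axes onto
#' which each program can then be projected — the robustness control for
#' conclusions drawn from any one program's axes.
#'
#' @param programs list of `rate_matrix` objects over the same neurons.
#' @param var_threshold cumulative variance fraction for `d`.
#' @return an `embedding` fit to the concatenation (its `P` and `t` span the
#'   concatenated rows in order).
#' @export
common_axes <- function(programs, var_threshold = 0.80) {
  stopifnot(length(programs) >= 1)
  ids <- programs[[1]]$neuron_ids
  for (p in programs)
    if (!identical(p$neuron_ids, ids))
      ss_stop("ss_alignment", "programs must share an identical neuron set")
  F <- do.call(rbind, lapply(programs, function(p) p$F))
  tt <- unlist(lapply(programs, function(p) p$t), use.names = FALSE)
  cat_rm <- structure(list(t = tt, F = F, sigma = programs[[1]]$sigma,
                           dt = programs[[1]]$dt,
                           window = range(tt), neuron_ids = ids),
                      class = "rate_matrix")
  emb <- embed_population(cat_rm, var_threshold = var_threshold)
  emb$source <- "concatenated"
  emb
}

#' Shuffled-projection control trajectory
#'
#' Permutes which neuron label carries which rate time-series, then projects
#' the permuted matrix onto the given axes. Destroys the match between
#' loadings and neurons while preserving every single-neuron statistic: the
#' null for manifold-distance comparisons.
#'
#' @param rates a `rate_matrix`.
#' @param embedding the reference `embedding`.
#' @param seed RNG seed (ignored when `perm` is given).
#' @param perm optional explicit permutation of the neuron columns.
#' @return trajectory matrix (time x d).
#' @export
shuffled_projection <- function(rates, embedding, seed = NULL, perm = NULL) {
  stopifnot(inherits(rates, "rate_matrix"))
  n <- ncol(rates$F)
  if (n < 2) ss_stop("ss_validation", "need >= 2 neurons to shuffle")
  if (is.null(perm)) {
    if (!is.null(seed)) set.seed(seed)
    perm <- sample.int(n)
  }
  shuf <- rates
  shuf$F <- rates$F[, perm, drop = FALSE]
  colnames(shuf$F) <- rates$neuron_ids
  project_onto(embedding, shuf, centering = "self")
}
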