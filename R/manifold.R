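#' Symmetric Hausdorff distance between two point sets
#'
#' \eqn{\max\{h(A \to B), h(B \to A)\}} with \eqn{h(X \to Y)} the maximum
#' over points of X of the Euclidean distance to the nearest point of Y: the
#' maximum minimum distance needed to travel from one set to the other.
#' Suited to comparing the irregularly shaped sets of recurrent points of two
#' programs.
#'
#' @param A,B point matrices (points x d), non-empty, same d.
#' @return non-negative scalar; 0 iff the sets are equal as point sets.
#' @export
hausdorff_distance <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (nrow(A) == 0 || nrow(B) == 0)
    ss_stop("ss_undefined", "Hausdorff distance of an empty set is undefined")
  cpp_hausdorff(A, B)
}

#' Compare the manifolds of two programs against a shuffle control
#'
#' Projects both programs onto a common set of axes, takes their recurrent
#' point sets and computes the Hausdorff distance between them; the control
#' is the same distance against `n_shuffles` shuffled projections (neuron
#' labels permuted before projecting) of each program,
#' \eqn{\max\{h(A \to B^*), h(B \to A^*)\}}. The `normalized` distance
#' (data / control mean) puts all pairs on one scale: below 1 means closer
#' than random projections.
#'
#' @param ratesA,ratesB `rate_matrix` objects over the same neurons.
#' @param embedding reference `embedding` providing the common axes.
#' @param n_shuffles number of shuffled projections (default 100).
#' @param seed RNG seed for the shuffles.
#' @param recurrence_args list of arguments passed on to [find_recurrence()]
#'   (e.g. `scan`, `theta_percentile`).
#' @param recA,recB optional precomputed `recurrence` results for the two
#'   projections (skips recomputation).
#' @param max_points cap on the recurrent points entering each Hausdorff
#'   evaluation (uniform time-stride subsample, applied identically to the
#'   data and to every shuffle, so the comparison stays like for like); the
#'   exact distance is quadratic in set size, and beyond a few thousand
#'   points the extra resolution does not change the comparison.
#' @return class `manifold_comparison`: list with `hausdorff`,
#'   `control_mean`, `control_sem`, `normalized`, the shuffle distances, and
#'   the recurrent point counts.
#' @export
compare_manifolds <- function(ratesA, ratesB, embedding, n_shuffles = 100,
                              seed = NULL, recurrence_args = list(),
                              recA = NULL, recB = NULL, max_points = 1500) {
  PA <- project_onto(embedding, ratesA)
  PB <- project_onto(embedding, ratesB)
  if (is.null(recA))
    recA <- do.call(find_recurrence, c(list(PA, t = ratesA$t), recurrence_args))
  if (is.null(recB))
    recB <- do.call(find_recurrence, c(list(PB, t = ratesB$t), recurrence_args))
  idxA <- seq(recA$scan[1], recA$scan[2])[recA$recurrent]
  idxB <- seq(recB$scan[1], recB$scan[2])[recB$recurrent]
  if (!length(idxA) || !length(idxB))
    ss_stop("ss_undefined", "a program has no recurrent points")
  thin <- function(idx) {
    if (length(idx) <= max_points) idx
    else idx[unique(round(seq(1, length(idx), length.out = max_points)))]
  }
  idxA <- thin(idxA)
  idxB <- thin(idxB)
  H <- cpp_hausdorff(PA[idxA, , drop = FALSE], PB[idxB, , drop = FALSE])
  if (!is.null(seed)) set.seed(seed)
  ctrl <- vapply(seq_len(n_shuffles), function(k) {
    SA <- shuffled_projection(ratesA, embedding)
    SB <- shuffled_projection(ratesB, embedding)
    max(cpp_directed_hausdorff(PA[idxA, , drop = FALSE],
                               SB[idxB, , drop = FALSE]),
        cpp_directed_hausdorff(PB[idxB, , drop = FALSE],
                               SA[idxA, , drop = FALSE]))
  }, numeric(1))
  cm <- mean(ctrl)
  structure(list(hausdorff = H, control_mean = cm,
                 control_sem = sd(ctrl) / sqrt(n_shuffles),
                 normalized = if (cm > 0) H / cm else 0,
                 control = ctrl,
                 n_recurrent = c(A = length(idxA), B = length(idxB))),
            class = "manifold_comparison")
}

#' @export
print.manifold_comparison <- function(x, ...) {
  cat(sprintf("manifold comparison: Hausdorff %.4g, control %.4g +/- %.2g (2 SEM), normalized %.3f\n",
              x$hausdorff, x$control_mean, 2 * x$control_sem, x$normalized))
  invisible(x)
}

#' Three-state distances between two programs
#'
#' Distances between a pair of programs at the three epochs of a trial: at
#' stimulus onset (end of spontaneous activity), the maximum pointwise
#' distance between stimulation onset and the later of the two coalescence
#' times (the transient approach), and the Hausdorff distance between the
#' post-coalescence recurrent point sets (on the manifold).
#'
#' @param PA,PB trajectories of the two programs in shared axes, on the same
#'   time grid `t`.
#' @param t time grid (s).
#' @param stim_on stimulus onset (s).
#' @param coalA,coalB coalescence times (s) of the two programs.
#' @param recA,recB `recurrence` results for the two trajectories.
#' @return named numeric vector `(spontaneous, pre_coalescence_max,
#'   post_coalescence)`.
#' @export
state_distances <- function(PA, PB, t, stim_on, coalA, coalB, recA, recB) {
  PA <- as.matrix(PA); PB <- as.matrix(PB)
  if (is.na(coalA) || is.na(coalB))
    ss_stop("ss_validation", "coalescence must be defined for both programs")
  pointwise <- sqrt(rowSums((PA - PB)^2))
  i_on <- which.min(abs(t - stim_on))
  pre <- t >= stim_on & t <= max(coalA, coalB)
  post_setA <- {
    idx <- seq(recA$scan[1], recA$scan[2])
    sel <- recA$recurrent & recA$scan_t >= coalA
    PA[idx[sel], , drop = FALSE]
  }
  post_setB <- {
    idx <- seq(recB$scan[1], recB$scan[2])
    sel <- recB$recurrent & recB$scan_t >= coalB
    PB[idx[sel], , drop = FALSE]
  }
  if (!nrow(post_setA) || !nrow(post_setB))
    ss_stop("ss_undefined", "no post-coalescence recurrent points")
  c(spontaneous = pointwise[i_on],
    pre_coalescence_max = max(pointwise[pre]),
    post_coalescence = cpp_hausdorff(post_setA, post_setB))
}

#' Pairwise-similarity conservation against an analytic null
#'
#' Projection-free test that two programs share a manifold: if they do, the
#' pairwise similarity structure of the neurons' spike-density functions
#' should be conserved. Computes the neuron-by-neuron similarity matrices
#' S(A), S(B) (Pearson correlation by default), the correlation `r_data` of
#' their off-diagonal entries, and the control correlation `r_control` of
#' S(A) against the null matrix \eqn{E_{ij} = s_i s_j / T} built from S(B)'s
#' totals \eqn{s_i} (total absolute similarity of neuron i, \eqn{T = \sum_i
#' s_i}) — each neuron keeps its total similarity but distributes it at
#' random.
#'
#' @param ratesA,ratesB `rate_matrix` objects over the same neurons
#'   (post-stimulus windows).
#' @param metric `"pearson"` (default; absolute values are used for the
#'   totals), `"abs_pearson"` or `"cosine"`.
#' @return class `similarity_comparison`: list with `S_A`, `S_B`, `E`,
#'   `r_data`, `r_control`, and the ids of any excluded constant neurons.
#' @export
similarity_null_test <- function(ratesA, ratesB,
                                 metric = c("pearson", "abs_pearson", "cosine")) {
  metric <- match.arg(metric)
  stopifnot(inherits(ratesA, "rate_matrix"), inherits(ratesB, "rate_matrix"))
  if (!identical(ratesA$neuron_ids, ratesB$neuron_ids))
    ss_stop("ss_alignment", "programs must share the neuron set")
  const <- apply(ratesA$F, 2, sd) == 0 | apply(ratesB$F, 2, sd) == 0
  if (any(const))
    ss_log("excluding %d constant neurons: %s", sum(const),
           paste(ratesA$neuron_ids[const], collapse = ", "))
  FA <- ratesA$F[, !const, drop = FALSE]
  FB <- ratesB$F[, !const, drop = FALSE]
  simmat <- function(F) {
    S <- switch(metric,
                pearson = cor(F),
                abs_pearson = abs(cor(F)),
                cosine = {
                  G <- crossprod(F)
                  nrm <- sqrt(diag(G))
                  G / tcrossprod(nrm)
                })
    S
  }
  S_A <- simmat(FA)
  S_B <- simmat(FB)
  s <- rowSums(abs(S_B))
  E <- tcrossprod(s) / sum(s)
  off <- upper.tri(S_A) | lower.tri(S_A)
  structure(list(S_A = S_A, S_B = S_B, E = E,
                 r_data = cor(S_A[off], S_B[off]),
                 r_control = cor(S_A[off], E[off]),
                 excluded = ratesA$neuron_ids[const], metric = metric),
            class = "similarity_comparison")
}

#' @export
print.similarity_comparison <- function(x, ...) {
  cat(sprintf("similarity conservation: r_data = %.3f, r_control = %.3f (%s)\n",
              x$r_data, x$r_control, x$metric))
  invisible(x)
}
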