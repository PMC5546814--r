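#' Analysis configuration with field defaults
#'
#' Collects every tunable constant of the pipeline with its standard value:
#' spike-density grid `dt` 0.01 s, kernel span +/-5 sigma, sigma divisor 12;
#' embedding variance threshold 0.80; recurrence threshold at the 10%
#' distance percentile, scan from 5 s after stimulation to 10 s before the
#' recording end, 1 s histogram bins, delays below 5 s excluded, qualifying
#' peaks > 100 points, 5 s windows advanced by 1 s, coalescence at 90%
#' density, divergence thresholds 90%/50%, same-manifold fraction 0.10;
#' local linear neighbourhoods within 2.5 theta with >= 100 points; drift
#' test with 10000 permutations, two-sided; decoding with 40 s fit / 10 s
#' forecast / 1 s slide and 50-200 ms histories in 10 ms steps;
#' participation outliers at 3 SD, 20 Hellinger bins; 100 shuffles.
#'
#' @param ... overrides as `section.key = value`, e.g.
#'   `recurrence.theta_percentile = 5`.
#' @return nested list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    sdf = list(dt = 0.01, sigma_divisor = 12, span_sigmas = 5),
    embed = list(var_threshold = 0.80, centering = "self"),
    recurrence = list(theta_percentile = 10, scan_start_after_stim = 5,
                      scan_end_margin = 10, bin = 1, min_delay = 5,
                      min_peak_points = 100, window = 5, step = 1,
                      coalesce = 0.90, diverge_low = 0.50,
                      same_manifold_min = 0.10),
    lineardyn = list(radius_mult = 2.5, min_points = 100, anchor_stride = 1),
    drift = list(n_perm = 10000, tail = "two"),
    decode = list(fit_s = 40, forecast_s = 10, slide_s = 1,
                  history_min_ms = 50, history_max_ms = 200,
                  history_step_ms = 10, max_dims = 10),
    participation = list(outlier_sd = 3, hellinger_bins = 20),
    shuffles = 100, seed = 1)
  dots <- list(...)
  for (nm in names(dots)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    if (length(parts) == 1) {
      if (!parts %in% names(cfg))
        ss_stop("ss_validation", "unknown config key: %s", nm)
      cfg[[parts]] <- dots[[nm]]
    } else if (length(parts) == 2) {
      if (!parts[1] %in% names(cfg) || !parts[2] %in% names(cfg[[parts[1]]]))
        ss_stop("ss_validation", "unknown config key: %s", nm)
      cfg[[parts[1]]][[parts[2]]] <- dots[[nm]]
    } else ss_stop("ss_validation", "unknown config key: %s", nm)
  }
  structure(cfg, class = "run_config")
}

#' Hash of a configuration (provenance)
#'
#' @param cfg a `run_config`.
#' @return character scalar changing iff any constant changes.
#' @export
config_hash <- function(cfg) {
  s <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  ## small polynomial rolling hash, enough for provenance
  h <- 0
  for (b in utf8ToInt(as.character(s)))
    h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Assemble a complete synthetic preparation
#'
#' Packages the structural analogue of one experimental preparation: three
#' sequentially evoked programs drawn from the same latent orbit (shared
#' per-neuron gains and phases, independent spikes), an optional
#' phase-locked nerve recording per program, optional neuron coordinates,
#' and the ground truth.
#'
#' @param params a [spiral_params] (per-program sizes; its seed is the root
#'   seed of the bundle).
#' @param n_programs number of programs.
#' @param nerve if `TRUE`, generate a nerve train per program from the
#'   latent trajectory with known coefficients.
#' @param nerve_beta0 nerve intercept (log spikes/s).
#' @param nerve_gain coefficient magnitude on the first latent dimension.
#' @param coords if `TRUE`, draw (x, y) neuron positions.
#' @return class `preparation`: list with `programs` (list of
#'   [spike_data]), `nerve` (list of spike-time vectors or `NULL`),
#'   `truth`, `config_seed`, `provenance`.
#' @export
make_preparation <- function(params = spiral_params(), n_programs = 3,
                             nerve = TRUE, nerve_beta0 = log(10),
                             nerve_gain = 1.5, coords = TRUE) {
  root <- params$seed
  set.seed(root)
  gains <- draw_mixture_gains(params)
  phases <- runif(params$n_neurons, 0, 2 * pi)
  xy <- if (coords) cbind(x = runif(params$n_neurons),
                          y = runif(params$n_neurons)) else NULL
  programs <- list()
  nerves <- if (nerve) list() else NULL
  truth <- NULL
  m <- 10L
  beta <- NULL
  for (k in seq_len(n_programs)) {
    pk <- params
    pk$gains <- gains
    pk$phases <- phases
    pk$seed <- root + 1000L * k
    gp <- generate_spiral_population(pk)
    gp$spikes$coords <- xy
    programs[[k]] <- gp$spikes
    if (k == 1) truth <- gp$truth
    if (nerve) {
      if (is.null(beta)) {
        beta <- matrix(0, 2, m)
        beta[1, ] <- nerve_gain / m
      }
      nv <- generate_nerve_output(gp$truth$latent, beta0 = nerve_beta0,
                                  beta = beta, dt = params$dt,
                                  t0 = 0, seed = pk$seed + 1L)
      nerves[[k]] <- nv$spike_times
    }
  }
  if (nerve) truth$true_beta <- list(beta0 = nerve_beta0, beta = beta)
  structure(list(programs = programs, nerve = nerves, coords = xy,
                 truth = truth, config_seed = root,
                 provenance = list(seed = root,
                                   version = as.character(utils::packageVersion("spiralscope")))),
            class = "preparation")
}

#' @export
print.preparation <- function(x, ...) {
  cat(sprintf("preparation: %d programs, %d neurons, nerve: %s\n",
              length(x$programs), length(x$programs[[1]]$spikes),
              if (is.null(x$nerve)) "no" else "yes"))
  invisible(x)
}

## run all stages for one program; isolate failures
analyse_program <- function(spk, nerve, cfg) {
  res <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      res$failures[[name]] <<- conditionMessage(e)
      NULL
    })
  }
  rc <- cfg$recurrence
  emb <- stage("embed", {
    rm_full <- spike_density(spk, dt = cfg$sdf$dt,
                             sigma_divisor = cfg$sdf$sigma_divisor)
    res$sigma <- rm_full$sigma
    res$rates <- rm_full
    embed_population(rm_full, var_threshold = cfg$embed$var_threshold,
                     window = c(spk$stim_on, spk$duration))
  })
  if (is.null(emb)) return(res)
  rm_full <- res$rates
  res$d <- emb$d
  res$embedding <- emb
  rec <- stage("recurrence", {
    r <- find_recurrence(emb, scan = c(spk$stim_on + rc$scan_start_after_stim,
                                       spk$duration - rc$scan_end_margin),
                         theta_percentile = rc$theta_percentile)
    detect_periodic_orbit(r, bin = rc$bin, min_delay = rc$min_delay,
                          min_peak_points = rc$min_peak_points)
  })
  res$recurrence <- rec
  if (!is.null(rec)) {
    res$period <- rec$period
    res$aperiodic <- is.na(rec$dominant)
    dens <- window_density(rec, win = rc$window, step = rc$step)
    res$density <- dens
    res$coalescence <- coalescence_time(dens, rc$coalesce)
    if (!res$aperiodic && !is.na(res$coalescence)) {
      res$perturbations <- stage("perturbations",
        detect_perturbations(rec, dens, rec$period, res$coalescence,
                             diverge_high = rc$coalesce,
                             diverge_low = rc$diverge_low,
                             same_manifold_min = rc$same_manifold_min))
      res$attractor <- stage("lineardyn", {
        anchors <- seq(rec$scan[1], rec$scan[2])[rec$recurrent]
        stride <- max(1L, as.integer(cfg$lineardyn$anchor_stride))
        anchors <- anchors[seq(1, length(anchors), by = stride)]
        fits <- local_linear_fits(emb$P, anchors, rec$theta,
                                  radius_mult = cfg$lineardyn$radius_mult,
                                  min_points = cfg$lineardyn$min_points)
        summarize_attractor(fits, rec, dt = cfg$sdf$dt)
      })
      res$drift <- stage("drift",
        period_drift(dens, res$coalescence, n_perm = cfg$drift$n_perm,
                     seed = cfg$seed, tail = cfg$drift$tail))
    }
  }
  if (!is.null(nerve)) {
    res$decoding <- stage("decode", {
      nerve_sd <- spike_data(list(p10 = nerve), duration = spk$duration)
      nr <- spike_density(nerve_sd, dt = cfg$sdf$dt, sigma = rm_full$sigma)
      ## forecasting gains nothing from trailing noise dimensions; cap the
      ## decoder input at the leading max_dims components
      dd <- min(emb$d, cfg$decode$max_dims)
      evaluate_decoding(emb$P[, seq_len(dd), drop = FALSE], nr$F[, 1], rm_full$t,
                        history_grid = seq(cfg$decode$history_min_ms,
                                           cfg$decode$history_max_ms,
                                           by = cfg$decode$history_step_ms),
                        fit_s = cfg$decode$fit_s,
                        forecast_s = cfg$decode$forecast_s,
                        step_s = cfg$decode$slide_s,
                        start_t = spk$stim_on)
    })
  }
  res$participation <- participation_scores(emb)
  res
}

#' Run the full analysis pipeline on a preparation
#'
#' Executes every stage for each program — spike-density functions,
#' embedding, recurrence and orbit detection, coalescence, perturbation
#' events, local-linear attractor estimation, period drift, decoding (when
#' a nerve recording is present), participation — then the cross-program
#' stages (manifold comparisons on the first program's axes, participation
#' noise model). A stage failure is isolated: the report carries a
#' machine-readable failure record for that stage and the rest completes.
#'
#' @param prep a `preparation` (see [make_preparation()]), or any list with
#'   `programs` (list of [spike_data]) and optional `nerve`.
#' @param config a [run_config()].
#' @param out_dir optional directory: writes `report.json` plus per-program
#'   TSVs.
#' @return class `preparation_report`: per-program summaries plus
#'   cross-program comparisons and provenance.
#' @export
run_pipeline <- function(prep, config = run_config(), out_dir = NULL) {
  stopifnot(is.list(prep$programs), length(prep$programs) >= 1)
  cfg <- config
  progs <- lapply(seq_along(prep$programs), function(k)
    analyse_program(prep$programs[[k]],
                    if (!is.null(prep$nerve)) prep$nerve[[k]] else NULL,
                    cfg))
  names(progs) <- paste0("program", seq_along(progs))
  cross <- list()
  if (length(progs) >= 2) {
    ref <- progs[[1]]$embedding
    pairs <- utils::combn(length(progs), 2)
    cross$manifold <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
      i <- pairs[1, k]; j <- pairs[2, k]
      cm <- tryCatch(
        compare_manifolds(progs[[i]]$rates, progs[[j]]$rates, ref,
                          n_shuffles = cfg$shuffles, seed = cfg$seed + k,
                          recurrence_args = list(
                            scan = c(prep$programs[[i]]$stim_on +
                                       cfg$recurrence$scan_start_after_stim,
                                     prep$programs[[i]]$duration -
                                       cfg$recurrence$scan_end_margin),
                            theta_percentile = cfg$recurrence$theta_percentile)),
        error = function(e) NULL)
      if (is.null(cm)) return(NULL)
      data.frame(program_a = i, program_b = j, hausdorff = cm$hausdorff,
                 control_mean = cm$control_mean, normalized = cm$normalized)
    }))
    embs <- lapply(progs, `[[`, "embedding")
    if (!any(vapply(embs, is.null, logical(1)))) {
      pt <- participation_table(embs)
      cross$participation <- pt$table
      cross$noise_model <- tryCatch(
        fit_noise_model(pt$changes, sd_mult = cfg$participation$outlier_sd),
        error = function(e) NULL)
      if (!is.null(cross$noise_model)) {
        idx <- (seq_along(pt$changes) - 1) %% nrow(pt$table) + 1
        cross$strongly_variable <-
          unique(pt$table$neuron[idx[cross$noise_model$outliers]])
      }
    }
  }
  report <- list(
    programs = lapply(progs, function(p)
      list(sigma = p$sigma, d = p$d, period = p$period,
           aperiodic = isTRUE(p$aperiodic),
           coalescence = p$coalescence,
           classification = if (!is.null(p$attractor)) p$attractor$classification,
           contraction_pct_per_s = if (!is.null(p$attractor)) p$attractor$contraction_pct_per_s,
           period_est = if (!is.null(p$attractor)) p$attractor$period_est,
           drift = if (!is.null(p$drift)) list(rho = p$drift$rho, p = p$drift$p),
           n_perturbations = if (!is.null(p$perturbations)) nrow(p$perturbations),
           perturbation_outcomes = if (!is.null(p$perturbations)) p$perturbations$outcome,
           decoding_best_history = if (!is.null(p$decoding)) p$decoding$best_history,
           decoding_median_R = if (!is.null(p$decoding))
             median(p$decoding$scores$R[p$decoding$scores$history_ms ==
                                          p$decoding$best_history], na.rm = TRUE),
           failures = p$failures)),
    cross = list(
      manifold = cross$manifold,
      strongly_variable = cross$strongly_variable,
      noise_model = if (!is.null(cross$noise_model))
        cross$noise_model[c("mu", "sd", "threshold_lo", "threshold_hi",
                            "n_iterations")]),
    provenance = list(config_hash = config_hash(cfg), seed = cfg$seed,
                      version = as.character(utils::packageVersion("spiralscope"))))
  out <- structure(list(report = report, detail = progs, cross = cross,
                        config = cfg),
                   class = "preparation_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE)
    for (k in seq_along(progs)) {
      p <- progs[[k]]
      if (!is.null(p$density))
        write.table(p$density, file.path(out_dir, sprintf("density_%d.tsv", k)),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      if (!is.null(p$participation))
        write.table(p$participation,
                    file.path(out_dir, sprintf("participation_%d.tsv", k)),
                    sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  out
}

#' @export
print.preparation_report <- function(x, ...) {
  cat("preparation report\n")
  for (nm in names(x$report$programs)) {
    p <- x$report$programs[[nm]]
    cat(sprintf("  %s: d = %d, period %.2f s, coalescence %.1f s, %s%s\n",
                nm, p$d %||% NA_integer_, p$period %||% NA, p$coalescence %||% NA,
                p$classification %||% if (p$aperiodic) "aperiodic" else "(no estimate)",
                if (!is.null(p$decoding_median_R))
                  sprintf(", decode R %.2f", p$decoding_median_R) else ""))
  }
  if (!is.null(x$report$cross$strongly_variable))
    cat(sprintf("  strongly variable neurons: %d\n",
                length(x$report$cross$strongly_variable)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
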