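#' Population spike-train container
#'
#' Bundles per-neuron spike-time lists with the recording metadata needed by
#' every downstream stage: total recording span and the stimulus window that
#' separates spontaneous from evoked activity. Optionally carries per-neuron
#' (x, y) coordinates for participation maps.
#'
#' @param spikes named list of numeric vectors, one per neuron, spike times in
#'   seconds sorted ascending. Silent neurons are retained as empty vectors.
#' @param duration recording span in seconds.
#' @param stim_on,stim_off stimulus onset/offset in seconds
#'   (`stim_on <= stim_off <= duration`).
#' @param coords optional two-column matrix or data frame of (x, y) positions,
#'   one row per neuron.
#' @return an object of class `spike_data`.
#' @examples
#' sd <- spike_data(list(a = c(0.5, 1.2), b = numeric(0)), duration = 5)
#' print(sd)
#' @export
spike_data <- function(spikes, duration, stim_on = 0, stim_off = stim_on,
                       coords = NULL) {
  if (!is.list(spikes) || length(spikes) == 0)
    ss_stop("ss_validation", "spikes must be a non-empty list of numeric vectors")
  if (is.null(names(spikes)) || anyDuplicated(names(spikes)))
    names(spikes) <- sprintf("n%03d", seq_along(spikes))
  spikes <- lapply(spikes, as.numeric)
  for (id in names(spikes)) {
    s <- spikes[[id]]
    if (length(s)) {
      if (is.unsorted(s))
        ss_stop("ss_validation", "spike times of neuron %s are not sorted", id)
      if (s[1] < 0 || s[length(s)] > duration)
        ss_stop("ss_validation",
                "neuron %s has spike times outside [0, %g]", id, duration)
    }
  }
  if (!(stim_on <= stim_off && stim_off <= duration && stim_on >= 0))
    ss_stop("ss_validation", "need 0 <= stim_on <= stim_off <= duration")
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    if (nrow(coords) != length(spikes) || ncol(coords) != 2)
      ss_stop("ss_validation", "coords must be one (x, y) row per neuron")
    rownames(coords) <- names(spikes)
  }
  structure(list(spikes = spikes, duration = duration, stim_on = stim_on,
                 stim_off = stim_off, neuron_ids = names(spikes),
                 coords = coords),
            class = "spike_data")
}

#' @export
print.spike_data <- function(x, ...) {
  n_sp <- sum(lengths(x$spikes))
  cat(sprintf("spike_data: %d neurons, %.1f s (stimulus %.1f-%.1f s), %d spikes\n",
              length(x$spikes), x$duration, x$stim_on, x$stim_off, n_sp))
  invisible(x)
}

#' @export
summary.spike_data <- function(object, ...) {
  rates <- lengths(object$spikes) / object$duration
  cat(sprintf("spike_data with %d neurons over %.1f s\n",
              length(object$spikes), object$duration))
  cat("per-neuron mean rate (spikes/s):\n")
  print(summary(rates))
  invisible(rates)
}

#' Read / write the two-column spike table format
#'
#' The on-disk format is a tab-delimited table `neuron_id<TAB>spike_time_s`
#' (times printed with 6 decimal places, i.e. microsecond resolution) plus a
#' JSON sidecar `<path>.json` holding `duration_s`, `stim_on_s`, `stim_off_s`,
#' `n_neurons` and the full neuron id list, so silent neurons survive the
#' round trip.
#'
#' @param x a [spike_data] object.
#' @param path path of the spike table; the sidecar is written at
#'   `paste0(path, ".json")`.
#' @return `read_spike_table` returns a [spike_data]; `write_spike_table`
#'   returns `path` invisibly.
#' @export
write_spike_table <- function(x, path) {
  stopifnot(inherits(x, "spike_data"))
  ids <- rep(x$neuron_ids, lengths(x$spikes))
  tab <- data.frame(neuron_id = ids,
                    spike_time_s = sprintf("%.6f", unlist(x$spikes, use.names = FALSE)))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(duration_s = x$duration, stim_on_s = x$stim_on,
               stim_off_s = x$stim_off, n_neurons = length(x$spikes),
               neuron_ids = x$neuron_ids)
  if (!is.null(x$coords))
    meta$coords <- data.frame(neuron_id = x$neuron_ids,
                              x = x$coords[, 1], y = x$coords[, 2])
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_spike_table
#' @export
read_spike_table <- function(path) {
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path))
    ss_stop("ss_validation", "missing metadata sidecar %s", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  tab <- read.table(path, header = TRUE, sep = "\t",
                    colClasses = c("character", "numeric"))
  bad <- which(tab$spike_time_s < 0 | tab$spike_time_s > meta$duration_s)
  if (length(bad))
    ss_stop("ss_validation", "spike times outside recording at line(s) %s",
            paste(bad + 1L, collapse = ", "))
  spikes <- split(tab$spike_time_s, factor(tab$neuron_id, levels = meta$neuron_ids))
  spikes <- lapply(spikes, sort)
  unsorted <- names(spikes)[vapply(split(tab$spike_time_s,
                                         factor(tab$neuron_id, levels = meta$neuron_ids)),
                                   is.unsorted, logical(1))]
  if (length(unsorted))
    ss_log("re-sorted spike times for: %s", paste(unsorted, collapse = ", "))
  coords <- NULL
  if (!is.null(meta$coords))
    coords <- as.matrix(meta$coords[match(meta$neuron_ids, meta$coords$neuron_id),
                                    c("x", "y")])
  spike_data(spikes, duration = meta$duration_s, stim_on = meta$stim_on_s,
             stim_off = meta$stim_off_s, coords = coords)
}
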