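#' Spike raster container
#'
#' The universal currency of the package: timed spike events per neuron per
#' stimulus presentation, together with a presentation table carrying the
#' stimulus class labels. Times are in ms relative to presentation onset;
#' neuron indices are 1-based in R (the on-disk format is 0-based).
#'
#' @param events data.frame with columns `presentation` (integer id),
#'   `neuron` (1-based index) and `time` (ms, within `[0, duration)`).
#' @param presentations data.frame with columns `presentation`, `class`
#'   (stimulus class label), `exemplar` (exemplar index within class) and
#'   `duration` (ms). One row per presentation.
#' @param n_neurons Number of neurons in the layer the raster belongs to.
#' @return An object of class `spike_raster`.
#' @export
spike_raster <- function(events, presentations, n_neurons) {
  stopifnot(all(c("presentation", "neuron", "time") %in% names(events)),
            all(c("presentation", "class", "exemplar", "duration") %in%
                  names(presentations)),
            n_neurons >= 1)
  if (nrow(events)) {
    if (any(events$neuron < 1 | events$neuron > n_neurons))
      stop("neuron index outside [1, n_neurons]")
    dur <- presentations$duration[match(events$presentation,
                                        presentations$presentation)]
    if (any(is.na(dur)))
      stop("event references unknown presentation id")
    if (any(events$time < 0 | events$time > dur))
      stop("event time outside presentation window")
  }
  if (anyDuplicated(presentations$presentation))
    stop("duplicate presentation ids")
  structure(list(events = as.data.frame(events),
                 presentations = as.data.frame(presentations),
                 n_neurons = as.integer(n_neurons)),
            class = "spike_raster")
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf("spike_raster: %d neurons, %d presentations, %d spikes\n",
              x$n_neurons, nrow(x$presentations), nrow(x$events)))
  cls <- table(x$presentations$class)
  cat("  classes:",
      paste(sprintf("%s (%d)", names(cls), cls), collapse = ", "), "\n")
  invisible(x)
}

#' Events of a single presentation
#' @param raster A `spike_raster`.
#' @param id Presentation id.
#' @return data.frame of events.
#' @export
presentation_events <- function(raster, id) {
  raster$events[raster$events$presentation == id, , drop = FALSE]
}

#' Mean firing rate per neuron (Hz)
#'
#' Spike count of each neuron divided by total presentation time, pooled
#' over the given presentations.
#'
#' @param raster A `spike_raster`.
#' @param ids Presentation ids (default all).
#' @return Numeric vector of length `n_neurons`.
#' @export
firing_rates <- function(raster, ids = raster$presentations$presentation) {
  ev <- raster$events[raster$events$presentation %in% ids, , drop = FALSE]
  tot_ms <- sum(raster$presentations$duration[
    raster$presentations$presentation %in% ids])
  counts <- tabulate(ev$neuron, nbins = raster$n_neurons)
  counts / (tot_ms / 1000)
}

#' Write / read a spike raster as delimited text
#'
#' Two tab-separated tables in one file: a `#presentations` block with
#' columns (id, class, exemplar, duration_ms) and an `#events` block with
#' columns (presentation_id, neuron, time_ms). Neuron indices are 0-based
#' on disk.
#'
#' @param raster A `spike_raster`.
#' @param path File path.
#' @return `write_raster` returns `path` invisibly; `read_raster` returns a
#'   `spike_raster`.
#' @export
write_raster <- function(raster, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#n_neurons\t%d", raster$n_neurons), con)
  writeLines("#presentations\tid\tclass\texemplar\tduration_ms", con)
  p <- raster$presentations
  writeLines(sprintf("P\t%d\t%s\t%s\t%.6g", p$presentation,
                     as.character(p$class), as.character(p$exemplar),
                     p$duration), con)
  writeLines("#events\tpresentation_id\tneuron\ttime_ms", con)
  e <- raster$events
  if (nrow(e))
    writeLines(sprintf("E\t%d\t%d\t%.6f", e$presentation,
                       e$neuron - 1L, e$time), con)
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  lines <- readLines(path)
  n_neurons <- as.integer(strsplit(lines[grepl("^#n_neurons", lines)],
                                   "\t")[[1]][2])
  pl <- strsplit(lines[startsWith(lines, "P\t")], "\t")
  presentations <- data.frame(
    presentation = as.integer(vapply(pl, `[`, "", 2)),
    class = vapply(pl, `[`, "", 3),
    exemplar = vapply(pl, `[`, "", 4),
    duration = as.numeric(vapply(pl, `[`, "", 5)))
  el <- strsplit(lines[startsWith(lines, "E\t")], "\t")
  events <- data.frame(
    presentation = as.integer(vapply(el, `[`, "", 2)),
    neuron = as.integer(vapply(el, `[`, "", 3)) + 1L,
    time = as.numeric(vapply(el, `[`, "", 4)))
  spike_raster(events, presentations, n_neurons)
}
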