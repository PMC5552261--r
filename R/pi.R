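#' Windowed co-firing pattern matrix
#'
#' For one presentation and one reference cell `j`, samples one of `j`'s
#' spikes uniformly at random (time `t_j`), then bins the spikes of all
#' cells at 1 ms resolution into the window `t_j +/- half_window` ms. The
#' result is an `n_cells x (2 * half_window + 1)` count matrix; lags that
#' fall outside the presentation are zero-padded. The centre element (cell
#' `j` at lag 0) holds the sampled spike and is excluded from all maxima
#' computations downstream.
#'
#' @param raster A [spike_raster()].
#' @param cell Reference cell index (1-based).
#' @param presentation Presentation id.
#' @param half_window Half window in ms (default 50, the maximum conduction
#'   delay; the window is then 101 columns).
#' @param cells Optional subset of cells forming the matrix rows (used by
#'   the temporal decoding features); default all cells. `cell` must be a
#'   member.
#' @return The count matrix with attributes `t_j` (sampled time) and
#'   `lags`, or `NULL` if the reference cell is silent in this
#'   presentation (the caller records the skip).
#' @export
pattern_matrix <- function(raster, cell, presentation, half_window = 50,
                           cells = seq_len(raster$n_neurons)) {
  ev <- presentation_events(raster, presentation)
  pm_from_events(ev, raster$n_neurons, cell, half_window, cells)
}

pm_from_events <- function(ev, n_neurons, cell, half_window,
                           cells = seq_len(n_neurons)) {
  row_of <- match(seq_len(n_neurons), cells)
  stopifnot(!is.na(row_of[cell]))
  own <- ev$time[ev$neuron == cell]
  if (length(own) == 0) return(NULL)
  t_j <- if (length(own) == 1) own else own[sample.int(length(own), 1)]
  n_lags <- 2L * half_window + 1L
  m <- matrix(0L, nrow = length(cells), ncol = n_lags)
  keep0 <- !is.na(row_of[ev$neuron])
  lag <- round(ev$time[keep0] - t_j)
  nrn <- ev$neuron[keep0]
  keep <- lag >= -half_window & lag <= half_window
  if (any(keep)) {
    idx <- row_of[nrn[keep]] + length(cells) * (lag[keep] + half_window)
    cnt <- tabulate(idx, nbins = length(cells) * n_lags)
    m <- matrix(cnt, nrow = length(cells), ncol = n_lags)
  }
  attr(m, "t_j") <- t_j
  attr(m, "lags") <- seq(-half_window, half_window)
  m
}

#' Layer mean firing statistic
#'
#' Mean spike count per cell per 1 ms bin, pooled over the analysed
#' presentations of the layer: the chance level against which windowed
#' co-firing counts are compared.
#'
#' @param raster A [spike_raster()].
#' @param ids Presentation ids (default all).
#' @return A scalar (`> 0` for any non-silent raster).
#' @export
layer_rate_stat <- function(raster, ids = raster$presentations$presentation) {
  ev <- raster$events[raster$events$presentation %in% ids, , drop = FALSE]
  tot <- sum(raster$presentations$duration[
    raster$presentations$presentation %in% ids])
  nrow(ev) / (raster$n_neurons * tot)
}

top_mean <- function(m, exclude_row, exclude_col, n_top = 10) {
  # stable top-n: count desc, lag (column) asc, cell (row) asc
  v <- as.vector(m)
  v[exclude_row + nrow(m) * (exclude_col - 1L)] <- -Inf
  rows <- rep(seq_len(nrow(m)), ncol(m))
  cols <- rep(seq_len(ncol(m)), each = nrow(m))
  ord <- order(-v, cols, rows)[seq_len(min(n_top, length(v) - 1L))]
  mean(v[ord])
}

#' Polychronization index
#'
#' Quantifies, per reference cell, the prevalence of reproducible
#' spatio-temporal firing patterns. For each stimulus class `s`, the
#' exemplar matrices from [pattern_matrix()] are averaged over all usable
#' presentations of `s` (presentations where the reference cell is silent
#' are skipped and counted); `a_s` is the mean of the ten largest elements
#' of the averaged matrix (centre element excluded) divided by the layer
#' mean firing statistic `f`, and the index is `PI = max_s a_s`.
#'
#' @param raster A [spike_raster()].
#' @param cells Reference cells to score (default all).
#' @param seed RNG seed for the per-presentation spike sampling.
#' @param half_window Half window in ms (default 50).
#' @param n_top Number of largest elements averaged (default 10).
#' @return data.frame of class `pi_result` with one row per reference
#'   cell: `cell`, one `a_<class>` column per class, `pi`, `n_skipped`.
#'   The layer statistic `f` is attached as attribute `f`.
#' @export
polychronization_index <- function(raster, cells = seq_len(raster$n_neurons),
                                   seed, half_window = 50, n_top = 10) {
  set.seed(seed)
  pres <- raster$presentations
  classes <- unique(pres$class)
  f <- layer_rate_stat(raster)
  if (f <= 0) stop("silent raster: layer firing statistic is zero")
  n_lags <- 2L * half_window + 1L
  a <- matrix(NA_real_, nrow = length(cells), ncol = length(classes),
              dimnames = list(NULL, classes))
  n_skipped <- integer(length(cells))
  any_usable <- FALSE
  ev_split <- split(raster$events,
                    factor(raster$events$presentation,
                           levels = pres$presentation))
  for (ci in seq_along(cells)) {
    j <- cells[ci]
    for (s in classes) {
      ids <- which(pres$class == s)
      acc <- matrix(0, nrow = raster$n_neurons, ncol = n_lags)
      used <- 0L
      for (id in ids) {
        m <- pm_from_events(ev_split[[id]], raster$n_neurons, j, half_window)
        if (is.null(m)) { n_skipped[ci] <- n_skipped[ci] + 1L; next }
        acc <- acc + m
        used <- used + 1L
      }
      if (used == 0L) next
      any_usable <- TRUE
      a[ci, s] <- top_mean(acc / used, j, half_window + 1L, n_top) / f
    }
  }
  if (!any_usable)
    stop("no usable exemplar for any class and any reference cell")
  out <- data.frame(cell = cells)
  for (s in classes) out[[paste0("a_", s)]] <- a[, s]
  out$pi <- apply(a, 1, function(x) if (all(is.na(x))) NA_real_
                                    else max(x, na.rm = TRUE))
  out$n_skipped <- n_skipped
  attr(out, "f") <- f
  class(out) <- c("pi_result", "data.frame")
  out
}
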