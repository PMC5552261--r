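#' Temporal-code feature vectors
#'
#' For each presentation, builds the windowed co-firing matrix of a
#' reference cell over a subsample of cells (see [pattern_matrix()]) and
#' reduces it to the concatenation of its row sums and column sums: with
#' `J` sampled cells and a 101-lag window this is a `J + 101` element
#' vector capturing the spatio-temporal structure around the reference
#' cell's firing.
#'
#' @param raster A [spike_raster()].
#' @param cells The sampled cell subset (matrix rows).
#' @param ref_cell Reference cell (must be in `cells`).
#' @param ids Presentation ids (default all).
#' @param half_window Half window in ms (default 50).
#' @return A matrix with one row per presentation (`NA` rows where the
#'   reference cell was silent) and `length(cells) + 2*half_window + 1`
#'   columns; row names are presentation ids.
#' @export
temporal_features <- function(raster, cells, ref_cell,
                              ids = raster$presentations$presentation,
                              half_window = 50) {
  temporal_feature_set(raster, cells, ref_cell, ids, half_window)[[1]]
}

# feature matrices for several reference cells in one pass (events are
# subset and split only once)
temporal_feature_set <- function(raster, cells, ref_cells,
                                 ids = raster$presentations$presentation,
                                 half_window = 50) {
  n_feat <- length(cells) + 2L * half_window + 1L
  ev_all <- raster$events[raster$events$presentation %in% ids, , drop = FALSE]
  keep <- ev_all$neuron %in% cells
  ev_all <- ev_all[keep, , drop = FALSE]
  ev_split <- split(ev_all, factor(ev_all$presentation, levels = ids))
  out <- lapply(ref_cells, function(j)
    matrix(NA_real_, nrow = length(ids), ncol = n_feat,
           dimnames = list(ids, NULL)))
  names(out) <- as.character(ref_cells)
  for (i in seq_along(ids)) {
    ev <- ev_split[[i]]
    for (k in seq_along(ref_cells)) {
      m <- pm_from_events(ev, raster$n_neurons, ref_cells[k],
                          half_window, cells)
      if (is.null(m)) next
      out[[k]][i, ] <- c(rowSums(m), colSums(m))
    }
  }
  out
}

#' Rate-code feature vectors
#'
#' Mean firing rate (Hz) of each sampled cell in each presentation: spike
#' count divided by presentation duration. Invariant to within-presentation
#' spike timing by construction.
#'
#' @param raster A [spike_raster()].
#' @param cells Sampled cell indices.
#' @param ids Presentation ids (default all).
#' @return A matrix, presentations by cells; row names are presentation ids.
#' @export
rate_features <- function(raster, cells,
                          ids = raster$presentations$presentation) {
  dur <- raster$presentations$duration[
    match(ids, raster$presentations$presentation)]
  out <- matrix(0, nrow = length(ids), ncol = length(cells),
                dimnames = list(ids, NULL))
  ev <- raster$events[raster$events$presentation %in% ids &
                        raster$events$neuron %in% cells, , drop = FALSE]
  if (nrow(ev)) {
    tab <- table(factor(ev$presentation, levels = ids),
                 factor(ev$neuron, levels = cells))
    out <- unclass(tab) / (dur / 1000)
    dimnames(out) <- list(ids, NULL)
  }
  out
}

#' Mutual information estimate from a confusion joint table
#'
#' `I(S;R) = sum p(s,r) log2( p(s,r) / (p(s) p(r)) )` with `0 log 0 = 0`,
#' plus the entropy ceiling `H(S)` of the class priors and the first-order
#' sampling bias `#bins / (2 N ln 2)` bits.
#'
#' @param joint Matrix of joint probabilities, predictions in rows, actual
#'   classes in columns; entries `>= 0`, summing to 1.
#' @param n_trials Number of trials behind the estimate (for the bias).
#' @return A list of class `info_estimate`: `mi`, `h_s`, `bias` (bits),
#'   `n_trials`, `n_bins`.
#' @export
mutual_information <- function(joint, n_trials = NA_integer_) {
  joint <- as.matrix(joint)
  if (any(joint < 0)) stop("negative joint probabilities")
  if (abs(sum(joint) - 1) > 1e-8) stop("joint probabilities must sum to 1")
  ps <- colSums(joint)
  pr <- rowSums(joint)
  expected <- outer(pr, ps)
  nz <- joint > 0
  mi <- sum(joint[nz] * log2(joint[nz] / expected[nz]))
  h_s <- -sum(ps[ps > 0] * log2(ps[ps > 0]))
  structure(list(mi = mi, h_s = h_s,
                 bias = mi_bias(length(joint), n_trials),
                 n_trials = n_trials, n_bins = length(joint)),
            class = "info_estimate")
}

#' @export
print.info_estimate <- function(x, ...) {
  cat(sprintf("I(S;R) = %.4f bits (H(S) = %.3f, bias ~ %.4f, N = %s)\n",
              x$mi, x$h_s, x$bias,
              if (is.na(x$n_trials)) "?" else x$n_trials))
  invisible(x)
}

#' First-order information sampling bias
#'
#' The positive bias of plug-in mutual-information estimates,
#' `#bins / (2 N ln 2)` bits, where `#bins` is the number of potentially
#' non-zero cells of the joint table and `N` the number of trials.
#'
#' @param n_bins Number of potentially non-zero joint cells.
#' @param n_trials Number of trials.
#' @return Bias in bits.
#' @examples
#' mi_bias(4, 752)  # ~0.004 bits
#' @export
mi_bias <- function(n_bins, n_trials) {
  n_bins / (2 * n_trials * log(2))
}

#' Confusion joint-probability table from predictions
#'
#' Each column (actual class `s`) is normalised by its own presentation
#' count and divided by the number of classes, so the class priors are
#' exactly uniform regardless of test-set imbalance.
#'
#' @param predicted,actual Factors/vectors of equal length.
#' @param classes Class levels (default: sorted unique actual values).
#' @return Joint probability matrix, predictions in rows.
#' @export
confusion_joint <- function(predicted, actual,
                            classes = sort(unique(actual))) {
  n_cl <- length(classes)
  joint <- matrix(0, n_cl, n_cl, dimnames = list(classes, classes))
  for (s in classes) {
    n_s <- sum(actual == s)
    if (n_s == 0) stop("no presentations of class ", s)
    for (r in classes)
      joint[as.character(r), as.character(s)] <-
        sum(predicted == r & actual == s) / (n_s * n_cl)
  }
  joint
}

fit_mlp <- function(x, y, hidden = 20, maxit = 200, decay = 1e-3) {
  # y: factor with two levels; returns function(newx) -> predicted level
  if (nlevels(droplevels(y)) < 2)
    stop("degenerate single-class training labels")
  lv <- levels(y)
  ybin <- as.numeric(y == lv[2])
  sc <- pmax(apply(x, 2, stats::sd), 1e-8)
  mu <- colMeans(x)
  xs <- scale(x, center = mu, scale = sc)
  fit <- nnet::nnet(xs, ybin, size = hidden, entropy = TRUE,
                    maxit = maxit, decay = decay, trace = FALSE,
                    MaxNWts = 50000, abstol = 1e-6, reltol = 1e-10)
  function(newx) {
    ns <- scale(newx, center = mu, scale = sc)
    p <- as.numeric(stats::predict(fit, ns))
    factor(ifelse(p > 0.5, lv[2], lv[1]), levels = lv)
  }
}

#' Decoder ensemble for temporal features
#'
#' Trains one small multi-layer perceptron (single hidden layer of
#' `hidden` saturating units, cross-entropy objective) per reference cell
#' on that cell's temporal feature vectors; the ensemble prediction for a
#' presentation is the majority vote across decoders. Reference cells
#' silent in a presentation abstain for it; a tie goes to the first class
#' level.
#'
#' @param features List of feature matrices, one per reference cell
#'   (rows = presentations, `NA` rows abstain).
#' @param labels Factor of class labels, one per presentation.
#' @param train Logical vector marking training presentations.
#' @param hidden Hidden-layer size (default 20).
#' @param maxit Maximum optimizer iterations.
#' @return A list with `predictions` (factor, test presentations),
#'   `actual`, `joint` (confusion joint table) and `votes`.
#' @export
fit_decoders <- function(features, labels, train, hidden = 20, maxit = 200,
                         decay = 1e-3) {
  labels <- factor(labels)
  labels <- droplevels(labels)
  if (nlevels(labels) < 2)
    stop("degenerate single-class labels")
  lv <- levels(labels)
  test <- !train
  votes <- matrix(0L, nrow = sum(test), ncol = length(lv),
                  dimnames = list(NULL, lv))
  for (f in features) {
    tr_ok <- train & !is.na(f[, 1])
    te_ok <- test & !is.na(f[, 1])
    if (sum(tr_ok) < 4 || length(unique(labels[tr_ok])) < 2) next
    pred_fun <- fit_mlp(f[tr_ok, , drop = FALSE],
                        droplevels(labels[tr_ok]),
                        hidden = hidden, maxit = maxit, decay = decay)
    if (!any(te_ok)) next
    pr <- pred_fun(f[te_ok, , drop = FALSE])
    rows <- match(which(te_ok), which(test))
    for (k in seq_along(rows))
      votes[rows[k], as.character(pr[k])] <-
        votes[rows[k], as.character(pr[k])] + 1L
  }
  predictions <- factor(lv[max.col(votes, ties.method = "first")],
                        levels = lv)
  actual <- labels[test]
  list(predictions = predictions, actual = actual,
       joint = confusion_joint(predictions, actual, lv), votes = votes)
}

#' Mutual information carried by a layer under a coding scheme
#'
#' The full decoding protocol for one layer: repeatedly subsample cells,
#' extract temporal or rate features, train decoders on a stratified
#' 50/50 presentation split, predict the held-out presentations, build the
#' confusion joint table and compute mutual information. Temporal mode
#' trains one decoder per sampled reference cell and majority-votes; rate
#' mode trains a single decoder on the rate vectors.
#'
#' @param raster A [spike_raster()] of the layer.
#' @param mode `"temporal"` or `"rate"`.
#' @param n_subsamples Number of independent cell subsamples (default 20).
#' @param j_cells Cells per subsample: temporal default 100 (also the
#'   number of voting decoders), rate default 201. Capped at the layer
#'   size.
#' @param seed RNG seed.
#' @param hidden Hidden-layer size; the default (`NULL`) uses 10\% of the
#'   feature dimension, i.e. 20 units at the full 201-feature protocol.
#' @param maxit Optimizer iteration budget per decoder.
#' @param decay Weight-decay regularisation of the decoders.
#' @param half_window Temporal-feature half window (ms).
#' @return data.frame of class `mi_result`: one row per subsample with
#'   `mode`, `rep`, `mi`, `accuracy`, `n_test`; attributes `h_s` and
#'   `bias`.
#' @export
decode_mi <- function(raster, mode = c("temporal", "rate"),
                      n_subsamples = 20,
                      j_cells = if (mode[1] == "temporal") 100 else 201,
                      seed, hidden = NULL, maxit = 200, decay = 1e-3,
                      half_window = 50) {
  mode <- match.arg(mode)
  set.seed(seed)
  pres <- raster$presentations
  labels <- factor(pres$class)
  if (nlevels(labels) != 2)
    stop("information protocol expects exactly two stimulus classes")
  j_cells <- min(j_cells, raster$n_neurons)
  n_feat <- if (mode == "temporal") j_cells + 2L * half_window + 1L else j_cells
  if (is.null(hidden)) hidden <- max(2L, round(0.1 * n_feat))
  out <- data.frame()
  joint_acc <- NULL
  for (r in seq_len(n_subsamples)) {
    train <- stratified_split(labels)
    cells <- sort(sample.int(raster$n_neurons, j_cells))
    if (mode == "temporal") {
      feats <- temporal_feature_set(raster, cells, cells,
                                    pres$presentation, half_window)
      fit <- fit_decoders(feats, labels, train, hidden, maxit, decay)
    } else {
      f <- rate_features(raster, cells, pres$presentation)
      pred_fun <- fit_mlp(f[train, , drop = FALSE],
                          droplevels(labels[train]), hidden, maxit, decay)
      predictions <- pred_fun(f[!train, , drop = FALSE])
      fit <- list(predictions = predictions, actual = labels[!train],
                  joint = confusion_joint(predictions, labels[!train],
                                          levels(labels)))
    }
    est <- mutual_information(fit$joint, n_trials = sum(!train))
    out <- rbind(out, data.frame(
      mode = mode, rep = r, mi = est$mi,
      accuracy = mean(fit$predictions == fit$actual),
      n_test = sum(!train)))
    joint_acc <- est
  }
  attr(out, "h_s") <- joint_acc$h_s
  attr(out, "bias") <- joint_acc$bias
  class(out) <- c("mi_result", "data.frame")
  out
}

stratified_split <- function(labels, frac = 0.5) {
  train <- logical(length(labels))
  for (lv in levels(labels)) {
    idx <- which(labels == lv)
    train[sample(idx, floor(length(idx) * frac))] <- TRUE
  }
  train
}

#' Evaluate information across layers and coding schemes
#'
#' Convenience wrapper running [decode_mi()] for each layer raster and
#' mode, returning one tidy table.
#'
#' @param rasters Named list of [spike_raster()] objects.
#' @param modes Coding schemes to evaluate.
#' @param ... Passed on to [decode_mi()] (`n_subsamples`, `j_cells`,
#'   `hidden`, `maxit`...).
#' @param seed Base seed; each layer/mode combination derives its own.
#' @return data.frame with columns `layer`, `mode`, `rep`, `mi`,
#'   `accuracy`, `n_test`.
#' @export
evaluate_information <- function(rasters, modes = c("temporal", "rate"),
                                 seed, ...) {
  out <- data.frame()
  k <- 0
  for (ly in names(rasters)) {
    for (md in modes) {
      k <- k + 1
      res <- decode_mi(rasters[[ly]], md, seed = sub_seed(seed, k), ...)
      res$layer <- ly
      out <- rbind(out, res)
    }
  }
  out[, c("layer", setdiff(names(out), "layer"))]
}
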