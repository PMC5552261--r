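#' Network configuration presets
#'
#' Builds the configuration of the full seven-population auditory pathway
#' (AN, the three cochlear-nucleus subpopulations CH/PL/ON, IC, A1, Belt)
#' or the reduced three-population control (AN, A1, Belt) in which the
#' subcortical stages are bypassed and the auditory nerve projects straight
#' to cortex.
#'
#' Layer sizes, within-layer inhibition, between-layer connectivity kinds,
#' fixed weights, the plastic-weight initialisation band `[30, 35]` nA, the
#' conduction-delay range `[0, 50]` ms and the STDP constants are the model
#' defaults; `n_scale` shrinks every population proportionally for
#' desk-scale simulation while keeping per-synapse weights (and hence
#' single-neuron dynamics) unchanged. Gaussian tonotopic widths are in
#' fibre-index units and are not rescaled.
#'
#' @param preset `"full"` or `"reduced"`.
#' @param n_scale Multiplier applied to all population sizes (default 1).
#' @param cortical_scale Multiplier for the cortical (A1, Belt)
#'   populations; defaults to `n_scale`. Keeping the subcortical chain
#'   wider than the cortex preserves the cortical afferent counts (hence
#'   per-cell drive) that the fixed Table-style weights assume.
#' @param p_dead Proportion of dead synapses on the sparse AN to onset-cell
#'   projection. Default 0.46; the alternative reading of the sparse
#'   connectivity (34\% connectivity, i.e. `p_dead = 0.66`) can be set here.
#' @param delay_range Conduction-delay range (ms) on plastic projections.
#' @param w_init Initial weight range (nA) on plastic projections.
#' @param alpha_d LTD magnitude; defaults to -0.015 for the full model and
#'   -0.033 for the reduced one.
#' @return A config list consumed by [build_network()].
#' @export
network_config <- function(preset = c("full", "reduced"), n_scale = 1,
                           cortical_scale = n_scale,
                           p_dead = 0.46, delay_range = c(0, 50),
                           w_init = c(30, 35),
                           alpha_d = if (preset[1] == "reduced") -0.033
                                     else -0.015) {
  preset <- match.arg(preset)
  n <- function(x) max(1L, as.integer(round(x * n_scale)))
  nc <- function(x) max(1L, as.integer(round(x * cortical_scale)))
  stdp <- stdp_params(alpha_d = alpha_d)
  layer <- function(name, n_exc, n_inh, exc_preset, w_ei, w_ie)
    list(name = name, n_exc = n_exc, n_inh = n_inh,
         exc_preset = exc_preset, inh_preset = "inhibitory",
         w_ei = w_ei, w_ie = w_ie)
  proj <- function(src, dst, kind, ..., w = NULL, plastic = FALSE)
    c(list(src = src, dst = dst, kind = kind, w = w, plastic = plastic,
           stdp = if (plastic) stdp), list(...))
  if (preset == "full") {
    layers <- list(
      layer("AN",   n(1000), 0L,      "excitatory_subcortical", 0, 0),
      layer("CH",   n(1000), n(1000), "excitatory_subcortical", 0, 0),
      layer("PL",   n(1000), n(1000), "excitatory_subcortical", 0, 0),
      layer("ON",   n(100),  n(100),  "excitatory_subcortical", 1000, -75),
      layer("IC",   n(1000), n(1000), "excitatory_subcortical", 1000, 0),
      layer("A1",   nc(1000), nc(1000), "excitatory_cortical",    1000, -6),
      layer("Belt", nc(1000), nc(1000), "excitatory_cortical",    1000, -6))
    projections <- list(
      proj("AN", "CH", "gaussian", sigma = 26, w_range = c(25, 30)),
      proj("AN", "PL", "one_to_one", w = 1000),
      proj("AN", "ON", "sparse", p_dead = p_dead, w = 26),
      proj("CH", "IC", "gaussian", sigma = 2, w = 400),
      proj("PL", "IC", "one_to_one", w = 400),
      proj("ON", "IC", "full", w = 3),
      proj("IC", "A1", "full", plastic = TRUE,
           w_range = w_init, delay_range = delay_range),
      proj("A1", "Belt", "full", plastic = TRUE,
           w_range = w_init, delay_range = delay_range))
  } else {
    layers <- list(
      layer("AN",   n(1000), 0L,      "excitatory_subcortical", 0, 0),
      layer("A1",   nc(1000), nc(1000), "excitatory_cortical",    1000, -6),
      layer("Belt", nc(1000), nc(1000), "excitatory_cortical",    1000, -6))
    projections <- list(
      proj("AN", "A1", "full", plastic = TRUE,
           w_range = w_init, delay_range = delay_range),
      proj("A1", "Belt", "full", plastic = TRUE,
           w_range = w_init, delay_range = delay_range))
  }
  list(preset = preset, n_scale = n_scale, cortical_scale = cortical_scale,
       dt = 0.1, layers = layers, projections = projections)
}

connect_pairs <- function(kind, n_src, n_dst, sigma = NULL, p_dead = NULL) {
  switch(kind,
    one_to_one = {
      if (n_src != n_dst)
        stop("one_to_one projection requires equal layer sizes (",
             n_src, " vs ", n_dst, ")")
      cbind(pre = seq_len(n_src), post = seq_len(n_dst))
    },
    full = {
      g <- expand.grid(pre = seq_len(n_src), post = seq_len(n_dst))
      cbind(pre = g$pre, post = g$post)
    },
    gaussian = {
      if (is.null(sigma) || sigma <= 0) stop("gaussian kind needs sigma > 0")
      out <- vector("list", n_dst)
      for (i in seq_len(n_dst)) {
        centre <- if (n_dst == 1) (n_src + 1) / 2 else
          1 + (i - 1) * (n_src - 1) / (n_dst - 1)
        p <- exp(-(seq_len(n_src) - centre)^2 / (2 * sigma^2))
        keep <- which(stats::runif(n_src) < p)
        if (length(keep))
          out[[i]] <- cbind(pre = keep, post = rep.int(i, length(keep)))
      }
      do.call(rbind, out)
    },
    sparse = {
      if (is.null(p_dead) || p_dead < 0 || p_dead > 1)
        stop("sparse kind needs p_dead in [0, 1]")
      g <- expand.grid(pre = seq_len(n_src), post = seq_len(n_dst))
      keep <- stats::runif(nrow(g)) >= p_dead
      cbind(pre = g$pre[keep], post = g$post[keep])
    },
    stop("unknown connectivity kind: ", kind))
}

#' Gaussian tonotopic connection census
#'
#' Realises the Gaussian topological connectivity used on the AN to chopper
#' and chopper to IC projections: each target cell draws Bernoulli
#' afferents from a tonotopic neighbourhood of its linearly aligned source
#' index, with connection probability `exp(-(j - centre)^2 / (2 sigma^2))`
#' (peak probability 1, truncated at the array edges, no wraparound).
#'
#' @param n_src,n_dst Source and target population sizes.
#' @param sigma Tonotopic width in source-index units, `> 0`.
#' @param seed RNG seed.
#' @return data.frame with columns `pre`, `post` (1-based indices).
#' @export
connect_gaussian <- function(n_src, n_dst, sigma, seed) {
  set.seed(seed)
  as.data.frame(connect_pairs("gaussian", n_src, n_dst, sigma = sigma))
}

#' Build a spiking network from a configuration
#'
#' Instantiates populations and synapses: one excitatory and (optionally)
#' one inhibitory population per layer, one-to-one excitatory-to-inhibitory
#' and all-to-all inhibitory-to-excitatory within-layer wiring, and the
#' configured between-layer projections. Random draws (Gaussian/sparse
#' connectivity, initial plastic weights, conduction delays) are
#' deterministic under `seed`.
#'
#' @param config A list from [network_config()], or a hand-built one with
#'   the same shape.
#' @param seed Integer RNG seed.
#' @return An object of class `spiking_network`.
#' @export
build_network <- function(config, seed) {
  set.seed(seed)
  dt <- config$dt %||% 0.1
  layers <- config$layers
  lnames <- vapply(layers, `[[`, "", "name")
  if (anyDuplicated(lnames)) stop("duplicate layer names")

  groups <- list(); gidx <- c()
  for (ly in layers) {
    ge <- list(name = paste0(ly$name, ":E"), n = ly$n_exc,
               is_input = identical(ly$name, lnames[1]) && ly$n_inh == 0,
               preset = ly$exc_preset)
    groups[[length(groups) + 1]] <- ge
    gidx[ge$name] <- length(groups)
    if (ly$n_inh > 0) {
      gi <- list(name = paste0(ly$name, ":I"), n = ly$n_inh,
                 is_input = FALSE, preset = ly$inh_preset)
      groups[[length(groups) + 1]] <- gi
      gidx[gi$name] <- length(groups)
    }
  }

  projections <- list()
  add_proj <- function(name, src, dst, pre, post, w, delay_steps,
                       plastic = FALSE, stdp = NULL) {
    projections[[name]] <<- list(
      name = name, src = src, dst = dst,
      pre = as.integer(pre), post = as.integer(post),
      w = as.numeric(w), delay_steps = as.integer(delay_steps),
      plastic = plastic, stdp = stdp)
  }

  # within-layer inhibition (omitted entirely when I cells cannot act back)
  for (ly in layers) {
    if (ly$n_inh > 0 && ly$w_ei != 0 && ly$w_ie != 0) {
      if (ly$n_inh != ly$n_exc)
        stop("one_to_one E->I wiring requires n_inh == n_exc in ", ly$name)
      add_proj(paste0(ly$name, ":EI"),
               paste0(ly$name, ":E"), paste0(ly$name, ":I"),
               seq_len(ly$n_exc), seq_len(ly$n_inh),
               rep(ly$w_ei, ly$n_exc), rep(1L, ly$n_exc))
    }
    if (ly$n_inh > 0 && ly$w_ie != 0) {
      g <- expand.grid(pre = seq_len(ly$n_inh), post = seq_len(ly$n_exc))
      add_proj(paste0(ly$name, ":IE"),
               paste0(ly$name, ":I"), paste0(ly$name, ":E"),
               g$pre, g$post, rep(ly$w_ie, nrow(g)), rep(1L, nrow(g)))
    }
  }

  # between-layer projections
  for (pj in config$projections) {
    src <- layers[[match(pj$src, lnames)]]
    dst <- layers[[match(pj$dst, lnames)]]
    if (is.null(src) || is.null(dst))
      stop("projection references unknown layer")
    pairs <- connect_pairs(pj$kind, src$n_exc, dst$n_exc,
                           sigma = pj$sigma, p_dead = pj$p_dead)
    m <- nrow(pairs)
    w <- if (!is.null(pj$w_range))
      stats::runif(m, pj$w_range[1], pj$w_range[2]) else rep(pj$w, m)
    delay_steps <- if (!is.null(pj$delay_range)) {
      d_ms <- stats::runif(m, pj$delay_range[1], pj$delay_range[2])
      pmax(1L, as.integer(ceiling(d_ms / dt)))
    } else rep(1L, m)
    add_proj(paste0(pj$src, "->", pj$dst),
             paste0(pj$src, ":E"), paste0(pj$dst, ":E"),
             pairs[, "pre"], pairs[, "post"], w, delay_steps,
             plastic = isTRUE(pj$plastic), stdp = pj$stdp)
  }

  structure(list(config = config, dt = dt, seed = seed,
                 layers = layers, layer_names = lnames,
                 groups = groups, group_index = gidx,
                 projections = projections),
            class = "spiking_network")
}

#' @export
print.spiking_network <- function(x, ...) {
  cat(sprintf("spiking_network (%s preset, scale %g): %d layers, %d projections\n",
              x$config$preset %||% "custom", x$config$n_scale %||% 1,
              length(x$layers), length(x$projections)))
  for (p in x$projections)
    cat(sprintf("  %-12s %7d synapses%s\n", p$name, length(p$w),
                if (p$plastic) " [plastic]" else ""))
  invisible(x)
}

#' Plastic weights of a network
#' @param network A `spiking_network`.
#' @return Named list of numeric weight vectors, one per plastic projection.
#' @export
plastic_weights <- function(network) {
  pl <- Filter(function(p) p$plastic, network$projections)
  stats::setNames(lapply(pl, `[[`, "w"), vapply(pl, `[[`, "", "name"))
}

engine_groups <- function(network, record_groups) {
  lapply(network$groups, function(g) {
    if (g$is_input)
      return(list(n = g$n, is_input = TRUE, record = FALSE))
    p <- izh_preset(g$preset)
    r <- izh_rest(p)
    list(n = g$n, is_input = FALSE, record = g$name %in% record_groups,
         a = p$a, b = p$b, c = p$c, d = p$d, threshold = p$threshold,
         v0 = r$v, u0 = r$u)
  })
}

engine_projections <- function(network) {
  gidx <- network$group_index
  lapply(unname(network$projections), function(p) {
    out <- list(src = gidx[[p$src]] - 1L, dst = gidx[[p$dst]] - 1L,
                pre = p$pre - 1L, post = p$post - 1L, w = p$w,
                delay = p$delay_steps, plastic = p$plastic)
    if (p$plastic) {
      s <- p$stdp
      out <- c(out, list(tau_p = s$tau_p, tau_d = s$tau_d,
                         alpha_p = s$alpha_p, alpha_d = s$alpha_d,
                         w_max = s$w_max,
                         window = 7 * max(s$tau_p, s$tau_d),
                         blank = max(s$tau_p, s$tau_d)))
    }
    out
  })
}

#' Run the discrete-time simulation
#'
#' Presents every presentation of the input raster to the network in
#' schedule order. Input-layer events are injected as spikes at their
#' listed times; downstream populations are integrated at `dt = 0.1` ms
#' with per-synapse delay buffers; when `learn = TRUE` the plastic weights
#' are updated online by the nearest-only mixed STDP rule and carried
#' across presentations. Neuron state, synaptic currents and STDP pairing
#' ledgers are reset at each presentation onset. The run is fully
#' deterministic given the built network and input.
#'
#' @param network A `spiking_network`; the input layer is the first layer.
#' @param input A [spike_raster()] for the input layer.
#' @param learn Update plastic weights online?
#' @param record Character vector of layer names to record (default all).
#' @param record_inhibitory Also record inhibitory populations?
#' @return A list with `rasters` (named list of `spike_raster`, one per
#'   recorded layer), `weights_before`, `weights_after` (named lists of
#'   plastic weight vectors) and `network` (with updated weights).
#' @export
run_network <- function(network, input, learn = FALSE,
                        record = network$layer_names,
                        record_inhibitory = FALSE) {
  stopifnot(inherits(network, "spiking_network"),
            inherits(input, "spike_raster"))
  in_layer <- network$layer_names[1]
  n_in <- network$layers[[1]]$n_exc
  if (input$n_neurons != n_in)
    stop("input raster has ", input$n_neurons, " neurons; input layer has ",
         n_in)
  dt <- network$dt
  record_groups <- c(paste0(record, ":E"),
                     if (record_inhibitory) paste0(record, ":I"))
  g_in <- engine_groups(network, record_groups)
  p_in <- engine_projections(network)
  gnames <- vapply(network$groups, `[[`, "", "name")
  input_gi <- which(gnames == paste0(in_layer, ":E"))

  weights_before <- plastic_weights(network)
  pl_idx <- which(vapply(network$projections, `[[`, TRUE, "plastic"))
  sched <- input$presentations
  ev_split <- split(input$events, factor(input$events$presentation,
                                         levels = sched$presentation))

  rec_events <- stats::setNames(
    rep(list(vector("list", nrow(sched))), length(record_groups)),
    record_groups)

  for (pi in seq_len(nrow(sched))) {
    pid <- sched$presentation[pi]
    dur <- sched$duration[pi]
    n_steps <- as.integer(ceiling(dur / dt))
    ev <- ev_split[[pi]]
    inp <- rep(list(list(neuron = integer(), step = integer())),
               length(g_in))
    inp[[input_gi]] <- list(neuron = as.integer(ev$neuron) - 1L,
                            step = as.integer(floor(ev$time / dt)))
    res <- engine_run(g_in, p_in, inp, n_steps, dt, learn)
    # carry plastic weights into the next presentation
    for (k in seq_along(pl_idx))
      p_in[[pl_idx[k]]]$w <- res$weights[[pl_idx[k]]]
    for (g in seq_along(g_in)) {
      if (!isTRUE(g_in[[g]]$record)) next
      sp <- res$spikes[[g]]
      if (length(sp$neuron) == 0) next
      rec_events[[gnames[g]]][[pi]] <- data.frame(
        presentation = pid, neuron = sp$neuron + 1L,
        time = sp$step * dt)
    }
  }

  for (k in seq_along(pl_idx))
    network$projections[[pl_idx[k]]]$w <- p_in[[pl_idx[k]]]$w

  rasters <- list()
  for (ly in record) {
    gname <- paste0(ly, ":E")
    if (ly == in_layer) { rasters[[ly]] <- input; next }
    ev <- do.call(rbind, rec_events[[gname]])
    if (is.null(ev))
      ev <- data.frame(presentation = integer(), neuron = integer(),
                       time = numeric())
    n_ly <- network$layers[[match(ly, network$layer_names)]]$n_exc
    rasters[[ly]] <- spike_raster(ev, sched, n_ly)
  }

  list(rasters = rasters, weights_before = weights_before,
       weights_after = plastic_weights(network), network = network)
}

#' Weight histogram before/after training
#'
#' @param before,after Numeric weight vectors of equal length (one plastic
#'   projection, e.g. from [plastic_weights()]).
#' @param bins Number of bins over `[0, w_max]`.
#' @param w_max Upper edge of the histogram (default 60 nA).
#' @return data.frame with columns `lower`, `upper`, `before`, `after`.
#' @export
weight_histogram <- function(before, after, bins = 60, w_max = 60) {
  if (length(before) != length(after))
    stop("weight snapshots differ in length")
  br <- seq(0, w_max, length.out = bins + 1)
  bin_counts <- function(w) {
    idx <- pmin(pmax(findInterval(w, br, rightmost.closed = TRUE), 1L), bins)
    tabulate(idx, nbins = bins)
  }
  data.frame(lower = br[-length(br)], upper = br[-1],
             before = bin_counts(before), after = bin_counts(after))
}

#' Shuffle plastic weights within projections
#'
#' Permutes the assignment of weights to synapses within each named
#' projection, preserving the weight multiset exactly. Used as the
#' shuffled-weight control: a network with the trained weight distribution
#' but destroyed weight-to-delay-line correspondence.
#'
#' @param network A `spiking_network`.
#' @param projections Names of projections to shuffle (default all plastic).
#' @param seed RNG seed.
#' @return The network with shuffled weights.
#' @export
shuffle_weights <- function(network, projections = names(plastic_weights(network)),
                            seed) {
  set.seed(seed)
  for (nm in projections) {
    if (is.null(network$projections[[nm]]))
      stop("unknown projection: ", nm)
    w <- network$projections[[nm]]$w
    network$projections[[nm]]$w <- w[sample.int(length(w))]
  }
  network
}
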