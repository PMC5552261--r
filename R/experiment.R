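#' Derive a sub-seed from a master seed
#'
#' Counter-based derivation (a SplitMix-style integer hash of the pair)
#' so that adding a pipeline stage never perturbs the randomness of
#' earlier stages. Results stay within the positive 32-bit integer range.
#'
#' @param master Master seed (integer).
#' @param index Stage counter (integer, >= 0).
#' @return An integer seed.
#' @export
sub_seed <- function(master, index) {
  x <- (as.double(master) * 2654435761 + as.double(index) * 40503 + 1013904223)
  x <- x %% 2147483647
  z <- (x * 48271) %% 2147483647
  as.integer(z %% 2147483562 + 1)
}

#' Experiment configuration
#'
#' Bundles every knob of an end-to-end run: synthetic-dataset parameters,
#' network preset and scale, training passes, and evaluation settings.
#' Fully serialisable (plain lists and atomic values); every stochastic
#' stage of [run_experiment()] receives a sub-seed derived from
#' `master_seed` with [sub_seed()].
#'
#' @param preset Network preset, `"full"` or `"reduced"`.
#' @param n_scale Population-size multiplier (default 0.1: 100-cell
#'   layers).
#' @param cortical_scale Multiplier for the cortical populations
#'   (defaults to `n_scale`; see [network_config()]).
#' @param epochs Training passes over the training set (default 10).
#' @param n_speakers Speakers (latent positions) per class.
#' @param n_test_repetitions Presentations of each test exemplar
#'   (default 4; repeats differ by input stochasticity only).
#' @param template_args,noise_args Argument lists for
#'   [pattern_templates()] and [noise_model()].
#' @param silence_ms Post-stimulus silence (ms).
#' @param eval_layers Layers to evaluate (default: input plus the plastic
#'   cortical layers).
#' @param modes Coding schemes for the information analysis.
#' @param n_subsamples,j_temporal,j_rate,hidden,maxit Decoding settings
#'   (see [decode_mi()]).
#' @param pi_cells Number of reference cells scored per layer by the
#'   polychronization index.
#' @param controls Character subset of `c("untrained", "shuffled")`:
#'   additional evaluations of the untrained network and of the trained
#'   network with within-projection weight shuffling.
#' @param lambda_offset_test Latent offset of test pronunciations.
#' @param master_seed Master seed.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(preset = "full", n_scale = 0.1,
                              cortical_scale = n_scale, epochs = 10,
                              n_speakers = 8, n_test_repetitions = 4,
                              template_args = list(), noise_args = list(),
                              silence_ms = 100,
                              eval_layers = NULL,
                              modes = c("temporal", "rate"),
                              n_subsamples = 5, j_temporal = 20,
                              j_rate = 60, hidden = NULL, maxit = 150,
                              pi_cells = 30,
                              controls = character(),
                              lambda_offset_test = 0.03,
                              master_seed = 1) {
  cfg <- list(preset = preset, n_scale = n_scale,
              cortical_scale = cortical_scale, epochs = epochs,
              n_speakers = n_speakers,
              n_test_repetitions = n_test_repetitions,
              template_args = template_args, noise_args = noise_args,
              silence_ms = silence_ms, eval_layers = eval_layers,
              modes = modes, n_subsamples = n_subsamples,
              j_temporal = j_temporal, j_rate = j_rate, hidden = hidden,
              maxit = maxit, pi_cells = pi_cells, controls = controls,
              lambda_offset_test = lambda_offset_test,
              master_seed = master_seed)
  class(cfg) <- "experiment_config"
  cfg
}

config_fingerprint <- function(cfg) {
  json <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  # order-stable digest of the serialised config (no external digest dep)
  bytes <- as.integer(charToRaw(as.character(json)))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x-%d", h, nchar(json))
}

#' Run a complete seeded experiment
#'
#' Generates the synthetic dataset, builds the network, trains it with the
#' configured number of interleaved passes (each pass re-realises the
#' training pronunciations with fresh input stochasticity), evaluates the
#' trained model on held-out pronunciations with repeated presentations,
#' and computes the polychronization-index and mutual-information tables.
#' Optional controls re-evaluate the untrained network and a
#' shuffled-weight version of the trained network on the same test input.
#'
#' @param config An [experiment_config()].
#' @param verbose Print stage progress?
#' @return A list of class `experiment_result`: `rasters` (test responses
#'   per layer), `pi` (per-layer PI tables), `mi` (information table,
#'   including control conditions), `weights_before`, `weights_after`,
#'   `controls`, and `manifest` (config, fingerprint, derived seeds).
#' @export
run_experiment <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  ms <- config$master_seed
  say <- function(...) if (verbose) message(sprintf(...))

  tpl_args <- utils::modifyList(
    list(n_classes = 2, n_fibres = max(1L, as.integer(round(1000 * config$n_scale))),
         seed = sub_seed(ms, 1)),
    config$template_args)
  templates <- do.call(pattern_templates, tpl_args)
  noise <- do.call(noise_model, config$noise_args)

  say("building %s network (scale %g)", config$preset, config$n_scale)
  net <- build_network(network_config(config$preset, config$n_scale,
                                      config$cortical_scale %||% config$n_scale),
                       seed = sub_seed(ms, 2))
  net0 <- net
  weights_before <- plastic_weights(net)

  say("training: %d epochs x %d speakers x 2 classes", config$epochs,
      config$n_speakers)
  if (config$epochs > 0) {
    for (ep in seq_len(config$epochs)) {
      train_raster <- generate_dataset(
        templates, noise, config$n_speakers, n_repetitions = 1,
        silence_ms = config$silence_ms, seed = sub_seed(ms, 100 + ep))
      run <- run_network(net, train_raster, learn = TRUE,
                         record = character())
      net <- run$network
    }
  }
  weights_after <- plastic_weights(net)

  say("evaluating on held-out pronunciations")
  test_raster <- generate_dataset(
    templates, noise, config$n_speakers,
    n_repetitions = config$n_test_repetitions,
    silence_ms = config$silence_ms, seed = sub_seed(ms, 3),
    lambda_offset = config$lambda_offset_test)
  eval_layers <- config$eval_layers %||%
    intersect(c("AN", "IC", "A1", "Belt"), net$layer_names)
  run <- run_network(net, test_raster, learn = FALSE, record = eval_layers)

  say("polychronization index")
  pi_tabs <- list()
  for (ly in eval_layers) {
    ra <- run$rasters[[ly]]
    cells <- seq_len(min(config$pi_cells, ra$n_neurons))
    pi_tabs[[ly]] <- tryCatch(
      polychronization_index(ra, cells, seed = sub_seed(ms, 4)),
      error = function(e) NULL)
  }

  say("information analysis")
  mi <- data.frame()
  k <- 0
  eval_mi <- function(rasters, condition) {
    for (ly in names(rasters)) for (md in config$modes) {
      k <<- k + 1
      jc <- if (md == "temporal") config$j_temporal else config$j_rate
      res <- decode_mi(rasters[[ly]], md, config$n_subsamples, jc,
                       seed = sub_seed(ms, 200 + k),
                       hidden = config$hidden, maxit = config$maxit)
      res$layer <- ly; res$condition <- condition
      mi <<- rbind(mi, res)
    }
  }
  eval_mi(run$rasters, "trained")

  control_runs <- list()
  if ("untrained" %in% config$controls && config$epochs > 0) {
    say("control: untrained network")
    r0 <- run_network(net0, test_raster, learn = FALSE,
                      record = setdiff(eval_layers, "AN"))
    control_runs$untrained <- r0$rasters
    eval_mi(r0$rasters, "untrained")
  }
  if ("shuffled" %in% config$controls) {
    say("control: shuffled weights")
    ns <- shuffle_weights(net, seed = sub_seed(ms, 5))
    rs <- run_network(ns, test_raster, learn = FALSE,
                      record = setdiff(eval_layers, "AN"))
    control_runs$shuffled <- rs$rasters
    eval_mi(rs$rasters, "shuffled")
  }

  manifest <- list(
    config = unclass(config),
    fingerprint = config_fingerprint(config),
    seeds = list(templates = sub_seed(ms, 1), network = sub_seed(ms, 2),
                 test_set = sub_seed(ms, 3), pi = sub_seed(ms, 4)),
    layers = eval_layers)

  structure(list(rasters = run$rasters, pi = pi_tabs, mi = mi,
                 weights_before = weights_before,
                 weights_after = weights_after,
                 controls = control_runs, network = net,
                 manifest = manifest),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("experiment_result:", x$manifest$config$preset, "preset,",
      "fingerprint", x$manifest$fingerprint, "\n")
  if (nrow(x$mi)) {
    agg <- stats::aggregate(mi ~ layer + mode + condition, data = x$mi,
                            FUN = stats::median)
    print(agg, row.names = FALSE)
  }
  invisible(x)
}
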