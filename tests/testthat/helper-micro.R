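# Builders for micro-networks used across tests.

micro_layer <- function(name, n, preset = "excitatory_subcortical",
                        n_inh = 0L, w_ei = 0, w_ie = 0) {
  list(name = name, n_exc = as.integer(n), n_inh = as.integer(n_inh),
       exc_preset = preset, inh_preset = "inhibitory",
       w_ei = w_ei, w_ie = w_ie)
}

# input layer `IN` of n_in fibres feeding one layer `OUT`
micro_net <- function(n_in, n_out, kind = "full", w = NULL,
                      w_range = NULL, delay_range = NULL, plastic = FALSE,
                      stdp = stdp_params(), out_preset = "excitatory_subcortical",
                      w_ie = 0, n_inh = 0L, seed = 1) {
  cfg <- list(dt = 0.1, layers = list(
    micro_layer("IN", n_in),
    micro_layer("OUT", n_out, out_preset, n_inh = n_inh,
                w_ei = if (n_inh > 0) 1000 else 0, w_ie = w_ie)),
    projections = list(list(src = "IN", dst = "OUT", kind = kind, w = w,
                            w_range = w_range, delay_range = delay_range,
                            plastic = plastic, stdp = stdp)))
  build_network(cfg, seed = seed)
}

one_pres_raster <- function(neuron, time, n_neurons, duration = 100,
                            class = "a") {
  spike_raster(data.frame(presentation = 1L, neuron = neuron, time = time),
               data.frame(presentation = 1L, class = class, exemplar = 1L,
                          duration = duration),
               n_neurons)
}

# raster from a list of per-presentation event data.frames (neuron, time)
multi_pres_raster <- function(events_list, n_neurons, duration,
                              classes = rep("a", length(events_list))) {
  ev <- do.call(rbind, lapply(seq_along(events_list), function(i) {
    e <- events_list[[i]]
    if (nrow(e)) cbind(presentation = i, e) else NULL
  }))
  if (is.null(ev))
    ev <- data.frame(presentation = integer(), neuron = integer(),
                     time = numeric())
  spike_raster(ev,
               data.frame(presentation = seq_along(events_list),
                          class = classes,
                          exemplar = seq_along(events_list),
                          duration = duration),
               n_neurons)
}
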