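#' Class pattern templates for the auditory-nerve surrogate
#'
#' Each stimulus class is a repeating spatio-temporal spike pattern across
#' the input fibres, organised the way voiced speech drives the auditory
#' nerve: spikes cluster into near-synchronous volleys at the glottal
#' pulse times of a fundamental (`f0_hz`), and a spectral envelope of a
#' few strongly driven tonotopic bands (a formant surrogate) sets the
#' per-fibre firing rates. A fraction `band_share` of the bands is common
#' to every class; the rest are class-specific, so classes differ both
#' spectrally (as spoken words do) and — far more strongly — in the
#' spatio-temporal arrangement of spikes across pulses. Mean rates are
#' equal across classes, the functional analogue of loudness
#' normalisation.
#'
#' Pronunciation (speaker) variability is a smooth one-dimensional latent
#' factor `lambda` in `[0, 1]`: the speaker's fundamental is scaled by
#' `1 + f0_spread * (lambda - 1/2)`, every pulse carries a smooth per-pulse
#' time warp, and each event a fibre drift. Densely sampled `lambda`
#' values give strongly overlapping neighbouring exemplars, the data
#' constraint under which Hebbian learning can bind within-class variants
#' together (continuous-transformation learning).
#'
#' @param n_classes Number of stimulus classes.
#' @param n_fibres Number of input fibres.
#' @param duration Pattern duration in ms.
#' @param rate_hz Mean within-pattern firing rate per fibre (Hz). Equal
#'   across classes, the functional analogue of loudness normalisation.
#' @param f0_hz Fundamental (glottal pulse rate) of the canonical
#'   pronunciation, Hz.
#' @param pulse_jitter SD (ms) of spike placement around its pulse.
#' @param f0_spread Relative spread of the fundamental across speakers.
#' @param warp_sd SD of the smooth per-pulse time warp (ms per unit
#'   lambda).
#' @param drift_max Maximum per-event fibre drift (fibres per unit lambda).
#' @param n_bands Number of strongly driven tonotopic bands in the
#'   spectral envelope (formant surrogate).
#' @param band_sd Band width (SD, in fibre-index units) as a fraction of
#'   `n_fibres`.
#' @param band_contrast Peak-to-floor ratio of the spectral envelope.
#' @param band_share Fraction of the bands common to every class (band
#'   positions rounded up). The default 1 matches the classes spectrally,
#'   the raster analogue of loudness normalisation: class identity is
#'   then carried by which fibres fire on which pulses rather than by
#'   fibre-level rates. Lower values give classes private formant bands,
#'   as distinct spoken words have, letting rate codes carry class
#'   information too.
#' @param seed RNG seed.
#' @return A list of class `pattern_templates`: one element per class with
#'   fields `class`, `events` (fibre, pulse, offset, dfibre),
#'   `pulse_times`, `pulse_warp`, `f0_hz`, `f0_spread`, `duration`,
#'   `n_fibres`.
#' @export
pattern_templates <- function(n_classes = 2, n_fibres = 100, duration = 300,
                              rate_hz = 60, f0_hz = 100, pulse_jitter = 1,
                              f0_spread = 0.15, warp_sd = 4, drift_max = 3,
                              n_bands = 4, band_sd = 0.04,
                              band_contrast = 25, band_share = 1, seed) {
  stopifnot(n_classes >= 1, n_fibres >= 1, duration > 0, rate_hz >= 0,
            f0_hz > 0, n_bands >= 0, band_contrast >= 1,
            band_share >= 0, band_share <= 1)
  set.seed(seed)
  f <- seq_len(n_fibres)
  n_shared <- if (n_bands > 0) ceiling(n_bands * band_share) else 0L
  shared <- stats::runif(n_shared, 0.05, 0.95) * n_fibres
  envelope <- function(centres) {
    profile <- rep(1, n_fibres)
    for (cb in centres)
      profile <- profile +
        (band_contrast - 1) * exp(-(f - cb)^2 / (2 * (band_sd * n_fibres)^2))
    profile / mean(profile)
  }
  pulse_times <- seq(1000 / f0_hz / 2, duration - 1e-9, by = 1000 / f0_hz)
  n_pulses <- length(pulse_times)
  # with a fully shared envelope the per-fibre spike budget is drawn once
  # and reused, so fibre-level rates carry no class information at all
  counts_shared <- stats::rpois(n_fibres,
                                envelope(shared) * rate_hz * duration / 1000)
  out <- lapply(seq_len(n_classes), function(cl) {
    counts <- if (n_shared == n_bands) counts_shared else {
      own <- stats::runif(n_bands - n_shared, 0.05, 0.95) * n_fibres
      stats::rpois(n_fibres, envelope(c(shared, own)) * rate_hz *
                     duration / 1000)
    }
    fibre <- rep(f, counts)
    n_ev <- length(fibre)
    ev <- data.frame(
      fibre = fibre,
      pulse = sample.int(n_pulses, n_ev, replace = TRUE),
      offset = stats::rnorm(n_ev, 0, pulse_jitter),
      dfibre = sample(seq(-drift_max, drift_max), n_ev, replace = TRUE))
    list(class = paste0("class", cl), events = ev,
         pulse_times = pulse_times,
         pulse_warp = stats::rnorm(n_pulses, 0, warp_sd),
         f0_hz = f0_hz, f0_spread = f0_spread,
         duration = duration, n_fibres = n_fibres)
  })
  structure(out, class = "pattern_templates")
}

#' Noise model for the auditory-nerve surrogate
#'
#' The stochastic degradations applied to every pattern presentation:
#' temporal jitter (Gaussian, truncated at three SDs) emulating degraded
#' phase locking, spatial jitter relocating a spike to a uniformly chosen
#' fibre within `spatial_range` (the volley principle), per-spike deletion,
#' and additive background Poisson firing on every fibre.
#'
#' @param bg_rate_hz Background Poisson rate per fibre (Hz).
#' @param jitter_sd Temporal jitter SD (ms).
#' @param spatial_range Spatial jitter range in fibres (0 disables).
#' @param p_delete Pattern-spike deletion probability.
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(bg_rate_hz = 5, jitter_sd = 1, spatial_range = 1,
                        p_delete = 0.1) {
  stopifnot(bg_rate_hz >= 0, jitter_sd >= 0, spatial_range >= 0,
            p_delete >= 0, p_delete <= 1)
  structure(list(bg_rate_hz = bg_rate_hz, jitter_sd = jitter_sd,
                 spatial_range = as.integer(spatial_range),
                 p_delete = p_delete),
            class = "noise_model")
}

rtnorm3 <- function(n, sd) {
  # Gaussian truncated at +/- 3 sd by resampling
  if (sd == 0 || n == 0) return(numeric(n))
  x <- stats::rnorm(n, 0, sd)
  bad <- abs(x) > 3 * sd
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), 0, sd)
    bad <- abs(x) > 3 * sd
  }
  x
}

realise_presentation <- function(template, lambda, noise) {
  ev <- template$events
  n_f <- template$n_fibres
  dur <- template$duration
  fibre <- ev$fibre + round(lambda * ev$dfibre)
  # speaker realisation of the pulse train: scaled fundamental plus a
  # smooth per-pulse warp, shared by all fibres so volleys stay aligned
  pulses <- template$pulse_times / (1 + template$f0_spread * (lambda - 0.5)) +
    lambda * template$pulse_warp
  time <- pulses[ev$pulse] + ev$offset
  keep <- stats::runif(nrow(ev)) >= noise$p_delete
  fibre <- fibre[keep]; time <- time[keep]
  if (noise$spatial_range > 0 && length(fibre))
    fibre <- fibre + sample(seq(-noise$spatial_range, noise$spatial_range),
                            length(fibre), replace = TRUE)
  if (noise$jitter_sd > 0)
    time <- time + rtnorm3(length(time), noise$jitter_sd)
  ok <- fibre >= 1 & fibre <= n_f & time >= 0 & time < dur
  fibre <- fibre[ok]; time <- time[ok]
  if (noise$bg_rate_hz > 0) {
    n_bg <- stats::rpois(1, n_f * noise$bg_rate_hz * dur / 1000)
    fibre <- c(fibre, sample.int(n_f, n_bg, replace = TRUE))
    time <- c(time, stats::runif(n_bg, 0, dur))
  }
  data.frame(neuron = fibre, time = time)
}

#' Generate a synthetic auditory-nerve dataset
#'
#' Produces an interleaved presentation schedule of class exemplars. Each
#' presentation realises its class template at the speaker's latent
#' position, applies the noise model afresh, and is followed by
#' `silence_ms` of empty raster (the presentation duration includes the
#' silence). Deterministic under `seed`.
#'
#' @param templates A [pattern_templates()] object.
#' @param noise A [noise_model()].
#' @param n_speakers Number of speakers (latent positions, evenly spaced in
#'   `[0, 1]`).
#' @param n_repetitions Presentations per speaker per class.
#' @param silence_ms Silence appended after each pattern (ms).
#' @param seed RNG seed.
#' @param lambda_offset Shift added to every speaker's latent position
#'   (used to realise unseen pronunciations of the same speakers).
#' @return A [spike_raster()] whose presentation table carries `class`,
#'   `exemplar` (speaker), `repetition` and `lambda`.
#' @export
generate_dataset <- function(templates, noise, n_speakers, n_repetitions = 1,
                             silence_ms = 100, seed, lambda_offset = 0) {
  stopifnot(inherits(templates, "pattern_templates"),
            inherits(noise, "noise_model"), n_speakers >= 1)
  set.seed(seed)
  n_f <- templates[[1]]$n_fibres
  dur <- templates[[1]]$duration + silence_ms
  lambdas <- if (n_speakers == 1) 0.5 else
    seq(0, 1, length.out = n_speakers)
  lambdas <- pmin(1, pmax(0, lambdas + lambda_offset))
  grid <- expand.grid(class_i = seq_along(templates),
                      speaker = seq_len(n_speakers),
                      repetition = seq_len(n_repetitions))
  # interleaved: classes alternate fastest
  grid <- grid[order(grid$repetition, grid$speaker, grid$class_i), ]
  events <- vector("list", nrow(grid))
  pres <- data.frame(
    presentation = seq_len(nrow(grid)),
    class = vapply(templates, `[[`, "", "class")[grid$class_i],
    exemplar = grid$speaker, repetition = grid$repetition,
    lambda = lambdas[grid$speaker], duration = dur)
  for (i in seq_len(nrow(grid))) {
    ev <- realise_presentation(templates[[grid$class_i[i]]],
                               pres$lambda[i], noise)
    if (nrow(ev)) ev$presentation <- pres$presentation[i]
    events[[i]] <- ev
  }
  events <- do.call(rbind, events)
  if (is.null(events) || nrow(events) == 0)
    events <- data.frame(presentation = integer(), neuron = integer(),
                         time = numeric())
  spike_raster(events[, c("presentation", "neuron", "time")], pres, n_f)
}

#' Continuous spike stream with an embedded repeating pattern
#'
#' The single-neuron pattern-from-noise benchmark: a continuous Poisson
#' spike stream over `n_input` afferents in which a frozen spatio-temporal
#' pattern of `pattern_ms` recurs in a fraction `pattern_fraction` of time
#' segments. Pattern segments replay the frozen spikes of the pattern
#' afferents (optionally jittered); all other activity is fresh Poisson at
#' the same rate, so pattern and background segments are statistically
#' identical in rate.
#'
#' @param n_input Number of afferent fibres.
#' @param pattern_fraction Fraction of segments carrying the pattern,
#'   in `(0, 1]`.
#' @param duration_s Stream length in seconds.
#' @param rate_hz Firing rate per afferent (Hz), everywhere.
#' @param pattern_ms Pattern (and segment) duration in ms.
#' @param pattern_afferents Indices of afferents participating in the
#'   pattern (default: all, so pattern and background segments are
#'   exchangeable except for the frozen structure).
#' @param jitter_sd Temporal jitter SD (ms) on replayed pattern spikes.
#' @param pattern Optional frozen pattern (the `pattern` element of a
#'   previous call) to re-embed in fresh background — used to build test
#'   streams carrying the trained pattern.
#' @param seed RNG seed.
#' @return A list with `raster` (single-presentation [spike_raster()];
#'   events carry an `is_pattern` mask column identifying replayed pattern
#'   spikes), `segments` (data.frame of segment onsets and pattern flags)
#'   and `pattern` (the frozen template events).
#' @export
masquelier_stream <- function(n_input = 200, pattern_fraction = 0.25,
                              duration_s = 20, rate_hz = 25,
                              pattern_ms = 40,
                              pattern_afferents = seq_len(n_input),
                              jitter_sd = 0, pattern = NULL, seed) {
  stopifnot(pattern_fraction > 0, pattern_fraction <= 1,
            all(pattern_afferents >= 1 & pattern_afferents <= n_input))
  set.seed(seed)
  n_seg <- floor(duration_s * 1000 / pattern_ms)
  dur <- n_seg * pattern_ms
  if (is.null(pattern)) {
    # frozen pattern: Poisson at rate_hz on the pattern afferents
    pat <- data.frame(neuron = integer(), time = numeric())
    for (a in pattern_afferents) {
      k <- stats::rpois(1, rate_hz * pattern_ms / 1000)
      if (k) pat <- rbind(pat, data.frame(neuron = a,
                                          time = stats::runif(k, 0, pattern_ms)))
    }
  } else {
    pat <- pattern
    pattern_afferents <- sort(unique(pat$neuron))
  }
  is_pat_seg <- stats::runif(n_seg) < pattern_fraction
  ev <- vector("list", n_seg)
  others <- setdiff(seq_len(n_input), pattern_afferents)
  for (s in seq_len(n_seg)) {
    onset <- (s - 1) * pattern_ms
    if (is_pat_seg[s]) {
      t_pat <- pat$time + if (jitter_sd > 0)
        rtnorm3(nrow(pat), jitter_sd) else 0
      keep <- t_pat >= 0 & t_pat < pattern_ms
      pe <- data.frame(neuron = pat$neuron[keep],
                       time = onset + t_pat[keep], is_pattern = TRUE)
      if (length(others)) {
        n_bg <- stats::rpois(1, length(others) * rate_hz * pattern_ms / 1000)
        be <- data.frame(
          neuron = sample(others, n_bg, replace = TRUE),
          time = onset + stats::runif(n_bg, 0, pattern_ms),
          is_pattern = rep(FALSE, n_bg))
        ev[[s]] <- rbind(pe, be)
      } else ev[[s]] <- pe
    } else {
      n_bg <- stats::rpois(1, n_input * rate_hz * pattern_ms / 1000)
      ev[[s]] <- data.frame(
        neuron = sample.int(n_input, n_bg, replace = TRUE),
        time = onset + stats::runif(n_bg, 0, pattern_ms),
        is_pattern = FALSE)
    }
  }
  ev <- do.call(rbind, ev)
  ev$presentation <- 1L
  pres <- data.frame(presentation = 1L, class = "stream", exemplar = 1L,
                     duration = dur)
  raster <- spike_raster(ev[, c("presentation", "neuron", "time")],
                         pres, n_input)
  raster$events$is_pattern <- ev$is_pattern
  list(raster = raster,
       segments = data.frame(segment = seq_len(n_seg),
                             onset = (seq_len(n_seg) - 1) * pattern_ms,
                             duration = pattern_ms,
                             is_pattern = is_pat_seg),
       pattern = pat)
}

#' Single-neuron pattern-from-noise learning experiment
#'
#' End-to-end replication of the mechanism by which a single spiking
#' neuron with LTD-dominant STDP learns to pick a repeating
#' spatio-temporal pattern out of statistically identical noise: a
#' coincidence-detector output neuron (Class-1 subcortical preset) with
#' full plastic afferent connectivity from the stream is trained with
#' learning on, then evaluated with learning off on a fresh stream
#' carrying the same frozen pattern in new background. Selectivity is
#' summarised as the output spike rate inside pattern windows (hit rate)
#' versus outside (false-alarm rate).
#'
#' @param n_input Afferent count.
#' @param pattern_fraction Fraction of segments carrying the pattern.
#' @param rate_hz Afferent firing rate (Hz).
#' @param pattern_ms Pattern duration (ms).
#' @param train_s,test_s Training and evaluation stream lengths (s).
#' @param stdp STDP parameters (defaults: the model's cortical values).
#' @param w_init Initial weight band (nA).
#' @param jitter_sd Temporal jitter on replayed pattern spikes (ms).
#' @param seed RNG seed.
#' @return A list with `hit_rate`, `fa_rate` (Hz), `ratio`,
#'   `weights_before`, `weights_after`, and the trained `network`.
#' @export
pattern_detection_experiment <- function(n_input = 200,
                                         pattern_fraction = 0.25,
                                         rate_hz = 25, pattern_ms = 40,
                                         train_s = 60, test_s = 20,
                                         stdp = stdp_params(),
                                         w_init = c(30, 35),
                                         jitter_sd = 0, seed) {
  cfg <- list(dt = 0.1, layers = list(
    list(name = "IN", n_exc = as.integer(n_input), n_inh = 0L,
         exc_preset = "excitatory_subcortical",
         inh_preset = "inhibitory", w_ei = 0, w_ie = 0),
    list(name = "OUT", n_exc = 1L, n_inh = 0L,
         exc_preset = "excitatory_subcortical",
         inh_preset = "inhibitory", w_ei = 0, w_ie = 0)),
    projections = list(list(src = "IN", dst = "OUT", kind = "full",
                            plastic = TRUE, w_range = w_init,
                            stdp = stdp)))
  net <- build_network(cfg, seed = sub_seed(seed, 1))
  w_before <- plastic_weights(net)[[1]]
  train <- masquelier_stream(n_input, pattern_fraction, train_s, rate_hz,
                             pattern_ms, jitter_sd = jitter_sd,
                             seed = sub_seed(seed, 2))
  net <- run_network(net, train$raster, learn = TRUE,
                     record = character())$network
  test <- masquelier_stream(n_input, pattern_fraction, test_s, rate_hz,
                            pattern_ms, jitter_sd = jitter_sd,
                            pattern = train$pattern,
                            seed = sub_seed(seed, 3))
  ev <- run_network(net, test$raster, learn = FALSE,
                    record = "OUT")$rasters$OUT$events
  seg <- test$segments
  in_pat <- seg$is_pattern[pmin(floor(ev$time / pattern_ms) + 1L,
                                nrow(seg))]
  t_in <- sum(seg$is_pattern) * pattern_ms / 1000
  t_out <- sum(!seg$is_pattern) * pattern_ms / 1000
  hit <- sum(in_pat) / t_in
  fa <- sum(!in_pat) / t_out
  list(hit_rate = hit, fa_rate = fa, ratio = hit / max(fa, 1e-9),
       weights_before = w_before, weights_after = plastic_weights(net)[[1]],
       network = net)
}
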