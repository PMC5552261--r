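#' Full-versus-reduced architecture comparison study
#'
#' The package's headline in-silico experiment at desk scale: for each
#' seed, both architectures are built and trained on the same synthetic
#' two-class dataset, and the trained full model is additionally compared
#' against its untrained and shuffled-weight controls on identical
#' held-out input. A separate reduced-model training on patternless
#' jittered input probes the weight-distribution mechanism (LTD dominance
#' pushes the weight mass below its initialisation band, while patterned
#' input leaves a strengthened tail above it).
#'
#' Summary statistics per seed: median polychronization index of the
#' input and midbrain layers; decoder mutual information (bits) of the
#' plastic cortical layers under temporal and rate codes for the trained
#' full model, and under the temporal code for the controls; and plastic
#' weight summaries. Scale defaults (population sizes, input statistics,
#' exposure) are the package's desk-scale study conditions, documented in
#' the methods vignette.
#'
#' @param n_seeds Number of independent replicate seeds.
#' @param master_seed Base seed; replicate `i` uses `master_seed + i - 1`.
#' @param n_scale,cortical_scale Network scale (see [network_config()]).
#' @param rate_hz Mean input firing rate (Hz) of the synthetic templates.
#' @param epochs Training passes.
#' @param n_speakers Speakers per class.
#' @param n_test_repetitions Held-out presentations per test exemplar.
#' @param j_temporal,j_rate,n_subsamples,maxit Decoding protocol scale
#'   (see [decode_mi()]).
#' @param pi_cells Reference cells scored per layer for the PI.
#' @param verbose Print per-seed progress?
#' @return data.frame with one row per seed; class `comparison_study`.
#' @export
comparison_study <- function(n_seeds = 10, master_seed = 1,
                             n_scale = 0.5, cortical_scale = 0.3,
                             rate_hz = 40, epochs = 2, n_speakers = 6,
                             n_test_repetitions = 4,
                             j_temporal = 15, j_rate = 60,
                             n_subsamples = 1, maxit = 80,
                             pi_cells = 25, verbose = FALSE) {
  rows <- vector("list", n_seeds)
  for (i in seq_len(n_seeds)) {
    seed <- master_seed + i - 1
    say <- function(...) if (verbose) message(sprintf(...))
    say("study seed %d (%d/%d)", seed, i, n_seeds)
    nf <- max(1L, as.integer(round(1000 * n_scale)))
    tpl <- pattern_templates(2, nf, 300, rate_hz = rate_hz,
                             seed = sub_seed(seed, 1))
    noi <- noise_model()

    train_net <- function(preset, templates, noise = noi) {
      net <- build_network(
        network_config(preset, n_scale = n_scale,
                       cortical_scale = cortical_scale),
        seed = sub_seed(seed, 2))
      net0 <- net
      for (ep in seq_len(epochs)) {
        ds <- generate_dataset(templates, noise, n_speakers,
                               seed = sub_seed(seed, 100 + ep))
        net <- run_network(net, ds, learn = TRUE,
                           record = character())$network
      }
      list(net = net, net0 = net0)
    }
    fu <- train_net("full", tpl)
    re <- train_net("reduced", tpl)
    # reduced model on patternless input: same rate statistics, no
    # repeating structure (fresh Poisson each presentation)
    tpl0 <- pattern_templates(2, nf, 300, rate_hz = 0, n_bands = 0,
                              seed = sub_seed(seed, 5))
    noi0 <- noise_model(bg_rate_hz = rate_hz, jitter_sd = noi$jitter_sd,
                        spatial_range = noi$spatial_range,
                        p_delete = noi$p_delete)
    re0 <- train_net("reduced", tpl0, noi0)
    say("  trained")

    te <- generate_dataset(tpl, noi, n_speakers,
                           n_repetitions = n_test_repetitions,
                           seed = sub_seed(seed, 3), lambda_offset = 0.03)
    r_fu <- run_network(fu$net, te, learn = FALSE,
                        record = c("AN", "IC", "A1", "Belt"))
    r_un <- run_network(fu$net0, te, learn = FALSE,
                        record = c("A1", "Belt"))
    r_sh <- run_network(shuffle_weights(fu$net, seed = sub_seed(seed, 4)),
                        te, learn = FALSE, record = c("A1", "Belt"))
    r_re <- run_network(re$net, te, learn = FALSE,
                        record = c("A1", "Belt"))
    say("  evaluated")

    mi1 <- function(run, ly, md) {
      r <- decode_mi(run$rasters[[ly]], md, n_subsamples = n_subsamples,
                     j_cells = if (md == "temporal") j_temporal else j_rate,
                     seed = sub_seed(seed, 500), maxit = maxit)
      stats::median(r$mi)
    }
    pi1 <- function(run, ly) {
      res <- tryCatch(
        polychronization_index(run$rasters[[ly]], seq_len(pi_cells),
                               seed = sub_seed(seed, 6)),
        error = function(e) NULL)
      if (is.null(res)) NA_real_ else stats::median(res$pi, na.rm = TRUE)
    }
    w_fu <- plastic_weights(fu$net)
    w_re0 <- plastic_weights(re0$net)
    rows[[i]] <- data.frame(
      seed = seed,
      pi_an = pi1(r_fu, "AN"),
      pi_ic = pi1(r_fu, "IC"),
      mi_belt_temporal = mi1(r_fu, "Belt", "temporal"),
      mi_belt_rate = mi1(r_fu, "Belt", "rate"),
      mi_a1_temporal = mi1(r_fu, "A1", "temporal"),
      mi_a1_rate = mi1(r_fu, "A1", "rate"),
      mi_belt_temporal_untrained = mi1(r_un, "Belt", "temporal"),
      mi_a1_temporal_untrained = mi1(r_un, "A1", "temporal"),
      mi_belt_temporal_shuffled = mi1(r_sh, "Belt", "temporal"),
      mi_belt_temporal_reduced = mi1(r_re, "Belt", "temporal"),
      mi_a1_temporal_reduced = mi1(r_re, "A1", "temporal"),
      w_median_full = stats::median(w_fu[["IC->A1"]]),
      w_tail_full = mean(w_fu[["IC->A1"]] > 35) +
        mean(w_fu[["A1->Belt"]] > 35),
      w_median_patternless = stats::median(w_re0[["AN->A1"]]),
      w_tail_patternless = mean(w_re0[["AN->A1"]] > 35),
      rate_a1 = mean(firing_rates(r_fu$rasters$A1)),
      rate_belt = mean(firing_rates(r_fu$rasters$Belt)))
    say("  done")
  }
  out <- do.call(rbind, rows)
  class(out) <- c("comparison_study", "data.frame")
  out
}

#' @export
print.comparison_study <- function(x, ...) {
  cat("comparison_study over", nrow(x), "seeds (medians):\n")
  med <- vapply(x[, -1], stats::median, numeric(1), na.rm = TRUE)
  print(round(med, 4))
  invisible(x)
}
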