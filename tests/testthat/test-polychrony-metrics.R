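test_that("pattern matrix bins spikes around the sampled reference spike", {
  # reference cell fires once (deterministic t_j); a companion fires at
  # +10 ms in every presentation
  ev <- data.frame(neuron = c(1L, 2L, 3L), time = c(100, 110, 10))
  ra <- multi_pres_raster(list(ev, ev, ev), 5, duration = 200)
  for (id in 1:3) {
    m <- pattern_matrix(ra, cell = 1, presentation = id)
    expect_equal(dim(m), c(5, 101))
    expect_equal(attr(m, "t_j"), 100)
    expect_equal(m[2, 51 + 10], 1)          # lag +10
    expect_equal(m[1, 51], 1)               # the sampled spike itself
    expect_equal(sum(m), 2)                 # cell 3 fires outside the window
  }
  # silent reference cell -> skip (NULL)
  expect_null(pattern_matrix(ra, cell = 4, presentation = 1))
  # silent everyone else -> all-zero matrix apart from the centre
  ra2 <- one_pres_raster(1, 50, 4, duration = 100)
  m <- pattern_matrix(ra2, 1, 1)
  expect_equal(sum(m), 1)
  expect_equal(m[1, 51], 1)
})

test_that("window edges are zero-padded, not discarded", {
  ra <- one_pres_raster(c(1L, 2L), c(5, 95), 3, duration = 100)
  m <- pattern_matrix(ra, 1, 1)           # t_j = 5; lags < -5 fall outside
  expect_equal(dim(m), c(3, 101))
  expect_equal(sum(m[, 1:45]), 0)
})

test_that("poisson binning matches its expected count rate", {
  set.seed(8)
  rate <- 20; dur <- 1000; n <- 50
  evs <- lapply(1:40, function(i) {
    k <- rpois(1, n * rate * dur / 1000)
    data.frame(neuron = sample(n, k, TRUE), time = runif(k, 0, dur))
  })
  ra <- multi_pres_raster(evs, n, dur)
  # each matrix element away from the centre is Poisson with mean r * 1ms
  ms <- lapply(1:40, function(id) pattern_matrix(ra, 2, id))
  ms <- ms[!vapply(ms, is.null, TRUE)]
  acc <- Reduce(`+`, ms) / length(ms)
  inner <- acc[-2, 20:80]                 # away from centre row and edges
  expect_equal(mean(inner), rate / 1000, tolerance = 0.15)
})

test_that("hand-built deterministic pattern yields the derived score", {
  # 100 cells, 200 ms, one spike per cell per presentation:
  # f = 100 / (100 * 200) = 0.005 per cell per 1 ms bin.
  # cells 2..11 fire at lags +1..+10 from the reference spike of cell 1;
  # the other 89 cells fire far outside the window. The ten largest
  # elements of the exemplar-mean matrix each average 1.0, so
  # a = 1.0 / 0.005 = 200.
  ev <- data.frame(
    neuron = 1:100,
    time = c(100, 100 + 1:10, seq(5, 40, length.out = 89)))
  ra <- multi_pres_raster(list(ev, ev, ev, ev), 100, duration = 200,
                          classes = rep("w", 4))
  res <- polychronization_index(ra, cells = 1, seed = 1)
  expect_equal(attr(res, "f"), 0.005)
  expect_equal(res$a_w, 200)
  expect_equal(res$pi, 200)
  expect_equal(res$n_skipped, 0)
})

test_that("the class maximum picks the patterned class", {
  ev_pat <- data.frame(neuron = 1:11, time = c(100, 100 + 1:10))
  set.seed(2)
  ev_noise <- function() data.frame(neuron = sample(2:11, 10, TRUE),
                                    time = runif(10, 0, 200))
  ra <- multi_pres_raster(
    list(ev_pat, ev_pat, rbind(ev_noise(), data.frame(neuron = 1, time = 100)),
         rbind(ev_noise(), data.frame(neuron = 1, time = 100))),
    11, duration = 200, classes = c("pat", "pat", "noise", "noise"))
  res <- polychronization_index(ra, cells = 1, seed = 3)
  expect_equal(res$pi, res$a_pat)
  expect_gt(res$a_pat, res$a_noise)
})

test_that("poisson null index approaches one as exemplars accumulate", {
  set.seed(21)
  rate <- 20; dur <- 300; n <- 100
  gen <- function(K) {
    evs <- lapply(seq_len(K), function(i) {
      k <- rpois(1, n * rate * dur / 1000)
      data.frame(neuron = sample(n, k, TRUE), time = runif(k, 0, dur))
    })
    multi_pres_raster(evs, n, dur)
  }
  pi_at <- vapply(c(10, 100, 1000), function(K)
    polychronization_index(gen(K), cells = 1, seed = K)$pi, numeric(1))
  expect_true(all(diff(pi_at) < 0))       # monotone convergence downwards
  expect_gt(pi_at[1], 3)                  # small-sample inflation
  expect_lt(pi_at[3], 2.2)                # approaching the chance level 1
})

test_that("added background activity dilutes the pattern score", {
  base_ev <- data.frame(neuron = 1:11, time = c(100, 100 + 1:10))
  score_at <- function(bg_per_pres) {
    set.seed(5)
    evs <- lapply(1:6, function(i) {
      bg <- data.frame(neuron = sample(12:80, bg_per_pres, TRUE),
                       time = runif(bg_per_pres, 0, 200))
      rbind(base_ev, bg)
    })
    polychronization_index(multi_pres_raster(evs, 80, 200),
                           cells = 1, seed = 7)$pi
  }
  scores <- vapply(c(0, 50, 200, 800), score_at, numeric(1))
  expect_true(all(diff(scores) < 0))
})

test_that("silent exemplars are skipped and fully silent input errors", {
  ev <- data.frame(neuron = 2L, time = 50)
  ev_with <- data.frame(neuron = c(1L, 2L), time = c(40, 50))
  ra <- multi_pres_raster(list(ev, ev_with, ev_with), 3, 100)
  res <- polychronization_index(ra, cells = 1, seed = 1)
  expect_equal(res$n_skipped, 1)
  ra_silent <- multi_pres_raster(list(ev, ev), 3, 100)
  expect_error(polychronization_index(ra_silent, cells = 1, seed = 1),
               "usable")
})
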