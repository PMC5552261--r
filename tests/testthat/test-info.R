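test_that("temporal features are the matrix marginals", {
  # reference cell with a single spike -> deterministic window centre
  set.seed(31)
  evs <- lapply(1:4, function(i)
    rbind(data.frame(neuron = 1L, time = 150),
          data.frame(neuron = sample(2:20, 60, TRUE),
                     time = runif(60, 0, 300))))
  ra <- multi_pres_raster(evs, 20, 300, classes = rep(c("a", "b"), 2))
  cells <- 1:10
  f <- temporal_features(ra, cells, ref_cell = 1)
  expect_equal(dim(f), c(4, 10 + 101))
  for (i in 1:4) {
    m <- pattern_matrix(ra, 1, i, cells = cells)
    expect_equal(f[i, 1:10], unname(rowSums(m)))
    expect_equal(f[i, 11:111], unname(colSums(m)))
  }
  # mass conservation: row sums and column sums add to the same total
  expect_equal(sum(f[1, 1:10]), sum(f[1, 11:111]))
  # all-silent companion cells -> only the centre spike contributes
  ra0 <- multi_pres_raster(list(data.frame(neuron = 1L, time = 50)), 10, 100)
  f0 <- temporal_features(ra0, 1:10, 1)
  expect_equal(sum(f0), 2)   # once in its row sum, once in the lag-0 column
})

test_that("silent reference cells yield abstaining rows", {
  ra <- multi_pres_raster(list(data.frame(neuron = 2L, time = 10),
                               data.frame(neuron = c(1L, 2L), time = c(5, 10))),
                          5, 100)
  f <- temporal_features(ra, 1:5, 1)
  expect_true(all(is.na(f[1, ])))
  expect_false(anyNA(f[2, ]))
})

test_that("rate features are duration-normalised counts", {
  ra <- multi_pres_raster(
    list(data.frame(neuron = c(1, 1, 2), time = c(1, 2, 3)),
         data.frame(neuron = 3, time = 250)),
    4, duration = 500)
  f <- rate_features(ra, cells = 1:4)
  expect_equal(f[1, ], c(4, 2, 0, 0))    # 2 spikes / 0.5 s = 4 Hz
  expect_equal(f[2, ], c(0, 0, 2, 0))
  # permuting spike times within a presentation changes nothing
  ra2 <- ra; ra2$events$time <- rev(ra2$events$time)
  expect_equal(rate_features(ra2, 1:4), f)
})

test_that("mutual information matches closed forms", {
  perfect <- matrix(c(0.5, 0, 0, 0.5), 2, 2)
  est <- mutual_information(perfect, n_trials = 752)
  expect_equal(est$mi, 1)
  expect_equal(est$h_s, 1)
  expect_equal(mutual_information(matrix(0.25, 2, 2))$mi, 0)
  # symmetric 90% accuracy: I = 1 - Hb(0.9)
  j90 <- matrix(c(0.45, 0.05, 0.05, 0.45), 2, 2)
  hb <- -(0.9 * log2(0.9) + 0.1 * log2(0.1))
  expect_equal(mutual_information(j90)$mi, 1 - hb, tolerance = 1e-12)
  expect_error(mutual_information(matrix(c(-0.1, 0.5, 0.3, 0.3), 2)),
               "negative")
})

test_that("the bias approximation reproduces the reported magnitude", {
  expect_equal(mi_bias(4, 752), 4 / (2 * 752 * log(2)), tolerance = 1e-15)
  expect_equal(round(mi_bias(4, 752), 3), 0.004)
})

test_that("confusion joint has uniform priors by construction", {
  pred <- factor(c("a", "a", "b", "a", "b", "b", "b"),
                 levels = c("a", "b"))
  act <- factor(c("a", "a", "a", "a", "b", "b", "b"),
                levels = c("a", "b"))
  j <- confusion_joint(pred, act)
  expect_equal(sum(j), 1)
  expect_equal(colSums(j), c(a = 0.5, b = 0.5))
  expect_equal(j["a", "a"], 3 / (4 * 2))
})

test_that("decoders attain the capacity and chance endpoints", {
  set.seed(77)
  n <- 60
  labels <- factor(rep(c("a", "b"), n / 2))
  sep <- matrix(rnorm(n * 10), n, 10)
  sep[, 1] <- sep[, 1] + ifelse(labels == "b", 4, -4)   # separable
  train <- rep(c(TRUE, TRUE, FALSE, FALSE), n / 4)
  fit <- fit_decoders(list(sep, sep, sep), labels, train,
                      hidden = 4, maxit = 150)
  expect_gt(mean(fit$predictions == fit$actual), 0.95)
  expect_gt(mutual_information(fit$joint)$mi, 0.5)

  # label-shuffled control: held-out accuracy near one half
  acc <- vapply(1:6, function(s) {
    set.seed(s)
    lab_s <- sample(labels)
    f <- fit_decoders(list(sep), lab_s, train, hidden = 4, maxit = 80)
    mean(f$predictions == f$actual)
  }, numeric(1))
  expect_lt(abs(mean(acc) - 0.5), 0.17)   # binomial error over 6x30 trials

  # unanimous voters decide the ensemble
  one_sided <- matrix(5, n, 3)
  one_sided[labels == "a", ] <- -5
  fit <- fit_decoders(list(sep, sep), labels, train, hidden = 4,
                      maxit = 100)
  tab <- table(fit$predictions)
  expect_equal(sum(tab), sum(!train))
  expect_error(fit_decoders(list(sep), factor(rep("a", n), levels = c("a", "b")),
                            train, hidden = 2, maxit = 10), "class")
})

test_that("decode_mi respects the entropy ceiling and determinism", {
  set.seed(55)
  # strongly class-labelled rate patterns
  evs <- lapply(1:24, function(i) {
    cl <- i %% 2
    cells <- if (cl == 0) 1:10 else 11:20
    data.frame(neuron = sample(cells, 80, TRUE), time = runif(80, 0, 200))
  })
  ra <- multi_pres_raster(evs, 20, 200,
                          classes = rep(c("two", "one"), 12))
  r1 <- decode_mi(ra, "rate", n_subsamples = 2, j_cells = 20, seed = 9,
                  maxit = 100)
  expect_true(all(r1$mi <= 1 + 1e-9))
  expect_gt(max(r1$mi), 0.5)            # rate-separable by construction
  r2 <- decode_mi(ra, "rate", n_subsamples = 2, j_cells = 20, seed = 9,
                  maxit = 100)
  expect_identical(r1, r2)
  expect_equal(attr(r1, "h_s"), 1)
})

test_that("noise-only input decodes to about the bias level", {
  set.seed(66)
  evs <- lapply(1:40, function(i)
    data.frame(neuron = sample(1:30, 60, TRUE), time = runif(60, 0, 200)))
  ra <- multi_pres_raster(evs, 30, 200, classes = rep(c("a", "b"), 20))
  r <- decode_mi(ra, "rate", n_subsamples = 4, j_cells = 30, seed = 2,
                 maxit = 80)
  # classes are identical Poisson noise; MI stays near zero + bias
  expect_lt(median(r$mi), 3 * attr(r, "bias") + 0.1)
})
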