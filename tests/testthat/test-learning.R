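test_that("cross-entropy of the normalised readout has its closed forms", {
  expect_equal(cross_entropy_loss(c(1, rep(0, 7)), 1), 0)
  expect_equal(cross_entropy_loss(rep(0.125, 8), 5), log(8))
  expect_equal(cross_entropy_loss(c(0.5, 0.5, rep(0, 6)), 2), log(2))
  expect_equal(cross_entropy_loss(rep(0.125, 8), c(0, 0, 1, 0, 0, 0, 0, 0)),
               log(8))
  expect_warning(e <- cross_entropy_loss(c(0, 1, rep(0, 6)), 1), "clamped")
  expect_equal(e, -log(1e-12))
})

test_that("exact analytic gradients agree with central finite differences", {
  # the core oracle: every coordinate, scaled by the gradient magnitude,
  # against Richardson-extrapolated central differences
  for (seed in c(2, 9)) {
    pair <- random_pair(8, 8, 4, direction = ((seed * 5) %% 8) + 1, seed = seed)
    enc <- encode_dataset(list(pair))
    set.seed(seed)
    p <- avs_params(init = "uniform")
    bw <- backward_gradients(enc, p, "exact")
    num <- numeric_gradient_oracle(function(pp) batch_loss(enc, pp), p,
                                   step = 1e-3, richardson = TRUE)
    scale <- max(abs(num$gw), abs(num$gq), abs(bw$gw), abs(bw$gq))
    expect_lt(max(abs(bw$gw - num$gw)) / scale, 1e-6)
    expect_lt(max(abs(bw$gq - num$gq)) / scale, 1e-6)
  }
})

test_that("finite-difference error shows the expected step-size behaviour", {
  # on a smooth scalar function the central-difference error is O(step^2)
  # until cancellation noise takes over
  f <- function(p) sum(sin(p$w)) + sum(p$q^2)
  set.seed(1)
  p <- avs_params(I = 2L, M = 1L, C = 1L, init = "uniform")
  errs <- vapply(c(1e-2, 1e-3, 1e-4), function(h) {
    g <- numeric_gradient_oracle(f, p, step = h)
    max(abs(g$gw - cos(p$w)), abs(g$gq - 2 * p$q))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))        # shrinking truncation error
  expect_lt(errs[3], 1e-8)                # plateau near machine precision
  expect_error(numeric_gradient_oracle(f, p, step = 0), "step")
})

test_that("synapses that never see input carry exactly zero weight gradient", {
  set.seed(5)
  X <- matrix(rbinom(6 * 27, 1, 0.5), 6, 27)
  X[, 3] <- 0  # channel 1, slot 3 never active
  enc <- structure(list(
    samples = list(list(X = X, n = rep(2L, 6), label = 4L, n_pixels = 12L)),
    labels = 4L, config = "DL", object_size = 4L,
    eps_vertical = 0, eps_horizontal = 1), class = "avs_encoded")
  p <- avs_params(init = "uniform")
  for (mode in c("exact", "simplified")) {
    bw <- backward_gradients(enc, p, mode)
    expect_identical(unname(bw$gw[3, 1, , 1]), rep(0, 8))
    expect_true(all(is.finite(bw$gw)) && all(is.finite(bw$gq)))
  }
})

test_that("the shortcut backward rule differs from the exact chain rule", {
  pair <- random_pair(8, 8, 4, 2, seed = 13)
  enc <- encode_dataset(list(pair))
  set.seed(13)
  p <- avs_params()
  exact <- backward_gradients(enc, p, "exact")
  literal <- backward_gradients(enc, p, "simplified")
  expect_gt(max(abs(exact$gw - literal$gw)), 0)
})

test_that("a small exact-gradient step decreases the loss", {
  pair <- random_pair(10, 10, 6, 7, seed = 21)
  enc <- encode_dataset(list(pair))
  set.seed(21)
  p <- avs_params()
  before <- batch_loss(enc, p)
  bw <- backward_gradients(enc, p, "exact")
  after <- batch_loss(enc, sgd_step(p, bw, 1e-3))
  expect_lt(after, before)
})

test_that("gradient-descent updates touch only w and q", {
  set.seed(3)
  p <- avs_params()
  zero <- list(gw = array(0, dim(p$w)), gq = array(0, dim(p$q)))
  expect_identical(sgd_step(p, zero, 0.5), p)
  g1 <- list(gw = array(1, dim(p$w)), gq = array(1, dim(p$q)))
  expect_identical(sgd_step(p, g1, 0), p)
  stepped <- sgd_step(p, g1, 0.1)
  expect_equal(stepped$w, p$w - 0.1)
  expect_identical(stepped$v, p$v)
  bad <- g1; bad$gw[5] <- NaN
  expect_error(sgd_step(p, bad, 0.1), "non-finite gradient in w")
})

test_that("training converges on a small high-contrast set and is seeded", {
  spec <- dataset_spec(configurations = "DL", object_sizes = 16L,
                       pairs_per_direction = 3L, seed = 7)
  enc <- encode_dataset(generate_dataset(spec))  # 24 pairs
  cfg <- train_config(epochs = 200L, seed = 4L, early_stop_patience = 200L)
  fit <- train_model(enc, cfg)
  expect_equal(evaluate_accuracy(fit$params, enc), 1)
  expect_lte(nrow(fit$history), 200L)
  fit2 <- train_model(enc, cfg)
  expect_identical(fit2$params$w, fit$params$w)
  expect_identical(fit2$history, fit$history)
  expect_error(train_model(structure(list(samples = list()),
                                     class = "avs_encoded"), cfg),
               "empty")
})

test_that("a zero learning rate leaves accuracy at the chance level", {
  spec <- dataset_spec(configurations = "LD", object_sizes = 8L,
                       pairs_per_direction = 10L, seed = 15)
  enc <- encode_dataset(generate_dataset(spec))  # 80 pairs, balanced
  fit <- train_model(enc, train_config(learning_rate = 0, epochs = 2L,
                                       seed = 6L))
  acc <- evaluate_accuracy(fit$params, enc)
  se <- sqrt(0.125 * 0.875 / length(enc$samples))
  expect_lt(abs(acc - 0.125), 3 * se)
})

test_that("training recovers direction-selective connection states", {
  spec <- dataset_spec(configurations = "DL", object_sizes = c(8L, 16L),
                       pairs_per_direction = 10L, seed = 5)
  enc <- encode_dataset(generate_dataset(spec))
  fit <- train_model(enc, train_config(seed = 11L))
  expect_gte(evaluate_accuracy(fit$params, enc), 0.95)
  p <- fit$params
  own_exc <- 0L; other_exc <- 0L
  for (m in 1:8) for (ch in 1:3) {
    expect_equal(connection_state(p$w[5, 1, m, ch], p$q[5, 1, m, ch]),
                 "excitatory")
    for (i in setdiff(1:9, 5)) {
      exc <- connection_state(p$w[i, 1, m, ch], p$q[i, 1, m, ch]) ==
        "excitatory"
      if (i == slot_of_direction[m]) own_exc <- own_exc + exc
      else other_exc <- other_exc + exc
    }
  }
  # excitatory surround synapses concentrate on the slot the object moves to
  expect_gt(own_exc, 0L)
  expect_gt(own_exc / 24, other_exc / 168)
})

test_that("idealised parameters classify high-contrast pairs perfectly", {
  spec <- dataset_spec(configurations = c("DL", "LD"), object_sizes = 8L,
                       pairs_per_direction = 2L, seed = 33)
  enc <- encode_dataset(generate_dataset(spec))
  expect_equal(evaluate_accuracy(ideal_params(), enc), 1)
})
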