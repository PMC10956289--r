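test_that("feature extraction honours the shape contract and determinism", {
  cfg <- tiny_model_config()
  w <- init_weights(cfg, seed = 1)
  set.seed(2)
  crops <- array(runif(8 * 8 * 12) * 255, c(8, 8, 12))
  crops[, , 2] <- crops[, , 1] # duplicate crop
  ml <- make_miniloop(crops)
  fs <- extract_spatial_features(ml, cfg, w)
  expect_equal(dim(fs$features), c(12, 4))
  expect_identical(fs$features[1, ], fs$features[2, ])
  bad <- make_miniloop(array(0, c(16, 16, 12)))
  expect_error(extract_spatial_features(bad, cfg, w), "input_size")
})

test_that("temporal adaptive pooling averages per phase", {
  # 12 scalar features 1..12 -> block means (2.5, 6.5, 10.5)
  expect_equal(as.vector(temporal_adaptive_pool(matrix(1:12, 12, 1))),
               c(2.5, 6.5, 10.5))
  # constant-per-phase basis vectors pool to the basis
  E <- diag(3)
  X <- E[rep(1:3, each = 4), ]
  expect_equal(temporal_adaptive_pool(X), E)
  # F = 1: identity
  X3 <- matrix(rnorm(9), 3)
  expect_equal(temporal_adaptive_pool(X3), X3)
  expect_error(temporal_adaptive_pool(X3, pooled_len = 5), "exceeds")
})

test_that("mini-loop probabilities are in (0,1), deterministic, order-aware", {
  cfg <- tiny_model_config()
  w <- init_weights(cfg, seed = 3)
  set.seed(4)
  pooled <- matrix(rnorm(3 * 4, sd = 2), 3, 4)
  p1 <- predict_miniloop(pooled, w, cfg)
  expect_gt(p1, 0); expect_lt(p1, 1)
  expect_identical(p1, predict_miniloop(pooled, w, cfg))
  p_perm <- predict_miniloop(pooled[c(3, 1, 2), ], w, cfg)
  expect_false(isTRUE(all.equal(p1, p_perm)))
})

test_that("backward gradients match finite differences end to end", {
  cfg <- tiny_model_config()
  w <- init_weights(cfg, seed = 2)
  set.seed(3)
  ml <- make_miniloop(array(runif(8 * 8 * 6) * 255, c(8, 8, 6)), F = 2L,
                      label = 1)
  loss <- function(w) {
    p <- ceusdx:::.net_forward(ml, w, cfg)$prob
    -log(min(max(p, 1e-12), 1 - 1e-12))
  }
  fw <- ceusdx:::.net_forward(ml, w, cfg)
  g <- ceusdx:::.net_backward(fw$prob - 1, fw, w, cfg)
  eps <- 1e-6
  probe <- function(getter, setter, grad) {
    v <- getter(w)
    for (ij in sample(length(v), min(4, length(v)))) {
      w2 <- w
      v2 <- v; v2[ij] <- v2[ij] + eps
      w2 <- setter(w2, v2)
      fd <- (loss(w2) - loss(w)) / eps
      expect_equal(fd, grad[ij], tolerance = 1e-4)
    }
  }
  probe(function(w) w$backbone$conv1$W,
        function(w, v) { w$backbone$conv1$W <- v; w }, g$backbone$conv1$W)
  probe(function(w) w$lstm1b$U,
        function(w, v) { w$lstm1b$U <- v; w }, g$lstm1b$U)
  probe(function(w) w$lstm2$W,
        function(w, v) { w$lstm2$W <- v; w }, g$lstm2$W)
  probe(function(w) w$head$W,
        function(w, v) { w$head$W <- v; w }, g$head$W)
})

test_that("training validates input, runs the schedule, freezes the prefix", {
  cfg <- tiny_model_config()
  tcfg <- train_config(epochs = 2, batch_size = 4, seed = 5)
  set.seed(6)
  mls <- lapply(1:8, function(i) {
    lvl <- if (i %% 2 == 0) 200 else 20
    make_miniloop(array(runif(8 * 8 * 12) * 30 + lvl, c(8, 8, 12)),
                  label = as.integer(i %% 2 == 0),
                  case_id = paste0("c", i))
  })
  expect_error(train_cnn_lstm(mls[c(1, 3)], cfg, tcfg), "both classes")
  expect_error(train_config(epochs = 0), "epochs")
  expect_equal(epoch_lr(train_config(), 4), 0.01)
  expect_equal(epoch_lr(train_config(), 5), 0.001)

  fit <- train_cnn_lstm(mls, cfg, tcfg)
  expect_length(fit$history, 2)
  expect_true(all(is.finite(fit$history)))

  # frozen prefix: first module bit-identical, later modules move
  cfg_f <- tiny_model_config()
  cfg_f$freeze_prefix_layers <- 1L
  w0 <- init_weights(cfg_f, seed = 5)
  fit_f <- train_cnn_lstm(mls, cfg_f, train_config(epochs = 1, batch_size = 4,
                                                   seed = 5))
  expect_identical(fit_f$weights$backbone$conv1$W, w0$backbone$conv1$W)
  expect_false(identical(fit_f$weights$backbone$conv2$W,
                         w0$backbone$conv2$W))
  expect_false(identical(fit_f$weights$head$W, w0$head$W))
})

test_that("the resnet backbone refuses to run without supplied weights", {
  cfg <- model_config("resnet18_frozen5")
  expect_equal(cfg$freeze_prefix_layers, 5L)
  expect_error(init_weights(cfg, seed = 1), "pretrained")
})

test_that("majority vote aggregation follows the vote and tie rules", {
  expect_equal(aggregate_case(c(0.9, 0.8, 0.2))$case_label, 1L)
  tie <- aggregate_case(c(0.9, 0.1))
  expect_equal(tie$case_prob, 0.5)
  expect_equal(tie$case_label, 1L) # tie resolves via mean >= threshold
  expect_equal(aggregate_case(0.4)$case_label, 0L)
  expect_error(aggregate_case(numeric(0)), "no mini-loop")
  # order invariance and consistency
  p <- c(0.2, 0.7, 0.9, 0.4)
  expect_equal(aggregate_case(p)$case_label,
               aggregate_case(rev(p))$case_label)
  expect_equal(aggregate_case(rep(0.37, 5))$case_prob, 0.37)
})
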