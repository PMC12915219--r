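tinyCfg <- networkConfig(frame = 16L, baseChannels = 2L, nResEncoder = 1L,
                         nResDecoder = 1L, nDUS = 1L)

tinyNet <- function(seed = 3L, cfg = tinyCfg) {
  shapes <- lutomo:::layerShapes(cfg)
  withr::with_seed(seed, {
    W <- lapply(shapes, function(s)
      matrix(rnorm(s$out * s$inK, sd = sqrt(2 / s$inK)), s$out, s$inK))
    b <- lapply(shapes, function(s) rnorm(s$out, sd = 0.1))
  })
  structure(list(config = cfg, params = list(W = W, b = b),
                 waterRef = matrix(0, cfg$frame, cfg$frame), constant = 57e-6,
                 trained = FALSE, history = NULL), class = "sosNet")
}

test_that("the forward pass is shape preserving and structurally sound", {
  net <- buildNetwork(networkConfig(frame = 64L, baseChannels = 4L))
  out <- predictSoS(net, matrix(0.5, 64, 64))
  expect_identical(dim(out$raw), c(64L, 64L))
  expect_s4_class(out$map, "SoSMap")
  # zero weights: output is the constant output-layer bias
  zero <- net
  zero$params$W <- lapply(zero$params$W, function(w) w * 0)
  zero$params$b <- lapply(zero$params$b, function(b) b * 0)
  zero$params$b[[length(zero$params$b)]][] <- 0.25
  outZ <- predictSoS(zero, matrix(0.4, 64, 64))
  expect_true(all(abs(outZ$raw - 0.25) < 1e-12))
  # frame not divisible by the cumulative stride is rejected
  expect_error(networkConfig(frame = 66L), "divisible")
  # unnormalised inputs are rejected
  expect_error(predictSoS(net, matrix(1.4, 64, 64)), "normalised")
})

test_that("doubling the width roughly quadruples the parameter count", {
  n1 <- nnetParams(buildNetwork(networkConfig(frame = 64L, baseChannels = 8L)))
  n2 <- nnetParams(buildNetwork(networkConfig(frame = 64L, baseChannels = 16L)))
  expect_gt(n2 / n1, 3.5)
  expect_lt(n2 / n1, 4.2)
})

test_that("analytic gradients match finite differences", {
  net <- tinyNet()
  cv <- lutomo:::cfgVector(net$config)
  withr::with_seed(4, {
    X <- array(runif(16 * 16 * 2), c(16, 16, 2))
    Y <- array(runif(16 * 16 * 2), c(16, 16, 2))
  })
  lg <- lutomo:::.cnn_loss_grad(net$params, cv, X, Y)
  eps <- 1e-6
  set.seed(5)
  for (li in sample(seq_along(net$params$W), 4)) {
    k <- sample(length(net$params$W[[li]]), 1)
    p2 <- net$params
    p2$W[[li]][k] <- p2$W[[li]][k] + eps
    f1 <- lutomo:::.cnn_loss_grad(p2, cv, X, Y)$loss
    p2$W[[li]][k] <- p2$W[[li]][k] - 2 * eps
    f2 <- lutomo:::.cnn_loss_grad(p2, cv, X, Y)$loss
    num <- (f1 - f2) / (2 * eps)
    expect_equal(lg$grad$W[[li]][k], num, tolerance = 1e-4)
  }
})

test_that("training is deterministic and reduces the loss", {
  net <- tinyNet()
  withr::with_seed(6, {
    X <- array(runif(16 * 16 * 8, 0.3, 0.7), c(16, 16, 8))
    Y <- array(rep(snapClasses(runif(8)), each = 256), c(16, 16, 8))
  })
  inputs <- lapply(seq_len(8), function(i) X[, , i])
  targets <- lapply(seq_len(8), function(i) Y[, , i])
  tc <- trainConfig(epochs = 40L, batchSize = 4L, learningRate = 3e-3,
                    lrPatience = 30L, valFraction = 0.25, seed = 9L)
  f1 <- trainNetwork(net, inputs, targets, tc)
  f2 <- trainNetwork(net, inputs, targets, tc)
  expect_identical(f1$history, f2$history)
  expect_lt(tail(f1$history$trainLoss, 1), f1$history$trainLoss[1] * 0.5)
})

test_that("the plateau schedule halves the rate after the patience window", {
  net <- tinyNet()
  withr::with_seed(7, {
    inputs <- lapply(1:4, function(i) matrix(runif(256), 16, 16))
    targets <- lapply(1:4, function(i) matrix(0.5, 16, 16))
  })
  # a vanishing learning rate never improves validation, so the schedule
  # fires every `patience` epochs after the first
  tc <- trainConfig(epochs = 19L, batchSize = 4L, learningRate = 1e-4,
                    lrFactor = 0.5, lrPatience = 8L, valFraction = 0.25,
                    seed = 1L)
  tc$learningRate <- 1e-20
  fit <- trainNetwork(net, inputs, targets, tc)
  expect_equal(fit$history$lr[2], 1e-20)
  expect_equal(fit$history$lr[9], 1e-20)        # stagnant epochs 2..9
  expect_equal(fit$history$lr[10], 0.5e-20)     # schedule fired
  expect_equal(fit$history$lr[18], 0.25e-20)    # and again 8 epochs later
})

test_that("split leakage is rejected", {
  net <- tinyNet()
  inputs <- lapply(1:4, function(i) matrix(0.5, 16, 16))
  targets <- lapply(1:4, function(i) matrix(0.5, 16, 16))
  expect_error(trainNetwork(net, inputs, targets,
                            trainConfig(epochs = 1L),
                            trainIdx = 1:3, valIdx = 3:4), "leakage")
})

test_that("class snapping uses the midpoint thresholds", {
  expect_identical(snapClasses(c(0.51, 0.76, 0.24, 0.25, 0.75)),
                   c(0.5, 1, 0, 0.5, 1))
})

test_that("prediction degenerating to uniform water is reported, not fatal", {
  net <- buildNetwork(networkConfig(frame = 64L, baseChannels = 4L))
  zero <- net
  zero$params$W <- lapply(zero$params$W, function(w) w * 0)
  zero$params$b <- lapply(zero$params$b, function(b) b * 0)
  zero$params$b[[length(zero$params$b)]][] <- 0.5 # always predicts water
  spec <- experimentalPhantoms()$A
  target <- classEncode(renderSoSMap(spec, sosGrid(64)))
  bench <- reconstructionBenchmark(zero, list(matrix(0.5, 64, 64)),
                                   list(target), sosGrid(64))
  expect_length(bench$rows, 0L)
  expect_true("phantom" %in% bench$perMap[[1]]$missing)
})
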