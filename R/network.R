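# Convolutional encoder-residual-DUS-decoder reconstruction network.
#
# Topology: one stride-2 3x3 convolution (feature extraction), encoder
# residual blocks, a chain of down-and-up-scaling (DUS) units (stride-2
# down path, 3x3 processing, depth-to-space block-2 up path, additive
# skip), decoder residual blocks, a long additive skip from the encoder
# output, and a linear 3x3 head whose 4 channels are rearranged by
# depth-to-space back to the full grid. All activations are rectified
# linear; the output is linear and snapped to the class codes post hoc.

#' Network configuration
#'
#' @param frame input/output side length in pixels (must be divisible by 4;
#'   128 for the full-scale grid, 64 for the desk preset).
#' @param baseChannels channel width after feature extraction. Channel
#'   widths, residual-block counts and kernel sizes are free parameters of
#'   the architecture family; the full-scale sizing guide is a capacity of
#'   roughly 1e8 parameters, while the desk preset uses 8 channels.
#' @param nResEncoder,nResDecoder residual blocks in encoder / decoder.
#' @param nDUS number of DUS units (4).
#' @param conditionGain fixed input-conditioning gain: the network sees
#'   `(x - waterReference) * conditionGain`, which is zero outside the
#'   stacked blocks and of order one inside them (normalised ToF
#'   perturbations are of order 1e-2).
#' @return list of class `NetworkConfig`.
#' @export
networkConfig <- function(frame = 128L, baseChannels = 32L, nResEncoder = 2L,
                          nResDecoder = 2L, nDUS = 4L, conditionGain = 200) {
  frame <- as.integer(frame)
  if (frame %% 4L != 0L)
    stop("frame must be divisible by the cumulative stride (4)")
  structure(list(frame = frame, baseChannels = as.integer(baseChannels),
                 nResEncoder = as.integer(nResEncoder),
                 nResDecoder = as.integer(nResDecoder),
                 nDUS = as.integer(nDUS), conditionGain = conditionGain),
            class = "NetworkConfig")
}

cfgVector <- function(config) {
  c(H = config$frame, C = config$baseChannels, nEnc = config$nResEncoder,
    nDec = config$nResDecoder, nDUS = config$nDUS)
}

# layer shapes in the order the C++ core expects; d2s marks layers whose
# output feeds a depth-to-space rearrangement (sub-pixel groups of 4)
layerShapes <- function(config) {
  C <- config$baseChannels
  shapes <- list(list(out = C, inK = 9L, d2s = FALSE))
  for (r in seq_len(config$nResEncoder))
    shapes <- c(shapes, list(list(out = C, inK = 9L * C, d2s = FALSE),
                             list(out = C, inK = 9L * C, d2s = FALSE)))
  for (d in seq_len(config$nDUS))
    shapes <- c(shapes, list(list(out = 2L * C, inK = 9L * C, d2s = FALSE),
                             list(out = 4L * C, inK = 9L * 2L * C,
                                  d2s = TRUE)))
  for (r in seq_len(config$nResDecoder))
    shapes <- c(shapes, list(list(out = C, inK = 9L * C, d2s = FALSE),
                             list(out = C, inK = 9L * C, d2s = FALSE)))
  c(shapes, list(list(out = 4L, inK = 9L * C, d2s = TRUE)))
}

#' Build an untrained reconstruction network
#'
#' Initialises all convolution kernels with He-scaled Gaussian weights
#' (seed-deterministic) and precomputes the fixed input-conditioning
#' reference: the stacked, normalised water-only ToF input for the given
#' geometry, so conditioned inputs vanish for a water-filled tank.
#'
#' @param config a [networkConfig()].
#' @param geom the [ArrayGeometry-class] whose water reference conditions
#'   the input.
#' @param constant ToF normalisation constant (seconds) or `"auto"`.
#' @param seed RNG seed for the weight initialisation.
#' @return list of class `sosNet` with elements `config`, `params`,
#'   `waterRef`, `constant`, `trained`, `history`.
#' @examples
#' net <- buildNetwork(networkConfig(frame = 64, baseChannels = 4))
#' nnetParams(net)  # parameter count
#' @export
buildNetwork <- function(config = networkConfig(), geom = arrayGeometry(),
                         constant = "auto", seed = 1L) {
  norm <- normaliseToFs(list(referenceToFMatrix(geom),
                             referenceToFMatrix(geom, viewAngle = 90)),
                        constant)
  ref <- stackViews(norm$matrices[[1]], norm$matrices[[2]], norm$constant,
                    frame = config$frame)
  shapes <- layerShapes(config)
  withSeed(seed, {
    W <- lapply(shapes, function(s) {
      if (s$d2s) {
        # sub-pixel (ICNR-style) initialisation: the four depth-to-space
        # channels of each output feature start identical, so upsampling
        # begins free of checkerboard artefacts
        base <- matrix(rnorm(s$out / 4L * s$inK, sd = sqrt(2 / s$inK)),
                       s$out / 4L, s$inK)
        base[rep(seq_len(s$out / 4L), each = 4L), , drop = FALSE]
      } else {
        matrix(rnorm(s$out * s$inK, sd = sqrt(2 / s$inK)), s$out, s$inK)
      }
    })
    b <- lapply(shapes, function(s) numeric(s$out))
    # start from the water background: the output head predicts 0.5
    b[[length(b)]][] <- 0.5
    structure(list(config = config, params = list(W = W, b = b),
                   waterRef = ref$padded, constant = norm$constant,
                   trained = FALSE, history = NULL),
              class = "sosNet")
  })
}

#' @describeIn buildNetwork Total trainable parameter count.
#' @param net a `sosNet`.
#' @export
nnetParams <- function(net) {
  sum(vapply(net$params$W, length, 0)) + sum(vapply(net$params$b, length, 0))
}

#' @export
print.sosNet <- function(x, ...) {
  cat(sprintf(
    "sosNet: %d x %d frame, %d base channels, %d+%d residual blocks, %d DUS units, %s parameters%s\n",
    x$config$frame, x$config$frame, x$config$baseChannels,
    x$config$nResEncoder, x$config$nResDecoder, x$config$nDUS,
    format(nnetParams(x), big.mark = ","),
    if (x$trained) " (trained)" else ""))
  invisible(x)
}

conditionInput <- function(net, padded) {
  if (min(padded) < 0 || max(padded) > 1)
    stop("network input must be normalised to [0, 1]")
  (padded - net$waterRef) * net$config$conditionGain
}

# Reciprocity symmetry: transposing both 16x16 view blocks of a stacked
# input is exactly the acquisition of the medium mirrored about the tank's
# horizontal midline (generation and detection roles swap); the matching
# target is the map with its rows reversed. Used for train-time
# augmentation and test-time symmetrisation.
reciprocalInput <- function(x, blockSize = 16L) {
  b <- blockSize
  out <- x
  out[seq_len(b), seq_len(b)] <- t(x[seq_len(b), seq_len(b)])
  out[b + seq_len(b), b + seq_len(b)] <- t(x[b + seq_len(b), b + seq_len(b)])
  out
}

inputArray <- function(net, inputs) {
  if (is.array(inputs) && length(dim(inputs)) == 3L) return(inputs)
  arr <- vapply(inputs, function(s) {
    conditionInput(net, if (inherits(s, "StackedInput")) s$padded else s)
  }, matrix(0, net$config$frame, net$config$frame))
  arr
}

targetArray <- function(targets, frame) {
  vapply(targets, function(m) {
    if (is(m, "SoSMap")) m@values else m
  }, matrix(0, frame, frame))
}

#' Training protocol configuration
#'
#' Defaults follow the full-scale protocol: Adam at learning rate 1e-4, MSE
#' loss, batch 16, 100 epochs, learning rate halved after 8 epochs without
#' validation improvement. The desk preset ([deskPreset()]) shrinks the
#' problem so the whole loop runs on one CPU in minutes and raises the
#' learning rate accordingly.
#'
#' @param epochs,batchSize,learningRate,lrFactor,lrPatience see description.
#' @param valFraction fraction of samples held out for validation when no
#'   explicit split is given.
#' @param clipNorm global gradient-norm clip (0 disables); lets small-scale
#'   runs use faster learning rates without divergence.
#' @param emaDecay Polyak weight-averaging decay (0 disables); when enabled,
#'   validation is scored on, and the returned model carries, the averaged
#'   weights.
#' @param seed RNG seed controlling the split and data order.
#' @return list of class `TrainConfig`.
#' @export
trainConfig <- function(epochs = 100L, batchSize = 16L, learningRate = 1e-4,
                        lrFactor = 0.5, lrPatience = 8L, valFraction = 0.1,
                        clipNorm = 0, emaDecay = 0, seed = 1L) {
  stopifnot(lrPatience >= 1L, epochs >= 1L, batchSize >= 1L,
            learningRate > 0, lrFactor > 0, lrFactor <= 1,
            clipNorm >= 0, emaDecay >= 0, emaDecay < 1)
  structure(list(epochs = as.integer(epochs), batchSize = as.integer(batchSize),
                 learningRate = learningRate, lrFactor = lrFactor,
                 lrPatience = as.integer(lrPatience),
                 valFraction = valFraction, clipNorm = clipNorm,
                 emaDecay = emaDecay, seed = as.integer(seed)),
            class = "TrainConfig")
}

#' Train the reconstruction network
#'
#' Adam with MSE loss and a reduce-on-plateau schedule (learning rate times
#' `lrFactor` after `lrPatience` epochs without validation improvement);
#' the best-validation parameters are retained. Inputs must be normalised
#' stacked ToF frames, targets class-coded maps.
#'
#' @param net a `sosNet` from [buildNetwork()].
#' @param inputs list of `StackedInput` (or raw padded matrices in \[0,1\]).
#' @param targets list of class-coded [SoSMap-class] (or plain matrices).
#' @param config a [trainConfig()].
#' @param trainIdx,valIdx optional explicit disjoint index vectors (sample =
#'   spec identity; overlap is an error). Default: a seed-deterministic
#'   split with `valFraction` held out.
#' @param augmentReciprocal also train on the reciprocity-mirrored copy of
#'   every training sample (transposed view blocks, row-reversed target);
#'   the validation set is left unaugmented.
#' @return the trained `sosNet`, with `history` (data frame of per-epoch
#'   train/validation loss and learning rate).
#' @export
trainNetwork <- function(net, inputs, targets, config = trainConfig(),
                         trainIdx = NULL, valIdx = NULL,
                         augmentReciprocal = FALSE) {
  stopifnot(inherits(net, "sosNet"))
  X <- inputArray(net, inputs)
  Y <- targetArray(targets, net$config$frame)
  n <- dim(X)[3]
  if (dim(Y)[3] != n) stop("inputs and targets differ in length")
  if (is.null(trainIdx)) {
    nVal <- max(0L, round(config$valFraction * n))
    idx <- withSeed(config$seed, sample.int(n))
    valIdx <- if (nVal > 0) idx[seq_len(nVal)] else integer(0)
    trainIdx <- setdiff(idx, valIdx)
  }
  if (length(intersect(trainIdx, valIdx)))
    stop("split leakage: a spec id appears in both train and validation")
  Xv <- X[, , valIdx, drop = FALSE]; Yv <- Y[, , valIdx, drop = FALSE]
  Xt <- X[, , trainIdx, drop = FALSE]; Yt <- Y[, , trainIdx, drop = FALSE]
  if (augmentReciprocal) {
    nt <- dim(Xt)[3]
    Xa <- array(0, dim(Xt) + c(0, 0, nt))
    Ya <- array(0, dim(Yt) + c(0, 0, nt))
    Xa[, , seq_len(nt)] <- Xt; Ya[, , seq_len(nt)] <- Yt
    for (k in seq_len(nt)) {
      Xa[, , nt + k] <- reciprocalInput(Xt[, , k])
      Ya[, , nt + k] <- Yt[dim(Yt)[1]:1, , k]
    }
    Xt <- Xa; Yt <- Ya
  }
  fit <- .cnn_train(net$params, cfgVector(net$config), Xt, Yt, Xv, Yv,
                    config$epochs, config$batchSize, config$learningRate,
                    config$lrFactor, config$lrPatience, config$seed,
                    config$clipNorm, config$emaDecay)
  net$params <- fit$best
  net$trained <- TRUE
  net$history <- data.frame(epoch = seq_len(config$epochs),
                            trainLoss = fit$trainLoss, valLoss = fit$valLoss,
                            lr = fit$lr)
  net
}

#' Snap continuous map values to the nearest class code
#'
#' Midpoint thresholds: below 0.25 becomes 0 (gel), below 0.75 becomes 0.5
#' (water), else 1 (10 wt% glycerol).
#'
#' @param x numeric matrix or vector.
#' @export
snapClasses <- function(x) {
  ifelse(x < 0.25, 0, ifelse(x < 0.75, 0.5, 1))
}

#' Reconstruct a SoS map from a stacked ToF input
#'
#' Single forward pass of the trained network. Returns both the raw
#' continuous output and the class-snapped map.
#'
#' @param net a trained `sosNet`.
#' @param input a `StackedInput` (from [stackViews()]) or a raw padded
#'   matrix with entries in \[0, 1\].
#' @param grid the [GridSpec-class] for the returned maps (defaults to the
#'   network frame on the standard 77.4 mm extent).
#' @param symmetrise also run the reciprocity-mirrored input (transposed
#'   view blocks) through the network and average the un-mirrored outputs;
#'   exact by acoustic reciprocity and deterministic.
#' @return list with `raw` (numeric matrix) and `map` (class-coded
#'   [SoSMap-class]).
#' @export
predictSoS <- function(net, input, grid = NULL, symmetrise = TRUE) {
  stopifnot(inherits(net, "sosNet"))
  if (is.null(grid)) grid <- sosGrid(net$config$frame)
  padded <- if (inherits(input, "StackedInput")) input$padded else input
  if (!all(dim(padded) == net$config$frame))
    stop("input frame does not match the network")
  x <- conditionInput(net, padded)
  if (symmetrise) {
    X <- array(0, c(dim(x), 2L))
    X[, , 1] <- x
    X[, , 2] <- reciprocalInput(x)
    out <- .cnn_forward(net$params, cfgVector(net$config), X)
    raw <- (out[, , 1] + out[nrow(out):1, , 2]) / 2
  } else {
    X <- array(x, c(dim(x), 1L))
    raw <- .cnn_forward(net$params, cfgVector(net$config), X)[, , 1]
  }
  map <- new("SoSMap", values = snapClasses(raw), grid = grid,
             viewAngle = 0, coding = "class", spec = list())
  list(raw = raw, map = map)
}

#' Generate a synthetic training dataset
#'
#' Samples phantom specifications, renders both views, runs the eikonal
#' solver and assembles normalised stacked inputs paired with class-coded
#' targets. Deterministic for a fixed seed.
#'
#' @param n number of phantoms.
#' @param grid a [GridSpec-class].
#' @param geom an [ArrayGeometry-class].
#' @param params sampling ranges from [phantomParams()]; by default the gel
#'   margin is one pixel of the rendering grid, so segmentation-separable
#'   regions survive rasterisation at any grid size.
#' @param seed RNG seed.
#' @param factor eikonal refinement factor.
#' @param constant ToF normalisation constant or `"auto"`.
#' @param frame padded input frame (defaults to grid size).
#' @return list with `inputs` (list of `StackedInput`), `targets` (list of
#'   class-coded [SoSMap-class]), `specs`, `constant`.
#' @export
makeTrainingDataset <- function(n, grid = sosGrid(), geom = arrayGeometry(),
                                params = NULL, seed = 1L,
                                factor = 5L, constant = "auto", frame = NULL) {
  if (is.null(frame)) frame <- grid@nPixels
  if (is.null(params))
    params <- phantomParams(gelMargin = max(77.4 / 128, pixelPitch(grid)))
  withSeed(seed, {
    specs <- lapply(seq_len(n), function(i) samplePhantomSpec(params))
    inputs <- vector("list", n); targets <- vector("list", n)
    const <- constant
    for (i in seq_len(n)) {
      pair <- buildTrainingPair(specs[[i]], grid, geom, constant = const,
                                factor = factor, frame = frame)
      inputs[[i]] <- pair$input
      targets[[i]] <- pair$target
      const <- pair$input$constant # freeze the auto constant dataset-wide
    }
    list(inputs = inputs, targets = targets, specs = specs, constant = const)
  })
}

#' Train with random restarts selected by validation loss
#'
#' Builds and trains `nRestarts` networks from different initialisation
#' seeds and returns the one with the lowest final validation loss. At
#' desk scale a short training run occasionally lands in a visibly poor
#' optimum (validation loss well above the typical run); selection across
#' restarts by validation -- never by any test quantity -- removes that
#' failure mode.
#'
#' @param netConfig a [networkConfig()].
#' @param geom an [ArrayGeometry-class].
#' @param inputs,targets training data (as for [trainNetwork()]).
#' @param config a [trainConfig()].
#' @param nRestarts number of initialisations.
#' @param baseSeed first initialisation seed; restart k uses `baseSeed + k - 1`.
#' @param augmentReciprocal passed to [trainNetwork()].
#' @return the selected trained `sosNet` (its `history` carries an
#'   attribute `"restartSeeds"` with the seeds and final validation losses).
#' @export
trainWithRestarts <- function(netConfig, geom, inputs, targets,
                              config = trainConfig(), nRestarts = 2L,
                              baseSeed = 1L, augmentReciprocal = FALSE) {
  best <- NULL; info <- NULL
  for (k in seq_len(nRestarts)) {
    seedK <- baseSeed + k - 1L
    net <- buildNetwork(netConfig, geom, seed = seedK)
    net <- trainNetwork(net, inputs, targets, config,
                        augmentReciprocal = augmentReciprocal)
    vl <- min(net$history$valLoss)
    info <- rbind(info, data.frame(seed = seedK, valLoss = vl))
    if (is.null(best) || vl < min(best$history$valLoss)) best <- net
  }
  attr(best$history, "restartSeeds") <- info
  best
}

#' Desk-scale preset
#'
#' A configuration of the whole pipeline small enough to generate data,
#' train and evaluate on a single CPU in minutes: 64 x 64 grid, 8 base
#' channels, 200 training phantoms, 30 epochs at learning rate 8e-3 with
#' batch 8, gradient clipping and Polyak averaging (the plateau schedule
#' and loss are kept from the full protocol). Training at this scale is
#' expected to be combined with reciprocity augmentation
#' (`trainNetwork(..., augmentReciprocal = TRUE)`).
#'
#' @param nTrain,nTest dataset sizes.
#' @return list with `grid`, `geom`, `netConfig`, `trainConfig`, `nTrain`,
#'   `nTest`, `factor`.
#' @export
deskPreset <- function(nTrain = 200L, nTest = 20L) {
  list(grid = sosGrid(64L), geom = arrayGeometry(),
       netConfig = networkConfig(frame = 64L, baseChannels = 8L,
                                 nResEncoder = 2L, nResDecoder = 2L,
                                 nDUS = 4L),
       trainConfig = trainConfig(epochs = 30L, batchSize = 8L,
                                 learningRate = 8e-3, lrPatience = 8L,
                                 valFraction = 0.1, clipNorm = 1,
                                 emaDecay = 0.99),
       nTrain = as.integer(nTrain), nTest = as.integer(nTest), factor = 5L)
}

#' Benchmark a trained network on a test set
#'
#' Per-image MSE, difference maps and the full region-metric comparison
#' ([compareMaps()]) of each prediction against its ground truth.
#'
#' @param net a trained `sosNet`.
#' @param inputs,targets test set (as for [trainNetwork()]).
#' @param grid the [GridSpec-class] of the maps.
#' @return list with `mse` (vector), `rows` (all `ComparisonRow`s),
#'   `perMap` (list of [compareMaps()] results), `stats`
#'   (`AggregateStats` over all matched regions, or `NULL` if none).
#' @export
reconstructionBenchmark <- function(net, inputs, targets, grid = NULL) {
  if (is.null(grid)) grid <- sosGrid(net$config$frame)
  n <- length(inputs)
  mse <- numeric(n)
  perMap <- vector("list", n)
  rows <- list()
  for (i in seq_len(n)) {
    pred <- predictSoS(net, inputs[[i]], grid)
    gt <- targets[[i]]
    gtv <- if (is(gt, "SoSMap")) gt@values else gt
    mse[i] <- mean((pred$raw - gtv)^2)
    gtMap <- if (is(gt, "SoSMap")) gt else
      new("SoSMap", values = gt, grid = grid, viewAngle = 0,
          coding = "class", spec = list())
    perMap[[i]] <- compareMaps(pred$map, gtMap, label = paste0("map", i))
    rows <- c(rows, perMap[[i]]$rows)
  }
  list(mse = mse, rows = rows, perMap = perMap,
       stats = if (length(rows)) aggregateStats(rows) else NULL)
}
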