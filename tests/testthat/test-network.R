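test_that("the network is image-to-image with a single linear output", {
  m <- buildUnet(unetSpec(depth = 2L, baseFilters = 4L), 32L, seed = 1)
  x <- array(rnorm(32 * 32), c(32, 32, 1))
  y <- pavision:::.predictRaw(m@params, m@spec, x)
  expect_identical(dim(y), c(32L, 32L, 1L))
  # linear output: negative values possible (no final activation)
  expect_lt(min(y), 0)
  expect_error(buildUnet(unetSpec(depth = 3L, baseFilters = 4L), 30L),
               "divisible")
  expect_error(unetSpec(dropoutRate = 1.2), "dropoutRate")
})

test_that("the full-scale architecture carries about 3.1e7 parameters", {
  n <- paramCount(unetPresetFull())
  expect_gt(n, 2.7e7)
  expect_lt(n, 3.3e7)
  # closed-form layer-by-layer count agrees with the instantiated weights
  countConv <- function(cin, cout) cout * 9 * cin + cout + 2 * cout
  ch <- 64 * 2^(0:3)
  expected <- countConv(1, 64) + countConv(64, 64)
  for (l in 2:4) expected <- expected + countConv(ch[l - 1], ch[l]) +
    countConv(ch[l], ch[l])
  expected <- expected + countConv(512, 1024) + countConv(1024, 1024)
  for (l in 4:1) {
    cb <- if (l == 4) 1024 else ch[l + 1]
    expected <- expected + ch[l] * 4 * cb + ch[l] +      # transposed conv
      countConv(2 * ch[l], ch[l]) + countConv(ch[l], ch[l])
  }
  expected <- expected + 64 + 1                          # final 1x1 conv
  expect_identical(as.numeric(n), as.numeric(expected))
})

test_that("the reduced preset is an order of magnitude smaller", {
  expect_lt(paramCount(unetPresetReduced()), paramCount(unetPresetFull()) / 10)
})

test_that("the optimizer can drive a single pair to near-zero error", {
  ds <- buildDataset(2, fxMicroPhantomConfig(), fxMicroProbe(), seed = 3,
                     split = c(1L, 1L, 0L), reconPitchUm = 80)
  m <- buildUnet(unetSpec(depth = 2L, baseFilters = 8L, dropoutRate = 0),
                 32L, seed = 1)
  fit <- trainNetwork(m, ds, trainConfig(maxEpochs = 500L, patience = 500L,
                                         batchSize = 1L, lr = 3e-3))
  h <- fit@history
  expect_lt(utils::tail(h$trainLoss, 1), 1e-3 * h$trainLoss[1])
})

test_that("training contracts: zero epochs, early stopping, reproducibility", {
  m <- buildUnet(unetPresetMicro(), 32L, seed = 5)
  same <- trainNetwork(m, fxMicroDataset(), trainConfig(maxEpochs = 0L))
  expect_identical(same@params, m@params)
  fit <- fxMicroModel()
  expect_gt(nrow(fit@history), 0)
  # restored weights correspond to the minimum validation loss
  expect_equal(fit@provenance$bestEpoch,
               fit@history$epoch[which.min(fit@history$valLoss)])
  d <- pavision:::.trainArrays(fxMicroDataset())
  yv <- pavision:::.predictRaw(fit@params, fit@spec,
                               pavision:::.normalizeInputArray(d$valInput))
  expect_equal(mean((yv - d$valTarget)^2), min(fit@history$valLoss),
               tolerance = 1e-6)
  # same seed + data + config reproduce the weights exactly
  fit2 <- trainNetwork(buildUnet(unetPresetMicro(), 32L, seed = 1),
                       fxMicroDataset(),
                       trainConfig(maxEpochs = 12L, patience = 12L, seed = 1))
  expect_identical(fit2@params, fit@params)
})

test_that("prediction is deterministic and batch-consistent", {
  fit <- fxMicroModel()
  ds <- fxMicroDataset()
  x <- ds@input[, , 1]
  expect_identical(predictImage(fit, x), predictImage(fit, x))
  xb <- ds@input[, , 1:3]
  yb <- predictImage(fit, xb)
  for (i in 1:3)
    expect_equal(yb[, , i], predictImage(fit, ds@input[, , i]),
                 tolerance = 1e-6)
  expect_error(predictImage(fit, matrix(0, 16, 16)), "shape")
})

test_that("a trained network beats DAS envelopes on held-out phantoms", {
  ev <- fxBenchEval()
  expect_gt(ev$net@meanNcc, ev$das@meanNcc)
  expect_gt(ev$net@meanSssim, ev$das@meanSssim)
})

test_that("fine-tuning honours degenerate budgets", {
  pre <- fxMicroModel()
  # empty fine-tune set returns the pretrained model
  empty <- subsetDataset(fxMicroDataset(), which(fxMicroDataset()@split != "train"))
  out <- pretrainFinetune(fxMicroDataset(), empty,
                          trainConfig(maxEpochs = 12L, patience = 12L,
                                      seed = 1),
                          model = buildUnet(unetPresetMicro(), 32L, seed = 1))
  expect_identical(out@params, pre@params)
  # lr = 0 leaves the trainable weights unchanged
  cfg0 <- trainConfig(maxEpochs = 2L, lr = 0, seed = 2)
  tuned <- trainNetwork(pre, fxMicroDataset(), cfg0)
  nms <- names(pre@params)
  trainable <- nms[pavision:::.isTrainable(nms)]
  for (nm in trainable)
    expect_equal(tuned@params[[nm]], pre@params[[nm]], tolerance = 1e-12)
})
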