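test_that("domain specifications encode the intended forward perturbations", {
  sim <- domainSpec("simulation")
  ex <- domainSpec("experimental")
  expect_true(is.infinite(sim$noiseSnr))
  expect_identical(ex$cSim, 1480)
  expect_gt(ex$pulseBwScale, 1)
  expect_gt(ex$pulseFcScale, 1)
})

test_that("a minimal learning curve produces one row per size and arm", {
  lc <- runLearningCurve(
    learningCurveConfig(setSizes = 8L, nRepeats = 1L, pretrain = TRUE,
                        pretrainPairs = 24L, seed = 3),
    trainCfg = trainConfig(maxEpochs = 4L, patience = 4L),
    nTest = 4L)
  expect_identical(nrow(lc), 2L)
  expect_setequal(lc$arm, c("scratch", "pretrained"))
  expect_true(all(is.finite(lc$sssim)))
  smry <- attr(lc, "summary")
  expect_identical(nrow(smry), 2L)
  prov <- attr(lc, "provenance")
  expect_identical(prov$setSizes, 8L)
  expect_gt(length(prov$poolSeeds), 0)
})

test_that("identical inputs for both arms give identical scores (control)", {
  ds <- buildDataset(14, fxMicroPhantomConfig(), fxMicroProbe(),
                     noise = noiseConfig(60), seed = 19,
                     split = c(8L, 3L, 3L), keepDmbf = TRUE,
                     reconPitchUm = 80)
  ds@inputDmbf <- ds@input  # force the two arms to see the same data
  rpt <- compareInputs(ds, trainConfig(maxEpochs = 4L, patience = 4L),
                       seeds = 1L)
  expect_equal(rpt$perSeed$ncc[rpt$perSeed$arm == "mBF"],
               rpt$perSeed$ncc[rpt$perSeed$arm == "dmBF"], tolerance = 1e-12)
  expect_equal(rpt$perSeed$sssim[rpt$perSeed$arm == "mBF"],
               rpt$perSeed$sssim[rpt$perSeed$arm == "dmBF"],
               tolerance = 1e-12)
})

test_that("comparison reports survive a JSON round trip", {
  skip_if_not_installed("jsonlite")
  rpt <- list(perSeed = data.frame(seed = 1L, arm = c("mBF", "dmBF"),
                                   ncc = c(0.9, 0.8), sssim = c(0.85, 0.7)),
              summary = data.frame(arm = c("dmBF", "mBF"),
                                   ncc = c(0.8, 0.9), sssim = c(0.7, 0.85)))
  back <- jsonlite::fromJSON(jsonlite::toJSON(rpt, digits = NA))
  expect_equal(back$perSeed$ncc, rpt$perSeed$ncc)
  expect_equal(back$summary$sssim, rpt$summary$sssim)
})

test_that("the modulated input outperforms the envelope input", {
  ds <- buildDataset(80, fxMicroPhantomConfig(), fxMicroProbe(),
                     noise = noiseConfig(60), seed = 33,
                     split = c(60L, 10L, 10L), keepDmbf = TRUE,
                     reconPitchUm = 80)
  rpt <- compareInputs(ds, trainConfig(maxEpochs = 15L, patience = 6L,
                                       lr = 2e-3), seeds = 1:5)
  s <- rpt$summary
  expect_gte(s$sssim[s$arm == "mBF"], s$sssim[s$arm == "dmBF"])
  # the advantage holds seed by seed at this scale
  w <- merge(rpt$perSeed[rpt$perSeed$arm == "mBF", c("seed", "sssim")],
             rpt$perSeed[rpt$perSeed$arm == "dmBF", c("seed", "sssim")],
             by = "seed", suffixes = c("M", "D"))
  expect_gte(sum(w$sssimM > w$sssimD), 4)
})
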