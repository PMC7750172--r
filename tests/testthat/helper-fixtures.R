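# Shared fixtures, built lazily and memoized for the whole test run.
# Heavy objects (trained models, datasets) are constructed once here so that
# several test files can interrogate the same run.

.fx <- new.env(parent = emptyenv())

.memo <- function(key, builder) {
  if (is.null(.fx[[key]])) .fx[[key]] <- builder()
  .fx[[key]]
}

# probe with the default waterbath-standoff acquisition window
fxProbe <- function() linearProbe()

# shallow small-aperture probe for fast self-consistent physics tests
fxSmallProbe <- function()
  linearProbe(nElements = 64L, pitchMm = 0.2, nSamples = 360L)

# micro experiment scale: 2.56 mm patches reconstructed at 80 um (32 px),
# phantoms rasterized at 40 um (below half the acoustic wavelength)
fxMicroPhantomConfig <- function()
  phantomConfig(fieldSizeMm = 7.68, patchSizeMm = 2.56, branchDepth = 3L)

fxMicroProbe <- function() linearProbe(nSamples = 800L)

fxMicroDatasetArgs <- function() list(reconPitchUm = 80)

# a small paired dataset at micro scale (shared by network/uncertainty tests)
fxMicroDataset <- function() .memo("microDataset", function() {
  buildDataset(26, fxMicroPhantomConfig(), fxMicroProbe(),
               noise = noiseConfig(60), seed = 42,
               split = c(18L, 5L, 3L), reconPitchUm = 80)
})

# a micro U-Net trained briefly on that dataset: not a good model, but a
# genuinely trained one (loss decreases, dropout layers active)
fxMicroModel <- function() .memo("microModel", function() {
  trainNetwork(buildUnet(unetPresetMicro(), 32L, seed = 1),
               fxMicroDataset(),
               trainConfig(maxEpochs = 12L, patience = 12L, seed = 1))
})

# benchmark-scale run: 300/30/15 pairs, phantoms at 40 um, reconstruction
# and network at 80 um (64 px); shared by the DAS-vs-network benchmark and
# the uncertainty-calibration checks
fxBenchPhantomConfig <- function() phantomConfig()

fxBenchProbe <- function() linearProbe()

fxBenchDataset <- function() .memo("benchDataset", function() {
  buildDataset(345, fxBenchPhantomConfig(), fxBenchProbe(),
               noise = noiseConfig(60), seed = 101,
               split = c(300L, 30L, 15L), keepDmbf = TRUE,
               reconPitchUm = 80)
})

fxBenchModel <- function() .memo("benchModel", function() {
  trainNetwork(buildUnet(unetPresetReduced(), 64L, seed = 1),
               fxBenchDataset(),
               trainConfig(maxEpochs = 25L, patience = 6L, seed = 1))
})

fxBenchEval <- function() .memo("benchEval", function() {
  ds <- fxBenchDataset()
  fit <- fxBenchModel()
  te <- which(ds@split == "test")
  preds <- predictImage(fit, ds@input[, , te])
  netPairs <- lapply(seq_along(te), function(i)
    list(pred = preds[, , i], truth = ds@target[, , te[i]]))
  dasPairs <- lapply(te, function(i)
    list(pred = ds@inputDmbf[, , i], truth = ds@target[, , i]))
  list(net = evaluateSet(netPairs), das = evaluateSet(dasPairs),
       preds = preds, testIdx = te)
})

# deterministic reference phantom raster (128 px crop with content)
fxRefRaster <- function() .memo("refRaster", function() {
  values(generateBranchingPhantom(phantomConfig(seed = 9)))[61:188, 61:188]
})
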