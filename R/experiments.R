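# Desk-scale experiment drivers: the learning curve with and without
# simulation pretraining, and the mBF-vs-dmBF input comparison.
#
# Domain shift between "simulation" and "experiment-like" data is emulated
# in a controlled way: the simulated arm uses the nominal impulse response,
# no noise and the nominal speed of sound; the experiment-like arm perturbs
# the impulse response (+10% bandwidth, +5% centre frequency), adds
# SNR-60 noise, and synthesizes at 1480 m/s while reconstruction assumes
# 1500 m/s (an unmodeled medium error). This reproduces the character of a
# sim-to-real gap without access to physical acquisitions.

#' Domain descriptions for transfer-learning experiments
#'
#' @param which "simulation" (nominal forward model, noiseless) or
#'   "experimental" (perturbed impulse response, SNR-60 noise, speed-of-
#'   sound mismatch).
#' @param snr amplitude SNR of the experiment-like arm.
#' @return list of \code{buildDataset} forward-model arguments.
#' @export
domainSpec <- function(which = c("simulation", "experimental"), snr = 60) {
  which <- match.arg(which)
  if (which == "simulation")
    list(noiseSnr = Inf, cSim = NULL, pulseFcScale = 1, pulseBwScale = 1)
  else
    list(noiseSnr = snr, cSim = 1480, pulseFcScale = 1.05,
         pulseBwScale = 1.1)
}

.domainDataset <- function(n, domain, config, probe, seed, split = NULL,
                           keepDmbf = FALSE, reconPitchUm = 80) {
  noise <- if (is.finite(domain$noiseSnr))
    noiseConfig(targetSnr = domain$noiseSnr, seed = seed) else NULL
  buildDataset(n, config = config, probe = probe, noise = noise, seed = seed,
               split = split, keepDmbf = keepDmbf, cSim = domain$cSim,
               pulseFcScale = domain$pulseFcScale,
               pulseBwScale = domain$pulseBwScale,
               reconPitchUm = reconPitchUm)
}

#' Learning curve with and without simulation pretraining
#'
#' For each training-set size and each repeat, draws a fresh random subset
#' of an experiment-like pool (train and validation disjoint), trains the
#' network from scratch and, optionally, from weights pretrained once on a
#' simulated dataset, and evaluates NCC/sSSIM on a fixed held-out test set.
#'
#' @param cfg a \linkS4class{LearningCurveConfig}.
#' @param config phantom configuration (shared by both domains).
#' @param probe probe geometry.
#' @param spec network architecture (micro preset by default: the sweep
#'   trains dozens of models).
#' @param trainCfg training configuration template.
#' @param nTest held-out test pairs.
#' @param valFrac validation fraction of each drawn subset.
#' @param pretrained optional already-pretrained \linkS4class{TrainedModel}
#'   to reuse for the pretrained arm (skips the pretraining phase).
#' @param verbose print progress lines.
#' @return data.frame with columns size, arm, repeat_, ncc, sssim; the
#'   summary (mean sSSIM per size per arm) is in \code{attr(x, "summary")}
#'   and full provenance in \code{attr(x, "provenance")}.
#' @export
runLearningCurve <- function(cfg = learningCurveConfig(),
                             config = phantomConfig(
                               fieldSizeMm = 7.68, patchSizeMm = 2.56,
                               branchDepth = 3L),
                             probe = linearProbe(nSamples = 800L),
                             spec = unetPresetMicro(),
                             trainCfg = trainConfig(maxEpochs = 30L,
                                                    patience = 6L,
                                                    lr = 2e-3),
                             nTest = 15L, valFrac = 0.25, pretrained = NULL,
                             verbose = FALSE) {
  stopifnot(is(cfg, "LearningCurveConfig"))
  simDomain <- domainSpec("simulation")
  expDomain <- domainSpec("experimental")
  nPatch <- round(config@patchSizeMm * 1000 / 80)  # 80 um recon grid
  maxSize <- max(cfg@setSizes)
  poolN <- maxSize + ceiling(maxSize * valFrac) + 5L
  pool <- .domainDataset(poolN, expDomain, config, probe,
                         seed = .subSeed(cfg@seed, 11L))
  test <- .domainDataset(nTest, expDomain, config, probe,
                         seed = .subSeed(cfg@seed, 13L))
  testPairs <- lapply(seq_len(nTest), function(i)
    list(pred = NULL, truth = test@target[, , i]))

  if (cfg@pretrain && is.null(pretrained)) {
    pretrained <- pretrainOnSimulation(cfg, config, probe, spec, trainCfg)
    if (verbose) message("pretraining done: best val loss ",
                         signif(min(pretrained@history$valLoss), 3))
  }

  evalModel <- function(model) {
    preds <- predictImage(model, test@input)
    pairs <- lapply(seq_len(nTest), function(i)
      list(pred = preds[, , i], truth = test@target[, , i]))
    rpt <- evaluateSet(pairs)
    c(ncc = rpt@meanNcc, sssim = rpt@meanSssim)
  }

  arms <- c("scratch", if (cfg@pretrain) "pretrained")
  rows <- list()
  for (size in cfg@setSizes) {
    for (rep_ in seq_len(cfg@nRepeats)) {
      drawSeed <- .subSeed(cfg@seed, 1000L + size * 10L + rep_)
      set.seed(drawSeed)
      nv <- max(3L, ceiling(size * valFrac))
      take <- sample(dim(pool@input)[3], size + nv)
      sub <- subsetDataset(pool, take,
                           split = rep(c("train", "val"), c(size, nv)))
      tc <- trainCfg
      tc@seed <- drawSeed
      for (arm in arms) {
        model <- if (arm == "scratch")
          buildUnet(spec, nPatch, seed = drawSeed)
        else pretrained
        fit <- trainNetwork(model, sub, tc)
        sc <- evalModel(fit)
        rows[[length(rows) + 1L]] <-
          data.frame(size = size, arm = arm, repeat_ = rep_,
                     ncc = sc["ncc"], sssim = sc["sssim"])
        if (verbose)
          message(sprintf("size %d rep %d %s: sSSIM %.3f", size, rep_, arm,
                          sc["sssim"]))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  smry <- stats::aggregate(cbind(ncc, sssim) ~ size + arm, data = out, mean)
  attr(out, "summary") <- smry[order(smry$arm, smry$size), ]
  attr(out, "provenance") <- list(seed = cfg@seed,
                                  setSizes = cfg@setSizes,
                                  nRepeats = cfg@nRepeats,
                                  pretrainPairs = if (cfg@pretrain)
                                    cfg@pretrainPairs else 0L,
                                  poolSeeds = pool@pairSeeds,
                                  testSeeds = test@pairSeeds)
  out
}

#' Pretrain a network on the simulated domain
#'
#' Builds the simulated dataset (nominal forward model, noiseless) and
#' trains a fresh network on it; used as the initialization of the
#' pretrained arm of the learning curve.
#'
#' @inheritParams runLearningCurve
#' @return a \linkS4class{TrainedModel}.
#' @export
pretrainOnSimulation <- function(cfg, config = phantomConfig(
                                   fieldSizeMm = 7.68, patchSizeMm = 2.56,
                                   branchDepth = 3L),
                                 probe = linearProbe(nSamples = 800L),
                                 spec = unetPresetMicro(),
                                 trainCfg = trainConfig(maxEpochs = 30L,
                                                        patience = 6L,
                                                        lr = 2e-3)) {
  nPatch <- round(config@patchSizeMm * 1000 / 80)  # 80 um recon grid
  nv <- max(8L, ceiling(cfg@pretrainPairs * 0.15))
  sim <- .domainDataset(cfg@pretrainPairs + nv, domainSpec("simulation"),
                        config, probe, seed = .subSeed(cfg@seed, 17L),
                        split = c(cfg@pretrainPairs, nv, 0L))
  trainNetwork(buildUnet(spec, nPatch, seed = cfg@seed), sim, trainCfg)
}

#' Plot a learning curve
#'
#' @param lc output of \code{\link{runLearningCurve}}.
#' @param metric "sssim" or "ncc".
#' @export
plotLearningCurve <- function(lc, metric = "sssim") {
  smry <- attr(lc, "summary")
  arms <- unique(smry$arm)
  cols <- c(scratch = "red3", pretrained = "blue3")
  graphics::plot(NA, xlim = range(smry$size), ylim = range(smry[[metric]]),
                 log = "x", xlab = "training pairs",
                 ylab = paste("mean", toupper(metric)))
  for (a in arms) {
    s <- smry[smry$arm == a, ]
    graphics::lines(s$size, s[[metric]], type = "b", pch = 19,
                    col = cols[[a]])
  }
  graphics::legend("bottomright", legend = arms, col = cols[arms], lty = 1,
                   pch = 19, bty = "n")
  invisible(smry)
}

#' Compare mBF and dmBF network inputs
#'
#' Trains twin models under identical seeds and budget, one on the
#' modulated (mBF) input and one on the demodulated envelope (dmBF), and
#' reports paired test-set NCC/sSSIM. The mBF image carries the phase of
#' the RF signals, which the envelope discards.
#'
#' @param dataset a \linkS4class{PADataset} built with
#'   \code{keepDmbf = TRUE} and a train/val/test split.
#' @param trainCfg training configuration.
#' @param spec architecture.
#' @param seeds training seeds (one paired run per seed).
#' @return list with \code{perSeed} data.frame (seed, arm, ncc, sssim) and
#'   \code{summary}; serializable to JSON.
#' @export
compareInputs <- function(dataset, trainCfg = trainConfig(maxEpochs = 20L,
                                                          patience = 6L),
                          spec = unetPresetMicro(), seeds = 1:5) {
  stopifnot(is(dataset, "PADataset"))
  if (!is.array(dataset@inputDmbf))
    stop("dataset must be built with keepDmbf = TRUE")
  n <- dim(dataset@input)[1]
  te <- which(dataset@split == "test")
  if (length(te) == 0) stop("dataset has no test split")
  armData <- function(arm) {
    x <- if (arm == "mBF") dataset@input else dataset@inputDmbf
    list(input = x[, , dataset@split == "train", drop = FALSE],
         target = dataset@target[, , dataset@split == "train", drop = FALSE],
         valInput = x[, , dataset@split == "val", drop = FALSE],
         valTarget = dataset@target[, , dataset@split == "val", drop = FALSE],
         testInput = x[, , te, drop = FALSE])
  }
  rows <- list()
  for (sd in seeds) {
    for (arm in c("mBF", "dmBF")) {
      d <- armData(arm)
      tc <- trainCfg
      tc@seed <- as.integer(sd)
      fit <- trainNetwork(buildUnet(spec, n, seed = as.integer(sd)), d, tc)
      preds <- predictImage(fit, d$testInput)
      pairs <- lapply(seq_along(te), function(i)
        list(pred = preds[, , i], truth = dataset@target[, , te[i]]))
      rpt <- evaluateSet(pairs)
      rows[[length(rows) + 1L]] <-
        data.frame(seed = sd, arm = arm, ncc = rpt@meanNcc,
                   sssim = rpt@meanSssim)
    }
  }
  perSeed <- do.call(rbind, rows)
  rownames(perSeed) <- NULL
  list(perSeed = perSeed,
       summary = stats::aggregate(cbind(ncc, sssim) ~ arm, data = perSeed,
                                  mean))
}
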