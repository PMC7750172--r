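# Modified U-Net mapping mBF images to artefact-free predictions.
# Architecture: depth down/up levels of (conv3x3-BN-ReLU x2 + dropout)
# blocks, 2x2 max pooling, 2x2 stride-2 transposed-conv upsampling with
# skip concatenation, and a single-filter linear 1x1 output layer (no final
# activation: the output is a real-valued image).
#
# Parameter storage: flat named list. Conv kernels are (Cout x 9 Cin)
# matrices matching the im2col row order of the C++ engine; transposed-conv
# kernels are (Cout x 4 Cin). Batch-norm layers carry trainable g (scale)
# and be (shift) plus running statistics rm/rv (not trainable).

.unetChannels <- function(spec) spec@baseFilters * 2^(seq_len(spec@depth) - 1)

.convParams <- function(name, cin, cout, useBn) {
  p <- list()
  p[[paste0(name, ".W")]] <- matrix(stats::rnorm(cout * 9 * cin,
                                                 sd = sqrt(2 / (9 * cin))),
                                    cout, 9 * cin)
  p[[paste0(name, ".b")]] <- numeric(cout)
  if (useBn) {
    p[[paste0(name, ".g")]] <- rep(1, cout)
    p[[paste0(name, ".be")]] <- numeric(cout)
    p[[paste0(name, ".rm")]] <- numeric(cout)
    p[[paste0(name, ".rv")]] <- rep(1, cout)
  }
  p
}

.initUnetParams <- function(spec, seed) {
  set.seed(seed)
  ch <- .unetChannels(spec)
  bn <- spec@useBatchnorm
  p <- list()
  for (l in seq_len(spec@depth)) {
    cin <- if (l == 1) 1L else ch[l - 1]
    p <- c(p, .convParams(sprintf("enc%d.c1", l), cin, ch[l], bn),
           .convParams(sprintf("enc%d.c2", l), ch[l], ch[l], bn))
  }
  cb <- ch[spec@depth] * 2L
  p <- c(p, .convParams("bott.c1", ch[spec@depth], cb, bn),
         .convParams("bott.c2", cb, cb, bn))
  for (l in seq_len(spec@depth)) {
    cbelow <- if (l == spec@depth) cb else ch[l + 1]
    up <- list()
    up[[sprintf("dec%d.up.W", l)]] <-
      matrix(stats::rnorm(ch[l] * 4 * cbelow, sd = sqrt(2 / (4 * cbelow))),
             ch[l], 4 * cbelow)
    up[[sprintf("dec%d.up.b", l)]] <- numeric(ch[l])
    p <- c(p, up,
           .convParams(sprintf("dec%d.c1", l), 2L * ch[l], ch[l], bn),
           .convParams(sprintf("dec%d.c2", l), ch[l], ch[l], bn))
  }
  p[["out.W"]] <- matrix(stats::rnorm(ch[1], sd = sqrt(1 / ch[1])), 1, ch[1])
  p[["out.b"]] <- 0
  p
}

.isTrainable <- function(nms) !grepl("\\.(rm|rv)$", nms)

#' Build an (untrained) U-Net
#'
#' @param spec a \linkS4class{UNetSpec}.
#' @param inputSize side length of the square single-channel input; must be
#'   divisible by 2^depth.
#' @param seed weight-initialization seed (He initialization).
#' @return a \linkS4class{TrainedModel} with empty history.
#' @examples
#' m <- buildUnet(unetSpec(depth = 2, baseFilters = 4), inputSize = 16)
#' paramCount(m)
#' @export
buildUnet <- function(spec, inputSize = 128L, seed = 1L) {
  stopifnot(is(spec, "UNetSpec"))
  inputSize <- as.integer(inputSize)
  if (inputSize %% 2^spec@depth != 0)
    stop("input size must be divisible by 2^depth")
  params <- .initUnetParams(spec, seed)
  new("TrainedModel", params = params, spec = spec, inputSize = inputSize,
      history = data.frame(epoch = integer(), trainLoss = numeric(),
                           valLoss = numeric()),
      provenance = list(initSeed = seed))
}

#' @rdname paramCount
#' @export
setMethod("paramCount", "TrainedModel", function(x, ...) {
  nms <- names(x@params)
  sum(vapply(x@params[.isTrainable(nms)], length, numeric(1)))
})

#' @rdname paramCount
#' @export
setMethod("paramCount", "UNetSpec", function(x, ...) {
  m <- buildUnet(x, inputSize = as.integer(2^x@depth), seed = 1L)
  paramCount(m)
})

#' Full-scale U-Net preset
#'
#' Depth 4, base 64 filters: approximately 3.1e7 trainable parameters for a
#' 128 x 128 single-channel input.
#' @return a \linkS4class{UNetSpec}.
#' @export
unetPresetFull <- function() unetSpec(depth = 4L, baseFilters = 64L)

#' Reduced U-Net preset for CPU desk-scale runs
#'
#' Depth 4, base 16 filters, intended for 64 x 64 inputs.
#' @return a \linkS4class{UNetSpec}.
#' @export
unetPresetReduced <- function() unetSpec(depth = 4L, baseFilters = 16L)

#' Micro U-Net preset for experiment sweeps
#'
#' Depth 3, base 8 filters, intended for 32 x 32 inputs; used by the
#' learning-curve and input-comparison drivers where dozens of trainings
#' are needed.
#' @return a \linkS4class{UNetSpec}.
#' @export
unetPresetMicro <- function() unetSpec(depth = 3L, baseFilters = 8L)

# normalize each image of an (H, W, N) array by its max |value|
.normalizeInputArray <- function(x) {
  if (length(dim(x)) == 2) x <- array(x, c(dim(x), 1))
  for (i in seq_len(dim(x)[3])) {
    m <- max(abs(x[, , i]))
    if (m > 0) x[, , i] <- x[, , i] / m
  }
  x
}

.adamInit <- function(params) {
  nms <- names(params)[.isTrainable(names(params))]
  list(m = lapply(params[nms], function(p) p * 0),
       v = lapply(params[nms], function(p) p * 0), t = 0L, nms = nms)
}

.adamUpdate <- function(params, grads, state, cfg) {
  state$t <- state$t + 1L
  params <- cpp_adam_step(params, grads, state$m, state$v, state$nms,
                          state$t, cfg@lr, cfg@beta1, cfg@beta2, 1e-8)
  list(params = params, state = state)
}

.predictRaw <- function(params, spec, x, mcDropout = FALSE, seed = 1,
                        dropoutRate = NULL) {
  d <- dim(x)
  cpp_unet_predict(params, as.numeric(x), d[1], d[2], d[3], spec@depth,
                   spec@baseFilters, spec@useBatchnorm, mcDropout,
                   dropoutRate %||% spec@dropoutRate, seed)
}

#' Train a U-Net on paired images
#'
#' Mini-batch Adam on the mean squared error, with early stopping on the
#' validation loss and restoration of the best-validation weights. Inputs
#' are max-|value|-normalized per image before entering the network; targets
#' are used as stored (the dataset builder max-normalizes them).
#'
#' @param model a \linkS4class{TrainedModel} (untrained or to fine-tune).
#' @param dataset a \linkS4class{PADataset} (its "train" and "val" splits
#'   are used) or a list with elements \code{input}, \code{target},
#'   \code{valInput}, \code{valTarget} (H x W x N arrays).
#' @param cfg a \linkS4class{TrainConfig}; \code{maxEpochs = 0} returns the
#'   model unchanged.
#' @return the trained \linkS4class{TrainedModel} with per-epoch history.
#' @export
trainNetwork <- function(model, dataset, cfg = trainConfig()) {
  stopifnot(is(model, "TrainedModel"), is(cfg, "TrainConfig"))
  if (cfg@maxEpochs == 0L) return(model)
  d <- .trainArrays(dataset)
  xtr <- .normalizeInputArray(d$input); ttr <- d$target
  xval <- .normalizeInputArray(d$valInput); tval <- d$valTarget
  H <- dim(xtr)[1]; W <- dim(xtr)[2]; ntr <- dim(xtr)[3]
  if (H != model@inputSize)
    stop("dataset image size does not match the model input size")
  spec <- model@spec
  params <- model@params
  state <- .adamInit(params)
  set.seed(cfg@seed)
  best <- list(loss = Inf, params = params, epoch = 0L)
  hist <- vector("list", cfg@maxEpochs)
  bad <- 0L
  step <- 0L
  for (epoch in seq_len(cfg@maxEpochs)) {
    idx <- sample(ntr)
    losses <- c()
    for (b in seq_len(ceiling(ntr / cfg@batchSize))) {
      take <- idx[((b - 1) * cfg@batchSize + 1):min(b * cfg@batchSize, ntr)]
      step <- step + 1L
      res <- cpp_unet_train_step(
        params, as.numeric(xtr[, , take, drop = FALSE]),
        as.numeric(ttr[, , take, drop = FALSE]), H, W, length(take),
        spec@depth, spec@baseFilters, spec@useBatchnorm, spec@dropoutRate,
        .subSeed(cfg@seed, step), cfg@bnMomentum)
      if (!is.finite(res$loss))
        stop("NaN/Inf training loss at epoch ", epoch, ", step ", step,
             "; lower the learning rate")
      losses <- c(losses, res$loss)
      for (nm in names(res$stats)) params[[nm]] <- res$stats[[nm]]
      upd <- .adamUpdate(params, res$grads, state, cfg)
      params <- upd$params; state <- upd$state
    }
    yv <- .predictRaw(params, spec, xval)
    vloss <- mean((yv - tval)^2)
    hist[[epoch]] <- data.frame(epoch = epoch, trainLoss = mean(losses),
                                valLoss = vloss)
    if (vloss < best$loss) {
      best <- list(loss = vloss, params = params, epoch = epoch)
      bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= cfg@patience) break
    }
  }
  model@params <- best$params
  model@history <- do.call(rbind, hist[!vapply(hist, is.null, logical(1))])
  model@provenance <- c(model@provenance,
                        list(trainSeed = cfg@seed, bestEpoch = best$epoch,
                             nTrain = ntr))
  model
}

.trainArrays <- function(dataset) {
  if (is(dataset, "PADataset")) {
    tr <- dataset@split == "train"; va <- dataset@split == "val"
    if (!any(va)) stop("dataset has no validation split")
    list(input = dataset@input[, , tr, drop = FALSE],
         target = dataset@target[, , tr, drop = FALSE],
         valInput = dataset@input[, , va, drop = FALSE],
         valTarget = dataset@target[, , va, drop = FALSE])
  } else if (is.list(dataset)) {
    stopifnot(all(c("input", "target", "valInput", "valTarget") %in%
                    names(dataset)))
    dataset
  } else stop("unsupported dataset type")
}

#' Deterministic network prediction
#'
#' Forward pass with dropout disabled and batch normalization in inference
#' mode: two calls on the same input give identical outputs, and batched
#' prediction equals per-image prediction.
#'
#' @param model a trained \linkS4class{TrainedModel}.
#' @param mbf a \linkS4class{ReconImage} (kind "mBF"), matrix, or
#'   H x W x N array; max-|value|-normalized internally.
#' @return a \linkS4class{ReconImage} of kind "prediction" (or an H x W x N
#'   array for array input).
#' @export
predictImage <- function(model, mbf) {
  stopifnot(is(model, "TrainedModel"))
  isImg <- is(mbf, "ReconImage")
  x <- if (isImg) mbf@values else mbf
  arrIn <- length(dim(x)) == 3
  x <- .normalizeInputArray(x)
  if (dim(x)[1] != model@inputSize || dim(x)[2] != model@inputSize)
    stop("input shape does not match the model input size")
  y <- .predictRaw(model@params, model@spec, x)
  if (arrIn) return(y)
  v <- matrix(y[, , 1], dim(x)[1], dim(x)[2])
  if (isImg) reconImage(v, mbf@grid, "prediction") else v
}

#' Pretrain on simulated pairs, then fine-tune
#'
#' Trains on the (large, cheap) simulated dataset first, then fine-tunes all
#' weights on the target-domain dataset. An empty fine-tune set returns the
#' pretrained model.
#'
#' @param simDataset,expDataset datasets as in \code{\link{trainNetwork}};
#'   must share the grid size.
#' @param cfg a \linkS4class{TrainConfig} used for both phases (seed offset
#'   for the fine-tune phase).
#' @param model an initial \linkS4class{TrainedModel}; built from
#'   \code{spec}/\code{inputSize} if missing.
#' @param spec,inputSize used when \code{model} is missing.
#' @return the fine-tuned \linkS4class{TrainedModel}; both histories kept in
#'   \code{provenance$pretrainHistory} and \code{history}.
#' @export
pretrainFinetune <- function(simDataset, expDataset, cfg = trainConfig(),
                             model = NULL, spec = unetPresetReduced(),
                             inputSize = 64L) {
  if (is.null(model)) model <- buildUnet(spec, inputSize, seed = cfg@seed)
  pre <- trainNetwork(model, simDataset, cfg)
  empty <- is.null(expDataset) ||
    (is(expDataset, "PADataset") && !any(expDataset@split == "train"))
  if (empty) return(pre)
  cfg2 <- cfg
  cfg2@seed <- .subSeed(cfg@seed, 999L)
  fin <- trainNetwork(pre, expDataset, cfg2)
  fin@provenance$pretrainHistory <- pre@history
  fin
}
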