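## Training: Adam on the flattened parameter vector, warmup + cosine
## learning-rate schedule, optional target standardization.

#' Training hyperparameters
#'
#' Defaults follow the reference protocol for the molecular benchmarks:
#' Adam, batch size 64, 1000 epochs with a 250-epoch warmup to 1e-4 and
#' cosine annealing to 1e-8.  Desk-scale runs override epochs, widths and
#' the peak rate.
#'
#' @param epochs number of passes over the training set.
#' @param batchSize molecules per optimization step.
#' @param warmupEpochs linear-ramp length (default a quarter of
#'   \code{epochs}, mirroring 250/1000).
#' @param peakLR,floorLR learning-rate peak and cosine floor.
#' @param standardize center/scale the targets during optimization and fold
#'   the transform back at prediction time (recorded with the model).
#' @param shuffle reshuffle molecules into batches each epoch.
#' @param seed RNG seed for shuffling (and any other training randomness).
#' @param checkpointEvery if > 0, record a layerwise Dirichlet-energy
#'   profile on a validation molecule every this many epochs.
#' @param verbose print a line per epoch.
#' @return list of class \code{TrainControl}.
#' @export
trainControl <- function(epochs = 1000L, batchSize = 64L,
                         warmupEpochs = max(1L, round(epochs / 4)),
                         peakLR = 1e-4, floorLR = 1e-8,
                         standardize = TRUE, shuffle = TRUE, seed = 1L,
                         checkpointEvery = 0L, verbose = FALSE) {
  if (peakLR < floorLR)
    stop("configuration error: peakLR < floorLR", call. = FALSE)
  ctl <- list(epochs = as.integer(epochs), batchSize = as.integer(batchSize),
              warmupEpochs = as.integer(warmupEpochs), peakLR = peakLR,
              floorLR = floorLR, standardize = isTRUE(standardize),
              shuffle = isTRUE(shuffle), seed = as.integer(seed),
              checkpointEvery = as.integer(checkpointEvery),
              verbose = isTRUE(verbose))
  class(ctl) <- "TrainControl"
  ctl
}

flattenParams <- function(params) unlist(params, use.names = FALSE)

unflattenParams <- function(v, skeleton) utils::relist(v, skeleton)

#' Train a model with Adam
#'
#' Minimizes \code{MAE + lambda * L_reg} over mini-batches with Adam
#' (beta1 = 0.9, beta2 = 0.999) under the warmup-plus-cosine schedule.
#' Fully deterministic given the seeds in \code{config} and \code{control}
#' (up to floating-point summation order).
#'
#' @param trainGraphs list of \code{MolecularGraph} with finite targets.
#' @param config a \code{\link{modelConfig}}.
#' @param control a \code{\link{trainControl}}.
#' @param valGraphs optional validation list; when given, the history
#'   records the validation MAE each epoch.
#' @return list of class \code{PairRegFit} with elements \code{params},
#'   \code{config}, \code{control}, \code{targetStats} (center/scale used
#'   during optimization), \code{history} (one row per epoch: epoch, lr,
#'   trainLoss, trainMAE, lReg, valMAE) and \code{energyCheckpoints}.
#' @export
trainModel <- function(trainGraphs, config, control = trainControl(),
                       valGraphs = NULL) {
  stopifnot(length(trainGraphs) >= 1L)
  yTrain <- vapply(trainGraphs, targetValue, numeric(1))
  if (!all(is.finite(yTrain)))
    stop("all training targets must be finite", call. = FALSE)
  if (control$standardize) {
    mu <- mean(yTrain)
    sdy <- stats::sd(yTrain)
    if (!is.finite(sdy) || sdy == 0) sdy <- 1
  } else {
    mu <- 0
    sdy <- 1
  }
  targetStats <- c(center = mu, scale = sdy)
  yScaled <- (yTrain - mu) / sdy

  params <- initModelParams(config)
  flat <- flattenParams(params)
  mAdam <- vAdam <- numeric(length(flat))
  beta1 <- 0.9; beta2 <- 0.999; epsAdam <- 1e-8
  tStep <- 0L

  nTrain <- length(trainGraphs)
  history <- data.frame(epoch = integer(0), lr = numeric(0),
                        trainLoss = numeric(0), trainMAE = numeric(0),
                        lReg = numeric(0), valMAE = numeric(0))
  energyCheckpoints <- list()
  set.seed(control$seed)

  for (epoch in seq_len(control$epochs)) {
    lr <- lrSchedule(epoch - 1L, control$epochs, control$warmupEpochs,
                     control$peakLR, control$floorLR)
    ord <- if (control$shuffle) sample.int(nTrain) else seq_len(nTrain)
    batchIdx <- split(ord, ceiling(seq_along(ord) / control$batchSize))
    epochLoss <- epochMAE <- epochLReg <- 0
    for (bi in batchIdx) {
      batch <- batchGraphs(trainGraphs[bi])
      lg <- lossAndGradient(batch, params, config, targets = yScaled[bi])
      if (!is.finite(lg$loss))
        stop("training diverged: non-finite loss at epoch ", epoch,
             call. = FALSE)
      gFlat <- flattenParams(lg$grads)
      tStep <- tStep + 1L
      mAdam <- beta1 * mAdam + (1 - beta1) * gFlat
      vAdam <- beta2 * vAdam + (1 - beta2) * gFlat * gFlat
      mHat <- mAdam / (1 - beta1^tStep)
      vHat <- vAdam / (1 - beta2^tStep)
      flat <- flat - lr * mHat / (sqrt(vHat) + epsAdam)
      params <- unflattenParams(flat, params)
      w <- length(bi) / nTrain
      epochLoss <- epochLoss + w * lg$loss
      epochMAE <- epochMAE + w * lg$mae
      epochLReg <- epochLReg + w * lg$lReg
    }
    valMAE <- if (!is.null(valGraphs))
      evaluateModel(valGraphs, params, config, targetStats) else NA_real_
    history[epoch, ] <- list(epoch, lr, epochLoss, epochMAE, epochLReg,
                             valMAE)
    if (control$checkpointEvery > 0L &&
        (epoch %% control$checkpointEvery == 0L || epoch == control$epochs)) {
      probe <- if (!is.null(valGraphs)) valGraphs[[1L]] else trainGraphs[[1L]]
      fwp <- modelForward(asBatch(probe), params, config, withTrace = TRUE)
      energyCheckpoints[[length(energyCheckpoints) + 1L]] <-
        list(epoch = epoch,
             profile = energyProfile(fwp$hTrace, edgeIndex(probe)))
    }
    if (control$verbose)
      message(sprintf("epoch %d  lr %.3g  loss %.5f  valMAE %.5f",
                      epoch, lr, epochLoss, valMAE))
  }

  fit <- list(params = params, config = config, control = control,
              targetStats = targetStats, history = history,
              energyCheckpoints = energyCheckpoints)
  class(fit) <- "PairRegFit"
  fit
}

#' @export
print.PairRegFit <- function(x, ...) {
  cat("PairRegFit:", configFingerprint(x$config), "\n")
  last <- x$history[nrow(x$history), ]
  cat(sprintf("  %d epochs; final train loss %.5f, val MAE %s\n",
              nrow(x$history), last$trainLoss, format(last$valMAE)))
  invisible(x)
}

#' Predict molecular properties
#'
#' @param fitOrParams a \code{PairRegFit}, or a raw parameter list (then
#'   \code{config} is required).
#' @param graphs list of \code{MolecularGraph}.
#' @param config,targetStats used when raw parameters are given.
#' @param batchSize molecules per forward pass.
#' @return numeric vector of predictions on the original target scale.
#' @export
predictMolecules <- function(fitOrParams, graphs, config = NULL,
                             targetStats = c(center = 0, scale = 1),
                             batchSize = 64L) {
  if (inherits(fitOrParams, "PairRegFit")) {
    params <- fitOrParams$params
    config <- fitOrParams$config
    targetStats <- fitOrParams$targetStats
  } else {
    params <- fitOrParams
    if (is.null(config)) stop("config required with raw parameters",
                              call. = FALSE)
  }
  idx <- split(seq_along(graphs),
               ceiling(seq_along(graphs) / batchSize))
  preds <- unlist(lapply(idx, function(bi) {
    modelForward(batchGraphs(graphs[bi]), params, config)$pred
  }), use.names = FALSE)
  preds * targetStats[["scale"]] + targetStats[["center"]]
}

#' Mean absolute error of a model on a molecule set
#'
#' @param graphs list of \code{MolecularGraph} with finite targets.
#' @param paramsOrFit parameters or a \code{PairRegFit}.
#' @param config,targetStats used when raw parameters are given.
#' @return scalar MAE on the original target scale.
#' @export
evaluateModel <- function(graphs, paramsOrFit, config = NULL,
                          targetStats = c(center = 0, scale = 1)) {
  preds <- predictMolecules(paramsOrFit, graphs, config, targetStats)
  y <- vapply(graphs, targetValue, numeric(1))
  mean(abs(preds - y))
}

#' Baseline MAE of always predicting the training mean
#'
#' @param trainGraphs,evalGraphs molecule lists with targets.
#' @return scalar MAE of the constant mean predictor.
#' @export
meanPredictorMAE <- function(trainGraphs, evalGraphs = trainGraphs) {
  mu <- mean(vapply(trainGraphs, targetValue, numeric(1)))
  mean(abs(vapply(evalGraphs, targetValue, numeric(1)) - mu))
}
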