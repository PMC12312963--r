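## Model assembly: embedding -> L stacked PairReg layers -> invariant readout.

#' Model configuration
#'
#' Collects the architectural choices of the network.  Defaults follow the
#' deep-stack setting used for molecular property regression: nine layers and
#' hidden width 128; desk-scale configurations shrink these.
#'
#' @param vocabulary atom-type vocabulary (drives the input feature width
#'   \code{length(vocabulary) + 1}).
#' @param nLayers number of stacked layers (>= 1, default 9).
#' @param fHidden hidden node-feature width (default 128).
#' @param mWidth message width (default \code{fHidden}).
#' @param mode a \code{\link{pairRegMode}} (default \code{"full"}).
#' @param readout pooling over atoms, \code{"sum"} (default) or
#'   \code{"mean"}.
#' @param zScale atomic-number feature scale (default 1/9).
#' @param cMode coordinate-update normalization, \code{"nminus1"} (default,
#'   the reciprocal of the summand count) or \code{"n"}.
#' @param coordGain initialization scale of the coordinate gate output layer.
#' @param seed integer seed used by \code{\link{initModelParams}}.
#' @return A list of class \code{ModelConfig}.
#' @export
modelConfig <- function(vocabulary = qm9Vocabulary(), nLayers = 9L,
                        fHidden = 128L, mWidth = fHidden,
                        mode = pairRegMode("full"),
                        readout = c("sum", "mean"), zScale = 1 / 9,
                        cMode = c("nminus1", "n"), coordGain = 1e-3,
                        seed = 1L) {
  readout <- match.arg(readout)
  cMode <- match.arg(cMode)
  nLayers <- as.integer(nLayers)
  fHidden <- as.integer(fHidden)
  mWidth <- as.integer(mWidth)
  if (nLayers < 1L) stop("nLayers must be >= 1", call. = FALSE)
  if (fHidden < 1L || mWidth < 1L) stop("widths must be >= 1", call. = FALSE)
  if (!inherits(mode, "PairRegMode")) stop("mode must be a PairRegMode",
                                           call. = FALSE)
  cfg <- list(vocabulary = as.character(vocabulary), fIn =
                length(vocabulary) + 1L, nLayers = nLayers,
              fHidden = fHidden, mWidth = mWidth, mode = mode,
              readout = readout, zScale = zScale, cMode = cMode,
              coordGain = coordGain, seed = as.integer(seed))
  class(cfg) <- "ModelConfig"
  cfg
}

#' @export
print.ModelConfig <- function(x, ...) {
  cat("ModelConfig:", x$nLayers, "layers, width", x$fHidden,
      "(messages", x$mWidth, "), readout", x$readout, "\n")
  print(x$mode)
  invisible(x)
}

configFingerprint <- function(config) {
  paste0("L", config$nLayers, "-f", config$fHidden, "-m", config$mWidth,
         "-", config$mode$preset, "-", config$readout, "-seed", config$seed)
}

#' Initialize all model parameters
#'
#' Draws the embedding map, one \code{\link{layerParams}} set per layer, and
#' the readout maps (per-node perceptron, pooling, then a perceptron to one
#' scalar) from the seed recorded in the configuration.  The parameter count
#' is a deterministic function of the configuration.
#'
#' @param config a \code{\link{modelConfig}}.
#' @return Nested list with elements \code{embedding}, \code{layers},
#'   \code{readout}.
#' @export
initModelParams <- function(config) {
  f <- config$fHidden
  m <- config$mWidth
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  set.seed(config$seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  params <- list(
    embedding = list(We = glorotUniform(config$fIn, f), be = numeric(f)),
    layers = lapply(seq_len(config$nLayers), function(l)
      layerParams(f, m, coordGain = config$coordGain)),
    readout = list(
      U1 = glorotUniform(f, f), c1 = numeric(f),
      U2 = glorotUniform(f, f), c2 = numeric(f),
      V1 = glorotUniform(f, f), e1 = numeric(f),
      v2 = glorotUniform(f, 1L), e2 = 0)
  )
  params
}

#' Invariant readout to one scalar per molecule
#'
#' Per-node two-layer perceptron, permutation-invariant pooling (sum or
#' mean) per molecule, then a two-layer perceptron to a scalar.
#'
#' @param hFinal n x f node features after the last layer.
#' @param membership node -> molecule index.
#' @param params the \code{readout} parameter list.
#' @param pooling \code{"sum"} or \code{"mean"}.
#' @param cache keep intermediates for backpropagation.
#' @return list with \code{pred} (one scalar per molecule) and optionally
#'   \code{cache}.
#' @export
readoutForward <- function(hFinal, membership, params,
                           pooling = c("sum", "mean"), cache = FALSE) {
  pooling <- match.arg(pooling)
  nMol <- max(membership)
  counts <- tabulate(membership, nbins = nMol)
  if (any(counts == 0L)) stop("empty molecule in batch", call. = FALSE)
  p1 <- linearForward(hFinal, params$U1, params$c1)
  q1 <- silu(p1)
  p2 <- linearForward(q1, params$U2, params$c2)
  pooled <- segmentSum(p2, membership, nMol)
  if (pooling == "mean") pooled <- pooled / counts
  r1 <- linearForward(pooled, params$V1, params$e1)
  s1 <- silu(r1)
  pred <- drop(s1 %*% params$v2) + params$e2
  out <- list(pred = pred)
  if (cache)
    out$cache <- list(hFinal = hFinal, p1 = p1, q1 = q1, p2 = p2,
                      pooled = pooled, r1 = r1, s1 = s1,
                      counts = counts, pooling = pooling)
  out
}

#' Full model forward pass
#'
#' Embeds the input features, applies the stacked PairReg layers, and reads
#' out one scalar per molecule.  The prediction is invariant to rigid
#' motions and atom permutations; the final coordinates are equivariant.
#'
#' @param batch a \code{\link{GraphBatch}} (or a single
#'   \code{MolecularGraph}).
#' @param params parameters from \code{\link{initModelParams}}.
#' @param config the generating \code{\link{modelConfig}}.
#' @param withTrace if \code{TRUE}, retain the per-layer node features
#'   (\code{hTrace[[1]]} is the embedded input) for diagnostics.
#' @param cache if \code{TRUE}, retain all intermediates for
#'   backpropagation.
#' @return list with \code{pred} (scalars), \code{xFinal} (n x 3),
#'   \code{x0}, and optionally \code{hTrace} and \code{caches}.
#' @export
modelForward <- function(batch, params, config, withTrace = FALSE,
                         cache = FALSE) {
  batch <- asBatch(batch)
  feats <- nodeFeatures(batch)
  if (ncol(feats) != nrow(params$embedding$We))
    stop("configuration error: batch feature width ", ncol(feats),
         " does not match embedding input ", nrow(params$embedding$We),
         call. = FALSE)
  h <- linearForward(feats, params$embedding$We, params$embedding$be)
  x <- coords(batch)
  x0 <- x
  edges <- edgeIndex(batch)
  mode <- config$mode
  hTrace <- if (withTrace) list(h) else NULL
  caches <- if (cache) vector("list", config$nLayers) else NULL
  for (l in seq_len(config$nLayers)) {
    step <- pairRegLayer(h, x, edges, params$layers[[l]], mode,
                         cMode = config$cMode, cache = cache)
    h <- step$h
    x <- step$x
    if (withTrace) hTrace[[l + 1L]] <- h
    if (cache) caches[[l]] <- step$cache
  }
  ro <- readoutForward(h, membership(batch), params$readout,
                       pooling = config$readout, cache = cache)
  out <- list(pred = ro$pred, xFinal = x, x0 = x0)
  if (withTrace) out$hTrace <- hTrace
  if (cache) {
    out$caches <- caches
    out$readoutCache <- ro$cache
    out$feats <- feats
    out$hFinal <- h
  }
  out
}

#' Training loss: MAE plus the coordinate-regression penalty
#'
#' \code{L = mean(|pred - target|) + lambda * L_reg(x_final, x_0)}.  The
#' penalty term is dropped (identically zero) when \code{lambda} is zero or
#' the coordinate matrices are absent, as when the coordinate path is off.
#'
#' @param pred,target one scalar per molecule.
#' @param xFinal,x0 optional n x 3 coordinate matrices.
#' @param membership node -> molecule index (required with coordinates).
#' @param lambda non-negative penalty weight.
#' @return scalar loss.
#' @export
totalLoss <- function(pred, target, xFinal = NULL, x0 = NULL,
                      membership = NULL, lambda = 0) {
  if (lambda < 0) stop("configuration error: lambda must be >= 0",
                       call. = FALSE)
  if (length(pred) != length(target))
    stop("one prediction and one target per molecule", call. = FALSE)
  loss <- mean(abs(pred - target))
  if (lambda > 0 && !is.null(xFinal))
    loss <- loss + lambda * coordRegularizer(xFinal, x0, membership)
  loss
}

#' Warmup-plus-cosine learning-rate schedule
#'
#' Linear ramp from 0 to \code{peak} over the first \code{warmupEpochs}
#' epochs, then cosine annealing from \code{peak} down to \code{floor} at
#' the final epoch; the two pieces join continuously.  Defaults follow the
#' protocol of warming up to 1e-4 over 250 of 1000 epochs, then annealing
#' to 1e-8.
#'
#' @param epoch 0-based epoch index, \code{0 <= epoch < totalEpochs}.
#' @param totalEpochs total epoch count.
#' @param warmupEpochs ramp length (\code{< totalEpochs}).
#' @param peak learning rate at the end of the warmup.
#' @param floor learning rate at the final epoch.
#' @return the learning rate, a positive scalar (zero at epoch 0).
#' @examples
#' lrSchedule(250, 1000)  # 1e-4, the peak
#' lrSchedule(999, 1000)  # 1e-8, the floor
#' @export
lrSchedule <- function(epoch, totalEpochs, warmupEpochs = 250L,
                       peak = 1e-4, floor = 1e-8) {
  if (peak < floor) stop("configuration error: peak < floor", call. = FALSE)
  if (warmupEpochs >= totalEpochs)
    stop("warmupEpochs must be smaller than totalEpochs", call. = FALSE)
  if (any(epoch < 0) || any(epoch >= totalEpochs))
    stop("epoch out of range", call. = FALSE)
  ramp <- if (warmupEpochs > 0) peak * epoch / warmupEpochs else peak
  span <- totalEpochs - 1L - warmupEpochs
  tt <- if (span > 0) pmin(pmax((epoch - warmupEpochs) / span, 0), 1) else 0
  cosine <- floor + (peak - floor) * (1 + cos(pi * tt)) / 2
  ifelse(epoch <= warmupEpochs, ramp, cosine)
}
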