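## Reverse-mode differentiation of the full model, hand-derived layer by
## layer.  Gradient lists mirror the parameter lists exactly (same names,
## same shapes) so they can be flattened with unlist()/relist() for the
## optimizer and for finite-difference verification.

## backward through one PairReg layer.
## dH, dX: gradients of the loss wrt the layer OUTPUTS (h, x).
## Returns gradients wrt the layer INPUTS plus the per-parameter gradients.
pairRegLayerBackward <- function(dH, dX, cache, params, mode, cMode) {
  f <- ncol(cache$hIn)
  m <- ncol(cache$msg)
  n <- nrow(cache$hIn)
  iIdx <- cache$iIdx
  jIdx <- cache$jIdx

  ## coordinate output path
  if (mode$coordMode == "average") {
    dXu <- dX / 2
    dXin <- dX / 2
  } else if (mode$coordMode == "update") {
    dXu <- dX
    dXin <- matrix(0, n, 3L)
  } else {  # frozen: x passed straight through
    dXu <- NULL
    dXin <- dX
  }

  ## residual projection
  if (mode$nodeResidual) {
    hcat <- cbind(cache$hIn, cache$hMid, deparse.level = 0)
    gWr <- crossprod(hcat, dH)
    gbr <- colSums(dH)
    dcat <- dH %*% t(params$Wr)
    dHin <- dcat[, seq_len(f), drop = FALSE]
    dHmid <- dcat[, f + seq_len(f), drop = FALSE]
  } else {
    gWr <- zerosLike(params$Wr)
    gbr <- zerosLike(params$br)
    dHin <- matrix(0, n, f)
    dHmid <- dH
  }

  ## phi_h
  gWh2 <- crossprod(cache$ah, dHmid)
  gbh2 <- colSums(dHmid)
  dah <- dHmid %*% t(params$Wh2)
  dv1 <- dah * siluGradCached(cache$v1, cache$sgv)
  gWh1 <- crossprod(cache$hin, dv1)
  gbh1 <- colSums(dv1)
  dhin <- dv1 %*% t(params$Wh1)
  dHin <- dHin + dhin[, seq_len(f), drop = FALSE]
  dMagg <- dhin[, f + seq_len(m), drop = FALSE]

  nEdges <- length(iIdx)
  dDiff <- matrix(0, nEdges, 3L)
  dM <- matrix(0, nEdges, m)

  ## coordinate update x_u = x + C * segsum(diff * s)
  if (cache$updateCoords && !is.null(dXu)) {
    dXin <- dXin + dXu
    dXuE <- dXu[iIdx, , drop = FALSE]
    Ce <- cache$C[iIdx]
    dS <- Ce * rowSums(dXuE * cache$diff)
    dDiff <- dDiff + (Ce * cache$s) * dXuE
    ## phi_x backward
    gwx2 <- crossprod(cache$ax, dS)
    dax <- outer(dS, drop(params$wx2))
    du1 <- dax * siluGradCached(cache$u1, cache$sgu)
    gWx1 <- crossprod(cache$msg, du1)
    gbx1 <- colSums(du1)
    dM <- dM + du1 %*% t(params$Wx1)
  } else {
    ## coordinate update skipped in the forward pass: x_u = x, so any
    ## gradient routed to x_u flows straight to the input coordinates
    if (!is.null(dXu)) dXin <- dXin + dXu
    gwx2 <- zerosLike(params$wx2)
    gWx1 <- zerosLike(params$Wx1)
    gbx1 <- zerosLike(params$bx1)
  }

  ## aggregation m_i = segsum(g * msg)
  dWm <- dMagg[iIdx, , drop = FALSE]
  dG <- rowSums(dWm * cache$msg)
  dM <- dM + dWm * cache$g

  ## edge gate g = sigmoid(msg winf + binf)
  dzg <- dG * cache$g * (1 - cache$g)
  gwinf <- crossprod(cache$msg, dzg)
  gbinf <- sum(dzg)
  dM <- dM + outer(dzg, drop(params$winf))

  ## phi_e: msg = silu(z2), z2 = a1 We2 + be2, a1 = silu(z1), z1 = ein We1+be1
  dz2 <- dM * siluGradCached(cache$z2, cache$sg2)
  gWe2 <- crossprod(cache$a1, dz2)
  gbe2 <- colSums(dz2)
  da1 <- dz2 %*% t(params$We2)
  dz1 <- da1 * siluGradCached(cache$z1, cache$sg1)
  gWe1 <- crossprod(cache$ein, dz1)
  gbe1 <- colSums(dz1)
  dein <- dz1 %*% t(params$We1)

  ## scatter edge-input gradients back to nodes
  dHin <- dHin + segmentSum(dein[, seq_len(f), drop = FALSE], iIdx, n)
  dHin <- dHin + segmentSum(dein[, f + seq_len(f), drop = FALSE], jIdx, n)
  dD2 <- dein[, 2L * f + 1L]
  dDiff <- dDiff + 2 * dD2 * cache$diff
  dXin <- dXin + segmentSum(dDiff, iIdx, n) - segmentSum(dDiff, jIdx, n)

  list(dH = dHin, dX = dXin,
       grads = list(We1 = gWe1, be1 = gbe1, We2 = gWe2, be2 = gbe2,
                    winf = gwinf, binf = gbinf,
                    Wx1 = gWx1, bx1 = gbx1, wx2 = gwx2,
                    Wh1 = gWh1, bh1 = gbh1, Wh2 = gWh2, bh2 = gbh2,
                    Wr = gWr, br = gbr))
}

## backward through the readout given dPred (one scalar per molecule)
readoutBackward <- function(dPred, cache, params, membership) {
  ds1 <- outer(dPred, drop(params$v2))
  gv2 <- crossprod(cache$s1, dPred)
  ge2 <- sum(dPred)
  dr1 <- ds1 * siluGrad(cache$r1)
  gV1 <- crossprod(cache$pooled, dr1)
  ge1 <- colSums(dr1)
  dPooled <- dr1 %*% t(params$V1)
  if (cache$pooling == "mean") dPooled <- dPooled / cache$counts
  dP2 <- dPooled[membership, , drop = FALSE]
  gU2 <- crossprod(cache$q1, dP2)
  gc2 <- colSums(dP2)
  dq1 <- dP2 %*% t(params$U2)
  dp1 <- dq1 * siluGrad(cache$p1)
  gU1 <- crossprod(cache$hFinal, dp1)
  gc1 <- colSums(dp1)
  dHf <- dp1 %*% t(params$U1)
  list(dH = dHf,
       grads = list(U1 = gU1, c1 = gc1, U2 = gU2, c2 = gc2,
                    V1 = gV1, e1 = ge1, v2 = gv2, e2 = ge2))
}

## gradient of the coordinate-regression penalty wrt xFinal
coordRegularizerGrad <- function(xFinal, x0, membership) {
  d <- xFinal - x0
  nrm <- sqrt(rowSums(d * d))
  nMol <- max(membership)
  counts <- tabulate(membership, nbins = nMol)
  scale <- 1 / (counts[membership] * nMol)
  ## the norm is not differentiable at zero displacement; use subgradient 0
  ## there (non-finite rows are left zero too and caught by the divergence
  ## check on the loss)
  safe <- which(nrm > 0)
  g <- d * 0
  g[safe, ] <- d[safe, , drop = FALSE] * (scale[safe] / nrm[safe])
  g
}

#' Loss and analytic gradient of the full model on a batch
#'
#' One forward pass with cached intermediates followed by hand-derived
#' reverse-mode differentiation through the readout, every layer (messages,
#' gate, aggregation, coordinate update, node update, residual, coordinate
#' averaging), the coordinate-regression penalty and the embedding.  The
#' gradient list mirrors the parameter list shape-for-shape.
#'
#' @param batch a \code{\link{GraphBatch}}.
#' @param params model parameters (\code{\link{initModelParams}}).
#' @param config the \code{\link{modelConfig}}.
#' @param targets optional override of \code{targets(batch)}.
#' @return list with \code{loss}, \code{mae}, \code{lReg}, \code{pred} and
#'   \code{grads}.
#' @seealso \code{\link{totalLoss}}, \code{\link{trainModel}}
#' @export
lossAndGradient <- function(batch, params, config, targets = NULL) {
  batch <- asBatch(batch)
  if (is.null(targets)) targets <- targets(batch)
  mode <- config$mode
  lambda <- if (mode$coordMode == "average") mode$lambda else 0
  fw <- modelForward(batch, params, config, cache = TRUE)
  memb <- membership(batch)
  nMol <- length(targets)

  resid <- fw$pred - targets
  mae <- mean(abs(resid))
  lReg <- if (lambda > 0) coordRegularizer(fw$xFinal, fw$x0, memb) else 0
  loss <- mae + lambda * lReg

  dPred <- sign(resid) / nMol
  ro <- readoutBackward(dPred, fw$readoutCache, params$readout, memb)
  dH <- ro$dH
  dX <- if (lambda > 0)
    lambda * coordRegularizerGrad(fw$xFinal, fw$x0, memb)
  else matrix(0, nrow(fw$xFinal), 3L)

  layerGrads <- vector("list", config$nLayers)
  for (l in rev(seq_len(config$nLayers))) {
    bk <- pairRegLayerBackward(dH, dX, fw$caches[[l]], params$layers[[l]],
                               mode, config$cMode)
    dH <- bk$dH
    dX <- bk$dX
    layerGrads[[l]] <- bk$grads
  }

  gWe <- crossprod(fw$feats, dH)
  gbe <- colSums(dH)

  list(loss = loss, mae = mae, lReg = lReg, pred = fw$pred,
       grads = list(embedding = list(We = gWe, be = gbe),
                    layers = layerGrads,
                    readout = ro$grads))
}
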