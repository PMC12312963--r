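# Naive reference implementations used as independent oracles: explicit
# loops over edges/pairs and per-row perceptron evaluation, no shared code
# with the vectorized package internals.

refSilu <- function(v) v / (1 + exp(-v))

refMLP2 <- function(v, W1, b1, W2, b2, finalSilu = FALSE) {
  a <- refSilu(as.numeric(v %*% W1) + b1)
  out <- as.numeric(a %*% W2) + b2
  if (finalSilu) refSilu(out) else out
}

## one edge message from scratch
refEdgeMessage <- function(hi, hj, d2, p) {
  refMLP2(c(hi, hj, d2), p$We1, p$be1, p$We2, p$be2, finalSilu = TRUE)
}

refEdgeWeight <- function(m, p) {
  z <- sum(m * p$winf) + p$binf
  1 / (1 + exp(-z))
}

refAggregate <- function(messages, weights, edges, n) {
  out <- matrix(0, n, ncol(messages))
  for (e in seq_len(nrow(edges)))
    out[edges[e, 1], ] <- out[edges[e, 1], ] +
      weights[e] * messages[e, ]
  out
}

refCoordGate <- function(m, p) {
  a <- refSilu(as.numeric(m %*% p$Wx1) + p$bx1)
  sum(a * p$wx2)
}

refCoordUpdate <- function(x, messages, edges, p, cMode = "nminus1") {
  n <- nrow(x)
  if (nrow(edges) == 0) return(x)
  out <- x
  deg <- tabulate(edges[, 1], nbins = n)
  for (e in seq_len(nrow(edges))) {
    i <- edges[e, 1]; j <- edges[e, 2]
    C <- if (cMode == "nminus1") 1 / max(deg[i], 1) else 1 / (deg[i] + 1)
    out[i, ] <- out[i, ] +
      C * (x[i, ] - x[j, ]) * refCoordGate(messages[e, ], p)
  }
  out
}

refNodeUpdate <- function(h, mAgg, p) {
  t(sapply(seq_len(nrow(h)), function(i)
    refMLP2(c(h[i, ], mAgg[i, ]), p$Wh1, p$bh1, p$Wh2, p$bh2)))
}

## full EGCL layer, one edge at a time
refEgclForward <- function(h, x, edges, p, cMode = "nminus1") {
  nE <- nrow(edges)
  msgs <- matrix(0, nE, length(p$be2))
  wts <- numeric(nE)
  for (e in seq_len(nE)) {
    i <- edges[e, 1]; j <- edges[e, 2]
    d2 <- sum((x[i, ] - x[j, ])^2)
    msgs[e, ] <- refEdgeMessage(h[i, ], h[j, ], d2, p)
    wts[e] <- refEdgeWeight(msgs[e, ], p)
  }
  list(h = refNodeUpdate(h, refAggregate(msgs, wts, edges, nrow(h)), p),
       x = refCoordUpdate(x, msgs, edges, p, cMode))
}

refDirichlet <- function(h, edges, normalized = TRUE) {
  if (is.null(dim(h))) h <- matrix(h, ncol = 1)
  tot <- 0
  for (e in seq_len(nrow(edges)))
    tot <- tot + sum((h[edges[e, 1], ] - h[edges[e, 2], ])^2)
  if (normalized) tot / (2 * nrow(edges)) else tot
}

refInvariantTarget <- function(types, xyz, coefs) {
  n <- length(types)
  y <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    y <- y + coefs$a[types[i], types[j]] * exp(-d) +
      coefs$b[types[i], types[j]] / d
  }
  y
}
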