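## The equivariant graph convolutional layer (EGCL).
##
## One round of message passing over a fully connected molecular graph:
##   m_ij = phi_e(h_i, h_j, ||x_i - x_j||^2)        edge message (invariant)
##   e_ij = sigmoid(linear(m_ij))                   soft edge gate
##   m_i  = sum_{j != i} e_ij m_ij                  gated aggregation
##   x_i' = x_i + C sum_{j != i} (x_i - x_j) phi_x(m_ij)   coordinate update
##   h_i' = phi_h(h_i, m_i)                         node update
## No perceptron ever sees raw coordinates -- only squared distances -- so
## h' is E(3)-invariant and x' is E(3)-equivariant by construction.

#' Initialize the learnable maps of one EGCL layer
#'
#' Creates the parameter list for the five maps of a layer: the edge
#' perceptron \code{phi_e} (two layers, SiLU activations), the scalar edge
#' gate \code{phi_inf} (linear + sigmoid), the coordinate gate \code{phi_x}
#' (hidden SiLU layer, then a bias-free linear scalar output initialized at
#' small scale so early coordinate updates are near-zero), the node
#' perceptron \code{phi_h}, and the residual projection \code{phi_r} (a
#' single linear map from width 2f to f, initialized as the block average
#' \code{[I/2 | I/2]}).  Hidden weights are Glorot-uniform draws from the
#' current RNG state.
#'
#' @param f node feature width.
#' @param m message width (defaults to \code{f}).
#' @param coordGain initialization scale of the final \code{phi_x} weights
#'   (default \code{1e-3}).
#' @return A named list of weight matrices and bias vectors.
#' @export
layerParams <- function(f, m = f, coordGain = 1e-3) {
  list(
    We1 = glorotUniform(2L * f + 1L, m), be1 = numeric(m),
    We2 = glorotUniform(m, m),           be2 = numeric(m),
    winf = glorotUniform(m, 1L),         binf = 0,
    Wx1 = glorotUniform(m, m),           bx1 = numeric(m),
    wx2 = glorotUniform(m, 1L, gain = coordGain),
    Wh1 = glorotUniform(f + m, m),       bh1 = numeric(m),
    Wh2 = glorotUniform(m, f),           bh2 = numeric(f),
    Wr = rbind(diag(f) / 2, diag(f) / 2), br = numeric(f)
  )
}

#' Edge message from invariant inputs
#'
#' Evaluates \code{phi_e} on the concatenation (h_i, h_j, squared distance),
#' vectorized over edges.  Coordinates enter only through the squared
#' distance, so the message is invariant under rigid motions.
#'
#' @param hI,hJ E x f matrices (or length-f vectors) of receiver and
#'   neighbor features.
#' @param distSq length-E vector of squared inter-atomic distances (>= 0).
#' @param params a \code{\link{layerParams}} list.
#' @return E x m message matrix.
#' @export
edgeMessage <- function(hI, hJ, distSq, params) {
  if (is.null(dim(hI))) hI <- matrix(hI, nrow = 1L)
  if (is.null(dim(hJ))) hJ <- matrix(hJ, nrow = 1L)
  if (any(!is.finite(hI)) || any(!is.finite(hJ)) || any(!is.finite(distSq)))
    stop("non-finite inputs to edgeMessage", call. = FALSE)
  if (any(distSq < 0)) stop("negative squared distance", call. = FALSE)
  ein <- cbind(hI, hJ, distSq, deparse.level = 0)
  silu(linearForward(silu(linearForward(ein, params$We1, params$be1)),
                     params$We2, params$be2))
}

#' Soft edge gate
#'
#' A linear map of the message followed by a sigmoid, yielding a scalar gate
#' in (0, 1) per edge.
#'
#' @param msg E x m message matrix (or a length-m vector).
#' @param params a \code{\link{layerParams}} list.
#' @return length-E vector of gates, each strictly inside (0, 1).
#' @export
edgeWeight <- function(msg, params) {
  if (is.null(dim(msg))) msg <- matrix(msg, nrow = 1L)
  drop(sigmoidStable(linearForward(msg, params$winf, params$binf)))
}

#' Gated message aggregation
#'
#' Per receiving node i, sums the gated messages over all incident directed
#' edges: \code{m_i = sum_{j != i} e_ij m_ij}.  A node with no incident
#' edges (a single-atom molecule) receives the zero vector.
#'
#' @param messages E x m matrix of edge messages.
#' @param weights length-E vector of edge gates.
#' @param edges E x 2 integer matrix; column 1 is the receiver.
#' @param n number of nodes.
#' @return n x m matrix of aggregated messages.
#' @export
aggregateMessages <- function(messages, weights, edges, n) {
  if (is.null(dim(messages))) messages <- matrix(messages, ncol = 1L)
  if (nrow(messages) != nrow(edges) || length(weights) != nrow(edges))
    stop("one message and one weight required per directed edge",
         call. = FALSE)
  if (nrow(edges) && (min(edges) < 1L || max(edges) > n))
    stop("edge index out of range", call. = FALSE)
  segmentSum(messages * weights, edges[, 1L], n)
}

## per-node normalization constant for the coordinate update: the reciprocal
## of the number of summands (receiver degree = N-1 within a molecule), or of
## the node count when cMode = "n"
coordNormalization <- function(edges, n, cMode = c("nminus1", "n")) {
  cMode <- match.arg(cMode)
  deg <- tabulate(edges[, 1L], nbins = n)
  denom <- if (cMode == "nminus1") pmax(deg, 1L) else deg + 1L
  1 / denom
}

## phi_x: hidden SiLU layer then bias-free linear scalar output
coordGate <- function(messages, params) {
  drop(silu(linearForward(messages, params$Wx1, params$bx1)) %*% params$wx2)
}

#' Equivariant coordinate update
#'
#' Moves each atom along the (ungated) pairwise difference vectors:
#' \code{x_i' = x_i + C_i sum_{j != i} (x_i - x_j) phi_x(m_ij)}, with
#' \code{C_i} the reciprocal of the summand count (N-1 within a molecule;
#' configurable to 1/N).  Single-atom molecules are returned unchanged.
#' The update commutes with every rigid motion of the inputs.
#'
#' @param x n x 3 coordinate matrix.
#' @param messages E x m matrix of edge messages.
#' @param edges E x 2 integer matrix (receiver first).
#' @param params a \code{\link{layerParams}} list.
#' @param cMode \code{"nminus1"} (default) or \code{"n"} normalization.
#' @return Updated n x 3 coordinate matrix.
#' @export
coordUpdate <- function(x, messages, edges, params, cMode = "nminus1") {
  n <- nrow(x)
  if (!nrow(edges)) return(x)
  s <- coordGate(messages, params)
  diff <- x[edges[, 1L], , drop = FALSE] - x[edges[, 2L], , drop = FALSE]
  C <- coordNormalization(edges, n, cMode)
  x + C * segmentSum(diff * s, edges[, 1L], n)
}

#' Node feature update
#'
#' Row-wise evaluation of \code{phi_h} on the concatenation (h_i, m_i): a
#' two-layer perceptron with a SiLU hidden activation and linear output.
#'
#' @param h n x f node feature matrix.
#' @param mAgg n x m aggregated message matrix.
#' @param params a \code{\link{layerParams}} list.
#' @return n x f updated feature matrix.
#' @export
nodeUpdate <- function(h, mAgg, params) {
  if (nrow(h) != nrow(mAgg))
    stop("h and aggregated messages disagree on the node count",
         call. = FALSE)
  hin <- cbind(h, mAgg, deparse.level = 0)
  linearForward(silu(linearForward(hin, params$Wh1, params$bh1)),
                params$Wh2, params$bh2)
}

#' One EGCL forward pass
#'
#' Composes \code{\link{edgeMessage}}, \code{\link{edgeWeight}},
#' \code{\link{aggregateMessages}}, \code{\link{coordUpdate}} and
#' \code{\link{nodeUpdate}} over a (possibly batched) graph.  Molecules in a
#' batch never interact because edges never cross molecule boundaries.
#'
#' @param h n x f node features.
#' @param x n x 3 coordinates.
#' @param edges E x 2 integer matrix (receiver first).
#' @param params a \code{\link{layerParams}} list.
#' @param cMode coordinate normalization, see \code{\link{coordUpdate}}.
#' @param updateCoords if \code{FALSE}, skip the coordinate update and return
#'   \code{x} unchanged (used when coordinates are neither transmitted nor
#'   updated).
#' @param cache if \code{TRUE}, also return the intermediate activations
#'   needed for backpropagation.
#' @return list with \code{h} (n x f), \code{x} (n x 3) and optionally
#'   \code{cache}.
#' @export
egclForward <- function(h, x, edges, params, cMode = "nminus1",
                        updateCoords = TRUE, cache = FALSE) {
  n <- nrow(h)
  iIdx <- edges[, 1L]
  jIdx <- edges[, 2L]
  diff <- x[iIdx, , drop = FALSE] - x[jIdx, , drop = FALSE]
  d2 <- rowSums(diff * diff)
  ein <- cbind(h[iIdx, , drop = FALSE], h[jIdx, , drop = FALSE], d2,
               deparse.level = 0)
  z1 <- linearForward(ein, params$We1, params$be1)
  sg1 <- sigmoidStable(z1)
  a1 <- z1 * sg1
  z2 <- linearForward(a1, params$We2, params$be2)
  sg2 <- sigmoidStable(z2)
  msg <- z2 * sg2
  zg <- linearForward(msg, params$winf, params$binf)
  g <- drop(sigmoidStable(zg))
  mAgg <- segmentSum(msg * g, iIdx, n)
  if (updateCoords && nrow(edges)) {
    u1 <- linearForward(msg, params$Wx1, params$bx1)
    sgu <- sigmoidStable(u1)
    ax <- u1 * sgu
    s <- drop(ax %*% params$wx2)
    C <- coordNormalization(edges, n, cMode)
    xNew <- x + C * segmentSum(diff * s, iIdx, n)
  } else {
    u1 <- sgu <- ax <- s <- C <- NULL
    xNew <- x
  }
  hin <- cbind(h, mAgg, deparse.level = 0)
  v1 <- linearForward(hin, params$Wh1, params$bh1)
  sgv <- sigmoidStable(v1)
  ah <- v1 * sgv
  hNew <- linearForward(ah, params$Wh2, params$bh2)
  out <- list(h = hNew, x = xNew)
  if (cache)
    out$cache <- list(hIn = h, xIn = x, iIdx = iIdx, jIdx = jIdx,
                      diff = diff, ein = ein, z1 = z1, sg1 = sg1, a1 = a1,
                      z2 = z2, sg2 = sg2, msg = msg, g = g, mAgg = mAgg,
                      u1 = u1, sgu = sgu, ax = ax, s = s, C = C,
                      hin = hin, v1 = v1, sgv = sgv, ah = ah,
                      updateCoords = updateCoords && nrow(edges) > 0L)
  out
}
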