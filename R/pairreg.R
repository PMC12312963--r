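## The PairReg mechanism: a concatenation residual on node features, midpoint
## averaging of pre-/post-layer coordinates, and a final-loss penalty on the
## total coordinate displacement.

#' PairReg mode: which parts of the mechanism are active
#'
#' Encodes the ablation axes of the mechanism.  \code{nodeResidual} switches
#' the concatenation residual on node features; \code{coordMode} selects how
#' coordinates move through a layer:
#' \describe{
#'   \item{\code{"average"}}{equivariant coordinate update followed by
#'     midpoint averaging with the layer input, and the coordinate-regression
#'     penalty is active — the PairReg coordinate path.}
#'   \item{\code{"update"}}{the plain EGCL coordinate update with no
#'     averaging and no penalty (the unmodified baseline network).}
#'   \item{\code{"frozen"}}{coordinates are neither transmitted nor updated:
#'     every layer sees the input geometry.}
#' }
#' The presets map to the ablation settings \code{"full"} = residual +
#' average, \code{"coord"} = average only, \code{"node"} = residual + frozen,
#' and \code{"plain"} = neither (baseline EGCL stack).
#'
#' @param preset one of \code{"full"}, \code{"coord"}, \code{"node"},
#'   \code{"plain"}; supplies defaults for the other arguments.
#' @param nodeResidual logical, apply the concatenation residual.
#' @param coordMode \code{"average"}, \code{"update"} or \code{"frozen"}.
#' @param lambda non-negative weight of the coordinate-regression penalty in
#'   the training loss; only meaningful when \code{coordMode = "average"}
#'   (default 0.1 for the presets with an active coordinate path, else 0).
#' @return A list of class \code{PairRegMode}.
#' @examples
#' pairRegMode("full")
#' pairRegMode("node")$coordMode  # "frozen"
#' @export
pairRegMode <- function(preset = c("full", "coord", "node", "plain"),
                        nodeResidual = NULL, coordMode = NULL,
                        lambda = NULL) {
  preset <- match.arg(preset)
  defaults <- switch(preset,
    full  = list(nodeResidual = TRUE,  coordMode = "average", lambda = 0.1),
    coord = list(nodeResidual = FALSE, coordMode = "average", lambda = 0.1),
    node  = list(nodeResidual = TRUE,  coordMode = "frozen",  lambda = 0),
    plain = list(nodeResidual = FALSE, coordMode = "update",  lambda = 0))
  mode <- list(
    preset = preset,
    nodeResidual = if (is.null(nodeResidual)) defaults$nodeResidual
                   else isTRUE(nodeResidual),
    coordMode = if (is.null(coordMode)) defaults$coordMode
                else match.arg(coordMode, c("average", "update", "frozen")),
    lambda = if (is.null(lambda)) defaults$lambda else as.numeric(lambda))
  if (mode$lambda < 0)
    stop("lambda must be non-negative", call. = FALSE)
  class(mode) <- "PairRegMode"
  mode
}

#' @export
print.PairRegMode <- function(x, ...) {
  cat("PairRegMode <", x$preset, ">: nodeResidual=", x$nodeResidual,
      ", coordMode=", x$coordMode, ", lambda=", x$lambda, "\n", sep = "")
  invisible(x)
}

#' Concatenation residual on node features
#'
#' Projects the concatenation of a layer's input and output features back to
#' the feature width through the single linear map \code{phi_r}:
#' \code{h <- phi_r([h_prev, h_new])}.  Row-local: row i of the output
#' depends only on rows i of the two inputs.
#'
#' @param hPrev,hNew n x f matrices of equal shape.
#' @param params a \code{\link{layerParams}} list (uses \code{Wr}, \code{br}).
#' @return n x f matrix.
#' @export
concatResidual <- function(hPrev, hNew, params) {
  if (!identical(dim(hPrev), dim(hNew)))
    stop("hPrev and hNew must have equal shapes", call. = FALSE)
  linearForward(cbind(hPrev, hNew, deparse.level = 0), params$Wr, params$br)
}

#' Midpoint averaging of coordinates
#'
#' The elementwise midpoint \code{(x_prev + x_new) / 2}.  As an affine
#' combination with weights summing to 1 it commutes with every rigid
#' motion applied to both arguments.
#'
#' @param xPrev,xNew n x 3 matrices of equal shape.
#' @return n x 3 matrix of midpoints.
#' @export
averageCoords <- function(xPrev, xNew) {
  if (!identical(dim(xPrev), dim(xNew)))
    stop("coordinate matrices must have equal shapes", call. = FALSE)
  (xPrev + xNew) / 2
}

#' Coordinate-regression penalty
#'
#' The mean (over atoms, then over molecules) of the per-atom Euclidean
#' displacement between the final and the initial coordinates:
#' \code{L_reg = mean_mol mean_atom ||x_final,i - x_0,i||}.  Invariant under
#' a common rigid motion of both arguments; zero iff the coordinates agree.
#'
#' @param xFinal,x0 n x 3 matrices of equal shape.
#' @param membership integer vector mapping nodes to molecules (default: one
#'   molecule).
#' @param squared if \code{TRUE} use squared displacements (mean-squared
#'   variant) instead of the Euclidean norm.
#' @return Non-negative scalar.
#' @examples
#' coordRegularizer(rbind(c(3, 4, 0)), rbind(c(0, 0, 0)))  # 5
#' @export
coordRegularizer <- function(xFinal, x0, membership = NULL, squared = FALSE) {
  if (!identical(dim(xFinal), dim(x0)))
    stop("coordinate matrices must have equal shapes", call. = FALSE)
  if (is.null(membership)) membership <- rep(1L, nrow(xFinal))
  d <- xFinal - x0
  nrm <- rowSums(d * d)
  if (!squared) nrm <- sqrt(nrm)
  perMol <- drop(segmentSum(nrm, membership, max(membership))) /
    tabulate(membership, nbins = max(membership))
  mean(perMol)
}

#' One PairReg layer
#'
#' Runs \code{\link{egclForward}} and then applies the mechanism selected by
#' \code{mode}: the concatenation residual on features when
#' \code{nodeResidual} is on, and the coordinate handling given by
#' \code{coordMode} (midpoint averaging, plain update, or frozen
#' coordinates).  All equivariance contracts of the underlying layer are
#' preserved.
#'
#' @param h n x f node features entering the layer.
#' @param x n x 3 coordinates entering the layer.
#' @param edges E x 2 integer matrix (receiver first).
#' @param params a \code{\link{layerParams}} list.
#' @param mode a \code{\link{pairRegMode}}.
#' @param cMode coordinate normalization, see \code{\link{coordUpdate}}.
#' @param cache if \code{TRUE} keep intermediates for backpropagation.
#' @return list with \code{h}, \code{x}, optionally \code{cache}.
#' @export
pairRegLayer <- function(h, x, edges, params, mode, cMode = "nminus1",
                         cache = FALSE) {
  fw <- egclForward(h, x, edges, params, cMode = cMode,
                    updateCoords = mode$coordMode != "frozen",
                    cache = cache)
  hOut <- if (mode$nodeResidual) concatResidual(h, fw$h, params) else fw$h
  xOut <- switch(mode$coordMode,
                 average = averageCoords(x, fw$x),
                 update = fw$x,
                 frozen = x)
  out <- list(h = hOut, x = xOut)
  if (cache) {
    fw$cache$hMid <- fw$h
    out$cache <- fw$cache
  }
  out
}
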