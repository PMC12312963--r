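#' @import methods
NULL

#' MolecularGraph: one molecule as a fully connected geometric graph
#'
#' Holds the atom types, 3D coordinates, featurized node attributes, the full
#' directed edge set over the atoms, and an optional scalar target property.
#' Graphs are fully connected by construction: every ordered pair (i, j) with
#' i != j is an edge, matching message passing that sums over all j != i.
#'
#' @slot atomTypes character vector of categorical atom identities (length N).
#' @slot coords N x 3 double matrix of positions.
#' @slot nodeFeatures N x f double matrix (one-hot block plus scaled atomic
#'   number, see \code{\link{oneHotFeatures}}).
#' @slot edges E x 2 integer matrix of directed edges; column 1 is the
#'   receiving node i, column 2 the neighbor j.
#' @slot target length-1 numeric, the molecular property (may be \code{NA}).
#' @seealso \code{\link{buildGraph}}, \code{\link{batchGraphs}}
#' @export
setClass("MolecularGraph",
  representation(
    atomTypes = "character",
    coords = "matrix",
    nodeFeatures = "matrix",
    edges = "matrix",
    target = "numeric"
  )
)

setValidity("MolecularGraph", function(object) {
  n <- length(object@atomTypes)
  msgs <- character(0)
  if (n < 1L) msgs <- c(msgs, "graph must contain at least one atom")
  if (!is.numeric(object@coords) || ncol(object@coords) != 3L ||
      nrow(object@coords) != n)
    msgs <- c(msgs, "coords must be an N x 3 numeric matrix")
  if (nrow(object@nodeFeatures) != n)
    msgs <- c(msgs, "nodeFeatures row count must equal the atom count")
  if (length(object@target) != 1L)
    msgs <- c(msgs, "target must be a length-1 numeric")
  if (nrow(object@edges) != n * (n - 1L))
    msgs <- c(msgs, "edge set must contain all N(N-1) ordered pairs")
  if (nrow(object@edges) > 0L) {
    if (any(object@edges[, 1L] == object@edges[, 2L]))
      msgs <- c(msgs, "self-edges are not allowed")
    if (any(object@edges < 1L) || any(object@edges > n))
      msgs <- c(msgs, "edge indices out of range")
    key <- (object@edges[, 1L] - 1L) * n + object@edges[, 2L]
    if (anyDuplicated(key))
      msgs <- c(msgs, "duplicate directed edges")
  }
  if (n >= 2L && any(stats::dist(object@coords) == 0))
    msgs <- c(msgs, "degenerate geometry: two atoms share a position")
  if (length(msgs)) msgs else TRUE
})

#' GraphBatch: several molecules stacked into one disjoint graph
#'
#' Node rows of the member molecules are concatenated; edge indices are
#' offset so that edges never cross molecule boundaries. \code{membership}
#' maps each node to its molecule (1-based), and \code{targets} carries one
#' scalar per molecule.
#'
#' @slot atomTypes character, concatenated atom identities.
#' @slot nodeFeatures stacked N x f matrix.
#' @slot coords stacked N x 3 matrix.
#' @slot edges E x 2 integer matrix with offset-shifted indices.
#' @slot membership integer vector, node -> molecule index.
#' @slot targets numeric, one value per molecule.
#' @seealso \code{\link{batchGraphs}}, \code{\link{unbatchGraphs}}
#' @export
setClass("GraphBatch",
  representation(
    atomTypes = "character",
    nodeFeatures = "matrix",
    coords = "matrix",
    edges = "matrix",
    membership = "integer",
    targets = "numeric"
  )
)

setValidity("GraphBatch", function(object) {
  n <- length(object@membership)
  msgs <- character(0)
  if (nrow(object@coords) != n || nrow(object@nodeFeatures) != n ||
      length(object@atomTypes) != n)
    msgs <- c(msgs, "node-level slots disagree on the node count")
  if (n > 0L && (min(object@membership) < 1L ||
                 max(object@membership) != length(object@targets)))
    msgs <- c(msgs, "membership must index 1..length(targets)")
  if (nrow(object@edges) > 0L) {
    same <- object@membership[object@edges[, 1L]] ==
            object@membership[object@edges[, 2L]]
    if (!all(same)) msgs <- c(msgs, "edges must not cross molecule boundaries")
  }
  if (length(msgs)) msgs else TRUE
})

#' DiagnosticsReport: oversmoothing and symmetry diagnostics of a model
#'
#' @slot energies numeric vector of layerwise Dirichlet energies (entry 1 is
#'   the embedded input, entry l+1 the output of layer l).
#' @slot invarianceDeviation max deviation of the scalar prediction under
#'   random rigid motions.
#' @slot equivarianceDeviation max deviation of output coordinates from the
#'   group-transformed originals.
#' @slot permutationDeviation max deviation under random atom relabelings.
#' @slot fingerprint character, a short description of the generating
#'   configuration.
#' @export
setClass("DiagnosticsReport",
  representation(
    energies = "numeric",
    invarianceDeviation = "numeric",
    equivarianceDeviation = "numeric",
    permutationDeviation = "numeric",
    fingerprint = "character"
  )
)

setValidity("DiagnosticsReport", function(object) {
  vals <- c(object@energies, object@invarianceDeviation,
            object@equivarianceDeviation, object@permutationDeviation)
  if (!all(is.finite(vals)) || any(vals < 0))
    return("all diagnostic entries must be finite and non-negative")
  TRUE
})
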