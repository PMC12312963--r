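## Data model: molecules as fully connected geometric graphs.

## atomic numbers of the elements appearing in small-organic benchmarks;
## unknown symbols fall back to their position in the vocabulary
.ATOMIC_NUMBERS <- c(H = 1, C = 6, N = 7, O = 8, F = 9,
                     P = 15, S = 16, Cl = 17, Br = 35, I = 53)

#' The element vocabulary of small-organic benchmark molecules
#'
#' @return \code{c("H", "C", "N", "O", "F")}, the elements occurring in the
#'   QM9 benchmark, in conventional order.
#' @export
qm9Vocabulary <- function() c("H", "C", "N", "O", "F")

## all ordered pairs (i, j), i != j, receiver first
fullEdgeSet <- function(n) {
  if (n < 2L)
    return(matrix(integer(0), 0L, 2L, dimnames = list(NULL, c("i", "j"))))
  i <- rep(seq_len(n), each = n - 1L)
  j <- unlist(lapply(seq_len(n), function(k) seq_len(n)[-k]), use.names = FALSE)
  m <- cbind(i = as.integer(i), j = as.integer(j))
  m
}

#' One-hot atom-type featurization with an atomic-number channel
#'
#' Builds the node feature matrix: a one-hot block over the type vocabulary
#' followed by one real column carrying the atomic number scaled by
#' \code{zScale}.  Output width is \code{length(vocabulary) + 1}.
#'
#' @param atomTypes character vector of atom identities.
#' @param vocabulary ordered character vector of admissible types.
#' @param zScale multiplier applied to the atomic-number column; the default
#'   1/9 maps the heaviest QM9 element (F, Z = 9) to 1 so inputs stay O(1).
#' @param atomicNumbers optional named numeric vector overriding the built-in
#'   element lookup; types absent from both fall back to their vocabulary
#'   position.
#' @return N x (|vocabulary| + 1) double matrix; each one-hot block row sums
#'   to exactly 1.
#' @examples
#' oneHotFeatures(c("H", "C", "H"), qm9Vocabulary())
#' @export
oneHotFeatures <- function(atomTypes, vocabulary, zScale = 1 / 9,
                           atomicNumbers = NULL) {
  idx <- match(atomTypes, vocabulary)
  if (anyNA(idx))
    stop("atom type(s) not in vocabulary: ",
         paste(unique(atomTypes[is.na(idx)]), collapse = ", "), call. = FALSE)
  n <- length(atomTypes)
  onehot <- matrix(0, n, length(vocabulary))
  onehot[cbind(seq_len(n), idx)] <- 1
  zTable <- .ATOMIC_NUMBERS
  if (!is.null(atomicNumbers)) zTable[names(atomicNumbers)] <- atomicNumbers
  z <- unname(zTable[vocabulary])
  z[is.na(z)] <- seq_along(vocabulary)[is.na(z)]
  out <- cbind(onehot, z[idx] * zScale, deparse.level = 0)
  dimnames(out) <- NULL
  out
}

#' Build a fully connected molecular graph
#'
#' Constructs a \code{\link{MolecularGraph}} with all N(N-1) directed edges
#' and node features from \code{\link{oneHotFeatures}}.
#'
#' @param atomTypes character vector of atom identities (length N >= 1).
#' @param coords N x 3 numeric matrix of finite positions; no two atoms may
#'   coincide.
#' @param target optional scalar molecular property (default \code{NA}).
#' @param vocabulary type vocabulary for featurization (default
#'   \code{\link{qm9Vocabulary}()}).
#' @param zScale,atomicNumbers passed to \code{\link{oneHotFeatures}}.
#' @return A validated \code{MolecularGraph}.
#' @examples
#' g <- buildGraph(c("O", "H", "H"),
#'                 rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0)))
#' nAtoms(g)
#' nrow(edgeIndex(g))  # 6 directed edges
#' @export
buildGraph <- function(atomTypes, coords, target = NA_real_,
                       vocabulary = qm9Vocabulary(), zScale = 1 / 9,
                       atomicNumbers = NULL) {
  if (length(atomTypes) == 0L)
    stop("empty input: a molecule needs at least one atom", call. = FALSE)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3L || nrow(coords) != length(atomTypes))
    stop("coords must be an N x 3 matrix matching atomTypes", call. = FALSE)
  if (!all(is.finite(coords)))
    stop("coords must be finite", call. = FALSE)
  if (nrow(coords) >= 2L && any(stats::dist(coords) == 0))
    stop("degenerate geometry: two atoms at identical positions",
         call. = FALSE)
  feats <- oneHotFeatures(atomTypes, vocabulary, zScale, atomicNumbers)
  new("MolecularGraph",
      atomTypes = as.character(atomTypes),
      coords = coords,
      nodeFeatures = feats,
      edges = fullEdgeSet(nrow(coords)),
      target = as.numeric(target)[1L])
}

#' Stack molecules into a batch
#'
#' Concatenates node-level arrays and offsets the edge indices of molecule k
#' by the cumulative node count of molecules 1..k-1, so molecules never
#' interact.  \code{unbatchGraphs} is its exact inverse.
#'
#' @param graphs non-empty list of \code{MolecularGraph} objects sharing one
#'   feature width.
#' @return A \code{\link{GraphBatch}}.
#' @examples
#' g1 <- buildGraph(c("H", "H"), rbind(c(0, 0, 0), c(1, 0, 0)))
#' g2 <- buildGraph(c("C", "H", "H"), diag(3))
#' b <- batchGraphs(list(g1, g2))
#' membership(b)
#' @export
batchGraphs <- function(graphs) {
  if (!length(graphs)) stop("cannot batch an empty list", call. = FALSE)
  if (!all(vapply(graphs, is, logical(1), class2 = "MolecularGraph")))
    stop("all elements must be MolecularGraph objects", call. = FALSE)
  widths <- vapply(graphs, function(g) ncol(g@nodeFeatures), integer(1))
  if (length(unique(widths)) != 1L)
    stop("mixed feature widths: ", paste(unique(widths), collapse = ", "),
         call. = FALSE)
  ns <- vapply(graphs, nAtoms, integer(1))
  offsets <- cumsum(c(0L, ns[-length(ns)]))
  edges <- do.call(rbind, lapply(seq_along(graphs), function(k) {
    e <- graphs[[k]]@edges
    if (nrow(e)) e + offsets[k] else e
  }))
  new("GraphBatch",
      atomTypes = unlist(lapply(graphs, atomTypes), use.names = FALSE),
      nodeFeatures = do.call(rbind, lapply(graphs, nodeFeatures)),
      coords = do.call(rbind, lapply(graphs, coords)),
      edges = edges,
      membership = rep(seq_along(graphs), times = ns),
      targets = vapply(graphs, function(g) g@target, numeric(1)))
}

#' @rdname batchGraphs
#' @param batch a \code{GraphBatch}.
#' @return \code{unbatchGraphs}: the list of member \code{MolecularGraph}s.
#' @export
unbatchGraphs <- function(batch) {
  stopifnot(is(batch, "GraphBatch"))
  m <- batch@membership
  lapply(seq_len(nMolecules(batch)), function(k) {
    rows <- which(m == k)
    new("MolecularGraph",
        atomTypes = batch@atomTypes[rows],
        coords = batch@coords[rows, , drop = FALSE],
        nodeFeatures = batch@nodeFeatures[rows, , drop = FALSE],
        edges = fullEdgeSet(length(rows)),
        target = batch@targets[k])
  })
}

#' Coerce a single molecule to a one-molecule batch
#'
#' @param x a \code{MolecularGraph} or \code{GraphBatch}.
#' @return A \code{GraphBatch}.
#' @export
asBatch <- function(x) {
  if (is(x, "GraphBatch")) return(x)
  if (is(x, "MolecularGraph")) return(batchGraphs(list(x)))
  stop("cannot coerce object of class ", class(x)[1L], " to GraphBatch",
       call. = FALSE)
}

#' Apply a rigid motion or atom permutation to a molecule
#'
#' Utilities for symmetry testing: \code{transformGraph} moves the
#' coordinates by a rigid motion (features and types untouched);
#' \code{permuteGraph} relabels the atoms by a permutation.
#'
#' @param graph a \code{MolecularGraph}.
#' @param motion list with \code{R}, \code{t} (see
#'   \code{\link{randomRigidMotion}}).
#' @return A new \code{MolecularGraph}.
#' @export
transformGraph <- function(graph, motion) {
  new("MolecularGraph",
      atomTypes = graph@atomTypes,
      coords = applyRigidMotion(graph@coords, motion),
      nodeFeatures = graph@nodeFeatures,
      edges = graph@edges,
      target = graph@target)
}

#' @rdname transformGraph
#' @param perm integer permutation of \code{seq_len(nAtoms(graph))}.
#' @export
permuteGraph <- function(graph, perm) {
  stopifnot(length(perm) == nAtoms(graph), !anyDuplicated(perm))
  new("MolecularGraph",
      atomTypes = graph@atomTypes[perm],
      coords = graph@coords[perm, , drop = FALSE],
      nodeFeatures = graph@nodeFeatures[perm, , drop = FALSE],
      edges = fullEdgeSet(nAtoms(graph)),
      target = graph@target)
}
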