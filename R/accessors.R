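#' @rdname MolecularGraph-class
#' @aliases atomTypes,MolecularGraph-method
setMethod("atomTypes", "MolecularGraph", function(x) x@atomTypes)

#' @rdname MolecularGraph-class
setMethod("coords", "MolecularGraph", function(x) x@coords)

#' @rdname MolecularGraph-class
setMethod("nodeFeatures", "MolecularGraph", function(x) x@nodeFeatures)

#' @rdname MolecularGraph-class
setMethod("edgeIndex", "MolecularGraph", function(x) x@edges)

#' @rdname MolecularGraph-class
setMethod("nAtoms", "MolecularGraph", function(x) length(x@atomTypes))

#' @rdname MolecularGraph-class
#' @export
setGeneric("targetValue", function(x) standardGeneric("targetValue"))

#' @rdname MolecularGraph-class
setMethod("targetValue", "MolecularGraph", function(x) x@target)

#' @rdname GraphBatch-class
setMethod("atomTypes", "GraphBatch", function(x) x@atomTypes)

#' @rdname GraphBatch-class
setMethod("coords", "GraphBatch", function(x) x@coords)

#' @rdname GraphBatch-class
setMethod("nodeFeatures", "GraphBatch", function(x) x@nodeFeatures)

#' @rdname GraphBatch-class
setMethod("edgeIndex", "GraphBatch", function(x) x@edges)

#' @rdname GraphBatch-class
setMethod("nAtoms", "GraphBatch", function(x) length(x@membership))

#' @rdname GraphBatch-class
setMethod("membership", "GraphBatch", function(x) x@membership)

#' @rdname GraphBatch-class
setMethod("targets", "GraphBatch", function(x) x@targets)

#' @rdname GraphBatch-class
setMethod("nMolecules", "GraphBatch", function(x) length(x@targets))

setMethod("show", "MolecularGraph", function(object) {
  cat("MolecularGraph:", nAtoms(object), "atoms,",
      nrow(object@edges), "directed edges\n")
  cat("  types:", paste(object@atomTypes, collapse = " "), "\n")
  cat("  feature width:", ncol(object@nodeFeatures),
      " target:", format(object@target), "\n")
  invisible(object)
})

setMethod("show", "GraphBatch", function(object) {
  cat("GraphBatch:", nMolecules(object), "molecules,",
      nAtoms(object), "atoms,", nrow(object@edges), "directed edges\n")
  invisible(object)
})

setMethod("show", "DiagnosticsReport", function(object) {
  cat("DiagnosticsReport (", object@fingerprint, ")\n", sep = "")
  cat("  layerwise Dirichlet energies:\n")
  prof <- object@energies
  labels <- c("input", paste0("layer ", seq_len(length(prof) - 1L)))
  for (k in seq_along(prof))
    cat(sprintf("    %-8s %.6g\n", labels[k], prof[k]))
  cat(sprintf("  invariance deviation:    %.3g\n",
              object@invarianceDeviation))
  cat(sprintf("  equivariance deviation:  %.3g\n",
              object@equivarianceDeviation))
  cat(sprintf("  permutation deviation:   %.3g\n",
              object@permutationDeviation))
  invisible(object)
})
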