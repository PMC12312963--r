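#' @rdname MolecularGraph-class
#' @param x,object a \code{MolecularGraph} or \code{GraphBatch}.
#' @export
setGeneric("atomTypes", function(x) standardGeneric("atomTypes"))

#' @rdname MolecularGraph-class
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @rdname MolecularGraph-class
#' @export
setGeneric("nodeFeatures", function(x) standardGeneric("nodeFeatures"))

#' @rdname MolecularGraph-class
#' @export
setGeneric("edgeIndex", function(x) standardGeneric("edgeIndex"))

#' @rdname MolecularGraph-class
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname GraphBatch-class
#' @param x a \code{GraphBatch}.
#' @export
setGeneric("membership", function(x) standardGeneric("membership"))

#' @rdname GraphBatch-class
#' @export
setGeneric("targets", function(x) standardGeneric("targets"))

#' @rdname GraphBatch-class
#' @export
setGeneric("nMolecules", function(x) standardGeneric("nMolecules"))
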