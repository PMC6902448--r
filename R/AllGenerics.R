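#' @name tRNAcif-generics
#' @title Accessor generics
#' @description Accessor generics for the core S4 classes.
#' @param x an object.
#' @param ... further arguments for methods.
#' @keywords internal
NULL

#' @rdname tRNAcif-generics
#' @export
setGeneric("sprinzlCoordinates", function(x) standardGeneric("sprinzlCoordinates"))

#' @rdname tRNAcif-generics
#' @export
setGeneric("geneData", function(x) standardGeneric("geneData"))

#' @rdname tRNAcif-generics
#' @export
setGeneric("genomeIds", function(x) standardGeneric("genomeIds"))

#' @rdname tRNAcif-generics
#' @export
setGeneric("nGenes", function(x) standardGeneric("nGenes"))

#' @rdname tRNAcif-generics
#' @export
setGeneric("cladeLabels", function(x) standardGeneric("cladeLabels"))

#' @rdname tRNAcif-generics
#' @export
setGeneric("cladeAssignments", function(x) standardGeneric("cladeAssignments"))

#' @rdname tRNAcif-generics
#' @export
setGeneric("cladeSets", function(x) standardGeneric("cladeSets"))

#' @rdname tRNAcif-generics
#' @export
setGeneric("excludedClades", function(x) standardGeneric("excludedClades"))

#' @rdname tRNAcif-generics
#' @export
setGeneric("heights", function(x) standardGeneric("heights"))

#' @rdname tRNAcif-generics
#' @export
setGeneric("featureInfo", function(x) standardGeneric("featureInfo"))

#' @rdname tRNAcif-generics
#' @export
setGeneric("featureSupport", function(x) standardGeneric("featureSupport"))

#' @rdname tRNAcif-generics
#' @export
setGeneric("logoBackground", function(x) standardGeneric("logoBackground"))

#' @rdname complementSummary-methods
#' @export
setGeneric("complementSummary", function(x, ...) standardGeneric("complementSummary"))
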