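#' Accessor generics
#'
#' Identifier registries, layer tags and result components of the package's
#' S4 containers.
#'
#' @param x an object of one of the package's classes.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("lncrnaIds", function(x) standardGeneric("lncrnaIds"))

#' @rdname accessors
#' @export
setGeneric("diseaseIds", function(x) standardGeneric("diseaseIds"))

#' @rdname accessors
#' @export
setGeneric("entityIds", function(x) standardGeneric("entityIds"))

#' @rdname accessors
#' @export
setGeneric("simKind", function(x) standardGeneric("simKind"))

#' @rdname accessors
#' @export
setGeneric("scoreStage", function(x) standardGeneric("scoreStage"))

#' @rdname accessors
#' @export
setGeneric("auc", function(x) standardGeneric("auc"))

#' @rdname accessors
#' @export
setGeneric("rocPoints", function(x) standardGeneric("rocPoints"))

#' @rdname accessors
#' @export
setGeneric("perFoldRanks", function(x) standardGeneric("perFoldRanks"))

#' @rdname accessors
#' @export
setGeneric("ontologyEdges", function(x) standardGeneric("ontologyEdges"))
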