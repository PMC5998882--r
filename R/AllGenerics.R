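#' @rdname ProteinNetwork-class
#' @param x a `ProteinNetwork`.
#' @export
setGeneric("proteins", function(x) standardGeneric("proteins"))

#' @rdname ProteinNetwork-class
#' @export
setGeneric("numProteins", function(x) standardGeneric("numProteins"))

#' @rdname ProteinNetwork-class
#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))

#' @rdname ProteinNetwork-class
#' @export
setGeneric("edgeList", function(x) standardGeneric("edgeList"))

#' @rdname ProteinNetwork-class
#' @export
setGeneric("degrees", function(x) standardGeneric("degrees"))

#' @rdname ProteinNetwork-class
#' @param protein a single protein ID.
#' @export
setGeneric("neighborsOf", function(x, protein) standardGeneric("neighborsOf"))

#' Ordered protein IDs of a ranking-like object
#'
#' Returns the protein IDs of a ranking, best first. Works on character
#' vectors (returned as is), ranking data frames with a `protein` column,
#' and [FPEResult-class] objects.
#'
#' @param x ranking-like object.
#' @return character vector of protein IDs, best first.
#' @export
setGeneric("rankedProteins", function(x) standardGeneric("rankedProteins"))

#' @rdname FPEResult-class
#' @param x an `FPEResult`.
#' @export
setGeneric("gbestMembers", function(x) standardGeneric("gbestMembers"))

#' @rdname FPEResult-class
#' @export
setGeneric("fitnessHistory", function(x) standardGeneric("fitnessHistory"))

#' @rdname FPEResult-class
#' @export
setGeneric("gscRanking", function(x) standardGeneric("gscRanking"))
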