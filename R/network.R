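#' @rdname ProteinNetwork-class
#' @export
setMethod("proteins", "ProteinNetwork", function(x) x@nodes)

#' @rdname ProteinNetwork-class
#' @export
setMethod("numProteins", "ProteinNetwork", function(x) length(x@nodes))

#' @rdname ProteinNetwork-class
#' @export
setMethod("numEdges", "ProteinNetwork", function(x) nrow(x@edges))

#' @rdname ProteinNetwork-class
#' @export
setMethod("edgeList", "ProteinNetwork", function(x) {
  em <- x@edges
  dimnames(em) <- list(NULL, c("proteinA", "proteinB"))
  em
})

#' @rdname ProteinNetwork-class
#' @export
setMethod("degrees", "ProteinNetwork", function(x) {
  lengths(x@adjacency)
})

#' @rdname ProteinNetwork-class
#' @export
setMethod("neighborsOf", "ProteinNetwork", function(x, protein) {
  if (!protein %in% x@nodes) stop("unknown protein: ", protein)
  x@adjacency[[protein]]
})

setMethod("show", "ProteinNetwork", function(object) {
  cat(
    "ProteinNetwork with", length(object@nodes), "proteins and",
    nrow(object@edges), "interactions\n"
  )
})

# integer-index adjacency, the workhorse representation for the
# neighborhood-overlap computations (ECC, LAC)
indexAdjacency <- function(net) {
  lapply(net@adjacency, match, table = net@nodes)
}

# dense symmetric 0/1 adjacency matrix; the networks this package targets
# (thousands of nodes) are comfortably dense-representable
adjacencyMatrix <- function(net) {
  n <- numProteins(net)
  A <- matrix(0, n, n, dimnames = list(net@nodes, net@nodes))
  em <- net@edges
  if (nrow(em)) {
    i <- match(em[, 1L], net@nodes)
    j <- match(em[, 2L], net@nodes)
    A[cbind(i, j)] <- 1
    A[cbind(j, i)] <- 1
  }
  A
}

asIgraph <- function(net) {
  el <- as.data.frame(net@edges, stringsAsFactors = FALSE)
  if (nrow(el) == 0L) el <- data.frame(from = character(0), to = character(0))
  igraph::graph_from_data_frame(el, directed = FALSE, vertices = net@nodes)
}

# named integer component membership (igraph does the traversal)
componentMembership <- function(net) {
  memb <- igraph::components(asIgraph(net))$membership
  memb[net@nodes]
}
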