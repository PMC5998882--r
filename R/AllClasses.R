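#' Protein-protein interaction network
#'
#' An undirected simple graph over protein identifiers. Edges are stored in
#' canonical orientation (first endpoint lexicographically smaller) with no
#' self-loops and no duplicates; the adjacency list is kept in sync so that
#' `degrees(x)` is always `lengths` of the neighbor sets.
#'
#' @slot nodes character vector of protein IDs (sorted, unique).
#' @slot edges two-column character matrix of canonical edges.
#' @slot adjacency named list (one entry per node) of neighbor ID vectors.
#'
#' @seealso [proteinNetwork()], [readNetwork()]
#' @export
setClass("ProteinNetwork",
  slots = c(nodes = "character", edges = "matrix", adjacency = "list")
)

setValidity("ProteinNetwork", function(object) {
  nodes <- object@nodes
  em <- object@edges
  adj <- object@adjacency
  if (anyDuplicated(nodes)) return("duplicate node IDs")
  if (ncol(em) != 2L && length(em) > 0L)
    return("edge matrix must have two columns")
  if (nrow(em)) {
    if (any(em[, 1L] == em[, 2L])) return("self-loop present")
    if (any(em[, 1L] > em[, 2L])) return("edges not in canonical orientation")
    if (anyDuplicated(edgeKeys(em[, 1L], em[, 2L]))) return("duplicate edges")
    if (!all(c(em) %in% nodes)) return("edge endpoint not in node set")
  }
  if (!identical(names(adj), nodes)) return("adjacency names != nodes")
  if (sum(lengths(adj)) != 2L * nrow(em))
    return("degree sum does not equal twice the edge count")
  TRUE
})

#' Construct a protein interaction network from an edge list
#'
#' Self-loops are dropped, duplicate interactions (in either orientation) are
#' collapsed, and edges are stored in canonical orientation. Isolated nodes
#' can be kept by listing them in `nodes`.
#'
#' @param edges two-column character matrix or data frame of interactions.
#' @param nodes optional additional node IDs (e.g. isolated proteins).
#' @return A [ProteinNetwork-class] object.
#' @examples
#' net <- proteinNetwork(rbind(c("a", "b"), c("b", "a"), c("b", "c")))
#' numEdges(net)
#' degrees(net)
#' @export
proteinNetwork <- function(edges, nodes = character()) {
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (is.null(edges) || length(edges) == 0L) {
    edges <- matrix(character(0), ncol = 2L)
  }
  if (ncol(edges) < 2L) stop("edge list needs two columns")
  a <- as.character(edges[, 1L])
  b <- as.character(edges[, 2L])
  keep <- a != b
  a <- a[keep]
  b <- b[keep]
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  dup <- duplicated(edgeKeys(lo, hi))
  lo <- lo[!dup]
  hi <- hi[!dup]
  ord <- order(lo, hi)
  em <- cbind(lo[ord], hi[ord])
  allNodes <- sort(unique(c(as.character(nodes), c(em))))
  ends <- factor(c(em[, 1L], em[, 2L]), levels = allNodes)
  adj <- lapply(split(c(em[, 2L], em[, 1L]), ends), sort)
  new("ProteinNetwork", nodes = allNodes, edges = em, adjacency = adj)
}

#' Synthetic benchmark dataset
#'
#' Bundles the five inputs of the pipeline (network, expression matrix,
#' subcellular localization records, complex catalog, ground-truth essential
#' set) generated with planted structure by [generateDataset()].
#'
#' @slot network a [ProteinNetwork-class].
#' @slot expression numeric matrix, proteins x time points.
#' @slot subcellular data frame with columns `protein`, `location`.
#' @slot complexes list of character vectors (complex member sets).
#' @slot essentials character vector of ground-truth essential protein IDs.
#' @slot config list of generator settings (including the seed).
#' @export
setClass("SyntheticDataset",
  slots = c(
    network = "ProteinNetwork", expression = "matrix",
    subcellular = "data.frame", complexes = "list",
    essentials = "character", config = "list"
  )
)

setValidity("SyntheticDataset", function(object) {
  nodes <- object@network@nodes
  if (!all(object@essentials %in% nodes))
    return("essential ID not in network")
  if (!all(rownames(object@expression) %in% nodes))
    return("expression row not in network")
  if (ncol(object@expression) < 2L) return("fewer than 2 time points")
  if (!all(c("protein", "location") %in% names(object@subcellular)))
    return("subcellular table needs protein and location columns")
  if (any(lengths(object@complexes) == 0L)) return("empty complex")
  TRUE
})

#' Result of an FPE optimization run
#'
#' Holds the best candidate essential-protein set found (`Gbest`), its GSC
#' ranking, the per-iteration best-fitness trace, and the resolved control
#' parameters.
#'
#' @slot ranking data frame with columns `rank`, `protein`, `score`
#'   (per-protein GSC, descending).
#' @slot gbest character vector, the best size-Q candidate set.
#' @slot fitness total GSC fitness of `gbest`.
#' @slot history numeric vector of best fitness after initialization and
#'   after each iteration (non-decreasing).
#' @slot control the [fpeControl()] list used for the run.
#' @export
setClass("FPEResult",
  slots = c(
    ranking = "data.frame", gbest = "character", fitness = "numeric",
    history = "numeric", control = "list"
  )
)

setValidity("FPEResult", function(object) {
  h <- object@history
  if (length(h) && any(diff(h) < 0)) return("fitness history decreases")
  if (length(h) && abs(object@fitness - h[length(h)]) > 1e-9)
    return("final fitness does not match history")
  if (anyDuplicated(object@gbest)) return("duplicate members in gbest")
  TRUE
})
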