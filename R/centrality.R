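# Topology-only node scores used as comparison baselines, plus the edge
# clustering coefficient that also feeds the PeC biological score.

#' Edge clustering coefficient
#'
#' For every edge (i, j), the number of common neighbors of i and j divided
#' by the smaller of the two endpoint degrees:
#' `ECC(i,j) = |N_i intersect N_j| / min(d_i, d_j)`. ECC measures how deeply
#' an interaction is embedded in triangles and is a strong signal for both
#' complex detection and essentiality.
#'
#' @param net a [ProteinNetwork-class].
#' @return named numeric vector, one entry per edge, named by the canonical
#'   tab-joined endpoint pair; all values in \[0, 1\].
#' @examples
#' tri <- proteinNetwork(rbind(c("a", "b"), c("b", "c"), c("a", "c")))
#' edgeClusteringCoefficient(tri) # 1/2 for every edge
#' @export
edgeClusteringCoefficient <- function(net) {
  if (numProteins(net) == 0L) stop("empty network")
  em <- net@edges
  adjI <- indexAdjacency(net)
  deg <- lengths(adjI)
  i <- match(em[, 1L], net@nodes)
  j <- match(em[, 2L], net@nodes)
  common <- mapply(
    function(a, b) length(intersect(adjI[[a]], adjI[[b]])),
    i, j
  )
  ecc <- as.numeric(common) / pmin(deg[i], deg[j])
  names(ecc) <- edgeKeys(em[, 1L], em[, 2L])
  ecc
}

#' Degree centrality (DC)
#'
#' The classical centrality-lethality baseline: a protein's interaction
#' count.
#'
#' @param net a [ProteinNetwork-class].
#' @return named numeric vector over all network proteins.
#' @export
degreeCentrality <- function(net) {
  out <- as.numeric(degrees(net))
  names(out) <- net@nodes
  out
}

#' Subgraph centrality (SC)
#'
#' `SC(i)` is the i-th diagonal entry of `expm(A)`: the count of closed walks
#' starting and ending at i, weighted by 1/l! per length-l walk. Computed
#' exactly from the symmetric eigendecomposition for networks up to
#' `seriesThreshold` nodes, and by the truncated walk-count series (tolerance
#' 1e-8) beyond that.
#'
#' @param net a [ProteinNetwork-class].
#' @param seriesThreshold node count above which the series fallback is used.
#' @return named numeric vector; every value is >= 1.
#' @export
subgraphCentrality <- function(net, seriesThreshold = 5000L) {
  n <- numProteins(net)
  if (n == 0L) stop("empty network")
  A <- adjacencyMatrix(net)
  if (n <= seriesThreshold) {
    es <- eigen(A, symmetric = TRUE)
    sc <- as.vector((es$vectors^2) %*% exp(es$values))
  } else {
    sc <- rep(1, n)              # l = 0 term
    term <- diag(n)
    for (l in seq_len(300L)) {
      term <- (term %*% A) / l
      sc <- sc + diag(term)
      # odd-walk diagonals vanish on bipartite-ish graphs, so judge
      # convergence on the whole term, not the diagonal increment
      if (l > 2L && max(abs(term)) < 1e-10) break
    }
  }
  names(sc) <- net@nodes
  sc
}

#' Eigenvector centrality (EC)
#'
#' Principal-eigenvector entries of the adjacency matrix, computed per
#' connected component and normalized to unit Euclidean norm with all entries
#' non-negative (the Perron vector, so the sign is deterministic). Isolated
#' nodes score 0.
#'
#' @param net a [ProteinNetwork-class].
#' @return named numeric vector over all network proteins.
#' @export
eigenvectorCentrality <- function(net) {
  if (numProteins(net) == 0L) stop("empty network")
  memb <- componentMembership(net)
  A <- adjacencyMatrix(net)
  out <- setNames(numeric(length(memb)), net@nodes)
  for (comp in unique(memb)) {
    idx <- which(memb == comp)
    if (length(idx) < 2L) next
    es <- eigen(A[idx, idx, drop = FALSE], symmetric = TRUE)
    v <- es$vectors[, 1L]
    if (sum(v) < 0) v <- -v
    v <- pmax(v, 0)              # clamp numerical noise in the Perron vector
    out[idx] <- v / sqrt(sum(v^2))
  }
  out
}

#' Information centrality (IC)
#'
#' The Stephenson-Zelen measure: with `B = D - A + J` (degree matrix minus
#' adjacency plus all-ones) and `C = B^-1` on a connected component of size
#' n, the pairwise information is `I_ij = 1/(C_ii + C_jj - 2 C_ij)` and
#' `IC(i) = n / sum_j 1/I_ij` with the self term `1/I_ii` defined as 0.
#' Disconnected networks are handled per component; isolated nodes score 0.
#'
#' @param net a [ProteinNetwork-class].
#' @return named numeric vector over all network proteins.
#' @export
informationCentrality <- function(net) {
  if (numProteins(net) == 0L) stop("empty network")
  memb <- componentMembership(net)
  A <- adjacencyMatrix(net)
  out <- setNames(numeric(length(memb)), net@nodes)
  for (comp in unique(memb)) {
    idx <- which(memb == comp)
    nc <- length(idx)
    if (nc < 2L) next
    Asub <- A[idx, idx, drop = FALSE]
    B <- diag(rowSums(Asub), nc) - Asub + 1
    C <- solve(B)
    # sum_j (C_ii + C_jj - 2 C_ij) over the component, self term vanishing
    out[idx] <- nc / (nc * diag(C) + sum(diag(C)) - 2 * rowSums(C))
  }
  out
}

#' Local average connectivity (LAC)
#'
#' Mean degree of a protein's neighbors within the subgraph induced by its
#' neighborhood; proteins without neighbors score 0.
#'
#' @param net a [ProteinNetwork-class].
#' @return named numeric vector over all network proteins.
#' @export
localAverageConnectivity <- function(net) {
  adjI <- indexAdjacency(net)
  out <- setNames(numeric(length(adjI)), net@nodes)
  for (i in seq_along(adjI)) {
    nb <- adjI[[i]]
    if (length(nb) == 0L) next
    within <- vapply(
      nb, function(u) length(intersect(adjI[[u]], nb)), integer(1)
    )
    out[i] <- sum(within) / length(nb)
  }
  out
}

#' Neighborhood centrality (NC)
#'
#' Sum of the edge clustering coefficients of a protein's incident edges.
#'
#' @param net a [ProteinNetwork-class].
#' @return named numeric vector over all network proteins.
#' @export
neighborhoodCentrality <- function(net) {
  out <- setNames(numeric(numProteins(net)), net@nodes)
  if (numEdges(net) == 0L) {
    return(out)
  }
  ecc <- edgeClusteringCoefficient(net)
  em <- net@edges
  acc <- rowsum(c(ecc, ecc), group = c(em[, 1L], em[, 2L]))
  out[rownames(acc)] <- acc[, 1L]
  out
}

#' Rank proteins by a centrality vector
#'
#' Descending score order with ties broken by protein ID (ascending), so a
#' ranking is fully deterministic.
#'
#' @param scores named numeric vector.
#' @return character vector of protein IDs, best first.
#' @export
centralityRanking <- function(scores) {
  names(scores)[order(-scores, names(scores), method = "radix")]
}
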