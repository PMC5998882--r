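# Small graphs and brute-force oracles shared across the suite.

netFromPairs <- function(...) {
  proteinNetwork(matrix(c(...), ncol = 2, byrow = TRUE))
}

triangleNet <- function() netFromPairs("a", "b", "b", "c", "a", "c")

pathNet <- function() netFromPairs("a", "b", "b", "c")

starNet <- function(leaves = 5L) {
  ids <- sprintf("l%02d", seq_len(leaves))
  proteinNetwork(cbind("hub", ids))
}

completeNet <- function(n) {
  ids <- sprintf("k%02d", seq_len(n))
  proteinNetwork(t(combn(ids, 2L)))
}

# Erdos-Renyi simple graph over n labelled nodes (isolated nodes kept)
randomSimpleNet <- function(n, p) {
  ids <- sprintf("n%03d", seq_len(n))
  pairs <- t(combn(ids, 2L))
  keep <- runif(nrow(pairs)) < p
  proteinNetwork(pairs[keep, , drop = FALSE], nodes = ids)
}

# independent ECC oracle: triple loop over nodes counting common neighbors
bruteForceECC <- function(net) {
  em <- edgeList(net)
  nodes <- proteins(net)
  vals <- numeric(nrow(em))
  for (r in seq_len(nrow(em))) {
    i <- em[r, 1L]
    j <- em[r, 2L]
    common <- 0L
    for (v in nodes) {
      if (v %in% neighborsOf(net, i) && v %in% neighborsOf(net, j)) {
        common <- common + 1L
      }
    }
    vals[r] <- common / min(length(neighborsOf(net, i)),
                            length(neighborsOf(net, j)))
  }
  names(vals) <- paste(em[, 1L], em[, 2L], sep = "\t")
  vals
}

# independent PeC oracle: explicit loop over edges via the scalar helpers
bruteForcePeC <- function(net, expr) {
  ecc <- edgeClusteringCoefficient(net)
  out <- setNames(numeric(numProteins(net)), proteins(net))
  em <- edgeList(net)
  for (r in seq_len(nrow(em))) {
    i <- em[r, 1L]
    j <- em[r, 2L]
    pc <- coClusterProbability(ecc, expr, i, j)
    out[i] <- out[i] + pc
    out[j] <- out[j] + pc
  }
  out
}

# default small dataset used by several suites
smallDataset <- function(seed = 1L, n = 150L, complexes = 6L) {
  generateDataset(
    nProteins = n, nComplexes = complexes, complexSizeRange = c(3L, 6L),
    seed = seed
  )
}
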