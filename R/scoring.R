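# Biological per-protein scores: PeC (co-expression x edge clustering),
# SL (subcellular-localization frequency among known essentials), and PC
# (complex membership count). Missing annotations always contribute the
# neutral value 0, so every score is a total function of the protein set.

#' Pearson correlation of two expression profiles
#'
#' Sample Pearson correlation over the T time points. A profile with zero
#' variance makes the textbook formula undefined; such pairs score 0 (a
#' neutral co-expression contribution).
#'
#' @param x,y numeric vectors of equal length T >= 2.
#' @return correlation in \[-1, 1\], or 0 for a zero-variance input.
#' @export
pearsonCorrelation <- function(x, y) {
  if (length(x) != length(y)) stop("expression profiles differ in length")
  if (length(x) < 2L) stop("need at least 2 time points")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)
}

# rows centered and scaled to unit sum of squares; zero-variance rows become
# all-zero so any inner product with them is 0 (the neutral PCC convention)
normalizeProfiles <- function(expr) {
  ctr <- expr - rowMeans(expr)
  ss <- sqrt(rowSums(ctr^2))
  ctr[ss > 0, ] <- ctr[ss > 0, , drop = FALSE] / ss[ss > 0]
  ctr[ss == 0, ] <- 0
  ctr
}

#' Co-clustering probability of an interacting pair
#'
#' `p_c(i,j) = ECC(i,j) * PCC(i,j)`: an interaction supported by both a
#' triangle-dense neighborhood and correlated expression is likely to lie
#' inside a module. If either endpoint has no expression profile the PCC
#' term is 0 and so is `p_c`.
#'
#' @param ecc edge score vector from [edgeClusteringCoefficient()].
#' @param expr expression matrix with protein row names.
#' @param i,j the two endpoint protein IDs of an existing edge.
#' @return numeric co-clustering probability.
#' @export
coClusterProbability <- function(ecc, expr, i, j) {
  key <- edgeKeys(i, j)
  if (!key %in% names(ecc)) stop("edge not scored: ", i, " -- ", j)
  if (!(i %in% rownames(expr)) || !(j %in% rownames(expr))) return(0)
  unname(ecc[[key]] * pearsonCorrelation(expr[i, ], expr[j, ]))
}

#' PeC scores
#'
#' `PeC(i) = sum over neighbors v of ECC(i,v) * PCC(i,v)`; a protein whose
#' interactions are both clustered and co-expressed accumulates a high
#' score. Proteins without expression profiles contribute 0 on their edges.
#'
#' @param net a [ProteinNetwork-class].
#' @param expr expression matrix with protein row names.
#' @return named numeric vector over all network proteins.
#' @export
pecScores <- function(net, expr) {
  out <- setNames(numeric(numProteins(net)), net@nodes)
  if (numEdges(net) == 0L) {
    return(out)
  }
  ecc <- edgeClusteringCoefficient(net)
  em <- net@edges
  Z <- normalizeProfiles(expr)
  ia <- match(em[, 1L], rownames(Z))
  ja <- match(em[, 2L], rownames(Z))
  pcc <- numeric(nrow(em))
  ok <- !is.na(ia) & !is.na(ja)
  if (any(ok)) {
    pcc[ok] <- rowSums(Z[ia[ok], , drop = FALSE] * Z[ja[ok], , drop = FALSE])
  }
  pc <- as.numeric(ecc) * pcc
  acc <- rowsum(c(pc, pc), group = c(em[, 1L], em[, 2L]))
  out[rownames(acc)] <- acc[, 1L]
  out
}

#' Location frequencies among known essential proteins
#'
#' Restricts the localization records to proteins in the known essential set
#' (the relationship dataset S) and tabulates `F(r) = S_r / |S|`, the share
#' of essential-protein records falling in location r. Frequencies over all
#' locations sum to 1.
#'
#' @param subcell data frame with `protein` and `location` columns.
#' @param essential character vector of known essential protein IDs.
#' @param exclude optional protein IDs to leave out of the frequency
#'   estimation (e.g. an evaluation set, to avoid circularity when
#'   benchmarking).
#' @return named numeric vector of frequencies over every location label in
#'   `subcell`.
#' @export
locationFrequencies <- function(subcell, essential, exclude = NULL) {
  keepEss <- setdiff(essential, exclude)
  S <- subcell[subcell$protein %in% keepEss, , drop = FALSE]
  if (nrow(S) == 0L) {
    stop("no essential protein has a subcellular record; SL is undefined")
  }
  locs <- sort(unique(subcell$location))
  tab <- table(factor(S$location, levels = locs))
  freq <- as.numeric(tab) / nrow(S)
  names(freq) <- locs
  freq
}

#' Subcellular localization scores
#'
#' `SL(i)` is the sum of location frequencies over the locations protein i is
#' annotated with; proteins absent from the record set score 0. Since the
#' frequencies form a probability vector and a protein's locations are a
#' subset of all locations, SL is always in \[0, 1\].
#'
#' @param subcell data frame with `protein` and `location` columns.
#' @param freq frequency vector from [locationFrequencies()].
#' @return named numeric vector over the proteins present in `subcell`.
#' @export
slScores <- function(subcell, freq) {
  rec <- subcell[!duplicated(subcell), , drop = FALSE]
  f <- freq[rec$location]
  f[is.na(f)] <- 0
  acc <- rowsum(as.numeric(f), group = rec$protein)
  setNames(acc[, 1L], rownames(acc))
}

#' Protein-complex membership counts
#'
#' `PC(i)` is the number of cataloged complexes containing protein i;
#' proteins in no complex score 0.
#'
#' @param complexes list of character vectors (complex member sets).
#' @return named integer vector over the proteins appearing in any complex.
#' @export
pcScores <- function(complexes) {
  members <- unlist(lapply(complexes, unique), use.names = FALSE)
  if (length(members) == 0L) return(setNames(integer(0), character(0)))
  tab <- table(members)
  setNames(as.integer(tab), names(tab))
}

#' Assemble the per-protein score table
#'
#' Computes PeC, SL and PC for every protein and combines them into the
#' per-protein GSC component `SL * (alpha * PeC + (1 - alpha) * PC)`. The
#' table covers every network node plus any protein appearing in the
#' biological inputs; proteins missing an annotation get the neutral value 0
#' for that score. Only network nodes can ever enter a candidate set.
#'
#' @param net a [ProteinNetwork-class].
#' @param expr expression matrix with protein row names.
#' @param subcell data frame with `protein` and `location` columns.
#' @param complexes list of character vectors.
#' @param essential character vector of known essential protein IDs.
#' @param alpha mixing weight in \[0, 1\] between PeC and PC (default 0.6).
#' @param excludeFromFrequencies optional IDs excluded from the SL frequency
#'   estimation; see [locationFrequencies()].
#' @return data frame with columns `protein`, `pec`, `sl`, `pc`, `gsc`.
#' @export
proteinScores <- function(net, expr, subcell, complexes, essential,
                          alpha = 0.6,
                          excludeFromFrequencies = NULL) {
  stopifnot(alpha >= 0, alpha <= 1)
  pec <- pecScores(net, expr)
  freq <- locationFrequencies(subcell, essential, excludeFromFrequencies)
  sl <- slScores(subcell, freq)
  pc <- pcScores(complexes)
  ids <- sort(unique(c(
    net@nodes, rownames(expr), subcell$protein,
    unlist(complexes, use.names = FALSE)
  )))
  lookup <- function(v, default = 0) {
    out <- v[ids]
    out[is.na(out)] <- default
    unname(out)
  }
  tab <- data.frame(
    protein = ids,
    pec = lookup(pec),
    sl = lookup(sl),
    pc = lookup(pc),
    stringsAsFactors = FALSE
  )
  tab$gsc <- tab$sl * (alpha * tab$pec + (1 - alpha) * tab$pc)
  attr(tab, "alpha") <- alpha
  tab
}
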