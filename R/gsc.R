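# The GSC fitness: per protein, SL * [alpha * PeC + (1 - alpha) * PC];
# for a candidate set, the sum of the members' values. Additivity makes the
# size-Q optimum a closed form (the top-Q proteins by per-protein GSC),
# which the tests use as a convergence oracle for the optimizer.

#' Per-protein GSC vector
#'
#' Recomputes `SL * (alpha * PeC + (1 - alpha) * PC)` from a score table for
#' a given mixing weight.
#'
#' @param scores score table from [proteinScores()].
#' @param alpha mixing weight in \[0, 1\]; `NULL` reuses the table's alpha.
#' @return named numeric vector over all scored proteins.
#' @export
gscVector <- function(scores, alpha = NULL) {
  alpha <- alpha %||% attr(scores, "alpha") %||% 0.6
  stopifnot(alpha >= 0, alpha <= 1)
  setNames(
    scores$sl * (alpha * scores$pec + (1 - alpha) * scores$pc),
    scores$protein
  )
}

#' GSC component of a single protein
#'
#' @param scores score table from [proteinScores()].
#' @param protein a scored protein ID.
#' @param alpha mixing weight; `NULL` reuses the table's alpha.
#' @return numeric GSC value.
#' @examples
#' tab <- data.frame(protein = "a", pec = 2, sl = 0.5, pc = 3)
#' proteinGSC(tab, "a", alpha = 0.6) # 0.5 * (0.6*2 + 0.4*3) = 1.2
#' @export
proteinGSC <- function(scores, protein, alpha = NULL) {
  row <- match(protein, scores$protein)
  if (is.na(row)) stop("protein not in score table: ", protein)
  alpha <- alpha %||% attr(scores, "alpha") %||% 0.6
  stopifnot(alpha >= 0, alpha <= 1)
  scores$sl[row] * (alpha * scores$pec[row] + (1 - alpha) * scores$pc[row])
}

#' GSC fitness of a candidate protein set
#'
#' Sum of [proteinGSC()] over the members; the empty set scores 0. The
#' fitness is additive and permutation-invariant, so disjoint sets satisfy
#' `fitness(A union B) = fitness(A) + fitness(B)`.
#'
#' @param members character vector of scored protein IDs (a candidate set).
#' @param scores score table from [proteinScores()].
#' @param alpha mixing weight; `NULL` reuses the table's alpha.
#' @return numeric fitness.
#' @export
gscFitness <- function(members, scores, alpha = NULL) {
  if (length(members) == 0L) return(0)
  g <- gscVector(scores, alpha)
  miss <- setdiff(members, names(g))
  if (length(miss)) stop("unscored members: ", paste(miss, collapse = ", "))
  sum(g[members])
}

#' Rank proteins by their GSC component
#'
#' Descending GSC with ties broken by protein ID ascending, so rankings are
#' deterministic and reproducible.
#'
#' @param proteinIds protein IDs to rank (default: every scored protein).
#' @param scores score table from [proteinScores()].
#' @param alpha mixing weight; `NULL` reuses the table's alpha.
#' @return data frame with columns `rank`, `protein`, `score`.
#' @export
rankDescending <- function(proteinIds = NULL, scores, alpha = NULL) {
  g <- gscVector(scores, alpha)
  ids <- proteinIds %||% names(g)
  miss <- setdiff(ids, names(g))
  if (length(miss)) stop("unscored proteins: ", paste(miss, collapse = ", "))
  vals <- g[ids]
  ord <- order(-vals, ids, method = "radix")
  data.frame(
    rank = seq_along(ids),
    protein = ids[ord],
    score = unname(vals[ord]),
    stringsAsFactors = FALSE
  )
}
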