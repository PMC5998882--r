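# Evaluation of ranked candidate lists against a reference essential set:
# top-k precision, precision-recall curve, jackknife (cumulative-hit) curve,
# and multi-method comparison tables.

#' Precision among the top k ranked proteins
#'
#' `|top-k intersect truth| / k`.
#'
#' @param ranking ranking-like object (see [rankedProteins()]).
#' @param truth character vector of true essential protein IDs.
#' @param k cutoff, between 1 and the ranking length.
#' @return numeric precision in \[0, 1\].
#' @export
precisionAtK <- function(ranking, truth, k) {
  ids <- rankedProteins(ranking)
  if (k < 1L || k > length(ids)) {
    stop("k = ", k, " outside 1..", length(ids))
  }
  sum(ids[seq_len(k)] %in% truth) / k
}

#' Precision-recall curve of a ranking
#'
#' For every cutoff k: precision = hits(k)/k and recall = hits(k)/|truth|.
#'
#' @param ranking ranking-like object.
#' @param truth non-empty character vector of true essential protein IDs.
#' @return data frame with columns `k`, `recall`, `precision`.
#' @export
prCurve <- function(ranking, truth) {
  if (length(truth) == 0L) stop("empty truth set")
  ids <- rankedProteins(ranking)
  hits <- cumsum(ids %in% truth)
  k <- seq_along(ids)
  data.frame(k = k, recall = hits / length(unique(truth)), precision = hits / k)
}

#' Jackknife curve of a ranking
#'
#' Cumulative count of true essential proteins as a function of rank; the
#' non-decreasing curve whose area summarizes ranking quality.
#'
#' @param ranking ranking-like object.
#' @param truth character vector of true essential protein IDs.
#' @return data frame with columns `rank` and `cumulativeHits`.
#' @export
jackknifeCurve <- function(ranking, truth) {
  ids <- rankedProteins(ranking)
  data.frame(rank = seq_along(ids), cumulativeHits = cumsum(ids %in% truth))
}

#' Compare several rankings at fixed cutoffs
#'
#' Counts the true essential proteins each method places in its top k, for
#' every requested cutoff. Cutoffs beyond a ranking's length are reported as
#' NA (FPE rankings have length Q while topology baselines rank the whole
#' network).
#'
#' @param rankings named list of ranking-like objects.
#' @param truth character vector of true essential protein IDs.
#' @param cutoffs integer vector of top-k cutoffs.
#' @return data frame with a `method` column and one `top<k>` column per
#'   cutoff.
#' @export
compareMethods <- function(rankings, truth,
                           cutoffs = c(100L, 200L, 300L, 400L, 500L, 600L)) {
  if (is.null(names(rankings)) || any(!nzchar(names(rankings)))) {
    stop("rankings must be a named list")
  }
  rows <- lapply(rankings, function(r) {
    ids <- rankedProteins(r)
    vapply(cutoffs, function(k) {
      if (k > length(ids)) return(NA_integer_)
      sum(ids[seq_len(k)] %in% truth)
    }, integer(1))
  })
  out <- data.frame(
    method = names(rankings),
    do.call(rbind, rows),
    stringsAsFactors = FALSE, row.names = NULL
  )
  names(out)[-1L] <- paste0("top", cutoffs)
  out
}
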