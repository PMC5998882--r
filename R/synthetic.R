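# Seeded generator for self-contained benchmark datasets: a scale-free
# interaction backbone with planted protein complexes (cliques), expression
# profiles correlated within complexes via a shared latent signal,
# localization records enriched for a "hub" location among the planted
# essentials, and the ground-truth essential list itself.

#' Generate a synthetic benchmark dataset
#'
#' Construction, fully reproducible from `seed`:
#' 1. a preferential-attachment backbone of `nProteins` nodes
#'    (`attachmentEdges` edges per arriving node), giving the heavy-tailed
#'    degree distribution typical of PPI networks;
#' 2. `ceiling(essentialFraction * nProteins)` proteins designated essential;
#' 3. `nComplexes` planted cliques with sizes drawn from
#'    `complexSizeRange`, members drawn preferentially from the essentials
#'    (each member slot is essential with probability
#'    `complexEssentialBias` while the essential pool lasts); complexes are
#'    pairwise disjoint so the planted co-expression stays analytically
#'    exact; all clique edges are added to the network;
#' 4. expression: each complex carries a latent time course of length
#'    `nTimepoints`; members observe `baseline + s * latent + noise` with
#'    `s = noiseSd * sqrt(rho / (1 - rho))`, so the expected
#'    within-complex pairwise correlation is exactly
#'    `rho = s^2 / (s^2 + noiseSd^2)`; non-members observe independent
#'    noise;
#' 5. localization: one record per protein; essentials are annotated with a
#'    designated hub location with probability `essentialLocationBias`,
#'    everything else uniformly over the `nLocations` labels.
#'
#' @param nProteins number of proteins (default 1000).
#' @param attachmentEdges preferential-attachment edges per node (default 3).
#' @param nComplexes number of planted complexes (default 30).
#' @param complexSizeRange integer `c(min, max)` complex size (default 3-8).
#' @param essentialFraction fraction of proteins that are essential
#'   (default 0.1).
#' @param withinComplexCorrelation target expected pairwise expression
#'   correlation within a complex, in \[0, 1) (default 0.7).
#' @param noiseSd expression noise standard deviation (default 1).
#' @param nTimepoints expression time points (default 36, as in typical
#'   yeast metabolic-cycle time courses).
#' @param nLocations number of subcellular location labels (default 11, the
#'   number of yeast compartments).
#' @param essentialLocationBias probability an essential protein is
#'   annotated at the hub location (default 0.9).
#' @param complexEssentialBias probability a complex member slot is drawn
#'   from the essential pool (default 0.8).
#' @param seed RNG seed.
#' @return a [SyntheticDataset-class].
#' @export
generateDataset <- function(nProteins = 1000L, attachmentEdges = 3L,
                            nComplexes = 30L, complexSizeRange = c(3L, 8L),
                            essentialFraction = 0.1,
                            withinComplexCorrelation = 0.7, noiseSd = 1,
                            nTimepoints = 36L, nLocations = 11L,
                            essentialLocationBias = 0.9,
                            complexEssentialBias = 0.8, seed = NULL) {
  stopifnot(
    nProteins >= 3L, attachmentEdges >= 1L, nComplexes >= 1L,
    length(complexSizeRange) == 2L, complexSizeRange[1L] >= 2L,
    complexSizeRange[1L] <= complexSizeRange[2L],
    essentialFraction > 0, essentialFraction < 1,
    withinComplexCorrelation >= 0, withinComplexCorrelation < 1,
    noiseSd > 0, nTimepoints >= 2L, nLocations >= 2L,
    essentialLocationBias >= 0, essentialLocationBias <= 1,
    complexEssentialBias >= 0, complexEssentialBias <= 1
  )
  if (complexSizeRange[2L] > nProteins) {
    stop("largest complex size exceeds the number of proteins")
  }
  if (nComplexes * complexSizeRange[2L] > nProteins) {
    stop("complexes cannot be disjoint: nComplexes * max size > nProteins")
  }
  if (!is.null(seed)) set.seed(seed)
  ids <- sprintf("P%0*d", max(4L, nchar(nProteins)), seq_len(nProteins))

  # 1. scale-free backbone (preferential attachment, Barabasi-Albert)
  g <- igraph::sample_pa(
    nProteins, power = 1, m = attachmentEdges, directed = FALSE
  )
  backbone <- igraph::as_edgelist(g, names = FALSE)
  backbone <- cbind(ids[backbone[, 1L]], ids[backbone[, 2L]])

  # 2. ground-truth essentials
  essentials <- sort(sampleSet(ids, ceiling(essentialFraction * nProteins)))

  # 3. disjoint planted complexes, member slots biased toward essentials
  essPool <- sampleSet(essentials, length(essentials))
  bgPool <- sampleSet(setdiff(ids, essentials), nProteins - length(essentials))
  sizes <- sample(
    seq(complexSizeRange[1L], complexSizeRange[2L]), nComplexes,
    replace = TRUE
  )
  complexes <- vector("list", nComplexes)
  for (k in seq_len(nComplexes)) {
    nEss <- min(rbinom(1L, sizes[k], complexEssentialBias), length(essPool))
    nBg <- min(sizes[k] - nEss, length(bgPool))
    members <- c(utils::head(essPool, nEss), utils::head(bgPool, nBg))
    essPool <- utils::tail(essPool, length(essPool) - nEss)
    bgPool <- utils::tail(bgPool, length(bgPool) - nBg)
    complexes[[k]] <- sort(members)
  }
  cliqueEdges <- do.call(rbind, lapply(complexes, function(m) {
    t(utils::combn(m, 2L))
  }))
  network <- proteinNetwork(rbind(backbone, cliqueEdges))

  # 4. expression with a shared latent signal per complex
  rho <- withinComplexCorrelation
  s <- if (rho > 0) noiseSd * sqrt(rho / (1 - rho)) else 0
  baseline <- 5
  expr <- baseline + matrix(
    rnorm(nProteins * nTimepoints, sd = noiseSd),
    nProteins, nTimepoints,
    dimnames = list(ids, sprintf("t%02d", seq_len(nTimepoints)))
  )
  for (k in seq_len(nComplexes)) {
    latent <- rnorm(nTimepoints)
    for (m in complexes[[k]]) {
      expr[m, ] <- baseline + s * latent + rnorm(nTimepoints, sd = noiseSd)
    }
  }

  # 5. one localization record per protein, essentials biased to the hub
  locations <- sprintf("loc%02d", seq_len(nLocations))
  hub <- locations[1L]
  loc <- sample(locations, nProteins, replace = TRUE)
  isEss <- ids %in% essentials
  atHub <- isEss & runif(nProteins) < essentialLocationBias
  loc[atHub] <- hub
  subcellular <- data.frame(
    protein = ids, location = loc, stringsAsFactors = FALSE
  )

  new("SyntheticDataset",
    network = network, expression = expr, subcellular = subcellular,
    complexes = complexes, essentials = essentials,
    config = list(
      nProteins = nProteins, attachmentEdges = attachmentEdges,
      nComplexes = nComplexes, complexSizeRange = complexSizeRange,
      essentialFraction = essentialFraction,
      withinComplexCorrelation = withinComplexCorrelation,
      noiseSd = noiseSd, nTimepoints = nTimepoints,
      nLocations = nLocations,
      essentialLocationBias = essentialLocationBias,
      complexEssentialBias = complexEssentialBias, seed = seed
    )
  )
}

#' Write a synthetic dataset to the five standard input files
#'
#' Emits `network.tsv`, `expression.tsv`, `subcellular.tsv`,
#' `complexes.tsv` and `essential.txt` in the package's file dialect; the
#' files round-trip through the corresponding readers.
#'
#' @param dataset a [SyntheticDataset-class].
#' @param dir output directory (created if needed).
#' @return named character vector of the five file paths, invisibly.
#' @export
writeDataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    network = file.path(dir, "network.tsv"),
    expression = file.path(dir, "expression.tsv"),
    subcellular = file.path(dir, "subcellular.tsv"),
    complexes = file.path(dir, "complexes.tsv"),
    essential = file.path(dir, "essential.txt")
  )
  writeNetwork(dataset@network, paths[["network"]])
  writeExpression(dataset@expression, paths[["expression"]])
  writeSubcellular(dataset@subcellular, paths[["subcellular"]])
  writeComplexes(dataset@complexes, paths[["complexes"]])
  writeEssential(dataset@essentials, paths[["essential"]])
  invisible(paths)
}

#' Score table of a synthetic dataset
#'
#' Convenience wrapper calling [proteinScores()] on the bundled inputs.
#'
#' @param dataset a [SyntheticDataset-class].
#' @param alpha GSC mixing weight.
#' @return data frame from [proteinScores()].
#' @export
scoreDataset <- function(dataset, alpha = 0.6) {
  proteinScores(
    dataset@network, dataset@expression, dataset@subcellular,
    dataset@complexes, dataset@essentials, alpha = alpha
  )
}

setMethod("show", "SyntheticDataset", function(object) {
  cat(
    "SyntheticDataset:", numProteins(object@network), "proteins,",
    numEdges(object@network), "interactions,",
    length(object@complexes), "planted complexes,",
    length(object@essentials), "essentials\n"
  )
})
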