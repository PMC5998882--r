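# The discrete, set-encoded flower pollination optimizer (FPE).
#
# A pollen is a candidate essential-protein set of exactly Q distinct
# network nodes; its fitness is the additive GSC of its members. Each
# iteration every pollen draws u ~ Uniform(0,1): u < p triggers the global
# move (keep the part of the pollen that agrees with a random gamma-portion
# of Gbest, refill the rest uniformly at random from the network), otherwise
# the local move, which leaves the position unchanged. An update replaces
# the incumbent pollen only if its fitness is at least as high (greedy,
# elitist acceptance), so the best-so-far fitness trace is non-decreasing.
#
# RNG discipline: a single stream, consumed in a documented order —
# initialization first (per non-elite pollen: members to replace, then
# replacements), then per iteration and per pollen: the switch draw, and for
# a global move the Gbest subset followed by the random refill. Identical
# seed and inputs give byte-identical output.

#' Control parameters for the FPE optimizer
#'
#' @param Q candidate-set size (default 600, the largest cutoff usually
#'   evaluated).
#' @param p switch probability in \[0, 1\]; probability of the global,
#'   Gbest-guided move (default 0.3, the value found best in practice).
#' @param alpha GSC mixing weight between PeC and PC (default 0.6).
#' @param popSize number of pollens N (default 20).
#' @param iterations iteration budget T_max (default 100); the optimizer
#'   always runs the full budget, with no plateau-based early stop.
#' @param beta perturbance factor in \[0, 1\]: the fraction of the top-degree
#'   elite replaced at random in each non-elite initial pollen (default 0.2).
#' @param gamma Gbest retention fraction in (0, 1\]: the portion of Gbest a
#'   global move may inherit (default 0.99; for any `gamma < 1` at least one
#'   slot is always refilled, so the move never degenerates to a no-op --
#'   see the methods vignette for the sensitivity analysis behind this
#'   choice).
#' @param seed optional RNG seed consumed by [runFPE()].
#' @return a named list of class `fpeControl`.
#' @export
fpeControl <- function(Q = 600L, p = 0.3, alpha = 0.6, popSize = 20L,
                       iterations = 100L, beta = 0.2, gamma = 0.99,
                       seed = NULL) {
  stopifnot(
    Q >= 1L, p >= 0, p <= 1, alpha >= 0, alpha <= 1, popSize >= 1L,
    iterations >= 0L, beta >= 0, beta <= 1, gamma > 0, gamma <= 1
  )
  structure(
    list(
      Q = as.integer(Q), p = p, alpha = alpha, popSize = as.integer(popSize),
      iterations = as.integer(iterations), beta = beta, gamma = gamma,
      seed = seed
    ),
    class = "fpeControl"
  )
}

newPollen <- function(members, gsc) {
  list(members = members, fitness = sum(gsc[members]))
}

#' Initialize the pollen population
#'
#' Pollen 1 is the elite: the Q highest-degree proteins (degree ties broken
#' by ID). Every other pollen perturbs the elite by replacing
#' `ceiling(beta * Q)` uniformly chosen members with uniformly chosen
#' non-members, so the initial population is diverse but degree-informed.
#' Uses the current RNG state; seed beforehand (or via [runFPE()]).
#'
#' @param net a [ProteinNetwork-class].
#' @param scores score table from [proteinScores()].
#' @param control an [fpeControl()] list.
#' @return optimizer state: list with `population`, `gbest`, `history`,
#'   plus the cached node set and GSC vector.
#' @export
initializePopulation <- function(net, scores, control = fpeControl()) {
  nodes <- proteins(net)
  Q <- control$Q
  if (Q > length(nodes)) {
    stop("Q = ", Q, " exceeds the ", length(nodes), " network proteins")
  }
  gscAll <- gscVector(scores, control$alpha)
  miss <- setdiff(nodes, names(gscAll))
  if (length(miss)) stop("network proteins missing from score table")
  gsc <- gscAll[nodes]
  deg <- degrees(net)
  elite <- nodes[order(-deg, nodes, method = "radix")][seq_len(Q)]
  nRep <- min(ceiling(control$beta * Q), length(nodes) - Q)
  population <- vector("list", control$popSize)
  population[[1L]] <- newPollen(elite, gsc)
  for (k in seq_len(control$popSize)[-1L]) {
    if (nRep > 0L) {
      drop <- sampleSet(elite, nRep)
      add <- sampleSet(setdiff(nodes, elite), nRep)
      members <- c(setdiff(elite, drop), add)
    } else {
      members <- elite
    }
    population[[k]] <- newPollen(members, gsc)
  }
  fits <- vapply(population, `[[`, numeric(1), "fitness")
  gbest <- population[[which.max(fits)]]
  list(
    population = population, gbest = gbest, history = gbest$fitness,
    nodes = nodes, gsc = gsc
  )
}

#' Global pollination move
#'
#' Draws a uniform subset G' of `ceiling(gamma * Q)` Gbest members, keeps
#' `K = pollen intersect G'` (the part of the pollen that agrees with the
#' guide), and refills the remaining `Q - |K|` slots with uniform draws
#' (without replacement) from the rest of the network. The result always
#' holds exactly Q distinct nodes.
#'
#' @param pollen,gbest pollens (lists with `members` and `fitness`).
#' @param nodes character vector of all network nodes.
#' @param gsc named GSC vector over `nodes`.
#' @param control an [fpeControl()] list.
#' @return the proposed pollen with recomputed fitness.
#' @export
globalPollination <- function(pollen, gbest, nodes, gsc, control) {
  Q <- control$Q
  # a retention proportion below 1 must leave at least one slot to refill,
  # or the move degenerates to a no-op once a pollen equals Gbest
  nKeep <- if (control$gamma >= 1) Q else min(ceiling(control$gamma * Q), Q - 1L)
  gPrime <- sampleSet(gbest$members, nKeep)
  K <- intersect(pollen$members, gPrime)
  fill <- sampleSet(setdiff(nodes, K), Q - length(K))
  newPollen(c(K, fill), gsc)
}

#' Local pollination move
#'
#' The discrete local move leaves the position unchanged: the pollen is
#' returned with identical members and fitness (and is therefore
#' idempotent). The switch probability p thus controls the effective update
#' rate of the search.
#'
#' @param pollen a pollen (list with `members` and `fitness`).
#' @return the same pollen.
#' @export
localPollination <- function(pollen) {
  pollen
}

#' One FPE iteration
#'
#' For each pollen independently: draw u ~ Uniform(0,1); apply the global
#' move if u < p, the local move otherwise; accept the proposal only if its
#' fitness is not lower than the incumbent's. Gbest is then updated to the
#' strictly best pollen seen (ties keep the incumbent Gbest) and its fitness
#' appended to the history.
#'
#' @param state optimizer state from [initializePopulation()] / `fpeStep()`.
#' @param control an [fpeControl()] list.
#' @return the updated state.
#' @export
fpeStep <- function(state, control = fpeControl()) {
  for (k in seq_along(state$population)) {
    incumbent <- state$population[[k]]
    u <- runif(1L)
    candidate <- if (u < control$p) {
      globalPollination(incumbent, state$gbest, state$nodes, state$gsc,
                        control)
    } else {
      localPollination(incumbent)
    }
    if (candidate$fitness >= incumbent$fitness) {
      state$population[[k]] <- candidate
    }
  }
  fits <- vapply(state$population, `[[`, numeric(1), "fitness")
  best <- which.max(fits)
  if (fits[best] > state$gbest$fitness) {
    state$gbest <- state$population[[best]]
  }
  state$history <- c(state$history, state$gbest$fitness)
  state
}

#' Run the FPE optimizer
#'
#' Initializes the population from the top-degree elite, runs the full
#' iteration budget, and returns the best candidate set found, ranked in
#' descending per-protein GSC order (ties broken by protein ID). With the
#' same seed, inputs and control, the output is identical.
#'
#' @param net a [ProteinNetwork-class].
#' @param scores score table from [proteinScores()].
#' @param control an [fpeControl()] list.
#' @param seed RNG seed; overrides `control$seed` when given.
#' @return an [FPEResult-class].
#' @export
runFPE <- function(net, scores, control = fpeControl(), seed = NULL) {
  seed <- seed %||% control$seed
  if (!is.null(seed)) set.seed(seed)
  state <- initializePopulation(net, scores, control)
  for (t in seq_len(control$iterations)) {
    state <- fpeStep(state, control)
  }
  ranking <- rankDescending(state$gbest$members, scores, control$alpha)
  new("FPEResult",
    ranking = ranking, gbest = state$gbest$members,
    fitness = state$gbest$fitness, history = state$history,
    control = unclass(control)
  )
}

#' @rdname FPEResult-class
#' @export
setMethod("gbestMembers", "FPEResult", function(x) x@gbest)

#' @rdname FPEResult-class
#' @export
setMethod("fitnessHistory", "FPEResult", function(x) x@history)

#' @rdname FPEResult-class
#' @export
setMethod("gscRanking", "FPEResult", function(x) x@ranking)

#' @rdname rankedProteins
#' @export
setMethod("rankedProteins", "FPEResult", function(x) x@ranking$protein)

#' @rdname rankedProteins
#' @export
setMethod("rankedProteins", "character", function(x) x)

#' @rdname rankedProteins
#' @export
setMethod("rankedProteins", "data.frame", function(x) {
  if (!"protein" %in% names(x)) stop("ranking data frame needs a protein column")
  if ("rank" %in% names(x)) x <- x[order(x$rank), , drop = FALSE]
  x$protein
})

setMethod("show", "FPEResult", function(object) {
  cat(
    "FPEResult: candidate set of", length(object@gbest), "proteins,",
    "GSC fitness", format(object@fitness, digits = 6), "\n",
    "  after", length(object@history) - 1L, "iterations (initial fitness",
    format(object@history[1L], digits = 6), ")\n"
  )
})
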