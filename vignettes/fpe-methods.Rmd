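---
title: "Methods: GSC scoring and the discrete flower pollination search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GSC scoring and the discrete flower pollination search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fpeNet)
```

## The problem

Essential proteins are those whose loss is lethal to the cell. In
protein–protein interaction (PPI) networks they tend to be highly connected
(the centrality–lethality rule), but pure topology is noisy: PPI screens
carry many false positives, and essentiality is as much a property of
biological context — expression modules, compartments, complexes — as of
wiring. `fpeNet` scores proteins by combining both kinds of evidence and
then searches the network for a whole candidate *set* of likely-essential
proteins, rather than thresholding a per-protein ranking.

## The GSC score

For a protein $i$ the package combines three signals:

* **PeC** — co-clustering along edges. Each edge $(i,j)$ gets an edge
  clustering coefficient
  $ECC(i,j) = |N_i \cap N_j| / \min(d_i, d_j)$
  and a Pearson correlation $PCC(i,j)$ of the two expression time courses;
  their product $p_c(i,j) = ECC \times PCC$ is a co-clustering probability,
  and $PeC(i) = \sum_{v \in N_i} p_c(i,v)$.
* **SL** — localization evidence. Among the localization records of the
  *known* essential proteins, each compartment $r$ has a frequency
  $F(r) = S_r / |S|$; $SL(i)$ is the sum of $F(r)$ over the compartments
  protein $i$ is annotated with, so $SL(i) \in [0,1]$.
* **PC** — the number of cataloged protein complexes containing $i$.

These are mixed, with $\alpha \in [0,1]$ (default 0.6), into the
per-protein component

$$g(i) = SL(i)\,\bigl[\alpha\,PeC(i) + (1-\alpha)\,PC(i)\bigr],$$

and the fitness of a candidate set $H = \{h_1,\dots,h_Q\}$ is
$GSC(H) = \sum_{i \in H} g(i)$.

Missing data is always neutral: a protein without an expression profile
contributes 0 to $p_c$ on its edges, a protein with no localization record
has $SL = 0$, and a protein in no complex has $PC = 0$, so $GSC$ is a total
function on the node set. A zero-variance expression profile — for which
the correlation is undefined — also contributes 0. The index set of the
ranking is deterministic throughout: ties are broken by protein ID.

Because $GSC$ is additive over members, the best size-$Q$ set is, in closed
form, the top $Q$ proteins by $g(i)$. The package still implements the
metaheuristic in full — the search procedure is the point, and on variants
of the fitness that are *not* additive it would be the only option — and
uses the closed form as an independent convergence oracle in its tests.

## The FPE search

A *pollen* is a candidate set of exactly $Q$ distinct network proteins.
The population (default $N = 20$) is initialized at the $Q$ highest-degree
proteins (the elite), with every other pollen perturbed by replacing
$\lceil \beta Q \rceil$ members (default $\beta = 0.2$) with random
non-members. Each iteration, each pollen draws $u \sim U(0,1)$:

* $u < p$ (default $p = 0.3$): **global pollination.** Draw a uniform
  subset $G'$ of Gbest of size $\lceil \gamma Q \rceil$, keep
  $K = \text{pollen} \cap G'$, and refill the remaining $Q - |K|$ slots
  uniformly without replacement from the rest of the network.
* otherwise: **local pollination**, which for this discrete encoding is the
  identity — the position is unchanged, so $p$ is effectively the update
  rate of the search.

A proposal replaces the incumbent pollen only if its fitness is at least as
high (greedy, elitist acceptance); Gbest tracks the strictly best pollen
seen, so the best-fitness trace is non-decreasing by construction. The run
uses a fixed iteration budget with no early stopping, and a single RNG
stream consumed in documented order (initialization first, then per
iteration per pollen), so identical seeds give byte-identical rankings. The
final output is Gbest ranked by $g(i)$, descending.

### Dynamics, and why $\gamma$ defaults to 0.99

Two properties of this move/acceptance pair shape the defaults:

* **Pollens far from Gbest freeze.** Their kept part $K$ is small, so
  their proposals are mostly random sets with fitness far below their
  incumbent, and greedy acceptance rejects essentially all of them. The
  effective search is carried by the pollens at (or within a swap or two
  of) Gbest.
* **Near Gbest, the move is a single-swap hill climb.** When a pollen
  equals Gbest and $\lceil \gamma Q\rceil = Q-1$, a global move drops one
  uniformly chosen member and refills one uniformly chosen node, accepting
  only non-decreasing swaps. Because the fitness is additive, single-swap
  local optima are exactly the global optimum, so this climb cannot get
  stuck — it is only a matter of proposal budget.

Small retention fractions therefore cripple the endgame: with
$\gamma = 0.5$ every global move discards half of a good set and must win
back the difference from uniform refills, and measured runs stall around
60 % of the closed-form optimum. With $\gamma = 0.99$ the same budget
reaches 99–100 %. Hence the default $\gamma = 0.99$, with two guards:
for any $\gamma < 1$ the retained portion is capped at $Q - 1$, so a
global move always resamples at least one slot (otherwise
$\lceil \gamma Q \rceil$ can round up to $Q$ and the move degenerates to a
no-op once a pollen reaches Gbest); $\gamma = 1$ is left exact, keeping the
pollen-equals-Gbest fixed point. A sensitivity test in the suite checks
that high retention outperforms low retention on average.

The proposal budget scales accordingly. A run makes about
$T_{\max} \times N \times p$ global proposals, and a swap that improves a
set with $b$ suboptimal members succeeds with probability of order
$(b/Q)(b'/|V|)$, so late-stage progress costs on the order of $|V|\,Q / b^2$
proposals per swap. The package's study sizes are chosen from this
estimate: the convergence-oracle test uses $|V| = 60$, $Q = 8$, 500
iterations (a budget that suffices with margin at that size); the
planted-recovery study uses the generator defaults ($|V| = 1000$,
$Q = 100$) with a 40 000-iteration budget (~30 s per run), which reaches
≈ 99 % of the closed-form optimum.

## The synthetic benchmark

`generateDataset()` emulates the five inputs of a real study:

* **Network** — a preferential-attachment backbone (igraph's
  Barabási–Albert sampler, $m = 3$ edges per arriving node), giving the
  heavy-tailed degree distribution of PPI data, with all planted complex
  cliques added on top.
* **Essentials** — 10 % of proteins, drawn uniformly.
* **Complexes** — 30 disjoint cliques of size 3–8 whose member slots are
  drawn from the essential pool with probability 0.8 (until it is
  exhausted), emulating the observation that essentiality concentrates in
  complexes.
* **Expression** — 36 time points. Members of a complex share a latent
  signal: $x = \mu + s\,z + \varepsilon$ with
  $s = \sigma\sqrt{\rho/(1-\rho)}$, so the expected within-complex pairwise
  correlation is exactly $\rho = s^2/(s^2+\sigma^2)$ (default
  $\rho = 0.7$, $\sigma = 1$); everything else is independent noise.
* **Localization** — one record per protein over 11 compartment labels;
  essentials are annotated at a designated hub compartment with
  probability 0.9, everything else uniformly.

Keeping complexes **disjoint** is a deliberate simplification: it makes the
planted correlation analytically exact (a protein in two complexes would mix
two latents and dilute both), at the price of $PC \in \{0, 1\}$ rather than
real multi-membership counts. Other features of real data the generator
does **not** model: false-positive/false-negative interactions as an
explicit corruption process, periodic (cell-cycle) expression structure,
multi-compartment annotations, and ID mismatches across sources. Passing
tests on this benchmark therefore show that the pipeline recovers planted
signal of the designed kind — not that it would achieve any particular
precision on a specific organism's data.

Under these defaults the planted essentials dominate all three scores by
construction, and the closed-form top-100 contains ≈ 90 true essentials;
an FPE run at the study budget recovers essentially the same set, while
degree centrality — whose top of the list is dominated by backbone hubs —
finds only ≈ 20–25. These numbers are recomputed, not quoted, by
`scripts/acceptance.R` and the test suite.

## Numerical choices and degenerate inputs

* Subgraph centrality uses the symmetric eigendecomposition of the
  adjacency matrix (exact, networks up to 5000 nodes) and a truncated
  walk-series fallback beyond, with convergence judged on the whole term
  matrix at tolerance 1e-8 (odd-walk diagonals vanish on bipartite graphs,
  so the diagonal increment alone is not a safe criterion).
* Eigenvector and information centrality are computed per connected
  component (the only well-defined reading on disconnected input);
  isolated nodes score 0; the eigenvector is the non-negative unit-norm
  Perron vector, making the sign deterministic.
* Networks are canonicalized at construction: self-loops dropped,
  duplicate edges (either orientation) collapsed, edges stored with the
  lexicographically smaller endpoint first.
* $SL$ estimation fails loudly if no known essential protein carries a
  localization record (every SL would be 0 and the GSC degenerate).
* All rankings break score ties by protein ID, ascending.

## Limitations

* The GSC fitness is additive, so the optimizer is, strictly speaking,
  unnecessary for the default score — the closed-form top-$Q$ is optimal.
  The implementation is faithful to the metaheuristic design and is
  validated against that closed form.
* SL uses the full known-essential list, as the original protocol does;
  when benchmarking against that same list this is circular by design.
  `proteinScores(..., excludeFromFrequencies = )` lets a benchmark hold
  its evaluation proteins out of the frequency estimation.
* The package assumes pre-matched protein IDs across the five inputs; no
  identifier mapping is attempted.
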