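# fpeNet

Essential proteins are the proteins a cell cannot live without. Because
they tend to sit in densely wired, module-rich parts of protein–protein
interaction (PPI) networks, they can be predicted computationally — but
topology alone is noisy, and the strongest predictors combine the network
with biological context. `fpeNet` is for computational/systems biologists
who want to run (and benchmark, on fully synthetic data) such a combined
predictor without any external downloads.

The package implements:

* **GSC scoring.** Each protein `i` gets
  `g(i) = SL(i) * [alpha * PeC(i) + (1 - alpha) * PC(i)]`, where
  `PeC(i) = sum over neighbors v of ECC(i,v) * PCC(i,v)` combines the edge
  clustering coefficient `ECC(i,j) = |N_i ∩ N_j| / min(d_i, d_j)` with the
  Pearson correlation of expression time courses; `SL(i)` sums, over the
  compartments `i` is annotated with, each compartment's frequency among
  known essential proteins' localization records; and `PC(i)` counts the
  protein complexes containing `i`. A candidate set `H` of `Q` proteins has
  fitness `GSC(H) = sum of g(i) over H`.
* **FPE**, a discrete, set-encoded flower pollination metaheuristic that
  searches the network for a high-fitness size-`Q` candidate set: a
  top-degree elite initialization with a perturbance factor, a
  Gbest-guided global move (keep the part of a pollen that agrees with a
  random portion of the best set found, refill the rest at random), an
  identity local move, a switch probability `p` between them, and greedy
  elitist acceptance.
* **Baseline centralities** used in comparisons — DC, SC, IC, EC, LAC, NC
  and PeC — under their standard definitions.
* **Evaluation**: precision at top-k cutoffs, precision–recall curves,
  jackknife (cumulative-hit) curves, multi-method comparison tables.
* **A seeded synthetic-data generator** producing all five inputs
  (network, expression, localization, complexes, essential list) with
  planted structure, so the whole pipeline is testable end to end.

See `vignettes/fpe-methods.Rmd` for the model, the parameter choices and
their rationale, and known limitations.

## Worked example

```r
library(fpeNet)

ds <- generateDataset(nProteins = 300, nComplexes = 10, seed = 7)
ds
#> SyntheticDataset: 300 proteins, 1049 interactions, 10 planted complexes, 30 essentials

scores <- scoreDataset(ds)                    # PeC, SL, PC and GSC per protein
res <- runFPE(ds@network, scores,
              fpeControl(Q = 30, iterations = 2000), seed = 1)
res
#> FPEResult: candidate set of 30 proteins, GSC fitness 32.457
#>   after 2000 iterations (initial fitness 15.0925)

head(gscRanking(res), 5)
#>   rank protein    score
#> 1    1   P0126 1.818254
#> 2    2   P0298 1.801062
#> 3    3   P0003 1.790235
#> 4    4   P0026 1.758021
#> 5    5   P0100 1.708303

precisionAtK(res, ds@essentials, 30)
#> [1] 0.8666667

dc <- centralityRanking(degreeCentrality(ds@network))
compareMethods(list(FPE = res, DC = dc), ds@essentials, cutoffs = c(10, 30))
#>   method top10 top30
#> 1    FPE     9    26
#> 2     DC     2     8
```

The optimizer started from the top-degree elite (fitness 15.1, a set
dominated by backbone hubs) and climbed to fitness 32.5; 26 of its 30
candidates are planted essentials, against 8 for plain degree centrality —
the expected picture when essentiality is concentrated in co-expressed,
co-localized complexes rather than in raw hubness.

## Command line

The same pipeline is available as subcommands of the installed `exec/fpe`
script (`synth`, `score`, `baseline`, `run`, `evaluate`), each writing a
JSON manifest with the resolved parameters and input digests next to its
output:

```sh
fpe synth --out data --n 1000 --complexes 30 --seed 7
fpe run --network data/network.tsv --expression data/expression.tsv \
    --subcell data/subcellular.tsv --complexes data/complexes.tsv \
    --essential data/essential.txt --q 100 --seed 42 --out ranking.tsv
fpe evaluate --ranking ranking.tsv --essential data/essential.txt \
    --cutoffs 25,50,100 --out report.tsv
```

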