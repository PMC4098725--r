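# cocin — conserved protein complexes from interolog networks

`cocin` identifies protein complexes conserved between two species. Given
two protein–protein interaction (PPI) networks $G_1(V_1,E_1)$,
$G_2(V_2,E_2)$ and a many-to-many ortholog-group mapping
$\theta \subseteq V_1 \times V_2$, it builds the **interolog network**
$G_I(V_I, E_I)$:

- $V_I = \{(p,q) : p \in V_1,\ q \in V_2,\ (p,q) \in \theta\}$ — nodes are
  homologous protein pairs;
- an edge joins $(p,q)$ and $(r,s)$ iff $(p,r) \in E_1$ **and**
  $(q,s) \in E_2$ — edges are interactions conserved in both species
  (*interologs*); nodes sharing a protein (paralog fan-outs of the
  many-to-many mapping) are linked by auxiliary shared-protein edges.

Because every interolog edge needs support from both species,
species-specific false positives vanish from $G_I$. Dense clusters of
$G_I$ — found by maximal-clique merging (CMC) or Markov clustering
(MCL) — are back-projected coordinate-wise into the two PPI networks,
yielding pairs of conserved complex predictions. Conservation between
complexes is scored with the **Multi-set Jaccard** over ortholog-group
multiplicities,

$$\mathrm{MSJ}(C_1,C_2)=\frac{\sum_g \min(I_{C_1}(g), I_{C_2}(g))}{\sum_g \max(I_{C_1}(g), I_{C_2}(g))},$$

which drives the gold-standard benchmark (pairs with MSJ ≥ 0.5, both
sizes > 3) and the evaluation: a prediction matches a curated complex at
Jaccard ≥ t = 0.50; precision is the fraction of predictions matched and
conserved-complex recall the fraction of gold pairs detected.

The package is for computational biologists who want to run this
cross-species pipeline on their own edge lists and catalogs, or to study
its behaviour under controlled conditions with the built-in synthetic
generator (planted conserved complexes, paralog expansions, species-level
noise).

## Worked example

```r
library(cocin)
sc <- generateScenario(scenarioParams(seed = 42))   # default study conditions
res <- runBaselines(sc@ppiA, sc@ppiB, sc@map,
                    sc@catalogA, sc@catalogB, sc@benchmark)
res$table
#>                 method n_predicted n_matched precision n_gold n_detected recall
#> 1                cocin          23        22 0.9565217     20         19   0.95
#> 2               direct          99        38 0.3838384     20         17   0.85
#> 3 conserved_subnetwork          39        38 0.9743590     20         18   0.90
```

The scenario plants 20 conserved complexes (sizes 4–8) in two networks of
~220 proteins each, with paralog expansions, 10% edge loss and twice as
many random species-specific noise edges as planted ones. The table reads:
the interolog pipeline (`cocin`) emitted 23 complex-pair predictions, 22
matched curated complexes on both sides (precision 0.96), and 19 of the 20
planted conserved pairs were detected (recall 0.95). Direct clustering of
the raw networks drowns in noise-derived clusters (precision 0.38), while
clustering each species' *conserved subnetwork* (interactions whose
orthologous counterparts exist in the other species) recovers most of the
precision benefit — the signal is conservation itself.

A command-line interface wrapping the same functions is installed at
`exec/cocin` (subcommands `simulate`, `score-edges`, `build-in`,
`cluster`, `project`, `benchmark`, `evaluate`, `run`):

```sh
Rscript "$(Rscript -e 'cat(system.file("exec","cocin",package="cocin"))')" \
  run --seed 42 --out cocin_run/
```

## Layout

- `R/` — S4 classes (`PPINetwork`, `OrthologMap`, `InterologNetwork`,
  `ComplexCatalog`, `ClusterSet`, `ConservedBenchmark`, …), readers and
  writers, interolog construction, clustering engines, evaluation,
  synthetic generator, pipeline.
- `vignettes/conserved-complexes.Rmd` — model, assumptions, parameter
  choices, and what the synthetic tests do and do not show.
- `tests/testthat/` — unit, property and end-to-end acceptance tests,
  including exhaustive-oracle checks of the interolog construction and
  clique enumeration.
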