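# godin

Protein function prediction by diffusing Gene Ontology (GO) terms through a
degree-oriented protein–protein interaction (PPI) network.

## The problem

Most network-based function predictors assume guilt-by-association: interacting
proteins share the same GO terms, so known annotations are copied across edges.
But interaction partners are frequently *not* functional equals — low-degree
proteins tend to perform few, specific functions, while high-degree hubs
perform general ones and participate in many processes. Copying terms verbatim
across such asymmetric interactions systematically mislabels partners whose
functions are merely *similar* or *related*, not identical.

`godin` is for computational biologists who want annotation transfer across a
PPI network that respects this asymmetry: instead of the known term itself, it
transfers the *relative* of the known term (a parent, grandparent, sibling,
child or grandchild in the GO DAG) whose specificity best matches the partner's
position in the network.

## The method

Given an undirected PPI network with degree map `d(.)` and a GO sub-ontology:

* **Orientation.** Every interaction is oriented from its low-degree
  ("proactive") endpoint to its high-degree ("reactive") endpoint; the descent
  direction of functional specificity is
  `O(vi, vj) = 1` if `d(vi) < d(vj)`, `0` if equal, `-1` otherwise.
  Equal-degree pairs get a bidirectional arch.
* **Functional difference.** `CV(vi, vj) = |1/d(vi) - 1/d(vj)|`, the
  coefficient variation of the interaction.
* **Term specificity.** Each term `g` has a semantic value
  `S(g) = dep(g) * (1 - log(desc(g) + 1) / log(G_total))`,
  where `dep` is its longest-path depth (root = 1), `desc` its number of
  transitive descendants, and `G_total` the sub-ontology size. Deep terms with
  few descendants — specific functions — score high; the root scores 0.
* **Diffusion.** For a known term `g` of protein `vi` crossing the edge to
  `vj`, the *ideal* term for `vj` has semantic value
  `S(g*) = (1 + CV(vi, vj))^O(vi, vj) * S(g)`,
  and the relative of `g` minimizing `|S(relative) - S(g*)|` is selected to
  annotate `vj` (equal-degree partners share terms verbatim). An iterative
  algorithm repeats this from "seed" proteins, protects existing annotations
  with the True Path Rule (a candidate that is an ancestor of a term the
  target already holds adds no information and is discarded), retires each
  seed after one round and consumes its edges, until no seed remains.

Evaluation follows the CAFA conventions: precision over proteins with at
least one prediction, recall over all targets, and their harmonic mean F.

## Worked example

The package ships a hand-built fixture of the canonical walk-through: protein
M (degree 3) is annotated with the specific term `g7` (S = 0.35), L with the
general ancestor `g4`, and M's hub partner E has degree 6:

```r
library(godin)
fx <- fig3_fixture()
st <- diffuse(fx$net, fx$dag, fx$initial, sem = fx$sem)
st
#> diffusion_state: 3 iteration(s), 15 annotated protein(s), 15 prediction record(s), 15 / 15 edges consumed
subset(st$history, protein %in% c("E", "J", "L", "A"))
#>   iteration protein term source_protein source_term ideal_value selected_value
#> 1         1       E   g8              M          g7      0.4083           0.40
#> 2         1       J   g8              M          g7      0.3792           0.40
#> 3         2       L   g7              E          g8      0.3429           0.35
#> 8         2       A   g8              J          g8      0.4000           0.40
```

Reading the first row: in iteration 1 the seed M diffuses `g7` to E across an
edge with `O = 1`, `CV = 1/6`; the ideal semantic value is
`0.35 * (7/6) = 0.408`, and among `g7`'s relatives the sibling `g8`
(S = 0.40) is nearest, so E is annotated with `g8` — a *more specific*
sibling function, not a verbatim copy. In iteration 2, E pushes `g8` back
toward L (`O = -1`, ideal `0.4 * 6/7 = 0.343`) selecting `g7`, and J shares
`g8` with its equal-degree partner A unchanged.

A command-line wrapper is installed at `inst/scripts/godin`
(subcommands `diffuse`, `evaluate`, `analyze`, `simulate`), e.g.:

```sh
Rscript inst/scripts/godin simulate --n-terms 50 --n-proteins 200 --out-prefix sim/ --seed 42
Rscript inst/scripts/godin diffuse --network sim/edges.tsv --obo sim/go.obo \
    --annotations sim/annotations.tsv --tie-policy first --out sim/pred.tsv
```

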