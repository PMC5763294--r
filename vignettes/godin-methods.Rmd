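---
title: "Degree-oriented diffusion of GO terms: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Degree-oriented diffusion of GO terms: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(godin)
```

## The model

`godin` treats annotation transfer across a protein–protein interaction (PPI)
network as a directed process. Its premises:

1. A protein's degree reflects how many activities it participates in; hubs
   perform general functions, low-degree proteins specific ones. Interactions
   are therefore oriented from the low-degree ("proactive") endpoint to the
   high-degree ("reactive") one, with descent direction
   $O(v_i, v_j) \in \{1, 0, -1\}$ by degree comparison.
2. The *amount* of functional difference across an interaction is the
   coefficient variation $CV(v_i, v_j) = |1/d(v_i) - 1/d(v_j)|$. It is 0 for
   equal-degree pairs and bounded above by 1.
3. A GO term's specificity is its semantic value
   $S(g) = dep(g)\,\bigl(1 - \log(desc(g)+1)/\log(G_{total})\bigr)$.
4. When a known term $g$ crosses an edge, the partner should not inherit $g$
   itself but the *relative* of $g$ (parent, grandparent, sibling, child or
   grandchild) whose semantic value is nearest to an ideal value
   $S(g^*) = (1 + CV)^{O}\, S(g)$ computed along the direction of transfer.
   Equal-degree partners share terms verbatim.

Predictions are unscored term sets; evaluation uses CAFA-style precision
(over proteins with at least one prediction), recall (over all targets) and
their harmonic mean.

## Conventions the formulas leave open

**Depth.** We define $dep(g)$ as the number of nodes on the longest `is_a`
path from the namespace root (root = 1), the dominant convention for GO term
"level". A shortest-path variant would compress deep multi-parent terms and
change semantic values, but not the architecture.

**$G_{total}$ scope.** Counted per sub-ontology, not over the whole GO. Terms
never leave their namespace during diffusion, and only under the
per-namespace count does the root's semantic value vanish exactly
($desc(root) + 1 = G_{total}$), matching the reading that the root carries no
functional information.

**Relations.** `is_a` only by default; `parse_obo(include_part_of = TRUE)`
additionally treats `part_of` as a parent link. `is_a` is the safe relation
for True-Path-Rule reasoning. Siblings are terms sharing at least one parent.

**Log base.** Immaterial — the base cancels in the ratio; we use natural log
and the test suite checks the log10 identity.

**Exponent sign.** The package supports two reciprocal conventions for the
ideal value, `worked_example` ($ (1+CV)^{+O} $) and `equation4`
($ (1+CV)^{-O} $). The default is `worked_example`: it is the one consistent
with both canonical numeric examples of the rule
(`ideal_semantic_value(0.35, 1, 1/6)` = 0.408 and
`ideal_semantic_value(0.4, -1, 1/6)` = 0.343), i.e. diffusing *toward* the
hub raises the target specificity scale by the coefficient variation and
diffusing away lowers it. Both conventions are exposed because the
transposed-sign formula also appears in circulation; their ideal values
multiply to $S(g)^2$, an identity the tests assert.

## The iterative algorithm

Each iteration takes a snapshot of the annotation state and then:

1. **Seed selection.** Candidates are annotated, non-retired proteins with at
   least one non-consumed edge. They are scanned greedily in descending order
   of annotation specificity (the maximum semantic value among the protein's
   current terms; ties broken by protein id), and a candidate adjacent
   through a usable edge to a seed already chosen this iteration defers to a
   later round. The deferral rule is this package's resolution of a genuinely
   open design point: some rule must decide which of two annotated partners
   on a live edge diffuses first, and specificity-first matches the model's
   premise that information originates at specific, proactive proteins. It
   also guarantees no edge is processed from both ends simultaneously.
2. **Forward diffusion.** Each seed pushes every known term across each of
   its usable edges: directed edges always (the TPR guard below decides what
   sticks), bidirectional edges only onto partners not yet annotated —
   equal-degree copies onto an already-annotated partner would pre-empt the
   directed inference that partner is due to receive.
3. **Reverse update.** Partners annotated *before* the current iteration
   that are reactive (higher degree) or equal to the seed diffuse their terms
   back onto the seed the same way. Partners first annotated within the
   iteration do not feed back.
4. **Retirement.** Seeds retire permanently and every edge incident to a
   retired seed is consumed, whether or not it carried a transfer.

The **True Path Rule guard** applies to every candidate: a term that already
annotates the target is a no-op, and a candidate that is an *ancestor* of a
term the target holds is discarded — under the True Path Rule the target
already implies it. Annotation sets therefore only grow; degrees are frozen
at network construction and never recomputed after edge consumption.

Termination is structural: every iteration retires at least one seed (the
top-priority candidate is never deferred) and consumes its edges, so the
iteration count is bounded by the number of proteins. The suite
property-tests halting, monotonic growth and TPR safety on 200 random
networks of 20–500 proteins.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `convention` | `worked_example` | exponent sign of the ideal value (dimensionless factor $(1+CV)^{\pm O}$) |
| `tie_policy` | `all_ties` | relatives tied in $\lvert S - S(g^*)\rvert$: keep all, or the lexicographically first for single-label output |
| `max_iterations` | $10^5$ | safety cap; never binding in practice (halting is structural) |
| `namespace` | single namespace of the ontology | sub-ontology to diffuse; molecular function, biological process and cellular component run independently |
| `excluded_codes` | IEA, NR, ND, IC | evidence codes dropped from prediction inputs; the analysis functions use the extended set adding IPI and IGI, whose annotations derive from interactions and would make interaction/annotation comparisons circular |
| `min_confidence` | off | optional pre-filter on a third edge-list column; never enters $O$ or $CV$ |

Ties in the relative selection are declared at absolute distance
$\le 10^{-9}$; all floating-point output is printed at 6 decimals.

## Synthetic data

`make_toy_dag()` grows a rooted random DAG (backbone chain fixing the depth
span, random attachment bounded by `max_children`, occasional second parents
creating diamonds). `make_network()` wraps preferential attachment
(`igraph::sample_pa`), whose heavy-tailed degrees emulate the hub structure
of curated PPI networks, with a density-matched uniform random graph as
contrast; the largest component is kept. Neither generator attempts to match
any specific curated network's degree distribution, term names, or
annotation depth profile quantitatively.

`plant_annotations()` creates ground truth *under the diffusion model
itself*: a `density` fraction (default 0.4) of the locally minimal-degree
proteins receives one or two random deep terms (depth $\ge 3$), and every
other protein's annotations are generated by running the diffusion. Hiding
all non-source proteins and re-diffusing under the same configuration
replays the identical trajectory, which is what makes exact-recovery tests
(F = 1 under `lexicographic_first`) possible. Passing those tests shows the
machinery is self-consistent — it does **not** show that real annotations
follow the generative assumption; performance on real networks depends on
how well degree asymmetry actually tracks functional specificity.

One caveat the suite documents deliberately: re-diffusing a
`lexicographic_first`-planted truth under `all_ties` need not reach recall
1. The first tied selection injects extra terms that change seed priorities,
consume different edges, diffuse onward as sources of their own, and can
TPR-block later true candidates; the two trajectories decouple, so false
positives are no longer confined to the recorded tie partners. The
corresponding assertions are kept strict and are expected to fail, as a
record of this property rather than a defect.

## Degenerate inputs and edge cases

* Isolated proteins and self-loops are dropped at network load (degree
  $\ge 1$ is required by $CV$); duplicate and reversed edges collapse.
* Obsolete terms never enter the DAG; alternate ids resolve to canonical
  terms; annotation rows with `NOT` qualifiers or unknown terms are dropped.
* A term with no relatives (a childless root) simply transfers nothing.
* Components with no annotated protein stay unannotated at termination.
* `holdout_evaluate()` errors rather than silently evaluating when the
  hidden fraction leaves no seeds or no targets; proteins with empty known
  sets are excluded from recall with a warning.
* Known and predicted sets are compared as-is by default; `tpr_closure =
  TRUE` closes both sides over ancestors first. The guard inside diffusion
  already suppresses redundant ancestors, so closure mostly rewards shallow
  predictions and is off by default.
* Quartiles in `cv_distribution_summary()` use the linear-interpolation
  quantile rule (R type 7), declared for reproducibility.

## Problem sizes

The test suite and examples run at desk scale, chosen to exercise every code
path while keeping the full suite around two minutes: toy DAGs of 15–50
terms, networks of 20–500 proteins, 1000 randomized relative-selection
trials, 200 random diffusion runs, and a 200-protein / 50-term planted
recovery benchmark.

## Known limitations

* Predictions are unscored sets; there is no threshold sweep or calibrated
  confidence, hence no $F_{max}$ curve.
* Orientation uses degree only; interaction confidence scores, edge types
  and directionality evidence (e.g. kinase–substrate) are ignored.
* Each sub-ontology diffuses independently; no cross-namespace inference.
* One pass of edge consumption: the algorithm never revisits consumed edges
  to refine early predictions.
* The semantic value ignores annotation corpora (it is structural, not
  information-content based), so two structurally identical terms score
  identically regardless of usage.
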