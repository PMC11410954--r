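---
title: "Methods: federated ensemble GNNs on patient-specific PPI graphs"
author: "fedgnn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: federated ensemble GNNs on patient-specific PPI graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fedgnn)
```

## The modelling problem

Many disease phenotypes are driven not by single genes but by perturbed
subnetworks of interacting proteins. fedgnn models each patient as the
*same* protein–protein interaction (PPI) graph, with the patient's own gene
expression values attached as node features, and treats diagnosis as a
*graph classification* problem: one binary label per patient graph. Because
clinical expression data usually cannot leave the institution that holds
it, the package also simulates a federated workflow in which only trained
models and vote weights — never patient-level data — cross site boundaries,
and in which human experts can reweight the ensemble's members.

The pipeline per site is:

1. build one attributed graph per patient (`buildPatientGraphs()`),
2. split patients into train/validation/test (`splitDataset()`),
3. train a graph neural network on the full PPI (`trainGNN()`),
4. attribute its predictions to edges and nodes (`computeImportance()`),
5. extract connected high-importance subnetworks (`extractSubgraphs()`),
6. train one small classifier per subnetwork and combine them by weighted
   majority vote (`trainEnsemble()`, `weightedVote()`),
7. detach the ensemble from the data and share it (`detachData()`).

`runFederation()` wires several such sites to a coordinator that
concatenates all local ensembles into a global federated model and, in
interactive (UI-mode) runs, averages expert-supplied vote weights.

## The graph classifier

No graph-neural-network library is part of the package's dependency set;
the classifier is implemented directly on BLAS matrix products, which for
cohort-scale problems (hundreds of patients, up to a few hundred genes) is
both fast and fully transparent.

The architecture is deliberately the smallest standard graph classifier
able to recover a planted expression signal. With $S = A + I$ the
adjacency-plus-self matrix of the shared topology and $H^{(0)}$ the
patients' node features (one expression value per node):

$$H^{(l)} = \mathrm{ReLU}\!\left(S\, H^{(l-1)} W^{(l)} + b^{(l)}\right),
  \qquad l = 1, \dots, L$$

followed by global mean pooling over nodes and a linear two-logit output
head trained with cross-entropy. Message passing therefore *sums* over a
node's neighbours and itself; pooling makes the output invariant to any
consistent node relabelling (a tested contract).

Tunable parameters (`gnnConfig()`), with defaults and rationale:

| parameter | default | why |
|---|---|---|
| `messagePassingLayers` | 2 | two hops cover the small subnetworks the ensemble uses; deeper stacks oversmooth tiny graphs |
| `hiddenDim` | 32 | ample capacity for 1-dimensional node features |
| `epochs` | 50 | Adam converges well before this on separable cohorts |
| `learningRate` | 0.01 | Adam default scale for inputs standardized to unit variance |
| `batchSize` | 16 | stable gradients at cohort sizes of tens to hundreds |
| `seed` | 1 | initialization (Glorot-uniform) and batch order are the only random draws |

Training is deterministic under the seed: two runs with identical inputs
and configuration produce bit-identical parameter vectors, and the
caller's RNG stream is restored afterwards. Ties in the predicted class
probabilities are broken toward class 0, a fixed rule required for
reproducible voting.

## Explainability and subgraph extraction

The explainer asks, for every edge, how sensitive the predicted-class
logit is to that edge's message contribution: the gradient of the logit
with respect to the corresponding entries of $S$ (both directions of the
undirected edge), computed by backpropagation. Sensitivities are averaged
as absolute values across correctly-classified patients — misclassified
patients would attribute a decision the model did not actually make; if no
patient is classified correctly the average falls back to all patients
with a warning. Node importance is the maximum over incident edges, which
keeps node and edge scores consistent when both are reported side by side.
Both are rescaled to $[0,1]$ by their maximum; an all-zero model yields
all-zero scores and no rescaling.

A gradient-based explainer was chosen over a learned edge mask because it
is deterministic, has no hyperparameters of its own, and is cheap enough
to serve as a reproducible oracle in tests; the module boundary
(`computeImportance()` returns plain scores) allows a mask-learning
explainer to be swapped in without touching extraction.

Extraction seeds one subgraph at each of the `nMembers` highest-importance
genes (ties broken lexicographically) and grows each subgraph greedily,
always adding the neighbouring gene of highest importance, until
`memberSize` genes are reached or the component is exhausted. Subgraphs
may overlap — neighbourhoods of important hubs legitimately share genes;
defaults are 10 members of 5 genes, capped at the network size. The
procedure is deterministic given the scores.

## Ensemble voting and expert weighting

Each subnetwork trains its own classifier on the features of its genes
only. The ensemble predicts by weighted majority vote over the members'
hard labels: class $c$ scores $\sum_i w_i\,[v_i = c]$ and the larger score
wins, exact ties going to class 0. Hard labels rather than probability
averaging match a voting committee of independently interpretable members.
Weights are non-negative with default 1 (neutral); there is no upper bound
and no normalization, because rescaling all weights by a positive constant
provably never changes a prediction. Member performance shown to experts
is computed on the validation split, and every interactive re-scoring
after a weight change uses the validation split only — the test split is
reserved for final reporting.

Performance is reported as accuracy, balanced accuracy, sensitivity and
specificity from the confusion counts; balanced accuracy is the headline
metric because cohorts need not be class-balanced.

## Federation

The coordinator/client protocol is simulated in-process as a ten-state
machine (`federationStates()`, `federationStep()`): shared INITIAL and
TERMINAL states, coordinator-only aggregation/waiting states, and
client-only working states. The coordinator holds no data and trains
nothing. Clients upload *detached* ensembles: subnetwork topologies, gene
names, architecture, flat parameter vectors and performance summaries —
no sample ids, labels or expression values, a contract asserted on every
simulated transcript. All numerics in a payload are serialized in
fixed-width scientific notation (10 significant digits), so a payload's
byte size depends only on the architecture and member count, never on the
cohort behind it.

The global model is the concatenation of all clients' members in client
registration order, preserving local member order — this fixes what "the
same index" means on every site when weights are exchanged. Expert weight
lists shorter than the global member count are padded with the neutral 1;
the aggregate is the elementwise arithmetic mean; lists longer than the
global member count are rejected (nothing meaningful exists for the extra
entries to vote on). Each aggregation round averages only the freshly
submitted lists; previous aggregates are not carried forward, so a round's
result is a pure function of its submissions. A client terminating while
a round is in flight, or left without a scripted action while others are
waiting on it, aborts the simulation with the transcript attached rather
than deadlocking silently.

## The synthetic benchmark

Real multi-site expression cohorts cannot ship with the package, so the
generator (`syntheticSpec()`, `generateDataset()`) builds the study
conditions every test runs under: a connected Barabási–Albert
preferential-attachment network over `nGenes` gene symbols (scale-free
degree structure, like curated PPI networks), a connected `signalSize`-gene
subnetwork grown breadth-first from a seeded random start, and a balanced
cohort whose background expression is i.i.d. $N(0, \sigma^2)$ with the
signal genes of class-1 patients shifted by `effectSize`$\cdot\sigma$.

Reference conditions: 100 genes at 2 attachment edges, 100 patients per
class, a 5-gene signal at a 2$\sigma$ shift, unit noise. A 2$\sigma$ shift
on a small gene set is a strong but realistic differential-expression
effect and gives the pipeline a recoverable target without making the
problem trivial; the additive Gaussian model is the simplest structure
under which both the classifier and the explainer have a well-defined
ground truth. What the generator does *not* emulate — gene–gene
correlation structure, batch effects, heavy-tailed counts, label noise,
covariate shift between sites — bounds what passing tests show: they
validate the machinery (training, attribution, extraction, voting,
federation) under a known signal, not clinical performance on real data.

At these conditions the full pipeline reaches global-ensemble test
balanced accuracy at or above 0.80, and signal genes out-rank background
genes in importance (one-sided rank-sum), in at least 8 of 10 seeds; the
test suite and `scripts/acceptance.R` recompute both. Problem sizes in the
suite were chosen as the smallest that exercise each property: protocol
tests run on 12–16-gene networks with a handful of patients, and the
recovery study runs the full reference conditions over 10 seeds.

## Numerical and design notes

- **Splits.** Stratified by label with largest-remainder rounding, so split
  sizes always sum to the patient count; defaults 0.6/0.2/0.2
  train/validation/test. Indices are 1-based, as everywhere in R.
- **Label coercion.** Any two-valued outcome is accepted; non-numeric
  values map lexicographically smaller → 0, and the mapping is reported.
- **Gene mismatches.** Genes present in only one of expression table and
  PPI are dropped (never imputed) and counted in a message; fewer than two
  shared genes is an error.
- **Normalization.** The generator emits already-standardized values;
  `buildPatientGraphs(..., zscore = TRUE)` offers optional per-gene
  z-scoring for raw inputs, off by default.
- **Degenerate inputs.** Single-class training sets, empty topologies,
  empty networks after self-loop removal, mismatched node sets and
  malformed weight vectors all raise typed errors early.
- **Isolated seeds.** A subgraph seed whose component is a single gene
  cannot form a valid (≥ 2 gene) member and is dropped with a warning;
  this cannot occur on connected networks such as the generator's.

## Known limitations

- Single expression channel per node; multi-omics node features (e.g.
  methylation) are an extension point, not implemented.
- The in-process simulation validates protocol logic, not networking,
  authentication or secure aggregation.
- Hard-label voting discards member confidence; probability averaging is
  out of scope by design.
- The gradient explainer attributes the model, not biology: high
  importance means the trained classifier relies on an edge, which is
  evidence, not proof, of mechanistic relevance.
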