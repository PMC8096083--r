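---
title: "Multi-source term embeddings and edge prediction: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-source term embeddings and edge prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

meshwalk learns one embedding per term of a controlled biomedical vocabulary
(MeSH headings are the motivating case) by fusing three data sources that
describe the same terms in structurally different ways, and evaluates the
embeddings by predicting held-out edges of a semantic-predication graph. This
vignette explains the model and its assumptions, the parameters that matter,
what the synthetic fixture does and does not emulate, and the design choices
made where the protocol left them open.

## The model

**Inputs.** Three views over one vocabulary $V$ of $N$ terms:

* a corpus $D$: each document is a *set* of at least two terms (the
  "indexing terms of one publication" view);
* an ontology $G_o$: the is-a hierarchy as a DAG, read as child $\to$ parent
  edges;
* a predication graph $G_s$: term pairs linked by one chosen semantic
  predicate (e.g. *treats*), read as subject $\to$ object edges.

Both graphs are stored and walked **undirected** with unit edge weights. The
second-order walk law below needs "neighbors of the predecessor", which is
ill-posed on a DAG walked forward (walks dead-end at roots and sinks, and no
dead-end rule is part of the model), and undirected walks are the standard
practice for this family of graph embedding methods.

**Step 1 — sequences.** Each source becomes a multiset of term sequences:

* each document yields one uniformly random permutation of its full term
  set, generated once per pipeline run;
* each graph is walked with second-order $(p, q)$-biased random walks:
  $r$ walks of length $l$ start at every node. Given the step
  $t \to v$, the next node $x$ is drawn from the neighbors of $v$ with
  unnormalized weight

  $$\pi_{vx} = \begin{cases} 1/p & d_{tx} = 0 \text{ (backtrack to } t) \\
  1 & d_{tx} = 1 \text{ (}x\text{ adjacent to } t) \\
  1/q & d_{tx} = 2 \text{ (otherwise)} \end{cases}$$

  normalized over the neighbors of $v$. The first step of a walk has no
  predecessor and is uniform over the neighbors of the start node. Isolated
  nodes emit length-1 walks rather than being skipped, so every vocabulary
  term receives an embedding; a length-1 sequence simply contributes no
  context pairs downstream.

**Step 2 — equalize and merge.** The three sequence multisets differ in
size, so the smaller ones are up-sampled with replacement to
$N_{\max} = \max(|S_c|, |S_o|, |S_s|)$ and the three are concatenated
(strategy `up`; the largest set passes through unchanged, so the dominant
source is preserved deterministically). Two ablation variants exist:
`none` (plain concatenation) and `up_down` (the up-sampled pool re-sampled
with replacement back to the original total). Union here is multiset
concatenation: collapsing duplicates would undo exactly what up-sampling is
for.

**Step 3 — skip-gram.** A single table $f : V \to \mathbb{R}^d$ is trained
by stochastic gradient ascent on the skip-gram likelihood with negative
sampling: for each (center, context) pair within a $k$-span window,

$$\log \sigma(f(w_c)^\top f(w)) + \sum_{u \in S(w)} \log \sigma(-f(u)^\top f(w)),$$

with $S(w)$ drawn **uniformly over the vocabulary** (deliberately not the
3/4-power unigram distribution). The exact objective it approximates — the
full softmax over $V$ — is implemented as well
(`full_softmax_log_likelihood()`) and serves as the oracle that training
must improve on small vocabularies.

**Evaluation.** Edges of $G_s$ are split 50/25/25 into train/validation/test
positives such that the train-positive graph has exactly the connected
components of $G_s$; equally many uniformly drawn non-edges per split are
the negatives. Embeddings are learned with the **train-positive graph only**
standing in for $G_s$ (asserted at run time: no held-out edge is in the walk
graph). An edge is represented by the average of its endpoint vectors, a
two-hidden-layer (256-unit, ReLU) softmax classifier is trained with
cross-entropy and early stopping, and six metrics are reported: P, R, F1 at
the argmax decision, MAP (step-interpolated average precision), AUROC, and
AUPRC (trapezoidal). Heuristic baselines (Jaccard, preferential attachment,
Adamic-Adar, common neighbors) are scored on the same train graph and the
same split files.

## Parameters

| parameter | default | meaning and rationale |
|---|---|---|
| $p$, $q$ | 0.25, 4 | return and in-out bias; these defaults make walks strongly local (backtracking favored 4:1, outward moves 1:4) |
| $r$, $l$ | 80, 10 | walks per node and walk length (nodes) |
| $d$ | 128 | embedding dimension |
| $k$ | 5 | window *span*: up to $(k-1)/2 = 2$ context terms per side. This is the literal reading of "a $k$-sized window centered on $w$"; note it differs from the word2vec convention where `window = 5` means 5 per side |
| negatives | 5 | per positive pair, uniform over $V$ |
| epochs, $\alpha$ | 5, 0.025 $\to$ $10^{-4}$ | standard skip-gram schedule, linear decay over all pairs |
| classifier | 2 × 256 ReLU, Adam $10^{-3}$, batch 64, patience 10, max 2000 epochs | see design notes |

The first six rows are the protocol's fixed settings; the optimizer rows are
package choices.

## Numerical and design choices

**Negative draws include the center term.** With a single shared vector
table, the term $-\sigma(\lVert f(w)\rVert^2)$ contributed by drawing $w$
itself as its own negative is the only force bounding vector norms — it
mirrors the $u = w$ term in the full-softmax denominator. Excluding self and
context draws (a word2vec habit motivated by its huge vocabularies and dual
tables) makes norms grow without bound and the exact objective *decrease*
during training; we verified both behaviors empirically, and the uniform-
over-$V$ reading is also the faithful one.

**Spanning forest, not just bridges.** Placing all bridge edges in the
training split is necessary but not sufficient for connectivity
preservation: removing two edges of one cycle disconnects a graph although
neither is a bridge. The train split therefore starts from a random
spanning forest (every bridge is in every spanning forest), is filled to
$\lceil 0.5|E| \rceil$ with shuffled remaining edges, and the component
structure is asserted after every split. If the forest alone exceeds the
train quota, train keeps the whole forest and the remainder is split evenly
between validation and test, with a warning when either ends up empty
(bridge-dominated graphs such as paths).

**Classifier batch size.** An "epoch" must contain several gradient updates
for patience-based early stopping to mean anything. With a batch of 512 —
a natural choice at the original data scale — a desk-scale split of a few
hundred edges gives exactly one Adam update per epoch, and the 10-epoch
patience window expires while the network still sits at its initial
$\ln 2$ plateau. The default batch is therefore 64. Edge features enter the
classifier raw: the informative component of the averaged-edge vector
includes its norm ($\lVert g \rVert^2$ encodes $f(u)^\top f(v)$), which
per-dimension standardization destroys (measured: mean test AUROC drops by
about 0.04).

**Metric conventions.** MAP and AUPRC both summarize the precision-recall
relationship but are reported as distinct numbers, so two interpolation
conventions are used deliberately: step interpolation (mean precision at
each positive) for MAP, trapezoidal integration over recall for AUPRC.
P/R/F1 are macro-averaged over the two classes by default (micro is a
flag); for heuristics, whose scores are unbounded, the P/R/F1 threshold is
the median test score — a documented convention, with the threshold-free
rank metrics primary. Adamic-Adar skips common neighbors of degree
$\le 1$ to avoid dividing by $\ln 1$.

**Seeding.** One master seed drives every stage through fixed offsets
(`derive_seed()`), so a pipeline run is bit-reproducible and each stage is
independently reproducible. The C++ trainer uses its own Mersenne Twister
seeded from the configuration, single-threaded.

## The synthetic fixture

Real inputs (PubMed indexing, the NLM tree, SemMedDB) are out of scope;
`make_fixture()` generates a desk-scale stand-in over one shared vocabulary:

* **predications**: a planted-partition graph — $n = 60$ terms in 2 equal
  blocks, within-block edge probability 0.3, between-block 0.02;
* **ontology**: a random rooted DAG (tree plus ~20% extra forward edges)
  whose tree parents prefer the home block, so the hierarchy echoes the
  partition;
* **corpus**: 2000 documents of 3–8 distinct terms; each term comes from
  the document's home block with probability 0.9.

Document sizes of 3–8 and a branching factor of 1.2 are desk-scale
realistic choices fixed once; the remaining values are the package's
standing study conditions.

What the fixture does *not* emulate matters for interpreting results. A
planted-partition graph has no transitivity beyond its density and no
degree heterogeneity, so conditional on the train graph, a held-out
within-block edge is statistically exchangeable with a within-block
non-edge: *no* method can separate them, and the achievable test AUROC is
capped well below what the method reaches on real predication graphs. An
oracle classifier given the true block labels, train degrees and
neighborhood-overlap scores measures this ceiling at about 0.73 mean test
AUROC over the five study seeds. The pipeline's own results under the
study conditions (five seeds, batch-64 classifier) are mean test AUROC
about 0.61 for `up`, 0.60 for `none`, 0.63 for `up_down`, and 0.63 for the
corpus-and-ontology ablation — so the qualitative orderings (up-sampling
helps; embeddings beat the heuristics; the ablation stays above chance)
are reproduced, while absolute numbers from the original full-scale corpora
are not reproducible at desk scale and are not targeted. Passing tests on
this fixture demonstrate the machinery and the orderings, not real-data
performance levels.

Problem sizes throughout the test suite (graphs of 6–60 nodes, corpora of
up to 2000 documents, 10^5-step walk simulations, five-seed pipeline
repetitions) were chosen as the smallest scales at which the statistical
assertions are stable.

## Known limitations

* Single predicate per predication graph; no multi-relation modeling.
* Walks are single-threaded; determinism is guaranteed per seed, not across
  numerically different BLAS builds for the classifier.
* The up-sampling equalizes *sequence counts*, not context-pair counts:
  sources with longer sequences (graph walks, length 10) still contribute
  more training pairs per sequence than short documents. This mirrors the
  protocol as stated.
* No frequency subsampling or minimum-count pruning: the vocabulary is
  controlled and every term is kept.
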