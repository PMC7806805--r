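---
title: "Methods: food-chemical graph embeddings in flavorwalk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: food-chemical graph embeddings in flavorwalk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Food pairing questions -- which ingredients go well together, which
compounds explain a flavor, which foods carry a given molecule -- draw on
two complementary sources of evidence: *statistical* co-usage of
ingredients across large recipe collections, and *chemical* composition,
i.e. which flavor or drug-like compounds occur in which foods.  Chemical
annotations cover only a small minority of ingredients (the
*chemical-hub* ingredients), so a useful food representation has to
propagate chemical information from that minority to the unannotated
majority while still respecting co-usage statistics.

`flavorwalk` implements a complete, desk-scale version of this program: a
heterogeneous graph over ingredients and compounds, metapath-constrained
random walks, skip-gram embeddings with a semi-supervised chemical
structure prediction (CSP) head, and the evaluation battery (category
clustering by NMI, cosine pairing queries, thresholded compound-food
relation prediction).

# The graph

Nodes are ingredients, flavor compounds and drug compounds.  Edges:

* **ingredient-ingredient**, weighted by normalized pointwise mutual
  information (NPMI) over a recipe corpus.  With `p(x, y)` the fraction of
  recipes containing both ingredients,

  $$\mathrm{pmi}(x;y) = \ln\frac{p(x,y)}{p(x)\,p(y)}, \qquad
    \mathrm{npmi}(x;y) = \frac{\mathrm{pmi}(x;y)}{-\ln p(x,y)} \in [-1, 1].$$

  NPMI is $-1$ for pairs that never co-occur (limit convention), $0$ at
  independence, $1$ for perfect co-occurrence.  Logs are natural; NPMI is
  base-invariant, so this is presentational only.

* **ingredient-compound**, unweighted, from curated tables.  An ingredient
  with at least one such edge is a chemical hub (`is_hub`).

An ingredient pair becomes an edge if it satisfies any of (A) each
ingredient in more than 20 recipes and the pair together in more than 5
("more than" read strictly, as printed); (B) NPMI at least 0.25; (C) the
global top-20 below-threshold pairs by NPMI (deterministic ties by pair
id).  Rule A is taken literally as sufficient on its own -- no additional
NPMI floor.  Pairs that never co-occur carry NPMI $-1$ and can enter only
through rule C; enumerating them is only feasible (and only matters) for
small vocabularies, so `select_ingredient_edges()` enumerates
never-co-occurring candidates only below a candidate-pair cap.

Numerical note: NPMI is evaluated in probability space,
`log((cj/n) / ((cx/n) * (cy/n)))`, which is bit-level symmetric in the two
tokens, and the perfect co-occurrence case (`cj == cx == cy`) returns the
limit value 1 structurally rather than through floating-point
cancellation.  A pair present in *every* recipe makes the denominator 0;
the limit value 1 is returned with a warning.

# Walks

Two food-specific metapath schemas route chemical information through
hubs: `C-H-N-H-C` (compound to compound through a hub, a non-hub, and a
second hub) and `N-H-C-H-N`.  Schemas extend cyclically up to the length
cap of 50 nodes without repeating the junction symbol, which is why mean
walk lengths sit close to the cap on well-connected graphs.  Each step
draws uniformly among neighbors of the required class; the "primed
symbols differ" rule is enforced by excluding the most recent node of the
target class whenever an alternative exists, and terminating the walk
when the repeat is the only option (this guarantees progress without
rejection sampling).  100 walks start from every node matching the first
symbol; a third strategy of schema-free uniform walks starts from every
node of every type so all nodes are reflected in the corpus.  Each
strategy gets its own `walks_per_start`; the three corpora are merged
with a seeded deterministic shuffle.

Walk generation is compiled (Rcpp) with a dedicated `mt19937_64` stream
derived from the user seed; identical seeds give byte-identical corpora.
`validate_walk()` re-checks any walk against schema and graph and is used
by the tests as the generator's independent auditor.

# Embedding objective

Training is skip-gram with negative sampling over the merged walk corpus.
For a center token $u$ with context $c$ within a window (default radius
5) and $M$ negatives $u^m$ drawn from $Q \propto$ corpus
frequency$^{0.75}$, the per-pair loss (negated for minimization) is

$$\ell = -\ln\sigma(X_{c}\!\cdot\!X_u)
         -\sum_{m=1}^{M}\ln\sigma(-X_{u^m}\!\cdot\!X_{c}),$$

where the *negative* terms dot the sampled node with the **context**
vector, following the printed form of the objective this package
implements (the classical formulation dots negatives with the center
vector; the two coincide in expectation at optimum but differ as written,
and we follow the source form literally).  Center vectors, context
vectors and negatives map to separate tables; negatives and centers share
the center table.  Dots are clipped to $\pm 30$ before exponentiation.

The CSP head is a linear map $f(u) = \sigma(W^\top x_u + b)$ from the
center embedding to 881 substructure probabilities (the standard 881-bit
binary substructure fingerprint).  Its loss is the mean binary
cross-entropy over the 881 bits, added with weight $\lambda \in [0,1]$
whenever the center token carries a fingerprint label -- a semi-supervised
arrangement in which unlabeled tokens simply skip the term.  Gradients
flow into $W$, $b$ and $x_u$.  By default the term applies per labeled
*center occurrence* (frequent compounds get proportionally more chemical
updates); `csp_mode = "per_epoch"` instead applies it once per labeled
node per epoch.  The head predicts structures only for nodes that have
labels -- in practice compounds -- resolving the ambiguity about
"predictions for all ingredients" in favour of the label-availability
reading.

Choices the objective leaves open, fixed here once:

* optimizer: plain SGD, rate 0.025 decaying linearly to $10^{-4}$ over
  all center positions;
* initialization: center vectors uniform in $(-0.5/d, 0.5/d)$, context
  vectors zero, $W$ Xavier-uniform, bias zero;
* $\lambda$ default 0.5, dimension default 300 (32 in the synthetic
  pipeline), window 5, $M = 5$;
* the $1/D$ normalization sits inside the CSP term and $\lambda$ outside,
  following the printed objective.

The reference trainer is single-threaded and byte-deterministic under the
seed: one `mt19937_64` stream drives initialization and sampling, and the
CSP weight matrix is initialized even when the head is disabled so that a
$\lambda = 0$ run and a head-free run consume identical RNG prefixes --
that is what makes the exact-reduction test possible.  The CSP inner loop
(two matrix-vector products and one rank-1 update per labeled occurrence)
is delegated to BLAS.

# Evaluation

* **Clustering**: k-means (Euclidean, 10 restarts, fixed seed) on the
  center vectors of labeled nodes, scored by NMI with arithmetic-mean
  normalization $2I(A;B)/(H(A)+H(B))$.  The clusterer and the
  normalization variant are choices; the source material fixes only the
  $[0,1]$ scaling.  Two constant labelings score 1 (identical partitions).
* **Pairing queries**: the query vector is the element-wise sum of the
  query tokens' center vectors; candidates (optionally restricted to a
  node class, e.g. non-hub ingredients) are ranked by cosine similarity,
  ties broken by token id, and query tokens are *not* excluded from the
  result list.
* **Relation prediction**: an edge (compound, food) is predicted when the
  cosine of their center vectors reaches a threshold; the threshold is
  explicit (or calibrated on labeled data by F1).  Confusion metrics
  require an explicit candidate universe for `tn`, accuracy and MCC --
  the package refuses to invent that denominator.  MCC is 0 by convention
  when a marginal factor vanishes.
* **Chemical coherence**: the category-level Jaccard matrix averages
  pairwise Jaccard similarity of hub ingredients' compound sets within
  and between categories.
* **Fingerprint decodability** (`fingerprint_auc`): a ridge linear probe
  from centered compound embeddings to each fingerprint bit, evaluated by
  exact leave-one-out via the hat-matrix identity, AUC averaged over bits
  with at least two compounds per class.  The probe's hypothesis class (a
  linear readout) matches what the CSP head optimizes, so it measures
  precisely the information the head is meant to inject.  An earlier
  cosine-neighbor-vote probe was discarded as an instrument because it
  saturates at community level on the synthetic worlds -- it returned
  identical values for materially different embeddings -- which makes it
  unable to detect bit-level chemical signal at all.

# The synthetic world

Real inputs (million-recipe corpora, curated compound databases) are out
of scope; a deterministic generator produces worlds with planted
structure instead:

* `n_communities = 3` communities of 20 ingredients; each of 2000 recipes
  picks a home community uniformly and draws 6 distinct ingredients, each
  slot from the home community with weight 0.8 versus 0.1 for each other
  community;
* the first 30% of each community's ingredients become hubs, linked to
  all 10 of their community's compounds (the last compound of each
  community is drug-like, the rest flavor compounds);
* each compound's 881-bit fingerprint sets its community's disjoint
  40-bit signal block and then flips every bit with probability 0.02;
* categories are the communities, mapped onto the canonical nine-label
  vocabulary.

Everything is byte-deterministic under the generator seed.  The generator
emulates *community structure* -- same-category foods sharing compounds
and co-occurring in recipes -- and deliberately does not emulate the
heavy-tailed token frequencies, ingredient multiplicity or annotation
sparsity of real recipe corpora.  A green end-to-end test therefore
establishes that the pipeline recovers planted community structure, not
that it reproduces production-scale behaviour.

**Edge selection at desk scale.**  The production thresholds (counts over
a million-recipe corpus; NPMI 0.25) are calibrated to a far larger,
sparser world.  In a 2000-recipe, 60-ingredient world every pair clears
the absolute-count rule, and no pair can structurally reach NPMI 0.25
(with recipe-level probabilities around $10^{-2}$, attainable NPMI for
genuinely associated pairs peaks near 0.1).  The synthetic graph builder
therefore defaults to NPMI $> 0$ with the count rule disabled: the
independence point is the scale-free boundary between planted
within-community association (about $+0.1$) and cross-community noise
(about $-0.13$), derived from the generator's own statistics.  The
production operation keeps the standard defaults; `edge_args` overrides
are available in both directions.

# Degenerate inputs and numerical corners

* PMI of a never-co-occurring pair is undefined; `pmi()` returns `-Inf`
  and callers must handle it; `npmi()` maps it to the limit $-1$.
* All logits are clipped at $\pm 30$ before `exp`/`log`; losses are
  finite by construction.
* Isolated nodes yield single-node uniform walks; schemas with no
  eligible start nodes yield an empty corpus with a warning, never an
  error.
* Negative sampling resamples on collision with the positive context
  token; a vocabulary of size one is rejected.
* k-means requires at least `k` labeled nodes; fewer is an error, not a
  silent fallback.

# Known limitations

* Single-threaded training only; the multi-worker throughput of
  production word2vec implementations is out of scope, as are GPU paths
  and hierarchical softmax.
* The negative-sampling form follows the printed objective (negatives
  against the context vector); consumers comparing against classical
  word2vec should expect small systematic differences.
* Rule C (rescue) enumerates never-co-occurring pairs only for small
  vocabularies (configurable cap).
* The candidate universe for relation-prediction accuracy/MCC must be
  supplied by the caller; the package does not construct one.
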