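---
title: "Methods: learning chemical ontology classes from structures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: learning chemical ontology classes from structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemont)
```

## The classification problem

A structure-annotated chemical ontology is a directed acyclic graph of
terms connected by subsumption (`is_a`) edges. Some terms carry a SMILES
string describing a fully defined molecular structure; within the hierarchy
these are typically leaves. chemont frames ontology classification as
supervised learning over this graph with a deliberate distinction:

* a **class** is a term subsuming multiple members — it is what we predict;
* a **leaf member** is a term with no `is_a` children *and* a SMILES
  annotation — it is a classification instance.

Both conditions matter. A childless term without a structure cannot be an
instance (there is nothing to encode), and a structure-bearing term with
children (as happens in ChEBI, e.g. alanine above L-alanine) acts as a
class. Leaf status is decided *after* restricting the graph to the
designated root branch, because in ChEBI the useful instances sit below
'molecular entity' and pruning other branches can turn inner terms into
leaves of the retained subgraph.

## Balanced, non-overlapping N×M sampling

Real chemical ontologies are diamond-shaped: general structural features
combine compositionally, so mid-level classes overlap heavily in their leaf
membership. Training single-label classifiers on raw class memberships
would therefore leak molecules across classes and across train/test splits.
The sampler builds a problem of N classes × M members under two rules:

1. **Disjointness** — a leaf member is assigned to at most one class, even
   though it genuinely belongs to several.
2. **Smallest first** — candidate classes (terms with at least two leaf
   members in their descendant closure) are processed in ascending order of
   leaf-member count, ties broken by term identifier. A class is filled by
   drawing M unused members uniformly at random from its closure when
   enough remain, and skipped otherwise, until N classes are filled.

Smallest-first matters because a small class's members are often a subset
of a larger class's: serving the large class first can consume exactly the
leaves the small class needed (the test suite constructs such an ontology
where a largest-first greedy provably starves the nested class). Skipping
partially fillable classes rather than aborting reads the selection as a
greedy scan; an error is raised only when fewer than N classes can be
filled at all, reporting how many could. Members are drawn from the full
descendant leaf closure, not only direct children, so an assigned class
need not be a direct parent of its members — which is why the evaluation
also measures distance to the *sampled* class separately from the asserted
parents. No chemical-diversity weighting is applied.

Splitting is stratified per class with largest-remainder rounding, so each
class's contribution to each partition is within one molecule of exact
proportionality, and a (0.7, 0.1, 0.2) split of 500 classes × 100 members
puts exactly 10,000 of 50,000 records in test. The validation fraction may
be zero: the classical models have no tuned hyperparameters and use a
two-way split, while the network tracks a validation set per epoch.

## Encodings

**Fingerprints.** Fixed-length classifiers consume a 1024-bit hashed
topological path fingerprint: every linear path of length 1–7 through the
molecular graph (atom types, bond types, branches) is hashed into the bit
string. The implementation delegates to OpenBabel's FP2 fingerprint through
ChemmineOB, which is exactly this construction, behind a stable contract
(same SMILES + configuration → same bits). Other widths are produced by
XOR-folding the 1024-bit string; the walk bound is fixed at 7 by the
backend and the configuration refuses other values rather than silently
computing something else. Because the OpenBabel reader is lenient (it
silently repairs strings such as `"C("`), a syntactic SMILES validator —
balanced parentheses and brackets, matched ring-closure digits, legal
characters, no dangling bond — guards the encoder and raises a structured
condition carrying the offending strings, so callers can log and skip them
the way a practitioner skips unprocessable inputs.

**Token sequences.** The sequence model consumes SMILES as a language.
Character-level tokenisation emits one token per character. Atom-grouped
tokenisation additionally merges two-letter periodic-table symbols
(uppercase+lowercase, e.g. Cl, Br, Si, Na) into single tokens — inside or
outside bracket atoms — while everything else stays single-character;
multi-digit ring indices in particular stay split into digits because they
are unbounded and would blow up the embedding vocabulary. Both modes
concatenate back to the input exactly; their length difference is exactly
the number of two-letter element occurrences. The rare ambiguity where a
two-letter symbol could also read as two atoms (Sc as scandium versus
sulfur + aromatic carbon) is resolved greedily toward the element with a
warning; genuine scandium is vanishingly rare in organic SMILES, and the
warning makes the choice auditable. Vocabularies reserve index 0 for
padding and 1 for unknown tokens so unseen test tokens degrade gracefully
instead of crashing inference.

## Classifiers

Eight classical algorithms sit behind one fit/predict surface, all
multi-class single-label (exactly one prediction per molecule, never an
abstention): one-vs-rest logistic regression, K-nearest neighbours, a
decision tree, random forest, naive Bayes, LDA, and SVMs with linear, RBF
and sigmoid kernels. They are backed by the standard R implementations
(glmnet, class, rpart, randomForest, e1071, MASS). Choices worth recording:

* **LR** fits one ridge-penalised binary discriminator per class
  (penalty 1e-3, effectively a numerically stabilised unregularised fit on
  these problem sizes) and predicts the argmax of the per-class scores;
  ties resolve to the lowest class index for determinism. The test suite
  checks the prediction equals the argmax of the exposed per-class scores.
* **Naive Bayes** treats fingerprint bits as two-level factors (Bernoulli
  likelihood with Laplace smoothing). Modelling 0/1 bits as Gaussians
  degenerates when a bit is nearly constant within a class.
* **LDA** drops columns with (near-)zero pooled within-group variance
  before fitting — they carry no discriminative information and break the
  covariance estimate — and records the retained columns in the model.
* Hyperparameters the backends need but the problem does not pin down
  (k = 5, 500 trees, SVM cost 1) are library defaults, frozen in the spec
  object and stored with the model.

## The sequence network

The multi-label model is: token embedding (64) → unidirectional LSTM (128)
→ dense ReLU (128) → dropout (0.2) → per-class sigmoid, trained with
binary cross-entropy and Adam (learning rate 1e-3, batch 32), 100 epochs by
default, membership threshold 0.5. No deep-learning framework is involved:
the forward pass, masked backpropagation through time and Adam are
implemented in C++ (Armadillo) inside the package, with gradient clipping
at global norm 5 and a forget-gate bias of 1. Right-padding uses the
reserved index 0 and freezes the LSTM state at padded positions, so the
"output of the last cell" is the state at the last real token. The
analytic gradients are verified against central finite differences in the
test suite, which is the strongest correctness check available for a
hand-built network.

Labels are **single-hot** by default — the positive class is the class the
molecule was sampled for, because predictions are scored against the
sampled classes. Since a molecule truly belongs to many classes, an
ancestor-closure **multi-hot** mode is available in `labelMatrix()` for
experiments where superclasses should also count as positives; it is not
the default because the sampling deliberately flattens multi-membership.

Prediction thresholds strictly (score > 0.5): a molecule whose scores all
fall at or below the threshold receives the empty set, i.e. the network
*abstains*. Abstentions are enumerable from the prediction set and are
reported by the evaluator, because they are precisely the molecules for
which a fallback method would be needed in practice. Strict comparison
makes the boundary case deterministic.

All stochastic pieces — initialisation, shuffling, dropout — derive from
the configuration seed, so training is bit-reproducible. Because the loss
surface is non-convex, learning-quality checks average over (take the best
of) three seeds rather than asserting on one.

## Evaluation

Per-class precision, recall and F1 follow the standard confusion-count
formulas, with the zero-denominator convention that an undefined ratio is
reported as 0 and flagged — this keeps macro averages total over classes
with no predictions. Multi-label predictions additionally yield a
per-molecule F1 (between predicted and true class sets) whose distribution
separates confident correct predictions from abstentions.

The ontology-aware metric measures, for every pair of an asserted and a
predicted parent class, the number of subsumption edges between them: 0 for
an exact match, 1 when one is the direct parent of the other, and so on.
Two design points are genuinely open and decided as follows:

* **Direction.** A prediction can land in a sibling branch with no
  ancestor/descendant relation to the asserted class. Distances are
  therefore computed on the subsumption graph treated as *undirected*
  (breadth-first search), which agrees with the parent/grandparent examples
  and is total over realistic prediction sets; genuinely disconnected pairs
  get a no-path marker, are excluded from means, and are counted
  separately. The BFS implementation is cross-checked against an
  independent graph library oracle on random DAGs.
* **Weighting.** The overall mean weights each (asserted, predicted) pair
  equally, not each molecule; per-molecule minima/maxima/means are reported
  alongside so either view is available.

Prediction sets are first *condensed* to an antichain — any predicted class
that subsumes another predicted class is dropped — so that trivially true
high-level predictions (e.g. a root such as 'molecular entity') inflate
neither the parent counts nor the path statistics. Condensation is
idempotent and its output provably contains no ancestor pairs; the mean
condensed set size per molecule is the parent-count statistic.

## The synthetic fixture generator

`makeToyOntology()` emulates the features of a real chemical ontology that
the pipeline is sensitive to: a single root, configurable depth, mid-level
classes, and an `overlapFraction` of leaves attached under two classes,
reproducing the diamond-shaped overlap that makes the sampler's
disjointness constraint binding. Class identity is encoded chemically: each
class has a distinctive SMILES fragment (halogens, hetero groups,
triple-bond motifs — none producible by the random decoration grammar) and
every member embeds its class motif inside random decoration drawn from a
small grammar of acyclic C/O/N chains, an optional branch and one optional
ring. Validity is guaranteed by construction, not rejection sampling.

What the fixtures do *not* emulate: realistic chemistry (valence-checked
but arbitrary molecules), deep multiple inheritance, unbalanced class
sizes, aromatic ring variety, and the sheer scale of ChEBI. Passing tests
therefore demonstrate that the machinery is correct and that the learners
recover a recoverable signal; they say nothing about absolute performance
on a real ontology, where class boundaries are far subtler. This is the
reason the checks are property-based (round-trips, invariants, oracle
agreement, learnability of a planted signal) rather than comparisons
against any published benchmark number.

## Problem sizes and numerical choices

The shipped checks run at desk scale on one CPU: the classical condition
uses 10 classes × 50 members (500 molecules, 1024-bit fingerprints), the
network condition 5 classes × 200 members (1000 molecules, ≤ 30 epochs),
chosen as the smallest sizes at which the planted signal is comfortably
learnable and the learning-rate/threshold defaults are exercised
end-to-end. Sampling, splitting and training are deterministic given the
seed; the binary cross-entropy is clamped at 1e-7 for numerical safety;
argmax and threshold ties are resolved deterministically as described
above.

## Known limitations

* The path metric's undirected-shortest-path reading of "subclass
  relationships traversed" is an assumption where predictions are neither
  ancestors nor descendants of the truth; a common-ancestor path convention
  would give systematically longer sibling distances.
* The OBO reader covers the subset of OBO 1.2/1.4 a subsumption analysis
  needs ([Term] stanzas, `id`, `name`, `is_a`, `is_obsolete`,
  `property_value` SMILES); it is not a general OBO implementation.
* The LSTM is intentionally minimal (no bidirectionality, attention or
  gradient-descent refinements beyond Adam); it is the reference
  architecture, not a performance ceiling.
* Fingerprints are limited to the hashed linear-path family; count-based
  and circular fingerprints are out of scope.
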