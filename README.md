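# chemont

Machine learning for **structure-based chemical ontology classification**.

Chemical ontologies such as ChEBI arrange chemical classes in a subsumption
(`is_a`) hierarchy, with fully defined molecular entities — terms carrying a
SMILES structure — sitting at the leaves. Manually curating such an ontology
does not scale to the size of open chemical databases, so an obvious question
is how well machine learning can place a novel structure into the ontology.
chemont turns a structure-annotated OBO ontology into supervised
classification problems and evaluates both classical classifiers and a
recurrent neural network on them, entirely offline: a synthetic-fixture
generator produces toy ontologies with motif-bearing SMILES leaves, so every
stage is testable without downloading anything.

## What the package implements

* **Ontology handling** — OBO parsing into a subsumption DAG (`is_a` edges
  only, obsolete terms dropped, optional restriction to a root branch such as
  ChEBI's *molecular entity*), the class/member distinction (a *leaf member*
  is a term with no children and a SMILES annotation), ancestor/descendant
  queries, antichain condensation, and shortest-path distances on the
  undirected subsumption graph.
* **Balanced N×M sampling** — a dataset of N classes × M members each is
  drawn by iterating candidate classes *smallest first* (by leaf-member
  count) and sampling M still-unused leaf members from each class's
  descendant closure, so that no molecule is assigned to two classes; this
  keeps train/test splits cleanly separable despite the heavily overlapping
  ("diamond-shaped") class structure of real chemical ontologies. Stratified
  train/validation/test splitting is reproducible from a seed.
* **Encodings** — 1024-bit topological path fingerprints (a hash of all
  linear paths of length 1–7 through the molecular graph, computed by
  OpenBabel's FP2 via ChemmineOB) for fixed-length classifiers, and two
  SMILES tokenisations for the sequence model: character-level, and
  atom-grouped where two-letter element symbols (Cl, Br, Si, Na, …) become
  single tokens while ring-closure digits stay split.
* **Classifiers** — a uniform fit/predict surface over one-vs-rest logistic
  regression, K-nearest neighbours, a decision tree, random forest, naive
  Bayes, linear discriminant analysis and SVMs with linear/RBF/sigmoid
  kernels; all are multi-class single-label and never abstain.
* **Sequence network** — token embedding → unidirectional LSTM → dense
  (ReLU) → dropout → per-class sigmoid, trained with binary cross-entropy
  (implemented in C++/Armadillo with masked backpropagation through time and
  Adam). Scores above a 0.5 threshold yield a possibly-empty multi-label
  prediction set; the empty set is an *abstention*.
* **Evaluation** — per-class precision `TP/(TP+FP)`, recall `TP/(TP+FN)` and
  F1 (their harmonic mean), per-molecule F1 distributions, abstention
  reporting, and an ontology-aware **path-length metric**: for every
  (asserted, predicted) parent pair, the number of subsumption edges between
  the two classes (0 = exact match), with per-molecule min/max and overall
  means, and condensation of prediction sets so that no counted class
  subsumes another.

## Worked example

```r
library(chemont)

# a toy ontology: 5 classes, each marked by a distinctive SMILES fragment
fx <- fixtureSpec(nClasses = 5, membersPerClass = 40, seed = 1)
g  <- makeToyOntology(fx)
g
#> OntologyGraph with 206 terms and 205 is_a edges
#>   root: TOY:0000001
#>   leaf members (structure-bearing leaves): 200

ds <- selectBalanced(g, 5, 40, seed = 1)     # balanced 5 x 40, disjoint
sp <- splitDataset(ds, c(0.8, 0, 0.2), seed = 1)

X  <- smilesFingerprint(setNames(sp$smiles, sp$member_id))
tr <- sp$split == "train"; te <- sp$split == "test"
model <- trainClassical(classifierSpec("LR"), X[tr, ], sp$class_id[tr])
pred  <- setNames(predict(model, X[te, ]), sp$member_id[te])
scoreSingleLabel(pred, setNames(sp$class_id[te], sp$member_id[te]))
#>     class_id tp fp fn precision recall f1
#>  TOY:C000001  8  0  0         1      1  1
#>  ...                                    1
```

Every held-out molecule of every class is recovered (per-class F1 = 1.0,
macro-F1 = 1.0) because each toy class is marked by a fragment the
fingerprint captures; the path-length report on the same predictions gives a
mean of 0 (every prediction is the asserted class). The two tokenisations of
benzoyl chloride illustrate the encodings:

```r
tokenizeSmiles("ClC(=O)C1=CC=CC=C1", mode = "atom")[[1]]
#>  [1] "Cl" "C"  "("  "="  "O"  ")"  "C"  "1"  "="  "C"  "C"  "="  "C"  "C"
#> [15] "="  "C"  "1"
```

18 character-level tokens versus 17 atom-grouped tokens: the difference is
the chlorine symbol, which is one token in atom-grouped mode.

The staged pipeline (`runSample()` → `runEncode()` → `runTrain()` →
`runEvaluate()`, or `runAll()`) drives the same steps from a JSON
configuration and writes each stage's artifact plus a provenance record; a
thin command-line wrapper lives at `inst/scripts/chemont-cli.R`.

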