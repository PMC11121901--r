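---
title: "Methods: rare-disease term extraction and weakly supervised classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rare-disease term extraction and weakly supervised classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raremesh)
```

## The problem

MeSH, the controlled vocabulary used to index MEDLINE/PubMed, has no
subtree that gathers rare diseases: the *Rare Diseases* descriptor
(`D035583`) is an attribute term, not a parent, and many rare diseases
exist in MeSH only as supplementary concepts without tree numbers.
`raremesh` builds a rare-disease MeSH term set by cross-referencing a
disease ontology with MeSH, uses it to weakly label citation records into
three classes (rare disease / non-rare disease / other), and trains and
evaluates a transformer-style text classifier on the result. Everything
runs offline against seeded synthetic fixtures that emulate the real input
dialects.

## Term extraction

A Mondo-style ontology is read from OBO-graph JSON. A node counts as
**rare** when any of its subset or property annotations, after stripping
the IRI path, equals the marker string (default `"rare"`); releases differ
in how the subset IRI is spelled, so matching on the final path component
is deliberately lenient, and the marker is configurable.

A node counts as a **leaf** when it has no `is_a` children anywhere in the
graph — not merely no rare children. This is the plain reading of "leaf
term"; evaluating leafness on a rare-only subgraph would admit interior
nodes whose children happen not to be marked, which would then drag whole
MeSH subtrees into the term set during expansion.

Each rare leaf contributes MeSH identifiers by the first route that
succeeds:

1. direct `MESH:` xrefs (`direct_xref`);
2. otherwise `GARD:` xrefs resolved through a two-column GARD→MeSH table
   (`via_gard`). Unresolvable GARD ids are skipped with a warning — they
   are expected, not exceptional, in real mappings.

Direct xrefs win when both routes exist, mirroring the "direct link or via
GARD" fallback ordering. MeSH ids are normalized to bare UIs and both
descriptor (`D…`) and supplementary-concept (`C…`) UIs are accepted. When
several nodes reach the same MeSH id, one provenance row is kept
(direct over GARD, then smallest origin id) so the output is a set,
independent of node iteration order.

## MeSH tree expansion

Descriptors carry dotted tree numbers (`C06.101.100`); descent is lexical:
`t2` descends from `t1` iff `t2 == t1 + "." + suffix`. "Adding children"
is implemented as **all descendants**, not depth-1 children: MeSH indexing
conventions are subtree-based, and stopping at depth 1 would silently drop
grandchild diseases. Supplementary concepts have no tree numbers, so they
are kept in the set but never expanded. A descriptor reachable through any
of its polyhierarchy positions is included once. `D035583` is always
added. Expansion is monotone and idempotent, and the package tests verify
it against a brute-force pairwise prefix scan.

## Record filtering and weak labeling

Citation records pass the quality filter iff, checked in this order:
"Journal Article" is among the publication types; the PMID is nonempty and
not already accepted (first occurrence wins — revision semantics are out
of scope); the publication year parses; title and abstract are nonempty;
at least one MeSH heading is present; and the text (title and abstract
joined with a single space — the join is unspecified upstream, a single
space is the minimal choice) has ≥ 128 whitespace-delimited tokens.
Rejections carry the first failed reason, which makes the rejection log
stable and auditable.

Labels follow a fixed cascade over the document's MeSH headings:

1. any heading in the rare term set → `RARE`;
2. else any heading with a tree number under `C` (Diseases) or `F03`
   (Mental Disorders) → `NON_RARE`;
3. else → `OTHER`.

Supplementary-concept headings can satisfy rule 1 by plain set membership
but have no tree numbers, so by default they cannot satisfy rule 2. An
option (`map_supplementary`) maps them to their mapped-to descriptors
before the tree test; it is off by default because the literal rule text
operates on the headings as given, and the original procedure's behaviour
on this point is unstated. Single-letter prefixes are matched as whole
MeSH categories, longer prefixes as whole leading segments, so `F03` does
not match a hypothetical `F030…`.

News articles are labeled by the same cascade with no token-count floor,
and are used exclusively as an external test set — never for training.

## Dataset construction

`sample_balanced()` draws the same number of documents per class with a
per-class reservoir (Algorithm R), then shuffles and cuts contiguously
into train/validation/test. Reservoir sampling keeps the pass
single-scan — the real baseline corpus is far larger than memory — and the
whole procedure is a deterministic function of the plan's seed. The
reference design is 24,000 records per class split 20,000/2,000/2,000
(72,000 in total); desk-scale tests use the same machinery at tens to
hundreds of examples.

## The classifier

The encoder is a **contract**, not a dependency: anything that maps a text
to a `d_model`-dimensional start-token representation qualifies. The
package ships a toy encoder — lowercased whitespace tokens hashed into a
frozen seeded embedding table, with the start-token state defined as
`tanh(start + mean(token embeddings))` as a stand-in for attention
pooling. It is deliberately simple: deterministic, fast, and sufficient
for corpora whose classes use disjoint vocabularies. A pretrained
125M-parameter encoder (`d_model = 768`) is the intended production
plug-in but is not bundled.

The head is the standard sequence-classification head: dropout → dense
`d_model × d_model` with tanh → dropout → projection `d_model × K` →
softmax, with `K = 3`. Dropout defaults to 0.1 (the convention for this
head; the rate is not specified upstream) and is the identity at
evaluation time. Inputs truncate at `max_tokens = 512`, the standard
encoder limit.

Training is minibatch cross-entropy over **all** classes — background
exclusion applies only to the selection metric — using an Adam optimizer
implemented in the package (β₁ = 0.9, β₂ = 0.999, ε = 1e-8, no weight
decay, no schedule or warmup; only the learning rate is exposed, matching
the published hyperparameter table of batch size 32, learning rate 3e-5,
10 epochs). At each epoch end the model is scored on the validation set by
micro-F1 excluding the background class, and the best epoch's parameters
are returned (earliest epoch wins ties). Forward, backward and the
optimizer are plain matrix code, which keeps runs bit-reproducible under
the training seed.

**Learning-rate choice at desk scale.** 3e-5 is a fine-tuning rate for a
large pretrained encoder. The desk-scale setting instead trains a freshly
initialised head on frozen random features, where the conventional Adam
rate for a shallow head is 1e-3–1e-2; package tests and the acceptance
script use 0.01. With ~10 epochs over a few hundred examples, 3e-5 would
move the head weights by ~1e-2 in total and could not learn from random
initialisation; this is a property of the optimization scale, not of the
architecture.

## Metrics

Per-class metrics are one-vs-rest: precision `TP/(TP+FP)`, recall
`TP/(TP+FN)`, `F1` the harmonic mean, with the convention that a metric
with zero denominator is 0 (not `NaN`) so that degenerate fixtures remain
testable. Macro averages are unweighted means over the included classes;
micro averages recompute from summed tallies. For single-label multiclass
data with all classes included, micro precision = micro recall = accuracy
— an identity the tests exercise on random confusion matrices.

**Background exclusion** removes only the background class's own
one-vs-rest tallies from the averages. Errors involving the background
still count: a background-true document predicted foreground is a false
positive of that foreground class, and a foreground-true document
predicted background is a false negative. Equivalently, only correctly
classified background documents vanish from the scores. This is the
standard treatment of a catch-all class and the literal reading of
"omitting correctly classified background instances".

Internal values are kept at full precision; presentation rounds to two
decimals with round-half-even. A consequence worth knowing: recomputing a
per-class F1 from *printed* (2-decimal) precision and recall does not
always round back to the *printed* F1, because the table's F1 was computed
from full-precision values — e.g. printed (0.69, 0.54) gives 0.6059, which
rounds to 0.61 while the full-precision original printed as 0.60.

## What the synthetic fixtures do and do not show

The generators emit the same dialects the real readers consume (MeSH
descriptor/supplementary XML, OBO-graph JSON, GARD TSV, PubMed citation
XML, news JSONL) with internally consistent structure: every tree number's
parent prefix exists, ontology negative controls (rare non-leaves,
non-rare leaves, unresolvable GARD links) are present, citation records
straddle the 128-token threshold and include duplicate/missing-field
rejects, and each generator writes golden answer files computed by
independent brute-force scans, so pipeline tests are self-verifying.

Class vocabularies are pairwise disjoint, which makes the classes
separable by construction — a bag-of-words oracle is perfect on the
fixture. Passing the training-sanity check therefore shows that the
optimization, selection and metric machinery work, **not** that the toy
encoder can separate real abstracts, where class vocabularies overlap
heavily and performance is encoder-bound. Reported full-scale results
(≈0.86 accuracy on abstracts, ≈0.70 on news) require the multi-gigabyte
PubMed baseline, current ontology releases and a pretrained encoder, and
are outside what this package's offline tests can or should claim.
Linguistic realism of generated text is a non-goal.

Problem sizes used by the test suite and acceptance script — tens of
descriptors, ~40 citations, 360 labeled examples, 10 training epochs at
`d_model = 32` — were chosen as the smallest scales at which every code
path (expansion, rejection reasons, both extraction routes, checkpoint
selection) is exercised.

## Known limitations

- There is no universally agreed rare-disease list; the extracted term set
  is a function of the ontology release and marker spelling, so real-world
  counts are version-bound and not asserted.
- Whether tree expansion should take immediate children or all descendants
  is ambiguous upstream; this package takes descendants (see above) and
  treats the alternative as a configuration a fork could make.
- The duplicate-PMID rule is first-accepted-wins; MEDLINE revision/delete
  files are not handled.
- The toy encoder ignores word order entirely; it exists to exercise the
  contract, not to model language.
- News-article evaluation inherits the annotation quality of its expert
  headings; articles without headings default to the background class.
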