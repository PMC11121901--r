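# raremesh

Weakly supervised three-class text classification of biomedical documents
into **rare disease**, **non-rare disease** and **other**, built from
disease-ontology / MeSH cross-references.

Rare diseases are individually uncommon but collectively affect hundreds of
millions of people, and the literature and news coverage about them is hard
to find: MeSH (Medical Subject Headings, the NLM controlled vocabulary used
to index MEDLINE/PubMed) has a *Rare Diseases* attribute descriptor
(`D035583`) but no subtree gathering the rare diseases themselves. `raremesh`
is for text-mining researchers and public-health informaticians who need to
separate rare-disease documents from other disease literature at corpus
scale without manual annotation.

## What the package does

1. **Rare-disease term set.** Parse a Mondo-style disease ontology
   (OBO-graph JSON) and collect every *leaf* term carrying the "rare"
   subset marker that links to MeSH — directly via a `MESH:` xref, or
   indirectly via a `GARD:` xref resolved through a GARD→MeSH mapping.
   Expand the resulting MeSH descriptors to all of their MeSH-tree
   descendants (tree numbers are dotted paths; descent is lexical prefix
   extension) and add `D035583`. Supplementary-concept UIs (C-prefixed, no
   tree numbers) are kept but never expanded.
2. **Weak labeling.** Filter MEDLINE/PubMed citation XML down to journal
   articles with a unique PMID, a valid date, title, abstract, MeSH
   headings, and at least 128 whitespace-delimited tokens of joined
   title + abstract. Label each document by a fixed cascade over its MeSH
   headings: any term-set heading → `RARE`; else any heading in the
   Diseases (`C`) tree or Mental Disorders (`F03`) subtree → `NON_RARE`;
   else `OTHER`.
3. **Balanced datasets.** Reservoir-sample the same number of documents per
   class and split them into disjoint train/validation/test sets, all
   deterministic under a seed.
4. **Classifier.** A transformer-style sequence classifier: an encoder
   (a contract — any text → start-token representation map; a seeded toy
   encoder ships for offline work) feeding the standard classification head

   `dropout → dense(d_model × d_model, tanh) → dropout → projection(d_model × K) → softmax`,

   trained with minibatch cross-entropy and Adam, selecting the epoch with
   the best validation micro-F1 *excluding the background class*.
5. **Background-aware metrics.** Per-class precision `TP/(TP+FP)`, recall
   `TP/(TP+FN)`, `F1 = 2PR/(P+R)`, plus micro and macro averages computed
   with and without the background class; exclusion drops only the
   background's own tallies — errors involving the background still
   penalize the foreground classes.
6. **Synthetic fixtures.** Seeded generators emit miniature MeSH XML,
   ontology JSON, GARD TSV, citation XML and news JSONL with golden answer
   files, so the whole pipeline runs and tests offline.

## Worked example

```r
library(raremesh)

spec     <- fixture_spec(seed = 42)
dir      <- tempfile()
mesh_fix <- make_mesh_fixture(spec, dir)
onto_fix <- make_ontology_fixture(spec, mesh_fix, dir)
vocab    <- parse_mesh(mesh_fix$descriptor_path, mesh_fix$supplementary_path)
graph    <- parse_ontology(onto_fix$ontology_path)
gard     <- read_gard_mapping(onto_fix$gard_path)
terms    <- build_rare_term_set(extract_rare_mesh_terms(graph, gard), vocab)
print(terms, n = 5)
#> # A tibble: 13 × 3
#>   mesh_id source              origin_node
#>   <chr>   <chr>               <chr>
#> 1 C800001 direct_xref         MONDO:0000007
#> 2 D035583 seed_attribute_term <NA>
#> 3 D100001 direct_xref         MONDO:0000002
#> 4 D100002 direct_xref         MONDO:0000003
#> 5 D100003 direct_xref         MONDO:0000004
```

Thirteen MeSH identifiers make up the fixture's rare term set: ontology
leaves linked directly or via GARD, their tree descendants (`tree_child`),
and the always-included attribute descriptor. Training the toy-encoder
classifier on a separable synthetic corpus and evaluating the held-out
test split:

```r
corpus <- make_labeled_corpus(spec, n_per_class = 120)
ds     <- sample_balanced(corpus, sampling_plan(120, 80, 20, 20, seed = 42))
model  <- classifier_model(toy_encoder(), model_config(), init_seed = 42) |>
  train_classifier(ds[ds$split == "train", ], ds[ds$split == "val", ],
                   train_config(batch_size = 32, learning_rate = 0.01,
                                max_epochs = 10, seed = 42))
glance(model)
#> # A tibble: 1 × 6
#>   d_model n_classes dropout_rate trained best_epoch best_val_micro_f1_excl_bg
#> 1      32         3          0.1 TRUE             6                         1

evaluate_classifier(model, ds[ds$split == "test", ])
#> Confusion matrix (rows = truth):
#>           predicted
#> truth      RARE NON_RARE OTHER
#>   RARE       20        0     0
#>   NON_RARE    0       19     1
#>   OTHER       0        0    20
#>
#> Accuracy: 0.98
#> ...
#>  without_background   micro      1.00   0.98 0.99
```

The report shows per-class precision/recall/F1 and the four averages; note
how excluding the background keeps the one `NON_RARE → OTHER` error as a
false negative (micro recall 0.98) while the 20 correctly classified
`OTHER` documents drop out. `tidy()`, `glance()` and `autoplot()` methods
are available on models and reports.

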