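# orphannot

Dictionary-based annotation of scientific articles with rare-disease
taxonomy concepts, in R.

Research on a given rare disease is hard to find: bibliographic databases
carry no rare-disease classification, and the reference nomenclature for
rare diseases (OrphaNet, with its ORPHAcodes, synonyms, poly-hierarchy and
monthly deprecations) is too specific and too dynamic for supervised text
classifiers — there is no large gold-labeled corpus to train on. `orphannot`
implements the unsupervised alternative: annotate each article record
(title, abstract, keywords) by matching disease names and synonyms from the
taxonomy directly in the text, and make the whole pipeline measurable.

The package is aimed at bibliometricians, ontology engineers and biomedical
NLP practitioners who need concept-level indexing of literature by rare
disease, together with an evaluation harness and fully synthetic test data.

## What it computes

For a document *d* (fields joined as `title [SEP] abstract [SEP] keywords`)
and a compiled dictionary of normalized surfaces *s* with token count *k*:

* **Exact matching** — every token-boundary-aligned occurrence of *s* in the
  normalized token stream of one field of *d* is a mention with score 1.
  Shorter matches strictly contained in a longer match are suppressed
  (leftmost-longest convention).
* **Fuzzy matching** — every window *w* of *k−1*, *k* or *k+1* consecutive
  tokens is scored by normalized Levenshtein similarity

  ```
  sim(w, s) = 1 − lev(w, s) / max(|w|, |s|)
  ```

  and kept when `sim ≥ 0.8` (the default threshold). Short surfaces
  (acronyms, under 4 characters by default) are never fuzzy-matched.
* **Concept resolution** — mention concepts are mapped through
  `replaced_by` deprecation links to the current active code (e.g. an
  article saying "β thalassemia major" is indexed under the current
  "beta-thalassemia" code).
* **Propagation** — each matched concept is also assigned to its ancestors
  at hierarchy distance 1–2 (shortest path in the parent DAG).
* **Evaluation** — micro-averaged precision/recall/F1 over (document,
  concept) pairs, plus CorrectRatio (≥ 1 correct concept per document) and
  ExactRatio (predicted set identical to gold), each with a Wilson score
  confidence interval.
* **Counting** — full-counting publication tables per disease, country or
  subject area, with unique-publication and total-match totals.

A seeded generator (`generate_bundle()`) produces disease-like taxonomies,
corpora with injected exact/synonym/misspelled mentions and matching gold
labels, so every step above is testable without licensed data.

## Worked example

```r
library(orphannot)

tax <- taxonomy(list(
  list(code = "ORPHA:79201", preferred_label = "lysosomal storage disease"),
  list(code = "ORPHA:355",   preferred_label = "Gaucher disease",
       synonyms = c("glucocerebrosidase deficiency"),
       parents = "ORPHA:79201"),
  list(code = "ORPHA:848",   preferred_label = "beta-thalassemia"),
  list(code = "ORPHA:231214", preferred_label = "beta-thalassemia major",
       status = "deprecated", replaced_by = "ORPHA:848")
), version_tag = "demo")

dict <- build_dictionary(tax)

rec <- article_record(
  doc_id   = "pmid:1",
  title    = "Enzyme therapy in Gaucher disease",
  abstract = "We studied gauchers disease and a case of β thalassemia major.",
  keywords = c("lysosomal storage disease", "enzyme replacement")
)

ann <- annotate_document(rec, dict, tax)
ann$mentions[, c("code", "start", "end", "surface", "match_type", "score")]
#>          code start end                   surface match_type  score
#> 1   ORPHA:355    18  33           Gaucher disease      exact 1.0000
#> 2   ORPHA:355    51  67          gauchers disease      fuzzy 0.9375
#> 3   ORPHA:848    82 101       β thalassemia major      exact 1.0000
#> 4 ORPHA:79201   109 134 lysosomal storage disease      exact 1.0000
```

The misspelling "gauchers disease" is one edit from a 15-character surface
(similarity 1 − 1/16 = 0.9375, above threshold), and "β thalassemia major"
normalizes onto the deprecated label and is indexed under the current code
`ORPHA:848`. Scoring against a gold standard:

```r
gold <- gold_set(list("pmid:1" = c("ORPHA:355", "ORPHA:848")))
evaluate_annotations(prediction_sets(list(ann), include_propagated = FALSE), gold)
#> <orpha_eval> 1 documents | tp 2 fp 1 fn 0
#>   precision:     0.667 [0.208, 0.939]
#>   recall:        1.000 [0.342, 1.000]
#>   f1:            0.800
#>   correct_ratio: 1.000 [0.207, 1.000]
#>   exact_ratio:   0.000 [0.000, 0.793]
```

The false positive is the (correct but unlabeled) group concept matched in
the keywords — the usual tension between indexing depth and gold coverage.

A command-line front end over the same functions lives in
`inst/cli/orphannot.R` (`annotate`, `evaluate`, `synth`, `stats`
subcommands).

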