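---
title: "Annotating rare-disease literature: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating rare-disease literature: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orphannot)
```

## The problem and the model

Rare diseases have no indexing infrastructure in bibliographic databases,
and no corpus large enough to train a supervised classifier against the
reference nomenclature (OrphaNet-style: ~9,000+ concepts, synonyms,
poly-hierarchical parent structure, monthly updates with deprecations and
renames). `orphannot` therefore treats article indexing as unsupervised
dictionary-based named-entity recognition plus concept normalization:

1. **Document preparation.** Title, abstract and keywords are concatenated
   with a `[SEP]` sentinel between fields (keywords joined by `"; "`).
   Full text is deliberately not used: at the precision levels this kind of
   pipeline targets, full text mostly adds false positives. Matches never
   cross a field boundary; a literal `[SEP]` inside a field is neutralized
   so a document always has exactly three fields.
2. **Normalization.** Both dictionary terms and documents pass through the
   same deterministic policy: Greek letters spelled out (β → beta),
   diacritics stripped, lowercasing, non-alphanumeric characters to spaces
   (digits are kept — "type 1" is meaningful), whitespace collapsed. The
   policy is idempotent, and every step tracks character provenance so
   mention offsets always refer to the original text.
3. **Exact matching.** Token-boundary-aligned lookup of normalized surfaces
   ("disease" never matches inside "diseased"), implemented as a hashed
   index over token n-grams. A shorter match strictly contained in a longer
   one is suppressed (leftmost-longest): "hodgkin lymphoma" wins over the
   nested "lymphoma"; the generic concept is recovered, if wanted, by
   propagation rather than by double annotation. Surfaces shared by several
   concepts produce one mention per concept — there is no statistical
   disambiguation, by design.
4. **Fuzzy matching.** For a term of $k$ tokens, windows of $k-1$, $k$,
   $k+1$ consecutive tokens are scored by
   $\mathrm{sim}(w,s) = 1 - \mathrm{lev}(w,s)/\max(|w|,|s|)$ on the
   normalized strings, and kept at $\mathrm{sim} \ge 0.8$. This is the
   simplest token-window similarity consistent with a "token-based
   matching, score ≥ 0.8" contract; the function is a plain normalized
   Levenshtein and deliberately not tunable per term. Windows identical to
   the term are dropped — exact matching owns those, which makes
   threshold 1.0 collapse the combined engine exactly onto exact-only.
5. **Resolution and propagation.** Mention concepts are resolved through
   `replaced_by` chains to active codes (renamed concepts keep matching
   under their old labels), then each direct concept is propagated to its
   ancestors at shortest-path distance 1–2 in the parent DAG, with
   provenance (source concept and distance) recorded.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `fuzzy_threshold` | 0.8 | minimum normalized Levenshtein similarity; raising it trades recall for precision |
| `max_dist` | 2 | propagation bound, read as ancestor distance strictly less than three (i.e. 1 or 2); exposed as a parameter because "within three" is the other defensible reading |
| `min_term_chars` | 4 | surfaces shorter than this (mostly acronyms) are exact-matched only (`short_term_policy = "exact_only"`) or dropped (`"drop"`); fuzzy-matching 2–3-character strings would destroy precision |
| `resolve_mentions` | TRUE | resolve deprecated codes after matching; dictionary compilation also remaps deprecated labels, so both orders of the resolve/match question are covered |
| `confidence` | 0.95 | Wilson interval level in evaluation reports |

## Evaluation conventions

Precision, recall and F1 are micro-averaged over pooled (document, concept)
pairs. The averaging choice is not dictated by the task; micro-averaging is
the standard for multi-label indexing benchmarks and makes the Wilson
interval well-defined as a binomial proportion on pair counts (precision on
$tp+fp$ pairs, recall on $tp+fn$). Per-document (example-based) averaging is
available behind `averaging = "example"`. CorrectRatio and ExactRatio are
document-level proportions (interval on $n$ documents). No interval is
attached to F1 — it is not a binomial proportion, and inventing an $n$ for
it would overstate certainty. Precision with zero predictions is defined
as 0; empty gold sets are excluded by construction (a document enters the
gold only with at least one in-taxonomy label, mirroring how evaluation
sets are filtered out of corpora labeled with other vocabularies such as
MeSH).

Gold construction from an external vocabulary goes through an explicit
label-to-code mapping (`filter_gold_by_taxonomy()`); building that mapping
is out of scope — an identity mapping is accepted.

## The synthetic generator: what it emulates, what it does not

`synthetic_spec()` fixes every condition of a test corpus: taxonomy size
and depth, synonym and acronym rates, a deprecated fraction (default 0.1,
with `replaced_by` links), number of documents, mentions per document
(1–3), probability that a mention uses a synonym (0.3), misspelling
probability and exact edit count, and document length (60–120 distractor
tokens). One integer seed determines every byte of the output.

Two constructions make expected engine behavior analytic rather than
statistical:

* no generated surface is a contiguous token-subsequence of another
  concept's surface, so exact matches are unambiguous by construction;
* distractor tokens are drawn from a disjoint syllable alphabet and
  rejected unless at edit distance ≥ 3 from every dictionary token, so
  distractor text can produce neither exact matches nor (at threshold 0.8)
  fuzzy ones.

Under these conditions a noise-free bundle is recovered at exactly
micro P = R = 1 by the exact engine, and a single-edit misspelling regime
separates the engines cleanly: exact recall 0 on perturbed mentions,
combined recall 1 (one edit on a ≥ 12-character surface scores
≥ 1 − 1/12 ≈ 0.92). Injected mentions never overlap each other or field
boundaries, which keeps the gold labels unambiguous.

What the generator does **not** emulate: real linguistic context (documents
are token salads, so there are no hard polysemy cases), realistic synonym
morphology (synonyms are independent names, not inflectional variants),
abbreviation conventions beyond initial-letter acronyms, and external
vocabularies (cross-vocabulary filtering is tested with identity-plus-gap
mappings). Passing on synthetic data therefore demonstrates correctness of
the machinery — matching, scoring, propagation, bookkeeping — not
field-realistic precision/recall levels, which depend on the taxonomy
version and corpus at hand.

## Numerical and degenerate-input choices

* Similarity comparisons reuse the same floating-point expression in the
  prefilter and the final check, so windows scoring exactly at the
  threshold are never lost to rounding (1 − 0.8 is not exactly 0.2 in
  binary).
* Wilson bounds are clamped to exact 0/1 at $k = 0$ / $k = n$, where the
  closed form is exact but floating point leaves residue.
* Tie-breaks are deterministic everywhere: dictionary entries are ordered
  by (code, surface); count-table rows by count descending then key;
  propagated provenance by (code, distance, source).
* Degenerate inputs fail loudly: records with all fields empty, taxonomies
  with parent or `replaced_by` cycles, dangling references, thresholds
  outside (0, 1], and terminal-deprecated codes (an error class carrying
  the code) are all rejected with named errors.
* The edit-perturbation operator verifies the achieved Levenshtein distance
  and resamples if edits collapse, so "exactly $n$ edits" is a guarantee,
  not an expectation; edits never touch token boundaries.

## Problem sizes used in the test suite

The shipped tests run the matcher-versus-brute-force comparison on 200
generated documents (≤ 300 tokens) against dictionaries of ≤ 50 entries,
recovery and regime checks on bundles of 100–200 documents over 30–100
concepts, the Wilson grid over $n \in \{1, 10, 100\}$, and propagation
checks on random DAGs of up to 100 nodes — sizes chosen so the full suite
exercises every code path in a few minutes on one core while keeping the
brute-force oracles exhaustive.

## Known limitations

* No negation or context handling: "no evidence of Gaucher disease" still
  matches — inherent to dictionary NER.
* No abbreviation detection (long-form/short-form alignment) and no
  embedding-based semantic matching; acronym synonyms only match exactly.
* Ambiguous surfaces annotate all mapped concepts; disambiguation is left
  to downstream consumers.
* The taxonomy interchange format is this package's JSON schema; a
  converter from native nomenclature XML releases is an extension point,
  not included.
* Count tables implement full counting only; fractional counting is out of
  scope.
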