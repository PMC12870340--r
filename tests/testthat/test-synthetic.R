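test_that("generated taxonomies satisfy every structural invariant", {
  spec <- synthetic_spec(n_concepts = 100, max_depth = 4, seed = 3)
  tax <- generate_taxonomy(spec)   # the constructor runs the validator
  expect_s3_class(tax, "orpha_taxonomy")
  expect_length(tax$concepts, 100)
  # depth bound: every concept reaches a root in at most max_depth steps
  depth_of <- function(code) {
    d <- 0L
    frontier <- code
    while (length(frontier)) {
      parents <- unique(unlist(lapply(frontier, function(cd)
        tax$concepts[[cd]]$parents)))
      if (!length(parents)) break
      d <- d + 1L
      frontier <- parents
    }
    d
  }
  depths <- vapply(active_codes(tax), depth_of, integer(1))
  expect_true(all(depths <= 4))
  # all deprecated concepts resolve to an active one
  dep <- setdiff(names(tax$concepts), active_codes(tax))
  for (cd in dep) {
    expect_true(resolve_concept(tax, cd) %in% active_codes(tax))
  }
  # single-concept edge case
  one <- generate_taxonomy(synthetic_spec(n_concepts = 1, seed = 9))
  expect_length(one$concepts, 1)
  expect_length(one$concepts[[1]]$parents, 0)
})

test_that("no surface is a token-subsequence of another concept's surface", {
  tax <- generate_taxonomy(synthetic_spec(n_concepts = 60, seed = 21))
  surf <- list()
  for (cp in tax$concepts) {
    for (s in c(cp$preferred_label, cp$synonyms)) {
      if (nchar(s) < 8) next  # acronyms live in their own namespace
      surf[[length(surf) + 1L]] <- list(code = cp$code,
                                        toks = strsplit(s, " ")[[1]])
    }
  }
  is_sub <- function(a, b) {
    na <- length(a); nb <- length(b)
    if (na > nb) return(FALSE)
    any(vapply(seq_len(nb - na + 1L), function(i)
      all(b[i:(i + na - 1L)] == a), logical(1)))
  }
  violations <- 0L
  for (i in seq_along(surf)) {
    for (j in seq_along(surf)) {
      if (surf[[i]]$code == surf[[j]]$code) next
      if (is_sub(surf[[i]]$toks, surf[[j]]$toks)) violations <- violations + 1L
    }
  }
  expect_equal(violations, 0L)
})

test_that("the whole bundle is a pure function of the spec", {
  spec <- synthetic_spec(n_concepts = 25, n_docs = 10, typo_prob = 0.5,
                         seed = 12345)
  b1 <- generate_bundle(spec)
  b2 <- generate_bundle(spec)
  expect_identical(serialize(b1, NULL), serialize(b2, NULL))
  # a different seed changes the output
  b3 <- generate_bundle(synthetic_spec(n_concepts = 25, n_docs = 10,
                                       typo_prob = 0.5, seed = 54321))
  expect_false(identical(serialize(b1, NULL), serialize(b3, NULL)))
  # and generation does not disturb the session RNG stream
  set.seed(1); before <- runif(3)
  set.seed(1); invisible(generate_bundle(spec)); after <- runif(3)
  expect_identical(before, after)
})

test_that("perturb_term hits the requested edit distance exactly", {
  for (i in 1:40) {
    term <- c("gaucher disease", "niemann pick disease type b",
              "glucocerebrosidase deficiency")[[(i %% 3) + 1]]
    n_edits <- (i %% 2) + 1L
    out <- perturb_term(term, n_edits, seed = i)
    expect_equal(as.integer(adist(term, out)), n_edits,
                 info = sprintf("%s / %d edits / seed %d", term, n_edits, i))
    # token structure preserved: same number of tokens
    expect_equal(length(strsplit(out, " ")[[1]]),
                 length(strsplit(term, " ")[[1]]))
  }
  expect_identical(perturb_term("gaucher disease", 1, 7),
                   perturb_term("gaucher disease", 1, 7))
  expect_error(perturb_term("gaucher disease", 0, 1), ">= 1")
  expect_error(perturb_term("ab", 2, 1), "too short")
})

test_that("injection log reconstructs the gold labels exactly", {
  spec <- synthetic_spec(n_concepts = 30, n_docs = 25, typo_prob = 0.3,
                         seed = 8)
  b <- generate_bundle(spec)
  from_log <- split(b$injection_log$concept, b$injection_log$doc_id)
  from_log <- lapply(from_log, function(x)
    sort(unique(vapply(x, function(cd) resolve_concept(b$taxonomy, cd),
                       character(1), USE.NAMES = FALSE))))
  expect_identical(from_log[order(names(from_log))],
                   b$gold$labels[order(names(b$gold$labels))])
})

test_that("noise-free corpora are recovered perfectly by the exact engine", {
  spec <- synthetic_spec(n_concepts = 40, n_docs = 40, typo_prob = 0,
                         seed = 17)
  b <- generate_bundle(spec)
  dict <- build_dictionary(b$taxonomy)
  anns <- annotate_corpus(b$corpus, dict, b$taxonomy,
                          annotator_config(fuzzy = FALSE, propagate = FALSE))
  ev <- evaluate_annotations(prediction_sets(anns, FALSE), b$gold)
  expect_equal(ev$precision, 1)
  expect_equal(ev$recall, 1)
  expect_equal(ev$exact_ratio, 1)
})

test_that("distractor text cannot produce exact matches", {
  spec <- synthetic_spec(n_concepts = 20, n_docs = 10,
                         mentions_per_doc = c(1L, 1L), seed = 4)
  tax <- generate_taxonomy(spec)
  dict <- build_dictionary(tax)
  b <- generate_corpus(tax, spec)
  # strip the injected mentions: rebuild documents from distractors only by
  # annotating and checking that every exact mention is an injected surface
  normalized_injected <- normalize_text(b$injection_log$surface, dict$policy)
  for (rec in b$corpus) {
    doc <- prepare_document(rec, dict$policy)
    m <- exact_match(doc, dict)
    ok <- vapply(seq_len(nrow(m)), function(i) {
      normalize_text(m$surface[i], dict$policy) %in% normalized_injected
    }, logical(1))
    expect_true(all(ok))
  }
})

test_that("the single-edit typo regime separates the engines cleanly", {
  spec <- synthetic_spec(n_concepts = 30, n_docs = 30, typo_prob = 1,
                         typo_edits = 1, acronym_prob = 0, seed = 23)
  b <- generate_bundle(spec)
  dict <- build_dictionary(b$taxonomy)
  ex <- annotate_corpus(b$corpus, dict, b$taxonomy,
                        annotator_config(fuzzy = FALSE, propagate = FALSE))
  cb <- annotate_corpus(b$corpus, dict, b$taxonomy,
                        annotator_config(fuzzy = TRUE, propagate = FALSE))
  ev_ex <- evaluate_annotations(prediction_sets(ex, FALSE), b$gold)
  ev_cb <- evaluate_annotations(prediction_sets(cb, FALSE), b$gold)
  # every mention is perturbed by one edit on a >= 12-char surface, so the
  # exact engine finds nothing and the fuzzy engine recovers everything
  expect_equal(ev_ex$recall, 0)
  expect_equal(ev_cb$recall, 1)
  expect_equal(ev_cb$precision, 1)
})

test_that("bundles round-trip through their on-disk formats", {
  spec <- synthetic_spec(n_concepts = 15, n_docs = 8, seed = 2)
  b <- generate_bundle(spec)
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  expect_setequal(list.files(dir), c("taxonomy.json", "corpus.jsonl",
                                     "gold.tsv", "injection_log.tsv"))
  tax2 <- load_taxonomy(file.path(dir, "taxonomy.json"), strict = TRUE)
  expect_identical(tax2$concepts, b$taxonomy$concepts)
  corpus2 <- read_corpus_jsonl(file.path(dir, "corpus.jsonl"))
  expect_identical(serialize(corpus2, NULL), serialize(b$corpus, NULL))
  gold2 <- read_gold(file.path(dir, "gold.tsv"))
  expect_identical(gold2$labels[order(names(gold2$labels))],
                   b$gold$labels[order(names(b$gold$labels))])
})
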