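test_that("document preparation concatenates fields with [SEP] and records spans", {
  doc <- prepare_document(article_record("d", title = "T", abstract = "A",
                                         keywords = c("k1", "k2")))
  expect_equal(doc$full_text, "T [SEP] A [SEP] k1; k2")
  expect_equal(doc$field_boundaries$field, c("title", "abstract", "keywords"))
  expect_equal(doc$field_boundaries$start, c(0L, 8L, 16L))
  expect_equal(doc$field_boundaries$end, c(1L, 9L, 22L))
  # separator tokens never survive into the token stream
  expect_false("sep" %in% doc$tokens$token)

  # keywords-only record: empty title/abstract spans
  kw <- prepare_document(article_record("d", keywords = "k1"))
  expect_equal(kw$full_text, " [SEP]  [SEP] k1")
  expect_equal(kw$field_boundaries$start[1:2], kw$field_boundaries$end[1:2])
  expect_equal(kw$tokens$field, "keywords")
  expect_equal(kw$tokens$token, "k1")

  expect_error(prepare_document(article_record("d")), "all empty")
})

test_that("a literal [SEP] inside a field is neutralized", {
  doc <- prepare_document(article_record("d", title = "bad [SEP] title",
                                         abstract = "A", keywords = "k"))
  # still exactly two separators -> three fields, and all title tokens are
  # attributed to the title
  expect_equal(nrow(doc$field_boundaries), 3L)
  tt <- doc$tokens[doc$tokens$field == "title", ]
  expect_true(all(c("bad", "title") %in% tt$token))
  expect_equal(sum(doc$tokens$field == "abstract"), 1L)
})

test_that("no token and no mention crosses a field boundary", {
  tax <- taxonomy(list(
    list(code = "c1", preferred_label = "gaucher disease")
  ))
  dict <- build_dictionary(tax)
  # "gaucher" ends the title and "disease" starts the abstract: the surface
  # spans the [SEP] boundary and must NOT match
  rec <- article_record("d", title = "study of gaucher",
                        abstract = "disease progression", keywords = "x")
  doc <- prepare_document(rec, dict$policy)
  b <- doc$field_boundaries
  for (i in seq_len(nrow(doc$tokens))) {
    fld <- doc$tokens$field[i]
    expect_true(doc$tokens$start[i] >= b$start[b$field == fld] &&
                  doc$tokens$end[i] <= b$end[b$field == fld])
  }
  expect_equal(nrow(exact_match(doc, dict)), 0L)
  expect_equal(nrow(fuzzy_match(doc, dict)), 0L)
})

test_that("exact matching finds token-aligned surfaces with score 1", {
  dict <- toy_dictionary()
  rec <- toy_record()
  doc <- prepare_document(rec, dict$policy)
  m <- exact_match(doc, dict)
  expect_true(all(m$score == 1))
  expect_true(all(m$match_type == "exact"))
  expect_setequal(m$code, c("L", "P", "P2"))
  g <- m[m$code == "L", ]
  expect_equal(substr(doc$full_text, g$start + 1, g$end), "Gaucher disease")
})

test_that("word boundaries are respected: 'disease' does not match in 'diseased'", {
  tax <- taxonomy(list(list(code = "c1", preferred_label = "disease")))
  dict <- build_dictionary(tax)
  doc <- prepare_document(article_record("d", abstract = "diseased tissue"),
                          dict$policy)
  expect_equal(nrow(exact_match(doc, dict)), 0L)
  doc2 <- prepare_document(article_record("d", abstract = "the disease is"),
                           dict$policy)
  expect_equal(nrow(exact_match(doc2, dict)), 1L)
})

test_that("longest match wins; contained generic matches are suppressed", {
  tax <- taxonomy(list(
    list(code = "c2", preferred_label = "lymphoma"),
    list(code = "c3", preferred_label = "hodgkin lymphoma")
  ))
  dict <- build_dictionary(tax)
  doc <- prepare_document(article_record(
    "d", abstract = "hodgkin lymphoma and diffuse lymphoma cases"
  ), dict$policy)
  m <- exact_match(doc, dict)
  # c3 at the long span; c2 only at its standalone occurrence
  expect_equal(m$code, c("c3", "c2"))
  expect_equal(m$matched_term, c("hodgkin lymphoma", "lymphoma"))
})

test_that("ambiguous surfaces yield one mention per mapped concept", {
  tax <- taxonomy(list(
    list(code = "c1", preferred_label = "pompe disease"),
    list(code = "c2", preferred_label = "gsd ii", synonyms = "pompe disease")
  ))
  dict <- build_dictionary(tax)
  doc <- prepare_document(article_record("d", abstract = "on pompe disease"),
                          dict$policy)
  m <- exact_match(doc, dict)
  expect_setequal(m$code, c("c1", "c2"))
  expect_equal(unique(m$start), m$start[1])
})

test_that("fuzzy matching scores by normalized Levenshtein over token windows", {
  tax <- taxonomy(list(list(code = "c1", preferred_label = "gaucher disease")))
  dict <- build_dictionary(tax)
  doc <- prepare_document(article_record("d", abstract = "on gauchers disease"),
                          dict$policy)
  m <- fuzzy_match(doc, dict, threshold = 0.8)
  expect_equal(nrow(m), 1L)
  expect_equal(m$match_type, "fuzzy")
  expect_equal(m$score, 1 - 1 / 16)   # one edit, max length 16
  # dissimilar text: nothing
  far <- prepare_document(article_record("d", abstract = "heart failure"),
                          dict$policy)
  expect_equal(nrow(fuzzy_match(far, dict, 0.8)), 0L)
  expect_error(fuzzy_match(doc, dict, 0), "threshold")
  expect_error(fuzzy_match(doc, dict, 1.2), "threshold")
})

test_that("threshold 1 leaves nothing: exact precedence absorbs all candidates", {
  dict <- toy_dictionary()
  doc <- prepare_document(toy_record(), dict$policy)
  expect_equal(nrow(fuzzy_match(doc, dict, threshold = 1)), 0L)
})

test_that("short terms are never fuzzy-matched", {
  tax <- taxonomy(list(
    list(code = "c1", preferred_label = "angelman syndrome", synonyms = "AS")
  ))
  dict <- build_dictionary(tax)  # exact_only for "as"
  doc <- prepare_document(article_record("d", abstract = "was at it"),
                          dict$policy)
  expect_equal(nrow(fuzzy_match(doc, dict, 0.5)), 0L)
})

test_that("exact and fuzzy matchers equal brute-force scans on random instances", {
  set.seed(77)
  spec <- synthetic_spec(n_concepts = 12, n_docs = 10, typo_prob = 0.5,
                         typo_edits = 1, tokens_per_doc = c(30L, 60L),
                         seed = 31)
  b <- generate_bundle(spec)
  dict <- build_dictionary(b$taxonomy)
  for (rec in b$corpus) {
    doc <- prepare_document(rec, dict$policy)
    got_e <- exact_match(doc, dict)[, c("code", "start", "end", "matched_term")]
    want_e <- oracle_exact_scan(doc, dict)
    rownames(got_e) <- rownames(want_e) <- NULL
    expect_equal(got_e, want_e)
    got_f <- fuzzy_match(doc, dict)[, c("code", "start", "end",
                                        "matched_term", "score")]
    want_f <- oracle_fuzzy_scan(doc, dict)
    rownames(got_f) <- rownames(want_f) <- NULL
    expect_equal(got_f, want_f)
  }
})

test_that("combine_mentions applies exact precedence and flags overlaps", {
  e <- data.frame(code = "c1", start = 0L, end = 15L, surface = "s",
                  matched_term = "s", match_type = "exact", score = 1,
                  overlapping = FALSE, stringsAsFactors = FALSE)
  f_same <- e; f_same$match_type <- "fuzzy"; f_same$score <- 0.9
  f_other <- f_same; f_other$code <- "c2"
  f_far <- f_same; f_far$start <- 20L; f_far$end <- 30L

  expect_equal(nrow(combine_mentions(e, f_same)), 1L)
  expect_equal(combine_mentions(e, f_same)$match_type, "exact")

  both <- combine_mentions(e, f_other)
  expect_equal(nrow(both), 2L)
  expect_true(all(both$overlapping))

  disj <- combine_mentions(e, f_far)
  expect_equal(nrow(disj), 2L)
  expect_false(any(disj$overlapping))
  expect_equal(disj$start, c(0L, 20L))  # sorted by start

  expect_equal(combine_mentions(e, e[0, ]), e)
})

test_that("propagation assigns ancestors with provenance, skipping direct codes", {
  tax <- toy_taxonomy()
  p <- propagate_concepts("L", tax, max_dist = 2)
  expect_equal(p$code, c("G", "P"))
  expect_equal(p$source, c("L", "L"))
  expect_equal(p$distance, c(2L, 1L))
  # codes already direct are not re-added
  p2 <- propagate_concepts(c("L", "P"), tax, max_dist = 2)
  expect_false("P" %in% p2$code)
  expect_true("G" %in% p2$code)
  # a root propagates nothing
  expect_equal(nrow(propagate_concepts("R", tax)), 0L)
  expect_error(propagate_concepts("NOPE", tax), "unknown concept code")
})

test_that("annotate_document composes the pipeline end to end", {
  tax <- toy_taxonomy()
  dict <- build_dictionary(tax)
  rec <- article_record("d", abstract = "a case of Gaucher disease")
  off <- annotate_document(rec, dict, tax,
                           annotator_config(propagate = FALSE))
  expect_equal(off$final_concepts$code, "L")
  on <- annotate_document(rec, dict, tax, annotator_config(max_dist = 2))
  expect_setequal(on$final_concepts$code, c("L", "P", "G"))
  expect_equal(on$final_concepts$origin[on$final_concepts$code == "L"],
               "direct")
  prop <- on$propagated
  expect_true(all(prop$distance <= 2))
  # deprecated surface resolves to the current concept
  old <- annotate_document(
    article_record("d2", abstract = "classic beta thalassemia major case"),
    dict, tax, annotator_config(propagate = FALSE))
  expect_equal(old$final_concepts$code, "L2")
})

test_that("a misspelled long synonym is recovered only by the combined engine", {
  tax <- toy_taxonomy()
  dict <- build_dictionary(tax)
  # one edit on a 29-char synonym: similarity 1 - 1/29 >> 0.8
  rec <- article_record("d", abstract = "glucocerebrosidaze deficiency noted")
  ex <- annotate_document(rec, dict, tax,
                          annotator_config(fuzzy = FALSE, propagate = FALSE))
  cb <- annotate_document(rec, dict, tax,
                          annotator_config(fuzzy = TRUE, propagate = FALSE))
  expect_equal(nrow(ex$final_concepts), 0L)
  expect_equal(cb$final_concepts$code, "L")
  expect_equal(max(cb$mentions$score), 1 - 1 / 29)
})

test_that("engine and propagation monotonicity hold on a synthetic corpus", {
  spec <- synthetic_spec(n_concepts = 25, n_docs = 15, typo_prob = 0.4,
                         seed = 11)
  b <- generate_bundle(spec)
  dict <- build_dictionary(b$taxonomy)
  for (rec in b$corpus[1:8]) {
    ex <- annotate_document(rec, dict, b$taxonomy,
                            annotator_config(fuzzy = FALSE, propagate = FALSE))
    cb <- annotate_document(rec, dict, b$taxonomy,
                            annotator_config(fuzzy = TRUE, propagate = FALSE))
    pr <- annotate_document(rec, dict, b$taxonomy,
                            annotator_config(fuzzy = TRUE, propagate = TRUE))
    expect_true(all(ex$final_concepts$code %in% cb$final_concepts$code))
    expect_true(all(cb$final_concepts$code %in% pr$final_concepts$code))
  }
})

test_that("annotation is a pure function of its inputs", {
  spec <- synthetic_spec(n_concepts = 15, n_docs = 5, typo_prob = 0.5,
                         seed = 5)
  b <- generate_bundle(spec)
  dict <- build_dictionary(b$taxonomy)
  a1 <- annotate_corpus(b$corpus, dict, b$taxonomy)
  a2 <- annotate_corpus(b$corpus, dict, b$taxonomy)
  expect_identical(serialize(a1, NULL), serialize(a2, NULL))
})

test_that("policy mismatch between document and dictionary is an error", {
  dict <- toy_dictionary()
  doc <- prepare_document(toy_record(),
                          normalization_policy(transliterate_greek = FALSE))
  expect_error(exact_match(doc, dict), "different normalization policies")
  expect_error(fuzzy_match(doc, dict), "different normalization policies")
})
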