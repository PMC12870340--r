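# Seeded synthetic data: disease-like taxonomies, corpora with injected
# mentions under controlled noise, and matching gold labels. Everything is a
# pure function of the spec (including its seed), so all other modules are
# testable end-to-end without external data.
#
# Two constructions make the expected behavior of the matchers analytic
# rather than statistical:
#   * no dictionary surface is a contiguous token-subsequence of a surface
#     of a different concept, so exact matches are unambiguous;
#   * distractor tokens are kept at edit distance >= 3 from every dictionary
#     token, so distractor text cannot produce exact matches and, at the
#     default 0.8 similarity threshold, essentially cannot produce fuzzy
#     ones either.

.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Parameters for the synthetic generator
#'
#' Defaults describe a corpus of short bibliographic records over a
#' moderately deep disease hierarchy: documents of 60-120 tokens carrying
#' 1-3 injected disease mentions, a third of them using a synonym rather
#' than the preferred label, and (under `typo_prob` > 0) misspellings at a
#' controlled edit distance.
#'
#' @param n_concepts Total number of concepts (active + deprecated).
#' @param max_depth Maximum depth of the hierarchy (root at depth 0).
#' @param branching Integer range `c(lo, hi)`: children drawn per internal
#'   node.
#' @param synonyms_per_concept Integer range: synonyms per concept (long,
#'   disease-like synonyms; acronyms come on top).
#' @param acronym_prob Probability that a concept additionally gets an
#'   acronym synonym (initial letters of its preferred label).
#' @param deprecated_frac Fraction of concepts that are deprecated with a
#'   `replaced_by` link to an active concept.
#' @param n_docs Number of article records.
#' @param mentions_per_doc Integer range: injected mentions per document
#'   (distinct concepts).
#' @param typo_prob Probability that an injected mention is perturbed.
#' @param typo_edits Number of character edits applied when perturbing.
#' @param synonym_use_prob Probability that a mention uses a synonym instead
#'   of the preferred label.
#' @param distractor_vocab_size Size of the distractor token vocabulary.
#' @param tokens_per_doc Integer range: distractor tokens per document.
#' @param seed Integer seed; fully determines every generated artifact.
#' @return An object of class `orpha_synthspec`.
#' @export
synthetic_spec <- function(n_concepts = 100L,
                           max_depth = 4L,
                           branching = c(2L, 4L),
                           synonyms_per_concept = c(1L, 3L),
                           acronym_prob = 0.25,
                           deprecated_frac = 0.1,
                           n_docs = 200L,
                           mentions_per_doc = c(1L, 3L),
                           typo_prob = 0,
                           typo_edits = 1L,
                           synonym_use_prob = 0.3,
                           distractor_vocab_size = 400L,
                           tokens_per_doc = c(60L, 120L),
                           seed = 1L) {
  spec <- list(
    n_concepts = as.integer(n_concepts), max_depth = as.integer(max_depth),
    branching = as.integer(branching),
    synonyms_per_concept = as.integer(synonyms_per_concept),
    acronym_prob = acronym_prob, deprecated_frac = deprecated_frac,
    n_docs = as.integer(n_docs),
    mentions_per_doc = as.integer(mentions_per_doc),
    typo_prob = typo_prob, typo_edits = as.integer(typo_edits),
    synonym_use_prob = synonym_use_prob,
    distractor_vocab_size = as.integer(distractor_vocab_size),
    tokens_per_doc = as.integer(tokens_per_doc), seed = as.integer(seed)
  )
  for (p in c("acronym_prob", "deprecated_frac", "typo_prob",
              "synonym_use_prob")) {
    if (spec[[p]] < 0 || spec[[p]] > 1) {
      stop("`", p, "` must be in [0, 1]", call. = FALSE)
    }
  }
  if (spec$n_concepts < 1L) stop("`n_concepts` must be >= 1", call. = FALSE)
  class(spec) <- "orpha_synthspec"
  spec
}

.rint <- function(range) {
  if (length(range) == 1L) range else sample(range[1]:range[2], 1L)
}

# Disease-name word generator: pronounceable consonant-vowel syllable words.
.syn_word <- function(min_syl = 2L, max_syl = 3L) {
  cons <- c("b", "c", "d", "f", "g", "h", "k", "l", "m", "n", "p", "r",
            "s", "t", "v", "z", "ch", "th", "st", "br")
  vows <- c("a", "e", "i", "o", "u", "au", "ei")
  n_syl <- sample(min_syl:max_syl, 1L)
  word <- paste0(sample(cons, n_syl, replace = TRUE),
                 sample(vows, n_syl, replace = TRUE), collapse = "")
  if (stats::runif(1) < 0.3) word <- paste0(word, sample(cons[1:16], 1L))
  word
}

.syn_name <- function(min_chars = 12L) {
  for (i in 1:100) {
    n_words <- sample(2:4, 1L)
    words <- vapply(seq_len(n_words), function(i) .syn_word(), character(1))
    name <- paste(words, collapse = " ")
    u <- stats::runif(1)
    if (u < 0.25) {
      name <- paste(name, "syndrome")
    } else if (u < 0.45) {
      name <- paste(name, "disease type", sample(1:9, 1L))
    } else if (u < 0.6) {
      name <- paste(name, "deficiency")
    }
    if (nchar(name) >= min_chars) return(name)
  }
  name
}

# TRUE if the token vector `a` occurs as a contiguous subsequence of `b`
.is_subseq <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na > nb) return(FALSE)
  for (i in seq_len(nb - na + 1L)) {
    if (all(b[i:(i + na - 1L)] == a)) return(TRUE)
  }
  FALSE
}

#' Generate a synthetic disease taxonomy
#'
#' Builds a rooted DAG of `n_concepts` disease-like concepts with multi-token
#' names, synonyms and optional acronym synonyms; a `deprecated_frac`
#' fraction of concepts are deprecated with `replaced_by` links to active
#' concepts. A small fraction of nodes get a second parent, exercising the
#' poly-hierarchy. Surfaces are generated so that no name or synonym is a
#' contiguous token-subsequence of a surface of a different concept. The
#' result validates under the full set of taxonomy invariants.
#'
#' @param spec A [synthetic_spec()].
#' @return An `orpha_taxonomy`.
#' @export
generate_taxonomy <- function(spec) {
  stopifnot(inherits(spec, "orpha_synthspec"))
  .with_seed(spec$seed, {
    n_dep <- min(spec$n_concepts - 1L,
                 round(spec$deprecated_frac * spec$n_concepts))
    if (spec$n_concepts == 1L) n_dep <- 0L
    n_act <- spec$n_concepts - n_dep

    # surfaces, rejecting cross-concept token-subsequence collisions
    all_token_seqs <- list()
    fresh_surface <- function(min_chars = 12L) {
      for (try in 1:200) {
        s <- .syn_name(min_chars)
        toks <- strsplit(s, " ", fixed = TRUE)[[1]]
        clash <- any(vapply(all_token_seqs, function(other) {
          .is_subseq(toks, other) || .is_subseq(other, toks)
        }, logical(1)))
        if (!clash) {
          all_token_seqs[[length(all_token_seqs) + 1L]] <<- toks
          return(s)
        }
      }
      stop("could not generate a collision-free surface", call. = FALSE)
    }

    concepts <- vector("list", spec$n_concepts)
    depth <- integer(n_act)
    codes <- sprintf("ORPHA:%d", 100000L + seq_len(spec$n_concepts))
    for (i in seq_len(n_act)) {
      pref <- fresh_surface()
      n_syn <- .rint(spec$synonyms_per_concept)
      syns <- if (n_syn > 0L) {
        vapply(seq_len(n_syn), function(j) fresh_surface(), character(1))
      } else character(0)
      if (stats::runif(1) < spec$acronym_prob) {
        acro <- toupper(paste(substr(strsplit(pref, " ")[[1]], 1, 1),
                              collapse = ""))
        syns <- c(syns, acro)
      }
      if (i == 1L) {
        parents <- character(0)
        depth[i] <- 0L
      } else {
        eligible <- which(depth[seq_len(i - 1L)] < spec$max_depth)
        # bias toward shallower nodes so the tree respects the branching
        # range on average rather than degenerating into a path
        par1 <- if (length(eligible) == 1L) eligible else {
          sample(eligible, 1L, prob = 1 / (1 + depth[eligible]))
        }
        parents <- codes[par1]
        depth[i] <- depth[par1] + 1L
        if (stats::runif(1) < 0.15) {
          second <- which(depth[seq_len(i - 1L)] < depth[i])
          second <- setdiff(second, par1)
          if (length(second)) {
            par2 <- if (length(second) == 1L) second else sample(second, 1L)
            parents <- c(parents, codes[par2])
          }
        }
      }
      concepts[[i]] <- list(code = codes[i], preferred_label = pref,
                            synonyms = syns, status = "active",
                            replaced_by = NULL, parents = parents)
    }
    for (i in seq_len(n_dep)) {
      k <- n_act + i
      target <- codes[sample(seq_len(n_act), 1L)]
      concepts[[k]] <- list(code = codes[k],
                            preferred_label = fresh_surface(),
                            synonyms = character(0), status = "deprecated",
                            replaced_by = target, parents = character(0))
    }
    taxonomy(concepts, version_tag = sprintf("synthetic-%d", spec$seed))
  })
}

#' Perturb a term by an exact number of character edits
#'
#' Applies exactly `n_edits` random character-level edits (substitution,
#' insertion or deletion of a letter inside a token — token boundaries are
#' never touched), then verifies `levenshtein(term, output) == n_edits` and
#' resamples if edits collapsed. Deterministic in `(term, n_edits, seed)`.
#'
#' @param term A string with tokens of alphanumeric characters.
#' @param n_edits Number of edits (>= 1).
#' @param seed Integer seed.
#' @return The perturbed string, at edit distance exactly `n_edits` from
#'   `term`.
#' @export
perturb_term <- function(term, n_edits, seed) {
  n_edits <- as.integer(n_edits)
  if (is.na(n_edits) || n_edits < 1L) {
    stop("`n_edits` must be >= 1", call. = FALSE)
  }
  if (nchar(gsub(" ", "", term, fixed = TRUE)) <= n_edits) {
    stop("term too short to guarantee edit distance ", n_edits, call. = FALSE)
  }
  letters_pool <- letters
  .with_seed(seed, {
    for (attempt in 1:100) {
      out <- term
      for (e in seq_len(n_edits)) {
        chars <- strsplit(out, "", fixed = TRUE)[[1]]
        ed <- sample(c("sub", "ins", "del"), 1L)
        pos_alnum <- which(chars != " ")
        if (ed == "sub") {
          p <- if (length(pos_alnum) == 1L) pos_alnum else sample(pos_alnum, 1L)
          repl <- sample(setdiff(letters_pool, chars[p]), 1L)
          chars[p] <- repl
        } else if (ed == "ins") {
          p <- if (length(pos_alnum) == 1L) pos_alnum else sample(pos_alnum, 1L)
          chars <- append(chars, sample(letters_pool, 1L), after = p)
        } else {
          # delete only from a token of length >= 2 so no token vanishes
          ok <- pos_alnum[vapply(pos_alnum, function(p) {
            left <- p > 1L && chars[p - 1L] != " "
            right <- p < length(chars) && chars[p + 1L] != " "
            left || right
          }, logical(1))]
          if (!length(ok)) {
            chars[sample(pos_alnum, 1L)] <- sample(letters_pool, 1L)
          } else {
            p <- if (length(ok) == 1L) ok else sample(ok, 1L)
            chars <- chars[-p]
          }
        }
        out <- paste(chars, collapse = "")
      }
      if (as.integer(utils::adist(term, out)) == n_edits) return(out)
    }
    stop("could not reach exact edit distance ", n_edits, " for '", term, "'",
         call. = FALSE)
  })
}

# distractor tokens at edit distance >= 3 from every dictionary token
.distractor_vocab <- function(size, dict_tokens) {
  vocab <- character(0)
  cons <- c("w", "x", "q", "j", "y", "wr", "xh", "qu", "jy")
  vows <- c("a", "e", "i", "o", "u", "y")
  while (length(vocab) < size) {
    need <- size - length(vocab)
    cands <- unique(vapply(seq_len(need * 2L), function(i) {
      n_syl <- sample(3:4, 1L)
      paste0(sample(cons, n_syl, replace = TRUE),
             sample(vows, n_syl, replace = TRUE), collapse = "")
    }, character(1)))
    cands <- setdiff(cands, vocab)
    if (!length(cands)) next
    dmin <- apply(utils::adist(cands, dict_tokens), 1, min)
    vocab <- c(vocab, cands[dmin >= 3])
  }
  vocab[seq_len(size)]
}

#' Generate a synthetic corpus with injected mentions and gold labels
#'
#' Each document is built from distractor tokens (drawn from a vocabulary
#' disjoint from, and at edit distance >= 3 to, every dictionary token) with
#' disease mentions spliced in at random non-overlapping token positions in
#' the title, abstract or keywords. Each mention uses the concept's
#' preferred label or one of its long synonyms (with probability
#' `synonym_use_prob`) and is perturbed by exactly `typo_edits` character
#' edits with probability `typo_prob`. The gold label of a document is the
#' set of injected (resolved) concepts; the injection log reconstructs it
#' exactly. Records carry synthetic metadata (year, countries, subject
#' areas) for the aggregation module.
#'
#' @param tax An `orpha_taxonomy`, typically from [generate_taxonomy()].
#' @param spec The [synthetic_spec()] (its `seed` also seeds this step).
#' @return An object of class `orpha_bundle`: `taxonomy`, `corpus` (list of
#'   records), `gold` (an `orpha_gold`), `injection_log` (data.frame) and
#'   `spec`.
#' @export
generate_corpus <- function(tax, spec) {
  stopifnot(inherits(spec, "orpha_synthspec"))
  .check_taxonomy(tax)
  .with_seed(spec$seed + 1000003L, {
    act <- active_codes(tax)
    # injectable surfaces: preferred label plus long synonyms (acronyms are
    # deliberately not injected; they exist to exercise the short-term policy)
    surfaces <- lapply(tax$concepts[act], function(cp) {
      syn <- cp$synonyms[nchar(cp$synonyms) >= 8]
      list(preferred = cp$preferred_label, synonyms = syn)
    })
    pol <- normalization_policy()
    dict_tokens <- unique(unlist(lapply(tax$concepts, function(cp) {
      strsplit(normalize_text(c(cp$preferred_label, cp$synonyms), pol),
               " ", fixed = TRUE)
    }), use.names = FALSE))
    dict_tokens <- dict_tokens[nzchar(dict_tokens)]
    distractors <- .distractor_vocab(spec$distractor_vocab_size, dict_tokens)
    countries <- c("NL", "US", "CN", "DE", "FR", "UK", "IT", "ES", "JP", "BE")
    areas <- c("Medicine", "Biochemistry", "Neuroscience", "Genetics",
               "Pharmacology", "Immunology", "Engineering", "Computer Science")

    corpus <- vector("list", spec$n_docs)
    gold <- list()
    log_rows <- list()
    for (d in seq_len(spec$n_docs)) {
      doc_id <- sprintf("doc%05d", d)
      n_m <- min(.rint(spec$mentions_per_doc), length(act))
      cps <- sample(act, n_m)
      n_tok <- .rint(spec$tokens_per_doc)
      n_title <- max(1L, min(sample(5:9, 1L), n_tok - 2L))
      n_kw <- sample(2:4, 1L)
      n_abs <- max(1L, n_tok - n_title - n_kw)
      title_toks <- sample(distractors, n_title, replace = TRUE)
      abs_toks <- sample(distractors, n_abs, replace = TRUE)
      kw_items <- vapply(seq_len(n_kw), function(i) {
        paste(sample(distractors, sample(1:2, 1L), replace = TRUE),
              collapse = " ")
      }, character(1))

      # choose the field for each mention, then distinct insertion slots per
      # field so mentions never overlap and always have a distractor between
      fields <- sample(c("title", "abstract", "keywords"), n_m,
                       replace = TRUE, prob = c(0.2, 0.6, 0.2))
      ins <- list(title = integer(0), abstract = integer(0))
      mention_surfaces <- character(n_m)
      perturbed <- logical(n_m)
      edits <- integer(n_m)
      for (j in seq_len(n_m)) {
        cp <- cps[j]
        sf <- surfaces[[cp]]
        use_syn <- length(sf$synonyms) > 0L &&
          stats::runif(1) < spec$synonym_use_prob
        surf <- if (use_syn) sample(sf$synonyms, 1L) else sf$preferred
        if (spec$typo_prob > 0 && stats::runif(1) < spec$typo_prob) {
          surf <- perturb_term(surf, spec$typo_edits,
                               seed = (as.numeric(spec$seed) * 1009 +
                                         d * 131 + j) %% 2147483647)
          perturbed[j] <- TRUE
          edits[j] <- spec$typo_edits
        }
        mention_surfaces[j] <- surf
      }
      for (fld in c("title", "abstract")) {
        idx <- which(fields == fld)
        if (!length(idx)) next
        m_here <- length(idx)
        base <- if (fld == "title") title_toks else abs_toks
        slots <- sort(sample(0:length(base), min(m_here, length(base) + 1L)))
        if (length(slots) < m_here) {
          # field too small: overflow mentions go to the abstract's keywords
          fields[idx[(length(slots) + 1L):m_here]] <- "keywords"
          idx <- idx[seq_along(slots)]
        }
        # splice mention tokens at the chosen slots (process back to front)
        for (o in order(slots, decreasing = TRUE)) {
          j <- idx[o]
          mt <- strsplit(mention_surfaces[j], " ", fixed = TRUE)[[1]]
          base <- append(base, mt, after = slots[o])
        }
        if (fld == "title") title_toks <- base else abs_toks <- base
      }
      kw_idx <- which(fields == "keywords")
      if (length(kw_idx)) {
        kw_items <- c(kw_items, mention_surfaces[kw_idx])
        kw_items <- sample(kw_items)  # shuffle positions
      }
      corpus[[d]] <- article_record(
        doc_id = doc_id,
        title = paste(title_toks, collapse = " "),
        abstract = paste(abs_toks, collapse = " "),
        keywords = kw_items,
        metadata = list(
          year = sample(2012:2022, 1L),
          countries = sample(countries, sample(1:3, 1L)),
          subject_areas = sample(areas, sample(1:3, 1L))
        )
      )
      gold[[doc_id]] <- sort(unique(.resolve_or_na(tax, cps)))
      log_rows[[d]] <- data.frame(
        doc_id = doc_id, concept = cps, surface = mention_surfaces,
        perturbed = perturbed, edit_count = edits, stringsAsFactors = FALSE
      )
    }
    structure(
      list(taxonomy = tax, corpus = corpus,
           gold = gold_set(gold, provenance = "synthetic injection"),
           injection_log = do.call(rbind, log_rows), spec = spec),
      class = "orpha_bundle"
    )
  })
}

#' Generate a full synthetic bundle (taxonomy + corpus + gold)
#'
#' @param spec A [synthetic_spec()].
#' @return An `orpha_bundle`; see [generate_corpus()].
#' @export
generate_bundle <- function(spec = synthetic_spec()) {
  tax <- generate_taxonomy(spec)
  generate_corpus(tax, spec)
}

#' Write a synthetic bundle to a directory
#'
#' Writes `taxonomy.json`, `corpus.jsonl`, `gold.tsv` and
#' `injection_log.tsv`.
#'
#' @param bundle An `orpha_bundle`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_taxonomy_json(bundle$taxonomy, file.path(dir, "taxonomy.json"))
  write_corpus_jsonl(bundle$corpus, file.path(dir, "corpus.jsonl"))
  write_gold_tsv(bundle$gold, file.path(dir, "gold.tsv"))
  utils::write.table(bundle$injection_log, file.path(dir, "injection_log.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(dir)
}

#' @export
print.orpha_bundle <- function(x, ...) {
  cat("<orpha_bundle>", length(x$corpus), "documents,",
      length(x$taxonomy$concepts), "concepts,",
      nrow(x$injection_log), "injected mentions\n")
  invisible(x)
}
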