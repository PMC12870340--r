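# Annotation engine: document preparation (title [SEP] abstract [SEP]
# keywords), exact token-boundary matching, threshold-based fuzzy matching
# over token windows, mention merging, concept resolution and hierarchy
# propagation.

.SEP <- " [SEP] "

#' Construct an article record
#'
#' @param doc_id Unique document identifier.
#' @param title,abstract Strings (may be empty).
#' @param keywords Character vector (may be empty).
#' @param metadata Optional named list; recognized fields are `year`
#'   (integer), `countries` (character vector) and `subject_areas`
#'   (character vector).
#' @return An object of class `orpha_record`.
#' @export
article_record <- function(doc_id, title = "", abstract = "",
                           keywords = character(0), metadata = list()) {
  title <- as.character(title)[1] %||% ""
  abstract <- as.character(abstract)[1] %||% ""
  keywords <- as.character(keywords)
  if (is.na(title)) title <- ""
  if (is.na(abstract)) abstract <- ""
  keywords <- keywords[!is.na(keywords)]
  rec <- structure(
    list(doc_id = as.character(doc_id)[1], title = title, abstract = abstract,
         keywords = keywords, metadata = metadata),
    class = "orpha_record"
  )
  rec
}

.check_record <- function(rec) {
  if (!inherits(rec, "orpha_record")) {
    stop("expected an `orpha_record` (see article_record())", call. = FALSE)
  }
  rec
}

#' Prepare a document for annotation
#'
#' Concatenates title, abstract and keywords into a single string with the
#' sentinel `[SEP]` between fields (keywords joined by `"; "`), records the
#' character span of each field, and tokenizes with offsets. Tokens arising
#' from the separators are discarded and every retained token is tagged with
#' its field, so no later match can cross a field boundary. A literal
#' "[SEP]" inside a field is neutralized (brackets stripped) so the
#' document always has exactly two separators.
#'
#' @param rec An [article_record()].
#' @param policy A [normalization_policy()].
#' @return An object of class `orpha_prepared` with elements `doc_id`,
#'   `full_text`, `field_boundaries` (data.frame `field`, `start`, `end`)
#'   and `tokens` (data.frame `token`, `start`, `end`, `field`).
#' @export
prepare_document <- function(rec, policy = normalization_policy()) {
  .check_record(rec)
  .check_policy(policy)
  kw <- paste(rec$keywords, collapse = "; ")
  fields <- c(title = rec$title, abstract = rec$abstract, keywords = kw)
  if (all(!nzchar(fields))) {
    stop("record '", rec$doc_id,
         "': title, abstract and keywords are all empty", call. = FALSE)
  }
  fields <- vapply(fields, function(f) gsub("[SEP]", "SEP", f, fixed = TRUE),
                   character(1))
  full_text <- paste(fields, collapse = .SEP)
  n <- nchar(fields, type = "chars")
  sep_n <- nchar(.SEP, type = "chars")
  starts <- c(0L, n[1] + sep_n, n[1] + sep_n + n[2] + sep_n)
  bounds <- data.frame(
    field = c("title", "abstract", "keywords"),
    start = as.integer(starts),
    end = as.integer(starts + n),
    stringsAsFactors = FALSE
  )
  toks <- tokenize_text(full_text, policy)
  if (nrow(toks)) {
    fld <- rep(NA_character_, nrow(toks))
    for (i in seq_len(nrow(bounds))) {
      inside <- toks$start >= bounds$start[i] & toks$end <= bounds$end[i]
      fld[inside] <- bounds$field[i]
    }
    toks$field <- fld
    toks <- toks[!is.na(toks$field), , drop = FALSE]  # drops [SEP] tokens
    rownames(toks) <- NULL
  } else {
    toks$field <- character(0)
  }
  structure(
    list(doc_id = rec$doc_id, full_text = full_text,
         field_boundaries = bounds, tokens = toks,
         policy_key = .policy_key(policy)),
    class = "orpha_prepared"
  )
}

.check_prepared <- function(doc) {
  if (!inherits(doc, "orpha_prepared")) {
    stop("expected an `orpha_prepared` document (see prepare_document())",
         call. = FALSE)
  }
  doc
}

.empty_mentions <- function() {
  data.frame(code = character(0), start = integer(0), end = integer(0),
             surface = character(0), matched_term = character(0),
             match_type = character(0), score = numeric(0),
             overlapping = logical(0), stringsAsFactors = FALSE)
}

.substr_chars <- function(s, start, end) {
  # 0-based half-open character offsets -> substring
  substr(s, start + 1L, end)
}

.check_same_policy <- function(doc, dict) {
  if (!identical(doc$policy_key, dict$policy_key)) {
    stop("document and dictionary were prepared under different ",
         "normalization policies", call. = FALSE)
  }
}

# paste n consecutive tokens for all windows of width n
.window_strings <- function(tokens, n) {
  m <- length(tokens) - n + 1L
  if (m < 1L) return(character(0))
  out <- tokens[seq_len(m)]
  if (n > 1L) {
    for (j in 2:n) out <- paste(out, tokens[seq_len(m) + j - 1L])
  }
  out
}

#' Exact dictionary matching
#'
#' Finds every occurrence of every dictionary surface as a token-boundary
#' aligned subsequence of the document's normalized token stream, within a
#' single field (matches never cross a `[SEP]` boundary). Ambiguous surfaces
#' yield one mention per mapped concept. A shorter match strictly contained
#' in a longer match is suppressed (longest-match-wins), so "lymphoma" is
#' not separately reported inside a "hodgkin lymphoma" match; equal spans
#' from ambiguous surfaces are all kept.
#'
#' @param doc An `orpha_prepared` document.
#' @param dict An `orpha_dictionary` compiled under the same policy.
#' @return A mention data.frame with columns `code`, `start`, `end`,
#'   `surface`, `matched_term`, `match_type` (`"exact"`), `score` (1.0) and
#'   `overlapping`.
#' @export
exact_match <- function(doc, dict) {
  .check_prepared(doc)
  .check_dictionary(dict)
  .check_same_policy(doc, dict)
  toks <- doc$tokens
  out <- list()
  for (fld in unique(toks$field)) {
    ft <- toks[toks$field == fld, , drop = FALSE]
    for (n in dict$token_counts) {
      if (n > nrow(ft)) next
      wins <- .window_strings(ft$token, n)
      hit <- which(vapply(wins, function(w) !is.null(dict$index[[w]]),
                          logical(1)))
      for (i in hit) {
        rows <- dict$index[[wins[i]]]
        st <- ft$start[i]
        en <- ft$end[i + n - 1L]
        for (r in rows) {
          out[[length(out) + 1L]] <- data.frame(
            code = dict$entries$code[r], start = st, end = en,
            surface = .substr_chars(doc$full_text, st, en),
            matched_term = dict$entries$surface[r],
            match_type = "exact", score = 1.0, overlapping = FALSE,
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  if (!length(out)) return(.empty_mentions())
  m <- do.call(rbind, out)
  m <- unique(m)
  .suppress_contained(m)
}

# longest-match-wins: drop mentions strictly contained in a longer mention
# (any concept); equal spans — e.g. an ambiguous surface mapping to several
# concepts — are all kept
.suppress_contained <- function(m) {
  if (nrow(m) < 2L) return(.sort_mentions(m))
  drop <- logical(nrow(m))
  for (i in seq_len(nrow(m))) {
    longer <- (m$end - m$start) > (m$end[i] - m$start[i])
    contained <- longer & m$start <= m$start[i] & m$end >= m$end[i]
    if (any(contained)) drop[i] <- TRUE
  }
  .sort_mentions(m[!drop, , drop = FALSE])
}

.sort_mentions <- function(m) {
  m <- m[order(m$start, m$end, m$code, m$match_type), , drop = FALSE]
  rownames(m) <- NULL
  m
}

#' Fuzzy dictionary matching
#'
#' For every fuzzy-eligible dictionary term of `k` tokens, every window of
#' `k-1`, `k` or `k+1` consecutive document tokens within one field is
#' scored by normalized Levenshtein similarity
#' `1 - d(window, term) / max(nchar(window), nchar(term))` on the
#' normalized strings. Windows scoring at or above `threshold` yield fuzzy
#' mentions. Windows identical to the term string are dropped — those are
#' exact matches and exact matching takes precedence. Terms shorter than the
#' dictionary's `min_term_chars` are never fuzzy-matched.
#'
#' @param doc An `orpha_prepared` document.
#' @param dict An `orpha_dictionary` compiled under the same policy.
#' @param threshold Similarity threshold in `(0, 1]`; default 0.8.
#' @return A mention data.frame (`match_type = "fuzzy"`, `score` in
#'   `[threshold, 1)`).
#' @export
fuzzy_match <- function(doc, dict, threshold = 0.8) {
  .check_prepared(doc)
  .check_dictionary(dict)
  .check_same_policy(doc, dict)
  if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold) ||
      threshold <= 0 || threshold > 1) {
    stop("`threshold` must be in (0, 1]", call. = FALSE)
  }
  ent <- dict$entries[dict$entries$fuzzy_eligible, , drop = FALSE]
  if (!nrow(ent)) return(.empty_mentions())
  terms <- unique(ent[, c("surface", "token_count", "nchar")])
  toks <- doc$tokens
  out <- list()
  for (fld in unique(toks$field)) {
    ft <- toks[toks$field == fld, , drop = FALSE]
    widths <- sort(unique(pmax(1L, c(terms$token_count - 1L,
                                     terms$token_count,
                                     terms$token_count + 1L))))
    wins_by_width <- list()
    for (w in widths) {
      if (w > nrow(ft)) next
      wins_by_width[[as.character(w)]] <- .window_strings(ft$token, w)
    }
    for (t in seq_len(nrow(terms))) {
      k <- terms$token_count[t]
      term <- terms$surface[t]
      tn <- terms$nchar[t]
      for (w in unique(pmax(1L, (k - 1L):(k + 1L)))) {
        wins <- wins_by_width[[as.character(w)]]
        if (is.null(wins)) next
        wn <- nchar(wins)
        # edit distance is at least the length difference, so windows whose
        # length alone caps the score below threshold can be skipped; same
        # arithmetic as the final check to avoid float boundary effects
        maxlen <- pmax(wn, tn)
        cand <- which(1 - abs(wn - tn) / maxlen >= threshold)
        if (!length(cand)) next
        d <- as.integer(utils::adist(wins[cand], term))
        sc <- 1 - d / maxlen[cand]
        keep <- which(sc >= threshold & wins[cand] != term)
        for (j in keep) {
          i <- cand[j]
          st <- ft$start[i]
          en <- ft$end[i + w - 1L]
          rows <- which(ent$surface == term)
          for (r in rows) {
            out[[length(out) + 1L]] <- data.frame(
              code = ent$code[r], start = st, end = en,
              surface = .substr_chars(doc$full_text, st, en),
              matched_term = term, match_type = "fuzzy",
              score = sc[j], overlapping = FALSE,
              stringsAsFactors = FALSE
            )
          }
        }
      }
    }
  }
  if (!length(out)) return(.empty_mentions())
  .sort_mentions(unique(do.call(rbind, out)))
}

#' Merge exact and fuzzy mentions
#'
#' Union of the two mention lists. A fuzzy mention overlapping an exact
#' mention of the same concept is removed (exact takes precedence); mentions
#' overlapping across different concepts are both retained and flagged
#' `overlapping`. Result is sorted by `(start, end)`.
#'
#' @param exact,fuzzy Mention data.frames from [exact_match()] and
#'   [fuzzy_match()] on the same document.
#' @return A merged mention data.frame.
#' @export
combine_mentions <- function(exact, fuzzy) {
  if (nrow(fuzzy)) {
    drop <- logical(nrow(fuzzy))
    for (i in seq_len(nrow(fuzzy))) {
      ov <- exact$code == fuzzy$code[i] &
        exact$start < fuzzy$end[i] & exact$end > fuzzy$start[i]
      if (any(ov)) drop[i] <- TRUE
    }
    fuzzy <- fuzzy[!drop, , drop = FALSE]
  }
  m <- rbind(exact, fuzzy)
  if (nrow(m) > 1L) {
    for (i in seq_len(nrow(m))) {
      ov <- m$start < m$end[i] & m$end > m$start[i] & m$code != m$code[i]
      if (any(ov)) m$overlapping[i] <- TRUE
    }
  }
  .sort_mentions(m)
}

#' Propagate concepts to near ancestors
#'
#' Each directly matched concept is also assigned to its ancestors within
#' `max_dist` parent edges (shortest-path distance in the taxonomy DAG), the
#' hierarchy-propagation step of the pipeline. Codes already matched
#' directly are not re-added as propagated.
#'
#' @param direct Character vector of (active) concept codes.
#' @param tax An `orpha_taxonomy`.
#' @param max_dist Maximum ancestor distance; default 2, i.e. ancestors at
#'   distance 1 or 2.
#' @return A data.frame `code`, `source`, `distance`, one row per
#'   (ancestor, direct source) pair.
#' @export
propagate_concepts <- function(direct, tax, max_dist = 2L) {
  .check_taxonomy(tax)
  direct <- unique(as.character(direct))
  out <- list()
  for (cd in direct) {
    .check_code(tax, cd)
    dist <- .ancestor_distances(tax, cd, max_dist)
    anc <- setdiff(names(dist), direct)
    if (length(anc)) {
      out[[length(out) + 1L]] <- data.frame(
        code = anc, source = cd, distance = unname(dist[anc]),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(data.frame(code = character(0), source = character(0),
                      distance = integer(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$code, res$distance, res$source), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Annotator configuration
#'
#' @param fuzzy Run the fuzzy matcher in addition to exact matching.
#' @param fuzzy_threshold Similarity threshold for fuzzy matches.
#' @param propagate Propagate assignments to near ancestors.
#' @param max_dist Propagation distance bound (ancestors at distance
#'   `1..max_dist`).
#' @param resolve_mentions Map mention concepts through [resolve_concept()]
#'   before forming the document's concept set.
#' @return An object of class `orpha_config`.
#' @export
annotator_config <- function(fuzzy = TRUE, fuzzy_threshold = 0.8,
                             propagate = TRUE, max_dist = 2L,
                             resolve_mentions = TRUE) {
  structure(
    list(fuzzy = isTRUE(fuzzy), fuzzy_threshold = fuzzy_threshold,
         propagate = isTRUE(propagate), max_dist = as.integer(max_dist),
         resolve_mentions = isTRUE(resolve_mentions)),
    class = "orpha_config"
  )
}

#' Annotate one article record
#'
#' Full pipeline for a single document: prepare, exact match, fuzzy match
#' (if enabled), merge, resolve mention concepts to active codes, and
#' propagate to near ancestors (if enabled). Deterministic for fixed inputs
#' and configuration.
#'
#' @param rec An [article_record()].
#' @param dict An `orpha_dictionary` built from `tax`.
#' @param tax The `orpha_taxonomy` the dictionary was built from.
#' @param config An [annotator_config()].
#' @return An object of class `orpha_annotation`: `doc_id`, `mentions`
#'   (data.frame), `direct_concepts` (sorted codes), `propagated`
#'   (data.frame `code`, `source`, `distance`) and `final_concepts`
#'   (data.frame `code`, `origin`, `source`, `distance`).
#' @export
annotate_document <- function(rec, dict, tax,
                              config = annotator_config()) {
  .check_record(rec)
  .check_dictionary(dict)
  .check_taxonomy(tax)
  doc <- prepare_document(rec, dict$policy)
  em <- exact_match(doc, dict)
  fm <- if (config$fuzzy) fuzzy_match(doc, dict, config$fuzzy_threshold)
        else .empty_mentions()
  mentions <- combine_mentions(em, fm)
  codes <- mentions$code
  if (config$resolve_mentions && length(codes)) {
    codes <- .resolve_or_na(tax, codes)
    codes <- codes[!is.na(codes)]
  }
  direct <- sort(unique(codes))
  propagated <- if (config$propagate && length(direct)) {
    propagate_concepts(direct, tax, config$max_dist)
  } else {
    data.frame(code = character(0), source = character(0),
               distance = integer(0), stringsAsFactors = FALSE)
  }
  final <- .final_concepts(direct, propagated)
  structure(
    list(doc_id = rec$doc_id, mentions = mentions, direct_concepts = direct,
         propagated = propagated, final_concepts = final, config = config),
    class = "orpha_annotation"
  )
}

# one row per final code: direct codes as-is, propagated codes with their
# minimum distance and (deterministically) the lexicographically first source
# among minimum-distance sources
.final_concepts <- function(direct, propagated) {
  rows <- list()
  for (cd in direct) {
    rows[[length(rows) + 1L]] <- data.frame(
      code = cd, origin = "direct", source = NA_character_, distance = 0L,
      stringsAsFactors = FALSE
    )
  }
  for (cd in sort(unique(propagated$code))) {
    sub <- propagated[propagated$code == cd, , drop = FALSE]
    dmin <- min(sub$distance)
    src <- sort(sub$source[sub$distance == dmin])[1]
    rows[[length(rows) + 1L]] <- data.frame(
      code = cd, origin = "propagated", source = src, distance = dmin,
      stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) {
    return(data.frame(code = character(0), origin = character(0),
                      source = character(0), distance = integer(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$code), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate a corpus
#'
#' @param corpus A list of [article_record()]s.
#' @param dict,tax,config As in [annotate_document()].
#' @return A list of `orpha_annotation`s, one per record, named by `doc_id`.
#' @export
annotate_corpus <- function(corpus, dict, tax, config = annotator_config()) {
  anns <- lapply(corpus, annotate_document, dict = dict, tax = tax,
                 config = config)
  names(anns) <- vapply(anns, `[[`, character(1), "doc_id")
  anns
}

#' Extract per-document predicted concept sets
#'
#' @param annotations A list of `orpha_annotation`s.
#' @param include_propagated Include propagated concepts in the predicted
#'   sets (otherwise only directly matched concepts).
#' @return A named list mapping `doc_id` to a character vector of codes.
#' @export
prediction_sets <- function(annotations, include_propagated = TRUE) {
  out <- lapply(annotations, function(a) {
    if (include_propagated) a$final_concepts$code else a$direct_concepts
  })
  names(out) <- vapply(annotations, `[[`, character(1), "doc_id")
  out
}

#' @export
print.orpha_annotation <- function(x, ...) {
  cat("<orpha_annotation>", x$doc_id, "-", nrow(x$mentions), "mention(s),",
      length(x$direct_concepts), "direct,",
      length(unique(x$propagated$code)), "propagated concept(s)\n")
  invisible(x)
}
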