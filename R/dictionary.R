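# Compiled term dictionary: one entry per (concept, label-or-synonym) pair,
# normalized under a fixed policy, indexed for multi-pattern exact lookup
# over token n-grams. Surfaces shared by several concepts are recorded in an
# ambiguity map; the matcher emits one mention per mapped concept (no
# statistical disambiguation).

#' Compile a term dictionary from a taxonomy
#'
#' Every active concept contributes its preferred label and synonyms as
#' normalized term entries. Labels of deprecated concepts are remapped to
#' their active replacement via [resolve_concept()] (so an old name still
#' matches, but is assigned the current code); terminal-deprecated concepts
#' are skipped. Entries shorter than `min_term_chars` (typically acronyms)
#' are either dropped or retained for exact matching only, depending on
#' `short_term_policy` — short strings are never fuzzy-matched, which
#' preserves precision.
#'
#' @param tax An `orpha_taxonomy`.
#' @param policy A [normalization_policy()]; must match the policy used to
#'   prepare documents.
#' @param min_term_chars Minimum normalized surface length for a term to be
#'   eligible for fuzzy matching (default 4).
#' @param short_term_policy `"exact_only"` (default): short terms stay in the
#'   dictionary but only exact-match; `"drop"`: short terms are removed.
#' @param remap_deprecated Include labels of resolvable deprecated concepts,
#'   mapped to their active replacement.
#' @return An object of class `orpha_dictionary` with elements `entries`
#'   (data.frame: `surface`, `token_count`, `code`, `source`, `original`,
#'   `fuzzy_eligible`), `ambiguity` (named list surface -> codes), `policy`,
#'   and the compiled exact-lookup index.
#' @export
build_dictionary <- function(tax,
                             policy = normalization_policy(),
                             min_term_chars = 4L,
                             short_term_policy = c("exact_only", "drop"),
                             remap_deprecated = TRUE) {
  .check_taxonomy(tax)
  .check_policy(policy)
  short_term_policy <- match.arg(short_term_policy)
  min_term_chars <- as.integer(min_term_chars)

  act <- active_codes(tax)
  if (!length(act)) stop("taxonomy has no active concepts", call. = FALSE)

  rows <- list()
  for (cp in tax$concepts) {
    if (cp$status == "active") {
      target <- cp$code
    } else if (remap_deprecated) {
      target <- tryCatch(resolve_concept(tax, cp$code),
                         orpha_unresolvable = function(e) NA_character_)
      if (is.na(target)) next
    } else {
      next
    }
    surfaces <- c(cp$preferred_label, cp$synonyms)
    src <- c("preferred_label", rep("synonym", length(cp$synonyms)))
    rows[[length(rows) + 1L]] <- data.frame(
      code = target, original = surfaces, source = src,
      stringsAsFactors = FALSE
    )
  }
  entries <- do.call(rbind, rows)
  entries$surface <- normalize_text(entries$original, policy)
  entries <- entries[nzchar(entries$surface), , drop = FALSE]
  entries$token_count <- vapply(strsplit(entries$surface, " ", fixed = TRUE),
                                length, integer(1))
  entries$nchar <- nchar(entries$surface)

  short <- entries$nchar < min_term_chars
  if (short_term_policy == "drop") {
    entries <- entries[!short, , drop = FALSE]
    entries$fuzzy_eligible <- rep(TRUE, nrow(entries))
  } else {
    entries$fuzzy_eligible <- !short
  }
  if (!nrow(entries)) stop("no dictionary entries survive filtering", call. = FALSE)

  # deduplicate identical (code, surface) pairs silently (e.g. a synonym that
  # normalizes to the preferred label); keep the preferred_label row if present
  entries <- entries[order(entries$code, entries$surface,
                           entries$source != "preferred_label"), , drop = FALSE]
  dup <- duplicated(entries[, c("code", "surface")])
  entries <- entries[!dup, , drop = FALSE]
  rownames(entries) <- NULL
  entries <- entries[, c("surface", "token_count", "code", "source",
                         "original", "nchar", "fuzzy_eligible")]

  # surface -> entry row indices (hashed environment = the exact-match index)
  index <- new.env(parent = emptyenv(), size = nrow(entries) * 2L)
  for (i in seq_len(nrow(entries))) {
    s <- entries$surface[i]
    index[[s]] <- c(index[[s]], i)
  }
  ambiguity <- list()
  for (s in ls(index)) {
    codes <- unique(entries$code[index[[s]]])
    if (length(codes) > 1L) ambiguity[[s]] <- sort(codes)
  }

  structure(
    list(
      entries = entries,
      index = index,
      token_counts = sort(unique(entries$token_count)),
      ambiguity = ambiguity,
      policy = policy,
      policy_key = .policy_key(policy),
      min_term_chars = min_term_chars,
      short_term_policy = short_term_policy,
      taxonomy_version = tax$version_tag
    ),
    class = "orpha_dictionary"
  )
}

.check_dictionary <- function(dict) {
  if (!inherits(dict, "orpha_dictionary")) {
    stop("expected an `orpha_dictionary` object", call. = FALSE)
  }
  dict
}

#' @export
print.orpha_dictionary <- function(x, ...) {
  cat("<orpha_dictionary>", nrow(x$entries), "entries over",
      length(unique(x$entries$code)), "concepts\n")
  cat("  token counts:", paste(x$token_counts, collapse = ", "), "\n")
  cat("  ambiguous surfaces:", length(x$ambiguity), "\n")
  cat("  min_term_chars:", x$min_term_chars,
      "| short terms:", x$short_term_policy, "\n")
  invisible(x)
}

#' Export a dictionary to TSV
#'
#' Columns: `surface_normalized`, `concept_code`, `source`,
#' `original_surface`. Intended for auditing and diffing dictionaries built
#' from different taxonomy versions.
#'
#' @param dict An `orpha_dictionary`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
export_dictionary_tsv <- function(dict, path) {
  .check_dictionary(dict)
  df <- data.frame(
    surface_normalized = dict$entries$surface,
    concept_code = dict$entries$code,
    source = dict$entries$source,
    original_surface = dict$entries$original,
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
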