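# Bibliometric aggregation of annotations: publication counts per disease
# concept, country or subject area under the full-counting convention (every
# (publication, key) incidence contributes one full count, so a co-authored
# publication counts once for each collaborating country, and a publication
# indexed with k diseases counts once for each of them).

#' Aggregate annotations into a count table
#'
#' Documents with no final concept are excluded. For `dimension =
#' "concept"`, each distinct concept of a publication counts once; for
#' `"country"` and `"subject_area"`, each metadata value counts once per
#' publication (full counting). Also reports the number of unique
#' publications matched to at least one disease and the total number of
#' (publication, concept) matches — two different totals by construction.
#'
#' @param annotations A list of `orpha_annotation`s.
#' @param corpus The list of [article_record()]s the annotations came from
#'   (source of the metadata); required for the metadata dimensions.
#' @param dimension One of `"concept"`, `"country"`, `"subject_area"`.
#' @param include_propagated Count propagated concepts in addition to
#'   directly matched ones.
#' @return An object of class `orpha_counts`: `dimension`, `rows`
#'   (data.frame `key`, `publication_count`, sorted by count descending,
#'   ties broken lexicographically), `counting = "full"`,
#'   `n_unique_publications`, `n_total_matches`, `include_propagated`.
#' @export
aggregate_counts <- function(annotations, corpus = NULL,
                             dimension = c("concept", "country",
                                           "subject_area"),
                             include_propagated = FALSE) {
  dimension <- match.arg(dimension)
  meta <- list()
  if (!is.null(corpus)) {
    for (rec in corpus) meta[[rec$doc_id]] <- rec$metadata
  }
  concept_sets <- prediction_sets(annotations, include_propagated)
  has_concept <- vapply(concept_sets, function(x) length(x) > 0L, logical(1))
  concept_sets <- concept_sets[has_concept]
  n_unique <- length(concept_sets)
  n_total <- sum(vapply(concept_sets, length, integer(1)))

  keys <- character(0)
  if (dimension == "concept") {
    keys <- unlist(concept_sets, use.names = FALSE)
  } else {
    fld <- if (dimension == "country") "countries" else "subject_areas"
    for (d in names(concept_sets)) {
      vals <- meta[[d]][[fld]]
      if (is.null(vals) || !length(vals)) {
        warning("document '", d, "' has no metadata field '", fld,
                "'; skipped for dimension '", dimension, "'", call. = FALSE)
        next
      }
      keys <- c(keys, unique(as.character(vals)))
    }
  }
  rows <- if (length(keys)) {
    tab <- table(keys)
    df <- data.frame(key = names(tab), publication_count = as.integer(tab),
                     stringsAsFactors = FALSE)
    df[order(-df$publication_count, df$key), , drop = FALSE]
  } else {
    data.frame(key = character(0), publication_count = integer(0),
               stringsAsFactors = FALSE)
  }
  rownames(rows) <- NULL
  structure(
    list(dimension = dimension, rows = rows, counting = "full",
         n_unique_publications = n_unique, n_total_matches = n_total,
         include_propagated = isTRUE(include_propagated)),
    class = "orpha_counts"
  )
}

#' Top-N rows of a count table
#'
#' Sorts by count descending (ties broken lexicographically by key), removes
#' excluded keys before truncation, and keeps the first `n` rows. Exclusion
#' before truncation mirrors the convention of dropping a dominant catch-all
#' category (e.g. "Medicine") from subject-area rankings.
#'
#' @param table An `orpha_counts`.
#' @param n Number of rows to retain (>= 1).
#' @param exclude Character vector of keys to remove before truncation.
#' @return An `orpha_counts` with at most `n` rows (totals unchanged).
#' @export
top_counts <- function(table, n, exclude = character(0)) {
  if (!inherits(table, "orpha_counts")) {
    stop("expected an `orpha_counts` object", call. = FALSE)
  }
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("`n` must be >= 1", call. = FALSE)
  rows <- table$rows
  rows <- rows[!rows$key %in% exclude, , drop = FALSE]
  rows <- rows[order(-rows$publication_count, rows$key), , drop = FALSE]
  rows <- utils::head(rows, n)
  rownames(rows) <- NULL
  out <- table
  out$rows <- rows
  out
}

#' Write a count table as TSV plus a JSON summary
#'
#' @param table An `orpha_counts`.
#' @param path Output TSV path (`key`, `count`).
#' @param summary_path Optional JSON path for
#'   `{n_unique_publications, n_total_matches, dimension,
#'   include_propagated}`.
#' @return `path`, invisibly.
#' @export
write_counts_tsv <- function(table, path, summary_path = NULL) {
  if (!inherits(table, "orpha_counts")) {
    stop("expected an `orpha_counts` object", call. = FALSE)
  }
  df <- table$rows
  names(df) <- c("key", "count")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  if (!is.null(summary_path)) {
    jsonlite::write_json(
      list(dimension = table$dimension,
           n_unique_publications = table$n_unique_publications,
           n_total_matches = table$n_total_matches,
           counting = table$counting,
           include_propagated = table$include_propagated),
      summary_path, auto_unbox = TRUE
    )
  }
  invisible(path)
}

#' @export
print.orpha_counts <- function(x, n = 10, ...) {
  cat("<orpha_counts> by", x$dimension, "| full counting",
      if (x$include_propagated) "(incl. propagated)" else "(direct only)", "\n")
  cat("  unique publications:", x$n_unique_publications,
      "| total matches:", x$n_total_matches, "\n")
  print(utils::head(x$rows, n), row.names = FALSE)
  invisible(x)
}
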