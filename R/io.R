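# File formats: JSONL corpora and annotations, TSV/JSONL gold labels.
# All files are UTF-8 plain text.

#' Read a corpus from JSONL
#'
#' One article record per line:
#' `{"doc_id", "title", "abstract", "keywords", "metadata"}`.
#'
#' @param path Path to a JSONL file.
#' @return A list of [article_record()]s.
#' @export
read_corpus_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(ln) {
    x <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
    if (is.null(x$doc_id)) stop("corpus line without doc_id", call. = FALSE)
    article_record(
      doc_id = x$doc_id,
      title = x$title %||% "",
      abstract = x$abstract %||% "",
      keywords = unlist(x$keywords, use.names = FALSE) %||% character(0),
      metadata = .canon_metadata(x$metadata)
    )
  })
}

.canon_metadata <- function(md) {
  if (is.null(md)) return(list())
  out <- list()
  if (!is.null(md$year)) out$year <- as.integer(md$year)
  if (!is.null(md$countries)) {
    out$countries <- as.character(unlist(md$countries, use.names = FALSE))
  }
  if (!is.null(md$subject_areas)) {
    out$subject_areas <- as.character(unlist(md$subject_areas,
                                             use.names = FALSE))
  }
  out
}

#' Write a corpus to JSONL
#'
#' @param corpus A list of [article_record()]s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corpus_jsonl <- function(corpus, path) {
  lines <- vapply(corpus, function(rec) {
    jsonlite::toJSON(list(
      doc_id = rec$doc_id, title = rec$title, abstract = rec$abstract,
      keywords = as.list(rec$keywords),
      metadata = if (length(rec$metadata)) {
        md <- rec$metadata
        if (!is.null(md$countries)) md$countries <- as.list(md$countries)
        if (!is.null(md$subject_areas)) {
          md$subject_areas <- as.list(md$subject_areas)
        }
        md
      } else NULL
    ), auto_unbox = TRUE, null = "null")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write annotations to JSONL (and optionally a flat TSV)
#'
#' Each JSONL line carries the document's mentions (with offsets, matched
#' term, match type and score) and its final concept set with propagation
#' provenance. The TSV companion (`doc_id`, `code`, `origin`) is the flat
#' form consumed by downstream counting.
#'
#' @param annotations A list of `orpha_annotation`s.
#' @param path Output JSONL path.
#' @param tsv_path Optional output TSV path.
#' @return `path`, invisibly.
#' @export
write_annotations_jsonl <- function(annotations, path, tsv_path = NULL) {
  lines <- vapply(annotations, function(a) {
    mentions <- lapply(seq_len(nrow(a$mentions)), function(i) {
      m <- a$mentions[i, ]
      list(code = m$code, start = m$start, end = m$end, surface = m$surface,
           matched_term = m$matched_term, match_type = m$match_type,
           score = m$score)
    })
    finals <- lapply(seq_len(nrow(a$final_concepts)), function(i) {
      f <- a$final_concepts[i, ]
      list(code = f$code, origin = f$origin,
           source = if (is.na(f$source)) NULL else f$source,
           distance = f$distance)
    })
    jsonlite::toJSON(list(doc_id = a$doc_id, mentions = mentions,
                          final_concepts = finals),
                     auto_unbox = TRUE, null = "null", digits = NA)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  if (!is.null(tsv_path)) {
    rows <- do.call(rbind, lapply(annotations, function(a) {
      if (!nrow(a$final_concepts)) return(NULL)
      data.frame(doc_id = a$doc_id, code = a$final_concepts$code,
                 origin = a$final_concepts$origin, stringsAsFactors = FALSE)
    }))
    if (is.null(rows)) {
      rows <- data.frame(doc_id = character(0), code = character(0),
                         origin = character(0))
    }
    utils::write.table(rows, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' Read gold labels
#'
#' Accepts either a TSV with columns `doc_id`, `code` (one pair per row) or
#' a JSONL file with lines `{"doc_id": ..., "codes": [...]}`; the format is
#' chosen by file extension (`.tsv`/`.txt` vs `.jsonl`/`.json`).
#'
#' @param path Input path.
#' @param provenance Provenance string stored on the gold set.
#' @return An `orpha_gold`.
#' @export
read_gold <- function(path, provenance = path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tsv", "txt")) {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            colClasses = "character", fileEncoding = "UTF-8")
    if (!all(c("doc_id", "code") %in% names(df))) {
      stop("gold TSV must have columns doc_id, code", call. = FALSE)
    }
    labels <- split(df$code, df$doc_id)
  } else if (ext %in% c("jsonl", "json")) {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    labels <- list()
    for (ln in lines) {
      x <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
      labels[[x$doc_id]] <- unlist(x$codes, use.names = FALSE)
    }
  } else {
    stop("unsupported gold file extension: .", ext, call. = FALSE)
  }
  gold_set(labels, provenance = provenance)
}

#' Write gold labels as TSV
#'
#' @param gold An `orpha_gold`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_gold_tsv <- function(gold, path) {
  .check_gold(gold)
  rows <- do.call(rbind, lapply(names(gold$labels), function(d) {
    data.frame(doc_id = d, code = gold$labels[[d]], stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
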