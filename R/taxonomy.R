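# Rare-disease taxonomy: load, validate, resolve deprecated codes, ancestor
# queries, cross-vocabulary coverage.
#
# The taxonomy mirrors the structure of the OrphaNet nomenclature: each
# concept has an opaque code (ORPHAcode-like), a preferred label, synonyms,
# an active/deprecated status with an optional replacement code, and zero or
# more parents. The parent graph is a DAG (poly-hierarchy is allowed); top
# nodes are generic disease groups, leaves the most specific diseases.

#' Construct a taxonomy from a list of concepts
#'
#' Validates the full set of structural invariants: unique codes, resolvable
#' parent references, acyclic parent graph, acyclic and resolvable
#' `replaced_by` chains, and no self-parenting.
#'
#' @param concepts A list of concept entries, each a list with elements
#'   `code`, `preferred_label`, `synonyms` (character vector, possibly
#'   empty), `status` (`"active"` or `"deprecated"`), `replaced_by`
#'   (code or `NULL`) and `parents` (character vector of codes).
#' @param version_tag Free-text version identifier.
#' @return An object of class `orpha_taxonomy`.
#' @export
taxonomy <- function(concepts, version_tag = "unversioned") {
  if (!is.list(concepts) || length(concepts) == 0L) {
    stop("`concepts` must be a non-empty list", call. = FALSE)
  }
  concepts <- lapply(concepts, .canon_concept)
  codes <- vapply(concepts, `[[`, character(1), "code")
  dup <- unique(codes[duplicated(codes)])
  if (length(dup)) {
    stop("duplicate concept code(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  names(concepts) <- codes
  tax <- structure(
    list(concepts = concepts, version_tag = as.character(version_tag)[1]),
    class = "orpha_taxonomy"
  )
  .validate_taxonomy(tax)
  tax
}

.canon_concept <- function(x) {
  if (is.null(x$code) || !nzchar(x$code)) {
    stop("concept with missing or empty `code`", call. = FALSE)
  }
  code <- as.character(x$code)[1]
  if (is.null(x$preferred_label) || !nzchar(x$preferred_label)) {
    stop("concept '", code, "': missing `preferred_label`", call. = FALSE)
  }
  status <- if (is.null(x$status)) "active" else as.character(x$status)[1]
  if (!status %in% c("active", "deprecated")) {
    stop("concept '", code, "': status must be 'active' or 'deprecated', got '",
         status, "'", call. = FALSE)
  }
  replaced_by <- x$replaced_by
  if (!is.null(replaced_by) && (length(replaced_by) == 0L || is.na(replaced_by))) {
    replaced_by <- NULL
  }
  if (!is.null(replaced_by)) replaced_by <- as.character(replaced_by)[1]
  parents <- unique(as.character(if (is.null(x$parents)) character(0) else x$parents))
  parents <- parents[!is.na(parents) & nzchar(parents)]
  if (code %in% parents) {
    stop("concept '", code, "' lists itself as parent", call. = FALSE)
  }
  synonyms <- as.character(if (is.null(x$synonyms)) character(0) else x$synonyms)
  synonyms <- synonyms[!is.na(synonyms) & nzchar(synonyms)]
  list(
    code = code,
    preferred_label = as.character(x$preferred_label)[1],
    synonyms = synonyms,
    status = status,
    replaced_by = replaced_by,
    parents = parents
  )
}

.validate_taxonomy <- function(tax) {
  codes <- names(tax$concepts)
  for (cp in tax$concepts) {
    missing_par <- setdiff(cp$parents, codes)
    if (length(missing_par)) {
      stop("concept '", cp$code, "' references unknown parent(s): ",
           paste(missing_par, collapse = ", "), call. = FALSE)
    }
    if (!is.null(cp$replaced_by) && !cp$replaced_by %in% codes) {
      stop("concept '", cp$code, "' replaced_by unknown code '",
           cp$replaced_by, "'", call. = FALSE)
    }
    if (cp$status == "active" && !is.null(cp$replaced_by)) {
      stop("active concept '", cp$code, "' must not carry replaced_by",
           call. = FALSE)
    }
  }
  cyc <- .find_cycle(tax, edge = "parents")
  if (!is.null(cyc)) {
    stop("cycle in parent graph: ", paste(cyc, collapse = " -> "),
         call. = FALSE)
  }
  cyc <- .find_cycle(tax, edge = "replaced_by")
  if (!is.null(cyc)) {
    stop("cycle in replaced_by chain: ", paste(cyc, collapse = " -> "),
         call. = FALSE)
  }
  invisible(tax)
}

# Iterative DFS cycle detection (colors: 0 unseen, 1 on stack, 2 done).
# Returns the cycle as a code vector, or NULL.
.find_cycle <- function(tax, edge = c("parents", "replaced_by")) {
  edge <- match.arg(edge)
  codes <- names(tax$concepts)
  color <- integer(length(codes))
  names(color) <- codes
  succ <- function(code) {
    cp <- tax$concepts[[code]]
    if (edge == "parents") cp$parents
    else if (is.null(cp$replaced_by)) character(0) else cp$replaced_by
  }
  for (start in codes) {
    if (color[start] != 0L) next
    stack <- list(list(node = start, i = 0L))
    path <- character(0)
    color[start] <- 1L
    path <- c(path, start)
    while (length(stack)) {
      top <- stack[[length(stack)]]
      nxt <- succ(top$node)
      if (top$i < length(nxt)) {
        stack[[length(stack)]]$i <- top$i + 1L
        child <- nxt[top$i + 1L]
        if (color[child] == 1L) {
          at <- match(child, path)
          return(c(path[at:length(path)], child))
        }
        if (color[child] == 0L) {
          color[child] <- 1L
          path <- c(path, child)
          stack[[length(stack) + 1L]] <- list(node = child, i = 0L)
        }
      } else {
        color[top$node] <- 2L
        path <- path[-length(path)]
        stack[[length(stack)]] <- NULL
      }
    }
  }
  NULL
}

#' Load a taxonomy from its JSON interchange format
#'
#' The schema is `{"version": str, "concepts": [{"code", "preferred_label",
#' "synonyms", "status", "replaced_by", "parents"}]}` in UTF-8. With
#' `strict = TRUE`, unknown keys in a concept entry are rejected.
#'
#' @param path Path to a JSON file.
#' @param format Input format; only `"json"` is supported.
#' @param strict Reject unknown keys in concept entries.
#' @return An `orpha_taxonomy`.
#' @export
load_taxonomy <- function(path, format = "json", strict = FALSE) {
  format <- match.arg(format, "json")
  if (!file.exists(path)) stop("taxonomy file not found: ", path, call. = FALSE)
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(raw$concepts)) {
    stop("taxonomy JSON must have a top-level 'concepts' array", call. = FALSE)
  }
  known <- c("code", "preferred_label", "synonyms", "status", "replaced_by",
             "parents")
  if (strict) {
    for (cp in raw$concepts) {
      extra <- setdiff(names(cp), known)
      if (length(extra)) {
        stop("concept '", cp$code %||% "<missing code>",
             "': unknown key(s) under strict validation: ",
             paste(extra, collapse = ", "), call. = FALSE)
      }
    }
  }
  concepts <- lapply(raw$concepts, function(cp) {
    cp$synonyms <- unlist(cp$synonyms, use.names = FALSE)
    cp$parents <- unlist(cp$parents, use.names = FALSE)
    cp
  })
  taxonomy(concepts, version_tag = raw$version %||% "unversioned")
}

#' Write a taxonomy to the JSON interchange format
#'
#' @param tax An `orpha_taxonomy`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_taxonomy_json <- function(tax, path) {
  .check_taxonomy(tax)
  concepts <- lapply(unname(tax$concepts), function(cp) {
    list(
      code = cp$code,
      preferred_label = cp$preferred_label,
      synonyms = as.list(cp$synonyms),
      status = cp$status,
      replaced_by = cp$replaced_by,
      parents = as.list(cp$parents)
    )
  })
  jsonlite::write_json(list(version = tax$version_tag, concepts = concepts),
                       path, auto_unbox = TRUE, null = "null", pretty = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.check_taxonomy <- function(tax) {
  if (!inherits(tax, "orpha_taxonomy")) {
    stop("expected an `orpha_taxonomy` object", call. = FALSE)
  }
  tax
}

.check_code <- function(tax, code) {
  if (length(code) != 1L || is.na(code) || !code %in% names(tax$concepts)) {
    stop("unknown concept code: '", code, "'", call. = FALSE)
  }
  code
}

#' Codes of active concepts
#'
#' @param tax An `orpha_taxonomy`.
#' @return Character vector of active concept codes, in taxonomy order.
#' @export
active_codes <- function(tax) {
  .check_taxonomy(tax)
  st <- vapply(tax$concepts, `[[`, character(1), "status")
  names(tax$concepts)[st == "active"]
}

#' Resolve a (possibly deprecated) code to its active replacement
#'
#' Follows `replaced_by` links transitively until an active concept is
#' reached; the OrphaNet-style deprecation convention under which, e.g.,
#' a renamed concept's old label redirects to the current one. Active codes
#' resolve to themselves. A deprecated concept with no replacement
#' (terminal-deprecated) raises an error of class `orpha_unresolvable`
#' carrying the deprecated code.
#'
#' @param tax An `orpha_taxonomy`.
#' @param code A single concept code present in `tax`.
#' @return The active code.
#' @export
resolve_concept <- function(tax, code) {
  .check_taxonomy(tax)
  .check_code(tax, code)
  cur <- code
  repeat {
    cp <- tax$concepts[[cur]]
    if (cp$status == "active") return(cur)
    if (is.null(cp$replaced_by)) {
      stop(structure(
        class = c("orpha_unresolvable", "error", "condition"),
        list(message = paste0("concept '", cur,
                              "' is deprecated with no replacement"),
             call = sys.call(-1), code = cur)
      ))
    }
    cur <- cp$replaced_by  # chain acyclicity validated at load time
  }
}

# Vectorized resolve that maps terminal-deprecated codes to NA instead of
# erroring; used internally where skipping is the right behavior.
.resolve_or_na <- function(tax, codes) {
  vapply(codes, function(cd) {
    tryCatch(resolve_concept(tax, cd),
             orpha_unresolvable = function(e) NA_character_)
  }, character(1), USE.NAMES = FALSE)
}

# BFS up the parent DAG; returns named integer vector of shortest-path
# distances (1..max_dist) for all ancestors within max_dist.
.ancestor_distances <- function(tax, code, max_dist) {
  dist <- stats::setNames(integer(0), character(0))
  frontier <- code
  d <- 0L
  seen <- code
  while (length(frontier) && d < max_dist) {
    d <- d + 1L
    nxt <- unique(unlist(lapply(frontier, function(cd) {
      tax$concepts[[cd]]$parents
    }), use.names = FALSE))
    nxt <- setdiff(nxt, seen)
    if (!length(nxt)) break
    dist[nxt] <- d
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  dist
}

#' Ancestors within a bounded hierarchy distance
#'
#' Returns all concepts reachable from `code` by following 1 to `max_dist`
#' parent edges, with distance taken as the shortest path in the DAG. The
#' input code itself is excluded; multiple parent paths are deduplicated.
#'
#' @param tax An `orpha_taxonomy`.
#' @param code A concept code present in `tax`.
#' @param max_dist Maximum ancestor distance (>= 1).
#' @return Character vector of ancestor codes (sorted).
#' @export
ancestors_within <- function(tax, code, max_dist = 2L) {
  .check_taxonomy(tax)
  .check_code(tax, code)
  max_dist <- as.integer(max_dist)
  if (is.na(max_dist) || max_dist < 1L) {
    stop("`max_dist` must be a positive integer", call. = FALSE)
  }
  sort(names(.ancestor_distances(tax, code, max_dist)))
}

#' Coverage of the taxonomy by another vocabulary
#'
#' Fraction of the taxonomy's active concepts that are present in another
#' vocabulary, given as a set of identifiers after any external mapping
#' (identifier construction is up to the caller).
#'
#' @param tax An `orpha_taxonomy`.
#' @param other_vocabulary Character vector of identifiers.
#' @return A fraction in `[0, 1]`.
#' @export
taxonomy_coverage <- function(tax, other_vocabulary) {
  .check_taxonomy(tax)
  act <- active_codes(tax)
  if (!length(act)) stop("taxonomy has no active concepts", call. = FALSE)
  length(intersect(act, unique(as.character(other_vocabulary)))) / length(act)
}

#' @export
print.orpha_taxonomy <- function(x, ...) {
  st <- vapply(x$concepts, `[[`, character(1), "status")
  n_edge <- sum(vapply(x$concepts, function(cp) length(cp$parents), integer(1)))
  cat("<orpha_taxonomy> version:", x$version_tag, "\n")
  cat("  concepts:", length(x$concepts),
      sprintf("(%d active, %d deprecated)", sum(st == "active"),
              sum(st == "deprecated")), "\n")
  cat("  parent edges:", n_edge, "\n")
  invisible(x)
}
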