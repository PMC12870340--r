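# Text normalization with character-level offset bookkeeping.
#
# Disease names carry diacritics, Greek letters and punctuation
# ("beta-thalassemia" vs "β thalassemia"); matching is done on a
# normalized surface while annotation offsets must refer to the original
# text, so every normalization step tracks, for each output character,
# the index of the original character it came from.

.greek_map <- c(
  "α" = "alpha",   "Α" = "alpha",
  "β" = "beta",    "Β" = "beta",
  "γ" = "gamma",   "Γ" = "gamma",
  "δ" = "delta",   "Δ" = "delta",
  "ε" = "epsilon", "Ε" = "epsilon",
  "ζ" = "zeta",    "Ζ" = "zeta",
  "η" = "eta",     "Η" = "eta",
  "θ" = "theta",   "Θ" = "theta",
  "ι" = "iota",    "Ι" = "iota",
  "κ" = "kappa",   "Κ" = "kappa",
  "λ" = "lambda",  "Λ" = "lambda",
  "μ" = "mu",      "Μ" = "mu",
  "µ" = "mu",      # micro sign, often used for Greek mu
  "ν" = "nu",      "Ν" = "nu",
  "ξ" = "xi",      "Ξ" = "xi",
  "ο" = "omicron", "Ο" = "omicron",
  "π" = "pi",      "Π" = "pi",
  "ρ" = "rho",     "Ρ" = "rho",
  "σ" = "sigma",   "ς" = "sigma", "Σ" = "sigma",
  "τ" = "tau",     "Τ" = "tau",
  "υ" = "upsilon", "Υ" = "upsilon",
  "φ" = "phi",     "Φ" = "phi",
  "χ" = "chi",     "Χ" = "chi",
  "ψ" = "psi",     "Ψ" = "psi",
  "ω" = "omega",   "Ω" = "omega"
)

#' Create a text normalization policy
#'
#' A normalization policy fixes the deterministic text cleanup applied both
#' to dictionary terms and to documents before matching. All steps are
#' idempotent, so `normalize_text()` is a fixed point on its own output.
#'
#' @param lowercase Lowercase all characters.
#' @param strip_diacritics Map accented Latin characters to their ASCII base
#'   (e.g. "Sjögren" to "sjogren").
#' @param transliterate_greek Spell out Greek letters with their Latin names
#'   (e.g. "β" to "beta"), so "β-thalassemia" and
#'   "beta-thalassemia" normalize identically.
#' @param non_alnum_to_space Replace every character that is not an ASCII
#'   letter or digit by a space. Digits are kept: many disease names contain
#'   numerals ("type 1").
#' @param collapse_whitespace Collapse runs of whitespace to a single space
#'   and trim the ends.
#'
#' @return An object of class `orpha_policy`.
#' @export
#' @examples
#' normalize_text("β-Thalassemia", normalization_policy())
normalization_policy <- function(lowercase = TRUE,
                                 strip_diacritics = TRUE,
                                 transliterate_greek = TRUE,
                                 non_alnum_to_space = TRUE,
                                 collapse_whitespace = TRUE) {
  pol <- list(
    lowercase = isTRUE(lowercase),
    strip_diacritics = isTRUE(strip_diacritics),
    transliterate_greek = isTRUE(transliterate_greek),
    non_alnum_to_space = isTRUE(non_alnum_to_space),
    collapse_whitespace = isTRUE(collapse_whitespace)
  )
  class(pol) <- "orpha_policy"
  pol
}

#' @export
print.orpha_policy <- function(x, ...) {
  on <- names(Filter(isTRUE, unclass(x)))
  cat("<orpha_policy> steps:", paste(on, collapse = ", "), "\n")
  invisible(x)
}

.policy_key <- function(policy) {
  paste(vapply(unclass(policy), function(v) as.character(as.integer(v)),
               character(1)), collapse = "")
}

.check_policy <- function(policy) {
  if (!inherits(policy, "orpha_policy")) {
    stop("`policy` must be created with normalization_policy()", call. = FALSE)
  }
  policy
}

# Core: normalize `s` character by character, returning the output characters
# together with, for each, the 0-based index of the original character that
# produced it. One original character may expand to several output characters
# (Greek transliteration) or to none (rare translit drops).
.norm_chars <- function(s, policy) {
  if (length(s) != 1L) stop("`s` must be a single string", call. = FALSE)
  if (is.na(s) || !nzchar(s)) {
    return(list(chars = character(0), orig = integer(0)))
  }
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  repl <- chars
  if (policy$transliterate_greek) {
    hit <- match(repl, names(.greek_map))
    idx <- which(!is.na(hit))
    if (length(idx)) repl[idx] <- unname(.greek_map[hit[idx]])
  }
  if (policy$strip_diacritics) {
    non_ascii <- which(vapply(repl, function(ch) any(utf8ToInt(ch) > 127L),
                              logical(1)))
    if (length(non_ascii)) {
      repl[non_ascii] <- stringi::stri_trans_general(repl[non_ascii],
                                                     "Latin-ASCII")
    }
  }
  if (policy$lowercase) repl <- tolower(repl)
  if (policy$non_alnum_to_space) {
    repl <- gsub("[^0-9A-Za-z]", " ", repl)
  }
  nc <- nchar(repl, type = "chars")
  orig <- rep.int(seq_along(chars) - 1L, nc)
  keep <- nc > 0L
  out <- unlist(strsplit(repl[keep], "", fixed = TRUE), use.names = FALSE)
  if (is.null(out)) out <- character(0)
  if (policy$collapse_whitespace && length(out)) {
    is_sp <- out %in% c(" ", "\t", "\n", "\r")
    out[is_sp] <- " "
    # drop a space if it is first or follows another space; then trim the tail
    drop <- is_sp & c(TRUE, is_sp[-length(is_sp)])
    out <- out[!drop]
    orig <- orig[!drop]
    while (length(out) && out[length(out)] == " ") {
      out <- out[-length(out)]
      orig <- orig[-length(orig)]
    }
  }
  list(chars = out, orig = orig)
}

#' Normalize a string under a policy
#'
#' Applies, in order: Greek transliteration, diacritic stripping,
#' lowercasing, replacement of non-alphanumeric characters by spaces, and
#' whitespace collapsing. The function is total (any Unicode string is
#' accepted) and idempotent.
#'
#' @param s A character vector.
#' @param policy A [normalization_policy()].
#' @return A character vector of normalized strings.
#' @export
#' @examples
#' normalize_text("Niemann-Pick  disease,  type B", normalization_policy())
normalize_text <- function(s, policy = normalization_policy()) {
  .check_policy(policy)
  vapply(as.character(s), function(x) {
    if (is.na(x)) return(NA_character_)
    paste(.norm_chars(x, policy)$chars, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Tokenize a string with offsets into the original text
#'
#' Normalizes `s` under `policy` and splits the result into maximal
#' alphanumeric runs. Each token carries 0-based, half-open character
#' offsets into the ORIGINAL string, kept consistent through normalization
#' steps that change string length (e.g. "β" expanding to "beta").
#'
#' @param s A single string (the original, un-normalized text).
#' @param policy A [normalization_policy()].
#' @return A `data.frame` with columns `token`, `start`, `end`.
#' @export
#' @examples
#' tokenize_text("Gaucher disease")
#' tokenize_text("β-Thalassemia")
tokenize_text <- function(s, policy = normalization_policy()) {
  .check_policy(policy)
  nc <- .norm_chars(s, policy)
  empty <- data.frame(token = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE)
  if (!length(nc$chars)) return(empty)
  is_tok <- nc$chars != " "
  if (!any(is_tok)) return(empty)
  starts <- which(is_tok & !c(FALSE, is_tok[-length(is_tok)]))
  ends <- which(is_tok & !c(is_tok[-1], FALSE))
  data.frame(
    token = vapply(seq_along(starts), function(i) {
      paste(nc$chars[starts[i]:ends[i]], collapse = "")
    }, character(1)),
    start = nc$orig[starts],
    end = nc$orig[ends] + 1L,
    stringsAsFactors = FALSE
  )
}
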