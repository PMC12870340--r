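# Evaluation of predicted concept sets against gold labels: micro-averaged
# precision/recall/F1 over (document, concept) pairs, CorrectRatio and
# ExactRatio over documents, with Wilson score confidence intervals.

#' Wilson score confidence interval for a binomial proportion
#'
#' @param k Number of successes (0 <= k <= n).
#' @param n Number of trials (>= 1).
#' @param confidence Confidence level, default 0.95.
#' @return Numeric vector `c(lo, hi)`; always contains `k/n`.
#' @export
#' @examples
#' wilson_interval(0, 10)    # upper bound ~ 0.2775
#' wilson_interval(50, 100)  # symmetric about 0.5
wilson_interval <- function(k, n, confidence = 0.95) {
  if (length(k) != 1L || length(n) != 1L || is.na(k) || is.na(n)) {
    stop("`k` and `n` must be single non-missing numbers", call. = FALSE)
  }
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  if (k < 0 || k > n) stop("`k` must satisfy 0 <= k <= n", call. = FALSE)
  if (confidence <= 0 || confidence >= 1) {
    stop("`confidence` must be in (0, 1)", call. = FALSE)
  }
  z <- stats::qnorm((1 + confidence) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- (z / denom) * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  # boundary cases are exact by symmetry; avoids float residue around 0/1
  lo <- if (k == 0) 0 else max(0, center - half)
  hi <- if (k == n) 1 else min(1, center + half)
  c(lo = lo, hi = hi)
}

#' Construct a gold-label set
#'
#' @param labels Named list mapping `doc_id` to a non-empty character vector
#'   of concept codes.
#' @param provenance Free-text description of where the labels came from.
#' @return An object of class `orpha_gold`.
#' @export
gold_set <- function(labels, provenance = "unspecified") {
  if (!is.list(labels) || is.null(names(labels)) ||
      any(!nzchar(names(labels)))) {
    stop("`labels` must be a named list (doc_id -> codes)", call. = FALSE)
  }
  if (anyDuplicated(names(labels))) {
    stop("duplicate doc_id in gold labels", call. = FALSE)
  }
  labels <- lapply(labels, function(x) sort(unique(as.character(x))))
  if (any(vapply(labels, length, integer(1)) == 0L)) {
    stop("gold label sets must be non-empty", call. = FALSE)
  }
  structure(list(labels = labels, provenance = as.character(provenance)[1]),
            class = "orpha_gold")
}

.check_gold <- function(gold) {
  if (!inherits(gold, "orpha_gold")) {
    stop("expected an `orpha_gold` object (see gold_set())", call. = FALSE)
  }
  gold
}

#' Build a gold set by filtering external labels through a vocabulary mapping
#'
#' Emulates the construction of an evaluation set from corpora labeled with
#' another vocabulary (e.g. MeSH): a document is kept if and only if at
#' least one of its labels maps into the taxonomy; the retained gold sets
#' contain only the mapped codes, resolved to active concepts.
#'
#' @param external_labels Named list: `doc_id` -> character vector of
#'   external-vocabulary labels.
#' @param mapping Named character vector: external label -> taxonomy code
#'   (identity mapping permitted).
#' @param tax Optional `orpha_taxonomy`; when given, mapped codes are
#'   resolved via [resolve_concept()] and unresolvable ones dropped.
#' @param provenance Free-text provenance string.
#' @return An `orpha_gold` containing only documents with >= 1 mapped label.
#' @export
filter_gold_by_taxonomy <- function(external_labels, mapping, tax = NULL,
                                    provenance = "filtered") {
  if (length(mapping) == 0L || is.null(names(mapping))) {
    stop("`mapping` must be a non-empty named character vector", call. = FALSE)
  }
  out <- list()
  for (d in names(external_labels)) {
    labs <- as.character(external_labels[[d]])
    mapped <- unname(mapping[labs[labs %in% names(mapping)]])
    if (!is.null(tax)) {
      mapped <- mapped[mapped %in% names(tax$concepts)]
      mapped <- .resolve_or_na(tax, mapped)
      mapped <- mapped[!is.na(mapped)]
    }
    if (length(mapped)) out[[d]] <- sort(unique(mapped))
  }
  if (!length(out)) {
    warning("no document had a label mapping into the taxonomy; gold set is empty")
    return(structure(list(labels = list(), provenance = provenance),
                     class = "orpha_gold"))
  }
  gold_set(out, provenance = provenance)
}

#' Evaluate predicted concept sets against gold labels
#'
#' Micro-averaged over (document, concept) pairs pooled across the gold
#' documents: `tp` are predicted codes present in the gold set, `fp`
#' predicted codes absent from it, `fn` gold codes not predicted. Documents
#' missing from `predictions` are treated as empty predictions. Two
#' set-level metrics are also reported: CorrectRatio, the fraction of
#' documents with at least one correct detection, and ExactRatio, the
#' fraction whose predicted set equals the gold set exactly. Wilson score
#' intervals are attached to the four ratio-type metrics (precision on
#' `tp+fp` pairs, recall on `tp+fn` pairs, the two ratios on documents);
#' no interval is computed for F1, which is not a binomial proportion.
#'
#' @param predictions Named list: `doc_id` -> character vector of codes.
#' @param gold An `orpha_gold`.
#' @param confidence Confidence level for the Wilson intervals.
#' @param averaging `"micro"` (default) pools pairs; `"example"` additionally
#'   reports per-document averaged precision/recall/F1.
#' @return An object of class `orpha_eval`.
#' @export
evaluate_annotations <- function(predictions, gold, confidence = 0.95,
                                 averaging = c("micro", "example")) {
  .check_gold(gold)
  averaging <- match.arg(averaging)
  docs <- names(gold$labels)
  if (!length(docs)) stop("gold set is empty", call. = FALSE)
  missing <- setdiff(docs, names(predictions))
  if (length(missing)) {
    message(length(missing), " gold document(s) missing from predictions; ",
            "treated as empty predictions")
  }
  tp <- fp <- fn <- 0L
  n_correct <- n_exact <- 0L
  per_doc <- matrix(0, nrow = length(docs), ncol = 3,
                    dimnames = list(docs, c("p", "r", "f1")))
  for (d in docs) {
    g <- gold$labels[[d]]
    p <- unique(as.character(predictions[[d]] %||% character(0)))
    tpd <- length(intersect(p, g))
    fpd <- length(setdiff(p, g))
    fnd <- length(setdiff(g, p))
    tp <- tp + tpd; fp <- fp + fpd; fn <- fn + fnd
    if (tpd > 0L) n_correct <- n_correct + 1L
    if (setequal(p, g)) n_exact <- n_exact + 1L
    pd <- if (tpd + fpd > 0L) tpd / (tpd + fpd) else 0
    rd <- if (tpd + fnd > 0L) tpd / (tpd + fnd) else 0
    per_doc[d, ] <- c(pd, rd, if (pd + rd > 0) 2 * pd * rd / (pd + rd) else 0)
  }
  n <- length(docs)
  precision <- if (tp + fp > 0L) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0L) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  correct_ratio <- n_correct / n
  exact_ratio <- n_exact / n
  ci <- list(
    precision = if (tp + fp > 0L) wilson_interval(tp, tp + fp, confidence)
                else c(lo = 0, hi = 1),
    recall = if (tp + fn > 0L) wilson_interval(tp, tp + fn, confidence)
             else c(lo = 0, hi = 1),
    correct_ratio = wilson_interval(n_correct, n, confidence),
    exact_ratio = wilson_interval(n_exact, n, confidence)
  )
  rep <- list(
    tp = tp, fp = fp, fn = fn,
    precision = precision, recall = recall, f1 = f1,
    correct_ratio = correct_ratio, exact_ratio = exact_ratio,
    n_docs = n, confidence = confidence, wilson_ci = ci,
    averaging = averaging
  )
  if (averaging == "example") {
    rep$example_precision <- mean(per_doc[, "p"])
    rep$example_recall <- mean(per_doc[, "r"])
    rep$example_f1 <- mean(per_doc[, "f1"])
  }
  structure(rep, class = "orpha_eval")
}

#' @export
print.orpha_eval <- function(x, digits = 3, ...) {
  fmt <- function(v, m) {
    ci <- x$wilson_ci[[m]]
    if (is.null(ci)) sprintf("%.*f", digits, v)
    else sprintf("%.*f [%.*f, %.*f]", digits, v, digits, ci[["lo"]],
                 digits, ci[["hi"]])
  }
  cat("<orpha_eval>", x$n_docs, "documents | tp", x$tp, "fp", x$fp,
      "fn", x$fn, "\n")
  cat("  precision:    ", fmt(x$precision, "precision"), "\n")
  cat("  recall:       ", fmt(x$recall, "recall"), "\n")
  cat("  f1:           ", sprintf("%.*f", digits, x$f1), "\n")
  cat("  correct_ratio:", fmt(x$correct_ratio, "correct_ratio"), "\n")
  cat("  exact_ratio:  ", fmt(x$exact_ratio, "exact_ratio"), "\n")
  invisible(x)
}

#' Side-by-side comparison of two evaluation reports
#'
#' @param report_a,report_b `orpha_eval` objects computed on the same gold
#'   set (same `n_docs`).
#' @param names Labels for the two engines.
#' @return A data.frame with one row per metric: point estimates, Wilson CI
#'   bounds where defined, and the difference `b - a`. An attribute
#'   `dominance` is `"a"`/`"b"` when one report is at least as good on every
#'   metric (and better on some), `"none"` otherwise.
#' @export
compare_engines <- function(report_a, report_b,
                            names = c("engine_a", "engine_b")) {
  if (!inherits(report_a, "orpha_eval") || !inherits(report_b, "orpha_eval")) {
    stop("expected two `orpha_eval` objects", call. = FALSE)
  }
  if (report_a$n_docs != report_b$n_docs) {
    stop("reports were computed on different gold sets (n_docs ",
         report_a$n_docs, " vs ", report_b$n_docs, ")", call. = FALSE)
  }
  metrics <- c("precision", "recall", "f1", "correct_ratio", "exact_ratio")
  get_ci <- function(rep, m, which) {
    ci <- rep$wilson_ci[[m]]
    if (is.null(ci)) NA_real_ else unname(ci[[which]])
  }
  df <- data.frame(
    metric = metrics,
    a = vapply(metrics, function(m) report_a[[m]], numeric(1)),
    a_lo = vapply(metrics, get_ci, numeric(1), rep = report_a, which = "lo"),
    a_hi = vapply(metrics, get_ci, numeric(1), rep = report_a, which = "hi"),
    b = vapply(metrics, function(m) report_b[[m]], numeric(1)),
    b_lo = vapply(metrics, get_ci, numeric(1), rep = report_b, which = "lo"),
    b_hi = vapply(metrics, get_ci, numeric(1), rep = report_b, which = "hi"),
    stringsAsFactors = FALSE
  )
  df$delta <- df$b - df$a
  names(df)[c(2, 5)] <- make.names(names)
  rownames(df) <- NULL
  dominance <- if (all(df$delta >= 0) && any(df$delta > 0)) "b"
               else if (all(df$delta <= 0) && any(df$delta < 0)) "a"
               else "none"
  attr(df, "dominance") <- dominance
  df
}
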