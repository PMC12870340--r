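# Independent oracles used to cross-check the implementation. Each is a
# deliberately naive, separate route to the same quantity.

# Plain dynamic-programming Levenshtein distance (no library call).
lev_dp <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  na <- length(ca); nb <- length(cb)
  prev <- 0:nb
  for (i in seq_len(na)) {
    cur <- c(i, integer(nb))
    for (j in seq_len(nb)) {
      cur[j + 1] <- min(prev[j + 1] + 1, cur[j] + 1,
                        prev[j] + (ca[i] != cb[j]))
    }
    prev <- cur
  }
  prev[nb + 1]
}

# Brute-force exact scan: compare every dictionary surface against every
# token window of matching width, field by field; then apply
# longest-match-wins by pairwise containment checks.
oracle_exact_scan <- function(doc, dict) {
  toks <- doc$tokens
  hits <- list()
  for (r in seq_len(nrow(dict$entries))) {
    surf <- dict$entries$surface[r]
    n <- dict$entries$token_count[r]
    for (fld in unique(toks$field)) {
      ft <- toks[toks$field == fld, , drop = FALSE]
      if (n > nrow(ft)) next
      for (i in seq_len(nrow(ft) - n + 1L)) {
        win <- paste(ft$token[i:(i + n - 1L)], collapse = " ")
        if (win == surf) {
          hits[[length(hits) + 1L]] <- data.frame(
            code = dict$entries$code[r], start = ft$start[i],
            end = ft$end[i + n - 1L], matched_term = surf,
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(code = character(0), start = integer(0),
                      end = integer(0), matched_term = character(0)))
  }
  m <- unique(do.call(rbind, hits))
  keep <- rep(TRUE, nrow(m))
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(nrow(m))) {
      if (i == j) next
      if ((m$end[j] - m$start[j]) > (m$end[i] - m$start[i]) &&
          m$start[j] <= m$start[i] && m$end[j] >= m$end[i]) {
        keep[i] <- FALSE
      }
    }
  }
  m <- m[keep, , drop = FALSE]
  m <- m[order(m$start, m$end, m$code), , drop = FALSE]
  rownames(m) <- NULL
  m
}

# Brute-force fuzzy scan: every (window, term) pair at widths k-1..k+1,
# scored with the DP Levenshtein; windows identical to the term are dropped.
oracle_fuzzy_scan <- function(doc, dict, threshold = 0.8) {
  toks <- doc$tokens
  ent <- dict$entries[dict$entries$fuzzy_eligible, , drop = FALSE]
  hits <- list()
  for (r in seq_len(nrow(ent))) {
    term <- ent$surface[r]
    k <- ent$token_count[r]
    for (fld in unique(toks$field)) {
      ft <- toks[toks$field == fld, , drop = FALSE]
      for (w in unique(pmax(1L, (k - 1L):(k + 1L)))) {
        if (w > nrow(ft)) next
        for (i in seq_len(nrow(ft) - w + 1L)) {
          win <- paste(ft$token[i:(i + w - 1L)], collapse = " ")
          if (win == term) next
          d <- lev_dp(win, term)
          sc <- 1 - d / max(nchar(win), nchar(term))
          if (sc >= threshold) {
            hits[[length(hits) + 1L]] <- data.frame(
              code = ent$code[r], start = ft$start[i],
              end = ft$end[i + w - 1L], matched_term = term, score = sc,
              stringsAsFactors = FALSE
            )
          }
        }
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(code = character(0), start = integer(0),
                      end = integer(0), matched_term = character(0),
                      score = numeric(0)))
  }
  m <- unique(do.call(rbind, hits))
  m <- m[order(m$start, m$end, m$code, m$matched_term), , drop = FALSE]
  rownames(m) <- NULL
  m
}

# Vectorized brute-force scans for larger instances: same exhaustive
# (window x term) enumeration with no index and no prefilter, with the edit
# distance from base R's adist. Results are canonical sorted tuple frames.
all_windows <- function(doc, widths) {
  toks <- doc$tokens
  out <- list()
  for (fld in unique(toks$field)) {
    ft <- toks[toks$field == fld, , drop = FALSE]
    for (w in widths) {
      if (w > nrow(ft)) next
      m <- nrow(ft) - w + 1L
      s <- ft$token[seq_len(m)]
      if (w > 1L) for (j in 2:w) s <- paste(s, ft$token[seq_len(m) + j - 1L])
      out[[length(out) + 1L]] <- data.frame(
        win = s, width = w, start = ft$start[seq_len(m)],
        end = ft$end[seq_len(m) + w - 1L], stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(data.frame(win = character(0), width = integer(0),
                      start = integer(0), end = integer(0)))
  }
  do.call(rbind, out)
}

oracle_exact_fast <- function(doc, dict) {
  hits <- list()
  wins_all <- all_windows(doc, sort(unique(dict$entries$token_count)))
  for (r in seq_len(nrow(dict$entries))) {
    n <- dict$entries$token_count[r]
    wins <- wins_all[wins_all$width == n, , drop = FALSE]
    at <- which(wins$win == dict$entries$surface[r])
    if (length(at)) {
      hits[[length(hits) + 1L]] <- data.frame(
        code = dict$entries$code[r], start = wins$start[at],
        end = wins$end[at], matched_term = dict$entries$surface[r],
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(hits)) {
    return(data.frame(code = character(0), start = integer(0),
                      end = integer(0), matched_term = character(0)))
  }
  m <- unique(do.call(rbind, hits))
  keep <- vapply(seq_len(nrow(m)), function(i) {
    !any((m$end - m$start) > (m$end[i] - m$start[i]) &
           m$start <= m$start[i] & m$end >= m$end[i])
  }, logical(1))
  m <- m[keep, , drop = FALSE]
  m <- m[order(m$start, m$end, m$code), , drop = FALSE]
  rownames(m) <- NULL
  m
}

oracle_fuzzy_fast <- function(doc, dict, threshold = 0.8) {
  ent <- dict$entries[dict$entries$fuzzy_eligible, , drop = FALSE]
  hits <- list()
  if (nrow(ent)) {
    wins <- all_windows(doc, 1:max(ent$token_count + 1L))
    if (nrow(wins)) {
      dmat <- utils::adist(wins$win, ent$surface)
      for (r in seq_len(nrow(ent))) {
        k <- ent$token_count[r]
        ok_width <- wins$width >= max(1L, k - 1L) & wins$width <= k + 1L
        sc <- 1 - dmat[, r] / pmax(nchar(wins$win), ent$nchar[r])
        at <- which(ok_width & sc >= threshold & wins$win != ent$surface[r])
        if (length(at)) {
          hits[[length(hits) + 1L]] <- data.frame(
            code = ent$code[r], start = wins$start[at], end = wins$end[at],
            matched_term = ent$surface[r], score = sc[at],
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(code = character(0), start = integer(0),
                      end = integer(0), matched_term = character(0),
                      score = numeric(0)))
  }
  m <- unique(do.call(rbind, hits))
  m <- m[order(m$start, m$end, m$code, m$matched_term), , drop = FALSE]
  rownames(m) <- NULL
  m
}

# BFS ancestor oracle via igraph shortest paths on the child->parent graph.
oracle_ancestors <- function(tax, code, max_dist) {
  codes <- names(tax$concepts)
  edges <- do.call(rbind, lapply(tax$concepts, function(cp) {
    if (!length(cp$parents)) return(NULL)
    cbind(cp$code, cp$parents)
  }))
  g <- igraph::graph_from_data_frame(
    d = as.data.frame(edges %||% matrix(character(0), ncol = 2)),
    directed = TRUE, vertices = codes
  )
  d <- igraph::distances(g, v = code, mode = "out")[1, ]
  sort(names(d)[is.finite(d) & d >= 1 & d <= max_dist])
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# Wilson interval oracle: roots of (phat - p)^2 = z^2 p (1 - p) / n found by
# numeric root-finding rather than the closed form.
oracle_wilson <- function(k, n, confidence = 0.95) {
  z <- qnorm((1 + confidence) / 2)
  phat <- k / n
  g <- function(p) (phat - p)^2 - z^2 * p * (1 - p) / n
  # g vanishes at phat itself when phat is 0 or 1, so nudge that endpoint
  lo <- if (phat == 0) 0 else {
    uniroot(g, c(0, min(phat, 1 - 1e-12)), tol = 1e-12)$root
  }
  hi <- if (phat == 1) 1 else {
    uniroot(g, c(max(phat, 1e-12), 1), tol = 1e-12)$root
  }
  c(lo = lo, hi = hi)
}

# Random small taxonomy as a plain edge structure (DAG by construction:
# parents always have a smaller index).
random_taxonomy <- function(n, max_parents = 2, p_deprecated = 0.15,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  codes <- sprintf("C%03d", seq_len(n))
  concepts <- vector("list", n)
  for (i in seq_len(n)) {
    parents <- if (i == 1L) character(0) else {
      k <- sample(0:min(max_parents, i - 1L), 1L)
      if (k > 0L) codes[sample(seq_len(i - 1L), k)] else character(0)
    }
    deprecated <- i > 1L && runif(1) < p_deprecated
    concepts[[i]] <- list(
      code = codes[i],
      preferred_label = paste("disease", i),
      synonyms = character(0),
      status = if (deprecated) "deprecated" else "active",
      replaced_by = if (deprecated) codes[sample(seq_len(i - 1L), 1L)] else NULL,
      parents = if (deprecated) character(0) else parents
    )
  }
  taxonomy(concepts, version_tag = "random")
}
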