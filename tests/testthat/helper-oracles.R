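# Independent brute-force oracles used by the property tests. These stay
# deliberately separate from the package's own algorithms: the gazetteer
# oracle scans every token window, the pattern oracle enumerates every
# assignment of arcs to token positions, and the group-mean oracle is a
# naive two-pass loop.

# All contiguous token windows of length <= the longest entry, checked
# against every lexicon entry.
oracle_gazetteer <- function(document, lexicons) {
  out <- list()
  for (sid in document$sentences$sentence_id) {
    tok <- document$tokens[document$tokens$sentence_id == sid, , drop = FALSE]
    low <- tolower(tok$text)
    n <- nrow(tok)
    for (l in lexicons$lexicons) {
      for (start in seq_len(n)) {
        best_len <- 0L
        for (e in seq_along(l$entries)) {
          len <- length(l$entries[[e]])
          if (start + len - 1L > n) next
          if (!identical(low[start:(start + len - 1L)], l$entries[[e]])) next
          pc <- l$pos_constraint[e]
          if (!is.na(pc) && tok$pos[start + len - 1L] != pc) next
          best_len <- max(best_len, len)
        }
        if (best_len > 0L) {
          out[[length(out) + 1L]] <- data.frame(
            lexicon_name = l$name, sentence_id = sid,
            token_start = tok$index_in_sentence[start],
            token_end = tok$index_in_sentence[start + best_len - 1L],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(lexicon_name = character(0), sentence_id = integer(0),
                      token_start = integer(0), token_end = integer(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$sentence_id, res$token_start, res$lexicon_name), ,
      drop = FALSE]
}

# Arcs leaving the state entered by the gap at full-pattern index e:
# optional LEX/LITERAL chain plus the first required arc.
oracle_gap_blockers <- function(elements, e) {
  lex <- character(0)
  lit <- character(0)
  for (j in seq(e + 1L, length(elements))) {
    el <- elements[[j]]
    if (el$kind == "LEX") lex <- c(lex, el$name)
    if (el$kind == "LITERAL") lit <- c(lit, el$word)
    if (!isTRUE(el$optional)) break
  }
  list(lex = lex, lit = lit)
}

# Every match span (1-based local token start/end) of `pattern` in the
# sentence, by exhaustive enumeration: for each inclusion choice of the
# optional arcs, assign every consumer arc to every compatible position
# and keep the feasible assignments; per start token, the longest span.
oracle_match_spans <- function(pattern, tok, hits) {
  low <- tolower(tok$text)
  is_word <- tok$is_word
  n <- nrow(tok)
  els <- pattern$elements
  hit_list <- if (nrow(hits) > 0L) {
    data.frame(name = hits$lexicon_name, s = hits$token_start + 1L,
               e = hits$token_end + 1L, stringsAsFactors = FALSE)
  } else data.frame(name = character(0), s = integer(0), e = integer(0))

  begins_block <- function(pos, blockers) {
    any(hit_list$s == pos & hit_list$name %in% blockers$lex) ||
      low[pos] %in% blockers$lit
  }
  seg_feasible <- function(from, to, budget, blockers) {
    # tokens strictly between consumed spans: from..to (may be empty)
    if (from > to) return(TRUE)
    if (is.null(budget)) return(FALSE)  # adjacency required
    words <- 0L
    for (pos in from:to) {
      if (begins_block(pos, blockers)) return(FALSE)
      if (is_word[pos]) words <- words + 1L
    }
    words <= budget
  }

  opt_idx <- which(vapply(els, function(e) isTRUE(e$optional), logical(1)))
  n_sub <- 2L^length(opt_idx)
  spans <- list()
  for (mask in seq_len(n_sub) - 1L) {
    include <- rep(TRUE, length(els))
    if (length(opt_idx) > 0L) {
      include[opt_idx] <- as.logical(bitwAnd(mask, 2L^(seq_along(opt_idx) - 1L)))
    }
    # consumers in order, with the gap (budget + blockers) preceding each
    consumers <- list()
    pending_gap <- NULL
    for (j in seq_along(els)) {
      el <- els[[j]]
      if (el$kind == "GAP") {
        pending_gap <- list(budget = el$max_tokens,
                            blockers = oracle_gap_blockers(els, j))
        next
      }
      if (!include[j]) next
      consumers[[length(consumers) + 1L]] <-
        list(el = el, gap = pending_gap)
      pending_gap <- NULL
    }
    if (length(consumers) == 0L) next
    positions <- function(el) {
      if (el$kind == "LEX") {
        idx <- which(hit_list$name == el$name)
        lapply(idx, function(i) c(hit_list$s[i], hit_list$e[i]))
      } else {
        lapply(which(low == el$word), function(t) c(t, t))
      }
    }
    assignments <- list(list())
    ok <- TRUE
    for (ci in seq_along(consumers)) {
      cand <- positions(consumers[[ci]]$el)
      nxt <- list()
      for (a in assignments) {
        prev_end <- if (length(a) == 0L) NULL else a[[length(a)]][2]
        for (p in cand) {
          if (is.null(prev_end)) {
            nxt[[length(nxt) + 1L]] <- c(a, list(p))
          } else {
            gap <- consumers[[ci]]$gap
            feas <- if (is.null(gap)) {
              p[1] == prev_end + 1L
            } else {
              p[1] > prev_end &&
                seg_feasible(prev_end + 1L, p[1] - 1L,
                             gap$budget, gap$blockers)
            }
            if (feas) nxt[[length(nxt) + 1L]] <- c(a, list(p))
          }
        }
      }
      assignments <- nxt
      if (length(assignments) == 0L) { ok <- FALSE; break }
    }
    if (!ok) next
    for (a in assignments) {
      spans[[length(spans) + 1L]] <- c(a[[1]][1], a[[length(a)]][2])
    }
  }
  if (length(spans) == 0L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  df <- unique(do.call(rbind, spans))
  df <- data.frame(start = df[, 1], end = df[, 2])
  # per start token, longest extension wins
  agg <- stats::aggregate(end ~ start, df, max)
  agg[order(agg$start), , drop = FALSE]
}

# Random matching cases over a tiny vocabulary.
make_random_case <- function() {
  vocab <- c("alpha", "bravo", "carol", "delta", "ember", "frost",
             "gamma", "hollow")
  lex_names <- paste0("L", 1:4)
  lexicons <- lexicon_set(lapply(lex_names, function(nm) {
    k <- sample(1:3, 1)
    terms <- vapply(seq_len(k), function(i) {
      paste(sample(vocab, sample(1:2, 1)), collapse = " ")
    }, character(1))
    lexicon(nm, "all", unique(terms))
  }))
  n_tok <- sample(4:12, 1)
  words <- sample(c(vocab, ","), n_tok, replace = TRUE,
                  prob = c(rep(1, length(vocab)), 0.8))
  sent <- paste(words, collapse = " ")
  doc <- preprocess(sent, "case")

  n_arcs <- sample(1:4, 1)
  els <- list()
  for (i in seq_len(n_arcs)) {
    if (i > 1L && stats::runif(1) < 0.7) {
      els[[length(els) + 1L]] <- pattern_element("GAP",
                                                 max_tokens = sample(0:5, 1))
    }
    optional <- i == n_arcs && n_arcs > 1L && stats::runif(1) < 0.4
    if (stats::runif(1) < 0.2) {
      els[[length(els) + 1L]] <- pattern_element(
        "LITERAL", word = sample(vocab, 1), optional = optional)
    } else {
      els[[length(els) + 1L]] <- pattern_element(
        "LEX", name = sample(lex_names, 1), optional = optional)
    }
  }
  pat <- tryCatch(pattern("A1a.1", els), error = function(e) NULL)
  list(doc = doc, lexicons = lexicons, pattern = pat)
}

# Naive two-pass group means for the aggregation oracle.
oracle_group_means <- function(profiles) {
  status <- ifelse(profiles$case_status %in% c("ASD", "non-ASD"),
                   profiles$case_status, "unknown")
  out <- list()
  for (y in unique(profiles$year)) {
    for (st in unique(status)) {
      idx <- profiles$year == y & status == st
      if (!any(idx)) next
      for (cid in criterion_ids()) {
        vals <- profiles[[paste0("norm_", cid)]][idx]
        s <- 0
        for (v in vals) s <- s + v
        out[[length(out) + 1L]] <- data.frame(
          year = y, case_status = st, criterion = cid,
          mean_normalized_count = s / length(vals), n = length(vals),
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  res[order(res$year, res$case_status, res$criterion), , drop = FALSE]
}

# Tiny fixture ruleset used by several module tests.
toy_ruleset <- function() {
  lex <- lexicon_set(list(
    lexicon("Freq", "all", c("often", "frequently")),
    lexicon("Odd", "all", c("reduced", "loud", "breathy")),
    lexicon("Speech", "all", c("volume", "voice"))
  ))
  pats <- list(
    pattern("A2c.1", list(
      pattern_element("LEX", name = "Freq"),
      pattern_element("GAP", max_tokens = 5),
      pattern_element("LEX", name = "Odd"),
      pattern_element("LEX", name = "Speech", optional = TRUE)
    ))
  )
  ruleset(lex, pats)
}
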