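# Finite-state annotation patterns over lexicon hits.
#
# A pattern is an ordered sequence of arcs: LEX(name) consumes the tokens
# of a gazetteer hit of that lexicon, LEX?(name) is an optional lexicon
# arc, LITERAL("word") consumes one matching word token, and GAP(k)
# consumes up to k intervening word tokens that do not themselves begin a
# hit satisfying an arc leaving the gap state (punctuation tokens inside a
# gap are free). A match is emitted when all required arcs have been
# satisfied; it spans from the first to the last consumed token and never
# crosses a sentence boundary.

#' Construct a pattern element
#'
#' @param kind One of `"LEX"`, `"GAP"`, `"LITERAL"`.
#' @param name Lexicon name (for `LEX`).
#' @param max_tokens Gap budget in word tokens (for `GAP`).
#' @param word Literal word, matched case-insensitively (for `LITERAL`).
#' @param optional Whether a `LEX`/`LITERAL` arc may be skipped.
#' @return A `dsm_pattern_element`.
#' @export
pattern_element <- function(kind, name = NULL, max_tokens = NULL,
                            word = NULL, optional = FALSE) {
  kind <- match.arg(kind, c("LEX", "GAP", "LITERAL"))
  if (kind == "LEX" && (is.null(name) || !nzchar(name))) {
    stop("LEX element needs a lexicon name")
  }
  if (kind == "GAP") {
    if (is.null(max_tokens) || max_tokens < 0) {
      stop("GAP element needs max_tokens >= 0")
    }
    if (optional) stop("GAP elements cannot be marked optional")
  }
  if (kind == "LITERAL" && (is.null(word) || !nzchar(word))) {
    stop("LITERAL element needs a word")
  }
  structure(list(kind = kind, name = name,
                 max_tokens = if (!is.null(max_tokens))
                   as.integer(max_tokens) else NULL,
                 word = if (!is.null(word)) tolower(word) else NULL,
                 optional = isTRUE(optional)),
            class = "dsm_pattern_element")
}

#' Construct a pattern
#'
#' @param pattern_id Identifier of the form `<criterion>.<n>`, e.g.
#'   `"A2c.1"`; the criterion label is taken from the prefix unless
#'   `criterion` is given.
#' @param elements List of [pattern_element()] objects. The first element
#'   may not be a gap, gaps may not be adjacent or final, and at least one
#'   required `LEX` arc is needed.
#' @param criterion Criterion label (`A1a`..`A3d`).
#' @return A `dsm_pattern`. Its `accept_early` field is `TRUE` when the
#'   pattern ends in one or more optional arcs, i.e. the state before them
#'   is already accepting.
#' @export
pattern <- function(pattern_id, elements,
                    criterion = sub("\\..*$", "", pattern_id)) {
  stopifnot(is.character(pattern_id), length(pattern_id) == 1L)
  if (!criterion %in% .criterion_ids) {
    stop("pattern '", pattern_id, "': unknown criterion '", criterion, "'")
  }
  ok <- vapply(elements, inherits, logical(1), "dsm_pattern_element")
  if (length(elements) == 0L || !all(ok)) {
    stop("pattern '", pattern_id, "': elements must be pattern_element objects")
  }
  kinds <- vapply(elements, `[[`, character(1), "kind")
  opt <- vapply(elements, function(e) isTRUE(e$optional), logical(1))
  if (kinds[1] == "GAP") {
    stop("pattern '", pattern_id, "': first element may not be a GAP")
  }
  if (kinds[length(kinds)] == "GAP") {
    stop("pattern '", pattern_id, "': last element may not be a GAP")
  }
  if (any(kinds[-1] == "GAP" & kinds[-length(kinds)] == "GAP")) {
    stop("pattern '", pattern_id, "': adjacent GAP elements")
  }
  if (!any(kinds == "LEX" & !opt)) {
    stop("pattern '", pattern_id, "': needs at least one required LEX arc")
  }
  structure(list(pattern_id = pattern_id, criterion = criterion,
                 elements = elements,
                 accept_early = opt[length(opt)]),
            class = "dsm_pattern")
}

#' @export
print.dsm_pattern <- function(x, ...) {
  cat(format_pattern(x), "\n")
  invisible(x)
}

#' Render a pattern in the pattern DSL
#' @param x A `dsm_pattern`.
#' @return Character scalar, e.g.
#'   `"A2c.1: LEX(A2c_frequent) GAP(5) LEX(A2c_idiosyncratic) LEX?(A2c_speech)"`.
#' @export
format_pattern <- function(x) {
  els <- vapply(x$elements, function(e) {
    switch(e$kind,
           LEX = sprintf("LEX%s(%s)", if (e$optional) "?" else "", e$name),
           GAP = sprintf("GAP(%d)", e$max_tokens),
           LITERAL = sprintf("LITERAL%s(\"%s\")",
                             if (e$optional) "?" else "", e$word))
  }, character(1))
  paste0(x$pattern_id, ": ", paste(els, collapse = " "))
}

## ---- pattern DSL parsing ------------------------------------------------

.parse_pattern_line <- function(line, lineno = NA) {
  where <- if (is.na(lineno)) "" else paste0(" at line ", lineno)
  m <- regmatches(line, regexec("^\\s*([A-Za-z0-9]+\\.[A-Za-z0-9]+)\\s*:\\s*(.+)$",
                                line))[[1]]
  if (length(m) == 0L) stop("cannot parse pattern definition", where)
  pid <- m[2]
  body <- m[3]
  el_re <- paste0("(LEX\\??\\(\\s*[A-Za-z0-9_]+\\s*\\)",
                  "|GAP\\(\\s*[0-9]+\\s*\\)",
                  "|LITERAL\\??\\(\\s*\"[^\"]+\"\\s*\\))")
  toks <- regmatches(body, gregexpr(el_re, body))[[1]]
  residue <- gsub(el_re, "", body)
  if (length(toks) == 0L || grepl("[^[:space:]]", residue)) {
    stop("syntax error in pattern '", pid, "'", where)
  }
  elements <- lapply(toks, function(tk) {
    if (startsWith(tk, "LEX")) {
      pattern_element("LEX",
                      name = trimws(sub("^LEX\\??\\(([^)]*)\\)$", "\\1", tk)),
                      optional = startsWith(tk, "LEX?"))
    } else if (startsWith(tk, "GAP")) {
      pattern_element("GAP",
                      max_tokens = as.integer(trimws(sub("^GAP\\(([^)]*)\\)$",
                                                         "\\1", tk))))
    } else {
      pattern_element("LITERAL",
                      word = sub("^LITERAL\\??\\(\\s*\"([^\"]*)\"\\s*\\)$",
                                 "\\1", tk),
                      optional = startsWith(tk, "LITERAL?"))
    }
  })
  pattern(pid, elements)
}

#' Parse a pattern DSL file
#'
#' One pattern per line: `<criterion>.<n>: ELEMENT ELEMENT ...` with
#' elements `LEX(name)`, `LEX?(name)`, `GAP(k)` and `LITERAL("word")`;
#' `#` comment lines and blank lines are ignored. Every referenced lexicon
#' name must resolve against `lexicons`.
#'
#' @param path Path to the pattern file.
#' @param lexicons A `dsm_lexicon_set` the patterns are compiled against.
#' @return List of `dsm_pattern` objects.
#' @export
parse_pattern_file <- function(path, lexicons) {
  stopifnot(inherits(lexicons, "dsm_lexicon_set"))
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  rows <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
  if (length(rows) == 0L) stop("no pattern definitions found in ", path)
  pats <- lapply(rows, function(i) .parse_pattern_line(lines[i], i))
  known <- names(lexicons$lexicons)
  for (p in pats) {
    for (e in p$elements) {
      if (e$kind == "LEX" && !e$name %in% known) {
        stop("pattern '", p$pattern_id,
             "' references unknown lexicon '", e$name, "'")
      }
    }
  }
  ids <- vapply(pats, `[[`, character(1), "pattern_id")
  if (anyDuplicated(ids)) {
    stop("duplicate pattern ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  pats
}

## ---- ruleset ------------------------------------------------------------

#' Bundle lexicons and patterns into a ruleset
#'
#' Validates that every `LEX` reference resolves, that each referenced
#' lexicon's scope covers the pattern's criterion, and that every criterion
#' with patterns has at least one lexicon in scope.
#'
#' @param lexicon_set A `dsm_lexicon_set`.
#' @param patterns List of `dsm_pattern` objects.
#' @return A `dsm_ruleset`.
#' @export
ruleset <- function(lexicon_set, patterns) {
  stopifnot(inherits(lexicon_set, "dsm_lexicon_set"),
            is.list(patterns), length(patterns) > 0L)
  ok <- vapply(patterns, inherits, logical(1), "dsm_pattern")
  if (!all(ok)) stop("patterns must be dsm_pattern objects")
  scopes <- vapply(lexicon_set$lexicons, `[[`, character(1), "scope")
  for (p in patterns) {
    for (e in p$elements) {
      if (e$kind != "LEX") next
      if (!e$name %in% names(lexicon_set$lexicons)) {
        stop("pattern '", p$pattern_id,
             "' references unknown lexicon '", e$name, "'")
      }
      if (!.scope_covers(scopes[[e$name]], p$criterion)) {
        stop("pattern '", p$pattern_id, "' uses lexicon '", e$name,
             "' whose scope '", scopes[[e$name]],
             "' does not cover criterion ", p$criterion)
      }
    }
  }
  ids <- vapply(patterns, `[[`, character(1), "pattern_id")
  if (anyDuplicated(ids)) stop("duplicate pattern ids")
  names(patterns) <- ids
  structure(list(lexicon_set = lexicon_set, patterns = patterns),
            class = "dsm_ruleset")
}

#' @export
print.dsm_ruleset <- function(x, ...) {
  cat(sprintf("<dsm_ruleset: %d lexicons (%d terms), %d patterns, %d criteria>\n",
              length(x$lexicon_set$lexicons), n_terms(x$lexicon_set),
              length(x$patterns),
              length(unique(vapply(x$patterns, `[[`, character(1),
                                   "criterion")))))
  invisible(x)
}

## ---- matching -----------------------------------------------------------

# Lexicon names / literal words on the arcs leaving the state entered by
# the gap at element index `e`: the chain of optional arcs after it plus
# the first required arc. A gap filler token may not begin a hit (or equal
# a literal) satisfying any of these.
.gap_out_arcs <- function(elements, e) {
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

#' Match one pattern against one sentence
#'
#' Scans left to right over the sentence's tokens. For every start token,
#' the longest feasible match is kept (leftmost start, longest extension);
#' matches at different start positions may overlap. Gap arcs consume up to
#' their budget of word tokens, skip punctuation freely, and may not
#' consume a token that begins a hit satisfying an arc leaving the gap
#' state. Matches never cross the sentence boundary.
#'
#' @param pattern A `dsm_pattern`.
#' @param document A `dsm_document`.
#' @param sentence_id Sentence to match within.
#' @param hits Gazetteer hits for the document (or at least this sentence),
#'   as returned by [gazetteer_annotate()].
#' @return Data frame of annotations: `record_id`, `sentence_id`,
#'   `criterion`, `char_start`, `char_end`, `pattern_id`, `matched_text`.
#' @export
match_sentence <- function(pattern, document, sentence_id, hits) {
  stopifnot(inherits(pattern, "dsm_pattern"),
            inherits(document, "dsm_document"))
  tok <- document$tokens[document$tokens$sentence_id == sentence_id, ,
                         drop = FALSE]
  if (nrow(tok) == 0L) return(.empty_annotations())
  sh <- hits[hits$sentence_id == sentence_id, , drop = FALSE]
  spans <- .match_token_spans(pattern, tolower(tok$text), tok$is_word,
                              .sentence_hit_index(sh))
  .spans_to_annotations(pattern, document, sentence_id, tok, spans)
}

# Hit end position (1-based local) by lexicon and 0-based start index.
.sentence_hit_index <- function(sh) {
  hit_end <- new.env(parent = emptyenv(), hash = TRUE)
  for (r in seq_len(nrow(sh))) {
    hit_end[[paste0(sh$lexicon_name[r], "\r", sh$token_start[r] + 1L)]] <-
      sh$token_end[r] + 1L
  }
  hit_end
}

# Core matcher over prepared sentence vectors; returns a list of
# c(start, end) 1-based local token spans, one per start token (longest).
.match_token_spans <- function(pattern, low, is_word, hit_end) {
  n <- length(low)
  lookup <- function(name, t) hit_end[[paste0(name, "\r", t)]]

  elements <- pattern$elements
  n_el <- length(elements)

  blocks <- function(arcs, pos) {
    if (pos > n) return(FALSE)
    for (nm in arcs$lex) if (!is.null(lookup(nm, pos))) return(TRUE)
    low[pos] %in% arcs$lit
  }

  # Best (max) last-consumed token over completions of elements e.. with
  # the next consumption beginning exactly at token t; -1 when infeasible.
  rec <- function(e, t, last) {
    if (e > n_el) return(last)
    el <- elements[[e]]
    best <- -1L
    if (el$kind == "LEX") {
      if (t <= n) {
        h <- lookup(el$name, t)
        if (!is.null(h)) best <- max(best, rec(e + 1L, h + 1L, h))
      }
      if (el$optional) best <- max(best, rec(e + 1L, t, last))
    } else if (el$kind == "LITERAL") {
      if (t <= n && low[t] == el$word) {
        best <- max(best, rec(e + 1L, t + 1L, t))
      }
      if (el$optional) best <- max(best, rec(e + 1L, t, last))
    } else {  # GAP
      arcs <- .gap_out_arcs(elements, e)
      g <- 0L
      pos <- t
      repeat {
        best <- max(best, rec(e + 1L, pos, last))
        if (last < 0L) break         # nothing consumed yet: gap is inert
        if (pos > n) break
        if (blocks(arcs, pos)) break
        if (!is_word[pos]) { pos <- pos + 1L; next }
        if (g >= el$max_tokens) break
        g <- g + 1L
        pos <- pos + 1L
      }
    }
    best
  }

  spans <- list()
  for (s in seq_len(n)) {
    end <- rec(1L, s, -1L)
    if (end >= s) spans[[length(spans) + 1L]] <- c(s, end)
  }
  spans
}

.spans_to_annotations <- function(pattern, document, sentence_id, tok,
                                  spans) {
  if (length(spans) == 0L) return(.empty_annotations())
  s <- vapply(spans, `[`, integer(1), 1L)
  e <- vapply(spans, `[`, integer(1), 2L)
  data.frame(
    record_id = document$record_id,
    sentence_id = sentence_id,
    criterion = pattern$criterion,
    char_start = tok$char_start[s],
    char_end = tok$char_end[e],
    pattern_id = pattern$pattern_id,
    matched_text = substring(document$text, tok$char_start[s] + 1L,
                             tok$char_end[e]),
    stringsAsFactors = FALSE
  )
}

.empty_annotations <- function() {
  data.frame(record_id = character(0), sentence_id = integer(0),
             criterion = character(0), char_start = integer(0),
             char_end = integer(0), pattern_id = character(0),
             matched_text = character(0), stringsAsFactors = FALSE)
}

#' Annotate a document with every pattern of a ruleset
#'
#' Runs gazetteer lookup, matches every pattern against every sentence,
#' deduplicates annotations per (criterion, span) keeping the
#' lexicographically smallest pattern id, and sorts by sentence and start
#' offset. The result is a pure function of (ruleset, document).
#'
#' @param ruleset A `dsm_ruleset`.
#' @param document A `dsm_document`.
#' @param hits Optional precomputed gazetteer hits.
#' @param index Precompiled gazetteer index (internal use).
#' @return Data frame of criterion annotations (see [match_sentence()]).
#' @examples
#' rs <- load_default_ruleset()
#' doc <- preprocess("He often speaks with reduced volume.", "r1")
#' annotate_document(rs, doc)
#' @export
annotate_document <- function(ruleset, document, hits = NULL, index = NULL) {
  stopifnot(inherits(ruleset, "dsm_ruleset"),
            inherits(document, "dsm_document"))
  if (is.null(hits)) {
    hits <- gazetteer_annotate(document, ruleset$lexicon_set, index = index)
  }
  required_lex <- lapply(ruleset$patterns, function(p) {
    unlist(lapply(p$elements, function(e) {
      if (e$kind == "LEX" && !e$optional) e$name else NULL
    }))
  })
  tok_by_sid <- split(seq_len(nrow(document$tokens)),
                      document$tokens$sentence_id)
  hit_by_sid <- split(seq_len(nrow(hits)), hits$sentence_id)
  out <- list()
  for (sid in names(hit_by_sid)) {
    sh <- hits[hit_by_sid[[sid]], , drop = FALSE]
    tok <- document$tokens[tok_by_sid[[sid]], , drop = FALSE]
    low <- tolower(tok$text)
    hit_env <- .sentence_hit_index(sh)
    present <- unique(sh$lexicon_name)
    for (pi in seq_along(ruleset$patterns)) {
      if (!all(required_lex[[pi]] %in% present)) next
      p <- ruleset$patterns[[pi]]
      spans <- .match_token_spans(p, low, tok$is_word, hit_env)
      if (length(spans) > 0L) {
        out[[length(out) + 1L]] <- .spans_to_annotations(
          p, document, as.integer(sid), tok, spans)
      }
    }
  }
  if (length(out) == 0L) return(.empty_annotations())
  ann <- do.call(rbind, out)
  ann <- ann[order(ann$sentence_id, ann$char_start, ann$char_end,
                   ann$criterion, ann$pattern_id), , drop = FALSE]
  dup <- duplicated(ann[, c("criterion", "char_start", "char_end")])
  ann <- ann[!dup, , drop = FALSE]
  rownames(ann) <- NULL
  ann
}

#' Annotate every document of a corpus
#'
#' @param ruleset A `dsm_ruleset`.
#' @param documents A list of `dsm_document` objects.
#' @return One data frame of annotations over all records.
#' @export
annotate_corpus <- function(ruleset, documents) {
  index <- .compile_gazetteer(ruleset$lexicon_set)
  res <- lapply(documents,
                function(d) annotate_document(ruleset, d, index = index))
  out <- do.call(rbind, res)
  if (is.null(out)) .empty_annotations() else out
}

## ---- standoff annotation i/o -------------------------------------------

#' Write annotations as standoff TSV
#'
#' Columns: `record_id`, `char_start`, `char_end`, `criterion`,
#' `pattern_id`, `matched_text`. The file is also readable as gold-standard
#' input by [read_gold()].
#'
#' @param annotations Annotation data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_annotations <- function(annotations, path) {
  cols <- c("record_id", "char_start", "char_end", "criterion")
  stopifnot(all(cols %in% names(annotations)))
  df <- annotations[, c(cols,
                        intersect(c("pattern_id", "matched_text"),
                                  names(annotations))), drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read annotations from standoff TSV
#'
#' @param path Path to a TSV written by [write_annotations()].
#' @return Annotation data frame.
#' @export
read_annotations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  cols <- c("record_id", "char_start", "char_end", "criterion")
  if (!all(cols %in% names(df))) {
    stop("annotation file must have columns ", paste(cols, collapse = ", "))
  }
  bad <- which(!df$criterion %in% .criterion_ids)
  if (length(bad) > 0L) {
    stop("invalid criterion '", df$criterion[bad[1]], "' at data row ",
         bad[1], " of ", path)
  }
  df
}
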