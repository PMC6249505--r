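# Scoped trigger-word lexicons and gazetteer lookup.
#
# A lexicon is a named list of surface-form entries (1..k tokens each) with
# a scope: shared by all criteria ("all"), by one criterion group
# ("group:A1" / "group:A2" / "group:A3"), or specific to one criterion
# ("criterion:A1a"). The same surface term may appear in multiple lexicons.

.valid_scopes <- c("all", paste0("group:", c("A1", "A2", "A3")),
                   paste0("criterion:", .criterion_ids))

# Does a lexicon scope cover a given criterion id?
.scope_covers <- function(scope, criterion) {
  scope == "all" |
    scope == paste0("group:", substr(criterion, 1, 2)) |
    scope == paste0("criterion:", criterion)
}

.tokenize_term <- function(term) {
  m <- gregexpr(.token_regex, term, perl = TRUE)[[1]]
  if (m[1] == -1L) character(0) else tolower(regmatches(term, list(m))[[1]])
}

#' Construct a lexicon
#'
#' @param name Lexicon label, e.g. `"A2c_idiosyncratic"`. Must be unique
#'   within a [lexicon_set()].
#' @param scope One of `"all"`, `"group:A1"`, `"group:A2"`, `"group:A3"`,
#'   or `"criterion:<id>"` with `<id>` one of the twelve criterion ids.
#' @param terms Character vector of surface terms; multi-word terms match
#'   contiguous tokens within one sentence. Stored case-folded.
#' @param pos_constraint Optional coarse POS class (`"NOUN"`, `"VERB"`,
#'   `"ADJ"`, `"ADV"`) required of each entry's head (last) token; a scalar
#'   (applied to all terms) or a vector parallel to `terms` with `NA` for
#'   unconstrained entries.
#' @return A `dsm_lexicon` object.
#' @examples
#' lexicon("A1a_nonVerbalBehavior", "criterion:A1a",
#'         c("eye contact", "eye-to-eye gaze", "gestures"))
#' @export
lexicon <- function(name, scope, terms, pos_constraint = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!scope %in% .valid_scopes) {
    stop("unknown scope '", scope, "' for lexicon '", name, "'")
  }
  terms <- as.character(terms)
  if (length(terms) == 0L) stop("lexicon '", name, "' has no terms")
  if (is.null(pos_constraint)) {
    pos_constraint <- rep(NA_character_, length(terms))
  } else if (length(pos_constraint) == 1L) {
    pos_constraint <- rep(as.character(pos_constraint), length(terms))
  }
  stopifnot(length(pos_constraint) == length(terms))
  bad <- !is.na(pos_constraint) &
    !pos_constraint %in% c("NOUN", "VERB", "ADJ", "ADV")
  if (any(bad)) stop("invalid pos_constraint for lexicon '", name, "'")
  terms_cf <- tolower(terms)
  dup <- duplicated(terms_cf)
  entries <- lapply(terms_cf[!dup], .tokenize_term)
  if (any(lengths(entries) == 0L)) {
    stop("lexicon '", name, "' contains an empty term")
  }
  structure(
    list(name = name, scope = scope, terms = terms_cf[!dup],
         entries = entries, pos_constraint = pos_constraint[!dup]),
    class = "dsm_lexicon"
  )
}

#' Construct a lexicon set
#'
#' @param lexicons A list of [lexicon()] objects with unique names.
#' @return A `dsm_lexicon_set` object; lexicons are retrievable by name
#'   with `set$lexicons[[name]]`.
#' @export
lexicon_set <- function(lexicons) {
  stopifnot(is.list(lexicons), length(lexicons) > 0L)
  ok <- vapply(lexicons, inherits, logical(1), "dsm_lexicon")
  if (!all(ok)) stop("all elements must be lexicon objects")
  nms <- vapply(lexicons, `[[`, character(1), "name")
  if (anyDuplicated(nms)) {
    stop("duplicate lexicon names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  names(lexicons) <- nms
  structure(list(lexicons = lexicons), class = "dsm_lexicon_set")
}

#' @export
print.dsm_lexicon_set <- function(x, ...) {
  cat(sprintf("<dsm_lexicon_set: %d lexicons, %d terms>\n",
              length(x$lexicons), n_terms(x)))
  invisible(x)
}

#' Number of terms in a lexicon set
#' @param set A `dsm_lexicon_set`.
#' @return Integer: total entry count over all lexicons.
#' @export
n_terms <- function(set) {
  stopifnot(inherits(set, "dsm_lexicon_set"))
  sum(vapply(set$lexicons, function(l) length(l$terms), integer(1)))
}

#' Load lexicons from a tab-separated file
#'
#' Format: one term per row with columns `lexicon_name`, `scope`, `term`
#' and optionally `pos_constraint`; lines starting with `#` and blank lines
#' are ignored; UTF-8. Rows sharing a `lexicon_name` are merged into one
#' lexicon (its scope must be consistent); duplicate (name, term) pairs are
#' deduplicated. The same term may appear in multiple lexicons.
#'
#' @param path Path to the lexicon TSV.
#' @return A `dsm_lexicon_set`.
#' @export
load_lexicons <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- nzchar(trimws(lines)) & !grepl("^\\s*#", lines)
  rows <- which(keep)
  if (length(rows) == 0L) stop("no lexicon rows found in ", path)
  name <- scope <- term <- pos <- character(length(rows))
  for (j in seq_along(rows)) {
    i <- rows[j]
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L || any(!nzchar(trimws(f[1:3])))) {
      stop("malformed lexicon row at line ", i, " of ", path)
    }
    if (!trimws(f[2]) %in% .valid_scopes) {
      stop("unknown scope '", trimws(f[2]), "' at line ", i, " of ", path)
    }
    name[j] <- trimws(f[1]); scope[j] <- trimws(f[2]); term[j] <- trimws(f[3])
    pos[j] <- if (length(f) >= 4L && nzchar(trimws(f[4])))
      trimws(f[4]) else NA_character_
  }
  lex <- lapply(unique(name), function(nm) {
    idx <- name == nm
    sc <- unique(scope[idx])
    if (length(sc) > 1L) {
      stop("lexicon '", nm, "' declared with conflicting scopes in ", path)
    }
    lexicon(nm, sc, term[idx], pos[idx])
  })
  lexicon_set(lex)
}

#' Write a lexicon set to the lexicon TSV format
#' @param set A `dsm_lexicon_set`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_lexicons <- function(set, path) {
  stopifnot(inherits(set, "dsm_lexicon_set"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("# lexicon_name\tscope\tterm\tpos_constraint", con)
  for (l in set$lexicons) {
    pc <- ifelse(is.na(l$pos_constraint), "", l$pos_constraint)
    writeLines(paste(l$name, l$scope, l$terms, pc, sep = "\t"), con)
  }
  invisible(path)
}

## ---- gazetteer lookup ---------------------------------------------------

# Index entries by first token for fast candidate lookup.
.compile_gazetteer <- function(set) {
  idx <- new.env(parent = emptyenv(), hash = TRUE)
  for (l in set$lexicons) {
    for (e in seq_along(l$entries)) {
      toks <- l$entries[[e]]
      key <- toks[1]
      cand <- list(lexicon = l$name, tokens = toks,
                   pos = l$pos_constraint[e])
      idx[[key]] <- c(idx[[key]], list(cand))
    }
  }
  idx
}

#' Annotate lexicon hits over a tokenized document
#'
#' Performs case-insensitive gazetteer lookup of every lexicon entry over
#' the document's token sequences. Matches are maximal per (lexicon, start
#' position): when entries of different lengths from the same lexicon match
#' at the same start token, only the longest is kept. Hits from different
#' lexicons may coexist on the same span, and hits never cross sentence
#' boundaries. Entries with a POS constraint only match when the head
#' (last) token of the span carries the required coarse class, so e.g. an
#' entry "object" constrained to `NOUN` does not fire on "I object".
#'
#' @param document A `dsm_document` from [preprocess()].
#' @param lexicons A `dsm_lexicon_set`.
#' @return Data frame of hits: `lexicon_name`, `sentence_id`,
#'   `token_start`, `token_end` (0-based `index_in_sentence`, inclusive),
#'   `char_start`, `char_end`, `text`. Zero rows when nothing matches.
#' @param index Precompiled gazetteer index for `lexicons` (internal use:
#'   lets corpus-scale callers compile once).
#' @export
gazetteer_annotate <- function(document, lexicons, index = NULL) {
  stopifnot(inherits(document, "dsm_document"),
            inherits(lexicons, "dsm_lexicon_set"))
  idx <- if (is.null(index)) .compile_gazetteer(lexicons) else index
  out <- list()
  k <- 0L
  for (sid in document$sentences$sentence_id) {
    tok <- document$tokens[document$tokens$sentence_id == sid, , drop = FALSE]
    low <- tolower(tok$text)
    n <- length(low)
    for (i in seq_len(n)) {
      cands <- idx[[low[i]]]
      if (is.null(cands)) next
      best <- list()  # per-lexicon longest match at this start
      for (cand in cands) {
        len <- length(cand$tokens)
        if (i + len - 1L > n) next
        if (!all(low[i:(i + len - 1L)] == cand$tokens)) next
        if (!is.na(cand$pos) && tok$pos[i + len - 1L] != cand$pos) next
        prev <- best[[cand$lexicon]]
        if (is.null(prev) || len > prev) {
          best[[cand$lexicon]] <- len
        }
      }
      for (nm in names(best)) {
        len <- best[[nm]]
        k <- k + 1L
        out[[k]] <- data.frame(
          lexicon_name = nm,
          sentence_id = sid,
          token_start = tok$index_in_sentence[i],
          token_end = tok$index_in_sentence[i + len - 1L],
          char_start = tok$char_start[i],
          char_end = tok$char_end[i + len - 1L],
          text = substring(document$text, tok$char_start[i] + 1L,
                           tok$char_end[i + len - 1L]),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (k == 0L) {
    return(data.frame(lexicon_name = character(0), sentence_id = integer(0),
                      token_start = integer(0), token_end = integer(0),
                      char_start = integer(0), char_end = integer(0),
                      text = character(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$sentence_id, res$char_start, res$lexicon_name), ,
      drop = FALSE]
}
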