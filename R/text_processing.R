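# Tokenization, sentence splitting, coarse POS tagging and lemmatization.
#
# All character offsets in this package are 0-based, half-open offsets into
# the original, unmodified record text (standard standoff-annotation
# practice). Token indices within a sentence start at 0.

## ---- coarse POS dictionaries -------------------------------------------

.pos_determiners <- c("the", "a", "an", "this", "that", "these", "those",
                      "his", "her", "their", "its", "my", "your", "our",
                      "no", "any", "some", "each", "every", "another", "both")
.pos_pronouns <- c("i", "he", "she", "it", "we", "they", "you", "who")
.pos_modals <- c("will", "would", "can", "could", "shall", "should", "may",
                 "might", "must", "do", "does", "did")
.pos_function <- c(.pos_determiners, .pos_pronouns, .pos_modals,
                   "with", "in", "on", "at", "by", "for", "of", "to", "from",
                   "and", "or", "but", "as", "than", "into", "onto", "over",
                   "under", "about", "during", "while", "when", "if",
                   "because", "so", "not", "nor", "is", "are", "was", "were",
                   "be", "been", "being", "has", "have", "had", "am",
                   "there", "here", "him", "them", "us", "me", "himself",
                   "herself", "themselves")
.pos_adverbs <- c("often", "frequently", "rarely", "seldom", "never",
                  "always", "sometimes", "usually", "occasionally", "very",
                  "quite", "too", "also", "well", "again", "typically",
                  "consistently", "still", "yet", "once")
.pos_adjectives <- c("good", "poor", "minimal", "limited", "severe",
                     "significant", "pervasive", "marked", "consistent",
                     "appropriate", "satisfactory", "abnormal", "reduced",
                     "loud", "breathy", "nonfunctional", "idiosyncratic",
                     "same", "different", "new", "social", "verbal",
                     "nonverbal", "repetitive", "stereotyped", "spontaneous",
                     "inflexible", "persistent", "restricted", "odd",
                     "unusual", "atypical", "flat", "monotone")

.pos_verb_bases <- c("speak", "talk", "make", "exhibit", "show", "display",
                     "engage", "respond", "react", "struggle", "handle",
                     "walk", "run", "play", "use", "gain", "obtain", "say",
                     "go", "see", "look", "avoid", "seek", "share",
                     "initiate", "sustain", "develop", "demonstrate",
                     "present", "appear", "seem", "line", "stack", "arrange",
                     "flap", "rock", "spin", "tap", "clap", "grind", "twirl",
                     "point", "gesture", "communicate", "interact",
                     "recognize", "attend", "regard", "note", "observe",
                     "report", "describe", "prefer", "insist", "repeat",
                     "echo", "perseverate", "object", "require", "need",
                     "want", "like", "enjoy", "follow", "understand")

.inflect_verb <- function(base) {
  es <- grepl("(s|x|z|ch|sh|o)$", base)
  third <- ifelse(es, paste0(base, "es"), paste0(base, "s"))
  e_final <- grepl("e$", base)
  ing <- ifelse(e_final, paste0(sub("e$", "", base), "ing"), paste0(base, "ing"))
  past <- ifelse(e_final, paste0(base, "d"), paste0(base, "ed"))
  c(base, third, ing, past)
}

.pos_verb_forms <- unique(c(
  unlist(lapply(.pos_verb_bases, .inflect_verb)),
  "spoke", "spoken", "speaks", "made", "making", "went", "gone", "saw",
  "seen", "ran", "running", "shown", "sought", "said", "struggles"
))

# Words that are nouns or verbs depending on context; the surrounding word
# decides ("object" after a determiner is a noun, after a pronoun a verb).
.pos_nv_ambiguous <- unique(c(
  "object", "objects", "play", "plays", "note", "notes", "report", "reports",
  "line", "lines", "rock", "rocks", "point", "points", "gesture", "gestures",
  "stack", "stacks", "spin", "spins", "tap", "taps", "clap", "claps",
  "display", "displays", "need", "needs", "look", "looks", "use", "uses"
))

# Tag one sentence worth of tokens. `texts` are the raw token strings.
# Context enters only through the noun/verb-ambiguous words, whose tag is
# decided by the preceding word token (pronoun/modal/"to" or an adverb
# selects the verb reading), so the tagger vectorizes cleanly.
.tag_pos <- function(texts) {
  low <- tolower(texts)
  is_word <- grepl("[[:alnum:]]", texts)
  n <- length(texts)
  is_adv <- is_word & (low %in% .pos_adverbs |
                         (nchar(low) > 3L & endsWith(low, "ly")))
  prev_low <- rep("", n)       # previous *word* token, skipping punctuation
  prev_adv <- rep(FALSE, n)
  wi <- which(is_word)
  if (length(wi) > 1L) {
    prev_low[wi[-1]] <- low[wi[-length(wi)]]
    prev_adv[wi[-1]] <- is_adv[wi[-length(wi)]]
  }
  pos <- rep("NOUN", n)
  pos[!is_word] <- "OTHER"
  verbish <- is_word & low %in% .pos_verb_forms
  ambiguous <- verbish & low %in% .pos_nv_ambiguous
  verb_ctx <- prev_low %in% c(.pos_pronouns, .pos_modals, "to") | prev_adv
  pos[verbish & (!ambiguous | verb_ctx)] <- "VERB"
  adjish <- is_word & pos == "NOUN" &
    (low %in% .pos_adjectives |
       (grepl("(ous|ful|less|ive|ish|ic|al)$", low) & nchar(low) > 4L))
  pos[adjish] <- "ADJ"
  pos[is_adv] <- "ADV"
  pos[is_word & low %in% .pos_function] <- "OTHER"
  pos
}

## ---- lemmatizer ---------------------------------------------------------

.lemma_irregular <- c(
  spoke = "speak", spoken = "speak", said = "say", made = "make",
  went = "go", gone = "go", saw = "see", seen = "see", ran = "run",
  had = "have", has = "have", was = "be", were = "be", is = "be",
  are = "be", am = "be", been = "be", being = "be", did = "do",
  does = "do", done = "do", children = "child", men = "man",
  women = "woman", feet = "foot", teeth = "tooth", shown = "show",
  sought = "seek"
)

# Small suffix-stripping lemmatizer; only the decision-tree baseline uses
# lemmas (the rule engine matches surface forms), so a deterministic
# approximation is sufficient.
.lemmatize <- function(words) {
  w <- tolower(words)
  out <- unname(.lemma_irregular[w])
  todo <- is.na(out)
  x <- w[todo]
  x <- sub("sses$", "ss", x)
  x <- sub("ies$", "y", x)
  x <- sub("(x|ch|sh|ss|z)es$", "\\1", x)
  x <- ifelse(grepl("[^su]s$", x) & nchar(x) > 3L, sub("s$", "", x), x)
  ing <- grepl("ing$", x) & nchar(x) > 5L
  x[ing] <- sub("ing$", "", x[ing])
  ed <- grepl("ed$", x) & nchar(x) > 4L
  x[ed] <- sub("ed$", "", x[ed])
  # undouble final consonant left by -ing/-ed stripping (running -> run)
  dbl <- grepl("([b-df-hj-np-tv-z])\\1$", x)
  x[dbl] <- sub("([b-df-hj-np-tv-z])\\1$", "\\1", x[dbl])
  out[todo] <- x
  out
}

## ---- sentence splitting and preprocessing ------------------------------

# 0-based cut offsets (exclusive sentence ends) within `text`.
.sentence_cuts <- function(text) {
  cuts <- integer(0)
  m <- gregexpr("[.!?]+[\"')\\]]*", text, perl = TRUE)[[1]]
  if (m[1] != -1L) {
    ends <- as.integer(m) + attr(m, "match.length") - 1L  # 1-based last char
    nxt <- substring(text, ends + 1L, ends + 1L)
    ok <- nxt == "" | grepl("^[[:space:]]$", nxt)
    cuts <- c(cuts, ends[ok])                              # 0-based exclusive
  }
  nl <- gregexpr("\n", text, fixed = TRUE)[[1]]
  if (nl[1] != -1L) cuts <- c(cuts, as.integer(nl) - 1L)
  sort(unique(c(cuts, nchar(text))))
}

#' Preprocess raw record text into a tokenized document
#'
#' Splits the text into sentences and tokens, assigns coarse part-of-speech
#' tags (`NOUN`, `VERB`, `ADJ`, `ADV`, `OTHER`) and lemmas, and records
#' character offsets (0-based, half-open) into the unmodified input text.
#' The tokenizer splits on whitespace and punctuation but keeps internal
#' hyphens, so "eye-to-eye" is a single token. `word_count` counts tokens
#' containing at least one alphanumeric character.
#'
#' @param raw_text Non-empty character scalar: the record's free text.
#' @param record_id Character scalar identifying the record.
#' @param metadata Optional list with elements `surveillance_year` (integer)
#'   and `case_status` (`"ASD"`, `"non-ASD"` or `"unknown"`).
#' @return A `dsm_document`: a list with elements `record_id`, `text`,
#'   `sentences` (data frame: `sentence_id`, `char_start`, `char_end`),
#'   `tokens` (data frame: `sentence_id`, `index_in_sentence`, `text`,
#'   `char_start`, `char_end`, `pos`, `lemma`, `is_word`), `metadata` and
#'   `word_count`.
#' @examples
#' doc <- preprocess("He makes minimal eye contact.", "rec1")
#' doc$word_count
#' @export
preprocess <- function(raw_text, record_id = "record",
                       metadata = list()) {
  if (!is.character(raw_text) || length(raw_text) != 1L || is.na(raw_text) ||
      !nzchar(trimws(raw_text))) {
    stop("`raw_text` must be a non-empty character scalar")
  }
  stopifnot(is.character(record_id), length(record_id) == 1L)
  metadata <- list(
    surveillance_year = if (!is.null(metadata$surveillance_year))
      as.integer(metadata$surveillance_year) else NA_integer_,
    case_status = if (!is.null(metadata$case_status) &&
                      !is.na(metadata$case_status))
      match.arg(as.character(metadata$case_status),
                c("ASD", "non-ASD", "unknown")) else "unknown"
  )

  cuts <- .sentence_cuts(raw_text)
  starts <- c(0L, cuts[-length(cuts)])
  seg <- data.frame(start = starts, end = cuts)
  seg <- seg[seg$end > seg$start, , drop = FALSE]

  sent_rows <- list()
  tok_rows <- list()
  sid <- 0L
  for (i in seq_len(nrow(seg))) {
    s0 <- seg$start[i]
    s1 <- seg$end[i]
    chunk <- substring(raw_text, s0 + 1L, s1)
    m <- gregexpr(.token_regex, chunk, perl = TRUE)[[1]]
    if (m[1] == -1L) next
    sid <- sid + 1L
    t_start <- s0 + as.integer(m) - 1L           # 0-based
    t_end <- t_start + attr(m, "match.length")
    texts <- regmatches(chunk, list(m))[[1]]
    sent_rows[[sid]] <- data.frame(
      sentence_id = sid, char_start = t_start[1],
      char_end = t_end[length(t_end)]
    )
    tok_rows[[sid]] <- data.frame(
      sentence_id = sid,
      index_in_sentence = seq_along(texts) - 1L,
      text = texts,
      char_start = t_start,
      char_end = t_end,
      pos = .tag_pos(texts),
      lemma = .lemmatize(texts),
      is_word = grepl("[[:alnum:]]", texts),
      stringsAsFactors = FALSE
    )
  }
  if (sid == 0L) stop("`raw_text` contains no tokens")
  tokens <- do.call(rbind, tok_rows)
  structure(
    list(record_id = record_id, text = raw_text,
         sentences = do.call(rbind, sent_rows),
         tokens = tokens, metadata = metadata,
         word_count = sum(tokens$is_word)),
    class = "dsm_document"
  )
}

#' @export
print.dsm_document <- function(x, ...) {
  cat(sprintf("<dsm_document %s: %d sentences, %d tokens, %d words>\n",
              x$record_id, nrow(x$sentences), nrow(x$tokens), x$word_count))
  invisible(x)
}

#' Word tokens of a document or sentence
#'
#' Returns the tokens that contain at least one alphanumeric character,
#' i.e. excluding pure punctuation. These are the tokens counted by the
#' pattern engine's gap budgets and by `word_count`.
#'
#' @param document A `dsm_document`.
#' @param sentence_id Optional sentence id; if given, only that sentence's
#'   word tokens are returned.
#' @return Data frame of token rows (possibly zero rows).
#' @export
word_tokens <- function(document, sentence_id = NULL) {
  stopifnot(inherits(document, "dsm_document"))
  tok <- document$tokens
  if (!is.null(sentence_id)) tok <- tok[tok$sentence_id == sentence_id, ]
  tok[tok$is_word, , drop = FALSE]
}

## ---- corpus readers/writers --------------------------------------------

#' Read a corpus from a directory of text files
#'
#' Each `.txt` file becomes one record (record id = file name without
#' extension). An optional tab-separated metadata table supplies
#' `record_id`, `year` and `case_status` columns.
#'
#' @param dir Directory containing `.txt` files.
#' @param metadata_path Optional path to the metadata TSV.
#' @return A list of `dsm_document` objects (class `dsm_corpus`).
#' @export
read_corpus_dir <- function(dir, metadata_path = NULL) {
  files <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  if (length(files) == 0L) stop("no .txt files found in ", dir)
  meta <- NULL
  if (!is.null(metadata_path)) {
    meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
    if (!all(c("record_id", "year", "case_status") %in% names(meta))) {
      stop("metadata table must have columns record_id, year, case_status")
    }
  }
  docs <- lapply(files, function(f) {
    rid <- tools::file_path_sans_ext(basename(f))
    md <- list()
    if (!is.null(meta) && rid %in% meta$record_id) {
      row <- meta[meta$record_id == rid, ][1, ]
      md <- list(surveillance_year = row$year, case_status = row$case_status)
    }
    preprocess(paste(readLines(f, warn = FALSE), collapse = "\n"), rid, md)
  })
  structure(docs, class = "dsm_corpus")
}

#' Read a corpus from a JSON-lines file
#'
#' One record per line with fields `record_id`, `text` and optionally
#' `year` and `case_status`.
#'
#' @param path Path to the JSON-lines file.
#' @return A list of `dsm_document` objects (class `dsm_corpus`).
#' @export
read_corpus_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty corpus file: ", path)
  docs <- lapply(lines, function(l) {
    rec <- jsonlite::fromJSON(l)
    if (is.null(rec$record_id) || is.null(rec$text)) {
      stop("corpus line missing record_id or text")
    }
    preprocess(rec$text, rec$record_id,
               list(surveillance_year = rec$year,
                    case_status = rec$case_status))
  })
  structure(docs, class = "dsm_corpus")
}

#' Write tokenized documents as JSON-lines (for debugging)
#'
#' @param documents A list of `dsm_document` objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_tokens_jsonl <- function(documents, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (doc in documents) {
    writeLines(jsonlite::toJSON(
      list(record_id = doc$record_id, text = doc$text,
           metadata = doc$metadata, word_count = doc$word_count,
           tokens = doc$tokens),
      auto_unbox = TRUE, dataframe = "rows"), con)
  }
  invisible(path)
}
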