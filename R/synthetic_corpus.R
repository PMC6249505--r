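# Seeded synthetic EHR-like corpora with planted gold annotations.
#
# Positive sentences are template instantiations of the packaged patterns
# (trigger terms sampled from the pattern's own lexicons, filler tokens
# within the gap budgets), so recall on planted data is decidable by
# construction and verified at generation time. Distractor sentences are
# built from a filler vocabulary disjoint from every lexicon term and can
# therefore never match. Near-miss sentences exercise false positives:
# half are pattern-completing fragments excluded from the gold standard
# (emulating accidental matches to nonsensical fragments), half reuse
# isolated lexicon terms without completing any pattern.

.filler_candidates <- c(
  "the", "a", "his", "her", "their", "was", "were", "seen", "for", "this",
  "week", "today", "team", "plan", "goals", "review", "meeting", "summary",
  "services", "support", "program", "staff", "during", "session", "again",
  "across", "several", "settings", "provider", "general", "daily", "areas",
  "skills", "level", "overall", "continues", "remains", "present", "some",
  "other", "various", "multiple", "activities", "tasks", "items", "given",
  "within", "toward", "progress", "update", "current", "ongoing", "period",
  "placement", "classwork", "materials", "morning", "afternoon", "weekly")

#' Synthetic corpus configuration
#'
#' Defaults emulate the surveillance records the parser was built for:
#' records averaging 1900 words (the era means were roughly 1400 before
#' 2006 and 2450 after), roughly 0.5\%-5\% of sentences expressing any one
#' criterion, biennial collection waves 2000-2010, and a small rate of
#' near-miss distractors standing in for the naturally occurring
#' false-positive fragments of real notes.
#'
#' @param n_records Number of records to generate.
#' @param mean_words_per_record Mean record length in words; lengths are
#'   sampled log-normally around it.
#' @param prevalence Per-criterion probability that a sentence of an
#'   ASD-labeled record expresses the criterion; a scalar (recycled) or a
#'   named vector over the 12 criteria. Default 0.02.
#' @param non_asd_factor Multiplier applied to `prevalence` for non-ASD
#'   records (default 1/3: criteria are described less often in non-ASD
#'   records).
#' @param asd_fraction Fraction of records labeled ASD (default 0.55).
#' @param years Surveillance years records are drawn from.
#' @param near_miss_rate Probability that a sentence is a near-miss
#'   distractor (default 0.02; set 0 for a corpus where the packaged
#'   ruleset attains perfect precision by construction).
#' @param seed Mandatory integer seed; the whole corpus is a deterministic
#'   function of (config, ruleset).
#' @return A `dsm_corpus_config`.
#' @export
corpus_config <- function(n_records = 100L,
                          mean_words_per_record = 1900,
                          prevalence = 0.02,
                          non_asd_factor = 1 / 3,
                          asd_fraction = 0.55,
                          years = seq(2000L, 2010L, by = 2L),
                          near_miss_rate = 0.02,
                          seed) {
  if (missing(seed)) stop("`seed` is mandatory")
  if (length(prevalence) == 1L && is.null(names(prevalence))) {
    prevalence <- stats::setNames(rep(prevalence, 12L), .criterion_ids)
  }
  if (is.null(names(prevalence)) ||
      !setequal(names(prevalence), .criterion_ids)) {
    stop("`prevalence` must be a scalar or named over the 12 criteria")
  }
  prevalence <- prevalence[.criterion_ids]
  if (any(prevalence < 0) || any(prevalence > 0.2)) {
    stop("per-criterion prevalence outside a plausible range")
  }
  if (sum(prevalence) + near_miss_rate > 0.9) {
    stop("total planted prevalence infeasible for a record")
  }
  stopifnot(n_records >= 1L, mean_words_per_record >= 50,
            asd_fraction >= 0, asd_fraction <= 1,
            near_miss_rate >= 0, near_miss_rate < 1,
            non_asd_factor > 0, non_asd_factor <= 1)
  structure(list(n_records = as.integer(n_records),
                 mean_words_per_record = mean_words_per_record,
                 prevalence = prevalence,
                 non_asd_factor = non_asd_factor,
                 asd_fraction = asd_fraction,
                 years = as.integer(years),
                 near_miss_rate = near_miss_rate,
                 seed = as.integer(seed)),
            class = "dsm_corpus_config")
}

# Sample a surface term usable for planting: no POS constraint.
.plantable_terms <- function(lex) {
  lex$terms[is.na(lex$pos_constraint)]
}

# Instantiate a pattern as a token sequence; returns list(words, arc_idx)
# where arc_idx flags tokens consumed by LEX/LITERAL arcs.
.instantiate_pattern <- function(pat, lexicons, fillers) {
  words <- character(0)
  arc <- logical(0)
  for (e in pat$elements) {
    if (e$kind == "GAP") {
      j <- sample.int(min(e$max_tokens, 3L) + 1L, 1L) - 1L
      if (j > 0L) {
        words <- c(words, sample(fillers, j, replace = TRUE))
        arc <- c(arc, rep(FALSE, j))
      }
    } else if (e$kind == "LITERAL") {
      if (!e$optional || stats::runif(1) < 0.5) {
        words <- c(words, e$word)
        arc <- c(arc, TRUE)
      }
    } else {
      if (e$optional && stats::runif(1) >= 0.5) next
      terms <- .plantable_terms(lexicons$lexicons[[e$name]])
      if (length(terms) == 0L) {
        stop("lexicon '", e$name, "' has no plantable terms")
      }
      words <- c(words, sample(terms, 1L))
      arc <- c(arc, TRUE)
    }
  }
  list(words = words, arc = arc)
}

# Assemble words into a sentence string; returns the string plus 0-based
# local char offsets of each word.
.assemble_sentence <- function(words) {
  starts <- integer(length(words))
  pos <- 0L
  for (i in seq_along(words)) {
    starts[i] <- pos
    pos <- pos + nchar(words[i]) + 1L  # word + space (or final period)
  }
  list(text = paste0(paste(words, collapse = " "), "."),
       starts = starts,
       ends = starts + nchar(words))
}

# Engine check on one standalone sentence: annotations produced by the
# ruleset on `text`, as a data frame with local offsets.
.check_sentence <- function(ruleset, text, index = NULL) {
  annotate_document(ruleset, preprocess(text, "chk"), index = index)
}

#' Generate a synthetic surveillance corpus
#'
#' Sentences are planted according to the per-criterion prevalence (scaled
#' down by `non_asd_factor` for non-ASD records), near-miss distractors
#' according to `near_miss_rate`, and pure-filler distractors otherwise.
#' Every planted positive sentence is verified at generation time to be
#' matched by the ruleset with exactly the recorded gold span and no other
#' annotation; isolated-term near-misses are verified to match nothing.
#' The corpus is byte-identical across runs with the same config and
#' ruleset.
#'
#' @param config A [corpus_config()].
#' @param ruleset A `dsm_ruleset` (default: the packaged one).
#' @return A `dsm_synth_corpus`: list with `records` (each holding
#'   `document`, `gold`, `ledger`), `config`.
#' @examples
#' sc <- generate_corpus(corpus_config(n_records = 2, seed = 7,
#'                                     mean_words_per_record = 200))
#' corpus_summary(sc)$per_criterion
#' @export
generate_corpus <- function(config, ruleset = load_default_ruleset()) {
  stopifnot(inherits(config, "dsm_corpus_config"),
            inherits(ruleset, "dsm_ruleset"))
  gaz_index <- .compile_gazetteer(ruleset$lexicon_set)
  lex_tokens <- unique(unlist(lapply(ruleset$lexicon_set$lexicons,
                                     function(l) unlist(l$entries))))
  fillers <- setdiff(.filler_candidates, lex_tokens)
  if (length(fillers) < 20L) stop("filler vocabulary too small")
  pat_by_crit <- split(ruleset$patterns,
                       vapply(ruleset$patterns, `[[`, character(1),
                              "criterion"))
  missing_crit <- setdiff(names(config$prevalence)[config$prevalence > 0],
                          names(pat_by_crit))
  if (length(missing_crit) > 0L) {
    stop("no patterns for criteria with positive prevalence: ",
         paste(missing_crit, collapse = ", "))
  }

  .with_seed(config$seed, {
    records <- vector("list", config$n_records)
    for (r in seq_len(config$n_records)) {
      record_id <- sprintf("synth%04d", r)
      status <- if (stats::runif(1) < config$asd_fraction) "ASD" else "non-ASD"
      year <- sample(config$years, 1L)
      prev <- config$prevalence *
        if (status == "ASD") 1 else config$non_asd_factor
      n_words <- max(30L, round(stats::rlnorm(
        1, log(config$mean_words_per_record) - 0.35^2 / 2, 0.35)))

      sent_texts <- character(0)
      gold_local <- list()   # per sentence: df of (start, end, criterion)
      ledger <- list()
      words_done <- 0L
      s_idx <- 0L
      while (words_done < n_words) {
        s_idx <- s_idx + 1L
        u <- stats::runif(1)
        cum <- cumsum(prev)
        planted <- which(u < cum)
        if (length(planted) > 0L) {
          cid <- .criterion_ids[planted[1]]
          pats <- pat_by_crit[[cid]]
          pat <- pats[[sample.int(length(pats), 1L)]]
          sent <- NULL
          for (try in 1:25) {
            inst <- .instantiate_pattern(pat, ruleset$lexicon_set, fillers)
            n_pre <- sample.int(4L, 1L) - 1L
            n_suf <- sample.int(4L, 1L) - 1L
            words <- c(sample(fillers, n_pre, replace = TRUE),
                       unlist(strsplit(inst$words, " ", fixed = TRUE)),
                       sample(fillers, n_suf, replace = TRUE))
            arc_words <- c(rep(FALSE, n_pre),
                           rep(inst$arc,
                               lengths(strsplit(inst$words, " ", fixed = TRUE))),
                           rep(FALSE, n_suf))
            asm <- .assemble_sentence(words)
            lo <- asm$starts[which(arc_words)[1]]
            hi <- asm$ends[max(which(arc_words))]
            ann <- .check_sentence(ruleset, asm$text, gaz_index)
            if (nrow(ann) == 1L && ann$criterion == cid &&
                ann$char_start == lo && ann$char_end == hi) {
              sent <- list(text = asm$text, lo = lo, hi = hi,
                           pattern_id = pat$pattern_id)
              break
            }
          }
          if (is.null(sent)) {
            stop("could not instantiate a verified positive sentence for ",
                 cid, " (pattern ", pat$pattern_id, ")")
          }
          sent_texts <- c(sent_texts, sent$text)
          gold_local[[s_idx]] <- data.frame(start = sent$lo, end = sent$hi,
                                            criterion = cid)
          ledger[[s_idx]] <- data.frame(
            sentence_index = s_idx, kind = "positive", criterion = cid,
            pattern_id = sent$pattern_id, stringsAsFactors = FALSE)
        } else if (u < sum(prev) + config$near_miss_rate) {
          if (stats::runif(1) < 0.5) {
            # pattern-completing fragment, excluded from gold (false
            # positive generator)
            pat <- ruleset$patterns[[sample.int(length(ruleset$patterns), 1L)]]
            inst <- .instantiate_pattern(pat, ruleset$lexicon_set, fillers)
            words <- c(sample(fillers, 2L),
                       unlist(strsplit(inst$words, " ", fixed = TRUE)),
                       sample(fillers, 2L))
            asm <- .assemble_sentence(words)
            sent_texts <- c(sent_texts, asm$text)
            ledger[[s_idx]] <- data.frame(
              sentence_index = s_idx, kind = "near_miss_match",
              criterion = pat$criterion, pattern_id = pat$pattern_id,
              stringsAsFactors = FALSE)
          } else {
            # isolated lexicon terms that complete no pattern
            sent <- NULL
            for (try in 1:25) {
              lx <- ruleset$lexicon_set$lexicons[[
                sample.int(length(ruleset$lexicon_set$lexicons), 1L)]]
              terms <- .plantable_terms(lx)
              if (length(terms) == 0L) next
              words <- c(sample(fillers, 3L),
                         strsplit(sample(terms, 1L), " ", fixed = TRUE)[[1]],
                         sample(fillers, 3L))
              asm <- .assemble_sentence(words)
              if (nrow(.check_sentence(ruleset, asm$text, gaz_index)) == 0L) {
                sent <- asm$text
                break
              }
            }
            if (is.null(sent)) stop("could not build an isolated-term near-miss")
            sent_texts <- c(sent_texts, sent)
            ledger[[s_idx]] <- data.frame(
              sentence_index = s_idx, kind = "near_miss_isolated",
              criterion = NA_character_, pattern_id = NA_character_,
              stringsAsFactors = FALSE)
          }
        } else {
          n_w <- sample(8:16, 1L)
          asm <- .assemble_sentence(sample(fillers, n_w, replace = TRUE))
          sent_texts <- c(sent_texts, asm$text)
        }
        toks <- regmatches(sent_texts[s_idx],
                           gregexpr(.token_regex, sent_texts[s_idx],
                                    perl = TRUE))[[1]]
        words_done <- words_done + sum(grepl("[[:alnum:]]", toks))
      }

      text <- paste(sent_texts, collapse = " ")
      offsets <- cumsum(c(0L, nchar(sent_texts[-length(sent_texts)]) + 1L))
      gold_rows <- list()
      for (i in seq_along(gold_local)) {
        gl <- gold_local[[i]]
        if (is.null(gl)) next
        gold_rows[[length(gold_rows) + 1L]] <- data.frame(
          record_id = record_id,
          char_start = gl$start + offsets[i],
          char_end = gl$end + offsets[i],
          criterion = gl$criterion,
          text = substring(text, gl$start + offsets[i] + 1L,
                           gl$end + offsets[i]),
          stringsAsFactors = FALSE)
      }
      gold <- if (length(gold_rows) > 0L) do.call(rbind, gold_rows) else
        data.frame(record_id = character(0), char_start = integer(0),
                   char_end = integer(0), criterion = character(0),
                   text = character(0), stringsAsFactors = FALSE)
      doc <- preprocess(text, record_id,
                        list(surveillance_year = year, case_status = status))
      records[[r]] <- list(
        document = doc, gold = gold,
        ledger = if (length(ledger) > 0L)
          do.call(rbind, ledger[!vapply(ledger, is.null, logical(1))])
        else NULL)
    }
    structure(list(records = records, config = config),
              class = "dsm_synth_corpus")
  })
}

#' @export
print.dsm_synth_corpus <- function(x, ...) {
  cat(sprintf("<dsm_synth_corpus: %d records, %d gold annotations, seed %d>\n",
              length(x$records), nrow(corpus_gold(x)), x$config$seed))
  invisible(x)
}

#' Documents of a synthetic corpus
#' @param sc A `dsm_synth_corpus`.
#' @return List of `dsm_document` objects.
#' @export
corpus_documents <- function(sc) {
  stopifnot(inherits(sc, "dsm_synth_corpus"))
  lapply(sc$records, `[[`, "document")
}

#' Gold annotations of a synthetic corpus
#' @param sc A `dsm_synth_corpus`.
#' @return Gold annotation data frame over all records.
#' @export
corpus_gold <- function(sc) {
  stopifnot(inherits(sc, "dsm_synth_corpus"))
  golds <- lapply(sc$records, `[[`, "gold")
  out <- do.call(rbind, golds)
  rownames(out) <- NULL
  out
}

#' Summarize a synthetic corpus
#'
#' @param sc A `dsm_synth_corpus`.
#' @return List with `per_year` (record counts and mean word counts by
#'   case status), `per_criterion` (gold annotation counts), and
#'   `n_records`.
#' @export
corpus_summary <- function(sc) {
  stopifnot(inherits(sc, "dsm_synth_corpus"))
  docs <- corpus_documents(sc)
  meta <- data.frame(
    year = vapply(docs, function(d) d$metadata$surveillance_year,
                  integer(1)),
    case_status = vapply(docs, function(d) d$metadata$case_status,
                         character(1)),
    word_count = vapply(docs, `[[`, integer(1), "word_count"))
  per_year <- stats::aggregate(word_count ~ year + case_status, meta,
                               function(w) c(n = length(w),
                                             mean_words = mean(w)))
  per_year <- do.call(data.frame, per_year)
  names(per_year) <- c("year", "case_status", "n_records", "mean_words")
  gold <- corpus_gold(sc)
  per_criterion <- data.frame(
    criterion = .criterion_ids,
    gold_n = vapply(.criterion_ids,
                    function(cid) sum(gold$criterion == cid), integer(1)))
  rownames(per_criterion) <- NULL
  list(per_year = per_year[order(per_year$year, per_year$case_status), ],
       per_criterion = per_criterion, n_records = length(docs))
}

#' Write a corpus (synthetic or not) as JSON-lines plus gold TSV
#'
#' Emits the same formats the corpus readers accept: `corpus.jsonl` (one
#' record per line with `record_id`, `text`, `year`, `case_status`) and,
#' for synthetic corpora, `gold.tsv`.
#'
#' @param x A `dsm_synth_corpus` or list of `dsm_document`s.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_corpus <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  docs <- if (inherits(x, "dsm_synth_corpus")) corpus_documents(x) else x
  con <- file(file.path(dir, "corpus.jsonl"), open = "wt")
  for (doc in docs) {
    writeLines(jsonlite::toJSON(
      list(record_id = doc$record_id, text = doc$text,
           year = doc$metadata$surveillance_year,
           case_status = doc$metadata$case_status),
      auto_unbox = TRUE, na = "null"), con)
  }
  close(con)
  if (inherits(x, "dsm_synth_corpus")) {
    write_gold(corpus_gold(x), file.path(dir, "gold.tsv"))
  }
  invisible(dir)
}
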