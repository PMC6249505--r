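test_that("the pattern DSL parses and validates", {
  lex <- toy_ruleset()$lexicon_set
  path <- withr::local_tempfile(fileext = ".dsl")
  writeLines(c("# patterns",
               "A2c.1: LEX(Freq) GAP(5) LEX(Odd) LEX?(Speech)"), path)
  pats <- parse_pattern_file(path, lex)
  expect_length(pats, 1L)
  p <- pats[[1]]
  expect_equal(p$criterion, "A2c")
  kinds <- vapply(p$elements, `[[`, character(1), "kind")
  expect_equal(sum(kinds == "LEX"), 3L)
  expect_equal(sum(kinds == "GAP"), 1L)
  expect_true(p$accept_early)
  expect_equal(format_pattern(p),
               "A2c.1: LEX(Freq) GAP(5) LEX(Odd) LEX?(Speech)")

  writeLines("A2c.2: GAP(3) LEX(Freq)", path)
  expect_error(parse_pattern_file(path, lex), "GAP")
  writeLines("A2c.3: LEX(Nope)", path)
  expect_error(parse_pattern_file(path, lex), "Nope")
  writeLines("A2c.4: LEX(Freq) JUNK", path)
  expect_error(parse_pattern_file(path, lex), "syntax")
  writeLines("A9z.1: LEX(Freq)", path)
  expect_error(parse_pattern_file(path, lex), "criterion")
})

test_that("pattern invariants are enforced by the constructor", {
  expect_error(pattern("A1a.1", list(pattern_element("GAP", max_tokens = 2),
                                     pattern_element("LEX", name = "L"))),
               "GAP")
  expect_error(pattern("A1a.1", list(pattern_element("LEX", name = "L",
                                                     optional = TRUE))),
               "required LEX")
  expect_error(pattern("A1a.1", list(pattern_element("LEX", name = "L"),
                                     pattern_element("GAP", max_tokens = 1))),
               "last element")
})

test_that("gap budgets bound the intervening word tokens", {
  rs <- toy_ruleset()
  # five word tokens between the triggers: still within the budget
  ok <- preprocess("often alpha bravo carol delta ember reduced volume", "r")
  ann <- annotate_document(rs, ok)
  expect_equal(nrow(ann), 1L)
  expect_equal(ann$matched_text,
               "often alpha bravo carol delta ember reduced volume")
  # six word tokens: budget exceeded, no match
  over <- preprocess("often alpha bravo carol delta ember frost reduced volume",
                     "r")
  expect_equal(nrow(annotate_document(rs, over)), 0L)
  # punctuation inside a gap is free
  punct <- preprocess("often alpha, bravo, carol, delta, ember reduced volume",
                      "r")
  expect_equal(nrow(annotate_document(rs, punct)), 1L)
})

test_that("GAP(0) requires adjacency and larger budgets only add matches", {
  lex <- lexicon_set(list(lexicon("A", "all", "alpha"),
                          lexicon("B", "all", "bravo")))
  mk <- function(k) ruleset(lex, list(pattern("A1a.1", list(
    pattern_element("LEX", name = "A"),
    pattern_element("GAP", max_tokens = k),
    pattern_element("LEX", name = "B")))))
  doc_adj <- preprocess("alpha bravo", "r")
  doc_one <- preprocess("alpha carol bravo", "r")
  expect_equal(nrow(annotate_document(mk(0), doc_adj)), 1L)
  expect_equal(nrow(annotate_document(mk(0), doc_one)), 0L)
  expect_equal(nrow(annotate_document(mk(1), doc_one)), 1L)
  for (k in 1:5) {
    a_small <- annotate_document(mk(k - 1), doc_one)
    a_big <- annotate_document(mk(k), doc_one)
    expect_true(all(a_small$matched_text %in% a_big$matched_text))
  }
})

test_that("gap fillers may not begin a hit of the next required arc", {
  # with "bravo" also in lexicon B, "alpha bravo carol" must transition at
  # "bravo", not swallow it as filler to reach the later "bravo"
  lex <- lexicon_set(list(lexicon("A", "all", "alpha"),
                          lexicon("B", "all", "bravo")))
  rs <- ruleset(lex, list(pattern("A1a.1", list(
    pattern_element("LEX", name = "A"),
    pattern_element("GAP", max_tokens = 5),
    pattern_element("LEX", name = "B")))))
  doc <- preprocess("alpha bravo carol bravo", "r")
  ann <- annotate_document(rs, doc)
  expect_equal(ann$matched_text, "alpha bravo")
})

test_that("literal arcs consume exactly their word", {
  lex <- lexicon_set(list(lexicon("Odd", "all", "reduced")))
  rs <- ruleset(lex, list(pattern("A2c.9", list(
    pattern_element("LITERAL", word = "speaks"),
    pattern_element("GAP", max_tokens = 2),
    pattern_element("LEX", name = "Odd")))))
  expect_equal(nrow(annotate_document(rs, preprocess("speaks with reduced volume", "r"))), 1L)
  expect_equal(nrow(annotate_document(rs, preprocess("talks with reduced volume", "r"))), 0L)
})

test_that("annotations never cross sentence boundaries and are per-sentence", {
  rs <- toy_ruleset()
  doc <- preprocess("often speaks. with reduced volume", "r")
  expect_equal(nrow(annotate_document(rs, doc)), 0L)
  dup <- preprocess("often speaks with reduced volume. often speaks with reduced volume.",
                    "r")
  ann <- annotate_document(rs, dup)
  expect_equal(nrow(ann), 2L)
  expect_equal(ann$sentence_id, c(1L, 2L))
})

test_that("annotate_document is deterministic and deduplicates spans", {
  rs <- load_default_ruleset()
  doc <- preprocess(
    "He makes minimal eye contact with adults and struggles with turn-taking in conversations",
    "r")
  a1 <- annotate_document(rs, doc)
  a2 <- annotate_document(rs, doc)
  expect_identical(a1, a2)
  expect_false(any(duplicated(a1[, c("criterion", "char_start", "char_end")])))
  doc0 <- preprocess("nothing relevant here at all", "r")
  expect_equal(nrow(annotate_document(rs, doc0)), 0L)
})

test_that("the matcher agrees with the brute-force arc-assignment oracle", {
  withr::with_seed(77, {
    done <- 0
    while (done < 120) {
      case <- make_random_case()
      if (is.null(case$pattern)) next
      done <- done + 1
      hits <- gazetteer_annotate(case$doc, case$lexicons)
      got <- match_sentence(case$pattern, case$doc, 1L, hits)
      tok <- case$doc$tokens
      want <- oracle_match_spans(case$pattern, tok,
                                 hits[hits$sentence_id == 1L, , drop = FALSE])
      got_spans <- data.frame(
        start = match(got$char_start, tok$char_start),
        end = match(got$char_end, tok$char_end))
      got_spans <- got_spans[order(got_spans$start), , drop = FALSE]
      expect_equal(unname(as.matrix(got_spans)), unname(as.matrix(want)),
                   ignore_attr = TRUE)
    }
  })
})

test_that("annotation standoff TSV round-trips", {
  rs <- toy_ruleset()
  doc <- preprocess("often speaks with reduced volume", "r")
  ann <- annotate_document(rs, doc)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_annotations(ann, path)
  back <- read_annotations(path)
  expect_equal(back$criterion, ann$criterion)
  expect_equal(back$char_start, ann$char_start)
  # the same file can be used as gold input
  gold <- read_gold(path)
  expect_equal(nrow(gold), nrow(ann))
})
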