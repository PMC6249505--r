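test_that("lexicon TSV loading validates and merges rows", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment",
               "A1a_nonVerbalBehavior\tcriterion:A1a\teye contact",
               "A1a_nonVerbalBehavior\tcriterion:A1a\tgestures",
               "A1a_nonVerbalBehavior\tcriterion:A1a\teye contact",
               "Body_parts\tall\tnose\tNOUN"),
             path)
  set <- load_lexicons(path)
  expect_length(set$lexicons, 2L)
  lx <- set$lexicons[["A1a_nonVerbalBehavior"]]
  expect_equal(sort(lx$terms), c("eye contact", "gestures"))  # deduplicated
  expect_equal(lx$entries[[match("eye contact", lx$terms)]],
               c("eye", "contact"))
  expect_equal(set$lexicons[["Body_parts"]]$pos_constraint, "NOUN")

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("# nothing here", empty)
  expect_error(load_lexicons(empty), "no lexicon rows")

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("L1\tall\tword", "L2\tnowhere\tword"), bad)
  expect_error(load_lexicons(bad), "line 2")

  malformed <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("L1\tall\tword", "only_one_field"), malformed)
  expect_error(load_lexicons(malformed), "line 2")
})

test_that("lexicon sets round-trip through the TSV format", {
  set <- lexicon_set(list(
    lexicon("A2c_idiosyncratic", "criterion:A2c", c("jargon", "echolalia")),
    lexicon("Objects", "all", c("object", "objects"), "NOUN")))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_lexicons(set, path)
  back <- load_lexicons(path)
  expect_equal(names(back$lexicons), names(set$lexicons))
  expect_equal(back$lexicons[["Objects"]]$pos_constraint, c("NOUN", "NOUN"))
  expect_equal(n_terms(back), n_terms(set))
})

test_that("gazetteer finds maximal multi-word hits within sentences", {
  set <- lexicon_set(list(
    lexicon("A1a_nonVerbalBehavior", "criterion:A1a",
            c("eye contact", "eye"))))
  doc <- preprocess("poor eye contact", "r")
  hits <- gazetteer_annotate(doc, set)
  expect_equal(nrow(hits), 1L)  # longest entry wins at the same start
  expect_equal(hits$token_start, 1L)
  expect_equal(hits$token_end, 2L)
  expect_equal(hits$text, "eye contact")

  # hits never cross sentence boundaries
  doc2 <- preprocess("poor eye. contact noted", "r")
  expect_equal(nrow(gazetteer_annotate(doc2, lexicon_set(list(
    lexicon("L", "all", "eye contact"))))), 0L)
})

test_that("the A2c worked fragment gets one hit per trigger lexicon", {
  set <- lexicon_set(list(
    lexicon("A2c_frequent", "criterion:A2c", c("often", "frequently")),
    lexicon("A2c_idiosyncratic", "criterion:A2c", c("reduced", "breathy")),
    lexicon("A2c_speech", "criterion:A2c", c("volume", "voice"))))
  doc <- preprocess("often speaks with reduced volume", "r")
  hits <- gazetteer_annotate(doc, set)
  expect_equal(hits$lexicon_name[order(hits$token_start)],
               c("A2c_frequent", "A2c_idiosyncratic", "A2c_speech"))
  expect_equal(hits$text[order(hits$token_start)],
               c("often", "reduced", "volume"))
})

test_that("POS-constrained entries respect the head token's class", {
  set <- lexicon_set(list(lexicon("Obj", "all", "object", "NOUN")))
  expect_equal(nrow(gazetteer_annotate(preprocess("I object to that", "r"),
                                       set)), 0L)
  hits <- gazetteer_annotate(preprocess("He lined up the object", "r"), set)
  expect_equal(nrow(hits), 1L)
})

test_that("gazetteer equals the brute-force window scan on random sentences", {
  vocab <- c("alpha", "bravo", "carol", "delta", "ember", ",")
  withr::with_seed(421, {
    for (case in 1:40) {
      set <- lexicon_set(lapply(1:3, function(i) {
        terms <- unique(vapply(1:3, function(j) {
          paste(sample(vocab[1:5], sample(1:2, 1)), collapse = " ")
        }, character(1)))
        lexicon(paste0("L", i), "all", terms)
      }))
      sent <- paste(sample(vocab, sample(4:12, 1), replace = TRUE),
                    collapse = " ")
      doc <- preprocess(sent, "r")
      got <- gazetteer_annotate(doc, set)
      want <- oracle_gazetteer(doc, set)
      expect_equal(got[, c("lexicon_name", "sentence_id", "token_start",
                           "token_end")],
                   want, ignore_attr = TRUE)
    }
  })
})

test_that("adding a term never removes existing hits", {
  doc <- preprocess("poor eye contact and reduced volume today", "r")
  base <- lexicon_set(list(lexicon("L", "all", c("eye contact", "volume"))))
  more <- lexicon_set(list(lexicon("L", "all",
                                   c("eye contact", "volume", "poor"))))
  h1 <- gazetteer_annotate(doc, base)
  h2 <- gazetteer_annotate(doc, more)
  key <- function(h) paste(h$lexicon_name, h$token_start, h$token_end)
  expect_true(all(key(h1) %in% key(h2)))
  expect_gt(nrow(h2), nrow(h1))
})
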