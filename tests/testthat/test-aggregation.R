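test_that("record filtering uses an inclusive 40-character cutoff", {
  txt39 <- paste(rep("word", 8), collapse = " ")   # 8*4 + 7 spaces
  short <- preprocess(txt39, "short")
  exact <- preprocess(paste0(txt39, "s"), "exact")
  expect_equal(nchar(short$text), 39L)
  expect_equal(nchar(exact$text), 40L)
  docs <- list(short, exact)
  kept <- filter_records(docs)
  expect_equal(vapply(kept, `[[`, character(1), "record_id"), "exact")
  expect_length(filter_records(list()), 0L)
  expect_length(filter_records(docs, min_chars = 10), 2L)
})

test_that("record profiles normalize by word count and count distinct criteria", {
  txt <- paste(rep("plain filler sentence here today.", 40), collapse = " ")
  doc <- preprocess(txt, "r1",
                    list(surveillance_year = 2006, case_status = "ASD"))
  wc <- doc$word_count
  ann <- data.frame(
    record_id = "r1",
    criterion = c("A1a", "A2a", "A2a", "A3b"),
    char_start = c(0, 10, 20, 30), char_end = c(5, 15, 25, 35),
    stringsAsFactors = FALSE)
  prof <- profile_record(doc, ann)
  expect_equal(prof$raw_A2a, 2L)
  expect_equal(prof$norm_A2a, 2 / wc)
  expect_equal(prof$norm_A1a, 1 / wc)
  expect_equal(prof$distinct_criteria, 3L)

  none <- profile_record(doc, ann[0, ])
  expect_equal(none$distinct_criteria, 0L)
  expect_true(all(none[paste0("raw_", criterion_ids())] == 0))
})

test_that("doubling a record leaves normalized counts unchanged", {
  base <- "Minimal eye contact was noted today."
  d1 <- preprocess(base, "r")
  d2 <- preprocess(paste(base, base), "r")
  rs <- load_default_ruleset()
  p1 <- profile_record(d1, annotate_document(rs, d1))
  p2 <- profile_record(d2, annotate_document(rs, d2))
  for (cid in criterion_ids()) {
    expect_equal(p2[[paste0("norm_", cid)]], p1[[paste0("norm_", cid)]],
                 tolerance = 1e-12)
    expect_equal(p2[[paste0("raw_", cid)]], 2L * p1[[paste0("raw_", cid)]])
  }
})

test_that("trend tables agree with a naive two-pass oracle", {
  rs <- load_default_ruleset()
  sc <- generate_corpus(corpus_config(n_records = 15L,
                                      mean_words_per_record = 250,
                                      seed = 59), rs)
  docs <- filter_records(corpus_documents(sc))
  ann <- annotate_corpus(rs, docs)
  prof <- profile_corpus(docs, ann)
  tt <- trend_table(prof)
  want <- oracle_group_means(prof)
  expect_equal(tt$table$mean_normalized_count, want$mean_normalized_count,
               tolerance = 1e-12)
  expect_equal(tt$table$n, want$n)
  expect_equal(sum(unique(tt$table[, c("year", "case_status", "n")])$n),
               nrow(prof))
  expect_true(all(prof$distinct_criteria >= 0 &
                    prof$distinct_criteria <= 12))
  expect_equal(tt$mean_distinct_criteria, mean(prof$distinct_criteria))
})

test_that("ASD records average more criteria than non-ASD under 3x prevalence", {
  rs <- load_default_ruleset()
  sc <- generate_corpus(corpus_config(n_records = 120L,
                                      mean_words_per_record = 400,
                                      prevalence = 0.03,
                                      non_asd_factor = 1 / 3,
                                      asd_fraction = 0.5,
                                      near_miss_rate = 0, seed = 61), rs)
  docs <- corpus_documents(sc)
  prof <- profile_corpus(docs, annotate_corpus(rs, docs))
  tt <- trend_table(prof)$table
  agg <- stats::aggregate(mean_normalized_count ~ case_status + criterion,
                          tt, mean)
  for (cid in criterion_ids()) {
    asd <- agg$mean_normalized_count[agg$criterion == cid &
                                       agg$case_status == "ASD"]
    non <- agg$mean_normalized_count[agg$criterion == cid &
                                       agg$case_status == "non-ASD"]
    expect_gt(asd, non)
  }
})

test_that("zero-word records are rejected by profiling", {
  doc <- preprocess("...", "empty")
  expect_equal(doc$word_count, 0L)
  expect_error(profile_record(doc, data.frame(record_id = character(0),
                                              criterion = character(0),
                                              char_start = integer(0),
                                              char_end = integer(0))),
               "zero words")
})

test_that("trend tables write as tidy TSV", {
  rs <- load_default_ruleset()
  sc <- generate_corpus(corpus_config(n_records = 6L,
                                      mean_words_per_record = 200,
                                      seed = 67), rs)
  docs <- corpus_documents(sc)
  prof <- profile_corpus(docs, annotate_corpus(rs, docs))
  tt <- trend_table(prof)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trend_table(tt, path)
  back <- utils::read.delim(path)
  expect_equal(names(back), c("year", "case_status", "criterion",
                              "mean_normalized_count", "n"))
  expect_equal(nrow(back), nrow(tt$table))
})
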