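ann_row <- function(record, crit, s, e) {
  data.frame(record_id = record, criterion = crit, char_start = s,
             char_end = e, stringsAsFactors = FALSE)
}

test_that("partial match needs same criterion and >= 1 char overlap", {
  m <- ann_row("r", "A1a", 3, 29)    # "exhibited poor eye contact"
  g <- ann_row("r", "A1a", 13, 45)   # "poor eye contact with the examiner"
  expect_true(partial_match(m, g))
  expect_false(partial_match(ann_row("r", "A1a", 0, 10),
                             ann_row("r", "A1b", 0, 10)))
  expect_false(partial_match(ann_row("r", "A1a", 0, 10),
                             ann_row("r", "A1a", 10, 20)))
  expect_false(partial_match(ann_row("r1", "A1a", 0, 10),
                             ann_row("r2", "A1a", 0, 10)))
})

test_that("annotation-level counting is greedy one-to-one", {
  gold <- rbind(ann_row("r", "A1a", 0, 10), ann_row("r", "A1a", 20, 30),
                ann_row("r", "A1a", 40, 50), ann_row("r", "A2a", 5, 15))
  machine <- rbind(ann_row("r", "A1a", 5, 12), ann_row("r", "A1a", 22, 28),
                   ann_row("r", "A1a", 45, 55), ann_row("r", "A1a", 60, 70))
  rep <- evaluate_annotation_level(machine, gold)
  a1a <- rep$per_criterion[rep$per_criterion$row == "A1a", ]
  expect_equal(a1a$tp, 3)
  expect_equal(a1a$fp, 1)
  expect_equal(a1a$precision, 0.75)
  expect_equal(a1a$recall, 1)

  # one machine span overlapping two same-criterion gold spans earns one tp
  gold2 <- rbind(ann_row("r", "A2a", 0, 10), ann_row("r", "A2a", 12, 20))
  machine2 <- ann_row("r", "A2a", 5, 15)
  rep2 <- evaluate_annotation_level(machine2, gold2)
  a2a <- rep2$per_criterion[rep2$per_criterion$row == "A2a", ]
  expect_equal(a2a$tp, 1)
  expect_equal(a2a$fn, 1)
})

test_that("degenerate machine sets are flagged, not NaN", {
  gold <- ann_row("r", "A1a", 0, 10)
  machine <- gold[0, ]
  rep <- evaluate_annotation_level(machine, gold)
  a1a <- rep$per_criterion[rep$per_criterion$row == "A1a", ]
  expect_equal(a1a$precision, 0)
  expect_true(a1a$precision_undefined)
  expect_equal(a1a$recall, 0)
  expect_equal(a1a$f_measure, 0)
})

test_that("sentence-level counts, specificity and any-rule are correct", {
  # one record of 100 identical sentences
  txt <- paste(rep("filler words here now.", 100), collapse = " ")
  doc <- preprocess(txt, "r")
  expect_equal(nrow(doc$sentences), 100L)
  sent_span <- function(i) c(doc$sentences$char_start[i],
                             doc$sentences$char_end[i])
  g <- rbind(ann_row("r", "A1a", sent_span(1)[1], sent_span(1)[2]),
             ann_row("r", "A1a", sent_span(2)[1], sent_span(2)[2]))
  m <- rbind(g, ann_row("r", "A1a", sent_span(50)[1], sent_span(50)[2]))
  rep <- evaluate_sentence_level(m, g, list(doc))
  a1a <- rep$per_criterion[rep$per_criterion$row == "A1a", ]
  expect_equal(a1a[, c("tp", "fp", "fn", "tn")],
               data.frame(tp = 2, fp = 1, fn = 0, tn = 97),
               ignore_attr = TRUE)
  expect_equal(a1a$specificity, 97 / 98)

  # sentence with gold A1a and A2b; machine finds only A2b
  g2 <- rbind(ann_row("r", "A1a", sent_span(3)[1], sent_span(3)[2]),
              ann_row("r", "A2b", sent_span(3)[1], sent_span(3)[2]))
  m2 <- ann_row("r", "A2b", sent_span(3)[1], sent_span(3)[2])
  rep2 <- evaluate_sentence_level(m2, g2, list(doc))
  tab2 <- rep2$per_criterion
  expect_equal(tab2$tp[tab2$row == "A2b"], 1)
  expect_equal(tab2$fn[tab2$row == "A1a"], 1)
  expect_equal(rep2$any_rule$tp, 1)
  expect_equal(rep2$any_rule$fn, 0)
})

test_that("report rows satisfy the metric identities", {
  sc <- generate_corpus(corpus_config(n_records = 6, seed = 303,
                                      mean_words_per_record = 250),
                        load_default_ruleset())
  docs <- corpus_documents(sc)
  gold <- corpus_gold(sc)
  machine <- annotate_corpus(load_default_ruleset(), docs)
  for (report in list(evaluate_annotation_level(machine, gold),
                      evaluate_sentence_level(machine, gold, docs))) {
    tab <- metrics_table(report)
    pr <- tab$precision + tab$recall
    f_expect <- ifelse(pr > 0, 2 * tab$precision * tab$recall / pr, 0)
    expect_equal(tab$f_measure, f_expect, tolerance = 1e-12)
    # microaverage recall equals pooled tp over pooled gold count
    per <- report$per_criterion
    expect_equal(report$microaverage$recall,
                 sum(per$tp) / max(1, sum(per$tp) + sum(per$fn)))
  }
  srep <- evaluate_sentence_level(machine, gold, docs)
  n_sent <- sum(vapply(docs, function(d) nrow(d$sentences), integer(1)))
  per <- srep$per_criterion
  expect_equal(per$tp + per$fn, per$gold_n)
  expect_equal(per$tp + per$fp + per$fn + per$tn,
               rep(n_sent, 12L))
})

test_that("annotations referencing unknown records are rejected", {
  doc <- preprocess("some sentence here.", "r1")
  g <- ann_row("r1", "A1a", 0, 4)
  m <- ann_row("ghost", "A1a", 0, 4)
  expect_error(evaluate_sentence_level(m, g, list(doc)), "ghost")
  expect_error(evaluate_annotation_level(m, g, corpus = list(doc)), "ghost")
})

test_that("gold standoff files round-trip and validate", {
  gold <- rbind(
    data.frame(record_id = "r1", char_start = 0L, char_end = 10L,
               criterion = "A1a", text = "poor eye c"),
    data.frame(record_id = "r1", char_start = 5L, char_end = 12L,
               criterion = "A2b", text = "ye cont"))  # overlap is fine
  path <- withr::local_tempfile(fileext = ".tsv")
  write_gold(gold, path)
  back <- read_gold(path)
  expect_equal(back[, names(gold)], gold, ignore_attr = TRUE)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("record_id\tchar_start\tchar_end\tcriterion",
               "r1\t0\t10\tA4x"), bad)
  expect_error(read_gold(bad), "line")
})

test_that("the packaged reference benchmark tables are well-formed", {
  ref <- reference_benchmarks()
  expect_equal(nrow(ref$gold_overview), 12L)
  expect_equal(ref$n_test_records, 50L)
  expect_equal(nrow(ref$sentence_level), 14L)  # 12 criteria + micro + any
  expect_true(all(ref$annotation_level$precision <= 1))
})
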