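# Build a separable corpus for the baseline tests: each criterion has a
# unique marker word, each positive sentence contains it, negatives are
# filler-only. Returns the documents plus gold annotations over the
# marker sentences.
make_separable_corpus <- function(n_sentences, per_criterion, seed,
                                  n_records = 10L) {
  fill <- c("today", "session", "review", "goals", "team", "plan",
            "week", "staff", "program", "support")
  markers <- stats::setNames(paste0("marker", tolower(criterion_ids())),
                             criterion_ids())
  withr::with_seed(seed, {
    kinds <- rep(NA_character_, n_sentences)
    pos_idx <- sample(n_sentences, per_criterion * 12L)
    kinds[pos_idx] <- rep(criterion_ids(), each = per_criterion)
    sents <- vapply(seq_len(n_sentences), function(i) {
      words <- sample(fill, 5, replace = TRUE)
      if (!is.na(kinds[i])) words[3] <- markers[[kinds[i]]]
      paste0(paste(words, collapse = " "), ".")
    }, character(1))
    split_id <- rep(seq_len(n_records), length.out = n_sentences)
    docs <- list()
    gold <- list()
    for (r in seq_len(n_records)) {
      idx <- which(split_id == r)
      text <- paste(sents[idx], collapse = " ")
      rid <- sprintf("sep%02d", r)
      doc <- preprocess(text, rid)
      docs[[r]] <- doc
      for (j in seq_along(idx)) {
        k <- kinds[idx[j]]
        if (is.na(k)) next
        s <- doc$sentences[j, ]
        gold[[length(gold) + 1L]] <- data.frame(
          record_id = rid, char_start = s$char_start,
          char_end = s$char_end, criterion = k, stringsAsFactors = FALSE)
      }
    }
    list(docs = docs, gold = do.call(rbind, gold))
  })
}
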