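# Decision-tree sentence-classification baseline.
#
# Sentences are represented as bags of lemmas over a frequency-thresholded
# vocabulary; one binary pruned decision tree (CART, via rpart) is trained
# per criterion, with the negative class undersampled at a fixed ratio
# except for the two high-prevalence communication criteria (A2a, A2b),
# which use all negatives. Lemmas are the only features; the rule engine,
# by contrast, matches surface forms.

#' Baseline configuration
#'
#' @param undersample_ratio Negatives kept per positive during training
#'   (default 30).
#' @param undersample_exempt Criteria trained on all negatives (default
#'   A2a and A2b, which occur frequently enough to use the entire
#'   training data).
#' @param pruning_strength Pruning confidence in (0, 1]; smaller values
#'   prune more aggressively. Internally mapped onto rpart's
#'   cost-complexity parameter as `cp = 0.01 * (1 - s) / s`, so the
#'   default 0.25 gives cp = 0.03 and 1 disables pruning.
#' @param min_frequency Lemmas must occur strictly more than this many
#'   times in the training corpus to enter the vocabulary (default 5).
#' @param seed Integer seed; recorded in the model and driving the
#'   undersampling draws.
#' @return A `dsm_baseline_config`.
#' @export
baseline_config <- function(undersample_ratio = 30L,
                            undersample_exempt = c("A2a", "A2b"),
                            pruning_strength = 0.25,
                            min_frequency = 5L,
                            seed = 1L) {
  stopifnot(undersample_ratio >= 1L,
            pruning_strength > 0, pruning_strength <= 1,
            min_frequency >= 0L,
            all(undersample_exempt %in% .criterion_ids))
  structure(list(undersample_ratio = as.integer(undersample_ratio),
                 undersample_exempt = undersample_exempt,
                 pruning_strength = pruning_strength,
                 min_frequency = as.integer(min_frequency),
                 seed = as.integer(seed)),
            class = "dsm_baseline_config")
}

# Canonical per-sentence lemma bags: one row per sentence, ordered by
# (record_id, sentence_id) so results do not depend on input order.
.sentence_units <- function(corpus) {
  stopifnot(is.list(corpus), length(corpus) > 0L)
  ids <- vapply(corpus, `[[`, character(1), "record_id")
  corpus <- corpus[order(ids)]
  units <- list()
  for (doc in corpus) {
    wt <- doc$tokens[doc$tokens$is_word, , drop = FALSE]
    for (sid in doc$sentences$sentence_id) {
      units[[length(units) + 1L]] <- list(
        record_id = doc$record_id, sentence_id = sid,
        char_start = doc$sentences$char_start[
          doc$sentences$sentence_id == sid],
        char_end = doc$sentences$char_end[
          doc$sentences$sentence_id == sid],
        lemmas = wt$lemma[wt$sentence_id == sid])
    }
  }
  units
}

#' Build the lemma vocabulary
#'
#' Keeps every lemma whose corpus frequency is strictly greater than
#' `min_frequency` ("appeared more than n times"), ordered by frequency
#' (descending) then lexicographically, so two corpora differing only in
#' record order yield identical vocabularies.
#'
#' @param corpus List of `dsm_document` objects (the training corpus).
#' @param config A [baseline_config()].
#' @return A `dsm_vocabulary`: list with `lemmas`, `frequencies`,
#'   `min_frequency`.
#' @export
build_vocabulary <- function(corpus, config = baseline_config()) {
  units <- .sentence_units(corpus)
  all_lemmas <- unlist(lapply(units, `[[`, "lemmas"), use.names = FALSE)
  if (length(all_lemmas) == 0L) stop("corpus contains no word tokens")
  counts <- table(all_lemmas)
  keep <- counts > config$min_frequency
  counts <- counts[keep]
  ord <- order(-as.integer(counts), names(counts))
  structure(list(lemmas = names(counts)[ord],
                 frequencies = as.integer(counts)[ord],
                 min_frequency = config$min_frequency),
            class = "dsm_vocabulary")
}

#' Vectorize a sentence over a vocabulary
#'
#' @param lemmas Character vector of a sentence's word-token lemmas (or a
#'   `dsm_document` plus `sentence_id`).
#' @param vocabulary A `dsm_vocabulary`.
#' @param sentence_id Sentence to vectorize when `lemmas` is a document.
#' @return Integer vector of term counts, one per vocabulary lemma;
#'   out-of-vocabulary lemmas are ignored.
#' @export
vectorize <- function(lemmas, vocabulary, sentence_id = NULL) {
  stopifnot(inherits(vocabulary, "dsm_vocabulary"))
  if (inherits(lemmas, "dsm_document")) {
    stopifnot(!is.null(sentence_id))
    wt <- word_tokens(lemmas, sentence_id)
    lemmas <- wt$lemma
  }
  counts <- table(factor(lemmas, levels = vocabulary$lemmas))
  stats::setNames(as.integer(counts), vocabulary$lemmas)
}

.vectorize_units <- function(units, vocabulary) {
  X <- matrix(0L, nrow = length(units), ncol = length(vocabulary$lemmas))
  for (i in seq_along(units)) {
    X[i, ] <- vectorize(units[[i]]$lemmas, vocabulary)
  }
  colnames(X) <- paste0("V", seq_len(ncol(X)))
  X
}

# Sentence x criterion label matrix from gold annotations: a sentence is
# positive for criterion c when it contains any gold annotation of c.
.sentence_label_matrix <- function(units, gold, corpus) {
  docs_by_id <- stats::setNames(corpus, vapply(corpus, `[[`, character(1),
                                               "record_id"))
  keys <- vapply(units, function(u) paste0(u$record_id, "\r", u$sentence_id),
                 character(1))
  lab <- matrix(FALSE, nrow = length(units), ncol = 12L,
                dimnames = list(NULL, .criterion_ids))
  if (nrow(gold) > 0L) {
    gk <- .sentence_keys(gold, docs_by_id, "gold annotation")
    for (j in seq_len(nrow(gold))) {
      i <- match(gk[j], keys)
      if (!is.na(i)) lab[i, gold$criterion[j]] <- TRUE
    }
  }
  lab
}

#' Undersample negative training examples
#'
#' Keeps all positives; for non-exempt criteria draws a seeded uniform
#' sample of `undersample_ratio` x (number of positives) negatives (capped
#' at the available negatives). Exempt criteria keep every negative.
#'
#' @param positives,negatives Integer indices of positive and negative
#'   training sentences.
#' @param config A [baseline_config()].
#' @param criterion Criterion being trained (decides exemption and the
#'   per-criterion sampling stream).
#' @return Sorted integer indices of the retained training sentences.
#' @export
undersample <- function(positives, negatives, config, criterion) {
  stopifnot(inherits(config, "dsm_baseline_config"),
            criterion %in% .criterion_ids)
  if (criterion %in% config$undersample_exempt) {
    return(sort(c(positives, negatives)))
  }
  n_keep <- min(length(negatives),
                config$undersample_ratio * length(positives))
  kept <- .with_seed(
    .sub_seed(config$seed, match(criterion, .criterion_ids)),
    sort(negatives)[sample.int(length(negatives), n_keep)]
  )
  sort(c(positives, kept))
}

#' Train the per-criterion decision-tree baseline
#'
#' Builds the lemma vocabulary from the training corpus, derives sentence
#' labels from the gold annotations, undersamples negatives per criterion,
#' and fits one binary pruned CART tree per criterion (one-vs-rest). A
#' criterion with no positive sentences is skipped with a warning; a
#' degenerate single-class training set yields a constant classifier with
#' a warning. Training is deterministic under a fixed config seed,
#' regardless of the order of the input documents.
#'
#' @param corpus List of `dsm_document` objects.
#' @param gold Gold annotation data frame for `corpus`.
#' @param config A [baseline_config()].
#' @return A `dsm_baseline`: list with `models` (per criterion: an rpart
#'   fit or a constant), `vocabulary`, `config`.
#' @export
train_baseline <- function(corpus, gold, config = baseline_config()) {
  .check_annotation_frame(gold, "gold")
  vocabulary <- build_vocabulary(corpus, config)
  units <- .sentence_units(corpus)
  X <- .vectorize_units(units, vocabulary)
  lab <- .sentence_label_matrix(units, gold, corpus)
  cp <- 0.01 * (1 - config$pruning_strength) / config$pruning_strength
  models <- stats::setNames(vector("list", 12L), .criterion_ids)
  for (cid in .criterion_ids) {
    pos <- which(lab[, cid])
    neg <- which(!lab[, cid])
    if (length(pos) == 0L) {
      warning("criterion ", cid, ": no positive sentences; skipped")
      models[[cid]] <- list(type = "constant", value = FALSE)
      next
    }
    keep <- undersample(pos, neg, config, cid)
    y <- factor(lab[keep, cid], levels = c(FALSE, TRUE))
    if (length(unique(y)) < 2L) {
      warning("criterion ", cid,
              ": single-class training set; constant classifier")
      models[[cid]] <- list(type = "constant", value = lab[keep[1], cid])
      next
    }
    df <- data.frame(y = y, X[keep, , drop = FALSE])
    fit <- rpart::rpart(y ~ ., data = df, method = "class",
                        control = rpart::rpart.control(
                          cp = cp, xval = 0L, minsplit = 10L,
                          minbucket = 3L))
    models[[cid]] <- list(type = "tree", fit = fit)
  }
  structure(list(models = models, vocabulary = vocabulary,
                 config = config),
            class = "dsm_baseline")
}

#' @export
print.dsm_baseline <- function(x, ...) {
  n_tree <- sum(vapply(x$models, function(m) m$type == "tree", logical(1)))
  cat(sprintf("<dsm_baseline: %d/12 criterion trees, vocabulary %d lemmas, seed %d>\n",
              n_tree, length(x$vocabulary$lemmas), x$config$seed))
  invisible(x)
}

#' Predict sentence labels with a trained baseline
#'
#' @param baseline A `dsm_baseline` from [train_baseline()].
#' @param corpus List of `dsm_document` objects to classify.
#' @return Data frame of predicted positive sentences: `record_id`,
#'   `sentence_id`, `criterion`, `char_start`, `char_end` (the sentence
#'   span, usable as a sentence-level machine annotation).
#' @export
predict_baseline <- function(baseline, corpus) {
  stopifnot(inherits(baseline, "dsm_baseline"))
  units <- .sentence_units(corpus)
  X <- .vectorize_units(units, baseline$vocabulary)
  out <- list()
  newdata <- as.data.frame(X)
  for (cid in .criterion_ids) {
    m <- baseline$models[[cid]]
    pred <- if (m$type == "constant") {
      rep(isTRUE(m$value), nrow(X))
    } else {
      prob <- predict(m$fit, newdata = newdata)[, "TRUE"]
      prob > 0.5
    }
    for (i in which(pred)) {
      u <- units[[i]]
      out[[length(out) + 1L]] <- data.frame(
        record_id = u$record_id, sentence_id = u$sentence_id,
        criterion = cid, char_start = u$char_start, char_end = u$char_end,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(record_id = character(0), sentence_id = integer(0),
                      criterion = character(0), char_start = integer(0),
                      char_end = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Predict and evaluate the baseline at sentence level
#'
#' @param baseline A `dsm_baseline`.
#' @param corpus Test corpus (list of `dsm_document`s).
#' @param gold Gold annotations for the test corpus.
#' @return A `dsm_metrics` report from [evaluate_sentence_level()].
#' @export
predict_and_evaluate <- function(baseline, corpus, gold) {
  pred <- predict_baseline(baseline, corpus)
  evaluate_sentence_level(pred, gold, corpus)
}

#' Save / load a baseline model file
#'
#' The file is self-describing: it contains the per-criterion trees, the
#' vocabulary and the configuration including the seed.
#'
#' @param baseline A `dsm_baseline`.
#' @param path File path.
#' @return `save_baseline` returns `path` invisibly; `load_baseline`
#'   returns the `dsm_baseline`.
#' @export
save_baseline <- function(baseline, path) {
  stopifnot(inherits(baseline, "dsm_baseline"))
  saveRDS(baseline, path)
  invisible(path)
}

#' @rdname save_baseline
#' @export
load_baseline <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "dsm_baseline")) stop("not a baseline model file: ", path)
  x
}
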