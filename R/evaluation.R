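# Scoring machine annotations against a gold standard.
#
# Partial-match semantics: a machine annotation is correct when it shares
# the criterion label with a gold annotation in the same record and their
# character spans overlap by at least one character. Evaluation is done at
# the annotation level (greedy one-to-one matching of individual spans)
# and at the sentence level (each sentence is one unit per criterion).

#' Partial-match test between a machine and a gold annotation
#'
#' @param machine,gold One-row data frames (or lists) with `record_id`,
#'   `criterion`, `char_start`, `char_end`.
#' @return `TRUE` iff both refer to the same record, carry the same
#'   criterion label and their spans overlap by at least one character.
#' @examples
#' m <- list(record_id = "r", criterion = "A1a", char_start = 3, char_end = 29)
#' g <- list(record_id = "r", criterion = "A1a", char_start = 13, char_end = 45)
#' partial_match(m, g)
#' @export
partial_match <- function(machine, gold) {
  machine$record_id == gold$record_id &&
    machine$criterion == gold$criterion &&
    max(machine$char_start, gold$char_start) <
      min(machine$char_end, gold$char_end)
}

# One metrics row from confusion counts; tn = NA at annotation level.
.metrics_row <- function(tp, fp, fn, tn = NA_real_) {
  p_undef <- (tp + fp) == 0
  r_undef <- (tp + fn) == 0
  precision <- if (p_undef) 0 else tp / (tp + fp)
  recall <- if (r_undef) 0 else tp / (tp + fn)
  f <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  specificity <- if (is.na(tn)) NA_real_ else {
    if (tn + fp == 0) 1 else tn / (tn + fp)
  }
  data.frame(tp = tp, fp = fp, fn = fn, tn = tn,
             precision = precision, recall = recall, f_measure = f,
             specificity = specificity,
             precision_undefined = p_undef, recall_undefined = r_undef)
}

.check_annotation_frame <- function(x, what) {
  need <- c("record_id", "criterion", "char_start", "char_end")
  if (!all(need %in% names(x))) {
    stop(what, " must have columns ", paste(need, collapse = ", "))
  }
  bad <- !x$criterion %in% .criterion_ids
  if (any(bad)) {
    stop(what, " contains invalid criterion label(s): ",
         paste(unique(x$criterion[bad]), collapse = ", "))
  }
  invisible(x)
}

#' Annotation-level evaluation
#'
#' For each criterion, machine annotations are matched one-to-one to gold
#' annotations by [partial_match()], greedily: machine annotations are
#' visited in span order and each claims the earliest-starting unmatched
#' overlapping gold annotation, so one machine span can never earn credit
#' for two gold annotations. `tp` = matched pairs, `fp` = unmatched
#' machine, `fn` = unmatched gold. The microaverage row pools the counts
#' across all twelve criteria. Specificity is not defined at this level
#' (the number of candidate non-annotations is not defined) and is
#' reported as `NA`.
#'
#' @param machine,gold Annotation data frames with `record_id`,
#'   `criterion`, `char_start`, `char_end`.
#' @param corpus Optional list of `dsm_document`s; when supplied, records
#'   referenced by annotations must exist in it.
#' @return A `dsm_metrics` report (see [metrics_table()]).
#' @export
evaluate_annotation_level <- function(machine, gold, corpus = NULL) {
  .check_annotation_frame(machine, "machine")
  .check_annotation_frame(gold, "gold")
  if (!is.null(corpus)) {
    known <- vapply(corpus, `[[`, character(1), "record_id")
    unknown <- setdiff(unique(c(machine$record_id, gold$record_id)), known)
    if (length(unknown) > 0L) {
      stop("annotations reference unknown record(s): ",
           paste(unknown, collapse = ", "))
    }
  }
  rows <- lapply(.criterion_ids, function(cid) {
    m <- machine[machine$criterion == cid, , drop = FALSE]
    g <- gold[gold$criterion == cid, , drop = FALSE]
    m <- m[order(m$record_id, m$char_start, m$char_end), , drop = FALSE]
    g <- g[order(g$record_id, g$char_start, g$char_end), , drop = FALSE]
    g_used <- rep(FALSE, nrow(g))
    tp <- 0L
    for (i in seq_len(nrow(m))) {
      cand <- which(!g_used &
                      g$record_id == m$record_id[i] &
                      pmax(g$char_start, m$char_start[i]) <
                        pmin(g$char_end, m$char_end[i]))
      if (length(cand) > 0L) {
        g_used[cand[1]] <- TRUE  # earliest gold start (g is sorted)
        tp <- tp + 1L
      }
    }
    cbind(data.frame(row = cid, gold_n = nrow(g)),
          .metrics_row(tp, nrow(m) - tp, sum(!g_used)))
  })
  per <- do.call(rbind, rows)
  micro <- cbind(data.frame(row = "Microaverage", gold_n = sum(per$gold_n)),
                 .metrics_row(sum(per$tp), sum(per$fp), sum(per$fn)))
  structure(list(level = "annotation", per_criterion = per,
                 microaverage = micro, any_rule = NULL),
            class = "dsm_metrics")
}

# Map annotations to sentence keys "record\rsentence_id" using the corpus
# sentence inventory (first sentence whose span overlaps the annotation).
.sentence_keys <- function(ann, docs_by_id, what) {
  if (nrow(ann) == 0L) return(character(0))
  keys <- character(nrow(ann))
  for (i in seq_len(nrow(ann))) {
    doc <- docs_by_id[[ann$record_id[i]]]
    if (is.null(doc)) {
      stop(what, " references unknown record '", ann$record_id[i], "'")
    }
    s <- doc$sentences
    hit <- which(pmax(s$char_start, ann$char_start[i]) <
                   pmin(s$char_end, ann$char_end[i]))
    if (length(hit) == 0L) {
      stop(what, " span [", ann$char_start[i], ",", ann$char_end[i],
           ") lies outside the sentences of record '", ann$record_id[i], "'")
    }
    keys[i] <- paste0(ann$record_id[i], "\r", s$sentence_id[hit[1]])
  }
  keys
}

#' Sentence-level evaluation
#'
#' Each sentence of the corpus is one unit per criterion: `tp` = sentences
#' containing gold annotations of the criterion in which the system placed
#' at least one annotation of the same criterion; `fn` = gold sentences
#' with none; `fp` = sentences with machine annotations of the criterion
#' but no gold for it; `tn` = all remaining sentences, and specificity =
#' TN/(TN+FP). The microaverage row pools counts across criteria. The
#' `any_rule` row repeats the computation with the twelve labels collapsed
#' to a single binary "contains any criterion" label.
#'
#' @param machine,gold Annotation data frames (see
#'   [evaluate_annotation_level()]).
#' @param corpus List of `dsm_document` objects providing the sentence
#'   inventory; every annotated record must be present.
#' @return A `dsm_metrics` report.
#' @export
evaluate_sentence_level <- function(machine, gold, corpus) {
  .check_annotation_frame(machine, "machine")
  .check_annotation_frame(gold, "gold")
  stopifnot(is.list(corpus), length(corpus) > 0L)
  docs_by_id <- stats::setNames(corpus,
                                vapply(corpus, `[[`, character(1),
                                       "record_id"))
  n_sentences <- sum(vapply(corpus, function(d) nrow(d$sentences),
                            integer(1)))
  m_key <- .sentence_keys(machine, docs_by_id, "machine annotation")
  g_key <- .sentence_keys(gold, docs_by_id, "gold annotation")

  count_level <- function(m_keys, g_keys) {
    gs <- unique(g_keys)
    ms <- unique(m_keys)
    tp <- length(intersect(gs, ms))
    fn <- length(setdiff(gs, ms))
    fp <- length(setdiff(ms, gs))
    tn <- n_sentences - tp - fn - fp
    c(tp = tp, fp = fp, fn = fn, tn = tn, gold_n = length(gs))
  }

  rows <- lapply(.criterion_ids, function(cid) {
    cc <- count_level(m_key[machine$criterion == cid],
                      g_key[gold$criterion == cid])
    cbind(data.frame(row = cid, gold_n = cc[["gold_n"]]),
          .metrics_row(cc[["tp"]], cc[["fp"]], cc[["fn"]], cc[["tn"]]))
  })
  per <- do.call(rbind, rows)
  micro <- cbind(data.frame(row = "Microaverage", gold_n = sum(per$gold_n)),
                 .metrics_row(sum(per$tp), sum(per$fp), sum(per$fn),
                              sum(per$tn)))
  any_cc <- count_level(m_key, g_key)
  any_rule <- cbind(data.frame(row = "Any rule", gold_n = any_cc[["gold_n"]]),
                    .metrics_row(any_cc[["tp"]], any_cc[["fp"]],
                                 any_cc[["fn"]], any_cc[["tn"]]))
  structure(list(level = "sentence", per_criterion = per,
                 microaverage = micro, any_rule = any_rule),
            class = "dsm_metrics")
}

#' Combined metrics table of a report
#'
#' @param report A `dsm_metrics` object.
#' @return Data frame with the per-criterion rows followed by the
#'   microaverage and (sentence level) "Any rule" rows; metric columns are
#'   kept at full precision.
#' @export
metrics_table <- function(report) {
  stopifnot(inherits(report, "dsm_metrics"))
  out <- rbind(report$per_criterion, report$microaverage)
  if (!is.null(report$any_rule)) out <- rbind(out, report$any_rule)
  rownames(out) <- NULL
  out
}

#' @export
print.dsm_metrics <- function(x, digits = 2, ...) {
  tab <- metrics_table(x)
  show <- tab[, c("row", "gold_n", "precision", "recall", "f_measure",
                  "specificity")]
  for (cn in c("precision", "recall", "f_measure", "specificity")) {
    show[[cn]] <- round(show[[cn]], digits)
  }
  cat(sprintf("%s-level evaluation\n", x$level))
  print(show, row.names = FALSE)
  invisible(x)
}

#' Write a metrics report as JSON
#' @param report A `dsm_metrics` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_metrics_json <- function(report, path) {
  jsonlite::write_json(
    list(level = report$level, table = metrics_table(report)),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

## ---- gold standard i/o --------------------------------------------------

#' Read gold-standard annotations from standoff TSV
#'
#' Expects a header and columns `record_id`, `char_start`, `char_end`,
#' `criterion`, optionally `text`. Malformed rows (unknown criterion,
#' non-numeric or inverted spans) are rejected with their line numbers.
#'
#' @param path Path to the TSV.
#' @return Gold annotation data frame.
#' @export
read_gold <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  need <- c("record_id", "char_start", "char_end", "criterion")
  if (!all(need %in% names(df))) {
    stop("gold file must have columns ", paste(need, collapse = ", "))
  }
  bad <- which(!df$criterion %in% .criterion_ids |
                 !is.finite(df$char_start) | !is.finite(df$char_end) |
                 df$char_start >= df$char_end)
  if (length(bad) > 0L) {
    stop("malformed gold row(s) at line(s) ",
         paste(bad + 1L, collapse = ", "), " of ", path)
  }
  df
}

#' Write gold-standard annotations as standoff TSV
#' @param gold Gold annotation data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gold <- function(gold, path) {
  .check_annotation_frame(gold, "gold")
  cols <- c("record_id", "char_start", "char_end", "criterion",
            intersect("text", names(gold)))
  utils::write.table(gold[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Published benchmark reference tables
#'
#' The summary tables from the original clinical evaluation of this
#' extraction approach on 50 expert-annotated surveillance records (6634
#' sentences), distributed with the package for consistency checking:
#' the gold-standard overview (annotation totals per criterion over the 50
#' test records), annotation-level and sentence-level parser results, and
#' the decision-tree sentence-classification baseline results. Metric
#' values are as printed in the original report, rounded to 2 decimals.
#'
#' @return List of data frames: `gold_overview`, `annotation_level`,
#'   `sentence_level`, `baseline_sentence`, plus `n_test_records` (50).
#' @export
reference_benchmarks <- function() {
  dir <- system.file("extdata", "reference", package = "dsmparse",
                     mustWork = TRUE)
  rd <- function(f) utils::read.delim(file.path(dir, f),
                                      stringsAsFactors = FALSE)
  list(gold_overview = rd("gold_overview.tsv"),
       annotation_level = rd("annotation_level.tsv"),
       sentence_level = rd("sentence_level.tsv"),
       baseline_sentence = rd("baseline_sentence.tsv"),
       n_test_records = 50L)
}
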