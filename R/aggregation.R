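# Longitudinal aggregation of extracted criteria: record filtering,
# length-normalized per-criterion counts, distinct criteria per record,
# and grouping by surveillance year and case status.

#' Filter records by minimum text length
#'
#' Records need a minimum of text for a complete annotation to be
#' possible; the default cutoff of 40 characters (roughly ten words or one
#' full sentence) is inclusive: records with exactly 40 characters are
#' retained.
#'
#' @param documents List of `dsm_document` objects.
#' @param min_chars Minimum raw text length in characters (default 40).
#' @return The retained documents (possibly an empty list).
#' @export
filter_records <- function(documents, min_chars = 40L) {
  keep <- vapply(documents, function(d) nchar(d$text) >= min_chars,
                 logical(1))
  documents[keep]
}

#' Per-record criteria profile
#'
#' Counts annotations per criterion, normalizes by record length
#' (annotation count divided by the record's word count, so longer records
#' do not inflate counts), and counts the distinct criteria present.
#'
#' @param document A `dsm_document`.
#' @param annotations Annotation data frame; only rows for this record are
#'   used.
#' @return One-row data frame: `record_id`, `year`, `case_status`,
#'   `word_count`, `distinct_criteria`, and per criterion `raw_<id>` and
#'   `norm_<id>` columns.
#' @export
profile_record <- function(document, annotations) {
  stopifnot(inherits(document, "dsm_document"))
  if (document$word_count == 0L) {
    stop("record '", document$record_id,
         "' has zero words; filter it out before profiling")
  }
  ann <- annotations[annotations$record_id == document$record_id, ,
                     drop = FALSE]
  raw <- vapply(.criterion_ids, function(cid) sum(ann$criterion == cid),
                integer(1))
  out <- data.frame(record_id = document$record_id,
                    year = document$metadata$surveillance_year,
                    case_status = document$metadata$case_status,
                    word_count = document$word_count,
                    distinct_criteria = sum(raw > 0L),
                    stringsAsFactors = FALSE)
  for (cid in .criterion_ids) {
    out[[paste0("raw_", cid)]] <- raw[[cid]]
    out[[paste0("norm_", cid)]] <- raw[[cid]] / document$word_count
  }
  out
}

#' Profile every record of a corpus
#'
#' @param documents List of `dsm_document` objects (already filtered).
#' @param annotations Annotation data frame over the corpus.
#' @return Data frame with one [profile_record()] row per document.
#' @export
profile_corpus <- function(documents, annotations) {
  do.call(rbind, lapply(documents, profile_record,
                        annotations = annotations))
}

#' Trend table of mean normalized criterion counts
#'
#' Groups record profiles by surveillance year and case status and
#' averages the length-normalized per-criterion counts, mirroring the
#' "average criteria per record" analysis. Records with unknown case
#' status form their own `"unknown"` group.
#'
#' @param profiles Data frame from [profile_corpus()].
#' @return List with `table` (tidy data frame: `year`, `case_status`,
#'   `criterion`, `mean_normalized_count`, `n`), `mean_distinct_criteria`
#'   (overall mean of distinct criteria per record) and `n_records`.
#' @export
trend_table <- function(profiles) {
  stopifnot(is.data.frame(profiles), nrow(profiles) > 0L)
  status <- ifelse(is.na(profiles$case_status) |
                     !profiles$case_status %in% c("ASD", "non-ASD"),
                   "unknown", profiles$case_status)
  year <- profiles$year
  key <- interaction(year, status, drop = TRUE)
  rows <- list()
  for (g in levels(key)) {
    idx <- key == g
    for (cid in .criterion_ids) {
      rows[[length(rows) + 1L]] <- data.frame(
        year = year[idx][1],
        case_status = status[idx][1],
        criterion = cid,
        mean_normalized_count = mean(profiles[[paste0("norm_", cid)]][idx]),
        n = sum(idx),
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$year, tab$case_status, tab$criterion), ]
  rownames(tab) <- NULL
  list(table = tab,
       mean_distinct_criteria = mean(profiles$distinct_criteria),
       n_records = nrow(profiles))
}

#' Write a trend table as tidy TSV
#' @param trends Result of [trend_table()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_trend_table <- function(trends, path) {
  utils::write.table(trends$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
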