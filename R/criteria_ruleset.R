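# The DSM-IV-TR autistic-disorder criterion catalog and the packaged
# starter ruleset (lexicons + patterns) shipped under inst/extdata/ruleset.

.criteria_catalog <- data.frame(
  id = .criterion_ids,
  group = rep(c("A1", "A2", "A3"), each = 4L),
  group_label = rep(c("social interaction", "communication",
                      "restricted/repetitive behaviors and interests"),
                    each = 4L),
  theme = c("Nonverbal behaviors", "Peer relationships", "Seeking to share",
            "Emotional reciprocity", "Spoken language",
            "Initiate or sustain conversation",
            "Stereotyped or idiosyncratic language", "Social imitative play",
            "Restricted patterns of interest", "Adherence to routines",
            "Stereotyped motor mannerisms",
            "Preoccupation with parts of objects"),
  description = c(
    paste("Marked impairment in the use of multiple nonverbal behaviors",
          "such as eye-to-eye gaze, facial expression, body postures, and",
          "gestures to regulate social interaction"),
    "Failure to develop peer relationships appropriate to developmental level",
    paste("A lack of spontaneous seeking to share enjoyment, interests, or",
          "achievements with other people"),
    "Lack of social or emotional reciprocity",
    paste("Delay in, or total lack of, the development of spoken language",
          "(not accompanied by an attempt to compensate through alternative",
          "modes of communication such as gesture or mime)"),
    paste("In individuals with adequate speech, marked impairment in the",
          "ability to initiate or sustain a conversation with others"),
    "Stereotyped and repetitive use of language or idiosyncratic language",
    paste("Lack of varied, spontaneous make-believe play or social",
          "imitative play appropriate to developmental level"),
    paste("Encompassing preoccupation with 1 or more stereotyped and",
          "restricted patterns of interest that is abnormal either in",
          "intensity or focus"),
    paste("Apparently inflexible adherence to specific, nonfunctional",
          "routines or rituals"),
    "Stereotyped and repetitive motor mannerisms",
    "Persistent preoccupation with parts of objects"),
  stringsAsFactors = FALSE
)

#' The DSM-IV-TR criterion catalog
#'
#' The twelve autistic-disorder criteria in three groups: A1 (qualitative
#' impairment in social interaction), A2 (qualitative impairments in
#' communication) and A3 (restrictive, repetitive and stereotyped patterns
#' of behaviors, interests and activities).
#'
#' @return Data frame with columns `id`, `group`, `group_label`, `theme`
#'   and `description` (the full criterion text), one row per criterion.
#' @examples
#' dsm_criteria()[, c("id", "theme")]
#' @export
dsm_criteria <- function() .criteria_catalog

#' Path to the bundled ruleset data directory
#' @return Directory containing `lexicons.tsv` and `patterns.dsl`; users
#'   can copy and extend these files and reload them with
#'   [load_lexicons()] and [parse_pattern_file()].
#' @export
default_ruleset_dir <- function() {
  system.file("extdata", "ruleset", package = "dsmparse", mustWork = TRUE)
}

#' Load the packaged starter ruleset
#'
#' The bundled ruleset covers all twelve criteria: every criterion has at
#' least one lexicon and one pattern. It contains the published example
#' terms under their published lexicon names, the A2c pattern with a
#' frequency arc, a bounded gap, an idiosyncratic-language arc and an
#' optional speech arc, and reconstructed template patterns (impairment
#' cue + gap + criterion-specific behavior lexicon) for the remaining
#' criteria. The shared-lexicon structure (11 shared by all criteria, 7 by
#' group A1, 3 by group A2, 2 by group A3) mirrors the original inventory;
#' lexicons beyond the published examples are reconstructions, not
#' replicas, and the set is user-extensible via [default_ruleset_dir()].
#'
#' @return A `dsm_ruleset`.
#' @examples
#' rs <- load_default_ruleset()
#' describe_ruleset(rs)$per_scope
#' @export
load_default_ruleset <- function() {
  dir <- default_ruleset_dir()
  lex <- load_lexicons(file.path(dir, "lexicons.tsv"))
  pats <- parse_pattern_file(file.path(dir, "patterns.dsl"), lex)
  rs <- ruleset(lex, pats)
  covered <- unique(vapply(rs$patterns, `[[`, character(1), "criterion"))
  if (!all(.criterion_ids %in% covered)) {
    stop("bundled ruleset does not cover criteria: ",
         paste(setdiff(.criterion_ids, covered), collapse = ", "))
  }
  rs
}

#' Summarize a ruleset
#'
#' @param ruleset A `dsm_ruleset`.
#' @return List with `per_criterion` (criterion, number of in-scope
#'   lexicons, their total terms, number of patterns), `per_scope`
#'   (lexicon counts by scope class: `all`, `group:A1`, `group:A2`,
#'   `group:A3`, `criterion`), and totals `n_lexicons`, `n_terms`,
#'   `n_patterns`.
#' @export
describe_ruleset <- function(ruleset) {
  stopifnot(inherits(ruleset, "dsm_ruleset"))
  lex <- ruleset$lexicon_set$lexicons
  scopes <- vapply(lex, `[[`, character(1), "scope")
  sizes <- vapply(lex, function(l) length(l$terms), integer(1))
  pat_crit <- vapply(ruleset$patterns, `[[`, character(1), "criterion")
  per_criterion <- do.call(rbind, lapply(.criterion_ids, function(cid) {
    in_scope <- .scope_covers(scopes, cid)
    data.frame(criterion = cid,
               n_lexicons = sum(in_scope),
               n_terms = sum(sizes[in_scope]),
               n_patterns = sum(pat_crit == cid),
               stringsAsFactors = FALSE)
  }))
  scope_class <- ifelse(startsWith(scopes, "criterion:"), "criterion", scopes)
  per_scope <- as.data.frame(table(scope = scope_class),
                             stringsAsFactors = FALSE)
  names(per_scope) <- c("scope", "n_lexicons")
  list(per_criterion = per_criterion, per_scope = per_scope,
       n_lexicons = length(lex), n_terms = n_terms(ruleset$lexicon_set),
       n_patterns = length(ruleset$patterns))
}
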