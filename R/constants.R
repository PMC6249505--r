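# Shared constants (loaded before the files that use them at top level).

# Token regex: runs of alphanumerics with internal hyphens/apostrophes kept
# ("eye-to-eye" is one token), or a single punctuation character.
.token_regex <- "[[:alnum:]]+(?:['-][[:alnum:]]+)*|[^[:alnum:][:space:]]"

.criterion_ids <- c("A1a", "A1b", "A1c", "A1d",
                    "A2a", "A2b", "A2c", "A2d",
                    "A3a", "A3b", "A3c", "A3d")

#' The twelve DSM-IV-TR criterion identifiers
#'
#' Returns the criterion labels `A1a`..`A3d` in catalog order: group A1
#' (social interaction), A2 (communication), A3 (restricted and repetitive
#' behaviors and interests), four criteria each.
#'
#' @return Character vector of length 12.
#' @export
criterion_ids <- function() .criterion_ids
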