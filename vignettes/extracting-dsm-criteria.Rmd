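---
title: "Extracting DSM-IV-TR autism criteria from clinical text: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting DSM-IV-TR autism criteria from clinical text: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsmparse)
```

## The problem

Autism spectrum disorder surveillance programs review free-text school and
clinical records for evidence of the twelve DSM-IV-TR autistic-disorder
diagnostic criteria — four each for qualitative impairment in social
interaction (A1a–A1d), impairments in communication (A2a–A2d), and
restricted, repetitive and stereotyped behaviors and interests (A3a–A3d).
Clinicians express the same criterion in highly variable language
("makes minimal eye contact", "poor eye-to-eye gaze"), and criterion
evidence is sparse: on the order of 0.5–5% of sentences in a record
express any one criterion. With so few labeled examples per criterion,
`dsmparse` takes a rule-based approach — trigger-word lexicons combined by
finite-state patterns — which extracts criterion-labeled character spans
precisely and transparently, and pairs it with a decision-tree baseline
for comparison.

## Pipeline

1. **Text processing** (`preprocess()`): sentence splitting, tokenization,
   coarse part-of-speech tagging, lemmatization. Offsets are 0-based and
   half-open into the unmodified record text, the usual convention for
   standoff annotation. The tokenizer splits on whitespace and punctuation
   but keeps internal hyphens, because lexicon entries such as
   "eye-to-eye gaze" treat the hyphenated compound as one word.
2. **Gazetteer lookup** (`gazetteer_annotate()`): case-insensitive
   dictionary matching of every lexicon entry over token sequences.
3. **Pattern matching** (`annotate_document()`): finite-state patterns
   over the lexicon hits emit criterion-labeled spans.
4. **Evaluation** (`evaluate_annotation_level()`,
   `evaluate_sentence_level()`) against standoff gold annotations with
   partial-match semantics.
5. **Aggregation** (`profile_corpus()`, `trend_table()`) by surveillance
   year and case status.

## Lexicons and scopes

A lexicon is a named list of surface terms (including singular/plural
variants spelled out — the engine matches surface forms, not stems) with a
*scope*: shared by all criteria, shared within a criterion group (A1, A2
or A3), or specific to one criterion. The packaged set reproduces the
published example terms under their published lexicon names and the
published shared-scope structure (11 lexicons shared by all rules, 7 by
group A1, 3 by group A2, 2 by group A3); the complete original inventory
(92 lexicons, 1787 terms) is unpublished, so the remaining shared
lexicons are reconstructions and the whole set is deliberately
user-extensible (`default_ruleset_dir()` points at plain TSV/DSL files
that can be copied and edited). A term may appear in several lexicons;
lookups are case-folded; multi-word entries must match contiguous tokens
within one sentence, and the longest entry wins per (lexicon, start).
Entries may carry a coarse POS constraint on their head (last) token, so
"object" as a lexicon entry can be restricted to its noun reading and not
fire on "I object". Tags are coarse classes (NOUN, VERB, ADJ, ADV, OTHER)
from a small dictionary-plus-suffix tagger with one contextual rule for
noun/verb-ambiguous words; that is the entire surface the engine needs
from POS tagging, so a heavier tagger would add dependency weight without
changing behavior.

## Pattern semantics

A pattern is an ordered sequence of arcs applied left to right within one
sentence:

* `LEX(name)` consumes the tokens of a gazetteer hit of that lexicon;
* `LEX?(name)` is an optional lexicon arc;
* `LITERAL("word")` consumes one matching word token;
* `GAP(k)` consumes up to `k` intervening *word* tokens. Punctuation
  inside a gap is free, and a gap may not consume a token that begins a
  hit satisfying an arc leaving the gap state. The default budget of 5
  keeps pattern elements related within one clause without making the
  patterns overly specific; it is per-arc configurable.

A match is emitted when all required arcs are satisfied, spanning from the
first to the last consumed token; matching is leftmost with longest
extension, matches starting at the same token collapse to the longest,
and duplicate (criterion, span) pairs from different patterns are reduced
to one annotation (lowest pattern id). Ties and determinism: the output
of `annotate_document()` is a pure function of (ruleset, document).

Two design points were genuinely open:

* **Early acceptance.** The published A2c automaton ends in a speech-term
  arc, yet the same pattern is also reported matching a fragment that ends
  at the idiosyncratic-language term ("frequently … loud"). The DSL
  therefore supports optional trailing arcs, and the packaged `A2c.1`
  marks the speech arc optional (`accept_early` is true), which makes both
  reported behaviors — "often speaks with reduced volume" matched in full,
  and the early-accepted false-positive fragment — reproducible with a
  single pattern.
* **Gap blocking.** What blocks a gap from consuming a token is the set of
  arcs *leaving the gap state* (the chain of optional arcs plus the first
  required one), not every lexicon in the ruleset: a gap may freely cross
  tokens that happen to belong to lexicons irrelevant to the current
  pattern. For every packaged pattern no optional arc directly follows a
  gap, so this coincides with blocking on the next required arc only.

## Evaluation

A machine annotation is *partially matched* to a gold annotation when the
record and criterion agree and the character spans overlap by at least one
character; clinical annotators are inconsistent about including subjects
and verbs inside span boundaries, so demanding exact spans would punish
boundary taste rather than extraction quality.

At the **annotation level**, machine and gold annotations are matched
one-to-one per criterion, greedily in span order with the
earliest-starting gold candidate claimed first, so a single machine span
can never earn credit for two gold annotations (if a sentence contains two
gold annotations of one criterion, both must be found individually).
Specificity is undefined at this level — there is no inventory of
candidate non-annotations — and is reported as `NA`. With an empty machine
set, precision is reported as 0 with an explicit `precision_undefined`
flag rather than `NaN`.

At the **sentence level**, each corpus sentence is one unit per criterion
(tp: a gold sentence with at least one machine annotation of the same
criterion; a sentence counts once per criterion however many machine
annotations it holds), true negatives are well defined, and specificity =
TN/(TN+FP). The microaverage row pools counts across criteria, and the
"Any rule" row collapses all twelve labels into a single binary
"expresses any criterion" label. F is always the harmonic mean of the
same row's precision and recall; metrics are kept at full precision
internally and rounded to two decimals only when printed.

## The decision-tree baseline

Sentence classification (twelve criterion labels or null) with
bag-of-lemma counts over a vocabulary of lemmas occurring strictly more
than 5 times in the training corpus, ordered by frequency then
lexicographically. Because criterion sentences are rare, negatives are
undersampled at 30 per positive — except A2a and A2b, which are frequent
enough to train on all negatives. Because that per-criterion exemption is
only coherent per label, the implementation trains twelve one-vs-rest
binary trees rather than a single multiclass tree. Trees are CART fits
(`rpart`); the C4.5-style "pruning confidence" in (0, 1] is exposed as
`pruning_strength` and mapped onto the cost-complexity parameter as
`cp = 0.01 (1 - s)/s`, a monotone map under which smaller strengths prune
at least as hard (the default 0.25 gives cp = 0.03 and 1 disables
pruning); bit-parity with any particular C4.5 implementation is a
non-goal. All sampling is driven by per-criterion streams derived from
one config seed, and sentences are processed in a canonical
(record, sentence) order, so training is deterministic and independent of
input order.

## The synthetic corpus generator

Real surveillance records are confidential, so the generator emulates
their statistical shape: records of log-normally distributed length
around a configurable mean of 1900 words (the era means of the motivating
corpus were roughly 1400 and 2450), per-criterion sentence prevalence
defaulting to 2% for ASD-labeled records (within the reported 0.5–5%
band) and one third of that for non-ASD records, an ASD fraction of 0.55,
and biennial collection years 2000–2010.

Positive sentences are instantiations of the actual packaged patterns —
sampled trigger terms, filler tokens within gap budgets, optional arcs
included with probability one half — so recall on planted data is
decidable by construction; each one is verified at generation time to
yield exactly one annotation with exactly the recorded gold span.
Distractor sentences are built from a filler vocabulary disjoint from
every lexicon token and therefore cannot match anything. Near-miss
sentences exercise false positives the way real notes do: half are
pattern-completing fragments embedded in scrambled filler and excluded
from gold (the analogue of accidental matches to nonsensical fragments),
half reuse isolated lexicon terms that complete no pattern (verified).
The pattern-completing half is what makes precision degrade below 1.0
when `near_miss_rate > 0` while recall on planted sentences stays 1.0 —
isolated terms alone can never trip a two-arc pattern, so a purely
isolated-term notion of "near miss" would leave precision pinned at 1.0
and exercise nothing.

What passing on synthetic data does *not* show: robustness to negated
mentions, coreference, cross-sentence context, section headers,
misspellings or genuinely novel phrasings — real clinical prose is none
of the generator's business, and recall on real records is bounded by
lexicon and pattern coverage, not by the engine.

## Aggregation choices

Records with fewer than 40 characters of text (about ten words — too
short to hold a complete annotation) are dropped; the cutoff is
inclusive (exactly 40 characters is retained) and configurable.
Per-record criterion counts are normalized by the record's word count
(alphanumeric tokens), so longer records do not inflate counts; the
normalization divides *annotation* counts, while the distinct-criteria
summary (0–12) is reported separately. Group means are taken per
(surveillance year, case status); unknown statuses form their own group.

## Problem sizes and numerical checks

The test suite and the acceptance script run the matcher against a
brute-force arc-assignment enumerator on 500+ random (pattern, sentence)
cases (≤4 lexicon arcs, gap budgets ≤5, sentences ≤12 tokens), recover
planted annotations on a 100-record clean corpus at both evaluation
levels, degrade precision on a 40-record near-miss corpus, and train the
baseline on 2000 separable sentences — sizes chosen to exercise every
code path at interactive run times. Group means are checked against a
naive two-pass oracle at 1e-12; F-measure identities at 1e-12; binomial
prevalence recovery at three standard errors.

## Known limitations

* No negation or hedge handling: "no eye contact concerns" will still
  match an impairment pattern. This is the single largest source of
  potential false positives on real text.
* The packaged ruleset is a faithful seed (every published term and
  pattern, plus reconstructed templates), not a replica of the original
  104-pattern inventory; absolute recall on real records is therefore not
  comparable to the published figures.
* The coarse tagger and suffix lemmatizer are intentionally small;
  domain-specific abbreviations and misspellings are out of scope.
* Criterion extraction stops short of case-status logic (the DSM's
  "6 or more items from …" rule): extracted criteria are inputs to, not a
  replacement for, case review.
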