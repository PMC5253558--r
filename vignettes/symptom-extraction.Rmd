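---
title: "Extracting SMI symptoms from clinical text: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting SMI symptoms from clinical text}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smisym)
```

## The extraction model

`smisym` treats symptom extraction as per-sentence binary classification.
A **candidate instance** of a symptom construct is a sentence containing one
of its keyword patterns; for constructs whose keyword is too generic on its
own (`speech*`, `mood`, `withdraw*`), a **modifier** term must additionally
occur within eight words of the keyword (*mandatory* mode), while for others
a modifier merely subtypes the mention (*optional* mode, e.g. `audit*` for
hallucinations). The eight-word window counts word tokens — tokens
containing at least one letter or digit — between the nearest edges of the
keyword and modifier spans, in either direction, within one sentence.
Punctuation tokens do not count: clinical text is punctuation-heavy and
counting commas would shrink the window arbitrarily. The window never
crosses a sentence boundary because the sentence is the classification unit.

The shipped lexicon has 50 constructs in five domains (positive, negative,
disorganisation, manic, catatonic). Per-construct status flags record how
each is handled downstream: 43 receive statistical models, one (mutism) is
reliable on the keyword alone, two (catalepsy, echopraxia) are rare enough
to review by hand, and four (loosening of associations, stereotypy, low
mood, poor motivation) are excluded because their keywords are hopelessly
ambiguous in routine text — "association" and "motivation" occur constantly
in non-symptom senses, and "mood" sits next to the distinct construct of
*affect* in mental-state examinations. Two editions ship: `table1_verbatim`
(the keyword table exactly as printed, including `hallucinate*` and
`flight of idea`) and `curated` (default), which widens those two stems to
`hallucinat*` and `flight of idea*` because the worked annotation examples
themselves use the wider stem; the choice is logged in the lexicon files.
Matching is case-insensitive throughout, and two run-together keyword cells
were split into alternatives (`ftd` | `thought disorder`, `mute` |
`mutism`). "Catatonic syndrome" carries no published domain assignment and
is placed in the catatonic domain as an editorial decision flagged in the
file. Excluded constructs ship with an empty domain; `domain_of()` refuses
them rather than inventing a grouping.

Within one construct, overlapping keyword hits are resolved
leftmost-longest — one instance per locus — but hits from *different*
constructs sharing a keyword are all kept (a sentence with "speech" is a
candidate for both poverty of speech and pressured speech until modifiers
and classifiers disambiguate). Disambiguation between, say, elevated mood
and low mood over the shared keyword "mood" is deliberately left to each
construct's classifier, not the matcher.

## Context rules

The rules arm is a ConText-style engine: trigger phrases assert negation,
experiencer or temporality over a scope that runs from a forward trigger to
the end of the sentence, or from the sentence start to a backward trigger,
in both cases cut at termination terms ("but", "however", …). A property
applies to an instance iff the keyword span lies inside a scope.
Pseudo-negation phrases ("no increase", "not only") block negation triggers
inside their span. The default scope has no token-count cap: since the
sentence is the classification unit, a sentence-bounded scope is the
natural choice, and termination terms handle intra-sentence contrast.

The shipped base table was initialised from the published ConText/NegEx
term lists, re-typed as an editable TSV, plus screening-verb hypothetical
phrases ("examined the patient for", "monitor for") that mental-state
documentation uses for not-yet-observed symptoms. Because those published
lists were written for US medical English, a separate British-English
overlay ("nil", "denies any", "not elicited") ships **off by default**:
keeping the base table faithful to the published lists makes the rules arm
reproducible, while the overlay is an explicit, versioned deviation.

`context_only_label()` is the rules-only decision: positive iff not
negated, experiencer patient, temporality not hypothetical. Historical
mentions remain positive — a previously documented symptom is still a
documented symptom — while hypothetical/screening contexts are negative.

## The hybrid classifier

Per construct, a linear SVM (LibSVM via `e1071`) is trained over sparse
binary features: sentence unigrams and bigrams of word tokens, the matched
keyword string, position-indexed tokens and coarse POS tags within ±5
tokens of the keyword span, modifier presence and strings, and the three
context flags. A linear kernel is the standard choice for sparse
bag-of-words problems and keeps the weights interpretable; the part-of-speech
tagger is a small deterministic closed-class + suffix heuristic over a
coarse tagset, used only as a feature source — tags never gate matching.
The feature extractor is versioned (`bow-ctx-1`) and models refuse to
predict under a mismatched extractor version.

Hyperparameters: stratified, seeded 10-fold cross-validation grid-searches
the regularisation strength over {0.01, 0.1, 1, 10, 100}; the selection
metric is mean positive-class F1 across folds with ties broken towards the
smaller strength (stronger regularisation); the final model is refit on all
data. Fold assignment is stratified by label; document-level grouping of
sentences is not applied by default but the fold count is configurable.
With fewer than one instance per fold, training stops with an instruction
to reduce `config$n_folds` rather than silently degenerating.

**Margin filtering.** Records restate symptoms across visits, so recall
lost at one mention is often recovered at another; precision errors, by
contrast, propagate into cohort tables. The margin filter therefore demotes
positive predictions whose |decision value| falls below a threshold θ to
negative — abstention folds into the negative class because the evaluation
is binary and leaves no third bucket. `calibrate_margin()` sweeps candidate
thresholds at the observed decision values on held-out data and returns the
smallest θ reaching a target precision (default 0.85), reporting the recall
paid for it; an unreachable target returns the maximum observed decision
value with a warning, and a model that never predicts positive is a
calibration error. Precision and recall are non-monotone in θ only through
the discrete sweep, and the predicted-positive set itself shrinks
monotonically — a property the test suite asserts.

Undefined evaluation ratios (zero denominators) are reported as missing
values, never 0, and are excluded from cross-concept means/medians with a
footnote count: averaging in zeros would silently bias multi-concept
summaries downwards. Cohen's κ uses chance agreement from the raters'
marginal frequencies; the degenerate both-raters-constant case is reported
as κ = 1 with a flag. Because the aggregation used for a published average
of per-concept κ values is ambiguous, both the unweighted and the
instance-weighted mean can be formed from the per-concept reports.

## Cohort aggregation

A patient has a symptom iff at least one instance of it is labelled
positive in any of their documents. ICD-10 grouping: F20x, F25x and F31x
are the SMI families; two or more distinct families make "Multiple" (family
level, not 4-character level, since the reporting tables are family-level);
F32/F33 (excluding the psychotic-depression codes F32.3/F33.3), F40–F48 and
F60 with no SMI code form the non-SMI control; everything else —
including patients whose only qualifying code is an excluded one — is
Unclassified, dropped from crosstabs with a logged count so the two cohorts
stay disjoint by construction. Coverage percentages are rounded half away
from zero to integers, matching how such figures are conventionally
printed; the crosstab's Total row is recomputed as the column sum over the
five groups on every run.

## The synthetic corpus

No real clinical corpus can ship, so `generate_corpus()` emulates discharge
summaries mechanically: filler sentences (verified to contain no lexicon
keyword) interleaved with planted template sentences in five context
classes — affirmed, negated, hypothetical, other-experiencer, and
irrelevant-homograph plants that reuse a keyword in a non-clinical sense
("The rapport workshop meeting was rescheduled…"). Non-affirmed templates
are built around trigger phrases from the shipped tables, so the expected
rule behaviour holds by construction; the expected gold label is positive
iff the planted class is affirmed. Defaults, chosen once as plausible
reference conditions: 60 patients, 1–3 documents each, 0.8 expected
mentions per construct per document, context mix 50% affirmed / 20% negated
/ 10% hypothetical / 10% other-experiencer / 10% homograph, and a diagnosis
mix of 30% F20 / 5% F25 / 15% F31 / 10% Multiple / 40% non-SMI. All
randomness flows from one master seed, split into per-purpose streams
(patient assembly; per-document planting keyed by document index) so adding
a template class or concept does not shift unrelated draws.

The templates are deliberately stylised mental-state-examination phrasing,
not naturalistic prose. That is a feature: the generator exercises the
pipeline's mechanics — matching, windows, scopes, joins, calibration —
under known ground truth, and the resulting near-perfect classifier scores
say *nothing* about performance on real clinical language, with its
spelling noise, ellipsis, dialect and genuinely ambiguous mentions. The
generator also omits de-identification masks, section headers and OCR
artefacts. Benchmarks on it (e.g. `synthetic_benchmark()`: five constructs
spanning all modifier modes, 160 patients × 2 documents at 1.8 mentions per
construct, 60/20/20 train/calibration/test) demonstrate the expected
*qualitative* pattern — rules alone keep near-perfect recall but lose
precision to homographs; the hybrid arm buys precision at the 0.85
operating point — not quantitative performance claims.

## Numerical and degenerate-input choices

Character offsets are 0-based half-open and every sentence and token slices
back to its exact source substring, so instances are auditable against the
original document. Tokenization splits on whitespace and peels
leading/trailing punctuation into single-character tokens; hyphenated words
stay whole. Text with no terminal punctuation is one sentence; empty text
yields no sentences (not an error), while an empty lexicon file is an
error, not an empty lexicon. SVM decision values are re-oriented
empirically against the fitted machine (LibSVM's sign convention follows
label order in the data, not factor levels). Model artefacts are plain text
(weights TSV, YAML metadata at 15-digit precision, CV report CSV) and
reload to reproduce decision values to ~1e-12. Ties in the cost grid go to
the first (smallest) cost; `which.max` guarantees this because the grid
ascends.

## Known limitations

Single-site vocabulary assumptions are baked into the trigger tables;
cross-sentence context, coreference, section detection, uncertainty as a
separate class, temporal modelling of symptom course, and modifier-based
subclassification scoring are out of scope. The coarse POS tagger is
intentionally crude; richer taggers would change feature vectors but not
the pipeline's contracts. SNOMED identifiers are carried as annotations
only — no terminology-service expansion is attempted, by design, since
synonym broadening beyond clinician-documented phrasing increases
uncertainty about author intent.
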