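---
title: "Extracting mental-health disorder mentions from domestic-violence police narratives"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting mental-health disorder mentions from domestic-violence police narratives}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dvmh)
```

## The problem

Police forces record domestic-violence (DV) events as structured fields plus
free-text event narratives. The narratives routinely mention the mental
health of the people involved -- "the accused is suffering from
schizophrenia", "victim takes Valium", "POI has a history of depression,
self-harm, and suicidal tendencies" -- but the text is unstructured, noisy
(misspellings, informal abbreviations such as "vic" or "pinop"), and far too
voluminous for manual review. `dvmh` implements a knowledge-driven pipeline
that surfaces this information for surveillance and research:

1. **Gazetteer lookup.** Thirteen hand-curated dictionaries mark role
   anchors (POI, victim), linking vocabulary (forms of *be* and *have*,
   pattern verbs, history expressions, negators, family terms) and the four
   capture vocabularies that can constitute a mention: disorder terms,
   medication brand names, medication classes, and addictive substances,
   plus disorder adjectives ("schizophrenic").
2. **Rule matching.** Declarative lexical rules anchored on a role term
   match semifrozen expressions ("is suffering from", "has a history of",
   "takes") and capture the disorder slot, with negation exclusion and
   enumeration expansion.
3. **Standardization and mapping.** The captured surface form is
   standardized through the dictionary's canonical form (so "schitzophrenia"
   becomes "Schizophrenia") and mapped into an extended ICD-10 schema at up
   to three reporting levels.
4. **Narrative-level unification.** Duplicate (role, disorder) records are
   eliminated per narrative (or per event), because one narrative often
   repeats the same disorder many times.
5. **Aggregation and evaluation.** Deduplicated records are aggregated into
   corpus summaries (counts and percentages per role and ICD level) or
   scored against gold annotations with precision, recall and F-score.

Because real police narratives are access-restricted, the package also ships
a seeded synthetic-narrative generator with gold annotations
(`generate_corpus()`), which is what all shipped tests run on.

## Tokenization and sentence scope

`tokenize()` produces word tokens (alphanumeric runs, keeping internal
hyphens and apostrophes so "self-harm" and "doesn't" are single tokens) and
single-character punctuation tokens, with 0-based half-open character
offsets. Matching is case-insensitive via the case-folded token column.

Rules never match across sentence boundaries. `segment_sentences()` splits
after `.`, `!`, `?` and at newlines. The clause-local scope is a deliberate
design choice: the target patterns ("defendant suffers from ...") are
clause-local, and allowing matches to span sentences mostly manufactures
role-attribution errors. No Unicode normalization beyond what the input
already has is applied -- the narratives are plain English text.

## Dictionaries

`load_gazetteers()` reads one `.lst` file per dictionary: one entry per
line, optionally a tab-separated canonical form and `key=value` attributes.
Matching (`match_gazetteers()`) is leftmost-longest *within* each dictionary
(the multiword entry "suicidal tendencies" suppresses the shorter "suicidal"
it covers), while matches from different dictionaries may overlap freely --
a role anchor and a disorder term must coexist in one clause.

The original dictionary contents were never published, so the shipped set is
a representative reconstruction: the disorder dictionary is seeded from
ICD-10 chapter-V rubric names plus reported example terms, unofficial
variants, and deliberate misspelling entries (`misspelling=true`). Sizes are
therefore configurable facts about this reconstruction, not invariants --
the manifest (`gazetteer_manifest()`) reports what is actually loaded.
There is **no fuzzy matching at runtime**: misspellings are matched only if
they are listed, which is also why the generator only injects
gazetteer-listed misspellings by default.

## Rule semantics

Rules are declarative blocks (see `dv_rules_path()` for the shipped file):

```
rule poi_verb_disorder
role POI
pattern lookup(poi) not(negation)[0,1] lookup(be)[0,1] lookup(verbs)
        literal(from)[0,1] literal(with)[0,1] not(negation)[0,2]
        capture(mental_disorder|drug_addiction)
```

Element kinds are `lookup(dict)`, `capture(dict)` (exactly one per rule,
restricted to the disorder/medication dictionaries), `literal(word)`,
`not(dict)` (one token *not* covered by the named dictionary) and `any`;
quantifiers are `?` or `[m,n]`.

Three semantics matter most:

* **Negation is window exclusion, not a separate pass.** Gaps between the
  anchor and the capture slot are `not(negation)` windows: "POI does not
  suffer from depression" cannot be bridged, so the rule simply does not
  fire. Windows are capped at 3 tokens, favoring precision over recall.
* **The capture binds to the earliest disorder slot.** Among all ways a
  pattern can complete from a given anchor, the match whose capture starts
  earliest wins (windows are lazy). This matters for enumerations:
  "suffering from schizophrenia and mental health problems" must capture
  "schizophrenia" and let the enumeration expander collect the rest, rather
  than letting the window swallow the first disorder.
* **Enumeration expansion.** After a capture, repeated
  {comma | "and" | comma+"and"} + disorder-lookup groups each emit a
  mention with the rule's role; expansion stops at the first token that is
  neither separator nor disorder lookup ("POI has depression today and
  left" yields only depression).

All rules apply independently; per rule, overlapping candidates resolve
leftmost-longest; identical (role, span, canonical) emissions are reported
once under the lexicographically smallest rule id; output order is
deterministic (span start, role, rule id). A sentence matched by both a POI
rule and a victim rule yields both mentions -- events can genuinely involve
both roles, and no arbitration heuristic is attempted.

The original rule inventory is unpublished; the shipped set is generated
compositionally as {role anchor} x {linking template} from the quoted
pattern fragments, eight templates per role. Rule counts are configuration,
not parity claims. The family dictionary ships and is loadable/matchable,
but no default rule consumes it: extracting third-party (relative, witness)
mentions was explicitly declined to protect precision, and no published
pattern uses it. The `*_due_to` rules are deliberately kept although they
reproduce a documented role-misattribution failure ("... violent with the
victims due to her alcoholism" yields a victim mention); see
`adversarial_suite()`.

## ICD mapping schema

The schema is two editable TSV tables: categories with parent links
(level 1, 2, 3) and term groups (canonical name to category). Level 1 has
exactly 26 categories: 18 ICD-10-derived groups plus 8 custom additions
(four psychotropic-medication classes, drug prescription abuse, substance
abuse (unspecified), traumatic brain injury, unspecified drug-induced
disorders). Mapping assigns the deepest category whose term group contains
the canonical name and fills ancestors backward; fourth-level ICD rubrics
(e.g. "Intermittent explosive disorder") are stored directly as level-3
categories, the usual reporting merge. Names carrying a generic marker
("mental", "psychiatric", "psychological") but no term-group hit fall back
to the level-1 category "Unspecified mental disorder"; anything else raises
an unmapped-term error or a QC report (`map_records(on_unmapped =
"report")`) -- never a silent drop.

Two conventions worth making explicit:

* Medication mentions map only into the four medication categories; a
  medication never implies a disorder diagnosis.
* "Mood stabilizer" has no clean home among the four medication classes; it
  is mapped to `Medications-antipsychotics`, the closest clinical overlap.

The deeper levels are likewise reconstructions (the original four-level
table is unavailable): level-2/3 membership follows ICD-10 chapter-V rubric
structure seeded with every category the reporting tables name.
`validate_schema()` enforces the structural invariants (unique names per
level, complete parent chains, collision-free term groups) and reports the
actual counts.

Deduplication keys on (role, canonical disorder) -- not on the level-1
category -- so distinct disorders under one category survive unification.

## Metrics and display rounding

`evaluate_extractions()` works on unique (narrative, role, canonical)
triples: precision `100*TP/(TP+FP)`, recall `100*TP/(TP+FN)`, F-score the
harmonic mean. Undefined cases (zero denominators) return `NA` with a
warning rather than a silent zero. Inter-annotator `absolute_agreement()` is
operationalized as intersection-over-union of annotation triples; a mean
directed-overlap alternative is selectable, since "absolute agreement rate"
admits both readings.

Full precision is kept internally; display rounding is a separate step
(`fmt_metric()`), at one decimal by default. Published evaluation tables in
this field are inconsistent about the last digit -- some cells match
round-half-up, others truncation -- so both modes are provided; half-up is
the default. Corpus summary percentages (`summarize_corpus()`) are
`100 * category count / role-level total`, rounded half-up to two decimals,
with the role-level total being the number of records mapped at that level
for that role (a record lacking level-3 detail counts at levels 1-2 only).

## The synthetic generator

`generate_corpus()` assembles narratives from role anchors (including
abbreviations), eight linking templates mirroring the rules' semifrozen
expressions, disorder/medication terms sampled from the gazetteers,
optional gazetteer-listed misspellings, optional negation (negated plants
produce *no* gold record), optional enumerations of 2-3 distinct disorders,
and distractor sentences with no anchor-disorder pair. Gold is defined at
the deduplicated (narrative, role, canonical) triple level -- the same unit
the evaluator uses.

Default calibration, chosen once to emulate the qualitative shape of a
large DV corpus: 13.2% of events mention the POI, 3.6% the victim, 1.0%
both (so ~15.8% of events carry any mention and POI mentions outnumber
victim mentions roughly 4.7:1); 1-3 narratives per event; negation 0.10,
enumeration 0.15, misspelling 0.10, medication 0.15, distractor rate 0.70.
These are calibration defaults for realistic fixtures, not claims about any
particular corpus.

What passing tests on this generator do and do not show: under clean
conditions (`p_negation = 0`, in-vocabulary misspellings) the pipeline
recovers the gold standard exactly -- precision = recall = 100% on 10,000
events -- which validates the *mechanics* (role attribution, negation,
enumeration, standardization, mapping, dedup). It says nothing about recall
on real police prose, whose unseen phrasings, typos outside the gazetteers,
and anchor-free mentions are exactly what the documented false negatives
look like. The `adversarial_suite()` keeps those documented failure modes
(two expected false positives, three expected misses) under regression so
they are not silently "fixed" or regressed.

## Numerical and engineering choices

* Character offsets are 0-based half-open; sentence spans are 1-based
  half-open token-index ranges. Both are asserted by property tests on
  random strings.
* Rule matching backtracks over quantifier counts; sentences are short, so
  exhaustive completion enumeration is cheap. Candidate starts are indexed
  by the rule's first element, so cost scales with the number of role
  anchors, not sentence length.
* Ties between rules on the same span: smallest rule id wins, purely for
  provenance stability.
* Test and acceptance problem sizes: end-to-end recovery and prevalence
  calibration run on 10,000 events (about a minute of extraction); the
  matcher-vs-oracle property uses 1,000 random instances; smaller unit
  fixtures use 50-500 events.
* `round_half_up()` adds a 1e-9 epsilon before flooring to absorb binary
  representation error (0.145 * 10 is slightly below 1.45).

## Known limitations

* No coreference or anaphora: "her alcoholism" attributes to the nearest
  matching anchor pattern, which is the documented misattribution mode.
* No fuzzy matching: out-of-vocabulary misspellings are missed by design;
  the generator can emit them (`p_misspelling` with custom dictionaries) to
  measure the degradation.
* No third-party roles (witnesses, children, relatives) and no
  machine-learned components; the pipeline is precision-first by design.
* Validity of the mentions themselves (police-recorded, not clinician
  diagnoses) is out of scope.
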