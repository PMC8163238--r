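---
title: "mirlit: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mirlit: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirlit)
```

## The problem and the approach

Most experimentally established facts about microRNAs — which gene a
miRNA targets, whether it marks a disease or its outcome, whether its
level rises in patient serum — are reported in abstract text and
scattered across tens of thousands of papers. `mirlit` extracts these
facts with *rules*: closed trigger inventories, dictionary lookups and
bounded-window patterns. Rules trade recall on creative phrasings for
three properties that matter in a curation-support tool: every output is
traceable to a named rule and an evidence sentence, behavior is
deterministic, and the system runs offline on commodity hardware.

The pipeline is document-centric. An abstract becomes a document with
exactly one title, an ordered sentence list (0-based, half-open
code-point offsets; slicing the concatenated title + abstract text with
a sentence's offsets reproduces its text exactly), a list of typed,
offset-anchored, ontology-normalized entity mentions, and a list of
relations that reference those mentions. Documents serialize losslessly
to one-line JSON records; a corpus is a JSON-lines file plus rebuildable
inverted indices.

## Entity recognition

**miRNA mentions** are found by a regular-expression grammar over the
dialects seen in Medline text (`miR-21`, `miRNA-21`, `microRNA 21`,
`hsa-miR-17-5p`, `let-7b`, en-dash and space separators, OCR-split
paralog letters like `miR-30 c`). Enumerations distribute their shared
prefix (`miR-19a/b` → miR-19a, miR-19b; `miR-10a/10b` → both), with each
expanded item anchored at its own span. Normalization to a family
identifier applies, in order: case folding, dash/space repair, species
prefix stripping, head-token mapping to `mir` (or `let`), arm-suffix
stripping (`-5p`/`-3p`), genomic-copy stripping after a paralog letter
(`mir-125b-1` → `mir-125b`). The function is idempotent and never
collapses paralog letters, so `mir-18a` and `mir-18b` remain distinct
families — the distinction matters when reconciling expression evidence
across papers. Cluster notations (`miR-17-92`) are detected and flagged
`cluster` but deliberately excluded from family normalization: the
grammar cannot know which member the author meant, and fabricating
family semantics would contaminate downstream counts. Mentions that fail
normalization are kept and flagged `unmapped`; nothing is silently
dropped.

**Dictionary entities** (genes, diseases, processes, fluids,
transporters) use exact case-insensitive matching after whitespace
normalization — no fuzzy matching, by design: "closest match" is
operationalized as the longest exact surface match so that behavior is
reproducible and testable. Matching is token-boundary-respecting,
longest-match-wins and non-overlapping; equal-length ties resolve by the
fixed class priority GENE > DISEASE > PROCESS > FLUID > TRANSPORTER,
then by position. The process dictionary combines GO biological-process
and Pathway Ontology names/synonyms with terms mined from text by the
cue-plus-list pattern ("cellular processes such as X, Y and Z" emits X,
Y, Z); mined terms that exactly match an ontology surface inherit its
identifier, the rest get stable `MINED:` slugs. Fluids normalize to
BRENDA tissue ontology IDs when an exact name/synonym exists, else they
are flagged `unmapped` with a slug. MeSH→DOID mapping scans Disease
Ontology `xref` lines and keeps *all* DOIDs citing a MeSH ID (no
arbitration), reporting unmapped IDs separately.

## The pattern engine

All extractors share one abstraction: a parse graph whose tokens are
maximal non-whitespace runs tiling the sentence. Two compliance levels
exist. Level A attaches arcs from a user-supplied dependency-parser
backend and measures trigger–argument connection as undirected BFS path
length (bound: 4). Level B — the default, since no dependency parser is
available offline in this environment — is a linear chain, where the
same rules run with token-window semantics (bound: 8 tokens; 5 for the
precision-oriented extracellular patterns). The window defaults encode
"close textual proximity": large enough to clear a typical adverbial
("was significantly (P = 0.013) reduced"), small enough not to bridge
clauses. A rule is a trigger lemma set plus class-constrained slots; all
slot-filler combinations are returned deterministically. Lemma matching
uses a fixed inflection table generated from the trigger vocabulary
(s/es/ed/ing with e-drop, y→ies and consonant doubling), not a
statistical lemmatizer.

Three cross-cutting guards:

* **Negation** — a negation token (`not`, `no`, `neither`, `fail(ed)`,
  `never`, `cannot`) within three tokens before a trigger suppresses the
  match.
* **Coordination** — a slot that matched one mention also accepts
  same-class mentions reachable through comma/"and" chains, so "suppressed
  ... p-AKT, EZH2, EGFR, BMI1 and XIAP" yields five relations even though
  the last conjunct is beyond the raw window.
* **Argument-type separation** — trigger and aspect-keyword tokens lying
  *inside* an entity mention never fire ("response" inside the process
  mention "inflammatory response" is an argument, not a treatment cue;
  "activated" inside "mitogen activated protein kinase signaling
  pathway" is not a regulation trigger). This rule fell out of
  synthetic-corpus diagnostics and is the package's reading of
  separating disease aspects by the type of the arguments.

## Relation families

**miRNA–gene.** Direct-target triggers (the lemma *target*, or *bind*
with a 3'UTR token nearby) produce `MIRNA_TARGET` regardless of argument
order. Generic regulation triggers (positive: induce, increase,
upregulate, enhance, promote; negative: suppress, inhibit, repress,
downregulate, reduce, silence, attenuate) produce `MIRNA_GENE` or
`GENE_MIRNA` depending on which class is the agent; under level B the
mention preceding the trigger is the agent, and a passive cue
(be-form before, "by" after) swaps roles. Relations deduplicate per
(family, miRNA family, gene id, sentence); when both a target trigger
and a regulation trigger fire on one pair, only `MIRNA_TARGET` survives
(specificity wins). Target polarity defaults to negative — miRNA
targeting represses — unless an explicit positive trigger co-occurs on
the pair; the default reflects the biology, not the text, and is
recorded as such.

**miRNA–process.** The same engine with process slots and three
connection strengths: regulation (signed), involvement (involve,
contribute, mediate, play, confer, implicate, participate) and
association (associate, correlate, link, relate).

**miRNA–disease roles.** Copular "is_a" patterns (`is/are/as`, or the
verbs act/serve/emerge/represent) classify the complement head noun:
marker/biomarker/indicator/predictor → BIOMARKER (a "diagnostic and
prognostic marker" is *one* BIOMARKER relation; the qualifier text is
kept in the rule id, mirroring an interface that groups both under one
tab); *target* qualified by therapeutic/drug/anticancer or followed by
"for (the) treatment" → THERAPEUTIC_TARGET — the qualifier requirement
is what keeps "a direct functional target" in the gene family and out of
the disease family. Connection triggers plus keyword lexicons give
OUTCOME (survival, prognosis, outcome, recurrence, metastasis) and
TREATMENT (resistance, sensitivity, response, chemo-/radiosensitivity,
chemotherapy, radiotherapy, therapy, "radiation treatment"). OTHER fires
only for association/regulation with a disease mention when no specific
role fired for that miRNA and sentence. The disease argument resolves
same-sentence first, then the title, then the nearest prior sentence
with a disease mention, and the provenance is always recorded; when an
abstract has no disease mention at all the relation is kept with
provenance `"none"` rather than invented or dropped (the spec's
provenance enum has no value for this case; `"none"` makes the choice
auditable).

**Differential expression.** A comparative frame needs a direction word
(down: reduced, decreased, lower, downregulated, down-regulated; up:
elevated, increased, higher, upregulated, up-regulated, overexpressed —
unknown direction words never emit), used *predicatively*: a linking
verb within the six preceding tokens, or the inherently comparative
higher/lower. Without this guard, active-voice regulation ("TGF-β1
increased miR-34a expression in fibroblasts") would be mis-read as a
comparative statement. The frame further needs an "in <sample>" phrase
and/or an explicit comparison marker (compared to/with, versus, vs,
relative to, than). Sample and control phrases are captured verbatim
with leading determiners and numeric quantifiers trimmed ("in 10 out of
20 tumors" → "tumors") and control phrases cut at trailing adverbials
("controls over the entire study length" → "controls").

**Extracellular locations.** Step 1 (PROXIMITY, high precision) pairs an
miRNA with a fluid/transporter in the same sentence within a 5-token
window under restrictive shapes: location modifying the miRNA phrase
("seminal plasma miRNA, let-7b-5p", "serum miR-21", "<fluid> levels of
<mirna>", adjectives like "exosomal" mapping to their canonical
transporter), or "<mirna> in <fluid>". Step 2 detects patient-context
(PC) sentences ("serum of 18 patients", "patients with X", "samples
were collected from") and links each PC location to miRNAs mentioned in
expression/analysis statements (expression cues, or analyzed / measured
/ quantified / detected / profiled) in *other* sentences — the
conservative reading of "fluids sampled from the study's patients are
very likely connected to the miRNAs the paper measures". Linking only
through analysis sentences, rather than to every miRNA in the abstract,
is this package's explicit choice: it is the auditable proxy for a step
that is known to trade some precision for coverage. PC pairs never
duplicate proximity pairs, and the method tag is carried on every row so
users can filter by step.

## Store and queries

Three query modes over rebuildable inverted indices: miRNA-centric
(documents whose entities normalize to the queried family — any surface
dialect works as the query); context-centric boolean keyword queries
(AND/OR with parentheses, AND binding tighter; multi-word literals
require all their tokens), always intersected with documents containing
an miRNA cue token, i.e. `expr AND (miR OR miRNA OR microRNA)`; and
disease-centric queries that expand a DOID (or resolvable disease name)
to its name plus exact synonyms and delegate the OR-of-terms to the
context query. Tokenization keeps case-folded alphanumeric-plus-hyphen
runs so "miR-21" survives as one token. Aspect views flatten relations
into sortable tables; filtering is case-insensitive substring over all
columns including the normalized label, which is why filtering for
"PTEN" retains a row whose mention surfaced as "phosphatase and tensin
homolog".

## The synthetic corpus: what a green test establishes

The generator emits seeded abstracts from seventeen templates — one per
rule family variant (direct target, signed regulation in both
directions, gene→miRNA, four process connection types, biomarker,
therapeutic target, outcome, treatment, unspecific association, both
differential-expression directions, fluid proximity, and a two-sentence
patient-context pair) — with entities sampled from the bundled lexicons
and exactly one gold relation per quota item. Distractors are inserted
per document with probability `distractor_rate`: trigger-free
co-occurrence, negated triggers, and lookalike tokens ("the MIRROR
cohort"). Defaults are 200 documents, one templated relation each, and
distractor rates 0 and 0.3 in the acceptance checks; at seed 42 the
pipeline recovers the gold standard with precision = recall = 1.0 at
rate 0 and ≥ 0.95 at rate 0.3 (the suite asserts these; the current
build measures 1.0 in both settings, and the same holds at other seeds
tried during development).

What this does **not** establish: the templates paraphrase the sentence
shapes the rules were designed around, so perfect recovery demonstrates
internal consistency (rules fire where intended, guards block
distractors, normalization and scoring agree end-to-end), not recall on
the unbounded phrasing diversity of real Medline text. Statistical
realism of the language, multilinguality and corpus-scale counts are
explicitly out of scope. The worked-example suite complements this with
real printed sentences (including an OCR artifact and a typo) asserted
exactly; those sentences are reserved for the extractor test suites and
never fed to the generator.

## Numerical and degenerate-input choices

* Offsets: 0-based half-open Unicode code points everywhere; empty text
  splits to an empty sentence list; a 1-token sentence has 0 arcs.
* The sentence splitter keeps known abbreviations ("vs.", "e.g.",
  "Fig.") and lowercase continuations unsplit, except continuations that
  start a legitimate lowercase miRNA name ("miR-21 is ...").
* Scoring: precision is defined as 0 when predictions are empty but gold
  is not; both empty score 1. Extracellular pairs score
  method-agnostically. Matching keys are (pmid, family, normalized
  miRNA, normalized partner, role/direction where applicable).
* Determinism: no global RNG leakage from the generator (seed is set on
  entry, the caller's RNG state restored on exit); all extractors and
  queries are pure functions of their inputs with stable orderings.

## Known limitations

Level-B agent/theme assignment is positional and fails on clause-initial
themes; cross-sentence gene relations and coreference are out of scope;
the cancer-only disease lexicon is an input, not a hard-coded
restriction (the role extractor is disease-agnostic); cluster mentions
are flagged rather than resolved; the bundled ontologies are synthetic
desk-scale subsets, so canonical IDs outside them fall back to slugs.
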