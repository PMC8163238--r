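# mirlit

Rule-based mining of microRNA relations from biomedical abstracts — a
fully offline, desk-scale R package for researchers who need structured
miRNA facts (who targets what, in which disease, measured where) pulled
out of free-text Medline abstracts with auditable rules instead of
black-box models.

## What it does

microRNAs (miRNAs) repress gene expression post-transcriptionally, and a
large share of what is known about them lives only in abstract text:
"miR-340 suppressed EZH2", "miR-122 is a prognostic marker for HCC",
"serum miR-21 was elevated in patients versus controls". `mirlit`
re-implements a classic rule-based extraction stack as one library + CLI:

* **miRNA NER + normalization** — a regular-expression grammar over the
  common surface dialects (`miR-21`, `microRNA-21`, `hsa-miR-17-5p`,
  `let-7b-5p`, enumerations like `miR-19a/b`, OCR splits like
  `miR-30 c`), normalized to miRBase-style family IDs
  (`mir-17`, `let-7b`): case-fold, strip the species prefix and the
  `-5p`/`-3p` arm, drop genomic-copy numerals (`mir-125b-1` → `mir-125b`),
  keep paralog letters (`mir-18a` ≠ `mir-18b`).
* **Dictionary NER** for genes (NCBI Gene IDs), diseases (DOIDs),
  biological processes/pathways (GO/PW plus pattern-mined terms) and
  extracellular locations (BTO biofluids, transporter forms), with
  case-insensitive longest-match semantics.
* **Relation extraction** over a declarative trigger/slot pattern engine
  (token-window semantics by default; a dependency-parser backend can be
  plugged in):
  * miRNA–gene: `MIRNA_TARGET` (direct-target triggers),
    `MIRNA_GENE` (miRNA as regulator, signed) and `GENE_MIRNA`
    (regulators of miRNA expression, signed);
  * miRNA–process: regulation/involvement/association connections;
  * miRNA–disease roles: BIOMARKER and THERAPEUTIC_TARGET via copular
    "is a / acts as / serves as" patterns classified by the complement
    head noun, OUTCOME and TREATMENT via connection triggers plus aspect
    keyword lexicons, OTHER as the unspecific fallback;
  * differential expression: comparative frames
    (direction word + "in <sample>" + optional "compared to <control>"),
    with sample/control descriptors captured;
  * extracellular locations: high-precision same-sentence proximity
    patterns plus patient-context (PC) sentence linking across
    sentences.
* **A corpus store**: JSON-lines persistence of the document-centric
  schema (one title, many sentences/entities/relations), inverted
  indices, miRNA-centric / boolean context / disease-centric (DOID
  synonym-expanded) queries, aspect views with filtering and sorting,
  CSV/JSON export.
* **A seeded synthetic-abstract generator** with gold annotations for
  every relation family plus distractors (trigger-free co-occurrence,
  negated triggers, lookalike tokens such as "the MIRROR cohort"), and a
  precision/recall/F1 scorer — so the whole pipeline is testable with no
  downloads.

## Worked example

```r
library(mirlit)
lex <- default_lexicons()
doc <- abstract_document("25831237", "",
  paste("Mechanistic studies disclosed that, miR-340 over-expression",
        "suppressed several oncogenes including p-AKT, EZH2, EGFR, BMI1 and XIAP."))
doc <- extract_relations(annotate_document(doc, lex))
relations_table(list(doc))[, 1:6]
```

prints

```
      pmid sentence_index relation_family role_or_direction mirna_id partner_id
1 25831237              0      MIRNA_GENE          negative  mir-340       1956
2 25831237              0      MIRNA_GENE          negative  mir-340        207
3 25831237              0      MIRNA_GENE          negative  mir-340       2146
4 25831237              0      MIRNA_GENE          negative  mir-340        331
5 25831237              0      MIRNA_GENE          negative  mir-340        648
```

one signed miRNA→gene regulation per conjoined gene (the trigger
"suppressed" distributes over the list; partner ids are NCBI Gene IDs —
1956 = EGFR, 207 = AKT1, 2146 = EZH2, 331 = XIAP, 648 = BMI1; the
evidence sentence is carried on every row).

End-to-end on synthetic data:

```r
gen  <- generate_corpus(synth_config(seed = 42, n_documents = 200))
docs <- process_corpus(gen$documents)
score_relations(predictions_table(docs), gen$gold)$overall
#> $precision [1] 1   $recall [1] 1   $f1 [1] 1   (200 gold relations)
```

## CLI

```sh
inst/cli/mirlit ingest  --in abstracts.tsv --out corpus.jsonl
inst/cli/mirlit extract --corpus corpus.jsonl --out extracted.jsonl
inst/cli/mirlit query   --corpus extracted.jsonl --mirna miR-21
inst/cli/mirlit view    --corpus extracted.jsonl --aspect gene_regulation --filter PTEN
inst/cli/mirlit export  --corpus extracted.jsonl --format csv --out relations.csv
inst/cli/mirlit stats   --corpus extracted.jsonl
```

Input dialects: 3-column TSV (`pmid \t title \t abstract`) or Medline
XML (`PubmedArticleSet`).

## Scope

Everything runs offline against bundled desk-scale fixture lexicons and
synthetic ontology subsets (`inst/extdata/`, labeled as such). No web
service, no live PubMed/BioPortal calls, no corpus-scale statistics —
see the methods vignette (`vignettes/mirlit-methods.Rmd`) for the model,
parameter defaults, and what the green tests do and do not establish.
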