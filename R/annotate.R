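# annotate: ties miRNA NER and dictionary matching together and runs all
# relation extractors over a document.

#' Bundle the lexicons used for annotation
#'
#' @param gene,disease,process,location `mir_lexicon` objects (any may be
#'   NULL to skip that entity class).
#' @return A list of class `mir_lexicon_set`.
#' @export
lexicon_set <- function(gene = NULL, disease = NULL, process = NULL,
                        location = NULL) {
  structure(list(gene = gene, disease = disease, process = process,
                 location = location), class = "mir_lexicon_set")
}

#' Load the bundled desk-scale fixture lexicons
#'
#' Small cancer-focused dictionaries shipped under `inst/extdata`: a gene
#' symbol table (NCBI Gene IDs), a cancer lexicon keyed to DOIDs, GO/PW
#' subsets plus mined process terms, and biofluid/transporter lists with a
#' BTO subset.  These are synthetic desk-scale subsets for testing and
#' examples, not full ontologies.
#'
#' @return A `mir_lexicon_set`.
#' @export
default_lexicons <- function() {
  p <- function(f) system.file("extdata", f, package = "mirlit",
                               mustWork = TRUE)
  mined <- readLines(p("process_extra.txt"), warn = FALSE, encoding = "UTF-8")
  mined <- trimws(mined[nzchar(trimws(mined)) & !startsWith(mined, "#")])
  tr <- utils::read.delim(p("transporters.tsv"), header = FALSE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "#", fileEncoding = "UTF-8")
  names(tr) <- c("surface", "canonical")
  fl <- readLines(p("fluids.txt"), warn = FALSE, encoding = "UTF-8")
  fl <- trimws(fl[nzchar(trimws(fl)) & !startsWith(fl, "#")])
  lexicon_set(
    gene = build_gene_lexicon(p("genes.tsv")),
    disease = build_disease_lexicon(p("diseases.tsv")),
    process = build_process_lexicon(p("go_subset.obo"), p("pw_subset.obo"),
                                    mined),
    location = build_location_lexicon(fl, tr, p("bto_subset.obo")))
}

#' Annotate a document with entity mentions
#'
#' Runs miRNA detection first (regex grammar, highest priority), then
#' dictionary matching for the remaining classes with longest-match-wins
#' overlap resolution.  miRNA mentions are normalized to family IDs;
#' surfaces that fail normalization (e.g. cluster notations) are kept and
#' flagged `unmapped` - no silent drops.
#'
#' @param doc A `mir_document`.
#' @param lexicons A `mir_lexicon_set` (default: bundled fixtures).
#' @return The document with its `entities` table filled.
#' @export
annotate_document <- function(doc, lexicons = default_lexicons()) {
  dict <- Filter(Negate(is.null),
                 lexicons[c("gene", "disease", "process", "location")])
  merged <- if (length(dict)) do.call(merge_lexicons, unname(dict)) else NULL
  rows <- list()
  for (k in seq_len(nrow(doc$sentences))) {
    si <- doc$sentences$index[k]
    text <- doc$sentences$text[k]
    mir <- detect_mirna_mentions(text)
    if (nrow(mir)) {
      fam <- normalize_mirna_or_na(mir$name)
      is_cluster <- grepl("cluster", mir$flags)
      flags <- mir$flags
      flags[is.na(fam) & !nzchar(flags)] <- "unmapped"
      flags[is.na(fam) & nzchar(mir$flags)] <-
        paste0(mir$flags[is.na(fam) & nzchar(mir$flags)], ",unmapped")
      rows[[length(rows) + 1L]] <- data.frame(
        entity_class = "MIRNA", sentence_index = si, start = mir$start,
        end = mir$end, surface = mir$surface,
        canonical_id = ifelse(is.na(fam), NA_character_, fam),
        canonical_label = mir$name, flags = flags, stringsAsFactors = FALSE)
    }
    if (!is.null(merged)) {
      blocked <- if (nrow(mir)) mir[, c("start", "end")] else NULL
      dm <- match_lexicon(text, merged, blocked = blocked)
      if (nrow(dm)) {
        rows[[length(rows) + 1L]] <- data.frame(
          entity_class = dm$entity_class, sentence_index = si,
          start = dm$start, end = dm$end, surface = dm$surface,
          canonical_id = dm$canonical_id, canonical_label = dm$canonical_label,
          flags = dm$flags, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    doc$entities <- empty_entities()
    return(doc)
  }
  ent <- do.call(rbind, rows)
  ent <- stable_order(ent, c("sentence_index", "start"))
  ent$id <- paste0("E", seq_len(nrow(ent)))
  doc$entities <- canon_df(ent, .entity_schema)
  validate_document(doc)
  doc
}

#' Run every relation extractor over an annotated document
#'
#' @param doc An annotated `mir_document`.
#' @return The document with its `relations` table filled (relation ids
#'   `R1..Rn` in deterministic order).
#' @export
extract_relations <- function(doc) {
  rel <- rbind(extract_gene_relations(doc),
               extract_process_relations(doc),
               extract_disease_roles(doc),
               extract_diffexpr(doc),
               extract_extracellular(doc))
  if (nrow(rel)) rel$id <- paste0("R", seq_len(nrow(rel)))
  doc$relations <- canon_df(rel, .relation_schema)
  validate_document(doc)
  doc
}

#' Annotate and extract over a whole corpus
#'
#' @param docs List of `mir_document`.
#' @param lexicons A `mir_lexicon_set`.
#' @return List of fully annotated documents.
#' @export
process_corpus <- function(docs, lexicons = default_lexicons()) {
  lapply(docs, function(d) extract_relations(annotate_document(d, lexicons)))
}
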