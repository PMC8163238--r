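# Shared fixtures: lexicons are loaded once per test run; documents are
# built in code (no binary fixtures).

fixture_lexicons <- local({
  lex <- NULL
  function() {
    if (is.null(lex)) lex <<- default_lexicons()
    lex
  }
})

# annotate + extract a single-abstract document
pipeline_doc <- function(abstract, title = "", pmid = "1") {
  extract_relations(annotate_document(
    abstract_document(pmid, title, abstract), fixture_lexicons()))
}

# random valid documents for property tests (entities/relations populated
# directly through the constructors, independent of the annotators)
random_document <- function(i) {
  n_sen <- sample(1:4, 1)
  sen_text <- replicate(n_sen, paste(
    sample(c("miR-21", "PTEN", "apoptosis", "serum", "cells", "in",
             "suppressed", "expression", "tumor", "levels"),
           sample(3:8, 1), replace = TRUE), collapse = " "))
  sen_text <- paste0(sen_text, ".")
  starts <- cumsum(c(0L, head(nchar(sen_text) + 1L, -1L)))
  sentences <- data.frame(index = seq_len(n_sen) - 1L, text = sen_text,
                          start = starts, end = starts + nchar(sen_text))
  entities <- NULL
  if (stats::runif(1) < 0.8) {
    k <- sample(1:3, 1)
    rows <- lapply(seq_len(k), function(j) {
      si <- sample(seq_len(n_sen), 1) - 1L
      txt <- sen_text[si + 1L]
      s <- sample(0:(nchar(txt) - 2L), 1)
      e <- min(nchar(txt), s + sample(1:6, 1))
      data.frame(id = paste0("E", j), entity_class = sample(
        c("MIRNA", "GENE", "PROCESS"), 1), sentence_index = si,
        start = s, end = e, surface = substr(txt, s + 1L, e),
        canonical_id = paste0("ID:", j), canonical_label = "x",
        flags = "", stringsAsFactors = FALSE)
    })
    entities <- do.call(rbind, rows)
  }
  relations <- NULL
  if (!is.null(entities) && nrow(entities) >= 2 && stats::runif(1) < 0.6) {
    relations <- data.frame(
      id = "R1", family = "MIRNA_GENE", mirna = entities$id[1],
      partner = entities$id[2], partner_type = "GENE",
      polarity = "negative", sentence_index = entities$sentence_index[1],
      rule_id = "t", evidence = "e", stringsAsFactors = FALSE)
  }
  new_document(paste0("P", i), "A title.", sentences,
               entities %||% mirlit:::empty_entities(),
               relations %||% mirlit:::empty_relations())
}

`%||%` <- function(a, b) if (is.null(a)) b else a
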