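store_corpus <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gen <- generate_corpus(synth_config(seed = 123L, n_documents = 50L,
                                          distractor_rate = 0.2,
                                          lexicons = fixture_lexicons()))
      cache <<- process_corpus(gen$documents, fixture_lexicons())
    }
    cache
  }
})

test_that("build_index is deterministic and rebuildable", {
  expect_identical(length(build_index(list())$documents), 0L)
  doc <- pipeline_doc("miR-21 suppressed PTEN in glioma cells.")
  idx <- build_index(list(doc))
  expect_identical(idx$mirna[["mir-21"]], "1")
  idx2 <- build_index(list(doc))
  expect_identical(idx, idx2)
})

test_that("token index agrees with a brute-force scan", {
  docs <- store_corpus()
  idx <- build_index(docs)
  probe_tokens <- c("mir-21", "serum", "patients", "suppressed", "pcr",
                    "quantified", "cancer")
  for (tok in probe_tokens) {
    brute <- sort(vapply(Filter(function(d)
      tok %in% unlist(lapply(c(d$title, d$sentences$text),
                             mirlit:::index_tokens)), docs),
      function(d) d$pmid, ""))
    expect_identical(sort(idx$tokens[[tok]] %||% character(0)), brute)
  }
})

test_that("query_mirna returns exactly the documents with that family", {
  docs <- store_corpus()
  idx <- build_index(docs)
  expect_identical(query_mirna(idx, "mir-99999")$pmids, character(0))
  fam <- names(idx$mirna)[1]
  res <- query_mirna(idx, fam)
  expect_true(length(res$pmids) > 0)
  brute <- sort(vapply(Filter(function(d)
    fam %in% d$entities$canonical_id[d$entities$entity_class == "MIRNA"],
    docs), function(d) d$pmid, ""))
  expect_identical(res$pmids, brute)
  expect_true(all(res$pmids %in% names(idx$documents)))
})

test_that("query_mirna normalizes surface dialect queries", {
  doc <- pipeline_doc("microRNA-21 suppressed PTEN in glioma cells.")
  idx <- build_index(list(doc))
  expect_identical(query_mirna(idx, "mir-21")$pmids, "1")
  expect_identical(query_mirna(idx, "hsa-miR-21-5p")$pmids, "1")
})

test_that("query_context applies the miRNA-cue intersection", {
  d1 <- pipeline_doc("miR-21 suppressed PTEN in glioma.", pmid = "a")
  # document with the keyword but no miRNA cue token
  d2 <- extract_relations(annotate_document(
    abstract_document("b", "", "PTEN is mutated in glioma."),
    fixture_lexicons()))
  idx <- build_index(list(d1, d2))
  res <- query_context(idx, "PTEN")
  expect_identical(res$pmids, "a")
})

test_that("boolean semantics agree with a brute-force evaluation", {
  docs <- store_corpus()
  idx <- build_index(docs)
  has_tok <- function(d, tok) tok %in% unlist(lapply(
    c(d$title, d$sentences$text), mirlit:::index_tokens))
  cue <- function(d) d$pmid %in% idx$mirna_cue_pmids
  words <- c("serum", "patients", "cancer", "suppressed", "biomarker")
  set.seed(42)
  for (i in 1:10) {
    w <- sample(words, 2)
    q_and <- sprintf("%s AND %s", w[1], w[2])
    q_or <- sprintf("%s OR %s", w[1], w[2])
    got_and <- query_context(idx, q_and)$pmids
    got_or <- query_context(idx, q_or)$pmids
    brute_and <- sort(vapply(Filter(function(d)
      has_tok(d, w[1]) && has_tok(d, w[2]) && cue(d), docs),
      function(d) d$pmid, ""))
    brute_or <- sort(vapply(Filter(function(d)
      (has_tok(d, w[1]) || has_tok(d, w[2])) && cue(d), docs),
      function(d) d$pmid, ""))
    expect_identical(got_and, brute_and)
    expect_identical(got_or, brute_or)
    # monotonicity: OR superset of AND; results subset of corpus
    expect_true(all(got_and %in% got_or))
    expect_true(all(got_or %in% names(idx$documents)))
  }
})

test_that("query_disease expands DOID names and synonyms", {
  docs <- store_corpus()
  idx <- build_index(docs)
  obo <- system.file("extdata", "doid_subset.obo", package = "mirlit")
  res <- query_disease(idx, "DOID:10534", obo)
  expect_identical(res$doid, "DOID:10534")
  expect_setequal(res$terms, c("stomach cancer", "gastric cancer"))
  # name input resolves to its DOID first
  res2 <- query_disease(idx, "stomach cancer", obo)
  expect_identical(res2$doid, "DOID:10534")
  expect_identical(res2$pmids, res$pmids)
  expect_error(query_disease(idx, "DOID:99999999", obo), "unknown disease")
})

test_that("aspect views carry normalized ids and filter by synonym label", {
  d <- pipeline_doc(
    "miR-21 suppressed phosphatase and tensin homolog in glioma cells.")
  idx <- build_index(list(d))
  rows <- aspect_view(mirlit:::index_result(idx, "1"), "gene_regulation")
  expect_identical(nrow(rows), 1L)
  expect_identical(rows$partner_id, "5728")
  # filtering by the primary symbol retains the synonym row
  expect_identical(nrow(filter_view(rows, "PTEN")), 1L)
  expect_identical(nrow(filter_view(rows, "ZZZNOPE")), 0L)
})

test_that("views: row counts, filter antitonicity, stable sort", {
  docs <- store_corpus()
  idx <- build_index(docs)
  res <- mirlit:::index_result(idx, names(idx$documents))
  for (aspect in c("gene_regulation", "process", "disease_roles",
                   "diffexpr", "extracellular")) {
    rows <- aspect_view(res, aspect)
    fams <- mirlit:::.aspect_families[[aspect]]
    n_rel <- sum(vapply(docs, function(d)
      sum(d$relations$family %in% fams), 0L))
    expect_identical(nrow(rows), n_rel)
    filt <- filter_view(rows, "mir")
    expect_lte(nrow(filt), nrow(rows))
  }
  rows <- aspect_view(res, "gene_regulation")
  srt <- sort_view(rows, "pmid")
  expect_identical(nrow(srt), nrow(rows))
  expect_true(!is.unsorted(srt$pmid))
  # stability: equal keys preserve original relative order
  rows$ord <- seq_len(nrow(rows))
  srt2 <- sort_view(rows, "family")
  for (f in unique(srt2$family))
    expect_false(is.unsorted(srt2$ord[srt2$family == f]))
})

test_that("summarize_counts matches generator ground truth", {
  expect_identical(summarize_counts(build_index(list()))$n_documents, 0L)
  gen <- generate_corpus(synth_config(seed = 9L, n_documents = 34L,
                                      distractor_rate = 0,
                                      lexicons = fixture_lexicons()))
  docs <- process_corpus(gen$documents, fixture_lexicons())
  s <- summarize_counts(build_index(docs))
  expect_identical(s$n_documents, 34L)
  # relation counts per family equal the gold bookkeeping
  gtab <- table(gen$gold$family)
  for (f in names(gtab))
    expect_identical(s$relations[[f]], as.integer(gtab[[f]]))
  expect_identical(s$unique_mirnas, length(unique(gen$gold$mirna)))
  # permutation invariance over document order
  s2 <- summarize_counts(build_index(rev(docs)))
  expect_identical(s2, s)
})
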