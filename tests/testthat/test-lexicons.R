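go_path <- system.file("extdata", "go_subset.obo", package = "mirlit")
pw_path <- system.file("extdata", "pw_subset.obo", package = "mirlit")
doid_path <- system.file("extdata", "doid_subset.obo", package = "mirlit")
bto_path <- system.file("extdata", "bto_subset.obo", package = "mirlit")

test_that("parse_obo reads stanzas, synonyms and xrefs", {
  obo <- parse_obo(go_path)
  apop <- Filter(function(t) t$id == "GO:0006915", obo)[[1]]
  expect_identical(apop$name, "apoptotic process")
  expect_true("apoptosis" %in% apop$synonyms$text)
  expect_identical(apop$synonyms$scope[apop$synonyms$text == "apoptosis"],
                   "EXACT")
  doid <- parse_obo(doid_path)
  gbm <- Filter(function(t) t$id == "DOID:3068", doid)[[1]]
  expect_true("MESH:D005909" %in% gbm$xrefs)

  bad <- withr::local_tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: GO:1"), bad)  # no name
  expect_error(parse_obo(bad), "unparseable OBO stanza")
})

test_that("build_process_lexicon combines ontology terms and mined terms", {
  # GO stanza with a synonym: 2+ surfaces, one GO id
  lex <- build_process_lexicon(go_path, pw_path)
  e <- lex$entries
  apo <- e[e$canonical_id == "GO:0006915", ]
  expect_true(all(c("apoptotic process", "apoptosis") %in% apo$surface))
  expect_identical(unique(apo$canonical_id), "GO:0006915")

  # mined term matching a GO name keeps the GO id, not a slug
  lex2 <- build_process_lexicon(go_path, pw_path,
                                mined_terms = c("cell death", "weird process"))
  e2 <- lex2$entries
  # the mined term that matches a GO name resolves to the GO id (the
  # duplicate surface collapses onto the ontology entry), never a slug
  expect_identical(unique(e2$canonical_id[e2$surface == "cell death"]),
                   "GO:0008219")
  expect_identical(e2$canonical_id[e2$surface == "weird process"],
                   "MINED:weird-process")
  # empty mined_terms -> ontology entries only
  expect_true(all(lex$entries$source %in% c("GO", "PW")))
})

test_that("mine_process_terms extracts cue-plus-list enumerations", {
  got <- mine_process_terms(
    "These miRNAs affect cellular processes such as migration, invasion and cell death in tumors.")
  expect_identical(got, c("migration", "invasion", "cell death"))
  expect_length(got, 3)

  expect_identical(mine_process_terms("No cue phrase in this sentence."),
                   character(0))
  expect_identical(mine_process_terms("processes including X and Y"),
                   c("X", "Y"))
})

test_that("mining -> lexicon -> matching closure re-detects mined terms", {
  src <- "It alters biological processes such as drug efflux, stemness and dormancy."
  mined <- mine_process_terms(src)
  expect_true(length(mined) >= 3)
  lex <- build_process_lexicon(go_path, pw_path, mined)
  hits <- match_lexicon(src, lex)
  expect_true(all(vapply(mined, function(m)
    any(tolower(hits$surface) == tolower(m)), logical(1))))
})

test_that("build_location_lexicon normalizes fluids to BTO", {
  lex <- build_location_lexicon(c("serum", "seminal plasma", "weirdfluid"),
                                character(0), bto_path)
  e <- lex$entries
  expect_identical(e$canonical_id[e$surface == "serum"], "BTO:0000133")
  expect_identical(e$canonical_id[e$surface == "seminal plasma"],
                   "BTO:0001078")
  expect_identical(e$flags[e$surface == "weirdfluid"], "unmapped")
  expect_true(all(e$entity_class == "FLUID"))
  # with transporters
  lex2 <- build_location_lexicon("serum",
                                 data.frame(surface = c("exosome", "exosomal"),
                                            canonical = "exosome"),
                                 bto_path)
  e2 <- lex2$entries
  expect_identical(unique(e2$canonical_id[e2$entity_class == "TRANSPORTER"]),
                   "exosome")
})

test_that("map_mesh_to_doid scans xrefs without arbitration", {
  res <- map_mesh_to_doid(c("MESH:D005909", "MESH:D999999",
                            "MESH:D008545"), doid_path)
  expect_identical(res$mapped[["MESH:D005909"]], "DOID:3068")
  expect_identical(res$unmapped, "MESH:D999999")
  expect_identical(res$mapped[["MESH:D008545"]], "DOID:1909")
  # an id cited by two DOIDs keeps both (construct in-memory)
  f <- withr::local_tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: DOID:1", "name: a", "xref: MESH:D1",
               "", "[Term]", "id: DOID:2", "name: b", "xref: MESH:D1"), f)
  res2 <- map_mesh_to_doid("MESH:D1", f)
  expect_identical(res2$mapped[["MESH:D1"]], c("DOID:1", "DOID:2"))
})

test_that("match_lexicon is longest-match, non-overlapping, deterministic", {
  lex <- new_lexicon(data.frame(
    surface = c("cell", "cell death", "apoptosis"),
    canonical_id = c("X:1", "GO:0008219", "GO:0006915"),
    entity_class = "PROCESS"))
  hits <- match_lexicon("Induction of cell death and apoptosis in cells", lex)
  expect_identical(hits$surface, c("cell death", "apoptosis"))
  expect_identical(hits$canonical_id[1], "GO:0008219")

  # exhaustive-span oracle: every reported span case-folds to a lexicon
  # surface and no shorter overlapping candidate is reported
  txt <- "cell death cell apoptosis celldeath"
  hits <- match_lexicon(txt, lex)
  surfaces <- tolower(gsub("\\s+", " ", hits$surface))
  expect_true(all(surfaces %in% lex$entries$surface))
  expect_false(any(duplicated(unlist(lapply(seq_len(nrow(hits)), function(i)
    seq(hits$start[i], hits$end[i] - 1L))))))  # spans never overlap
  # token-boundary guard: "celldeath" must not match "cell"
  expect_false(any(hits$start >= 26))
})

test_that("gene synonyms map to the same id and label", {
  lex <- fixture_lexicons()$gene
  hits <- match_lexicon("phosphatase and tensin homolog and PTEN", lex)
  expect_identical(unique(hits$canonical_id), "5728")
  expect_identical(unique(hits$canonical_label), "PTEN")
})

test_that("match_lexicon output never overlaps across random inputs", {
  lex <- merge_lexicons(fixture_lexicons()$gene, fixture_lexicons()$process)
  set.seed(99)
  vocab <- c("PTEN", "apoptosis", "cell", "death", "cell death", "EGFR",
             "random", "tokens", "in", "the")
  for (i in 1:25) {
    txt <- paste(sample(vocab, sample(4:12, 1), replace = TRUE),
                 collapse = " ")
    hits <- match_lexicon(txt, lex)
    if (nrow(hits) < 2) next
    spans <- unlist(lapply(seq_len(nrow(hits)), function(k)
      seq(hits$start[k], hits$end[k] - 1L)))
    expect_false(any(duplicated(spans)))
    expect_true(all(tolower(gsub("\\s+", " ", hits$surface)) %in%
                      lex$entries$surface))
  }
})
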