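test_that("process regulation distributes over conjoined processes", {
  d <- pipeline_doc(paste0(
    "microRNA-29b promotes high-fat diet-stimulated endothelial ",
    "permeability and apoptosis in apoE knock-out mice by down-regulating ",
    "MT1 expression."))
  rel <- d$relations[d$relations$family == "PROCESS", ]
  expect_identical(nrow(rel), 2L)
  expect_identical(unique(rel$relation), "regulation_positive")
  canon <- d$entities$canonical_id[match(rel$partner, d$entities$id)]
  expect_setequal(canon, c("MINED:endothelial-permeability", "GO:0006915"))
})

test_that("promoting a process is captured as positive regulation", {
  d <- pipeline_doc(
    "miR-221 was shown to target PTEN, promoting proliferation in GBM cells.")
  rel <- d$relations[d$relations$family == "PROCESS", ]
  expect_true(nrow(rel) >= 1L)
  expect_identical(unique(rel$relation), "regulation_positive")
  expect_identical(
    unique(d$entities$canonical_id[match(rel$partner, d$entities$id)]),
    "GO:0008283")
})

test_that("no process mention means no process relation", {
  d <- pipeline_doc("miR-21 suppressed PTEN in cells.")
  expect_identical(nrow(d$relations[d$relations$family == "PROCESS", ]), 0L)
})

test_that("is_a biomarker classification (argument-type separation)", {
  d <- pipeline_doc(paste0(
    "From a clinical point of view, our study emphasizes miR-122 as a ",
    "diagnostic and prognostic marker for HCC progression."))
  rel <- d$relations[d$relations$family == "DISEASE_ROLE", ]
  expect_identical(nrow(rel), 1L)
  expect_identical(rel$role, "BIOMARKER")
  expect_identical(rel$disease, "DOID:684")
  expect_identical(rel$disease_provenance, "same_sentence")
  expect_identical(
    d$entities$canonical_id[match(rel$mirna, d$entities$id)], "mir-122")
})

test_that("is_a therapeutic-target classification", {
  d <- pipeline_doc(paste0(
    "Our data suggest that miR-429 may serve as a potential anticancer ",
    "target for the treatment of HCC."))
  rel <- d$relations[d$relations$family == "DISEASE_ROLE", ]
  expect_identical(rel$role, "THERAPEUTIC_TARGET")
  expect_identical(rel$disease, "DOID:684")
})

test_that("outcome and treatment roles via connection triggers", {
  d <- pipeline_doc(
    "High miR-21 expression is associated with poor survival and poor therapeutic outcome.")
  rel <- d$relations[d$relations$family == "DISEASE_ROLE", ]
  expect_identical(rel$role, "OUTCOME")
  expect_identical(rel$disease_provenance, "none")

  d2 <- pipeline_doc(paste0(
    "The role of miR-181a in conferring cellular resistance to radiation ",
    "treatment was validated both in cell culture models and in mouse ",
    "tumor xenograft models."))
  rel2 <- d2$relations[d2$relations$family == "DISEASE_ROLE", ]
  expect_identical(rel2$role, "TREATMENT")
  expect_identical(
    d2$entities$canonical_id[match(rel2$mirna, d2$entities$id)], "mir-181a")
})

test_that("unspecific association with a disease yields OTHER per miRNA", {
  d <- pipeline_doc(paste0(
    "Altered expression of miR-21, miR-31, miR-143 and miR-145 is ",
    "related to clinicopathologic features of colorectal cancer."))
  rel <- d$relations[d$relations$family == "DISEASE_ROLE", ]
  expect_identical(nrow(rel), 4L)
  expect_identical(unique(rel$role), "OTHER")
  expect_identical(unique(rel$disease), "DOID:9256")
  mirs <- d$entities$canonical_id[match(rel$mirna, d$entities$id)]
  expect_setequal(mirs, c("mir-21", "mir-31", "mir-143", "mir-145"))
})

test_that("specific roles take precedence over OTHER, with deduplication", {
  d <- pipeline_doc(
    "miR-122 is a prognostic marker associated with hepatocellular carcinoma.")
  rel <- d$relations[d$relations$family == "DISEASE_ROLE", ]
  expect_identical(unique(rel$role), "BIOMARKER")
  # at most one relation per (mirna, disease, role, sentence)
  key <- paste(rel$mirna, rel$disease, rel$role, rel$sentence_index)
  expect_false(any(duplicated(key)))
})

test_that("disease falls back to title then nearest prior mention", {
  doc <- abstract_document("5", "MicroRNAs in glioblastoma.",
    "miR-21 acts as a prognostic marker in these patients.")
  d <- extract_relations(annotate_document(doc, fixture_lexicons()))
  rel <- d$relations[d$relations$family == "DISEASE_ROLE", ]
  expect_identical(rel$role, "BIOMARKER")
  expect_identical(rel$disease, "DOID:3068")
  expect_identical(rel$disease_provenance, "title")

  d2 <- pipeline_doc(paste(
    "Patients with breast cancer were enrolled.",
    "Serum samples were stored.",
    "miR-155 may serve as a promising biomarker in this cohort."))
  rel2 <- d2$relations[d2$relations$family == "DISEASE_ROLE", ]
  expect_identical(rel2$disease, "DOID:1612")
  expect_identical(rel2$disease_provenance, "nearest_prior")
})

test_that("differential-expression frames capture direction and phrases", {
  d <- pipeline_doc(paste0(
    "Extrapolation of this study to human primary HCCs revealed that ",
    "miR-122 expression was significantly (P = 0.013) reduced in 10 out ",
    "of 20 tumors compared to the pair-matched control tissues."))
  rel <- d$relations[d$relations$family == "DIFFEXPR", ]
  expect_identical(nrow(rel), 1L)
  expect_identical(rel$direction, "down")
  expect_identical(rel$sample_descriptor, "tumors")
  expect_identical(rel$comparison_descriptor, "pair-matched control tissues")
  expect_identical(
    d$entities$canonical_id[match(rel$mirna, d$entities$id)], "mir-122")
})

test_that("coordinated miRNAs share a differential-expression frame", {
  d <- pipeline_doc(paste0(
    "We found that levels of miR-30 c and miR-206 remained significantly ",
    "elevated in DMD patients relative to controls over the entire study ",
    "length."))
  rel <- d$relations[d$relations$family == "DIFFEXPR", ]
  expect_identical(nrow(rel), 2L)
  expect_identical(unique(rel$direction), "up")
  expect_identical(unique(rel$comparison_descriptor), "controls")
  mirs <- d$entities$canonical_id[match(rel$mirna, d$entities$id)]
  expect_setequal(mirs, c("mir-30c", "mir-206"))
})

test_that("incomplete frames and unknown direction words never fire", {
  # direction word with neither an in-phrase nor a comparison marker
  d <- pipeline_doc("miR-21 expression was significantly elevated.")
  expect_identical(nrow(d$relations[d$relations$family == "DIFFEXPR", ]), 0L)
  # unknown direction word
  d2 <- pipeline_doc(
    "miR-21 expression was strange in tumors compared with controls.")
  expect_identical(nrow(d2$relations[d2$relations$family == "DIFFEXPR", ]), 0L)
  # attributive active verb (no linking verb) does not open a frame
  d3 <- pipeline_doc("STAT3 increased miR-21 expression in fibroblasts.")
  expect_identical(nrow(d3$relations[d3$relations$family == "DIFFEXPR", ]), 0L)
})
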