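# rel_extracellular: pairing circulating miRNAs with biofluids and
# extracellular transporter forms.
#
# Step 1 (PROXIMITY) uses precision-oriented same-sentence patterns where
# the miRNA and the location are in close textual proximity.  Step 2
# (PATIENT_CONTEXT) detects patient-context sentences describing study
# subjects/samples and links their fluids to miRNAs measured elsewhere in
# the abstract.

# tokens allowed between a location mention and the miRNA it modifies
.prox_bridge <- c("mirna", "mirnas", "microrna", "micrornas", "mir",
                  "levels", "level", "expression", "of", "the", ",", "")

#' Extract proximity miRNA-location pairs (step 1)
#'
#' Patterns (all within a 5-token window, same sentence):
#' a location mention directly modifying an miRNA noun phrase
#' ("serum miR-21", "seminal plasma miRNA, let-7b-5p",
#' "<fluid> levels of <mirna>", "exosomal <mirna>"), and
#' "<mirna> in <fluid/transporter>".
#'
#' @param doc An annotated `mir_document` (needs MIRNA and FLUID /
#'   TRANSPORTER mentions).
#' @param window Token-window bound (default 5).
#' @return Relation rows with family `EXTRACELLULAR`, method `PROXIMITY`.
#' @export
extract_proximity_pairs <- function(doc, window = 5L) {
  out <- list()
  for (si in doc$sentences$index) {
    sen <- doc$sentences[doc$sentences$index == si, ]
    men <- doc$entities[doc$entities$sentence_index == si, ]
    mi <- which(men$entity_class == "MIRNA")
    li <- which(men$entity_class %in% c("FLUID", "TRANSPORTER"))
    if (!length(mi) || !length(li)) next
    graph <- build_parse(sen$text, sentence_index = si)
    toks_raw <- graph$tokens$token
    ranges <- lapply(seq_len(nrow(men)), function(i)
      mention_token_range(graph, men$start[i], men$end[i]))
    for (m in mi) for (l in li) {
      rm <- ranges[[m]]; rl <- ranges[[l]]
      if (any(is.na(rm)) || any(is.na(rl))) next
      gap <- if (rl[2] < rm[1] && rl[2] + 1L <= rm[1] - 1L)
               seq.int(rl[2] + 1L, rm[1] - 1L)
             else if (rm[2] < rl[1] && rm[2] + 1L <= rl[1] - 1L)
               seq.int(rm[2] + 1L, rl[1] - 1L)
             else integer(0)
      dist <- if (rl[2] < rm[1]) rm[1] - rl[2]
              else if (rm[2] < rl[1]) rl[1] - rm[2] else 0L
      if (dist > window) next
      between <- tolower(strip_punct(toks_raw[gap]))
      matched <- FALSE
      if (rl[2] < rm[1]) {
        # location modifies the miRNA phrase: all bridge tokens connective
        if (all(between %in% .prox_bridge)) matched <- TRUE
      } else if (rm[2] < rl[1]) {
        # "<mirna> in <fluid/transporter>"
        if ("in" %in% between &&
            all(between %in% c("in", "the", "a", "an", "human", "patient",
                               "circulating", "")))
          matched <- TRUE
      }
      if (!matched) next
      out[[length(out) + 1L]] <- data.frame(
        family = "EXTRACELLULAR", mirna = men$id[m], partner = men$id[l],
        partner_type = men$entity_class[l],
        location_class = men$entity_class[l], method = "PROXIMITY",
        sentence_index = si, mirna_sentence = si, location_sentence = si,
        rule_id = "excell.proximity", evidence = sen$text,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty_relations())
  rel <- do.call(rbind, out)
  canon <- entity_canonicalizer(doc)
  key <- paste(canon(rel$mirna), canon(rel$partner), sep = "\r")
  rel <- rel[!duplicated(key), , drop = FALSE]
  canon_df(stable_order(rel, c("sentence_index")), .relation_schema)
}

.pc_cues <- c(
  pc.fluid_of_patients = "\\b(?:of|from)\\s+(?:approximately\\s+)?\\d+\\s+(?:patients|subjects|individuals)\\b",
  pc.patients_with     = "\\bpatients\\s+with\\b",
  pc.samples_collected = "\\bsamples?\\s+(?:were\\s+|was\\s+)?(?:collected|obtained|taken)\\s+from\\b",
  pc.fluid_samples     = "\\b(?:serum|plasma|urine|blood|saliva|csf)\\s+samples?\\b",
  pc.patients          = "\\bpatients?\\b")

#' Detect patient-context (PC) sentences
#'
#' PC sentences describe the patients/samples involved in the study
#' ("serum of 18 patients", "patients with X", "samples were collected
#' from ...").  A PC sentence is linkable only when it contains an
#' extracellular-location mention.
#'
#' @param doc An annotated `mir_document`.
#' @return A data.frame: `sentence_index`, `cue` (first matching pattern
#'   id), `locations` (comma-joined location mention ids), `linkable`.
#' @export
detect_pc_sentences <- function(doc) {
  rows <- list()
  for (si in doc$sentences$index) {
    text <- doc$sentences$text[doc$sentences$index == si]
    hit <- NA_character_
    for (cue in names(.pc_cues)) {
      if (grepl(.pc_cues[[cue]], text, perl = TRUE, ignore.case = TRUE)) {
        hit <- cue; break
      }
    }
    if (is.na(hit)) next
    men <- doc$entities[doc$entities$sentence_index == si &
                        doc$entities$entity_class %in%
                          c("FLUID", "TRANSPORTER"), , drop = FALSE]
    rows[[length(rows) + 1L]] <- data.frame(
      sentence_index = si, cue = hit,
      locations = paste(men$id, collapse = ","),
      linkable = nrow(men) > 0, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(sentence_index = integer(), cue = character(),
                      locations = character(), linkable = logical(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

.analysis_lemmas <- c("analyze", "analyse", "measure", "quantify", "detect",
                      "profile")

# sentence indices containing an expression cue or analysis verb
analysis_sentences <- function(doc) {
  tab <- lemma_table(.analysis_lemmas)
  keep <- logical(nrow(doc$sentences))
  for (k in seq_len(nrow(doc$sentences))) {
    toks <- tolower(strip_punct(strsplit(doc$sentences$text[k],
                                         "\\s+")[[1]]))
    lems <- token_lemma(toks, tab)
    keep[k] <- any(toks %in% .expr_cues) || any(lems %in% .analysis_lemmas)
  }
  doc$sentences$index[keep]
}

#' Link patient-context fluids to analyzed miRNAs (step 2)
#'
#' Each linkable PC location is paired with every miRNA mention occurring
#' in an expression/analysis statement in a different sentence of the same
#' abstract.  Pairs already found by the proximity step are not
#' duplicated.
#'
#' @param doc An annotated `mir_document`.
#' @param pc Output of [detect_pc_sentences()].
#' @param proximity Proximity relations (used for deduplication); computed
#'   from `doc` when NULL.
#' @return Relation rows with family `EXTRACELLULAR`, method
#'   `PATIENT_CONTEXT`.
#' @export
link_pc_pairs <- function(doc, pc = detect_pc_sentences(doc),
                          proximity = NULL) {
  if (is.null(proximity)) proximity <- extract_proximity_pairs(doc)
  canon <- entity_canonicalizer(doc)
  seen <- paste(canon(proximity$mirna), canon(proximity$partner), sep = "\r")
  pc <- pc[pc$linkable, , drop = FALSE]
  if (nrow(pc) == 0) return(empty_relations())
  analysis <- analysis_sentences(doc)
  out <- list()
  for (k in seq_len(nrow(pc))) {
    loc_ids <- strsplit(pc$locations[k], ",", fixed = TRUE)[[1]]
    for (loc in loc_ids) {
      mi <- doc$entities[doc$entities$entity_class == "MIRNA" &
                         doc$entities$sentence_index %in%
                           setdiff(analysis, pc$sentence_index[k]), ,
                         drop = FALSE]
      if (nrow(mi) == 0) next
      for (r in seq_len(nrow(mi))) {
        key <- paste(canon(mi$id[r]), canon(loc), sep = "\r")
        if (key %in% seen) next
        seen <- c(seen, key)
        lc <- doc$entities$entity_class[doc$entities$id == loc]
        out[[length(out) + 1L]] <- data.frame(
          family = "EXTRACELLULAR", mirna = mi$id[r], partner = loc,
          partner_type = lc, location_class = lc,
          method = "PATIENT_CONTEXT",
          sentence_index = mi$sentence_index[r],
          mirna_sentence = mi$sentence_index[r],
          location_sentence = pc$sentence_index[k],
          rule_id = paste0("excell.pc[", pc$cue[k], "]"),
          evidence = doc$sentences$text[doc$sentences$index ==
                                          mi$sentence_index[r]],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(empty_relations())
  canon_df(stable_order(do.call(rbind, out),
                        c("location_sentence", "mirna_sentence")),
           .relation_schema)
}

#' Extract all miRNA-extracellular-location relations (both steps)
#'
#' @param doc An annotated `mir_document`.
#' @return Combined PROXIMITY and PATIENT_CONTEXT relation rows.
#' @export
extract_extracellular <- function(doc) {
  prox <- extract_proximity_pairs(doc)
  pcs <- link_pc_pairs(doc, proximity = prox)
  rbind(prox, pcs)
}
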