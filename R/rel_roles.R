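# rel_roles: miRNA-process connections (the association / involvement /
# regulation pattern family), miRNA-disease role classification via the
# copular "is_a" pattern family with argument-type separation, and
# differential-expression statement mining.

.involve_lemmas <- c("involve", "contribute", "mediate", "play", "confer",
                     "implicate", "participate")
.assoc_lemmas <- c("associate", "correlate", "link", "relate")
.cair_lemmas <- c(.assoc_lemmas, .involve_lemmas, .reg_lemmas)

.outcome_terms <- c("survival", "prognosis", "outcome", "outcomes",
                    "recurrence", "metastasis")
.treatment_terms <- c("resistance", "sensitivity", "response",
                      "chemosensitivity", "radiosensitivity",
                      "chemotherapy", "radiotherapy", "therapy")
.biomarker_heads <- c("marker", "markers", "biomarker", "biomarkers",
                      "indicator", "indicators", "predictor", "predictors")
.tt_qualifiers <- c("therapeutic", "drug", "anticancer", "antitumor",
                    "druggable")
.isa_connectors <- c(.be_forms, "as")
.isa_verb_lemmas <- c("act", "serve", "emerge", "represent", "constitute")

roles_lemma_tab <- function() {
  lemma_table(c(.cair_lemmas, .isa_verb_lemmas, .negation_lemmas))
}

#' Extract miRNA-process relations
#'
#' Connects MIRNA and PROCESS mentions through regulation triggers
#' (promote/enhance/induce -> `regulation_positive`;
#' suppress/inhibit/attenuate/reduce -> `regulation_negative`),
#' involvement triggers (involved in, contributes to, mediates, plays a
#' role in) and association triggers (associated/correlated with, linked
#' to).  Coordination distributes over conjoined process mentions.
#'
#' @param doc An annotated `mir_document`.
#' @param window Token-window bound (default 8).
#' @return Relation rows with family `PROCESS` and the pattern-family tag
#'   in the `relation` column.
#' @export
extract_process_relations <- function(doc, window = 8L) {
  tab <- roles_lemma_tab()
  rules <- list(
    pattern_rule("process.reg.pos", .pos_reg_lemmas,
                 c(mirna = "MIRNA", process = "PROCESS"), window = window,
                 tag = "regulation_positive"),
    pattern_rule("process.reg.neg", .neg_reg_lemmas,
                 c(mirna = "MIRNA", process = "PROCESS"), window = window,
                 tag = "regulation_negative"),
    pattern_rule("process.involve", .involve_lemmas,
                 c(mirna = "MIRNA", process = "PROCESS"), window = window,
                 tag = "involvement"),
    pattern_rule("process.assoc", .assoc_lemmas,
                 c(mirna = "MIRNA", process = "PROCESS"), window = window,
                 tag = "association"))
  out <- list()
  for (si in doc$sentences$index) {
    sen <- doc$sentences[doc$sentences$index == si, ]
    men <- doc$entities[doc$entities$sentence_index == si, ]
    if (!any(men$entity_class == "MIRNA") ||
        !any(men$entity_class == "PROCESS")) next
    graph <- build_parse(sen$text, sentence_index = si)
    for (rule in rules) {
      m <- match_rule(rule, graph, men, lemma_tab = tab)
      if (nrow(m) == 0) next
      out[[length(out) + 1L]] <- data.frame(
        family = "PROCESS", mirna = m$mirna, partner = m$process,
        partner_type = "PROCESS", relation = m$tag, sentence_index = si,
        rule_id = m$rule_id, evidence = sen$text, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty_relations())
  rel <- do.call(rbind, out)
  canon <- entity_canonicalizer(doc)
  key <- paste(canon(rel$mirna), canon(rel$partner), rel$relation,
               rel$sentence_index, sep = "\r")
  rel <- rel[!duplicated(key), , drop = FALSE]
  canon_df(stable_order(rel, c("sentence_index", "relation")),
           .relation_schema)
}

entity_canonicalizer <- function(doc) {
  function(id) {
    i <- match(id, doc$entities$id)
    out <- doc$entities$canonical_id[i]
    ifelse(is.na(out) | !nzchar(out), id, out)
  }
}

# Resolve the disease argument for a relation found in sentence `si`:
# same-sentence DISEASE mention first (nearest to `near_start`), else a
# title mention, else the nearest prior sentence with a disease mention.
resolve_disease <- function(doc, si, near_start = 0L) {
  dis <- doc$entities[doc$entities$entity_class == "DISEASE", , drop = FALSE]
  no <- list(disease = NA_character_, provenance = "none")
  if (nrow(dis) == 0) return(no)
  pick <- function(rows) {
    rows$canonical_id[which.min(abs(rows$start - near_start))]
  }
  same <- dis[dis$sentence_index == si, , drop = FALSE]
  if (nrow(same)) return(list(disease = pick(same),
                              provenance = "same_sentence"))
  ti <- title_sentence_index(doc)
  if (!is.na(ti)) {
    ttl <- dis[dis$sentence_index == ti, , drop = FALSE]
    if (nrow(ttl)) return(list(disease = ttl$canonical_id[1],
                               provenance = "title"))
  }
  prior <- dis[dis$sentence_index < si, , drop = FALSE]
  if (nrow(prior)) {
    best <- prior[prior$sentence_index == max(prior$sentence_index), ,
                  drop = FALSE]
    return(list(disease = best$canonical_id[nrow(best)],
                provenance = "nearest_prior"))
  }
  no
}

#' Classify miRNA-disease roles
#'
#' Three pattern groups, applied per sentence:
#' (a) copular "is_a" patterns (`X is/acts as/serves as/may serve as/
#'     emerged as/could be Y`) with an miRNA subject; the complement head
#'     noun decides the role: marker/biomarker/indicator/predictor ->
#'     BIOMARKER; therapeutic/drug/anticancer target or "target for (the)
#'     treatment" -> THERAPEUTIC_TARGET;
#' (b) association/involvement/regulation triggers with an outcome term
#'     (survival, prognosis, outcome, recurrence, metastasis) -> OUTCOME,
#'     or a treatment term (resistance, sensitivity, response,
#'     chemo-/radiosensitivity, chemotherapy, therapy, radiation
#'     treatment) -> TREATMENT;
#' (c) association/regulation with a DISEASE mention and none of the
#'     above -> OTHER.
#' The disease argument resolves same-sentence first, then title, then the
#' nearest prior disease mention; the provenance is always recorded.  A
#' single "diagnostic and prognostic marker" match yields one BIOMARKER
#' relation, with the qualifier kept as free text in the rule id.
#'
#' @param doc An annotated `mir_document`.
#' @param window Token-window bound (default 8; the is_a complement scan
#'   looks ahead up to 10 tokens).
#' @return Relation rows with family `DISEASE_ROLE`, at most one per
#'   (miRNA, disease, role, sentence).
#' @export
extract_disease_roles <- function(doc, window = 8L) {
  tab <- roles_lemma_tab()
  out <- list()
  emit <- function(mid, role, si, dis, rule_id, evidence) {
    out[[length(out) + 1L]] <<- data.frame(
      family = "DISEASE_ROLE", mirna = mid, partner = dis$disease,
      partner_type = "DISEASE", role = role, disease = dis$disease,
      disease_provenance = dis$provenance, sentence_index = si,
      rule_id = rule_id, evidence = evidence, stringsAsFactors = FALSE)
  }
  for (si in doc$sentences$index) {
    sen <- doc$sentences[doc$sentences$index == si, ]
    men <- doc$entities[doc$entities$sentence_index == si, ]
    mi <- which(men$entity_class == "MIRNA")
    if (!length(mi)) next
    graph <- build_parse(sen$text, sentence_index = si)
    toks <- tolower(strip_punct(graph$tokens$token))
    lems <- token_lemma(graph$tokens$token, tab)
    n <- length(toks)
    ranges <- lapply(seq_len(nrow(men)), function(i)
      mention_token_range(graph, men$start[i], men$end[i]))
    specific <- character(0)   # mirna mention ids with a specific role here

    # ---- (a) is_a patterns -----------------------------------------------
    for (i in mi) {
      h <- ranges[[i]][2]
      if (is.na(h)) next
      hi <- min(n, h + 10L)
      if (h + 1L > hi) next
      span <- (h + 1L):hi
      connector_at <- span[toks[span] %in% .isa_connectors |
                           lems[span] %in% .isa_verb_lemmas]
      if (!length(connector_at)) next
      cstart <- min(connector_at)
      head_at <- span[span > cstart]
      for (p in head_at) {
        if (any(toks[max(1L, p - 3L):(p - 1L)] %in% c("not", "no", "neither")))
          next
        role <- NA_character_
        if (toks[p] %in% .biomarker_heads) role <- "BIOMARKER"
        else if (lems[p] == "target" || toks[p] %in% c("target", "targets")) {
          qual <- toks[max(1L, p - 2L):(p - 1L)]
          after <- toks[p:min(n, p + 3L)]
          if (any(qual %in% .tt_qualifiers) ||
              any(after %in% c("treatment", "treatments")))
            role <- "THERAPEUTIC_TARGET"
        }
        if (!is.na(role)) {
          qualifier <- paste(toks[(cstart + 1L):max(cstart + 1L, p - 1L)],
                             collapse = " ")
          dis <- resolve_disease(doc, si, men$start[i])
          emit(men$id[i], role, si, dis,
               paste0("role.is_a[", trimws(qualifier), "]"), sen$text)
          break   # one role per miRNA mention from the is_a scan
        }
      }
    }

    # ---- (b) outcome / treatment via CAIR triggers -----------------------
    # argument-type separation: trigger and aspect-keyword tokens lying
    # inside an entity mention belong to that argument and do not fire
    inside <- covered_tokens(ranges)
    trig <- setdiff(which(lems %in% .cair_lemmas), inside)
    trig <- trig[!vapply(trig, function(t) negated_trigger(graph, t, tab),
                         logical(1))]
    bigram_radiation <- which(toks == "radiation")
    treat_at <- which(toks %in% .treatment_terms)
    if (length(bigram_radiation))
      treat_at <- sort(unique(c(treat_at,
        bigram_radiation[toks[pmin(n, bigram_radiation + 1L)] == "treatment"])))
    treat_at <- setdiff(treat_at, inside)
    outcome_at <- setdiff(which(toks %in% .outcome_terms), inside)
    for (t in trig) {
      near_mi <- mi[vapply(mi, function(i)
        range_distance(t, ranges[[i]]) <= window, logical(1))]
      if (length(near_mi)) near_mi <- expand_conjuncts(graph, men, near_mi)
      if (!length(near_mi)) next
      for (kind in c("OUTCOME", "TREATMENT")) {
        at <- if (kind == "OUTCOME") outcome_at else treat_at
        if (!length(at) || !any(abs(at - t) <= window)) next
        for (i in near_mi) {
          dis <- resolve_disease(doc, si, men$start[i])
          emit(men$id[i], kind, si, dis, paste0("role.cair.",
               tolower(kind)), sen$text)
        }
      }
    }

    # ---- (c) OTHER: association/regulation with a disease mention --------
    di <- which(men$entity_class == "DISEASE")
    if (length(di)) {
      other_trig <- setdiff(which(lems %in% c(.assoc_lemmas, .reg_lemmas,
                                              .involve_lemmas)), inside)
      other_trig <- other_trig[!vapply(other_trig, function(t)
        negated_trigger(graph, t, tab), logical(1))]
      for (t in other_trig) {
        near_mi <- mi[vapply(mi, function(i)
          range_distance(t, ranges[[i]]) <= window, logical(1))]
        if (length(near_mi)) near_mi <- expand_conjuncts(graph, men, near_mi)
        near_di <- di[vapply(di, function(i)
          range_distance(t, ranges[[i]]) <= window, logical(1))]
        if (!length(near_mi) || !length(near_di)) next
        for (i in near_mi) for (d in near_di) {
          emit(men$id[i], "OTHER", si,
               list(disease = men$canonical_id[d],
                    provenance = "same_sentence"),
               "role.cair.other", sen$text)
        }
      }
    }
  }
  if (!length(out)) return(empty_relations())
  rel <- do.call(rbind, out)
  canon <- entity_canonicalizer(doc)
  # role partition: specific roles beat OTHER for the same miRNA+sentence
  mkey <- paste(canon(rel$mirna), rel$sentence_index, sep = "\r")
  specific_keys <- unique(mkey[rel$role != "OTHER"])
  rel <- rel[!(rel$role == "OTHER" & mkey %in% specific_keys), ,
             drop = FALSE]
  key <- paste(canon(rel$mirna), rel$disease, rel$role, rel$sentence_index,
               sep = "\r")
  rel <- rel[!duplicated(key), , drop = FALSE]
  canon_df(stable_order(rel, c("sentence_index", "role")), .relation_schema)
}

# ---- differential expression ---------------------------------------------

.dir_down <- c("reduced", "decreased", "lower", "downregulated",
               "down-regulated")
.dir_up <- c("elevated", "increased", "higher", "upregulated",
             "up-regulated", "overexpressed")
.expr_cues <- c("expression", "level", "levels", "abundance")
.linking_verbs <- c("was", "were", "is", "are", "be", "been", "remained",
                    "remains", "found", "significantly")
.cmp_markers <- c("compared", "versus", "vs", "than", "relative")
.phrase_stop <- c("over", "during", "throughout", "across", "within",
                  "after", "before", "between", "using", "by", "which",
                  "that", "and")
.determiners <- c("a", "an", "the", "this", "these", "those")

#' Extract differential-expression statements
#'
#' A comparative frame requires a direction word (reduced/decreased/lower/
#' downregulated -> down; elevated/increased/higher/upregulated/
#' overexpressed -> up) used predicatively (a linking verb within six
#' preceding tokens, or the inherently comparative adjectives
#' higher/lower), plus an `in <sample/disease phrase>` and/or an explicit
#' comparison marker (compared to/with, versus, vs, relative to, than).
#' Sample and control phrases are captured verbatim with leading
#' determiners and numeric quantifiers trimmed.  Unknown direction words
#' never emit a relation.
#'
#' @param doc An annotated `mir_document`.
#' @param window Token-window bound for attaching miRNA mentions
#'   (default 8).
#' @return Relation rows with family `DIFFEXPR`.
#' @export
extract_diffexpr <- function(doc, window = 8L) {
  out <- list()
  for (si in doc$sentences$index) {
    sen <- doc$sentences[doc$sentences$index == si, ]
    men <- doc$entities[doc$entities$sentence_index == si, ]
    mi <- which(men$entity_class == "MIRNA")
    if (!length(mi)) next
    graph <- build_parse(sen$text, sentence_index = si)
    toks <- tolower(strip_punct(graph$tokens$token))
    raw <- graph$tokens$token
    n <- length(toks)
    ranges <- lapply(seq_len(nrow(men)), function(i)
      mention_token_range(graph, men$start[i], men$end[i]))
    dirs <- which(toks %in% c(.dir_down, .dir_up))
    for (d in dirs) {
      direction <- if (toks[d] %in% .dir_down) "down" else "up"
      predicative <- toks[d] %in% c("higher", "lower") ||
        any(toks[max(1L, d - 6L):max(1L, d - 1L)] %in% .linking_verbs)
      if (!predicative && d > 1L) next
      if (any(toks[max(1L, d - 3L):max(1L, d - 1L)] %in%
              c("not", "no", "neither"))) next
      # sample phrase: first "in" after the direction word
      in_at <- which(toks == "in" & seq_len(n) > d)
      cmp_at <- which(toks %in% .cmp_markers & seq_len(n) > d)
      if (!length(in_at) && !length(cmp_at)) next
      sample <- NA_character_
      if (length(in_at)) {
        s0 <- in_at[1] + 1L
        stop_at <- c(cmp_at[cmp_at >= s0], which(seq_len(n) > s0 &
                       toks %in% .phrase_stop), n + 1L)
        s1 <- min(stop_at) - 1L
        if (s1 >= s0) {
          words <- toks[s0:s1]
          keep <- !(words %in% c(.determiners, "out", "of") |
                      grepl("^\\d+(\\.\\d+)?%?$", words))
          # trim only the leading quantifier run
          first_keep <- which(keep)[1]
          if (!is.na(first_keep) && first_keep <= length(words)) {
            phrase <- strip_punct(raw[(s0 + first_keep - 1L):s1])
            sample <- collapse_ws(paste(phrase, collapse = " "))
          }
        }
      }
      comparison <- NA_character_
      if (length(cmp_at)) {
        c0 <- cmp_at[1] + 1L
        while (c0 <= n && toks[c0] %in% c("to", "with", "the", "a", "an"))
          c0 <- c0 + 1L
        stop_at <- c(which(seq_len(n) > c0 & toks %in% .phrase_stop), n + 1L)
        c1 <- min(stop_at) - 1L
        # stop at sentence punctuation too
        punct <- which(seq_len(n) >= c0 & grepl("[.;:]$", raw))
        if (length(punct)) c1 <- min(c1, punct[1])
        if (c1 >= c0)
          comparison <- collapse_ws(paste(strip_punct(raw[c0:c1]),
                                          collapse = " "))
      }
      if (is.na(sample) && is.na(comparison)) next
      near_mi <- mi[vapply(mi, function(i)
        range_distance(d, ranges[[i]]) <= window, logical(1))]
      if (length(near_mi)) near_mi <- expand_conjuncts(graph, men, near_mi)
      for (i in near_mi) {
        dis <- resolve_disease(doc, si, men$start[i])
        out[[length(out) + 1L]] <- data.frame(
          family = "DIFFEXPR", mirna = men$id[i], partner = dis$disease,
          partner_type = "DISEASE", direction = direction,
          disease = dis$disease, disease_provenance = dis$provenance,
          sample_descriptor = sample, comparison_descriptor = comparison,
          sentence_index = si, rule_id = "diffexpr.frame",
          evidence = sen$text, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(empty_relations())
  rel <- do.call(rbind, out)
  canon <- entity_canonicalizer(doc)
  key <- paste(canon(rel$mirna), rel$direction, rel$sentence_index,
               sep = "\r")
  rel <- rel[!duplicated(key), , drop = FALSE]
  canon_df(stable_order(rel, c("sentence_index", "direction")),
           .relation_schema)
}
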