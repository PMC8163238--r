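# rel_gene: the three miRNA-gene relation types with polarity.
#
# (i) MIRNA_GENE  - regulation with the miRNA as agent (no direct-target
#                   evidence); polarity from the trigger lemma.
# (ii) MIRNA_TARGET - a direct-target trigger fired (target/direct target/
#                   functional target/validated as a target/binds the
#                   3'UTR); polarity defaults to negative (targeting
#                   represses) unless a positive trigger co-occurs.
# (iii) GENE_MIRNA - a gene/protein regulates the miRNA's expression.
#
# Agent/theme under the level-B chain graph: the mention preceding the
# trigger is the agent, the one following the theme; a passive cue
# ("was/were ... by") swaps roles.

.pos_reg_lemmas <- c("induce", "increase", "upregulate", "up-regulate",
                     "enhance", "promote")
.neg_reg_lemmas <- c("suppress", "inhibit", "repress", "downregulate",
                     "down-regulate", "reduce", "silence", "attenuate")
.reg_lemmas <- c(.pos_reg_lemmas, .neg_reg_lemmas)
.target_lemmas <- c("target")
.be_forms <- c("is", "are", "was", "were", "be", "been", "being")

gene_lemma_tab <- function() {
  lemma_table(c(.reg_lemmas, .target_lemmas, "bind", "validate",
                .negation_lemmas))
}

reg_polarity <- function(lemma) {
  if (lemma %in% .pos_reg_lemmas) "positive"
  else if (lemma %in% .neg_reg_lemmas) "negative"
  else "unspecified"
}

# passive-voice cue around trigger token t: be-form shortly before and
# "by" shortly after
passive_cue <- function(graph, t) {
  n <- nrow(graph$tokens)
  toks <- tolower(strip_punct(graph$tokens$token))
  before <- toks[max(1L, t - 3L):max(1L, t - 1L)]
  after <- toks[min(n, t + 1L):min(n, t + 4L)]
  (t > 1 && any(before %in% .be_forms)) && any(after == "by")
}

#' Extract miRNA-gene relations from an annotated document
#'
#' Requires MIRNA and GENE entity mentions (see [annotate_document()]).
#' One relation per (family, miRNA, gene, sentence) after deduplication;
#' coordination distributes over conjoined gene lists; when both a
#' direct-target trigger and a generic regulation trigger fire on the same
#' pair in one sentence, only the MIRNA_TARGET relation is kept.
#'
#' @param doc An annotated `mir_document`.
#' @param window Token-window bound (default 8).
#' @return A relation data.frame in the package-wide schema with families
#'   MIRNA_TARGET, MIRNA_GENE, GENE_MIRNA.
#' @export
extract_gene_relations <- function(doc, window = 8L) {
  out <- list()
  tab <- gene_lemma_tab()
  for (si in doc$sentences$index) {
    sen <- doc$sentences[doc$sentences$index == si, ]
    men <- doc$entities[doc$entities$sentence_index == si, ]
    if (!any(men$entity_class == "MIRNA") || !any(men$entity_class == "GENE"))
      next
    graph <- build_parse(sen$text, sentence_index = si)
    lems <- token_lemma(graph$tokens$token, tab)
    ranges <- lapply(seq_len(nrow(men)), function(i)
      mention_token_range(graph, men$start[i], men$end[i]))
    has_3utr <- any(grepl("^3'?-?utr", tolower(strip_punct(graph$tokens$token))))

    emit <- function(family, mi, gi, polarity, rule_id, t) {
      out[[length(out) + 1L]] <<- data.frame(
        family = family, mirna = men$id[mi], partner = men$id[gi],
        partner_type = "GENE", polarity = polarity,
        sentence_index = si, rule_id = rule_id, evidence = sen$text,
        trigger = t, stringsAsFactors = FALSE)
    }

    rules <- list(
      list(id = "gene.target", lemmas = .target_lemmas, family = "TARGET"),
      list(id = "gene.bind3utr", lemmas = "bind", family = "TARGET",
           guard = function() has_3utr),
      list(id = "gene.regulation", lemmas = .reg_lemmas, family = "REG"))
    inside <- covered_tokens(ranges)
    for (rl in rules) {
      trig <- setdiff(which(lems %in% rl$lemmas), inside)
      for (t in trig) {
        if (!is.null(rl$guard) && !rl$guard()) next
        if (negated_trigger(graph, t, tab)) next
        mi_all <- which(men$entity_class == "MIRNA")
        gi_all <- which(men$entity_class == "GENE")
        mi <- mi_all[vapply(mi_all, function(i)
          range_distance(t, ranges[[i]]) <= window, logical(1))]
        gi <- gi_all[vapply(gi_all, function(i)
          range_distance(t, ranges[[i]]) <= window, logical(1))]
        if (length(mi)) mi <- expand_conjuncts(graph, men, mi)
        if (length(gi)) gi <- expand_conjuncts(graph, men, gi)
        if (!length(mi) || !length(gi)) next
        passive <- passive_cue(graph, t)
        for (m in mi) for (g in gi) {
          if (rl$family == "TARGET") {
            emit("MIRNA_TARGET", m, g, "negative", rl$id, t)
          } else {
            pol <- reg_polarity(lems[t])
            m_before <- ranges[[m]][2] < t
            g_before <- ranges[[g]][2] < t
            agent_is_mirna <-
              if (m_before && !g_before) TRUE
              else if (g_before && !m_before) FALSE
              else ranges[[m]][1] < ranges[[g]][1]  # same side: leftmost
            if (passive) agent_is_mirna <- !agent_is_mirna
            if (agent_is_mirna) emit("MIRNA_GENE", m, g, pol, rl$id, t)
            else emit("GENE_MIRNA", g, m, pol, rl$id, t)
          }
        }
      }
    }
  }
  if (!length(out)) return(empty_relations())
  rel <- do.call(rbind, out)
  # GENE_MIRNA rows were emitted agent-first; the schema keeps the miRNA
  # mention in `mirna` and the gene in `partner` for every family.
  gm <- rel$family == "GENE_MIRNA"
  if (any(gm)) {
    tmp <- rel$mirna[gm]
    rel$mirna[gm] <- rel$partner[gm]
    rel$partner[gm] <- tmp
  }
  dedup_gene_relations(rel, doc)
}

# Deduplicate on (family, mirna-canonical, gene-canonical, sentence);
# specificity: MIRNA_TARGET beats MIRNA_GENE on the same pair; a
# MIRNA_TARGET pair that also saw a positive regulation trigger flips to
# positive polarity.
dedup_gene_relations <- function(rel, doc) {
  canon <- function(id) {
    i <- match(id, doc$entities$id)
    out <- doc$entities$canonical_id[i]
    ifelse(is.na(out) | !nzchar(out), id, out)
  }
  rel$mkey <- canon(rel$mirna)
  rel$gkey <- canon(rel$partner)
  pairkey <- paste(rel$mkey, rel$gkey, rel$sentence_index, sep = "\r")
  tgt <- rel$family == "MIRNA_TARGET"
  pos_pairs <- unique(pairkey[rel$family == "MIRNA_GENE" &
                              rel$polarity == "positive"])
  rel$polarity[tgt & pairkey %in% pos_pairs] <- "positive"
  # specificity: drop MIRNA_GENE when a target relation covers the pair
  drop <- rel$family == "MIRNA_GENE" & pairkey %in% unique(pairkey[tgt])
  rel <- rel[!drop, , drop = FALSE]
  key <- paste(rel$family, pairkey[!drop], sep = "\r")
  rel <- rel[!duplicated(key), , drop = FALSE]
  rel <- stable_order(rel, c("sentence_index", "family", "mkey", "gkey"))
  canon_df(rel[, c("family", "mirna", "partner", "partner_type", "polarity",
                   "sentence_index", "rule_id", "evidence")],
           .relation_schema)
}
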