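# synth_corpus: seeded synthetic abstracts with gold-standard annotations
# covering every relation family, plus the precision/recall scorer.
#
# Templates paraphrase the sentence shapes the extractors are designed
# for (target statement, regulation statement, gene->miRNA statement,
# process connection, is_a biomarker / therapeutic target, outcome
# association, treatment, differential-expression frame, fluid proximity,
# patient-context + analysis sentence pair).  Distractor sentences are
# trigger-free co-occurrences, negated triggers and lookalike tokens.
# Every quota item instantiates exactly one gold relation.

.template_kinds <- c("target", "gene_reg_pos", "gene_reg_neg", "gene_mirna",
                     "process_reg_pos", "process_reg_neg",
                     "process_involve", "process_assoc", "biomarker",
                     "therapeutic_target", "outcome", "treatment", "other",
                     "diffexpr_up", "diffexpr_down", "proximity",
                     "patient_context")

#' Configuration for the synthetic-corpus generator
#'
#' @param seed Integer RNG seed; identical configs yield byte-identical
#'   corpora.
#' @param n_documents Number of documents (default 200, one templated
#'   relation per document).
#' @param quotas Named integer vector over the template kinds; default
#'   distributes `n_documents` round-robin over all kinds.
#' @param distractor_rate Probability in [0,1] that a document receives a
#'   distractor sentence.
#' @param lexicons `mir_lexicon_set` supplying the entity pools.
#' @return A list of class `mir_synth_config`.
#' @export
synth_config <- function(seed = 42L, n_documents = 200L, quotas = NULL,
                         distractor_rate = 0, lexicons = default_lexicons()) {
  stopifnot(distractor_rate >= 0, distractor_rate <= 1)
  if (is.null(quotas)) {
    kinds <- rep(.template_kinds, length.out = n_documents)
    quotas <- table(factor(kinds, levels = .template_kinds))
    quotas <- stats::setNames(as.integer(quotas), names(quotas))
  } else {
    missing <- setdiff(names(quotas), .template_kinds)
    if (length(missing))
      stop("unknown template kinds: ", paste(missing, collapse = ", "),
           call. = FALSE)
    quotas <- stats::setNames(as.integer(quotas), names(quotas))
  }
  structure(list(seed = as.integer(seed), n_documents = as.integer(n_documents),
                 quotas = quotas, distractor_rate = distractor_rate,
                 lexicons = lexicons), class = "mir_synth_config")
}

# entity pools drawn from the configured lexicons (primary labels only,
# so gold partners have unambiguous canonical ids)
synth_pools <- function(lexicons) {
  primary <- function(lex) {
    e <- lexicon_entries(lex)
    e[!duplicated(e$canonical_id), , drop = FALSE]
  }
  g <- primary(lexicons$gene)
  d <- primary(lexicons$disease)
  pr <- primary(lexicons$process)
  loc <- lexicon_entries(lexicons$location)
  fl <- loc[loc$entity_class == "FLUID", , drop = FALSE]
  fl <- fl[!duplicated(fl$canonical_id), , drop = FALSE]
  list(gene = g, disease = d, process = pr, fluid = fl)
}

sample_mirna <- function() {
  num <- sample(1:520, 1L)
  letter <- sample(c("", "a", "b"), 1L, prob = c(0.6, 0.2, 0.2))
  dialect <- sample(c("miR-%d%s", "microRNA-%d%s", "miRNA-%d%s",
                      "hsa-miR-%d%s"), 1L,
                    prob = c(0.55, 0.2, 0.15, 0.1))
  surface <- sprintf(dialect, num, letter)
  list(surface = surface, family = normalize_mirna(surface))
}

sample_row <- function(pool) pool[sample(nrow(pool), 1L), , drop = FALSE]

# capitalize the first character of a sentence fragment
cap1 <- function(x) paste0(toupper(substr(x, 1, 1)), substr(x, 2, nchar(x)))

synth_templates <- function(kind, m, pools) {
  g <- sample_row(pools$gene); d <- sample_row(pools$disease)
  p <- sample_row(pools$process); f <- sample_row(pools$fluid)
  G <- toupper(g$label); D <- d$surface; P <- p$surface; FL <- f$surface
  s <- switch(kind,
    target = sprintf(
      "Luciferase reporter assays confirmed that %s is a direct target of %s.",
      G, m$surface),
    gene_reg_pos = sprintf(
      "Ectopic %s markedly increased %s expression at both mRNA and protein levels.",
      m$surface, G),
    gene_reg_neg = sprintf(
      "Overexpression of %s markedly suppressed %s at both mRNA and protein levels.",
      m$surface, G),
    gene_mirna = sprintf(
      "%s treatment increased %s expression in cultured fibroblasts.",
      G, m$surface),
    process_reg_pos = sprintf("%s promotes %s in vitro.", m$surface, P),
    process_reg_neg = sprintf("%s inhibits %s in vitro.", m$surface, P),
    process_involve = sprintf("%s is involved in %s.", m$surface, P),
    process_assoc = sprintf(
      "%s expression is closely associated with %s.", m$surface, P),
    biomarker = sprintf(
      "%s may serve as a promising biomarker for %s.", m$surface, D),
    therapeutic_target = sprintf(
      "%s could be a novel therapeutic target for %s.", m$surface, D),
    outcome = sprintf(
      "High %s expression was associated with poor prognosis in %s.",
      m$surface, D),
    treatment = sprintf(
      "%s enhances the chemosensitivity of %s cells to cisplatin.",
      m$surface, D),
    other = sprintf(
      "Altered expression of %s is related to clinicopathologic features of %s.",
      m$surface, D),
    diffexpr_up = sprintf(
      "%s expression was significantly elevated in %s tissues compared with adjacent normal tissues.",
      cap1(m$surface), D),
    diffexpr_down = sprintf(
      "%s expression was significantly decreased in %s tissues compared with adjacent normal tissues.",
      cap1(m$surface), D),
    proximity = sprintf(
      "Expression of %s in %s was assessed by quantitative PCR.",
      m$surface, FL),
    patient_context = c(sprintf(
      "%s samples were collected from 40 patients with %s and 20 healthy controls.",
      cap1(FL), D),
      sprintf("Levels of %s were quantified using droplet digital PCR.",
              m$surface))
  )
  gold <- switch(kind,
    target = list(family = "MIRNA_TARGET", rod = "",
                  partner = g$canonical_id, ptype = "GENE"),
    gene_reg_pos = list(family = "MIRNA_GENE", rod = "positive",
                        partner = g$canonical_id, ptype = "GENE"),
    gene_reg_neg = list(family = "MIRNA_GENE", rod = "negative",
                        partner = g$canonical_id, ptype = "GENE"),
    gene_mirna = list(family = "GENE_MIRNA", rod = "positive",
                      partner = g$canonical_id, ptype = "GENE"),
    process_reg_pos = list(family = "PROCESS", rod = "regulation_positive",
                           partner = p$canonical_id, ptype = "PROCESS"),
    process_reg_neg = list(family = "PROCESS", rod = "regulation_negative",
                           partner = p$canonical_id, ptype = "PROCESS"),
    process_involve = list(family = "PROCESS", rod = "involvement",
                           partner = p$canonical_id, ptype = "PROCESS"),
    process_assoc = list(family = "PROCESS", rod = "association",
                         partner = p$canonical_id, ptype = "PROCESS"),
    biomarker = list(family = "DISEASE_ROLE", rod = "BIOMARKER",
                     partner = d$canonical_id, ptype = "DISEASE"),
    therapeutic_target = list(family = "DISEASE_ROLE",
                              rod = "THERAPEUTIC_TARGET",
                              partner = d$canonical_id, ptype = "DISEASE"),
    outcome = list(family = "DISEASE_ROLE", rod = "OUTCOME",
                   partner = d$canonical_id, ptype = "DISEASE"),
    treatment = list(family = "DISEASE_ROLE", rod = "TREATMENT",
                     partner = d$canonical_id, ptype = "DISEASE"),
    other = list(family = "DISEASE_ROLE", rod = "OTHER",
                 partner = d$canonical_id, ptype = "DISEASE"),
    diffexpr_up = list(family = "DIFFEXPR", rod = "up",
                       partner = d$canonical_id, ptype = "DISEASE"),
    diffexpr_down = list(family = "DIFFEXPR", rod = "down",
                         partner = d$canonical_id, ptype = "DISEASE"),
    proximity = list(family = "EXTRACELLULAR", rod = "",
                     partner = f$canonical_id, ptype = "FLUID"),
    patient_context = list(family = "EXTRACELLULAR", rod = "",
                           partner = f$canonical_id, ptype = "FLUID")
  )
  list(sentences = s, gold = gold)
}

.distractor_templates <- function(m, g) {
  c(sprintf("%s and %s have both been described in earlier reports.",
            m, g),
    sprintf("%s did not suppress %s in any of these assays.", m, g),
    "The MIRROR cohort was described previously.")
}

#' Generate a synthetic corpus with gold annotations
#'
#' @param config A `mir_synth_config`.
#' @return A list with `documents` (un-annotated `mir_document`s) and
#'   `gold` (data.frame: pmid, family, role_or_direction, mirna, partner,
#'   partner_type, sentence_index).  Deterministic in the seed; the gold
#'   size equals the quota sum exactly.
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "mir_synth_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  }, add = TRUE)
  set.seed(config$seed)
  pools <- synth_pools(config$lexicons)
  kinds <- rep(names(config$quotas), times = config$quotas)
  if (length(kinds) == 0)
    return(list(documents = list(), gold = empty_gold()))
  docs <- vector("list", length(kinds))
  gold <- vector("list", length(kinds))
  for (i in seq_along(kinds)) {
    kind <- kinds[i]
    pmid <- sprintf("9%06d", i)
    m <- sample_mirna()
    tpl <- synth_templates(kind, m, pools)
    body <- c("This study investigated small RNA regulatory biology.",
              tpl$sentences)
    if (stats::runif(1) < config$distractor_rate) {
      dm <- sample_mirna()
      dg <- toupper(sample_row(pools$gene)$label)
      body <- c(body, sample(.distractor_templates(dm$surface, dg), 1L))
    }
    title <- "Synthetic abstract on microRNA regulation."
    docs[[i]] <- abstract_document(pmid, title, paste(body, collapse = " "))
    # sentence_index of the (last) template sentence: title is sentence 0,
    # filler sentence 1, template sentences follow
    tpl_sentence <- 1L + length(tpl$sentences)
    gold[[i]] <- data.frame(
      pmid = pmid, family = tpl$gold$family,
      role_or_direction = tpl$gold$rod, mirna = m$family,
      partner = tpl$gold$partner, partner_type = tpl$gold$ptype,
      sentence_index = tpl_sentence, stringsAsFactors = FALSE)
  }
  list(documents = docs, gold = do.call(rbind, gold))
}

empty_gold <- function() {
  data.frame(pmid = character(), family = character(),
             role_or_direction = character(), mirna = character(),
             partner = character(), partner_type = character(),
             sentence_index = integer(), stringsAsFactors = FALSE)
}

#' Convert processed documents to prediction rows for scoring
#'
#' @param docs Annotated + extracted documents.
#' @return A data.frame in the gold schema (one row per deduplicated
#'   prediction key).
#' @export
predictions_table <- function(docs) {
  tab <- relations_table(docs)
  if (nrow(tab) == 0) return(empty_gold())
  out <- data.frame(pmid = tab$pmid, family = tab$relation_family,
                    role_or_direction = tab$role_or_direction,
                    mirna = tab$mirna_id, partner = tab$partner_id,
                    partner_type = tab$partner_type,
                    sentence_index = tab$sentence_index,
                    rule_id = tab$rule_id,   # diagnostics: FP provenance
                    stringsAsFactors = FALSE)
  # extracellular pairs score method-agnostically
  key <- score_key(out)
  out[!duplicated(key), , drop = FALSE]
}

score_key <- function(df) {
  paste(df$pmid, df$family, df$mirna, df$partner, df$role_or_direction,
        sep = "\r")
}

#' Score predictions against a gold standard
#'
#' A prediction matches a gold item iff (pmid, family, normalized miRNA,
#' normalized partner, role/direction where applicable) agree.  Precision
#' is defined as 0 when there are no predictions but gold items exist;
#' an empty gold with empty predictions scores 1.
#'
#' @param predicted Prediction rows ([predictions_table()] output or
#'   equivalent).
#' @param gold Gold rows ([generate_corpus()] output).
#' @return A list with `overall` (precision, recall, f1, counts) and
#'   `per_family` (data.frame), plus `false_positives` /
#'   `false_negatives` tables for diagnostics.
#' @export
score_relations <- function(predicted, gold) {
  pk <- unique(score_key(predicted))
  gk <- unique(score_key(gold))
  prf <- function(pk, gk) {
    tp <- length(intersect(pk, gk))
    p <- if (length(pk) == 0) { if (length(gk) == 0) 1 else 0 }
         else tp / length(pk)
    r <- if (length(gk) == 0) 1 else tp / length(gk)
    f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    c(precision = p, recall = r, f1 = f1, tp = tp,
      n_pred = length(pk), n_gold = length(gk))
  }
  fams <- sort(unique(c(predicted$family, gold$family)))
  per <- do.call(rbind, lapply(fams, function(f) {
    data.frame(family = f, t(prf(
      unique(score_key(predicted[predicted$family == f, , drop = FALSE])),
      unique(score_key(gold[gold$family == f, , drop = FALSE])))),
      stringsAsFactors = FALSE)
  }))
  fp <- predicted[!(score_key(predicted) %in% gk), , drop = FALSE]
  fn <- gold[!(score_key(gold) %in% pk), , drop = FALSE]
  list(overall = as.list(prf(pk, gk)), per_family = per,
       false_positives = fp, false_negatives = fn)
}
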