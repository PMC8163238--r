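# corpus_store: inverted indices over annotated documents and the three
# query modes (miRNA-centric, context-centric boolean keywords,
# disease-centric), plus aspect views, filtering/sorting, counting and
# export.  The indices are derived data: rebuildable from the documents
# alone, deterministically.

index_tokens <- function(text) {
  toks <- strsplit(tolower(text), "[^\\p{L}\\p{N}-]+", perl = TRUE)[[1]]
  toks <- gsub("^-+|-+$", "", toks)
  unique(toks[nzchar(toks)])
}

.mirna_cue_rx <- "^(mir|mirna|mirnas|microrna|micrornas)$|^(?:[a-z]{3}-)?(?:mir|let|microrna|mirna)-"

#' Build a corpus index
#'
#' @param docs List of annotated `mir_document`.
#' @return An object of class `mir_index` with documents by pmid and
#'   inverted indices: miRNA family -> pmids, lowercased token -> pmids,
#'   disease id -> pmids, plus the set of pmids containing an miRNA cue
#'   token.
#' @export
build_index <- function(docs) {
  documents <- list(); mirna <- list(); tokens <- list(); disease <- list()
  cue <- character(0)
  for (d in docs) {
    documents[[d$pmid]] <- d
  }
  for (pmid in sort(names(documents))) {
    d <- documents[[pmid]]
    fams <- unique(stats::na.omit(
      d$entities$canonical_id[d$entities$entity_class == "MIRNA"]))
    for (f in fams) mirna[[f]] <- c(mirna[[f]], pmid)
    dids <- unique(stats::na.omit(
      d$entities$canonical_id[d$entities$entity_class == "DISEASE"]))
    for (x in dids) disease[[x]] <- c(disease[[x]], pmid)
    toks <- unique(unlist(lapply(c(d$title, d$sentences$text), index_tokens)))
    for (t in toks) tokens[[t]] <- c(tokens[[t]], pmid)
    if (any(grepl(.mirna_cue_rx, toks, perl = TRUE))) cue <- c(cue, pmid)
  }
  structure(list(documents = documents, mirna = mirna, tokens = tokens,
                 disease = disease, mirna_cue_pmids = sort(cue)),
            class = "mir_index")
}

#' @export
print.mir_index <- function(x, ...) {
  cat(sprintf("<mir_index: %d documents, %d miRNA families, %d tokens>\n",
              length(x$documents), length(x$mirna), length(x$tokens)))
  invisible(x)
}

index_result <- function(index, pmids) {
  pmids <- sort(unique(pmids))
  docs <- index$documents[pmids]
  structure(list(pmids = pmids, documents = docs), class = "mir_result")
}

#' miRNA-centric query
#'
#' Returns exactly the documents whose entity set contains a mention
#' normalizing to the given family (any accepted surface dialect works as
#' the query).
#'
#' @param index A `mir_index`.
#' @param family An miRNA family id or surface form (e.g. `"mir-21"`,
#'   `"microRNA-21"`).
#' @return A `mir_result` with `pmids`, `documents` and `relations` (the
#'   relation rows mentioning the family).
#' @export
query_mirna <- function(index, family) {
  fam <- normalize_mirna(family)
  res <- index_result(index, index$mirna[[fam]] %||% character(0))
  tab <- relations_table(res$documents)
  res$relations <- tab[tab$mirna_id == fam, , drop = FALSE]
  res
}

# ---- boolean query expressions -------------------------------------------

#' Parse a boolean keyword query
#'
#' Grammar: literals separated by AND / OR (case-insensitive), with
#' parentheses; AND binds tighter than OR; consecutive words form one
#' phrase literal.  The tree is non-empty and literals are matched
#' case-insensitively.
#'
#' @param s Query string, e.g. `"GBM AND EGFR"` or
#'   `"(glioma OR glioblastoma) AND PTEN"`.
#' @return A query-expression tree (nested lists with `op` and
#'   `args`/`value`).
#' @export
parse_query <- function(s) {
  s <- trimws(s)
  if (!nzchar(s)) stop("empty query expression", call. = FALSE)
  raw <- regmatches(s, gregexpr("\\(|\\)|[^()\\s]+", s, perl = TRUE))[[1]]
  pos <- 1L
  peek <- function() if (pos <= length(raw)) raw[pos] else NA_character_
  advance <- function() { tok <- raw[pos]; pos <<- pos + 1L; tok }
  is_op <- function(t, what) !is.na(t) && toupper(t) == what
  parse_expr <- function() {
    left <- parse_term()
    args <- list(left)
    while (is_op(peek(), "OR")) { advance(); args <- c(args, list(parse_term())) }
    if (length(args) == 1L) left else list(op = "OR", args = args)
  }
  parse_term <- function() {
    left <- parse_factor()
    args <- list(left)
    while (is_op(peek(), "AND")) { advance(); args <- c(args, list(parse_factor())) }
    if (length(args) == 1L) left else list(op = "AND", args = args)
  }
  parse_factor <- function() {
    t <- peek()
    if (is.na(t)) stop("malformed query: unexpected end", call. = FALSE)
    if (t == "(") {
      advance()
      e <- parse_expr()
      if (!identical(peek(), ")")) stop("malformed query: missing ')'",
                                        call. = FALSE)
      advance()
      return(e)
    }
    words <- character(0)
    while (!is.na(peek()) && !peek() %in% c("(", ")") &&
           !toupper(peek()) %in% c("AND", "OR"))
      words <- c(words, advance())
    if (!length(words)) stop("malformed query: expected a keyword",
                             call. = FALSE)
    list(op = "LIT", value = paste(words, collapse = " "))
  }
  e <- parse_expr()
  if (!is.na(peek())) stop("malformed query: trailing tokens", call. = FALSE)
  e
}

eval_query <- function(index, expr) {
  if (expr$op == "LIT") {
    toks <- index_tokens(expr$value)
    if (!length(toks)) return(character(0))
    sets <- lapply(toks, function(t) index$tokens[[t]] %||% character(0))
    return(Reduce(intersect, sets))
  }
  sets <- lapply(expr$args, function(a) eval_query(index, a))
  if (expr$op == "AND") Reduce(intersect, sets)
  else Reduce(union, sets)
}

#' Context-centric query
#'
#' Evaluates the boolean expression over the token index, then intersects
#' with documents containing an miRNA cue token - i.e. the effective query
#' is `expr AND (miR OR miRNA OR microRNA)`.
#'
#' @param index A `mir_index`.
#' @param expr A query string or a tree from [parse_query()].
#' @return A `mir_result`.
#' @export
query_context <- function(index, expr) {
  if (is.character(expr)) expr <- parse_query(expr)
  pmids <- intersect(eval_query(index, expr), index$mirna_cue_pmids)
  res <- index_result(index, pmids)
  res$relations <- relations_table(res$documents)
  res
}

#' Disease-centric query
#'
#' Expands a DOID (or official disease name) to its name plus exact
#' synonyms from the Disease Ontology file, builds the OR-of-terms
#' expression and delegates to [query_context()].
#'
#' @param index A `mir_index`.
#' @param doid A DOID (`"DOID:684"`) or a disease name resolvable in the
#'   ontology.
#' @param do_obo Parsed Disease Ontology (`parse_obo()`) or path.
#' @return A `mir_result`; unknown identifiers are an error.
#' @export
query_disease <- function(index, doid, do_obo) {
  if (is.character(do_obo) && length(do_obo) == 1L && file.exists(do_obo))
    do_obo <- parse_obo(do_obo)
  term <- NULL
  if (grepl("^DOID:", doid)) {
    for (t in do_obo) if (identical(t$id, doid)) { term <- t; break }
  } else {
    key <- norm_surface(doid)
    for (t in do_obo) {
      if (norm_surface(t$name) == key ||
          key %in% norm_surface(t$synonyms$text)) { term <- t; break }
    }
  }
  if (is.null(term))
    stop(sprintf("unknown disease identifier or name: '%s'", doid),
         call. = FALSE)
  exact <- term$synonyms$text[term$synonyms$scope == "EXACT"]
  terms <- unique(c(term$name, exact))
  expr <- list(op = "OR", args = lapply(terms, function(x)
    list(op = "LIT", value = x)))
  res <- query_context(index, expr)
  res$doid <- term$id
  res$terms <- terms
  res
}

# ---- aspect views ---------------------------------------------------------

.aspect_families <- list(
  gene_regulation = c("MIRNA_TARGET", "MIRNA_GENE", "GENE_MIRNA"),
  process = "PROCESS",
  disease_roles = "DISEASE_ROLE",
  diffexpr = "DIFFEXPR",
  extracellular = "EXTRACELLULAR")

#' Tabulate an aspect-specific view of query results
#'
#' @param results A `mir_result` (or a plain list of documents).
#' @param aspect One of `"gene_regulation"`, `"process"`,
#'   `"disease_roles"`, `"diffexpr"`, `"extracellular"`.
#' @return A data.frame, one row per relation of the aspect's families,
#'   carrying pmid, evidence sentence, surfaces and normalized ids.
#' @export
aspect_view <- function(results, aspect = names(.aspect_families)) {
  aspect <- match.arg(aspect)
  docs <- if (inherits(results, "mir_result")) results$documents
          else results
  fams <- .aspect_families[[aspect]]
  rows <- list()
  for (d in docs) {
    r <- d$relations[d$relations$family %in% fams, , drop = FALSE]
    if (nrow(r) == 0) next
    ent <- d$entities
    look <- function(id, col) {
      v <- ent[[col]][match(id, ent$id)]
      ifelse(is.na(v), "", v)
    }
    detail <- ifelse(r$family == "DISEASE_ROLE", r$role,
              ifelse(r$family == "DIFFEXPR", r$direction,
              ifelse(r$family == "PROCESS", r$relation,
              ifelse(r$family == "EXTRACELLULAR", r$method, r$polarity))))
    partner_id <- ifelse(r$family == "DISEASE_ROLE",
                         ifelse(is.na(r$disease), "", r$disease),
                         look(r$partner, "canonical_id"))
    rows[[length(rows) + 1L]] <- data.frame(
      pmid = d$pmid, sentence_index = r$sentence_index, family = r$family,
      detail = ifelse(is.na(detail), "", detail),
      mirna = look(r$mirna, "canonical_id"),
      mirna_surface = look(r$mirna, "surface"),
      partner_id = partner_id,
      partner_label = ifelse(r$family == "DISEASE_ROLE",
                             look_disease_label(d, r$disease),
                             look(r$partner, "canonical_label")),
      partner_type = r$partner_type, evidence = r$evidence,
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(pmid = character(), sentence_index = integer(),
                      family = character(), detail = character(),
                      mirna = character(), mirna_surface = character(),
                      partner_id = character(), partner_label = character(),
                      partner_type = character(), evidence = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

look_disease_label <- function(d, disease_ids) {
  ent <- d$entities[d$entities$entity_class == "DISEASE", , drop = FALSE]
  v <- ent$canonical_label[match(disease_ids, ent$canonical_id)]
  ifelse(is.na(v), "", v)
}

#' Filter view rows by case-insensitive substring
#'
#' Matches over every character column (or one named column), so a
#' normalized label like "PTEN" retains rows whose mention surfaced as a
#' synonym.  Adding a filter never increases the row count.
#'
#' @param rows A view data.frame from [aspect_view()].
#' @param pattern Substring to look for (fixed, case-insensitive).
#' @param column Optional single column name.
#' @return The filtered data.frame.
#' @export
filter_view <- function(rows, pattern, column = NULL) {
  if (nrow(rows) == 0) return(rows)
  cols <- if (is.null(column)) names(rows)[vapply(rows, is.character,
                                                  logical(1))]
          else column
  hit <- rep(FALSE, nrow(rows))
  for (c in cols)
    hit <- hit | grepl(pattern, rows[[c]], fixed = FALSE,
                       ignore.case = TRUE)
  rows[hit, , drop = FALSE]
}

#' Stable sort of view rows by a column
#'
#' @param rows A view data.frame.
#' @param column Column name.
#' @param decreasing Sort direction.
#' @export
sort_view <- function(rows, column, decreasing = FALSE) {
  if (nrow(rows) == 0) return(rows)
  rows[order(rows[[column]], method = "radix", decreasing = decreasing), ,
       drop = FALSE]
}

#' Summary counts for a corpus index
#'
#' @param index A `mir_index`.
#' @return A list: number of documents; unique miRNA families, genes,
#'   processes, diseases, locations participating in relations; and
#'   relation counts per family.
#' @export
summarize_counts <- function(index) {
  docs <- index$documents
  fam_counts <- c(MIRNA_TARGET = 0L, MIRNA_GENE = 0L, GENE_MIRNA = 0L,
                  PROCESS = 0L, DISEASE_ROLE = 0L, DIFFEXPR = 0L,
                  EXTRACELLULAR = 0L)
  uniq <- list(mirna = character(), gene = character(),
               process = character(), disease = character(),
               location = character())
  for (d in docs) {
    r <- d$relations
    if (nrow(r) == 0) next
    tb <- table(r$family)
    fam_counts[names(tb)] <- fam_counts[names(tb)] + as.integer(tb)
    ent <- d$entities
    used <- unique(c(r$mirna, r$partner))
    sub <- ent[ent$id %in% used, , drop = FALSE]
    cid <- function(cls) unique(stats::na.omit(
      sub$canonical_id[sub$entity_class == cls]))
    uniq$mirna <- union(uniq$mirna, cid("MIRNA"))
    uniq$gene <- union(uniq$gene, cid("GENE"))
    uniq$process <- union(uniq$process, cid("PROCESS"))
    uniq$disease <- union(uniq$disease,
                          unique(stats::na.omit(r$disease)))
    uniq$location <- union(uniq$location,
                           c(cid("FLUID"), cid("TRANSPORTER")))
  }
  list(n_documents = length(docs),
       unique_mirnas = length(uniq$mirna), unique_genes = length(uniq$gene),
       unique_processes = length(uniq$process),
       unique_diseases = length(uniq$disease),
       unique_locations = length(uniq$location),
       relations = as.list(fam_counts))
}
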