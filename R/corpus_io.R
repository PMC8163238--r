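# corpus_io: reading abstracts, sentence splitting with stable character
# offsets, and the document-centric JSON serialization.
#
# A document holds exactly one title, an ordered list of sentences and the
# entity mentions / relations attached to those sentences.  Offsets are
# 0-based half-open Unicode code-point positions.  Sentence offsets index
# into the concatenated title + " " + abstract text; entity offsets index
# into their sentence's text.

.sentence_schema <- c(index = "integer", text = "character",
                      start = "integer", end = "integer")

.entity_schema <- c(id = "character", entity_class = "character",
                    sentence_index = "integer", start = "integer",
                    end = "integer", surface = "character",
                    canonical_id = "character", canonical_label = "character",
                    flags = "character")

.relation_schema <- c(id = "character", family = "character",
                      mirna = "character", partner = "character",
                      partner_type = "character", polarity = "character",
                      role = "character", direction = "character",
                      relation = "character", method = "character",
                      location_class = "character", disease = "character",
                      disease_provenance = "character",
                      sample_descriptor = "character",
                      comparison_descriptor = "character",
                      sentence_index = "integer", mirna_sentence = "integer",
                      location_sentence = "integer", rule_id = "character",
                      evidence = "character")

empty_sentences <- function() canon_df(NULL, .sentence_schema)
empty_entities  <- function() canon_df(NULL, .entity_schema)
empty_relations <- function() canon_df(NULL, .relation_schema)

#' Construct a document
#'
#' @param pmid PubMed identifier (character scalar, preserved verbatim).
#' @param title Article title (character scalar; may be empty).
#' @param sentences Sentence table as returned by [split_sentences()].
#' @param entities Entity mention table (see [annotate_document()]).
#' @param relations Relation table (see [extract_relations()]).
#' @return An object of class `mir_document`.
#' @export
new_document <- function(pmid, title, sentences = empty_sentences(),
                         entities = empty_entities(),
                         relations = empty_relations()) {
  doc <- structure(
    list(pmid = as.character(pmid), title = as.character(title),
         sentences = canon_df(sentences, .sentence_schema),
         entities = canon_df(entities, .entity_schema),
         relations = canon_df(relations, .relation_schema)),
    class = "mir_document")
  validate_document(doc)
  doc
}

#' Validate a document against the schema invariants
#'
#' Checks the one-title rule, contiguous 0-based sentence indices,
#' non-overlapping in-order sentence spans and that every entity/relation
#' references an existing sentence.
#'
#' @param doc A `mir_document`.
#' @return The document, invisibly; stops with a validation error otherwise.
#' @export
validate_document <- function(doc) {
  fail <- function(field, why)
    stop(sprintf("document validation error [%s]: %s", field, why),
         call. = FALSE)
  if (length(doc$pmid) != 1L || is.na(doc$pmid) || !nzchar(doc$pmid))
    fail("pmid", "must be a single non-empty string")
  if (length(doc$title) != 1L || is.na(doc$title))
    fail("title", "exactly one title is required")
  s <- doc$sentences
  if (nrow(s) > 0) {
    if (!identical(s$index, seq_len(nrow(s)) - 1L))
      fail("sentences", "indices must be contiguous 0..n-1")
    if (any(s$end <= s$start)) fail("sentences", "end must exceed start")
    if (nrow(s) > 1 && any(s$start[-1] < s$end[-nrow(s)]))
      fail("sentences", "spans must be non-overlapping and in order")
  }
  for (tbl in c("entities", "relations")) {
    si <- doc[[tbl]]$sentence_index
    if (length(si) && any(!is.na(si) & !(si %in% s$index)))
      fail(tbl, "sentence_index references a missing sentence")
  }
  e <- doc$entities
  if (nrow(e) > 0) {
    len <- n_cp(s$text[match(e$sentence_index, s$index)])
    bad <- e$start < 0 | e$end <= e$start | e$end > len
    if (any(bad)) fail("entities", "offsets out of sentence bounds")
    slice <- substr(s$text[match(e$sentence_index, s$index)],
                    e$start + 1L, e$end)
    if (any(slice != e$surface))
      fail("entities", "surface does not equal the sentence slice")
  }
  invisible(doc)
}

#' @export
print.mir_document <- function(x, ...) {
  cat(sprintf("<mir_document %s: %d sentence(s), %d entit(ies), %d relation(s)>\n",
              x$pmid, nrow(x$sentences), nrow(x$entities), nrow(x$relations)))
  invisible(x)
}

# Abbreviations that must not terminate a sentence.
.abbrev <- c("vs", "e.g", "i.e", "fig", "figs", "et al", "al", "dr", "mr",
             "mrs", "ms", "st", "ca", "cf", "approx", "no", "etc", "ref",
             "refs", "resp", "inc", "spp", "sp")

#' Split text into sentences with character offsets
#'
#' Rule-based splitter: a run of `.`, `!` or `?` followed by whitespace ends
#' a sentence unless the preceding word is a known abbreviation or the next
#' non-space character is lowercase (so "vs. controls" does not split).
#' Offsets are 0-based half-open code points into `text`; slicing `text`
#' with them reproduces each sentence exactly.
#'
#' @param text A character scalar (may be empty).
#' @return A data.frame with columns `index`, `text`, `start`, `end`.
#' @export
split_sentences <- function(text) {
  stopifnot(!is.null(text), length(text) == 1L)
  if (is.na(text) || !nzchar(trimws(text))) return(empty_sentences())
  n <- n_cp(text)
  chars <- strsplit(text, "")[[1]]
  is_ws <- grepl("^\\s$", chars)
  ends <- integer(0)   # 1-based inclusive position of sentence-final punct
  i <- 1L
  while (i <= n) {
    if (chars[i] %in% c(".", "!", "?")) {
      j <- i
      while (j < n && chars[j + 1L] %in% c(".", "!", "?")) j <- j + 1L
      at_end <- j == n
      next_ws <- !at_end && is_ws[j + 1L]
      if (at_end || next_ws) {
        ok <- TRUE
        # abbreviation guard: word immediately before the punctuation
        k <- i - 1L
        while (k >= 1L && !is_ws[k]) k <- k - 1L
        word <- tolower(paste0(chars[seq.int(k + 1L, max(k + 1L, i - 1L))],
                               collapse = ""))
        word <- gsub("^[^a-z0-9.]+", "", word)
        word <- sub("\\.$", "", word)
        if (word %in% .abbrev) ok <- FALSE
        # lowercase-continuation guard; miRNA-style sentence openers
        # ("miR-21 is ...", "let-7b levels ...") are legitimate starts
        if (ok && !at_end) {
          m <- j + 1L
          while (m <= n && is_ws[m]) m <- m + 1L
          if (m <= n && grepl("^[a-z]$", chars[m])) {
            nxt <- paste0(chars[m:min(n, m + 9L)], collapse = "")
            if (!grepl("^([a-z]{3}-)?(mi[rR]|let-7|microRNA|miRNA)", nxt))
              ok <- FALSE
          }
        }
        if (ok) ends <- c(ends, j)
      }
      i <- j + 1L
    } else i <- i + 1L
  }
  if (length(ends) == 0L || ends[length(ends)] < n) {
    # trailing material without final punctuation forms the last sentence
    last_non_ws <- max(which(!is_ws))
    if (length(ends) == 0L || last_non_ws > ends[length(ends)])
      ends <- c(ends, last_non_ws)
  }
  starts <- integer(length(ends))
  prev_end <- 0L
  rows <- vector("list", length(ends))
  for (k in seq_along(ends)) {
    s <- prev_end + 1L
    while (s <= n && is_ws[s]) s <- s + 1L
    starts[k] <- s
    prev_end <- ends[k]
    rows[[k]] <- data.frame(index = k - 1L,
                            text = paste0(chars[s:ends[k]], collapse = ""),
                            start = s - 1L, end = ends[k],
                            stringsAsFactors = FALSE)
  }
  canon_df(do.call(rbind, rows), .sentence_schema)
}

#' Build a document from a pmid, title and abstract
#'
#' The title (when non-empty) becomes sentence 0; abstract sentences follow
#' with offsets into the concatenated `title + " " + abstract` text.
#'
#' @param pmid,title,abstract Character scalars.
#' @return A `mir_document` with empty entity and relation tables.
#' @export
abstract_document <- function(pmid, title, abstract) {
  title <- as.character(title %||% "")
  if (is.na(title)) title <- ""
  abstract <- as.character(abstract %||% "")
  if (nzchar(trimws(title))) {
    shift <- n_cp(title) + 1L
    ab <- split_sentences(abstract)
    ab$start <- ab$start + shift
    ab$end <- ab$end + shift
    sen <- rbind(
      data.frame(index = 0L, text = title, start = 0L, end = n_cp(title),
                 stringsAsFactors = FALSE),
      ab)
    sen$index <- seq_len(nrow(sen)) - 1L
  } else {
    sen <- split_sentences(abstract)
  }
  new_document(pmid, title, sen)
}

# TRUE for the sentence index holding the document title (if any)
title_sentence_index <- function(doc) {
  if (nzchar(doc$title) && nrow(doc$sentences) > 0 &&
      doc$sentences$text[1] == doc$title) 0L else NA_integer_
}

#' Read abstracts from Medline XML or delimited text
#'
#' Two dialects are accepted: a `PubmedArticleSet` Medline XML file, or
#' 3-column tab-separated text (`pmid`, `title`, `abstract`; UTF-8, no
#' header).  Records with an empty abstract are skipped with a warning;
#' duplicate pmids resolve last-wins with a warning.
#'
#' @param path Path to the input file.
#' @param format `"auto"` (default; sniffs for XML), `"tsv"` or `"medline"`.
#' @return A list of `mir_document` (entities/relations empty).
#' @export
read_abstracts <- function(path, format = c("auto", "tsv", "medline")) {
  format <- match.arg(format)
  if (format == "auto") {
    head1 <- readLines(path, n = 1L, warn = FALSE, encoding = "UTF-8")
    format <- if (length(head1) && grepl("^\\s*<", head1)) "medline" else "tsv"
  }
  recs <- if (format == "medline") read_medline_records(path)
          else read_tsv_records(path)
  docs <- list()
  for (r in recs) {
    if (!nzchar(trimws(r$abstract))) {
      warning(sprintf("skipping record %s: empty abstract", r$pmid),
              call. = FALSE)
      next
    }
    if (r$pmid %in% names(docs))
      warning(sprintf("duplicate pmid %s: keeping last record", r$pmid),
              call. = FALSE)
    docs[[r$pmid]] <- abstract_document(r$pmid, r$title, r$abstract)
  }
  unname(docs)
}

read_tsv_records <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  lapply(seq_along(lines), function(i) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2L)
      stop(sprintf("malformed delimited record at line %d: expected 3 fields",
                   i), call. = FALSE)
    list(pmid = parts[1], title = parts[2],
         abstract = if (length(parts) >= 3L) parts[3] else "")
  })
}

read_medline_records <- function(path) {
  xml <- tryCatch(xml2::read_xml(path), error = function(e)
    stop(sprintf("malformed Medline XML in '%s': %s", path,
                 conditionMessage(e)), call. = FALSE))
  arts <- xml2::xml_find_all(xml, ".//PubmedArticle")
  lapply(arts, function(a) {
    pmid <- xml2::xml_text(xml2::xml_find_first(a, ".//MedlineCitation/PMID"))
    title <- xml2::xml_text(xml2::xml_find_first(a, ".//ArticleTitle"))
    abst <- xml2::xml_find_all(a, ".//Abstract/AbstractText")
    list(pmid = pmid, title = title,
         abstract = paste(vapply(abst, xml2::xml_text, ""), collapse = " "))
  })
}

#' Serialize a document to a single-line JSON record
#'
#' @param doc A `mir_document`.
#' @return A character scalar of JSON with fields
#'   `pmid`, `title`, `sentences`, `entities`, `relations`.
#' @export
serialize_document <- function(doc) {
  validate_document(doc)
  obj <- list(pmid = jsonlite::unbox(doc$pmid),
              title = jsonlite::unbox(doc$title),
              sentences = doc$sentences,
              entities = doc$entities,
              relations = doc$relations)
  as.character(jsonlite::toJSON(obj, dataframe = "rows", na = "null",
                                digits = NA))
}

#' Deserialize a JSON record back into a document
#'
#' `deserialize_document(serialize_document(d))` equals `d` field for field.
#' Schema-violating records raise a validation error naming the field.
#'
#' @param record A JSON character scalar.
#' @return A `mir_document`.
#' @export
deserialize_document <- function(record) {
  obj <- jsonlite::fromJSON(record, simplifyDataFrame = TRUE)
  for (field in c("pmid", "title"))
    if (is.null(obj[[field]]))
      stop(sprintf("document validation error [%s]: missing field", field),
           call. = FALSE)
  new_document(obj$pmid, obj$title,
               canon_df(obj$sentences, .sentence_schema),
               canon_df(obj$entities, .entity_schema),
               canon_df(obj$relations, .relation_schema))
}

#' Write / read a JSON-lines corpus
#'
#' One serialized document per line.
#'
#' @param docs List of `mir_document`.
#' @param path Output (or input) file path.
#' @return `read_corpus` returns a list of documents.
#' @export
write_corpus <- function(docs, path) {
  writeLines(vapply(docs, serialize_document, ""), path, useBytes = FALSE)
  invisible(path)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lapply(lines[nzchar(lines)], deserialize_document)
}

#' Export relation rows as a flat table
#'
#' Columns follow the interchange dialect: pmid, sentence_index,
#' relation_family, role_or_direction, mirna_id, partner_id, partner_type,
#' evidence_text.
#'
#' @param docs List of annotated documents.
#' @return A data.frame, one row per relation.
#' @export
relations_table <- function(docs) {
  rows <- lapply(docs, function(d) {
    r <- d$relations
    if (nrow(r) == 0) return(NULL)
    ent <- d$entities
    canon <- function(id) {
      i <- match(id, ent$id)
      out <- ent$canonical_id[i]
      ifelse(is.na(out) | !nzchar(out), id, out)
    }
    rod <- ifelse(r$family == "DISEASE_ROLE", r$role,
           ifelse(r$family == "DIFFEXPR", r$direction,
           ifelse(r$family == "PROCESS", r$relation,
           ifelse(r$family %in% c("MIRNA_GENE", "GENE_MIRNA"), r$polarity, ""))))
    partner <- ifelse(r$family == "DISEASE_ROLE",
                      ifelse(is.na(r$disease), "", r$disease),
                      canon(r$partner))
    data.frame(pmid = d$pmid, sentence_index = r$sentence_index,
               relation_family = r$family,
               role_or_direction = ifelse(is.na(rod), "", rod),
               mirna_id = canon(r$mirna), partner_id = partner,
               partner_type = r$partner_type, evidence_text = r$evidence,
               rule_id = r$rule_id, stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0)
    return(data.frame(pmid = character(), sentence_index = integer(),
                      relation_family = character(),
                      role_or_direction = character(),
                      mirna_id = character(), partner_id = character(),
                      partner_type = character(), evidence_text = character(),
                      rule_id = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' @rdname relations_table
#' @param path Output path for the CSV export.
#' @export
export_relations_csv <- function(docs, path) {
  utils::write.csv(relations_table(docs), path, row.names = FALSE)
  invisible(path)
}
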