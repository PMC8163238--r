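# lexicons: dictionaries for non-miRNA entity recognition/normalization.
#
# A lexicon is a table of (surface, canonical_id, entity_class, source,
# label) rows indexed for case-insensitive, token-boundary, longest-match
# lookup.  "Closest match" is operationalized as exact case-insensitive
# string matching after whitespace normalization; there is no fuzzy
# matching, so lookups are deterministic.

.lexicon_schema <- c(surface = "character", canonical_id = "character",
                     entity_class = "character", source = "character",
                     label = "character", flags = "character")

.class_priority <- c(MIRNA = 0L, GENE = 1L, DISEASE = 2L, PROCESS = 3L,
                     FLUID = 4L, TRANSPORTER = 5L)

#' Construct a lexicon
#'
#' @param entries data.frame with columns `surface`, `canonical_id`,
#'   `entity_class` and optionally `source`, `label`, `flags`.
#' @return An object of class `mir_lexicon`. Surfaces are case-folded and
#'   whitespace-collapsed; duplicate (surface, canonical_id) pairs are
#'   dropped; empty surfaces are an error.
#' @export
new_lexicon <- function(entries) {
  e <- canon_df(entries, .lexicon_schema)
  e$surface <- norm_surface(e$surface)
  if (any(!nzchar(e$surface)))
    stop("lexicon entries must have a non-empty surface", call. = FALSE)
  if (any(is.na(e$canonical_id) | !nzchar(e$canonical_id)))
    stop("lexicon entries must have a canonical_id", call. = FALSE)
  e$source[is.na(e$source)] <- "user"
  e$flags[is.na(e$flags)] <- ""
  # label defaults to the first surface registered for a canonical_id
  first <- !duplicated(e$canonical_id)
  lab <- e$surface[first]
  names(lab) <- e$canonical_id[first]
  e$label <- ifelse(is.na(e$label) | !nzchar(e$label),
                    unname(lab[e$canonical_id]), e$label)
  e <- e[!duplicated(paste(e$surface, e$canonical_id, sep = "\r")), ,
         drop = FALSE]
  rownames(e) <- NULL
  structure(list(entries = e,
                 max_tokens = max(1L, lengths(strsplit(e$surface, " ")))),
            class = "mir_lexicon")
}

#' @export
print.mir_lexicon <- function(x, ...) {
  cat(sprintf("<mir_lexicon: %d entries, classes: %s>\n",
              nrow(x$entries),
              paste(unique(x$entries$entity_class), collapse = ", ")))
  invisible(x)
}

lexicon_entries <- function(lex) {
  if (inherits(lex, "mir_lexicon")) lex$entries else canon_df(lex, .lexicon_schema)
}

#' Merge several lexicons into one
#' @param ... `mir_lexicon` objects.
#' @export
merge_lexicons <- function(...) {
  parts <- lapply(list(...), lexicon_entries)
  new_lexicon(do.call(rbind, parts))
}

#' Mine process terms from cue-plus-list sentence patterns
#'
#' Recognizes a cue phrase ("cellular processes", "biological processes" or
#' "processes") followed by "such as" or "including" and a comma/"and"
#' separated enumeration; every list item is emitted (determiners trimmed).
#'
#' @param sentences Character vector of sentence texts.
#' @return Character vector of candidate process terms (unique, in order of
#'   first appearance).
#' @export
mine_process_terms <- function(sentences) {
  out <- character(0)
  rx <- "(?i)\\b(?:cellular processes|biological processes|processes)\\s*,?\\s*(?:such as|including)\\s+([^.;:]*)"
  for (s in sentences) {
    m <- regmatches(s, gregexpr(rx, s, perl = TRUE))[[1]]
    for (hit in m) {
      tail <- sub(rx, "\\1", hit, perl = TRUE)
      items <- strsplit(tail, "\\s*,\\s*|\\s+and\\s+|\\s+or\\s+",
                        perl = TRUE)[[1]]
      items <- trimws(items)
      items <- sub("^(?:the|a|an)\\s+", "", items, ignore.case = TRUE)
      # a list item ends where a function word starts a trailing modifier
      items <- sub("\\s+(?:in|of|for|with|by|during|via|that|which|to)\\s.*$",
                   "", items, perl = TRUE)
      items <- items[nzchar(items)]
      out <- c(out, items)
    }
  }
  unique(out)
}

#' Build the biological process / pathway lexicon
#'
#' Entries combine term names and synonyms from a Gene Ontology biological
#' process subset and a Pathway Ontology subset, plus terms mined from text
#' with [mine_process_terms()].  Mined terms are normalized to GO/PW by
#' exact (case-insensitive) string matching; terms with no ontology match
#' get a stable `MINED:` slug and source `"mined"`.
#'
#' @param go_obo,pw_obo Parsed ontologies (`parse_obo()`) or file paths.
#' @param mined_terms Character vector (may be empty).
#' @return A `mir_lexicon` with entity class `PROCESS`.
#' @export
build_process_lexicon <- function(go_obo, pw_obo, mined_terms = character(0)) {
  rows <- list()
  add_onto <- function(obo, src) {
    if (is.character(obo)) obo <- parse_obo(obo)
    for (t in obo) {
      if (isTRUE(t$obsolete)) next
      surf <- c(t$name, t$synonyms$text)
      rows[[length(rows) + 1L]] <<- data.frame(
        surface = surf, canonical_id = t$id, entity_class = "PROCESS",
        source = src, label = t$name, flags = "", stringsAsFactors = FALSE)
    }
  }
  add_onto(go_obo, "GO")
  add_onto(pw_obo, "PW")
  onto <- do.call(rbind, rows)
  onto_key <- norm_surface(onto$surface)
  for (term in unique(mined_terms)) {
    key <- norm_surface(term)
    hit <- match(key, onto_key)
    if (!is.na(hit)) {
      rows[[length(rows) + 1L]] <- data.frame(
        surface = term, canonical_id = onto$canonical_id[hit],
        entity_class = "PROCESS", source = "mined",
        label = onto$label[hit], flags = "", stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        surface = term, canonical_id = paste0("MINED:", slugify(term)),
        entity_class = "PROCESS", source = "mined", label = key,
        flags = "", stringsAsFactors = FALSE)
    }
  }
  new_lexicon(do.call(rbind, rows))
}

#' Build the extracellular-location lexicon
#'
#' Biofluids are normalized to BRENDA tissue ontology (BTO) identifiers
#' when an exact case-insensitive name/synonym match exists, else kept with
#' a slug and flagged `unmapped`.  Transporter forms (exosome,
#' microvesicle, ...) keep class `TRANSPORTER`; the transporter table may
#' map surface variants (e.g. "exosomal") onto one canonical form.
#'
#' @param fluid_list Character vector of fluid terms.
#' @param transporter_list Character vector, or 2-column data.frame
#'   (`surface`, `canonical`).
#' @param bto_obo Parsed BTO subset (`parse_obo()`) or path; may be NULL.
#' @return A `mir_lexicon` with classes `FLUID` and `TRANSPORTER`.
#' @export
build_location_lexicon <- function(fluid_list, transporter_list = character(0),
                                   bto_obo = NULL) {
  bto_key <- character(0); bto_id <- character(0); bto_label <- character(0)
  if (!is.null(bto_obo)) {
    if (is.character(bto_obo)) bto_obo <- parse_obo(bto_obo)
    for (t in bto_obo) {
      if (isTRUE(t$obsolete)) next
      surf <- c(t$name, t$synonyms$text)
      bto_key <- c(bto_key, norm_surface(surf))
      bto_id <- c(bto_id, rep(t$id, length(surf)))
      bto_label <- c(bto_label, rep(t$name, length(surf)))
    }
  }
  rows <- list()
  for (f in unique(fluid_list)) {
    hit <- match(norm_surface(f), bto_key)
    if (!is.na(hit)) {
      rows[[length(rows) + 1L]] <- data.frame(
        surface = f, canonical_id = bto_id[hit], entity_class = "FLUID",
        source = "BTO", label = bto_label[hit], flags = "",
        stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        surface = f, canonical_id = paste0("FLUID:", slugify(f)),
        entity_class = "FLUID", source = "list", label = norm_surface(f),
        flags = "unmapped", stringsAsFactors = FALSE)
    }
  }
  if (is.data.frame(transporter_list)) {
    tl <- transporter_list
    names(tl)[1:2] <- c("surface", "canonical")
  } else if (length(transporter_list)) {
    tl <- data.frame(surface = transporter_list,
                     canonical = transporter_list, stringsAsFactors = FALSE)
  } else tl <- NULL
  if (!is.null(tl) && nrow(tl)) {
    rows[[length(rows) + 1L]] <- data.frame(
      surface = tl$surface, canonical_id = slugify(tl$canonical),
      entity_class = "TRANSPORTER", source = "list",
      label = norm_surface(tl$canonical), flags = "",
      stringsAsFactors = FALSE)
  }
  new_lexicon(do.call(rbind, rows))
}

#' Build a gene lexicon from a symbol-to-identifier table
#'
#' @param tab Path to a 2/3-column TSV (`surface`, NCBI Gene ID, optional
#'   preferred label) or an equivalent data.frame.  The first row seen for
#'   an ID defines its label, so list the primary symbol before synonyms.
#' @return A `mir_lexicon` with entity class `GENE`.
#' @export
build_gene_lexicon <- function(tab) {
  if (is.character(tab))
    tab <- utils::read.delim(tab, header = FALSE, stringsAsFactors = FALSE,
                             quote = "", comment.char = "#",
                             fileEncoding = "UTF-8")
  df <- data.frame(surface = tab[[1]], canonical_id = as.character(tab[[2]]),
                   entity_class = "GENE", source = "gene_table",
                   label = if (ncol(tab) >= 3) tab[[3]] else NA_character_,
                   flags = "", stringsAsFactors = FALSE)
  new_lexicon(df)
}

#' Build a disease lexicon keyed to Disease Ontology identifiers
#'
#' @param tab Path to a 2/3-column TSV (`surface`, DOID, optional label) or
#'   an equivalent data.frame.
#' @return A `mir_lexicon` with entity class `DISEASE`.
#' @export
build_disease_lexicon <- function(tab) {
  if (is.character(tab))
    tab <- utils::read.delim(tab, header = FALSE, stringsAsFactors = FALSE,
                             quote = "", comment.char = "#",
                             fileEncoding = "UTF-8")
  df <- data.frame(surface = tab[[1]], canonical_id = as.character(tab[[2]]),
                   entity_class = "DISEASE", source = "disease_table",
                   label = if (ncol(tab) >= 3) tab[[3]] else NA_character_,
                   flags = "", stringsAsFactors = FALSE)
  new_lexicon(df)
}

# Word tokens used for dictionary matching: letter/digit runs that may
# contain internal hyphens and apostrophes ("qRT-PCR", "3'UTR", "TGF-β1").
word_tokens <- function(text) {
  m <- gregexpr("[\\p{L}\\p{N}][\\p{L}\\p{N}'’-]*", text, perl = TRUE)[[1]]
  if (m[1] == -1L)
    return(data.frame(token = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  len <- attr(m, "match.length")
  data.frame(token = regmatches(text, list(m))[[1]],
             start = as.integer(m) - 1L,
             end = as.integer(m) - 1L + len, stringsAsFactors = FALSE)
}

#' Match a lexicon against a sentence
#'
#' Case-insensitive, token-boundary-respecting, longest-match-wins,
#' non-overlapping.  Equal-length overlap ties resolve by the fixed class
#' priority GENE > DISEASE > PROCESS > FLUID > TRANSPORTER, then by
#' position.
#'
#' @param text Sentence text (character scalar).
#' @param lexicon A `mir_lexicon` (possibly multi-class, see
#'   [merge_lexicons()]).
#' @param blocked Optional data.frame with `start`/`end` columns of spans
#'   that must not be overlapped (e.g. miRNA mentions).
#' @return A data.frame of mentions: `start`, `end`, `surface`,
#'   `entity_class`, `canonical_id`, `canonical_label`, `flags`.
#' @export
match_lexicon <- function(text, lexicon, blocked = NULL) {
  toks <- word_tokens(text)
  ent <- lexicon_entries(lexicon)
  none <- data.frame(start = integer(), end = integer(),
                     surface = character(), entity_class = character(),
                     canonical_id = character(), canonical_label = character(),
                     flags = character(), stringsAsFactors = FALSE)
  if (nrow(toks) == 0 || nrow(ent) == 0) return(none)
  max_n <- if (inherits(lexicon, "mir_lexicon")) lexicon$max_tokens
           else max(lengths(strsplit(ent$surface, " ")))
  key <- paste(ent$surface, ent$entity_class, sep = "\r")
  cand <- list()
  ntok <- nrow(toks)
  tok_norm <- tolower(toks$token)
  for (i in seq_len(ntok)) {
    for (j in i:min(ntok, i + max_n - 1L)) {
      k <- paste(tok_norm[i:j], collapse = " ")
      hits <- which(ent$surface == k)
      if (length(hits)) {
        for (h in hits) {
          cand[[length(cand) + 1L]] <- data.frame(
            start = toks$start[i], end = toks$end[j],
            surface = slice_cp(text, toks$start[i], toks$end[j]),
            entity_class = ent$entity_class[h],
            canonical_id = ent$canonical_id[h],
            canonical_label = ent$label[h], flags = ent$flags[h],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(cand) == 0) return(none)
  cand <- do.call(rbind, cand)
  cand$len <- cand$end - cand$start
  cand$prio <- .class_priority[cand$entity_class]
  cand <- cand[order(-cand$len, cand$start, cand$prio, method = "radix"), ,
               drop = FALSE]
  taken <- if (!is.null(blocked) && nrow(blocked))
    data.frame(start = blocked$start, end = blocked$end) else
    data.frame(start = integer(), end = integer())
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    s <- cand$start[r]; e <- cand$end[r]
    if (!any(s < taken$end & e > taken$start)) {
      keep[r] <- TRUE
      taken <- rbind(taken, data.frame(start = s, end = e))
    }
  }
  out <- cand[keep, c("start", "end", "surface", "entity_class",
                      "canonical_id", "canonical_label", "flags")]
  out <- stable_order(out, "start")
  rownames(out) <- NULL
  out
}
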