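# Minimal OBO 1.2/1.4 flat-file parser.  Only the fields the lexicon
# builders need are retained: id, name, synonyms (with scope), xrefs and
# namespace.  No pre-installed R package parses OBO, so this is kept
# in-package and deliberately small.

#' Parse an OBO flat file
#'
#' @param path Path to an OBO 1.2/1.4 file.
#' @return A list of class `mir_obo`: one element per `[Term]` stanza with
#'   fields `id`, `name`, `synonyms` (data.frame text/scope), `xrefs`
#'   (character), `namespace`, `obsolete`.
#' @export
parse_obo <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  terms <- list()
  cur <- NULL
  stanza_line <- 0L
  flush <- function(cur) {
    if (is.null(cur)) return(NULL)
    if (is.null(cur[["id"]]) || is.null(cur[["name"]]))
      stop(sprintf("unparseable OBO stanza starting at line %d: missing %s",
                   cur$line, if (is.null(cur[["id"]])) "id" else "name"),
           call. = FALSE)
    cur
  }
  in_term <- FALSE
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (grepl("^\\[", ln)) {
      t <- flush(if (in_term) cur else NULL)
      if (!is.null(t)) terms[[length(terms) + 1L]] <- t
      in_term <- identical(trimws(ln), "[Term]")
      cur <- list(line = i, synonyms = character(0), scopes = character(0),
                  xrefs = character(0), namespace = NA_character_,
                  obsolete = FALSE)
      next
    }
    if (!in_term || !nzchar(trimws(ln))) next
    m <- regmatches(ln, regexec("^([A-Za-z_]+):\\s*(.*)$", ln))[[1]]
    if (length(m) < 3) next
    key <- m[2]; val <- trimws(m[3])
    val <- sub("\\s*!.*$", "", val)   # trailing comments
    if (key == "id") cur$id <- val
    else if (key == "name") cur$name <- val
    else if (key == "namespace") cur$namespace <- val
    else if (key == "is_obsolete") cur$obsolete <- identical(val, "true")
    else if (key == "synonym") {
      sm <- regmatches(val, regexec('^"((?:[^"\\\\]|\\\\.)*)"\\s*([A-Z_]*)',
                                    val))[[1]]
      if (length(sm) >= 2) {
        txt <- gsub('\\\\(.)', "\\1", sm[2])
        cur$synonyms <- c(cur$synonyms, txt)
        cur$scopes <- c(cur$scopes,
                        if (length(sm) >= 3 && nzchar(sm[3])) sm[3]
                        else "RELATED")
      }
    } else if (key == "xref") cur$xrefs <- c(cur$xrefs, val)
  }
  t <- flush(if (in_term) cur else NULL)
  if (!is.null(t)) terms[[length(terms) + 1L]] <- t
  terms <- lapply(terms, function(t) {
    t$synonyms <- data.frame(text = t$synonyms, scope = t$scopes,
                             stringsAsFactors = FALSE)
    t$scopes <- NULL
    t
  })
  structure(terms, class = "mir_obo")
}

#' Map MeSH identifiers to Disease Ontology identifiers via xrefs
#'
#' Each MeSH ID maps to the set of DOIDs whose `xref` lines cite it; IDs
#' cited by several DOIDs keep all of them (no arbitration).
#'
#' @param mesh_ids Character vector of MeSH identifiers (e.g. `"MESH:D005909"`;
#'   a bare `"D005909"` is also accepted).
#' @param doid_obo A parsed Disease Ontology (`parse_obo()` result) or a path.
#' @return A list with `mapped` (named list MeSH ID -> character vector of
#'   DOIDs) and `unmapped` (character vector).
#' @export
map_mesh_to_doid <- function(mesh_ids, doid_obo) {
  if (is.character(doid_obo)) doid_obo <- parse_obo(doid_obo)
  xref_map <- list()
  for (t in doid_obo) {
    if (isTRUE(t$obsolete)) next
    mesh <- grep("^MESH:", t$xrefs, value = TRUE)
    for (x in mesh) xref_map[[x]] <- c(xref_map[[x]], t$id)
  }
  key <- ifelse(grepl("^MESH:", mesh_ids), mesh_ids,
                paste0("MESH:", mesh_ids))
  mapped <- list(); unmapped <- character(0)
  for (i in seq_along(mesh_ids)) {
    hit <- xref_map[[key[i]]]
    if (is.null(hit)) unmapped <- c(unmapped, mesh_ids[i])
    else mapped[[mesh_ids[i]]] <- sort(unique(hit))
  }
  list(mapped = mapped, unmapped = unmapped)
}
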