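# ner_mirna: regular-expression detection of miRNA mentions and
# normalization to miRBase-style family identifiers.
#
# Accepted surface dialects include miR-21, mir-21, miRNA-21, microRNA-21,
# MicroRNA 21, hsa-miR-21, let-7b, let-7b-5p, miR-17-5p, miR-125b-1, with
# space/en-dash separators and OCR-split paralog letters ("miR-30 c").
# Enumerations distribute the shared prefix: "miR-19a/b" -> miR-19a,
# miR-19b; "miR-10a/10b" -> miR-10a, miR-10b.  Cluster notations like
# miR-17-92 are detected and flagged `cluster` but excluded from family
# normalization.

# paralog letter: optional single lowercase letter, possibly OCR-separated
# by one space, never the start of a longer word
.mir_letter <- "(?: ?[a-z](?![\\p{L}\\p{N}]))?"
.mir_tail <- "(?:-\\d+)?(?:-[35]p)?"

.mir_core <- paste0(
  "(?:[A-Za-z]{3}-)?",                       # species prefix (hsa-, mmu-, ...)
  "(?:micro[ -]?RNA[s]?|miRNA[s]?|miR)",     # head token
  "[-– ]?\\d+", .mir_letter, .mir_tail)

.let_core <- paste0("(?:[A-Za-z]{3}-)?let[-– ]?7", .mir_letter,
                    "(?:-[35]p)?")

.mir_rx <- paste0("(?<![\\p{L}\\p{N}-])(?:", .mir_core, "|", .let_core,
                  ")(?![\\p{L}\\p{N}])")

# shorthand enumeration item following "/": "b", "10b", "222", "19b-5p"
.enum_rx <- "^\\s*/\\s*(\\d+[a-z]?(?:-[35]p)?|[a-z])(?![\\p{L}\\p{N}])"

#' Detect miRNA mentions in a sentence
#'
#' @param text Sentence text (character scalar).
#' @return A data.frame with one row per mention: `start`, `end` (0-based
#'   half-open code points), `surface` (the exact sentence slice), `name`
#'   (the full reconstructed miRNA name, equal to `surface` except for
#'   expanded enumeration items), `flags` (comma-separated; may contain
#'   `enum` and/or `cluster`).
#' @export
detect_mirna_mentions <- function(text) {
  none <- data.frame(start = integer(), end = integer(),
                     surface = character(), name = character(),
                     flags = character(), stringsAsFactors = FALSE)
  if (is.na(text) || !nzchar(text)) return(none)
  m <- gregexpr(.mir_rx, text, perl = TRUE, ignore.case = TRUE)[[1]]
  if (m[1] == -1L) return(none)
  len <- attr(m, "match.length")
  rows <- list()
  nct <- n_cp(text)
  for (k in seq_along(m)) {
    s0 <- as.integer(m[k]) - 1L
    e0 <- s0 + len[k]
    surf <- slice_cp(text, s0, e0)
    rows[[length(rows) + 1L]] <- data.frame(
      start = s0, end = e0, surface = surf, name = surf,
      flags = mirna_flags(surf), stringsAsFactors = FALSE)
    # shorthand enumeration items ("/b", "/10b") share the base's prefix
    base <- surf
    pos <- e0
    repeat {
      rest <- slice_cp(text, pos, nct)
      em <- regmatches(rest, regexec(.enum_rx, rest, perl = TRUE))[[1]]
      if (length(em) == 0) break
      item <- em[2]
      whole <- em[1]
      item_start <- pos + n_cp(whole) - n_cp(item)
      item_end <- pos + n_cp(whole)
      name <- expand_enum_item(base, item)
      rows[[length(rows) + 1L]] <- data.frame(
        start = item_start, end = item_end,
        surface = slice_cp(text, item_start, item_end), name = name,
        flags = paste0("enum", flag_suffix(mirna_flags(name))),
        stringsAsFactors = FALSE)
      pos <- item_end
    }
  }
  out <- do.call(rbind, rows)
  out <- stable_order(out, "start")
  rownames(out) <- NULL
  out
}

flag_suffix <- function(f) if (nzchar(f)) paste0(",", f) else ""

# cluster: a letterless base followed by a >=2-digit trailing numeral
# (miR-17-92); single trailing digits after a letterless base are treated
# as genomic copies (miR-1-2).
mirna_flags <- function(name) {
  s <- tolower(name)
  s <- gsub("–", "-", s)
  s <- sub("-[35]p$", "", s)
  if (grepl("\\d-\\d{2,}$", s)) "cluster" else ""
}

# Replace or extend the numeric/letter tail of `base` with enumeration item
expand_enum_item <- function(base, item) {
  if (grepl("^[a-z]$", item)) {
    # single letter: replace the paralog letter of the base
    core <- sub("(?: ?[a-z])?(-[35]p)?$", "", base, perl = TRUE)
    return(paste0(core, item))
  }
  # number(+letter)(+arm): distribute the head prefix up to the number
  head <- sub("([-– ]?)\\d+.*$", "\\1", base, perl = TRUE)
  paste0(head, item)
}

#' Normalize an miRNA surface form to its miRBase-style family identifier
#'
#' Applies, in order: case folding; en-dash/space repair (including
#' OCR-split paralog letters such as "miR-30 c"); species-prefix stripping
#' (3-letter code + hyphen); head-token mapping (miR / miRNA / microRNA ->
#' "mir"); arm-suffix stripping (-5p/-3p); genomic-copy stripping
#' (mir-125b-1 -> mir-125b).  Paralog letters are preserved (mir-18a and
#' mir-18b stay distinct).  The function is idempotent.
#'
#' @param surface A surface form produced by [detect_mirna_mentions()] (or
#'   matching its dialects).
#' @return Canonical family identifier, e.g. `"mir-21"` or `"let-7b"`.
#'   Unparseable surfaces (including cluster notations) raise an error of
#'   class `mirna_normalization_error`.
#' @export
normalize_mirna <- function(surface) {
  s <- tolower(trimws(surface))
  s <- gsub("–", "-", s)
  s <- gsub("(\\d) ([a-z])\\b", "\\1\\2", s, perl = TRUE)  # OCR split letter
  s <- gsub("\\s+", "-", s)
  s <- sub("^[a-z]{3}-(?=(?:micro-?rna|mirna|mir|let)\\b|(?:micro-?rna|mirna|mir|let)-?\\d)",
           "", s, perl = TRUE)
  s <- sub("^(?:micro-?rna|mirna|mir)s?-?", "mir-", s, perl = TRUE)
  s <- sub("^let-?", "let-", s, perl = TRUE)
  s <- sub("-[35]p$", "", s)
  s <- sub("(?<=\\d[a-z])-\\d+$", "", s, perl = TRUE)    # copy after paralog letter
  s <- sub("^((?:mir|let)-\\d+)-\\d$", "\\1", s)         # single-digit copy
  if (!grepl("^(mir-\\d+[a-z]?|let-7[a-z]?)$", s))
    stop(structure(class = c("mirna_normalization_error", "error",
                             "condition"),
                   list(message = sprintf(
                     "cannot normalize miRNA surface '%s'", surface),
                     call = NULL)))
  s
}

# Vectorized, NA on failure (used by the annotator, which keeps failed
# mentions flagged `unmapped` rather than dropping them).
normalize_mirna_or_na <- function(surfaces) {
  vapply(surfaces, function(s)
    tryCatch(normalize_mirna(s), error = function(e) NA_character_),
    "", USE.NAMES = FALSE)
}
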