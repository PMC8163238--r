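# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

collapse_ws <- function(x) gsub("\\s+", " ", trimws(x))

#' @noRd
norm_surface <- function(x) tolower(collapse_ws(x))

# Stable lowercase slug for terms that have no ontology identifier.
slugify <- function(x) {
  s <- tolower(trimws(x))
  s <- gsub("[^a-z0-9]+", "-", s)
  gsub("^-+|-+$", "", s)
}

# Character-count (code point) substring with 0-based half-open offsets,
# the offset convention used throughout the package.
slice_cp <- function(text, start, end) substr(text, start + 1L, end)

n_cp <- function(text) nchar(text, type = "chars")

# Strip leading/trailing punctuation from a token (keeps internal hyphens,
# apostrophes and Greek letters).
strip_punct <- function(tok) {
  gsub("^[^\\p{L}\\p{N}]+|[^\\p{L}\\p{N}]+$", "", tok, perl = TRUE)
}

# Coerce a data.frame (possibly NULL / empty list from JSON) to a fixed
# column schema. `schema` is a named character vector column -> type.
canon_df <- function(df, schema) {
  if (is.null(df) || (is.list(df) && !is.data.frame(df) && length(df) == 0)) {
    df <- data.frame()
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  out <- vector("list", length(schema))
  names(out) <- names(schema)
  n <- nrow(df)
  for (col in names(schema)) {
    v <- if (col %in% names(df)) df[[col]] else rep(NA, n)
    out[[col]] <- switch(schema[[col]],
      character = as.character(v),
      integer   = as.integer(v),
      numeric   = as.numeric(v),
      logical   = as.logical(v),
      v
    )
  }
  res <- as.data.frame(out, stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

# deterministic ordering helper: order by multiple columns, stable
stable_order <- function(df, cols, decreasing = FALSE) {
  if (nrow(df) == 0) return(df)
  args <- lapply(cols, function(c) df[[c]])
  idx <- do.call(order, c(args, list(method = "radix", decreasing = decreasing)))
  df[idx, , drop = FALSE]
}
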