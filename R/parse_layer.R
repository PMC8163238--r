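# parse_layer: the syntactic abstraction shared by all relation
# extractors.
#
# Two compliance levels: (A) "full", where arcs come from a user-supplied
# dependency-parser backend, and (B) "degraded", a linear chain graph
# (token i -> i+1) used when no parser is configured.  Every pattern rule
# runs under level B with token-window semantics, so the package is fully
# functional offline; a parser backend can only tighten matching.

#' Build a parse graph for a sentence
#'
#' Tokens are maximal non-whitespace runs (they tile the sentence's
#' non-whitespace text).  With the default chain backend the graph has
#' exactly n-1 arcs.
#'
#' @param text Sentence text.
#' @param backend `NULL` for the level-B chain graph, or a function
#'   `function(tokens) -> data.frame(from, to, label)` supplying dependency
#'   arcs over 1-based token indices.  A failing backend falls back to the
#'   chain with a warning.
#' @param sentence_index Ordinal stored on the graph.
#' @return An object of class `mir_parse`: list(tokens, arcs, level,
#'   sentence_index).
#' @export
build_parse <- function(text, backend = NULL, sentence_index = NA_integer_) {
  m <- gregexpr("\\S+", text, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    tokens <- data.frame(token = character(), start = integer(),
                         end = integer(), stringsAsFactors = FALSE)
  } else {
    len <- attr(m, "match.length")
    tokens <- data.frame(token = regmatches(text, list(m))[[1]],
                         start = as.integer(m) - 1L,
                         end = as.integer(m) - 1L + len,
                         stringsAsFactors = FALSE)
  }
  n <- nrow(tokens)
  chain <- if (n > 1L)
    data.frame(from = seq_len(n - 1L), to = 2:n, label = "next",
               stringsAsFactors = FALSE)
  else data.frame(from = integer(), to = integer(), label = character(),
                  stringsAsFactors = FALSE)
  level <- "B"; arcs <- chain
  if (!is.null(backend)) {
    arcs2 <- tryCatch(backend(tokens), error = function(e) {
      warning("parse backend failed; falling back to chain graph: ",
              conditionMessage(e), call. = FALSE)
      NULL
    })
    if (!is.null(arcs2) && nrow(arcs2) > 0) {
      bad <- arcs2$from < 1 | arcs2$from > n | arcs2$to < 1 | arcs2$to > n
      if (any(bad)) {
        warning("parse backend returned invalid arcs; falling back to chain",
                call. = FALSE)
      } else {
        arcs <- arcs2; level <- "A"
      }
    }
  }
  structure(list(tokens = tokens, arcs = arcs, level = level,
                 sentence_index = sentence_index, text = text),
            class = "mir_parse")
}

#' Undirected shortest-path length between two tokens
#'
#' Breadth-first search over the arc set; unreachable pairs return `Inf`.
#'
#' @param graph A `mir_parse`.
#' @param i,j 1-based token indices.
#' @return Path length (0 when `i == j`; `Inf` when disconnected).
#' @export
shortest_path <- function(graph, i, j) {
  n <- nrow(graph$tokens)
  stopifnot(i >= 1, i <= n, j >= 1, j <= n)
  if (i == j) return(0)
  adj <- vector("list", n)
  for (k in seq_len(nrow(graph$arcs))) {
    f <- graph$arcs$from[k]; t <- graph$arcs$to[k]
    adj[[f]] <- c(adj[[f]], t); adj[[t]] <- c(adj[[t]], f)
  }
  dist <- rep(Inf, n); dist[i] <- 0
  frontier <- i
  while (length(frontier)) {
    nxt <- integer(0)
    for (v in frontier) for (w in adj[[v]]) if (is.infinite(dist[w])) {
      dist[w] <- dist[v] + 1
      if (w == j) return(dist[w])
      nxt <- c(nxt, w)
    }
    frontier <- nxt
  }
  Inf
}

# ---- lemma matching -------------------------------------------------------
# Deterministic suffix handling via a fixed inflection table generated from
# the trigger vocabulary (not a full lemmatizer).

inflect_forms <- function(base) {
  f <- c(base, paste0(base, "s"), paste0(base, "es"), paste0(base, "ed"),
         paste0(base, "ing"))
  if (grepl("e$", base)) {
    stem <- sub("e$", "", base)
    f <- c(f, paste0(base, "d"), paste0(stem, "ing"))
  }
  if (grepl("y$", base)) {
    stem <- sub("y$", "", base)
    f <- c(f, paste0(stem, "ies"), paste0(stem, "ied"))
  }
  if (grepl("[^aeiou][aeiou][^aeiouwxy]$", base)) {
    last <- substr(base, nchar(base), nchar(base))
    f <- c(f, paste0(base, last, "ing"), paste0(base, last, "ed"))
  }
  unique(f)
}

# named vector: inflected form -> base lemma
lemma_table <- function(bases) {
  forms <- lapply(bases, inflect_forms)
  stats::setNames(rep(bases, lengths(forms)), unlist(forms))
}

# Lemma of a raw token under a lemma table (surrounding punctuation
# stripped, case folded; unknown forms map to themselves).
token_lemma <- function(tok, table) {
  t <- tolower(strip_punct(tok))
  hit <- table[t]
  ifelse(is.na(hit), t, hit)
}

.negation_lemmas <- c("not", "no", "neither", "fail", "never", "cannot")

# TRUE when a negation token governs / immediately precedes token t
# (within 3 tokens under level B)
negated_trigger <- function(graph, t, table) {
  lo <- max(1L, t - 3L)
  if (lo >= t) return(FALSE)
  lem <- token_lemma(graph$tokens$token[lo:(t - 1L)], table)
  any(lem %in% .negation_lemmas)
}

#' Construct a declarative pattern rule
#'
#' @param rule_id Identifier string.
#' @param trigger Character vector of trigger lemmas.
#' @param slots Named character vector: slot role -> required entity class
#'   (e.g. `c(mirna = "MIRNA", gene = "GENE")`).
#' @param path_bound Maximum dependency-path length (level A), default 4.
#' @param window Token-window bound (level B fallback), default 8; must be
#'   >= `path_bound`.
#' @param tag Output polarity/role tag carried on matches.
#' @param negation_guard Suppress matches with a negated trigger
#'   (default TRUE).
#' @return A list of class `mir_rule`.
#' @export
pattern_rule <- function(rule_id, trigger, slots, path_bound = 4L,
                         window = 8L, tag = NA_character_,
                         negation_guard = TRUE) {
  stopifnot(length(slots) >= 1L, path_bound >= 1L, window >= path_bound)
  structure(list(rule_id = rule_id, trigger = trigger, slots = slots,
                 path_bound = as.integer(path_bound),
                 window = as.integer(window), tag = tag,
                 negation_guard = isTRUE(negation_guard)),
            class = "mir_rule")
}

#' Load pattern rules from a declarative TSV file
#'
#' Columns: `rule_id`, `trigger` (comma-separated lemmas), `slots`
#' (comma-separated `role:CLASS` pairs), `path_bound`, `window`, `tag`,
#' `negation_guard` (`true`/`false`).
#'
#' @param path TSV file path.
#' @return A list of `mir_rule`.
#' @export
load_rules <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          quote = "", comment.char = "#",
                          fileEncoding = "UTF-8")
  lapply(seq_len(nrow(df)), function(i) {
    slots_raw <- strsplit(df$slots[i], ",", fixed = TRUE)[[1]]
    parts <- strsplit(trimws(slots_raw), ":", fixed = TRUE)
    slots <- stats::setNames(vapply(parts, `[`, "", 2),
                             vapply(parts, `[`, "", 1))
    pattern_rule(df$rule_id[i],
                 trimws(strsplit(df$trigger[i], ",", fixed = TRUE)[[1]]),
                 slots, path_bound = df$path_bound[i], window = df$window[i],
                 tag = as.character(df$tag[i]),
                 negation_guard = tolower(df$negation_guard[i]) %in%
                   c("true", "1", "yes"))
  })
}

# token index whose span contains the mention start (mentions carry
# sentence-relative char offsets)
mention_token <- function(graph, start) {
  hit <- which(graph$tokens$start <= start & graph$tokens$end > start)
  if (length(hit)) hit[1] else NA_integer_
}

# first and last token index covered by a [start,end) span
mention_token_range <- function(graph, start, end) {
  covered <- which(graph$tokens$end > start & graph$tokens$start < end)
  if (!length(covered)) return(c(NA_integer_, NA_integer_))
  c(min(covered), max(covered))
}

# token indices covered by any mention token range (a trigger or aspect
# keyword inside an entity mention is part of that argument, not a
# predicate - argument-type separation)
covered_tokens <- function(ranges) {
  unique(unlist(lapply(ranges, function(r)
    if (any(is.na(r))) integer(0) else r[1]:r[2])))
}

# token distance between a token index and a mention token range
range_distance <- function(t, range) {
  if (any(is.na(range))) return(Inf)
  if (t < range[1]) range[1] - t
  else if (t > range[2]) t - range[2]
  else 0L
}

# Expand a set of accepted mentions along conjunction chains: a mention of
# the same class separated from an accepted one only by commas,
# "and"/"or"/"as well as" tokens or other mentions of that class joins the
# set (coordination distributes over conjoined argument lists).
.conj_tokens <- c("and", "or", "as", "well", "plus", ",", "/")

expand_conjuncts <- function(graph, mentions, accepted_idx) {
  if (!length(accepted_idx)) return(accepted_idx)
  cls <- mentions$entity_class[accepted_idx[1]]
  same <- which(mentions$entity_class == cls)
  ranges <- lapply(same, function(i)
    mention_token_range(graph, mentions$start[i], mentions$end[i]))
  names(ranges) <- as.character(same)
  tok_ok <- function(a, b) {
    # tokens strictly between ranges a and b are all connective
    lo <- min(a[2], b[2]) + 1L; hi <- max(a[1], b[1]) - 1L
    if (lo > hi) return(TRUE)
    raw <- graph$tokens$token[lo:hi]
    all(tolower(strip_punct(raw)) %in% c(.conj_tokens, "") |
          tolower(raw) %in% .conj_tokens)
  }
  acc <- intersect(accepted_idx, same)
  repeat {
    added <- FALSE
    for (i in setdiff(same, acc)) {
      for (j in acc) {
        if (tok_ok(ranges[[as.character(i)]], ranges[[as.character(j)]])) {
          acc <- c(acc, i); added <- TRUE; break
        }
      }
    }
    if (!added) break
  }
  sort(unique(c(accepted_idx, acc)))
}

#' Match a pattern rule against a parsed sentence
#'
#' A match requires a trigger token whose lemma is in the rule's trigger
#' set and, for each slot, a mention of the required class whose head
#' token lies within the path bound (level A) or token-window bound
#' (level B) of the trigger.  With `conj_expand = TRUE` (the default) a
#' slot that matched at least one mention also accepts mentions of the
#' same class reachable through conjunction chains (comma/"and" lists),
#' so coordination distributes.  Negated triggers (a negation token within
#' 3 tokens before the trigger) are suppressed when the rule asks for it.
#' All slot-filler combinations are returned, deterministically ordered.
#'
#' @param rule A `mir_rule`.
#' @param graph A `mir_parse` for the sentence.
#' @param mentions Mention data.frame with at least `id`, `entity_class`,
#'   `start`, `end` (sentence-relative offsets).
#' @param lemma_tab Optional custom lemma table; defaults to one generated
#'   from the rule's trigger lemmas.
#' @param conj_expand Expand slot fillers along conjunction chains.
#' @return A data.frame with columns `rule_id`, `trigger_index`, `tag` and
#'   one column per slot role holding the filling mention id.
#' @export
match_rule <- function(rule, graph, mentions, lemma_tab = NULL,
                       conj_expand = TRUE) {
  roles <- names(rule$slots)
  none <- do.call(data.frame, c(
    list(rule_id = character(), trigger_index = integer(),
         tag = character(), stringsAsFactors = FALSE),
    stats::setNames(rep(list(character()), length(roles)), roles)))
  n <- nrow(graph$tokens)
  if (n == 0 || nrow(mentions) == 0) return(none)
  if (is.null(lemma_tab)) lemma_tab <- lemma_table(rule$trigger)
  lems <- token_lemma(graph$tokens$token, lemma_tab)
  trig <- which(lems %in% rule$trigger)
  if (!length(trig)) return(none)
  ranges <- lapply(seq_len(nrow(mentions)), function(i)
    mention_token_range(graph, mentions$start[i], mentions$end[i]))
  trig <- setdiff(trig, covered_tokens(ranges))
  out <- list()
  for (t in trig) {
    if (rule$negation_guard && negated_trigger(graph, t, lemma_tab)) next
    fillers <- list()
    ok <- TRUE
    for (r in roles) {
      cls <- rule$slots[[r]]
      cand <- which(mentions$entity_class == cls)
      within <- cand[vapply(cand, function(i) {
        d <- if (graph$level == "A") {
          h <- ranges[[i]][1]
          if (is.na(h)) Inf else min(shortest_path(graph, t, h),
                                     shortest_path(graph, t, ranges[[i]][2]))
        } else range_distance(t, ranges[[i]])
        d <= (if (graph$level == "A") rule$path_bound else rule$window)
      }, logical(1))]
      if (conj_expand && length(within))
        within <- expand_conjuncts(graph, mentions, within)
      if (!length(within)) { ok <- FALSE; break }
      fillers[[r]] <- within
    }
    if (!ok) next
    combos <- expand.grid(fillers, KEEP.OUT.ATTRS = FALSE,
                          stringsAsFactors = FALSE)
    # distinct mentions across slots
    if (ncol(combos) > 1) {
      keep <- apply(combos, 1, function(row) !anyDuplicated(row))
      combos <- combos[keep, , drop = FALSE]
    }
    for (k in seq_len(nrow(combos))) {
      row <- c(list(rule_id = rule$rule_id, trigger_index = t,
                    tag = rule$tag),
               stats::setNames(
                 lapply(roles, function(r) mentions$id[combos[k, r]]),
                 roles))
      out[[length(out) + 1L]] <- as.data.frame(row, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(none)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
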