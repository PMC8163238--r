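test_that("build_parse produces tiling tokens and a chain graph", {
  g <- build_parse("one")
  expect_identical(nrow(g$tokens), 1L)
  expect_identical(nrow(g$arcs), 0L)

  g <- build_parse("five tokens in this sentence")
  expect_identical(nrow(g$arcs), nrow(g$tokens) - 1L)
  expect_identical(g$level, "B")
  # tokens tile the non-whitespace text
  txt <- "a bb  ccc"
  g <- build_parse(txt)
  covered <- unlist(lapply(seq_len(nrow(g$tokens)), function(i)
    seq(g$tokens$start[i] + 1L, g$tokens$end[i])))
  nonws <- which(strsplit(txt, "")[[1]] != " ")
  expect_identical(sort(covered), nonws)
})

test_that("shortest_path is BFS with an Inf sentinel", {
  g <- build_parse("a b c d")
  expect_identical(shortest_path(g, 2, 3), 1)
  expect_identical(shortest_path(g, 2, 2), 0)
  expect_identical(shortest_path(g, 1, 4), 3)
  # disconnected custom backend
  backend <- function(tokens) data.frame(from = 1L, to = 2L, label = "dep")
  g2 <- build_parse("a b c d", backend = backend)
  expect_identical(g2$level, "A")
  expect_identical(shortest_path(g2, 3, 4), Inf)
})

test_that("failing backends fall back to the chain with a warning", {
  backend <- function(tokens) stop("boom")
  expect_warning(g <- build_parse("a b c", backend = backend),
                 "falling back")
  expect_identical(g$level, "B")
  expect_identical(nrow(g$arcs), 2L)
})

mk_mentions <- function(graph, spec) {
  # spec: list(list(class=, token=)) -> mention df over whole tokens
  rows <- lapply(seq_along(spec), function(i) {
    t <- spec[[i]]$token
    data.frame(id = paste0("E", i), entity_class = spec[[i]]$class,
               start = graph$tokens$start[t], end = graph$tokens$end[t],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

test_that("match_rule fires triggers with class-constrained slots", {
  rule <- pattern_rule("r1", "target", c(mirna = "MIRNA", gene = "GENE"),
                       window = 5L, tag = "t")
  g <- build_parse("miR-21 directly targets PTEN here")
  men <- mk_mentions(g, list(list(class = "MIRNA", token = 1L),
                             list(class = "GENE", token = 4L)))
  m <- match_rule(rule, g, men)
  expect_identical(nrow(m), 1L)
  expect_identical(m$mirna, "E1")
  expect_identical(m$gene, "E2")

  # negation guard suppresses the match
  g2 <- build_parse("miR-21 does not target PTEN here")
  men2 <- mk_mentions(g2, list(list(class = "MIRNA", token = 1L),
                               list(class = "GENE", token = 5L)))
  expect_identical(nrow(match_rule(rule, g2, men2)), 0L)
  # ... unless the guard is off
  rule_ng <- pattern_rule("r1", "target", c(mirna = "MIRNA", gene = "GENE"),
                          window = 5L, negation_guard = FALSE)
  expect_identical(nrow(match_rule(rule_ng, g2, men2)), 1L)
})

test_that("all slot assignments are enumerated", {
  rule <- pattern_rule("r2", "suppress", c(mirna = "MIRNA", gene = "GENE"),
                       window = 6L)
  g <- build_parse("miR-1 and miR-2 suppress PTEN strongly")
  men <- mk_mentions(g, list(list(class = "MIRNA", token = 1L),
                             list(class = "MIRNA", token = 3L),
                             list(class = "GENE", token = 5L)))
  m <- match_rule(rule, g, men)
  expect_identical(nrow(m), 2L)
  expect_setequal(m$mirna, c("E1", "E2"))
  expect_identical(unique(m$gene), "E3")
})

test_that("level-B match_rule equals an independent window matcher", {
  # independent implementation: pure token-window check, no conjunction
  # expansion
  window_oracle <- function(trigger_lemmas, window, tokens, mentions) {
    tab <- mirlit:::lemma_table(trigger_lemmas)
    lems <- mirlit:::token_lemma(tokens$token, tab)
    hits <- list()
    covered <- unlist(lapply(seq_len(nrow(mentions)), function(i) {
      r <- which(tokens$end > mentions$start[i] &
                 tokens$start < mentions$end[i])
      r
    }))
    for (t in which(lems %in% trigger_lemmas)) {
      if (t %in% covered) next
      lo <- max(1, t - 3)
      if (lo < t && any(mirlit:::token_lemma(tokens$token[lo:(t - 1)], tab)
                        %in% mirlit:::.negation_lemmas)) next
      for (i in seq_len(nrow(mentions))) {
        r <- which(tokens$end > mentions$start[i] &
                   tokens$start < mentions$end[i])
        d <- if (t < min(r)) min(r) - t else if (t > max(r)) t - max(r) else 0
        if (d <= window)
          hits[[length(hits) + 1L]] <- c(t = t, i = i)
      }
    }
    hits
  }
  set.seed(11)
  vocab <- c("mirA", "geneB", "suppresses", "the", "and", "in", "cells",
             "not", "strongly", "geneC")
  for (rep in 1:30) {
    toks <- sample(vocab, sample(5:12, 1), replace = TRUE)
    txt <- paste(toks, collapse = " ")
    g <- build_parse(txt)
    ment_at <- which(toks %in% c("mirA", "geneB", "geneC"))
    if (length(ment_at) == 0) next
    men <- do.call(rbind, lapply(seq_along(ment_at), function(k) {
      t <- ment_at[k]
      data.frame(id = paste0("E", k),
                 entity_class = if (toks[t] == "mirA") "MIRNA" else "GENE",
                 start = g$tokens$start[t], end = g$tokens$end[t],
                 stringsAsFactors = FALSE)
    }))
    rule <- pattern_rule("w", "suppress", c(x = "MIRNA"), window = 4L)
    got <- match_rule(rule, g, men, conj_expand = FALSE)
    oracle <- window_oracle("suppress", 4L, g$tokens, men)
    want <- unique(vapply(Filter(function(h)
      men$entity_class[h["i"]] == "MIRNA", oracle),
      function(h) paste(h["t"], men$id[h["i"]]), ""))
    expect_setequal(paste(got$trigger_index, got$x), want)
  }
})

test_that("match_rule is deterministic", {
  g <- build_parse("miR-1 and miR-2 suppress PTEN and EGFR now")
  men <- mk_mentions(g, list(list(class = "MIRNA", token = 1L),
                             list(class = "MIRNA", token = 3L),
                             list(class = "GENE", token = 5L),
                             list(class = "GENE", token = 7L)))
  rule <- pattern_rule("r", "suppress", c(m = "MIRNA", g = "GENE"),
                       window = 8L)
  m1 <- match_rule(rule, g, men)
  m2 <- match_rule(rule, g, men)
  expect_identical(m1, m2)
  expect_identical(nrow(m1), 4L)
})

test_that("load_rules reads the declarative TSV format", {
  rules <- load_rules(system.file("extdata", "example_rules.tsv",
                                  package = "mirlit"))
  expect_length(rules, 3)
  r <- rules[[1]]
  expect_s3_class(r, "mir_rule")
  expect_identical(r$rule_id, "gene.reg.neg")
  expect_true("suppress" %in% r$trigger)
  expect_identical(r$slots, c(mirna = "MIRNA", gene = "GENE"))
  expect_identical(r$window, 8L)
  expect_true(r$negation_guard)
})
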