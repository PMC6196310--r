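test_that("build_grct layers SYNT/POS/LEX and preserves token order", {
  # 1-token sentence: SYNT -> POS -> LEX chain
  p1 <- tkrex:::new_parse("runs", 0L, "root", "VBZ")
  t1 <- build_grct(p1)
  expect_equal(t1$kind, "SYNT"); expect_equal(t1$label, "root")
  expect_equal(t1$children[[1]]$kind, "POS")
  expect_equal(t1$children[[1]]$children[[1]]$kind, "LEX")
  expect_equal(t1$children[[1]]$children[[1]]$label, "runs")
  # heads [2,0,2]: root SYNT holds both dependents plus the verb chain,
  # ordered by token position
  p3 <- tkrex:::new_parse(c("dog", "runs", "fast"), c(2L, 0L, 2L),
                          c("nsubj", "root", "advmod"), c("NN", "VBZ", "RB"))
  t3 <- build_grct(p3)
  expect_equal(t3$label, "root")
  expect_equal(vapply(t3$children, `[[`, "", "kind"),
               c("SYNT", "POS", "SYNT"))
  expect_equal(t3$children[[2]]$children[[1]]$label, "runs")
  expect_equal(tkrex:::tree_lex_labels(t3), c("dog", "runs", "fast"))
  # every LEX leaf has a POS parent; leaf count equals token count
  check_layers <- function(node) {
    for (ch in node$children) {
      if (ch$kind == "LEX") expect_equal(node$kind, "POS")
      if (ch$kind == "POS") expect_true(node$kind == "SYNT")
      check_layers(ch)
    }
  }
  check_layers(t3)
  # property over random fallback parses: leaf order equals token order
  rng <- tkrex:::make_rng(31L)
  tags <- c("NN", "VBZ", "DT", "JJ", "IN", "VBD")
  for (i in 1:25) {
    n <- 1L + tkrex:::rng_int(rng, 8L)
    pos <- tags[vapply(seq_len(n), function(j)
      tkrex:::rng_int(rng, length(tags)), 0L)]
    toks <- paste0("w", seq_len(n))
    tr <- build_grct(fallback_parse(toks, pos))
    expect_equal(tkrex:::tree_lex_labels(tr), toks)
    expect_equal(tkrex:::tree_lex_tokens(tr), seq_len(n))
  }
  expect_error(build_grct(list(tokens = c("a", "b"), heads = c(0L, 0L),
                               deprels = c("root", "root"),
                               pos = c("NN", "NN"))), "root")
})

test_that("match_pattern scores contexts by anchored alignment", {
  pos <- c("CHEMICAL", "RELATION", "DT", "NN", "GENEPRO")
  x <- structure(list(instance_id = "I1", doc_id = "D1", sentence_index = 0L,
                      e1_id = "T1", e2_id = "T2", relation_class = "CPR:3",
                      mode = "TRAIN", norm_tokens = paste0("w", 1:5),
                      norm_pos = pos, src_index = 1:5,
                      e1_idx = 1L, e2_idx = 5L, rel_idx = 2L,
                      verb_src_idx = 2L, verb_surface = NA_character_,
                      verb_lemma = NA_character_,
                      orig_tokens = paste0("w", 1:5), orig_pos = pos),
                 class = "tkrex_instance")
  own <- list(class = "CPR:3",
              entity1_context = c("CHEMICAL", "RELATION", "DT", "NN"),
              relation_context = c("RELATION", "DT", "NN", "GENEPRO"),
              entity2_context = "GENEPRO",
              support = 1L)
  m <- match_pattern(x, list(own))
  # perfect match: 2 per aligned position over all three contexts
  expect_equal(m$score, 2 * (4 + 4 + 1))
  expect_equal(m$covered, 1:5)
  # disjoint-alphabet pattern scores below threshold -> no match
  alien <- list(class = "CPR:9", entity1_context = c("XX", "YY"),
                relation_context = c("ZZ"), entity2_context = c("QQ"),
                support = 1L)
  expect_null(match_pattern(x, list(alien)))
  # the higher-coverage pattern wins
  small <- list(class = "CPR:3", entity1_context = c("CHEMICAL", "RELATION"),
                relation_context = NULL, entity2_context = "GENEPRO",
                support = 1L)
  m2 <- match_pattern(x, list(small, own))
  expect_identical(m2$pattern, own)
  expect_error(match_pattern(x, list()), "empty")
})

test_that("pruning keeps covered leaves plus ancestors and is monotone", {
  pos <- c("NN", "VBZ", "DT", "NN", "NN")
  toks <- c("c1", "binds", "the", "promoter", "g1")
  tree <- build_grct(fallback_parse(toks, pos))
  # full cover: tree unchanged
  expect_identical(serialize_tree(prune_tree(tree, 1:5)), serialize_tree(tree))
  # partial cover: exactly the covered LEX leaves survive, in order
  pr <- prune_tree(tree, c(1L, 2L, 5L))
  expect_equal(tkrex:::tree_lex_tokens(pr), c(1L, 2L, 5L))
  expect_equal(tkrex:::tree_lex_labels(pr), c("c1", "binds", "g1"))
  # structure invariants survive pruning
  check_layers <- function(node) {
    if (node$kind == "POS") expect_length(node$children, 1L)
    for (ch in node$children) check_layers(ch)
  }
  check_layers(pr)
  # monotone: A subset of B implies leaves(prune(A)) subset of leaves(prune(B))
  rng <- tkrex:::make_rng(13L)
  for (i in 1:20) {
    B <- sort(tkrex:::rng_sample(rng, 5L, 1L + tkrex:::rng_int(rng, 4L)))
    A <- sort(B[tkrex:::rng_sample(rng, length(B),
                                   tkrex:::rng_int(rng, length(B)))])
    expect_true(all(tkrex:::tree_lex_tokens(prune_tree(tree, A)) %in%
                    tkrex:::tree_lex_tokens(prune_tree(tree, B))))
  }
  expect_error(prune_tree(tree, integer()), "covers no tokens")
  expect_error(prune_tree(tree, 99L), "covers no tokens")
})

test_that("decoration prefixes the class node and refuses double decoration", {
  tree <- build_grct(fallback_parse(c("c1", "binds", "g1"),
                                    c("NN", "VBZ", "NN")))
  dec <- decorate_tree(tree, "CPR:4")
  expect_equal(dec$label, "TOP")
  expect_equal(tkrex:::tree_lex_labels(dec)[1], "Class4")
  expect_error(decorate_tree(dec, "CPR:4"), "already")
  # negative class decorates symmetrically
  dneg <- decorate_tree(tree, NEGATIVE_CLASS)
  expect_equal(tkrex:::tree_lex_labels(dneg)[1], "Class10")
})

test_that("tree serialization round-trips and rejects malformed input", {
  expect_equal(serialize_tree(tnode("x", "LEX")), "(LEX:x)")
  rng <- tkrex:::make_rng(17L)
  for (i in 1:30) {
    tr <- random_tree(rng)
    s <- serialize_tree(tr)
    expect_identical(serialize_tree(parse_tree(s)), s)
  }
  # labels with brackets and spaces survive escaping
  odd <- tnode("a (weird) label", "LEX")
  expect_equal(parse_tree(serialize_tree(odd))$label, "a (weird) label")
  expect_error(parse_tree("(SYNT:a(POS:b)"), "position")
  expect_error(parse_tree("(SYNT:a))"), "position")
  # file round-trip with instance-id prefixes
  trees <- list(i1 = random_tree(rng), i2 = random_tree(rng))
  path <- withr::local_tempfile(fileext = ".trees")
  write_trees(trees, path)
  reread <- read_trees(path)
  expect_named(reread, c("i1", "i2"))
  expect_identical(lapply(reread, serialize_tree),
                   lapply(trees, serialize_tree))
})
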