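test_that("segment_and_tag assigns every mention to exactly one sentence", {
  doc <- list(doc_id = "D1", title = "Title",
              abstract_text = "aspirin inhibits COX2 . morphine blocks OPRM1 .")
  # offsets on title + tab + abstract axis; abstract starts at 6
  ents <- data.frame(
    doc_id = "D1", mention_id = c("T1", "T2", "T3", "T4"),
    entity_type = c("CHEMICAL", "GENE_PROTEIN", "CHEMICAL", "GENE_PROTEIN"),
    start = c(6L, 23L, 30L, 46L), end = c(13L, 27L, 38L, 51L),
    surface = c("aspirin", "COX2", "morphine", "OPRM1"),
    stringsAsFactors = FALSE)
  sents <- segment_and_tag(doc, ents)
  with_mentions <- Filter(function(s) nrow(s$mention_spans) > 0, sents)
  expect_length(with_mentions, 2L)
  expect_equal(vapply(with_mentions, function(s) nrow(s$mention_spans), 0L),
               c(2L, 2L))
  # each mention appears exactly once over all sentences
  all_ids <- unlist(lapply(sents, function(s) s$mention_spans$mention_id))
  expect_setequal(all_ids, ents$mention_id)
  expect_false(anyDuplicated(all_ids) > 0)
  # tokens and tags stay parallel
  for (s in sents) expect_length(s$pos_tags, length(s$tokens))
})

test_that("a boundary inside a mention is repaired, keeping the mention whole", {
  doc <- list(doc_id = "D1", title = "T",
              abstract_text = "drug X. Y acts on geneZ .")
  # mention "X. Y" spans the would-be boundary after "X."
  ents <- data.frame(doc_id = "D1", mention_id = "T1", entity_type = "CHEMICAL",
                     start = 7L, end = 11L, surface = "X. Y",
                     stringsAsFactors = FALSE)
  sents <- segment_and_tag(doc, ents)
  holder <- Filter(function(s) nrow(s$mention_spans) > 0, sents)
  expect_length(holder, 1L)
  sp <- holder[[1]]$mention_spans
  toks <- holder[[1]]$tokens[sp$first:sp$last]
  expect_equal(paste(toks, collapse = ""), "X.Y")
})

test_that("candidate counts follow the heterogeneous-pair rule", {
  # 3 chemicals + 1 protein in one sentence -> 3 instances
  s <- make_sentence(
    c("c1", "and", "c2", "and", "c3", "inhibits", "g1", "."),
    c("NN", "CC", "NN", "CC", "NN", "VBZ", "NN", "."),
    rbind(mention_row("T1", "CHEMICAL", 1), mention_row("T2", "CHEMICAL", 3),
          mention_row("T3", "CHEMICAL", 5),
          mention_row("T4", "GENE_PROTEIN", 7)))
  rels <- data.frame(doc_id = "D1", relation_class = "CPR:4", evaluated = TRUE,
                     arg1 = "T1", arg2 = "T4", stringsAsFactors = FALSE)
  inst <- generate_candidate_instances(s, rels, "TRAIN")
  expect_length(inst, 3L)
  expect_equal(sum(vapply(inst, function(x) x$relation_class, "") == "CPR:4"), 1L)
  # no proteins -> empty, not an error
  s2 <- make_sentence(c("c1", "acts", "."), c("NN", "VBZ", "."),
                      mention_row("T1", "CHEMICAL", 1))
  expect_length(generate_candidate_instances(s2, rels, "TRAIN"), 0L)
  # TEST mode replicates per class
  inst_test <- generate_candidate_instances(
    s2 <- make_sentence(c("c1", "inhibits", "g1"), c("NN", "VBZ", "NN"),
                        rbind(mention_row("T1", "CHEMICAL", 1),
                              mention_row("T2", "GENE_PROTEIN", 3))),
    NULL, "TEST", class_inventory = paste0("CPR:", 3:7))
  expect_length(inst_test, 5L)
  expect_setequal(vapply(inst_test, function(x) x$relation_class, ""),
                  paste0("CPR:", 3:7))
})

test_that("normalization rewrites focal pair, generics and the proximal verb", {
  s <- make_sentence(
    c("c1", "and", "c2", "inhibits", "g1", "."),
    c("NN", "CC", "NN", "VBZ", "NN", "."),
    rbind(mention_row("T1", "CHEMICAL", 1), mention_row("T2", "CHEMICAL", 3),
          mention_row("T3", "GENE_PROTEIN", 5)))
  rels <- data.frame(doc_id = "D1", relation_class = "CPR:3", evaluated = TRUE,
                     arg1 = "T1", arg2 = "T3", stringsAsFactors = FALSE)
  inst <- generate_candidate_instances(s, rels, "TRAIN")
  pos1 <- inst[[which(vapply(inst, function(x) x$e1_id, "") == "T1")]]
  expect_equal(pos1$relation_class, "CPR:3")
  expect_equal(pos1$norm_tokens[pos1$e1_idx], "ChemicalR1T3")
  expect_equal(pos1$norm_pos[pos1$e1_idx], "CHEMICAL")
  expect_equal(pos1$norm_tokens[pos1$rel_idx], "Relation3")
  expect_equal(pos1$norm_pos[pos1$rel_idx], "RELATION")
  # non-focal chemical becomes the bare generic symbol in both layers
  gen_idx <- which(pos1$norm_tokens == "CHEMICAL")
  expect_length(gen_idx, 1L)
  expect_equal(pos1$norm_pos[gen_idx], "CHEMICAL")
  # exactly one focal tag per role
  expect_equal(sum(grepl("^ChemicalR", pos1$norm_tokens)), 1L)
  expect_equal(sum(grepl("^GeneproR", pos1$norm_tokens)), 1L)
  expect_length(pos1$norm_pos, length(pos1$norm_tokens))
  # negative instance: no Relation tag, Pri-normalized pair
  neg <- inst[[which(vapply(inst, function(x) x$e1_id, "") == "T2")]]
  expect_equal(neg$relation_class, NEGATIVE_CLASS)
  expect_true(is.na(neg$rel_idx))
  expect_equal(neg$norm_tokens[neg$e1_idx], "ChemicalPri")
  # reversibility: the original sentence is recoverable
  expect_equal(denormalize_instance(pos1), s$tokens)
})

test_that("proximal verb selection minimizes distance, prefers inflected, then leftmost", {
  # exhaustive check of the documented rule on small configurations
  check_rule <- function(pos, e1, e2) {
    s <- make_sentence(paste0("w", seq_along(pos)), pos)
    got <- select_proximal_verb(s, c(e1, e1), c(e2, e2))
    cand <- setdiff(which(startsWith(pos, "VB")), c(e1, e2))
    if (!length(cand)) return(expect_true(is.na(got)))
    dist <- abs(cand - e1) + abs(cand - e2)
    base <- !(pos[cand] %in% c("VBD", "VBZ", "VBP", "VBN", "VBG"))
    want <- cand[order(dist, base, cand)][1]
    expect_identical(got, want)
  }
  check_rule(c("NN", "VBZ", "NN"), 1L, 3L)              # simple case
  check_rule(c("NN", "NN", "NN"), 1L, 3L)               # no verb -> NA
  check_rule(c("VB", "NN", "NN", "NN", "VBD"), 3L, 3L)  # equidistant: VBD wins
  check_rule(c("VBD", "NN", "NN", "NN", "VB"), 3L, 3L)
  check_rule(c("VBZ", "NN", "NN", "NN", "VBD"), 3L, 3L) # both inflected: leftmost
  # random configurations against the re-derived rule
  rng <- tkrex:::make_rng(42L)
  tags <- c("NN", "VB", "VBD", "VBZ", "DT")
  for (i in 1:50) {
    n <- 3L + tkrex:::rng_int(rng, 5L)
    pos <- tags[vapply(seq_len(n), function(j) tkrex:::rng_int(rng, length(tags)), 0L)]
    e1 <- tkrex:::rng_int(rng, n); e2 <- tkrex:::rng_int(rng, n)
    s <- make_sentence(paste0("w", seq_len(n)), pos)
    got <- select_proximal_verb(s, c(e1, e1), c(e2, e2))
    cand <- setdiff(which(startsWith(pos, "VB")), c(e1, e2))
    if (!length(cand)) expect_true(is.na(got))
    else {
      dist <- abs(cand - e1) + abs(cand - e2)
      base <- !(pos[cand] %in% c("VBD", "VBZ", "VBP", "VBN", "VBG"))
      expect_identical(got, cand[order(dist, base, cand)][1])
    }
  }
})

test_that("negative sampling is capped, gold-disjoint and seed-deterministic", {
  gen <- generate_corpus(default_templates(),
                         synthetic_config(n_abstracts = 12, seed = 9,
                                          negatives_fraction = 0.5))
  neg1 <- sample_negative_instances(gen$corpus, seed = 4L)
  neg2 <- sample_negative_instances(gen$corpus, seed = 4L)
  expect_identical(vapply(neg1, function(x) x$instance_id, ""),
                   vapply(neg2, function(x) x$instance_id, ""))
  expect_true(all(vapply(neg1, function(x) x$relation_class, "") ==
                  NEGATIVE_CLASS))
  # none of the sampled negatives is a gold pair
  gold <- gen$corpus$relations
  gold_keys <- c(paste(gold$doc_id, gold$arg1, gold$arg2),
                 paste(gold$doc_id, gold$arg2, gold$arg1))
  neg_keys <- vapply(neg1, function(x) paste(x$doc_id, x$e1_id, x$e2_id), "")
  expect_length(intersect(neg_keys, gold_keys), 0L)
  # per-abstract cap at ratio 1: negatives <= max(1, positives)
  ct <- corpus_training_instances(gen$corpus, seed = 4L, neg_ratio = 1)
  cls <- vapply(ct$instances, function(x) x$relation_class, "")
  docs <- vapply(ct$instances, function(x) x$doc_id, "")
  for (d in unique(docs)) {
    np <- sum(docs == d & cls != NEGATIVE_CLASS)
    nn <- sum(docs == d & cls == NEGATIVE_CLASS)
    expect_lte(nn, max(1L, np))
  }
})

test_that("keyword filter keeps sentences with training verbs, drops others", {
  s_pos <- make_sentence(c("c1", "induced", "g1"), c("NN", "VBD", "NN"),
                         rbind(mention_row("T1", "CHEMICAL", 1),
                               mention_row("T2", "GENE_PROTEIN", 3)))
  rels <- data.frame(doc_id = "D1", relation_class = "CPR:3", evaluated = TRUE,
                     arg1 = "T1", arg2 = "T2", stringsAsFactors = FALSE)
  train_inst <- generate_candidate_instances(s_pos, rels, "TRAIN")
  kw <- collect_keywords(train_inst)
  expect_equal(kw, "induce")
  # "induces" matches by lemma
  s_match <- make_sentence(c("c9", "induces", "g9"), c("NN", "VBZ", "NN"),
                           rbind(mention_row("T1", "CHEMICAL", 1),
                                 mention_row("T2", "GENE_PROTEIN", 3)))
  s_miss <- make_sentence(c("c9", "near", "g9"), c("NN", "IN", "NN"),
                          rbind(mention_row("T1", "CHEMICAL", 1),
                                mention_row("T2", "GENE_PROTEIN", 3)))
  ti <- c(generate_candidate_instances(s_match, NULL, "TRAIN"),
          generate_candidate_instances(s_miss, NULL, "TRAIN"))
  kept <- filter_test_instances(ti, kw)
  expect_length(kept, 1L)
  expect_equal(kept[[1]]$orig_tokens[2], "induces")
  # empty keyword set passes everything with a warning
  expect_warning(kept_all <- filter_test_instances(ti, character()), "empty")
  expect_length(kept_all, 2L)
})

test_that("instance totals match the chem x gene product before capping", {
  gen <- generate_corpus(default_templates(),
                         synthetic_config(n_abstracts = 8, seed = 21,
                                          multi_pair_sentence_rate = 0.5))
  tagger <- fallback_tagger()
  for (d in seq_len(nrow(gen$corpus$documents))) {
    doc <- as.list(gen$corpus$documents[d, ])
    ents <- gen$corpus$entities[gen$corpus$entities$doc_id == doc$doc_id, ]
    rels <- gen$corpus$relations[gen$corpus$relations$doc_id == doc$doc_id, ]
    for (s in segment_and_tag(doc, ents, tagger)) {
      inst <- generate_candidate_instances(s, rels, "TRAIN", tagger = tagger)
      ms <- s$mention_spans
      nc <- sum(ms$entity_type == "CHEMICAL")
      ng <- sum(ms$entity_type != "CHEMICAL")
      # one instance per pair, plus one extra per additional gold relation
      expect_gte(length(inst), nc * ng)
    }
  }
})
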