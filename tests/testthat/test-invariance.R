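make_instance <- function(pos, e1, rel = NA_integer_, e2,
                          id = "I1", class = "CPR:3") {
  structure(list(instance_id = id, doc_id = "D1", sentence_index = 0L,
                 e1_id = "T1", e2_id = "T2", relation_class = class,
                 mode = "TRAIN", norm_tokens = paste0("w", seq_along(pos)),
                 norm_pos = pos, src_index = seq_along(pos),
                 e1_idx = e1, e2_idx = e2, rel_idx = rel,
                 verb_src_idx = rel, verb_surface = NA_character_,
                 verb_lemma = NA_character_,
                 orig_tokens = paste0("w", seq_along(pos)), orig_pos = pos),
            class = "tkrex_instance")
}

test_that("frame extraction emits n+1 frames per role, truncated at edges", {
  pos <- c("DT", "NN", "CHEMICAL", "RELATION", "DT", "GENEPRO", "NN", "IN")
  x <- make_instance(pos, e1 = 3L, rel = 4L, e2 = 6L)
  frames <- extract_context_frames(x, 3L)
  expect_length(frames, 3L * 4L)                       # 3 roles x e_c in 0..3
  e1f <- Filter(function(f) f$role == "ENTITY1", frames)
  expect_equal(vapply(e1f, function(f) f$e_c, 0L), 0:3)
  # e_c = 0: window starts at the anchor
  expect_equal(e1f[[1]]$tags, c("CHEMICAL", "RELATION", "DT", "GENEPRO"))
  expect_equal(e1f[[1]]$m, 0L)
  # anchor near sentence start: left truncation shrinks m, not the rule
  x2 <- make_instance(c("CHEMICAL", "RELATION", "GENEPRO", "NN"),
                      e1 = 1L, rel = 2L, e2 = 3L)
  f2 <- Filter(function(f) f$role == "ENTITY1" && f$e_c == 2L,
               extract_context_frames(x2, 3L))[[1]]
  expect_equal(f2$m, 0L)                               # truncated to the anchor
  expect_equal(f2$tags[1], "CHEMICAL")
  # negative instances contribute no RELATION frames
  xneg <- make_instance(c("CHEMICAL", "CC", "GENEPRO"), e1 = 1L, e2 = 3L,
                        class = NEGATIVE_CLASS)
  expect_length(Filter(function(f) f$role == "RELATION",
                       extract_context_frames(xneg, 3L)), 0L)
  expect_length(extract_context_frames(xneg, 3L), 2L * 4L)
})

test_that("frame scores match independent subsequence counting", {
  # constructed mini-corpus of frames giving c(DT)=5, c(DT,CHEMICAL)=3,
  # c(DT,CHEMICAL,VBZ)=2
  frames <- list(
    list(tags = c("DT", "CHEMICAL", "VBZ"), m = 1L),
    list(tags = c("DT", "CHEMICAL", "VBZ"), m = 1L),
    list(tags = c("DT", "CHEMICAL", "NN"), m = 1L),
    list(tags = c("DT", "JJ", "NN"), m = 1L),
    list(tags = c("DT", "NN", "NN"), m = 0L))
  counts <- build_frame_counts(frames)
  # independent oracle: count prefixes by brute force over the frame list
  oracle_count <- function(prefix) {
    sum(vapply(frames, function(f)
      length(f$tags) >= length(prefix) &&
        identical(f$tags[seq_along(prefix)], prefix), TRUE))
  }
  expect_equal(oracle_count("DT"), 5L)
  expect_equal(oracle_count(c("DT", "CHEMICAL")), 3L)
  expect_equal(oracle_count(c("DT", "CHEMICAL", "VBZ")), 2L)
  rho <- score_frame(frames[[1]], counts)
  expect_equal(rho, (3 / 5) * (2 / 3), tolerance = 1e-12)
  expect_equal(rho, 0.4, tolerance = 1e-12)
  # any m = 0 frame scores 1 + fringe
  expect_equal(score_frame(frames[[5]], counts, fringe = 1e-8), 1 + 1e-8)
  # unique frame with unique prefixes and m = n scores 1
  fr_unique <- list(tags = c("RB", "RB", "RB"), m = 2L)
  counts2 <- build_frame_counts(c(frames, list(fr_unique)))
  expect_equal(score_frame(fr_unique, counts2), 1)
  # scoring against a foreign counts table errors
  expect_error(score_frame(list(tags = c("XX", "YY"), m = 1L), counts),
               "counts")
  # rho is always >= 0 and case-1 rho <= 1 under nested counts
  for (f in frames[vapply(frames, function(f) f$m > 0, TRUE)]) {
    r <- score_frame(f, counts)
    expect_gte(r, 0); expect_lte(r, 1)
  }
})

test_that("coefficient consolidation applies the OR pass-through semantics", {
  fs <- list(list(role = "ENTITY1", rho = 2), list(role = "RELATION", rho = 3),
             list(role = "ENTITY2", rho = 1))
  p <- consolidate_coefficients(fs)
  expect_equal(c(p$p20, p$p02, p$p11), c(6, 3, 18))
  # negative instance: RELATION absent -> entity scores pass through
  pneg <- consolidate_coefficients(fs[c(1, 3)])
  expect_equal(c(pneg$p20, pneg$p02, pneg$p11), c(2, 1, 2))
  # all-ones
  p1 <- consolidate_coefficients(list(list(role = "ENTITY1", rho = 1),
                                      list(role = "RELATION", rho = 1),
                                      list(role = "ENTITY2", rho = 1)))
  expect_equal(c(p1$p20, p1$p11, p1$p02), c(1, 1, 1))
  expect_error(consolidate_coefficients(fs[1:2]), "entity")
})

test_that("the invariant equals the rotation-invariant of the quadratic form", {
  expect_equal(invariant_score(list(p20 = 1, p11 = 0, p02 = 1)), 2)
  expect_equal(invariant_score(list(p20 = 0, p11 = 2, p02 = 0)), 2)
  # rotation oracle: p' from R(theta) M R(theta)^T with M the form matrix
  rotate_poly <- function(p, theta) {
    M <- matrix(c(p$p20, p$p11 / 2, p$p11 / 2, p$p02), 2, 2)
    R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
    Mp <- R %*% M %*% t(R)
    list(p20 = Mp[1, 1], p11 = 2 * Mp[1, 2], p02 = Mp[2, 2])
  }
  p <- list(p20 = 2, p11 = 0, p02 = 1)
  pr <- rotate_poly(p, pi / 4)
  expect_equal(c(pr$p20, pr$p11, pr$p02), c(1.5, 1, 1.5), tolerance = 1e-12)
  expect_equal(invariant_score(pr), 5)
  expect_equal(invariant_score(p), 5)
  rng <- tkrex:::make_rng(100L)
  for (i in 1:200) {
    u <- tkrex:::rng_unif(rng, 4L)
    p <- list(p20 = 10 * u[1], p11 = 10 * u[2], p02 = 10 * u[3])
    pr <- rotate_poly(p, 2 * pi * u[4])
    expect_equal(invariant_score(pr), invariant_score(p), tolerance = 1e-9)
  }
})

test_that("best representation takes the invariant argmax with smallest-e_c ties", {
  pos <- c("DT", "NN", "CHEMICAL", "RELATION", "DT", "GENEPRO", "NN", "IN")
  x <- make_instance(pos, e1 = 3L, rel = 4L, e2 = 6L)
  cfg <- invariance_config(3L)
  counts <- build_frame_counts(extract_context_frames(x, cfg$n))
  best <- best_instance_representation(x, counts, cfg)
  # oracle: evaluate all e_c by the exported primitives
  Is <- vapply(0:3, function(ec) {
    fs <- Filter(function(f) f$e_c == ec, extract_context_frames(x, cfg$n))
    scored <- lapply(fs, function(f)
      list(role = f$role, rho = score_frame(f, counts, cfg$fringe)))
    invariant_score(consolidate_coefficients(scored, ec))
  }, 0)
  expect_equal(best$I, max(Is))
  expect_equal(best$e_c, which.max(Is) - 1L)
  # identical instances receive identical invariants
  x2 <- make_instance(pos, e1 = 3L, rel = 4L, e2 = 6L, id = "I2")
  counts2 <- build_frame_counts(c(extract_context_frames(x, cfg$n),
                                  extract_context_frames(x2, cfg$n)))
  b1 <- best_instance_representation(x, counts2, cfg)
  b2 <- best_instance_representation(x2, counts2, cfg)
  expect_equal(b1$I, b2$I)
  expect_equal(b1$e_c, b2$e_c)
})

test_that("invariance clustering follows the successor-ratio rule", {
  cfg <- invariance_config(ratio_tolerance = 0.01)
  part <- function(I, ids = paste0("I", seq_along(I))) {
    cl <- cluster_by_invariance(
      data.frame(instance_id = ids, I = I, stringsAsFactors = FALSE), cfg)
    lapply(cl, `[[`, "members")
  }
  expect_equal(part(c(4, 4, 2)), list(c("I1", "I2"), "I3"))
  expect_equal(part(5), list("I1"))
  expect_equal(part(c(9, 3, 3, 1)), list("I1", c("I2", "I3"), "I4"))
  expect_error(part(c(1, -2)), "positive")
  # permutation invariance and idempotence on random score lists
  rng <- tkrex:::make_rng(7L)
  for (rep in 1:100) {
    k <- 2L + tkrex:::rng_int(rng, 8L)
    base <- c(1, 2, 4, 8)[vapply(seq_len(k), function(i)
      tkrex:::rng_int(rng, 4L), 0L)]
    I <- base * (1 + 1e-9 * tkrex:::rng_unif(rng, k))
    ids <- paste0("I", seq_len(k))
    ref <- part(I, ids)
    perm <- tkrex:::rng_sample(rng, k, k)
    expect_equal(part(I[perm], ids[perm]), ref)
    # idempotence: clustering the representatives of singleton re-runs
    expect_equal(part(I, ids), ref)
  }
})

test_that("align_pair reproduces exhaustive global-alignment maximization", {
  cfg <- alignment_config()
  expect_equal(align_pair(c("NN", "DT", "VB"), c("NN", "DT", "VB"), cfg)$score, 6)
  expect_equal(align_pair("NN", "DT", cfg)$score, -2)
  expect_equal(align_pair(c("NN", "DT"), "NN", cfg)$score, 0)
  expect_error(align_pair(character(), "NN", cfg), "non-empty")
  # exhaustive over a 2-symbol alphabet up to length 4 (every pair)
  ab <- c("A", "B")
  seqs <- unlist(lapply(1:4, function(l) {
    g <- do.call(expand.grid, rep(list(ab), l))
    lapply(seq_len(nrow(g)), function(i) as.character(unlist(g[i, ])))
  }), recursive = FALSE)
  for (a in seqs) for (b in seqs)
    expect_identical(align_pair(a, b, cfg)$score, bf_align_score(a, b, cfg))
  # random pairs over a 4-symbol alphabet up to length 6
  rng <- tkrex:::make_rng(11L)
  tags <- c("NN", "DT", "VB", "JJ")
  for (i in 1:150) {
    a <- tags[vapply(seq_len(tkrex:::rng_int(rng, 6L)), function(j)
      tkrex:::rng_int(rng, 4L), 0L)]
    b <- tags[vapply(seq_len(tkrex:::rng_int(rng, 6L)), function(j)
      tkrex:::rng_int(rng, 4L), 0L)]
    al <- align_pair(a, b, cfg)
    expect_identical(al$score, bf_align_score(a, b, cfg))
    # returned alignment is consistent with its score
    sc <- 0
    for (p in seq_along(al$a_aligned)) {
      sa <- al$a_aligned[p]; sb <- al$b_aligned[p]
      sc <- sc + if (sa == "-" || sb == "-") cfg$gap
                 else if (sa == sb) cfg$match else cfg$mismatch
    }
    expect_equal(sc, al$score)
    expect_equal(al$a_aligned[al$a_aligned != "-"], a)
    expect_equal(al$b_aligned[al$b_aligned != "-"], b)
  }
})

test_that("cluster consensus follows the majority rule with first-member ties", {
  cfg <- invariance_config(3L)
  pos_a <- c("CHEMICAL", "DT", "JJ")
  pos_b <- c("CHEMICAL", "DT", "NN")
  reps <- list(
    I1 = list(frames = list(list(role = "ENTITY1", tags = pos_a))),
    I2 = list(frames = list(list(role = "ENTITY1", tags = pos_b))))
  # singleton cluster: pattern equals its frames verbatim
  p1 <- consolidate_pattern(list(members = "I1"), reps, "CPR:3")
  expect_equal(p1$entity1_context, pos_a)
  expect_equal(p1$support, 1L)
  expect_null(p1$relation_context)
  # two identical members: same pattern, support 2
  reps2 <- list(I1 = reps$I1, I2 = reps$I1)
  p2 <- consolidate_pattern(list(members = c("I1", "I2")), reps2, "CPR:3")
  expect_equal(p2$entity1_context, pos_a)
  expect_equal(p2$support, 2L)
  # tie on the third column resolves toward the first-processed member
  p3 <- consolidate_pattern(list(members = c("I1", "I2")), reps, "CPR:3")
  expect_equal(p3$entity1_context[1:2], c("CHEMICAL", "DT"))
  expect_true(p3$entity1_context[3] %in% c("JJ", "NN"))
  expect_equal(p3$entity1_context[3], "JJ")
  expect_error(consolidate_pattern(list(members = character()), reps, "x"),
               "empty")
})

test_that("learn_patterns mines one pattern per planted structure", {
  mk <- function(id, pos, class) make_instance(
    pos, e1 = match("CHEMICAL", pos), rel = match("RELATION", pos),
    e2 = match("GENEPRO", pos), id = id, class = class)
  pos1 <- c("CHEMICAL", "RELATION", "DT", "NN", "GENEPRO")
  pos2 <- c("CHEMICAL", "RB", "RELATION", "GENEPRO", "NN")
  inst <- c(lapply(1:4, function(i) mk(paste0("A", i), pos1, "CPR:3")),
            lapply(1:4, function(i) mk(paste0("B", i), pos2, "CPR:4")))
  learned <- learn_patterns(inst, invariance_config(3L))
  classes <- vapply(learned$patterns, `[[`, "", "class")
  expect_setequal(unique(classes), c("CPR:3", "CPR:4"))
  # identical instances of one class collapse into a single pattern
  one_class <- learn_patterns(inst[1:4], invariance_config(3L))
  expect_length(one_class$patterns, 1L)
  expect_equal(one_class$patterns[[1]]$support, 4L)
  # empty input
  expect_length(learn_patterns(list())$patterns, 0L)
  # pattern serialization round-trips
  path <- withr::local_tempfile(fileext = ".tsv")
  write_patterns(learned$patterns, path)
  reread <- read_patterns(path)
  expect_equal(length(reread), length(learned$patterns))
  for (i in seq_along(reread)) {
    expect_equal(reread[[i]]$class, learned$patterns[[i]]$class)
    expect_equal(reread[[i]]$entity1_context,
                 learned$patterns[[i]]$entity1_context)
    expect_equal(reread[[i]]$support, learned$patterns[[i]]$support)
  }
})
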