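# Independent oracles and fixture builders, kept deliberately naive: they
# re-derive expected values by enumeration, not by the package's own
# algorithms.

# exhaustive global-alignment maximization (no DP)
bf_align_score <- function(a, b, cfg = alignment_config()) {
  rec <- function(i, j) {
    if (i > length(a) && j > length(b)) return(0)
    best <- -Inf
    if (i <= length(a)) best <- max(best, cfg$gap + rec(i + 1L, j))
    if (j <= length(b)) best <- max(best, cfg$gap + rec(i, j + 1L))
    if (i <= length(a) && j <= length(b)) {
      sub <- if (a[i] == b[j]) cfg$match else cfg$mismatch
      best <- max(best, sub + rec(i + 1L, j + 1L))
    }
    best
  }
  rec(1L, 1L)
}

tnode <- function(label, kind = "SYNT", children = list(), token = NA_integer_)
  list(label = label, kind = kind, children = children, token = token)

leafp <- function(n) !length(n$children)

# naive SPTK delta: enumerate all equal-length child-subsequence pairs
bf_delta <- function(n1, n2, params = kernel_params()) {
  sigma <- node_similarity(n1, n2, params)
  if (sigma == 0) return(0)
  mu <- params$mu; la <- params$lambda
  if (leafp(n1) && leafp(n2)) return(mu * la * sigma)
  p <- length(n1$children); q <- length(n2$children)
  total <- 0
  if (p > 0 && q > 0) {
    for (l in seq_len(min(p, q))) {
      I1s <- utils::combn(p, l, simplify = FALSE)
      I2s <- utils::combn(q, l, simplify = FALSE)
      for (I1 in I1s) for (I2 in I2s) {
        d1 <- I1[l] - I1[1] + 1L
        d2 <- I2[l] - I2[1] + 1L
        prod_delta <- 1
        for (j in seq_len(l))
          prod_delta <- prod_delta *
            bf_delta(n1$children[[I1[j]]], n2$children[[I2[j]]], params)
        total <- total + la^(d1 + d2) * prod_delta
      }
    }
  }
  mu * sigma * (la^2 + total)
}

all_nodes <- function(tree) {
  out <- list(tree)
  for (ch in tree$children) out <- c(out, all_nodes(ch))
  out
}

bf_kernel <- function(t1, t2, params = kernel_params()) {
  s <- 0
  for (a in all_nodes(t1)) for (b in all_nodes(t2))
    s <- s + bf_delta(a, b, params)
  s
}

# fixture trees with <= 6 nodes, mixed kinds and shapes
fixture_trees <- function() {
  list(
    tnode("A", "POS", list(tnode("x", "LEX"))),
    tnode("root", children = list(tnode("A", "POS", list(tnode("x", "LEX"))))),
    tnode("root", children = list(
      tnode("A", "POS", list(tnode("x", "LEX"))),
      tnode("B", "POS", list(tnode("y", "LEX"))))),
    tnode("root", children = list(
      tnode("nsubj", children = list(tnode("A", "POS", list(tnode("x", "LEX"))))),
      tnode("B", "POS"))),
    tnode("root", children = list(
      tnode("B", "POS", list(tnode("y", "LEX"))),
      tnode("A", "POS", list(tnode("x", "LEX"))))),
    tnode("conj", children = list(
      tnode("A", "POS", list(tnode("x", "LEX"))),
      tnode("A", "POS", list(tnode("x", "LEX"))))),
    tnode("z", "LEX"),
    tnode("root", children = list(
      tnode("A", "POS"), tnode("B", "POS"), tnode("C", "POS"),
      tnode("D", "POS"), tnode("E", "POS"))))
}

# random labeled tree (valid bracketing, arbitrary kinds)
random_tree <- function(rng_state, max_depth = 3L, max_kids = 3L,
                        alphabet = c("a", "b", "c", "dep", "NN", "VBZ")) {
  lab <- alphabet[tkrex:::rng_int(rng_state, length(alphabet))]
  kind <- c("SYNT", "POS", "LEX")[tkrex:::rng_int(rng_state, 3L)]
  if (max_depth <= 0L || kind == "LEX" ||
      tkrex:::rng_unif(rng_state) < 0.35)
    return(tnode(lab, kind))
  k <- tkrex:::rng_int(rng_state, max_kids)
  tnode(lab, kind, lapply(seq_len(k), function(i)
    random_tree(rng_state, max_depth - 1L, max_kids, alphabet)))
}

# tiny hand-written corpus files
write_mini_corpus <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  abstracts <- file.path(dir, "abstracts.tsv")
  entities <- file.path(dir, "entities.tsv")
  relations <- file.path(dir, "relations.tsv")
  title <- "A title"
  abstract <- "aspirin inhibits COX2 in cells ."
  # axis: title (7 chars) + tab at offset 7, abstract starts at 8
  writeLines(paste("D1", title, abstract, sep = "\t"), abstracts)
  writeLines(c(paste("D1", "T1", "CHEMICAL", 8, 15, "aspirin", sep = "\t"),
               paste("D1", "T2", "GENE_PROTEIN", 25, 29, "COX2", sep = "\t")),
             entities)
  writeLines(paste("D1", "CPR:4", "Y", "T1", "T2", sep = "\t"), relations)
  list(abstracts = abstracts, entities = entities, relations = relations)
}

# sentence object straight from token/tag vectors (bypasses segmentation)
make_sentence <- function(tokens, pos, mentions = NULL, doc_id = "D1",
                          sentence_index = 0L) {
  if (is.null(mentions))
    mentions <- data.frame(mention_id = character(), entity_type = character(),
                           first = integer(), last = integer(),
                           stringsAsFactors = FALSE)
  off <- cumsum(c(0L, nchar(tokens) + 1L))[seq_along(tokens)]
  list(doc_id = doc_id, sentence_index = sentence_index,
       text = paste(tokens, collapse = " "),
       char_span = c(0L, sum(nchar(tokens)) + length(tokens) - 1L),
       tokens = tokens, pos_tags = pos,
       token_start = off, token_end = off + nchar(tokens),
       mention_spans = mentions)
}

mention_row <- function(id, type, first, last = first)
  data.frame(mention_id = id, entity_type = type, first = first, last = last,
             stringsAsFactors = FALSE)
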