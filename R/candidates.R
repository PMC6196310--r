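# Candidate-instance generation.
#
# Every co-sentential heterogeneous entity pair (chemical x gene/protein, or
# chemical x disease) yields one derivative copy of its sentence in which the
# focal pair is rewritten to normalized role tags, all other entity mentions
# are rewritten to a generic type symbol, and -- for interacting pairs only --
# the proximal verb is rewritten to a class-indexed Relation tag.  The PoS
# sequence is rewritten in parallel; these normalized PoS sequences are the
# substrate for pattern mining.

GENERIC_SYMBOL <- c(CHEMICAL = "CHEMICAL", GENE_PROTEIN = "GENEPRO",
                    PROTEIN = "GENEPRO", DISEASE = "DISEASE")

#' Default negative (non-interacting) class label
#' @export
NEGATIVE_CLASS <- "CPR:10"

class_number <- function(relation_class) {
  num <- gsub("[^0-9]", "", relation_class)
  if (nzchar(num)) num else relation_class
}

is_positive_class <- function(relation_class, negative_class = NEGATIVE_CLASS) {
  relation_class != negative_class
}

# ---- sentence segmentation ---------------------------------------------------

#' Split a document into tagged sentences
#'
#' Sentence boundaries are proposed after `.`/`!`/`?` followed by whitespace
#' and an uppercase letter, and at the tab separating title from abstract.
#' A proposed boundary falling strictly inside an entity-mention span is
#' repaired (dropped), so no mention is ever split across sentences.
#' Sentences tile the document character axis without overlap.
#'
#' @param document one row of a corpus `documents` table
#' @param entities entity mentions of this document (data.frame)
#' @param tagger a tagger contract (default [fallback_tagger()])
#' @return list of sentences; each has `doc_id`, `sentence_index` (0-based),
#'   `text`, `char_span`, `tokens`, `pos_tags`, `token_start`, `token_end`
#'   (0-based char offsets on the document axis) and `mention_spans`
#'   (data.frame mention_id / entity_type / first / last token index, 1-based)
#' @export
segment_and_tag <- function(document, entities, tagger = fallback_tagger()) {
  text <- document_text(document)
  n <- nchar(text)
  ends <- integer()
  tab_at <- regexpr("\t", text, fixed = TRUE)[1]
  if (tab_at > 0L) ends <- c(ends, tab_at)          # boundary after the tab
  m <- gregexpr("[.!?](?=[ \t]+[A-Za-z0-9])", text, perl = TRUE)[[1]]
  if (m[1] != -1L) ends <- c(ends, as.integer(m))   # boundary after punct
  ends <- sort(unique(ends))
  # repair: drop boundaries strictly inside a mention [start, end)
  if (nrow(entities)) {
    keep <- vapply(ends, function(b)
      !any(entities$start < b & b < entities$end), TRUE)
    ends <- ends[keep]
  }
  bounds <- unique(c(0L, ends, n))
  bounds <- bounds[bounds <= n]
  sentences <- list()
  for (si in seq_len(length(bounds) - 1L)) {
    s0 <- bounds[si]; s1 <- bounds[si + 1L]
    raw <- substr(text, s0 + 1L, s1)
    tk <- tokenize_with_offsets(raw)
    if (!length(tk$tokens)) next
    pos <- tagger$tag(tk$tokens)
    if (length(pos) != length(tk$tokens))
      stop("tagger output length mismatch", call. = FALSE)
    tok_start <- tk$start + s0
    tok_end <- tk$end + s0
    sent_ents <- entities[entities$start >= s0 & entities$start < s1, , drop = FALSE]
    if (nrow(sent_ents)) {
      firsts <- integer(nrow(sent_ents)); lasts <- integer(nrow(sent_ents))
      for (i in seq_len(nrow(sent_ents))) {
        e <- sent_ents[i, ]
        if (e$end > s1)
          stop(sprintf("mention %s crosses a sentence boundary after repair",
                       e$mention_id), call. = FALSE)
        ov <- which(tok_start < e$end & tok_end > e$start)
        if (!length(ov))
          stop(sprintf("mention %s maps to no token", e$mention_id), call. = FALSE)
        firsts[i] <- min(ov); lasts[i] <- max(ov)
      }
      mention_spans <- data.frame(mention_id = sent_ents$mention_id,
                                  entity_type = sent_ents$entity_type,
                                  first = firsts, last = lasts,
                                  stringsAsFactors = FALSE)
    } else {
      mention_spans <- data.frame(mention_id = character(),
                                  entity_type = character(),
                                  first = integer(), last = integer(),
                                  stringsAsFactors = FALSE)
    }
    sentences[[length(sentences) + 1L]] <- list(
      doc_id = document$doc_id, sentence_index = length(sentences),
      text = raw, char_span = c(s0, s1),
      tokens = tk$tokens, pos_tags = pos,
      token_start = tok_start, token_end = tok_end,
      mention_spans = mention_spans)
  }
  sentences
}

# ---- proximal verb -----------------------------------------------------------

INFLECTED_VERB_TAGS <- c("VBD", "VBZ", "VBP", "VBN", "VBG")

#' Select the proximal verb for an entity pair
#'
#' The main verb nearest to the focal pair: among verb-tagged tokens outside
#' both spans, minimize the summed token distance to the two spans; at equal
#' distance prefer an inflected form (VBD/VBZ/VBP/VBN/VBG) over base VB, then
#' the leftmost. Returns `NA_integer_` when the sentence has no verb.
#'
#' @param sentence a sentence from [segment_and_tag()]
#' @param e1_span,e2_span integer `c(first, last)` token spans (1-based)
#' @return token index of the proximal verb, or `NA_integer_`
#' @export
select_proximal_verb <- function(sentence, e1_span, e2_span) {
  pos <- sentence$pos_tags
  cand <- which(startsWith(pos, "VB"))
  inside <- function(i, sp) i >= sp[1] && i <= sp[2]
  cand <- cand[!vapply(cand, function(i)
    inside(i, e1_span) || inside(i, e2_span), TRUE)]
  if (!length(cand)) return(NA_integer_)
  span_dist <- function(i, sp) if (inside(i, sp)) 0 else min(abs(i - sp))
  dist <- vapply(cand, function(i)
    span_dist(i, e1_span) + span_dist(i, e2_span), numeric(1))
  base <- as.integer(!(pos[cand] %in% INFLECTED_VERB_TAGS))
  cand[order(dist, base, cand)][1L]
}

# ---- instance construction ---------------------------------------------------

build_instance <- function(sentence, e1, e2, relation_class, relation_ordinal,
                           mode, negative_class, tagger) {
  positive <- is_positive_class(relation_class, negative_class)
  cnum <- class_number(relation_class)
  verb_idx <- if (positive)
    select_proximal_verb(sentence, c(e1$first, e1$last), c(e2$first, e2$last))
  else NA_integer_

  ms <- sentence$mention_spans
  n <- length(sentence$tokens)
  owner <- integer(n)                      # 0 = plain token, else mention row
  for (i in seq_len(nrow(ms)))
    owner[ms$first[i]:ms$last[i]] <- i
  e1_row <- which(ms$mention_id == e1$mention_id)
  e2_row <- which(ms$mention_id == e2$mention_id)

  e1_tok <- if (positive) sprintf("ChemicalR%dT%s", relation_ordinal, cnum)
            else "ChemicalPri"
  role2 <- unname(GENERIC_SYMBOL[e2$entity_type])
  e2_base <- if (role2 == "DISEASE") "Disease" else "Genepro"
  e2_tok <- if (positive) sprintf("%sR%dT%s", e2_base, relation_ordinal, cnum)
            else paste0(e2_base, "Pri")

  norm_tokens <- character(); norm_pos <- character()
  src_index <- integer()                   # first original token of each norm token
  e1_idx <- e2_idx <- rel_idx <- NA_integer_
  i <- 1L
  while (i <= n) {
    o <- owner[i]
    if (o > 0L && i == ms$first[o]) {      # collapse mention span to one token
      if (o == e1_row) {
        norm_tokens <- c(norm_tokens, e1_tok); norm_pos <- c(norm_pos, "CHEMICAL")
        e1_idx <- length(norm_tokens)
      } else if (o == e2_row) {
        norm_tokens <- c(norm_tokens, e2_tok); norm_pos <- c(norm_pos, role2)
        e2_idx <- length(norm_tokens)
      } else {
        g <- unname(GENERIC_SYMBOL[ms$entity_type[o]])
        norm_tokens <- c(norm_tokens, g); norm_pos <- c(norm_pos, g)
      }
      src_index <- c(src_index, i)
      i <- ms$last[o] + 1L
    } else {
      if (!is.na(verb_idx) && i == verb_idx) {
        norm_tokens <- c(norm_tokens, paste0("Relation", cnum))
        norm_pos <- c(norm_pos, "RELATION")
        rel_idx <- length(norm_tokens)
      } else {
        norm_tokens <- c(norm_tokens, sentence$tokens[i])
        norm_pos <- c(norm_pos, sentence$pos_tags[i])
      }
      src_index <- c(src_index, i)
      i <- i + 1L
    }
  }
  verb_surface <- if (!is.na(verb_idx)) sentence$tokens[verb_idx] else NA_character_
  verb_lemma <- if (!is.na(verb_idx)) tagger$lemmatize(verb_surface) else NA_character_
  structure(list(
    instance_id = sprintf("%s#s%d#%s-%s#%s#%d", sentence$doc_id,
                          sentence$sentence_index, e1$mention_id,
                          e2$mention_id, relation_class, relation_ordinal),
    doc_id = sentence$doc_id, sentence_index = sentence$sentence_index,
    e1_id = e1$mention_id, e2_id = e2$mention_id,
    relation_class = relation_class, mode = mode,
    norm_tokens = norm_tokens, norm_pos = norm_pos, src_index = src_index,
    e1_idx = e1_idx, e2_idx = e2_idx, rel_idx = rel_idx,
    verb_src_idx = verb_idx, verb_surface = verb_surface,
    verb_lemma = verb_lemma,
    orig_tokens = sentence$tokens, orig_pos = sentence$pos_tags),
    class = "tkrex_instance")
}

#' Generate candidate instances for one sentence
#'
#' One instance per unique heterogeneous entity pair co-located in the
#' sentence. In TRAIN mode, each gold relation over a pair yields one
#' positive instance (a pair in several gold relations yields several
#' instances) and each non-gold pair yields one negative-class instance
#' with no Relation-tag normalization. In TEST mode each pair is replicated
#' once per class in `class_inventory`, each replica carrying that class's
#' normalized tags.
#'
#' @param sentence a sentence from [segment_and_tag()]
#' @param relations gold relations of the sentence's document (data.frame);
#'   ignored in TEST mode
#' @param mode `"TRAIN"` or `"TEST"`
#' @param class_inventory character vector of relation classes (TEST mode)
#' @param negative_class label for non-interacting pairs
#' @param tagger tagger contract, used for verb lemmas
#' @return list of `tkrex_instance` (possibly empty)
#' @export
generate_candidate_instances <- function(sentence, relations = NULL,
                                         mode = c("TRAIN", "TEST"),
                                         class_inventory = NULL,
                                         negative_class = NEGATIVE_CLASS,
                                         tagger = fallback_tagger()) {
  mode <- match.arg(mode)
  ms <- sentence$mention_spans
  chems <- ms[ms$entity_type == "CHEMICAL", , drop = FALSE]
  others <- ms[ms$entity_type != "CHEMICAL", , drop = FALSE]
  if (!nrow(chems) || !nrow(others)) return(list())
  out <- list()
  for (ci in seq_len(nrow(chems))) for (oi in seq_len(nrow(others))) {
    e1 <- as.list(chems[ci, ]); e2 <- as.list(others[oi, ])
    if (mode == "TEST") {
      if (is.null(class_inventory) || !length(class_inventory))
        stop("TEST mode requires a class inventory", call. = FALSE)
      for (k in seq_along(class_inventory))
        out[[length(out) + 1L]] <- build_instance(
          sentence, e1, e2, class_inventory[k], 1L, mode, negative_class, tagger)
    } else {
      hit <- integer()
      if (!is.null(relations) && nrow(relations)) {
        hit <- which((relations$arg1 == e1$mention_id & relations$arg2 == e2$mention_id) |
                     (relations$arg2 == e1$mention_id & relations$arg1 == e2$mention_id))
      }
      if (length(hit)) {
        for (j in seq_along(hit))
          out[[length(out) + 1L]] <- build_instance(
            sentence, e1, e2, relations$relation_class[hit[j]], j, mode,
            negative_class, tagger)
      } else {
        out[[length(out) + 1L]] <- build_instance(
          sentence, e1, e2, negative_class, 1L, mode, negative_class, tagger)
      }
    }
  }
  out
}

#' Generate all training instances of a corpus, with capped negatives
#'
#' Positives are kept in full; negative (non-gold cross-group) pairs are
#' down-sampled per abstract to at most `neg_ratio` times that abstract's
#' positive count (at least one negative is kept per abstract that has any,
#' so abstracts without gold relations still contribute). Sampling is
#' deterministic for a fixed seed.
#'
#' @param corpus a `tkrex_corpus`
#' @param seed integer seed for negative down-sampling
#' @param neg_ratio negatives-to-positives cap within each abstract
#' @param negative_class label for non-interacting pairs
#' @param tagger tagger contract
#' @return list with `instances` (positives + sampled negatives) and
#'   `sentences` (named by `"<doc_id>#<sentence_index>"`)
#' @export
corpus_training_instances <- function(corpus, seed = 1L, neg_ratio = 1,
                                      negative_class = NEGATIVE_CLASS,
                                      tagger = fallback_tagger()) {
  all_sentences <- list()
  positives <- list()
  negatives_by_doc <- list()
  for (d in seq_len(nrow(corpus$documents))) {
    doc <- as.list(corpus$documents[d, ])
    ents <- corpus$entities[corpus$entities$doc_id == doc$doc_id, , drop = FALSE]
    rels <- corpus$relations[corpus$relations$doc_id == doc$doc_id, , drop = FALSE]
    sents <- segment_and_tag(doc, ents, tagger)
    for (s in sents) {
      all_sentences[[paste0(doc$doc_id, "#", s$sentence_index)]] <- s
      inst <- generate_candidate_instances(s, rels, "TRAIN",
                                           negative_class = negative_class,
                                           tagger = tagger)
      for (x in inst) {
        if (is_positive_class(x$relation_class, negative_class))
          positives[[length(positives) + 1L]] <- x
        else
          negatives_by_doc[[doc$doc_id]] <-
            c(negatives_by_doc[[doc$doc_id]], list(x))
      }
    }
  }
  n_pos_by_doc <- table(vapply(positives, function(x) x$doc_id, ""))
  negatives <- list()
  rng <- make_rng(seed)
  for (doc_id in names(negatives_by_doc)) {
    neg <- negatives_by_doc[[doc_id]]
    cap <- max(1L, floor(neg_ratio * (if (doc_id %in% names(n_pos_by_doc))
      n_pos_by_doc[[doc_id]] else 0L)))
    if (length(neg) > cap) {
      keep <- sort(rng_sample(rng, length(neg), cap))
      neg <- neg[keep]
    }
    negatives <- c(negatives, neg)
  }
  list(instances = c(positives, negatives), sentences = all_sentences)
}

#' Sample capped negative instances from a corpus
#'
#' Convenience wrapper returning only the down-sampled negative-class
#' instances of [corpus_training_instances()].
#'
#' @inheritParams corpus_training_instances
#' @return list of negative `tkrex_instance`
#' @export
sample_negative_instances <- function(corpus, seed = 1L, neg_ratio = 1,
                                      negative_class = NEGATIVE_CLASS,
                                      tagger = fallback_tagger()) {
  all <- corpus_training_instances(corpus, seed, neg_ratio, negative_class,
                                   tagger)$instances
  Filter(function(x) !is_positive_class(x$relation_class, negative_class), all)
}

# ---- keyword filter ----------------------------------------------------------

#' Collect interaction keywords from training instances
#'
#' The keyword set is the lemmatized proximal verbs of the positive training
#' instances; it backs the test-time keyword filter.
#'
#' @param instances training `tkrex_instance` list
#' @param negative_class label for non-interacting pairs
#' @return character vector of lemmas (sorted, unique)
#' @export
collect_keywords <- function(instances, negative_class = NEGATIVE_CLASS) {
  lemmas <- vapply(instances, function(x) {
    if (is_positive_class(x$relation_class, negative_class) &&
        !is.na(x$verb_lemma)) x$verb_lemma else NA_character_
  }, "")
  sort(unique(lemmas[!is.na(lemmas)]))
}

#' Filter test instances by interaction keywords
#'
#' A test instance passes iff its sentence contains at least one token whose
#' lemma is in the keyword set. With an empty keyword set the filter passes
#' everything and emits a warning.
#'
#' @param instances list of `tkrex_instance`
#' @param keywords lemma set from [collect_keywords()]
#' @param tagger tagger contract (for lemmatization)
#' @return filtered instance list
#' @export
filter_test_instances <- function(instances, keywords,
                                  tagger = fallback_tagger()) {
  if (!length(keywords)) {
    warning("empty keyword set: keyword filter passes all instances")
    return(instances)
  }
  Filter(function(x) any(tagger$lemmatize(x$orig_tokens) %in% keywords),
         instances)
}

#' Recover the original sentence from an instance
#'
#' Normalization is reversible: each normalized token remembers the original
#' token span it replaced.
#'
#' @param instance a `tkrex_instance`
#' @return the original token vector of the sentence
#' @export
denormalize_instance <- function(instance) instance$orig_tokens
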