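# Synthetic-corpus generator.
#
# Emits corpora in the exact BioCreative dialect of the readers, with
# planted relation classes realized from PoS templates over small fixed
# lexicons (so the fallback tagger tags every word deterministically),
# configurable class imbalance, negative sentences, multi-pair sentences
# and two noise modes.  The generator is the no-download test surface for
# the whole pipeline: a corpus at zero noise carries its templates verbatim
# in every positive sentence's normalized PoS sequence.

template_spec <- function(class, slots, e1_lex, e2_lex) {
  list(class = class, slots = slots, e1_lex = e1_lex, e2_lex = e2_lex)
}

#' Default planted templates
#'
#' Two chemical-protein relation classes with disjoint vocabularies and
#' distinct PoS skeletons:
#' \itemize{
#'   \item CPR:3 (up-regulation): `CHEMICAL RELATION DT NN IN GENEPRO`
#'     ("chemA1 activates the expression of geneA2 ...")
#'   \item CPR:4 (down-regulation): `CHEMICAL RB RELATION GENEPRO NN`
#'     ("chemB1 strongly inhibited geneB2 signaling ...")
#' }
#' Every sentence ends with the neutral tail "in this study ." which keeps
#' flanking-mode noise outside the template context windows for frame sizes
#' up to 3.
#'
#' @return list of template specs
#' @export
default_templates <- function() {
  list(
    template_spec("CPR:3", slots = list(
      list(type = "E1"),
      list(type = "V", words = c("activates", "induces", "stimulates")),
      list(type = "W", words = "the", tag = "DT"),
      list(type = "W", words = c("expression", "release", "activity"), tag = "NN"),
      list(type = "W", words = "of", tag = "IN"),
      list(type = "E2")),
      e1_lex = "chemA", e2_lex = "geneA"),
    template_spec("CPR:4", slots = list(
      list(type = "E1"),
      list(type = "W", words = c("strongly", "markedly", "significantly"),
           tag = "RB"),
      list(type = "V", words = c("inhibited", "suppressed", "blocked")),
      list(type = "E2"),
      list(type = "W", words = c("signaling", "phosphorylation", "degradation"),
           tag = "NN")),
      e1_lex = "chemB", e2_lex = "geneB"))
}

SENTENCE_TAIL <- c("in", "this", "study", ".")
NOISE_VOCAB <- c("moreover", "furthermore", "samples", "results", "notably")
NEG_SENTENCE <- list(verbs = c("were", "measured"),
                     e1_lex = "chemN", e2_lex = "geneN")

# Normalized-PoS skeleton of a template (tail included)
template_skeleton <- function(template) {
  tags <- vapply(template$slots, function(s) switch(s$type,
    E1 = "CHEMICAL", E2 = "GENEPRO", V = "RELATION", W = s$tag), "")
  tail_tags <- fallback_tagger()$tag(SENTENCE_TAIL)
  c(tags, tail_tags)
}

template_anchor <- function(template, role) {
  types <- vapply(template$slots, `[[`, "", "type")
  switch(role, ENTITY1 = match("E1", types), RELATION = match("V", types),
         ENTITY2 = match("E2", types))
}

# Context window of a template skeleton for one role and anchor offset
template_context <- function(template, role, n, e_c = 0L) {
  sk <- template_skeleton(template)
  a <- template_anchor(template, role)
  if (is.na(a)) return(NULL)
  lo <- max(1L, a - e_c); hi <- min(length(sk), a - e_c + n)
  sk[lo:hi]
}

#' Synthetic-corpus configuration
#'
#' @param n_abstracts number of abstracts
#' @param class_proportions named fractions over the template classes
#'   (must sum to 1); defaults to uniform
#' @param negatives_fraction probability that a generated sentence is a
#'   negative (non-interacting chemical+protein) sentence
#' @param noise_token_rate expected noise tokens per core token
#' @param noise_mode `"flanking"` inserts noise only after the sentence tail
#'   (outside template context windows, so planted patterns stay intact at
#'   any rate); `"corrupting"` inserts at uniform positions inside the core
#' @param multi_pair_sentence_rate probability that a positive sentence
#'   carries a second, coordinated chemical (both pairs gold, same class)
#' @param seed integer; fully determines the output
#' @return config list
#' @export
synthetic_config <- function(n_abstracts = 100L, class_proportions = NULL,
                             negatives_fraction = 0.3, noise_token_rate = 0,
                             noise_mode = c("flanking", "corrupting"),
                             multi_pair_sentence_rate = 0.15, seed = 1L) {
  noise_mode <- match.arg(noise_mode)
  list(n_abstracts = as.integer(n_abstracts),
       class_proportions = class_proportions,
       negatives_fraction = negatives_fraction,
       noise_token_rate = noise_token_rate, noise_mode = noise_mode,
       multi_pair_sentence_rate = multi_pair_sentence_rate,
       seed = as.integer(seed))
}

#' Generate a synthetic corpus
#'
#' Abstracts of 1-4 sentences; each positive sentence realizes one template
#' with entity surfaces from the template's lexicon, a relation verb, the
#' neutral tail, and noise at the configured rate; negative sentences hold
#' a non-interacting chemical+protein pair with neutral vocabulary.
#' Byte-identical output under a fixed seed.
#'
#' @param templates list of template specs (default [default_templates()])
#' @param config a [synthetic_config()]
#' @return list: `corpus` (a `tkrex_corpus`), `parses` (fallback parses
#'   keyed `"<doc_id>#<sentence_index>"`), `manifest` (planted ground truth
#'   per sentence), `templates`
#' @export
generate_corpus <- function(templates = default_templates(),
                            config = synthetic_config()) {
  if (!length(templates)) stop("need at least one template", call. = FALSE)
  classes <- vapply(templates, `[[`, "", "class")
  props <- config$class_proportions
  if (is.null(props)) props <- setNames(rep(1 / length(classes), length(classes)),
                                        classes)
  if (abs(sum(props) - 1) > 1e-8)
    stop("class proportions must sum to 1", call. = FALSE)
  if (any(props * config$n_abstracts < 1))
    stop("infeasible class proportions: expected class count below 1", call. = FALSE)
  # separability: templates of distinct classes must differ somewhere
  sks <- lapply(templates, template_skeleton)
  for (i in seq_along(sks)) for (j in seq_along(sks))
    if (i < j && identical(sks[[i]], sks[[j]]))
      stop("templates of distinct classes have identical skeletons", call. = FALSE)

  rng <- make_rng(config$seed)
  tagger <- fallback_tagger()
  docs <- list(); ents <- list(); rels <- list()
  parses <- list(); manifest <- list()
  ent_counter <- 0L

  pick <- function(words) words[rng_int(rng, length(words))]
  sample_class <- function() {
    u <- rng_unif(rng)
    classes[findInterval(u, cumsum(props), left.open = TRUE) + 1L]
  }

  for (d in seq_len(config$n_abstracts)) {
    doc_id <- sprintf("D%04d", d)
    n_sent <- rng_int(rng, 4L)
    title <- sprintf("Synthetic abstract %d", d)
    sent_texts <- character(n_sent)
    doc_ents <- list(); doc_rels <- list(); doc_manifest <- list()
    t_counter <- 0L
    for (s in seq_len(n_sent)) {
      is_neg <- rng_unif(rng) < config$negatives_fraction
      tokens <- character(); roles <- character()
      if (is_neg) {
        ent_counter <- ent_counter + 1L
        e1_surface <- paste0(NEG_SENTENCE$e1_lex, ent_counter)
        ent_counter <- ent_counter + 1L
        e2_surface <- paste0(NEG_SENTENCE$e2_lex, ent_counter)
        tokens <- c(e1_surface, "and", e2_surface, NEG_SENTENCE$verbs)
        roles <- c("E1", "W", "E2", "W", "W")
        cls <- NA_character_; multi <- FALSE
      } else {
        cls <- sample_class()
        tpl <- templates[[match(cls, classes)]]
        multi <- rng_unif(rng) < config$multi_pair_sentence_rate
        for (slot in tpl$slots) {
          if (slot$type == "E1") {
            ent_counter <- ent_counter + 1L
            tokens <- c(tokens, paste0(tpl$e1_lex, ent_counter)); roles <- c(roles, "E1")
            if (multi) {
              ent_counter <- ent_counter + 1L
              tokens <- c(tokens, "and", paste0(tpl$e1_lex, ent_counter))
              roles <- c(roles, "W", "E1b")
            }
          } else if (slot$type == "E2") {
            ent_counter <- ent_counter + 1L
            tokens <- c(tokens, paste0(tpl$e2_lex, ent_counter)); roles <- c(roles, "E2")
          } else {
            tokens <- c(tokens, pick(slot$words)); roles <- c(roles, "W")
          }
        }
      }
      tokens <- c(tokens, SENTENCE_TAIL)
      roles <- c(roles, rep("TAIL", length(SENTENCE_TAIL)))
      # noise insertion
      n_core <- sum(roles %in% c("E1", "E1b", "E2", "V", "W"))
      n_noise <- with_rng(rng, stats::rbinom(1L, n_core, min(1, config$noise_token_rate)))
      if (n_noise > 0L) {
        for (k in seq_len(n_noise)) {
          w <- NOISE_VOCAB[rng_int(rng, length(NOISE_VOCAB))]
          if (config$noise_mode == "flanking") {
            tokens <- c(tokens, w); roles <- c(roles, "NOISE")
          } else {
            at <- rng_int(rng, length(tokens) + 1L) - 1L  # insert after 'at'
            tokens <- append(tokens, w, after = at)
            roles <- append(roles, "NOISE", after = at)
          }
        }
      }
      sent_texts[s] <- paste(tokens, collapse = " ")
      doc_manifest[[s]] <- list(sentence_index = s - 1L,
                                class = cls, multi_pair = multi,
                                tokens = tokens)
      # entity records are positioned after the abstract is assembled
      for (i in seq_along(tokens)) {
        if (roles[i] %in% c("E1", "E1b", "E2")) {
          t_counter <- t_counter + 1L
          doc_ents[[length(doc_ents) + 1L]] <- list(
            mention_id = paste0("T", t_counter),
            entity_type = if (roles[i] == "E2") "GENE_PROTEIN" else "CHEMICAL",
            sentence = s, token_index = i, surface = tokens[i],
            role = roles[i])
        }
      }
      if (!is_neg) {
        sent_ent <- doc_ents[vapply(doc_ents, function(e) e$sentence == s, TRUE)]
        ids_by_role <- function(r) vapply(
          sent_ent[vapply(sent_ent, function(e) e$role == r, TRUE)],
          `[[`, "", "mention_id")
        e2_id <- ids_by_role("E2")
        for (e1_id in c(ids_by_role("E1"), ids_by_role("E1b")))
          doc_rels[[length(doc_rels) + 1L]] <- list(
            relation_class = cls, arg1 = e1_id, arg2 = e2_id)
      }
    }
    abstract <- paste(sent_texts, collapse = " ")
    axis <- paste0(title, "\t", abstract)
    docs[[d]] <- data.frame(doc_id = doc_id, title = title,
                            abstract_text = abstract, stringsAsFactors = FALSE)
    # char offsets on the shared axis
    sent_start <- nchar(title) + 1L  # 0-based offset of abstract start
    for (s in seq_len(n_sent)) {
      toks <- doc_manifest[[s]]$tokens
      tok_off <- integer(length(toks)); off <- sent_start
      for (i in seq_along(toks)) {
        tok_off[i] <- off
        off <- off + nchar(toks[i]) + 1L
      }
      sent_end <- off - 1L
      for (e in doc_ents) {
        if (e$sentence != s) next
        st <- tok_off[e$token_index]
        ents[[length(ents) + 1L]] <- data.frame(
          doc_id = doc_id, mention_id = e$mention_id,
          entity_type = e$entity_type, start = st,
          end = st + nchar(e$surface), surface = e$surface,
          stringsAsFactors = FALSE)
      }
      pos <- tagger$tag(toks)
      parses[[paste0(doc_id, "#", s - 1L)]] <- fallback_parse(toks, pos)
      doc_manifest[[s]]$char_span <- c(sent_start, sent_end)
      sent_start <- sent_end + 1L
    }
    for (r in doc_rels)
      rels[[length(rels) + 1L]] <- data.frame(
        doc_id = doc_id, relation_class = r$relation_class, evaluated = TRUE,
        arg1 = r$arg1, arg2 = r$arg2, stringsAsFactors = FALSE)
    manifest[[doc_id]] <- doc_manifest
  }
  corpus <- new_corpus(
    do.call(rbind, docs),
    if (length(ents)) do.call(rbind, ents) else
      data.frame(doc_id = character(), mention_id = character(),
                 entity_type = character(), start = integer(),
                 end = integer(), surface = character(),
                 stringsAsFactors = FALSE),
    if (length(rels)) do.call(rbind, rels) else empty_relations())
  list(corpus = corpus, parses = parses, manifest = manifest,
       templates = templates)
}

#' Write a generated corpus plus its manifest
#'
#' Emits the three corpus files, the fallback parses as CoNLL-U and the
#' planted ground truth as JSON.
#'
#' @param generated result of [generate_corpus()]
#' @param dir output directory (created if missing)
#' @return invisibly, the file paths
#' @export
write_synthetic_corpus <- function(generated, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list(abstracts = file.path(dir, "abstracts.tsv"),
                entities = file.path(dir, "entities.tsv"),
                relations = file.path(dir, "relations.tsv"),
                parses = file.path(dir, "parses.conllu"),
                manifest = file.path(dir, "manifest.json"))
  write_corpus(generated$corpus, paths$abstracts, paths$entities, paths$relations)
  write_parses(generated$parses, paths$parses)
  jsonlite::write_json(generated$manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}

#' Pattern-recovery report
#'
#' For each planted template, the best total alignment score of its three
#' role contexts against any learned pattern of the same class, maximized
#' over anchor offsets `e_c = 0..n` of the template window. A template
#' counts as recovered when its best score reaches `threshold_frac` of the
#' perfect score (2 per aligned position, summed over its contexts).
#'
#' @param patterns learned patterns (see [learn_patterns()])
#' @param templates planted template specs
#' @param n frame size used when learning
#' @param threshold_frac fraction of the perfect score required
#' @param align_config an [alignment_config()]
#' @return list: `fraction` recovered, `per_template` data.frame with
#'   class, best score, perfect score, recovered flag
#' @export
recovery_report <- function(patterns, templates, n = 3L, threshold_frac = 0.5,
                            align_config = alignment_config()) {
  rows <- lapply(templates, function(tpl) {
    same <- Filter(function(p) p$class == tpl$class, patterns)
    perfect <- 0; best <- -Inf
    for (role in ROLE_NAMES) {
      base_ctx <- template_context(tpl, role, n, 0L)
      if (is.null(base_ctx)) next
      perfect <- perfect + 2 * length(base_ctx)
      role_best <- -Inf
      for (p in same) {
        ctx <- switch(role, ENTITY1 = p$entity1_context,
                      RELATION = p$relation_context,
                      ENTITY2 = p$entity2_context)
        if (is.null(ctx)) next
        for (e_c in 0:n) {
          w <- template_context(tpl, role, n, e_c)
          role_best <- max(role_best,
                           align_pair(ctx, w, align_config)$score)
        }
      }
      best <- if (is.finite(role_best)) {
        if (is.finite(best)) best + role_best else role_best
      } else best
    }
    if (!length(same)) best <- -Inf
    data.frame(class = tpl$class, best_score = best, perfect = perfect,
               recovered = is.finite(best) && best >= threshold_frac * perfect,
               stringsAsFactors = FALSE)
  })
  per_template <- do.call(rbind, rows)
  list(fraction = mean(per_template$recovered), per_template = per_template)
}
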