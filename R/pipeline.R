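# End-to-end pipeline: corpus -> candidate instances -> patterns ->
# pattern-pruned GRCTs -> SPTK Gram matrices -> binary + one-vs-all SVM.
#
# Two tree views are built per candidate pair:
#   binary view: class-hypothesis-free (negative-style normalization, no
#     decoration), matched against the full pattern set -- the interacting /
#     non-interacting gate is trained and applied on these;
#   class view: one tree per class hypothesis, normalized and decorated with
#     that class, matched against that class's patterns -- the one-vs-all
#     models score the matching replica, and the argmax class is assigned to
#     pairs that pass the binary gate.

#' Pipeline configuration with per-task presets
#'
#' Presets follow the per-corpus settings of the method: chemical-protein
#' (`CPI`) uses frame size `n = 3` and score cutoffs `(0, -0.3)`;
#' chemical-disease (`CDR`) uses `n = 5`; protein-protein (`PPI`) uses
#' `n = 3` with the range decision rule (interacting iff the binary score
#' lies in `[0, 1]`).
#'
#' @param mode `"CPI"`, `"CDR"` or `"PPI"`
#' @param n frame size override (defaults to the preset)
#' @param C soft-margin cost
#' @param cutoffs `c(pos_cut, neg_cut)` for the cutoff decision rule
#' @param mu,lambda kernel decay factors
#' @param neg_ratio negative:positive cap per abstract
#' @param min_match_score minimum pattern-match score for pruning
#' @param seed master seed
#' @return a config list
#' @export
pipeline_config <- function(mode = c("CPI", "CDR", "PPI"), n = NULL, C = 1,
                            cutoffs = c(0, -0.3), mu = 0.4, lambda = 0.4,
                            neg_ratio = 1, min_match_score = 0, seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(n)) n <- switch(mode, CPI = 3L, CDR = 5L, PPI = 3L)
  list(mode = mode,
       invariance = invariance_config(n = n),
       align = alignment_config(),
       kernel = kernel_params(mu = mu, lambda = lambda),
       C = C, cutoffs = cutoffs,
       decision_rule = if (mode == "PPI") "range" else "cutoff",
       neg_ratio = neg_ratio, min_match_score = min_match_score,
       seed = as.integer(seed))
}

patterns_of_class <- function(patterns, cl)
  Filter(function(p) p$class == cl, patterns)

instance_tree <- function(instance, patterns, config, decorate_class = NULL) {
  parse <- fallback_parse(instance$norm_tokens, instance$norm_pos)
  tree <- build_grct(parse)
  if (length(patterns)) {
    m <- match_pattern(instance, patterns, config$align, config$min_match_score)
    if (!is.null(m)) tree <- prune_tree(tree, m$covered)
  }
  if (!is.null(decorate_class)) tree <- decorate_tree(tree, decorate_class)
  tree
}

# class-hypothesis-free twin of an instance (negative-style normalization)
neutralize_instance <- function(instance, sentences,
                                negative_class = NEGATIVE_CLASS,
                                tagger = fallback_tagger()) {
  s <- sentences[[paste0(instance$doc_id, "#", instance$sentence_index)]]
  ms <- s$mention_spans
  e1 <- as.list(ms[ms$mention_id == instance$e1_id, ])
  e2 <- as.list(ms[ms$mention_id == instance$e2_id, ])
  build_instance(s, e1, e2, negative_class, 1L, "TRAIN", negative_class, tagger)
}

pair_key <- function(x) paste(x$doc_id, x$e1_id, x$e2_id, sep = "#")

#' Train the full relation-extraction model
#'
#' Runs candidate generation with capped negatives, pattern mining, tree
#' construction (both views), Gram computation and SVM training.
#'
#' @param corpus a training `tkrex_corpus` with gold relations
#' @param config a [pipeline_config()]
#' @param verbose log progress to stderr
#' @return a `tkrex_pipeline_model`
#' @export
train_pipeline <- function(corpus, config = pipeline_config(),
                           verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  tagger <- fallback_tagger()
  ct <- corpus_training_instances(corpus, seed = config$seed,
                                  neg_ratio = config$neg_ratio,
                                  tagger = tagger)
  instances <- ct$instances
  if (!length(instances)) stop("no candidate instances in corpus", call. = FALSE)
  classes <- vapply(instances, function(x) x$relation_class, "")
  say("candidates: %d instances (%d positive)", length(instances),
      sum(classes != NEGATIVE_CLASS))

  learned <- learn_patterns(instances, config$invariance, config$align)
  patterns <- learned$patterns
  say("patterns: %d", length(patterns))
  keywords <- collect_keywords(instances)

  # class view: gold-class normalization, class patterns, gold decoration
  ova_trees <- list()
  for (x in instances)
    ova_trees[[x$instance_id]] <-
      instance_tree(x, patterns_of_class(patterns, x$relation_class), config,
                    decorate_class = x$relation_class)
  gram_ova <- sptk_gram(ova_trees, params = config$kernel)
  positive_classes <- sort(setdiff(unique(classes), NEGATIVE_CLASS))
  ova_models <- train_multiclass_ova(gram_ova, classes, C = config$C,
                                     positive_classes = positive_classes)
  say("one-vs-all models: %s", paste(names(ova_models), collapse = ", "))

  # binary view: hypothesis-free normalization, all patterns, no decoration
  neutral <- lapply(instances, neutralize_instance, sentences = ct$sentences,
                    tagger = tagger)
  keys <- vapply(neutral, pair_key, "")
  keep <- !duplicated(keys)
  neutral <- neutral[keep]
  bin_label <- ifelse(
    vapply(split(classes != NEGATIVE_CLASS, keys), any, TRUE)[keys[keep]],
    1, -1)
  binary_trees <- list()
  for (x in neutral)
    binary_trees[[x$instance_id]] <- instance_tree(x, patterns, config)
  gram_bin <- sptk_gram(binary_trees, params = config$kernel)
  binary_model <- train_binary(gram_bin, bin_label, C = config$C)
  say("binary model: %d support candidates", sum(binary_model$alpha > 0))

  structure(list(patterns = patterns, keywords = keywords,
                 ova_models = ova_models, binary_model = binary_model,
                 ova_trees = ova_trees, binary_trees = binary_trees,
                 positive_classes = positive_classes, config = config),
            class = "tkrex_pipeline_model")
}

#' Predict relations for a test corpus
#'
#' Generates one hypothesis-free tree per candidate pair for the binary
#' gate and one decorated replica per positive class for the one-vs-all
#' stage; applies the keyword filter (filtered pairs are assigned the
#' negative class), the binary cutoff/range rule, and the argmax class
#' assignment.
#'
#' @param model a `tkrex_pipeline_model`
#' @param corpus a test `tkrex_corpus` (relations, if present, are ignored)
#' @param verbose log progress to stderr
#' @return data.frame: doc_id, arg1, arg2, label, score, binary_score
#' @export
predict_pipeline <- function(model, corpus, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  config <- model$config
  tagger <- fallback_tagger()
  neutral <- list(); replicas <- list()
  for (d in seq_len(nrow(corpus$documents))) {
    doc <- as.list(corpus$documents[d, ])
    ents <- corpus$entities[corpus$entities$doc_id == doc$doc_id, , drop = FALSE]
    for (s in segment_and_tag(doc, ents, tagger)) {
      neutral <- c(neutral,
                   generate_candidate_instances(s, NULL, "TRAIN",
                                                tagger = tagger))
      if (length(model$positive_classes))
        replicas <- c(replicas,
                      generate_candidate_instances(s, NULL, "TEST",
                                                   class_inventory = model$positive_classes,
                                                   tagger = tagger))
    }
  }
  if (!length(neutral))
    return(data.frame(doc_id = character(), arg1 = character(),
                      arg2 = character(), label = character(),
                      score = numeric(), binary_score = numeric(),
                      stringsAsFactors = FALSE))
  keys <- vapply(neutral, pair_key, "")
  keep <- !duplicated(keys)
  neutral <- neutral[keep]; keys <- keys[keep]
  passes <- vapply(neutral, function(x)
    any(tagger$lemmatize(x$orig_tokens) %in% model$keywords), TRUE)
  if (!length(model$keywords)) passes[] <- TRUE
  say("test pairs: %d (%d pass keyword filter)", length(neutral), sum(passes))

  n <- length(neutral)
  bscore <- rep(NA_real_, n)
  per_class <- matrix(-Inf, n, length(model$positive_classes),
                      dimnames = list(keys, model$positive_classes))
  active <- which(passes)
  if (length(active)) {
    btrees <- list()
    for (x in neutral[active])
      btrees[[x$instance_id]] <- instance_tree(x, model$patterns, config)
    rows <- sptk_gram(btrees, model$binary_trees, params = config$kernel)
    bscore[active] <- decision_scores(model$binary_model, rows)
    rep_keys <- vapply(replicas, pair_key, "")
    for (cl in model$positive_classes) {
      if (is.null(model$ova_models[[cl]])) next
      sel <- which(rep_keys %in% keys[active] &
                   vapply(replicas, function(x) x$relation_class == cl, TRUE))
      if (!length(sel)) next
      ctrees <- list()
      for (x in replicas[sel])
        ctrees[[x$instance_id]] <-
          instance_tree(x, patterns_of_class(model$patterns, cl), config,
                        decorate_class = cl)
      crows <- sptk_gram(ctrees, model$ova_trees, params = config$kernel)
      sc <- decision_scores(model$ova_models[[cl]], crows)
      per_class[match(rep_keys[sel], keys), cl] <- sc
    }
  }
  interacting <- if (config$decision_rule == "range")
    !is.na(bscore) & bscore >= 0 & bscore <= 1
  else
    !is.na(bscore) & bscore > config$cutoffs[1L]
  label <- rep(NEGATIVE_CLASS, n)
  score <- ifelse(is.na(bscore), -Inf, bscore)
  for (i in which(interacting)) {
    if (ncol(per_class) && any(is.finite(per_class[i, ]))) {
      k <- which.max(per_class[i, ])
      label[i] <- colnames(per_class)[k]
      score[i] <- per_class[i, k]
    } else label[i] <- "POSITIVE"
  }
  data.frame(doc_id = vapply(neutral, function(x) x$doc_id, ""),
             arg1 = vapply(neutral, function(x) x$e1_id, ""),
             arg2 = vapply(neutral, function(x) x$e2_id, ""),
             label = label, score = score, binary_score = bscore,
             stringsAsFactors = FALSE)
}

#' Evaluate pipeline predictions against gold relations
#'
#' Pairs the predictions with the corpus gold standard by
#' (doc_id, arg1, arg2) -- argument order-insensitively -- labels non-gold
#' pairs with the negative class, and reports per-class and pooled
#' precision/recall/F1.
#'
#' @param predictions data.frame from [predict_pipeline()]
#' @param corpus the test `tkrex_corpus` carrying gold relations
#' @return list: `report` (see [evaluate_predictions()]), `binary_f1`
#'   (interacting vs not), `multiclass_f1` (pooled positive-class F1)
#' @export
evaluate_pipeline <- function(predictions, corpus) {
  gold_map <- new.env(parent = emptyenv(), hash = TRUE)
  r <- corpus$relations
  for (i in seq_len(nrow(r))) {
    gold_map[[paste(r$doc_id[i], r$arg1[i], r$arg2[i], sep = "#")]] <-
      r$relation_class[i]
    gold_map[[paste(r$doc_id[i], r$arg2[i], r$arg1[i], sep = "#")]] <-
      r$relation_class[i]
  }
  gold <- vapply(seq_len(nrow(predictions)), function(i) {
    v <- gold_map[[paste(predictions$doc_id[i], predictions$arg1[i],
                         predictions$arg2[i], sep = "#")]]
    if (is.null(v)) NEGATIVE_CLASS else v
  }, "")
  report <- evaluate_predictions(predictions$label, gold)
  bin_pred <- ifelse(predictions$label == NEGATIVE_CLASS, "NEG", "POS")
  bin_gold <- ifelse(gold == NEGATIVE_CLASS, "NEG", "POS")
  bin <- evaluate_predictions(bin_pred, bin_gold, exclude = "NEG")
  list(report = report,
       binary_f1 = bin$F1[bin$class == "ALL"],
       multiclass_f1 = report$F1[report$class == "ALL"])
}
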