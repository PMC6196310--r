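# SVM over precomputed SPTK Gram matrices.
#
# No precomputed-kernel SVM is available in the dependency set, so the dual
# soft-margin problem is solved here with a deterministic SMO (sequential
# minimal optimization) loop.  Problems in this pipeline are small (hundreds
# of instances), where SMO converges in a handful of passes.

#' Train a binary SVM on a precomputed kernel
#'
#' Deterministic SMO on the dual soft-margin problem
#' `max sum(alpha) - 1/2 sum alpha_i alpha_j y_i y_j K_ij`,
#' `0 <= alpha <= C`. The decision function is
#' `f(x) = sum_i alpha_i y_i K(x_i, x) + b`.
#'
#' @param gram symmetric training Gram matrix with instance-id dimnames
#' @param labels vector in `{-1, +1}` (or a 2-level factor/character whose
#'   levels sort `(-1, +1)`), parallel to rows of `gram`
#' @param C soft-margin cost
#' @param tol KKT tolerance
#' @param max_passes SMO passes without change before stopping
#' @return a `tkrex_model`: `alpha`, `y`, `b`, `ids`, `C`
#' @export
train_binary <- function(gram, labels, C = 1, tol = 1e-4, max_passes = 10L) {
  y <- if (is.numeric(labels)) labels else ifelse(labels == sort(unique(labels))[2L], 1, -1)
  if (length(unique(y)) < 2L)
    stop("training labels contain a single class", call. = FALSE)
  stopifnot(nrow(gram) == ncol(gram), nrow(gram) == length(y))
  n <- length(y)
  alpha <- numeric(n); b <- 0
  fcache <- function(i) sum(alpha * y * gram[, i]) + b
  passes <- 0L; max_iter <- 200L; iter <- 0L
  while (passes < max_passes && iter < max_iter) {
    iter <- iter + 1L
    changed <- 0L
    E <- as.numeric(gram %*% (alpha * y)) + b - y
    for (i in seq_len(n)) {
      Ei <- sum(alpha * y * gram[, i]) + b - y[i]
      if ((y[i] * Ei < -tol && alpha[i] < C) ||
          (y[i] * Ei > tol && alpha[i] > 0)) {
        E <- as.numeric(gram %*% (alpha * y)) + b - y
        j_order <- order(-abs(E[i] - E), seq_len(n))
        j <- setdiff(j_order, i)[1L]
        Ej <- E[j]
        ai_old <- alpha[i]; aj_old <- alpha[j]
        if (y[i] != y[j]) {
          L <- max(0, aj_old - ai_old); H <- min(C, C + aj_old - ai_old)
        } else {
          L <- max(0, ai_old + aj_old - C); H <- min(C, ai_old + aj_old)
        }
        if (L >= H) next
        eta <- 2 * gram[i, j] - gram[i, i] - gram[j, j]
        if (eta >= 0) next
        aj <- aj_old - y[j] * (Ei - Ej) / eta
        aj <- min(H, max(L, aj))
        if (abs(aj - aj_old) < 1e-7) next
        ai <- ai_old + y[i] * y[j] * (aj_old - aj)
        alpha[i] <- ai; alpha[j] <- aj
        b1 <- b - Ei - y[i] * (ai - ai_old) * gram[i, i] -
          y[j] * (aj - aj_old) * gram[i, j]
        b2 <- b - Ej - y[i] * (ai - ai_old) * gram[i, j] -
          y[j] * (aj - aj_old) * gram[j, j]
        b <- if (ai > 0 && ai < C) b1
             else if (aj > 0 && aj < C) b2
             else (b1 + b2) / 2
        changed <- changed + 1L
      }
    }
    passes <- if (changed == 0L) passes + 1L else 0L
  }
  structure(list(alpha = alpha, y = y, b = b,
                 ids = rownames(gram), C = C),
            class = "tkrex_model")
}

#' Decision scores of a trained model
#'
#' @param model a `tkrex_model`
#' @param gram_rows kernel rows `K(test_i, train_j)`, columns aligned to the
#'   model's training ids (checked via column names when present)
#' @return numeric decision scores
#' @export
decision_scores <- function(model, gram_rows) {
  if (is.null(dim(gram_rows))) gram_rows <- matrix(gram_rows, nrow = 1L)
  if (ncol(gram_rows) != length(model$alpha))
    stop("kernel rows do not match the model's training set", call. = FALSE)
  if (!is.null(colnames(gram_rows)) && !is.null(model$ids) &&
      !identical(colnames(gram_rows), model$ids))
    stop("kernel row columns are not aligned to the model's training ids",
         call. = FALSE)
  as.numeric(gram_rows %*% (model$alpha * model$y)) + model$b
}

#' Train one-vs-all models for the positive classes
#'
#' One binary model per positive class label (class vs all other training
#' instances). A class with fewer than 2 instances is skipped with a
#' warning and can then never be assigned at prediction time.
#'
#' @param gram symmetric training Gram matrix
#' @param labels class labels parallel to rows
#' @param C soft-margin cost
#' @param positive_classes classes to build models for; defaults to every
#'   label except [NEGATIVE_CLASS]
#' @param class_weight if `TRUE`, scale C per class inversely to class
#'   frequency (imbalance mitigation; off by default)
#' @return named list of `tkrex_model`
#' @export
train_multiclass_ova <- function(gram, labels, C = 1,
                                 positive_classes = NULL,
                                 class_weight = FALSE) {
  if (is.null(positive_classes))
    positive_classes <- setdiff(sort(unique(labels)), NEGATIVE_CLASS)
  if (length(unique(labels)) < 2L) stop("need at least 2 classes", call. = FALSE)
  models <- list()
  for (cl in positive_classes) {
    n_cl <- sum(labels == cl)
    if (n_cl < 2L) {
      warning(sprintf("class %s has %d instance(s); OvA model skipped", cl, n_cl))
      next
    }
    y <- ifelse(labels == cl, 1, -1)
    Ccl <- if (class_weight) C * length(labels) / (2 * n_cl) else C
    models[[cl]] <- train_binary(gram, y, Ccl)
  }
  models
}

#' Two-stage prediction: binary gate, then one-vs-all
#'
#' Binary stage: a candidate is interacting when its binary score exceeds
#' `pos_cut`, non-interacting below `neg_cut`, and scores in the dead zone
#' `[neg_cut, pos_cut]` abstain to non-interacting. In `"range"` mode
#' (protein-protein corpora) a pair is interacting iff the score lies in
#' `[0, 1]`. Interacting candidates are then scored by every OvA model and
#' assigned the argmax class.
#'
#' @param binary_model `tkrex_model` for interacting-vs-not
#' @param ova_models named list from [train_multiclass_ova()]
#' @param binary_rows kernel rows of the test instances against the binary
#'   model's training set
#' @param ova_rows kernel rows against the OvA training set (may be the same
#'   matrix)
#' @param instance_ids ids parallel to the rows
#' @param cutoffs `c(pos_cut, neg_cut)`; defaults `(0, -0.3)`
#' @param decision_rule `"cutoff"` or `"range"`
#' @param negative_class label assigned to non-interacting candidates
#' @return data.frame: instance_id, binary_score, label, score, plus one
#'   `score.<class>` column per OvA model
#' @export
predict_relations <- function(binary_model, ova_models, binary_rows, ova_rows,
                              instance_ids, cutoffs = c(0, -0.3),
                              decision_rule = c("cutoff", "range"),
                              negative_class = NEGATIVE_CLASS) {
  decision_rule <- match.arg(decision_rule)
  if (is.null(dim(binary_rows))) binary_rows <- matrix(binary_rows, nrow = 1L)
  bscore <- decision_scores(binary_model, binary_rows)
  interacting <- if (decision_rule == "range")
    bscore >= 0 & bscore <= 1
  else
    bscore > cutoffs[1L]
  per_class <- if (length(ova_models))
    vapply(ova_models, function(m) decision_scores(m, ova_rows),
           numeric(length(bscore)))
  else matrix(numeric(0), nrow = length(bscore), ncol = 0L)
  if (is.null(dim(per_class)))
    per_class <- matrix(per_class, nrow = length(bscore),
                        dimnames = list(NULL, names(ova_models)))
  label <- rep(negative_class, length(bscore))
  score <- bscore
  for (i in which(interacting)) {
    if (ncol(per_class)) {
      k <- which.max(per_class[i, ])
      label[i] <- colnames(per_class)[k]
      score[i] <- per_class[i, k]
    } else {
      label[i] <- "POSITIVE"
    }
  }
  out <- data.frame(instance_id = instance_ids, binary_score = bscore,
                    label = label, score = score, stringsAsFactors = FALSE)
  if (ncol(per_class))
    for (cl in colnames(per_class)) out[[paste0("score.", cl)]] <- per_class[, cl]
  out
}

# ---- evaluation --------------------------------------------------------------

#' Per-class precision, recall and F1
#'
#' `P = TP/(TP+FP)`, `R = TP/(TP+FN)`, `F1 = 2PR/(P+R)` for every class in
#' the union of predicted and gold labels; the negative class can be
#' excluded (standard for relation extraction, where only interacting pairs
#' are scored).
#'
#' @param predicted,gold parallel label vectors keyed identically (same
#'   instances in the same order)
#' @param exclude character vector of classes not to report (default: the
#'   negative class)
#' @return data.frame: class, TP, FP, FN, P, R, F1, plus an aggregate
#'   `"ALL"` row over the pooled counts
#' @export
evaluate_predictions <- function(predicted, gold, exclude = NEGATIVE_CLASS) {
  if (!length(gold)) stop("empty gold standard", call. = FALSE)
  stopifnot(length(predicted) == length(gold))
  classes <- setdiff(sort(unique(c(predicted, gold))), exclude)
  prf <- function(tp, fp, fn) {
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    c(p, r, f)
  }
  rows <- lapply(classes, function(cl) {
    tp <- sum(predicted == cl & gold == cl)
    fp <- sum(predicted == cl & gold != cl)
    fn <- sum(predicted != cl & gold == cl)
    m <- prf(tp, fp, fn)
    data.frame(class = cl, TP = tp, FP = fp, FN = fn,
               P = m[1], R = m[2], F1 = m[3], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  tp <- sum(out$TP); fp <- sum(out$FP); fn <- sum(out$FN)
  m <- prf(tp, fp, fn)
  rbind(out, data.frame(class = "ALL", TP = tp, FP = fp, FN = fn,
                        P = m[1], R = m[2], F1 = m[3],
                        stringsAsFactors = FALSE))
}

#' Data-size-weighted micro-average of F1 scores
#'
#' `avg_mu = sum(F1_k * w_k) / sum(w_k)` over evaluation sets `k`.
#'
#' @param f1s per-set F1 scores
#' @param weights proportional data sizes `w_k`
#' @return the weighted mean
#' @export
micro_average <- function(f1s, weights) {
  stopifnot(length(f1s) == length(weights), sum(weights) > 0)
  sum(f1s * weights) / sum(weights)
}

# ---- model archive -----------------------------------------------------------

#' Save a model archive
#'
#' Single portable JSON file holding the binary and OvA models (dual
#' coefficients, bias, training ids), the serialized training trees and the
#' kernel-parameter snapshot, sufficient to reproduce the decision function.
#'
#' @param binary_model,ova_models trained models
#' @param train_trees named list of GRCT roots used for training
#' @param params the [kernel_params()] snapshot
#' @param path output path
#' @export
write_model_archive <- function(binary_model, ova_models, train_trees,
                                params, path) {
  pack <- function(m) list(alpha = m$alpha, y = m$y, b = m$b, ids = m$ids,
                           C = m$C)
  obj <- list(
    binary = pack(binary_model),
    ova = lapply(ova_models, pack),
    trees = lapply(train_trees, serialize_tree),
    kernel = params[c("mu", "lambda", "similarity_mode", "normalize")])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

#' Load a model archive written by [write_model_archive()]
#' @param path input path
#' @return list: `binary`, `ova`, `trees`, `kernel`
#' @export
read_model_archive <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  unpack <- function(m)
    structure(list(alpha = as.numeric(m$alpha), y = as.numeric(m$y),
                   b = as.numeric(m$b), ids = as.character(m$ids),
                   C = as.numeric(m$C)), class = "tkrex_model")
  trees <- lapply(obj$trees, parse_tree)
  ova <- lapply(obj$ova, unpack)
  list(binary = unpack(obj$binary), ova = ova, trees = trees,
       kernel = kernel_params(mu = obj$kernel$mu, lambda = obj$kernel$lambda,
                              similarity_mode = obj$kernel$similarity_mode,
                              normalize = obj$kernel$normalize))
}
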