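# Grammatical-relation-centered trees (GRCT).
#
# A GRCT re-expresses a dependency parse in three node layers: SYNT nodes
# carry the grammatical relation of each head-dependent edge, POS nodes the
# part of speech, and LEX leaves the tokens.  Pattern-guided pruning removes
# the leaves (and their now-empty ancestor hierarchies) that the selected
# linguistic pattern does not cover; decoration prefixes a class node so the
# kernel can separate interaction types.

grct_node <- function(label, kind, children = list(), token = NA_integer_) {
  list(label = label, kind = kind, children = children, token = token)
}

# ---- fallback dependency parser ----------------------------------------------

#' Deterministic fallback dependency parser
#'
#' A heuristic parse good enough to exercise the pipeline without an
#' external parser: the first verb (or Relation tag) is the root; every
#' other token attaches to the nearest verb (ties to the left), non-root
#' verbs attach to the root, and if the sentence has no verb everything
#' attaches to the first token. Dependency labels are coarse Universal
#' Dependencies names chosen by PoS. Real parses enter via [read_parses()].
#'
#' @param tokens,pos parallel token and PoS vectors
#' @return a `tkrex_parse`
#' @export
fallback_parse <- function(tokens, pos) {
  n <- length(tokens)
  stopifnot(n >= 1L, length(pos) == n)
  verbish <- which(startsWith(pos, "VB") | pos == "RELATION")
  heads <- integer(n); deprels <- character(n)
  if (!length(verbish)) {
    root <- 1L
    heads[] <- root; heads[root] <- 0L
  } else {
    root <- verbish[1L]
    for (i in seq_len(n)) {
      if (i == root) { heads[i] <- 0L; next }
      if (i %in% verbish) { heads[i] <- root; next }
      d <- abs(verbish - i)
      heads[i] <- verbish[order(d, verbish)][1L]
    }
  }
  for (i in seq_len(n)) {
    if (heads[i] == 0L) { deprels[i] <- "root"; next }
    p <- pos[i]
    deprels[i] <-
      if (p == "DT") "det"
      else if (p == "IN") "case"
      else if (p == "TO") "mark"
      else if (p == "JJ") "amod"
      else if (p == "RB") "advmod"
      else if (p == "CC") "cc"
      else if (p %in% c(".", ",", ":")) "punct"
      else if (startsWith(p, "VB") || p == "RELATION") "conj"
      else if (i < heads[i]) "nsubj"
      else "obj"
  }
  new_parse(tokens, heads, deprels, pos)
}

# ---- GRCT construction -------------------------------------------------------

#' Build the GRCT of a dependency parse
#'
#' One SYNT node per dependency relation, arranged by head structure: the
#' SYNT node of a head token has as children the SYNT subtrees of its
#' dependents together with the head's own POS-LEX chain, all ordered by
#' token position so that the left-to-right LEX leaf order equals the token
#' order.
#'
#' @param parse a `tkrex_parse` (single-rooted, acyclic)
#' @return the root `grct_node`
#' @export
build_grct <- function(parse) {
  n <- length(parse$tokens)
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    h <- parse$heads[i]
    if (h > 0L) kids[[h]] <- c(kids[[h]], i)
  }
  build <- function(i) {
    chain <- grct_node(parse$pos[i], "POS",
                       list(grct_node(parse$tokens[i], "LEX", token = i)))
    deps <- kids[[i]]
    parts <- lapply(deps, build)
    ord <- order(c(deps, i))
    children <- c(parts, list(chain))[ord]
    grct_node(parse$deprels[i], "SYNT", children)
  }
  root <- which(parse$heads == 0L)
  if (length(root) != 1L) stop("parse must have exactly one root", call. = FALSE)
  build(root)
}

tree_lex_tokens <- function(node) {
  if (node$kind == "LEX") return(node$token)
  unlist(lapply(node$children, tree_lex_tokens))
}

tree_lex_labels <- function(node) {
  if (node$kind == "LEX") return(node$label)
  unlist(lapply(node$children, tree_lex_labels))
}

tree_size <- function(node) {
  1L + sum(vapply(node$children, tree_size, 0L))
}

# ---- pattern matching --------------------------------------------------------

role_symbol <- function(instance, role) {
  switch(role, ENTITY1 = "CHEMICAL", RELATION = "RELATION",
         ENTITY2 = instance$norm_pos[instance$e2_idx])
}

match_one_context <- function(instance, context, role, align_config) {
  anchor <- role_anchor(instance, role)
  if (is.na(anchor) || is.null(context)) return(NULL)
  pa <- match(role_symbol(instance, role), context)
  if (is.na(pa)) pa <- 1L
  start <- anchor - (pa - 1L)
  len <- length(instance$norm_pos)
  lo <- max(1L, start); hi <- min(len, start + length(context) - 1L)
  if (hi < lo) return(NULL)
  window <- instance$norm_pos[lo:hi]
  al <- align_pair(context, window, align_config)
  covered <- integer(); wi <- lo - 1L
  for (p in seq_along(al$b_aligned)) {
    if (al$b_aligned[p] != "-") {
      wi <- wi + 1L
      if (al$a_aligned[p] != "-") covered <- c(covered, wi)
    }
  }
  list(score = al$score, covered = covered)
}

#' Match linguistic patterns against a candidate instance
#'
#' Each pattern's three contexts are globally aligned against the
#' instance's normalized PoS sequence, each anchored at its referential
#' group's position; the pattern score is the sum of the three alignment
#' scores (an absent role contributes 0). Returns the best-scoring pattern
#' with the normalized-token indices its non-gap columns cover -- the focal
#' entity tokens are always included -- or `NULL` if no pattern reaches
#' `min_score`.
#'
#' @param instance a `tkrex_instance`
#' @param patterns list of patterns (see [learn_patterns()])
#' @param align_config an [alignment_config()]
#' @param min_score minimum total score for a usable match; the default
#'   accepts any strictly positive alignment
#' @return `list(pattern, covered, score)` or `NULL`
#' @export
match_pattern <- function(instance, patterns,
                          align_config = alignment_config(), min_score = 0) {
  if (!length(patterns)) stop("empty pattern set", call. = FALSE)
  best <- NULL
  for (p in patterns) {
    total <- 0; covered <- integer()
    for (role in ROLE_NAMES) {
      ctx <- switch(role, ENTITY1 = p$entity1_context,
                    RELATION = p$relation_context,
                    ENTITY2 = p$entity2_context)
      m <- match_one_context(instance, ctx, role, align_config)
      if (!is.null(m)) { total <- total + m$score; covered <- c(covered, m$covered) }
    }
    if (is.null(best) || total > best$score)
      best <- list(pattern = p, covered = covered, score = total)
  }
  if (is.null(best) || best$score <= min_score) return(NULL)
  focal <- c(instance$e1_idx, instance$e2_idx, instance$rel_idx)
  best$covered <- sort(unique(c(best$covered, focal[!is.na(focal)])))
  best
}

# ---- pruning and decoration --------------------------------------------------

#' Prune a GRCT to the tokens a pattern covers
#'
#' Removes LEX leaves whose token index is not in the covered set, then
#' every POS/SYNT ancestor left without any LEX descendant. The relative
#' order of surviving leaves is preserved.
#'
#' @param tree a GRCT root
#' @param covered integer set of covered token indices (from
#'   [match_pattern()]'s `covered`)
#' @return the pruned GRCT root
#' @export
prune_tree <- function(tree, covered) {
  if (!length(covered)) stop("match covers no tokens", call. = FALSE)
  rec <- function(node) {
    if (node$kind == "LEX")
      return(if (node$token %in% covered) node else NULL)
    kept <- Filter(Negate(is.null), lapply(node$children, rec))
    if (!length(kept)) return(NULL)
    node$children <- kept
    node
  }
  out <- rec(tree)
  if (is.null(out)) stop("match covers no tokens of this tree", call. = FALSE)
  out
}

#' Decorate a GRCT with its interaction-class node
#'
#' Wraps the tree in a fresh super-root whose leftmost child is a class
#' node (e.g. `Class4` for a CPR:4 interaction), so the kernel sees the
#' class hypothesis as part of the structure. Decorating twice is an error.
#'
#' @param tree a (typically pruned) GRCT root
#' @param class_label relation class string, e.g. `"CPR:4"`
#' @return the decorated GRCT root
#' @export
decorate_tree <- function(tree, class_label) {
  if (identical(tree$label, "TOP") && tree$kind == "SYNT" &&
      length(tree$children) >= 1L &&
      identical(tree$children[[1L]]$label, "class"))
    stop("tree is already decorated", call. = FALSE)
  class_leaf <- grct_node(paste0("Class", class_number(class_label)), "LEX",
                          token = 0L)
  class_node <- grct_node("class", "SYNT",
                          list(grct_node("CLASS", "POS", list(class_leaf))))
  grct_node("TOP", "SYNT", list(class_node, tree))
}

# ---- serialization -----------------------------------------------------------

escape_label <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub("(", "%28", x, fixed = TRUE)
  x <- gsub(")", "%29", x, fixed = TRUE)
  x <- gsub(" ", "%20", x, fixed = TRUE)
  x
}
unescape_label <- function(x) {
  x <- gsub("%20", " ", x, fixed = TRUE)
  x <- gsub("%29", ")", x, fixed = TRUE)
  x <- gsub("%28", "(", x, fixed = TRUE)
  x <- gsub("%25", "%", x, fixed = TRUE)
  x
}

#' Serialize a GRCT to a bracketed string
#'
#' Deterministic child-order-preserving serialization,
#' `(KIND:label child child ...)`; parentheses, spaces and percent signs in
#' labels are percent-escaped.
#'
#' @param tree a GRCT root
#' @return a single string
#' @export
serialize_tree <- function(tree) {
  rec <- function(node) {
    head <- paste0(node$kind, ":", escape_label(node$label))
    if (!length(node$children)) return(paste0("(", head, ")"))
    paste0("(", head, paste0(vapply(node$children, rec, ""), collapse = ""), ")")
  }
  rec(tree)
}

#' Parse a bracketed GRCT string
#'
#' Inverse of [serialize_tree()]; errors name the character position of any
#' bracket imbalance.
#'
#' @param text a bracketed tree string
#' @return the GRCT root
#' @export
parse_tree <- function(text) {
  i <- 1L; n <- nchar(text)
  peek <- function() substr(text, i, i)
  fail <- function(msg) stop(sprintf("tree parse error at position %d: %s", i, msg),
                             call. = FALSE)
  rec <- function() {
    if (peek() != "(") fail("expected '('")
    i <<- i + 1L
    j <- i
    while (j <= n && !substr(text, j, j) %in% c("(", ")")) j <- j + 1L
    head <- substr(text, i, j - 1L)
    i <<- j
    parts <- strsplit(head, ":", fixed = TRUE)[[1]]
    if (length(parts) < 2L) fail("node must be KIND:label")
    kind <- parts[1L]
    label <- unescape_label(paste(parts[-1L], collapse = ":"))
    children <- list()
    while (i <= n && peek() == "(")
      children[[length(children) + 1L]] <- rec()
    if (i > n || peek() != ")") fail("expected ')'")
    i <<- i + 1L
    grct_node(label, kind, children)
  }
  out <- rec()
  if (i <= n && nzchar(trimws(substr(text, i, n)))) fail("trailing text")
  out
}

#' Write trees as one bracketed line per instance
#' @param trees named list of GRCT roots (names are instance ids)
#' @param path output path
#' @export
write_trees <- function(trees, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(trees))
    writeLines(paste(names(trees),
                     vapply(trees, serialize_tree, ""), sep = "\t"),
               con, sep = "\n")
  invisible(NULL)
}

#' Read trees written by [write_trees()]
#' @param path input path
#' @return named list of GRCT roots
#' @export
read_trees <- function(path) {
  lines <- read_tsv_lines(path)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    f <- split_fields(ln)
    if (length(f) != 2L) stop("malformed tree line: ", ln, call. = FALSE)
    out[[f[1L]]] <- parse_tree(f[2L])
  }
  out
}
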