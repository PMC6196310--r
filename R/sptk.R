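# Smoothed partial tree kernel over GRCTs.
#
# K(T1, T2) = sum over all node pairs of Delta(n1, n2), where Delta counts
# (decay-weighted) shared partial-tree fragments rooted at the pair.  Node
# matching goes through a graded similarity sigma: exact kind+label match by
# default, or a user-supplied lexical similarity table for LEX-LEX pairs.

#' Kernel parameters
#'
#' @param mu vertical decay factor in (0, 1]; penalizes fragment depth
#' @param lambda horizontal decay factor in (0, 1]; penalizes fragment width
#'   and gaps in child subsequences
#' @param similarity_mode `"EXACT_LABEL"` or `"LEXICAL_TABLE"`
#' @param normalize normalize so that `K(t, t) = 1`
#' @param lexical_table for `LEXICAL_TABLE` mode: data.frame with columns
#'   `label_a`, `label_b`, `similarity` (values in `[0, 1]`), applied
#'   symmetrically to LEX-LEX pairs; pairs absent from the table fall back
#'   to exact match
#' @return a `KernelParams` list
#' @export
kernel_params <- function(mu = 0.4, lambda = 0.4,
                          similarity_mode = c("EXACT_LABEL", "LEXICAL_TABLE"),
                          normalize = TRUE, lexical_table = NULL) {
  similarity_mode <- match.arg(similarity_mode)
  if (mu <= 0 || mu > 1 || lambda <= 0 || lambda > 1)
    stop("decay factors mu and lambda must lie in (0, 1]", call. = FALSE)
  if (similarity_mode == "LEXICAL_TABLE") {
    if (is.null(lexical_table))
      stop("LEXICAL_TABLE mode requires a lexical_table", call. = FALSE)
    if (any(lexical_table$similarity < 0 | lexical_table$similarity > 1))
      stop("lexical similarities must lie in [0, 1]", call. = FALSE)
  }
  list(mu = mu, lambda = lambda, similarity_mode = similarity_mode,
       normalize = normalize, lexical_table = lexical_table)
}

#' Read a lexical-similarity table
#'
#' Three-column file `label_a TAB label_b TAB similarity`.
#'
#' @param path input path
#' @return data.frame usable as `lexical_table` in [kernel_params()]
#' @export
read_lexical_table <- function(path) {
  lines <- read_tsv_lines(path)
  lines <- lines[nzchar(lines)]
  f <- lapply(lines, split_fields)
  tab <- data.frame(label_a = vapply(f, `[`, "", 1L),
                    label_b = vapply(f, `[`, "", 2L),
                    similarity = as.numeric(vapply(f, `[`, "", 3L)),
                    stringsAsFactors = FALSE)
  if (any(tab$similarity < 0 | tab$similarity > 1))
    stop("lexical similarities must lie in [0, 1]", call. = FALSE)
  tab
}

#' Node similarity sigma
#'
#' `EXACT_LABEL`: 1 for same kind and same label, else 0.
#' `LEXICAL_TABLE`: for LEX-LEX pairs, the (symmetric) table value, falling
#' back to exact match when the pair is absent; all other kinds use exact
#' match.
#'
#' @param a,b `grct_node`s
#' @param params a [kernel_params()]
#' @return similarity in `[0, 1]`
#' @export
node_similarity <- function(a, b, params = kernel_params()) {
  if (a$kind != b$kind) return(0)
  if (a$label == b$label) return(1)
  if (params$similarity_mode == "LEXICAL_TABLE" && a$kind == "LEX") {
    tab <- params$lexical_table
    hit <- which((tab$label_a == a$label & tab$label_b == b$label) |
                 (tab$label_a == b$label & tab$label_b == a$label))
    if (length(hit)) return(tab$similarity[hit[1L]])
  }
  0
}

# Flatten trees to the C++ representation: preorder node list with integer
# label ids drawn from a shared kind-qualified dictionary.
flatten_trees <- function(trees, params) {
  dict <- new.env(parent = emptyenv(), hash = TRUE)
  dict$n <- 0L
  label_id <- function(kind, label) {
    k <- paste0(kind, "\x1f", label)
    v <- dict[[k]]
    if (is.null(v)) {
      dict$n <- dict$n + 1L
      v <- dict$n
      dict[[k]] <- v
    }
    v
  }
  flat <- lapply(trees, function(tree) {
    labels <- integer(); children <- list(); kinds <- character()
    rec <- function(node) {
      id <- length(labels) + 1L
      labels[id] <<- label_id(node$kind, node$label)
      kinds[id] <<- node$kind
      children[[id]] <<- integer()
      for (ch in node$children) {
        cid <- rec(ch)
        children[[id]] <<- c(children[[id]], cid - 1L)  # 0-based for C++
      }
      id
    }
    rec(tree)
    list(labels = labels - 1L, children = children, kinds = kinds)
  })
  nlab <- dict$n
  S <- diag(1, nlab, nlab)
  if (params$similarity_mode == "LEXICAL_TABLE" &&
      !is.null(params$lexical_table)) {
    tab <- params$lexical_table
    for (r in seq_len(nrow(tab))) {
      ka <- paste0("LEX\x1f", tab$label_a[r])
      kb <- paste0("LEX\x1f", tab$label_b[r])
      ia <- dict[[ka]]; ib <- dict[[kb]]
      if (!is.null(ia) && !is.null(ib) && ia != ib) {
        S[ia, ib] <- tab$similarity[r]
        S[ib, ia] <- tab$similarity[r]
      }
    }
  }
  list(flat = flat, S = S)
}

#' Delta of the smoothed partial tree kernel at a node pair
#'
#' Leaf pair: `mu * lambda * sigma`. Internal pair:
#' `mu * sigma * (lambda^2 + sum over equal-length child subsequence pairs
#' of lambda^(d1+d2) * prod Delta(child pairs))`, with `d` the index span
#' of a subsequence. Exposed mainly for testing; [sptk_kernel()] sums it
#' over all node pairs.
#'
#' @param a,b `grct_node`s (roots of the subtrees compared)
#' @param params a [kernel_params()]
#' @return the Delta value
#' @export
delta_sptk <- function(a, b, params = kernel_params()) {
  # R-side recursion (the C++ path exposes only the full double sum); the
  # trees Delta is called on directly are small, so this stays cheap
  sigma <- node_similarity(a, b, params)
  if (sigma == 0) return(0)
  mu <- params$mu; la <- params$lambda
  if (!length(a$children) && !length(b$children)) return(mu * la * sigma)
  p <- length(a$children); q <- length(b$children)
  total <- 0
  if (p > 0 && q > 0) {
    D <- matrix(0, p, q)
    for (x in seq_len(p)) for (y in seq_len(q))
      D[x, y] <- delta_sptk(a$children[[x]], b$children[[y]], params)
    C <- D
    total <- sum(C)
    lmax <- min(p, q)
    l <- 1L
    while (l < lmax) {
      T <- matrix(0, p, q)
      for (x in seq_len(p)) for (y in seq_len(q)) {
        t <- C[x, y]
        if (x > 1) t <- t + la * T[x - 1, y]
        if (y > 1) t <- t + la * T[x, y - 1]
        if (x > 1 && y > 1) t <- t - la^2 * T[x - 1, y - 1]
        T[x, y] <- t
      }
      Cn <- matrix(0, p, q)
      for (x in seq_len(p)) for (y in seq_len(q))
        if (x > 1 && y > 1) Cn[x, y] <- D[x, y] * la^2 * T[x - 1, y - 1]
      C <- Cn
      lev <- sum(C)
      total <- total + lev
      if (lev == 0) break
      l <- l + 1L
    }
  }
  mu * sigma * la^2 * (1 + total)
}

#' Smoothed partial tree kernel between two GRCTs
#'
#' `K(T1, T2) = sum over node pairs of Delta`; with `normalize` the value
#' is `K / sqrt(K(T1,T1) K(T2,T2))`.
#'
#' @param t1,t2 GRCT roots
#' @param params a [kernel_params()]
#' @return the kernel value
#' @export
sptk_kernel <- function(t1, t2, params = kernel_params()) {
  fl <- flatten_trees(list(t1, t2), params)
  k <- cpp_sptk_pair(fl$flat[[1L]], fl$flat[[2L]], fl$S,
                     params$mu, params$lambda)
  if (params$normalize) {
    k11 <- cpp_sptk_pair(fl$flat[[1L]], fl$flat[[1L]], fl$S,
                         params$mu, params$lambda)
    k22 <- cpp_sptk_pair(fl$flat[[2L]], fl$flat[[2L]], fl$S,
                         params$mu, params$lambda)
    if (k11 <= 0 || k22 <= 0)
      stop("zero self-kernel under normalization (degenerate tree or sigma)",
           call. = FALSE)
    k <- k / sqrt(k11 * k22)
  }
  k
}

#' Gram matrix of the smoothed partial tree kernel
#'
#' Symmetry is exploited when `cols` is `NULL` (rows vs themselves).
#'
#' @param rows named list of GRCT roots
#' @param cols named list of GRCT roots, or `NULL` for the symmetric case
#' @param params a [kernel_params()]
#' @return numeric matrix with row/column names from the tree ids
#' @export
sptk_gram <- function(rows, cols = NULL, params = kernel_params()) {
  stopifnot(length(rows) >= 1L)
  symmetric <- is.null(cols)
  all_trees <- if (symmetric) rows else c(rows, cols)
  fl <- flatten_trees(all_trees, params)
  nr <- length(rows)
  frow <- fl$flat[seq_len(nr)]
  fcol <- if (symmetric) list() else fl$flat[-seq_len(nr)]
  G <- cpp_sptk_gram(frow, fcol, fl$S, params$mu, params$lambda, symmetric)
  if (params$normalize) {
    self_of <- function(f) vapply(f, function(t)
      cpp_sptk_pair(t, t, fl$S, params$mu, params$lambda), 0)
    sr <- if (symmetric) diag(G) else self_of(frow)
    sc <- if (symmetric) sr else self_of(fcol)
    if (any(sr <= 0) || any(sc <= 0))
      stop("zero self-kernel under normalization", call. = FALSE)
    G <- G / sqrt(outer(sr, sc))
  }
  rownames(G) <- names(rows)
  colnames(G) <- if (symmetric) names(rows) else names(cols)
  G
}

#' Write a Gram matrix as dense TSV with id headers
#' @param gram matrix from [sptk_gram()]
#' @param path output path
#' @export
write_gram <- function(gram, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c("id", colnames(gram)), collapse = "\t"), con, sep = "\n")
  for (i in seq_len(nrow(gram)))
    writeLines(paste(c(rownames(gram)[i],
                       format(gram[i, ], trim = TRUE, digits = 12)),
                     collapse = "\t"), con, sep = "\n")
  invisible(NULL)
}

#' Read a Gram matrix written by [write_gram()]
#' @param path input path
#' @return numeric matrix with dimnames
#' @export
read_gram <- function(path) {
  lines <- read_tsv_lines(path)
  lines <- lines[nzchar(lines)]
  header <- split_fields(lines[1L])[-1L]
  rows <- lapply(lines[-1L], split_fields)
  G <- t(vapply(rows, function(r) as.numeric(r[-1L]), numeric(length(header))))
  rownames(G) <- vapply(rows, `[`, "", 1L)
  colnames(G) <- header
  G
}
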