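#' @useDynLib tkrex, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats setNames
#' @importFrom utils head tail
NULL

# BioCreative-style tab-separated corpus I/O.
#
# A corpus is three parallel tables:
#   documents: doc_id, title, abstract_text
#   entities : doc_id, mention_id, entity_type, start, end, surface
#   relations: doc_id, relation_class, evaluated, arg1, arg2
#
# Character offsets are 0-based half-open over the axis
# title + "\t" + abstract (title and abstract share one axis).

ENTITY_TYPES <- c("CHEMICAL", "GENE_PROTEIN", "DISEASE", "PROTEIN")

#' Document character axis
#'
#' Title and abstract share a single 0-based character axis, joined by a
#' tab character. All entity offsets are interpreted on this axis.
#'
#' @param document one row of the documents table (list or 1-row data.frame)
#' @return a single string
#' @export
document_text <- function(document) {
  paste0(document$title, "\t", document$abstract_text)
}

new_corpus <- function(documents, entities, relations) {
  structure(list(documents = documents, entities = entities,
                 relations = relations),
            class = "tkrex_corpus")
}

#' @export
print.tkrex_corpus <- function(x, ...) {
  cat(sprintf("tkrex corpus: %d documents, %d entity mentions, %d relations\n",
              nrow(x$documents), nrow(x$entities), nrow(x$relations)))
  invisible(x)
}

empty_relations <- function() {
  data.frame(doc_id = character(), relation_class = character(),
             evaluated = logical(), arg1 = character(), arg2 = character(),
             stringsAsFactors = FALSE)
}

read_tsv_lines <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  sub("\r$", "", lines)
}

split_fields <- function(line) strsplit(line, "\t", fixed = TRUE)[[1]]

stop_line <- function(path, i, why) {
  stop(sprintf("%s: line %d: %s", path, i, why), call. = FALSE)
}

#' Read a BioCreative-style corpus
#'
#' Reads the three tab-separated files of the BioCreative dialect:
#' abstracts (`doc_id TAB title TAB abstract`), entity mentions
#' (`doc_id TAB mention_id TAB entity_type TAB start TAB end TAB surface`)
#' and, optionally, gold relations
#' (`doc_id TAB relation_class TAB evaluated(Y/N) TAB arg1 TAB arg2`).
#' `Arg1:`/`Arg2:` prefixes on the argument columns are tolerated and
#' stripped. Offsets are validated against the title+tab+abstract axis and
#' each surface string must equal the referenced document slice.
#'
#' @param abstracts_path path to the abstracts file
#' @param entities_path path to the entity-mention file
#' @param relations_path path to the relation file, or `NULL` (test mode:
#'   the corpus is returned with an empty relation table)
#' @return a `tkrex_corpus`
#' @export
read_corpus <- function(abstracts_path, entities_path, relations_path = NULL) {
  doc_lines <- read_tsv_lines(abstracts_path)
  doc_lines <- doc_lines[nzchar(doc_lines)]
  docs <- lapply(seq_along(doc_lines), function(i) {
    f <- split_fields(doc_lines[i])
    if (length(f) != 3L) stop_line(abstracts_path, i, "expected 3 tab-separated fields")
    f
  })
  documents <- data.frame(
    doc_id = vapply(docs, `[`, "", 1L),
    title = vapply(docs, `[`, "", 2L),
    abstract_text = vapply(docs, `[`, "", 3L),
    stringsAsFactors = FALSE)
  if (anyDuplicated(documents$doc_id))
    stop(sprintf("%s: duplicate doc_id", abstracts_path), call. = FALSE)
  doc_text <- setNames(paste0(documents$title, "\t", documents$abstract_text),
                       documents$doc_id)

  ent_lines <- read_tsv_lines(entities_path)
  ent_lines <- ent_lines[nzchar(ent_lines)]
  ents <- lapply(seq_along(ent_lines), function(i) {
    f <- split_fields(ent_lines[i])
    if (length(f) != 6L) stop_line(entities_path, i, "expected 6 tab-separated fields")
    f
  })
  entities <- data.frame(
    doc_id = vapply(ents, `[`, "", 1L),
    mention_id = vapply(ents, `[`, "", 2L),
    entity_type = vapply(ents, `[`, "", 3L),
    start = as.integer(vapply(ents, `[`, "", 4L)),
    end = as.integer(vapply(ents, `[`, "", 5L)),
    surface = vapply(ents, `[`, "", 6L),
    stringsAsFactors = FALSE)
  bad_type <- setdiff(unique(entities$entity_type), ENTITY_TYPES)
  if (length(bad_type))
    stop(sprintf("%s: unknown entity type(s): %s", entities_path,
                 paste(bad_type, collapse = ", ")), call. = FALSE)
  for (i in seq_len(nrow(entities))) {
    e <- entities[i, ]
    if (!e$doc_id %in% documents$doc_id)
      stop(sprintf("entity %s references unknown doc %s", e$mention_id, e$doc_id),
           call. = FALSE)
    txt <- doc_text[[e$doc_id]]
    if (is.na(e$start) || is.na(e$end) || e$start < 0L || e$end <= e$start ||
        e$end > nchar(txt))
      stop(sprintf("entity %s (doc %s): offsets [%s,%s) invalid for document of length %d",
                   e$mention_id, e$doc_id, e$start, e$end, nchar(txt)), call. = FALSE)
    slice <- substr(txt, e$start + 1L, e$end)
    if (slice != e$surface)
      stop(sprintf("entity %s (doc %s): surface %s != document slice %s",
                   e$mention_id, e$doc_id, dQuote(e$surface), dQuote(slice)),
           call. = FALSE)
  }

  if (is.null(relations_path)) {
    relations <- empty_relations()
  } else {
    rel_lines <- read_tsv_lines(relations_path)
    rel_lines <- rel_lines[nzchar(rel_lines)]
    rels <- lapply(seq_along(rel_lines), function(i) {
      f <- split_fields(rel_lines[i])
      if (length(f) != 5L) stop_line(relations_path, i, "expected 5 tab-separated fields")
      f
    })
    strip_arg <- function(x, pfx) sub(paste0("^", pfx, ":"), "", x)
    relations <- data.frame(
      doc_id = vapply(rels, `[`, "", 1L),
      relation_class = vapply(rels, `[`, "", 2L),
      evaluated = vapply(rels, `[`, "", 3L) %in% c("Y", "y", "TRUE", "true"),
      arg1 = strip_arg(vapply(rels, `[`, "", 4L), "Arg1"),
      arg2 = strip_arg(vapply(rels, `[`, "", 5L), "Arg2"),
      stringsAsFactors = FALSE)
    key <- paste(entities$doc_id, entities$mention_id)
    bad1 <- !(paste(relations$doc_id, relations$arg1) %in% key)
    bad2 <- !(paste(relations$doc_id, relations$arg2) %in% key)
    if (any(bad1 | bad2)) {
      i <- which(bad1 | bad2)[1L]
      stop(sprintf("relation line %d references unknown mention in doc %s",
                   i, relations$doc_id[i]), call. = FALSE)
    }
  }
  new_corpus(documents, entities, relations)
}

#' Write a corpus in the BioCreative dialect
#'
#' Inverse of [read_corpus()]: emits the three tab-separated files with LF
#' line endings and UTF-8 text, in table row order.
#'
#' @param corpus a `tkrex_corpus`
#' @param abstracts_path,entities_path,relations_path output paths;
#'   `relations_path` may be `NULL` to skip the relation file
#' @export
write_corpus <- function(corpus, abstracts_path, entities_path,
                         relations_path = NULL) {
  write_lf <- function(lines, path) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    if (length(lines)) writeLines(lines, con, sep = "\n", useBytes = TRUE)
  }
  d <- corpus$documents
  write_lf(paste(d$doc_id, d$title, d$abstract_text, sep = "\t"), abstracts_path)
  e <- corpus$entities
  write_lf(paste(e$doc_id, e$mention_id, e$entity_type, e$start, e$end,
                 e$surface, sep = "\t"), entities_path)
  if (!is.null(relations_path)) {
    r <- corpus$relations
    write_lf(paste(r$doc_id, r$relation_class, ifelse(r$evaluated, "Y", "N"),
                   r$arg1, r$arg2, sep = "\t"), relations_path)
  }
  invisible(NULL)
}

# ---- CoNLL-U dependency parses ----------------------------------------------

new_parse <- function(tokens, heads, deprels, pos) {
  n <- length(tokens)
  stopifnot(length(heads) == n, length(deprels) == n, length(pos) == n)
  if (sum(heads == 0L) != 1L) stop("parse must have exactly one root", call. = FALSE)
  if (any(heads < 0L | heads > n)) stop("head index out of range", call. = FALSE)
  # cycle check: walk each token to the root
  for (i in seq_len(n)) {
    seen <- logical(n); j <- i
    while (heads[j] != 0L) {
      j <- heads[j]
      if (seen[j]) stop("cyclic head assignment in parse", call. = FALSE)
      seen[j] <- TRUE
    }
  }
  structure(list(tokens = tokens, heads = as.integer(heads),
                 deprels = deprels, pos = pos), class = "tkrex_parse")
}

#' Read dependency parses from CoNLL-U
#'
#' Sentences must carry `# doc_id = ...` and `# sentence_index = ...`
#' comments; multiword-token and empty-node lines are skipped. The UPOS
#' column is used as the PoS layer.
#'
#' @param conllu_path path to a CoNLL-U file
#' @return named list of parses, keyed `"<doc_id>#<sentence_index>"`, each a
#'   `tkrex_parse` with parallel `tokens`, `heads` (1-based, 0 = root),
#'   `deprels`, `pos`
#' @export
read_parses <- function(conllu_path) {
  lines <- read_tsv_lines(conllu_path)
  parses <- list()
  meta <- list(); rows <- list()
  flush <- function() {
    if (!length(rows)) return()
    if (is.null(meta$doc_id) || is.null(meta$sentence_index))
      stop(sprintf("%s: sentence missing doc_id/sentence_index metadata", conllu_path),
           call. = FALSE)
    key <- paste0(meta$doc_id, "#", meta$sentence_index)
    parses[[key]] <<- new_parse(
      tokens = vapply(rows, `[`, "", 2L),
      heads = as.integer(vapply(rows, `[`, "", 7L)),
      deprels = vapply(rows, `[`, "", 8L),
      pos = vapply(rows, `[`, "", 4L))
    meta <<- list(); rows <<- list()
  }
  for (ln in lines) {
    if (!nzchar(ln)) { flush(); next }
    if (startsWith(ln, "#")) {
      m <- regmatches(ln, regexec("^# *([A-Za-z_]+) *= *(.*)$", ln))[[1]]
      if (length(m) == 3L) meta[[m[2L]]] <- trimws(m[3L])
      next
    }
    f <- split_fields(ln)
    if (length(f) < 8L)
      stop(sprintf("%s: malformed CoNLL-U token line: %s", conllu_path, ln),
           call. = FALSE)
    if (grepl("[-.]", f[1L])) next  # multiword / empty nodes
    rows[[length(rows) + 1L]] <- f
  }
  flush()
  parses
}

#' Write dependency parses as CoNLL-U
#'
#' @param parses named list of `tkrex_parse` objects keyed
#'   `"<doc_id>#<sentence_index>"`, as returned by [read_parses()]
#' @param conllu_path output path
#' @export
write_parses <- function(parses, conllu_path) {
  con <- file(conllu_path, open = "wb")
  on.exit(close(con))
  for (key in names(parses)) {
    p <- parses[[key]]
    parts <- strsplit(key, "#", fixed = TRUE)[[1]]
    writeLines(c(paste0("# doc_id = ", parts[1L]),
                 paste0("# sentence_index = ", parts[2L])), con, sep = "\n")
    n <- length(p$tokens)
    writeLines(paste(seq_len(n), p$tokens, "_", p$pos, "_", "_",
                     p$heads, p$deprels, "_", "_", sep = "\t"),
               con, sep = "\n")
    writeLines("", con, sep = "\n")
  }
  invisible(NULL)
}

#' Write predictions
#'
#' One tab-separated line per result
#' (`doc_id TAB arg1 TAB arg2 TAB label TAB score`), sorted by
#' (doc_id, arg1, arg2) so output is deterministic regardless of input order.
#'
#' @param results data.frame with columns doc_id, arg1, arg2, label, score
#' @param path output path
#' @export
write_predictions <- function(results, path) {
  stopifnot(all(c("doc_id", "arg1", "arg2", "label", "score") %in% names(results)))
  o <- order(results$doc_id, results$arg1, results$arg2)
  r <- results[o, , drop = FALSE]
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (nrow(r))
    writeLines(paste(r$doc_id, r$arg1, r$arg2, r$label,
                     format(r$score, trim = TRUE, digits = 10), sep = "\t"),
               con, sep = "\n")
  invisible(NULL)
}

#' Read predictions written by [write_predictions()]
#' @param path input path
#' @return data.frame with columns doc_id, arg1, arg2, label, score
#' @export
read_predictions <- function(path) {
  lines <- read_tsv_lines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(data.frame(doc_id = character(), arg1 = character(),
                      arg2 = character(), label = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  f <- lapply(lines, split_fields)
  data.frame(doc_id = vapply(f, `[`, "", 1L),
             arg1 = vapply(f, `[`, "", 2L),
             arg2 = vapply(f, `[`, "", 3L),
             label = vapply(f, `[`, "", 4L),
             score = as.numeric(vapply(f, `[`, "", 5L)),
             stringsAsFactors = FALSE)
}
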