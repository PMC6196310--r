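# Deterministic fallback PoS tagger and lemmatizer (Penn Treebank tagset).
#
# A tagger is a plug-in contract: a list with functions
#   tag(tokens)       -> character vector of PoS labels, parallel to tokens
#   lemmatize(tokens) -> character vector of lemmas, parallel to tokens
# External taggers can be wired in by satisfying this contract; the built-in
# lexicon + suffix-rule tagger below is deterministic and sufficient for
# synthetic corpora.

.verb_lexicon <- c(
  # lemma = inflected forms (VBZ, VBD, VBG, VBN, VBP/VB share surface)
  inhibit = "inhibits inhibited inhibiting inhibit",
  induce = "induces induced inducing induce",
  activate = "activates activated activating activate",
  suppress = "suppresses suppressed suppressing suppress",
  stimulate = "stimulates stimulated stimulating stimulate",
  block = "blocks blocked blocking block",
  bind = "binds bound binding bind",
  cause = "causes caused causing cause",
  regulate = "regulates regulated regulating regulate",
  antagonize = "antagonizes antagonized antagonizing antagonize",
  reduce = "reduces reduced reducing reduce",
  increase = "increases increased increasing increase",
  attenuate = "attenuates attenuated attenuating attenuate",
  enhance = "enhances enhanced enhancing enhance",
  measure = "measures measured measuring measure",
  contain = "contains contained containing contain",
  observe = "observes observed observing observe",
  be = "is was were are being been be")

build_verb_tables <- function() {
  form2lemma <- character(); form2tag <- character()
  for (lemma in names(.verb_lexicon)) {
    forms <- strsplit(.verb_lexicon[[lemma]], " ", fixed = TRUE)[[1]]
    for (f in forms) {
      form2lemma[f] <- lemma
      form2tag[f] <-
        if (f == lemma) "VBP"
        else if (endsWith(f, "ing")) "VBG"
        else if (endsWith(f, "s")) "VBZ"
        else "VBD"
    }
  }
  # irregular 'be'
  form2tag[c("is", "was", "were", "are", "being", "been", "be")] <-
    c("VBZ", "VBD", "VBD", "VBP", "VBG", "VBN", "VB")
  list(lemma = form2lemma, tag = form2tag)
}
.verb_tables <- build_verb_tables()

.closed_class <- c(
  the = "DT", a = "DT", an = "DT", this = "DT", these = "DT", that = "DT",
  each = "DT", its = "PRP$",
  of = "IN", "in" = "IN", by = "IN", with = "IN", on = "IN", at = "IN",
  "for" = "IN", via = "IN", through = "IN", as = "IN", from = "IN",
  to = "TO", and = "CC", or = "CC", but = "CC", also = "RB", not = "RB",
  strongly = "RB", significantly = "RB", markedly = "RB", slowly = "RB",
  "." = ".", "," = ",", ";" = ":", ":" = ":", "(" = "-LRB-", ")" = "-RRB-")

.adjectives <- c("latent", "potent", "human", "novel", "selective",
                 "dependent", "specific", "surmountable", "reversible")

fallback_tag_one <- function(tok) {
  low <- tolower(tok)
  if (!is.na(.closed_class[low])) return(unname(.closed_class[low]))
  vt <- .verb_tables$tag[low]
  if (!is.na(vt)) return(unname(vt))
  if (low %in% .adjectives) return("JJ")
  if (grepl("ly$", low)) return("RB")
  if (grepl("(ous|ive|ic|al|able|ible)$", low) && nchar(low) > 4L) return("JJ")
  if (grepl("^[0-9.]+$", low)) return("CD")
  if (grepl("^[A-Z][A-Z0-9-]+$", tok)) return("NN")  # gene-symbol style
  "NN"
}

fallback_lemma_one <- function(tok) {
  low <- tolower(tok)
  vl <- .verb_tables$lemma[low]
  if (!is.na(vl)) return(unname(vl))
  if (grepl("ies$", low) && nchar(low) > 4L) return(sub("ies$", "y", low))
  if (grepl("(s)$", low) && !grepl("(ss|us|is)$", low) && nchar(low) > 3L)
    return(sub("s$", "", low))
  low
}

#' Built-in deterministic tagger
#'
#' Lexicon + suffix-rule Penn Treebank tagger with a matching rule-based
#' lemmatizer. Deterministic for fixed input and sufficient for the
#' synthetic corpora produced by [generate_corpus()]; real corpora should
#' plug an external tagger into the same contract (`tag`, `lemmatize`).
#'
#' @return a tagger: `list(tag = function(tokens), lemmatize = function(tokens))`
#' @export
fallback_tagger <- function() {
  list(
    tag = function(tokens) vapply(tokens, fallback_tag_one, "", USE.NAMES = FALSE),
    lemmatize = function(tokens) vapply(tokens, fallback_lemma_one, "", USE.NAMES = FALSE)
  )
}

#' Tagger from a pre-computed token/tag side channel
#'
#' Reads a two-column `token TAB tag` file and returns a tagger whose `tag`
#' function looks tokens up in that table, falling back to the built-in
#' rules for unknown tokens.
#'
#' @param path two-column token/tag file
#' @return a tagger contract list
#' @export
table_tagger <- function(path) {
  lines <- read_tsv_lines(path)
  lines <- lines[nzchar(lines)]
  f <- lapply(lines, split_fields)
  tab <- setNames(vapply(f, `[`, "", 2L), vapply(f, `[`, "", 1L))
  fb <- fallback_tagger()
  list(
    tag = function(tokens) {
      out <- unname(tab[tokens])
      miss <- is.na(out)
      if (any(miss)) out[miss] <- fb$tag(tokens[miss])
      out
    },
    lemmatize = fb$lemmatize
  )
}

# Tokenize text into words/punctuation with 0-based half-open char offsets.
# Hyphens, digits and commas inside alphanumeric runs stay attached so that
# chemical names like "U50,488H" or "beta 1-adrenoceptor" pieces survive.
tokenize_with_offsets <- function(text) {
  m <- gregexpr("[A-Za-z0-9][A-Za-z0-9,'/+#:_-]*[A-Za-z0-9]|[A-Za-z0-9]|[^ \t\n]",
                text)[[1]]
  if (m[1] == -1L)
    return(list(tokens = character(), start = integer(), end = integer()))
  starts <- as.integer(m) - 1L
  lens <- attr(m, "match.length")
  list(tokens = regmatches(text, list(m))[[1]],
       start = starts, end = starts + lens)
}
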