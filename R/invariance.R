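# Invariance-based linguistic pattern mining.
#
# Each candidate instance is mapped to a second-order polynomial
#   P(x, y) = p20 x^2 + p11 x y + p02 y^2
# whose coefficients are built from scores of PoS n-gram "context frames"
# anchored at the three referential groups (entity1 = chemical, relation =
# proximal verb, entity2 = gene/protein/disease).  The rotation invariant
#   I(p) = p20^2 + p11^2 / 2 + p02^2
# of that conic is the instance's signature: instances whose I ratio is 1
# (within tolerance) are clustered, and each cluster is consolidated by
# progressive global alignment of its member frames into one consensus
# pattern -- a triple of PoS contexts.

#' Pattern-mining configuration
#'
#' @param n context-frame size; the frame spans `n + 1` PoS tags. Typical
#'   values 3 (chemical-protein, protein-protein) to 5 (chemical-disease);
#'   meaningful range 3-7.
#' @param delta determinant of the assumed transformation; 1.00 encodes the
#'   zero-rotation premise under which equal invariants mean equivalence
#' @param W invariant weight; 1 treats instances as absolute representations
#' @param ratio_tolerance tolerance around an invariance ratio of 1 when
#'   clustering floating-point scores
#' @param fringe the fringe value added when a frame is conditioned on
#'   itself (anchor at frame start), keeping self-conditioned frames from
#'   accruing weight they carry no information for
#' @return an `InvarianceConfig` list
#' @export
invariance_config <- function(n = 3L, delta = 1.00, W = 1,
                              ratio_tolerance = 1e-6, fringe = 1e-8) {
  n <- as.integer(n)
  if (n < 1L) stop("frame size n must be >= 1", call. = FALSE)
  if (n > 7L) warning("frame size n above the studied range 3-7")
  list(n = n, delta = delta, W = W, ratio_tolerance = ratio_tolerance,
       fringe = fringe)
}

ROLE_NAMES <- c("ENTITY1", "RELATION", "ENTITY2")

role_anchor <- function(instance, role) {
  switch(role,
         ENTITY1 = instance$e1_idx,
         RELATION = instance$rel_idx,
         ENTITY2 = instance$e2_idx,
         stop("unknown role ", role, call. = FALSE))
}

#' Extract PoS context frames for one instance
#'
#' For every referential group present in the instance (negative-class
#' instances carry no RELATION anchor) and every anchor offset
#' `e_c = 0..n`, the frame is the window of `n + 1` PoS tags whose position
#' `e_c` (0-based) is the anchor tag, truncated -- not padded -- at sentence
#' boundaries. `m` records the anchor's offset inside the (possibly
#' truncated) frame.
#'
#' @param instance a `tkrex_instance`
#' @param n frame size
#' @return list of frames: `role`, `e_c`, `m`, `tags`, `instance_id`
#' @export
extract_context_frames <- function(instance, n) {
  pos <- instance$norm_pos
  len <- length(pos)
  out <- list()
  for (role in ROLE_NAMES) {
    a <- role_anchor(instance, role)
    if (is.na(a)) {
      if (role == "RELATION") next
      stop(sprintf("instance %s: no anchor for role %s",
                   instance$instance_id, role), call. = FALSE)
    }
    for (e_c in 0:n) {
      lo <- a - e_c
      hi <- lo + n
      lo_t <- max(1L, lo); hi_t <- min(len, hi)
      out[[length(out) + 1L]] <- list(
        role = role, e_c = e_c, m = a - lo_t,
        tags = pos[lo_t:hi_t], instance_id = instance$instance_id)
    }
  }
  out
}

# ---- frame counts and scoring ------------------------------------------------

frame_key <- function(tags) paste(tags, collapse = "\x1f")

#' Build the corpus frame-count table
#'
#' Counts, over all frames of all training instances, every prefix
#' subsequence `x0..xj` of every frame. These counts are the
#' sum-of-occurrence terms in the frame score.
#'
#' @param frames frames from [extract_context_frames()] over all instances
#' @return environment mapping tag-tuple keys to integer counts
#' @export
build_frame_counts <- function(frames) {
  counts <- new.env(parent = emptyenv(), hash = TRUE)
  for (fr in frames) {
    tags <- fr$tags
    for (j in seq_along(tags)) {
      k <- frame_key(tags[seq_len(j)])
      counts[[k]] <- (if (is.null(counts[[k]])) 0L else counts[[k]]) + 1L
    }
  }
  counts
}

count_of <- function(counts, tags) {
  v <- counts[[frame_key(tags)]]
  if (is.null(v)) 0L else v
}

#' Score one context frame
#'
#' The score is a modified joint conditional probability over the corpus
#' frame inventory. With `m` the anchor offset inside the frame and `x0..xn`
#' its tags:
#' \itemize{
#'   \item `0 < m <= n`:
#'     `rho = (c(x0..xm) / c(x0..x_{m-1})) * (c(x0..xn) / c(x0..xm))`
#'   \item `m = 0` (frame conditioned on itself):
#'     `rho = c(x0..xn) / c(xm..xn) + fringe`, which evaluates to
#'     `1 + fringe` since the suffix is the whole frame
#' }
#' Counts `c(...)` are prefix-occurrence counts from
#' [build_frame_counts()]; because the frame itself contributes to every
#' one of its prefix counts, denominators are never zero when the table was
#' built from the same instance set.
#'
#' @param frame a frame from [extract_context_frames()]
#' @param counts table from [build_frame_counts()]
#' @param fringe fringe value for self-conditioned frames
#' @return the non-negative score `rho`
#' @export
score_frame <- function(frame, counts, fringe = 1e-8) {
  tags <- frame$tags
  nn <- length(tags)
  if (count_of(counts, tags) == 0L)
    stop("frame not present in counts table; counts must be built from the same instances",
         call. = FALSE)
  m <- frame$m
  if (m == 0L) {
    count_of(counts, tags) / count_of(counts, tags) + fringe
  } else {
    c_m <- count_of(counts, tags[seq_len(m + 1L)])
    c_m1 <- count_of(counts, tags[seq_len(m)])
    c_n <- count_of(counts, tags)
    (c_m / c_m1) * (c_n / c_m)
  }
}

# ---- polynomial representation and invariant ---------------------------------

#' Consolidate frame scores into conic coefficients
#'
#' At a fixed anchor offset `e_c`, each role's scores are cumulated
#' (summed) into a per-role score `rho*`. The coefficients couple the
#' paired referential groups `Entity1 OR Relation` (x axis) and
#' `Entity2 OR Relation` (y axis):
#' `p20 = rho*_E1 (x) rho*_REL`, `p02 = rho*_E2 (x) rho*_REL`,
#' `p11 = p20 * p02`, where `(x)` is a product when both operands exist and
#' passes the entity score through unchanged when the instance has no
#' Relation anchor (the OR semantics: an absent group leaves the variable's
#' contribution intact).
#'
#' @param frame_scores list of `list(role, rho)` for one instance at one `e_c`
#' @param e_c the shared anchor offset (recorded in the result)
#' @return list `p20`, `p11`, `p02`, `e_c`
#' @export
consolidate_coefficients <- function(frame_scores, e_c = NA_integer_) {
  rho <- list(ENTITY1 = 0, RELATION = NULL, ENTITY2 = 0)
  seen <- c(ENTITY1 = FALSE, RELATION = FALSE, ENTITY2 = FALSE)
  for (fs in frame_scores) {
    r <- fs$role
    rho[[r]] <- (if (is.null(rho[[r]])) 0 else rho[[r]]) + fs$rho
    seen[[r]] <- TRUE
  }
  if (!seen[["ENTITY1"]] || !seen[["ENTITY2"]])
    stop("both entity roles must contribute frame scores", call. = FALSE)
  p20 <- if (seen[["RELATION"]]) rho$ENTITY1 * rho$RELATION else rho$ENTITY1
  p02 <- if (seen[["RELATION"]]) rho$ENTITY2 * rho$RELATION else rho$ENTITY2
  list(p20 = p20, p11 = p20 * p02, p02 = p02, e_c = e_c)
}

#' Rotation invariant of a conic
#'
#' `I(p) = p20^2 + p11^2 / 2 + p02^2` -- the squared Frobenius norm of the
#' quadratic-form matrix `[[p20, p11/2], [p11/2, p02]]` up to the constant
#' factor absorbed in the definition, hence invariant under rotation of the
#' coordinate frame.
#'
#' @param poly list with `p20`, `p11`, `p02`
#' @return the scalar invariant
#' @export
invariant_score <- function(poly) {
  poly$p20^2 + poly$p11^2 / 2 + poly$p02^2
}

#' Best polynomial representation of an instance
#'
#' Scores the instance's frames at every anchor offset `e_c = 0..n`,
#' consolidates each offset into a conic, and returns the representation
#' with the highest invariant; ties break toward the smallest `e_c`.
#'
#' @param instance a `tkrex_instance`
#' @param counts frame-count table over the full training set
#' @param config an [invariance_config()]
#' @return list `poly`, `I`, `e_c`, `frames` (the winning offset's frames,
#'   one per role)
#' @export
best_instance_representation <- function(instance, counts, config) {
  frames <- extract_context_frames(instance, config$n)
  best <- NULL
  for (e_c in 0:config$n) {
    fs <- Filter(function(f) f$e_c == e_c, frames)
    scored <- lapply(fs, function(f)
      list(role = f$role, rho = score_frame(f, counts, config$fringe)))
    poly <- consolidate_coefficients(scored, e_c)
    I <- invariant_score(poly)
    if (is.null(best) || I > best$I)
      best <- list(poly = poly, I = I, e_c = e_c, frames = fs)
  }
  best
}

# ---- clustering --------------------------------------------------------------

#' Cluster instances by invariance ratio
#'
#' Instances are ranked by invariant score in descending order (ties by
#' instance id) and chained: an instance joins the open cluster iff the
#' ratio of the cluster representative's score to its own lies within
#' `ratio_tolerance` of `delta^W = 1`; otherwise it opens a new cluster.
#' Comparing against the cluster representative (its first, highest-scoring
#' member) makes the partition idempotent and permutation-invariant.
#'
#' @param scored data.frame with columns `instance_id`, `I`
#' @param config an [invariance_config()]
#' @return list of clusters: `members` (instance ids), `representative_I`
#' @export
cluster_by_invariance <- function(scored, config = invariance_config()) {
  if (!nrow(scored)) return(list())
  if (any(!is.finite(scored$I)) || any(scored$I <= 0))
    stop("invariant scores must be finite and positive", call. = FALSE)
  o <- order(-scored$I, scored$instance_id)
  ids <- scored$instance_id[o]; I <- scored$I[o]
  target <- config$delta ^ config$W
  eps <- config$ratio_tolerance
  clusters <- list()
  rep_I <- NA_real_
  for (i in seq_along(ids)) {
    ratio <- if (i == 1L) NA_real_ else rep_I / I[i]
    if (i == 1L || abs(ratio - target) > eps) {
      clusters[[length(clusters) + 1L]] <-
        list(members = ids[i], representative_I = I[i])
      rep_I <- I[i]
    } else {
      k <- length(clusters)
      clusters[[k]]$members <- c(clusters[[k]]$members, ids[i])
    }
  }
  clusters
}

# ---- alignment ---------------------------------------------------------------

#' Alignment scoring configuration
#'
#' Fixed penalties of the pattern-consensus recurrence: match +2,
#' mismatch -2, gap -2.
#'
#' @param match,mismatch,gap scores
#' @return a list with the three scores
#' @export
alignment_config <- function(match = 2, mismatch = -2, gap = -2) {
  list(match = match, mismatch = mismatch, gap = gap)
}

#' Global alignment of two PoS label sequences
#'
#' Needleman-Wunsch over the three-way recurrence
#' `sim(i,j) = max(sim(i-1,j-1) + lambda(i,j), sim(i-1,j) + gap,
#' sim(i,j-1) + gap)` with `lambda(i,j) = +2` on a match and `-2`
#' otherwise. Traceback ties prefer diagonal, then up (gap in `b`), then
#' left (gap in `a`).
#'
#' @param a,b character vectors of PoS labels (non-empty)
#' @param config an [alignment_config()]
#' @return list `score`, `a_aligned`, `b_aligned` (gap symbol `"-"`)
#' @export
align_pair <- function(a, b, config = alignment_config()) {
  if (!length(a) || !length(b))
    stop("align_pair requires non-empty sequences", call. = FALSE)
  na <- length(a); nb <- length(b)
  S <- matrix(0, na + 1L, nb + 1L)
  S[, 1L] <- config$gap * (0:na)
  S[1L, ] <- config$gap * (0:nb)
  for (i in seq_len(na)) for (j in seq_len(nb)) {
    sub <- if (a[i] == b[j]) config$match else config$mismatch
    S[i + 1L, j + 1L] <- max(S[i, j] + sub,
                             S[i, j + 1L] + config$gap,
                             S[i + 1L, j] + config$gap)
  }
  # traceback, ties diagonal > up > left
  i <- na; j <- nb
  ra <- character(); rb <- character()
  while (i > 0L || j > 0L) {
    if (i > 0L && j > 0L) {
      sub <- if (a[i] == b[j]) config$match else config$mismatch
      if (S[i + 1L, j + 1L] == S[i, j] + sub) {
        ra <- c(a[i], ra); rb <- c(b[j], rb); i <- i - 1L; j <- j - 1L; next
      }
    }
    if (i > 0L && S[i + 1L, j + 1L] == S[i, j + 1L] + config$gap) {
      ra <- c(a[i], ra); rb <- c("-", rb); i <- i - 1L; next
    }
    ra <- c("-", ra); rb <- c(b[j], rb); j <- j - 1L
  }
  list(score = S[na + 1L, nb + 1L], a_aligned = ra, b_aligned = rb)
}

# ---- pattern consolidation ---------------------------------------------------

majority_symbol <- function(column_counts) {
  # column_counts: named numeric; ties resolve toward the first-recorded name
  best <- names(column_counts)[1L]
  for (nm in names(column_counts))
    if (column_counts[[nm]] > column_counts[[best]]) best <- nm
  best
}

consensus_of_sequences <- function(seqs, config = alignment_config()) {
  # progressive alignment against the growing consensus; per-column symbol
  # counts are kept so the majority is over all members, with ties resolved
  # toward the earliest-processed member's symbol
  stopifnot(length(seqs) >= 1L)
  cols <- lapply(seqs[[1L]], function(s) setNames(1, s))
  consensus <- seqs[[1L]]
  if (length(seqs) > 1L) for (k in 2:length(seqs)) {
    al <- align_pair(consensus, seqs[[k]], config)
    new_cols <- list()
    ci <- 0L
    for (p in seq_along(al$a_aligned)) {
      sa <- al$a_aligned[p]; sb <- al$b_aligned[p]
      if (sa != "-") {
        ci <- ci + 1L
        cc <- cols[[ci]]
      } else {
        cc <- setNames(numeric(), character())
      }
      if (sb != "-") {
        if (is.na(cc[sb])) cc[sb] <- 1 else cc[sb] <- cc[sb] + 1
      }
      new_cols[[length(new_cols) + 1L]] <- cc
    }
    cols <- Filter(length, new_cols)          # drop all-gap columns
    consensus <- vapply(cols, majority_symbol, "")
  }
  consensus
}

#' Consolidate one invariance cluster into a linguistic pattern
#'
#' Per referential group, the members' winning context frames are
#' progressively aligned (most frequent frame first, then instance id) and
#' collapsed to the column-majority consensus; all-gap columns are dropped
#' and ties resolve toward the first-processed member.
#'
#' @param cluster one cluster from [cluster_by_invariance()]
#' @param representations named list (by instance id) of
#'   [best_instance_representation()] results
#' @param class_label relation class of the cluster's instances
#' @param config an [alignment_config()]
#' @return a pattern: `class`, `entity1_context`, `relation_context`
#'   (possibly NULL), `entity2_context`, `support`
#' @export
consolidate_pattern <- function(cluster, representations, class_label,
                                config = alignment_config()) {
  if (!length(cluster$members)) stop("empty cluster", call. = FALSE)
  ctx <- list(ENTITY1 = NULL, RELATION = NULL, ENTITY2 = NULL)
  for (role in ROLE_NAMES) {
    seqs <- list(); owners <- character()
    for (id in cluster$members) {
      fr <- Filter(function(f) f$role == role, representations[[id]]$frames)
      if (length(fr)) {
        seqs[[length(seqs) + 1L]] <- fr[[1L]]$tags
        owners <- c(owners, id)
      }
    }
    if (!length(seqs)) next
    keys <- vapply(seqs, frame_key, "")
    freq <- table(keys)
    o <- order(-as.integer(freq[keys]), owners)
    ctx[[role]] <- consensus_of_sequences(seqs[o], config)
  }
  list(class = class_label,
       entity1_context = ctx$ENTITY1,
       relation_context = ctx$RELATION,
       entity2_context = ctx$ENTITY2,
       support = length(cluster$members))
}

#' Mine linguistic patterns from training instances
#'
#' Orchestrates the full mining pass: frame extraction over all instances,
#' corpus-wide prefix counts, per-instance best conic representation,
#' per-class invariance clustering, and per-cluster consensus. Deterministic
#' for fixed input order.
#'
#' @param instances training `tkrex_instance` list
#' @param config an [invariance_config()]
#' @param align_config an [alignment_config()]
#' @return list with `patterns` (list of patterns), `representations`
#'   (named by instance id), `counts`
#' @export
learn_patterns <- function(instances, config = invariance_config(),
                           align_config = alignment_config()) {
  if (!length(instances))
    return(list(patterns = list(), representations = list(), counts = NULL))
  all_frames <- list()
  for (x in instances)
    all_frames <- c(all_frames, extract_context_frames(x, config$n))
  counts <- build_frame_counts(all_frames)
  reps <- list()
  for (x in instances)
    reps[[x$instance_id]] <- best_instance_representation(x, counts, config)
  classes <- vapply(instances, function(x) x$relation_class, "")
  patterns <- list()
  for (cl in unique(classes)) {
    ids <- vapply(instances[classes == cl], function(x) x$instance_id, "")
    if (!length(ids)) { warning("class with zero instances: ", cl); next }
    scored <- data.frame(instance_id = ids,
                         I = vapply(ids, function(i) reps[[i]]$I, 0),
                         stringsAsFactors = FALSE)
    for (cluster in cluster_by_invariance(scored, config))
      patterns[[length(patterns) + 1L]] <-
        consolidate_pattern(cluster, reps, cl, align_config)
  }
  list(patterns = patterns, representations = reps, counts = counts)
}

# ---- pattern I/O -------------------------------------------------------------

#' Write a pattern set
#'
#' One pattern per line:
#' `class TAB entity1_context TAB relation_context TAB entity2_context TAB
#' support`, contexts space-separated; an absent relation context is `-`.
#'
#' @param patterns list of patterns
#' @param path output path
#' @export
write_patterns <- function(patterns, path) {
  fmt <- function(x) if (is.null(x)) "-" else paste(x, collapse = " ")
  lines <- vapply(patterns, function(p)
    paste(p$class, fmt(p$entity1_context), fmt(p$relation_context),
          fmt(p$entity2_context), p$support, sep = "\t"), "")
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines)) writeLines(lines, con, sep = "\n")
  invisible(NULL)
}

#' Read a pattern set written by [write_patterns()]
#' @param path input path
#' @return list of patterns
#' @export
read_patterns <- function(path) {
  lines <- read_tsv_lines(path)
  lines <- lines[nzchar(lines)]
  lapply(lines, function(ln) {
    f <- split_fields(ln)
    if (length(f) != 5L) stop("malformed pattern line: ", ln, call. = FALSE)
    parse_ctx <- function(s) if (s == "-") NULL else strsplit(s, " ", fixed = TRUE)[[1]]
    list(class = f[1L], entity1_context = parse_ctx(f[2L]),
         relation_context = parse_ctx(f[3L]),
         entity2_context = parse_ctx(f[4L]), support = as.integer(f[5L]))
  })
}
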