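# Shared test helpers: brute-force pattern-mining oracle, random sequence
# databases, and a tiny tagged-corpus builder. The oracle enumerates every
# sub-pattern of every database sequence and counts supports by direct
# subsequence tests — independent of the prefix-growth miner it checks.

# all sub-patterns of one sequence: increasing element indices, a non-empty
# subset of each chosen element
enumerate_subpatterns <- function(s, max_length = Inf) {
  out <- new.env(parent = emptyenv())
  nonempty_subsets <- function(e) {
    idx <- seq_along(e)
    subs <- unlist(lapply(seq_along(e), function(k)
      utils::combn(idx, k, simplify = FALSE)), recursive = FALSE)
    lapply(subs, function(ii) e[ii])
  }
  recurse <- function(from, pattern, len) {
    if (len > 0L) assign(format_sequence(pattern), pattern, out)
    if (from > length(s) || len >= max_length) return()
    for (ei in from:length(s)) {
      for (sub in nonempty_subsets(s[[ei]])) {
        if (len + length(sub) > max_length) next
        recurse(ei + 1L, c(pattern, list(sub)), len + length(sub))
      }
    }
  }
  recurse(1L, list(), 0L)
  mget(ls(out), envir = out)
}

# exhaustive frequent-pattern miner (the oracle)
brute_force_patterns <- function(db, min_sup, max_length = Inf,
                                 contiguous = FALSE, strict = FALSE) {
  cand <- list()
  for (rec in db$records)
    cand <- c(cand, enumerate_subpatterns(rec$elements, max_length))
  cand <- cand[!duplicated(names(cand))]
  rows <- lapply(names(cand), function(key) {
    sup <- sum(vapply(db$records, function(rec)
      is_subsequence(cand[[key]], rec$elements, contiguous = contiguous),
      logical(1)))
    ok <- if (strict) sup > min_sup else sup >= min_sup
    if (ok) data.frame(pattern = key, support = sup,
                       length = sequence_length(cand[[key]]),
                       stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(pattern = character(), support = integer(),
                      length = integer(), stringsAsFactors = FALSE))
  df <- do.call(rbind, rows)
  df <- df[order(-df$support, df$pattern), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# random database: n_seq sequences of up to max_items items over a small
# alphabet; with prob `p_itemset` an element carries two items
random_seqdb <- function(n_seq = 5, max_items = 6, alphabet = letters[1:4],
                         p_itemset = 0.2) {
  seqs <- lapply(seq_len(n_seq), function(i) {
    elems <- list()
    budget <- sample.int(max_items, 1L)
    while (budget > 0L) {
      k <- if (budget >= 2L && stats::runif(1) < p_itemset) 2L else 1L
      elems[[length(elems) + 1L]] <- sort(sample(alphabet, k))
      budget <- budget - k
    }
    elems
  })
  as_sequence_database(seqs)
}

# deterministic single-word-element database (text mode)
random_textdb <- function(n_seq = 6, max_words = 6,
                          vocab = c("eye", "left", "right", "acuity",
                                    "visual", "lens")) {
  seqs <- lapply(seq_len(n_seq), function(i)
    as.list(sample(vocab, sample.int(max_words, 1L), replace = TRUE)))
  as_sequence_database(seqs)
}

# direct frequent n-gram counter (dual route for contiguous text mining)
ngram_counter <- function(db, min_sup, max_length = 4L) {
  words_list <- lapply(db$records, function(r)
    vapply(r$elements, `[`, character(1), 1L))
  grams <- new.env(parent = emptyenv())
  for (si in seq_along(words_list)) {
    w <- words_list[[si]]
    seen <- character()
    for (n in seq_len(min(max_length, length(w))))
      for (st in seq_len(length(w) - n + 1L))
        seen <- c(seen, paste(w[st:(st + n - 1L)], collapse = " "))
    for (g in unique(seen))
      assign(g, (if (exists(g, grams)) get(g, grams) else 0L) + 1L, grams)
  }
  keys <- ls(grams)
  sup <- vapply(keys, function(k) get(k, grams), integer(1))
  keep <- sup >= min_sup
  df <- data.frame(pattern = keys[keep], support = unname(sup[keep]),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$support, df$pattern), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# corpus whose tags come from an explicit per-word table
make_tagged_corpus <- function(texts, tags) {
  preprocess_corpus(texts, tagger = lookup_tagger(tags, default = "NN"))
}

# independent TextRank oracle: solve the linear fixed point
#   x = (1-d) 1 + d P^T x  directly
textrank_solve <- function(g, d = 0.85) {
  n <- length(g$vertices)
  W <- matrix(0, n, n, dimnames = list(g$vertices, g$vertices))
  if (nrow(g$edges)) {
    iu <- match(g$edges$u, g$vertices); iv <- match(g$edges$v, g$vertices)
    W[cbind(iu, iv)] <- g$edges$weight; W[cbind(iv, iu)] <- g$edges$weight
  }
  s <- rowSums(W)
  P <- W
  nz <- s > 0
  P[nz, ] <- P[nz, , drop = FALSE] / s[nz]
  x <- solve(diag(n) - d * t(P), rep(1 - d, n))
  stats::setNames(x, g$vertices)
}

make_term_graph <- function(vertices, edges) {
  structure(list(vertices = sort(vertices), edges = edges),
            class = "term_graph")
}

# context in which the first extractor perfectly separates positives:
# ranks 1..n_pos of method 1 are exactly the positives (all P at or above
# the 0.5 cut, all N below), so full weight on it classifies perfectly.
# Methods 2 and 3 extracted only the domain terms, with complementary
# (reversed) preferences — so fusion weights leaning on method 1 stay
# perfect while weights leaning away lose the low-ranked positives.
perfect_context <- function(n_terms = 40, threshold = 0.5) {
  terms <- sprintf("term%02d", seq_len(n_terms))
  n_pos <- sum(1 - (seq_len(n_terms) - 1) / n_terms >= threshold)
  r1 <- data.frame(term = terms, score = rev(seq_len(n_terms)))
  r2 <- data.frame(term = terms[seq_len(n_pos)], score = seq_len(n_pos))
  ann <- stats::setNames(
    c(rep("domain", n_pos), rep("non-domain", n_terms - n_pos)), terms)
  gt <- build_ground_truth(list(terms), ann)
  ns <- lapply(list(r1, r2, r2), normalize_ranking)
  ga_context(ns, gt)
}
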