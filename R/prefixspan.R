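# PrefixSpan frequent-sequence mining.
#
# A sequence is an ordered list of elements; each element is an itemset held
# as an alphabetically sorted character vector. In text mode every element is
# a singleton word. Postfixes may start with a partial element (the "(_b)"
# notation): the remainder of the element that matched the prefix's last
# element.

#' Parse a sequence from its text form
#'
#' Elements are separated by whitespace; multi-item elements are
#' parenthesised, e.g. \code{"a b (a c d)"}. Items within an element are
#' stored alphabetically sorted.
#'
#' @param text sequence in text form.
#' @return list of character vectors (one per element).
#' @export
parse_sequence <- function(text) {
  toks <- regmatches(text, gregexpr("\\([^)]*\\)|[^()[:space:]]+", text))[[1]]
  lapply(toks, function(t) {
    if (startsWith(t, "(")) {
      items <- strsplit(trimws(gsub("[()]", "", t)), "[[:space:]]+")[[1]]
      sort(items)
    } else t
  })
}

#' Format a sequence (or postfix) as text
#'
#' @param s list of elements; an attribute \code{partial = TRUE} marks the
#'   first element as a partial-element continuation, rendered \code{(_x)}.
#' @return character scalar such as \code{"a (a b) c"} or \code{"(_b) c"}.
#' @export
format_sequence <- function(s) {
  if (!length(s)) return("<>")
  partial <- isTRUE(attr(s, "partial"))
  parts <- vapply(seq_along(s), function(i) {
    e <- s[[i]]
    if (i == 1L && partial) paste0("(_", paste(e, collapse = " "), ")")
    else if (length(e) > 1L) paste0("(", paste(e, collapse = " "), ")")
    else e
  }, character(1))
  paste(parts, collapse = " ")
}

#' Total number of item instances in a sequence
#'
#' @param s a sequence (list of itemset elements).
#' @return integer count of item instances across all elements.
#' @examples
#' sequence_length(parse_sequence("a b (a d c)")) # 5
#' @export
sequence_length <- function(s) sum(lengths(s))

#' Subsequence test
#'
#' \code{pattern} is a subsequence of \code{s} when its elements can be
#' matched, in order, to elements of \code{s} at strictly increasing indices,
#' each pattern element being an itemset subset of the matched element. With
#' \code{contiguous = TRUE} the matched indices must additionally be
#' consecutive.
#'
#' @param pattern,s sequences (lists of itemset elements).
#' @param contiguous require a gap-free match.
#' @return logical.
#' @export
is_subsequence <- function(pattern, s, contiguous = FALSE) {
  n <- length(pattern)
  if (n == 0L) return(TRUE)
  m <- length(s)
  if (contiguous) {
    # gap-free n-gram semantics: the pattern is an exact consecutive run of
    # elements (itemset equality, not subset)
    if (m < n) return(FALSE)
    for (st in seq_len(m - n + 1L)) {
      ok <- TRUE
      for (k in seq_len(n)) {
        a <- pattern[[k]]; b <- s[[st + k - 1L]]
        if (length(a) != length(b) || !all(a == b)) { ok <- FALSE; break }
      }
      if (ok) return(TRUE)
    }
    return(FALSE)
  }
  j <- 1L
  for (k in seq_len(n)) {
    found <- FALSE
    while (j <= m) {
      if (all(pattern[[k]] %in% s[[j]])) { found <- TRUE; j <- j + 1L; break }
      j <- j + 1L
    }
    if (!found) return(FALSE)
  }
  TRUE
}

# Remainder of element `e` after matching itemset `matched`: the items
# alphabetically after the largest matched item.
.element_remainder <- function(e, matched) {
  rest <- e[e > max(matched)]
  rest
}

#' Postfix of a sequence with respect to a prefix
#'
#' Computes the remainder of \code{s} after the leftmost occurrence of
#' \code{prefix}: pattern elements are matched greedily to the earliest
#' possible elements of \code{s}; the items of the last matched element that
#' sort after the matched itemset form a partial first element (shown as
#' \code{(_x)}).
#'
#' @param s a sequence.
#' @param prefix a sequential pattern.
#' @return the postfix sequence (possibly with a partial first element,
#'   marked via attribute \code{partial}), or \code{NULL} when \code{prefix}
#'   does not occur in \code{s}.
#' @examples
#' s <- parse_sequence("a (a b) c")
#' format_sequence(postfix_sequence(s, parse_sequence("a")))   # "(a b) c"
#' format_sequence(postfix_sequence(s, parse_sequence("a b"))) # "c"
#' format_sequence(postfix_sequence(s, parse_sequence("a a"))) # "(_b) c"
#' @export
postfix_sequence <- function(s, prefix) {
  if (!length(prefix)) return(s)
  j <- 0L
  last_matched <- NULL
  for (k in seq_along(prefix)) {
    pe <- prefix[[k]]
    j <- j + 1L
    while (j <= length(s) && !all(pe %in% s[[j]])) j <- j + 1L
    if (j > length(s)) return(NULL)
    last_matched <- pe
  }
  rem <- .element_remainder(s[[j]], last_matched)
  tail_elems <- if (j < length(s)) s[(j + 1L):length(s)] else list()
  if (length(rem)) {
    out <- c(list(rem), tail_elems)
    attr(out, "partial") <- TRUE
    out
  } else tail_elems
}

#' Project a sequence database on a prefix pattern
#'
#' @param db a \code{sequence_database} (see
#'   \code{\link{as_sequence_database}}).
#' @param prefix a sequential pattern (list of elements) or its text form.
#' @return list with \code{prefix} and \code{postfixes}: a list of
#'   \code{list(seq_id, postfix)} for every database sequence containing the
#'   prefix.
#' @export
project_database <- function(db, prefix) {
  if (is.character(prefix)) prefix <- parse_sequence(prefix)
  postfixes <- list()
  for (rec in db$records) {
    pf <- postfix_sequence(rec$elements, prefix)
    if (!is.null(pf))
      postfixes[[length(postfixes) + 1L]] <- list(seq_id = rec$seq_id,
                                                  postfix = pf)
  }
  list(prefix = prefix, postfixes = postfixes)
}

#' Build a sequence database
#'
#' @param seqs list of sequences (each a list of itemset elements, or a text
#'   form accepted by \code{\link{parse_sequence}}), or a character vector of
#'   text-form sequences.
#' @param seq_ids optional identifiers (default \code{s1, s2, ...}).
#' @param source_docs optional source document ids (for resolving
#'   document-based support thresholds).
#' @return object of class \code{"sequence_database"}: list with
#'   \code{records} and \code{n_documents}.
#' @export
as_sequence_database <- function(seqs, seq_ids = NULL, source_docs = NULL) {
  if (is.character(seqs)) seqs <- lapply(seqs, parse_sequence)
  seqs <- lapply(seqs, function(s) if (is.character(s) && length(s) > 1L)
    as.list(s) else s)
  if (is.null(seq_ids)) seq_ids <- sprintf("s%d", seq_along(seqs))
  if (anyDuplicated(seq_ids)) stop("seq_id must be unique")
  if (is.null(source_docs)) source_docs <- seq_ids
  records <- Map(function(id, s, d) list(seq_id = id,
                                         elements = lapply(s, sort),
                                         source_doc = d),
                 seq_ids, seqs, source_docs)
  structure(list(records = unname(records),
                 n_documents = length(unique(source_docs))),
            class = "sequence_database")
}

#' Turn a preprocessed corpus into a sentence-level sequence database
#'
#' Each sentence becomes one sequence whose elements are the lemmas of its
#' valid tokens (singleton elements: text mode).
#'
#' @param corpus a \code{"term_corpus"}.
#' @return a \code{"sequence_database"}.
#' @export
corpus_sequence_database <- function(corpus) {
  stopifnot(inherits(corpus, "term_corpus"))
  seqs <- list(); ids <- character(); docs <- character()
  for (d in corpus) {
    for (si in seq_along(d$sentences)) {
      s <- d$sentences[[si]]
      words <- s$lemma[s$valid]
      if (!length(words)) next
      seqs[[length(seqs) + 1L]] <- as.list(words)
      ids <- c(ids, paste0(d$doc_id, "#", si))
      docs <- c(docs, d$doc_id)
    }
  }
  as_sequence_database(seqs, seq_ids = ids, source_docs = docs)
}

#' Resolve a minimum-support setting to an absolute count
#'
#' Fractional settings are resolved against the chosen basis and rounded up;
#' e.g. 0.001 of a 29,232-document corpus resolves to 30.
#'
#' @param min_sup absolute count (>= 1) or fraction in (0, 1).
#' @param db a \code{"sequence_database"}.
#' @param basis \code{"sequences"} or \code{"documents"} — what the fraction
#'   is taken of.
#' @return integer absolute support threshold (>= 1).
#' @export
resolve_min_sup <- function(min_sup, db, basis = c("documents", "sequences")) {
  basis <- match.arg(basis)
  stopifnot(is.numeric(min_sup), length(min_sup) == 1L, min_sup > 0)
  if (min_sup < 1) {
    n <- if (basis == "documents") db$n_documents else length(db$records)
    min_sup <- ceiling(min_sup * n)
  }
  max(1L, as.integer(min_sup))
}

# Scan a gapped projected database for frequent extension items.
# Returns data.frame(item, assembled, support).
.scan_extensions <- function(postfixes, last_element, contiguous) {
  counts <- new.env(parent = emptyenv())
  bump <- function(key) {
    assign(key, (if (exists(key, counts)) get(key, counts) else 0L) + 1L,
           counts)
  }
  for (pf in postfixes) {
    s <- pf$postfix
    partial <- isTRUE(attr(s, "partial"))
    seen <- character()
    if (contiguous) {
      # only the immediate next element can extend (text mode: singleton)
      if (length(s) && !partial) {
        it <- s[[1L]][1L]
        seen <- paste0("n\r", it)
      }
    } else {
      start_full <- if (partial) 2L else 1L
      if (partial)
        for (it in s[[1L]]) seen <- c(seen, paste0("a\r", it))
      if (length(s) >= start_full)
        for (ei in start_full:length(s)) {
          e <- s[[ei]]
          for (it in e) seen <- c(seen, paste0("n\r", it))
          if (!is.null(last_element)) {
            after <- max(last_element)
            for (it in e[e > after])
              if (all(last_element %in% e)) seen <- c(seen, paste0("a\r", it))
          }
        }
    }
    for (key in unique(seen)) bump(key)
  }
  keys <- ls(counts)
  if (!length(keys))
    return(data.frame(item = character(), assembled = logical(),
                      support = integer(), stringsAsFactors = FALSE))
  parts <- strsplit(keys, "\r", fixed = TRUE)
  data.frame(item = vapply(parts, `[`, character(1), 2L),
             assembled = vapply(parts, `[`, character(1), 1L) == "a",
             support = vapply(keys, function(k) get(k, counts), integer(1)),
             stringsAsFactors = FALSE, row.names = NULL)
}

# Project gapped postfixes on an extension (item, assembled).
.project_postfixes <- function(postfixes, item, assembled, last_element,
                               contiguous) {
  out <- list()
  for (pf in postfixes) {
    s <- pf$postfix
    partial <- isTRUE(attr(s, "partial"))
    newpf <- NULL
    if (contiguous) {
      if (length(s) && !partial && s[[1L]][1L] == item)
        newpf <- if (length(s) > 1L) s[2:length(s)] else list()
    } else if (assembled) {
      target <- sort(c(last_element, item))
      if (partial && item %in% s[[1L]]) {
        rem <- s[[1L]][s[[1L]] > item]
        tail_elems <- if (length(s) > 1L) s[2:length(s)] else list()
        newpf <- if (length(rem)) {
          o <- c(list(rem), tail_elems); attr(o, "partial") <- TRUE; o
        } else tail_elems
      } else {
        start_full <- if (partial) 2L else 1L
        if (length(s) >= start_full)
          for (ei in start_full:length(s)) {
            e <- s[[ei]]
            if (all(target %in% e)) {
              rem <- .element_remainder(e, target)
              tail_elems <- if (ei < length(s)) s[(ei + 1L):length(s)]
                            else list()
              newpf <- if (length(rem)) {
                o <- c(list(rem), tail_elems); attr(o, "partial") <- TRUE; o
              } else tail_elems
              break
            }
          }
      }
    } else {
      start_full <- if (partial) 2L else 1L
      if (length(s) >= start_full)
        for (ei in start_full:length(s)) {
          e <- s[[ei]]
          if (item %in% e) {
            rem <- .element_remainder(e, item)
            tail_elems <- if (ei < length(s)) s[(ei + 1L):length(s)]
                          else list()
            newpf <- if (length(rem)) {
              o <- c(list(rem), tail_elems); attr(o, "partial") <- TRUE; o
            } else tail_elems
            break
          }
        }
    }
    if (!is.null(newpf))
      out[[length(out) + 1L]] <- list(seq_id = pf$seq_id, postfix = newpf)
  }
  out
}

#' Mine frequent sequential patterns (PrefixSpan)
#'
#' Recursive prefix-growth mining: scan the projected database for frequent
#' single items, append each to the current prefix (either into the last
#' element — the \code{(_b)} assembled case — or as a new element), emit the
#' grown pattern and recurse on its projected database.
#'
#' @param db a \code{"sequence_database"}.
#' @param min_sup absolute count or fraction (see
#'   \code{\link{resolve_min_sup}}).
#' @param max_length cap on pattern length in item instances
#'   (default \code{Inf}).
#' @param contiguous gap-free matching; supported for text-mode databases
#'   (singleton elements) where mined patterns are word n-grams.
#' @param strict when \code{TRUE}, require support strictly greater than the
#'   threshold; the default treats a pattern at exactly \code{min_sup} as
#'   frequent (min_sup as minimum frequency).
#' @param basis basis for fractional \code{min_sup}
#'   (\code{"documents"} or \code{"sequences"}).
#' @return data frame with columns \code{pattern} (text form),
#'   \code{support}, \code{length}, ordered by support descending then
#'   pattern text ascending.
#' @export
mine_frequent_patterns <- function(db, min_sup, max_length = Inf,
                                   contiguous = FALSE, strict = FALSE,
                                   basis = "documents") {
  stopifnot(inherits(db, "sequence_database"))
  if (!length(db$records))
    return(data.frame(pattern = character(), support = integer(),
                      length = integer(), stringsAsFactors = FALSE))
  thr <- resolve_min_sup(min_sup, db, basis)
  if (contiguous &&
      any(vapply(db$records,
                 function(r) any(lengths(r$elements) > 1L), logical(1))))
    stop("contiguous mining is defined for text-mode (singleton) databases")
  frequent <- function(sup) if (strict) sup > thr else sup >= thr
  results <- list()
  recurse <- function(prefix, plen, postfixes) {
    last_element <- if (plen > 0L) prefix[[length(prefix)]] else NULL
    ext <- .scan_extensions(postfixes, last_element, contiguous)
    ext <- ext[frequent(ext$support), , drop = FALSE]
    if (!nrow(ext)) return()
    ord <- order(ext$assembled, ext$item)
    for (r in ord) {
      item <- ext$item[r]; assembled <- ext$assembled[r]
      if (assembled && plen == 0L) next
      newprefix <- if (assembled)
        c(prefix[-length(prefix)], list(sort(c(last_element, item))))
      else c(prefix, list(item))
      results[[length(results) + 1L]] <<-
        list(pattern = format_sequence(newprefix),
             support = ext$support[r], length = plen + 1L)
      if (plen + 1L < max_length) {
        sub <- .project_postfixes(postfixes, item, assembled, last_element,
                                  contiguous)
        recurse(newprefix, plen + 1L, sub)
      }
    }
  }
  init <- if (contiguous) {
    # one postfix per occurrence position: every suffix of every sequence
    pfs <- list()
    for (rec in db$records)
      for (st in seq_along(rec$elements))
        pfs[[length(pfs) + 1L]] <-
          list(seq_id = rec$seq_id,
               postfix = rec$elements[st:length(rec$elements)])
    pfs
  } else {
    lapply(db$records, function(r) list(seq_id = r$seq_id,
                                        postfix = r$elements))
  }
  if (contiguous) {
    # support must count distinct sequences, not occurrences
    res <- .mine_contiguous(db, thr, max_length, strict)
    return(res)
  }
  recurse(list(), 0L, init)
  .pattern_frame(results)
}

# Direct contiguous miner over singleton databases: prefix growth where each
# occurrence keeps its own postfix; support = distinct containing sequences.
.mine_contiguous <- function(db, thr, max_length, strict) {
  frequent <- function(sup) if (strict) sup > thr else sup >= thr
  results <- list()
  recurse <- function(prefix_words, occs) {
    # occs: list of (seq_id, words remaining after the occurrence)
    nxt <- new.env(parent = emptyenv())
    for (oc in occs) {
      if (!length(oc$rest)) next
      w <- oc$rest[[1L]]
      cur <- if (exists(w, nxt)) get(w, nxt) else list(ids = character(),
                                                       occ = list())
      cur$ids <- c(cur$ids, oc$seq_id)
      cur$occ[[length(cur$occ) + 1L]] <-
        list(seq_id = oc$seq_id, rest = oc$rest[-1L])
      assign(w, cur, nxt)
    }
    for (w in sort(ls(nxt))) {
      cur <- get(w, nxt)
      sup <- length(unique(cur$ids))
      if (!frequent(sup)) next
      pat <- c(prefix_words, w)
      results[[length(results) + 1L]] <<-
        list(pattern = paste(pat, collapse = " "), support = sup,
             length = length(pat))
      if (length(pat) < max_length) recurse(pat, cur$occ)
    }
  }
  occs <- list()
  for (rec in db$records) {
    words <- vapply(rec$elements, `[`, character(1), 1L)
    for (st in seq_along(words))
      occs[[length(occs) + 1L]] <-
        list(seq_id = rec$seq_id, rest = as.list(words[st:length(words)]))
  }
  recurse(character(), occs)
  .pattern_frame(results)
}

.pattern_frame <- function(results) {
  if (!length(results))
    return(data.frame(pattern = character(), support = integer(),
                      length = integer(), stringsAsFactors = FALSE))
  df <- data.frame(
    pattern = vapply(results, `[[`, character(1), "pattern"),
    support = vapply(results, function(r) as.integer(r$support), integer(1)),
    length = vapply(results, function(r) as.integer(r$length), integer(1)),
    stringsAsFactors = FALSE)
  df <- df[!duplicated(df$pattern), , drop = FALSE]
  df <- df[order(-df$support, df$pattern), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' PrefixSpan term ranking over a corpus
#'
#' Pipeline preset: mines contiguous word n-grams (1 to \code{max_length}
#' words) from sentence sequences, support counted per sentence, threshold
#' resolved as a fraction of the document count by default. The raw ensemble
#' score of a pattern is its support.
#'
#' @param corpus a preprocessed \code{"term_corpus"}.
#' @param min_sup support threshold; default 0.001 (0.1 % of the corpus'
#'   document count).
#' @param max_length maximum term length in words (default 4).
#' @param basis fraction basis, default \code{"documents"}.
#' @return data frame \code{term}, \code{score} (support), ordered best
#'   first (support descending, term ascending).
#' @export
prefixspan_ranking <- function(corpus, min_sup = 0.001, max_length = 4L,
                               basis = "documents") {
  db <- corpus_sequence_database(corpus)
  pats <- mine_frequent_patterns(db, min_sup = min_sup,
                                 max_length = max_length, contiguous = TRUE,
                                 basis = basis)
  data.frame(term = pats$pattern, score = as.numeric(pats$support),
             stringsAsFactors = FALSE)
}
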