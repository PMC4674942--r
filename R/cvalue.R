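# C-Value termhood scoring.
#
# CV(a) weighs a candidate's corpus frequency f(a) by log2 of its word length
# and discounts the average frequency of the longer extracted candidates that
# contain it (the nested-term set T_a):
#
#   CV(a) = log2|a| * f(a)                                     if T_a empty
#   CV(a) = log2|a| * (f(a) - (1/P(T_a)) * sum_{b in T_a} f(b)) otherwise
#
# The printed unigram branch log2(1) * f(a) zeroes every single-word term;
# `unigram_mode = "plus_one"` (the default) uses log2(|a|+1) for unigrams so
# frequency still ranks them, while "as_printed" keeps the literal formula.

# contiguous word-level sub-span containment: is `a` inside `b`?
.is_subspan <- function(a, b) {
  grepl(paste0(" ", a, " "), paste0(" ", b, " "), fixed = TRUE) && a != b
}

#' Corpus frequency table and nesting index for candidate terms
#'
#' \code{f} counts every chunked occurrence of each distinct candidate
#' (including occurrences inside longer candidates). \code{T_a} for a term is
#' the set of strictly longer distinct extracted candidates containing it as
#' a contiguous word sub-span.
#'
#' @param candidates candidate occurrence table from
#'   \code{\link{chunk_corpus}} (columns \code{text}, \code{length}), or a
#'   character vector of occurrence texts.
#' @return list with \code{freq} (named occurrence counts) and \code{nested}
#'   (named list: term -> character vector of containing terms).
#' @export
build_frequency_and_nesting <- function(candidates) {
  texts <- if (is.character(candidates)) candidates else candidates$text
  if (!length(texts))
    return(list(freq = integer(), nested = list()))
  freq <- table(texts)
  freq <- stats::setNames(as.integer(freq), names(freq))
  terms <- names(freq)
  nwords <- lengths(strsplit(terms, " ", fixed = TRUE))
  nested <- stats::setNames(vector("list", length(terms)), terms)
  ord <- order(nwords)
  for (i in seq_along(terms)) {
    a <- terms[i]
    longer <- terms[nwords > nwords[i]]
    if (length(longer)) {
      hit <- vapply(longer, .is_subspan, logical(1), a = a)
      nested[[a]] <- unname(longer[hit])
    } else nested[[a]] <- character()
  }
  list(freq = freq, nested = nested)
}

#' C-Value of one candidate term
#'
#' @param term candidate text (space-joined lemmas).
#' @param stats result of \code{\link{build_frequency_and_nesting}}.
#' @param unigram_mode \code{"plus_one"} (default; unigram length weight
#'   log2(2) = 1) or \code{"as_printed"} (log2(1) = 0 zeroes unigrams).
#' @return numeric C-Value.
#' @examples
#' st <- list(freq = c("left eye" = 8), nested = list("left eye" = character()))
#' compute_cvalue("left eye", st)  # log2(2) * 8 = 8
#' @export
compute_cvalue <- function(term, stats, unigram_mode = c("plus_one",
                                                         "as_printed")) {
  unigram_mode <- match.arg(unigram_mode)
  f <- stats$freq[term]
  if (is.na(f)) stop("term not present in frequency table: ", term)
  f <- as.numeric(f)
  len <- length(strsplit(term, " ", fixed = TRUE)[[1]])
  L <- if (len == 1L && unigram_mode == "plus_one") log2(len + 1) else
    log2(len)
  ta <- stats$nested[[term]]
  if (len == 1L || is.null(ta) || !length(ta)) return(L * f)
  L * (f - mean(as.numeric(stats$freq[ta])))
}

#' C-Value ranking over a corpus
#'
#' Chunks noun-phrase candidates, builds frequency and nesting statistics and
#' scores every distinct candidate, returning scores sorted descending with
#' lexicographic tie-break.
#'
#' @param corpus a preprocessed \code{"term_corpus"} or a candidate
#'   occurrence table from \code{\link{chunk_corpus}}.
#' @inheritParams compute_cvalue
#' @param max_len maximum candidate length in words (default 4).
#' @return data frame \code{term}, \code{score} (C-Value), \code{freq},
#'   \code{nested_count}, best first.
#' @export
cvalue_ranking <- function(corpus, unigram_mode = "plus_one", max_len = 4L) {
  candidates <- if (inherits(corpus, "term_corpus"))
    chunk_corpus(corpus, max_len = max_len) else corpus
  st <- build_frequency_and_nesting(candidates)
  terms <- names(st$freq)
  if (!length(terms))
    return(data.frame(term = character(), score = numeric(),
                      freq = integer(), nested_count = integer(),
                      stringsAsFactors = FALSE))
  cv <- vapply(terms, compute_cvalue, numeric(1), stats = st,
               unigram_mode = unigram_mode)
  out <- data.frame(term = terms, score = unname(cv),
                    freq = unname(st$freq[terms]),
                    nested_count = unname(vapply(st$nested[terms], length,
                                                 integer(1))),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
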