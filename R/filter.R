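# Dictionary filtering of extracted term rankings.
#
# Extractors surface frequent but non-medical phrases ("twelve months"); a
# domain dictionary increases the likelihood that surviving terms are
# medically related. Filtering never reorders or rescores: it is a
# subsequence operation on the ranking.

.default_stopwords <- c("the", "a", "an", "of", "in", "on", "at", "by",
                        "to", "for", "with", "and", "or", "from")

#' Load a medical dictionary from a newline-delimited term list
#'
#' Entries are normalised with the same conventions as the preprocessing
#' pipeline (lower-cased, tokenised, lemmatised, space-joined); duplicates
#' collapse and empty lines are skipped. The dictionary's vocabulary is the
#' set of all single words appearing in its entries.
#'
#' @param path file path, or a character vector of terms given directly.
#' @param lemmatizer token -> lemma mapping used for normalisation.
#' @return object of class \code{"medical_dictionary"}: list with
#'   \code{entries} (sorted character vector) and \code{vocabulary}.
#' @export
load_dictionary <- function(path, lemmatizer = identity_lemmatizer) {
  raw <- if (length(path) == 1L && file.exists(path))
    readLines(path, warn = FALSE, encoding = "UTF-8") else as.character(path)
  raw <- trimws(raw)
  raw <- raw[nzchar(raw)]
  entries <- vapply(raw, function(term) {
    toks <- regmatches(term, gregexpr(.token_pattern, term))[[1]]
    toks <- toks[grepl("[A-Za-z0-9]", toks)]
    paste(tolower(lemmatizer(toks)), collapse = " ")
  }, character(1), USE.NAMES = FALSE)
  entries <- sort(unique(entries[nzchar(entries)]))
  vocabulary <- sort(unique(unlist(strsplit(entries, " ", fixed = TRUE))))
  structure(list(entries = entries, vocabulary = vocabulary),
            class = "medical_dictionary")
}

#' @export
print.medical_dictionary <- function(x, ...) {
  cat("<medical_dictionary>", length(x$entries), "entries,",
      length(x$vocabulary), "vocabulary words\n")
  invisible(x)
}

#' Filter a ranked term list against a medical dictionary
#'
#' Keeps a term when it matches the dictionary under the chosen mode:
#' \describe{
#'   \item{whole_term}{the full term text is a dictionary entry;}
#'   \item{token_coverage}{every non-stopword token of the term occurs in
#'     the dictionary vocabulary (default — compositional phrases like
#'     "fundus examination" survive even when absent verbatim);}
#'   \item{either}{union of the two.}
#' }
#' Survivors keep their scores and relative order.
#'
#' @param ranked data frame with columns \code{term}, \code{score}, ordered
#'   best first.
#' @param dict a \code{"medical_dictionary"}.
#' @param match_mode matching granularity (see above).
#' @param stopwords words ignored by token coverage.
#' @return the surviving rows of \code{ranked} (order preserved) with
#'   attribute \code{survivor_fraction} = kept / input size.
#' @export
filter_terms <- function(ranked, dict,
                         match_mode = c("token_coverage", "whole_term",
                                        "either"),
                         stopwords = .default_stopwords) {
  match_mode <- match.arg(match_mode)
  stopifnot(inherits(dict, "medical_dictionary"),
            is.data.frame(ranked), "term" %in% names(ranked))
  if (!nrow(ranked)) {
    attr(ranked, "survivor_fraction") <- NA_real_
    return(ranked)
  }
  whole <- ranked$term %in% dict$entries
  toks <- strsplit(ranked$term, " ", fixed = TRUE)
  covered <- vapply(toks, function(tt) {
    tt <- setdiff(tt, stopwords)
    length(tt) > 0L && all(tt %in% dict$vocabulary)
  }, logical(1))
  keep <- switch(match_mode,
                 whole_term = whole,
                 token_coverage = covered,
                 either = whole | covered)
  out <- ranked[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "survivor_fraction") <- sum(keep) / nrow(ranked)
  out
}
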