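# Tokens are words ([A-Za-z0-9'-]+) or single punctuation characters.
.token_pattern <- "[A-Za-z0-9'-]+|[^A-Za-z0-9[:space:]]"

#' Identity lemmatizer
#'
#' Maps every token to its lower-cased surface form. Useful as a deterministic
#' stand-in for a dictionary or statistical lemmatizer: downstream counting is
#' unaffected as long as the mapping is total and canonical.
#'
#' @param tokens character vector of token surfaces.
#' @return character vector of lemmas (lower case).
#' @export
identity_lemmatizer <- function(tokens) tolower(tokens)

#' Build a lookup-table lemmatizer
#'
#' @param table named character vector mapping lower-cased surface to lemma.
#' @return a function mapping token surfaces to lemmas; surfaces absent from
#'   the table fall back to their lower-cased form.
#' @export
lookup_lemmatizer <- function(table) {
  stopifnot(is.character(table), !is.null(names(table)))
  names(table) <- tolower(names(table))
  function(tokens) {
    lw <- tolower(tokens)
    out <- unname(table[lw])
    out[is.na(out)] <- lw[is.na(out)]
    tolower(out)
  }
}

#' Build a lookup-table part-of-speech tagger
#'
#' Returns a deterministic tagger assigning Penn-Treebank-style tags from a
#' lemma -> tag table. Punctuation tokens are tagged \code{"SYM"}; lemmas
#' absent from the table receive \code{default}.
#'
#' @param table named character vector, lemma -> tag (e.g. "JJ", "NN", "VBD").
#' @param default tag for out-of-table lemmas (default \code{"NN"}: unknown
#'   content words in clinical text are most often nouns).
#' @return function: character vector of lemmas -> character vector of tags.
#' @export
lookup_tagger <- function(table = character(), default = "NN") {
  stopifnot(is.character(table))
  function(lemmas) {
    out <- rep(default, length(lemmas))
    if (length(table)) {
      hit <- match(lemmas, names(table))
      out[!is.na(hit)] <- unname(table[hit[!is.na(hit)]])
    }
    out[!grepl("[a-z0-9]", lemmas)] <- "SYM"
    out
  }
}

# Closed-class word lists for the bundled heuristic tagger.
.closed_class_tags <- c(
  the = "DT", a = "DT", an = "DT", this = "DT", that = "DT", these = "DT",
  those = "DT", his = "PRP$", her = "PRP$", its = "PRP$", their = "PRP$",
  of = "IN", "in" = "IN", on = "IN", at = "IN", by = "IN", with = "IN",
  from = "IN", to = "TO", "for" = "IN", after = "IN", before = "IN",
  since = "IN", during = "IN", into = "IN", over = "IN", under = "IN",
  and = "CC", or = "CC", but = "CC", nor = "CC",
  he = "PRP", she = "PRP", it = "PRP", they = "PRP", we = "PRP", i = "PRP",
  is = "VBZ", was = "VBD", are = "VBP", were = "VBD", be = "VB", been = "VBN",
  has = "VBZ", have = "VBP", had = "VBD", will = "MD", would = "MD",
  can = "MD", could = "MD", may = "MD", should = "MD",
  not = "RB", no = "DT", very = "RB", quite = "RB", again = "RB",
  today = "RB", yesterday = "RB", now = "RB", then = "RB", there = "EX",
  who = "WP", which = "WDT", when = "WRB", as = "IN", `if` = "IN",
  than = "IN"
)

#' Bundled heuristic part-of-speech tagger
#'
#' A small deterministic tagger: closed-class words from a built-in list,
#' numbers as \code{CD}, common adjectival suffixes (-ous, -al, -ic, -ive,
#' -ar, -ary) and -ed/-ing forms heuristically, everything else \code{NN}
#' (plural \code{NNS}). Intended for tests and synthetic corpora; production
#' use should inject tags from a trained tagger via \code{\link{lookup_tagger}}.
#'
#' @param lemmas character vector of lemmas.
#' @return character vector of Penn-Treebank-style tags.
#' @export
heuristic_tagger <- function(lemmas) {
  out <- character(length(lemmas))
  for (k in seq_along(lemmas)) {
    w <- lemmas[k]
    out[k] <- if (!grepl("[a-z0-9]", w)) "SYM"
    else if (!is.na(.closed_class_tags[w])) unname(.closed_class_tags[w])
    else if (grepl("^[0-9.-]+$", w)) "CD"
    else if (grepl("(ous|ful|ive|ary|al|ic|ar)$", w) && nchar(w) > 4) "JJ"
    else if (grepl("ing$", w) && nchar(w) > 5) "VBG"
    else if (grepl("ed$", w) && nchar(w) > 4) "VBD"
    else if (grepl("s$", w) && !grepl("(ss|us|is)$", w)) "NNS"
    else "NN"
  }
  out
}

#' Normalise a raw letter into tagged sentences
#'
#' Splits \code{raw_text} into sentences on sentence-final punctuation
#' (\code{. ! ?} followed by whitespace), tokenises, lemmatises (lower-casing
#' throughout; no stemming, since stems conflate distinct medical meanings)
#' and POS-tags each sentence. A token is flagged invalid when its surface
#' contains any symbol or punctuation character other than hyphen.
#'
#' @param raw_text a single character string (one clinical letter).
#' @param doc_id document identifier.
#' @param lemmatizer total function token surfaces -> lemmas
#'   (default \code{\link{identity_lemmatizer}}).
#' @param tagger total function lemma vector -> tag vector
#'   (default \code{\link{heuristic_tagger}}).
#' @return an object of class \code{"term_document"}: list with \code{doc_id}
#'   and \code{sentences}, each sentence a data frame with columns
#'   \code{surface}, \code{lemma}, \code{tag}, \code{valid}.
#' @examples
#' d <- preprocess_document("The IOP was 18. Dry-eye noted.", doc_id = "ex")
#' length(d$sentences)
#' @export
preprocess_document <- function(raw_text, doc_id = "doc1",
                                lemmatizer = identity_lemmatizer,
                                tagger = heuristic_tagger) {
  stopifnot(is.character(raw_text), length(raw_text) == 1L)
  if (is.na(raw_text)) stop("raw_text must not be NA")
  if (!validEnc(raw_text)) {
    bad <- which(!validEnc(strsplit(raw_text, "")[[1]]))[1]
    stop("undecodable byte sequence in input near offset ", bad)
  }
  sentences <- list()
  if (nzchar(trimws(raw_text))) {
    pieces <- strsplit(raw_text, "(?<=[.!?])[[:space:]]+", perl = TRUE)[[1]]
    pieces <- pieces[nzchar(trimws(pieces))]
    for (p in pieces) {
      m <- regmatches(p, gregexpr(.token_pattern, p))[[1]]
      if (!length(m)) next
      lemma <- tolower(lemmatizer(m))
      stopifnot(length(lemma) == length(m), all(nzchar(lemma)))
      tag <- tagger(lemma)
      stopifnot(length(tag) == length(m))
      valid <- grepl("^[a-z0-9-]+$", lemma)
      sentences[[length(sentences) + 1L]] <-
        data.frame(surface = m, lemma = lemma, tag = tag, valid = valid,
                   stringsAsFactors = FALSE)
    }
  }
  structure(list(doc_id = doc_id, sentences = sentences),
            class = "term_document")
}

#' Preprocess a whole corpus
#'
#' @param texts named character vector (names become doc ids) or a
#'   \code{"term_corpus"} of raw texts from \code{\link{read_corpus}}.
#' @inheritParams preprocess_document
#' @return object of class \code{"term_corpus"}: list of
#'   \code{"term_document"}s.
#' @export
preprocess_corpus <- function(texts, lemmatizer = identity_lemmatizer,
                              tagger = heuristic_tagger) {
  if (inherits(texts, "term_corpus") && !is.character(texts))
    texts <- vapply(texts, function(d) d$text, character(1),
                    USE.NAMES = TRUE)
  if (is.null(names(texts)) || anyDuplicated(names(texts)))
    names(texts) <- sprintf("doc%04d", seq_along(texts))
  docs <- lapply(names(texts), function(id)
    preprocess_document(texts[[id]], doc_id = id,
                        lemmatizer = lemmatizer, tagger = tagger))
  structure(docs, class = "term_corpus")
}

#' @export
print.term_document <- function(x, ...) {
  cat("<term_document>", x$doc_id, "-", length(x$sentences), "sentence(s)\n")
  invisible(x)
}

#' @export
print.term_corpus <- function(x, ...) {
  cat("<term_corpus>", length(x), "document(s)\n")
  invisible(x)
}

#' Read a corpus of clinical letters from disk
#'
#' Accepts either a directory of \code{.txt} files (one letter per file; file
#' name minus extension becomes the document id) or a JSON-lines file with
#' fields \code{doc_id} and \code{text}.
#'
#' @param path directory or \code{.jsonl}/\code{.json} file path.
#' @return named character vector of raw texts.
#' @export
read_corpus <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.txt$", full.names = TRUE))
    if (!length(files)) stop("no .txt files found under ", path)
    texts <- vapply(files, function(f)
      paste(readLines(f, warn = FALSE, encoding = "UTF-8"), collapse = "\n"),
      character(1))
    names(texts) <- sub("\\.txt$", "", basename(files))
    return(texts)
  }
  if (!file.exists(path)) stop("corpus path does not exist: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  recs <- lapply(seq_along(lines), function(i) {
    r <- tryCatch(jsonlite::fromJSON(lines[i]),
                  error = function(e) stop("malformed JSON on line ", i, ": ",
                                           conditionMessage(e)))
    if (is.null(r$doc_id) || is.null(r$text))
      stop("line ", i, ": JSON record must carry doc_id and text")
    r
  })
  texts <- vapply(recs, function(r) as.character(r$text), character(1))
  names(texts) <- vapply(recs, function(r) as.character(r$doc_id), character(1))
  if (anyDuplicated(names(texts))) stop("duplicate doc_id in corpus file")
  texts
}

#' Extract noun-phrase candidate terms from a tagged document
#'
#' Applies the semi-closed linguistic filter: a candidate is a token run whose
#' tags match \code{JJ* NN+} (any number of adjectives followed by one or more
#' nouns, tags matched by prefix so NNS/NNP count as nouns). For every maximal
#' match all contiguous sub-spans that themselves match the pattern are also
#' emitted, so nested-term frequencies can be counted in a single pass. Spans
#' containing an invalid token are discarded, as are spans longer than
#' \code{max_len} words. Occurrences are returned in document order with
#' duplicates retained.
#'
#' @param doc a \code{"term_document"} from \code{\link{preprocess_document}}.
#' @param max_len maximum candidate length in words (default 4).
#' @return data frame with columns \code{text} (space-joined lemmas),
#'   \code{length}, \code{doc_id}, \code{sent_id} — one row per occurrence.
#' @export
chunk_candidates <- function(doc, max_len = 4L) {
  if (!inherits(doc, "term_document"))
    stop("doc must be a preprocessed term_document")
  out <- vector("list", length(doc$sentences))
  for (si in seq_along(doc$sentences)) {
    s <- doc$sentences[[si]]
    if (is.null(s$tag)) stop("document is not POS-tagged")
    cls <- ifelse(!s$valid, "x",
           ifelse(startsWith(s$tag, "JJ"), "A",
           ifelse(startsWith(s$tag, "NN"), "N", "x")))
    str <- paste(cls, collapse = "")
    mt <- gregexpr("A*N+", str)[[1]]
    if (mt[1] == -1L) next
    rows <- list()
    for (mi in seq_along(mt)) {
      st <- mt[mi]
      en <- st + attr(mt, "match.length")[mi] - 1L
      first_n <- st + regexpr("N", substr(str, st, en)) - 1L
      for (i in st:en) {
        for (j in max(i, first_n):en) {
          if (j - i + 1L > max_len) break
          rows[[length(rows) + 1L]] <-
            data.frame(text = paste(s$lemma[i:j], collapse = " "),
                       length = j - i + 1L,
                       doc_id = doc$doc_id, sent_id = si,
                       stringsAsFactors = FALSE)
        }
      }
    }
    out[[si]] <- do.call(rbind, rows)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(text = character(), length = integer(),
                      doc_id = character(), sent_id = integer(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Extract candidates from every document of a corpus
#'
#' @param corpus a \code{"term_corpus"} of preprocessed documents.
#' @inheritParams chunk_candidates
#' @return row-bound candidate occurrence table (see
#'   \code{\link{chunk_candidates}}).
#' @export
chunk_corpus <- function(corpus, max_len = 4L) {
  stopifnot(inherits(corpus, "term_corpus"))
  res <- do.call(rbind, lapply(corpus, chunk_candidates, max_len = max_len))
  if (is.null(res))
    res <- data.frame(text = character(), length = integer(),
                      doc_id = character(), sent_id = integer(),
                      stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}
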