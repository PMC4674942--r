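# Evaluation against a small annotated term set.
#
# The universe U is the union of the three filtered extractor outputs;
# positives P are the terms annotated as domain terms (optionally joined by
# unigrams confirmed by the dictionary); negatives N = U \ P.

#' Read term annotations
#'
#' Accepts a TSV with either two columns (\code{term}, \code{label} in
#' \{domain, non-domain\}) or three (\code{term}, \code{votes_valid},
#' \code{votes_total}); with votes, a term is a valid domain term when at
#' least two annotators voted for it.
#'
#' @param path TSV path (no header), or a data frame in one of the above
#'   shapes.
#' @param lemmatizer normalisation lemmatizer (must match the extractor
#'   pipeline's).
#' @return named character vector term -> label ("domain"/"non-domain").
#' @export
read_annotations <- function(path, lemmatizer = identity_lemmatizer) {
  df <- if (is.data.frame(path)) path
  else utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                         quote = "")
  if (ncol(df) == 2L) {
    labels <- as.character(df[[2L]])
    bad <- setdiff(unique(labels), c("domain", "non-domain"))
    if (length(bad))
      stop("annotation label(s) outside {domain, non-domain}: ",
           paste(bad, collapse = ", "))
  } else if (ncol(df) >= 3L) {
    labels <- ifelse(as.numeric(df[[2L]]) >= 2, "domain", "non-domain")
  } else stop("annotation file must have 2 or 3 columns")
  terms <- vapply(as.character(df[[1L]]), function(term) {
    toks <- regmatches(term, gregexpr(.token_pattern, term))[[1]]
    toks <- toks[grepl("[A-Za-z0-9]", toks)]
    paste(tolower(lemmatizer(toks)), collapse = " ")
  }, character(1), USE.NAMES = FALSE)
  keep <- !duplicated(terms)
  stats::setNames(labels[keep], terms[keep])
}

#' Build the evaluation ground truth
#'
#' @param filtered_lists list of filtered ranked term data frames (or plain
#'   character vectors of terms), one per extractor; their union forms the
#'   universe U.
#' @param annotations named label vector from \code{\link{read_annotations}}.
#' @param dictionary optional \code{"medical_dictionary"}; when supplied,
#'   unigrams of U found in its vocabulary are auto-confirmed positive even
#'   without an annotation.
#' @param include_unigrams when \code{FALSE}, single-word terms are removed
#'   from U (and hence from P and N) — the complex-terms-only condition.
#' @return object of class \code{"ground_truth"}: list with \code{universe},
#'   \code{positives}, \code{negatives}.
#' @export
build_ground_truth <- function(filtered_lists, annotations,
                               dictionary = NULL,
                               include_unigrams = TRUE) {
  terms_of <- function(x) if (is.data.frame(x)) x$term else as.character(x)
  U <- sort(unique(unlist(lapply(filtered_lists, terms_of))))
  if (!include_unigrams) U <- U[grepl(" ", U, fixed = TRUE)]
  P <- intersect(names(annotations)[annotations == "domain"], U)
  if (!is.null(dictionary)) {
    stopifnot(inherits(dictionary, "medical_dictionary"))
    unigrams <- U[!grepl(" ", U, fixed = TRUE)]
    confirmed <- unigrams[unigrams %in% dictionary$vocabulary]
    # dictionary confirmation never overrides an explicit non-domain label
    confirmed <- setdiff(confirmed,
                         names(annotations)[annotations == "non-domain"])
    P <- union(P, confirmed)
  }
  P <- sort(P)
  structure(list(universe = U, positives = P, negatives = setdiff(U, P)),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth> |U| =", length(x$universe),
      " |P| =", length(x$positives), " |N| =", length(x$negatives), "\n")
  invisible(x)
}

#' Precision, recall and F-measure of a predicted term set
#'
#' Counts are taken over the ground-truth universe; predicted terms outside
#' it are ignored (their number is reported). Zero denominators yield 0 with
#' a flag rather than NaN, so the GA fitness is total.
#'
#' @param predicted character vector of predicted domain terms.
#' @param gt a \code{"ground_truth"}.
#' @return list with \code{precision}, \code{recall}, \code{f_measure},
#'   \code{counts} (TP/FP/FN/TN), \code{zero_division} flag and
#'   \code{n_outside} (predictions outside U).
#' @export
compute_metrics <- function(predicted, gt) {
  stopifnot(inherits(gt, "ground_truth"))
  predicted <- unique(as.character(predicted))
  n_outside <- sum(!(predicted %in% gt$universe))
  pred <- intersect(predicted, gt$universe)
  tp <- length(intersect(pred, gt$positives))
  fp <- length(intersect(pred, gt$negatives))
  fn <- length(setdiff(gt$positives, pred))
  tn <- length(setdiff(gt$negatives, pred))
  zero <- FALSE
  precision <- if (tp + fp > 0) tp / (tp + fp) else { zero <- TRUE; 0 }
  recall <- if (tp + fn > 0) tp / (tp + fn) else { zero <- TRUE; 0 }
  f <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall)
  else { zero <- TRUE; 0 }
  list(precision = precision, recall = recall, f_measure = f,
       counts = c(TP = tp, FP = fp, FN = fn, TN = tn),
       zero_division = zero, n_outside = n_outside)
}
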