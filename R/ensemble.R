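# Rank fusion: normalise each extractor's ranking to [0, 1], combine with a
# simplex weight vector and classify at a score threshold.
#
#   r_w(t) = sum_i w_i * r_i(t),  w_i in [0, 1], sum w_i = 1
#
# with r_i(t) the normalised ranking score of term t under method i and
# r_i(t) = 0 for terms the method did not extract.

.simplex_tol <- 1e-9

#' Validate a fusion weight vector
#'
#' @param w numeric vector; each entry in [0, 1], summing to 1 within 1e-9.
#' @param n_methods expected length (default: length of \code{w}).
#' @return \code{w}, invisibly, after validation.
#' @export
check_weights <- function(w, n_methods = length(w)) {
  if (length(w) != n_methods || any(w < -.simplex_tol) ||
      any(w > 1 + .simplex_tol) || abs(sum(w) - 1) > .simplex_tol)
    stop("weights must lie on the ", n_methods, "-simplex (each in [0,1], ",
         "summing to 1)")
  invisible(w)
}

#' Rank-normalise a scored term list
#'
#' The term at rank k of N receives r = 1 - (k - 1)/N, so the top term maps
#' to 1 and the bottom to 1/N. Raw extractor scales (support, C-Value,
#' TextRank weight) are incommensurable; rank normalisation places all three
#' on a common [0, 1] footing. A min-max alternative on raw scores is
#' provided.
#'
#' @param ranked data frame \code{term}, \code{score}, ordered best first
#'   (score descending, ties broken by term text ascending).
#' @param method \code{"rank"} (default) or \code{"minmax"}.
#' @return named numeric vector term -> r in (0, 1]; terms absent from the
#'   list are later treated as 0.
#' @export
normalize_ranking <- function(ranked, method = c("rank", "minmax")) {
  method <- match.arg(method)
  if (!nrow(ranked)) return(stats::setNames(numeric(), character()))
  ord <- order(-ranked$score, ranked$term)
  ranked <- ranked[ord, , drop = FALSE]
  if (anyDuplicated(ranked$term)) stop("terms must be unique within a list")
  n <- nrow(ranked)
  r <- if (method == "rank") 1 - (seq_len(n) - 1) / n
  else {
    rng <- range(ranked$score)
    if (diff(rng) == 0) rep(1, n) else (ranked$score - rng[1]) / diff(rng)
  }
  stats::setNames(r, ranked$term)
}

#' Weighted-sum ensemble scores
#'
#' @param norm_scores list of named numeric vectors (one per method, in
#'   weight order), as returned by \code{\link{normalize_ranking}}.
#' @param w weight vector on the simplex, one weight per method.
#' @param terms universe of terms to score (default: union of all methods'
#'   terms).
#' @return named numeric vector term -> r_w(t) in [0, 1].
#' @export
ensemble_score <- function(norm_scores, w,
                           terms = sort(unique(unlist(lapply(norm_scores,
                                                             names))))) {
  check_weights(w, length(norm_scores))
  R <- score_matrix(norm_scores, terms)
  stats::setNames(as.numeric(R %*% w), terms)
}

#' Matrix of normalised scores (terms by methods)
#'
#' @inheritParams ensemble_score
#' @return numeric matrix, one row per term, absent terms scored 0.
#' @export
score_matrix <- function(norm_scores, terms) {
  R <- vapply(norm_scores, function(ns) {
    v <- ns[terms]
    v[is.na(v)] <- 0
    unname(v)
  }, numeric(length(terms)))
  if (length(terms) == 1L) R <- matrix(R, nrow = 1L)
  rownames(R) <- terms
  R
}

#' Classify terms at the rank threshold
#'
#' @param scores named ensemble scores from \code{\link{ensemble_score}}.
#' @param rank_threshold cut-off in [0, 1]; a term is predicted
#'   domain-related when its score is greater than or equal to it
#'   (default 0.50).
#' @return logical vector (named like \code{scores}).
#' @export
classify_terms <- function(scores, rank_threshold = 0.50) {
  stopifnot(rank_threshold >= 0, rank_threshold <= 1)
  scores >= rank_threshold
}
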