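# TextRank over a term co-occurrence graph.
#
# Candidate terms are vertices; two terms are connected when they occur in
# the same sentence, the whole corpus being treated as one concatenated
# document. Scores follow the weighted voting recursion
#
#   WS(v_i) = (1 - d) + d * sum_{j in in(i)} w_ji / (sum_k w_jk) * WS(v_j)
#
# iterated synchronously from a uniform 1/n start until the largest absolute
# per-vertex change drops below epsilon or the iteration cap is reached.

#' Build the sentence co-occurrence term graph
#'
#' @param corpus a preprocessed \code{"term_corpus"} or a candidate
#'   occurrence table (columns \code{text}, \code{doc_id}, \code{sent_id}).
#' @param edge_weighting \code{"cooccurrence_count"} (edge weight = number of
#'   sentences in which both terms occur, default) or \code{"unweighted"}
#'   (all weights 1).
#' @param max_len maximum candidate length in words when chunking.
#' @return object of class \code{"term_graph"}: list with \code{vertices}
#'   (sorted character vector) and \code{edges} (data frame \code{u},
#'   \code{v}, \code{weight}, with \code{u < v}; no self-loops).
#' @export
build_term_graph <- function(corpus,
                             edge_weighting = c("cooccurrence_count",
                                                "unweighted"),
                             max_len = 4L) {
  edge_weighting <- match.arg(edge_weighting)
  occ <- if (inherits(corpus, "term_corpus"))
    chunk_corpus(corpus, max_len = max_len) else corpus
  if (!nrow(occ))
    return(structure(list(vertices = character(),
                          edges = data.frame(u = character(),
                                             v = character(),
                                             weight = numeric(),
                                             stringsAsFactors = FALSE)),
                     class = "term_graph"))
  vertices <- sort(unique(occ$text))
  key <- paste(occ$doc_id, occ$sent_id, sep = "\r")
  pair_counts <- new.env(parent = emptyenv())
  for (sk in unique(key)) {
    terms <- sort(unique(occ$text[key == sk]))
    if (length(terms) < 2L) next
    for (i in seq_len(length(terms) - 1L))
      for (j in (i + 1L):length(terms)) {
        pk <- paste(terms[i], terms[j], sep = "\r")
        assign(pk, (if (exists(pk, pair_counts)) get(pk, pair_counts)
                    else 0) + 1, pair_counts)
      }
  }
  keys <- sort(ls(pair_counts))
  edges <- if (length(keys)) {
    parts <- strsplit(keys, "\r", fixed = TRUE)
    data.frame(u = vapply(parts, `[`, character(1), 1L),
               v = vapply(parts, `[`, character(1), 2L),
               weight = if (edge_weighting == "unweighted")
                 rep(1, length(keys))
               else vapply(keys, function(k) get(k, pair_counts), numeric(1)),
               stringsAsFactors = FALSE, row.names = NULL)
  } else data.frame(u = character(), v = character(), weight = numeric(),
                    stringsAsFactors = FALSE)
  structure(list(vertices = vertices, edges = edges), class = "term_graph")
}

#' @export
print.term_graph <- function(x, ...) {
  cat("<term_graph>", length(x$vertices), "vertices,", nrow(x$edges),
      "edges\n")
  invisible(x)
}

#' Iterate TextRank scores on a term graph
#'
#' Synchronous fixed-point iteration (all updates read the previous
#' iteration's scores, vertices in fixed sorted order, so results are
#' bit-reproducible). Every vertex starts at 1/n; isolated vertices settle at
#' exactly \code{1 - d}.
#'
#' @param g a \code{"term_graph"}.
#' @param d damping factor in (0, 1), default 0.85.
#' @param max_iterations iteration cap, default 30.
#' @param epsilon convergence threshold on the maximum absolute per-vertex
#'   change, default 1e-4.
#' @return object of class \code{"textrank_state"}: list with \code{scores}
#'   (named, sorted by vertex), \code{iterations}, \code{converged}.
#' @export
run_textrank <- function(g, d = 0.85, max_iterations = 30L,
                         epsilon = 1e-4) {
  stopifnot(inherits(g, "term_graph"), d > 0, d < 1, epsilon > 0)
  n <- length(g$vertices)
  if (n == 0L)
    return(structure(list(scores = numeric(), iterations = 0L,
                          converged = TRUE), class = "textrank_state"))
  W <- matrix(0, n, n, dimnames = list(g$vertices, g$vertices))
  if (nrow(g$edges)) {
    iu <- match(g$edges$u, g$vertices)
    iv <- match(g$edges$v, g$vertices)
    W[cbind(iu, iv)] <- g$edges$weight
    W[cbind(iv, iu)] <- g$edges$weight
  }
  strength <- rowSums(W)
  P <- W
  nz <- strength > 0
  P[nz, ] <- P[nz, , drop = FALSE] / strength[nz]
  x <- rep(1 / n, n)
  it <- 0L
  converged <- FALSE
  while (it < max_iterations) {
    xn <- (1 - d) + d * as.numeric(crossprod(P, x))
    it <- it + 1L
    delta <- max(abs(xn - x))
    x <- xn
    if (delta < epsilon) { converged <- TRUE; break }
  }
  structure(list(scores = stats::setNames(x, g$vertices),
                 iterations = it, converged = converged),
            class = "textrank_state")
}

#' @export
print.textrank_state <- function(x, ...) {
  cat("<textrank_state>", length(x$scores), "vertices;",
      x$iterations, "iterations;",
      if (x$converged) "converged" else "iteration cap reached", "\n")
  invisible(x)
}

#' TextRank term ranking over a corpus
#'
#' Builds the corpus-level co-occurrence graph and ranks candidate terms by
#' converged TextRank score (descending, lexicographic tie-break).
#'
#' @inheritParams build_term_graph
#' @inheritParams run_textrank
#' @return data frame \code{term}, \code{score}, best first.
#' @export
textrank_ranking <- function(corpus, d = 0.85, max_iterations = 30L,
                             epsilon = 1e-4,
                             edge_weighting = "cooccurrence_count",
                             max_len = 4L) {
  g <- build_term_graph(corpus, edge_weighting = edge_weighting,
                        max_len = max_len)
  st <- run_textrank(g, d = d, max_iterations = max_iterations,
                     epsilon = epsilon)
  if (!length(st$scores))
    return(data.frame(term = character(), score = numeric(),
                      stringsAsFactors = FALSE))
  out <- data.frame(term = names(st$scores), score = unname(st$scores),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
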