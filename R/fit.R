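# The central fitting surface: run the three extractors, filter, fuse, and
# learn the fusion weights with the GA, returning a classed model object.

#' Fit a GA-weighted ensemble term extractor
#'
#' Runs the full unsupervised pipeline on a corpus of clinical letters:
#' preprocesses and chunks the text, ranks candidate terms with PrefixSpan
#' (contiguous frequent word sequences), C-Value (termhood) and TextRank
#' (co-occurrence graph voting), filters each ranking against the domain
#' dictionary, builds the evaluation universe (the union of the three
#' filtered lists) with annotated positives, and evolves fusion weights on
#' the 3-simplex that maximise the F-measure of the thresholded weighted-sum
#' score.
#'
#' @param corpus raw letters as a named character vector, a preprocessed
#'   \code{"term_corpus"}, or a \code{"synthetic_corpus"} (whose exact tag
#'   table is then used automatically).
#' @param dictionary a \code{"medical_dictionary"}, or a path/character
#'   vector accepted by \code{\link{load_dictionary}}.
#' @param annotations named label vector from \code{\link{read_annotations}}
#'   (or anything that function accepts).
#' @param lemmatizer,tagger preprocessing plug-ins (defaults:
#'   \code{\link{identity_lemmatizer}}, \code{\link{heuristic_tagger}}).
#' @param min_sup PrefixSpan support threshold (fraction of documents or
#'   absolute; default 0.001 = 0.1 % of the corpus).
#' @param max_term_length candidate/pattern length cap in words (default 4).
#' @param d,tr_iterations,tr_epsilon TextRank damping (0.85), iteration cap
#'   (30) and convergence threshold (1e-4).
#' @param unigram_mode C-Value unigram handling (see
#'   \code{\link{compute_cvalue}}).
#' @param match_mode dictionary matching mode (see
#'   \code{\link{filter_terms}}).
#' @param include_unigrams evaluate with single-word terms (\code{TRUE}) or
#'   complex terms only (\code{FALSE}); exclusion applies symmetrically to
#'   the universe, the positives and predictions.
#' @param confirm_unigrams auto-confirm dictionary unigrams as positives
#'   when building the ground truth (default \code{TRUE}).
#' @param ga a \code{\link{ga_config}}; the fitness threshold is taken from
#'   its \code{rank_threshold}.
#' @return an object of class \code{"term_ensemble"} with components
#'   \code{rankings}, \code{filtered}, \code{normalized}, \code{ground_truth},
#'   \code{ga}, \code{weights}, \code{scores}, \code{predicted},
#'   \code{metrics}; supports \code{print}, \code{summary}, \code{coef},
#'   \code{predict} and \code{plot}.
#' @examples
#' syn <- generate_corpus(n_documents = 30, seed = 7)
#' truth <- generate_truth()
#' fit <- term_ensemble(syn, truth$dictionary, truth$annotations,
#'                      ga = ga_config(population_size = 20, generations = 10,
#'                                     runs = 2, rng_seed = 7))
#' coef(fit)
#' @export
term_ensemble <- function(corpus, dictionary, annotations,
                          lemmatizer = identity_lemmatizer,
                          tagger = heuristic_tagger,
                          min_sup = 0.001, max_term_length = 4L,
                          d = 0.85, tr_iterations = 30L, tr_epsilon = 1e-4,
                          unigram_mode = "plus_one",
                          match_mode = "token_coverage",
                          include_unigrams = TRUE,
                          confirm_unigrams = TRUE,
                          ga = ga_config()) {
  cl <- match.call()
  if (inherits(corpus, "synthetic_corpus")) {
    tagger <- lookup_tagger(corpus$tag_table)
    corpus <- corpus$texts
  }
  if (!inherits(corpus, "term_corpus") ||
      !inherits(corpus[[1]], "term_document"))
    corpus <- preprocess_corpus(corpus, lemmatizer = lemmatizer,
                                tagger = tagger)
  if (!inherits(dictionary, "medical_dictionary"))
    dictionary <- load_dictionary(dictionary, lemmatizer = lemmatizer)
  if (!is.character(annotations) || is.null(names(annotations)))
    annotations <- read_annotations(annotations, lemmatizer = lemmatizer)

  rankings <- list(
    prefixspan = prefixspan_ranking(corpus, min_sup = min_sup,
                                    max_length = max_term_length),
    cvalue = {
      cv <- cvalue_ranking(corpus, unigram_mode = unigram_mode,
                           max_len = max_term_length)
      cv[, c("term", "score")]
    },
    textrank = textrank_ranking(corpus, d = d,
                                max_iterations = tr_iterations,
                                epsilon = tr_epsilon,
                                max_len = max_term_length))
  filtered <- lapply(rankings, filter_terms, dict = dictionary,
                     match_mode = match_mode)
  gt <- build_ground_truth(filtered, annotations,
                           dictionary = if (confirm_unigrams) dictionary,
                           include_unigrams = include_unigrams)
  drop_unigrams <- function(df)
    df[grepl(" ", df$term, fixed = TRUE), , drop = FALSE]
  norm_input <- if (include_unigrams) filtered
  else lapply(filtered, drop_unigrams)
  normalized <- lapply(norm_input, normalize_ranking)
  ctx <- ga_context(normalized, gt)
  ga_res <- run_ga(ctx, ga)
  weights <- stats::setNames(ga_res$best_weights, names(rankings))
  scores <- ensemble_score(normalized, unname(weights),
                           terms = gt$universe)
  predicted <- classify_terms(scores, ga$rank_threshold)
  metrics <- compute_metrics(names(predicted)[predicted], gt)
  structure(list(call = cl, rankings = rankings, filtered = filtered,
                 normalized = normalized, ground_truth = gt, ga = ga_res,
                 weights = weights, scores = scores, predicted = predicted,
                 metrics = metrics,
                 settings = list(min_sup = min_sup,
                                 max_term_length = max_term_length,
                                 d = d, tr_iterations = tr_iterations,
                                 tr_epsilon = tr_epsilon,
                                 unigram_mode = unigram_mode,
                                 match_mode = match_mode,
                                 include_unigrams = include_unigrams,
                                 rank_threshold = ga$rank_threshold)),
            class = "term_ensemble")
}

#' @export
print.term_ensemble <- function(x, ...) {
  cat("GA-weighted ensemble term extractor\n\n")
  cat("Extractors: prefixspan, cvalue, textrank",
      sprintf("(universe: %d terms, %d annotated positive)\n",
              length(x$ground_truth$universe),
              length(x$ground_truth$positives)))
  cat("Fusion weights:\n")
  print(round(x$weights, 4))
  cat(sprintf("Ensemble F-measure: %.4f (precision %.4f, recall %.4f)\n",
              x$metrics$f_measure, x$metrics$precision, x$metrics$recall))
  invisible(x)
}

#' @export
coef.term_ensemble <- function(object, ...) object$weights

#' @export
fitted.term_ensemble <- function(object, ...) object$scores

#' Predict domain relatedness of terms
#'
#' Scores terms with the fitted fusion weights (terms unseen by every
#' extractor score 0) and classifies them at the fitted rank threshold.
#'
#' @param object a fitted \code{"term_ensemble"}.
#' @param newdata character vector of normalised term texts; defaults to the
#'   fitted universe.
#' @param ... unused.
#' @return data frame \code{term}, \code{score}, \code{predicted}, ordered
#'   by score descending.
#' @export
predict.term_ensemble <- function(object, newdata = NULL, ...) {
  terms <- if (is.null(newdata)) object$ground_truth$universe
  else as.character(newdata)
  sc <- ensemble_score(object$normalized, unname(object$weights),
                       terms = terms)
  out <- data.frame(term = names(sc), score = unname(sc),
                    predicted = unname(classify_terms(
                      sc, object$settings$rank_threshold)),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarise a fitted ensemble
#'
#' Reports, per extractor, the filtered list size and the metrics of using
#' that extractor alone (its rank-normalised scores thresholded at the rank
#' threshold), alongside the ensemble's learnt weights and metrics.
#'
#' @param object a fitted \code{"term_ensemble"}.
#' @param ... unused.
#' @return object of class \code{"summary.term_ensemble"}.
#' @export
summary.term_ensemble <- function(object, ...) {
  gt <- object$ground_truth
  thr <- object$settings$rank_threshold
  per_method <- do.call(rbind, lapply(names(object$normalized), function(m) {
    ns <- object$normalized[[m]]
    pred <- names(ns)[ns >= thr]
    met <- compute_metrics(pred, gt)
    data.frame(method = m, n_filtered = length(ns),
               precision = met$precision, recall = met$recall,
               f_measure = met$f_measure, stringsAsFactors = FALSE)
  }))
  structure(list(per_method = per_method, weights = object$weights,
                 metrics = object$metrics,
                 avg_fitness = object$ga$avg_fitness,
                 universe = length(gt$universe),
                 positives = length(gt$positives),
                 include_unigrams = object$settings$include_unigrams),
            class = "summary.term_ensemble")
}

#' @export
print.summary.term_ensemble <- function(x, ...) {
  cat("GA-weighted ensemble term extractor —",
      if (x$include_unigrams) "with unigrams" else "complex terms only",
      "\n\n")
  cat(sprintf("Universe: %d terms (%d positive)\n\n", x$universe,
              x$positives))
  cat("Individual extractors (thresholded alone):\n")
  pm <- x$per_method
  pm[, 3:5] <- round(pm[, 3:5], 4)
  print(pm, row.names = FALSE)
  cat("\nLearnt fusion weights:\n")
  print(round(x$weights, 4))
  cat(sprintf("\nEnsemble: precision %.4f, recall %.4f, F-measure %.4f\n",
              x$metrics$precision, x$metrics$recall, x$metrics$f_measure))
  cat(sprintf("GA end-of-run fitness (avg over runs): best %.4f, mean %.4f\n",
              x$avg_fitness["best"], x$avg_fitness["mean"]))
  invisible(x)
}

#' Plot the GA fitness history
#'
#' Best, mean and worst population fitness per generation, averaged over
#' runs.
#'
#' @param x a fitted \code{"term_ensemble"} (or a \code{"ga_result"}).
#' @param ... passed to \code{matplot}.
#' @export
plot.term_ensemble <- function(x, ...) {
  h <- if (inherits(x, "term_ensemble")) x$ga$history else x$history
  if (!nrow(h)) {
    warning("no generations were run; nothing to plot")
    return(invisible(NULL))
  }
  graphics::matplot(h$generation, h[, c("best", "mean", "worst")],
                    type = "l", lty = c(1, 2, 3), col = c(1, 2, 4),
                    xlab = "generation", ylab = "F-measure",
                    main = "GA fitness history (averaged over runs)", ...)
  graphics::legend("bottomright", legend = c("best", "mean", "worst"),
                   lty = c(1, 2, 3), col = c(1, 2, 4), bty = "n")
  invisible(x)
}

#' @export
plot.ga_result <- plot.term_ensemble
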