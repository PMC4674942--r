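# File-level pipeline binding the modules together: each command reads and
# writes plain-text artifacts (TSV rankings, newline dictionaries, YAML
# config) so runs are scriptable and re-runnable.

#' Assemble a pipeline configuration
#'
#' Values resolve with precedence: direct arguments in \code{...} over the
#' YAML config file over built-in defaults. The defaults equal the study
#' conditions: min_sup 0.1 % of documents, damping 0.85 with 30 iterations
#' and threshold 1e-4, term length cap 4, elitism 0.40, rank/domination
#' thresholds 0.50/0.85, population 100, generations 200.
#'
#' @param path optional YAML file of settings.
#' @param ... named overrides of any setting.
#' @return named list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(path = NULL, ...) {
  defaults <- list(
    corpus = NULL, dictionary = NULL, annotations = NULL, tags = NULL,
    output_dir = ".", min_sup = 0.001, max_term_length = 4L,
    d = 0.85, tr_iterations = 30L, tr_epsilon = 1e-4,
    unigram_mode = "plus_one", match_mode = "token_coverage",
    include_unigrams = TRUE, rank_threshold = 0.50,
    domination_threshold = 0.85, population_size = 100L,
    generations = 200L, runs = 100L, elitism_rate = 0.40,
    child_mutation_prob = 0.20, elite_mutation_prob = 0.10,
    crossover_switch_fraction = 0.5, seed = 1L,
    n_documents = 100L, log_level = "info")
  cfg <- defaults
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    from_file <- yaml::read_yaml(path)
    unknown <- setdiff(names(from_file), names(defaults))
    if (length(unknown))
      stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    cfg[names(from_file)] <- from_file
  }
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(overrides)] <- overrides
  structure(cfg, class = "pipeline_config")
}

.log <- function(cfg, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message(format(Sys.time(), "%H:%M:%S "), ...)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  path
}

.read_ranked_tsv <- function(path) {
  if (!file.exists(path)) stop("missing input: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
  if (!all(c("term", "score") %in% names(df)))
    stop("malformed TSV (need term/score columns): ", path)
  df
}

.load_pipeline_corpus <- function(cfg) {
  if (is.null(cfg$corpus)) stop("missing input path: corpus")
  texts <- read_corpus(cfg$corpus)
  tagger <- if (!is.null(cfg$tags)) {
    tt <- utils::read.delim(cfg$tags, stringsAsFactors = FALSE, quote = "")
    lookup_tagger(stats::setNames(tt$tag, tt$lemma))
  } else heuristic_tagger
  preprocess_corpus(texts, tagger = tagger)
}

#' Run a pipeline command
#'
#' Commands:
#' \describe{
#'   \item{synth}{write a synthetic corpus bundle (JSON-lines corpus, tag
#'     table, dictionary, annotations) into the output directory;}
#'   \item{extract}{run the three extractors over the corpus and write
#'     \code{prefixspan.tsv}, \code{cvalue.tsv}, \code{textrank.tsv};}
#'   \item{filter}{apply dictionary filtering to the three rankings, writing
#'     \code{*_filtered.tsv};}
#'   \item{fuse}{combine filtered rankings with given weights into
#'     \code{ensemble.tsv} (per-method normalised scores, fused score,
#'     prediction);}
#'   \item{train}{fit the full ensemble (GA weight learning) and write
#'     \code{weights.tsv}, \code{history.tsv} and \code{ensemble.tsv};}
#'   \item{evaluate}{score a prediction TSV against the ground truth twice —
#'     with unigrams and complex-terms-only — writing
#'     \code{metrics_with_unigrams.tsv} and
#'     \code{metrics_without_unigrams.tsv}.}
#' }
#'
#' @param command one of the above.
#' @param config a \code{\link{pipeline_config}} (or YAML path).
#' @param weights numeric fusion weights for \code{fuse} (default uniform).
#' @return invisibly, a named list of written artifact paths (plus command
#'   results such as the fitted model for \code{train}).
#' @export
run_pipeline <- function(command = c("extract", "filter", "fuse", "train",
                                     "evaluate", "synth"),
                         config = pipeline_config(), weights = NULL) {
  command <- match.arg(command)
  cfg <- if (inherits(config, "pipeline_config")) config
  else pipeline_config(config)
  out <- cfg$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  .log(cfg, "command=", command, " seed=", cfg$seed, " output=", out)
  art <- list()

  if (command == "synth") {
    lex <- term_lexicon(cfg$n_documents)
    syn <- generate_corpus(lex, n_documents = cfg$n_documents,
                           seed = cfg$seed)
    truth <- generate_truth(lex)
    corpus_path <- file.path(out, "corpus.jsonl")
    writeLines(vapply(names(syn$texts), function(id)
      jsonlite::toJSON(list(doc_id = id, text = syn$texts[[id]]),
                       auto_unbox = TRUE), character(1)), corpus_path)
    tags_path <- .write_tsv(
      data.frame(lemma = names(syn$tag_table),
                 tag = unname(syn$tag_table), stringsAsFactors = FALSE),
      file.path(out, "tags.tsv"))
    dict_path <- file.path(out, "dictionary.txt")
    writeLines(truth$dictionary$entries, dict_path)
    ann_path <- .write_tsv(
      data.frame(term = names(truth$annotations),
                 label = unname(truth$annotations),
                 stringsAsFactors = FALSE),
      file.path(out, "annotations.tsv"))
    art <- list(corpus = corpus_path, tags = tags_path,
                dictionary = dict_path, annotations = ann_path)
  } else if (command == "extract") {
    corpus <- .load_pipeline_corpus(cfg)
    art$prefixspan <- .write_tsv(
      prefixspan_ranking(corpus, min_sup = cfg$min_sup,
                         max_length = cfg$max_term_length),
      file.path(out, "prefixspan.tsv"))
    cv <- cvalue_ranking(corpus, unigram_mode = cfg$unigram_mode,
                         max_len = cfg$max_term_length)
    art$cvalue <- .write_tsv(cv, file.path(out, "cvalue.tsv"))
    art$textrank <- .write_tsv(
      textrank_ranking(corpus, d = cfg$d,
                       max_iterations = cfg$tr_iterations,
                       epsilon = cfg$tr_epsilon,
                       max_len = cfg$max_term_length),
      file.path(out, "textrank.tsv"))
  } else if (command == "filter") {
    if (is.null(cfg$dictionary)) stop("missing input path: dictionary")
    dict <- load_dictionary(cfg$dictionary)
    for (m in c("prefixspan", "cvalue", "textrank")) {
      ranked <- .read_ranked_tsv(file.path(out, paste0(m, ".tsv")))
      kept <- filter_terms(ranked[, c("term", "score")], dict,
                           match_mode = cfg$match_mode)
      .log(cfg, m, ": kept ", nrow(kept), "/", nrow(ranked),
           " (survivor fraction ",
           format(attr(kept, "survivor_fraction"), digits = 3), ")")
      art[[m]] <- .write_tsv(kept, file.path(out,
                                             paste0(m, "_filtered.tsv")))
    }
  } else if (command == "fuse") {
    lists <- lapply(c("prefixspan", "cvalue", "textrank"), function(m)
      .read_ranked_tsv(file.path(out, paste0(m, "_filtered.tsv"))))
    normalized <- lapply(lists, normalize_ranking)
    if (is.null(weights)) weights <- rep(1 / 3, 3)
    check_weights(weights, 3L)
    terms <- sort(unique(unlist(lapply(normalized, names))))
    R <- score_matrix(normalized, terms)
    rw <- as.numeric(R %*% weights)
    ens <- data.frame(term = terms, r1 = R[, 1], r2 = R[, 2], r3 = R[, 3],
                      r_w = rw, predicted = rw >= cfg$rank_threshold,
                      stringsAsFactors = FALSE)
    ens <- ens[order(-ens$r_w, ens$term), , drop = FALSE]
    art$ensemble <- .write_tsv(ens, file.path(out, "ensemble.tsv"))
  } else if (command == "train") {
    corpus <- .load_pipeline_corpus(cfg)
    if (is.null(cfg$dictionary)) stop("missing input path: dictionary")
    if (is.null(cfg$annotations)) stop("missing input path: annotations")
    ann_df <- utils::read.delim(cfg$annotations, stringsAsFactors = FALSE,
                                quote = "")
    fit <- term_ensemble(
      corpus, load_dictionary(cfg$dictionary),
      read_annotations(ann_df),
      min_sup = cfg$min_sup, max_term_length = cfg$max_term_length,
      d = cfg$d, tr_iterations = cfg$tr_iterations,
      tr_epsilon = cfg$tr_epsilon, unigram_mode = cfg$unigram_mode,
      match_mode = cfg$match_mode,
      include_unigrams = cfg$include_unigrams,
      ga = ga_config(population_size = cfg$population_size,
                     generations = cfg$generations, runs = cfg$runs,
                     elitism_rate = cfg$elitism_rate,
                     child_mutation_prob = cfg$child_mutation_prob,
                     elite_mutation_prob = cfg$elite_mutation_prob,
                     rank_threshold = cfg$rank_threshold,
                     domination_threshold = cfg$domination_threshold,
                     crossover_switch_fraction =
                       cfg$crossover_switch_fraction,
                     rng_seed = cfg$seed))
    art$weights <- .write_tsv(
      data.frame(w_prefixspan = fit$weights[1], w_cvalue = fit$weights[2],
                 w_textrank = fit$weights[3]),
      file.path(out, "weights.tsv"))
    art$history <- .write_tsv(fit$ga$history, file.path(out, "history.tsv"))
    pred <- predict(fit)
    art$ensemble <- .write_tsv(pred, file.path(out, "ensemble.tsv"))
    art$fit <- fit
  } else if (command == "evaluate") {
    if (is.null(cfg$annotations)) stop("missing input path: annotations")
    ann_df <- utils::read.delim(cfg$annotations, stringsAsFactors = FALSE,
                                quote = "")
    ann <- read_annotations(ann_df)
    dict <- if (!is.null(cfg$dictionary)) load_dictionary(cfg$dictionary)
    lists <- lapply(c("prefixspan", "cvalue", "textrank"), function(m)
      .read_ranked_tsv(file.path(out, paste0(m, "_filtered.tsv"))))
    ens <- utils::read.delim(file.path(out, "ensemble.tsv"),
                             stringsAsFactors = FALSE, quote = "")
    predicted <- ens$term[as.logical(ens$predicted)]
    for (mode in c("with_unigrams", "without_unigrams")) {
      inc <- mode == "with_unigrams"
      gt <- build_ground_truth(lists, ann, dictionary = dict,
                               include_unigrams = inc)
      pred <- if (inc) predicted
      else predicted[grepl(" ", predicted, fixed = TRUE)]
      met <- compute_metrics(pred, gt)
      art[[paste0("metrics_", mode)]] <- .write_tsv(
        data.frame(metric = c("precision", "recall", "f_measure",
                              "TP", "FP", "FN", "TN"),
                   value = c(met$precision, met$recall, met$f_measure,
                             met$counts)),
        file.path(out, paste0("metrics_", mode, ".tsv")))
    }
  }
  invisible(art)
}
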