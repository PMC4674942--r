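# Synthetic clinical-letter generator.
#
# Emulates the shape of a specialist-letter corpus: short letters (~120
# words) of templated subject-verb-object clauses, with multi-word domain
# terms planted at exact document frequencies, a nested term pair (a short
# term contained in a longer one), frequent non-domain distractor phrases
# ("twelve months"), and filler clauses. Every generated token has a known
# POS tag, so the deterministic lookup tagger reproduces the intended chunk
# structure exactly and all downstream statistics are hand-computable.

.plant_templates <- c(
  "the patient presented with %s during this visit .",
  "we noted %s on review today .",
  "she reported %s again last month .",
  "there was %s which seemed stable .",
  "his %s has improved since then ."
)

.filler_templates <- c(
  "the patient was seen in the clinic today .",
  "i reviewed her again at the appointment .",
  "he is doing well and seems happy .",
  "we will arrange another appointment soon .",
  "thank you for your referral letter .",
  "she was seen by the nurse yesterday .",
  "the prescription was renewed without concern ."
)

# tags for every word the templates can emit (beyond the closed-class list)
.template_tags <- c(
  patient = "NN", presented = "VBD", visit = "NN", noted = "VBD",
  review = "NN", reported = "VBD", month = "NN", months = "NNS",
  seemed = "VBD", stable = "JJ", improved = "VBN", seen = "VBN",
  clinic = "NN", reviewed = "VBD", appointment = "NN", doing = "VBG",
  well = "RB", seems = "VBZ", happy = "JJ", arrange = "VB", another = "DT",
  soon = "RB", thank = "VBP", you = "PRP", your = "PRP$", referral = "NN",
  letter = "NN", nurse = "NN", prescription = "NN", renewed = "VBN",
  without = "IN", concern = "NN", last = "JJ", week = "NN",
  twelve = "JJ", kind = "JJ", regards = "NNS"
)

#' Default synthetic term lexicon
#'
#' Ophthalmology-flavoured domain terms with target document frequencies,
#' one nested term pair ("angle closure" inside "acute angle closure"),
#' non-domain distractor phrases, and per-word POS tags. Frequencies are
#' chosen so that, in a 100-letter corpus, every domain term clears a 0.1 %
#' document-frequency support floor by a wide margin.
#'
#' @param n_documents corpus size the frequencies are scaled for
#'   (default 100).
#' @return list of class \code{"term_lexicon"} with \code{domain_terms}
#'   (data frame \code{term}, \code{df}), \code{nested_pairs},
#'   \code{distractors} (same shape as \code{domain_terms}), and
#'   \code{word_tags} (named tag vector for term and distractor words).
#' @export
term_lexicon <- function(n_documents = 100L) {
  scale <- n_documents / 100
  df <- function(x) max(2L, as.integer(round(x * scale)))
  domain_terms <- data.frame(
    term = c("intraocular pressure", "visual acuity", "cataract surgery",
             "optic disc", "macular degeneration", "dry eye",
             "angle closure", "acute angle closure", "retinal detachment",
             "fundus examination", "posterior vitreous detachment",
             "glaucoma", "cataract"),
    df = c(df(30), df(28), df(22), df(18), df(15), df(12), df(10), df(8),
           df(9), df(11), df(7), df(20), df(16)),
    stringsAsFactors = FALSE)
  distractors <- data.frame(
    term = c("twelve months", "kind regards", "last week"),
    df = c(df(25), df(20), df(15)),
    stringsAsFactors = FALSE)
  word_tags <- c(
    intraocular = "JJ", pressure = "NN", visual = "JJ", acuity = "NN",
    cataract = "NN", surgery = "NN", optic = "JJ", disc = "NN",
    macular = "JJ", degeneration = "NN", dry = "JJ", eye = "NN",
    angle = "NN", closure = "NN", acute = "JJ", retinal = "JJ",
    detachment = "NN", fundus = "NN", examination = "NN",
    posterior = "JJ", vitreous = "JJ", glaucoma = "NN")
  structure(list(domain_terms = domain_terms,
                 nested_pairs = data.frame(
                   short = "angle closure", long = "acute angle closure",
                   stringsAsFactors = FALSE),
                 distractors = distractors,
                 word_tags = word_tags),
            class = "term_lexicon")
}

#' Generate a synthetic clinical-letter corpus with known ground truth
#'
#' Each domain term and distractor is planted in exactly its target number
#' of distinct documents (one templated sentence per planted document, the
#' receiving documents drawn at random); filler sentences pad every letter
#' to the configured length. The returned tag table covers every token the
#' corpus contains, so \code{lookup_tagger(tag_table)} tags it exactly.
#'
#' @param lex a \code{"term_lexicon"} (default \code{term_lexicon()}).
#' @param n_documents number of letters (default 100).
#' @param sentences_range min/max filler+planted sentences per letter.
#' @param seed RNG seed (seeded generation is deterministic).
#' @return list of class \code{"synthetic_corpus"}: \code{texts} (named
#'   character vector), \code{tag_table} (named tag vector for
#'   \code{\link{lookup_tagger}}), \code{placements} (data frame
#'   \code{term}, \code{doc_id}), \code{realized_df} (named counts).
#' @export
generate_corpus <- function(lex = NULL, n_documents = 100L,
                            sentences_range = c(5L, 8L), seed = 42L) {
  if (is.null(lex)) lex <- term_lexicon(n_documents)
  stopifnot(inherits(lex, "term_lexicon"), n_documents >= 1L)
  plan <- rbind(lex$domain_terms, lex$distractors)
  if (any(plan$df > n_documents))
    stop("infeasible lexicon: a target document frequency exceeds the ",
         "number of documents")
  set.seed(seed)
  doc_ids <- sprintf("doc%03d", seq_len(n_documents))
  planted <- stats::setNames(
    lapply(doc_ids, function(d) character()), doc_ids)
  placements <- list()
  for (i in seq_len(nrow(plan))) {
    term <- plan$term[i]
    docs <- sample(doc_ids, plan$df[i])
    for (d in docs) {
      tpl <- sample(.plant_templates, 1L)
      planted[[d]] <- c(planted[[d]], sprintf(tpl, term))
    }
    placements[[i]] <- data.frame(term = term, doc_id = docs,
                                  stringsAsFactors = FALSE)
  }
  texts <- vapply(doc_ids, function(d) {
    target <- sample(sentences_range[1]:sentences_range[2], 1L)
    sents <- planted[[d]]
    n_fill <- max(1L, target - length(sents))
    sents <- c(sents, sample(.filler_templates, n_fill, replace = TRUE))
    paste(sample(sents), collapse = " ")
  }, character(1))
  placements <- do.call(rbind, placements)
  tag_table <- c(lex$word_tags, .template_tags, .closed_class_tags)
  tag_table <- tag_table[!duplicated(names(tag_table))]
  toks <- unique(unlist(regmatches(texts, gregexpr(.token_pattern, texts))))
  toks <- tolower(toks[grepl("[a-z0-9]", tolower(toks))])
  missing <- setdiff(toks, names(tag_table))
  if (length(missing))
    stop("generator bug: untagged tokens ", paste(missing, collapse = ", "))
  structure(list(texts = texts, tag_table = tag_table,
                 placements = placements,
                 realized_df = table(placements$term)),
            class = "synthetic_corpus")
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat("<synthetic_corpus>", length(x$texts), "letters;",
      nrow(x$placements), "planted term occurrences\n")
  invisible(x)
}

#' Ground-truth bundle for a synthetic lexicon
#'
#' The dictionary holds every domain term (its vocabulary is derived from
#' their tokens); annotations label domain terms \code{"domain"} and
#' distractors \code{"non-domain"}.
#'
#' @param lex a \code{"term_lexicon"}.
#' @return list with \code{dictionary} (a \code{"medical_dictionary"}) and
#'   \code{annotations} (named label vector).
#' @export
generate_truth <- function(lex = term_lexicon()) {
  stopifnot(inherits(lex, "term_lexicon"))
  dictionary <- load_dictionary(lex$domain_terms$term)
  annotations <- stats::setNames(
    c(rep("domain", nrow(lex$domain_terms)),
      rep("non-domain", nrow(lex$distractors))),
    c(lex$domain_terms$term, lex$distractors$term))
  list(dictionary = dictionary, annotations = annotations)
}
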