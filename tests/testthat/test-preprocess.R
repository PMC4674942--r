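test_that("tokens are flagged valid unless they contain non-hyphen symbols", {
  d <- preprocess_document("The IOP was 18.", "d1")
  expect_length(d$sentences, 1)
  s <- d$sentences[[1]]
  expect_equal(s$lemma, c("the", "iop", "was", "18", "."))
  expect_true(s$valid[s$lemma == "18"])
  expect_false(s$valid[s$lemma == "."])

  d2 <- preprocess_document("dry-eye noted", "d2")
  s2 <- d2$sentences[[1]]
  expect_equal(s2$valid, c(TRUE, TRUE))   # hyphen is exempt

  d3 <- preprocess_document("cost was $5 (approx.)", "d3")
  s3 <- d3$sentences[[1]]
  expect_false(s3$valid[s3$surface == "$"])
})

test_that("empty input yields a document with zero sentences", {
  expect_length(preprocess_document("", "e")$sentences, 0)
  expect_length(preprocess_document("   \n  ", "e")$sentences, 0)
})

test_that("sentences split on sentence-final punctuation", {
  d <- preprocess_document("She was seen. Vision stable! Review soon?", "d")
  expect_length(d$sentences, 3)
  expect_equal(d$sentences[[2]]$lemma[1], "vision")
})

test_that("injected lemmatizer and tagger are honoured", {
  lem <- lookup_lemmatizer(c(eyes = "eye", lenses = "lens"))
  tag <- lookup_tagger(c(eye = "NN", lens = "NN", both = "DT"),
                       default = "VB")
  d <- preprocess_document("Both eyes", "d", lemmatizer = lem, tagger = tag)
  s <- d$sentences[[1]]
  expect_equal(s$lemma, c("both", "eye"))
  expect_equal(s$tag, c("DT", "NN"))
})

test_that("preprocessing the detokenised lemma stream is idempotent", {
  raw <- "The patient has severe dry eye. Review in twelve months."
  d1 <- preprocess_document(raw, "a")
  rebuilt <- paste(vapply(d1$sentences, function(s)
    paste(s$lemma, collapse = " "), character(1)), collapse = " ")
  d2 <- preprocess_document(rebuilt, "b")
  lem1 <- unlist(lapply(d1$sentences, `[[`, "lemma"))
  lem2 <- unlist(lapply(d2$sentences, `[[`, "lemma"))
  expect_equal(lem2, lem1)
})

test_that("chunking emits the maximal adjective-noun span and its sub-spans", {
  tags <- c(severe = "JJ", dry = "JJ", eye = "NN", syndrome = "NN",
            was = "VBD", noted = "VBD")
  corp <- make_tagged_corpus(c(d1 = "severe dry eye syndrome was noted"),
                             tags)
  cand <- chunk_candidates(corp[[1]])
  expect_true(all(c("severe dry eye syndrome", "dry eye syndrome",
                    "eye syndrome", "eye", "syndrome",
                    "severe dry eye", "dry eye") %in% cand$text))
  # no span may start with a noun then contain an adjective
  expect_false("eye severe" %in% cand$text)
})

test_that("runs without nouns produce no candidates", {
  tags <- c(quickly = "RB", went = "VBD")
  corp <- make_tagged_corpus(c(d1 = "went quickly"), tags)
  expect_equal(nrow(chunk_candidates(corp[[1]])), 0)
})

test_that("candidates are capped at four words", {
  tags <- c(a1 = "NN", a2 = "NN", a3 = "NN", a4 = "NN", a5 = "NN")
  corp <- make_tagged_corpus(c(d1 = "a1 a2 a3 a4 a5"), tags)
  cand <- chunk_candidates(corp[[1]])
  expect_true(all(cand$length <= 4))
  expect_false("a1 a2 a3 a4 a5" %in% cand$text)
  expect_true(all(c("a1 a2 a3 a4", "a2 a3 a4 a5") %in% cand$text))
})

test_that("spans containing an invalid token are discarded", {
  tags <- c(left = "JJ", eye = "NN", `eye%` = "NN")
  corp <- make_tagged_corpus(c(d1 = "left eye% eye"), tags)
  cand <- chunk_candidates(corp[[1]])
  expect_false(any(grepl("%", cand$text)))
  expect_true("eye" %in% cand$text)
})

test_that("every emitted candidate replays the adjective*(noun)+ pattern", {
  set.seed(11)
  vocab <- c(bright = "JJ", small = "JJ", lens = "NN", eye = "NN",
             retina = "NNS", sees = "VBZ", under = "IN", the = "DT")
  for (rep in 1:20) {
    words <- sample(names(vocab), 12, replace = TRUE)
    corp <- make_tagged_corpus(c(d = paste(words, collapse = " ")), vocab)
    cand <- chunk_candidates(corp[[1]])
    if (!nrow(cand)) next
    for (text in cand$text) {
      tags <- unname(vocab[strsplit(text, " ")[[1]]])
      expect_match(paste(ifelse(startsWith(tags, "JJ"), "A", "N"),
                         collapse = ""), "^A*N+$")
    }
    expect_true(all(cand$length <= 4))
  }
})

test_that("corpus readers accept directories and JSON-lines", {
  tmp <- withr::local_tempdir()
  writeLines("The left eye is fine.", file.path(tmp, "a.txt"))
  writeLines("Review soon.", file.path(tmp, "b.txt"))
  texts <- read_corpus(tmp)
  expect_named(texts, c("a", "b"))

  jl <- file.path(tmp, "corpus.jsonl")
  writeLines(c('{"doc_id":"x","text":"The left eye."}',
               '{"doc_id":"y","text":"Review."}'), jl)
  texts2 <- read_corpus(jl)
  expect_named(texts2, c("x", "y"))
  expect_error(read_corpus(file.path(tmp, "nope.jsonl")), "does not exist")
})
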