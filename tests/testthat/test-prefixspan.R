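test_that("sequence length counts item instances across elements", {
  expect_equal(sequence_length(parse_sequence("a b (a d c)")), 5)
  expect_equal(sequence_length(list()), 0)
  expect_equal(sequence_length(parse_sequence("(x y)")), 2)
})

test_that("subsequence relation matches the definition, with and without gaps", {
  expect_true(is_subsequence(parse_sequence("a b"),
                             parse_sequence("c d a b c d")))
  expect_true(is_subsequence(list(), parse_sequence("a b")))
  s <- parse_sequence("a (a b) c")
  expect_true(is_subsequence(parse_sequence("a c"), s))
  expect_false(is_subsequence(parse_sequence("a c"), s, contiguous = TRUE))
  expect_true(is_subsequence(parse_sequence("(a b) c"), s,
                             contiguous = TRUE))
  expect_false(is_subsequence(parse_sequence("b a"), parse_sequence("a b")))
})

test_that("postfixes of <a (a b) c> reproduce the worked prefixes", {
  s <- parse_sequence("a (a b) c")
  expect_equal(format_sequence(postfix_sequence(s, parse_sequence("a"))),
               "(a b) c")
  expect_equal(format_sequence(postfix_sequence(s, parse_sequence("a b"))),
               "c")
  expect_equal(format_sequence(postfix_sequence(s, parse_sequence("a a"))),
               "(_b) c")
  expect_null(postfix_sequence(s, parse_sequence("d")))
})

test_that("project_database keeps one postfix per containing sequence", {
  db <- as_sequence_database(c("a (a b) c", "d e", "a c"))
  proj <- project_database(db, "a")
  expect_length(proj$postfixes, 2)
  expect_equal(proj$postfixes[[1]]$seq_id, "s1")
  expect_equal(format_sequence(proj$postfixes[[1]]$postfix), "(a b) c")
  expect_equal(format_sequence(proj$postfixes[[2]]$postfix), "c")
})

test_that("frequent word pairs are mined with correct support", {
  db <- as_sequence_database(c("the visual acuity", "visual acuity good",
                               "visual acuity"))
  got <- mine_frequent_patterns(db, 2, contiguous = TRUE)
  row <- got[got$pattern == "visual acuity", ]
  expect_equal(row$support, 3)
  reord <- order(-got$support, got$pattern)
  expect_equal(reord, seq_len(nrow(got)))   # deterministic output order
  # a threshold above the database size mines nothing
  expect_equal(nrow(mine_frequent_patterns(db, 4)), 0)
  empty <- as_sequence_database(list())
  expect_equal(nrow(mine_frequent_patterns(empty, 1)), 0)
})

test_that("strict support semantics excludes patterns at the threshold", {
  db <- as_sequence_database(c("a b", "a b", "a c"))
  lax <- mine_frequent_patterns(db, 2)
  strictly <- mine_frequent_patterns(db, 2, strict = TRUE)
  expect_true("a b" %in% lax$pattern)        # support 2 >= 2
  expect_false("a b" %in% strictly$pattern)  # support 2 is not > 2
  expect_true("a" %in% strictly$pattern)     # support 3 > 2
})

test_that("fractional support thresholds resolve against the chosen basis", {
  db <- as_sequence_database(c("a", "b", "c"),
                             source_docs = c("d1", "d1", "d2"))
  expect_equal(resolve_min_sup(0.001, db), 1)
  expect_equal(resolve_min_sup(0.5, db, basis = "sequences"), 2)
  expect_equal(resolve_min_sup(0.5, db, basis = "documents"), 1)
  expect_equal(resolve_min_sup(30, db), 30)
})

test_that("gapped mining equals the brute-force enumeration oracle", {
  for (seed in 1:40) {
    set.seed(seed)
    db <- random_seqdb(n_seq = sample(2:8, 1), max_items = 6)
    min_sup <- sample(2:3, 1)
    got <- mine_frequent_patterns(db, min_sup, basis = "sequences")
    want <- brute_force_patterns(db, min_sup)
    expect_equal(got, want, info = paste("seed", seed))
  }
})

test_that("anti-monotonicity holds: prefixes are frequent with >= support", {
  set.seed(99)
  db <- random_seqdb(n_seq = 8, max_items = 6)
  got <- mine_frequent_patterns(db, 2, basis = "sequences")
  sup <- stats::setNames(got$support, got$pattern)
  for (pat in got$pattern) {
    elems <- parse_sequence(gsub("_", "", pat))
    if (length(elems) < 2) next
    prefix_txt <- format_sequence(elems[-length(elems)])
    expect_true(prefix_txt %in% got$pattern)
    expect_gte(sup[[prefix_txt]], sup[[pat]])
  }
  expect_true(all(got$support <= length(db$records)))
})

test_that("contiguous text-mode mining coincides with direct n-gram counts", {
  for (seed in 1:10) {
    set.seed(seed)
    db <- random_textdb(n_seq = 6, max_words = 6)
    got <- mine_frequent_patterns(db, 2, contiguous = TRUE, max_length = 4,
                                  basis = "sequences")
    want <- ngram_counter(db, 2, max_length = 4)
    expect_equal(got[, c("pattern", "support")], want,
                 info = paste("seed", seed))
  }
})

test_that("corpus sequences are sentence-level lemma runs of valid tokens", {
  corp <- preprocess_corpus(c(d1 = "Left eye fine. See soon!",
                              d2 = "Left eye."))
  db <- corpus_sequence_database(corp)
  expect_equal(length(db$records), 3)
  expect_equal(db$n_documents, 2)
  expect_equal(vapply(db$records[[1]]$elements, `[`, character(1), 1),
               c("left", "eye", "fine"))
})

test_that("ranking preset orders by support with lexicographic ties", {
  corp <- preprocess_corpus(c(d1 = "visual acuity stable.",
                              d2 = "visual acuity stable.",
                              d3 = "cataract surgery done."))
  r <- prefixspan_ranking(corp, min_sup = 2)
  expect_true(all(diff(r$score) <= 0))
  expect_true(all(c("visual", "acuity", "visual acuity") %in% r$term))
  expect_false("cataract" %in% r$term)
})
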