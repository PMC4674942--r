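test_that("frequency table and nesting index count what the formula needs", {
  occ <- c(rep("left eye", 3), rep("eye", 5))
  st <- build_frequency_and_nesting(occ)
  expect_equal(st$freq[["eye"]], 5)
  expect_equal(st$freq[["left eye"]], 3)
  expect_equal(st$nested[["eye"]], "left eye")
  expect_equal(st$nested[["left eye"]], character(0))

  st2 <- build_frequency_and_nesting(c("angle closure",
                                       "acute angle closure"))
  expect_true("acute angle closure" %in% st2$nested[["angle closure"]])

  st3 <- build_frequency_and_nesting("glaucoma")
  expect_equal(st3$nested[["glaucoma"]], character(0))
})

test_that("nesting is contiguous word-level containment only", {
  st <- build_frequency_and_nesting(c("eye", "eyelid margin", "dry left eye"))
  expect_equal(st$nested[["eye"]], "dry left eye")  # not "eyelid margin"
})

test_that("C-Value matches the closed forms and the worked nested example", {
  st <- list(freq = c(t = 8), nested = list(t = character()))
  names(st$freq) <- "left eye"; names(st$nested) <- "left eye"
  expect_equal(compute_cvalue("left eye", st), 8)  # log2(2) * 8

  st2 <- list(freq = c("angle closure" = 50, "b one two" = 10,
                       "c other x" = 4),
              nested = list("angle closure" = c("b one two", "c other x")))
  expect_equal(compute_cvalue("angle closure", st2), 43)  # 1*(50 - 14/2)

  # unnested multi-word closed form log2|a| * f(a)
  st3 <- list(freq = c("a b c" = 5), nested = list("a b c" = character()))
  expect_equal(compute_cvalue("a b c", st3), log2(3) * 5)

  expect_error(compute_cvalue("missing", st3), "not present")
})

test_that("unigram handling follows the selected mode", {
  st <- list(freq = c(eye = 7), nested = list(eye = character()))
  expect_equal(compute_cvalue("eye", st, unigram_mode = "as_printed"), 0)
  expect_equal(compute_cvalue("eye", st, unigram_mode = "plus_one"), 7)
  # unigrams never receive the nesting subtraction in either mode
  st2 <- list(freq = c(eye = 7, "left eye" = 3),
              nested = list(eye = "left eye", "left eye" = character()))
  expect_equal(compute_cvalue("eye", st2, unigram_mode = "plus_one"), 7)
})

test_that("C-Value is non-negative and monotone in frequency", {
  set.seed(5)
  for (rep in 1:50) {
    f_long <- sample(1:10, 2)
    f_a <- max(f_long) + sample(0:10, 1)  # superstring occurrences <= f(a)
    st <- list(freq = c("x y" = f_a, "w x y" = f_long[1], "x y z" = f_long[2]),
               nested = list("x y" = c("w x y", "x y z")))
    cv <- compute_cvalue("x y", st)
    expect_gte(cv, 0)
    st$freq[["x y"]] <- f_a + 1
    expect_gte(compute_cvalue("x y", st), cv)
  }
})

test_that("ranking is deterministic: score descending, text ascending", {
  tags <- c(intraocular = "JJ", pressure = "NN", dry = "JJ", eye = "NN",
            noted = "VBD", again = "RB", was = "VBD", fine = "JJ")
  corp <- make_tagged_corpus(
    c(d1 = "intraocular pressure noted. intraocular pressure again.",
      d2 = "intraocular pressure noted. dry eye noted.",
      d3 = "dry eye again."),
    tags)
  r <- cvalue_ranking(corp)
  expect_equal(r$term[1], "intraocular pressure")
  expect_true(all(diff(r$score) <= 0))
  ties <- r$term[r$score == r$score[which.max(duplicated(r$score))]]
  expect_equal(ties, sort(ties))
})

test_that("a term always nested in an equal-frequency superset scores zero", {
  occ <- c(rep("acute angle closure", 4))  # chunker also emits sub-spans
  occ <- c(occ, rep("angle closure", 4), rep("closure", 4), rep("angle", 4),
           rep("acute angle", 4))
  st <- build_frequency_and_nesting(occ)
  expect_equal(compute_cvalue("angle closure", st), 0)
  r <- cvalue_ranking(data.frame(text = occ,
                                 length = lengths(strsplit(occ, " ")),
                                 stringsAsFactors = FALSE))
  expect_equal(r$score[r$term == "angle closure"], 0)
})
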