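test_that("the single-exchange echo yields proportion 4/5", {
  t <- parse_transcript(
    "E And the moon was coming up.\nC The moon was coming up then.", 1
  )
  expect_identical(compute_repetition_proportion(t), 0.8)
  sp <- match_spans(c("and", "the", "moon", "was", "coming", "up"),
                    c("the", "moon", "was", "coming", "up", "then"))
  expect_equal(nrow(sp), 1L)
  expect_equal(sp$matched_child_words, 4L)
  expect_equal(sp$child_start, 2L)  # "the" is deletable, not matched
  expect_equal(sp$child_end, 5L)
})

test_that("substitution and deletion rules apply on either side", {
  sp <- match_spans(c("i", "like", "the", "dog"), c("you", "like", "dog"))
  expect_equal(matched_total(sp), 3L)
  # substitution symmetry: swapping within a group leaves the count unchanged
  sp2 <- match_spans(c("i", "like", "the", "dog"), c("we", "like", "dog"))
  expect_equal(matched_total(sp2), 3L)
  # no 2-word run -> no spans
  expect_equal(nrow(match_spans(c("what", "do", "you", "like"),
                                c("i", "hate", "school"))), 0L)
  # a span cannot be built from deletable words alone
  expect_equal(nrow(match_spans(c("the", "a", "is"), c("the", "a", "is"))), 0L)
})

test_that("spans are non-overlapping and the selection maximizes matched words", {
  # two separate echoes of one examiner turn
  sp <- match_spans(
    c("we", "went", "home", "and", "played", "ball"),
    c("went", "home", "dog", "played", "ball")
  )
  expect_equal(matched_total(sp), 4L)
  expect_equal(nrow(sp), 2L)
  ord <- order(sp$child_start)
  expect_true(all(sp$child_end[ord][-nrow(sp)] < sp$child_start[ord][-1]))
})

test_that("repetition proportion handles missing examiner context and isolated words", {
  t <- parse_transcript("C The moon was coming up.", 1)
  expect_equal(compute_repetition_proportion(t), 0)
  t2 <- parse_transcript("E The moon was up.\nC Moon.\nC Up.", 1)
  expect_equal(compute_repetition_proportion(t2), 0)
  expect_error(compute_repetition_proportion(parse_transcript("E Hi there.", 1)),
               "no child words")
  # full echo -> proportion 1
  t3 <- parse_transcript("E My dog came home.\nC My dog came home.", 1)
  expect_equal(compute_repetition_proportion(t3), 1)
})

test_that("only the immediately previous examiner turn is matched", {
  t <- parse_transcript(c(
    "E The moon was coming up.",
    "E What did you see.",
    "C The moon was coming up."   # echoes the first turn, not the previous
  ), duration_min = 1)
  # consecutive examiner c-units form one turn, so the echo IS in the
  # previous turn here
  expect_gt(compute_repetition_proportion(t), 0)
  t2 <- parse_transcript(c(
    "E The moon was coming up.",
    "C I saw stuff.",
    "E What did you see.",
    "C The moon was coming up."
  ), duration_min = 1)
  expect_equal(compute_repetition_proportion(t2), 0)
})

test_that("appending an unmatched word never increases the matched count", {
  set.seed(404)
  for (i in 1:25) {
    ex <- random_turn()
    ch <- random_turn()
    base <- matched_total(match_spans(ex, ch))
    more <- matched_total(match_spans(ex, c(ch, "zzz")))
    expect_lte(more - base, 0L)
  }
})

test_that("matcher agrees with the brute-force oracle on random turns", {
  set.seed(707)
  for (i in 1:60) {
    ex <- random_turn()
    ch <- random_turn()
    expect_identical(matched_total(match_spans(ex, ch)),
                     brute_force_repetition_oracle(ex, ch),
                     info = paste(c("ex:", ex, "| ch:", ch), collapse = " "))
  }
})

test_that("oracle guards its combinatorial domain", {
  expect_error(
    brute_force_repetition_oracle(rep("a", 11), c("b", "c")),
    "at most 10"
  )
  expect_identical(
    brute_force_repetition_oracle(rep("dog", 6), rep("dog", 6)), 6L
  )
})

test_that("maze and unintelligible child words are excluded from matching", {
  t <- parse_transcript(
    "E The moon was coming up.\nC (moon was) Moon was coming X.", 1
  )
  # out-of-maze eligible words: moon was coming (X excluded) -> 3 matched / 3
  expect_equal(compute_repetition_proportion(t), 1)
})
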