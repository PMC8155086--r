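test_that("parser handles mazes, morphemes, and intelligibility marks", {
  t <- parse_transcript("C And (um) I like dog/s.", duration_min = 1)
  cu <- t$cunits[[1]]
  expect_equal(cu$speaker, "child")
  expect_length(cu$mazes, 1L)
  expect_equal(cu$mazes[[1]]$kind, "filler_only")
  expect_equal(sum(cu$tokens$n_morphemes), 5L)  # and, i, like, dog+PL
  expect_false(cu$is_fluent)
  expect_true(cu$is_complete)

  t2 <- parse_transcript("C (My mom) My dad picked me up.", duration_min = 1)
  m <- t2$cunits[[1]]$mazes[[1]]
  expect_equal(m$kind, "content")
  expect_equal(sum(!m$tokens$is_filler), 2L)

  t3 <- parse_transcript("C I went to the X.", duration_min = 1)
  expect_false(t3$cunits[[1]]$is_intelligible)
  expect_true(t3$cunits[[1]]$tokens$is_unintelligible[5])

  t4 <- parse_transcript("C I was going to say >", duration_min = 1)
  expect_false(t4$cunits[[1]]$is_complete)
})

test_that("bound-morpheme markers produce roots and morpheme counts", {
  t <- parse_transcript("C He/'s walk/ed dog/s go/ing.", duration_min = 1)
  tok <- t$cunits[[1]]$tokens
  expect_equal(tok$surface, c("he's", "walked", "dogs", "going"))
  expect_equal(tok$root, c("he", "walk", "dog", "go"))
  expect_equal(tok$n_morphemes, c(2L, 2L, 2L, 2L))
  expect_false(any(grepl("/", tok$root, fixed = TRUE)))
})

test_that("multiword fillers are merged as units inside mazes", {
  t <- parse_transcript("C (you know um I mean) It fun.", duration_min = 1)
  m <- t$cunits[[1]]$mazes[[1]]
  expect_equal(m$tokens$surface, c("you know", "um", "i mean"))
  expect_true(all(m$tokens$is_filler))
  expect_equal(m$kind, "filler_only")
  # out-of-maze words are not merged
  t2 <- parse_transcript("C You know him.", duration_min = 1)
  expect_equal(t2$cunits[[1]]$tokens$surface, c("you", "know", "him"))
})

test_that("maze token classification matches the closed filler lexicon", {
  for (w in setdiff(filler_lexicon(), c("you know", "i mean"))) {
    t <- parse_transcript(sprintf("C (%s) It fun.", w), duration_min = 1)
    expect_equal(t$cunits[[1]]$mazes[[1]]$kind, "filler_only")
  }
  t <- parse_transcript("C (banana) It fun.", duration_min = 1)
  expect_equal(t$cunits[[1]]$mazes[[1]]$kind, "content")
})

test_that("parse errors name the offending construct", {
  expect_error(parse_transcript("C I went (um home.", 1), "unclosed maze")
  expect_error(parse_transcript("Q Hello there.", 1), "unknown speaker")
  expect_error(parse_transcript("C Hello there.", 0), "duration_min")
  expect_error(parse_transcript("C Hello there."), "duration_min")
  expect_error(parse_transcript("", 1), "empty")
})

test_that("headers supply metadata and arguments override them", {
  txt <- c("+ participant_id: P07", "+ duration_min: 6.27", "C It fun.")
  t <- parse_transcript(txt)
  expect_equal(t$participant_id, "P07")
  expect_equal(t$duration_min, 6.27)
  t2 <- parse_transcript(txt, duration_min = 2)
  expect_equal(t2$duration_min, 2)
})

test_that("write/parse round trip is the identity on structure", {
  t <- parse_transcript(fixture_text())
  t2 <- parse_transcript(write_transcript(t))
  expect_identical(unclass(t), unclass(t2))

  # generator-produced transcripts round trip too
  spec <- cohort_spec(list(g = group_params(
    n = 4, mean_cunits = 15, unintell_prob = 0.1, echo_prob = 0.2,
    maze_rate = 0.6
  )), seed = 31)
  for (p in generate_cohort(spec)) {
    back <- parse_transcript(write_transcript(p$transcript))
    expect_identical(unclass(p$transcript), unclass(back))
  }

  # empty transcript -> header-only document
  empty <- parse_transcript(write_transcript(
    structure(list(participant_id = "E0", cunits = list(), duration_min = 1),
              class = "salt_transcript")
  ))
  expect_length(empty$cunits, 0L)
})

test_that("c-unit flags are consistent with their definitions", {
  spec <- cohort_spec(list(g = group_params(
    n = 3, mean_cunits = 20, unintell_prob = 0.15, maze_rate = 0.5
  )), seed = 13)
  for (p in generate_cohort(spec)) {
    for (cu in p$transcript$cunits) {
      expect_identical(cu$is_fluent, length(cu$mazes) == 0L)
      any_x <- any(cu$tokens$is_unintelligible) ||
        any(vapply(cu$mazes, function(m) any(m$tokens$is_unintelligible),
                   logical(1)))
      expect_identical(cu$is_intelligible, !any_x)
      expect_true(all(cu$tokens$n_morphemes >= 1L))
      expect_false(any(cu$tokens$is_unintelligible & cu$tokens$is_filler))
    }
  }
})

test_that("validate_transcript reports machine-readable diagnostics", {
  d1 <- validate_transcript(parse_transcript("C Hello there.", 1))
  expect_true("um_proportion_undefined" %in% d1$code)

  d2 <- validate_transcript(parse_transcript("E What do you like.", 1))
  expect_equal(d2$code, "no_child_speech")

  d3 <- validate_transcript(
    parse_transcript("C (um) I like dog/s.\nC It fun.", 1)
  )
  expect_equal(nrow(d3), 0L)

  d4 <- validate_transcript(parse_transcript("C (um) I like X.", 1))
  expect_true("no_eligible_cunits" %in% d4$code)
})

test_that("JSON export reproduces the parsed structure", {
  t <- parse_transcript(fixture_text())
  js <- jsonlite::fromJSON(transcript_to_json(t), simplifyDataFrame = FALSE)
  expect_equal(js$participant_id, "FIX01")
  expect_equal(length(js$cunits), length(t$cunits))
  expect_equal(js$cunits[[2]]$tokens[[1]]$surface, "i")
})
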