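test_that("eligibility requires complete, fluent, intelligible child c-units", {
  t <- parse_transcript(c(
    "C (um) I like dog/s.",   # maze -> not fluent
    "C I went to X.",          # unintelligible
    "C I was going >",         # abandoned
    "E That sounds fun.",      # examiner
    "C It fun."                # eligible
  ), duration_min = 1)
  el <- eligible_cunits(t)
  expect_length(el, 1L)
  expect_equal(el[[1]]$tokens$surface, c("it", "fun"))
})

test_that("MLUM averages morphemes over eligible c-units", {
  t <- parse_transcript("C He walk/ed home.\nC Dog/s bark.", 1)
  expect_equal(compute_mlum(t), 3.5)
  expect_true(is.na(compute_mlum(parse_transcript("C (um) X.", 1))))
})

test_that("NDWR counts distinct roots without lemmatization", {
  t <- parse_transcript("C Dog/s dog run/ing.", 1)
  expect_equal(compute_ndwr(t), 2L)
  t2 <- parse_transcript("C He ran.\nC He run/ing.", 1)
  expect_equal(compute_ndwr(t2), 3L)  # he, ran, run: no lemmatizer
  expect_true(is.na(compute_ndwr(parse_transcript("C I went to X.", 1))))
})

test_that("um proportion counts filled pauses anywhere in child speech", {
  t <- parse_transcript("C (um um) I um said.\nC (uh) Stop.", 1)
  expect_equal(compute_um_proportion(t), 0.75)
  expect_true(is.na(compute_um_proportion(parse_transcript("C It fun.", 1))))
  t0 <- parse_transcript("C (uh) One.\nC (uh uh uh) Two.", 1)
  expect_equal(compute_um_proportion(t0), 0)
  # examiner um does not count
  t3 <- parse_transcript("E (um) Right.\nC (uh) Go.", 1)
  expect_equal(compute_um_proportion(t3), 0)
})

test_that("content maze proportion uses content mazes over mazes + fillers", {
  t <- parse_transcript(c(
    "C (My mom) My dad came.",
    "C (uh) I left.",
    "C (um) We stay/ed."
  ), duration_min = 1)
  expect_equal(compute_content_maze_proportion(t), 1 / 3)
  expect_equal(
    compute_content_maze_proportion(parse_transcript("C (uh) Go.", 1)), 0
  )
  expect_true(is.na(
    compute_content_maze_proportion(parse_transcript("C It fun.", 1))
  ))
  # fillers inside a content maze do not enter the denominator
  t2 <- parse_transcript("C (um my mom) My dad came.\nC (uh) Go.", 1)
  expect_equal(compute_content_maze_proportion(t2), 1 / 2)
})

test_that("unintelligible proportion and CPM follow the counting rules", {
  lines <- c(sprintf("C Word number%d.", 1:8), "C I saw X.", "C XX >")
  t <- parse_transcript(lines, duration_min = 2)
  expect_equal(compute_unintelligible_proportion(t), 0.2)
  expect_equal(compute_cpm(t), 5)
  t2 <- parse_transcript(c("C One.", rep("C Two.", 29)), duration_min = 5)
  expect_equal(compute_cpm(t2), 6)
  expect_error(
    compute_unintelligible_proportion(parse_transcript("E Hi.", 1)),
    "no child c-units"
  )
})

test_that("the hand-tallied fixture reproduces all frozen measure values", {
  p <- compute_profile(parse_transcript(fixture_text()))
  for (nm in names(fixture_expected)) {
    expect_equal(p[[nm]], fixture_expected[[nm]], tolerance = 0, info = nm)
  }
})

test_that("profile equals the individual measure functions", {
  spec <- cohort_spec(list(g = group_params(
    n = 4, mean_cunits = 25, unintell_prob = 0.08, echo_prob = 0.15
  )), seed = 21)
  for (p in generate_cohort(spec)) {
    t <- p$transcript
    pr <- compute_profile(t)
    expect_equal(pr$mlum, compute_mlum(t))
    expect_equal(pr$ndwr, compute_ndwr(t))
    expect_equal(pr$um_prop, compute_um_proportion(t))
    expect_equal(pr$content_maze_prop, compute_content_maze_proportion(t))
    expect_equal(pr$unintell_prop, compute_unintelligible_proportion(t))
    expect_equal(pr$cpm, compute_cpm(t))
    expect_equal(pr$repetition_prop, compute_repetition_proportion(t))
    def <- unlist(unclass(pr))
    def <- def[!is.na(def)]
    props <- intersect(names(def), c("um_prop", "content_maze_prop",
                                     "unintell_prop", "repetition_prop"))
    expect_true(all(def[props] >= 0 & def[props] <= 1))
  }
  expect_error(compute_profile(parse_transcript("E Only examiner.", 1)),
               "no child c-units")
})

test_that("adding a filler-only maze leaves MLUM/NDWR unchanged and cannot raise content maze proportion", {
  base <- c("C He walk/ed home.", "C (My mom) My dad came.", "C (uh) Go.")
  t0 <- parse_transcript(base, duration_min = 1)
  t1 <- parse_transcript(c(base, "C (um) Dog/s bark."), duration_min = 1)
  # the new c-unit is not eligible (maze), so MLUM/NDWR keep their values
  expect_equal(compute_mlum(t1), compute_mlum(t0))
  expect_equal(compute_ndwr(t1), compute_ndwr(t0))
  expect_lte(compute_content_maze_proportion(t1),
             compute_content_maze_proportion(t0))
})

test_that("NDWR is invariant under duplicating an eligible c-unit; MLUM under duplicating all", {
  lines <- c("C He walk/ed home.", "C Dog/s bark.", "C It fun.")
  t0 <- parse_transcript(lines, duration_min = 1)
  t_dup_one <- parse_transcript(c(lines, lines[2]), duration_min = 1)
  expect_equal(compute_ndwr(t_dup_one), compute_ndwr(t0))
  t_dup_all <- parse_transcript(c(lines, lines), duration_min = 1)
  expect_equal(compute_mlum(t_dup_all), compute_mlum(t0))
})
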