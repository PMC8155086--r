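# Examiner question templates for the conversational task. The child
# vocabulary pool below is deliberately disjoint from every template word,
# from the substitutable pronoun groups, and from the deletable function
# words, so that without explicit echo injection no child turn can contain a
# two-word contiguous match to examiner speech: with echo probability zero,
# repetition proportion is exactly zero by construction.
.examiner_templates <- list(
  c("what", "do", "you", "like", "to", "do", "with", "your", "friends"),
  c("tell", "me", "about", "your", "best", "friend"),
  c("why", "is", "having", "friends", "important", "to", "you"),
  c("how", "did", "you", "meet", "your", "best", "friend"),
  c("would", "you", "want", "to", "get", "married", "someday"),
  c("what", "makes", "somebody", "a", "good", "friend"),
  c("who", "do", "you", "spend", "time", "with", "at", "recess"),
  c("what", "do", "people", "your", "age", "worry", "about"),
  c("do", "you", "think", "friendships", "change", "as", "people", "grow"),
  c("what", "would", "you", "do", "if", "a", "friend", "moved", "away"),
  c("how", "can", "you", "tell", "somebody", "is", "your", "friend"),
  c("is", "it", "easy", "or", "hard", "for", "you", "to", "make", "friends")
)

.child_vocab <- c(
  "dog", "cat", "school", "game", "ball", "house", "mom", "dad", "brother",
  "sister", "teacher", "park", "movie", "book", "bike", "pizza", "lunch",
  "soccer", "football", "basketball", "computer", "phone", "music", "song",
  "class", "homework", "weekend", "summer", "winter", "snow", "rain", "beach",
  "pool", "water", "tree", "yard", "street", "store", "toy", "card", "team",
  "coach", "player", "level", "robot", "dragon", "monster", "castle", "planet",
  "rocket", "space", "star", "moon", "car", "truck", "train", "plane", "boat",
  "fish", "bird", "horse", "rabbit", "turtle", "snake", "lizard", "bug",
  "spider", "grass", "flower", "garden", "kitchen", "bedroom", "basement",
  "garage", "window", "door", "table", "chair", "couch", "television",
  "picture", "color", "paper", "pencil", "marker", "paint", "craft", "puzzle",
  "block", "piece", "candy", "cookie", "cake", "sandwich", "apple", "banana",
  "grape", "juice", "milk", "cereal", "dinner", "breakfast", "snack", "play",
  "run", "jump", "climb", "swim", "ride", "build", "draw", "read", "watch",
  "listen", "sing", "dance", "laugh", "talk", "walk", "sleep", "eat", "drink",
  "win", "lose", "catch", "throw", "kick", "hit", "race", "chase", "hide",
  "seek", "pretend", "imagine", "remember", "forget", "learn", "teach",
  "help", "share", "trade", "collect", "count", "pick", "find", "look",
  "stay", "visit", "travel", "camp", "fun", "funny", "cool", "awesome",
  "big", "small", "fast", "slow", "loud", "quiet", "happy", "sad", "mad",
  "scared", "brave", "silly", "smart", "kind", "nice", "gentle", "tall",
  "short", "young", "old", "red", "blue", "green", "yellow", "purple",
  "orange", "black", "white", "brown", "pink", "together", "outside",
  "inside", "upstairs", "downstairs", "yesterday", "today", "tomorrow",
  "always", "never", "sometimes", "usually", "maybe", "really", "very",
  "pretty", "super", "favorite", "special", "different", "another", "every",
  "lots", "many", "most", "some", "few", "also", "again", "later", "soon",
  "early", "late", "morning", "night", "afternoon", "minute", "hour", "day",
  "week", "month", "year", "birthday", "party", "present", "surprise",
  "holiday", "vacation", "trip", "adventure"
)

check_prob <- function(x, nm) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("%s must be a probability in [0, 1]", nm), call. = FALSE)
  }
  x
}

#' Generative parameters for one synthetic group
#'
#' @param n Number of participants.
#' @param mean_words Mean child utterance length in words (utterance lengths
#'   are 1 + negative-binomial, allowing overdispersion).
#' @param morph_rate Probability a child word carries a slash-marked bound
#'   morpheme (`/s`, `/ed`, `/ing`), so expected morphemes per word is
#'   `1 + morph_rate`.
#' @param vocab_size Size of the child's Zipf-weighted vocabulary pool
#'   (capped at the built-in pool size).
#' @param maze_rate Probability a child c-unit begins with a maze.
#' @param content_maze_prob Probability a maze is a content maze (contains
#'   non-filler words) rather than a filler-only maze.
#' @param um_pref Probability that a filled pause is "um" rather than "uh".
#' @param filler_um_uh_prob Probability a filler-maze token is a filled
#'   pause (um/uh) rather than another lexicon filler.
#' @param unintell_prob Probability a child c-unit contains an
#'   unintelligible word.
#' @param echo_prob Probability a child c-unit opens by echoing a window of
#'   the examiner's previous turn.
#' @param echo_len Integer range (min, max) of the echoed window length.
#' @param cpm Mean child speech rate in attempted c-units per minute; each
#'   participant draws an individual rate from a gamma distribution with
#'   this mean and coefficient of variation `cpm_cv`, and the task duration
#'   is the c-unit count divided by that rate.
#' @param cpm_cv Coefficient of variation of the per-participant speech
#'   rate (0 makes every participant's rate exactly `cpm`).
#' @param mean_cunits Mean number of child c-units per transcript.
#' @param incomplete_rate Probability a child c-unit is abandoned.
#' @param age_range Age range (years) for uniform sampling.
#' @param iq_mean,iq_sd Normal IQ distribution (truncated at 70).
#' @param male_prob Probability of male sex.
#' @return A named list of class `alm_group_params`.
#' @export
group_params <- function(n = 30, mean_words = 5.1, morph_rate = 0.3,
                         vocab_size = 320, maze_rate = 0.35,
                         content_maze_prob = 0.40, um_pref = 0.70,
                         filler_um_uh_prob = 0.85, unintell_prob = 0.009,
                         echo_prob = 0.05, echo_len = c(2L, 5L), cpm = 13.5,
                         cpm_cv = 0.2,
                         mean_cunits = 80, incomplete_rate = 0.03,
                         age_range = c(7, 17), iq_mean = 112, iq_sd = 13,
                         male_prob = 0.6) {
  stopifnot(n >= 1, mean_words > 1, vocab_size >= 10, cpm > 0, cpm_cv >= 0,
            mean_cunits >= 5, echo_len[1] >= 2, echo_len[2] >= echo_len[1])
  for (nm in c("morph_rate", "maze_rate", "content_maze_prob", "um_pref",
               "filler_um_uh_prob", "unintell_prob", "echo_prob",
               "incomplete_rate", "male_prob")) {
    check_prob(get(nm), nm)
  }
  structure(as.list(environment())[c(
    "n", "mean_words", "morph_rate", "vocab_size", "maze_rate",
    "content_maze_prob", "um_pref", "filler_um_uh_prob", "unintell_prob",
    "echo_prob", "echo_len", "cpm", "cpm_cv", "mean_cunits", "incomplete_rate",
    "age_range", "iq_mean", "iq_sd", "male_prob"
  )], class = "alm_group_params")
}

#' Specification of a synthetic cohort
#'
#' Bundles per-group generative parameters and a random seed. The default
#' two-group specification plants effects in the direction reported for
#' ASD versus non-ASD conversation samples: shorter utterances, a smaller
#' vocabulary pool, more (and more often content-bearing) mazes, a
#' preference for "uh" over "um", more unintelligible c-units, a slower
#' c-unit rate, and more echoing of the examiner.
#'
#' @param groups Named list of [group_params()] objects; default is the
#'   planted two-group (`asd`, `nonasd`) design.
#' @param seed Integer random seed; generation is deterministic given the
#'   spec.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(groups = NULL, seed = 20210526) {
  if (is.null(groups)) {
    groups <- list(
      asd = group_params(
        n = 50, mean_words = 4.5, vocab_size = 260, maze_rate = 0.45,
        content_maze_prob = 0.65, um_pref = 0.45, unintell_prob = 0.026,
        echo_prob = 0.10, cpm = 11.2, mean_cunits = 73,
        iq_mean = 99, iq_sd = 19, male_prob = 0.83
      ),
      nonasd = group_params(n = 50)
    )
  }
  stopifnot(length(groups) >= 1, !is.null(names(groups)),
            all(nzchar(names(groups))))
  for (g in groups) {
    if (!inherits(g, "alm_group_params")) {
      stop("every group must be built with group_params()", call. = FALSE)
    }
  }
  structure(list(groups = groups, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Two-group null cohort specification
#'
#' Both groups share identical generative parameters, for type-I-error and
#' calibration studies. `mean_cunits` defaults to a smaller transcript size
#' than the planted design since null calibration does not depend on
#' transcript length.
#'
#' @param n_per_group Participants per group.
#' @param seed Random seed.
#' @param mean_cunits Mean child c-units per transcript.
#' @param ... Further arguments passed to [group_params()] for both groups.
#' @return A `cohort_spec`.
#' @export
null_cohort_spec <- function(n_per_group = 30, seed = 1, mean_cunits = 30, ...) {
  p <- group_params(n = n_per_group, mean_cunits = mean_cunits, ...)
  cohort_spec(groups = list(g1 = p, g2 = p), seed = seed)
}

make_word_tokens <- function(bases, suffixed, suffixes) {
  surface <- ifelse(suffixed, paste0(bases, suffixes), bases)
  raw <- ifelse(suffixed, paste0(bases, "/", suffixes), bases)
  new_tokens(
    surface = surface, root = bases, n_morphemes = 1L + suffixed,
    is_filler = surface %in% .filler_lex,
    is_unintelligible = rep(FALSE, length(bases)), raw = raw
  )
}

make_plain_tokens <- function(words) {
  new_tokens(
    surface = words, root = words,
    n_morphemes = rep(1L, length(words)),
    is_filler = words %in% .filler_lex,
    is_unintelligible = words %in% c("X", "XX"),
    raw = words
  )
}

.unint_token <- function() {
  new_tokens("X", "X", 1L, FALSE, TRUE, "X")
}

sample_filler_maze <- function(p) {
  k <- if (runif(1) < 0.3) 2L else 1L
  words <- character(k)
  for (i in seq_len(k)) {
    if (runif(1) < p$filler_um_uh_prob) {
      words[i] <- if (runif(1) < p$um_pref) "um" else "uh"
    } else {
      words[i] <- sample(c("ah", "mm", "hmm", "like", "well", "you know"), 1L)
    }
  }
  make_plain_tokens(words)
}

generate_participant <- function(p, id, group) {
  vocab <- .child_vocab[seq_len(min(p$vocab_size, length(.child_vocab)))]
  zipf_p <- 1 / seq_along(vocab)
  zipf_p <- zipf_p / sum(zipf_p)
  nc <- max(5L, rnbinom(1L, mu = p$mean_cunits, size = 20))

  # batch-draw the per-c-unit randomness, then assemble
  lens <- 1L + rnbinom(nc, mu = p$mean_words - 1, size = 8)
  total <- sum(lens)
  bases <- vocab[sample.int(length(vocab), total, replace = TRUE, prob = zipf_p)]
  suffixed <- runif(total) < p$morph_rate
  sfx <- sample(c("s", "ed", "ing"), total, replace = TRUE)
  surface_all <- bases
  raw_all <- bases
  if (any(suffixed)) {
    surface_all[suffixed] <- paste0(bases[suffixed], sfx[suffixed])
    raw_all[suffixed] <- paste0(bases[suffixed], "/", sfx[suffixed])
  }
  nm_all <- 1L + suffixed
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  do_echo <- runif(nc) < p$echo_prob
  do_unint <- runif(nc) < p$unintell_prob
  do_maze <- runif(nc) < p$maze_rate
  maze_content <- runif(nc) < p$content_maze_prob
  incomplete <- runif(nc) < p$incomplete_rate

  cunits <- vector("list", 2L * nc)
  k <- 0L
  made <- 0L
  while (made < nc) {
    tpl <- .examiner_templates[[sample.int(length(.examiner_templates), 1L)]]
    k <- k + 1L
    cunits[[k]] <- new_cunit("examiner", make_plain_tokens(tpl), list(), TRUE)
    n_resp <- min(1L + rpois(1L, 0.7), nc - made)
    for (r in seq_len(n_resp)) {
      made <- made + 1L
      idx <- starts[made]:ends[made]
      len <- lens[made]
      tokens <- list(
        surface = surface_all[idx], root = bases[idx],
        n_morphemes = nm_all[idx], is_filler = rep(FALSE, len),
        is_unintelligible = rep(FALSE, len), raw = raw_all[idx]
      )
      if (do_echo[made]) {
        wl <- min(sample(p$echo_len[1]:p$echo_len[2], 1L), length(tpl))
        if (wl >= 2L) {
          start <- sample.int(length(tpl) - wl + 1L, 1L)
          win <- tpl[start:(start + wl - 1L)]
          if (runif(1) < 0.5) win[win == "you"] <- "i"
          tokens <- concat_tokens(make_plain_tokens(win), tokens)
        }
      }
      if (do_unint[made]) {
        i <- sample.int(n_tokens(tokens), 1L)
        tokens$surface[i] <- "X"; tokens$root[i] <- "X"
        tokens$n_morphemes[i] <- 1L; tokens$is_filler[i] <- FALSE
        tokens$is_unintelligible[i] <- TRUE; tokens$raw[i] <- "X"
      }
      mazes <- list()
      if (do_maze[made]) {
        mtok <- if (maze_content[made]) {
          nb <- if (runif(1) < 0.4) 2L else 1L
          mb <- vocab[sample.int(length(vocab), nb, replace = TRUE, prob = zipf_p)]
          list(surface = mb, root = mb, n_morphemes = rep(1L, nb),
               is_filler = rep(FALSE, nb), is_unintelligible = rep(FALSE, nb),
               raw = mb)
        } else {
          sample_filler_maze(p)
        }
        mazes <- list(list(position = 0L, kind = maze_kind(mtok), tokens = mtok))
      }
      k <- k + 1L
      cunits[[k]] <- new_cunit("child", tokens, mazes,
                               is_complete = !incomplete[made])
    }
  }
  rate <- if (p$cpm_cv > 0) {
    shape <- 1 / p$cpm_cv^2
    rgamma(1, shape = shape, rate = shape / p$cpm)
  } else {
    p$cpm
  }
  duration <- nc / rate
  age <- round(runif(1, p$age_range[1], p$age_range[2]), 1)
  iq <- round(max(70, rnorm(1, p$iq_mean, p$iq_sd)))
  sex <- if (runif(1) < p$male_prob) "m" else "f"
  list(
    id = id, group = group, age = age, iq = iq, sex = sex,
    transcript = new_transcript(id, cunits[seq_len(k)], duration),
    params = p
  )
}

#' Generate a synthetic examiner-child cohort
#'
#' Produces one synthetic participant per row of the specification:
#' transcripts alternate examiner question templates with child responses
#' realizing the group's token model (utterance length, Zipf vocabulary,
#' mazes built from the filler lexicon, um/uh choice, unintelligibility
#' marks, echo insertion, abandonment), plus age/IQ/sex covariates. The task
#' duration is derived from the c-unit count and the group's speech rate, so
#' c-units per minute recovers the planted rate. Deterministic given the
#' spec's seed.
#'
#' @param spec A [cohort_spec()].
#' @return List of synthetic participants, each a list with `id`, `group`,
#'   `age`, `iq`, `sex`, `transcript` (a `salt_transcript`), and `params`
#'   (the true generating parameters).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  out <- list()
  for (gname in names(spec$groups)) {
    p <- spec$groups[[gname]]
    for (i in seq_len(p$n)) {
      id <- sprintf("%s_%03d", gname, i)
      out[[length(out) + 1L]] <- generate_participant(p, id, gname)
    }
  }
  out
}

#' Cohort covariate table from generated participants
#'
#' @param participants Output of [generate_cohort()].
#' @return Data frame: `participant_id`, `group`, `age`, `iq`, `sex`,
#'   `duration_min`.
#' @export
cohort_table <- function(participants) {
  do.call(rbind, lapply(participants, function(p) {
    data.frame(
      participant_id = p$id, group = p$group, age = p$age, iq = p$iq,
      sex = p$sex, duration_min = p$transcript$duration_min,
      stringsAsFactors = FALSE
    )
  }))
}

#' Check recovery of planted generative parameters
#'
#' Generates `n_reps` cohorts from the spec (seeds derived deterministically
#' from the spec seed), computes the ALM profiles, and compares group-level
#' ALM means to the generating parameters where a direct target exists
#' (um proportion = um preference; CPM = speech rate; unintelligible
#' proportion = per-c-unit unintelligibility probability; MLUM and content
#' maze proportion have analytic approximations; NDWR and repetition
#' proportion have no closed-form target and are reported without bias).
#'
#' @param spec A [cohort_spec()].
#' @param n_reps Number of replicate cohorts.
#' @return Data frame: `group`, `alm`, `planted` (NA where no direct
#'   target), `recovered` (mean of group means across reps), `sd_across_reps`,
#'   `bias`.
#' @export
parameter_recovery_check <- function(spec, n_reps = 5) {
  stopifnot(inherits(spec, "cohort_spec"), n_reps >= 1)
  acc <- list()
  for (r in seq_len(n_reps)) {
    s <- spec
    s$seed <- spec$seed + r
    parts <- generate_cohort(s)
    tab <- compute_alm_table(lapply(parts, `[[`, "transcript"))
    tab$group <- vapply(parts, `[[`, character(1), "group")
    for (g in unique(tab$group)) {
      for (alm in alm_names()) {
        acc[[length(acc) + 1L]] <- data.frame(
          rep = r, group = g, alm = alm,
          value = mean(tab[[alm]][tab$group == g], na.rm = TRUE)
        )
      }
    }
  }
  acc <- do.call(rbind, acc)
  rows <- list()
  for (g in names(spec$groups)) {
    p <- spec$groups[[g]]
    fill_mean <- 1 * 0.7 + 2 * 0.3  # filler tokens per filler-only maze
    planted <- c(
      mlum = p$mean_words * (1 + p$morph_rate),
      ndwr = NA_real_,
      um_prop = p$um_pref,
      content_maze_prop = p$content_maze_prob /
        (p$content_maze_prob + (1 - p$content_maze_prob) * fill_mean),
      unintell_prop = p$unintell_prob,
      cpm = p$cpm,
      repetition_prop = NA_real_
    )
    for (alm in alm_names()) {
      v <- acc$value[acc$group == g & acc$alm == alm]
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, alm = alm, planted = unname(planted[alm]),
        recovered = mean(v), sd_across_reps = if (length(v) > 1) stats::sd(v) else NA_real_,
        bias = mean(v) - unname(planted[alm])
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
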