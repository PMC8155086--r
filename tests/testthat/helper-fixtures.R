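# Hand-tallied ten-utterance fixture. Frozen expected values (manual tally):
#   eligible c-units: lines 2 (7 morphemes), 5 (3), 8 (5), 9 (3), 10 (8)
#   MLUM = 26/5 = 5.2; NDWR = 21 distinct roots; um = 2, uh = 1 -> 2/3;
#   content mazes = 1, fillers in filler-only mazes = 4 -> 1/5;
#   unintelligible c-units = 1/10; CPM = 10/2.5 = 4;
#   repetition: one 2-word echo ("i like" ~ "you like") over 45 eligible
#   child words -> 2/45.
fixture_text <- function() {
  c(
    "+ participant_id: FIX01",
    "+ duration_min: 2.5",
    "E What do you like to do with your friend/s?",
    "C (Um) I like play/ing video game/s.",
    "C We play/ed at his house yesterday.",
    "C (He play) He win/s all the time.",
    "C I go/ing to X his dog.",
    "C That not fair!",
    "C (uh um) He cheat/s sometimes >",
    "E Why do you think he cheat/s?",
    "C (you know) Because he want/s to win.",
    "C I do not care much.",
    "C It fun anyway.",
    "C My friend/s like/s that game too."
  )
}

fixture_expected <- list(
  mlum = 5.2, ndwr = 21, um_prop = 2 / 3, content_maze_prop = 0.2,
  unintell_prop = 0.1, cpm = 4, repetition_prop = 2 / 45
)

# Independent iteratively-reweighted least-squares logistic oracle.
irls_logistic <- function(X, y, tol = 1e-12, maxit = 200) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    beta_new <- drop(solve(crossprod(X, X * w), crossprod(X, w * z)))
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  beta
}

# Vocabulary for random matcher stress cases: deliberately includes the
# deletable function words and the substitutable pronouns.
matcher_vocab <- c(
  "the", "a", "an", "is", "are", "am", "moon", "was", "coming", "up", "i",
  "you", "we", "me", "us", "him", "her", "he", "she", "dog", "like",
  "school", "went", "play", "home", "then", "ball", "red"
)

random_turn <- function(max_len = 8) {
  sample(matcher_vocab, sample(2:max_len, 1), replace = TRUE)
}

matched_total <- function(spans) {
  if (is.null(spans) || nrow(spans) == 0L) 0L else sum(spans$matched_child_words)
}
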