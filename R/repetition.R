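.empty_spans <- data.frame(
  child_start = integer(0), child_end = integer(0),
  examiner_start = integer(0), examiner_end = integer(0),
  matched_child_words = integer(0)
)

# Word equivalence under the pronoun substitution groups.
word_matches <- function(a, b, table) {
  if (a == b) return(TRUE)
  for (g in table$substitutable_groups) {
    if (a %in% g && b %in% g) return(TRUE)
  }
  FALSE
}

# Drop deletable function words, keeping a map back to original indices.
reduce_deletable <- function(words, table) {
  keep <- !(words %in% table$deletable)
  list(words = words[keep], index = which(keep))
}

# Substitution groups are disjoint, so equivalence under substitution is
# equality after mapping every group member to a canonical class label.
canon_words <- function(words, table) {
  subs <- unlist(table$substitutable_groups, use.names = FALSE)
  labs <- rep(paste0("\001grp", seq_along(table$substitutable_groups)),
              lengths(table$substitutable_groups))
  m <- match(words, subs)
  hit <- !is.na(m)
  words[hit] <- labs[m[hit]]
  words
}

#' Find echoed spans between an examiner turn and the following child turn
#'
#' Detects the child's repetition of the examiner's immediately previous
#' turn: contiguous runs (on both sides, after removal of deletable function
#' words) of two or more child words that equal a contiguous examiner
#' subsequence under word identity or the pronoun substitutions of
#' `table`. Among non-overlapping (on child indices) candidate sets, the
#' selection maximizes the total number of matched child words, with a
#' leftmost-longest tie break. Deletable words never count as matched words.
#'
#' @param examiner_tokens Character vector of the examiner turn's words
#'   (case-folded, mazes and unintelligible tokens already removed).
#' @param child_tokens Character vector of the child turn's words, same
#'   preprocessing.
#' @param table A [substitution_table()].
#' @return A data frame with one row per span: `child_start`, `child_end`,
#'   `examiner_start`, `examiner_end` (1-based indices into the original
#'   token vectors) and `matched_child_words` (>= 2).
#' @examples
#' match_spans(
#'   c("and", "the", "moon", "was", "coming", "up"),
#'   c("the", "moon", "was", "coming", "up", "then"),
#'   substitution_table()
#' )
#' @export
match_spans <- function(examiner_tokens, child_tokens, table = substitution_table()) {
  ex <- reduce_deletable(tolower(examiner_tokens), table)
  ch <- reduce_deletable(tolower(child_tokens), table)
  match_spans_reduced(canon_words(ch$words, table), ch$index,
                      canon_words(ex$words, table), ex$index)
}

# core matcher on canonicalized, deletable-free word vectors with maps back
# to original token indices
match_spans_reduced <- function(chw, ch_index, exw, ex_index) {
  empty <- .empty_spans
  n <- length(chw)
  m <- length(exw)
  if (n < 2L || m < 2L) return(empty)

  eq <- outer(chw, exw, "==")
  if (!any(eq)) return(empty)

  # M[i, j]: length of the longest run matching child i.. against examiner j..
  M <- matrix(0L, n + 1L, m + 1L)
  L <- integer(n)
  for (i in n:1) {
    run <- M[i + 1L, 2L:(m + 1L)] + 1L
    run[!eq[i, ]] <- 0L
    M[i, seq_len(m)] <- run
    L[i] <- max(run)
  }

  # g[i]: best total matched child words using reduced child positions i..n.
  g <- integer(n + 2L)
  for (i in n:1) {
    best <- g[i + 1L]
    if (L[i] >= 2L) {
      for (len in 2L:L[i]) {
        cand <- len + g[i + len + 1L]
        if (cand > best) best <- cand
      }
    }
    g[i] <- best
  }
  if (g[1L] == 0L) return(empty)

  # Reconstruct left to right, preferring to start a span at the leftmost
  # position and taking the longest length consistent with the optimum.
  cs <- integer(0); ce <- integer(0); es <- integer(0); ee <- integer(0)
  mw <- integer(0)
  i <- 1L
  while (i <= n) {
    taken <- FALSE
    if (L[i] >= 2L) {
      for (len in L[i]:2L) {
        if (len + g[i + len + 1L] == g[i]) {
          j0 <- which(M[i, seq_len(m)] >= len)[1L]
          cs <- c(cs, ch_index[i])
          ce <- c(ce, ch_index[i + len - 1L])
          es <- c(es, ex_index[j0])
          ee <- c(ee, ex_index[j0 + len - 1L])
          mw <- c(mw, len)
          i <- i + len
          taken <- TRUE
          break
        }
      }
    }
    if (!taken) i <- i + 1L
  }
  data.frame(child_start = cs, child_end = ce, examiner_start = es,
             examiner_end = ee, matched_child_words = mw)
}

# Child/examiner word extraction for matching: out-of-maze, intelligible
# surfaces of one turn (a run of consecutive same-speaker c-units).
turn_match_words <- function(cunits) {
  w <- unlist(lapply(cunits, function(cu) {
    cu$tokens$surface[!cu$tokens$is_unintelligible]
  }), use.names = FALSE)
  if (is.null(w)) character(0) else w
}

transcript_turns <- function(t) {
  sp <- vapply(t$cunits, `[[`, character(1), "speaker")
  if (length(sp) == 0L) return(list())
  r <- rle(sp)
  stops <- cumsum(r$lengths)
  starts <- stops - r$lengths + 1L
  lapply(seq_along(r$values), function(k) {
    list(speaker = r$values[k], cunits = t$cunits[starts[k]:stops[k]])
  })
}

#' Repetition proportion
#'
#' The number of child words echoed, in matched sets of two or more words,
#' from the examiner's immediately previous turn, divided by the total number
#' of child words. Matching uses [match_spans()]; consistently with the
#' matcher, child words inside mazes, unintelligible tokens, and deletable
#' function words are excluded from both numerator and denominator (the
#' deletable words `the/a/an/is/are/am/'m/'s/'re` can be freely dropped on
#' either side and so carry no matching information). A child turn with no
#' preceding examiner turn contributes zero matches.
#'
#' @param t A `salt_transcript`.
#' @param table A [substitution_table()].
#' @return A proportion in `[0, 1]`. Errors when the transcript has no child
#'   words; returns 0 when child speech consists only of deletable words.
#' @export
compute_repetition_proportion <- function(t, table = substitution_table()) {
  if (!inherits(t, "salt_transcript")) stop("not a salt_transcript", call. = FALSE)
  turns <- transcript_turns(t)
  total <- 0L
  matched <- 0L
  any_child_word <- FALSE
  prev_examiner <- NULL
  for (turn in turns) {
    if (turn$speaker == "examiner") {
      prev_examiner <- turn_match_words(turn$cunits)
      next
    }
    cw <- turn_match_words(turn$cunits)
    if (length(cw) > 0L) any_child_word <- TRUE
    cw_red <- reduce_deletable(cw, table)
    total <- total + length(cw_red$words)
    if (!is.null(prev_examiner) && length(cw_red$words) >= 2L) {
      ex_red <- reduce_deletable(prev_examiner, table)
      if (length(ex_red$words) >= 2L) {
        chw <- canon_words(cw_red$words, table)
        exw <- canon_words(ex_red$words, table)
        if (any(chw %in% exw)) {
          sp <- match_spans_reduced(chw, cw_red$index, exw, ex_red$index)
          if (nrow(sp) > 0L) matched <- matched + sum(sp$matched_child_words)
        }
      }
    }
    prev_examiner <- NULL
  }
  if (!any_child_word) stop("transcript has no child words", call. = FALSE)
  if (total == 0L) return(0)
  matched / total
}

#' Brute-force repetition matching oracle
#'
#' Exhaustive reference implementation used to verify [match_spans()]:
#' enumerates every set of non-overlapping contiguous child index ranges,
#' every contiguous examiner range for each, and every full alignment of the
#' two ranges under match / delete-deletable-child / delete-deletable-examiner
#' moves, and returns the maximum total of matched non-deletable child words
#' over sets whose spans each contain at least two matched words. Limited to
#' short turns to keep the enumeration tractable.
#'
#' @inheritParams match_spans
#' @return Integer: the maximum total matched child words.
#' @export
brute_force_repetition_oracle <- function(examiner_tokens, child_tokens,
                                          table = substitution_table()) {
  ex <- tolower(examiner_tokens)
  ch <- tolower(child_tokens)
  if (length(ex) > 10L || length(ch) > 10L) {
    stop("oracle limited to turns of at most 10 tokens", call. = FALSE)
  }
  n <- length(ch)
  m <- length(ex)
  del <- function(w) w %in% table$deletable

  # Max matched non-deletable child words when fully aligning ch[i..j] with
  # ex[a..b]; -Inf when no full alignment exists.
  align <- function(ci, cj, ea, eb) {
    f <- function(i, j) {
      if (i > cj && j > eb) return(0)
      best <- -Inf
      if (i <= cj && del(ch[i])) best <- max(best, f(i + 1L, j))
      if (j <= eb && del(ex[j])) best <- max(best, f(i, j + 1L))
      if (i <= cj && j <= eb && word_matches(ch[i], ex[j], table)) {
        v <- f(i + 1L, j + 1L)
        if (is.finite(v)) best <- max(best, v + if (del(ch[i])) 0 else 1)
      }
      best
    }
    f(ci, ea)
  }

  span_value <- function(ci, cj) {
    best <- -Inf
    if (m >= 1L) {
      for (ea in 1:m) {
        for (eb in ea:m) {
          best <- max(best, align(ci, cj, ea, eb))
        }
      }
    }
    if (is.finite(best) && best >= 2) best else -Inf
  }

  memo <- rep(NA_real_, n + 2L)
  h <- function(i) {
    if (i > n) return(0)
    if (!is.na(memo[i])) return(memo[i])
    best <- h(i + 1L)
    for (j in (i + 1L):n) {
      if (j > n) break
      v <- span_value(i, j)
      if (is.finite(v)) best <- max(best, v + h(j + 1L))
    }
    memo[i] <<- best
    best
  }
  if (n < 2L || m < 1L) return(0L)
  as.integer(h(1L))
}
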