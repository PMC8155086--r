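#' Filler lexicon
#'
#' The closed set of filler words used to classify maze material as filler
#' versus content: `ah, uh, um, mm, hmm, like, well, you know, I mean`.
#' The two multiword entries are matched greedily, left to right, as single
#' units during maze tokenization.
#'
#' @return Character vector of lowercased filler surfaces.
#' @export
filler_lexicon <- function() .filler_lex

.filler_lex <- c("ah", "uh", "um", "mm", "hmm", "like", "well", "you know", "i mean")

# internal: the multiword filler pairs merged during maze tokenization
.fillers_multi <- list(c("you", "know"), c("i", "mean"))

#' Substitution table for approximate repetition matching
#'
#' Encodes the approximate-match rules for detecting a child's echo of the
#' examiner's previous turn: pronouns within a group may substitute for one
#' another, and common function words/copulas may be deleted on either side.
#'
#' @return An object of class `substitution_table` with elements
#'   `substitutable_groups` (list of character vectors) and `deletable`
#'   (character vector). All comparisons are case-insensitive (tokens are
#'   case-folded upstream).
#' @export
substitution_table <- function() {
  structure(
    list(
      substitutable_groups = list(
        c("you", "i", "me", "we", "us"),
        c("him", "her"),
        c("he", "she")
      ),
      deletable = c("the", "a", "an", "is", "are", "am", "'m", "'s", "'re")
    ),
    class = "substitution_table"
  )
}
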