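child_cunits <- function(t) {
  Filter(function(cu) cu$speaker == "child", t$cunits)
}

#' Eligible c-units for MLUM and NDWR
#'
#' Returns the child c-units that are complete (not abandoned), fluent
#' (containing no maze), and intelligible (containing no unintelligible
#' token) — the utterance set over which utterance length and lexical
#' diversity are defined.
#'
#' @param t A `salt_transcript`.
#' @return List of c-units.
#' @export
eligible_cunits <- function(t) {
  if (!inherits(t, "salt_transcript")) stop("not a salt_transcript", call. = FALSE)
  Filter(function(cu) {
    cu$speaker == "child" && cu$is_complete && cu$is_fluent && cu$is_intelligible
  }, t$cunits)
}

#' Mean length of utterance in morphemes (MLUM)
#'
#' Mean, over all complete, fluent, and intelligible child c-units, of the
#' number of morphemes outside mazes (one per word plus one per slash-marked
#' bound morpheme).
#'
#' @param t A `salt_transcript`.
#' @return A real value, or `NA` when no c-unit is eligible.
#' @export
compute_mlum <- function(t) {
  el <- eligible_cunits(t)
  if (length(el) == 0L) return(NA_real_)
  mean(vapply(el, function(cu) sum(cu$tokens$n_morphemes), numeric(1)))
}

#' Number of different word roots (NDWR)
#'
#' Count of distinct case-folded word roots (surface minus bound-morpheme
#' markers; no lemmatization, so "ran" and "run/ing" are distinct roots)
#' outside mazes across all eligible c-units.
#'
#' @param t A `salt_transcript`.
#' @return An integer, or `NA` when no c-unit is eligible.
#' @export
compute_ndwr <- function(t) {
  el <- eligible_cunits(t)
  if (length(el) == 0L) return(NA_integer_)
  roots <- unlist(lapply(el, function(cu) cu$tokens$root), use.names = FALSE)
  length(unique(roots))
}

um_uh_counts <- function(t) {
  um <- 0L; uh <- 0L
  for (cu in child_cunits(t)) {
    s <- c(cu$tokens$surface,
           unlist(lapply(cu$mazes, function(m) m$tokens$surface), use.names = FALSE))
    um <- um + sum(s == "um")
    uh <- uh + sum(s == "uh")
  }
  c(um = um, uh = uh)
}

#' Um proportion
#'
#' `#um / (#um + #uh)` over all child speech, mazes included (filled pauses
#' live inside mazes under SALT conventions).
#'
#' @param t A `salt_transcript`.
#' @return A proportion in `[0, 1]`, or `NA` when neither um nor uh occurs.
#' @export
compute_um_proportion <- function(t) {
  n <- um_uh_counts(t)
  if (n[["um"]] + n[["uh"]] == 0L) return(NA_real_)
  n[["um"]] / (n[["um"]] + n[["uh"]])
}

content_maze_counts <- function(t) {
  content <- 0L; fillers <- 0L
  for (cu in child_cunits(t)) {
    for (m in cu$mazes) {
      if (m$kind == "content") {
        content <- content + 1L
      } else {
        fillers <- fillers + sum(m$tokens$is_filler)
      }
    }
  }
  c(content = content, fillers = fillers)
}

#' Content maze proportion
#'
#' `#content mazes / (#content mazes + #fillers)`, where a content maze is a
#' maze containing at least one non-filler word, and the filler count is the
#' number of filler tokens occurring in filler-only mazes (a maze is
#' classified wholesale; fillers inside content mazes are not counted).
#'
#' @param t A `salt_transcript`.
#' @return A proportion in `[0, 1]`, or `NA` when the denominator is zero
#'   (no mazes or fillers at all).
#' @export
compute_content_maze_proportion <- function(t) {
  n <- content_maze_counts(t)
  d <- n[["content"]] + n[["fillers"]]
  if (d == 0L) return(NA_real_)
  n[["content"]] / d
}

#' Unintelligible proportion
#'
#' Fraction of child c-units that are partially or fully unintelligible
#' (contain at least one unintelligibility mark, in or out of a maze).
#'
#' @param t A `salt_transcript`.
#' @return A proportion in `[0, 1]`. Errors when the transcript has no child
#'   c-units.
#' @export
compute_unintelligible_proportion <- function(t) {
  child <- child_cunits(t)
  if (length(child) == 0L) stop("transcript has no child c-units", call. = FALSE)
  mean(!vapply(child, `[[`, logical(1), "is_intelligible"))
}

#' C-units per minute (CPM)
#'
#' Number of attempted child c-units (all of them, regardless of
#' completeness or intelligibility) per minute of task audio.
#'
#' @param t A `salt_transcript`.
#' @return A non-negative real value.
#' @export
compute_cpm <- function(t) {
  if (!inherits(t, "salt_transcript")) stop("not a salt_transcript", call. = FALSE)
  if (is.null(t$duration_min) || is.na(t$duration_min) || t$duration_min <= 0) {
    stop("duration_min must be > 0 to compute c-units per minute", call. = FALSE)
  }
  length(child_cunits(t)) / t$duration_min
}

#' Compute the full seven-measure ALM profile
#'
#' Computes all seven automated language measures for one transcript.
#' Undefined values (zero denominators for the um and content maze
#' proportions; no eligible c-units for MLUM/NDWR) are encoded as `NA`,
#' never imputed.
#'
#' @param t A `salt_transcript`.
#' @param table Substitution table for repetition matching; defaults to
#'   [substitution_table()].
#' @return An object of class `alm_profile`: a named list with elements
#'   `mlum`, `ndwr`, `um_prop`, `content_maze_prop`, `unintell_prop`, `cpm`,
#'   `repetition_prop`.
#' @export
compute_profile <- function(t, table = substitution_table()) {
  if (!inherits(t, "salt_transcript")) stop("not a salt_transcript", call. = FALSE)
  if (is.null(t$duration_min) || is.na(t$duration_min) || t$duration_min <= 0) {
    stop("duration_min must be > 0 to compute c-units per minute", call. = FALSE)
  }
  # single pass over c-units; equivalence with the per-measure functions is
  # asserted in the test suite
  n_child <- 0L
  n_unint <- 0L
  n_el <- 0L
  morph_sum <- 0
  roots <- vector("list", length(t$cunits))
  um <- 0L; uh <- 0L
  n_content <- 0L; n_fillers <- 0L
  for (cu in t$cunits) {
    if (cu$speaker != "child") next
    n_child <- n_child + 1L
    if (!cu$is_intelligible) n_unint <- n_unint + 1L
    s <- cu$tokens$surface
    um <- um + sum(s == "um")
    uh <- uh + sum(s == "uh")
    for (m in cu$mazes) {
      ms <- m$tokens$surface
      um <- um + sum(ms == "um")
      uh <- uh + sum(ms == "uh")
      if (m$kind == "content") {
        n_content <- n_content + 1L
      } else {
        n_fillers <- n_fillers + sum(m$tokens$is_filler)
      }
    }
    if (cu$is_complete && cu$is_fluent && cu$is_intelligible) {
      n_el <- n_el + 1L
      morph_sum <- morph_sum + sum(cu$tokens$n_morphemes)
      roots[[n_el]] <- cu$tokens$root
    }
  }
  if (n_child == 0L) {
    stop("transcript has no child c-units; ALM profile is undefined",
         call. = FALSE)
  }
  cm_den <- n_content + n_fillers
  structure(
    list(
      mlum = if (n_el > 0L) morph_sum / n_el else NA_real_,
      ndwr = if (n_el > 0L) {
        length(unique(unlist(roots[seq_len(n_el)], use.names = FALSE)))
      } else NA_integer_,
      um_prop = if (um + uh > 0L) um / (um + uh) else NA_real_,
      content_maze_prop = if (cm_den > 0L) n_content / cm_den else NA_real_,
      unintell_prop = n_unint / n_child,
      cpm = n_child / t$duration_min,
      repetition_prop = compute_repetition_proportion(t, table)
    ),
    class = "alm_profile"
  )
}

#' @export
print.alm_profile <- function(x, ...) {
  cat("<alm_profile>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-18s %s\n", nm,
                if (is.na(x[[nm]])) "undefined" else format(x[[nm]], digits = 4)))
  }
  invisible(x)
}

#' Names of the seven ALMs
#'
#' @return Character vector of the seven measure column names, in canonical
#'   order.
#' @export
alm_names <- function() {
  c("mlum", "ndwr", "um_prop", "content_maze_prop", "unintell_prop",
    "cpm", "repetition_prop")
}

#' Compute an ALM table for a set of transcripts
#'
#' @param transcripts List of `salt_transcript` objects.
#' @return A data frame with `participant_id` plus the seven ALM columns
#'   (`NA` marks undefined values), one row per transcript.
#' @export
compute_alm_table <- function(transcripts) {
  profs <- lapply(transcripts, compute_profile)
  out <- data.frame(
    participant_id = vapply(transcripts, `[[`, character(1), "participant_id"),
    stringsAsFactors = FALSE
  )
  for (alm in alm_names()) {
    out[[alm]] <- vapply(profs, function(p) as.numeric(p[[alm]]), numeric(1))
  }
  out
}
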