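cunit_to_line <- function(cu) {
  code <- if (cu$speaker == "child") "C" else "E"
  pieces <- character(0)
  ntok <- n_tokens(cu$tokens)
  mz_at <- vapply(cu$mazes, `[[`, integer(1), "position")
  for (pos in 0:ntok) {
    for (j in which(mz_at == pos)) {
      pieces <- c(pieces,
                  paste0("(", paste(cu$mazes[[j]]$tokens$raw, collapse = " "), ")"))
    }
    if (pos < ntok) pieces <- c(pieces, cu$tokens$raw[pos + 1L])
  }
  term <- if (cu$is_complete) "." else " >"
  paste0(code, " ", paste(pieces, collapse = " "), term)
}

#' Write a transcript back to the SALT dialect
#'
#' Serializes a `salt_transcript` to the same dialect [parse_transcript()]
#' reads, with `+` metadata headers. Round trip is guaranteed:
#' re-parsing the output reproduces the structured transcript exactly.
#'
#' @param t A `salt_transcript`.
#' @param path Optional file path; when given the document is written there.
#' @return The document as a single string (invisibly when `path` is given).
#' @export
write_transcript <- function(t, path = NULL) {
  stopifnot(inherits(t, "salt_transcript"))
  lines <- c(
    paste0("+ participant_id: ", t$participant_id),
    paste0("+ duration_min: ", sprintf("%.17g", t$duration_min)),
    vapply(t$cunits, cunit_to_line, character(1))
  )
  doc <- paste(lines, collapse = "\n")
  if (!is.null(path)) {
    writeLines(doc, path, useBytes = TRUE)
    return(invisible(doc))
  }
  doc
}

#' Validate a transcript and report diagnostics
#'
#' Returns machine-readable warnings about conditions downstream measures
#' care about; it never throws. Codes: `no_child_speech` (no child c-units),
#' `um_proportion_undefined` (no um/uh anywhere in child speech, so the um
#' proportion denominator is zero), `no_eligible_cunits` (no complete,
#' fluent, intelligible child c-unit, so MLUM/NDWR are undefined),
#' `content_maze_denominator_zero` (no content mazes and no fillers in
#' filler-only mazes).
#'
#' @param t A `salt_transcript`.
#' @return A data frame with columns `code` and `message` (zero rows when
#'   the transcript is clean).
#' @export
validate_transcript <- function(t) {
  stopifnot(inherits(t, "salt_transcript"))
  codes <- character(0)
  msgs <- character(0)
  add <- function(code, msg) {
    codes <<- c(codes, code); msgs <<- c(msgs, msg)
  }
  child <- child_cunits(t)
  if (length(child) == 0L) {
    add("no_child_speech", "transcript contains no child c-units")
    return(data.frame(code = codes, message = msgs))
  }
  if (um_uh_counts(t)[["um"]] + um_uh_counts(t)[["uh"]] == 0L) {
    add("um_proportion_undefined",
        "no um or uh tokens in child speech; um proportion will be undefined")
  }
  if (length(eligible_cunits(t)) == 0L) {
    add("no_eligible_cunits",
        "no complete, fluent, intelligible child c-units; MLUM/NDWR undefined")
  }
  cm <- content_maze_counts(t)
  if (cm[["content"]] + cm[["fillers"]] == 0L) {
    add("content_maze_denominator_zero",
        "no content mazes and no fillers; content maze proportion undefined")
  }
  data.frame(code = codes, message = msgs)
}

#' Export a transcript structure as JSON
#'
#' Debugging/audit export of the parsed structure (tokens, mazes, flags).
#'
#' @param t A `salt_transcript`.
#' @param path Optional file path.
#' @return JSON string (invisibly when `path` is given).
#' @export
transcript_to_json <- function(t, path = NULL) {
  stopifnot(inherits(t, "salt_transcript"))
  x <- list(
    participant_id = t$participant_id,
    duration_min = t$duration_min,
    cunits = lapply(t$cunits, function(cu) {
      list(
        speaker = cu$speaker,
        is_complete = cu$is_complete,
        is_intelligible = cu$is_intelligible,
        is_fluent = cu$is_fluent,
        tokens = as.data.frame(cu$tokens, stringsAsFactors = FALSE),
        mazes = lapply(cu$mazes, function(m) {
          list(position = m$position, kind = m$kind,
               tokens = as.data.frame(m$tokens, stringsAsFactors = FALSE))
        })
      )
    })
  )
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
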