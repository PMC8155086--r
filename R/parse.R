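# Token sets are stored as parallel vectors rather than data frames: a
# transcript holds hundreds of tiny token groups and data.frame overhead
# dominates at cohort scale.
new_tokens <- function(surface = character(), root = character(),
                       n_morphemes = integer(), is_filler = logical(),
                       is_unintelligible = logical(), raw = character()) {
  list(
    surface = surface, root = root, n_morphemes = as.integer(n_morphemes),
    is_filler = is_filler, is_unintelligible = is_unintelligible, raw = raw
  )
}

n_tokens <- function(tok) length(tok$surface)

new_cunit <- function(speaker, tokens, mazes, is_complete) {
  unint <- any(tokens$is_unintelligible) ||
    any(vapply(mazes, function(m) any(m$tokens$is_unintelligible), logical(1)))
  list(
    speaker = speaker,
    tokens = tokens,
    mazes = mazes,
    is_complete = is_complete,
    is_intelligible = !unint,
    is_fluent = length(mazes) == 0L
  )
}

new_transcript <- function(participant_id, cunits, duration_min) {
  structure(
    list(participant_id = participant_id, cunits = cunits,
         duration_min = duration_min),
    class = "salt_transcript"
  )
}

#' @export
print.salt_transcript <- function(x, ...) {
  sp <- vapply(x$cunits, `[[`, character(1), "speaker")
  cat(sprintf(
    "<salt_transcript> %s: %d c-units (%d child, %d examiner), %.2f min\n",
    x$participant_id, length(x$cunits), sum(sp == "child"),
    sum(sp == "examiner"), x$duration_min
  ))
  invisible(x)
}

# Build a token set from whitespace-split word strings. Terminal punctuation
# is stripped per word; "X"/"XX" (upper case, pre-folding) mark unintelligible
# material; slash suffixes mark bound morphemes ("dog/s" -> root "dog",
# 2 morphemes). Inside mazes, the multiword fillers "you know" / "I mean" are
# merged greedily left-to-right into single filler units.
tokenize_words <- function(words, in_maze = FALSE) {
  words <- sub("[.,!?;:]+$", "", words)
  words <- words[nzchar(words)]
  n <- length(words)
  if (n == 0L) return(new_tokens())
  unint <- words %in% c("X", "XX")
  raw <- ifelse(unint, words, tolower(words))
  surface <- character(n)
  root <- character(n)
  nm <- integer(n)
  for (i in seq_len(n)) {
    if (unint[i]) {
      surface[i] <- raw[i]
      root[i] <- raw[i]
      nm[i] <- 1L
    } else {
      parts <- strsplit(raw[i], "/", fixed = TRUE)[[1]]
      parts <- parts[nzchar(parts)]
      if (length(parts) == 0L) parts <- raw[i]
      surface[i] <- paste(parts, collapse = "")
      root[i] <- parts[[1]]
      nm[i] <- length(parts)
    }
  }
  if (in_maze && n >= 2L) {
    keep <- rep(TRUE, n)
    i <- 1L
    while (i < n) {
      if (keep[i] && !unint[i] && !unint[i + 1L]) {
        pair <- c(surface[i], surface[i + 1L])
        hit <- any(vapply(.fillers_multi, function(f) all(f == pair), logical(1)))
        if (hit) {
          surface[i] <- paste(pair, collapse = " ")
          root[i] <- surface[i]
          nm[i] <- 1L
          raw[i] <- paste(raw[i], raw[i + 1L])
          keep[i + 1L] <- FALSE
          i <- i + 2L
          next
        }
      }
      i <- i + 1L
    }
    surface <- surface[keep]; root <- root[keep]; nm <- nm[keep]
    unint <- unint[keep]; raw <- raw[keep]
  }
  filler <- !unint & surface %in% .filler_lex
  new_tokens(surface, root, nm, filler, unint, raw)
}

maze_kind <- function(tokens) {
  content <- any(!tokens$is_filler & !tokens$is_unintelligible)
  if (content) "content" else "filler_only"
}

parse_speech_line <- function(line, lineno) {
  m <- regmatches(line, regexec("^([A-Za-z]+)\\s+(.*)$", line))[[1]]
  if (length(m) == 0L) {
    stop(sprintf("line %d: cannot parse speaker code in %s", lineno,
                 deparse(line)), call. = FALSE)
  }
  code <- m[2]
  body <- m[3]
  speaker <- switch(code,
    C = "child", c = "child", E = "examiner", e = "examiner",
    stop(sprintf("line %d: unknown speaker code '%s'", lineno, code),
         call. = FALSE)
  )
  is_complete <- !grepl(">\\s*$", body)
  body <- sub(">\\s*$", "", body)
  body <- sub("[[:space:].!?]+$", "", body)

  opens <- gregexpr("(", body, fixed = TRUE)[[1]]
  closes <- gregexpr(")", body, fixed = TRUE)[[1]]
  n_open <- sum(opens > 0)
  n_close <- sum(closes > 0)
  if (n_open != n_close) {
    stop(sprintf("line %d: unclosed maze parenthesis", lineno), call. = FALSE)
  }
  tokens <- new_tokens()
  mazes <- list()
  pos <- 0L
  rest <- body
  repeat {
    op <- regexpr("(", rest, fixed = TRUE)
    if (op < 0) {
      out <- tokenize_words(strsplit(trimws(rest), "\\s+")[[1]])
      tokens <- concat_tokens(tokens, out)
      break
    }
    pre <- substr(rest, 1L, op - 1L)
    out <- tokenize_words(strsplit(trimws(pre), "\\s+")[[1]])
    tokens <- concat_tokens(tokens, out)
    pos <- n_tokens(tokens)
    rest <- substr(rest, op + 1L, nchar(rest))
    cl <- regexpr(")", rest, fixed = TRUE)
    op2 <- regexpr("(", rest, fixed = TRUE)
    if (cl < 0 || (op2 > 0 && op2 < cl)) {
      stop(sprintf("line %d: unclosed maze parenthesis", lineno), call. = FALSE)
    }
    inside <- substr(rest, 1L, cl - 1L)
    mtok <- tokenize_words(strsplit(trimws(inside), "\\s+")[[1]], in_maze = TRUE)
    if (n_tokens(mtok) == 0L) {
      stop(sprintf("line %d: empty maze", lineno), call. = FALSE)
    }
    mazes[[length(mazes) + 1L]] <- list(
      position = pos, kind = maze_kind(mtok), tokens = mtok
    )
    rest <- substr(rest, cl + 1L, nchar(rest))
  }
  new_cunit(speaker, tokens, mazes, is_complete)
}

concat_tokens <- function(a, b) {
  if (n_tokens(b) == 0L) return(a)
  if (n_tokens(a) == 0L) return(b)
  new_tokens(
    c(a$surface, b$surface), c(a$root, b$root),
    c(a$n_morphemes, b$n_morphemes), c(a$is_filler, b$is_filler),
    c(a$is_unintelligible, b$is_unintelligible), c(a$raw, b$raw)
  )
}

#' Parse a SALT-dialect transcript
#'
#' Parses a plain-text transcript in the package's documented SALT dialect:
#' each speech line is a speaker code (`C` for the child, `E` for the
#' examiner) followed by one c-unit; mazes (disfluencies) are parenthesized;
#' bound morphemes are slash-marked (`dog/s`, `walk/ed`, `he/'s`); an
#' unintelligible word is `X` and a fully unintelligible segment `XX`;
#' abandoned (incomplete) c-units end with `>`. Optional header lines start
#' with `+` and supply metadata (`+ participant_id: P01`,
#' `+ duration_min: 6.27`).
#'
#' @param text Transcript document: a single string or character vector of
#'   lines.
#' @param duration_min Task audio length in minutes. Overrides a
#'   `duration_min` header if both are present; required (here or in a
#'   header) because c-units per minute needs it and it cannot be inferred
#'   from text.
#' @param participant_id Optional participant id; overrides the header.
#' @return An object of class `salt_transcript`: a list with
#'   `participant_id`, `cunits` (each with `speaker`, out-of-maze `tokens`,
#'   `mazes` with positions, and `is_complete`/`is_intelligible`/`is_fluent`
#'   flags) and `duration_min`.
#' @seealso [write_transcript()], [validate_transcript()], [compute_profile()]
#' @examples
#' t <- parse_transcript("C And (um) I like dog/s.", duration_min = 1)
#' t$cunits[[1]]$mazes[[1]]$kind
#' @export
parse_transcript <- function(text, duration_min = NULL, participant_id = NULL) {
  if (length(text) == 0L || all(!nzchar(trimws(text)))) {
    stop("empty transcript text", call. = FALSE)
  }
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  header <- list()
  cunits <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (!nzchar(ln)) next
    if (startsWith(ln, "+")) {
      hm <- regmatches(ln, regexec("^\\+\\s*([A-Za-z_]+)\\s*:\\s*(.*)$", ln))[[1]]
      if (length(hm) == 3L) header[[hm[2]]] <- trimws(hm[3])
      next
    }
    cunits[[length(cunits) + 1L]] <- parse_speech_line(ln, i)
  }
  if (is.null(participant_id)) {
    participant_id <- header$participant_id %||% "unknown"
  }
  if (is.null(duration_min) && !is.null(header$duration_min)) {
    duration_min <- as.numeric(header$duration_min)
  }
  if (is.null(duration_min) || is.na(duration_min)) {
    stop("duration_min must be supplied as an argument or '+ duration_min:' header",
         call. = FALSE)
  }
  if (duration_min <= 0) stop("duration_min must be > 0", call. = FALSE)
  new_transcript(participant_id, cunits, duration_min)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a SALT-dialect transcript file
#'
#' @param path File path. The participant id defaults to the file name
#'   (without extension) when no `+ participant_id:` header is present.
#' @inheritParams parse_transcript
#' @return A `salt_transcript`.
#' @export
read_transcript <- function(path, duration_min = NULL) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  t <- parse_transcript(lines, duration_min = duration_min)
  if (identical(t$participant_id, "unknown")) {
    t$participant_id <- tools::file_path_sans_ext(basename(path))
  }
  t
}
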