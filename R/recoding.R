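#' ALMs scored in reverse (low raw value = high impairment)
#'
#' @return Character vector: the measures for which lower raw values
#'   indicate greater impairment (MLUM, NDWR, um proportion, CPM).
#' @export
reversed_alms <- function() c("mlum", "ndwr", "um_prop", "cpm")

#' Fit centile bins for ordinal recoding of one ALM
#'
#' Converts a cohort sample of one raw measure into cutpoints for the common
#' ordinal 1-4 impairment scale. Values are first *oriented* so that larger
#' means more impaired (negated for the reversed measures, see
#' [reversed_alms()]); thresholds are then the empirical 50th, 75th, and
#' 90th centiles of the oriented sample (type-7 linear interpolation), with
#' right-closed bins: oriented values at or below the 50th centile score 1,
#' above the 90th score 4. For the um proportion, when more than 10% of the
#' sample is exactly zero the top threshold is lowered to the largest
#' oriented value strictly below zero, so that every zero (the most impaired
#' possible value of a reversed measure) scores 4 while no positive value
#' scores higher than a smaller positive value.
#'
#' @param values Numeric cohort sample of one ALM; `NA` (undefined) values
#'   are excluded before fitting.
#' @param alm_name One of [alm_names()].
#' @return An object of class `centile_bins` with fields `alm_name`,
#'   `thresholds` (three non-decreasing cutpoints on the oriented scale),
#'   `reversed`, `zero_adjusted`, `fitted_n`.
#' @export
fit_bins <- function(values, alm_name) {
  alm_name <- match.arg(alm_name, alm_names())
  x <- values[!is.na(values)]
  if (length(x) < 10L) {
    stop(sprintf("need at least 10 defined values to fit bins for %s (got %d)",
                 alm_name, length(x)), call. = FALSE)
  }
  if (diff(range(x)) == 0) {
    stop(sprintf("constant sample for %s: centile bins are degenerate", alm_name),
         call. = FALSE)
  }
  reversed <- alm_name %in% reversed_alms()
  oriented <- if (reversed) -x else x
  thr <- unname(quantile(oriented, c(0.5, 0.75, 0.9), type = 7))
  zero_adjusted <- FALSE
  if (alm_name == "um_prop" && mean(x == 0) > 0.10) {
    below <- oriented[oriented < 0]
    # all-zero samples are caught by the constant check above
    thr[3] <- max(below)
    thr[2] <- min(thr[2], thr[3])
    thr[1] <- min(thr[1], thr[2])
    zero_adjusted <- TRUE
  }
  structure(
    list(alm_name = alm_name, thresholds = thr, reversed = reversed,
         zero_adjusted = zero_adjusted, fitted_n = length(x)),
    class = "centile_bins"
  )
}

#' Apply fitted centile bins to raw values
#'
#' Maps raw measure values to ordinal impairment scores 1-4 through fitted
#' [fit_bins()] cutpoints. Ties at a threshold fall in the lower-impairment
#' bin.
#'
#' @param value Numeric vector of raw values; `NA` is an error (exclusion
#'   decisions belong to the pipeline, not the scale).
#' @param bins A `centile_bins` object.
#' @return Integer vector of scores in `{1, 2, 3, 4}`; higher = more
#'   impaired.
#' @export
apply_bins <- function(value, bins) {
  stopifnot(inherits(bins, "centile_bins"))
  if (anyNA(value)) {
    stop("undefined (NA) values cannot be scored; exclude them upstream",
         call. = FALSE)
  }
  v <- if (bins$reversed) -value else value
  thr <- bins$thresholds
  score <- 1L + (v > thr[1]) + (v > thr[2]) + (v > thr[3])
  as.integer(score)
}

#' @export
print.centile_bins <- function(x, ...) {
  cat(sprintf(
    "<centile_bins> %s (n = %d%s%s): thresholds %s on the %s scale\n",
    x$alm_name, x$fitted_n,
    if (x$reversed) ", reversed" else "",
    if (x$zero_adjusted) ", zero-adjusted" else "",
    paste(format(x$thresholds, digits = 4), collapse = ", "),
    if (x$reversed) "negated (impairment-oriented)" else "raw"
  ))
  invisible(x)
}

#' Serialize fitted bins to JSON
#'
#' @param bins A single `centile_bins` object or a named list of them.
#' @param path Optional file path.
#' @return JSON string (invisibly when `path` is given).
#' @export
bins_to_json <- function(bins, path = NULL) {
  if (inherits(bins, "centile_bins")) bins <- list(bins)
  payload <- lapply(bins, function(b) {
    list(alm_name = b$alm_name, thresholds = b$thresholds,
         reversed = b$reversed, zero_adjusted = b$zero_adjusted,
         fitted_n = b$fitted_n)
  })
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Read fitted bins back from JSON
#'
#' @param path File path or JSON string produced by [bins_to_json()].
#' @return Named list of `centile_bins`, keyed by ALM name.
#' @export
bins_from_json <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  out <- lapply(raw, function(b) {
    structure(
      list(alm_name = b$alm_name, thresholds = as.numeric(unlist(b$thresholds)),
           reversed = isTRUE(b$reversed), zero_adjusted = isTRUE(b$zero_adjusted),
           fitted_n = as.integer(b$fitted_n)),
      class = "centile_bins"
    )
  })
  names(out) <- vapply(out, `[[`, character(1), "alm_name")
  out
}

#' Recode a raw ALM table onto the ordinal 1-4 scale
#'
#' Fits [fit_bins()] per measure on the defined values of the whole sample
#' and applies them row-wise. Measures with fewer than 10 defined values or
#' a constant sample are skipped with a warning (their score column is all
#' `NA`). Undefined raw values yield `NA` scores.
#'
#' @param alm_table Data frame with a `participant_id` column and raw ALM
#'   columns (any subset of [alm_names()]).
#' @param bins Optional named list of pre-fitted `centile_bins` (e.g. from
#'   [bins_from_json()]); measures absent from it are fitted from the data.
#' @return A list with `scores` (data frame: `participant_id` plus
#'   `score_<alm>` integer columns) and `bins` (named list of fitted
#'   `centile_bins`).
#' @export
recode_alm_table <- function(alm_table, bins = NULL) {
  present <- intersect(alm_names(), names(alm_table))
  scores <- data.frame(participant_id = alm_table$participant_id,
                       stringsAsFactors = FALSE)
  fitted <- list()
  for (alm in present) {
    x <- alm_table[[alm]]
    b <- bins[[alm]]
    if (is.null(b)) {
      b <- tryCatch(fit_bins(x, alm), error = function(e) {
        warning(sprintf("skipping %s: %s", alm, conditionMessage(e)),
                call. = FALSE)
        NULL
      })
    }
    col <- rep(NA_integer_, nrow(alm_table))
    if (!is.null(b)) {
      ok <- !is.na(x)
      col[ok] <- apply_bins(x[ok], b)
      fitted[[alm]] <- b
    }
    scores[[paste0("score_", alm)]] <- col
  }
  list(scores = scores, bins = fitted)
}
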