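run_metadata <- function(seed, config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA), tf)
  list(
    seed = seed,
    version = as.character(packageVersion("saltalm")),
    config_hash = unname(tools::md5sum(tf))
  )
}

write_json_file <- function(x, path) {
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE),
             path)
  invisible(path)
}

#' Simulate a cohort to disk
#'
#' Writes one SALT-dialect transcript file per synthetic participant, a
#' cohort covariate CSV, and a JSON of the true generating parameters and
#' run metadata (seed, package version, config hash).
#'
#' @param out_dir Output directory (created if needed); transcripts go under
#'   `<out_dir>/transcripts`.
#' @param spec A [cohort_spec()]; `seed`, when given, overrides the spec's.
#' @param seed Optional integer seed override.
#' @return Invisibly, the list of generated participants.
#' @export
alm_simulate <- function(out_dir, spec = cohort_spec(), seed = NULL) {
  if (!is.null(seed)) spec$seed <- as.integer(seed)
  dir.create(file.path(out_dir, "transcripts"), recursive = TRUE,
             showWarnings = FALSE)
  parts <- generate_cohort(spec)
  for (p in parts) {
    write_transcript(p$transcript,
                     file.path(out_dir, "transcripts", paste0(p$id, ".slt")))
  }
  write.csv(cohort_table(parts), file.path(out_dir, "cohort.csv"),
            row.names = FALSE)
  write_json_file(
    list(meta = run_metadata(spec$seed, lapply(spec$groups, unclass)),
         groups = lapply(spec$groups, unclass)),
    file.path(out_dir, "true_params.json")
  )
  invisible(parts)
}

#' Compute the per-participant ALM table for a directory of transcripts
#'
#' Reads every `*.slt` transcript under `input_dir`, computes the seven
#' ALMs, and writes a wide CSV (`NA` marks undefined values) plus a
#' machine-readable exclusion/diagnostic ledger. A transcript that fails to
#' parse is logged (reason code `unparseable`) and the run continues; one
#' with no child speech is logged `no_child_speech`; undefined um proportion
#' is logged `undefined_um`.
#'
#' @param input_dir Directory containing `.slt` transcript files.
#' @param out_file Optional path of the output CSV.
#' @param log_file Optional path of the diagnostics CSV.
#' @return List with `alms` (data frame) and `log` (data frame with columns
#'   `file`, `participant_id`, `code`, `message`).
#' @export
alm_compute <- function(input_dir, out_file = NULL, log_file = NULL) {
  files <- list.files(input_dir, pattern = "\\.slt$", full.names = TRUE)
  if (length(files) == 0L) {
    stop(sprintf("no .slt transcripts found in %s", input_dir), call. = FALSE)
  }
  rows <- list()
  log <- list()
  add_log <- function(file, id, code, message) {
    log[[length(log) + 1L]] <<- data.frame(
      file = basename(file), participant_id = id, code = code,
      message = message, stringsAsFactors = FALSE
    )
  }
  for (f in files) {
    t <- tryCatch(read_transcript(f), error = function(e) e)
    if (inherits(t, "error")) {
      add_log(f, NA_character_, "unparseable", conditionMessage(t))
      next
    }
    diags <- validate_transcript(t)
    for (i in seq_len(nrow(diags))) {
      code <- diags$code[i]
      if (code == "um_proportion_undefined") code <- "undefined_um"
      add_log(f, t$participant_id, code, diags$message[i])
    }
    if (any(diags$code == "no_child_speech")) next
    p <- compute_profile(t)
    rows[[length(rows) + 1L]] <- as.data.frame(
      c(list(participant_id = t$participant_id), unclass(p)),
      stringsAsFactors = FALSE
    )
  }
  alms <- if (length(rows)) do.call(rbind, rows) else NULL
  logdf <- if (length(log)) do.call(rbind, log) else
    data.frame(file = character(0), participant_id = character(0),
               code = character(0), message = character(0))
  if (!is.null(out_file) && !is.null(alms)) {
    write.csv(alms, out_file, row.names = FALSE)
  }
  if (!is.null(log_file)) write.csv(logdf, log_file, row.names = FALSE)
  list(alms = alms, log = logdf)
}

#' Recode an ALM table to ordinal scores, saving the fitted scale
#'
#' Thin pipeline wrapper over [recode_alm_table()]: fits centile bins on the
#' whole sample (or reapplies a frozen scale), writes the ordinal score CSV
#' and the bins JSON so the scale can be reused.
#'
#' @param alm_table Data frame from [alm_compute()], or a path to its CSV.
#' @param out_file Optional path of the ordinal score CSV.
#' @param bins_file Optional path of the serialized bins JSON.
#' @param bins Optional pre-fitted bins (object or JSON path) to reapply.
#' @return List with `scores` and `bins` as in [recode_alm_table()].
#' @export
alm_recode <- function(alm_table, out_file = NULL, bins_file = NULL,
                       bins = NULL) {
  if (is.character(alm_table)) alm_table <- read.csv(alm_table)
  if (is.character(bins)) bins <- bins_from_json(bins)
  rec <- recode_alm_table(alm_table, bins = bins)
  if (!is.null(out_file)) write.csv(rec$scores, out_file, row.names = FALSE)
  if (!is.null(bins_file)) bins_to_json(rec$bins, bins_file)
  rec
}

#' Run the validation battery and write the report bundle
#'
#' Merges the raw ALM table, ordinal scores, and cohort covariates, runs
#' [run_validation()], and writes a JSON report, CSV tables (group
#' comparisons, post-hoc contrasts, model summaries, correlations), and an
#' overlaid ROC figure. Every artifact embeds the seed, package version, and
#' config hash.
#'
#' @param alm_table Raw ALM data frame or CSV path.
#' @param cohort Cohort covariate data frame or CSV path (must contain
#'   `participant_id`, the group column, and the covariates).
#' @param out_dir Output directory for the report bundle.
#' @param scores Optional ordinal score data frame or CSV path (recomputed
#'   from the raw table when absent).
#' @param group_col,case_group,covariates,clinical_cols,cutoff Passed to
#'   [run_validation()].
#' @param seed Seed recorded in the report metadata.
#' @return The `alm_validation` object, invisibly.
#' @export
alm_validate <- function(alm_table, cohort, out_dir, scores = NULL,
                         group_col = "group", case_group = "asd",
                         covariates = c("age", "iq"), clinical_cols = NULL,
                         cutoff = 0.5, seed = NA_integer_) {
  if (is.character(alm_table)) alm_table <- read.csv(alm_table)
  if (is.character(cohort)) cohort <- read.csv(cohort)
  if (is.character(scores)) scores <- read.csv(scores)
  if (!group_col %in% names(cohort)) {
    stop(sprintf("cohort table lacks group column '%s'", group_col),
         call. = FALSE)
  }
  merged <- merge(cohort, alm_table, by = "participant_id", sort = TRUE)
  if (!is.null(scores)) {
    merged <- merge(merged, scores, by = "participant_id", sort = TRUE)
  }
  val <- run_validation(merged, group_col = group_col, case_group = case_group,
                        covariates = covariates, clinical_cols = clinical_cols,
                        cutoff = cutoff)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  meta <- run_metadata(seed, list(group_col = group_col,
                                  case_group = case_group,
                                  covariates = covariates, cutoff = cutoff))
  write.csv(val$group_comparisons,
            file.path(out_dir, "group_comparisons.csv"), row.names = FALSE)
  if (!is.null(val$posthoc)) {
    write.csv(val$posthoc, file.path(out_dir, "posthoc.csv"), row.names = FALSE)
  }
  write.csv(val$model_summary, file.path(out_dir, "model_summary.csv"),
            row.names = FALSE)
  write.csv(as.data.frame(val$spearman$rho),
            file.path(out_dir, "spearman_rho.csv"))
  report <- list(
    meta = meta,
    n_used = val$n_used,
    excluded = val$excluded,
    group_comparisons = val$group_comparisons,
    posthoc = val$posthoc,
    model_summary = val$model_summary,
    auc = lapply(val$roc, `[[`, "auc")
  )
  write_json_file(report, file.path(out_dir, "report.json"))
  fig <- plot_roc(val)
  ggplot2::ggsave(file.path(out_dir, "roc_overlay.png"), fig,
                  width = 7, height = 5, dpi = 150)
  invisible(val)
}
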