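#' Run the full cohort validation battery
#'
#' Reproduces the structure of the validation analyses on a cohort table:
#' (a) per-ALM Kruskal-Wallis comparisons across the diagnostic groups with
#' rank eta-squared and Games-Howell post-hoc contrasts (post-hoc only when
#' k > 2); (b) a Spearman correlation matrix of the raw ALMs and any
#' supplied clinical scores; (c) a logistic classification battery — a
#' covariates-only baseline model, one model per ordinal ALM, and a combined
#' model with all ALMs — fitted on one identical listwise-complete
#' subsample (participants with any undefined ALM, e.g. um proportion, or a
#' missing covariate are removed from every model, so `n_used` is identical
#' across models); (d) ROC curves and AUCs of all models' fitted
#' probabilities.
#'
#' @param cohort Data frame with `participant_id`, a group column, covariate
#'   columns, the seven raw ALM columns ([alm_names()]), and optionally
#'   `score_<alm>` ordinal columns (computed via [recode_alm_table()] on the
#'   whole sample when absent) and clinical score columns.
#' @param group_col Name of the group column.
#' @param case_group Group label treated as the positive (case) class for
#'   classification; all other groups are pooled as controls.
#' @param covariates Covariate columns for the adjusted models, default age
#'   and IQ.
#' @param clinical_cols Optional clinical score columns for the convergent
#'   validity correlations.
#' @param cutoff Classification cutoff, default 0.5.
#' @return Object of class `alm_validation`: list with `group_comparisons`
#'   (data frame), `posthoc` (data frame or NULL), `spearman`, `models`
#'   (named list of [fit_logistic()] results: `baseline`, one per ALM,
#'   `combined`), `model_summary` (data frame), `roc` (named list),
#'   `n_used`, `excluded` (data frame of excluded ids and reasons), `bins`.
#' @export
run_validation <- function(cohort, group_col = "group", case_group = "asd",
                           covariates = c("age", "iq"), clinical_cols = NULL,
                           cutoff = 0.5) {
  stopifnot("participant_id" %in% names(cohort), group_col %in% names(cohort))
  if (anyDuplicated(cohort$participant_id)) {
    stop("inconsistent participant ids: duplicates in cohort table",
         call. = FALSE)
  }
  alms <- intersect(alm_names(), names(cohort))
  if (length(alms) == 0L) stop("cohort table has no ALM columns", call. = FALSE)
  groups <- unique(as.character(cohort[[group_col]]))
  if (length(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (!case_group %in% groups) {
    stop(sprintf("case_group '%s' not present in '%s'", case_group, group_col),
         call. = FALSE)
  }

  # (a) group comparisons on raw ALMs
  comp_rows <- list()
  posthoc_rows <- list()
  for (alm in alms) {
    samples <- split(cohort[[alm]], as.character(cohort[[group_col]]))
    kw <- kruskal_wallis_eta2(samples)
    comp_rows[[alm]] <- data.frame(
      alm = alm, H = kw$H, df = kw$df, p = kw$p, eta2 = kw$eta2, n = kw$n
    )
    if (length(samples) > 2L && kw$p < 0.05) {
      gh <- games_howell(samples)
      gh$alm <- alm
      posthoc_rows[[alm]] <- gh
    }
  }
  group_comparisons <- do.call(rbind, comp_rows)
  rownames(group_comparisons) <- NULL
  posthoc <- if (length(posthoc_rows)) do.call(rbind, posthoc_rows) else NULL

  # (b) convergent validity correlations
  corr_cols <- c(alms, intersect(clinical_cols, names(cohort)))
  spearman <- spearman_matrix(cohort[corr_cols])

  # ordinal scores: use provided score_ columns or fit on the whole sample
  score_cols <- paste0("score_", alms)
  bins <- NULL
  if (!all(score_cols %in% names(cohort))) {
    rec <- recode_alm_table(cohort[c("participant_id", alms)])
    cohort <- merge(cohort[setdiff(names(cohort), score_cols)], rec$scores,
                    by = "participant_id", sort = FALSE)
    bins <- rec$bins
  }

  # (c) one listwise-complete subsample for every model
  model_vars <- c(score_cols, covariates)
  ok <- complete.cases(cohort[model_vars])
  excluded <- data.frame(
    participant_id = cohort$participant_id[!ok],
    reason = vapply(which(!ok), function(i) {
      bad <- model_vars[which(is.na(cohort[i, model_vars]))]
      paste(bad, collapse = ";")
    }, character(1))
  )
  sub <- cohort[ok, , drop = FALSE]
  sub$.case <- as.integer(as.character(sub[[group_col]]) == case_group)
  if (length(unique(sub$.case)) < 2L) {
    stop("listwise-complete subsample does not contain both classes",
         call. = FALSE)
  }

  models <- list(
    baseline = fit_logistic(sub, ".case", covariates = covariates,
                            cutoff = cutoff)
  )
  for (alm in alms) {
    models[[alm]] <- fit_logistic(sub, ".case",
                                  ordinal = paste0("score_", alm),
                                  covariates = covariates, cutoff = cutoff)
  }
  models$combined <- fit_logistic(sub, ".case", ordinal = score_cols,
                                  covariates = covariates, cutoff = cutoff)

  model_summary <- do.call(rbind, lapply(names(models), function(nm) {
    m <- models[[nm]]
    data.frame(
      model = nm, n_used = m$n_used, minus2_loglik = m$minus2_loglik,
      nagelkerke_r2 = m$nagelkerke_r2, accuracy = m$accuracy,
      specificity = m$specificity, sensitivity = m$sensitivity,
      auc = m$auc, separation = m$separation
    )
  }))

  roc <- lapply(models, function(m) roc_auc(m$fitted_probs, m$outcome))

  structure(
    list(
      group_comparisons = group_comparisons, posthoc = posthoc,
      spearman = spearman, models = models, model_summary = model_summary,
      roc = roc, n_used = nrow(sub), excluded = excluded, bins = bins
    ),
    class = "alm_validation"
  )
}

#' @export
print.alm_validation <- function(x, ...) {
  cat(sprintf("<alm_validation> %d participants in classification models (%d excluded)\n",
              x$n_used, nrow(x$excluded)))
  cat("\nGroup comparisons (Kruskal-Wallis):\n")
  print(x$group_comparisons, digits = 4, row.names = FALSE)
  cat("\nClassification models:\n")
  print(x$model_summary, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Overlay ROC curves of all validation models
#'
#' @param validation An `alm_validation` object.
#' @return A ggplot object with one ROC curve per model, labelled with its
#'   AUC.
#' @export
plot_roc <- function(validation) {
  stopifnot(inherits(validation, "alm_validation"))
  dfs <- lapply(names(validation$roc), function(nm) {
    r <- validation$roc[[nm]]
    data.frame(
      model = sprintf("%s (AUC %.3f)", nm, r$auc),
      fpr = c(0, r$fpr, 1), tpr = c(0, r$tpr, 1)
    )
  })
  df <- do.call(rbind, dfs)
  ggplot2::ggplot(df, ggplot2::aes(x = fpr, y = tpr, colour = model)) +
    ggplot2::geom_abline(intercept = 0, slope = 1, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
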