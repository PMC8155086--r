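as_group_list <- function(samples) {
  stopifnot(is.list(samples))
  if (is.null(names(samples)) || any(!nzchar(names(samples)))) {
    names(samples) <- paste0("group", seq_along(samples))
  }
  lapply(samples, function(x) as.numeric(x[!is.na(x)]))
}

#' Kruskal-Wallis group comparison with rank eta-squared
#'
#' Tie-corrected Kruskal-Wallis one-way ANOVA on ranks across k groups, with
#' the rank eta-squared effect size `(H - k + 1) / (n - k)`, reported
#' unclamped (it can be slightly negative under the null).
#'
#' @param samples Named list of k numeric vectors (one per group); `NA`
#'   values are dropped.
#' @return List with `H`, `df`, `p`, `eta2`, `n`, `k`, and `group_stats`
#'   (per-group n, mean, sd).
#' @export
kruskal_wallis_eta2 <- function(samples) {
  samples <- as_group_list(samples)
  if (length(samples) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(lengths(samples) == 0L)) stop("empty group", call. = FALSE)
  x <- unlist(samples, use.names = FALSE)
  g <- factor(rep(names(samples), lengths(samples)), levels = names(samples))
  kt <- kruskal.test(x, g)
  k <- length(samples)
  n <- length(x)
  H <- unname(kt$statistic)
  list(
    H = H, df = k - 1L, p = kt$p.value,
    eta2 = (H - k + 1) / (n - k),
    n = n, k = k,
    group_stats = data.frame(
      group = names(samples), n = lengths(samples),
      mean = vapply(samples, mean, numeric(1)),
      sd = vapply(samples, function(v) if (length(v) > 1) stats::sd(v) else NA_real_,
                  numeric(1)),
      row.names = NULL
    )
  )
}

#' Games-Howell pairwise post-hoc comparisons
#'
#' Pairwise contrasts robust to unequal variances: for each pair of groups,
#' the mean difference, its unpooled standard error, Welch-Satterthwaite
#' degrees of freedom, and a p-value from the studentized range distribution
#' with `k` means (`ptukey`).
#'
#' @param samples Named list of k numeric vectors, each with at least 3
#'   non-missing values.
#' @return Data frame with one row per unordered pair: `group1`, `group2`,
#'   `diff` (mean of group1 minus mean of group2), `se`, `df`, `p`.
#' @export
games_howell <- function(samples) {
  samples <- as_group_list(samples)
  k <- length(samples)
  if (k < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(lengths(samples) < 3L)) {
    stop("each group needs at least 3 values for Games-Howell", call. = FALSE)
  }
  nm <- names(samples)
  n <- lengths(samples)
  m <- vapply(samples, mean, numeric(1))
  v <- vapply(samples, var, numeric(1))
  rows <- list()
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      se2 <- v[i] / n[i] + v[j] / n[j]
      d <- m[i] - m[j]
      if (se2 == 0) {
        p <- if (d == 0) 1 else 0
        df <- n[i] + n[j] - 2
      } else {
        df <- se2^2 / ((v[i] / n[i])^2 / (n[i] - 1) + (v[j] / n[j])^2 / (n[j] - 1))
        q <- abs(d) / sqrt(se2 / 2)
        p <- ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        group1 = nm[i], group2 = nm[j], diff = unname(d),
        se = sqrt(se2), df = unname(df), p = unname(p)
      )
    }
  }
  do.call(rbind, rows)
}

#' Spearman rank correlation matrix with pairwise-complete handling
#'
#' Tie-corrected Spearman rho (Pearson on midranks) and two-sided asymptotic
#' p-values for every pair of columns, using pairwise-complete observations.
#' Cells with fewer than 3 complete pairs are flagged undefined (`NA`).
#'
#' @param table Data frame or matrix of numeric variables (columns) by
#'   participants (rows).
#' @return List with `variables`, `rho`, `p`, and `n` (complete pairs), each
#'   matrix symmetric with unit/NA diagonal conventions.
#' @export
spearman_matrix <- function(table) {
  df <- as.data.frame(table)
  vars <- names(df)
  k <- length(vars)
  rho <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  p <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  nmat <- matrix(0L, k, k, dimnames = list(vars, vars))
  for (i in seq_len(k)) {
    rho[i, i] <- 1
    p[i, i] <- 0
    nmat[i, i] <- sum(!is.na(df[[i]]))
    if (i == k) break
    for (j in (i + 1L):k) {
      ok <- !is.na(df[[i]]) & !is.na(df[[j]])
      nmat[i, j] <- nmat[j, i] <- sum(ok)
      if (sum(ok) < 3L) next
      ct <- suppressWarnings(
        cor.test(df[[i]][ok], df[[j]][ok], method = "spearman", exact = FALSE)
      )
      rho[i, j] <- rho[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  list(variables = vars, rho = rho, p = p, n = nmat)
}

nagelkerke_r2 <- function(model, null_model) {
  n <- length(model$y)
  ll1 <- as.numeric(logLik(model))
  ll0 <- as.numeric(logLik(null_model))
  cs <- 1 - exp(2 / n * (ll0 - ll1))
  denom <- 1 - exp(2 / n * ll0)
  if (denom == 0) return(0)
  cs / denom
}

#' Fit a logistic classification model with the battery's reporting
#'
#' Maximum-likelihood binary logistic regression where each ordinal ALM
#' score enters as a 4-level categorical predictor (level 1 reference, so a
#' joint Wald test on 3 degrees of freedom; levels unobserved in the sample
#' are dropped, reducing the df accordingly) and covariates (age, IQ, ...)
#' enter linearly (Wald df = 1). Reports -2 log-likelihood, Nagelkerke
#' pseudo-R-squared, in-sample accuracy/sensitivity/specificity at the given
#' cutoff, and the AUC of the fitted probabilities. Quasi-complete
#' separation is flagged, not silently ignored.
#'
#' @param data Data frame containing all variables; must be complete (no
#'   `NA`) in the used columns — listwise exclusion happens upstream.
#' @param outcome Name of the 0/1 (or logical) outcome column.
#' @param ordinal Character vector of ordinal ALM score columns (values in
#'   1-4), possibly empty.
#' @param covariates Character vector of numeric covariate columns, possibly
#'   empty (an empty model is the intercept-only null model).
#' @param cutoff Classification cutoff on the predicted probability;
#'   prediction is positive when the probability is `>= cutoff`.
#' @return Object of class `alm_logit`: list with `coefficients` (data
#'   frame: term, estimate, se), `wald` (data frame: predictor, chi2, df,
#'   p), `minus2_loglik`, `nagelkerke_r2`, `accuracy`, `sensitivity`,
#'   `specificity`, `auc`, `n_used`, `separation`, `fitted_probs`,
#'   `outcome`, `model`.
#' @export
fit_logistic <- function(data, outcome, ordinal = character(0),
                         covariates = character(0), cutoff = 0.5) {
  used <- c(outcome, ordinal, covariates)
  stopifnot(all(used %in% names(data)))
  if (anyNA(data[used])) {
    stop("data contain missing values; apply listwise exclusion upstream",
         call. = FALSE)
  }
  y <- as.integer(data[[outcome]])
  stopifnot(all(y %in% c(0L, 1L)))
  df <- data.frame(.y = y)
  # unused score levels are dropped so small samples stay estimable; the
  # joint Wald df is then (observed levels - 1), i.e. 3 when all four occur
  for (v in ordinal) df[[v]] <- droplevels(factor(data[[v]], levels = 1:4))
  for (v in covariates) df[[v]] <- as.numeric(data[[v]])
  rhs <- if (length(c(ordinal, covariates)) == 0L) "1" else
    paste(c(ordinal, covariates), collapse = " + ")
  fml <- stats::as.formula(paste(".y ~", rhs))

  separation <- FALSE
  fit <- withCallingHandlers(
    glm(fml, data = df, family = binomial()),
    warning = function(w) {
      msg <- conditionMessage(w)
      if (grepl("fitted probabilities numerically 0 or 1", msg) ||
          grepl("algorithm did not converge", msg)) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (!fit$converged || any(abs(coef(fit)[!is.na(coef(fit))]) > 15)) {
    separation <- TRUE
  }
  if (anyNA(coef(fit))) {
    stop("rank-deficient design: aliased coefficients in logistic model",
         call. = FALSE)
  }
  null_fit <- glm(.y ~ 1, data = df, family = binomial())

  cf <- coef(summary(fit))
  coefs <- data.frame(term = rownames(cf), estimate = cf[, 1], se = cf[, 2],
                      row.names = NULL)
  V <- vcov(fit)
  wald_rows <- lapply(c(ordinal, covariates), function(v) {
    idx <- if (v %in% ordinal) {
      which(startsWith(rownames(cf), v))
    } else {
      which(rownames(cf) == v)
    }
    b <- cf[idx, 1]
    W <- as.numeric(t(b) %*% solve(V[idx, idx, drop = FALSE]) %*% b)
    data.frame(predictor = v, chi2 = W, df = length(idx),
               p = pchisq(W, df = length(idx), lower.tail = FALSE))
  })
  wald <- if (length(wald_rows)) do.call(rbind, wald_rows) else
    data.frame(predictor = character(0), chi2 = numeric(0), df = integer(0),
               p = numeric(0))

  probs <- unname(fit$fitted.values)
  cm <- classification_metrics(probs, y, cutoff = cutoff)
  auc <- if (length(unique(y)) == 2L) roc_auc(probs, y)$auc else NA_real_

  structure(
    list(
      coefficients = coefs, wald = wald,
      minus2_loglik = -2 * as.numeric(logLik(fit)),
      nagelkerke_r2 = nagelkerke_r2(fit, null_fit),
      accuracy = cm$accuracy, sensitivity = cm$sensitivity,
      specificity = cm$specificity, auc = auc,
      n_used = nrow(df), separation = separation,
      fitted_probs = probs, outcome = y, model = fit
    ),
    class = "alm_logit"
  )
}

#' @export
print.alm_logit <- function(x, ...) {
  cat(sprintf(
    "<alm_logit> n = %d, -2LL = %.3f, Nagelkerke R2 = %.3f, AUC = %.3f%s\n",
    x$n_used, x$minus2_loglik, x$nagelkerke_r2, x$auc,
    if (x$separation) " [separation flagged]" else ""
  ))
  cat(sprintf("  accuracy %.3f, sensitivity %.3f, specificity %.3f\n",
              x$accuracy, x$sensitivity, x$specificity))
  if (nrow(x$wald)) {
    cat("  Wald tests:\n")
    for (i in seq_len(nrow(x$wald))) {
      cat(sprintf("    %-20s chi2(%d) = %7.3f, p = %.4f\n", x$wald$predictor[i],
                  x$wald$df[i], x$wald$chi2[i], x$wald$p[i]))
    }
  }
  invisible(x)
}

#' In-sample classification metrics at a probability cutoff
#'
#' Predictions are positive when the probability is at or above the cutoff
#' (ties classify positive).
#'
#' @param probs Predicted probabilities.
#' @param labels 0/1 outcome labels.
#' @param cutoff Probability cutoff, default 0.5.
#' @return List with `accuracy`, `sensitivity` (true positive rate),
#'   `specificity` (true negative rate).
#' @export
classification_metrics <- function(probs, labels, cutoff = 0.5) {
  labels <- as.integer(labels)
  pred <- as.integer(probs >= cutoff)
  tp <- sum(pred == 1L & labels == 1L)
  tn <- sum(pred == 0L & labels == 0L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  list(
    accuracy = (tp + tn) / length(labels),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_
  )
}

#' Empirical ROC curve and AUC
#'
#' Receiver operating characteristic over all observed score thresholds,
#' with the AUC equal to the probability of concordance (ties credited 1/2).
#'
#' @param scores Predicted probabilities or scores (higher = more likely
#'   positive).
#' @param labels 0/1 outcome labels; both classes must be present.
#' @return List with `thresholds`, `tpr`, `fpr` (each ordered so the curve
#'   runs from (0,0) to (1,1)) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) {
    stop("both classes must be present to compute a ROC curve", call. = FALSE)
  }
  r <- pROC::roc(response = labels, predictor = as.numeric(scores),
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  ord <- order(1 - r$specificities, r$sensitivities)
  list(
    thresholds = r$thresholds[ord],
    tpr = r$sensitivities[ord],
    fpr = 1 - r$specificities[ord],
    auc = as.numeric(r$auc)
  )
}
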