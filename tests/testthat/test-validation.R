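test_that("Kruskal-Wallis H and rank eta-squared match the hand formulas", {
  kw <- kruskal_wallis_eta2(list(a = 1:3, b = 4:6, c = 7:9))
  expect_equal(kw$H, 7.2)
  expect_equal(kw$eta2, (7.2 - 3 + 1) / (9 - 3))
  expect_equal(kw$df, 2L)
  kw0 <- kruskal_wallis_eta2(list(a = c(1, 2, 3), b = c(1, 2, 3),
                                  c = c(1, 2, 3)))
  expect_equal(kw0$H, 0)
  expect_error(kruskal_wallis_eta2(list(a = 1:3)), "2 groups")
  expect_error(kruskal_wallis_eta2(list(a = 1:3, b = numeric(0))), "empty")
})

test_that("H is invariant under strictly monotone transforms", {
  set.seed(5)
  x <- list(a = rnorm(12), b = rnorm(12, 1), c = rnorm(12, 2))
  h1 <- kruskal_wallis_eta2(x)$H
  h2 <- kruskal_wallis_eta2(lapply(x, exp))$H
  h3 <- kruskal_wallis_eta2(lapply(x, function(v) 5 * v - 2))$H
  expect_equal(h2, h1)
  expect_equal(h3, h1)
})

test_that("Games-Howell contrasts behave on identical, separated, and k=3 designs", {
  gh0 <- games_howell(list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4)))
  expect_equal(gh0$diff, 0)
  expect_equal(gh0$p, 1, tolerance = 1e-12)

  set.seed(8)
  a <- rnorm(30); b <- rnorm(30, 10)
  gh <- games_howell(list(a = a, b = b))
  expect_lt(gh$p, 0.001)
  # permutation oracle agrees on rejection
  obs <- abs(mean(a) - mean(b))
  pool <- c(a, b)
  perm <- replicate(499, {
    idx <- sample.int(60, 30)
    abs(mean(pool[idx]) - mean(pool[-idx]))
  })
  expect_lt(mean(c(perm, obs) >= obs), 0.01)

  gh3 <- games_howell(list(a = rnorm(10), b = rnorm(10), c = rnorm(10)))
  expect_equal(nrow(gh3), 3L)
  expect_error(games_howell(list(a = 1:2, b = 1:5)), "at least 3")
})

test_that("Spearman matrix is tie-corrected, symmetric, and pairwise-complete", {
  s <- spearman_matrix(data.frame(x = 1:3, y = c(10, 20, 30),
                                  z = c(30, 20, 10)))
  expect_equal(s$rho["x", "y"], 1)
  expect_equal(s$rho["x", "z"], -1)
  expect_equal(s$rho, t(s$rho))

  set.seed(9)
  x <- sample(rep(1:5, 6)); y <- x + rnorm(30)
  s2 <- spearman_matrix(data.frame(x = x, y = y))
  expect_equal(s2$rho["x", "y"], cor(rank(x), rank(y)))  # midrank Pearson

  d <- data.frame(x = c(1, 2, NA, NA, NA), y = c(NA, NA, 3, 2, 1),
                  w = c(5, 1, 4, 2, 3))
  s3 <- spearman_matrix(d)
  expect_true(is.na(s3$rho["x", "y"]))  # < 3 complete pairs
  expect_false(is.na(s3$rho["y", "w"]))

  # invariance under a monotone transform of one variable
  set.seed(10)
  u <- runif(20); v <- runif(20)
  expect_equal(spearman_matrix(data.frame(u = exp(u), v = v))$rho["u", "v"],
               spearman_matrix(data.frame(u = u, v = v))$rho["u", "v"])
})

test_that("logistic fits match an independent IRLS oracle to 1e-6", {
  set.seed(2024)
  n <- 20
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  d$y <- rbinom(n, 1, plogis(0.5 + 0.8 * d$x1 - 0.5 * d$x2))
  fit <- fit_logistic(d, "y", covariates = c("x1", "x2"))
  X <- cbind(1, d$x1, d$x2)
  expect_equal(fit$coefficients$estimate, irls_logistic(X, d$y),
               tolerance = 1e-6)

  # ordinal predictor expands to 3 reference-coded contrasts (Wald df = 3)
  set.seed(2025)
  d2 <- data.frame(score = sample(1:4, 60, replace = TRUE), age = rnorm(60))
  d2$y <- rbinom(60, 1, plogis(-1 + 0.7 * (d2$score - 1)))
  fit2 <- fit_logistic(d2, "y", ordinal = "score", covariates = "age")
  w <- fit2$wald
  expect_equal(w$df[w$predictor == "score"], 3L)
  expect_equal(w$df[w$predictor == "age"], 1L)
  X2 <- cbind(1, d2$score == 2, d2$score == 3, d2$score == 4, d2$age)
  expect_equal(fit2$coefficients$estimate, irls_logistic(X2, d2$y),
               tolerance = 1e-6)
})

test_that("null model has zero Nagelkerke R2; separation and aliasing are surfaced", {
  d <- data.frame(y = rep(0:1, 10))
  f0 <- fit_logistic(d, "y")
  expect_equal(f0$nagelkerke_r2, 0)
  expect_equal(f0$minus2_loglik, -2 * (20 * log(0.5)))

  d1 <- data.frame(y = rep(0:1, each = 10), x = c(1:10, 21:30))
  f1 <- fit_logistic(d1, "y", covariates = "x")
  expect_true(f1$separation)

  d2 <- data.frame(y = rep(0:1, 10), x = rnorm(20))
  d2$x2 <- 2 * d2$x
  expect_error(fit_logistic(d2, "y", covariates = c("x", "x2")),
               "rank-deficient")
  d3 <- d2; d3$x[1] <- NA
  expect_error(fit_logistic(d3, "y", covariates = "x"), "missing values")
})

test_that("deviance and Nagelkerke R2 are monotone under nesting", {
  set.seed(31)
  d <- data.frame(x = rnorm(40), noise = rnorm(40))
  d$y <- rbinom(40, 1, plogis(d$x))
  f1 <- fit_logistic(d, "y", covariates = "x")
  f2 <- fit_logistic(d, "y", covariates = c("x", "noise"))
  expect_lte(f2$minus2_loglik, f1$minus2_loglik + 1e-8)
  expect_gte(f2$nagelkerke_r2, f1$nagelkerke_r2 - 1e-8)
})

test_that("classification metrics follow the >= cutoff convention", {
  m <- classification_metrics(c(0, 0, 1, 1), c(0, 0, 1, 1))
  expect_equal(unlist(m), c(accuracy = 1, sensitivity = 1, specificity = 1))
  m2 <- classification_metrics(rep(0.5, 8), rep(0:1, 4))
  expect_equal(m2$sensitivity, 1)
  expect_equal(m2$specificity, 0)
  # TP=3 FN=1 TN=2 FP=2
  probs <- c(0.9, 0.8, 0.7, 0.2, 0.1, 0.3, 0.6, 0.8)
  labs <- c(1, 1, 1, 1, 0, 0, 0, 0)
  m3 <- classification_metrics(probs, labs)
  expect_equal(m3$sensitivity, 0.75)
  expect_equal(m3$specificity, 0.5)
  expect_equal(m3$accuracy, 0.625)
})

test_that("ROC/AUC equals concordance with tie credit and behaves at the edges", {
  r <- roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(r$auc, 0.75)
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0, 0, 1, 1))$auc, 1)
  expect_equal(roc_auc(rep(0.3, 10), rep(0:1, 5))$auc, 0.5)
  expect_error(roc_auc(runif(5), rep(1, 5)), "both classes")
  # complement property
  set.seed(12)
  s <- runif(30); l <- rbinom(30, 1, 0.5)
  expect_equal(roc_auc(s, l)$auc + roc_auc(1 - s, l)$auc, 1)
  # curve monotone from (0,0) to (1,1)
  expect_true(all(diff(r$tpr) >= 0))
  expect_true(all(diff(r$fpr) >= 0))
})
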