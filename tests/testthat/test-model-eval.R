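test_that("OLS fits match the normal-equations oracle", {
  set.seed(1)
  n <- 10
  X <- matrix(rnorm(n * 3), n, dimnames = list(NULL, c("a", "b", "c")))
  y <- rnorm(n)
  d <- data.frame(subject_id = as.character(1:n), X, SPO2 = y,
                  check.names = FALSE, stringsAsFactors = FALSE)
  fit <- fit_model1(d)
  Xs <- cbind(1, scale(X))
  beta <- solve(t(Xs) %*% Xs, t(Xs) %*% y)
  expect_equal(unname(fit$coefficients), unname(drop(beta)),
               tolerance = 1e-10)
  expect_equal(fit$rss, sum((y - Xs %*% beta)^2), tolerance = 1e-10)
  ## exactly linear response: zero residuals
  d2 <- d; d2$SPO2 <- 2 * X[, 1] - X[, 2] + 5
  fit2 <- fit_model1(d2)
  expect_lt(fit2$rss, 1e-20)
  expect_equal(fit2$rmse_in, 0, tolerance = 1e-10)
})

test_that("model 2 regresses SpO2 change on the other composites", {
  set.seed(2)
  n <- 300
  scores <- matrix(rnorm(n * 4), n,
                   dimnames = list(NULL, paste0("LV", 1:4)))
  blocks <- data.frame(trait = c("T1", "T2", "SPO2", "T4"),
                       block_id = 1:4)
  y <- scores[, "LV2"] * -0.5 + rnorm(n, sd = 0.3)
  d <- data.frame(subject_id = as.character(1:n), SPO2 = y,
                  stringsAsFactors = FALSE)
  fit <- fit_model2(scores, d, blocks)
  expect_equal(fit$p_predictors, 3) # LV3 (the SpO2 block) excluded
  expect_false("LV3" %in% names(fit$coefficients))
  expect_lt(fit$coefficients[["LV2"]], 0) # sign recovery
  ## orthonormal predictors, y = one of them
  d3 <- d; d3$SPO2 <- scores[, "LV4"]
  fit3 <- fit_model2(scores, d3, blocks)
  ## per-SD coefficient of the generating composite; residuals vanish
  expect_equal(unname(fit3$coefficients["LV4"]), sd(scores[, "LV4"]),
               tolerance = 0.02)
  expect_lt(fit3$rss, 1e-20)
})

test_that("aliased predictors are dropped with a warning", {
  set.seed(3)
  n <- 40
  X <- matrix(rnorm(n * 2), n, dimnames = list(NULL, c("a", "b")))
  d <- data.frame(subject_id = as.character(1:n), X,
                  c = X[, 1] + X[, 2], SPO2 = rnorm(n),
                  check.names = FALSE, stringsAsFactors = FALSE)
  expect_warning(fit <- fit_model1(d), "aliased")
  expect_equal(fit$p_predictors, 2)
})

test_that("information criteria follow the Gaussian-likelihood formula", {
  ## hand-computed case: n = 20, rss = 5, p = 2
  ic <- information_criteria(rss = 5, n = 20, p_predictors = 2)
  base <- 20 * log(2 * pi * 5 / 20) + 20
  expect_equal(unname(ic["aic"]), base + 2 * 4)
  expect_equal(unname(ic["bic"]), base + log(20) * 4)
  ## equal rss and p give equal criteria; rss = 0 errors
  expect_equal(information_criteria(rss = 3, n = 15, p_predictors = 4),
               information_criteria(rss = 3, n = 15, p_predictors = 4))
  expect_error(information_criteria(rss = 0, n = 10, p_predictors = 1),
               "positive")
})

test_that("criteria agree with stats::AIC and are convention-invariant", {
  set.seed(4)
  n <- 50
  X <- matrix(rnorm(n * 3), n, dimnames = list(NULL, c("a", "b", "c")))
  y <- X[, 1] + rnorm(n)
  d <- data.frame(subject_id = as.character(1:n), X, SPO2 = y,
                  check.names = FALSE, stringsAsFactors = FALSE)
  fit <- fit_model1(d)
  lmfit <- lm(y ~ scale(X))
  expect_equal(unname(fit$aic), AIC(lmfit), tolerance = 1e-8)
  expect_equal(unname(fit$bic), BIC(lmfit), tolerance = 1e-8)
  ## only differences matter: an additive constant cancels between models
  ic_a <- information_criteria(rss = 4, n = 30, p_predictors = 2)
  ic_b <- information_criteria(rss = 7, n = 30, p_predictors = 5)
  diff_ml <- (30 * log(4 / 30) + 2 * 4) - (30 * log(7 / 30) + 2 * 7)
  expect_equal(unname(ic_a["aic"] - ic_b["aic"]), diff_ml,
               tolerance = 1e-10)
})

test_that("a pure-noise predictor raises BIC", {
  set.seed(5)
  wins <- replicate(40, {
    n <- 60
    x <- rnorm(n); y <- x + rnorm(n)
    f1 <- ols_fit(cbind(x = x), y)
    f2 <- ols_fit(cbind(x = x, junk = rnorm(n)), y)
    f2$bic > f1$bic
  })
  expect_gt(mean(wins), 0.8)
})

test_that("cross-validation is exact on deterministic responses", {
  set.seed(6)
  n <- 40
  X <- matrix(rnorm(n * 2), n)
  y <- 3 * X[, 1] - X[, 2] + 1
  cv <- cross_validate(X, y, folds = 5, seed = 2)
  expect_equal(max(cv$mse), 0, tolerance = 1e-18)
  expect_equal(length(cv$mse), 5)
  ## partitions reproduce under the seed and can be reused
  cv2 <- cross_validate(X, y, folds = 5, seed = 2)
  expect_identical(cv$assignment, cv2$assignment)
  cv3 <- cross_validate(X, y + rnorm(n), folds = cv$assignment)
  expect_identical(cv3$assignment, cv$assignment)
  expect_error(cross_validate(X, y, folds = 30), "fewer folds")
})

test_that("leave-one-out errors satisfy the PRESS identity", {
  set.seed(7)
  n <- 15
  X <- matrix(rnorm(n * 3), n)
  y <- X[, 1] + rnorm(n)
  loo <- cross_validate(X, y, folds = "loo")
  Xd <- cbind(1, scale(X))
  H <- Xd %*% solve(t(Xd) %*% Xd) %*% t(Xd)
  e <- y - H %*% y
  press <- (e / (1 - diag(H)))^2
  expect_equal(loo$mse, drop(press), tolerance = 1e-8)
  expect_equal(loo$rmse, sqrt(mean(press)), tolerance = 1e-8)
})

test_that("ten-fold and leave-one-out errors agree on smooth problems", {
  set.seed(8)
  n <- 400
  X <- matrix(rnorm(n * 5), n)
  y <- X %*% runif(5) + rnorm(n)
  cv <- cross_validate(X, y, folds = 10, seed = 1)
  loo <- cross_validate(X, y, folds = "loo")
  expect_equal(mean(cv$mse), mean(loo$mse), tolerance = 0.1 * mean(loo$mse))
})

test_that("paired model comparison matches exact and reference results", {
  ## model 1 strictly worse in all 10 folds: one-sided p = 1/2^10
  m1 <- seq(2, 3, length.out = 10)
  m2 <- m1 - 0.5
  out <- compare_models(m1, m2)
  expect_equal(out$p, 1 / 1024)
  ## equal errors: p = 1 with warning
  expect_warning(eq <- compare_models(m1, m1), "zero")
  expect_equal(eq$p, 1)
  ## agreement with stats::wilcox.test in exact mode
  set.seed(9)
  a <- rnorm(12); b <- rnorm(12, 0.4)
  got <- compare_models(a, b)
  ref <- wilcox.test(a, b, paired = TRUE, alternative = "greater")
  expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  expect_error(compare_models(1:3, 1:4), "equal length")
})

test_that("fold-label permutation leaves the paired comparison unchanged", {
  set.seed(10)
  n <- 200
  X <- matrix(rnorm(n * 6), n)
  y <- X[, 1] + rnorm(n)
  cv1 <- cross_validate(X, y, folds = 10, seed = 3)
  cv2 <- cross_validate(X[, 1:3], y, folds = cv1$assignment)
  p_orig <- compare_models(cv1$mse, cv2$mse)$p
  perm <- sample(10)
  p_perm <- compare_models(cv1$mse[perm], cv2$mse[perm])$p
  expect_equal(p_orig, p_perm)
})

test_that("the composite model beats the raw-trait model end to end", {
  res <- small_cohort(seed = 2)
  al <- suppressMessages(align_signs(res$delta, res$cohort$true_blocks))
  fit <- fit_plspm(al, build_path_model(res$cohort$true_blocks))
  mc <- evaluate_models(res$delta, fit$scores, res$cohort$true_blocks,
                        seed = 5)
  expect_equal(unname(mc$winner_by),
               rep("model2_composites", 4))
  expect_equal(length(mc$cv1), 10)
  expect_equal(length(mc$loo1), nrow(res$delta))
})
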