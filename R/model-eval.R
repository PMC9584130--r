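#' Ordinary least squares with standardized predictors
#'
#' Internal backbone of the two oxygen-saturation models: OLS of `y` on
#' standardized predictors (so coefficients are per predictor SD), with
#' rank-deficiency handling (aliased columns dropped with a warning).
#'
#' @param X Predictor matrix.
#' @param y Response vector.
#' @return List of class `regression_fit`: `coefficients` (incl.
#'   `(Intercept)`), `fitted`, `residuals`, `rss`, `n`, `p_predictors`,
#'   `aic`, `bic`, `rmse_in`, `scaling` (centers/sds used), `X` (the
#'   standardized design without intercept), `y`.
#' @keywords internal
ols_fit <- function(X, y) {
  X <- as.matrix(X)
  keep_sd <- apply(X, 2, stats::sd)
  if (any(keep_sd == 0)) {
    warning("dropping constant predictor(s): ",
            paste(colnames(X)[keep_sd == 0], collapse = ", "))
    X <- X[, keep_sd > 0, drop = FALSE]
    keep_sd <- keep_sd[keep_sd > 0]
  }
  centers <- colMeans(X)
  Xs <- scale(X)
  qr_ <- qr(cbind(`(Intercept)` = 1, Xs))
  if (qr_$rank < ncol(Xs) + 1L) {
    aliased <- colnames(Xs)[setdiff(seq_len(ncol(Xs)),
                                    qr_$pivot[seq_len(qr_$rank)] - 1L)]
    aliased <- aliased[!is.na(aliased)]
    warning("dropping aliased predictor(s): ",
            paste(aliased, collapse = ", "))
    Xs <- Xs[, setdiff(colnames(Xs), aliased), drop = FALSE]
  }
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, Xs), y)
  rss <- sum(fit$residuals^2)
  n <- length(y)
  p <- ncol(Xs)
  ic <- information_criteria(rss = rss, n = n, p_predictors = p)
  structure(list(coefficients = fit$coefficients,
                 fitted = fit$fitted.values, residuals = fit$residuals,
                 rss = rss, n = n, p_predictors = p,
                 aic = ic["aic"], bic = ic["bic"],
                 rmse_in = sqrt(rss / n),
                 scaling = list(center = centers, sd = keep_sd),
                 X = Xs, y = y),
            class = "regression_fit")
}

#' Model 1: oxygen-saturation change on raw trait changes
#'
#' OLS of the SpO2 change score on the other 27 trait change scores
#' (standardized). The SpO2 column itself is excluded from the predictors.
#'
#' @param change A change table containing an `SPO2` column.
#' @param spo2 Name of the oxygen-saturation column (default `"SPO2"`).
#' @return A `regression_fit`.
#' @export
fit_model1 <- function(change, spo2 = "SPO2") {
  m <- change_matrix(change)
  if (!spo2 %in% colnames(m)) stop("no ", spo2, " column in change table")
  y <- m[, spo2]
  X <- m[, setdiff(colnames(m), spo2), drop = FALSE]
  if (nrow(X) <= ncol(X) + 2L) stop("need n > predictors + 2")
  ols_fit(X, y)
}

#' Model 2: oxygen-saturation change on composite phenotypes
#'
#' OLS of the SpO2 change score on the composite-phenotype scores of all
#' blocks except the SpO2 block itself.
#'
#' @param scores LV score matrix from [fit_plspm()].
#' @param change The change table supplying the SpO2 response.
#' @param blocks The `block_structure` matching `scores` (used to locate
#'   and exclude the SpO2 block).
#' @param spo2 Name of the oxygen-saturation trait.
#' @return A `regression_fit`.
#' @export
fit_model2 <- function(scores, change, blocks, spo2 = "SPO2") {
  m <- change_matrix(change)
  if (!spo2 %in% colnames(m)) stop("no ", spo2, " column in change table")
  y <- m[, spo2]
  spo2_block <- blocks$block_id[blocks$trait == spo2]
  if (length(spo2_block) != 1L) stop("cannot locate the ", spo2, " block")
  X <- as.matrix(scores)
  drop_col <- paste0("LV", spo2_block)
  X <- X[, setdiff(colnames(X), drop_col), drop = FALSE]
  if (nrow(X) <= ncol(X) + 2L) stop("need n > predictors + 2")
  ols_fit(X, y)
}

#' Gaussian-likelihood information criteria
#'
#' `aic = n log(2 pi rss / n) + n + 2 (p + 2)` and
#' `bic = n log(2 pi rss / n) + n + log(n) (p + 2)`, counting `p`
#' coefficients plus intercept plus error variance. The same convention is
#' applied to every model, so only differences are meaningful; the values
#' agree with [stats::AIC()]/[stats::BIC()] on `lm` fits.
#'
#' @param fit A `regression_fit`, or leave `NULL` and supply `rss`, `n`,
#'   `p_predictors` directly.
#' @param rss,n,p_predictors Components when `fit` is not given.
#' @return Named vector `c(aic, bic)`.
#' @export
information_criteria <- function(fit = NULL, rss = fit$rss, n = fit$n,
                                 p_predictors = fit$p_predictors) {
  if (rss <= 0) stop("rss must be positive for a finite criterion")
  base <- n * log(2 * pi * rss / n) + n
  npar <- p_predictors + 2
  c(aic = base + 2 * npar, bic = base + log(n) * npar)
}

#' Cross-validated prediction errors
#'
#' Random `folds`-fold partition (from `seed`) or leave-one-out; each fold
#' is predicted from an OLS fit on the remaining subjects. Returns the
#' per-fold mean squared prediction errors (per-observation squared errors
#' for leave-one-out) together with the fold assignment, so that the same
#' partition can be reused for a competing model (pass the returned
#' `assignment` as `folds`).
#'
#' @param X Predictor matrix.
#' @param y Response vector.
#' @param folds Number of folds, `"loo"`, or an integer vector of fold
#'   labels to reuse a partition.
#' @param seed Seed for the fold assignment.
#' @return List: `mse` (per fold/observation), `rmse`
#'   (`sqrt(mean(all squared errors))`), `assignment`, `folds`.
#' @export
cross_validate <- function(X, y, folds = 10L, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  loo <- identical(folds, "loo")
  if (loo) {
    assignment <- seq_len(n)
  } else if (length(folds) == n && is.numeric(folds)) {
    assignment <- as.integer(folds)
  } else {
    k <- as.integer(folds)
    if (k < 2L) stop("folds must be >= 2 or \"loo\"")
    assignment <- with_seed(seed, sample(rep(seq_len(k), length.out = n)))
  }
  Xs <- scale(X)
  Xd <- cbind(1, Xs)
  if (!loo && min(table(assignment)) <= ncol(X))
    stop("fold(s) with <= p observations; use fewer folds")
  sq_err <- numeric(n)
  for (f in unique(assignment)) {
    test <- assignment == f
    if (sum(!test) <= ncol(Xd))
      stop("a fold leaves too few observations to fit; use fewer folds")
    fit <- stats::lm.fit(Xd[!test, , drop = FALSE], y[!test])
    beta <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
    pred <- Xd[test, , drop = FALSE] %*% beta
    sq_err[test] <- (y[test] - pred)^2
  }
  mse <- if (loo) sq_err else
    vapply(split(sq_err, assignment), mean, numeric(1))
  list(mse = unname(mse), rmse = sqrt(mean(sq_err)),
       assignment = assignment, folds = if (loo) "loo" else
         length(unique(assignment)))
}

#' Paired one-sided comparison of model errors
#'
#' One-sided Wilcoxon signed-rank test on the paired error differences
#' `m1_errors - m2_errors`, alternative "greater" (model 1 errors located
#' above model 2's). Exact for up to 25 pairs, normal approximation with
#' continuity correction beyond.
#'
#' @param m1_errors,m2_errors Equal-length paired error vectors (e.g.
#'   per-fold MSEs on a shared partition).
#' @return List `statistic`, `p`.
#' @export
compare_models <- function(m1_errors, m2_errors) {
  if (length(m1_errors) != length(m2_errors))
    stop("paired error vectors must have equal length")
  d <- m1_errors - m2_errors
  if (all(d == 0)) {
    warning("all error differences are zero; p = 1")
    return(list(statistic = 0, p = 1))
  }
  st <- signed_rank_test(d, alternative = "greater")
  list(statistic = st$statistic, p = st$p)
}

#' Compare the raw-trait and composite-phenotype models
#'
#' Fits Model 1 (27 raw trait changes) and Model 2 (13 composite
#' phenotypes) for the SpO2 change response, and compares them by AIC,
#' BIC, `folds`-fold cross-validated RMSE and leave-one-out RMSE, with
#' paired one-sided signed-rank tests on the shared-partition fold MSEs
#' (and per-observation leave-one-out squared errors).
#'
#' @param change Change table (with `SPO2`).
#' @param scores LV score matrix.
#' @param blocks `block_structure` matching `scores`.
#' @param folds Folds for the k-fold comparison (default 10).
#' @param seed Seed for the fold partition.
#' @param spo2 Oxygen-saturation trait name.
#' @return List of class `model_comparison`: `fit1`, `fit2`, `table`
#'   (AIC/BIC/CV-RMSE/LOO-RMSE per model), `wilcoxon_p_cv`,
#'   `wilcoxon_p_loo`, `cv1`, `cv2`, `loo1`, `loo2`, `winner_by`.
#' @export
#' @examples
#' coh <- generate_cohort(default_cohort_config())
#' delta <- compute_changes(coh$baseline, coh$chronic)
#' fit <- fit_plspm(align_signs(delta, coh$true_blocks),
#'                  build_path_model(coh$true_blocks))
#' mc <- evaluate_models(delta, fit$scores, coh$true_blocks)
#' mc$table
evaluate_models <- function(change, scores, blocks, folds = 10L,
                            seed = 1L, spo2 = "SPO2") {
  fit1 <- fit_model1(change, spo2 = spo2)
  fit2 <- fit_model2(scores, change, blocks, spo2 = spo2)
  cv1 <- cross_validate(fit1$X, fit1$y, folds = folds, seed = seed)
  cv2 <- cross_validate(fit2$X, fit2$y, folds = cv1$assignment)
  loo1 <- cross_validate(fit1$X, fit1$y, folds = "loo")
  loo2 <- cross_validate(fit2$X, fit2$y, folds = "loo")
  w_cv <- compare_models(cv1$mse, cv2$mse)
  w_loo <- compare_models(loo1$mse, loo2$mse)
  tab <- data.frame(
    model = c("model1_raw_traits", "model2_composites"),
    aic = c(fit1$aic, fit2$aic), bic = c(fit1$bic, fit2$bic),
    cv_rmse = c(cv1$rmse, cv2$rmse), loo_rmse = c(loo1$rmse, loo2$rmse),
    stringsAsFactors = FALSE)
  winner <- vapply(c("aic", "bic", "cv_rmse", "loo_rmse"), function(cn)
    tab$model[which.min(tab[[cn]])], character(1))
  structure(list(fit1 = fit1, fit2 = fit2, table = tab,
                 wilcoxon_p_cv = w_cv$p, wilcoxon_p_loo = w_loo$p,
                 cv1 = cv1$mse, cv2 = cv2$mse,
                 loo1 = loo1$mse, loo2 = loo2$mse,
                 winner_by = winner),
            class = "model_comparison")
}
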