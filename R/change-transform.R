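#' Compute per-subject change scores between two phases
#'
#' Forms the change table `chronic - baseline` on the subjects shared by the
#' two phase tables. Subjects present in only one phase are dropped with a
#' message; subjects with any missing trait value in either phase are
#' likewise dropped (complete-case analysis). The trait sets must match.
#'
#' @param baseline,chronic Phase tables: data.frames with a `subject_id`
#'   column followed by identical trait columns.
#' @return A data.frame with `subject_id` and one change column per trait,
#'   rows ordered as in `baseline`.
#' @export
#' @examples
#' coh <- generate_cohort(default_cohort_config(n_subjects = 50))
#' delta <- compute_changes(coh$baseline, coh$chronic)
#' mean(delta$HGB) # close to the planted mean HGB rise
compute_changes <- function(baseline, chronic) {
  for (df in list(baseline, chronic))
    if (!"subject_id" %in% names(df))
      stop("phase tables must have a subject_id column")
  tb <- setdiff(names(baseline), "subject_id")
  tcr <- setdiff(names(chronic), "subject_id")
  if (!setequal(tb, tcr))
    stop("trait sets differ between phases: ",
         paste(union(setdiff(tb, tcr), setdiff(tcr, tb)), collapse = ", "))
  if (anyDuplicated(baseline$subject_id) || anyDuplicated(chronic$subject_id))
    stop("duplicate subject_id within a phase table")
  shared <- intersect(baseline$subject_id, chronic$subject_id)
  dropped <- union(setdiff(baseline$subject_id, shared),
                   setdiff(chronic$subject_id, shared))
  if (length(shared) == 0L) stop("no subjects shared between phases")
  if (length(dropped))
    message("dropping ", length(dropped),
            " subject(s) present in only one phase: ",
            paste(utils::head(dropped, 5L), collapse = ", "),
            if (length(dropped) > 5L) ", ..." else "")
  b <- baseline[match(shared, baseline$subject_id), tb, drop = FALSE]
  c2 <- chronic[match(shared, chronic$subject_id), tb, drop = FALSE]
  cc <- stats::complete.cases(b) & stats::complete.cases(c2)
  if (!all(cc)) {
    message("dropping ", sum(!cc), " subject(s) with missing trait values")
    shared <- shared[cc]
    b <- b[cc, , drop = FALSE]
    c2 <- c2[cc, , drop = FALSE]
  }
  if (nrow(b) == 0L) stop("no complete-case subjects shared between phases")
  out <- data.frame(subject_id = shared,
                    as.data.frame(as.matrix(c2) - as.matrix(b)),
                    stringsAsFactors = FALSE, check.names = FALSE)
  names(out) <- c("subject_id", tb)
  rownames(out) <- NULL
  out
}

#' Extract the numeric change matrix from a change table
#' @param change A change table from [compute_changes()].
#' @return Numeric matrix, subjects x traits, rownames = subject ids.
#' @keywords internal
change_matrix <- function(change) {
  m <- as.matrix(change[, setdiff(names(change), "subject_id"), drop = FALSE])
  rownames(m) <- change$subject_id
  storage.mode(m) <- "double"
  m
}

#' Wilcoxon signed-rank test for paired phase measurements
#'
#' Two-sided (or one-sided) signed-rank test on the paired differences
#' `x_chronic - x_baseline`. Zero differences are dropped (the Wilcoxon
#' convention) and tied absolute differences receive average ranks. For up
#' to 25 non-zero pairs the exact null distribution of the rank sum is
#' computed by dynamic programming over the (doubled, hence integer)
#' mid-ranks, which remains exact under ties; for larger samples the normal
#' approximation with tie correction and a 0.5 continuity correction is
#' used. `type = "rank_sum"` instead performs the unpaired two-sample
#' rank-sum (Mann-Whitney) test via [stats::wilcox.test()], preserving the
#' alternative reading of a "rank-sum test, paired = true" protocol line.
#'
#' @param x_baseline,x_chronic Equal-length numeric vectors (>= 5 pairs for
#'   the signed-rank test).
#' @param alternative One of `"two.sided"`, `"greater"`, `"less"`; for the
#'   signed-rank test, `"greater"` means the differences
#'   `x_chronic - x_baseline` are located above zero.
#' @param type `"signed_rank"` (default) or `"rank_sum"`.
#' @return A list with `statistic` (the positive-rank sum V) and `p`.
#' @export
#' @examples
#' paired_test(c(1, 2, 3, 4, 5, 6), c(2, 3, 4, 5, 6, 7))$p # 2/2^6
paired_test <- function(x_baseline, x_chronic,
                        alternative = c("two.sided", "greater", "less"),
                        type = c("signed_rank", "rank_sum")) {
  alternative <- match.arg(alternative)
  type <- match.arg(type)
  if (length(x_baseline) != length(x_chronic))
    stop("phase vectors must have equal length")
  if (type == "rank_sum") {
    wt <- stats::wilcox.test(x_chronic, x_baseline,
                             alternative = alternative, exact = FALSE,
                             correct = TRUE)
    return(list(statistic = unname(wt$statistic), p = wt$p.value))
  }
  if (length(x_baseline) < 5L)
    stop("signed-rank test requires at least 5 pairs")
  signed_rank_test(x_chronic - x_baseline, alternative = alternative)
}

#' Wilcoxon signed-rank test on a vector of differences
#'
#' @param d Numeric vector of paired differences.
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @param exact_max Largest number of non-zero differences for which the
#'   exact distribution is used (default 25).
#' @return A list with `statistic` (positive-rank sum V), `p`, `n_used`
#'   (non-zero differences) and `method` (`"exact"` or `"normal"`).
#' @export
signed_rank_test <- function(d, alternative = c("two.sided", "greater",
                                                "less"),
                             exact_max = 25L) {
  alternative <- match.arg(alternative)
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warning("all differences are zero; p = 1")
    return(list(statistic = 0, p = 1, n_used = 0L, method = "degenerate"))
  }
  r <- rank(abs(d)) # average ranks for ties
  V <- sum(r[d > 0])
  if (n <= exact_max) {
    ## exact null distribution over 2^n sign assignments via DP on the
    ## doubled ranks (integers even under midranks)
    r2 <- as.integer(round(2 * r))
    tot <- sum(r2)
    f <- numeric(tot + 1L)
    f[1L] <- 1
    for (ri in r2) {
      shifted <- c(numeric(ri), f[seq_len(tot + 1L - ri)])
      f <- f + shifted
    }
    f <- f / 2^n
    v2 <- as.integer(round(2 * V))
    p_le <- sum(f[seq_len(v2 + 1L)])
    p_ge <- sum(f[(v2 + 1L):(tot + 1L)])
    p <- switch(alternative,
                two.sided = min(1, 2 * min(p_le, p_ge)),
                greater = p_ge,
                less = p_le)
    return(list(statistic = V, p = p, n_used = n, method = "exact"))
  }
  mu <- n * (n + 1) / 4
  tie_tab <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(tie_tab^3 - tie_tab) / 48
  cc <- 0.5
  z <- switch(alternative,
              two.sided = (V - mu - sign(V - mu) * cc) / sqrt(sigma2),
              greater = (V - mu - cc) / sqrt(sigma2),
              less = (V - mu + cc) / sqrt(sigma2))
  p <- switch(alternative,
              two.sided = 2 * stats::pnorm(-abs(z)),
              greater = stats::pnorm(z, lower.tail = FALSE),
              less = stats::pnorm(z))
  list(statistic = V, p = min(1, p), n_used = n, method = "normal")
}

#' Univariate screening of trait changes
#'
#' Runs the paired test of [paired_test()] per trait on the two phase
#' tables and applies a Bonferroni correction over the traits tested.
#'
#' @param baseline,chronic Aligned phase tables (same subjects and traits).
#' @param alpha Family-wise significance level (default 0.05).
#' @inheritParams paired_test
#' @return A data.frame with one row per trait: `trait`, `statistic`,
#'   `p_raw`, `p_bonferroni` (`min(1, m * p_raw)`) and `significant`
#'   (`p_bonferroni < alpha`).
#' @export
screen_traits <- function(baseline, chronic, alpha = 0.05,
                          type = c("signed_rank", "rank_sum")) {
  type <- match.arg(type)
  shared <- intersect(baseline$subject_id, chronic$subject_id)
  traits <- setdiff(names(baseline), "subject_id")
  if (!setequal(traits, setdiff(names(chronic), "subject_id")))
    stop("trait sets differ between phases")
  b <- baseline[match(shared, baseline$subject_id), , drop = FALSE]
  c2 <- chronic[match(shared, chronic$subject_id), , drop = FALSE]
  m <- length(traits)
  res <- lapply(traits, function(tr) {
    tt <- paired_test(b[[tr]], c2[[tr]], type = type)
    data.frame(trait = tr, statistic = tt$statistic, p_raw = tt$p,
               p_bonferroni = min(1, m * tt$p),
               stringsAsFactors = FALSE, check.names = FALSE)
  })
  out <- do.call(rbind, res)
  out$significant <- out$p_bonferroni < alpha
  rownames(out) <- NULL
  out
}
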