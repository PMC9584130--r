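#' Default synthetic-cohort configuration
#'
#' Builds the configuration of the default synthetic acclimatization cohort:
#' 883 subjects, the 28 traits of [trait_catalog()] with their published
#' baseline/chronic moments, the 14-block composite-phenotype structure, and
#' two hidden subgroups (proportions 508/883 and 375/883) whose means differ
#' on the red-cell (block 5), hemoglobin-concentration (block 6) and
#' platelet (block 7) blocks by 1.5 within-group factor SDs.
#'
#' Within-block correlation targets are full signed matrices per block (see
#' `block_cor_catalog()`), planted so each block's Cronbach alpha and
#' leading correlation eigenvalues reproduce the published
#' unidimensionality diagnostics. Change-score SDs are derived from the
#' baseline and chronic SDs under a baseline-chronic correlation
#' `phase_r` (default 0.5, a typical test-retest correlation for
#' physiological measurements; the published tables leave it undetermined).
#'
#' A weak negative coupling `lls_spo2_r = -0.07` between the Lake Louise
#' score and SpO2 change scores is planted, matching the effect size implied
#' by the published LLS regression coefficient (p = 0.04 at n = 883).
#'
#' @param n_subjects Number of subjects.
#' @param phase_r Baseline-chronic correlation used to derive change-score
#'   SDs from the two phase SDs.
#' @param group_shift Mean shift (within-group factor SD units) applied to
#'   blocks `shift_blocks` in group 2, along each block's first principal
#'   correlation axis.
#' @param shift_blocks Integer ids of the shifted blocks.
#' @param group_proportions Two group proportions (must sum to 1).
#' @param cross_block_r Optional equicorrelation between block factors
#'   (default 0; must not exceed `cross_block_r_max`).
#' @param cross_block_r_max Documented upper bound for cross-block
#'   correlations (the published composite phenotypes correlate mostly
#'   below 0.2, and typically below 0.1).
#' @param lls_spo2_r Planted change-score correlation between LLS and SpO2.
#' @param noise_sd Extra independent Gaussian noise (as a fraction of the
#'   standardized change score) mixed into every trait; default 0.
#' @param seed Integer seed stored in the config (used by
#'   [generate_cohort()] unless overridden).
#' @return An object of class `cohort_config`.
#' @seealso [generate_cohort()]
#' @export
default_cohort_config <- function(n_subjects = 883,
                                  phase_r = 0.5,
                                  group_shift = 1.5,
                                  shift_blocks = c(5L, 6L, 7L),
                                  group_proportions = c(508, 375) / 883,
                                  cross_block_r = 0,
                                  cross_block_r_max = 0.1,
                                  lls_spo2_r = -0.07,
                                  noise_sd = 0,
                                  seed = 1L) {
  tc <- trait_catalog()
  traits <- data.frame(
    name = tc$name,
    baseline_mean = tc$baseline_mean,
    baseline_sd = tc$baseline_sd,
    change_mean = tc$chronic_mean - tc$baseline_mean,
    change_sd = sqrt(tc$baseline_sd^2 + tc$chronic_sd^2 -
                       2 * phase_r * tc$baseline_sd * tc$chronic_sd),
    block_id = tc$block_id,
    stringsAsFactors = FALSE, check.names = FALSE
  )
  cfg <- list(
    n_subjects = as.integer(n_subjects),
    traits = traits,
    block_cor = block_cor_catalog(),
    n_groups = 2L,
    group_proportions = group_proportions,
    group_shift = group_shift,
    shift_blocks = as.integer(shift_blocks),
    cross_block_r = cross_block_r,
    cross_block_r_max = cross_block_r_max,
    lls_spo2_r = lls_spo2_r,
    noise_sd = noise_sd,
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

#' Validate a cohort configuration
#'
#' @param cfg A `cohort_config` object.
#' @return `cfg`, invisibly, or an error describing the violated invariant.
#' @keywords internal
validate_cohort_config <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  if (cfg$n_subjects < 1L)
    stop("n_subjects must be positive, got ", cfg$n_subjects)
  if (abs(sum(cfg$group_proportions) - 1) > 1e-8)
    stop("group_proportions must sum to 1 (got ",
         sum(cfg$group_proportions), ")")
  if (any(cfg$group_proportions <= 0))
    stop("group_proportions must all be positive")
  if (any(cfg$traits$baseline_sd <= 0))
    stop("baseline_sd must be > 0 for all traits")
  if (any(cfg$traits$change_sd < 0))
    stop("change_sd must be >= 0 for all traits")
  blocks <- sort(unique(cfg$traits$block_id))
  if (!identical(blocks, seq_along(blocks)))
    stop("block ids must be contiguous 1..B")
  for (b in names(cfg$block_cor)) {
    C <- cfg$block_cor[[b]]
    if (any(abs(C) > 1) || any(diag(C) != 1) || !isSymmetric(C))
      stop("block_cor[[", b, "]] is not a correlation matrix")
    if (any(abs(C[upper.tri(C)]) >= 1))
      stop("block_cor[[", b, "]] has |r| >= 1 off-diagonal")
    ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8)
      stop("block_cor[[", b, "]] is not positive semi-definite")
  }
  if (cfg$cross_block_r < 0 || cfg$cross_block_r > cfg$cross_block_r_max)
    stop("cross_block_r must lie in [0, cross_block_r_max]")
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0")
  invisible(cfg)
}

#' Build an equicorrelated cohort configuration
#'
#' Convenience constructor for property tests and degenerate-case studies:
#' every multi-trait block is planted with a single within-block correlation
#' `within_block_r` instead of the calibrated matrices of
#' [default_cohort_config()].
#'
#' @inheritParams default_cohort_config
#' @param within_block_r Common within-block correlation, in `[0, 1]`.
#' @return A `cohort_config`.
#' @export
uniform_cohort_config <- function(within_block_r,
                                  n_subjects = 883,
                                  group_shift = 1.5,
                                  noise_sd = 0, seed = 1L, ...) {
  cfg <- default_cohort_config(n_subjects = n_subjects,
                               group_shift = group_shift,
                               noise_sd = noise_sd, seed = seed, ...)
  for (b in names(cfg$block_cor)) {
    m <- nrow(cfg$block_cor[[b]])
    C <- matrix(within_block_r, m, m, dimnames = dimnames(cfg$block_cor[[b]]))
    diag(C) <- 1
    cfg$block_cor[[b]] <- C
  }
  cfg$lls_spo2_r <- 0
  validate_cohort_config(cfg)
  cfg
}

#' Generate a seeded two-phase synthetic cohort
#'
#' Simulates baseline and chronic phase tables whose change scores carry the
#' configured block-correlation structure and hidden subgroups.
#'
#' Per block, standardized change scores are drawn from the planted signed
#' correlation matrix; in the shifted blocks, group 2 is displaced along the
#' block's first principal correlation axis by `group_shift` within-group
#' factor SDs, and the within-group correlations are calibrated so that the
#' *mixture* (whole-cohort) correlations still equal the planted targets.
#' Baselines are independent Gaussians with the configured trait moments,
#' and the chronic phase is `baseline + change`. Identical seeds give
#' identical tables.
#'
#' @param cfg A `cohort_config`, e.g. [default_cohort_config()].
#' @param seed Optional seed overriding `cfg$seed`.
#' @return A list with components `baseline` and `chronic` (data.frames with
#'   `subject_id` followed by the 28 trait columns), `true_blocks` (a
#'   data.frame `trait`, `block_id`) and `true_groups` (a data.frame
#'   `subject_id`, `group`).
#' @export
#' @examples
#' coh <- generate_cohort(default_cohort_config(n_subjects = 100))
#' dim(coh$baseline)
#' table(coh$true_groups$group)
generate_cohort <- function(cfg = default_cohort_config(), seed = NULL) {
  validate_cohort_config(cfg)
  if (is.null(seed)) seed <- cfg$seed
  set.seed(seed)
  tr <- cfg$traits
  n <- cfg$n_subjects
  p <- nrow(tr)
  blocks <- tr$block_id
  B <- max(blocks)

  ## group labels: sizes from proportions (largest-remainder), then shuffled
  sizes <- floor(n * cfg$group_proportions)
  rem <- n - sum(sizes)
  if (rem > 0) {
    frac <- n * cfg$group_proportions - sizes
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    sizes[add] <- sizes[add] + 1
  }
  g <- sample(rep(seq_along(sizes), sizes))
  pq <- prod(sizes / n) # p1*p2 for the two-group default

  ## optional equicorrelated coupling between block factors
  G <- if (cfg$cross_block_r > 0) rnorm(n) else NULL
  couple <- function(x) {
    if (is.null(G)) return(x)
    rho <- cfg$cross_block_r
    sqrt(rho) * G + sqrt(1 - rho) * x
  }

  z <- matrix(0, n, p)
  lls_col <- which(blocks == 12L)
  spo2_col <- which(blocks == 13L)
  for (b in seq_len(B)) {
    idx <- which(blocks == b)
    m <- length(idx)
    if (b == 12L) next # generated jointly with block 13
    if (b == 13L && cfg$lls_spo2_r != 0) {
      r <- cfg$lls_spo2_r
      Cj <- matrix(c(1, r, r, 1), 2, 2)
      x <- matrix(rnorm(n * 2), n, 2) %*% chol(Cj)
      z[, lls_col] <- couple(x[, 1])
      z[, spo2_col] <- couple(x[, 2])
      next
    }
    if (m == 1L) {
      z[, idx] <- couple(rnorm(n))
      next
    }
    C <- cfg$block_cor[[as.character(b)]]
    if (b %in% cfg$shift_blocks && cfg$group_shift != 0) {
      e1 <- eigen(C, symmetric = TRUE)
      lam <- e1$vectors[, 1] * sqrt(e1$values[1]) # signed PC1 loadings
      if (sum(lam) < 0) lam <- -lam
      sj <- cfg$group_shift * lam                 # per-trait shift
      vj <- 1 + pq * sj^2                         # mixture variances
      ## within-group correlations calibrated so the mixture matches C
      C0 <- sweep(sweep(C, 1, sqrt(vj), "*"), 2, sqrt(vj), "*") -
        pq * (sj %o% sj)
      diag(C0) <- 1
      x <- matrix(rnorm(n * m), n, m) %*% chol(C0) +
        outer(as.numeric(g == 2L), sj)
      x <- sweep(x, 2, sqrt(vj), "/")
    } else {
      x <- matrix(rnorm(n * m), n, m) %*% chol(C)
    }
    for (k in seq_len(m)) z[, idx[k]] <- couple(x[, k])
  }
  if (cfg$noise_sd > 0) {
    z <- (z + cfg$noise_sd * matrix(rnorm(n * p), n, p)) /
      sqrt(1 + cfg$noise_sd^2)
  }

  delta <- sweep(sweep(z, 2, tr$change_sd, "*"), 2, tr$change_mean, "+")
  baseline <- sapply(seq_len(p), function(j)
    rnorm(n, tr$baseline_mean[j], tr$baseline_sd[j]))
  chronic <- baseline + delta

  ids <- sprintf("S%04d", seq_len(n))
  as_phase <- function(m) {
    df <- data.frame(subject_id = ids, m, stringsAsFactors = FALSE,
                     check.names = FALSE)
    names(df) <- c("subject_id", tr$name)
    df
  }
  list(
    baseline = as_phase(baseline),
    chronic = as_phase(chronic),
    true_blocks = data.frame(trait = tr$name, block_id = tr$block_id,
                             stringsAsFactors = FALSE, check.names = FALSE),
    true_groups = data.frame(subject_id = ids, group = g,
                             stringsAsFactors = FALSE)
  )
}

#' Write a generated cohort to CSV files
#'
#' Writes the two phase tables, the true block structure and the true group
#' labels as plain CSV (columns as produced by [generate_cohort()]).
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    baseline = file.path(dir, "baseline.csv"),
    chronic = file.path(dir, "chronic.csv"),
    blocks = file.path(dir, "true_blocks.csv"),
    groups = file.path(dir, "true_groups.csv")
  )
  utils::write.csv(cohort$baseline, paths["baseline"], row.names = FALSE)
  utils::write.csv(cohort$chronic, paths["chronic"], row.names = FALSE)
  utils::write.csv(cohort$true_blocks, paths["blocks"], row.names = FALSE)
  utils::write.csv(cohort$true_groups, paths["groups"], row.names = FALSE)
  invisible(paths)
}

#' Read a phase table from CSV
#'
#' @param path CSV file with a `subject_id` column followed by trait columns.
#' @return A data.frame with `subject_id` as character.
#' @export
read_phase_table <- function(path) {
  if (!file.exists(path)) stop("phase table not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"subject_id" %in% names(df))
    stop("phase table ", path, " lacks a subject_id column")
  df$subject_id <- as.character(df$subject_id)
  df
}
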