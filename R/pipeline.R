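#' Pipeline configuration
#'
#' Assembles all tunables of the five analysis stages with their defaults.
#' A configuration can also be read from a YAML or JSON file holding any
#' subset of these fields (see [read_pipeline_config()]).
#'
#' @param baseline,chronic Paths to the two phase CSVs (ignored when
#'   `synthetic = TRUE`).
#' @param out_dir Directory for stage artifacts.
#' @param synthetic Generate the input cohort with
#'   [default_cohort_config()] instead of reading files.
#' @param blocks_file Optional user-supplied block-structure CSV (columns
#'   `trait`, `block_id`); skips block discovery.
#' @param k_nn,affinity_mode,sig_level,laplacian,self_loop,k_max Trait
#'   clustering controls, see [discover_blocks()].
#' @param plspm_tol,plspm_max_iter,plspm_scheme PLSPM controls.
#' @param target Optional target block for a star path model (default
#'   saturated).
#' @param kmax_subjects Largest subject-cluster count for the majority
#'   rule.
#' @param gap_b Gap-statistic reference sets.
#' @param folds Cross-validation folds.
#' @param paired_test_type `"signed_rank"` or `"rank_sum"` for screening.
#' @param seeds Named integer seeds, one per stochastic stage:
#'   `cohort`, `blocks`, `groups`, `cv`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(baseline = NULL, chronic = NULL,
                            out_dir = "phenoblocks_out",
                            synthetic = is.null(baseline),
                            blocks_file = NULL,
                            k_nn = 2L, affinity_mode = "recip_rank",
                            sig_level = 0.01, laplacian = "sym",
                            self_loop = 0.25, k_max = NULL,
                            plspm_tol = 1e-6, plspm_max_iter = 100L,
                            plspm_scheme = "centroid", target = NULL,
                            kmax_subjects = 10L, gap_b = 20L,
                            folds = 10L,
                            paired_test_type = "signed_rank",
                            seeds = c(cohort = 1L, blocks = 1L,
                                      groups = 1L, cv = 1L)) {
  cfg <- as.list(environment())
  stopifnot(all(c("cohort", "blocks", "groups", "cv") %in% names(seeds)),
            all(seeds == as.integer(seeds)))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path A `.yaml`/`.yml` (requires the yaml package) or `.json`
#'   file whose top-level fields override [pipeline_config()] defaults.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the yaml package")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(vals$seeds)) vals$seeds <- unlist(vals$seeds)
  do.call(pipeline_config, vals)
}

#' Run the composite-phenotype pipeline end to end
#'
#' Executes changes -> screening -> block discovery -> PLSPM scoring ->
#' subject heterogeneity -> model comparison, writing one artifact per
#' stage into `cfg$out_dir`:
#'
#' * `delta.csv` - change table
#' * `screen.csv` - univariate screening results
#' * `blocks.csv`, `spectrum.csv` - discovered structure and Laplacian
#'   spectrum
#' * `scores.csv`, `loadings.csv`, `unidim.csv` - composite scores and
#'   diagnostics
#' * `groups.csv`, `hetero.json` - subject groups, index votes,
#'   silhouettes, per-LV tests, correlation comparisons
#' * `model_comparison.json` - AIC/BIC/CV table and signed-rank p-values
#'
#' A stage failure aborts with the stage name; artifacts of completed
#' stages are retained. With identical configuration (and seeds) the
#' artifact set is byte-identical across runs.
#'
#' @param cfg A `pipeline_config`.
#' @return Invisibly, a list with the main in-memory results.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage [", name, "] failed: ", conditionMessage(e),
           call. = FALSE))
  }
  log_line <- function(...) message("[phenoblocks] ", ...)

  ## stage 1: inputs and change table
  truth <- NULL
  inputs <- stage("input", {
    if (isTRUE(cfg$synthetic)) {
      log_line("generating synthetic cohort (seed ",
               cfg$seeds[["cohort"]], ")")
      coh <- generate_cohort(default_cohort_config(),
                             seed = cfg$seeds[["cohort"]])
      truth <<- coh[c("true_blocks", "true_groups")]
      coh[c("baseline", "chronic")]
    } else {
      list(baseline = read_phase_table(cfg$baseline),
           chronic = read_phase_table(cfg$chronic))
    }
  })
  delta <- stage("changes", {
    d <- compute_changes(inputs$baseline, inputs$chronic)
    utils::write.csv(d, file.path(cfg$out_dir, "delta.csv"),
                     row.names = FALSE)
    d
  })
  stage("screen", {
    sc <- screen_traits(inputs$baseline, inputs$chronic,
                        type = cfg$paired_test_type)
    utils::write.csv(sc, file.path(cfg$out_dir, "screen.csv"),
                     row.names = FALSE)
    log_line(sum(sc$significant), "/", nrow(sc),
             " traits significant after Bonferroni")
  })

  ## stage 2: block structure
  blocks <- stage("blocks", {
    if (!is.null(cfg$blocks_file)) {
      b <- utils::read.csv(cfg$blocks_file, check.names = FALSE,
                           stringsAsFactors = FALSE)
      stopifnot(all(c("trait", "block_id") %in% names(b)))
      utils::write.csv(b, file.path(cfg$out_dir, "blocks.csv"),
                       row.names = FALSE)
      b
    } else {
      bd <- discover_blocks(delta, k_nn = cfg$k_nn,
                            mode = cfg$affinity_mode,
                            sig_level = cfg$sig_level,
                            laplacian = cfg$laplacian,
                            self_loop = cfg$self_loop,
                            k_max = cfg$k_max,
                            seed = cfg$seeds[["blocks"]])
      log_line("eigengap selected ", bd$k, " trait blocks (knn ",
               cfg$k_nn, ", ", cfg$affinity_mode, ")")
      utils::write.csv(bd$blocks, file.path(cfg$out_dir, "blocks.csv"),
                       row.names = FALSE)
      utils::write.csv(
        data.frame(index = seq_along(bd$embedding$values),
                   eigenvalue = bd$embedding$values),
        file.path(cfg$out_dir, "spectrum.csv"), row.names = FALSE)
      bd$blocks
    }
  })

  ## stage 3: composite phenotypes
  fit <- stage("plspm", {
    aligned <- align_signs(delta, blocks)
    model <- build_path_model(blocks, target = cfg$target)
    f <- fit_plspm(aligned, model, tol = cfg$plspm_tol,
                   max_iter = cfg$plspm_max_iter,
                   scheme = cfg$plspm_scheme)
    utils::write.csv(
      data.frame(subject_id = delta$subject_id, f$scores,
                 check.names = FALSE),
      file.path(cfg$out_dir, "scores.csv"), row.names = FALSE)
    utils::write.csv(
      data.frame(trait = names(f$loadings), loading = f$loadings,
                 weight = f$weights,
                 block_id = blocks$block_id[match(names(f$loadings),
                                                  blocks$trait)]),
      file.path(cfg$out_dir, "loadings.csv"), row.names = FALSE)
    utils::write.csv(unidimensionality(delta, blocks),
                     file.path(cfg$out_dir, "unidim.csv"),
                     row.names = FALSE)
    f
  })

  ## stage 4: subject heterogeneity
  hetero <- stage("groups", {
    sel <- select_k_majority(fit$scores,
                             k_range = 2:cfg$kmax_subjects,
                             seed = cfg$seeds[["groups"]],
                             gap_b = cfg$gap_b)
    ga <- kmeans_subjects(fit$scores, sel$k,
                          seed = cfg$seeds[["groups"]])
    log_line("majority rule chose k = ", sel$k, " subject groups (",
             paste(ga$sizes, collapse = "/"), ")")
    utils::write.csv(
      data.frame(subject_id = delta$subject_id, group = ga$labels),
      file.path(cfg$out_dir, "groups.csv"), row.names = FALSE)
    sil <- silhouette_report(fit$scores, ga$labels)
    res <- list(k = sel$k, votes = as.list(sel$votes),
                sizes = ga$sizes, silhouette_mean = sil$mean)
    if (sel$k == 2L) {
      res$lv_tests <- group_lv_tests(fit$scores, ga$labels)
      res$correlation_comparison <-
        groupwise_correlation_matrices(fit$scores, ga$labels)$comparison
    }
    jsonlite::write_json(res, file.path(cfg$out_dir, "hetero.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    res
  })

  ## stage 5: model comparison
  mc <- stage("models", {
    m <- evaluate_models(delta, fit$scores, blocks, folds = cfg$folds,
                         seed = cfg$seeds[["cv"]])
    jsonlite::write_json(
      list(table = m$table, wilcoxon_p_cv = m$wilcoxon_p_cv,
           wilcoxon_p_loo = m$wilcoxon_p_loo,
           winner_by = as.list(m$winner_by)),
      file.path(cfg$out_dir, "model_comparison.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    log_line("model comparison written (CV signed-rank p = ",
             signif(m$wilcoxon_p_cv, 3), ")")
    m
  })

  invisible(list(delta = delta, blocks = blocks, fit = fit,
                 hetero = hetero, models = mc, truth = truth))
}
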