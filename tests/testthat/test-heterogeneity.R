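test_that("k-means recovers well-separated clouds deterministically", {
  set.seed(1)
  X <- rbind(matrix(rnorm(120), 60), matrix(rnorm(80, mean = 6), 40))
  truth <- rep(1:2, c(60, 40))
  ga <- kmeans_subjects(X, 2, seed = 3)
  expect_equal(ari(ga$labels, truth), 1)
  ## labels ordered by descending size
  expect_equal(ga$sizes, c(60, 40))
  ## determinism under the seed
  ga2 <- kmeans_subjects(X, 2, seed = 3)
  expect_identical(ga$labels, ga2$labels)
  expect_error(kmeans_subjects(X, 1), "k must be")
  expect_error(kmeans_subjects(X[1:3, ], 5), "smaller")
})

test_that("collinear score columns trigger the multicollinearity guard", {
  set.seed(2)
  a <- rnorm(100)
  X <- cbind(a, a + rnorm(100, sd = 0.2), rnorm(100))
  expect_warning(kmeans_subjects(X, 2, seed = 1), "0.5")
})

test_that("silhouette matches brute force and the cluster package", {
  set.seed(3)
  X <- rbind(matrix(rnorm(20), 10), matrix(rnorm(20, 3), 10))
  cl <- rep(1:2, each = 10)
  sil <- silhouette_report(X, cl)
  expect_equal(sil$widths, brute_silhouette(X, cl), tolerance = 1e-12)
  skip_if_not_installed("cluster")
  ref <- cluster::silhouette(cl, dist(X))
  expect_equal(sil$widths, ref[, "sil_width"], tolerance = 1e-10,
               ignore_attr = TRUE)
  ## far-apart tight clusters approach width 1
  Y <- rbind(matrix(rnorm(8, sd = .01), 4), matrix(rnorm(8, 50, .01), 4))
  expect_gt(silhouette_report(Y, rep(1:2, each = 4))$mean, 0.99)
  ## singleton clusters take width 0 with a warning
  expect_warning(s1 <- silhouette_report(X, c(3, cl[-1])), "singleton")
  expect_equal(s1$widths[1], 0)
})

test_that("an arbitrarily split single cloud has near-zero silhouette", {
  set.seed(4)
  X <- matrix(rnorm(400), 200)
  cl <- rep(1:2, 100)
  expect_lt(abs(silhouette_report(X, cl)$mean), 0.1)
})

test_that("majority rule finds two separated clouds", {
  set.seed(5)
  X <- rbind(matrix(rnorm(300), 150), matrix(rnorm(300, 4), 150))
  ## the separation itself induces |r| > 0.5 between columns, so the
  ## multicollinearity guard fires throughout; that is not under test here
  sel <- suppressWarnings(
    select_k_majority(X, k_range = 2:6, seed = 1, gap_b = 10))
  expect_equal(sel$k, 2)
  expect_gte(sum(sel$votes == 2), length(sel$votes) / 2)
  ## when every index top-scores the same k the majority agrees trivially
  expect_equal(unname(sel$tally[["2"]]), sum(sel$votes == 2))
})

test_that("per-composite group tests detect planted shifts only", {
  set.seed(6)
  n <- 400
  g <- rep(1:2, each = n / 2)
  X <- cbind(LVa = rnorm(n) + 1.5 * (g == 2), LVb = rnorm(n))
  res <- group_lv_tests(X, g)
  expect_lt(res$p[res$lv == "LVa"], 0.05 / 14)
  expect_gt(res$p[res$lv == "LVb"], 0.01)
  expect_error(group_lv_tests(X, rep(1, n)), "two groups")
})

test_that("rank-sum p-values are uniform under the null", {
  set.seed(7)
  p <- replicate(300, {
    g <- rep(1:2, each = 30)
    group_lv_tests(matrix(rnorm(60), ncol = 1), g)$p
  })
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.04)
  expect_gt(ks.test(p, "punif")$p.value, 0.001)
})

test_that("Fisher-z comparison reproduces the published group contrasts", {
  ## equal correlations: no evidence
  eq <- compare_correlations_fisher(0.4, 100, 0.4, 200)
  expect_equal(eq$z_stat, 0)
  expect_equal(eq$p, 1)
  ## LV6-LV13 contrast from printed (rounded) correlations
  fc <- compare_correlations_fisher(0.12, 508, -0.03, 375)
  expect_equal(fc$p, 0.0275, tolerance = 0.005)
  ## LV5-LV7 contrast: order of magnitude 1e-8
  fc2 <- compare_correlations_fisher(-0.2, 508, 0.17, 375)
  expect_lt(fc2$p, 1e-7)
  expect_gt(fc2$p, 1e-9)
  ## antisymmetry under group swap
  a <- compare_correlations_fisher(0.3, 120, 0.1, 80)
  b <- compare_correlations_fisher(0.1, 80, 0.3, 120)
  expect_equal(a$z_stat, -b$z_stat)
  expect_equal(a$p, b$p)
  expect_error(compare_correlations_fisher(1, 50, 0.2, 50), "infinite")
  expect_error(compare_correlations_fisher(0.5, 3, 0.2, 50), "n >= 4")
})

test_that("group-wise correlation matrices behave under copy and flip", {
  set.seed(8)
  n <- 150
  X1 <- matrix(rnorm(n * 3), n, dimnames = list(NULL, c("A", "B", "C")))
  ## group 2 an exact copy of group 1: all comparisons p = 1
  gw <- groupwise_correlation_matrices(rbind(X1, X1),
                                       rep(1:2, each = n))
  expect_true(all(gw$comparison$p == 1))
  expect_true(isSymmetric(gw$cor1) && all(diag(gw$cor1) == 1))
  ## a sign-flipped coupling is flagged at FDR 0.05
  f <- rnorm(n)
  make <- function(s) cbind(A = f + 0.6 * rnorm(n),
                            B = s * f + 0.6 * rnorm(n),
                            C = rnorm(n))
  gw2 <- groupwise_correlation_matrices(rbind(make(1), make(-1)),
                                        rep(1:2, each = n))
  hit <- gw2$comparison[gw2$comparison$lv_a == "A" &
                          gw2$comparison$lv_b == "B", ]
  expect_lt(hit$p_bh, 0.05)
})

test_that("default cohort yields two groups matching the planted labels", {
  res <- small_cohort(seed = 4)
  al <- suppressMessages(align_signs(res$delta, res$cohort$true_blocks))
  fit <- fit_plspm(al, build_path_model(res$cohort$true_blocks))
  ga <- kmeans_subjects(fit$scores, 2, seed = 1)
  acc <- max(mean(ga$labels == res$cohort$true_groups$group),
             mean(ga$labels != res$cohort$true_groups$group))
  expect_gte(acc, 0.85)
  ## the shifted composites carry the separation
  lt <- group_lv_tests(fit$scores, ga$labels)
  expect_lt(min(lt$p[lt$lv %in% c("LV5", "LV6", "LV7")]), 1e-20)
})
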