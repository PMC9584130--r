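test_that("path models are built and validated as specified", {
  blocks <- data.frame(trait = paste0("T", 1:6),
                       block_id = rep(1:3, each = 2))
  star <- build_path_model(blocks, target = 3)
  expect_equal(sum(star$path), 2)          # two arcs into the target
  expect_true(all(which(star$path, arr.ind = TRUE)[, 1] == 3))
  sat <- build_path_model(blocks)
  expect_equal(sum(sat$path), 3)           # saturated lower triangle
  expect_error(build_path_model(blocks, target = 9), "unknown target")
  ## 14 blocks, star into the oxygen-saturation block: 13 arcs
  tb <- generate_cohort(default_cohort_config(n_subjects = 30))$true_blocks
  expect_equal(sum(build_path_model(tb, target = "SPO2")$path), 13)
  ## cyclic user matrices are rejected
  cyc <- matrix(FALSE, 3, 3); cyc[1, 2] <- cyc[2, 1] <- TRUE
  expect_error(build_path_model(blocks, path = cyc), "cyclic")
  cyc2 <- matrix(FALSE, 3, 3)
  cyc2[2, 1] <- cyc2[3, 2] <- cyc2[1, 3] <- TRUE
  expect_error(build_path_model(blocks, path = cyc2), "cyclic")
})

test_that("sign alignment flips exactly the anti-correlated traits", {
  set.seed(5)
  n <- 400
  f <- rnorm(n)
  d <- data.frame(subject_id = as.character(1:n),
                  P1 = f + 0.4 * rnorm(n), P2 = f + 0.4 * rnorm(n),
                  P3 = f + 0.4 * rnorm(n), N1 = -f + 0.4 * rnorm(n),
                  stringsAsFactors = FALSE)
  blocks <- data.frame(trait = c("P1", "P2", "P3", "N1"), block_id = 1L)
  expect_message(al <- align_signs(d, blocks), "N1")
  expect_equal(attr(al, "flipped"), "N1")
  expect_equal(al$N1, -d$N1)
  ## idempotent: a second pass flips nothing
  al2 <- align_signs(al, blocks)
  expect_equal(attr(al2, "flipped"), character(0))
  expect_equal(al2$N1, al$N1)
  ## all-positive blocks are untouched
  al3 <- align_signs(d[, 1:4], blocks[1:3, ])
  expect_equal(attr(al3, "flipped"), character(0))
})

test_that("default cohort alignment flips one anti-correlated pair of LV6", {
  res <- small_cohort(seed = 1)
  al <- suppressMessages(align_signs(res$delta, res$cohort$true_blocks))
  flipped <- attr(al, "flipped")
  ## the hemoglobin-concentration block splits into {MCH, MCHC} vs
  ## {MCV, MPV}; either anti-group may be reported, never a mixture
  lv6 <- sort(intersect(flipped, c("MCV", "MCH", "MCHC", "MPV")))
  expect_true(identical(lv6, c("MCH", "MCHC")) ||
                identical(lv6, c("MCV", "MPV")))
  ## the liver block's ratio trait is anti-correlated with its source
  expect_true("AST/ALT" %in% flipped || "ALT" %in% flipped)
})

test_that("single-trait blocks bypass estimation with unit loadings", {
  set.seed(6)
  d <- data.frame(subject_id = as.character(1:50),
                  A = rnorm(50), B = rnorm(50), C = rnorm(50),
                  stringsAsFactors = FALSE)
  blocks <- data.frame(trait = c("A", "B", "C"), block_id = 1:3)
  fit <- fit_plspm(d, build_path_model(blocks))
  expect_true(fit$converged)
  expect_equal(unname(fit$loadings), rep(1, 3))
  expect_equal(fit$scores[, 1], scale(d$A)[, 1], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("two-trait blocks reach the equal-weight closed form", {
  r <- 0.6
  xy <- exact_cor_pair(r, n = 40)
  z <- scale(xy[, 1] + xy[, 2])[, 1] # symmetric neighbour
  d <- data.frame(subject_id = as.character(1:40),
                  x = xy[, 1], y = xy[, 2], z = z,
                  stringsAsFactors = FALSE)
  blocks <- data.frame(trait = c("x", "y", "z"),
                       block_id = c(1L, 1L, 2L))
  fit <- fit_plspm(d, build_path_model(blocks))
  expect_true(fit$converged)
  expect_equal(unname(fit$loadings[c("x", "y")]),
               rep(sqrt((1 + r) / 2), 2), tolerance = 1e-8)
})

test_that("scores are standardized with majority-positive loadings", {
  res <- small_cohort(seed = 3)
  al <- suppressMessages(align_signs(res$delta, res$cohort$true_blocks))
  fit <- fit_plspm(al, build_path_model(res$cohort$true_blocks))
  expect_true(fit$converged)
  expect_lt(max(abs(colMeans(fit$scores))), 1e-10)
  expect_lt(max(abs(apply(fit$scores, 2, sd) - 1)), 1e-10)
  for (b in unique(fit$blocks$block_id)) {
    ld <- fit$loadings[fit$blocks$trait[fit$blocks$block_id == b]]
    expect_gte(sum(ld > 0), sum(ld < 0))
  }
})

test_that("mode-A loadings recover planted one-factor loadings", {
  ## five-indicator blocks: the composite-vs-factor loading gap
  ## sqrt((1 + 4 r)/5) - 0.85 is ~0.034, inside the 0.05 recovery band
  oc <- one_factor_cohort(n = 2000, n_blocks = 4, mvs_per_block = 5,
                          loading = 0.85, factor_r = 0.3, seed = 8)
  fit <- fit_plspm(oc$delta, build_path_model(oc$blocks))
  expect_true(fit$converged)
  expect_lt(max(abs(fit$loadings - 0.85)), 0.05)
})

test_that("zero-variance manifest variables are refused", {
  d <- data.frame(subject_id = as.character(1:20), A = rnorm(20), B = 1,
                  stringsAsFactors = FALSE)
  blocks <- data.frame(trait = c("A", "B"), block_id = 1:2)
  expect_error(fit_plspm(d, build_path_model(blocks)), "zero-variance")
})

test_that("two-trait unidimensionality identities hold exactly", {
  for (r in c(0, 0.25, 0.5, 0.9)) {
    C <- matrix(c(1, r, r, 1), 2, 2)
    u <- unidim_from_cor(C)
    expect_equal(u$eig_1st, 1 + r, tolerance = 1e-12)
    expect_equal(u$eig_2nd, 1 - r, tolerance = 1e-12)
    expect_equal(u$c_alpha, 2 * r / (1 + r), tolerance = 1e-12)
    lam <- sqrt((1 + r) / 2)
    expect_equal(u$dg_rho, (2 * lam)^2 / ((2 * lam)^2 + 2 * (1 - lam^2)),
                 tolerance = 1e-12)
  }
})

test_that("unidimensionality reports follow the spectral trace identity", {
  res <- small_cohort(seed = 2)
  ud <- unidimensionality(res$delta, res$cohort$true_blocks)
  expect_equal(nrow(ud), 14)
  ## single-trait blocks: exactly (1, 1, 1, 0)
  singles <- ud[ud$n_mvs == 1, ]
  expect_equal(nrow(singles), 6)
  expect_true(all(singles$c_alpha == 1 & singles$dg_rho == 1 &
                    singles$eig_1st == 1 & singles$eig_2nd == 0))
  ## eigenvalues of each block correlation matrix sum to the trait count
  d <- as.matrix(res$delta[, -1])
  for (i in seq_len(nrow(ud))) {
    traits <- strsplit(ud$traits[i], ", ", fixed = TRUE)[[1]]
    ev <- eigen(cor(d[, traits, drop = FALSE]))$values
    expect_equal(sum(ev), ud$n_mvs[i], tolerance = 1e-10)
    expect_equal(ev[1], ud$eig_1st[i], tolerance = 1e-10)
  }
})
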