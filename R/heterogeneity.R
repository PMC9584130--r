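#' Cluster subjects on composite-phenotype scores
#'
#' Best-of-restarts k-means with k-means++ seeding. Each restart draws
#' k-means++ centers and polishes them with [stats::kmeans()]
#' (Hartigan-Wong); the solution with the lowest total within-cluster sum
#' of squares wins. Groups are relabelled by descending size.
#'
#' Before clustering, a multicollinearity guard warns when any pair of
#' score columns correlates above 0.5 in absolute value (k-means on
#' strongly correlated composites can be misleading).
#'
#' @param scores Numeric matrix, subjects x LVs (e.g. `fit$scores`).
#' @param k Number of groups (>= 2, < number of subjects).
#' @param seed Seed for the restarts.
#' @param n_restarts Number of k-means++ restarts (default 25).
#' @return A list of class `group_assignment`: `labels` (1 = largest
#'   group), `centroids`, `inertia` (total within-SS), `sizes`.
#' @export
kmeans_subjects <- function(scores, k = 2L, seed = 1L, n_restarts = 25L) {
  X <- as.matrix(scores)
  n <- nrow(X)
  if (k < 2L) stop("k must be >= 2")
  if (k >= n) stop("k must be smaller than the number of subjects")
  C <- suppressWarnings(stats::cor(X))
  C[!is.finite(C)] <- 0
  diag(C) <- 0
  if (any(abs(C) > 0.5))
    warning("score columns with |r| > 0.5 detected; ",
            "k-means groups may reflect multicollinearity")
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      cen <- kmeanspp_centers(X, k)
      km <- tryCatch(
        stats::kmeans(X, centers = cen, iter.max = 100L),
        error = function(e) NULL)
      if (is.null(km)) next
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
  })
  if (is.null(best)) stop("k-means failed on all restarts")
  ## relabel by descending group size (ties: lower original label first)
  ord <- order(-tabulate(best$cluster, nbins = k), seq_len(k))
  relab <- match(seq_len(k), ord)
  labels <- relab[best$cluster]
  centroids <- best$centers[ord, , drop = FALSE]
  rownames(centroids) <- NULL
  structure(list(labels = labels, centroids = centroids,
                 inertia = best$tot.withinss,
                 sizes = tabulate(labels, nbins = k)),
            class = "group_assignment")
}

#' k-means++ center seeding
#' @keywords internal
kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  centers[1, ] <- X[sample.int(n, 1L), ]
  d2 <- rowSums((X - matrix(centers[1, ], n, ncol(X), byrow = TRUE))^2)
  for (j in seq_len(k - 1L) + 1L) {
    pr <- d2 / sum(d2)
    pick <- sample.int(n, 1L, prob = pr)
    centers[j, ] <- X[pick, ]
    d2 <- pmin(d2, rowSums((X - matrix(centers[j, ], n, ncol(X),
                                       byrow = TRUE))^2))
  }
  centers + matrix(stats::rnorm(length(centers), 0, 1e-10), k) # break ties
}

#' Per-subject silhouette widths
#'
#' Standard silhouette `s(i) = (b - a) / max(a, b)` with Euclidean
#' distances, where `a` is the mean distance to the subject's own cluster
#' and `b` the smallest mean distance to another cluster. Subjects in
#' singleton clusters get `s(i) = 0` (with a warning).
#'
#' @param scores Subjects x LVs matrix.
#' @param labels Integer cluster labels.
#' @return List with `widths` (per subject) and `mean`.
#' @export
silhouette_report <- function(scores, labels) {
  X <- as.matrix(scores)
  n <- nrow(X)
  if (length(labels) != n) stop("labels length mismatch")
  if (length(unique(labels)) < 2L) stop("need at least 2 clusters")
  D <- as.matrix(stats::dist(X))
  sizes <- table(labels)
  if (any(sizes == 1L))
    warning("singleton cluster(s); silhouette set to 0 for their members")
  groups <- split(seq_len(n), labels)
  s <- vapply(seq_len(n), function(i) {
    own <- labels[i]
    if (sizes[as.character(own)] == 1L) return(0)
    a <- mean(D[i, setdiff(groups[[as.character(own)]], i)])
    b <- min(vapply(groups[names(groups) != as.character(own)],
                    function(idx) mean(D[i, idx]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  list(widths = s, mean = mean(s))
}

#' Cluster-validity index roster
#'
#' Computes twelve classical internal validity indices for k-means
#' partitions over a range of cluster counts. Each index carries its
#' optimality rule (maximize or minimize; the gap statistic uses the
#' Tibshirani first-SE rule; Ball-Hall uses the largest successive drop).
#'
#' @param scores Subjects x LVs matrix.
#' @param k_range Candidate cluster counts (default 2:10).
#' @param seed Seed for k-means and the gap-statistic reference sets.
#' @param n_restarts Restarts per k.
#' @param gap_b Reference sets for the gap statistic (default 20).
#' @return A list: `votes` (named integer vector, one optimal k per
#'   index), `table` (index values per k).
#' @export
validity_indices <- function(scores, k_range = 2:10, seed = 1L,
                             n_restarts = 10L, gap_b = 20L) {
  X <- as.matrix(scores)
  n <- nrow(X)
  p <- ncol(X)
  D <- as.matrix(stats::dist(X))
  dv <- D[lower.tri(D)]
  tot_ss <- sum(scale(X, scale = FALSE)^2)

  per_k <- lapply(k_range, function(k) {
    ga <- kmeans_subjects(X, k, seed = seed + k, n_restarts = n_restarts)
    cl <- ga$labels
    cen <- ga$centroids
    W <- ga$inertia
    Bss <- tot_ss - W
    sizes <- tabulate(cl, nbins = k)
    sil <- silhouette_report(X, cl)$mean
    ch <- (Bss / (k - 1)) / (W / (n - k))
    ## dispersion per cluster for Davies-Bouldin
    sig <- vapply(seq_len(k), function(g)
      sqrt(mean(rowSums((X[cl == g, , drop = FALSE] -
                           matrix(cen[g, ], sizes[g], p,
                                  byrow = TRUE))^2))), numeric(1))
    dcen <- as.matrix(stats::dist(cen))
    db <- mean(vapply(seq_len(k), function(g)
      max(vapply(setdiff(seq_len(k), g), function(h)
        (sig[g] + sig[h]) / dcen[g, h], numeric(1))), numeric(1)))
    ## Dunn
    sep <- min(vapply(seq_len(k - 1), function(g)
      min(vapply((g + 1):k, function(h)
        min(D[cl == g, cl == h]), numeric(1))), numeric(1)))
    diam <- max(vapply(seq_len(k), function(g) {
      d <- D[cl == g, cl == g]
      if (length(d) > 1) max(d) else 0
    }, numeric(1)))
    dunn <- sep / diam
    ## C-index and point-biserial and McClain-Rao from within/between dists
    same <- outer(cl, cl, "==")[lower.tri(D)]
    sw <- sum(dv[same]); nw <- as.numeric(sum(same))
    sb <- sum(dv[!same]); nb <- as.numeric(sum(!same))
    dv_sorted <- sort(dv)
    smin <- sum(dv_sorted[seq_len(nw)])
    smax <- sum(dv_sorted[(length(dv) - nw + 1L):length(dv)])
    cindex <- (sw - smin) / (smax - smin)
    mcclain <- (sw / nw) / (sb / nb)
    ptbis <- (sb / nb - sw / nw) * sqrt(nw * nb / length(dv)^2) /
      stats::sd(dv)
    ## PBM
    d_to_cen <- sqrt(rowSums((X - cen[cl, , drop = FALSE])^2))
    e1 <- sum(sqrt(rowSums(scale(X, scale = FALSE)^2)))
    ek <- sum(d_to_cen)
    dmaxc <- max(dcen)
    pbm <- ((e1 / ek) * (dmaxc / k))^2
    ## Ratkowsky-Lance: mean over variables of sqrt(BGSS_j/TSS_j) / sqrt(k)
    bg_j <- vapply(seq_len(p), function(j)
      sum(sizes * (cen[, j] - mean(X[, j]))^2), numeric(1))
    ts_j <- vapply(seq_len(p), function(j)
      sum((X[, j] - mean(X[, j]))^2), numeric(1))
    ratkowsky <- mean(sqrt(bg_j / ts_j)) / sqrt(k)
    ## Xie-Beni: W / (n * min squared center separation)
    xb <- W / (n * min(dcen[upper.tri(dcen)])^2)
    ball <- W / k
    c(sil = sil, ch = ch, db = db, dunn = dunn, cindex = cindex,
      mcclain = mcclain, ptbis = ptbis, pbm = pbm,
      ratkowsky = ratkowsky, xb = xb, ball = ball, W = W)
  })
  tab <- do.call(rbind, per_k)
  rownames(tab) <- k_range

  ## gap statistic over uniform reference sets in the PCA-aligned box
  gap <- gap_statistic(X, k_range, b = gap_b, seed = seed,
                       n_restarts = max(2L, n_restarts %/% 2L))

  votes <- c(
    silhouette = k_range[which.max(tab[, "sil"])],
    calinski_harabasz = k_range[which.max(tab[, "ch"])],
    davies_bouldin = k_range[which.min(tab[, "db"])],
    dunn = k_range[which.max(tab[, "dunn"])],
    c_index = k_range[which.min(tab[, "cindex"])],
    mcclain_rao = k_range[which.min(tab[, "mcclain"])],
    point_biserial = k_range[which.max(tab[, "ptbis"])],
    pbm = k_range[which.max(tab[, "pbm"])],
    ratkowsky_lance = k_range[which.max(tab[, "ratkowsky"])],
    xie_beni = k_range[which.min(tab[, "xb"])],
    ball_hall = k_range[which.max(-diff(c(tot_ss, tab[, "ball"])))],
    gap = gap$k
  )
  list(votes = votes, table = cbind(tab, gap = gap$gap, gap_se = gap$se))
}

#' Tibshirani gap statistic
#' @keywords internal
gap_statistic <- function(X, k_range, b = 20L, seed = 1L,
                          n_restarts = 5L) {
  n <- nrow(X); p <- ncol(X)
  ## PCA-aligned uniform reference (Tibshirani et al. variant b)
  Xc <- scale(X, scale = FALSE)
  sv <- svd(Xc, nu = 0)
  Xp <- Xc %*% sv$v
  rng <- apply(Xp, 2, range)
  logW <- function(M, k, sd_) log(kmeans_subjects(M, k, seed = sd_,
                                                  n_restarts = n_restarts)$inertia)
  obs <- vapply(k_range, function(k) logW(X, k, seed + k), numeric(1))
  ref <- with_seed(seed + 777L, {
    vapply(seq_len(b), function(i) {
      Z <- vapply(seq_len(p), function(j)
        stats::runif(n, rng[1, j], rng[2, j]), numeric(n))
      Z <- Z %*% t(sv$v)
      vapply(k_range, function(k) logW(Z, k, seed + 31L * i + k),
             numeric(1))
    }, numeric(length(k_range)))
  })
  gap <- rowMeans(ref) - obs
  se <- apply(ref, 1, stats::sd) * sqrt(1 + 1 / b)
  ## first k whose gap >= gap[k+1] - se[k+1]
  pick <- length(k_range)
  for (i in seq_len(length(k_range) - 1L)) {
    if (gap[i] >= gap[i + 1L] - se[i + 1L]) { pick <- i; break }
  }
  list(k = k_range[pick], gap = gap, se = se)
}

#' Select the number of subject groups by validity-index majority rule
#'
#' Each validity index of [validity_indices()] votes for its optimal
#' cluster count; the modal vote wins, ties resolving to the smallest k.
#' Indices that fail on degenerate input abstain with a message.
#'
#' @inheritParams validity_indices
#' @return A list: `k` (chosen), `votes`, `tally`.
#' @export
#' @examples
#' set.seed(1)
#' X <- rbind(matrix(rnorm(200), 100), matrix(rnorm(200, 4), 100))
#' select_k_majority(X, k_range = 2:6)$k # 2
select_k_majority <- function(scores, k_range = 2:10, seed = 1L,
                              n_restarts = 10L, gap_b = 20L) {
  vi <- validity_indices(scores, k_range = k_range, seed = seed,
                         n_restarts = n_restarts, gap_b = gap_b)
  votes <- vi$votes[!is.na(vi$votes)]
  if (length(votes) < 5L) stop("fewer than 5 validity indices available")
  tally <- table(factor(votes, levels = sort(unique(k_range))))
  winners <- as.integer(names(tally)[tally == max(tally)])
  if (length(winners) > 1L)
    warning("validity-index tie between k = ",
            paste(winners, collapse = ", "), "; taking the smallest")
  list(k = min(winners), votes = vi$votes, tally = tally)
}

#' Per-composite group difference tests
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test of each score column
#' between two groups, with normal approximation and tie correction.
#'
#' @param scores Subjects x LVs matrix.
#' @param labels Two-group labels.
#' @return Data.frame `lv`, `statistic`, `p`.
#' @export
group_lv_tests <- function(scores, labels) {
  X <- as.matrix(scores)
  gr <- sort(unique(labels))
  if (length(gr) != 2L) stop("exactly two groups required")
  if (min(table(labels)) < 2L) stop("each group needs >= 2 subjects")
  res <- lapply(seq_len(ncol(X)), function(j) {
    wt <- stats::wilcox.test(X[labels == gr[1], j], X[labels == gr[2], j],
                             exact = FALSE, correct = TRUE)
    data.frame(lv = colnames(X)[j] %||% paste0("LV", j),
               statistic = unname(wt$statistic), p = wt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Compare two Pearson correlations by Fisher's z
#'
#' `z_i = atanh(r_i)`; the statistic is
#' `(z1 - z2) / sqrt(1/(n1-3) + 1/(n2-3))` with a two-sided normal p-value.
#'
#' @param r1,r2 Correlations (|r| < 1).
#' @param n1,n2 Sample sizes (>= 4).
#' @return List `z_stat`, `p`, plus the inputs.
#' @export
#' @examples
#' compare_correlations_fisher(0.12, 508, -0.03, 375)$p # ~0.0275
compare_correlations_fisher <- function(r1, n1, r2, n2) {
  if (n1 < 4 || n2 < 4) stop("need n >= 4 in each group")
  if (abs(r1) >= 1 || abs(r2) >= 1)
    stop("|r| = 1: Fisher transform is infinite")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(r1 = r1, n1 = n1, r2 = r2, n2 = n2, z_stat = z,
       p = 2 * stats::pnorm(-abs(z)))
}

#' Group-wise correlation matrices and their comparison
#'
#' Pearson correlation matrix of the scores within each of two groups,
#' plus Fisher-z comparisons for every score pair with
#' Benjamini-Hochberg-adjusted p-values alongside the raw ones.
#'
#' @param scores Subjects x LVs matrix.
#' @param labels Two-group labels.
#' @return List `cor1`, `cor2` (matrices), `comparison` (data.frame
#'   `lv_a`, `lv_b`, `r1`, `r2`, `z_stat`, `p`, `p_bh`).
#' @export
groupwise_correlation_matrices <- function(scores, labels) {
  X <- as.matrix(scores)
  gr <- sort(unique(labels))
  if (length(gr) != 2L) stop("exactly two groups required")
  X1 <- X[labels == gr[1], , drop = FALSE]
  X2 <- X[labels == gr[2], , drop = FALSE]
  for (M in list(X1, X2))
    if (any(apply(M, 2, stats::sd) == 0))
      stop("constant score column within a group")
  C1 <- stats::cor(X1); C2 <- stats::cor(X2)
  n1 <- nrow(X1); n2 <- nrow(X2)
  nm <- colnames(X) %||% paste0("LV", seq_len(ncol(X)))
  pairs <- which(upper.tri(C1), arr.ind = TRUE)
  comp <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs[i, 1]; b <- pairs[i, 2]
    fc <- compare_correlations_fisher(C1[a, b], n1, C2[a, b], n2)
    data.frame(lv_a = nm[a], lv_b = nm[b], r1 = C1[a, b], r2 = C2[a, b],
               z_stat = fc$z_stat, p = fc$p, stringsAsFactors = FALSE)
  }))
  comp$p_bh <- stats::p.adjust(comp$p, method = "BH")
  rownames(comp) <- NULL
  list(cor1 = C1, cor2 = C2, comparison = comp)
}
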