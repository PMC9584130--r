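#' Absolute Spearman similarity between trait changes
#'
#' Computes the traits x traits matrix of absolute Spearman rank
#' correlations of the change scores (average ranks under ties). Taking
#' absolute values makes the similarity invariant to trait orientation, so
#' anti-correlated traits (e.g. a ratio trait against its denominator)
#' still count as strongly related.
#'
#' @param change A change table from [compute_changes()], or a numeric
#'   subjects x traits matrix.
#' @return Symmetric matrix with unit diagonal, entries in `[0, 1]`.
#' @export
spearman_similarity <- function(change) {
  m <- if (is.data.frame(change)) change_matrix(change) else as.matrix(change)
  if (nrow(m) < 3L) stop("need at least 3 subjects")
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0))
    stop("constant trait(s): ",
         paste(colnames(m)[sds == 0], collapse = ", "))
  S <- abs(stats::cor(m, method = "spearman"))
  diag(S) <- 1
  S
}

#' Sparse affinity graph from a similarity matrix
#'
#' Converts a similarity matrix into a sparse non-negative affinity graph
#' by a nearest-neighbour filter. Three filters are available:
#'
#' * `"recip_rank"` (default): an edge i-j is kept when
#'   `rank_i(j) + rank_j(i) <= 2 * k_nn`, where `rank_i(j)` is j's position
#'   in i's similarity order. This relaxation of mutual kNN requires the
#'   relationship to be highly ranked *from both sides*, so edges from a
#'   trait inside a tight block to an outside trait are removed (the block
#'   occupies the top ranks), while modest rank slippage inside weak blocks
#'   is tolerated.
#' * `"mutual"`: both `rank_i(j) <= k_nn` and `rank_j(i) <= k_nn`.
#' * `"union"`: classical union-symmetrized kNN
#'   (`rank_i(j) <= k_nn` or `rank_j(i) <= k_nn`).
#'
#' In addition, edges whose similarity is not significantly different from
#' zero are removed: the threshold is the Bonferroni-corrected two-sided
#' Fisher-z critical value at level `sig_level` for `n` subjects, so purely
#' noise-driven edges vanish and unrelated traits become isolated vertices
#' (which the regularized Laplacian of [spectral_embed()] keeps spectrally
#' identifiable). Set `sig_level = NULL` (or `n = NULL`) to disable.
#'
#' Rank ties are resolved deterministically by trait order.
#'
#' @param S Similarity matrix from [spearman_similarity()].
#' @param k_nn Neighbour depth, `1 <= k_nn <= p - 1`.
#' @param mode `"recip_rank"`, `"mutual"` or `"union"`.
#' @param n Number of subjects behind `S` (for the significance floor).
#' @param sig_level Family-wise level of the edge-significance floor
#'   (default 0.01).
#' @return A list of class `affinity_graph`: `W` (weighted adjacency, zero
#'   diagonal), `degrees`, `k_nn`, `mode`, `sig_floor`.
#' @export
knn_affinity <- function(S, k_nn = 2L,
                         mode = c("recip_rank", "mutual", "union"),
                         n = NULL, sig_level = 0.01) {
  mode <- match.arg(mode)
  p <- ncol(S)
  if (k_nn < 1L || k_nn > p - 1L)
    stop("k_nn must be in 1..", p - 1L)
  R <- matrix(0L, p, p)
  for (j in seq_len(p)) {
    ord <- order(S[j, -j], decreasing = TRUE) # stable: ties by trait order
    R[j, (seq_len(p))[-j][ord]] <- seq_len(p - 1L)
  }
  K <- switch(mode,
              recip_rank = (R + t(R)) <= 2L * k_nn,
              mutual = (R <= k_nn) & (t(R) <= k_nn),
              union = (R <= k_nn) | (t(R) <= k_nn))
  sig_floor <- 0
  if (!is.null(sig_level) && !is.null(n)) {
    m_tests <- p * (p - 1) / 2
    sig_floor <- tanh(stats::qnorm(1 - sig_level / (2 * m_tests)) /
                        sqrt(n - 3))
    K <- K & (S >= sig_floor)
  }
  W <- S * K
  diag(W) <- 0
  W <- pmax(W, t(W)) # exact symmetry
  d <- rowSums(W)
  if (any(d == 0))
    warning("disconnected affinity graph: ", sum(d == 0),
            " isolated trait(s); eigengap will reveal components")
  structure(list(W = W, degrees = d, k_nn = k_nn, mode = mode,
                 sig_floor = sig_floor),
            class = "affinity_graph")
}

#' Spectral embedding of an affinity graph
#'
#' Builds a graph Laplacian from the affinity graph and returns its full
#' eigendecomposition (eigenvalues ascending). The default is the
#' symmetric normalized Laplacian with a self-affinity regularization
#' `self_loop` added to the diagonal of W before normalization:
#' `L = I - (D + tau I)^{-1/2} (W + tau I) (D + tau I)^{-1/2}`.
#'
#' The regularization (a lazy-random-walk construction) serves two
#' purposes on sparse trait graphs: isolated vertices get a well-defined
#' degree and an exact zero eigenvalue (so graph components are counted
#' correctly), and weakly attached vertices produce small eigenvalues
#' proportional to their attachment strength instead of being renormalized
#' into the bulk of the spectrum.
#'
#' @param g An `affinity_graph` from [knn_affinity()], or a plain
#'   adjacency matrix.
#' @param laplacian `"sym"` (normalized symmetric, default), `"rw"`
#'   (random-walk; same spectrum as `"sym"`), or `"unnorm"` (`D - W`).
#' @param self_loop Regularization weight `tau >= 0` (default 0.25). With
#'   `laplacian = "unnorm"` it is ignored.
#' @return A list of class `spectral_embedding`: `values` (ascending),
#'   `vectors` (columns matching `values`), `laplacian`, `self_loop`.
#' @export
spectral_embed <- function(g, laplacian = c("sym", "rw", "unnorm"),
                           self_loop = 0.25) {
  laplacian <- match.arg(laplacian)
  W <- if (inherits(g, "affinity_graph")) g$W else as.matrix(g)
  p <- ncol(W)
  if (laplacian == "unnorm") {
    L <- diag(rowSums(W)) - W
  } else {
    Wt <- W
    diag(Wt) <- diag(Wt) + self_loop
    d <- rowSums(Wt)
    if (any(d <= 0))
      stop("zero-degree vertices (no self-loop): ",
           paste(which(d <= 0), collapse = ", "))
    ds <- 1 / sqrt(d)
    L <- diag(p) - (ds * Wt) * rep(ds, each = p) # D^-1/2 W D^-1/2
    ## rw has the same eigenvalues as sym; eigenvectors are D^-1/2 u
  }
  e <- eigen((L + t(L)) / 2, symmetric = TRUE)
  vals <- rev(e$values)
  vecs <- e$vectors[, p:1, drop = FALSE]
  if (laplacian == "rw") {
    Wt <- W; diag(Wt) <- diag(Wt) + self_loop
    vecs <- vecs / sqrt(rowSums(Wt))
  }
  rownames(vecs) <- colnames(W)
  structure(list(values = vals, vectors = vecs, laplacian = laplacian,
                 self_loop = self_loop),
            class = "spectral_embedding")
}

#' Choose the number of clusters by the maximum eigengap
#'
#' Returns the `k` in `2..k_max` maximizing the gap
#' `values[k + 1] - values[k]` of the Laplacian spectrum; ties resolve to
#' the smallest `k`.
#'
#' @param emb A `spectral_embedding`.
#' @param k_max Largest cluster count considered (default `p - 1`).
#' @return Integer `k`.
#' @export
select_k_eigengap <- function(emb, k_max = length(emb$values) - 1L) {
  v <- emb$values
  p <- length(v)
  if (k_max >= p) stop("k_max must be < number of traits")
  gaps <- diff(v)[2:k_max] # gap above k, for k = 2..k_max
  ## ties (to numerical tolerance) resolve to the smallest k
  unname(which(gaps >= max(gaps) - 1e-10)[1] + 1L)
}

#' Cluster traits from a spectral embedding
#'
#' Takes the first `k` eigenvectors, row-normalizes to unit length (rows
#' that are numerically zero are left unnormalized, with a warning), and
#' clusters rows by k-means with `n_restarts` restarts. Labels are
#' relabelled to contiguous ids ordered by first trait occurrence.
#'
#' @param emb A `spectral_embedding`.
#' @param k Number of clusters, `2 <= k <= p`.
#' @param n_restarts k-means restarts (default 50).
#' @param seed Seed for the k-means restarts.
#' @return A data.frame `trait`, `block_id` (class `block_structure`).
#' @export
spectral_cluster <- function(emb, k, n_restarts = 50L, seed = 1L) {
  U <- emb$vectors[, seq_len(k), drop = FALSE]
  p <- nrow(U)
  if (k < 2L || k > p) stop("k must be in 2..", p)
  nrm <- sqrt(rowSums(U^2))
  zero <- nrm < 1e-12
  if (any(zero)) {
    warning("embedding row(s) with zero norm left unnormalized: ",
            paste(rownames(U)[zero], collapse = ", "))
    nrm[zero] <- 1
  }
  U <- U / nrm
  cl <- with_seed(seed, {
    if (k == p) {
      seq_len(p)
    } else {
      stats::kmeans(U, centers = k, nstart = n_restarts,
                    iter.max = 100L)$cluster
    }
  })
  labels <- match(cl, unique(cl)) # contiguous, by first occurrence
  out <- data.frame(trait = rownames(U) %||% paste0("V", seq_len(p)),
                    block_id = labels, stringsAsFactors = FALSE,
                    check.names = FALSE)
  class(out) <- c("block_structure", "data.frame")
  out
}

#' Discover the composite-phenotype block structure
#'
#' End-to-end trait clustering: absolute-Spearman similarity, sparse
#' affinity graph, regularized normalized Laplacian, eigengap selection of
#' the number of blocks, and spectral k-means.
#'
#' @inheritParams knn_affinity
#' @inheritParams spectral_embed
#' @param change A change table from [compute_changes()].
#' @param k Optional fixed number of blocks (default: eigengap-selected).
#' @param k_max Largest block count considered by the eigengap.
#' @param n_restarts,seed Passed to [spectral_cluster()].
#' @return A list: `blocks` (a `block_structure`), `k`, `similarity`,
#'   `graph`, `embedding`.
#' @export
#' @examples
#' coh <- generate_cohort(default_cohort_config())
#' delta <- compute_changes(coh$baseline, coh$chronic)
#' bd <- discover_blocks(delta)
#' bd$k # 14 blocks expected under the default structure
discover_blocks <- function(change, k = NULL, k_nn = 2L,
                            mode = c("recip_rank", "mutual", "union"),
                            sig_level = 0.01,
                            laplacian = c("sym", "rw", "unnorm"),
                            self_loop = 0.25,
                            k_max = NULL, n_restarts = 50L, seed = 1L) {
  mode <- match.arg(mode)
  laplacian <- match.arg(laplacian)
  m <- change_matrix(change)
  S <- spearman_similarity(m)
  g <- suppressWarnings(
    knn_affinity(S, k_nn = k_nn, mode = mode, n = nrow(m),
                 sig_level = sig_level))
  emb <- spectral_embed(g, laplacian = laplacian, self_loop = self_loop)
  if (is.null(k_max)) k_max <- ncol(S) - 1L
  if (is.null(k)) k <- select_k_eigengap(emb, k_max = k_max)
  blocks <- spectral_cluster(emb, k, n_restarts = n_restarts, seed = seed)
  list(blocks = blocks, k = k, similarity = S, graph = g, embedding = emb)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
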