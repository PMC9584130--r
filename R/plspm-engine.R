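#' Build an inner path model over composite-phenotype blocks
#'
#' Constructs the latent-variable path matrix used by [fit_plspm()]. With
#' `target = NULL` (default) the model is saturated: every pair of latent
#' variables is connected, oriented lower-triangularly by block order
#' (acyclic by construction). This agnostic default gives every reflective
#' block a non-trivial inner estimate, which mode-A estimation needs for
#' stable composite scores when no structural theory is available. With a
#' `target` block, the model is the regression-style star in which every
#' other latent variable sends one arc into the target (the layout of the
#' oxygen-saturation regression model).
#'
#' @param blocks A `block_structure` (data.frame `trait`, `block_id`).
#' @param target Optional block id or trait name selecting the star layout.
#' @param path Optional user-supplied LV x LV arc matrix (`path[i, j]`
#'   meaning j -> i); must be acyclic.
#' @return A list of class `path_model`: `blocks`, `path` (lower-triangular
#'   logical LV x LV matrix, `path[i, j]` meaning j -> i), `modes` (all
#'   `"A"`), `scheme`.
#' @export
build_path_model <- function(blocks, target = NULL, path = NULL) {
  stopifnot(is.data.frame(blocks), all(c("trait", "block_id") %in%
                                         names(blocks)))
  B <- max(blocks$block_id)
  lv_names <- paste0("LV", seq_len(B))
  if (!is.null(path)) {
    if (nrow(path) != B) stop("path matrix must be ", B, " x ", B)
    path <- validate_path_matrix(path)
    dimnames(path) <- list(lv_names, lv_names)
    return(structure(list(blocks = blocks, path = path,
                          modes = rep("A", B), scheme = "centroid"),
                     class = "path_model"))
  }
  path <- matrix(FALSE, B, B, dimnames = list(lv_names, lv_names))
  if (is.null(target)) {
    path[lower.tri(path)] <- TRUE
  } else {
    if (is.character(target)) {
      hit <- blocks$block_id[blocks$trait == target]
      if (length(hit) != 1L) stop("unknown target trait: ", target)
      target <- hit
    }
    if (!target %in% seq_len(B)) stop("unknown target block: ", target)
    path[target, -target] <- TRUE
  }
  structure(list(blocks = blocks, path = path,
                 modes = rep("A", B), scheme = "centroid"),
            class = "path_model")
}

#' Validate a user-supplied path matrix
#' @keywords internal
validate_path_matrix <- function(path) {
  if (!is.matrix(path) || nrow(path) != ncol(path))
    stop("path matrix must be square")
  path <- path != 0
  if (any(diag(path))) stop("path matrix has self-loops")
  if (any(path & t(path)))
    stop("path matrix is cyclic (mutual arcs)")
  ## Kahn topological check; path[i, j] means arc j -> i
  remaining <- seq_len(nrow(path))
  while (length(remaining)) {
    indeg <- rowSums(path[remaining, remaining, drop = FALSE])
    src <- which(indeg == 0)
    if (!length(src)) stop("path matrix is cyclic")
    remaining <- remaining[-src]
  }
  path
}

#' Align trait signs within blocks
#'
#' Within each block, any trait whose correlation with the block's first
#' principal axis is negative is multiplied by -1, so that all traits point
#' in the block's dominant direction (reflective blocks with positive
#' loadings). Flips are reported via message and in the `flipped`
#' attribute. Applying the operation twice changes nothing.
#'
#' @param change A change table.
#' @param blocks A `block_structure`.
#' @return The change table with flipped columns; attribute `flipped` holds
#'   the flipped trait names.
#' @export
#' @examples
#' coh <- generate_cohort(default_cohort_config())
#' delta <- compute_changes(coh$baseline, coh$chronic)
#' aligned <- align_signs(delta, coh$true_blocks)
#' attr(aligned, "flipped") # MCH and MCHC on the default structure
align_signs <- function(change, blocks) {
  m <- change_matrix(change)
  missing <- setdiff(colnames(m), blocks$trait)
  if (length(missing))
    stop("blocks do not cover traits: ", paste(missing, collapse = ", "))
  flipped <- character(0)
  for (b in unique(blocks$block_id)) {
    traits <- intersect(colnames(m), blocks$trait[blocks$block_id == b])
    if (length(traits) < 2L) next
    C <- stats::cor(m[, traits, drop = FALSE])
    v1 <- eigen(C, symmetric = TRUE)$vectors[, 1]
    if (sum(v1) < 0) v1 <- -v1       # orient axis toward the majority
    neg <- traits[v1 < 0]
    for (tr in neg) {
      change[[tr]] <- -change[[tr]]
      flipped <- c(flipped, tr)
    }
  }
  if (length(flipped))
    message("sign-aligned (multiplied by -1): ",
            paste(flipped, collapse = ", "))
  attr(change, "flipped") <- flipped
  change
}

#' Fit a PLS path model (mode A)
#'
#' Lohmoeller-style alternating estimation of latent-variable scores.
#' Manifest variables are standardized; outer weights start at 1; each
#' iteration forms outer LV estimates `Y_b` (standardized `X_b w_b`), inner
#' estimates `Z_b` as the scheme-weighted sum of adjacent LV estimates
#' (centroid scheme: signs of `cor(Y_b, Y_adj)`; factorial: the
#' correlations themselves), and mode-A weight updates
#' `w_b = cor(X_b, Z_b)`. Iteration stops when the largest change of any
#' (normalized) outer weight falls below `tol`. Blocks with a single
#' manifest variable bypass iteration: their score is the standardized
#' variable and the loading is 1.
#'
#' Each returned score column is standardized; its sign is chosen so that
#' the majority of its loadings are positive.
#'
#' @param change A change table (ideally after [align_signs()]).
#' @param model A `path_model` from [build_path_model()].
#' @param tol Convergence tolerance on outer weights (default 1e-6).
#' @param max_iter Maximum iterations (default 100).
#' @param scheme Inner weighting scheme, `"centroid"` (default) or
#'   `"factorial"`.
#' @return A list of class `plspm_model`: `scores` (subjects x LVs,
#'   standardized), `weights`, `loadings` (per-trait correlation with its
#'   LV), `blocks`, `converged`, `n_iter`.
#' @export
fit_plspm <- function(change, model, tol = 1e-6, max_iter = 100L,
                      scheme = c("centroid", "factorial")) {
  scheme <- match.arg(scheme)
  X <- change_matrix(change)
  blocks <- model$blocks
  if (!all(colnames(X) %in% blocks$trait))
    stop("path model blocks do not cover the change table traits")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance manifest variable(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  X <- scale(X)
  n <- nrow(X)
  B <- max(blocks$block_id)
  idx <- lapply(seq_len(B), function(b)
    match(blocks$trait[blocks$block_id == b], colnames(X)))
  idx <- lapply(idx, function(i) i[!is.na(i)])
  if (any(lengths(idx) == 0L)) stop("empty block in path model")
  adj <- model$path | t(model$path)

  std <- function(v) v / stats::sd(v)
  Y <- matrix(0, n, B)
  w <- lapply(idx, function(i) rep(1 / sqrt(length(i)), length(i)))
  for (b in seq_len(B))
    Y[, b] <- std(X[, idx[[b]], drop = FALSE] %*% w[[b]])
  multi <- which(lengths(idx) > 1L)

  converged <- length(multi) == 0L
  it <- 0L
  while (!converged && it < max_iter) {
    it <- it + 1L
    delta <- 0
    Cyy <- stats::cor(Y)
    for (b in multi) {
      nb <- which(adj[b, ])
      e <- switch(scheme,
                  centroid = sign(Cyy[b, nb]),
                  factorial = Cyy[b, nb])
      e[e == 0] <- 1
      Z <- std(Y[, nb, drop = FALSE] %*% e)
      wb <- drop(stats::cor(X[, idx[[b]], drop = FALSE], Z))
      wb <- wb / sqrt(sum(wb^2))
      delta <- max(delta, max(abs(wb - w[[b]])))
      w[[b]] <- wb
      Y[, b] <- std(X[, idx[[b]], drop = FALSE] %*% wb)
    }
    if (delta < tol) converged <- TRUE
  }
  if (!converged)
    warning("PLSPM did not converge in ", max_iter,
            " iterations (last max weight change above tol)")

  loadings <- numeric(ncol(X))
  names(loadings) <- colnames(X)
  for (b in seq_len(B)) {
    ld <- drop(stats::cor(X[, idx[[b]], drop = FALSE], Y[, b]))
    if (sum(ld > 0) < sum(ld < 0)) { # majority-positive sign convention
      Y[, b] <- -Y[, b]
      ld <- -ld
      w[[b]] <- -w[[b]]
    }
    loadings[idx[[b]]] <- ld
  }
  Y <- scale(Y) # exact mean 0 / sd 1
  colnames(Y) <- rownames(model$path)
  rownames(Y) <- rownames(X)
  weights <- numeric(ncol(X))
  names(weights) <- colnames(X)
  for (b in seq_len(B)) weights[idx[[b]]] <- w[[b]]
  structure(list(scores = Y, weights = weights, loadings = loadings,
                 blocks = blocks, converged = converged, n_iter = it),
            class = "plspm_model")
}

#' Unidimensionality diagnostics from a block correlation matrix
#'
#' @param C Correlation matrix of one block's (sign-aligned or raw) traits.
#' @return List `c_alpha`, `dg_rho`, `eig_1st`, `eig_2nd`, `n_mvs`.
#' @export
unidim_from_cor <- function(C) {
  k <- ncol(C)
  if (k == 1L)
    return(list(c_alpha = 1, dg_rho = 1, eig_1st = 1, eig_2nd = 0,
                n_mvs = 1L))
  e <- eigen(C, symmetric = TRUE)
  ## sign-align on the first principal axis before averaging correlations;
  ## under an eigenvalue tie (e.g. two uncorrelated traits) the axis is
  ## taken as the symmetric direction
  v1 <- if (e$values[1] - e$values[2] < 1e-8)
    rep(1 / sqrt(k), k) else e$vectors[, 1]
  if (sum(v1) < 0) v1 <- -v1
  sgn <- ifelse(v1 >= 0, 1, -1)
  Ca <- C * (sgn %o% sgn)
  rbar <- mean(Ca[upper.tri(Ca)])
  c_alpha <- k * rbar / (1 + (k - 1) * rbar)
  lam <- abs(v1) * sqrt(e$values[1]) # first-PC loadings (aligned)
  dg_rho <- sum(lam)^2 / (sum(lam)^2 + sum(1 - lam^2))
  list(c_alpha = c_alpha, dg_rho = dg_rho,
       eig_1st = e$values[1], eig_2nd = e$values[2], n_mvs = k)
}

#' Unidimensionality diagnostics for each block
#'
#' For every block computes the standardized Cronbach alpha
#' (`k r / (1 + (k - 1) r)` with `r` the mean off-diagonal correlation
#' after sign alignment), the Dillon-Goldstein rho from first
#' principal-component loadings, and the two largest eigenvalues of the
#' block correlation matrix. Single-trait blocks return `(1, 1, 1, 0)`.
#'
#' @param change A change table.
#' @param blocks A `block_structure`, or a character vector of traits
#'   forming one block.
#' @return A data.frame with one row per block: `block_id`, `n_mvs`,
#'   `c_alpha`, `dg_rho`, `eig_1st`, `eig_2nd`, `traits`.
#' @export
#' @examples
#' coh <- generate_cohort(default_cohort_config())
#' delta <- compute_changes(coh$baseline, coh$chronic)
#' unidimensionality(delta, coh$true_blocks)
unidimensionality <- function(change, blocks) {
  m <- change_matrix(change)
  if (is.character(blocks))
    blocks <- data.frame(trait = blocks, block_id = 1L,
                         stringsAsFactors = FALSE)
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance trait(s): ",
         paste(colnames(m)[sds == 0], collapse = ", "))
  out <- lapply(sort(unique(blocks$block_id)), function(b) {
    traits <- intersect(colnames(m), blocks$trait[blocks$block_id == b])
    if (length(traits) == 0L) return(NULL)
    u <- unidim_from_cor(stats::cor(m[, traits, drop = FALSE]))
    data.frame(block_id = b, n_mvs = u$n_mvs, c_alpha = u$c_alpha,
               dg_rho = u$dg_rho, eig_1st = u$eig_1st, eig_2nd = u$eig_2nd,
               traits = paste(traits, collapse = ", "),
               stringsAsFactors = FALSE, check.names = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
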