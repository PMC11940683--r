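#' Principal components with varimax rotation
#'
#' PCA on the correlation matrix of the input, retaining components with
#' eigenvalue > 1 (strict), followed by varimax rotation with Kaiser row
#' normalization (rows scaled by communalities before rotating, rescaled
#' after) when two or more components are retained. Variance proportions are
#' reported before and after rotation; rotation redistributes but conserves
#' the retained variance.
#'
#' @param X observations x variables matrix or data.frame (e.g.
#'   communicator-level judgment means); >= 3 observations.
#' @return A `pca_result`: `eigenvalues`, `loadings` (unrotated, all
#'   components), `rotated` (retained components, NULL if < 2 retained),
#'   `n_retained`, `variance` (proportion per unrotated component),
#'   `variance_rotated`, `cumulative_retained_pct`, `rank_warning`.
#' @export
pca_varimax <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)
  rank_warning <- n < p
  if (rank_warning)
    warning("fewer observations than variables; correlation matrix is singular",
            call. = FALSE)
  R <- stats::cor(X)
  eig <- eigen(R, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  loadings <- eig$vectors %*% diag(sqrt(ev), p)
  # sign convention: largest absolute loading of each component positive
  for (j in seq_len(p)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) loadings[, j] <- -loadings[, j]
  }
  dimnames(loadings) <- list(colnames(X), paste0("PC", seq_len(p)))
  retained <- which(ev > 1)
  rotated <- NULL
  var_rot <- NULL
  if (length(retained) >= 2L) {
    rot <- stats::varimax(loadings[, retained, drop = FALSE], normalize = TRUE)
    rotated <- unclass(rot$loadings)
    for (j in seq_len(ncol(rotated))) {
      i <- which.max(abs(rotated[, j]))
      if (rotated[i, j] < 0) rotated[, j] <- -rotated[, j]
    }
    # order rotated components by explained variance, descending
    ssq <- colSums(rotated^2)
    ord <- order(ssq, decreasing = TRUE)
    rotated <- rotated[, ord, drop = FALSE]
    colnames(rotated) <- paste0("RC", seq_along(ord))
    var_rot <- colSums(rotated^2) / p
  }
  structure(list(eigenvalues = ev, loadings = loadings, rotated = rotated,
                 n_retained = length(retained),
                 variance = ev / p, variance_rotated = var_rot,
                 cumulative_retained_pct = cumulative_variance(ev, p,
                                                               length(retained)),
                 rank_warning = rank_warning),
            class = "pca_result")
}

#' Cumulative percent variance of retained components
#'
#' For a correlation-matrix PCA of `p` variables the eigenvalues sum to `p`,
#' so the first `k` components explain `100 * sum(eigenvalues[1:k]) / p`
#' percent of the variance.
#'
#' @param eigenvalues eigenvalues in decreasing order.
#' @param p number of variables.
#' @param k number of retained components (default: eigenvalue > 1).
#' @return Percent of variance, a scalar.
#' @examples
#' cumulative_variance(c(3.404, 1.120), p = 6, k = 2) # 75.4
#' @export
cumulative_variance <- function(eigenvalues, p, k = sum(eigenvalues > 1)) {
  if (k < 1) return(0)
  100 * sum(eigenvalues[seq_len(k)]) / p
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d retained component(s), %.1f%% of variance\n",
              x$n_retained, x$cumulative_retained_pct))
  invisible(x)
}

#' Tucker congruence between two loading matrices
#'
#' Column-matched absolute congruence coefficients; columns of `B` are
#' greedily matched to columns of `A`. Used to verify factor recovery of the
#' jury simulator.
#'
#' @param A,B loading matrices with equal row count.
#' @return Mean absolute congruence over matched columns.
#' @export
tucker_congruence <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  phi <- abs(crossprod(A, B) /
               outer(sqrt(colSums(A^2)), sqrt(colSums(B^2))))
  ks <- min(ncol(A), ncol(B))
  used <- integer(0)
  vals <- numeric(ks)
  for (j in seq_len(ks)) {
    cand <- phi[j, setdiff(seq_len(ncol(B)), used)]
    pick <- setdiff(seq_len(ncol(B)), used)[which.max(cand)]
    vals[j] <- phi[j, pick]
    used <- c(used, pick)
  }
  mean(vals)
}

#' Exact one-dimensional two-cluster K-means
#'
#' In one dimension the optimal two-cluster partition is a split of the
#' sorted values, so the global optimum is found exactly by scanning all
#' `n - 1` splits for the minimum within-cluster sum of squares. Cluster
#' separation is summarized by `F = (BSS/1) / (WSS/(n-2))` on (1, n-2)
#' degrees of freedom.
#'
#' @param values numeric vector (>= 2 values, not all equal).
#' @return A `cluster_result`: `labels` (`"high"`/`"low"` per input value),
#'   `centers` (named, high > low), `sizes`, `F`, `df`, `wss`, `bss`.
#' @export
kmeans_binary <- function(values) {
  v <- as.numeric(values)
  n <- length(v)
  if (n < 2L) stop("need at least 2 values", call. = FALSE)
  if (max(v) == min(v)) stop("degenerate clustering: all values equal",
                             call. = FALSE)
  o <- order(v)
  s <- v[o]
  css <- function(x) sum((x - mean(x))^2)
  wss_at <- vapply(seq_len(n - 1L), function(k)
    css(s[seq_len(k)]) + css(s[(k + 1L):n]), 0)
  k <- which.min(wss_at)
  low_mean <- mean(s[seq_len(k)])
  high_mean <- mean(s[(k + 1L):n])
  labels <- rep("low", n)
  labels[o[(k + 1L):n]] <- "high"
  wss <- wss_at[k]
  bss <- css(s) - wss
  Fstat <- if (n > 2L) (bss / 1) / (wss / (n - 2L)) else Inf
  structure(list(labels = labels,
                 centers = c(high = high_mean, low = low_mean),
                 sizes = c(high = n - k, low = k),
                 F = Fstat, df = c(1L, n - 2L), wss = wss, bss = bss),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> high %.3f (n=%d) / low %.3f (n=%d), F(1,%d) = %.2f\n",
              x$centers["high"], x$sizes["high"], x$centers["low"],
              x$sizes["low"], x$df[2], x$F))
  invisible(x)
}
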