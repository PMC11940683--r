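#' Paired t test
#'
#' Classical paired t on the differences `x - y`, two-sided. Degenerate
#' inputs are resolved explicitly instead of erroring: all-zero differences
#' give `t = 0, p = 1`; zero-variance differences with a nonzero mean give an
#' infinite t (flagged) with `p = 0`.
#'
#' @param x,y paired samples of equal length >= 3.
#' @return List with `t`, `df`, `p`, `md` (mean difference), `se`, and
#'   `infinite` flag.
#' @export
paired_t_test <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 pairs", call. = FALSE)
  d <- x - y
  n <- length(d)
  if (stats::sd(d) == 0) {
    if (mean(d) == 0)
      return(list(t = 0, df = n - 1L, p = 1, md = 0, se = 0, infinite = FALSE))
    return(list(t = sign(mean(d)) * Inf, df = n - 1L, p = 0, md = mean(d),
                se = 0, infinite = TRUE))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       md = unname(tt$estimate), se = unname(tt$stderr), infinite = FALSE)
}

#' Chi-square test of independence for a 2x2 table
#'
#' Pearson statistic (no continuity correction), df = 1, with an optional
#' exact p computed by full enumeration of all tables with the observed
#' margins (hypergeometric probabilities, tables ordered by their Pearson
#' statistic).
#'
#' @param tab 2x2 matrix of non-negative integer counts with positive margins.
#' @param exact also compute the exact enumeration p (default TRUE for
#'   `sum(tab) <= 200`).
#' @return List with `chi2`, `df`, `p` (asymptotic) and `p_exact` (or NA).
#' @examples
#' chi2_independence(matrix(c(9, 2, 7, 14), 2)) # chi2 = 6.788
#' @export
chi2_independence <- function(tab, exact = sum(tab) <= 200) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("tab must be 2x2", call. = FALSE)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero margin", call. = FALSE)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  chi2 <- unname(ct$statistic)
  p_exact <- NA_real_
  if (exact) {
    r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
    c1 <- sum(tab[, 1]); N <- sum(tab)
    a_range <- max(0L, c1 - r2):min(r1, c1)
    stat_of <- function(a) {
      t2 <- matrix(c(a, c1 - a, r1 - a, r2 - c1 + a), 2L)
      E <- outer(rowSums(t2), colSums(t2)) / N
      sum((t2 - E)^2 / E)
    }
    stats_all <- vapply(a_range, stat_of, 0)
    probs <- stats::dhyper(a_range, r1, r2, c1)
    p_exact <- sum(probs[stats_all >= chi2 - 1e-9])
  }
  list(chi2 = chi2, df = 1L, p = ct$p.value, p_exact = p_exact)
}

#' Pearson correlation matrix with p values
#'
#' Pairwise Pearson correlations with two-sided p values from the t
#' transform on `n - 2` degrees of freedom. Zero-variance columns give NA
#' cells (flagged in `degenerate`).
#'
#' @param data data.frame or matrix of numeric columns, n >= 4 rows.
#' @return List with matrices `r` and `p`, the common `n`, and `degenerate`,
#'   the names of constant columns.
#' @export
pearson_corr_matrix <- function(data) {
  X <- as.matrix(data)
  n <- nrow(X)
  if (n < 4L) stop("need at least 4 observations", call. = FALSE)
  sds <- apply(X, 2L, stats::sd)
  degenerate <- colnames(X)[sds == 0]
  r <- suppressWarnings(stats::cor(X))
  r[, sds == 0] <- NA_real_
  r[sds == 0, ] <- NA_real_
  diag(r) <- ifelse(sds == 0, NA_real_, 1)
  tval <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tval), n - 2)
  diag(p) <- NA_real_
  list(r = r, p = p, n = n, degenerate = degenerate)
}
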