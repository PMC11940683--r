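#' Jury-rating simulator configuration
#'
#' Configures a raters x communicators x 6-dimension Likert judgment
#' simulator with a two-factor latent structure: a *Content* factor (Interest,
#' Agreement) and a *Performance* factor (Authoritativeness, Learning,
#' Clarity), with Engagement loading on both. Default loadings follow that
#' rotated two-component pattern; default dimension means span the observed
#' 3.3-3.9 range of such panels.
#'
#' @param n_raters number of raters (default 26).
#' @param n_communicators number of rated communicators (default 30).
#' @param loadings 6 x 2 matrix of factor loadings (rows follow `dimensions`).
#' @param means length-6 vector of dimension means on the 1-5 scale.
#' @param factor_sd standard deviation of the latent communicator factor
#'   scores (default 0.5; loadings are on the rating scale per unit score).
#' @param rater_bias_sd standard deviation of the per-rater leniency bias.
#' @param residual_sd standard deviation of the rating residual.
#' @param round_likert round ratings to integer Likert steps (default FALSE;
#'   downstream analyses use communicator means, which are continuous).
#' @return A `jury_config` object.
#' @export
jury_config <- function(n_raters = 26, n_communicators = 30,
                        loadings = NULL, means = NULL, factor_sd = 0.5,
                        rater_bias_sd = 0.25, residual_sd = 0.5,
                        round_likert = FALSE) {
  dimensions <- c("Interest", "Agreement", "Engagement",
                  "Authoritativeness", "Learning", "Clarity")
  if (is.null(loadings)) {
    loadings <- rbind(c(0.943, 0.164),
                      c(0.864, 0.158),
                      c(0.716, 0.525),
                      c(0.118, 0.823),
                      c(0.172, 0.790),
                      c(0.310, 0.779))
  }
  loadings <- as.matrix(loadings)
  if (!all(dim(loadings) == c(6L, 2L)))
    stop("loadings must be a 6 x 2 matrix", call. = FALSE)
  rownames(loadings) <- dimensions
  colnames(loadings) <- c("Content", "Performance")
  if (is.null(means)) means <- c(3.269, 3.380, 3.456, 3.499, 3.680, 3.921)
  if (length(means) != 6L || any(means < 1) || any(means > 5))
    stop("means must be 6 values within [1, 5]", call. = FALSE)
  implied <- factor_sd^2 * tcrossprod(loadings) +
    diag(residual_sd^2 + 1e-12, 6L)
  if (min(eigen(implied, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("implied rating covariance is not positive definite", call. = FALSE)
  structure(list(n_raters = n_raters, n_communicators = n_communicators,
                 dimensions = dimensions, loadings = loadings, means = means,
                 factor_sd = factor_sd, rater_bias_sd = rater_bias_sd,
                 residual_sd = residual_sd, round_likert = round_likert),
            class = "jury_config")
}

#' Simulate jury judgments with a two-factor latent structure
#'
#' Each rating is `mean_d + sum_k loading[d, k] * score[k, c] + bias_r +
#' noise`, clipped to the 1-5 scale. Latent communicator scores are standard
#' normal scaled by `factor_sd`; recovering the loading pattern from the
#' communicator-level means via [pca_varimax()] is the round-trip this
#' generator is designed to support.
#'
#' @param cfg a [jury_config].
#' @param seed optional integer seed.
#' @return List with `ratings`, an `n_raters x n_communicators x 6` array,
#'   and `scores`, the `n_communicators x 2` matrix of true factor scores.
#' @export
simulate_jury <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "jury_config"))
  if (!is.null(seed)) set.seed(seed)
  nr <- cfg$n_raters; nc <- cfg$n_communicators
  scores <- matrix(stats::rnorm(nc * 2L, 0, cfg$factor_sd), nc, 2L,
                   dimnames = list(NULL, colnames(cfg$loadings)))
  bias <- stats::rnorm(nr, 0, cfg$rater_bias_sd)
  ratings <- array(NA_real_, c(nr, nc, 6L),
                   dimnames = list(rater = NULL, communicator = NULL,
                                   dimension = cfg$dimensions))
  signal <- scores %*% t(cfg$loadings) # nc x 6
  for (r in seq_len(nr)) {
    eps <- matrix(stats::rnorm(nc * 6L, 0, cfg$residual_sd), nc, 6L)
    val <- sweep(signal + eps, 2L, cfg$means, "+") + bias[r]
    if (cfg$round_likert) val <- round(val)
    ratings[r, , ] <- pmin(5, pmax(1, val))
  }
  list(ratings = ratings, scores = scores)
}

#' Communicator-level mean judgments
#'
#' Averages a raters x communicators x dimensions array over raters, the
#' aggregation used before PCA and clustering.
#'
#' @param ratings a 3-D ratings array as produced by [simulate_jury()].
#' @return A `n_communicators x n_dimensions` matrix of means.
#' @export
communicator_means <- function(ratings) {
  apply(ratings, c(2L, 3L), mean)
}
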