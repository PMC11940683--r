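test_that("paired t matches the closed form and the one-sample oracle", {
  out <- paired_t_test(c(2, 4, 6), c(1, 2, 3)) # differences 1, 2, 3
  expect_equal(out$t, 2 / (1 / sqrt(3)), tolerance = 1e-9)
  expect_equal(out$t, 3.4641016, tolerance = 1e-6)
  expect_identical(out$df, 2)

  x <- c(5, 5, 5); y <- x
  same <- paired_t_test(x, y)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  shifted <- paired_t_test(x + 2, y)
  expect_true(shifted$infinite)
  expect_equal(shifted$p, 0)

  set.seed(5)
  a <- rnorm(10); b <- rnorm(10)
  ours <- paired_t_test(a, b)
  d <- a - b # brute-force one-sample t on differences
  tt <- mean(d) / (stats::sd(d) / sqrt(10))
  expect_equal(ours$t, tt, tolerance = 1e-10)
  expect_equal(ours$p, 2 * stats::pt(-abs(tt), 9), tolerance = 1e-10)
})

test_that("chi-square independence matches closed forms", {
  out <- chi2_independence(matrix(c(9, 2, 7, 14), 2))
  expect_equal(out$chi2, 6.788, tolerance = 5e-4)
  expect_identical(out$df, 1L)
  expect_equal(chi2_independence(matrix(c(5, 5, 5, 5), 2))$chi2, 0)
  # all expected cells are 2: chi2 = 4 * 1 / 2 = 2
  expect_equal(chi2_independence(matrix(c(3, 1, 1, 3), 2))$chi2, 2)
  expect_error(chi2_independence(matrix(c(0, 0, 3, 4), 2)), "margin")

  # exact p: brute-force enumeration oracle written out independently
  tab <- matrix(c(9, 2, 7, 14), 2)
  r1 <- 16; r2 <- 16; c1 <- 11; N <- 32
  stats_all <- p_all <- numeric(0)
  for (a in max(0, c1 - r2):min(r1, c1)) {
    t2 <- matrix(c(a, c1 - a, r1 - a, r2 - c1 + a), 2)
    E <- outer(rowSums(t2), colSums(t2)) / N
    stats_all <- c(stats_all, sum((t2 - E)^2 / E))
    p_all <- c(p_all, stats::dhyper(a, r1, r2, c1))
  }
  oracle <- sum(p_all[stats_all >= out$chi2 - 1e-9])
  expect_equal(out$p_exact, oracle, tolerance = 1e-10)
})

test_that("correlation matrix matches the covariance formula", {
  expect_equal(pearson_corr_matrix(data.frame(a = 1:4, b = c(2, 4, 6, 8)))$r[1, 2], 1)
  set.seed(30)
  X <- data.frame(u = rnorm(30), v = rnorm(30))
  out <- pearson_corr_matrix(X)
  r_oracle <- sum((X$u - mean(X$u)) * (X$v - mean(X$v))) /
    sqrt(sum((X$u - mean(X$u))^2) * sum((X$v - mean(X$v))^2))
  expect_equal(out$r[1, 2], r_oracle, tolerance = 1e-12)
  ct <- stats::cor.test(X$u, X$v)
  expect_equal(out$p[1, 2], ct$p.value, tolerance = 1e-10)
  # zero-variance column flagged
  X$w <- 1
  out2 <- pearson_corr_matrix(X)
  expect_identical(out2$degenerate, "w")
  expect_true(is.na(out2$r["u", "w"]))
})

test_that("PCA conserves eigenvalue mass and varimax conserves retained variance", {
  sim <- simulate_jury(jury_config(), seed = 9)
  pca <- pca_varimax(communicator_means(sim$ratings))
  expect_equal(sum(pca$eigenvalues), 6, tolerance = 1e-9)
  expect_identical(pca$n_retained, 2L)
  retained_var <- sum(pca$eigenvalues[1:2])
  rotated_var <- sum(colSums(pca$rotated^2))
  expect_equal(rotated_var, retained_var, tolerance = 1e-6)
  # cumulative variance arithmetic (printed-eigenvalue consistency check)
  expect_equal(cumulative_variance(c(3.404, 1.120), 6), 75.4)
  expect_equal(round(cumulative_variance(c(3.404, 1.120), 6)), 75)
  # components at exactly 1 are not retained
  expect_equal(cumulative_variance(c(1, 1, 1), 3), 0)
})

test_that("jury PCA round trip recovers the generating loadings", {
  cfg <- jury_config()
  ok <- 0
  set.seed(77)
  for (r in 1:40) {
    sim <- simulate_jury(cfg)
    pca <- suppressWarnings(pca_varimax(communicator_means(sim$ratings)))
    if (pca$n_retained == 2 &&
        tucker_congruence(cfg$loadings, pca$rotated) >= 0.95) ok <- ok + 1
  }
  expect_gte(ok / 40, 0.9)
})

test_that("exact 1-D 2-means equals exhaustive search and stats::kmeans", {
  km <- kmeans_binary(c(1.0, 1.1, 0.9, 5.0, 5.1, 4.9))
  expect_equal(unname(km$centers), c(5.0, 1.0))
  expect_equal(unname(km$sizes), c(3L, 3L))
  two <- kmeans_binary(c(2, 7))
  expect_equal(unname(two$sizes), c(1L, 1L))
  expect_error(kmeans_binary(rep(3, 5)), "degenerate")

  set.seed(14)
  for (r in 1:20) {
    v <- rnorm(25, mean = sample(c(0, 3), 25, TRUE))
    ours <- kmeans_binary(v)
    # exhaustive oracle over sorted splits
    s <- sort(v)
    wss <- vapply(1:24, function(k)
      sum((s[1:k] - mean(s[1:k]))^2) +
        sum((s[(k + 1):25] - mean(s[(k + 1):25]))^2), 0)
    expect_equal(ours$wss, min(wss), tolerance = 1e-10)
    # stats::kmeans with many restarts should find the same optimum
    ref <- stats::kmeans(v, 2, nstart = 25)
    expect_equal(ours$wss, ref$tot.withinss, tolerance = 1e-8)
  }
})

test_that("within-subject Pillai matches the stats::manova oracle", {
  set.seed(42)
  n <- 8
  dat <- data.frame(subject = rep(sprintf("s%d", 1:n), each = 3),
                    phase = rep(c("pre", "interview", "post"), n),
                    dv = rnorm(3 * n, mean = rep(c(10, 8, 12), n)))
  fit <- rm_anova(dat, "dv")
  Y <- matrix(dat$dv, n, 3, byrow = TRUE)
  D <- Y %*% stats::contr.poly(3)
  mv <- summary(stats::manova(D ~ 1), test = "Pillai", intercept = TRUE)$stats
  ours <- fit$table[fit$table$test == "multivariate", ]
  expect_equal(ours$pillai[1], mv[1, "Pillai"], tolerance = 1e-8)
  expect_equal(ours$F[1], mv[1, "approx F"], tolerance = 1e-8)
  expect_equal(ours$p[1], mv[1, "Pr(>F)"], tolerance = 1e-8)

  # with a balanced between factor
  dat$g <- rep(c("a", "b"), each = 12)
  fit2 <- rm_anova(dat, "dv", between = "g")
  g <- factor(rep(c("a", "b"), each = 4))
  mv2 <- summary(stats::manova(D ~ g), test = "Pillai", intercept = TRUE)$stats
  ours2 <- fit2$table[fit2$table$test == "multivariate", ]
  expect_equal(ours2$pillai[ours2$effect == "phase"], mv2["(Intercept)", "Pillai"],
               tolerance = 1e-8)
  expect_equal(ours2$pillai[ours2$effect == "phase:g"], mv2["g", "Pillai"],
               tolerance = 1e-8)
  expect_equal(ours2$F[ours2$effect == "phase:g"], mv2["g", "approx F"],
               tolerance = 1e-8)
})

test_that("rm_anova handles degenerate and invalid inputs", {
  # constant dv across phases: zero within effect
  dat <- data.frame(subject = rep(1:6, each = 3),
                    phase = rep(c("a", "b", "c"), 6),
                    dv = rep(rnorm(6), each = 3))
  fit <- rm_anova(dat, "dv")
  mrow <- fit$table[fit$table$test == "multivariate", ]
  expect_equal(mrow$pillai, 0)
  expect_equal(mrow$F, 0)

  # partial eta^2 identity for univariate rows
  set.seed(6)
  dat2 <- data.frame(subject = rep(1:10, each = 3),
                     phase = rep(c("a", "b", "c"), 10),
                     dv = rnorm(30))
  f2 <- rm_anova(dat2, "dv")
  w <- f2$table[f2$table$test == "within", ]
  expect_equal(w$eta_p2, w$F * w$df1 / (w$F * w$df1 + w$df2), tolerance = 1e-6)
  eps <- w$gg_epsilon
  expect_true(eps >= 0.5 && eps <= 1)

  # aliased covariate is named
  dat2$c1 <- rep(rnorm(10), each = 3)
  dat2$c2 <- 2 * dat2$c1
  expect_error(rm_anova(dat2, "dv", covariates = c("c1", "c2")), "aliased")

  # incomplete within data is refused
  expect_error(rm_anova(dat2[-1, ], "dv"), "incomplete")
})

test_that("rm_anova keeps its nominal size under the null", {
  set.seed(101)
  rej <- 0
  for (r in 1:500) {
    Y <- matrix(rnorm(60), 20, 3)
    d <- data.frame(subject = rep(1:20, each = 3),
                    phase = rep(c("a", "b", "c"), 20),
                    dv = as.vector(t(Y)))
    f <- rm_anova(d, "dv")
    rej <- rej + (f$table$p[f$table$test == "multivariate"][1] < 0.05)
  }
  expect_gte(rej / 500, 0.03)
  expect_lte(rej / 500, 0.07)
})

test_that("adjusted contrasts reduce to raw means without covariates", {
  set.seed(15)
  Y <- matrix(rnorm(36, mean = rep(c(5, 3, 7), each = 12)), 12, 3)
  d <- data.frame(subject = rep(1:12, 3), phase = rep(c("p1", "p2", "p3"), each = 12),
                  dv = as.vector(Y))
  fit <- rm_anova(d, "dv")
  ctr <- adjusted_pairwise_contrasts(fit)
  expect_equal(ctr$means$emmean, colMeans(Y), tolerance = 1e-10,
               ignore_attr = TRUE)
  md <- ctr$contrasts$md
  em <- ctr$means$emmean
  expect_equal(md, c(em[1] - em[2], em[1] - em[3], em[2] - em[3]),
               tolerance = 1e-10)
  expect_equal(ctr$contrasts$p_adj, pmin(1, ctr$contrasts$p * 3))

  # with covariates, each MD still equals the difference of adjusted means
  d$age <- rep(rnorm(12, 50, 8), 3)
  fit2 <- rm_anova(d, "dv", covariates = "age")
  ctr2 <- adjusted_pairwise_contrasts(fit2)
  em2 <- ctr2$means$emmean
  expect_equal(ctr2$contrasts$md,
               c(em2[1] - em2[2], em2[1] - em2[3], em2[2] - em2[3]),
               tolerance = 1e-10)
})
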