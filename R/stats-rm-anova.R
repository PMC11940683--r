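# Pillai's trace and its F approximation for a multivariate linear
# hypothesis with hypothesis SSCP H, error SSCP E, q hypothesis df,
# p response dimensions, dfe error df.
pillai_test <- function(H, E, q, p, dfe) {
  HE <- H + E
  if (max(abs(H)) < 1e-12) {
    V <- 0
  } else {
    V <- sum(diag(solve(HE, H)))
  }
  s <- min(p, q)
  m <- (abs(p - q) - 1) / 2
  nn <- (dfe - p - 1) / 2
  df1 <- s * (2 * m + s + 1)
  df2 <- s * (2 * nn + s + 1)
  if (df2 <= 0) # not enough error df for the multivariate approximation
    return(list(pillai = V, F = NA_real_, df1 = df1, df2 = df2, p = NA_real_,
                eta_p2 = V / s))
  Fstat <- if (V >= s) Inf else ((2 * nn + s + 1) / (2 * m + s + 1)) *
    (V / s) / (1 - V / s)
  pval <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  list(pillai = V, F = Fstat, df1 = df1, df2 = df2, p = pval,
       eta_p2 = V / s)
}

# Greenhouse-Geisser epsilon from the error SSCP of orthonormalized
# within-subject contrasts: eps = tr(S)^2 / ((k-1) * tr(S %*% S))
gg_epsilon <- function(E, dfe, k) {
  S <- E / dfe
  tr2 <- sum(diag(S))^2
  trS2 <- sum(S * t(S))
  if (trS2 <= 0) return(1)
  min(1, max(1 / (k - 1), tr2 / ((k - 1) * trS2)))
}

#' Repeated-measures ANOVA with covariates
#'
#' Tests a within-subject factor (e.g. recording phase) and its interactions
#' with between-subject factors and covariates. The within-subject responses
#' are transformed by `k - 1` orthonormal polynomial contrasts and regressed
#' on the between-subject design (intercept, sum-to-zero coded factors,
#' mean-centered covariates), so the intercept row of the multivariate model
#' is the within-factor main effect evaluated at the covariate means.
#' Within effects are reported multivariately with Pillai's trace (the robust
#' choice at small n) and univariately with the Greenhouse-Geisser
#' sphericity correction applied unconditionally. Between-subject effects are
#' tested on the subject means. Effect sizes are partial eta squared
#' (`V / s` for Pillai, `SS_h / (SS_h + SS_e)` univariately, which equals
#' `F df1 / (F df1 + df2)`).
#'
#' @param data long-format data.frame.
#' @param dv name of the dependent-variable column.
#' @param subject name of the subject id column (default `"subject"`).
#' @param within name of the within-subject factor column (default
#'   `"phase"`); its levels are taken in order of first appearance. Every
#'   subject must have one complete set of levels.
#' @param between character vector of between-subject factor columns.
#' @param covariates character vector of numeric covariate columns.
#' @return An `hrv_rm_anova` object; its `table` element is a tidy data.frame
#'   `effect, test, F, df1, df2, p, eta_p2, pillai, gg_epsilon` with tests
#'   `multivariate`, `within` (GG-corrected univariate) and `between`.
#' @export
rm_anova <- function(data, dv, subject = "subject", within = "phase",
                     between = NULL, covariates = NULL) {
  need <- c(dv, subject, within, between, covariates)
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  levels_w <- unique(as.character(data[[within]]))
  k <- length(levels_w)
  if (k < 2L) stop("within factor needs >= 2 levels", call. = FALSE)
  subjects <- unique(as.character(data[[subject]]))
  n <- length(subjects)
  Y <- matrix(NA_real_, n, k, dimnames = list(subjects, levels_w))
  for (i in seq_len(nrow(data))) {
    Y[as.character(data[[subject]][i]), as.character(data[[within]][i])] <-
      data[[dv]][i]
  }
  if (anyNA(Y)) {
    bad <- rownames(Y)[apply(Y, 1L, anyNA)]
    stop("incomplete within-subject data for: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }

  # subject-level between table
  first <- match(subjects, as.character(data[[subject]]))
  bt <- data.frame(row.names = subjects)
  for (v in between) bt[[v]] <- factor(data[[v]][first])
  cov_means <- numeric(0)
  for (v in covariates) {
    cv <- as.numeric(data[[v]][first])
    cov_means[v] <- mean(cv)
    bt[[v]] <- cv - cov_means[v]
  }
  rhs <- if (length(c(between, covariates)))
    paste(c(between, covariates), collapse = " + ") else "1"
  fml <- stats::as.formula(paste("~", rhs))
  contrasts_arg <- NULL
  if (length(between)) {
    contrasts_arg <- stats::setNames(
      replicate(length(between), "contr.sum", simplify = FALSE), between)
  }
  X <- stats::model.matrix(fml, data = bt, contrasts.arg = contrasts_arg)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    aliased <- colnames(X)[qrx$pivot[(qrx$rank + 1L):ncol(X)]]
    stop("singular design; aliased: ", paste(aliased, collapse = ", "),
         call. = FALSE)
  }
  XtXinv <- chol2inv(chol(crossprod(X)))
  dfe <- n - ncol(X)
  if (dfe < 1L) stop("no residual degrees of freedom", call. = FALSE)

  Cmat <- stats::contr.poly(k)         # k x (k-1), orthonormal
  D <- Y %*% Cmat
  B <- XtXinv %*% crossprod(X, D)      # ncol(X) x (k-1)
  E <- crossprod(D - X %*% B)
  p_dim <- k - 1L

  asgn <- attr(X, "assign")
  term_labels <- attr(stats::terms(fml), "term.labels")

  rows <- list()
  add_row <- function(effect, test, F, df1, df2, p, eta, pillai = NA_real_,
                      eps = NA_real_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      effect = effect, test = test, F = F, df1 = df1, df2 = df2, p = p,
      eta_p2 = eta, pillai = pillai, gg_epsilon = eps,
      stringsAsFactors = FALSE)
  }

  # within-subject effects: intercept = within main effect; term j = its
  # interaction with the within factor
  within_terms <- c(0L, seq_along(term_labels))
  for (tj in within_terms) {
    cols <- which(asgn == tj)
    q <- length(cols)
    if (q == 0L) next
    Bq <- B[cols, , drop = FALSE]
    Vq <- XtXinv[cols, cols, drop = FALSE]
    H <- t(Bq) %*% solve(Vq, Bq)
    eff <- if (tj == 0L) within else paste(within, term_labels[tj], sep = ":")
    mv <- pillai_test(H, E, q, p_dim, dfe)
    add_row(eff, "multivariate", mv$F, mv$df1, mv$df2, mv$p, mv$eta_p2,
            pillai = mv$pillai)
    # univariate with GG correction
    ssh <- sum(diag(H)); sse <- sum(diag(E))
    df1u <- q * p_dim; df2u <- dfe * p_dim
    Fu <- if (sse > 0) (ssh / df1u) / (sse / df2u) else
      (if (ssh > 0) Inf else 0)
    eps <- gg_epsilon(E, dfe, k)
    pu <- stats::pf(Fu, df1u * eps, df2u * eps, lower.tail = FALSE)
    etau <- if (ssh + sse > 0) ssh / (ssh + sse) else 0
    add_row(eff, "within", Fu, df1u * eps, df2u * eps, pu, etau, eps = eps)
  }

  # between-subject effects on the subject means
  M <- rowMeans(Y)
  bM <- XtXinv %*% crossprod(X, M)
  resM <- M - X %*% bM
  sseM <- sum(resM^2)
  for (tj in seq_along(term_labels)) {
    cols <- which(asgn == tj)
    q <- length(cols)
    if (q == 0L) next
    bq <- bM[cols, , drop = FALSE]
    Vq <- XtXinv[cols, cols, drop = FALSE]
    ssh <- drop(t(bq) %*% solve(Vq, bq))
    Fb <- if (sseM > 0) (ssh / q) / (sseM / dfe) else
      (if (ssh > 0) Inf else 0)
    pb <- stats::pf(Fb, q, dfe, lower.tail = FALSE)
    add_row(term_labels[tj], "between", Fb, q, dfe, pb,
            if (ssh + sseM > 0) ssh / (ssh + sseM) else 0)
  }

  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(table = tab, Y = Y, X = X, XtXinv = XtXinv, dfe = dfe,
                 contrasts = Cmat, within = within, levels = levels_w,
                 dv = dv, covariate_means = cov_means,
                 between = between, covariates = covariates),
            class = "hrv_rm_anova")
}

#' @export
print.hrv_rm_anova <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA for '%s' (%d subjects, %d levels of %s)\n",
              x$dv, nrow(x$Y), length(x$levels), x$within))
  if (length(x$covariate_means))
    cat("covariates evaluated at: ",
        paste(sprintf("%s = %.4f", names(x$covariate_means),
                      x$covariate_means), collapse = ", "), "\n", sep = "")
  print(x$table, digits = 4)
  invisible(x)
}

#' Covariate-adjusted pairwise contrasts of the within factor
#'
#' Estimated marginal means per within level at the covariate means (and
#' balanced factor weights, which the sum-to-zero design encodes in the
#' intercept), with all pairwise differences, their standard errors and
#' multiplicity-adjusted p values.
#'
#' @param model an [rm_anova()] fit.
#' @param adjust `"bonferroni"` (default) or `"none"`.
#' @return List with `means` (`level, emmean, se`) and `contrasts`
#'   (`contrast, md, se, t, df, p, p_adj`).
#' @export
adjusted_pairwise_contrasts <- function(model, adjust = c("bonferroni", "none")) {
  stopifnot(inherits(model, "hrv_rm_anova"))
  adjust <- match.arg(adjust)
  X <- model$X; XtXinv <- model$XtXinv; Y <- model$Y
  dfe <- model$dfe
  lev <- model$levels
  est_int <- function(y) {
    b <- XtXinv %*% crossprod(X, y)
    r <- y - X %*% b
    s2 <- sum(r^2) / dfe
    c(est = b[1L, 1L], se = sqrt(s2 * XtXinv[1L, 1L]))
  }
  means <- t(vapply(lev, function(l) est_int(Y[, l]), c(est = 0, se = 0)))
  means_df <- data.frame(level = lev, emmean = means[, "est"],
                         se = means[, "se"], stringsAsFactors = FALSE,
                         row.names = NULL)
  prs <- utils::combn(lev, 2L)
  n_c <- ncol(prs)
  out <- vector("list", n_c)
  for (j in seq_len(n_c)) {
    a <- prs[1L, j]; b <- prs[2L, j]
    e <- est_int(Y[, a] - Y[, b])
    tval <- if (e["se"] > 0) e["est"] / e["se"] else
      (if (e["est"] == 0) 0 else sign(e["est"]) * Inf)
    p <- 2 * stats::pt(-abs(tval), dfe)
    out[[j]] <- data.frame(contrast = paste(a, "-", b), md = unname(e["est"]),
                           se = unname(e["se"]), t = unname(tval), df = dfe,
                           p = p, stringsAsFactors = FALSE)
  }
  ctr <- do.call(rbind, out)
  ctr$p_adj <- if (adjust == "bonferroni") pmin(1, ctr$p * n_c) else ctr$p
  list(means = means_df, contrasts = ctr)
}
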