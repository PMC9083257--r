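# Vowel-duration analysis: crossed-random-intercept Gaussian mixed model by
# profiled maximum likelihood, plus rank correlations.

#' Crossed-random-intercept linear mixed model
#'
#' Fits y = X beta + u[group1] + v[group2] + e with independent Gaussian
#' random intercepts, by maximum likelihood: the two variance ratios
#' gamma_k = sigma_k^2 / sigma_e^2 are profiled over a coarse log-scale grid
#' followed by Nelder-Mead refinement, with generalized least squares for
#' the fixed effects at each candidate (Woodbury identities on the q x q
#' random-effect system). REML is available as a flag.
#'
#' @param y numeric response.
#' @param X fixed-effect design matrix (include the intercept column).
#' @param group1,group2 grouping factors (at least 2 levels each).
#' @param REML use the REML criterion instead of ML (default FALSE).
#' @param gamma optional fixed variance ratios c(gamma1, gamma2), skipping
#'   optimization; \code{c(0, 0)} reproduces OLS exactly.
#' @return an object of class \code{duration_fit}: \code{coefficients}
#'   (estimate, se, t per column of X), \code{varcomp} (group1, group2,
#'   residual standard deviations), \code{logLik}, \code{gamma}, \code{n}.
#' @export
fit_random_intercept_lmm <- function(y, X, group1, group2, REML = FALSE,
                                     gamma = NULL) {
  X <- as.matrix(X)
  n <- length(y)
  g1 <- factor(group1); g2 <- factor(group2)
  if (nlevels(g1) < 2 || nlevels(g2) < 2)
    stopf("data error: each grouping factor needs at least 2 levels")
  Z1 <- stats::model.matrix(~ 0 + g1)
  Z2 <- stats::model.matrix(~ 0 + g2)
  Z <- cbind(Z1, Z2)
  q1 <- ncol(Z1); q2 <- ncol(Z2)
  p <- ncol(X)

  ZtZ <- crossprod(Z); ZtX <- crossprod(Z, X); Zty <- crossprod(Z, y)
  XtX <- crossprod(X); Xty <- crossprod(X, y); yty <- sum(y^2)

  eval_gamma <- function(gam) {
    active <- gam > 0
    idx <- c(if (active[1]) seq_len(q1),
             if (active[2]) q1 + seq_len(q2))
    if (length(idx) == 0) {
      XVX <- XtX; XVy <- Xty; yVy <- yty; logdetV <- 0
    } else {
      gvec <- c(rep(gam[1], q1), rep(gam[2], q2))[idx]
      M <- ZtZ[idx, idx, drop = FALSE] + diag(1 / gvec, length(idx))
      R <- tryCatch(chol(M), error = function(e) NULL)
      if (is.null(R)) return(list(nll = 1e30))
      solveM <- function(B) backsolve(R, forwardsolve(t(R),
                                                      B[idx, , drop = FALSE]))
      XVX <- XtX - crossprod(ZtX[idx, , drop = FALSE], solveM(ZtX))
      XVy <- Xty - crossprod(ZtX[idx, , drop = FALSE], solveM(Zty))
      yVy <- yty - sum(Zty[idx, ] * solveM(Zty))
      logdetV <- 2 * sum(log(diag(R))) + sum(log(gvec))
    }
    Rx <- tryCatch(chol(XVX), error = function(e) NULL)
    if (is.null(Rx)) return(list(nll = 1e30))
    beta <- backsolve(Rx, forwardsolve(t(Rx), XVy))
    qform <- max(yVy - sum(beta * XVy), 1e-300)
    df <- if (REML) n - p else n
    sigma2 <- qform / df
    nll <- 0.5 * (df * (log(2 * pi * sigma2) + 1) + logdetV)
    if (REML) nll <- nll + sum(log(diag(Rx))) - 0.5 * p * log(sigma2)
    list(nll = nll, beta = beta, sigma2 = sigma2, XVX = XVX,
         logdetV = logdetV)
  }

  if (is.null(gamma)) {
    grid <- expand.grid(l1 = seq(-6, 4, length.out = 6),
                        l2 = seq(-6, 4, length.out = 6))
    vals <- apply(grid, 1, function(g) eval_gamma(exp(as.numeric(g)))$nll)
    start <- as.numeric(grid[which.min(vals), ])
    opt <- stats::optim(start, function(lg) eval_gamma(exp(lg))$nll,
                        method = "Nelder-Mead",
                        control = list(maxit = 300, reltol = 1e-9))
    gamma <- exp(opt$par)
  }
  sol <- eval_gamma(gamma)
  if (sol$nll >= 1e30)
    stopf("numeric error: covariance not positive definite at optimum")
  se <- sqrt(sol$sigma2 * diag(chol2inv(chol(sol$XVX))))
  coefs <- data.frame(estimate = as.numeric(sol$beta), se = se,
                      t = as.numeric(sol$beta) / se,
                      row.names = colnames(X) %||%
                        paste0("b", seq_len(p)))
  out <- list(coefficients = coefs,
              varcomp = c(group1 = sqrt(gamma[1] * sol$sigma2),
                          group2 = sqrt(gamma[2] * sol$sigma2),
                          residual = sqrt(sol$sigma2)),
              logLik = -sol$nll, gamma = gamma, n = n, REML = REML)
  class(out) <- "duration_fit"
  out
}

#' @export
print.duration_fit <- function(x, ...) {
  cat(sprintf("crossed-random-intercept LMM (%s), n = %d\n",
              if (x$REML) "REML" else "ML", x$n))
  print(round(x$coefficients, 4))
  cat(sprintf("sd(group1) = %.3f, sd(group2) = %.3f, sd(residual) = %.3f\n",
              x$varcomp[1], x$varcomp[2], x$varcomp[3]))
  invisible(x)
}

#' Regress log vowel duration on activation
#'
#' Linear mixed model of log vowel duration on an activation measure,
#' controlling for local speaking rate and the number of segments in the
#' word, with crossed random intercepts for speakers and words.
#'
#' @param tokens a token-level table from \code{\link{token_table}}.
#' @param activation activation column name.
#' @param REML passed to \code{\link{fit_random_intercept_lmm}}.
#' @return a \code{duration_fit}.
#' @export
duration_model <- function(tokens, activation, REML = FALSE) {
  X <- cbind("(Intercept)" = 1,
             activation = tokens[[activation]],
             speaking_rate = tokens$speaking_rate,
             n_segments = tokens$n_segments)
  fit_random_intercept_lmm(tokens$log_duration, X, tokens$speaker,
                           tokens$word, REML = REML)
}

#' Spearman and Pearson correlation
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return named vector \code{c(spearman_rho, pearson_r)} (Spearman via
#'   midrank ties).
#' @export
rank_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stopf("data error: 'x' and 'y' must have equal length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stopf("data error: zero variance input")
  c(spearman_rho = stats::cor(x, y, method = "spearman"),
    pearson_r = stats::cor(x, y, method = "pearson"))
}
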