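# Penalized-spline trajectory regression: additive models with tensor-product
# smooths, by-factor smooths, grouped (random) factor smooths, AR1
# pre-whitening at fixed rho, smoothing parameters chosen by Gaussian
# log marginal likelihood (coefficients integrated out, sigma^2 profiled).

#' Declare a smooth term
#'
#' @param kind one of \code{"univariate"}, \code{"tensor"},
#'   \code{"partial_tensor"} (interaction-only tensor), or
#'   \code{"factor_smooth"} (per-level penalized spline deviations sharing
#'   one smoothing parameter pair — the random factor smooth analog).
#' @param covariates covariate name (univariate), two covariate names
#'   (tensors), or \code{c(covariate, grouping_factor)} for factor smooths.
#' @param by optional factor name; one centered smooth per level.
#' @param k basis size per covariate (defaults: 10 univariate, 5 per tensor
#'   margin, 5 factor smooth).
#' @param penalty_order difference-penalty order (2; factor smooths use 1
#'   plus a ridge penalty on the whole block).
#' @return an object of class \code{smooth_term}.
#' @export
smooth_term <- function(kind = c("univariate", "tensor", "partial_tensor",
                                 "factor_smooth"),
                        covariates, by = NULL, k = NULL, penalty_order = 2) {
  kind <- match.arg(kind)
  k <- k %||% switch(kind, univariate = 10, tensor = c(5, 5),
                     partial_tensor = c(5, 5), factor_smooth = 5)
  if (any(k < penalty_order + 1))
    stopf("configuration error: basis_size must be >= penalty_order + 1")
  out <- list(kind = kind, covariates = covariates, by = by, k = k,
              penalty_order = penalty_order)
  class(out) <- "smooth_term"
  out
}

#' Specify a trajectory regression model
#'
#' @param terms list of \code{\link{smooth_term}}s.
#' @param fixed character vector of factor names entering as fixed intercepts
#'   (plus the overall intercept); may be empty.
#' @param response response column name.
#' @param rho fixed AR1 coefficient in [0, 1) used to pre-whiten responses
#'   and design rows within each series; \code{rho = 0} disables whitening.
#' @param series column name(s) whose interaction identifies one AR1 run
#'   (default token by formant dimension), or \code{NULL} for a single
#'   series.
#' @param time_var column ordering samples within a series.
#' @return an object of class \code{model_spec}.
#' @export
model_spec <- function(terms, fixed = "dbc", response = "response",
                       rho = 0.8, series = c("token_id", "dimension"),
                       time_var = "time") {
  if (!is.finite(rho) || rho < 0 || rho >= 1)
    stopf("configuration error: 'rho' must lie in [0, 1)")
  out <- list(terms = terms, fixed = fixed, response = response, rho = rho,
              series = series, time_var = time_var)
  class(out) <- "model_spec"
  out
}

# ---- term construction -----------------------------------------------------

.term_label <- function(term) {
  lab <- switch(term$kind,
                univariate = sprintf("s(%s)", term$covariates[1]),
                tensor = sprintf("te(%s,%s)", term$covariates[1],
                                 term$covariates[2]),
                partial_tensor = sprintf("ti(%s,%s)", term$covariates[1],
                                         term$covariates[2]),
                factor_smooth = sprintf("fs(%s,%s)", term$covariates[1],
                                        term$covariates[2]))
  if (!is.null(term$by)) lab <- paste0(lab, ":", term$by)
  lab
}

.by_levels <- function(term, data) {
  if (is.null(term$by)) return(NA_character_)
  lv <- data[[term$by]]
  if (!is.factor(lv)) lv <- factor(lv)
  levels(lv)
}

# Build one smooth term on `data`. Returns the design block, penalty
# contributions grouped into eigen-blocks, and a blueprint for prediction.
build_term <- function(term, data) {
  n <- nrow(data)
  label <- .term_label(term)
  by_lv <- .by_levels(term, data)
  by_val <- if (!is.null(term$by)) as.character(data[[term$by]]) else NULL

  if (term$kind == "factor_smooth") {
    x <- data[[term$covariates[1]]]
    g <- as.character(data[[term$covariates[2]]])
    lev <- if (is.null(term$by)) sort(unique(g)) else
      sort(unique(paste(g, by_val, sep = "\r")))
    B <- bspline_basis(x, term$k[1], range = range(x))
    K <- ncol(B)
    S1 <- diff_penalty(attr(B, "greville"), order = 1)
    scale1 <- max(abs(S1))
    Xb <- matrix(0, n, K * length(lev))
    key <- if (is.null(term$by)) g else paste(g, by_val, sep = "\r")
    for (j in seq_along(lev)) {
      rows <- key == lev[j]
      Xb[rows, ((j - 1) * K + 1):(j * K)] <- B[rows, , drop = FALSE]
    }
    p_t <- ncol(Xb)
    Sdiff <- diag(length(lev)) %x% (S1 / scale1)
    blocks <- list(list(cols = seq_len(p_t),
                        contrib = list(list(lam = 1L, S = Sdiff),
                                       list(lam = 2L, S = diag(p_t)))))
    blueprint <- list(kind = term$kind, label = label, term = term,
                      basis = attributes(B)[c("knots", "range", "degree",
                                              "greville")],
                      levels = lev, K = K, random = TRUE)
    return(list(X = Xb, n_lambda = 2L, blocks = blocks, label = label,
                blueprint = blueprint))
  }

  lev <- if (is.null(term$by)) NA_character_ else by_lv
  per_level <- vector("list", length(lev))

  if (term$kind == "univariate") {
    x <- data[[term$covariates[1]]]
    B <- bspline_basis(x, term$k[1], range = range(x))
    S <- diff_penalty(attr(B, "greville"), term$penalty_order)
    n_lam <- 1L
    basis_info <- list(attributes(B)[c("knots", "range", "degree",
                                       "greville")])
    for (j in seq_along(lev)) {
      mask <- if (is.null(term$by)) rep(TRUE, n) else by_val == lev[j]
      C <- matrix(colSums(B[mask, , drop = FALSE]), 1)
      Z <- nullspace_of(C)
      Xl <- (B %*% Z) * mask
      per_level[[j]] <- list(X = Xl, S = list(crossprod(Z, S %*% Z)), Z = Z)
    }
  } else {
    x1 <- data[[term$covariates[1]]]
    x2 <- data[[term$covariates[2]]]
    B1 <- bspline_basis(x1, term$k[1], range = range(x1))
    B2 <- bspline_basis(x2, term$k[length(term$k)], range = range(x2))
    TT <- row_kronecker(B1, B2)
    S1 <- diff_penalty(attr(B1, "greville"), term$penalty_order) %x%
      diag(ncol(B2))
    S2 <- diag(ncol(B1)) %x%
      diff_penalty(attr(B2, "greville"), term$penalty_order)
    n_lam <- 2L
    basis_info <- list(attributes(B1)[c("knots", "range", "degree",
                                        "greville")],
                       attributes(B2)[c("knots", "range", "degree",
                                        "greville")])
    for (j in seq_along(lev)) {
      mask <- if (is.null(term$by)) rep(TRUE, n) else by_val == lev[j]
      C <- if (term$kind == "tensor") {
        matrix(colSums(TT[mask, , drop = FALSE]), 1)
      } else {
        M <- cbind(1, B1, B2)[mask, , drop = FALSE]
        crossprod(M, TT[mask, , drop = FALSE])
      }
      Z <- nullspace_of(C)
      Xl <- (TT %*% Z) * mask
      per_level[[j]] <- list(X = Xl, S = list(crossprod(Z, S1 %*% Z),
                                              crossprod(Z, S2 %*% Z)), Z = Z)
    }
  }

  # one lambda per marginal penalty, shared across by-levels; normalize each
  # lambda group by its largest penalty entry so log-lambda scales align
  scales <- vapply(seq_len(n_lam), function(q)
    max(vapply(per_level, function(pl) max(abs(pl$S[[q]])), numeric(1)), 1e-300),
    numeric(1))
  Xb <- do.call(cbind, lapply(per_level, `[[`, "X"))
  blocks <- list()
  off <- 0L
  for (j in seq_along(per_level)) {
    p_l <- ncol(per_level[[j]]$X)
    blocks[[j]] <- list(cols = off + seq_len(p_l),
                        contrib = lapply(seq_len(n_lam), function(q)
                          list(lam = q, S = per_level[[j]]$S[[q]] / scales[q])))
    off <- off + p_l
  }
  blueprint <- list(kind = term$kind, label = label, term = term,
                    basis = basis_info, levels = lev,
                    Z = lapply(per_level, `[[`, "Z"), random = FALSE)
  list(X = Xb, n_lambda = n_lam, blocks = blocks, label = label,
       blueprint = blueprint)
}

# Evaluate one term's design block for new data (prediction).
predict_term <- function(blueprint, newdata, exclude_random = TRUE) {
  n <- nrow(newdata)
  term <- blueprint$term
  if (blueprint$kind == "factor_smooth") {
    if (exclude_random) return(NULL)
    b <- blueprint$basis
    B <- bspline_basis(newdata[[term$covariates[1]]], term$k[1],
                       degree = b$degree, range = b$range)
    K <- blueprint$K
    g <- as.character(newdata[[term$covariates[2]]])
    key <- if (is.null(term$by)) g else
      paste(g, as.character(newdata[[term$by]]), sep = "\r")
    X <- matrix(0, n, K * length(blueprint$levels))
    for (j in seq_along(blueprint$levels)) {
      rows <- key == blueprint$levels[j]
      if (any(rows)) X[rows, ((j - 1) * K + 1):(j * K)] <- B[rows, , drop = FALSE]
    }
    return(X)
  }
  by_val <- if (!is.null(term$by)) as.character(newdata[[term$by]]) else NULL
  if (blueprint$kind == "univariate") {
    b <- blueprint$basis[[1]]
    B <- bspline_basis(newdata[[term$covariates[1]]], term$k[1],
                       degree = b$degree, range = b$range)
    base <- B
  } else {
    b1 <- blueprint$basis[[1]]; b2 <- blueprint$basis[[2]]
    B1 <- bspline_basis(newdata[[term$covariates[1]]], term$k[1],
                        degree = b1$degree, range = b1$range)
    B2 <- bspline_basis(newdata[[term$covariates[2]]],
                        term$k[length(term$k)],
                        degree = b2$degree, range = b2$range)
    base <- row_kronecker(B1, B2)
  }
  out <- vector("list", length(blueprint$levels))
  for (j in seq_along(blueprint$levels)) {
    mask <- if (is.null(term$by)) rep(TRUE, n) else
      by_val == blueprint$levels[j]
    out[[j]] <- (base %*% blueprint$Z[[j]]) * mask
  }
  do.call(cbind, out)
}

# ---- fitting ---------------------------------------------------------------

.ar1_whiten <- function(M, series, rho) {
  if (rho == 0) return(M)
  M <- as.matrix(M)
  n <- nrow(M)
  first <- !duplicated(series)
  lag <- rbind(0, M[-n, , drop = FALSE])
  W <- M - rho * lag
  W[first, ] <- sqrt(1 - rho^2) * M[first, , drop = FALSE]
  W
}

.fit_control <- function(control) {
  utils::modifyList(list(maxit = 150, starts = 2, seed = 1, reltol = 1e-7),
                    control %||% list())
}

#' Fit a penalized-spline trajectory model
#'
#' Responses and design rows are AR1-pre-whitened within each series at the
#' fixed \code{rho} of the model specification (the first sample of each
#' series is scaled by
#' \code{sqrt(1 - rho^2)}). Smoothing parameters maximize the exact Gaussian
#' log marginal likelihood (coefficients integrated out under the penalty
#' prior, sigma^2 profiled) by Nelder-Mead over log-lambda with deterministic
#' plus seeded random restarts; coefficients come from penalized least
#' squares at the optimum, and each term's effective degrees of freedom are
#' the trace of its block of the influence matrix.
#'
#' @param table model data frame (e.g. from
#'   \code{\link{assemble_model_table}}).
#' @param spec a \code{\link{model_spec}}.
#' @param lambda optional fixed smoothing parameters (recycled over the
#'   model's lambda slots; skips optimization). \code{lambda = 0} gives the
#'   unpenalized fit.
#' @param control list: \code{maxit}, \code{starts}, \code{seed},
#'   \code{reltol} for the optimizer.
#' @param start optional extra log-lambda starting vector (e.g. a warm start
#'   from a nested model), tried in addition to the default starts.
#' @return an object of class \code{discform_fit} with elements including
#'   \code{coefficients}, \code{lambda}, \code{ml_score} (negative log
#'   marginal likelihood; smaller is better), \code{edf} (per term),
#'   \code{fitted}, \code{residuals} (response scale, original row order),
#'   \code{n_used}.
#' @export
fit_model <- function(table, spec, lambda = NULL, control = list(),
                      start = NULL) {
  ctrl <- .fit_control(control)
  df <- as.data.frame(table)
  need <- unique(c(spec$response, spec$fixed, spec$series,
                   unlist(lapply(spec$terms, function(t)
                     c(t$covariates, t$by)))))
  miss <- setdiff(need[!is.na(need)], names(df))
  if (length(miss))
    stopf("model table lacks column(s): %s", paste(miss, collapse = ", "))

  series <- if (is.null(spec$series)) rep(1L, nrow(df)) else
    interaction(df[spec$series], drop = TRUE)
  ord <- if (!is.null(spec$time_var) && spec$time_var %in% names(df))
    order(series, df[[spec$time_var]]) else order(series)
  df <- df[ord, , drop = FALSE]
  series <- series[ord]

  y <- df[[spec$response]]
  if (length(spec$fixed) > 0) {
    for (f in spec$fixed) if (!is.factor(df[[f]])) df[[f]] <- factor(df[[f]])
    Xf <- stats::model.matrix(stats::reformulate(spec$fixed), df)
    xlev <- lapply(df[spec$fixed], levels)
  } else {
    Xf <- matrix(1, nrow(df), 1, dimnames = list(NULL, "(Intercept)"))
    xlev <- list()
  }

  built <- lapply(spec$terms, build_term, data = df)
  X <- do.call(cbind, c(list(Xf), lapply(built, `[[`, "X")))
  p <- ncol(X)
  n <- nrow(X)

  # global bookkeeping: term column ranges, lambda slots, eigen-blocks
  term_cols <- list(fixed = seq_len(ncol(Xf)))
  blocks <- list()
  lam_offset <- 0L
  n_lambda <- 0L
  off <- ncol(Xf)
  for (b in built) {
    cols <- off + seq_len(ncol(b$X))
    term_cols[[b$label]] <- cols
    for (blk in b$blocks) {
      blocks[[length(blocks) + 1L]] <- list(
        cols = off + blk$cols,
        contrib = lapply(blk$contrib, function(cc)
          list(lam = lam_offset + cc$lam, S = cc$S)))
    }
    off <- off + ncol(b$X)
    lam_offset <- lam_offset + b$n_lambda
  }
  n_lambda <- lam_offset

  wX <- .ar1_whiten(X, series, spec$rho)
  wy <- as.numeric(.ar1_whiten(matrix(y), series, spec$rho))
  XtX <- crossprod(wX)
  Xty <- crossprod(wX, wy)
  yty <- sum(wy^2)

  assemble <- function(lam) {
    A <- XtX
    logdetS <- 0
    rank_S <- 0L
    for (blk in blocks) {
      S <- 0
      for (cc in blk$contrib) S <- S + lam[cc$lam] * cc$S
      A[blk$cols, blk$cols] <- A[blk$cols, blk$cols] + S
      ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
      tol <- max(ev, 0) * 1e-10
      pos <- ev > tol
      logdetS <- logdetS + sum(log(ev[pos]))
      rank_S <- rank_S + sum(pos)
    }
    list(A = A, logdetS = logdetS, Mp = p - rank_S)
  }

  score_of <- function(loglam) {
    lam <- exp(pmin(pmax(loglam, -30), 30))
    asm <- assemble(lam)
    R <- tryCatch(chol(asm$A), error = function(e) NULL)
    if (is.null(R)) {
      R <- tryCatch(chol(asm$A + diag(1e-8 * mean(diag(XtX)), p)),
                    error = function(e) NULL)
      if (is.null(R)) return(1e30)
    }
    beta <- backsolve(R, forwardsolve(t(R), Xty))
    rss_pen <- max(yty - sum(beta * Xty), 1e-12 * max(yty, 1))
    nf <- n - asm$Mp
    if (nf <= 0) return(1e30)
    sigma2 <- rss_pen / nf
    0.5 * (nf * (log(2 * pi * sigma2) + 1) + 2 * sum(log(diag(R))) -
             asm$logdetS)
  }

  if (!is.null(lambda)) {
    lam <- rep_len(lambda, max(n_lambda, 1L))
    loglam <- log(pmax(lam, 1e-300))
    loglam[lam == 0] <- -300
  } else if (n_lambda == 0L) {
    loglam <- numeric(0)
  } else {
    starts <- list(rep(0, n_lambda))
    if (!is.null(start) && length(start) == n_lambda)
      starts <- c(list(start), starts)
    if (ctrl$starts > 1) {
      extra <- with_seed(ctrl$seed, lapply(seq_len(ctrl$starts - 1),
                                           function(i) stats::rnorm(n_lambda, 0, 2)))
      starts <- c(starts, extra)
    }
    best <- NULL
    for (s in starts) {
      opt <- if (n_lambda == 1L)
        stats::optim(s, score_of, method = "Brent", lower = -25, upper = 25)
      else
        stats::optim(s, score_of, method = "Nelder-Mead",
                     control = list(maxit = ctrl$maxit, reltol = ctrl$reltol))
      if (is.null(best) || opt$value < best$value) best <- opt
    }
    loglam <- best$par
  }
  lam <- if (length(loglam)) exp(pmin(pmax(loglam, -300), 30)) else numeric(0)
  if (!is.null(lambda)) lam <- rep_len(lambda, max(n_lambda, 1L))

  asm <- assemble(lam)
  A <- asm$A
  R <- tryCatch(chol(A), error = function(e)
    chol(A + diag(1e-8 * mean(diag(XtX)), p)))
  beta <- backsolve(R, forwardsolve(t(R), Xty))
  rss_pen <- max(yty - sum(beta * Xty), 0)
  nf <- n - asm$Mp
  sigma2 <- rss_pen / max(nf, 1)
  ml_score <- 0.5 * (nf * (log(2 * pi * max(sigma2, 1e-300)) + 1) +
                       2 * sum(log(diag(R))) - asm$logdetS)
  Ainv <- chol2inv(R)
  diagF <- rowSums(Ainv * XtX)
  edf <- vapply(term_cols, function(cols) sum(diagF[cols]), numeric(1))

  fitted_sorted <- as.numeric(X %*% beta)
  resid_sorted <- y - fitted_sorted
  wresid_sorted <- wy - as.numeric(wX %*% beta)
  inv <- order(ord)

  fit <- list(coefficients = beta, lambda = lam, loglam = loglam,
              ml_score = ml_score, edf = edf, edf_total = sum(diagF),
              sigma2 = sigma2, n_used = n, Mp = asm$Mp,
              fitted = fitted_sorted[inv], residuals = resid_sorted[inv],
              residuals_white = wresid_sorted[inv],
              spec = spec, xlev = xlev,
              blueprints = lapply(built, `[[`, "blueprint"),
              term_cols = term_cols, control = ctrl)
  class(fit) <- "discform_fit"
  fit
}

#' @export
print.discform_fit <- function(x, ...) {
  cat(sprintf("penalized-spline fit: n = %d, total edf = %.2f, ML score = %.3f\n",
              x$n_used, x$edf_total, x$ml_score))
  for (nm in names(x$edf))
    cat(sprintf("  %-28s edf %7.2f\n", nm, x$edf[[nm]]))
  invisible(x)
}

#' Predict from a fitted trajectory model
#'
#' @param object a \code{discform_fit}.
#' @param newdata data frame with the model's covariates and factors.
#' @param exclude_random drop grouped (random) factor-smooth contributions
#'   (default TRUE — population-level predictions).
#' @param ... unused.
#' @return numeric vector of predicted responses.
#' @export
predict.discform_fit <- function(object, newdata, exclude_random = TRUE,
                                 ...) {
  spec <- object$spec
  if (length(spec$fixed) > 0) {
    for (f in spec$fixed)
      newdata[[f]] <- factor(newdata[[f]], levels = object$xlev[[f]])
    Xf <- stats::model.matrix(stats::reformulate(spec$fixed), newdata)
  } else {
    Xf <- matrix(1, nrow(newdata), 1)
  }
  pieces <- list(Xf)
  for (bp in object$blueprints) {
    Xt <- predict_term(bp, newdata, exclude_random = exclude_random)
    if (is.null(Xt)) Xt <- matrix(0, nrow(newdata),
                                  length(object$term_cols[[bp$label]]))
    pieces[[length(pieces) + 1L]] <- Xt
  }
  X <- do.call(cbind, pieces)
  as.numeric(X %*% object$coefficients)
}

#' Trim large residuals and refit once
#'
#' Removes rows whose standardized (whitened-scale) residuals exceed
#' \code{k} standard deviations, then refits the model on the remaining
#' rows. Applied once, not iterated.
#'
#' @param fit a \code{discform_fit} computed on \code{table}.
#' @param table the model table the fit used.
#' @param spec its \code{\link{model_spec}}.
#' @param k trim threshold in residual standard deviations (default 2.5).
#' @param lambda,control passed on to \code{\link{fit_model}}.
#' @return the refitted \code{discform_fit}; attribute \code{"rows_kept"}
#'   holds the logical keep mask, \code{"trim_warning"} is TRUE when more
#'   than 20 percent of rows were removed.
#' @export
trim_and_refit <- function(fit, table, spec, k = 2.5, lambda = NULL,
                           control = fit$control) {
  r <- fit$residuals_white
  keep <- abs(r / stats::sd(r)) <= k
  warn <- mean(!keep) > 0.2
  if (warn)
    warning(sprintf("residual trimming removed %.1f%% of rows",
                    100 * mean(!keep)))
  refit <- fit_model(table[keep, , drop = FALSE], spec, lambda = lambda,
                     control = control)
  attr(refit, "rows_kept") <- keep
  attr(refit, "trim_warning") <- warn
  refit
}

# ---- the model ladder ------------------------------------------------------

.ladder_specs <- function(activation, rho = 0.8, dbc_col = "dbc") {
  te_dur <- function(by) smooth_term("tensor", c("time", "log_duration"),
                                     by = by, k = c(5, 5))
  fs_spk <- smooth_term("factor_smooth", c("time", "speaker"),
                        by = "dimension", k = 5)
  s_act <- function(by) smooth_term("univariate", activation, by = by, k = 10)
  ti_act <- function(by) smooth_term("partial_tensor", c("time", activation),
                                     by = by, k = c(5, 5))
  base <- list(te_dur(dbc_col), fs_spk)
  list(
    m0 = model_spec(base, fixed = dbc_col, rho = rho),
    m1 = model_spec(c(base, list(s_act("dimension"))), fixed = dbc_col,
                    rho = rho),
    m2 = model_spec(c(base, list(s_act(dbc_col))), fixed = dbc_col,
                    rho = rho),
    m3 = model_spec(c(base, list(s_act(dbc_col), ti_act("dimension"))),
                    fixed = dbc_col, rho = rho),
    m4 = model_spec(c(base, list(s_act(dbc_col), ti_act(dbc_col))),
                    fixed = dbc_col, rho = rho))
}

#' Fit the baseline-to-activation model ladder
#'
#' Fits the baseline model m0 (dimension-by-class intercepts, a tensor
#' smooth of time by log vowel duration per dbc level, and by-speaker random
#' factor smooths of time per dimension) and then m1--m4, which add the
#' activation predictor as a by-dimension smooth (m1), a by-dbc smooth (m2),
#' and additionally a time-by-activation interaction tensor by dimension
#' (m3) or by dbc (m4). Reports the marginal-likelihood improvement
#' \code{delta_ml = ml_score(m0) - ml_score(mk)} (positive = better fit) and
#' the change in total effective degrees of freedom.
#'
#' @param table a \code{\link{assemble_model_table}} result.
#' @param activation name of the activation column to test.
#' @param models which of m1--m4 to fit (default all).
#' @param rho fixed AR1 coefficient (default 0.8).
#' @param m0_fit optional pre-fitted baseline (reused across ladders on the
#'   same table).
#' @param collapse_classes if TRUE, additionally refit the baseline with
#'   each pair of word classes merged and report the ML change (a check that
#'   the three classes are genuinely distinct).
#' @param control optimizer control, see \code{\link{fit_model}}.
#' @return list with \code{fits} (named list of \code{discform_fit}) and
#'   \code{report} (data frame: model, ml_score, delta_ml, edf_total,
#'   delta_edf), plus \code{collapse} when requested.
#' @export
ml_ladder <- function(table, activation, models = c("m1", "m2", "m3", "m4"),
                      rho = 0.8, m0_fit = NULL, collapse_classes = FALSE,
                      control = list()) {
  specs <- .ladder_specs(activation, rho = rho)
  fits <- list()
  refine_m0 <- is.null(m0_fit)
  fits$m0 <- m0_fit %||% fit_model(table, specs$m0, control = control)
  warm0 <- fits$m0$loglam
  for (m in models) {
    extra <- length(unlist(lapply(specs[[m]]$terms, function(t)
      if (t$kind == "univariate") 1 else 1:2))) -
      length(warm0)
    warm <- if (extra >= 0) c(warm0, rep(0, extra)) else NULL
    fits[[m]] <- fit_model(table, specs[[m]], control = control,
                           start = warm)
  }
  if (refine_m0 && length(models) > 0) {
    # every ladder model shares the baseline's penalty structure as a
    # prefix; feed their optima back as starting points so the baseline is
    # never under-optimized relative to the models it is compared with
    ctrl1 <- utils::modifyList(.fit_control(control), list(starts = 1))
    n0 <- length(warm0)
    for (m in models) {
      cand <- fit_model(table, specs$m0, control = ctrl1,
                        start = fits[[m]]$loglam[seq_len(n0)])
      if (cand$ml_score < fits$m0$ml_score) fits$m0 <- cand
    }
  }
  ml0 <- fits$m0$ml_score
  edf0 <- fits$m0$edf_total
  report <- data.frame(
    model = names(fits),
    ml_score = vapply(fits, `[[`, numeric(1), "ml_score"),
    delta_ml = ml0 - vapply(fits, `[[`, numeric(1), "ml_score"),
    edf_total = vapply(fits, `[[`, numeric(1), "edf_total"),
    delta_edf = vapply(fits, `[[`, numeric(1), "edf_total") - edf0,
    row.names = NULL, stringsAsFactors = FALSE)
  out <- list(fits = fits, report = report, activation = activation)
  if (collapse_classes) {
    classes <- sort(unique(as.character(table$word_class)))
    coll <- list()
    for (i in seq_along(classes)) for (j in seq_len(i - 1L)) {
      t2 <- table
      merged <- as.character(t2$word_class)
      merged[merged %in% c(classes[i], classes[j])] <- "merged"
      t2$word_class <- merged
      t2$dbc <- factor(paste(as.character(t2$dimension), merged, sep = "."))
      f <- fit_model(t2, specs$m0, control = control)
      coll[[paste(classes[j], classes[i], sep = "+")]] <-
        c(ml_score = f$ml_score, delta_ml_vs_m0 = ml0 - f$ml_score)
    }
    out$collapse <- coll
  }
  class(out) <- "discform_ladder"
  out
}

#' @export
print.discform_ladder <- function(x, ...) {
  cat(sprintf("model ladder for '%s'\n", x$activation))
  print(x$report, row.names = FALSE)
  invisible(x)
}

#' Predicted trajectories at percentiles of a covariate
#'
#' Predicts population-level (random smooths excluded) F1/F2 z-score
#' trajectories over a 100-point normalized-time grid at the requested
#' percentiles of \code{variable}, holding other covariates at their medians
#' and factors at reference levels (the most frequent word class).
#'
#' @param fit a \code{discform_fit} on an assembled model table.
#' @param table the model table (supplies percentile and median values).
#' @param variable covariate to vary (e.g. an activation column or
#'   \code{"log_duration"}).
#' @param percentiles percentiles in (0, 100); default 10, 30, 50, 70, 90.
#' @param n_grid time-grid resolution (default 100; endpoints exactly 0
#'   and 1).
#' @return data frame with columns \code{percentile}, \code{time},
#'   \code{f1_z}, \code{f2_z} — suitable for plotting F2 against F1.
#' @export
predict_percentile_trajectories <- function(fit, table, variable,
                                            percentiles = c(10, 30, 50, 70, 90),
                                            n_grid = 100) {
  if (any(percentiles <= 0 | percentiles >= 100))
    stopf("percentiles must lie strictly inside (0, 100)")
  qs <- stats::quantile(table[[variable]], percentiles / 100, names = FALSE)
  tgrid <- seq(0, 1, length.out = n_grid)
  covs <- setdiff(unique(unlist(lapply(fit$spec$terms, `[[`, "covariates"))),
                  c("time", variable, "speaker"))
  ref_class <- names(sort(table(as.character(table$word_class)),
                          decreasing = TRUE))[1]
  dims <- levels(factor(table$dimension))
  out <- list()
  for (pi in seq_along(percentiles)) {
    preds <- list()
    for (d in dims) {
      nd <- data.frame(time = tgrid, dimension = d,
                       dbc = paste(d, ref_class, sep = "."),
                       speaker = NA_character_,
                       stringsAsFactors = FALSE)
      nd[[variable]] <- qs[pi]
      for (cv in covs) nd[[cv]] <- stats::median(table[[cv]])
      preds[[d]] <- predict(fit, nd, exclude_random = TRUE)
    }
    out[[pi]] <- data.frame(percentile = percentiles[pi], time = tgrid,
                            f1_z = preds[[dims[1]]],
                            f2_z = if (length(dims) > 1) preds[[dims[2]]]
                            else NA_real_)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
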