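simple_smooth_data <- function(n = 500, sd = 0.1, seed = 1) {
  set.seed(seed)
  x <- runif(n)
  data.frame(response = sin(2 * pi * x) + rnorm(n, 0, sd), x = x,
             truth = sin(2 * pi * x))
}

uni_spec <- function(k = 10)
  model_spec(list(smooth_term("univariate", "x", k = k)),
             fixed = character(0), rho = 0, series = NULL, time_var = "x")

test_that("zero penalty reproduces unpenalized least squares", {
  df <- simple_smooth_data(200, sd = 0.3, seed = 4)
  fit <- fit_model(df, uni_spec(), lambda = 0)
  B <- bspline_basis(df$x, 10)
  ols <- stats::lm.fit(B, df$response)
  expect_lt(max(abs(fit$residuals - ols$residuals)), 1e-8)
  expect_equal(fit$edf_total, 10, tolerance = 1e-6)
})

test_that("infinite penalty converges to the ordinary least-squares line", {
  df <- simple_smooth_data(200, sd = 0.3, seed = 5)
  fit <- fit_model(df, uni_spec(), lambda = 1e12)
  line <- stats::lm(response ~ x, df)
  expect_lt(max(abs(fit$fitted - stats::fitted(line))), 1e-4)
  expect_equal(fit$edf_total, 2, tolerance = 1e-3)
})

test_that("marginal-likelihood smoothing recovers a sine curve", {
  df <- simple_smooth_data(500, sd = 0.1, seed = 6)
  fit <- fit_model(df, uni_spec())
  expect_lt(sqrt(mean((fit$fitted - df$truth)^2)), 0.05)
  expect_gt(fit$edf_total - 1, 4)   # smooth edf excluding the intercept
  expect_lt(fit$edf_total - 1, 9)
})

test_that("the fit agrees with an independent GAMM implementation", {
  skip_if_not_installed("mgcv")
  df <- simple_smooth_data(400, sd = 0.15, seed = 7)
  fit <- fit_model(df, uni_spec())
  g <- mgcv::gam(response ~ s(x, k = 10), data = df, method = "ML")
  expect_lt(sqrt(mean((fit$fitted - stats::fitted(g))^2)), 0.03)
})

test_that("edf decreases monotonically in lambda", {
  df <- simple_smooth_data(300, sd = 0.2, seed = 8)
  edfs <- vapply(c(1e-4, 1e-2, 1, 1e2, 1e4), function(l)
    fit_model(df, uni_spec(), lambda = l)$edf_total, numeric(1))
  expect_true(all(diff(edfs) < 0))
})

test_that("AR1 pre-whitening transforms series as specified", {
  X <- matrix(c(1, 2, 4, 7, 1, 1, 1, 1), ncol = 2)
  series <- c("a", "a", "a", "b")
  W <- discform:::.ar1_whiten(X, series, 0.5)
  expect_equal(W[1, ], sqrt(0.75) * X[1, ])
  expect_equal(W[2, ], X[2, ] - 0.5 * X[1, ])
  expect_equal(W[3, ], X[3, ] - 0.5 * X[2, ])
  expect_equal(W[4, ], sqrt(0.75) * X[4, ])
  expect_identical(discform:::.ar1_whiten(X, series, 0), X)
})

ar1_table <- function(seed = 9, n_tok = 60) {
  set.seed(seed)
  rows <- list()
  for (i in seq_len(n_tok)) {
    m <- sample(4:8, 1)
    tt <- seq(0, 1, length.out = m)
    for (d in c("F1", "F2")) {
      e <- as.numeric(stats::filter(rnorm(m, 0, 0.3), 0.6,
                                    method = "recursive"))
      rows[[length(rows) + 1]] <- data.frame(
        token_id = sprintf("t%03d", i), time = tt, dimension = d,
        x = runif(1),
        response = sin(2 * pi * tt) * (1 + (d == "F2")) + e,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

test_that("the ML score ignores row order within series", {
  tab <- ar1_table(10)
  sp <- model_spec(list(smooth_term("univariate", "time", by = "dimension",
                                    k = 8)),
                   fixed = "dimension", rho = 0.6,
                   series = c("token_id", "dimension"), time_var = "time")
  f1 <- fit_model(tab, sp)
  set.seed(1)
  perm <- sample(nrow(tab))
  f2 <- fit_model(tab[perm, ], sp)
  expect_equal(f2$ml_score, f1$ml_score, tolerance = 1e-8)
  expect_equal(f2$fitted, f1$fitted[perm], tolerance = 1e-8)
})

test_that("with rho = 0 whitening is the identity transform", {
  tab <- ar1_table(11)
  sp0 <- model_spec(list(smooth_term("univariate", "time", by = "dimension",
                                     k = 8)),
                    fixed = "dimension", rho = 0,
                    series = c("token_id", "dimension"), time_var = "time")
  f0 <- fit_model(tab, sp0, lambda = 1)
  spn <- sp0; spn$series <- NULL
  tab_sorted <- tab[order(interaction(tab$token_id, tab$dimension),
                          tab$time), ]
  f1 <- fit_model(tab_sorted, spn, lambda = 1)
  expect_equal(sort(f0$fitted), sort(f1$fitted), tolerance = 1e-9)
  expect_equal(f0$ml_score, f1$ml_score, tolerance = 1e-8)
})

test_that("residual trimming removes exactly the planted outlier, once", {
  df <- simple_smooth_data(300, sd = 0.1, seed = 12)
  fit0 <- fit_model(df, uni_spec())
  # no violators: the refit uses every row
  refit0 <- trim_and_refit(fit0, df, uni_spec(), k = 10)
  expect_true(all(attr(refit0, "rows_kept")))
  expect_equal(refit0$ml_score, fit0$ml_score, tolerance = 1e-6)

  df2 <- df
  df2$response[17] <- df2$response[17] + 10 * 0.1 * 30
  fit <- fit_model(df2, uni_spec())
  trimmed <- trim_and_refit(fit, df2, uni_spec(), k = 2.5)
  kept <- attr(trimmed, "rows_kept")
  expect_false(kept[17])
  expect_gt(mean(kept), 0.95)
  expect_equal(trimmed$n_used, sum(kept))
})

test_that("factor smooths absorb speaker-specific trajectories", {
  set.seed(13)
  rows <- list()
  off <- c(s1 = 1, s2 = -1, s3 = 0.5)
  for (i in 1:45) {
    sp <- names(off)[(i %% 3) + 1]
    tt <- seq(0, 1, length.out = 6)
    rows[[i]] <- data.frame(token_id = sprintf("t%02d", i), time = tt,
                            dimension = "F1", speaker = sp,
                            response = sin(pi * tt) + off[sp] +
                              rnorm(6, 0, 0.1),
                            stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  sp <- model_spec(list(smooth_term("univariate", "time", k = 8),
                        smooth_term("factor_smooth", c("time", "speaker"),
                                    k = 5)),
                   fixed = character(0), rho = 0,
                   series = c("token_id", "dimension"), time_var = "time")
  fit <- fit_model(tab, sp)
  expect_gt(fit$edf[["fs(time,speaker)"]], 1.5)
  # random-effect predictions recover the speaker offsets
  nd <- data.frame(time = 0.5, dimension = "F1",
                   speaker = names(off), stringsAsFactors = FALSE)
  pr_with <- predict(fit, nd, exclude_random = FALSE)
  pr_without <- predict(fit, nd, exclude_random = TRUE)
  est_off <- pr_with - pr_without
  expect_gt(stats::cor(est_off, off), 0.99)
})

test_that("percentile trajectories order with an injected monotone effect", {
  set.seed(14)
  rows <- list()
  for (i in 1:80) {
    a <- runif(1)
    tt <- seq(0, 1, length.out = 5)
    for (d in c("F1", "F2")) {
      rows[[length(rows) + 1]] <- data.frame(
        token_id = sprintf("t%03d", i), time = tt, dimension = d,
        word_class = "content", dbc = paste(d, "content", sep = "."),
        log_duration = log(0.06), speaker = "s1", act = a,
        response = sin(pi * tt) + 2 * a + rnorm(5, 0, 0.1),
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  sp <- model_spec(list(smooth_term("univariate", "act",
                                    by = "dimension", k = 6)),
                   fixed = "dimension", rho = 0,
                   series = c("token_id", "dimension"), time_var = "time")
  fit <- fit_model(tab, sp)
  tr <- predict_percentile_trajectories(fit, tab, "act")
  expect_equal(range(tr$time), c(0, 1))
  expect_equal(nrow(tr), 5 * 100)
  heights <- tapply(tr$f1_z, tr$percentile, mean)
  expect_true(all(diff(heights) > 0))
  expect_error(predict_percentile_trajectories(fit, tab, "act",
                                               percentiles = c(0, 50)),
               "percentiles")

  # with all smooth coefficients zeroed the trajectories coincide
  fit0 <- fit
  fit0$coefficients[-seq_along(fit$term_cols$fixed)] <- 0
  tr0 <- predict_percentile_trajectories(fit0, tab, "act")
  expect_lt(max(abs(tr0$f1_z - mean(tr0$f1_z))), 1e-10)
})
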