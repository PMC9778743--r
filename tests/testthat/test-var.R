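test_that("zero-noise VAR(1) is recovered exactly", {
  A1 <- matrix(c(0.5, 0.1, -0.2, 0.4), 2, 2)
  cvec <- c(0.3, -0.1)
  Y <- matrix(0, 50, 2)
  Y[1, ] <- c(1, 1)
  for (t in 2:50) Y[t, ] <- cvec + A1 %*% Y[t - 1, ]
  colnames(Y) <- c("a", "b")
  fit <- fit_var(Y, 1)
  expect_equal(unname(fit$intercept), cvec, tolerance = 1e-8)
  expect_equal(unname(fit$A[[1]]), A1, tolerance = 1e-8)
  expect_true(all(abs(fit$residuals) < 1e-8))
})

test_that("coefficients equal the normal-equations oracle", {
  withr::with_seed(21, {
    for (i in 1:30) {
      K <- sample(2:4, 1)
      p <- sample(1:3, 1)
      T_n <- 40 + sample(0:40, 1)
      Y <- matrix(rnorm(T_n * K), T_n, K)
      fit <- fit_var(Y, p)
      rows <- (p + 1):T_n
      X <- matrix(1, length(rows), 1)
      for (j in 1:p) X <- cbind(X, Y[rows - j, , drop = FALSE])
      for (k in 1:K) {
        beta <- ols_oracle(X, Y[rows, k])$beta
        expect_equal(unname(fit$coef_matrix[, k]), as.vector(beta),
                     tolerance = 1e-8)
      }
    }
  })
})

test_that("residual means are ~0 and Sigma is symmetric PSD", {
  Y <- sim_var_direct(list(0.5 * diag(3)), diag(3), T = 300, seed = 4)
  fit <- fit_var(Y, 1)
  expect_true(all(abs(colMeans(fit$residuals)) < 1e-8))
  expect_equal(fit$Sigma, t(fit$Sigma))
  expect_true(min(eigen(fit$Sigma, symmetric = TRUE)$values) > -1e-10)
  expect_equal(fit$T_effective, 299)
})

test_that("coefficient error shrinks as T grows", {
  A1 <- matrix(c(0.5, 0.2, -0.1, 0.3), 2, 2)
  err <- sapply(c(200, 2000), function(T_n) {
    e <- sapply(1:10, function(i) {
      Y <- sim_var_direct(list(A1), diag(2), T = T_n, seed = 100 + i)
      mean(abs(fit_var(Y, 1)$A[[1]] - A1))
    })
    mean(e)
  })
  expect_lt(err[2], err[1])
})

test_that("tidy and glance expose the fitted model", {
  Y <- sim_var_direct(list(0.5 * diag(2)), diag(2), T = 100, seed = 2)
  fit <- fit_var(Y, 2)
  td <- tidy(fit)
  expect_equal(nrow(td), 2 + 2 * 4)  # intercepts + 2 lags x K^2
  expect_setequal(unique(td$lag), 0:2)
  gl <- glance(fit)
  expect_equal(gl$p, 2)
  expect_true(gl$stable)
})

test_that("insufficient rows and rank deficiency are errors", {
  Y <- matrix(rnorm(10 * 4), 10, 4)
  expect_error(fit_var(Y, 3), "need T >=")
  Yd <- cbind(a = rnorm(50), b = rnorm(50))
  Yd <- cbind(Yd, c = Yd[, "a"] + Yd[, "b"])  # exact collinearity
  expect_error(fit_var(Yd, 1), "rank-deficient")
})

test_that("AIC/BIC penalty ordering flips exactly at ln(T_c) = 2", {
  # ln(T_c) > 2 makes the BIC penalty the larger one
  Y_small <- sim_var_direct(list(0.3 * diag(2)), diag(2), T = 9, seed = 7)
  sel_small <- select_lag(Y_small, 2)     # T_c = 7, ln < 2
  expect_true(all(sel_small$criteria$bic <= sel_small$criteria$aic))
  Y_big <- sim_var_direct(list(0.3 * diag(2)), diag(2), T = 102, seed = 7)
  sel_big <- select_lag(Y_big, 2)         # T_c = 100, ln > 2
  expect_true(all(sel_big$criteria$bic >= sel_big$criteria$aic))
})

test_that("lag selection is deterministic and tie-breaks to smaller order", {
  Y <- sim_var_direct(list(0.4 * diag(2)), diag(2), T = 300, seed = 13)
  s1 <- select_lag(Y, 5)
  s2 <- select_lag(Y, 5)
  expect_identical(s1, s2)
  expect_equal(s1$bic_order, s1$criteria$p[which.min(s1$criteria$bic)])
  # forced exact tie: constant series is impossible here, so check the
  # documented rule on a synthetic criteria table instead
  crit <- tibble::tibble(p = 1:3, aic = c(1, 1, 2), bic = c(1, 1, 2))
  expect_equal(crit$p[which.min(crit$aic)], 1)
})

test_that("white noise selects the smallest candidate order", {
  picks <- sapply(1:40, function(i) {
    Y <- withr::with_seed(300 + i, matrix(rnorm(500 * 2), 500, 2))
    select_lag(Y, 4)$bic_order
  })
  expect_gte(mean(picks == 1), 0.8)
})

test_that("companion matrix has the stacked-identity structure", {
  Y <- sim_var_direct(list(0.5 * diag(2)), diag(2), T = 100, seed = 3)
  fit1 <- fit_var(Y, 1)
  expect_equal(companion_matrix(fit1), unname(fit1$A[[1]]))

  # K = 1, p = 2 with coefficients (0.5, 0.3)
  y <- numeric(60); y[1:2] <- c(1, 0.5)
  e <- withr::with_seed(9, rnorm(60, sd = 0.1))
  for (t in 3:60) y[t] <- 0.5 * y[t - 1] + 0.3 * y[t - 2] + e[t]
  fit2 <- fit_var(matrix(y, ncol = 1), 2)
  C <- companion_matrix(fit2)
  expect_equal(C[2, ], c(1, 0))
  expect_equal(C[1, ], c(fit2$A[[1]][1, 1], fit2$A[[2]][1, 1]))
  # companion eigenvalues equal the inverse characteristic roots (scalar case)
  roots <- polyroot(c(1, -fit2$A[[1]][1, 1], -fit2$A[[2]][1, 1]))
  expect_equal(sort(Mod(eigen(C)$values)), sort(Mod(1 / roots)),
               tolerance = 1e-8)
})

test_that("stability verdicts match the analytic cases", {
  mk_model <- function(a) {
    Y <- sim_var_direct(list(0.2 * diag(4)), diag(4), T = 60, seed = 5)
    fit <- fit_var(Y, 1)
    fit$A[[1]] <- a * diag(4)
    fit
  }
  stable <- check_stability(mk_model(0.5))
  expect_true(stable$is_stable)
  expect_equal(stable$moduli, rep(0.5, 4))
  unstable <- check_stability(mk_model(1.1))
  expect_false(unstable$is_stable)
  expect_equal(unstable$max_modulus, 1.1)
})

test_that("scalar AR(1) stability agrees with |a| < 1 exactly", {
  mk <- function(a) {
    y <- numeric(80); e <- withr::with_seed(6, rnorm(80))
    for (t in 2:80) y[t] <- a * y[t - 1] + e[t]
    fit <- fit_var(matrix(y, ncol = 1), 1)
    fit$A[[1]][1, 1] <- a
    fit
  }
  for (a in c(-1.5, -0.99, 0, 0.99, 1, 1.0001)) {
    expect_equal(check_stability(mk(a))$is_stable, abs(a) < 1)
  }
})

test_that("random stable-by-construction models are reported stable", {
  withr::with_seed(31, {
    for (i in 1:100) {
      K <- sample(2:4, 1)
      A1 <- matrix(rnorm(K * K), K, K)
      A1 <- A1 * (0.9 / max(Mod(eigen(A1, only.values = TRUE)$values)))
      Y <- sim_var_direct(list(A1), diag(K), T = 80, seed = 1000 + i)
      fit <- fit_var(Y, 1)
      fit$A[[1]] <- A1
      expect_true(check_stability(fit)$is_stable)
    }
  })
})

test_that("Granger F and p match the brute-force oracle", {
  withr::with_seed(41, {
    for (i in 1:30) {
      K <- sample(2:4, 1)
      p <- sample(1:3, 1)
      Y <- matrix(rnorm(120 * K), 120, K)
      colnames(Y) <- paste0("v", 1:K)
      pair <- sample(colnames(Y), 2)
      got <- granger_test(Y, pair[1], pair[2], p)
      ref <- granger_oracle(Y, pair[1], pair[2], p)
      expect_equal(got$F, ref$F, tolerance = 1e-8)
      expect_equal(got$p_value, ref$p_value, tolerance = 1e-8)
      expect_equal(got$df_den, ref$df_den)
      expect_gte(got$F, 0)
    }
  })
})

test_that("granger_test rejects bad arguments", {
  Y <- matrix(rnorm(100 * 2), 100, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(granger_test(Y, "a", "a", 1), "must differ")
  expect_error(granger_test(Y, "a", "zz", 1), "panel columns")
})

test_that("granger_matrix runs six directed hypotheses deterministically", {
  truth <- var_truth_preset("anxiety-driver")
  panel <- simulate_var_series(truth, T = 300, seed = 17)
  g1 <- granger_matrix(panel[, -1], p = 1)
  expect_equal(nrow(g1), 6)
  expect_equal(g1$cause[1:3], c("anger", "anxiety", "sadness"))
  expect_equal(g1$effect[4:6], c("anger", "anxiety", "sadness"))
  expect_identical(g1, granger_matrix(panel[, -1], p = 1))
})

test_that("a lag-1 copy of behavior is detected in both directions", {
  # behavior is AR(2); anger is behavior shifted one week (plus tiny noise so
  # the unrestricted RSS is not exactly zero), so each variable's past helps
  # predict the other
  withr::with_seed(55, {
    n <- 600
    b <- numeric(n)
    e <- rnorm(n)
    for (t in 3:n) b[t] <- 0.5 * b[t - 1] + 0.3 * b[t - 2] + e[t]
    Y <- cbind(behavior = b[-1], anger = b[-n] + 1e-6 * rnorm(n - 1))
  })
  g <- granger_matrix(Y[101:599, ], p = 1)
  expect_true(all(g$reject))
})

test_that("bivariate option gives the 2-variable sub-VAR test", {
  truth <- var_truth_preset("anxiety-driver")
  panel <- simulate_var_series(truth, T = 300, seed = 23)
  Y <- panel_mat <- as.matrix(panel[, c("behavior", "anger", "anxiety", "sadness")])
  full <- granger_test(Y, "anxiety", "behavior", 2)
  biv <- granger_test(Y, "anxiety", "behavior", 2, bivariate = TRUE)
  ref <- granger_oracle(Y[, c("behavior", "anxiety")], "anxiety", "behavior", 2)
  expect_equal(biv$F, ref$F, tolerance = 1e-8)
  expect_false(isTRUE(all.equal(full$F, biv$F)))
})
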