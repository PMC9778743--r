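fit_from_truth <- function(A_list, Sigma, T = 300, seed = 1) {
  Y <- sim_var_direct(A_list, Sigma, T = T, seed = seed)
  fit_var(Y, length(A_list))
}

test_that("Psi_0 is the identity and diagonal VAR(1) gives matrix powers", {
  fit <- fit_from_truth(list(matrix(c(0.5, 0.1, 0, 0.3), 2, 2)), diag(2))
  Psi <- ma_coefficients(fit, 6)
  expect_equal(unname(Psi[[1]]), diag(2))

  # exact diagonal case: overwrite the fitted matrices with the truth
  fit$A[[1]] <- diag(c(0.5, 0.2))
  Psi <- ma_coefficients(fit, 8)
  for (h in 0:8) {
    expect_equal(unname(Psi[[h + 1]]), diag(c(0.5^h, 0.2^h)),
                 tolerance = 1e-10)
  }
  expect_error(ma_coefficients(fit, -1), ">= 0")
})

test_that("Psi_h equals the zero-noise impulse simulation", {
  withr::with_seed(77, {
    for (i in 1:10) {
      K <- sample(2:4, 1)
      p <- sample(1:3, 1)
      A_list <- lapply(1:p, function(j) matrix(rnorm(K * K, sd = 0.3), K, K))
      # rescale jointly so the companion spectral radius is 0.8:
      # replacing A_j by s^j A_j scales every companion eigenvalue by s
      comp <- matrix(0, K * p, K * p)
      comp[1:K, ] <- do.call(cbind, A_list)
      if (p > 1) comp[(K + 1):(K * p), 1:(K * (p - 1))] <- diag(K * (p - 1))
      sr <- max(Mod(eigen(comp, only.values = TRUE)$values))
      A_list <- lapply(1:p, function(j) (0.8 / sr)^j * A_list[[j]])
      fit <- fit_from_truth(A_list, diag(K), T = 150, seed = 500 + i)
      H <- 12
      Psi <- ma_coefficients(fit, H)
      # propagate a unit impulse in variable k through the fitted dynamics
      for (k in 1:K) {
        path <- matrix(0, H + p + 1, K)
        path[p + 1, k] <- 1
        for (t in (p + 2):(H + p + 1)) {
          acc <- rep(0, K)
          for (j in 1:p) acc <- acc + fit$A[[j]] %*% path[t - j, ]
          path[t, ] <- acc
        }
        for (h in 0:H) {
          expect_equal(unname(Psi[[h + 1]][, k]), path[p + 1 + h, ],
                       tolerance = 1e-10)
        }
      }
    }
  })
})

test_that("identity Sigma makes Theta equal Psi; sigma^2 I scales by sigma", {
  fit <- fit_from_truth(list(0.4 * diag(3)), diag(3))
  fit$Sigma <- diag(3)
  irf <- orthogonalized_irf(fit, 5)
  Psi <- ma_coefficients(fit, 5)
  for (h in 0:5) expect_equal(irf$responses[h + 1, , ], Psi[[h + 1]])

  fit$Sigma <- 4 * diag(3)
  irf2 <- orthogonalized_irf(fit, 5)
  for (h in 0:5) {
    expect_equal(unname(irf2$responses[h + 1, , ]), 2 * unname(Psi[[h + 1]]))
  }
})

test_that("h = 0 responses equal the Cholesky factor (hand example)", {
  fit <- fit_from_truth(list(0.3 * diag(2)), diag(2))
  fit$Sigma <- matrix(c(4, 0, 0, 9), 2, 2,
                      dimnames = dimnames(fit$Sigma))
  irf <- orthogonalized_irf(fit, 3)
  expect_equal(unname(irf$responses[1, , ]), matrix(c(2, 0, 0, 3), 2, 2))
  # with diagonal Sigma the ordering is irrelevant
  rev_irf <- orthogonalized_irf(fit, 3, ordering = rev(fit$var_names))
  expect_equal(rev_irf$responses, irf$responses)
})

test_that("unit-shock convention rescales own-impact to one", {
  fit <- fit_from_truth(list(0.3 * diag(2)), diag(2), seed = 12)
  irf <- orthogonalized_irf(fit, 2, unit_shock = TRUE)
  expect_equal(unname(diag(irf$responses[1, , ])), c(1, 1))
})

test_that("orderings must be permutations and Sigma positive definite", {
  fit <- fit_from_truth(list(0.3 * diag(2)), diag(2))
  expect_error(orthogonalized_irf(fit, 2, ordering = c("y1", "y1")),
               "permutation")
  fit$Sigma <- matrix(c(1, 1, 1, 1), 2, 2)
  expect_error(orthogonalized_irf(fit, 2), "positive definite")
})

test_that("responses of stable models decay towards zero", {
  withr::with_seed(88, {
    for (i in 1:20) {
      K <- sample(2:3, 1)
      A1 <- matrix(rnorm(K * K), K, K)
      A1 <- A1 * (0.85 / max(Mod(eigen(A1, only.values = TRUE)$values)))
      fit <- fit_from_truth(list(A1), diag(K), T = 200, seed = 900 + i)
      fit$A[[1]] <- A1
      irf <- orthogonalized_irf(fit, 50)
      expect_lt(max(abs(irf$responses[51, , ])),
                max(abs(irf$responses[1, , ])))
    }
  })
})

test_that("bootstrap bands are seed-reproducible and ordered", {
  Y <- sim_var_direct(list(matrix(c(0.5, 0.2, 0.1, 0.4), 2, 2)), diag(2),
                      T = 150, seed = 14)
  b1 <- bootstrap_irf_bands(Y, p = 1, H = 6, B = 100, seed = 42)
  b2 <- bootstrap_irf_bands(Y, p = 1, H = 6, B = 100, seed = 42)
  expect_identical(b1$lower, b2$lower)
  expect_identical(b1$upper, b2$upper)
  expect_true(all(b1$lower <= b1$upper + 1e-12))
  b3 <- bootstrap_irf_bands(Y, p = 1, H = 6, B = 100, seed = 43)
  expect_false(identical(b1$lower, b3$lower))
  expect_error(bootstrap_irf_bands(Y, p = 1, H = 6, B = 50, seed = 1),
               ">= 100")
})

test_that("bootstrapping an unstable fit is refused", {
  # explosive AR(1) pair: the fitted root sits near 1.05
  e <- withr::with_seed(3, matrix(rnorm(200 * 2, sd = 0.1), 200, 2))
  Y <- matrix(0, 200, 2, dimnames = list(NULL, c("a", "b")))
  Y[1, ] <- c(1, -1)
  for (t in 2:200) Y[t, ] <- 1.05 * Y[t - 1, ] + e[t, ]
  expect_false(check_stability(fit_var(Y, 1))$is_stable)
  expect_error(bootstrap_irf_bands(Y, p = 1, H = 4, B = 100, seed = 1),
               "unstable")
})

test_that("bands shrink on average as T grows", {
  A1 <- matrix(c(0.5, 0.2, 0.1, 0.4), 2, 2)
  width <- sapply(c(100, 800), function(T_n) {
    w <- sapply(1:5, function(i) {
      Y <- sim_var_direct(list(A1), diag(2), T = T_n, seed = 200 + i)
      b <- bootstrap_irf_bands(Y, p = 1, H = 4, B = 150, seed = 300 + i)
      mean(b$upper - b$lower)
    })
    mean(w)
  })
  expect_lt(width[2], width[1])
})

test_that("tidy and autoplot expose the IRF grid", {
  Y <- sim_var_direct(list(0.4 * diag(2)), diag(2), T = 150, seed = 19)
  b <- bootstrap_irf_bands(Y, p = 1, H = 5, B = 100, seed = 5)
  td <- tidy(b)
  expect_equal(nrow(td), 6 * 2 * 2)
  expect_true(all(td$lower <= td$upper))
  expect_s3_class(autoplot(b), "ggplot")
})
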