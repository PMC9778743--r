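#' Fit a VAR(p) by equation-wise least squares
#'
#' Each variable is regressed on an intercept plus lags `1..p` of every
#' variable, using rows `p+1..T`. The residual covariance uses the
#' maximum-likelihood scaling (divide by the effective sample size
#' `T - p`), which keeps information criteria comparable across lag orders.
#'
#' @param panel An `emovar_panel`, a data frame of numeric series, or a
#'   numeric matrix (columns are variables).
#' @param p Lag order (>= 1).
#' @return An object of class `emovar_var` with elements `K`, `p`,
#'   `var_names`, `intercept` (length-`K` vector), `A` (list of `p` `K x K`
#'   lag coefficient matrices, row = equation), `Sigma`, `residuals`
#'   (`(T-p) x K`), `rss` (per equation), `T_effective`, `coef_matrix`
#'   (stacked `(1 + Kp) x K` regression coefficients) and `standardized`.
#' @examples
#' y <- simulate_var_series(var_truth_preset("null"), T = 200, seed = 1)
#' fit <- fit_var(y, p = 1)
#' glance(fit)
#' @export
fit_var <- function(panel, p) {
  p <- as.integer(p)
  stopifnot(p >= 1)
  Y <- panel_to_matrix(panel)
  K <- ncol(Y)
  T_total <- nrow(Y)
  if (T_total < K * p + p + 2) {
    abort(sprintf("need T >= %d rows to fit a VAR(%d) in %d variables, got %d",
                  K * p + p + 2, p, K, T_total))
  }
  Z <- stats::embed(Y, p + 1L)
  resp <- Z[, seq_len(K), drop = FALSE]
  X <- cbind(1, Z[, -seq_len(K), drop = FALSE])
  fit <- ols_fit(X, resp)
  T_eff <- nrow(resp)
  Sigma <- crossprod(fit$residuals) / T_eff
  dimnames(Sigma) <- list(colnames(Y), colnames(Y))

  A <- lapply(seq_len(p), function(j) {
    Aj <- t(fit$coef[1L + (j - 1L) * K + seq_len(K), , drop = FALSE])
    dimnames(Aj) <- list(colnames(Y), colnames(Y))
    Aj
  })
  structure(list(
    K = K, p = p, var_names = colnames(Y),
    intercept = setNames(fit$coef[1, ], colnames(Y)),
    A = A, Sigma = Sigma,
    residuals = fit$residuals,
    rss = setNames(colSums(fit$residuals^2), colnames(Y)),
    T_effective = T_eff,
    coef_matrix = fit$coef,
    standardized = isTRUE(attr(panel, "standardized"))
  ), class = "emovar_var")
}

# multi-response OLS with an explicit rank check
ols_fit <- function(X, Y) {
  qx <- qr(X)
  if (qx$rank < ncol(X)) abort("rank-deficient regressor matrix in VAR fit")
  coef <- qr.coef(qx, Y)
  list(coef = coef, residuals = Y - X %*% coef)
}

panel_to_matrix <- function(panel) {
  if (is.matrix(panel)) {
    Y <- panel
    if (is.null(colnames(Y))) colnames(Y) <- paste0("y", seq_len(ncol(Y)))
  } else if (is.data.frame(panel)) {
    Y <- panel_matrix(panel)
  } else {
    abort("panel must be a data frame or numeric matrix")
  }
  storage.mode(Y) <- "double"
  Y
}

#' @export
print.emovar_var <- function(x, ...) {
  cat(sprintf("<emovar_var> VAR(%d), K = %d (%s), T_effective = %d\n",
              x$p, x$K, paste(x$var_names, collapse = ", "), x$T_effective))
  invisible(x)
}

#' @rdname fit_var
#' @param x,object An `emovar_var`.
#' @param ... Unused.
#' @method tidy emovar_var
#' @export
tidy.emovar_var <- function(x, ...) {
  rows <- purrr::map_dfr(seq_len(x$p), function(j) {
    tibble::tibble(
      equation = rep(x$var_names, each = x$K),
      term = rep(x$var_names, times = x$K),
      lag = j,
      estimate = as.vector(t(x$A[[j]]))
    )
  })
  dplyr::bind_rows(
    tibble::tibble(equation = x$var_names, term = "intercept", lag = 0L,
                   estimate = unname(x$intercept)),
    rows
  )
}

#' @rdname fit_var
#' @method glance emovar_var
#' @export
glance.emovar_var <- function(x, ...) {
  n_par <- x$K^2 * x$p + x$K
  ld <- determinant(x$Sigma, logarithm = TRUE)$modulus[1]
  tibble::tibble(
    K = x$K, p = x$p, T_effective = x$T_effective,
    log_det_sigma = ld,
    aic = ld + 2 * n_par / x$T_effective,
    bic = ld + log(x$T_effective) * n_par / x$T_effective,
    stable = check_stability(x)$is_stable
  )
}

#' Select the VAR lag order by AIC and BIC
#'
#' Candidates `1..p_max` are all estimated on the common sample (rows
#' `p_max+1..T`), so criteria are comparable. With `T_c` the common effective
#' sample size and the ML covariance \eqn{\Sigma_p}:
#' \deqn{AIC(p) = \ln\det\Sigma_p + 2(K^2 p + K)/T_c}
#' \deqn{BIC(p) = \ln\det\Sigma_p + \ln(T_c)\,(K^2 p + K)/T_c}
#' The parameter count includes the intercepts. Ties break toward the
#' smaller order (parsimony).
#'
#' @param panel Panel data frame or matrix.
#' @param p_max Largest candidate order.
#' @return A list of class `emovar_lag_selection`: `criteria` (tibble with
#'   `p`, `aic`, `bic`), `aic_order`, `bic_order`, `T_common`.
#' @export
select_lag <- function(panel, p_max) {
  p_max <- as.integer(p_max)
  if (p_max < 1) abort("p_max must be >= 1")
  Y <- panel_to_matrix(panel)
  K <- ncol(Y)
  T_total <- nrow(Y)
  T_c <- T_total - p_max
  if (T_c < K * p_max + 2) {
    abort(sprintf("p_max = %d is infeasible with T = %d rows", p_max, T_total))
  }
  Z <- stats::embed(Y, p_max + 1L)
  resp <- Z[, seq_len(K), drop = FALSE]
  crit <- purrr::map_dfr(seq_len(p_max), function(p) {
    X <- cbind(1, Z[, K + seq_len(K * p), drop = FALSE])
    fit <- ols_fit(X, resp)
    Sigma <- crossprod(fit$residuals) / T_c
    ld <- determinant(Sigma, logarithm = TRUE)$modulus[1]
    n_par <- K^2 * p + K
    tibble::tibble(p = p, aic = ld + 2 * n_par / T_c,
                   bic = ld + log(T_c) * n_par / T_c)
  })
  structure(list(
    criteria = crit,
    aic_order = crit$p[which.min(crit$aic)],
    bic_order = crit$p[which.min(crit$bic)],
    T_common = T_c
  ), class = "emovar_lag_selection")
}

#' @export
print.emovar_lag_selection <- function(x, ...) {
  cat(sprintf("<emovar_lag_selection> AIC -> p = %d, BIC -> p = %d (T_common = %d)\n",
              x$aic_order, x$bic_order, x$T_common))
  print(x$criteria)
  invisible(x)
}

#' Companion matrix of a fitted VAR
#'
#' Stacks the lag coefficient matrices into the first-order (companion) form:
#' top block row `[A_1 ... A_p]`, identity blocks on the subdiagonal, zeros
#' elsewhere. The VAR is stable iff every eigenvalue of this matrix has
#' modulus below one.
#'
#' @param model An `emovar_var`.
#' @return A `(K*p) x (K*p)` matrix.
#' @export
companion_matrix <- function(model) {
  stopifnot(inherits(model, "emovar_var"))
  K <- model$K
  p <- model$p
  C <- matrix(0, K * p, K * p)
  C[seq_len(K), ] <- do.call(cbind, model$A)
  if (p > 1) {
    C[K + seq_len(K * (p - 1)), seq_len(K * (p - 1))] <-
      diag(K * (p - 1))
  }
  C
}

#' Stability diagnostics for a fitted VAR
#'
#' Reports the moduli of the companion-matrix eigenvalues (sorted
#' descending). The model is stable when all moduli are strictly below one —
#' equivalently, the reciprocals of the roots of the VAR characteristic
#' polynomial all lie inside the unit circle.
#'
#' @param model An `emovar_var`.
#' @return A list of class `emovar_stability`: `moduli`, `is_stable`,
#'   `max_modulus`, `tolerance`.
#' @export
check_stability <- function(model) {
  moduli <- sort(Mod(eigen(companion_matrix(model), only.values = TRUE)$values),
                 decreasing = TRUE)
  structure(list(
    moduli = moduli,
    max_modulus = moduli[1],
    is_stable = moduli[1] < 1,
    tolerance = 0
  ), class = "emovar_stability")
}

#' @export
print.emovar_stability <- function(x, ...) {
  cat(sprintf("<emovar_stability> max eigenvalue modulus %.6f -> %s\n",
              x$max_modulus, if (x$is_stable) "stable" else "UNSTABLE"))
  invisible(x)
}

#' Granger causality block F test
#'
#' Tests whether `cause` Granger-causes `effect` by comparing the effect's
#' equation in the full `K`-variable VAR(p) (unrestricted) with the same
#' regression after removing all `p` lags of the cause (restricted):
#' \deqn{F = \frac{(RSS_r - RSS_u)/p}{RSS_u / (T_{eff} - (Kp + 1))}}
#' with an upper-tail `F(p, T_eff - (Kp+1))` p-value. By default the test is
#' run inside the full system (block exclusion); `bivariate = TRUE` restricts
#' the system to the cause/effect pair.
#'
#' @param panel Panel data frame or matrix.
#' @param cause,effect Column names (must differ).
#' @param p Lag order.
#' @param alpha Significance level for the reject flag.
#' @param bivariate If `TRUE`, test in the 2-variable sub-VAR instead of the
#'   full system.
#' @return One-row tibble: `cause`, `effect`, `lag`, `F`, `df_num`, `df_den`,
#'   `p_value`, `reject`.
#' @export
granger_test <- function(panel, cause, effect, p, alpha = 0.05,
                         bivariate = FALSE) {
  if (identical(cause, effect)) abort("cause and effect must differ")
  Y <- panel_to_matrix(panel)
  if (!all(c(cause, effect) %in% colnames(Y))) {
    abort("cause and effect must be panel columns")
  }
  if (bivariate) Y <- Y[, c(effect, cause), drop = FALSE]
  p <- as.integer(p)
  K <- ncol(Y)
  Z <- stats::embed(Y, p + 1L)
  y <- Z[, match(effect, colnames(Y)), drop = FALSE]
  X_u <- cbind(1, Z[, -seq_len(K), drop = FALSE])
  # columns of the cause's lags inside the unrestricted design
  cause_cols <- 1L + (seq_len(p) - 1L) * K + match(cause, colnames(Y))
  X_r <- X_u[, -cause_cols, drop = FALSE]

  rss_u <- sum(ols_fit(X_u, y)$residuals^2)
  rss_r <- sum(ols_fit(X_r, y)$residuals^2)
  T_eff <- nrow(Z)
  df_den <- T_eff - (K * p + 1L)
  if (df_den < 1) abort("not enough observations for the Granger F test")
  F_stat <- max(0, ((rss_r - rss_u) / p) / (rss_u / df_den))
  p_value <- pf(F_stat, p, df_den, lower.tail = FALSE)
  tibble::tibble(
    cause = cause, effect = effect, lag = p,
    F = F_stat, df_num = p, df_den = df_den,
    p_value = p_value, reject = p_value < alpha
  )
}

#' All directed Granger tests between emotions and behavior
#'
#' Runs [granger_test()] for every ordered (emotion, behavior) pair in both
#' directions: first each emotion as a candidate cause of behavior, then
#' behavior as a candidate cause of each emotion.
#'
#' @inheritParams granger_test
#' @param behavior_col Name of the behavior column.
#' @return Tibble with one row per directed hypothesis (`2 x` number of
#'   emotions), columns as in [granger_test()].
#' @export
granger_matrix <- function(panel, p, alpha = 0.05, behavior_col = "behavior",
                           bivariate = FALSE) {
  vars <- colnames(panel_to_matrix(panel))
  if (!behavior_col %in% vars) {
    abort(sprintf("panel has no '%s' column", behavior_col))
  }
  emotions <- setdiff(vars, behavior_col)
  if (!length(emotions)) abort("panel needs at least one emotion column")
  dplyr::bind_rows(
    purrr::map_dfr(emotions, ~ granger_test(panel, .x, behavior_col, p,
                                            alpha, bivariate)),
    purrr::map_dfr(emotions, ~ granger_test(panel, behavior_col, .x, p,
                                            alpha, bivariate))
  )
}
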