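#' Moving-average coefficients of a fitted VAR
#'
#' The MA(\eqn{\infty}) representation truncated at horizon `H`:
#' \eqn{\Psi_0 = I} and \eqn{\Psi_h = \sum_{j=1}^{\min(h,p)} A_j \Psi_{h-j}}.
#' Column `k` of \eqn{\Psi_h} is the horizon-`h` response of every variable
#' to a one-unit impulse in variable `k`'s reduced-form innovation.
#'
#' @param model An `emovar_var`.
#' @param H Horizon (>= 0).
#' @return List of `H + 1` `K x K` matrices `Psi_0 .. Psi_H`.
#' @export
ma_coefficients <- function(model, H) {
  stopifnot(inherits(model, "emovar_var"))
  H <- as.integer(H)
  if (H < 0) abort("H must be >= 0")
  K <- model$K
  Psi <- vector("list", H + 1L)
  Psi[[1]] <- diag(K)
  dimnames(Psi[[1]]) <- list(model$var_names, model$var_names)
  for (h in seq_len(H)) {
    M <- matrix(0, K, K)
    for (j in seq_len(min(h, model$p))) {
      M <- M + model$A[[j]] %*% Psi[[h - j + 1L]]
    }
    dimnames(M) <- list(model$var_names, model$var_names)
    Psi[[h + 1L]] <- M
  }
  Psi
}

# lower-triangular Cholesky impact matrix under a variable ordering,
# expressed in the model's original variable indexing
cholesky_impact <- function(Sigma, var_names, ordering, unit_shock = FALSE) {
  if (!setequal(ordering, var_names) || length(ordering) != length(var_names)) {
    abort("ordering must be a permutation of the model's variables")
  }
  perm <- match(ordering, var_names)
  P_perm <- tryCatch(t(chol(Sigma[perm, perm, drop = FALSE])),
                     error = function(e) {
                       abort("residual covariance is not positive definite")
                     })
  Q <- matrix(0, length(perm), length(perm),
              dimnames = list(var_names, var_names))
  Q[perm, perm] <- P_perm
  if (unit_shock) Q <- Q %*% diag(1 / diag(Q), nrow = nrow(Q))
  Q
}

irf_point_array <- function(model, H, ordering, unit_shock = FALSE) {
  Psi <- ma_coefficients(model, H)
  Q <- cholesky_impact(model$Sigma, model$var_names, ordering, unit_shock)
  K <- model$K
  theta <- array(NA_real_, c(H + 1L, K, K),
                 dimnames = list(NULL, model$var_names, model$var_names))
  for (h in 0:H) theta[h + 1L, , ] <- Psi[[h + 1L]] %*% Q
  theta
}

new_irf <- function(theta, ordering, shock, lower = NULL, upper = NULL,
                    band_method = NULL, level = NULL, B = NULL, seed = NULL) {
  structure(list(
    H = dim(theta)[1] - 1L,
    responses = theta,
    lower = lower, upper = upper,
    shock = shock, ordering = ordering,
    band_method = band_method, level = level, B = B, seed = seed
  ), class = "emovar_irf")
}

#' Orthogonalized impulse-response functions
#'
#' Responses to mutually uncorrelated shocks obtained from the lower
#' triangular Cholesky factor `P` of the residual covariance (taken under the
#' given variable ordering): \eqn{\Theta_h = \Psi_h P}. Column `k` of
#' \eqn{\Theta_h} is the horizon-`h` response to a one-standard-deviation
#' orthogonal shock in variable `k`; at `h = 0` the response equals `P`
#' itself. With `unit_shock = TRUE` the columns of `P` are rescaled so the
#' shocked variable's own impact is one unit instead of one SD.
#'
#' @param model An `emovar_var`.
#' @param H Horizon.
#' @param ordering Variable ordering used for the Cholesky factorization
#'   (default: the model's column order). Results are reported in the
#'   original variable order regardless.
#' @param unit_shock Rescale shocks to unit own-impact.
#' @return An `emovar_irf`: `responses` is an `(H+1) x K x K` array indexed
#'   (horizon, response variable, shock variable); `lower`/`upper` are `NULL`
#'   (see [bootstrap_irf_bands()] for bands).
#' @export
orthogonalized_irf <- function(model, H, ordering = model$var_names,
                               unit_shock = FALSE) {
  theta <- irf_point_array(model, H, ordering, unit_shock)
  new_irf(theta, ordering = ordering,
          shock = if (unit_shock) "unit-shock" else "orthogonalized-one-SD")
}

#' Orthogonalized IRFs with residual-bootstrap confidence bands
#'
#' Recursive-design residual bootstrap: the fitted residuals are centered and
#' resampled with replacement; artificial series are regenerated from the
#' first `p` observed rows using the fitted intercept and lag matrices; the
#' VAR is refit on each artificial series and its orthogonalized IRF
#' recomputed. Pointwise percentile bands are taken at `alpha/2` and
#' `1 - alpha/2`. Fully deterministic given `seed`.
#'
#' @param panel Panel data frame or matrix.
#' @param p Lag order.
#' @param H Horizon.
#' @param ordering Cholesky ordering (default: panel column order).
#' @param B Bootstrap replicates (>= 100).
#' @param alpha Band level (0.05 gives 95% bands).
#' @param seed Integer seed (required).
#' @param unit_shock Passed to the IRF convention.
#' @return An `emovar_irf` with `lower` and `upper` band arrays.
#' @export
bootstrap_irf_bands <- function(panel, p, H, ordering = NULL, B = 1000,
                                alpha = 0.05, seed, unit_shock = FALSE) {
  if (B < 100) abort("B must be >= 100 bootstrap replicates")
  if (missing(seed)) abort("bootstrap bands require an explicit seed")
  Y <- panel_to_matrix(panel)
  model <- fit_var(Y, p)
  ordering <- ordering %||% model$var_names
  stab <- check_stability(model)
  if (!stab$is_stable) {
    abort(sprintf("point estimate is unstable (max eigenvalue modulus %.4f); refusing to bootstrap",
                  stab$max_modulus))
  }
  theta_hat <- irf_point_array(model, H, ordering, unit_shock)
  K <- model$K
  T_total <- nrow(Y)
  T_eff <- model$T_effective
  E <- sweep(model$residuals, 2, colMeans(model$residuals))

  draws <- array(NA_real_, c(H + 1L, K, K, B))
  withr::with_seed(seed, {
    idx <- matrix(sample.int(T_eff, T_eff * B, replace = TRUE), T_eff, B)
    # regenerate all B artificial series jointly, one time step at a time
    Yb <- array(0, c(T_total, K, B))
    Yb[seq_len(p), , ] <- Y[seq_len(p), , drop = FALSE]
    cvec <- model$intercept
    for (t in (p + 1L):T_total) {
      acc <- matrix(cvec, K, B)
      for (j in seq_len(p)) {
        acc <- acc + model$A[[j]] %*% matrix(Yb[t - j, , ], K, B)
      }
      draws_t <- t(E[idx[t - p, ], , drop = FALSE])
      Yb[t, , ] <- acc + draws_t
    }
    for (b in seq_len(B)) {
      Yb_mat <- matrix(Yb[, , b], T_total, K,
                       dimnames = list(NULL, model$var_names))
      draws[, , , b] <- tryCatch({
        mb <- fit_var(Yb_mat, p)
        irf_point_array(mb, H, ordering, unit_shock)
      }, error = function(e) NA_real_)
    }
  })
  ok <- !apply(is.na(draws[1, 1, 1, , drop = FALSE]), 4, any)
  if (sum(ok) < B) {
    warn(sprintf("%d of %d bootstrap refits failed and were dropped",
                 B - sum(ok), B))
  }
  qs <- apply(draws[, , , ok, drop = FALSE], c(1, 2, 3), stats::quantile,
              probs = c(alpha / 2, 1 - alpha / 2), names = FALSE)
  lower <- qs[1, , , ]
  upper <- qs[2, , , ]
  dim(lower) <- dim(upper) <- dim(theta_hat)
  dimnames(lower) <- dimnames(upper) <- dimnames(theta_hat)
  new_irf(theta_hat, ordering = ordering,
          shock = if (unit_shock) "unit-shock" else "orthogonalized-one-SD",
          lower = lower, upper = upper,
          band_method = "recursive-design residual bootstrap, percentile",
          level = 1 - alpha, B = as.integer(sum(ok)), seed = seed)
}

#' @export
print.emovar_irf <- function(x, ...) {
  cat(sprintf("<emovar_irf> %s, H = %d, ordering: %s%s\n",
              x$shock, x$H, paste(x$ordering, collapse = " > "),
              if (is.null(x$lower)) "" else
                sprintf("; %g%% %s bands (B = %d, seed = %s)",
                        100 * x$level, x$band_method, x$B, format(x$seed))))
  invisible(x)
}

#' @rdname orthogonalized_irf
#' @param x,object An `emovar_irf`.
#' @param ... Unused.
#' @method tidy emovar_irf
#' @export
tidy.emovar_irf <- function(x, ...) {
  dn <- dimnames(x$responses)
  out <- tidyr::expand_grid(
    shock = dn[[3]], response = dn[[2]], h = 0:x$H
  ) |>
    dplyr::arrange(.data$shock, .data$response, .data$h)
  out$estimate <- purrr::pmap_dbl(out, function(shock, response, h) {
    x$responses[h + 1L, response, shock]
  })
  if (!is.null(x$lower)) {
    out$lower <- purrr::pmap_dbl(out[1:3], function(shock, response, h) {
      x$lower[h + 1L, response, shock]
    })
    out$upper <- purrr::pmap_dbl(out[1:3], function(shock, response, h) {
      x$upper[h + 1L, response, shock]
    })
  }
  out
}

#' Plot an impulse-response grid
#'
#' One facet per (response, shock) pair: solid line for the point IRF and a
#' shaded ribbon for the confidence band when present, with a dashed zero
#' line.
#'
#' @param object An `emovar_irf`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot emovar_irf
#' @export
autoplot.emovar_irf <- function(object, ...) {
  df <- tidy(object)
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$h, y = .data$estimate))
  if (!is.null(object$lower)) {
    gg <- gg + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
      fill = "grey70", alpha = 0.6)
  }
  gg +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_line() +
    ggplot2::facet_grid(response ~ shock,
                        labeller = ggplot2::label_both, scales = "free_y") +
    ggplot2::labs(
      x = "horizon (weeks)",
      y = if (object$shock == "unit-shock") "response to a unit shock"
          else "response to a one-SD orthogonal shock",
      title = if (is.null(object$level)) "Orthogonalized impulse responses"
              else sprintf("Orthogonalized impulse responses with %g%% bands",
                           100 * object$level)
    ) +
    ggplot2::theme_minimal()
}
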