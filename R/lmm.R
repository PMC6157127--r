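#' Eigen-decomposition of the additive relationship matrix
#'
#' The null mixed model is fitted after rotating the data by the eigenvectors
#' of `A = 2 * phi`, which diagonalises the polygenic covariance. The
#' decomposition depends only on the pedigree, so it is computed once and
#' reused across outcomes and per-gene refits.
#'
#' @param K A `kinship_matrix` (from [kinship()]) or a symmetric positive
#'   semidefinite relationship matrix `A` with dimnames.
#' @return A list of class `kinship_eigen` with `ids`, `U` (eigenvectors,
#'   columns) and `lambda` (eigenvalues, decreasing, clipped at 0).
#' @export
kinship_eigen <- function(K) {
  if (inherits(K, "kinship_eigen")) return(K)
  A <- if (inherits(K, "kinship_matrix")) K$A else as.matrix(K)
  if (is.null(rownames(A))) {
    stop_methregion("Relationship matrix needs dimnames (sample ids).",
                    "methregion_kinship_error")
  }
  eig <- eigen(A, symmetric = TRUE)
  if (min(eig$values) < -1e-8 * max(abs(eig$values))) {
    stop_methregion("Relationship matrix is not positive semidefinite.",
                    "methregion_kinship_error")
  }
  structure(list(ids = rownames(A), U = eig$vectors,
                 lambda = pmax(eig$values, 0)),
            class = "kinship_eigen")
}

# Profile REML criterion at variance ratio delta = sigma_e^2 / sigma_g^2,
# on rotated data. Returns the restricted log-likelihood up to an additive
# constant, along with the pieces needed to finish the fit.
reml_profile <- function(delta, ytil, Xtil, lambda) {
  n <- length(ytil); p <- ncol(Xtil)
  w <- 1 / (lambda + delta)
  Xw <- Xtil * w
  XtWX <- crossprod(Xw, Xtil)
  XtWy <- crossprod(Xw, ytil)
  ch <- tryCatch(chol(XtWX), error = function(e) NULL)
  if (is.null(ch)) return(list(ll = -Inf))
  beta <- backsolve(ch, forwardsolve(t(ch), XtWy))
  r <- ytil - Xtil %*% beta
  rssw <- sum(w * r^2)
  sigma_g2 <- rssw / (n - p)
  ll <- -0.5 * ((n - p) * log(sigma_g2) + sum(log(lambda + delta)) +
                  2 * sum(log(diag(ch))) + (n - p))
  list(ll = ll, beta = drop(beta), sigma_g2 = sigma_g2, chol = ch, w = w)
}

# Ordinary least squares limit (sigma_g^2 = 0) of the same criterion; the
# delta-dependent terms cancel as delta -> Inf, leaving this value.
reml_ols <- function(ytil, Xtil) {
  n <- length(ytil); p <- ncol(Xtil)
  ch <- chol(crossprod(Xtil))
  beta <- backsolve(ch, forwardsolve(t(ch), crossprod(Xtil, ytil)))
  rss <- sum((ytil - Xtil %*% beta)^2)
  sigma_e2 <- rss / (n - p)
  ll <- -0.5 * ((n - p) * log(sigma_e2) + 2 * sum(log(diag(ch))) + (n - p))
  list(ll = ll, beta = drop(beta), sigma_e2 = sigma_e2, chol = ch)
}

# Core REML fit on rotated data. Grid search over log10(delta) in
# [-5, 5] followed by golden-section refinement, with the sigma_g^2 = 0
# boundary checked explicitly against the interior optimum.
reml_fit_rotated <- function(ytil, Xtil, lambda, n_grid = 100L,
                             delta_range = c(1e-5, 1e5), tol = 1e-8) {
  n <- length(ytil); p <- ncol(Xtil)
  grid <- exp(seq(log(delta_range[1]), log(delta_range[2]), length.out = n_grid))
  ll_grid <- vapply(grid, function(d) reml_profile(d, ytil, Xtil, lambda)$ll,
                    numeric(1))
  if (all(!is.finite(ll_grid))) {
    return(list(converged = FALSE))
  }
  i_best <- which.max(ll_grid)
  lo <- grid[max(1L, i_best - 1L)]
  hi <- grid[min(n_grid, i_best + 1L)]
  opt <- optimize(function(ld) reml_profile(exp(ld), ytil, Xtil, lambda)$ll,
                  lower = log(lo), upper = log(hi), maximum = TRUE,
                  tol = tol)
  delta <- exp(opt$maximum)
  at_opt <- reml_profile(delta, ytil, Xtil, lambda)
  ols <- reml_ols(ytil, Xtil)
  boundary <- ols$ll >= at_opt$ll - 1e-8 || i_best == n_grid
  if (boundary) {
    list(converged = TRUE, boundary = TRUE,
         sigma_g2 = 0, sigma_e2 = ols$sigma_e2, delta = Inf,
         beta = ols$beta, chol_xtwx = ols$chol / sqrt(ols$sigma_e2),
         v = rep(ols$sigma_e2, n), ll = ols$ll, ll_ols = ols$ll)
  } else {
    sigma_g2 <- at_opt$sigma_g2
    # chol above is of X'diag(1/(lambda+delta))X; rescale to X'V^-1 X.
    v <- sigma_g2 * (lambda + delta)
    list(converged = TRUE, boundary = FALSE,
         sigma_g2 = sigma_g2, sigma_e2 = sigma_g2 * delta, delta = delta,
         beta = at_opt$beta, chol_xtwx = at_opt$chol / sqrt(sigma_g2),
         v = v, ll = at_opt$ll, ll_ols = ols$ll)
  }
}

#' Fit the null kinship linear mixed model by REML
#'
#' Fits `y = X alpha + g + e` with `g ~ N(0, sigma_g^2 A)`, `A = 2 phi` from
#' the pedigree, and `e ~ N(0, sigma_e^2 I)`. Estimation rotates the data by
#' the eigenvectors of `A` and maximises the one-parameter profile restricted
#' likelihood in the variance ratio `delta = sigma_e^2 / sigma_g^2` (log-grid
#' bracketing plus golden-section refinement); the boundary solution
#' `sigma_g^2 = 0` is checked explicitly. Fixed effects are the GLS estimates
#' at the optimum.
#'
#' @param y Outcome vector (named by sample id, or aligned to `X` rows).
#' @param X Design matrix with intercept (see [covariate_design()]).
#' @param K `kinship_matrix`, relationship matrix, or a precomputed
#'   [kinship_eigen()] (reused across fits).
#' @return An object of class `kin_lmm`: fixed-effect estimates and
#'   covariance, variance components, REML log-likelihood, convergence flag,
#'   and the rotated quantities needed by [score_stats()] and [wald_test()].
#' @export
fit_null <- function(y, X, K) {
  eig <- kinship_eigen(K)
  ids <- rownames(X) %||% eig$ids
  if (!is.null(rownames(X)) && !identical(rownames(X), eig$ids)) {
    eig <- kinship_eigen(kinship_subset_matrix(K, rownames(X)))
  }
  if (length(y) != nrow(X)) {
    stop_methregion("`y` and `X` have different lengths.", "methregion_bad_argument")
  }
  if (!is.null(names(y)) && !is.null(rownames(X))) {
    if (!setequal(names(y), rownames(X))) {
      stop_methregion("`y` names do not match `X` rownames.", "methregion_bad_argument")
    }
    y <- y[rownames(X)]
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    stop_methregion("Design matrix is rank deficient.", "methregion_bad_argument")
  }
  ytil <- drop(crossprod(eig$U, y))
  Xtil <- crossprod(eig$U, X)
  fit <- reml_fit_rotated(ytil, Xtil, eig$lambda)
  if (!isTRUE(fit$converged)) {
    stop_methregion("REML fit did not converge.", "methregion_fit_error")
  }
  beta <- setNames(fit$beta, colnames(X))
  cov_beta <- chol2inv(fit$chol_xtwx)
  dimnames(cov_beta) <- list(colnames(X), colnames(X))
  rtil <- ytil - drop(Xtil %*% fit$beta)
  # restricted LRT of sigma_g^2 > 0 against the boundary null; the reference
  # distribution is the 50:50 mixture of a point mass at 0 and chi-square(1)
  lrt <- max(0, 2 * (fit$ll - fit$ll_ols))
  polygenic_p <- if (lrt == 0) 1 else 0.5 * pchisq(lrt, df = 1, lower.tail = FALSE)
  structure(list(
    ids = ids, n = length(y), p = ncol(X),
    beta = beta, cov_beta = cov_beta,
    sigma_g2 = fit$sigma_g2, sigma_e2 = fit$sigma_e2, delta = fit$delta,
    boundary = fit$boundary, converged = fit$converged,
    loglik_reml = fit$ll, polygenic_lrt_p = polygenic_p,
    eigen = eig, ytil = ytil, Xtil = Xtil, rtil = rtil,
    v = fit$v,
    y = y, X = X
  ), class = "kin_lmm")
}

# Subset helper that accepts the same K forms as kinship_eigen.
kinship_subset_matrix <- function(K, ids) {
  if (inherits(K, "kinship_matrix")) return(kinship_subset(K, ids)$A)
  if (inherits(K, "kinship_eigen")) {
    A <- K$U %*% (K$lambda * t(K$U))
    dimnames(A) <- list(K$ids, K$ids)
    return(A[ids, ids, drop = FALSE])
  }
  as.matrix(K)[ids, ids, drop = FALSE]
}

#' @export
print.kin_lmm <- function(x, ...) {
  cat(sprintf("<kin_lmm> n = %d, p = %d fixed effects\n", x$n, x$p))
  cat(sprintf("  sigma_g^2 = %.4g, sigma_e^2 = %.4g%s\n",
              x$sigma_g2, x$sigma_e2,
              if (x$boundary) " (polygenic boundary)" else ""))
  cat(sprintf("  REML loglik (up to const) = %.4f\n", x$loglik_reml))
  invisible(x)
}

#' @export
#' @importFrom generics tidy
generics::tidy

#' @export
#' @importFrom generics glance
generics::glance

#' Tidy fixed-effect estimates of a kinship mixed model
#' @param x A `kin_lmm` fit.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value` (Wald, standard normal reference).
#' @method tidy kin_lmm
#' @export
tidy.kin_lmm <- function(x, ...) {
  se <- sqrt(diag(x$cov_beta))
  z <- x$beta / se
  tibble(term = names(x$beta), estimate = unname(x$beta),
         std.error = unname(se), statistic = unname(z),
         p.value = 2 * pnorm(-abs(unname(z))))
}

#' One-row model summary of a kinship mixed model
#' @param x A `kin_lmm` fit.
#' @param ... Unused.
#' @return A tibble with `nobs`, `sigma_g2`, `sigma_e2`, `heritability`
#'   (`sigma_g2 / (sigma_g2 + sigma_e2)`), `logLik`, `polygenic_p` (boundary
#'   LRT of `sigma_g2 > 0`), `boundary`, `converged`.
#' @method glance kin_lmm
#' @export
glance.kin_lmm <- function(x, ...) {
  tibble(nobs = x$n, sigma_g2 = x$sigma_g2, sigma_e2 = x$sigma_e2,
         heritability = x$sigma_g2 / (x$sigma_g2 + x$sigma_e2),
         logLik = x$loglik_reml, polygenic_p = x$polygenic_lrt_p,
         boundary = x$boundary, converged = x$converged)
}

#' Wald test of one extra covariate under the kinship mixed model
#'
#' Appends column `z` to the null design, refits by REML, and reports the
#' estimate, standard error and two-sided p-value (standard normal
#' reference) for the appended term — the statistic the median methylation
#' level test reports per gene.
#'
#' @param fit A `kin_lmm` null fit.
#' @param z Covariate vector aligned to the fit's samples.
#' @return A tibble with `effect`, `se`, `p` (all `NA`, with a warning
#'   reason, when `z` is constant or collinear with the design).
#' @export
wald_test <- function(fit, z) {
  stopifnot(inherits(fit, "kin_lmm"))
  if (length(z) != fit$n) {
    stop_methregion("`z` length does not match the fit.", "methregion_bad_argument")
  }
  na_row <- tibble(effect = NA_real_, se = NA_real_, p = NA_real_)
  if (any(is.na(z)) || sd(z) == 0) return(na_row)
  ztil <- drop(crossprod(fit$eigen$U, z))
  Xz <- cbind(fit$Xtil, ztil)
  if (qr(Xz)$rank < ncol(Xz)) return(na_row)
  f <- reml_fit_rotated(fit$ytil, Xz, fit$eigen$lambda)
  if (!isTRUE(f$converged)) return(na_row)
  k <- ncol(Xz)
  cov_beta <- chol2inv(f$chol_xtwx)
  effect <- f$beta[k]
  se <- sqrt(cov_beta[k, k])
  tibble(effect = effect, se = se, p = 2 * pnorm(-abs(effect / se)))
}

#' Per-CpG score statistics under the null fit
#'
#' For a samples-by-CpGs matrix `Z` of methylation changes, computes the
#' marginal score statistics `S = Z' P y` and their null covariance
#' `Sigma_S = Z' P Z`, where `P` is the REML projection
#' `V^-1 - V^-1 X (X' V^-1 X)^-1 X' V^-1` of the null fit. Missing entries
#' are mean-imputed per CpG (with a message) before the computation.
#'
#' @param fit A `kin_lmm` null fit.
#' @param Z Samples-by-CpGs numeric matrix, rows aligned to the fit (by
#'   rowname when present).
#' @return A list of class `score_stats` with `S` (vector), `Sigma_S`
#'   (matrix) and `cpg_ids`.
#' @export
score_stats <- function(fit, Z) {
  stopifnot(inherits(fit, "kin_lmm"))
  Z <- as.matrix(Z)
  if (!is.null(rownames(Z)) && !is.null(rownames(fit$X))) {
    if (!setequal(rownames(Z), rownames(fit$X))) {
      stop_methregion("`Z` rows do not match the fitted samples.",
                      "methregion_bad_argument")
    }
    Z <- Z[rownames(fit$X), , drop = FALSE]
  } else if (nrow(Z) != fit$n) {
    stop_methregion("`Z` rows do not match the fitted samples.",
                    "methregion_bad_argument")
  }
  n_na <- sum(is.na(Z))
  if (n_na > 0L) {
    inform(sprintf("score_stats: mean-imputing %d missing value(s).", n_na))
    for (j in seq_len(ncol(Z))) {
      miss <- is.na(Z[, j])
      if (any(miss)) Z[miss, j] <- mean(Z[, j], na.rm = TRUE)
    }
    Z[is.na(Z)] <- 0  # all-NA column
  }
  w <- 1 / fit$v
  Ztil <- crossprod(fit$eigen$U, Z)
  # S = Z' V^-1 r  (P y = V^-1 (y - X beta_GLS))
  S <- drop(crossprod(Ztil, w * fit$rtil))
  ZtWX <- crossprod(Ztil * w, fit$Xtil)
  XtWX_inv <- chol2inv(chol(crossprod(fit$Xtil * w, fit$Xtil)))
  Sigma_S <- crossprod(Ztil * sqrt(w)) - ZtWX %*% XtWX_inv %*% t(ZtWX)
  Sigma_S <- (Sigma_S + t(Sigma_S)) / 2
  structure(list(S = S, Sigma_S = Sigma_S,
                 cpg_ids = colnames(Z) %||% as.character(seq_len(ncol(Z)))),
            class = "score_stats")
}
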