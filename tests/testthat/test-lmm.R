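# Shared family fixture for mixed-model tests.
family_fixture <- function(n_families = 50L, seed = 40L,
                           structure = "nuclear4") {
  cfg <- scenario_config(n_families = n_families, family_structure = structure,
                         seed = seed)
  peds <- simulate_pedigrees(cfg)
  ids <- peds$pedigree$individual_id
  withr::with_seed(seed + 1L, {
    X <- cbind(intercept = 1, age = rnorm(length(ids), 47, 16),
               sex = rbinom(length(ids), 1, 0.5))
  })
  rownames(X) <- ids
  list(ped = peds$pedigree, kin = peds$kinship, X = X, ids = ids,
       eig = kinship_eigen(peds$kinship))
}

# Draw y = X alpha + g + e with known variance components.
draw_outcome <- function(fx, alpha = c(1, 0.01, -0.2), sg2 = 1, se2 = 1) {
  n <- nrow(fx$X)
  g <- drop(fx$eig$U %*% (sqrt(fx$eig$lambda * sg2) * rnorm(n)))
  y <- drop(fx$X %*% alpha) + g + rnorm(n, 0, sqrt(se2))
  setNames(y, fx$ids)
}

test_that("identity kinship reduces REML to ordinary least squares", {
  withr::with_seed(41, {
    n <- 150
    A <- identity_kinship(n)
    X <- cbind(intercept = 1, x1 = rnorm(n), x2 = rbinom(n, 1, 0.4))
    rownames(X) <- rownames(A)
    y <- setNames(drop(X %*% c(2, 0.5, -1)) + rnorm(n), rownames(A))
  })
  fit <- fit_null(y, X, A)
  ols <- lm(y ~ 0 + X)
  expect_lt(max(abs(fit$beta - coef(ols))), 1e-8)
  s2_ols <- sum(resid(ols)^2) / (n - ncol(X))
  expect_equal(fit$sigma_g2 + fit$sigma_e2, s2_ols, tolerance = 1e-8)
})

test_that("the boundary check finds no polygenic component under iid noise", {
  fx <- family_fixture(n_families = 75L)  # n = 300
  withr::with_seed(42, {
    fits <- replicate(200, {
      y <- setNames(drop(fx$X %*% c(1, 0.01, -0.2)) + rnorm(nrow(fx$X)),
                    fx$ids)
      f <- fit_null(y, fx$X, fx$eig)
      c(at_zero = f$sigma_g2 == 0, accept = f$polygenic_lrt_p > 0.05)
    })
  })
  # the REML estimate sits exactly on the boundary about half the time ...
  expect_gt(mean(fits["at_zero", ]), 0.3)
  # ... and the boundary LRT accepts sigma_g^2 = 0 at its nominal 95% rate
  # (3 binomial SE band around 0.95 over 200 replicates)
  expect_gt(mean(fits["accept", ]), 0.95 - 3 * sqrt(0.95 * 0.05 / 200))
})

test_that("the REML projection annihilates the fixed effects", {
  fx <- family_fixture(n_families = 30L)
  withr::with_seed(43, y <- draw_outcome(fx))
  fit <- fit_null(y, fx$X, fx$eig)
  ss <- score_stats(fit, fx$X)  # Z = X must give zero scores: X'Py = 0
  expect_lt(max(abs(ss$S)), 1e-8)
  expect_lt(max(abs(ss$Sigma_S)), 1e-8)
})

test_that("projection quantities are invariant under consistent reordering", {
  fx <- family_fixture(n_families = 20L)
  withr::with_seed(44, {
    y <- draw_outcome(fx)
    Z <- matrix(rnorm(nrow(fx$X) * 3), nrow(fx$X), 3,
                dimnames = list(fx$ids, paste0("z", 1:3)))
    perm <- sample(fx$ids)
  })
  fit1 <- fit_null(y, fx$X, fx$eig)
  s1 <- score_stats(fit1, Z)
  fit2 <- fit_null(y[perm], fx$X[perm, ], fx$eig)
  s2 <- score_stats(fit2, Z[perm, ])
  expect_equal(s1$S, s2$S, tolerance = 1e-6)
  expect_equal(s1$Sigma_S, s2$Sigma_S, tolerance = 1e-6)
})

test_that("REML optimum is stable to the starting bracket", {
  fx <- family_fixture(n_families = 25L)
  withr::with_seed(45, y <- draw_outcome(fx, sg2 = 0.8, se2 = 1.2))
  ytil <- drop(crossprod(fx$eig$U, y))
  Xtil <- crossprod(fx$eig$U, fx$X)
  f1 <- methregion:::reml_fit_rotated(ytil, Xtil, fx$eig$lambda)
  f2 <- methregion:::reml_fit_rotated(ytil, Xtil, fx$eig$lambda,
                                      n_grid = 57L, delta_range = c(1e-4, 1e4))
  expect_equal(f1$delta, f2$delta, tolerance = 1e-5)
})

test_that("wald_test is calibrated, powered, and NA on degenerate covariates", {
  fx <- family_fixture(n_families = 40L)
  withr::with_seed(46, {
    y <- draw_outcome(fx)
    fit <- fit_null(y, fx$X, fx$eig)
    # independent covariates: p uniform
    p_null <- replicate(300, wald_test(fit, rnorm(fit$n))$p)
    expect_gt(stats::ks.test(p_null, "punif")$p.value, 0.01)
  })
  # perfect covariate
  expect_lt(wald_test(fit, fit$y)$p, 1e-20)
  # constant covariate
  expect_true(is.na(wald_test(fit, rep(2, fit$n))$p))
})

test_that("wald effect SE tracks the Monte-Carlo spread of the estimates", {
  fx <- family_fixture(n_families = 40L)
  withr::with_seed(47, {
    z <- rnorm(nrow(fx$X), 0, 0.2)
    draws <- t(replicate(150, {
      y <- draw_outcome(fx, sg2 = 0.3, se2 = 0.5) + 1.0 * z
      unlist(wald_test(fit_null(y, fx$X, fx$eig), z))
    }))
  })
  expect_lt(abs(mean(draws[, "effect"]) - 1.0), 0.15)
  expect_lt(abs(mean(draws[, "se"]) / sd(draws[, "effect"]) - 1), 0.15)
})

test_that("score statistics match the dense projection-matrix oracle", {
  fx <- family_fixture(n_families = 12L)  # n = 48
  withr::with_seed(48, {
    y <- draw_outcome(fx)
    Z <- matrix(rnorm(nrow(fx$X) * 4), nrow(fx$X), 4,
                dimnames = list(fx$ids, paste0("z", 1:4)))
  })
  fit <- fit_null(y, fx$X, fx$eig)
  A <- fx$kin$A[fx$ids, fx$ids]
  P <- dense_projection(fit, A)
  ss <- score_stats(fit, Z)
  expect_equal(drop(t(Z) %*% P %*% y), ss$S,
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(t(Z) %*% P %*% Z, ss$Sigma_S,
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("with identity kinship and intercept-only design, scores are scaled covariances", {
  withr::with_seed(49, {
    n <- 80
    A <- identity_kinship(n)
    X <- matrix(1, n, 1, dimnames = list(rownames(A), "intercept"))
    y <- setNames(rnorm(n), rownames(A))
    Z <- matrix(rnorm(n * 3), n, 3, dimnames = list(rownames(A), paste0("z", 1:3)))
  })
  fit <- fit_null(y, X, A)
  ss <- score_stats(fit, Z)
  want <- drop(crossprod(Z, y - mean(y))) / fit$sigma_e2
  expect_equal(ss$S, want, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("variance components are recovered on nuclear families", {
  fx <- family_fixture(n_families = 100L, seed = 50L)  # n = 400
  withr::with_seed(51, {
    est <- t(replicate(60, {
      y <- draw_outcome(fx, sg2 = 1, se2 = 1)
      f <- fit_null(y, fx$X, fx$eig)
      c(f$sigma_g2, f$sigma_e2)
    }))
  })
  expect_lt(abs(mean(est[, 1]) - 1), 0.15)
  expect_lt(abs(mean(est[, 2]) - 1), 0.15)
})

test_that("tidy and glance summarise a fit", {
  fx <- family_fixture(n_families = 15L)
  withr::with_seed(52, y <- draw_outcome(fx))
  fit <- fit_null(y, fx$X, fx$eig)
  td <- tidy(fit)
  expect_equal(td$term, colnames(fx$X))
  expect_true(all(td$std.error > 0))
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_gte(gl$heritability, 0)
  expect_lte(gl$heritability, 1)
})
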