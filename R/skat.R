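#' SKAT Q statistic
#'
#' `Q = sum_j w_j^2 S_j^2`: the (weighted) sum of squares of the per-CpG
#' score statistics. With unit weights this is the unweighted set statistic.
#'
#' @param S Vector of per-CpG score statistics.
#' @param w Nonnegative per-CpG weights, same length as `S`.
#' @return The scalar Q.
#' @export
skat_q <- function(S, w = rep(1, length(S))) {
  if (length(w) != length(S)) {
    stop_methregion("Weights and scores have different lengths.",
                    "methregion_bad_argument")
  }
  sum((w * S)^2)
}

#' Beta-density weights from folded dosage frequencies
#'
#' The dosage-weighting sensitivity analysis borrows rare-variant semantics:
#' the folded dosage frequency `f*` of a CpG plays the role of a minor allele
#' frequency, and each CpG is weighted by the Beta(a, b) density at `f*`
#' (defaults a = 1, b = 25, the seqMeta default). Small `f*` — methylation
#' consistently changed — gets large weight; `f*` near 0.5 — unchanged —
#' gets nearly none.
#'
#' @param f_star Folded dosage frequencies in `[0, 0.5]` (see
#'   [dosage_transform()]).
#' @param a,b Beta density parameters.
#' @return Weight vector `dbeta(f_star, a, b)`.
#' @export
beta_weights <- function(f_star, a = 1, b = 25) {
  if (any(f_star < 0 | f_star > 1, na.rm = TRUE)) {
    stop_methregion("Folded frequencies must lie in [0, 1].",
                    "methregion_bad_argument")
  }
  dbeta(f_star, a, b)
}

#' Tail probability of a mixture of 1-df chi-squares
#'
#' Computes `P(sum_i lambda_i * chisq_1 > q)`, the asymptotic null survival
#' function of the SKAT Q statistic. The default route inverts the
#' characteristic function numerically (Davies/Imhof quadrature, absolute
#' accuracy ~1e-9); the moment-matching approximation of Liu, Tang and Zhang
#' is used as a fallback when the inversion reports a fault or the p-value is
#' at the integration noise floor (p <= 1e-12).
#'
#' @param q Observed statistic (nonnegative scalar).
#' @param lambda Nonnegative mixture eigenvalues, not all zero.
#' @param method `"davies"`, `"liu"` or `"auto"` (default: Davies with Liu
#'   fallback).
#' @return The p-value, clamped to `(0, 1]`.
#' @export
mixture_pvalue <- function(q, lambda, method = c("auto", "davies", "liu")) {
  method <- match.arg(method)
  assert_scalar_number(q, "q")
  lambda <- lambda[lambda > 0]
  if (length(lambda) == 0L) {
    stop_methregion("All mixture eigenvalues are zero: region untestable.",
                    "methregion_untestable")
  }
  if (q <= 0) return(1)
  if (method == "liu") return(liu_pvalue(q, lambda))
  dav <- davies_pvalue(q, lambda)
  if (method == "davies") return(dav$p)
  if (dav$fault || dav$p <= 1e-12) return(liu_pvalue(q, lambda))
  dav$p
}

# Characteristic-function inversion (Imhof's formula):
#   P(Q > q) = 1/2 + (1/pi) * Int_0^Inf sin(theta(u)) / (u * rho(u)) du
# with theta(u) = sum(atan(lambda u))/2 - q u / 2 and
# rho(u) = prod (1 + lambda^2 u^2)^(1/4).
#
# The integrand oscillates with slowly decaying amplitude, so naive
# quadrature over (0, Inf) cannot reach high absolute accuracy. Instead the
# integral is split into panels between consecutive zeros of sin(theta) —
# each panel is smooth and single-signed — and the alternating tail series
# of panel integrals is summed by iterated averaging (Euler acceleration).
davies_pvalue <- function(q, lambda) {
  m <- length(lambda)
  # one eigenvalue (or all equal): the mixture IS a scaled chi-square
  if (diff(range(lambda)) < 1e-12 * max(lambda)) {
    return(list(p = pchisq(q / lambda[1], df = m, lower.tail = FALSE),
                fault = FALSE))
  }
  # rescale so the problem is O(1) in u (p is scale invariant)
  sc <- mean(lambda)
  lambda <- lambda / sc
  q <- q / sc

  theta <- function(u) {
    0.5 * colSums(atan(outer(lambda, u))) - 0.5 * q * u
  }
  g_limit0 <- 0.5 * (sum(lambda) - q)  # lim u->0 of sin(theta)/(u rho)
  g <- function(u) {
    log_rho <- 0.25 * colSums(log1p(outer(lambda^2, u^2)))
    out <- sin(theta(u)) / (u * exp(log_rho))
    out[u < 1e-10] <- g_limit0
    out
  }
  # march in steps short enough to contain at most one zero of sin(theta):
  # |theta'(u)| <= max(sum(lambda), q) / 2
  h <- pi / max(sum(lambda), q)
  max_panels <- 2000L
  n_tail <- 40L
  zeros <- numeric(0)
  u_prev <- h * 1e-6
  sin_prev <- sin(theta(u_prev))
  u <- h
  n_found <- 0L
  while (n_found < max_panels) {
    s_here <- sin(theta(u))
    if (sign(s_here) != sign(sin_prev) && sin_prev != 0) {
      z <- stats::uniroot(function(x) sin(theta(x)), c(u_prev, u),
                          tol = 1e-13)$root
      if (n_found == 0L || z > zeros[n_found] + 1e-12) {
        zeros <- c(zeros, z)
        n_found <- n_found + 1L
      }
    }
    sin_prev <- s_here
    u_prev <- u
    u <- u + h
    # stop once the amplitude envelope at the last zero is negligible or we
    # have a healthy alternating tail to accelerate
    if (n_found >= 3L) {
      z_last <- zeros[n_found]
      env <- exp(-0.25 * sum(log1p(lambda^2 * z_last^2))) / z_last
      if (env < 1e-13 || n_found >= 60L) break
    }
  }
  if (length(zeros) < 1L) {
    # no sign change found: integrand decayed before first oscillation
    res <- tryCatch(
      integrate(g, 0, Inf, subdivisions = 2000L, rel.tol = 1e-10),
      error = function(e) NULL)
    if (is.null(res)) return(list(p = NA_real_, fault = TRUE))
    p <- 0.5 + res$value / pi
    return(list(p = min(max(p, 1e-300), 1), fault = res$abs.error > 1e-8))
  }
  bounds <- c(0, zeros)
  panel_int <- vapply(seq_len(length(bounds) - 1L), function(i) {
    stats::integrate(g, bounds[i], bounds[i + 1L],
                     rel.tol = 1e-10, abs.tol = 1e-13,
                     subdivisions = 200L)$value
  }, numeric(1))
  n_p <- length(panel_int)
  if (n_p <= 5L) {
    total <- sum(panel_int)
  } else {
    n_acc <- min(n_tail, n_p - 2L)
    head_sum <- sum(panel_int[seq_len(n_p - n_acc)])
    tail_terms <- panel_int[seq(n_p - n_acc + 1L, n_p)]
    # iterated averaging of the partial sums of the alternating tail,
    # extrapolating the truncated series to its limit
    S <- cumsum(tail_terms)
    while (length(S) > 1L) S <- (S[-1L] + S[-length(S)]) / 2
    total <- head_sum + S
  }
  p <- 0.5 + total / pi
  list(p = min(max(p, 1e-300), 1), fault = !is.finite(p))
}

# Liu-Tang-Zhang four-moment approximation: match skewness (and kurtosis
# when possible) of the mixture with a noncentral chi-square.
liu_pvalue <- function(q, lambda) {
  c1 <- sum(lambda); c2 <- sum(lambda^2); c3 <- sum(lambda^3); c4 <- sum(lambda^4)
  s1 <- c3 / c2^1.5
  s2 <- c4 / c2^2
  mu_q <- c1
  sigma_q <- sqrt(2 * c2)
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    ncp <- s1 * a^3 - a^2
    df <- a^2 - 2 * ncp
  } else {
    df <- 1 / s2
    ncp <- 0
    a <- sqrt(df)
  }
  mu_x <- df + ncp
  sigma_x <- sqrt(2 * (df + 2 * ncp))
  t_star <- (q - mu_q) / sigma_q
  min(max(pchisq(t_star * sigma_x + mu_x, df = df, ncp = ncp,
                 lower.tail = FALSE), 1e-300), 1)
}

#' SKAT test of one region
#'
#' Composes the per-CpG score statistics of the null fit, the (weighted) Q
#' statistic, the mixture eigenvalues of `W^(1/2) Sigma_S W^(1/2)` with
#' `W = diag(w^2)`, and the mixture chi-square p-value.
#'
#' @param fit A `kin_lmm` null fit.
#' @param Z Samples-by-CpGs change matrix for the region.
#' @param w Per-CpG weights (default all 1).
#' @param method p-value route, see [mixture_pvalue()].
#' @return A one-row tibble: `n_cpg`, `statistic` (Q), `p` (`NA` with all
#'   fields retained when the region is degenerate).
#' @export
skat_region <- function(fit, Z, w = rep(1, ncol(Z)), method = "auto") {
  Z <- as.matrix(Z)
  ss <- score_stats(fit, Z)
  skat_from_scores(ss, w, method)
}

# Shared tail: Q, eigenvalues, p from precomputed score statistics.
skat_from_scores <- function(ss, w, method = "auto") {
  m <- length(ss$S)
  if (length(w) != m) {
    stop_methregion("Weight length does not match CpG count.",
                    "methregion_bad_argument")
  }
  q_obs <- skat_q(ss$S, w)
  Wh <- w  # W^(1/2) = diag(w) since W = diag(w^2)
  M <- t(ss$Sigma_S * Wh) * Wh
  M <- (M + t(M)) / 2
  lam <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  lam <- lam[lam > 1e-10 * max(lam, 0)]
  if (length(lam) == 0L) {
    return(tibble(n_cpg = m, statistic = NA_real_, p = NA_real_))
  }
  tibble(n_cpg = m, statistic = q_obs,
         p = mixture_pvalue(q_obs, lam, method = method))
}

#' Region-based SKAT across a region map
#'
#' Runs the variance-component set test for every testable region under one
#' global null fit (no per-region refitting: the score construction is
#' marginal). Weights are unit by default, or the dosage Beta-density weights
#' when `weights = "beta_dosage"`.
#'
#' @param fit A `kin_lmm` null fit of the outcome on covariates + kinship.
#' @param delta Samples-by-probes methylation-change matrix
#'   (from [delta_methylation()]).
#' @param region_map A `region_map` from [map_probes()].
#' @param weights `"unit"` or `"beta_dosage"`.
#' @param beta_a,beta_b Beta-density parameters for dosage weights.
#' @param method p-value route, see [mixture_pvalue()].
#' @return A tibble with one row per testable region: `gene`, `n_cpg`,
#'   `method`, `statistic`, `p`.
#' @export
skat_region_all <- function(fit, delta, region_map,
                            weights = c("unit", "beta_dosage"),
                            beta_a = 1, beta_b = 25, method = "auto") {
  weights <- match.arg(weights)
  regs <- region_map$regions[region_map$regions$testable, , drop = FALSE]
  if (!is.null(rownames(delta)) && !is.null(rownames(fit$X))) {
    delta <- delta[rownames(fit$X), , drop = FALSE]
  }
  f_star <- NULL
  if (weights == "beta_dosage") {
    f_star <- dosage_transform(delta)$folded_freq
  }
  method_label <- if (weights == "unit") "SKAT" else "SKAT_weighted"
  rows <- vector("list", nrow(regs))
  for (i in seq_len(nrow(regs))) {
    probes <- intersect(regs$probe_ids[[i]], colnames(delta))
    if (length(probes) == 0L) {
      rows[[i]] <- tibble(gene = regs$gene_id[i], n_cpg = 0L,
                          method = method_label,
                          statistic = NA_real_, p = NA_real_)
      next
    }
    Z <- delta[, probes, drop = FALSE]
    w <- if (weights == "unit") rep(1, length(probes))
         else beta_weights(f_star[probes], beta_a, beta_b)
    res <- tryCatch(
      skat_region(fit, Z, w = w, method = method),
      methregion_untestable = function(e) tibble(n_cpg = length(probes),
                                                 statistic = NA_real_,
                                                 p = NA_real_)
    )
    rows[[i]] <- tibble(gene = regs$gene_id[i], n_cpg = as.integer(res$n_cpg),
                        method = method_label,
                        statistic = res$statistic, p = res$p)
  }
  dplyr::bind_rows(rows)
}

#' Median methylation level test (MMLT) across a region map
#'
#' For each testable region, the change in median methylation is appended to
#' the covariate design as one extra fixed effect, the kinship mixed model is
#' refitted by REML, and the Wald effect/SE/p of the median-change term is
#' reported.
#'
#' @param y Outcome vector (log-scale lipid change).
#' @param X Covariate design matrix (see [covariate_design()]).
#' @param K Kinship (any form accepted by [kinship_eigen()]).
#' @param median_change Samples-by-genes matrix from [region_median_change()].
#' @param region_map Optional `region_map` supplying per-gene CpG counts.
#' @return A tibble with one row per gene: `gene`, `n_cpg`, `method`
#'   (`"MMLT"`), `effect`, `se`, `p` (`NA` rows, retained, for constant or
#'   missing median change).
#' @export
mmlt <- function(y, X, K, median_change, region_map = NULL) {
  fit <- fit_null(y, X, K)
  genes <- colnames(median_change)
  n_cpg <- rep(NA_integer_, length(genes))
  if (!is.null(region_map)) {
    lookup <- setNames(region_map$regions$n_cpg, region_map$regions$gene_id)
    n_cpg <- as.integer(lookup[genes])
  }
  if (!is.null(rownames(median_change)) && !is.null(rownames(X))) {
    median_change <- median_change[rownames(X), , drop = FALSE]
  }
  rows <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    z <- median_change[, i]
    if (any(is.na(z)) || sd(z) == 0) {
      rows[[i]] <- tibble(effect = NA_real_, se = NA_real_, p = NA_real_)
    } else {
      rows[[i]] <- wald_test(fit, z)
    }
  }
  out <- dplyr::bind_rows(rows)
  tibble(gene = genes, n_cpg = n_cpg, method = "MMLT",
         effect = out$effect, se = out$se, p = out$p)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment: `q_(i) = min_(j >= i) p_(j) * m / j`, capped at 1,
#' mapped back to input order. `NA` p-values pass through as `NA` and do not
#' count toward `m`.
#'
#' @param p Vector of p-values in `(0, 1]` (`NA` allowed).
#' @return Vector of q-values, same length and order.
#' @export
bh_fdr <- function(p) {
  p.adjust(p, method = "BH")
}

#' Append BH q-values to a results tibble
#'
#' @param results Tibble with a `p` column (e.g. from [mmlt()] or
#'   [skat_region_all()]); adjustment is per `method` group when a `method`
#'   column is present.
#' @return The tibble with a `q` column added.
#' @export
add_bh_q <- function(results) {
  if ("method" %in% names(results)) {
    dplyr::mutate(dplyr::group_by(results, .data$method),
                  q = bh_fdr(.data$p)) |> dplyr::ungroup()
  } else {
    dplyr::mutate(results, q = bh_fdr(.data$p))
  }
}
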