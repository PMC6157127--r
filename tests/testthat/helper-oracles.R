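# Independent oracles used by the tests. These deliberately avoid the
# package's own computation paths.

# Monte-Carlo kinship by gene dropping: founders carry unique alleles,
# children inherit one random allele from each parent; the kinship of (i, j)
# is the probability that one allele drawn from each is identical by descent.
gene_drop_kinship <- function(ped, n_drops = 20000L) {
  ids <- ped$individual_id
  n <- length(ids)
  idx <- stats::setNames(seq_len(n), ids)
  fa <- idx[ped$father_id]
  mo <- idx[ped$mother_id]
  ord <- methregion:::pedigree_order(ped)
  a1 <- matrix(0L, n_drops, n)
  a2 <- matrix(0L, n_drops, n)
  next_allele <- 1L
  for (i in ord) {
    if (is.na(fa[i]) && is.na(mo[i])) {
      a1[, i] <- next_allele
      a2[, i] <- next_allele + 1L
      next_allele <- next_allele + 2L
    } else {
      pick <- function(par) {
        if (is.na(par)) {
          out <- rep(next_allele, n_drops)
          next_allele <<- next_allele + 1L
          return(out)
        }
        take1 <- stats::runif(n_drops) < 0.5
        ifelse(take1, a1[, par], a2[, par])
      }
      a1[, i] <- pick(fa[i])
      a2[, i] <- pick(mo[i])
    }
  }
  phi <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in i:n) {
      ibd <- (a1[, i] == a1[, j]) + (a1[, i] == a2[, j]) +
        (a2[, i] == a1[, j]) + (a2[, i] == a2[, j])
      phi[i, j] <- phi[j, i] <- mean(ibd) / 4
    }
  }
  phi
}

# Step-up BH implementation written independently of p.adjust.
bh_stepup_oracle <- function(p) {
  ok <- !is.na(p)
  q <- rep(NA_real_, length(p))
  pv <- p[ok]
  m <- length(pv)
  if (m == 0L) return(q)
  o <- order(pv)
  ranked <- pv[o] * m / seq_len(m)
  qv <- rev(cummin(rev(ranked)))
  qv <- pmin(qv, 1)
  out <- numeric(m)
  out[o] <- qv
  q[ok] <- out
  q
}

# Monte-Carlo survival function of a mixture of 1-df chi-squares.
mixture_mc <- function(q, lambda, n_draws = 200000L) {
  draws <- as.matrix(matrix(stats::rnorm(n_draws * length(lambda)),
                            n_draws, length(lambda))^2) %*% lambda
  mean(draws > q)
}

# Dense projection matrix P = V^-1 - V^-1 X (X'V^-1 X)^-1 X'V^-1 built
# directly from a fit's variance components (no eigen-rotation shortcut).
dense_projection <- function(fit, A) {
  V <- fit$sigma_g2 * A + fit$sigma_e2 * diag(fit$n)
  Vi <- solve(V)
  X <- fit$X
  Vi - Vi %*% X %*% solve(t(X) %*% Vi %*% X) %*% t(X) %*% Vi
}
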