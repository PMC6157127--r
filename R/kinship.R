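#' Kinship matrix from a pedigree
#'
#' Computes pedigree kinship coefficients by the standard recursion over
#' individuals sorted so parents precede children: for founders
#' `phi(i, i) = 1/2` and `phi(i, j) = 0`; otherwise
#' `phi(i, i) = (1 + phi(father, mother)) / 2` and
#' `phi(i, j) = (phi(father, j) + phi(mother, j)) / 2` for any `j` placed
#' earlier. The additive relationship matrix is `A = 2 * phi` — the
#' covariance structure of the polygenic random effect.
#'
#' @param ped Validated pedigree tibble (see [read_pedigree()]).
#' @return A list of class `kinship_matrix` with elements `ids`, `phi`
#'   (kinship coefficients) and `A` (`2 * phi`), both dense symmetric
#'   matrices ordered like `ids`.
#' @export
kinship <- function(ped) {
  ped <- validate_pedigree(ped)
  ord <- pedigree_order(ped)
  ids <- ped$individual_id
  n <- length(ids)
  idx <- setNames(seq_len(n), ids)
  fa <- idx[ped$father_id]
  mo <- idx[ped$mother_id]
  phi <- matrix(0, n, n, dimnames = list(ids, ids))
  pos <- integer(0)  # indices already placed, in topological order
  for (i in ord) {
    f <- fa[i]; m <- mo[i]
    if (is.na(f) && is.na(m)) {
      phi[i, i] <- 0.5
    } else {
      phi_fm <- if (!is.na(f) && !is.na(m)) phi[f, m] else 0
      phi[i, i] <- 0.5 * (1 + phi_fm)
      if (length(pos) > 0L) {
        phi_f <- if (!is.na(f)) phi[f, pos] else rep(0, length(pos))
        phi_m <- if (!is.na(m)) phi[m, pos] else rep(0, length(pos))
        val <- 0.5 * (phi_f + phi_m)
        phi[i, pos] <- val
        phi[pos, i] <- val
      }
    }
    pos <- c(pos, i)
  }
  structure(list(ids = ids, phi = phi, A = 2 * phi),
            class = "kinship_matrix")
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat(sprintf("<kinship_matrix> %d individuals, mean off-diagonal phi %.4f\n",
              length(x$ids),
              mean(x$phi[upper.tri(x$phi)])))
  invisible(x)
}

# Reorder (and subset) a kinship matrix to a given id vector.
kinship_subset <- function(K, ids) {
  miss <- setdiff(ids, K$ids)
  if (length(miss) > 0L) {
    stop_methregion(sprintf("Ids absent from kinship matrix: %s",
                            paste(head(miss, 5L), collapse = ", ")),
                    "methregion_kinship_error")
  }
  structure(list(ids = ids,
                 phi = K$phi[ids, ids, drop = FALSE],
                 A = K$A[ids, ids, drop = FALSE]),
            class = "kinship_matrix")
}
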