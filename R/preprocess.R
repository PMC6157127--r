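#' Filter probes against SNP and cross-reactivity exclusion lists
#'
#' Removes probes whose ids appear in an externally supplied SNP-overlap list
#' or cross-reactive list (the lists correspond to published 450K exclusion
#' sets; computing them requires genotype data and is upstream of this
#' package). Probes carrying `snp_flag`/`crossreactive_flag` in the manifest
#' are removed as well.
#'
#' @param manifest Probe manifest tibble.
#' @param snp_list Character vector of probe ids overlapping SNPs.
#' @param crossreactive_list Character vector of cross-reactive probe ids.
#' @return A list with `manifest` (retained probes) and `report`, a tibble
#'   with per-criterion counts: `n_input`, `n_snp`, `n_crossreactive`,
#'   `n_overlap`, `n_removed`, `n_retained`, `n_unknown_ids`.
#' @export
filter_probes <- function(manifest, snp_list = character(),
                          crossreactive_list = character()) {
  unknown <- setdiff(union(snp_list, crossreactive_list), manifest$probe_id)
  if (length(unknown) > 0L) {
    warn_methregion(
      sprintf("%d exclusion-list id(s) absent from manifest; ignored.", length(unknown)),
      "methregion_unknown_probe_ids")
  }
  snp_hit <- manifest$probe_id %in% snp_list | manifest$snp_flag
  xr_hit <- manifest$probe_id %in% crossreactive_list | manifest$crossreactive_flag
  drop <- snp_hit | xr_hit
  report <- tibble(
    n_input = nrow(manifest),
    n_snp = sum(snp_hit),
    n_crossreactive = sum(xr_hit),
    n_overlap = sum(snp_hit & xr_hit),
    n_removed = sum(drop),
    n_retained = sum(!drop),
    n_unknown_ids = length(unknown)
  )
  list(manifest = manifest[!drop, , drop = FALSE], report = report)
}

#' Per-CpG methylation change
#'
#' Computes the sample-by-probe difference matrix between the two timepoints,
#' `pre - post` by default. Samples are aligned by id; probe universes must
#' overlap (the intersection is used, in pre-matrix order).
#'
#' @param pre,post `meth_matrix` objects.
#' @param orientation `"pre_minus_post"` (default) or `"post_minus_pre"`.
#' @return A samples-by-probes matrix of changes in `[-1, 1]` (`NA` where
#'   either timepoint is missing).
#' @export
delta_methylation <- function(pre, post, orientation = "pre_minus_post") {
  sgn <- orientation_sign(orientation)
  al <- align_samples(pre, post)
  shared <- intersect(colnames(pre), colnames(post))
  if (length(shared) == 0L) {
    stop_methregion("Pre and post matrices share no probes.", "methregion_probe_mismatch")
  }
  d <- sgn * (unclass(al$pre)[, shared, drop = FALSE] -
                unclass(al$post)[, shared, drop = FALSE])
  d
}

#' Region median-methylation change
#'
#' For each testable region and each sample, the median beta over the
#' region's CpGs is taken at each timepoint separately, and the change of
#' medians (`pre - post` by default) is returned. `NA` probes are dropped per
#' (sample, region) before the median; a cell where a sample has no observed
#' probe in the region is `NA`. Medians of even-sized sets are the mean of
#' the two central values.
#'
#' @param pre,post `meth_matrix` objects.
#' @param region_map A `region_map` from [map_probes()].
#' @param orientation `"pre_minus_post"` (default) or `"post_minus_pre"`.
#' @return A samples-by-genes matrix of median changes (testable regions only).
#' @export
region_median_change <- function(pre, post, region_map,
                                 orientation = "pre_minus_post") {
  sgn <- orientation_sign(orientation)
  al <- align_samples(pre, post)
  regs <- region_map$regions[region_map$regions$testable, , drop = FALSE]
  pre_m <- unclass(al$pre); post_m <- unclass(al$post)
  out <- matrix(NA_real_, nrow = nrow(pre_m), ncol = nrow(regs),
                dimnames = list(rownames(pre_m), regs$gene_id))
  for (i in seq_len(nrow(regs))) {
    probes <- regs$probe_ids[[i]]
    probes_pre <- intersect(probes, colnames(pre_m))
    probes_post <- intersect(probes, colnames(post_m))
    if (length(probes_pre) == 0L || length(probes_post) == 0L) next
    med_pre <- matrixStats::rowMedians(pre_m[, probes_pre, drop = FALSE], na.rm = TRUE)
    med_post <- matrixStats::rowMedians(post_m[, probes_post, drop = FALSE], na.rm = TRUE)
    out[, i] <- sgn * (med_pre - med_post)
  }
  out[is.nan(out)] <- NA_real_
  out
}

#' Principal components of a methylation matrix
#'
#' Column-centered PCA of the beta values; probes with any missing value are
#' excluded before decomposition. Component signs are fixed so that each
#' component's largest-magnitude probe loading is positive, making scores
#' reproducible across runs.
#'
#' @param m `meth_matrix` (or plain samples-by-probes matrix).
#' @param k Number of components requested (default 20).
#' @return A samples-by-`k` score matrix (fewer columns, with a warning, if
#'   the matrix rank is below `k`); attribute `"sdev"` carries the component
#'   standard deviations and `"n_probes_used"` the complete-case probe count.
#' @export
compute_pcs <- function(m, k = 20L) {
  x <- unclass(m)
  complete <- colSums(is.na(x)) == 0L
  if (!all(complete)) {
    inform(sprintf("compute_pcs: excluding %d probe(s) with missing values.",
                   sum(!complete)))
  }
  x <- x[, complete, drop = FALSE]
  if (nrow(x) < 2L || ncol(x) == 0L) {
    stop_methregion("Too little complete data for PCA.", "methregion_pca_error")
  }
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  rank_eff <- sum(pc$sdev > max(pc$sdev) * 1e-10)
  k_eff <- min(k, rank_eff)
  if (k_eff < k) {
    warn_methregion(sprintf("Requested %d components but rank is %d; returning %d.",
                            k, rank_eff, k_eff),
                    "methregion_pca_rank")
  }
  scores <- pc$x[, seq_len(k_eff), drop = FALSE]
  # Sign convention: largest-|loading| entry of each rotation column positive.
  for (j in seq_len(k_eff)) {
    load_j <- pc$rotation[, j]
    if (load_j[which.max(abs(load_j))] < 0) scores[, j] <- -scores[, j]
  }
  rownames(scores) <- rownames(x)
  attr(scores, "sdev") <- pc$sdev[seq_len(k_eff)]
  attr(scores, "n_probes_used") <- ncol(x)
  scores
}

#' Screen principal components against an outcome
#'
#' Marginal simple linear regression of the outcome on each candidate score
#' column; columns with p below `alpha` are selected. Pre- and post-treatment
#' PC blocks are screened jointly by passing their column-bound scores.
#'
#' @param pcs Samples-by-components score matrix.
#' @param y Outcome vector aligned to the score rows.
#' @param alpha Selection threshold (default 0.05).
#' @return Integer vector of selected column indices (possibly empty).
#' @export
screen_pcs <- function(pcs, y, alpha = 0.05) {
  stopifnot(nrow(pcs) == length(y))
  if (alpha <= 0) return(integer(0))
  ok <- is.finite(y)
  pvals <- vapply(seq_len(ncol(pcs)), function(j) {
    x <- pcs[ok, j]
    if (var(x) == 0) return(1)
    fit <- summary(lm(y[ok] ~ x))
    fit$coefficients["x", "Pr(>|t|)"]
  }, numeric(1))
  which(pvals < alpha)
}

#' Log-scale lipid change
#'
#' The outcome is the signed log-ratio `log(pre) - log(post)` (or its
#' negative under the flipped orientation): monotone in the raw change,
#' defined for any positive pair, and oriented pre-minus-post like the
#' methylation changes.
#'
#' @param lipid_pre,lipid_post Positive lipid levels (mg/dL).
#' @param orientation `"pre_minus_post"` (default) or `"post_minus_pre"`.
#' @return Numeric vector of log-scale changes.
#' @export
log_change <- function(lipid_pre, lipid_post, orientation = "pre_minus_post") {
  sgn <- orientation_sign(orientation)
  if (any(!is.na(lipid_pre) & lipid_pre <= 0) ||
      any(!is.na(lipid_post) & lipid_post <= 0)) {
    stop_methregion("Lipid levels must be strictly positive.", "methregion_lipid_range")
  }
  sgn * (log(lipid_pre) - log(lipid_post))
}

#' Methylation-changing dosage transform
#'
#' Maps per-CpG changes to a dosage `d = delta + 1` in `[0, 2]`, by analogy
#' with an allele dosage: d near 1 means unchanged methylation, d near 0 or 2
#' means a large change. Per probe, the dosage frequency is `f = mean(d) / 2`
#' over non-missing samples, and the folded frequency `f* = min(f, 1 - f)`
#' plays the role of a minor-allele frequency (f* near 0.5 = unchanged; f*
#' near 0 = consistently changed in either direction).
#'
#' @param delta Samples-by-probes change matrix from [delta_methylation()].
#' @return A list with `dosage` (matrix in `[0, 2]`), `freq` and
#'   `folded_freq` (per-probe named vectors).
#' @export
dosage_transform <- function(delta) {
  d <- delta + 1
  f <- colMeans(d, na.rm = TRUE) / 2
  list(dosage = d, freq = f, folded_freq = pmin(f, 1 - f))
}

#' Build the fixed-effect design matrix
#'
#' Intercept, age, sex, field center, metabolic syndrome, two smoking
#' indicators (past, current; never is the reference) and any selected
#' principal-component score columns.
#'
#' @param phenotypes Phenotype tibble (see [read_phenotypes()]).
#' @param pcs Optional score matrix whose selected columns are appended.
#' @param pc_cols Indices into `pcs` columns (e.g. from [screen_pcs()]).
#' @return A numeric design matrix with rownames = sample ids.
#' @export
covariate_design <- function(phenotypes, pcs = NULL, pc_cols = integer(0)) {
  X <- cbind(
    intercept = 1,
    age = phenotypes$age,
    sex = as.numeric(phenotypes$sex),
    center = as.numeric(phenotypes$center),
    metabolic_syndrome = as.numeric(phenotypes$metabolic_syndrome),
    smoking_past = as.numeric(phenotypes$smoking == "past"),
    smoking_current = as.numeric(phenotypes$smoking == "current")
  )
  rownames(X) <- phenotypes$sample_id
  if (!is.null(pcs) && length(pc_cols) > 0L) {
    sel <- pcs[phenotypes$sample_id, pc_cols, drop = FALSE]
    colnames(sel) <- paste0("pc_", pc_cols)
    X <- cbind(X, sel)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_cols <- qrX$pivot[seq(qrX$rank + 1L, ncol(X))]
    warn_methregion(
      sprintf("Dropping %d collinear design column(s): %s",
              length(drop_cols), paste(colnames(X)[drop_cols], collapse = ", ")),
      "methregion_rank_deficient")
    X <- X[, -drop_cols, drop = FALSE]
  }
  X
}
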