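test_that("filter_probes does the documented set arithmetic", {
  man <- toy_manifest(10L)
  out <- filter_probes(man, snp_list = c("cg001", "cg002"),
                       crossreactive_list = c("cg002", "cg003"))
  expect_equal(out$report$n_retained, 7L)
  expect_equal(out$report$n_snp, 2L)
  expect_equal(out$report$n_crossreactive, 2L)
  expect_equal(out$report$n_overlap, 1L)
  expect_setequal(out$manifest$probe_id, sprintf("cg%03d", 4:10))

  ident <- filter_probes(man)
  expect_equal(ident$manifest, man)

  expect_warning(filter_probes(man, snp_list = "not_a_probe"),
                 class = "methregion_unknown_probe_ids")
})

test_that("filter_probes agrees with brute-force set difference on random lists", {
  withr::with_seed(21, {
    for (rep in 1:5) {
      man <- toy_manifest(50L)
      snp <- sample(man$probe_id, 12L)
      xr <- sample(man$probe_id, 8L)
      out <- filter_probes(man, snp, xr)
      expect_setequal(out$manifest$probe_id,
                      setdiff(man$probe_id, union(snp, xr)))
    }
  })
})

test_that("delta is the aligned elementwise difference, oriented pre minus post", {
  pair <- toy_meth_pair()
  d <- delta_methylation(pair$pre, pair$post)
  expect_equal(d, unclass(pair$pre) - unclass(pair$post), ignore_attr = TRUE)
  expect_true(all(abs(d) <= 1))

  expect_equal(max(abs(delta_methylation(pair$pre, pair$pre))), 0)

  ids <- list(list("s", "p"))
  one <- meth_matrix(matrix(1, 1, 1, dimnames = list("s", "p")), "pre")
  zero <- meth_matrix(matrix(0, 1, 1, dimnames = list("s", "p")), "post")
  expect_equal(drop(delta_methylation(one, zero)), 1)
  expect_equal(drop(delta_methylation(one, zero, "post_minus_pre")), -1)
})

test_that("region medians follow the stated conventions and a brute-force oracle", {
  # median of 3, exact example
  pre <- meth_matrix(matrix(c(0.2, 0.4, 0.6), 1, 3,
                            dimnames = list("s1", c("a", "b", "c"))), "pre")
  post <- meth_matrix(matrix(c(0.1, 0.4, 0.7), 1, 3,
                             dimnames = list("s1", c("a", "b", "c"))), "post")
  regs <- tibble::tibble(gene_id = "g1", chrom = "chr1", start = 1L, end = 10L)
  man <- tibble::tibble(probe_id = c("a", "b", "c"), chrom = "chr1",
                        pos = 1:3, snp_flag = FALSE, crossreactive_flag = FALSE)
  rm <- map_probes(regs, man)
  expect_equal(drop(region_median_change(pre, post, rm)), 0)

  # even count: mean of the two central values
  pre2 <- meth_matrix(matrix(c(0.2, 0.4), 1, 2,
                             dimnames = list("s1", c("a", "b"))), "pre")
  post2 <- meth_matrix(matrix(c(0.0, 0.0), 1, 2,
                              dimnames = list("s1", c("a", "b"))), "post")
  man2 <- man[1:2, ]
  rm2 <- map_probes(regs, man2)
  expect_equal(drop(region_median_change(pre2, post2, rm2)), 0.3)

  # NA probes dropped per (sample, region); all-NA cell is NA
  pre_na <- unclass(pre); pre_na[1, ] <- NA
  expect_true(is.na(drop(region_median_change(meth_matrix(pre_na, "pre"), post, rm))))

  # brute-force oracle across random regions
  withr::with_seed(22, {
    man_r <- toy_manifest(60L, start = 1L, by = 10L)
    regs_r <- tibble::tibble(
      gene_id = paste0("g", 1:20), chrom = "chr1",
      start = as.integer(sample.int(500L, 20)))
    regs_r$end <- regs_r$start + 120L
    pair <- toy_meth_pair(n_samples = 8L, n_probes = 60L, seed = 5L)
  })
  colnames(pair$pre) <- colnames(pair$post) <- man_r$probe_id
  rm_r <- map_probes(regs_r, man_r)
  got <- region_median_change(pair$pre, pair$post, rm_r)
  testable <- rm_r$regions[rm_r$regions$testable, ]
  for (i in seq_len(nrow(testable))) {
    probes <- testable$probe_ids[[i]]
    for (s in rownames(pair$pre)) {
      want <- median(unclass(pair$pre)[s, probes]) -
        median(unclass(pair$post)[s, probes])
      expect_equal(got[s, testable$gene_id[i]], want)
    }
  }

  # self-difference is identically zero
  expect_true(all(region_median_change(pair$pre, pair$pre, rm_r) == 0))
})

test_that("compute_pcs matches an independent eigen-decomposition", {
  withr::with_seed(23, {
    x <- matrix(runif(30 * 12), 30, 12,
                dimnames = list(paste0("s", 1:30), paste0("p", 1:12)))
  })
  m <- meth_matrix(x, "pre")
  sc <- compute_pcs(m, k = 12L)
  # orthogonal score columns
  cp <- crossprod(sc)
  expect_lt(max(abs(cp[upper.tri(cp)])), 1e-8)
  # score variances equal covariance eigenvalues
  ev <- eigen(stats::cov(x), symmetric = TRUE)$values
  expect_equal(apply(sc, 2, function(v) sum(v^2) / (nrow(x) - 1)),
               ev[1:12], tolerance = 1e-8, ignore_attr = TRUE)
  # with all components the scores carry the full centered sum of squares
  xc <- scale(x, center = TRUE, scale = FALSE)
  expect_equal(sum(sc^2), sum(xc^2), tolerance = 1e-8)

  # rank-1 matrix: PC1 carries all variance
  r1 <- outer(runif(20), runif(5))
  dimnames(r1) <- list(paste0("s", 1:20), paste0("p", 1:5))
  expect_warning(sc1 <- compute_pcs(meth_matrix(r1 / max(r1), "pre"), k = 5L),
                 class = "methregion_pca_rank")
  expect_equal(ncol(sc1), 1L)
})

test_that("screen_pcs selects true signal and honours alpha boundaries", {
  withr::with_seed(24, {
    pcs <- matrix(rnorm(200 * 6), 200, 6)
    y <- pcs[, 1] + rnorm(200, 0, 0.01)
    expect_true(1 %in% screen_pcs(pcs, y))
    expect_equal(screen_pcs(pcs, y, alpha = 0), integer(0))
    # null outcome: selection rate near alpha over replicates
    hits <- replicate(60, length(screen_pcs(pcs, rnorm(200), alpha = 0.05)))
    expect_lt(abs(mean(hits) / 6 - 0.05), 0.03)
  })
})

test_that("log_change is the signed log-ratio", {
  expect_equal(log_change(100, 100), 0)
  expect_equal(log_change(exp(1) * 50, 50), 1)
  expect_error(log_change(-1, 50), class = "methregion_lipid_range")
  withr::with_seed(25, {
    pre <- rexp(200) + 0.01
    post <- rexp(200) + 0.01
    expect_true(all(sign(log_change(pre, post)) == sign(pre - post)))
  })
})

test_that("dosage transform is affine in the mean change", {
  pair <- toy_meth_pair(n_samples = 10L, n_probes = 8L, seed = 6L)
  d <- delta_methylation(pair$pre, pair$post)
  dos <- dosage_transform(d)
  expect_equal(dos$dosage, d + 1)
  expect_equal(dos$freq, (colMeans(d) + 1) / 2)
  expect_equal(dos$folded_freq, pmin(dos$freq, 1 - dos$freq))

  zero <- dosage_transform(matrix(0, 3, 2, dimnames = list(NULL, c("a", "b"))))
  expect_true(all(zero$dosage == 1))
  expect_true(all(zero$freq == 0.5))
  expect_true(all(zero$folded_freq == 0.5))

  extreme <- dosage_transform(matrix(-1, 3, 2, dimnames = list(NULL, c("a", "b"))))
  expect_true(all(extreme$dosage == 0))
  expect_true(all(extreme$folded_freq == 0))
})
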