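test_that("pedigree simulation hits the requested structure and is seeded", {
  cfg <- scenario_config(n_families = 100L, family_structure = "nuclear4",
                         seed = 80L)
  out <- simulate_pedigrees(cfg)
  expect_equal(nrow(out$pedigree), 400L)
  expect_equal(sum(methregion:::is_founder(out$pedigree)), 200L)

  # same seed, byte-identical pedigree file
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_pedigree(simulate_pedigrees(cfg)$pedigree, p1)
  write_pedigree(simulate_pedigrees(cfg)$pedigree, p2)
  expect_identical(readLines(p1), readLines(p2))

  # study-scale mix: 139 families of ~3.2 members on average
  mix <- simulate_pedigrees(scenario_config(n_families = 139L, seed = 81L))
  expect_gt(nrow(mix$pedigree), 417)  # 139 * 3
  expect_lt(nrow(mix$pedigree), 473)  # 139 * 3.4
})

test_that("simulated beta values respect [0,1] and a zero-noise world is static", {
  cfg <- scenario_config(n_families = 50L, n_regions = 30L, seed = 82L)
  st <- simulate_study(cfg)
  expect_true(all(unclass(st$pre) >= 0 & unclass(st$pre) <= 1))
  expect_true(all(unclass(st$post) >= 0 & unclass(st$post) <= 1))

  cfg0 <- scenario_config(n_families = 20L, n_regions = 10L, seed = 83L,
                          shift_sd = 0, noise_sd = 0)
  st0 <- simulate_study(cfg0)
  d <- delta_methylation(st0$pre, st0$post)
  expect_true(all(d == 0))
})

test_that("per-CpG changes center on zero when no shift is injected", {
  cfg <- scenario_config(n_families = 125L, family_structure = "nuclear4",
                         n_regions = 20L, seed = 84L, shift_sd = 0)
  st <- simulate_study(cfg)  # n = 500
  d <- delta_methylation(st$pre, st$post)
  tstat <- abs(colMeans(d)) / (apply(d, 2, sd) / sqrt(nrow(d)))
  expect_gt(mean(tstat < 3), 0.95)
})

test_that("covariate marginals match the target descriptive table", {
  cfg <- scenario_config(n_families = 139L, seed = 85L)
  st <- simulate_study(cfg)
  ph <- st$phenotypes
  n <- nrow(ph)
  expect_lt(abs(mean(ph$age) - 47), 3 * 16 / sqrt(n))
  expect_lt(abs(sd(ph$age) - 16), 3 * 16 / sqrt(2 * n))
  expect_lt(abs(mean(ph$metabolic_syndrome) - 0.401), 3 * 0.5 / sqrt(n))
  expect_lt(abs(mean(ph$smoking == "never") - 0.709), 3 * 0.46 / sqrt(n))
  expect_true(all(ph$tg_pre > 0 & ph$tg_post > 0 & ph$hdl_pre > 0 &
                    ph$hdl_post > 0))
})

test_that("the signed log-ratio of the constructed lipids reproduces the outcome", {
  cfg <- scenario_config(n_families = 30L, n_regions = 10L, seed = 86L)
  st <- simulate_study(cfg)
  expect_equal(log_change(st$phenotypes$tg_pre, st$phenotypes$tg_post),
               st$y, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("truth record reconstructs the outcome and the causal contributions", {
  cfg <- scenario_config(n_families = 40L, n_regions = 20L,
                         scenario = "opposing", tau = 3, fraction_causal = 0.5,
                         seed = 87L)
  st <- simulate_study(cfg)
  comp <- st$truth$components
  y_rebuilt <- comp$fixed + comp$causal + comp$batch + comp$polygenic +
    comp$residual
  expect_equal(y_rebuilt, st$y, tolerance = 1e-10)
  # each causal region's contribution recomputes from delta and tau
  d <- delta_methylation(st$pre, st$post)[st$pedigree$individual_id, ]
  for (g in st$truth$causal_genes) {
    rows <- st$truth$causal[st$truth$causal$gene == g, ]
    want <- drop(d[, rows$probe_id, drop = FALSE] %*% rows$tau)
    expect_equal(st$truth$region_contributions[[g]], want, tolerance = 1e-10)
  }
  # opposing scenario alternates signs of equal magnitude
  taus <- st$truth$causal$tau
  expect_true(all(abs(taus) == cfg$tau))
  expect_true(any(taus > 0) && any(taus < 0))
})

test_that("sibling correlation of the random part approaches h2/2", {
  cfg <- scenario_config(n_families = 100L, family_structure = "nuclear4",
                         h2 = 0.8, random_sd = 1, seed = 88L)
  peds <- simulate_pedigrees(cfg)
  ped <- peds$pedigree
  eig <- kinship_eigen(peds$kinship)
  n <- nrow(ped)
  sib1 <- which(!methregion:::is_founder(ped))[c(TRUE, FALSE)]
  sib2 <- which(!methregion:::is_founder(ped))[c(FALSE, TRUE)]
  withr::with_seed(89, {
    cors <- replicate(100, {
      g <- drop(eig$U %*% (sqrt(eig$lambda * 0.8) * rnorm(n)))
      yr <- g + rnorm(n, 0, sqrt(0.2))
      cov(yr[sib1], yr[sib2])
    })
  })
  # theoretical sib covariance = sigma_g^2 * 2 * phi_sib = 0.8 * 0.5
  se <- sd(cors) / sqrt(length(cors))
  expect_lt(abs(mean(cors) - 0.4), 3 * se)
})

test_that("run_scenario writes a complete, re-parseable study", {
  dir <- withr::local_tempdir()
  cfg <- scenario_config(n_families = 15L, n_regions = 8L, seed = 90L)
  st <- run_scenario(cfg, file.path(dir, "study"))
  paths <- attr(st, "paths")
  expect_true(all(file.exists(paths)))

  expect_no_warning({
    ped <- read_pedigree(paths["pedigree"])
    man <- read_probe_manifest(paths["manifest"])
    ann <- read_annotation(paths["annotation"], "gtf")
    pre <- read_methylation(paths["methylation_pre"], "pre")
    post <- read_methylation(paths["methylation_post"], "post")
    ph <- read_phenotypes(paths["phenotypes"])
  })
  expect_equal(nrow(ped), nrow(st$pedigree))
  expect_equal(man$probe_id, sort(st$manifest$probe_id))
  expect_setequal(ann$gene_id, st$annotation$gene_id)
  expect_equal(dim(pre), dim(st$pre))
  expect_equal(unclass(pre), unclass(st$pre), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(ph$sample_id, st$phenotypes$sample_id)

  # refuses to clobber without force
  expect_error(run_scenario(cfg, file.path(dir, "study")),
               class = "methregion_output_exists")
  expect_no_error(run_scenario(cfg, file.path(dir, "study"), force = TRUE))

  # same seed -> identical file content
  st2 <- run_scenario(cfg, file.path(dir, "study2"))
  for (f in names(paths)) {
    expect_identical(readLines(paths[[f]]),
                     readLines(attr(st2, "paths")[[f]]),
                     info = f)
  }
})
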