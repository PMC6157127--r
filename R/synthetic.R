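# Synthetic family-cohort generator. The generator emulates the design the
# region tests were built for: families with known kinship, beta-valued CpG
# methylation measured pre- and post-treatment, Table-1-scale covariates and
# lipids, a polygenic (kinship-structured) outcome, and optional region-level
# effects with concordant or opposing per-CpG signs.

#' Scenario configuration for the synthetic cohort generator
#'
#' @param n_families Number of families (default 139, the study scale).
#' @param family_structure `"mix"` (mix of trios and two-child nuclear
#'   families averaging ~3.2 members), `"trio"`, `"nuclear4"` or
#'   `"threegen"` (three-generation, 6 members).
#' @param n_regions Number of gene regions.
#' @param cpgs_per_region Integer range (length 2) of CpGs per region.
#' @param h2 Narrow-sense heritability of the outcome's random part.
#' @param random_sd Total standard deviation of the outcome's random part
#'   (polygenic + residual), log-ratio scale.
#' @param scenario `"null"`, `"concordant"`, `"opposing"` or
#'   `"sparse_change"`.
#' @param tau Per-CpG effect size on the outcome (log-ratio units per unit
#'   methylation change) for causal regions.
#' @param fraction_causal Fraction of regions carrying effects (ignored for
#'   `"null"`).
#' @param fraction_changed Fraction of CpGs per region receiving a treatment
#'   shift under `"sparse_change"`.
#' @param shift_sd SD of per-CpG treatment shifts on the latent logit scale
#'   (default 0.15; 0.3 under `"sparse_change"`, where the changed CpGs
#'   represent strong responders whose dosage frequencies separate from the
#'   unchanged background).
#' @param noise_sd SD of per-(sample, CpG) measurement noise between
#'   timepoints (latent scale).
#' @param batch_sd Under `"sparse_change"` only: SD of shared batch offsets
#'   added to the unchanged CpGs' changes and to the outcome, emulating the
#'   unmodelled technical confounding that inflates an unweighted set test.
#' @param n_batches Number of batches under `"sparse_change"`.
#' @param alpha Named fixed-effect sizes for the covariates.
#' @param outcome Which lipid carries the modelled outcome (`"tg"` or
#'   `"hdl"`); the other is generated as covariates-plus-noise only.
#' @param seed Mandatory integer seed.
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(n_families = 139L,
                            family_structure = c("mix", "trio", "nuclear4", "threegen"),
                            n_regions = 100L,
                            cpgs_per_region = c(2L, 15L),
                            h2 = 0.3,
                            random_sd = 0.4,
                            scenario = c("null", "concordant", "opposing", "sparse_change"),
                            tau = 0,
                            fraction_causal = 0.3,
                            fraction_changed = 0.2,
                            shift_sd = NULL,
                            noise_sd = 0.12,
                            batch_sd = 0.15,
                            n_batches = 40L,
                            alpha = c(intercept = 0.35, age = 0.003, sex = -0.05,
                                      center = 0.02, metabolic_syndrome = 0.08,
                                      smoking_past = 0.03, smoking_current = 0.06),
                            outcome = c("tg", "hdl"),
                            seed) {
  if (missing(seed)) {
    stop_methregion("`seed` is mandatory in scenario_config().",
                    "methregion_bad_argument")
  }
  if (h2 < 0 || h2 >= 1) {
    stop_methregion("`h2` must lie in [0, 1).", "methregion_bad_argument")
  }
  if (fraction_causal < 0 || fraction_causal > 1 ||
      fraction_changed < 0 || fraction_changed > 1) {
    stop_methregion("Causal/changed fractions must lie in [0, 1].",
                    "methregion_bad_argument")
  }
  scenario <- match.arg(scenario)
  if (is.null(shift_sd)) {
    shift_sd <- if (scenario == "sparse_change") 0.3 else 0.15
  }
  structure(list(
    n_families = as.integer(n_families),
    family_structure = match.arg(family_structure),
    n_regions = as.integer(n_regions),
    cpgs_per_region = as.integer(cpgs_per_region),
    h2 = h2, random_sd = random_sd,
    scenario = scenario,
    tau = tau, fraction_causal = fraction_causal,
    fraction_changed = fraction_changed,
    shift_sd = shift_sd, noise_sd = noise_sd,
    batch_sd = batch_sd, n_batches = as.integer(n_batches),
    alpha = alpha,
    outcome = match.arg(outcome),
    seed = as.integer(seed)
  ), class = "scenario_config")
}

# Run `expr` under a derived seed, restoring the RNG state afterwards so the
# generator's component streams are independently reproducible.
with_derived_seed <- function(seed, offset, expr) {
  derived <- (as.double(seed) * 7 + offset) %% 2147483629
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(derived))
  force(expr)
}

#' Simulate pedigrees and their kinship matrix
#'
#' @param cfg A [scenario_config()].
#' @return A list with `pedigree` (tibble) and `kinship`
#'   (`kinship_matrix` from [kinship()]).
#' @export
simulate_pedigrees <- function(cfg) {
  ped <- with_derived_seed(cfg$seed, 1L, {
    fams <- lapply(seq_len(cfg$n_families), function(f) {
      structure_f <- switch(cfg$family_structure,
        mix = if (runif(1) < 0.8) "trio" else "nuclear4",
        cfg$family_structure)
      make_family(sprintf("F%03d", f), structure_f)
    })
    dplyr::bind_rows(fams)
  })
  ped <- validate_pedigree(ped)
  list(pedigree = ped, kinship = kinship(ped))
}

make_family <- function(fid, structure) {
  id <- function(k) sprintf("%s_I%02d", fid, k)
  kid_sex <- function(n) sample(c(1L, 2L), n, replace = TRUE)
  base <- switch(structure,
    trio = tibble(
      individual_id = id(1:3),
      father_id = c(NA, NA, id(1)),
      mother_id = c(NA, NA, id(2)),
      sex = c(1L, 2L, kid_sex(1))),
    nuclear4 = tibble(
      individual_id = id(1:4),
      father_id = c(NA, NA, id(1), id(1)),
      mother_id = c(NA, NA, id(2), id(2)),
      sex = c(1L, 2L, kid_sex(2))),
    threegen = tibble(
      individual_id = id(1:6),
      father_id = c(NA, NA, id(1), NA, id(3), id(3)),
      mother_id = c(NA, NA, id(2), NA, id(4), id(4)),
      sex = c(1L, 2L, 1L, 2L, kid_sex(2)))
  )
  dplyr::bind_cols(tibble(family_id = fid), base)
}

#' Simulate a toy annotation and probe manifest
#'
#' Genes are placed on one chromosome, spaced so that +/-100 kb regions do
#' not overlap; each gene gets a uniform number of CpGs inside its region.
#'
#' @param cfg A [scenario_config()].
#' @return A list with `annotation` (tibble as from [read_annotation()]) and
#'   `manifest` (probe tibble).
#' @export
simulate_annotation <- function(cfg) {
  with_derived_seed(cfg$seed, 2L, {
    spacing <- 250000L
    tss <- 150000L + (seq_len(cfg$n_regions) - 1L) * spacing
    annotation <- tibble(
      gene_id = sprintf("G%04d", seq_len(cfg$n_regions)),
      chrom = "chr1",
      strand = rep(c("+", "-"), length.out = cfg$n_regions),
      tss_list = as.list(tss)
    )
    n_cpg <- sample(seq(cfg$cpgs_per_region[1], cfg$cpgs_per_region[2]),
                    cfg$n_regions, replace = TRUE)
    manifest <- dplyr::bind_rows(lapply(seq_len(cfg$n_regions), function(i) {
      pos <- sort(sample(seq(tss[i] - 90000L, tss[i] + 90000L), n_cpg[i]))
      tibble(probe_id = sprintf("cg_%s_%02d", annotation$gene_id[i], seq_len(n_cpg[i])),
             chrom = "chr1", pos = pos,
             snp_flag = FALSE, crossreactive_flag = FALSE)
    }))
    list(annotation = annotation, manifest = manifest)
  })
}

#' Simulate pre/post methylation matrices
#'
#' Beta values follow a logit-normal model: a region-level mean plus per-CpG
#' offset plus individual noise on the logit scale, pushed through the
#' inverse logit. Post-treatment values add a per-CpG treatment shift and
#' per-(sample, CpG) noise on the same latent scale. Under
#' `"sparse_change"` only a `fraction_changed` subset of each region's CpGs
#' receives a shift, the remaining CpGs change only through shared batch
#' offsets.
#'
#' @param cfg A [scenario_config()].
#' @param sample_ids Sample ids (from the simulated pedigree).
#' @param manifest Probe manifest from [simulate_annotation()].
#' @return A list with `pre` and `post` (`meth_matrix`), `changed` (logical
#'   per probe: carries a treatment shift), `batch` (integer per sample or
#'   `NULL`), `batch_loadings` (per probe) and `shift` (per probe).
#' @export
simulate_methylation <- function(cfg, sample_ids, manifest) {
  with_derived_seed(cfg$seed, 3L, {
    n <- length(sample_ids)
    m <- nrow(manifest)
    gene_of <- sub("^cg_(G[0-9]+)_.*$", "\\1", manifest$probe_id)
    genes <- unique(gene_of)
    region_mu <- setNames(rnorm(length(genes), 0, 1), genes)
    cpg_mu <- region_mu[gene_of] + rnorm(m, 0, 0.5)
    latent_pre <- matrix(rnorm(n * m, 0, 0.3), n, m) +
      matrix(cpg_mu, n, m, byrow = TRUE)
    sparse <- cfg$scenario == "sparse_change"
    changed <- rep(TRUE, m)
    if (sparse) {
      changed <- rep(FALSE, m)
      for (ix in split(seq_len(m), gene_of)) {
        n_ch <- max(1L, round(cfg$fraction_changed * length(ix)))
        changed[ix[sample.int(length(ix), n_ch)]] <- TRUE
      }
    }
    shift <- ifelse(changed, rnorm(m, 0, cfg$shift_sd), 0)
    noise <- matrix(rnorm(n * m, 0, cfg$noise_sd), n, m)
    batch <- NULL
    batch_load <- rep(0, m)
    batch_mat <- 0
    if (sparse) {
      batch <- sample.int(cfg$n_batches, n, replace = TRUE)
      batch_load <- ifelse(changed, 0, 1)
      batch_off <- matrix(rnorm(cfg$n_batches * m, 0, cfg$batch_sd),
                          cfg$n_batches, m)
      batch_mat <- batch_off[batch, , drop = FALSE] *
        matrix(batch_load, n, m, byrow = TRUE)
    }
    latent_post <- latent_pre + matrix(shift, n, m, byrow = TRUE) + noise + batch_mat
    pre <- stats::plogis(latent_pre)
    post <- stats::plogis(latent_post)
    dimnames(pre) <- dimnames(post) <- list(sample_ids, manifest$probe_id)
    list(pre = meth_matrix(pre, "pre"),
         post = meth_matrix(post, "post"),
         changed = setNames(changed, manifest$probe_id),
         batch = batch,
         batch_loadings = setNames(batch_load, manifest$probe_id),
         shift = setNames(shift, manifest$probe_id))
  })
}

#' Simulate covariates, lipid levels and the model outcome
#'
#' Covariate marginals are calibrated to the study's descriptive table (age
#' 47 +/- 16 years, ~52% women, ~55% Utah, 40% metabolic syndrome, smoking
#' 71/22/7%). The outcome is
#' `y = X alpha + sum_causal tau_j * delta_j + b + g + eps` with
#' `g ~ N(0, sigma_g^2 2Phi)` polygenic, `eps` iid, and `b` a batch offset
#' under `"sparse_change"` only. Raw lipids are back-constructed so that the
#' signed log-ratio of the chosen lipid reproduces `y` exactly:
#' `pre ~ lognormal`, `post = pre * exp(-y)`.
#'
#' @param cfg A [scenario_config()].
#' @param ped Pedigree tibble.
#' @param kin `kinship_matrix` for the pedigree.
#' @param meth Methylation list from [simulate_methylation()].
#' @return A list with `phenotypes` (tibble), `truth` (components of the
#'   outcome and the injected effects) and `y` (the modelled outcome).
#' @export
simulate_phenotypes <- function(cfg, ped, kin, meth) {
  with_derived_seed(cfg$seed, 4L, {
    n <- nrow(ped)
    ids <- ped$individual_id
    fam_center <- setNames(rbinom(length(unique(ped$family_id)), 1, 0.549),
                           unique(ped$family_id))
    ph <- tibble(
      sample_id = ids,
      age = rnorm(n, 47, 16),
      sex = as.integer(ped$sex == 2L),
      center = as.integer(fam_center[ped$family_id]),
      metabolic_syndrome = rbinom(n, 1, 0.401),
      smoking = sample(c("never", "past", "current"), n, replace = TRUE,
                       prob = c(0.709, 0.224, 0.067))
    )
    X <- covariate_design(ph)
    fixed <- drop(X %*% cfg$alpha[colnames(X)])

    sigma_tot2 <- cfg$random_sd^2
    sigma_g2 <- cfg$h2 * sigma_tot2
    sigma_e2 <- (1 - cfg$h2) * sigma_tot2
    eig <- kinship_eigen(kinship_subset(kin, ids))
    g <- drop(eig$U %*% (sqrt(pmax(eig$lambda, 0) * sigma_g2) * rnorm(n)))
    eps <- rnorm(n, 0, sqrt(sigma_e2))

    batch_y <- rep(0, n)
    if (cfg$scenario == "sparse_change" && !is.null(meth$batch)) {
      b_off <- rnorm(cfg$n_batches, 0, cfg$batch_sd)
      batch_y <- b_off[meth$batch]
    }

    delta <- delta_methylation(meth$pre, meth$post)[ids, , drop = FALSE]
    causal <- causal_effects(cfg, meth)
    causal_part <- rep(0, n)
    region_parts <- list()
    if (nrow(causal) > 0L) {
      for (gene in unique(causal$gene)) {
        rows <- causal[causal$gene == gene, ]
        contrib <- drop(delta[, rows$probe_id, drop = FALSE] %*% rows$tau)
        region_parts[[gene]] <- contrib
        causal_part <- causal_part + contrib
      }
    }
    y <- fixed + causal_part + batch_y + g + eps

    lipid_pre <- if (cfg$outcome == "tg") {
      exp(rnorm(n, log(140), 0.3))
    } else {
      exp(rnorm(n, log(50), 0.2))
    }
    lipid_post <- lipid_pre * exp(-y)
    other_pre <- if (cfg$outcome == "tg") exp(rnorm(n, log(50), 0.2))
                 else exp(rnorm(n, log(140), 0.3))
    other_post <- other_pre * exp(-rnorm(n, 0.05, 0.1))
    if (cfg$outcome == "tg") {
      ph$tg_pre <- lipid_pre; ph$tg_post <- lipid_post
      ph$hdl_pre <- other_pre; ph$hdl_post <- other_post
    } else {
      ph$hdl_pre <- lipid_pre; ph$hdl_post <- lipid_post
      ph$tg_pre <- other_pre; ph$tg_post <- other_post
    }
    truth <- list(
      scenario = cfg$scenario,
      causal = causal,
      causal_genes = unique(causal$gene),
      components = list(fixed = fixed, causal = causal_part,
                        batch = batch_y, polygenic = g, residual = eps),
      region_contributions = region_parts,
      sigma_g2 = sigma_g2, sigma_e2 = sigma_e2,
      y = y
    )
    list(phenotypes = validate_phenotypes(ph), truth = truth, y = y)
  })
}

# Which CpGs carry outcome effects, with which sign pattern.
causal_effects <- function(cfg, meth) {
  empty <- tibble(gene = character(), probe_id = character(), tau = numeric())
  if (cfg$scenario == "null" || cfg$tau == 0) return(empty)
  probe_ids <- names(meth$changed)
  gene_of <- sub("^cg_(G[0-9]+)_.*$", "\\1", probe_ids)
  genes <- unique(gene_of)
  n_causal <- round(cfg$fraction_causal * length(genes))
  if (n_causal == 0L) return(empty)
  causal_genes <- genes[seq_len(n_causal)]
  rows <- lapply(causal_genes, function(g) {
    probes <- probe_ids[gene_of == g & meth$changed]
    if (length(probes) == 0L) return(NULL)
    tau <- switch(cfg$scenario,
      concordant = rep(cfg$tau, length(probes)),
      opposing = cfg$tau * (-1)^(seq_along(probes) - 1L),
      sparse_change = rep(cfg$tau, length(probes)))
    tibble(gene = g, probe_id = probes, tau = tau)
  })
  dplyr::bind_rows(rows)
}

#' Simulate a complete synthetic study in memory
#'
#' @param cfg A [scenario_config()].
#' @return A list of class `synthetic_study`: `config`, `pedigree`,
#'   `kinship`, `annotation`, `manifest`, `pre`, `post`, `phenotypes`, `y`
#'   (modelled outcome) and `truth`.
#' @export
simulate_study <- function(cfg) {
  peds <- simulate_pedigrees(cfg)
  ann <- simulate_annotation(cfg)
  meth <- simulate_methylation(cfg, peds$pedigree$individual_id, ann$manifest)
  phen <- simulate_phenotypes(cfg, peds$pedigree, peds$kinship, meth)
  structure(list(
    config = cfg,
    pedigree = peds$pedigree, kinship = peds$kinship,
    annotation = ann$annotation, manifest = ann$manifest,
    pre = meth$pre, post = meth$post,
    methylation_truth = meth[c("changed", "batch", "batch_loadings", "shift")],
    phenotypes = phen$phenotypes, y = phen$y, truth = phen$truth
  ), class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study> %d individuals / %d families, %d regions, %d CpGs, scenario '%s'\n",
              nrow(x$pedigree), length(unique(x$pedigree$family_id)),
              nrow(x$annotation), nrow(x$manifest), x$config$scenario))
  invisible(x)
}

#' Write a synthetic study to disk in the pipeline's file formats
#'
#' Writes `pedigree.fam`, `manifest.tsv`, `annotation.gtf`,
#' `methylation_pre.tsv`, `methylation_post.tsv`, `phenotypes.tsv` and
#' `truth.json` into `dir`.
#'
#' @param cfg A [scenario_config()] (or a ready [simulate_study()] result).
#' @param dir Output directory.
#' @param force Overwrite an existing non-empty directory?
#' @return The `synthetic_study`, invisibly; file paths in attribute
#'   `"paths"`.
#' @export
run_scenario <- function(cfg, dir, force = FALSE) {
  study <- if (inherits(cfg, "synthetic_study")) cfg else simulate_study(cfg)
  if (dir.exists(dir) && length(list.files(dir)) > 0L && !force) {
    stop_methregion(sprintf("Output directory '%s' exists and is not empty; use force = TRUE.", dir),
                    "methregion_output_exists")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    pedigree = file.path(dir, "pedigree.fam"),
    manifest = file.path(dir, "manifest.tsv"),
    annotation = file.path(dir, "annotation.gtf"),
    methylation_pre = file.path(dir, "methylation_pre.tsv"),
    methylation_post = file.path(dir, "methylation_post.tsv"),
    phenotypes = file.path(dir, "phenotypes.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_pedigree(study$pedigree, paths["pedigree"])
  write_probe_manifest(study$manifest, paths["manifest"])
  write_annotation_gtf(study$annotation, paths["annotation"])
  write_methylation(study$pre, paths["methylation_pre"])
  write_methylation(study$post, paths["methylation_post"])
  write_phenotypes(study$phenotypes, paths["phenotypes"])
  truth_out <- list(
    scenario = study$config$scenario,
    seed = study$config$seed,
    tau = study$config$tau,
    causal = study$truth$causal,
    sigma_g2 = study$truth$sigma_g2,
    sigma_e2 = study$truth$sigma_e2
  )
  jsonlite::write_json(truth_out, paths["truth"], auto_unbox = TRUE,
                       digits = NA)
  attr(study, "paths") <- paths
  invisible(study)
}

# GTF writer for the toy annotation: one transcript feature per TSS.
write_annotation_gtf <- function(annotation, path) {
  lines <- unlist(lapply(seq_len(nrow(annotation)), function(i) {
    g <- annotation[i, ]
    vapply(g$tss_list[[1]], function(tss) {
      start <- if (g$strand == "+") tss else tss - 1000L
      end <- if (g$strand == "+") tss + 1000L else tss
      sprintf("%s\tsynthetic\ttranscript\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s.t%d\";",
              g$chrom, start, end, g$strand, g$gene_id, g$gene_id,
              match(tss, g$tss_list[[1]]))
    }, character(1))
  }))
  writeLines(lines, path)
  invisible(path)
}
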