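#' Pipeline configuration
#'
#' Collects paths and analysis settings for [run_pipeline()]. Either the
#' file paths or an in-memory `synthetic_study` (argument `study`) must be
#' supplied.
#'
#' @param pedigree,manifest,annotation,methylation_pre,methylation_post,phenotypes
#'   Input file paths (see the `io` readers).
#' @param annotation_format `"gtf"` or `"bed"`.
#' @param study Optional `synthetic_study`; when given, file paths are
#'   ignored.
#' @param snp_exclude,crossreactive_exclude Character vectors of probe ids to
#'   drop at QC.
#' @param flank Region flank in basepairs (default 100 kb).
#' @param outcome `"tg"` or `"hdl"`.
#' @param methods Subset of `c("mmlt", "skat", "skat_weighted")`.
#' @param beta_a,beta_b Dosage-weight Beta parameters.
#' @param n_pcs Principal components per timepoint (0 disables the PC step).
#' @param screen_alpha Marginal screening threshold for PC selection.
#' @param fdr_threshold Benjamini-Hochberg significance threshold.
#' @param orientation Change orientation, see [delta_methylation()].
#' @param seed Seed recorded in the run manifest (the pipeline itself is
#'   deterministic).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(pedigree = NULL, manifest = NULL, annotation = NULL,
                            methylation_pre = NULL, methylation_post = NULL,
                            phenotypes = NULL, annotation_format = "gtf",
                            study = NULL,
                            snp_exclude = character(),
                            crossreactive_exclude = character(),
                            flank = 100000L,
                            outcome = c("tg", "hdl"),
                            methods = c("mmlt", "skat", "skat_weighted"),
                            beta_a = 1, beta_b = 25,
                            n_pcs = 20L, screen_alpha = 0.05,
                            fdr_threshold = 0.05,
                            orientation = "pre_minus_post",
                            seed = 1L) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (fdr_threshold <= 0 || fdr_threshold >= 1) {
    stop_methregion("`fdr_threshold` must lie in (0, 1).", "methregion_bad_argument")
  }
  structure(list(
    pedigree = pedigree, manifest = manifest, annotation = annotation,
    annotation_format = annotation_format,
    methylation_pre = methylation_pre, methylation_post = methylation_post,
    phenotypes = phenotypes, study = study,
    snp_exclude = snp_exclude, crossreactive_exclude = crossreactive_exclude,
    flank = flank, outcome = match.arg(outcome), methods = methods,
    beta_a = beta_a, beta_b = beta_b,
    n_pcs = as.integer(n_pcs), screen_alpha = screen_alpha,
    fdr_threshold = fdr_threshold,
    orientation = check_orientation(orientation), seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Run the full region-based methylation association pipeline
#'
#' Executes probe QC, region building and probe mapping, pre/post change
#' computation, principal-component screening, the REML kinship null model,
#' the requested region tests (MMLT, unweighted SKAT, dosage-weighted SKAT),
#' BH-FDR, and QQ/genomic-control diagnostics. A run manifest records the
#' configuration hash, seed and row counts at every stage so no record is
#' lost silently.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory; when given, writes
#'   `results.tsv`, `qq_overall.tsv`, `qq_by_ncpg.tsv` and
#'   `run_manifest.json`.
#' @return A list of class `pipeline_result`: `results` (tibble with q
#'   values, sorted by p within method), `qq_overall`, `qq_by_ncpg`,
#'   `fit` (`kin_lmm`), `filter_report`, `audit` (stage row counts) and
#'   `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(what) inform(sprintf("[methregion] %s", what))

  stage("reading inputs")
  if (!is.null(config$study)) {
    st <- config$study
    ped <- st$pedigree; man <- st$manifest; ann <- st$annotation
    pre <- st$pre; post <- st$post; ph <- st$phenotypes
    kin <- st$kinship
  } else {
    ped <- read_pedigree(config$pedigree)
    man <- read_probe_manifest(config$manifest)
    ann <- read_annotation(config$annotation, config$annotation_format)
    pre <- read_methylation(config$methylation_pre, "pre")
    post <- read_methylation(config$methylation_post, "post")
    ph <- read_phenotypes(config$phenotypes)
    kin <- kinship(ped)
  }

  stage("probe QC")
  flt <- filter_probes(man, config$snp_exclude, config$crossreactive_exclude)

  stage("building regions")
  regions <- build_regions(ann, flank = config$flank)
  rmap <- map_probes(regions, flt$manifest)

  stage("methylation changes")
  delta <- delta_methylation(pre, post, config$orientation)
  med_change <- region_median_change(pre, post, rmap, config$orientation)

  stage("outcome and covariates")
  ids <- ph$sample_id
  y <- if (config$outcome == "tg") {
    log_change(ph$tg_pre, ph$tg_post, config$orientation)
  } else {
    log_change(ph$hdl_pre, ph$hdl_post, config$orientation)
  }
  names(y) <- ids
  pc_selected <- integer(0)
  pcs <- NULL
  if (config$n_pcs > 0L) {
    k <- min(config$n_pcs, nrow(unclass(pre)) - 1L)
    pcs_pre <- compute_pcs(pre, k)
    pcs_post <- compute_pcs(post, k)
    colnames(pcs_pre) <- paste0("pre_", seq_len(ncol(pcs_pre)))
    colnames(pcs_post) <- paste0("post_", seq_len(ncol(pcs_post)))
    pcs <- cbind(pcs_pre[ids, , drop = FALSE], pcs_post[ids, , drop = FALSE])
    pc_selected <- screen_pcs(pcs, y, alpha = config$screen_alpha)
  }
  X <- covariate_design(ph, pcs = pcs, pc_cols = pc_selected)

  stage("null mixed model")
  eig <- kinship_eigen(kinship_subset(kin, ids))
  fit <- fit_null(y, X, eig)

  stage("region tests")
  res_list <- list()
  delta_aligned <- delta[ids, , drop = FALSE]
  med_aligned <- med_change[ids, , drop = FALSE]
  if ("mmlt" %in% config$methods) {
    res_list$mmlt <- mmlt(y, X, eig, med_aligned, region_map = rmap)
  }
  if ("skat" %in% config$methods) {
    res_list$skat <- skat_region_all(fit, delta_aligned, rmap, weights = "unit")
  }
  if ("skat_weighted" %in% config$methods) {
    res_list$skat_w <- skat_region_all(fit, delta_aligned, rmap,
                                       weights = "beta_dosage",
                                       beta_a = config$beta_a,
                                       beta_b = config$beta_b)
  }
  results <- dplyr::bind_rows(res_list)
  results <- add_bh_q(results)
  results <- dplyr::arrange(results, .data$method, .data$p)

  stage("diagnostics")
  qq_overall <- dplyr::bind_rows(lapply(split(results, results$method), function(r) {
    s <- qq_summary(r)
    s$method <- r$method[1]
    s
  }))
  qq_strat <- tryCatch(
    dplyr::bind_rows(lapply(split(results, results$method), function(r) {
      s <- suppressWarnings(qq_summary(r, stratify_by_ncpg = TRUE))
      s$method <- r$method[1]
      s
    })),
    error = function(e) NULL
  )

  audit <- tibble(
    stage = c("samples", "probes_input", "probes_removed_qc", "probes_retained",
              "probes_mapped", "regions_total", "regions_testable",
              "regions_untestable", "results_rows", "results_na_p"),
    n = c(length(ids), flt$report$n_input, flt$report$n_removed,
          flt$report$n_retained,
          length(unique(rmap$probe_to_genes$probe_id)),
          nrow(rmap$regions), sum(rmap$regions$testable),
          sum(!rmap$regions$testable), nrow(results), sum(is.na(results$p)))
  )
  manifest <- list(
    package_version = as.character(utils::packageVersion("methregion")),
    seed = config$seed,
    outcome = config$outcome,
    methods = config$methods,
    orientation = config$orientation,
    flank = config$flank,
    fdr_threshold = config$fdr_threshold,
    pc_selected = pc_selected,
    config_hash = rlang::hash(config[setdiff(names(config), "study")]),
    counts = setNames(as.list(audit$n), audit$stage)
  )
  out <- structure(list(results = results, qq_overall = qq_overall,
                        qq_by_ncpg = qq_strat, fit = fit,
                        filter_report = flt$report, audit = audit,
                        manifest = manifest),
                   class = "pipeline_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_results(results, file.path(out_dir, "results.tsv"))
    readr::write_tsv(as_tibble(qq_overall), file.path(out_dir, "qq_overall.tsv"),
                     progress = FALSE)
    if (!is.null(qq_strat)) {
      readr::write_tsv(as_tibble(qq_strat), file.path(out_dir, "qq_by_ncpg.tsv"),
                       progress = FALSE)
    }
    jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d result rows (%d regions x %d method(s))\n",
              nrow(x$results), length(unique(x$results$gene)),
              length(unique(x$results$method))))
  lam <- unique(x$qq_overall[, c("method", "lambda_gc")])
  for (i in seq_len(nrow(lam))) {
    cat(sprintf("  lambda_GC[%s] = %.3f\n", lam$method[i], lam$lambda_gc[i]))
  }
  invisible(x)
}
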