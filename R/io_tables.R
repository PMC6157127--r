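#' Read a CpG probe manifest
#'
#' A delimited text file with a header and columns `probe_id`, `chrom`, `pos`
#' (1-based basepair) and optionally logical flags `snp_flag` and
#' `crossreactive_flag` (missing flag columns default to `FALSE`).
#'
#' @param path Path to the manifest file.
#' @return A tibble sorted by `(chrom, pos)` with columns `probe_id`, `chrom`,
#'   `pos`, `snp_flag`, `crossreactive_flag`.
#' @export
read_probe_manifest <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  req <- c("probe_id", "chrom", "pos")
  if (!all(req %in% names(raw))) {
    stop_methregion(sprintf("Manifest must have columns %s.", paste(req, collapse = ", ")),
                    "methregion_io_error")
  }
  pos_num <- suppressWarnings(as.numeric(raw$pos))
  bad <- is.na(pos_num) | pos_num != floor(pos_num)
  if (any(bad)) {
    stop_methregion(
      sprintf("Non-integer probe position at line(s): %s",
              paste(which(bad) + 1L, collapse = ", ")),  # +1 for header
      "methregion_io_error")
  }
  man <- tibble(
    probe_id = raw$probe_id,
    chrom = raw$chrom,
    pos = as.integer(pos_num),
    snp_flag = parse_flag(raw[["snp_flag"]], nrow(raw)),
    crossreactive_flag = parse_flag(raw[["crossreactive_flag"]], nrow(raw))
  )
  validate_probe_manifest(man)
  dplyr::arrange(man, .data$chrom, .data$pos)
}

parse_flag <- function(x, n) {
  if (is.null(x)) return(rep(FALSE, n))
  tolower(x) %in% c("true", "t", "1", "yes")
}

validate_probe_manifest <- function(man) {
  dup <- man$probe_id[duplicated(man$probe_id)]
  if (length(dup) > 0L) {
    stop_methregion(sprintf("Duplicate probe id(s): %s", paste(unique(dup), collapse = ", ")),
                    "methregion_io_error")
  }
  if (any(man$pos < 1L)) {
    stop_methregion("Probe positions must be >= 1 (1-based coordinates).",
                    "methregion_io_error")
  }
  if (any(!nzchar(man$chrom))) {
    stop_methregion("Empty chromosome name in manifest.", "methregion_io_error")
  }
  invisible(man)
}

#' Write a probe manifest
#' @param man Manifest tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_probe_manifest <- function(man, path) {
  readr::write_tsv(man, path, progress = FALSE)
  invisible(path)
}

#' Read gene annotation (GTF or BED) into per-gene TSS lists
#'
#' Transcript start sites are strand-aware: the start coordinate of a `+`
#' strand transcript and the end coordinate of a `-` strand transcript.
#' Duplicate TSS positions within a gene are collapsed. GTF is read natively
#' (1-based); BED starts are converted to 1-based on read.
#'
#' @param path Path to the annotation file.
#' @param format `"gtf"` or `"bed"`. BED files use the name column as the
#'   gene id.
#' @return A tibble with columns `gene_id`, `chrom`, `strand` and a
#'   list-column `tss_list` of sorted unique 1-based TSS positions.
#' @export
read_annotation <- function(path, format = c("gtf", "bed")) {
  format <- match.arg(format)
  gr <- rtracklayer::import(path, format = format)
  if (format == "gtf") {
    type <- as.character(gr$type)
    if (any(type == "transcript")) gr <- gr[type == "transcript"]
    gene_id <- gr$gene_id
    if (is.null(gene_id)) {
      stop_methregion("GTF transcripts must carry a gene_id attribute.",
                      "methregion_io_error")
    }
  } else {
    gene_id <- gr$name
    if (is.null(gene_id)) {
      stop_methregion("BED annotation must have a name column (gene id).",
                      "methregion_io_error")
    }
  }
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(!strand %in% c("+", "-"))) {
    stop_methregion("Unknown strand character in annotation (need + or -).",
                    "methregion_io_error")
  }
  # rtracklayer already yields 1-based starts for both formats.
  tss <- ifelse(strand == "+", BiocGenerics::start(gr), BiocGenerics::end(gr))
  ann <- tibble(
    gene_id = as.character(gene_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = strand,
    tss = as.integer(tss)
  )
  ann <- dplyr::summarise(
    dplyr::group_by(ann, .data$gene_id),
    chrom = .data$chrom[1L],
    strand = .data$strand[1L],
    tss_list = list(sort(unique(.data$tss))),
    .groups = "drop"
  )
  ann
}

#' Read a sample-by-probe methylation matrix
#'
#' Delimited text: one header row of probe ids, first column the sample id,
#' remaining columns beta values in `[0, 1]` (or `NA` for missing).
#'
#' @param path Path to the matrix file.
#' @param timepoint `"pre"` or `"post"`; stored as an attribute.
#' @return A numeric matrix (samples in rows, probes in columns) of class
#'   `meth_matrix` with a `timepoint` attribute.
#' @export
read_methylation <- function(path, timepoint = c("pre", "post")) {
  timepoint <- match.arg(timepoint)
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(raw[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(raw[[1L]])
  meth_matrix(m, timepoint = timepoint)
}

#' Construct and validate a methylation matrix
#'
#' @param beta Numeric matrix, samples in rows (rownames = sample ids),
#'   probes in columns (colnames = probe ids), values in `[0, 1]` or `NA`.
#' @param timepoint `"pre"` or `"post"`.
#' @return The matrix with class `meth_matrix`.
#' @export
meth_matrix <- function(beta, timepoint = c("pre", "post")) {
  timepoint <- match.arg(timepoint)
  if (is.null(rownames(beta)) || is.null(colnames(beta))) {
    stop_methregion("Methylation matrix needs sample rownames and probe colnames.",
                    "methregion_io_error")
  }
  bad <- !is.na(beta) & (beta < 0 | beta > 1)
  if (any(bad)) {
    off <- which(bad, arr.ind = TRUE)[1L, ]
    stop_methregion(
      sprintf("Beta value outside [0, 1] at sample %s, probe %s.",
              rownames(beta)[off[1L]], colnames(beta)[off[2L]]),
      "methregion_beta_range")
  }
  structure(beta, class = c("meth_matrix", class(beta)),
            timepoint = timepoint)
}

#' Write a methylation matrix
#' @param m `meth_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_methylation <- function(m, path) {
  df <- data.frame(sample_id = rownames(m), unclass(m), check.names = FALSE,
                   stringsAsFactors = FALSE)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Align two methylation matrices on shared sample ids
#'
#' Matrices may list samples in different orders; alignment is always by id.
#'
#' @param pre,post `meth_matrix` objects.
#' @return A list with elements `pre` and `post`, rows in identical order.
#' @export
align_samples <- function(pre, post) {
  if (!setequal(rownames(pre), rownames(post))) {
    off <- c(setdiff(rownames(pre), rownames(post)),
             setdiff(rownames(post), rownames(pre)))
    stop_methregion(
      sprintf("Sample id mismatch between matrices: %s", paste(off, collapse = ", ")),
      "methregion_sample_mismatch")
  }
  list(pre = pre, post = post[rownames(pre), , drop = FALSE])
}

#' Read a phenotype and covariate table
#'
#' Expects a delimited table with columns `sample_id`, `age`, `sex`, `center`,
#' `metabolic_syndrome`, `smoking` (`never`/`past`/`current`), `tg_pre`,
#' `tg_post`, `hdl_pre`, `hdl_post`. Lipid values must be strictly positive so
#' the log-ratio outcome is defined.
#'
#' @param path Path to the table.
#' @return A validated tibble.
#' @export
read_phenotypes <- function(path) {
  ph <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_phenotypes(ph)
}

#' Validate a phenotype table
#' @param ph Phenotype tibble (see [read_phenotypes()] for columns).
#' @return The validated tibble.
#' @export
validate_phenotypes <- function(ph) {
  req <- c("sample_id", "age", "sex", "center", "metabolic_syndrome",
           "smoking", "tg_pre", "tg_post", "hdl_pre", "hdl_post")
  miss <- setdiff(req, names(ph))
  if (length(miss) > 0L) {
    stop_methregion(sprintf("Phenotype table missing column(s): %s",
                            paste(miss, collapse = ", ")),
                    "methregion_io_error")
  }
  lipids <- c("tg_pre", "tg_post", "hdl_pre", "hdl_post")
  for (col in lipids) {
    if (any(!is.na(ph[[col]]) & ph[[col]] <= 0)) {
      stop_methregion(sprintf("Nonpositive value in `%s`; lipid levels must be > 0.", col),
                      "methregion_lipid_range")
    }
  }
  if (any(!ph$smoking %in% c("never", "past", "current"))) {
    stop_methregion("`smoking` must be one of never/past/current.",
                    "methregion_io_error")
  }
  as_tibble(ph)
}

#' Write a phenotype table
#' @param ph Phenotype tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(ph, path) {
  readr::write_tsv(ph, path, progress = FALSE)
  invisible(path)
}

#' Write region test results
#'
#' Emits a TSV with columns `gene`, `n_cpg`, `method`, `statistic`, `effect`,
#' `se`, `p`, `q` (the Q statistic for SKAT rows goes in `statistic`; MMLT
#' rows carry `effect`/`se`).
#'
#' @param results Results tibble from [mmlt()] / [skat_region_all()] after
#'   [add_bh_q()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  cols <- c("gene", "n_cpg", "method", "statistic", "effect", "se", "p", "q")
  out <- results
  for (col in setdiff(cols, names(out))) out[[col]] <- NA_real_
  readr::write_tsv(out[, cols], path, progress = FALSE)
  invisible(path)
}

#' Read region test results written by [write_results()]
#' @param path Path to the results TSV.
#' @return A tibble.
#' @export
read_results <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    gene = readr::col_character(),
                    n_cpg = readr::col_integer(),
                    method = readr::col_character(),
                    .default = readr::col_double()
                  ))
}
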