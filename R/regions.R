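#' Build gene regions from TSS lists
#'
#' A gene's region is the strand-independent hull of its transcript start
#' sites, extended by `flank` basepairs on each side:
#' `[min(TSS) - flank, max(TSS) + flank]`, clipped at position 1.
#'
#' @param annotation Annotation tibble from [read_annotation()].
#' @param flank Flanking distance in basepairs (default 100 kb).
#' @return A tibble with columns `gene_id`, `chrom`, `start`, `end`.
#' @export
build_regions <- function(annotation, flank = 100000L) {
  assert_scalar_number(flank, "flank")
  if (flank < 0) {
    stop_methregion("`flank` must be >= 0.", "methregion_bad_argument")
  }
  if (nrow(annotation) == 0L) {
    return(tibble(gene_id = character(), chrom = character(),
                  start = integer(), end = integer()))
  }
  tibble(
    gene_id = annotation$gene_id,
    chrom = annotation$chrom,
    start = pmax(1L, as.integer(purrr::map_int(annotation$tss_list, min) - flank)),
    end = as.integer(purrr::map_int(annotation$tss_list, max) + flank)
  )
}

#' Assign probes to gene regions
#'
#' Each QC-passed probe is assigned to every region whose interval contains
#' its position (1-based, inclusive at both ends, same chromosome). A probe
#' may belong to several overlapping regions. Regions without any probe are
#' retained and flagged untestable.
#'
#' @param regions Region tibble from [build_regions()].
#' @param manifest Probe manifest tibble (already QC-filtered).
#' @return A list of class `region_map` with elements
#'   \describe{
#'     \item{regions}{tibble `gene_id, chrom, start, end, n_cpg, testable`,
#'       plus a list-column `probe_ids` (probes sorted by position)}
#'     \item{probe_to_genes}{tibble `probe_id, gene_id` (one row per
#'       assignment)}
#'   }
#' @export
map_probes <- function(regions, manifest) {
  manifest <- dplyr::arrange(manifest, .data$chrom, .data$pos)
  shared <- intersect(unique(regions$chrom), unique(manifest$chrom))
  only_reg <- setdiff(unique(regions$chrom), shared)
  only_man <- setdiff(unique(manifest$chrom), shared)
  if (length(only_reg) > 0L || length(only_man) > 0L) {
    warn_methregion(
      sprintf("Chromosome mismatch: %d region chrom(s) and %d manifest chrom(s) unmatched.",
              length(only_reg), length(only_man)),
      "methregion_chrom_mismatch")
  }
  reg_gr <- GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(start = regions$start, end = regions$end)
  )
  probe_gr <- GenomicRanges::GRanges(
    seqnames = manifest$chrom,
    ranges = IRanges::IRanges(start = manifest$pos, width = 1L)
  )
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(probe_gr, reg_gr, type = "within")
  )
  assign_tbl <- tibble(
    probe_id = manifest$probe_id[S4Vectors::queryHits(hits)],
    gene_id = regions$gene_id[S4Vectors::subjectHits(hits)]
  )
  probes_by_gene <- split(assign_tbl$probe_id, assign_tbl$gene_id)
  out <- regions
  out$probe_ids <- unname(lapply(regions$gene_id, function(g) {
    p <- probes_by_gene[[g]]
    if (is.null(p)) character(0) else p
  }))
  out$n_cpg <- lengths(out$probe_ids)
  out$testable <- out$n_cpg > 0L
  structure(list(regions = out, probe_to_genes = assign_tbl),
            class = "region_map")
}

#' @export
print.region_map <- function(x, ...) {
  cat(sprintf("<region_map> %d regions (%d testable), %d probe assignments\n",
              nrow(x$regions), sum(x$regions$testable), nrow(x$probe_to_genes)))
  invisible(x)
}
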