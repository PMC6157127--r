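#' Genomic-control inflation factor
#'
#' `lambda_GC = median(qchisq(1 - p, df = 1)) / 0.4549364`: the median of the
#' p-values' implied 1-df chi-squares over the null median. Values above 1
#' indicate test-statistic inflation, below 1 deflation.
#'
#' @param p Vector of p-values in `(0, 1]`; `NA`s are dropped.
#' @return The scalar inflation factor.
#' @export
genomic_lambda <- function(p) {
  p <- p[!is.na(p)]
  if (length(p) == 0L) {
    stop_methregion("No p-values supplied.", "methregion_bad_argument")
  }
  chisq <- qchisq(p, df = 1, lower.tail = FALSE)
  median(chisq) / qchisq(0.5, df = 1)
}

#' QQ summary of region test results, optionally stratified by CpG count
#'
#' Sorted observed `-log10(p)` against expected uniform order statistics
#' (plotting positions `(i - 0.5) / m`), with a per-stratum genomic-control
#' factor. Stratification bins regions by the quartiles of their CpG counts
#' (breaks at the 25/50/75 percentiles, ties to the lower bin).
#'
#' @param results Tibble with columns `p` and (when stratifying) `n_cpg`.
#' @param stratify_by_ncpg Stratify into CpG-count quartile bins?
#' @return A tibble of class `qq_summary` with columns `stratum`, `expected`,
#'   `observed` (both `-log10` scale) and `lambda_gc` (repeated within
#'   stratum).
#' @export
qq_summary <- function(results, stratify_by_ncpg = FALSE) {
  res <- results[!is.na(results$p), , drop = FALSE]
  if (nrow(res) == 0L) {
    stop_methregion("No non-missing p-values.", "methregion_bad_argument")
  }
  if (!stratify_by_ncpg) {
    strata <- list(overall = res$p)
  } else {
    if (nrow(res) < 8L) {
      stop_methregion("Need at least 8 results to stratify by CpG-count quartile.",
                      "methregion_bad_argument")
    }
    br <- unique(stats::quantile(res$n_cpg, probs = c(0.25, 0.5, 0.75),
                                 type = 1))
    if (length(br) == 0L || length(unique(res$n_cpg)) == 1L) {
      warn_methregion("All CpG counts identical; single stratum returned.",
                      "methregion_single_stratum")
      strata <- list(`all n_cpg` = res$p)
    } else {
      bin <- findInterval(res$n_cpg, vec = br, left.open = TRUE) + 1L
      labs <- quartile_labels(br, max(res$n_cpg))
      strata <- split(res$p, labs[bin])
      strata <- strata[unique(labs[sort(unique(bin))])]  # keep bin order
    }
  }
  out <- purrr::imap(strata, function(pv, nm) {
    pv <- sort(pv)
    m <- length(pv)
    tibble(stratum = nm,
           expected = -log10((seq_len(m) - 0.5) / m),
           observed = -log10(pv),
           lambda_gc = genomic_lambda(pv))
  })
  out <- dplyr::bind_rows(out)
  out$stratum <- factor(out$stratum, levels = unique(out$stratum))
  class(out) <- c("qq_summary", class(out))
  out
}

quartile_labels <- function(breaks, max_n) {
  edges <- c(-Inf, breaks, Inf)
  n_bins <- length(breaks) + 1L
  vapply(seq_len(n_bins), function(i) {
    lo <- edges[i]; hi <- edges[i + 1L]
    if (!is.finite(lo)) sprintf("n_cpg <= %g", hi)
    else if (!is.finite(hi)) sprintf("n_cpg > %g", lo)
    else sprintf("%g < n_cpg <= %g", lo, hi)
  }, character(1))
}

#' QQ plot of region test p-values
#'
#' One panel per stratum, identity line, genomic-control factor annotated in
#' the panel label.
#'
#' @param object A `qq_summary` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot qq_summary
#' @export
autoplot.qq_summary <- function(object, ...) {
  df <- as_tibble(object)
  df$panel <- sprintf("%s  (lambda[GC] == %.3f)", df$stratum, df$lambda_gc)
  df$panel <- factor(df$panel, levels = unique(df$panel))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$expected, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = expression(Expected ~ -log[10](p)),
                  y = expression(Observed ~ -log[10](p))) +
    ggplot2::theme_bw()
}

#' @export
#' @importFrom ggplot2 autoplot
ggplot2::autoplot

#' Write a QQ plot to file
#'
#' @param summary A `qq_summary` tibble.
#' @param path Output path (extension selects the device, e.g. `.png`,
#'   `.pdf`).
#' @param width,height Plot size in inches.
#' @return `path`, invisibly.
#' @export
qq_plot <- function(summary, path, width = 7, height = 5) {
  plt <- autoplot.qq_summary(summary)
  suppressMessages(ggplot2::ggsave(path, plot = plt, width = width,
                                   height = height, dpi = 120))
  invisible(path)
}
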