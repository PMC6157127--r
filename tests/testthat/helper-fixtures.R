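# Small fixtures shared across test files, all built in code.

trio_pedigree <- function() {
  tibble::tibble(
    family_id = "F1",
    individual_id = c("dad", "mom", "kid"),
    father_id = c(NA, NA, "dad"),
    mother_id = c(NA, NA, "mom"),
    sex = c(1L, 2L, 1L)
  )
}

# Two parents, two full siblings, one grandchild (kid1 x in-law).
extended_pedigree <- function() {
  tibble::tibble(
    family_id = "F1",
    individual_id = c("gpa", "gma", "kid1", "kid2", "inlaw", "gkid"),
    father_id = c(NA, NA, "gpa", "gpa", NA, "kid1"),
    mother_id = c(NA, NA, "gma", "gma", NA, "inlaw"),
    sex = c(1L, 2L, 1L, 2L, 2L, 1L)
  )
}

# Identity-kinship fixture: unrelated singletons.
identity_kinship <- function(n, prefix = "s") {
  ids <- paste0(prefix, seq_len(n))
  A <- diag(n)
  dimnames(A) <- list(ids, ids)
  A
}

toy_manifest <- function(n = 10L, chrom = "chr1", start = 100L, by = 50L) {
  tibble::tibble(
    probe_id = sprintf("cg%03d", seq_len(n)),
    chrom = chrom,
    pos = as.integer(start + (seq_len(n) - 1L) * by),
    snp_flag = FALSE,
    crossreactive_flag = FALSE
  )
}

toy_meth_pair <- function(n_samples = 6L, n_probes = 10L, seed = 1L) {
  withr::with_seed(seed, {
    ids <- paste0("s", seq_len(n_samples))
    probes <- sprintf("cg%03d", seq_len(n_probes))
    pre <- matrix(runif(n_samples * n_probes, 0.1, 0.9), n_samples, n_probes,
                  dimnames = list(ids, probes))
    post <- pmin(pmax(pre + rnorm(n_samples * n_probes, 0, 0.05), 0), 1)
    dimnames(post) <- dimnames(pre)
    list(pre = meth_matrix(pre, "pre"), post = meth_matrix(post, "post"))
  })
}

write_gtf_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".gtf", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
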