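#' Read a PLINK-style pedigree file
#'
#' Reads a whitespace-delimited pedigree in the PLINK `.fam` dialect: one
#' individual per line with columns family id, individual id, father id,
#' mother id, sex (1 = male, 2 = female, anything else unknown). A parent id
#' of `"0"` means the parent is not in the study (founder side).
#'
#' @param path Path to the pedigree file.
#' @return A tibble with columns `family_id`, `individual_id`, `father_id`,
#'   `mother_id` (both `NA` for founders) and `sex` (integer, `NA` if
#'   unknown), validated for unique ids, resolvable parent links and acyclic
#'   parentage.
#' @export
read_pedigree <- function(path) {
  raw <- utils::read.table(path, header = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 5L) {
    stop_methregion("Pedigree file must have at least 5 columns (fam, id, father, mother, sex).",
                    "methregion_io_error")
  }
  ped <- tibble(
    family_id     = raw[[1L]],
    individual_id = raw[[2L]],
    father_id     = ifelse(raw[[3L]] == "0", NA_character_, raw[[3L]]),
    mother_id     = ifelse(raw[[4L]] == "0", NA_character_, raw[[4L]]),
    sex           = suppressWarnings(as.integer(raw[[5L]]))
  )
  ped$sex[!ped$sex %in% c(1L, 2L)] <- NA_integer_
  validate_pedigree(ped)
}

#' Validate a pedigree tibble
#'
#' Checks id uniqueness, parent resolvability (a non-missing parent id that
#' does not appear as an individual is re-coded as missing, with a warning:
#' the individual is treated as having a founder on that side), and that the
#' parentage graph is acyclic.
#'
#' @param ped A tibble with the columns produced by [read_pedigree()].
#' @return The validated tibble (invisibly modified: unresolvable parent ids
#'   replaced by `NA`).
#' @export
validate_pedigree <- function(ped) {
  stopifnot(all(c("family_id", "individual_id", "father_id", "mother_id", "sex")
                %in% names(ped)))
  dup <- ped$individual_id[duplicated(ped$individual_id)]
  if (length(dup) > 0L) {
    stop_methregion(
      sprintf("Duplicate individual id(s) in pedigree: %s",
              paste(unique(dup), collapse = ", ")),
      "methregion_pedigree_error")
  }
  ids <- ped$individual_id
  for (col in c("father_id", "mother_id")) {
    bad <- !is.na(ped[[col]]) & !(ped[[col]] %in% ids)
    if (any(bad)) {
      warn_methregion(
        sprintf("%d %s value(s) not present as individuals; treated as founders.",
                sum(bad), col),
        "methregion_unknown_parent")
      ped[[col]][bad] <- NA_character_
    }
  }
  # Parents must belong to the same family.
  fam_of <- setNames(ped$family_id, ped$individual_id)
  for (col in c("father_id", "mother_id")) {
    known <- !is.na(ped[[col]])
    mismatch <- known & fam_of[ped[[col]]] != ped$family_id
    if (any(mismatch)) {
      stop_methregion(
        sprintf("Parent(s) from a different family: %s",
                paste(ped$individual_id[mismatch], collapse = ", ")),
        "methregion_pedigree_error")
    }
  }
  pedigree_order(ped)  # errors on cycles
  as_tibble(ped)
}

# Topological order of a pedigree: parents before children. Errors on cycles
# (including an individual listed as its own ancestor).
pedigree_order <- function(ped) {
  ids <- ped$individual_id
  idx <- setNames(seq_along(ids), ids)
  father <- idx[ped$father_id]
  mother <- idx[ped$mother_id]
  n <- length(ids)
  placed <- logical(n)
  order_out <- integer(0)
  repeat {
    ready <- !placed &
      (is.na(father) | placed[ifelse(is.na(father), 1L, father)]) &
      (is.na(mother) | placed[ifelse(is.na(mother), 1L, mother)])
    if (!any(ready)) break
    order_out <- c(order_out, which(ready))
    placed[ready] <- TRUE
  }
  if (!all(placed)) {
    stop_methregion(
      sprintf("Cyclic parentage involving: %s",
              paste(ids[!placed], collapse = ", ")),
      "methregion_pedigree_cycle")
  }
  order_out
}

#' Write a pedigree to a PLINK-style file
#'
#' @param ped Pedigree tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  out <- data.frame(
    fam    = ped$family_id,
    id     = ped$individual_id,
    father = ifelse(is.na(ped$father_id), "0", ped$father_id),
    mother = ifelse(is.na(ped$mother_id), "0", ped$mother_id),
    sex    = ifelse(is.na(ped$sex), 0L, ped$sex),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, quote = FALSE, sep = " ",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Founders = individuals with both parents missing.
is_founder <- function(ped) is.na(ped$father_id) & is.na(ped$mother_id)
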