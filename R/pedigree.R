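#' Read a trio pedigree file
#'
#' Parses a tab-separated pedigree with columns `trio_id`, `child`, `mother`,
#' `father` and optional `mother_age`, `father_age` (parental ages in years at
#' the child's birth). A header line is optional; columns are matched by name
#' when present and by position otherwise.
#'
#' @param path Path to the pedigree TSV.
#' @return A tibble with one row per trio: `trio_id`, `child_id`, `mother_id`,
#'   `father_id`, `mother_age`, `father_age` (ages `NA` when absent).
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) abort(paste0("pedigree file not found: ", path))
  raw <- utils::read.table(path, header = FALSE,
                           colClasses = "character", fill = TRUE,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (nrow(raw) == 0) abort("pedigree file is empty")
  has_header <- identical(tolower(raw[1, 1]), "trio_id")
  if (has_header) raw <- raw[-1, , drop = FALSE]
  if (ncol(raw) < 4) abort("pedigree needs at least trio_id, child, mother, father columns")
  ped <- tibble(
    trio_id   = raw[[1]],
    child_id  = raw[[2]],
    mother_id = raw[[3]],
    father_id = raw[[4]],
    mother_age = if (ncol(raw) >= 5) suppressWarnings(as.numeric(raw[[5]])) else NA_real_,
    father_age = if (ncol(raw) >= 6) suppressWarnings(as.numeric(raw[[6]])) else NA_real_
  )
  validate_pedigree(ped)
  ped
}

validate_pedigree <- function(ped) {
  if (anyDuplicated(ped$trio_id)) {
    abort(paste0("duplicate trio_id: ",
                 paste(unique(ped$trio_id[duplicated(ped$trio_id)]), collapse = ", ")))
  }
  self_parent <- ped$child_id == ped$mother_id | ped$child_id == ped$father_id |
    ped$mother_id == ped$father_id
  if (any(self_parent)) {
    abort(paste0("trio with non-distinct sample ids: ",
                 paste(ped$trio_id[self_parent], collapse = ", ")))
  }
  for (col in c("mother_age", "father_age")) {
    age <- ped[[col]]
    bad <- !is.na(age) & (age < 10 | age > 100)
    if (any(bad)) abort(paste0(col, " outside [10, 100] for trio ",
                               paste(ped$trio_id[bad], collapse = ", ")))
  }
  invisible(ped)
}

#' Write a pedigree tibble to TSV
#'
#' @param ped Tibble as returned by [read_pedigree()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  readr::write_tsv(
    ped %>% select("trio_id", "child_id", "mother_id", "father_id",
                   "mother_age", "father_age"),
    path, col_names = TRUE)
  invisible(path)
}
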