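#' Write a candidate DNM report to TSV
#'
#' Writes the tab-separated candidate report with a fixed column set and a
#' deterministic ordering by (trio_id, chrom, pos), so repeated runs produce
#' byte-identical files.
#'
#' @param candidates Candidate DNM tibble (see [detect_candidates()]); must
#'   contain `trio_id`, `chrom`, `pos`, `ref`, `alt`, `variant_class`,
#'   `config`, `substitution`, `ts_tv`, `filter_status`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dnm_report <- function(candidates, path) {
  cols <- c("trio_id", "chrom", "pos", "ref", "alt", "variant_class",
            "config", "substitution", "ts_tv", "filter_status")
  if (nrow(candidates) == 0) {
    candidates <- tibble(trio_id = character(), chrom = character(),
                         pos = numeric(), ref = character(), alt = character(),
                         variant_class = character(), config = character(),
                         substitution = character(), ts_tv = character(),
                         filter_status = character())
  }
  missing_cols <- setdiff(cols, names(candidates))
  for (mc in missing_cols) candidates[[mc]] <- NA_character_
  out <- candidates %>%
    select(all_of(cols)) %>%
    arrange(.data$trio_id, .data$chrom, .data$pos)
  readr::write_tsv(out, path, na = "NA")
  invisible(path)
}

#' Read a candidate DNM report written by [write_dnm_report()]
#'
#' @param path Path to the TSV report.
#' @return Tibble with the report columns.
#' @export
read_dnm_report <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    trio_id = readr::col_character(),
    chrom = readr::col_character(),
    pos = readr::col_double(),
    ref = readr::col_character(),
    alt = readr::col_character(),
    variant_class = readr::col_character(),
    config = readr::col_character(),
    substitution = readr::col_character(),
    ts_tv = readr::col_character(),
    filter_status = readr::col_character()
  ))
}

#' Write per-trio callable-probability sums
#'
#' Caches the per-trio denominator contributions (sums of per-site callable
#' probabilities for SNVs and indels) so rate estimation can re-run without
#' touching the VCFs.
#'
#' @param sums Tibble with `trio_id`, `p_snv_sum`, `p_indel_sum`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_callable_sums <- function(sums, path) {
  readr::write_tsv(sums %>% select("trio_id", "p_snv_sum", "p_indel_sum"), path)
  invisible(path)
}

#' @rdname write_callable_sums
#' @export
read_callable_sums <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    trio_id = readr::col_character(),
    p_snv_sum = readr::col_double(),
    p_indel_sum = readr::col_double()
  ))
}
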