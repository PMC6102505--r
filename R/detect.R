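#' Detect Mendelian-violation candidate DNMs
#'
#' Scans trio site records for the three genotype configurations that cannot
#' arise by Mendelian inheritance and therefore indicate a candidate de novo
#' mutation:
#'
#' * child `Het`, both parents `HomR` — the child carries an alternate allele
#'   absent from both parents (`het_child_homref_parents`);
#' * child `Het`, both parents `HomA` — the child carries a reference allele
#'   absent from both parents (`het_child_homalt_parents`);
#' * child `HomR`, both parents `HomA`, indel allele — the "reversible" indel
#'   configuration in which both parents are homozygous for a non-reference
#'   indel and the child reverts to the reference (`reversible_indel`).
#'
#' All other configurations are consistent with inheritance and yield no
#' candidate. Records with any `Missing` genotype violate the precondition;
#' pre-filter with [drop_missing_records()].
#'
#' @param records Trio site record tibble with a `trio_id` column (add one
#'   before calling when reading per-trio VCFs).
#' @return Tibble of candidates: the key and evidence columns of `records`
#'   plus `variant_class` (`SNV`/`indel`), `config`, `substitution`
#'   (e.g. `"A>G"`, `NA` for indels) and `ts_tv`
#'   (`transition`/`transversion`/`NA`).
#' @export
detect_candidates <- function(records) {
  if (nrow(records) == 0) return(mutate(records, variant_class = character(0),
                                        config = character(0),
                                        substitution = character(0),
                                        ts_tv = character(0)))
  if (any(records$child_gt == "Missing" | records$mother_gt == "Missing" |
            records$father_gt == "Missing")) {
    abort("records contain Missing genotypes; apply drop_missing_records() first")
  }
  is_indel <- nchar(records$ref) != 1 | nchar(records$alt) != 1
  config <- dplyr::case_when(
    records$child_gt == "Het" & records$mother_gt == "HomR" &
      records$father_gt == "HomR" ~ "het_child_homref_parents",
    records$child_gt == "Het" & records$mother_gt == "HomA" &
      records$father_gt == "HomA" ~ "het_child_homalt_parents",
    records$child_gt == "HomR" & records$mother_gt == "HomA" &
      records$father_gt == "HomA" & is_indel ~ "reversible_indel",
    TRUE ~ NA_character_
  )
  out <- records[!is.na(config), , drop = FALSE]
  out$config <- config[!is.na(config)]
  is_indel <- is_indel[!is.na(config)]
  out$variant_class <- ifelse(is_indel, "indel", "SNV")
  out$substitution <- ifelse(is_indel, NA_character_,
                             paste0(out$ref, ">", out$alt))
  out$ts_tv <- NA_character_
  if (any(!is_indel)) {
    out$ts_tv[!is_indel] <- classify_substitution(out$ref[!is_indel],
                                                  out$alt[!is_indel])
  }
  as_tibble(out)
}

#' Classify a substitution as transition or transversion
#'
#' Transitions are purine-purine (A<->G) or pyrimidine-pyrimidine (C<->T)
#' exchanges; all other single-base substitutions are transversions. Indel
#' allele pairs return `NA`.
#'
#' @param ref,alt Character vectors of reference and alternate alleles.
#' @return Character vector: `"transition"`, `"transversion"` or `NA`
#'   (indels).
#' @export
#' @examples
#' classify_substitution(c("A", "A", "AC"), c("G", "T", "A"))
classify_substitution <- function(ref, alt) {
  n <- max(length(ref), length(alt))
  ref <- rep_len(toupper(ref), n)
  alt <- rep_len(toupper(alt), n)
  is_indel <- nchar(ref) != 1 | nchar(alt) != 1
  snv_ref <- ref[!is_indel]
  snv_alt <- alt[!is_indel]
  if (any(!snv_ref %in% c("A", "C", "G", "T")) ||
        any(!snv_alt %in% c("A", "C", "G", "T"))) {
    abort("non-ACGT base in single-nucleotide substitution")
  }
  purine <- c("A", "G")
  out <- rep(NA_character_, n)
  same_class <- (snv_ref %in% purine) == (snv_alt %in% purine)
  out[!is_indel] <- ifelse(same_class, "transition", "transversion")
  out
}

#' Apply quality filters to candidate DNMs
#'
#' Applies the candidate filters to every trio member: genotype quality
#' `>= min_gq`, read depth strictly `> min_depth_exclusive`, and an
#' allele-balance consistency rule. Heterozygous members must have allele
#' balance (alt reads / informative reads) inside `[ab_low, ab_high]`
#' (inclusive); homozygous-reference members must fall below `ab_low` and
#' homozygous-alternate members above `ab_high`, since a mid-range allele
#' balance in a homozygous parent indicates a missed heterozygote. The
#' allele-balance rule is evaluated only for members with at least one
#' informative read. The first failing rule (checked in the order `min_gq`,
#' `min_depth`, `allele_balance`) is recorded.
#'
#' @param candidates Candidate tibble from [detect_candidates()] carrying the
#'   per-member evidence columns.
#' @param thresholds A [filter_thresholds()] object.
#' @return `candidates` with a `filter_status` column: `"pass"` or the first
#'   failing rule.
#' @export
apply_filters <- function(candidates, thresholds = filter_thresholds()) {
  stopifnot(inherits(thresholds, "filter_thresholds"))
  if (nrow(candidates) == 0) {
    candidates$filter_status <- character(0)
    return(candidates)
  }
  members <- c("child", "mother", "father")
  gq_ok <- depth_ok <- ab_ok <- rep(TRUE, nrow(candidates))
  for (m in members) {
    gt <- candidates[[paste0(m, "_gt")]]
    gq <- candidates[[paste0(m, "_gq")]]
    dp <- candidates[[paste0(m, "_dp")]]
    rr <- candidates[[paste0(m, "_ref_reads")]]
    ar <- candidates[[paste0(m, "_alt_reads")]]
    gq_ok <- gq_ok & gq >= thresholds$min_gq
    depth_ok <- depth_ok & dp > thresholds$min_depth_exclusive
    informative <- (rr + ar) > 0
    ab <- ifelse(informative, ar / (rr + ar), NA_real_)
    member_ab_ok <- dplyr::case_when(
      !informative ~ TRUE,
      gt == "Het" ~ ab >= thresholds$ab_low & ab <= thresholds$ab_high,
      gt == "HomR" ~ ab < thresholds$ab_low,
      gt == "HomA" ~ ab > thresholds$ab_high,
      TRUE ~ TRUE
    )
    ab_ok <- ab_ok & member_ab_ok
  }
  candidates$filter_status <- dplyr::case_when(
    !gq_ok ~ "min_gq",
    !depth_ok ~ "min_depth",
    !ab_ok ~ "allele_balance",
    TRUE ~ "pass"
  )
  candidates
}

#' Flag trios with an anomalously high DNM count
#'
#' A trio whose candidate count lies in the extreme upper tail of a Poisson
#' distribution around the expected per-trio mean is flagged for review (for
#' example, an excess consistent with non-paternity). A trio is flagged when
#' `P(X >= count | lambda = expected_mean) < alpha`. Flagging is advisory;
#' no trio is excluded automatically.
#'
#' @param per_trio_counts Tibble with `trio_id` and `n_dnm` columns (counts
#'   may include trios with zero candidates).
#' @param expected_mean Expected DNM count per trio (`> 0`).
#' @param alpha Upper-tail probability threshold; default `1e-6`.
#' @return Tibble of flagged trios with `trio_id`, `n_dnm` and the Poisson
#'   upper-tail `p_value`.
#' @export
flag_outlier_trios <- function(per_trio_counts, expected_mean, alpha = 1e-6) {
  stopifnot(expected_mean > 0, all(per_trio_counts$n_dnm >= 0))
  tail_p <- ppois(per_trio_counts$n_dnm - 1, lambda = expected_mean,
                  lower.tail = FALSE)
  per_trio_counts %>%
    mutate(p_value = tail_p) %>%
    filter(.data$p_value < alpha) %>%
    select("trio_id", "n_dnm", "p_value")
}
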