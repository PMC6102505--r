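#' Read trio genotype records from a multi-sample VCF
#'
#' Extracts per-site genotype evidence for the three members of one trio from
#' a VCF with `GT`, `DP`, `AD` and `GQ` FORMAT fields. Multiallelic records
#' are decomposed into one record per alternate allele: relative to alt `k`, a
#' sample is `HomR` when neither of its alleles is `k`, `Het` when exactly one
#' is, and `HomA` when both are. Genotypes with any missing allele, or with a
#' missing FORMAT field, become `Missing` (with a warning for missing FORMAT
#' fields).
#'
#' @param path Path to a VCF 4.x file containing all three trio samples.
#' @param trio One-row tibble (or list) with `child_id`, `mother_id`,
#'   `father_id` naming samples in the VCF header.
#' @return A tibble of trio site records, in file order, one row per
#'   site-by-alt combination, with columns `chrom`, `pos`, `ref`, `alt` and,
#'   for each of `child`/`mother`/`father`: `_gt` (HomR/Het/HomA/Missing),
#'   `_dp`, `_ref_reads`, `_alt_reads`, `_gq`.
#' @export
read_trio_vcf <- function(path, trio) {
  if (!file.exists(path)) abort(paste0("VCF not found: ", path))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(vcf@gt)[-1]
  members <- c(child = trio$child_id[[1]], mother = trio$mother_id[[1]],
               father = trio$father_id[[1]])
  missing <- members[!members %in% samples]
  if (length(missing) > 0) {
    abort(paste0("trio sample(s) not in VCF header: ",
                 paste(missing, collapse = ", ")))
  }
  fix <- vcf@fix
  n_rec <- nrow(fix)
  if (is.null(n_rec) || n_rec == 0) {
    return(empty_trio_records())
  }

  gt <- vcfR::extract.gt(vcf, element = "GT")
  dp <- suppressWarnings(vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE))
  gq <- suppressWarnings(vcfR::extract.gt(vcf, element = "GQ", as.numeric = TRUE))
  ad <- vcfR::extract.gt(vcf, element = "AD")

  alts <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  n_alt <- lengths(alts)
  rec_idx <- rep.int(seq_len(n_rec), n_alt)   # source record per output row
  alt_k <- unlist(lapply(n_alt, seq_len))     # which alt within the record

  out <- tibble(
    chrom = unname(fix[rec_idx, "CHROM"]),
    pos = as.numeric(fix[rec_idx, "POS"]),
    ref = unname(fix[rec_idx, "REF"]),
    alt = unname(unlist(alts))
  )

  any_missing_format <- FALSE
  for (m in names(members)) {
    s <- members[[m]]
    gt_s <- unname(gt[, s][rec_idx])
    dp_s <- unname(dp[, s][rec_idx])
    gq_s <- unname(gq[, s][rec_idx])
    ad_s <- unname(ad[, s][rec_idx])

    alleles <- strsplit(gt_s, "[/|]")
    a1 <- suppressWarnings(as.integer(vapply(alleles, `[`, "", 1)))
    a2 <- suppressWarnings(as.integer(vapply(alleles, function(x) {
      if (length(x) >= 2) x[2] else NA_character_
    }, "")))

    n_k <- (a1 == alt_k) + (a2 == alt_k)
    gcall <- dplyr::case_when(
      is.na(a1) | is.na(a2) ~ "Missing",
      n_k == 0 ~ "HomR",
      n_k == 1 ~ "Het",
      TRUE ~ "HomA"
    )
    ad_fields <- strsplit(ifelse(is.na(ad_s), "", ad_s), ",", fixed = TRUE)
    ref_reads <- suppressWarnings(as.numeric(vapply(ad_fields, function(x) {
      if (length(x) >= 1) x[1] else NA_character_
    }, "")))
    alt_reads <- suppressWarnings(as.numeric(mapply(function(x, k) {
      if (length(x) >= k + 1) x[k + 1] else NA_character_
    }, ad_fields, alt_k)))

    bad_fmt <- gcall != "Missing" & (is.na(dp_s) | is.na(gq_s) |
                                       is.na(ref_reads) | is.na(alt_reads))
    if (any(bad_fmt)) {
      any_missing_format <- TRUE
      gcall[bad_fmt] <- "Missing"
    }
    out[[paste0(m, "_gt")]] <- gcall
    out[[paste0(m, "_dp")]] <- dp_s
    out[[paste0(m, "_ref_reads")]] <- ref_reads
    out[[paste0(m, "_alt_reads")]] <- alt_reads
    out[[paste0(m, "_gq")]] <- gq_s
  }
  if (any_missing_format) {
    warn("records with missing FORMAT fields: affected genotypes set to Missing")
  }
  out
}

empty_trio_records <- function() {
  cols <- c("chrom", "pos", "ref", "alt",
            paste0(rep(c("child", "mother", "father"), each = 5),
                   c("_gt", "_dp", "_ref_reads", "_alt_reads", "_gq")))
  out <- lapply(cols, function(x) if (x %in% c("chrom", "ref", "alt") ||
                                        grepl("_gt$", x)) character() else numeric())
  as_tibble(setNames(out, cols))
}

#' Drop records where any trio member's genotype is Missing
#'
#' Sites with an uncallable member contribute neither candidate calls nor
#' callable-probability mass, so both detection and the rate denominator
#' operate on the complete-genotype subset.
#'
#' @param records Trio site records from [read_trio_vcf()].
#' @return The subset of `records` with all three genotypes non-Missing.
#' @export
drop_missing_records <- function(records) {
  records %>%
    filter(.data$child_gt != "Missing",
           .data$mother_gt != "Missing",
           .data$father_gt != "Missing")
}

#' Write trio genotype records to a VCF file
#'
#' Serialises records produced by the simulator (or [read_trio_vcf()]) to a
#' minimal VCF 4.2 file with GT:DP:AD:GQ FORMAT fields and the three trio
#' samples as columns.
#'
#' @param records Trio site record tibble (biallelic rows).
#' @param trio One-row tibble with `child_id`, `mother_id`, `father_id`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trio_vcf <- function(records, trio, path) {
  gt_code <- c(HomR = "0/0", Het = "0/1", HomA = "1/1", Missing = "./.")
  fmt_member <- function(m) {
    g <- gt_code[records[[paste0(m, "_gt")]]]
    dp <- records[[paste0(m, "_dp")]]
    rr <- records[[paste0(m, "_ref_reads")]]
    ar <- records[[paste0(m, "_alt_reads")]]
    gq <- records[[paste0(m, "_gq")]]
    sprintf("%s:%d:%d,%d:%d", g, as.integer(dp), as.integer(rr),
            as.integer(ar), as.integer(gq))
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", trio$child_id[[1]], trio$mother_id[[1]],
          trio$father_id[[1]], sep = "\t")
  )
  body <- paste(records$chrom, format(records$pos, scientific = FALSE,
                                      trim = TRUE),
                ".", records$ref, records$alt, ".", "PASS", ".",
                "GT:DP:AD:GQ",
                fmt_member("child"), fmt_member("mother"), fmt_member("father"),
                sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
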