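#' Transition/transversion ratio of a DNM set
#'
#' @param candidates Candidate tibble with a `ts_tv` column (indels, with
#'   `NA`, are ignored).
#' @return Ratio of transition to transversion counts; `Inf` when there are
#'   transitions but no transversions.
#' @export
tstv_ratio <- function(candidates) {
  tstv <- candidates$ts_tv[!is.na(candidates$ts_tv)]
  if (length(tstv) == 0) abort("no single-nucleotide candidates: Ts/Tv undefined")
  n_ts <- sum(tstv == "transition")
  n_tv <- sum(tstv == "transversion")
  if (n_tv == 0) return(Inf)
  n_ts / n_tv
}

#' Substitution-spectrum counts
#'
#' @param candidates Candidate tibble with `substitution` and `ts_tv`.
#' @return Tibble of counts per substitution type, with its
#'   transition/transversion class.
#' @export
substitution_spectrum <- function(candidates) {
  candidates %>%
    filter(!is.na(.data$substitution)) %>%
    count(.data$substitution, .data$ts_tv, name = "n") %>%
    arrange(desc(.data$n))
}

#' Per-chromosome DNM distribution and its correlates
#'
#' Counts passing DNMs per chromosome, attaches the standard error of the
#' per-trio mean count, and tests (Pearson) whether per-chromosome counts
#' track gene density or chromosome length.
#'
#' @param candidates Candidate tibble with `trio_id` and `chrom`.
#' @param chrom_info Tibble with `chrom`, `length` and `gene_density`
#'   covering every chromosome present in `candidates`.
#' @param n_trios Number of trios contributing (used for the per-trio SEM;
#'   trios with zero DNMs on a chromosome count as zeros).
#' @return List with `table` (per-chromosome `n`, `mean_per_trio`, `sem`)
#'   and `correlations` (one row per predictor with Pearson `estimate` and
#'   two-sided `p_value`).
#' @export
per_chromosome_summary <- function(candidates, chrom_info, n_trios) {
  stopifnot(n_trios > 0, nrow(candidates) > 0)
  missing_chrom <- setdiff(unique(candidates$chrom), chrom_info$chrom)
  if (length(missing_chrom) > 0) {
    abort(paste0("chromosome(s) absent from chrom_info: ",
                 paste(missing_chrom, collapse = ", ")))
  }
  per_trio <- candidates %>%
    count(.data$chrom, .data$trio_id, name = "n_trio") %>%
    tidyr::complete(chrom = chrom_info$chrom,
                    trio_id = unique(candidates$trio_id),
                    fill = list(n_trio = 0))
  tab <- per_trio %>%
    group_by(.data$chrom) %>%
    summarise(
      n = sum(.data$n_trio),
      # zeros for trios never seen in `candidates` still dilute the mean
      mean_per_trio = sum(.data$n_trio) / n_trios,
      sem = stats::sd(c(.data$n_trio,
                        rep(0, max(0, n_trios - dplyr::n())))) / sqrt(n_trios),
      .groups = "drop") %>%
    left_join(chrom_info, by = "chrom") %>%
    arrange(match(.data$chrom, chrom_info$chrom))
  correlations <- purrr::map_dfr(c("gene_density", "length"), function(v) {
    if (stats::sd(tab$n) == 0) {
      # constant counts carry no association with any predictor
      return(tibble(predictor = v, estimate = 0, p_value = 1,
                    n_chrom = nrow(tab)))
    }
    ct <- cor.test(tab$n, tab[[v]], method = "pearson")
    tibble(predictor = v, estimate = unname(ct$estimate),
           p_value = ct$p.value, n_chrom = nrow(tab))
  })
  list(table = tab, correlations = correlations)
}

#' Mean number of DNMs per offspring
#'
#' @param candidates Candidate tibble (one row per DNM).
#' @param n_trios Number of offspring in the denominator.
#' @return Total DNMs divided by `n_trios`.
#' @export
per_person_mean <- function(candidates, n_trios) {
  stopifnot(n_trios > 0)
  nrow(candidates) / n_trios
}

# left-align an indel representation by trimming the shared suffix, then the
# shared prefix (advancing pos); identity on SNVs
normalize_allele <- function(pos, ref, alt) {
  n <- max(length(pos), length(ref), length(alt))
  pos <- rep_len(pos, n); ref <- rep_len(ref, n); alt <- rep_len(alt, n)
  for (i in seq_len(n)) {
    r <- strsplit(ref[i], "")[[1]]
    a <- strsplit(alt[i], "")[[1]]
    while (length(r) > 1 && length(a) > 1 && r[length(r)] == a[length(a)]) {
      r <- r[-length(r)]; a <- a[-length(a)]
    }
    while (length(r) > 1 && length(a) > 1 && r[1] == a[1]) {
      r <- r[-1]; a <- a[-1]; pos[i] <- pos[i] + 1
    }
    ref[i] <- paste(r, collapse = ""); alt[i] <- paste(a, collapse = "")
  }
  tibble(pos = pos, ref = ref, alt = alt)
}

#' Concordance between two candidate DNM sets
#'
#' Compares two call sets keyed on (trio, chromosome, position, ref, alt)
#' after left-aligning indel representations, and reports the shared count
#' together with several normalisations (different published concordance
#' figures use different denominators, so all are returned).
#'
#' @param set_a,set_b Candidate tibbles with `trio_id`, `chrom`, `pos`,
#'   `ref`, `alt`.
#' @return One-row tibble: `n_a`, `n_b`, `n_shared`, `n_union`, `jaccard`,
#'   `pct_of_union`, `pct_of_a`, `pct_of_b`.
#' @export
concordance <- function(set_a, set_b) {
  key <- function(df) {
    if (nrow(df) == 0) return(character(0))
    norm <- normalize_allele(df$pos, df$ref, df$alt)
    unique(paste(df$trio_id, df$chrom, norm$pos, norm$ref, norm$alt,
                 sep = ":"))
  }
  a <- key(set_a); b <- key(set_b)
  shared <- length(intersect(a, b))
  uni <- length(union(a, b))
  tibble(
    n_a = length(a), n_b = length(b), n_shared = shared, n_union = uni,
    jaccard = if (uni == 0) 0 else shared / uni,
    pct_of_union = if (uni == 0) 0 else 100 * shared / uni,
    pct_of_a = if (length(a) == 0) 0 else 100 * shared / length(a),
    pct_of_b = if (length(b) == 0) 0 else 100 * shared / length(b)
  )
}
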